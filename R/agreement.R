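#' Inter-annotator agreement on token identification
#'
#' Two annotators working independently over the same document need not mark
#' the same set of connective / AltLex tokens.  Identification agreement is
#' measured on overlapping tokens: tokens are paired one-to-one when their
#' span sets overlap in at least one character, and the agreement ratio is
#' the number of common tokens over common plus uncommon tokens,
#' `n_common / (n_a + n_b - n_common)`.  With 20 tokens from one annotator,
#' 30 from the other and 15 overlapping pairs, the ratio is 15/35 (43%).
#'
#' Pairing is greedy left-to-right over annotator A's tokens; among the
#' unmatched overlapping candidates from B the one with the earliest end is
#' chosen (ties broken by larger overlap, then by position).  For disjoint
#' token spans this greedy attains the maximum possible number of pairs;
#' `method = "exhaustive"` computes the maximum bipartite matching by
#' augmenting paths and is provided as an independent check.
#'
#' @param set_a,set_b lists of [span_set()]s, the tokens marked by each
#'   annotator in one document.
#' @param method `"greedy"` (default) or `"exhaustive"`.
#' @return An object of class `overlap_agreement`: a list with `n_a`, `n_b`,
#'   `n_common`, `n_union`, `ratio`, and `pairs` (two-column matrix of
#'   indices into `set_a` / `set_b`).
#' @export
match_connectives <- function(set_a, set_b, method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(is.list(set_a), is.list(set_b))
  n_a <- length(set_a); n_b <- length(set_b)
  ov <- matrix(0L, nrow = n_a, ncol = n_b)
  if (n_a > 0L && n_b > 0L) {
    for (i in seq_len(n_a)) {
      for (j in seq_len(n_b)) {
        ov[i, j] <- span_overlap_size(set_a[[i]], set_b[[j]])
      }
    }
  }
  pairs <- if (method == "greedy") {
    greedy_interval_matching(set_a, set_b, ov)
  } else {
    max_bipartite_matching(ov > 0L)
  }
  n_common <- nrow(pairs)
  n_union <- n_a + n_b - n_common
  structure(list(n_a = n_a, n_b = n_b, n_common = n_common,
                 n_union = n_union,
                 ratio = if (n_union == 0L) 1 else n_common / n_union,
                 pairs = pairs),
            class = "overlap_agreement")
}

#' @export
print.overlap_agreement <- function(x, ...) {
  cat(sprintf("<overlap_agreement> %d/%d = %.3f (A: %d, B: %d tokens)\n",
              x$n_common, x$n_union, x$ratio, x$n_a, x$n_b))
  invisible(x)
}

greedy_interval_matching <- function(set_a, set_b, ov) {
  n_a <- length(set_a); n_b <- length(set_b)
  if (n_a == 0L || n_b == 0L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  a_start <- vapply(set_a, function(s) if (length(s)) s$start[1L] else NA_integer_, 0L)
  b_end <- vapply(set_b, function(s) if (length(s)) max(s$end) else NA_integer_, 0L)
  taken <- logical(n_b)
  pa <- integer(); pb <- integer()
  for (i in order(a_start)) {
    cand <- which(!taken & ov[i, ] > 0L)
    if (length(cand) == 0L) next
    # earliest end first; larger overlap breaks ties
    cand <- cand[order(b_end[cand], -ov[i, cand], cand)]
    j <- cand[1L]
    taken[j] <- TRUE
    pa <- c(pa, i); pb <- c(pb, j)
  }
  matrix(c(pa, pb), ncol = 2L, dimnames = list(NULL, c("a", "b")))
}

# maximum bipartite matching via Kuhn's augmenting paths over a logical
# adjacency matrix; independent oracle for the greedy matcher
max_bipartite_matching <- function(adj) {
  n_a <- nrow(adj); n_b <- ncol(adj)
  match_b <- rep(NA_integer_, n_b)
  visited <- logical(n_b)
  augment <- function(i) {
    for (j in which(adj[i, ])) {
      if (visited[j]) next
      visited[j] <<- TRUE
      if (is.na(match_b[j]) || augment(match_b[j])) {
        match_b[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(n_a)) {
    visited <- logical(n_b)
    augment(i)
  }
  pb <- which(!is.na(match_b))
  matrix(c(match_b[pb], pb), ncol = 2L, dimnames = list(NULL, c("a", "b")))
}

#' Argument span agreement over matched relation pairs
#'
#' Computed only on the tokens where the annotators agreed (the pairing from
#' [match_connectives()], or Arg2-start-aligned pairs for implicit
#' relations; see [pair_implicit_records()]).  Under the `exact` criterion a
#' pair agrees when the two span sets cover the identical set of characters;
#' under the relaxed `partial` criterion one overlapping character suffices.
#'
#' @param pairs a list of two-element lists of [relation_record()]s
#'   (`list(a_record, b_record)`).
#' @param which `"Arg1"` or `"Arg2"`.
#' @param criterion `"exact"` or `"partial"`.
#' @return Agreement ratio (agreeing pairs / total pairs).
#' @export
argument_agreement <- function(pairs, which = c("Arg1", "Arg2"),
                               criterion = c("exact", "partial")) {
  which <- match.arg(which)
  criterion <- match.arg(criterion)
  if (length(pairs) == 0L) {
    stop("agreement ratio undefined on an empty pair list", call. = FALSE)
  }
  slot <- if (which == "Arg1") "arg1_spans" else "arg2_spans"
  agree <- vapply(pairs, function(p) {
    sa <- p[[1L]][[slot]]; sb <- p[[2L]][[slot]]
    if (criterion == "exact") {
      setequal(span_coverage(sa), span_coverage(sb))
    } else {
      spans_overlap(sa, sb)
    }
  }, logical(1L))
  mean(agree)
}

#' Sense labeling agreement (observed)
#'
#' Annotators may assign up to two senses per token; they are taken to agree
#' on a token if *at least one* sense is shared, compared at the leaf (31
#' category) granularity.
#'
#' @param pairs matched record pairs as in [argument_agreement()]; both
#'   records of every pair must carry `sense1`.
#' @return Observed agreement in `[0, 1]`.
#' @export
sense_observed_agreement <- function(pairs) {
  if (length(pairs) == 0L) {
    stop("agreement undefined on an empty pair list", call. = FALSE)
  }
  agree <- vapply(pairs, function(p) {
    sa <- record_senses(p[[1L]]); sb <- record_senses(p[[2L]])
    if (length(sa) == 0L || length(sb) == 0L) {
      stop("record without sense labels in sense agreement", call. = FALSE)
    }
    length(intersect(sa, sb)) > 0L
  }, logical(1L))
  mean(agree)
}

record_senses <- function(rec) {
  out <- character()
  if (!is.null(rec$sense1)) out <- c(out, format(rec$sense1))
  if (!is.null(rec$sense2)) out <- c(out, format(rec$sense2))
  out
}

#' Cohen's kappa for two aligned label sequences
#'
#' Observed agreement `Ao` is the fraction of identically labeled items;
#' expected (chance) agreement `Ae` is the match probability under
#' independent draws from each annotator's own marginal distribution
#' (Cohen's convention, not pooled marginals); kappa is
#' `(Ao - Ae) / (1 - Ae)`.
#'
#' @param labels_a,labels_b equal-length character vectors.
#' @return An object of class `kappa_result` with fields `observed`,
#'   `expected`, `kappa`, `n`.
#' @examples
#' cohens_kappa(c("x", "y", "x"), c("x", "y", "y"))
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  if (length(labels_a) != length(labels_b) || length(labels_a) == 0L) {
    stop("label vectors must be non-empty and of equal length", call. = FALSE)
  }
  n <- length(labels_a)
  ao <- mean(labels_a == labels_b)
  cats <- union(labels_a, labels_b)
  pa <- tabulate(match(labels_a, cats), length(cats)) / n
  pb <- tabulate(match(labels_b, cats), length(cats)) / n
  ae <- sum(pa * pb)
  if (ae >= 1) {
    stop("degenerate kappa: expected agreement is 1 (both annotators constant)",
         call. = FALSE)
  }
  structure(list(observed = ao, expected = ae,
                 kappa = kappa_from_rates(ao, ae), n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa> %.3f (Ao = %.3f, Ae = %.3f, n = %d)\n",
              x$kappa, x$observed, x$expected, x$n))
  invisible(x)
}

#' Kappa from observed and expected agreement rates
#'
#' Closed form `(ao - ae) / (1 - ae)`; e.g. observed agreement 0.85 with
#' expected agreement 0.48 gives kappa 0.71.
#'
#' @param ao observed agreement in `[0, 1]`.
#' @param ae expected (chance) agreement in `[0, 1)`.
#' @return Kappa value.
#' @examples
#' kappa_from_rates(0.85, 0.48)   # 0.71 (explicit/AltLex sense labeling)
#' kappa_from_rates(0.82, 0.52)   # 0.625 (implicit sense labeling)
#' @export
kappa_from_rates <- function(ao, ae) {
  stopifnot(is.numeric(ao), is.numeric(ae))
  if (any(ae >= 1)) {
    stop("expected agreement must be < 1", call. = FALSE)
  }
  if (any(ao < 0 | ao > 1) || any(ae < 0)) {
    stop("agreement rates must lie in [0, 1]", call. = FALSE)
  }
  (ao - ae) / (1 - ae)
}

#' Pair records of two annotators
#'
#' Explicit and AltLex records are paired through their connective spans via
#' [match_connectives()].  Implicit (and NoRel) records, which have no
#' connective anchor, are paired when their Arg2 start offsets coincide —
#' the Arg2 start is the conventional location identifier for such
#' relations.
#'
#' @param recs_a,recs_b lists of [relation_record()]s from one document.
#' @param type `"explicit"` (Explicit + AltLex, span-matched) or
#'   `"implicit"` (Arg2-start-matched).
#' @return List with `pairs` (list of record pairs) and, for the explicit
#'   route, the [match_connectives()] `overlap` object.
#' @export
pair_records <- function(recs_a, recs_b, type = c("explicit", "implicit")) {
  type <- match.arg(type)
  if (type == "explicit") {
    ra <- Filter(function(r) r$rel_type %in% c("Explicit", "AltLex"), recs_a)
    rb <- Filter(function(r) r$rel_type %in% c("Explicit", "AltLex"), recs_b)
    ov <- match_connectives(lapply(ra, `[[`, "conn_spans"),
                            lapply(rb, `[[`, "conn_spans"))
    pairs <- apply(ov$pairs, 1L, function(ij) list(ra[[ij[1L]]], rb[[ij[2L]]]),
                   simplify = FALSE)
    list(pairs = pairs, overlap = ov)
  } else {
    ra <- Filter(function(r) r$rel_type == "Implicit", recs_a)
    rb <- Filter(function(r) r$rel_type == "Implicit", recs_b)
    key <- function(r) r$arg2_spans$start[1L]
    ka <- vapply(ra, key, 0L); kb <- vapply(rb, key, 0L)
    common <- intersect(ka, kb)
    pairs <- lapply(common, function(k) {
      list(ra[[match(k, ka)]], rb[[match(k, kb)]])
    })
    list(pairs = pairs, overlap = NULL)
  }
}

#' Full agreement report for a doubly annotated corpus
#'
#' Computes, separately for explicit + AltLex and for implicit relations:
#' token identification overlap (explicit route only), Arg1/Arg2 agreement
#' under the exact and partial criteria, and sense agreement (observed
#' agreement, chance agreement and kappa over first-sense labels at leaf
#' granularity).
#'
#' @param corpus_a,corpus_b two [annotated_corpus()] objects over the same
#'   documents.
#' @return A data frame with one row per (relation group, statistic).
#' @export
agreement_report <- function(corpus_a, corpus_b) {
  stopifnot(is_corpus(corpus_a), is_corpus(corpus_b))
  ids <- intersect(names(corpus_a$documents), names(corpus_b$documents))
  rows <- list()
  for (grp in c("explicit", "implicit")) {
    pairs <- list(); n_c <- 0L; n_u <- 0L
    for (id in ids) {
      pr <- pair_records(corpus_a$documents[[id]]$relations,
                         corpus_b$documents[[id]]$relations, grp)
      pairs <- c(pairs, pr$pairs)
      if (!is.null(pr$overlap)) {
        n_c <- n_c + pr$overlap$n_common
        n_u <- n_u + pr$overlap$n_union
      }
    }
    add <- function(stat, value) {
      rows[[length(rows) + 1L]] <<- data.frame(
        group = grp, statistic = stat, value = value,
        stringsAsFactors = FALSE)
    }
    if (grp == "explicit") add("connective_overlap",
                               if (n_u == 0L) 1 else n_c / n_u)
    if (length(pairs) > 0L) {
      for (w in c("Arg1", "Arg2")) {
        for (cr in c("exact", "partial")) {
          add(paste(w, cr, sep = "_"), argument_agreement(pairs, w, cr))
        }
      }
      sensed <- Filter(function(p) {
        length(record_senses(p[[1L]])) > 0L && length(record_senses(p[[2L]])) > 0L
      }, pairs)
      if (length(sensed) > 0L) {
        add("sense_observed", sense_observed_agreement(sensed))
        la <- vapply(sensed, function(p) format(p[[1L]]$sense1), "")
        lb <- vapply(sensed, function(p) format(p[[2L]]$sense1), "")
        kp <- cohens_kappa(la, lb)
        add("sense_kappa", kp$kappa)
        add("sense_expected", kp$expected)
      }
    }
  }
  do.call(rbind, rows)
}
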