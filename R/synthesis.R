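#' Synthetic corpus configuration
#'
#' Describes the generating distribution of a synthetic relation bank.  The
#' defaults state a corpus shaped like the reference bank: the relation-type
#' mix (2636 explicit / 3001 implicit / 193 AltLex / 29 NoRel over 24
#' documents), per-connective sense conditionals built from the published
#' ambiguity inventory (the first-listed sense receives probability 0.7,
#' the remainder is spread uniformly), a 7.4% multiple-sense rate with
#' ordered sense pairs drawn from the published pair inventory, and IMRAD
#' section quotas proportional to the published segment distribution.
#'
#' @param n_relations named integer vector with entries `Explicit`,
#'   `Implicit`, `AltLex`, `NoRel`.
#' @param connectives list of entries `list(conn =, weight =, senses =)`
#'   where `senses` is a named probability vector over type-level senses
#'   (rows must sum to 1 within 1e-9).
#' @param implicit_senses named non-negative weights over type-level senses
#'   for implicit relations.
#' @param altlex list of entries `list(expr =, sense =, weight =)`.
#' @param multi_sense_rate probability that an explicit/AltLex token
#'   receives a second sense.
#' @param pair_table named list: sense1 type -> candidate sense2 types.
#' @param sections named numeric section quotas, in document order;
#'   normalized to sum to 1.
#' @param n_docs number of documents.
#' @param seed integer RNG seed; the same seed yields byte-identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_relations = c(Explicit = 2636L, Implicit = 3001L,
                                         AltLex = 193L, NoRel = 29L),
                         connectives = default_connectives(),
                         implicit_senses = default_implicit_senses(),
                         altlex = default_altlex(),
                         multi_sense_rate = 0.074,
                         pair_table = default_pair_table(),
                         sections = default_sections(),
                         n_docs = 24L,
                         seed = 42L) {
  stopifnot(all(c("Explicit", "Implicit", "AltLex", "NoRel") %in%
                  names(n_relations)))
  n_relations <- n_relations[c("Explicit", "Implicit", "AltLex", "NoRel")]
  if (any(n_relations < 0L)) stop("relation counts must be non-negative",
                                  call. = FALSE)
  if (n_docs < 1L) stop("need at least one document", call. = FALSE)
  if (multi_sense_rate < 0 || multi_sense_rate > 1) {
    stop("multi_sense_rate must lie in [0, 1]", call. = FALSE)
  }
  types <- names(build_taxonomy())
  for (e in connectives) {
    if (abs(sum(e$senses) - 1) > 1e-9) {
      stop(sprintf("sense conditional of '%s' does not sum to 1", e$conn),
           call. = FALSE)
    }
    if (!all(names(e$senses) %in% types)) {
      stop(sprintf("unknown sense type in conditional of '%s'", e$conn),
           call. = FALSE)
    }
    if (e$conn %in% .filler_words) {
      stop(sprintf("connective '%s' collides with the filler lexicon",
                   e$conn), call. = FALSE)
    }
  }
  if (n_relations[["Explicit"]] > 0L && length(connectives) == 0L) {
    stop("explicit relations requested but no connectives configured",
         call. = FALSE)
  }
  sections <- sections / sum(sections)
  structure(list(n_relations = n_relations, connectives = connectives,
                 implicit_senses = implicit_senses, altlex = altlex,
                 multi_sense_rate = multi_sense_rate,
                 pair_table = pair_table, sections = sections,
                 n_docs = as.integer(n_docs), seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %s relations, %d connectives, %d docs, seed %d\n",
              paste(sprintf("%s=%d", names(x$n_relations), x$n_relations),
                    collapse = " "),
              length(x$connectives), x$n_docs, x$seed))
  invisible(x)
}

#' Default per-connective sense conditionals
#'
#' Built from the published ambiguity inventory (27 ambiguous connective
#' types with their type-level sense inventories and token counts used as
#' sampling weights; the first-listed sense gets probability 0.7, the rest
#' share 0.3 uniformly) plus five unambiguous connectives filling the
#' remaining 1308 explicit tokens so the ambiguous share is 1328/2636.
#'
#' @return List of connective entries, see [synth_config()].
#' @export
default_connectives <- function() {
  out <- lapply(.tab_ambiguity, function(e) {
    k <- length(e[[2L]])
    p <- c(0.7, rep(0.3 / (k - 1L), k - 1L))
    list(conn = e[[1L]], weight = as.numeric(e[[3L]]),
         senses = stats::setNames(p, e[[2L]]))
  })
  unambiguous <- list(
    list(conn = "because", weight = 400, senses = c(Cause = 1)),
    list(conn = "in order to", weight = 500, senses = c(Purpose = 1)),
    list(conn = "for example", weight = 100, senses = c(Instantiation = 1)),
    list(conn = "also", weight = 200, senses = c(Conjunction = 1)),
    list(conn = "in addition", weight = 108, senses = c(Conjunction = 1)))
  c(out, unambiguous)
}

#' Default implicit sense weights (published implicit sense distribution)
#' @export
default_implicit_senses <- function() {
  stats::setNames(as.numeric(.tab_senses_single$Implicit),
                  .tab_senses_single$sense)
}

default_altlex <- function() {
  w <- stats::setNames(as.numeric(.tab_senses_single$AltLex),
                       .tab_senses_single$sense)
  w <- w[w > 0]
  exprs <- c(Alternative = "an alternative explanation is",
             Background = "as previously described here",
             Cause = "these results suggest that",
             Circumstance = "under these conditions we",
             Concession = "despite this observation the",
             Conjunction = "a further observation is",
             Contrast = "a contrasting finding is",
             Instantiation = "one such example is",
             Purpose = "this approach enables the",
             Reinforcement = "consistent with this the",
             Restatement = "in other words the",
             Temporal = "at this point the")
  lapply(names(w), function(ty) {
    list(expr = unname(exprs[ty]), sense = ty, weight = unname(w[ty]))
  })
}

default_pair_table <- function() {
  tab <- split(.tab_senses_multi$sense2, .tab_senses_multi$sense1)
  lapply(tab, unique)
}

default_sections <- function() {
  tot <- colSums(.tab_imrad[, c("Abstract", "Introduction", "Methods",
                                "Results", "Discussion")])
  tot / sum(tot)
}

# ---- text realization -------------------------------------------------

new_doc_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$pieces <- character()
  env$cur <- 0L
  env
}

db_add <- function(db, text) {
  n <- nchar(text)
  db$pieces[length(db$pieces) + 1L] <- text
  span <- c(db$cur, db$cur + n)
  db$cur <- db$cur + n
  span
}

db_text <- function(db) paste(db$pieces, collapse = "")

draw_leaf <- function(type, taxonomy) {
  subs <- taxonomy[[type]]
  if (length(subs) == 0L) sense_label(type)
  else sense_label(type, if (length(subs) == 1L) subs else sample(subs, 1L))
}

sample_weighted <- function(names, weights) {
  if (length(names) == 1L) names else sample(names, 1L, prob = weights)
}

#' Generate a synthetic annotated corpus
#'
#' Produces documents of filler sentences with connective strings planted at
#' recorded character offsets, so that every annotation has a known ground
#' truth: extracting a connective span yields exactly the planted string,
#' sense draws follow the configured per-connective conditionals, and every
#' record passes [validate_record()].  Documents are divided into contiguous
#' rhetorical sections per the configured quotas, recorded both as per-record
#' labels and as per-document section ranges (round-tripped through the
#' `.sec` sidecar by [write_corpus()] / [read_corpus()]).  Generation is
#' fully seeded: the same configuration yields byte-identical output.
#'
#' @param cfg a [synth_config()].
#' @return An [annotated_corpus()].
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  taxonomy <- build_taxonomy()
  local_seed(cfg$seed, {
    conn_w <- vapply(cfg$connectives, `[[`, 0, "weight")
    alt_w <- vapply(cfg$altlex, `[[`, 0, "weight")
    imp_w <- cfg$implicit_senses[cfg$implicit_senses > 0]
    if (cfg$n_relations[["Implicit"]] > 0L && length(imp_w) == 0L) {
      stop("implicit relations requested but implicit sense weights are all zero",
           call. = FALSE)
    }
    if (cfg$n_relations[["AltLex"]] > 0L && length(cfg$altlex) == 0L) {
      stop("AltLex relations requested but no expressions configured",
           call. = FALSE)
    }
    rel_seq <- sample(rep(names(cfg$n_relations), cfg$n_relations))
    doc_of <- sort(rep_len(seq_len(cfg$n_docs), length(rel_seq)))
    docs <- list()
    for (d in seq_len(cfg$n_docs)) {
      db <- new_doc_builder()
      units <- rel_seq[doc_of == d]
      nu <- length(units)
      # contiguous section blocks per quota
      bounds <- round(cumsum(cfg$sections) * nu)
      section_of <- if (nu > 0L) {
        cut(seq_len(nu), breaks = c(0L, bounds), labels = names(cfg$sections))
      } else factor()
      relations <- vector("list", nu)
      unit_start <- integer(nu); unit_end <- integer(nu)
      for (i in seq_len(nu)) {
        unit_start[i] <- db$cur
        rel <- units[i]
        a1 <- paste(sample(.filler_words, sample(4:8, 1L), replace = TRUE),
                    collapse = " ")
        a2 <- paste(sample(.filler_words, sample(4:8, 1L), replace = TRUE),
                    collapse = " ")
        if (rel == "Explicit") {
          e <- cfg$connectives[[
            sample_weighted(seq_along(cfg$connectives), conn_w)]]
          s1_type <- sample_weighted(names(e$senses), e$senses)
          sp1 <- db_add(db, a1); db_add(db, " ")
          spc <- db_add(db, e$conn); db_add(db, " ")
          sp2 <- db_add(db, a2); db_add(db, ". ")
          rec <- relation_record("Explicit",
                                 arg1_spans = span_set(sp1[1L], sp1[2L]),
                                 arg2_spans = span_set(sp2[1L], sp2[2L]),
                                 conn_spans = span_set(spc[1L], spc[2L]),
                                 sense1 = draw_leaf(s1_type, taxonomy))
        } else if (rel == "AltLex") {
          e <- cfg$altlex[[sample_weighted(seq_along(cfg$altlex), alt_w)]]
          sp1 <- db_add(db, a1); db_add(db, ". ")
          spc <- db_add(db, e$expr); db_add(db, " ")
          sp2 <- db_add(db, a2); db_add(db, ". ")
          rec <- relation_record("AltLex",
                                 arg1_spans = span_set(sp1[1L], sp1[2L]),
                                 arg2_spans = span_set(spc[1L], sp2[2L]),
                                 conn_spans = span_set(spc[1L], spc[2L]),
                                 sense1 = draw_leaf(e$sense, taxonomy))
        } else if (rel == "Implicit") {
          ty <- sample_weighted(names(imp_w), imp_w)
          conn_str <- if (ty %in% c("Continuation", "Background",
                                    "Circumstance")) {
            "NONE"
          } else {
            default_implicit_conn(ty)
          }
          sp1 <- db_add(db, a1); db_add(db, ". ")
          sp2 <- db_add(db, a2); db_add(db, ". ")
          rec <- relation_record("Implicit",
                                 arg1_spans = span_set(sp1[1L], sp1[2L]),
                                 arg2_spans = span_set(sp2[1L], sp2[2L]),
                                 implicit_conn = conn_str,
                                 sense1 = draw_leaf(ty, taxonomy))
        } else {
          sp1 <- db_add(db, a1); db_add(db, ". ")
          sp2 <- db_add(db, a2); db_add(db, ". ")
          rec <- relation_record("NoRel",
                                 arg1_spans = span_set(sp1[1L], sp1[2L]),
                                 arg2_spans = span_set(sp2[1L], sp2[2L]))
        }
        # optional second sense for explicit/AltLex tokens
        if (rel %in% c("Explicit", "AltLex") &&
            stats::runif(1L) < cfg$multi_sense_rate) {
          cand <- cfg$pair_table[[rec$sense1$type]]
          if (is.null(cand)) {
            cand <- setdiff(names(taxonomy), rec$sense1$type)
          }
          rec$sense2 <- draw_leaf(sample_weighted(cand, rep(1, length(cand))),
                                  taxonomy)
        }
        rec$doc_id <- sprintf("doc%02d", d)
        rec$section <- as.character(section_of[i])
        relations[[i]] <- rec
        unit_end[i] <- db$cur
      }
      sections <- NULL
      if (nu > 0L) {
        seg <- as.character(section_of)
        sections <- do.call(rbind, lapply(unique(seg), function(s) {
          idx <- which(seg == s)
          data.frame(start = unit_start[idx[1L]],
                     end = unit_end[idx[length(idx)]],
                     label = s, stringsAsFactors = FALSE)
        }))
      }
      docs[[sprintf("doc%02d", d)]] <- list(text = db_text(db),
                                            relations = relations,
                                            sections = sections)
    }
    annotated_corpus(docs)
  })
}

default_implicit_conn <- function(type) {
  map <- c(Cause = "because", Condition = "if", Purpose = "in order to",
           Temporal = "then", Concession = "nevertheless",
           Contrast = "however", Alternative = "alternatively",
           Instantiation = "for example", Conjunction = "in addition",
           Exception = "except that", Similarity = "similarly",
           Restatement = "specifically", Reinforcement = "indeed")
  out <- unname(map[type])
  if (is.na(out)) "that is" else out
}

#' Second-annotator noise configuration
#'
#' @param span_jitter_p probability that a record's argument spans are
#'   jittered (the Arg1 start and Arg2 end are each moved by at least one
#'   and at most `jitter_max` characters, within document bounds).
#' @param jitter_max maximum jitter width in characters.
#' @param delete_p probability that an explicit/AltLex token is missed
#'   (dropped) by the second annotator.
#' @param insert_p probability, per explicit token, that the second
#'   annotator additionally marks a spurious connective (a filler-word span
#'   inside Arg1, so it never overlaps a true connective).
#' @param sense_confusion_p probability that the first sense is replaced by
#'   a different label (uniform over the alternatives at the label's own
#'   granularity; for implicit records with the `"NONE"` marker the
#'   replacement stays within the three marker-compatible types).
#' @param seed integer RNG seed.
#' @return An object of class `perturb_config`.
#' @export
perturb_config <- function(span_jitter_p = 0, jitter_max = 3L,
                           delete_p = 0, insert_p = 0,
                           sense_confusion_p = 0, seed = 1L) {
  for (p in c(span_jitter_p, delete_p, insert_p, sense_confusion_p)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (jitter_max < 1L) stop("jitter_max must be at least 1", call. = FALSE)
  structure(list(span_jitter_p = span_jitter_p,
                 jitter_max = as.integer(jitter_max),
                 delete_p = delete_p, insert_p = insert_p,
                 sense_confusion_p = sense_confusion_p,
                 seed = as.integer(seed)),
            class = "perturb_config")
}

jitter_offset <- function(value, lo, hi, width) {
  # move value by a nonzero amount within [lo, hi]; NA if impossible
  deltas <- setdiff(seq.int(-width, width), 0L)
  cand <- value + deltas
  cand <- cand[cand >= lo & cand <= hi]
  if (length(cand) == 0L) return(NA_integer_)
  if (length(cand) == 1L) cand else sample(cand, 1L)
}

confuse_sense <- function(label, taxonomy, allowed_types = NULL) {
  pool <- if (is.null(allowed_types)) names(taxonomy) else allowed_types
  if (is.na(label$subtype) && length(taxonomy[[label$type]]) > 0L) {
    # type-level label (aggregate-table granularity): substitute the type
    types <- setdiff(pool, label$type)
    if (length(types) == 0L) return(label)
    sense_label(if (length(types) == 1L) types else sample(types, 1L))
  } else {
    # leaf label: substitute within the leaf space so strict validity holds
    leaves <- taxonomy_leaves(taxonomy)
    leaves <- leaves[sub("\\..*$", "", leaves) %in% pool]
    leaves <- setdiff(leaves, format(label))
    if (length(leaves) == 0L) return(label)
    pick <- if (length(leaves) == 1L) leaves else sample(leaves, 1L)
    parse_sense(pick, taxonomy)
  }
}

#' Derive a noisy second-annotator corpus
#'
#' Applies the configured noise processes independently to every record of a
#' (typically generated) corpus: missed and spurious explicit tokens, span
#' jitter on argument boundaries, and sense substitution.  The source texts
#' are untouched — both "annotators" annotate the same documents — and every
#' emitted record remains structurally valid (jitter that would produce an
#' empty or out-of-bounds span is redrawn, AltLex containment is preserved).
#' Seeded and reproducible.
#'
#' @param corpus an [annotated_corpus()].
#' @param cfg a [perturb_config()].
#' @return A new [annotated_corpus()] over the same documents.
#' @export
perturb_annotations <- function(corpus, cfg) {
  stopifnot(is_corpus(corpus), inherits(cfg, "perturb_config"))
  taxonomy <- build_taxonomy()
  nonelike <- c("Continuation", "Background", "Circumstance")
  local_seed(cfg$seed, {
    docs <- corpus$documents
    for (id in names(docs)) {
      doc <- docs[[id]]
      n <- nchar(doc$text)
      out <- list()
      for (rec in doc$relations) {
        if (rec$rel_type %in% c("Explicit", "AltLex") &&
            stats::runif(1L) < cfg$delete_p) {
          next
        }
        nr <- rec
        if (!is.null(nr$sense1) && stats::runif(1L) < cfg$sense_confusion_p) {
          allowed <- if (identical(nr$implicit_conn, "NONE")) nonelike
          nr$sense1 <- confuse_sense(nr$sense1, taxonomy, allowed)
        }
        if (stats::runif(1L) < cfg$span_jitter_p) {
          a1 <- nr$arg1_spans
          new_start <- jitter_offset(a1$start[1L], 0L,
                                     a1$end[1L] - 1L, cfg$jitter_max)
          if (!is.na(new_start)) {
            a1$start[1L] <- new_start
            nr$arg1_spans <- a1
          }
          a2 <- nr$arg2_spans
          k <- length(a2$start)
          lo <- a2$start[k] + 1L
          if (nr$rel_type == "AltLex" && !is.null(nr$conn_spans)) {
            lo <- max(lo, max(nr$conn_spans$end))
          }
          new_end <- jitter_offset(a2$end[k], lo, n, cfg$jitter_max)
          if (!is.na(new_end)) {
            a2$end[k] <- new_end
            nr$arg2_spans <- a2
          }
        }
        out[[length(out) + 1L]] <- nr
        if (nr$rel_type == "Explicit" && stats::runif(1L) < cfg$insert_p) {
          sp <- spurious_connective(rec, taxonomy)
          if (!is.null(sp)) {
            sp$doc_id <- rec$doc_id
            sp$section <- rec$section
            out[[length(out) + 1L]] <- sp
          }
        }
      }
      docs[[id]]$relations <- out
    }
    annotated_corpus(docs)
  })
}

spurious_connective <- function(rec, taxonomy) {
  a1 <- rec$arg1_spans
  if (a1$end[1L] - a1$start[1L] < 6L) return(NULL)
  s <- a1$start[1L] + 1L + sample.int(a1$end[1L] - a1$start[1L] - 5L, 1L)
  relation_record("Explicit",
                  arg1_spans = rec$arg1_spans,
                  arg2_spans = rec$arg2_spans,
                  conn_spans = span_set(s, s + 3L),
                  sense1 = draw_leaf(sample(names(taxonomy), 1L), taxonomy))
}

#' Closed-form optimum of the connective-only classifier
#'
#' With the connective string as the sole feature, the best attainable
#' accuracy on data drawn from a [synth_config()] is the Bayes rate of that
#' feature: the connective-marginal-weighted maximum of each per-connective
#' sense conditional,
#' `sum_c p(c) * max_l p(l | c)`, at the requested label granularity.  Used
#' as the independent oracle for classifier convergence tests.
#'
#' @param cfg a [synth_config()].
#' @param granularity `"class"` or `"type"`.
#' @param mapping a [pdtb_class_mapping()].
#' @return The optimum accuracy as a single number in `[0, 1]`.
#' @export
closed_form_bayes_rate <- function(cfg, granularity = c("class", "type"),
                                   mapping = pdtb_class_mapping()) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(cfg, "synth_config"))
  w <- vapply(cfg$connectives, `[[`, 0, "weight")
  p_conn <- w / sum(w)
  best <- vapply(cfg$connectives, function(e) {
    cond <- e$senses
    if (granularity == "class") {
      cond <- tapply(cond, unname(mapping[names(cond)]), sum)
    }
    max(cond)
  }, 0)
  sum(p_conn * best)
}
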