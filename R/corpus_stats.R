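#' @title Descriptive corpus statistics
#' @name corpus_stats
#' @description Reproducible summary tables over an annotated corpus:
#'   relation-type distribution, sense distributions split by relation type,
#'   contextual ambiguity of explicit connectives, and sense distributions
#'   across IMRAD rhetorical segments.  All tables are plain data frames of
#'   class `distribution_table`; percentages are always recomputed from the
#'   counts they describe.
NULL

distribution_table <- function(df, total, row_totals = NULL) {
  attr(df, "total") <- total
  if (!is.null(row_totals)) attr(df, "row_totals") <- row_totals
  class(df) <- c("distribution_table", "data.frame")
  df
}

#' @export
print.distribution_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  if (!is.null(attr(x, "total"))) cat("Total:", attr(x, "total"), "\n")
  invisible(x)
}

conn_surface <- function(rec, doc_text) {
  # case-insensitive connective identity; internal whitespace collapsed
  s <- extract_text(doc_text, rec$conn_spans)
  normalize_connective(s)
}

normalize_connective <- function(s) {
  tolower(gsub("[[:space:]]+", " ", trimws(s)))
}

#' Relation-type distribution
#'
#' Token counts, percentage of the corpus total and unique expression-type
#' counts per relation type.  Connective types are counted case-insensitively
#' over the surface strings, with modified forms distinct (e.g. *after* and
#' *one day after* are different types); implicit types are counted over the
#' annotator-inserted strings, excluding the `"NONE"` marker; NoRel has no
#' expression and no type count.
#'
#' @param corpus an [annotated_corpus()].
#' @return A `distribution_table` with columns `rel_type`, `tokens`, `pct`,
#'   `types`.
#' @export
relation_type_distribution <- function(corpus) {
  stopifnot(is_corpus(corpus))
  types <- c("Explicit", "Implicit", "AltLex", "NoRel")
  tokens <- stats::setNames(integer(4L), types)
  surfaces <- list(Explicit = character(), Implicit = character(),
                   AltLex = character())
  for (doc in corpus$documents) {
    for (rec in doc$relations) {
      tokens[rec$rel_type] <- tokens[rec$rel_type] + 1L
      if (rec$rel_type %in% c("Explicit", "AltLex")) {
        surfaces[[rec$rel_type]] <- c(surfaces[[rec$rel_type]],
                                      conn_surface(rec, doc$text))
      } else if (rec$rel_type == "Implicit" &&
                 !identical(rec$implicit_conn, "NONE")) {
        surfaces$Implicit <- c(surfaces$Implicit,
                               normalize_connective(rec$implicit_conn))
      }
    }
  }
  total <- sum(tokens)
  distribution_table(data.frame(
    rel_type = types,
    tokens = unname(tokens),
    pct = if (total == 0L) rep(0, 4L) else unname(100 * tokens / total),
    types = c(length(unique(surfaces$Explicit)),
              length(unique(surfaces$Implicit)),
              length(unique(surfaces$AltLex)), NA_integer_),
    stringsAsFactors = FALSE), total = total)
}

sense_key <- function(lab, granularity) {
  if (granularity == "type") lab$type else format(lab)
}

#' Sense distribution split by relation type
#'
#' Counts sense occurrences per relation type (Explicit / Implicit /
#' AltLex).  Records carrying a single sense are tallied under that sense;
#' records with two senses are listed separately under the *ordered* pair
#' `"Sense1/Sense2"` to expose the extent of multiple-sense annotation
#' (implicit relations never carry two senses).
#'
#' @param corpus an [annotated_corpus()].
#' @param granularity `"type"` (16 types, the granularity of aggregate
#'   tables) or `"leaf"` (31 categories).
#' @return A `distribution_table` with columns `sense`, `multi`, `Explicit`,
#'   `Implicit`, `AltLex`, `total`.
#' @export
sense_distribution <- function(corpus, granularity = c("type", "leaf")) {
  granularity <- match.arg(granularity)
  stopifnot(is_corpus(corpus))
  counts <- new.env(parent = emptyenv())
  bump <- function(key, col) {
    cur <- if (is.null(counts[[key]])) c(Explicit = 0L, Implicit = 0L,
                                         AltLex = 0L) else counts[[key]]
    cur[col] <- cur[col] + 1L
    counts[[key]] <- cur
  }
  for (rec in corpus_records(corpus, c("Explicit", "Implicit", "AltLex"))) {
    if (is.null(rec$sense1)) next
    key <- if (is.null(rec$sense2)) {
      sense_key(rec$sense1, granularity)
    } else {
      paste(sense_key(rec$sense1, granularity),
            sense_key(rec$sense2, granularity), sep = "/")
    }
    bump(key, rec$rel_type)
  }
  keys <- sort(ls(counts))
  multi <- grepl("/", keys, fixed = TRUE)
  keys <- c(keys[!multi], keys[multi])   # single-sense rows first
  m <- t(vapply(keys, function(k) counts[[k]], c(Explicit = 0L,
                                                 Implicit = 0L, AltLex = 0L)))
  df <- data.frame(sense = keys, multi = grepl("/", keys, fixed = TRUE),
                   Explicit = m[, "Explicit"], Implicit = m[, "Implicit"],
                   AltLex = m[, "AltLex"],
                   total = as.integer(rowSums(m)), row.names = NULL,
                   stringsAsFactors = FALSE)
  distribution_table(df, total = sum(df$total))
}

#' Contextual ambiguity of explicit connectives
#'
#' A connective type (case-insensitive surface string) is contextually
#' ambiguous when it occurs with two or more distinct type-level senses
#' across the corpus.  Only explicit relations are considered and, for
#' tokens annotated with two senses, only the first sense is used.
#'
#' @param corpus an [annotated_corpus()].
#' @return A `distribution_table` with one row per ambiguous connective
#'   type: `connective`, `n_senses`, `senses` (comma-joined type-level
#'   inventory), `tokens` (all tokens of that connective).  The `"total"`
#'   attribute is the grand token count over ambiguous types; the
#'   `"explicit_tokens"` attribute carries the explicit token total for
#'   share-of-corpus calculations.
#' @export
ambiguity_table <- function(corpus) {
  stopifnot(is_corpus(corpus))
  conns <- character(); senses <- character()
  for (doc in corpus$documents) {
    for (rec in doc$relations) {
      if (rec$rel_type != "Explicit" || is.null(rec$sense1)) next
      conns <- c(conns, conn_surface(rec, doc$text))
      senses <- c(senses, rec$sense1$type)
    }
  }
  n_explicit <- length(conns)
  rows <- list()
  for (cn in sort(unique(conns))) {
    inv <- sort(unique(senses[conns == cn]))
    if (length(inv) < 2L) next
    rows[[length(rows) + 1L]] <- data.frame(
      connective = cn, n_senses = length(inv),
      senses = paste(inv, collapse = ", "),
      tokens = sum(conns == cn), stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(connective = character(), n_senses = integer(),
               senses = character(), tokens = integer(),
               stringsAsFactors = FALSE)
  }
  out <- distribution_table(df, total = sum(df$tokens))
  attr(out, "explicit_tokens") <- n_explicit
  out
}

#' Normalize a rhetorical section label to its canonical IMRAD segment
#'
#' The five canonical segments are Introduction, Methods, Results,
#' Discussion and Abstract.  *Background* sections are counted together
#' with *Introduction* and *Materials and Methods* with *Methods*; sections
#' such as *Conclusions*, *Authors' Contributions* and figure/table
#' captions — and any unrecognized label — are `"excluded"`.
#'
#' @param raw character vector of raw section labels.
#' @return Character vector of canonical segment names or `"excluded"`.
#' @examples
#' normalize_section(c("Background", "Materials and Methods", "Conclusions"))
#' @export
normalize_section <- function(raw) {
  canon <- c("Introduction", "Methods", "Results", "Discussion", "Abstract")
  vapply(as.character(raw), function(x) {
    if (is.na(x)) return("excluded")
    x <- tolower(gsub("[[:space:]]+", " ", trimws(x)))
    if (x == "background") return("Introduction")
    if (x == "materials and methods") return("Methods")
    hit <- match(x, tolower(canon))
    if (!is.na(hit)) canon[hit] else "excluded"
  }, "", USE.NAMES = FALSE)
}

#' Sense distribution across IMRAD segments
#'
#' Cross-tabulates type-level first senses against canonical rhetorical
#' segments over all Explicit, Implicit and AltLex relations.  Records in
#' excluded sections are dropped, and documents without any conventional
#' IMRAD structure (no record in a canonical segment) are skipped wholesale.
#' Percentages are row-wise shares of the row total; when the corpus
#' carries a `"row_total_override"` attribute (printed totals of a
#' reconstructed reference table) the override is used as the denominator
#' and rows whose cells do not sum to it are flagged.
#'
#' @param corpus an [annotated_corpus()], records carrying section labels.
#' @return A `distribution_table` with one row per sense type: counts for
#'   the five segments, `total`, and matching `pct_*` columns.  Attribute
#'   `"flagged"` names rows whose cells do not sum to the row denominator.
#' @export
imrad_distribution <- function(corpus) {
  stopifnot(is_corpus(corpus))
  segs <- c("Introduction", "Methods", "Results", "Abstract", "Discussion")
  tab <- list()
  for (doc in corpus$documents) {
    keep <- Filter(function(r) r$rel_type %in% c("Explicit", "Implicit",
                                                 "AltLex"), doc$relations)
    seg <- normalize_section(vapply(keep, `[[`, "", "section"))
    if (!any(seg %in% segs)) next   # document lacks IMRAD structure
    for (i in seq_along(keep)) {
      if (!seg[i] %in% segs || is.null(keep[[i]]$sense1)) next
      ty <- keep[[i]]$sense1$type
      if (is.null(tab[[ty]])) tab[[ty]] <- stats::setNames(integer(5L), segs)
      tab[[ty]][seg[i]] <- tab[[ty]][seg[i]] + 1L
    }
  }
  senses <- sort(names(tab))
  m <- t(vapply(senses, function(s) tab[[s]], stats::setNames(integer(5L), segs)))
  override <- attr(corpus, "row_total_override")
  row_total <- as.integer(rowSums(m))
  names(row_total) <- senses
  denom <- row_total
  flagged <- character()
  if (!is.null(override)) {
    hit <- intersect(senses, names(override))
    denom[hit] <- as.integer(override[hit])
    flagged <- hit[denom[hit] != row_total[hit]]
  }
  df <- data.frame(sense = senses, m, total = unname(denom),
                   row.names = NULL, stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (s in segs) {
    df[[paste0("pct_", s)]] <- ifelse(df$total > 0, 100 * df[[s]] / df$total, 0)
  }
  out <- distribution_table(df, total = as.integer(sum(denom)))
  attr(out, "flagged") <- flagged
  out
}
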