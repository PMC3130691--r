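#' Relation records
#'
#' One annotated discourse relation.  Four relation types are distinguished:
#'
#' * `Explicit` — the relation is signaled by an explicit connective whose
#'   text is anchored by `conn_spans`; at least one sense is annotated, a
#'   second sense is optional.
#' * `Implicit` — no connective is present in the text; the annotator
#'   *inserts* the connective string best expressing the inferred relation
#'   (`implicit_conn`), or the marker `"NONE"` when the inferred sense is one
#'   of Continuation, Background or Circumstance, for which no connective can
#'   be inserted.  Exactly one sense; a second sense is not permitted.
#' * `AltLex` — the relation is conveyed by an alternative lexicalization, an
#'   open-class expression anchored by `conn_spans` that is always fully
#'   contained within the Arg2 spans.
#' * `NoRel` — the sentence bears no coherent relation to prior text; no
#'   connective and no senses, and both arguments are single contiguous
#'   spans (the adjacent complete sentences).
#'
#' @param rel_type one of `"Explicit"`, `"Implicit"`, `"AltLex"`, `"NoRel"`.
#' @param arg1_spans,arg2_spans [span_set()]s anchoring the two arguments.
#' @param conn_spans [span_set()] anchoring the connective / AltLex
#'   expression, or `NULL`.
#' @param implicit_conn inserted connective string, the marker `"NONE"`, or
#'   `NULL`.
#' @param sense1,sense2 [sense_label()]s or `NULL`.
#' @param doc_id document identifier.
#' @param section optional free-text rhetorical section label (e.g.
#'   `"Results"`); carried through unvalidated, normalized only by the
#'   statistics layer.
#' @return An object of class `relation_record`.
#' @seealso [validate_record()] for the full invariant check.
#' @export
relation_record <- function(rel_type,
                            arg1_spans, arg2_spans,
                            conn_spans = NULL,
                            implicit_conn = NULL,
                            sense1 = NULL, sense2 = NULL,
                            doc_id = NA_character_,
                            section = NA_character_) {
  rel_type <- match.arg(rel_type, c("Explicit", "Implicit", "AltLex", "NoRel"))
  stopifnot(is_span_set(arg1_spans), is_span_set(arg2_spans),
            is.null(conn_spans) || is_span_set(conn_spans),
            is.null(sense1) || is_sense_label(sense1),
            is.null(sense2) || is_sense_label(sense2),
            is.null(implicit_conn) ||
              (is.character(implicit_conn) && length(implicit_conn) == 1L))
  structure(list(rel_type = rel_type,
                 conn_spans = conn_spans,
                 implicit_conn = implicit_conn,
                 sense1 = sense1, sense2 = sense2,
                 arg1_spans = arg1_spans, arg2_spans = arg2_spans,
                 doc_id = as.character(doc_id),
                 section = as.character(section)),
            class = "relation_record")
}

is_relation_record <- function(x) inherits(x, "relation_record")

#' @export
print.relation_record <- function(x, ...) {
  cat(sprintf("<relation_record> %s", x$rel_type))
  if (!is.null(x$conn_spans)) cat(" conn=", format(x$conn_spans), sep = "")
  if (!is.null(x$implicit_conn)) cat(" conn='", x$implicit_conn, "'", sep = "")
  if (!is.null(x$sense1)) cat(" sense1=", format(x$sense1), sep = "")
  if (!is.null(x$sense2)) cat(" sense2=", format(x$sense2), sep = "")
  cat("\n  Arg1=", format(x$arg1_spans), " Arg2=", format(x$arg2_spans),
      "\n", sep = "")
  invisible(x)
}

#' Check a relation record against the data-model invariants
#'
#' Returns (rather than raises) all detected violations, so that corpus
#' readers can collect and report them.  Checks, per relation type: presence
#' and absence of the connective fields and senses, containment of AltLex
#' expressions within Arg2, contiguity of NoRel arguments, validity of sense
#' labels against the taxonomy, and — when the document text is supplied —
#' that every span offset lies within the document.
#'
#' @param rec a [relation_record()].
#' @param doc_text the source document text, or `NULL` to skip bounds checks.
#' @param taxonomy a [build_taxonomy()].
#' @param strict_senses if `TRUE` sense labels must be taxonomy leaves; set
#'   to `FALSE` for corpora annotated at the type level.
#' @return Character vector of human-readable violations; empty if the
#'   record is well-formed.
#' @export
validate_record <- function(rec, doc_text = NULL,
                            taxonomy = build_taxonomy(),
                            strict_senses = TRUE) {
  stopifnot(is_relation_record(rec))
  v <- character()
  has_conn <- !is.null(rec$conn_spans) && length(rec$conn_spans) > 0L
  has_impl <- !is.null(rec$implicit_conn)

  if (rec$rel_type %in% c("Explicit", "AltLex")) {
    if (!has_conn) v <- c(v, paste0(rec$rel_type, ": connective spans missing"))
    if (has_impl) v <- c(v, paste0(rec$rel_type, ": implicit connective must be absent"))
    if (is.null(rec$sense1)) v <- c(v, paste0(rec$rel_type, ": sense1 missing"))
  }
  if (rec$rel_type == "Implicit") {
    if (has_conn) v <- c(v, "Implicit: connective spans must be absent")
    if (!has_impl) v <- c(v, "Implicit: inserted connective string missing")
    if (is.null(rec$sense1)) v <- c(v, "Implicit: sense1 missing")
    if (!is.null(rec$sense2)) v <- c(v, "Implicit: multiple senses are not permitted")
    if (has_impl && identical(rec$implicit_conn, "NONE") &&
        !is.null(rec$sense1) &&
        !rec$sense1$type %in% c("Continuation", "Background", "Circumstance")) {
      v <- c(v, sprintf(
        "Implicit: 'NONE' connective is reserved for Continuation/Background/Circumstance, not %s",
        rec$sense1$type))
    }
  }
  if (rec$rel_type == "AltLex" && has_conn &&
      !spans_contained(rec$conn_spans, rec$arg2_spans)) {
    v <- c(v, "AltLex: expression spans not contained within Arg2 spans")
  }
  if (rec$rel_type == "NoRel") {
    if (has_conn || has_impl) v <- c(v, "NoRel: must carry no connective")
    if (!is.null(rec$sense1) || !is.null(rec$sense2)) {
      v <- c(v, "NoRel: must carry no senses")
    }
    if (length(rec$arg1_spans) != 1L || length(rec$arg2_spans) != 1L) {
      v <- c(v, "NoRel: arguments must be single contiguous spans")
    }
  }
  for (slot in c("sense1", "sense2")) {
    s <- rec[[slot]]
    if (!is.null(s) && !is_valid_sense(s, taxonomy, strict = strict_senses)) {
      v <- c(v, sprintf("%s: invalid sense label '%s'", slot, format(s)))
    }
  }
  if (length(rec$arg1_spans) == 0L) v <- c(v, "Arg1 spans empty")
  if (length(rec$arg2_spans) == 0L) v <- c(v, "Arg2 spans empty")
  if (!is.null(doc_text)) {
    n <- nchar(doc_text)
    for (slot in c("conn_spans", "arg1_spans", "arg2_spans")) {
      ss <- rec[[slot]]
      if (!is.null(ss) && length(ss) > 0L && max(ss$end) > n) {
        v <- c(v, sprintf("%s: offset %d exceeds document length %d",
                          slot, max(ss$end), n))
      }
    }
  }
  v
}

#' Annotated corpora
#'
#' A corpus is a named list of documents; each document holds the source
#' text, its ordered relation records and, optionally, a table of rhetorical
#' section ranges (`start`, `end`, `label`) used to attach section labels to
#' records.
#'
#' @param documents named list; each element a list with components `text`
#'   (string), `relations` (list of [relation_record()]) and optionally
#'   `sections` (data.frame with columns `start`, `end`, `label`).
#' @return An object of class `annotated_corpus`.
#' @export
annotated_corpus <- function(documents = list()) {
  stopifnot(is.list(documents))
  if (length(documents) > 0L && is.null(names(documents))) {
    stop("documents must be named by doc_id", call. = FALSE)
  }
  structure(list(documents = documents), class = "annotated_corpus")
}

is_corpus <- function(x) inherits(x, "annotated_corpus")

#' @export
print.annotated_corpus <- function(x, ...) {
  nrel <- sum(vapply(x$documents, function(d) length(d$relations), 0L))
  cat(sprintf("<annotated_corpus> %d document(s), %d relation(s)\n",
              length(x$documents), nrel))
  invisible(x)
}

#' Flatten all records of a corpus into one list
#'
#' @param corpus an [annotated_corpus()].
#' @param rel_type optional filter on relation types.
#' @return List of [relation_record()]s in document order.
#' @export
corpus_records <- function(corpus, rel_type = NULL) {
  stopifnot(is_corpus(corpus))
  recs <- unlist(lapply(corpus$documents, `[[`, "relations"),
                 recursive = FALSE, use.names = FALSE)
  if (is.null(recs)) recs <- list()
  if (!is.null(rel_type)) {
    recs <- Filter(function(r) r$rel_type %in% rel_type, recs)
  }
  recs
}

#' Validate every record of a corpus
#'
#' @param corpus an [annotated_corpus()].
#' @inheritParams validate_record
#' @return Data frame with columns `doc_id`, `record`, `violation`; zero rows
#'   when the corpus is clean.
#' @export
validate_corpus <- function(corpus, taxonomy = build_taxonomy(),
                            strict_senses = TRUE) {
  stopifnot(is_corpus(corpus))
  out <- list()
  for (id in names(corpus$documents)) {
    doc <- corpus$documents[[id]]
    for (i in seq_along(doc$relations)) {
      v <- validate_record(doc$relations[[i]], doc$text, taxonomy,
                           strict_senses = strict_senses)
      if (length(v)) {
        out[[length(out) + 1L]] <- data.frame(
          doc_id = id, record = i, violation = v, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(doc_id = character(), record = integer(),
                      violation = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
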