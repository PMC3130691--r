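#' Stand-off format dialects
#'
#' Annotation files are stored separately ("stand-off") from the source
#' texts: flat text files with one relation per line, fields separated by
#' `|`.  Only a fixed subset of the columns is meaningful; the rest are
#' written empty (the layout descends from an annotation tool that also
#' recorded attribution features):
#'
#' | field | content                                         |
#' |------:|-------------------------------------------------|
#' |   0   | relation type (Explicit, Implicit, AltLex, NoRel)|
#' |   1   | span set of the connective (Explicit/AltLex)     |
#' |   7   | connective string inserted for Implicit          |
#' |   8   | sense 1                                          |
#' |   9   | sense 2                                          |
#' |  14   | span set of Arg1                                 |
#' |  20   | span set of Arg2                                 |
#'
#' Span sets serialize as `start..end` pairs joined by `;`, offsets 0-based
#' and half-open by default.
#'
#' @param n_fields total number of `|`-separated columns per line.  The
#'   default 27 matches the compact layout; 48 accommodates the classic
#'   full-width layout.
#' @param end_inclusive if `TRUE`, end offsets in files are inclusive and are
#'   converted to the internal half-open convention on read (and back on
#'   write).
#' @param normalize_crlf if `TRUE`, CRLF sequences in source texts are
#'   normalized to LF before offsets are resolved.
#' @return An object of class `standoff_dialect`.
#' @export
standoff_dialect <- function(n_fields = 27L, end_inclusive = FALSE,
                             normalize_crlf = FALSE) {
  n_fields <- as.integer(n_fields)
  if (n_fields < 21L) {
    stop("n_fields must be at least 21 to accommodate the Arg2 field",
         call. = FALSE)
  }
  structure(list(n_fields = n_fields,
                 end_inclusive = isTRUE(end_inclusive),
                 normalize_crlf = isTRUE(normalize_crlf),
                 fields = c(rel_type = 0L, conn_spans = 1L,
                            implicit_conn = 7L, sense1 = 8L, sense2 = 9L,
                            arg1_spans = 14L, arg2_spans = 20L)),
            class = "standoff_dialect")
}

parse_error <- function(fmt, ...) {
  stop(structure(class = c("drbank_parse_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

#' Parse a serialized span-set field
#'
#' The grammar is `start..end(;start..end)*`; the empty string denotes the
#' empty span set.
#'
#' @param text the field content, e.g. `"21670..21678;21729..21737"`.
#' @param end_inclusive interpret end offsets as inclusive (they are
#'   converted to the half-open internal convention).
#' @return A [span_set()].
#' @examples
#' parse_spanset("9171..9174")
#' parse_spanset("21670..21678;21729..21737")
#' parse_spanset("")
#' @export
parse_spanset <- function(text, end_inclusive = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (text == "") return(span_set())
  toks <- strsplit(text, ";", fixed = TRUE)[[1L]]
  start <- integer(length(toks)); end <- integer(length(toks))
  for (i in seq_along(toks)) {
    m <- regmatches(toks[i], regexec("^([0-9]+)\\.\\.([0-9]+)$", toks[i]))[[1L]]
    if (length(m) != 3L) {
      parse_error("malformed span token '%s' (expected start..end)", toks[i])
    }
    start[i] <- as.integer(m[2L])
    end[i] <- as.integer(m[3L]) + if (end_inclusive) 1L else 0L
    if (start[i] >= end[i]) {
      parse_error("empty or inverted span token '%s'", toks[i])
    }
  }
  sset <- tryCatch(span_set(start, end), error = function(e) {
    parse_error("invalid span set '%s': %s", text, conditionMessage(e))
  })
  sset
}

format_spanset <- function(spans, end_inclusive = FALSE) {
  if (length(spans) == 0L) return("")
  end <- spans$end - if (end_inclusive) 1L else 0L
  paste(sprintf("%d..%d", spans$start, end), collapse = ";")
}

parse_sense_field <- function(text, taxonomy) {
  text <- trimws(text)
  if (text == "") return(NULL)
  lab <- parse_sense(text, taxonomy)
  if (is.null(taxonomy[[lab$type]])) {
    parse_error("unknown sense '%s'", text)
  }
  if (!is.na(lab$subtype) && !lab$subtype %in% taxonomy[[lab$type]]) {
    parse_error("unknown subtype in sense '%s'", text)
  }
  lab
}

#' Parse one stand-off annotation line
#'
#' Tolerates missing *trailing* delimiters but rejects lines with fewer than
#' 21 fields (the Arg2 column would be missing) or more than
#' `dialect$n_fields`.
#'
#' @param line one line of an annotation file.
#' @param dialect a [standoff_dialect()].
#' @param taxonomy taxonomy for validating sense fields.
#' @param doc_id,section carried onto the record.
#' @return A [relation_record()].
#' @export
parse_relation_line <- function(line, dialect = standoff_dialect(),
                                taxonomy = build_taxonomy(),
                                doc_id = NA_character_,
                                section = NA_character_) {
  stopifnot(inherits(dialect, "standoff_dialect"))
  fields <- strsplit(line, "|", fixed = TRUE)[[1L]]
  # strsplit drops a trailing empty field; lines always end in a delimiter
  if (length(fields) > dialect$n_fields) {
    parse_error("line has %d fields, dialect allows %d",
                length(fields), dialect$n_fields)
  }
  if (length(fields) < 21L) {
    parse_error("line has %d fields, at least 21 required", length(fields))
  }
  fields <- c(fields, rep("", dialect$n_fields - length(fields)))
  fld <- function(name) fields[dialect$fields[[name]] + 1L]

  rel_type <- trimws(fld("rel_type"))
  if (!rel_type %in% c("Explicit", "Implicit", "AltLex", "NoRel")) {
    parse_error("unknown relation type '%s'", rel_type)
  }
  conn <- parse_spanset(fld("conn_spans"), dialect$end_inclusive)
  impl <- trimws(fld("implicit_conn"))
  relation_record(
    rel_type = rel_type,
    conn_spans = if (length(conn) > 0L) conn else NULL,
    implicit_conn = if (impl != "") impl else NULL,
    sense1 = parse_sense_field(fld("sense1"), taxonomy),
    sense2 = parse_sense_field(fld("sense2"), taxonomy),
    arg1_spans = parse_spanset(fld("arg1_spans"), dialect$end_inclusive),
    arg2_spans = parse_spanset(fld("arg2_spans"), dialect$end_inclusive),
    doc_id = doc_id, section = section)
}

#' Serialize a relation record to a stand-off line
#'
#' The inverse of [parse_relation_line()]: for any structurally valid record
#' `parse_relation_line(serialize_relation(rec))` reproduces `rec`
#' field-for-field.  Structurally invalid records are refused with the full
#' violation list.
#'
#' @param rec a [relation_record()].
#' @param dialect a [standoff_dialect()].
#' @param taxonomy taxonomy used for the validity check; sense labels are
#'   accepted at type level (lenient), matching aggregate-table corpora.
#' @return A single line of text with `dialect$n_fields` columns.
#' @export
serialize_relation <- function(rec, dialect = standoff_dialect(),
                               taxonomy = build_taxonomy()) {
  stopifnot(is_relation_record(rec), inherits(dialect, "standoff_dialect"))
  v <- validate_record(rec, doc_text = NULL, taxonomy = taxonomy,
                       strict_senses = FALSE)
  if (length(v)) {
    stop(sprintf("refusing to serialize invalid record: %s",
                 paste(v, collapse = "; ")), call. = FALSE)
  }
  fields <- rep("", dialect$n_fields)
  set <- function(name, value) {
    fields[dialect$fields[[name]] + 1L] <<- value
  }
  set("rel_type", rec$rel_type)
  if (!is.null(rec$conn_spans)) {
    set("conn_spans", format_spanset(rec$conn_spans, dialect$end_inclusive))
  }
  if (!is.null(rec$implicit_conn)) set("implicit_conn", rec$implicit_conn)
  if (!is.null(rec$sense1)) set("sense1", format(rec$sense1))
  if (!is.null(rec$sense2)) set("sense2", format(rec$sense2))
  set("arg1_spans", format_spanset(rec$arg1_spans, dialect$end_inclusive))
  set("arg2_spans", format_spanset(rec$arg2_spans, dialect$end_inclusive))
  paste(fields, collapse = "|")
}

section_for_offset <- function(sections, offset) {
  if (is.null(sections) || nrow(sections) == 0L) return(NA_character_)
  hit <- which(sections$start <= offset & offset < sections$end)
  if (length(hit) == 0L) NA_character_ else sections$label[hit[1L]]
}

read_section_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("start", "end", "label"),
                          quote = "")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

#' Read an annotated corpus from disk
#'
#' Expects one annotation file per source document: for a source file
#' `<id>.txt` the annotations are read from `<id>.ann` (one relation per
#' line) and, if present, rhetorical section ranges from a sidecar
#' `<id>.sec` (tab-separated `start end label`).  Records are assigned a
#' section label by locating the start offset of their Arg2 span — the
#' conventional location identifier for relations — in the sidecar ranges.
#'
#' Every record is validated; invariant violations are collected in the
#' `"violations"` attribute of the returned corpus (and raised as a warning),
#' never silently dropped.  Malformed lines and spans that exceed the
#' document length are errors naming the document and line.
#'
#' @param src_dir directory containing `*.txt` source documents.
#' @param ann_dir directory containing the `*.ann` files (defaults to
#'   `src_dir`).
#' @param dialect a [standoff_dialect()].
#' @param taxonomy a [build_taxonomy()].
#' @param strict_senses validate sense labels as leaves (`TRUE`) or allow
#'   type-level labels (`FALSE`, the default: distributed corpora mix both
#'   granularities).
#' @return An [annotated_corpus()] with attribute `"violations"`.
#' @export
read_corpus <- function(src_dir, ann_dir = src_dir,
                        dialect = standoff_dialect(),
                        taxonomy = build_taxonomy(),
                        strict_senses = FALSE) {
  src_files <- sort(list.files(src_dir, pattern = "\\.txt$",
                               full.names = TRUE))
  if (length(src_files) == 0L) {
    stop(sprintf("no source documents (*.txt) found in '%s'", src_dir),
         call. = FALSE)
  }
  docs <- list()
  for (sf in src_files) {
    id <- sub("\\.txt$", "", basename(sf))
    af <- file.path(ann_dir, paste0(id, ".ann"))
    if (!file.exists(af)) {
      stop(sprintf("missing annotation file for document '%s'", id),
           call. = FALSE)
    }
    text <- readChar(sf, file.size(sf), useBytes = FALSE)
    if (dialect$normalize_crlf) text <- gsub("\r\n", "\n", text, fixed = TRUE)
    sections <- read_section_sidecar(file.path(ann_dir, paste0(id, ".sec")))
    lines <- readLines(af, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    n <- nchar(text)
    relations <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(
        parse_relation_line(lines[i], dialect, taxonomy, doc_id = id),
        drbank_parse_error = function(e) {
          parse_error("%s line %d: %s", id, i, conditionMessage(e))
        })
      for (slot in c("conn_spans", "arg1_spans", "arg2_spans")) {
        ss <- rec[[slot]]
        if (!is.null(ss) && length(ss) > 0L && max(ss$end) > n) {
          stop(sprintf("%s line %d: %s end %d exceeds document length %d",
                       id, i, slot, max(ss$end), n), call. = FALSE)
        }
      }
      if (length(rec$arg2_spans) > 0L) {
        rec$section <- section_for_offset(sections, rec$arg2_spans$start[1L])
      }
      relations[[i]] <- rec
    }
    docs[[id]] <- list(text = text, relations = relations,
                       sections = sections)
  }
  corpus <- annotated_corpus(docs)
  viol <- validate_corpus(corpus, taxonomy, strict_senses = strict_senses)
  if (nrow(viol) > 0L) {
    warning(sprintf("%d record(s) violate data-model invariants; see attr(corpus, 'violations')",
                    nrow(viol)), call. = FALSE)
  }
  attr(corpus, "violations") <- viol
  corpus
}

#' Write an annotated corpus to disk
#'
#' Writes `<id>.txt`, `<id>.ann` and (when the document carries section
#' ranges) `<id>.sec` for every document, in the layout read back by
#' [read_corpus()].
#'
#' @param corpus an [annotated_corpus()].
#' @param dir output directory (created if missing).
#' @param dialect a [standoff_dialect()].
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, dialect = standoff_dialect()) {
  stopifnot(is_corpus(corpus))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(corpus$documents)) {
    doc <- corpus$documents[[id]]
    writeChar(doc$text, file.path(dir, paste0(id, ".txt")), eos = NULL)
    lines <- vapply(doc$relations, serialize_relation, "", dialect = dialect)
    writeLines(lines, file.path(dir, paste0(id, ".ann")))
    if (!is.null(doc$sections) && nrow(doc$sections) > 0L) {
      utils::write.table(doc$sections, file.path(dir, paste0(id, ".sec")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(dir)
}

# field-for-field equality of two corpora (texts, sections, records)
corpus_identical <- function(a, b, dialect = standoff_dialect()) {
  if (!identical(sort(names(a$documents)), sort(names(b$documents)))) {
    return(FALSE)
  }
  for (id in names(a$documents)) {
    da <- a$documents[[id]]; db <- b$documents[[id]]
    if (!identical(da$text, db$text)) return(FALSE)
    if (length(da$relations) != length(db$relations)) return(FALSE)
    la <- vapply(da$relations, serialize_relation, "", dialect = dialect)
    lb <- vapply(db$relations, serialize_relation, "", dialect = dialect)
    if (!identical(la, lb)) return(FALSE)
  }
  TRUE
}
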