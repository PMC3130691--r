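#' The two-tier sense taxonomy
#'
#' Discourse relation senses are organized in two tiers: 16 top-level *types*,
#' 9 of which are refined by *subtypes*.  A sense label is a leaf of this
#' hierarchy: either a `Type.Subtype` pair (for the 9 subtyped types) or a
#' bare type (for the 7 subtype-less types), giving 31 leaf categories in
#' total.  Subtypes either refine the semantics of the type (e.g. the three
#' conditional subtypes) or record the directionality of the arguments (e.g.
#' the two concessive subtypes).
#'
#' @return A named list of class `sense_taxonomy`: one element per type, each
#'   a (possibly empty) character vector of subtype names in canonical order.
#' @examples
#' tax <- build_taxonomy()
#' length(tax)                    # 16 types
#' taxonomy_leaves(tax)           # 31 leaf labels
#' tax$Cause                      # four causal subtypes
#' @export
build_taxonomy <- function() {
  structure(list(
    Cause        = c("Reason", "Result", "Claim", "Justification"),
    Condition    = c("Hypothetical", "Factual", "Non-Factual"),
    Purpose      = c("Goal", "Enablement"),
    Temporal     = c("Synchronous", "Precedence", "Succession"),
    Concession   = c("Contra-Expectation", "Expectation"),
    Contrast     = character(),
    Alternative  = c("Chosen-Alternative", "Conjunctive", "Disjunctive"),
    Instantiation = character(),
    Conjunction  = character(),
    Exception    = character(),
    Similarity   = character(),
    Continuation = character(),
    Circumstance = c("Forward-Circumstance", "Backward-Circumstance"),
    Background   = c("Forward-Background", "Backward-Background"),
    Restatement  = c("Equivalence", "Generalization", "Specification"),
    Reinforcement = character()
  ), class = "sense_taxonomy")
}

#' @export
print.sense_taxonomy <- function(x, ...) {
  cat(sprintf("<sense_taxonomy> %d types, %d leaves\n",
              length(x), length(taxonomy_leaves(x))))
  invisible(x)
}

#' Leaf labels of a sense taxonomy
#'
#' A leaf is `"Type.Subtype"` for subtyped types and `"Type"` otherwise.
#'
#' @param taxonomy a [build_taxonomy()] object.
#' @return Character vector of leaf labels.
#' @export
taxonomy_leaves <- function(taxonomy = build_taxonomy()) {
  unlist(lapply(names(taxonomy), function(ty) {
    subs <- taxonomy[[ty]]
    if (length(subs) == 0L) ty else paste(ty, subs, sep = ".")
  }), use.names = FALSE)
}

#' Grouping of sense types into the four generalized classes
#'
#' Maps each of the 16 sense types onto one of the four top-level classes
#' used for cross-domain comparison: Comparison, Contingency, Temporal and
#' Expansion.
#'
#' @return Named character vector of class `class_mapping`: names are sense
#'   types, values are generalized classes.
#' @examples
#' m <- pdtb_class_mapping()
#' m["Concession"]   # Comparison
#' table(m)          # 2 / 3 / 10 / 1 split over the four classes
#' @export
pdtb_class_mapping <- function() {
  structure(c(
    Concession = "Comparison", Contrast = "Comparison",
    Cause = "Contingency", Condition = "Contingency", Purpose = "Contingency",
    Temporal = "Temporal",
    Alternative = "Expansion", Background = "Expansion",
    Circumstance = "Expansion", Conjunction = "Expansion",
    Continuation = "Expansion", Exception = "Expansion",
    Instantiation = "Expansion", Reinforcement = "Expansion",
    Restatement = "Expansion", Similarity = "Expansion"
  ), class = "class_mapping")
}

#' The four generalized sense classes
#' @export
pdtb_classes <- function() c("Comparison", "Contingency", "Expansion", "Temporal")

#' Sense labels
#'
#' Constructs a two-tier sense label.  The canonical serialized form is
#' `"Type.Subtype"`, e.g. `"Concession.Contra-Expectation"`, or the bare type
#' name for subtype-less types.
#'
#' @param type a sense type name (see [build_taxonomy()]).
#' @param subtype optional subtype name, `NA`/`NULL` for none.
#' @return An object of class `sense_label` with fields `type` and `subtype`.
#' @examples
#' sense_label("Cause", "Result")
#' sense_label("Contrast")
#' @export
sense_label <- function(type, subtype = NULL) {
  if (is.null(subtype) || (length(subtype) == 1L && is.na(subtype))) {
    subtype <- NA_character_
  }
  stopifnot(is.character(type), length(type) == 1L,
            length(subtype) == 1L)
  structure(list(type = type, subtype = as.character(subtype)),
            class = "sense_label")
}

is_sense_label <- function(x) inherits(x, "sense_label")

#' @export
format.sense_label <- function(x, ...) {
  if (is.na(x$subtype)) x$type else paste(x$type, x$subtype, sep = ".")
}

#' @export
print.sense_label <- function(x, ...) {
  cat("<sense> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.sense_label` <- function(e1, e2) {
  format(e1) == format(e2)
}

#' Parse a serialized sense label
#'
#' Splits on the first `.`; normalizes case and surrounding whitespace to the
#' canonical spellings of the taxonomy (hyphenated subtype names are matched
#' case-insensitively), so `"cause.result"` parses to `Cause.Result`.
#'
#' @param text string such as `"Temporal.Precedence"` or `"Contrast"`.
#' @param taxonomy taxonomy used for normalization.
#' @return A [sense_label()].  Unknown names are kept verbatim; use
#'   [validate_sense()] to check them.
#' @export
parse_sense <- function(text, taxonomy = build_taxonomy()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  parts <- strsplit(text, ".", fixed = TRUE)[[1L]]
  type <- trimws(parts[1L])
  subtype <- if (length(parts) > 1L) {
    trimws(paste(parts[-1L], collapse = "."))
  } else {
    NA_character_
  }
  # normalize to canonical casing when a case-insensitive match exists
  hit <- match(tolower(type), tolower(names(taxonomy)))
  if (!is.na(hit)) {
    canon <- names(taxonomy)[hit]
    if (!is.na(subtype)) {
      shit <- match(tolower(subtype), tolower(taxonomy[[canon]]))
      if (!is.na(shit)) subtype <- taxonomy[[canon]][shit]
    }
    type <- canon
  }
  sense_label(type, subtype)
}

#' Validate a sense label against the taxonomy
#'
#' Under `strict = TRUE` (the annotation-record rule) a label must be a leaf:
#' for a type that carries subtypes the subtype is mandatory — the bare type
#' level cannot be chosen.  Under `strict = FALSE` (the convention of
#' aggregate tables, which report at the type level) a bare type label is
#' accepted for any known type.
#'
#' @param label a [sense_label()].
#' @param taxonomy a [build_taxonomy()] object.
#' @param strict logical flag, see Details.
#' @return `TRUE` invisibly if valid; otherwise throws an error of class
#'   `drbank_sense_error` naming the offending component.
#' @examples
#' validate_sense(sense_label("Contrast"))                      # valid
#' try(validate_sense(sense_label("Cause")))                    # needs subtype
#' validate_sense(sense_label("Cause"), strict = FALSE)         # table mode
#' @export
validate_sense <- function(label, taxonomy = build_taxonomy(), strict = TRUE) {
  stopifnot(is_sense_label(label))
  subs <- taxonomy[[label$type]]
  if (is.null(subs)) {
    stop(structure(class = c("drbank_sense_error", "error", "condition"),
                   list(message = sprintf("unknown sense type '%s'", label$type),
                        call = NULL)))
  }
  if (is.na(label$subtype)) {
    if (strict && length(subs) > 0L) {
      stop(structure(class = c("drbank_sense_error", "error", "condition"),
                     list(message = sprintf(
                       "type '%s' requires one of its subtypes (%s)",
                       label$type, paste(subs, collapse = ", ")),
                       call = NULL)))
    }
  } else {
    if (!label$subtype %in% subs) {
      stop(structure(class = c("drbank_sense_error", "error", "condition"),
                     list(message = sprintf(
                       "unknown subtype '%s' for type '%s'",
                       label$subtype, label$type), call = NULL)))
    }
  }
  invisible(TRUE)
}

is_valid_sense <- function(label, taxonomy = build_taxonomy(), strict = TRUE) {
  ok <- tryCatch({ validate_sense(label, taxonomy, strict); TRUE },
                 drbank_sense_error = function(e) FALSE)
  ok
}

#' Generalize a sense label to its four-way class
#'
#' @param label a [sense_label()] (the subtype is ignored).
#' @param mapping a [pdtb_class_mapping()].
#' @return One of `"Comparison"`, `"Contingency"`, `"Temporal"`,
#'   `"Expansion"`.
#' @examples
#' to_pdtb_class(sense_label("Concession", "Expectation"))  # Comparison
#' to_pdtb_class(sense_label("Purpose", "Goal"))            # Contingency
#' @export
to_pdtb_class <- function(label, mapping = pdtb_class_mapping()) {
  stopifnot(is_sense_label(label))
  cls <- unname(mapping[label$type])
  if (is.na(cls)) {
    stop(sprintf("sense type '%s' has no generalized class", label$type),
         call. = FALSE)
  }
  cls
}
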