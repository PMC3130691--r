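#' Character span sets
#'
#' Annotations are anchored in source documents by character offsets using a
#' 0-based, half-open convention: a span `(start, end)` covers the characters
#' at positions `start, start + 1, ..., end - 1`, so its length is
#' `end - start` and empty spans are forbidden.  A *span set* is an ordered
#' list of pairwise non-overlapping spans; the order of its elements reflects
#' the linear order of the (possibly discontinuous) pieces in the text.
#'
#' @param start,end integer vectors of equal length; `start[i] < end[i]` for
#'   every element and consecutive spans must satisfy `end[i] <= start[i+1]`.
#' @return An object of class `span_set`.
#' @examples
#' span_set(c(0L, 4L), c(2L, 6L))
#' span_set()                      # empty set
#' @export
span_set <- function(start = integer(), end = integer()) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("`start` and `end` must have equal length", call. = FALSE)
  }
  if (anyNA(start) || anyNA(end)) {
    stop("span offsets must not be NA", call. = FALSE)
  }
  if (any(start < 0L)) {
    stop("span offsets must be non-negative", call. = FALSE)
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("empty or inverted span %d..%d", start[bad], end[bad]),
         call. = FALSE)
  }
  if (length(start) > 1L && any(end[-length(end)] > start[-1L])) {
    stop("spans must be non-overlapping and in linear text order",
         call. = FALSE)
  }
  structure(list(start = start, end = end), class = "span_set")
}

#' @export
length.span_set <- function(x) length(x$start)

#' @export
format.span_set <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste(sprintf("%d..%d", x$start, x$end), collapse = ";")
}

#' @export
print.span_set <- function(x, ...) {
  cat("<span_set> ", if (length(x) == 0L) "(empty)" else format(x), "\n",
      sep = "")
  invisible(x)
}

#' @export
`==.span_set` <- function(e1, e2) {
  identical(e1$start, e2$start) && identical(e1$end, e2$end)
}

is_span_set <- function(x) inherits(x, "span_set")

#' Set of character positions covered by a span set
#'
#' @param x a [span_set()].
#' @return Sorted integer vector of 0-based covered positions.
#' @export
span_coverage <- function(x) {
  stopifnot(is_span_set(x))
  if (length(x) == 0L) return(integer())
  unlist(lapply(seq_along(x$start),
                function(i) seq.int(x$start[i], x$end[i] - 1L)),
         use.names = FALSE)
}

#' Total number of characters covered by a span set
#' @param x a [span_set()].
#' @export
span_width <- function(x) {
  stopifnot(is_span_set(x))
  sum(x$end - x$start)
}

#' Do two span sets overlap in at least one character?
#' @param a,b span sets.
#' @return `TRUE` if the coverages share at least one position.
#' @export
spans_overlap <- function(a, b) {
  span_overlap_size(a, b) > 0L
}

span_overlap_size <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  tot <- 0L
  for (i in seq_along(a$start)) {
    lo <- pmax(a$start[i], b$start)
    hi <- pmin(a$end[i], b$end)
    tot <- tot + sum(pmax(hi - lo, 0L))
  }
  tot
}

#' Is span set `inner` fully contained in the coverage of `outer`?
#' @param inner,outer span sets.
#' @export
spans_contained <- function(inner, outer) {
  if (length(inner) == 0L) return(TRUE)
  cov <- span_coverage(outer)
  all(span_coverage(inner) %in% cov)
}

#' Extract the text anchored by a span set
#'
#' Concatenates the substrings selected by each span, in span order, joining
#' discontinuous pieces with a single space.
#'
#' @param text a length-one character string (the source document).
#' @param spans a [span_set()]; all offsets must lie within `nchar(text)`.
#' @return A character string.
#' @examples
#' extract_text("abcdef", span_set(1, 4))          # "bcd"
#' extract_text("abcdef", span_set(c(0, 4), c(2, 6)))  # "ab ef"
#' @export
extract_text <- function(text, spans) {
  stopifnot(is.character(text), length(text) == 1L, is_span_set(spans))
  if (length(spans) == 0L) return("")
  n <- nchar(text)
  if (any(spans$end > n)) {
    stop(sprintf("span %s exceeds document length %d",
                 format(spans), n), call. = FALSE)
  }
  # substring() is 1-based and inclusive; offsets are 0-based half-open
  paste(substring(text, spans$start + 1L, spans$end), collapse = " ")
}
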