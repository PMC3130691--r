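# shared helpers: tiny hand-built corpora and record shortcuts

sp <- function(start, end) span_set(start, end)

# a minimal one-document corpus built directly in memory; text layout:
# 0........10........20........30........40........50
# "aaaa bbbb because cccc dddd. eeee ffff. gggg hhhh."
tiny_doc_text <- "aaaa bbbb because cccc dddd. eeee ffff. gggg hhhh."

tiny_explicit <- function(sense1 = sense_label("Cause", "Reason"),
                          sense2 = NULL) {
  relation_record("Explicit",
                  arg1_spans = sp(0, 9),
                  arg2_spans = sp(18, 27),
                  conn_spans = sp(10, 17),
                  sense1 = sense1, sense2 = sense2,
                  doc_id = "tiny")
}

tiny_corpus <- function(records) {
  annotated_corpus(list(tiny = list(text = tiny_doc_text,
                                    relations = records)))
}

# small seeded generator config used across tests
small_cfg <- function(n_explicit = 60, n_implicit = 40, n_altlex = 10,
                      n_norel = 5, seed = 31, ...) {
  synth_config(n_relations = c(Explicit = n_explicit, Implicit = n_implicit,
                               AltLex = n_altlex, NoRel = n_norel),
               n_docs = 3, seed = seed, ...)
}

# build a raw stand-off line from named fields (independent of the
# package's serializer)
raw_line <- function(..., n_fields = 27L) {
  fields <- rep("", n_fields)
  vals <- list(...)
  idx <- c(rel_type = 1L, conn = 2L, impl = 8L, sense1 = 9L, sense2 = 10L,
           arg1 = 15L, arg2 = 21L)
  for (nm in names(vals)) fields[idx[[nm]]] <- vals[[nm]]
  paste(fields, collapse = "|")
}

# independent Cohen's kappa oracle: contingency-table computation
kappa_oracle <- function(a, b) {
  cats <- sort(union(a, b))
  tab <- table(factor(a, cats), factor(b, cats))
  n <- sum(tab)
  ao <- sum(diag(tab)) / n
  ae <- sum(rowSums(tab) * colSums(tab)) / n^2
  (ao - ae) / (1 - ae)
}
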