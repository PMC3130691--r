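test_that("parse_spanset handles single, discontinuous and empty fields", {
  s <- parse_spanset("9171..9174")
  expect_identical(s$start, 9171L)
  expect_identical(s$end, 9174L)
  d <- parse_spanset("21670..21678;21729..21737")
  expect_identical(length(d), 2L)
  expect_identical(d$start, c(21670L, 21729L))
  expect_identical(length(parse_spanset("")), 0L)
  # inclusive-end dialect shifts the end by one
  expect_identical(parse_spanset("3..5", end_inclusive = TRUE)$end, 6L)
})

test_that("parse_spanset rejects malformed tokens, naming the offender", {
  expect_error(parse_spanset("12..x"), "12\\.\\.x")
  expect_error(parse_spanset("1234"), "1234")
  expect_error(parse_spanset("9..9"), "empty or inverted")
  expect_error(parse_spanset("10..3"), "empty or inverted")
  expect_error(parse_spanset("5..8;6..9"), "non-overlapping")
})

test_that("parse_relation_line reads the documented example rows", {
  # explicit connective with two senses
  r1 <- parse_relation_line(raw_line(
    rel_type = "Explicit", conn = "9171..9174",
    sense1 = "Temporal.Precedence", sense2 = "Conjunction",
    arg1 = "9137..9170", arg2 = "9175..9244"))
  expect_identical(r1$rel_type, "Explicit")
  expect_identical(format(r1$sense1), "Temporal.Precedence")
  expect_identical(format(r1$sense2), "Conjunction")
  expect_identical(r1$conn_spans$start, 9171L)

  # implicit relation with an inserted connective string
  r4 <- parse_relation_line(raw_line(
    rel_type = "Implicit", impl = "as a result", sense1 = "Cause.Result",
    arg1 = "3418..3655", arg2 = "3657..3714"))
  expect_identical(r4$rel_type, "Implicit")
  expect_identical(r4$implicit_conn, "as a result")
  expect_identical(format(r4$sense1), "Cause.Result")
  expect_null(r4$conn_spans)
  expect_identical(r4$arg1_spans$start, 3418L)
  expect_identical(r4$arg2_spans$end, 3714L)

  # AltLex with two senses; expression contained in Arg2
  r5 <- parse_relation_line(raw_line(
    rel_type = "AltLex", conn = "25183..25199", sense1 = "Reinforcement",
    sense2 = "Cause.Claim", arg1 = "24621..25181", arg2 = "25183..25444"))
  expect_identical(r5$rel_type, "AltLex")
  expect_true(spans_contained(r5$conn_spans, r5$arg2_spans))
})

test_that("parse_relation_line rejects malformed lines", {
  expect_error(parse_relation_line("Explicit|1..2|x|y|z"),
               "at least 21 required")
  expect_error(parse_relation_line(raw_line(rel_type = "Wrong",
                                            arg1 = "0..5", arg2 = "6..9")),
               "unknown relation type")
  expect_error(parse_relation_line(raw_line(rel_type = "Explicit",
                                            conn = "0..2",
                                            sense1 = "Bogus.Label",
                                            arg1 = "0..5", arg2 = "6..9")),
               "unknown sense")
  expect_error(parse_relation_line(raw_line(rel_type = "Explicit",
                                            n_fields = 40L)),
               "dialect allows 27")
})

test_that("serialize_relation writes the mapped fields and nothing else", {
  line <- serialize_relation(tiny_explicit(sense2 = sense_label("Conjunction")))
  fields <- strsplit(line, "|", fixed = TRUE)[[1L]]
  expect_identical(fields[1L], "Explicit")
  expect_identical(fields[2L], "10..17")
  expect_identical(fields[9L], "Cause.Reason")
  expect_identical(fields[10L], "Conjunction")
  expect_identical(fields[15L], "0..9")
  expect_identical(fields[21L], "18..27")
  expect_true(all(fields[-c(1L, 2L, 9L, 10L, 15L, 21L)] == ""))

  norel <- relation_record("NoRel", arg1_spans = sp(0, 9),
                           arg2_spans = sp(29, 38))
  nf <- strsplit(serialize_relation(norel), "|", fixed = TRUE)[[1L]]
  expect_true(all(nf[-c(1L, 15L, 21L)] == ""))

  # invalid records are refused with the violation list
  bad <- relation_record("Implicit", arg1_spans = sp(0, 9),
                         arg2_spans = sp(29, 38), implicit_conn = "so",
                         sense1 = sense_label("Cause", "Reason"),
                         sense2 = sense_label("Conjunction"))
  expect_error(serialize_relation(bad), "not permitted")
})

test_that("parse . serialize is the identity over generated corpora", {
  corp <- generate_corpus(small_cfg())
  dialect <- standoff_dialect()
  for (id in names(corp$documents)) {
    for (rec in corp$documents[[id]]$relations) {
      line <- serialize_relation(rec, dialect)
      back <- parse_relation_line(line, dialect, doc_id = rec$doc_id,
                                  section = rec$section)
      expect_identical(serialize_relation(back, dialect), line)
    }
  }
  # discontinuous spans survive with order and count intact
  disc <- relation_record("Explicit",
                          arg1_spans = sp(c(0, 5), c(4, 9)),
                          arg2_spans = sp(c(29, 40), c(38, 48)),
                          conn_spans = sp(c(10, 23), c(17, 27)),
                          sense1 = sense_label("Alternative", "Disjunctive"))
  back <- parse_relation_line(serialize_relation(disc))
  expect_identical(back$conn_spans$start, c(10L, 23L))
  expect_identical(back$arg2_spans$end, c(38L, 48L))
})

test_that("extract_text obeys the half-open convention and joins pieces", {
  expect_identical(extract_text("abcdef", sp(1, 4)), "bcd")
  expect_identical(extract_text("abcdef", sp(c(0, 4), c(2, 6))), "ab ef")
  expect_identical(extract_text("abcdef", span_set()), "")
  expect_error(extract_text("abcdef", sp(3, 9)), "exceeds document length")
  # planted connective strings are recovered exactly from generated text
  corp <- generate_corpus(small_cfg(seed = 77))
  for (rec in corpus_records(corp, "Explicit")[1:10]) {
    doc <- corp$documents[[rec$doc_id]]
    surf <- extract_text(doc$text, rec$conn_spans)
    expect_true(surf %in% vapply(default_connectives(), `[[`, "", "conn"))
  }
})

test_that("read_corpus round-trips a written corpus and reports errors", {
  corp <- generate_corpus(small_cfg(seed = 5))
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  back <- read_corpus(dir)
  expect_true(drbank:::corpus_identical(corp, back))
  expect_identical(nrow(attr(back, "violations")), 0L)
  # section labels survive through the sidecar
  secs_in <- vapply(corpus_records(corp), `[[`, "", "section")
  secs_out <- vapply(corpus_records(back), `[[`, "", "section")
  expect_identical(secs_out, secs_in)

  # missing annotation file
  file.remove(list.files(dir, pattern = "doc01\\.ann$", full.names = TRUE))
  expect_error(read_corpus(dir), "missing annotation file")

  # span beyond the document length names document and line
  dir2 <- withr::local_tempdir()
  writeChar("short text.", file.path(dir2, "d.txt"), eos = NULL)
  writeLines(raw_line(rel_type = "Explicit", conn = "0..5",
                      sense1 = "Contrast", arg1 = "0..5", arg2 = "6..500"),
             file.path(dir2, "d.ann"))
  expect_error(read_corpus(dir2), "d line 1.*exceeds document length")
})

test_that("invariant violations are collected, not dropped", {
  dir <- withr::local_tempdir()
  writeChar("aaaa bbbb because cccc dddd. eeee.", file.path(dir, "d.txt"),
            eos = NULL)
  writeLines(c(
    raw_line(rel_type = "Explicit", conn = "10..17", sense1 = "Cause.Reason",
             arg1 = "0..9", arg2 = "18..27"),
    raw_line(rel_type = "Explicit", sense1 = "Contrast",
             arg1 = "0..9", arg2 = "18..27")),  # missing connective spans
    file.path(dir, "d.ann"))
  expect_warning(corpus <- read_corpus(dir), "violate")
  v <- attr(corpus, "violations")
  expect_identical(nrow(v), 1L)
  expect_identical(v$record, 2L)
  expect_identical(length(corpus_records(corpus)), 2L)
})
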