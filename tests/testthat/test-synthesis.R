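test_that("synth_config validates its probability tables", {
  expect_error(synth_config(connectives = list(
    list(conn = "since", weight = 1, senses = c(Cause = 0.6, Temporal = 0.3)))),
    "does not sum to 1")
  expect_error(synth_config(connectives = list(
    list(conn = "since", weight = 1, senses = c(Causal = 1)))),
    "unknown sense type")
  expect_error(synth_config(n_relations = c(Explicit = -1, Implicit = 0,
                                            AltLex = 0, NoRel = 0)),
               "non-negative")
  expect_error(synth_config(multi_sense_rate = 1.5), "multi_sense_rate")
  expect_error(synth_config(connectives = list(
    list(conn = "regulon", weight = 1, senses = c(Cause = 1)))),
    "collides with the filler lexicon")
  # defaults are internally consistent
  cfg <- synth_config()
  expect_identical(sum(cfg$n_relations), 5859L)
  expect_equal(sum(cfg$sections), 1)
})

test_that("generation is deterministic: same seed, byte-identical files", {
  cfg <- small_cfg(seed = 101)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus(generate_corpus(cfg), d1)
  write_corpus(generate_corpus(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  # a different seed changes the corpus
  d3 <- withr::local_tempdir()
  write_corpus(generate_corpus(small_cfg(seed = 102)), d3)
  ann1 <- readLines(list.files(d1, pattern = "\\.ann$", full.names = TRUE)[1])
  ann3 <- readLines(list.files(d3, pattern = "\\.ann$", full.names = TRUE)[1])
  expect_false(identical(ann1, ann3))
})

test_that("generated corpora have the planted mix and pass validation", {
  cfg <- small_cfg(n_explicit = 80, n_implicit = 50, n_altlex = 12,
                   n_norel = 6, seed = 19)
  corp <- generate_corpus(cfg)
  tab <- relation_type_distribution(corp)
  expect_identical(tab$tokens, c(80L, 50L, 12L, 6L))
  expect_identical(nrow(validate_corpus(corp, strict_senses = TRUE)), 0L)
  # every record carries a section label from the configured layout
  secs <- vapply(corpus_records(corp), `[[`, "", "section")
  expect_true(all(secs %in% names(cfg$sections)))
})

test_that("per-connective sense conditionals are respected in distribution", {
  cfg <- synth_config(
    n_relations = c(Explicit = 1000L, Implicit = 0L, AltLex = 0L, NoRel = 0L),
    connectives = list(
      list(conn = "since", weight = 1,
           senses = c(Cause = 0.6, Temporal = 0.4))),
    multi_sense_rate = 0, n_docs = 2, seed = 7)
  corp <- generate_corpus(cfg)
  inst <- build_instances(corp, "first", "type")
  p_hat <- mean(inst$label == "Cause")
  se <- sqrt(0.6 * 0.4 / 1000)
  expect_lt(abs(p_hat - 0.6), 3 * se)
})

test_that("multi-sense rate and pair inventory are honored", {
  cfg <- small_cfg(n_explicit = 2000, n_implicit = 0, n_altlex = 0,
                   n_norel = 0, seed = 3)
  corp <- generate_corpus(cfg)
  recs <- corpus_records(corp, "Explicit")
  has2 <- vapply(recs, function(r) !is.null(r$sense2), logical(1))
  se <- sqrt(0.074 * 0.926 / 2000)
  expect_lt(abs(mean(has2) - 0.074), 3 * se)
  # implicit records never carry a second sense by construction
  corp2 <- generate_corpus(small_cfg(seed = 4))
  expect_true(all(vapply(corpus_records(corp2, "Implicit"),
                         function(r) is.null(r$sense2), logical(1))))
})

test_that("zero-noise perturbation is the identity with perfect agreement", {
  corp <- generate_corpus(small_cfg(seed = 47))
  same <- perturb_annotations(corp, perturb_config(seed = 1))
  expect_true(drbank:::corpus_identical(corp, same))
  rep <- agreement_report(corp, same)
  vals <- rep$value[rep$statistic != "sense_expected"]
  expect_true(all(abs(vals - 1) < 1e-12))   # incl. kappa: Ao = 1 forces 1
})

test_that("deletion-only noise matches exhaustive matching on realized sets", {
  corp <- generate_corpus(small_cfg(n_explicit = 120, n_implicit = 0,
                                    n_altlex = 0, n_norel = 0, seed = 61))
  noisy <- perturb_annotations(corp, perturb_config(delete_p = 0.3, seed = 9))
  for (id in names(corp$documents)) {
    a <- lapply(corp$documents[[id]]$relations, `[[`, "conn_spans")
    b <- lapply(noisy$documents[[id]]$relations, `[[`, "conn_spans")
    g <- match_connectives(a, b, "greedy")
    x <- match_connectives(a, b, "exhaustive")
    expect_identical(g$n_common, x$n_common)
    # survivors all match: common = |B|, union = |A|
    expect_identical(g$n_common, length(b))
    expect_identical(g$n_union, length(a))
  }
})

test_that("perturbed corpora remain structurally valid and round-trip", {
  corp <- generate_corpus(small_cfg(seed = 83))
  noisy <- perturb_annotations(corp, perturb_config(
    span_jitter_p = 0.5, jitter_max = 3, delete_p = 0.15, insert_p = 0.1,
    sense_confusion_p = 0.2, seed = 12))
  expect_identical(nrow(validate_corpus(noisy, strict_senses = TRUE)), 0L)
  dir <- withr::local_tempdir()
  write_corpus(noisy, dir)
  expect_true(drbank:::corpus_identical(noisy, read_corpus(dir)))
  # spurious insertions never overlap true connective spans
  for (id in names(corp$documents)) {
    true_cov <- unlist(lapply(corp$documents[[id]]$relations, function(r) {
      if (is.null(r$conn_spans)) integer() else span_coverage(r$conn_spans)
    }))
    n_true <- sum(vapply(corp$documents[[id]]$relations,
                         function(r) r$rel_type == "Explicit", logical(1)))
    recs <- noisy$documents[[id]]$relations
    expl <- Filter(function(r) r$rel_type == "Explicit", recs)
    if (length(expl) > n_true) {
      # at least one insertion happened in this document; all connective
      # spans must still be pairwise disjoint from the true inventory or
      # identical to one of them
      for (r in expl) {
        cov <- span_coverage(r$conn_spans)
        expect_true(all(cov %in% true_cov) || !any(cov %in% true_cov))
      }
    }
  }
})

test_that("closed-form optimum matches brute-force enumeration", {
  cfg <- synth_config(
    n_relations = c(Explicit = 10L, Implicit = 0L, AltLex = 0L, NoRel = 0L),
    connectives = list(
      list(conn = "since", weight = 2,
           senses = c(Cause = 0.55, Temporal = 0.45)),
      list(conn = "while", weight = 1,
           senses = c(Concession = 0.5, Conjunction = 0.3, Temporal = 0.2)),
      list(conn = "but", weight = 1, senses = c(Contrast = 1))),
    multi_sense_rate = 0, n_docs = 1, seed = 1)
  # brute force: scan every deterministic per-connective labeling and take
  # the best achievable expected accuracy
  types <- c("Cause", "Temporal", "Concession", "Conjunction", "Contrast")
  w <- c(2, 1, 1) / 4
  cond <- list(c(Cause = 0.55, Temporal = 0.45),
               c(Concession = 0.5, Conjunction = 0.3, Temporal = 0.2),
               c(Contrast = 1))
  best <- 0
  for (l1 in types) for (l2 in types) for (l3 in types) {
    f <- c(l1, l2, l3)
    acc <- sum(vapply(1:3, function(i) {
      p <- cond[[i]][f[i]]
      w[i] * if (is.na(p)) 0 else p
    }, 0))
    best <- max(best, acc)
  }
  expect_equal(closed_form_bayes_rate(cfg, "type"), best)
  # trivial cases
  det <- synth_config(
    n_relations = c(Explicit = 1L, Implicit = 0L, AltLex = 0L, NoRel = 0L),
    connectives = list(list(conn = "but", weight = 1,
                            senses = c(Contrast = 1))),
    n_docs = 1, seed = 1)
  expect_equal(closed_form_bayes_rate(det, "type"), 1)
  unif <- synth_config(
    n_relations = c(Explicit = 1L, Implicit = 0L, AltLex = 0L, NoRel = 0L),
    connectives = list(list(conn = "and", weight = 1,
                            senses = c(Contrast = 0.25, Cause = 0.25,
                                       Temporal = 0.25, Conjunction = 0.25))),
    n_docs = 1, seed = 1)
  expect_equal(closed_form_bayes_rate(unif, "class"), 0.25)
})

test_that("class-level optimum aggregates conditionals before maximizing", {
  cfg <- synth_config(
    n_relations = c(Explicit = 1L, Implicit = 0L, AltLex = 0L, NoRel = 0L),
    connectives = list(list(conn = "by", weight = 1,
                            senses = c(Cause = 0.4, Purpose = 0.35,
                                       Temporal = 0.25))),
    n_docs = 1, seed = 1)
  # type level: best single type is Cause (0.4); class level: Cause and
  # Purpose both collapse to Contingency (0.75)
  expect_equal(closed_form_bayes_rate(cfg, "type"), 0.4)
  expect_equal(closed_form_bayes_rate(cfg, "class"), 0.75)
})

test_that("table fixtures are bit-stable across calls", {
  for (tb in c(3, 4, 5, 12)) {
    a <- fixture_from_tables(tb)
    b <- fixture_from_tables(tb)
    expect_true(drbank:::corpus_identical(a, b))
  }
  expect_error(fixture_from_tables(6), "%in%")
})
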