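test_that("build_instances implements the three sense scenarios", {
  f4 <- fixture_from_tables(4)
  expect_identical(nrow(build_instances(f4, "first", "class")), 2636L)
  expect_identical(nrow(build_instances(f4, "second", "class")), 2636L)
  expect_identical(nrow(build_instances(f4, "both", "class")), 2831L)
  # second slot falls back on sense1 when no second sense exists
  corp <- tiny_corpus(list(tiny_explicit(sense1 = sense_label("Contrast"))))
  inst <- build_instances(corp, "second", "type")
  expect_identical(inst$label, "Contrast")
  # class granularity collapses via the mapping
  instc <- build_instances(corp, "first", "class")
  expect_identical(instc$label, "Comparison")
  expect_identical(instc$feature, "because")
})

test_that("train_rules learns per-connective majorities with fallback", {
  inst <- data.frame(
    feature = c(rep("because", 10), rep("since", 52)),
    label = c(rep("Contingency", 10),
              rep("Contingency", 30), rep("Temporal", 22)),
    stringsAsFactors = FALSE)
  m <- train_rules(inst)
  r <- m$rules
  expect_identical(r$label[r$feature == "because"], "Contingency")
  expect_equal(r$confidence[r$feature == "because"], 1)
  expect_identical(r$label[r$feature == "since"], "Contingency")
  expect_equal(r$confidence[r$feature == "since"], 30 / 52)
  expect_identical(m$fallback, "Contingency")
  expect_identical(unname(predict(m, "never seen")), "Contingency")
  expect_error(train_rules(inst[0, ]), "empty instance set")
})

test_that("rule ties break by global prior, then lexicographically", {
  inst <- data.frame(
    feature = c("x", "x", "y", "y", "y"),
    label = c("B", "A", "A", "A", "B"),
    stringsAsFactors = FALSE)
  # for "x": tie 1-1; global prior A=3 > B=2 -> A
  m <- train_rules(inst)
  expect_identical(m$rules$label[m$rules$feature == "x"], "A")
  # fully symmetric corpus: lexicographic tie-break
  inst2 <- data.frame(feature = c("x", "x"), label = c("B", "A"),
                      stringsAsFactors = FALSE)
  expect_identical(train_rules(inst2)$rules$label, "A")
})

test_that("evaluate matches a hand-computed confusion matrix", {
  # confusion matrix [[4,0],[2,4]] (rows truth Pos/Neg, cols predicted)
  # realized through two connectives
  test <- data.frame(
    feature = c(rep("p", 3), "p", rep("q", 2), rep("q", 4)),
    label = c(rep("Pos", 3), "Pos", rep("Pos", 2), rep("Neg", 4)),
    stringsAsFactors = FALSE)
  model <- train_rules(data.frame(feature = c("p", "q"),
                                  label = c("Pos", "Neg"),
                                  stringsAsFactors = FALSE))
  # p -> Pos (4 true Pos), q -> Neg (2 Pos misclassified, 4 Neg correct)
  res <- evaluate(model, test)
  expect_equal(res$accuracy, 8 / 10)
  pos <- res$per_class[res$per_class$label == "Pos", ]
  expect_equal(pos$precision, 4 / 4)
  expect_equal(pos$recall, 4 / 6)
  expect_equal(pos$f1, 2 * 1 * (4 / 6) / (1 + 4 / 6))
  neg <- res$per_class[res$per_class$label == "Neg", ]
  expect_equal(neg$precision, 4 / 6)
  expect_equal(neg$recall, 1)
  expect_equal(res$macro_f1, mean(res$per_class$f1))
  expect_error(evaluate(model, test[0, ]), "empty test set")
})

test_that("never-predicted classes get precision 0 and are flagged", {
  model <- train_rules(data.frame(feature = "p", label = "A",
                                  stringsAsFactors = FALSE))
  res <- evaluate(model, data.frame(feature = c("p", "p"),
                                    label = c("A", "B"),
                                    stringsAsFactors = FALSE))
  b <- res$per_class[res$per_class$label == "B", ]
  expect_equal(b$precision, 0)
  expect_true(b$never_predicted)
  expect_equal(b$f1, 0)
})

test_that("accuracy equals micro-averaged recall; macro-F1 <= max class F1", {
  corp <- generate_corpus(small_cfg(n_explicit = 200, seed = 17))
  inst <- build_instances(corp, "first", "class")
  model <- train_rules(inst)
  res <- evaluate(model, inst)
  micro_recall <- sum(res$per_class$recall * res$per_class$support) /
    sum(res$per_class$support)
  expect_equal(res$accuracy, micro_recall)
  expect_lte(res$macro_f1, max(res$per_class$f1))
})

test_that("cross-validation is perfect on deterministic conditionals", {
  # every connective carries exactly one label and appears in every fold
  inst <- data.frame(
    feature = rep(c("because", "but", "then", "also"), each = 25),
    label = rep(c("Contingency", "Comparison", "Temporal", "Expansion"),
                each = 25),
    stringsAsFactors = FALSE)
  res <- cross_validate(inst, k = 10, seed = 4)
  expect_equal(res$accuracy, 1)
  expect_equal(res$macro_f1, 1)
  expect_error(cross_validate(inst[1:5, ], k = 10), "fewer instances")
  expect_error(cross_validate(inst, k = 1), "at least 2")
})

test_that("degenerate single-feature data scores the majority-class prior", {
  inst <- data.frame(feature = "and",
                     label = c(rep("Expansion", 70), rep("Temporal", 30)),
                     stringsAsFactors = FALSE)
  res <- evaluate(train_rules(inst), inst)
  expect_equal(res$accuracy, 0.7)
})

test_that("cross-validation is reproducible under a fixed seed", {
  corp <- generate_corpus(small_cfg(n_explicit = 300, seed = 23))
  inst <- build_instances(corp, "first", "class")
  r1 <- cross_validate(inst, k = 5, seed = 11)
  r2 <- cross_validate(inst, k = 5, seed = 11)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
})

test_that("learning curve uses one fixed test set and nested training sets", {
  inst <- data.frame(
    feature = rep(c("because", "but", "then", "also"), 50),
    label = rep(c("Contingency", "Comparison", "Temporal", "Expansion"), 50),
    stringsAsFactors = FALSE)
  curve <- learning_curve(inst, train_size = 150, test_size = 50,
                          increment = 30, seed = 2)
  expect_identical(curve$n_train, seq(30L, 150L, by = 30L))
  # deterministic conditionals: perfect once every connective is covered
  expect_equal(curve$accuracy[nrow(curve)], 1)
  expect_error(learning_curve(inst, 150, 50, increment = 40, seed = 1),
               "must divide")
  expect_error(learning_curve(inst, 190, 50, increment = 19, seed = 1),
               "exceeds")
})

test_that("learning curve is non-decreasing in expectation on synthetic data", {
  cfg <- small_cfg(n_explicit = 600, n_implicit = 0, n_altlex = 0,
                   n_norel = 0, seed = 41)
  inst <- build_instances(generate_corpus(cfg), "first", "class")
  finals <- firsts <- numeric(5)
  for (s in 1:5) {
    curve <- learning_curve(inst, train_size = 500, test_size = 100,
                            increment = 50, seed = s)
    firsts[s] <- curve$accuracy[1]
    finals[s] <- curve$accuracy[nrow(curve)]
  }
  se <- sqrt(0.25 / (5 * 100))
  expect_gte(mean(finals), mean(firsts) - 3 * se)
})

test_that("cross-domain evaluation: resubstitution and disjoint vocabularies", {
  corp <- generate_corpus(small_cfg(n_explicit = 250, seed = 29))
  inst <- build_instances(corp, "first", "class")
  resub <- evaluate(train_rules(inst), inst)
  xd <- cross_domain_eval(corp, corp)
  expect_equal(xd$accuracy, resub$accuracy)
  expect_equal(xd$per_class$f1, resub$per_class$f1)

  # disjoint connective vocabulary: pure fallback, accuracy = test prior of
  # the training majority class
  train_corp <- tiny_corpus(list(tiny_explicit(sense_label("Cause", "Reason"))))
  mk <- function(s1) {
    r <- relation_record("Explicit", arg1_spans = sp(0, 9),
                         arg2_spans = sp(44, 49), conn_spans = sp(40, 43),
                         sense1 = s1, doc_id = "tiny")
    r
  }
  test_corp <- tiny_corpus(list(mk(sense_label("Cause", "Claim")),
                                mk(sense_label("Contrast")),
                                mk(sense_label("Conjunction")),
                                mk(sense_label("Temporal", "Precedence"))))
  xd2 <- cross_domain_eval(train_corp, test_corp)
  expect_equal(xd2$accuracy, 0.25)   # Contingency prior in the test corpus
})
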