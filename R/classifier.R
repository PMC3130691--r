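#' Build classification instances from a corpus
#'
#' The classification task uses the case-insensitive connective surface
#' string as the *only* predictive feature; each explicit relation yields
#' one instance (or two, see below) labeled with a sense at the requested
#' granularity.  Because tokens may carry up to two senses, three scenarios
#' are defined:
#'
#' * `"first"` — every relation contributes one instance labeled with its
#'   first sense.
#' * `"second"` — one instance per relation, labeled with the second sense
#'   when present, otherwise the first.
#' * `"both"` — one instance per relation plus one *extra* instance for
#'   every relation with a second sense.
#'
#' @param corpus an [annotated_corpus()].
#' @param slot sense scenario, see Details.
#' @param granularity `"class"` (4-way generalized classes via `mapping`) or
#'   `"type"` (16 type-level senses).
#' @param mapping a [pdtb_class_mapping()].
#' @return Data frame with columns `feature` (normalized connective string)
#'   and `label`.
#' @export
build_instances <- function(corpus,
                            slot = c("first", "second", "both"),
                            granularity = c("class", "type"),
                            mapping = pdtb_class_mapping()) {
  slot <- match.arg(slot)
  granularity <- match.arg(granularity)
  stopifnot(is_corpus(corpus))
  lab <- function(sense) {
    if (granularity == "class") to_pdtb_class(sense, mapping) else sense$type
  }
  feats <- character(); labels <- character()
  for (doc in corpus$documents) {
    for (rec in doc$relations) {
      if (rec$rel_type != "Explicit") next
      if (is.null(rec$sense1)) {
        stop("explicit relation without sense1", call. = FALSE)
      }
      f <- conn_surface(rec, doc$text)
      picked <- switch(slot,
        first = list(rec$sense1),
        second = list(if (is.null(rec$sense2)) rec$sense1 else rec$sense2),
        both = c(list(rec$sense1),
                 if (!is.null(rec$sense2)) list(rec$sense2)))
      for (s in picked) {
        feats <- c(feats, f)
        labels <- c(labels, lab(s))
      }
    }
  }
  data.frame(feature = feats, label = labels, stringsAsFactors = FALSE)
}

#' Train the per-connective rule classifier
#'
#' With a single categorical feature, a confidence-rated rule learner's
#' decision surface reduces to one constant prediction per connective.  The
#' model therefore assigns to each training connective its training-majority
#' label (confidence = the label's relative frequency for that connective)
#' and falls back on the global majority label for unseen connectives.  Ties
#' are broken by the higher global label prior, then lexicographically, so
#' training is fully deterministic.
#'
#' @param train data frame with columns `feature`, `label` (from
#'   [build_instances()]).
#' @return An object of class `rule_model` with components `rules` (data
#'   frame `feature`, `label`, `confidence`, `n`), `fallback`, `labels`.
#' @export
train_rules <- function(train) {
  if (is.null(train) || nrow(train) == 0L) {
    stop("cannot train on an empty instance set", call. = FALSE)
  }
  prior <- table(train$label)
  pick <- function(counts) {
    # majority; ties -> higher global prior, then lexicographic
    best <- names(counts)[counts == max(counts)]
    if (length(best) > 1L) {
      pr <- prior[best]
      best <- best[pr == max(pr)]
      best <- sort(best)
    }
    best[1L]
  }
  feats <- sort(unique(train$feature))
  rules <- do.call(rbind, lapply(feats, function(f) {
    counts <- table(train$label[train$feature == f])
    lab <- pick(counts)
    data.frame(feature = f, label = lab,
               confidence = as.numeric(counts[lab]) / sum(counts),
               n = as.integer(sum(counts)), stringsAsFactors = FALSE)
  }))
  structure(list(rules = rules, fallback = pick(prior),
                 labels = sort(unique(train$label))),
            class = "rule_model")
}

#' @export
print.rule_model <- function(x, ...) {
  cat(sprintf("<rule_model> %d rule(s), fallback '%s'\n",
              nrow(x$rules), x$fallback))
  invisible(x)
}

#' Predict sense labels for connective features
#'
#' @param object a [train_rules()] model.
#' @param newdata character vector of normalized connective strings, or a
#'   data frame with a `feature` column.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.rule_model <- function(object, newdata, ...) {
  feats <- if (is.data.frame(newdata)) newdata$feature else newdata
  hit <- match(feats, object$rules$feature)
  out <- object$rules$label[hit]
  out[is.na(hit)] <- object$fallback
  out
}

#' Evaluate predictions on a test set
#'
#' @param model a [train_rules()] model.
#' @param test data frame with columns `feature`, `label`.
#' @return An `eval_result`: `accuracy`, `per_class` (data frame with
#'   `label`, `precision`, `recall`, `f1`, `support`, `never_predicted`),
#'   `macro_f1` (unweighted mean F1 over the union of observed and
#'   predicted labels).  A class that is never predicted has precision 0 by
#'   convention and is flagged.
#' @export
evaluate <- function(model, test) {
  if (is.null(test) || nrow(test) == 0L) {
    stop("cannot evaluate on an empty test set", call. = FALSE)
  }
  pred <- predict(model, test)
  truth <- test$label
  labels <- sort(union(truth, pred))
  per <- do.call(rbind, lapply(labels, function(l) {
    tp <- sum(pred == l & truth == l)
    fp <- sum(pred == l & truth != l)
    fn <- sum(pred != l & truth == l)
    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(label = l, precision = prec, recall = rec, f1 = f1,
               support = as.integer(sum(truth == l)),
               never_predicted = (tp + fp == 0L),
               stringsAsFactors = FALSE)
  }))
  structure(list(accuracy = mean(pred == truth), per_class = per,
                 macro_f1 = mean(per$f1), n = nrow(test)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> accuracy %.3f, macro-F1 %.3f (n = %d)\n",
              x$accuracy, x$macro_f1, x$n))
  print.data.frame(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}

#' k-fold cross-validation of the rule classifier
#'
#' Instances are partitioned into `k` folds uniformly at random (seeded,
#' non-stratified); each fold is held out once, the model is trained on the
#' remainder, and the evaluation metrics are averaged over folds.
#'
#' @param instances data frame with `feature`, `label`.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return An `eval_result` whose `accuracy`, `macro_f1` and per-class
#'   metrics are fold means; component `fold_accuracy` holds the per-fold
#'   accuracies.
#' @export
cross_validate <- function(instances, k = 10L, seed = 1L) {
  n <- nrow(instances)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("fewer instances than folds", call. = FALSE)
  fold <- local_seed(seed, sample(rep_len(seq_len(k), n)))
  evals <- lapply(seq_len(k), function(f) {
    evaluate(train_rules(instances[fold != f, , drop = FALSE]),
             instances[fold == f, , drop = FALSE])
  })
  acc <- vapply(evals, `[[`, 0, "accuracy")
  labels <- sort(unique(unlist(lapply(evals, function(e) e$per_class$label))))
  per <- do.call(rbind, lapply(labels, function(l) {
    rows <- lapply(evals, function(e) {
      e$per_class[e$per_class$label == l, , drop = FALSE]
    })
    rows <- do.call(rbind, rows[vapply(rows, nrow, 0L) > 0L])
    data.frame(label = l, precision = mean(rows$precision),
               recall = mean(rows$recall), f1 = mean(rows$f1),
               support = as.integer(sum(rows$support)),
               never_predicted = all(rows$never_predicted),
               stringsAsFactors = FALSE)
  }))
  structure(list(accuracy = mean(acc), per_class = per,
                 macro_f1 = mean(vapply(evals, `[[`, 0, "macro_f1")),
                 n = n, k = k, fold_accuracy = acc),
            class = "eval_result")
}

#' Learning curve at fixed test set
#'
#' Splits the instances into a seeded training pool of `train_size` and a
#' held-out test set of `test_size`, then trains on nested subsets of sizes
#' `increment, 2*increment, ..., train_size`, evaluating every model on the
#' *same* test set.
#'
#' @param instances data frame with `feature`, `label`.
#' @param train_size,test_size,increment sizes in instances;
#'   `increment` must divide `train_size` and
#'   `train_size + test_size <= nrow(instances)`.
#' @param seed RNG seed for the split and the pool order.
#' @return Data frame with columns `n_train`, `accuracy`.
#' @export
learning_curve <- function(instances, train_size, test_size, increment,
                           seed = 1L) {
  train_size <- as.integer(train_size)
  test_size <- as.integer(test_size)
  increment <- as.integer(increment)
  n <- nrow(instances)
  if (train_size %% increment != 0L) {
    stop("increment must divide train_size", call. = FALSE)
  }
  if (train_size + test_size > n) {
    stop("train_size + test_size exceeds the number of instances",
         call. = FALSE)
  }
  idx <- local_seed(seed, sample.int(n))
  test <- instances[idx[seq_len(test_size)], , drop = FALSE]
  pool <- instances[idx[test_size + seq_len(train_size)], , drop = FALSE]
  sizes <- seq.int(increment, train_size, by = increment)
  acc <- vapply(sizes, function(m) {
    evaluate(train_rules(pool[seq_len(m), , drop = FALSE]), test)$accuracy
  }, 0)
  data.frame(n_train = sizes, accuracy = acc)
}

#' Cross-domain evaluation
#'
#' Trains the rule classifier on every instance of one corpus and evaluates
#' it on every instance of another, with labels collapsed to the four
#' generalized classes so that corpora annotated under different sense
#' inventories remain comparable.
#'
#' @param train_corpus,test_corpus [annotated_corpus()] objects.
#' @param mapping a [pdtb_class_mapping()].
#' @param slot sense scenario (default `"first"`).
#' @param granularity label granularity (default `"class"`).
#' @return An `eval_result` with class-wise precision/recall/F1.
#' @export
cross_domain_eval <- function(train_corpus, test_corpus,
                              mapping = pdtb_class_mapping(),
                              slot = "first", granularity = "class") {
  train <- build_instances(train_corpus, slot, granularity, mapping)
  test <- build_instances(test_corpus, slot, granularity, mapping)
  evaluate(train_rules(train), test)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
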