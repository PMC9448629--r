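test_that("count derivations and validation", {
  cc <- evaluation_counts(tp = 5, fp = 2, fn = 3, tn = 10)
  expect_equal(cc$air, 8)    # TP + FN
  expect_equal(cc$dr, 7)     # TP + FP
  expect_equal(cc$cdr, 15)   # TP + TN
  expect_error(evaluation_counts(-1, 0, 0), "non-negative")
  expect_error(metrics_from_totals(10, 5, 20), ">= TP")
})

test_that("metric identities: harmonic mean, bounds, equal-rate case", {
  m <- compute_metrics(evaluation_counts(tp = 30, fp = 30, fn = 30))
  expect_equal(m$precision, m$recall)
  expect_equal(m$f1, m$precision)          # F1 = P = R when P == R
  set.seed(81)
  for (i in 1:200) {
    cc <- evaluation_counts(tp = rpois(1, 20), fp = rpois(1, 10),
                            fn = rpois(1, 10), tn = rpois(1, 50))
    m <- compute_metrics(cc)
    if (m$precision_defined && m$recall_defined && m$f1 > 0) {
      expect_equal(m$f1,
                   2 * m$precision * m$recall / (m$precision + m$recall))
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("zero denominators flag as undefined instead of erroring", {
  m <- compute_metrics(evaluation_counts(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_false(m$precision_defined)
  expect_false(m$recall_defined)
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
})

test_that("confusion counts agree with an independent per-pair tally", {
  expect_error(confusion_counts(c("BC", "QDC"), "BC", "BC"), "equal length")
  # all correct, single class
  cc <- confusion_counts(rep("BC", 4), rep("BC", 4), "BC")
  expect_equal(c(cc$fp, cc$fn), c(0, 0))
  expect_equal(compute_metrics(cc)$precision, 1)
  # empty predictions count as negative decisions
  cc2 <- confusion_counts(rep(NA_character_, 5), rep("BC", 5), "BC")
  expect_equal(cc2$tp, 0)
  expect_equal(cc2$fn, 5)
  set.seed(91)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    pred <- sample(c(constitution_labels, NA), n, replace = TRUE)
    truth <- sample(constitution_labels, n, replace = TRUE)
    cl <- sample(constitution_labels, 1)
    cc <- confusion_counts(pred, truth, cl)
    tally <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (j in seq_len(n)) {
      p <- !is.na(pred[j]) && pred[j] == cl
      t <- truth[j] == cl
      k <- if (p && t) "tp" else if (p) "fp" else if (t) "fn" else "tn"
      tally[k] <- tally[k] + 1
    }
    expect_equal(c(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn), tally)
    expect_equal(sum(tally), n)
  }
})

test_that("macro averages are invariant to class relabeling", {
  set.seed(101)
  pred <- sample(constitution_labels[1:4], 80, replace = TRUE)
  truth <- sample(constitution_labels[1:4], 80, replace = TRUE)
  ev1 <- evaluate_predictions(pred, truth)
  perm <- stats::setNames(constitution_labels[c(3, 1, 4, 2)],
                          constitution_labels[1:4])
  ev2 <- evaluate_predictions(unname(perm[pred]), unname(perm[truth]))
  expect_equal(ev2$macro, ev1$macro)
})

test_that("fold assignment is balanced, deterministic and stratified", {
  # the printed-corpus arithmetic: 30,071 records in 10 folds
  labels <- sample(constitution_labels, 30071, replace = TRUE)
  folds <- make_folds(labels, k = 10, seed = 4)
  sizes <- tabulate(folds, 10)
  expect_equal(sort(sizes), c(rep(3007L, 9), 3008L))
  expect_identical(folds, make_folds(labels, k = 10, seed = 4))
  expect_false(identical(folds, make_folds(labels, k = 10, seed = 5)))
  # disjoint + exhaustive by construction; per-class balance within 1
  for (cl in constitution_labels) {
    per <- tabulate(folds[labels == cl], 10)
    expect_lte(max(per) - min(per), 1)
  }
  # unstratified folds are still size-balanced
  f2 <- make_folds(labels[1:103], k = 10, seed = 1, stratify = FALSE)
  expect_lte(diff(range(tabulate(f2, 10))), 1)
  expect_error(make_folds(labels[1:5], k = 10), "at least k")
  expect_error(make_folds(labels, k = 1), "k must be")
})

test_that("cross-validation recovers a near-deterministic planted world", {
  sim <- gen_corpus(600, "noise_free", seed = 21)
  cv <- cross_validate(sim$records, k = 5, seed = 2, min_support_count = 10)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(sum(cv$folds$n_test), 600)
  expect_gte(cv$mean[["precision"]], 0.95)
  expect_gte(cv$mean[["recall"]], 0.95)
  expect_error(cross_validate(sim$records[1:5], k = 10), "at least k")
})
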