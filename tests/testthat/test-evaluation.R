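test_that("thresholding is inclusive at tau", {
  expect_equal(apply_threshold(c(0.2, 0.8), 0.5), c(0L, 1L))
  expect_equal(apply_threshold(c(0.2, 0.8), 0), c(1L, 1L))
  expect_equal(apply_threshold(0.37, 0.37), 1L)
  expect_error(apply_threshold(c(0.2), 1.5), "\\[0, 1\\]")
})

test_that("confusion counts partition the samples", {
  expect_equal(unlist(confusion(c(0, 1), c(0, 1))[c("fp", "fn")]),
               c(fp = 0L, fn = 0L))
  cm <- confusion(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(unlist(cm), c(tn = 1L, fp = 1L, fn = 1L, tp = 1L))
  expect_equal(as.matrix(cm), matrix(c(1, 1, 1, 1), 2, 2,
               dimnames = list(true = c("No_DR", "DR"), pred = c("No_DR", "DR"))))
  # all-negative predictor on a 361/372 test composition
  labels <- c(rep(0, 361), rep(1, 372))
  cm2 <- confusion(labels, rep(0, 733))
  expect_equal(unlist(cm2), c(tn = 361L, fp = 0L, fn = 372L, tp = 0L))
  expect_error(confusion(c(0, 1), c(0, 1, 1)), "length")
})

test_that("published per-model confusion matrices reproduce their metric rows", {
  # best-configuration matrices for the four CNN backbones with the
  # accuracy/precision/recall/F1 rows printed alongside them (2 dp)
  cases <- list(
    list(cm = c(354, 7, 3, 369), acc = 98.64, prec = 98.14, rec = 99.19, f1 = 98.66),
    list(cm = c(352, 9, 3, 369), acc = 98.36, prec = 97.62, rec = 99.19, f1 = 98.40),
    list(cm = c(353, 8, 4, 368), acc = 98.36, prec = 97.87, rec = 98.92, f1 = 98.40),
    list(cm = c(352, 9, 4, 368), acc = 98.23, prec = 97.61, rec = 98.92, f1 = 98.26)
  )
  for (cs in cases) {
    m <- metrics_from_confusion(do.call(confusion_matrix, as.list(cs$cm)))
    expect_equal(round(m$accuracy, 2), cs$acc)
    expect_equal(round(m$precision, 2), cs$prec)
    expect_equal(round(m$recall, 2), cs$rec)
    expect_equal(round(m$f1, 2), cs$f1)
  }
})

test_that("degenerate and perfect classifiers hit the zero-denominator conventions", {
  # all-negative predictor on 361 negatives / 372 positives
  m <- metrics_from_confusion(confusion_matrix(361, 0, 372, 0))
  expect_equal(m$accuracy, 100 * 361 / 733)
  expect_equal(m$accuracy, 49.24, tolerance = 0.01)
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
  perfect <- metrics_from_confusion(confusion_matrix(10, 0, 0, 10))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "specificity", "f1", "balanced_accuracy")]) == 100))
  expect_error(confusion_matrix(0, 0, 0, 0), "at least one")
})

test_that("accuracy decomposes into prevalence-weighted recall and specificity", {
  set.seed(13)
  for (rep in 1:25) {
    counts <- rmultinom(1, size = sample(10:500, 1), prob = runif(4, 0.05, 1))[, 1]
    if (sum(counts) == 0) next
    cm <- confusion_matrix(counts[1], counts[2], counts[3], counts[4])
    m <- metrics_from_confusion(cm)
    total <- sum(counts)
    lhs <- m$accuracy
    rhs <- (m$recall * (cm$tp + cm$fn) + m$specificity * (cm$tn + cm$fp)) / total
    expect_equal(lhs, rhs, tolerance = 1e-9)
    expect_equal(m$balanced_accuracy, (m$recall + m$specificity) / 2, tolerance = 1e-9)
  }
})

test_that("ROC-AUC equals the pairwise Mann-Whitney oracle", {
  labels <- c(0, 0, 1, 1)
  expect_equal(roc_auc(labels, c(0.1, 0.2, 0.8, 0.9)), 100)
  expect_equal(roc_auc(labels, rep(0.5, 4)), 50)
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(labels, scores), oracle_auc_pairwise(labels, scores),
                 tolerance = 1e-9)
  }
  expect_error(roc_auc(rep(1, 4), runif(4)), "both classes")
})

test_that("ROC-AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  labels <- rbinom(200, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- plogis(rnorm(200, mean = labels))
  ref <- 100 * as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<")))
  expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-8)
})

test_that("ROC-AUC is invariant to strictly increasing score transforms", {
  set.seed(37)
  labels <- rbinom(100, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- runif(100)
  base <- roc_auc(labels, scores)
  expect_equal(roc_auc(labels, scores^3), base)
  expect_equal(roc_auc(labels, plogis(7 * scores - 3)), base)
})

test_that("threshold sweep returns the smallest grid maximizer", {
  # separated classes: any tau in (0.3, 0.7] is perfect; smallest grid point 0.31
  scores <- c(0.05, 0.15, 0.30, 0.70, 0.85, 0.95)
  labels <- c(0, 0, 0, 1, 1, 1)
  res <- optimize_threshold(labels, scores, "f1", step = 0.01)
  expect_equal(res$tau_star, 0.31)
  expect_equal(res$best_value, 100)
  # tau = 0 predicts everything positive: recall 100, precision = prevalence
  at0 <- res$curve$value[res$curve$tau == 0]
  m0 <- metrics_from_confusion(confusion(labels, rep(1L, 6)))
  expect_equal(m0$recall, 100)
  expect_equal(m0$precision, 50)
  expect_equal(at0, m0$f1)
  # the returned optimum dominates every grid point
  expect_true(all(res$best_value >= res$curve$value))
  expect_error(optimize_threshold(rep(1, 5), runif(5)), "both classes")
  expect_error(optimize_threshold(labels, scores, step = 0), "step")
})

test_that("threshold sweep matches an independent exhaustive search", {
  set.seed(43)
  for (objective in c("f1", "balanced_accuracy", "accuracy")) {
    for (rep in 1:10) {
      n <- sample(20:80, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.45))
      scores <- plogis(rnorm(n, mean = 1.5 * labels))
      res <- optimize_threshold(labels, scores, objective, step = 0.01)
      ref <- oracle_best_tau(labels, scores, objective, step = 0.01)
      expect_equal(res$tau_star, ref$tau)
      expect_equal(res$best_value, ref$value, tolerance = 1e-9)
    }
  }
})

test_that("evaluate_scores bundles confusion, metrics and AUC", {
  labels <- c(0, 0, 1, 1)
  ev <- evaluate_scores(labels, c(0.1, 0.6, 0.7, 0.9), tau = 0.5)
  expect_equal(unlist(ev$confusion), c(tn = 1L, fp = 1L, fn = 0L, tp = 2L))
  expect_equal(ev$metrics$auc, 100)
})
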