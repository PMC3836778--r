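test_that("metric formulas reproduce hand-computed values and conventions", {
  m <- metrics_from_counts(TP = 10, FN = 0, TN = 10, FP = 0)
  expect_equal(m$MCC, 1)
  expect_equal(m$Q2, 1)
  # the 136/957-split profile, frozen from direct arithmetic
  m <- metrics_from_counts(TP = 112, FN = 24, TN = 928, FP = 29)
  expect_equal(m$sensitivity, 112 / 136, tolerance = 1e-12)
  expect_equal(m$specificity, 928 / 957, tolerance = 1e-12)
  expect_equal(m$Q2, 1040 / 1093, tolerance = 1e-12)
  expect_equal(m$MCC, 0.7810782, tolerance = 1e-6)
  # all-positive degenerate classifier on a balanced set
  m <- metrics_from_counts(TP = 25, FN = 0, TN = 0, FP = 25)
  expect_equal(m$MCC, 0)
  expect_true(m$mcc_degenerate)
  expect_equal(m$Q2, 0.5)
})

test_that("metrics from counts agree with per-example tallies on random prediction vectors", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    labels <- rbinom(n, 1, 0.5)
    calls <- rbinom(n, 1, 0.5)
    m <- metrics_from_counts(TP = sum(labels & calls), FN = sum(labels & !calls),
                             TN = sum(!labels & !calls), FP = sum(!labels & calls))
    expect_equal(m$Q2, mean(labels == calls), tolerance = 1e-12)
    if (any(labels == 1)) {
      expect_equal(m$sensitivity, mean(calls[labels == 1] == 1), tolerance = 1e-12)
    }
    if (any(labels == 0)) {
      expect_equal(m$specificity, mean(calls[labels == 0] == 0), tolerance = 1e-12)
    }
  }
})

test_that("rank-method AUC equals all-pairs concordance and known cases", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  # one discordant pair out of nine
  expect_equal(roc_auc(c(1, 1, 1, 0, 0, 0),
                       c(0.9, 0.8, 0.4, 0.5, 0.3, 0.2))$auc, 8 / 9,
               tolerance = 1e-12)
  set.seed(15)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    labels <- c(1L, 0L, rbinom(n - 2, 1, 0.5))     # both classes guaranteed
    scores <- round(runif(n), 2)                   # ties likely
    expect_equal(roc_auc(labels, scores)$auc,
                 oracle_auc_pairs(labels, scores), tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "both classes")
})

test_that("rank-method AUC matches an independent ROC library", {
  set.seed(16)
  labels <- rbinom(200, 1, 0.3)
  labels[1:2] <- c(0L, 1L)
  scores <- runif(200) + 0.4 * labels
  expect_equal(roc_auc(labels, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("RI coverage curve has 11 rows, full coverage at t = 0, non-increasing fraction", {
  set.seed(17)
  labels <- rbinom(120, 1, 0.4)
  O <- pmin(pmax(labels * 0.6 + runif(120, 0, 0.4), 0), 1)
  curve <- ri_coverage_curve(labels, O)
  expect_identical(nrow(curve), 11L)
  expect_identical(curve$RI_threshold, 0:10)
  expect_equal(curve$fraction[1], 1)
  expect_true(all(diff(curve$fraction) <= 1e-12))
  # all-correct, maximally confident corner
  curve2 <- ri_coverage_curve(rep(1L, 5), rep(1.0, 5))
  expect_true(all(curve2$fraction == 1))
  expect_true(all(curve2$accuracy == 1))
})

test_that("cross-validation stratifies, conserves counts, and is seed-reproducible", {
  ds <- make_toy_dataset(n_per_class = 24, seed = 22)
  p <- pseaac_params("I", 0.05, 3)
  cv <- cross_validate(ds, p, folds = 6, seed = 4, ntree = 100)
  expect_identical(nrow(cv$predictions), 48L)
  # per-class fold sizes differ by at most 1
  tab <- table(cv$predictions$fold, cv$predictions$label)
  expect_true(all(apply(tab, 2, function(x) diff(range(x))) <= 1))
  # fold test sizes sum to n
  expect_equal(sum(rowSums(cv$per_fold[, c("TP", "FN", "TN", "FP")])), 48)
  cv2 <- cross_validate(ds, p, folds = 6, seed = 4, ntree = 100)
  expect_identical(cv$predictions$propensity, cv2$predictions$propensity)
  # 2-fold and folds = n both run with conserved counts (the latter reduces
  # to per-class leave-one-out under stratification, with a warning)
  small <- make_toy_dataset(n_per_class = 6, seed = 23)
  for (k in c(2L, 12L)) {
    cvk <- suppressWarnings(
      cross_validate(small, p, folds = k, seed = 1, ntree = 50))
    expect_equal(sum(rowSums(cvk$per_fold[, c("TP", "FN", "TN", "FP")])), 12)
  }
})

test_that("fold count drops to the rarer class size with a warning", {
  ds <- generate_fixture(fixture_spec(5, 40, c(60, 90), delta = 0.3, seed = 24))
  expect_warning(
    cv <- cross_validate(ds, pseaac_params("I", 0.05, 2), folds = 20,
                         seed = 1, ntree = 50),
    "using 5 folds")
  expect_identical(cv$folds, 5L)
})

test_that("parameter sweep covers the grid and sorts by MCC with stable ties", {
  ds <- make_toy_dataset(n_per_class = 15, seed = 25)
  res <- parameter_sweep(ds, types = "I", w_grid = 0.05, lambda_grid = c(1, 2),
                         folds = 3, seed = 2, ntree = 50)
  expect_identical(nrow(res), 2L)
  expect_true(all(diff(res$MCC) <= 0))
  res2 <- parameter_sweep(ds, types = c("I", "II"), w_grid = c(0.05, 0.5),
                          lambda_grid = c(1, 3), folds = 3, seed = 2, ntree = 50)
  expect_identical(nrow(res2), 8L)
  expect_identical(res2$MCC[1], max(res2$MCC))
})

test_that("terminal scan emits one row per (terminal, k) and is truncation-consistent at large k", {
  ds <- make_toy_dataset(n_per_class = 15, seed = 26, length_range = c(60L, 80L))
  p <- pseaac_params("I", 0.05, 3)
  res <- terminal_scan(ds, p, lengths = c(17, 50), folds = 3, seed = 6, ntree = 50)
  expect_identical(nrow(res), 4L)
  # k beyond every sequence: N and C scans see identical data, folds and seeds
  res_full <- terminal_scan(ds, p, lengths = 100, folds = 3, seed = 6, ntree = 50)
  expect_identical(res_full$MCC[res_full$terminal == "N"],
                   res_full$MCC[res_full$terminal == "C"])
})

test_that("propensity correlation reproduces OLS facts and affine invariance", {
  # perfectly collinear (lm warns about the perfect fit; that is the point)
  expect_equal(
    suppressWarnings(propensity_correlation(c(0.1, 0.5, 0.9), c(10, 50, 90)))$r_squared,
    1)
  set.seed(18)
  x <- runif(10); y <- 3 * x + rnorm(10, 0, 0.2)
  r1 <- propensity_correlation(x, y)
  r2 <- propensity_correlation(2 * x + 1, 5 * y - 3)
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-12)
  expect_error(propensity_correlation(c(0.1, 0.2), c(1, 2)), "at least 3")
  expect_error(propensity_correlation(rep(0.5, 4), c(1, 2, 3, 4)), "zero variance")
})

test_that("derived sub-seeds are stable, label-sensitive, and in range", {
  expect_identical(derive_seed(1, "folds"), derive_seed(1, "folds"))
  expect_false(derive_seed(1, "folds") == derive_seed(2, "folds"))
  expect_false(derive_seed(1, "folds") == derive_seed(1, "forest", 1))
  seeds <- vapply(1:50, function(i) derive_seed(i, "x", i), 1L)
  expect_true(all(seeds >= 1L & seeds <= 2147483646))
})
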