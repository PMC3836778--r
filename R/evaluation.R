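#' Derive a reproducible sub-seed from a master seed
#'
#' A stable string hash combining the master seed with arbitrary labels, so
#' independent randomized steps (fold assignment, per-grid-point forests,
#' fixture streams) get distinct but reproducible seeds. The hash is a
#' polynomial rolling hash modulo 2^31 - 1, identical across platforms.
#'
#' @param master Integer master seed.
#' @param ... Labels (coerced to character) identifying the consumer.
#' @return A single integer seed in 1 .. 2^31 - 2.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = ":")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  h <- (h + (as.double(master) %% 2147483647) * 2654435) %% 2147483646
  as.integer(h + 1)
}

#' Classification metrics from confusion counts
#'
#' Computes the metric suite from pooled confusion counts: sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, overall accuracy
#' `Q2 = (TP+TN)/(TP+TN+FP+FN)`, and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' When any factor of the MCC denominator is zero (a degenerate classifier
#' or a single-class evaluation set) MCC is defined as 0, the standard
#' continuity convention; the report flags this case.
#'
#' @param TP,FN,TN,FP Non-negative integer confusion counts (true/false
#'   positives/negatives; positives are secreted proteins).
#' @return An object of class `metrics_report`: list with `sensitivity`,
#'   `specificity`, `Q2`, `MCC`, `counts`, `mcc_degenerate`.
#' @examples
#' m <- metrics_from_counts(TP = 112, FN = 24, TN = 928, FP = 29)
#' round(c(m$sensitivity, m$specificity, m$Q2, m$MCC), 2)
#' @export
metrics_from_counts <- function(TP, FN, TN, FP) {
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("confusion counts must be non-negative with a positive total")
  }
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  q2 <- (TP + TN) / sum(counts)
  denom2 <- as.double(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  degenerate <- denom2 == 0
  mcc <- if (degenerate) 0 else
    (as.double(TP) * TN - as.double(FP) * FN) / sqrt(denom2)
  structure(
    list(sensitivity = sens, specificity = spec, Q2 = q2, MCC = mcc,
         counts = counts, mcc_degenerate = degenerate),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MCC %.3f | Q2 %.3f | sensitivity %.3f | specificity %.3f%s\n",
              x$MCC, x$Q2, x$sensitivity, x$specificity,
              if (!is.null(x$AUC)) sprintf(" | AUC %.3f", x$AUC) else ""))
  cat(sprintf("  counts: TP %d, FN %d, TN %d, FP %d\n",
              x$counts["TP"], x$counts["FN"], x$counts["TN"], x$counts["FP"]))
  invisible(x)
}

# pooled confusion counts from labels and calls (O >= 0.5 => secreted)
.confusion <- function(labels, O) {
  call_pos <- O >= 0.5
  metrics_from_counts(
    TP = sum(labels == 1L & call_pos),
    FN = sum(labels == 1L & !call_pos),
    TN = sum(labels == 0L & !call_pos),
    FP = sum(labels == 0L & call_pos)
  )
}

#' Area under the ROC curve by the rank method
#'
#' AUC computed as the Mann-Whitney statistic: with `r` the (midrank-tied)
#' ranks of all scores, `AUC = (sum of positive ranks - n_pos(n_pos+1)/2) /
#' (n_pos * n_neg)`. Equivalent to the trapezoidal area under the empirical
#' ROC curve with tied scores sharing rank. Also returns the curve points.
#'
#' @param labels 0/1 vector.
#' @param O Scores (propensities), same length.
#' @return List with `auc` and `curve`, a `data.frame` of
#'   `(threshold, fpr, tpr)` sorted from the most permissive threshold.
#' @export
roc_auc <- function(labels, O) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("ROC requires both classes present")
  r <- rank(O)                      # midranks for ties
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(O), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(O >= t & labels == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(O >= t & labels == 0L) / n_neg, 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}

#' Reliability-index coverage curve
#'
#' For each reliability-index threshold `t = 0..10`, the fraction of
#' proteins with `RI >= t` and the prediction accuracy among them — the
#' cumulative accuracy-vs-coverage trade-off of the reliability index. The
#' coverage fraction is non-increasing in `t`; the `t = 0` row always covers
#' everything.
#'
#' @param labels 0/1 vector.
#' @param O Out-of-fold propensities, same length.
#' @return `data.frame` with columns `RI_threshold`, `fraction`, `accuracy`
#'   (`NA` where no protein reaches the threshold).
#' @export
ri_coverage_curve <- function(labels, O) {
  labels <- as.integer(labels)
  ri <- reliability_index(O)
  correct <- (O >= 0.5) == (labels == 1L)
  do.call(rbind, lapply(0:10, function(t) {
    sel <- ri >= t
    data.frame(RI_threshold = t,
               fraction = mean(sel),
               accuracy = if (any(sel)) mean(correct[sel]) else NA_real_)
  }))
}

# deterministic stratified fold assignment: within each class, ids are
# shuffled under the fold seed and dealt round-robin, so per-class fold
# sizes differ by at most one
.assign_folds <- function(labels, folds, fold_seed) {
  n <- length(labels)
  fold_of <- integer(n)
  set.seed(fold_seed)
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' Stratified k-fold cross-validation of the secretion predictor
#'
#' Encodes the dataset once with the given PseAAC parameters, assigns
#' stratified folds (deterministic under the seed), trains one random
#' forest per fold and scores its held-out proteins. Confusion counts are
#' pooled (micro-averaged) over all out-of-fold predictions before the
#' metric formulas are applied; the out-of-fold propensities are retained
#' for ROC and reliability-index analyses.
#'
#' Stratification keeps every fold populated with both classes even at the
#' 136:957 imbalance typical of this problem. If the rarer class has fewer
#' members than `folds`, the fold count is reduced to it with a warning.
#'
#' @param dataset A `labeled_dataset` (see [attach_labels()]), or a list
#'   with `features` (matrix) and `labels` for pre-encoded input.
#' @param params A [pseaac_params()] object (ignored for pre-encoded input).
#' @param folds Number of folds (default 20).
#' @param seed Master seed; fold assignment and per-fold forest seeds are
#'   derived from it via [derive_seed()].
#' @param ntree Trees per forest.
#' @param table An [aa_property_table()].
#' @param fold_seed Override for the fold-assignment seed (used by the
#'   parameter sweep so every grid point sees identical folds).
#' @return An object of class `cv_result`: `metrics` (a `metrics_report`
#'   with `AUC` added), `predictions` (`data.frame`: id, label, fold,
#'   propensity, call, RI), `per_fold` (fold-wise confusion counts),
#'   `folds`, `params`.
#' @export
cross_validate <- function(dataset, params = pseaac_params(), folds = 20L,
                           seed = 1L, ntree = 500L,
                           table = aa_property_table(), fold_seed = NULL) {
  if (inherits(dataset, "labeled_dataset")) {
    features <- encode_batch(dataset$sequences, params, table)
    labels <- as.integer(dataset$labels)
  } else {
    features <- as.matrix(dataset$features)
    labels <- as.integer(dataset$labels)
  }
  n_by_class <- c(sum(labels == 0L), sum(labels == 1L))
  if (any(n_by_class == 0L)) stop("both classes must be present for cross-validation")
  folds <- as.integer(folds)
  if (min(n_by_class) < folds) {
    folds <- min(n_by_class)
    warning(sprintf("rarer class has fewer members than requested folds; using %d folds", folds))
  }
  if (is.null(fold_seed)) fold_seed <- derive_seed(seed, "folds")
  fold_of <- .assign_folds(labels, folds, fold_seed)

  O <- numeric(length(labels))
  for (f in seq_len(folds)) {
    test <- fold_of == f
    fit <- train_forest(features[!test, , drop = FALSE], labels[!test],
                        ntree = ntree, seed = derive_seed(seed, "forest", f))
    O[test] <- predict(fit, features[test, , drop = FALSE])$propensity
  }

  metrics <- .confusion(labels, O)
  metrics$AUC <- roc_auc(labels, O)$auc
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  predictions <- data.frame(
    id = ids, label = labels, fold = fold_of, propensity = O,
    call = ifelse(O >= 0.5, "secreted", "not_secreted"),
    RI = reliability_index(O), stringsAsFactors = FALSE
  )
  per_fold <- do.call(rbind, lapply(seq_len(folds), function(f) {
    m <- .confusion(labels[fold_of == f], O[fold_of == f])
    data.frame(fold = f, TP = m$counts["TP"], FN = m$counts["FN"],
               TN = m$counts["TN"], FP = m$counts["FP"], row.names = NULL)
  }))
  structure(
    list(metrics = metrics, predictions = predictions, per_fold = per_fold,
         folds = folds, params = params),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d proteins)\n",
              x$folds, nrow(x$predictions)))
  print(x$metrics)
  invisible(x)
}

#' Sweep PseAAC parameters with cross-validation
#'
#' Runs [cross_validate()] at every point of a (type, w, lambda) grid and
#' tabulates the metric suite, sorted by MCC (descending, stable: ties keep
#' grid order — type, then w, then lambda). All grid points share one fold
#' assignment (derived from the master seed) so rows are comparable; each
#' point gets its own forest seed derived from (seed, type, w, lambda).
#'
#' The default grid spans the region where this family of models is
#' typically tuned: `w` in 0.05..0.5 by 0.05 and `lambda` in 1..20.
#'
#' @param dataset A `labeled_dataset`.
#' @param types Encoding types to sweep, subset of `c("I", "II")`.
#' @param w_grid Weight-factor grid.
#' @param lambda_grid Correlation-rank grid.
#' @param folds,seed,ntree,table As in [cross_validate()].
#' @param properties Property scales (Type II tracks).
#' @return `data.frame` with one row per grid point: `type`, `w`, `lambda`,
#'   `MCC`, `Q2`, `sensitivity`, `specificity`, `AUC`, sorted by MCC
#'   descending.
#' @export
parameter_sweep <- function(dataset, types = c("I", "II"),
                            w_grid = seq(0.05, 0.5, by = 0.05),
                            lambda_grid = 1:20, folds = 20L, seed = 1L,
                            ntree = 500L, table = aa_property_table(),
                            properties = SCALE_NAMES) {
  stopifnot(length(types) > 0, length(w_grid) > 0, length(lambda_grid) > 0)
  fold_seed <- derive_seed(seed, "folds")
  grid <- expand.grid(lambda = lambda_grid, w = w_grid, type = types,
                      stringsAsFactors = FALSE)[, c("type", "w", "lambda")]
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    type <- grid$type[g]; w <- grid$w[g]; lam <- grid$lambda[g]
    p <- pseaac_params(type = type, w = w, lambda = lam, properties = properties)
    cv <- cross_validate(dataset, p, folds = folds,
                         seed = derive_seed(seed, type, w, lam),
                         ntree = ntree, table = table, fold_seed = fold_seed)
    m <- cv$metrics
    data.frame(type = type, w = w, lambda = lam, MCC = m$MCC, Q2 = m$Q2,
               sensitivity = m$sensitivity, specificity = m$specificity,
               AUC = m$AUC, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$MCC), , drop = FALSE]   # stable: ties keep grid order
  rownames(out) <- NULL
  out
}

#' Terminal truncation scan
#'
#' Measures how much of the secretion signal sits at each end of the
#' sequence: for every window length `k` and each terminal, every protein
#' is truncated to its first (N) or last (C) `k` residues, re-encoded
#' (short windows use the effective correlation rank, keeping the feature
#' dimension fixed), and cross-validated. Folds and the per-`k` forest seed
#' are shared between the N and C scans, so at `k` beyond the longest
#' sequence the two terminals give identical results.
#'
#' @param dataset A `labeled_dataset`.
#' @param params Base [pseaac_params()] (its truncation field is
#'   overwritten).
#' @param lengths Integer vector of window lengths `k`.
#' @param terminals Subset of `c("N", "C")`.
#' @param folds,seed,ntree,table As in [cross_validate()].
#' @return `data.frame` with one row per (terminal, k): `terminal`, `k`,
#'   `MCC`, `Q2`, `AUC`.
#' @export
terminal_scan <- function(dataset, params = pseaac_params(), lengths,
                          terminals = c("N", "C"), folds = 20L, seed = 1L,
                          ntree = 500L, table = aa_property_table()) {
  lengths <- as.integer(lengths)
  if (any(lengths < 2L)) stop("window lengths must be >= 2")
  fold_seed <- derive_seed(seed, "folds")
  rows <- list()
  for (term in terminals) {
    for (k in lengths) {
      p <- params
      p$truncation <- list(terminal = term, k = k)
      cv <- cross_validate(dataset, p, folds = folds,
                           seed = derive_seed(seed, "scan", k),
                           ntree = ntree, table = table, fold_seed = fold_seed)
      m <- cv$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        terminal = term, k = k, MCC = m$MCC, Q2 = m$Q2, AUC = m$AUC,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between predicted propensity and measured secretion
#'
#' Ordinary least squares of the measured extracellular percentage on the
#' predicted secretion propensity, as used to validate predictions against
#' expression experiments. R-squared equals the squared Pearson correlation.
#'
#' @param propensity Predicted propensities (at least 3).
#' @param measured Measured extracellular percentages, same length.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @examples
#' panel <- read.delim(system.file("extdata", "beta_galactosidase_panel.tsv",
#'                                 package = "pichiasec"), comment.char = "#")
#' propensity_correlation(panel$propensity, panel$extracellular_pct)
#' @export
propensity_correlation <- function(propensity, measured) {
  if (length(propensity) < 3L || length(propensity) != length(measured)) {
    stop("at least 3 (propensity, measured) pairs are required")
  }
  if (stats::var(propensity) == 0 || stats::var(measured) == 0) {
    stop("zero variance in propensity or measurement")
  }
  fit <- stats::lm(measured ~ propensity)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       n = length(propensity))
}
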