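#' Reliability index of a propensity score
#'
#' Grades the confidence of a secretion call from the random-forest output
#' `O` (the vote fraction for the secreted class) as
#' `RI = floor(20 * |O - 0.5|)`, an integer from 0 (uninformative, O near
#' 0.5) to 10 (maximal, O at 0 or 1). Symmetric under `O -> 1 - O`.
#'
#' @param O Numeric vector of propensities in \[0, 1\].
#' @return Integer vector of reliability indices in 0..10.
#' @examples
#' reliability_index(c(0.5, 0.18, 0.90, 1.0))  # 0 6 8 10
#' @export
reliability_index <- function(O) {
  if (!is.numeric(O) || any(is.na(O)) || any(O < 0 | O > 1)) {
    stop("propensity O must lie in [0, 1]")
  }
  as.integer(floor(20 * abs(O - 0.5)))
}

#' Train the secretion-propensity random forest
#'
#' Fits a random forest to a PseAAC feature matrix with binary labels
#' (1 = secreted, 0 = not secreted). The forest's vote fraction for the
#' secreted class is the secretion propensity `O`. Training is deterministic
#' given (data, settings, seed). No resampling or class weighting is applied
#' by default; the class ratio of the training data is used as-is.
#'
#' @param features Numeric matrix, rows = proteins (rownames = ids),
#'   columns = PseAAC components.
#' @param labels 0/1 vector aligned with the rows of `features`.
#' @param ntree Number of trees (default 500, the conventional default of
#'   the original random-forest implementation).
#' @param seed Integer seed for the forest's randomness.
#' @param params Optional [pseaac_params()] stored with the model so raw
#'   FASTA can be re-encoded consistently at prediction time.
#' @param classwt Optional class weights `c(not_secreted, secreted)` passed
#'   to the forest; `NULL` (default) disables weighting.
#' @return An object of class `secretion_model`.
#' @export
train_forest <- function(features, labels, ntree = 500L, seed = 1L,
                         params = NULL, classwt = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) stop("features and labels differ in length")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < 2L)) {
    stop("training requires at least 2 examples of each class (secreted and not secreted)")
  }
  y <- factor(labels, levels = c(0L, 1L))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fit <- randomForest::randomForest(
    x = features, y = y, ntree = as.integer(ntree),
    classwt = classwt
  )
  structure(
    list(forest = fit, params = params, ntree = as.integer(ntree),
         seed = as.integer(seed),
         class_counts = c(not_secreted = unname(counts["0"]),
                          secreted = unname(counts["1"])),
         n_features = ncol(features),
         feature_names = colnames(features)),
    class = "secretion_model"
  )
}

#' @export
print.secretion_model <- function(x, ...) {
  cat(sprintf(
    "Secretion-propensity random forest: %d trees, %d features, trained on %d/%d (secreted/not)\n",
    x$ntree, x$n_features, x$class_counts["secreted"], x$class_counts["not_secreted"]))
  invisible(x)
}

#' Predict secretion propensity
#'
#' Scores proteins with a trained model. The propensity `O` is the fraction
#' of trees voting for the secreted class; the binary call is secreted when
#' `O >= 0.5` (the tie at exactly 0.5 is called secreted by convention); the
#' reliability index is `floor(20 * |O - 0.5|)`.
#'
#' @param object A `secretion_model`.
#' @param features PseAAC feature matrix (same dimension as at training), or
#'   a named character vector of raw sequences if the model stores its
#'   [pseaac_params()].
#' @param table An [aa_property_table()], used only when re-encoding raw
#'   sequences.
#' @param ... Unused.
#' @return `data.frame` with columns `id`, `propensity`, `call`
#'   (`"secreted"` / `"not_secreted"`), `RI`.
#' @export
predict.secretion_model <- function(object, features,
                                    table = aa_property_table(), ...) {
  if (is.character(features)) {
    if (is.null(object$params)) {
      stop("model stores no PseAAC parameters; supply an encoded feature matrix")
    }
    features <- encode_batch(features, object$params, table)
  }
  features <- as.matrix(features)
  if (ncol(features) != object$n_features) {
    stop(sprintf("feature dimension %d does not match the model's %d",
                 ncol(features), object$n_features))
  }
  prob <- stats::predict(object$forest, newdata = features, type = "prob")
  O <- unname(prob[, "1"])
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  data.frame(
    id = ids,
    propensity = O,
    call = ifelse(O >= 0.5, "secreted", "not_secreted"),
    RI = reliability_index(O),
    stringsAsFactors = FALSE
  )
}

#' Save / load a trained model
#'
#' The model archive is an RDS file; a JSON sidecar (`<path>.json`) records
#' the encoding parameters, seed, class counts and feature dimension for
#' human inspection. A reloaded model yields bit-identical predictions.
#'
#' @param model A `secretion_model`.
#' @param path Archive path (e.g. `model.rds`).
#' @return `save_model()`: `path`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(
    ntree = model$ntree, seed = model$seed,
    class_counts = as.list(model$class_counts),
    n_features = model$n_features,
    pseaac = if (is.null(model$params)) NULL else
      model$params[c("type", "w", "lambda", "properties", "residue_policy")]
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "secretion_model")) stop("not a secretion_model archive")
  model
}
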