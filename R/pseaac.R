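#' PseAAC encoding parameters
#'
#' Bundles the configuration of the pseudo amino acid composition encoder:
#' the encoding type, the weight factor `w` balancing sequence-order
#' correlation factors against plain composition, the maximum correlation
#' rank `lambda`, the property scales used, an optional terminal truncation
#' window, and the non-standard-residue policy.
#'
#' Type I (parallel correlation) folds all selected property scales into a
#' single squared-difference correlation function and yields a vector of
#' dimension `20 + lambda`. Type II (series correlation) keeps one
#' correlation track per property scale and yields `20 + i * lambda`
#' components for `i` selected scales.
#'
#' @param type `"I"` (parallel correlation) or `"II"` (series correlation).
#' @param w Weight factor for the correlation part, `0 < w <= 1`.
#' @param lambda Maximum correlation rank (lag), integer `>= 1`. Sequences
#'   shorter than `lambda + 1` are encoded with an effective rank
#'   `min(lambda, L - 1)`; the missing lags contribute 0 so the output
#'   dimension never varies across sequences.
#' @param properties Character vector naming the property scales to use, an
#'   ordered subset of the six packaged scales. Defaults to all six.
#' @param truncation `NULL`, or `list(terminal = "N"|"C", k = <int>)` to
#'   encode only the first/last `k` residues of every sequence.
#' @param residue_policy What to do with non-standard residues (B, Z, X, U,
#'   O, ...): `"strict"` (default) raises an error naming the position,
#'   `"drop"` removes them before encoding.
#' @return An object of class `pseaac_params`.
#' @examples
#' pseaac_params(type = "I", w = 0.05, lambda = 19)
#' @export
pseaac_params <- function(type = c("I", "II"), w = 0.05, lambda = 19,
                          properties = SCALE_NAMES, truncation = NULL,
                          residue_policy = c("strict", "drop")) {
  type <- match.arg(type)
  residue_policy <- match.arg(residue_policy)
  if (!is.numeric(w) || length(w) != 1L || w <= 0 || w > 1) {
    stop("w must be a single number in (0, 1]")
  }
  lambda <- as.integer(lambda)
  if (is.na(lambda) || lambda < 1L) stop("lambda must be an integer >= 1")
  bad <- setdiff(properties, SCALE_NAMES)
  if (length(bad) > 0 || length(properties) < 1L) {
    stop("properties must be a non-empty subset of: ",
         paste(SCALE_NAMES, collapse = ", "))
  }
  if (!is.null(truncation)) {
    if (!is.list(truncation) || !truncation$terminal %in% c("N", "C") ||
        !is.numeric(truncation$k) || truncation$k < 1) {
      stop("truncation must be list(terminal = \"N\" or \"C\", k >= 1)")
    }
    truncation$k <- as.integer(truncation$k)
  }
  structure(
    list(type = type, w = w, lambda = lambda, properties = properties,
         truncation = truncation, residue_policy = residue_policy),
    class = "pseaac_params"
  )
}

#' @export
print.pseaac_params <- function(x, ...) {
  dim <- if (x$type == "I") 20L + x$lambda else 20L + length(x$properties) * x$lambda
  cat(sprintf("PseAAC parameters: Type %s, w = %g, lambda = %d, %d properties (dim %d)\n",
              x$type, x$w, x$lambda, length(x$properties), dim))
  if (!is.null(x$truncation)) {
    cat(sprintf("  truncation: %s-terminal, k = %d\n",
                x$truncation$terminal, x$truncation$k))
  }
  invisible(x)
}

#' Validate and clean an amino-acid sequence
#'
#' Uppercases the sequence, strips whitespace and trailing stop symbols
#' (`*`), then applies the configured non-standard-residue policy: under
#' `"strict"` any residue outside the 20 standard one-letter codes is an
#' error naming its position; under `"drop"` such residues are removed.
#'
#' @param seq A single amino-acid string.
#' @param params A [pseaac_params()] object (only `residue_policy` is used).
#' @return The cleaned, uppercase sequence string.
#' @export
validate_sequence <- function(seq, params = pseaac_params()) {
  if (!is.character(seq) || length(seq) != 1L) stop("seq must be a single string")
  s <- toupper(gsub("[[:space:]]", "", seq))
  s <- gsub("\\*+$", "", s)
  if (nchar(s) == 0L) stop("empty sequence after cleaning")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_STANDARD)
  if (length(bad) > 0) {
    if (params$residue_policy == "strict") {
      stop(sprintf("non-standard residue '%s' at position %d (strict policy)",
                   chars[bad[1L]], bad[1L]))
    }
    chars <- chars[-bad]
  }
  if (length(chars) < 2L) {
    stop("sequence too short: at least 2 standard residues are required")
  }
  paste(chars, collapse = "")
}

#' Take an N- or C-terminal window of a sequence
#'
#' @param seq Amino-acid string.
#' @param terminal `"N"` (prefix) or `"C"` (suffix).
#' @param k Window length in residues; `k >= L` returns the full sequence.
#' @return The truncated sequence.
#' @examples
#' truncate_terminal("MKTAYIAKQR", "N", 3)  # "MKT"
#' truncate_terminal("MKTAYIAKQR", "C", 3)  # "KQR"
#' @export
truncate_terminal <- function(seq, terminal = c("N", "C"), k) {
  terminal <- match.arg(terminal)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  L <- nchar(seq)
  if (k >= L) return(seq)
  if (terminal == "N") substr(seq, 1L, k) else substr(seq, L - k + 1L, L)
}

# residue indices (1..20) for a clean sequence
.seq_idx <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1L]], AA_STANDARD)
}

#' Type I (parallel) sequence-order correlation factor
#'
#' The lag-`j` correlation factor of the parallel-correlation PseAAC:
#' \deqn{\theta_j = \frac{1}{L-j} \sum_{i=1}^{L-j} \Theta(R_i, R_{i+j}),
#'   \quad \Theta(R_i, R_{i+j}) = \frac{1}{m} \sum_{k=1}^{m}
#'   [H_k(R_{i+j}) - H_k(R_i)]^2}
#' where the `m` selected property scales `H_k` are PseAAC-normalized.
#' Always non-negative and invariant under sequence reversal.
#'
#' @param seq Clean amino-acid string (see [validate_sequence()]).
#' @param j Lag, `1 <= j <= L - 1`.
#' @param table An [aa_property_table()].
#' @param properties Scales to include (default all six).
#' @return The scalar correlation factor.
#' @export
theta_type1 <- function(seq, j, table = aa_property_table(),
                        properties = SCALE_NAMES) {
  idx <- .seq_idx(seq)
  L <- length(idx)
  j <- as.integer(j)
  if (j < 1L || j >= L) stop(sprintf("lag j must satisfy 1 <= j <= L-1 (L = %d)", L))
  H <- table$normalized[properties, , drop = FALSE]
  a <- idx[seq_len(L - j)]
  b <- idx[seq_len(L - j) + j]
  diffs <- H[, b, drop = FALSE] - H[, a, drop = FALSE]
  mean(colMeans(diffs^2))
}

#' Type II (series) sequence-order correlation factor
#'
#' The lag-`j` correlation factor of the series-correlation PseAAC for one
#' property scale `k`:
#' \deqn{\tau_{j,k} = \frac{1}{L-j} \sum_{i=1}^{L-j} H_k(R_i) H_k(R_{i+j})}
#' with `H_k` PseAAC-normalized. May be negative; invariant under sequence
#' reversal.
#'
#' @param seq Clean amino-acid string.
#' @param j Lag, `1 <= j <= L - 1`.
#' @param scale Name of the property scale.
#' @param table An [aa_property_table()].
#' @return The scalar correlation factor.
#' @export
tau_type2 <- function(seq, j, scale, table = aa_property_table()) {
  idx <- .seq_idx(seq)
  L <- length(idx)
  j <- as.integer(j)
  if (j < 1L || j >= L) stop(sprintf("lag j must satisfy 1 <= j <= L-1 (L = %d)", L))
  H <- table$normalized[scale, ]
  a <- idx[seq_len(L - j)]
  b <- idx[seq_len(L - j) + j]
  sum(H[a] * H[b]) / (L - j)
}

#' Encode a protein sequence as a PseAAC feature vector
#'
#' Transforms a variable-length amino-acid sequence into a fixed-length
#' feature vector combining the 20 amino-acid frequencies with
#' sequence-order correlation factors. For Type I the vector is
#' \deqn{x_u = \frac{f_u}{1 + w \sum_j \theta_j} \ (u \le 20), \quad
#'   x_{20+j} = \frac{w\,\theta_j}{1 + w \sum_j \theta_j}}
#' (dimension `20 + lambda`); Type II replaces the `theta` block with one
#' `tau` track per property scale, ordered lag-major (for each lag, the
#' selected scales in their configured order), giving dimension
#' `20 + i * lambda`. `f_u` is the relative residue frequency, so the
#' components always sum to 1; Type I components are additionally all
#' non-negative.
#'
#' Sequences shorter than `lambda + 1` use the effective rank
#' `min(lambda, L - 1)`; lags beyond it contribute 0 and the dimension is
#' unchanged, so feature matrices stay rectangular under terminal
#' truncation.
#'
#' @param seq Amino-acid string; validated (and optionally truncated) per
#'   `params`.
#' @param params A [pseaac_params()] object.
#' @param table An [aa_property_table()].
#' @return Named numeric vector: the 20 amino-acid codes, then `theta_1..`
#'   (Type I) or `tau_<lag>_<scale>` (Type II).
#' @examples
#' tab <- aa_property_table()
#' x <- encode_pseaac("MKTAYIAKQRQISFVK", pseaac_params("I", 0.05, 3), tab)
#' sum(x)  # 1
#' @export
encode_pseaac <- function(seq, params = pseaac_params(),
                          table = aa_property_table()) {
  s <- validate_sequence(seq, params)
  if (!is.null(params$truncation)) {
    s <- truncate_terminal(s, params$truncation$terminal, params$truncation$k)
  }
  idx <- .seq_idx(s)
  L <- length(idx)
  f <- tabulate(idx, nbins = 20L) / L
  lam <- params$lambda
  lam_eff <- min(lam, L - 1L)
  H <- table$normalized[params$properties, , drop = FALSE]
  m <- nrow(H)

  if (params$type == "I") {
    corr <- numeric(lam)
    for (j in seq_len(lam_eff)) {
      a <- idx[seq_len(L - j)]
      b <- idx[seq_len(L - j) + j]
      diffs <- H[, b, drop = FALSE] - H[, a, drop = FALSE]
      corr[j] <- sum(diffs^2) / (m * (L - j))
    }
    cnames <- paste0("theta_", seq_len(lam))
  } else {
    # lag-major ordering: lag 1 tracks for each scale, then lag 2, ...
    corr <- numeric(lam * m)
    for (j in seq_len(lam_eff)) {
      a <- idx[seq_len(L - j)]
      b <- idx[seq_len(L - j) + j]
      prods <- H[, a, drop = FALSE] * H[, b, drop = FALSE]
      corr[(j - 1L) * m + seq_len(m)] <- rowSums(prods) / (L - j)
    }
    cnames <- as.vector(t(outer(seq_len(lam), params$properties,
                                function(j, k) paste0("tau_", j, "_", k))))
  }
  denom <- 1 + params$w * sum(corr)
  if (abs(denom) <= 1e-12) {
    stop("degenerate PseAAC denominator (correlation factors cancel composition)")
  }
  out <- c(f, params$w * corr) / denom
  names(out) <- c(AA_STANDARD, cnames)
  out
}

#' Encode a batch of sequences into a feature matrix
#'
#' Applies [encode_pseaac()] to every record, preserving input order. Any
#' failing record aborts the batch with an error listing the offending ids.
#'
#' @param seqs Named character vector (names are sequence ids) or a
#'   `labeled_dataset` (its sequences are used).
#' @param params A [pseaac_params()] object.
#' @param table An [aa_property_table()].
#' @return Numeric matrix, one row per sequence (rownames = ids), columns as
#'   in [encode_pseaac()].
#' @export
encode_batch <- function(seqs, params = pseaac_params(),
                         table = aa_property_table()) {
  if (inherits(seqs, "labeled_dataset")) seqs <- seqs$sequences
  n <- length(seqs)
  dim_out <- 20L + params$lambda *
    (if (params$type == "I") 1L else length(params$properties))
  if (n == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = dim_out))
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  rows <- vector("list", n)
  failed <- character(0)
  for (r in seq_len(n)) {
    rows[[r]] <- tryCatch(encode_pseaac(seqs[[r]], params, table),
                          error = function(e) {
                            failed <<- c(failed, ids[r])
                            NULL
                          })
  }
  if (length(failed) > 0) {
    stop("encoding failed for record(s): ", paste(failed, collapse = ", "))
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  mat
}
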