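HYDROPHOBIC_SET <- c("A", "I", "L", "M", "F", "V")

# UniProt-style average residue frequencies, for the natural-background option
NATURAL_FREQS <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0591, K = 0.0580, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0475, Q = 0.0393, R = 0.0553,
  S = 0.0665, T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292
)

#' Specify a synthetic two-class protein sequence set
#'
#' Describes a labeled fixture with controllable signal, so every stage of
#' the prediction pipeline can be exercised and planted effects recovered
#' without any external dataset. Two kinds of signal are available:
#'
#' * a composition bias: positives receive `delta` extra probability mass,
#'   spread evenly over a designated hydrophobic residue set and removed
#'   evenly from the remaining residues — a pure amino-acid-composition
#'   difference between the classes;
#' * a periodic motif: a short residue pattern stamped at a fixed period
#'   into one class, either anywhere or only inside the first `k` residues —
#'   a sequence-order / positional signal, used e.g. to mirror an
#'   N-terminal-localized secretion determinant.
#'
#' The background composition is uniform over the 20 residues by default so
#' that the planted signal is the only structure present; a natural-
#' abundance background is available.
#'
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param length_range Two integers, inclusive range of sequence lengths
#'   (drawn uniformly).
#' @param delta Excess probability mass on the hydrophobic set for
#'   positives, `0 <= delta` (must leave all residue probabilities
#'   non-negative).
#' @param motif `NULL`, or `list(motif = <string>, period = <int>,
#'   class = "pos"|"neg", region = NULL | <int k>)`; `region = k` confines
#'   the stamping to residues `1..k` (N-terminal window), `NULL` allows it
#'   anywhere.
#' @param background `"uniform"` (default) or `"natural"`.
#' @param hydrophobic_set Residues receiving the composition bias.
#' @param seed Master seed; lengths, residues and motif placement use
#'   separate streams derived from it, so changing one knob leaves the
#'   other draws unchanged.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_pos, n_neg, length_range = c(80L, 200L),
                         delta = 0.15, motif = NULL,
                         background = c("uniform", "natural"),
                         hydrophobic_set = HYDROPHOBIC_SET, seed = 1L) {
  background <- match.arg(background)
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  if (n_pos < 1L || n_neg < 1L) stop("n_pos and n_neg must be >= 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1L] > length_range[2L] ||
      length_range[1L] < 2L) {
    stop("length_range must be two integers (min <= max, min >= 2)")
  }
  base <- if (background == "uniform") {
    stats::setNames(rep(1 / 20, 20L), AA_STANDARD)
  } else NATURAL_FREQS[AA_STANDARD]
  in_set <- AA_STANDARD %in% hydrophobic_set
  p_pos <- base
  p_pos[in_set] <- p_pos[in_set] + delta / sum(in_set)
  p_pos[!in_set] <- p_pos[!in_set] - delta / sum(!in_set)
  if (any(p_pos < 0) || abs(sum(p_pos) - 1) > 1e-9) {
    stop("delta makes the positive-class residue distribution invalid")
  }
  if (!is.null(motif)) {
    motif$motif <- toupper(motif$motif)
    if (!all(strsplit(motif$motif, "")[[1L]] %in% AA_STANDARD)) {
      stop("motif must use the 20 standard residues")
    }
    if (is.null(motif$class)) motif$class <- "pos"
    if (is.null(motif$period) || motif$period < 1L) stop("motif period must be >= 1")
  }
  structure(
    list(n_pos = n_pos, n_neg = n_neg, length_range = length_range,
         delta = delta, motif = motif, background = background,
         p_pos = p_pos, p_neg = base, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# stamp motif copies at positions 1, 1+period, ... within [1, region_end]
.stamp_motif <- function(chars, motif, period, region_end) {
  mchars <- strsplit(motif, "")[[1L]]
  m <- length(mchars)
  start <- 1L
  while (start + m - 1L <= min(region_end, length(chars))) {
    chars[start:(start + m - 1L)] <- mchars
    start <- start + period
  }
  chars
}

#' Generate a synthetic labeled dataset
#'
#' Draws the sequence set described by a [fixture_spec()]: class sizes
#' exactly as requested, lengths uniform over the range, residues i.i.d.
#' from the per-class composition, then any configured motif stamped in.
#' Deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return A `labeled_dataset` with ids `POS0001..` / `NEG0001..`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_pos + spec$n_neg
  labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  ids <- c(sprintf("POS%04d", seq_len(spec$n_pos)),
           sprintf("NEG%04d", seq_len(spec$n_neg)))

  set.seed(derive_seed(spec$seed, "lengths"))
  lens <- sample(spec$length_range[1L]:spec$length_range[2L], n, replace = TRUE)

  set.seed(derive_seed(spec$seed, "residues"))
  seqs <- character(n)
  for (r in seq_len(n)) {
    p <- if (labels[r] == 1L) spec$p_pos else spec$p_neg
    seqs[r] <- paste(sample(AA_STANDARD, lens[r], replace = TRUE, prob = p),
                     collapse = "")
  }

  if (!is.null(spec$motif)) {
    set.seed(derive_seed(spec$seed, "motif"))
    target <- if (spec$motif$class == "pos") labels == 1L else labels == 0L
    region <- spec$motif$region
    for (r in which(target)) {
      chars <- strsplit(seqs[r], "")[[1L]]
      region_end <- if (is.null(region)) length(chars) else min(region, length(chars))
      chars <- .stamp_motif(chars, spec$motif$motif, spec$motif$period, region_end)
      seqs[r] <- paste(chars, collapse = "")
    }
  }

  names(seqs) <- ids
  attach_labels(seqs, stats::setNames(labels, ids),
                provenance = sprintf(
                  "synthetic fixture (seed %d, delta %g, background %s%s)",
                  spec$seed, spec$delta, spec$background,
                  if (is.null(spec$motif)) "" else
                    sprintf(", motif %s/period %d", spec$motif$motif, spec$motif$period)))
}

#' Fixture preset at the real-world class imbalance
#'
#' A [fixture_spec()] with 136 positive and 957 negative sequences — the
#' class ratio of the curated secretion dataset this package emulates —
#' with a moderate composition bias.
#'
#' @param delta Composition bias (default 0.15).
#' @param seed Master seed.
#' @return A `fixture_spec`.
#' @export
imbalanced_preset <- function(delta = 0.15, seed = 1L) {
  fixture_spec(n_pos = 136L, n_neg = 957L, length_range = c(80L, 200L),
               delta = delta, seed = seed)
}
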