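AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

SCALE_NAMES <- c("hydrophobicity", "hydrophilicity", "side_chain_mass",
                 "pK_alpha_COOH", "pK_alpha_NH3", "pI_25C")

#' Normalize a physicochemical scale for PseAAC
#'
#' Applies the standard PseAAC conversion to a raw 20-residue property scale:
#' subtract the 20-residue mean and divide by the root-mean-square deviation
#' over the 20 residues, \eqn{H(i) = (H^0(i) - \bar{H^0}) / \sqrt{\sum_i
#' (H^0(i) - \bar{H^0})^2 / 20}}. The result has mean 0 and root-mean-square
#' 1, making heterogeneous scales (masses, pK values, hydropathies)
#' commensurable inside the sequence-order correlation factors.
#'
#' @param x Numeric vector of 20 raw scale values, one per standard amino
#'   acid. Names, if present, are preserved.
#' @return Numeric vector of 20 normalized values (mean 0, RMS 1).
#' @examples
#' h <- c(rep(1, 10), rep(-1, 10))
#' all.equal(normalize_scale(h), h)  # already mean-0, RMS-1
#' @export
normalize_scale <- function(x) {
  if (length(x) != 20L || !is.numeric(x)) {
    stop("a property scale must be a numeric vector of 20 values")
  }
  centred <- x - mean(x)
  rms <- sqrt(sum(centred^2) / 20)
  if (rms <= 0 || !is.finite(rms)) {
    stop("degenerate scale: all 20 values are equal, cannot normalize")
  }
  centred / rms
}

#' Load the amino-acid physicochemical property table
#'
#' Reads the six-scale, 20-residue property table (hydrophobicity,
#' hydrophilicity, side-chain mass, pK of the alpha-COOH group, pK of the
#' alpha-NH3+ group, and pI at 25 degrees C) and attaches the PseAAC-normalized
#' version of every scale (see [normalize_scale()]). By default the table
#' packaged with pichiasec is used; a user file with the same layout (tab
#' separated, one row per amino acid, '#' comments) may be supplied.
#'
#' Non-standard residues (B, Z, X, U, O) have no scale values; how they are
#' handled is a policy of the encoder, not of this table.
#'
#' @param path Path to a tab-separated scale file; `NULL` (default) loads the
#'   packaged table.
#' @return An object of class `aa_property_table`: a list with `raw` and
#'   `normalized`, each a 6 x 20 numeric matrix (rows = scales, columns =
#'   one-letter amino-acid codes), plus `scale_names` and `source`.
#' @examples
#' tab <- aa_property_table()
#' tab$raw["hydrophobicity", "A"]
#' rowMeans(tab$normalized)  # all zero
#' @export
aa_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_physicochemical_scales.tsv",
                        package = "pichiasec", mustWork = TRUE)
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"aa" %in% names(df)) stop("scale file must have an 'aa' column")
  missing_scales <- setdiff(SCALE_NAMES, names(df))
  if (length(missing_scales) > 0) {
    stop("scale file is missing scale(s): ", paste(missing_scales, collapse = ", "))
  }
  for (sc in SCALE_NAMES) {
    absent <- setdiff(AA_STANDARD, df$aa[!is.na(df[[sc]])])
    if (length(absent) > 0) {
      stop(sprintf("scale file is missing value(s) for scale '%s', residue(s): %s",
                   sc, paste(absent, collapse = ", ")))
    }
  }
  df <- df[match(AA_STANDARD, df$aa), , drop = FALSE]
  raw <- t(as.matrix(df[, SCALE_NAMES]))
  colnames(raw) <- AA_STANDARD
  normalized <- t(apply(raw, 1L, normalize_scale))
  colnames(normalized) <- AA_STANDARD
  structure(
    list(raw = raw, normalized = normalized,
         scale_names = SCALE_NAMES, source = path),
    class = "aa_property_table"
  )
}

#' @export
print.aa_property_table <- function(x, ...) {
  cat("Amino-acid physicochemical property table\n")
  cat("  scales:  ", paste(x$scale_names, collapse = ", "), "\n", sep = "")
  cat("  residues:", ncol(x$raw), " (raw + PseAAC-normalized values)\n", sep = "")
  invisible(x)
}
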