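# Independent reference implementations, written straight from the defining
# formulas with explicit loops. These stay deliberately naive: they are the
# oracle the fast vectorized encoder is checked against, not a code path of
# the package.

ORACLE_AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# (x - mean) / RMS-deviation over the 20 residues
oracle_normalize <- function(x) {
  m <- sum(x) / 20
  d <- sqrt(sum((x - m)^2) / 20)
  (x - m) / d
}

# straight-from-formula PseAAC: composition + correlation factors, lags
# beyond L - 1 contribute zero, lag-major track order for the series type
oracle_encode <- function(seq, type, w, lambda,
                          properties = rownames(tab_global$normalized),
                          table = tab_global) {
  aa <- strsplit(seq, "")[[1L]]
  L <- length(aa)
  f <- vapply(ORACLE_AAS, function(a) sum(aa == a), 0) / L
  H <- table$normalized[properties, , drop = FALSE]
  m <- length(properties)
  if (type == "I") {
    corr <- numeric(lambda)
    for (j in seq_len(lambda)) {
      if (j <= L - 1L) {
        tot <- 0
        for (i in seq_len(L - j)) {
          s <- 0
          for (k in seq_len(m)) s <- s + (H[k, aa[i + j]] - H[k, aa[i]])^2
          tot <- tot + s / m
        }
        corr[j] <- tot / (L - j)
      }
    }
  } else {
    corr <- numeric(lambda * m)
    pos <- 0L
    for (j in seq_len(lambda)) {
      for (k in seq_len(m)) {
        pos <- pos + 1L
        if (j <= L - 1L) {
          v <- 0
          for (i in seq_len(L - j)) v <- v + H[k, aa[i]] * H[k, aa[i + j]]
          corr[pos] <- v / (L - j)
        }
      }
    }
  }
  den <- 1 + w * sum(corr)
  unname(c(f, w * corr) / den)
}

# AUC by exhaustive concordance counting over all (positive, negative) pairs
oracle_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

random_aa_seq <- function(L) {
  paste(sample(ORACLE_AAS, L, replace = TRUE), collapse = "")
}

reverse_seq <- function(s) {
  paste(rev(strsplit(s, "")[[1L]]), collapse = "")
}

# one shared property table for the whole suite (loading is pure)
tab_global <- aa_property_table()

# small datasets for fast unit tests
make_toy_dataset <- function(n_per_class = 30L, delta = 0.3, seed = 1L,
                             length_range = c(60L, 100L)) {
  generate_fixture(fixture_spec(n_per_class, n_per_class, length_range,
                                delta = delta, seed = seed))
}
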