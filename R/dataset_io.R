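#' Read protein sequences from a FASTA file
#'
#' Wraps `Biostrings::readAAStringSet()`. Ids are the first
#' whitespace-delimited token of each header; wrapped sequence lines are
#' joined and uppercased; trailing stop symbols (`*`) are stripped.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("\\*+$", "", seqs)
  if (any(nchar(seqs) == 0L)) {
    stop("empty record(s) in FASTA: ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate sequence id(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a two-column label table
#'
#' Tab-separated file of `id<TAB>label` with labels 0 (not secreted) or 1
#' (secreted); `#` comment lines allowed, no header.
#'
#' @param path Path to the label file.
#' @return Named integer vector of 0/1 labels (names = ids).
#' @export
read_label_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("id", "label"))
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  stats::setNames(as.integer(df$label), df$id)
}

#' Write a two-column label table
#'
#' @param labels Named integer vector of 0/1 labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(data.frame(id = names(labels), label = as.integer(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Apply the curation length filter
#'
#' Removes short proteins: records with fewer than `min_length` residues are
#' excluded (the strict reading of the "< 50 amino acids" rule — a 50-residue
#' protein is kept). Upstream curation steps (redundancy reduction,
#' signal-peptide removal, transmembrane filtering) are external
#' preprocessing and are only recorded as provenance, never re-run here.
#'
#' @param seqs Named character vector of sequences.
#' @param min_length Minimum retained length (default 50).
#' @return List with `sequences` (retained records) and `filter_log`, a
#'   named count of removals by reason.
#' @export
apply_filters <- function(seqs, min_length = 50L) {
  lens <- nchar(seqs)
  keep <- lens >= min_length
  if (!any(keep)) stop("all records removed by the length filter")
  list(sequences = seqs[keep],
       filter_log = c(short = sum(!keep)))
}

#' Attach class labels to sequence records
#'
#' Builds a `labeled_dataset` joining sequences to their secreted (1) /
#' not-secreted (0) labels. Every record must be labeled; no implicit class
#' balancing is performed, so imbalanced sets (e.g. 136 positive vs 957
#' negative) load as-is.
#'
#' @param seqs Named character vector of sequences, or the result of
#'   [apply_filters()].
#' @param labels Named 0/1 vector (names = ids), e.g. from
#'   [read_label_table()].
#' @param provenance Free-text note on the origin and upstream curation of
#'   the records.
#' @return An object of class `labeled_dataset`: list with `sequences`,
#'   `labels` (aligned named integer vector), `provenance`, `filter_log`.
#' @export
attach_labels <- function(seqs, labels, provenance = "") {
  filter_log <- integer(0)
  if (is.list(seqs) && !is.null(seqs$sequences)) {
    filter_log <- seqs$filter_log
    seqs <- seqs$sequences
  }
  ids <- names(seqs)
  missing <- setdiff(ids, names(labels))
  if (length(missing) > 0) {
    stop("no label for record(s): ", paste(missing, collapse = ", "))
  }
  lab <- labels[ids]
  structure(
    list(sequences = seqs, labels = lab,
         provenance = provenance, filter_log = filter_log),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled protein dataset: %d records (%d secreted, %d not secreted)\n",
              length(x$sequences), sum(x$labels == 1L), sum(x$labels == 0L)))
  if (length(x$filter_log) > 0) {
    cat("  removed by filters:",
        paste(sprintf("%s=%d", names(x$filter_log), x$filter_log), collapse = ", "),
        "\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$sequences)
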