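#' Read an aligned FASTA and map reference positions to columns
#'
#' Loads a multiple sequence alignment of orthologous protein sequences
#' (gap character `-`) and builds a column map from one-based ungapped
#' positions of the designated reference (human) sequence to alignment
#' columns.
#'
#' @param path Aligned FASTA file; all sequences must have equal length.
#' @param reference_id Name (FASTA header up to the first whitespace) of
#'   the reference sequence.
#' @return A `tricall_msa` object: list with `seqs` (character matrix,
#'   sequences x columns), `ids`, `reference_id`, and `column_map`
#'   (integer vector; `column_map[p]` is the alignment column of ungapped
#'   reference position `p`).
#' @export
read_msa <- function(path, reference_id) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the Biostrings package is required to read FASTA alignments")
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  widths <- Biostrings::width(ss)
  if (length(unique(widths)) != 1) {
    abort(paste0("ragged alignment in ", path,
                 ": sequence lengths ", paste(unique(widths), collapse = ", ")))
  }
  seqs <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  rownames(seqs) <- ids
  new_msa(seqs, ids, reference_id, source = path)
}

#' Build an alignment object from in-memory sequences
#'
#' @param sequences Named character vector of equal-length aligned
#'   sequences (gap `-`).
#' @param reference_id Name of the reference sequence.
#' @return A `tricall_msa` object, as for [read_msa()].
#' @export
msa_from_strings <- function(sequences, reference_id) {
  if (length(unique(nchar(sequences))) != 1) {
    abort("ragged alignment: sequences differ in length")
  }
  seqs <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(seqs) <- names(sequences)
  new_msa(seqs, names(sequences), reference_id, source = "<memory>")
}

new_msa <- function(seqs, ids, reference_id, source) {
  if (!reference_id %in% ids) {
    abort(paste0("reference sequence '", reference_id, "' not found in ",
                 source))
  }
  ref_row <- seqs[match(reference_id, ids), ]
  column_map <- which(ref_row != "-")
  structure(list(seqs = seqs, ids = ids, reference_id = reference_id,
                 column_map = as.integer(column_map)),
            class = "tricall_msa")
}

#' @export
print.tricall_msa <- function(x, ...) {
  cat("<tricall_msa> ", nrow(x$seqs), " sequences x ", ncol(x$seqs),
      " columns; reference '", x$reference_id, "' (",
      length(x$column_map), " residues)\n", sep = "")
  invisible(x)
}

#' Per-column residue proportions for a substitution
#'
#' Computes the sequence-profile conservation features at the alignment
#' column holding a reference position: the proportion of sequences
#' carrying the reference residue (`f_ref`), the proportion carrying the
#' variant residue (`f_var`), and the number of sequences (`n_seq`).  By
#' default the denominator counts every sequence, including rows gapped
#' at that column.
#'
#' @param msa A `tricall_msa` from [read_msa()] or [msa_from_strings()].
#' @param position One-based ungapped position(s) on the reference
#'   sequence (vectorised).
#' @param ref_aa,var_aa Reference and variant residues (recycled).
#' @param count_gaps If `TRUE` (default) gapped rows stay in the
#'   denominator; if `FALSE` only residue-bearing rows are counted.
#' @return A tibble with columns `f_ref`, `f_var`, `n_seq`.
#' @export
sequence_profile <- function(msa, position, ref_aa, var_aa,
                             count_gaps = TRUE) {
  stopifnot(inherits(msa, "tricall_msa"))
  n <- max(length(position), length(ref_aa), length(var_aa))
  position <- rep_len(position, n)
  ref_aa <- rep_len(ref_aa, n)
  var_aa <- rep_len(var_aa, n)
  if (any(position < 1 | position > length(msa$column_map))) {
    abort(paste0("position out of range: reference has ",
                 length(msa$column_map), " residues"))
  }
  cols <- msa$column_map[position]
  f_ref <- numeric(n)
  f_var <- numeric(n)
  n_seq <- integer(n)
  for (i in seq_len(n)) {
    col <- msa$seqs[, cols[i]]
    denom <- if (count_gaps) length(col) else sum(col != "-")
    f_ref[i] <- sum(col == ref_aa[i]) / denom
    f_var[i] <- sum(col == var_aa[i]) / denom
    n_seq[i] <- nrow(msa$seqs)
  }
  tibble(f_ref = f_ref, f_var = f_var, n_seq = n_seq)
}
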