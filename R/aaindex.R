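#' Read an AAindex flat file
#'
#' Parses the AAindex1/2/3 flat-file format.  AAindex1 entries (`I`
#' blocks) yield a named 20-value vector per accession; AAindex2/3
#' entries (`M` blocks) yield a 20x20 matrix, symmetrised when the file
#' stores only a triangle.  Cells given as `NA` or `-` are recorded as
#' missing and flag the entry.
#'
#' @param path Path to an AAindex flat file.
#' @param section Which database the file belongs to: 1 (per-residue
#'   indices) or 2/3 (substitution/contact matrices).  Used to check that
#'   entries have the expected shape.
#' @return A tibble with one row per accession: `accession`,
#'   `description`, `type` (`"index"` or `"matrix"`), `data`
#'   (list-column of named vectors or matrices) and `has_na`.
#' @export
read_aaindex <- function(path, section = 1) {
  if (!file.exists(path)) abort(paste0("AAindex file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "//")
  if (length(ends) == 0) abort(paste0("no entries (missing //) in ", path))
  start <- 1L
  entries <- list()
  for (e in ends) {
    block <- lines[start:(e - 1L)]
    start <- e + 1L
    if (all(!nzchar(trimws(block)))) next
    entries[[length(entries) + 1L]] <- parse_aaindex_entry(block)
  }
  out <- dplyr::bind_rows(lapply(entries, function(en) {
    tibble(accession = en$accession, description = en$description,
           type = en$type, data = list(en$data), has_na = en$has_na)
  }))
  expected <- if (section == 1) "index" else "matrix"
  if (nrow(out) > 0 && any(out$type != expected)) {
    bad <- out$accession[out$type != expected][1]
    warn(paste0("entry ", bad, " is not of the shape expected for AAindex",
                section))
  }
  out
}

parse_aaindex_entry <- function(block) {
  acc <- sub("^H\\s+", "", grep("^H\\s", block, value = TRUE))[1]
  if (is.na(acc)) abort("AAindex entry without an H (accession) line")
  desc <- sub("^D\\s+", "", grep("^D\\s", block, value = TRUE))[1]
  if (is.na(desc)) desc <- ""
  i_at <- grep("^I\\s", block)
  m_at <- grep("^M\\s", block)
  num <- function(x) suppressWarnings(
    as.numeric(ifelse(x %in% c("NA", "-", "NA."), NA, x)))
  if (length(i_at) == 1) {
    vals_lines <- block[(i_at + 1L):length(block)]
    vals <- num(unlist(strsplit(trimws(vals_lines), "\\s+")))
    if (length(vals) != 20) {
      abort(paste0("truncated AAindex1 entry ", acc, ": expected 20 values, ",
                   "got ", length(vals)))
    }
    v <- setNames(vals, AA_AAINDEX_ORDER)
    return(list(accession = acc, description = desc, type = "index",
                data = v, has_na = anyNA(v)))
  }
  if (length(m_at) == 1) {
    hdr <- block[m_at]
    rows_str <- sub(".*rows\\s*=\\s*([A-Za-z]+).*", "\\1", hdr)
    cols_str <- sub(".*cols\\s*=\\s*([A-Za-z]+).*", "\\1", hdr)
    row_aa <- strsplit(rows_str, "")[[1]]
    col_aa <- strsplit(cols_str, "")[[1]]
    vals_lines <- block[(m_at + 1L):length(block)]
    vals_lines <- vals_lines[nzchar(trimws(vals_lines))]
    if (length(vals_lines) != length(row_aa)) {
      abort(paste0("truncated AAindex matrix entry ", acc, ": expected ",
                   length(row_aa), " rows, got ", length(vals_lines)))
    }
    m <- matrix(NA_real_, length(row_aa), length(col_aa),
                dimnames = list(row_aa, col_aa))
    triangular <- FALSE
    for (r in seq_along(vals_lines)) {
      v <- num(unlist(strsplit(trimws(vals_lines[r]), "\\s+")))
      if (length(v) < length(col_aa)) triangular <- TRUE
      if (length(v) > length(col_aa)) {
        abort(paste0("malformed row ", r, " in AAindex entry ", acc))
      }
      m[r, seq_along(v)] <- v
    }
    if (triangular) {
      # lower-triangular storage: mirror across the diagonal
      upper <- upper.tri(m)
      m[upper] <- t(m)[upper]
    }
    list(accession = acc, description = desc, type = "matrix",
         data = m, has_na = anyNA(m))
  } else {
    abort(paste0("truncated AAindex entry ", acc, ": no I or M block"))
  }
}

#' Drop AAindex entries containing missing values
#'
#' Mirrors the preprocessing that keeps only complete amino acid
#' property entries before feature assembly.
#'
#' @param indices A tibble from [read_aaindex()] (sections may be mixed).
#' @return The subset with `has_na == FALSE`; the number retained and
#'   dropped is reported as a message.
#' @export
filter_complete_indices <- function(indices) {
  kept <- dplyr::filter(indices, !.data$has_na)
  inform(paste0("retained ", nrow(kept), " of ", nrow(indices),
                " AAindex entries (", nrow(indices) - nrow(kept),
                " with missing values dropped)"))
  kept
}

#' Look up an AAindex entry by accession
#'
#' @param indices A tibble from [read_aaindex()].
#' @param accession Entry accession, e.g. `"KOSJ950114"`.
#' @return The entry's data: a named 20-vector or a matrix.
#' @export
aaindex_get <- function(indices, accession) {
  i <- match(accession, indices$accession)
  if (is.na(i)) abort(paste0("accession not found: ", accession))
  indices$data[[i]]
}

#' Difference of a per-residue amino acid index
#'
#' For an AAindex1 entry the feature value of a substitution is the
#' index of the reference residue minus the index of the variant
#' residue, so the value is antisymmetric under swapping the two.
#'
#' @param index Named numeric vector over the 20 residues.
#' @param ref_aa,var_aa Residue letters (vectorised, recycled).
#' @return Numeric vector of differences; `NA` where a residue is absent
#'   from the index.
#' @export
aaindex1_delta <- function(index, ref_aa, var_aa) {
  unname(index[ref_aa] - index[var_aa])
}

#' Substitution matrix lookup
#'
#' For AAindex2/3 entries the feature value is taken directly from the
#' matrix cell `[ref_aa, var_aa]` (matrices stored as a triangle were
#' symmetrised on load).
#'
#' @param matrix A 20x20 matrix with residue dimnames.
#' @param ref_aa,var_aa Residue letters (vectorised, recycled).
#' @return Numeric vector of matrix values; `NA` for missing cells.
#' @export
aaindex_matrix_value <- function(matrix, ref_aa, var_aa) {
  n <- max(length(ref_aa), length(var_aa))
  ref_aa <- rep_len(ref_aa, n)
  var_aa <- rep_len(var_aa, n)
  matrix[cbind(ref_aa, var_aa)]
}
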