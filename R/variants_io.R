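#' Read a variant table
#'
#' Reads a TSV of amino acid substitutions into a validated tibble.  The
#' file must carry the columns `variant_id`, `protein_id`, `position`
#' (one-based along the unaligned reference protein, as in substitution
#' notation like p.R97W), `ref_aa` and `var_aa`.  Optional columns
#' (`label`, `family_id`, `omega`, and any numeric feature columns) are
#' preserved.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A tibble of variants (class `tricall_variants`), one row per
#'   substitution, with a `class_counts` attribute tallying labels.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("variant_id\tprotein_id\tposition\tref_aa\tvar_aa\tlabel",
#'              "v1\tP1\t97\tR\tW\tpathogenic"), tf)
#' read_variants(tf)
read_variants <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("variant file not found: ", path))
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_variants(x, source = path)
}

#' Validate a variant data frame
#'
#' Checks the invariants of a variant table built in memory (for example
#' by the synthetic generator) and stamps it as a `tricall_variants`
#' tibble.  Positions must be positive integers, residues standard
#' one-letter amino acid codes, the reference and variant residue must
#' differ (synonymous records are rejected), and `variant_id` must be
#' unique.
#'
#' @param x A data frame with at least `variant_id`, `protein_id`,
#'   `position`, `ref_aa`, `var_aa`.
#' @param source Optional label used in error messages (e.g. a file name).
#' @return The validated tibble with class `tricall_variants`.
#' @export
validate_variants <- function(x, source = "variant table") {
  x <- as_tibble(x)
  required <- c("variant_id", "protein_id", "position", "ref_aa", "var_aa")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(source, ": missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  line_of <- function(i) paste0(source, " line ", i + 1L)  # +1 for header
  bad_aa <- which(!(x$ref_aa %in% AA_STANDARD) | !(x$var_aa %in% AA_STANDARD))
  if (length(bad_aa) > 0) {
    abort(paste0(line_of(bad_aa[1]), ": malformed amino-acid letter (ref '",
                 x$ref_aa[bad_aa[1]], "', var '", x$var_aa[bad_aa[1]], "')"))
  }
  if (any(is.na(x$position)) || any(x$position < 1) ||
      any(x$position != as.integer(x$position))) {
    i <- which(is.na(x$position) | x$position < 1 |
                 x$position != as.integer(x$position))[1]
    abort(paste0(line_of(i), ": position must be a positive integer (one-based)"))
  }
  syn <- which(x$ref_aa == x$var_aa)
  if (length(syn) > 0) {
    abort(paste0(line_of(syn[1]),
                 ": ref_aa equals var_aa (synonymous record rejected)"))
  }
  dup <- which(duplicated(x$variant_id))
  if (length(dup) > 0) {
    abort(paste0(line_of(dup[1]), ": duplicate variant_id '",
                 x$variant_id[dup[1]], "'"))
  }
  x$position <- as.integer(x$position)
  if ("label" %in% names(x)) {
    bad <- which(!is.na(x$label) &
                   !(x$label %in% c(CLASS_LEVELS, "unlabelled")))
    if (length(bad) > 0) {
      abort(paste0(line_of(bad[1]), ": label must be pathogenic, neutral ",
                   "or unlabelled"))
    }
  }
  attr(x, "class_counts") <- class_counts(x)
  class(x) <- unique(c("tricall_variants", class(x)))
  x
}

class_counts <- function(x) {
  lab <- if ("label" %in% names(x)) x$label else character(0)
  c(pathogenic = sum(lab == "pathogenic", na.rm = TRUE),
    neutral = sum(lab == "neutral", na.rm = TRUE))
}

#' Write tri-class predictions to TSV
#'
#' Serialises a prediction tibble (see [predict.tricall_ensemble()]) with
#' a deterministic column order.  Floating point columns are written with
#' 6 significant digits; re-reading the file recovers the written values
#' exactly.
#'
#' @param predictions Tibble with columns `variant_id`, `mu`, `sigma`,
#'   `lower`, `upper`, `call`, `combined`.
#' @param path Output file path.
#' @return The written tibble, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("variant_id", "mu", "sigma", "lower", "upper", "call", "combined")
  missing_cols <- setdiff(cols, names(predictions))
  if (length(missing_cols) > 0) {
    abort(paste0("predictions lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(predictions)[, cols]
  for (nm in c("mu", "sigma", "lower", "upper")) {
    out[[nm]] <- signif(out[[nm]], 6)
  }
  out$call <- as.character(out$call)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' Read a tri-class prediction TSV
#'
#' Inverse of [write_predictions()].
#'
#' @param path File written by [write_predictions()].
#' @return A tibble of predictions.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    variant_id = readr::col_character(),
                    mu = readr::col_double(),
                    sigma = readr::col_double(),
                    lower = readr::col_double(),
                    upper = readr::col_double(),
                    call = readr::col_character(),
                    combined = readr::col_logical()))
}

#' Read a functional/structural site annotation table
#'
#' Sites are one-based inclusive intervals on the protein sequence, with a
#' free-text annotation type (e.g. Binding, Metal, Active, IM, Site).
#'
#' @param path TSV with columns `protein_id`, `start`, `end`, `type`.
#' @return A validated tibble of site annotations.
#' @export
read_sites <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sites(x)
}

#' @rdname read_sites
#' @param x A data frame of site annotations to validate.
#' @export
validate_sites <- function(x) {
  x <- as_tibble(x)
  required <- c("protein_id", "start", "end", "type")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("site table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(x$start < 1) || any(x$end < x$start)) {
    abort("site intervals must satisfy 1 <= start <= end")
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x
}

#' Read per-protein GO annotations
#'
#' @param path TSV with columns `protein_id`, `term` (one row per
#'   protein-term pair).
#' @return A tibble with columns `protein_id`, `term`.
#' @export
read_go_annotations <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("protein_id", "term") %in% names(x))) {
    abort("GO annotation table must have columns protein_id, term")
  }
  as_tibble(x)[, c("protein_id", "term")]
}
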