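#' Build the GO term frequency context from training variants
#'
#' For each class (pathogenic / neutral) a frequency table of GO terms is
#' accumulated.  Each protein's annotated terms are ancestor-expanded and
#' deduplicated so the protein carries each term once; by default each
#' training *variant* then contributes its protein's term set to its
#' class's counts (so a protein with several training variants is counted
#' once per variant).  Set `count_unit = "protein"` to count each protein
#' once per class regardless of its number of variants.
#'
#' The context must be built from training-partition variants only; the
#' dataset fingerprint is stored so leakage can be audited.
#'
#' @param training A labelled variant tibble (see [validate_variants()]);
#'   rows with label `pathogenic` or `neutral` are used.
#' @param annotations Tibble with columns `protein_id`, `term`.
#' @param ontology A `tricall_ontology` used for ancestor expansion, or
#'   `NULL` to use the annotated terms as-is.
#' @param count_unit `"variant"` (default) or `"protein"`.
#' @return A `go_context` object with elements `path_freq`, `neut_freq`
#'   (named integer vectors), `protein_terms` (expanded term set per
#'   protein), `count_unit` and `built_from` (fingerprint).
#' @export
build_go_context <- function(training, annotations, ontology = NULL,
                             count_unit = c("variant", "protein")) {
  count_unit <- arg_match(count_unit)
  if (!"label" %in% names(training)) abort("training variants must be labelled")
  training <- dplyr::filter(training, .data$label %in% CLASS_LEVELS)
  if (nrow(training) == 0) abort("empty training set: no labelled variants")

  term_sets <- split(annotations$term, annotations$protein_id)
  if (!is.null(ontology)) {
    term_sets <- lapply(term_sets, expand_terms, onto = ontology)
  } else {
    term_sets <- lapply(term_sets, unique)
  }

  tally <- function(rows) {
    if (count_unit == "protein") {
      prots <- unique(rows$protein_id)
    } else {
      prots <- rows$protein_id  # one contribution per variant
    }
    terms <- unlist(term_sets[prots], use.names = FALSE)
    if (length(terms) == 0) return(integer(0))
    tab <- table(terms)
    setNames(as.integer(tab), names(tab))
  }
  structure(list(
    path_freq = tally(training[training$label == "pathogenic", ]),
    neut_freq = tally(training[training$label == "neutral", ]),
    protein_terms = term_sets,
    count_unit = count_unit,
    built_from = dataset_fingerprint(training)
  ), class = "go_context")
}

dataset_fingerprint <- function(x) {
  ids <- sort(x$variant_id)
  paste0("n=", length(ids), ";sum=",
         sum(utf8ToInt(paste(ids, collapse = ""))))
}

#' @export
print.go_context <- function(x, ...) {
  cat("<go_context> ", length(x$path_freq), " pathogenic-set terms, ",
      length(x$neut_freq), " neutral-set terms (counted per ",
      x$count_unit, ")\n", sep = "")
  invisible(x)
}

#' GO log-ratio feature for a protein
#'
#' The GO feature of a protein is the sum, over its deduplicated term
#' set, of the log ratio of add-one smoothed class frequencies:
#' `LR = sum_i log((f(P_i) + 1) / (f(N_i) + 1))`, with `f(P_i)` and
#' `f(N_i)` the counts of term `i` in the pathogenic and neutral training
#' sets.  Natural log by default; the base only rescales the feature.
#'
#' @param protein_terms Character vector of the protein's (expanded,
#'   deduplicated) terms.  An empty set yields `NA` (feature missing).
#' @param ctx A `go_context` from [build_go_context()].
#' @param base Logarithm base (default `exp(1)`).
#' @return The log-ratio feature value, or `NA_real_`.
#' @export
go_log_ratio <- function(protein_terms, ctx, base = exp(1)) {
  protein_terms <- unique(protein_terms)
  if (length(protein_terms) == 0) return(NA_real_)
  fp <- ctx$path_freq[protein_terms]
  fn <- ctx$neut_freq[protein_terms]
  fp[is.na(fp)] <- 0L
  fn[is.na(fn)] <- 0L
  sum(log((fp + 1) / (fn + 1), base = base))
}

#' Counting surrogate for codon-level selective pressure
#'
#' The selective-pressure feature omega (Ka/Ks) is normally an input
#' computed with a dedicated selection-analysis tool on a codon
#' alignment.  This function is a simple counting surrogate — it is NOT
#' equivalent to a codon-model estimate — provided so the pipeline can
#' run end-to-end without external tools.  For one reference codon it
#' counts, over all pairwise comparisons of the reference with each
#' ortholog, the synonymous and non-synonymous single-nucleotide
#' differences (each differing position classified by mutating the
#' reference codon at that position alone), normalises each count by the
#' reference codon's synonymous / non-synonymous site counts times the
#' number of comparisons, and returns the ratio of the two rates.
#'
#' @param codon_alignment Character matrix or named character vector of
#'   equal-length, in-frame aligned coding sequences; first row/element
#'   (or `reference_id`) is the reference.
#' @param codon_position One-based codon index on the reference
#'   (gap-free codons only).
#' @param reference_id Optional name of the reference sequence; defaults
#'   to the first.
#' @return Non-negative ratio, or `NA_real_` when the synonymous rate is
#'   zero (including fully conserved columns).
#' @export
surrogate_omega <- function(codon_alignment, codon_position,
                            reference_id = NULL) {
  if (is.character(codon_alignment) && is.null(dim(codon_alignment))) {
    codon_alignment <- do.call(rbind, strsplit(toupper(codon_alignment), ""))
  }
  if (ncol(codon_alignment) %% 3 != 0) {
    abort("codon alignment length is not a multiple of 3 (frame error)")
  }
  ids <- rownames(codon_alignment) %||% as.character(seq_len(nrow(codon_alignment)))
  ref_i <- if (is.null(reference_id)) 1L else match(reference_id, ids)
  if (is.na(ref_i)) abort(paste0("reference '", reference_id, "' not in alignment"))
  j <- (codon_position - 1L) * 3L + 1L
  if (j + 2L > ncol(codon_alignment)) abort("codon position beyond alignment")
  ref_codon <- paste(codon_alignment[ref_i, j:(j + 2L)], collapse = "")
  if (grepl("[^ACGT]", ref_codon)) return(NA_real_)
  if (translate_codon(ref_codon) == "*") {
    abort("internal stop codon in reference (frame error)")
  }
  sites <- codon_site_counts(ref_codon)
  nd <- 0; sd_ <- 0; m <- 0L
  for (i in setdiff(seq_len(nrow(codon_alignment)), ref_i)) {
    codon <- paste(codon_alignment[i, j:(j + 2L)], collapse = "")
    if (grepl("[^ACGT]", codon)) next
    m <- m + 1L
    for (p in 1:3) {
      a <- substr(ref_codon, p, p); b <- substr(codon, p, p)
      if (a == b) next
      mutated <- ref_codon
      substr(mutated, p, p) <- b
      if (translate_codon(mutated) == translate_codon(ref_codon)) {
        sd_ <- sd_ + 1
      } else {
        nd <- nd + 1
      }
    }
  }
  if (m == 0L) return(NA_real_)
  rate_n <- nd / (sites["n_sites"] * m)
  rate_s <- if (sites["s_sites"] > 0) sd_ / (sites["s_sites"] * m) else 0
  if (rate_s == 0) {
    if (rate_n == 0) return(NA_real_)
    return(NA_real_)  # non-synonymous rate over a zero synonymous rate
  }
  unname(rate_n / rate_s)
}

translate_codon <- function(codon) {
  GENETIC_CODE_TABLE[[codon]] %||% "X"
}

# standard genetic code, codon -> one-letter amino acid ('*' = stop)
GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  as.list(setNames(aas, codons))
})

# per-codon synonymous/non-synonymous site counts (Nei-Gojobori style):
# each position contributes the fraction of its three possible changes
# that are synonymous.
codon_site_counts <- function(codon) {
  aa <- translate_codon(codon)
  s <- 0
  for (p in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, p, p)) next
      mutated <- codon
      substr(mutated, p, p) <- b
      if (translate_codon(mutated) == aa) s <- s + 1 / 3
    }
  }
  c(s_sites = s, n_sites = 3 - s)
}

#' Assemble the per-variant feature table
#'
#' Builds one row per variant with the configured named numeric features.
#' The default feature set is the one used by the final predictor: the GO
#' log-ratio (`go_lr`), selective pressure (`omega`, taken from an
#' `omega` column on the variant table), the three sequence-profile
#' features (`f_ref`, `f_var`, `n_seq`) and the three amino acid property
#' features `KOSJ950114`, `RACS820113`, `TANS770104`.  Feature columns
#' already present on `variants` (for example from the synthetic
#' generator or a precomputed store) pass through unchanged; providers
#' are consulted only for features not already present.  A provider that
#' cannot serve a variant leaves the cell `NA` (missing), never a silent
#' zero.
#'
#' @param variants A validated variant tibble.
#' @param features Character vector of feature column names to assemble.
#' @param go_context,go_annotations,ontology GO provider: a
#'   [build_go_context()] context plus per-protein annotations (and
#'   optional ontology for expansion).
#' @param msas Named list of `tricall_msa` objects keyed by protein id
#'   (sequence-profile provider).
#' @param aaindex Tibble from [read_aaindex()] covering any requested
#'   accession-named features.
#' @param count_gaps Passed to [sequence_profile()].
#' @return A tibble `variant_id` + one numeric column per feature, with a
#'   `provenance` attribute describing each column's provider and missing
#'   count.
#' @export
assemble_features <- function(variants,
                              features = c("go_lr", "omega", "f_ref",
                                           "f_var", "n_seq", "KOSJ950114",
                                           "RACS820113", "TANS770104"),
                              go_context = NULL, go_annotations = NULL,
                              ontology = NULL, msas = NULL, aaindex = NULL,
                              count_gaps = TRUE) {
  out <- tibble(variant_id = variants$variant_id)
  provenance <- list()
  have_profile <- FALSE
  for (f in features) {
    if (f %in% names(variants)) {
      out[[f]] <- as.numeric(variants[[f]])
      provenance[[f]] <- list(provider = "passthrough")
    } else if (f == "go_lr" && !is.null(go_context)) {
      term_sets <- protein_term_sets(variants$protein_id, go_annotations,
                                     ontology, go_context)
      out[[f]] <- map_dbl(term_sets, go_log_ratio, ctx = go_context)
      provenance[[f]] <- list(provider = "go_log_ratio",
                              count_unit = go_context$count_unit)
    } else if (f %in% c("f_ref", "f_var", "n_seq") && !is.null(msas)) {
      if (!have_profile) {
        prof <- profile_rows(variants, msas, count_gaps)
        have_profile <- TRUE
      }
      out[[f]] <- prof[[f]]
      provenance[[f]] <- list(provider = "sequence_profile",
                              count_gaps = count_gaps)
    } else if (!is.null(aaindex) && f %in% aaindex$accession) {
      entry <- aaindex_get(aaindex, f)
      out[[f]] <- if (is.matrix(entry)) {
        aaindex_matrix_value(entry, variants$ref_aa, variants$var_aa)
      } else {
        aaindex1_delta(entry, variants$ref_aa, variants$var_aa)
      }
      provenance[[f]] <- list(provider = "aaindex")
    } else {
      out[[f]] <- NA_real_
      provenance[[f]] <- list(provider = "none")
    }
    provenance[[f]]$n_missing <- sum(is.na(out[[f]]))
  }
  attr(out, "provenance") <- provenance
  out
}

protein_term_sets <- function(protein_ids, go_annotations, ontology, ctx) {
  if (!is.null(go_annotations)) {
    sets <- split(go_annotations$term, go_annotations$protein_id)
    sets <- if (!is.null(ontology)) lapply(sets, expand_terms, onto = ontology)
            else lapply(sets, unique)
  } else {
    sets <- ctx$protein_terms
  }
  lapply(protein_ids, function(p) sets[[p]] %||% character(0))
}

profile_rows <- function(variants, msas, count_gaps) {
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    msa <- msas[[variants$protein_id[i]]]
    ok <- !is.null(msa) && variants$position[i] <= length(msa$column_map)
    rows[[i]] <- if (ok) {
      sequence_profile(msa, variants$position[i], variants$ref_aa[i],
                       variants$var_aa[i], count_gaps = count_gaps)
    } else {
      tibble(f_ref = NA_real_, f_var = NA_real_, n_seq = NA_integer_)
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a feature table with a provenance sidecar
#'
#' Serialises the feature tibble as TSV and its provenance attribute as a
#' JSON sidecar (`<path>.json`).
#'
#' @param feature_table Output of [assemble_features()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(feature_table, path) {
  readr::write_tsv(feature_table, path, progress = FALSE)
  prov <- attr(feature_table, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
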