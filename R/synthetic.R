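#' Synthetic dataset configuration
#'
#' Describes a synthetic variant dataset with the statistical structure
#' the predictor assumes: approximately balanced pathogenic/neutral
#' classes, protein-family structure with heavy-tailed family sizes,
#' class-shifted informative features plus class-independent noise
#' features, a right-skewed selective-pressure variable with pathogenic
#' mass near zero (variants at conserved sites), class-biased functional
#' annotation types, and GO term sets skewed by protein-level pathogenic
#' propensity.
#'
#' @param n_proteins Number of proteins.
#' @param variants_per_protein Variants simulated per protein.
#' @param class_balance Marginal probability that a variant is
#'   pathogenic (0.5 = balanced design).
#' @param informative_features Names of class-shifted informative
#'   features; their class-conditional laws are unit-variance normals
#'   with a mean gap set by `overlap`.
#' @param n_noise_features Number of class-independent N(0,1) noise
#'   features (`noise1`, `noise2`, ...).
#' @param include_omega Add a right-skewed `omega` feature whose
#'   class separation also shrinks with `overlap`.
#' @param annotation_types Named numeric vector of target pathogenic
#'   proportions per annotation type.
#' @param annotation_density Fraction of variants overlapped by sites of
#'   each annotation type.
#' @param go_signal Skew in `[0, 1]` of risk-term assignment with
#'   protein-level pathogenic propensity (0 = uninformative GO tables).
#' @param overlap Class separability control in `[0, 1]`: 0 gives
#'   disjoint feature supports, 1 identical class distributions; between,
#'   the normal mean gap is `-2 * qnorm(overlap / 2)` so the class
#'   overlap coefficient of one feature is approximately `overlap`.
#' @param protein_length Length of each simulated protein.
#' @param family_concentration Log-normal sd of family sizes (larger =
#'   heavier tail).
#' @param seed Integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 40, variants_per_protein = 8,
                             class_balance = 0.5,
                             informative_features = c("go_lr", "f_ref",
                                                      "aa_prop"),
                             n_noise_features = 5, include_omega = TRUE,
                             annotation_types = c(Metal = 0.95,
                                                  Active = 0.90,
                                                  Binding = 0.88),
                             annotation_density = 0.15, go_signal = 0.8,
                             overlap = 0.3, protein_length = 200,
                             family_concentration = 0.8, seed = 1) {
  if (overlap < 0 || overlap > 1) abort("overlap must lie in [0, 1]")
  if (class_balance <= 0 || class_balance >= 1) {
    abort("class_balance must lie strictly between 0 and 1")
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a synthetic variant dataset
#'
#' Produces a labelled variant table, a dense feature table, annotation
#' sites realising the configured class biases, GO annotation tables
#' with a toy ontology, and a truth record naming the planted signal.
#'
#' @param cfg A [generator_config()].
#' @return A list: `variants` (validated variant tibble with `label`,
#'   `family_id`), `features` (tibble `variant_id` + feature columns),
#'   `data` (variants joined with features, ready for [fit_ensemble()]),
#'   `sites`, `go_annotations`, `ontology`, `obo_text`, `truth`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    proteins <- sprintf("P%03d", seq_len(cfg$n_proteins))
    families <- draw_families(cfg$n_proteins, cfg$family_concentration)
    # protein-level pathogenic propensity around the class balance, so GO
    # (a protein-level signal) has something to correlate with
    propensity <- stats::rbeta(cfg$n_proteins,
                               cfg$class_balance * 4,
                               (1 - cfg$class_balance) * 4)
    n_var <- cfg$n_proteins * cfg$variants_per_protein
    protein_of <- rep(proteins, each = cfg$variants_per_protein)
    label <- ifelse(runif(n_var) < rep(propensity,
                                       each = cfg$variants_per_protein),
                    "pathogenic", "neutral")
    if (length(unique(label)) < 2) {  # degenerate draw: force one of each
      label[1] <- "pathogenic"; label[2] <- "neutral"
    }
    ref <- sample(AA_STANDARD, n_var, replace = TRUE)
    var <- vapply(ref, function(a) sample(setdiff(AA_STANDARD, a), 1), "")
    variants <- tibble(
      variant_id = sprintf("v%04d", seq_len(n_var)),
      protein_id = protein_of,
      position = as.integer(sample(cfg$protein_length, n_var,
                                   replace = TRUE)),
      ref_aa = ref, var_aa = unname(var), label = label,
      family_id = rep(families, each = cfg$variants_per_protein))
    variants <- validate_variants(variants, source = "synthetic dataset")

    is_path <- label == "pathogenic"
    features <- tibble(variant_id = variants$variant_id)
    for (f in cfg$informative_features) {
      features[[f]] <- draw_informative(is_path, cfg$overlap)
    }
    if (cfg$include_omega) {
      shift <- 0.8 * (1 - cfg$overlap)
      features$omega <- rlnorm(n_var,
                               meanlog = ifelse(is_path, -1.5 - shift,
                                                -1.5 + shift),
                               sdlog = 0.5)
    }
    for (i in seq_len(cfg$n_noise_features)) {
      features[[paste0("noise", i)]] <- rnorm(n_var)
    }

    sites <- place_sites(variants, cfg)
    go <- plant_go(proteins, propensity, cfg)

    truth <- list(
      informative_features = c(cfg$informative_features,
                               if (cfg$include_omega) "omega"),
      noise_features = paste0("noise", seq_len(cfg$n_noise_features)),
      annotation_types = cfg$annotation_types,
      risk_terms = go$risk_terms, overlap = cfg$overlap,
      propensity = setNames(propensity, proteins))

    list(variants = variants, features = features,
         data = left_join(as_tibble(variants), features, by = "variant_id"),
         sites = sites, go_annotations = go$annotations,
         ontology = go$ontology, obo_text = go$obo_text, truth = truth)
  })
}

draw_families <- function(n_proteins, concentration) {
  sizes <- integer(0)
  while (sum(sizes) < n_proteins) {
    sizes <- c(sizes, pmax(1L, round(rlnorm(n_proteins, 0, concentration))))
  }
  cum <- cumsum(sizes)
  k <- which(cum >= n_proteins)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n_proteins)
  rep(sprintf("FAM%03d", seq_along(sizes)), times = sizes)
}

draw_informative <- function(is_path, overlap) {
  n <- length(is_path)
  if (overlap == 0) {
    # disjoint supports with a unit margin
    runif(n, 0.5, 1.5) * ifelse(is_path, 1, -1)
  } else {
    gap <- -2 * qnorm(overlap / 2)
    rnorm(n, mean = ifelse(is_path, gap / 2, -gap / 2), sd = 1)
  }
}

place_sites <- function(variants, cfg) {
  n_var <- nrow(variants)
  used <- character(0)
  rows <- list()
  for (ty in names(cfg$annotation_types)) {
    pa <- cfg$annotation_types[[ty]]
    n_overlap <- max(2L, round(cfg$annotation_density * n_var))
    n_path <- round(pa * n_overlap)
    pool_p <- setdiff(variants$variant_id[variants$label == "pathogenic"],
                      used)
    pool_n <- setdiff(variants$variant_id[variants$label == "neutral"], used)
    take_p <- sample(pool_p, min(n_path, length(pool_p)))
    take_n <- sample(pool_n, min(n_overlap - n_path, length(pool_n)))
    ids <- c(take_p, take_n)
    if (length(ids) == 0) next
    used <- c(used, ids)
    hit <- variants[match(ids, variants$variant_id), ]
    rows[[ty]] <- tibble(protein_id = hit$protein_id, start = hit$position,
                         end = hit$position, type = ty)
  }
  dplyr::bind_rows(rows)
}

plant_go <- function(proteins, propensity, cfg) {
  obo_text <- generate_toy_ontology(depth = 2, branching = 3)
  onto <- obo_from_text(obo_text)
  leaves <- setdiff(onto$terms,
                    unique(unlist(onto$parents)))
  half <- length(leaves) %/% 2
  risk <- leaves[seq_len(half)]
  benign <- setdiff(leaves, risk)
  rows <- list()
  for (i in seq_along(proteins)) {
    p_risk <- 0.5 + cfg$go_signal * (propensity[i] - 0.5)
    n_terms <- 3L
    pick <- ifelse(runif(n_terms) < p_risk,
                   sample(risk, n_terms, replace = TRUE),
                   sample(benign, n_terms, replace = TRUE))
    rows[[i]] <- tibble(protein_id = proteins[i], term = unique(pick))
  }
  list(annotations = dplyr::bind_rows(rows), ontology = onto,
       obo_text = obo_text, risk_terms = risk)
}

#' Generate a toy alignment with a target conservation profile
#'
#' Builds an ungapped multiple sequence alignment whose column-wise
#' frequency of the reference residue approximates the requested
#' conservation profile: the reference always carries its residue, and
#' every other sequence carries it independently with the column's
#' conservation probability, otherwise a random different residue.
#'
#' @param n_seq Number of sequences (reference included).
#' @param length Alignment length; must equal
#'   `length(conservation_profile)`.
#' @param conservation_profile Numeric vector of per-column reference
#'   residue probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @param reference_id Name given to the reference sequence.
#' @return A `tricall_msa` object (see [msa_from_strings()]).
#' @export
generate_toy_msa <- function(n_seq, length, conservation_profile, seed = 1,
                             reference_id = "human") {
  if (base::length(conservation_profile) != length) {
    abort("conservation_profile length must equal the alignment length")
  }
  with_seed(seed, {
    ref <- sample(AA_STANDARD, length, replace = TRUE)
    seqs <- matrix("", nrow = n_seq, ncol = length)
    seqs[1, ] <- ref
    for (j in seq_len(length)) {
      keep <- runif(n_seq - 1) < conservation_profile[j]
      other <- sample(setdiff(AA_STANDARD, ref[j]), n_seq - 1,
                      replace = TRUE)
      seqs[-1, j] <- ifelse(keep, ref[j], other)
    }
    ids <- c(reference_id, sprintf("ortholog%03d", seq_len(n_seq - 1)))
    msa_from_strings(setNames(apply(seqs, 1, paste, collapse = ""), ids),
                     reference_id = reference_id)
  })
}

#' Write an alignment as FASTA
#'
#' @param msa A `tricall_msa`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  lines <- as.vector(rbind(paste0(">", msa$ids),
                           apply(msa$seqs, 1, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a toy tree-structured ontology as OBO text
#'
#' Builds a complete `branching`-ary tree of the given depth below a
#' single root, so every leaf has exactly `depth` ancestors and the
#' ontology has `(branching^(depth+1) - 1) / (branching - 1)` terms
#' (or `depth + 1` when `branching` is 1).
#'
#' @param depth Levels below the root (>= 1).
#' @param branching Children per node (>= 1).
#' @return OBO 1.2 text (single string) parseable by [obo_from_text()].
#' @export
generate_toy_ontology <- function(depth, branching) {
  stopifnot(depth >= 1, branching >= 1)
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("T:%07d", counter)
  }
  stanzas <- character(0)
  emit <- function(id, parent) {
    stanzas <<- c(stanzas,
                  "[Term]", paste0("id: ", id), paste0("name: term ", id),
                  if (!is.null(parent)) paste0("is_a: ", parent), "")
  }
  root <- new_id()
  emit(root, NULL)
  level <- root
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (parent in level) {
      for (b in seq_len(branching)) {
        id <- new_id()
        emit(id, parent)
        nxt <- c(nxt, id)
      }
    }
    level <- nxt
  }
  paste(c("format-version: 1.2", "", stanzas), collapse = "\n")
}

#' Write the full synthetic input bundle to a directory
#'
#' Serialises everything [generate_dataset()] produced in the external
#' formats the readers consume: `variants.tsv`, `features.tsv`,
#' `sites.tsv`, `go_annotations.tsv`, `ontology.obo`, per-protein toy
#' alignments under `msa/`, and `truth.json`.
#'
#' @param ds Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param msa Also write toy alignments (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(ds, dir, msa = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(as_tibble(ds$variants), file.path(dir, "variants.tsv"),
                   progress = FALSE)
  readr::write_tsv(ds$features, file.path(dir, "features.tsv"),
                   progress = FALSE)
  readr::write_tsv(ds$sites, file.path(dir, "sites.tsv"), progress = FALSE)
  readr::write_tsv(ds$go_annotations, file.path(dir, "go_annotations.tsv"),
                   progress = FALSE)
  writeLines(ds$obo_text, file.path(dir, "ontology.obo"))
  if (msa) {
    msa_dir <- file.path(dir, "msa")
    dir.create(msa_dir, showWarnings = FALSE)
    proteins <- unique(ds$variants$protein_id)
    len <- max(ds$variants$position)
    for (i in seq_along(proteins)) {
      m <- generate_toy_msa(30, len, runif(len, 0.4, 1),
                            seed = i)
      write_msa_fasta(m, file.path(msa_dir, paste0(proteins[i], ".fasta")))
    }
  }
  truth <- ds$truth
  truth$propensity <- as.list(truth$propensity)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
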