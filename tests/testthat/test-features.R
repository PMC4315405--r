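make_ctx <- function(path_freq, neut_freq) {
  structure(list(path_freq = path_freq, neut_freq = neut_freq,
                 protein_terms = list(), count_unit = "variant",
                 built_from = "test"), class = "go_context")
}

test_that("go_log_ratio follows the smoothed log-ratio arithmetic", {
  ctx <- make_ctx(c(t1 = 0L), c(t1 = 0L))
  expect_equal(go_log_ratio("t1", ctx), 0)           # log(1/1)
  ctx2 <- make_ctx(c(t1 = 9L), c(t1 = 4L))
  expect_equal(go_log_ratio("t1", ctx2), log(10 / 5))  # 0.6931...
  ctx3 <- make_ctx(c(a = 1L, b = 3L), c(a = 3L, b = 1L))
  expect_equal(go_log_ratio(c("a", "b"), ctx3), 0)   # symmetric pair cancels
  expect_true(is.na(go_log_ratio(character(0), ctx2)))
})

test_that("go_log_ratio is antisymmetric under exchanging the class maps", {
  set.seed(1)
  for (i in 1:20) {
    terms <- paste0("t", 1:6)
    fp <- setNames(rpois(6, 3), terms)
    fn <- setNames(rpois(6, 3), terms)
    ctx <- make_ctx(fp, fn)
    swapped <- make_ctx(fn, fp)
    sub <- sample(terms, sample(1:6, 1))
    expect_equal(go_log_ratio(sub, ctx), -go_log_ratio(sub, swapped))
    # a term with equal class frequencies leaves LR unchanged
    ctx_eq <- make_ctx(c(fp, eq = 5L), c(fn, eq = 5L))
    expect_equal(go_log_ratio(c(sub, "eq"), ctx_eq), go_log_ratio(sub, ctx))
  }
})

test_that("the GO context counts each protein's terms once per variant", {
  onto <- obo_from_text(toy_obo_text())
  ann <- tibble::tibble(protein_id = c("P1", "P1", "P2"),
                        term = c("GO:A", "GO:B", "GO:D"))
  training <- validate_variants(tibble::tibble(
    variant_id = c("v1", "v2", "v3"),
    protein_id = c("P1", "P1", "P2"),
    position = c(1L, 2L, 3L), ref_aa = c("A", "A", "A"),
    var_aa = c("V", "W", "V"),
    label = c("pathogenic", "pathogenic", "neutral")))
  ctx <- build_go_context(training, ann, onto)
  # P1 expands {A,B} -> {A,B,C}; two pathogenic variants count it twice
  expect_equal(unname(ctx$path_freq[c("GO:A", "GO:B", "GO:C")]), c(2L, 2L, 2L))
  # ancestors reached twice through a diamond still count once per protein
  expect_equal(unname(ctx$neut_freq[["GO:C"]]), 1L)
  # per-protein counting collapses the duplicate contribution
  ctx_p <- build_go_context(training, ann, onto, count_unit = "protein")
  expect_equal(unname(ctx_p$path_freq[["GO:A"]]), 1L)
  expect_error(build_go_context(training[0, ], ann, onto), "empty")
})

test_that("aaindex1 deltas are reference minus variant and antisymmetric", {
  idx <- read_aaindex(aaindex1_fixture())
  v <- aaindex_get(idx, "FAKE000001")
  expect_equal(aaindex1_delta(v, "A", "W"), 1.8 - (-0.9))
  expect_equal(aaindex1_delta(v, "W", "A"), -2.7)
  for (pair in list(c("A", "C"), c("R", "Y"), c("G", "V"))) {
    expect_equal(aaindex1_delta(v, pair[1], pair[2]),
                 -aaindex1_delta(v, pair[2], pair[1]))
  }
  expect_equal(aaindex1_delta(v, "A", "A"), 0)
})

test_that("filter_complete_indices drops exactly the entries with NA", {
  idx <- read_aaindex(aaindex1_fixture())
  kept <- suppressMessages(filter_complete_indices(idx))
  expect_equal(kept$accession, "FAKE000001")
  all_ok <- suppressMessages(filter_complete_indices(kept))
  expect_equal(nrow(all_ok), nrow(kept))
})

test_that("sequence_profile counts residues with gaps in the denominator", {
  msa <- msa_from_strings(c(human = "AAAAAAAAAA", o1 = "AAAAAAAAAA",
                            o2 = "AAAAAAAAAA", o3 = "AAAAAAAAAA"), "human")
  p <- sequence_profile(msa, 3, "A", "V")
  expect_equal(p$f_ref, 1); expect_equal(p$f_var, 0)
  expect_equal(p$n_seq, 4L)

  # column {A, A, V, -} for an A->V substitution
  msa2 <- msa_from_strings(c(human = "CAC", o1 = "CAC", o2 = "CVC",
                             o3 = "C-C"), "human")
  p2 <- sequence_profile(msa2, 2, "A", "V")
  expect_equal(p2$f_ref, 0.5)
  expect_equal(p2$f_var, 0.25)
  expect_equal(p2$n_seq, 4L)
  p2b <- sequence_profile(msa2, 2, "A", "V", count_gaps = FALSE)
  expect_equal(p2b$f_ref, 2 / 3)

  single <- msa_from_strings(c(human = "ACD"), "human")
  ps <- sequence_profile(single, 1, "A", "V")
  expect_equal(ps$f_ref, 1); expect_equal(ps$n_seq, 1L)
  expect_error(sequence_profile(single, 9, "A", "V"), "out of range")
})

test_that("f_ref and f_var stay in [0,1] with bounded sum", {
  set.seed(42)
  for (i in 1:10) {
    msa <- generate_toy_msa(12, 20, runif(20), seed = i)
    pos <- sample(20, 5)
    p <- sequence_profile(msa, pos, sample(c("A", "V", "L"), 5,
                                           replace = TRUE), "W")
    expect_true(all(p$f_ref >= 0 & p$f_ref <= 1))
    expect_true(all(p$f_var >= 0 & p$f_var <= 1))
    expect_true(all(p$f_ref + p$f_var <= 1 + 1e-12))
  }
})

test_that("the omega counting surrogate matches a brute-force classifier", {
  # independent oracle: classify each single-nucleotide difference via the
  # standard genetic code from Biostrings
  skip_if_not_installed("Biostrings")
  gc <- Biostrings::GENETIC_CODE
  oracle <- function(ref, others) {
    aa <- function(codon) unname(gc[[codon]])
    syn_sites <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(ref, p, p))) {
      mut <- ref; substr(mut, p, p) <- b
      if (aa(mut) == aa(ref)) syn_sites <- syn_sites + 1 / 3
    }
    nd <- 0; sd_ <- 0
    for (o in others) for (p in 1:3) {
      if (substr(ref, p, p) == substr(o, p, p)) next
      mut <- ref; substr(mut, p, p) <- substr(o, p, p)
      if (aa(mut) == aa(ref)) sd_ <- sd_ + 1 else nd <- nd + 1
    }
    m <- length(others)
    rn <- nd / ((3 - syn_sites) * m)
    rs <- if (syn_sites > 0) sd_ / (syn_sites * m) else 0
    if (rs == 0) NA_real_ else rn / rs
  }
  cases <- list(
    list(ref = "TTA", others = c("TTG", "CTA", "TCA")),
    list(ref = "GGA", others = c("GGG", "AGA")),
    list(ref = "ATG", others = c("ATA", "CTG")))
  for (cs in cases) {
    aln <- c(human = cs$ref, setNames(cs$others,
                                      paste0("o", seq_along(cs$others))))
    expect_equal(surrogate_omega(aln, 1, reference_id = "human"),
                 oracle(cs$ref, cs$others))
  }
})

test_that("omega surrogate degenerate columns follow the stated contract", {
  # fully conserved column: no differences at all -> missing
  expect_true(is.na(surrogate_omega(c("GAA", "GAA", "GAA"), 1)))
  # synonymous-only difference -> 0
  expect_equal(surrogate_omega(c(human = "GAA", o1 = "GAG"), 1, "human"), 0)
  # non-synonymous-only difference over a zero synonymous rate -> missing
  expect_true(is.na(surrogate_omega(c(human = "GAA", o1 = "GAC"), 1, "human")))
  expect_error(surrogate_omega(c("GAAA", "GAAA"), 1), "frame")
})

test_that("assemble_features masks missing providers and passes through", {
  ds <- signal_dataset(seed = 2)
  # planted columns pass through unchanged; unknown providers are masked
  ft <- assemble_features(ds$data,
                          features = c("sig1", "sig2", "KOSJ950114"))
  expect_equal(ft$sig1, ds$features$sig1)
  expect_true(all(is.na(ft$KOSJ950114)))
  prov <- attr(ft, "provenance")
  expect_equal(prov$sig1$provider, "passthrough")
  expect_equal(prov$KOSJ950114$provider, "none")
  expect_equal(prov$KOSJ950114$n_missing, nrow(ft))

  # a synthetic bundle yields a dense table for its planted features
  dense <- assemble_features(ds$data, features = c("sig1", "sig2", "noise1"))
  expect_false(anyNA(dense[-1]))

  # GO provider: a protein absent from the annotation table is masked
  onto <- obo_from_text(toy_obo_text())
  ann <- tibble::tibble(protein_id = ds$variants$protein_id[1],
                        term = "GO:A")
  ctx <- build_go_context(ds$variants, ann, onto)
  ft2 <- assemble_features(ds$variants, features = c("go_lr", "sig_absent"),
                           go_context = ctx, go_annotations = ann,
                           ontology = onto)
  first_prot <- ds$variants$protein_id == ds$variants$protein_id[1]
  expect_false(anyNA(ft2$go_lr[first_prot]))
  expect_true(all(is.na(ft2$go_lr[!first_prot])))
})

test_that("feature tables serialize with a provenance sidecar", {
  ds <- signal_dataset(seed = 3)
  ft <- assemble_features(ds$data, features = c("sig1", "sig2"))
  path <- tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$sig1, ft$sig1)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$sig1$provider, "passthrough")
})
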