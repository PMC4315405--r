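test_that("family folds never split a family and are deterministic", {
  ds <- signal_dataset(seed = 41)
  f1 <- family_kfold(ds$data, k = 5, seed = 2)
  f2 <- family_kfold(ds$data, k = 5, seed = 2)
  expect_identical(f1, f2)
  spans <- f1 |>
    dplyr::distinct(family_id, fold) |>
    dplyr::count(family_id)
  expect_true(all(spans$n == 1))
  expect_setequal(unique(f1$fold), 1:5)
})

test_that("ten equal families with k = 10 give one family per fold", {
  d <- tibble::tibble(variant_id = sprintf("v%02d", 1:40),
                      family_id = rep(sprintf("F%02d", 1:10), each = 4))
  f <- family_kfold(d, k = 10, seed = 1)
  per_fold <- f |> dplyr::distinct(family_id, fold) |> dplyr::count(fold)
  expect_true(all(per_fold$n == 1))
  expect_error(family_kfold(d, k = 11, seed = 1), "11 folds")
})

test_that("backward elimination keeps the informative features", {
  ds <- generate_dataset(generator_config(
    seed = 51, overlap = 0.15, n_proteins = 30, variants_per_protein = 8,
    informative_features = c("infA", "infB"), include_omega = FALSE,
    n_noise_features = 8))
  folds <- family_kfold(ds$data, k = 4, seed = 3)$fold
  cands <- c("infA", "infB", paste0("noise", 1:8))
  res <- backward_elimination(ds$data[folds != 1, ], ds$data[folds == 1, ],
                              cands, selection_config(n_trees = 60, seed = 5))
  expect_true(all(c("infA", "infB") %in% res$subset))
  expect_equal(nrow(res$trace), length(cands))
  # single candidate short-circuits
  single <- backward_elimination(ds$data, ds$data, "infA",
                                 selection_config(seed = 1))
  expect_equal(single$subset, "infA")
})

test_that("forward selection stops once redundancy adds nothing", {
  ds <- generate_dataset(generator_config(
    seed = 61, overlap = 0.2, n_proteins = 30, variants_per_protein = 8,
    informative_features = "core", include_omega = FALSE,
    n_noise_features = 2))
  d <- ds$data
  # redundant copies of the dominant feature plus a little jitter
  set.seed(99)
  d$copy1 <- d$core + rnorm(nrow(d), 0, 0.01)
  d$copy2 <- d$core + rnorm(nrow(d), 0, 0.01)
  res <- forward_selection(c("core", "copy1", "copy2"), d,
                           selection_config(n_trees = 60, k = 5, seed = 7))
  expect_lte(length(res$selected), 2)
  expect_true(any(c("core", "copy1", "copy2") %in% res$selected))
  # accepted accuracies strictly increase
  expect_true(all(diff(res$trace$accuracy) > 0))
})

test_that("all-noise candidates add no real accuracy beyond the seed", {
  ds <- generate_dataset(generator_config(
    seed = 71, overlap = 1, n_proteins = 25, variants_per_protein = 8,
    informative_features = character(0), include_omega = FALSE,
    n_noise_features = 4))
  lens <- integer(0)
  for (s in 1:4) {
    res <- forward_selection(paste0("noise", 1:4), ds$data,
                             selection_config(n_trees = 40, k = 5, seed = s))
    lens <- c(lens, length(res$selected))
    # whatever chance fluctuations admit, CV accuracy stays near chance
    expect_lt(max(res$trace$accuracy), 0.62)
  }
  # in expectation no addition improves on the seeded feature, so the
  # selected set stays small even when noise occasionally slips in
  expect_lte(mean(lens), 2.5)
})

test_that("two-step selection recovers planted features and is leak-free", {
  ds <- generate_dataset(generator_config(
    seed = 81, overlap = 0.2, n_proteins = 30, variants_per_protein = 8,
    informative_features = c("sigA", "sigB", "sigC"), include_omega = FALSE,
    n_noise_features = 5))
  cands <- c("sigA", "sigB", "sigC", paste0("noise", 1:5))
  sel <- run_two_step_selection(ds$data, cands,
                                selection_config(n_trees = 60, k = 5,
                                                 seed = 9))
  # with strongly separating features the last planted one can be genuinely
  # redundant for accuracy, so require most of the signal, not all of it
  expect_gte(sum(c("sigA", "sigB", "sigC") %in% sel$selected), 2)
  expect_lte(length(setdiff(sel$selected, c("sigA", "sigB", "sigC"))), 2)
  expect_true(all(sel$selected %in% sel$non_redundant))
  expect_true(all(sel$non_redundant %in% cands))
  # no family straddles folds inside the selection CV
  spans <- sel$folds |> dplyr::distinct(family_id, fold) |>
    dplyr::count(family_id)
  expect_true(all(spans$n == 1))
  # determinism under the master seed
  sel2 <- run_two_step_selection(ds$data, cands,
                                 selection_config(n_trees = 60, k = 5,
                                                  seed = 9))
  expect_identical(sel$selected, sel2$selected)
  # candidates equal to an already-selected set come back unchanged
  fixed <- run_two_step_selection(ds$data, c("sigA", "sigB"),
                                  selection_config(n_trees = 40, k = 5,
                                                   seed = 2))
  expect_setequal(fixed$non_redundant, c("sigA", "sigB"))
})

test_that("selection traces serialize to JSON", {
  ds <- signal_dataset(seed = 91)
  sel <- run_two_step_selection(ds$data, c("sig1", "sig2", "noise1"),
                                selection_config(n_trees = 30, k = 4,
                                                 seed = 1))
  path <- tempfile(fileext = ".json")
  write_selection_trace(sel, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$selected, sel$selected)
  expect_equal(sort(js$non_redundant), sort(sel$non_redundant))
  expect_s3_class(tidy(sel), "tbl_df")
  expect_equal(glance(sel)$n_selected, length(sel$selected))
})
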