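test_that("stratified bootstrap preserves per-class counts exactly", {
  labels <- c(rep("pathogenic", 10), rep("neutral", 14))
  for (seed in 1:5) {
    idx <- stratified_bootstrap(labels, seed)
    expect_length(idx, 24)
    expect_equal(sum(labels[idx] == "pathogenic"), 10)
    expect_equal(sum(labels[idx] == "neutral"), 14)
  }
  expect_identical(stratified_bootstrap(labels, 7),
                   stratified_bootstrap(labels, 7))
  # different seeds give different multisets essentially always
  draws <- vapply(1:30, function(s)
    paste(sort(stratified_bootstrap(labels, s)), collapse = ","), "")
  expect_gt(length(unique(draws)), 28)
  expect_error(stratified_bootstrap(rep("pathogenic", 5), 1), "both classes")
})

test_that("chebyshev_classify applies the k = 1/sqrt(1-confidence) gate", {
  k95 <- 1 / sqrt(1 - 0.95)
  expect_equal(k95, sqrt(20))
  # 0.9 +/- 4.47*0.01 excludes 0.5
  expect_equal(chebyshev_classify(0.9, 0.01, 0.95), "pathogenic")
  # 0.6 +/- 4.47*0.1 straddles 0.5
  expect_equal(chebyshev_classify(0.6, 0.1, 0.95), "unknown")
  expect_equal(chebyshev_classify(0.1, 0.01, 0.95), "neutral")
  # the midpoint is always unknown, whatever the spread
  for (s in c(0, 0.01, 0.3)) {
    expect_equal(chebyshev_classify(0.5, s, 0.95), "unknown")
  }
  # zero spread: decided purely by mu vs 0.5
  expect_equal(chebyshev_classify(c(0.51, 0.49, 0.5), 0, 0.95),
               c("pathogenic", "neutral", "unknown"))
  # an interval endpoint exactly at 0.5 rejects (strict inequality):
  # confidence 0.75 gives k = 2 exactly, and 1.0 - 2 * 0.25 = 0.5
  expect_equal(chebyshev_classify(1.0, 0.25, 0.75), "unknown")
  expect_error(chebyshev_classify(0.5, 0.1, 1), "confidence")
})

test_that("training is deterministic and accurate on well-separated data", {
  ds <- signal_dataset(seed = 21, overlap = 0.1)
  feats <- c("sig1", "sig2", "noise1", "noise2", "noise3")
  train_rows <- ds$data$family_id %in% unique(ds$data$family_id)[1:8]
  fit1 <- fit_ensemble(ds$data[train_rows, ], smoke_config(seed = 9),
                       features = feats)
  fit2 <- fit_ensemble(ds$data[train_rows, ], smoke_config(seed = 9),
                       features = feats)
  test_data <- ds$data[!train_rows, ]
  p1 <- predict(fit1, test_data)
  p2 <- predict(fit2, test_data)
  expect_identical(p1$mu, p2$mu)  # bit-identical member probabilities
  acc <- mean(p1$binary_call == test_data$label)
  expect_gt(acc, 0.9)
})

test_that("a 2-member smoke config trains and predicts", {
  ds <- signal_dataset(seed = 4)
  fit <- fit_ensemble(ds$data, ensemble_config(n_bootstrap = 2, n_trees = 5,
                                               seed = 1),
                      features = c("sig1", "sig2"))
  expect_length(fit$members, 2)
  probs <- member_probability(fit, ds$data[1:4, ])
  expect_equal(dim(probs), c(4L, 2L))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("member probabilities are invariant to query row order", {
  ds <- signal_dataset(seed = 6)
  fit <- fit_ensemble(ds$data, smoke_config(), features = c("sig1", "sig2"))
  rows <- ds$data[1:10, ]
  perm <- c(7, 3, 1, 10, 5, 2, 9, 4, 8, 6)
  p_direct <- member_probability(fit, rows)
  p_perm <- member_probability(fit, rows[perm, ])
  expect_equal(p_perm, p_direct[perm, ])
})

test_that("training rejects degenerate inputs", {
  ds <- signal_dataset(seed = 8)
  d <- ds$data
  expect_error(fit_ensemble(d, smoke_config(), features = "sig1"),
               "at least 2 features")
  d$dead <- NA_real_
  expect_error(fit_ensemble(d, smoke_config(),
                            features = c("sig1", "dead")), "dead")
  d2 <- ds$data[ds$data$label == "pathogenic", ]
  expect_error(fit_ensemble(d2, smoke_config(),
                            features = c("sig1", "sig2")), "both classes")
})

test_that("annotation priors shift predictions per the noisy-OR rule", {
  ds <- signal_dataset(seed = 13)
  fit <- fit_ensemble(ds$data, smoke_config(), features = c("sig1", "sig2"))
  q <- ds$data[1:12, ]
  base <- predict(fit, q)
  zero <- predict(fit, q, annotation_pa = rep(0, 12))
  expect_equal(zero$mu, base$mu)     # pa = 0 is the identity
  expect_equal(zero$call, base$call)
  one <- predict(fit, q, annotation_pa = rep(1, 12))
  expect_equal(one$mu, rep(1, 12))   # pa = 1 absorbs: mu 1, sigma 0
  expect_equal(one$sigma, rep(0, 12))
  expect_true(all(one$call == "pathogenic"))
  # per-member combination moves the interval, not only its centre
  half <- predict(fit, q, annotation_pa = rep(0.7, 12))
  expect_true(all(half$sigma <= base$sigma + 1e-12))
})

test_that("raising confidence never un-rejects and coverage is monotone", {
  ds <- signal_dataset(seed = 17, overlap = 0.5)
  fit <- fit_ensemble(ds$data, smoke_config(seed = 2),
                      features = c("sig1", "sig2", "noise1"))
  pred <- predict(fit, ds$data)
  confs <- c(0.5, 0.8, 0.95, 0.99)
  calls <- lapply(confs, function(cf)
    chebyshev_classify(pred$mu, pred$sigma, cf))
  coverage <- vapply(calls, function(cl) mean(cl != "unknown"), 0)
  expect_true(all(diff(coverage) <= 0))
  for (i in seq_len(length(confs) - 1)) {
    was_unknown <- calls[[i]] == "unknown"
    expect_true(all(calls[[i + 1]][was_unknown] == "unknown"))
  }
})

test_that("variants lacking GO are served by the fallback ensemble", {
  ds <- signal_dataset(seed = 23)
  d <- ds$data
  d$go_lr <- d$sig1
  d$go_lr[d$protein_id %in% unique(d$protein_id)[1:5]] <- NA
  fit <- fit_ensemble(d, smoke_config(), features = c("go_lr", "sig2",
                                                      "noise1"))
  expect_false(is.null(fit$fallback_members))
  pred <- predict(fit, d)
  expect_equal(unique(pred$model_used[is.na(d$go_lr)]), "fallback")
  expect_equal(unique(pred$model_used[!is.na(d$go_lr)]), "main")
  # impute-only mode keeps a single ensemble
  fit2 <- fit_ensemble(d, smoke_config(), features = c("go_lr", "sig2",
                                                       "noise1"),
                       missing = "impute")
  expect_null(fit2$fallback_members)
  expect_equal(unique(predict(fit2, d)$model_used), "main")
})

test_that("models persist to a directory and reload intact", {
  ds <- signal_dataset(seed = 31)
  fit <- fit_ensemble(ds$data, ensemble_config(n_bootstrap = 3, n_trees = 10,
                                               seed = 4),
                      features = c("sig1", "sig2"))
  dir <- file.path(tempdir(), "tricall-model-test")
  write_ensemble(fit, dir)
  back <- read_ensemble(dir)
  expect_equal(predict(back, ds$data[1:5, ])$mu,
               predict(fit, ds$data[1:5, ])$mu)
  unlink(dir, recursive = TRUE)
})

test_that("tidy and glance summarise an ensemble", {
  ds <- signal_dataset(seed = 37)
  fit <- fit_ensemble(ds$data, smoke_config(),
                      features = c("sig1", "sig2", "noise1"))
  td <- tidy(fit)
  expect_setequal(td$feature, c("sig1", "sig2", "noise1"))
  expect_true(all(td$mean_decrease_gini >= 0))
  # planted signal outranks noise
  expect_true(which(td$feature == "noise1") == 3)
  gl <- glance(fit)
  expect_equal(gl$n_members, 15L)
  expect_lt(gl$mean_oob_error, 0.5)
})
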