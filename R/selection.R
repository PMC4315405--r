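#' Configuration for greedy feature selection
#'
#' Selection trains many single random forests, so a smaller forest
#' (default 100 trees) is used during the search; the final model is
#' always trained with the full ensemble configuration.
#'
#' @param n_trees Trees per selection forest.
#' @param mtry Features sampled per split.
#' @param k Number of family-aware cross-validation folds.
#' @param gain How "improved the accuracy by the highest percentage" is
#'   scored in forward selection: `"relative"` (default, largest relative
#'   gain over the current accuracy) or `"absolute"`; the argmax is the
#'   same whenever baselines are equal.
#' @param seed Master seed; all selection forests and folds derive from
#'   it deterministically.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(n_trees = 100, mtry = 2, k = 10,
                             gain = c("relative", "absolute"), seed = 1) {
  gain <- arg_match(gain)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 k = as.integer(k), gain = gain, seed = as.integer(seed)),
            class = "selection_config")
}

#' Family-aware k-fold partition
#'
#' Assigns variants to `k` cross-validation folds such that all variants
#' of one protein family land in the same fold (no homology leakage).
#' Variants without a `family_id` get a singleton family named after
#' their protein.  Families are balanced across folds greedily by size
#' (largest first, each to the currently smallest fold), with ties
#' shuffled by the seed.
#'
#' @param data Variant data frame with `variant_id` and optionally
#'   `family_id` / `protein_id`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A tibble `variant_id`, `family_id`, `fold`.
#' @export
family_kfold <- function(data, k = 10, seed = 1) {
  data <- as_tibble(data)
  fam <- if ("family_id" %in% names(data)) as.character(data$family_id)
         else rep(NA_character_, nrow(data))
  if ("protein_id" %in% names(data)) {
    fam[is.na(fam)] <- paste0("singleton:", data$protein_id[is.na(fam)])
  } else {
    fam[is.na(fam)] <- paste0("singleton:", data$variant_id[is.na(fam)])
  }
  sizes <- table(fam)
  if (length(sizes) < k) {
    abort(paste0("only ", length(sizes), " families for ", k, " folds"))
  }
  ord <- with_seed(seed, {
    shuffled <- sample(names(sizes))
    shuffled[order(-sizes[shuffled])]
  })
  fold_of <- integer(0)
  load <- numeric(k)
  for (f in ord) {
    target <- which.min(load)
    fold_of[f] <- target
    load[target] <- load[target] + sizes[[f]]
  }
  tibble(variant_id = data$variant_id, family_id = fam,
         fold = unname(fold_of[fam]))
}

selection_forest <- function(x, y, cfg, seed) {
  with_seed(seed, randomForest::randomForest(
    x = as.data.frame(x), y = y, ntree = cfg$n_trees,
    mtry = min(cfg$mtry, ncol(x)), importance = FALSE))
}

forest_accuracy <- function(rf, x_test, y_test) {
  pred <- predict(rf, as.data.frame(x_test))
  mean(pred == y_test)
}

gini_ranking <- function(rf, features) {
  imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  imp <- imp[features]
  # ties broken by feature name order for reproducibility
  features[order(-imp, features)]
}

prepare_xy <- function(data, features, label_col = "label") {
  y <- factor(as.character(data[[label_col]]), levels = CLASS_LEVELS)
  x <- as.data.frame(data[, features, drop = FALSE])
  med <- vapply(x, median, numeric(1), na.rm = TRUE)
  list(x = impute_medians(x, med), y = y, medians = med)
}

#' Backward elimination on one cross-validation fold
#'
#' Starting from all candidate features, repeatedly trains a random
#' forest on the training partition, measures accuracy on the held-out
#' partition, ranks features by mean decrease in Gini index, and drops
#' the least important feature, retraining each iteration until one
#' feature remains.  The feature set of the most accurate classifier is
#' returned (ties resolved toward the smaller set).
#'
#' @param train,test Data frames with a `label` column and the candidate
#'   feature columns.
#' @param candidates Character vector of feature names (>= 2 for an
#'   actual search; a single candidate is returned as-is).
#' @param cfg A [selection_config()].
#' @return List with `subset` (selected feature names) and `trace` (a
#'   tibble of per-iteration feature sets and test accuracies).
#' @export
backward_elimination <- function(train, test, candidates, cfg = selection_config()) {
  if (length(candidates) == 1) {
    return(list(subset = candidates,
                trace = tibble(step = 1L, n_features = 1L,
                               features = list(candidates),
                               accuracy = NA_real_)))
  }
  tr <- prepare_xy(train, candidates)
  te_x <- impute_medians(as.data.frame(test[, candidates, drop = FALSE]),
                         tr$medians)
  te_y <- factor(as.character(test$label), levels = CLASS_LEVELS)
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L,
                                          length(candidates)))
  current <- candidates
  steps <- list()
  i <- 1L
  while (length(current) >= 1) {
    rf <- selection_forest(tr$x[, current, drop = FALSE], tr$y, cfg, seeds[i])
    acc <- forest_accuracy(rf, te_x[, current, drop = FALSE], te_y)
    steps[[i]] <- tibble(step = i, n_features = length(current),
                         features = list(current), accuracy = acc)
    if (length(current) == 1) break
    ranking <- gini_ranking(rf, current)
    current <- setdiff(current, ranking[length(ranking)])
    i <- i + 1L
  }
  trace <- dplyr::bind_rows(steps)
  # highest accuracy; ties -> smaller feature set (later step)
  best <- trace |> arrange(dplyr::desc(.data$accuracy), .data$n_features) |>
    dplyr::slice(1)
  list(subset = best$features[[1]], trace = trace)
}

cv_accuracy <- function(data, features, folds, cfg, seeds) {
  correct <- 0L
  total <- 0L
  for (f in sort(unique(folds))) {
    tr_rows <- folds != f
    tr <- prepare_xy(data[tr_rows, , drop = FALSE], features)
    te_x <- impute_medians(
      as.data.frame(data[!tr_rows, features, drop = FALSE]), tr$medians)
    te_y <- factor(as.character(data$label[!tr_rows]), levels = CLASS_LEVELS)
    rf <- selection_forest(tr$x, tr$y, cfg, seeds[f])
    pred <- predict(rf, te_x)
    correct <- correct + sum(pred == te_y)
    total <- total + length(te_y)
  }
  correct / total
}

#' Forward selection over the non-redundant feature set
#'
#' Seeds the selected set with the top Gini-ranked feature of a forest
#' trained on the full non-redundant set, then repeatedly evaluates
#' adding each remaining feature by family-aware k-fold cross-validation
#' accuracy, accepting the addition with the largest strictly positive
#' gain, and stops when no addition improves the accuracy.
#'
#' @param non_redundant Character vector of candidate feature names.
#' @param data Data frame with `variant_id`, `label`, family information
#'   and the candidate feature columns.
#' @param cfg A [selection_config()].
#' @param folds Optional precomputed fold vector aligned with rows of
#'   `data`; defaults to [family_kfold()] with `cfg$k` folds.
#' @return List with `selected` (ordered character vector) and `trace`
#'   (tibble of accepted steps with CV accuracies, strictly increasing).
#' @export
forward_selection <- function(non_redundant, data, cfg = selection_config(),
                              folds = NULL) {
  stopifnot(length(non_redundant) >= 1)
  data <- as_tibble(data)
  if (is.null(folds)) {
    folds <- family_kfold(data, k = cfg$k, seed = cfg$seed)$fold
  }
  seeds <- with_seed(cfg$seed + 1L,
                     sample.int(.Machine$integer.max - 1L, cfg$k))
  all_xy <- prepare_xy(data, non_redundant)
  seed_rf <- selection_forest(all_xy$x, all_xy$y, cfg, seeds[1])
  selected <- gini_ranking(seed_rf, non_redundant)[1]
  remaining <- setdiff(non_redundant, selected)
  acc <- cv_accuracy(data, selected, folds, cfg, seeds)
  trace <- list(tibble(step = 0L, added = selected, accuracy = acc,
                       features = list(selected)))
  step <- 1L
  while (length(remaining) > 0) {
    cand_acc <- map_dbl(remaining, function(f) {
      cv_accuracy(data, c(selected, f), folds, cfg, seeds)
    })
    gains <- if (cfg$gain == "relative" && acc > 0) (cand_acc - acc) / acc
             else cand_acc - acc
    best <- order(-gains, remaining)[1]
    if (gains[best] <= 0) break
    selected <- c(selected, remaining[best])
    acc <- cand_acc[best]
    trace[[length(trace) + 1L]] <-
      tibble(step = step, added = remaining[best], accuracy = acc,
             features = list(selected))
    remaining <- remaining[-best]
    step <- step + 1L
  }
  list(selected = selected, trace = dplyr::bind_rows(trace))
}

#' Two-step greedy feature selection
#'
#' Step one runs backward elimination independently on each of `k`
#' family-aware cross-validation splits (train on k-1 folds, evaluate on
#' the held-out fold), yielding `k` feature subsets.  Their union forms
#' the non-redundant feature set.  Step two runs forward selection over
#' the non-redundant set with family-aware cross-validation.  Accuracy
#' throughout is binary accuracy over all predictions (no reject
#' option), since selection precedes the reliability gate.
#'
#' @param data Data frame with `variant_id`, `label`, `family_id` (or
#'   `protein_id`) and candidate feature columns.
#' @param candidates Character vector of candidate feature names.
#' @param cfg A [selection_config()].
#' @return A `tricall_selection` object: `selected` (final ordered set),
#'   `non_redundant`, `step1_subsets` (list of k subsets),
#'   `step1_traces`, `forward_trace`, `folds`.
#' @export
run_two_step_selection <- function(data, candidates,
                                   cfg = selection_config()) {
  data <- as_tibble(data)
  fold_tbl <- family_kfold(data, k = cfg$k, seed = cfg$seed)
  folds <- fold_tbl$fold
  step_cfgs <- lapply(seq_len(cfg$k), function(i) {
    cfg2 <- cfg
    cfg2$seed <- cfg$seed + 1000L + i
    cfg2
  })
  step1 <- lapply(sort(unique(folds)), function(f) {
    backward_elimination(data[folds != f, , drop = FALSE],
                         data[folds == f, , drop = FALSE],
                         candidates, step_cfgs[[f]])
  })
  subsets <- lapply(step1, `[[`, "subset")
  non_redundant <- sort(unique(unlist(subsets)))
  fwd <- forward_selection(non_redundant, data, cfg, folds = folds)
  structure(list(selected = fwd$selected, non_redundant = non_redundant,
                 step1_subsets = subsets,
                 step1_traces = lapply(step1, `[[`, "trace"),
                 forward_trace = fwd$trace, folds = fold_tbl,
                 candidates = candidates, config = cfg),
            class = "tricall_selection")
}

#' @export
print.tricall_selection <- function(x, ...) {
  cat("<tricall_selection> ", length(x$selected), " of ",
      length(x$candidates), " candidate features selected:\n  ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy tricall_selection
#' @export
tidy.tricall_selection <- function(x, ...) {
  x$forward_trace |> select("step", "added", "accuracy")
}

#' @method glance tricall_selection
#' @export
glance.tricall_selection <- function(x, ...) {
  tibble(n_candidates = length(x$candidates),
         n_non_redundant = length(x$non_redundant),
         n_selected = length(x$selected),
         final_cv_accuracy = max(x$forward_trace$accuracy))
}

#' Serialise a selection trace as JSON
#'
#' @param x A `tricall_selection`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(x, path) {
  jsonlite::write_json(
    list(selected = x$selected, non_redundant = x$non_redundant,
         step1_subsets = x$step1_subsets,
         forward_trace = dplyr::select(x$forward_trace, -"features")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
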