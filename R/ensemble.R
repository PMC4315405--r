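#' Ensemble configuration
#'
#' Defaults follow the published training recipe: 200 stratified
#' bootstrap samples, a 300-tree random forest per sample, 2 candidate
#' features per split, and a 0.95 reliability confidence level.
#'
#' @param n_bootstrap Number of bootstrap ensemble members.
#' @param n_trees Trees grown in each member forest.
#' @param mtry Features sampled at each split.
#' @param confidence Reliability confidence level in (0, 1); determines
#'   the Chebyshev multiplier `k = 1 / sqrt(1 - confidence)`.
#' @param seed Master seed; every member is seeded deterministically from
#'   it so results are independent of scheduling.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_bootstrap = 200, n_trees = 300, mtry = 2,
                            confidence = 0.95, seed = 1) {
  stopifnot(n_bootstrap >= 1, n_trees >= 1, mtry >= 1)
  if (confidence <= 0 || confidence >= 1) {
    abort("confidence must lie strictly between 0 and 1")
  }
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 confidence = confidence, seed = as.integer(seed)),
            class = "ensemble_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified bootstrap indices
#'
#' Draws, with replacement and separately within each class, a sample of
#' the same size and the same per-class composition as the original
#' labelled data.
#'
#' @param labels Character or factor vector of class labels
#'   (`pathogenic` / `neutral`); both classes must be present.
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @return Integer vector of row indices of length `length(labels)`.
#' @export
stratified_bootstrap <- function(labels, seed) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) {
    abort("stratified bootstrap requires both classes in the data")
  }
  with_seed(seed, {
    idx <- unlist(lapply(sort(classes), function(cl) {
      rows <- which(labels == cl)
      sample(rows, length(rows), replace = TRUE)
    }))
    unname(idx)
  })
}

#' Train the bootstrap random-forest ensemble
#'
#' Fits `n_bootstrap` random forests, each on a stratified bootstrap
#' resample of the training rows, producing a model whose per-variant
#' spread of member probabilities feeds the reliability gate.  Missing
#' feature values are median-imputed (medians learned on the training
#' data), except the GO feature: when some training proteins lack GO
#' annotation, a parallel fallback ensemble trained without the GO column
#' serves GO-missing variants at prediction time, so those predictions
#' rest on the remaining features rather than an imputed GO value.
#'
#' @param data Data frame with a `variant_id` column, a label column, and
#'   numeric feature columns.
#' @param config An [ensemble_config()].
#' @param features Feature column names; default all numeric columns
#'   except `variant_id` and the label.
#' @param label_col Name of the label column (default `"label"`).
#' @param go_feature Name of the GO feature column governed by the
#'   fallback rule, or `NULL`.
#' @param missing `"go_fallback"` (default) or `"impute"` (median-impute
#'   everything, single ensemble).
#' @return A `tricall_ensemble` model object.
#' @export
fit_ensemble <- function(data, config = ensemble_config(), features = NULL,
                         label_col = "label", go_feature = "go_lr",
                         missing = c("go_fallback", "impute")) {
  missing <- arg_match(missing)
  data <- as_tibble(data)
  if (!label_col %in% names(data)) {
    abort(paste0("label column '", label_col, "' not found"))
  }
  labels <- as.character(data[[label_col]])
  if (!all(labels %in% CLASS_LEVELS)) {
    abort("labels must be 'pathogenic' or 'neutral' for training")
  }
  if (length(unique(labels)) < 2) abort("training data must contain both classes")
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        c("variant_id", label_col, "position"))
  }
  if (length(features) < 2) abort("at least 2 features are required")
  x <- as.data.frame(data[, features])
  all_missing <- features[vapply(x, function(v) all(is.na(v)), logical(1))]
  if (length(all_missing) > 0) {
    abort(paste0("feature column(s) entirely missing: ",
                 paste(all_missing, collapse = ", ")))
  }
  medians <- vapply(x, median, numeric(1), na.rm = TRUE)
  y <- factor(labels, levels = CLASS_LEVELS)

  use_fallback <- missing == "go_fallback" && !is.null(go_feature) &&
    go_feature %in% features && anyNA(x[[go_feature]])
  member_seeds <- with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1L,
                                       config$n_bootstrap))

  main_rows <- if (use_fallback) which(!is.na(x[[go_feature]]))
               else seq_len(nrow(x))
  main <- train_members(impute_medians(x[main_rows, , drop = FALSE], medians),
                        y[main_rows], config, member_seeds)
  fallback <- NULL
  if (use_fallback) {
    fb_feats <- setdiff(features, go_feature)
    if (length(fb_feats) >= 2) {
      fallback <- train_members(
        impute_medians(x[, fb_feats, drop = FALSE], medians[fb_feats]),
        y, config, member_seeds + 1L)
    }
  }
  structure(list(members = main, fallback_members = fallback,
                 features = features,
                 fallback_features = if (!is.null(fallback))
                   setdiff(features, go_feature) else NULL,
                 go_feature = go_feature, medians = medians,
                 config = config, classes = CLASS_LEVELS,
                 member_seeds = member_seeds,
                 fingerprint = dataset_fingerprint(data)),
            class = "tricall_ensemble")
}

impute_medians <- function(x, medians) {
  for (nm in names(x)) {
    miss <- is.na(x[[nm]])
    if (any(miss)) x[[nm]][miss] <- medians[[nm]]
  }
  x
}

train_members <- function(x, y, config, member_seeds) {
  lapply(seq_len(config$n_bootstrap), function(b) {
    with_seed(member_seeds[b], {
      idx <- {
        classes <- sort(unique(as.character(y)))
        unlist(lapply(classes, function(cl) {
          rows <- which(as.character(y) == cl)
          sample(rows, length(rows), replace = TRUE)
        }))
      }
      randomForest::randomForest(
        x = x[idx, , drop = FALSE], y = y[idx],
        ntree = config$n_trees,
        mtry = min(config$mtry, ncol(x)))
    })
  })
}

#' @export
print.tricall_ensemble <- function(x, ...) {
  cat("<tricall_ensemble> ", length(x$members), " members x ",
      x$config$n_trees, " trees (mtry ", x$config$mtry, "), ",
      length(x$features), " features",
      if (!is.null(x$fallback_members)) " + GO-fallback ensemble" else "",
      "\n", sep = "")
  invisible(x)
}

#' Per-member pathogenicity probabilities
#'
#' For each query row and each ensemble member, the fraction of that
#' member forest's trees voting pathogenic.
#'
#' @param object A `tricall_ensemble`.
#' @param newdata Data frame carrying the model's feature columns.
#' @param member Optional single member index; if given, a plain numeric
#'   vector for that member is returned.
#' @return Numeric matrix (rows x members) or vector.
#' @export
member_probability <- function(object, newdata, member = NULL) {
  newdata <- as_tibble(newdata)
  x <- as.data.frame(newdata[, object$features])
  x <- impute_medians(x, object$medians)
  members <- object$members
  if (!is.null(member)) members <- members[member]
  probs <- vapply(members, function(rf) {
    p <- predict(rf, x, type = "prob")
    if ("pathogenic" %in% colnames(p)) p[, "pathogenic"] else
      rep(0, nrow(x))
  }, numeric(nrow(x)))
  probs <- matrix(probs, nrow = nrow(x))
  if (!is.null(member) && length(member) == 1) return(drop(probs))
  probs
}

fallback_probability <- function(object, newdata) {
  x <- as.data.frame(as_tibble(newdata)[, object$fallback_features])
  x <- impute_medians(x, object$medians[object$fallback_features])
  probs <- vapply(object$fallback_members, function(rf) {
    p <- predict(rf, x, type = "prob")
    if ("pathogenic" %in% colnames(p)) p[, "pathogenic"] else rep(0, nrow(x))
  }, numeric(nrow(x)))
  matrix(probs, nrow = nrow(x))
}

#' Tri-class call from a Chebyshev reliability interval
#'
#' The bootstrap probabilities of a variant have mean `mu` and standard
#' deviation `sigma`; by Chebyshev's inequality at least a fraction
#' `confidence` of them lie within `k * sigma` of `mu` with
#' `k = 1 / sqrt(1 - confidence)`.  When the interval `mu +/- k sigma`
#' excludes 0.5 the prediction is reliable: pathogenic if the whole
#' interval is above 0.5, neutral if below.  Otherwise the variant is
#' rejected as unknown.  Inequalities are strict, so an interval endpoint
#' exactly at 0.5 rejects.
#'
#' @param mu Mean member probability in `[0, 1]` (vectorised).
#' @param sigma Standard deviation of member probabilities (>= 0).
#' @param confidence Confidence level in (0, 1); 0.95 gives
#'   `k = sqrt(20) ~ 4.47`.
#' @return Character vector: `"pathogenic"`, `"neutral"` or `"unknown"`.
#' @export
chebyshev_classify <- function(mu, sigma, confidence = 0.95) {
  if (any(confidence <= 0 | confidence >= 1)) {
    abort("confidence must lie strictly between 0 and 1")
  }
  k <- 1 / sqrt(1 - confidence)
  lower <- mu - k * sigma
  upper <- mu + k * sigma
  dplyr::case_when(lower > 0.5 ~ "pathogenic",
                   upper < 0.5 ~ "neutral",
                   TRUE ~ "unknown")
}

#' Predict tri-class pathogenicity calls
#'
#' Computes per-member probabilities for each query variant, optionally
#' merges a functional-annotation prior into every member probability by
#' the noisy-OR rule (so the reliability interval itself moves, not just
#' its centre), and gates the mean/spread through the Chebyshev
#' reliability interval.  Variants missing the GO feature are served by
#' the fallback ensemble when one was trained.
#'
#' @param object A `tricall_ensemble` from [fit_ensemble()].
#' @param newdata Data frame with `variant_id` and the model's feature
#'   columns.
#' @param annotation_pa Optional annotation priors: either a numeric
#'   vector aligned with `newdata` rows or the tibble returned by
#'   [annotate_variants()] (matched by `variant_id`); `NA` means no
#'   annotation.
#' @param confidence Reliability confidence level; defaults to the
#'   trained configuration's.
#' @param combine `"per_member"` (default; the prior passes through each
#'   member probability before `mu`/`sigma` are computed) or `"mean"`
#'   (combine the mean only).
#' @param ... Unused.
#' @return A tibble with one row per query variant: `variant_id`, `mu`,
#'   `sigma`, `k`, `lower`, `upper`, `call` (tri-class), `binary_call`
#'   (threshold 0.5 on `mu`, the no-reject fallback), `combined`,
#'   `model_used`.
#' @export
predict.tricall_ensemble <- function(object, newdata, annotation_pa = NULL,
                                     confidence = NULL,
                                     combine = c("per_member", "mean"),
                                     ...) {
  combine <- arg_match(combine)
  confidence <- confidence %||% object$config$confidence
  newdata <- as_tibble(newdata)
  if (!"variant_id" %in% names(newdata)) {
    newdata$variant_id <- paste0("q", seq_len(nrow(newdata)))
  }
  pa <- resolve_pa(annotation_pa, newdata)

  probs <- member_probability(object, newdata)
  model_used <- rep("main", nrow(newdata))
  if (!is.null(object$fallback_members) &&
      object$go_feature %in% names(newdata)) {
    miss_go <- is.na(newdata[[object$go_feature]])
    if (any(miss_go)) {
      fb <- fallback_probability(object, newdata[miss_go, , drop = FALSE])
      probs[miss_go, ] <- fb
      model_used[miss_go] <- "fallback"
    }
  }

  has_pa <- !is.na(pa)
  if (combine == "per_member" && any(has_pa)) {
    probs[has_pa, ] <- combine_probability(pa[has_pa], probs[has_pa, ,
                                                             drop = FALSE])
  }
  mu <- rowMeans(probs)
  sigma <- apply(probs, 1, sd)
  if (ncol(probs) == 1) sigma <- rep(0, nrow(probs))
  if (combine == "mean" && any(has_pa)) {
    mu[has_pa] <- combine_probability(pa[has_pa], mu[has_pa])
  }
  k <- 1 / sqrt(1 - confidence)
  tibble(variant_id = newdata$variant_id, mu = mu, sigma = sigma, k = k,
         lower = mu - k * sigma, upper = mu + k * sigma,
         call = chebyshev_classify(mu, sigma, confidence),
         binary_call = ifelse(mu > 0.5, "pathogenic", "neutral"),
         combined = has_pa, model_used = model_used)
}

resolve_pa <- function(annotation_pa, newdata) {
  if (is.null(annotation_pa)) return(rep(NA_real_, nrow(newdata)))
  if (is.data.frame(annotation_pa)) {
    return(annotation_pa$pa[match(newdata$variant_id,
                                  annotation_pa$variant_id)])
  }
  rep_len(as.numeric(annotation_pa), nrow(newdata))
}

#' @method tidy tricall_ensemble
#' @export
tidy.tricall_ensemble <- function(x, ...) {
  imp <- Reduce(`+`, lapply(x$members, function(rf) {
    randomForest::importance(rf)[x$features, "MeanDecreaseGini"]
  })) / length(x$members)
  tibble(feature = x$features, mean_decrease_gini = unname(imp)) |>
    arrange(dplyr::desc(.data$mean_decrease_gini))
}

#' @method glance tricall_ensemble
#' @export
glance.tricall_ensemble <- function(x, ...) {
  oob <- mean(vapply(x$members, function(rf) {
    rf$err.rate[nrow(rf$err.rate), "OOB"]
  }, numeric(1)))
  tibble(n_members = length(x$members), n_trees = x$config$n_trees,
         mtry = x$config$mtry, n_features = length(x$features),
         confidence = x$config$confidence, mean_oob_error = oob,
         has_fallback = !is.null(x$fallback_members))
}

#' Persist / load an ensemble model directory
#'
#' The model is stored as a directory: `config.json` (configuration and
#' feature manifest) plus serialized member forests.  Loading verifies
#' the manifest; [predict.tricall_ensemble()] then checks feature columns
#' against it.
#'
#' @param object A `tricall_ensemble`.
#' @param dir Directory path.
#' @return `dir` (write) or the model (read).
#' @export
write_ensemble <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(features = object$features,
                   fallback_features = object$fallback_features,
                   go_feature = object$go_feature,
                   medians = as.list(object$medians),
                   config = unclass(object$config),
                   fingerprint = object$fingerprint)
  jsonlite::write_json(manifest, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(object, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  object <- readRDS(file.path(dir, "model.rds"))
  if (!identical(sort(manifest$features), sort(object$features))) {
    abort("model manifest does not match serialized members")
  }
  object
}
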