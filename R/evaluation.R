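#' Six performance measures, nMCC and OPM from a confusion table
#'
#' Computes positive and negative predictive value, sensitivity,
#' specificity, accuracy, the Matthews correlation coefficient, the
#' normalized MCC `nMCC = (1 + MCC) / 2`, and the overall performance
#' measure `OPM = (PPV + NPV)(Sens + Spec)(Acc + nMCC) / 8` (the
#' normalized volume of the performance cuboid).  TP and TN are the
#' correctly predicted pathogenic and neutral cases; FP and FN the
#' misclassified neutral and pathogenic cases.
#'
#' A measure whose denominator is zero is undefined and reported as
#' `NA`; OPM is `NA` whenever any constituent is.
#'
#' @param tp,tn,fp,fn Non-negative counts (vectorised).
#' @return A tibble with columns `tp`, `tn`, `fp`, `fn`, `ppv`, `npv`,
#'   `sensitivity`, `specificity`, `accuracy`, `mcc`, `nmcc`, `opm`.
#' @export
#' @examples
#' confusion_metrics(6375, 7860, 805, 778)
confusion_metrics <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) abort("confusion counts must be >= 0")
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ifelse(mcc_den > 0, (tp * tn - fp * fn) / mcc_den, NA_real_)
  nmcc <- (1 + mcc) / 2
  opm <- (ppv + npv) * (sens + spec) * (acc + nmcc) / 8
  tibble(tp = tp, tn = tn, fp = fp, fn = fn, ppv = ppv, npv = npv,
         sensitivity = sens, specificity = spec, accuracy = acc,
         mcc = mcc, nmcc = nmcc, opm = opm)
}

#' OPM from the six performance scores
#'
#' The overall performance measure is the normalized volume of the
#' performance cuboid: `(PPV + NPV)(Sens + Spec)(Acc + nMCC) / 8` with
#' `nMCC = (1 + MCC) / 2`.  Useful for recomputing OPM from published
#' score tables.
#'
#' @param ppv,npv,sensitivity,specificity,accuracy Scores in `[0, 1]`.
#' @param mcc Matthews correlation coefficient in `[-1, 1]`.
#' @return The OPM, in `[0, 1]`.
#' @export
#' @examples
#' opm_from_scores(0.89, 0.91, 0.89, 0.91, 0.90, 0.80)  # ~0.73
opm_from_scores <- function(ppv, npv, sensitivity, specificity, accuracy,
                            mcc) {
  in01 <- c(ppv, npv, sensitivity, specificity, accuracy)
  if (any(in01 < 0 | in01 > 1) || any(mcc < -1 | mcc > 1)) {
    abort("scores out of range: the five rates must be in [0,1], MCC in [-1,1]")
  }
  nmcc <- (1 + mcc) / 2
  (ppv + npv) * (sensitivity + specificity) * (accuracy + nmcc) / 8
}

#' Evaluate tri-class predictions against labels
#'
#' Builds the confusion table over reliably classified variants (calls of
#' pathogenic or neutral); unknown calls are excluded from the table but
#' stay in the denominator of coverage, the proportion of submitted
#' variants receiving a class call.  When the predictions carry a
#' `binary_call` column the all-variant no-reject confusion table is
#' reported alongside (the parenthesised convention of published score
#' tables).
#'
#' @param predictions Tibble with `variant_id`, `call`, and optionally
#'   `binary_call` (e.g. from [predict.tricall_ensemble()]).
#' @param labels Either a vector of labels aligned with `predictions`
#'   rows, or a data frame with `variant_id` and `label` columns.
#' @return A `tricall_eval` object; `tidy()` returns one metric row per
#'   subset (`reliable`, `all`), `glance()` a one-row summary.
#' @export
evaluate_predictions <- function(predictions, labels) {
  predictions <- as_tibble(predictions)
  if (is.data.frame(labels)) {
    lab <- labels$label[match(predictions$variant_id, labels$variant_id)]
  } else {
    if (length(labels) != nrow(predictions)) {
      abort("labels length does not match the number of predictions")
    }
    lab <- as.character(labels)
  }
  if (anyNA(lab)) abort("every prediction needs a pathogenic/neutral label")
  call <- as.character(predictions$call)
  classified <- call %in% c("pathogenic", "neutral")
  ct <- count_confusion(call[classified], lab[classified])
  coverage <- mean(classified)
  fallback <- NULL
  if ("binary_call" %in% names(predictions)) {
    fallback <- count_confusion(as.character(predictions$binary_call), lab)
  }
  structure(list(reliable = ct, fallback = fallback, coverage = coverage,
                 n = length(call), n_classified = sum(classified)),
            class = "tricall_eval")
}

count_confusion <- function(pred, lab) {
  list(tp = sum(pred == "pathogenic" & lab == "pathogenic"),
       tn = sum(pred == "neutral" & lab == "neutral"),
       fp = sum(pred == "pathogenic" & lab == "neutral"),
       fn = sum(pred == "neutral" & lab == "pathogenic"))
}

#' @export
print.tricall_eval <- function(x, ...) {
  cat("<tricall_eval> ", x$n_classified, "/", x$n,
      " variants classified (coverage ",
      format(round(x$coverage, 3)), ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @method tidy tricall_eval
#' @export
tidy.tricall_eval <- function(x, ...) {
  rows <- list(with(x$reliable,
                    mutate(confusion_metrics(tp, tn, fp, fn),
                           subset = "reliable", coverage = x$coverage)))
  if (!is.null(x$fallback)) {
    rows <- c(rows, list(with(x$fallback,
                              mutate(confusion_metrics(tp, tn, fp, fn),
                                     subset = "all", coverage = 1))))
  }
  dplyr::bind_rows(rows) |>
    select("subset", dplyr::everything())
}

#' @method glance tricall_eval
#' @export
glance.tricall_eval <- function(x, ...) {
  m <- with(x$reliable, confusion_metrics(tp, tn, fp, fn))
  tibble(n = x$n, n_classified = x$n_classified, coverage = x$coverage,
         accuracy = m$accuracy, mcc = m$mcc, opm = m$opm)
}

#' Performance-cuboid geometry
#'
#' Represents the six performance scores as the distances of the six
#' faces of an axis-aligned cuboid from the origin: +x PPV, -x NPV,
#' +y sensitivity, -y specificity, +z accuracy, -z nMCC.  The cuboid's
#' volume divided by 8 (the volume of the perfect classifier's unit-face
#' cube) equals the OPM.
#'
#' @param scores A one-row data frame with columns `ppv`, `npv`,
#'   `sensitivity`, `specificity`, `accuracy` and either `nmcc` or `mcc`
#'   (e.g. a row of [confusion_metrics()]).
#' @return A `tricall_cuboid`: list with `faces` (named length-6 vector),
#'   `vertices` (8 x 3 matrix), `volume` and `opm` (`volume / 8`).
#' @export
cuboid_geometry <- function(scores) {
  scores <- as.list(scores)
  if (is.null(scores$nmcc)) {
    if (is.null(scores$mcc)) abort("scores need nmcc or mcc")
    scores$nmcc <- (1 + scores$mcc) / 2
  }
  need <- c("ppv", "npv", "sensitivity", "specificity", "accuracy", "nmcc")
  vals <- unlist(scores[need])
  if (anyNA(vals)) abort("cuboid geometry needs all six scores defined")
  faces <- setNames(as.numeric(vals), need)
  xs <- c(-faces[["npv"]], faces[["ppv"]])
  ys <- c(-faces[["specificity"]], faces[["sensitivity"]])
  zs <- c(-faces[["nmcc"]], faces[["accuracy"]])
  vertices <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  volume <- diff(xs) * diff(ys) * diff(zs)
  structure(list(faces = faces, vertices = vertices, volume = volume,
                 opm = volume / 8),
            class = "tricall_cuboid")
}

#' @export
print.tricall_cuboid <- function(x, ...) {
  cat("<tricall_cuboid> volume ", format(x$volume), ", OPM ",
      format(x$opm), "\n", sep = "")
  invisible(x)
}

#' Write cuboid vertices for 3-D plotting
#'
#' @param cuboid A `tricall_cuboid`.
#' @param path Output TSV path (columns x, y, z, one vertex per row).
#' @return `path`, invisibly.
#' @export
write_cuboid_vertices <- function(cuboid, path) {
  readr::write_tsv(as_tibble(cuboid$vertices), path, progress = FALSE)
  invisible(path)
}
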