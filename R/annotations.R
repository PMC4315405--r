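#' Select informative functional-site annotation types
#'
#' For each annotation type, computes the proportion of training variants
#' falling inside any site of that type that are pathogenic (`pa`).  A
#' type is retained when its majority-class proportion,
#' `max(pa, 1 - pa)`, exceeds `threshold` (default 0.85): such strongly
#' class-biased site types carry usable prior information.  Types with no
#' overlapping training variant are excluded with a warning.
#'
#' @param training Labelled variant tibble.
#' @param sites Site annotation tibble (`protein_id`, `start`, `end`,
#'   `type`), one-based inclusive intervals.
#' @param threshold Majority-class proportion that must be exceeded.
#' @return A `tricall_annotation_model`: list with `types` (tibble:
#'   `type`, `pa`, `n_pathogenic`, `n_neutral`, `selected`) and
#'   `threshold`.
#' @export
select_annotation_types <- function(training, sites, threshold = 0.85) {
  if (!"label" %in% names(training)) abort("training variants must be labelled")
  training <- dplyr::filter(training, .data$label %in% CLASS_LEVELS)
  sites <- validate_sites(sites)
  all_types <- unique(sites$type)
  hits <- overlap_pairs(training, sites)
  per_type <- hits |>
    distinct(.data$variant_id, .data$type, .keep_all = TRUE) |>
    group_by(.data$type) |>
    summarise(n_pathogenic = sum(.data$label == "pathogenic"),
              n_neutral = sum(.data$label == "neutral"), .groups = "drop")
  empty <- setdiff(all_types, per_type$type)
  if (length(empty) > 0) {
    warn(paste0("annotation type(s) with no overlapping training variant ",
                "excluded: ", paste(empty, collapse = ", ")))
  }
  types <- per_type |>
    mutate(pa = .data$n_pathogenic / (.data$n_pathogenic + .data$n_neutral),
           selected = pmax(.data$pa, 1 - .data$pa) > threshold) |>
    select("type", "pa", "n_pathogenic", "n_neutral", "selected") |>
    arrange(.data$type)
  structure(list(types = types, threshold = threshold),
            class = "tricall_annotation_model")
}

overlap_pairs <- function(variants, sites) {
  joined <- dplyr::inner_join(
    as_tibble(variants)[, c("variant_id", "protein_id", "position",
                            intersect("label", names(variants)))],
    sites, by = "protein_id", relationship = "many-to-many")
  dplyr::filter(joined, .data$position >= .data$start,
                .data$position <= .data$end)
}

#' @export
print.tricall_annotation_model <- function(x, ...) {
  sel <- dplyr::filter(x$types, .data$selected)
  cat("<tricall_annotation_model> ", nrow(sel), " of ", nrow(x$types),
      " annotation types selected at threshold ", x$threshold, "\n", sep = "")
  print(sel)
  invisible(x)
}

#' @method tidy tricall_annotation_model
#' @export
tidy.tricall_annotation_model <- function(x, ...) x$types

#' Serialise / load an annotation model as JSON
#'
#' @param model A `tricall_annotation_model`.
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_annotation_model <- function(model, path) {
  jsonlite::write_json(list(threshold = model$threshold, types = model$types),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation_model
#' @export
read_annotation_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(types = as_tibble(x$types), threshold = x$threshold),
            class = "tricall_annotation_model")
}

#' Noisy-OR combination of an annotation prior with a forest probability
#'
#' Combines the annotation-derived prior probability of pathogenicity
#' `pa` with the random-forest probability `prf` as
#' `pc = pa + prf - pa * prf`.  The result is at least `max(pa, prf)`
#' and at most 1; `pa = 0` leaves `prf` unchanged and `pa = 1` is
#' absorbing.
#'
#' @param pa,prf Probabilities in `[0, 1]` (vectorised, recycled).
#' @return Combined probability vector.
#' @export
combine_probability <- function(pa, prf) {
  if (any(pa < 0 | pa > 1, na.rm = TRUE) ||
      any(prf < 0 | prf > 1, na.rm = TRUE)) {
    abort("combine_probability inputs must lie in [0, 1]")
  }
  pa + prf - pa * prf
}

#' Annotation prior for variants
#'
#' Looks up, for each variant, the selected annotation type(s) whose site
#' intervals contain the variant position and returns that type's class
#' prior `pa`.  When several selected types overlap a position the most
#' informative one — the `pa` farthest from 0.5 — is used by default.
#'
#' @param variants Variant tibble.
#' @param sites Site annotation tibble.
#' @param model A `tricall_annotation_model`.
#' @param multiple `"most_informative"` (default) or `"first"` (first
#'   matching site in table order).
#' @return A tibble `variant_id`, `annotation_type`, `pa` (`NA` where no
#'   selected site overlaps).
#' @export
annotate_variants <- function(variants, sites, model,
                              multiple = c("most_informative", "first")) {
  multiple <- arg_match(multiple)
  sel <- dplyr::filter(model$types, .data$selected)
  out <- tibble(variant_id = variants$variant_id,
                annotation_type = NA_character_, pa = NA_real_)
  if (nrow(sel) == 0) return(out)
  sites <- dplyr::filter(validate_sites(sites), .data$type %in% sel$type)
  hits <- overlap_pairs(variants, sites) |>
    distinct(.data$variant_id, .data$type) |>
    left_join(sel[, c("type", "pa")], by = "type")
  if (nrow(hits) == 0) return(out)
  picked <- if (multiple == "most_informative") {
    hits |>
      group_by(.data$variant_id) |>
      arrange(dplyr::desc(abs(.data$pa - 0.5)), .data$type,
              .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
  } else {
    hits |> group_by(.data$variant_id) |> dplyr::slice(1) |> ungroup()
  }
  i <- match(picked$variant_id, out$variant_id)
  out$annotation_type[i] <- picked$type
  out$pa[i] <- picked$pa
  out
}
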