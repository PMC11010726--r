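#' Tumor-to-normal ratio of a fluorescence channel
#'
#' Computes the mean fluorescence intensity over the tumor mask and over the
#' normal-brain mask and returns their ratio, the tumor-to-normal ratio
#' (TNR) — the primary contrast metric when fluorescent agents are compared.
#' Means are arithmetic over mask pixels; no background subtraction is
#' applied. If a `tissue_mask` is supplied the normal ROI is first
#' intersected with it.
#'
#' @param channel Intensity matrix (AU).
#' @param tumor_mask,normal_mask Disjoint, non-empty [region_mask]s (or
#'   logical matrices) matching the channel's shape.
#' @param tissue_mask Optional [region_mask] of tissue pixels.
#' @param section_id,animal_id,agent Identifiers carried into the result.
#' @return A `tnr_result`: list with `tumor_mean`, `normal_mean`, `tnr`,
#'   `tumor_pixels`, `normal_pixels` and the identifiers.
#' @examples
#' ch <- matrix(1, 10, 10); ch[2:4, 2:4] <- 30
#' tm <- nm <- matrix(FALSE, 10, 10); tm[2:4, 2:4] <- TRUE; nm[6:8, 6:8] <- TRUE
#' compute_tnr(ch, tm, nm)$tnr
#' @export
compute_tnr <- function(channel, tumor_mask, normal_mask,
                        tissue_mask = NULL,
                        section_id = NA_character_,
                        animal_id = NA_character_,
                        agent = NA_character_) {
  tpx <- mask_pixels(tumor_mask)
  npx <- mask_pixels(normal_mask)
  if (!is.matrix(channel) || !is.numeric(channel)) {
    fgs_abort("channel must be a numeric matrix", "fgs_parameter_error")
  }
  if (!identical(dim(channel), dim(tpx)) ||
      !identical(dim(channel), dim(npx))) {
    fgs_abort("mask shapes must match the channel", "fgs_geometry_error")
  }
  if (!is.null(tissue_mask)) npx <- npx & mask_pixels(tissue_mask)
  if (!any(tpx) || !any(npx)) {
    fgs_abort("tumor and normal masks must each contain at least one pixel",
              "fgs_mask_error")
  }
  if (any(tpx & npx)) {
    fgs_abort("tumor and normal masks overlap", "fgs_mask_error")
  }
  tumor_mean <- mean(channel[tpx])
  normal_mean <- mean(channel[npx])
  if (normal_mean <= 0) {
    fgs_abort("normal-region mean is not positive; TNR is undefined",
              "fgs_quantification_error")
  }
  new_tnr_result(tumor_mean, normal_mean, sum(tpx), sum(npx),
                 section_id, animal_id, agent)
}

new_tnr_result <- function(tumor_mean, normal_mean, tumor_pixels,
                           normal_pixels, section_id = NA_character_,
                           animal_id = NA_character_, agent = NA_character_) {
  structure(list(tumor_mean = tumor_mean, normal_mean = normal_mean,
                 tnr = tumor_mean / normal_mean,
                 tumor_pixels = as.integer(tumor_pixels),
                 normal_pixels = as.integer(normal_pixels),
                 section_id = section_id, animal_id = animal_id,
                 agent = agent),
            class = "tnr_result")
}

#' @export
print.tnr_result <- function(x, ...) {
  id <- paste(stats::na.omit(c(x$animal_id, x$section_id, x$agent)),
              collapse = " / ")
  if (nzchar(id)) id <- paste0("  [", id, "]")
  cat(sprintf("TNR = %.4g  (tumor %.4g AU over %d px; normal %.4g AU over %d px)%s\n",
              x$tnr, x$tumor_mean, x$tumor_pixels,
              x$normal_mean, x$normal_pixels, id))
  invisible(x)
}

#' @export
as.data.frame.tnr_result <- function(x, ...) {
  data.frame(section_id = x$section_id, animal_id = x$animal_id,
             agent = x$agent, tumor_mean = x$tumor_mean,
             normal_mean = x$normal_mean, tnr = x$tnr,
             tumor_px = x$tumor_pixels, normal_px = x$normal_pixels,
             stringsAsFactors = FALSE)
}

#' Normalize a channel to the normal-brain mean
#'
#' Divides every pixel by the mean intensity over the normal-brain mask, so
#' the normal region has mean 1 and tumor pixels read directly as
#' fold-over-normal. Idempotent: normalizing an already-normalized image
#' changes nothing.
#'
#' @inheritParams compute_tnr
#' @return A dimensionless matrix of the channel's shape.
#' @export
normalize_to_normal <- function(channel, normal_mask) {
  npx <- mask_pixels(normal_mask)
  if (!identical(dim(channel), dim(npx))) {
    fgs_abort("mask shape must match the channel", "fgs_geometry_error")
  }
  if (!any(npx)) fgs_abort("normal mask is empty", "fgs_mask_error")
  m <- mean(channel[npx])
  if (m <= 0) {
    fgs_abort("normal-region mean is not positive", "fgs_quantification_error")
  }
  channel / m
}

#' Coefficient of variation of per-section ratios
#'
#' Sample standard deviation divided by mean, used to quantify between-
#' section consistency of the TNR within one animal.
#'
#' @param per_section_tnrs Numeric vector of at least two positive ratios.
#' @return The coefficient of variation (dimensionless fraction).
#' @examples
#' section_cv(c(8, 12))  # 0.2828...
#' @export
section_cv <- function(per_section_tnrs) {
  x <- as.numeric(per_section_tnrs)
  if (length(x) < 2L) {
    fgs_abort("need at least two section values for a CV", "fgs_input_error")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    fgs_abort("section TNRs must be positive and finite", "fgs_input_error")
  }
  sd(x) / mean(x)
}

#' Weight-normalized homogenate tumor-to-normal ratio
#'
#' Spectrofluorimetric homogenate readings are normalized to the weight of
#' the tissue sample; the TNR of an animal is the tumor per-mg fluorescence
#' divided by the normal per-mg fluorescence. Normalization to a different
#' denominator column (e.g. total protein, which gives similar results) is
#' available via `denominator`.
#'
#' @param records Data frame as produced by [generate_homogenates()]:
#'   columns `animal_id`, `tissue`, `fluorescence_au` and the denominator
#'   column.
#' @param animal_id Animal whose ratio to compute.
#' @param denominator Name of the normalization column (default
#'   `"weight_mg"`).
#' @return The animal's TNR (dimensionless).
#' @examples
#' h <- data.frame(animal_id = "a1", tissue = c("tumor", "normal"),
#'                 fluorescence_au = c(3000, 200), weight_mg = c(10, 20))
#' homogenate_tnr(h, "a1")  # 30
#' @export
homogenate_tnr <- function(records, animal_id, denominator = "weight_mg") {
  if (!all(c("animal_id", "tissue", "fluorescence_au", denominator) %in%
           names(records))) {
    fgs_abort("records lack the required homogenate columns",
              "fgs_input_error")
  }
  rows <- records[records$animal_id == animal_id, , drop = FALSE]
  tum <- rows[rows$tissue == "tumor", , drop = FALSE]
  nor <- rows[rows$tissue == "normal", , drop = FALSE]
  if (nrow(tum) != 1L || nrow(nor) != 1L) {
    fgs_abort(sprintf(
      "animal '%s' must have exactly one tumor and one normal record",
      animal_id), "fgs_input_error")
  }
  wt <- tum[[denominator]]
  wn <- nor[[denominator]]
  if (!is.finite(wt) || !is.finite(wn) || wt <= 0 || wn <= 0) {
    fgs_abort("normalization denominators must be strictly positive",
              "fgs_input_error")
  }
  (tum$fluorescence_au / wt) / (nor$fluorescence_au / wn)
}

#' Stained-to-unstained mean fluorescence intensity ratio
#'
#' Quantifies probe uptake of a cell population as the ratio of the mean
#' fluorescence intensity (MFI) of stained cells to that of unstained cells.
#'
#' @param stained_mfi,unstained_mfi MFI values (AU); `unstained_mfi` must be
#'   positive.
#' @return The MFI ratio.
#' @export
mfi_ratio <- function(stained_mfi, unstained_mfi) {
  if (!is_scalar_num(stained_mfi) || !is_scalar_num(unstained_mfi) ||
      unstained_mfi <= 0) {
    fgs_abort("unstained MFI must be a positive scalar", "fgs_input_error")
  }
  stained_mfi / unstained_mfi
}

#' Normalize ex-vivo fragment fluorescence to the reference tissue
#'
#' Divides each fragment's fluorescence by the mean fluorescence of the
#' reference group (healthy mouse brain processed alongside the human
#' material) within the same experiment and timepoint. This removes
#' between-experiment scale differences: two experiments with different
#' reference levels but identical within-experiment ratios yield identical
#' normalized values, and the reference group's normalized mean is 1.
#'
#' @param fragments Data frame as produced by [generate_exvivo()].
#' @param experiment_id Optional single experiment to normalize; default all.
#' @return The input rows (restricted to `experiment_id` if given) with an
#'   added `normalized_fluorescence` column.
#' @export
normalize_exvivo <- function(fragments, experiment_id = NULL) {
  need <- c("sample_id", "group", "timepoint_min", "fluorescence_au",
            "experiment_id")
  if (!all(need %in% names(fragments))) {
    fgs_abort("fragments lack the required ex-vivo columns", "fgs_input_error")
  }
  if (!is.null(experiment_id)) {
    fragments <- fragments[fragments$experiment_id %in% experiment_id, ,
                           drop = FALSE]
  }
  if (nrow(fragments) == 0L) {
    fgs_abort("no fragments to normalize", "fgs_input_error")
  }
  key <- interaction(fragments$experiment_id, fragments$timepoint_min,
                     drop = TRUE)
  out <- fragments
  out$normalized_fluorescence <- NA_real_
  for (k in levels(key)) {
    sel <- key == k
    ref <- fragments$group[sel] == "reference"
    if (!any(ref)) {
      fgs_abort(sprintf(
        "experiment/timepoint group '%s' has no reference fragment", k),
        "fgs_input_error")
    }
    ref_mean <- mean(fragments$fluorescence_au[sel][ref])
    if (ref_mean <= 0) {
      fgs_abort("reference mean is not positive", "fgs_quantification_error")
    }
    out$normalized_fluorescence[sel] <-
      fragments$fluorescence_au[sel] / ref_mean
  }
  out
}

#' Fold difference between two groups
#'
#' Ratio of group means, e.g. GBM over PRE probe activation at the final
#' incubation timepoint.
#'
#' @param group_a_values,group_b_values Non-empty vectors of positive values.
#' @return `mean(group_a) / mean(group_b)`.
#' @export
fold_difference <- function(group_a_values, group_b_values) {
  a <- as.numeric(group_a_values)
  b <- as.numeric(group_b_values)
  if (length(a) == 0L || length(b) == 0L) {
    fgs_abort("both groups must be non-empty", "fgs_input_error")
  }
  if (any(!is.finite(c(a, b))) || any(c(a, b) <= 0)) {
    fgs_abort("group values must be positive and finite", "fgs_input_error")
  }
  mean(a) / mean(b)
}

#' Aggregate per-section TNRs to one value per animal
#'
#' When multiple sections exist per animal, the per-animal TNR is by default
#' the mean of the per-section TNRs, so each section is one observation (and
#' the between-section CV is meaningful). Alternatively, `"pooled"` merges
#' all sections' pixels via pixel-count-weighted means before taking the
#' ratio.
#'
#' @param results Data frame of per-section rows (see
#'   [as.data.frame.tnr_result()]): columns `animal_id`, `tnr`,
#'   `tumor_mean`, `normal_mean`, `tumor_px`, `normal_px`.
#' @param method `"mean"` (default) or `"pooled"`.
#' @return Data frame with one row per animal: `animal_id`, `tnr`,
#'   `n_sections`.
#' @export
aggregate_tnr <- function(results, method = c("mean", "pooled")) {
  method <- match.arg(method)
  ids <- unique(results$animal_id)
  rows <- lapply(ids, function(id) {
    r <- results[results$animal_id == id, , drop = FALSE]
    tnr <- if (method == "mean") {
      mean(r$tnr)
    } else {
      sum(r$tumor_mean * r$tumor_px) / sum(r$tumor_px) /
        (sum(r$normal_mean * r$normal_px) / sum(r$normal_px))
    }
    data.frame(animal_id = id, tnr = tnr, n_sections = nrow(r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
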