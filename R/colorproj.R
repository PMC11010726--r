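#' Discriminative RGB-to-grayscale projection for PPIX images
#'
#' Protoporphyrin IX fluorescence under blue light appears as a red-pink
#' color over a blue tissue background; tumor and background may differ in
#' hue more than in luminance, so a fixed luminance conversion wastes the
#' contrast. These functions implement the discriminative alternative: a
#' unit RGB projection vector chosen to maximize the separation between the
#' median tumor color and the median healthy-tissue color, applied as a
#' scalar product to convert RGB images to a single grayscale channel on
#' which the TNR is computed.
#'
#' @param v Numeric 3-vector of projection weights (need not be normalized;
#'   it is scaled to unit Euclidean norm).
#' @return `projection_vector()` returns an object of class
#'   `projection_vector`: a unit-norm numeric 3-vector.
#' @name colorproj
NULL

#' @rdname colorproj
#' @export
projection_vector <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3L || any(!is.finite(v))) {
    fgs_abort("a projection vector has three finite components",
              "fgs_parameter_error")
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    fgs_abort("a projection vector cannot be the zero vector",
              "fgs_parameter_error")
  }
  structure(v / nrm, class = "projection_vector")
}

#' @export
print.projection_vector <- function(x, ...) {
  cat(sprintf("<projection_vector> (R, G, B) = (%.4f, %.4f, %.4f)\n",
              x[1], x[2], x[3]))
  invisible(x)
}

#' Channel-wise median color of a masked region
#'
#' The marginal per-channel median of the RGB values inside a mask; the
#' robust color summary used to fit projection vectors. For even pixel
#' counts the midpoint (mean of the two central order statistics) is used.
#'
#' @param rgb H x W x 3 array with components in `[0, 1]`.
#' @param mask A [region_mask] or logical matrix.
#' @return Numeric 3-vector.
#' @export
median_color <- function(rgb, mask) {
  px <- mask_pixels(mask)
  if (!identical(dim(rgb)[1:2], dim(px))) {
    fgs_abort("mask shape must match the image", "fgs_geometry_error")
  }
  if (!any(px)) fgs_abort("mask is empty", "fgs_mask_error")
  vapply(1:3, function(k) median(rgb[, , k][px]), numeric(1))
}

#' Optimal projection vector for a tumor/normal median-color pair
#'
#' The unit vector `v` maximizing the absolute difference between the
#' projected median colors, `|v . m_tumor - v . m_normal|`, with the sign
#' fixed so the tumor median projects higher. Under the unit-norm
#' constraint the maximizer is the normalized median difference,
#' `v = (m_tumor - m_normal) / ||m_tumor - m_normal||`.
#'
#' @param median_tumor,median_normal Median RGB 3-vectors (see
#'   [median_color()]); must differ.
#' @param nonnegative If `TRUE`, restrict `v` to non-negative components:
#'   negative components of the unconstrained solution are clamped to zero
#'   before renormalization (the active-set solution of the constrained
#'   problem).
#' @return A [projection_vector()].
#' @examples
#' optimal_projection(c(0.80, 0.20, 0.24), c(0.16, 0.16, 0.47))
#' @export
optimal_projection <- function(median_tumor, median_normal,
                               nonnegative = FALSE) {
  mt <- as.numeric(median_tumor)
  mn <- as.numeric(median_normal)
  if (length(mt) != 3L || length(mn) != 3L) {
    fgs_abort("median colors must be 3-vectors", "fgs_parameter_error")
  }
  d <- mt - mn
  if (all(d == 0)) {
    fgs_abort("tumor and normal median colors are identical: no separating projection exists",
              "fgs_separation_error")
  }
  if (nonnegative) d <- pmax(d, 0)
  if (all(d == 0)) {
    fgs_abort("no non-negative projection separates these medians",
              "fgs_separation_error")
  }
  projection_vector(d)
}

#' Cohort mean projection vector
#'
#' Arithmetic mean of per-sample unit projection vectors, renormalized to
#' unit norm; this single vector is then used to convert all RGB images of
#' a cohort to grayscale. Near-antipodal inputs whose mean is numerically
#' zero cannot be aggregated.
#'
#' @param vectors List of [projection_vector()]s (or 3-vectors).
#' @return A [projection_vector()].
#' @export
mean_projection <- function(vectors) {
  if (length(vectors) == 0L) {
    fgs_abort("need at least one projection vector", "fgs_input_error")
  }
  vs <- lapply(vectors, function(v) unclass(projection_vector(v)))
  m <- Reduce(`+`, vs) / length(vs)
  if (sqrt(sum(m^2)) < 1e-8) {
    fgs_abort("projection vectors cancel out (near-antipodal); no mean direction exists",
              "fgs_aggregation_error")
  }
  projection_vector(m)
}

#' Convert an RGB image to grayscale by scalar projection
#'
#' Each pixel is mapped to the scalar product of its RGB color with the
#' projection vector. By default negative products are clamped to zero
#' (`mode = "clamp"`): projected values proportional to PPIX-specific
#' signal cannot meaningfully be negative, and the TNR needs a positive
#' denominator. `mode = "offset"` instead shifts the whole image by its
#' global minimum, preserving differences.
#'
#' @param rgb H x W x 3 array in `[0, 1]`.
#' @param v A [projection_vector()] (or 3-vector; normalized if needed).
#' @param mode `"clamp"` (default) or `"offset"`.
#' @return H x W numeric matrix of projected intensities.
#' @export
project_to_gray <- function(rgb, v, mode = c("clamp", "offset")) {
  mode <- match.arg(mode)
  v <- projection_vector(v)
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L)) {
    fgs_abort("rgb must be an H x W x 3 array", "fgs_parameter_error")
  }
  g <- rgb[, , 1] * v[1] + rgb[, , 2] * v[2] + rgb[, , 3] * v[3]
  out <- switch(mode,
                clamp = pmax(0, g),
                offset = g - min(g))
  matrix(out, dim(rgb)[1], dim(rgb)[2])
}

#' TNR of a PPIX RGB image via discriminative projection
#'
#' Converts the RGB image to grayscale with [project_to_gray()] and applies
#' [compute_tnr()] to the result.
#'
#' @inheritParams project_to_gray
#' @inheritParams compute_tnr
#' @return A `tnr_result` (see [compute_tnr()]).
#' @export
ppix_tnr <- function(rgb, tumor_mask, normal_mask, v,
                     mode = c("clamp", "offset"),
                     section_id = NA_character_,
                     animal_id = NA_character_,
                     agent = "PPIX") {
  gray <- project_to_gray(rgb, v, mode = match.arg(mode))
  tryCatch(
    compute_tnr(gray, tumor_mask, normal_mask,
                section_id = section_id, animal_id = animal_id,
                agent = agent),
    fgs_quantification_error = function(e) {
      fgs_abort(paste0(conditionMessage(e),
                       " (projected normal mean <= 0; consider mode = \"offset\")"),
                "fgs_quantification_error")
    }
  )
}
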