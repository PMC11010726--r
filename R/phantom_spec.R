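#' Specify a synthetic coronal-section phantom
#'
#' A `phantom_spec` fixes the geometry, intensity levels, colors and noise of
#' a synthetic two-hemisphere coronal brain section carrying an elliptical
#' high-cell-density tumor in one hemisphere. The same specification drives
#' the nuclear-dye channel, the near-infrared (NIR) probe channel whose true
#' tumor:normal contrast `nir_contrast` the pipeline must recover, and an RGB
#' blue-light channel in which tumor pixels are a red-pink protoporphyrin IX
#' (PPIX) color over a blue background.
#'
#' Intensities are in arbitrary units (AU). The defaults describe the
#' reference simulation conditions used throughout the package: a 192 x 256
#' pixel section, tumor in the right hemisphere, nuclear contrast 10:1
#' (1.0 AU over 0.1 AU), NIR contrast 30 (the order of magnitude reported for
#' protease-activated NIR probes in tissue sections), additive Gaussian noise
#' with sd 0.05 AU (5% of the nuclear tumor level) clipped at zero, and PPIX
#' colors chosen so tumor and background differ mainly in hue.
#'
#' @param image_height,image_width Section size in pixels.
#' @param midline_col Column position of the hemispheric midline. May be
#'   half-integral (the default places it between the two middle columns so
#'   the hemispheres are exact mirror images).
#' @param tumor_center Numeric `(row, col)` of the tumor ellipse center.
#' @param tumor_axes Numeric `(semi_axis_row, semi_axis_col)` in pixels.
#' @param nuclear_tumor_level,nuclear_background_level Nuclear-dye intensities
#'   (AU, strictly positive) inside and outside the tumor.
#' @param nir_contrast True tumor:normal NIR intensity ratio (rho >= 1).
#' @param nir_normal_level NIR intensity of normal tissue (AU > 0).
#' @param gaussian_noise_sd Standard deviation (AU >= 0) of additive Gaussian
#'   noise applied to the nuclear and NIR channels; results are clipped at 0.
#' @param infiltration_width Width in pixels (>= 0) of a margin band outside
#'   the ellipse over which tumor signal decays linearly to background,
#'   emulating an infiltrating-cell margin. `0` gives a sharp edge.
#' @param ppix_tumor_color,ppix_background_color RGB triples in `[0, 1]`.
#' @param ppix_color_jitter_sd Per-channel Gaussian jitter sd for the RGB
#'   channel (in `[0, 1]`); jittered values are clipped to `[0, 1]`.
#' @param seed Integer seed used by default when the spec is realized.
#'
#' @return An object of class `phantom_spec`.
#'
#' @details The tumor ellipse must lie entirely on one side of
#'   `midline_col`; specifications violating this (or with non-positive
#'   levels) are rejected at construction time.
#'
#' @seealso [generate_section()], [generate_cohort()]
#' @examples
#' spec <- phantom_spec(nir_contrast = 30, gaussian_noise_sd = 0)
#' sec <- generate_section(spec, seed = 1)
#' mean(sec$nir[sec$ground_truth_mask$pixels]) /
#'   mean(sec$nir[!sec$ground_truth_mask$pixels & col(sec$nir) < 128])
#' @export
phantom_spec <- function(image_height = 192L,
                         image_width = 256L,
                         midline_col = (image_width + 1) / 2,
                         tumor_center = c(96, 192),
                         tumor_axes = c(30, 24),
                         nuclear_tumor_level = 1.0,
                         nuclear_background_level = 0.1,
                         nir_contrast = 30,
                         nir_normal_level = 1.0,
                         gaussian_noise_sd = 0.05,
                         infiltration_width = 0,
                         ppix_tumor_color = c(0.80, 0.20, 0.24),
                         ppix_background_color = c(0.16, 0.16, 0.47),
                         ppix_color_jitter_sd = 0.02,
                         seed = 1L) {
  spec <- structure(
    list(
      image_height = as.integer(image_height),
      image_width = as.integer(image_width),
      midline_col = midline_col,
      tumor_center = as.numeric(tumor_center),
      tumor_axes = as.numeric(tumor_axes),
      nuclear_tumor_level = nuclear_tumor_level,
      nuclear_background_level = nuclear_background_level,
      nir_contrast = nir_contrast,
      nir_normal_level = nir_normal_level,
      gaussian_noise_sd = gaussian_noise_sd,
      infiltration_width = infiltration_width,
      ppix_tumor_color = as.numeric(ppix_tumor_color),
      ppix_background_color = as.numeric(ppix_background_color),
      ppix_color_jitter_sd = ppix_color_jitter_sd,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  if (!is_count(spec$image_height) || !is_count(spec$image_width)) {
    fgs_abort("image dimensions must be positive integers",
              "fgs_parameter_error")
  }
  if (length(spec$tumor_center) != 2L || length(spec$tumor_axes) != 2L) {
    fgs_abort("tumor_center and tumor_axes must each have two elements",
              "fgs_parameter_error")
  }
  pos <- c(nuclear_tumor_level = spec$nuclear_tumor_level,
           nuclear_background_level = spec$nuclear_background_level,
           nir_normal_level = spec$nir_normal_level)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    fgs_abort("intensity levels must be strictly positive",
              "fgs_parameter_error")
  }
  if (spec$nir_contrast < 1) {
    fgs_abort("nir_contrast must be >= 1", "fgs_parameter_error")
  }
  if (any(spec$tumor_axes <= 0)) {
    fgs_abort("tumor_axes must be strictly positive", "fgs_parameter_error")
  }
  nonneg <- c(spec$gaussian_noise_sd, spec$infiltration_width,
              spec$ppix_color_jitter_sd)
  if (any(!is.finite(nonneg)) || any(nonneg < 0)) {
    fgs_abort("noise, jitter and infiltration parameters must be >= 0",
              "fgs_parameter_error")
  }
  rgbs <- c(spec$ppix_tumor_color, spec$ppix_background_color)
  if (any(rgbs < 0) || any(rgbs > 1)) {
    fgs_abort("PPIX colors must have components in [0, 1]",
              "fgs_parameter_error")
  }
  lo <- spec$tumor_center[2] - spec$tumor_axes[2]
  hi <- spec$tumor_center[2] + spec$tumor_axes[2]
  if (lo <= spec$midline_col && hi >= spec$midline_col) {
    fgs_abort("tumor ellipse must lie entirely on one side of the midline",
              "fgs_geometry_error")
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom specification\n")
  cat(sprintf("  section: %d x %d px, midline at column %.1f\n",
              x$image_height, x$image_width, x$midline_col))
  cat(sprintf("  tumor ellipse: center (%.0f, %.0f), semi-axes (%.0f, %.0f) px\n",
              x$tumor_center[1], x$tumor_center[2],
              x$tumor_axes[1], x$tumor_axes[2]))
  cat(sprintf("  nuclear levels: tumor %.3g AU / background %.3g AU\n",
              x$nuclear_tumor_level, x$nuclear_background_level))
  cat(sprintf("  NIR: true contrast %.3g, normal level %.3g AU\n",
              x$nir_contrast, x$nir_normal_level))
  cat(sprintf("  noise sd %.3g AU, infiltration width %.3g px, RGB jitter sd %.3g\n",
              x$gaussian_noise_sd, x$infiltration_width, x$ppix_color_jitter_sd))
  invisible(x)
}
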