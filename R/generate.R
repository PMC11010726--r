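#' Generate one synthetic multi-channel coronal section
#'
#' Realizes a [phantom_spec()] into a co-registered nuclear / NIR / RGB
#' section with known ground truth. The nuclear channel takes
#' `nuclear_tumor_level` inside the tumor ellipse and
#' `nuclear_background_level` outside, with a linear ramp across the
#' infiltration band; the NIR channel takes `nir_contrast * nir_normal_level`
#' inside and `nir_normal_level` outside (same ramp); both then receive
#' additive zero-mean Gaussian noise clipped at zero. The RGB channel blends
#' `ppix_tumor_color` over `ppix_background_color` with clipped per-channel
#' jitter. The exact rasterized tumor ellipse is attached as
#' `ground_truth_mask`.
#'
#' The output is a pure function of `(spec, seed)`: identical inputs give
#' bit-identical sections.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @param section_id,animal_id Identifiers attached to the section.
#' @return An object of class `fgs_section`: a list with matrices `nuclear`
#'   and `nir` (AU, >= 0), array `rgb` (H x W x 3 in `[0, 1]`),
#'   `midline_col`, `section_id`, `animal_id`, `ground_truth_mask`
#'   ([region_mask]) and `ground_truth_contrast` (the true NIR ratio).
#' @examples
#' sec <- generate_section(phantom_spec(gaussian_noise_sd = 0), seed = 7)
#' range(sec$nir)
#' @export
generate_section <- function(spec, seed = spec$seed,
                             section_id = "section1",
                             animal_id = "animal1") {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  H <- spec$image_height
  W <- spec$image_width
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  a <- spec$tumor_axes[1]
  b <- spec$tumor_axes[2]
  # normalized elliptical radius: 1 on the ellipse boundary
  re <- sqrt(((rr - spec$tumor_center[1]) / a)^2 +
               ((cc - spec$tumor_center[2]) / b)^2)
  inside <- re <= 1
  # tumor weight: 1 inside, linear decay to 0 over the infiltration band
  # (band width measured in pixels via the geometric-mean semi-axis)
  w <- ifelse(inside, 1, 0)
  if (spec$infiltration_width > 0) {
    s <- sqrt(a * b)
    band <- pmin(1, pmax(0, 1 - (re - 1) * s / spec$infiltration_width))
    w <- pmax(w, band)
  }

  with_seed(seed, {
    nuclear <- spec$nuclear_background_level +
      (spec$nuclear_tumor_level - spec$nuclear_background_level) * w
    nir <- spec$nir_normal_level * (1 + (spec$nir_contrast - 1) * w)
    if (spec$gaussian_noise_sd > 0) {
      nuclear <- matrix(pmax(0, nuclear + rnorm(H * W, sd = spec$gaussian_noise_sd)), H, W)
      nir <- matrix(pmax(0, nir + rnorm(H * W, sd = spec$gaussian_noise_sd)), H, W)
    }
    rgb <- array(0, dim = c(H, W, 3L))
    for (k in 1:3) {
      plane <- spec$ppix_background_color[k] +
        (spec$ppix_tumor_color[k] - spec$ppix_background_color[k]) * w
      if (spec$ppix_color_jitter_sd > 0) {
        plane <- plane + rnorm(H * W, sd = spec$ppix_color_jitter_sd)
      }
      rgb[, , k] <- pmin(1, pmax(0, plane))
    }
    new_fgs_section(
      nuclear = nuclear, nir = nir, rgb = rgb,
      midline_col = spec$midline_col,
      section_id = section_id, animal_id = animal_id,
      ground_truth_mask = region_mask(inside, "tumor", "nuclear"),
      ground_truth_contrast = spec$nir_contrast
    )
  })
}

new_fgs_section <- function(nuclear, nir, rgb, midline_col,
                            section_id = NA_character_,
                            animal_id = NA_character_,
                            ground_truth_mask = NULL,
                            ground_truth_contrast = NA_real_) {
  if (!is.matrix(nuclear) || !is.matrix(nir) ||
      !(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L)) {
    fgs_abort("channels must be H x W matrices and an H x W x 3 RGB array",
              "fgs_parameter_error")
  }
  if (!identical(dim(nuclear), dim(nir)) ||
      !identical(dim(nuclear), dim(rgb)[1:2])) {
    fgs_abort("all channels must share identical dimensions",
              "fgs_geometry_error")
  }
  if (min(nuclear) < 0 || min(nir) < 0) {
    fgs_abort("intensities must be non-negative", "fgs_parameter_error")
  }
  if (min(rgb) < 0 || max(rgb) > 1) {
    fgs_abort("RGB components must lie in [0, 1]", "fgs_parameter_error")
  }
  if (!is.null(ground_truth_mask) &&
      !identical(dim(mask_pixels(ground_truth_mask)), dim(nuclear))) {
    fgs_abort("ground-truth mask dimensions must match the channels",
              "fgs_geometry_error")
  }
  structure(list(nuclear = nuclear, nir = nir, rgb = rgb,
                 midline_col = midline_col,
                 section_id = section_id, animal_id = animal_id,
                 ground_truth_mask = ground_truth_mask,
                 ground_truth_contrast = ground_truth_contrast),
            class = "fgs_section")
}

#' @export
print.fgs_section <- function(x, ...) {
  d <- dim(x$nuclear)
  cat(sprintf("<fgs_section> %s / %s  %d x %d px, midline %.1f\n",
              x$animal_id, x$section_id, d[1], d[2], x$midline_col))
  cat(sprintf("  nuclear [%.3g, %.3g] AU; NIR [%.3g, %.3g] AU%s\n",
              min(x$nuclear), max(x$nuclear), min(x$nir), max(x$nir),
              if (is.na(x$ground_truth_contrast)) ""
              else sprintf("; true contrast %.3g", x$ground_truth_contrast)))
  invisible(x)
}

#' Display a section's channels
#'
#' Draws the nuclear, NIR and projected-luminance RGB channels side by side
#' with base graphics.
#'
#' @param x An `fgs_section`.
#' @param ... Ignored.
#' @export
plot.fgs_section <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, main) {
    graphics::image(t(m[nrow(m):1, ]), axes = FALSE, main = main,
                    col = grDevices::gray.colors(256, start = 0, end = 1))
  }
  show(x$nuclear, "nuclear")
  show(x$nir, "NIR")
  lum <- 0.299 * x$rgb[, , 1] + 0.587 * x$rgb[, , 2] + 0.114 * x$rgb[, , 3]
  show(lum, "RGB (luminance)")
  invisible(x)
}

#' Generate a cohort of phantom sections with between-animal variability
#'
#' Each animal draws its own true NIR contrast from a lognormal distribution
#' with median `spec$nir_contrast` and coefficient of variation
#' `between_animal_cv` (reflecting the large spread of tumor-to-normal ratios
#' across animals), then contributes `sections_per_animal` sections generated
#' from that per-animal contrast. With `between_animal_cv = 0` every animal
#' has exactly the specified contrast.
#'
#' @param spec A [phantom_spec()]; its `nir_contrast` is the cohort median.
#' @param n_animals Number of animals (>= 1).
#' @param sections_per_animal Sections per animal (>= 1).
#' @param between_animal_cv Coefficient of variation of the per-animal
#'   contrast (>= 0).
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A list of [generate_section()] outputs (length
#'   `n_animals * sections_per_animal`), each carrying its animal's true
#'   contrast in `ground_truth_contrast`.
#' @export
generate_cohort <- function(spec, n_animals, sections_per_animal = 1,
                            between_animal_cv = 0, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is_count(n_animals) || !is_count(sections_per_animal)) {
    fgs_abort("animal and section counts must be positive integers",
              "fgs_parameter_error")
  }
  if (between_animal_cv < 0) {
    fgs_abort("between_animal_cv must be >= 0", "fgs_parameter_error")
  }
  n_total <- n_animals * sections_per_animal
  draws <- with_seed(seed, {
    rho <- if (between_animal_cv == 0) {
      rep(spec$nir_contrast, n_animals)
    } else {
      sigma <- sqrt(log1p(between_animal_cv^2))
      # median of the lognormal equals the specified contrast
      exp(log(spec$nir_contrast) + rnorm(n_animals, sd = sigma))
    }
    list(rho = pmax(1, rho),
         seeds = sample.int(.Machine$integer.max - 1L, n_total))
  })
  sections <- vector("list", n_total)
  idx <- 0L
  for (i in seq_len(n_animals)) {
    spec_i <- spec
    spec_i$nir_contrast <- draws$rho[i]
    for (j in seq_len(sections_per_animal)) {
      idx <- idx + 1L
      sections[[idx]] <- generate_section(
        spec_i, seed = draws$seeds[idx],
        section_id = sprintf("animal%03d_s%02d", i, j),
        animal_id = sprintf("animal%03d", i)
      )
    }
  }
  sections
}

#' Generate paired tumor/normal homogenate fluorescence records
#'
#' Emulates spectrofluorimetric readings of mechanically homogenized tumor
#' and contralateral normal brain tissue: each animal contributes one tumor
#' and one normal record with weight (mg) and total fluorescence (AU), such
#' that the weight-normalized tumor signal equals `true_tnr` times the
#' weight-normalized normal signal up to multiplicative lognormal noise with
#' mean 1 and coefficient of variation `noise_cv`.
#'
#' @param n_animals Number of animals (>= 1).
#' @param true_tnr True tumor-to-normal ratio (>= 1).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 makes every animal's ratio exactly `true_tnr`).
#' @param seed Integer seed.
#' @param normal_level Per-mg fluorescence of normal tissue (AU/mg).
#' @param weight_range Sampling range (mg) for tissue sample weights.
#' @return A data frame with columns `animal_id`, `tissue`
#'   (`"tumor"`/`"normal"`), `fluorescence_au` and `weight_mg`, two rows per
#'   animal.
#' @seealso [homogenate_tnr()]
#' @export
generate_homogenates <- function(n_animals, true_tnr, noise_cv = 0.2,
                                 seed = 1L, normal_level = 100,
                                 weight_range = c(10, 30)) {
  if (!is_count(n_animals)) {
    fgs_abort("n_animals must be a positive integer", "fgs_parameter_error")
  }
  if (!is_scalar_num(true_tnr) || true_tnr < 1) {
    fgs_abort("true_tnr must be >= 1", "fgs_parameter_error")
  }
  if (noise_cv < 0) fgs_abort("noise_cv must be >= 0", "fgs_parameter_error")
  with_seed(seed, {
    ids <- sprintf("animal%03d", seq_len(n_animals))
    w_t <- runif(n_animals, weight_range[1], weight_range[2])
    w_n <- runif(n_animals, weight_range[1], weight_range[2])
    # per-animal normal per-mg level varies between animals
    base <- normal_level * rln_mean1(n_animals, noise_cv)
    per_mg_n <- base
    per_mg_t <- true_tnr * base * rln_mean1(n_animals, noise_cv)
    data.frame(
      animal_id = rep(ids, each = 2L),
      tissue = rep(c("tumor", "normal"), n_animals),
      fluorescence_au = as.vector(rbind(per_mg_t * w_t, per_mg_n * w_n)),
      weight_mg = as.vector(rbind(w_t, w_n)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate an ex-vivo fragment activation time course
#'
#' Emulates incubation of tissue fragments with an activatable probe and
#' fluorescence measurement at several timepoints. Fragments belong to a
#' glioblastoma group (`"GBM"`), a nonmalignant pharmacoresistant-epilepsy
#' group (`"PRE"`), or the reference group of healthy mouse brain tissue
#' processed alongside each experiment (used by [normalize_exvivo()] to
#' remove between-experiment scale differences). Activation follows a
#' saturating time course `t / (t + t_half)` that increases strictly with
#' time within every fragment; the expected GBM mean is
#' `fold_gbm_vs_pre` times the expected PRE mean at every timepoint.
#'
#' @param n_gbm,n_pre Number of GBM and PRE fragments (>= 1 each).
#' @param fold_gbm_vs_pre True GBM/PRE activation fold (>= 1).
#' @param timepoints Incubation times in minutes (non-empty); the default is
#'   the 2, 5, 10 and 120 minute design.
#' @param seed Integer seed.
#' @param noise_cv Coefficient of variation of per-fragment multiplicative
#'   noise (>= 0).
#' @param n_reference Reference fragments per experiment (>= 1).
#' @param t_half Half-saturation time (minutes) of the activation kinetics.
#' @param experiment_id Identifier for the experiment.
#' @return A data frame with columns `sample_id`, `group`, `timepoint_min`,
#'   `fluorescence_au` and `experiment_id`, one row per fragment and
#'   timepoint.
#' @seealso [normalize_exvivo()], [fold_difference()]
#' @export
generate_exvivo <- function(n_gbm, n_pre, fold_gbm_vs_pre,
                            timepoints = c(2, 5, 10, 120), seed = 1L,
                            noise_cv = 0.15, n_reference = 3L,
                            t_half = 10, experiment_id = "exp1") {
  if (!is_count(n_gbm) || !is_count(n_pre) || !is_count(n_reference)) {
    fgs_abort("fragment counts must be positive integers",
              "fgs_parameter_error")
  }
  if (!is_scalar_num(fold_gbm_vs_pre) || fold_gbm_vs_pre < 1) {
    fgs_abort("fold_gbm_vs_pre must be >= 1", "fgs_parameter_error")
  }
  if (length(timepoints) == 0L || any(timepoints <= 0)) {
    fgs_abort("timepoints must be a non-empty vector of positive minutes",
              "fgs_parameter_error")
  }
  timepoints <- sort(unique(as.numeric(timepoints)))
  groups <- c(rep("GBM", n_gbm), rep("PRE", n_pre),
              rep("reference", n_reference))
  level <- c(GBM = 1000 * fold_gbm_vs_pre, PRE = 1000, reference = 200)
  with_seed(seed, {
    n_frag <- length(groups)
    eps <- rln_mean1(n_frag, noise_cv)  # one draw per fragment: monotone t-course
    rows <- lapply(seq_len(n_frag), function(i) {
      act <- timepoints / (timepoints + t_half)
      data.frame(
        sample_id = sprintf("%s_%s%02d", experiment_id, tolower(groups[i]), i),
        group = groups[i],
        timepoint_min = timepoints,
        fluorescence_au = level[[groups[i]]] * eps[i] * act,
        experiment_id = experiment_id,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
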