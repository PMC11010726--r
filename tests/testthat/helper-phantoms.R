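# Compact phantom geometries used across the suite (full-size sections are
# exercised in the acceptance tests). Named arguments override the compact
# defaults.

spec_with <- function(defaults, ...) {
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(phantom_spec, defaults)
}

small_spec <- function(...) {
  spec_with(list(image_height = 96L, image_width = 128L, midline_col = 64.5,
                 tumor_center = c(48, 96), tumor_axes = c(16, 12)), ...)
}

tiny_spec <- function(...) {
  spec_with(list(image_height = 24L, image_width = 32L, midline_col = 16.5,
                 tumor_center = c(12, 24), tumor_axes = c(5, 4)), ...)
}

noiseless_small <- function(...) {
  small_spec(gaussian_noise_sd = 0, ppix_color_jitter_sd = 0, ...)
}
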