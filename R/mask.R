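#' Region masks
#'
#' A `region_mask` is a boolean pixel grid labelling a region of a section:
#' the tumor, the contralateral normal-brain ROI, or generic tissue. Tumor
#' and normal masks must contain at least one pixel.
#'
#' @param pixels Logical matrix (H x W).
#' @param label One of `"tumor"`, `"normal"`, `"tissue"`.
#' @param source_channel Channel the mask was derived from: `"nuclear"`,
#'   `"nir"` or `"rgb"`.
#' @return An object of class `region_mask` with elements `pixels`, `label`
#'   and `source_channel`.
#' @seealso [segment_tumor()], [mirror_roi()], [transfer_mask()]
#' @export
region_mask <- function(pixels, label = c("tumor", "normal", "tissue"),
                        source_channel = c("nuclear", "nir", "rgb")) {
  label <- match.arg(label)
  source_channel <- match.arg(source_channel)
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    fgs_abort("mask pixels must be a logical matrix", "fgs_mask_error")
  }
  if (anyNA(pixels)) fgs_abort("mask pixels must not contain NA",
                               "fgs_mask_error")
  if (label %in% c("tumor", "normal") && !any(pixels)) {
    fgs_abort(sprintf("a %s mask must contain at least one pixel", label),
              "fgs_mask_error")
  }
  structure(list(pixels = pixels, label = label,
                 source_channel = source_channel),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> label=%s source=%s  %d x %d px, %d set (%.1f%%)\n",
              x$label, x$source_channel, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

mask_area <- function(mask) sum(mask$pixels)

# Extract a logical matrix from either a region_mask or a raw logical matrix.
mask_pixels <- function(mask) {
  if (inherits(mask, "region_mask")) mask$pixels
  else if (is.matrix(mask) && is.logical(mask)) mask
  else fgs_abort("expected a region_mask or logical matrix", "fgs_mask_error")
}
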