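#' Segment the tumor from the nuclear-dye channel
#'
#' Builds the tumor mask from the nuclear channel: an automatic two-class
#' threshold (between-class variance maximization over a 256-bin histogram,
#' ties broken toward the lowest candidate) separates the high-cell-density
#' tumor from background tissue; morphological cleanup by reconstruction
#' with a disc of radius `smoothing_radius` removes speckle smaller than the
#' structuring element while leaving the boundary of surviving components
#' untouched; components smaller than `min_area` are discarded and the
#' largest remaining component is returned.
#'
#' Because the threshold is chosen on the image's own histogram, the result
#' is invariant to multiplying the channel by any positive gain.
#'
#' @param nuclear Nuclear-channel intensity matrix (non-negative,
#'   non-constant), or an `fgs_section` whose `$nuclear` is used.
#' @param min_area Minimum component area in pixels.
#' @param smoothing_radius Radius (pixels) of the cleanup structuring
#'   element; `0` disables cleanup.
#' @return A tumor [region_mask].
#' @section Errors: A constant image admits no two-class threshold and
#'   raises a segmentation error, as does an image in which no component
#'   reaches `min_area`.
#' @examples
#' sec <- generate_section(phantom_spec(gaussian_noise_sd = 0), seed = 1)
#' m <- segment_tumor(sec)
#' identical(m$pixels, sec$ground_truth_mask$pixels)
#' @export
segment_tumor <- function(nuclear, min_area = 25, smoothing_radius = 1) {
  if (inherits(nuclear, "fgs_section")) nuclear <- nuclear$nuclear
  if (!is.matrix(nuclear) || !is.numeric(nuclear)) {
    fgs_abort("nuclear must be a numeric matrix", "fgs_parameter_error")
  }
  if (min(nuclear) < 0) {
    fgs_abort("nuclear intensities must be non-negative",
              "fgs_parameter_error")
  }
  th <- otsu_threshold(nuclear)
  bw <- nuclear > th
  if (smoothing_radius > 0) bw <- open_reconstruct(bw, smoothing_radius)
  if (!any(bw)) {
    fgs_abort("no foreground pixels survive morphological cleanup",
              "fgs_segmentation_error")
  }
  lab <- EBImage::bwlabel(bw * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L) {
    fgs_abort(sprintf("no connected component reaches min_area = %d px",
                      as.integer(min_area)), "fgs_segmentation_error")
  }
  largest <- keep[which.max(sizes[keep])]  # which.max: first (lowest label) tie
  region_mask(matrix(lab == largest, nrow(nuclear), ncol(nuclear)),
              label = "tumor", source_channel = "nuclear")
}

# Between-class-variance-maximizing two-class threshold on a 256-bin
# histogram spanning [min, max]; returns the bin-edge threshold. Among tied
# candidates the lowest is chosen, making the result deterministic.
otsu_threshold <- function(x, n_bins = 256L) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) {
    fgs_abort("image is constant: no two-class threshold exists",
              "fgs_segmentation_error")
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(n_bins, pmax(1L, findInterval(x, edges, rightmost.closed = TRUE))),
    nbins = n_bins
  )
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)[-n_bins]
  mu0 <- cumsum(p * mids)[-n_bins]
  mu_total <- sum(p * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_total * w0[valid] - mu0[valid])^2 /
    (w0[valid] * w1[valid])
  k <- which(bcv == max(bcv))[1L]
  edges[k + 1L]
}

# Morphological opening by reconstruction: erode with a disc of radius r,
# then restore every connected component of the original mask that survives
# erosion. Removes sub-radius speckle without nibbling retained components.
open_reconstruct <- function(bw, radius) {
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  eroded <- EBImage::erode(bw * 1, brush) > 0.5
  if (!any(eroded)) return(matrix(FALSE, nrow(bw), ncol(bw)))
  lab <- EBImage::bwlabel(bw * 1)
  survivors <- unique(lab[eroded & lab > 0])
  matrix(lab %in% survivors, nrow(bw), ncol(bw))
}

#' Mirror a tumor mask across the hemispheric midline
#'
#' Reflects the tumor mask across the midline column to obtain a same-size,
#' location-matched normal-brain ROI in the contralateral hemisphere. The
#' tumor mask must lie entirely on one side of the midline; pixels whose
#' reflection falls outside the image are dropped, but only up to 1% of the
#' mask may be lost this way.
#'
#' @param tumor_mask A tumor [region_mask] (or logical matrix).
#' @param midline_col Column position of the midline (may be half-integral).
#' @return A [region_mask] with label `"normal"`.
#' @examples
#' m <- matrix(FALSE, 8, 9); m[4, 7] <- TRUE
#' mirror_roi(region_mask(m, "tumor"), midline_col = 5)$pixels[4, 3]
#' @export
mirror_roi <- function(tumor_mask, midline_col) {
  px <- mask_pixels(tumor_mask)
  if (!any(px)) fgs_abort("tumor mask is empty", "fgs_mask_error")
  idx <- which(px, arr.ind = TRUE)
  cols <- idx[, 2]
  if (min(cols) < midline_col && max(cols) > midline_col) {
    fgs_abort("tumor mask straddles the midline", "fgs_geometry_error")
  }
  if (any(cols == midline_col)) {
    fgs_abort("tumor mask touches the midline column", "fgs_geometry_error")
  }
  refl <- round(2 * midline_col - cols)
  inb <- refl >= 1 & refl <= ncol(px)
  if (mean(!inb) >= 0.01) {
    fgs_abort(sprintf(
      "%.1f%% of reflected pixels fall outside the image (>= 1%% limit)",
      100 * mean(!inb)), "fgs_geometry_error")
  }
  out <- matrix(FALSE, nrow(px), ncol(px))
  out[cbind(idx[inb, 1], refl[inb])] <- TRUE
  src <- if (inherits(tumor_mask, "region_mask")) tumor_mask$source_channel
         else "nuclear"
  region_mask(out, label = "normal", source_channel = src)
}

#' Translate a mask into a co-registered target image
#'
#' Shifts a mask by an integer `(rows, cols)` offset, for transferring a
#' tumor mask drawn on the nuclear channel into the corresponding position
#' of a co-registered fluorescence channel. The target must have the same
#' shape as the mask; pixels shifted out of bounds are dropped, but a
#' transfer losing more than 10% of the mask is refused.
#'
#' @param mask A [region_mask] (or logical matrix).
#' @param target_shape Integer `(H, W)` of the target image; must equal the
#'   mask's shape.
#' @param offset Integer `(rows, cols)` translation; default `c(0, 0)`.
#' @return A translated [region_mask] with the same label.
#' @export
transfer_mask <- function(mask, target_shape = dim(mask_pixels(mask)),
                          offset = c(0L, 0L)) {
  px <- mask_pixels(mask)
  if (!identical(as.integer(target_shape), as.integer(dim(px)))) {
    fgs_abort("target shape must equal the mask shape (images are co-registered)",
              "fgs_geometry_error")
  }
  offset <- as.integer(round(offset))
  idx <- which(px, arr.ind = TRUE)
  n0 <- nrow(idx)
  if (n0 == 0L) fgs_abort("mask is empty", "fgs_mask_error")
  r2 <- idx[, 1] + offset[1]
  c2 <- idx[, 2] + offset[2]
  inb <- r2 >= 1 & r2 <= dim(px)[1] & c2 >= 1 & c2 <= dim(px)[2]
  lost <- 1 - sum(inb) / n0
  if (lost > 0.10) {
    fgs_abort(sprintf("offset would drop %.1f%% of mask pixels (> 10%% limit)",
                      100 * lost), "fgs_transfer_error")
  }
  out <- matrix(FALSE, dim(px)[1], dim(px)[2])
  out[cbind(r2[inb], c2[inb])] <- TRUE
  lbl <- if (inherits(mask, "region_mask")) mask$label else "tumor"
  src <- if (inherits(mask, "region_mask")) mask$source_channel else "nuclear"
  region_mask(out, label = lbl, source_channel = src)
}

#' Contralateral hemisphere as the normal-tissue ROI
#'
#' Alternative to [mirror_roi()]: takes every tissue pixel of the hemisphere
#' opposite the tumor as the normal ROI, where tissue is defined as nuclear
#' intensity above a low quantile of the channel.
#'
#' @param nuclear Nuclear-channel matrix or an `fgs_section`.
#' @param midline_col Midline column position.
#' @param tumor_side Side of the image the tumor is on: `"right"` (default)
#'   or `"left"`; the ROI is the other side.
#' @param tissue_quantile Quantile of the nuclear channel used as the tissue
#'   threshold.
#' @return A [region_mask] with label `"normal"`.
#' @export
hemisphere_roi <- function(nuclear, midline_col = NULL,
                           tumor_side = c("right", "left"),
                           tissue_quantile = 0.05) {
  if (inherits(nuclear, "fgs_section")) {
    if (is.null(midline_col)) midline_col <- nuclear$midline_col
    nuclear <- nuclear$nuclear
  }
  if (is.null(midline_col)) {
    fgs_abort("midline_col is required", "fgs_parameter_error")
  }
  tumor_side <- match.arg(tumor_side)
  th <- quantile(nuclear, tissue_quantile, names = FALSE)
  tissue <- nuclear >= th
  cc <- col(nuclear)
  side <- if (tumor_side == "right") cc < midline_col else cc > midline_col
  out <- tissue & side
  if (!any(out)) {
    fgs_abort("contralateral hemisphere contains no tissue pixels",
              "fgs_segmentation_error")
  }
  region_mask(out, label = "normal", source_channel = "nuclear")
}
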