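# Readers and writers: multi-page TIFF for intensity channels, PNG for RGB,
# YAML sidecars for metadata, CSV for tables.
#
# Intensity pages are stored as 16-bit samples scaled into [0, 1] by a
# power-of-two `channel_scale` recorded in the sidecar (quantization step
# scale/65535, ~0.05% of the normal-tissue level at default scales, far
# below any measurement noise). Values are snapped to the 16-bit grid before
# writing, so write -> load returns exactly the stored values and a loaded
# section re-written and re-loaded is bit-identical.

TIFF_BITS <- 16L
TIFF_LEVELS <- 65535

quantize_grid <- function(x) {
  d <- dim(x)
  y <- round(x * TIFF_LEVELS) / TIFF_LEVELS
  dim(y) <- d
  y
}

check_overwrite <- function(paths, force) {
  exists <- file.exists(paths)
  if (any(exists) && !force) {
    fgs_abort(sprintf("refusing to overwrite existing output (use force = TRUE): %s",
                      paths[exists][1]), "fgs_io_error")
  }
}

require_file <- function(path) {
  if (!file.exists(path)) {
    fgs_abort(sprintf("file not found: %s", path), "fgs_io_error")
  }
  path
}

#' Write a section to disk
#'
#' Writes the nuclear and NIR channels as a two-page 16-bit TIFF, the RGB
#' channel as an 8-bit PNG, the ground-truth mask (if present) as an 8-bit
#' mask TIFF, and a YAML sidecar holding geometry, identifiers, the channel
#' scale factor and the file names. The sidecar is the handle that
#' [load_section()] takes.
#'
#' @param section An `fgs_section`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the files; defaults to the section id.
#' @param force Overwrite existing files?
#' @return (Invisibly) the path of the YAML sidecar.
#' @export
write_section <- function(section, dir, name = section$section_id,
                          force = FALSE) {
  stopifnot(inherits(section, "fgs_section"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, paste0(name, ".tif"))
  pngf <- file.path(dir, paste0(name, ".png"))
  maskf <- file.path(dir, paste0(name, "_mask.tif"))
  yml <- file.path(dir, paste0(name, ".yml"))
  check_overwrite(c(tif, pngf, maskf, yml), force)

  # power-of-two scale: division is exact and the scale is stable under the
  # TIFF quantization, so write -> load -> write is idempotent
  scale <- 2^ceiling(log2(max(1, max(section$nuclear), max(section$nir))))
  tiff::writeTIFF(list(quantize_grid(section$nuclear / scale),
                       quantize_grid(section$nir / scale)),
                  tif, bits.per.sample = TIFF_BITS, compression = "none",
                  reduce = FALSE)
  png::writePNG(section$rgb, pngf)
  has_mask <- !is.null(section$ground_truth_mask)
  if (has_mask) {
    tiff::writeTIFF(section$ground_truth_mask$pixels * 1.0, maskf,
                    bits.per.sample = 8L, compression = "none",
                    reduce = FALSE)
  }
  meta <- list(
    section_id = section$section_id,
    animal_id = section$animal_id,
    midline_col = section$midline_col,
    channel_scale = scale,
    ground_truth_contrast = if (is.na(section$ground_truth_contrast)) NULL
                            else section$ground_truth_contrast,
    files = list(channels = basename(tif), rgb = basename(pngf),
                 ground_truth_mask = if (has_mask) basename(maskf) else NULL),
    pages = c("nuclear", "nir"),
    writer = paste0("fgsquant ", as.character(packageVersion("fgsquant")))
  )
  yaml::write_yaml(meta, yml)
  invisible(yml)
}

#' Load a section from its YAML sidecar
#'
#' Reads the channel TIFF, RGB PNG and optional ground-truth mask named in
#' the sidecar, restores intensities with the recorded scale factor (8-bit
#' RGB is returned in `[0, 1]`), and attaches the metadata.
#'
#' @param yaml_path Path to the sidecar written by [write_section()].
#' @return An `fgs_section`.
#' @export
load_section <- function(yaml_path) {
  require_file(yaml_path)
  meta <- yaml::read_yaml(yaml_path)
  need <- c("midline_col", "channel_scale", "files")
  if (!all(need %in% names(meta))) {
    fgs_abort(sprintf("sidecar %s lacks required metadata (%s)",
                      yaml_path, paste(setdiff(need, names(meta)),
                                       collapse = ", ")),
              "fgs_io_error")
  }
  dir <- dirname(yaml_path)
  tif <- require_file(file.path(dir, meta$files$channels))
  pngf <- require_file(file.path(dir, meta$files$rgb))
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (length(pages) < 2L) {
    fgs_abort(sprintf("channel TIFF %s must have two pages (nuclear, nir)",
                      tif), "fgs_io_error")
  }
  nuclear <- pages[[1]] * meta$channel_scale
  nir <- pages[[2]] * meta$channel_scale
  rgb <- png::readPNG(pngf)
  if (length(dim(rgb)) == 2L) rgb <- array(rep(rgb, 3), c(dim(rgb), 3L))
  if (dim(rgb)[3] > 3L) rgb <- rgb[, , 1:3, drop = FALSE]
  if (!identical(dim(nuclear), dim(nir)) ||
      !identical(dim(nuclear), dim(rgb)[1:2])) {
    fgs_abort(sprintf("channel dimensions disagree between %s and %s",
                      tif, pngf), "fgs_io_error")
  }
  gt <- NULL
  if (!is.null(meta$files$ground_truth_mask)) {
    gt <- read_mask(require_file(file.path(dir, meta$files$ground_truth_mask)),
                    label = "tumor", source_channel = "nuclear")
  }
  new_fgs_section(
    nuclear = nuclear, nir = nir, rgb = rgb,
    midline_col = meta$midline_col,
    section_id = meta$section_id %||% NA_character_,
    animal_id = meta$animal_id %||% NA_character_,
    ground_truth_mask = gt,
    ground_truth_contrast = meta$ground_truth_contrast %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a region mask as an 8-bit TIFF with YAML sidecar
#'
#' Masks are stored as single-page 8-bit TIFFs (0/255) plus a sidecar
#' recording the label and source channel.
#'
#' @param mask A [region_mask].
#' @param path Output TIFF path; the sidecar replaces the extension with
#'   `.yml`.
#' @param force Overwrite existing files?
#' @return `write_mask()` returns the TIFF path invisibly; `read_mask()`
#'   returns a [region_mask].
#' @export
write_mask <- function(mask, path, force = FALSE) {
  stopifnot(inherits(mask, "region_mask"))
  yml <- sub("\\.[^.]+$", ".yml", path)
  check_overwrite(c(path, yml), force)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(mask$pixels * 1.0, path, bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  yaml::write_yaml(list(label = mask$label,
                        source_channel = mask$source_channel), yml)
  invisible(path)
}

#' @rdname write_mask
#' @param label,source_channel Used when no sidecar is found next to `path`.
#' @export
read_mask <- function(path, label = "tumor", source_channel = "nuclear") {
  require_file(path)
  yml <- sub("\\.[^.]+$", ".yml", path)
  if (file.exists(yml)) {
    meta <- yaml::read_yaml(yml)
    label <- meta$label %||% label
    source_channel <- meta$source_channel %||% source_channel
  }
  px <- tiff::readTIFF(path)
  region_mask(px > 0.5, label = label, source_channel = source_channel)
}

tnr_table_columns <- c("section_id", "animal_id", "agent", "tumor_mean",
                       "normal_mean", "tnr", "tumor_px", "normal_px")

#' Write tabular results as CSV
#'
#' Fixed, schema-stable headers: per-section TNR tables use
#' `section_id,animal_id,agent,tumor_mean,normal_mean,tnr,tumor_px,normal_px`;
#' homogenate tables `animal_id,tissue,fluorescence_au,weight_mg`; ex-vivo
#' tables `sample_id,group,timepoint_min,fluorescence_au,experiment_id`
#' (plus `normalized_fluorescence` once normalized).
#'
#' @param x Data frame (or list of `tnr_result`s for `write_tnr_table()`).
#' @param path Output CSV path.
#' @param force Overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_tnr_table <- function(x, path, force = FALSE) {
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1), "tnr_result"))) {
    x <- do.call(rbind, lapply(x, as.data.frame))
  }
  if (!all(tnr_table_columns %in% names(x))) {
    fgs_abort("TNR table lacks required columns", "fgs_input_error")
  }
  write_csv_checked(x[tnr_table_columns], path, force)
}

#' @rdname write_tnr_table
#' @export
write_table_csv <- function(x, path, force = FALSE) {
  write_csv_checked(x, path, force)
}

write_csv_checked <- function(x, path, force) {
  check_overwrite(path, force)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a homogenate or ex-vivo CSV, validating its schema
#'
#' @param path CSV path.
#' @param kind `"homogenate"` or `"exvivo"`.
#' @return A data frame with the canonical columns.
#' @export
read_fluorescence_table <- function(path, kind = c("homogenate", "exvivo")) {
  kind <- match.arg(kind)
  require_file(path)
  need <- switch(kind,
    homogenate = c("animal_id", "tissue", "fluorescence_au", "weight_mg"),
    exvivo = c("sample_id", "group", "timepoint_min", "fluorescence_au",
               "experiment_id"))
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(need %in% names(x))) {
    fgs_abort(sprintf("%s lacks required %s columns (%s)", path, kind,
                      paste(setdiff(need, names(x)), collapse = ", ")),
              "fgs_io_error")
  }
  x
}

#' Write fitted projection vectors to YAML
#'
#' Records each per-sample vector and the cohort mean vector (the one used
#' for grayscale conversion), all unit-norm.
#'
#' @param per_sample Named list of [projection_vector()]s.
#' @param mean_vector The [mean_projection()] of `per_sample`.
#' @param path Output YAML path.
#' @param force Overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_projection_yaml <- function(per_sample, mean_vector, path,
                                  force = FALSE) {
  check_overwrite(path, force)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(
    per_sample = lapply(per_sample, function(v)
      as.numeric(projection_vector(v))),
    mean = as.numeric(projection_vector(mean_vector))
  ), path, precision = 15L)
  invisible(path)
}

#' @rdname write_projection_yaml
#' @export
read_projection_yaml <- function(path) {
  require_file(path)
  meta <- yaml::read_yaml(path)
  list(per_sample = lapply(meta$per_sample, projection_vector),
       mean = projection_vector(meta$mean))
}
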