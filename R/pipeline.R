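#' Configure an end-to-end quantification run
#'
#' Bundles every knob of the pipeline — phantom cohort (or an input
#' directory of previously written sections), segmentation parameters,
#' normal-ROI mode, projection options, the statistical test, output
#' directory and the single seed from which all randomness flows — into one
#' object that is serialized alongside every output.
#'
#' @param phantom A [phantom_spec()] describing the cohort to simulate
#'   (ignored when `input_dir` is given).
#' @param input_dir Optional directory of `*.yml` section sidecars to load
#'   instead of simulating.
#' @param n_animals,sections_per_animal,between_animal_cv Cohort layout; see
#'   [generate_cohort()].
#' @param min_area,smoothing_radius Segmentation parameters; see
#'   [segment_tumor()].
#' @param normal_roi `"mirror"` (contralateral mirror of the tumor mask,
#'   default) or `"hemisphere"` (all contralateral tissue pixels).
#' @param projection_mode `"clamp"` or `"offset"`; see [project_to_gray()].
#' @param projection_nonnegative Constrain fitted projection vectors to
#'   non-negative components?
#' @param stats_test `"wilcoxon"`, `"paired_t"` or `"mann_whitney"`.
#' @param out_dir Optional output directory for CSV/YAML results.
#' @param seed Integer master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            input_dir = NULL,
                            n_animals = 10L,
                            sections_per_animal = 3L,
                            between_animal_cv = 0.55,
                            min_area = 25,
                            smoothing_radius = 1,
                            normal_roi = c("mirror", "hemisphere"),
                            projection_mode = c("clamp", "offset"),
                            projection_nonnegative = FALSE,
                            stats_test = c("wilcoxon", "paired_t",
                                           "mann_whitney"),
                            out_dir = NULL,
                            seed = 1L) {
  cfg <- list(
    phantom = phantom, input_dir = input_dir,
    n_animals = as.integer(n_animals),
    sections_per_animal = as.integer(sections_per_animal),
    between_animal_cv = between_animal_cv,
    min_area = min_area, smoothing_radius = smoothing_radius,
    normal_roi = match.arg(normal_roi),
    projection_mode = match.arg(projection_mode),
    projection_nonnegative = isTRUE(projection_nonnegative),
    stats_test = match.arg(stats_test),
    out_dir = out_dir, seed = as.integer(seed)
  )
  if (is.null(cfg$input_dir)) stopifnot(inherits(phantom, "phantom_spec"))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  src <- if (is.null(x$input_dir)) {
    sprintf("simulate %d animals x %d sections (between-animal CV %.2f)",
            x$n_animals, x$sections_per_animal, x$between_animal_cv)
  } else sprintf("load sections from %s", x$input_dir)
  cat("Pipeline configuration\n")
  cat("  input:     ", src, "\n", sep = "")
  cat(sprintf("  segment:   min_area %g px, smoothing radius %g px, normal ROI = %s\n",
              x$min_area, x$smoothing_radius, x$normal_roi))
  cat(sprintf("  project:   mode = %s, nonnegative = %s\n",
              x$projection_mode, x$projection_nonnegative))
  cat(sprintf("  compare:   %s; seed %d\n", x$stats_test, x$seed))
  invisible(x)
}

#' Run the end-to-end quantification pipeline
#'
#' Chains generation (or loading) of multi-channel sections, nuclear-channel
#' tumor segmentation, contralateral normal-ROI construction, NIR TNR
#' quantification, per-sample projection-vector fitting, cohort-mean
#' projection, projected PPIX TNR quantification, per-animal aggregation
#' and the paired agent comparison. Deterministic: the same configuration
#' and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param force Overwrite existing files in `config$out_dir`?
#' @return An object of class `fgs_pipeline_result`: list with `sections`
#'   (per-section TNR table, both agents), `per_animal` (aggregated table),
#'   `projection` (per-sample and mean vectors), `comparison` (an
#'   `fgs_test`), `section_cv` (per-animal NIR CV, where >= 2 sections) and
#'   `config`. If `config$out_dir` is set, tables and vectors are also
#'   written there together with the resolved configuration and a run log.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  sections <- if (!is.null(config$input_dir)) {
    ymls <- sort(list.files(config$input_dir, pattern = "\\.yml$",
                            full.names = TRUE))
    ymls <- ymls[!grepl("_mask\\.yml$", ymls)]
    if (length(ymls) == 0L) {
      fgs_abort(sprintf("no section sidecars (*.yml) found in %s",
                        config$input_dir), "fgs_io_error")
    }
    say("loading %d sections from %s", length(ymls), config$input_dir)
    lapply(ymls, load_section)
  } else {
    say("simulating cohort: %d animals x %d sections, seed %d",
        config$n_animals, config$sections_per_animal, config$seed)
    generate_cohort(config$phantom, config$n_animals,
                    config$sections_per_animal,
                    config$between_animal_cv, seed = config$seed)
  }

  rows <- list()
  vectors <- list()
  for (sec in sections) {
    stage <- "segmentation"
    res <- tryCatch({
      tumor <- segment_tumor(sec$nuclear, min_area = config$min_area,
                             smoothing_radius = config$smoothing_radius)
      normal <- if (config$normal_roi == "mirror") {
        m <- mirror_roi(tumor, sec$midline_col)
        # keep the ROIs disjoint even if the mirror grazes the tumor side
        m$pixels <- m$pixels & !tumor$pixels
        m
      } else {
        tumor_side <- if (mean(col(sec$nuclear)[tumor$pixels]) >
                          sec$midline_col) "right" else "left"
        h <- hemisphere_roi(sec$nuclear, sec$midline_col, tumor_side)
        h$pixels <- h$pixels & !tumor$pixels
        h
      }
      stage <- "quantification"
      nir <- compute_tnr(sec$nir, tumor, normal,
                         section_id = sec$section_id,
                         animal_id = sec$animal_id, agent = "NIR")
      stage <- "projection fitting"
      mt <- median_color(sec$rgb, tumor)
      mn <- median_color(sec$rgb, normal)
      v <- optimal_projection(mt, mn,
                              nonnegative = config$projection_nonnegative)
      list(tumor = tumor, normal = normal, nir = nir, v = v)
    }, fgs_error = function(e) {
      fgs_abort(sprintf("[%s / section %s] %s", stage, sec$section_id,
                        conditionMessage(e)), class(e)[1])
    })
    rows[[sec$section_id]] <- res
    vectors[[sec$section_id]] <- res$v
  }

  v_mean <- mean_projection(vectors)
  say("cohort mean projection vector: (%.4f, %.4f, %.4f)",
      v_mean[1], v_mean[2], v_mean[3])

  tab <- do.call(rbind, lapply(sections, function(sec) {
    r <- rows[[sec$section_id]]
    ppix <- ppix_tnr(sec$rgb, r$tumor, r$normal, v_mean,
                     mode = config$projection_mode,
                     section_id = sec$section_id,
                     animal_id = sec$animal_id)
    rbind(as.data.frame(r$nir), as.data.frame(ppix))
  }))
  rownames(tab) <- NULL

  per_animal <- do.call(rbind, lapply(c("NIR", "PPIX"), function(ag) {
    sub <- aggregate_tnr(tab[tab$agent == ag, , drop = FALSE])
    sub$agent <- ag
    sub
  }))
  per_animal <- per_animal[c("animal_id", "agent", "tnr", "n_sections")]

  nir_tab <- tab[tab$agent == "NIR", , drop = FALSE]
  cv_ids <- unique(nir_tab$animal_id[duplicated(nir_tab$animal_id)])
  cvs <- if (length(cv_ids)) {
    data.frame(animal_id = cv_ids,
               cv = vapply(cv_ids, function(id)
                 section_cv(nir_tab$tnr[nir_tab$animal_id == id]),
                 numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else NULL

  comparison <- compare_agents(per_animal, c("NIR", "PPIX"),
                               test = config$stats_test)
  say("comparison (%s): statistic %.4g, p = %.4g",
      comparison$test, comparison$statistic, comparison$p_value)

  result <- structure(
    list(sections = tab, per_animal = per_animal, projection =
           list(per_sample = vectors, mean = v_mean),
         comparison = comparison, section_cv = cvs, config = config),
    class = "fgs_pipeline_result"
  )

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    write_tnr_table(tab, file.path(out, "sections_tnr.csv"), force = force)
    write_table_csv(per_animal, file.path(out, "per_animal_tnr.csv"),
                    force = force)
    if (!is.null(cvs)) {
      write_table_csv(cvs, file.path(out, "section_cv.csv"), force = force)
    }
    write_projection_yaml(vectors, v_mean,
                          file.path(out, "projection_vectors.yml"),
                          force = force)
    cfg <- unclass(config)
    cfg$phantom <- if (!is.null(cfg$phantom)) unclass(cfg$phantom)
    yaml::write_yaml(list(config = cfg,
                          version = as.character(packageVersion("fgsquant"))),
                     file.path(out, "run_config.yml"))
    writeLines(log_lines, file.path(out, "run_log.txt"))
    say("results written to %s", out)
  }
  result
}

#' @export
print.fgs_pipeline_result <- function(x, ...) {
  cat("FGS quantification pipeline result\n")
  cat(sprintf("  %d sections, %d animals\n", nrow(x$sections) / 2,
              length(unique(x$per_animal$animal_id))))
  for (ag in unique(x$per_animal$agent)) {
    t <- x$per_animal$tnr[x$per_animal$agent == ag]
    cat(sprintf("  %-5s TNR: mean %.3g, sd %.3g (n = %d animals)\n",
                ag, mean(t), sd(t), length(t)))
  }
  if (!is.null(x$section_cv)) {
    cat(sprintf("  per-animal section CV (NIR): median %.3g, max %.3g\n",
                median(x$section_cv$cv), max(x$section_cv$cv)))
  }
  cat("  ")
  print(x$comparison)
  invisible(x)
}
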