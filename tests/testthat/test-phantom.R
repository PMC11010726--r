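test_that("noiseless sections realize the specified contrast exactly", {
  spec <- noiseless_small(nir_contrast = 30)
  sec <- generate_section(spec, seed = 1)
  tumor <- sec$ground_truth_mask$pixels
  mirrored <- mirror_roi(sec$ground_truth_mask, spec$midline_col)$pixels
  expect_identical(mean(sec$nir[tumor]) / mean(sec$nir[mirrored]), 30)
  expect_identical(mean(sec$nuclear[tumor]), spec$nuclear_tumor_level)
  expect_identical(mean(sec$nuclear[mirrored]), spec$nuclear_background_level)

  flat <- generate_section(noiseless_small(nir_contrast = 1), seed = 1)
  expect_identical(max(flat$nir), min(flat$nir))
})

test_that("sections are a pure function of (spec, seed)", {
  spec <- small_spec()
  expect_identical(generate_section(spec, seed = 11),
                   generate_section(spec, seed = 11))
  s1 <- generate_section(spec, seed = 11)
  s2 <- generate_section(spec, seed = 12)
  expect_true(any(s1$nir != s2$nir))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_section(spec, seed = 5)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("generated sections satisfy the multi-channel invariants", {
  for (seed in 1:5) {
    sec <- generate_section(small_spec(gaussian_noise_sd = 0.3,
                                       ppix_color_jitter_sd = 0.2,
                                       infiltration_width = 4), seed = seed)
    expect_identical(dim(sec$nuclear), dim(sec$nir))
    expect_identical(dim(sec$rgb)[1:2], dim(sec$nuclear))
    expect_gte(min(sec$nuclear), 0)
    expect_gte(min(sec$nir), 0)
    expect_gte(min(sec$rgb), 0)
    expect_lte(max(sec$rgb), 1)
  }
})

test_that("invalid specifications are rejected", {
  expect_error(small_spec(tumor_center = c(48, 64)), class = "fgs_geometry_error")
  expect_error(small_spec(nuclear_tumor_level = 0), class = "fgs_parameter_error")
  expect_error(small_spec(nir_normal_level = -1), class = "fgs_parameter_error")
  expect_error(small_spec(nir_contrast = 0.5), class = "fgs_parameter_error")
  expect_error(small_spec(gaussian_noise_sd = -0.1), class = "fgs_parameter_error")
  expect_error(small_spec(ppix_tumor_color = c(1.2, 0, 0)), class = "fgs_parameter_error")
})

test_that("infiltration adds a decaying margin without touching the core", {
  sharp <- generate_section(noiseless_small(), seed = 1)
  soft <- generate_section(noiseless_small(infiltration_width = 6), seed = 1)
  core <- sharp$ground_truth_mask$pixels
  expect_identical(soft$nir[core], sharp$nir[core])
  band <- soft$nir > min(soft$nir) & !core
  expect_gt(sum(band), 0)
  expect_true(all(soft$nir[band] < max(soft$nir)))
})

test_that("cohorts draw per-animal contrast as specified", {
  spec <- small_spec(nir_contrast = 12)
  cohort <- generate_cohort(spec, n_animals = 10, sections_per_animal = 3,
                            between_animal_cv = 0, seed = 2)
  expect_length(cohort, 30L)
  rho <- vapply(cohort, `[[`, numeric(1), "ground_truth_contrast")
  expect_true(all(rho == 12))
  expect_length(unique(vapply(cohort, `[[`, character(1), "animal_id")), 10L)

  varied <- generate_cohort(spec, n_animals = 10, sections_per_animal = 1,
                            between_animal_cv = 0.5, seed = 2)
  rho_v <- vapply(varied, `[[`, numeric(1), "ground_truth_contrast")
  expect_length(unique(rho_v), 10L)
})

test_that("the between-animal contrast sampler attains the requested CV", {
  cohort <- generate_cohort(tiny_spec(ppix_color_jitter_sd = 0,
                                      gaussian_noise_sd = 0),
                            n_animals = 10000, sections_per_animal = 1,
                            between_animal_cv = 0.5, seed = 3)
  rho <- vapply(cohort, `[[`, numeric(1), "ground_truth_contrast")
  expect_lt(abs(sd(rho) / mean(rho) - 0.5) / 0.5, 0.05)
})

test_that("homogenate records pair tumor and normal per animal", {
  h <- generate_homogenates(5, true_tnr = 30, noise_cv = 0, seed = 1)
  expect_identical(nrow(h), 10L)
  expect_identical(as.integer(table(h$animal_id)), rep(2L, 5))
  for (id in unique(h$animal_id)) {
    expect_identical(homogenate_tnr(h, id), 30)
  }
})

test_that("homogenate TNR is recovered on average under noise", {
  h <- generate_homogenates(1000, true_tnr = 8, noise_cv = 0.2, seed = 4)
  tnrs <- vapply(unique(h$animal_id), function(id) homogenate_tnr(h, id),
                 numeric(1))
  expect_lt(abs(mean(tnrs) - 8) / 8, 0.05)
})

test_that("ex-vivo fragments follow the four-timepoint activation design", {
  ev <- generate_exvivo(3, 1, fold_gbm_vs_pre = 1.91, seed = 1)
  expect_setequal(unique(ev$timepoint_min), c(2, 5, 10, 120))
  expect_identical(unname(table(ev$sample_id))[1], 4L)
  expect_true(all(c("GBM", "PRE", "reference") %in% ev$group))
  # activation increases strictly with incubation time within every fragment
  for (id in unique(ev$sample_id)) {
    f <- ev[ev$sample_id == id, ]
    f <- f[order(f$timepoint_min), ]
    expect_true(all(diff(f$fluorescence_au) > 0))
  }
})

test_that("noiseless ex-vivo cohorts reproduce the specified fold exactly", {
  same <- generate_exvivo(4, 4, fold_gbm_vs_pre = 1, noise_cv = 0, seed = 1)
  for (tp in unique(same$timepoint_min)) {
    g <- same[same$timepoint_min == tp, ]
    expect_equal(mean(g$fluorescence_au[g$group == "GBM"]),
                 mean(g$fluorescence_au[g$group == "PRE"]))
  }
  ev <- generate_exvivo(4, 4, fold_gbm_vs_pre = 2, noise_cv = 0, seed = 1)
  nv <- normalize_exvivo(ev)
  last <- nv[nv$timepoint_min == 120, ]
  expect_identical(
    fold_difference(last$normalized_fluorescence[last$group == "GBM"],
                    last$normalized_fluorescence[last$group == "PRE"]),
    2)
})

test_that("generator parameter errors are classed", {
  expect_error(generate_cohort(small_spec(), n_animals = 0),
               class = "fgs_parameter_error")
  expect_error(generate_homogenates(5, true_tnr = 0.5),
               class = "fgs_parameter_error")
  expect_error(generate_exvivo(0, 1, 2), class = "fgs_parameter_error")
  expect_error(generate_exvivo(1, 1, 2, timepoints = numeric(0)),
               class = "fgs_parameter_error")
})
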