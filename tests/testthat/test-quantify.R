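uniform_case <- function(tumor_val = 30, normal_val = 1) {
  ch <- matrix(normal_val, 12, 12)
  tm <- nm <- matrix(FALSE, 12, 12)
  tm[2:5, 2:5] <- TRUE
  nm[8:11, 8:11] <- TRUE
  ch[tm] <- tumor_val
  list(ch = ch, tm = region_mask(tm, "tumor"), nm = region_mask(nm, "normal"))
}

test_that("TNR of uniform regions is the level ratio", {
  u <- uniform_case(30, 1)
  res <- compute_tnr(u$ch, u$tm, u$nm)
  expect_identical(res$tnr, 30)
  expect_identical(res$tumor_pixels, 16L)
  expect_identical(res$normal_pixels, 16L)
  expect_equal(res$tnr, res$tumor_mean / res$normal_mean)
})

test_that("ratio outputs are invariant to a common positive gain", {
  u <- uniform_case(17.3, 2.1)
  base <- compute_tnr(u$ch, u$tm, u$nm)$tnr
  # dyadic gains scale IEEE doubles exactly: bit-identical ratios
  for (gain in c(2, 64, 0.125)) {
    expect_identical(compute_tnr(u$ch * gain, u$tm, u$nm)$tnr, base)
  }
  expect_equal(compute_tnr(u$ch * 7, u$tm, u$nm)$tnr, base,
               tolerance = 1e-12)
  expect_identical(section_cv(c(8, 12) * 4), section_cv(c(8, 12)))
  expect_identical(mfi_ratio(500 * 2, 50 * 2), mfi_ratio(500, 50))
  expect_identical(fold_difference(c(2, 2) * 8, c(1, 1) * 8),
                   fold_difference(c(2, 2), c(1, 1)))
})

test_that("TNR guards reject invalid masks and zero normal signal", {
  u <- uniform_case()
  zero <- u$ch
  zero[u$nm$pixels] <- 0
  expect_error(compute_tnr(zero, u$tm, u$nm),
               class = "fgs_quantification_error")
  overlap <- u$tm
  expect_error(compute_tnr(u$ch, overlap, overlap), class = "fgs_mask_error")
  expect_error(compute_tnr(matrix(1, 3, 3), u$tm, u$nm),
               class = "fgs_geometry_error")
})

test_that("a tissue mask restricts the normal ROI", {
  u <- uniform_case(30, 1)
  u$ch[8:11, 8:9] <- 0  # non-tissue half of the normal ROI
  tissue <- region_mask(u$ch > 0.5, "tissue")
  res <- compute_tnr(u$ch, u$tm, u$nm, tissue_mask = tissue)
  expect_identical(res$normal_pixels, 8L)
  expect_identical(res$tnr, 30)
})

test_that("normalization to the normal mean is unit-mean and idempotent", {
  sec <- generate_section(small_spec(gaussian_noise_sd = 0.05), seed = 3)
  nm <- mirror_roi(sec$ground_truth_mask, sec$midline_col)
  norm <- normalize_to_normal(sec$nir, nm)
  expect_equal(mean(norm[nm$pixels]), 1)
  expect_equal(normalize_to_normal(norm, nm), norm)
  u <- uniform_case(30, 1)
  expect_identical(normalize_to_normal(u$ch, u$nm)[u$tm$pixels][1], 30)
})

test_that("the section CV follows the sample definition", {
  expect_identical(section_cv(c(10, 10, 10)), 0)
  expect_equal(section_cv(c(8, 12)), sqrt(8) / 10)
  expect_error(section_cv(5), class = "fgs_input_error")
  expect_error(section_cv(c(1, -1)), class = "fgs_input_error")
})

test_that("homogenate TNR normalizes to sample weight", {
  h <- data.frame(animal_id = rep("m1", 2), tissue = c("tumor", "normal"),
                  fluorescence_au = c(3000, 200), weight_mg = c(10, 20))
  expect_identical(homogenate_tnr(h, "m1"), 30)
  eq <- data.frame(animal_id = rep("m2", 2), tissue = c("tumor", "normal"),
                   fluorescence_au = c(100, 50), weight_mg = c(10, 5))
  expect_identical(homogenate_tnr(eq, "m2"), 1)
  bad <- h; bad$weight_mg[1] <- 0
  expect_error(homogenate_tnr(bad, "m1"), class = "fgs_input_error")
  expect_error(homogenate_tnr(h, "missing"), class = "fgs_input_error")
})

test_that("an alternative denominator column is honored", {
  h <- data.frame(animal_id = rep("m1", 2), tissue = c("tumor", "normal"),
                  fluorescence_au = c(3000, 200), weight_mg = c(10, 20),
                  protein_mg = c(5, 2))
  expect_identical(homogenate_tnr(h, "m1", denominator = "protein_mg"),
                   (3000 / 5) / (200 / 2))
})

test_that("MFI ratio behaves as a guarded quotient", {
  expect_identical(mfi_ratio(500, 50), 10)
  expect_identical(mfi_ratio(75, 75), 1)
  expect_error(mfi_ratio(500, 0), class = "fgs_input_error")
})

test_that("ex-vivo normalization removes between-experiment scale", {
  ev1 <- generate_exvivo(3, 2, 1.5, noise_cv = 0, seed = 1,
                         experiment_id = "expA")
  ev2 <- ev1
  ev2$experiment_id <- "expB"
  ev2$fluorescence_au <- ev2$fluorescence_au * 13  # different instrument scale
  both <- normalize_exvivo(rbind(ev1, ev2))
  a <- both[both$experiment_id == "expA", "normalized_fluorescence"]
  b <- both[both$experiment_id == "expB", "normalized_fluorescence"]
  expect_equal(a, b)
  ref <- both[both$group == "reference" & both$experiment_id == "expA", ]
  for (tp in unique(ref$timepoint_min)) {
    expect_equal(mean(ref$normalized_fluorescence[ref$timepoint_min == tp]), 1)
  }
  no_ref <- ev1[ev1$group != "reference", ]
  expect_error(normalize_exvivo(no_ref), class = "fgs_input_error")
})

test_that("fold difference is the ratio of group means", {
  expect_identical(fold_difference(c(2, 2), c(1, 1)), 2)
  expect_identical(fold_difference(c(3, 5), c(3, 5)), 1)
  expect_error(fold_difference(numeric(0), 1), class = "fgs_input_error")
  expect_error(fold_difference(c(1, -2), c(1, 1)), class = "fgs_input_error")
  ev <- generate_exvivo(5, 3, 1.91, noise_cv = 0, seed = 2)
  nv <- normalize_exvivo(ev)
  last <- nv[nv$timepoint_min == 120, ]
  expect_equal(
    fold_difference(last$normalized_fluorescence[last$group == "GBM"],
                    last$normalized_fluorescence[last$group == "PRE"]),
    1.91)
})

test_that("per-animal aggregation averages sections by default", {
  tab <- data.frame(
    section_id = c("s1", "s2", "s3"),
    animal_id = c("a1", "a1", "a2"),
    agent = "NIR",
    tumor_mean = c(30, 20, 10), normal_mean = c(1, 1, 1),
    tnr = c(30, 20, 10), tumor_px = c(100, 300, 100),
    normal_px = c(100, 300, 100))
  agg <- aggregate_tnr(tab)
  expect_identical(agg$tnr[agg$animal_id == "a1"], 25)
  pooled <- aggregate_tnr(tab, method = "pooled")
  expect_identical(pooled$tnr[pooled$animal_id == "a1"],
                   (30 * 100 + 20 * 300) / 400)
})
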