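uniform_rgb <- function(color, H = 6, W = 6) {
  array(rep(color, each = H * W), dim = c(H, W, 3))
}

test_that("median color is the channel-wise median over the mask", {
  img <- uniform_rgb(c(0.8, 0.2, 0.24))
  mask <- matrix(TRUE, 6, 6)
  expect_identical(median_color(img, mask), c(0.8, 0.2, 0.24))

  two <- array(0, dim = c(1, 2, 3))
  two[1, 2, ] <- 1
  expect_identical(median_color(two, matrix(TRUE, 1, 2)), c(0.5, 0.5, 0.5))

  # duplicating every pixel leaves the median unchanged
  set.seed(3)
  rnd <- array(runif(6 * 6 * 3), dim = c(6, 6, 3))
  dup <- array(0, dim = c(6, 12, 3))
  dup[, 1:6, ] <- rnd
  dup[, 7:12, ] <- rnd
  expect_identical(median_color(dup, matrix(TRUE, 6, 12)),
                   median_color(rnd, matrix(TRUE, 6, 6)))
})

test_that("the optimal projection is the normalized median difference", {
  v <- optimal_projection(c(0.80, 0.20, 0.24), c(0.16, 0.16, 0.47))
  expect_equal(as.numeric(v), c(0.9395, 0.0587, -0.3376), tolerance = 1e-3)
  expect_equal(sum(v^2), 1)
  # tumor median must project higher
  expect_gt(sum(v * c(0.80, 0.20, 0.24)), sum(v * c(0.16, 0.16, 0.47)))

  expect_identical(as.numeric(optimal_projection(c(0.5, 0.2, 0.2),
                                                 c(0.1, 0.2, 0.2))),
                   c(1, 0, 0))
  expect_error(optimal_projection(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3)),
               class = "fgs_separation_error")
})

test_that("the closed form agrees with a dense sphere-search oracle", {
  dirs <- fibonacci_sphere(100000)
  set.seed(42)
  for (i in 1:20) {
    mt <- runif(3)
    mn <- runif(3)
    if (all(mt == mn)) next
    v <- optimal_projection(mt, mn)
    vb <- brute_projection(mt, mn, dirs)
    expect_lt(angle_deg(as.numeric(v), vb), 1)
  }
})

test_that("the returned projection attains the maximal median separation", {
  set.seed(7)
  mt <- c(0.7, 0.3, 0.2); mn <- c(0.2, 0.25, 0.6)
  v <- optimal_projection(mt, mn)
  sep <- abs(sum(v * mt) - sum(v * mn))
  rand <- matrix(rnorm(3e4), ncol = 3)
  rand <- rand / sqrt(rowSums(rand^2))
  seps <- abs(rand %*% (mt - mn))
  expect_gte(sep, max(seps))
})

test_that("the mean projection averages unit vectors and renormalizes", {
  v <- projection_vector(c(0.2, -0.5, 0.6))
  expect_equal(as.numeric(mean_projection(list(v, v, v))), as.numeric(v))
  m <- mean_projection(list(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(as.numeric(m), c(sqrt(0.5), sqrt(0.5), 0))
  expect_error(mean_projection(list(c(1, 0, 0), c(-1, 0, 0))),
               class = "fgs_aggregation_error")
  expect_error(mean_projection(list()), class = "fgs_input_error")
})

test_that("projection to grayscale is a clamped scalar product", {
  img <- uniform_rgb(c(0.5, 0.3, 0.9), 2, 2)
  expect_identical(project_to_gray(img, c(1, 0, 0))[1, 1], 0.5)
  # linearity before clamping: project(alpha * p) = alpha * project(p)
  v <- projection_vector(c(0.6, 0.3, 0.74))
  p <- c(0.2, 0.5, 0.1)
  expect_equal(project_to_gray(uniform_rgb(p / 2, 1, 1), v)[1, 1],
               0.5 * project_to_gray(uniform_rgb(p, 1, 1), v)[1, 1])
  # negative products clamp to zero...
  neg <- uniform_rgb(c(0, 0, 1), 2, 2)
  expect_identical(project_to_gray(neg, c(1, 0, -1))[1, 1], 0)
  # ...unless offset mode is chosen
  off <- project_to_gray(neg, c(1, 0, -1), mode = "offset")
  expect_identical(min(off), 0)
})

test_that("projected PPIX TNR matches the closed-form dot-product ratio", {
  mt <- c(0.80, 0.20, 0.24)
  mn <- c(0.16, 0.16, 0.47)
  H <- 10; W <- 10
  img <- uniform_rgb(mn, H, W)
  tm <- nm <- matrix(FALSE, H, W)
  tm[2:4, 2:4] <- TRUE; nm[7:9, 7:9] <- TRUE
  for (k in 1:3) { plane <- img[, , k]; plane[tm] <- mt[k]; img[, , k] <- plane }
  v <- optimal_projection(mt, mn)
  res <- ppix_tnr(img, region_mask(tm, "tumor"), region_mask(nm, "normal"), v)
  expect_equal(res$tnr,
               max(0, sum(v * mt)) / max(0, sum(v * mn)))
  expect_identical(res$agent, "PPIX")
})

test_that("projected TNR increases as the tumor color moves along +v", {
  mn <- c(0.16, 0.16, 0.47)
  mt0 <- c(0.55, 0.25, 0.35)
  v <- optimal_projection(mt0, mn)
  H <- 8; W <- 8
  tm <- nm <- matrix(FALSE, H, W)
  tm[2:3, 2:3] <- TRUE; nm[6:7, 6:7] <- TRUE
  tnrs <- vapply(seq(0, 0.18, length.out = 10), function(step) {
    mt <- pmin(1, pmax(0, mt0 + step * as.numeric(v)))
    img <- uniform_rgb(mn, H, W)
    for (k in 1:3) { p <- img[, , k]; p[tm] <- mt[k]; img[, , k] <- p }
    ppix_tnr(img, region_mask(tm, "tumor"), region_mask(nm, "normal"), v)$tnr
  }, numeric(1))
  expect_true(all(diff(tnrs) > 0))
})

test_that("discriminative projection beats luminance on hue-only contrast", {
  # tumor and background matched in luminance, separated in hue
  lum <- c(0.299, 0.587, 0.114)
  tumor_col <- c(0.60, 0.20, 0.50)
  bg_col <- c(0.20, 0.40, 0.25)
  bg_col <- bg_col * sum(lum * tumor_col) / sum(lum * bg_col)
  expect_equal(sum(lum * tumor_col), sum(lum * bg_col))
  spec <- small_spec(ppix_tumor_color = tumor_col,
                     ppix_background_color = bg_col,
                     ppix_color_jitter_sd = 0.02)
  sec <- generate_section(spec, seed = 5)
  tm <- sec$ground_truth_mask
  nm <- mirror_roi(tm, sec$midline_col)
  v <- optimal_projection(median_color(sec$rgb, tm), median_color(sec$rgb, nm))
  proj_tnr <- ppix_tnr(sec$rgb, tm, nm, v)$tnr
  lum_tnr <- ppix_tnr(sec$rgb, tm, nm, projection_vector(lum))$tnr
  expect_gt(proj_tnr, lum_tnr)
})

test_that("nonnegative-constrained projections clamp negative components", {
  v <- optimal_projection(c(0.8, 0.2, 0.24), c(0.16, 0.16, 0.47),
                          nonnegative = TRUE)
  expect_true(all(as.numeric(v) >= 0))
  expect_equal(sum(v^2), 1)
})
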