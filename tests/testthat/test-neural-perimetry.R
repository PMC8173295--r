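test_that("coverage map equals the unit-amplitude Gaussian profile", {
  r <- vf_raster(10, 0.5)
  cov <- coverage_from_estimates(tibble::tibble(x0 = 0, y0 = 0, sigma = 2), r)
  co <- raster_coords(r)
  origin <- which(co$px == 0 & co$py == 0)
  at2 <- which(co$px == 2 & co$py == 0)
  expect_equal(cov$values[origin], 1)
  expect_equal(cov$values[at2], exp(-0.5), tolerance = 1e-12)
  expect_true(all(cov$values >= 0 & cov$values <= 1))

  # max over voxels is idempotent for duplicated voxels
  cov2 <- coverage_from_estimates(
    tibble::tibble(x0 = c(0, 0), y0 = c(0, 0), sigma = c(2, 2)), r)
  expect_identical(cov2$values, cov$values)
})

test_that("coverage matches a brute-force per-pixel maximum oracle", {
  r <- vf_raster(10, 1)
  set.seed(11)
  est <- tibble::tibble(x0 = runif(5, -8, 8), y0 = runif(5, -8, 8),
                        sigma = runif(5, 0.5, 4))
  cov <- coverage_from_estimates(est, r)
  co <- raster_coords(r)
  oracle <- numeric(nrow(co))
  for (px in seq_len(nrow(co))) {
    best <- 0
    for (v in seq_len(5)) {
      g <- exp(-((co$px[px] - est$x0[v])^2 + (co$py[px] - est$y0[v])^2) /
                 (2 * est$sigma[v]^2))
      if (g > best) best <- g
    }
    oracle[px] <- best
  }
  expect_equal(cov$values, oracle, tolerance = 1e-12)
})

test_that("empty estimate sets give an all-zero map with a warning", {
  expect_warning(
    cov <- coverage_from_estimates(
      tibble::tibble(x0 = numeric(), y0 = numeric(), sigma = numeric()),
      vf_raster(10, 1)),
    "all-zero")
  expect_true(all(cov$values == 0))
})

test_that("downsampling takes cell maxima and renormalises globally", {
  r <- vf_raster(45, 0.5)
  grid <- make_302_grid()
  # uniform coverage -> all locations 1 after division by the global max
  cov <- coverage_from_estimates(tibble::tibble(x0 = 0, y0 = 0, sigma = 2), r)
  cov$values <- rep(0.8, length(cov$values))
  np <- downsample_to_grid(cov, grid)
  expect_true(all(np$value == 1))
  expect_true(all(np$value_raw == 0.8))

  # coverage concentrated inside one cell -> that location 1, others 0
  co <- raster_coords(r)
  cov$values <- as.numeric(abs(co$px - 9) < 2 & abs(co$py - 15) < 2) * 0.6
  np <- downsample_to_grid(cov, grid)
  hit <- np$x_deg == 9 & np$y_deg == 15
  expect_equal(np$value[hit], 1)
  expect_true(all(np$value[!hit] == 0))

  # raster that does not cover the perimetric grid is rejected
  small <- coverage_from_estimates(tibble::tibble(x0 = 0, y0 = 0, sigma = 2),
                                   vf_raster(20, 0.5))
  expect_error(downsample_to_grid(small, grid), "outside the raster")
})

test_that("cell maxima agree with a brute-force cell scan", {
  r <- vf_raster(45, 1)
  est <- tibble::tibble(x0 = c(5, -14), y0 = c(3, -20), sigma = c(3, 5))
  cov <- coverage_from_estimates(est, r)
  grid <- make_302_grid()
  np <- downsample_to_grid(cov, grid)
  co <- raster_coords(r)
  oracle <- vapply(seq_len(nrow(grid)), function(i) {
    best <- 0
    for (px in seq_len(nrow(co))) {
      if (co$px[px] >= grid$x_deg[i] - 3 && co$px[px] < grid$x_deg[i] + 3 &&
          co$py[px] >= grid$y_deg[i] - 3 && co$py[px] < grid$y_deg[i] + 3 &&
          cov$values[px] > best) best <- cov$values[px]
    }
    best
  }, 1)
  expect_equal(np$value_raw, oracle, tolerance = 1e-12)
  expect_equal(np$value, oracle / max(oracle), tolerance = 1e-12)
})

test_that("coverage is monotone in the voxel set", {
  r <- vf_raster(20, 1)
  set.seed(3)
  base <- tibble::tibble(x0 = runif(6, -15, 15), y0 = runif(6, -15, 15),
                         sigma = runif(6, 1, 4))
  added <- rbind(base, tibble::tibble(x0 = 2, y0 = 2, sigma = 3))
  c1 <- coverage_from_estimates(base, r)
  c2 <- coverage_from_estimates(added, r)
  expect_true(all(c2$values >= c1$values - 1e-15))
})

test_that("binarisation is strict and nests across thresholds", {
  grid <- make_302_grid()
  v <- rep(0.1, 76); v[2:4] <- c(0.49, 0.5, 0.51); v[10] <- 1
  np <- neural_perimetry_from_values(v, grid)
  b <- binarize_coverage(np, 0.5)
  expect_identical(b$covered[2:4], c(0L, 0L, 1L))
  expect_error(binarize_coverage(np, 0))
  expect_error(binarize_coverage(np, 1))

  # monotone nesting over random maps: Ret+ at 0.75 subset of Ret+ at 0.25
  set.seed(8)
  for (i in 1:20) {
    vv <- runif(76)
    m <- neural_perimetry_from_values(vv, grid)
    hi <- binarize_coverage(m, 0.75)$covered
    lo <- binarize_coverage(m, 0.25)$covered
    expect_true(all(lo[hi == 1] == 1))
  }

  # all-zero map binarises to all Ret-
  z <- binarize_coverage(neural_perimetry_from_values(rep(0, 76), grid))
  expect_true(all(z$covered == 0))
})

test_that("a healthy tiled hemisphere covers every non-blind-spot location", {
  vox <- simulate_voxels(NULL, n_voxels = 800, seed = 21)
  cov <- coverage_from_estimates(vox, vf_raster(45, 0.5))
  np <- binarize_coverage(downsample_to_grid(cov, make_302_grid()))
  expect_true(all(np$covered[!np$blind_spot] == 1))
})
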