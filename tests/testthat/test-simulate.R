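test_that("region primitives contain and measure depth correctly", {
  hl <- region_hemifield("left")
  expect_true(region_contains(hl, -5, 3))
  expect_false(region_contains(hl, 5, 3))
  expect_equal(region_depth(hl, -5, 3), 5)
  expect_equal(region_depth(hl, 5, 3), 0)
  q <- region_quadrant("upper_right")
  expect_true(region_contains(q, 2, 7))
  expect_equal(region_depth(q, 2, 7), 2)
  ci <- region_circle(10, 0, 4)
  expect_true(region_contains(ci, 12, 0))
  expect_equal(region_depth(ci, 10, 0), 4)
  u <- region_union(hl, ci)
  expect_true(all(region_contains(u, c(-5, 12), c(0, 0))))
  s <- region_sector(45, 135)
  expect_true(region_contains(s, 0, 5))
  expect_false(region_contains(s, 5, 0))
})

test_that("lesion specs validate islands and erode by the reserve margin", {
  expect_error(lesion_spec(region_hemifield("left"),
                           tibble::tibble(x = 5, y = 0, radius = 2)),
               "inside the scotoma")
  les <- lesion_spec(region_hemifield("left"),
                     tibble::tibble(x = -10, y = 10, radius = 3),
                     reserve_margin = 4)
  expect_true(in_behavioral_scotoma(les, -2, 0))
  expect_false(in_neural_scotoma(les, -2, 0))   # inside the margin band
  expect_true(in_neural_scotoma(les, -20, -20)) # deep scotoma
  expect_false(in_neural_scotoma(les, -10, 10)) # island centre
  expect_false(in_neural_scotoma(les, 5, 5))    # intact field
})

test_that("voxel simulation removes exactly the neurally silent centres", {
  # empty lesion: nothing removed
  v0 <- simulate_voxels(NULL, n_voxels = 200, seed = 1)
  expect_true(all(v0$surviving))
  # full-hemifield scotoma, no margin, no islands: no survivors on that side
  les <- lesion_spec(region_hemifield("left"))
  v1 <- simulate_voxels(les, n_voxels = 300, seed = 2)
  expect_false(any(v1$surviving & v1$x0 < 0))
  expect_true(all(v1$surviving[v1$x0 > 0]))
  # island survival matches a brute-force point-in-region test
  isl <- tibble::tibble(x = -10, y = 5, radius = 3)
  les2 <- lesion_spec(region_hemifield("left"), isl)
  v2 <- simulate_voxels(les2, n_voxels = 500, seed = 3)
  oracle <- v2$x0 > 0 |
    ((v2$x0 - isl$x)^2 + (v2$y0 - isl$y)^2 <= isl$radius^2)
  expect_identical(v2$surviving, oracle)
  # sizes grow with eccentricity
  expect_true(all(diff(v2$sigma[order(sqrt(v2$x0^2 + v2$y0^2))]) >= 0))
})

test_that("time-series simulation is exact at infinite SNR and seeded", {
  aps <- coarse_apertures()
  truth <- tibble::tibble(voxel_id = c("a", "b"), x0 = c(3, -10),
                          y0 = c(2, 5), sigma = c(1, 3), beta = c(2, 1),
                          baseline = c(100, 0))
  ts <- simulate_timeseries(truth, aps, snr = Inf)
  pred_a <- predict_timeseries(3, 2, 1, aps)
  expect_equal(ts$signal[ts$voxel_id == "a"], 2 * pred_a + 100,
               tolerance = 1e-12)
  t1 <- simulate_timeseries(truth, aps, snr = 3, seed = 5)
  t2 <- simulate_timeseries(truth, aps, snr = 3, seed = 5)
  expect_identical(t1, t2)
  t3 <- simulate_timeseries(truth, aps, snr = 3, seed = 6)
  expect_false(identical(t1$signal, t3$signal))
})

test_that("hill-of-vision perimetry declines with eccentricity and zeroes
           the scotoma", {
  g <- make_302_grid()
  m <- simulate_perimetry(NULL, g, noise_sd = 0)
  keep <- !g$blind_spot
  ord <- order(g$ecc[keep])
  db <- m$db[keep][ord]
  ecc <- g$ecc[keep][ord]
  expect_true(all(diff(db)[diff(ecc) > 0] < 0))
  expect_equal(m$db[g$blind_spot], 0)

  les <- lesion_spec(region_hemifield("left"))
  ms <- simulate_perimetry(les, g, noise_sd = 0)
  expect_identical(sum(ms$db == 0), 38L + 1L) # hemifield + blind spot
  expect_true(all(ms$db[g$x_deg < 0] == 0))

  a <- simulate_perimetry(les, g, seed = 4)
  b <- simulate_perimetry(les, g, seed = 4)
  expect_identical(a$db, b$db)
})

test_that("post-training maps add category effects with truncation report", {
  g <- make_302_grid()
  les <- lesion_spec(region_hemifield("left"), reserve_margin = 7)
  pre <- simulate_perimetry(les, g, noise_sd = 0)
  cats <- ifelse(g$blind_spot, "excluded",
                 ifelse(g$x_deg > 0, "HumP_RetP",
                        ifelse(g$x_deg == -3, "HumM_RetP", "HumM_RetM")))
  # zero effects -> identical map
  post0 <- simulate_post_training(pre, cats,
                                  effect_means = c(HumP_RetP = 0,
                                                   HumM_RetP = 0,
                                                   HumM_RetM = 0),
                                  effect_sds = c(HumP_RetP = 0,
                                                 HumM_RetP = 0,
                                                 HumM_RetM = 0))
  expect_identical(post0$db, pre$db)
  # deterministic reserve-only effect
  post10 <- simulate_post_training(pre, cats,
                                   effect_means = c(HumP_RetP = 0,
                                                    HumM_RetP = 10,
                                                    HumM_RetM = 0),
                                   effect_sds = c(HumP_RetP = 0,
                                                  HumM_RetP = 0,
                                                  HumM_RetM = 0))
  ch <- change_map(pre, post10)
  expect_true(all(ch$change[cats == "HumM_RetP"] == 10))
  expect_true(all(ch$change[cats != "HumM_RetP" & !ch$excluded] == 0))
  expect_true(!is.null(attr(post10, "truncation_bias")))
})

test_that("zero-inflated mixture hits the target category mean", {
  # ~10,000 draws: all-reserve truth over 135 replicate maps
  g <- make_302_grid()
  pre <- perimetry_map(rep(0, 76), g)
  cats <- ifelse(g$blind_spot, "excluded", "HumM_RetP")
  draws <- unlist(lapply(1:135, function(i) {
    post <- simulate_post_training(pre, cats, mixture = TRUE, seed = 9000 + i)
    change_map(pre, post)$change[!g$blind_spot]
  }))
  expect_gt(length(draws), 10000 - 200)
  expect_lt(abs(mean(draws) - 1.34), 0.2)
  improved <- draws[draws >= 1]
  expect_lt(abs(mean(improved) - 9.12), 0.5)
})

test_that("GAS simulation respects the scale and the linkage", {
  n <- c(0, 3, 6, 9, 12)
  g0 <- simulate_gas(n, noise_sd = 0)
  a <- gas_association(tibble::tibble(n_reserve_improved = n, gas = g0$gas))
  expect_equal(a$r, 1) # noise-free linkage is exact
  expect_true(all(g0$gas >= -3 & g0$gas <= 2))
  gbig <- simulate_gas(c(0, 1000), noise_sd = 0)
  expect_true(all(gbig$gas <= 2)) # clipped to the 6-point scale
  # slope 0: correlation centred on zero over replicates
  rs <- vapply(1:30, function(i) {
    nn <- seq(0, 20, length.out = 10)
    gg <- simulate_gas(nn, slope = 0, seed = i)
    suppressWarnings(gas_association(
      tibble::tibble(n_reserve_improved = nn, gas = gg$gas))$r)
  }, 1)
  expect_lt(abs(mean(rs)), 0.2)
})

test_that("cohorts are deterministic, carry truth, and expose seeds", {
  c1 <- simulate_cohort(n_patients = 4, seed = 77)
  c2 <- simulate_cohort(n_patients = 4, seed = 77)
  expect_identical(c1$locations, c2$locations)
  expect_identical(c1$patients$gas, c2$patients$gas)
  expect_identical(length(c1$params$sub_seeds), 4L)
  expect_true(all(c("category_true", "coverage", "db_pre", "db_post",
                    "change") %in% names(c1$locations)))
  # change column is exactly post - pre
  expect_equal(c1$locations$change,
               c1$locations$db_post - c1$locations$db_pre)
  c3 <- simulate_cohort(n_patients = 4, seed = 78)
  expect_false(identical(c1$locations$db_post, c3$locations$db_post))
})

test_that("pipeline classification reproduces cohort ground truth without
           noise", {
  co <- simulate_cohort(n_patients = 3, seed = 5, noise_sd = 0)
  cl <- classify_cohort(co, drop_rare = FALSE)
  expect_identical(as.character(cl$category),
                   as.character(cl$category_true))
})
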