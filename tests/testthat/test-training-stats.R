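toy_effect_data <- function() {
  tibble::tibble(
    patient = 1,
    category = c("HumM_RetP", "HumM_RetP", "HumP_RetP", "HumM_RetM"),
    change = c(2, 4, 1, 0)
  )
}

test_that("category means match hand arithmetic", {
  eff <- category_effects(toy_effect_data(), pooling = "pooled_locations")
  m <- setNames(eff$mean_change, as.character(eff$category))
  expect_equal(unname(m["HumM_RetP"]), 3)
  expect_equal(unname(m["HumP_RetP"]), 1)
  expect_equal(unname(m["HumM_RetM"]), 0)
  expect_true(is.na(m["HumP_RetM"]))
  expect_identical(eff$n[eff$category == "HumP_RetM"], 0L)
})

test_that("all-zero changes give zero means, and changed_only empties", {
  d <- toy_effect_data()
  d$change <- 0
  eff <- category_effects(d)
  expect_true(all(eff$mean_change[eff$n > 0] == 0))
  eff2 <- category_effects(d, variant = "changed_only")
  expect_true(all(eff2$n == 0))
})

test_that("changed_only keeps >= 1 dB (inclusive) or nonzero by flag", {
  d <- tibble::tibble(patient = 1, category = "HumM_RetP",
                      change = c(0, 0.5, 1, 3, -2))
  eff <- category_effects(d, variant = "changed_only")
  expect_identical(eff$n_locations[eff$category == "HumM_RetP"], 2L)
  expect_equal(eff$mean_change[eff$category == "HumM_RetP"], 2)
  effnz <- category_effects(d, variant = "changed_only",
                            changed_rule = "nonzero")
  expect_identical(effnz$n_locations[effnz$category == "HumM_RetP"], 4L)
})

test_that("pooling modes differ as documented and SE = SD/sqrt(n)", {
  d <- tibble::tibble(
    patient = rep(1:2, c(3, 1)),
    category = "HumM_RetP",
    change = c(1, 2, 3, 10)
  )
  pooled <- category_effects(d, pooling = "pooled_locations")
  i <- pooled$category == "HumM_RetP"
  expect_equal(pooled$mean_change[i], 4)
  expect_equal(pooled$se[i], sd(c(1, 2, 3, 10)) / 2)
  perpat <- category_effects(d) # patient means 2 and 10
  j <- perpat$category == "HumM_RetP"
  expect_equal(perpat$mean_change[j], 6)
  expect_equal(perpat$se[j], sd(c(2, 10)) / sqrt(2))
  expect_identical(perpat$n[j], 2L)
})

cohort_like <- function(n_pat = 6, shift_reserve = 0, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_pat), function(p) {
    tibble::tibble(
      patient = p,
      category = rep(c("HumM_RetP", "HumP_RetP", "HumM_RetM"),
                     times = c(10, 20, 10)),
      change = rnorm(40, 0.5, 0.5) +
        rep(c(shift_reserve, 0, 0), times = c(10, 20, 10))
    )
  })
}

test_that("permutation test is reproducible and detects extreme separation", {
  d <- cohort_like(shift_reserve = 10, seed = 2)
  p1 <- permutation_test_categories(d, n_iterations = 500, seed = 11)
  p2 <- permutation_test_categories(d, n_iterations = 500, seed = 11)
  expect_identical(tidy(p1), tidy(p2)) # bit-reproducible under the seed
  # extreme separation hits the +1-smoothed floor
  expect_equal(p1$comparisons$p_value, rep(1 / 501, 2))
  expect_identical(glance(p1)$n_iterations, 500)
})

test_that("permutation guards: single category, few iterations", {
  d <- tibble::tibble(patient = 1, category = "HumM_RetP", change = 1:10)
  expect_error(permutation_test_categories(d), "two non-empty")
  d2 <- cohort_like(seed = 3)
  expect_warning(permutation_test_categories(d2, n_iterations = 50, seed = 1),
                 "100")
})

test_that("p-values are shift-invariant and scale-equivariant", {
  d <- cohort_like(shift_reserve = 0.4, seed = 4)
  base <- permutation_test_categories(d, n_iterations = 400, seed = 5)
  d_shift <- d; d_shift$change <- d$change + 100
  shifted <- permutation_test_categories(d_shift, n_iterations = 400,
                                         seed = 5)
  expect_equal(shifted$comparisons$p_value, base$comparisons$p_value)
  expect_equal(shifted$comparisons$observed_diff,
               base$comparisons$observed_diff)
  d_scale <- d; d_scale$change <- d$change * 3
  scaled <- permutation_test_categories(d_scale, n_iterations = 400,
                                        seed = 5)
  expect_equal(scaled$comparisons$p_value, base$comparisons$p_value)
  expect_equal(scaled$comparisons$observed_diff,
               3 * base$comparisons$observed_diff)
})

test_that("identity permutation reproduces the observed difference", {
  d <- cohort_like(seed = 6)
  pt <- permutation_test_categories(d, n_iterations = 200, seed = 7)
  eff <- category_effects(d)
  m <- setNames(eff$mean_change, as.character(eff$category))
  expect_equal(pt$comparisons$observed_diff[1],
               unname(m["HumM_RetP"] - m["HumP_RetP"]), tolerance = 1e-12)
})

test_that("GAS association recovers hand-computed correlations", {
  # perfectly collinear
  d <- tibble::tibble(n_reserve_improved = 1:5, gas = seq(-2, 2))
  a <- gas_association(d)
  expect_equal(a$r, 1)
  expect_equal(a$slope, 1)
  # zero-variance predictor
  d0 <- tibble::tibble(n_reserve_improved = rep(3, 5), gas = rnorm(5))
  expect_warning(a0 <- gas_association(d0), "zero variance")
  expect_true(is.na(a0$r))
  expect_true(glance(a0)$degenerate)
  # 5-point dataset against the closed-form Pearson formula
  x <- c(0, 2, 3, 7, 11); y <- c(-2, -1, 0.5, 0.5, 2)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  a5 <- gas_association(tibble::tibble(n_reserve_improved = x, gas = y))
  expect_equal(a5$r, r_hand, tolerance = 1e-12)
  expect_equal(a5$slope, unname(coef(lm(y ~ x))[2]), tolerance = 1e-12)
  expect_error(gas_association(tibble::tibble(n_reserve_improved = 1:2,
                                              gas = 1:2)), "3 patients")
})

test_that("trained vs untrained comparison behaves at the boundaries", {
  set.seed(9)
  same <- rnorm(10, 0.5, 0.2)
  cmp0 <- pre_post_reliability_compare(same, same, n_iterations = 500,
                                       seed = 1)
  expect_equal(cmp0$difference, 0)
  expect_gt(cmp0$p_value, 0.2)
  expect_error(pre_post_reliability_compare(1, c(0.1, 0.2)), "two patients")
  expect_error(pre_post_reliability_compare(c(1, 2), 0.1), "two patients")
})

test_that("training is detected against test-retest drift", {
  # scaled-down power check: per-patient mean changes at the published
  # cohort scales (trained 0.90, untrained drift 0.11)
  detected <- 0
  for (i in 1:20) {
    set.seed(100 + i)
    trained <- rnorm(27, 0.90, 0.52)
    untrained <- rnorm(6, 0.11, 0.39)
    cmp <- pre_post_reliability_compare(trained, untrained,
                                        n_iterations = 300, seed = i)
    detected <- detected + (cmp$p_value < 0.05)
  }
  expect_gte(detected, 16) # >= 80% of replicates
})

test_that("reliability index t-tests report one row per index", {
  set.seed(10)
  pre <- tibble::tibble(fixation_losses = runif(8, 0, 0.2),
                        blindspot_fp = runif(8, 0, 0.1))
  post <- tibble::tibble(
    fixation_losses = pre$fixation_losses + 0.01 + rnorm(8, 0, 0.01),
    blindspot_fp = pre$blindspot_fp) # constant difference -> NA statistics
  out <- reliability_ttests(pre, post)
  expect_identical(out$index, c("fixation_losses", "blindspot_fp"))
  ref <- t.test(pre$fixation_losses, post$fixation_losses, paired = TRUE)
  expect_equal(out$t[1], unname(ref$statistic))
  expect_equal(out$p_value[1], ref$p.value)
  expect_true(is.na(out$t[2]))
})
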