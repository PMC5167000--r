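test_that("ols_slope is exact on degenerate and collinear input", {
  flat <- ols_slope(c(2, 5, 8), c(2.5, 2.5, 2.5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 2.5)

  x <- c(2, 4, 6, 8)
  line <- ols_slope(x, 3.0 - 0.05 * x)
  expect_equal(line$slope, -0.05, tolerance = 1e-14)
  expect_equal(line$intercept, 3.0, tolerance = 1e-14)

  expect_error(ols_slope(c(1, 2), c(1, 2)), "3 points")
  expect_error(ols_slope(c(3, 3, 3), c(1, 2, 3)), "constant")
})

test_that("ols_slope matches the normal-equations oracle on random inputs", {
  set.seed(11)
  for (i in 1:250) {
    n <- sample(3:40, 1)
    x <- runif(n, 0, 30)
    y <- 3 + rnorm(1, 0, 0.1) * x + rnorm(n, 0, 0.3)
    fit <- ols_slope(x, y)
    ora <- ols_oracle(x, y)
    expect_equal(fit$slope, ora$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, ora$intercept, tolerance = 1e-10)
  }
})

test_that("noise-free rate estimation has exact slopes and zero-width CIs", {
  sim <- generate_cohort(line_config(rate_early = -0.072, rate_late = -0.02))
  rates <- estimate_rates(sim$cohort, sim$thickness, n_boot = 300, seed = 4)
  early <- rates[rates$stage == "Early", ]
  expect_equal(early$slope, -0.072, tolerance = 1e-10)
  expect_equal(early$ci_low, early$ci_high, tolerance = 1e-10)
  expect_equal(early$ci_low, -0.072, tolerance = 1e-10)
})

test_that("rate estimates are reproducible and stable under added regions", {
  sim <- generate_cohort(tiny_config())
  a <- estimate_rates(sim$cohort, sim$thickness, n_boot = 400, seed = 9)
  b <- estimate_rates(sim$cohort, sim$thickness, n_boot = 400, seed = 9)
  expect_identical(a, b)
  # per-region seed derivation: dropping columns leaves the rest unchanged
  sub <- estimate_rates(sim$cohort, sim$thickness[, 2:3, drop = FALSE],
                        n_boot = 400, seed = 9)
  merged <- merge(sub, a, by = c("region", "hemisphere", "stage"))
  expect_equal(merged$ci_low.x, merged$ci_low.y, tolerance = 1e-14)
  expect_equal(merged$ci_high.x, merged$ci_high.y, tolerance = 1e-14)
})

test_that("rate estimation rejects undersized inputs", {
  sim <- generate_cohort(tiny_config(n_early = 2, n_late = 10))
  expect_error(estimate_rates(sim$cohort, sim$thickness, n_boot = 300),
               "at least 3")
  sim2 <- generate_cohort(tiny_config())
  expect_error(estimate_rates(sim2$cohort, sim2$thickness, n_boot = 100),
               "n_boot")
})

test_that("percentile CI brackets the point estimate on non-degenerate data", {
  sim <- generate_cohort(tiny_config(seed = 13))
  rates <- estimate_rates(sim$cohort, sim$thickness, n_boot = 500, seed = 13)
  expect_true(all(rates$ci_low <= rates$slope + 1e-12))
  expect_true(all(rates$slope <= rates$ci_high + 1e-12))
  expect_true(all(rates$n >= 3))
})

test_that("slope recovery approaches the generating rate as n grows", {
  sim <- generate_cohort(sim_config(n_early = 5000, n_late = 0,
                                    regions = "G_insular_short",
                                    hemispheres = "left",
                                    rate_early = -0.072, noise_sd = 0.1,
                                    seed = 17))
  rates <- estimate_rates(sim$cohort, sim$thickness, stage = "Early",
                          n_boot = 200, seed = 17)
  # SE of the slope ~ noise / (sd(duration) * sqrt(n)) ~ 0.00064 here
  expect_equal(rates$slope, -0.072, tolerance = 0.005 / 0.072)
})

test_that("noise-free slope difference follows the CI sign rule exactly", {
  sim <- generate_cohort(line_config(rate_early = -0.07, rate_late = -0.02))
  d <- slope_difference(sim$cohort, sim$thickness, "G_insular_short", "left",
                        n_boot = 300, seed = 3)
  expect_equal(d$difference, -0.05, tolerance = 1e-10)
  expect_equal(d$ci_low, -0.05, tolerance = 1e-10)
  expect_equal(d$ci_high, -0.05, tolerance = 1e-10)
  expect_true(d$significant_early)
  expect_false(d$significant_late)

  same <- generate_cohort(line_config(rate_early = -0.03, rate_late = -0.03,
                                      baseline_early = 2.7,
                                      baseline_late = 2.7))
  d0 <- slope_difference(same$cohort, same$thickness, "G_insular_short",
                         "left", n_boot = 300, seed = 3)
  expect_equal(d0$difference, 0, tolerance = 1e-10)
  expect_false(d0$significant_early || d0$significant_late)
})

test_that("swapping the stage labels negates the slope difference", {
  sim <- generate_cohort(line_config())
  fwd <- slope_difference(sim$cohort, sim$thickness, "G_insular_short",
                          "left", n_boot = 300, seed = 8)
  flipped <- sim$cohort
  flipped$stage <- ifelse(sim$cohort$stage == "Early", "Late", "Early")
  rev <- slope_difference(flipped, sim$thickness, "G_insular_short", "left",
                          n_boot = 300, seed = 8)
  expect_equal(rev$difference, -fwd$difference, tolerance = 1e-12)
  expect_identical(rev$significant_early, fwd$significant_late)
  expect_identical(rev$significant_late, fwd$significant_early)
})

test_that("significance flags are mutually exclusive and imply 0 outside the CI", {
  for (seed in 1:15) {
    sim <- generate_cohort(tiny_config(
      regions = "G_cuneus", rate_early = -0.06, rate_late = -0.01,
      noise_sd = 0.12, seed = 400 + seed))
    d <- slope_difference(sim$cohort, sim$thickness, "G_cuneus", "left",
                          n_boot = 250, seed = seed)
    expect_false(d$significant_early && d$significant_late)
    if (d$significant_early || d$significant_late) {
      expect_true(d$ci_high < 0 || d$ci_low > 0)
    }
    expect_lte(d$ci_low, d$ci_high)
  }
})

test_that("bootstrap CI width shrinks roughly as 1 / sqrt(n)", {
  width_at <- function(n, seed) {
    sim <- generate_cohort(sim_config(
      n_early = n, n_late = 10, regions = "G_cuneus", hemispheres = "left",
      rate_early = -0.03, noise_sd = 0.15, seed = seed))
    r <- estimate_rates(sim$cohort, sim$thickness, stage = "Early",
                        n_boot = 500, seed = seed)
    r$ci_high - r$ci_low
  }
  w_small <- mean(vapply(1:8, function(s) width_at(100, 600 + s), 0))
  w_big <- mean(vapply(1:8, function(s) width_at(1600, 600 + s), 0))
  ratio <- w_small / w_big # expected 4
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.5)
})

test_that("the atrophy fit bundles rates and differences coherently", {
  sim <- generate_cohort(tiny_config(
    rate_early = c(lh_G_insular_short_thickness = -0.08),
    rate_late = -0.01, noise_sd = 0.05, seed = 19))
  fit <- atrophy_rates(sim$cohort, sim$thickness, n_boot = 300, seed = 19)
  expect_s3_class(fit, "atrophy_fit")
  expect_equal(nrow(fit$rates), 2 * ncol(sim$thickness))
  expect_equal(nrow(fit$differences), ncol(sim$thickness))
  cf <- coef(fit)
  expect_equal(cf$difference, cf$slope_early - cf$slope_late)
  # the engineered left-insular contrast dominates
  ins <- fit$differences[fit$differences$region == "G_insular_short" &
                           fit$differences$hemisphere == "left", ]
  expect_true(ins$significant_early)
  # summary and residuals are consistent with the fit
  s <- summary(fit)
  expect_equal(sum(s$by_hemisphere$significant_early),
               sum(fit$differences$significant_early))
  res <- residuals(fit)
  expect_equal(dim(res), dim(sim$thickness))
  expect_lt(max(abs(colMeans(res))), 0.05)
  sims <- simulate(fit, nsim = 1, seed = 2)
  expect_equal(dim(sims[[1]]$thickness), dim(sim$thickness))
})
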