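test_that("homologous pairs are matched across hemispheres", {
  sim <- generate_cohort(tiny_config())
  pairs <- homologous_pairs(sim$thickness)
  expect_equal(nrow(pairs), 4)
  expect_true(all(pairs$left_key %in% colnames(sim$thickness)))
  expect_true(all(pairs$right_key %in% colnames(sim$thickness)))
  # drop one right-hemisphere column: its region becomes unpaired
  dropped <- sim$thickness[, -match("rh_G_cuneus_thickness",
                                    colnames(sim$thickness))]
  pairs2 <- homologous_pairs(dropped)
  expect_false("G_cuneus" %in% pairs2$region)
  expect_true("G_cuneus" %in% attr(pairs2, "unpaired"))
})

test_that("perfectly linear thinning gives r = -1; toy cases match the oracle", {
  cohort <- data.frame(patient_id = sprintf("P%d", 1:6),
                       duration = c(2, 3, 5, 7, 8, 9))
  thick <- matrix(3.2 - 0.05 * cohort$duration, ncol = 1,
                  dimnames = list(cohort$patient_id,
                                  "lh_S_orbital_med-olfact_thickness"))
  res <- duration_correlation(cohort, thick, "S_orbital_med-olfact", "left")
  expect_equal(res$r, -1, tolerance = 1e-12)

  set.seed(47)
  thick[, 1] <- thick[, 1] + rnorm(6, 0, 0.1)
  res <- duration_correlation(cohort, thick, "S_orbital_med-olfact", "left")
  ora <- pearson_oracle(cohort$duration, thick[, 1])
  expect_equal(res$r, ora$r, tolerance = 1e-12)
  expect_equal(res$p_value, ora$p_value, tolerance = 1e-12)
  expect_equal(res$n, 6)

  flat <- matrix(rep(3, 6), ncol = 1, dimnames = dimnames(thick))
  expect_error(duration_correlation(cohort, flat, "S_orbital_med-olfact",
                                    "left"), "zero variance")
})

test_that("correlation is invariant to affine rescaling up to scale sign", {
  sim <- generate_cohort(tiny_config(seed = 61))
  base <- duration_correlation(sim$cohort, sim$thickness, "G_cuneus", "left")
  scaled <- sim$thickness
  scaled[, "lh_G_cuneus_thickness"] <-
    0.2 + 0.5 * scaled[, "lh_G_cuneus_thickness"]
  up <- duration_correlation(sim$cohort, scaled, "G_cuneus", "left")
  expect_equal(up$r, base$r, tolerance = 1e-12)
  flipped <- sim$thickness
  flipped[, "lh_G_cuneus_thickness"] <-
    5 - 1 * flipped[, "lh_G_cuneus_thickness"]
  dn <- duration_correlation(sim$cohort, flipped, "G_cuneus", "left")
  expect_equal(dn$r, -base$r, tolerance = 1e-12)
})

test_that("subgroup filters restrict the correlation sample", {
  sim <- generate_cohort(tiny_config(n_early = 60, n_late = 40, seed = 63))
  lh <- duration_correlation(sim$cohort, sim$thickness, "G_cuneus", "left",
                             subgroup = "left-handed")
  expect_equal(lh$n, sum(sim$cohort$handedness == "L"))
  expect_equal(lh$subgroup, "left-handed")
  pred <- duration_correlation(sim$cohort, sim$thickness, "G_cuneus", "left",
                               subgroup = function(co) co$stage == "Early")
  expect_equal(pred$n, sum(sim$cohort$stage == "Early"))
  expect_error(duration_correlation(sim$cohort, sim$thickness, "G_cuneus",
                                    "left", subgroup = "ambidextrous"),
               "unknown subgroup")
})

test_that("identical hemispheres give zero difference with p = 1", {
  sim <- generate_cohort(tiny_config(n_early = 8, n_late = 6))
  thick <- sim$thickness
  thick[, "rh_G_cuneus_thickness"] <- thick[, "lh_G_cuneus_thickness"]
  res <- paired_hemisphere_test(sim$cohort, thick, "G_cuneus")
  expect_equal(res$difference, 0)
  expect_equal(res$p_value, 1)
})

test_that("the paired comparison matches a one-sample-t oracle and formats means", {
  set.seed(67)
  cohort <- data.frame(patient_id = sprintf("P%d", 1:6), duration = runif(6, 3, 9))
  lv <- rnorm(6, 3.42, 0.3)
  rv <- rnorm(6, 3.28, 0.3)
  thick <- cbind(lv, rv)
  dimnames(thick) <- list(cohort$patient_id,
                          c("lh_G_insular_short_thickness",
                            "rh_G_insular_short_thickness"))
  res <- paired_hemisphere_test(cohort, thick, "G_insular_short")
  expect_equal(res$p_value, paired_oracle(lv, rv), tolerance = 1e-10)
  expect_equal(res$difference, mean(lv) - mean(rv), tolerance = 1e-12)
  expect_match(res$left_summary, "^[0-9]+\\.[0-9]{2} ± [0-9]+\\.[0-9]{2}$")
  expect_equal(res$left_summary, sprintf("%.2f ± %.2f", mean(lv), sd(lv)))
})

test_that("the paired comparison is antisymmetric under hemisphere swap", {
  sim <- generate_cohort(tiny_config(seed = 71))
  fwd <- paired_hemisphere_test(sim$cohort, sim$thickness, "G_cuneus")
  swapped <- sim$thickness
  colnames(swapped) <- sub("^lh_", "zz_", colnames(swapped))
  colnames(swapped) <- sub("^rh_", "lh_", colnames(swapped))
  colnames(swapped) <- sub("^zz_", "rh_", colnames(swapped))
  rev <- paired_hemisphere_test(sim$cohort, swapped, "G_cuneus")
  expect_equal(rev$difference, -fwd$difference, tolerance = 1e-12)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
  expect_equal(rev$left_mean, fwd$right_mean)
})

test_that("asymmetry classification follows the sign rule per hemisphere", {
  cfg <- tiny_config(
    regions = "G_insular_short",
    rate_early = c(lh_G_insular_short_thickness = -0.08,
                   rh_G_insular_short_thickness = -0.02),
    rate_late = -0.02, noise_sd = 0, seed = 73)
  sim <- generate_cohort(cfg)
  ld <- slope_difference(sim$cohort, sim$thickness, "G_insular_short",
                         "left", n_boot = 300, seed = 7)
  rd <- slope_difference(sim$cohort, sim$thickness, "G_insular_short",
                         "right", n_boot = 300, seed = 7)
  expect_equal(asymmetry_contrast(ld, rd)$lateralized, "left-only")

  # mirrored data swaps the classification
  mirrored <- sim$thickness
  colnames(mirrored) <- sub("^lh_", "zz_", colnames(mirrored))
  colnames(mirrored) <- sub("^rh_", "lh_", colnames(mirrored))
  colnames(mirrored) <- sub("^zz_", "rh_", colnames(mirrored))
  ld2 <- slope_difference(sim$cohort, mirrored, "G_insular_short", "left",
                          n_boot = 300, seed = 7)
  rd2 <- slope_difference(sim$cohort, mirrored, "G_insular_short", "right",
                          n_boot = 300, seed = 7)
  expect_equal(asymmetry_contrast(ld2, rd2)$lateralized, "right-only")

  # matched-settings guard
  rd_other <- slope_difference(sim$cohort, sim$thickness, "G_insular_short",
                               "right", n_boot = 400, seed = 7)
  expect_error(asymmetry_contrast(ld, rd_other), "n_boot")
  expect_error(asymmetry_contrast(ld, ld), "left and right")
})

test_that("a strong left-only generating contrast is classified left-only", {
  hits <- 0
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    sim <- generate_cohort(tiny_config(
      n_early = 80, n_late = 80, regions = "G_insular_short",
      rate_early = c(lh_G_insular_short_thickness = -0.09,
                     rh_G_insular_short_thickness = -0.02),
      rate_late = -0.02, noise_sd = 0.08, seed = 900 + i))
    ld <- slope_difference(sim$cohort, sim$thickness, "G_insular_short",
                           "left", n_boot = 300, seed = i)
    rd <- slope_difference(sim$cohort, sim$thickness, "G_insular_short",
                           "right", n_boot = 300, seed = i)
    if (asymmetry_contrast(ld, rd)$lateralized == "left-only") hits <- hits + 1
  }
  # nominal left-only probability is 1 - alpha = 0.95 (the null right
  # hemisphere flags at rate alpha); allow 2 Monte-Carlo SDs below nominal
  expect_gte(hits / n_rep, 0.95 - 2 * sqrt(0.95 * 0.05 / n_rep))
})
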