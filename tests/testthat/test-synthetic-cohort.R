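test_that("ACE parameter validation rejects malformed inputs", {
  expect_error(ace_params(a2_x = 0.5, c2_x = 0.5, e2_x = 0.1),
               class = "twinclock_parameter_error")
  expect_error(ace_params(a2_x = -0.1, c2_x = 0.6, e2_x = 0.5),
               class = "twinclock_parameter_error")
  expect_error(ace_params(rA = 1.2), class = "twinclock_parameter_error")
  expect_error(
    generate_twin_traits(ace_params(),
                         cohort_config(n_mz_pairs = 0, n_dz_pairs = 0,
                                       n_singletons = 0)),
    class = "twinclock_empty_cohort_error")
})

test_that("within-pair trait correlations match ACE expectations", {
  # Pure unique environment: co-twins are uncorrelated.
  ace_e <- ace_params(a2_x = 0, c2_x = 0, e2_x = 1,
                      a2_y = 0, c2_y = 0, e2_y = 1, rE = 0)
  co <- generate_twin_traits(ace_e, cohort_config(n_mz_pairs = 2000, seed = 5))
  pr <- make_pairs(co, "true_accel_x", "true_accel_x", zygosity = "MZ")
  expect_lt(abs(cor(pr$x1, pr$x2)), 0.05)

  # a2 = 0.6, c2 = 0.1: rMZ = a2 + c2 = 0.7, rDZ = a2/2 + c2 = 0.4.
  ace <- ace_params(a2_x = 0.6, c2_x = 0.1, e2_x = 0.3,
                    a2_y = 0.6, c2_y = 0.1, e2_y = 0.3)
  co <- generate_twin_traits(
    ace, cohort_config(n_mz_pairs = 5000, n_dz_pairs = 5000, seed = 11))
  mz <- make_pairs(co, "true_accel_x", "true_accel_x", zygosity = "MZ")
  dz <- make_pairs(co, "true_accel_x", "true_accel_x", zygosity = "DZ")
  se_mz <- (1 - 0.7^2) / sqrt(5000)
  se_dz <- (1 - 0.4^2) / sqrt(5000)
  expect_lt(abs(cor(mz$x1, mz$x2) - 0.7), 3 * se_mz)
  expect_lt(abs(cor(dz$x1, dz$x2) - 0.4), 3 * se_dz)

  # Unit variance and zero mean in expectation.
  expect_lt(abs(var(co$true_accel_x) - 1), 3 * sqrt(2 / nrow(co)))
  expect_lt(abs(mean(co$true_accel_y)), 3 / sqrt(nrow(co)))
})

test_that("MZ cross-twin cross-trait structure follows the latent model", {
  ace <- ace_params(a2_x = 0.7, c2_x = 0.1, e2_x = 0.2,
                    a2_y = 0.7, c2_y = 0.1, e2_y = 0.2,
                    rA = 0.8, rC = 0.3, rE = 0.5)
  co <- generate_twin_traits(ace, cohort_config(n_mz_pairs = 10000, seed = 21))
  pr <- make_pairs(co, "true_accel_x", "true_accel_y", zygosity = "MZ")

  expected_ctct <- 0.8 * sqrt(0.7 * 0.7) + 0.3 * sqrt(0.1 * 0.1)
  obs <- cor(c(pr$x1, pr$x2), c(pr$y2, pr$y1))
  expect_lt(abs(obs - expected_ctct),
            3 * (1 - expected_ctct^2) / sqrt(10000))

  # Within-pair differences carry only E: corr(dx, dy) -> rE.
  r_diff <- cor(pr$x1 - pr$x2, pr$y1 - pr$y2)
  expect_lt(abs(r_diff - 0.5), 3 * (1 - 0.25) / sqrt(10000))
})

test_that("cohort generation is deterministic and order-invariant", {
  ace <- ace_params(rE = 0.3)
  cfg <- cohort_config(n_mz_pairs = 30, n_dz_pairs = 10, n_singletons = 5,
                       seed = 77)
  a <- simulate_twin_cohort(ace, cfg)
  b <- simulate_twin_cohort(ace, cfg)
  expect_identical(a, b)

  # Shuffling cohort rows does not change any individual's covariates.
  traits <- generate_twin_traits(ace, cfg)
  shuffled <- traits[rev(seq_len(nrow(traits))), ]
  cov1 <- generate_covariates(traits, cfg)
  cov2 <- generate_covariates(shuffled, cfg)
  expect_identical(cov1, cov2)
  expect_identical(generate_brain_ages(traits, cfg),
                   generate_brain_ages(shuffled, cfg))
})

test_that("covariates respect compositional and zygosity constraints", {
  co <- simulate_twin_cohort(
    ace_params(), cohort_config(n_mz_pairs = 80, n_dz_pairs = 40, seed = 9))
  wbc_sum <- co$pct_neutrophils + co$pct_lymphocytes + co$pct_monocytes +
    co$pct_eosinophils + co$pct_basophils
  expect_true(all(abs(wbc_sum - 100) <= 0.5))

  mz <- co[co$zygosity %in% "MZ", ]
  same_sex <- tapply(mz$sex, mz$family_id, function(s) length(unique(s)))
  expect_true(all(same_sex == 1))

  expect_true(all(co$plate %in% 1:34))
  expect_true(all(co$array_row %in% 1:6))
  expect_true(all(co$smoking %in% c("never", "former", "current")))
  expect_true(all(co$age_mri >= 20 & co$age_mri <= 84))
})

test_that("simulated brain ages carry exactly the configured bias", {
  ace <- ace_params()
  # Identity case: no bias, no noise, no acceleration signal.
  cfg0 <- cohort_config(n_mz_pairs = 50, bias_slope = 0, bias_intercept = 0,
                        sigma_brain = 0, accel_scale_brain = 0, seed = 2)
  co <- generate_twin_traits(ace, cfg0)
  ba <- generate_brain_ages(co, cfg0)
  expect_equal(ba$predicted_age, ba$chron_age, tolerance = 1e-12)

  # Injected slope is recovered by OLS of the gap on age at large n.
  cfg <- cohort_config(n_mz_pairs = 1000, bias_slope = -0.3,
                       bias_intercept = 8, sigma_brain = 5, seed = 3)
  co <- generate_twin_traits(ace, cfg)
  ba <- generate_brain_ages(co, cfg)
  fit <- lm(I(predicted_age - chron_age) ~ chron_age, data = ba)
  expect_lt(abs(coef(fit)[2] - (-0.3)), 3 * summary(fit)$coefficients[2, 2])
})
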