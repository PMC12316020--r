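test_that("apply_clock computes the weighted sum and transform exactly", {
  one <- clock_model("one", 0, c(cg1 = 1))
  b1 <- matrix(0.42, 1, 1, dimnames = list("cg1", "s1"))
  expect_equal(apply_clock(b1, one)$estimate, 0.42)

  clk <- clock_model("toy", 10, c(cgA = 2, cgB = -1, cgC = 5))
  b <- matrix(c(0.1, 0.5, 0.2), 3, 1,
              dimnames = list(c("cgA", "cgB", "cgC"), "s1"))
  expect_equal(apply_clock(b, clk)$estimate, 10.7)
})

test_that("log-linear age transform round-trips through its knot", {
  # Forward of age 30 with knot 20 is (30 - 20) / 21.
  expect_equal(twinclock:::horvath_forward(30, 20), 10 / 21)
  ages <- c(0.5, 5, 19.99, 20, 20.01, 30, 65, 92)
  back <- twinclock:::horvath_inverse(twinclock:::horvath_forward(ages, 20), 20)
  expect_lt(max(abs(back - ages)), 1e-9)
})

test_that("apply_clock matches the brute-force oracle on random clocks", {
  for (seed in 1:30) {
    case <- random_clock_case(seed)
    got <- apply_clock(case$betas, case$clock)$estimate
    want <- oracle_clock(case$betas, case$clock)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("identity-transform clocks are linear in the beta matrix", {
  case <- random_clock_case(101)
  clk <- case$clock
  clk$transform <- "identity"
  b <- case$betas
  lambda <- 0.3
  mix <- lambda * b[, 1] + (1 - lambda) * b[, 2]
  bm <- cbind(b[, 1:2], mix = mix)
  est <- apply_clock(bm, clk)$estimate
  expect_lt(abs(est[3] - (lambda * est[1] + (1 - lambda) * est[2])), 1e-10)
})

test_that("missing-probe policy errors by default and imputes on request", {
  clk <- clock_model("toy", 0, c(cgA = 1, cgB = 1))
  b <- matrix(0.4, 1, 2, dimnames = list("cgA", c("s1", "s2")))
  expect_error(apply_clock(b, clk), class = "twinclock_missing_probe_error")
  expect_warning(est <- apply_clock(b, clk, missing_probes = "impute"),
                 "imputing")
  expect_equal(est$estimate, c(0.9, 0.9))  # 0.4 + imputed 0.5

  bad <- matrix(1.2, 2, 1, dimnames = list(c("cgA", "cgB"), "s1"))
  expect_error(apply_clock(bad, clk), class = "twinclock_domain_error")
})

test_that("age-acceleration residuals are exact OLS residuals", {
  ages <- c(20, 30, 40, 50, 60)
  est <- c(25, 28, 45, 48, 65)
  d <- compute_age_acceleration(
    tibble::tibble(estimate = est, chron_age = ages))
  want <- oracle_ols_resid(cbind(1, ages), est)
  expect_equal(d$accel, want, tolerance = 1e-10)
  expect_lt(abs(mean(d$accel)), 1e-10)
  expect_lt(abs(sum(d$accel * ages)), 1e-8)

  # Perfect linear relation leaves zero residuals.
  d0 <- compute_age_acceleration(
    tibble::tibble(estimate = 2 + 1.1 * ages, chron_age = ages))
  expect_lt(max(abs(d0$accel)), 1e-10)

  expect_error(
    compute_age_acceleration(
      tibble::tibble(estimate = est, chron_age = rep(40, 5))),
    class = "twinclock_degenerate_error")
})

test_that("acceleration is invariant to affine-in-age components", {
  set.seed(4)
  ages <- runif(60, 20, 80)
  est <- 10 + 0.9 * ages + rnorm(60)
  a1 <- compute_age_acceleration(
    tibble::tibble(estimate = est, chron_age = ages))$accel
  a2 <- compute_age_acceleration(
    tibble::tibble(estimate = est + 7 - 2.5 * ages, chron_age = ages))$accel
  expect_lt(max(abs(a1 - a2)), 1e-8)
})

test_that("pace estimates pass through untouched and check clock kind", {
  pace <- clock_model("pace", 1, c(cg1 = 0.1), output_kind = "pace_unitless")
  expect_equal(pace_passthrough(c(1.0, 1.2, 0.9), pace), c(1.0, 1.2, 0.9))
  age_clk <- clock_model("age", 0, c(cg1 = 1))
  expect_error(pace_passthrough(c(1, 2), age_clk),
               class = "twinclock_kind_mismatch_error")
})

test_that("beta-matrix inversion solves the clock exactly at zero noise", {
  for (clk in list(synthetic_clock("a", 40, seed = 1),
                   synthetic_clock("b", 60, "horvath_log_linear", seed = 2))) {
    targets <- setNames(seq(15, 90, length.out = 25),
                        paste0("s", 1:25))
    b <- generate_beta_matrix(clk, targets, noise_sd = 0)
    expect_true(min(b) >= 0 && max(b) <= 1)
    got <- apply_clock(b, clk)$estimate
    expect_lt(max(abs(got - targets)), 1e-8)
  }
})

test_that("beta-matrix noise model yields the configured RMSE", {
  clk <- synthetic_clock("n", 50, seed = 5)
  n <- 2000
  targets <- runif(n, 25, 75)
  b <- generate_beta_matrix(clk, targets, noise_sd = 2, seed = 8)
  rmse <- sqrt(mean((apply_clock(b, clk)$estimate - targets)^2))
  # chi distribution: SE of RMSE approx sd / sqrt(2 n)
  expect_lt(abs(rmse - 2), 3 * 2 / sqrt(2 * n))
})

test_that("infeasible targets are reported, not silently clipped", {
  clk <- synthetic_clock("tight", 10, seed = 6)
  expect_error(generate_beta_matrix(clk, c(far = 1e4)),
               class = "twinclock_infeasible_target_error")
})

test_that("clock files round-trip through the text format", {
  clk <- clock_model("rt", intercept = -3.25,
                     weights = c(cg001 = 1.5, cg002 = -0.75),
                     transform = "horvath_log_linear", adult_age = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_clock(clk, path)
  back <- read_clock(path)
  expect_equal(back$intercept, clk$intercept)
  expect_equal(back$weights, clk$weights)
  expect_equal(back$transform, clk$transform)
  expect_equal(back$adult_age, clk$adult_age)

  b <- generate_beta_matrix(synthetic_clock("m", 20, seed = 3),
                            c(s1 = 40, s2 = 55))
  bp <- withr::local_tempfile(fileext = ".csv")
  write_beta_matrix(b, bp)
  expect_equal(read_beta_matrix(bp), b, tolerance = 1e-12)
})
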