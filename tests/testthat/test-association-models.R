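# Build a minimal design object for testing the fitter in isolation
# (intercept + exposure only, no covariates).
minimal_design <- function(x, y, family_id) {
  X <- cbind("(Intercept)" = 1, exposure = x)
  structure(list(
    data = tibble::tibble(.y = y, exposure = x),
    formula = .y ~ exposure, x = X, y = y,
    family_id = family_id,
    individual_id = as.character(seq_along(y)),
    exposure = "exposure", response = "y", model = "base"
  ), class = "twinclock_design")
}

test_that("standardization yields exact Z-scores", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  z <- standardize(rnorm(100, 50, 9))
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_error(standardize(rep(2, 10)), class = "twinclock_degenerate_error")
  expect_error(standardize(3), class = "twinclock_degenerate_error")
})

test_that("plate collapsing forms contiguous near-equal groups", {
  plates <- rep(1:34, times = sample(3:6, 34, replace = TRUE))
  g <- collapse_plates(plates, 6)
  expect_equal(nlevels(g), 6)
  per_group <- tapply(plates, g, function(p) length(unique(p)))
  expect_equal(as.vector(sort(per_group, decreasing = TRUE)),
               c(6, 6, 6, 6, 5, 5))
  # Consecutive plates share groups; extremes do not.
  expect_equal(g[plates == 1][1], g[plates == 2][1])
  expect_false(g[plates == 1][1] == g[plates == 34][1])
  # Contiguity: group index is non-decreasing in plate order.
  ord <- as.integer(sub("P", "", tapply(as.character(g), plates, unique)))
  expect_true(all(diff(ord) >= 0))

  expect_equal(length(unique(collapse_plates(1:8, 8))), 8)
  expect_error(collapse_plates(1:5, 0), class = "twinclock_parameter_error")
})

test_that("design matrices contain exactly the specified covariates", {
  co <- simulate_twin_cohort(ace_params(),
                             cohort_config(n_mz_pairs = 60, seed = 17))
  co$brain_aa <- rnorm(nrow(co))
  co$clockx <- rnorm(nrow(co))

  base <- build_design(co, "clockx", model = "base")
  # intercept + exposure + 5 plate dummies + array row
  expect_equal(ncol(base$x), 1 + 1 + 5 + 1)

  full <- build_design(co, "clockx", model = "full")
  cn <- colnames(full$x)
  expect_true(all(c("pct_neutrophils", "pct_monocytes",
                    "pct_eosinophils") %in% cn))
  expect_false(any(grepl("lymph|baso", cn)))
  expect_true(all(c("sexM", "bmi", "smokingformer", "smokingcurrent")
                  %in% cn))
  # Reference category: never-smokers have both dummies at zero.
  never <- co$smoking == "never"
  expect_true(all(full$x[never, "smokingformer"] == 0))
  expect_true(all(full$x[never, "smokingcurrent"] == 0))

  scan <- build_design(co, "clockx", model = "full_scanner")
  expect_true(any(grepl("scanner_ft", colnames(scan$x))))

  # Continuous columns are Z-scored; dummies untouched.
  expect_lt(abs(mean(full$x[, "bmi"])), 1e-10)
  expect_equal(sd(full$x[, "bmi"]), 1, tolerance = 1e-10)
  expect_true(all(full$x[, "sexM"] %in% 0:1))

  expect_error(build_design(co[, setdiff(names(co), "bmi")], "clockx",
                            model = "full"),
               class = "twinclock_schema_error")
})

test_that("singleton-family fits reduce exactly to OLS", {
  set.seed(23)
  n <- 120
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n)
  d <- minimal_design(x, y, family_id = as.character(1:n))
  fit <- fit_family_lmm(d)
  expect_true(fit$singleton_ols)
  ols <- oracle_ols_coef(d$x, y)
  expect_equal(tidy(fit)$estimate, unname(ols), tolerance = 1e-6)
  expect_equal(fit$random_intercept_var, 0)

  # Perfect fit: slope one, vanishing residual variance.
  d2 <- minimal_design(x, x, family_id = as.character(1:n))
  fit2 <- suppressWarnings(fit_family_lmm(d2))  # perfect fit, zero variance
  expect_equal(tidy(fit2)$estimate[2], 1, tolerance = 1e-10)
  expect_lt(fit2$residual_var, 1e-20)
})

test_that("with standardized traits the exposure slope is the correlation", {
  set.seed(29)
  n <- 150
  x <- standardize(rnorm(n))
  y <- standardize(0.3 * x + rnorm(n))
  fit <- fit_family_lmm(minimal_design(x, y, as.character(1:n)))
  expect_equal(tidy(fit)$estimate[2], cor(x, y), tolerance = 1e-6)
})

test_that("the mixed model recovers a known exposure effect", {
  set.seed(31)
  n_fam <- 400
  fam <- rep(sprintf("f%03d", 1:n_fam), each = 2)
  x <- rnorm(2 * n_fam)
  y <- 0.15 * x + rep(rnorm(n_fam, 0, 0.5), each = 2) + rnorm(2 * n_fam)
  fit <- fit_family_lmm(minimal_design(x, y, fam))
  td <- tidy(fit)
  expect_false(fit$singleton_ols)
  expect_lt(abs(td$estimate[2] - 0.15), 3 * td$std_error[2])
  # Variance components in the right ballpark (tau2 = 0.25, sigma2 = 1).
  expect_gt(fit$random_intercept_var, 0.05)
  expect_lt(abs(fit$residual_var - 1), 0.3)
})

test_that("fits are invariant to plate-group label permutation", {
  co <- simulate_twin_cohort(ace_params(rE = 0.4),
                             cohort_config(n_mz_pairs = 80, seed = 37))
  co$brain_aa <- 0.2 * co$true_accel_y + rnorm(nrow(co))
  co$clockx <- co$true_accel_x
  d1 <- build_design(co, "clockx", model = "full")
  d2 <- d1
  d2$data$plate_group <- factor(d2$data$plate_group,
                                levels = rev(levels(d2$data$plate_group)))
  d2$x <- stats::model.matrix(d2$formula, d2$data)
  b1 <- tidy(fit_family_lmm(d1))
  b2 <- tidy(fit_family_lmm(d2))
  expect_equal(b1$estimate[b1$term == "clockx"],
               b2$estimate[b2$term == "clockx"], tolerance = 1e-8)
})

test_that("family-clustered null exposure keeps its type-I error rate", {
  set.seed(41)
  n_fam <- 127
  fam <- rep(seq_len(n_fam), each = 2)
  n_rep <- 400
  hits <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(2 * n_fam)
    y <- rep(rnorm(n_fam, 0, 0.7), each = 2) + rnorm(2 * n_fam)
    fit <- fit_family_lmm(minimal_design(x, y, as.character(fam)))
    hits[i] <- tidy(fit)$p_value[2] < 0.05
  }
  rate <- mean(hits)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("blood-to-MRI interval subsetting is strict and idempotent", {
  co <- tibble::tibble(individual_id = c("a", "b", "c"),
                       age_mri = c(50, 50, 50),
                       age_blood = c(48.1, 48.0, 47.9))
  sub <- subset_by_blood_mri_gap(co, 2)
  expect_equal(sub$individual_id, "c")
  expect_identical(subset_by_blood_mri_gap(sub, 2), sub)
  expect_equal(nrow(subset_by_blood_mri_gap(co, 0)), 3)
})

test_that("effective-tests Bonferroni threshold behaves", {
  th <- bonferroni_effective(0.05, 3)
  expect_equal(th$display, 0.0167)
  expect_equal(th$threshold, 0.05 / 3)
  expect_equal(bonferroni_effective(0.05, 1)$threshold, 0.05)
  ks <- 1:8
  ths <- vapply(ks, function(k) bonferroni_effective(0.05, k)$threshold, 1)
  expect_true(all(diff(ths) < 0))
  expect_error(bonferroni_effective(1.5, 2),
               class = "twinclock_parameter_error")
})
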