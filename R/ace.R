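#' Bivariate ACE parameters for the cohort simulator
#'
#' Defines the latent variance decomposition of the two acceleration traits
#' carried by a simulated twin cohort: trait X (DNA-methylation age
#' acceleration) and trait Y (brain-age acceleration). Each trait's variance
#' is split into additive-genetic (A), shared-environment (C) and
#' unique-environment (E) fractions, and the cross-trait association is
#' imposed on like components only: corr(A_x, A_y) = `rA`, corr(C_x, C_y) =
#' `rC`, corr(E_x, E_y) = `rE`.
#'
#' Under this parameterisation the expected monozygotic (MZ) cross-twin
#' cross-trait correlation is `rA*sqrt(a2_x*a2_y) + rC*sqrt(c2_x*c2_y)`, and
#' the correlation of within-MZ-pair trait differences is `rE`.
#'
#' @param a2_x,c2_x,e2_x Variance fractions of trait X; must be non-negative
#'   and sum to 1.
#' @param a2_y,c2_y,e2_y Variance fractions of trait Y; must be non-negative
#'   and sum to 1.
#' @param rA,rC,rE Cross-trait correlations of the A, C and E latent
#'   components, each in \[-1, 1\].
#'
#' @return An object of class `ace_params` (a named list).
#' @examples
#' ace_params(a2_x = 0.6, c2_x = 0.1, e2_x = 0.3,
#'            a2_y = 0.4, c2_y = 0.2, e2_y = 0.4,
#'            rA = 0.5, rC = 0, rE = 0.3)
#' @export
ace_params <- function(a2_x = 0.5, c2_x = 0.1, e2_x = 0.4,
                       a2_y = 0.5, c2_y = 0.1, e2_y = 0.4,
                       rA = 0, rC = 0, rE = 0) {
  fr <- c(a2_x = a2_x, c2_x = c2_x, e2_x = e2_x,
          a2_y = a2_y, c2_y = c2_y, e2_y = e2_y)
  if (any(!is.finite(fr)) || any(fr < 0)) {
    abort("All ACE variance fractions must be finite and >= 0.",
          class = "twinclock_parameter_error")
  }
  if (abs(a2_x + c2_x + e2_x - 1) > 1e-12 ||
      abs(a2_y + c2_y + e2_y - 1) > 1e-12) {
    abort("ACE variance fractions must sum to 1 per trait (tolerance 1e-12).",
          class = "twinclock_parameter_error")
  }
  rs <- c(rA = rA, rC = rC, rE = rE)
  if (any(!is.finite(rs)) || any(abs(rs) > 1)) {
    abort("rA, rC and rE must lie in [-1, 1].",
          class = "twinclock_parameter_error")
  }
  structure(as.list(c(fr, rs)), class = "ace_params")
}

#' @export
print.ace_params <- function(x, ...) {
  cat("Bivariate ACE parameters\n")
  cat(sprintf("  trait X: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$a2_x, x$c2_x, x$e2_x))
  cat(sprintf("  trait Y: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$a2_y, x$c2_y, x$e2_y))
  cat(sprintf("  cross-trait: rA = %.3f, rC = %.3f, rE = %.3f\n",
              x$rA, x$rC, x$rE))
  invisible(x)
}

#' Configuration of a simulated twin cohort
#'
#' Sampling plan and noise model for [generate_twin_traits()] and the other
#' simulator stages. Defaults describe a mixed adult cohort: ages spanning
#' young adulthood to old age, a brain-age predictor with a moderate negative
#' age-proportional bias (older brains under-predicted, the usual regression-
#' to-the-mean artefact of brain-age models) and blood drawn on average two
#' years before the MRI visit.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons Number of monozygotic pairs,
#'   dizygotic pairs and unpaired individuals.
#' @param age_min,age_max Age-at-MRI range (years); pair members share one age
#'   drawn uniformly from this range.
#' @param bias_slope,bias_intercept Linear age bias injected into simulated
#'   brain-age predictions (unitless slope on chronological age; intercept in
#'   years).
#' @param accel_scale_brain,accel_scale_clock Years of predicted-age shift per
#'   standard-deviation unit of the latent acceleration traits.
#' @param sigma_brain,sigma_clock Gaussian measurement noise SD (years) of the
#'   brain-age and clock-age predictions.
#' @param blood_mri_gap_mean,blood_mri_gap_sd Mean and SD (years) of
#'   age-at-MRI minus age-at-blood-draw.
#' @param n_plates,n_array_rows Number of bisulphite plates and of array rows
#'   used for the technical covariates.
#' @param p_smoking Probabilities of never/former/current smoking status.
#' @param seed Integer seed; every simulator stage is deterministic given it.
#'
#' @return An object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_mz_pairs = 120, n_dz_pairs = 32, n_singletons = 0,
                          age_min = 20, age_max = 84,
                          bias_slope = -0.3, bias_intercept = 8,
                          accel_scale_brain = 5, accel_scale_clock = 5,
                          sigma_brain = 5, sigma_clock = 2,
                          blood_mri_gap_mean = 2, blood_mri_gap_sd = 4,
                          n_plates = 34, n_array_rows = 6,
                          p_smoking = c(never = 0.60, former = 0.24, current = 0.16),
                          seed = 1L) {
  counts <- c(n_mz_pairs, n_dz_pairs, n_singletons)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Cohort counts must be non-negative integers.",
          class = "twinclock_parameter_error")
  }
  if (!(age_min < age_max)) {
    abort("`age_min` must be strictly less than `age_max`.",
          class = "twinclock_parameter_error")
  }
  if (sigma_brain < 0 || sigma_clock < 0 || blood_mri_gap_sd < 0) {
    abort("Noise SDs must be >= 0.", class = "twinclock_parameter_error")
  }
  if (length(p_smoking) != 3 || any(p_smoking < 0) ||
      abs(sum(p_smoking) - 1) > 1e-8) {
    abort("`p_smoking` must be three non-negative probabilities summing to 1.",
          class = "twinclock_parameter_error")
  }
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs),
    n_dz_pairs = as.integer(n_dz_pairs),
    n_singletons = as.integer(n_singletons),
    age_min = age_min, age_max = age_max,
    bias_slope = bias_slope, bias_intercept = bias_intercept,
    accel_scale_brain = accel_scale_brain,
    accel_scale_clock = accel_scale_clock,
    sigma_brain = sigma_brain, sigma_clock = sigma_clock,
    blood_mri_gap_mean = blood_mri_gap_mean,
    blood_mri_gap_sd = blood_mri_gap_sd,
    n_plates = as.integer(n_plates),
    n_array_rows = as.integer(n_array_rows),
    p_smoking = p_smoking,
    seed = as.integer(seed)
  ), class = "cohort_config")
}
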