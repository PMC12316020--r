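#' Simulate latent acceleration traits for a twin cohort
#'
#' Draws a cohort of MZ pairs, DZ pairs and singletons whose two standardized
#' acceleration traits (`true_accel_x`, DNA-methylation side; `true_accel_y`,
#' brain side) follow the bivariate ACE structure in `ace`. For each
#' individual the trait is `sqrt(a2)*A + sqrt(c2)*C + sqrt(e2)*E` with the
#' additive-genetic component A correlated 1 across MZ co-twins and 0.5
#' across DZ co-twins, the shared-environment component C identical within a
#' pair, and the unique-environment component E independent across twins.
#' Cross-trait correlation is imposed on like components only (A with A, C
#' with C, E with E), so both traits have unit variance in expectation.
#'
#' Age at MRI is drawn uniformly over the configured range and shared within
#' a pair; age at blood draw is age at MRI minus a Gaussian gap.
#'
#' @param ace An [ace_params()] object.
#' @param config A [cohort_config()] object.
#' @return A tibble with one row per individual: `individual_id`,
#'   `family_id`, `zygosity` (`"MZ"`, `"DZ"` or `NA` for singletons),
#'   `twin_order` (1, 2 or `NA`), `age_mri`, `age_blood`, `true_accel_x`,
#'   `true_accel_y`.
#' @examples
#' ace <- ace_params(a2_x = 0.6, c2_x = 0.1, e2_x = 0.3,
#'                   a2_y = 0.6, c2_y = 0.1, e2_y = 0.3, rE = 0.5)
#' cohort <- generate_twin_traits(ace, cohort_config(n_mz_pairs = 50, seed = 7))
#' head(cohort)
#' @export
generate_twin_traits <- function(ace, config) {
  if (!inherits(ace, "ace_params")) ace <- do.call(ace_params, as.list(ace))
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  n_mz <- config$n_mz_pairs
  n_dz <- config$n_dz_pairs
  n_sg <- config$n_singletons
  n_total <- 2L * n_mz + 2L * n_dz + n_sg
  if (n_total == 0L) {
    abort("Cohort configuration yields zero individuals.",
          class = "twinclock_empty_cohort_error")
  }

  load_x <- sqrt(c(ace$a2_x, ace$c2_x, ace$e2_x))
  load_y <- sqrt(c(ace$a2_y, ace$c2_y, ace$e2_y))

  with_seed(config$seed, {
    blocks <- list()

    if (n_mz > 0) {
      # A and C are single draws shared by both co-twins; E is twin-specific.
      A <- rbinorm(n_mz, ace$rA)
      C <- rbinorm(n_mz, ace$rC)
      E1 <- rbinorm(n_mz, ace$rE)
      E2 <- rbinorm(n_mz, ace$rE)
      blocks$mz <- tibble(
        family = rep(seq_len(n_mz), each = 2L),
        zygosity = "MZ",
        twin_order = rep(1:2, n_mz),
        ax = rep(A[, 1], each = 2L), ay = rep(A[, 2], each = 2L),
        cx = rep(C[, 1], each = 2L), cy = rep(C[, 2], each = 2L),
        ex = as.vector(rbind(E1[, 1], E2[, 1])),
        ey = as.vector(rbind(E1[, 2], E2[, 2]))
      )
    }

    if (n_dz > 0) {
      # Half of the additive-genetic variance is shared between DZ co-twins,
      # half is twin-specific: cross-twin corr(A) = 0.5, and the cross-twin
      # cross-trait A correlation is 0.5 * rA.
      As <- rbinorm(n_dz, ace$rA)
      Au1 <- rbinorm(n_dz, ace$rA)
      Au2 <- rbinorm(n_dz, ace$rA)
      C <- rbinorm(n_dz, ace$rC)
      E1 <- rbinorm(n_dz, ace$rE)
      E2 <- rbinorm(n_dz, ace$rE)
      h <- sqrt(0.5)
      blocks$dz <- tibble(
        family = rep(seq_len(n_dz), each = 2L),
        zygosity = "DZ",
        twin_order = rep(1:2, n_dz),
        ax = h * rep(As[, 1], each = 2L) +
          h * as.vector(rbind(Au1[, 1], Au2[, 1])),
        ay = h * rep(As[, 2], each = 2L) +
          h * as.vector(rbind(Au1[, 2], Au2[, 2])),
        cx = rep(C[, 1], each = 2L), cy = rep(C[, 2], each = 2L),
        ex = as.vector(rbind(E1[, 1], E2[, 1])),
        ey = as.vector(rbind(E1[, 2], E2[, 2]))
      )
    }

    if (n_sg > 0) {
      A <- rbinorm(n_sg, ace$rA)
      C <- rbinorm(n_sg, ace$rC)
      E <- rbinorm(n_sg, ace$rE)
      blocks$sg <- tibble(
        family = seq_len(n_sg),
        zygosity = NA_character_,
        twin_order = NA_integer_,
        ax = A[, 1], ay = A[, 2],
        cx = C[, 1], cy = C[, 2],
        ex = E[, 1], ey = E[, 2]
      )
    }

    raw <- bind_rows(blocks, .id = "group")
    fam_key <- paste(raw$group, raw$family)
    raw$family_id <- sprintf(
      "fam%04d", as.integer(factor(fam_key, levels = unique(fam_key))))
    n_fam <- length(unique(raw$family_id))
    fam_age <- setNames(runif(n_fam, config$age_min, config$age_max),
                        unique(raw$family_id))
    age_mri <- unname(fam_age[raw$family_id])
    gap <- rnorm(n_total, config$blood_mri_gap_mean, config$blood_mri_gap_sd)

    tibble(
      individual_id = paste0(
        raw$family_id, "_",
        ifelse(is.na(raw$twin_order), 1L, raw$twin_order)),
      family_id = raw$family_id,
      zygosity = raw$zygosity,
      twin_order = raw$twin_order,
      age_mri = age_mri,
      age_blood = age_mri - gap,
      true_accel_x = load_x[1] * raw$ax + load_x[2] * raw$cx +
        load_x[3] * raw$ex,
      true_accel_y = load_y[1] * raw$ay + load_y[2] * raw$cy +
        load_y[3] * raw$ey
    )
  })
}

#' Add demographic, lifestyle and technical covariates to a simulated cohort
#'
#' Fills the covariate roster a blood-methylation/MRI analysis adjusts for:
#' sex (identical within MZ pairs), BMI, smoking status, the five white-blood
#' cell percentages (normalized to sum to 100), bisulphite plate and
#' methylation array row. Distributions are calibrated to typical adult
#' population-cohort values; they carry no dependence on the latent traits,
#' so covariates are non-confounding by construction.
#'
#' @param cohort A cohort tibble from [generate_twin_traits()].
#' @param config The [cohort_config()] used to generate it (supplies plate
#'   and array-row counts, smoking probabilities and the seed).
#' @return `cohort` with columns `sex`, `bmi`, `smoking`, `pct_neutrophils`,
#'   `pct_monocytes`, `pct_eosinophils`, `pct_lymphocytes`, `pct_basophils`,
#'   `plate`, `array_row`, `scanner_ft` appended.
#' @export
generate_covariates <- function(cohort, config) {
  stopifnot_columns(cohort, c("individual_id", "family_id", "zygosity"),
                    "cohort")
  cohort <- arrange(cohort, .data$individual_id)
  n <- nrow(cohort)

  # Pooled WBC differential means (%) and spreads for an adult blood draw.
  wbc_mean <- c(neutrophils = 53, lymphocytes = 35.2, monocytes = 8.6,
                eosinophils = 2.7, basophils = 0.46)
  wbc_sd <- c(6, 5.5, 1.8, 1.5, 0.3)

  with_seed(config$seed + 1L, {
    fam_ids <- unique(cohort$family_id)
    fam_sex <- setNames(sample(c("M", "F"), length(fam_ids), replace = TRUE),
                        fam_ids)
    sex <- ifelse(
      !is.na(cohort$zygosity) & cohort$zygosity == "MZ",
      fam_sex[cohort$family_id],
      sample(c("M", "F"), n, replace = TRUE)
    )

    wbc <- sapply(seq_along(wbc_mean), function(j) {
      pmax(rnorm(n, wbc_mean[j], wbc_sd[j]), 0.05)
    })
    wbc <- 100 * wbc / rowSums(wbc)

    fam_scanner <- setNames(
      sample(c("1.5T", "3T"), length(fam_ids), replace = TRUE,
             prob = c(0.3, 0.7)),
      fam_ids)

    mutate(
      cohort,
      sex = unname(sex),
      bmi = pmin(pmax(rnorm(n, 24, 3.5), 15), 45),
      smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                       prob = config$p_smoking),
      pct_neutrophils = wbc[, 1],
      pct_lymphocytes = wbc[, 2],
      pct_monocytes = wbc[, 3],
      pct_eosinophils = wbc[, 4],
      pct_basophils = wbc[, 5],
      plate = sample(seq_len(config$n_plates), n, replace = TRUE),
      array_row = sample(seq_len(config$n_array_rows), n, replace = TRUE),
      scanner_ft = unname(fam_scanner[.data$family_id])
    )
  })
}

#' Simulate brain-age predictions carrying an age-proportional bias
#'
#' Emulates the output of a structural-MRI brain-age model: the predicted
#' age equals chronological age plus a scaled contribution of the latent
#' brain acceleration trait, a linear age bias (`bias_intercept +
#' bias_slope * age`), and Gaussian measurement noise. The injected bias is
#' what the downstream age-bias correction is expected to remove.
#'
#' @param cohort A cohort tibble with `age_mri` and `true_accel_y`.
#' @param config A [cohort_config()]; uses `bias_slope`, `bias_intercept`,
#'   `accel_scale_brain`, `sigma_brain` and `seed`.
#' @return A tibble `sample_id`, `predicted_age`, `chron_age` (one row per
#'   individual, ordered by id).
#' @export
generate_brain_ages <- function(cohort, config) {
  stopifnot_columns(cohort, c("individual_id", "age_mri", "true_accel_y"),
                    "cohort")
  cohort <- arrange(cohort, .data$individual_id)
  with_seed(config$seed + 2L, {
    noise <- rnorm(nrow(cohort), 0, config$sigma_brain)
    tibble(
      sample_id = cohort$individual_id,
      predicted_age = cohort$age_mri +
        config$accel_scale_brain * cohort$true_accel_y +
        config$bias_intercept + config$bias_slope * cohort$age_mri +
        noise,
      chron_age = cohort$age_mri
    )
  })
}

#' Simulate a complete twin cohort
#'
#' Convenience wrapper chaining [generate_twin_traits()] and
#' [generate_covariates()].
#'
#' @inheritParams generate_twin_traits
#' @return A cohort tibble with traits and covariates.
#' @export
simulate_twin_cohort <- function(ace = ace_params(), config = cohort_config()) {
  generate_twin_traits(ace, config) |>
    generate_covariates(config)
}
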