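#' Generate a synthetic linear clock
#'
#' Builds a clock with random positive CpG weights scaled so that any target
#' in a wide age (or pace) range is reachable by the beta-matrix inversion of
#' [generate_beta_matrix()] without leaving the \[0, 1\] beta domain.
#'
#' @param name Clock name.
#' @param n_cpgs Number of CpGs.
#' @param transform `"identity"` or `"horvath_log_linear"`.
#' @param output_kind `"age_years"` or `"pace_unitless"`.
#' @param seed Integer seed for weights and CpG ids.
#' @return A [clock_model()].
#' @export
synthetic_clock <- function(name = "synthetic", n_cpgs = 71,
                            transform = "identity",
                            output_kind = "age_years", seed = 1L) {
  with_seed(seed, {
    u <- runif(n_cpgs, 2, 4)
    ids <- sprintf("cg%08d", sample.int(1e8L, n_cpgs))
    scale <- if (output_kind == "pace_unitless") {
      0.01
    } else if (transform == "horvath_log_linear") {
      0.05
    } else {
      1
    }
    center <- if (output_kind == "pace_unitless") {
      1
    } else if (transform == "horvath_log_linear") {
      horvath_forward(50, 20)
    } else {
      50
    }
    w <- setNames(u * scale, ids)
    clock_model(name, intercept = center - 0.5 * sum(w), weights = w,
                transform = transform, output_kind = output_kind)
  })
}

#' Configuration of an end-to-end pipeline run
#'
#' Bundles inputs and analysis choices for [run_pipeline()]. In synthetic
#' mode (the default), a twin cohort with known ACE structure is generated
#' and CpG beta matrices are built per clock so that every stage, from clock
#' arithmetic to twin models, runs on data with known ground truth. File
#' mode is selected by supplying `pheno_path` and `brainage_path` (plus
#' `clock_paths` and `beta_path`, or a ready acceleration column per clock).
#'
#' @param ace [ace_params()] for synthetic mode.
#' @param cohort [cohort_config()] for synthetic mode; its `seed` is the run
#'   seed.
#' @param clocks List of [clock_model()] objects; default one first-
#'   generation-style identity clock and one log-linear-transform clock.
#' @param pheno_path,brainage_path,beta_path,clock_paths Optional input
#'   files (comma-separated; see the reader functions) switching the run to
#'   file mode.
#' @param trained_range Age range (years) outside which brain-age records
#'   are excluded.
#' @param required_covariates Covariates that must be non-missing.
#' @param rosner_k_max,rosner_alpha Outlier-screen settings; the screen is
#'   applied to brain-age acceleration and each clock's acceleration, and
#'   the union of flags removed.
#' @param models Association covariate sets to fit.
#' @param sensitivity_gaps Blood-to-MRI intervals (years) for the subset
#'   re-fits of the full model.
#' @param alpha,k_eff Family-wise alpha and effective number of independent
#'   tests for the significance threshold.
#' @param df_method Degrees-of-freedom convention for Wald p-values.
#' @param out_dir Optional directory; when set, all result tables plus a
#'   manifest are written there as comma-separated text.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ace = ace_params(a2_x = 0.5, c2_x = 0.1, e2_x = 0.4,
                                             a2_y = 0.5, c2_y = 0.1, e2_y = 0.4,
                                             rA = 0, rC = 0, rE = 0.4),
                            cohort = cohort_config(),
                            clocks = NULL,
                            pheno_path = NULL, brainage_path = NULL,
                            beta_path = NULL, clock_paths = NULL,
                            trained_range = c(18, 92),
                            required_covariates = c("sex", "bmi", "smoking",
                                                    "pct_neutrophils",
                                                    "pct_monocytes",
                                                    "pct_eosinophils",
                                                    "plate", "array_row"),
                            rosner_k_max = 10, rosner_alpha = 0.05,
                            models = c("base", "full"),
                            sensitivity_gaps = c(2, 4),
                            alpha = 0.05, k_eff = 3,
                            df_method = "residual",
                            out_dir = NULL) {
  if (is.null(clocks)) {
    clocks <- list(
      synthetic_clock("clock_a", n_cpgs = 71, transform = "identity",
                      seed = cohort$seed + 11L),
      synthetic_clock("clock_b", n_cpgs = 100,
                      transform = "horvath_log_linear",
                      seed = cohort$seed + 12L)
    )
  }
  names(clocks) <- vapply(clocks, function(cl) cl$name, "")
  if (anyDuplicated(names(clocks))) {
    abort("Clock names must be unique.", class = "twinclock_parameter_error")
  }
  structure(list(
    ace = ace, cohort = cohort, clocks = clocks,
    pheno_path = pheno_path, brainage_path = brainage_path,
    beta_path = beta_path, clock_paths = clock_paths,
    trained_range = trained_range,
    required_covariates = required_covariates,
    rosner_k_max = rosner_k_max, rosner_alpha = rosner_alpha,
    models = models, sensitivity_gaps = sensitivity_gaps,
    alpha = alpha, k_eff = k_eff, df_method = df_method,
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full acceleration-association pipeline
#'
#' Executes, in order: trained-age-range filter, brain-age gap and
#' sample-level age-bias correction, clock application and age-acceleration
#' residualization, merge, missing-covariate filter, generalized-ESD outlier
#' screen, standardization, base/full family-clustered regressions per
#' clock, cross-twin cross-trait and MZ-difference twin models, and
#' sensitivity subset re-fits. Every stage's sample bookkeeping is recorded
#' and all randomness derives from the cohort seed, so two runs with the
#' same configuration are identical.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `twinclock_run`: list with `associations`,
#'   `twin`, `sensitivity`, `counts`, `exclusions`, `threshold`,
#'   `n_analysis`, `n_mz_pairs`, `clock_names`, `seed`, `log`, and `cohort`
#'   (the analysis-ready table).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().",
          class = "twinclock_parameter_error")
  }
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message("[twinclock] ", line)
  }
  seed <- config$cohort$seed
  clocks <- config$clocks

  # ---- inputs ---------------------------------------------------------
  if (is.null(config$pheno_path)) {
    say("simulating cohort (seed %d)", seed)
    cohort <- simulate_twin_cohort(config$ace, config$cohort)
    brain <- generate_brain_ages(cohort, config$cohort)
    betas <- lapply(seq_along(clocks), function(i) {
      cl <- clocks[[i]]
      scale <- if (cl$output_kind == "pace_unitless") 0.05 else
        config$cohort$accel_scale_clock
      noise <- if (cl$output_kind == "pace_unitless") 0.02 else
        config$cohort$sigma_clock
      target <- if (cl$output_kind == "pace_unitless") {
        1 + scale * cohort$true_accel_x
      } else {
        cohort$age_blood + scale * cohort$true_accel_x
      }
      names(target) <- cohort$individual_id
      generate_beta_matrix(cl, target, noise_sd = noise,
                           seed = seed + 100L + i)
    })
    names(betas) <- names(clocks)
  } else {
    say("reading cohort from %s", config$pheno_path)
    cohort <- readr::read_csv(config$pheno_path, show_col_types = FALSE)
    brain <- readr::read_csv(config$brainage_path, show_col_types = FALSE)
    if (!is.null(config$clock_paths)) {
      clocks <- lapply(config$clock_paths, read_clock)
      names(clocks) <- vapply(clocks, function(cl) cl$name, "")
    }
    b <- read_beta_matrix(config$beta_path)
    betas <- rep(list(b), length(clocks))
    names(betas) <- names(clocks)
  }
  n0 <- nrow(cohort)
  counts <- tibble(stage = "input", n_in = n0, n_kept = n0, n_excluded = 0L)

  # ---- brain side: range filter, gap, bias correction -----------------
  rng <- filter_trained_range(brain, config$trained_range[1],
                              config$trained_range[2])
  say("trained-range filter: kept %d, excluded %d",
      nrow(rng$kept), nrow(rng$excluded))
  brain_ok <- beheshti_correct(compute_bag(rng$kept))
  say("age-bias correction: slope %.3f, intercept %.2f",
      attr(brain_ok, "bias_slope"), attr(brain_ok, "bias_intercept"))

  # ---- clock side: estimates and acceleration -------------------------
  accel_tbl <- tibble(individual_id = cohort$individual_id,
                      age_blood = cohort$age_blood)
  for (nm in names(clocks)) {
    cl <- clocks[[nm]]
    est <- apply_clock(betas[[nm]], cl)
    est <- est[match(accel_tbl$individual_id, est$sample_id), ]
    if (cl$output_kind == "pace_unitless") {
      accel_tbl[[paste0(nm, "_accel")]] <- pace_passthrough(est$estimate, cl)
    } else {
      tmp <- compute_age_acceleration(
        tibble(estimate = est$estimate, chron_age = accel_tbl$age_blood))
      accel_tbl[[paste0(nm, "_accel")]] <- tmp$accel
    }
  }
  clock_cols <- paste0(names(clocks), "_accel")

  # ---- merge ----------------------------------------------------------
  merged <- cohort |>
    left_join(select(brain_ok, "sample_id", "bag_corrected"),
              by = c(individual_id = "sample_id")) |>
    left_join(select(accel_tbl, -"age_blood"), by = "individual_id") |>
    rename(brain_aa = "bag_corrected") |>
    filter(!is.na(.data$brain_aa))
  counts <- bind_rows(counts, tibble(
    stage = "trained_range", n_in = n0, n_kept = nrow(merged),
    n_excluded = n0 - nrow(merged)))

  # ---- exclusions -----------------------------------------------------
  mc <- filter_missing_covariates(merged, config$required_covariates)
  say("missing-covariate filter: removed %d", nrow(mc$removed))
  counts <- bind_rows(counts, tibble(
    stage = "missing_covariates", n_in = nrow(merged),
    n_kept = nrow(mc$kept), n_excluded = nrow(mc$removed)))

  ro <- screen_outliers(mc$kept, c("brain_aa", clock_cols),
                        k_max = config$rosner_k_max,
                        alpha = config$rosner_alpha)
  say("outlier screen: removed %d", nrow(ro$removed))
  counts <- bind_rows(counts, tibble(
    stage = "rosner_outlier", n_in = nrow(mc$kept),
    n_kept = nrow(ro$kept), n_excluded = nrow(ro$removed)))
  analysis <- ro$kept

  # ---- standardize traits for the twin models -------------------------
  analysis <- mutate(analysis,
                     brain_aa_z = standardize(.data$brain_aa),
                     across(all_of(clock_cols), standardize,
                            .names = "{.col}_z"))

  threshold <- bonferroni_effective(config$alpha, config$k_eff)

  # ---- association models ---------------------------------------------
  assoc <- purrr::map_dfr(names(clocks), function(nm) {
    purrr::map_dfr(config$models, function(mdl) {
      fit <- fit_association(analysis, paste0(nm, "_accel"),
                             response = "brain_aa", model = mdl,
                             df_method = config$df_method)
      mutate(tidy(fit), clock = nm, model = mdl, n = fit$n,
             .before = 1)
    })
  })
  assoc <- mutate(assoc,
                  significant = .data$p_value < threshold$threshold)

  # ---- twin models ----------------------------------------------------
  twin <- purrr::map_dfr(names(clocks), function(nm) {
    prs <- make_pairs(analysis, paste0(nm, "_accel_z"), "brain_aa_z",
                      zygosity = "MZ")
    if (nrow(prs) < 3) {
      say("twin models skipped for %s: only %d complete MZ pairs",
          nm, nrow(prs))
      return(tibble())
    }
    ct <- ctct_correlation(prs)
    dm <- mz_difference_regression(prs)
    bind_rows(
      tibble(clock = nm, analysis = "ctct", n = ct$n_obs,
             estimate = ct$r, p = ct$p),
      tibble(clock = nm, analysis = "delta_mz", n = dm$n_pairs,
             estimate = dm$b, p = dm$p)
    )
  })
  n_mz_pairs <- if (nrow(twin) > 0) {
    max(twin$n[twin$analysis == "delta_mz"])
  } else 0L

  # ---- sensitivity subsets --------------------------------------------
  sens <- purrr::map_dfr(config$sensitivity_gaps, function(gap) {
    sub <- subset_by_blood_mri_gap(analysis, gap)
    purrr::map_dfr(names(clocks), function(nm) {
      if (nrow(sub) < 30) {
        say("sensitivity gap > %g skipped for %s: n = %d", gap, nm,
            nrow(sub))
        return(tibble())
      }
      fit <- fit_association(sub, paste0(nm, "_accel"),
                             response = "brain_aa", model = "full",
                             df_method = config$df_method)
      g <- glance(fit)
      tibble(clock = nm, gap_years = gap, n = g$n, b = g$b, p = g$p)
    })
  })

  run <- structure(list(
    associations = assoc,
    twin = twin,
    sensitivity = sens,
    counts = counts,
    exclusions = list(missing = mc$report, outliers = ro$report),
    threshold = threshold,
    n_analysis = nrow(analysis),
    n_mz_pairs = n_mz_pairs,
    clock_names = names(clocks),
    seed = seed,
    log = log_lines,
    cohort = analysis,
    version = as.character(utils::packageVersion("twinclock"))
  ), class = "twinclock_run")

  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.twinclock_run <- function(x, ...) {
  cat(sprintf("<twinclock_run> seed %d: %d individuals analysed (%d MZ pairs)\n",
              x$seed, x$n_analysis, x$n_mz_pairs))
  cat(sprintf("  significance threshold: %.4f\n", x$threshold$display))
  ex <- x$associations[x$associations$term %in%
                         paste0(x$clock_names, "_accel"), ]
  for (i in seq_len(nrow(ex))) {
    cat(sprintf("  %s [%s]: b = %.3f, p = %.4f%s\n",
                ex$clock[i], ex$model[i], ex$estimate[i], ex$p_value[i],
                if (ex$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Serializes all result tables of a [run_pipeline()] report as
#' comma-separated text, along with the run log and a manifest (file, row
#' count, md5 checksum) for auditability.
#'
#' @param run A `twinclock_run`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    associations = run$associations,
    twin = run$twin,
    sensitivity = run$sensitivity,
    counts = run$counts,
    exclusions_missing = run$exclusions$missing,
    exclusions_outliers = run$exclusions$outliers
  )
  for (nm in names(tabs)) {
    readr::write_csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  writeLines(run$log, file.path(out_dir, "run.log"))
  files <- file.path(out_dir, paste0(names(tabs), ".csv"))
  manifest <- tibble(
    file = basename(files),
    rows = vapply(tabs, nrow, 1L),
    md5 = unname(tools::md5sum(files))
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(out_dir)
}
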