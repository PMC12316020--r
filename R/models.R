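#' Z-score a numeric vector
#'
#' Centers to mean 0 and scales to sample SD 1 (n - 1 denominator).
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return The standardized vector.
#' @export
standardize <- function(values) {
  if (length(values) < 2) {
    abort("Standardization needs at least 2 values.",
          class = "twinclock_degenerate_error")
  }
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    abort("Zero or undefined SD: cannot standardize.",
          class = "twinclock_degenerate_error")
  }
  (values - mean(values, na.rm = TRUE)) / s
}

#' Collapse ordered plate labels into contiguous groups
#'
#' Bisulphite plates processed consecutively share batch conditions, and
#' sparse plates make dummy coding unstable; collapsing consecutive plates
#' into a handful of contiguous groups of near-equal size (group sizes
#' differing by at most one plate, larger groups first) keeps the batch
#' adjustment while bounding the number of dummies. Collapsing 34 plates
#' into 6 groups yields plate counts 6, 6, 6, 6, 5, 5.
#'
#' @param plate_labels Vector of plate labels; ordering is taken from sorted
#'   unique values (numeric sort where labels are numeric).
#' @param n_groups Number of collapsed groups.
#' @return A factor of length `length(plate_labels)` with levels
#'   `"P1" ... "Pn_groups"`.
#' @export
collapse_plates <- function(plate_labels, n_groups = 6) {
  if (n_groups < 1) {
    abort("`n_groups` must be >= 1.", class = "twinclock_parameter_error")
  }
  lv <- sort(unique(plate_labels))
  if (n_groups > length(lv)) {
    abort("`n_groups` exceeds the number of distinct plates.",
          class = "twinclock_parameter_error")
  }
  base_size <- length(lv) %/% n_groups
  extra <- length(lv) %% n_groups
  sizes <- rep(base_size, n_groups) + rep(1:0, c(extra, n_groups - extra))
  group_of <- rep(seq_len(n_groups), times = sizes)
  factor(paste0("P", group_of[match(plate_labels, lv)]),
         levels = paste0("P", seq_len(n_groups)))
}

#' Build the design for a family-clustered association model
#'
#' Assembles response, exposure and covariates for one regression of brain
#' age acceleration on one clock's acceleration. Three covariate sets are
#' supported:
#' \describe{
#'   \item{`base`}{exposure + collapsed-plate dummies (reference-coded) +
#'     array row.}
#'   \item{`full`}{base + sex + BMI + smoking dummies (former and current
#'     vs. never) + neutrophil, monocyte and eosinophil percentages.
#'     Lymphocytes are omitted (near-collinear with neutrophils in a
#'     compositional differential) and basophils are omitted (negligible
#'     between-person variance).}
#'   \item{`full_scanner`}{full + MRI scanner field-strength dummy.}
#' }
#' All continuous variables (response, exposure, array row, BMI, WBC
#' percentages) are Z-scored on the analysis sample; dummies are untouched.
#'
#' @param cohort Analysis-ready cohort tibble (post exclusions).
#' @param exposure Column name of the clock acceleration measure.
#' @param response Column name of the (corrected) brain-age acceleration.
#' @param model Covariate set: `"base"`, `"full"` or `"full_scanner"`.
#' @param n_plate_groups Number of collapsed plate groups.
#' @return An object of class `twinclock_design`: list with the model
#'   `data`, `formula`, fixed-effects matrix `x`, response `y`, `family_id`,
#'   and the `exposure`/`model` labels.
#' @export
build_design <- function(cohort, exposure, response = "brain_aa",
                         model = c("base", "full", "full_scanner"),
                         n_plate_groups = 6) {
  model <- match.arg(model)
  need <- c("individual_id", "family_id", exposure, response, "plate",
            "array_row")
  if (model %in% c("full", "full_scanner")) {
    need <- c(need, "sex", "bmi", "smoking", "pct_neutrophils",
              "pct_monocytes", "pct_eosinophils")
  }
  if (model == "full_scanner") need <- c(need, "scanner_ft")
  stopifnot_columns(cohort, need, "cohort")
  if (exposure %in% c("plate", "array_row", "sex", "bmi", "smoking")) {
    abort("`exposure` collides with a covariate column.",
          class = "twinclock_parameter_error")
  }

  dat <- tibble(
    .y = standardize(cohort[[response]]),
    exposure = standardize(cohort[[exposure]]),
    plate_group = collapse_plates(cohort$plate, n_plate_groups),
    array_row = standardize(as.numeric(cohort$array_row))
  )
  rhs <- c("exposure", "plate_group", "array_row")
  if (model %in% c("full", "full_scanner")) {
    dat$sex <- factor(cohort$sex, levels = c("F", "M"))
    dat$bmi <- standardize(cohort$bmi)
    dat$smoking <- factor(cohort$smoking,
                          levels = c("never", "former", "current"))
    dat$pct_neutrophils <- standardize(cohort$pct_neutrophils)
    dat$pct_monocytes <- standardize(cohort$pct_monocytes)
    dat$pct_eosinophils <- standardize(cohort$pct_eosinophils)
    rhs <- c(rhs, "sex", "bmi", "smoking", "pct_neutrophils",
             "pct_monocytes", "pct_eosinophils")
  }
  if (model == "full_scanner") {
    dat$scanner_ft <- factor(cohort$scanner_ft)
    rhs <- c(rhs, "scanner_ft")
  }

  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  x <- stats::model.matrix(fml, dat)
  structure(list(
    data = dat, formula = fml, x = x, y = dat$.y,
    family_id = cohort$family_id,
    individual_id = cohort$individual_id,
    exposure = exposure, response = response, model = model
  ), class = "twinclock_design")
}

#' Fit a family-clustered linear model
#'
#' Fits `response = X beta + u_family + e` with one Gaussian random
#' intercept per family (restricted maximum likelihood via \pkg{lme4}),
#' accounting for the non-independence of twins and siblings. Wald p-values
#' use a residual degrees-of-freedom approximation (`n - p`) by default; a
#' Satterthwaite option is available via \pkg{lmerTest}. When every family
#' contributes a single individual the random intercept is unidentified and
#' the model reduces exactly to ordinary least squares, which is what is
#' fitted in that case.
#'
#' @param design A `twinclock_design` from [build_design()].
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @return An object of class `twinclock_fit`; see [tidy.twinclock_fit()]
#'   and [glance.twinclock_fit()].
#' @export
fit_family_lmm <- function(design, df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  if (!inherits(design, "twinclock_design")) {
    abort("`design` must come from build_design().",
          class = "twinclock_parameter_error")
  }
  x <- design$x
  y <- design$y
  n <- length(y)
  p <- ncol(x)
  if (n <= p) {
    abort("More fixed-effect columns than observations.",
          class = "twinclock_rank_error")
  }
  if (qr(x)$rank < p) {
    abort("Singular fixed-effects design.", class = "twinclock_rank_error")
  }
  fam <- factor(design$family_id)
  singleton_only <- all(table(fam) == 1L)

  if (singleton_only) {
    fit <- lm(y ~ x - 1)
    s <- summary(fit)
    est <- coef(fit)
    se <- s$coefficients[, 2]
    df <- fit$df.residual
    tval <- est / se
    pval <- 2 * pt(-abs(tval), df)
    tau2 <- 0
    sigma2 <- s$sigma^2
    converged <- TRUE
  } else {
    md <- data.frame(.y = y, .family = fam, x[, -1, drop = FALSE],
                     check.names = TRUE)
    xn <- colnames(md)[-(1:2)]
    fml <- stats::as.formula(paste(
      ".y ~", paste(c("1", xn), collapse = " + "), "+ (1 | .family)"))
    use_lmertest <- df_method == "satterthwaite" &&
      requireNamespace("lmerTest", quietly = TRUE)
    # lme4 raises its diagnostics as raw warnings; capture them and re-emit
    # a single summarized warning for genuine convergence failures (a
    # boundary-singular fit, i.e. random-intercept variance estimated at
    # zero, is a valid REML solution, not a failure).
    fit <- withCallingHandlers(
      if (use_lmertest) {
        lmerTest::lmer(fml, data = md, REML = TRUE)
      } else {
        lme4::lmer(fml, data = md, REML = TRUE)
      },
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")
    )
    conv_msgs <- fit@optinfo$conv$lme4$messages
    real_problems <- setdiff(
      conv_msgs,
      grep("boundary \\(singular\\)", conv_msgs, value = TRUE))
    grad_ok <- tryCatch({
      dv <- fit@optinfo$derivs
      is.null(dv) || max(abs(dv$gradient)) < 0.01
    }, error = function(e) TRUE)
    if (length(real_problems) > 0 && !grad_ok) {
      warn(paste("Mixed-model convergence message:",
                 paste(real_problems, collapse = "; ")))
    }
    sm <- summary(fit)
    co <- sm$coefficients
    est <- co[, "Estimate"]
    se <- co[, "Std. Error"]
    tval <- est / se
    if (use_lmertest) {
      df <- co[, "df"]
      pval <- co[, "Pr(>|t|)"]
    } else {
      df <- rep(n - p, p)
      pval <- 2 * pt(-abs(tval), df)
    }
    vc <- as.data.frame(lme4::VarCorr(fit))
    tau2 <- vc$vcov[vc$grp == ".family"]
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    converged <- length(real_problems) == 0 || grad_ok
    # restore the original design-column names
    names(est) <- names(se) <- colnames(x)
  }

  terms_tbl <- tibble(
    term = colnames(x),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(tval),
    df = unname(df),
    p_value = unname(pval)
  )
  terms_tbl$term[terms_tbl$term == "exposure"] <- design$exposure

  structure(list(
    terms = terms_tbl,
    exposure = design$exposure,
    response = design$response,
    model = design$model,
    n = n, n_families = nlevels(fam),
    random_intercept_var = tau2,
    residual_var = sigma2,
    df_method = if (singleton_only) "residual" else df_method,
    singleton_ols = singleton_only,
    converged = converged,
    fit = fit
  ), class = "twinclock_fit")
}

#' @export
print.twinclock_fit <- function(x, ...) {
  cat(sprintf(
    "<twinclock_fit> %s ~ %s (%s model), n = %d in %d families\n",
    x$response, x$exposure, x$model, x$n, x$n_families))
  ex <- x$terms[x$terms$term == x$exposure, ]
  cat(sprintf("  exposure b = %.3f (SE %.3f), p = %.4g\n",
              ex$estimate, ex$std_error, ex$p_value))
  cat(sprintf("  random-intercept var = %.3f, residual var = %.3f\n",
              x$random_intercept_var, x$residual_var))
  invisible(x)
}

#' Regress brain-age acceleration on one clock's acceleration
#'
#' One-call wrapper: [build_design()] then [fit_family_lmm()].
#'
#' @inheritParams build_design
#' @inheritParams fit_family_lmm
#' @return A `twinclock_fit`.
#' @export
fit_association <- function(cohort, exposure, response = "brain_aa",
                            model = "base", n_plate_groups = 6,
                            df_method = "residual") {
  build_design(cohort, exposure, response = response, model = model,
               n_plate_groups = n_plate_groups) |>
    fit_family_lmm(df_method = df_method)
}

#' Subset a cohort by the blood-to-MRI interval
#'
#' Keeps individuals whose blood was drawn strictly more than `min_years`
#' before the MRI visit, i.e. `age_mri - age_blood > min_years`.
#'
#' @param cohort A data frame with `age_mri` and `age_blood`.
#' @param min_years Minimum interval in years (strict inequality).
#' @return The subset tibble.
#' @export
subset_by_blood_mri_gap <- function(cohort, min_years) {
  stopifnot_columns(cohort, c("age_mri", "age_blood"), "cohort")
  as_tibble(cohort[cohort$age_mri - cohort$age_blood > min_years, ,
                   drop = FALSE])
}

#' Bonferroni threshold for an effective number of independent tests
#'
#' Correlated outcomes (here, five epigenetic biomarkers spanning fewer
#' independent dimensions) warrant dividing the family-wise alpha by the
#' effective number of independent tests rather than the raw test count.
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param k_eff Effective number of independent tests (integer >= 1).
#' @return A list: `threshold` (exact `alpha / k_eff`, used for comparison)
#'   and `display` (rounded to 4 decimals for reporting).
#' @examples
#' bonferroni_effective(0.05, 3)$display  # 0.0167
#' @export
bonferroni_effective <- function(alpha = 0.05, k_eff = 1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "twinclock_parameter_error")
  }
  if (!is.finite(k_eff) || k_eff < 1 || k_eff != round(k_eff)) {
    abort("`k_eff` must be an integer >= 1.",
          class = "twinclock_parameter_error")
  }
  list(threshold = alpha / k_eff, display = round(alpha / k_eff, 4))
}
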