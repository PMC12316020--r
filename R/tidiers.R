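#' Tidy a family-clustered model fit
#'
#' @param x A `twinclock_fit` from [fit_family_lmm()].
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: `term`, `estimate`,
#'   `std_error`, `statistic`, `df`, `p_value`.
#' @method tidy twinclock_fit
#' @export
tidy.twinclock_fit <- function(x, ...) {
  x$terms
}

#' One-row summary of a family-clustered model fit
#'
#' @param x A `twinclock_fit` from [fit_family_lmm()].
#' @param ... Unused.
#' @return A one-row tibble: exposure/response/model labels, exposure
#'   coefficient and p-value, sample and family counts, variance components,
#'   df method, convergence flag.
#' @method glance twinclock_fit
#' @export
glance.twinclock_fit <- function(x, ...) {
  ex <- x$terms[x$terms$term == x$exposure, ]
  tibble(
    response = x$response,
    exposure = x$exposure,
    model = x$model,
    b = ex$estimate,
    se = ex$std_error,
    p = ex$p_value,
    n = x$n,
    n_families = x$n_families,
    random_intercept_var = x$random_intercept_var,
    residual_var = x$residual_var,
    df_method = x$df_method,
    converged = x$converged
  )
}

#' Tidy a pipeline run into its association table
#'
#' @param x A `twinclock_run` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-clock, per-model association tibble.
#' @method tidy twinclock_run
#' @export
tidy.twinclock_run <- function(x, ...) {
  x$associations
}

#' One-row summary of a pipeline run
#'
#' @param x A `twinclock_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble of sample bookkeeping and the significance
#'   threshold applied.
#' @method glance twinclock_run
#' @export
glance.twinclock_run <- function(x, ...) {
  tibble(
    n_input = x$counts$n_in[1],
    n_analysis = x$n_analysis,
    n_mz_pairs = x$n_mz_pairs,
    n_clocks = length(x$clock_names),
    threshold = x$threshold$threshold,
    seed = x$seed
  )
}
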