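#' Assemble complete twin pairs for two traits
#'
#' Reshapes an individual-level cohort into one row per complete twin pair,
#' with trait values of twin 1 and twin 2 side by side. Incomplete pairs
#' (singletons, or pairs where either twin lacks either trait) are dropped
#' and counted.
#'
#' @param cohort Individual-level tibble with `family_id`, `zygosity`,
#'   `twin_order` and the two trait columns.
#' @param trait_x,trait_y Column names of the two (standardized) traits;
#'   conventionally X is a clock's acceleration and Y brain-age acceleration.
#' @param zygosity Keep only pairs of this zygosity (`"MZ"`, `"DZ"`, or
#'   `NULL` for both).
#' @return A tibble `family_id`, `zygosity`, `x1`, `x2`, `y1`, `y2` with one
#'   row per family; the number of incomplete pairs dropped is attached as
#'   attribute `n_dropped`.
#' @export
make_pairs <- function(cohort, trait_x, trait_y, zygosity = "MZ") {
  stopifnot_columns(cohort, c("family_id", "zygosity", "twin_order",
                              trait_x, trait_y), "cohort")
  twins <- cohort[!is.na(cohort$twin_order), , drop = FALSE]
  if (!is.null(zygosity)) {
    twins <- twins[!is.na(twins$zygosity) & twins$zygosity %in% zygosity, ,
                   drop = FALSE]
  }
  dup <- duplicated(twins[, c("family_id", "twin_order")])
  if (any(dup)) {
    abort("Duplicated twin_order within family.",
          class = "twinclock_data_integrity_error")
  }

  wide <- tibble(family_id = twins$family_id,
                 zygosity = twins$zygosity,
                 twin_order = twins$twin_order,
                 x = twins[[trait_x]],
                 y = twins[[trait_y]]) |>
    tidyr::pivot_wider(names_from = "twin_order",
                       values_from = c("x", "y"),
                       names_sep = "")
  for (col in c("x1", "x2", "y1", "y2")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  complete <- stats::complete.cases(wide[, c("x1", "x2", "y1", "y2")])
  out <- wide[complete, c("family_id", "zygosity", "x1", "x2", "y1", "y2")]
  attr(out, "n_dropped") <- sum(!complete)
  out
}

#' Cross-twin cross-trait correlation
#'
#' Correlates trait X in one twin with trait Y in the co-twin. A familial
#' (genetic and/or shared-environmental) aetiology of the X-Y association
#' predicts a positive cross-twin cross-trait correlation in MZ pairs; under
#' the bivariate ACE model its expectation in MZ pairs is
#' `rA*sqrt(a2_x*a2_y) + rC*sqrt(c2_x*c2_y)`.
#'
#' With `double_entry = TRUE` (default) each pair enters in both orderings,
#' `(x1, y2)` and `(x2, y1)`, making the estimate exactly invariant to the
#' arbitrary within-pair labelling. Because the two entries of a pair are
#' not independent, the default p-value conservatively uses `n_pairs - 2`
#' degrees of freedom; `df = "observations"` uses `2*n_pairs - 2` instead
#' (the convention that reports n as twice the pair count).
#'
#' @param pairs A pair table from [make_pairs()].
#' @param double_entry Include each pair in both orderings.
#' @param df Degrees-of-freedom convention for the p-value: `"pairs"`
#'   (`n_pairs - 2`) or `"observations"` (`n_obs - 2`).
#' @return A tibble: `r`, `p`, `n_obs`, `n_pairs`, `df`.
#' @export
ctct_correlation <- function(pairs, double_entry = TRUE,
                             df = c("pairs", "observations")) {
  df <- match.arg(df)
  if (nrow(pairs) < 3) {
    abort("Cross-twin cross-trait correlation needs >= 3 pairs.",
          class = "twinclock_degenerate_error")
  }
  if (double_entry) {
    a <- c(pairs$x1, pairs$x2)
    b <- c(pairs$y2, pairs$y1)
  } else {
    a <- pairs$x1
    b <- pairs$y2
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Zero variance in cross-twin entries.",
          class = "twinclock_degenerate_error")
  }
  r <- cor(a, b)
  n_obs <- length(a)
  dof <- if (df == "pairs") nrow(pairs) - 2 else n_obs - 2
  tstat <- r * sqrt(dof / (1 - r^2))
  tibble(r = r, p = 2 * pt(-abs(tstat), dof),
         n_obs = n_obs, n_pairs = nrow(pairs), df = dof)
}

#' MZ-twin difference regression
#'
#' Regresses within-pair differences in trait Y on within-pair differences
#' in trait X across MZ pairs. MZ co-twins share all additive-genetic and
#' shared-environmental influences, so any association between the
#' differences can only arise from unique-environment factors; on
#' standardized traits the no-intercept slope estimates the
#' unique-environment cross-trait correlation rE.
#'
#' The default omits the intercept because pair ordering is arbitrary, so
#' the differences have expectation zero; `include_intercept = TRUE` is
#' available. The slope is invariant to a global flip of all pair orderings.
#'
#' @param pairs An MZ pair table from [make_pairs()].
#' @param include_intercept Fit an intercept term.
#' @return A tibble: `b`, `se`, `p`, `n_pairs`, `df`.
#' @export
mz_difference_regression <- function(pairs, include_intercept = FALSE) {
  if (nrow(pairs) < 3) {
    abort("MZ difference regression needs >= 3 pairs.",
          class = "twinclock_degenerate_error")
  }
  dx <- pairs$x1 - pairs$x2
  dy <- pairs$y1 - pairs$y2
  if (all(dx == 0)) {
    abort("All within-pair differences in trait X are zero.",
          class = "twinclock_degenerate_error")
  }
  fit <- if (include_intercept) lm(dy ~ dx) else lm(dy ~ dx - 1)
  s <- summary(fit)$coefficients
  row <- if (include_intercept) 2L else 1L
  dof <- fit$df.residual
  tibble(b = s[row, 1], se = s[row, 2],
         p = 2 * pt(-abs(s[row, 1] / s[row, 2]), dof),
         n_pairs = nrow(pairs), df = dof)
}
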