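#' Remove individuals with missing covariate values
#'
#' @param cohort A data frame with an `individual_id` column.
#' @param required_columns Character vector of covariate columns that must be
#'   complete.
#' @return A list: `kept` (rows complete on all required columns), `removed`,
#'   and `report` (a tibble `individual_id`, `missing_columns` naming the
#'   offending columns per removed row).
#' @export
filter_missing_covariates <- function(cohort, required_columns) {
  stopifnot_columns(cohort, c("individual_id", required_columns), "cohort")
  miss <- is.na(as.data.frame(cohort)[, required_columns, drop = FALSE])
  any_miss <- rowSums(miss) > 0
  report <- tibble(
    individual_id = cohort$individual_id[any_miss],
    missing_columns = apply(miss[any_miss, , drop = FALSE], 1, function(r) {
      paste(required_columns[r], collapse = ";")
    })
  )
  list(kept = as_tibble(cohort[!any_miss, , drop = FALSE]),
       removed = as_tibble(cohort[any_miss, , drop = FALSE]),
       report = report)
}

#' Rosner's generalized extreme studentized deviate (ESD) outlier test
#'
#' Tests for up to `k_max` outliers in an approximately normal sample.
#' Iteratively, for `i = 1..k_max`, the statistic `R_i = max|x - mean(x)| /
#' sd(x)` is computed on the current set, the most extreme value removed,
#' and `R_i` compared against the critical value
#' `lambda_i = (n-i) * t / sqrt((n-i-1+t^2) * (n-i+1))`, where `t` is the
#' `1 - alpha / (2*(n-i+1))` quantile of the t-distribution with `n-i-1`
#' degrees of freedom. The declared number of outliers is the largest `i`
#' with `R_i > lambda_i` (so an inlying value removed en route can be
#' re-declared an outlier if a later `R_i` exceeds its threshold). Ties at
#' the maximum deviation are broken by lowest original index.
#'
#' @param values Numeric vector (no `NA`s).
#' @param k_max Maximum number of outliers to test for; must satisfy
#'   `k_max <= n - 3`.
#' @param alpha Significance level of the test.
#' @return A list: `outliers` (integer indices into `values`, in removal
#'   order) and `report` (a tibble with one row per iteration: `iteration`,
#'   `R`, `lambda`, `candidate_index`, `candidate_value`, `flagged`).
#' @examples
#' x <- c(rnorm(50), 25)
#' rosner_esd(x, k_max = 3)$outliers  # 51
#' @export
rosner_esd <- function(values, k_max = 10, alpha = 0.05) {
  n <- length(values)
  if (anyNA(values)) {
    abort("`values` must not contain NA.", class = "twinclock_parameter_error")
  }
  if (k_max < 1 || k_max > n - 3) {
    abort("`k_max` must satisfy 1 <= k_max <= n - 3.",
          class = "twinclock_parameter_error")
  }
  if (sd(values) == 0) {
    abort("Zero variance: ESD test is degenerate.",
          class = "twinclock_degenerate_error")
  }

  cur <- values
  idx <- seq_len(n)
  removed <- integer(k_max)
  R <- lambda <- cand_val <- numeric(k_max)
  for (i in seq_len(k_max)) {
    m <- mean(cur)
    s <- sd(cur)
    if (s == 0) {
      # Remaining values identical: nothing further can be studentized.
      removed <- removed[seq_len(i - 1L)]
      R <- R[seq_len(i - 1L)]; lambda <- lambda[seq_len(i - 1L)]
      cand_val <- cand_val[seq_len(i - 1L)]
      break
    }
    dev <- abs(cur - m)
    j <- which.max(dev)          # first max = lowest original index
    R[i] <- dev[j] / s
    p <- 1 - alpha / (2 * (n - i + 1))
    tq <- qt(p, df = n - i - 1)
    lambda[i] <- (n - i) * tq / sqrt((n - i - 1 + tq^2) * (n - i + 1))
    removed[i] <- idx[j]
    cand_val[i] <- cur[j]
    cur <- cur[-j]
    idx <- idx[-j]
  }

  k_done <- length(R)
  n_out <- if (k_done > 0 && any(R > lambda)) max(which(R > lambda)) else 0L
  report <- tibble(
    iteration = seq_len(k_done),
    R = R, lambda = lambda,
    candidate_index = removed,
    candidate_value = cand_val,
    flagged = seq_len(k_done) <= n_out
  )
  list(outliers = removed[seq_len(n_out)], report = report)
}

#' Flag outliers across several cohort columns and remove their union
#'
#' Applies [rosner_esd()] separately to each named column and removes the
#' union of flagged individuals, the screening convention used before the
#' association models.
#'
#' @param cohort A data frame with `individual_id`.
#' @param columns Character vector of numeric columns to screen.
#' @param k_max,alpha Passed to [rosner_esd()].
#' @return A list: `kept`, `removed`, and `report` (tibble `individual_id`,
#'   `column` for every flag raised).
#' @export
screen_outliers <- function(cohort, columns, k_max = 10, alpha = 0.05) {
  stopifnot_columns(cohort, c("individual_id", columns), "cohort")
  flags <- purrr::map_dfr(columns, function(col) {
    res <- rosner_esd(cohort[[col]], k_max = k_max, alpha = alpha)
    tibble(individual_id = cohort$individual_id[res$outliers], column = col)
  })
  out_ids <- unique(flags$individual_id)
  is_out <- cohort$individual_id %in% out_ids
  list(kept = as_tibble(cohort[!is_out, , drop = FALSE]),
       removed = as_tibble(cohort[is_out, , drop = FALSE]),
       report = flags)
}
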