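#' Define a linear CpG clock
#'
#' A clock is a linear predictor over CpG beta values: `intercept +
#' sum(weights * beta)`, followed by an inverse output transform. Two
#' transforms are supported: `"identity"` (clocks trained directly on age or
#' on pace of ageing) and `"horvath_log_linear"`, the piecewise
#' log-linear age transform used by multi-tissue chronological-age clocks,
#' parameterised by an adult-age knot (default 20 years).
#'
#' @param name Clock name (used to label output columns).
#' @param intercept Intercept on the transform scale.
#' @param weights Named numeric vector of CpG weights; names are CpG ids.
#' @param transform `"identity"` or `"horvath_log_linear"`.
#' @param adult_age Knot of the log-linear transform (years); required > 0
#'   when `transform = "horvath_log_linear"`.
#' @param output_kind `"age_years"` (estimate is an age, later residualized
#'   on chronological age) or `"pace_unitless"` (estimate is a pace of
#'   ageing, used as-is).
#'
#' @return An object of class `clock_model`.
#' @examples
#' clock_model("toy", intercept = 10,
#'             weights = c(cg01 = 2, cg02 = -1, cg03 = 5))
#' @export
clock_model <- function(name, intercept, weights,
                        transform = c("identity", "horvath_log_linear"),
                        adult_age = 20, output_kind = c("age_years",
                                                        "pace_unitless")) {
  transform <- match.arg(transform)
  output_kind <- match.arg(output_kind)
  if (length(weights) < 1 || is.null(names(weights)) ||
      any(!nzchar(names(weights)))) {
    abort("`weights` must be a non-empty named numeric vector of CpG weights.",
          class = "twinclock_parameter_error")
  }
  if (anyDuplicated(names(weights))) {
    abort("CpG ids in `weights` must be unique.",
          class = "twinclock_parameter_error")
  }
  if (transform == "horvath_log_linear" &&
      (!is.finite(adult_age) || adult_age <= 0)) {
    abort("`adult_age` must be > 0 for the horvath_log_linear transform.",
          class = "twinclock_parameter_error")
  }
  structure(list(name = name, intercept = intercept,
                 weights = weights, transform = transform,
                 adult_age = adult_age, output_kind = output_kind),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s: %d CpGs, transform = %s, output = %s\n",
              x$name, length(x$weights), x$transform, x$output_kind))
  invisible(x)
}

# Piecewise transform between age (years) and the linear-predictor scale.
# Forward maps age -> transform scale; inverse is its exact inverse:
# inverse(y) = (A+1)*exp(y) - 1 for y < 0, else y*(A+1) + A.
horvath_forward <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

horvath_inverse <- function(y, adult_age = 20) {
  ifelse(y < 0,
         (adult_age + 1) * exp(y) - 1,
         y * (adult_age + 1) + adult_age)
}

forward_transform <- function(clock, value) {
  switch(clock$transform,
         identity = value,
         horvath_log_linear = horvath_forward(value, clock$adult_age))
}

inverse_transform <- function(clock, value) {
  switch(clock$transform,
         identity = value,
         horvath_log_linear = horvath_inverse(value, clock$adult_age))
}

#' Apply a clock to a beta-value matrix
#'
#' Computes the clock estimate for every sample:
#' `inverse_transform(intercept + sum_i w_i * beta_i)`.
#'
#' @param betas Numeric matrix of beta values, CpG ids as rownames, sample
#'   ids as colnames; all values in \[0, 1\] or `NA`.
#' @param clock A [clock_model()].
#' @param missing_probes `"error"` (default) to fail when a clock CpG is
#'   absent from `betas` or its value is `NA`; `"impute"` to substitute the
#'   hemi-methylated value 0.5 with a warning.
#' @return A tibble `sample_id`, `estimate` (years for age clocks, unitless
#'   for pace clocks), `clock`.
#' @examples
#' clk <- clock_model("toy", 10, c(cg01 = 2, cg02 = -1, cg03 = 5))
#' b <- matrix(c(0.1, 0.5, 0.2), nrow = 3,
#'             dimnames = list(c("cg01", "cg02", "cg03"), "s1"))
#' apply_clock(b, clk)  # 10 + 0.2 - 0.5 + 1.0 = 10.7
#' @export
apply_clock <- function(betas, clock, missing_probes = c("error", "impute")) {
  missing_probes <- match.arg(missing_probes)
  if (!is.matrix(betas) || is.null(rownames(betas)) ||
      is.null(colnames(betas))) {
    abort("`betas` must be a matrix with CpG rownames and sample colnames.",
          class = "twinclock_parameter_error")
  }
  if (anyDuplicated(rownames(betas)) || anyDuplicated(colnames(betas))) {
    abort("CpG ids and sample ids in `betas` must be unique.",
          class = "twinclock_parameter_error")
  }
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    abort("Beta values must lie in [0, 1].",
          class = "twinclock_domain_error")
  }

  cpgs <- names(clock$weights)
  absent <- setdiff(cpgs, rownames(betas))
  sub <- matrix(NA_real_, length(cpgs), ncol(betas),
                dimnames = list(cpgs, colnames(betas)))
  present <- intersect(cpgs, rownames(betas))
  sub[present, ] <- betas[present, , drop = FALSE]

  if (anyNA(sub)) {
    bad <- cpgs[rowSums(is.na(sub)) > 0]
    if (missing_probes == "error") {
      abort(
        sprintf("Clock '%s': %d required CpG(s) missing or NA: %s%s",
                clock$name, length(bad),
                paste(head(bad, 5), collapse = ", "),
                if (length(bad) > 5) ", ..." else ""),
        class = "twinclock_missing_probe_error")
    }
    warn(sprintf(
      "Clock '%s': imputing 0.5 for %d missing CpG value(s) (%d absent probes).",
      clock$name, sum(is.na(sub)), length(absent)))
    sub[is.na(sub)] <- 0.5
  }

  linear <- clock$intercept + drop(crossprod(sub, clock$weights))
  tibble(sample_id = colnames(betas),
         estimate = unname(inverse_transform(clock, linear)),
         clock = clock$name)
}

#' Age-acceleration residuals of clock estimates
#'
#' Residualizes clock age estimates on chronological age by ordinary least
#' squares within the sample at hand: the acceleration of an individual is
#' the part of their clock age not explained by the cohort-level linear
#' age trend. Residuals sum to zero and are uncorrelated with chronological
#' age by construction.
#'
#' @param data A data frame holding estimates and ages.
#' @param estimate,chron_age Column names (strings) of the clock estimate
#'   and chronological age.
#' @param accel Name of the output column.
#' @return `data` with the acceleration column appended.
#' @export
compute_age_acceleration <- function(data, estimate = "estimate",
                                     chron_age = "chron_age",
                                     accel = "accel") {
  stopifnot_columns(data, c(estimate, chron_age), "data")
  est <- data[[estimate]]
  age <- data[[chron_age]]
  if (length(est) < 3) {
    abort("Age-acceleration residuals need at least 3 samples.",
          class = "twinclock_degenerate_error")
  }
  if (sd(age) == 0) {
    abort("Chronological ages are constant; residualization is degenerate.",
          class = "twinclock_degenerate_error")
  }
  data[[accel]] <- unname(resid(lm(est ~ age)))
  data
}

#' Pass pace-of-ageing estimates through unchanged
#'
#' Pace-type clocks (estimating years of physiological ageing per calendar
#' year) are not residualized on chronological age; their estimates enter
#' the association models directly, with standardization deferred to the
#' modelling stage.
#'
#' @param estimates Numeric vector of pace estimates.
#' @param clock The [clock_model()] they came from (must have
#'   `output_kind = "pace_unitless"`).
#' @return `estimates`, unchanged.
#' @export
pace_passthrough <- function(estimates, clock) {
  if (!inherits(clock, "clock_model") ||
      clock$output_kind != "pace_unitless") {
    abort("`pace_passthrough()` requires a pace-type clock.",
          class = "twinclock_kind_mismatch_error")
  }
  estimates
}

#' Read and write clock coefficient files
#'
#' The on-disk format is delimited text with columns `cpg,weight`; the
#' intercept is the reserved row `(Intercept)`. Clock metadata (`name`,
#' `transform`, `adult_age`, `output_kind`) travels in `#key=value` header
#' comment lines before the column header.
#'
#' @param path File path.
#' @return For `read_clock()`, a [clock_model()].
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(name = "clock", transform = "identity", adult_age = "20",
               output_kind = "age_years")
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  tab <- readr::read_csv(I(grep("^#", lines, invert = TRUE, value = TRUE)),
                         col_types = readr::cols(
                           cpg = readr::col_character(),
                           weight = readr::col_double()))
  is_int <- tab$cpg == "(Intercept)"
  intercept <- if (any(is_int)) tab$weight[is_int][1] else 0
  w <- tab$weight[!is_int]
  names(w) <- tab$cpg[!is_int]
  clock_model(meta$name, intercept, w, transform = meta$transform,
              adult_age = as.numeric(meta$adult_age),
              output_kind = meta$output_kind)
}

#' @rdname read_clock
#' @param clock A [clock_model()] to serialize.
#' @export
write_clock <- function(clock, path) {
  header <- c(sprintf("#name=%s", clock$name),
              sprintf("#transform=%s", clock$transform),
              sprintf("#adult_age=%s", format(clock$adult_age)),
              sprintf("#output_kind=%s", clock$output_kind))
  body <- c("cpg,weight",
            sprintf("(Intercept),%s", format(clock$intercept, digits = 17)),
            sprintf("%s,%s", names(clock$weights),
                    vapply(clock$weights, format, "", digits = 17)))
  writeLines(c(header, body), path)
  invisible(path)
}
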