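#' Construct a beta matrix that a given clock maps to target ages
#'
#' Solves the inverse problem of the clock engine: given target ages (one per
#' sample), build CpG beta values in \[0, 1\] such that [apply_clock()]
#' recovers `target + Normal(0, noise_sd)`. All CpGs start at the
#' hemi-methylated value 0.5 and are displaced together along the normalized
#' coefficient direction by the scalar solving the linear predictor for the
#' (noisy) transformed target, then clipped to \[0, 1\]. A post-clip residual
#' check guarantees that clipping never silently degraded a sample: if the
#' required displacement is infeasible within the beta domain, the offending
#' samples are reported as an error.
#'
#' The construction deliberately perturbs one direction rather than modelling
#' per-CpG methylation variation: the object under test downstream is the
#' clock arithmetic, not methylation biology.
#'
#' @param clock A [clock_model()].
#' @param target_ages Numeric vector of target clock outputs (years for age
#'   clocks, unitless for pace clocks); names, if present, become sample ids.
#' @param noise_sd SD (same units as `target_ages`) of Gaussian noise added
#'   to the targets before inversion.
#' @param seed Integer seed for the noise draw.
#' @return A numeric matrix (CpG x sample) with `rownames` the clock's CpG
#'   ids and `colnames` the sample ids.
#' @examples
#' clk <- clock_model("toy", 0, c(cg01 = 30, cg02 = 40, cg03 = 50))
#' b <- generate_beta_matrix(clk, c(s1 = 40, s2 = 60))
#' apply_clock(b, clk)$estimate  # 40, 60 (exactly, noise_sd = 0)
#' @export
generate_beta_matrix <- function(clock, target_ages, noise_sd = 0, seed = 1L) {
  if (!inherits(clock, "clock_model")) {
    abort("`clock` must be a clock_model.",
          class = "twinclock_parameter_error")
  }
  if (length(target_ages) < 1) {
    abort("`target_ages` must be non-empty.",
          class = "twinclock_parameter_error")
  }
  if (clock$transform == "horvath_log_linear" && any(target_ages <= -1)) {
    abort("Target ages must exceed -1 year for the log-linear transform.",
          class = "twinclock_parameter_error")
  }
  sample_ids <- names(target_ages) %||%
    sprintf("s%04d", seq_along(target_ages))

  w <- clock$weights
  wnorm <- sqrt(sum(w^2))
  noisy <- with_seed(seed, target_ages + rnorm(length(target_ages), 0, noise_sd))
  y <- forward_transform(clock, noisy)

  # beta = 0.5 + delta * w/||w||  =>  w . beta = 0.5*sum(w) + delta*||w||
  delta <- (y - clock$intercept - 0.5 * sum(w)) / wnorm
  betas <- 0.5 + outer(w / wnorm, delta)
  betas <- pmin(pmax(betas, 0), 1)
  dimnames(betas) <- list(names(w), sample_ids)

  achieved <- inverse_transform(
    clock, clock$intercept + drop(crossprod(betas, w)))
  off <- which(abs(achieved - noisy) > 1e-6)
  if (length(off) > 0) {
    abort(
      sprintf(
        "Target infeasible within [0,1] betas for sample(s): %s%s",
        paste(head(sample_ids[off], 5), collapse = ", "),
        if (length(off) > 5) ", ..." else ""),
      class = "twinclock_infeasible_target_error")
  }
  betas
}

#' Read and write beta matrices as delimited text
#'
#' Format: comma-separated with CpG ids in the first column (`cpg`) and
#' sample ids as the remaining column headers. `read_beta_matrix()` also
#' accepts gzip-compressed files.
#'
#' @param path File path.
#' @return For `read_beta_matrix()`, a numeric CpG x sample matrix.
#' @export
read_beta_matrix <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    cpg = readr::col_character(), .default = readr::col_double()))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$cpg
  m
}

#' @rdname read_beta_matrix
#' @param betas A CpG x sample matrix to serialize.
#' @export
write_beta_matrix <- function(betas, path) {
  tab <- as_tibble(betas, rownames = "cpg")
  readr::write_csv(tab, path)
  invisible(path)
}
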