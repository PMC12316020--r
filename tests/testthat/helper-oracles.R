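# Independent brute-force oracles, deliberately coded differently from the
# package implementations they check.

# OLS by explicit normal equations.
oracle_ols_coef <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

oracle_ols_resid <- function(X, y) {
  drop(y - X %*% solve(t(X) %*% X, t(X) %*% y))
}

# Generalized ESD with explicit sum-based moments and index bookkeeping via
# a logical mask over the original vector.
oracle_esd <- function(x, k_max, alpha = 0.05) {
  n0 <- length(x)
  keep <- rep(TRUE, n0)
  Rs <- lam <- numeric(k_max)
  rem <- integer(k_max)
  for (i in 1:k_max) {
    xi <- x[keep]
    m <- length(xi)
    mu <- sum(xi) / m
    s <- sqrt(sum((xi - mu)^2) / (m - 1))
    d <- abs(x - mu)
    d[!keep] <- -Inf
    j <- which(d == max(d))[1]
    Rs[i] <- abs(x[j] - mu) / s
    pp <- 1 - alpha / (2 * (n0 - i + 1))
    tq <- stats::qt(pp, n0 - i - 1)
    lam[i] <- (n0 - i) * tq / sqrt((n0 - i - 1 + tq^2) * (n0 - i + 1))
    rem[i] <- j
    keep[j] <- FALSE
  }
  k <- if (any(Rs > lam)) max(which(Rs > lam)) else 0L
  list(outliers = rem[seq_len(k)], R = Rs, lambda = lam)
}

# Clock arithmetic by per-sample, per-CpG accumulation loops.
oracle_clock <- function(betas, clock) {
  out <- numeric(ncol(betas))
  for (s in seq_len(ncol(betas))) {
    acc <- clock$intercept
    for (cg in names(clock$weights)) {
      acc <- acc + clock$weights[[cg]] * betas[cg, s]
    }
    if (clock$transform == "horvath_log_linear") {
      A <- clock$adult_age
      out[s] <- if (acc < 0) (A + 1) * exp(acc) - 1 else acc * (A + 1) + A
    } else {
      out[s] <- acc
    }
  }
  out
}

# A small random clock plus a matching random beta matrix.
random_clock_case <- function(seed) {
  set.seed(seed)
  n_cpg <- sample(3:10, 1)
  n_samp <- sample(2:8, 1)
  ids <- sprintf("cg%06d", sample.int(1e6, n_cpg))
  clk <- clock_model(
    name = paste0("rand", seed),
    intercept = rnorm(1, 0, 5),
    weights = setNames(rnorm(n_cpg, 0, 3), ids),
    transform = sample(c("identity", "horvath_log_linear"), 1),
    adult_age = 20
  )
  betas <- matrix(runif(n_cpg * n_samp), n_cpg, n_samp,
                  dimnames = list(ids, paste0("s", seq_len(n_samp))))
  list(clock = clk, betas = betas)
}

# Small hand-built cohort with a known pair structure for twin-table tests.
toy_pair_cohort <- function() {
  tibble::tibble(
    individual_id = c("f1_1", "f1_2", "f2_1", "f2_2", "f3_1", "f3_2", "f4_1"),
    family_id = c("f1", "f1", "f2", "f2", "f3", "f3", "f4"),
    zygosity = c("MZ", "MZ", "MZ", "MZ", "MZ", "MZ", NA),
    twin_order = c(1L, 2L, 1L, 2L, 1L, 2L, NA),
    x = c(0.1, -0.2, 1.5, 0.7, -1.0, -0.3, 2.0),
    y = c(0.5, 0.4, -0.6, 0.2, 1.1, -0.9, 0.3)
  )
}
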