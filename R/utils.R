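# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulator calls do not perturb the
# user's random stream.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# n independent draws from a standard bivariate normal with correlation r,
# returned as a two-column matrix.
rbinorm <- function(n, r) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  cbind(z1, r * z1 + sqrt(1 - r^2) * z2)
}

stopifnot_columns <- function(data, cols, what = "data") {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("Column(s) %s not found in %s.",
              paste0("`", missing_cols, "`", collapse = ", "), what),
      class = "twinclock_schema_error"
    )
  }
  invisible(data)
}
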