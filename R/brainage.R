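#' Restrict brain-age records to the predictor's trained age range
#'
#' Brain-age models extrapolate poorly outside the age range of their
#' training set, so samples whose chronological age falls outside that range
#' (inclusive at both ends) are set aside before any correction.
#'
#' @param records A data frame with a `chron_age` column.
#' @param min_age,max_age Trained range bounds (years); defaults match a
#'   predictor trained on 18-92 year-olds.
#' @return A list with tibbles `kept` and `excluded`; the two partition the
#'   input exactly.
#' @export
filter_trained_range <- function(records, min_age = 18, max_age = 92) {
  stopifnot_columns(records, "chron_age", "records")
  if (!(min_age < max_age)) {
    abort("`min_age` must be strictly less than `max_age`.",
          class = "twinclock_parameter_error")
  }
  inside <- records$chron_age >= min_age & records$chron_age <= max_age
  list(kept = as_tibble(records[inside, , drop = FALSE]),
       excluded = as_tibble(records[!inside, , drop = FALSE]))
}

#' Brain-age gap
#'
#' The raw brain-age gap (BAG) of a sample is its predicted brain age minus
#' its chronological age; positive values mean an older-looking brain.
#'
#' @param records A data frame with `predicted_age` and `chron_age` columns.
#' @return `records` with a `bag_raw` column appended.
#' @export
compute_bag <- function(records) {
  stopifnot_columns(records, c("predicted_age", "chron_age"), "records")
  mutate(as_tibble(records), bag_raw = .data$predicted_age - .data$chron_age)
}

#' Sample-level age-bias correction of the brain-age gap
#'
#' Brain-age predictors systematically over-predict young and under-predict
#' old brains, leaving the raw gap linearly dependent on chronological age.
#' The correction regresses the raw gap on chronological age over the whole
#' sample by ordinary least squares, `bag_raw = a * chron_age + b`, and
#' subtracts the fitted trend: `bag_corrected = bag_raw - (a * chron_age +
#' b)`. Corrected gaps have zero mean and zero linear age trend by
#' construction, and the operation is idempotent.
#'
#' @param records A data frame with `bag_raw` and `chron_age` columns (see
#'   [compute_bag()]).
#' @return `records` with a `bag_corrected` column appended; the fitted bias
#'   slope and intercept are attached as attributes `bias_slope` and
#'   `bias_intercept` and also returned via [glance()].
#' @examples
#' rec <- tibble::tibble(chron_age = c(20, 40, 60, 80),
#'                       predicted_age = c(28, 42, 56, 70))
#' out <- compute_bag(rec) |> beheshti_correct()
#' attr(out, "bias_slope")      # -0.3: the injected age bias
#' @export
beheshti_correct <- function(records) {
  stopifnot_columns(records, c("bag_raw", "chron_age"), "records")
  if (nrow(records) < 3) {
    abort("Age-bias correction needs at least 3 samples.",
          class = "twinclock_degenerate_error")
  }
  if (sd(records$chron_age) == 0) {
    abort("Chronological ages are constant; bias regression is degenerate.",
          class = "twinclock_degenerate_error")
  }
  fit <- lm(bag_raw ~ chron_age, data = records)
  out <- mutate(as_tibble(records), bag_corrected = unname(resid(fit)))
  attr(out, "bias_slope") <- unname(coef(fit)[2])
  attr(out, "bias_intercept") <- unname(coef(fit)[1])
  out
}
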