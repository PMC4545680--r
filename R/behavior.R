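#' Simulate binary pain judgments from an equal-variance detection model
#'
#' Each painful trial is answered "pain" with probability
#' `pnorm(dprime / 2 - criterion)` and each nonpainful trial with probability
#' `pnorm(-dprime / 2 - criterion)`: the observer's internal response is
#' Gaussian with unit standard deviation, signal and noise means at
#' `+dprime/2` and `-dprime/2`, and the decision criterion `c` is measured
#' from the neutral point between the two distributions.
#'
#' @param schedule A `trial_schedule`.
#' @param dprime True sensitivity (unitless).
#' @param criterion True criterion c (unitless; 0 is unbiased).
#' @param seed Integer seed.
#' @param p_miss_response Probability that no button press is recorded within
#'   the response window (response `NA`); default 0.
#' @return Data.frame with columns `run`, `trial`, `trial_type`, `painful`,
#'   `response` ("pain", "no_pain", or `NA`).
#' @export
generate_behavior <- function(schedule, dprime, criterion, seed = 1,
                              p_miss_response = 0) {
  validate_schedule(schedule)
  set.seed(seed)
  p_yes <- ifelse(schedule$painful,
                  stats::pnorm(dprime / 2 - criterion),
                  stats::pnorm(-dprime / 2 - criterion))
  yes <- stats::runif(nrow(schedule)) < p_yes
  resp <- ifelse(yes, "pain", "no_pain")
  if (p_miss_response > 0) {
    resp[stats::runif(nrow(schedule)) < p_miss_response] <- NA_character_
  }
  data.frame(run = schedule$run, trial = schedule$trial,
             trial_type = schedule$trial_type, painful = schedule$painful,
             response = resp, stringsAsFactors = FALSE)
}

#' Criterion achieving a target hit rate at a given sensitivity
#'
#' Convenience inverse: returns the criterion c for which the hit rate equals
#' `hit` when sensitivity is `dprime`.
#'
#' @param dprime Sensitivity.
#' @param hit Target hit rate in (0, 1).
#' @return Criterion c.
#' @export
criterion_for_hit_rate <- function(dprime, hit) {
  stopifnot(hit > 0, hit < 1)
  dprime / 2 - stats::qnorm(hit)
}
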