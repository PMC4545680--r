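#' Tabulate hit / false-alarm / miss / correct-rejection rates
#'
#' Painful trials are "signal" and nonpainful trials "noise"; a "pain"
#' response to a painful trial is a hit and to a nonpainful trial a false
#' alarm. Trials without a recorded response are excluded from both numerator
#' and denominator; their count is reported.
#'
#' @param responses Data.frame with logical `painful` and character `response`
#'   ("pain" / "no_pain" / `NA`) columns, as returned by
#'   [generate_behavior()].
#' @return An object of class `rate_table`: list with `hit`, `false_alarm`,
#'   `miss`, `correct_rejection` (proportions), `n_signal`, `n_noise` (counts
#'   of trials with responses) and `n_missing`.
#' @export
tabulate_rates <- function(responses) {
  stopifnot(is.data.frame(responses),
            all(c("painful", "response") %in% names(responses)))
  missing <- is.na(responses$response)
  r <- responses[!missing, ]
  n_signal <- sum(r$painful)
  n_noise <- sum(!r$painful)
  if (n_signal == 0L) stop("no signal (painful) trials with responses")
  if (n_noise == 0L) stop("no noise (nonpainful) trials with responses")
  hit <- sum(r$painful & r$response == "pain") / n_signal
  fa <- sum(!r$painful & r$response == "pain") / n_noise
  structure(list(hit = hit, false_alarm = fa,
                 miss = 1 - hit, correct_rejection = 1 - fa,
                 n_signal = n_signal, n_noise = n_noise,
                 n_missing = sum(missing)),
            class = "rate_table")
}

#' Construct a rate table from proportions
#'
#' @param hit,false_alarm Proportions in \[0, 1\].
#' @param n_signal,n_noise Trial counts (needed only when extreme-rate
#'   correction is requested downstream).
#' @return A `rate_table`.
#' @export
rate_table <- function(hit, false_alarm, n_signal = NA_integer_,
                       n_noise = NA_integer_) {
  stopifnot(hit >= 0, hit <= 1, false_alarm >= 0, false_alarm <= 1)
  structure(list(hit = hit, false_alarm = false_alarm,
                 miss = 1 - hit, correct_rejection = 1 - false_alarm,
                 n_signal = n_signal, n_noise = n_noise, n_missing = 0L),
            class = "rate_table")
}

# Replace rates of exactly 0 or 1 by 1/(2N) and 1 - 1/(2N) so the normal
# quantiles stay finite. Applied only when requested: the naive formula is
# the default.
correct_extreme_rates <- function(rates) {
  fix <- function(p, n) {
    if (p %in% c(0, 1)) {
      if (is.na(n) || n <= 0) stop("extreme rate with unknown trial count")
      p <- max(1 / (2 * n), min(1 - 1 / (2 * n), p))
    }
    p
  }
  rates$hit <- fix(rates$hit, rates$n_signal)
  rates$false_alarm <- fix(rates$false_alarm, rates$n_noise)
  rates$miss <- 1 - rates$hit
  rates$correct_rejection <- 1 - rates$false_alarm
  rates
}

#' Sensitivity d' from a rate table
#'
#' `d' = (mu_s - mu_n) / sd` for the equal-variance Gaussian observer, i.e.
#' the separation of the signal and noise distributions in standard-deviation
#' units; computed as `qnorm(hit) - qnorm(false_alarm)`. Larger values denote
#' better discrimination.
#'
#' @param rates A `rate_table`.
#' @param correct_extremes Replace rates of 0 or 1 by `1/(2N)` and
#'   `1 - 1/(2N)` before the quantile transform (default `FALSE`, which
#'   reproduces the naive formula and yields infinities for extreme rates).
#' @return d' (unitless).
#' @export
compute_dprime <- function(rates, correct_extremes = FALSE) {
  stopifnot(inherits(rates, "rate_table"))
  if (correct_extremes) rates <- correct_extreme_rates(rates)
  stats::qnorm(rates$hit) - stats::qnorm(rates$false_alarm)
}

#' Decision bias beta (and criterion) from a rate table
#'
#' `beta = f_s(lambda) / f_n(lambda)`: the ratio of the signal and noise
#' density heights at the decision criterion lambda. For the equal-variance
#' Gaussian model this equals `exp((z_F^2 - z_H^2) / 2)` with
#' `z_H = qnorm(hit)` and `z_F = qnorm(false_alarm)`. Values above 1 indicate
#' a conservative criterion (bias towards "no pain").
#'
#' @inheritParams compute_dprime
#' @return List with `beta`, `criterion_c` (`-(z_H + z_F)/2`, distance of the
#'   criterion from the neutral point) and `lambda` (criterion on the
#'   noise-distribution axis, `-z_F`).
#' @export
compute_beta <- function(rates, correct_extremes = FALSE) {
  stopifnot(inherits(rates, "rate_table"))
  if (correct_extremes) rates <- correct_extreme_rates(rates)
  z_h <- stats::qnorm(rates$hit)
  z_f <- stats::qnorm(rates$false_alarm)
  list(beta = exp((z_f^2 - z_h^2) / 2),
       criterion_c = -(z_h + z_f) / 2,
       lambda = -z_f)
}

#' All signal-detection measures for one response table
#'
#' @param responses Response table (see [tabulate_rates()]).
#' @inheritParams compute_dprime
#' @return List with the rate table, `d_prime`, `beta`, `criterion_c`.
#' @export
sdt_measures <- function(responses, correct_extremes = FALSE) {
  rates <- tabulate_rates(responses)
  b <- compute_beta(rates, correct_extremes)
  list(rates = rates,
       d_prime = compute_dprime(rates, correct_extremes),
       beta = b$beta, criterion_c = b$criterion_c)
}
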