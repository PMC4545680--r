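#' Canonical skin-conductance impulse response
#'
#' Gamma-family impulse response used both to synthesise phasic
#' skin-conductance responses and to build GLM regressors. Causal (0 at
#' `t <= 0`), unimodal, with its peak normalised to 1 at `peak_time`.
#' The shape is `t^(shape-1) * exp(-t/scale)` with
#' `scale = peak_time / (shape - 1)`.
#'
#' @param t Time in seconds (vectorised); values `<= 0` return 0.
#' @param peak_time Peak latency in seconds (default 3.5).
#' @param shape Gamma shape parameter (> 1; default 3). Larger values make
#'   the response more symmetric; the default gives the slow exponential
#'   recovery characteristic of electrodermal responses.
#' @return Amplitude (unitless, peak 1).
#' @export
canonical_scrf <- function(t, peak_time = 3.5, shape = 3) {
  stopifnot(shape > 1, peak_time > 0)
  scale <- peak_time / (shape - 1)
  peak <- peak_time^(shape - 1) * exp(-peak_time / scale)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- t[pos]^(shape - 1) * exp(-t[pos] / scale) / peak
  out
}

#' Simulate a skin-conductance trace for one or more runs
#'
#' The trace is a sum of canonical impulse responses at the trial onsets plus
#' a tonic baseline, slow drift (sinusoid plus linear trend) and Gaussian
#' noise. Each trial's response amplitude is
#' `amplitudes$all + amplitudes$pain * painful + N(0, amplitudes$trial_sd)`,
#' mirroring the two-regressor analysis model ("all images" plus an extra
#' "painful images" component).
#'
#' @param schedule A `trial_schedule`.
#' @param amplitudes List with elements `all`, `pain`, `trial_sd` (muS);
#'   defaults `list(all = 0.4, pain = 0.3, trial_sd = 0)`.
#' @param noise_sd Gaussian noise standard deviation (muS).
#' @param sampling_rate Hz; default 100 (a decimated rate; the acquisition
#'   rate of 2000 Hz is supported). Rates below 1 Hz cannot resolve the
#'   impulse response and are rejected.
#' @param seed Integer seed.
#' @param baseline Tonic level in muS (default 2).
#' @param drift List with `sin_amp` (muS), `sin_period` (s), `linear` (muS/s);
#'   defaults give a small slow drift inside the 0.01 Hz filter stopband.
#' @return List of `scr_trace` objects (one per run): each a list with
#'   `samples` (muS), `sampling_rate`, `run`, `onsets` (s, relative to run
#'   start), and attribute `trial_amplitudes` (ground truth).
#' @export
generate_scr <- function(schedule,
                         amplitudes = list(all = 0.4, pain = 0.3, trial_sd = 0),
                         noise_sd = 0.02, sampling_rate = 100, seed = 1,
                         baseline = 2,
                         drift = list(sin_amp = 0.1, sin_period = 300,
                                      linear = -2e-4)) {
  validate_schedule(schedule)
  if (sampling_rate < 1) stop("sampling rate too low to resolve the SCRF")
  set.seed(seed)
  dur <- attr(schedule, "run_duration")
  n <- round(dur * sampling_rate)
  kern <- canonical_scrf(seq_len(round(40 * sampling_rate)) / sampling_rate)
  lapply(unique(schedule$run), function(r) {
    s <- schedule[schedule$run == r, ]
    amp <- amplitudes$all + amplitudes$pain * s$painful
    if (!is.null(amplitudes$trial_sd) && amplitudes$trial_sd > 0) {
      amp <- amp + stats::rnorm(nrow(s), 0, amplitudes$trial_sd)
    }
    x <- numeric(n)
    for (i in seq_len(nrow(s))) {
      i0 <- round(s$onset[i] * sampling_rate) + 1L
      idx <- i0:min(n, i0 + length(kern) - 1L)
      x[idx] <- x[idx] + amp[i] * kern[seq_along(idx)]
    }
    tt <- (seq_len(n) - 1) / sampling_rate
    x <- x + baseline + drift$sin_amp * sin(2 * pi * tt / drift$sin_period) +
      drift$linear * tt
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    structure(list(samples = x, sampling_rate = sampling_rate, run = r,
                   onsets = s$onset),
              class = "scr_trace", trial_amplitudes = amp)
  })
}
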