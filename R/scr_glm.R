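#' Build the event-related skin-conductance design matrix for one run
#'
#' Two event regressors are formed by convolving onset stick functions with
#' the canonical skin-conductance impulse response: "all images" carries a
#' unit event at every trial onset, "painful images" only at painful-trial
#' onsets. Optionally a single trial is split out into its own column, with
#' "all other images" and "all other painful images" as the remainder
#' regressors (the single-trial model).
#'
#' @param schedule A `trial_schedule` (one run is selected via `run`).
#' @param run Which run of the schedule to use.
#' @param sampling_rate Hz of the target trace.
#' @param n_samples Number of samples of the target trace; defaults to the
#'   schedule's run duration times the sampling rate.
#' @param single_trial Optional trial index (1-64) to isolate.
#' @param scrf_args List of arguments passed to [canonical_scrf()].
#' @return Matrix of class `scr_design` with named columns; attribute
#'   `sampling_rate`.
#' @export
build_scr_design <- function(schedule, run = 1, sampling_rate = 100,
                             n_samples = NULL, single_trial = NULL,
                             scrf_args = list()) {
  s <- schedule[schedule$run == run, ]
  if (nrow(s) == 0L) stop("no trials for run ", run)
  if (is.null(n_samples)) {
    n_samples <- round(attr(schedule, "run_duration") * sampling_rate)
  }
  if (max(s$onset) * sampling_rate + 1 > n_samples) {
    stop("event onset beyond the end of the trace")
  }
  kern <- canonical_scrf(seq_len(round(40 * sampling_rate)) / sampling_rate)
  if (length(scrf_args)) {
    kern <- do.call(canonical_scrf,
                    c(list(seq_len(round(40 * sampling_rate)) / sampling_rate),
                      scrf_args))
  }
  conv_onsets <- function(onsets) {
    x <- numeric(n_samples)
    for (o in onsets) {
      i0 <- round(o * sampling_rate) + 1L
      idx <- i0:min(n_samples, i0 + length(kern) - 1L)
      x[idx] <- x[idx] + kern[seq_along(idx)]
    }
    x
  }
  if (is.null(single_trial)) {
    X <- cbind(all_images = conv_onsets(s$onset),
               painful_images = conv_onsets(s$onset[s$painful]))
  } else {
    stopifnot(single_trial >= 1, single_trial <= nrow(s))
    others <- setdiff(seq_len(nrow(s)), single_trial)
    X <- cbind(
      trial = conv_onsets(s$onset[single_trial]),
      other_images = conv_onsets(s$onset[others]),
      other_painful = conv_onsets(s$onset[intersect(others,
                                                    which(s$painful))]))
  }
  structure(X, class = c("scr_design", class(X)),
            sampling_rate = sampling_rate)
}

#' First-order Butterworth band-pass filter (zero-phase)
#'
#' The 0.01-0.12 Hz band removes tonic drift and high-frequency noise while
#' passing the phasic response. Applied forward and backward
#' ([signal::filtfilt()]) so the filter is zero-phase; the same operator must
#' be applied to data and design.
#'
#' @param x Numeric vector.
#' @param sampling_rate Hz.
#' @param band Pass band in Hz (default `c(0.01, 0.12)`).
#' @return Filtered vector.
#' @export
scr_bandpass <- function(x, sampling_rate, band = c(0.01, 0.12)) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] < sampling_rate / 2)
  bf <- signal::butter(1, band / (sampling_rate / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Fit the skin-conductance GLM for one run
#'
#' Both the trace and every design column are band-pass filtered
#' (first-order Butterworth, 0.01-0.12 Hz, zero-phase), the filtered trace is
#' normalised, and ordinary least squares is solved with an intercept. The
#' returned coefficients are nondimensional once the trace is z-scored
#' (`normalize = "trace"`, the default, which controls between-subject
#' amplitude differences); `normalize = "none"` keeps muS units.
#'
#' @param trace An `scr_trace`.
#' @param design An `scr_design` on the same sampling grid.
#' @param filter Apply the band-pass filter (default `TRUE`).
#' @param normalize `"trace"` (z-score the filtered trace), or `"none"`.
#' @param band Pass band in Hz.
#' @return List of class `scr_fit`: `betas` (named), `se`, `sigma2`, `df`.
#' @export
fit_scr_glm <- function(trace, design, filter = TRUE,
                        normalize = c("trace", "none"),
                        band = c(0.01, 0.12)) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(trace, "scr_trace"))
  fs <- trace$sampling_rate
  if (!isTRUE(all.equal(fs, attr(design, "sampling_rate")))) {
    stop("trace and design sampling rates differ")
  }
  y <- trace$samples
  X <- unclass(design)
  if (nrow(X) != length(y)) stop("trace and design lengths differ")
  if (filter) {
    y <- scr_bandpass(y, fs, band)
    X <- apply(X, 2, scr_bandpass, sampling_rate = fs, band = band)
  }
  if (normalize == "trace") {
    sdy <- stats::sd(y)
    if (sdy == 0) stop("flat trace cannot be normalised")
    y <- (y - mean(y)) / sdy
  }
  Xi <- cbind(X, intercept = 1)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qr_x$pivot[(qr_x$rank + 1):ncol(Xi)]]
    stop("rank-deficient filtered design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  res <- y - Xi %*% beta
  df <- length(y) - ncol(Xi)
  sigma2 <- sum(res^2) / df
  xtxi <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(xtxi))
  names(se) <- colnames(Xi)
  structure(list(betas = beta[colnames(X)], se = se[colnames(X)],
                 sigma2 = sigma2, df = df),
            class = "scr_fit")
}

#' Single-trial skin-conductance amplitudes
#'
#' For every trial of every run, fits a GLM in which that trial has its own
#' regressor alongside "all other images", "all other painful images" and an
#' intercept, and collects the trial column's coefficient. The resulting
#' trial-wise estimates can be entered as parametric modulators in the BOLD
#' GLM.
#'
#' @param traces List of `scr_trace` (one per run), e.g. from
#'   [generate_scr()].
#' @param schedule The `trial_schedule` that produced the traces.
#' @param ... Passed to [fit_scr_glm()] (e.g. `filter`, `normalize`).
#' @return Data.frame with `run`, `trial`, `beta`, in schedule order.
#' @export
single_trial_scr_betas <- function(traces, schedule, ...) {
  runs <- unique(schedule$run)
  stopifnot(length(traces) == length(runs))
  out <- lapply(seq_along(runs), function(k) {
    r <- runs[k]
    trace <- traces[[k]]
    n_trials <- sum(schedule$run == r)
    n_samples <- length(trace$samples)
    betas <- vapply(seq_len(n_trials), function(i) {
      d <- build_scr_design(schedule, run = r,
                            sampling_rate = trace$sampling_rate,
                            n_samples = n_samples, single_trial = i)
      fit_scr_glm(trace, d, ...)$betas[["trial"]]
    }, numeric(1))
    data.frame(run = r, trial = seq_len(n_trials), beta = betas)
  })
  do.call(rbind, out)
}
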