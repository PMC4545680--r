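#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking near 5 s
#' and a delayed undershoot. Defaults follow the standard canonical basis
#' (peak delay 6, undershoot delay 16, dispersions 1, undershoot ratio 1/6),
#' normalised to a peak of 1.
#'
#' @param t Seconds (vectorised); values `< 0` return 0.
#' @param peak_delay,under_delay Gamma shape parameters of response and
#'   undershoot (with unit dispersion these are the means in seconds).
#' @param peak_disp,under_disp Dispersions (rate reciprocal), seconds.
#' @param ratio Undershoot amplitude relative to the peak (default 1/6).
#' @return Amplitude (unitless).
#' @export
canonical_hrf <- function(t, peak_delay = 6, under_delay = 16,
                          peak_disp = 1, under_disp = 1, ratio = 1 / 6) {
  h <- function(tt) {
    stats::dgamma(tt, shape = peak_delay / peak_disp, scale = peak_disp) -
      ratio * stats::dgamma(tt, shape = under_delay / under_disp,
                            scale = under_disp)
  }
  out <- numeric(length(t))
  pos <- t >= 0
  grid <- seq(0, 32, by = 0.01)
  out[pos] <- h(t[pos]) / max(h(grid))
  out
}

#' Build an event-related BOLD design matrix for one run
#'
#' A train of delta functions at the trial onsets is convolved with the
#' canonical HRF on a microtime grid and sampled at the volume acquisition
#' times. The default two-event parameterisation has an "all images" column
#' (every onset) and a "painful images" column (painful onsets only), so the
#' painful-images coefficient captures activation over and above the common
#' response; `separate_events = TRUE` instead models painful and nonpainful
#' onsets in separate columns (the mathematically equivalent
#' parameterisation). A per-trial parametric modulator (e.g. single-trial
#' skin-conductance amplitudes) is mean-centred within the run, placed as
#' scaled deltas at the onsets and convolved likewise.
#'
#' @param schedule A `trial_schedule`.
#' @param run Run to use.
#' @param tr Repetition time in seconds (default 2.5).
#' @param n_volumes Volumes per run (default 165).
#' @param modulator Optional numeric vector, one value per trial of the run.
#' @param separate_events Use painful/nonpainful columns instead of
#'   all/painful.
#' @param microtime Time bins per TR for the convolution grid (default 16).
#' @param hrf_args List of arguments passed to [canonical_hrf()].
#' @return Matrix of class `bold_design` (n_volumes x columns), attributes
#'   `tr`, `microtime`.
#' @export
build_bold_design <- function(schedule, run = 1, tr = 2.5, n_volumes = 165,
                              modulator = NULL, separate_events = FALSE,
                              microtime = 16, hrf_args = list()) {
  s <- schedule[schedule$run == run, ]
  if (nrow(s) == 0L) stop("no trials for run ", run)
  run_dur <- n_volumes * tr
  if (max(s$onset) >= run_dur) stop("schedule does not fit within the run")
  dt <- tr / microtime
  nt <- n_volumes * microtime
  kern <- do.call(canonical_hrf, c(list(seq(0, 32, by = dt)), hrf_args))
  conv_sticks <- function(onsets, weights = rep(1, length(onsets))) {
    u <- numeric(nt)
    bins <- pmin(nt, floor(onsets / dt) + 1L)
    for (i in seq_along(bins)) u[bins[i]] <- u[bins[i]] + weights[i]
    full <- stats::convolve(u, rev(kern), type = "open")[seq_len(nt)]
    full[(seq_len(n_volumes) - 1L) * microtime + 1L]
  }
  if (separate_events) {
    X <- cbind(painful_images = conv_sticks(s$onset[s$painful]),
               nonpainful_images = conv_sticks(s$onset[!s$painful]))
  } else {
    X <- cbind(all_images = conv_sticks(s$onset),
               painful_images = conv_sticks(s$onset[s$painful]))
  }
  if (!is.null(modulator)) {
    if (length(modulator) != nrow(s)) {
      stop("modulator length must equal the run's trial count (",
           nrow(s), ")")
    }
    X <- cbind(X, scr_modulator = conv_sticks(s$onset,
                                              modulator - mean(modulator)))
  }
  structure(X, class = c("bold_design", class(X)), tr = tr,
            microtime = microtime)
}

#' Fit a region-of-interest BOLD GLM
#'
#' Ordinary least squares per region with an intercept and optional nuisance
#' covariates (e.g. six motion parameters). No autocorrelation whitening is
#' applied.
#'
#' @param ts Numeric matrix, volumes x regions (a single series may be a
#'   vector).
#' @param design A `bold_design` (or plain matrix) with the same number of
#'   rows.
#' @param nuisance Optional matrix of nuisance covariates (volumes x p).
#' @return List of class `bold_fit`: `betas` (regressors x regions), `se`,
#'   `sigma2`, `df`, `design_cols`.
#' @export
fit_bold_glm <- function(ts, design, nuisance = NULL) {
  Y <- as.matrix(ts)
  X <- unclass(design)
  if (nrow(X) != nrow(Y)) stop("design and time series grids differ")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(Y)) stop("nuisance covariate grid differs")
    colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  Xi <- cbind(X, intercept = 1)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) stop("rank-deficient design")
  beta <- qr.coef(qr_x, Y)
  res <- Y - Xi %*% beta
  df <- nrow(Y) - ncol(Xi)
  sigma2 <- colSums(res^2) / df
  xtxi_d <- diag(chol2inv(qr.R(qr_x)))
  se <- sqrt(outer(xtxi_d, sigma2))
  rownames(se) <- colnames(Xi)
  structure(list(betas = beta, se = se, sigma2 = sigma2, df = df,
                 design_cols = colnames(Xi)),
            class = "bold_fit")
}

#' Apply a contrast to a fitted BOLD GLM
#'
#' @param fit A `bold_fit`.
#' @param contrast Named numeric vector over design columns (missing columns
#'   get weight 0).
#' @return List with `estimate` and `se` per region.
#' @export
apply_contrast <- function(fit, contrast) {
  w <- numeric(length(fit$design_cols))
  names(w) <- fit$design_cols
  if (is.null(names(contrast))) stop("contrast must be named")
  unknown <- setdiff(names(contrast), fit$design_cols)
  if (length(unknown)) stop("unknown design columns: ",
                            paste(unknown, collapse = ", "))
  w[names(contrast)] <- contrast
  est <- drop(t(w) %*% fit$betas)
  list(estimate = est, contrast = w)
}

#' Principal eigenvariate of a multivoxel time-series matrix
#'
#' First principal-component time course of the (column-centred) data,
#' scaled by the leading singular value over the square root of the number
#' of time points, and sign-aligned so that it correlates positively with
#' the mean series — the standard summary used to feed regional data into
#' dynamic causal models.
#'
#' @param ts Matrix, volumes x voxels.
#' @return Numeric vector of length `nrow(ts)`.
#' @export
extract_eigenvariate <- function(ts) {
  Y <- as.matrix(ts)
  if (nrow(Y) < 2L) stop("need at least 2 volumes")
  if (all(Y == 0)) stop("all-zero input")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(Yc, nu = 1, nv = 0)
  e <- sv$u[, 1] * sv$d[1] / sqrt(nrow(Y))
  m <- rowMeans(Yc)
  if (sum(e * m) < 0) e <- -e
  e
}
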