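#' Microtime input functions for one run
#'
#' Builds the two experimental inputs on the microtime grid: u1 ("all
#' images") carries every trial onset, u2 ("painful images") only painful
#' onsets. With `input_duration = 0` each event is a stick of height 1
#' lasting one microtime bin; with a positive duration each event is a unit
#' boxcar of that length.
#'
#' @param schedule A `trial_schedule`.
#' @param run Run to use.
#' @param tr Repetition time, seconds.
#' @param n_volumes Volumes in the run.
#' @param microtime Bins per TR (default 16, i.e. 156.25 ms at TR 2.5 s).
#' @param input_duration Event duration in seconds (default 2.5, the
#'   stimulus/response window; 0 gives single-bin sticks).
#' @return 2 x (n_volumes * microtime) matrix; attribute `dt`.
#' @export
dcm_inputs <- function(schedule, run = 1, tr = 2.5, n_volumes = 165,
                       microtime = 16, input_duration = 2.5) {
  s <- schedule[schedule$run == run, ]
  if (nrow(s) == 0L) stop("no trials for run ", run)
  dt <- tr / microtime
  nt <- n_volumes * microtime
  nb <- max(1L, round(input_duration / dt))
  mark <- function(onsets) {
    u <- numeric(nt)
    for (o in onsets) {
      i0 <- floor(o / dt) + 1L
      if (i0 > nt) next # event after the sampled window
      u[i0:min(nt, i0 + nb - 1L)] <- 1
    }
    u
  }
  U <- rbind(all_images = mark(s$onset),
             painful_images = mark(s$onset[s$painful]))
  attr(U, "dt") <- dt
  U
}

#' Simulate region BOLD responses from a bilinear DCM
#'
#' Integrates the neural state equation `dx/dt = (A + u2 B) x + C u` with
#' fourth-order Runge-Kutta on the microtime grid, passes each region's
#' neural state through the balloon-type hemodynamic model, and samples the
#' predicted BOLD signal (percent, zero baseline) at the volume acquisition
#' times.
#'
#' @param params A `dcm_params` (must be stable at rest).
#' @param schedule A `trial_schedule`.
#' @param run Run to simulate.
#' @param tr,n_volumes,microtime,input_duration See [dcm_inputs()].
#' @param hemo A `hemo_params`.
#' @param return_states Also return sampled neural states.
#' @return `n_volumes x 3` matrix of BOLD (attributes `tr`); if
#'   `return_states`, a list with `bold` and `neural`.
#' @export
simulate_dcm <- function(params, schedule, run = 1, tr = 2.5,
                         n_volumes = 165, microtime = 16,
                         input_duration = 2.5,
                         hemo = hemodynamic_params(),
                         return_states = FALSE) {
  if (!dcm_stable(params)) {
    ev <- eigen(dcm_jacobian(params, 0), only.values = TRUE)$values
    stop("unstable parameters; eigenvalue real parts: ",
         paste(signif(Re(ev), 3), collapse = ", "))
  }
  U <- dcm_inputs(schedule, run, tr, n_volumes, microtime, input_duration)
  sim_from_inputs(params, U, tr, n_volumes, microtime, hemo, return_states)
}

# Shared forward call; U is the microtime input matrix.
sim_from_inputs <- function(params, U, tr, n_volumes, microtime, hemo,
                            return_states = FALSE) {
  dt <- tr / microtime
  Bcube <- array(0, dim = c(3, 3, 2))
  Bcube[, , 2] <- params$B
  sample_idx <- as.integer((seq_len(n_volumes) - 1L) * microtime + 1L)
  out <- cpp_dcm_simulate(params$A, Bcube, params$C, U, dt,
                          as.numeric(unclass(hemo)), sample_idx,
                          return_states)
  colnames(out$bold) <- dcm_regions()$regions
  attr(out$bold, "tr") <- tr
  if (return_states) {
    colnames(out$neural) <- dcm_regions()$regions
    return(out)
  }
  out$bold
}

#' Generate noisy ROI BOLD time series for all runs of a schedule
#'
#' Forward-simulates the DCM for each run and adds white Gaussian noise.
#' Noise can be given as an absolute standard deviation or via a target
#' signal-to-noise ratio (`sd(signal) / noise_sd`, computed per region from
#' the noise-free simulation).
#'
#' @param schedule A `trial_schedule`.
#' @param params A `dcm_params` (ground truth).
#' @param noise_sd Noise standard deviation (recycled over regions). Ignored
#'   when `snr` is given.
#' @param snr Target signal-to-noise ratio (e.g. 2).
#' @param seed Integer seed.
#' @param nuisance_sd If positive, also returns six smooth motion-like
#'   nuisance covariates per run (they do not enter the signal).
#' @param tr,n_volumes,microtime,input_duration,hemo See [simulate_dcm()].
#' @return List of per-run lists with `bold` (n_volumes x 3), `noise_free`,
#'   `nuisance` (or `NULL`), `tr`.
#' @export
generate_bold <- function(schedule, params, noise_sd = 0.1, snr = NULL,
                          seed = 1, nuisance_sd = 0, tr = 2.5,
                          n_volumes = 165, microtime = 16,
                          input_duration = 2.5,
                          hemo = hemodynamic_params()) {
  validate_schedule(schedule)
  set.seed(seed)
  lapply(unique(schedule$run), function(r) {
    y0 <- simulate_dcm(params, schedule, run = r, tr = tr,
                       n_volumes = n_volumes, microtime = microtime,
                       input_duration = input_duration, hemo = hemo)
    sds <- if (!is.null(snr)) {
      apply(y0, 2, stats::sd) / snr
    } else {
      rep_len(noise_sd, ncol(y0))
    }
    noise <- sapply(sds, function(s) stats::rnorm(nrow(y0), 0, s))
    nuis <- NULL
    if (nuisance_sd > 0) {
      nuis <- sapply(seq_len(6), function(i) {
        stats::filter(stats::rnorm(n_volumes, 0, nuisance_sd), 0.95,
                      method = "recursive")
      })
      nuis <- apply(nuis, 2, as.numeric)
    }
    list(bold = y0 + noise, noise_free = y0, nuisance = nuis, tr = tr,
         run = r)
  })
}
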