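#' Free-parameter index for a model specification
#'
#' @param spec A `dcm_spec`.
#' @return Data.frame with columns `name`, `mat` ("A", "B", "C"), `i`, `j`.
#' @export
dcm_par_index <- function(spec) {
  rg <- spec$regions
  rows <- list()
  for (j in 1:3) for (i in 1:3) {
    if (i != j && spec$a_mask[i, j]) {
      rows[[length(rows) + 1L]] <-
        data.frame(name = paste0("A_", rg[i], "_", rg[j]), mat = "A",
                   i = i, j = j)
    }
  }
  for (i in 1:3) {
    rows[[length(rows) + 1L]] <-
      data.frame(name = paste0("A_self_", rg[i]), mat = "A", i = i, j = i)
  }
  for (j in 1:3) for (i in 1:3) {
    if (spec$b_mask[i, j]) {
      nm <- if (i == j) paste0("B_self_", rg[i]) else
        paste0("B_", rg[i], "_", rg[j])
      rows[[length(rows) + 1L]] <- data.frame(name = nm, mat = "B",
                                              i = i, j = j)
    }
  }
  for (j in 1:2) for (i in 1:3) {
    if (spec$c_mask[i, j]) {
      rows[[length(rows) + 1L]] <-
        data.frame(name = paste0("C_", rg[i]), mat = "C", i = i, j = j)
    }
  }
  do.call(rbind, rows)
}

#' Gaussian shrinkage priors over the free parameters
#'
#' Zero-mean Gaussians: variance 1/16 for extrinsic fixed connections,
#' log-scale self terms and all modulatory entries, and 1/4 for driving
#' gains.
#'
#' @param spec A `dcm_spec`.
#' @param var_a,var_self,var_b,var_c Prior variances.
#' @return List of class `dcm_priors` with `mean`, `var`, `index`.
#' @export
dcm_priors <- function(spec, var_a = 1 / 16, var_self = 1 / 16,
                       var_b = 1 / 16, var_c = 1 / 4) {
  idx <- dcm_par_index(spec)
  v <- ifelse(idx$mat == "C", var_c,
              ifelse(idx$mat == "B", var_b,
                     ifelse(idx$i == idx$j, var_self, var_a)))
  structure(list(mean = stats::setNames(numeric(nrow(idx)), idx$name),
                 var = stats::setNames(v, idx$name), index = idx),
            class = "dcm_priors")
}

#' Convert a parameter vector to `dcm_params`
#'
#' @param theta Numeric vector in the order of [dcm_par_index()].
#' @param spec A `dcm_spec`.
#' @return A `dcm_params` (stability unchecked; the integrator guards).
#' @export
dcm_theta_to_params <- function(theta, spec) {
  idx <- dcm_par_index(spec)
  stopifnot(length(theta) == nrow(idx))
  A <- matrix(0, 3, 3)
  B <- matrix(0, 3, 3)
  C <- matrix(0, 3, 2)
  for (k in seq_len(nrow(idx))) {
    m <- idx$mat[k]
    if (m == "A") A[idx$i[k], idx$j[k]] <- theta[k]
    if (m == "B") B[idx$i[k], idx$j[k]] <- theta[k]
    if (m == "C") C[idx$i[k], idx$j[k]] <- theta[k]
  }
  dcm_params(A, B, C, check_stability = FALSE)
}

#' Extract the free-parameter vector from `dcm_params`
#'
#' @param params A `dcm_params`.
#' @param spec A `dcm_spec`.
#' @return Named numeric vector.
#' @export
dcm_params_to_theta <- function(params, spec) {
  idx <- dcm_par_index(spec)
  th <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    th[k] <- switch(idx$mat[k],
                    A = params$A[idx$i[k], idx$j[k]],
                    B = params$B[idx$i[k], idx$j[k]],
                    C = params$C[idx$i[k], idx$j[k]])
  }
  stats::setNames(th, idx$name)
}

#' Invert a DCM for one run by variational Laplace
#'
#' Gauss-Newton / EM ascent on the Laplace free-energy objective
#' (accuracy minus complexity) with a Levenberg-Marquardt trust region:
#' steps are accepted only when the free energy increases, so the reported
#' iteration trace is monotone. Observation noise is one precision
#' hyperparameter per region, updated in closed form each cycle.
#' Initialisation is at the prior mean, making the fit deterministic given
#' data and priors.
#'
#' @param spec A `dcm_spec`.
#' @param data `n_volumes x 3` matrix of region time series (columns in
#'   AIC, EBA, LPFC order). Each column is mean-centred internally.
#' @param schedule The `trial_schedule` of the run.
#' @param run Run index within the schedule.
#' @param priors A `dcm_priors` (defaults from the spec).
#' @param tr,microtime,input_duration,hemo Forward-model settings; see
#'   [simulate_dcm()].
#' @param max_iter Iteration cap (default 32).
#' @param tol Free-energy convergence tolerance (default 0.05).
#' @return Object of class `dcm_fit`: `theta` (posterior means), `Sigma`
#'   (posterior covariance), `params` (posterior means as matrices),
#'   `F` (free energy), `lambda` (noise precisions), `F_trace`, `converged`,
#'   `iterations`, `spec`, `prediction`.
#' @export
invert_dcm <- function(spec, data, schedule, run = 1,
                       priors = dcm_priors(spec), tr = 2.5, microtime = 16,
                       input_duration = 2.5, hemo = hemodynamic_params(),
                       max_iter = 32, tol = 0.05) {
  Y <- as.matrix(data)
  stopifnot(ncol(Y) == 3)
  if (any(!is.finite(Y))) stop("non-finite data")
  Y <- sweep(Y, 2, colMeans(Y))
  n_volumes <- nrow(Y)
  U <- dcm_inputs(schedule, run, tr, n_volumes, microtime, input_duration)
  idx <- priors$index
  np <- nrow(idx)
  nobs <- n_volumes

  # fast predictor: avoids per-call S3 construction
  a_sel <- as.matrix(idx[idx$mat == "A", c("i", "j")])
  b_sel <- as.matrix(idx[idx$mat == "B", c("i", "j")])
  c_sel <- as.matrix(idx[idx$mat == "C", c("i", "j")])
  a_pos <- idx$mat == "A"
  b_pos <- idx$mat == "B"
  c_pos <- idx$mat == "C"
  hemo_vec <- as.numeric(unclass(hemo))
  dt <- tr / microtime
  sample_idx <- as.integer((seq_len(n_volumes) - 1L) * microtime + 1L)
  pred <- function(theta) {
    A <- matrix(0, 3, 3); A[a_sel] <- theta[a_pos]
    Bc <- array(0, dim = c(3, 3, 2))
    Bm <- matrix(0, 3, 3); Bm[b_sel] <- theta[b_pos]
    Bc[, , 2] <- Bm
    Cm <- matrix(0, 3, 2); Cm[c_sel] <- theta[c_pos]
    g <- cpp_dcm_simulate(A, Bc, Cm, U, dt, hemo_vec, sample_idx, FALSE)$bold
    g - rep(colMeans(g), each = n_volumes)
  }
  Pi0 <- diag(1 / priors$var, np)
  mu0 <- priors$mean

  free_energy <- function(theta, lambda, rss, H0) {
    acc <- sum(nobs / 2 * log(lambda / (2 * pi)) - lambda * rss / 2)
    d <- theta - mu0
    cmplx <- 0.5 * sum(d^2 / priors$var)
    ld <- determinant(H0, logarithm = TRUE)$modulus # H0 = posterior precision
    acc - cmplx - 0.5 * as.numeric(ld) + 0.5 * sum(log(1 / priors$var))
  }

  theta <- mu0
  g <- pred(theta)
  e <- Y - g
  rss <- colSums(e^2)
  lambda <- nobs / pmax(rss, 1e-9)
  # Jacobian by forward differences on the C++ integrator
  jac <- function(theta, g) {
    J <- array(0, dim = c(nobs, 3, np))
    h <- 1e-4
    for (k in seq_len(np)) {
      tk <- theta
      tk[k] <- tk[k] + h
      J[, , k] <- (pred(tk) - g) / h
    }
    J
  }

  posterior_precision <- function(J, lambda) {
    H <- Pi0
    for (r in 1:3) {
      Jr <- J[, r, , drop = TRUE]
      if (np == 1L) Jr <- matrix(Jr, ncol = 1L)
      H <- H + lambda[r] * crossprod(Jr)
    }
    H
  }

  J <- jac(theta, g)
  H0 <- posterior_precision(J, lambda)
  F_cur <- free_energy(theta, lambda, rss, H0)
  F_trace <- F_cur
  ridge <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    grad <- -Pi0 %*% (theta - mu0)
    for (r in 1:3) {
      Jr <- J[, r, , drop = TRUE]
      if (np == 1L) Jr <- matrix(Jr, ncol = 1L)
      grad <- grad + lambda[r] * crossprod(Jr, e[, r])
    }
    accepted <- FALSE
    for (try in 1:8) {
      Hreg <- H0 + ridge * diag(diag(H0), np)
      step <- drop(solve(Hreg, grad))
      th_new <- theta + step
      g_new <- try(pred(th_new), silent = TRUE)
      if (!inherits(g_new, "try-error")) {
        e_new <- Y - g_new
        rss_new <- colSums(e_new^2)
        lam_new <- nobs / pmax(rss_new, 1e-9)
        J_new <- jac(th_new, g_new)
        H0_new <- posterior_precision(J_new, lam_new)
        F_new <- free_energy(th_new, lam_new, rss_new, H0_new)
        if (is.finite(F_new) && F_new > F_cur) {
          theta <- th_new; g <- g_new; e <- e_new; rss <- rss_new
          lambda <- lam_new; J <- J_new; H0 <- H0_new
          dF <- F_new - F_cur
          F_cur <- F_new
          F_trace <- c(F_trace, F_cur)
          ridge <- max(ridge / 2, 1e-6)
          accepted <- TRUE
          if (dF < tol) converged <- TRUE
          break
        }
      }
      ridge <- ridge * 8
    }
    if (!accepted) {
      converged <- TRUE  # no ascent direction improves F: local optimum
      break
    }
    if (converged) break
  }
  Sigma <- solve(H0)
  dimnames(Sigma) <- list(idx$name, idx$name)
  fit <- structure(list(theta = stats::setNames(theta, idx$name),
                        Sigma = Sigma,
                        params = dcm_theta_to_params(theta, spec),
                        F = F_cur, lambda = lambda, F_trace = F_trace,
                        converged = converged, iterations = iter,
                        spec = spec, prediction = g),
                   class = "dcm_fit")
  if (!converged && iter >= max_iter) {
    fit$converged <- FALSE
    warning("inversion hit the iteration cap (", max_iter,
            ") before the free-energy tolerance")
  }
  fit
}

#' Fit one model to all runs of a subject
#'
#' One inversion per run; the subject-level log evidence is the sum of the
#' per-run free energies, and parameters are combined across runs by
#' Bayesian model averaging ([bma_sessions()]).
#'
#' @param spec A `dcm_spec`.
#' @param runs List of per-run data (each `n_volumes x 3`), e.g. the `bold`
#'   elements of [generate_bold()] output.
#' @param schedule The `trial_schedule`.
#' @param ... Passed to [invert_dcm()].
#' @return List with `fits` (per run), `F` (summed), `bma` (averaged
#'   posterior).
#' @export
fit_dcm_subject <- function(spec, runs, schedule, ...) {
  run_ids <- unique(schedule$run)
  stopifnot(length(runs) == length(run_ids))
  fits <- lapply(seq_along(runs), function(k) {
    invert_dcm(spec, runs[[k]], schedule, run = run_ids[k], ...)
  })
  list(fits = fits, F = sum(vapply(fits, `[[`, numeric(1), "F")),
       bma = bma_sessions(fits))
}

#' Summarise the modulatory effects of a fitted model
#'
#' Reports each modulated connection. Self-connections are on the log
#' scale: the effective self-coupling during painful images is
#' `-0.5 * exp(a_self + b_self)`, so negative `b_self` shrinks
#' self-inhibition ("disinhibition"). Extrinsic entries are in Hz.
#'
#' @param fit A `dcm_fit`, or a `dcm_params` (then `spec` is required, e.g.
#'   for session-averaged parameters).
#' @param spec A `dcm_spec`; defaults to the fit's own specification.
#' @return Data.frame with `connection`, `type`, `estimate`, `baseline`,
#'   `during_pain`, `interpretation`.
#' @export
summarize_modulation <- function(fit, spec = NULL) {
  if (inherits(fit, "dcm_params")) {
    if (is.null(spec)) stop("spec required when passing parameters")
    p <- fit
  } else {
    if (is.null(spec)) spec <- fit$spec
    p <- fit$params
  }
  rg <- spec$regions
  rows <- list()
  for (j in 1:3) for (i in 1:3) {
    if (!spec$b_mask[i, j]) next
    if (i == j) {
      base <- -0.5 * exp(p$A[i, i])
      pain <- -0.5 * exp(p$A[i, i] + p$B[i, i])
      interp <- if (p$B[i, i] < 0) "disinhibition" else
        if (p$B[i, i] > 0) "increased self-inhibition" else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        connection = paste0(rg[i], " self"), type = "self",
        estimate = p$B[i, i], baseline = base, during_pain = pain,
        interpretation = interp)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        connection = paste0(rg[j], " -> ", rg[i]), type = "extrinsic",
        estimate = p$B[i, j], baseline = p$A[i, j],
        during_pain = p$A[i, j] + p$B[i, j],
        interpretation = if (p$B[i, j] == 0) "none" else
          if (p$B[i, j] > 0) "strengthened" else "weakened")
    }
  }
  if (!length(rows)) {
    return(data.frame(connection = character(), type = character(),
                      estimate = numeric(), baseline = numeric(),
                      during_pain = numeric(),
                      interpretation = character()))
  }
  do.call(rbind, rows)
}
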