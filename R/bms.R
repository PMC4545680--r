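#' Random-effects Bayesian model selection
#'
#' Hierarchical Dirichlet-multinomial model of model frequencies in the
#' population: subjects' log evidences (free energies) update a Dirichlet
#' posterior over model frequencies via the standard variational scheme, and
#' exceedance probabilities (the posterior probability that a model is the
#' most frequent) are estimated by seeded Dirichlet sampling.
#'
#' @param evidence Numeric matrix, subjects x models, of log evidence.
#'   Adding a per-subject constant leaves all outputs unchanged.
#' @param seed Integer seed for the exceedance sampler.
#' @param n_samples Dirichlet draws (default 1e6).
#' @param alpha0 Prior Dirichlet counts, scalar or per model (default 1).
#' @param tol Relative convergence tolerance of the variational updates.
#' @return Object of class `bms_result`: `alpha` (posterior counts),
#'   `expected_p`, `exceedance_p`, `alpha0`, `n_samples`.
#' @export
rfx_bms <- function(evidence, seed = 1, n_samples = 1e6, alpha0 = 1,
                    tol = 1e-8) {
  F <- as.matrix(evidence)
  if (any(!is.finite(F))) stop("non-finite log evidence")
  ns <- nrow(F)
  K <- ncol(F)
  stopifnot(ns >= 2, K >= 2)
  alpha0 <- rep_len(alpha0, K)
  Fs <- F - apply(F, 1, max)  # shift-invariant
  alpha <- alpha0 + ns / K
  repeat {
    w <- sweep(Fs, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- exp(w - apply(w, 1, max))
    g <- w / rowSums(w)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) / max(abs(alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  names(alpha) <- colnames(F)
  xp <- dirichlet_exceedance(alpha, n_samples, seed)
  structure(list(alpha = alpha, expected_p = alpha / sum(alpha),
                 exceedance_p = xp, alpha0 = alpha0,
                 n_samples = n_samples),
            class = "bms_result")
}

# Monte Carlo exceedance probabilities of a Dirichlet distribution.
dirichlet_exceedance <- function(alpha, n_samples, seed,
                                 groups = NULL) {
  set.seed(seed)
  K <- length(alpha)
  chunk <- 2e5
  done <- 0
  ngroups <- if (is.null(groups)) K else max(groups)
  wins <- numeric(ngroups)
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    G <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    if (!is.null(groups)) {
      Gg <- matrix(0, m, ngroups)
      for (k in seq_len(K)) Gg[, groups[k]] <- Gg[, groups[k]] + G[, k]
      G <- Gg
    }
    mx <- max.col(G, ties.method = "first")
    wins <- wins + tabulate(mx, nbins = ngroups)
    done <- done + m
  }
  p <- wins / n_samples
  names(p) <- if (is.null(groups)) names(alpha) else NULL
  p
}

#' Family-level random-effects Bayesian model selection
#'
#' Partitions the model space into families and reports family expected and
#' exceedance probabilities. Unequal family sizes are corrected through the
#' prior: each model's prior Dirichlet count is `1 / family size`, giving
#' every family the same prior mass, so uninformative evidence yields equal
#' family probabilities regardless of size. Family quantities are computed
#' by Gibbs sampling of the exact hierarchical model (sampling subject model
#' assignments and population frequencies in turn) and aggregating the
#' frequency samples over families; model-level fields come from the
#' variational scheme of [rfx_bms()] under its uniform prior.
#'
#' @param evidence Subjects x models log-evidence matrix.
#' @param partition Named list of integer vectors of model indices, e.g.
#'   [dcm_families()]; must cover all models disjointly.
#' @param seed,tol See [rfx_bms()].
#' @param n_samples Dirichlet draws for the model-level exceedance
#'   (default 1e6).
#' @param gibbs_samples Retained Gibbs sweeps for the family posterior
#'   (default 2e4, after `burn_in`).
#' @param burn_in Discarded initial sweeps (default 1000).
#' @return `bms_result` with additional `family_expected_p`,
#'   `family_exceedance_p`, `partition`.
#' @export
family_bms <- function(evidence, partition = dcm_families(), seed = 1,
                       n_samples = 1e6, gibbs_samples = 2e4,
                       burn_in = 1000, tol = 1e-8) {
  F <- as.matrix(evidence)
  K <- ncol(F)
  sizes <- lengths(partition)
  if (any(sizes == 0L)) stop("empty family")
  all_m <- sort(unname(unlist(partition)))
  if (!identical(as.integer(all_m), seq_len(K))) {
    stop("partition must cover all models disjointly")
  }
  res <- rfx_bms(evidence, seed = seed, n_samples = n_samples, tol = tol)
  alpha0 <- numeric(K)
  groups <- integer(K)
  for (f in seq_along(partition)) {
    alpha0[partition[[f]]] <- 1 / sizes[f]
    groups[partition[[f]]] <- f
  }
  ns <- nrow(F)
  L <- exp(F - apply(F, 1, max)) # subject likelihoods up to a constant
  set.seed(seed + 1L)
  r <- alpha0 / sum(alpha0)
  nf <- length(partition)
  fam_sum <- numeric(nf)
  fam_win <- numeric(nf)
  total <- burn_in + gibbs_samples
  for (t in seq_len(total)) {
    # subject-wise model assignments given frequencies
    P <- L * rep(r, each = ns)
    P <- P / rowSums(P)
    u <- stats::runif(ns)
    cum <- t(apply(P, 1, cumsum))
    m <- max.col(cum >= u, ties.method = "first")
    counts <- tabulate(m, nbins = K)
    # frequencies given assignments
    g <- stats::rgamma(K, shape = alpha0 + counts)
    r <- g / sum(g)
    if (t > burn_in) {
      rf <- vapply(partition, function(mm) sum(r[mm]), numeric(1))
      fam_sum <- fam_sum + rf
      fam_win[which.max(rf)] <- fam_win[which.max(rf)] + 1
    }
  }
  res$family_expected_p <- stats::setNames(fam_sum / gibbs_samples,
                                           names(partition))
  res$family_exceedance_p <- stats::setNames(fam_win / gibbs_samples,
                                             names(partition))
  res$partition <- partition
  res
}

#' Bayesian model averaging across sessions
#'
#' Combines per-session posteriors of the same model within subject, in a
#' parameter-specific fashion. The default (`"equal"`) averages the session
#' posteriors evenly and reports the moment-matched mixture covariance.
#' `"precision"` is the Bayesian fixed-effects combination (posterior
#' precisions add, means are precision-weighted); in practice its weights
#' inherit any miscalibration of the per-session Laplace covariances.
#' `"evidence"` weights whole sessions by the softmax of their free
#' energies, which saturates onto the single highest-evidence session when
#' free energies differ by more than a few units.
#'
#' @param fits List of `dcm_fit` objects sharing one specification.
#' @param weighting `"equal"` (default), `"precision"` or `"evidence"`.
#' @return List with `theta` (combined posterior means), `Sigma` (combined
#'   covariance), `weights` (session weights; for `"precision"` the mean
#'   diagonal weight per session), `params` (means as matrices).
#' @export
bma_sessions <- function(fits,
                         weighting = c("equal", "precision", "evidence")) {
  weighting <- match.arg(weighting)
  stopifnot(length(fits) >= 1)
  specs <- vapply(fits, function(f) f$spec$name, "")
  if (length(unique(specs)) != 1L) {
    stop("all fits must share one model specification")
  }
  if (weighting == "precision") {
    Ps <- lapply(fits, function(f) solve(f$Sigma))
    Ptot <- Reduce(`+`, Ps)
    Sg <- solve(Ptot)
    th <- drop(Sg %*% Reduce(`+`, Map(function(P, f) P %*% f$theta,
                                      Ps, fits)))
    names(th) <- names(fits[[1]]$theta)
    w <- vapply(Ps, function(P) mean(diag(P) / diag(Ptot)), numeric(1))
  } else {
    Fv <- vapply(fits, `[[`, numeric(1), "F")
    w <- if (weighting == "evidence") {
      e <- exp(Fv - max(Fv))
      e / sum(e)
    } else {
      rep(1 / length(fits), length(fits))
    }
    th <- Reduce(`+`, Map(function(f, wi) wi * f$theta, fits, w))
    Sg <- Reduce(`+`, Map(function(f, wi) {
      wi * (f$Sigma + tcrossprod(f$theta))
    }, fits, w)) - tcrossprod(th)
  }
  list(theta = th, Sigma = Sg, weights = w,
       params = dcm_theta_to_params(th, fits[[1]]$spec))
}
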