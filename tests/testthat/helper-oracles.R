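# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: they use root finding, brute-force
# convolution and a general-purpose ODE solver.

# Signal-detection oracle: given hit and false-alarm rates, locate the
# criterion lambda on the noise axis by root finding, then recover the
# signal-distribution mean, sensitivity and the density-ratio bias.
sdt_oracle <- function(hit, fa) {
  lambda <- stats::uniroot(function(l) 1 - stats::pnorm(l) - fa,
                           c(-10, 10), tol = 1e-12)$root
  mu_s <- stats::uniroot(function(m) 1 - stats::pnorm(lambda, mean = m) - hit,
                         c(-20, 20), tol = 1e-12)$root
  list(d_prime = mu_s,
       beta = stats::dnorm(lambda, mean = mu_s) / stats::dnorm(lambda),
       criterion_c = lambda - mu_s / 2)
}

# Discrete convolution oracle: unit events at onset samples convolved with a
# kernel, via stats::convolve.
convolve_oracle <- function(onsets, kernel, n, sampling_rate) {
  u <- numeric(n)
  idx <- round(onsets * sampling_rate) + 1
  for (i in idx) u[i] <- u[i] + 1
  stats::convolve(u, rev(kernel), type = "open")[seq_len(n)]
}

# Fine-step ODE oracle for the bilinear neural + balloon observation model,
# integrated with deSolve's fixed-step RK4 on a grid `refine` times finer
# than the microtime bins. Returns BOLD sampled at the volume times.
dcm_ode_oracle <- function(params, U, tr, n_volumes, microtime,
                           hemo = hemodynamic_params(), refine = 8) {
  dt <- tr / microtime
  hp <- as.numeric(unclass(hemo))
  n <- 3
  deriv <- function(t, st, parms) {
    bin <- min(ncol(U), floor(t / dt + 1e-9) + 1)
    u <- U[, bin]
    x <- st[1:n]; s <- st[n + 1:n]; f <- st[2 * n + 1:n]
    v <- st[3 * n + 1:n]; q <- st[4 * n + 1:n]
    J <- params$A + u[2] * params$B
    diag(J) <- -0.5 * exp(diag(params$A) + u[2] * diag(params$B))
    dx <- J %*% x + params$C %*% u
    ds <- x - hp[1] * s - hp[2] * (f - 1)
    df <- s
    fv <- v^(1 / hp[4])
    dv <- (f - fv) / hp[3]
    E <- 1 - (1 - hp[5])^(1 / f)
    dq <- (f * E / hp[5] - fv * q / v) / hp[3]
    list(c(dx, ds, df, dv, dq))
  }
  st0 <- c(rep(0, n), rep(0, n), rep(1, n), rep(1, n), rep(1, n))
  times <- seq(0, (n_volumes * microtime - 1) * dt, by = dt / refine)
  sol <- deSolve::rk4(st0, times, deriv, parms = NULL)
  vol_t <- (seq_len(n_volumes) - 1) * tr
  rows <- match(round(vol_t / (dt / refine)), round(sol[, 1] / (dt / refine)))
  v <- sol[rows, 1 + 3 * n + 1:n]
  q <- sol[rows, 1 + 4 * n + 1:n]
  k1 <- 7 * hp[5]; k2 <- 2; k3 <- 2 * hp[5] - 0.2
  100 * hp[6] * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

# Exhaustive flood-fill labelling oracle (6-connectivity) in plain R.
flood_fill_sizes <- function(vol) {
  d <- dim(vol)
  seen <- array(FALSE, d)
  sizes <- integer(0)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!vol[x, y, z] || seen[x, y, z]) next
    stack <- matrix(c(x, y, z), 1)
    seen[x, y, z] <- TRUE
    sz <- 0L
    while (nrow(stack) > 0) {
      v <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      sz <- sz + 1L
      for (k in 1:6) {
        w <- v + nb[k, ]
        if (any(w < 1) || any(w > d)) next
        if (vol[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack <- rbind(stack, w)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

# Small standard schedule reused across tests.
test_schedule <- function(n_runs = 1, seed = 11) {
  generate_schedule(n_runs = n_runs, seed = seed)
}
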