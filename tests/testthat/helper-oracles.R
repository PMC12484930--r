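# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Inhomogeneous Poisson by thinning against the max rate (independent of
# the renewal-warp implementation in the package).
thinning_poisson <- function(path, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t0 <- min(path$time); t1 <- max(path$time)
  trials <- lapply(seq_len(path$n_trials), function(k) {
    lmax <- max(path$rates[, k])
    if (lmax <= 0) return(numeric(0))
    n <- rpois(1, lmax * (t1 - t0))
    cand <- sort(runif(n, t0, t1))
    lam <- approx(path$time, path$rates[, k], xout = cand)$y
    keep <- runif(n) < lam / lmax
    cand[keep]
  })
  spike_train_set(trials, t0, t1)
}

# Drift-diffusion with absorbing bounds, vectorized and exact for the
# absorbing semantics: the unbounded path equals the bounded one up to the
# first bound crossing, after which the path is frozen at the bound.
ddm_oracle <- function(nu, D, lower, upper, lambda0, duration, dt, n_trials) {
  n_steps <- round(duration / dt)
  vapply(seq_len(n_trials), function(k) {
    incr <- nu * 1e3 * dt + sqrt(2 * D * 1e3 * dt) * rnorm(n_steps)
    path <- lambda0 + cumsum(incr)
    hit <- which(path <= lower | path >= upper)
    if (length(hit)) {
      h <- hit[1]
      path[h:n_steps] <- if (path[h] <= lower) lower else upper
    }
    c(lambda0, path)
  }, numeric(n_steps + 1))
}

# Spike-count set with known Poisson counts: counts drawn i.i.d. Poisson,
# spike times uniform in the window (order statistics of a homogeneous
# Poisson process given the count).
poisson_count_trials <- function(rate, duration, n_trials, seed = 1) {
  set.seed(seed)
  trials <- lapply(seq_len(n_trials), function(k) {
    sort(runif(rpois(1, rate * duration), 0, duration))
  })
  spike_train_set(trials, 0, duration)
}

expect_within <- function(value, target, tol, label = NULL) {
  expect_true(abs(value - target) <= tol,
              info = sprintf("%s: value %.6g, target %.6g, tol %.3g",
                             label %||% "check", value, target, tol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
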