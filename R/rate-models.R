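#' Per-trial instantaneous firing-rate paths
#'
#' A `rate_path` holds the instantaneous firing rate lambda(t) for a set of
#' trials on a shared uniform time grid. It is the first stage of the doubly
#' stochastic renewal (DSR) generative model: spikes are produced by a unit-
#' rate renewal process in operational time and warped back through the
#' cumulative integral of these paths.
#'
#' @param time Strictly increasing numeric vector of grid times in seconds
#'   with a constant step.
#' @param rates Numeric matrix of non-negative rates in Hz, one column per
#'   trial, `length(time)` rows.
#' @return An object of class `rate_path` with elements `time`, `rates`
#'   (matrix, trials in columns), `dt` (grid step, s) and `n_trials`.
#' @export
rate_path <- function(time, rates) {
  rates <- as.matrix(rates)
  stop_if_not(length(time) >= 2, "time grid needs at least 2 points")
  stop_if_not(nrow(rates) == length(time),
              "rates must have one row per grid time")
  steps <- diff(time)
  stop_if_not(all(steps > 0), "time grid must be strictly increasing")
  dt <- steps[1]
  stop_if_not(all(abs(steps - dt) <= 1e-12 * max(dt, 1)),
              "time grid step must be constant")
  stop_if_not(all(is.finite(rates)) && all(rates >= 0),
              "rates must be finite and non-negative")
  structure(list(time = time, rates = rates, dt = dt,
                 n_trials = ncol(rates)),
            class = "rate_path")
}

#' @export
print.rate_path <- function(x, ...) {
  cat(sprintf("<rate_path> %d trials, %.3g s at dt = %.3g s, mean rate %.3g Hz\n",
              x$n_trials, max(x$time) - min(x$time), x$dt, mean(x$rates)))
  invisible(x)
}

rate_grid <- function(duration, dt) {
  stop_if_not(duration > 0, "duration must be positive")
  stop_if_not(dt > 0 && dt <= duration, "dt must be in (0, duration]")
  seq(0, duration, by = dt)
}

#' Constant firing rate, identical within and across trials
#'
#' @param rate Firing rate in Hz (>= 0).
#' @param duration Trial duration in seconds.
#' @param dt Grid step in seconds (default 1 ms).
#' @param n_trials Number of trials.
#' @return A [rate_path].
#' @export
sample_constant_rate <- function(rate, duration, dt = 1e-3, n_trials = 1) {
  stop_if_not(is.numeric(rate) && length(rate) == 1 && rate >= 0,
              "rate must be a single non-negative number")
  tg <- rate_grid(duration, dt)
  rate_path(tg, matrix(rate, nrow = length(tg), ncol = n_trials))
}

#' Trial-constant rates drawn uniformly across trials
#'
#' Each trial's rate is flat in time; levels are i.i.d. uniform on
#' `[center - width/2, center + width/2]` across trials. This is the
#' across-trial rate-fluctuation model used in the estimator benchmark,
#' where the width controls trial-to-trial firing-rate variability
#' (benchmark settings: center 30 Hz, width 10-30 Hz).
#'
#' @param center Mean rate mu in Hz.
#' @param width Full width w of the uniform distribution in Hz; requires
#'   `center - width/2 >= 0` so rates cannot be negative.
#' @param duration,dt,n_trials As in [sample_constant_rate].
#' @param seed Optional integer seed; per-trial levels are reproducible and
#'   stable when `n_trials` is extended.
#' @return A [rate_path].
#' @export
sample_uniform_trial_rates <- function(center, width, duration, dt = 1e-3,
                                       n_trials = 1, seed = NULL) {
  stop_if_not(width >= 0, "width must be non-negative")
  stop_if_not(center - width / 2 >= 0,
              "center - width/2 must be >= 0 (rates cannot be negative)")
  tg <- rate_grid(duration, dt)
  seeds <- derive_seeds(seed, n_trials)
  levels <- vapply(seq_len(n_trials), function(k) {
    set.seed(seeds[k])
    runif(1, center - width / 2, center + width / 2)
  }, numeric(1))
  rate_path(tg, matrix(rep(levels, each = length(tg)),
                       nrow = length(tg), ncol = n_trials))
}

#' Drift-diffusion firing rate with sticky boundaries
#'
#' Euler-Maruyama integration of
#' `d lambda/dt = nu + sqrt(2 D) xi(t)` between the bounds, with
#' `d lambda/dt = 0` once a path sits at either bound: a step that would
#' cross a bound is clamped to it and (by default) the path is frozen there
#' for the rest of the trial, reading the boundary condition literally as
#' absorbing. Set `reentry = TRUE` to allow paths to diffuse off a bound
#' again (reflecting-style clipping at every step).
#'
#' Drift and diffusion are given in the per-millisecond units used
#' throughout (`nu` in Hz/ms, `D` in Hz^2/ms) and converted internally to
#' per-second units once: `nu_s = 1000 nu`, `D_s = 1000 D`.
#'
#' @param nu Drift in Hz/ms.
#' @param D Diffusion coefficient in Hz^2/ms (>= 0).
#' @param lower,upper Lower and upper bounds b_l < b_u in Hz.
#' @param lambda0 Initial rate in Hz, within `[lower, upper]`.
#' @param duration,dt,n_trials,seed As in [sample_uniform_trial_rates].
#'   The default dt = 1 ms resolves the bound dynamics for the parameter
#'   ranges used here (bound separations of tens of Hz).
#' @param reentry Logical; allow paths to leave a bound after contact
#'   (default `FALSE`, absorbing).
#' @return A [rate_path].
#' @export
sample_drift_diffusion <- function(nu = 0, D = 0, lower = 1, upper = 20,
                                   lambda0 = 10, duration = 2, dt = 1e-3,
                                   n_trials = 1, seed = NULL,
                                   reentry = FALSE) {
  stop_if_not(D >= 0, "diffusion coefficient D must be >= 0")
  stop_if_not(lower < upper, "lower bound must be below upper bound")
  stop_if_not(lambda0 >= lower && lambda0 <= upper,
              "lambda0 must lie in [lower, upper]")
  tg <- rate_grid(duration, dt)
  n_steps <- length(tg) - 1
  nu_s <- nu * 1e3
  D_s <- D * 1e3
  seeds <- derive_seeds(seed, n_trials)
  rates <- matrix(NA_real_, nrow = length(tg), ncol = n_trials)
  for (k in seq_len(n_trials)) {
    set.seed(seeds[k])
    incr <- nu_s * dt + sqrt(2 * D_s * dt) * rnorm(n_steps)
    path <- numeric(n_steps + 1)
    path[1] <- lambda0
    frozen <- !reentry && (lambda0 <= lower || lambda0 >= upper)
    for (i in seq_len(n_steps)) {
      if (frozen) {
        path[i + 1] <- path[i]
      } else {
        x <- path[i] + incr[i]
        if (x <= lower) {
          x <- lower
          if (!reentry) frozen <- TRUE
        } else if (x >= upper) {
          x <- upper
          if (!reentry) frozen <- TRUE
        }
        path[i + 1] <- x
      }
    }
    rates[, k] <- path
  }
  rate_path(tg, rates)
}
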