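#' Trial-structured spike trains
#'
#' @param trials List of numeric vectors, one per trial, each a strictly
#'   increasing sequence of spike times in seconds within
#'   `[t_start, t_end]`.
#' @param t_start,t_end Analysis window in seconds.
#' @param metadata Optional named list recording generator provenance.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(trials, t_start, t_end, metadata = list()) {
  stop_if_not(is.list(trials), "trials must be a list of numeric vectors")
  stop_if_not(t_end > t_start, "t_end must exceed t_start")
  trials <- lapply(trials, function(s) {
    s <- as.numeric(s)
    stop_if_not(all(diff(s) > 0), "spike times must be strictly increasing")
    stop_if_not(all(s >= t_start & s <= t_end),
                "spike times must lie in [t_start, t_end]")
    s
  })
  structure(list(trials = trials, t_start = t_start, t_end = t_end,
                 metadata = metadata),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- lengths(x$trials)
  cat(sprintf("<spike_train_set> %d trials on [%.3g, %.3g] s, %d spikes (mean rate %.3g Hz)\n",
              length(x$trials), x$t_start, x$t_end, sum(n),
              sum(n) / (length(x$trials) * (x$t_end - x$t_start))))
  invisible(x)
}

#' @export
length.spike_train_set <- function(x) length(x$trials)

#' Cumulative firing rate (operational-time map)
#'
#' Computes the per-trial operational-time map
#' `Lambda(t) = integral_0^t lambda(s) ds` by trapezoidal quadrature on the
#' rate grid. `Lambda` is the bridge between real and operational time:
#' spiking is unit-rate stationary renewal in `t' = Lambda(t)`.
#'
#' @param path A [rate_path].
#' @return An object of class `operational_map`: list with `time` (grid, s)
#'   and `Lambda` (matrix, one column per trial; `Lambda[1, ] = 0`).
#' @export
cumulative_rate <- function(path) {
  stop_if_not(inherits(path, "rate_path"), "path must be a rate_path")
  r <- path$rates
  n <- nrow(r)
  # trapezoid: dt * cumsum of midpoints
  mids <- (r[-1, , drop = FALSE] + r[-n, , drop = FALSE]) / 2
  Lambda <- rbind(0, apply(mids * path$dt, 2, cumsum))
  structure(list(time = path$time, Lambda = Lambda),
            class = "operational_map")
}

#' Sample operational-time events from the ISI model
#'
#' Draws i.i.d. ISIs from g() and accumulates them into event times on
#' `[0, mass]` (operational seconds). The sum is started at `-burn_in` so
#' that, after discarding pre-zero events, the process at `t' = 0` is
#' approximately an equilibrium renewal process rather than one with an
#' event at the origin. The default burn-in of 10 mean ISIs removes the
#' ordinary-renewal transient that would otherwise bias early-bin count
#' variance.
#'
#' @param model An [isi_model].
#' @param mass Total operational mass (> 0); since the operational-time rate
#'   is 1 Hz, about `mass` events are returned.
#' @param burn_in Burn-in in operational seconds before 0 (default 10).
#' @return Sorted event times in `(0, mass]`.
#' @export
sample_operational_isis <- function(model, mass, burn_in = 10) {
  stop_if_not(inherits(model, "isi_model"), "model must be an isi_model")
  stop_if_not(mass > 0, "mass must be positive")
  total <- burn_in + mass
  # expected count = total; draw with slack, extend if unlucky
  n_guess <- max(16L, ceiling(total + 6 * sqrt(max(total * model$phi, 1))))
  events <- cumsum(draw_isis(model, n_guess)) - burn_in
  while (length(events) && events[length(events)] < mass) {
    extra <- cumsum(draw_isis(model, n_guess)) + events[length(events)]
    events <- c(events, extra)
  }
  events[events > 0 & events <= mass]
}

#' Warp operational-time events to real time
#'
#' Inverts the cumulative rate by monotone linear interpolation of Lambda on
#' its grid: `t = Lambda^{-1}(t')`. Events beyond `Lambda(t_end)` are
#' dropped (their count is returned in the `"dropped"` attribute).
#'
#' @param op_events Sorted operational-time events (>= 0).
#' @param op_map An `operational_map` from [cumulative_rate].
#' @param trial Trial (column) index into the map.
#' @return Strictly increasing spike times in seconds.
#' @export
warp_to_real_time <- function(op_events, op_map, trial = 1) {
  stop_if_not(inherits(op_map, "operational_map"),
              "op_map must be an operational_map")
  L <- op_map$Lambda[, trial]
  mass <- L[length(L)]
  keep <- op_events <= mass
  dropped <- sum(!keep)
  ev <- op_events[keep]
  if (length(ev) == 0) {
    out <- numeric(0)
  } else {
    out <- approx(x = L, y = op_map$time, xout = ev, ties = "min")$y
    # enforce strict ordering (flat Lambda segments can map ties together)
    out <- out[c(TRUE, diff(out) > 0)]
  }
  attr(out, "dropped") <- dropped
  out
}

#' Simulate a doubly stochastic renewal spike train
#'
#' Composition of the three-step generative algorithm per trial: the trial's
#' rate path defines the operational-time map, events are drawn from the
#' unit-mean renewal ISI model in operational time, and warped back to real
#' time through the inverse map. The pair {g(), lambda(t)} therefore fully
#' specifies the process: `phi` controls spiking irregularity, the rate path
#' controls rate fluctuations within and across trials.
#'
#' @param model An [isi_model].
#' @param path A [rate_path] (one column per trial).
#' @param seed Optional integer seed (per-trial substreams).
#' @param burn_in Operational-time burn-in, see [sample_operational_isis].
#' @return A [spike_train_set] with generator provenance in `metadata`.
#' @export
simulate_dsr <- function(model, path, seed = NULL, burn_in = 10) {
  stop_if_not(inherits(model, "isi_model"), "model must be an isi_model")
  stop_if_not(inherits(path, "rate_path"), "path must be a rate_path")
  op_map <- cumulative_rate(path)
  seeds <- derive_seeds(seed, path$n_trials)
  trials <- vector("list", path$n_trials)
  for (k in seq_len(path$n_trials)) {
    mass <- op_map$Lambda[nrow(op_map$Lambda), k]
    if (mass <= 0) {
      trials[[k]] <- numeric(0)
      next
    }
    set.seed(seeds[k])
    ev <- sample_operational_isis(model, mass, burn_in = burn_in)
    st <- warp_to_real_time(ev, op_map, trial = k)
    attributes(st) <- NULL
    trials[[k]] <- st
  }
  spike_train_set(trials, t_start = min(path$time), t_end = max(path$time),
                  metadata = list(generator = "dsr", phi = model$phi,
                                  family = model$family, seed = seed,
                                  burn_in = burn_in))
}

#' Simulate an inhomogeneous Poisson spike train
#'
#' The inhomogeneous Poisson process is the phi = 1 special case of the DSR
#' model, and is implemented through the same code path (single source of
#' truth); an independent thinning implementation is kept in the test suite
#' as a distributional oracle.
#'
#' @param path A [rate_path].
#' @param seed Optional integer seed.
#' @return A [spike_train_set].
#' @export
simulate_inhomogeneous_poisson <- function(path, seed = NULL) {
  out <- simulate_dsr(isi_model(1, "exponential"), path, seed = seed)
  out$metadata$generator <- "inhomogeneous_poisson"
  out
}
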