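#' Across-trial spike-count statistics on a sliding bin grid
#'
#' For every window position `t_i` on the stride grid with
#' `t_i + T_bin <= window[2]`, counts spikes per trial in the half-open bin
#' `[t_i, t_i + T_bin)` and returns the across-trial mean and unbiased
#' (n - 1) variance.
#'
#' @param spikes A [spike_train_set] with at least 2 trials.
#' @param T_bin Bin size in seconds, > 0.
#' @param stride Step between window positions (default `T_bin / 2`,
#'   overlapping bins).
#' @param window Length-2 analysis window in seconds (default the set's
#'   full window).
#' @return Object of class `count_stats`: list with `t` (bin start times),
#'   `mean`, `variance`, `T_bin`, `n_trials`. Zero positions (window
#'   shorter than the bin) yields empty vectors with attribute
#'   `empty = TRUE`.
#' @export
count_stats <- function(spikes, T_bin, stride = T_bin / 2, window = NULL) {
  stop_if_not(inherits(spikes, "spike_train_set"),
              "spikes must be a spike_train_set")
  stop_if_not(length(spikes) >= 2, "need at least 2 trials")
  stop_if_not(T_bin > 0, "bin size must be positive")
  if (is.null(window)) window <- c(spikes$t_start, spikes$t_end)
  starts <- seq(window[1], window[2], by = stride)
  starts <- starts[starts + T_bin <= window[2] + 1e-12]
  out <- list(t = starts, mean = numeric(0), variance = numeric(0),
              T_bin = T_bin, n_trials = length(spikes))
  if (length(starts) == 0) {
    attr(out, "empty") <- TRUE
    class(out) <- "count_stats"
    return(out)
  }
  counts <- vapply(spikes$trials, function(s) {
    vapply(starts, function(t0) sum(s >= t0 & s < t0 + T_bin), numeric(1))
  }, numeric(length(starts)))
  counts <- matrix(counts, nrow = length(starts))
  out$mean <- rowMeans(counts)
  out$variance <- apply(counts, 1, var)
  class(out) <- "count_stats"
  out
}

#' Default bin size T = 2 / E[lambda]
#'
#' The partition approximation requires `T > 1/E[lambda]` while the
#' constant-rate-within-bin assumption favors small bins; `T = 2/E[lambda]`
#' satisfies both, with the mean rate taken as total spikes divided by
#' total observed time.
#'
#' @param spikes A [spike_train_set].
#' @param window Optional length-2 analysis window in seconds.
#' @return Bin size in seconds.
#' @export
choose_bin_size <- function(spikes, window = NULL) {
  stop_if_not(inherits(spikes, "spike_train_set"),
              "spikes must be a spike_train_set")
  if (is.null(window)) window <- c(spikes$t_start, spikes$t_end)
  n_spk <- sum(vapply(spikes$trials, function(s)
    sum(s >= window[1] & s < window[2]), numeric(1)))
  stop_if_not(n_spk > 0,
              "no spikes in window: supply a bin size manually")
  rate <- n_spk / (length(spikes) * (window[2] - window[1]))
  2 / rate
}

#' Roots of the two-bin quadratic for spiking irregularity
#'
#' Given exact or estimated count moments for bins of size T and alpha*T
#' (counts sharing the left edge), solves
#' \deqn{\frac{\alpha^2-1}{6}\phi^2 - (\alpha^2 E[N_T] - E[N_{\alpha T}])\phi
#'   + \alpha^2 Var(N_T) - Var(N_{\alpha T}) - \frac{\alpha^2-1}{6} = 0}
#' and selects the smaller positive real root. With exact Poisson moments
#' the roots are {1, 4m - 1} (alpha = 2): only the smaller root is stable
#' as the mean count m varies, which motivates the selection rule.
#'
#' @param mean_T,var_T Count mean and variance in the bin of size T.
#' @param mean_aT,var_aT Count mean and variance in the bin of size alpha*T.
#' @param alpha Bin-size ratio > 1 (default 2).
#' @return List with `phi` (selected root, NA if the discriminant is
#'   negative or no positive root exists) and `roots` (both roots).
#' @export
dsr_quadratic_roots <- function(mean_T, var_T, mean_aT, var_aT, alpha = 2) {
  stop_if_not(alpha > 1, "alpha must exceed 1")
  a <- (alpha^2 - 1) / 6
  b <- -(alpha^2 * mean_T - mean_aT)
  cc <- alpha^2 * var_T - var_aT - (alpha^2 - 1) / 6
  disc <- b^2 - 4 * a * cc
  if (!is.finite(disc) || disc < 0) {
    return(list(phi = NA_real_, roots = c(NA_real_, NA_real_)))
  }
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  pos <- roots[roots > 0]
  list(phi = if (length(pos)) pos[1] else NA_real_, roots = roots)
}

new_phi_estimate <- function(phi, method, T_bin, n_valid, diagnostics) {
  structure(list(phi = phi, method = method, T_bin = T_bin,
                 n_valid_windows = n_valid, diagnostics = diagnostics),
            class = "phi_estimate")
}

#' @export
print.phi_estimate <- function(x, ...) {
  cat(sprintf("<phi_estimate> phi = %.4g (%s, T = %.4g s, %d valid windows)\n",
              x$phi, x$method, x$T_bin, x$n_valid_windows))
  invisible(x)
}

#' DSR estimator of spiking irregularity
#'
#' At each window position `t_i`, measures count mean and variance in the
#' nested bins `[t_i, t_i + T)` and `[t_i, t_i + alpha T)`, solves the
#' two-bin quadratic ([dsr_quadratic_roots]) and averages the valid roots
#' across positions. Positions with a negative discriminant or no positive
#' root are dropped and counted in the diagnostics. The estimate is clipped
#' at 0 from below, never from above.
#'
#' @param spikes A [spike_train_set] with >= 2 trials.
#' @param T_bin Bin size in seconds; default `choose_bin_size(spikes)`.
#' @param alpha Bin-size ratio (default 2, as in all reference analyses).
#' @param stride Step between positions (default `T_bin / 2`).
#' @param window Optional length-2 analysis window.
#' @return A `phi_estimate` (`phi` is `NA` if every window failed).
#' @export
estimate_phi_dsr <- function(spikes, T_bin = NULL, alpha = 2,
                             stride = NULL, window = NULL) {
  stop_if_not(inherits(spikes, "spike_train_set"),
              "spikes must be a spike_train_set")
  if (is.null(window)) window <- c(spikes$t_start, spikes$t_end)
  if (is.null(T_bin)) T_bin <- choose_bin_size(spikes, window)
  if (is.null(stride)) stride <- T_bin / 2
  stop_if_not(window[2] - window[1] >= alpha * T_bin,
              "window too short for the large bin alpha*T")
  cs1 <- count_stats(spikes, T_bin, stride = stride, window = window)
  cs2 <- count_stats(spikes, alpha * T_bin, stride = stride, window = window)
  n_pos <- length(cs2$t)  # positions where both bins fit
  phis <- rep(NA_real_, n_pos)
  for (i in seq_len(n_pos)) {
    phis[i] <- dsr_quadratic_roots(cs1$mean[i], cs1$variance[i],
                                   cs2$mean[i], cs2$variance[i],
                                   alpha = alpha)$phi
  }
  valid <- !is.na(phis)
  phi <- if (any(valid)) max(0, mean(phis[valid])) else NA_real_
  new_phi_estimate(phi, "DSR", T_bin, sum(valid),
                   diagnostics = list(alpha = alpha, stride = stride,
                                      n_windows = n_pos,
                                      n_failed = sum(!valid),
                                      window_phis = phis))
}

#' Partition spike-count variance into rate and point-process components
#'
#' Per window position, the firing-rate variance is recovered from the
#' partition identity for the gamma family:
#' `Var(lambda T) = Var(N_T) - phi E[N_T] - (1/6)(1 - phi^2)`,
#' i.e. the general form `Var(N_T) - phi E[N_T] - 1/6 - phi^2/2 +
#' psi(phi)/3` with `psi(phi) = 2 phi^2`. Negative values are reported as 0
#' with the raw value retained.
#'
#' @param spikes A [spike_train_set].
#' @param phi Spiking irregularity (>= 0), e.g. from [estimate_phi_dsr].
#' @param T_bin Bin size in seconds; default `choose_bin_size(spikes)`.
#' @param stride,window As in [count_stats].
#' @return Object of class `partition_result`: list with `t`, `var_rate`
#'   (clipped), `var_rate_raw`, `var_point` (`phi E[N_T] + (1/6)(1-phi^2)`),
#'   `var_total`, `mean_count`, `phi`, `T_bin`.
#' @export
partition_variance <- function(spikes, phi, T_bin = NULL, stride = NULL,
                               window = NULL) {
  stop_if_not(is.numeric(phi) && phi >= 0, "phi must be >= 0")
  if (is.null(T_bin)) T_bin <- choose_bin_size(spikes, window)
  if (is.null(stride)) stride <- T_bin / 2
  cs <- count_stats(spikes, T_bin, stride = stride, window = window)
  var_point <- phi * cs$mean + (1 - phi^2) / 6
  raw <- cs$variance - var_point
  structure(list(t = cs$t, var_rate = pmax(raw, 0), var_rate_raw = raw,
                 var_point = var_point, var_total = cs$variance,
                 mean_count = cs$mean, phi = phi, T_bin = T_bin),
            class = "partition_result")
}

#' Deterministic time-rescaling (DTR) estimator
#'
#' Assumes the firing rate is identical on every trial: estimates the
#' trial-averaged rate (PSTH) with a sliding window, maps each trial's
#' spikes to operational time through the PSTH's cumulative integral, and
#' returns the squared coefficient of variation of the pooled within-trial
#' rescaled ISIs. Exact when across-trial rate variance is zero; biased
#' upward otherwise, increasingly so with trial-to-trial rate variability.
#'
#' @param spikes A [spike_train_set] with >= 2 trials.
#' @param psth_window Sliding-window width in seconds (default 60 ms).
#' @param psth_step Window increments in seconds (default 10 ms).
#' @param rate_floor Minimum PSTH rate in Hz so the cumulative map stays
#'   invertible (default 0.1); floored positions are counted in the
#'   diagnostics.
#' @param window Optional analysis window.
#' @return A `phi_estimate` with method `"DTR"`.
#' @export
estimate_phi_dtr <- function(spikes, psth_window = 0.06, psth_step = 0.01,
                             rate_floor = 0.1, window = NULL) {
  stop_if_not(inherits(spikes, "spike_train_set"),
              "spikes must be a spike_train_set")
  stop_if_not(length(spikes) >= 2, "need at least 2 trials")
  if (is.null(window)) window <- c(spikes$t_start, spikes$t_end)
  grid <- seq(window[1], window[2], by = psth_step)
  K <- length(spikes)
  half <- psth_window / 2
  # trial-averaged rate in centered sliding windows, edge-truncated
  rate <- vapply(grid, function(tc) {
    lo <- max(window[1], tc - half)
    hi <- min(window[2], tc + half)
    n <- sum(vapply(spikes$trials, function(s)
      sum(s >= lo & s < hi), numeric(1)))
    n / (K * (hi - lo))
  }, numeric(1))
  n_floored <- sum(rate < rate_floor)
  rate <- pmax(rate, rate_floor)
  Lambda <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * psth_step))
  isis <- unlist(lapply(spikes$trials, function(s) {
    s <- s[s >= window[1] & s <= window[2]]
    if (length(s) < 2) return(numeric(0))
    diff(approx(grid, Lambda, xout = s, rule = 2)$y)
  }))
  if (length(isis) < 2) {
    return(new_phi_estimate(NA_real_, "DTR", psth_window, 0,
                            list(n_isis = length(isis),
                                 n_floored = n_floored)))
  }
  phi <- var(isis) / mean(isis)^2
  new_phi_estimate(phi, "DTR", psth_window, length(isis),
                   diagnostics = list(n_isis = length(isis),
                                      n_floored = n_floored,
                                      mean_rescaled_isi = mean(isis)))
}

#' Minimum-ratio (MR) estimator
#'
#' Estimates phi as the minimum Fano factor `Var(N_T)/E[N_T]` across window
#' positions (positions with zero mean count excluded). Rests on the ansatz
#' that point-process variance is proportional to mean count, which for
#' renewal processes holds only asymptotically in T, so the estimate picks
#' up bin-size- and rate-dependent biases of either sign.
#'
#' @param spikes A [spike_train_set] with >= 2 trials.
#' @param T_bin Bin size in seconds (default 60 ms as in the reference
#'   analyses).
#' @param stride,window As in [count_stats].
#' @return A `phi_estimate` with method `"MR"` (`NA` if all bins empty).
#' @export
estimate_phi_mr <- function(spikes, T_bin = 0.06, stride = T_bin / 2,
                            window = NULL) {
  cs <- count_stats(spikes, T_bin, stride = stride, window = window)
  ok <- cs$mean > 0
  ff <- cs$variance[ok] / cs$mean[ok]
  phi <- if (length(ff)) min(ff) else NA_real_
  new_phi_estimate(phi, "MR", T_bin, sum(ok),
                   diagnostics = list(n_windows = length(cs$t),
                                      n_empty = sum(!ok)))
}

#' Predicted estimation error of the MR method
#'
#' For a doubly stochastic renewal process the MR estimate deviates from
#' the true phi by approximately
#' `min_t { T Var(lambda(t))/E[lambda(t)] +
#'          (1/T) (1/6 + phi^2/2 - psi(phi)/3) / E[lambda(t)] }`
#' with `psi(phi) = 2 phi^2` for the gamma family. The first term is the
#' rate-variability bias (positive), the second the finite-bin renewal
#' correction (positive for phi < 1, negative for phi > 1).
#'
#' @param model An [isi_model].
#' @param path A [rate_path] supplying per-time across-trial mean and
#'   variance of the rate.
#' @param T_bin MR bin size in seconds.
#' @return Predicted `phi_MR - phi` (scalar).
#' @export
mr_error_prediction <- function(model, path, T_bin) {
  stop_if_not(inherits(model, "isi_model"), "model must be an isi_model")
  stop_if_not(inherits(path, "rate_path"), "path must be a rate_path")
  mean_rate <- rowMeans(path$rates)
  var_rate <- apply(path$rates, 1, var)
  stop_if_not(any(mean_rate > 0), "mean rate is zero at all times")
  ok <- mean_rate > 0
  phi <- model$phi
  corr <- 1 / 6 + phi^2 / 2 - psi_gamma(phi) / 3
  min(T_bin * var_rate[ok] / mean_rate[ok] +
        corr / (T_bin * mean_rate[ok]))
}

#' Filter units by trial count and spike totals
#'
#' Keeps a unit only if every analyzed condition has at least `min_trials`
#' trials and at least `min_spikes` spikes in total within the analysis
#' window (both bounds inclusive).
#'
#' @param summaries Data frame with columns `unit`, `condition`, `n_trials`,
#'   `n_spikes` (one row per unit x condition).
#' @param min_trials,min_spikes Inclusive thresholds (defaults 20 and 500).
#' @return Vector of kept unit identifiers.
#' @export
select_units <- function(summaries, min_trials = 20, min_spikes = 500) {
  stop_if_not(all(c("unit", "condition", "n_trials", "n_spikes") %in%
                    names(summaries)),
              "summaries needs columns unit, condition, n_trials, n_spikes")
  ok <- tapply(summaries$n_trials >= min_trials &
                 summaries$n_spikes >= min_spikes,
               summaries$unit, all)
  names(ok)[ok]
}

#' Modulation index between two conditions
#'
#' `(a - b)/(a + b)` for `convention = "half"` (as used for Fano-factor
#' attention effects) or `2(a - b)/(a + b)` for `convention = "full"`.
#'
#' @param a,b Condition statistics with `a + b != 0`.
#' @param convention `"half"` (default) or `"full"`.
#' @return Dimensionless modulation index (vectorized).
#' @export
modulation_index <- function(a, b, convention = c("half", "full")) {
  convention <- match.arg(convention)
  stop_if_not(all(a + b != 0), "a + b must be nonzero")
  mi <- (a - b) / (a + b)
  if (convention == "full") mi <- 2 * mi
  mi
}
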