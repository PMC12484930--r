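#' Intracellular voltage trace
#'
#' @param voltage Numeric vector of membrane-potential samples in mV,
#'   uniformly sampled.
#' @param sample_rate Sampling rate in Hz (>= 1000 for spike detection).
#' @return Object of class `voltage_trace` with `voltage`, `time` (s),
#'   `sample_rate`, `duration`.
#' @export
voltage_trace <- function(voltage, sample_rate) {
  stop_if_not(all(is.finite(voltage)), "voltage samples must be finite")
  stop_if_not(sample_rate > 0, "sample rate must be positive")
  n <- length(voltage)
  structure(list(voltage = as.numeric(voltage),
                 time = (seq_len(n) - 1) / sample_rate,
                 sample_rate = sample_rate,
                 duration = n / sample_rate),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %.3g s at %g kHz, range [%.1f, %.1f] mV\n",
              x$duration, x$sample_rate / 1e3, min(x$voltage),
              max(x$voltage)))
  invisible(x)
}

#' Detect spikes and excise waveforms from a voltage trace
#'
#' Spike times are upward crossings of the threshold (default -30 mV, far
#' above the typical ~-60 mV subthreshold range); crossings closer than the
#' dedup window are merged into one event. The trace from `pre` before to
#' `post` after each spike is replaced by linear interpolation between the
#' boundary samples (overlapping windows merged; windows truncated at the
#' trace edges are filled one-sided with the available boundary value).
#'
#' @param trace A [voltage_trace] sampled at >= 1 kHz.
#' @param threshold Detection threshold in mV (default -30).
#' @param pre,post Excision extent in seconds (defaults 3 ms and 5 ms).
#' @param dedup Merge window for double crossings in seconds (default 2 ms).
#' @return List with `spike_times` (s) and `subthreshold` (a
#'   [voltage_trace] with waveforms removed).
#' @export
detect_and_remove_spikes <- function(trace, threshold = -30, pre = 3e-3,
                                     post = 5e-3, dedup = 2e-3) {
  stop_if_not(inherits(trace, "voltage_trace"), "trace must be a voltage_trace")
  stop_if_not(trace$sample_rate >= 1000, "sample rate must be >= 1 kHz")
  v <- trace$voltage
  n <- length(v)
  up <- which(v[-1] >= threshold & v[-n] < threshold) + 1L
  if (length(up) > 1) {
    keep <- c(TRUE, diff(trace$time[up]) > dedup)
    up <- up[keep]
  }
  spike_times <- trace$time[up]
  if (length(up)) {
    half_pre <- round(pre * trace$sample_rate)
    half_post <- round(post * trace$sample_rate)
    lo <- pmax(up - half_pre, 1L)
    hi <- pmin(up + half_post, n)
    # merge overlapping excision windows
    ord <- order(lo)
    lo <- lo[ord]; hi <- hi[ord]
    m_lo <- lo[1]; m_hi <- hi[1]
    segs <- list()
    for (i in seq_along(lo)[-1]) {
      if (lo[i] <= m_hi + 1L) {
        m_hi <- max(m_hi, hi[i])
      } else {
        segs[[length(segs) + 1]] <- c(m_lo, m_hi)
        m_lo <- lo[i]; m_hi <- hi[i]
      }
    }
    segs[[length(segs) + 1]] <- c(m_lo, m_hi)
    for (s in segs) {
      a <- s[1]; b <- s[2]
      va <- if (a > 1) v[a - 1L] else v[b + 1L]
      vb <- if (b < n) v[b + 1L] else v[a - 1L]
      v[a:b] <- va + (vb - va) * seq_len(b - a + 1L) / (b - a + 2L)
    }
  }
  list(spike_times = spike_times,
       subthreshold = voltage_trace(v, trace$sample_rate))
}

#' Bin subthreshold voltage against instantaneous firing rate
#'
#' Segments the recording into time bins of `dt_bin`; per time bin i the
#' mean subthreshold voltage V_i and spike count N_i are computed. Time
#' bins are then pooled into voltage bins of width `dv` spanning `v_range`,
#' and the rate in voltage bin k is
#' `r_k = sum_{i in S_k} N_i / (|S_k| dt_bin)`. Bin centers are geometric
#' (`v_range[1] + (k - 1/2) dv`). Empty voltage bins are omitted.
#'
#' @param subthreshold A [voltage_trace] with spikes removed.
#' @param spike_times Spike times in seconds.
#' @param dt_bin Time-bin size in seconds (default 50 ms; 25 ms is also in
#'   common use for display purposes).
#' @param v_range Voltage range in mV (default `c(-68, -40)`).
#' @param dv Voltage-bin width in mV (default 1).
#' @return Data frame with columns `v` (bin center, mV), `rate` (Hz),
#'   `n_bins` (|S_k|).
#' @export
bin_voltage_rate <- function(subthreshold, spike_times, dt_bin = 0.05,
                             v_range = c(-68, -40), dv = 1) {
  stop_if_not(inherits(subthreshold, "voltage_trace"),
              "subthreshold must be a voltage_trace")
  n_tb <- floor(subthreshold$duration / dt_bin + 1e-9)
  stop_if_not(n_tb >= 1, "recording shorter than one time bin")
  idx <- pmin(floor(subthreshold$time / dt_bin) + 1L, n_tb)
  keep <- idx <= n_tb
  V_i <- tapply(subthreshold$voltage[keep], idx[keep], mean)
  N_i <- tabulate(pmin(floor(spike_times / dt_bin) + 1L, n_tb), nbins = n_tb)
  edges <- seq(v_range[1], v_range[2], by = dv)
  k <- findInterval(V_i, edges, rightmost.closed = TRUE)
  ok <- k >= 1 & k <= length(edges) - 1
  rate <- tapply(N_i[ok], k[ok], sum) / (tabulate(k[ok])[sort(unique(k[ok]))] * dt_bin)
  counts <- tapply(rep(1, sum(ok)), k[ok], sum)
  kk <- as.integer(names(rate))
  data.frame(v = v_range[1] + (kk - 0.5) * dv,
             rate = as.numeric(rate),
             n_bins = as.integer(counts))
}

#' Fit a smooth voltage-to-rate map
#'
#' Cubic smoothing spline through the binned (V_k, r_k) relationship, with
#' the smoothing parameter chosen by generalized cross-validation. The
#' fitted map is clamped at 0 from below and extrapolates as a constant
#' outside the populated voltage range.
#'
#' @param binned Data frame from [bin_voltage_rate] (needs >= 4 rows).
#' @return Object of class `rate_map`; evaluate with `predict(map, v)`.
#' @export
fit_rate_map <- function(binned) {
  stop_if_not(nrow(binned) >= 4, "need at least 4 populated voltage bins")
  fit <- smooth.spline(binned$v, binned$rate, cv = FALSE)
  structure(list(fit = fit, v_lo = min(binned$v), v_hi = max(binned$v)),
            class = "rate_map")
}

#' @export
predict.rate_map <- function(object, v, ...) {
  vc <- pmin(pmax(v, object$v_lo), object$v_hi)
  pmax(predict(object$fit, vc)$y, 0)
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> f(v) on [%.1f, %.1f] mV, f = %.2g..%.2g Hz\n",
              x$v_lo, x$v_hi, predict(x, x$v_lo), predict(x, x$v_hi)))
  invisible(x)
}

#' Spiking irregularity from the subthreshold voltage
#'
#' Evaluates the instantaneous rate `lambda(t) = f(v(t))` on the
#' subthreshold trace, maps spikes to operational time through the
#' cumulative rate, and returns the mean and squared coefficient of
#' variation of the rescaled ISIs. If the DSR framework holds, the rescaled
#' ISI mean is close to 1 (operational-time rate 1 Hz) and CV^2 estimates
#' phi independently of any spike-count statistic.
#'
#' @param subthreshold A [voltage_trace] with spikes removed.
#' @param rate_map A fitted [fit_rate_map] object.
#' @param spike_times Spike times in seconds.
#' @return List with `phi_voltage` (CV^2 of rescaled ISIs), `mu_hat_g`
#'   (their mean), `cv2_raw` (CV^2 of raw real-time ISIs), `n_isis`, and
#'   `flag_zero_rate` (TRUE if the rate vanished over a spike-containing
#'   span, collapsing an ISI to zero).
#' @export
phi_from_voltage <- function(subthreshold, rate_map, spike_times) {
  stop_if_not(inherits(rate_map, "rate_map"), "rate_map must be a rate_map")
  stop_if_not(length(spike_times) >= 3, "need at least 3 spikes")
  lam <- predict(rate_map, subthreshold$voltage)
  dt <- 1 / subthreshold$sample_rate
  Lambda <- c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2 * dt))
  op <- approx(subthreshold$time, Lambda, xout = spike_times, rule = 2)$y
  isis <- diff(op)
  raw <- diff(spike_times)
  list(phi_voltage = var(isis) / mean(isis)^2,
       mu_hat_g = mean(isis),
       cv2_raw = var(raw) / mean(raw)^2,
       n_isis = length(isis),
       flag_zero_rate = any(isis <= 0))
}

#' Synthetic intracellular voltage trace with known ground truth
#'
#' Generates a smooth mean-reverting (Ornstein-Uhlenbeck) subthreshold
#' voltage, converts it to an instantaneous rate through a monotone
#' ground-truth map `f_true`, draws spikes from the DSR model with the
#' requested irregularity, and stamps a stereotyped spike waveform at each
#' spike time. This is a synthetic stand-in for a whole-cell recording,
#' built so the full voltage pipeline can be exercised end-to-end with
#' known `phi` and `f_true`.
#'
#' @param duration Recording duration in seconds.
#' @param phi Ground-truth spiking irregularity.
#' @param sample_rate Sampling rate in Hz (default 10 kHz).
#' @param v_mean,v_sd,tau_v OU mean (mV), stationary SD (mV) and timescale
#'   (s) of the subthreshold voltage (defaults -57 mV, 1.5 mV, 0.5 s; range
#'   clipped to [-68, -40] mV).
#' @param f_true Monotone voltage-to-rate function (Hz from mV); default a
#'   power law `0.4 * max(v + 65, 0)^2`, giving ~25 Hz at -57 mV.
#' @param waveform_amp Spike-waveform amplitude in mV added above the
#'   subthreshold value (default 65, peaking near +8 mV).
#' @param seed Optional integer seed.
#' @return List with `trace` (spikes stamped in), `subthreshold_true`,
#'   `true_spike_times`, `true_rate` (a single-trial [rate_path] on a 1 ms
#'   grid), `true_phi`, `f_true`.
#' @export
make_synthetic_voltage <- function(duration, phi = 1, sample_rate = 1e4,
                                   v_mean = -57, v_sd = 1.5, tau_v = 0.5,
                                   f_true = function(v) 0.35 * pmax(v + 65, 0)^2,
                                   waveform_amp = 65, seed = NULL) {
  stop_if_not(duration > 0, "duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sample_rate)
  dt <- 1 / sample_rate
  a <- exp(-dt / tau_v)
  eps <- rnorm(n, sd = v_sd * sqrt(1 - a^2))
  v <- as.numeric(stats::filter(eps, a, method = "recursive",
                                init = rnorm(1, sd = v_sd)))
  v <- pmin(pmax(v_mean + v, -68), -40)
  # rate on a 1 ms grid from the subthreshold voltage
  step <- max(1L, round(sample_rate / 1e3))
  grid_idx <- seq(1L, n, by = step)
  rp <- rate_path((grid_idx - 1) * dt, matrix(f_true(v[grid_idx]), ncol = 1))
  spikes <- simulate_dsr(isi_model(phi), rp,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  st <- spikes$trials[[1]]
  v_out <- v
  if (length(st)) {
    # stereotyped narrow waveform (~1 ms, fast-spiking): 0.3 ms linear
    # rise, 0.7 ms linear decay
    rise <- round(0.3e-3 * sample_rate)
    fall <- round(0.7e-3 * sample_rate)
    shape <- c(seq(0, 1, length.out = rise + 1)[-1],
               seq(1, 0, length.out = fall + 1)[-1])
    for (t0 in st) {
      i0 <- round(t0 * sample_rate) + 1L
      ii <- i0 + seq_along(shape) - 1L
      ok <- ii <= n
      v_out[ii[ok]] <- v_out[ii[ok]] + waveform_amp * shape[ok]
    }
  }
  list(trace = voltage_trace(v_out, sample_rate),
       subthreshold_true = voltage_trace(v, sample_rate),
       true_spike_times = st,
       true_rate = rp,
       true_phi = phi,
       f_true = f_true)
}

#' Segment a continuous recording into pseudo-trials
#'
#' @param spike_times Spike times in seconds.
#' @param duration Recording duration in seconds.
#' @param segment Segment length in seconds.
#' @return A [spike_train_set] with one trial per non-overlapping segment,
#'   times re-referenced to segment start.
#' @export
segment_recording <- function(spike_times, duration, segment) {
  n_seg <- floor(duration / segment)
  stop_if_not(n_seg >= 2, "recording shorter than two segments")
  trials <- lapply(seq_len(n_seg), function(k) {
    lo <- (k - 1) * segment
    s <- spike_times[spike_times >= lo & spike_times < lo + segment] - lo
    if (length(s) < 2) return(s)
    s[c(TRUE, diff(s) > 0)]
  })
  spike_train_set(trials, 0, segment,
                  metadata = list(generator = "segmented recording"))
}

#' End-to-end voltage validation pipeline
#'
#' Runs detection, excision, voltage-rate binning, spline fitting and
#' operational-time rescaling on a voltage trace, and compares the
#' voltage-based irregularity against the spike-only DSR estimate obtained
#' by segmenting the recording into pseudo-trials.
#'
#' @param trace A [voltage_trace].
#' @param dt_bin Voltage-rate binning time bin (s), default 50 ms.
#' @param segment Segment length for the spike-only DSR estimate (s),
#'   default 2 (many pseudo-trials keep the finite-trial bias of the
#'   two-bin quadratic small).
#' @param ... Passed to [detect_and_remove_spikes].
#' @return List with `phi_voltage`, `mu_hat_g`, `phi_dsr`, `cv2_raw`,
#'   `ratio_phi_cv2` (phi_voltage / cv2_raw), `n_spikes`, `rate_map`.
#' @export
validate_voltage <- function(trace, dt_bin = 0.05, segment = 2, ...) {
  det <- detect_and_remove_spikes(trace, ...)
  binned <- bin_voltage_rate(det$subthreshold, det$spike_times,
                             dt_bin = dt_bin)
  map <- fit_rate_map(binned)
  resc <- phi_from_voltage(det$subthreshold, map, det$spike_times)
  seg <- segment_recording(det$spike_times, trace$duration, segment)
  dsr <- estimate_phi_dsr(seg)
  list(phi_voltage = resc$phi_voltage,
       mu_hat_g = resc$mu_hat_g,
       phi_dsr = dsr$phi,
       cv2_raw = resc$cv2_raw,
       ratio_phi_cv2 = resc$phi_voltage / resc$cv2_raw,
       n_spikes = length(det$spike_times),
       rate_map = map)
}
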