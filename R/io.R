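#' Read and write trial-structured spike trains as delimited text
#'
#' The on-disk format is a CSV with header `trial,spike_time_s`, one row per
#' spike. Trials are canonicalized on read: sorted within trial (with a
#' warning if input order was shuffled); negative times are rejected with
#' the offending line numbers.
#'
#' @param path File path.
#' @param t_start,t_end Analysis window recorded in the returned set; by
#'   default 0 and the latest spike time (rounded up to 1 ms).
#' @param n_trials Number of trials; defaults to the largest trial id + 1
#'   (ids are 0-based in the file, matching the `trial_0, trial_1, ...`
#'   naming used elsewhere).
#' @return A [spike_train_set].
#' @export
read_spike_trains <- function(path, t_start = 0, t_end = NULL,
                              n_trials = NULL) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  df <- read.csv(path)
  stop_if_not(identical(names(df)[1:2], c("trial", "spike_time_s")),
              "header must be trial,spike_time_s")
  if (nrow(df) > 0) {
    bad <- which(!is.finite(df$spike_time_s) | df$spike_time_s < 0)
    stop_if_not(length(bad) == 0,
                sprintf("malformed/negative spike times at data lines: %s",
                        paste(head(bad, 10), collapse = ", ")))
  }
  if (is.null(n_trials)) {
    n_trials <- if (nrow(df)) max(df$trial) + 1 else 0
  }
  if (is.null(t_end)) {
    t_end <- if (nrow(df)) ceiling(max(df$spike_time_s) * 1e3) / 1e3 else 1
  }
  trials <- vector("list", max(n_trials, 1))
  for (k in seq_along(trials)) {
    s <- df$spike_time_s[df$trial == k - 1]
    if (is.unsorted(s, strictly = FALSE)) {
      warning(sprintf("trial %d had unsorted spike times; sorted", k - 1))
      s <- sort(s)
    }
    trials[[k]] <- unique(s)
  }
  if (n_trials == 0) trials <- list()
  spike_train_set(trials, t_start = t_start, t_end = t_end,
                  metadata = list(source = path))
}

#' @rdname read_spike_trains
#' @param spikes A [spike_train_set] to write.
#' @export
write_spike_trains <- function(spikes, path) {
  stop_if_not(inherits(spikes, "spike_train_set"),
              "spikes must be a spike_train_set")
  n <- lengths(spikes$trials)
  df <- data.frame(trial = rep(seq_along(spikes$trials) - 1L, n),
                   spike_time_s = unlist(spikes$trials))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write rate paths as delimited text
#'
#' Format: header `time_s,trial_0,trial_1,...`, one row per grid point.
#'
#' @param path File path.
#' @return A [rate_path].
#' @export
read_rate_path <- function(path) {
  df <- read.csv(path)
  stop_if_not(names(df)[1] == "time_s", "header must start with time_s")
  rate_path(df$time_s, as.matrix(df[, -1, drop = FALSE]))
}

#' @rdname read_rate_path
#' @param rp A [rate_path] to write.
#' @export
write_rate_path <- function(rp, path) {
  stop_if_not(inherits(rp, "rate_path"), "rp must be a rate_path")
  df <- data.frame(time_s = rp$time, rp$rates)
  names(df) <- c("time_s", paste0("trial_", seq_len(rp$n_trials) - 1))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write voltage traces as delimited text
#'
#' Format: header `time_s,voltage_mv`, uniform sampling.
#'
#' @param path File path.
#' @return A `voltage_trace` (see [voltage_trace]).
#' @export
read_voltage_trace <- function(path) {
  df <- read.csv(path)
  stop_if_not(identical(names(df)[1:2], c("time_s", "voltage_mv")),
              "header must be time_s,voltage_mv")
  dt <- diff(df$time_s[1:2])
  voltage_trace(df$voltage_mv, sample_rate = 1 / dt)
}

#' @rdname read_voltage_trace
#' @param trace A `voltage_trace` to write.
#' @export
write_voltage_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time, voltage_mv = trace$voltage)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
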