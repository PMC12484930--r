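#' Benchmark grid for the estimator comparison
#'
#' Fully factorial sweep over ground-truth phi and a rate-variability
#' parameter, run for all three estimators. The `"full"` preset matches the
#' reference benchmark (phi 0.1-1.0 by 0.1; uniform width w in {10, 20, 30}
#' Hz or diffusion D in {5, 9, 13} Hz^2/ms; 20 replicates of 100 trials);
#' the `"reduced"` preset (3 phi x 2 variability levels x 5 replicates)
#' preserves the method ordering at a fraction of the cost.
#'
#' @param rate_family `"uniform"` (trial-constant rates, center 30 Hz) or
#'   `"ddm"` (drift-diffusion, bounds 1-60 Hz, drift 0.0138 Hz/ms, initial
#'   rate 30 Hz).
#' @param preset `"full"` or `"reduced"`; individual fields can be
#'   overridden.
#' @param phi,variability,n_trials,n_replicates,duration Optional overrides.
#' @param seed Root seed; each (phi, variability, replicate) cell gets a
#'   deterministic subseed.
#' @return Object of class `benchmark_grid`.
#' @export
benchmark_grid <- function(rate_family = c("uniform", "ddm"),
                           preset = c("full", "reduced"),
                           phi = NULL, variability = NULL,
                           n_trials = 100, n_replicates = NULL,
                           duration = 2, seed = 1) {
  rate_family <- match.arg(rate_family)
  preset <- match.arg(preset)
  if (is.null(phi)) {
    phi <- if (preset == "full") seq(0.1, 1, by = 0.1) else c(0.1, 0.5, 1)
  }
  if (is.null(variability)) {
    variability <- if (rate_family == "uniform") {
      if (preset == "full") c(10, 20, 30) else c(10, 30)
    } else {
      if (preset == "full") c(5, 9, 13) else c(5, 13)
    }
  }
  if (is.null(n_replicates)) n_replicates <- if (preset == "full") 20 else 5
  stop_if_not(all(phi > 0) && all(variability > 0), "grid values must be positive")
  structure(list(rate_family = rate_family, phi = phi,
                 variability = variability, n_trials = n_trials,
                 n_replicates = n_replicates, duration = duration,
                 seed = seed, preset = preset),
            class = "benchmark_grid")
}

simulate_benchmark_cell <- function(grid, phi, variability, seed) {
  path <- if (grid$rate_family == "uniform") {
    sample_uniform_trial_rates(center = 30, width = variability,
                               duration = grid$duration,
                               n_trials = grid$n_trials, seed = seed)
  } else {
    # grid D values are quoted in Hz^2/s (see methods vignette); the
    # sampler's diffusion argument is per-ms
    sample_drift_diffusion(nu = 0.0138, D = variability / 1e3, lower = 1,
                           upper = 60, lambda0 = 30,
                           duration = grid$duration,
                           n_trials = grid$n_trials, seed = seed)
  }
  simulate_dsr(isi_model(phi), path, seed = seed + 1L)
}

#' Run the estimator benchmark
#'
#' For every grid cell, simulates a DSR spike-train set and estimates phi
#' with each method; reports the mean estimate and the RMSE against ground
#' truth across replicates. The harness is estimator-agnostic: `methods` is
#' a named list of functions `spike_train_set -> phi_estimate`, defaulting
#' to DSR (auto bin size), DTR (60 ms / 10 ms PSTH) and MR (60 ms bins).
#'
#' @param grid A [benchmark_grid].
#' @param methods Named list of estimator functions.
#' @param verbose Log one line per cell.
#' @return Object of class `benchmark_result`: data frame `cells` with one
#'   row per (phi, variability, method) holding `mean_estimate`, `rmse`,
#'   `n_failed`, plus the grid.
#' @export
run_benchmark <- function(grid,
                          methods = list(
                            DSR = function(s) estimate_phi_dsr(s),
                            DTR = function(s) estimate_phi_dtr(s),
                            MR  = function(s) estimate_phi_mr(s)),
                          verbose = FALSE) {
  stop_if_not(inherits(grid, "benchmark_grid"), "grid must be a benchmark_grid")
  cells <- expand.grid(phi = grid$phi, variability = grid$variability,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells) * length(methods))
  r <- 0L
  for (i in seq_len(nrow(cells))) {
    phi <- cells$phi[i]
    v <- cells$variability[i]
    est <- matrix(NA_real_, nrow = grid$n_replicates,
                  ncol = length(methods),
                  dimnames = list(NULL, names(methods)))
    for (rep_k in seq_len(grid$n_replicates)) {
      cell_seed <- grid$seed + 7919L * i + 2L * rep_k
      spikes <- simulate_benchmark_cell(grid, phi, v, cell_seed)
      for (m in names(methods)) {
        fit <- try(methods[[m]](spikes), silent = TRUE)
        if (!inherits(fit, "try-error")) est[rep_k, m] <- fit$phi
      }
    }
    for (m in names(methods)) {
      e <- est[, m]
      ok <- is.finite(e)
      r <- r + 1L
      rows[[r]] <- data.frame(
        phi = phi, variability = v, method = m,
        mean_estimate = mean(e[ok]),
        rmse = sqrt(mean((e[ok] - phi)^2)),
        n_failed = sum(!ok))
    }
    if (verbose) {
      message(sprintf("cell phi=%.2f %s=%.3g: %s", phi,
                      if (grid$rate_family == "uniform") "w" else "D", v,
                      paste(sprintf("%s=%.3f", names(methods),
                                    colMeans(est, na.rm = TRUE)),
                            collapse = " ")))
    }
  }
  structure(list(cells = do.call(rbind, rows), grid = grid),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %s rates, %d cells x %d replicates\n",
              x$grid$rate_family, nrow(x$cells) / 3, x$grid$n_replicates))
  agg <- tapply(x$cells$rmse, x$cells$method, mean)
  cat("mean RMSE by method:",
      paste(sprintf("%s=%.3f", names(agg), agg), collapse = " "), "\n")
  invisible(x)
}
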