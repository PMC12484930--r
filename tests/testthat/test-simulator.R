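test_that("isi_model validates and encodes the gamma parameterization", {
  m <- isi_model(0.3)
  expect_equal(m$mu_g, 1)
  expect_error(isi_model(0), "positive")
  expect_error(isi_model(0.5, "exponential"), "phi = 1")
  # exponential corrections cancel: variance = mean = T
  mm <- renewal_count_moments(isi_model(1), 7)
  expect_equal(mm$variance, mm$mean)
  # phi = 0.5, T = 10: 5 + 1/6 - 1/24
  expect_equal(renewal_count_moments(isi_model(0.5), 10)$variance,
               5 + 1 / 6 - 1 / 24)
})

test_that("operational-time ISIs have unit mean and CV^2 = phi", {
  mass <- 1e5
  for (phi in c(0.3, 1)) {
    set.seed(7)
    ev <- sample_operational_isis(isi_model(phi), mass)
    isis <- diff(ev)
    n <- length(isis)
    expect_within(length(ev), mass, 3 * sqrt(phi * mass), "event count")
    expect_within(mean(isis), 1, 3 * sqrt(phi / n), "mean ISI")
    cv2 <- var(isis) / mean(isis)^2
    # SE of CV^2 from the delta method on gamma moments, approximate
    expect_within(cv2, phi, 3 * phi * sqrt(8 / n), "CV^2")
  }
  expect_error(sample_operational_isis(isi_model(1), -1), "positive")
})

test_that("cumulative rate is the trapezoidal integral", {
  p <- sample_constant_rate(10, 2, n_trials = 2)
  om <- cumulative_rate(p)
  expect_equal(om$Lambda[nrow(om$Lambda), ], c(20, 20))
  expect_equal(om$Lambda[1, ], c(0, 0))
  expect_true(all(cumulative_rate(sample_constant_rate(0, 1))$Lambda == 0))
  # linear ramp 0 -> 20 Hz over 1 s integrates to 10
  tg <- seq(0, 1, 1e-3)
  ramp <- rate_path(tg, matrix(20 * tg, ncol = 1))
  expect_equal(cumulative_rate(ramp)$Lambda[length(tg), 1], 10,
               tolerance = 1e-9)
})

test_that("warping to real time inverts the cumulative rate", {
  p <- sample_constant_rate(8, 2, n_trials = 1)
  om <- cumulative_rate(p)
  ev <- c(0.5, 1, 4, 15.9)
  out <- warp_to_real_time(ev, om, 1)
  expect_equal(as.numeric(out), ev / 8, tolerance = 1e-9)
  # events beyond Lambda(t_end) dropped with a count
  out2 <- warp_to_real_time(c(1, 17), om, 1)
  expect_equal(attr(out2, "dropped"), 1L)
  expect_length(out2, 1)
})

test_that("spike density tracks a step rate profile", {
  # 5 Hz on [0,1), 20 Hz on [1,2): spike counts proportional to rates
  tg <- seq(0, 2, 1e-3)
  r <- ifelse(tg < 1, 5, 20)
  p <- rate_path(tg, matrix(rep(r, 60), ncol = 60))
  s <- simulate_dsr(isi_model(1), p, seed = 21)
  n1 <- sum(unlist(s$trials) < 1)
  n2 <- sum(unlist(s$trials) >= 1)
  # binomial oracle: each spike falls in segment 1 with p = 5/25
  expect_within(n1 / (n1 + n2), 0.2, 3 * sqrt(0.2 * 0.8 / (n1 + n2)),
                "step-rate density split")
})

test_that("DSR simulation composes the three steps with provenance", {
  p <- sample_constant_rate(20, 2, n_trials = 100)
  s <- simulate_dsr(isi_model(0.3), p, seed = 31)
  expect_s3_class(s, "spike_train_set")
  expect_equal(s$metadata$phi, 0.3)
  expect_true(all(vapply(s$trials, function(x) all(diff(x) > 0), logical(1))))
  # zero rate: empty trains
  s0 <- simulate_dsr(isi_model(0.7), sample_constant_rate(0, 1, n_trials = 3))
  expect_equal(lengths(s0$trials), c(0L, 0L, 0L))
  # determinism
  s2 <- simulate_dsr(isi_model(0.3), p, seed = 31)
  expect_identical(s$trials, s2$trials)
  # FF ordering in phi at matched rate paths
  f_of <- function(phi) {
    cs <- count_stats(simulate_dsr(isi_model(phi), p, seed = 41), 0.1)
    mean(cs$variance / cs$mean)
  }
  expect_lt(f_of(0.3), f_of(1.7))
})

test_that("time-rescaling closure: true Lambda recovers unit-rate renewal", {
  p <- sample_drift_diffusion(nu = 0, D = 9e-3, lower = 1, upper = 20,
                              lambda0 = 10, duration = 2, n_trials = 400,
                              seed = 51)
  s <- simulate_dsr(isi_model(0.5), p, seed = 52)
  om <- cumulative_rate(p)
  op_isis <- unlist(lapply(seq_len(400), function(k) {
    st <- s$trials[[k]]
    if (length(st) < 2) return(numeric(0))
    diff(approx(om$time, om$Lambda[, k], xout = st)$y)
  }))
  n <- length(op_isis)
  expect_within(mean(op_isis), 1, 3 * sqrt(0.5 / n), "rescaled ISI mean")
  expect_within(var(op_isis) / mean(op_isis)^2, 0.5, 3 * 0.5 * sqrt(8 / n),
                "rescaled ISI CV^2")
})

test_that("inhomogeneous Poisson matches an independent thinning oracle", {
  p <- sample_constant_rate(20, 1, n_trials = 800)
  s <- simulate_inhomogeneous_poisson(p, seed = 61)
  counts <- lengths(s$trials)
  # chi-squared goodness of fit against Poisson(20)
  k <- 0:40
  expected <- 800 * dpois(k, 20)
  obs <- tabulate(counts + 1, nbins = 41)
  grp <- expected >= 5
  chi2 <- sum((obs[grp] - expected[grp])^2 / expected[grp])
  df <- sum(grp) - 1
  expect_gt(pchisq(chi2, df, lower.tail = FALSE), 0.01)
  # two-sample check against thinning on a fluctuating rate
  pu <- sample_uniform_trial_rates(30, 20, 1, n_trials = 600, seed = 62)
  s1 <- simulate_inhomogeneous_poisson(pu, seed = 63)
  s2 <- thinning_poisson(pu, seed = 64)
  expect_gt(suppressWarnings(
    ks.test(lengths(s1$trials), lengths(s2$trials))$p.value), 0.01)
  # fluctuating-rate Poisson is over-dispersed
  cs <- count_stats(s1, 0.1)
  expect_gt(mean(cs$variance / cs$mean), 1)
  expect_equal(lengths(simulate_inhomogeneous_poisson(
    sample_constant_rate(0, 1, n_trials = 2))$trials), c(0L, 0L))
})
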