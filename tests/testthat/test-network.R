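# Small-network contract tests; population sizes are tiny perfect squares
# so the dynamics are fast but every structural invariant still applies.
tiny_config <- function(...) {
  network_config("desk", sizes = list(N_f = 64, N_e = 400, N_i = 100), ...)
}

test_that("connectivity has exact out-degrees and lattice positions", {
  cfg <- tiny_config()
  g <- build_connectivity(cfg, seed = 2)
  N_e <- cfg$sizes$N_e; N_i <- cfg$sizes$N_i
  # out-degrees are exact and follow the in-degree-preserving scaling:
  # K(alpha -> beta) = round(P * (N_alpha,ref / N_alpha) * N_beta)
  ee <- g$syn[g$syn$src < N_e & g$syn$tgt < N_e & g$syn$ker == 0, ]
  expect_true(all(tabulate(ee$src + 1, N_e) == 400))  # 0.01*(40000/400)*400
  ie <- g$syn[g$syn$src >= N_e & g$syn$src < N_e + N_i & g$syn$tgt < N_e, ]
  expect_true(all(tabulate(ie$src - N_e + 1, N_i) == 1600))  # 0.04*100*400
  fe <- g$pois_syn[g$pois_syn$tgt < N_e, ]
  expect_true(all(tabulate(fe$src + 1, cfg$sizes$N_f) ==
                    round(0.1 * 2500 / 64 * 400)))
  # reproducible graph
  g2 <- build_connectivity(cfg, seed = 2)
  expect_identical(g$syn, g2$syn)
  # in-degree bookkeeping sums to the synapse tables
  expect_equal(sum(g$indegree$n_ie),
               nrow(g$syn[g$syn$ker == 1, ]))
})

test_that("target displacements follow the wrapped-Gaussian kernel", {
  cfg <- tiny_config()
  g <- build_connectivity(cfg, seed = 3)
  N_e <- cfg$sizes$N_e
  n <- sqrt(N_e)
  ee <- g$syn[g$syn$src < N_e & g$syn$tgt < N_e & g$syn$ker == 0, ]
  # sources in lattice column 1 (x = 0): target x-coordinates should be
  # multinomial with probabilities proportional to the kernel
  col1 <- ee[ee$src %% n == 0, ]
  tx <- col1$tgt %% n
  coords <- (seq_len(n) - 1) / (n - 1)
  pk <- wrapped_gaussian(coords - 0, 0.1)
  pk <- pk / sum(pk)
  emp <- tabulate(tx + 1, n) / length(tx)
  z_tol <- 4 * sqrt(pk * (1 - pk) / length(tx)) + 1e-3
  expect_true(all(abs(emp - pk) <= z_tol))
  # a very broad kernel is indistinguishable from uniform
  flat <- wrapped_gaussian(coords, 10)
  expect_lt(diff(range(flat)) / mean(flat), 5e-3)
})

test_that("network is silent without input and reproducible with it", {
  cfg <- tiny_config(f_in = 0)
  g <- build_connectivity(cfg, seed = 4)
  rec <- simulate_network(cfg, g, duration = 0.5, seed = 5, record_start = 0.2)
  expect_length(rec$time, 0)
  cfg2 <- tiny_config()
  rec1 <- simulate_network(cfg2, g, duration = 1, seed = 6, record_start = 0.5)
  rec2 <- simulate_network(cfg2, g, duration = 1, seed = 6, record_start = 0.5)
  expect_identical(rec1$time, rec2$time)
  expect_identical(rec1$neuron, rec2$neuron)
  expect_gt(length(rec1$time), 0)
  # refractory contract: no ISI shorter than tau_ref anywhere
  for (j in unique(rec1$neuron)[1:20]) {
    isis <- diff(neuron_spikes(rec1, j))
    tref <- ifelse(rec1$pop[j + 1] %in% c("2e", "3e"), 1.5e-3, 0.5e-3)
    if (length(isis)) expect_true(all(isis >= tref - 1e-9))
  }
})

test_that("single EIF neuron rate matches a fine-step refinement", {
  # one isolated excitatory neuron, constant suprathreshold drive
  run1 <- function(dt) {
    set.seed(1)
    out <- dsrpp:::simulate_eif_cpp(
      1L, 25, -60, -50, -10, 2, -65, 1.5, mu = 0.6,
      ker_tau_r = c(1, 1, 2), ker_tau_d = c(5, 8, 100),
      syn_offset = c(0L, 0L), syn_tgt = integer(0), syn_w = numeric(0),
      syn_ker = integer(0), n_pois = 0L, pois_rate = 0,
      pois_offset = 0L, pois_tgt = integer(0), pois_w = numeric(0),
      pois_ker = integer(0), mix_fast = 0.2, mix_slow = 0.8,
      dt = dt, duration = 5000, record_start = 1000)
    length(out$time_ms) / 4
  }
  coarse <- run1(0.05)
  fine <- run1(0.05 / 20)
  expect_gt(coarse, 5)
  expect_within(coarse, fine, 0.02 * fine, "EIF rate vs dt/20 refinement")
})

test_that("halving dt changes population rates by less than 5 percent", {
  cfg <- tiny_config()
  g <- build_connectivity(cfg, seed = 7)
  r1 <- simulate_network(cfg, g, duration = 1.5, seed = 8, record_start = 0.5)
  cfg2 <- tiny_config(dt = 0.025)
  r2 <- simulate_network(cfg2, g, duration = 1.5, seed = 8, record_start = 0.5)
  rate1 <- length(r1$time) / 1.5
  rate2 <- length(r2$time) / 1.5
  expect_within(rate1, rate2, 0.05 * rate2 + 3 * sqrt(rate2 / 1.5),
                "dt convergence of population rate")
})

test_that("poissonized surrogates have phi near one", {
  cfg <- tiny_config()
  g <- build_connectivity(cfg, seed = 9)
  rec <- simulate_network(cfg, g, duration = 60, seed = 10)
  surro <- poissonize_recording(rec, seed = 11)
  # 1-s segments give 60 pseudo-trials: enough that the quadratic'"'"'s
  # small-sample bias (strong below ~30 trials) is negligible
  res <- analyze_irregularity(surro, segment = 1, min_spikes = 600)
  expect_gt(nrow(res$per_neuron), 10)
  expect_within(mean(res$per_neuron$phi), 1, 0.15, "poissonized phi")
  # real recording analysis returns finite slopes and balance values
  res2 <- analyze_irregularity(rec, segment = 1, min_spikes = 600)
  expect_true(is.finite(res2$slope_rate))
  expect_true(all(is.finite(res2$per_neuron$balance)))
})
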