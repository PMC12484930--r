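---
title: "Partitioning spiking variability with doubly stochastic renewal processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning spiking variability with doubly stochastic renewal processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrpp)
```

## The model

A spike train is a point process. The observed trial-to-trial variability of
spike counts mixes two very different sources: fluctuations of the underlying
instantaneous firing rate $\lambda(t)$ (a latent, smoothly varying intensity)
and the irregularity of the mechanism that turns a given rate into discrete
spikes. `dsrpp` implements a *doubly stochastic renewal* (DSR) process that
separates the two. A DSR process is defined by a pair $\{g(\cdot),
\boldsymbol\lambda(t)\}$:

1. draw a rate path $\lambda(t)$ for the trial from the stochastic process
   $\boldsymbol\lambda(t)$;
2. draw inter-spike intervals i.i.d. from a density $g(\cdot)$ with mean
   $\mu_g = 1$ s, producing a unit-rate stationary renewal process in
   *operational time* $t'$;
3. map events to real time through the inverse cumulative rate
   $t = \Lambda^{-1}(t')$, $\Lambda(t) = \int_0^t \lambda(s)\,ds$.

Because $\mu_g$ is pinned at 1 s, the shape of $g$ is summarized by a single
parameter, the squared coefficient of variation
$\phi = \sigma_g^2 / \mu_g^2$: $\phi = 1$ is Poisson, $\phi < 1$ regular
(sub-Poisson), $\phi > 1$ bursty (super-Poisson). We take $g$ to be the
gamma density with shape $1/\phi$ and scale $\phi$, whose third central
moment is $\psi(\phi) = 2\phi^2$.

For counts $N_T$ in bins of size $T$ (with $T > 1/E[\lambda]$ and the rate
approximately constant within a bin), the law of total variance gives the
partition

$$\mathrm{Var}(N_T) = \underbrace{\mathrm{Var}(\lambda T)}_{\text{rate}} +
\underbrace{\phi\, E[N_T] + \tfrac{1}{6}(1 - \phi^2)}_{\text{point process}}
+ O(T^{-1}).$$

Writing this equation for two nested bins $[t, t+T)$ and $[t, t+\alpha T)$
and eliminating the unknown $\mathrm{Var}(\lambda)$ yields a quadratic in
$\phi$ whose coefficients are the four measurable count moments:

$$\frac{\alpha^2-1}{6}\phi^2 - \left(\alpha^2 E[N_T] - E[N_{\alpha T}]\right)\phi
+ \alpha^2 \mathrm{Var}(N_T) - \mathrm{Var}(N_{\alpha T}) - \frac{\alpha^2-1}{6} = 0.$$

`estimate_phi_dsr()` solves this per window position and averages the valid
roots; `partition_variance()` then splits the total count variance using the
estimated $\phi$. Two reference estimators are included for comparison:
deterministic time rescaling (`estimate_phi_dtr()`, PSTH-based, exact only
when the rate is identical on every trial) and the minimum Fano-factor ratio
(`estimate_phi_mr()`), together with its closed-form bias prediction
(`mr_error_prediction()`).

## Numerical and design choices

**Root selection.** With exact Poisson moments the quadratic has roots
$\{1, 4m-1\}$; only the smaller root is stable as the mean count $m$ varies,
so the smaller positive real root is always selected. Window positions with
a negative discriminant or no positive root are dropped and counted in the
estimate's diagnostics; the final estimate is the mean over valid positions,
clipped at 0 from below and never from above.

**Bin size.** The partition needs $T > 1/E[\lambda]$ while the
constant-rate-within-bin assumption favors small $T$; the default is
$T = 2/E[\lambda]$ with $\alpha = 2$ and stride $T/2$ (overlapping windows;
the correlation between overlapping estimates is ignored in the point
estimate). Count variances use the unbiased $(n-1)$ estimator throughout.

**Finite samples.** The root is a nonlinear function of noisy moments, so
with few trials the estimator acquires a positive bias that grows with the
across-trial rate variance; at 100 trials and rate SD up to ~9 Hz (the
benchmark settings) the bias is small (RMSE 0.01–0.05). Analyses in this
package therefore prefer many short pseudo-trials over few long ones when
segmenting continuous recordings (default 2-s segments).

**Equilibrium start.** The operational-time sampler runs a burn-in of 10
mean ISIs before $t' = 0$, so the window starts in the equilibrium renewal
state rather than with an event at the origin; an ordinary-renewal start
would bias early-bin count variances. The cumulative rate is integrated by
the trapezoid rule on the rate grid (default 1 ms) and inverted by monotone
linear interpolation, so simulated spike times carry a grid-resolution
quantization. Gamma draws that underflow to zero (tiny $\phi$) are floored
at $10^{-9}$ operational seconds to preserve strict ordering.

## Rate models and the benchmark

Three rate families drive simulations: constant rates; rates constant
within a trial and uniform $[\mu - w/2, \mu + w/2]$ across trials (benchmark
center 30 Hz, widths 10–30 Hz); and a drift–diffusion process with sticky
bounds,
$d\lambda/dt = \nu + \sqrt{2D}\,\xi(t)$ between bounds $b_l$ and $b_u$ with
$d\lambda/dt = 0$ at the bounds. The bound condition is implemented as
absorbing, reading the equation literally (a `reentry` switch restores
per-step clipping without freezing; under the benchmark parameters the two
give indistinguishable estimator results). Integration is explicit
Euler–Maruyama at 1 ms; drift and diffusion arguments are in per-ms units
(`nu` in Hz/ms, `D` in Hz²/ms) and converted internally once.

One unit in the benchmark deserves a note. The drift–diffusion grid values
$D \in \{5, 9, 13\}$ are interpreted in Hz²/s, not Hz²/ms. At Hz²/ms
magnitudes the rate sweeps the entire 1–60 Hz range within ~0.2 s: it then
decorrelates *within* a counting bin, every estimator's slow-rate
assumption fails, the quadratic estimator is strongly biased, and the
implied rate variance (~10³ Hz²) is two orders of magnitude beyond the
companion uniform settings ($w^2/12 = 8$–$75$ Hz²). At Hz²/s the two rate
families produce commensurate trial-to-trial variability and the quadratic
estimator's RMSE is low and flat across $D$, which is the regime the
benchmark is designed to probe. The grid therefore passes `D/1000` to the
per-ms sampler interface.

`run_benchmark()` sweeps $\phi \in \{0.1, \dots, 1.0\}$ against $w$ or $D$,
100 trials of 2 s per simulation (trial duration is this package's choice),
20 replicates in the full preset and 5 in the reduced one, and reports the
mean estimate and RMSE per cell for each method.

## Voltage-based validation

The voltage pipeline provides an estimate of $\phi$ that never touches
spike-count statistics: detect spikes at an upward $-30$ mV crossing (2 ms
double-crossing merge), excise $[-3, +5]$ ms around each spike with linear
interpolation, bin the subthreshold trace into 50 ms bins, pool (mean
voltage, spike count) pairs into 1 mV voltage bins on $[-68, -40]$ mV, fit
a GCV-smoothed cubic spline $f(v)$ (clamped at 0, constant extrapolation
outside the populated range), and rescale the spikes by the cumulative
$f(v(t))$. The mean of the rescaled ISIs $\hat\mu_g$ should be ~1 s if
$f(v(t))$ is a faithful instantaneous rate, and their CV² estimates $\phi$.
Voltage bin centers are geometric ($-68 + (k - \tfrac12)\Delta V$). Both
50 ms and 25 ms time-bin conventions are in circulation for this kind of
voltage-rate analysis; both are supported and 50 ms is the default.

`make_synthetic_voltage()` makes the pipeline testable without any data
download: an Ornstein–Uhlenbeck subthreshold voltage (mean $-57$ mV, SD 1.5
mV, timescale 0.5 s, clipped to $[-68, -40]$ mV), a monotone power-law
ground-truth map $f_{\text{true}}(v) = 0.35\,(v+65)_+^2$ (≈23 Hz at the
resting mean, matching fast-spiking cortical interneurons with rates above
20 Hz), DSR spikes driven by $f_{\text{true}}(v(t))$, and a stereotyped
~1 ms waveform stamped at each spike time. The defaults emulate slow
state-like voltage fluctuations whose timescale (0.5 s) is long against the
counting bin, and a rate SD (~8 Hz) comparable to the benchmark settings —
they do *not* emulate synaptic shot noise, spike afterpotentials,
rate-dependent spike-shape changes, or any spike-to-voltage feedback. Burst
ISIs shorter than the 2 ms detection merge window are undetectable by
construction, so at $\phi = 1.7$ roughly a tenth of spikes are missed and
both the voltage-based and spike-only estimates are compressed toward
smaller values by ~20%; passing the closure test therefore bounds pipeline
distortion on this class of traces, not detector performance on real
bursty recordings.

## The spiking network

The circuit model is a three-layer, spatially ordered balanced network:
2500 thalamic Poisson units at 10 Hz, then two recurrent layers of
exponential integrate-and-fire neurons (40,000 excitatory + 10,000
inhibitory each at full scale) on a unit-square lattice with
wrapped-Gaussian, distance-dependent connectivity (wrap sum truncated at
$|k| \le 3$; below $10^{-12}$ for $\sigma \le 0.2$). Every presynaptic
neuron has an exact out-degree $\mathrm{round}(P \cdot N_{\text{target}})$,
multiple contacts allowed. Synaptic currents are differences of
exponentials (excitatory 1/5 ms rise/decay, inhibitory 1/8 ms); the
layer-2→3 projection mixes a fast and a slow (2/100 ms) component 0.2/0.8.
Integration is forward Euler at 0.05 ms (the integrator and step are this
package's choice; a dt-halving convergence check is part of the test
suite), with the spike upswing clamped rather than resolved and refractory
reset per type.

**Desk preset.** The full network is impractical interactively, and a naive
size reduction that keeps the full-scale weights under the
$1/\sqrt{N_e+N_i}$ rule weakens total recurrent coupling by
$\sqrt{N_{\text{full}}/N_{\text{desk}}}$ — measured at desk sizes, the
layer-3 shared fluctuations are then no longer suppressed by the attention
current, i.e. the network leaves the operating regime of interest. The desk
preset (3969 + 1024 neurons per layer, 256 thalamic units) instead
preserves each neuron's expected in-degrees and per-synapse weights:
connection probabilities are scaled up by the source-population reduction
factor and the weight normalization stays at the full-size
$1/\sqrt{50000}$. This keeps the mean-field operating point; the price is
stronger shared-input correlations (in-degree over network size grows), so
desk-scale modulation indices are meaningful at sign level only, not in
magnitude.

**Attention experiment.** Two runs share the connectivity graph and all
random inputs and differ only in the static depolarizing current to layer-3
inhibitory neurons (0.2 mV/ms unattended, 0.4 attended). Per layer-3 neuron
passing a 250-spike filter in both states (the desk-scale analysis choice;
the full-scale unit filter of 20 trials / 500 spikes is implemented in
`select_units()`), the recording is cut into 1-s pseudo-trials (32 of them; the two-bin
quadratic's small-sample bias, measured at about +0.5 on Poisson controls
with 15 trials and +0.04 with 60, argues for many short pseudo-trials) and
the Fano
factor, $\phi$ (DSR estimator) and $\mathrm{Var}(\lambda T)$ (partition
identity) are computed with a per-neuron bin size $T = 2/E[\lambda]$ shared
across states, so bin-size changes cannot masquerade as modulation.
Modulation indices use $(a_{\text{att}} - a_{\text{unatt}})/(a_{\text{att}}
+ a_{\text{unatt}})$. At desk scale the analysis subsamples 1500 layer-3
neurons and uses 32-s recordings per state; segment length, window and bin
settings for this analysis are desk-preset choices documented here.

## What the tests do and do not show

The test suite exercises every operation against independent oracles:
closed-form uniform and gamma moments, a thinning implementation of the
inhomogeneous Poisson process, brute-force fine-step integrations for the
drift–diffusion sampler and the single EIF neuron, hand-computed partition
identities, and end-to-end closure of the voltage pipeline on synthetic
traces. Passing them shows the implementation is faithful to the model and
that the estimators behave as derived *under the generators' assumptions*
(renewal spiking in operational time, smooth rates, stationary segments).
Real recordings violate these in ways the generators deliberately do not
emulate — adaptation and history dependence beyond renewal, non-stationary
task-locked dynamics, measurement noise and spike-sorting errors — so
agreement here bounds implementation error, not model adequacy for any
particular dataset. Problem sizes in the tests (simulation lengths, trial
counts, network sizes, replicate counts) are the package's desk-scale
choices; the full-size network configuration and the full benchmark grid
ship as named presets.
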