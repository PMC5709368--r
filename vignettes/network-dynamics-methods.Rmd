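---
title: "Methods: functional connectivity and dynamics of resting-state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional connectivity and dynamics of resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdyn)
```

# Overview

`netdyn` analyzes resting-state brain networks from two angles and links
them: correlation-based functional connectivity (within-network cohesion,
between-network integration) and phase-based dynamics (synchrony and
metastability of the Kuramoto order parameter), with a delay-coupled
Kuramoto simulator on a structural connectome as the generative model of
the dynamics. This vignette documents the models, the parameters that
matter, the numerical conventions, and what the synthetic-data generator
does and does not emulate.

# Phase extraction from BOLD signals

Regional BOLD series are first narrowband-filtered with the
maximal-overlap discrete wavelet transform (MODWT), using the Daubechies
least-asymmetric length-8 filter. Level $j$ of the transform isolates the
octave band $[f_s/2^{j+1},\, f_s/2^{j}]$; at a 1-s sampling interval the
default level 4 spans 0.031–0.063 Hz, the slow band conventionally quoted
as 0.03–0.06 Hz. The band-passed signal is the level-4 *detail* of the
multiresolution analysis — not the smooth, and not a sum of levels — so
that `rowSums(D) + S` reconstructs the input exactly (a property the test
suite checks on random series).

Numerical conventions, where more than one choice is defensible:

* **Boundary rule.** Circular (periodic) filtering, the common default
  for the MODWT. Any boundary rule distorts the series ends; the explicit
  border trim below mitigates this regardless of the rule.
* **Demeaning.** Each regional series is demeaned before the Hilbert
  transform; the analytic signal of a series with a nonzero mean has a
  distorted phase. The wavelet detail is already zero-mean up to boundary
  effects, so this is a safeguard rather than a correction.
* **Border trim.** The instantaneous phase $\varphi(t)$ and amplitude
  $A(t)$ are the argument and modulus of the FFT-based analytic signal
  $z(t) = s(t) + i\,H[s(t)]$. The first and last 10 *samples* are then
  discarded (at TR = 1 s, 10 s per edge), because the discrete Hilbert
  transform is least reliable at the series edges: a 410-sample recording
  leaves 390 analyzed samples. The trim is counted in samples, not
  seconds, so it scales naturally with the sampling rate.
* **Degenerate inputs.** A constant (all-zero after demeaning) series has
  no defined phase and raises an error instead of propagating NaN;
  Fisher's $z = \operatorname{atanh}(r)$ likewise refuses $|r| \ge 1$
  rather than silently clipping.

# Network metrics

For a network of $N$ member regions with phases $\varphi_n(t)$, the order
parameter is $R(t) = |\tfrac1N \sum_n e^{i\varphi_n(t)}|$, computed with
*unweighted* unit phasors (no amplitude weighting). Synchrony is the time
mean of $R(t)$ and metastability its time SD. Two conventions are fixed
deliberately:

* **Population SD** (divisor $T$) for metastability: $R(t)$ is treated as
  the complete realization under analysis rather than a sample from a
  longer one. At $T = 390$ the difference from the sample SD is
  negligible, but tests require one fixed convention.
* **Cohesion and integration at the ROI level.** Cohesion is the mean
  pairwise Pearson correlation among member ROI series; integration is
  the unweighted mean, over the other $K-1$ networks, of the correlation
  between network-mean series. Voxel-level definitions exist, but this
  package's inputs are regional time series by design, so ROI-level is
  the honest definition here.

A phase-locking-value matrix,
$\mathrm{PLV}_{ij} = |\,\overline{e^{i(\varphi_i - \varphi_j)}}\,|$, is
provided as an alternative, purely phase-based connectivity definition.

# The delay-coupled Kuramoto model

Each region is a phase oscillator,
$\dot\theta_n = \omega_n + k \sum_p C_{np}
\sin(\theta_p(t - D_{np}) - \theta_n)$, where $C$ is the structural
weight matrix and the delay matrix $D = L/v$ is derived from tract
lengths. The conduction velocity is set indirectly through the mean delay
$\tau$: $v = \overline{L}/\tau$ with $\overline{L}$ the mean length over
*connected* pairs (zeros would otherwise drag the mean toward zero and
make $v$ depend on density rather than anatomy). With
$\overline{L} = 57.3$ mm and $\tau = 6$ ms this gives $v = 9.55$ mm/ms,
printed at one decimal (half-up) as 9.6 m/s — inside the physiological
5–20 m/s range.

Key parameters and defaults:

| parameter | default | units | role |
|---|---|---|---|
| `omega_mean`, `omega_sd` | 60, 1 | Hz | intrinsic frequencies (gamma band) |
| `omega_dist` | `"uniform"` | — | uniform on mean ± √3·SD, i.e. the uniform with that mean/SD; `"normal"` available for slow-oscillator runs (e.g. 0.045 ± 0.01 Hz) |
| `tau_mean` | 6 | ms | mean conduction delay; 0 disables delays |
| `dt` | 0.1 | ms | Euler step (must resolve $\omega\,dt \ll 1$ at 60 Hz) |
| `duration`, `transient` | 410, 20 | s | simulated and discarded time |
| `store_stride` | ≤ 10 ms of simulated time | steps | stored phase resolution |
| `k` | swept, e.g. 1–25 | — | global coupling |

The frequency wording "uniformly distributed with mean 60 Hz and SD 1 Hz"
is taken literally: the uniform distribution with that mean and SD,
i.e. uniform on $[60-\sqrt3, 60+\sqrt3]$ Hz. A normal option is offered
because an SD is more commonly quoted for normal distributions; the
uniform reading is the default since it is what the words say.

Numerical choices:

* **Delay discretization** rounds $D_{np}/dt$ to the nearest step; the
  invariant $|D - dt\cdot\text{steps}| \le dt/2$ is tested.
* **History initialization.** A delay equation needs phases before
  $t = 0$; the pre-history is backward free rotation,
  $\theta_n(-s) = \theta_n(0) - \omega_n s$, which is the natural
  continuation of an uncoupled oscillator and avoids a spurious initial
  jolt that frozen history would inject.
* **Euler scheme** with random uniform initial phases; the two-oscillator
  closed form ($\dot\Delta = -2k\sin\Delta$, so
  $\tan(\Delta/2) = \tan(\Delta_0/2)e^{-2kt}$) and a dt-halving check
  bound the integration error at well under 1 % at the default steps.
* **Branch consistency.** The zero-delay fast path and the delay-aware
  path with zero delay steps produce bit-identical trajectories (tested),
  so enabling delays cannot silently change delay-free results.
* **Simulated phases feed $R(t)$ directly** — no wavelet/Hilbert
  re-processing; the model already produces phases, and re-filtering a
  60 Hz oscillation sampled for analysis would be meaningless at fMRI
  bands.

In a coupling sweep the same seed is reused for every $k$, so curves over
$k$ differ only through the coupling, not through initial conditions.

# Model fit

Fit error is the absolute difference between simulated and empirical
synchrony/metastability per network. The optimal coupling per network is
either the argmax of simulated metastability (the default working-point
definition) or the argmin of the summed absolute error; ties resolve to
the smallest $k$ so the choice is deterministic.

# Statistics

Bootstrap Pearson correlation: point estimate and $p$ from the exact
r-to-t reference distribution; 95 % CI from 1000 case-resampled
replicates (percentile method — no method beyond "95 % CI" is assumed).
Bootstrap one-way ANOVA: observed $F$ from the standard decomposition,
CI by resampling cases *within* groups, preserving group sizes (resampling
residuals is the alternative; cases-within-groups is simpler and makes no
homoscedasticity assumption for the CI). Covariate adjustment (network
size, demographics) is residualization of the response on the covariates
before the ANOVA; constant covariates reduce exactly to the unadjusted
analysis. Levene's test uses the mean-centered variant; the KS normality
check uses the Lilliefors correction by default because the normal's
parameters are estimated from the sample (the plain KS p would be
anti-conservative), with `correct = FALSE` available.

All resampling takes an explicit seed and is reproducible bit for bit.

# The synthetic-data generator

No subject data ship with the package, so the generator produces inputs
with known ground truth for every downstream stage:

* **Connectome**: block-structured symmetric weights (truncated-normal
  with SD = mean/4, floored at 0; within-block mean 1, between-block 0.2
  by default), shifted-gamma tract lengths with mean 57.3 mm and a 10-mm
  floor (tractography discards short fibers), zero diagonals, six
  networks of unequal size over 90 regions by default.
* **Signals**: each network carries a common narrowband carrier (uniform
  in 0.03–0.06 Hz); each member region follows it with a slowly varying
  phase offset whose stationary distribution is von Mises with the
  network's concentration $\kappa$. The offsets are built by a
  probability-integral transform of a Gaussian Ornstein–Uhlenbeck
  process, giving smooth paths with an *exact* von Mises marginal — so
  the expected order parameter of a large network has the closed form
  $I_1(\kappa)/I_0(\kappa)$, the generator's recorded ground truth.
  Gaussian measurement noise (SD 0.2) is added.

**Why the offset timescale is 60 s.** The phase-offset process modulates
the carrier; its spectral half-width is roughly
$1/(2\pi\,\text{timescale})$. For the generated coherence to survive the
level-4 band-pass unchanged, that modulation bandwidth must sit well
inside the 0.031–0.063 Hz band around the carrier. A 20-s timescale
(≈ 0.008 Hz half-width, against a 0.016 Hz band half-width) fails this:
the filter clips modulation sidebands, compresses the offsets and
inflates measured synchrony by up to ~0.1 at intermediate $\kappa$. At
60 s (≈ 0.003 Hz) the modulation is genuinely in-band and the pipeline
recovers the Bessel-ratio ground truth to within finite-network bias. The
cost is fewer independent offset configurations per run (~3 in 390 s), so
single-run synchrony estimates carry sampling variability of a few
hundredths to ~0.06 at low $\kappa$; the tests account for this with a
Monte-Carlo oracle of the finite-$N$, finite-$T$ resultant rather than by
comparing to $I_1/I_0$ alone.

What the generator does **not** emulate: hemodynamic convolution, scanner
drift and motion artifacts, spatially correlated noise, negative
structural "weights", and amplitude dynamics — the target is the
statistical structure the analysis consumes (modular anatomy, narrowband
partially synchronized phases), not realistic fMRI. Passing tests
therefore validate the analysis chain, not robustness to fMRI artifacts,
which are assumed to be handled upstream.

# Problem sizes used in validation

The test suite and the acceptance script run at desk scale, chosen so
each check has clear statistical power while the whole suite stays fast:
a 300-oscillator all-to-all network (40 s at dt = 10 ms, 5 seeds) for the
mean-field law $R = \sqrt{1 - K_c/K}$ with Lorentzian frequencies; a
12-node, 3-module connectome (30 s at dt = 0.5 ms, 7 coupling values) for
the metastability-peak shape; 90 regions × 410 s for the
$\kappa$-recovery study; $n = 180$, 20–200 replicates × 1000 resamples
for bootstrap CI coverage. The full-scale configuration of the simulator
(90 regions, 410 s at dt = 0.1 ms, 25 coupling values) is available
through the same interfaces.

# Known limitations

* First-order Kuramoto models do not exhibit true metastability in the
  dynamical-systems sense; "metastability" here is, by the field's
  convention, the SD of $R(t)$.
* The MODWT octave bands are fixed by the sampling rate; a TR other than
  1 s shifts the level-4 band away from 0.03–0.06 Hz, so the level should
  be chosen per dataset (`wavelet_band()` reports the nominal edges).
* Between-network integration averages over the other networks
  unweighted; with very unequal network sizes a weighted variant could
  differ.
* The volume normalization of connectome weights divides by the
  arithmetic mean of the two ROI volumes — symmetric and unit-preserving;
  sum or product conventions exist and would rescale weights
  monotonically without changing their ranking.
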