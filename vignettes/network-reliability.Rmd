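---
title: "Test-retest reliability of channel-space functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-retest reliability of channel-space functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrel)
```

## The model

A two-session resting-state optical study measures hemoglobin
concentration changes at `n` channels in each of `N` subjects, twice. The
analysis chain turns each recording into a functional network and asks how
repeatable the network's graph-theoretical description is:

* **Connectivity.** The Pearson correlation `r_ij` between the band-passed
  time series of channels `i` and `j` defines an `n x n` symmetric
  connectivity matrix per subject and session.
* **Binarization.** At sparsity `S`, the `K = round(S n(n-1)/2)` strongest
  correlations become edges of an unweighted, undirected graph. Because no
  single threshold is canonical, everything is evaluated on the grid
  `S = 0.01, 0.02, ..., 0.99`.
* **Graph metrics.** Ten global metrics (`Cp`, `Lp`, `gamma`, `lambda`,
  `sigma`, `Eloc`, `Eglob`, `Q`, `beta`, `r`) and three nodal metrics
  (degree, efficiency, betweenness) per network.
* **Reliability.** For each measured quantity the `N x 2` subject-by-session
  table is decomposed by one-way random-effects ANOVA into
  between-subject (`MS_b`) and within-subject (`MS_w`) mean squares,

  $$ICC = \frac{MS_b - MS_w}{MS_b + (k-1)\,MS_w}, \qquad k = 2,$$

  clamped below at 0 (a negative value means the within-subject noise
  exceeded the between-subject spread; the magnitude of a negative ICC has
  no interpretation). Grades partition `[0, 1]`: poor `[0, 0.25)`, low
  `[0.25, 0.4)`, fair `[0.4, 0.6)`, good `[0.6, 0.75)`, excellent
  `[0.75, 1]`; the boundaries are half-open on the left so that 0.6 grades
  "good" and 0.75 "excellent" — the prose ranges these grades are usually
  quoted in overlap at their endpoints, so a convention has to be fixed.
* **Threshold independence.** Since `ICC(S)` is a curve, each metric is
  also summarised by the trapezoidal area under its metric-versus-sparsity
  curve per subject and session; the ICC of those AUCs is a single
  threshold-free reliability scalar.

## The synthetic cohort and the planted reliability level

No public recordings accompany this design, so the package ships a
generator (`generator_config()`, `generate_dataset()`) whose defaults are
the study conditions the analysis is built around: 18 subjects, 2
sessions, 46 channels, 25 Hz sampling, 600 s of retained signal (15,000
samples), neural fluctuations confined to 0.009–0.08 Hz.

Each subject owns `n_latent = 3` latent band-limited Gaussian sources
(white noise hard-limited to the neural band in the frequency domain) with
subject-specific random channel loadings; each session adds an independent
set of the same construction. With planted reliability `rho`, the shared
and session-specific components enter with **variance** shares
`sqrt(rho) : sqrt(1 - rho)`. Edge correlations are linear in variance
shares, so the population edge value is

$$r_{ij} \propto \sqrt{\rho}\, C^{subj}_{ij} + \sqrt{1-\rho}\, C^{sess}_{ij},$$

whose between/within variance ratio gives an edge ICC of exactly `rho`.
(Scaling the *amplitudes* by `sqrt(rho)` instead would plant
`rho^2/(rho^2 + (1-rho)^2)`, which is not the intended contract.) The
small latent dimension is deliberate: with 3 latent "networks" the
edge-wise correlation spread across subjects is large (variance about
1/3), which is what keeps the finite-duration sampling noise of Pearson
estimates from dominating the within-subject variance.

That sampling noise is the one systematic bias of the chain: a 600-s
recording band-limited to 0.07 Hz of bandwidth carries only ~85
independent samples per correlation estimate, adding ~0.01 of
within-subject variance and attenuating a planted 0.7 to a measured
~0.68–0.69. The package's validation accepts the planted level within
±0.05 (at 200 subjects, where estimator noise is negligible and only this
attenuation remains); the limit behaviour — ICC → 1 as duration → ∞ when
`rho = 1` — is tested separately.

Physiological confounds are sinusoids with per-channel random phase and 2%
frequency jitter: cardiac 1 Hz (amplitude 0.8 in units of neural SD),
respiratory 0.3 Hz (0.5), Mayer waves 0.1 Hz (0.4), plus white instrument
noise (SD 0.3). These amplitudes are not fitted to any recording — no
amplitudes are published for the emulated design — they are chosen once as
qualitatively realistic: confounds comparable to the neural signal, nearly
all of their power outside the neural band so that the band-pass removes
them. HbR is `-0.4` times the neural component of HbO plus its own
confounds and noise (anti-correlated, smaller magnitude, as in real
hemodynamics; the exact ratio is irrelevant to correlation-based
networks), and HbT = HbO + HbR holds exactly by construction.

`plant_artifacts()` superimposes the artifact archetypes that motion and
superficial interference produce — step jumps, slow U/inverted-U bumps,
fast spike trains, and a rank-one global oscillation — while keeping the
clean copy for ground-truth scoring.

**What the generator does not emulate:** real optode-scalp coupling,
spatially structured physiological noise, non-stationarity of the resting
state, inter-session probe repositioning, or biophysical hemodynamics
(no balloon/Windkessel model). Passing the validation suite therefore
shows that the *analysis chain* is correct and recovers known truth; it
does not certify reliability magnitudes for any particular instrument.

## Preprocessing choices

* **Band-pass.** The filter family and order are a package choice: 4th
  order Butterworth, applied forward-backward (zero phase). At 25 Hz
  sampling the 0.009–0.08 Hz band is so narrow relative to Nyquist that a
  directly designed band-pass is numerically unstable in transfer-function
  form, so the pass band is realised as a stable cascade of a high-pass at
  0.009 Hz and a low-pass at 0.08 Hz after per-channel mean removal
  (which also makes the DC response exactly zero). Verified passband gain
  at 0.04 Hz is within 0.1% of unity; a 1 Hz tone is attenuated by >99.9%.
* **Initial discard.** `discard_initial()` drops `round(seconds * fs)`
  samples; the default pipeline records 660 s and discards 60 s, leaving
  the canonical 15,000 samples.
* **MBLL.** `mbll_convert()` inverts the 2x2 extinction system per channel
  with shipped defaults (Gratzer/Kollias coefficients at 690/830 nm,
  source-detector separation 3.2 cm, DPF 6.0 at both wavelengths). These
  constants set the concentration scale only; Pearson networks are
  invariant to per-channel affine maps, so their exact values never affect
  the reliability results.

## ICA denoising

`ica_decompose()` runs fixed-point deflation ICA on PCA-whitened data,
keeping the minimal number of principal components that retain >99% of
variance and extracting as many independent components. The default
contrast is skewness (`g(u) = u^2`), suited to asymmetric artifacts; on
nearly symmetric sources the iteration may report non-convergence, in
which case the partial decomposition is returned with a warning rather
than failing the run. A component is flagged as noise when **any** of
three criteria fires:

| criterion | statistic | default threshold |
|---|---|---|
| temporal anomaly | max robust z of first differences; count of distinct excursions beyond 5 robust SD | jump_z = 6; >= 10 spike events |
| spectral | dominant Welch-spectrum frequency (segments of <= 4096 samples, 50% overlap, Hann) | outside 0.01–0.1 Hz |
| spatial dispersiveness | participation ratio of the mixing column | > 0.7 x channel count |

Published descriptions of such components are partly visual
("slowly-varied U-shaped spike", "global and spatially dispersive"), so
these quantitative stand-ins are explicit and tunable rather than baked
in. Reconstruction zeroes the flagged mixing-matrix columns and restores
channel means; with no flags it reproduces the PCA-retained data exactly.
The pipeline's ICA arm runs ICA on the raw series and band-passes
afterwards; the order is configurable.

## Network and metric conventions

Degenerate inputs at the sparse and dense ends of the sweep force
conventions, all chosen to keep curves defined and all switchable or
reported:

* Edge ranking uses signed `r` (positive correlations enter first);
  `absolute = TRUE` ranks by `|r|`. `K` uses round-half-away-from-zero and
  ties break by (row, col) order, making every sweep deterministic and
  nested.
* A constant channel is a hard error (it indicates a dead channel or a
  degenerate configuration), not a silent `NA`.
* Clustering of a degree-<2 node is 0, keeping `Cp` defined at sparse
  thresholds (`exclude_low_degree = TRUE` averages over eligible nodes
  instead).
* `Lp` averages over *reachable* pairs only — the sparse end of the sweep
  is always disconnected and the curve must stay finite; efficiencies give
  disconnected pairs 0.
* Betweenness is the raw Brandes count over unordered pairs (no endpoint
  normalisation); a normalised variant is available.
* Modularity is optimised by deterministic greedy agglomeration (merge the
  connected pair with the largest gain, lexicographic tie-break, best
  partition along the full merge path). Determinism matters more than the
  last decimal of `Q` here: a stochastic optimiser would inject spurious
  within-subject variance straight into the ICC.
* `beta` (slope of log C against log k) and `r` (edge-endpoint degree
  correlation) are `NA` when their regressions are degenerate (regular
  graphs, all-zero clustering); missing values propagate as missing, never
  as zero, and AUC integration shrinks its range or bridges interior gaps
  by single trapezoids.
* `sigma` is always computed as `gamma/lambda` from the same null
  ensemble.

## Null models

Two randomization schemes normalise `Cp` and `Lp`:

* **Topology rewiring** (`rewire_null()`): Maslov–Sneppen double-edge
  swaps preserving the degree sequence exactly, 100 nulls with 100
  attempted swaps per edge by default (the counts are conventional; no
  canonical values exist). Complete graphs admit no swaps and are returned
  unchanged with a warning.
* **Correlation-matrix randomization** (`correlation_null()`): random
  correlation matrices matching the observed off-diagonal mean and
  variance (factor matrices with normal entries, `m` factors from the
  variance equation with the diagonal targeted at 1, then unit-diagonal
  normalisation). Because that normalisation slightly distorts the
  moments, the targets are recalibrated once against a 100-matrix pilot
  ensemble; in the realistic regime (mean r 0.3–0.4) the final moments
  track the observed ones within ~2%. Thresholding these nulls exactly
  like real matrices preserves the transitive structure that correlation
  networks inherit, which pure topology rewiring destroys — the reason the
  normalised small-world metrics are much more stable under this null.
  A non-positive off-diagonal mean is infeasible for this construction and
  raises an error.

Null generation consumes seeds derived per (subject, session, stage)
through `derive_seed()`, so full pipeline reruns are bit-identical.

## Statistical tests downstream of the ICC

Paired t-tests compare per-subject AUCs between sessions for every global
metric (all differences exactly zero is reported as `t = 0, p = 1`). The
two-factor repeated-measures ANOVA on nodal AUC-ICCs (factors: metric
type and signal type, nodes as observational units) uses the standard
within-unit sums-of-squares decomposition, each main effect tested against
its unit-by-factor interaction; no sphericity correction is applied, and
all p-values are reported unadjusted for multiplicity — both stated
limitations, matching common practice for this design.

## Problem sizes used in the validation suite

The shipped tests exercise the full 99-point grid and 46-channel
combinatorics where the quantities are forced (edge counts, nestedness),
and scale the stochastic checks to sizes where the Monte-Carlo error is
far below the tolerance being asserted: 100 nulls on 100-node graphs for
self-normalisation (`gamma`, `lambda`, `sigma` within 1 ± 0.1), 100
simulated 1000x2 tables per planted level for ICC recovery (±0.02), and a
200-subject, 46-channel cohort at full recording length for end-to-end
recovery of a planted 0.7 (±0.05), generated subject-by-subject so the
raw series never need to be held in memory together.

## Known limitations

* ICC(1,1) only; two-way forms (rater-fixed designs) are out of scope.
* Weighted networks, partial-correlation and coherence connectivity are
  not implemented; reliability operates on raw Pearson `r` without Fisher
  transformation.
* The correlation-randomization null requires a positive mean
  off-diagonal correlation.
* The ICA noise criteria are heuristics with fixed defaults; on data
  whose artifacts are symmetric and in-band they will under-flag.
* Reliability magnitudes measured on synthetic cohorts transfer to real
  instruments only to the extent the generator's noise structure does.
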