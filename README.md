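# netrel

Test–retest reliability of graph metrics in channel-space functional brain
networks, for resting-state fNIRS-style hemoglobin recordings.

## The problem

Resting-state fNIRS measures spontaneous fluctuations of oxygenated (HbO),
deoxygenated (HbR) and total (HbT = HbO + HbR) hemoglobin at a set of
optode channels. Correlating every channel pair yields a functional
connectivity network whose graph-theoretical summaries — small-world
indices, efficiencies, modularity, nodal centralities — are candidate
biomarkers. Before such metrics can be used longitudinally, their
test–retest reliability must be quantified: if the same subject is scanned
twice, how much of the variance in a metric is stable between-subject
signal rather than within-subject noise?

`netrel` implements that whole analysis as a reusable pipeline:

1. **Synthetic data** — a generator producing two-session, multi-subject
   hemoglobin time series with a *planted* reliability level, band-limited
   neural sources (0.009–0.08 Hz), physiological confounds (cardiac ~1 Hz,
   respiratory ~0.3 Hz, Mayer ~0.1 Hz), instrument noise and optional
   motion/interference artifacts.
2. **Preprocessing** — modified Beer–Lambert conversion, initial-sample
   discard, zero-phase Butterworth band-pass, and ICA-based denoising with
   three explicit noise-component criteria (temporal anomalies,
   out-of-band spectra, spatially dispersive mixing).
3. **Network construction** — Pearson correlation matrices, binarized
   across a sparsity sweep (0.01…0.99, step 0.01) by retaining the
   `K = round(S·n(n−1)/2)` strongest edges.
4. **Graph metrics** — clustering coefficient `Cp`, characteristic path
   length `Lp`, local/global efficiency, modularity `Q`, hierarchy `β`,
   assortativity `r`, nodal degree/efficiency/betweenness, and the
   null-normalised `γ = Cp/Cp_null`, `λ = Lp/Lp_null`, `σ = γ/λ` with
   degree-preserving rewiring or correlation-matrix randomization nulls.
5. **Reliability** — the one-way random-effects intraclass correlation

       ICC = (MS_b − MS_w) / (MS_b + (k − 1)·MS_w)

   per edge, per metric and per sparsity threshold, clamped at 0, graded
   (poor/low/fair/good/excellent), and summarised threshold-independently
   by the area under each metric-versus-sparsity curve (AUC), plus
   session-similarity correlations, strength–reliability correlation,
   paired session t-tests, and a two-factor repeated-measures ANOVA over
   metric and signal types.

## A worked example

```r
library(netrel)

cfg <- netrel_config(
  generator = generator_config(n_subjects = 6, n_channels = 12, fs = 25,
                               duration = 240, icc_target = 0.7, seed = 1),
  signals = "HbO", discard_seconds = 20,
  grid = sparsity_grid(0.1, 0.9, 0.1),
  global = c("Cp", "Lp", "Eglob"), nodal = "degree",
  seed = 1)
run <- run_pipeline(cfg)
run
#> <netrel_run> 6 subjects, 12 channels, signals: HbO
#>   HbO: mean edge ICC 0.64 +/- 0.24 over 66 connections
#>   1 warning(s); see $report$warnings

icc(cbind(c(1, 2, 3), c(2, 3, 4)))
#> ICC(1,1) = 0.6000 (good reliability)
#>   MS_between = 2 (df 2), MS_within = 0.5 (df 3), k = 2
```

The edge summary says that, of the 66 channel-pair correlations, the
average fraction of variance attributable to stable between-subject
differences is 0.64 — close to the generator's planted level of 0.7 (the
shortfall is the sampling noise of correlation estimates from a short
4-minute recording, which counts as within-subject variance; the reported
warning lists the edges whose ICC was clamped at 0). The printed
ICC object shows the underlying ANOVA mean squares: `(2 − 0.5)/(2 + 0.5)
= 0.6`, graded "good" (0.6 ≤ ICC < 0.75).

A command-line front end over the same functions is shipped at
`inst/scripts/netrel.R` (`run`, `simulate`, `metrics`, `icc` subcommands).

## Vignette

`vignettes/network-reliability.Rmd` documents the model assumptions, the
planted-reliability construction, all tunable thresholds and the numerical
choices (filter cascade, tie-breaking, degenerate-input conventions), and
what the synthetic validation does and does not show about real
recordings.
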