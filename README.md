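# srmeeg

Event-related EEG analysis of **self-referential processing**: evoked
alpha-band power, phase-lag-index (PLI) functional connectivity, and
graph-theoretic brain-network topology, compared between a control and
a patient group across the three encoding conditions of a
self-referential memory (SRM) task (*self*, *other*, *physical*).

The package targets studies in which each subject contributes
event-locked multichannel epochs (by default 59 channels at 500 Hz,
−300 to +800 ms around stimulus onset, 70 trials per condition) plus a
recognition-memory behavioral record. Because such patient recordings
are rarely shareable, the package ships a deterministic
**synthetic-cohort generator** with the same statistical structure —
1/f background noise, a phase-locked alpha burst whose amplitude
differs by group × condition, lag-consistent inter-channel coupling on
a posterior edge set, and binomial recognition counts — so the whole
pipeline is testable end to end and every planted effect size is known.

## Methods at a glance

* **Evoked power** — trials are averaged first, then transformed with
  complex Morlet wavelets (f₀/σ_f = 7; f₀ = 0.1–30 Hz in 0.5 Hz
  steps), so only activity phase-locked to stimulus onset survives:
  P(c, f, t) = |x̄(c, ·) ∗ ψ_f|²(t). Band × window summaries use the
  alpha band (8–13 Hz) and 200 ms windows from −200 to 600 ms.
* **PLI connectivity** — epochs are band-passed to 8–13 Hz
  (zero-phase order-4 Butterworth response), instantaneous phase comes
  from the Hilbert analytic signal (first/last 100 ms trimmed), and
  for each electrode pair (i, j):

  PLI_ij(t) = | (1/N) Σ_{n=1..N} sign(Δφ_ij(t, n)) |,

  with Δφ wrapped to (−π, π] and sign(0) = 0 — so exactly zero-lag
  (volume-conduction-like) coupling contributes nothing.
* **Network topology** — the 100–300 ms window-averaged PLI matrix is
  binarized by proportional threshold (sparsity S = 0.1–0.5, step
  0.05) and summarized by global efficiency, characteristic path
  length and nodal efficiency, each aggregated as area under the
  sparsity curve.
* **Behavior** — recognition score = hit rate − false-alarm rate per
  condition; SRM bias = recognition(self) − recognition(other).
* **Statistics** — mixed-design (group × condition) ANOVA, pooled
  two-sample t-tests, Pearson correlation, simple linear regression,
  Bonferroni correction.

## Worked example

```r
library(srmeeg)

sim <- sim_config(n_per_group = 18, n_channels = 6, n_trials = 70,
                  seed = 1)           # generator defaults plant the
                                      # patient self-condition deficits
cfg <- pipeline_config(sim = sim,
                       tf_grid = seq(8.1, 12.6, by = 0.5),
                       power_windows = list(c(100, 300)),
                       edge_tests = FALSE)
r <- run_pipeline(cfg)
r
#> <srm_report> 36 subjects | config 0e5c8b47 | seed 1
#>   SRM bias group t: t = 1.47, p = 0.15
#>   self-condition PLI group t: t = 21.97, p = 1.147e-21

subset(r$pli_group_t, condition == "self")
#>   condition statistic df            p    effect
#> 1      self  21.96661 34 1.146661e-21 0.1757111
subset(r$network_stats, metric == "e_global_auc")
#>         metric condition statistic df            p      effect
#> 1 e_global_auc      self -8.905992 34 2.077702e-10 -0.03519753
```

The patient group's mean self-condition PLI strength is ~0.18 lower
(t₃₄ ≈ 22 on the planted posterior-coupling deficit), and patients'
thresholded networks are *more* globally efficient (negative
control−patient effect): with the posterior clique degraded, the same
edge budget spreads over more dispersed pairs. The behavioral SRM
contrast (planted bias 0.14 vs 0.03 against a per-subject binomial
noise SD of ~0.14) has modest power at n = 18 and does not reach
significance on this seed — a property of the design, not of the
pipeline.

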