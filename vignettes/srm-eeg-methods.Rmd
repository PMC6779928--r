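---
title: "Evoked alpha power, PLI connectivity and network topology for self-referential memory EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evoked alpha power, PLI connectivity and network topology for self-referential memory EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmeeg)
```

## The analysis problem

Self-referential memory (SRM) paradigms compare how deeply adjectives
are encoded when judged relative to oneself, to another person, or to
a physical property. In clinical EEG studies of self-referential
processing the quantities of interest are (i) the **evoked
(phase-locked) alpha-band response** shortly after stimulus onset,
(ii) **phase-synchronization connectivity** between electrodes,
quantified by the phase lag index, (iii) **graph-theoretic topology**
of the resulting connectivity networks, and (iv) the **behavioral SRM
bias**, all compared between a patient and a control group across the
three encoding conditions.

`srmeeg` implements that full chain, plus a synthetic-cohort generator
that reproduces the statistical structure such data are assumed to
have. Because the generator's ground truth is known exactly, every
stage can be validated by parameter recovery instead of by eyeballing.

## Generative model of the synthetic cohort

For each subject, group `g`, condition `c` and trial `n`, the epoch
(channel × 550 samples at 500 Hz, −300 to +800 ms) is

```
x(ch, t, n) = noise(ch, t, n) + burst(t, n) + coupling(ch, t, n)
```

* **Background noise** is 1/f ("pink", exponent 1) with RMS 5 µV,
  synthesized in the frequency domain. Real EEG spectra are
  approximately 1/f, so band-pass filters and wavelets are exercised
  against a realistic spectral tilt rather than white noise.
* **Evoked burst**: a Gaussian-windowed 10 Hz sinusoid centered at
  200 ms (σ = 50 ms, i.e. effectively confined to 100–300 ms) with a
  phase that is fixed within subject. Phase constancy across trials is
  what makes the component *evoked*: it survives trial averaging. A
  per-trial phase-jitter parameter (0 to π) exists to demonstrate
  evoked-power cancellation; at full jitter the average retains ~1/N
  of the locked power. Amplitude is `burst_amp[g, c]` times a
  per-subject log-normal factor (σ_log = 0.2, a typical
  between-subject amplitude variability), which doubles as the subject
  random effect the mixed ANOVA assumes.
* **Lag-consistent coupling**: every connected component of the
  configured edge set shares one alpha source per trial with a *random*
  phase (so coupling is invisible to evoked power) and an envelope
  matching the burst window. Within a component, channel k receives
  the source delayed by `k · lag_ms · s_n`, where the common sign
  `s_n = +1` with probability `p = coupling_consistency[g, c]` and −1
  otherwise. Each coupled pair therefore has phase-difference sign
  `s_n`, and the window-averaged PLI is `|2B/N − 1|` with
  `B ~ Binomial(N, p)` — a closed-form target (`expected_pli()`)
  that the estimator must reproduce. The default edge set is the
  6-pair clique on a posterior cluster (P3/P4/O1/O2 on the 59-channel
  montage), where alpha-band connectivity effects are expected.
* **Behavior**: hits ~ Binomial(70, p_hit[g, c]) and false alarms ~
  Binomial(30, p_fa[g, c]).

### Default study conditions

The defaults encode the two-group, three-condition design of the
paradigm: 18 subjects per group, 70 trials per condition, 59 channels.
The planted contrasts are confined to the **self** condition of the
**patient** group:

| parameter | control | patient (self) | rationale |
|---|---|---|---|
| burst amplitude (µV) | 2.0 everywhere | 1.4 (−30 %) | evoked-alpha deficit |
| coupling consistency | 0.9 everywhere | 0.55 | near-abolished lag consistency |
| p_hit (self/other/physical) | .79 / .65 / .65 | .66 / .63 / .65 | recognition ≈ .49/.35/.35 vs .36/.33/.35 at p_fa = 0.30 |

The hit/false-alarm rates were chosen once so the *expected*
recognition scores and SRM bias (0.14 vs 0.03) match the magnitudes
typical of this paradigm; they are not tuned thereafter. Reaction
times are drawn per condition from normal distributions (self ≈ 999 ms,
other ≈ 1033 ms, physical ≈ 631 ms) but play no further analytic role.

Seeds derive deterministically from the master seed, the subject label
and the condition (`hash(seed, subject, condition)`), so cohorts
regenerate bit-identically, subjects can be generated independently in
any order, and the subject-level stream (amplitude factor, burst
phase) is shared across that subject's conditions.

## Preprocessing

* **Band-pass**: the filter is the squared-magnitude response of an
  order-4 analog Butterworth band-pass applied in the frequency domain
  on reflection-padded epochs. This realizes exactly the zero-phase
  magnitude response of a forward–backward (filtfilt) order-4
  Butterworth pass — zero phase is essential because any filter delay
  would bias the Hilbert phases — while vectorizing over all channels
  and trials; a unit test checks agreement with `signal::filtfilt`
  away from epoch edges. Broadband filtering twice attenuates
  transition-band shoulders (finite order), so idempotency holds for
  in-band content only.
* **Re-referencing** to the averaged mastoids subtracts the mastoid
  mean and drops those channels; the synthetic montage has no
  mastoids, so the pipeline default is `none`.
* **Epoching** cuts half-open `[−300, 800)` ms windows (550 samples;
  sample 151 is stimulus onset); out-of-bounds events are rejected and
  counted.
* **Spectral distortion** `|ΔP| = Σ_f |P_recon − P_raw|` (trial-averaged
  periodogram PSD, 0.1–30 Hz) quantifies how much an artifact-removal
  reconstruction distorts spectra. The decomposition itself is out of
  scope — synthetic data are artifact-free — but the metric accepts any
  (raw, reconstructed) pair so real-data users can plug in their own
  ICA.

## Evoked power

Wavelets are L2-normalized complex Morlets with `f0/sigma_f = 7`;
`evoked_power()` transforms the *trial average* (average first, then
transform), which by construction captures only time- and phase-locked
activity. L2 normalization makes power scale exactly quadratically
with amplitude, which the tests exploit. At 0.1 Hz the wavelet's
temporal support (σ_t ≈ 11 s) vastly exceeds the 1.1 s epoch: cells
within 2σ_t of an epoch edge are computed but masked, and every
aggregate (`band_window_mean`) is defined over unmasked cells only — a
fully-masked selection is an error, and the pipeline records such
band × window combinations as `NA`. No baseline correction is applied;
raw evoked power is compared between groups. Windows are half-open in
ms, so the 100–300 ms window covers exactly 100 samples at 500 Hz.

One transient-signal subtlety: for a short burst (envelope σ = 50 ms,
briefer than the 10 Hz wavelet's σ_t ≈ 111 ms), the instantaneous
power peak sits slightly *above* the carrier frequency, because
higher-frequency wavelets in a constant-Q family are shorter and
concentrate a transient better. The window-averaged spectrum, which
is what the band × window statistics consume, peaks at the carrier to
within one grid step.

## PLI connectivity

Instantaneous phase is the argument of the FFT-based analytic signal
of the alpha-filtered epochs; the first and last 100 ms (50 samples)
are flagged invalid because the transform is unreliable there. For
each pair and valid sample,

PLI(t) = |mean over trials of sign(Δφ(t))|,

with Δφ wrapped to (−π, π] before the sign and **sign(0) = 0** — the
mathematical convention that makes an exactly zero-lag common source
(the volume-conduction signature) contribute nothing; a scaled copy of
a channel yields PLI = 0 identically. The vectorized implementation
uses sign(Im z_i z̄_j), which equals the sign of the wrapped phase
difference for any positive amplitudes and is verified bit-exactly
against a naive per-trial loop. The active window is 100–300 ms
post-stimulus; the baseline window is −200–0 ms (the −300 to −200 ms
span is inside the trimmed edge anyway). Edgewise active-vs-baseline
maps use an independent-samples t-test across subjects as reported in
this literature, with a paired variant behind a flag (`paired = TRUE`)
since pairing is statistically the more natural choice; the display
threshold is p < 0.001 uncorrected with Bonferroni-adjusted p also
returned.

For efficiency the pipeline fuses the alpha band-pass and the analytic
transform into one padded FFT round (`band_analytic_phase()`,
gain × analytic weights), and `pli_timeseries()` can restrict
computation to the samples of the windows actually consumed. Both
shortcuts are tested for equivalence against the composed operators.

## Network topology

The window-averaged PLI matrix is binarized by **proportional
thresholding**: keep the top `round(S · n(n−1)/2)` edges, ties broken
by fixed lexicographic pair order so results are deterministic. The
sweep runs S = 0.1–0.5 in steps of 0.05 and each metric is aggregated
as trapezoidal area under its sparsity curve — the standard usage of
global-threshold network analysis when no single sparsity is
privileged. Graphs are binary; weighted variants are out of scope.

Distances are unweighted shortest paths (BFS via `igraph`).
Conventions for disconnected pairs differ by metric and are chosen so
that mean(nodal efficiency) = global efficiency holds as an exact
identity: efficiency uses 1/∞ = 0, characteristic path length averages
only finite distances and reports the number of excluded pairs. All
three metrics are verified exactly against a brute-force
Floyd–Warshall oracle on a thousand random graphs, including
disconnected ones.

### Why the planted network contrast has its sign

The generator does not plant a network metric directly — it plants
*clustered* strong coupling (a posterior clique) in controls and
degrades its lag consistency in patients. At a fixed edge budget,
control networks spend ~6 edges on a redundant 4-node clique (3 would
connect it), leaving the rest of the graph sparser; patient networks,
whose coupled edges sink toward the noise floor, spread the same
budget over noise-ranked, more dispersed pairs. Dispersed edges
shorten paths between otherwise distant nodes, so patient global
efficiency (AUC) is *higher* — the sign recorded in
`ground_truth$network_contrast` and required of the recovery tests.
This is an emergent consequence of thresholding, not an assumption;
characteristic path length over *connected* pairs is not similarly
determined (a clique yields many distance-1 pairs), which is why the
declared contrast is the global-efficiency AUC.

## Statistics

The mixed-design ANOVA uses classical split-plot sums of squares
(`aov` with `Error(subject/condition)`), no sphericity correction, and
flags F-ratios whose error mean square is numerically zero. The
two-sample t-test is pooled-variance Student (df = n₁ + n₂ − 2,
matching the df = 34 convention for 18 + 18 subjects), Pearson r gets
its t-based two-tailed p, regression is ordinary least squares with
R² = r² exactly, and Bonferroni is min(1, m·p). A from-scratch
sums-of-squares oracle and closed-form t/p formulas back the tests;
under planted nulls all p-values are checked for uniformity.

## What the tests do and do not show

The simulation reproduces the features the analysis depends on —
spectral tilt, phase-locked versus non-phase-locked components,
lag-consistent coupling with a known sign-consistency, binomial
behavioral counts, subject-level amplitude heterogeneity — but not
artifacts (blinks, muscle), volume-conduction mixing beyond the
zero-lag fixture, nonstationary background rhythms, or electrode-level
spatial correlation of noise. Passing recovery tests therefore
demonstrates correctness of the estimators and the statistical chain
under the assumed generative model, not robustness of the science to
real-world artifacts.

Problem sizes used by the validation suite were chosen to keep full
runs tractable while preserving the design quantities that drive the
statistics: recovery runs keep the 18 + 18 subjects and 70 trials of
the paradigm but use a 6-channel montage (coupling clique on the last
4 channels), and type-I calibration uses 500 null cohorts of 8–12
subjects per group, 4–6 channels and 12–16 trials — the rejection rate
of a calibrated test does not depend on montage size, and the cohort
sizes were piloted so each battery operates at its asymptotic level
(the mixed-ANOVA F tail needs ~12 subjects per group; the t batteries
are nominal at 8). The correlation-
recovery regime (r = 0.6 at n = 18) operates on subject-level summary
pairs from `gen_correlated_scores()`, since its question — attenuation
and sampling spread of r at small n — lives entirely at the subject
summary level.

## Numerical choices and edge cases

* Butterworth gain is evaluated analytically (no coefficient
  round-off at a 0.1 Hz edge on a 500 Hz grid); reflection padding is
  128–256 samples.
* The Hilbert construction uses the standard FFT half-spectrum
  weights; trimming is exactly `round(0.1 · fs)` samples per edge.
* Morlet kernels are truncated at ±4σ_t (capped at the epoch length)
  and convolved via FFT with power-of-small-primes padding.
* Ties in sparsity thresholding and in seed derivation are fully
  deterministic; all RNG flows through one master seed.
* Degenerate inputs (zero variance, fully masked selections, empty
  windows, graphs without edges) raise errors or flags rather than
  returning silent numbers.

## Interface notes

The package's surface is its R functions; the end-to-end entry point
is `pipeline_config()` + `run_pipeline()`, which stream subjects
(regenerating epochs from their seeds) so memory stays flat in cohort
size, tag every artifact with a configuration hash and the seed, and
write CSV/JSON reports when an output directory is set. Fixtures
travel as a documented plain-text container (`write_epochs()` /
`read_epochs()`: a TSV tensor plus a JSON sidecar). Reading vendor EEG
formats (BrainVision, EDF) is intentionally out of scope here; epochs
can be assembled from any source via `eeg_epochs()` or `segment()`.

## Known limitations

* The evoked-power and PLI pathways share the alpha burst as a
  zero-lag common component; with realistic noise this attenuates PLI
  on coupled edges below the exact binomial expectation (sign flips
  near phase crossings). Estimator-exactness tests therefore use
  coupling-isolation configurations (no burst, no noise); cohort-level
  group contrasts are unaffected since the attenuation is common to
  both groups.
* The mixed ANOVA applies no sphericity correction, matching the
  reporting convention it mirrors; with three conditions and planted
  compound-symmetric subject effects this is exact in expectation.
* Binary proportional thresholding discards PLI magnitude information
  below the cutoff; weighted network metrics are not implemented.
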