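---
title: "thermoHb: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thermoHb: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside thermoHb: the measurement model,
the synthetic cohort generator, the statistical layer, the numerical
choices, and the places where the design was genuinely open and a choice had
to be made.

## The measurement model

fNIRS measures light attenuation through the scalp at two wavelengths
(760 and 850 nm here, 3.91 Hz sampling). Attenuation changes relate to
oxy-/deoxyhemoglobin concentration changes through the modified
Beer–Lambert law (MBLL),

$$\Delta OD_\lambda(t) = L \cdot DPF_\lambda
  \left(\varepsilon_{\lambda,HbO}\,\Delta HbO(t) +
        \varepsilon_{\lambda,HbR}\,\Delta HbR(t)\right),$$

with $L$ the source–detector separation (3 cm) and $DPF_\lambda$ the
differential pathlength factor (7.25 at 760 nm, 6.38 at 850 nm) correcting
geometric distance for photon scattering. Per time point this is a 2×2
linear system solved by `mbll()`. The device tabulation this study follows
reports concentrations on an mM-labelled scale; the extinction constants
shipped in `extinctionDefaults()` (derived from the standard compiled
in-vitro tabulation) fold the molar-scale conversion in so that outputs
land on that scale. They are plain arguments and can be overridden.

Two conventions deserve a note:

* **Reference intensity.** `toOpticalDensity()` references each channel to
  its full-recording mean intensity, the common convention when the true
  source intensity is unknown. This leaves an arbitrary per-channel DC
  level in the concentrations; it is irrelevant downstream because every
  feature subtracts the pre-stimulus baseline. When the source intensity
  *is* known (as in a synthesis round trip), passing `reference =` makes
  the conversion the exact inverse of `inverseMbllEncode()`, and the round
  trip is accurate to better than 1e-9 mM.
* **Filtering.** The analysis band is 0.01–0.2 Hz, realized as a
  forward–backward (zero-phase) Butterworth filter of order 3 per pass.
  Zero-phase filtering is standard fNIRS practice because it does not shift
  peaks, which protects latency estimates. The series mean is removed
  before filtering to avoid the step transient a DC level would leave at
  the record edges.

## Quality control

Channels are screened on the *raw* intensities, before filtering, using the
coefficient of variation CV = 100·SD/mean per channel and wavelength
(sample SD, n−1). A channel is rejected when either wavelength's CV
*strictly* exceeds 7.5 % — the rule's wording ("exceeded") is read as a
strict inequality, so a CV of exactly 7.5 % is retained — or when its CV is
undefined (non-positive mean). Computing CV after filtering would be
meaningless: the band-pass removes precisely the variance the rule is meant
to catch. CV is computed on whole recordings (whether the original protocol
used per-trial segments is not stated; whole-recording is the simpler and
adopted reading).

## Features

Per ROI (left/right PFC, left/right MC; fixed channel groups with channels
9 and 12 shared by both PFC ROIs) and per thermal stimulus:

* baseline — mean HbO over the half-open 30 s window before the *primary*
  onset (shared by both stimuli);
* peak latency — time of the HbO maximum in the search window, earliest
  sample on ties (flagged), boundary flag when the maximum is the window's
  last sample;
* Δ-HbO — window maximum minus baseline;
* Δ-HbO\* — mean over the 15 s after stimulus end minus baseline, sign
  retained (an instantaneous single-sample variant is available via
  `starMethod = "instant"`; the mean is the default because a single sample
  at 3.91 Hz is fragile).

**Peak search window.** The peak is searched within the stimulation period
(`[onset, onset + duration]`), with a configurable extension
(`peakWindowExtension`, default 0 s). The choice matters: if the window is
extended to cover the post-stimulus window, the maximum over the enclosing
window can never be smaller than the mean over the enclosed one, i.e.
Δ-HbO ≥ Δ-HbO\* becomes a mathematical identity — yet the group summaries
this generator is calibrated to contain a cell (controls, left PFC, 5 °C)
whose mean Δ-HbO\* exceeds its mean Δ-HbO. Confining the search to the
stimulation period, which also matches the description of the measure as
the amplitude maximum *of the thermal stimulus*, decouples the two measures
and makes every configured cell generable. Setting
`peakWindowExtension = 15` restores the enclosing-window variant.

## The synthetic cohort generator

No subject-level recordings from the study are available, so the generator
is the package's test bed. It emulates, per subject:

1. **Paradigm** — 60 s rest, 30 s baseline, immersion at 25 °C then 5 °C
   with 2 min between, 15 s post-stimulus windows. Patients withdraw at
   first pain: immersion duration is drawn uniformly from [10, 30] s per
   trial; controls complete 30 s. (The true per-subject durations were not
   reported; the uniform range is a stand-in.)
2. **Response targets** — per ROI × temperature, the triple (peak latency,
   Δ-HbO, Δ-HbO\*) is drawn from normal distributions whose means are the
   study's group summaries and whose SDs are reconstructed as SE·√n from
   the reported standard errors (n = 22 patients, 19 controls) — the only
   defensible reconstruction from group summaries, frozen at those n even
   when larger cohorts are simulated. The two amplitude measures of one
   curve are drawn with latent correlation 0.9 (they measure the same
   response). Feasibility bounds, applied per draw: latency inside
   [0.5 s, duration − 0.3 s]; amplitude floored at 0.05 mM (a response
   needs a measurable positive peak for its latency to be defined);
   Δ-HbO\* bounded to [−3·Δ-HbO, 2·Δ-HbO] (outside that range the
   band-pass smears or rings the offset response above the in-stimulus
   maximum, making the peak location ill-defined). Because the
   reconstructed SDs are large relative to the means, these bounds bite for
   a minority of draws and shift some cell means by up to a few hundredths
   of an mM relative to the configured values; the recorded truth (below)
   accounts for this exactly.
3. **Response shape** — a gamma-variate transient peaking at the drawn
   latency with the drawn amplitude, plus a smooth post-offset response: a
   flat-topped bump starting 1 s after immersion ends and spanning the
   post-stimulus window, whose level is solved (linearly, on the sampled
   grid) so the sampled post-window mean equals the drawn Δ-HbO\*. The
   offset component is compact (~25 s), so its spectral content lies inside
   the 0.01–0.2 Hz band and survives filtering; post-offset responses to
   cold-pressor withdrawal are physiologically documented. A single
   monotone-decay kernel (`kernel = "monotone"`: gamma rise, exponential
   return-to-baseline with the time constant solved for Δ-HbO\*) is also
   provided; it raises a constraint error when the requested Δ-HbO\* is
   infeasible, and — important for interpretation — it cannot reproduce
   high Δ-HbO\*/Δ-HbO ratios once the 0.01 Hz high-pass is applied, because
   a sustained plateau loses most of its post-window mean to the high-pass
   edge. That attenuation is why the offset kernel is the default.
4. **Band calibration** — `generateCohort()` pre-compensates each ROI's
   kernel parameters through the analysis band-pass by fixed-point
   iteration (≤ 25 iterations; amplitudes converge to ~1e-5 typically,
   latency to the sample grid; the best iterate is kept, judged by
   amplitude error plus any latency error beyond one sample). Direct
   `simulateSubjectHbo()` output (`band = NULL`) hits the targets exactly
   without calibration.
5. **Recorded truth** — the cohort's `truth` table holds the features the
   analysis chain extracts from the *noiseless*, band-passed ROI averages.
   This equals the drawn targets whenever calibration converges (the norm)
   and differs only for near-degenerate draws and through the PFC overlap
   channels (9 and 12 carry the mean of both PFC responses, so a PFC ROI
   average is a 10:1 blend of its own and the contralateral response).
   Parameter recovery in the test-suite compares pipeline output against
   this truth: it is a measurement-chain test, with the sampler's
   documented clamping handled exactly.
6. **Noise** — per channel: cardiac (~1.2 Hz, 0.008 mM), respiratory
   (~0.25 Hz, 0.012 mM) and Mayer-wave (~0.095 Hz, 0.01 mM) sinusoids with
   random phase and 5 % frequency jitter, white noise (SD 0.02 mM), and a
   linear drift with slope drawn from N(0, 2e-4 mM/s). Amplitudes are
   ordinary for concentration-scale fNIRS simulation; the Mayer component
   matters most because it is in-band and controls how far noise can move
   the argmax along the broad filtered peak. HbR is modelled as −HbO/3
   with its own small noise — the MBLL needs two chromophores, but HbR is
   not analysed.
7. **Artifacts** — each channel is corrupted with probability 0.05 by a
   multiplicative gain ramp tuned (by root finding) to push its intensity
   CV to ~12 %, exercising the QC rule end to end.
8. **Clinical scores** — disability due to pain (0–91) and central
   sensitization (0–100) are drawn through a Gaussian copula tied to the
   latent Δ-HbO\* of the left PFC at 5 °C, with rank correlations 0.40 and
   0.60 respectively and 0.64 between the scores (Pearson latents via
   r = 2·sin(πρ/6)); marginals use the reported group means/SDs, rounded
   to integers and clipped to the instruments' ranges.

What the generator does **not** emulate: photon transport or head geometry,
scalp coupling and short-separation channels, HbR dynamics beyond the −1/3
ratio, non-stationary noise, serially correlated artifacts, or any
systematic group difference other than the configured response parameters
and scores. Passing recovery tests therefore show that the pipeline
measures what was injected under realistic noise — not that the pipeline
would behave identically on real scalp data.

## The statistical layer

* **Cohort characterization** — Mann–Whitney U (tie-corrected, normal
  approximation) for continuous variables, Fisher's exact test for
  categorical ones.
* **GEE** — one marginal linear model per ROI and outcome:
  `y ~ group * temperature`, cluster = subject (two observations each),
  exchangeable working correlation estimated by moments (with a
  degrees-of-freedom correction), robust sandwich covariance, Wald χ²
  (df 1) per effect. With the independence working structure the estimator
  reduces exactly to OLS with cluster-robust (CR0) covariance, which the
  test-suite verifies against an independent implementation. Cramér's V is
  computed from the Wald χ² with the number of subjects in the model,
  V = √(χ²/n) — the convention that reproduces the study's printed worked
  values. An optional Bonferroni flag over the four ROIs is available in
  the report layer; both raw and adjusted p-values are reported because the
  original correction family is not stated.
* **Severity models** — Spearman correlations (ties mid-ranked, two-tailed
  p, flagged at 0.05/0.01), and per clinical score a linear model on the
  left- and right-PFC Δ-HbO\* with Wald χ² and normal-theory 95 % CIs
  (matching how such coefficients are conventionally tabulated). An exactly
  constant outcome is reported as Wald 0, p 1 (no evidence of association)
  rather than 0/0.
* **Sample size** — smallest N with noncentral-F power ≥ 0.80 at α = 0.05
  for the 2-predictor omnibus test, λ = f²·N, then +10 % for attrition.
  The published computation's "effect size of 0.6" is ambiguous between
  Cohen's f and f²; both are selectable (`type =`), and the f²
  interpretation reproduces the published base/inflated sizes (20 → 22).
* **ROC screening** — empirical ROC at every attained score value
  (cutoffs are reported at attained values, matching how such cutoff
  tables are printed, not at midpoints). AUC is the trapezoidal area,
  identical to the normalized Mann–Whitney U with half credit for ties.
  Youden cutoff maximizes J = sens + spec − 1; ties prefer higher
  sensitivity, then smaller |cutoff|. The default CI is Hanley–McNeil
  (the study's phrase "exact binomial" is ambiguous for an AUC); a seeded
  within-class percentile bootstrap is the alternative. Orientation is
  explicit: group screening defaults to `low_positive` (patients show the
  lower Δ-HbO\*), which reconciles negative published cutoffs with
  positive group means; severity screening defaults to `high_positive`
  (severity correlates positively with the feature within patients).
  The severity dichotomization rule was never published; the default is a
  median split (configurable quantile), and the rule used is recorded in
  every result.

## Numerical choices and degenerate inputs

* MBLL rejects singular extinction matrices; the filter rejects bands
  outside (0, Nyquist); the paradigm rejects non-positive durations;
  ROC requires both classes; `severityScreen` rejects degenerate splits.
* An ROI whose member channels were all rejected is *missing* (NA row,
  count 0), not an error; a subject whose channels were all rejected aborts
  the run with the full channel list (QC is meant to be audited, not
  silently absorbed).
* Percent changes are rounded half away from zero to two decimals (the
  convention that reproduces the self-consistent printed group summaries;
  values whose published rounding is internally inconsistent by ±0.01 are
  verified to within 0.01, not to equality).
* Peak times in the generator are snapped to the sampling grid so that
  noiseless latency recovery is exact to the sample, and the post-window
  mean is solved on the sampled grid so noiseless Δ-HbO\* recovery is exact
  to ~1e-16.
* Determinism: every stochastic element (cohorts, artifacts, bootstrap)
  derives from an explicit integer seed; identical seeds give
  byte-identical metadata and series.

## Problem sizes used in the shipped checks

The test-suite's parameter-recovery check simulates 200 subjects per group
(enough that three standard errors of a cell mean is a few hundredths of an
mM); Monte-Carlo checks of the statistical layer use 200–500 replicates at
the study's own sample sizes; the severity-screen consistency check uses
500 replicates of n = 22. These sizes are the package's choice of a
desk-scale experiment that still constrains the estimators meaningfully.

## Known limitations

* The generator's feature targets come from published group summaries, so
  between-subject covariance beyond the single amplitude-correlation
  parameter, and any non-normality of the real features, are invented.
* The reconstructed SDs (SE·√n) are large relative to the means, implying
  occasional near-zero or negative responses; the documented feasibility
  bounds resolve this at the cost of small, exactly-recorded shifts of the
  realized cell means.
* Latency of a weak response is intrinsically fragile: the filtered
  transient has a broad top, and in-band noise moves the argmax by a second
  or two; this is a property of the measure, not of the implementation.
* No motion-correction algorithms (spline, wavelet, TDDR) are provided —
  channel rejection is the only cleaning step, mirroring the analysis this
  package implements; and SNIRF/HDF5 export is not included (CSV is the
  canonical interchange format here).
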