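---
title: "Phenotyping ototoxic hearing damage, hyperacusis and tinnitus: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping ototoxic hearing damage, hyperacusis and tinnitus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ototoxkit)
```

# The design this package analyzes

A longitudinal preclinical ototoxicity study: mice are assessed at baseline
and at five post-dosing epochs (weeks 2, 6, 10, 14, 18). Three kinds of data
are collected per animal and epoch:

* **ABR thresholds** per ear at 4, 8, 16 and 20 kHz, read in 5 dB steps up to
  a maximum presented level of 80 dB SPL;
* **startle input/output (I/O) sessions**: 135 trials, each of nine levels
  (60–100 dB SPL in 5 dB steps) presented 15 times in pseudorandom order,
  with the response quantified as center-of-mass displacement (CMD, mm)
  derived from load-cell force;
* **GPIAS test days**: three sessions of 15 blocks × 10 trials; each block
  uses one of five narrowband carriers (4, 8, 12.5, 16, 20 kHz) and mixes
  5 startle-only (SO) and 5 gap-preceded (GAP) trials pseudorandomly, plus 15
  startles in silence per day that only monitor habituation.

The analysis questions are per-ear and per-animal: which ears suffered a
clinically relevant threshold shift, which animals developed hyperacusis
(exaggerated startle), which developed tinnitus (frequency-specific loss of
gap-prepulse inhibition), and how incidence differs between a
tobramycin/vehicle group and a tobramycin + otoprotectant (ebselen) group.

# The synthetic-cohort generator

Because per-animal responder analyses are hard to validate on real data
(ground truth is unknown), the package ships a generator
(`cohort_config()`, `simulate_cohort()`) whose defaults *are* the study
conditions: 8 control, 14 vehicle and 14 ebselen mice, the session geometry
above, and planted effects whose recovery the test suite measures.

## What is planted, and why these defaults

* **Threshold shifts.** Latent baseline thresholds are Normal(25, 5²) dB SPL
  — typical for a normal-hearing CBA/Ca mouse; the value is configurable and
  not load-bearing. Left and right ears share a subject-level component
  (`ear_correlation = 0.5`): the analysis treats ears independently, but they
  come from one animal. Treated ears add a per-frequency, per-epoch mean
  shift (`default_shift_profile()`): 12.5 dB at 16 kHz at weeks 2 and 6 (the
  middle of the 10–15 dB elevation such dosing produces), smaller shifts at
  the flanking frequencies, decaying through week 14 and resolved by week 18.
  Every epoch, baseline included, adds Normal measurement noise
  (`shift_sd = 5` dB) before rounding, so a zero shift profile leaves all
  epochs identically distributed — the property the null-calibration tests
  rely on. Thresholds are rounded to the nearest 5 dB (ties away from zero,
  matching the 5 dB reading grid) and clamped to [0, 80]; shifts computed at
  the 80 dB cap are right-censored in reality and taken at face value here,
  as the clinical analysis does.
* **Startle magnitude.** CMD at level L follows a saturating logistic growth
  function (max 5 mm, midpoint 85 dB, slope 8 dB) — the standard shape of
  startle I/O functions. Long-term habituation multiplies all startles by
  `habituation_rate^(epoch index)` (default 0.9 per epoch), because
  habituation is the background against which hyperacusis must be detected.
  Trial noise is multiplicative lognormal with unit mean
  (`trial_noise_cv = 0.35`): startle magnitudes are positive and
  right-skewed, and no trial-level noise model is dictated by the protocol
  itself.
* **Hyperacusis.** Half of the vehicle group (`hyperacusis_prevalence = 0.5`)
  multiplies its startle CMD by `hyperacusis_gain = 3` during weeks 2–10.
* **Tinnitus.** 36% of the vehicle group (`tinnitus_prevalence = 0.36`)
  raises its true GAP/SO ratio by `tinnitus_ratio_delta = 0.3` at one carrier
  drawn from `tinnitus_freqs` (default 16 or 20 kHz — deficits concentrate
  above the frequency of the largest threshold shift) during weeks 2–10,
  against a normal inhibition ratio `baseline_gap_ratio = 0.65`.
* **Otoprotection.** The ebselen group scales the shift profile and both
  prevalences by `ebselen_multiplier = 0.3`. The magnitude is a free
  parameter; it makes the group contrast qualitatively reproducible.
* **ABR wave amplitudes.** Wave I declines (peak fraction
  `wave1_decline = 0.3`) and wave III rises slightly (`wave3_rise = 0.1`)
  along the normalized time course of the shift profile, so the wave III/I
  ratio rises above its baseline-normalized 100% at post-dosing epochs in
  treated ears — the direction the trajectory analysis must recover.
* **Force waveforms** (optional): startle trials are a damped-sinusoid
  template scaled so the force→CMD conversion round-trips exactly at zero
  noise; non-startle traces are slow drift with no template component.

## Reproducibility

One cohort seed drives named substreams per subject × epoch × assay
(`derive_seed()`), so regenerating a single session reproduces the same
numbers regardless of order, and identical configurations are bit-identical.
Ground-truth flags live only in the `subjects` table; no analysis function
reads them.

## What the generator does not emulate

No cochlear histology, pharmacokinetics, or voltage traces; no drift in
platform calibration; no correlation between hyperacusis and tinnitus status
(clinically they are comorbid); no animal dropout; trial noise is
exchangeable within a session (real sessions show serial dependence).
Passing the simulation-based tests therefore establishes that the pipeline
recovers effects *of the planted form at realistic noise levels* — it cannot
establish robustness to artifacts the generator does not produce.

# Analysis stages and their design choices

## Startle processing

Template matching classifies a force trace startle/non-startle by the
maximum normalized cross-correlation between a unit-norm damped-sinusoid
template and every same-length window (threshold 0.5, both configurable).
The internals of the hardware vendor's classifier are not public; normalized
cross-correlation is the simplest faithful reading of template matching, and
a zero-variance window scores 0 — a flat trace is definitionally a
non-startle. Force → CMD subtracts the mean of a 100 ms pre-stimulus
baseline, divides by mass, double-integrates by the trapezoid rule and
reports peak-to-peak displacement in a 100 ms response window (both windows
configurable; the protocol does not state them). When tables already carry
`cmd_mm` and `valid`, validation is skipped and the flag honored as-is.

Gap ratios divide the mean valid GAP CMD by the mean valid SO CMD per
carrier and session; the **best daily ratio is the minimum** across the
(usually three) sessions — lower ratio = more inhibition = better gap
detection, and "best performance" is read per carrier (a per-session variant
would discard carrier-specific best performance for no statistical gain).
Silence startles never enter ratios.

## CRC responder criteria

`crc_classify()` evaluates the three rules on the shift vector in
tested-frequency order; *adjacent* means consecutive tested frequencies (no
octave interpolation — only these four frequencies were tested). Shifts are
signed and only elevations count: the criteria target ototoxic worsening.
An ear missing an epoch drops out of that epoch's denominator only, which is
why incidence denominators may fluctuate across epochs. The classifier is
verified against exhaustive enumeration of all 2401 shift vectors on the
{0, 5, …, 30} dB grid.

## Per-animal hyperacusis

Trial-level two-way ANOVA (time × intensity) with a direction gate: positive
requires a significant time effect *and* a higher epoch marginal mean.
Under the null the positive rate is therefore about α/2 — deliberately
conservative; a significance criterion for a directional phenotype cannot
also sit exactly at α without becoming a one-sided test, and the phenotype
definition ("significant increase") is inherently two-stage. The
calibration suite asserts the one-sided bound rate ≤ α + 2·SE.

## Per-animal tinnitus

Session-level ratios (three per carrier per epoch) provide the within-epoch
error term — with one test day per epoch, the pre-best session ratios are
the only replication available, a deliberate deviation from using best-of-day
ratios alone, which would leave nothing to test. Two protection flavors are
implemented (`method` in `tinnitus_test()`):

* `"sidak"` (default): per-carrier one-sided p-values (increase = deficit),
  Šidák-adjusted across the five carriers; the omnibus is the smallest
  adjusted p (max-t union–intersection). Family-wise null rate ≈ α, and a
  deficit confined to one carrier keeps its power (measured ≈ 0.92 at the
  default planted delta in the test suite).
* `"lsd"`: Fisher-protected — a single joint F test of all epoch-involving
  terms gates unadjusted per-carrier contrasts. Faithful to the classical
  protected-LSD recipe, but a one-carrier deficit dilutes across the 5
  numerator df, and its measured power at the same delta is ≈ 0.72.

The default is `"sidak"` because the package's stated validation targets —
null positive rate ≤ α *and* high recovery of a one-carrier deficit — are
only jointly attainable by the targeted omnibus; both flavors of
multiple-comparison protection are standard in this literature. The
positivity rule is frequency specificity: significant carriers must form a
set of exactly 1, or 2 adjacent, carriers; broadband "deficits" (3+ carriers
or non-adjacent pairs) are more consistent with global reactivity change
than a tinnitus percept.

Baseline inclusion: animals whose mean baseline best ratio exceeds 0.8 are
excluded — a criterion value the protocol leaves unstated; it is exposed as
configuration and flagged in outputs.

## Statistical engines

* `two_way_anova()`: Type-II sums of squares (no a-priori factor ordering;
  on balanced data Type II equals Type I, verified against a naive
  sums-of-squares oracle to 1e-10). Constant data reports F = 0, p = 1.
* `rm_anova_gg()`: univariate repeated-measures ANOVA with
  Greenhouse–Geisser ε from the pairwise-complete within-level covariance —
  a sphericity-robust stand-in for a mixed model when profiles are mildly
  incomplete; true REML mixed models are out of scope. ε is clamped to
  [1/(k−1), 1] and equals 1 exactly at k = 2.
* `dunnett_mc()`: family-wise contrast-vs-control p-values by Monte-Carlo
  sampling of max|t| under the estimated contrast correlation (default
  100,000 seeded draws) rather than multivariate-t quadrature — simpler,
  directly testable against its Šidák (independence) and single-contrast
  (plain t) limits, and adequate at α = 0.05.
* `fisher_exact_2x2()`: conditional two-sided p as the sum of table
  probabilities ≤ the observed probability × (1 + 1e−7) (the mainstream
  floating-point-tie convention), with log-gamma arithmetic so large tables
  cannot overflow.
* `koopman_rr_ci()`: the score statistic at the constrained MLE (closed-form
  quadratic), bounds by bracket-expanded root search on log ρ (tolerance
  below 1e-8 in ρ). The score's 0/0 boundary cases (an all-positive or
  all-negative margin) are evaluated by their limits; a = 0 gives a zero
  lower bound, c = 0 an infinite upper bound, a = c = 0 is undefined.
* `counts_from_percent()`: exhaustive scan of candidate denominators for
  counts matching a printed one-decimal percentage — reconstruction of
  published tables stays explicit and auditable, never silently guessed.

α = 0.05 throughout, the significance convention of the analyses this
pipeline reproduces.

# Validation strategy and problem sizes

The test suite validates by construction rather than by reference data:

* **Oracle equivalence** — Fisher exact against full enumeration for every
  table with margins ≤ 12; the CRC classifier against the 2401-point grid;
  ANOVA against naive sums of squares on random balanced designs (1e-10).
* **Type-I calibration** — 1000 null subject-replicates per phenotype;
  per-epoch positive rates must stay below α + 2 binomial SE.
* **Parameter recovery** — 200 replicate cohorts under the default
  conditions; the replicate-averaged week-2 incidence must fall inside the
  95% binomial CI of the planted prevalence at one cohort's analyzable group
  size, and the vehicle-above-ebselen CRC ordering at weeks 2 and 6 must
  hold in ≥ 95% of seeds.
* **Coverage** — 5000 simulated tables at a true relative risk of 2
  (n = 30 per group); empirical 95% interval coverage within 1.5 points.

These sizes were chosen to give Monte-Carlo error well below the asserted
margins while keeping the default test run to a few minutes.

# Known limitations

* The per-animal tests treat trials and session ratios as exchangeable
  replicates; serial dependence within sessions would make the tests
  anticonservative on real data.
* An animal positive at any epoch is positive overall, so overall incidence
  estimates are inflated by roughly the union of per-epoch false-positive
  rates over five epochs (a property shared by the definition itself, not a
  bug of the implementation).
* The available-case Greenhouse–Geisser ANOVA approximates, but is not, a
  mixed-effects model; with severely unbalanced profiles a REML fit is
  preferable.
* The Koopman interval is asymptotic; at very small group sizes its coverage
  drifts below nominal, which is why the coverage test pins n = 30.
* Session counts per carrier (3 blocks × 10 trials × 3 sessions) follow the
  explicit block structure of the protocol; a published per-carrier trial
  total of 45 is arithmetically inconsistent with any single-session reading
  of that structure (30 SO+GAP trials per carrier per session, 90 per day)
  and the block structure is taken as authoritative.
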