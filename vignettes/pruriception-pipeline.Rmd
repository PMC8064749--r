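---
title: "Methods: pruriceptive spike trains, psychophysics, and DRG co-expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pruriceptive spike trains, psychophysics, and DRG co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`pruriphys`, the parameters that matter, the design choices made where the
experimental description leaves the analysis under-determined, and what
the synthetic-data generators do and do not emulate.

## Heat-response classification

### Model

A polymodal C-fiber's response to the stepped heat stimulus (default:
38 °C baseline, 49 °C target, 0.2 s rise, 3 s plateau) is reduced to the
instantaneous discharge frequency: for each consecutive spike pair the
reciprocal interspike interval, assigned to the *later* spike — the
frequency of a pair is only known once its second spike has arrived. The
series is three-point median smoothed (interior points replaced by the
median of themselves and their neighbours; endpoints pass through
unchanged, so smoothing preserves length and timestamps and is idempotent
on monotone series).

Two coordinates classify the fiber:

* the **time of peak discharge** `P` of the smoothed series, with ties
  broken by the earliest occurrence — the conservative direction, since an
  early peak points toward a rising-phase (QC-like) response;
* the **line of equality** `E = rise_time + conduction_latency_skin`. A
  spike emitted at the very end of the temperature rise is recorded at
  `E`; a recorded peak later than `E` therefore occurred during the
  plateau.

The rule, in order: a fiber with an onset burst is **QC** regardless of
`P` (bursting fibers occasionally peak above the line); otherwise
`P > E + tol` is **SC**; `|P − E| ≤ tol` is **unclassified**; and
`P < E − tol` is **QC**. Trains with fewer than two spikes inside the
response window `[0, latency + rise + plateau]` are unclassified with
empty diagnostics.

### Parameters and their defaults

* `tolerance` (0.1 s). "Close to the line of equality" is not quantified
  in the experimental description; 0.1 s is half the temperature rise
  time, i.e. the same order as the timing uncertainty introduced by the
  ramp itself. Configurable.
* Burst rule (`burst_params()`): at least `min_spikes = 3` smoothed
  frequency points of at least `min_freq = 20` Hz inside the onset window,
  *and* adaptation — the mean smoothed frequency in the final half of the
  plateau below `adaptation_ratio = 0.5` of the peak. No numeric burst
  definition exists in the source description; these values separate the
  two archetypal discharge shapes cleanly and every one is configurable.
* The onset window is `[0, latency + rise + 0.2 s]` in *recorded* time.
  The burst fires at the onset of the stimulus as seen by the fiber, but
  its spikes reach the electrode one conduction latency later; a window
  that ignored the latency would miss the burst of any fiber conducting
  slower than the window is long. `classify_heat_response()` passes the
  fiber's latency automatically.

Smoothing is applied to the spikes inside the stimulus window only, not
to the whole recording: classification concerns the evoked response, and
spontaneous spikes minutes away would otherwise leak into the endpoint
positions of the median filter.

Boundary conventions elsewhere in the characterization: conduction
velocity exactly 2 m/s is Aδ ("between 2 and 20 m/s"); a von Frey
threshold of exactly 6 bar counts as mechano-sensitive (the boundary is
stated as responsive below 6 bar vs threshold above 6 bar, leaving 6 bar
open; the inclusive choice is declared here and in the function
documentation). A fiber whose four-application series never reaches two
positives has threshold `Inf` (not reached) and is mechano-insensitive.

## Pruritogen response scoring

The net response of a fiber to an injected compound is

```
net = (post APs − baseline × window/60)_pruritogen − (post APs − baseline × window/60)_vehicle
```

with a 60-s pre-injection baseline prorated linearly to the scoring
window (default 300 s) and the vehicle block (extracellular fluid for
ALA, BAM8-18 for BAM8-22) preceding the pruritogen in the same fiber. A
unit is *responsive* at net ≥ 10 APs / 5 min; the boundary value 10 is
responsive. Negative nets are retained for statistics.

Design choices:

* The scoring window starts at the **end of the injection interval**
  (configurable to injection onset): spikes evoked mechanically by needle
  insertion and fluid delivery are not pruritogen responses, and
  recordings shade the injection period separately.
* Recordings terminated early under the three-silent-minutes stopping
  rule contain no late spikes and are implicitly zero-padded by the
  fixed window; counts and bins are unaffected.
* Time courses use half-open 10-s bins `[k·10, (k+1)·10)` over 0–300 s;
  counts conserve the spikes in the window.
* The χ² on the 2×2 joint-responsiveness table is the Pearson
  association statistic **without** continuity correction,
  `n(ad−bc)²/((a+b)(c+d)(a+c)(b+d))` on 1 df. This variant reproduces
  the reported statistic for the published joint counts exactly (the
  acceptance suite checks it against the closed form); a margin of zero
  is rejected as degenerate.
* The fiber type × pruritogen analysis is a split-plot RM-ANOVA (type
  III with sum-to-zero contrasts, so unequal subtype counts are tested
  at the unweighted grand mean). With a two-level within factor the
  sphericity correction is identically 1.
* Scheffé post hoc contrasts among the four cell means use two error
  terms: within-subtype contrasts use the subject × pruritogen residual
  mean square; contrasts crossing subtypes use the pooled
  `(MS_subjects + (k−1)·MS_residual)/k` with Satterthwaite degrees of
  freedom, because the variance of a cell mean contains both the
  between-subject and within-subject components. No installed package
  provides Scheffé contrasts with split-plot error terms, so this is
  implemented directly and checked against hand-computed sums of squares
  in the tests.
* A paired comparison in which every difference is exactly zero reports
  t = 0, p = 1 (identical conditions); a constant non-zero difference
  has no within-pair variance and is an error.

## Psychophysics

Ratings use the generalized Labeled Magnitude Scale (0–100, anchors at
0, 1, 6, 17, 35, 53, 100), reported every 30 s from 0.5 min after
injection, for at least 5 and at most 20 min or until every quality has
three successive zeros.

Per series (subject × stimulus × quality):

* **peak** — the session maximum;
* **duration** — from the onset of non-zero ratings to the *first zero
  after the last non-zero sample*. A sensation that waxes and wanes has
  not disappeared at an intermediate zero; only the zero following the
  final non-zero report ends it. If no such zero exists the sensation
  outlasted the session: duration runs to the session end and is flagged
  censored (the protocol cap makes 19.5 min the largest observable
  uncensored onset-to-offset span starting at 0.5 min).
* **AUC** — trapezoidal integral over the duration, with an implicit
  zero half a minute before the first non-zero rating: ratings are
  interval samples of a continuous percept that was absent at the
  previous report. Step integration was the alternative; the trapezoid
  is chosen and declared because the percept is continuous, and the two
  differ only by a constant factor on the first and last half-minute.

Zero-peak cells have no duration or AUC (there is no duration of an
absent sensation); the duration/AUC analyses therefore run on the subset
of subjects with non-zero peaks in *every* stimulus × quality cell
(`filter_all_nonzero()`), while peak analyses use all subjects. A second
filter (`filter_balanced_itch()`) retains subjects whose weakest
single-pruritogen peak itch is at least 50% of their strongest —
inclusive at the boundary — to check that no single compound dominates.

The RM-ANOVA engine (`rmanova_gg()`) fits the subject × cell matrix as a
multivariate linear model and extracts the univariate table with
Greenhouse–Geisser epsilon via `car::Anova` (type III). One or two
within-subject factors and an optional between factor (sex) are
supported; subjects with missing cells are excluded listwise with a
warning; effects with one numerator df have ε = 1 by construction.
Dropping the between factor when no interaction with it is significant
mirrors standard practice for these designs and is left to the analyst.
Bonferroni post hoc families are all pairwise comparisons within the
factor under test. Degenerate inputs (zero variance everywhere) report
F = 0, p = 1 rather than 0/0.

## ISH co-expression

A neuron is positive for a marker only when *strictly more* puncta than
the species threshold are present (5 for human RNAscope, 3 for macaque
BaseScope). Pairwise co-expression is reported both as the mean ± SEM of
per-donor percentages (SEM across donors, n−1 denominator — macaque
summaries aggregate per-DRG from one animal in place of per-donor) and
as the pooled count ratio; the two generally differ when donors are
unbalanced, and both are reported deliberately. Donors with no
A-positive neuron contribute no percentage and are dropped from the mean
with a message; a single contributing donor has undefined SEM. Venn
summaries require every neuron to carry all three panel markers and
their region counts sum to the neuron total. Each counted neuron is
assumed unique (no cross-section deduplication is attempted; sections
are 14–20 µm apart in the source protocol).

## Synthetic-data generators

The generators exist so every analysis stage can be exercised against
known ground truth. They emulate:

* **Heat trains** — inhomogeneous Poisson processes with deterministic
  rate profiles: QC, a 150 Hz boxcar during the rise followed by
  exponential adaptation (τ = 0.35 s) from 80 Hz; SC, a Gaussian rate
  bump (55 Hz peak, σ = 0.6 s) centred 1.5 s into the plateau.
  Conduction latencies are uniform on 0.1–0.5 s, consistent with C-fiber
  conduction below 2 m/s over a few-centimetre distance. The rate forms
  are declared model choices — only the qualitative discharge shapes are
  described in the source. `noise = FALSE` produces deterministic
  archetypes (spikes at the expected positions of the rate profile) used
  for the exact-recovery checks.
* **Injections** — per-compound response probabilities and target net-AP
  means (stored in `inst/extdata/fiber_defaults.yaml`, rounded from the
  reported QC/SC population cell means: QC-ALA 83, QC-BAM 52, SC-ALA 10,
  SC-BAM 94). Responders receive an exponentially decaying discharge
  whose expected count is `target/response_prob`, so the unconditional
  population mean equals the target exactly; vehicles produce only
  injection-interval artifact spikes and the default spontaneous
  baseline is zero (CMHs are essentially silent at rest), making the
  configured target the exact expectation of the net-response estimator.
* **Ratings** — a saturating-rise (0.7 min) × exponential-decay mean
  curve whose peak falls 1.2–1.4 min post-injection; decay constants of
  3.0–3.5 min for the MRGPR agonists and mixtures vs 6.3 min for
  histamine place the zero crossing near 10 vs 20 min, reproducing the
  described time courses. Subjects carry lognormal gains (overall
  sdlog 0.5, per-quality sdlog 0.6) and a per-cell chance of not
  perceiving a quality (itch 1.00, pricking/stinging 0.97, burning
  0.93), which yields roughly the observed fraction of subjects with a
  sensation in every cell. Rater noise is multiplicative smooth AR(1)
  (sdlog 0.25, ρ = 0.85 per 30-s step): ratings are ratio-scaled and
  drift rather than jump, and a percept that has ended is reported as
  zero, not as noise. Ratings below the "barely detectable" anchor
  report as zero, and the protocol stopping rule is applied.
* **Areas** — lognormal per-subject/measure models with a ×3–×5
  enlargement for histamine-containing stimuli (histamine drives wheal,
  flare and dysesthesias far more than the MRGPR agonists).
* **Puncta cohorts** — marker states drawn from a configured joint
  distribution over the co-expression regions, puncta counts from
  separated negative binomials (positive: μ = 30, size 8; negative:
  μ = 0.6, size 0.8 for human), so thresholding recovers states with a
  small known error (&lt;1% per call). The published pairwise
  percentages come from separate double-label experiments with different
  denominators, so no single three-marker joint reproduces all of them;
  the default joint honors P(MRGPRD⁺|MRGPRX1⁺) = 0.94,
  P(TRPV1⁺|MRGPRX1⁺) = 1, P(TRPV1⁺|MRGPRD⁺) ≈ 0.95 and
  P(MRGPRX1⁺|TRPV1⁺) ≈ 0.34, accepting 0.91 for P(MRGPRX1⁺|MRGPRD⁺)
  as the closest consistent value.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: no biophysical membrane dynamics, refractory
periods or bursting statistics beyond the rate profile; no
temperature-feedback dynamics of the laser; no mast-cell or flare
mechanisms behind vehicle or histamine responses; no scratching-induced
or attention-driven non-stationarity in ratings; no optical or
segmentation artifacts in puncta counts. Recovery of configured
parameters demonstrates that the estimators are unbiased and the
pipeline is wired correctly, not that the models capture primate
physiology.

All generators accept a seed and are byte-reproducible under it.

## Numerical choices and problem sizes

* Peak-time ties: earliest occurrence. Median filter endpoints: pass
  through. Binning: half-open intervals. Duplicate timestamps (zero
  interspike interval): error.
* The chi-squared implementation delegates to `stats::chisq.test`
  (uncorrected) after margin checks; the paired t to `stats::t.test`;
  both are verified against closed forms to 1e-9 in the tests, and the
  RM-ANOVA against an independent orthonormal-contrast implementation
  and frozen reference values from a second implementation.
* Test and acceptance problem sizes, chosen to bound runtime while
  keeping Monte-Carlo error small: 200 fibers for classification
  recovery (plus 50 noise-free archetypes), 500 fibers per subtype for
  net-AP recovery, 2000 replicates × 29 subjects for the type-I
  calibration of the GG-corrected F (nominal α = 0.05; the GG correction
  is mildly conservative when sphericity actually holds, which the
  calibration band accommodates), 500 neurons across 4 donors for
  co-expression recovery, and 200–500 subjects for rating properties.

## Known limitations

* The Scheffé cross-group error term uses a Satterthwaite approximation;
  exact small-sample behaviour is not claimed below ~5 subjects per
  group.
* `rmanova_gg()` supports at most two within factors and one between
  factor — the designs used here — not general factorial layouts.
* Censored durations (sensation persisting at 20 min) enter the duration
  RM-ANOVA at their censored value of 19.5 min minus onset; no survival
  treatment is attempted, matching the simple summary the protocol
  affords.
* The early-stop/zero-padding convention assumes silence after early
  termination; a fiber that resumed firing after three silent minutes
  would be truncated.
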