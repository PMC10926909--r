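---
title: "Methods: from wrist acceleration to activity recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wrist acceleration to activity recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actikids)
```

This vignette documents the models, rules and design decisions behind
`actikids`: a pipeline that turns wrist-worn triaxial accelerometer
recordings of school-age children into intensity summaries, ROC-derived
activity recommendations and compliance statistics. It is written the way a
methods section would be: what is computed, under which assumptions, and why
each genuinely open choice was made the way it was.

## 1. Signal chain

**Raw signal.** The device model is a wrist-worn triaxial accelerometer with
a ±8 g dynamic range sampling at a nominal 40 Hz. No noise filter is applied
at any point; all downstream quantities are computed from the raw (or
calibrated-raw) samples.

**Auto-calibration** (`autoCalibrate`). Gains and offsets drift per axis, so
the package estimates a per-axis correction `calibrated = raw * gain +
offset` from *static windows*: 10-s windows whose per-axis SD is below
13 mg (a standard stillness criterion) and which contain no clipped
samples. During stillness the acceleration vector should lie on the unit
gravity sphere, so the window means are iteratively regressed, axis by
axis, onto their projections onto the unit sphere until the mean absolute
deviation of the norms from 1 g stops changing (tolerance 1e-10, cap 200
iterations). Two degenerate regimes return the identity model with a
diagnostic flag rather than an error: fewer than 10 static windows, and
static orientations that do not spread over the sphere (all axis ranges
below 0.25 g — a single posture cannot identify gain and offset
simultaneously). Both regimes are exercised in the unit tests.

**ENMO epochs** (`computeEnmoEpochs`). The intensity metric is the
Euclidean norm minus one with negative values truncated to zero,
`e = max(0, ‖a‖ − 1)`. Truncation is applied **per sample, before epoch
averaging**. The alternative (truncating the epoch mean) differs on signals
that oscillate around 1 g; the per-sample convention follows the reference
implementations of this metric, and the package's property tests pin the
behaviour against a brute-force per-sample oracle at 1e-9. Epochs are 5 s
(200 samples at 40 Hz); a trailing partial epoch is dropped; values are
reported in mg.

**Z-angle** (`computeZAngle`). The posture angle of the device's z axis,
`atan(z / √(x² + y²))` in degrees, computed on **epoch-mean** calibrated
accelerations rather than per sample — the epoch mean suppresses movement
jitter, which is what makes the angle usable as a posture-stability signal.
The all-zero vector is mapped to 0° with a flag.

**Clipping** (`detectClipping`). An epoch is flagged when more than half of
its samples exceed 95% of the dynamic range on any axis (abnormally high
sustained values, e.g. device tapping or sensor faults). Flagged epochs are
excluded from calibration and carried as a flag in the epoch series.

## 2. Wear time

**Baseline rule.** The classical criterion for non-wear operates on raw
per-axis SDs over long windows. When only epoch data are available the
package uses a surrogate: 60-min windows advanced in 15-min steps are
non-wear when (a) the SD of epoch ENMO is below 13 mg and (b) the z-angle
range in the window is below 5°. Condition (b) is deliberate: the raw
per-axis criterion is dominated by gravity-orientation changes, which an
ENMO-only surrogate cannot see. Without it, quiet sleep (epoch ENMO SD
around 11 mg) would be misclassified as non-wear wholesale. This surrogate
is the one behavioural difference between the epoch-level fast path and a
raw-signal implementation, and it is flagged in the documentation rather
than hidden.

**Strict rule.** Short removals (e.g. for sport) escape 60-min windows, so
a stricter supplement flags maximal runs of epochs whose z-angle range
stays below 2°, provided the run's portion inside the daily 08:00–22:00
window lasts at least 30 minutes. Two readings of "angle changes below two
degrees" are possible: successive differences or total range. The package
uses **range (max − min) over the run**, the stricter and deterministic
reading — successive-difference criteria pass slow continuous drifts that
plainly indicate a resting device. Runs are found with a two-pointer
sliding-range scan (O(n)); a run crossing the window edge contributes only
its inside portion to the 30-min requirement, and only the inside portion
is flagged. The 08:00–22:00 gate means overnight stillness is never flagged
by this rule; overnight non-wear is the baseline rule's job.

**Reported sport substitution** (`substituteReportedSport`). When a child
reports removing the device for a known sport, the report is first verified
against detected non-wear; only the overlap is replaced, using the mean
intensity trajectory (band minutes per 30-min slot) of the same sport
observed in other participants. Unknown sports produce a warning and no
substitution, letting the interval fall through to generic imputation.
Ordering is substitution → imputation → validity: substituted epochs count
as *worn* in the validity accounting (their activity is accounted for),
while generically imputed epochs still count as non-wear — imputation must
not be able to rescue an invalid day.

**Imputation** (`imputeNonwear`). Residual non-wear on analysis-valid days
is imputed in intensity-minute space per 30-min clock slot: the gap's band
composition is the participant's mean composition over the same clock slot
on their other valid days of the same day type, falling back to all their
valid days when no same-type donor exists, and staying non-wear (with a
warning) when there is no donor at all. Imputed epochs are materialized
with fixed representative in-band ENMO values (geometric mid-band for
active bands), so intensity classification reproduces the donor
composition deterministically. The 30-min slot width is a configurable
choice; the source rule speaks only of "the time interval occupied by the
non-wear time", and half-hour slots are fine enough to track the school
day's structure while coarse enough to have stable donor compositions.

## 3. Day typing and weekly weighting

All clock intervals are half-open `[start, end)` at epoch resolution, and
all times are naive local clock times (the study design is
single-timezone; DST arithmetic is out of scope).

- **Valid day**: recording ≥ 20 h (of the 00:00–24:00 day) *and* non-wear
  accumulated in 08:00–22:00 ≤ 120 min. Bounds are inclusive on both
  sides, the literal reading of "a minimum of" and "no more than".
- **Valid school time** (school days, default 9:00–14:00): recorded school
  time ≥ 4 h and school-time non-wear ≤ 60 min. A valid school *day*
  requires both the day rule and the school-time rule.
- **Valid PE class**: the source rule — "less than 1 minute of non-wear,
  included at least 3 minutes of MVPA, or did not exceed 30 minutes of
  sedentary behaviour" — is grammatically ambiguous between a pure
  disjunction and a conjunction of non-wear with the activity clauses. The
  package adopts **non-wear AND (MVPA OR sedentary)**: a pure disjunction
  would validate a class with heavy non-wear merely because sedentary
  minutes (which cannot accumulate during non-wear) stayed low, which is
  circular. The reading is configurable (`rule = "disjunction"`).
- **Day types**: Saturday/Sunday are weekend days; holidays and school
  absences are excluded from analysis; a valid school day with a valid,
  scheduled PE class is a "school day with PE", otherwise "school day
  without PE". PE classes are taken from the recorded schedule only —
  no inference of PE from the signal.
- **Weekly weighting** (`weeklySummary`): duplicate weekdays are averaged
  first (two Mondays contribute one averaged Monday); the school mean
  (over distinct school weekdays) and weekend mean (over distinct weekend
  weekdays) are combined as 5/7 · school + 2/7 · weekend. An assessment is
  valid with ≥ 4 distinct valid weekdays including ≥ 2 school and
  ≥ 1 weekend day; "weekly days" is read as distinct weekdays after
  duplicate averaging, consistent with reporting average weekly days on a
  0–9 scale. With no valid weekend (or school) day the weighted mean is
  undefined and reported as NA rather than silently rescaled.

## 4. Intensity classification and anthropometry

Epoch ENMO is classified with the published wrist cut-points for children:
sedentary < 56.3 mg ≤ light < 191.6 mg ≤ moderate < 695.8 mg ≤ vigorous.
The sources give the bands as "from X to Y", which does not resolve the
boundary; the package assigns boundaries **upward** (half-open `[lo, hi)`),
configurably. Minutes are epoch counts / 12. Derived bands satisfy
MVPA = MPA + VPA and LMVPA = LPA + MVPA to 1e-9 by construction, and only
worn or imputed epochs contribute.

BMI is kg/m²; the waist-to-height ratio is waist (cm) / height (cm);
central obesity is WHtR ≥ 0.5 with an **inclusive** boundary. Weight-status
classification against external growth references (WHO / IOTF) is exposed
as a hook but deliberately not implemented — those are external reference
tables, not part of this package's scope.

## 5. ROC thresholds and recommendations

The positive class is central obesity, flagged when activity falls
*below* a threshold — so "meeting" a recommendation is being at or above
it, and boundary compliance is inclusive. Candidate thresholds are the
midpoints between consecutive distinct observed values plus ±∞ sentinels
(a grid adds nothing: the empirical ROC only moves at observed values).
Sensitivity at t is P(activity < t | obese); specificity is
P(activity ≥ t | non-obese). The AUC uses the rank (Mann–Whitney)
formulation with midranks for ties; its standard error is the asymptotic
placement-value (DeLong) variance, giving the 95% CI and a two-sided test
against AUC = 0.5. Property tests verify AUC = U/(n₁n₀) against exhaustive
pair counting and cross-check the DeLong interval against an independent
implementation.

The operating point maximizes the Youden index J = sensitivity +
specificity − 1, with **ties broken toward the higher threshold** (higher
sensitivity — the screening-oriented choice). Reported thresholds are
**rounded down** to a configurable half-minute granularity: rounding down
is the conservative direction for a "do at least this much" threshold and
jointly reproduces reporting a 12.5 unchanged while taking 9.7 to 9.5.

VPA recommendations are always sex-specific. MVPA thresholds are pooled
across sexes when their relative gap is below 5% — the pooled value is the
sample-size-weighted mean rounded to the nearest 5 minutes — formalizing
the practice of issuing one common MVPA guideline when the sexes barely
differ; both per-sex values are always retained alongside the pooled one.

## 6. Association statistics

Compliance tables are analysed with: Pearson chi-square **without**
continuity correction (the package standardizes on the uncorrected
statistic; correction is a configuration left to the caller since the
sources are silent); the phi coefficient with compliance = 1 and obesity
= 1 coding (so protective associations are negative); Cramér's V =
√(χ²/(n·(min(r,c)−1))), which equals |phi| on 2×2 tables (checked
exhaustively in tests); McNemar's test for paired day-type compliance with
the asymptotic (b−c)²/(b+c) statistic when b + c ≥ 25 and the exact
binomial otherwise (a standard switch point; the statistic depends on the
discordant cells only); Mann–Whitney U and Wilcoxon signed-rank tests via
the standard implementations (midranks, exact for small untied samples);
and conditional logistic regression for within-child contrasts (meeting a
recommendation on PE days or weekends given school days without PE),
stratified by participant. For the two-condition paired-binary case the
conditional-likelihood maximizer equals the discordant ratio b/c — the
package keeps that closed form as an independent oracle against the model
fit. Stratum-constant covariates (parental education, school status)
cancel from the conditional likelihood; where adjustment by such covariates
is wanted, the supported mode is stratified fitting by covariate level with
per-level ORs, since within-stratum cancellation makes a pooled
"adjustment" ill-defined.

## 7. The synthetic cohort generator

The generator exists so that every stage above is testable without access
to individual accelerometer data. It emulates the reference study
conditions: 360 children (48.9% boys), at least eight consecutive 24-h
days starting on a Monday, school 9:00–14:00 with a 30-min recess, two PE
days per week, and per-sex/per-day-type activity targets taken from the
published day-type tables (vigorous and MVPA means and SDs per day type;
light activity held flat at the weekly target; moderate = MVPA − VPA with
SDs combined in quadrature). Daily minutes are drawn as zero-floored
normals around a child latent level that carries 81% of the variance
(correlation 0.9), giving realistic day-to-day persistence; no
distributional family is stated in the sources, so normal-with-floor is an
assumption, documented here. Realized weekly means then reproduce the
published weekly table within sampling error, which the test suite checks
at 2 standard errors.

At the epoch level, a day is materialized as 17,280 5-s epochs whose band
totals match the day's truth to within one epoch per band: activity epochs
are placed with weights emulating the day's structure (concentrated MVPA
in PE classes at about 7 min/h vigorous and 23 min/h MVPA, elevated recess
and late-afternoon activity, quiet lessons, sedentary nights), in-band
values are drawn log-uniformly between band edges (sedentary: half-normal
below 56.3 mg) to avoid stacking at cut-points, and the posture angle
follows segmented drifts — stable enough to be realistic, variable enough
that sleep never triggers the strict non-wear rule. Non-wear injection
overwrites intervals with near-zero ENMO and a constant angle and returns
the truth mask for detector scoring.

**The obesity link.** Central obesity is drawn from a logistic model on
weekly VPA (and optionally MVPA). For a logistic link the Youden-optimal
threshold t\* satisfies `intercept + slope · t* = logit(prevalence)`, so
the generator calibrates intercepts by deterministic quadrature so that
the *population* Youden points sit exactly at 12.5 (boys) and 9.5 (girls)
min/day. The default slope is −1.5 per min/day — deliberately steep. The
empirical Youden maximizer converges at a cube-root rate, and at the
modest discriminations seen in real cohorts (AUC ≈ 0.65) its sampling
error at n = 360 is several minutes: a generator in that regime could not
serve as a recovery benchmark for the threshold machinery. The package
therefore separates concerns: threshold *recovery* is validated in the
sharply identified regime (the default link), while behaviour in the
realistic weak-association regime is covered by the null and
monotone-AUC property tests at slopes from 0 to −0.4. Implied prevalence
under the default link is about 26% overall. Anthropometry (waist, height,
BMI, age) is drawn from bivariate-normal targets and the waist is shifted
minimally so the WHtR ≥ 0.5 flag agrees with the drawn obesity label,
keeping the anthropometry module consistent with the labels.

**What the generator does not emulate**: physiological gait structure,
heart-rate coupling, seasonal and weather effects, bout structure within
bands, device temperature effects, or realistic AUCs in the default link
(see above). Passing tests on synthetic data therefore demonstrate the
correctness of the *rules and estimators*, not the field performance of
the detector thresholds on real signals.

## 8. Problem sizes and determinism

All randomness flows from explicit integer seeds; given a seed, every
generator and the full pipeline are bit-reproducible (the pipeline test
checks byte-identical output files). The test suite sizes simulations for
a desk-scale run: cohort-level checks use n = 360 children at the summary
level (20 replicates for threshold recovery, 60 cohorts for the
monotone-AUC property), epoch-level checks use single-child recordings of
1–8 days, the non-wear recovery harness injects 50 intervals of 30–120
min, and the raw-signal path uses 2–3 h recordings at 40 Hz. The
conditional-logistic coverage check runs 200 replicates of 300 matched
pairs.

## 9. Known limitations

- The epoch-level baseline non-wear rule is a surrogate (Section 2); exact
  equivalence with raw-signal implementations is neither claimed nor
  tested.
- Proprietary device binary formats are not parsed; raw input is CSV
  (timestamp, x, y, z in g) or epoch CSV.
- Weight-status classification against WHO/IOTF references is a hook, not
  an implementation.
- The conditional-logistic "adjustment" for stratum-constant covariates is
  offered only as stratified per-level fitting (Section 6).
- Energy-expenditure conversion and bout-based MVPA are out of scope; all
  minutes are total accumulated time in band.
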