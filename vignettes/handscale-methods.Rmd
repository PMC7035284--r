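---
title: "Models and methods behind handscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind handscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(handscale)
```

`handscale` estimates handwriting quality from digitizer pen recordings:
per-sample x/y position, pressure and the two pen-tilt angles at a nominal
60 Hz, segmented into strokes (maximal pen-down intervals). This vignette
explains the models the package implements, the parameters that matter,
the numerical choices made where the design was genuinely open, and what
the synthetic-data generator does and does not emulate.

## The data model

A recording is a tibble of on-surface samples with stroke ids; in-air
motion is *not* captured, so pen lifts exist only as time gaps between
strokes. Coordinates are device points with y growing downward; every
feature is either translation-invariant or unit-covariant, and the norm
stage absorbs device scale, so no physical unit is assumed. Pressure may
arrive on any non-negative device scale; the tilt angles must lie in
[0, 180] degrees. Timestamps are seconds as reals; a dialect that supplies
only sample indices is converted as `t = index / sampling_rate_hz`.
Degenerate strokes (fewer than two samples) are dropped with a warning
rather than an error, since single-sample contacts are common device
noise.

Lines of text are recovered, when not supplied, by single-linkage grouping
of stroke median-y: sorted by median y, a new line starts when the gap to
the previous stroke exceeds 1.5 times the median stroke height. The rule
is parameter-light and exact on well-separated manuscript lines; an
explicit `line_id` in the input always wins, and the operation is
idempotent and stroke-order invariant up to renumbering.

## The feature catalogue

The 62 features carry conventional identifiers 1–36 and 38–63 (the
numbering has no 37; the registry mirrors that convention rather than
renumbering) in four families: static (12), kinematic (11), pressure (13)
and tilt (26). Fixed constants live in `handscale_config()`:
300-point bins for the static straightness/size features, a 20-pixel grid
for density, 600-point bins for every spectrum, 10-sample averaged bins
for the rate-of-change series, and a 10-point window for the tremor
signal.

Three definitional choices deserve a note:

* **Rate of change.** The pressure/tilt "speed of change" series is the
  absolute difference between consecutive 10-sample bin means divided by
  the time between bin mid-points — the conventional rate. The
  alternative reading (time divided by value difference) diverges for
  equal bins and was rejected.
* **Average stroke direction** uses the circular mean of `atan2(dy, dx)`
  step directions; an arithmetic mean of angles is discontinuous at the
  ±π wrap and would make the feature depend on an arbitrary branch cut.
* **Handwriting size** averages the per-bin bounding-box area over bins so
  the feature does not grow with text length and stays comparable across
  children.

Inversion counts (features 31, 52, 53) are strict sign changes of
consecutive first differences with zero differences skipped, normalized by
the total elapsed writing time. The velocity-peaks feature (17) smooths
the speed series with a generalized-Gaussian window (M = 3, p = 0.5,
σ = 2, unit-normalized, reflect padding) before counting extrema.

Features whose preconditions fail (too few points for a bin or a spectrum)
are returned as `NA` with an `insufficient_data` flag — never a fabricated
value — and flagged features propagate as missing scores downstream. With
10-sample rate bins, the pressure/tilt rate spectra need roughly 6,000
on-surface samples (about 100 s of writing at 60 Hz); a five-sentence
manuscript task comfortably exceeds this, but short snippets will carry
flags on the rate-spectrum features.

## Spectral machinery

Every "…Frequencies" feature shares one construction. The signal (tremor
residuals, speed, or a rate-of-change series) is cut into consecutive
600-point bins; each bin is mean-removed and its DFT magnitude spectrum
taken on the nominal frequency grid `k · rate / 600`; spectra are averaged
point-wise and normalized to sum 1. Choices made where convention was
open, each fixed and documented:

* magnitude (not power) spectra are averaged;
* the normalization target is sum 1, making the spectrum a probability
  vector — required anyway for the entropy comparison;
* the 0 Hz line is excluded (after mean removal it carries no tremor or
  fluency information and would otherwise dominate the normalization);
* an all-zero spectrum (constant signal) falls back to the uniform vector
  with a warning;
* bins never span a between-stroke gap longer than 1 s — a page change —
  otherwise concatenation order defines the series;
* the nominal rather than empirical sampling rate defines the grid, so
  every writer shares one grid and cohort-average reference spectra are
  well defined.

The five summaries are: the 90% bandwidth (distance from the first
occupied line to the smallest frequency at which cumulative power reaches
0.9 — zero for a one-line spectrum); the spectral median (cumulative power
reaches 0.5); and, against the cohort-average reference spectrum, the
Kullback–Leibler divergence (with ε = 1e−12 smoothing on both vectors,
so disjoint supports stay finite), the Pearson correlation (defined as 1
for identical zero-variance vectors, 0 when otherwise undefined), and the
Euclidean distance. "Entropy", "correlation" and "distance" are named but
not defined in the source convention; KL, Pearson and Euclidean are the
package's fixed choices.

The tremor signal itself is geometric: for each local displacement vector
(consecutive point pair) the residual is the magnitude of its 2-D cross
product with the average of the local vectors in a forward 10-point
window. Straight writing gives near-parallel local and global vectors and
residuals near zero; shaky writing does not. The construction depends only
on the polyline, not on timing.

## Norm curves and feature scores

For each feature and each gender separately, `f_mean(age)` is a
least-squares cubic of value against age, treating age as continuous. The
spread curve `f_std(age)` — the estimation method for which was an open
choice — is a cubic fitted to the standard deviations of the mean-curve
residuals pooled in 1-year age bins, weighted by bin size. Rank-deficient
cells fall back to the highest degree the data support, with a warning.

Two numerical guards matter in practice:

* **The SD floor.** Evaluated `f_std` is clipped below at 10% of the
  feature's cohort SD. A cubic through seven or eight noisy binned SDs can
  dip to zero or below inside the age support; with a negligible floor,
  ordinary children at those ages would receive Z-scores in the tens of
  thousands on the affected features, and those few cells would dominate
  every downstream projection. One tenth of the cohort SD never binds
  where the SD curve is well estimated and keeps Z bounded where it is
  not. The fraction is exposed as `std_floor_frac`.
* **Age clamping.** Cubics extrapolate unsafely, so ages outside the
  fitted support are clamped to the boundary with a warning.

The feature score is `exp(−α · Z^β)` with `Z = |value − f_mean| / f_std`:
1 exactly on the norm, strictly decreasing, always in (0, 1]. α and β are
calibration constants with no canonical values; the defaults α = ln 2,
β = 2 put score 0.5 at one SD and 0.0625 at two SDs — a smooth,
interpretable calibration — and both are arguments everywhere they are
used. Norm models are per-cohort by design (different school systems
start handwriting instruction at different ages); models persist as
versioned JSON and are never mixed.

## Severity scales

The scale construction is deliberately unsupervised, so it is independent
of any existing test's labels. Its input representation was an open
choice: the package uses *signed* standardized deviations
`(value − f_mean(age)) / f_std(age)` — not raw values, which would let
age and gender masquerade as handwriting variance, and not the bounded
scores, which discard direction. The deviations are centered and scaled by
the fitting cohort's per-feature mean and SD, projected onto the three
leading principal axes, and clustered with K-means, k = 2. Base R's
Hartigan–Wong K-means with 50 random restarts under a fixed seed is used;
with three dimensions and two clusters this reliably reaches the global
optimum that k-means++ seeding targets. The typical cluster is the one
holding the majority of school-labeled children (ties toward the larger
cluster); `d_ref` is the school children's mean distance to its centroid.

The distance-to-score map `exp(−d / d_ref)` is the package's choice — the
source convention plots scores in (0, 1) without defining the map — so
absolute score values are calibration-dependent; ordering and threshold
semantics are not. Thresholds are rank-based: the threshold for fraction
`p` is the smallest reference score with at least `⌈p·n⌉` scores at or
below it, making realized fractions exact for distinct scores and only
ever *above* nominal under ties; interpolating quantile definitions were
rejected for auditability. The default fractions 2% / 8.6% / 15% / 25%
(the second being the conventional dysgraphia prevalence) are examples,
not clinical constants, and are configurable — as is the number of
retained axes, with a warning that thresholds must be refit.

Per-category sub-scales repeat the identical construction on one feature
family. Cluster/label agreement is summarized as sensitivity (dysgraphic
children in the atypical cluster) and specificity (school children in the
typical cluster).

## The synthetic generator

`simulate_recording()` produces plausible *statistics*, not legible
handwriting: sinusoidal letter-like oscillations advancing in x, several
strokes per line and several lines per page, sampled at 60 Hz. Age trends
are planted as smooth functions over 5–12 years (the emulated study's age
range): baseline horizontal speed and stroke frequency rise with age while
speed variability, pressure variability, tremor amplitude and letter size
fall — so mean velocity increases with age, as observed in real
development. Four deficit knobs act monotonically on their families:
kinematic (velocity jitter, high-frequency path tremor, longer pen lifts),
pressure (variability and inversion rate), tilt (orientation wobble) and
static (line waviness, size irregularity). Simulated pen lifts are capped
at 0.95 s so that even severe writers stay below the 1 s page-change rule
above. All randomness flows from one seed through per-writer derived
seeds, so cohorts are reproducible and writers independent.

Default recordings last ~115 s of on-surface writing (≈ 6,900 samples),
matching a five-sentence manuscript task and long enough for every
catalogued feature. `simulate_cohort()` draws ages uniformly, genders by a
mix fraction, and applies the deficit profile to the atypical group with a
±30% per-child severity jitter so that group is heterogeneous. The default
atypical profile concentrates the deficit in the kinematic and pressure
families, the families that dominate real group differences.

What the generator does **not** emulate: glyph shapes, letter or word
structure, within-child session-to-session variability, device noise
models, or correlations between feature families beyond those induced by
the shared trace. Passing tests therefore demonstrate that the pipeline
recovers planted structure of the kinds listed — not that it would
achieve any particular accuracy on clinical data, whose group separations
are far smaller than the planted ones.

## Verification strategy and problem sizes

The test suite checks every closed form against hand or brute-force
oracles (cross-product arithmetic for the tremor fixture, cumulative-sum
scans for bandwidth and median, an independent eigendecomposition for the
PCA, rank counting for thresholds), property-style invariants (round
trips, translation invariance and time-unit covariance of the full
catalogue, Gibbs' inequality, Bessel's inequality, score monotonicity,
severity-partition exhaustiveness), and parameter recovery at fixed seeds:
norm curves on a 400-writer planted cubic (mean curve within 5% of its
range, SD curve within 10%), 6-SD-separated Gaussian populations
(sensitivity and specificity ≥ 0.95), and a full
simulate→extract→fit→cluster run on a 250-writer cohort with strong
deficits (≥ 0.9 both). Determinism is asserted byte-for-byte on a
120-writer pipeline rerun. Cohort sizes in the tests (66–250 writers) were
chosen as the smallest at which the fitted curves and clusters are stable;
`scripts/acceptance.R` re-runs the pipeline at the emulated study's size
(390 + 58).

## Known limitations

* The feature catalogue's identifiers and the four-family partition follow
  the established convention, including its numbering gap; the historical
  count of "53 features" in parts of that literature refers to an earlier
  catalogue revision and does not match the 62 enumerated here.
* Norms require both genders and ≥ 20 children per gender spanning ≥ 3
  ages; smaller cohorts are refused rather than silently extrapolated.
* The in-air time ratio is inferred from between-stroke gaps; true in-air
  trajectories are not recorded.
* Laterality is stored but never conditioned on, and no longitudinal
  modeling is attempted.
* Absolute global-score values depend on the `exp(−d/d_ref)` calibration
  and are not comparable across differently fitted scales; severity bands,
  which are quantile-anchored, are.
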