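---
title: "Screening for cervical myelopathy from tablet shape tracings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for cervical myelopathy from tablet shape tracings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Cervical myelopathy (CM) — spinal cord dysfunction from cervical stenosis —
degrades fine hand control before it is diagnosed, and tracing simple
shapes with a stylus on a tablet is an attractive low-cost screen: the
device reports pen position and tip pressure at 120 frames per second, and
a clumsy, spastic hand produces slower, lighter and less steady tracings.
`cmscreen` implements the full analysis chain for such a screen: a data
model and file format for one-stroke pen recordings, a synthetic cohort
generator calibrated to published group statistics, extraction of the
three screening features, the seven shape-combination SVM models under
leave-one-out cross-validation (LOOCV) with ROC analysis, and the
group-comparison statistics of the standard clinical report.

Because the underlying clinical recordings are available only on request
from their authors, the package treats the *published summary statistics*
as its ground truth: the generator is calibrated so that features
extracted from raw simulated recordings reproduce the published per-shape
group medians, and everything downstream is exercised on those cohorts.

# Recordings and templates

A recording is an ordered series of samples `(t, x, y, pressure)` for one
participant tracing one guide shape in a single stroke. Coordinates are
screen points (origin top-left, y downward — the tablet convention; the
screening features never read them, but templates and simulation need a
fixed frame). Pressure is in device units on $[0, 4.166667]$, the device's
documented output range; timestamps are stored relative to first contact
so the drawing time equals the last timestamp. Files are plain CSV
(`t,x,y,pressure`) with a JSON metadata sidecar; a cohort is a directory
with a manifest. Validation flags non-monotone timestamps, out-of-range
pressures, and inter-sample gaps above 3 nominal sample periods — the gap
rule tolerates occasional dropped frames at 120 fps while catching pen
lifts; multi-stroke recordings are rejected from analysis by default or
trimmed to their longest stroke on request.

The three guide shapes are an Archimedean spiral ($r = b\theta$, traced
outward from the center), a square wave and a triangular wave (both traced
left to right, peak-to-peak twice their amplitude parameter). The study
guides' true on-screen dimensions are not published, so template geometry
(spiral: 3 turns, 40 pt spacing; waves: 3 cycles, 60 pt amplitude, 160 pt
wavelength) is a documented package default; tracing *durations* are
controlled by the simulator, not the template, so this choice does not
touch the features.

# The three features

For each tracing the package computes:

* **DT** — drawing time: the elapsed span of the tracing, in seconds.
* **AP** — average pressure: the mean of the pressure series linearly
  resampled onto a uniform 120 Hz grid (a time-weighted mean, robust to
  frame jitter), in device units.
* **SP** — SPARC, a spectral-arc-length smoothness score of the pressure
  change, dimensionless and negative; larger (closer to 0) = smoother.

SPARC computes the magnitude spectrum $V(f)$ of the analyzed signal
(zero-padded to $2^{\lceil\log_2 N\rceil + 4}$ points), normalizes it by
its DC value, $\hat V = V/V(0)$, finds an adaptive cutoff $f_c$ — the last
frequency below `fc_max` (10 Hz) at which $\hat V$ still reaches
`amp_threshold` (0.05) — and returns minus the polyline arc length of
$\hat V$ over $[0, f_c]$. Rough signals have longer, wigglier spectra, so
they score more negative. Two documented switches absorb the ambiguity in
"spectrum of the pressure change":

* `signal_mode`: the pressure series itself, or its first time-derivative
  (default). The derivative's spectral DC is the *net* pressure change of
  the tracing — a small normalizer — so high-frequency structure is
  amplified roughly in proportion to (fluctuation amplitude) / (net
  change), producing values in the tens-to-hundreds range. The pressure
  series' DC is $N \times$ (mean pressure), which grows linearly with
  duration while noise energy grows only as $\sqrt N$; its normalized arc
  length is therefore pinned near $-(f_c + \text{small})$ for any
  realistic tracing and cannot reach the published score scale
  ($-34$ to $-129$). That scale analysis is why the derivative reading is
  the default.
* `freq_normalized`: arc length over dimensionless frequency $f/f_c$ (the
  canonical form of the metric, values around $-1.5$ to $-5$) or over Hz
  (default).

In derivative mode a perfectly constant pressure trace has an identically
zero derivative; it is assigned the supremum score 0 rather than an error,
so that "smoothest possible" is representable. The metric is invariant to
positive rescaling of the signal in both modes, and each SPARC value is
checked in the test suite against a brute-force oracle (direct DFT by
explicit summation, explicit threshold scan, explicit segment sums).

# The cohort generator

The generator emulates the study conditions: 66 non-CM and 38 CM
participants, one tracing per shape each, 120 Hz sampling, pressure
clipped to the device range (clipped samples are counted; parameter sets
clipping more than 1% of samples are rejected by the calibrator, since
clipping breaks the pressure-level mapping). Demographics follow the
published cohort: ages log-normal with median (IQR) 69 (59–73) vs
66 (57–76) years, 58% vs 39% female, and CM participants receive JOA
severity scores (0–17, lower = worse; above 13 mild, 9–13 moderate, below
9 severe) allocated by exact counts in the published 9:18:11 proportion
with uniform scores within grade — exact counts make the severity table a
reproducible fixture rather than a multinomial draw.

Per participant and shape, a `subject_draw` collects the generative
parameters; the pressure model is

$$p(t) = \text{base} \;+\; \text{trend}\cdot(t/T - \tfrac12) \;+\;
  a_{\text{drift}} \sin(2\pi t/T + \varphi) \;+\; \varepsilon(t),$$

with base level, a centered linear trend with fixed net change
(magnitude 0.35 device units, sign random, capped at 0.8 × base for very
light pressers), a full-period sinusoidal drift (amplitude 0.15 × base,
random phase), and band-limited roughness $\varepsilon$ in 2–15 Hz
(above drift, below the 60 Hz Nyquist margin) with raised-cosine ramps
over the first and last 0.15 s (fluctuation attenuates at touch-down and
lift). The trend's fixed scale keeps the smoothness feature statistically
independent of the pressure-level feature, and pins the derivative
spectrum's DC so the SPARC-vs-roughness mapping is stable. The roughness
waveform uses constant-magnitude random-phase synthesis: its spectral
envelope is deterministic given the amplitude, which keeps
spectrum-derived features tight across equal-amplitude draws. The pen
position follows the template at constant arc-length speed plus low-pass
tremor (0.5 pt); trajectory fidelity is decorative here — none of the
three features reads coordinates — but it keeps the format and future
kinematic features exercisable.

Between-subject variation is log-normal per quantity (duration, pressure
level, roughness), parameterized by median and IQR: positive support and
right skew match the published asymmetric IQRs. A shared per-participant
factor induces mild positive correlation ($\rho = 0.3$) of each quantity
across shapes; no published value exists to validate $\rho$, so it is a
documented, configurable default. The sampler stratifies each latent
quantity over equal-probability quantiles (Latin-hypercube style,
rank-mapped so the correlation structure survives): a single simulated
cohort is then distributionally representative — its sample medians sit on
the generative medians — rather than an iid draw whose medians wander by
several percent at $n = 38$–$66$. Plain iid sampling remains available
via `stratified = FALSE`.

## Calibration

`calibrate_generator()` adjusts a group's parameters so that features
extracted from raw simulated recordings match per-shape targets. Duration
and pressure-level medians map one-to-one onto DT and AP and are set
directly. SPARC depends on duration (spectral resolution) and on the
roughness-to-trend ratio, so it is tuned last, by bisection in log space
on the roughness median against the median extracted SP of a fixed,
stratified calibration sample; the response is monotone (more roughness =
longer spectral arc), the bracket is verified, and the search fails loudly
if it cannot be established. Re-running the calibrator on already
calibrated parameters converges in zero iterations. The packaged defaults
in `default_group_params()` carry roughness medians produced by this
procedure (calibration sample of 200 subjects per shape, tolerance 1%) so
that a default cohort reproduces the published medians out of the box;
roughness IQRs inherit the spread of the published SP IQRs.

What a passing recovery test shows — and what it does not: the generator
matches the published *marginal* summaries (medians, IQR-scale spread,
group sizes). Real recordings additionally carry within-subject structure
across features and shapes, non-log-normal tails, device artifacts and
learning effects across trials, none of which the published summaries
constrain; conclusions about real-data classifier performance do not
follow from synthetic results (see Limitations).

# Screening models

All non-empty combinations of the three shapes give seven models; each
model's feature matrix has one row per participant and columns
(shape × {DT, AP, SP}). Evaluation is leave-one-out: for each held-out
participant the remaining rows are z-scored (means/SDs of the training
fold only — a leakage guard asserted in the tests), an SVM (radial kernel
by default, bandwidth from the median pairwise-distance heuristic, linear
by option) is trained, and the held-out decision value recorded. Decision
values are oriented so larger = more CM-like.

Raw SVM decision values are not comparable across folds: each fold has
its own offset and scale, and with a single held-out row per fold the
offset depends systematically on which class was removed, which biases
the pooled ROC toward chance (or, with per-fold class re-weighting, leaks
the held-out label outright). The package therefore standardizes each
fold's decision value by the mean and SD of the decision values on that
fold's *training* rows — training information only — before pooling; the
raw values are available with `standardize_scores = FALSE`.

The pooled scores give the ROC (thresholds swept over unique scores,
ties grouped, endpoints $(0,0)$ and $(1,1)$), the trapezoidal AUC (equal,
tie-corrected, to the Mann–Whitney $U/(n_1 n_2)$ — asserted to $10^{-12}$
in the tests), and the operating point: the vertex closest in Euclidean
distance to the ideal corner (sensitivity 1, specificity 1), ties broken
toward higher sensitivity, then higher specificity; on a fully degenerate
diagonal ROC this rule reports sensitivity 1 / specificity 0.

Hyperparameter tuning over the regularization grid
$C \in \{0.1, 1, 10, 100\}$ runs in two labeled modes.
`paper_faithful` (default) maximizes the aggregate LOOCV
sensitivity + specificity at the operating point over the grid (ties to
the smaller $C$, i.e. the larger margin) — the selection-optimistic
procedure matching the usual published description. `nested` selects $C$
per outer fold by an inner LOOCV, giving an honest out-of-sample
estimate; by construction its objective cannot exceed the aggregate
maximum, and reports always label which mode produced them. Whether the
original analysis normalized globally or per fold, and whether its tuning
was nested, is not stated in the source material, so both variants are
implemented and labeled rather than silently chosen
(`normalization = "global"` mimics the simpler behavior).

`cm_screen()` wraps all of this into one fitted object with `print`,
`summary`, `plot` (ROC with the operating point) and `predict` (retrain
on all participants with the tuned cost, classify new feature tables at
the stored threshold) methods.

# Group statistics

`comparison_table()` mirrors the standard layout: per shape × feature,
group medians with IQRs (type-7 linear-interpolation quantiles — reported
values depend on the convention, so it is fixed and documented) and the
Mann–Whitney two-sided p-value, flagged at 0.05 and reported raw — no
multiple-testing correction, matching the reporting style of this
literature. The Mann–Whitney statistic is $U = \min(U_a, U_b)$ from
midrank sums; the p-value is exact for pooled samples of at most 12
tie-free observations and otherwise uses the normal approximation with
tie and continuity corrections. (The exact and approximate p can differ
by up to 0.0155 for 6+6 tie-free samples — the worst case over all
configurations — which the tests assert as the true agreement bound.)
Demographics use the pooled two-sample t-test for age and the Pearson
chi-square without continuity correction for sex; the continuity
correction is an explicit flag because published values cannot adjudicate
the variant.

# Numerical and design notes

* Degenerate inputs: recordings need ≥ 2 samples (SPARC ≥ 4); an
  all-zero-mean pressure signal has no DC normalizer and errors in
  pressure mode; zero-variance feature columns inside a fold get unit
  scale with a note; single-class folds error.
* Resampling uses `m = round(duration × rate)` intervals so endpoints are
  preserved exactly; for whole-frame durations the effective rate is
  exactly 120 Hz.
* Determinism: every stochastic step is seeded; per-recording sub-seeds
  derive arithmetically from the cohort seed, so cohorts, feature tables
  and evaluation JSON reproduce byte-identically for a given seed.
* Problem sizes in the shipped tests: the study-sized cohort
  (66 + 38 participants × 3 shapes, seed 42) for recovery and
  discrimination checks; 2000 replicates for the Mann–Whitney type-I
  calibration; 50 random signals for the SPARC oracle; small cohorts
  (3–9 participants) for structural and pipeline tests.

# Limitations

* Calibration is to *marginal* medians/IQRs only. In particular, the
  relative ranking of the seven models on synthetic cohorts follows the
  published marginal effect sizes — under which the spiral carries the
  strongest pressure-level effect — and does **not** reproduce the
  published finding that the triangular-wave model screens best; that
  finding evidently rests on multivariate structure of the real
  recordings that summary tables cannot convey. Correspondingly, at these
  marginal effect sizes the triangular model's LOOCV AUC is only
  moderately above chance and its 99% bootstrap lower bound can fall
  below 0.5 on a typical cohort realization; the package reports this
  honestly rather than strengthening the generator beyond what the
  published summaries support.
* SPARC's exact parameterization in the original analysis is not
  recoverable; the mode flags and the calibration absorb the scale, and
  the calibrated roughness is interpretable only under the configured
  SPARC mode.
* The generator has no biomechanical hand model, no practice-trial
  learning effects (the study analyzed only the third tracing), and
  trajectory realism is minimal by design.
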