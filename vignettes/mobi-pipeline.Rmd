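---
title: "Models and methods of the MoBI Go/NoGo pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the MoBI Go/NoGo pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mobigng)
```

# The scientific problem

Mobile brain/body imaging (MoBI) studies record EEG, motion capture, and
task behavior simultaneously while participants act under combined
cognitive, motor, and sensory loads. The design this package implements
contrasts an ASD and a TD adolescent group across five conditions built
from three factors — standing vs treadmill walking (motor), static dots
vs radial optic flow (sensory), and performing vs not performing a visual
Go/NoGo task (cognitive) — yielding single- (S-NF-T), dual- (W-NF-T), and
tri-modal (W-F-T) task conditions plus two no-task walking controls. The
standing-with-flow-task cell is absent by design, which is why the
behavioral and ERP ANOVAs use a 3-level Condition factor rather than a
fully crossed Motor × Sensory design.

The pipeline's job is to turn the three raw streams into the study's
dependent variables and inferential statistics: signal-detection
behavior, stride-level gait kinematics, ERP component measures, and two
kinds of hypothesis tests (mixed repeated-measures ANOVA and pointwise
cluster maps with a consecutive-sample criterion).

# Behavioral model

Each trial is Go ('X', press) or NoGo ('O', withhold); NoGo trials occur
20% of the time within 180-trial blocks, stimuli last 400 ms, and the ISI
is uniform on 200–400 ms. A press 100–800 ms after an onset is assigned
to the most recent onset (first press wins); earlier presses are
anticipatory and attributed to no trial. This validity rule is this
package's own — trial length is 600–800 ms by design, and 100 ms is a
conventional anticipation bound — and is config-exposed.

Sensitivity is `d' = qnorm(hit_rate) - qnorm(fa_rate)`, positive for
above-chance performance. (A printed formula with the opposite sign
order would make every good performance negative, contradicting the
positive group means it accompanies, so the conventional orientation is
used.) Extreme rates are corrected before the probit, by default with
the log-linear rule (count + 0.5)/(n + 1); a clip to [1/(2n), 1 − 1/(2n)]
is available, and both are documented because the choice matters exactly
when a participant is at ceiling. RT is summarized over Hits only.

# Gait model

All gait metrics derive from the calcaneus (heel) markers at 100 Hz, in a
fixed axis frame: x mediolateral (positive right), y vertical, z
anterior–posterior (positive anterior). On a treadmill the heel is
dragged posterior at belt speed during stance and swings anterior during
swing, so:

* **heel strike** = local maximum of z (most anterior excursion),
* **heel lift** = minimum of z within the stride (most posterior),
* **stride time** = time between consecutive same-foot strikes,
* **stride length** = z(next strike) − z(lift), the literal AP distance,
* **step width** = |x_left − x_right| at each right heel strike,
* **CV%** = 100·SD/mean per block, with the sample (n−1) SD.

Peak detection uses local maxima with a minimum separation (default
600 ms) and a topographic prominence floor (default 20 mm), after an
optional zero-phase 50 ms moving average. The original workflow confirmed
peaks visually; a pipeline cannot, so a QC count of strides beyond 3 MAD
from the block median stride time substitutes as a reproducible flag.
Absolute (unsigned) lateral distance is used for step width; whether the
source work used signed distance is not stated, and the unsigned version
is invariant to marker left/right conventions.

# EEG and ERP model

Preprocessing follows the standard ERP chain: zero-phase band-pass
0.25–40 Hz (implemented as a 2nd-order Butterworth high-pass cascaded
with a 4th-order low-pass, each run forward–backward; channel means are
removed first so DC vanishes identically), average reference, and
bad-channel repair. Bad channels are those whose log-variance robust z
(median/MAD across channels) exceeds 3.5 or that are flat; they are
replaced by Perrin-style spherical-spline interpolation (order m = 4,
Legendre series to degree 7, regularization 1e-5). More than 25% bad
channels fails the recording. ICA-based artifact removal is deliberately
not in the default chain: no reproducible rejection rule exists to
implement, so the stage is a no-op hook.

Epochs span −100..800 ms around stimulus onset. At 512 Hz the package
fixes the sample convention as onset−51 .. onset+409, i.e. 461 samples —
the ms endpoints alone do not determine the span, so it is pinned and
tested. Baseline correction subtracts each channel's −100..0 ms mean
(standard practice; can be disabled). Averaging is subject-first:
subject averages per condition × response type, then the unweighted mean
over subjects, so unequal trial counts cannot tilt a grand average.

Peak measures use the two-pass window scheme: canonical windows (P2 FCz
200–280 ms, N2 FCz 280–380 ms, P3 CPz 350–500 ms) locate each group's
grand-average peak latency; definitive windows are that latency ±25 ms
(P2/N2) or ±50 ms (P3). `find_peak` returns the signed extremum,
prefers interior local extrema over window edges (flagging edge hits),
and breaks ties to the earliest latency for determinism. Peak amplitude
is the raw extremum; a mean-around-peak option exists because "average
peak amplitude" is ambiguous in the field's usage.

# Inferential machinery

**Mixed RM ANOVA.** One between factor (Group) and one or two within
factors, balanced within subjects, possibly unequal group sizes. The
implementation works on orthonormal within-subject contrast variables:
each within effect's hypothesis SS is the Type III quantity (the
unweighted group mean of contrasts for main effects; the group
discrepancy about the weighted mean for interactions), and its error SS
pools within-group contrast deviations. Greenhouse–Geisser ε comes from
the pooled contrast covariance, ε = tr(S)²/(q·tr(S²)), clamped to
[1/q, 1]; corrected and uncorrected p are always reported side by side,
with partial η² = SS_effect/(SS_effect + SS_error). The test suite pins
this against an independent multivariate-lm oracle (car::Anova with an
idesign) to 1e-8 on random balanced and unbalanced designs, and against
`aov` error strata on balanced ones.

**Cluster maps.** Pointwise paired or pooled-variance two-sample t-tests
over the full channels × time grid, then the run-length criterion: only
runs of ≥ 10 consecutive samples with p < 0.05 within a channel survive.
No spatial clustering crosses channels — that is exactly the procedure
described, which is a consecutive-sample (Guthrie–Buchwald-style)
criterion rather than a permutation test, so no permutation step is
implemented (a cross-channel variant exists behind a flag-level design
choice but is out of the default path). Zero-variance grid points get
t = 0, p = 1 rather than being dropped, keeping grid shapes stable.
The suite builds nine maps: 2 groups × 3 task conditions Hit-vs-CR
(paired), and per condition a two-sample map on per-subject CR − Hit
differences.

**Effect sizes.** Pooled Cohen's d with
s_p² = ((n1−1)s1² + (n2−1)s2²)/(n1+n2−2) for between-group contrasts —
the only variant recomputable from printed group means/SDs/ns — and
paired d (mean difference / SD of differences) for within contrasts.
The two-sample t uses pooled variance with df = n1+n2−2, matching the
printed df of the walking-speed contrast.

# The synthetic-data generator

The generator emulates the study's three streams with known ground
truth; its defaults are the study's design parameters wherever the
design states them (180 trials/block, 20% NoGo — exact by permutation
sampling, so the proportion is a testable property rather than a
binomial draw — 400 ms stimuli, 200–400 ms ISI, 64 channels at 512 Hz,
markers at 100 Hz, five conditions with S-F-T rejected).

Where the study does not print simulation parameters, defaults were
chosen once to sit near its printed group summaries and are labeled
synthetic, not estimates: hit/FA rates giving d′ ≈ 2.4 (TD) and ≈ 1.7
(ASD); log-normal RTs (the standard positive-support choice given only
means/SDs are printed) near 390–425 ms; ERP components as Gaussian bumps
in time with unit-sphere Gaussian spatial profiles
(exp(−angle²/2·spread²)) centered at FCz/FCz/CPz, with latencies chosen
so the two-pass windows land at the group windows the study reports
(e.g. TD P2 219–269 ms, ASD P3 355–455 ms) and CR-vs-Hit scale factors
strongest for the TD P3; gait parameters per group from the printed
means (TD step width 177.6 mm vs ASD 218.9 mm; stride-time CV 2.6 vs
3.8%), with belt speeds 0.845 and 0.657 m/s. Background EEG noise is
1/f-shaped (spectral slope −1, configurable), the textbook large-scale
EEG spectrum; gait-locked EEG artifact is not modeled by default because
the original removed artifacts by an unspecified ICA pass and a
controllable generator is worth more than an unverifiable artifact
model.

The gait generator realizes stride-time/length/width draws as Normal
jitter at the configured CV%, builds stance as linear posterior drift at
belt speed and swing as a raised-cosine return, phases the feet half a
stride apart, and interpolates the lateral traces through the drawn
widths at right-strike times, so every metric's ground truth is exact.

**What passing tests do and do not show.** The generator's EEG has no
eye blinks, muscle artifact, electrode drift, or gait-locked artifact;
its gait has no marker dropout or soft-tissue wobble; its behavior has
no sequential effects. Recovery within tolerances therefore validates
the pipeline's correctness — detection geometry, window logic, averaging
and statistics — not its robustness to every pathology of real
recordings. Real-data entry points (BDF/EDF, events TSV, marker CSV)
exist precisely so the same code paths run on real streams.

# Numerical choices and problem sizes

* Event latencies are 0-based sample indices end to end, converted to ms
  only for reporting, avoiding rounding drift across stages.
* EDF/BDF round trips are exact to the quantization step of the written
  physical range (2⁻²⁴ of it for BDF); marker CSV and YAML config round
  trips are lossless to < 1e-9. Event codes use an identity-scaled
  Status channel, with colliding codes shifted one sample so no trigger
  is ever lost.
* Peak ties break to the earliest sample; heel-lift ties take the
  earliest sample; degenerate (flat) grand averages are an error rather
  than an arbitrary peak.
* The ERP recovery property is evaluated at grand-average-equivalent
  noise: a group cell in the emulated study averages roughly 19 subjects
  × 3 blocks × ~130 valid trials ≈ 6–7·10³ trials, so 10 µV of raw noise
  leaves ≈ 0.12 µV in the average; the tests reproduce that residual
  with 200 trials at 1.6 µV RMS, where the ±4 ms / ±2·SE recovery
  tolerances are the binding constraints rather than estimator variance.
* Test problem sizes (chosen as the package's own validation scale):
  ~200-stride gait simulations, 50-seed ERP recovery runs, 100 random
  ANOVA designs against the oracle, 1000 null ANOVA simulations for
  type-I calibration, and 60-replication null cluster grids.
* The analysis drivers simulate 4 subjects per group with 60-trial
  blocks — the full design ratio at reduced depth — so the whole
  workflow runs on a laptop in minutes; `scenario_spec()` scales to the
  full 18/20-subject, 15-block design unchanged.

# Known limitations

* No source localization, time–frequency analysis, or gait-phase-locked
  EEG analysis; these were never in scope.
* ICA is a hook, not an implementation; with real data, artifact
  rejection must be supplied by the caller.
* The spherical layout is an idealized 10-20 construction, not a
  digitized montage; spline interpolation and spatial weighting are
  correspondingly idealized.
* Paired Cohen's d for within contrasts cannot be checked against
  printed values (difference SDs are not published); only pooled d is
  cross-validated.
* The consecutive-sample criterion controls isolated false positives
  but is not a family-wise error procedure; it is reported as the
  exploratory method it is.
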