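---
title: "Digit-tracking attention analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digit-tracking attention analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digitrack)
```

## The measurement model

Digit-tracking infers the allocation of visual attention without an eye
tracker.  An image is shown Gaussian-blurred, emulating the low spatial
resolution of the peripheral retina; touching the display reveals the
native-resolution image through a Gaussian aperture placed just above the
fingertip, emulating foveal vision.  Users therefore drag the aperture to
wherever they need detail, and the regularly sampled aperture centre plays
the role that fixations play in eye-tracking.  Both record types are
reduced to the same statistical object, a unity-normalised spatial density
of exploration (an *attention map*), after which every downstream analysis
(reliability, saliency readout, clinical scoring) is agnostic to the
recording device.

### Display geometry

All degree-valued parameters are defined through a `display_spec`.  The
package uses the linear small-angle conversion
\(\theta = (\mathrm{px}\cdot \mathrm{cm/px} / d)\cdot 180/\pi\) rather than
the \(2\arctan\) form: only the linear form is homogeneous (so "a 4000 px
path is 68°" and "1000 px/s is 17°/s" are the same statement), and it is
the convention under which the standard printed calibrations of both
canonical devices (46.5° tablet width at 32 cm; 39° monitor width at
50 cm) are reproduced.  For wide extents the two conventions diverge; a
reader comparing against the \(2\arctan\) value should expect a few
degrees of difference at 40°+ extents.  One printed calibration (46.5°)
matches the computed 46.553° only after truncation rather than rounding,
so the geometry self-checks accept either.

### Foveated rendering

Rendering parameters (`render_config`) default to blur σ = 40 px,
aperture σ = 110 px, upward shift 80 px, path threshold 4000 px.  Two
conventions had to be fixed because screen-space text rarely states them:
coordinates are 0-based with the origin top-left and y growing downward
("above the contact point" means smaller y), and the aperture blend is a
Gaussian alpha mask `out = a·native + (1−a)·blurred`,
`a = exp(−d²/2σ²)` clamped at 1 — the simplest reading of a "Gaussian
aperture window".  Blur uses reflective padding so image borders do not
acquire dark frames that would distort edge saliency.  The mapping from
blur σ to a psychophysical peripheral-acuity curve is deliberately *not*
modelled; the package exposes σ only.

### Stopping rule

A digit trial ends when the cumulative Euclidean path length of the
sampled track reaches the threshold (`truncate_at_path_threshold`): the
shortest prefix at or above threshold is kept, and an under-threshold
record is returned whole with a flag.  At the default 1000 px/s and
4000 px this makes a digit trial carry the same *quantity* of exploration
as a 4-s eye-tracking trial.  One numerical subtlety: the chord sum of a
sampled polyline slightly underestimates the true arc length wherever a
sampling interval straddles a direction change (about 2 px per corner at
60 Hz), so a simulated trajectory reaches threshold a few samples after
`threshold/speed`; the package treats the chord sum as the ground truth —
it is what a real device computes from touch samples — and the simulator
tests allow 2% slack on the duration arithmetic accordingly.

## Attention maps

Eye streams pass a dispersion fixation filter (radius 50 px, minimum
duration 50 ms): maximal runs whose samples stay within the radius of the
running centroid, split at sampling gaps longer than the minimum duration.
The exact algorithm behind commercial fixation filters is vendor-internal;
this dispersion rule is a documented stand-in sharing the two published
parameters.  Fixations enter the KDE weighted by duration; digit samples
enter unweighted (dwell time is already encoded in sample count).  The
KDE is an untruncated Gaussian kernel evaluated on the analysis raster
(default 1280 × 1024; bandwidth 30 px ≈ 1°, compensating measurement
imprecision of about one degree), with **no** per-point edge
renormalisation — unity normalisation (divide by the maximum) absorbs all
scale factors, which also makes maps invariant to uniform weight
rescaling.  Group maps are pixel means of per-subject unity-normalised
maps, re-normalised.  Correlations between maps are Pearson over all
raster pixels, unmasked.  The separable evaluation used internally is
algebraically identical to the per-pixel double sum and is oracle-tested
to 1e−9 relative.

Device records are brought into the analysis space by an aspect-preserving
scale-and-centre affine map (`transpose_to_analysis_space`), so tablet
(2736 × 1824) and monitor (1280 × 1024) data share one raster.

## Reliability statistics

*Inter-subject correlation* is the mean Pearson r over all unordered
subject pairs; pairs with a constant map are skipped with a warning, never
silently.  The *convergence curve* draws random subject orderings
(default 40), forms cumulative group maps for 1..N subjects, and records
for each n the percent of variance of the n-subject map explained by the
(n−1)-subject map.  "Percent of variance explained" is implemented as
100·r² between the two cumulative maps — the quantity is named but not
formalised in the source literature, so the estimator is pinned by a
hand-unrolled oracle test.  The minimal cohort size is the smallest n
exceeding the 95% level *stably* (every larger n also exceeds it); whether
the original criterion required stability is ambiguous, and the stable
reading was chosen because a transient crossing followed by a dip does not
constitute convergence.  *Split-half stability* correlates group maps of
two disjoint random n-subject halves, averaged over resamples.  All
resampling takes an explicit seed.

## The linear saliency readout

The saliency model is a linear readout over K aligned feature maps
(default K = 256 in the full-scale configuration; the synthetic bank used
in tests has K = 16 for speed).  Feature extraction is pluggable: any
`H × W × K` stack can be supplied (for example fifth-convolutional-layer
activations of a pretrained classification network, bilinearly
interpolated to the image raster), and the built-in bank provides semantic
blob channels plus smooth random fields.  The readout, not the feature
extractor, is the scientific object here, so no network is bundled or
required.

Two learners are provided.  `wCorr` estimates each channel weight
independently as the mean over images of the Pearson correlation between
the channel and the measured map; it is fast, bounded in [−1, 1], and
invariant to affine rescaling of either side.  The regression learner is a
lasso-regularised linear model (glmnet, regularisation chosen by 10-fold
cross-validation; pixel rows capped by deterministic stride subsampling,
default 60 000, for memory).  The original description mixes
support-vector and lasso vocabulary; lasso was chosen because it is the
regularisation actually named, and the two learners are held to the same
held-out prediction quality (within 0.05 CC) by test.  `wCorr` is the
default on the grounds of weight stability on small image sets.  Channel
standardisation before learning is off by default and not currently
exposed: the synthetic bank's channels are already on comparable scales.

Validation is leave-one-out: learn on all images but one, predict, score
with the Pearson CC against the measured map.  Note that "targets equal to
channel j gives CC = 1" holds only for an exactly orthogonal bank; with
realistic (spatially correlated) channels the other channels acquire small
sample correlations and CC ≈ 0.97–0.99 — the tests assert the honest
bound.  Channel ranking sorts weights descending with ties broken by
channel id; the chance probability that two independently learned
hierarchies agree on a prespecified top channel is 1/K (0.0039 for
K = 256).  Group comparisons of per-subject channel weights use two-sided
Wilcoxon rank-sum tests with Bonferroni correction over the channels
tested.

## Clinical deviation scores

The *exploration-neurotypicality score* of a subject is computed against a
reference cohort (default 10 independent neurotypical subjects per
picture): per picture, the mean correlation of the subject's map with the
reference maps is z-scored using the reference distribution of that
similarity; the z values are averaged across pictures; the average is
z-scored again against the cohort's distribution of averages.  Reference
subjects are scored leave-one-out, so the cohort's own members come out
with sample mean 0 and sd 1 exactly; whether the original cohort was
scored leave-one-out is unstated, and the LOO choice is ours.
"Z-transformed" is read as population standardisation, not Fisher's
r-to-z: both readings are monotone transforms of the same similarity, so
ROC/AUC discrimination — the quantity of clinical interest — is unchanged
by the choice.

Score distributions are fitted with a fixed-σ Gaussian kernel density
(σ = 0.6 score units, evaluated on a grid spanning the data ± 4σ,
integral 1 within 1e−3).  ROC curves sweep a threshold over the grid with
the orientation *lower score = atypical = positive call*; AUC is
trapezoidal and satisfies AUC(a,b) + AUC(b,a) = 1.  The binormal sanity
case (Δμ = 1, σ = 1) reproduces Φ(1/√2) ≈ 0.760.

The *laterality index* is the percentage of exploration mass right of the
display midline (x > width/2): duration-weighted for fixations, sample
counts for trajectories.  Against a reference cohort's indices it yields a
Z score and a normal-CDF centile, the convention used for bedside neglect
quantification.

## The synthetic world

The generator exists so that every module is testable offline, and its
defaults are fixed once:

* **Scenes** are Gaussian-blob compositions with semantic roles — two eye
  blobs (σ = 3% of width) inside a face blob (σ = 16%), an object blob,
  and a broad background — whose weighted sum *is* the ground-truth
  saliency (an exact construction identity, tested to 1e−12).  The default
  raster, 256 × 205, is the analysis space at 1/5 scale; the clinical
  benchmark runs at 1/10 (128 × 102) with the KDE bandwidth and jitter
  scaled accordingly.
* **Profiles** state populations as channel *mass fractions*: each channel
  is normalised to unit total mass before weighting, so preferences read
  as relative quantities of exploration independent of blob area.  The
  neurotypical preset (eyes 1, face 0.6, object 0.4, background 0.05)
  sends about half of all exploration to the eye region — the canonical
  top-attractor bias; the eyes-avoidant preset (eyes 0.1, face 0.9)
  collapses the eye-region share while preserving whole-face exploration;
  the neglect preset directs 85% of mass right of the midline.  An earlier
  per-pixel-weight parameterisation was rejected because broad channels
  then dominate by area and no stated phenotype is expressed.
* **Lateral bias** is enforced exactly: a sample's side is assigned before
  positional jitter and preserved by clamping at the midline, so the dial
  is unbiased under jitter (verified at large n).  The thin density ridge
  this can create at the midline is a documented simplification; `NA`
  disables the mechanism and leaves natural scene asymmetry untouched.
* **Explorers.**  Eye: fixation locations drawn from the profile density
  with Gaussian jitter (sd 8 px at the 256 raster ≈ 1.3° — the order of
  real calibration error), log-normal durations (median 250 ms,
  sdlog 0.5 — a typical free-viewing distribution; the source gives none),
  accumulating to the 4-s trial.  Digit: waypoints drawn like fixations,
  constant-speed linear motion between them sampled at 60 Hz, an optional
  stationary dwell at each waypoint ("slowing around regions of
  interest"), truncated at the path threshold.  `dwell_s` defaults to 0 so
  the duration arithmetic `threshold/speed` holds exactly; the population
  generator uses 0.25 s, without which a constant-speed track spreads most
  of its mass over inter-blob transit lines and no KDE can resemble the
  generating density.  Because of the transit mass and the jitter/kernel
  convolution, simulator-fidelity tests compare the group KDE against the
  *smoothing-matched* generating density (truth convolved with the
  jitter-plus-kernel Gaussian), which is the exact law-of-large-numbers
  limit for eye data and a close one for digit data; against the raw
  truth the correlation is systematically lower (≈ 0.8) and should not be
  read as a defect.

What a green synthetic test establishes: that the estimators recover the
quantities the generator encodes (preference hierarchies, lateral mass,
population separations) at the stated noise levels.  What it does not
establish: anything about real human exploration — real attention maps
have structured idiosyncrasies, scene semantics and inter-subject
correlations that blobs plus i.i.d. jitter do not emulate, and the
published empirical effect sizes (median map correlations ≈ 0.7, AUC
86–91%) are properties of human data that cannot be reproduced from a
desk.

## Numerical choices and degenerate inputs

Constant maps make Pearson r undefined: map correlation raises an error,
ISC skips the pair with a warning (erroring only if nothing remains),
LOO folds report `NA` and continue, and an all-zero prediction is returned
as a flagged constant map.  Zero cohort sd on a picture skips that picture
with a warning.  Rank-sum tests use exact enumeration up to n = 10 per
group without ties, else the normal approximation with tie and continuity
correction; fully tied inputs return p = 1.  All simulators are pure
functions of (parameters, seed); derived child seeds stay below 2³¹.

## Known limitations

* No binary image codec is assumed (none is available in the supported
  stack), so images are exchanged as plain-text PGM and arrays as
  TSV/JSON — adequate for analysis, not for production rendering.
* The fixation filter is a stand-in for vendor software; absolute fixation
  counts may differ from commercial filters even when maps agree.
* Digit kinematics are deliberately minimal (constant speed + dwells); no
  claim is made about human finger dynamics.
* The regression learner subsamples pixels for tractability; weights can
  differ slightly from a full-pixel fit (the recovery tests bound the
  consequences).
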