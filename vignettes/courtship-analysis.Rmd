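---
title: "Spatiotemporal analysis of male courtship around a fixed female"
author: "flycourt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal analysis of male courtship around a fixed female}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flycourt)
```

## The assay and its statistics

flycourt analyzes a reduced *Drosophila* courtship paradigm: a wingless,
legless virgin female is glued at the center of a 23 mm circular arena and
a male courts her for 10 minutes, filmed from above at 24 fps against a
bright backlit background. Because the female cannot move, every spatial
statistic can be expressed in her body-centered polar frame: the male's
angular position $\theta$ (radians, anterior $= 0$, wrapped to
$(-\pi, \pi]$) and his centroid distance $r$ (mm). The female's anterior
direction is random across trials and supplied as an annotation.

Four families of statistics are computed.

**Courtship path.** The angular space around the female is divided into
50 equal half-open bins partitioning $(-\pi, \pi]$ and the mean
male–female centroid distance is taken per bin over courtship frames.
Long low-motion contact runs (copulation attempts: speed $<$ 0.5 mm/s,
centroid distance $<$ 2.8 mm, sustained $\geq$ 30 s — thresholds
configurable, the assay literature states none) are masked out first,
because a male pressing against the female for minutes drags the nearby
bin means toward the contact distance.

**$D_A/D_P$.** The anterior maximum $D_A$ is the largest bin mean among
bins whose center lies strictly inside $(-\pi/2, \pi/2)$; $D_P$ is the
largest among the remaining bins; the ratio summarizes the
anterior–posterior asymmetry of the path. Empty bins never enter the
maxima (they are not interpolated — a conservative choice that only
matters for very sparse tracks). A bin center falling exactly on
$\pm\pi/2$ counts as posterior, following the strict inequalities in the
ratio's definition; with 50 bins the two boundary bins do sit exactly on
$\pm\pi/2$, but the profile is near its flank minimum there, so the
assignment does not affect the maxima in practice.

**Angular locations and circular tests.** For each courtship element the
circular mean and resultant length $R$ of $\theta$ over that element's
frames give the per-fly behavioral location; population statistics are
the unweighted circular mean and $R$ over per-fly means (per-fly
durations scale plot point sizes only — they never weight the test). The
Rayleigh test uses $R = |\sum e^{i\theta}|/n$ with the standard
large-sample approximation
$p = \exp\{\sqrt{1 + 4n + 4(n^2 - (nR)^2)} - (1 + 2n)\}$, which we
verified against Monte-Carlo nulls down to $n = 5$. The bimodal (axial)
test is *gated*: the raw angles are tested first; only when that test is
non-significant at $\alpha = 0.05$ are the angles doubled
($\theta = 2t \bmod 2\pi$) and retested. A significant doubled-angle test
yields the verdict *axial-bimodal* with axis = (mean of doubled)/2; a
non-significant one yields *uniform*. The gate matters: doubling a
unimodal sample also concentrates it, so an ungated axial test would
call tight unimodal clusters bimodal.

**Temporal indices and velocity.** Courtship latency is the time of the
first frame of the first annotated courtship bout (not the first
positive classification — classifications outside bouts are discarded,
so the bout is the semantic unit). The courtship index is
$t_{courting}/t_{trial}$; each element index is $t_{element}/t_{total}$,
normalized by courtship time, so the element indices plus the
none-within-courtship fraction sum to 1 exactly. Sideways velocity is
the magnitude of the male's velocity component perpendicular to the
male-to-female vector — in polar terms $r\,|\dot\theta|$ — binned into
the same 50 bins and summarized as $V_A$ ($|\theta| < \pi/4$), $V_P$
($|\theta| > 3\pi/4$) and $V_{ML}$ (the rest). The quarter-circle
sectors are a package choice (configurable); sector summaries average
the occupied bin means unweighted, and velocities are computed over
courtship frames only.

## Classification

Three binary classifiers — tapping, scissoring, orienting — score every
frame; precedence (active tapping, then stationary scissoring, then
stationary orienting) collapses the scores to one mutually exclusive
label per frame, and labels outside hand-annotated courtship bouts are
discarded. Each classifier is a discrete-AdaBoost ensemble of 100
depth-1 decision stumps (rpart is the weak learner; learning rate 1,
decision threshold at margin 0) — deliberately simple, matching the
behaviors' nearly rule-like definitions. Cross-validation is 4-fold and
*trial-grouped*: all frames of a video stay in one fold, since adjacent
frames are nearly identical and frame-level folds would leak.

The feature set is fixed in this package (the schema is shared verbatim
by the synthetic feature generator): male–female centroid distance and
its rate of change, translational/sideways/angular speed, heading error
(angle between male heading and the male-to-female direction), angular
position $\theta$ and $\cos\theta$, both wing angles and their maximum,
and ±5-frame window means of the kinematic features. These encode the
element definitions directly — tapping is courting within reach
(distance, speed), orienting is static gaze toward the female (windowed
speed below ~0.5 mm/s, heading error near zero, wings folded),
scissoring is orienting with a wing extended (wing maximum). Windowed
features use whatever frames exist near trial edges and skip gap frames.

## Tracking

Frames are segmented by background subtraction (dark flies on a bright
field). The background is the pixelwise median over up to 500 uniformly
sampled frames; the fixed female survives that median, so she is
segmented once from the background itself and each frame then
contributes the male's component. With an explicit clean background both
flies segment per frame, the two continuity-matched tracks are assigned
by motion (the low-variance track is the female), and two mobile tracks
are a hard error — the assay is violated. If both tracks are static the
wingless female provides the tie-break: the track with trailing wing
pixels is the male.

Poses come from image moments: a morphological opening (7 px disc at the
default 10 px/mm) erases the thin wings, the opened pixels give the
centroid and, via the second central moments, the body ellipse; wing
pixels are the component's pixels left outside the slightly inflated
body ellipse, split by side in body coordinates, each side's angle
measured at its outer pixels relative to the tail direction. The ellipse
axis is orientation modulo $\pi$; head–tail is resolved by (i) temporal
continuity, (ii) a majority vote aligning heading with displacement over
moving frames, (iii) the wings-trail-the-body prior when too few frames
move. Frames whose component count is wrong — including fly–fly contact,
which merges the blobs — are *gap* frames: NA poses, never interpolated,
skipped by every downstream statistic. On noise-free rendered video the
tracker recovers centroids to better than 0.1 mm RMSE, orientations to
better than 5 degrees, and wing angles to better than 8 degrees (asserted in
the test suite).

## The synthetic-data generator

Real videos for this assay are not redistributable, so the package
carries a generator whose defaults *are* the study conditions: 23 mm
arena, 24 fps, 600 s trials, cohorts of 62 flies, and a wildtype
scenario with tapping concentrated at the female's posterior (von Mises
$\mu = \pi$, $\kappa = 4$), orienting and scissoring at her anterior
($\mu = 0$, $\kappa$ = 2 and 2.5), occupancies
tapping/scissoring/orienting/none = 0.40/0.30/0.20/0.10 of courtship
time (the three elements together 90%), and an anterior-biased radial
profile with maxima 5.7 mm (anterior) and 3.8 mm (posterior) — a
generative asymmetry of 1.5. Red-light, headless, head-posterior and
white-eyed presets are pure parameter changes: axial mixtures for the
laws, flipped or flattened radial asymmetry, shifted occupancies. No
optics or surgery is simulated.

Choices the assay description does not pin down, fixed here once:

* **Radial profile.** $D(\theta) = D_P + (D_A - D_P)(1+\cos\theta)/2 -
  d_f \sin^2\theta$ with flank dip $d_f = 1.5$ mm. The dip gives the
  profile local maxima at *both* poles and a minimum at the flanks — the
  peanut-shaped path of a male skirting an elongated body, closest at
  her sides. A pure cosine blend ($d_f = 0$) would instead be monotone
  from head to tail, so the posterior half's maximum would sit at the
  $\pm\pi/2$ boundary at $\approx (D_A + D_P)/2$ and the measured
  $D_A/D_P$ would be $\approx 1.2$ regardless of the generative 1.5;
  with the dip, the measured ratio equals the generative one. The dip
  depth must exceed $|D_A - D_P|/2$ for both poles to be local maxima.
* **Bout structure.** Behavior bouts alternate with exponential
  durations (mean 2 s, minimum 0.25 s); courtship latency is exponential
  (mean 30 s); courtship bouts (mean 120 s) alternate with breaks (mean
  30 s). These are desk-scale stand-ins — the assay literature reports
  no bout-duration or latency distributions — and must not be read as
  empirical.
* **Bout scheduling.** The next bout's behavior is the one furthest
  below its occupancy quota, with a bonus for staying on the male's
  current side of the female. Quota balancing keeps realized occupancies
  within about one bout of their targets (well inside frame-level
  binomial error over a 10-min trial); side-stickiness keeps
  posterior-anterior dashes rare, as in real sequences.
* **Within-bout motion.** Each bout draws an anchor angle from its law;
  the male approaches it at a bounded angular speed (approach frames
  belong to the bout — an approach toward a tapping site is still
  tapping-bout behavior) and then holds with AR(1) angular jitter
  (stationary sd 0.15 rad for tapping, 0.03 rad for the static
  elements). Distances follow $D(\theta)$ plus smooth AR(1) noise (sd
  0.3 mm) on all courtship frames; outside courtship the male wanders at
  larger radii. All step series are rate-limited so consecutive-frame
  displacement respects the 35 mm/s speed bound, and headings turn at
  most 0.6 rad/frame — courting males face the female and sidestep;
  wandering males head where they walk.
* **Degenerate parameters.** $\kappa = \infty$ pins a law to $\mu$
  exactly (the sampler returns $\mu$, hold jitter collapses to zero), so
  degenerate scenarios are available for exact tests.

The renderer draws each fly as a filled dark ellipse (gray 30 on 230) at
its pose, the male's wings as thin trailing segments at the generated
wing angles, optionally with Gaussian pixel noise; ground truth
(centroids in px, orientation, wing angles) rides along. The synthetic
feature generator draws the classifier features directly from per-class
Gaussians around the elements' kinematic signatures, with a
`separation` dial: 1 = separable by construction, 0 = all classes
exactly exchangeable (a chance-level control used in the tests).

**What passing tests do and do not show.** The generator reproduces the
statistical structure the analysis assumes — behavior-dependent angular
concentration, radial asymmetry, bout structure, occupancies — but not
real image texture, legs, grooming postures, lighting drift, or real
bout dynamics. Recovery of the generative parameters therefore validates
the *pipeline's correctness* (transforms, binning, tests, masking,
classifier plumbing), not classifier performance on real video, which
always requires per-experiment retraining and validation against
hand-scored frames.

## Numerical choices

Angles are radians in $(-\pi, \pi]$ everywhere (`wrapAngle` maps $-\pi$
to $\pi$); lengths mm, times s; frame indices 0-based; bout intervals
half-open $[start, end)$. Derivatives are central differences (one-sided
at the ends), NA-propagating across gaps. Von Mises sampling is
Best–Fisher rejection. The Rayleigh p is clipped to $[0, 1]$. Bin
membership is $\lceil (\theta + \pi) / w \rceil$ clamped to $[1, 50]$.
The AdaBoost loop stops early on a weighted error of 0 (alpha capped) or
$\geq 0.5$. Fold assignment, bout scheduling and all noise draw from R's
RNG under explicit seeds: identical (scenario, arena, seed) inputs give
bit-identical trials, tables and CSV files; fly $i$ of a cohort uses
seed $+ i$.

Problem sizes in the shipped tests were chosen to keep the default suite
around five minutes on one core: full-length 600 s trials wherever a
distributional claim is tested (occupancies, angular laws, $D_A/D_P$,
element indices), a 62-fly cohort for the cohort-level recoveries, a
20 s rendered clip for tracker accuracy, 20 000-draw Monte-Carlo nulls,
and 200 replicates for the axial-verdict rate.

## Known limitations

* The feature schema is this package's normative definition, built from
  the elements' definitions; it is not guaranteed to match any
  particular deposited classifier's feature list.
* Contact (overlap) frames are gaps: tapping frames at literal contact
  are localized by their flanking frames rather than split from the
  merged blob.
* The tracker assumes exactly two flies, one of them fixed; it is not a
  general multi-animal tracker and does not handle 3D pose or
  appearance-based identity.
* Copulation-attempt thresholds, static-speed and proximity thresholds,
  and velocity sector boundaries are configurable defaults, not
  empirical constants.
* Population circular statistics are unweighted over flies; flies with
  zero frames of an element are excluded from that element's population
  test rather than imputed.

## A worked cohort

```{r cohort, eval = FALSE}
scenarioCfg <- wildtypeScenario(nFlies = 8)
trials <- generateCohort(scenarioCfg, arenaConfig())
ratios <- vapply(trials, function(tr) {
  track <- removeCopulationAttempts(toPolar(trackedTrial(tr),
                                            trueLabels(tr)))
  dadpRatio(courtshipPath(track))
}, numeric(1))
mean(ratios)   # recovers the generative asymmetry of 1.5
```

The full pipeline — including classifier training on a ground-truth
scored subset and every output table — is one call:

```{r pipeline, eval = FALSE}
res <- runPipeline(list(arena = arenaConfig(),
                        scenario = wildtypeScenario(nFlies = 8),
                        outDir = "wildtype_run"))
res$perFly[, c("fly", "latency_s", "courtship_index", "dadp_ratio")]
```
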