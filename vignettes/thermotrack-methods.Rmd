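---
title: "ThermoTrack: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ThermoTrack: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoTrack)
```

## The assay

The two-plate thermal place preference test exposes a freely moving mouse to
two adjacent plates held at different temperatures and records which plate
the animal occupies over a 5-minute session. The standard protocol runs nine
sessions whose plate pairs tile 0-45 °C in contiguous 5 °C steps — (0,5),
(5,10), ..., (40,45) — and each animal is measured at three timepoints:
before a neuropathy-inducing oxaliplatin injection, after oxaliplatin but
before a candidate analgesic ("pre-drug"), and after the analgesic
("post-drug"). The animal always starts each session on the colder plate.
Healthy mice prefer ambient temperatures of roughly 22-30 °C and treat
temperatures above about 34 °C as heat stress, so at cold sessions they sit
on the warmer plate and at hot sessions on the colder one. An analgesic's
effect is read out as the *loss* of a previously significant plate
preference, or its *reversal* toward the opposite plate.

ThermoTrack implements this workflow in four parts: an experimental-design
vocabulary (`standardProtocol()`, `PlatePair`), a stochastic thermotaxis
simulator with a video renderer, a frame-differencing tracker, and the
cohort statistics that issue preference and drug-effect calls.

## The thermotaxis agent

No behavioural model is implied by the assay itself, so the simulator uses
the smallest model that produces the three observable regimes (preference,
loss, reversal) with a single gain parameter.

**Comfort curve.** Thermal comfort is an asymmetric Gaussian bump

$$c(T) = \exp\!\left(-\tfrac{1}{2}\left(\tfrac{T - T_{opt}}{s(T)}\right)^2\right),
\qquad s(T) = \begin{cases} w & T \le T_{opt} \\ 0.75\,(T_{stress} - T_{opt}) & T > T_{opt},\end{cases}$$

with optimum $T_{opt} = 26$ °C (centre of the murine preferendum), cold-side
width $w = 10$ °C, and heat-stress onset $T_{stress} = 34$ °C. The narrower
warm-side width makes comfort collapse quickly past the stress onset, which
is what produces the colder-plate preference at the (35,40) and (40,45)
sessions. All three parameters are user-settable `AgentParams()` slots.

**Plate choice.** The agent attempts plate crossings as a Poisson process
with rate $\lambda = 0.15$ /s. An attempt on plate $i$ succeeds with
probability $\sigma(\beta\,(c_j - c_i))$, where $\sigma$ is the logistic
function and $\beta$ is the dimensionless preference gain (default 30). This
two-state chain has a convenient closed form: its stationary occupancy of
the more comfortable plate is $\sigma(\beta\,\Delta c)$, independent of
$\lambda$. At the default parameters that is about 0.91 at the (0,5) session
and effectively 1 at mid-range sessions — strong but imperfect preferences,
like the assay produces. $\beta = 0$ gives exactly 50/50 occupancy in
expectation, which is the null model used for calibration. The chain is
simulated by exact geometric sojourn sampling, so a 300 s session costs
microseconds and 500-cohort calibration studies stay cheap.

**Treatment effects.** An `EffectProfile` rescales the gain per timepoint
and per session ($\beta \mapsto \kappa\,\beta$; $\kappa = 0$ abolishes the
preference, $\kappa < 0$ inverts it) and can shift the comfort optimum. The
built-in `duloxetineProfile()` encodes a cold-selective analgesic
($\kappa = 0$ at (0,5), $\kappa = -1$ at (5,10), untouched elsewhere) and
`pregabalinProfile()` a non-selective one ($\kappa = 0$ at (0,5),
$\kappa = -1$ across (5,10)-(25,30)); both first sharpen thermal aversion
pre-drug ($\kappa = 1.2$) as a stand-in for oxaliplatin hypersensitivity.
`identityProfile()` is the exact identity.

**Movement and immobility.** Between crossings the position relaxes toward
the current plate centre (fraction 0.25 of the remaining distance per frame)
with Gaussian jitter (sd 2.5 px per frame at 10 fps), clamped so the
rendered blob stays in bounds. Each 10 s block is, with probability 0.1,
spent completely immobile — position frozen, chain paused. Immobility is
essential test surface: frame differencing is blind to a motionless animal,
so the tracker's fallback must be exercised. Per-animal trait variation uses
a log-normal multiplier on $\beta$ (sd 0.15 on the log scale) and a
Gaussian shift of the optimum (sd 1.5 °C), drawn once per subject so the
repeated-measures structure is genuine.

All randomness flows from one master seed through deterministic per-cell
streams, so cohorts, trajectories and rendered videos are bit-reproducible.
`simulateCohort()` tabulates occupancy from the same seeded chain that
`simulateTrajectory()` uses (a test asserts the equality), skipping only the
pixel-coordinate layer.

## Rendering

`renderFrames()` draws each trajectory point as a dark disc (radius 5 px,
intensity 40 on the 0-255 scale) on plate backgrounds of 200 (left) and 185
(right), adds i.i.d. Gaussian sensor noise (sd 5) and a slow sinusoidal
illumination drift (amplitude 6, one period per recording), clamps to
[0, 255] and rounds to integer intensities. The default arena is 128 x 64 px
at 10 fps — a 300 s session is 3000 frames, small enough that the full
ten-video benchmark runs in about a minute. Ground truth (blob centre and
true side per frame) travels with the `FrameSequence` and survives the PNG
round trip as `truth.csv`.

Pixel columns follow a half-open midline convention throughout: column $c$
belongs to the left plate iff $c < m$, with $m$ the first column of the
right plate (default: image centre, $m = 65$ at native resolution). This
makes side attribution unambiguous and testable at every layer —
trajectory, truth, mask counting.

## The tracker

Each iteration takes two frames separated by `stride` (default 1, i.e.
every adjacent pair) and applies, in order: bilinear resize (factor 0.5),
grayscale conversion (luminance weights 0.299/0.587/0.114 when input is
color), median filtering (3 x 3), absolute pixel-wise difference,
binarization (white where the difference strictly exceeds 15 on the 0-255
scale), a second 3 x 3 median filter to remove speckle, and a white-pixel
count on each side of the midline. The side with the larger count wins,
provided the total reaches `minMotionPixels` (default 5); otherwise the
iteration is "unknown". The absolute difference is used because a dark
animal darkens pixels it enters *and* lightens pixels it leaves — both
marks flank its position.

The median filter is implemented in compiled code with replicate-edge
padding and no intensity quantization, so constants are exact fixed points
and binary masks stay exactly binary; resizing and image I/O go through
EBImage. With `resizeFactor = 1` and `medianKernel = 1` preprocessing is
exactly the identity, which anchors the pixel-exact unit tests. A native
midline $m$ maps to $\lfloor (m-1) f \rfloor + 1$ post-resize.

**Stationary fallback.** Unknown iterations are resolved by carrying the
last determined side forward (leading unknowns are backfilled from the
first determined side): an animal that stops moving cannot change plates,
so physical continuity justifies the rule. A recording in which *no*
iteration ever resolves is an error, not a guess. Each iteration credits
`stride / frameRate` seconds to its resolved side; the final frame starts
no extra iteration, so seconds sum exactly and
`pctLeft + pctRight = 100` by construction.

Binarization uses a fixed threshold; with blob-background contrast of about
150 intensity units against noise of sd 5, the margin is wide, and the test
suite verifies that noise up to half the threshold moves session occupancy
by at most one percentage point. Exact left/right ties (`tiePolicy`
"hold"/"unknown") are left to the carry-forward rule either way.

## Statistics

Percent time per mouse on the two plates is complementary —
`pct_warmer = 100 - pct_colder` — so a two-factor plate x timepoint
repeated-measures model is singular. The analysis therefore models
`pct_colder` alone, which preserves both comparison families used in the
assay's figures:

* **Plate family (stars).** Colder vs warmer plate within a timepoint is
  the paired contrast of `pct_colder` against `pct_warmer`, i.e. a
  two-level family whose Tukey-adjusted p equals the paired comparison's p
  (a two-level studentized range *is* the paired t; the package computes it
  through the exact t distribution rather than `ptukey`, whose quadrature
  carries ~1e-4 error).
* **Timepoint family (hashes).** Percent time on the same plate compared
  across the three timepoints: Tukey HSD on the timepoint means using the
  error mean square of the one-way repeated-measures ANOVA
  (`rmAnova()`, classical sums-of-squares decomposition, verified in the
  tests against both a hand-computed fixture and `aov()`/`emmeans`).

No sphericity correction is applied by default — three levels and
cohorts of 8-10 leave little to estimate an epsilon from — but
Greenhouse-Geisser is available via `rmAnova(..., correction = "gg")`.
Significance labels use strict thresholds (`* p < 0.05` through
`**** p < 0.0001`; `p = 0.05` itself is "ns"). Families are corrected per
session, not jointly across the nine sessions. Tests are run on
percentages; seconds differ only by the affine factor `durationS / 100`,
which leaves every statistic here unchanged. Missing cells are an error
with the offending cells listed — silent imputation would change the test.
Degenerate cohorts (zero within-subject variance) are flagged and reported
at p = 1 rather than producing NaN.

`callPreference()` declares "warmer"/"colder" only when the adjusted p is
below alpha *and* the mean differs from 50; `callDrugEffect()` then
classifies each session by comparing pre-drug and post-drug calls:
maintained (same non-none direction), lost (preference gone), reversed
(direction flipped), or no_baseline (nothing to lose — excluded from
analgesia claims). The 3 x 3 direction grid is enumerated exhaustively in
the tests.

## Validation studies and their sizes

The acceptance script and `test-acceptance.R` re-run the package's
validation studies at the sizes the package documents as its reference
conditions:

* Tracker benchmark: ten 300 s videos (the nine standard sessions with the
  default agent, plus one indifferent wanderer), default render and tracker
  settings; per-iteration agreement with ground truth and the occupancy
  error per session.
* Noise-free exactness: a deterministic always-moving sweep, no noise, no
  resize, kernel 1; tracked side must equal truth on every iteration where
  the blob is clear of the midline in both frames.
* Stationary fallback: a blob that orbits on the left plate for 10 s and
  then freezes; the carry-forward rule must credit essentially the whole
  session to the left plate.
* Null calibration: 500 cohorts of 10 subjects with a zero-gain agent and
  identity effects; the plate-vs-plate test's rejection rate at
  alpha = 0.05 should sit near the nominal level. (The zero-gain agent is
  the null for this family: identity effects alone leave a real thermal
  preference in place at every timepoint.)
* Effect recovery: 200 cohorts per drug-like profile; the pipeline should
  call lost / reversed / maintained at the sessions the profiles target in
  a large majority of replicates.

## What the simulator does and does not emulate

The generator reproduces the features the tracker and statistics actually
consume: a dark mouse-sized blob on a lighter two-plate arena,
temperature-dependent side residence with realistic session-level
variability, cohort structure with stable per-animal traits, sensor noise,
slow illumination drift, and full immobility episodes. It does **not**
emulate shape change (rearing, grooming posture), shadows or reflections,
partial occlusion, abrupt lighting changes, camera shake, or multi-animal
scenes; nor does it model pharmacokinetics — treatment effects are
piecewise constant within a timepoint. Passing the synthetic benchmark
therefore validates the algorithmic chain (segmentation-free motion
localization, occupancy accounting, inference), not robustness to every
artefact of real recordings. Real deployments should check the tracker's
`nUnresolved` diagnostics and the debug occupancy series against a few
hand-scored sessions.

## Known limitations

* Frame differencing localizes *motion*, not the animal; the carry-forward
  rule covers stationarity, but an animal that freezes exactly astride the
  midline is credited to the side of its last detected motion.
* The comfort optimum of 26 °C makes the agent mildly prefer the colder
  plate at the (25,30) session, where real cohorts are near indifference;
  session-level comparisons at mid-preferendum temperatures are the least
  constrained part of the behavioural model.
* The plate-vs-plate test treats per-subject occupancy fractions as
  approximately normal; with few crossings per session the fractions are
  mildly heavy-tailed, and the null simulation shows rejection slightly
  above nominal (about 0.06 at alpha = 0.05) — within the package's
  documented calibration band.
* MP4/AVI containers are not decoded; recordings are consumed as numbered
  PNG/TIFF image sequences (any standard tool can explode a video into
  frames).
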