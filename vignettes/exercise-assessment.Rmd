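---
title: "Rule-based exercise assessment from skeletal streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based exercise assessment from skeletal streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exertrack)
library(dplyr)
```

`exertrack` measures and validates physical exercise from a depth sensor's
skeletal stream — the setting is a home exercise-assistance system for
older adults, where a sensor tracks 25 body joints at 30 frames per second
and the software must decide, in real time and with margins adapted to
elderly users, whether each repetition was executed correctly and how far
it went. This vignette explains the underlying model, the tunable
parameters and why their defaults are what they are, what the synthetic
data emulates, and the numerical choices that make the implementation
behave predictably.

## The skeletal model and its conventions

A frame holds 3D positions (metres) for the sensor SDK's standard 25-joint
skeleton. The sensor literature leaves the coordinate handedness and the
vertical axis open, so the package fixes a documented convention:
right-handed camera space with the origin at the sensor, +y up, +z pointing
from the sensor toward the user, +x completing the triad. All geometry is
convention-agnostic except two checks: torso tilt (which needs the world
vertical, +y) and the knee-over-toe rule (which needs the anteroposterior
axis; the user faces the sensor, so anterior is −z). If a capture cannot
guarantee the user faces the sensor, the knee rule is not meaningful —
this is a documented limitation, not a silent assumption.

The sensor's depth working range is 0.4–4.5 m. Frames with any joint depth
outside that interval are *flagged*, not dropped; calibration and
assessment refuse streams whose flagged fraction exceeds 10 % (a
configurable default — the intent is to fail loudly on a bad capture
rather than quietly analyze garbage).

Angles between segments are computed as `atan2(|u × v|, u · v)` rather
than `acos` of a clamped dot product: near 0° and 180° — exactly where an
upright knee or a hanging arm lives — the arccosine formulation loses half
its significant digits, while the atan2 form stays accurate to ~1e−12
degrees, which the rigid-motion invariance tests exercise at a 1e−9
tolerance.

## Calibration

Every exercise begins with the user standing relaxed in front of the
sensor for at least a second. The resting position of each joint is the
coordinate-wise mean over that window; the biometric limb vectors (arm SE,
forearm EW, thigh HK, shank KA) and their lengths derive from the means.
Calibration fails if any joint's per-axis positional standard deviation
exceeds 2 cm — a deliberately generous threshold, because elderly postural
sway is larger than the sensor's tracking jitter but genuine movement (a
step, an arm raise) is larger still.

A target angle θ for a shoulder exercise becomes a 3D goal coordinate: the
endpoint of the straight upper limb (length |SE| + |EW|) anchored at the
resting shoulder, rotated θ from the resting downward direction within the
frontal (camera x–y) plane, and reported to 5 decimals. Two choices here
were genuinely open. First, whether the "limb length" is the upper arm
only or the whole arm: the package uses the full upper-limb length, the
geometrically natural reading of an extended-arm goal (the alternative
would only rescale the sphere radius). Second, the frontal plane is
approximated by the camera x–y plane, consistent with the facing-the-sensor
interaction flow.

## Repetition segmentation and range-of-motion measurement

The stream of controlled-angle values (arm against the torso-down
direction for concentric exercises; knee angle for squats) is segmented
into repetitions by hysteresis relative to the calibrated resting angle: a
repetition opens when the excursion exceeds 10° and closes when it falls
back under 5°. Hysteresis, rather than a single threshold, prevents
tracking jitter at the boundary from double-counting repetitions; the
10°/5° pair is far above the jitter-induced angle noise (≈1° at 5 mm
jitter) and far below any meaningful exercise excursion. A repetition
still open when the stream ends is closed there, which keeps the
per-frame checks causal: truncating a stream never changes a violation
already committed.

Within a repetition the measure is the extremum of the controlled angle —
maximum for concentric exercises (higher is better), minimum knee angle
for the squat (lower is better; the correct squat range runs from 180°
upright to 90° with thighs parallel to the floor). The squat is bilateral
and the two knees rarely agree perfectly; the package reports the *worse*
(larger) of the two minima, so a one-legged squat cannot score as a deep
bilateral one. Measured angles are recorded to 5 decimal places, rounding
halves away from zero.

Before extremum-picking, the angle series is smoothed with a
Savitzky–Golay filter (polynomial order 2, window 9 ≈ 0.3 s at 30 Hz).
This filter reproduces locally quadratic peaks — which any smooth
trajectory is, near its extremum — essentially exactly: on a noise-free
raised-cosine repetition the recovered peak is within 5e−4 degrees of the
commanded one. Its value is on noisy streams: taking a raw maximum of a
jittered series biases the measurement upward by the expected maximum of
the noise (≈1.5–2° at 5 mm jitter), while the smoothed maximum stays
within a degree of truth. A plain moving average would also denoise but
flattens the peak by ~0.3°, failing the noise-free case.

## Tolerance margins and validity

Validity is a per-frame posture check over the whole repetition, governed
by a tolerance profile:

| margin | strict | elderly |
|---|---|---|
| torso tilt | 5° | 20° |
| knee advance beyond the foot | 0 cm | 10 cm |
| angular goal tolerance | 2° | 5° |

The strict column is the margin set for young adults without injury; the
elderly profile widens the torso-tilt allowance from 5° to 20° (arm raises
in older users typically recruit a compensatory lean) and permits up to
10 cm of knee-over-toe deviation in the squat. The angular goal tolerance
has no published value; 5°/2° are package defaults, applied *one-sided in
the direction of difficulty* (a concentric target of 90° is met at
≥ 85° under the elderly profile; a squat target of 100° at ≤ 105°) — a
margin meant to relax the goal must never penalize overachievement. An
invalid repetition never counts as meeting the goal, whatever its angle.
Margin comparisons carry a 1e−9 guard so a pose constructed exactly at a
limit (a 20.000° tilt) is accepted; without it the flip point would sit at
19° purely through floating-point rotation error.

Because the elderly margins dominate the strict ones component-wise,
validity is monotone: any stream valid under the strict profile is valid
under the elderly one. This is asserted as a property test.

## The isometric retraction rules

Scapular retraction is isometric — no joint angle moves appreciably — so
it is validated through distances rather than angles. With R, S, L the
right shoulder, upper spine and left shoulder, four conditions are
evaluated at each frame *t* ≥ *k* against the frame *k* frames earlier:
|RS| and |LS| must not shrink (shoulders moving away from the sternum),
|RL| must not grow (shoulders approaching each other), and
||RS| − |LS|| < ε (symmetric execution). The hold duration is the longest
contiguous span where all four hold; when a condition fails, the trace
records which one and which shoulder, so feedback can name the body part
to correct.

*k* trades responsiveness for permissiveness: small *k* compares nearby
frames and demands sustained deformation; large *k* tolerates brief
relaxation. The defaults, k = 10 frames (≈ 0.33 s) and ε = 3 cm, have no
published values and are exposed in the tolerance profile. On a monotone
deformation, decreasing *k* never lengthens the hold — another property
under test. Comparisons use a 1e−9 slack so that a perfectly static pose
(equality in all distance conditions) counts as holding, which is the
correct reading of non-strict inequalities.

## The swipe gesture recognizer

The interaction gesture is a horizontal hand swipe: the hand arms in a
starting band at half the user's height, sweeps along x keeping its height
approximately constant, and completes when it crosses the x-coordinate of
SPINE_MID toward the contralateral side. Three quantities have no
published values and are package defaults: the height band is ±0.1 × user
height around the halfway point, the same band defines "approximately
constant" during tracking, and the trunk-clearance test requires the hand
strictly beyond its own shoulder's lateral offset by 0.05 × user height.
The strictness matters: with a non-strict comparison and no margin, a
relaxed standing pose (hands hanging directly below the shoulders, i.e.
exactly at the shoulder offset, and — for typical proportions — inside the
height band) would arm the recognizer at rest, which contradicts the
intended behaviour that a motionless user produces no recognition.
Palm orientation cannot be inferred from joint positions and is not
checked. Recognition is mirror-symmetric, completion is a monotone prefix
property (extending a completed stream never changes the completion time),
and a trajectory that never satisfies the crossing predicate can never
complete — all fuzz-tested.

## What the simulator emulates, and what it does not

The simulator builds a parametric body from stature via fixed
anthropometric ratios (upper arm 0.186 h, forearm 0.146 h, thigh 0.245 h,
shank 0.246 h, shoulder half-width 0.129 h; the HEAD joint sits at
0.936 h, being the head's centre rather than the crown) and drives it
through raised-cosine joint trajectories sampled on an exact 1/rate grid,
so the commanded extremum lands on a frame and is achieved exactly before
noise. Noise is independent Gaussian displacement per joint, axis and
frame; 5 mm is the default jitter, a plausible magnitude for skeletal
tracking. What this does *not* emulate: occlusion dropouts, correlated
(low-frequency) tracking error, soft-tissue artefacts, biomechanical
coupling between joints, or fatigue within a session. Passing tests on
simulated streams therefore demonstrate the correctness of the rules and
measurements under the stated noise model, not robustness to every failure
mode of a physical sensor.

The study generator produces the longitudinal table (57 participants —
23, 19 and 15 in the age ranges 65–69, 70–74 and 75–80, genders balanced
29/28 — two exercises, six sessions) from a linear mixed model: group
baseline + participant effect (sd 3°) + session × improvement + residual
(sd 1.5°). The defaults are calibrated so the three qualitative
longitudinal patterns hold jointly: progress in every group over sessions,
absolute achievement decreasing with age, and improvement increasing with
age (+2/+3/+4° per session for abduction; −2/−3/−4° for the squat). The
last two patterns pull against each other: because older groups improve
faster, the cross-age gap shrinks over the six sessions by 10°, so
baseline gaps of 15° between adjacent groups (abduction 100/85/70°, squat
125/140/155°) are needed to keep every same-session cross-age contrast
decisively separated (p < 0.001) through session 6 while keeping
within-group session contrasts significant at p < 0.01. With narrower
baseline gaps the two requirements become jointly unsatisfiable under
this noise level — that trade-off, not realism alone, fixes the defaults.

## Nonparametric analytics

The progress statistics mirror standard practice for small, outlier-prone
ordinal-ish samples: the Mann–Whitney U test for independent
distributions, the Wilcoxon signed-rank test for paired series (pairing by
participant removes the subject effect), and Spearman's rank correlation.
The package implements them directly with midrank tie handling; the exact
branches enumerate the full null distribution (all `choose(n, nx)` label
arrangements for U when `nx + ny ≤ 12` with no ties; all `2^n` sign
assignments for the signed-rank test when `n ≤ 12`) and the large-sample
branches use normal approximations with the usual tie corrections, without
continuity correction. Two-sided p-values throughout — the sidedness of a
reported contrast is otherwise ambiguous, and two-sided is the
conservative reading. `stats::wilcox.test` (which makes different
exact/approximate choices) serves as an independent oracle in the test
suite, not as the implementation.

`progress_report()` applies the session contrasts (2,4), (2,6), (4,6)
within each group — sessions 2, 4 and 6 as reference points avoid both
first-session misunderstandings and the instability of consecutive
measurements — and compares adjacent groups within each session with the
Mann–Whitney test only, since the signed-rank test has no pairing across
independent groups. Distribution summaries use boxplots with whiskers at
the 10th and 90th percentiles and extreme values as points beyond them.
Degenerate cases degrade to notes rather than failures: a missing session
yields a reported gap; two identical sessions yield a "signed-rank
degenerate" note (all paired differences zero) while the Mann–Whitney
column is still filled.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (simulator noise,
study generation), and every generator is bit-reproducible given its seed.
The test suite and the acceptance script run entirely on synthetic data
generated at run time: single-repetition streams of a few seconds at
30 Hz for the geometry and assessment checks, 31-point tilt sweeps and
21-point knee-advance sweeps for the tolerance flip points, and 100-seed
replicate batches (57 × 2 × 6 records each) for the stochastic
power/type-I properties of the study analytics — sizes chosen so the
whole suite completes in a few minutes on one core while leaving the
stochastic assertions enough replicates to be stable.

## Known limitations

* The knee-over-toe rule proxies "the tip of the feet" by the FOOT joint
  and assumes the user faces the sensor; a rotated user invalidates the
  anteroposterior axis.
* Exercise goal achievement is assessed on the measured angle, not on the
  3D distance to the rendered goal point; the two coincide for an
  extended limb but can differ when the elbow bends.
* The shipped 52-exercise catalog is a systematic set of template
  instances faithful to the family counts and movement types; individual
  physiotherapist-authored prescriptions should be supplied as a catalog
  file.
* The score formula (100 × mean clipped achievement ratio) is a documented
  package convention; published systems describe scoring and rankings
  qualitatively.
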