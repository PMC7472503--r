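---
title: "Methods: automatic REBA scoring from 2D keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic REBA scoring from 2D keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quickreba)
```

## The model and its assumptions

REBA is an observational screen: a working posture is decomposed into
body parts, each part's angle is banded into a small integer score, the
scores are combined through three lookup tables with load, coupling and
activity modifiers, and the resulting 1–15 grand score maps to one of
five musculoskeletal-disorder risk levels. `quickreba` automates the
angle measurement and the observational judgments from a single 2D
skeleton (the 18-keypoint COCO layout of convolutional-pose-machine
estimators, plus a synthesised mid-hip), under the following
assumptions:

* **Single frame, single person.** No tracking, no temporal smoothing.
* **Planarity.** All angles are measured in the image plane. A camera
  viewing the sagittal plane measures flexion angles well; out-of-plane
  rotation (twist) is *not* measurable as an angle and is instead
  inferred from exposure (below).
* **Absence is information.** A keypoint below the confidence threshold
  is absent; absent joints propagate as undefined angles, paired parts
  fall back to the recognised side, and only when *both* sides of a
  required part are missing does the assessment fail, naming the part.

## Kinematics

The absolute limb angle is the full-quadrant arctangent of
$(\Delta y, \Delta x)$. The single-argument arctangent form of the same
quantity is undefined for vertical limbs — the *common* case, since an
upright trunk is vertical — so the two-argument extension is used
throughout; on its principal branch it agrees with the single-argument
form exactly.

REBA references postural angles to the vertical, so absolute angles are
rotated (`to_vertical_reference()`): a vertical limb maps to 0 and the
sign convention follows the body region (above-neck limbs keep the
signed deviation, below-neck limbs invert it). Inside the full pipeline
a sharper, deterministic sign rule is used: **flexion toward the body's
facing direction is positive**. The facing direction is inferred from
face anatomy — the nose is anterior to the ear midpoint — with
nose-vs-neck and eye-midpoint fallbacks, defaulting to image-left when
no face is visible. The anatomical cue was chosen over nose-vs-neck as
the primary rule because the latter is degenerate for a neutral upright
head, exactly the posture where a stable default matters.

Hinge joints (elbow, knee) use the relative angle between adjacent limb
vectors, the arc-cosine of the normalised dot product, in $[0, 180]$
with 0 = straight. The neck is measured **relative to the trunk line**
(standard REBA practice); a global-vertical alternative sits behind
`reba_config(neck_reference = "vertical")`. The neck's distal point is
the nose by default (`neck_distal = "ear_mid"` is available) — the
skeleton model does not offer a dedicated head-top point.

**Wrists.** The 18/19-joint model has no hand keypoints, so wrist
flexion cannot be measured; it defaults to 0° with a low-confidence
marker, and wrist *twist* is judged from externally supplied hand
exposure instead. Consequently the shipped posture profiles declare 0°
wrist targets.

## Heuristics and their thresholds

All thresholds live in `reba_config()`:

| parameter | default | units | meaning |
|---|---|---|---|
| `confidence_threshold` | 0.1 | fraction | keypoint presence cut-off |
| `twist_threshold` | 0.30 | fraction | chest/face exposure at or below ⇒ twisted |
| `leg_delta_threshold` | 30 | degrees | knee-angle difference ending bilateral support |
| `kneel_threshold` | 90 | degrees | flexed knee beyond ⇒ kneeling |
| `gravity_trunk_min` / `gravity_arm_max` | 45 / 20 | degrees | gravity-assisted arm window |
| `shoulder_threshold` | 25 | degrees | neck–shoulder line fold ⇒ shrug |
| `wrist_flip_threshold` | 0.30 | fraction | hand exposure at or below ⇒ wrist twist |
| `chest_width_ratio` | 0.75 | — | expected shoulder span / trunk length |
| `face_width_ratio` | 0.8 | — | expected ear span / neck–nose length |

Threshold comparisons are **inclusive** where the rule is phrased as
"reaching" a value (exposure 30 %, leg delta 30°) and **strict** where
it is phrased as exceeding one (kneeling > 90°). The exposure ratio is
operationalised as observed-over-expected transverse width, the
expectation coming from the skeleton's own scale via the anthropometric
ratios above (shoulder span ≈ 0.75 × trunk length and ear span ≈ 0.8 ×
neck–nose distance are ordinary adult proportions); the definition is
isolated in `exposure_ratio()`/`skeleton_exposures()` so an alternative
(e.g. reduction-relative-to-baseline) is a drop-in. The gravity-assisted
window (trunk ≥ 45°, arm ≤ 20°) instantiates "trunk bending large, arm
bending small" with the worksheet's own trunk/arm band edges, since a
deterministic, auditable rule is required.

## Scoring

Angle-to-score bands follow the canonical worksheet: trunk 1–5 (+1
twist), neck 1–3 (+1 twist; any extension scores 2), legs 1–4 (base 1
bilateral / 2 otherwise, +1 knee 30–60°, +2 beyond 60°), upper arm 1–6
(+1 shrug, −1 gravity **after** the addition, floored at 1), lower arm
1–2 (60–100° of elbow flexion is the good band), wrist 1–3 (+1 twist).
Scores A/B add load/coupling (0–3 each), clamp at 12 into Table C, and
the activity score (0–3, a user input — no automatic repetition
detection) completes the 1–15 grand score.

The three tables ship as CSV data (`inst/extdata/`) with recorded MD5
checksums, because transcription typos are the dominant failure mode for
worksheet tables; the test suite holds a *second, independently typed*
transcription in a different layout and checks the composite chain
cell-for-cell over the exhaustive 138 240-case domain.

## Numerical choices

* **Band-boundary stability.** Before banding, angles are rounded to
  10⁻⁹ degrees: a synthetic 20° neck otherwise recovers as
  20° + 10⁻¹⁴ and flips a score bin.
* **acos conditioning.** Relative angles of near-straight hinges lose
  about half the floating-point digits (acos near 1); property tests
  compare them with an absolute 10⁻⁵-degree tolerance, while the
  forward–inverse round trip itself is exact to well below 10⁻⁶ degrees.
* **Degenerate input.** Coincident joints raise a degenerate-limb error;
  a zero expected width raises a degenerate-skeleton error; both-sides
  missing parts raise a missing-data error naming the part.
* **Ties and degeneracy in statistics.** Spearman uses average ranks;
  the weighted-kappa p-value uses the large-sample null standard error;
  constant series and zero-variance differences raise explicit errors
  rather than returning NaN.

## The synthetic generator

`build_skeleton()` chains limb vectors from the mid-hip root at the
profile's ten target angles, so `compute_angles()` is its exact inverse
— the noiseless pipeline is an identity, which pins down every sign
convention by construction. Twist and shrug flags are realised
geometrically (shrunken shoulder/ear spread; folded neck–shoulder
lines), so the heuristics recover them too. The twelve shipped profiles
(`inst/extdata/postures.json`) are parameterised reconstructions of
common standing/stooping/kneeling/lifting tasks in the style of
ergonomic assessment worksheets; the true angles of any particular
photographed posture set are unpublished, so the profiles are
**representative, not replicas**, and ship as editable data rather than
code. Occlusion by a carried object is modelled as forced dropout of
the hidden wrist.

`perturb()` adds isotropic Gaussian displacement per landmark plus
independent dropout, seeded and restoring the caller's RNG state. For a
limb of length $L$ with endpoint noise $\sigma$, first-order error
propagation predicts an angular error of $\sigma\sqrt{2}/L$ radians;
the Monte-Carlo test (1000 replicates, $L$ = 100 px, $\sigma$ = 3 px)
agrees within 25 %.

What the generator does **not** emulate: perspective and lens
distortion, body-shape variation, correlated estimator error (real pose
nets fail jointly on occluded regions), and out-of-plane twist as an
actual 3D rotation (twist is *injected* via the exposure geometry the
heuristic reads). Passing benchmarks therefore demonstrate the internal
consistency and noise robustness of the pipeline, not field accuracy on
photographs.

## Problem sizes

The test suite runs the exhaustive 138 240-case scoring equivalence,
100-instance oracle batteries per statistic, benchmark runs of 12
postures × 3–4 repeats at a few noise levels, and the 1000-replicate
error-propagation check; the whole suite completes in well under a
minute on one CPU. `scripts/acceptance.R` re-enumerates the full scoring
domain at run time.

## Known limitations

* Shoulder abduction (arm raised sideways, out of plane) is not
  detected; it is genuinely hard from a single 2D view.
* The wrist score rests on the hand-exposure input; with no hand
  detector it defaults to the non-penalising state.
* The twist heuristic conflates "twisted" with "viewed in profile":
  a full-profile photograph of an untwisted worker reaches the same low
  exposure. Interpreting exposure relative to a frontal baseline image
  would disambiguate, and the isolated definition makes that swap easy.
* Expert judgment of load/coupling/activity is taken as given input
  (0–3 each), not estimated from the image.
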