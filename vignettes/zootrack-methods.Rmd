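---
title: "Motion-feature tracking of captive animals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-feature tracking of captive animals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The shared motion model

All three applications in `zootrack` rest on the same movement measure.
For each frame triple — the current frame $I_a$ and its two
predecessors $I_b$, $I_c$ — the double difference

$$I_{dif-dif} = \max\bigl(|I_a - I_b| - |I_b - I_c|,\; 0\bigr)$$

is binarized and cleaned by a morphological erosion followed by a
dilation, $I_{mov} = D(E(I_{dif-dif} > \tau))$. The subtraction of the
older difference removes the trail the animal left between $I_c$ and
$I_b$, so the surviving features concentrate on the newly covered
pixels, i.e. on the animal's current position. The count of nonzero
feature pixels (`features_nmb`) measures movement strength; the
"counting box" — an exhaustive stride-1 search for the window
containing the most features — localizes the main movement cluster,
whose feature centroid is the raw position. Features outside the
per-view useful-information polygon are deleted by a ray-casting
point-in-polygon test before any analysis.

Optical-flow and Kalman approaches are deliberately absent: the targets
here show abrupt speed and direction changes and strong illumination
changes, which break the brightness-constancy and motion-linearity
assumptions those methods need.

Numerical conventions, chosen once and used everywhere: intensities in
$[0,255]$; 0-based pixel coordinates, $x$ rightward, $y$ downward;
half-open rectangles $[x, x+w) \times [y, y+h)$; pixels outside the
image are background for both morphological operators; points exactly
on a polygon edge count as inside; counting-box ties resolve to the
smallest box origin ($y$, then $x$); color input converts to gray by
Rec.601 luma weights.

### Tunable parameters of the core

| parameter | default | meaning |
|---|---|---|
| `threshold` | 15 gray levels | binarization of the double difference |
| `erosion_size` | 3 px | square element removing isolated noise |
| `dilation_size` | 5 px | square element re-connecting the cluster |
| `box_w`, `box_h` | ~animal size | counting-box window |
| `relevance_thr` | app-specific | features needed for a relevant cluster |

The defaults suit targets moving several pixels per frame. The erosion
step erases motion bands thinner than the element, so the monkey and
panda pipelines — where slow walks at 1–2 px/frame matter — run the
core with `erosion_size = 1`, `dilation_size = 3` and a raised
`threshold = 20`; at that threshold the additive sensor-noise model
(below) contributes well under one false feature pixel per frame, which
is why the erosion can be dropped there.

## Rat behavior analysis

**Stage 1 (top view, head pose).** Scene geometry is recomputed every
frame because the experimenter can nudge the camera. A binarization
threshold is searched (Otsu's criterion first, then a sweep) until the
column projection of the dark pixels yields exactly five clusters under
proximity conditions (width and spacing bounds; thin second and fourth
clusters): the two box ends, the two middle-room walls, and the rat
itself. The middle-room walls $b_1, b_2$ are the midpoints of clusters
2 and 4. Frames failing the test are skipped.

The body is the largest connected component between the walls after
erosion with a 5×5 element — large enough that the 2–3 px tail never
joins the body; the eroded component is then reconstructed into the
binary image (conditional dilation) so the body box regains its true
extent. Head voting for elongated bodies: vote 1 compares body-pixel
counts of the two end flanks (strip width 1/3 of the box; "significantly
fewer" means a ratio below 0.8); vote 2 scans thin strips just outside
the box ends (1/4 box width, offset 3 px so the un-eroded body edge
cannot leak in) for the tail, a dark concentration around the midline,
and puts the head opposite. Agreement gives a certain decision; a
single reliable vote decides; on strong contradiction the tail vote
wins; otherwise the decision is deferred. Two consistent previous head
positions pre-empt the voting. Near-square bodies (turn-arounds) use
the previous movement direction, or emit the two best candidates.
Offline, ambiguous frames take the candidate closest to the next
reliable position (scanning right-to-left so resolved frames anchor
their predecessors) and deferred frames interpolate.

**Stage 2 (side view, visits).** Per frame, cage parameters
$0 < c_{11} < c_{12} < b_1 < b_2 < c_{21} < c_{22}$ come from the
column projection: outermost dark clusters are the cages, the two
clusters strictly inside $(c_{12}, c_{21})$ are the middle-room walls;
ordering violations skip the frame. The moving rat is tracked with the
counting box; frames without a relevant cluster keep the last position
(a resting rat stays where it was). Compartment membership uses the
mass-center $x$ against $(b_1, b_2)$ only. An entry is a compartment
change sustained at least `debounce` frames (default 3; boundary
flicker is folded into the running visit); the compartment the track
starts in counts as a visit but not as an entry.

## Monkey localization and head orientation

The cage is unevenly lit and the animal can switch the light, so each
frame carries a light indicator (mean intensity against a threshold).
A gray-level template ("model") of the head-mounted sensor box is
stored only when the scene is lit and the movement cluster is relevant,
the edge map shows the box's ring (edge count within a configured band
around the center, with an edge-free immediate vicinity), and the
center neighborhood is dark. The coarse cluster centroid is first
refined to the centroid of the dark mass in its vicinity (two
fixed-point iterations over a window sized to cover the box), which
removes the leading-edge bias of motion features. During tracking, a
candidate near the previous position must additionally achieve a
normalized cross-correlation of at least 0.7 against the model over a
small offset search; the match validates the detection while the
position itself stays at the dark-mass center, and the template is
refreshed after each accepted frame. A very relevant cluster far away
restarts tracking (with a fresh model); a uniform frame restarts the
whole process; in the dark the search is restricted around the previous
position so the animal's shadow cannot hijack the tracker.

The confidence index is the product
$100 \cdot w_{region} \cdot s_{match} \cdot 0.9^{it-1}$, with one extra
factor 0.9 when a resumed recognition coincides with a great
motion-trait count. The product form is this package's construction —
the factors (region reliability, match score, iteration penalty) are
given, their combination is not. Only localizations with confidence
strictly above 75% feed the orientation stage.

Orientation: the ROI is inflated by half its size in every direction,
converted to HSV, the value channel Gaussian-smoothed and binarized at
a threshold mapped linearly into $[30, 60]$ by the ROI brightness.
Among dark contours with area above 500 px, the one with the largest
filling index (pixel area over minimum-bounding-rectangle area) is the
sensor box; the long side of its minimum-area rectangle (rotating
calipers over the convex hull) gives the angle in $[0°, 180°)$.
Orientation is not attempted on light-off frames — the fixed
binarization band presumes a lit scene — and the 1-D filter estimates
those angles from their neighbors. The filter replaces each angle by
the windowed mean of the valid members (computed, confidence ≥
threshold; window `t = 11`), after unwrapping the members modulo 180°
about their median so a 178°/2° run averages near 0°, not 90°.

## Panda tracking, fusion, and stress analysis

**Per camera.** Movement strength is banded by three thresholds
`low < mid < high` (configured per camera, scaled to its view). A
session starts only on: (a) very strong movement — flagged as the zoo
technician when the rectangle height matches the technician profile
inside the technician gate; (b) moderate movement in a gate area; or
(c) moderate movement at the previous valid position. Within a session
each frame becomes `movement`, `freezing` or `no_information` exactly
per the three-band rules (freezing persists for an animal last seen in
an observable zone; door-area watches continue restrictively;
near-static mid-band rectangles after movement freeze). Candidate
movement frames are rejected on area bursts (ratio > 3), teleports
(further than 2 rectangle diagonals while in a visible zone, unless a
dark-mass body check contradicts the old position — the branch-play
case), direction reversals (angle above 90°), and, on general-view
cameras, bird-like detections outside the zone corresponding to the
previously fused zone. The search area is confined around the position
after movement, widened to the whole information polygon otherwise; on
the basin camera, water motion flooding the zone while the bear bathes
behind the stones restrains the watch to a window beside the last
observable position. A session ends after an exit through a gate
(position at a gate with sustained feature loss) or a long static run.

**Fusion and filtering.** Per synchronized frame the observation with
the most observable bear wins: out-of-zone and technician candidates
are dropped, the rest ranked by zone type (full > door > partial),
movement before freezing, ground cameras before general views, with
ties going to the previously selected camera. The fused list has
exactly `min(frame counts)` entries, initialized null. Compaction
replaces short foreign-camera insertions between large same-camera runs
by the main camera's own positions (or affine-transferred coordinates);
the same substitution mechanism, applied over several passes, also
compacts the freezing–moving switch and repeated-path contexts — those
contexts are a reconstruction, since only the first filtering pass is
described in full. Gaps of 2–100 frames bounded by the same camera are
linearly interpolated (movement if either boundary moves, else
freezing); longer or cross-camera gaps stay. Attributes are
majority-voted in a centered window (ties keep the current value).
Velocities are Euclidean displacements between same-camera neighbors,
weighted per camera (world-units-per-pixel times a resolution
normalization) and then window-averaged over valid samples.

**Stress classes.** `running`: $v > thr_{v1}$. `walking1`:
$thr_{v2} < v \le thr_{v1}$ in a moving series that follows a period in
a complete-visibility zone. `walking2`: the same band after a still
period at the garden housings. `walking3`:
$thr_{v3} < v \le thr_{v2}$ after a housing still period when the path
section shows a height — a point at least 20 px (configurable) from the
total-least-squares line of the section. `stationary`: camera-8 series
near the basin longer than 5 s. Label runs are cleaned before episode
extraction: interruptions up to 1.5 s inside one class are bridged and
runs under 1 s dropped — transition noise from the velocity window
otherwise splinters episodes. Episodes report start/end times,
durations and the dominant camera.

## The synthetic scenes

Every pipeline is exercised on seeded renderers with exact ground
truth; no external recordings are needed.

* **rat1** (320×240, top view): bright floor, four dark wall bands (the
  rat's own projection is the fifth cluster), a tapered dark ellipse
  body (56×22 px, head end thinner) with a thin tail, shuttling with
  pauses and 1-s turn-arounds — at least four per minute.
* **rat2** (320×120, side view): full-height dark cages at the sides,
  two-thirds-height wall bands at $b_1, b_2$, a dark ellipse following
  a visit plan (default includes a 70 s cage visit), plus a small
  random wander.
* **monkey** (320×240): horizontal illumination gradient, a dark
  rotated rectangle (44×18 px) for the sensor box, scripted light-off
  intervals (global dimming ×0.2 plus a jittering shadow blob 70 px
  from the resting animal), and a feeding-like burst outside the
  information polygon.
* **panda**: a 960×540 world projected by four affine cameras
  (480×270): two unit-scale ground views splitting the ground area, two
  half-scale general views. Six refuge gates, a housing band, a
  full-visibility zone, a basin occluded from the general views with
  two foreground stones and ripple speckle while the bear bathes, a
  technician column at the technician gate, and a bird crossing the
  general views. The 120 s default script produces, in order: a dash,
  a walking-1, a walking-2 and a zigzag walking-3 segment, a second
  dash, and a >5 s basin dwell, with per-frame ground-truth labels.
  Camera streams have deliberately unequal lengths.

Problem sizes were chosen so a full four-camera analysis of the 2-min
scenario completes in a few minutes on a laptop core: 10 fps rendering,
480×270 views, additive Gaussian noise σ = 3.

What the renderers do *not* emulate: articulated bodies and appearance
change, perspective distortion (panda projections are affine),
occlusion other than the scripted refuge/stone cases, compression
artifacts, and gradual illumination drift. Passing tests therefore
demonstrate the correctness of the algorithmic chain under the stated
geometry and noise model — not field performance on arbitrary footage,
where the unquantified constants (feature-count bands, edge-count
ranges, reliability weights) would need per-installation calibration,
exactly as they did in the original deployments.

## Design decisions on genuinely open points

* Unstated constants (difference threshold, structuring-element sizes,
  counting-box size, feature bands, Canny-style hysteresis thresholds,
  "close vicinity", "greatly surpassed", technician profile, zone
  hierarchy, filter windows) are configuration with the defaults listed
  above; each was fixed once from the geometry of the scenes.
* The interpolation and velocity formulas are implemented as linear
  interpolation and Euclidean distance — the only readings consistent
  with their surrounding text.
* The confidence combination is a product; any monotone combination
  gated at 75% would serve, and the product keeps the factors
  interpretable as independent attenuations.
* Angle averaging pre-unwraps modulo 180° about the window median; the
  0/180 wrap is otherwise a hidden failure mode of a plain mean.
* The per-camera view-boundary bands of the two ground cameras are
  configured as gates, so the state machine treats leaving a camera's
  half like leaving through a door; without it a camera would claim a
  frozen ghost position indefinitely and poison the fusion ranking.
* Edge detection is a Sobel-gradient, double-threshold hysteresis
  detector (weak components kept only when touching a strong pixel):
  the classic recipe minus non-maximum suppression, which the edge-count
  conditions do not need.
* The light-off orientation skip and the dark-mass centroid refinement
  are this package's additions; both are documented above and testable
  in isolation.

## Known limitations

* The head-pose voting assumes a single rat whose tail is thinner than
  the erosion element; overlapping animals are out of scope.
* Stage-2 tracking reports the motion centroid, which leads the body
  center during fast motion by up to the animal's half-length; visit
  timing absorbs this (crossing bias is a fraction of a second) but
  instantaneous positions are not body centers.
* Walking-1/2/3 context detection inspects a fixed lookback window
  (3 s); a bear that idles in an unzoned gap between areas can lose its
  context.
* The compaction filter's passes beyond the first are a parameterized
  reconstruction; their contexts are named but not specified in the
  source material.
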