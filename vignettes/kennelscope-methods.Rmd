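---
title: "Methods: depth-video behaviour analysis for a kennel-housed quadruped"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-video behaviour analysis for a kennel-housed quadruped}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kennelscope quantifies the behaviour of a single quadruped — typically a
shelter dog — confined in a pen, from a side-mounted depth camera. This
vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic generator does and does not
emulate, and the design choices made where the problem was genuinely open.

## 1. Scene model and segmentation

The pen is modelled as a set of planes (one floor, solid walls, a
see-through wire fence) in a metric pen frame: origin at the pen corner
nearest the sensor's left edge, x along the front fence, y into the pen, z
up. The camera is a pinhole model (default 320x240, 58 degrees horizontal
field of view, mounted 1.5 m above the floor, 2 m in front of a 3x3 m pen).
Depth frames store the camera-frame z coordinate in millimetres; 0 marks
invalid pixels, which are excluded from every computation.

Foreground extraction back-projects each valid pixel to 3D and discards
everything within a threshold of any calibrated plane or outside the pen
volume. The threshold defaults to 5 cm: comfortably above the depth noise
of consumer sensors (about 5 mm standard deviation at these ranges), and
below the clearance of a standing animal's belly. The largest 8-connected
component of the surviving pixels is the animal blob; components smaller
than `min_pixels` (default 200 at 320x240) are a no-detection. Connected
components come from `EBImage::bwlabel` (4-connectivity) followed by a
union-find merge of diagonally adjacent labels.

The blob's barycentre is the arithmetic mean of its 3D points. Note that
this is the centre of the *visible surface*, not of the body volume: it
sits a few centimetres toward the camera, and the bias direction changes
with viewing angle. Over a 2 m crossing of the pen this shortens the
measured displacement by roughly 2-4 cm with the default body radius — an
inherent limitation of single-view depth segmentation that users should
keep in mind when interpreting distances at centimetre precision.

Bird's-eye trajectories are produced by a ground-plane homography fitted
with a normalised DLT on floor points implied by the scene model (no manual
calibration). Each barycentre is first dropped orthogonally onto the floor
plane, then projected through the camera and mapped by the homography.
Corner reprojection error above 1 cm aborts with a calibration error.
Out-of-pen projections are clamped to the pen bounds and flagged rather
than dropped, so downstream alignment always sees gap-free trajectories.

## 2. The skeleton and its solution-vector encoding

The animal is a seven-part skeleton: head, torso, tail and four legs, each
a line segment. A frame's labelling is encoded as a 16-value solution
vector: per part, an in-plane orientation angle and a projected length
(seven parts x two values), plus the two components of the ground-plane
motion vector of the barycentre between consecutive frames. Parts absent
in a posture (folded legs when sitting or lying) use a zero-length
sentinel so the encoding is total across postures. The decoder re-anchors
the geometry deterministically: torso midpoint at the barycentre, head at
the torso front end, tail at the rear end, legs at the quarter points —
so encode/decode round-trips exactly on the quantised candidate grid.

## 3. Structured max-margin body-part labelling

Candidates are enumerated on a grid under anatomical constraints: torso
orientations through the barycentre (24 angles by default) crossed with
lengths spanning 0.5-1.1 of the blob extent (5 by default), head and tail
relative orientations (8 each), and joint leg placements (6). Posture
classes restrict the grid further: `stand` and `lie` keep the torso near
horizontal in the image, `sit` requires a raised front (the torso
direction points diagonally upward, facing either way), legs are
enumerated only where the posture has standing legs, and the `lie` class
omits legs entirely. Legs always point below the torso. The tests and the
acceptance experiments run a reduced grid (12 angles x 3 lengths x 4
head/tail angles x 3 leg placements, 1728 candidates per frame) so that
brute-force oracle audits stay cheap; the same code paths run at any grid
size.

The joint feature map phi(x, y) samples the blob appearance along each
candidate segment (7 points per segment by default): mask occupancy,
depth relative to the barycentre plane, and the height of the observed
surface above the pen floor split into rectified low/high half-features.
The height split matters: with a single signed height feature, each
posture model's training data spans too narrow a height range to fix the
weight sign, and maximisation exploits the ambiguity on out-of-class
blobs. Two additional blocks complete phi: occupancy at points offset
perpendicular to the torso (a standing torso shows an under-belly gap
below; sitting and lying torsos show floor-contact mass), and the motion
components with a torso/motion alignment term that lets training orient
the torso along the direction of travel. A frame whose blob is empty
yields an all-zero appearance block with the motion block passed through.

Training is an online passive-aggressive approximation of max-margin
structured learning. For each training pair the ground-truth skeleton is
snapped to the nearest grid candidate (loss: mean in-plane endpoint
distance, normalised by the torso length); each visit finds the
loss-augmented argmax and moves the weights so the ground truth outscores
it by a margin equal to its loss, with the step capped at C. Pair order
is shuffled with a fixed seed per epoch, and the *averaged* iterate is
returned — the mean of the weight trajectory generalises markedly more
stably than the last iterate under online updates. Defaults: 2-3 epochs,
C = 0.2-0.5 depending on the experiment (the conservative cap is used for
the learning-curve study, where slow, stable learning matters more than
fast convergence). Inference is the exhaustive argmax over the candidate
set; ties break to the lowest candidate index.

## 4. Posture scoring across the three classifiers

One structured classifier is trained per posture (stand, sit, lie), each
on frames of its own class only, and a frame's posture is the class whose
classifier produces the best score. Taken literally with raw linear
scores this is ill-posed: the three models are trained independently, so
their scores share no scale, and — more subtly — maximisation actively
exploits weight dimensions whose sign was never constrained by the
model's own training class, inflating scores on out-of-class blobs. We
therefore attach to each trained model the Gaussian statistics of a
compact *fit descriptor* over its own training fits — torso inclination,
barycentre height above the floor, fraction of blob points below 0.2 m,
95th-percentile blob height, torso length relative to the blob extent,
and mean occupancy along the fitted legs — and classify_posture scores
each model by the class-conditional penalty of its fitted solution's
descriptor (variance floor 0.03; the fit-dependent dimensions are capped
at 2 so no single implausible facet dominates). Blob-shape dimensions
count in full. Per-model additive offsets remain available as a user
knob, and ties break in the documented order stand > sit > lie.

This is the package's answer to an open calibration question, and its
limits are visible in the data: postures that genuinely interpolate
between sit and lie (rump down, torso held high) move the descriptor
smoothly from one class's statistics to the other's, so boundary frames
are confused between sit and lie — and essentially only between sit and
lie, which is exactly the error structure one expects from observers too.

`locomotion` is derived, not fitted: frames labelled stand are relabelled
when the barycentre speed over a centred 0.5 s window exceeds 0.1 m/s.

## 5. Ethogram

Durations are frame counts times the frame period; a bout is a maximal
run of one label (an optional minimum-bout filter, default off, merges
shorter runs into their predecessor); the interval table covers the
recording with a possibly short final interval. Frames with unknown
posture are excluded from label durations but kept in the total as
`unscored`. The pen floor divides into a 3x3 grid of half-open cells
indexed row-major from the pen origin, so boundary positions are never
double-counted, and occupancy, durations and interval tables each sum to
the total recording time to within one frame period by construction.
Activity metrics: distance is the summed consecutive displacement (path
length), time moving the duration of frames whose instantaneous speed
exceeds 0.1 m/s.

## 6. Unsupervised movement-pattern discovery

Recordings are partitioned into contiguous windows of nominal length 5 s
(a trailing remainder shorter than half a window is dropped; a longer one
is kept truncated). Windows are compared by Needleman-Wunsch global
alignment of their symbol sequences with the scheme: a symbol pair with
similarity c_b scores 2*c_b when c_b >= 0.5 and 2*(c_b - 0.5) below, i.e.
+2 for a perfect match and -1 for a complete mismatch; a symbol aligned
with a gap scores 0. The zero gap score deliberately tolerates temporal
stretch, so the same movement performed at different speeds still aligns
well. The score table uses the standard three-way recursion; with a zero
gap score the base row and column are zero (for nonzero gap
configurations we use cumulative sums, the standard convention). The
traceback breaks ties diagonal > up > left for determinism.

Two symbol types are supported. Trajectory symbols are ground positions
with c_b = exp(-||p-q|| / scale); the scale defaults to 1 m — the bare
negative exponential of the distance — which separates within-pen
patterns well in a 3 m pen. Action symbols are skeleton-graph
descriptors: the six body-part junctions form a graph whose edges join
junctions consecutive along the torso or sharing an attachment point,
weighted exp(-delta_theta) with delta_theta the unsigned 3D angle between
the two non-torso segments at the edge's endpoints. The normalised
Laplacian L = I - D^(-1/2) W D^(-1/2) of this graph summarises the pose;
two poses compare through the first k (default 3) non-trivial
eigenvectors, c_b = |det(Ba' Bb)| — 1 for identical subspaces, 0 for
orthogonal ones. Because only internal angles enter, the descriptor is
invariant to rigid rotation and uniform scaling of the skeleton, i.e. to
the animal's position, heading and size. Eigenvector sign (largest
magnitude entry positive) and the discard of exactly one trivial
component make the basis deterministic.

K-medoids runs on distances d = max(S) - S (any monotone decreasing
transform preserves the medoid structure; the global maximum keeps the
matrix symmetric). Initial medoids are drawn with a seeded RNG and
single-medoid swaps are applied greedily while the sum of within-cluster
distances to the medoid decreases; windows are reported ordered by
distance from their medoid, most representative first. The cluster count
is a user decision, as it should be for an exploratory tool.

## 7. The synthetic generator

The generator stands in for the depth camera: an articulated quadruped
(capsule primitives per segment, z-buffered over the pen planes) plays a
motion script at 10 frames per second in the 3x3 m pen, with additive
Gaussian depth noise (default 5 mm) and exact ground-truth masks,
skeletons, postures and trajectories. Posture templates: standing
shoulder height 0.45 m; sitting with the rump on the floor and the front
nearly at standing height; lying at torso-radius height with all legs
folded. A lambda parameter interpolates continuously from canonical sit
to canonical lie for ambiguous-posture fixtures. Scripted path
primitives (stay, line, circle, perimeter, pace) reproduce the classic
confinement patterns: perimeter circling, half-pen circling, side pacing
and corner standing.

What it does *not* emulate: fur and surface texture, self-occlusion
beyond what the capsule geometry produces, long-haired or very
short-legged morphologies, sunlight saturation artefacts, multiple
animals, and the rolling-shutter/holes noise structure of real
structured-light sensors. Passing tests on this generator therefore
demonstrate internal correctness and the qualitative behaviours of the
method — learning curves, confusion structure, pattern recovery — not
field accuracy on real recordings.

## 8. Problem sizes and numerical choices

The test and acceptance experiments use: 320x240 frames; the reduced
1728-candidate grid; a learning-curve study over training sizes
67/128/228/385 drawn from 930 frames of three animals with proportions
varied by up to 25%, all four postures mixed, evaluated on 60 held-out
frames and averaged over 5 seeds; posture models trained on 60 frames per
class and evaluated on held-out renders with shifted headings and fresh
noise plus 24 sit/lie interpolation fixtures; clustering on the 3/2/3/2
pattern composition at jitter 0 and 0.1 m. Alignment oracle checks
enumerate all global alignments for windows up to length 6. Degenerate
inputs are handled explicitly: empty blobs are no-detections, zero-length
segments carry sentinel encodings and angle 0 in the graph, constant
duration vectors leave Spearman's rho undefined rather than NaN, and
duplicated homography correspondences raise a calibration error rather
than returning a rank-deficient fit.

## 9. Known limitations

Single-view surface barycentre bias (section 1); posture calibration is
descriptor-based rather than a property of the margin training itself
(section 4); the candidate grid quantises part geometry, bounding
achievable part-localisation accuracy by the grid step; leg occlusion in
foreshortened views (animal facing the camera) is the dominant source of
part error; and the generator's idealisations listed in section 7.
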