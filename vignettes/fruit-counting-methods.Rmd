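---
title: "Counting fruit by tracking-by-detection: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting fruit by tracking-by-detection: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitrack)
```

## The problem

Estimating orchard yield from a walk-through video is a multi-object tracking
(MOT) problem: a detector proposes per-frame bounding boxes around fruit, a
tracker links the boxes into identities, and the number of distinct confirmed
identities is the fruit count. The dominant error mode is *identity
switching*: when a fruit is occluded by leaves, branches, or other fruit and
later reappears, a purely geometric tracker often opens a fresh identity, and
every such switch inflates the count by one. `fruitrack` implements a
multiple-rematching tracker (MR-SORT) that adds appearance-based
re-identification, plus the evaluation metrics and a synthetic orchard
simulator so the whole pipeline can be exercised and tested without any
external data.

## The tracking model

The tracker follows the modern tracking-by-detection recipe with two additions
(the rematch stages and their validation):

1. **Motion model.** Each track carries an 8-dimensional constant-velocity
   Kalman state over `(cx, cy, w, h)` and the per-frame velocities. Process
   and measurement noise standard deviations are scaled to the box size with
   weights 1/20 (position) and 1/160 (velocity), the convention of the
   BoT-SORT family of trackers. Before association, every state is advanced
   one frame and warped through the estimated camera motion.
2. **Camera-motion compensation.** A global affine transform between
   consecutive frames is estimated from sparse Harris keypoints matched by
   normalized intensity-patch descriptors, with a random-sample consensus fit
   and a least-squares refit on the inliers. Fits with fewer than 6 inliers,
   or whose linear part has determinant outside `[0.5, 2]`, fall back to the
   identity — coasting uncompensated is safer than warping through a bogus
   estimate.
3. **Two-stage association by confidence.** Detections are split at
   `track_high_thresh` (0.5) and `track_low_thresh` (0.1). High-confidence
   detections are assigned to tracks first, low-confidence ones to the
   remaining tracks second, both by minimum-cost one-to-one assignment
   (Hungarian algorithm) on the cost `1 - IoU`, gated at `match_thresh` (0.5).
   Low-confidence leftovers are discarded; high-confidence leftovers with
   score at least `new_track_thresh` (0.7) open tentative tracks.
4. **Appearance rematch (the "multiple rematching").** After each IoU stage,
   leftover detections and leftover tracks get a second chance: the
   detection crop's VLAD signature (below) is compared against the track's
   stored signatures by cosine distance, gated at `appearance_thresh` (0.5),
   assigned one-to-one, and finally checked by the displacement-consistency
   validation. Lost tracks stay eligible for all stages for `track_buffer`
   (30) frames, which is what allows a fully occluded fruit to be
   re-identified when it reappears.

Tracks are tentative until their second consecutive match (tracks opened on
the very first processed frame are confirmed immediately — no earlier frame
could corroborate them), confirmed tracks receive sequential ids from 1, and
the count is the maximum id ever issued.

## Appearance signatures

A region's appearance is summarized as a VLAD vector (Vector of Locally
Aggregated Descriptors): local descriptors are extracted at sparse keypoints,
each descriptor's residual to its nearest codebook centroid is accumulated
into that centroid's slot, and the concatenated vector is power-normalized
(signed square root) and L2-normalized. The codebook is fitted once per video
by seeded k-means (`codebook_k = 8`) on descriptors pooled from the first
frames' detections. Power normalization is standard VLAD practice; it damps
bursty descriptors.

The descriptor backend is pluggable by name. The built-in backend (`"patch"`)
is a Harris corner detector followed by a mean-centred, L2-normalized 8x8
intensity patch (64-d). Classical SURF/SIFT/ORB implementations are not
available as R bindings, and the method depends only on "a local descriptor
plus VLAD", not on a specific descriptor; any deterministic keypoint
descriptor slots in.

Two details matter for robustness:

* **Degenerate signatures.** A textureless crop yields no descriptors and an
  all-zero VLAD vector. Such signatures carry no evidence: similarity against
  them is the sentinel `NA`, never a number, and a degenerate crop can never
  pass an appearance-only rematch (it can still match geometrically).
* **Gallery of two.** Each track stores its best-scoring view and its most
  recent confident view, and rematching uses the better of the two
  similarities. Refreshing is restricted to detections with score at least
  `new_track_thresh`, so the shrinking sliver of a fruit disappearing behind
  an occluder does not pollute the stored appearance with a half-visible
  crop — exactly the views needed when the fruit reappears.

## The displacement-consistency validation

Appearance matching over small textured regions is noisy. The validation
mechanism exploits a rigidity property of orchard scenes: different regions
of the same (static) scene exhibit the same frame-to-frame displacement. A
candidate rematch is accepted only if its displacement agrees with that of an
independently matched *anchor* region — the highest-IoU pair from the first
association stage — within a pixel tolerance; with no anchor the check passes
vacuously.

Because a lost track may have been invisible for `k` frames, raw
displacements are not comparable across pairs. Both displacements are
therefore measured *per frame*: `(detection center - last observed center) /
gap`, where the gap is the number of frames since the track was last matched.
The tolerance is 10 px at a reference width of 1920, scaled proportionally to
the frame width, with a floor of 5 px: detector jitter is absolute in pixels
and does not shrink with resolution, so a purely proportional tolerance would
spuriously reject valid rematches on small frames.

## Evaluation metrics

* Detection: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, average precision
  as the area under the all-point interpolated precision-recall curve
  (precision envelope, step integration) at IoU 0.5, and mAP as the mean of
  per-class APs. Metrics are kept as fractions internally; percentage
  formatting is a presentation concern.
* Tracking: CLEAR-MOT accounting. Per frame, ground truth and results are
  matched by IoU-gated minimum-cost assignment with match persistence
  (previous pairings are kept while still above the gate). `MOTA = 1 -
  (misses + false positives + switches) / ground-truth boxes`; IDS counts
  identity changes between a ground-truth identity's consecutive matched
  frames.
* Counting: `MAE = mean(|predicted - true| / true)` over videos, and an
  ordinary least-squares fit of predicted on true counts with `R^2 = 1 -
  SS_res/SS_tot` (defined as 0 for a constant response).

## The synthetic orchard

The simulator renders a seeded world once — a green speckled background and
static, shaded, disk-shaped fruit in two texture families (fine per-pixel
speckle and coarse 3-px blocks, so appearance discrimination is testable) —
and produces each frame as a panning camera window over it, with opaque
vertical occluder strips drawn in camera coordinates over configurable frame
intervals. Ground truth per frame is the visible-region box of each fruit; a
fruit more than 80% covered is omitted for that frame, and identities are
stable across such gaps. Everything is deterministic given the seed.

Detector imperfection is modelled separately: independent misses
(`miss_prob`, default 0.05), Gaussian corner jitter (`jitter_sigma`, default
1 px), Poisson low-confidence false positives (`fp_rate`, default 0.2 per
frame), and a visibility-dependent confidence model centred at 0.9 for fully
visible fruit and dropping steeply with occlusion (roughly 0.5 at half
visibility), mirroring how detector confidence collapses on occluded objects.
With this model a heavily occluded sliver cannot open a new track
(`new_track_thresh = 0.7`), which gives the rematch stages a realistic window
to re-identify a reappearing fruit before a duplicate track is born.

What the simulator deliberately does **not** model: photorealistic
appearance, leaves and branches beyond rectangular strips, lighting changes,
out-of-plane rotation of fruit, and parallax (the world is planar and rigid).
Passing tests therefore demonstrate the mechanism — that appearance
rematching plus validation recovers identities a geometric tracker loses —
not field-ready accuracy on real orchard footage.

## Problem sizes in the test suites

The package's test and acceptance suites use desk-scale scenes chosen to
exercise every code path: clean-scene exactness uses 8 fruit in 160x120
frames over 40 frames across 10 seeds; the occlusion differential uses 12
fruit in 320x240 frames over 120 frames, a 30-px occluder strip, a 2 px/frame
pan, and 20 seeds per arm; the counting suite uses seven videos of 8-32 fruit
at 320x240 over 60 frames. The occlusion strip is wider than the largest
fruit diameter, so crossings include a fully occluded phase (about 25 frames
at the default pan, safely under the 30-frame track buffer).

## Numerical and design choices

* **Half-open, 0-based pixel boxes** everywhere; MOT files keep their native
  1-based frame/id columns. A single convention avoids off-by-one drift
  between masks, polygons, and boxes.
* **Assignment determinism.** The Hungarian solver breaks cost ties toward
  lower row, then lower column indices via an infinitesimal lexicographic
  perturbation, so tracker output is bit-reproducible.
* **Lost tracks in all stages.** Whether the first stage should be
  restricted to active tracks is an open design point; including lost tracks
  lets easy geometric re-acquisitions happen without burdening the
  appearance stages, and the ablation switch (`use_appearance = FALSE`)
  isolates the rematch contribution cleanly.
* **Batch normalization folded away** in the forward-only detector blocks:
  they are reference operators with externally supplied weights, not
  trainable layers. The attention-generating sub-networks of the dynamic
  convolution are likewise out of scope; attentions are operator inputs.
* **SSPPL window set {3, 5, 9, 13}**: the classic {5, 9, 13} pyramid plus the
  smallest odd window above 1 as the added small-target receptive field.
* **"Rotation" augmentations are flips.** The augmentation list includes
  horizontal/vertical "rotation"; arbitrary-angle rotation would break the
  axis-aligned normalized box format, so these are implemented as flips, with
  box centers reflected accordingly.
* **Codebook provenance.** One codebook per video, fitted from the first
  frames' pooled descriptors (at least 64 distinct ones) with a fixed seed.
  A per-video codebook adapts to the scene's texture statistics; refitting
  per frame would make signatures incomparable across time.
* **Kalman warp under camera motion** applies the affine linear part to every
  coordinate pair of the state (center, size, velocities) and the translation
  to the center only, propagating the covariance through the same linear map.

## Known limitations

* The built-in patch descriptor is not rotation- or scale-invariant; it is
  adequate for the near-constant viewpoint of orchard walk-throughs and for
  the simulator, but a real deployment would plug in a stronger backend.
* Appearance re-identification needs texture: smooth, uniformly lit fruit
  yields degenerate signatures, and such tracks can only be recovered
  geometrically.
* The validation mechanism assumes approximately rigid global motion; it
  would mis-reject valid rematches under strong parallax or independently
  moving occluders.
* Counting by maximum id assumes each fruit enters the field of view once;
  back-and-forth camera paths would double-count fruit that leave and
  re-enter beyond the track buffer.
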