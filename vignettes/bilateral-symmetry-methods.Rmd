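---
title: "Quantifying bilateral symmetry of the distal tibia with bisym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bilateral symmetry of the distal tibia with bisym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the measurement model

Surgeons planning the reduction of comminuted distal-tibia (pilon) fractures
increasingly template the repair on a mirrored model of the patient's intact
contralateral tibia. That is only sound if the left and right tibial plafond
are, to within the working resolution of CT-derived bone models, mirror
images of one another. `bisym` implements a correspondence-based measurement
of that assumption for pairs of triangulated bone surfaces in millimetres.

The protocol, stage by stage:

1. **Anatomical alignment.** Each bone receives an anatomical frame fitted
   from the principal axes of its vertex scatter: the dominant axis is
   longitudinal (proximal positive), signed so that the wider, flared
   (epiphyseal) end is distal; the second axis is mediolateral, signed using
   the medial malleolus (the most distal vertex), which lies medial; the
   anteroposterior axis completes a right-handed frame. Both bones are
   expressed in their frames before anything else happens, which makes every
   downstream quantity invariant to how the specimen lay in the scanner.
2. **Mirroring.** The left bone is reflected across its sagittal plane
   (the plane perpendicular to the mediolateral axis). Face winding is
   reversed so the mirrored surface stays outward-oriented.
3. **Rigid superposition with incremental cutting.** The mirrored left bone
   is superimposed onto the right by rigid Coherent Point Drift (CPD),
   first using the full bones, then again after cutting both 50 mm above
   the most distal point of the medial malleolus, and once more after
   cutting at 30 mm. Each cut uses the right bone's landmark so both bones
   are cut at the same world plane and the two plafond models are equally
   sized. The re-registrations focus the alignment progressively onto the
   plafond, where the comparison is made.
4. **Dense correspondence.** On the most distal 25 mm, a nonrigid CPD warp
   carries the right model onto the superimposed mirrored left. For each
   right vertex, its correspondence point is the closest point on the left
   surface (triangle-projected) to its *warped* position, and the recorded
   distance is the Euclidean distance from the *original* right vertex to
   that point. The warp supplies anatomical correspondence; the distance is
   measured between the unwarped surfaces.
5. **Articulating-surface region of interest.** A reference point is placed
   at the centre of the distal tibia (mean mediolateral and anteroposterior
   coordinate of the 30 mm plafond vertices) at the height of the most
   distal malleolus point. A vertex belongs to the articulating surface iff
   the angle between its outward normal and the line from the vertex to the
   reference point is strictly smaller than 90 degrees. A dot product of
   exactly zero is excluded, as are vertices on cut boundaries (their
   normals are artefacts of clipping) and isolated vertices.
6. **Statistics and rendering.** Distances are summarized by median,
   quartiles, 1st/99th percentiles (boxplot whiskers) and maximum, and
   rendered as a heatmap on the right plafond in axial view, clipped at
   2 mm (larger distances draw in dark red).

## Coherent Point Drift as implemented here

Both registrations treat the moving point set as the centroids of an
isotropic Gaussian mixture with a uniform outlier component of weight $w$,
fitted to the fixed set by EM. With moving points $y_m$, fixed points $x_n$
and variance $\sigma^2$, the E-step computes posteriors

$$P_{mn} = \frac{\exp(-\|x_n - T(y_m)\|^2/2\sigma^2)}
{\sum_k \exp(-\|x_n - T(y_k)\|^2/2\sigma^2) + (2\pi\sigma^2)^{3/2}\,\tfrac{w}{1-w}\,\tfrac{M}{N}}.$$

The rigid M-step recovers the rotation in closed form from the SVD of the
weighted cross-covariance, with a determinant correction so that only proper
rotations are returned. **Scale is fixed at 1**: allowing scale would absorb
genuine left–right size asymmetry, the very quantity under measurement.
The nonrigid M-step solves
$(\mathrm{d}(P\mathbf{1})G + \lambda\sigma^2 I)\,W = PX - \mathrm{d}(P\mathbf{1})Y$
for the coefficients of a displacement field
$v(z) = \sum_m \exp(-\|z - y_m\|^2/2\beta^2)\, W_m$, which can be evaluated
at any point — so the EM can run on a subsample while the final
correspondence uses every vertex.

Numerical choices:

* The tracked objective is the negative log-likelihood (plus
  $\tfrac{\lambda}{2}\mathrm{tr}(W^\top G W)$ for the nonrigid case); EM
  guarantees it is non-increasing, and the implementation asserts this in
  its tests to within a 1e-8 relative floating-point slack.
* $\sigma^2$ is floored at $10^{-10}\,\mathrm{mm}^2$; reaching the floor
  means the sets match to well below any physical resolution and iteration
  stops. Convergence otherwise triggers on a relative objective change
  below `tolerance`.
* Point sets larger than `subsample` are reduced by seeded farthest-point
  sampling before EM, giving near-uniform surface coverage; the seed makes
  every run reproducible.
* The rigid EM starts from a deterministic moment-based alignment: the
  clouds' principal axes are matched (all four proper sign combinations,
  scored by a nearest-neighbour cost on a fixed subsample) and centroids
  superposed. Plain identity initialization occasionally locks into a
  local minimum for rotations approaching 30 degrees; the moment
  alignment removes those cases without resorting to random multi-start,
  keeping runs reproducible.

Tunable parameters, defaults, and reasons:

| parameter | default | units | rationale |
|---|---|---|---|
| `outlier_weight` | 0.1 | — | tolerates segmentation debris and cut-edge effects without distorting the fit |
| `tolerance` | 1e-8 | relative | registration error well below the 0.01 mm scale of interest |
| `max_iterations` | 150 | — | rarely reached; convergence is typically 15–60 iterations |
| `beta` | 2 | mm | kernel width of the nonrigid field: narrow enough to follow anatomy at the scale of the malleolus and tubercle, wide enough to stay coherent |
| `lambda` | 3 | — | motion-coherence weight in the range recommended for CPD; larger values approach a smooth near-affine fit |
| `subsample` | 1500 | points | keeps each dense EM at desk scale (seconds per stage on one CPU) with no measurable accuracy cost on these surfaces |
| `cut1`, `cut2`, correspondence height | 50, 30, 25 | mm | the incremental cutting protocol |
| `roi_angle_deg` | 90 | degrees | the strict `< 90` articular-surface rule |
| `heatmap_cap_mm` | 2 | mm | reporting convention: larger differences saturate dark red |

## What the synthetic generator emulates — and what it does not

No suitable public cohort of paired tibia meshes exists, so the package
ships a parametric generator that stands in for one. The right bone is a
tapered elliptic shaft (default radius 12 mm, mediolaterally widened)
sweeping into a flared distal epiphysis (flare 1.5 over the distal 30 mm), a
concave plafond cap (4 mm deep), a rounded distal rim (4 mm fillet — bone
ends are blunt, and a sharp rim would be both unanatomical and numerically
hostile to normal-offset fields), a solid medial malleolus pulled distally
and medially by an anisotropic Gaussian (height 12 mm, width 8 mm), and an
anterolateral (Chaput) tubercle bump (3 mm). The left bone is the exact
sagittal mirror, optionally deformed at labelled asymmetry sites.

Asymmetry is modelled as Gaussian bumps applied along the left bone's
outward vertex normals, truncated at three kernel widths, because observed
left–right differences in real cohorts concentrate in compact regions at
the medial malleolus and anterior tubercle — plausibly segmentation-driven
surface offsets in low-contrast areas, which is exactly what a
normal-direction offset models. The site *centres* sit on the gently curved
faces of those prominences (the most medial vertex for the malleolus, the
tubercle's outward face), not on high-curvature tips: on a face with
coherent normals, an imposed offset of $a$ mm produces a surface separation
of $a$ mm, so recovery is well defined. Each site records two masks: a
`core` (within half a kernel width of the centre, where the imposed
displacement is at least ~88% of the peak and its disk-mean is ~94%), used
for amplitude-recovery checks, and the full `support` (three widths).

Surface noise of standard deviation 0.1 mm is added along vertex normals,
independently on the two bones — the conservative assumption for a symmetry
analysis — emulating sub-voxel segmentation jitter at ~0.8 mm CT voxels,
and applied *before* the rigid pose so it represents surface error, not
motion. Each bone then receives an independent random pose bounded at 15
degrees and 30 mm, emulating supine CT limb placement; the anatomical-frame
alignment in the pipeline removes poses of any size, so these bounds are a
realism choice, not a requirement.

What passing tests on this generator do **not** show: real bones have
cortical ridges, anatomical variation far richer than jittered ellipse
parameters, and segmentation artefacts that are spatially correlated rather
than independent per vertex. The generator validates the *pipeline* —
registration, cutting, correspondence, ROI logic, statistics — not the
clinical magnitude of human asymmetry.

## Design choices where the protocol was genuinely open

* **Anatomical frame.** Published anatomical coordinate systems for the
  tibia depend on landmarks this package does not require; the inertia-axis
  construction with deterministic sign rules is self-contained and
  equivariant, and the frame only steers the landmark height and the ROI
  rule, both robust to small rotations. A user-supplied frame is accepted
  everywhere.
* **"Most distal point of the medial malleolus"** is implemented as the
  globally most distal vertex: the malleolus tip *is* the tibia's most
  distal point, so no separate malleolus detector is needed.
* **Cut anchoring.** Both bones are cut at the plane defined by the *right*
  bone's landmark after each superposition, producing equally sized
  plafonds; anchoring each bone to its own landmark would let a small
  registration offset change the compared regions.
* **Cut boundaries** stay open (no cap) and their vertices are excluded
  from registration, correspondence and ROI; clipped-edge normals are
  meaningless and a cap would manufacture fictitious surface.
* **Correspondence distances** are taken to the nearest *surface* point
  (triangle-projected), not the nearest vertex, making the measure
  independent of the left mesh's sampling density.
* **Pooling.** Cohort outputs include both pooled-distance summaries (all
  correspondences of all specimens together; labelled primary) and
  per-specimen medians, since a cohort median can be formed either way.
* **Quantiles** use linear interpolation between closest ranks
  (`stats::quantile` type 7); interquartile values depend on this choice,
  so it is fixed and stated.

## Problem sizes

Default synthetic bones are meshed at 2.5 mm edge length (~3,000 vertices
per bone; ~900 on the 25 mm plafond), which the package's validation suite
uses for single-pair runs; amplitude-recovery experiments refine to 2.0 mm
so a site core holds a dozen or more vertices, and multi-amplitude cohort
sweeps coarsen to 3.0 mm. At these sizes a full pair runs in seconds to a
few tens of seconds on one CPU, and the choices above are stated so that
any reported number can be regenerated exactly.

## Known limitations

* Rigid CPD is initialized at the identity after anatomical-frame
  alignment; bones whose frames cannot be fitted (no dominant long axis —
  e.g. an isolated plafond fragment) need a manual frame.
* The closest-point step after warping assumes the warp lands near the
  anatomically corresponding patch; a grossly wrong warp (e.g. from
  registering unrelated bones) degrades to closest-point distances rather
  than failing loudly, though the divergence check on the EM objective
  catches most such cases.
* Distances are unsigned: the measure does not distinguish bone excess
  from deficit.
* PLY/STL/OBJ readers cover the dialects produced by mainstream
  segmentation tools (ASCII and binary little-endian PLY, ASCII and binary
  STL, geometry-only OBJ); exotic PLY variants (big-endian, non-triangular
  faces) are rejected with explicit errors rather than guessed at.

## A worked example

```{r, eval = FALSE}
library(bisym)

# a synthetic pair with a 1 mm medial-malleolus asymmetry
pair <- generate_pair(synthetic_pair_spec(
  seed = 42, asymmetry_sites = list(asymmetry_site("medial_malleolus", 1, 8))))

res <- run_pair(pair$left, pair$right, pipeline_config(seed = 1),
                specimen_id = "demo", out_dir = "demo_out")
res
# the heatmap PLY, axial PNG and JSON run record are in demo_out/
```
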