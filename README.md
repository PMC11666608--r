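# bisym — bilateral symmetry of the distal tibia from surface meshes

Pilon (tibial plafond) fractures are reduced ever more often against a
template: the patient's intact contralateral tibia, mirrored. That practice
presumes the left and right plafond are mirror images to within the working
resolution of CT-derived bone models. `bisym` measures that assumption. It
takes a pair of triangulated bone surfaces (PLY/STL/OBJ, millimetres),
mirrors the left bone in the sagittal plane, superimposes it onto the right
with rigid Coherent Point Drift (CPD) — re-registering after cuts 50 mm and
30 mm above the most distal point of the medial malleolus so the alignment
focuses on the plafond — establishes dense correspondences on the most
distal 25 mm with nonrigid CPD, restricts attention to the articulating
surface (vertices whose outward normal makes an angle of less than 90° with
the line to a reference point at the distal-tibia centre), and reports
per-correspondence Euclidean distances as boxplot statistics and surface
heatmaps (capped at 2 mm, dark red).

CPD models the moving point set as Gaussian-mixture centroids fitted to the
fixed set by EM with a uniform outlier component; the rigid variant
recovers rotation + translation in closed form via SVD of the weighted
cross-covariance (scale fixed at 1 — scaling would absorb true left–right
size asymmetry), and the nonrigid variant fits a Gaussian-kernel
displacement field `v(z) = Σ_m exp(−‖z − y_m‖²/2β²) W_m` with a motion-
coherence penalty `λ/2 · tr(WᵀGW)`. Correspondence distances are measured
from each *original* right vertex to the closest point on the left surface
at its *warped* position, so the warp supplies anatomy-aware pairing while
the distance measures real surface separation.

Because no cohort of paired tibia meshes is public, the package includes a
parametric synthetic distal-tibia generator (shaft, flared epiphysis,
concave plafond, solid medial malleolus, anterior tubercle) that produces
mirror pairs with ground-truth asymmetry fields at labelled sites, surface
noise at sub-voxel scale, and random poses — the basis of the validation
suite. See `vignettes/bilateral-symmetry-methods.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(bisym)

# a synthetic pair with a 1 mm asymmetry on the medial malleolus
pair <- generate_pair(synthetic_pair_spec(
  seed = 42, asymmetry_sites = list(asymmetry_site("medial_malleolus", 1, 8))))

res <- run_pair(pair$left, pair$right, pipeline_config(seed = 1),
                specimen_id = "demo", out_dir = "demo_out")
res
#> pair_result 'demo'
#>   entire plafond:      median 0.12 mm (IQR, 0.06 - 0.21), whiskers [0.01, 0.96], max 1.17 mm, n = 836
#>   articulating surface:median 0.11 mm (IQR, 0.06 - 0.19), whiskers [0.00, 0.84], max 0.95 mm, n = 398
```

The medians say the two plafonds agree to ~0.1 mm over most of the
surface; the 99th-percentile whisker and maximum approach the 1 mm
asymmetry that was injected at the malleolus, and the heatmap written to
`demo_out/demo_axial.png` (with the distance-carrying mesh in
`demo_out/demo_heatmap.ply` and a JSON run record alongside) shows that
hotspot exactly at the medial malleolus. On a truly symmetric pair all
summaries collapse to ~0.01 mm or below; real cohorts sit between these
extremes.

Cohorts run the same way from a list of pairs or a TSV manifest
(`specimen_id`, `left_path`, `right_path`):

```r
coh <- run_cohort(manifest, pipeline_config(seed = 0), out_dir = "cohort_out")
coh$summary_pooled_full       # pooled over all correspondence points
coh$per_specimen_median_full  # one median per specimen
```

A thin command-line front end with `simulate`, `run-pair` and `run-cohort`
subcommands is installed at `inst/cli/bisym.R`.

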