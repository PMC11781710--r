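# masel — multi-atlas segmentation with volume-feature atlas selection

Multi-atlas segmentation (MAS) labels an un-contoured CT volume by
deformably registering previously contoured images (atlases) onto it,
propagating their contours through the deformation fields, and fusing the
results by majority voting. Its weak point is atlas choice: deformable
registration degrades when target and atlas differ by a large organ-volume
change (bladder filling alone spans roughly 71–437 cc in a pelvic cohort),
and a badly matched atlas votes a wrong contour.

`masel` implements and compares four selection strategies for female pelvic
CT (bladder, rectum, femoral heads, bone marrow, body external), behind a
common registration/fusion core:

| strategy | candidate pool | ranking | registrations per target |
|----------|----------------|---------|--------------------------|
| cMAS     | all atlases    | NCC after deformable registration | all |
| SAGA     | k-means volume-feature subgroup | NCC after deformable registration | subgroup size |
| FASA     | all atlases    | feature distance `D = ‖V_atlas − V_target‖` | n |
| SIM      | all atlases    | mutual information after rigid registration | n |
| random   | all atlases    | seeded uniform draw | n |

Feature vectors are per-structure volumes (cc), min–max normalized to
[0, 1] on the atlas set; `n = 5` atlases are fused by per-voxel majority
vote; output quality is scored by Dice similarity coefficient (DSC) and the
95th-percentile Hausdorff distance (95HD, cm), with two-tailed paired
t-tests between strategies. A deterministic synthetic pelvic-phantom cohort
generator (CT-like intensities, ground-truth contours, smooth
diffeomorphic inter-subject warps whose magnitude scales with organ-volume
mismatch) makes the whole pipeline testable without any clinical data.

## Worked example

```r
library(masel)

# a small cohort: 8 phantoms, 4 mm grid for speed
cohort <- generate_cohort(8, seed = 11, dim = c(48, 48, 32),
                          spacing = c(4, 4, 4))

# atlas library = subjects 1..6; derive a target from subject 7
atlases <- cohort$atlases[1:6]
target  <- make_target(cohort$atlases[[7]], amplitude = 5, seed = 1)

# volume features, normalized on the atlas set only
vecs <- lapply(atlases, extract_features)
norm <- fit_normalizer(vecs)
nvecs <- lapply(vecs, normalize_features, norm = norm)
tvec <- normalize_features(
  feature_vector(pelvic_structures(), target$volumes[pelvic_structures()]),
  norm)

# feature-distance selection, registration, fusion, evaluation
sel <- select_fasa(tvec, nvecs, n = 3, target_id = target$id)
sel$ranked_atlases
#> [1] "atlas004" "atlas001" "atlas005"
round(sel$scores, 3)
#> [1] 0.341 0.494 0.623

fast <- reg_settings(def_levels = c(4, 2), def_maxit = c(60, 30),
                     lambda = 3e-4)
props <- lapply(sel$ranked_atlases, function(id) {
  field <- deformable_register(target$image, atlases[[id]]$image,
                               settings = fast)
  propagate_labels(atlases[[id]]$contours, field)
})
fused <- majority_vote(props)

round(dice(fused, target$labels, "bladder"), 3)
#> [1] 0.907
round(hd95(fused, target$labels, "bladder"), 2)   # cm
#> [1] 0.57
```

`sel$scores` are Euclidean distances in normalized volume-feature space
(smaller = more volumetrically similar); the fused bladder overlaps the
ground truth at DSC 0.907 with a 95th-percentile surface separation of
0.57 cm. `run_experiment()` wraps this loop over folds, targets and all
five strategies and returns tidy records plus a mean ± sd summary table
with paired t-tests; `inst/cli/masel.R` exposes `generate` / `features` /
`subgroup` / `run` verbs for shell use.

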