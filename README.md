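# cortibreak

Automated detection and quantification of small cortical interruptions in 3D
HR-pQCT volumes of finger joints.

Cortical interruptions — breaks in the thin cortical shell around the
metacarpal head and phalangeal base — are an early imaging sign of bone
erosion in rheumatoid arthritis. HR-pQCT resolves them at 82 µm isotropic
voxels, but scoring lesions of a few hundred micrometres by eye is slow and
subjective. `cortibreak` implements a fully automated morphological detector
for interruptions with a minimum diameter of 3 voxels (0.246 mm at 82 µm),
together with the statistics used to compare raters and procedures, and a
synthetic phantom generator with exact ground truth for validation.

## Method

The pipeline has four steps:

1. **Periosteal contour** — Gaussian smoothing (σ = 0.8 voxels, support 1)
   and a threshold of 105 ‰ of the maximum possible voxel value, followed by
   a 7-voxel morphological closing with cavity filling, giving a solid
   bounded by the outer bone surface (`auto_contour()`; an
   operator-corrected solid can be substituted via
   `load_corrected_contour()` — the *semi-automated* procedure).
2. **Bone segmentation** — Laplace–Hamming filtering and a constant
   threshold (400 ‰ of the filtered dynamic range) yield the binary bone
   model (`binarize_bone()`).
3. **Cortical mask** — the contour solid is eroded by 4 voxels
   (face-connected cross) and subtracted, leaving a shell of constant
   thickness 0.328 mm, the analysis compartment (`build_cortical_mask()`).
4. **Detection** — bone within the mask is dilated by 1 voxel, the image is
   inverted, and void components connected to *both* the periosteal and
   endosteal boundary are kept, dilated back, and measured
   (`detect_interruptions()`). The cross-shaped unit element makes the
   criterion exact: a surviving channel spans ≥ 3 consecutive slices with
   in-plane width ≥ 3 voxels (a 5-voxel plus-shaped opening), so the
   smallest detectable intra-cortical volume is 5 × 4 = 20 voxels
   (0.011 mm³). Each interruption's surface is its intra-cortical volume
   divided by the mask thickness:
   `surface = voxel_count · v³ / (4 · v)` with `v = 0.082 mm`.

Reliability between two raters/procedures uses one-to-one voxel-overlap
matching (≥ 20 voxels), the proportion of matching interruptions
`m / (n₁ + n₂ − m) · 100 %`, PPV and sensitivity against visual scoring,
and the single-measures two-way random-effects absolute-agreement
intraclass correlation ICC(2,1) (`match_interruptions()`,
`proportion_matching()`, `positive_predictive_value()`, `sensitivity()`,
`icc_two_way_random_absolute()`).

## Worked example

Carve three channels into a synthetic capsule-shaped joint — a minimal
3-voxel plus-cross channel, a 5-voxel circular channel (both qualifying),
and a 2-voxel channel (below the detection limit) — blur it and add 5 %
noise, then run the detector with the phantom's true periosteal contour:

```r
library(cortibreak)

ph <- generate_phantom(phantom_spec(
  shape = c(64, 56, 56), outer_radius_voxels = 16,
  channels = list(
    channel_spec(axis = 2, direction = +1, cross_section = "plus_cross",
                 width_voxels = 3, depth = "through", position = c(26, 28)),
    channel_spec(axis = 3, direction = +1, cross_section = "circle",
                 width_voxels = 5, depth = "through", position = c(38, 28)),
    channel_spec(axis = 2, direction = -1, cross_section = "square",
                 width_voxels = 2, depth = "through", position = c(32, 28))),
  trabecular = list(strut_spacing_voxels = 8, strut_thickness_voxels = 2),
  blur_sigma_voxels = 0.5, noise_sd_fraction = 0.05, seed = 1))

res <- detect_cortical_interruptions(ph$grayscale,
                                     contour = ph$truth$periosteal_solid)
res
#> <cortibreak joint result> 2 interruption(s), total surface 0.175 mm^2
#>   label voxel_count volume_mm3 surface_mm2
#> 1     1          84 0.04631491    0.141204
#> 2     2          20 0.01102736    0.033620

summarize_interruptions(res)
#>   n_interruptions total_surface_mm2 median_surface_mm2 total_volume_mm3
#> 1               2          0.174824           0.087412       0.05734227
```

Both qualifying channels are found — the minimal one at exactly the
20-voxel detection floor (0.0110 mm³ intra-cortical volume, 0.0336 mm²
surface) — and the 2-voxel channel is correctly erased by the 1-voxel bone
dilation. Matching the detections back to the carved ground truth:

```r
recovery_report(ph$truth, res)[1:4]
#> $n_true          [1] 2
#> $n_detected      [1] 2
#> $n_matched_to_truth [1] 2
#> $false_positives [1] 0
```

`detection_geometry()` restates the method constants for any voxel size,
e.g. `detection_geometry(0.061, 5)` gives the second-generation settings
(0.305 mm mask, 0.183 mm minimum diameter).

For file-based runs, `run_pipeline(run_config(input = "joint.nii",
out_dir = "out"))` reads NIfTI/MetaImage/TIFF volumes, writes the
interruption label map, a per-interruption CSV, and JSON summaries, and is
byte-reproducible. A command-line wrapper with `detect`, `phantom`,
`compare` and `icc` subcommands ships in `inst/cli/cortibreak.R`.

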