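---
title: "Detecting small cortical interruptions in HR-pQCT finger joint volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small cortical interruptions in HR-pQCT finger joint volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortibreak)
```

## The problem

Peri-articular cortical interruptions — small breaks in the cortical bone
shell of finger joints — are an early imaging correlate of bone erosion in
inflammatory arthritis. High-resolution peripheral quantitative CT (HR-pQCT)
resolves the cortex of metacarpophalangeal joints at 82 µm isotropic voxels
(61 µm for second-generation scanners), which makes interruptions of a few
hundred micrometres visible, but visual scoring of such small lesions is
laborious and subjective. `cortibreak` implements a fully automated
morphological detector of cortical interruptions, quantifies their
intra-cortical volume and surface, and supplies the reliability statistics
used to compare two raters or procedures, plus a synthetic phantom generator
so that every stage can be validated against exact ground truth without scan
data.

An interruption, for this detector, is a void pathway through the cortical
shell that

* is connected to both the periosteal (outer) and the endosteal (inner)
  boundary of a constant-thickness cortical mask, and
* survives a one-voxel erosion — equivalently, spans at least 3 consecutive
  slices with an in-plane width of at least 3 voxels (a 5-voxel plus-shaped
  opening), i.e. a minimum diameter of 0.246 mm at 82 µm voxels.

The smallest detectable intra-cortical volume is therefore
5 voxels × 4 voxels mask depth = 20 voxels (0.011 mm³); these constants are
recomputed by `detection_geometry()`.

## Pipeline

`detect_cortical_interruptions()` (and `run_pipeline()` around it) composes
four steps.

**1. Periosteal contouring** (`auto_contour()`). The volume is smoothed with
a sampled Gaussian (σ = 0.8 voxels, kernel truncated at 1 voxel) and
thresholded at 105 per mille of the *maximum possible* voxel value of the
acquisition (`intensity_max`), not of the observed maximum — a finger-joint
calibration: the cortex here is thinner and less mineralized than in
radius/tibia protocols, which use 120 ‰. The thresholded structure is closed
(dilation by 7 voxels, cavity fill, erosion by 7 voxels) and every
background component not connected to the lattice border is filled,
producing a solid bounded by the periosteal surface. Both the 105 ‰
threshold and the 7 closing steps are exposed in `contour_params()`.

Two numerical choices deserve note:

* *Closing metric.* The closing uses a true Euclidean ball of radius
  `closing_steps`, computed with a separable 3D distance transform. An
  iterated city-block cross would emboss diamond-shaped ridges of up to
  (√3 − 1) · 7 ≈ 5 voxels on oblique parts of a curved periosteal surface
  and sag the bridge that the closing builds over an interruption mouth,
  displacing the cortical mask exactly where interruptions sit. The
  detection-side unit dilations (below) deliberately do *not* use the
  Euclidean ball — there the cross element is the width criterion itself.
* *Boundary renormalization.* Gaussian smoothing renormalizes the kernel
  over in-lattice voxels, so constant volumes are exactly invariant and the
  105 ‰ threshold behaves identically at the volume border; the threshold
  comparison carries a 10⁻⁹·`intensity_max` tolerance so intensities exactly
  at the boundary count as foreground despite round-off.

**2. Bone segmentation** (`binarize_bone()`). A Laplace–Hamming filter —
edge enhancement plus high-frequency noise suppression — followed by a
constant threshold at 400 ‰ of the filtered dynamic range (endpoints clamped
to `[0, intensity_max]`). The scanner manufacturer's exact filter
coefficients are not public, so the frequency response here is explicit
package policy, fully exposed in `segmentation_params()`: with per-axis
frequencies written as fractions *f* of Nyquist and radial frequency
r = |f|/√3,

    H(f) = W(r) · (1 + ε · Σ_axes (1 − cos(π f_axis)))

where W = 1 below the cutoff (default 0.4 of Nyquist) and rolls off with a
Hamming taper above it, and the second factor is the response of sharpening
by the negated discrete Laplacian with weight ε (default 0.5). The filter is
linear, and ε = 0 with cutoff 1 gives plain thresholding. Because detection
correctness is asserted against phantoms with known binary structure, the
tests establish that results hold for this filter family rather than for one
proprietary coefficient set; segmentation output on real scans depends on
these parameters and should be reported with them.

**3. Cortical mask** (`build_cortical_mask()`). The contour solid is eroded
by `mask_thickness_voxels` (default 4, ≈ 0.328 mm; use 5 at 61 µm voxels for
a comparable 0.305 mm) with the face-connected cross, and the erosion is
subtracted, leaving a shell of constant thickness — the analysis
compartment. A constant-thickness mask avoids segmenting the unreliable
endosteal boundary; the default is set slightly below the ~0.39 mm average
MCP cortical thickness because the juxta-articular cortex, where
interruptions concentrate, is thinner. The mask's periosteal face is the
shell layer adjacent to the outside background, the endosteal face the layer
adjacent to the eroded interior. If the erosion exhausts the solid (a bone
thinner than the mask everywhere) the endosteal face is empty and a warning
is emitted, since no through-defect can then be detected.

**4. Detection** (`detect_interruptions()`). Within the shell: bone is
dilated by 1 voxel (face-connected cross), closing any void narrower than
3 voxels; the image is inverted; void components (6-connected by default,
configurable via `void_connectivity`) are kept only when they contain at
least one periosteal-face and one endosteal-face voxel; survivors are
dilated back by 1 voxel and clipped to non-bone shell voxels, restoring
approximately their original extent; components below
`min_component_voxels` (default 20) are dropped. Records report voxel
count, volume (count · voxel³), surface (volume / mask thickness in mm — an
area proxy exact by construction), centroid and bounding box, ordered by
descending size with lexicographic-centroid tie-break.

Boundary connection is tested by *containment* of face voxels, not by mere
adjacency to the face layer: a blind pit ending one voxel short of the
endosteal boundary is face-adjacent to (bone) voxels of that layer but does
not reach the boundary, and must not count. Containment is equivalent to
"adjacent to the outside background / to the eroded interior". Components
merged by the restoration dilation are counted once — they are closer than
two voxels apart and indistinguishable at the method's precision.

Voxel indices in all records are 1-based (R convention); the physical
position of index *i* is (*i* − 1) · `voxel_size_mm` at the voxel centre.

## Semi-automated pathway

`load_corrected_contour()` substitutes an operator-edited periosteal solid
(any external editor; the file just needs to match the lattice) for the
automatic one; the rest of the pipeline is unchanged. This matters at
interruption mouths: the closing bridge over a hole whose half-width is at
the detection limit can sit one voxel below the true surface (a digital
closing effect — the erosion ball dips into the widened mouth by
√(r² + a²) − r plus up to half a voxel of lattice rounding). A minimal
3-voxel-wide channel then restores to 16–19 voxels and falls below the
20-voxel floor. With a faithful contour the same channel yields exactly
20 voxels. This asymmetry between the fully- and semi-automated procedure is
inherent to contour-based masking, it is why the corrected-contour pathway
exists, and it is visible in the package's own tests: the phantom recovery
assertions run the corrected-contour pathway, while the fully-automated run
is asserted to produce no false positives and never to beat the corrected
one.

## Reliability statistics

`match_interruptions()` pairs interruptions from two label maps when their
voxel sets overlap by ≥ 20 voxels (the smallest detectable volume), greedily
one-to-one by descending overlap with smaller-label tie-break. The original
matching rule does not specify multi-overlap resolution; greedy-by-overlap
is documented policy here, and the tests check it against exhaustive
assignment on small cases. From the counts:

* proportion of matching interruptions = m / (n₁ + n₂ − m) · 100,
* PPV = m / n_algorithm · 100 and sensitivity = m / n_visual · 100 against a
  gold standard (visual scoring consumed as a label map or as counts — the
  human procedure itself is out of scope).

`icc_two_way_random_absolute()` computes single-measures ICC(2,1) — two-way
random effects, absolute agreement — from the ANOVA mean squares, with the
McGraw–Wong F-based 95 % CI. It matches `stats::aov` mean squares and an
established reference implementation to 10⁻¹⁰ (cross-checks in the tests,
not dependencies). Friedman and Wilcoxon comparisons are deliberately not
re-implemented; `summarize_interruptions()` emits the per-joint values they
need.

## The phantom generator

`generate_phantom()` renders a closed cortical shell — sphere, capsule
("capped cylinder": a shaft with hemispherical caps at *both* ends, so the
medullary cavity is enclosed and the border-connected flood fill cannot leak
through an open tube end), or ellipsoid — of default thickness 5 voxels
(≈ 0.41 mm, near the reported ~0.39 mm MCP average), with an optional
axis-aligned rod lattice standing in for trabeculae, and carves channels of
specified cross-section (plus-cross, square, circle), width and depth
(through, blind-periosteal, blind-endosteal, intracortical). Intensities
default to bone at 40 % of a 32767 maximum on a zero background, optionally
blurred (Gaussian, σ in voxels) and degraded with additive Gaussian noise
(SD as a fraction of the bone intensity, truncated at zero), then quantized
to integers as scanner exports are. Ground truth — periosteal solid, bone,
channel label map, and which channels satisfy the criteria (through, width
≥ 3, plus-cross contained in the cross-section) — is computed from the
analytic geometry only and shares no code with the detector, so agreement
between the two is a genuine test.

What the phantom does *not* emulate: beam hardening, motion artifacts (the
known failure mode in which a loose automatic contour produces false
positives — flagged for operator correction, not simulated), partial-volume
behaviour of real mineralization gradients, and real trabecular
architecture. Passing phantom tests therefore demonstrates the morphological
contract of the detector, not scanner-level robustness.

Default test problem sizes: phantoms of 64×56×56 voxels with an outer radius
of 16 voxels; oracle-equivalence sweeps use ≥ 100 random lattices of 10–48
voxels per side against brute-force reference implementations (explicit
neighbour loops, breadth-first search, offset-ball distance checks); the ICC
simulation uses 1000 joints × 2 raters. These sizes make every stage
exhaustively checkable while each suite file runs in seconds.

## Degenerate inputs and tie-breaks

* Empty structure approximation (no bone above threshold) → validation
  error "no bone found".
* Erosion exhausting the solid → warning, empty endosteal face, zero
  detections.
* Both interruption sets empty → proportion of matching interruptions is
  undefined (error), as are PPV/sensitivity with a zero denominator.
* Ratings with zero total variance → ICC undefined (error); an exactly
  consistent table returns ICC = 1 with a collapsed CI.
* Record ordering: descending voxel count, then lexicographic centroid,
  then original label — stable and deterministic, so repeated runs are
  byte-identical.
* Label maps are always contiguous 1..K; reading an external map compacts
  labels.

## Known limitations

* The Laplace–Hamming coefficients are package policy, not the scanner's;
  absolute agreement with scanner workstations on real scans is not claimed.
* The interruption surface divides volume by the nominal mask thickness; in
  cortices thinner than the mask the intra-cortical volume includes some
  trabecular compartment and the surface is correspondingly overestimated.
* The fully-automated contour can clip limit-sized interruptions at the
  mouth (see above); quality control of contours remains advisable.
* One joint region is analysed per volume; multi-bone instance separation
  is out of scope (all bone in the field of view is contoured as one solid
  set, possibly with several components).
* Proprietary scanner formats (ISQ/AIM) are not parsed; convert to NIfTI,
  MetaImage or TIFF externally. DICOM assembly and density calibration are
  out of scope.
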