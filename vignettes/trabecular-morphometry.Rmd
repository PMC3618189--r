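---
title: "Trabecular bone morphometry from anisotropic MRI stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular bone morphometry from anisotropic MRI stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabmorph)
```

This vignette is the package's account of its methods: what each stage
computes, the assumptions behind it, the parameters that matter, what the
synthetic generator does and does not emulate, and the design choices made
where the problem was genuinely open.

## The measurement problem

Peripheral MRI of the distal radius with strongly anisotropic voxels
(0.195 mm in-plane, 1 mm through-plane in the emulated protocol) supports
*apparent* trabecular morphometry: the measured quantities track the true
microarchitecture but are resolution-limited, so their value lies in
longitudinal and between-group comparison under a fixed protocol rather
than in absolute accuracy. The chain is:

1. **Slice matching.** Baseline and follow-up stacks of the same forearm are
   matched through-plane by an integer slice offset and in-plane by a rigid
   transform. Eight matched contiguous slices, starting at a distal
   reference slice, form the analysis volume.
2. **Endosteal segmentation.** Per slice, the region enclosed by the
   cortical rim is delineated; all further measurement is restricted to it.
3. **Binarization.** Bone (dark in gradient-echo contrast) is separated from
   marrow (bright) by Otsu's threshold computed from the within-mask
   histogram only.
4. **Morphometry.** Hole count and size by region growing; BV/TV by pixel
   counting; Tb.Th and Tb.Sp by maximal inscribed discs; Tb.N = BV/TV /
   Tb.Th; nodal and branch density from the skeletonized bone phase.
5. **Inference.** Per-subject percent change per variable; ordinary least
   squares of percent change on group plus screened covariates; adjusted
   (least-squares) means; Holm step-down correction across the nine-variable
   family.

## Per-slice 2D analysis of anisotropic volumes

All metrics are computed per slice in 2D and averaged over the 8-slice
volume. With voxels five times longer through-plane than in-plane, any 3D
maximal-sphere or 3D skeleton computation would be dominated by slice
thickness rather than by trabecular geometry; "maximal spheres" therefore
become maximal inscribed *discs* in-plane, and the skeleton is a 2D medial
axis per slice. This is a deliberate, documented reinterpretation of the
model-independent 3D distance-transform method for data this anisotropic.
Consequences worth knowing:

* Tb.Th and Tb.Sp are in-plane quantities; trabeculae oblique to the slice
  plane appear thicker than they are.
* The profile averages slices with equal weight, and Tb.N is recomputed from
  the *averaged* BV/TV and Tb.Th (not averaged per-slice Tb.N); with
  slice-to-slice variation of a few percent the two orders differ
  negligibly, but the order is fixed and documented.
* Whether the original style of analysis pooled holes across slices or
  averaged per-slice counts is not determinable; this implementation
  computes per-slice counts and averages them.

## Maximal-disc thickness: exact convention

For a phase pixel q the Euclidean distance transform d(q) gives the
center-to-center distance to the nearest background pixel (the image border
is *not* background). The inscribed radius of the largest disc centered at
q is r(q) = d(q) − 0.5 (half a pixel from the last foreground center to the
inter-pixel boundary). The local thickness of pixel p is the diameter of
the largest disc containing p and fitting in the phase:

> th(p) = 2 · max { r(q) : ‖p − q‖ ≤ r(q) − 0.5, q in phase; or q = p }

Tb.Th is the mean of th over bone pixels × voxel size; Tb.Sp is the same
functional on the marrow phase inside the mask. The implementation paints
discs in decreasing radius order (first write wins); the test suite holds it
to the exhaustive all-centers definition to 10⁻⁹ on every instance up to
64 × 64. This convention gives exactly w pixels for a w-pixel slab,
1 pixel for isolated pixels and checkerboards, and scales exactly linearly
with voxel size.

## Region growing and connectivity duality

Holes are marrow components found by seed-and-grow flood fill, which equals
connected-component labeling (and is held to an independent labeling oracle
on random maps). Marrow is 4-connected and bone 8-connected — the standard
duality that prevents both phases from "crossing" at a pixel corner.
Marrow components touching the endosteal rim are *counted* as holes by
default: they are intertrabecular space, and hole counts at the study scale
(~70 per slice against ~70 Voronoi cells) indicate no aggressive exclusion
was applied; `exclude_boundary = TRUE` reports them separately for
sensitivity analysis. There is no minimum hole size. Solid-bone slices
return a flagged empty hole set (count 0, undefined mean), never 0/0.

## Endosteal segmentation

The slice is thresholded (Otsu, full slice), bright components touching the
image border are discarded (air/background), the interior marrow is
morphologically closed with a 2 mm disc (padding first, so the element
never clips at the border), holes are filled, and the largest component is
kept. The boundary ring just outside the candidate mask must be
predominantly dark (cortical bone); otherwise the slice has no closed rim
and the function fails, flagging the slice for manual input. On synthetic
ground truth this recovers the endosteal disc area to within about 2 %
(spec'd tolerance 5 %); the residual bias is an *undershoot* of roughly
half a trabecular strut at the rim. An earlier design compensated by
dilating half a strut width, but measured against ground truth the closing
already reaches the border and the dilation pushed the mask into the
cortical rim, inflating BV/TV by ~2 percentage points; the compensation was
removed.

## Skeletonization and network analysis

Thinning is sequential simple-point deletion: a pixel may be deleted only
if its 3 × 3 neighborhood shows one 8-connected foreground component and
one 4-connected background component adjacent to the center (precomputed as
a 256-entry lookup), and endpoints are never deleted. Deleting one simple
point at a time preserves the homotopy type of the image by construction,
so the skeleton has exactly the Euler number (components minus holes) of
the bone phase — that topological identity, not any particular geometric
medial axis, is the acceptance surface, and it is tested on 100 random
maps. Four directional subcycles per pass keep the result near-medial.

Junction pixels (≥ 3 skeleton neighbors) are merged into nodes by
8-adjacency before counting — naive per-pixel junction counting inflates
nodal density, a known pitfall. Branches are the connected components of
the skeleton minus junction pixels; an isolated fragment is one branch, and
a branch running directly between two touching junction clusters (a
zero-length segment) is not counted, a documented convention. For acyclic
skeletons the counts satisfy branches = nodes + endpoints − 1.

## The synthetic generator

**Texture model.** A slice is a Voronoi-edge lattice: `hole_count_target`
seed points are placed on a jittered hexagonal grid inside the endosteal
disc, marrow cells are their Voronoi cells, and trabeculae are the cell
boundaries — pixels whose two nearest-seed distances differ by less than a
band width t. The alternative (thresholding a smoothed random field) was
rejected on percolation grounds: at ~52 % marrow fraction a smooth level
set sits above the 2D continuum percolation threshold, so marrow would form
one spanning component instead of ~68 discrete holes of ~2 mm² — the
defining feature of the measured tables. The lattice gives independent
control of hole count (seed count) and BV/TV (band width), and its implied
strut width at the study scale, BV/TV × area / total edge length ≈ 0.5 mm,
lands on the measured Tb.Th without further tuning.

**Calibration.** t is not set analytically: the generator sorts the
distance-difference field inside the disc and takes the exact order
statistic matching the BV/TV target, so the planted bone fraction is
correct to one pixel's worth. Parameter combinations that cannot be
realized (cells below ~9 pixels, strut width below one voxel, achieved
fraction off by more than 0.03) raise errors rather than clip.

**Imaging model.** Two-class contrast (bone and background 0.25, marrow
0.80), Gaussian PSF of FWHM 0.35 mm, additive Gaussian noise SD 0.06. The
acquisition's grey-level statistics are not published, so contrast and
noise are free parameters chosen once to make binarization non-trivial
(~97 % pixelwise agreement with ground truth at defaults, ~100 % noise
free) and held fixed. No bias fields, coil profiles or motion artifacts are
simulated — scans failing registration are the only "artifact" pathway, as
exclusion is the handling the analysis models.

**Longitudinal model.** Follow-up = surface thinning of the stated bone
fraction (boundary-distance order with reproducible tie-breaks) +
re-rendering with fresh noise + rigid misalignment (rotation about the
center, then integer-recorded translation; positive slice offsets drop
distal slices). Slices are generated independently: at 1 mm spacing the
through-plane texture correlation of real bone is not represented, which
matters only for methods that would exploit it (none here).

**Cohort model.** `render = "values"` draws per-subject baseline profiles
and percent changes directly from study-scale distributions — means/SDs of
the measured tables, group offsets per `effect_pct_change`, follow-up
interval 25.4 (1.9) months, ethnicity Bernoulli (0.80 Caucasian in the
diabetes group, 1.00 in controls, the follow-up proportions) — and is what
the Monte-Carlo statistical validation uses (200-replicate effect recovery,
1000-replicate family-wise error), since those criteria test the inference
stage, not the imaging chain. `render = "stacks"` generates full image
pairs with subject-level parameter jitter and group-dependent bone loss for
end-to-end validation. The ethnicity shift on the primary outcome defaults
to −34 % for Caucasians: calibrated by simulation so the realized
ethnicity–outcome correlation averages −0.36 at n = 35. A naive closed-form
back-calculation (r · SD_y / SD_x ≈ −18) misses two effects — the shift
itself inflates the outcome SD, and the group offset partially cancels the
covariance because the less-Caucasian group also has the lower outcome
mean — and lands at r ≈ −0.17; the simulation-based value is the one the
generator documents and tests.

**What passing tests do and do not show.** The generator's cells are
isotropic polygons; real intertrabecular spaces are elongated and
plate-rod structured. Hence Tb.Sp on synthetic data (~0.86 mm) sits above
the study scale (~0.55 mm) even though hole size, hole count, BV/TV,
endosteal area and Tb.Th all land on it, and skeleton densities
(~0.4 nodes/mm²) exceed the measured ~0.16/mm² — a Voronoi lattice with N
cells necessarily carries ~2N junctions, while the coarser real network at
this resolution resolves fewer. Matching *all* nine variables
simultaneously is impossible in this texture family; the package treats
hole count/size, BV/TV and area as the anchored scales and validates the
remaining estimators by oracle equivalence and closed-form fixtures rather
than by scale emulation.

## Registration design

Normalized cross-correlation is the similarity metric: the acquisition
software's metric is unpublished, and NCC is invariant to the global
intensity scaling expected between visits. Through-plane search is
restricted to integer slice offsets — at 1 mm slices vs 0.195 mm in-plane
resolution, through-plane interpolation would fabricate data. In-plane the
transform is rigid (rotation grid ±3° in 0.75° steps, then integer
translation via FFT cross-correlation, scored by exact NCC on the central
matched pair); the braced forearm justifies nothing more flexible. The
reported shift/rotation is the *displacement* of the follow-up relative to
baseline (the inverse of the aligning transform), matching how the
generator records planted misalignments. Pairs scoring below a floor
(default NCC 0.35) are declared unmatchable and the subject is excluded
and logged, mirroring motion-artifact exclusions. Measurements are taken on
the native follow-up grid — the transform informs slice pairing and QC but
no image is resampled before measurement, avoiding interpolation bias in
the binarization.

The distal reference slice is supplied manually in clinical use; for
synthetic stacks the generator can mark a dense growth-plate band and
`detect_reference_slice()` finds the first slice past it (per-slice bone
fraction below 0.60), which the tests hold to the recorded ground truth.

## Inference design

* **Adjusted means** are classic least-squares means: model predictions per
  group with covariates at the grand sample mean; SEs by the delta method.
  With no covariates the procedure reduces *exactly* (tested to 10⁻¹⁰) to
  the pooled-variance two-sample t-test.
* **Covariate screening** follows the study's stated principle: a covariate
  enters if its Pearson correlation with the primary outcome has p < 0.05.
  Zero-variance covariates are dropped with a warning (the all-Caucasian
  control group makes this a live case), collinear sets are an error naming
  the offending columns.
* **Holm family size m = 9**: all nine variables including the primary.
  This choice reproduces the published adjusted values exactly
  (0.010 × 9 = 0.090, 0.119 × 8 = 0.952), which resolves the otherwise
  ambiguous question of whether the primary outcome entered the family.
  The step-down arithmetic is delegated to `stats::p.adjust(method =
  "holm")` behind a validating wrapper; the tests hold it to a literal
  transcription of the definition.
* **Precision statistics**: RMSCV% = 100 · √(mean over subjects of
  (SD/mean)²) across replicate measurements; ICC is the one-way
  random-effects, single-measurement form — the form is fixed and
  documented because the citation styles vary and no alternative forms are
  offered. Replicate structures other than re-scan/re-analysis designs
  yield figures that are not comparable across studies; the function
  accepts any replicate structure and says so.
* **Descriptive tests** default to the pooled-variance t (Welch optional)
  and chi-square without continuity correction (optional with); published
  categorical cell counts at this scale are often internally inconsistent
  with stated group sizes, so categorical reproduction is treated as
  non-anchorable.

## Numerical choices and degenerate inputs

* Otsu thresholds use a 256-bin histogram over the observed within-mask
  range; constant histograms are errors, as are single-phase images for
  the phase-specific estimators.
* Seeded region growing takes seeds in raster order; labeling is
  permutation-invariant by construction (components are order-free).
* Thinning processes candidates in raster order within four directional
  subcycles; ties in the bone-loss thinning of the generator are broken by
  a seeded jitter so stacks are bit-reproducible.
* All internal values are kept at full precision; printing rounds to the
  reporting precision of the field (2 decimals for mm and /mm, 1 for %,
  integers for counts).
* Every stochastic function takes an explicit integer seed and restores the
  caller's RNG state; fixed seed ⇒ bit-identical output, which the pipeline
  manifest and tests assert.

## Problem sizes used in validation

The shipped validation uses sizes chosen to exercise every code path at
full fidelity while keeping the suite fast on one CPU: 8–11-slice stacks of
~112 × 112 px at the 0.195 mm scale for imaging checks; 100 random 64 × 64
maps for the labeling oracle; all sizes 16–64 for the exhaustive
maximal-disc oracle; 200 cohort replicates for effect recovery and 1000 for
family-wise error at the study's n = 14/21. The statistical replicates use
the values-mode generator; the imaging chain is validated separately on
rendered stacks.

## Known limitations

* 2D per-slice analysis understates the 3D connectivity of the network; no
  structure-model-index or 3D connectivity density is offered, by scope.
* The Voronoi texture cannot match Tb.Sp and skeleton densities to the
  study scale simultaneously with hole statistics (see above).
* Registration assumes rigid in-plane motion and integer slice
  correspondence; deformable motion or partial-slice offsets alias into
  measurement noise.
* The precision module computes RMSCV/ICC for whatever replicates it is
  given; it cannot recreate a specific published precision study design.
* Real-data mode expects the user to drive `read_stack()` /
  `register_pair()` / `measure_volume()` directly; only the synthetic
  pipeline is orchestrated end to end by `run_pipeline()`.
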