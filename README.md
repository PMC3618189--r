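# trabmorph

Quantification of apparent trabecular bone microarchitecture from axial
grey-level image stacks of the distal radius, and covariate-adjusted
comparison of its longitudinal change between groups.

Peripheral MRI of the distal radius (here emulating a 1 T acquisition with
195 µm × 195 µm × 1000 µm voxels, 20 axial slices) resolves the trabecular
network well enough to measure nine *apparent* structural variables per
visit, inside the endosteal border of the radius:

| variable | definition | units |
|---|---|---|
| Hole size | mean area of marrow regions grown by region growing | mm² |
| Number of holes | count of marrow regions per slice | – |
| Endosteal area | area enclosed by the endosteal border | mm² |
| BV/TV | bone pixels / endosteal pixels | % |
| Tb.Th | mean maximal-inscribed-disc diameter, bone phase | mm |
| Tb.Sp | mean maximal-inscribed-disc diameter, marrow phase | mm |
| Tb.N | BV/TV ÷ Tb.Th | /mm |
| Nodal density | skeleton junctions per endosteal area | /mm² |
| Branch density | skeleton segments per endosteal area | /mm² |

The longitudinal design measures each subject at baseline and at a ~2-year
follow-up visit: visits are matched through-plane by integer slice offset and
in-plane by a rigid transform (normalized cross-correlation), 8 matched
slices form the analysis volume, and per-subject percent change
(100 × (follow-up − baseline) / baseline) is compared between groups
(e.g. type 2 diabetes vs control) by ordinary least squares with covariate
adjustment (least-squares means), with Holm step-down correction across the
nine-variable family.

Because no real image data ship with the package, a synthetic generator
provides ground truth for every stage: trabecular slices are Voronoi-edge
lattices (marrow cells = Voronoi cells of a jittered point process inside an
endosteal disc, trabeculae = calibrated-width cell boundaries, plus a
cortical rim), rendered with bone dark / marrow bright, Gaussian PSF blur
and additive noise; follow-up visits are derived by surface thinning of a
stated bone fraction plus a recorded rigid misalignment; cohorts plant
known group effects and a known ethnicity–outcome correlation.

## Worked example

```r
library(trabmorph)

p <- trabecular_params(seed = 7)   # study-scale defaults
st <- generate_stack(p, n_slices = 8)
measure_volume(st)
```

```
Trabecular microarchitecture profile (8-slice mean)
  Hole size        1.98 mm^2
  Number of holes  68
  Endosteal area   260.7 mm^2
  BVTV             48.1 %
  Tb.Th            0.53 mm
  Tb.Sp            0.86 mm
  Tb.N             0.91 /mm
  Nodal density    0.41 /mm^2
  Branch density   0.70 /mm^2
```

The measured profile recovers the generator's targets: BV/TV 48.1 % against
a planted 47.7 %, 68 holes per slice as planted, endosteal area 260.7 mm²
against the planted disc's 265.9 mm² (−2 %), and Tb.N consistent with
BV/TV ÷ Tb.Th. Hole size and Tb.Sp both describe marrow spaces but differ by
construction: one is a region area, the other a maximal-disc diameter.

Holm step-down correction of a nine-variable family of raw p-values:

```r
raw_p <- c(hole_size = 0.172, hole_count = 0.010, endosteal_area = 0.225,
           bvtv = 0.263, tbth = 0.661, tbsp = 0.206, tbn = 0.119,
           nodal_density = 0.221, branch_density = 0.566)
round(holm_adjust(raw_p, m = 9), 3)
```

```
     hole_size     hole_count endosteal_area           bvtv           tbth
         1.000          0.090          1.000          1.000          1.000
          tbsp            tbn  nodal_density branch_density
         1.000          0.952          1.000          1.000
```

Only the smallest raw p survives multiplication by its step-down factor
below conventional thresholds (0.010 × 9 = 0.090); everything at or above
0.119 × 8 = 0.952 is effectively capped.

An end-to-end synthetic study (generate → register → measure → change →
compare) runs with one call:

```r
run <- run_pipeline(list(seed = 5, n_diabetes = 4, n_control = 4,
                         output_dir = "results/run1"))
print(run)
```

which writes per-visit profiles, per-subject changes, the adjusted
comparison table, a QC report of excluded subjects and a reproducibility
manifest. A thin command-line wrapper is installed at
`inst/scripts/trabmorph-run`.

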