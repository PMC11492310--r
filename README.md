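# npCTV

Rule-based auto-contouring of clinical target volumes (CTVs) for
nasopharyngeal cancer radiotherapy.

Delineating nasopharyngeal CTVs is slow and inter-observer variable:
the protocol prose ("expand the gross tumor by 3 mm, cover the inferior
sphenoid sinus for T1–T2, include level Ib only on an involved
hemineck, ...") has to be re-interpreted case by case. `npCTV`
implements that interpretation as explicit, auditable geometry. Given
binary masks of the head-and-neck anatomical structures (from any
segmentation source), the primary and nodal gross tumor volumes
(GTVp, GTVn) and the TNM stage, it constructs:

* **CTV1 = CTV1p ∪ CTV1n** — high dose: GTV + 3 mm, margin reduced to
  as low as 0 mm against critical organs at risk,
* **CTV2** — intermediate dose for selected nodes (small level-Ib
  nodes, d < 2 cm by equivalent-sphere diameter, and low-neck nodes),
* **CTV3 = CTV3p ∪ CTV3n** — intermediate dose: the landmark-driven
  primary volume (CTV1p + 5 mm, per-slice anatomical landmark polygons
  smoothed by Chaikin corner-cutting, stage-dependent sphenoid/clivus
  coverage, whole nasopharynx) plus the scenario-dependent elective
  nodal levels,
* **CTV4** — low dose, uninvolved low neck (levels IV / Vb),
* **CTV-Expansion = CTV1 ∪ CTV2** and **CTV-Overall**, the outer
  envelope of all tiers.

All margins are physical millimetres computed with an exact
anisotropic Euclidean distance transform; nodal coverage follows a
nine-scenario hemineck table; discrete islands of CTV3 are joined with
per-slice alpha shapes; final volumes are morphologically refined and
have the brain, spinal cord, optic apparatus, orbits, vertebral
column/bodies, hyoid, cricoid and mandible subtracted (outside the
protected GTV core). A seeded geometric head-and-neck phantom
generator makes the whole pipeline testable without patient data, and
`dsc()` / `msd()` provide Dice and mean-surface-distance comparison of
contour sets.

Intended users: radiotherapy physicists and auto-contouring
researchers who need protocol-faithful target volumes from existing
structure segmentations, or a reproducible reference implementation to
adapt to another contouring guideline (the landmark rules are a data
file, not code).

## Worked example

```r
library(npCTV)

# a synthetic T2 N1 case: 42 head-and-neck structures on a
# 128 x 128 x 80 grid at (1, 1, 2.5) mm, one 15 mm left level-II node
ph   <- generatePhantom(phantomSpec(seed = 7))
ctvs <- runPipeline(ph$structures, ph$tumor)
ctvs
#> CTVSet with 10 volume(s), 10 provenance step(s)
#>   ctv1p             9164 voxels     22.91 cm^3
#>   ctv1n             1722 voxels      4.30 cm^3
#>   ctv1             10886 voxels     27.21 cm^3
#>   ctv2                 0 voxels      0.00 cm^3
#>   ctv3p            27692 voxels     69.23 cm^3
#>   ctv3n            30391 voxels     75.98 cm^3
#>   ctv3             59652 voxels    149.13 cm^3
#>   ctv4             14724 voxels     36.81 cm^3
#>   ctv_expansion    10886 voxels     27.21 cm^3
#>   ctv_overall      74362 voxels    185.91 cm^3
```

The numbers read exactly as the protocol prescribes: CTV1p (22.9 cm³)
is the 14 cm³ GTVp plus its 3 mm margin; a level-II node meets neither
CTV2 condition (small level-Ib, or low-neck IV/Vb), so CTV2 is empty
and the node goes to CTV1n as node + 3 mm (4.3 cm³); the
left level-II involvement selects nodal scenario 3 (elective coverage
of Ib on the left plus bilateral II/III/Va in CTV3n, low neck in
CTV4); CTV-Overall is the union of every tier. `ctvProvenance(ctvs)`
returns the ordered log of each step with its parameters, and
`writeCTVSet(ctvs, "out/")` writes one NIfTI mask per volume.

Compare against any reference contours with

```r
evaluateContours(autoSet, referenceSet)   # DSC, MSD (mm), volumes
```

A command-line front end is installed at
`system.file("cli", "ctv.R", package = "npCTV")` with `build`, `eval`
and `phantom` subcommands.

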