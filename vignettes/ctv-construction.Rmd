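---
title: "Rule-based CTV construction for nasopharyngeal cancer: methods and design"
author: "npCTV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based CTV construction for nasopharyngeal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Radiotherapy of nasopharyngeal cancer irradiates not just the visible
(gross) tumor but concentric tiers of suspected microscopic spread —
the clinical target volumes. Protocol guidelines express those tiers
as rules over anatomy: fixed millimetre margins around the gross tumor
volumes, partial or whole inclusion of named structures depending on
T stage and invasion, and hemineck-level decisions about which lymph
node levels to cover depending on where nodal disease sits. `npCTV`
encodes one such rule system as deterministic 3-D mask geometry, so a
structure set plus GTVp/GTVn masks and a TNM stage map to a unique,
auditable set of target volumes.

The construction proceeds in a fixed order:

1. **CTV1p** — GTVp expanded 3 mm, with the margin collapsed (to as
   low as 0 mm) where it would enter a critical organ at risk. The
   expansion is a Euclidean distance-transform threshold in physical
   mm; the collapse is a *protected subtraction*: subtrahend voxels
   are removed unless they lie inside the GTV plus its floor margin.
2. **CTV3p** — the union of (a) CTV1p expanded a further 5 mm (8 mm
   total from the GTVp), (b) per-slice landmark polygons (below),
   (c) the sphenoid sinus target — its inferior half for T1–T2, the
   whole sinus for T3–T4, split at the centroid's axial plane with the
   centroid slice assigned inferiorly — and (d) the whole nasopharynx.
3. **Nodal logic** — each GTVn component is lateralized against the
   sagittal midline (bilateral when at least 5% of voxels lie on each
   side), assigned to the nodal levels it overlaps, and sized by
   equivalent-sphere diameter \(d = 2(3V/4\pi)^{1/3}\). The hemineck
   presence and low-neck (level IV/Vb) involvement flags select one of
   nine coverage scenarios, which dictates the level unions forming
   CTV3n and CTV4. CTV2 collects the 3 mm expansions of small
   (d < 2 cm) level-Ib nodes and of low-neck nodes; CTV1n covers all
   remaining nodes with 3 mm (OAR-protected), so every gross node lies
   in CTV1n or CTV2.
4. **Assembly** — CTV3 = CTV3p ∪ CTV3n; per-slice alpha-shape joining
   of nearby CTV3 islands; subtraction of the normal-structure list
   from every tier with GTV protection; morphological refinement; and
   the composites CTV-Expansion = CTV1 ∪ CTV2 and CTV-Overall (outer
   envelope of all tiers). Every step appends its parameters to a
   provenance log.

## Landmark polygons

The intermediate-dose primary volume is bounded by anatomy rather than
a fixed margin. Axial slices are grouped by which reference structures
they contain (eight groups, from retropharyngeal-node/pterygoid levels
up to the sphenoid sinus alone). On each grouped slice, every group
structure contributes landmarks defined as fractional anchors inside
its bounding box, snapped to a 7 × 7 candidate grid spanning the box:

* maxillary sinuses: the two lateral corners on the boundary between
  the posterior quarter and the anterior three-quarters — the
  posterior quarter of the sinus is the targeted part;
* clivus: the two corners on the anterior-third line when the GTVp
  does not invade the clivus (one third targeted), the posterior
  corners when it does (whole clivus targeted);
* retropharyngeal nodes and pterygoid fossae: the anterior point of
  the vertical mid-line, with the pterygoid anchor shifted to the
  lateral box edge on the hemineck involved by the GTVp;
* nasopharynx and sphenoid sinus: the four box corners; mastoids: the
  two lateral corners.

The landmarks are ordered counter-clockwise about their centroid
(ties by radius, then input order), closed into a simple polygon,
smoothed by three Chaikin corner-cutting passes (each edge replaced by
its 1/4 and 3/4 points, so vertex count doubles per pass and the curve
stays inside the input's convex hull), and rasterized with an even-odd
rule under a fixed half-open boundary convention.

The rules live in `inst/extdata/landmark_rules.yaml`, not in code, so
the same engine can be re-pointed at another guideline by overriding
the file (`ctvConfig(landmark_rules_path = ...)`). The nasopharynx,
mastoid and sphenoid anchors are declared approximations: the rule
language (fractional box anchors + 7 × 7 snapping) pins down the three
structure families above exactly, and box corners are the neutral
default for the rest.

Two grouping details were genuinely open. First, the published group
lists are partially nested (the sphenoid-only group is a subset of the
maxillary+sphenoid group), so "pick the highest-numbered fully present
group" would throw away maxillary landmarks; the engine instead picks
the *most specific* fully-present group (largest structure list, ties
to the more superior group). Second, slices between two grouped slices
are not interpolated; a slice either matches a group or contributes no
polygon.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `ctv1p_margin_mm`, `ctv1n_margin_mm`, `ctv2_margin_mm` | 3 mm | gross-tumor expansions |
| `min_margin_ctv1_mm` / `min_margin_ctv3_mm` | 0 / 1 mm | protected floor near critical OARs |
| `ctv3p_expansion_mm` | 5 mm | CTV1p to CTV3p-expansion |
| `ctv3n_margin_mm` | 5 mm | GTVn margin united into CTV3n |
| `chaikin_iterations` | 3 | polygon smoothing passes |
| `alpha_per_mm`, `max_gap_mm` | 0.2 /mm, 15 mm | island joining |
| `open_mm`, `close_mm` | 1, 2.5 mm | refinement radii |
| `min_hole_voxels`, `min_island_voxels` | 100, 50 | refinement thresholds |
| `bilateral_fraction` | 0.05 | per-side fraction for "bilateral" |
| `small_node_cm` | 2 cm | nodal size criterion |

The margins and the 2 cm / 5% criteria are protocol constants. The
smoothing, island-joining and refinement parameters are the package's
own defaults (three Chaikin passes give sub-millimetre corner error at
1 mm pixels; 1 mm opening removes rasterization specks without eating
structures; 2.5 mm closing matches the slice thickness; the hole and
island thresholds are ~0.1 and ~0.05 cm³ at the working resolution).
`ctv3n_margin_mm` deserves a note: the scenario table alone would make
CTV3n a pure union of elective level masks, but the intermediate-dose
nodal prescription also carries a 5 mm gross-node margin, and without
it a node expanded 3 mm for CTV1n could poke out of its level and
break the dose-tier nesting CTV1 ⊆ CTV3. The scenario construction
(`buildCtv3nCtv4`) stays a pure table lookup; the margin is united in
at assembly.

## Numerical choices

* **Distances.** All margins use an exact squared Euclidean distance
  transform (separable lower-envelope algorithm, compiled) with the
  anisotropic voxel spacing, thresholded inclusively
  (d ≤ margin, with a relative 1e−9 slack so exact lattice ties such
  as 3² ≤ 9 are kept). Erosion is the strict complement-dual, so
  dilation/erosion are consistent and opening/closing are extensive/
  anti-extensive exactly. Discrete opening legitimately shaves
  corner voxels of polyhedral shapes — tests assert bounded boundary
  change, not fake identity.
* **Alpha shapes.** No Delaunay triangulation is needed: the package
  uses the disk-complement characterization — a point belongs to the
  alpha shape iff no empty open disk of radius 1/α covers it — which
  on a raster is a morphological closing with that disk. Joining runs
  per axial slice (the pipeline is slice-polygon based throughout);
  when the smallest inter-island gap is within `max_gap_mm`, the
  closing radius is max(1/α, gap/2 + one voxel diagonal), so gating
  implies the merge; farther islands are left untouched rather than
  discarded.
* **Split/tie rules.** The sphenoid centroid slice goes to the
  inferior half (the half targeted at low stage — inclusive rounding
  is the conservative-coverage choice). Landmark snapping breaks
  candidate ties toward the smaller coordinate. A nodal equivalent
  diameter of exactly 2.0 cm routes to CTV1n (strict d < 2 cm for
  CTV2).
* **Rasterization.** Even-odd with half-open boundaries, so
  translation by a whole voxel pitch preserves voxel counts and
  shared edges are never double-counted.
* **Subtraction order.** Island joining, then normal-structure
  subtraction, then refinement — but closing during refinement can
  push a contour back into a subtracted structure, so the subtraction
  is re-applied once after refinement. This keeps the zero-overlap
  guarantee exact without reordering the pipeline.
* **Empty inputs.** Expanding an empty mask warns and returns empty;
  DSC of two empty masks is 1; MSD of an empty mask is an error.

## The phantom: what it does and does not show

`generatePhantom()` builds all 42 registry structures (27 anatomical
structures and OARs plus 14 nodal level compartments and the skull
base) as boxes/ellipsoids/tubes at fixed relative positions on a
128 × 128 × 80 grid at (1, 1, 2.5) mm — the working resolution the
pipeline resamples to — with mirror-symmetric lateral pairs, seeded
uniform jitter, a GTVp sphere placed confined/bilateral and optionally
clivus-invading, and GTVn spheres centered in requested levels. Jitter
is in-plane only: slice-band placement is quantized to the 2.5 mm
slices, which keeps the guarantee that every axial group matches at
least one slice (superior–inferior positioning uncertainty below one
slice thickness is unobservable on the grid anyway).
`generateScenarioSuite()` yields 12 cases covering all nine nodal
scenarios and all CTV2 condition combinations with analytically known
labels.

The phantom emulates topology and relative position, not shape: real
anatomy has curved, touching, partially-volumed structures, real
structure sets carry segmentation error, and real grids vary in
spacing and orientation. Passing tests therefore demonstrate that the
*rules* are implemented exactly as stated — margins to the voxel,
scenario tables to the level, subtraction guarantees to zero overlap —
not that the resulting contours are clinically acceptable on patients;
that judgment requires clinical data and physician review, which no
synthetic fixture can replace.

Problem sizes used by the tests and the acceptance script: the full
128 × 128 × 80 phantom for end-to-end runs (a complete pipeline run
takes on the order of tens of seconds on one CPU), and ≤ 20³ random
masks wherever a brute-force oracle (pairwise-distance dilation,
flood fill, O(n²) surface distance) verifies a compiled primitive
voxel-for-voxel.

## Known limitations

* NIfTI is the only interchange format (one binary mask per file);
  DICOM RT-STRUCT is not read or written.
* Protocol rows with no algorithmic definition — posterior ethmoid
  sinus coverage, cavernous sinus for T3–4, skull-base foramina —
  exist only as disabled config hooks
  (`cavernous_sinus_coverage` etc.); enabling them has no effect.
* Level Ib omission for T1/2 N0 cases is a config flag
  (`include_ib_t12n0`) without further logic.
* The slice axis must be the superior–inferior axis; oblique
  acquisitions must be resampled upstream.
* Masks are voxel sets; no sub-voxel surface geometry is produced.
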