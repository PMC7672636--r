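---
title: "Methods: 3D morphometry of RPE label volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry of RPE label volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the data
model, the estimators and their assumptions, the measurement
conventions, the synthetic phantom that validates them, and the
numerical choices that were genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The data model

Everything operates on a `label_volume`: a 3D integer grid (0 =
background, each positive id one segmented object), an explicit
`voxel_spacing` in nanometres, and a `label_table` mapping every id to a
(cell, compartment) pair. Compartments follow the segmentation
vocabulary of outer-retina reconstructions: `cell_body`, `nucleus`,
`microvilli`, `basal_infold_space`, `mitochondrion`, `outer_segment`,
`bruchs_membrane`.

Three modelling commitments matter:

* **One label per voxel.** Whether exported tracings may overlap is
  tool-dependent and usually undocumented; this model forbids overlap.
  Compartment masks are unions over labels (a bi-nucleate cell's two
  nuclei are two labels, one mask), so multiplicity is never lost.
* **Spacing is always explicit.** Acquisition pixel size is routinely
  halved by post-hoc downsampling, so TIFF tags are systematically
  untrustworthy; the spacing travels in the label-table JSON or the
  function call, never in image metadata.
* **A fixed orientation contract**: `y` runs apical→basal (microvilli
  at low y, Bruch's membrane at high y), `x` is the lateral in-plane
  axis, `z` the sectioning axis. Linear measurements (heights,
  thicknesses, tilt angles) are meaningless without such a contract; the
  phantom's generator and the test suite enforce it. Internally the
  grid is stored `[y, x, z]` so each slice is a contiguous R matrix.

I/O is deliberately boring: multi-page unsigned-integer TIFF (8- or
16-bit; ids above 65535 are refused rather than silently rescaled) and a
JSON label table. Write-then-read is bit-identical, and reading errors
out on any label the table does not know — an unlabelled object would
silently corrupt every downstream count.

## Shared-area estimation

The slice-wise estimator reimplements the published macro procedure for
measuring the touching edge of two adjacent segmented volumes, with its
behaviour made explicit and parameterised:

1. per slice, threshold object A and object B into binary masks;
2. dilate **A only**, once, with a 3×3 all-ones (8-connected) element —
   the reference platform's default binary dilation with count 1, the
   single biggest unstated parameter of the original;
3. AND with the undilated B; the original's `> 254` test on two
   255-valued masks reduces to exactly this logical AND;
4. `junctionLength = overlap pixels × dx`,
   `junctionArea = junctionLength × dz`; sum over slices.

Two further faithful details: the original's commented-out dilation of
object B is treated as disabled, and its loop `for (i = 1;
i < nSlices; i++)` provably never processes the final slice. Both the
faithful behaviour (`mode = "fidelity"`) and the fixed one
(`mode = "corrected"`, all N slices) exist, distinguishable in every
output's `mode` column; on any scene the fidelity total equals the
corrected total minus the last slice's contribution, an identity the
tests assert.

Known properties, measured rather than hidden:

* **Asymmetry.** Only A is dilated. On flat interfaces swapping A and B
  changes nothing (tested); in general it can. `cell_contact_areas()`
  fixes a canonical order — the lexicographically lower cell id is
  dilated — for determinism.
* **Orientation blindness.** In-plane dilation cannot cross slices, so
  an interface whose normal is the slice axis contributes zero. This is
  inherent to the procedure, which was designed for side-by-side
  neighbours in a monolayer.
* **Staircase bias.** The overlap count follows the L1 (staircase)
  length of the in-plane contact line, so a wall tilted by φ from the
  slice-normal direction reads ≈ (1 + tan φ)·cos φ times its true area.

The **voxel-face oracle** (`shared_area_voxel_faces`) exists precisely
because of these last two points: it counts 6-connected face pairs
between the two labels, weighting x-, y- and z-facing faces by
`dy·dz`, `dx·dz`, `dx·dy`. On an axis-aligned flat x-facing interface it
equals the corrected slice-wise estimate exactly (tested to machine
precision on the analytic two-cuboid fixture); on oblique or z-facing
interfaces it is the orientation-complete reference. Contact tables
report both. The monolayer adjacency graph uses the face area (> 0) as
its edge criterion, so z-neighbours are not spuriously disconnected.

## Morphometry conventions

* **Volume** is voxel count × voxel volume — unbiased and exact for the
  scales involved.
* **Surface area** uses exposed voxel-face counting. The mesh-based
  areas produced by segmentation tools are systematically different
  (staircase counting overestimates oblique surfaces by up to ~1.27×);
  since the reference tooling's mesh algorithm is unstated, the simple
  estimator whose bias is understood was preferred, and every output
  carries an `area_method` field so a mesh estimator can be added
  side-by-side later.
* **Cytoplasm volume** (the whole-cell table convention) includes the
  nuclei and mitochondria but excludes microvilli and sub-RPE spaces.
  This convention is forced by the published arithmetic itself: a
  mono-nucleate whole cell of 2220.2 µm³ minus its 141 µm³ nucleus gives
  exactly the published 2079.2 µm³ nucleus-excluded value, and the two
  bi-nucleate whole cells average to 2231.5 µm³ the same way
  (`summarise_cell_volumes()` reproduces both, and the acceptance tests
  pin them).
* **Photoreceptor support**: an outer segment is supported by a cell iff
  it shares ≥ 1 voxel face with that cell's microvilli. An OS touching
  two cells' microvilli is counted for both and flagged `shared` — at
  50 nm resolution true multi-contact is not distinguishable from a
  tie, so the ambiguity is surfaced, not resolved silently.
* **Densities** (photoreceptors per µm³ cytoplasm) are computed at full
  precision and *reported* at 2 significant figures, the printed-table
  convention. Note one published value does not survive recomputation:
  132 photoreceptors / 2360 µm³ is 0.056 at 2 s.f., not the printed
  0.059 (the partial-cell 102/1733 row does give 0.059). The package
  reports what it computes.
* **Mitochondria** are connected components of the mitochondrion
  compartment at 26-connectivity by default: a human tracer treats
  diagonally touching profiles as one organelle. The choice is
  explicit (`connectivity = 26 | 18 | 6`) and the corner-touch
  behaviour is pinned by a test. Per-component volumes are reported in
  nm³ (the organelle-table scale); `mean × count = total` is an exact
  identity on the unrounded volumes. The **basal fraction** is measured
  against the basal third of the *cell's own* y-extent, not the global
  grid — cells are sheared rhomboids, so global coordinates would
  misclassify.
* **Mitochondrial volume fraction**: the published "% of total
  cytoplasm" is not derivable from the published tables under any
  single denominator (the printed totals and cell volumes give 5.3%
  for the mono-nucleate cell, far from the stated 11.5%), so
  `mito_volume_fraction()` takes the denominator volume as an explicit
  argument instead of hard-coding a guess.

## Linear and angular measurements

The sampling protocol mirrors the manual one: visit every
`slice_interval`-th slice (default 50) and take
`measurements_per_slice` (default 10) seeded-random measurements per
visited slice. Fixed seed ⇒ identical sample sets (tested).

* **Microvillus profiles** are the 8-connected in-plane components of a
  cell's microvilli mask that come within 2 pixels of the cell solid
  (rooted at the apical surface). 4-connected labelling would shatter
  them: a rasterised tilted rod profile is a diagonal staircase.
* **Length and angle** are chord-based: the root is the basal-most
  pixel, the tip is the geodesically farthest pixel from it (weighted
  8-connected distance, used only to *find* the tip), and the
  measurement is the Euclidean root→tip chord. The angle is taken from
  the +x apical tangent, in the slice plane, range (0°, 180°) — chosen
  because the reference measurements exceed 90°, which implies
  measurement from the surface tangent rather than the normal. A
  skeleton-geodesic *length* was rejected deliberately: on a straight
  rod ~37° off-axis the 8-connected path metric overstates length by
  ~4.7% (the classic chessboard-metric bias), a systematic error of the
  same size as the validation tolerance; the chord matches the manual
  two-point protractor measurement the protocol emulates. Verticals
  read 90°; rods parallel to the surface read near 0°/180° by the
  chord's x-direction.
* **Body height** is the y-extent of the cell solid in *through
  columns* — columns reaching both the cell's apical-most and
  basal-most rows of that slice. Shear moves a column's entry and exit
  points but not their separation, so rhomboid cells read their true
  apical-basal height (tested at 25° shear); edge columns truncated by
  the slanted walls are excluded by construction. Combined epithelial
  height is the explicit sum of mean body height and mean microvillus
  length, mirroring how the composite figure is reported.
* **Membrane thickness** is the contiguous run of Bruch's-membrane
  voxels along y at a sampled column, × dy, in nm. Columns without
  membrane are skipped and counted, never zero-filled. The measurement
  is along y only (no surface-normal estimation): exact for the flat
  phantom slab and the on-screen vertical protocol it reproduces, a
  documented limitation for strongly curved membranes.

## The phantom

`generate_phantom()` emulates the segmented outer-retina scene at the
reconstructed magnitudes: a monolayer grid of rhomboid cells (15° shear;
width 10 µm, body height 6.7 µm), 1 or 2 ellipsoidal nuclei per cell,
spherical basal infold pockets, ellipsoidal mitochondria (axes jittered
±30% — the organelles are a heterogeneous population — placed 80% in
the basal third), unidirectional apical microvilli rods (5.5 µm at 143°,
radius 0.1 µm, 90 per cell), one collinear photoreceptor outer-segment
rod continuing each microvillus (90 per cell, within the reported
90–216 range; the count is a direct spec parameter, since only a range
is reported), and a Bruch's membrane slab whose per-column thickness is
drawn from a truncated Gaussian (524.4 ± 200.5 nm). Default spacing is
50 nm isotropic: a full-size cell at the acquisition's in-plane
resolution would be a ~10⁹-voxel scene, while at 50 nm the default
2×2-cell scene is 64 M voxels and every estimator runs in seconds to a
couple of minutes on one CPU; spacing is a spec field, so
higher-fidelity runs remain possible.

Construction rules worth knowing:

* **Rasterisation is voxel-centre-in-solid** — unbiased under sub-voxel
  placement jitter, with analytic solid volumes (prism W²H, ellipsoid
  4/3·π·abc, capsule πr²L + 4/3·πr³) recorded as ground truth.
* **Precedence**: membrane < cell body < infold pocket < nucleus <
  mitochondrion < microvilli < outer segment; later layers win, carved
  voxel counts are recorded in `truth$overlaps`, and truth volumes are
  the analytic volumes *after* carving (the cap an OS bites out of its
  microvillus is computed in closed form), so rasterised and true
  volumes are directly comparable. Rods carrying an OS get their axis
  extended by exactly the carved allowance, so the spec's
  `microvilli_length` is the visible, measurable length.
* **Placement** uses one seeded generator in a fixed documented order
  (per cell: nuclei, pockets, mitochondria, microvillus roots, OS
  subset; then the membrane field), so scenes are bit-reproducible.
  With `ensure_separation = TRUE` organelles are placed with
  conservative bounding-sphere rejection, guaranteeing that
  connected-component counts equal seeded counts exactly.
* **Microvillus roots** sit on a jittered grid whose x-columns are
  staggered in z by a golden-ratio offset, wrapped within the footprint.
  The stagger keeps the circular z-lattice (and hence the rod-to-rod
  separation that guarantees one-OS-one-cell contact) intact across
  cell boundaries while spreading rods over all slices — without it the
  rods would bunch into a few discrete z-bands that an interval-sampling
  protocol could miss entirely.

What the phantom does **not** emulate — and therefore what passing
recovery tests do and do not show: there is no greyscale texture or
segmentation error (truth is exact, so recovery tests validate the
*estimators*, not robustness to tracing noise); microvilli are straight
parallel rods, not wrapping tufts; the monolayer is flat (no retinal
curvature, so the y-only thickness measurement is exact here by
construction); there are no inner segments, synapses or choroid; and
real inter-cell walls are gently curved where the phantom's are planar,
so the slice-wise estimator's staircase bias shows up more starkly on
the phantom than it would in tissue.

## Numerical choices and degenerate inputs

* Membrane thickness draws are truncated to [dy, µ + 3.5σ]: a Gaussian
  tail below one voxel cannot be rasterised, and an unbounded upper tail
  would force unbounded grids. At the default parameters the truncation
  shifts the mean by well under 1%.
* Ties in root selection (several basal-most pixels) break to the
  smallest x; component sampling uses the scheme seed; everything else
  is deterministic.
* Empty masks are legal everywhere and return zeros (with a warning
  where a compartment was *requested* but absent); an absent label id is
  always an error.
* Single-slice stacks are rejected only in fidelity mode, whose loop
  would process zero slices.
* Sample SD uses the n−1 denominator (these are samples of a
  measurement protocol); n = 1 reports SD 0 with an explicit
  `sd_defined = FALSE` flag.

## Validation surface and problem sizes

The test suite validates: exact identities on analytic fixtures (the
two-cuboid interface at 8×8×50 nm, closed-form surface areas, the
published-table arithmetic), property-style invariants under seeded
random scenes (monotonicity of shared area, rotation invariance of
surface area, volume additivity, mask partition, mean×count=total), and
stochastic recovery on the default 64 M-voxel phantom: compartment
volumes within 5% of analytic truth (observed well under 1%),
photoreceptor counts and non-overlapping mitochondria counts exact
(including a 422-seed scene), microvillus tilt within 2° of 143°, and
membrane thickness within 5% of 524.4 nm using 50 columns on every 50th
slice (n = 400, mirroring the pooled n > 300 manual protocol —
10 per slice on an ~400-slice desk-scale stack gives n = 80, whose
sampling error alone approaches the tolerance). The same recovery run,
from scratch, is what `scripts/acceptance.R` reports.

Real-tissue population statistics (the 48.1 ± 19.2 µm² contact area,
5.5 ± 1.1 µm microvilli, measured mitochondria volumes) are **not**
reproducible without the original EM stacks, which were never deposited;
they enter this package as phantom default parameters and as
reporting-format conventions, and the synthetic recovery above is the
acceptance surface.

## Known limitations

* Surface areas and slice-wise contact areas carry staircase bias on
  oblique surfaces; a mesh (marching-cubes) estimator is the natural v2
  extension behind the existing `area_method` field.
* The slice-wise estimator is blind to z-facing interfaces by design;
  use the voxel-face area (always reported alongside) when orientation
  completeness matters.
* Thickness is measured along y, not along the local surface normal.
* No contact measurement between compartments of the same cell, and no
  registration or greyscale handling — the package starts from finished
  label volumes.
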