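# rpemorph

Quantitative 3D morphometry for segmented serial block face scanning
electron microscopy (SBF-SEM) stacks of the outer retina.

The retinal pigment epithelium (RPE) is a monolayer between the
photoreceptors and the choroid. Volume-EM reconstructions of RPE cells
yield integer *label volumes* — 3D grids in which every voxel carries the
id of the segmented object it belongs to (cell body, nucleus, apical
microvilli, basal infold spaces, mitochondria, photoreceptor outer
segments, Bruch's membrane). `rpemorph` turns such label stacks into the
quantities a reconstruction study reports: per-cell compartment volumes
and surface areas, nucleus-excluded cytoplasm, the number of
photoreceptors each cell supports, cell–cell contact areas, mitochondria
counts and volume statistics, microvillus length and tilt angle,
epithelial height, and Bruch's membrane thickness. It is written for
microscopists and image analysts who have finished segmentation (TrakEM2,
Amira, or any tool that exports labelled TIFF stacks) and need tested,
reproducible measurements.

Because volume-EM studies rarely deposit their raw stacks, the package
ships a synthetic outer-retina **phantom** generator whose scenes have
analytically known ground truth (prism, ellipsoid and capsule volumes;
planar interface areas; seeded thickness fields). Every estimator in the
package is validated by recovering that truth.

## The estimators

**Slice-wise shared area** (the field's macro procedure): for two labels
A and B, per slice *k*,

    overlap_k  = dilate8(A_k) AND B_k          (one 3x3 dilation of A only)
    junctionArea_k = |overlap_k| * dx * dz
    junctionArea_total = sum_k junctionArea_k

`mode = "fidelity"` replicates the original loop bound
(`for (i = 1; i < nSlices; i++)`), which skips the final slice;
`mode = "corrected"` processes all N slices. Because the dilation is
in-plane, the estimator cannot see interfaces whose normal is the slice
axis; the package therefore also provides the orientation-complete
**voxel-face oracle** (6-connected face counts weighted by `dy*dz`,
`dx*dz`, `dx*dy`), which agrees with the corrected slice-wise estimate
exactly on flat in-plane interfaces.

**Morphometry**: volume = voxel count × `dx*dy*dz`; surface area =
orientation-weighted exposed voxel faces; an outer segment is *supported*
by a cell iff it shares at least one voxel face with the cell's
microvilli; mitochondria are 26-connected components (configurable) of
the mitochondrion compartment.

**Geometry** (the manual measurement protocol, automated): every n-th
slice is visited and a seeded number of measurements taken per slice —
microvillus root→tip chord length and angle from the +x apical tangent,
through-column body height, and contiguous-run Bruch's membrane
thickness, all reported as mean ± SD.

## Worked example

Generate a small two-cell phantom and measure everything:

```r
library(rpemorph)

spec <- phantom_spec(n_cells_x = 2, n_cells_z = 1, cell_width = 6,
                     cell_body_height = 6.7, nuclei_per_cell = c(1, 2),
                     nucleus_semiaxes = c(1.2, 1.0, 1.2),
                     rods_per_cell = 36, os_per_cell = 36,
                     mito_per_cell = 40, seed = 1)
ph <- generate_phantom(spec)
ph$volume
#> <label_volume> 267 x 422 x 132 voxels (y, x, z) at 50 x 50 x 50 nm
#>   84 labels over 75 cells

cell_summary(ph$volume, "cell_1")
#>   cell_id n_nuclei cytoplasm_volume_um3 nucleus_excluded_volume_um3
#> 1  cell_1        1                  238                       231.9
#>   photoreceptors_supported photoreceptor_density_2sf
#> 1                       36                      0.15

cell_contact_areas(ph$volume)
#>   cell_a cell_b      mode total_area_um2 face_area_um2
#> 1 cell_1 cell_2 corrected             51            51

sch <- sampling_scheme(slice_interval = 25, measurements_per_slice = 10,
                       seed = 1)
microvillus_geometry(ph$volume, "cell_1", sch)
#> <microvillus_geometry> cell_1
#>   length: 5.51 um ± 0.0382 SD (n = 6)
#>   angle:  143 deg ± 0.259 SD (n = 6)

rpe_height(ph$volume, "cell_1", sch)
#> <rpe_height> cell_1: body 6.7 um ± 0.012 SD (n = 50);
#>   + microvilli 5.51 um = 12.2 um combined

brm_thickness(ph$volume, sch)
#> <brm_thickness> 496 nm ± 182 SD (n = 50)

mitochondria_stats(ph$volume, "cell_2")
#> <mitochondria_stats> cell_2: 40 organelles, mean 1.12e+08 nm^3,
#>   total 4.48e+09 nm^3 (26-connectivity)
```

The scene was built with 5.5 µm microvilli at 143°, a 6.7 µm cell body
and a 524.4 ± 200.5 nm membrane — the measurements above recover those
inputs (contact area 51 µm² is the two cells' shared 6 × 6.7 µm sheared
face, staircase-counted). `tidy()`/`glance()` turn every result into a
tibble, `autoplot()` draws it, and `run_all(run_config(...))` writes the
whole report bundle (morpho/mito/interfaces/contacts/geometry/summary
CSVs plus a `run.json` manifest) for a stack on disk or a phantom spec.

Real label stacks enter through
`read_label_stack("stack.tif", voxel_spacing(8, 8, 50), "labels.json")`,
where the JSON label table maps each label id to its cell and
compartment.

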