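# phantomct

Convert tetrahedral-mesh (TM) computational human phantoms into a DICOM
study — a CT image series plus a linked RT-structure set — that a
radiotherapy treatment-planning system (TPS) can import.

TM phantoms partition a body into tetrahedra, each carrying an organ ID and
hence a mass density. They are the most anatomically faithful computational
phantoms available (thin tissues keep their real thickness; postures deform
freely), but clinics speak DICOM. `phantomct` bridges the two and quantifies
the geometric cost of the translation.

**Who it is for:** medical physicists and phantom developers who need
whole-body or posture-deformed phantoms inside a TPS (e.g. for out-of-field
dose studies), and anyone validating mesh-to-image conversion chains.

## Method

Per voxel *V* of the CT grid, the density is the volume-fraction mixture

> *D<sub>V</sub>* = Σ<sub>i</sub> *w<sub>i</sub>* · *D*<sub>tet,i</sub> + (1 − Σ<sub>i</sub> *w<sub>i</sub>*) · *D*<sub>bg</sub>

where *w<sub>i</sub>* is the fraction of *N* = round(1000 · voxel mm³)
uniform random points claimed by tetrahedron *i* (boundary-inclusive
barycentric membership, first-claiming-tet tie-break) and *D*<sub>bg</sub> is
air. Densities become integer HU through a piecewise-linear calibration
table (air/water/bone anchors by default) and are written as an
explicit-VR-little-endian CT series (stored = HU + 1024, RescaleIntercept
−1024). In parallel, each contoured organ's boundary surface — the faces
belonging to exactly one of its tetrahedra — is sliced at the CT
slice-centre planes, chained into closed CCW polygons, and written as
`CLOSED_PLANAR` contours referencing the CT slices by SOPInstanceUID.

Conversion fidelity is reported per organ as |A − B| / A × 100 %, with
A = summed tetrahedron volume and B = contour-stack volume
(Σ slice polygon areas × slice thickness, the TPS convention).

Everything is deterministic: per-voxel counter-based RNG streams make the
voxelization independent of traversal order, and a fixed-clock flag makes
whole studies byte-reproducible. A voxelization cache lets a phantom be
reconverted in seconds.

## Worked example

Build a synthetic two-organ phantom (a 12 mm sphere inside a 60 mm cube of
unit-density "body"), convert it, and read the volume report:

```r
library(phantomct)

rec <- phantom_recipe(
  list(shape = "sphere", radius = 12, center = c(0, 0, 0), organ_id = 1L,
       density = 1.05, name = "Ball", level = 3L),
  list(shape = "box", extents = c(60, 60, 60), center = c(0, 0, 0),
       organ_id = 2L, density = 1.00, name = "Body"))
ph <- build_phantom(rec)

cfg <- run_config(mesh = ph$mesh, materials = ph$materials,
                  contours = ph$spec, out_dir = "demo_study",
                  fov_mm = 100, resolution = 128L, slice_thickness = 2,
                  seed = 1, verbose = FALSE)
res <- run_convert(cfg)
print(res$report)
#> Organ volume comparison (A = mesh, B = contours):
#>  organ_id name  A_cm3  B_cm3 pct_diff
#>         1 Ball   7.18   7.20     0.36
#>         2 Body 216.00 216.00     0.00
print(res$link)
#> study link OK (42 contour references verified)
```

`demo_study/` now holds 30 CT slices plus `RS.rtstruct.dcm`, one linked
study. A = 7.18 cm³ is the tetrahedral Ball volume (slightly below the
analytic 7.24 cm³ — the mesh is an inscribed polyhedron); B = 7.20 cm³ is
what a TPS will measure from the contours; 0.36 % is the conversion's volume
distortion at these coarse demo settings (it drops well below 0.1 % for
organ-scale structures at the default 500 mm FOV / 512² / 2 mm settings).
The Body, a grid-aligned box, is sliced exactly.

The same pipeline is scriptable from a shell via the thin CLI in
`inst/scripts/phantomct` (subcommands `convert`, `report`, `make-phantom`).

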