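---
title: "From tetrahedral-mesh phantoms to DICOM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tetrahedral-mesh phantoms to DICOM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tetrahedral-mesh (TM) computational human phantoms represent a body as a
conforming partition into tetrahedra, each labelled with an organ and hence a
mass density. They describe anatomy far more faithfully than voxel phantoms —
thin structures keep their true thickness, and postures can be changed by
moving nodes — but clinical treatment-planning systems (TPS) only consume
DICOM: a CT image series plus an RT-structure set of named, closed planar
contours. `phantomct` performs that conversion in one run, and quantifies how
much organ volume the conversion distorts.

The pipeline has two cooperating halves that share one geometry:

1. **CT generation.** The phantom is resampled onto a regular CT voxel grid.
   Each voxel's density is a tetrahedron-volume-weighted mixture, estimated by
   Monte-Carlo point sampling; densities become integer Hounsfield units (HU)
   through a piecewise-linear calibration table and are written as one DICOM
   CT file per slice.
2. **RT-structure generation.** Each contoured organ's boundary surface is
   extracted from its tetrahedra, sliced by the transverse planes through the
   CT slice centres, chained into closed polygons, and written as
   `CLOSED_PLANAR` contours that reference the CT slices by SOPInstanceUID.

## Voxel densities by Monte-Carlo volume fractions

For voxel $V$ the density is

$$D_V = \sum_{i=1}^{n} w_i \, D_{\mathrm{tet},i} + \Big(1 - \sum_i w_i\Big)\, D_{\mathrm{bg}},$$

where $w_i$ is the fraction of uniform random points in $V$ claimed by
tetrahedron $i$ and $D_{\mathrm{bg}}$ is the background (air,
0.00120 g/cm³) filling whatever no tetrahedron claims. The point budget is
`points_per_mm3` = 1000 by default, i.e. $N = \mathrm{round}(1000 \cdot
\mathrm{vox\ mm^3})$ points per voxel (≈1907 for the default
0.976562 × 0.976562 × 2 mm voxel). Membership is a boundary-inclusive
barycentric test with tolerance `tol` = 1e-9; a point on a shared face is
awarded to the lowest-indexed claiming tetrahedron, so
$\sum_i w_i \le 1$ always holds and equals 1 exactly inside an organ.

Three implementation decisions matter for reproducibility and speed:

* **Counter-based seeding.** Every voxel derives an independent RNG stream
  from (seed, global voxel linear index). Results are therefore independent
  of traversal order, of the organ sub-grid a voxel happens to be visited
  from, and of any parallel schedule — serial and accelerated runs are
  bit-identical, which the tests assert.
* **Spatial bin index.** Candidate tetrahedra per voxel come from a uniform
  bin index over tetrahedron bounding boxes. The candidate set is filtered to
  exact AABB-voxel overlap, so the accelerated result equals the brute-force
  all-tets scan bit for bit (also asserted).
* **Exact interior shortcut.** Barycentric coordinates are affine, so their
  extrema over a box are attained at its corners. If the lowest-indexed
  candidate contains all eight voxel corners (within `tol`) and every
  earlier candidate is separated from the voxel by one of its own
  barycentric planes, then *every* random point would have been claimed by
  that candidate: the kernel assigns $w = 1$ without drawing points. This is
  the provably-equal case, not an approximation, and it is what makes
  torso-scale conversions affordable on one CPU.

Mass conservation is the key invariant: the grid mass
$\sum_V D_V \cdot v_{\mathrm{vox}}$ must match the mesh mass
$\sum_i D_{\mathrm{tet},i} V_i$ within three binomial standard errors summed
over partially-claimed voxels. The tests check this on sphere and box
fixtures, and that doubling the point budget does not increase the expected
error.

## HU mapping

Densities map to HU through a piecewise-linear table, linearly extrapolated
beyond its terminal breakpoints, rounded half-away-from-zero, and clamped to
the 12-bit-plus-sign CT range [−1024, 3071]. The default table uses the
standard air (0.00120 → −1000), water (1.000 → 0) and cortical-bone
(1.92 → 1524) anchors and is fully replaceable via a two-column text file;
every volume-preservation figure in this package is contour-based and hence
independent of the table. Pixels are stored unsigned 16-bit with
RescaleIntercept −1024 and RescaleSlope 1, so `stored × slope + intercept`
reproduces the HU grid exactly — asserted voxelwise in the tests.

## Contours

`extract_surface()` collects the faces belonging to exactly one of an
organ's tetrahedra (the boundary of the organ solid), oriented outward; a
face shared by more than two tetrahedra aborts with a non-manifold
diagnostic. Slicing intersects each triangle with the plane through a CT
slice centre. Two degeneracy policies keep this robust:

* a vertex within `eps` (10⁻⁶ mm) of the plane moves the *plane*, not the
  vertex: the slice height is perturbed by +eps until clear;
* intersection points on a shared triangle edge are computed with the edge
  endpoints taken in vertex-index order, so adjacent triangles produce
  bit-identical endpoints and loop chaining can use a tight tolerance
  (10⁻⁶ mm) — looseness there would hide real watertightness bugs.

Chains must close; an open chain reports the gap distance and fails.  Outer
loops are oriented counter-clockwise viewed from +z, holes clockwise
(even-odd nesting parity). The contour-stack volume is
$\sum_{\mathrm{slices}} (\text{outer areas} - \text{hole areas}) \times
\text{thickness}$ — the same estimate a TPS computes — reported in cm³
against the organ's summed tetrahedron volume as
$|A - B| / A \times 100\,\%$.

Contours are taken at the CT slice-centre z positions rather than at
arbitrary planes so the RT-struct and the CT share their frame of reference
exactly; contour points are emitted raw (no decimation), with an optional
collinear-pruning step deliberately left out of the default path.

## Synthetic validation phantoms

Licensed reference phantoms cannot be redistributed, so validation runs on
analytic-volume synthetic phantoms generated in code:

* **Boxes** — cells split into 5 tetrahedra with checkerboard parity
  (neighbouring cells mirror, so face diagonals match); volume exact.
* **Spheres/ellipsoids** — concentric icosphere shells joined by prisms,
  each prism split into 3 tetrahedra with quad diagonals through the lowest
  global vertex index (adjacent prisms agree, so the mesh conforms); the
  innermost shell is coned to the centre. This layered construction keeps
  tetrahedra locally sized — a single cone to the centre would give every
  tetrahedron a phantom-scale bounding box and defeat the spatial index.
  The mesh is inscribed, so its volume is strictly below $(4/3)\pi abc$; the
  generator returns a chord-sagitta bound on the deficit, and refinement
  strictly shrinks it.
* **Deformations** — affine maps and circular-arc bends emulate posture
  change. Bends rotate cross-sections by $\kappa (z - z_0)$ about an axis at
  the bend radius $1/\kappa$; any inverted tetrahedron rejects the
  deformation. After a bend, the deformed mesh's own summed tetrahedron
  volumes are the ground truth A — the comparison asks whether *conversion*
  preserves volume, not whether the bend does.

The default validation recipe is a 300 × 200 × 400 mm unit-density torso box
enclosing a 1400 cm³ ellipsoid (half-axes 90, 70, 53.05 mm) and a 2 cm³
small-organ analogue (half-axes 5, 6, 15.92 mm), both 1.05 g/cm³. Enclosed
organs are listed before the enclosing body: the first-claiming-tet rule then
lets organs win their interior while the body claims the rest, which is how
a surrounding-tissue compartment behaves in real phantoms.

### Why these shapes: the slice-discretization error budget

The contour-stack volume is a midpoint-rule quadrature of the organ's
cross-section area $A(z)$ with step $t$ (slice thickness). For an ellipsoid,
$A(z)$ is exactly quadratic, so the systematic error is
$\approx (t^2/6)\,\pi a b / c$ plus jitter from the partially covered polar
slices. At $t = 2$ mm that predicts ≈0.02 % for the large organ and — because
the small organ is deliberately elongated along z (c ≈ 16 mm rather than a
compact blob) — ≈0.2 % for the small one, comfortably inside the 0.1 % and
2.5 % acceptance bands. A box aligned with the grid is sliced exactly; after
a bend its flat ends smear across ~15 slices into a linear ramp, which the
midpoint rule integrates with error far below the 0.5 % deformed-phantom
band. These are design-time error analyses, not tuned numbers: all fixture
shapes were fixed from this budget before the acceptance runs.

Because A (mesh volume) and B (contour volume) are computed from the *same*
polyhedral surface, the chord error of the inscribed mesh cancels in
$|A - B|$; what remains is purely the slicing discretization. This mirrors
the situation with real phantoms, where the TM mesh itself is the reference.

What the synthetic phantoms do **not** emulate: anatomical shape complexity
(lobed, branching, thin-walled organs), micron-scale layers, heterogeneous
densities within one organ, and meshes in the multi-million-tet range. The
passing tests therefore demonstrate the conversion machinery's correctness
and its discretization behaviour, not anatomical realism.

## Numerical choices, in one place

| Quantity | Default | Why |
|---|---|---|
| FOV / resolution / slice | 500 mm / 512 / 2 mm | standard CT conventions; pixel = FOV/resolution = 0.976562 mm |
| `points_per_mm3` | 1000 | sampling density convention for the volume fractions |
| membership `tol` | 1e-9 (barycentric) | boundary-inclusive; ties broken by first tet index |
| chain tolerance | 1e-6 mm | endpoints are exact by construction; tighter hides nothing, looser hides bugs |
| slice `eps` | 1e-6 mm | vertex-on-plane dodge by height perturbation |
| background | 0.00120 g/cm³ | air outside the body |
| HU range | [−1024, 3071] | 12-bit-plus-sign; stored = HU + 1024, unsigned |
| bend curvature (validation) | 1/2500 mm⁻¹ | visible posture change with no inverted tets |
| grid z origin | bbox min + t/2 | slice slabs exactly cover the phantom; overridable via the grid object |

The problem sizes used by the acceptance checks — ~82k tets for the large
organ (icosphere level 4, 6 shells), ~9k for the small organ (level 3), a
360-tet torso box — were chosen so each phantom's surface triangles are small
against the organ and large against a voxel, which is the regime the
reference phantoms occupy at their own scale.

## Known limitations

* Explicit-VR DICOM limits a single `ContourData` element to 65534 bytes
  (~1800 points per loop); the writer refuses rather than truncates. Raw
  (undecimated) contours of extremely refined surfaces could hit this.
* The voxelizer assumes a non-overlapping tet partition (nesting via the
  body-last convention aside); overlapping organs silently resolve by tet
  order rather than erroring at sampling time (the recipe builder does
  error).
* Sequences are written with defined lengths and the reader parses only
  explicit VR little endian — sufficient for this package's studies and for
  pydicom/TPS import, not a general DICOM toolkit.
* Bend deformations use a single circular arc; articulated postures
  (squatting, walking) would compose several fields.
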