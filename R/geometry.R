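#' @useDynLib phantomct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- axis-aligned bounding boxes -------------------------------------------

#' Axis-aligned bounding box
#'
#' A simple container for a 3-D axis-aligned box in millimetres.
#'
#' @param min,max numeric length-3 vectors, `min <= max` componentwise.
#' @return An object of class `"aabb"` with elements `min` and `max`.
#' @export
aabb <- function(min, max) {
  min <- as.numeric(min); max <- as.numeric(max)
  if (length(min) != 3L || length(max) != 3L)
    stop("aabb corners must be length-3 vectors")
  if (any(!is.finite(min)) || any(!is.finite(max)))
    stop("aabb corners must be finite")
  if (any(min > max))
    stop("aabb min corner must be <= max corner componentwise")
  structure(list(min = min, max = max), class = "aabb")
}

#' @export
print.aabb <- function(x, ...) {
  cat(sprintf("<aabb [%g, %g] x [%g, %g] x [%g, %g] mm>\n",
              x$min[1], x$max[1], x$min[2], x$max[2], x$min[3], x$max[3]))
  invisible(x)
}

aabb_of_points <- function(pts) {
  aabb(apply(pts, 2L, min), apply(pts, 2L, max))
}

# ---- tetrahedron volumes ---------------------------------------------------

#' Unsigned volume of a tetrahedron
#'
#' `|det(v1 - v0, v2 - v0, v3 - v0)| / 6`, in mm^3; zero for degenerate tets
#' (e.g. repeated vertices).
#'
#' @param verts a 4x3 numeric matrix of vertex coordinates (mm).
#' @return Volume in mm^3.
#' @seealso [tet_volumes()] for all tetrahedra of a mesh at once.
#' @export
tet_volume <- function(verts) {
  abs(signed_tet_volume(verts))
}

#' Signed volume of a tetrahedron
#'
#' Positive when vertices 1..4 follow the right-hand orientation convention.
#'
#' @inheritParams tet_volume
#' @return Signed volume in mm^3.
#' @export
signed_tet_volume <- function(verts) {
  verts <- as.matrix(verts)
  stopifnot(nrow(verts) == 4L, ncol(verts) == 3L)
  e1 <- verts[2L, ] - verts[1L, ]
  e2 <- verts[3L, ] - verts[1L, ]
  e3 <- verts[4L, ] - verts[1L, ]
  det3(e1, e2, e3) / 6
}

det3 <- function(e1, e2, e3) {
  e1[1] * (e2[2] * e3[3] - e2[3] * e3[2]) -
  e2[1] * (e1[2] * e3[3] - e1[3] * e3[2]) +
  e3[1] * (e1[2] * e2[3] - e1[3] * e2[2])
}

# vectorized signed volumes for all tets of a mesh (mm^3)
signed_tet_volumes <- function(nodes, tets) {
  if (nrow(tets) == 0L) return(numeric(0))
  a <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - a
  e2 <- nodes[tets[, 3L], , drop = FALSE] - a
  e3 <- nodes[tets[, 4L], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e2[, 1] * (e1[, 2] * e3[, 3] - e1[, 3] * e3[, 2]) +
   e3[, 1] * (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])) / 6
}

#' Volumes of all tetrahedra of a mesh
#'
#' @param mesh a [tet_mesh()] object.
#' @param organ_id optional organ ID; restrict to that organ's tetrahedra.
#' @return Numeric vector of unsigned volumes in mm^3.
#' @export
tet_volumes <- function(mesh, organ_id = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  tets <- mesh$tets
  if (!is.null(organ_id)) {
    keep <- mesh$organ == organ_id
    if (!any(keep)) stop("no tetrahedra with organ ID ", organ_id)
    tets <- tets[keep, , drop = FALSE]
  }
  abs(signed_tet_volumes(mesh$nodes, tets))
}

#' Per-organ mesh volumes
#'
#' Sums tetrahedron volumes by organ ID.
#'
#' @param mesh a [tet_mesh()] object.
#' @param unit `"mm3"` or `"cm3"`.
#' @return Named numeric vector (names are organ IDs).
#' @export
organ_volumes <- function(mesh, unit = c("mm3", "cm3")) {
  unit <- match.arg(unit)
  v <- abs(signed_tet_volumes(mesh$nodes, mesh$tets))
  out <- tapply(v, mesh$organ, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  if (unit == "cm3") out <- out * 1e-3
  out
}

# ---- point membership ------------------------------------------------------

#' Barycentric coordinates of a point with respect to a tetrahedron
#'
#' @param p numeric length-3 point (mm).
#' @param verts 4x3 vertex matrix (mm).
#' @return Length-4 numeric vector summing to 1 (coordinates w.r.t. vertices
#'   1..4).
#' @export
tet_barycentric <- function(p, verts) {
  verts <- as.matrix(verts)
  e <- t(verts[2:4, , drop = FALSE]) - verts[1L, ]   # 3x3, columns = edges
  d <- det3(e[, 1], e[, 2], e[, 3])
  if (abs(d) < 1e-300) stop("degenerate tetrahedron")
  lam <- solve(e, as.numeric(p) - verts[1L, ])
  c(1 - sum(lam), lam)
}

#' Test whether a point lies inside a tetrahedron
#'
#' Boundary-inclusive membership: true iff all four signed barycentric
#' coordinates are `>= -tol`.
#'
#' @inheritParams tet_barycentric
#' @param tol barycentric tolerance (default `1e-9`); points within `tol` of a
#'   face count as inside.
#' @return Logical scalar.
#' @export
point_in_tet <- function(p, verts, tol = 1e-9) {
  all(tet_barycentric(p, verts) >= -tol)
}

# ---- organ bounding boxes --------------------------------------------------

#' Tight bounding box of one organ
#'
#' The axis-aligned box spanned by all vertices of the organ's tetrahedra; in
#' the conversion pipeline this is the "virtual voxel" region within which the
#' organ is resampled.
#'
#' @param mesh a [tet_mesh()] object.
#' @param organ_id integer organ ID present in the mesh.
#' @return An [aabb()].
#' @export
organ_bbox <- function(mesh, organ_id) {
  stopifnot(inherits(mesh, "tet_mesh"))
  keep <- mesh$organ == organ_id
  if (!any(keep)) stop("no tetrahedra with organ ID ", organ_id)
  idx <- unique(as.vector(mesh$tets[keep, , drop = FALSE]))
  aabb_of_points(mesh$nodes[idx, , drop = FALSE])
}

#' Bounding box of a whole mesh
#'
#' @param mesh a [tet_mesh()] object.
#' @return An [aabb()] over all nodes referenced by tetrahedra.
#' @export
mesh_bbox <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (nrow(mesh$tets) == 0L) stop("mesh has no tetrahedra")
  idx <- unique(as.vector(mesh$tets))
  aabb_of_points(mesh$nodes[idx, , drop = FALSE])
}
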