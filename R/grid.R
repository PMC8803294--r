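# ---- CT voxel grid ----------------------------------------------------------

#' CT voxel grid
#'
#' A cuboid voxel lattice in patient coordinates (mm).  `origin` is the
#' centre of the first voxel (lowest x, y, z); in-plane dimensions equal the
#' pixel resolution and the in-plane spacing equals FOV / resolution.
#'
#' @param origin numeric length-3; centre of the first voxel, mm.
#' @param spacing numeric length-3; voxel pitch `(px, py, pz)`, mm, > 0.
#' @param dims integer length-3; voxel counts `(nx, ny, nz)`.
#' @return An object of class `"voxel_grid"`.
#' @export
voxel_grid <- function(origin, spacing, dims) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be > 0")
  if (any(dims < 1L)) stop("grid dims must be >= 1")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %d x %d x %d, spacing %.6f x %.6f x %g mm>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Build the CT grid for a phantom
#'
#' In-plane spacing is `fov_mm / resolution` with `resolution` pixels per
#' axis; the grid is centred transversely on the body bounding box.  The
#' z-extent uses `ceil(bbox z-range / slice_thickness)` slices, the first
#' slice centre sitting half a slice above the bbox minimum, so the slice
#' slabs exactly cover the phantom.
#'
#' @param fov_mm field of view, mm (default 500).
#' @param resolution in-plane pixel resolution (default 512).
#' @param slice_thickness slice thickness, mm (default 2).
#' @param body_bbox an [aabb()] enclosing the phantom.
#' @return A [voxel_grid()].
#' @examples
#' g <- build_grid(500, 512, 2, aabb(c(-100, -100, 0), c(100, 100, 10)))
#' g$spacing[1]  # 0.9765625 mm
#' @export
build_grid <- function(fov_mm = 500, resolution = 512L, slice_thickness = 2,
                       body_bbox) {
  stopifnot(fov_mm > 0, resolution >= 1, slice_thickness > 0,
            inherits(body_bbox, "aabb"))
  ext <- body_bbox$max - body_bbox$min
  if (ext[1] > fov_mm || ext[2] > fov_mm)
    stop(sprintf(paste0("phantom transverse extent %.1f x %.1f mm exceeds the",
                        " %.1f mm FOV; increase fov_mm so the phantom fits ",
                        "the image"), ext[1], ext[2], fov_mm))
  p <- fov_mm / resolution
  ctr <- (body_bbox$min + body_bbox$max) / 2
  nz <- max(1L, as.integer(ceiling(ext[3] / slice_thickness - 1e-9)))
  voxel_grid(origin = c(ctr[1] - (resolution / 2 - 0.5) * p,
                        ctr[2] - (resolution / 2 - 0.5) * p,
                        body_bbox$min[3] + slice_thickness / 2),
             spacing = c(p, p, slice_thickness),
             dims = c(as.integer(resolution), as.integer(resolution), nz))
}

#' Slice centre z-positions of a grid
#' @param grid a [voxel_grid()].
#' @return Numeric vector of length `nz` (mm).
#' @export
grid_slice_z <- function(grid) {
  grid$origin[3] + (seq_len(grid$dims[3]) - 1L) * grid$spacing[3]
}

# voxel-index range (1-based, clamped, one-voxel margin) covering an aabb
grid_subrange <- function(grid, box) {
  lo <- integer(3); hi <- integer(3)
  for (k in 1:3) {
    lo[k] <- as.integer(floor((box$min[k] - grid$origin[k]) / grid$spacing[k] + 0.5))
    hi[k] <- as.integer(ceiling((box$max[k] - grid$origin[k]) / grid$spacing[k] + 0.5)) + 1L
    lo[k] <- max(1L, min(grid$dims[k], lo[k]))
    hi[k] <- max(1L, min(grid$dims[k], hi[k]))
  }
  if (any(hi < lo)) stop("bounding box does not intersect the grid")
  list(lo = lo, hi = hi)
}
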