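# ---- organ surface extraction ----------------------------------------------

#' Extract an organ's closed boundary surface
#'
#' Boundary faces are the triangular faces belonging to exactly one of the
#' organ's tetrahedra; each is oriented outward (normal pointing away from the
#' opposite vertex of its tet).  For a solid organ the result is a closed,
#' watertight, consistently oriented triangle mesh — the surface-only
#' ("polygonal-mesh") representation of the organ.
#'
#' @param mesh a [tet_mesh()].
#' @param organ_id organ to extract.
#' @return An object of class `"organ_surface"`: `vertices` (v x 3, mm),
#'   `triangles` (f x 3 vertex indices, outward orientation), `organ_id`.
#' @export
extract_surface <- function(mesh, organ_id) {
  stopifnot(inherits(mesh, "tet_mesh"))
  keep <- mesh$organ == organ_id
  if (!any(keep)) stop("no tetrahedra with organ ID ", organ_id)
  tets <- mesh$tets[keep, , drop = FALSE]
  m <- nrow(tets)

  # 4 faces per tet; face k is opposite vertex opp[k]
  fa <- rbind(tets[, c(2L, 3L, 4L)], tets[, c(1L, 3L, 4L)],
              tets[, c(1L, 2L, 4L)], tets[, c(1L, 2L, 3L)])
  opp <- c(tets[, 1L], tets[, 2L], tets[, 3L], tets[, 4L])

  s1 <- pmin(fa[, 1], fa[, 2], fa[, 3])
  s3 <- pmax(fa[, 1], fa[, 2], fa[, 3])
  s2 <- fa[, 1] + fa[, 2] + fa[, 3] - s1 - s3
  nmax <- as.numeric(nrow(mesh$nodes)) + 1
  key <- (s1 * nmax + s2) * nmax + s3

  cnt <- table(key)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[cnt > 2L][1L]
    stop("non-manifold organ surface: a face is shared by ",
         max(cnt), " tetrahedra (face key ", bad, "); organ ", organ_id,
         " is not a valid solid")
  }
  boundary <- key %in% as.numeric(names(cnt)[cnt == 1L])
  fb <- fa[boundary, , drop = FALSE]
  ob <- opp[boundary]

  # outward orientation: flip faces whose right-hand normal points toward the
  # opposite vertex (positive signed volume of (a, b, c, opp))
  a <- mesh$nodes[fb[, 1], , drop = FALSE]
  e1 <- mesh$nodes[fb[, 2], , drop = FALSE] - a
  e2 <- mesh$nodes[fb[, 3], , drop = FALSE] - a
  e3 <- mesh$nodes[ob, , drop = FALSE] - a
  sv <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
        e2[, 1] * (e1[, 2] * e3[, 3] - e1[, 3] * e3[, 2]) +
        e3[, 1] * (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])
  flip <- sv > 0
  if (any(flip)) {
    tmp <- fb[flip, 2L]
    fb[flip, 2L] <- fb[flip, 3L]
    fb[flip, 3L] <- tmp
  }

  used <- sort(unique(as.vector(fb)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  structure(list(vertices = mesh$nodes[used, , drop = FALSE],
                 triangles = matrix(remap[fb], ncol = 3L),
                 organ_id = as.integer(organ_id)),
            class = "organ_surface")
}

#' @export
print.organ_surface <- function(x, ...) {
  cat(sprintf("<organ_surface organ %d: %d vertices, %d triangles>\n",
              x$organ_id, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Signed volume enclosed by an oriented closed surface
#'
#' Divergence-theorem sum `sum det(v1, v2, v3) / 6` over triangles; positive
#' when the surface is consistently outward-oriented.
#'
#' @param surface an `organ_surface`.
#' @return Volume in mm^3.
#' @export
surface_volume <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      b[, 1] * (a[, 2] * c3[, 3] - a[, 3] * c3[, 2]) +
      c3[, 1] * (a[, 2] * b[, 3] - a[, 3] * b[, 2])) / 6
}

#' Euler characteristic of a surface
#'
#' `V - E + F`; equals 2 for every closed surface of sphere topology, and
#' 2 per component for a disjoint union of such surfaces.
#'
#' @param surface an `organ_surface`.
#' @return Integer.
#' @export
surface_euler <- function(surface) {
  tr <- surface$triangles
  ed <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ne <- nrow(unique(ed))
  nrow(surface$vertices) - ne + nrow(tr)
}

# ---- plane slicing ----------------------------------------------------------

#' Slice a closed surface by a transverse plane
#'
#' Intersects every triangle with the plane `z = const`, producing one line
#' segment per crossing triangle.  Vertices lying within `eps` of the plane
#' are handled by perturbing the slice height by `+eps` (repeatedly if
#' needed), so no triangle is ever cut exactly through a vertex.  Segment
#' endpoints on a shared triangle edge are computed identically for both
#' triangles (edge endpoints are taken in vertex-index order), so chaining
#' can rely on exact endpoint coincidence.
#'
#' @param surface an `organ_surface`.
#' @param z slice height, mm.
#' @param eps degeneracy tolerance, mm (default `1e-6 * max(1, |z|)` scale
#'   guard `1e-6`).
#' @return A list with `segments` (s x 4 matrix: x1, y1, x2, y2), and `z`
#'   (the possibly perturbed slice height; points are reported at the
#'   requested z).  Empty matrix when the plane misses the surface.
#' @export
slice_surface <- function(surface, z, eps = 1e-6) {
  stopifnot(inherits(surface, "organ_surface"))
  vz <- surface$vertices[, 3L]
  zs <- z
  guard <- 0L
  while (any(abs(vz - zs) < eps)) {
    zs <- zs + eps
    guard <- guard + 1L
    if (guard > 1000L) stop("cannot dodge vertex-on-plane degeneracy")
  }
  tr <- surface$triangles
  d1 <- vz[tr[, 1L]] - zs
  d2 <- vz[tr[, 2L]] - zs
  d3 <- vz[tr[, 3L]] - zs
  cross <- (pmin(d1, d2, d3) < 0) & (pmax(d1, d2, d3) > 0)
  if (!any(cross))
    return(list(segments = matrix(numeric(0), 0L, 4L,
                                  dimnames = list(NULL, c("x1","y1","x2","y2"))),
                z = z))
  tr <- tr[cross, , drop = FALSE]
  dm <- cbind(d1[cross], d2[cross], d3[cross])

  # intersection of edge (i, j) with the plane, endpoints in index order so
  # both adjacent triangles compute bit-identical points
  edge_point <- function(i, j) {
    swap <- i > j
    a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
    za <- vz[a]; zb <- vz[b]
    t <- (zs - za) / (zb - za)
    va <- surface$vertices[a, , drop = FALSE]
    vb <- surface$vertices[b, , drop = FALSE]
    cbind(va[, 1] + t * (vb[, 1] - va[, 1]),
          va[, 2] + t * (vb[, 2] - va[, 2]))
  }

  # the lone vertex on one side determines the two crossing edges
  lone <- integer(nrow(tr))
  pos <- dm > 0
  npos <- rowSums(pos)
  lone[npos == 1L] <- max.col(pos[npos == 1L, , drop = FALSE], "first")
  lone[npos == 2L] <- max.col(!pos[npos == 2L, , drop = FALSE], "first")
  i1 <- tr[cbind(seq_len(nrow(tr)), lone)]
  oth <- matrix(0L, nrow(tr), 2L)
  oth[lone == 1L, ] <- tr[lone == 1L, c(2L, 3L), drop = FALSE]
  oth[lone == 2L, ] <- tr[lone == 2L, c(1L, 3L), drop = FALSE]
  oth[lone == 3L, ] <- tr[lone == 3L, c(1L, 2L), drop = FALSE]
  p1 <- edge_point(i1, oth[, 1L])
  p2 <- edge_point(i1, oth[, 2L])
  seg <- cbind(p1, p2)
  colnames(seg) <- c("x1", "y1", "x2", "y2")
  list(segments = seg, z = z)
}

# ---- loop assembly ----------------------------------------------------------

#' Chain segments into closed planar loops
#'
#' Segments are chained end-to-end by endpoint proximity (`< tol`); every
#' segment is used exactly once, every chain must close, and each resulting
#' loop is oriented counter-clockwise viewed from +z.  An unclosable chain
#' (gap wider than `tol`) is an error reporting the gap distance — it means
#' the surface was not watertight.
#'
#' @param segments s x 4 matrix (x1, y1, x2, y2) from [slice_surface()].
#' @param tol chaining tolerance, mm (default 1e-6; segments from a
#'   conforming mesh share endpoints exactly).
#' @return A list of closed loops, each an n x 2 matrix of vertices (first
#'   vertex not repeated; closure is implicit).
#' @export
assemble_loops <- function(segments, tol = 1e-6) {
  segments <- as.matrix(segments)
  if (nrow(segments) == 0L) return(list())
  n <- nrow(segments)
  ends <- rbind(segments[, 1:2, drop = FALSE], segments[, 3:4, drop = FALSE])
  key <- paste(round(ends[, 1] / tol), round(ends[, 2] / tol))
  slots <- split(seq_len(2L * n), key)

  used <- logical(n)
  ptaken <- logical(2L * n)
  # endpoint id e (1..2n): segment (e-1) %% n + 1, end 1 or 2
  other_end <- function(e) if (e > n) e - n else e + n

  find_partner <- function(e) {
    k <- key[e]
    cand <- slots[[k]]
    cand <- cand[cand != e & !ptaken[cand] & !used[(cand - 1L) %% n + 1L]]
    if (length(cand) == 0L) {
      # report the nearest free endpoint for the diagnostic
      free <- which(!ptaken & !used[(seq_len(2L * n) - 1L) %% n + 1L])
      free <- setdiff(free, e)
      gap <- if (length(free))
        sqrt(min((ends[free, 1] - ends[e, 1])^2 +
                 (ends[free, 2] - ends[e, 2])^2)) else Inf
      stop(sprintf(paste0("cannot close contour: endpoint (%.6f, %.6f) has ",
                          "no partner within %.1e mm (nearest gap %.3e mm); ",
                          "surface is not watertight"),
                   ends[e, 1], ends[e, 2], tol, gap))
    }
    cand[1L]
  }

  loops <- list()
  for (s0 in seq_len(n)) {
    if (used[s0]) next
    verts <- list()
    used[s0] <- TRUE
    start_e <- s0            # end 1 of s0
    ptaken[s0] <- TRUE
    cur_e <- other_end(s0)   # walk out of end 2
    verts[[1L]] <- ends[s0, ]
    verts[[2L]] <- ends[cur_e, ]
    repeat {
      ptaken[cur_e] <- TRUE
      nxt <- find_partner(cur_e)
      ptaken[nxt] <- TRUE
      seg <- (nxt - 1L) %% n + 1L
      used[seg] <- TRUE
      cur_e <- other_end(nxt)
      if (identical(key[cur_e], key[start_e])) {
        ptaken[cur_e] <- TRUE
        break
      }
      verts[[length(verts) + 1L]] <- ends[cur_e, ]
    }
    loop <- do.call(rbind, verts)
    if (nrow(loop) < 3L)
      stop("degenerate contour loop with fewer than 3 vertices")
    if (polygon_area(loop) < 0) loop <- loop[rev(seq_len(nrow(loop))), ]
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise orientation viewed from +z.
#'
#' @param loop n x 2 matrix of vertices (implicit closure).
#' @return Signed area, mm^2.
#' @export
polygon_area <- function(loop) {
  x <- loop[, 1]; y <- loop[, 2]
  j <- c(seq_len(nrow(loop))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# even-odd point-in-polygon (ray crossing)
point_in_polygon <- function(p, loop) {
  x <- loop[, 1]; y <- loop[, 2]
  nv <- length(x)
  j <- c(nv, seq_len(nv - 1L))
  crosses <- ((y > p[2]) != (y[j] > p[2])) &
             (p[1] < (x[j] - x) * (p[2] - y) / (y[j] - y) + x)
  sum(crosses) %% 2L == 1L
}

# nesting parity of each loop among its slice's loops (0 = outer)
loop_parity <- function(loops) {
  k <- length(loops)
  if (k <= 1L) return(rep(0L, k))
  par <- integer(k)
  for (i in seq_len(k)) {
    p <- loops[[i]][1L, ]
    for (j in seq_len(k)) {
      if (i == j) next
      if (point_in_polygon(p, loops[[j]])) par[i] <- par[i] + 1L
    }
  }
  par %% 2L
}

# ---- contour sets -----------------------------------------------------------

#' Per-organ contour set
#'
#' Closed planar polylines at CT slice heights, the content of one
#' RT-structure ROI.  Outer loops are counter-clockwise viewed from +z, holes
#' clockwise.
#'
#' @param organ_id integer organ ID.
#' @param slices list of entries `list(z =, loops = list of n x 2 matrices)`.
#' @return An object of class `"contour_set"`.
#' @export
contour_set <- function(organ_id, slices) {
  structure(list(organ_id = as.integer(organ_id), slices = slices),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  nl <- sum(vapply(x$slices, function(s) length(s$loops), integer(1)))
  cat(sprintf("<contour_set organ %d: %d slice(s), %d loop(s)>\n",
              x$organ_id, length(x$slices), nl))
  invisible(x)
}

#' Volume enclosed by a contour stack
#'
#' `sum over slices of (outer-loop areas - hole areas) x slice thickness`,
#' the same slice-wise polygon-area-times-thickness estimate a treatment
#' planning system computes from an RT-structure set.  Loop nesting is
#' decided by even-odd point-in-polygon parity.
#'
#' @param cset a [contour_set()].
#' @param slice_thickness slice thickness, mm.
#' @return Volume in cm^3.
#' @export
contour_volume <- function(cset, slice_thickness) {
  stopifnot(inherits(cset, "contour_set"), slice_thickness > 0)
  total_mm3 <- 0
  for (s in cset$slices) {
    if (length(s$loops) == 0L) next
    par <- loop_parity(s$loops)
    areas <- vapply(s$loops, function(l) abs(polygon_area(l[, 1:2, drop = FALSE])),
                    numeric(1))
    total_mm3 <- total_mm3 + sum(ifelse(par == 0L, areas, -areas)) *
                 slice_thickness
  }
  total_mm3 * 1e-3
}

#' Contour a phantom at the CT slice positions
#'
#' For every organ listed in the contour spec: extract its boundary surface,
#' slice it at each CT slice-centre z, and assemble closed loops (outer loops
#' CCW, holes CW).  Contours and CT images thereby share the same frame of
#' reference exactly.
#'
#' @param mesh a [tet_mesh()].
#' @param spec a [contour_spec()].
#' @param grid a [voxel_grid()] (slice positions are taken from it).
#' @param chain_tol loop-chaining tolerance, mm.
#' @return Named list of [contour_set()] objects (names = organ IDs as
#'   character).
#' @export
contour_phantom <- function(mesh, spec, grid, chain_tol = 1e-6) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(spec, "contour_spec"),
            inherits(grid, "voxel_grid"))
  missing_ids <- setdiff(spec$organ_id, mesh_organ_ids(mesh))
  if (length(missing_ids))
    stop("contour spec lists organ IDs absent from the mesh: ",
         paste(missing_ids, collapse = ", "))
  zs <- grid_slice_z(grid)
  out <- vector("list", length(spec$organ_id))
  names(out) <- as.character(spec$organ_id)
  for (i in seq_along(spec$organ_id)) {
    oid <- spec$organ_id[i]
    surf <- extract_surface(mesh, oid)
    zr <- range(surf$vertices[, 3L])
    slices <- list()
    for (z in zs) {
      if (z < zr[1] || z > zr[2]) next
      sl <- slice_surface(surf, z)
      if (nrow(sl$segments) == 0L) next
      loops <- assemble_loops(sl$segments, tol = chain_tol)
      par <- loop_parity(loops)
      loops <- lapply(seq_along(loops), function(j) {
        l <- loops[[j]]
        if (par[j] == 1L) l <- l[rev(seq_len(nrow(l))), , drop = FALSE]  # holes CW
        cbind(l, z)
      })
      slices[[length(slices) + 1L]] <- list(z = z, loops = loops)
    }
    out[[i]] <- contour_set(oid, slices)
  }
  out
}
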