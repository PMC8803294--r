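# ---- synthetic analytic-volume phantoms -------------------------------------
#
# Test phantoms with known analytic volumes, standing in for licensed
# reference phantoms: boxes (exact volume), spheres/ellipsoids (inscribed
# polyhedra with a printed chord-error bound), merged multi-organ recipes,
# and posture deformations (affine, bend).

# unit icosphere: icosahedron subdivided `level` times, vertices on the
# unit sphere
icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, phi, 0,  1, phi, 0,  -1, -phi, 0,  1, -phi, 0,
                0, -1, phi,  0, 1, phi,  0, -1, -phi,  0, 1, -phi,
                phi, 0, -1,  phi, 0, 1,  -phi, 0, -1,  -phi, 0, 1),
              ncol = 3L, byrow = TRUE) / sqrt(1 + phi^2)
  f <- matrix(c(1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
                2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
                4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
                5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2),
              ncol = 3L, byrow = TRUE)
  for (s in seq_len(level)) {
    ed <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    lo <- pmin(ed[, 1], ed[, 2]); hi <- pmax(ed[, 1], ed[, 2])
    key <- paste(lo, hi)
    uk <- !duplicated(key)
    mid_id <- nrow(v) + match(key, key[uk])  # midpoint vertex ids
    mids <- (v[lo[uk], , drop = FALSE] + v[hi[uk], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  list(vertices = v, faces = f)
}

# split a prism (bottom i1,i2,i3; top i4,i5,i6, i4 above i1) into 3 tets,
# choosing quad-face diagonals through each face's lowest global vertex id,
# so adjacent prisms split their shared quads identically (conforming mesh)
split_prism <- function(p) {
  rot <- list(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
              c(4, 6, 5, 1, 3, 2), c(6, 5, 4, 3, 2, 1), c(5, 4, 6, 2, 1, 3))
  w <- which.min(p)
  for (r in rot) if (r[1L] == w || p[r[1L]] == p[w]) { p <- p[r]; break }
  # p[1] is now the smallest id; faces (1,2,5,4) and (3,1,4,6) take the
  # diagonals 1-5 and 1-6; face (2,3,6,5) takes the min-corner diagonal
  if (min(p[2L], p[6L]) < min(p[3L], p[5L]))
    rbind(p[c(1L, 2L, 3L, 6L)], p[c(1L, 2L, 6L, 5L)], p[c(1L, 5L, 6L, 4L)])
  else
    rbind(p[c(1L, 2L, 3L, 5L)], p[c(1L, 5L, 3L, 6L)], p[c(1L, 5L, 6L, 4L)])
}

# layered ("onion") tetrahedralization of the unit ball: concentric
# icosphere shells joined by prisms, innermost shell coned to the centre.
# Keeps tetrahedra locally sized, which the voxelizer's spatial index needs.
unit_ball_tets <- function(level, shells = NULL) {
  if (is.null(shells)) shells <- max(2L, as.integer(ceiling(2^level / 3)))
  ico <- icosphere(level)
  nv <- nrow(ico$vertices)
  radii <- seq_len(shells) / shells
  nodes <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(radii, function(r) ico$vertices * r)))
  shell_ids <- function(k) 1L + (k - 1L) * nv + seq_len(nv)
  tets <- vector("list", shells)
  f <- ico$faces
  tets[[1L]] <- cbind(1L, matrix(shell_ids(1L)[f], ncol = 3L))
  for (k in seq_len(shells - 1L)) {
    bot <- matrix(shell_ids(k)[f], ncol = 3L)
    top <- matrix(shell_ids(k + 1L)[f], ncol = 3L)
    pr <- lapply(seq_len(nrow(f)), function(i)
      split_prism(c(bot[i, ], top[i, ])))
    tets[[k + 1L]] <- do.call(rbind, pr)
  }
  list(nodes = nodes, tets = do.call(rbind, tets))
}

#' Tetrahedral sphere phantom fragment
#'
#' An inscribed icosphere (subdivision `level`) tetrahedralized in concentric
#' shells.  The mesh volume is strictly below the analytic `(4/3) pi r^3`
#' (inscribed polyhedron); the returned `chord_bound` bounds the deficit by
#' surface area times the maximal chord sagitta.
#'
#' @param radius sphere radius, mm (> 0).
#' @param center centre, mm.
#' @param organ_id organ ID for all tets.
#' @param level icosphere subdivision level (>= 0; >= 2 recommended, each
#'   level quadruples the surface triangle count).
#' @return A list: `mesh` ([tet_mesh()]), `analytic_volume` (mm^3),
#'   `mesh_volume` (mm^3), `chord_bound` (mm^3, bound on their difference).
#' @export
make_tet_sphere <- function(radius, center = c(0, 0, 0), organ_id = 1L,
                            level = 3L) {
  make_tet_ellipsoid(c(radius, radius, radius), center, organ_id, level)
}

#' Tetrahedral ellipsoid phantom fragment
#'
#' The unit-ball tetrahedralization scaled by the semi-axes; analytic volume
#' `(4/3) pi a b c`.
#'
#' @param semiaxes half-axes `(a, b, c)`, mm, all > 0.
#' @param center centre, mm.
#' @param organ_id organ ID for all tets.
#' @param level icosphere subdivision level.
#' @return As [make_tet_sphere()].
#' @export
make_tet_ellipsoid <- function(semiaxes, center = c(0, 0, 0), organ_id = 1L,
                               level = 3L) {
  semiaxes <- as.numeric(semiaxes)
  if (any(semiaxes <= 0)) stop("ellipsoid semi-axes must be > 0")
  if (level < 0) stop("subdivision level must be >= 0")
  ball <- unit_ball_tets(as.integer(level))
  nodes <- sweep(sweep(ball$nodes, 2L, semiaxes, `*`), 2L, as.numeric(center),
                 `+`)
  mesh <- tet_mesh(nodes, ball$tets, rep(as.integer(organ_id),
                                         nrow(ball$tets)))
  # max sagitta of the unit icosphere chords, scaled anisotropically:
  # bound deficit by (surface area) x (max semi-axis x unit sagitta)
  ico <- icosphere(as.integer(level))
  tri <- ico$faces
  d <- vapply(seq_len(nrow(tri)), function(i) {
    m <- colMeans(ico$vertices[tri[i, ], , drop = FALSE])
    sqrt(sum(m^2))
  }, numeric(1))
  sag <- 1 - min(d)
  a <- semiaxes
  area <- 4 * pi * max(a)^2          # >= ellipsoid surface area
  analytic <- 4 / 3 * pi * prod(a)
  list(mesh = mesh, analytic_volume = analytic,
       mesh_volume = sum(tet_volumes(mesh)),
       chord_bound = area * max(a) * sag)
}

#' Tetrahedral box phantom fragment (exact volume)
#'
#' A grid of cells, each split into 5 tetrahedra with checkerboard parity so
#' neighbouring cells share face diagonals (conforming mesh).  The mesh
#' volume equals the box volume exactly.
#'
#' @param extents box edge lengths `(lx, ly, lz)`, mm, > 0.
#' @param center box centre, mm.
#' @param organ_id organ ID for all tets.
#' @param cells integer cell counts per axis (default: ~75 mm cells).
#' @return A list: `mesh`, `analytic_volume` (= mesh volume), `mesh_volume`,
#'   `chord_bound` (0).
#' @export
make_tet_box <- function(extents, center = c(0, 0, 0), organ_id = 1L,
                         cells = NULL) {
  extents <- as.numeric(extents)
  if (any(extents <= 0)) stop("box extents must be > 0")
  if (is.null(cells)) cells <- pmax(1L, as.integer(ceiling(extents / 75)))
  cells <- as.integer(cells)
  nx <- cells[1]; ny <- cells[2]; nz <- cells[3]
  gx <- seq(0, extents[1], length.out = nx + 1L) - extents[1] / 2 + center[1]
  gy <- seq(0, extents[2], length.out = ny + 1L) - extents[2] / 2 + center[2]
  gz <- seq(0, extents[3], length.out = nz + 1L) - extents[3] / 2 + center[3]
  nid <- function(i, j, k) as.integer(i + (nx + 1L) * (j + (ny + 1L) * k) + 1L)
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dimnames(nodes) <- NULL

  # 5-tet cell template: apex corners on the even-parity diagonal set
  even <- list(c(0,0,0, 1,0,0, 0,1,0, 0,0,1),
               c(1,1,0, 1,0,0, 0,1,0, 1,1,1),
               c(1,0,1, 1,0,0, 0,0,1, 1,1,1),
               c(0,1,1, 0,1,0, 0,0,1, 1,1,1),
               c(1,0,0, 0,1,0, 0,0,1, 1,1,1))
  tets <- vector("list", nx * ny * nz)
  t_i <- 0L
  for (k in 0:(nz - 1L)) for (j in 0:(ny - 1L)) for (i in 0:(nx - 1L)) {
    par <- (i + j + k) %% 2L
    cell <- vapply(even, function(tpl) {
      m <- matrix(tpl, 4L, 3L, byrow = TRUE)
      if (par == 1L) m[, 1L] <- 1L - m[, 1L]   # mirror for odd cells
      nid(i + m[, 1L], j + m[, 2L], k + m[, 3L])
    }, integer(4L))
    t_i <- t_i + 1L
    tets[[t_i]] <- t(cell)
  }
  mesh <- tet_mesh(nodes, do.call(rbind, tets),
                   rep(as.integer(organ_id), 5L * nx * ny * nz))
  vol <- prod(extents)
  list(mesh = mesh, analytic_volume = vol,
       mesh_volume = sum(tet_volumes(mesh)), chord_bound = 0)
}

# ---- recipes ----------------------------------------------------------------

#' Phantom recipe: a list of analytic organs
#'
#' Each organ is a list with `shape` ("sphere", "ellipsoid", "box"),
#' `center`, size parameters (`radius`, `semiaxes` or `extents`), `organ_id`,
#' `density` (g/cm^3), `name`, and refinement (`level` or `cells`).  Organs
#' are merged in list order; an organ fully enclosed by another must precede
#' it (the enclosing "body" claims only the points its enclosed organs left
#' unclaimed).
#'
#' @param ... organ lists.
#' @return An object of class `"phantom_recipe"`.
#' @export
phantom_recipe <- function(...) {
  organs <- list(...)
  ids <- vapply(organs, function(o) as.integer(o$organ_id), integer(1))
  if (anyDuplicated(ids)) stop("organ IDs in a recipe must be unique")
  structure(list(organs = organs), class = "phantom_recipe")
}

make_fragment <- function(o) {
  switch(o$shape,
    sphere = make_tet_sphere(o$radius, o$center, o$organ_id,
                             if (is.null(o$level)) 3L else o$level),
    ellipsoid = make_tet_ellipsoid(o$semiaxes, o$center, o$organ_id,
                                   if (is.null(o$level)) 3L else o$level),
    box = make_tet_box(o$extents, o$center, o$organ_id, o$cells),
    stop("unknown organ shape: ", o$shape))
}

#' Build a multi-organ phantom from a recipe
#'
#' Merges the organ fragments into one mesh with consistent node indexing,
#' plus a matching material table, contour spec, and the analytic per-organ
#' volumes.  Pairwise disjointness is verified by bounding-box overlap plus
#' point-membership testing of tet centroids; organs may be fully enclosed by
#' a *later-listed* organ (a surrounding body), but partial overlap — or a
#' body listed before an organ it encloses — is an error.
#'
#' @param recipe a [phantom_recipe()].
#' @return A list: `mesh`, `materials`, `spec`, `analytic_volumes` (named,
#'   cm^3), `chord_bounds` (named, cm^3).
#' @export
build_phantom <- function(recipe) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  frags <- lapply(recipe$organs, make_fragment)
  n_org <- length(frags)

  # pairwise disjointness / containment checks on tet centroids
  centroids <- lapply(frags, function(f) {
    m <- f$mesh
    ctr <- (m$nodes[m$tets[, 1], , drop = FALSE] +
            m$nodes[m$tets[, 2], , drop = FALSE] +
            m$nodes[m$tets[, 3], , drop = FALSE] +
            m$nodes[m$tets[, 4], , drop = FALSE]) / 4
    if (nrow(ctr) > 400L) ctr[seq(1L, nrow(ctr), length.out = 400L), ,
                              drop = FALSE] else ctr
  })
  boxes <- lapply(frags, function(f) mesh_bbox(f$mesh))
  frac_inside <- function(i, j) {
    m <- frags[[j]]$mesh
    mean(.points_in_mesh(m$nodes, m$tets, centroids[[i]], 1e-9))
  }
  for (i in seq_len(n_org)) for (j in seq_len(n_org)) {
    if (i >= j) next
    bi <- boxes[[i]]; bj <- boxes[[j]]
    if (any(bi$max < bj$min) || any(bi$min > bj$max)) next
    fij <- frac_inside(i, j)   # fraction of organ i inside organ j
    fji <- frac_inside(j, i)
    idi <- recipe$organs[[i]]$organ_id; idj <- recipe$organs[[j]]$organ_id
    if (fij == 0 && fji == 0) next
    if (fij == 1) next                  # i enclosed by later-listed body j: OK
    if (fji == 1)
      stop("organ ", idj, " lies inside earlier-listed organ ", idi,
           "; list enclosed organs before their enclosing body")
    stop("organs ", idi, " and ", idj, " overlap partially (",
         sprintf("%.0f%%/%.0f%%", 100 * fij, 100 * fji),
         " of sampled centroids); recipe solids must be disjoint or nested")
  }

  nodes <- do.call(rbind, lapply(frags, function(f) f$mesh$nodes))
  off <- cumsum(c(0L, vapply(frags, function(f) nrow(f$mesh$nodes),
                             integer(1))))
  tets <- do.call(rbind, lapply(seq_len(n_org), function(i)
    frags[[i]]$mesh$tets + off[i]))
  organ <- unlist(lapply(frags, function(f) f$mesh$organ))
  mesh <- tet_mesh(nodes, tets, organ)

  ids <- vapply(recipe$organs, function(o) as.integer(o$organ_id), integer(1))
  nms <- vapply(recipe$organs, function(o)
    if (is.null(o$name)) paste0("Organ", o$organ_id) else o$name, character(1))
  dens <- vapply(recipe$organs, function(o) as.numeric(o$density), numeric(1))
  av <- vapply(frags, function(f) f$analytic_volume, numeric(1)) * 1e-3
  cb <- vapply(frags, function(f) f$chord_bound, numeric(1)) * 1e-3
  list(mesh = mesh,
       materials = material_table(ids, nms, dens),
       spec = contour_spec(ids, nms),
       analytic_volumes = stats::setNames(av, ids),
       chord_bounds = stats::setNames(cb, ids))
}

#' Default validation phantom recipe
#'
#' A 300 x 200 x 400 mm "torso" box (1.00 g/cm^3) enclosing a 1400 cm^3
#' ellipsoid organ and a 2 cm^3 small-organ analogue (both 1.05 g/cm^3).
#' The small organ is elongated along z (half-axes 5, 6, ~15.9 mm) so its
#' slice-stack volume error at 2 mm slices stays well below the small-organ
#' tolerance; the large organ uses half-axes 90, 70, ~53.05 mm.
#'
#' @param level_large,level_small icosphere levels for the two ellipsoids.
#' @return A [phantom_recipe()].
#' @export
default_phantom_recipe <- function(level_large = 4L, level_small = 3L) {
  a_l <- 90; b_l <- 70
  c_l <- 1400e3 * 3 / (4 * pi * a_l * b_l)      # exact 1400 cm^3
  a_s <- 5; b_s <- 6
  c_s <- 2e3 * 3 / (4 * pi * a_s * b_s)         # exact 2 cm^3
  phantom_recipe(
    list(shape = "ellipsoid", semiaxes = c(a_l, b_l, c_l),
         center = c(0, 0, 80), organ_id = 1L, density = 1.05,
         name = "LargeOrgan", level = level_large),
    list(shape = "ellipsoid", semiaxes = c(a_s, b_s, c_s),
         center = c(0, 0, -100), organ_id = 2L, density = 1.05,
         name = "SmallOrgan", level = level_small),
    list(shape = "box", extents = c(300, 200, 400), center = c(0, 0, 0),
         organ_id = 3L, density = 1.00, name = "Torso"))
}

# ---- deformation ------------------------------------------------------------

#' Deform a phantom (posture change)
#'
#' Maps node coordinates through an affine transform or a circular-arc bend;
#' connectivity is untouched.  A deformation that inverts any tetrahedron is
#' rejected.  Volume-preserving affines (det = 1) leave per-organ volumes
#' unchanged; after a bend, the deformed mesh's own summed tet volumes are
#' the ground truth for downstream volume comparisons.
#'
#' @param mesh a [tet_mesh()].
#' @param field deformation description:
#'   `list(type = "affine", A = 3x3 matrix, b = length-3 offset)` or
#'   `list(type = "bend", axis = "x" or "y", curvature = 1/mm, center = z0)`
#'   (cross-sections at height z rotate by `curvature * (z - center)`
#'   radians about a line at the bend radius; small curvatures tilt the
#'   phantom smoothly).
#' @return The deformed [tet_mesh()].
#' @export
deform <- function(mesh, field) {
  stopifnot(inherits(mesh, "tet_mesh"))
  nodes <- mesh$nodes
  if (field$type == "affine") {
    A <- field$A
    b <- if (is.null(field$b)) c(0, 0, 0) else field$b
    if (det(A) <= 0) stop("affine deformation must preserve orientation (det > 0)")
    nodes <- nodes %*% t(A) + matrix(b, nrow(nodes), 3L, byrow = TRUE)
  } else if (field$type == "bend") {
    kappa <- field$curvature
    z0 <- if (is.null(field$center)) mean(range(nodes[, 3])) else field$center
    ax <- if (is.null(field$axis)) "x" else field$axis
    if (kappa != 0) {
      R <- 1 / kappa
      u <- if (ax == "x") nodes[, 1] else nodes[, 2]
      phi <- kappa * (nodes[, 3] - z0)
      un <- (R + u) * cos(phi) - R
      zn <- z0 + (R + u) * sin(phi)
      if (ax == "x") nodes[, 1] <- un else nodes[, 2] <- un
      nodes[, 3] <- zn
    }
  } else stop("unknown deformation type: ", field$type)

  sv <- signed_tet_volumes(nodes, mesh$tets)
  if (any(sv <= 0))
    stop(sum(sv <= 0), " tetrahedra inverted by the deformation; ",
         "use milder parameters (smaller curvature or shear)")
  tet_mesh(nodes, mesh$tets, mesh$organ)
}

#' Write a phantom to canonical node/ele/material/contour-spec files
#'
#' @param phantom a list as returned by [build_phantom()].
#' @param dir output directory.
#' @param basename file stem (default "phantom").
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_phantom_files <- function(phantom, dir, basename = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(node = file.path(dir, paste0(basename, ".node")),
             ele = file.path(dir, paste0(basename, ".ele")),
             material = file.path(dir, paste0(basename, ".material")),
             contours = file.path(dir, paste0(basename, ".contours")))
  write_node_file(phantom$mesh, paths[["node"]])
  write_ele_file(phantom$mesh, paths[["ele"]])
  write_material_table(phantom$materials, paths[["material"]])
  write_contour_spec(phantom$spec, paths[["contours"]])
  invisible(paths)
}
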