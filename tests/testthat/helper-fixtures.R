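# Fixtures are generated in code and memoised per test-file run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fix[[name]])) .fix[[name]] <- make()
  .fix[[name]]
}

sphere_fixture <- function(r = 20, level = 3L, organ_id = 1L) {
  fixture(sprintf("sphere_%g_%d_%d", r, level, organ_id),
          function() make_tet_sphere(r, c(0, 0, 0), organ_id, level))
}

box_fixture <- function(ext = c(20, 20, 20), cells = c(2L, 2L, 2L)) {
  fixture(paste0("box_", paste(ext, collapse = "x")),
          function() make_tet_box(ext, c(0, 0, 0), 1L, cells))
}

# two disjoint unit-density boxes (mass-conservation fixture)
two_box_fixture <- function() {
  fixture("two_box", function() {
    b1 <- make_tet_box(c(10, 10, 10), c(-10, 0, 0), 1L, c(1L, 1L, 1L))
    b2 <- make_tet_box(c(8, 12, 6), c(10, 0, 0), 2L, c(1L, 1L, 1L))
    mesh <- tet_mesh(rbind(b1$mesh$nodes, b2$mesh$nodes),
                     rbind(b1$mesh$tets, b2$mesh$tets + nrow(b1$mesh$nodes)),
                     c(b1$mesh$organ, b2$mesh$organ))
    list(mesh = mesh,
         materials = material_table(1:2, c("BoxA", "BoxB"), c(1.0, 1.0)))
  })
}

# one organ made of two disjoint spheres (two-lobed topology)
two_lobe_fixture <- function() {
  fixture("two_lobe", function() {
    s1 <- make_tet_sphere(8, c(-15, 0, 0), 7L, 2L)
    s2 <- make_tet_sphere(8, c(15, 0, 0), 7L, 2L)
    tet_mesh(rbind(s1$mesh$nodes, s2$mesh$nodes),
             rbind(s1$mesh$tets, s2$mesh$tets + nrow(s1$mesh$nodes)),
             c(s1$mesh$organ, s2$mesh$organ))
  })
}

# a single well-conditioned reference tetrahedron
ref_tet <- function() {
  rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(2, 2, 6))
}

# independent half-space membership oracle: p is inside iff, for each face,
# p lies on the same side as the opposite vertex (or on the plane)
point_in_tet_halfspace <- function(p, verts, tol = 0) {
  faces <- list(c(2, 3, 4, 1), c(1, 3, 4, 2), c(1, 2, 4, 3), c(1, 2, 3, 4))
  for (f in faces) {
    a <- verts[f[1], ]; b <- verts[f[2], ]; c3 <- verts[f[3], ]
    nrm <- c((b - a)[2] * (c3 - a)[3] - (b - a)[3] * (c3 - a)[2],
             (b - a)[3] * (c3 - a)[1] - (b - a)[1] * (c3 - a)[3],
             (b - a)[1] * (c3 - a)[2] - (b - a)[2] * (c3 - a)[1])
    s_opp <- sum(nrm * (verts[f[4], ] - a))
    s_p <- sum(nrm * (p - a))
    if (s_p * sign(s_opp) < -tol * abs(s_opp)) return(FALSE)
  }
  TRUE
}

rigid_motion <- function(pts, angles = c(0.3, -0.7, 1.1), shift = c(5, -3, 2)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), sin(angles[1]),
                 0, -sin(angles[1]), cos(angles[1])), 3, 3)
  ry <- matrix(c(cos(angles[2]), 0, -sin(angles[2]), 0, 1, 0,
                 sin(angles[2]), 0, cos(angles[2])), 3, 3)
  rz <- matrix(c(cos(angles[3]), sin(angles[3]), 0,
                 -sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3)
  pts %*% t(rz %*% ry %*% rx) + matrix(shift, nrow(pts), 3, byrow = TRUE)
}
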