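test_that("extract_surface keeps only boundary faces, outward oriented", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  one <- tet_mesh(nodes[1:4, ], rbind(c(1L, 2L, 3L, 4L)), 1L)
  s1 <- extract_surface(one, 1L)
  expect_equal(nrow(s1$triangles), 4L)
  # outward orientation: divergence-theorem volume equals tet volume
  expect_equal(surface_volume(s1), 1 / 6)

  two <- tet_mesh(nodes, rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L)),
                  c(1L, 1L))
  s2 <- extract_surface(two, 1L)
  expect_equal(nrow(s2$triangles), 6L)  # shared face removed
  expect_equal(surface_volume(s2), sum(tet_volumes(two)))
})

test_that("fixture organ surfaces are watertight with Euler characteristic 2", {
  expect_equal(surface_euler(extract_surface(sphere_fixture(20, 3L)$mesh, 1L)),
               2L)
  expect_equal(surface_euler(extract_surface(box_fixture()$mesh, 1L)), 2L)
  # two-lobed organ: 2 closed components
  expect_equal(surface_euler(extract_surface(two_lobe_fixture(), 7L)), 4L)
})

test_that("extract_surface rejects non-manifold input", {
  # three tets sharing one face
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1),
                 c(-1, -1, 1))
  mesh <- tet_mesh(nodes, rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 5L),
                                c(1L, 2L, 3L, 6L)), rep(1L, 3))
  expect_error(extract_surface(mesh, 1L), "non-manifold")
})

test_that("slicing an axis-aligned cube yields a square of perimeter 40", {
  b <- make_tet_box(c(10, 10, 10), c(5, 5, 5), 1L, c(1L, 1L, 1L))
  surf <- extract_surface(b$mesh, 1L)
  sl <- slice_surface(surf, 5)
  len <- sum(sqrt((sl$segments[, 1] - sl$segments[, 3])^2 +
                  (sl$segments[, 2] - sl$segments[, 4])^2))
  expect_equal(len, 40)
  loops <- assemble_loops(sl$segments)
  expect_length(loops, 1L)
  expect_equal(abs(polygon_area(loops[[1]])), 100)
  expect_gt(polygon_area(loops[[1]]), 0)  # CCW
  # below the z-range: empty
  expect_equal(nrow(slice_surface(surf, -3)$segments), 0L)
})

test_that("vertex-on-plane degeneracy is dodged by height perturbation", {
  b <- make_tet_box(c(10, 10, 10), c(5, 5, 5), 1L, c(2L, 2L, 2L))
  surf <- extract_surface(b$mesh, 1L)
  # z = 5 passes exactly through a ring of mesh vertices
  loops <- assemble_loops(slice_surface(surf, 5)$segments)
  expect_length(loops, 1L)
  expect_equal(abs(polygon_area(loops[[1]])), 100, tolerance = 1e-4)
})

test_that("sphere slice area matches the analytic circle within chord error", {
  s <- sphere_fixture(r = 50, level = 3L)
  surf <- extract_surface(s$mesh, 1L)
  loops <- assemble_loops(slice_surface(surf, 0.4)$segments)
  expect_length(loops, 1L)
  area <- abs(polygon_area(loops[[1]]))
  r_slice2 <- 50^2 - 0.4^2
  # inscribed polygon of an inscribed polyhedron: deficit O(theta^2)
  theta <- 1.1 / 2^3  # icosphere edge angle at level 3
  expect_lt(abs(area - pi * r_slice2) / (pi * r_slice2), theta^2)
})

test_that("loop assembly is independent of segment order and reports gaps", {
  sq <- rbind(c(0, 0, 1, 0), c(1, 0, 1, 1), c(1, 1, 0, 1), c(0, 1, 0, 0))
  set.seed(99)
  for (i in 1:10) {
    perm <- sample(4)
    flip <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    segs <- sq[perm, , drop = FALSE]
    segs[flip, ] <- segs[flip, c(3, 4, 1, 2), drop = FALSE]
    loops <- assemble_loops(segs)
    expect_length(loops, 1L)
    expect_equal(polygon_area(loops[[1]]), 1)  # CCW unit square
    expect_equal(nrow(loops[[1]]), 4L)
  }
  expect_error(assemble_loops(sq[-2, , drop = FALSE]), "not watertight")
})

test_that("a two-lobed organ slice assembles into exactly two loops", {
  surf <- extract_surface(two_lobe_fixture(), 7L)
  loops <- assemble_loops(slice_surface(surf, 0.3)$segments)
  expect_length(loops, 2L)
  expect_true(all(vapply(loops, polygon_area, numeric(1)) > 0))
})

test_that("contour_volume applies the slab rule with hole parity", {
  sq <- function(half) cbind(c(-half, half, half, -half),
                             c(-half, -half, half, half))
  slices <- lapply(1:5, function(k) list(z = 2 * k, loops = list(sq(5))))
  cs <- contour_set(1L, slices)
  expect_equal(contour_volume(cs, 2), 1.0)   # 100 mm^2 x 5 x 2 mm = 1 cm^3

  holed <- contour_set(1L, list(list(z = 0, loops = list(sq(5), sq(2.5)))))
  expect_equal(contour_volume(holed, 2), (100 - 25) * 2 * 1e-3)

  e <- make_tet_ellipsoid(c(12, 9, 16), c(0, 0, 0), 1L, 3L)
  g <- build_grid(40, 32, 2, mesh_bbox(e$mesh))
  cs2 <- contour_phantom(e$mesh, contour_spec(1L, "E"), g)[["1"]]
  v_mesh <- sum(tet_volumes(e$mesh)) * 1e-3
  # slice discretization bound ~ (t^2/6) * pi * a * b / c (plus cap jitter)
  bound <- (2^2 / 6) * pi * 12 * 9 / 16 * 1e-3 + pi * 12 * 9 * 2 / 16 * 1e-3 * 0.2
  expect_lt(abs(contour_volume(cs2, 2) - v_mesh), bound + 0.02 * v_mesh)
})

test_that("contour_phantom contours only listed organs at grid slice heights", {
  fix <- two_box_fixture()
  g <- build_grid(60, 48, 2, mesh_bbox(fix$mesh))
  cs <- contour_phantom(fix$mesh, contour_spec(1L, "BoxA"), g)
  expect_named(cs, "1")
  zs <- vapply(cs[["1"]]$slices, function(s) s$z, numeric(1))
  expect_true(all(zs %in% grid_slice_z(g)))
  expect_error(contour_phantom(fix$mesh, contour_spec(9L, "Nope"), g),
               "absent")
})

test_that("a sphere centred between two slices contours symmetrically", {
  s <- make_tet_sphere(15, c(0, 0, 0), 1L, 3L)
  g <- voxel_grid(c(-20, -20, -19), c(1, 1, 2), c(40L, 40L, 20L))
  # slice centres at odd z: symmetric pairs about z = 0
  cs <- contour_phantom(s$mesh, contour_spec(1L, "S"), g)[["1"]]
  zs <- vapply(cs$slices, function(x) x$z, numeric(1))
  areas <- vapply(cs$slices, function(x)
    sum(vapply(x$loops, function(l) abs(polygon_area(l[, 1:2])), numeric(1))),
    numeric(1))
  for (z in zs[zs > 0]) {
    i <- which(zs == z); j <- which(zs == -z)
    expect_length(j, 1L)
    expect_equal(areas[i], areas[j], tolerance = 1e-9)
  }
})

test_that("deformed phantoms still produce closed, correctly oriented loops", {
  fix <- sphere_fixture(r = 15, level = 2L)
  dm <- deform(fix$mesh, list(type = "bend", axis = "x", curvature = 1 / 300,
                              center = 0))
  g <- build_grid(50, 32, 2, mesh_bbox(dm))
  cs <- contour_phantom(dm, contour_spec(1L, "S"), g)[["1"]]
  expect_gt(length(cs$slices), 3L)
  for (s in cs$slices) {
    par <- phantomct:::loop_parity(lapply(s$loops, function(l) l[, 1:2]))
    for (j in seq_along(s$loops)) {
      a <- polygon_area(s$loops[[j]][, 1:2])
      if (par[j] == 0L) expect_gt(a, 0) else expect_lt(a, 0)
      expect_gte(nrow(s$loops[[j]]), 3L)
      expect_true(all(s$loops[[j]][, 3] == s$z))
    }
  }
})

test_that("random slice heights of watertight fixtures always close", {
  surf <- extract_surface(sphere_fixture(r = 20, level = 2L)$mesh, 1L)
  set.seed(31)
  zr <- range(surf$vertices[, 3])
  for (z in stats::runif(200, zr[1] - 2, zr[2] + 2)) {
    segs <- slice_surface(surf, z)$segments
    if (nrow(segs) == 0) next
    loops <- assemble_loops(segs)
    expect_gte(length(loops), 1L)
    expect_true(all(vapply(loops, polygon_area, numeric(1)) > 0))
  }
})
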