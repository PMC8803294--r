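test_that("box phantoms have exactly the analytic volume", {
  b1 <- make_tet_box(c(1, 1, 1), c(0, 0, 0), 1L, c(1L, 1L, 1L))
  expect_equal(nrow(b1$mesh$tets), 5L)
  expect_equal(b1$mesh_volume, 1)
  b <- make_tet_box(c(10, 10, 10), c(0, 0, 0), 1L, c(2L, 3L, 2L))
  expect_equal(b$mesh_volume, 1000)
  set.seed(5)
  for (i in 1:10) {
    ext <- stats::runif(3, 0.5, 40)
    bx <- make_tet_box(ext, stats::rnorm(3, sd = 10), 1L,
                       sample(1:3, 3, replace = TRUE))
    expect_equal(bx$mesh_volume, prod(ext), tolerance = 1e-12)
    expect_equal(surface_euler(extract_surface(bx$mesh, 1L)), 2L)
  }
  expect_error(make_tet_box(c(0, 1, 1)), "> 0")
})

test_that("sphere refinement shrinks the volume deficit monotonically", {
  r <- 50
  deficit <- vapply(2:4, function(lv) {
    s <- make_tet_sphere(r, c(0, 0, 0), 1L, lv)
    s$analytic_volume - s$mesh_volume
  }, numeric(1))
  expect_true(all(deficit > 0))              # strictly inscribed
  expect_true(all(diff(deficit) < 0))        # strictly decreasing
  s3 <- make_tet_sphere(50, c(0, 0, 0), 1L, 3L)
  expect_equal(s3$analytic_volume, 523598.776, tolerance = 1e-6)
  expect_lt(s3$analytic_volume - s3$mesh_volume, s3$chord_bound)
  expect_error(make_tet_sphere(0), "> 0")
  expect_error(make_tet_sphere(10, level = -1), ">= 0")
})

test_that("generated organ surfaces are watertight across shapes and levels", {
  shapes <- list(make_tet_sphere(12, c(1, 2, 3), 1L, 2L),
                 make_tet_ellipsoid(c(10, 6, 14), c(0, 0, 0), 1L, 3L),
                 make_tet_box(c(7, 11, 5), c(2, -1, 0), 1L))
  for (sh in shapes) {
    surf <- extract_surface(sh$mesh, 1L)
    expect_equal(surface_euler(surf), 2L)
    expect_equal(surface_volume(surf), sh$mesh_volume, tolerance = 1e-9)
  }
})

test_that("build_phantom merges organs with analytic ground truth", {
  rec <- phantom_recipe(
    list(shape = "sphere", radius = 10, center = c(-25, 0, 0), organ_id = 1L,
         density = 1.05, name = "A", level = 2L),
    list(shape = "sphere", radius = 8, center = c(25, 0, 0), organ_id = 2L,
         density = 1.02, name = "B", level = 2L),
    list(shape = "box", extents = c(100, 40, 40), center = c(0, 0, 0),
         organ_id = 3L, density = 1.00, name = "Body"))
  ph <- build_phantom(rec)
  expect_setequal(mesh_organ_ids(ph$mesh), 1:3)
  expect_equal(unname(ph$analytic_volumes["1"]), 4 / 3 * pi * 1000 * 1e-3)
  expect_equal(unname(ph$analytic_volumes["3"]), 160)
  expect_equal(ph$spec$organ_count, 3L)
  # single-organ recipe is identical to its fragment
  one <- build_phantom(phantom_recipe(
    list(shape = "sphere", radius = 10, center = c(0, 0, 0), organ_id = 4L,
         density = 1, name = "S", level = 2L)))
  frag <- make_tet_sphere(10, c(0, 0, 0), 4L, 2L)
  expect_identical(one$mesh$nodes, frag$mesh$nodes)
  expect_identical(one$mesh$tets, frag$mesh$tets)
})

test_that("build_phantom rejects partial overlap and mis-ordered nesting", {
  overlap <- phantom_recipe(
    list(shape = "sphere", radius = 10, center = c(0, 0, 0), organ_id = 1L,
         density = 1, name = "A", level = 2L),
    list(shape = "sphere", radius = 10, center = c(12, 0, 0), organ_id = 2L,
         density = 1, name = "B", level = 2L))
  expect_error(build_phantom(overlap), "overlap")
  body_first <- phantom_recipe(
    list(shape = "box", extents = c(60, 60, 60), center = c(0, 0, 0),
         organ_id = 1L, density = 1, name = "Body"),
    list(shape = "sphere", radius = 10, center = c(0, 0, 0), organ_id = 2L,
         density = 1.05, name = "A", level = 2L))
  expect_error(build_phantom(body_first), "before their enclosing body")
  expect_error(phantom_recipe(list(organ_id = 1L), list(organ_id = 1L)),
               "unique")
})

test_that("deformations preserve connectivity and detect inversion", {
  ph <- sphere_fixture(r = 12, level = 2L)
  # identity affine: identical mesh
  ident <- deform(ph$mesh, list(type = "affine", A = diag(3)))
  expect_equal(ident$nodes, ph$mesh$nodes)
  expect_identical(ident$tets, ph$mesh$tets)
  # det = 1 shear: per-organ volumes unchanged
  A <- matrix(c(1, 0, 0, 0.35, 1, 0, 0.1, 0, 1), 3, 3)
  expect_equal(det(A), 1)
  sheared <- deform(ph$mesh, list(type = "affine", A = A, b = c(1, 2, 3)))
  expect_equal(organ_volumes(sheared), organ_volumes(ph$mesh),
               tolerance = 1e-12)
  # small-curvature bend: valid, and its own tet volumes are the new truth
  bent <- deform(ph$mesh, list(type = "bend", axis = "x",
                               curvature = 1 / 500, center = 0))
  expect_identical(bent$tets, ph$mesh$tets)
  expect_false(isTRUE(all.equal(organ_volumes(bent), organ_volumes(ph$mesh))))
  expect_equal(organ_volumes(bent), organ_volumes(ph$mesh), tolerance = 0.05)
  # violent bend inverts tets
  expect_error(deform(ph$mesh, list(type = "bend", axis = "x",
                                    curvature = 1 / 10, center = 0)),
               "inverted")
  expect_error(deform(ph$mesh, list(type = "affine", A = -diag(3))),
               "det > 0")
})

test_that("deformed watertightness is preserved", {
  ph <- build_phantom(default_phantom_recipe(level_large = 2L,
                                             level_small = 2L))
  dm <- deform(ph$mesh, list(type = "bend", axis = "x", curvature = 1 / 2500,
                             center = 0))
  for (oid in mesh_organ_ids(dm))
    expect_equal(surface_euler(extract_surface(dm, oid)), 2L)
})

test_that("phantom files written by the generator round-trip through the readers", {
  ph <- build_phantom(phantom_recipe(
    list(shape = "sphere", radius = 8, center = c(0, 0, 0), organ_id = 1L,
         density = 1.05, name = "Ball", level = 2L)))
  d <- withr::local_tempdir()
  paths <- write_phantom_files(ph, d)
  mesh <- read_phantom(paths[["node"]], paths[["ele"]])
  expect_identical(mesh, ph$mesh)
  mt <- read_material_table(paths[["material"]])
  expect_equal(mt$density, ph$materials$density)
  sp <- read_contour_spec(paths[["contours"]])
  expect_equal(sp$organ_id, ph$spec$organ_id)
})
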