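test_that("build_grid reproduces the standard CT pixel spacings", {
  bb <- aabb(c(-100, -100, 0), c(100, 100, 10))
  g <- build_grid(500, 512, 2, bb)
  expect_equal(g$spacing[1], 500 / 512)
  expect_lt(abs(g$spacing[1] - 0.976562), 1e-6)
  expect_equal(g$dims[1:2], c(512L, 512L))
  g6 <- build_grid(600, 512, 2, bb)
  expect_equal(round(g6$spacing[1], 2), 1.17)
  # z coverage: 10 mm range at 2 mm thickness -> 5 slices from bbox min
  expect_equal(g$dims[3], 5L)
  expect_equal(grid_slice_z(g), c(1, 3, 5, 7, 9))
  # transverse centering
  expect_equal(g$origin[1] + (512 / 2 - 0.5) * g$spacing[1], 0)
  expect_error(build_grid(100, 64, 2, aabb(c(-80, 0, 0), c(80, 10, 10))),
               "FOV")
})

test_that("voxel_density is the weighted mixture of tet and background density", {
  expect_equal(voxel_density(1, 1.05, background = 0), 1.05)
  expect_equal(voxel_density(0.5, 2.0, background = 0), 1.0)
  expect_equal(voxel_density(c(0.2, 0.3, 0.5), c(1.0, 1.1, 0.9),
                             background = 0), 0.98)
  expect_equal(voxel_density(c(0.25, 0.25), c(1.0, 2.0), background = 0.5),
               1.0)
  expect_error(voxel_density(c(0.7, 0.6), c(1, 1)), "exceeds 1")
  mt <- material_table(1:2, c("A", "B"), c(1.0, 1.1))
  expect_equal(voxel_density(c(0.2, 0.3), materials = mt, organ_id = c(1L, 2L),
                             background = 0), 0.2 + 0.33)
})

test_that("sample_voxel weights behave for enclosing, empty and bisected voxels", {
  b <- box_fixture(ext = c(40, 40, 40), cells = c(1L, 1L, 1L))
  pol <- sampling_policy(1000, seed = 5)
  # voxel well inside the box: weights sum to exactly 1
  w <- sample_voxel(c(0, 0, 0), c(1, 1, 2), pol, b$mesh, materials = NULL)
  expect_equal(sum(w), 1)
  # no candidates
  w0 <- sample_voxel(c(0, 0, 0), c(1, 1, 2), pol, b$mesh,
                     candidates = integer(0))
  expect_length(w0, 0)
  # voxel bisected by the box face at x = 20: claimed fraction ~ 0.5
  w2 <- sample_voxel(c(20, 0, 0), c(1, 1, 2), pol, b$mesh)
  N <- attr(w2, "n_points")
  expect_lt(abs(sum(w2) - 0.5), 3 * sqrt(0.25 / N))
  # deterministic in (seed, voxel index); distinct across voxel indices
  w3 <- sample_voxel(c(20, 0, 0), c(1, 1, 2), pol, b$mesh)
  expect_identical(as.numeric(w2), as.numeric(w3))
  w4 <- sample_voxel(c(20, 0, 0), c(1, 1, 2), pol, b$mesh, voxel_index = 1)
  expect_false(identical(as.numeric(w2), as.numeric(w4)))
})

test_that("sampled weights converge to the exact clipped-volume fraction", {
  # single tet vs one voxel: brute-force fine-subgrid oracle
  verts <- ref_tet()
  nodes <- verts; tets <- rbind(1:4)
  mesh <- tet_mesh(nodes, tets, 1L)
  ctr <- c(2.1, 1.7, 1.3); sp <- c(2, 2, 2)
  m <- 60  # subgrid resolution per axis
  off <- (seq_len(m) - 0.5) / m
  gridpts <- as.matrix(expand.grid(x = ctr[1] - 1 + off * sp[1],
                                   y = ctr[2] - 1 + off * sp[2],
                                   z = ctr[3] - 1 + off * sp[3]))
  frac_oracle <- mean(.points_in_mesh(mesh$nodes, mesh$tets, gridpts, 0))
  pol <- sampling_policy(4000, seed = 9)
  w <- sample_voxel(ctr, sp, pol, mesh)
  N <- attr(w, "n_points")
  se <- sqrt(frac_oracle * (1 - frac_oracle) / N)
  subgrid_err <- 3 / m  # surface-cell bound on the oracle itself
  expect_lt(abs(sum(w) - frac_oracle), 3 * se + subgrid_err)
})

test_that("voxelize_organ equals the brute-force all-tets scan", {
  s <- sphere_fixture(r = 9, level = 2L)
  mt <- material_table(1L, "S", 1.05)
  g <- build_grid(24, 20, 1.2, mesh_bbox(s$mesh))
  pol <- sampling_policy(1000, seed = 2)
  fast <- voxelize_organ(s$mesh, 1L, g, pol, mt, accelerate = TRUE)
  slow <- voxelize_organ(s$mesh, 1L, g, pol, mt, accelerate = FALSE)
  expect_identical(fast, slow)
})

test_that("claimed fractions are bounded and exactly 1 inside an organ", {
  b <- box_fixture(ext = c(20, 20, 20), cells = c(2L, 2L, 2L))
  mt <- material_table(1L, "B", 1.0)
  g <- build_grid(30, 30, 2, mesh_bbox(b$mesh))
  dg <- voxelize_phantom(b$mesh, g, sampling_policy(1000, 4), mt,
                         background = 0)
  expect_true(all(dg$wsum >= 0 & dg$wsum <= 1 + 1e-12))
  # voxels whose full extent lies inside the box must have wsum exactly 1
  cx <- g$origin[1] + (seq_len(g$dims[1]) - 1) * g$spacing[1]
  cz <- grid_slice_z(g)
  inx <- which(cx - g$spacing[1] / 2 > -10 & cx + g$spacing[1] / 2 < 10)
  inz <- which(cz - g$spacing[3] / 2 > -10 & cz + g$spacing[3] / 2 < 10)
  interior <- dg$wsum[inx, inx, inz]
  expect_true(all(interior == 1))
  expect_true(all(dg$density[inx, inx, inz] == 1.0))
})

test_that("total mass is conserved within the Monte-Carlo error budget", {
  for (fix in list(sphere_fixture(r = 16, level = 3L),
                   two_box_fixture())) {
    mesh <- if (!is.null(fix$mesh_volume)) fix$mesh else fix$mesh
    mt <- if (!is.null(fix$materials)) fix$materials
          else material_table(1L, "S", 1.05)
    g <- build_grid(60, 48, 2, mesh_bbox(mesh))
    dg <- voxelize_phantom(mesh, g, sampling_policy(1000, 8), mt,
                           background = 0)
    m_grid <- grid_mass(dg)
    m_mesh <- mesh_mass(mesh, mt)
    # binomial SE summed over partially claimed voxels
    voxvol_cm3 <- prod(g$spacing) * 1e-3
    N <- round(1000 * prod(g$spacing))
    w <- dg$wsum
    se <- sqrt(sum(w * (1 - w)) / N) * voxvol_cm3 * max(mt$density)
    expect_lt(abs(m_grid - m_mesh), 3 * se + 1e-9)
  }
})

test_that("two disjoint boxes accumulate to the sum of their masses", {
  fix <- two_box_fixture()
  g <- build_grid(60, 48, 2, mesh_bbox(fix$mesh))
  dg <- voxelize_phantom(fix$mesh, g, sampling_policy(1000, 12),
                         fix$materials, background = 0)
  expect_equal(grid_mass(dg), mesh_mass(fix$mesh, fix$materials),
               tolerance = 1e-3)
})

test_that("an empty mesh voxelizes to a uniform background grid", {
  mesh <- tet_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 4),
                   integer(0))
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(4L, 4L, 4L))
  dg <- voxelize_phantom(mesh, g, sampling_policy(1000, 1),
                         material_table(1L, "x", 1), background = 0.0012)
  expect_true(all(dg$density == 0.0012))
  expect_true(all(dg$wsum == 0))
})

test_that("voxelization is deterministic for a fixed seed", {
  s <- sphere_fixture(r = 9, level = 2L)
  mt <- material_table(1L, "S", 1.05)
  g <- build_grid(24, 16, 2, mesh_bbox(s$mesh))
  d1 <- voxelize_phantom(s$mesh, g, sampling_policy(1000, 6), mt)
  d2 <- voxelize_phantom(s$mesh, g, sampling_policy(1000, 6), mt)
  expect_identical(d1$density, d2$density)
  d3 <- voxelize_phantom(s$mesh, g, sampling_policy(1000, 60), mt)
  expect_false(identical(d1$density, d3$density))
})

test_that("doubling the point budget does not worsen expected mass error", {
  s <- sphere_fixture(r = 6, level = 2L)
  mt <- material_table(1L, "S", 1.0)
  g <- build_grid(16, 10, 1.6, mesh_bbox(s$mesh))
  m_mesh <- mesh_mass(s$mesh, mt)
  err <- function(ppmm3, seed) {
    dg <- voxelize_phantom(s$mesh, g, sampling_policy(ppmm3, seed), mt,
                           background = 0)
    abs(grid_mass(dg) - m_mesh)
  }
  seeds <- 1:20
  e1 <- vapply(seeds, function(s0) err(250, s0), numeric(1))
  e2 <- vapply(seeds, function(s0) err(500, s0), numeric(1))
  expect_lte(mean(e2), mean(e1))
})

test_that("the voxelization cache reproduces grids and rejects stale metadata", {
  s <- sphere_fixture(r = 9, level = 2L)
  mt <- material_table(1L, "S", 1.05)
  g <- build_grid(24, 16, 2, mesh_bbox(s$mesh))
  pol <- sampling_policy(1000, 3)
  dg <- voxelize_phantom(s$mesh, g, pol, mt)
  f <- withr::local_tempfile(fileext = ".cache")
  save_cache(dg, f)
  dg2 <- load_cache(f, mesh = s$mesh, grid = g, policy = pol,
                    background = 0.0012)
  expect_identical(dg2$density, dg$density)
  expect_identical(dg2$wsum, dg$wsum)

  g_thick <- build_grid(24, 16, 2.5, mesh_bbox(s$mesh))
  expect_error(load_cache(f, grid = g_thick), "stale")
  expect_error(load_cache(f, policy = sampling_policy(500, 3)), "stale")
  other <- box_fixture()
  expect_error(load_cache(f, mesh = other$mesh), "stale")
})
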