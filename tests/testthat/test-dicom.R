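# shared small study fixture built once per file
local({
  s <- sphere_fixture(r = 9, level = 2L)
  mt <- material_table(1L, "Sphere", 1.05)
  g <- build_grid(24, 16, 2, mesh_bbox(s$mesh))
  dg <- voxelize_phantom(s$mesh, g, sampling_policy(1000, 17), mt)
  .fix$study <- list(mesh = s$mesh, grid = g, hu = hu_grid(dg),
                     spec = contour_spec(1L, "Sphere"))
})

write_study <- function(dir, uid_seed = 5L) {
  st <- .fix$study
  identity <- study_identity(st$grid$dims[3], uid_seed = uid_seed)
  ct <- write_ct_series(st$hu, st$grid, identity, dir)
  contours <- contour_phantom(st$mesh, st$spec, st$grid)
  rt <- file.path(dir, "RS.dcm")
  write_rtstruct(contours, identity, st$spec, st$grid, rt)
  list(ct = ct, rt = rt, identity = identity, contours = contours)
}

test_that("CT series geometry, instance numbering and HU round-trip are exact", {
  st <- .fix$study
  d <- withr::local_tempdir()
  sd <- write_study(d)
  expect_length(sd$ct, st$grid$dims[3])

  back <- read_ct_series(sd$ct)
  expect_identical(back$hu, array(as.integer(st$hu), dim(st$hu)))
  expect_equal(back$z, grid_slice_z(st$grid))
  expect_equal(diff(back$z), rep(st$grid$spacing[3], st$grid$dims[3] - 1L))
  expect_equal(back$pixel_spacing,
               c(st$grid$spacing[2], st$grid$spacing[1]))
  inst <- vapply(back$datasets, function(x) as.integer(x[["0020,0013"]]),
                 integer(1))
  expect_equal(inst, seq_len(st$grid$dims[3]))
  ipp <- as.numeric(strsplit(back$datasets[[1]][["0020,0032"]], "\\\\")[[1]])
  expect_equal(ipp[1:2], st$grid$origin[1:2], tolerance = 1e-6)
  expect_equal(back$datasets[[1]][["0020,0037"]], "1\\0\\0\\0\\1\\0")
})

test_that("the default FOV writes PixelSpacing 0.976562 at DS precision", {
  g <- build_grid(500, 512, 2, aabb(c(-50, -50, 0), c(50, 50, 4)))
  hu <- array(-1000L, g$dims)
  d <- withr::local_tempdir()
  files <- write_ct_series(hu, g, study_identity(g$dims[3]), d)
  ds <- read_dicom(files[1])
  expect_equal(ds[["0028,0030"]], "0.976562\\0.976562")
})

test_that("HU outside the CT range or wrong slice count are contract errors", {
  st <- .fix$study
  d <- withr::local_tempdir()
  bad <- st$hu; bad[1] <- 5000L
  expect_error(write_ct_series(bad, st$grid, study_identity(st$grid$dims[3]),
                               d), "-1024")
  expect_error(write_ct_series(st$hu, st$grid, study_identity(2L), d),
               "slice")
})

test_that("RT-struct items reference the CT slice at their z with all points", {
  d <- withr::local_tempdir()
  sd <- write_study(d)
  rs <- read_dicom(sd$rt)
  rois <- rs[["3006,0020"]]
  expect_length(rois, 1L)
  expect_equal(rois[[1]][["3006,0026"]], "Sphere")

  zs <- grid_slice_z(.fix$study$grid)
  n_items <- 0L
  for (roi in rs[["3006,0039"]]) for (ci in roi[["3006,0040"]]) {
    n_items <- n_items + 1L
    expect_equal(ci[["3006,0042"]], "CLOSED_PLANAR")
    pts <- as.numeric(strsplit(ci[["3006,0050"]], "\\\\")[[1]])
    expect_equal(length(pts) %% 3, 0)
    npts <- as.integer(ci[["3006,0046"]])
    expect_equal(npts, length(pts) / 3)      # NumberOfContourPoints
    z <- pts[3]
    expect_true(all(abs(pts[seq(3, length(pts), 3)] - z) < 1e-9))  # planar
    k <- which(abs(zs - z) < 1e-6)
    ref <- ci[["3006,0016"]][[1]][["0008,1155"]]
    expect_equal(ref, sd$identity$slice_sop_uids[k])
  }
  n_emitted <- sum(vapply(sd$contours[["1"]]$slices,
                          function(s) length(s$loops), integer(1)))
  expect_equal(n_items, n_emitted)
})

test_that("a two-lobed organ emits two contour items at the same z in one ROI", {
  mesh <- two_lobe_fixture()
  g <- build_grid(60, 32, 2, mesh_bbox(mesh))
  spec <- contour_spec(7L, "Lobes")
  contours <- contour_phantom(mesh, spec, g)
  identity <- study_identity(g$dims[3])
  d <- withr::local_tempdir()
  hu <- array(-1000L, g$dims)
  write_ct_series(hu, g, identity, d)
  rt <- file.path(d, "RS.dcm")
  write_rtstruct(contours, identity, spec, g, rt)
  rs <- read_dicom(rt)
  items <- rs[["3006,0039"]][[1]][["3006,0040"]]
  z_of <- vapply(items, function(ci)
    as.numeric(strsplit(ci[["3006,0050"]], "\\\\")[[1]])[3], numeric(1))
  expect_true(any(table(sprintf("%.3f", z_of)) == 2))
})

test_that("link_study passes on an intact study and flags dangling references", {
  d <- withr::local_tempdir()
  sd <- write_study(d)
  rep <- link_study(sd$ct, sd$rt)
  expect_length(rep$issues, 0)
  expect_gt(rep$n_contours, 0)
  # drop the CT slices the contours reference -> dangling references
  keep <- sd$ct[c(1L, length(sd$ct))]
  rep2 <- link_study(keep, sd$rt)
  expect_match(rep2$issues, "dangling", all = FALSE)
})

test_that("writing twice with a fixed clock and seed is byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- write_study(d1); s2 <- write_study(d2)
  expect_identical(readBin(s1$ct[3], "raw", 1e7), readBin(s2$ct[3], "raw", 1e7))
  expect_identical(readBin(s1$rt, "raw", 1e8), readBin(s2$rt, "raw", 1e8))
  s3 <- write_study(withr::local_tempdir(), uid_seed = 6L)
  expect_false(identical(readBin(s1$rt, "raw", 1e8),
                         readBin(s3$rt, "raw", 1e8)))
})

test_that("an independent DICOM reader reproduces the ROI volume", {
  d <- withr::local_tempdir()
  sd <- write_study(d)
  # package-internal re-parse
  own <- rtstruct_volumes(sd$rt, .fix$study$grid$spacing[3])
  v_mem <- contour_volume(sd$contours[["1"]], .fix$study$grid$spacing[3])
  expect_lt(abs(own[["Sphere"]] - v_mem) / v_mem, 1e-4)

  # external oracle: pydicom re-parse + shoelace
  py <- Sys.which("python")
  script <- sprintf("
import pydicom, sys
ds = pydicom.dcmread(r'%s')
vol = 0.0
for roi in ds.ROIContourSequence:
    for c in roi.ContourSequence:
        pts = [float(v) for v in c.ContourData]
        xs, ys = pts[0::3], pts[1::3]
        a = 0.0
        for i in range(len(xs)):
            j = (i + 1) %% len(xs)
            a += xs[i] * ys[j] - xs[j] * ys[i]
        vol += abs(a) / 2 * %f
print(repr(vol / 1000.0))
", sd$rt, .fix$study$grid$spacing[3])
  out <- system2(py, "-", input = script, stdout = TRUE, stderr = TRUE)
  v_py <- suppressWarnings(as.numeric(out[length(out)]))
  expect_false(is.na(v_py))
  expect_lt(abs(v_py - v_mem) / v_mem, 1e-4)
})
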