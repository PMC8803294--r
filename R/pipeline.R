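# ---- single-run conversion pipeline -----------------------------------------

#' Conversion run configuration
#'
#' Collects every input path and parameter of a conversion run.  Defaults
#' follow the standard CT conventions used throughout the package: 500 mm
#' FOV, 512 x 512 pixels, 2 mm slices, 1000 sampling points per mm^3.
#'
#' @param node,ele phantom node/element file paths (alternatively pass a
#'   `mesh` directly).
#' @param materials path to a material table file, or a [material_table()].
#' @param contours path to a contour-spec file, or a [contour_spec()]
#'   (default: contour every organ in the material table).
#' @param hu_table path to a density-to-HU table file, or an [hu_table()]
#'   (default [default_hu_table()]).
#' @param out_dir output directory for the DICOM study.
#' @param cache optional voxelization cache file path; reused when valid,
#'   created after a fresh voxelization.
#' @param fov_mm,resolution,slice_thickness grid parameters.
#' @param points_per_mm3,seed,background sampling parameters.
#' @param mesh optional [tet_mesh()] (overrides `node`/`ele`).
#' @param patient_name,patient_id,uid_root,fixed_clock study identity.
#' @param verbose emit per-stage progress.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(node = NULL, ele = NULL, materials, contours = NULL,
                       hu_table = NULL, out_dir = "dicom_out", cache = NULL,
                       fov_mm = 500, resolution = 512L, slice_thickness = 2,
                       points_per_mm3 = 1000, seed = 1L,
                       background = 0.00120, mesh = NULL,
                       patient_name = "PHANTOM^CT", patient_id = "PCT000",
                       uid_root = DEFAULT_UID_ROOT, fixed_clock = TRUE,
                       verbose = TRUE) {
  stopifnot(fov_mm > 0, resolution >= 1, slice_thickness > 0)
  structure(list(node = node, ele = ele, materials = materials,
                 contours = contours, hu_table = hu_table, out_dir = out_dir,
                 cache = cache, fov_mm = fov_mm,
                 resolution = as.integer(resolution),
                 slice_thickness = slice_thickness,
                 points_per_mm3 = points_per_mm3, seed = seed,
                 background = background, mesh = mesh,
                 patient_name = patient_name, patient_id = patient_id,
                 uid_root = uid_root, fixed_clock = fixed_clock,
                 verbose = verbose),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s stage] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full phantom-to-DICOM conversion
#'
#' Executes load -> voxelize (or cache reuse) -> HU mapping -> CT series ->
#' surface/contour extraction -> RT-structure -> study-link validation, and
#' returns the per-organ volume-comparison report.  Deterministic for a
#' fixed seed and `fixed_clock = TRUE`.
#'
#' @param config a [run_config()].
#' @return A list of class `"conversion_result"`: `ct_files`, `rtstruct`,
#'   `report` (see [run_report()]), `link` (study-link report), `grid`,
#'   `identity`, `dgrid`, `contours`, `from_cache`.
#' @export
run_convert <- function(config) {
  stopifnot(inherits(config, "run_config"))
  vmsg <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  mesh <- stage("load", {
    if (!is.null(config$mesh)) config$mesh
    else read_phantom(config$node, config$ele)
  })
  materials <- stage("load", {
    if (inherits(config$materials, "material_table")) config$materials
    else read_material_table(config$materials)
  })
  spec <- stage("load", {
    if (is.null(config$contours))
      contour_spec(materials$organ_id, materials$name)
    else if (inherits(config$contours, "contour_spec")) config$contours
    else read_contour_spec(config$contours)
  })
  htab <- stage("load", {
    if (is.null(config$hu_table)) default_hu_table()
    else if (inherits(config$hu_table, "hu_table")) config$hu_table
    else read_hu_table(config$hu_table)
  })
  val <- validate_mesh(mesh, materials)
  if (length(val$orphan_organ_ids))
    stop("[load stage] organ IDs without material entry: ",
         paste(val$orphan_organ_ids, collapse = ", "))

  grid <- stage("grid", build_grid(config$fov_mm, config$resolution,
                                   config$slice_thickness, mesh_bbox(mesh)))
  policy <- sampling_policy(config$points_per_mm3, config$seed)

  from_cache <- FALSE
  dgrid <- stage("voxelize", {
    if (!is.null(config$cache) && file.exists(config$cache)) {
      g <- load_cache(config$cache, mesh = mesh, grid = grid,
                      policy = policy, background = config$background)
      from_cache <- TRUE
      vmsg("voxelization skipped: reusing cache %s", config$cache)
      g
    } else {
      t0 <- proc.time()[["elapsed"]]
      g <- voxelize_phantom(mesh, grid, policy, materials,
                            background = config$background,
                            verbose = config$verbose)
      vmsg("voxelization: %.1f s", proc.time()[["elapsed"]] - t0)
      if (!is.null(config$cache)) {
        save_cache(g, config$cache)
        vmsg("voxelization cache written to %s", config$cache)
      }
      g
    }
  })

  identity <- study_identity(grid$dims[3], config$patient_name,
                             config$patient_id, config$uid_root,
                             uid_seed = config$seed,
                             fixed_clock = config$fixed_clock)
  hu <- stage("hu", hu_grid(dgrid, htab))
  ct_files <- stage("ct-write",
                    write_ct_series(hu, grid, identity, config$out_dir))
  vmsg("CT series: %d slices written to %s", length(ct_files), config$out_dir)

  contours <- stage("contour", contour_phantom(mesh, spec, grid))
  rtstruct <- stage("rtstruct-write", {
    p <- file.path(config$out_dir, "RS.rtstruct.dcm")
    write_rtstruct(contours, identity, spec, grid, p)
    p
  })
  link <- stage("link", link_study(ct_files, rtstruct))
  if (length(link$issues))
    stop("[link stage] study failed validation: ",
         paste(link$issues, collapse = "; "))
  report <- run_report(mesh, contours, grid, spec)
  if (isTRUE(config$verbose)) print(report)

  structure(list(ct_files = ct_files, rtstruct = rtstruct, report = report,
                 link = link, grid = grid, identity = identity,
                 dgrid = dgrid, contours = contours, from_cache = from_cache),
            class = "conversion_result")
}

#' Per-organ volume-comparison report
#'
#' For every contoured organ: A = summed tetrahedron volume (cm^3),
#' B = contour-stack volume (cm^3), and the relative difference
#' `|A - B| / A x 100` (%).
#'
#' @param mesh a [tet_mesh()].
#' @param contours list of [contour_set()]s, as from [contour_phantom()].
#' @param grid the [voxel_grid()] (for the slice thickness).
#' @param spec optional [contour_spec()] for organ names.
#' @return A data.frame of class `"volume_report"` with columns `organ_id`,
#'   `name`, `tm_volume_cm3`, `contour_volume_cm3`, `pct_diff`.
#' @export
run_report <- function(mesh, contours, grid, spec = NULL) {
  ids <- as.integer(names(contours))
  A <- vapply(ids, function(id) sum(tet_volumes(mesh, id)) * 1e-3, numeric(1))
  B <- vapply(contours, function(cs)
    contour_volume(cs, grid$spacing[3]), numeric(1))
  nms <- if (!is.null(spec)) spec$name[match(ids, spec$organ_id)]
         else paste0("Organ", ids)
  out <- data.frame(organ_id = ids, name = nms, tm_volume_cm3 = A,
                    contour_volume_cm3 = as.numeric(B),
                    pct_diff = abs(A - B) / A * 100, row.names = NULL)
  class(out) <- c("volume_report", "data.frame")
  out
}

#' @export
print.volume_report <- function(x, ...) {
  cat("Organ volume comparison (A = mesh, B = contours):\n")
  fmt <- data.frame(organ_id = x$organ_id, name = x$name,
                    A_cm3 = sprintf("%.2f", x$tm_volume_cm3),
                    B_cm3 = sprintf("%.2f", x$contour_volume_cm3),
                    pct_diff = sprintf("%.2f", x$pct_diff))
  print(fmt, row.names = FALSE)
  invisible(x)
}
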