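# ---- minimal conformant DICOM writer (explicit VR little endian) -----------

UID_TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
UID_CT_IMAGE_STORAGE    <- "1.2.840.10008.5.1.4.1.1.2"
UID_RTSTRUCT_STORAGE    <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_DETACHED_STUDY      <- "1.2.840.10008.3.1.2.3.1"
DEFAULT_UID_ROOT        <- "2.25"

# fixed palette for ROI display colors (RGB)
ROI_PALETTE <- matrix(c(255, 0, 0,   0, 255, 0,   0, 0, 255,
                        255, 255, 0, 0, 255, 255, 255, 0, 255,
                        255, 128, 0, 128, 0, 255, 0, 128, 0,
                        128, 128, 128),
                      ncol = 3L, byrow = TRUE)

int_le <- function(x, size) {
  x <- as.numeric(x)
  if (size == 2L) x <- ifelse(x > 32767, x - 65536, x)      # two's complement
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

SHORT_VRS <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO","LT",
               "PN","SH","SL","SS","ST","TM","UI","UL","US")

dcm_element <- function(group, elem, vr, payload) {
  if (vr %in% c("UI"))      payload <- pad_even(payload, as.raw(0x00))
  else if (!vr %in% c("SQ")) payload <- pad_even(payload)
  tag <- c(int_le(group, 2L), int_le(elem, 2L))
  if (vr %in% SHORT_VRS) {
    if (length(payload) > 65534L)
      stop(sprintf("DICOM element (%04X,%04X) %s payload of %d bytes exceeds ",
                   group, elem, vr, length(payload)),
           "the 65534-byte explicit-VR limit")
    c(tag, charToRaw(vr), int_le(length(payload), 2L), payload)
  } else {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), int_le(length(payload), 4L),
      payload)
  }
}

dcm_str <- function(group, elem, vr, value) {
  dcm_element(group, elem, vr, charToRaw(paste(value, collapse = "\\")))
}

dcm_us <- function(group, elem, value) {
  dcm_element(group, elem, "US", int_le(value, 2L))
}

# decimal string with <= 16 chars per value
fmt_ds <- function(x) {
  s <- sprintf("%.6f", x)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  ifelse(nchar(s) > 16L, sprintf("%.8g", x), s)
}

dcm_item <- function(payload) {
  c(int_le(0xFFFE, 2L), int_le(0xE000, 2L), int_le(length(payload), 4L),
    payload)
}

dcm_sq <- function(group, elem, items) {
  dcm_element(group, elem, "SQ", do.call(c, c(items, list(raw(0)))))
}

dcm_file <- function(sop_class, sop_instance, dataset_bytes) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_str(0x0002, 0x0002, "UI", sop_class),
    dcm_str(0x0002, 0x0003, "UI", sop_instance),
    dcm_str(0x0002, 0x0010, "UI", UID_TRANSFER_SYNTAX_ELE),
    dcm_str(0x0002, 0x0012, "UI", paste0(DEFAULT_UID_ROOT, ".86580943598.1")))
  grouplen <- dcm_element(0x0002, 0x0000, "UL", int_le(length(meta), 4L))
  c(raw(128L), charToRaw("DICM"), grouplen, meta, dataset_bytes)
}

# ---- study identity ---------------------------------------------------------

#' Generate DICOM study identity (UIDs and patient metadata)
#'
#' UIDs are built under a configurable root.  In deterministic mode each UID
#' derives from a content hash of `(uid_seed, counter)`, giving byte-stable
#' output for tests and reproducible studies; otherwise the seed is drawn
#' from R's RNG.
#'
#' @param n_slices number of CT slices.
#' @param patient_name,patient_id patient metadata strings.
#' @param uid_root DICOM UID root (default "2.25", the UUID-derived space).
#' @param uid_seed integer; fixes all UIDs when `deterministic = TRUE`.
#' @param deterministic derive UIDs from `uid_seed` (default TRUE).
#' @param fixed_clock use the fixed date/time 20200101/000000 instead of the
#'   wall clock, for byte-identical re-runs.
#' @return An object of class `"study_identity"`.
#' @export
study_identity <- function(n_slices, patient_name = "PHANTOM^CT",
                           patient_id = "PCT000", uid_root = DEFAULT_UID_ROOT,
                           uid_seed = 1L, deterministic = TRUE,
                           fixed_clock = TRUE) {
  if (!deterministic)
    uid_seed <- floor(stats::runif(1) * 2^31)
  mk <- function(counter) {
    h <- .fnv1a64(serialize(list(as.numeric(uid_seed), as.integer(counter)),
                            NULL, version = 2L))
    # two 8-hex-digit halves as decimal components: valid, unique UID
    paste0(uid_root, ".", strtoi(substr(h, 1L, 8L), 16L), ".",
           strtoi(substr(h, 9L, 16L), 16L), ".", counter)
  }
  structure(list(
    study_uid = mk(1L),
    ct_series_uid = mk(2L),
    rtstruct_series_uid = mk(3L),
    frame_of_reference_uid = mk(4L),
    rtstruct_sop_uid = mk(5L),
    slice_sop_uids = vapply(seq_len(n_slices) + 10L, mk, character(1)),
    patient_name = patient_name, patient_id = patient_id,
    date = if (fixed_clock) "20200101" else format(Sys.Date(), "%Y%m%d"),
    time = if (fixed_clock) "000000" else format(Sys.time(), "%H%M%S")),
    class = "study_identity")
}

common_dataset <- function(identity, modality) {
  c(dcm_str(0x0008, 0x0020, "DA", identity$date),
    dcm_str(0x0008, 0x0021, "DA", identity$date),
    dcm_str(0x0008, 0x0023, "DA", identity$date),
    dcm_str(0x0008, 0x0030, "TM", identity$time),
    dcm_str(0x0008, 0x0031, "TM", identity$time),
    dcm_str(0x0008, 0x0033, "TM", identity$time),
    dcm_str(0x0008, 0x0050, "SH", ""),
    dcm_str(0x0008, 0x0060, "CS", modality),
    dcm_str(0x0008, 0x0070, "LO", "phantomct"),
    dcm_str(0x0008, 0x0090, "PN", ""),
    dcm_str(0x0010, 0x0010, "PN", identity$patient_name),
    dcm_str(0x0010, 0x0020, "LO", identity$patient_id),
    dcm_str(0x0010, 0x0030, "DA", ""),
    dcm_str(0x0010, 0x0040, "CS", "O"))
}

# ---- CT series --------------------------------------------------------------

#' Write a DICOM CT image series
#'
#' One file per slice.  Pixels are stored as unsigned 16-bit with
#' RescaleSlope 1 and RescaleIntercept -1024 (stored value = HU + 1024), so
#' the round trip `stored * slope + intercept` reproduces the HU grid
#' exactly.  Geometry: PixelSpacing = (py, px), SliceThickness = pz,
#' ImagePositionPatient = centre of the slice's first voxel (mm, LPS, HFS
#' axial orientation 1\\0\\0\\0\\1\\0), InstanceNumber ascending with z.
#'
#' @param hu integer array (nx x ny x nz) of Hounsfield units in
#'   [-1024, 3071], as produced by [hu_grid()].
#' @param grid the [voxel_grid()] the HU array lives on.
#' @param identity a [study_identity()] with `n_slices == nz`.
#' @param out_dir output directory (created if needed).
#' @return Character vector of file paths (one per slice, ascending z),
#'   invisibly.
#' @export
write_ct_series <- function(hu, grid, identity, out_dir) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(identity, "study_identity"))
  dims <- grid$dims
  if (!all(dim(hu) == dims)) stop("HU array dimensions do not match the grid")
  if (length(identity$slice_sop_uids) != dims[3])
    stop("identity has ", length(identity$slice_sop_uids),
         " slice UIDs but the grid has ", dims[3], " slices")
  rng <- range(hu)
  if (rng[1] < -1024L || rng[2] > 3071L)
    stop("HU values outside [-1024, 3071]")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  zs <- grid_slice_z(grid)
  files <- character(dims[3])
  for (k in seq_len(dims[3])) {
    sop <- identity$slice_sop_uids[k]
    # DICOM row = y, column = x; column-major [x, y] is already row-major
    # pixel order with x varying fastest, first pixel at (x0, y0)
    stored <- as.integer(hu[, , k]) + 1024L
    px_bytes <- writeBin(stored, raw(), size = 2L, endian = "little")
    ds <- c(
      dcm_str(0x0008, 0x0008, "CS", c("DERIVED", "SECONDARY", "AXIAL")),
      dcm_str(0x0008, 0x0016, "UI", UID_CT_IMAGE_STORAGE),
      dcm_str(0x0008, 0x0018, "UI", sop),
      common_dataset(identity, "CT"),
      dcm_str(0x0018, 0x0050, "DS", fmt_ds(grid$spacing[3])),
      dcm_str(0x0020, 0x000D, "UI", identity$study_uid),
      dcm_str(0x0020, 0x000E, "UI", identity$ct_series_uid),
      dcm_str(0x0020, 0x0010, "SH", "1"),
      dcm_str(0x0020, 0x0011, "IS", "1"),
      dcm_str(0x0020, 0x0013, "IS", as.character(k)),
      dcm_str(0x0020, 0x0032, "DS",
              fmt_ds(c(grid$origin[1], grid$origin[2], zs[k]))),
      dcm_str(0x0020, 0x0037, "DS", fmt_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_str(0x0020, 0x0052, "UI", identity$frame_of_reference_uid),
      dcm_str(0x0020, 0x1040, "LO", ""),
      dcm_us(0x0028, 0x0002, 1L),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, dims[2]),          # Rows = ny
      dcm_us(0x0028, 0x0011, dims[1]),          # Columns = nx
      dcm_str(0x0028, 0x0030, "DS",
              fmt_ds(c(grid$spacing[2], grid$spacing[1]))),
      dcm_us(0x0028, 0x0100, 16L),
      dcm_us(0x0028, 0x0101, 16L),
      dcm_us(0x0028, 0x0102, 15L),
      dcm_us(0x0028, 0x0103, 0L),
      dcm_str(0x0028, 0x1052, "DS", "-1024"),
      dcm_str(0x0028, 0x1053, "DS", "1"),
      dcm_str(0x0028, 0x1054, "LO", "HU"),
      dcm_element(0x7FE0, 0x0010, "OW", px_bytes))
    files[k] <- file.path(out_dir, sprintf("CT.%04d.dcm", k))
    writeBin(dcm_file(UID_CT_IMAGE_STORAGE, sop, ds), files[k])
  }
  invisible(files)
}

# ---- RT structure set -------------------------------------------------------

#' Write a DICOM RT-structure set
#'
#' One ROI per contoured organ; every loop becomes a CLOSED_PLANAR contour
#' item (ContourData as x\\y\\z triplets in mm, patient coordinates, implicit
#' closure) referencing the SOPInstanceUID of the CT slice at its z.  ROI
#' display colors come from a fixed palette.
#'
#' @param contours named list of [contour_set()] objects, as returned by
#'   [contour_phantom()].
#' @param identity the [study_identity()] used for the CT series.
#' @param spec the [contour_spec()] providing ROI names.
#' @param grid the CT [voxel_grid()] (to map contour z to slice index).
#' @param out_path output file path.
#' @return `out_path`, invisibly.
#' @export
write_rtstruct <- function(contours, identity, spec, grid, out_path) {
  stopifnot(inherits(identity, "study_identity"),
            inherits(spec, "contour_spec"), inherits(grid, "voxel_grid"))
  zs <- grid_slice_z(grid)
  slice_for_z <- function(z) {
    k <- which(abs(zs - z) < grid$spacing[3] * 1e-6)
    if (length(k) != 1L)
      stop(sprintf("contour z = %.6f mm does not coincide with any CT slice",
                   z))
    k
  }

  ci_item <- function(sop)
    dcm_item(c(dcm_str(0x0008, 0x1150, "UI", UID_CT_IMAGE_STORAGE),
               dcm_str(0x0008, 0x1155, "UI", sop)))

  # referenced frame of reference -> study -> series -> all CT slices
  rfor <- dcm_sq(0x3006, 0x0010, list(dcm_item(c(
    dcm_str(0x0020, 0x0052, "UI", identity$frame_of_reference_uid),
    dcm_sq(0x3006, 0x0012, list(dcm_item(c(
      dcm_str(0x0008, 0x1150, "UI", UID_DETACHED_STUDY),
      dcm_str(0x0008, 0x1155, "UI", identity$study_uid),
      dcm_sq(0x3006, 0x0014, list(dcm_item(c(
        dcm_str(0x0020, 0x000E, "UI", identity$ct_series_uid),
        dcm_sq(0x3006, 0x0016,
               lapply(identity$slice_sop_uids, ci_item))))))))))))))

  roi_ids <- spec$organ_id
  ss_items <- list(); rc_items <- list(); ob_items <- list()
  for (i in seq_along(roi_ids)) {
    oid <- roi_ids[i]
    cset <- contours[[as.character(oid)]]
    if (is.null(cset)) stop("no contours supplied for organ ", oid)
    ss_items[[i]] <- dcm_item(c(
      dcm_str(0x3006, 0x0022, "IS", as.character(i)),
      dcm_str(0x3006, 0x0024, "UI", identity$frame_of_reference_uid),
      dcm_str(0x3006, 0x0026, "LO", spec$name[i]),
      dcm_str(0x3006, 0x0036, "CS", "AUTOMATIC")))

    citems <- list(); cn <- 0L
    for (s in cset$slices) {
      k <- slice_for_z(s$z)
      for (loop in s$loops) {
        cn <- cn + 1L
        pts <- cbind(loop[, 1], loop[, 2],
                     if (ncol(loop) >= 3L) loop[, 3] else s$z)
        citems[[cn]] <- dcm_item(c(
          dcm_sq(0x3006, 0x0016, list(ci_item(identity$slice_sop_uids[k]))),
          dcm_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
          dcm_str(0x3006, 0x0046, "IS", as.character(nrow(pts))),
          dcm_str(0x3006, 0x0048, "IS", as.character(cn)),
          dcm_str(0x3006, 0x0050, "DS", fmt_ds(as.vector(t(pts))))))
      }
    }
    col <- ROI_PALETTE[(i - 1L) %% nrow(ROI_PALETTE) + 1L, ]
    rc_items[[i]] <- dcm_item(c(
      dcm_str(0x3006, 0x002A, "IS", as.character(col)),
      dcm_str(0x3006, 0x0084, "IS", as.character(i)),
      if (length(citems)) dcm_sq(0x3006, 0x0040, citems)))

    ob_items[[i]] <- dcm_item(c(
      dcm_str(0x3006, 0x0082, "IS", as.character(i)),
      dcm_str(0x3006, 0x0084, "IS", as.character(i)),
      dcm_str(0x3006, 0x0085, "SH", substr(spec$name[i], 1L, 16L)),
      dcm_str(0x3006, 0x00A4, "CS", "ORGAN"),
      dcm_str(0x3006, 0x00A6, "PN", "")))
  }

  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_RTSTRUCT_STORAGE),
    dcm_str(0x0008, 0x0018, "UI", identity$rtstruct_sop_uid),
    common_dataset(identity, "RTSTRUCT"),
    dcm_str(0x0020, 0x000D, "UI", identity$study_uid),
    dcm_str(0x0020, 0x000E, "UI", identity$rtstruct_series_uid),
    dcm_str(0x0020, 0x0010, "SH", "1"),
    dcm_str(0x0020, 0x0011, "IS", "2"),
    dcm_str(0x3006, 0x0002, "SH", "phantomct"),
    dcm_str(0x3006, 0x0008, "DA", identity$date),
    dcm_str(0x3006, 0x0009, "TM", identity$time),
    rfor,
    dcm_sq(0x3006, 0x0020, ss_items),
    dcm_sq(0x3006, 0x0039, rc_items),
    dcm_sq(0x3006, 0x0080, ob_items))
  writeBin(dcm_file(UID_RTSTRUCT_STORAGE, identity$rtstruct_sop_uid, ds),
           out_path)
  invisible(out_path)
}
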