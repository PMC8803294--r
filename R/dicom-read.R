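# ---- minimal DICOM reader (explicit VR little endian) ----------------------
#
# Parses the subset this package writes (and any conformant explicit-VR
# little-endian file with defined or undefined sequence lengths) into a
# nested named list keyed by "GGGG,EEEE".

STRING_VRS <- c("AE","AS","CS","DA","DS","DT","IS","LO","LT","PN","SH","ST",
                "TM","UI","UT")

u16 <- function(b, off) as.integer(b[off]) + 256L * as.integer(b[off + 1L])
u32 <- function(b, off) {
  as.numeric(b[off]) + 256 * as.numeric(b[off + 1L]) +
    65536 * as.numeric(b[off + 2L]) + 16777216 * as.numeric(b[off + 3L])
}

parse_elements <- function(b, off, end) {
  out <- list()
  while (off + 7 <= end) {
    group <- u16(b, off); elem <- u16(b, off + 2L)
    tag <- sprintf("%04X,%04X", group, elem)
    if (group == 0xFFFE) {  # delimiters shouldn't appear here
      len <- u32(b, off + 4L)
      off <- off + 8L + len
      next
    }
    vr <- rawToChar(b[(off + 4L):(off + 5L)])
    if (vr %in% SHORT_VRS) {
      len <- u16(b, off + 6L)
      doff <- off + 8L
    } else {
      len <- u32(b, off + 8L)
      doff <- off + 12L
    }
    if (vr == "SQ") {
      if (len == 4294967295) {  # undefined length: scan for delimiter
        items <- list(); p <- doff
        repeat {
          g <- u16(b, p); e <- u16(b, p + 2L); l <- u32(b, p + 4L)
          if (g == 0xFFFE && e == 0xE0DD) { p <- p + 8L; break }
          stopifnot(g == 0xFFFE, e == 0xE000)
          items[[length(items) + 1L]] <- parse_elements(b, p + 8L, p + 8L + l - 1L)
          p <- p + 8L + l
        }
        value <- items
        off <- p
      } else {
        items <- list(); p <- doff
        while (p < doff + len) {
          g <- u16(b, p); e <- u16(b, p + 2L); l <- u32(b, p + 4L)
          stopifnot(g == 0xFFFE, e == 0xE000)
          items[[length(items) + 1L]] <- parse_elements(b, p + 8L, p + 8L + l - 1L)
          p <- p + 8L + l
        }
        value <- items
        off <- doff + len
      }
    } else {
      payload <- if (len > 0) b[doff:(doff + len - 1L)] else raw(0)
      value <- if (vr %in% STRING_VRS) {
        s <- rawToChar(payload[payload != as.raw(0)])
        trimws(s)
      } else if (vr == "US") {
        if (len >= 2) vapply(seq(1L, len, 2L), function(i) u16(payload, i),
                             integer(1)) else integer(0)
      } else if (vr == "UL") {
        if (len >= 4) vapply(seq(1L, len, 4L), function(i) u32(payload, i),
                             numeric(1)) else numeric(0)
      } else payload
      off <- doff + len
    }
    out[[tag]] <- value
  }
  out
}

#' Read a DICOM file written by this package
#'
#' Minimal explicit-VR little-endian parser; returns the dataset as a nested
#' named list keyed by `"GGGG,EEEE"` tags, with string VRs decoded to
#' character, US/UL to numeric, sequences to lists of items, and other VRs
#' (including PixelData) left as raw.
#'
#' @param path DICOM file path.
#' @return Named list with attributes `meta` (the group-0002 file meta
#'   elements).
#' @export
read_dicom <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  if (length(b) < 140L || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  # file meta: group-length element tells where the dataset starts
  stopifnot(u16(b, 133L) == 0x0002, u16(b, 135L) == 0x0000)
  meta_len <- u32(b, 141L)
  meta_end <- 144L + meta_len
  meta <- parse_elements(b, 133L, meta_end)
  ts <- meta[["0002,0010"]]
  if (!is.null(ts) && ts != UID_TRANSFER_SYNTAX_ELE)
    stop("unsupported transfer syntax: ", ts)
  ds <- parse_elements(b, meta_end + 1L, length(b))
  attr(ds, "meta") <- meta
  ds
}

#' Read back a CT series as a HU array
#'
#' Re-reads the per-slice files of [write_ct_series()] (sorted by
#' InstanceNumber) and reconstructs the HU array via
#' `stored * RescaleSlope + RescaleIntercept`.
#'
#' @param files character vector of CT file paths.
#' @return List: `hu` (nx x ny x nz integer array), `sop_uids`, `z` (slice
#'   positions), `pixel_spacing`, `datasets` (parsed per-slice lists).
#' @export
read_ct_series <- function(files) {
  dss <- lapply(files, read_dicom)
  inst <- vapply(dss, function(d) as.integer(d[["0020,0013"]]), integer(1))
  ord <- order(inst)
  dss <- dss[ord]
  rows <- dss[[1]][["0028,0010"]]
  cols <- dss[[1]][["0028,0011"]]
  slope <- as.numeric(dss[[1]][["0028,1053"]])
  icept <- as.numeric(dss[[1]][["0028,1052"]])
  hu <- array(0L, c(cols, rows, length(dss)))
  for (k in seq_along(dss)) {
    raw_px <- dss[[k]][["7FE0,0010"]]
    stored <- readBin(raw_px, "integer", n = length(raw_px) / 2L, size = 2L,
                      signed = FALSE, endian = "little")
    hu[, , k] <- as.integer(matrix(stored * slope + icept, nrow = cols,
                                   byrow = FALSE))
  }
  z <- vapply(dss, function(d)
    as.numeric(strsplit(d[["0020,0032"]], "\\\\")[[1]][3]), numeric(1))
  list(hu = hu,
       sop_uids = vapply(dss, function(d) d[["0008,0018"]], character(1)),
       z = z,
       pixel_spacing = as.numeric(strsplit(dss[[1]][["0028,0030"]],
                                           "\\\\")[[1]]),
       datasets = dss)
}

# ---- study linkage validation ----------------------------------------------

#' Validate that a CT series and RT-structure set form one linked study
#'
#' Re-reads the written files and verifies that (1) all CT slices and the
#' RT-struct share one StudyInstanceUID and FrameOfReferenceUID, and (2)
#' every ReferencedSOPInstanceUID in the RT-struct exists in the CT series.
#' A dangling reference is a fatal finding.
#'
#' @param ct_files character vector of CT slice file paths.
#' @param rtstruct_path RT-structure file path.
#' @return A list of class `"study_link_report"` with `issues` (character;
#'   empty when the study is intact) and `n_contours` (number of contour
#'   items checked).
#' @export
link_study <- function(ct_files, rtstruct_path) {
  ct <- lapply(ct_files, read_dicom)
  rs <- read_dicom(rtstruct_path)
  issues <- character(0)

  study_uids <- unique(c(vapply(ct, function(d) d[["0020,000D"]], character(1)),
                         rs[["0020,000D"]]))
  if (length(study_uids) != 1L)
    issues <- c(issues, "StudyInstanceUID differs between CT and RT-struct")
  ct_for <- unique(vapply(ct, function(d) d[["0020,0052"]], character(1)))
  rs_for <- unlist(lapply(rs[["3006,0010"]], function(it) it[["0020,0052"]]))
  if (length(ct_for) != 1L || !all(rs_for == ct_for))
    issues <- c(issues, "FrameOfReferenceUID differs between CT and RT-struct")

  ct_sops <- vapply(ct, function(d) d[["0008,0018"]], character(1))
  refs <- character(0)
  for (roi in rs[["3006,0039"]]) {
    for (citem in roi[["3006,0040"]]) {
      cis <- citem[["3006,0016"]]
      refs <- c(refs, vapply(cis, function(x) x[["0008,1155"]], character(1)))
    }
  }
  dangling <- setdiff(refs, ct_sops)
  if (length(dangling))
    issues <- c(issues,
                sprintf("dangling ReferencedSOPInstanceUID (no such CT slice): %s",
                        paste(utils::head(dangling, 3L), collapse = ", ")))
  structure(list(issues = issues, n_contours = length(refs)),
            class = "study_link_report")
}

#' @export
print.study_link_report <- function(x, ...) {
  if (length(x$issues) == 0L)
    cat(sprintf("study link OK (%d contour references verified)\n",
                x$n_contours))
  else cat("study link issues:\n", paste0("  - ", x$issues, "\n"), sep = "")
  invisible(x)
}

#' Recompute ROI volumes from a written RT-structure set
#'
#' Independent of the in-memory contour sets: parses the file, rebuilds each
#' ROI's polygons from ContourData, and applies the shoelace-area-times-
#' thickness rule (holes by even-odd parity).
#'
#' @param rtstruct_path RT-structure file path.
#' @param slice_thickness slice thickness, mm.
#' @return Named numeric vector of volumes (cm^3) keyed by ROI name.
#' @export
rtstruct_volumes <- function(rtstruct_path, slice_thickness) {
  rs <- read_dicom(rtstruct_path)
  rois <- rs[["3006,0020"]]
  names_by_number <- stats::setNames(
    vapply(rois, function(r) r[["3006,0026"]], character(1)),
    vapply(rois, function(r) r[["3006,0022"]], character(1)))
  out <- numeric(0)
  for (roi in rs[["3006,0039"]]) {
    num <- roi[["3006,0084"]]
    loops_by_z <- list()
    for (citem in roi[["3006,0040"]]) {
      xyz <- as.numeric(strsplit(citem[["3006,0050"]], "\\\\")[[1]])
      pts <- matrix(xyz, ncol = 3L, byrow = TRUE)
      zk <- sprintf("%.6f", pts[1, 3])
      loops_by_z[[zk]] <- c(loops_by_z[[zk]], list(pts[, 1:2, drop = FALSE]))
    }
    vol <- 0
    for (loops in loops_by_z) {
      par <- loop_parity(loops)
      areas <- vapply(loops, function(l) abs(polygon_area(l)), numeric(1))
      vol <- vol + sum(ifelse(par == 0L, areas, -areas)) * slice_thickness
    }
    out[names_by_number[[num]]] <- vol * 1e-3
  }
  out
}
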