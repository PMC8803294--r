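# ---- in-memory phantom model -----------------------------------------------

#' Tetrahedral-mesh phantom
#'
#' The in-memory model of a tetrahedral-mesh (TM) computational phantom: node
#' coordinates in millimetres, tetrahedra as four node indices, and one organ
#' (material) ID per tetrahedron.  On construction all tetrahedra are
#' orientation-normalized to positive signed volume, so downstream barycentric
#' sign conventions are uniform.
#'
#' @param nodes numeric n x 3 matrix of vertex coordinates (mm).
#' @param tets integer m x 4 matrix of node indices (1-based).
#' @param organ integer vector of length m; organ/material ID per tetrahedron.
#' @return An object of class `"tet_mesh"` with elements `nodes`, `tets`
#'   (positively oriented), and `organ`.
#' @export
tet_mesh <- function(nodes, tets, organ) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  organ <- as.integer(organ)
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns")
  if (ncol(tets) != 4L) stop("tets must have 4 columns")
  if (length(organ) != nrow(tets))
    stop("organ must have one ID per tetrahedron")
  if (nrow(tets) > 0L) {
    rng <- range(tets)
    if (rng[1] < 1L || rng[2] > nrow(nodes))
      stop("tetrahedron node index out of range [1, ", nrow(nodes), "]")
    rep_v <- tets[, 1] == tets[, 2] | tets[, 1] == tets[, 3] |
             tets[, 1] == tets[, 4] | tets[, 2] == tets[, 3] |
             tets[, 2] == tets[, 4] | tets[, 3] == tets[, 4]
    if (any(rep_v))
      stop("tetrahedra with repeated vertices: ",
           paste(utils::head(which(rep_v), 5L), collapse = ", "))
    sv <- signed_tet_volumes(nodes, tets)
    flip <- sv < 0
    if (any(flip)) {
      tmp <- tets[flip, 3L]
      tets[flip, 3L] <- tets[flip, 4L]
      tets[flip, 4L] <- tmp
    }
  }
  structure(list(nodes = nodes, tets = tets, organ = organ),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh: %d nodes, %d tets, %d organ(s)>\n",
              nrow(x$nodes), nrow(x$tets), length(unique(x$organ))))
  invisible(x)
}

#' Organ IDs present in a mesh
#' @param mesh a [tet_mesh()] object.
#' @return Sorted integer vector of distinct organ IDs.
#' @export
mesh_organ_ids <- function(mesh) sort(unique(mesh$organ))

# ---- material table ---------------------------------------------------------

#' Material table: organ ID to name and mass density
#'
#' Holds the per-organ mass densities (g/cm^3) used as the tetrahedron
#' densities during voxelization.
#'
#' @param organ_id integer vector of unique organ IDs.
#' @param name character vector of organ names.
#' @param density numeric vector of mass densities, g/cm^3, strictly positive.
#' @return An object of class `"material_table"`: a data.frame with columns
#'   `organ_id`, `name`, `density`.
#' @export
material_table <- function(organ_id, name, density) {
  organ_id <- as.integer(organ_id)
  density <- as.numeric(density)
  name <- as.character(name)
  if (anyDuplicated(organ_id))
    stop("duplicate organ IDs in material table: ",
         paste(unique(organ_id[duplicated(organ_id)]), collapse = ", "))
  if (any(!is.finite(density)) || any(density <= 0))
    stop("material densities must be finite and > 0")
  structure(data.frame(organ_id = organ_id, name = name, density = density,
                       stringsAsFactors = FALSE),
            class = c("material_table", "data.frame"))
}

#' Look up densities for organ IDs
#'
#' @param materials a [material_table()].
#' @param organ_id integer vector of organ IDs.
#' @return Numeric vector of densities (g/cm^3); errors on unknown IDs.
#' @export
material_density <- function(materials, organ_id) {
  i <- match(as.integer(organ_id), materials$organ_id)
  if (anyNA(i))
    stop("organ IDs missing from material table: ",
         paste(sort(unique(organ_id[is.na(i)])), collapse = ", "))
  materials$density[i]
}

# ---- contour specification --------------------------------------------------

#' Contour specification: which organs to contour
#'
#' Lists the organs to be emitted as RT-structure ROIs: an organ count and a
#' table of (organ ID, organ name) pairs.
#'
#' @param organ_id integer vector of organ IDs.
#' @param name character vector of organ names (same length).
#' @return An object of class `"contour_spec"`.
#' @export
contour_spec <- function(organ_id, name) {
  organ_id <- as.integer(organ_id)
  name <- as.character(name)
  if (length(organ_id) != length(name))
    stop("organ_id and name must have equal length")
  if (anyDuplicated(organ_id))
    stop("duplicate organ IDs in contour spec")
  structure(list(organ_count = length(organ_id),
                 organ_id = organ_id, name = name),
            class = "contour_spec")
}

#' @export
print.contour_spec <- function(x, ...) {
  cat(sprintf("<contour_spec: %d organ(s)>\n", x$organ_count))
  for (i in seq_along(x$organ_id))
    cat(sprintf("  %d  %s\n", x$organ_id[i], x$name[i]))
  invisible(x)
}

# ---- text-file parsing helpers ----------------------------------------------

# Reads a whitespace-tokenized text file, tolerating '#' comments and blank
# lines; returns a list of token vectors plus original line numbers.
read_tokens <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", raw)
  keep <- grepl("[^[:space:]]", stripped)
  toks <- strsplit(trimws(stripped[keep]), "[,[:space:]]+")
  list(tokens = toks, lines = which(keep), path = path)
}

parse_err <- function(tk, i, msg) {
  line <- if (i <= length(tk$lines)) tk$lines[i] else NA_integer_
  stop(sprintf("%s:%s: %s", tk$path, ifelse(is.na(line), "EOF", line), msg),
       call. = FALSE)
}

as_num_checked <- function(x, tk, i, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) parse_err(tk, i, paste0("non-numeric ", what, ": '",
                                        paste(x, collapse = " "), "'"))
  v
}

# ---- TetGen-dialect node/element files --------------------------------------

#' Read a TetGen-style node file
#'
#' Parses a `.node` file: a header line `<n> <dim> <n_attr> <n_marker>`
#' followed by `n` lines `<index> <x> <y> <z> ...`.  Coordinates are in
#' millimetres.  The index base (0 or 1) is detected from the first node's
#' index; comment (`#`) and blank lines are tolerated.
#'
#' @param path path to the node file.
#' @return A list with `coords` (n x 3 numeric matrix, mm) and `index_base`
#'   (0 or 1).
#' @export
read_node_file <- function(path) {
  tk <- read_tokens(path)
  if (length(tk$tokens) == 0L) parse_err(tk, 1L, "empty node file")
  hdr <- as_num_checked(tk$tokens[[1L]], tk, 1L, "header")
  if (length(hdr) < 2L) parse_err(tk, 1L, "malformed header (need count and dimension)")
  n <- hdr[1L]
  if (n != round(n) || n < 1) parse_err(tk, 1L, "invalid node count in header")
  n <- as.integer(n)
  if (hdr[2L] != 3) parse_err(tk, 1L, "dimension must be 3")
  body <- tk$tokens[-1L]
  if (length(body) != n)
    parse_err(tk, length(tk$tokens) + (length(body) < n),
              sprintf("header declares %d nodes but file contains %d", n,
                      length(body)))
  coords <- matrix(0, n, 3L)
  first_idx <- NA_integer_
  for (i in seq_len(n)) {
    row <- as_num_checked(body[[i]][seq_len(min(4L, length(body[[i]])))],
                          tk, i + 1L, "coordinate")
    if (length(row) < 4L) parse_err(tk, i + 1L, "node line needs index + 3 coordinates")
    if (i == 1L) {
      first_idx <- as.integer(row[1L])
      if (!first_idx %in% c(0L, 1L))
        parse_err(tk, i + 1L, "first node index must be 0 or 1 (index base detection)")
    }
    if (as.integer(row[1L]) != first_idx + i - 1L)
      parse_err(tk, i + 1L, "node indices must be consecutive")
    coords[i, ] <- row[2:4]
  }
  list(coords = coords, index_base = first_idx)
}

#' Read a TetGen-style element file
#'
#' Parses a `.ele` file: header `<m> <nodes_per_tet> <n_attr>` followed by
#' `m` lines `<index> <a> <b> <c> <d> <organ_id>`.  The attribute column is
#' mandatory and carries the organ/material ID.  Node references are
#' normalized to the package's internal 1-based indexing.
#'
#' @param path path to the element file.
#' @param node_count number of nodes parsed from the companion node file.
#' @param index_base index base (0 or 1) detected by [read_node_file()].
#' @return A list with `tets` (m x 4 integer matrix, 1-based) and `organ`
#'   (integer vector).
#' @export
read_ele_file <- function(path, node_count, index_base = 1L) {
  tk <- read_tokens(path)
  if (length(tk$tokens) == 0L) parse_err(tk, 1L, "empty element file")
  hdr <- as_num_checked(tk$tokens[[1L]], tk, 1L, "header")
  if (length(hdr) < 3L || hdr[3L] < 1)
    parse_err(tk, 1L,
              "element file must declare an attribute column (organ IDs are mandatory)")
  m <- hdr[1L]
  if (m != round(m) || m < 1) parse_err(tk, 1L, "invalid element count in header")
  m <- as.integer(m)
  if (hdr[2L] != 4) parse_err(tk, 1L, "only 4-node tetrahedra are supported")
  body <- tk$tokens[-1L]
  if (length(body) != m)
    parse_err(tk, length(tk$tokens) + (length(body) < m),
              sprintf("header declares %d elements but file contains %d", m,
                      length(body)))
  tets <- matrix(0L, m, 4L)
  organ <- integer(m)
  for (i in seq_len(m)) {
    row <- as_num_checked(body[[i]], tk, i + 1L, "element")
    if (length(row) < 6L)
      parse_err(tk, i + 1L, "element line needs index + 4 nodes + organ ID")
    idx <- as.integer(row[2:5]) - as.integer(index_base) + 1L
    if (any(idx < 1L) || any(idx > node_count))
      parse_err(tk, i + 1L,
                sprintf("node reference out of range [%d, %d]",
                        index_base, node_count + index_base - 1L))
    tets[i, ] <- idx
    organ[i] <- as.integer(row[6L])
  }
  list(tets = tets, organ = organ)
}

#' Read a phantom (node + element file pair)
#'
#' @param node_path,ele_path paths to the node and element files.
#' @return A [tet_mesh()].
#' @export
read_phantom <- function(node_path, ele_path) {
  nd <- read_node_file(node_path)
  el <- read_ele_file(ele_path, nrow(nd$coords), nd$index_base)
  tet_mesh(nd$coords, el$tets, el$organ)
}

fmt_coord <- function(x) sprintf("%.17g", x)

#' Write a TetGen-style node file (canonical dialect)
#'
#' Writes with full double precision (`%.17g`), so write-then-read
#' round-trips coordinates exactly and re-writing reproduces the file
#' bit-identically.
#'
#' @param mesh a [tet_mesh()] object.
#' @param path output path.
#' @param index_base 0 or 1 (default 1).
#' @return `path`, invisibly.
#' @export
write_node_file <- function(mesh, path, index_base = 1L) {
  n <- nrow(mesh$nodes)
  lines <- c(sprintf("%d 3 0 0", n),
             sprintf("%d %s %s %s", seq_len(n) - 1L + as.integer(index_base),
                     fmt_coord(mesh$nodes[, 1]), fmt_coord(mesh$nodes[, 2]),
                     fmt_coord(mesh$nodes[, 3])))
  writeLines(lines, path)
  invisible(path)
}

#' Write a TetGen-style element file (canonical dialect)
#'
#' @inheritParams write_node_file
#' @return `path`, invisibly.
#' @export
write_ele_file <- function(mesh, path, index_base = 1L) {
  m <- nrow(mesh$tets)
  b <- as.integer(index_base)
  lines <- c(sprintf("%d 4 1", m),
             sprintf("%d %d %d %d %d %d", seq_len(m) - 1L + b,
                     mesh$tets[, 1] - 1L + b, mesh$tets[, 2] - 1L + b,
                     mesh$tets[, 3] - 1L + b, mesh$tets[, 4] - 1L + b,
                     mesh$organ))
  writeLines(lines, path)
  invisible(path)
}

# ---- material table and contour spec files ----------------------------------

#' Read a material table file
#'
#' Text table with one row per organ: `<organ_id> <name> <density g/cm3>`,
#' whitespace- or comma-separated; `#` comments tolerated.  Multi-token names
#' are joined with spaces.
#'
#' @param path path to the table file.
#' @return A [material_table()].
#' @export
read_material_table <- function(path) {
  tk <- read_tokens(path)
  if (length(tk$tokens) == 0L) parse_err(tk, 1L, "empty material table")
  n <- length(tk$tokens)
  id <- integer(n); nm <- character(n); dens <- numeric(n)
  for (i in seq_len(n)) {
    row <- tk$tokens[[i]]
    if (length(row) < 3L)
      parse_err(tk, i, "material row needs organ_id, name, density")
    id[i] <- as.integer(as_num_checked(row[1L], tk, i, "organ ID"))
    dens[i] <- as_num_checked(row[length(row)], tk, i, "density")
    nm[i] <- paste(row[2:(length(row) - 1L)], collapse = " ")
  }
  if (anyDuplicated(id)) {
    first_dup <- which(duplicated(id))[1L]
    parse_err(tk, first_dup, paste0("duplicate organ ID ", id[first_dup]))
  }
  if (any(dens <= 0)) {
    bad <- which(dens <= 0)[1L]
    parse_err(tk, bad, paste0("non-positive density for organ ", id[bad]))
  }
  material_table(id, nm, dens)
}

#' Write a material table file
#' @param materials a [material_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_material_table <- function(materials, path) {
  writeLines(sprintf("%d %s %s", materials$organ_id,
                     gsub("[[:space:]]+", "_", materials$name),
                     fmt_coord(materials$density)), path)
  invisible(path)
}

#' Read a contour specification file
#'
#' Format: first data line is the organ count; each following line is
#' `<organ_id> <organ_name>`.
#'
#' @param path path to the contour-spec file.
#' @return A [contour_spec()].
#' @export
read_contour_spec <- function(path) {
  tk <- read_tokens(path)
  if (length(tk$tokens) == 0L) parse_err(tk, 1L, "empty contour spec")
  n <- as.integer(as_num_checked(tk$tokens[[1L]][1L], tk, 1L, "organ count"))
  body <- tk$tokens[-1L]
  if (length(body) != n)
    parse_err(tk, 1L, sprintf("organ count %d does not match %d entries",
                              n, length(body)))
  id <- integer(n); nm <- character(n)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) < 2L) parse_err(tk, i + 1L, "entry needs organ_id and name")
    id[i] <- as.integer(as_num_checked(row[1L], tk, i + 1L, "organ ID"))
    nm[i] <- paste(row[-1L], collapse = " ")
  }
  contour_spec(id, nm)
}

#' Write a contour specification file
#' @param spec a [contour_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contour_spec <- function(spec, path) {
  writeLines(c(sprintf("%d", spec$organ_count),
               sprintf("%d %s", spec$organ_id,
                       gsub("[[:space:]]+", "_", spec$name))), path)
  invisible(path)
}

# ---- validation --------------------------------------------------------------

#' Validate a phantom mesh against its material table
#'
#' Report-only check: flags degenerate tetrahedra (volume below tolerance),
#' organ IDs without a material entry, and summarizes per-organ tetrahedron
#' counts and volumes.
#'
#' @param mesh a [tet_mesh()] object.
#' @param materials optional [material_table()].
#' @param vol_tol volume tolerance in mm^3 below which a tet counts as
#'   degenerate.
#' @return A list of class `"mesh_validation"` with `issues` (character),
#'   `degenerate_tets` (integer indices), `orphan_organ_ids` (integer), and
#'   `organ_stats` (data.frame: organ_id, n_tets, volume_mm3).
#' @export
validate_mesh <- function(mesh, materials = NULL, vol_tol = 1e-12) {
  stopifnot(inherits(mesh, "tet_mesh"))
  v <- abs(signed_tet_volumes(mesh$nodes, mesh$tets))
  degen <- which(v <= vol_tol)
  issues <- character(0)
  if (length(degen))
    issues <- c(issues, sprintf("%d degenerate tetrahedra (volume <= %g mm^3)",
                                length(degen), vol_tol))
  orphan <- integer(0)
  if (!is.null(materials)) {
    ids <- mesh_organ_ids(mesh)
    orphan <- setdiff(ids, materials$organ_id)
    if (length(orphan))
      issues <- c(issues, paste0("organ IDs without material entry: ",
                                 paste(orphan, collapse = ", ")))
  }
  stats <- data.frame(
    organ_id = as.integer(names(tapply(v, mesh$organ, sum))),
    n_tets = as.integer(tapply(seq_along(v), mesh$organ, length)),
    volume_mm3 = as.numeric(tapply(v, mesh$organ, sum)),
    row.names = NULL)
  structure(list(issues = issues, degenerate_tets = degen,
                 orphan_organ_ids = as.integer(orphan), organ_stats = stats),
            class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  if (length(x$issues) == 0L) cat("mesh validation: no issues\n")
  else cat("mesh validation issues:\n", paste0("  - ", x$issues, "\n"), sep = "")
  print(x$organ_stats)
  invisible(x)
}
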