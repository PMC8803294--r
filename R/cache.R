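# ---- voxelization cache -----------------------------------------------------
#
# Self-describing binary layout (little endian), version 1:
#   bytes 0-7   magic "PCTCACHE"
#   int32       format version
#   char[16]    mesh content hash (FNV-1a hex)
#   3 x double  grid origin
#   3 x double  grid spacing
#   3 x int32   grid dims
#   double      points_per_mm3
#   double      seed
#   double      tol
#   double      background density
#   n x double  density values (column-major)
#   n x double  claimed volume fractions (column-major)

CACHE_MAGIC <- charToRaw("PCTCACHE")
CACHE_VERSION <- 1L

#' Save a voxelization cache
#'
#' Stores the density grid together with the mesh hash, grid geometry, and
#' sampling policy, so a later conversion of the same phantom can skip the
#' sampling stage entirely and reproduce the grid bit-identically.
#'
#' @param dgrid a `density_grid` from [voxelize_phantom()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_cache <- function(dgrid, path) {
  stopifnot(inherits(dgrid, "density_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CACHE_MAGIC, con)
  writeBin(CACHE_VERSION, con, size = 4L, endian = "little")
  writeBin(charToRaw(dgrid$mesh_hash), con)
  writeBin(as.numeric(dgrid$grid$origin), con, endian = "little")
  writeBin(as.numeric(dgrid$grid$spacing), con, endian = "little")
  writeBin(as.integer(dgrid$grid$dims), con, size = 4L, endian = "little")
  writeBin(c(dgrid$policy$points_per_mm3, dgrid$policy$seed,
             dgrid$policy$tol, dgrid$background), con, endian = "little")
  writeBin(as.vector(dgrid$density), con, endian = "little")
  writeBin(as.vector(dgrid$wsum), con, endian = "little")
  invisible(path)
}

#' Load a voxelization cache
#'
#' Refuses to load (with an explanation) when the cached metadata does not
#' match the expected mesh, grid, or sampling policy — a stale cache must
#' never silently stand in for a fresh voxelization.
#'
#' @param path cache file path.
#' @param mesh the [tet_mesh()] the cache must correspond to (checked by
#'   content hash); NULL skips the check.
#' @param grid expected [voxel_grid()]; NULL skips the check.
#' @param policy expected [sampling_policy()]; NULL skips the check.
#' @param background expected background density; NULL skips the check.
#' @return A `density_grid`, identical to the one that was saved.
#' @export
load_cache <- function(path, mesh = NULL, grid = NULL, policy = NULL,
                       background = NULL) {
  if (!file.exists(path)) stop("cache file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic, CACHE_MAGIC)) stop("not a voxelization cache: ", path)
  ver <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (ver != CACHE_VERSION)
    stop("unsupported cache version ", ver, " (expected ", CACHE_VERSION, ")")
  hash <- rawToChar(readBin(con, "raw", 16L))
  origin <- readBin(con, "double", 3L, endian = "little")
  spacing <- readBin(con, "double", 3L, endian = "little")
  dims <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  pars <- readBin(con, "double", 4L, endian = "little")
  n <- prod(dims)
  density <- array(readBin(con, "double", n, endian = "little"), dims)
  wsum <- array(readBin(con, "double", n, endian = "little"), dims)

  mismatch <- character(0)
  if (!is.null(mesh) && mesh_hash(mesh) != hash)
    mismatch <- c(mismatch, "mesh content hash differs (phantom changed)")
  if (!is.null(grid)) {
    if (!isTRUE(all.equal(grid$origin, origin)) ||
        !isTRUE(all.equal(grid$spacing, spacing)) ||
        !identical(as.integer(grid$dims), dims))
      mismatch <- c(mismatch, "grid geometry differs (FOV/resolution/slice thickness)")
  }
  if (!is.null(policy)) {
    if (policy$points_per_mm3 != pars[1] || policy$seed != pars[2] ||
        policy$tol != pars[3])
      mismatch <- c(mismatch, "sampling policy differs")
  }
  if (!is.null(background) && background != pars[4])
    mismatch <- c(mismatch, "background density differs")
  if (length(mismatch))
    stop("stale voxelization cache, refusing to reuse it:\n  - ",
         paste(mismatch, collapse = "\n  - "),
         "\nDelete the cache file or rerun with matching settings.")

  new_density_grid(voxel_grid(origin, spacing, dims), density, wsum,
                   sampling_policy(pars[1], pars[2], pars[3]), pars[4], hash)
}
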