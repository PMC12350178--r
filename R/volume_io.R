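# TIFF volume I/O and feature-table serialization.
#
# Volumes are plain numeric 3D arrays with dim = c(z, y, x) plus a voxel size
# in micrometres. Multi-channel stacks are stored plane-interleaved
# (ch1 z1, ch2 z1, ch1 z2, ...), the layout the usual microscope exports use.

#' Describe the geometry of a volume
#'
#' @param shape integer vector `c(z, y, x)` in voxels.
#' @param voxel_size isotropic voxel edge length in micrometres
#'   (default 0.3, the acquisition setting the canaliculi pipeline expects).
#' @param channels named channel roles, e.g. `c(apical = 1, cortical = 2)`.
#' @return An object of class `volume_spec`.
#' @export
volume_spec <- function(shape, voxel_size = 0.3,
                        channels = c(apical = 1L, cortical = 2L)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("'shape' must be three positive integers (z, y, x)")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("'voxel_size' must be a single positive number (um)")
  }
  structure(list(shape = shape, voxel_size = voxel_size, channels = channels),
            class = "volume_spec")
}

#' Read a multi-page TIFF stack into per-channel 3D arrays
#'
#' @param path TIFF file with one grayscale page per (channel, z) pair,
#'   plane-interleaved when `channels > 1`.
#' @param channels number of interleaved channels (default 1).
#' @param voxel_size voxel edge length in micrometres (default 0.3).
#' @return A list with `channels` (list of arrays, dim `c(z, y, x)`) and
#'   `voxel_size`. Single-channel reads still return a one-element list.
#' @export
read_volume <- function(path, channels = 1L, voxel_size = 0.3) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) stop("corrupt stack: no pages in ", path)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("corrupt stack: page size varies across z in ", path)
  }
  channels <- as.integer(channels)
  if (length(pages) %% channels != 0L) {
    stop("page count ", length(pages), " is not a multiple of ", channels,
         " channels")
  }
  nz <- length(pages) %/% channels
  ny <- dims[1L, 1L]; nx <- dims[2L, 1L]
  out <- vector("list", channels)
  for (ch in seq_len(channels)) {
    arr <- array(0, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) {
      arr[z, , ] <- pages[[(z - 1L) * channels + ch]]
    }
    out[[ch]] <- arr
  }
  list(channels = out, voxel_size = voxel_size)
}

#' Write one or more 3D arrays as a multi-page TIFF stack
#'
#' Integer-valued volumes round-trip losslessly through [read_volume()].
#'
#' @param vols a single array (dim `c(z, y, x)`) or list of equally shaped
#'   arrays, one per channel; values must lie in `[0, 2^bits - 1]`.
#' @param path output path.
#' @param bits bits per sample, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vols, path, bits = 16L) {
  if (!is.list(vols)) vols <- list(vols)
  if (!bits %in% c(8L, 16L)) stop("'bits' must be 8 or 16")
  shp <- dim(vols[[1L]])
  if (length(shp) != 3L) stop("volumes must be 3D arrays with dim (z, y, x)")
  for (v in vols) {
    if (!identical(dim(v), shp)) stop("all channels must share one shape")
  }
  maxval <- 2^bits - 1
  rng <- range(vapply(vols, range, numeric(2L)))
  if (rng[1L] < 0 || rng[2L] > maxval) {
    stop(sprintf("values outside [0, %d]; rescale before writing", maxval))
  }
  pages <- vector("list", shp[1L] * length(vols))
  k <- 0L
  for (z in seq_len(shp[1L])) {
    for (ch in seq_along(vols)) {
      k <- k + 1L
      pages[[k]] <- vols[[ch]][z, , ] / maxval
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Write a network feature table (plus per-branch sidecar) to CSV
#'
#' Scalar features go to `path`; the list-valued per-branch diameters are
#' flattened into a long-format sidecar CSV (`*_branches.csv`) keyed by
#' structure id.
#'
#' @param table data frame with one row per structure; an optional
#'   `branch_diameters_um` list-column holds per-branch mean diameters.
#' @param path output CSV path.
#' @return Named character vector of the files written, invisibly.
#' @export
write_features <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("'table' must be a nonempty data frame")
  }
  branch_col <- table[["branch_diameters_um"]]
  flat <- table[setdiff(names(table), "branch_diameters_um")]
  write.csv(flat, path, row.names = FALSE)
  files <- c(features = path)
  if (!is.null(branch_col)) {
    side <- sub("(\\.[^.]+)?$", "_branches.csv", path)
    ids <- rep(table$structure_id, lengths(branch_col))
    long <- data.frame(structure_id = ids,
                       branch = unlist(lapply(lengths(branch_col), seq_len)),
                       diameter_um = unlist(branch_col))
    write.csv(long, side, row.names = FALSE)
    files <- c(files, branches = side)
  }
  invisible(files)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV path given to [write_features()].
#' @return Data frame with the `branch_diameters_um` list-column restored when
#'   the sidecar file exists.
#' @export
read_features <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  side <- sub("(\\.[^.]+)?$", "_branches.csv", path)
  if (file.exists(side)) {
    long <- read.csv(side, stringsAsFactors = FALSE)
    tab$branch_diameters_um <- lapply(tab$structure_id, function(id) {
      long$diameter_um[long$structure_id == id]
    })
  }
  tab
}
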