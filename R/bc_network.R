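# 3D bile-canaliculi segmentation and skeleton-network feature extraction.
#
# Stage order (the published pipeline): median smoothing of both channels ->
# independent thresholding -> voxelwise overlap (apical patches) -> lumen
# completion (inflate, fill holes, deflate) -> size/border object filtering ->
# local thickness + skeletonization -> network graph features.

as_mask3d <- function(mask) {
  if (length(dim(mask)) != 3L) stop("expected a 3D array (z, y, x)")
  storage.mode(mask) <- "logical"
  mask
}

#' Configuration of the bile-canaliculi pipeline
#'
#' @param median_radius median filter radius in voxels (default 1, i.e. a
#'   3x3x3 window).
#' @param inflate,deflate numbers of 6-connected dilation/erosion iterations
#'   around the fill-holes step (defaults 3 and 3).
#' @param min_size_vox minimum object size in voxels (default 500, about
#'   13.5 um^3 at 0.3 um voxels).
#' @param border_policy which faces disqualify touching objects:
#'   `"all"` (default) or `"xy"` (lateral faces only, for thin stacks).
#' @param threshold_apical,threshold_cortical thresholding method per channel;
#'   currently `"isodata"`.
#' @param prune_spurs_um terminal (endpoint) branches shorter than this are
#'   pruned before network features are measured (default 3, just above the
#'   canaliculus diameter scale: shorter terminal stubs are thinning
#'   artefacts of rounded tube ends, not resolvable side branches).
#' @param merge_junction_um junction clusters connected by a branch shorter
#'   than this merge into a single junction node (default 1; well below the
#'   ~3 um scale at which distinct canaliculi junctions are resolvable).
#' @return An object of class `bc_config`.
#' @export
bc_config <- function(median_radius = 1L, inflate = 3L, deflate = 3L,
                      min_size_vox = 500L, border_policy = c("all", "xy"),
                      threshold_apical = "isodata",
                      threshold_cortical = "isodata",
                      prune_spurs_um = 3, merge_junction_um = 1) {
  border_policy <- match.arg(border_policy)
  stopifnot(median_radius >= 0, inflate >= 0, deflate >= 0, min_size_vox >= 0,
            prune_spurs_um >= 0, merge_junction_um >= 0)
  structure(list(median_radius = as.integer(median_radius),
                 inflate = as.integer(inflate), deflate = as.integer(deflate),
                 min_size_vox = as.integer(min_size_vox),
                 border_policy = border_policy,
                 threshold_apical = threshold_apical,
                 threshold_cortical = threshold_cortical,
                 prune_spurs_um = prune_spurs_um,
                 merge_junction_um = merge_junction_um),
            class = "bc_config")
}

#' 3D median filter
#'
#' Median over the `(2r+1)^3` neighborhood with edge reflection; radius 0 is
#' the identity.
#'
#' @param vol numeric 3D array (z, y, x).
#' @param radius non-negative integer radius in voxels.
#' @return Filtered array of the same shape.
#' @export
median_filter_3d <- function(vol, radius = 1L) {
  if (length(dim(vol)) != 3L) stop("expected a 3D array (z, y, x)")
  if (radius < 0) stop("'radius' must be >= 0")
  out <- cpp_median3d(as.numeric(vol), dim(vol), as.integer(radius))
  array(out, dim(vol))
}

#' IsoData (intermeans) threshold
#'
#' The iterative intermeans scheme behind the image software's default
#' automatic threshold: starting from the global mean, the threshold is
#' repeatedly replaced by the average of the mean intensity below and the mean
#' intensity above it, until it stabilizes on the integer histogram. The mask
#' selects intensities strictly above the converged threshold.
#'
#' @param vol numeric array (any dimension) of integer-valued intensities.
#' @return List with `threshold` (numeric) and `mask` (logical array).
#' @export
isodata_threshold <- function(vol) {
  v <- as.numeric(vol)
  if (diff(range(v)) == 0) {
    stop("degenerate histogram: volume is constant, cannot threshold")
  }
  vi <- round(v)
  off <- min(vi)
  h <- tabulate(vi - off + 1L, max(vi) - off + 1L)
  lev <- seq_along(h) - 1 + off
  t_cur <- sum(h * lev) / sum(h)
  repeat {
    lo <- lev <= t_cur
    m0 <- sum(h[lo] * lev[lo]) / sum(h[lo])
    m1 <- sum(h[!lo] * lev[!lo]) / sum(h[!lo])
    t_new <- (m0 + m1) / 2
    if (!is.finite(t_new) || abs(t_new - t_cur) < 0.5) break
    t_cur <- t_new
  }
  mask <- array(vol > t_cur, dim(vol))
  list(threshold = t_cur, mask = mask)
}

#' Voxelwise overlap of two segmentation masks
#'
#' The intersection of the apical-marker and cortical-actin segmentations
#' identifies the apical patches the lumen completion starts from.
#'
#' @param mask_apical,mask_cortical logical 3D arrays of equal shape.
#' @return Logical array, the voxelwise AND.
#' @export
apical_overlap <- function(mask_apical, mask_cortical) {
  if (!identical(dim(mask_apical), dim(mask_cortical))) {
    stop("mask shapes differ")
  }
  mask_apical & mask_cortical
}

#' Fill enclosed cavities of a binary volume
#'
#' Background voxels not 6-connected to the volume border are turned on.
#'
#' @param mask logical 3D array.
#' @return Logical array.
#' @export
fill_holes_3d <- function(mask) {
  mask <- as_mask3d(mask)
  reach <- array(cpp_background_reach6(mask, dim(mask)), dim(mask))
  mask | !reach
}

#' Complete apical patches into solid lumina
#'
#' Dilates `inflate` times (6-connected unit ball), fills enclosed cavities,
#' then erodes `deflate` times. With `inflate = deflate` the output contains
#' the plain fill-holes result.
#'
#' @param mask logical 3D array of apical patches.
#' @param cfg a [bc_config()].
#' @return Logical array of completed lumina.
#' @export
complete_lumina <- function(mask, cfg = bc_config()) {
  mask <- as_mask3d(mask)
  d <- dim(mask)
  m <- mask
  if (cfg$inflate > 0) {
    m <- array(cpp_morph6(m, d, cfg$inflate, TRUE), d)
  }
  m <- fill_holes_3d(m)
  if (cfg$deflate > 0) {
    m <- array(cpp_morph6(m, d, cfg$deflate, FALSE), d)
  }
  m
}

#' Remove small objects and objects touching the volume border
#'
#' Components are 26-connected. The size threshold is applied first, then the
#' border rule; an object failing both is reported under the size count.
#'
#' @param mask logical 3D array.
#' @param cfg a [bc_config()]; uses `min_size_vox` and `border_policy`.
#' @return List with `mask` (filtered array) and `report`
#'   (`removed_size`, `removed_border`, `kept`).
#' @export
filter_objects <- function(mask, cfg = bc_config()) {
  mask <- as_mask3d(mask)
  d <- dim(mask)
  lab <- array(cpp_label3d(mask, d, 26L), d)
  nlab <- max(lab)
  if (nlab == 0L) {
    return(list(mask = mask,
                report = list(removed_size = 0L, removed_border = 0L,
                              kept = 0L)))
  }
  sizes <- tabulate(lab[lab > 0L], nlab)
  small <- sizes < cfg$min_size_vox
  border_ids <- integer(0L)
  faces <- if (cfg$border_policy == "all") {
    list(lab[1L, , ], lab[d[1L], , ], lab[, 1L, ], lab[, d[2L], ],
         lab[, , 1L], lab[, , d[3L]])
  } else {
    list(lab[, 1L, ], lab[, d[2L], ], lab[, , 1L], lab[, , d[3L]])
  }
  border_ids <- unique(unlist(lapply(faces, function(f) f[f > 0L])))
  on_border <- seq_len(nlab) %in% border_ids
  removed_size <- which(small)
  removed_border <- setdiff(which(on_border), removed_size)
  keep <- setdiff(seq_len(nlab), c(removed_size, removed_border))
  out <- array(lab %in% keep, d)
  list(mask = out,
       report = list(removed_size = length(removed_size),
                     removed_border = length(removed_border),
                     kept = length(keep)))
}

#' Local thickness map
#'
#' Per foreground voxel, the diameter of the largest inscribed sphere that
#' contains the voxel (Hildebrand-Ruegsegger), computed by painting the
#' maximal distance-transform spheres. Zero on background.
#'
#' @param mask logical 3D array.
#' @param voxel_size voxel edge length in micrometres.
#' @return Numeric array of diameters in micrometres.
#' @export
local_thickness <- function(mask, voxel_size = 0.3) {
  mask <- as_mask3d(mask)
  array(cpp_local_thickness(mask, dim(mask)) * voxel_size, dim(mask))
}

#' Curve skeleton of a binary volume
#'
#' Homotopy-preserving sequential thinning: simple border points (in the
#' Bertrand-Malandain sense) that are not curve endpoints are deleted in
#' order of increasing distance from the background until no deletion is
#' possible. The skeleton is a subset of the mask and preserves the number of
#' 26-connected components.
#'
#' @param mask logical 3D array.
#' @return Logical array of skeleton voxels.
#' @export
skeletonize_3d <- function(mask) {
  mask <- as_mask3d(mask)
  array(cpp_skeletonize3d(mask, dim(mask)), dim(mask))
}
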