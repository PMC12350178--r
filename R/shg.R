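# Fibrillar-collagen quantification from second-harmonic-generation images:
# maximum projection, band threshold, ROI restriction, integrated density.

#' Maximum-intensity projection along z
#'
#' @param vol numeric 3D array (z, y, x) with at least one plane.
#' @return Numeric matrix (y, x), the per-pixel maximum over z.
#' @export
max_project <- function(vol) {
  d <- dim(vol)
  if (length(d) != 3L || d[1L] < 1L) {
    stop("expected a 3D array (z, y, x) with >= 1 plane")
  }
  out <- vol[1L, , ]
  if (d[1L] > 1L) {
    for (z in 2:d[1L]) out <- pmax(out, vol[z, , ])
  }
  out
}

#' Band threshold mask
#'
#' Selects pixels with `lo <= value <= hi`, both ends inclusive (the image
#' software's min/max threshold convention; defaults 60 and 110, the SHG
#' segmentation band).
#'
#' @param img numeric matrix.
#' @param lo,hi band limits, `lo <= hi`.
#' @return Logical matrix.
#' @export
band_threshold_mask <- function(img, lo = 60, hi = 110) {
  if (lo > hi) stop("'lo' must not exceed 'hi'")
  img >= lo & img <= hi
}

#' Integrated density over a masked selection
#'
#' The selection is the conjunction of the threshold mask and (optionally)
#' the interior of an ROI polygon, pixels included when their centre lies
#' inside by the even-odd rule. Reports `RawIntDen` (sum of pixel values in
#' the selection) and `IntDen` (area times mean grey value); with area
#' counted in pixels the two coincide.
#'
#' @param img numeric matrix (row = y, column = x).
#' @param mask logical matrix, same shape as `img`; use
#'   [band_threshold_mask()] for the standard band selection.
#' @param roi optional [polygon_outline()] in pixel coordinates (x right,
#'   y down, origin at the top-left pixel corner).
#' @param pixel_size physical pixel edge in micrometres (for `area_um2`).
#' @return An object of class `shg_result`: `area_px`, `area_um2`, `mean`,
#'   `raw_int_den`, `int_den`. An empty selection gives zeros with a warning.
#' @export
integrated_density <- function(img, mask = NULL, roi = NULL, pixel_size = 1) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (!identical(dim(img), dim(mask))) stop("mask shape differs from image")
  sel <- mask
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "polygon_outline"))
    v <- roi$vertices
    if (min(v[, 1L]) < 0 || min(v[, 2L]) < 0 ||
        max(v[, 1L]) > ncol(img) || max(v[, 2L]) > nrow(img)) {
      stop("ROI polygon extends outside the image")
    }
    px <- rep(seq_len(ncol(img)) - 0.5, each = nrow(img))
    py <- rep(seq_len(nrow(img)) - 0.5, times = ncol(img))
    inside <- matrix(points_in_polygon(px, py, v), nrow(img), ncol(img))
    sel <- sel & inside
  }
  n <- sum(sel)
  if (n == 0L) {
    warning("empty selection; integrated density is zero")
    return(structure(list(area_px = 0L, area_um2 = 0, mean = 0,
                          raw_int_den = 0, int_den = 0),
                     class = "shg_result"))
  }
  vals <- img[sel]
  m <- mean(vals)
  structure(list(area_px = n, area_um2 = n * pixel_size^2, mean = m,
                 raw_int_den = sum(vals), int_den = n * m),
            class = "shg_result")
}

#' @export
print.shg_result <- function(x, ...) {
  cat(sprintf(
    "shg_result: area %d px (%.1f um^2), mean %.2f, RawIntDen %.1f, IntDen %.1f\n",
    x$area_px, x$area_um2, x$mean, x$raw_int_den, x$int_den))
  invisible(x)
}
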