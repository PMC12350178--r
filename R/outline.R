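# Closed 2D organoid outlines in physical coordinates.
#
# Coordinate convention: image coordinates (x rightward, y downward). A polygon
# traced clockwise on screen has positive shoelace area under this convention,
# matching the Fiji polygon-selection export the loaders target. All stored
# outlines are normalized to that orientation.

#' Construct a closed polygon outline
#'
#' Creates the outline object used throughout the shape pipeline: an ordered,
#' closed vertex loop in physical micrometres, normalized to the clockwise
#' (image-convention, positive signed area) orientation.
#'
#' @param vertices two-column numeric matrix of (x, y) vertex coordinates in
#'   micrometres, one row per vertex, without a repeated closing vertex
#'   (a duplicated closing vertex is dropped silently).
#' @param label free-text identifier of the organoid/frame.
#' @param time_h optional acquisition time in hours.
#' @return An object of class `polygon_outline` with elements `vertices`
#'   (normalized matrix), `label`, `time_h`, `closed = TRUE` and
#'   `orientation = "clockwise"`.
#' @examples
#' sq <- polygon_outline(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' outline_area(sq)
#' @export
polygon_outline <- function(vertices, label = "outline", time_h = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || !is.numeric(vertices)) {
    stop("'vertices' must be a numeric matrix with two columns (x, y)")
  }
  if (anyNA(vertices)) stop("outline vertices contain missing values")
  n <- nrow(vertices)
  # drop explicit closing vertex
  if (n > 1L && all(vertices[1L, ] == vertices[n, ])) {
    vertices <- vertices[-n, , drop = FALSE]
    n <- n - 1L
  }
  # drop consecutive duplicates
  if (n > 1L) {
    keep <- c(TRUE, rowSums(abs(diff(vertices))) > 0)
    vertices <- vertices[keep, , drop = FALSE]
    n <- nrow(vertices)
  }
  if (n < 3L) stop("malformed outline: fewer than 3 distinct vertices")
  a <- signed_area(vertices)
  if (a == 0) stop("malformed outline: zero signed area (degenerate polygon)")
  if (a < 0) vertices <- vertices[n:1L, , drop = FALSE]
  structure(
    list(vertices = vertices, label = label, time_h = time_h,
         closed = TRUE, orientation = "clockwise"),
    class = "polygon_outline"
  )
}

# shoelace signed area; positive = clockwise under the image convention
signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Enclosed area of an outline
#' @param poly a [polygon_outline()].
#' @return Area in square micrometres (non-negative).
#' @export
outline_area <- function(poly) {
  stopifnot(inherits(poly, "polygon_outline"))
  abs(signed_area(poly$vertices))
}

#' Perimeter of an outline
#' @param poly a [polygon_outline()].
#' @return Perimeter in micrometres.
#' @export
outline_perimeter <- function(poly) {
  stopifnot(inherits(poly, "polygon_outline"))
  v <- poly$vertices
  d <- diff(rbind(v, v[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Area centroid of an outline
#' @param poly a [polygon_outline()].
#' @return Numeric length-2 vector (x, y) in micrometres.
#' @export
outline_centroid <- function(poly) {
  stopifnot(inherits(poly, "polygon_outline"))
  v <- poly$vertices
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' @export
print.polygon_outline <- function(x, ...) {
  cat(sprintf("polygon_outline '%s': %d vertices, area %.2f um^2%s\n",
              x$label, nrow(x$vertices), outline_area(x),
              if (!is.null(x$time_h)) sprintf(", t = %g h", x$time_h) else ""))
  invisible(x)
}

#' Read a Fiji-style xy-coordinate outline file
#'
#' Parses the plain-text format written by the image software's
#' "save xy coordinates" command: one vertex per line, two whitespace- or
#' tab-separated numeric fields (x then y). Blank lines are ignored. The
#' loaded polygon is closed, deduplicated, and normalized to the clockwise
#' orientation (a counter-clockwise file is reversed with a warning).
#'
#' @param path path to the text file.
#' @param scale physical size of one coordinate unit in micrometres
#'   (default 1; the export format does not record a unit).
#' @param label identifier; defaults to the file name.
#' @param time_h optional acquisition time in hours.
#' @return A [polygon_outline()].
#' @export
read_outline_txt <- function(path, scale = 1, label = NULL, time_h = NULL) {
  if (!file.exists(path)) stop("outline file not found: ", path)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("'scale' must be a single positive number (um per coordinate unit)")
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  coords <- matrix(NA_real_, length(nonblank), 2L)
  for (i in seq_along(nonblank)) {
    ln <- nonblank[i]
    tok <- strsplit(trimws(lines[ln]), "[\\s,]+", perl = TRUE)[[1L]]
    if (length(tok) != 2L) {
      stop(sprintf("parse error in '%s' line %d: expected two numeric fields",
                   path, ln))
    }
    val <- suppressWarnings(as.numeric(tok))
    if (anyNA(val)) {
      stop(sprintf("parse error in '%s' line %d: non-numeric token", path, ln))
    }
    coords[i, ] <- val
  }
  if (nrow(coords) < 3L) {
    stop("malformed outline: fewer than 3 distinct vertices in ", path)
  }
  v <- coords * scale
  # orientation check before normalization, so the reversal can be reported
  vv <- v
  n <- nrow(vv)
  if (n > 1L && all(vv[1L, ] == vv[n, ])) vv <- vv[-n, , drop = FALSE]
  if (nrow(vv) >= 3L && signed_area(vv) < 0) {
    warning("outline '", label,
            "' was counter-clockwise; vertex order reversed")
  }
  polygon_outline(v, label = label, time_h = time_h)
}

#' Write an outline to the xy-coordinate text format
#'
#' @param poly a [polygon_outline()].
#' @param path output file path.
#' @param scale micrometres per coordinate unit used on write (default 1).
#' @return `path`, invisibly.
#' @export
write_outline_txt <- function(poly, path, scale = 1) {
  stopifnot(inherits(poly, "polygon_outline"))
  v <- poly$vertices / scale
  writeLines(sprintf("%.6f\t%.6f", v[, 1L], v[, 2L]), path)
  invisible(path)
}
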