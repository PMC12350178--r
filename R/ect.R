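# Directional Euler characteristic curves and the smooth Euler characteristic
# transform (SECT) of a closed 2D outline.
#
# Two discretizations are provided:
#   * "vertex"  — exact piecewise-linear sublevel filtration on an ear-clipping
#     triangulation of the polygon itself (max-vertex / lower-star rule). The
#     Euler curve of a sublevel set is triangulation-independent, so this path
#     is resolution-free and exactly equivariant under rotations that map the
#     direction set onto itself. It is the default used by the descriptor
#     pipeline.
#   * "raster"  — cubical complex on a pixel raster (pixels are 2-cells with
#     their edges and vertices; a cell enters the filtration at the height of
#     its highest vertex). Useful when the input is a mask rather than a
#     polygon, and as an independent cross-check of the vertex path.

#' Raster window specification
#'
#' The window is a square of physical half-width `R` micrometres centred on
#' the shape centroid, sampled at `N` x `N` pixels.
#'
#' @param R half-width of the window in micrometres (> 0).
#' @param N raster resolution in pixels per side (>= 16).
#' @return An object of class `grid_spec` with fields `R`, `N` and the derived
#'   pixel `pitch = 2 R / N`.
#' @export
grid_spec <- function(R, N = 256L) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0) stop("'R' must be > 0")
  N <- as.integer(N)
  if (is.na(N) || N < 16L) stop("'N' must be an integer >= 16")
  structure(list(R = R, N = N, pitch = 2 * R / N), class = "grid_spec")
}

# default window: shape must fit strictly inside the inscribed disc so that
# every directional height lies within [-R, R]
default_grid <- function(poly, expand = 1.25, N = 256L) {
  v <- center_vertices(poly)
  grid_spec(expand * max(sqrt(rowSums(v^2))), N)
}

center_vertices <- function(poly) {
  stopifnot(inherits(poly, "polygon_outline"))
  sweep(poly$vertices, 2L, outline_centroid(poly))
}

# proper self-intersection test between non-adjacent edges, O(n^2)
is_simple_polygon <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  for (i in seq_len(n - 2L)) {
    j <- setdiff((i + 2L):n, if (i == 1L) n else integer(0L))
    if (length(j) == 0L) next
    d1 <- cross2(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], a[j, 1L], a[j, 2L])
    d2 <- cross2(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], b[j, 1L], b[j, 2L])
    d3 <- cross2(a[j, 1L], a[j, 2L], b[j, 1L], b[j, 2L], a[i, 1L], a[i, 2L])
    d4 <- cross2(a[j, 1L], a[j, 2L], b[j, 1L], b[j, 2L], b[i, 1L], b[i, 2L])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

# even-odd point-in-polygon for many query points (px, py)
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize an outline to a binary mask
#'
#' A pixel is on iff its centre lies inside the polygon (even-odd rule). The
#' window is centred on the polygon's area centroid.
#'
#' @param poly a [polygon_outline()]; must be simple (non-self-intersecting).
#' @param grid a [grid_spec()]; the shape must fit strictly inside the window.
#' @return `N` x `N` logical matrix (row = y, column = x).
#' @export
rasterize_polygon <- function(poly, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is_simple_polygon(poly$vertices)) {
    stop("geometry error: polygon self-intersects")
  }
  v <- center_vertices(poly)
  if (max(abs(v)) >= grid$R) {
    stop("shape clipped by the raster window; increase R")
  }
  ax <- -grid$R + (seq_len(grid$N) - 0.5) * grid$pitch
  px <- rep(ax, each = grid$N)   # column-major: row index = y, col = x
  py <- rep(ax, times = grid$N)
  matrix(points_in_polygon(px, py, v), grid$N, grid$N)
}

# cell-presence grids of the cubical complex induced by a mask:
# V: (N+1)x(M+1) vertices, EH: (N+1)xM horizontal edges (between vertices in
# one vertex row), EV: Nx(M+1) vertical edges, faces = mask itself
mask_complex <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  P <- matrix(FALSE, n + 2L, m + 2L)
  P[2:(n + 1L), 2:(m + 1L)] <- mask
  V <- P[1:(n + 1L), 1:(m + 1L)] | P[1:(n + 1L), 2:(m + 2L)] |
    P[2:(n + 2L), 1:(m + 1L)] | P[2:(n + 2L), 2:(m + 2L)]
  EH <- P[1:(n + 1L), 2:(m + 1L)] | P[2:(n + 2L), 2:(m + 1L)]
  EV <- P[2:(n + 1L), 1:(m + 1L)] | P[2:(n + 1L), 2:(m + 2L)]
  list(V = V, EH = EH, EV = EV)
}

#' Euler characteristic of a binary mask
#'
#' Computes V - E + F on the cubical complex whose 2-cells are the on-pixels
#' (closed unit squares). This equals the number of 8-connected foreground
#' components minus the number of enclosed (4-connected) background holes.
#'
#' @param mask logical matrix; an empty mask gives 0.
#' @return Integer Euler characteristic.
#' @examples
#' euler_characteristic(matrix(TRUE, 3, 3))           # disc: 1
#' m <- matrix(TRUE, 3, 3); m[2, 2] <- FALSE
#' euler_characteristic(m)                            # annulus: 0
#' @export
euler_characteristic <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  cx <- mask_complex(mask)
  as.integer(sum(cx$V) - sum(cx$EH) - sum(cx$EV) + sum(mask))
}

# cumulative count of cells entering the filtration, sampled at `thresholds`
bin_cells <- function(h, thresholds) {
  idx <- findInterval(h - 1e-9, thresholds) + 1L
  cumsum(tabulate(idx[idx <= length(thresholds)], length(thresholds)))
}

#' Directional Euler characteristic curve of a mask
#'
#' `curve[t]` is the Euler characteristic of the sub-complex of cells whose
#' highest vertex has height `<x, direction> <= thresholds[t]` — the sublevel
#' filtration in the given direction, accumulated in a single sorted sweep.
#' The final value equals [euler_characteristic()] of the mask provided the
#' shape lies within the inscribed disc of the window.
#'
#' @param mask `N` x `N` logical matrix from [rasterize_polygon()].
#' @param grid the [grid_spec()] used to rasterize.
#' @param direction length-2 unit vector (checked to 1e-12).
#' @param thresholds increasing heights, typically `seq(-R, R, length.out = T)`.
#' @return Integer vector of length `length(thresholds)`.
#' @export
ecc_directional <- function(mask, grid, direction, thresholds) {
  stopifnot(inherits(grid, "grid_spec"))
  if (abs(sum(direction^2) - 1) > 1e-12) {
    stop("'direction' must be a unit vector")
  }
  n <- nrow(mask); m <- ncol(mask)
  xv <- -grid$R + (seq_len(m + 1L) - 1L) * grid$pitch
  yv <- -grid$R + (seq_len(n + 1L) - 1L) * grid$pitch
  Hv <- outer(yv * direction[2L], xv * direction[1L], "+")
  cx <- mask_complex(mask)
  hv <- Hv[cx$V]
  heh <- pmax(Hv[, 1:m, drop = FALSE], Hv[, 2:(m + 1L), drop = FALSE])[cx$EH]
  hev <- pmax(Hv[1:n, , drop = FALSE], Hv[2:(n + 1L), , drop = FALSE])[cx$EV]
  hf <- pmax(Hv[1:n, 1:m], Hv[1:n, 2:(m + 1L)],
             Hv[2:(n + 1L), 1:m], Hv[2:(n + 1L), 2:(m + 1L)])[mask]
  as.integer(bin_cells(hv, thresholds) - bin_cells(heh, thresholds) -
               bin_cells(hev, thresholds) + bin_cells(hf, thresholds))
}

# ear-clipping triangulation of a positively oriented simple polygon;
# returns index triples into the vertex matrix
triangulate_polygon <- function(v) {
  n <- nrow(v)
  idx <- seq_len(n)
  tri <- matrix(0L, n - 2L, 3L)
  k <- 0L
  cross_at <- function(i0, i1, i2) {
    (v[i1, 1L] - v[i0, 1L]) * (v[i2, 2L] - v[i0, 2L]) -
      (v[i1, 2L] - v[i0, 2L]) * (v[i2, 1L] - v[i0, 1L])
  }
  while (length(idx) > 3L) {
    m <- length(idx)
    found <- FALSE
    for (j in seq_len(m)) {
      i0 <- idx[if (j == 1L) m else j - 1L]
      i1 <- idx[j]
      i2 <- idx[if (j == m) 1L else j + 1L]
      cr <- cross_at(i0, i1, i2)
      if (cr <= 0) next  # reflex or collinear corner: not an ear
      others <- setdiff(idx, c(i0, i1, i2))
      if (length(others)) {
        # strict point-in-triangle (barycentric sign test)
        d1 <- cross_at(i0, i1, others)
        d2 <- vapply(others, function(p) cross_at(i1, i2, p), 0)
        d3 <- vapply(others, function(p) cross_at(i2, i0, p), 0)
        eps <- 1e-12 * abs(cr)
        if (any(d1 > eps & d2 > eps & d3 > eps)) next
      }
      k <- k + 1L
      tri[k, ] <- c(i0, i1, i2)
      idx <- idx[-j]
      found <- TRUE
      break
    }
    if (!found) stop("triangulation failed; is the outline self-intersecting?")
  }
  k <- k + 1L
  tri[k, ] <- idx
  tri
}

#' Euler characteristic transform of an outline
#'
#' Computes the matrix of directional Euler characteristic curves: row `d` is
#' the sublevel-filtration Euler curve in direction `2*pi*(d-1)/D`, sampled at
#' `T` thresholds uniformly spanning `[-R, R]`. The default `"vertex"` method
#' evaluates the curves exactly on a triangulation of the polygon; the
#' `"raster"` method uses the cubical complex of the rasterized mask.
#'
#' @param poly a [polygon_outline()].
#' @param grid a [grid_spec()]; when `NULL`, `R` defaults to 1.25 times the
#'   maximal centroid-to-vertex distance and `N = 256`. When comparing frames
#'   of a time series pass a shared grid so that size change is preserved.
#' @param directions number of directions `D` (>= 8; default 72).
#' @param thresholds number of thresholds `T` (>= 32; default 128).
#' @param method `"vertex"` (exact, default) or `"raster"`.
#' @return An object of class `ect_matrix`: integer matrix `chi` (`D` x `T`),
#'   `angles`, `thresholds`, `R`, `N`, `method`, `label`.
#' @export
ect <- function(poly, grid = NULL, directions = 72L, thresholds = 128L,
                method = c("vertex", "raster")) {
  method <- match.arg(method)
  D <- as.integer(directions); Tn <- as.integer(thresholds)
  if (D < 8L) stop("'directions' must be >= 8")
  if (Tn < 32L) stop("'thresholds' must be >= 32")
  if (is.null(grid)) grid <- default_grid(poly)
  stopifnot(inherits(grid, "grid_spec"))
  angles <- 2 * pi * (seq_len(D) - 1L) / D
  thr <- seq(-grid$R, grid$R, length.out = Tn)
  chi <- matrix(0L, D, Tn)
  if (method == "vertex") {
    if (!is_simple_polygon(poly$vertices)) {
      stop("geometry error: polygon self-intersects")
    }
    v <- center_vertices(poly)
    if (max(sqrt(rowSums(v^2))) >= grid$R) {
      stop("shape reaches outside the inscribed disc of the window; ",
           "increase R")
    }
    tri <- triangulate_polygon(v)
    e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(1L, 3L)])
    e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
    stopifnot(nrow(v) - nrow(e) + nrow(tri) == 1L)  # disc topology
    for (d in seq_len(D)) {
      dir <- c(cos(angles[d]), sin(angles[d]))
      hv <- as.vector(v %*% dir)
      he <- pmax(hv[e[, 1L]], hv[e[, 2L]])
      ht <- pmax(hv[tri[, 1L]], hv[tri[, 2L]], hv[tri[, 3L]])
      chi[d, ] <- bin_cells(hv, thr) - bin_cells(he, thr) + bin_cells(ht, thr)
    }
  } else {
    mask <- rasterize_polygon(poly, grid)
    for (d in seq_len(D)) {
      dir <- c(cos(angles[d]), sin(angles[d]))
      chi[d, ] <- ecc_directional(mask, grid, dir, thr)
    }
  }
  cellcomplex <- if (method == "vertex") {
    list(v = v, edges = e, tris = tri)
  }
  structure(list(chi = chi, angles = angles, thresholds = thr,
                 R = grid$R, N = grid$N, method = method,
                 complex = cellcomplex, label = poly$label),
            class = "ect_matrix")
}

#' @export
print.ect_matrix <- function(x, ...) {
  cat(sprintf("ect_matrix '%s': %d directions x %d thresholds, R = %.2f um (%s)\n",
              x$label, nrow(x$chi), ncol(x$chi), x$R, x$method))
  invisible(x)
}

#' Smooth Euler characteristic transform descriptor
#'
#' Per direction, subtracts the mean of the Euler curve over the threshold
#' window and cumulatively integrates the centred curve: every row starts at
#' 0 and returns to 0 at the upper window edge, and the resulting `D` x `T`
#' real matrix is the shape's signature. For the exact `"vertex"` transform
#' the integral of the centred step function is evaluated in closed form
#' from the cell heights (the descriptor then varies smoothly with shape
#' rotation); for the `"raster"` transform the sampled curve is integrated
#' with the trapezoid rule.
#'
#' @param ectm an [ect()] result.
#' @return An object of class `sect_descriptor` with fields `s` (`D` x `T`),
#'   `angles`, `thresholds`, `R`, `label`.
#' @export
sect <- function(ectm) {
  stopifnot(inherits(ectm, "ect_matrix"))
  thr <- ectm$thresholds
  D <- nrow(ectm$chi)
  if (!is.null(ectm$complex)) {
    # exact integral of the centred Euler step function:
    #   s(t) = sum_cells sgn * max(0, t - h) - (t + R) * chibar,
    # with chibar the mean of chi over [-R, R]
    cx <- ectm$complex
    sgn <- c(rep(1, nrow(cx$v)), rep(-1, nrow(cx$edges)),
             rep(1, nrow(cx$tris)))
    R <- ectm$R
    s <- matrix(0, D, length(thr))
    for (d in seq_len(D)) {
      dir <- c(cos(ectm$angles[d]), sin(ectm$angles[d]))
      hv <- as.vector(cx$v %*% dir)
      h <- c(hv,
             pmax(hv[cx$edges[, 1L]], hv[cx$edges[, 2L]]),
             pmax(hv[cx$tris[, 1L]], hv[cx$tris[, 2L]], hv[cx$tris[, 3L]]))
      ord <- order(h)
      hs <- h[ord]
      gs <- sgn[ord]
      c1 <- cumsum(gs)            # running chi below a height
      c2 <- cumsum(gs * hs)
      chibar <- sum(sgn * (R - h)) / (2 * R)
      pos <- findInterval(thr, hs)
      s[d, ] <- ifelse(pos > 0, thr * c1[pmax(pos, 1L)] - c2[pmax(pos, 1L)],
                       0) - (thr + R) * chibar
    }
  } else {
    centred <- ectm$chi - rowMeans(ectm$chi)
    s <- t(apply(centred, 1L, function(row) {
      as.vector(pracma::cumtrapz(thr, row))
    }))
  }
  structure(list(s = s, angles = ectm$angles, thresholds = thr,
                 R = ectm$R, label = ectm$label),
            class = "sect_descriptor")
}

#' L2 magnitude of a SECT descriptor
#'
#' The norm under the product measure `dtheta * dt`; equals the descriptor's
#' distance to the descriptor of the empty shape.
#'
#' @param desc a [sect()] descriptor.
#' @return Non-negative scalar.
#' @export
sect_norm <- function(desc) {
  stopifnot(inherits(desc, "sect_descriptor"))
  dtheta <- 2 * pi / nrow(desc$s)
  dt <- desc$thresholds[2L] - desc$thresholds[1L]
  sqrt(sum(desc$s^2) * dtheta * dt)
}

#' @export
print.sect_descriptor <- function(x, ...) {
  cat(sprintf("sect_descriptor '%s': %d x %d, R = %.2f um, |s| = %.3f\n",
              x$label, nrow(x$s), ncol(x$s), x$R, sect_norm(x)))
  invisible(x)
}

#' @export
plot.sect_descriptor <- function(x, ...) {
  graphics::image(x$angles, x$thresholds, x$s,
                  xlab = "direction (rad)", ylab = "threshold (um)",
                  main = paste("SECT:", x$label), ...)
  invisible(x)
}
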