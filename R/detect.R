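# Temporal shape scoring (DETECT): rotation-aligned SECT distances over a
# frame series, the d1/d0 distance-ratio score, and distance-based clustering
# of morphology classes.

check_compatible <- function(a, b) {
  if (!identical(dim(a$s), dim(b$s)) ||
      abs(a$R - b$R) > 1e-9 * max(a$R, b$R)) {
    stop("incompatible descriptors: direction/threshold grids differ")
  }
}

rotate_rows <- function(m, shift) {
  D <- nrow(m)
  shift <- ((shift %% D) + D) %% D
  if (shift == 0L) return(m)
  m[c((shift + 1L):D, 1L:shift), , drop = FALSE]
}

# maximal cross-correlation of two descriptor matrices over continuous cyclic
# shifts of the direction axis, via trigonometric interpolation of the
# direction-axis cross-spectrum (fractional shifts act unitarily, so the
# resulting orbit distance remains a metric)
fractional_align <- function(A, B, oversample = 16L) {
  D <- nrow(A)
  FA <- stats::mvfft(A)
  FB <- stats::mvfft(B)
  cross <- rowSums(Conj(FA) * FB)
  DM <- D * oversample
  padded <- complex(length.out = DM)
  half <- D %/% 2L
  padded[1L] <- cross[1L]
  if (D %% 2L == 0L) {
    if (half > 1L) padded[2:half] <- cross[2:half]
    padded[half + 1L] <- cross[half + 1L] / 2          # split the Nyquist bin
    padded[DM - half + 1L] <- cross[half + 1L] / 2
    if (half > 1L) padded[(DM - half + 2L):DM] <- cross[(half + 2L):D]
  } else {
    padded[2:(half + 1L)] <- cross[2:(half + 1L)]
    padded[(DM - half + 1L):DM] <- cross[(half + 2L):D]
  }
  corr <- Re(stats::fft(padded, inverse = TRUE)) / D
  j <- which.max(corr)
  cm <- corr[if (j == 1L) DM else j - 1L]
  c0 <- corr[j]
  cp <- corr[if (j == DM) 1L else j + 1L]
  denom <- cm - 2 * c0 + cp
  delta <- if (abs(denom) > 0) 0.5 * (cm - cp) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  cstar <- c0 - 0.25 * (cm - cp) * delta
  list(corr = max(c0, cstar), shift = ((j - 1L + delta) / oversample) %% D)
}

#' Distance between two SECT descriptors
#'
#' L2 distance between descriptor matrices under the measure `dtheta * dt`.
#' With `align = TRUE` the distance is minimized over rotations of the
#' direction axis of `b`: the `D` integer cyclic shifts (so a rotation of the
#' shape by a multiple of `2*pi/D` is absorbed exactly) refined by continuous
#' fractional shifts via trigonometric interpolation (so arbitrary rotations
#' are absorbed up to the direction-sampling error). Both shift families act
#' as isometries, hence the aligned distance is an orbit metric: symmetric
#' and satisfying the triangle inequality.
#'
#' @param a,b [sect()] descriptors on the same grid.
#' @param align minimize over direction-axis rotations of `b`?
#'   Default `FALSE`.
#' @return Non-negative scalar; when `align = TRUE` the optimal direction
#'   shift (possibly fractional, in grid units) is attached as attribute
#'   `"shift"`.
#' @export
descriptor_distance <- function(a, b, align = FALSE) {
  stopifnot(inherits(a, "sect_descriptor"), inherits(b, "sect_descriptor"))
  check_compatible(a, b)
  D <- nrow(a$s)
  dtheta <- 2 * pi / D
  dt <- a$thresholds[2L] - a$thresholds[1L]
  if (!align) {
    return(sqrt(sum((a$s - b$s)^2) * dtheta * dt))
  }
  best <- Inf
  best_shift <- 0
  for (k in 0L:(D - 1L)) {
    ss <- sum((a$s - rotate_rows(b$s, k))^2)
    if (ss < best) {
      best <- ss
      best_shift <- k
    }
  }
  fr <- fractional_align(a$s, b$s)
  frac_ss <- sum(a$s^2) + sum(b$s^2) - 2 * fr$corr
  if (frac_ss < best) {
    best <- max(frac_ss, 0)
    best_shift <- fr$shift
  }
  structure(sqrt(best * dtheta * dt), shift = best_shift)
}

# canonical pose: cyclic shift that places the direction of maximal row energy
# at index 1 (ties broken by the lowest shift)
canonical_shift <- function(desc) {
  which.max(rowSums(desc$s^2)) - 1L
}

#' Build the temporal descriptor of an outline series
#'
#' Computes one SECT descriptor per frame on a common grid whose half-width is
#' fixed by the largest frame of the series (`expand` times its maximal
#' centroid-to-vertex distance), so that compaction changes the descriptor
#' rather than being normalized away. The orientation is estimated once on the
#' first frame (rotation to a canonical pose) and the same direction shift is
#' applied to every frame: an organoid's orientation in the well is common to
#' all frames, and per-frame re-alignment would absorb genuine shape change.
#'
#' @param outlines list of [polygon_outline()]s, ordered in time, sharing one
#'   organoid label.
#' @param times_h acquisition times in hours (strictly increasing); defaults
#'   to the outlines' `time_h` fields, or `0, 1, 2, ...` when absent.
#' @param directions,thresholds descriptor resolution, as in [ect()].
#' @param expand window half-width as a multiple of the largest frame's
#'   maximal centroid-to-vertex distance (default 1.25).
#' @param method descriptor discretization, as in [ect()].
#' @return An object of class `temporal_descriptor`: `frames` (list of
#'   [sect()] descriptors), `times_h`, `alignment_shift`, `R`, `label`.
#' @export
build_timecourse <- function(outlines, times_h = NULL, directions = 72L,
                             thresholds = 128L, expand = 1.25,
                             method = c("vertex", "raster")) {
  method <- match.arg(method)
  if (!is.list(outlines) || length(outlines) < 1L) {
    stop("'outlines' must be a nonempty list of polygon outlines")
  }
  for (p in outlines) stopifnot(inherits(p, "polygon_outline"))
  labels <- unique(vapply(outlines, function(p) p$label, ""))
  if (length(labels) > 1L) {
    stop("frames carry inconsistent labels: ", paste(labels, collapse = ", "))
  }
  if (is.null(times_h)) {
    times_h <- vapply(seq_along(outlines), function(i) {
      t <- outlines[[i]]$time_h
      if (is.null(t)) NA_real_ else t
    }, 0)
    if (anyNA(times_h)) times_h <- seq_along(outlines) - 1
  }
  if (length(times_h) != length(outlines) || any(diff(times_h) <= 0)) {
    stop("'times_h' must be strictly increasing, one value per frame")
  }
  rmax <- max(vapply(outlines, function(p) {
    max(sqrt(rowSums(center_vertices(p)^2)))
  }, 0))
  grid <- grid_spec(expand * rmax)
  frames <- lapply(outlines, function(p) {
    sect(ect(p, grid = grid, directions = directions,
             thresholds = thresholds, method = method))
  })
  shift <- canonical_shift(frames[[1L]])
  frames <- lapply(frames, function(f) {
    f$s <- rotate_rows(f$s, shift)
    f
  })
  structure(list(frames = frames, times_h = times_h,
                 alignment_shift = shift, R = grid$R, label = labels),
            class = "temporal_descriptor")
}

#' @export
print.temporal_descriptor <- function(x, ...) {
  cat(sprintf(
    "temporal_descriptor '%s': %d frames at t = %s h, R = %.2f um\n",
    x$label, length(x$frames), paste(x$times_h, collapse = "/"), x$R))
  invisible(x)
}

#' DETECT distance ratio of a time course
#'
#' Summarizes morphological change as `ratio = d1 / d0`, where `d0` is the
#' magnitude of the first frame's descriptor (its distance to the empty
#' shape) and `d1` is the distance between the final and the first frame
#' (frames already share the orientation frozen by [build_timecourse()]).
#' A shape that does not change over the series gives a ratio of 0 up to
#' discretization noise. Two variants are available: `"cumulative"` sums the
#' consecutive inter-frame distances into `d1`; `"consecutive"` uses the
#' largest single inter-frame distance.
#'
#' @param tc a [build_timecourse()] result with at least 2 frames.
#' @param variant how `d1` summarizes the series (default `"first_last"`).
#' @return An object of class `detect_ratio`: `d0`, `d1`, `ratio`,
#'   `interval_distances` (frame k to k+1), `times_h`, `label`, `variant`.
#' @export
distance_ratio <- function(tc,
                           variant = c("first_last", "cumulative",
                                       "consecutive")) {
  stopifnot(inherits(tc, "temporal_descriptor"))
  variant <- match.arg(variant)
  n <- length(tc$frames)
  if (n < 2L) stop("insufficient frames: the distance ratio needs >= 2")
  d0 <- sect_norm(tc$frames[[1L]])
  if (d0 < 1e-12) stop("undefined ratio: first frame has a degenerate (empty) descriptor")
  intervals <- vapply(seq_len(n - 1L), function(k) {
    descriptor_distance(tc$frames[[k]], tc$frames[[k + 1L]])
  }, 0)
  d1 <- switch(variant,
    first_last = descriptor_distance(tc$frames[[n]], tc$frames[[1L]]),
    cumulative = sum(intervals),
    consecutive = max(intervals))
  structure(list(d0 = d0, d1 = as.numeric(d1), ratio = as.numeric(d1) / d0,
                 interval_distances = intervals, times_h = tc$times_h,
                 label = tc$label, variant = variant),
            class = "detect_ratio")
}

#' @export
print.detect_ratio <- function(x, ...) {
  cat(sprintf("DETECT ratio '%s' (%s): d0 = %.4f, d1 = %.4f, d1/d0 = %.4f\n",
              x$label, x$variant, x$d0, x$d1, x$ratio))
  invisible(x)
}

#' SECT descriptors of several outlines on one shared grid
#'
#' Descriptor distances and clustering require a common window and threshold
#' grid; this helper fixes the half-width from the largest shape of the set
#' (`expand` times its maximal centroid-to-vertex distance) and computes all
#' descriptors on it.
#'
#' @param outlines list of [polygon_outline()]s.
#' @param directions,thresholds,expand,method as in [build_timecourse()].
#' @return List of [sect()] descriptors.
#' @export
descriptor_set <- function(outlines, directions = 72L, thresholds = 128L,
                           expand = 1.25, method = c("vertex", "raster")) {
  method <- match.arg(method)
  if (!is.list(outlines) || length(outlines) < 1L) {
    stop("'outlines' must be a nonempty list of polygon outlines")
  }
  rmax <- max(vapply(outlines, function(p) {
    max(sqrt(rowSums(center_vertices(p)^2)))
  }, 0))
  grid <- grid_spec(expand * rmax)
  lapply(outlines, function(p) {
    sect(ect(p, grid = grid, directions = directions,
             thresholds = thresholds, method = method))
  })
}

#' Pairwise aligned distance matrix of descriptors
#'
#' @param descriptors list of [sect()] descriptors on one common grid.
#' @param align use rotation alignment per pair (default `TRUE`)?
#' @return Symmetric numeric matrix with zero diagonal; row/column names are
#'   the descriptor labels.
#' @export
pairwise_matrix <- function(descriptors, align = TRUE) {
  n <- length(descriptors)
  if (n < 2L) stop("need at least 2 descriptors")
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <-
        as.numeric(descriptor_distance(descriptors[[i]], descriptors[[j]],
                                       align = align))
    }
  }
  labs <- vapply(descriptors, function(d) d$label, "")
  dimnames(m) <- list(labs, labs)
  m
}

#' Cluster shapes from a descriptor distance matrix
#'
#' Average-linkage agglomerative clustering cut at `k` clusters; deterministic
#' given the matrix.
#'
#' @param matrix symmetric distance matrix, e.g. from [pairwise_matrix()].
#' @param k number of clusters (2 <= k <= n).
#' @return Integer cluster labels (1..k), named after the matrix rows.
#' @export
cluster_shapes <- function(matrix, k = 2L) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop("'matrix' must be a square distance matrix")
  }
  n <- nrow(matrix)
  if (k < 2L) stop("'k' must be >= 2")
  if (k > n) stop("'k' exceeds the number of shapes")
  if (max(matrix) <= 1e-12 * max(1, mean(abs(diag(matrix))) + 1)) {
    warning("all pairwise distances are ~0; the k-cluster split is degenerate")
  }
  hc <- hclust(as.dist(matrix), method = "average")
  cutree(hc, k = k)
}
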