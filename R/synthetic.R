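# Seeded generators for outlines, time courses and tube-network phantoms with
# known ground truth. These stand in for the undeposited microscopy data: the
# outline families reproduce the two morphology classes (smooth spheres vs
# lobed, grape-like shapes), the time courses emulate progressive compaction,
# and the phantoms emulate hollow-membrane canaliculi staining geometry.

# evaluate `code` under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# smooth unit-amplitude periodic noise profile: low-order Fourier series with
# random phases, normalized to max |eta| = 1
smooth_noise_profile <- function(theta, harmonics = 2:6) {
  eta <- rep(0, length(theta))
  for (m in harmonics) {
    eta <- eta + (1 / m) * cos(m * theta + runif(1L, 0, 2 * pi))
  }
  eta / max(abs(eta))
}

#' Generate a synthetic organoid outline
#'
#' Radial shape model `r(theta) = R (1 + a cos(k theta) + eps eta(theta))`
#' with `eta` a smooth unit-amplitude noise profile: `a = 0` gives the smooth
#' spherical ("ball") class, `a > 0` the lobed ("grape") class. Output is a
#' clockwise closed polygon; a fixed seed reproduces it bit-exactly.
#'
#' @param family `"ball"` or `"grape"`.
#' @param radius base radius `R` in micrometres (default 50).
#' @param lobes lobe count `k` (grape only; >= 2, default 5).
#' @param amplitude lobe amplitude `a` in `[0, 1)` (default 0.35 for grape).
#' @param noise boundary noise amplitude `eps` as a fraction of `R`.
#' @param n_vertices vertices on the outline (default 100).
#' @param rotation global rotation in radians (default 0).
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @param label,time_h passed to [polygon_outline()].
#' @return A [polygon_outline()].
#' @export
gen_outline <- function(family = c("ball", "grape"), radius = 50, lobes = 5L,
                        amplitude = if (family == "grape") 0.35 else 0,
                        noise = 0, n_vertices = 100L, rotation = 0,
                        seed = NULL, label = family, time_h = NULL) {
  family <- match.arg(family)
  if (family == "grape" && lobes < 2L) stop("'lobes' must be >= 2")
  if (amplitude < 0 || amplitude >= 1) {
    stop("'amplitude' must lie in [0, 1) (self-intersection risk)")
  }
  if (noise < 0 || amplitude + noise >= 1) {
    stop("'amplitude' + 'noise' must stay below 1")
  }
  a <- if (family == "ball") 0 else amplitude
  with_seed(seed, {
    theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
    eta <- if (noise > 0) smooth_noise_profile(theta) else 0
    r <- radius * (1 + a * cos(lobes * theta) + noise * eta)
    ang <- theta + rotation
    polygon_outline(cbind(r * cos(ang), r * sin(ang)),
                    label = label, time_h = time_h)
  })
}

#' Generate a synthetic outline time course
#'
#' `mode = "static"` re-draws only the boundary noise each frame (the shape
#' itself does not change); `mode = "compacting"` additionally scales the
#' radius by `1 - shrink` per frame and decays the lobe amplitude by the same
#' factor (compaction = smaller and smoother). Default times follow the
#' live-imaging design: first frame 2 h after seeding, then every 24 h.
#'
#' @param mode `"static"` or `"compacting"`.
#' @param n_frames number of frames (>= 2, default 3).
#' @param shrink per-frame radius shrink fraction in `[0, 1)` (default 0.15;
#'   ignored for static courses).
#' @param family,radius,lobes,amplitude,n_vertices as in [gen_outline()].
#' @param noise per-frame boundary noise amplitude (default 0.001: the
#'   smooth, low-order component of manual outline-tracing error, the only
#'   part the descriptor is sensitive to; per-vertex jitter averages out).
#' @param times_h frame times in hours; default `2 + 24 (0:(n_frames-1))`.
#' @param seed optional RNG seed; also fixes the organoid's orientation.
#' @param label organoid label shared by all frames.
#' @return List of [polygon_outline()]s, one per frame.
#' @export
gen_timecourse <- function(mode = c("static", "compacting"), n_frames = 3L,
                           shrink = 0.15, family = "ball", radius = 50,
                           lobes = 5L,
                           amplitude = if (family == "grape") 0.35 else 0,
                           noise = 0.001, n_vertices = 100L, times_h = NULL,
                           seed = NULL, label = "organoid") {
  mode <- match.arg(mode)
  if (n_frames < 2L) stop("'n_frames' must be >= 2")
  if (shrink < 0 || shrink >= 1) stop("'shrink' must lie in [0, 1)")
  if (is.null(times_h)) times_h <- 2 + 24 * (seq_len(n_frames) - 1)
  with_seed(seed, {
    rot <- runif(1L, 0, 2 * pi)
    lapply(seq_len(n_frames), function(f) {
      fac <- if (mode == "compacting") (1 - shrink)^(f - 1L) else 1
      gen_outline(family, radius = radius * fac, lobes = lobes,
                  amplitude = amplitude * fac, noise = noise,
                  n_vertices = n_vertices, rotation = rot, seed = NULL,
                  label = label, time_h = times_h[f])
    })
  })
}

#' Reference 10-edge tube network graph
#'
#' A fixed tubular-network layout with one quadruple junction, two triple
#' junctions, two pass-through bends and five free ends, spanning roughly a
#' 30 x 30 x 20 micrometre block; node positions are jittered by up to
#' `jitter` micrometres under the seed.
#'
#' @param radius tube radius in micrometres: a single value for all edges
#'   (default 1) or one value per edge.
#' @param jitter maximal per-coordinate node jitter in micrometres.
#' @param seed optional RNG seed.
#' @return An object of class `tube_graph`: `nodes` (matrix, columns x/y/z in
#'   micrometres), `edges` (pairs of node indices), `radii` (per edge).
#' @export
gen_tube_graph <- function(radius = 1, jitter = 0.5, seed = NULL) {
  nodes <- rbind(
    A = c(6, 15, 9),  B = c(14, 15, 9), C = c(14, 23, 9),
    D = c(14, 7, 9),  E = c(22, 15, 9), F = c(8, 27, 12),
    G = c(20, 27, 6), H = c(26, 21, 13), I = c(26, 9, 5),
    J = c(8, 7, 13),  K = c(26, 3, 8))
  colnames(nodes) <- c("x", "y", "z")
  edges <- rbind(c(1, 2), c(2, 3), c(2, 4), c(2, 5), c(3, 6),
                 c(3, 7), c(5, 8), c(5, 9), c(4, 10), c(9, 11))
  radii <- rep_len(radius, nrow(edges))
  with_seed(seed, {
    if (jitter > 0) {
      nodes <- nodes + matrix(runif(length(nodes), -jitter, jitter),
                              nrow(nodes))
    }
    structure(list(nodes = nodes, edges = edges, radii = radii),
              class = "tube_graph")
  })
}

#' Ground-truth features of a tube graph
#'
#' @param graph a [gen_tube_graph()] (or same-shaped) object.
#' @param membrane membrane shell thickness in micrometres; branch diameters
#'   measured on the completed (membrane-filled) lumen are expected to be
#'   `2 radius + membrane`.
#' @return List with `edge_lengths_um`, `total_length_um`, `valences`,
#'   `n_triple`, `n_quad`, `expected_diameter_um`.
#' @export
tube_graph_truth <- function(graph, membrane = 0.6) {
  el <- apply(graph$edges, 1L, function(e) {
    sqrt(sum((graph$nodes[e[1L], ] - graph$nodes[e[2L], ])^2))
  })
  val <- tabulate(as.vector(graph$edges), nrow(graph$nodes))
  list(edge_lengths_um = el,
       total_length_um = sum(el),
       valences = val,
       n_triple = sum(val == 3L),
       n_quad = sum(val == 4L),
       expected_diameter_um = 2 * graph$radii + membrane)
}

# minimal distance from every voxel centre of a sub-box to a segment
segment_distance_box <- function(coords, p1, p2) {
  # coords: list(z =, y =, x =) voxel-centre coordinates of the sub-box (um)
  d <- c(length(coords$z), length(coords$y), length(coords$x))
  X <- array(rep(coords$x, each = d[1L] * d[2L]), d)
  Y <- array(rep(rep(coords$y, each = d[1L]), times = d[3L]), d)
  Z <- array(rep(coords$z, times = d[2L] * d[3L]), d)
  v <- p2 - p1
  len2 <- sum(v^2)
  if (len2 == 0) {
    return(sqrt((X - p1[1L])^2 + (Y - p1[2L])^2 + (Z - p1[3L])^2))
  }
  t <- ((X - p1[1L]) * v[1L] + (Y - p1[2L]) * v[2L] + (Z - p1[3L]) * v[3L]) /
    len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((X - (p1[1L] + t * v[1L]))^2 + (Y - (p1[2L] + t * v[2L]))^2 +
         (Z - (p1[3L] + t * v[3L]))^2)
}

#' Generate a two-channel tube-network phantom volume
#'
#' Emulates the staining geometry the canaliculi pipeline segments: the
#' apical channel is a hollow membrane shell around each tube (voxels whose
#' distance to the centreline lies in `[r - h/2, r + h/2]`, minus any tube
#' lumen, so lumina stay connected at junctions); the cortical channel adds
#' planar cell-border sheets. Both channels get additive Gaussian noise with
#' `sigma = (foreground - background) / snr` and are rounded to non-negative
#' integer intensities.
#'
#' @param graph a [gen_tube_graph()] layout (node coordinates in
#'   micrometres).
#' @param voxel_size isotropic voxel edge in micrometres (default 0.3).
#' @param membrane membrane shell thickness `h` in micrometres (default 0.6,
#'   i.e. two voxels, so the hollow-to-solid completion step is genuinely
#'   exercised).
#' @param snr signal-to-noise ratio; `Inf` for a noise-free phantom.
#' @param foreground,background membrane and background intensities.
#' @param margin clearance between structures and the volume border in
#'   micrometres (default 3).
#' @param n_sheets number of cell-border slabs in the cortical channel.
#' @param seed optional RNG seed.
#' @return List with `apical`, `cortical` (numeric arrays, dim (z, y, x)),
#'   `voxel_size`, `origin` (micrometre coordinate of the first voxel
#'   centre), and `truth` ([tube_graph_truth()] plus the graph).
#' @export
gen_tube_phantom <- function(graph, voxel_size = 0.3, membrane = 0.6,
                             snr = 5, foreground = 100, background = 10,
                             margin = 3, n_sheets = 2L, seed = NULL) {
  stopifnot(inherits(graph, "tube_graph"))
  rmax <- max(graph$radii) + membrane / 2
  lo <- apply(graph$nodes, 2L, min) - margin - rmax
  hi <- apply(graph$nodes, 2L, max) + margin + rmax
  n <- ceiling((hi - lo) / voxel_size)           # (x, y, z) counts
  dims <- c(n[["z"]], n[["y"]], n[["x"]])
  coords <- list(z = lo[["z"]] + (seq_len(dims[1L]) - 0.5) * voxel_size,
                 y = lo[["y"]] + (seq_len(dims[2L]) - 0.5) * voxel_size,
                 x = lo[["x"]] + (seq_len(dims[3L]) - 0.5) * voxel_size)
  envelope <- array(FALSE, dims)
  lumen <- array(FALSE, dims)
  for (e in seq_len(nrow(graph$edges))) {
    p1 <- graph$nodes[graph$edges[e, 1L], c("x", "y", "z")]
    p2 <- graph$nodes[graph$edges[e, 2L], c("x", "y", "z")]
    r <- graph$radii[e]
    pad <- r + membrane / 2 + voxel_size
    sub <- lapply(c(z = "z", y = "y", x = "x"), function(ax) {
      which(coords[[ax]] >= min(p1[[ax]], p2[[ax]]) - pad &
              coords[[ax]] <= max(p1[[ax]], p2[[ax]]) + pad)
    })
    dsub <- segment_distance_box(
      list(z = coords$z[sub$z], y = coords$y[sub$y], x = coords$x[sub$x]),
      c(p1[["x"]], p1[["y"]], p1[["z"]]), c(p2[["x"]], p2[["y"]], p2[["z"]]))
    envelope[sub$z, sub$y, sub$x] <-
      envelope[sub$z, sub$y, sub$x] | (dsub <= r + membrane / 2)
    lumen[sub$z, sub$y, sub$x] <-
      lumen[sub$z, sub$y, sub$x] | (dsub < r - membrane / 2)
  }
  shell <- envelope & !lumen
  sheets <- array(FALSE, dims)
  if (n_sheets > 0L) {
    at <- round(dims[1L] * seq_len(n_sheets) / (n_sheets + 1L))
    for (zz in at) sheets[zz + c(0L, 1L), , ] <- TRUE
  }
  sigma <- if (is.finite(snr)) (foreground - background) / snr else 0
  with_seed(seed, {
    mk <- function(mask) {
      v <- background + (foreground - background) * mask
      if (sigma > 0) v <- v + array(stats::rnorm(length(v), 0, sigma), dims)
      array(pmax(round(v), 0), dims)
    }
    apical <- mk(shell)
    cortical <- mk(shell | sheets)
    truth <- tube_graph_truth(graph, membrane)
    truth$graph <- graph
    list(apical = apical, cortical = cortical, voxel_size = voxel_size,
         origin = lo, truth = truth)
  })
}

#' Fixed five-object filtering fixture
#'
#' A binary volume with four interior boxes of 2000, 1500, 100 and 50 voxels
#' plus one 3000-voxel box touching the z = 1 face, at fixed positions. With
#' a 500-voxel size threshold and all-face border exclusion, exactly the two
#' large interior objects survive.
#'
#' @return List with `mask` (40^3 logical array) and `expected`
#'   (component sizes and the expected removal report).
#' @export
gen_filter_fixture <- function() {
  d <- c(40L, 40L, 40L)
  m <- array(FALSE, d)
  m[3:12, 3:12, 3:22] <- TRUE          # 10 x 10 x 20 = 2000, interior
  m[3:12, 16:30, 26:35] <- TRUE        # 10 x 15 x 10 = 1500, interior
  m[16:20, 3:7, 3:6] <- TRUE           # 5 x 5 x 4 = 100, interior
  m[16:20, 11:15, 10:11] <- TRUE       # 5 x 5 x 2 = 50, interior
  m[1:10, 20:34, 3:22] <- TRUE         # 10 x 15 x 20 = 3000, touches z face
  list(mask = m,
       expected = list(sizes = c(2000L, 1500L, 100L, 50L, 3000L),
                       removed_size = 2L, removed_border = 1L, kept = 2L))
}
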