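# Rasterization, Euler characteristics, directional Euler curves and the
# SECT descriptor.

test_that("rasterization matches an independent point-in-polygon oracle", {
  sq <- polygon_outline(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  g <- grid_spec(10, 40)  # pitch 0.5 um
  mask <- rasterize_polygon(sq, g)
  expect_true(abs(sum(mask) - 400) <= 40)
  # full agreement with the winding-angle oracle over all pixel centres
  ax <- -g$R + (seq_len(g$N) - 0.5) * g$pitch
  px <- rep(ax, each = g$N); py <- rep(ax, times = g$N)
  v <- sweep(sq$vertices, 2, outline_centroid(sq))
  expect_equal(as.vector(mask), oracle_point_in_polygon(px, py, v))
  # window region far from the polygon stays off
  expect_true(all(!mask[1:2, ]))
})

test_that("rasterized area converges with resolution", {
  gr <- gen_outline("grape", radius = 20, seed = 5)
  a1 <- sum(rasterize_polygon(gr, grid_spec(30, 128))) * (60 / 128)^2
  a2 <- sum(rasterize_polygon(gr, grid_spec(30, 256))) * (60 / 256)^2
  expect_lt(abs(a1 - a2) / a2, 0.02)
})

test_that("rasterization rejects bad geometry", {
  bowtie <- list(vertices = cbind(c(0, 10, 10, 0), c(0, 10, 0, 10)),
                 label = "bowtie")
  class(bowtie) <- "polygon_outline"
  expect_error(rasterize_polygon(bowtie, grid_spec(20)), "self-intersect")
  big <- polygon_outline(cbind(c(0, 30, 30, 0), c(0, 0, 30, 30)))
  expect_error(rasterize_polygon(big, grid_spec(10)), "increase R")
})

test_that("euler characteristic equals components minus holes on 200 masks", {
  skip_if_not_installed("igraph")
  mismatches <- 0L
  for (s in 1:200) {
    set.seed(s)
    mask <- if (s %% 2 == 0) {
      matrix(runif(32 * 32) < runif(1, 0.2, 0.7), 32, 32)
    } else {
      random_mask(32, s, p_extra = 0.05)
    }
    if (euler_characteristic(mask) != oracle_chi(mask)) {
      mismatches <- mismatches + 1L
    }
  }
  expect_identical(mismatches, 0L)
  # canonical cases
  expect_identical(euler_characteristic(matrix(TRUE, 8, 8)), 1L)
  ann <- matrix(TRUE, 8, 8); ann[4:5, 4:5] <- FALSE
  expect_identical(euler_characteristic(ann), 0L)
  expect_identical(euler_characteristic(matrix(FALSE, 4, 4)), 0L)
})

test_that("directional Euler curves behave as sublevel filtrations", {
  di <- gen_outline("ball", radius = 8, n_vertices = 64)
  g <- grid_spec(12, 64)
  mask <- rasterize_polygon(di, g)
  thr <- seq(-g$R, g$R, length.out = 64)
  cv <- ecc_directional(mask, g, c(1, 0), thr)
  # convex shape: monotone 0 -> 1
  expect_true(all(diff(cv) >= 0))
  expect_identical(sort(unique(cv)), c(0L, 1L))
  expect_identical(cv[64], euler_characteristic(mask))
  # square: single step at the left edge height, within one pixel pitch
  sq <- polygon_outline(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  gs <- grid_spec(10, 64)
  ms <- rasterize_polygon(sq, gs)
  thr_s <- seq(-10, 10, length.out = 64)
  cs <- ecc_directional(ms, gs, c(1, 0), thr_s)
  step_at <- thr_s[min(which(cs == 1L))]
  expect_lt(abs(step_at - (-5)), gs$pitch + diff(thr_s)[1])
  # empty mask: all-zero curve
  expect_identical(ecc_directional(matrix(FALSE, 8, 8), grid_spec(4, 16),
                                   c(0, 1), seq(-4, 4, length.out = 40)),
                   rep(0L, 40))
  # non-unit direction is rejected
  expect_error(ecc_directional(ms, gs, c(1, 1), thr_s), "unit vector")
})

test_that("incremental sweep equals from-scratch recomputation", {
  # 50 random shapes x 8 directions, exact equality against the oracle that
  # rebuilds the sub-complex at every threshold
  g <- grid_spec(8, 16)
  thr <- seq(-8, 8, length.out = 32)
  for (s in 1:50) {
    mask <- random_mask(16, 1000 + s, p_extra = 0.1)
    for (d in 1:8) {
      ang <- 2 * pi * (d - 1) / 8
      dir <- c(cos(ang), sin(ang))
      expect_equal(ecc_directional(mask, g, dir, thr),
                   oracle_ecc(mask, g, dir, thr),
                   ignore_attr = TRUE)
    }
  }
})

test_that("ect rows are direction-independent for a disc and not for lobes", {
  di <- gen_outline("ball", radius = 30, n_vertices = 256)
  e <- ect(di, directions = 24, thresholds = 64)
  # every row should agree up to one threshold step of jitter
  ref <- e$chi[1, ]
  for (d in 2:24) {
    expect_lte(max(abs(cumsum(e$chi[d, ]) - cumsum(ref))), 2)
  }
  gr <- gen_outline("grape", radius = 30)
  eg <- ect(gr, directions = 24, thresholds = 64)
  expect_gt(max(apply(eg$chi, 2, stats::var)), 0)
  # final threshold reaches the shape's Euler characteristic (1) everywhere
  expect_true(all(e$chi[, 64] == 1L))
  expect_true(all(eg$chi[, 64] == 1L))
  # raster path agrees on the final value too
  er <- ect(di, grid = grid_spec(40, 64), directions = 8, thresholds = 32,
            method = "raster")
  expect_true(all(er$chi[, 32] == 1L))
})

test_that("sect centres and integrates the curves", {
  gr <- gen_outline("grape", radius = 20, seed = 3)
  e <- ect(gr, directions = 16, thresholds = 64)
  s <- sect(e)
  centred <- e$chi - rowMeans(e$chi)
  expect_lt(max(abs(rowMeans(centred))), 1e-9)
  expect_true(all(s$s[, 1] == 0))
  # convex-shape closed form: the Euler curve of a disc is a single step at
  # the minimal support height h0, so the centred integral is
  # max(0, t - h0) - (t + R) (R - h0) / (2 R) -- an oracle independent of
  # the cell bookkeeping
  di <- gen_outline("ball", radius = 15, n_vertices = 128)
  ed <- ect(di, grid = grid_spec(20), directions = 16, thresholds = 64)
  sd_ <- sect(ed)
  v <- sweep(di$vertices, 2, outline_centroid(di))
  for (d in c(1, 5, 12)) {
    dir <- c(cos(ed$angles[d]), sin(ed$angles[d]))
    h0 <- min(v %*% dir)
    oracle <- pmax(0, ed$thresholds - h0) -
      (ed$thresholds + 20) * (20 - h0) / 40
    expect_equal(sd_$s[d, ], oracle, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # raster route: trapezoid integral of an all-zero curve matrix is zero
  e0 <- ect(di, grid = grid_spec(20, 32), directions = 16, thresholds = 64,
            method = "raster")
  e0$chi <- matrix(0L, 16, 64)
  s0 <- sect(e0)
  expect_true(all(s0$s == 0))
  expect_equal(sect_norm(s0), 0)
})

test_that("descriptors are translation invariant and resolution stable", {
  gr <- gen_outline("grape", radius = 25, seed = 9)
  moved <- polygon_outline(sweep(gr$vertices, 2, c(-40, 17.5), "+"),
                           label = gr$label)
  g <- grid_spec(45)
  a <- sect(ect(gr, grid = g, directions = 24, thresholds = 64))
  b <- sect(ect(moved, grid = g, directions = 24, thresholds = 64))
  expect_lt(descriptor_distance(a, b), 1e-9)
  # vertex-count refinement changes the norm by < 3%
  gr2 <- gen_outline("grape", radius = 25, n_vertices = 200, seed = 9)
  b2 <- sect(ect(gr2, grid = g, directions = 24, thresholds = 64))
  expect_lt(abs(sect_norm(b2) - sect_norm(a)) / sect_norm(a), 0.03)
  # raster path: norm stable when N doubles from the default resolution
  r1 <- sect(ect(gr, grid = grid_spec(45, 256), directions = 24,
                 thresholds = 64, method = "raster"))
  r2 <- sect(ect(gr, grid = grid_spec(45, 512), directions = 24,
                 thresholds = 64, method = "raster"))
  expect_lt(abs(sect_norm(r2) - sect_norm(r1)) / sect_norm(r1), 0.03)
})
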