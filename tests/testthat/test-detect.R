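# Descriptor metric properties, temporal scoring, and shape clustering.

shared_descs <- local({
  set.seed(42)
  polys <- lapply(1:10, function(i) {
    gen_outline(if (i %% 2) "ball" else "grape", radius = runif(1, 20, 40),
                amplitude = if (i %% 2) 0 else runif(1, 0.1, 0.35),
                noise = 0.01, seed = i, label = paste0("shape", i))
  })
  descriptor_set(polys, directions = 36, thresholds = 64)
})

test_that("descriptor distance is a metric (identity, symmetry, triangle)", {
  a <- shared_descs[[1]]
  expect_equal(descriptor_distance(a, a), 0)
  expect_equal(as.numeric(descriptor_distance(a, a, align = TRUE)), 0)
  m <- pairwise_matrix(shared_descs, align = TRUE)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  # triangle inequality over all triples (aligned distance = orbit metric)
  n <- nrow(m)
  worst <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    worst <- max(worst,
                 m[i, j] - m[i, k] - m[k, j],
                 m[i, k] - m[i, j] - m[j, k],
                 m[j, k] - m[j, i] - m[i, k])
  }
  expect_lte(worst, 1e-9)
  # grid mismatch is rejected
  other <- sect(ect(gen_outline("ball", radius = 10), grid = grid_spec(15),
                    directions = 36, thresholds = 64))
  expect_error(descriptor_distance(shared_descs[[1]], other), "incompatible")
})

test_that("rotation by grid angles is absorbed exactly, off-grid almost", {
  gr <- gen_outline("grape", radius = 30, noise = 0.01, seed = 4)
  g <- grid_spec(55)
  a <- sect(ect(gr, grid = g))
  rotg <- rotate_outline(gr, 2 * pi * 7 / 72)
  b <- sect(ect(rotg, grid = g))
  d <- descriptor_distance(a, b, align = TRUE)
  expect_lt(as.numeric(d), 1e-6 * sect_norm(a))
  expect_equal(as.numeric(attr(d, "shift")), 7, tolerance = 1e-6)
  # unaligned distance is large by comparison
  expect_gt(descriptor_distance(a, b), 100 * as.numeric(d) + 1e-12)
  # arbitrary (off-grid) rotation stays below 2% of the norm at D = 72
  roto <- rotate_outline(gr, 1.234)
  c2 <- sect(ect(roto, grid = g))
  expect_lt(as.numeric(descriptor_distance(a, c2, align = TRUE)),
            0.02 * sect_norm(a))
})

test_that("descriptor distance from a clean shape grows with boundary noise", {
  clean <- gen_outline("grape", radius = 30, seed = 100, label = "s")
  g <- grid_spec(55)
  ref <- sect(ect(clean, grid = g, directions = 36, thresholds = 64))
  eps <- c(0.005, 0.01, 0.02)
  means <- vapply(eps, function(e) {
    mean(vapply(1:15, function(r) {
      noisy <- gen_outline("grape", radius = 30, noise = e,
                           seed = 7000 + r, label = "s")
      descriptor_distance(ref, sect(ect(noisy, grid = g, directions = 36,
                                        thresholds = 64)))
    }, 0))
  }, 0)
  expect_true(all(diff(means) >= 0))
  # bounded by C * eps for a common constant C
  expect_lt(max(means / eps) / min(means / eps), 3)
})

test_that("time courses share one grid and a frozen alignment", {
  tc_static <- gen_timecourse("static", noise = 0, seed = 5, label = "o")
  tc <- build_timecourse(tc_static)
  expect_s3_class(tc, "temporal_descriptor")
  expect_length(tc$frames, 3)
  expect_equal(tc$times_h, c(2, 26, 50))
  # identical frames give identical descriptors
  expect_equal(tc$frames[[1]]$s, tc$frames[[2]]$s)
  expect_equal(tc$frames[[1]]$s, tc$frames[[3]]$s)
  # shrinking discs: on the series-fixed window the centred descriptor gains
  # signal as the shape shrinks, so norms are strictly monotone (increasing)
  shr <- gen_timecourse("compacting", shrink = 0.15, noise = 0, seed = 5,
                        label = "o")
  tcs <- build_timecourse(shr)
  norms <- vapply(tcs$frames, sect_norm, 0)
  expect_true(all(diff(norms) > 0))
  # empty input and label mixtures are errors
  expect_error(build_timecourse(list()), "nonempty")
  mixed <- gen_timecourse("static", seed = 1, label = "a")
  mixed[[2]]$label <- "b"
  expect_error(build_timecourse(mixed), "inconsistent labels")
})

test_that("distance ratio separates static from compacting series", {
  static <- distance_ratio(build_timecourse(
    gen_timecourse("static", noise = 0, seed = 8, label = "o")))
  expect_equal(static$ratio, 0, tolerance = 1e-9)
  fast <- distance_ratio(build_timecourse(
    gen_timecourse("compacting", shrink = 0.15, noise = 0, seed = 8,
                   label = "o")))
  slow <- distance_ratio(build_timecourse(
    gen_timecourse("compacting", shrink = 0.05, noise = 0, seed = 8,
                   label = "o")))
  expect_gt(fast$ratio, 0)
  expect_gt(fast$ratio, slow$ratio)   # monotone in compaction rate
  expect_length(fast$interval_distances, 2)
  # variants
  tc <- build_timecourse(gen_timecourse("compacting", seed = 8, label = "o"))
  expect_gte(distance_ratio(tc, "cumulative")$d1,
             distance_ratio(tc, "first_last")$d1 - 1e-9)
  # single frame: error
  one <- build_timecourse(list(gen_outline("ball", seed = 1)))
  expect_error(distance_ratio(one), "insufficient frames")
})

test_that("balls and grapes cluster apart; degenerate cases are flagged", {
  set.seed(7)
  polys <- c(
    lapply(1:8, function(i) gen_outline("ball", radius = runif(1, 28, 34),
                                        noise = 0.01, seed = i,
                                        label = paste0("ball", i))),
    lapply(1:8, function(i) gen_outline("grape", radius = runif(1, 28, 34),
                                        amplitude = 0.35, noise = 0.01,
                                        seed = 50 + i,
                                        label = paste0("grape", i))))
  descs <- descriptor_set(polys, directions = 36, thresholds = 64)
  m <- pairwise_matrix(descs)
  # within-class distances are far below between-class distances
  expect_lt(mean(m[1:8, 1:8]), mean(m[1:8, 9:16]) / 2)
  labels <- cluster_shapes(m, k = 2)
  expect_equal(cluster_purity(labels, rep(c("b", "g"), each = 8)), 1.0)
  # k = n gives singletons
  expect_length(unique(cluster_shapes(m, k = 16)), 16)
  # all-identical shapes: degenerate split warns
  same <- pairwise_matrix(descriptor_set(
    lapply(1:3, function(i) gen_outline("ball", seed = 1,
                                        label = paste0("s", i)))))
  expect_warning(cluster_shapes(same, k = 2), "degenerate")
  expect_error(cluster_shapes(m, k = 17), "exceeds")
})
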