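# 3D segmentation primitives and the skeleton-network feature extraction.

ball_mask <- function(dims, centre, radius) {
  ix <- arrayInd(seq_len(prod(dims)), dims)
  array(sqrt(rowSums(sweep(ix, 2, centre)^2)) <= radius, dims)
}

test_that("median filter matches a brute-force sliding window", {
  v <- array(0, c(7, 7, 7)); v[4, 4, 4] <- 100     # single salt voxel
  expect_true(all(median_filter_3d(v, 1) == 0))
  const <- array(3.5, c(5, 6, 7))
  expect_equal(median_filter_3d(const, 1), const)
  expect_equal(median_filter_3d(const, 0), const)
  set.seed(2)
  r <- array(runif(9^3), c(9, 9, 9))
  f <- median_filter_3d(r, 1)
  # interior crop checked against an explicit window median
  for (z in 3:7) for (y in 3:7) for (x in 3:7) {
    expect_identical(f[z, y, x],
                     median(r[(z - 1):(z + 1), (y - 1):(y + 1),
                              (x - 1):(x + 1)]))
  }
})

test_that("isodata threshold finds the intermeans fixed point", {
  v <- array(rep(c(10, 20), each = 500), c(10, 10, 10))
  r <- isodata_threshold(v)
  expect_equal(r$threshold, 15)
  expect_identical(sum(r$mask), 500L)
  expect_true(all(v[r$mask] == 20))
  # binary image: mask reproduces the bright class
  b <- array(sample(c(0, 255), 1000, replace = TRUE), c(10, 10, 10))
  rb <- isodata_threshold(b)
  expect_equal(rb$mask, array(b == 255, dim(b)), ignore_attr = TRUE)
  # bimodal phantom with labelled ground truth
  set.seed(5)
  truth <- array(runif(20^3) < 0.3, c(20, 20, 20))
  noisy <- array(rnorm(20^3, ifelse(truth, 120, 30), 5), c(20, 20, 20))
  rn <- isodata_threshold(round(noisy))
  expect_gt(rn$threshold, 45); expect_lt(rn$threshold, 105)
  expect_gt(sum(rn$mask & truth) / sum(truth), 0.99)
  expect_error(isodata_threshold(array(7, c(4, 4, 4))), "degenerate")
})

test_that("apical overlap is the voxelwise conjunction", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:2, , ] <- TRUE; b[3:4, , ] <- TRUE
  expect_true(all(!apical_overlap(a, b)))          # disjoint
  expect_equal(apical_overlap(a, a), a)            # identical
  expect_error(apical_overlap(a, array(FALSE, c(4, 4, 5))), "differ")
  # shell phantom: apical shell AND (shell + borders) recovers the shell
  shell <- ball_mask(c(15, 15, 15), c(8, 8, 8), 6) &
    !ball_mask(c(15, 15, 15), c(8, 8, 8), 4.5)
  borders <- array(FALSE, c(15, 15, 15)); borders[8, , ] <- TRUE
  expect_equal(apical_overlap(shell, shell | borders), shell)
})

test_that("lumen completion turns closed shells solid and respects topology", {
  dims <- c(21, 21, 21)
  shell <- ball_mask(dims, c(11, 11, 11), 5.5) &
    !ball_mask(dims, c(11, 11, 11), 4.5)
  solid <- complete_lumina(shell, bc_config(inflate = 2, deflate = 2))
  oracle <- ball_mask(dims, c(11, 11, 11), 5.5)
  expect_lt(abs(sum(solid) - sum(oracle)) / sum(oracle), 0.05)
  # a solid ball stays a solid ball (within a surface layer)
  ball <- ball_mask(dims, c(11, 11, 11), 6)
  done <- complete_lumina(ball, bc_config(inflate = 2, deflate = 2))
  expect_lte(sum(xor(done, ball)), sum(ball) - sum(ball_mask(dims, c(11, 11, 11), 5)))
  # k = 0: pure fill-holes; an open-ended tube encloses no cavity
  tube_shell <- array(FALSE, c(9, 15, 15))
  ix <- arrayInd(seq_len(prod(c(9, 15, 15))), c(9, 15, 15))
  rr <- sqrt((ix[, 2] - 8)^2 + (ix[, 3] - 8)^2)
  tube_shell[ix[rr >= 3 & rr <= 4.5, , drop = FALSE]] <- TRUE
  open_done <- complete_lumina(tube_shell, bc_config(inflate = 0, deflate = 0))
  expect_equal(open_done, tube_shell)
})

test_that("object filtering applies size then border rules with bookkeeping", {
  fx <- gen_filter_fixture()
  lab <- table(organoidmorph:::cpp_label3d(fx$mask, dim(fx$mask), 26L))
  expect_equal(sort(as.integer(lab[-1])), sort(fx$expected$sizes))
  res <- filter_objects(fx$mask, bc_config(min_size_vox = 500))
  expect_equal(res$report$removed_size, 2L)
  expect_equal(res$report$removed_border, 1L)
  expect_equal(res$report$kept, 2L)
  expect_equal(sum(res$mask), 3500L)               # 2000 + 1500 survive
  expect_true(all(res$mask[fx$mask == FALSE] == FALSE))  # subset of input
  # degenerate settings are identities
  off <- bc_config(min_size_vox = 0, border_policy = "xy")
  keep_all <- filter_objects(array(FALSE, c(5, 5, 5)), off)
  expect_identical(sum(keep_all$mask), 0L)
  expect_equal(keep_all$report$removed_size + keep_all$report$removed_border,
               0L)
})

test_that("local thickness recovers analytic ball and cylinder diameters", {
  dims <- c(31, 31, 31)
  ball <- ball_mask(dims, c(16, 16, 16), 6)
  th <- local_thickness(ball, 0.3)
  expect_lt(abs(th[16, 16, 16] - 3.6), 0.3)
  expect_equal(th[1, 1, 1], 0)
  ix <- arrayInd(seq_len(prod(dims)), dims)
  cyl <- array(sqrt((ix[, 1] - 16)^2 + (ix[, 2] - 16)^2) <= 4, dims)
  tc <- local_thickness(cyl, 0.3)
  mid <- vapply(8:24, function(x) tc[16, 16, x], 0)
  expect_true(all(abs(mid - 2.4) < 0.31))
  expect_lt(diff(range(mid)), 1e-9)               # constant along the axis
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(local_thickness(single, 0.3)[3, 3, 3], 0.3 * 2,
               tolerance = 0.31)
})

test_that("skeletonization thins tubes to centrelines, preserving topology", {
  dims <- c(21, 21, 100)
  ix <- arrayInd(seq_len(prod(dims)), dims)
  tube <- array(sqrt((ix[, 1] - 11)^2 + (ix[, 2] - 11)^2) <= 3 &
                  ix[, 3] >= 6 & ix[, 3] <= 95, dims)
  sk <- skeletonize_3d(tube)
  expect_true(all(tube[sk]))                       # skeleton within mask
  expect_true(abs(sum(sk) - 90) <= 9)
  # single 26-connected curve
  expect_equal(max(organoidmorph:::cpp_label3d(sk, dims, 26L)), 1L)
  # a solid ball collapses to a small central cluster
  ball <- ball_mask(c(21, 21, 21), c(11, 11, 11), 7)
  skb <- skeletonize_3d(ball)
  expect_lte(sum(skb), 27)
  expect_gte(sum(skb), 1)
  # empty stays empty
  expect_identical(sum(skeletonize_3d(array(FALSE, c(5, 5, 5)))), 0L)
})

test_that("component count is preserved by skeletonization on random blobs", {
  dims <- c(24, 24, 24)
  for (s in 1:20) {
    set.seed(s)
    m <- array(FALSE, dims)
    for (b in 1:3) {
      m <- m | ball_mask(dims, runif(3, 6, 18), runif(1, 2, 4))
    }
    before <- max(organoidmorph:::cpp_label3d(m, dims, 26L))
    after <- max(organoidmorph:::cpp_label3d(skeletonize_3d(m), dims, 26L))
    expect_identical(after, before)
  }
})

mk_graph <- function(nodes, edges, radius = 1) {
  colnames(nodes) <- c("x", "y", "z")
  structure(list(nodes = nodes, edges = edges,
                 radii = rep_len(radius, nrow(edges))),
            class = "tube_graph")
}

test_that("junction taxonomy: Y gives a triple, X a single quadruple", {
  gy <- mk_graph(rbind(c(15, 15, 9), c(15, 25, 9), c(7, 8, 9), c(23, 8, 9)),
                 rbind(c(1, 2), c(1, 3), c(1, 4)))
  ry <- run_bc_pipeline(gen_tube_phantom(gy, snr = Inf)$apical,
                        gen_tube_phantom(gy, snr = Inf)$cortical)
  expect_identical(ry$features$n_triple, 1L)
  expect_identical(ry$features$n_quad, 0L)
  expect_identical(nrow(ry$features$network$branches), 3L)
  gx <- mk_graph(rbind(c(15, 15, 9), c(5, 5, 9), c(25, 5, 9), c(5, 25, 9),
                       c(25, 25, 12)),
                 rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  phx <- gen_tube_phantom(gx, snr = Inf)
  rx <- run_bc_pipeline(phx$apical, phx$cortical)
  expect_identical(rx$features$n_triple, 0L)
  expect_identical(rx$features$n_quad, 1L)
  expect_identical(nrow(rx$features$network$branches), 4L)
  # two disjoint straight tubes: two networks, no junctions
  g2 <- mk_graph(rbind(c(5, 8, 7), c(25, 8, 7), c(5, 22, 11), c(25, 22, 11)),
                 rbind(c(1, 2), c(3, 4)))
  ph2 <- gen_tube_phantom(g2, snr = Inf)
  r2 <- run_bc_pipeline(ph2$apical, ph2$cortical)
  expect_length(r2$networks, 2L)
  expect_identical(r2$features$n_junctions, 0L)
})

test_that("largest network is selected by total length", {
  g2 <- mk_graph(rbind(c(4, 8, 7), c(31, 8, 7), c(13, 22, 11), c(22, 22, 11)),
                 rbind(c(1, 2), c(3, 4)))
  ph <- gen_tube_phantom(g2, snr = Inf)
  r <- run_bc_pipeline(ph$apical, ph$cortical)
  lens <- sort(vapply(r$networks, function(n) n$total_length_um, 0))
  expect_equal(r$features$total_length_um, max(lens))
  expect_gt(lens[2], 2 * lens[1])
  # a 2x2 lattice (crossing bars) is more interconnected than a chain of
  # comparable length
  gridg <- mk_graph(rbind(c(10, 4, 7), c(10, 10, 7), c(10, 18, 7),
                          c(10, 24, 7),
                          c(18, 4, 7), c(18, 10, 7), c(18, 18, 7),
                          c(18, 24, 7),
                          c(4, 10, 7), c(4, 18, 7), c(24, 10, 7),
                          c(24, 18, 7)),
                    rbind(c(1, 2), c(2, 3), c(3, 4), c(5, 6), c(6, 7),
                          c(7, 8), c(9, 2), c(2, 6), c(6, 11), c(10, 3),
                          c(3, 7), c(7, 12)))
  chain <- mk_graph(rbind(c(4, 8, 7), c(16, 8, 7), c(28, 8, 7),
                          c(28, 20, 7), c(16, 20, 7)),
                    rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  rg <- run_bc_pipeline(gen_tube_phantom(gridg, snr = Inf)$apical,
                        gen_tube_phantom(gridg, snr = Inf)$cortical)
  rc <- run_bc_pipeline(gen_tube_phantom(chain, snr = Inf)$apical,
                        gen_tube_phantom(chain, snr = Inf)$cortical)
  expect_gt(rg$features$n_junctions, rc$features$n_junctions)
  # empty network list yields a flagged zero row
  zero <- largest_network_features(list(), NULL, "empty")
  expect_true(zero$no_network)
  expect_equal(zero$total_length_um, 0)
})

test_that("diameter histogram uses half-open 0.25 um bins summing to 100", {
  h <- diameter_histogram(c(1.0, 1.1, 1.6, 2.0))
  expect_equal(sum(h$percent), 100, tolerance = 1e-6)
  expect_equal(h$percent[h$mid == 1.125], 50)
  expect_equal(h$percent[h$mid == 1.625], 25)
  expect_equal(h$percent[h$mid == 2.125], 25)
  expect_true(all(h$percent[!h$mid %in% c(1.125, 1.625, 2.125)] == 0))
  # all-equal values: one 100% bin
  h1 <- diameter_histogram(rep(0.8, 5))
  expect_equal(max(h1$percent), 100)
  # value on an edge falls in the upper bin
  h2 <- diameter_histogram(1.25)
  expect_equal(h2$percent[h2$mid == 1.375], 100)
  expect_error(diameter_histogram(numeric(0)), "no diameters")
  expect_error(diameter_histogram(c(1, -1)), "positive")
})

test_that("pipeline recovers phantom ground truth and aborts on blanks", {
  g <- gen_tube_graph(seed = 3)
  tr <- tube_graph_truth(g)
  ph <- gen_tube_phantom(g, snr = Inf, seed = 3)
  res <- run_bc_pipeline(ph$apical, ph$cortical, structure_id = "clean")
  expect_identical(res$features$n_triple, tr$n_triple)
  expect_identical(res$features$n_quad, tr$n_quad)
  expect_lt(abs(res$features$total_length_um - tr$total_length_um) /
              tr$total_length_um, 0.10)
  expect_true(all(abs(res$features$branch_diameters_um -
                        tr$expected_diameter_um[1]) <= 0.3))
  # blank volume aborts in the threshold stage, by name
  blank <- array(50, c(10, 10, 10))
  expect_error(run_bc_pipeline(blank, blank), "threshold stage")
  expect_error(run_bc_pipeline(blank, array(50, c(9, 9, 9))), "share")
})
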