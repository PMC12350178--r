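# Independent oracles used by the tests. These deliberately take different
# computational routes than the package implementation.

# Euler characteristic of a pixel mask as (#8-connected foreground
# components) - (#enclosed 4-connected background components), via igraph
oracle_chi <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  comp_count <- function(cells, adjacency) {
    if (nrow(cells) == 0L) return(list(count = 0L, membership = integer(0L)))
    id <- seq_len(nrow(cells))
    key <- cells[, 1L] + n * (cells[, 2L] - 1L)
    idx <- match(key, key)
    edges <- NULL
    for (k in seq_len(nrow(adjacency))) {
      nb_key <- (cells[, 1L] + adjacency[k, 1L]) +
        n * (cells[, 2L] + adjacency[k, 2L] - 1L)
      ok <- cells[, 1L] + adjacency[k, 1L] >= 1L &
        cells[, 1L] + adjacency[k, 1L] <= n &
        cells[, 2L] + adjacency[k, 2L] >= 1L &
        cells[, 2L] + adjacency[k, 2L] <= m
      hit <- match(nb_key, key)
      sel <- ok & !is.na(hit)
      if (any(sel)) edges <- rbind(edges, cbind(id[sel], hit[sel]))
    }
    g <- igraph::graph_from_edgelist(rbind(cbind(id, id), edges),
                                     directed = FALSE)
    comps <- igraph::components(g)
    list(count = comps$no, membership = comps$membership)
  }
  adj8 <- as.matrix(expand.grid(-1:1, -1:1))
  adj8 <- adj8[rowSums(abs(adj8)) > 0, ]
  adj4 <- adj8[rowSums(abs(adj8)) == 1, ]
  fg <- which(mask, arr.ind = TRUE)
  cfg <- comp_count(fg, adj8)
  bg <- which(!mask, arr.ind = TRUE)
  cbg <- comp_count(bg, adj4)
  holes <- 0L
  if (cbg$count > 0L) {
    on_border <- bg[, 1L] == 1L | bg[, 1L] == n |
      bg[, 2L] == 1L | bg[, 2L] == m
    outer_comps <- unique(cbg$membership[on_border])
    holes <- cbg$count - length(outer_comps)
  }
  cfg$count - holes
}

# point-in-polygon by the winding-angle method (for simple polygons this
# agrees with the even-odd rule the implementation uses)
oracle_point_in_polygon <- function(px, py, v) {
  vapply(seq_along(px), function(i) {
    dx <- v[, 1L] - px[i]
    dy <- v[, 2L] - py[i]
    dx2 <- c(dx[-1L], dx[1L])
    dy2 <- c(dy[-1L], dy[1L])
    ang <- atan2(dx * dy2 - dy * dx2, dx * dx2 + dy * dy2)
    abs(sum(ang)) > pi
  }, TRUE)
}

# directional Euler curve recomputed from scratch at every threshold:
# explicit sub-complex construction and V - E + F count, with its own height
# bookkeeping (vertex grid coordinates recomputed here)
oracle_ecc <- function(mask, grid, direction, thresholds) {
  n <- nrow(mask); m <- ncol(mask)
  vx <- -grid$R + (seq_len(m + 1L) - 1L) * grid$pitch
  vy <- -grid$R + (seq_len(n + 1L) - 1L) * grid$pitch
  hvert <- function(i, j) vx[j] * direction[1L] + vy[i] * direction[2L]
  # enumerate cells of the complex with their heights
  hv <- c(); he <- c(); hf <- c()
  vseen <- matrix(FALSE, n + 1L, m + 1L)
  ehseen <- matrix(FALSE, n + 1L, m)
  evseen <- matrix(FALSE, n, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (!mask[i, j]) next
      corners <- rbind(c(i, j), c(i + 1L, j), c(i, j + 1L), c(i + 1L, j + 1L))
      hs <- apply(corners, 1L, function(c2) hvert(c2[1L], c2[2L]))
      hf <- c(hf, max(hs))
      for (k in 1:4) {
        ci <- corners[k, 1L]; cj <- corners[k, 2L]
        if (!vseen[ci, cj]) {
          vseen[ci, cj] <- TRUE
          hv <- c(hv, hs[k])
        }
      }
      if (!ehseen[i, j]) { ehseen[i, j] <- TRUE; he <- c(he, max(hs[c(1, 3)])) }
      if (!ehseen[i + 1L, j]) {
        ehseen[i + 1L, j] <- TRUE
        he <- c(he, max(hs[c(2, 4)]))
      }
      if (!evseen[i, j]) { evseen[i, j] <- TRUE; he <- c(he, max(hs[c(1, 2)])) }
      if (!evseen[i, j + 1L]) {
        evseen[i, j + 1L] <- TRUE
        he <- c(he, max(hs[c(3, 4)]))
      }
    }
  }
  vapply(thresholds, function(t) {
    tol <- 1e-9
    sum(hv <= t + tol) - sum(he <= t + tol) + sum(hf <= t + tol)
  }, 0)
}

# exact two-tailed Mann-Whitney p by full enumeration of rank splits
oracle_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  us <- apply(splits, 2L, function(idx) {
    sum(ranks[idx]) - n1 * (n1 + 1) / 2
  })
  p_lo <- mean(us <= obs)
  p_hi <- mean(us >= obs)
  min(1, 2 * min(p_lo, p_hi))
}

# kernel density by an explicit double loop
oracle_kde <- function(values, bw, grid) {
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- 0
    for (v in values) {
      s <- s + exp(-((grid[i] - v) / bw)^2 / 2) / (bw * sqrt(2 * pi))
    }
    out[i] <- s / length(values)
  }
  out
}

# random blob mask: union of a few random discs on an n x n grid
random_mask <- function(n, seed, p_extra = 0.0) {
  set.seed(seed)
  mask <- matrix(FALSE, n, n)
  centres <- cbind(runif(3, 4, n - 3), runif(3, 4, n - 3))
  radii <- runif(3, 2, n / 3)
  ix <- as.matrix(expand.grid(seq_len(n), seq_len(n)))
  for (k in 1:3) {
    d <- sqrt((ix[, 1L] - centres[k, 1L])^2 + (ix[, 2L] - centres[k, 2L])^2)
    mask[ix[d <= radii[k], , drop = FALSE]] <- TRUE
  }
  if (p_extra > 0) {
    mask <- mask | matrix(runif(n * n) < p_extra, n, n)
  }
  mask
}

rotate_outline <- function(poly, angle) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  polygon_outline(poly$vertices %*% t(rot), label = poly$label,
                  time_h = poly$time_h)
}

# purity of a 2-cluster labelling against known group membership
cluster_purity <- function(labels, truth) {
  tab <- table(labels, truth)
  sum(apply(tab, 1L, max)) / length(labels)
}
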