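# Skeleton graph construction and network features.
#
# A "network" is one 26-connected component of the skeleton: junction nodes
# (voxels with >= 3 skeleton neighbors, adjacent candidates merged into one
# cluster), endpoints (1 neighbor), and branches traced between them. Branch
# length sums the Euclidean inter-voxel steps (1, sqrt 2, sqrt 3 times the
# voxel size), not the voxel count.

# linear index (1-based) <-> (z, y, x) helpers for dim d
lin_of <- function(zyx, d) {
  (zyx[, 1L]) + d[1L] * ((zyx[, 2L] - 1L) + d[2L] * (zyx[, 3L] - 1L))
}

neighbors26_of <- function(lin, d) {
  zyx <- arrayInd(lin, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  out <- vector("list", length(lin))
  for (i in seq_along(lin)) {
    nb <- sweep(offs, 2L, as.integer(zyx[i, ]), "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    out[[i]] <- lin_of(nb[ok, , drop = FALSE], d)
  }
  out
}

path_length_um <- function(zyx, voxel_size) {
  if (nrow(zyx) < 2L) return(0)
  sum(sqrt(rowSums(diff(zyx)^2))) * voxel_size
}

#' Build skeleton networks from a skeleton voxel set
#'
#' Classifies skeleton voxels by their 26-neighbor count (endpoint = 1,
#' slab = 2, junction candidate >= 3), merges 26-adjacent junction candidates
#' into junction nodes, traces the branches between nodes and endpoints, and
#' groups everything by connected component. Two cleanups follow, both
#' reflecting the finite voxel size: junction nodes connected by a branch
#' shorter than `cfg$merge_junction_um` collapse into one node (a single
#' anatomical junction split by the thinning discretization), and terminal
#' spurs shorter than `cfg$prune_spurs_um` are removed, dissolving any
#' junction thereby reduced to a pass-through.
#'
#' @param skeleton logical 3D array from [skeletonize_3d()].
#' @param voxel_size voxel edge length in micrometres.
#' @param cfg a [bc_config()] (cleanup thresholds).
#' @return List of `skeleton_network` objects, each with `component`,
#'   `nodes` (data frame: id, representative voxel, degree), `branches`
#'   (data frame: from, to, length_um; 0 marks a free end) and
#'   `branch_voxels` (list of (z, y, x) matrices).
#' @export
build_networks <- function(skeleton, voxel_size = 0.3, cfg = bc_config()) {
  skeleton <- as_mask3d(skeleton)
  d <- dim(skeleton)
  idx <- which(skeleton)
  if (length(idx) == 0L) return(list())
  comp <- cpp_label3d(skeleton, d, 26L)[idx]
  deg <- cpp_neighbor_count26(skeleton, d)[idx]
  is_cand <- deg >= 3L

  # junction clusters: 26-components of the candidate voxels
  cand_mask <- array(FALSE, d)
  cand_mask[idx[is_cand]] <- TRUE
  clu_full <- cpp_label3d(cand_mask, d, 26L)
  clu <- clu_full[idx]                      # 0 for non-candidates
  nclu <- max(clu, 0L)

  lookup <- function(lin) match(lin, idx)   # linear index -> row in idx

  nbrs <- neighbors26_of(idx, d)
  nbrs <- lapply(nbrs, function(nb) nb[!is.na(match(nb, idx))])

  visited <- rep(FALSE, length(idx))        # slab voxels consumed by a trace
  branches <- list()

  trace_from <- function(start_row, from_clu) {
    # start_row: row index of the first slab voxel of the branch
    path <- start_row
    visited[start_row] <<- TRUE
    prev_rows <- start_row
    repeat {
      cur <- path[length(path)]
      nb_rows <- lookup(nbrs[[cur]])
      cand_nb <- nb_rows[is_cand[nb_rows]]
      # terminate into a junction cluster (avoid bouncing straight back into
      # the start cluster from its first slab voxel)
      if (length(cand_nb)) {
        end_ok <- clu[cand_nb] != from_clu | length(path) >= 2L
        if (any(end_ok)) {
          endv <- cand_nb[end_ok][1L]
          return(list(path = path, end_row = endv, to = clu[endv]))
        }
      }
      step <- nb_rows[!is_cand[nb_rows] & !visited[nb_rows]]
      if (length(step) == 0L) {
        return(list(path = path, end_row = NA_integer_, to = 0L))
      }
      nxt <- step[1L]
      visited[nxt] <<- TRUE
      path <- c(path, nxt)
    }
  }

  zyx <- arrayInd(idx, d)

  # branches leaving junction clusters
  if (nclu > 0L) {
    for (ci in seq_len(nclu)) {
      for (v in which(clu == ci)) {
        for (u in lookup(nbrs[[v]])) {
          if (is_cand[u] || visited[u]) next
          tr <- trace_from(u, ci)
          rows <- c(v, tr$path, if (!is.na(tr$end_row)) tr$end_row)
          branches[[length(branches) + 1L]] <-
            list(from = ci, to = tr$to, rows = rows,
                 component = comp[v])
        }
      }
    }
  }
  # free paths: start at unvisited endpoints not adjacent to clusters
  for (v in which(deg == 1L & !visited & !is_cand)) {
    if (visited[v]) next
    tr <- trace_from(v, 0L)
    rows <- c(tr$path, if (!is.na(tr$end_row)) tr$end_row)
    branches[[length(branches) + 1L]] <-
      list(from = 0L, to = tr$to, rows = rows, component = comp[v])
  }
  # remaining slab voxels form junction-free cycles
  for (v in which(deg == 2L & !visited & !is_cand)) {
    if (visited[v]) next
    tr <- trace_from(v, 0L)
    branches[[length(branches) + 1L]] <-
      list(from = 0L, to = 0L, rows = c(tr$path, tr$path[1L]),
           component = comp[v], cyclic = TRUE)
  }
  # isolated single voxels (degree 0): zero-length free branch
  for (v in which(deg == 0L)) {
    branches[[length(branches) + 1L]] <-
      list(from = 0L, to = 0L, rows = v, component = comp[v])
  }

  for (b in seq_along(branches)) {
    branches[[b]]$length_um <-
      path_length_um(zyx[branches[[b]]$rows, , drop = FALSE], voxel_size)
  }

  # ---- cleanup: short junction-junction merges, then spur pruning ----------
  parent <- seq_len(max(nclu, 1L))
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nclu > 0L && length(branches)) {
    repeat {
      merged <- FALSE
      for (b in seq_along(branches)) {
        br <- branches[[b]]
        if (br$from == 0L || br$to == 0L) next
        f <- find_root(br$from); t <- find_root(br$to)
        if (f != t && br$length_um < cfg$merge_junction_um) {
          parent[max(f, t)] <- min(f, t)
          merged <- TRUE
        }
      }
      if (!merged) break
    }
    for (b in seq_along(branches)) {
      if (branches[[b]]$from > 0L) {
        branches[[b]]$from <- find_root(branches[[b]]$from)
      }
      if (branches[[b]]$to > 0L) {
        branches[[b]]$to <- find_root(branches[[b]]$to)
      }
    }
    # drop branches absorbed into a merged junction (both ends now one node)
    absorbed <- vapply(branches, function(br) {
      br$from > 0L && br$from == br$to &&
        br$length_um < cfg$merge_junction_um && is.null(br$cyclic)
    }, TRUE)
    branches <- branches[!absorbed]
  }

  repeat {
    if (!length(branches)) break
    degs <- table(factor(c(
      vapply(branches, function(b) b$from, 0L),
      vapply(branches, function(b) b$to, 0L)), exclude = 0L))
    spur <- vapply(branches, function(br) {
      xor(br$from == 0L, br$to == 0L) && br$length_um < cfg$prune_spurs_um
    }, TRUE)
    if (any(spur)) {
      branches <- branches[!spur]
      next
    }
    # dissolve pass-through nodes (degree 2 after pruning/merging)
    two <- as.integer(names(degs)[degs == 2L])
    two <- setdiff(two, 0L)
    if (!length(two)) break
    nd <- two[1L]
    inc <- which(vapply(branches, function(b) b$from == nd || b$to == nd, TRUE))
    if (length(inc) == 1L) {
      # both ends on nd: a loop; reclassify ends as free and keep
      branches[[inc]]$from <- 0L
      branches[[inc]]$to <- 0L
      next
    }
    b1 <- branches[[inc[1L]]]; b2 <- branches[[inc[2L]]]
    orient <- function(b, nd) {
      # voxel rows ordered away from nd
      if (b$to == nd) list(rows = b$rows, far = b$from)
      else list(rows = rev(b$rows), far = b$to)
    }
    o1 <- orient(b1, nd); o2 <- orient(b2, nd)
    branches[[inc[1L]]] <- list(
      from = o1$far, to = o2$far,
      rows = c(rev(o1$rows), o2$rows[-1L]),
      component = b1$component,
      length_um = b1$length_um + b2$length_um)
    branches <- branches[-inc[2L]]
  }

  if (!length(branches)) return(list())

  clu_roots <- vapply(clu, function(cl) {
    if (cl > 0L) find_root(cl) else 0L
  }, 0L)

  comps <- sort(unique(vapply(branches, function(b) b$component, 0L)))
  out <- lapply(comps, function(cc) {
    brs <- branches[vapply(branches, function(b) b$component == cc, TRUE)]
    ends <- c(vapply(brs, function(b) b$from, 0L),
              vapply(brs, function(b) b$to, 0L))
    node_ids <- sort(setdiff(unique(ends), 0L))
    nodes <- if (length(node_ids)) {
      data.frame(
        node = node_ids,
        degree = vapply(node_ids, function(nd) sum(ends == nd), 0L),
        t(vapply(node_ids, function(nd) {
          colMeans(zyx[clu_roots == nd, , drop = FALSE])
        }, numeric(3L))))
    } else {
      data.frame(node = integer(0L), degree = integer(0L))
    }
    if (length(node_ids)) names(nodes)[3:5] <- c("z", "y", "x")
    structure(list(
      component = cc,
      nodes = nodes,
      branches = data.frame(
        from = vapply(brs, function(b) b$from, 0L),
        to = vapply(brs, function(b) b$to, 0L),
        length_um = vapply(brs, function(b) b$length_um, 0)),
      branch_voxels = lapply(brs, function(b) {
        zyx[b$rows, , drop = FALSE]
      }),
      total_length_um = sum(vapply(brs, function(b) b$length_um, 0)),
      voxel_size = voxel_size
    ), class = "skeleton_network")
  })
  out
}

#' @export
print.skeleton_network <- function(x, ...) {
  cat(sprintf(
    "skeleton_network (component %d): %d branches, %.1f um total, %d junctions\n",
    x$component, nrow(x$branches), x$total_length_um,
    sum(x$nodes$degree >= 3)))
  invisible(x)
}

#' Features of the largest network in a structure
#'
#' Selects the network with the greatest total branch length (ties broken by
#' junction count, then component id) and measures the published feature set:
#' total length, triple/quadruple/total junction counts, and per-branch mean
#' diameters taken from the local thickness map.
#'
#' @param networks list of networks from [build_networks()].
#' @param thickness local thickness array in micrometres
#'   ([local_thickness()]), or `NULL` to skip diameters.
#' @param structure_id identifier used in the feature row.
#' @return An object of class `network_features`; if `networks` is empty, a
#'   zero row flagged with `no_network = TRUE`.
#' @export
largest_network_features <- function(networks, thickness = NULL,
                                     structure_id = "structure") {
  if (length(networks) == 0L) {
    return(structure(list(structure_id = structure_id, no_network = TRUE,
                          total_length_um = 0, n_triple = 0L, n_quad = 0L,
                          n_junctions = 0L,
                          branch_diameters_um = numeric(0L)),
                     class = "network_features"))
  }
  lens <- vapply(networks, function(n) n$total_length_um, 0)
  juncs <- vapply(networks, function(n) sum(n$nodes$degree >= 3L), 0L)
  ord <- order(-lens, -juncs, vapply(networks, function(n) n$component, 0L))
  net <- networks[[ord[1L]]]
  degs <- net$nodes$degree
  diam <- if (is.null(thickness)) {
    rep(NA_real_, nrow(net$branches))
  } else {
    d <- dim(thickness)
    vapply(net$branch_voxels, function(zyx) {
      mean(thickness[lin_of(zyx, d)])
    }, 0)
  }
  structure(list(
    structure_id = structure_id, no_network = FALSE,
    total_length_um = net$total_length_um,
    n_triple = sum(degs == 3L),
    n_quad = sum(degs == 4L),
    n_junctions = sum(degs >= 3L),
    branch_diameters_um = diam,
    network = net
  ), class = "network_features")
}

#' @export
print.network_features <- function(x, ...) {
  cat(sprintf(
    paste0("network_features '%s': length %.1f um, junctions %d ",
           "(%d triple, %d quadruple), %d branches\n"),
    x$structure_id, x$total_length_um, x$n_junctions, x$n_triple, x$n_quad,
    length(x$branch_diameters_um)))
  invisible(x)
}

#' One-row feature table from network features
#'
#' @param features a [largest_network_features()] result (or list of them).
#' @param condition optional condition label column.
#' @return Data frame suitable for [write_features()], with the per-branch
#'   diameters as a list-column.
#' @export
features_table <- function(features, condition = NA_character_) {
  if (inherits(features, "network_features")) features <- list(features)
  rows <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    data.frame(structure_id = f$structure_id,
               condition = condition[[min(i, length(condition))]],
               total_length_um = f$total_length_um,
               n_triple = f$n_triple, n_quad = f$n_quad,
               n_junctions = f$n_junctions,
               no_network = isTRUE(f$no_network))
  })
  out <- do.call(rbind, rows)
  out$branch_diameters_um <- lapply(features, function(f) {
    f$branch_diameters_um
  })
  out
}

#' Branch diameter histogram in 0.25 um bins
#'
#' Half-open bins `[k b, (k+1) b)` over the branch diameters, expressed as a
#' percentage of the number of branches; percentages sum to 100.
#'
#' @param diameters positive branch diameters in micrometres.
#' @param bin bin width in micrometres (default 0.25).
#' @return List with `breaks` (edges), `mid` (bin centres), `count` and
#'   `percent`.
#' @export
diameter_histogram <- function(diameters, bin = 0.25) {
  if (length(diameters) == 0L) stop("no diameters to histogram")
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("diameters must be positive and finite")
  }
  k <- floor(diameters / bin)
  kmax <- max(k)
  count <- tabulate(k + 1L, kmax + 1L)
  list(breaks = (0:(kmax + 1L)) * bin,
       mid = ((0:kmax) + 0.5) * bin,
       count = count,
       percent = 100 * count / sum(count))
}

#' Run the full bile-canaliculi pipeline on a two-channel volume
#'
#' Median smoothing, per-channel IsoData thresholding, channel overlap, lumen
#' completion, size/border filtering, local thickness, skeletonization, and
#' network feature extraction, with per-stage voxel/object counts logged. A
#' stage that empties the mask aborts with a diagnostic naming the stage.
#'
#' @param apical,cortical numeric 3D intensity arrays (z, y, x), equal shape.
#' @param voxel_size isotropic voxel edge length in micrometres (default 0.3).
#' @param cfg a [bc_config()].
#' @param structure_id identifier for the feature row.
#' @return An object of class `bc_result`: `features`
#'   ([largest_network_features()]), `networks`, `masks` (overlap, completed,
#'   filtered, skeleton), `thickness`, `report` (filter report), `log`
#'   (stage counts), `config`.
#' @export
run_bc_pipeline <- function(apical, cortical, voxel_size = 0.3,
                            cfg = bc_config(), structure_id = "structure") {
  if (!identical(dim(apical), dim(cortical))) {
    stop("apical and cortical volumes must share one shape")
  }
  if (length(dim(apical)) != 3L) stop("expected 3D arrays (z, y, x)")
  log <- list()
  ap <- median_filter_3d(apical, cfg$median_radius)
  co <- median_filter_3d(cortical, cfg$median_radius)
  th_ap <- tryCatch(isodata_threshold(ap), error = function(e) {
    stop("threshold stage (apical): ", conditionMessage(e), call. = FALSE)
  })
  th_co <- tryCatch(isodata_threshold(co), error = function(e) {
    stop("threshold stage (cortical): ", conditionMessage(e), call. = FALSE)
  })
  log$threshold <- list(apical = th_ap$threshold,
                        cortical = th_co$threshold,
                        apical_vox = sum(th_ap$mask),
                        cortical_vox = sum(th_co$mask))
  overlap <- apical_overlap(th_ap$mask, th_co$mask)
  log$overlap_vox <- sum(overlap)
  if (log$overlap_vox == 0L) {
    stop("overlap stage: no voxels shared by the two segmentations",
         call. = FALSE)
  }
  completed <- complete_lumina(overlap, cfg)
  log$completed_vox <- sum(completed)
  filt <- filter_objects(completed, cfg)
  log$filter <- filt$report
  if (sum(filt$mask) == 0L) {
    stop("object filter stage: all objects removed (size/border rules)",
         call. = FALSE)
  }
  thickness <- local_thickness(filt$mask, voxel_size)
  skeleton <- skeletonize_3d(filt$mask)
  log$skeleton_vox <- sum(skeleton)
  networks <- build_networks(skeleton, voxel_size, cfg)
  log$n_networks <- length(networks)
  features <- largest_network_features(networks, thickness, structure_id)
  structure(list(features = features, networks = networks,
                 masks = list(overlap = overlap, completed = filt$mask,
                              skeleton = skeleton),
                 thickness = thickness, report = filt$report, log = log,
                 config = cfg),
            class = "bc_result")
}

#' @export
print.bc_result <- function(x, ...) {
  cat("bile-canaliculi pipeline result\n")
  cat(sprintf("  thresholds: apical %.1f, cortical %.1f\n",
              x$log$threshold$apical, x$log$threshold$cortical))
  cat(sprintf("  objects kept: %d (removed: %d size, %d border)\n",
              x$report$kept, x$report$removed_size, x$report$removed_border))
  cat(sprintf("  networks: %d\n", x$log$n_networks))
  print(x$features)
  invisible(x)
}
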