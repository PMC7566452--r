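#' Build a segment skeleton of a tree cloud
#'
#' The cover step of the cylinder model: a k-nearest-neighbour graph is built
#' over the (optionally voxel-thinned) points, geodesic distances from the
#' lowest point are computed along it, points are binned into shells of width
#' `patch_size_m` by that distance, and each shell is split into connected
#' clusters — the segments. Each segment stores its centroid and member
#' points; its parent is the nearest cluster in the previous shell. The trunk
#' is the root-to-tip path that follows maximum cumulative point count (ties
#' broken by larger shell radius), a proxy for the monopodial main stem.
#'
#' @param cloud a [tree_cloud()].
#' @param patch_size_m shell width in m.
#' @param k neighbours per point in the graph.
#' @param voxel_m optional voxel size for thinning before graph construction
#'   (NULL disables). Fitting later uses all original points.
#' @param max_orphan_frac error threshold: if more than this fraction of
#'   points falls outside the largest connected component the cloud is
#'   declared disconnected; smaller orphan fractions (sparse branch-tip
#'   fragments) are dropped with a log message.
#' @param retry_denser on excess disconnection, retry once with a 3x denser
#'   neighbour graph before raising the error.
#' @return Object of class `tree_skeleton`.
#' @export
build_skeleton <- function(cloud, patch_size_m = 0.5, k = 8L, voxel_m = NULL,
                           max_orphan_frac = 0.2, retry_denser = TRUE) {
  stopifnot(inherits(cloud, "tree_cloud"))
  assert_scalar_num(patch_size_m, "patch_size_m", 0, strict_lower = TRUE)
  pts <- cloud$points
  idx_orig <- seq_len(nrow(pts))
  if (!is.null(voxel_m) && voxel_m > 0) {
    key <- paste(floor(pts[, 1] / voxel_m), floor(pts[, 2] / voxel_m),
                 floor(pts[, 3] / voxel_m))
    keep <- !duplicated(key)
    pts <- pts[keep, , drop = FALSE]
    idx_orig <- idx_orig[keep]
  }
  n <- nrow(pts)
  if (n < 10L) stopf("too few points (%d) for a skeleton", n)
  spacing_guess <- max((prod(apply(pts, 2, function(c) diff(range(c)) + 1e-6)) /
                          n)^(1 / 3), 1e-4)
  ed <- cpp_knn_edges(pts, as.integer(k), cell = 2 * spacing_guess)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(ed[, 1:2]))
  igraph::E(g)$weight <- ed[, 3]
  g <- igraph::simplify(g, edge.attr.comb = "min")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    main <- which.max(comp$csize)
    orphan_frac <- 1 - comp$csize[main] / n
    # small orphan fragments (sparse branch tips) are dropped; a genuinely
    # split cloud — any rival component of substance — is an error, after
    # one retry with a denser graph (anisotropic sampling can starve the
    # nearest-neighbour lists of cross-ring links)
    if (orphan_frac > max_orphan_frac) {
      if (retry_denser)
        return(build_skeleton(cloud, patch_size_m = patch_size_m,
                              k = 3L * k, voxel_m = voxel_m,
                              max_orphan_frac = max_orphan_frac,
                              retry_denser = FALSE))
      stopf("disconnected cloud: %d components, orphan fraction %.1f%%",
            comp$no, 100 * orphan_frac)
    }
    tb_log("dropping %.2f%% orphan points outside the main component",
           100 * orphan_frac)
    keep <- comp$membership == main
    pts <- pts[keep, , drop = FALSE]
    idx_orig <- idx_orig[keep]
    g <- igraph::induced_subgraph(g, which(keep))
    n <- nrow(pts)
  }
  root <- which.min(pts[, 3])
  # geodesic height from the basal band (multi-source via a zero-weight
  # virtual root), so shells are true distance-up-the-structure bands rather
  # than arcs around the lowest single point
  med_edge <- median(ed[, 3])
  base_band <- which(pts[, 3] <= pts[root, 3] +
                       max(2 * med_edge, patch_size_m / 8))
  gv <- igraph::add_vertices(g, 1L)
  virt <- igraph::vcount(gv)
  gv <- igraph::add_edges(gv, rbind(rep(virt, length(base_band)), base_band),
                          weight = 0)
  dist <- as.vector(igraph::distances(gv, v = virt,
                                      weights = igraph::E(gv)$weight))[-virt]
  shell <- pmin(floor(dist / patch_size_m), max(0, floor(max(dist[is.finite(dist)]) /
                                                           patch_size_m)))
  segs <- list()
  seg_of_point <- integer(n)
  for (s in sort(unique(shell))) {
    vs <- which(shell == s)
    sub <- igraph::induced_subgraph(g, vs)
    mem <- igraph::components(sub)$membership
    for (cl in seq_len(max(mem))) {
      members <- vs[mem == cl]
      segs[[length(segs) + 1L]] <- list(
        id = length(segs) + 1L, shell = s, members = members,
        centroid = colMeans(pts[members, , drop = FALSE]),
        n = length(members))
      seg_of_point[members] <- length(segs)
    }
  }
  # parent links: nearest segment (by centroid) in the previous shell
  shells <- vapply(segs, `[[`, 0, "shell")
  cents <- do.call(rbind, lapply(segs, `[[`, "centroid"))
  parent <- rep(NA_integer_, length(segs))
  for (i in seq_along(segs)) {
    s <- shells[i]
    if (s == min(shells)) next
    prev <- which(shells == s - 1L)
    if (!length(prev)) prev <- which(shells < s)
    if (!length(prev)) next
    d2 <- rowSums((cents[prev, , drop = FALSE] -
                     matrix(cents[i, ], length(prev), 3, byrow = TRUE))^2)
    parent[i] <- prev[which.min(d2)]
  }
  # trunk path: from root segment, follow child with max cumulative count
  counts <- vapply(segs, `[[`, 0, "n")
  children <- split(seq_along(segs), factor(parent, levels = seq_along(segs)))
  cum <- counts
  for (i in order(shells, decreasing = TRUE)) {
    p <- parent[i]
    if (!is.na(p)) cum[p] <- cum[p] + cum[i]
  }
  is_trunk <- logical(length(segs))
  cur <- which(shells == min(shells))[1]
  prev_dir <- c(0, 0, 1)
  for (s in sort(unique(shells[shells > min(shells)]))) {
    is_trunk[cur] <- TRUE
    cands <- which(shells == s)
    if (!length(cands)) next
    kids <- intersect(cands, children[[as.character(cur)]])
    dirs <- cents[cands, , drop = FALSE] -
      matrix(cents[cur, ], length(cands), 3, byrow = TRUE)
    nrm <- sqrt(rowSums(dirs^2)); nrm[nrm < 1e-9] <- 1
    cosang <- as.vector(dirs %*% prev_dir) / nrm
    if (length(kids)) {
      # the monopodial stem continues straight: prefer the heaviest subtree
      # among direction-consistent children (near-horizontal whorl branches
      # are excluded even when an occlusion stripe splits the trunk cluster)
      ik <- match(kids, cands)
      elig <- ik[cosang[ik] > 0.3]
      if (!length(elig)) elig <- ik
      best <- elig[order(-cum[cands[elig]], -counts[cands[elig]])][1]
    } else {
      # the stem cluster above attached to a sibling arc: hop to the nearest
      # direction-consistent cluster in this shell, or stop if none is close
      ok <- which(nrm < 3 * patch_size_m & cosang > 0.3)
      if (!length(ok)) break
      best <- ok[which.min(nrm[ok])]
    }
    # smooth the reference direction so one occlusion-shifted centroid does
    # not steer the path off the stem
    prev_dir <- 0.8 * prev_dir + 0.2 * dirs[best, ] / nrm[best]
    prev_dir <- prev_dir / sqrt(sum(prev_dir^2))
    cur <- cands[best]
  }
  is_trunk[cur] <- TRUE
  structure(list(segments = segs, parent = parent, is_trunk = is_trunk,
                 points = pts, point_index = idx_orig, root = root,
                 patch_size_m = patch_size_m, geodesic = dist,
                 cloud_id = cloud$tree_id),
            class = "tree_skeleton")
}

#' @export
print.tree_skeleton <- function(x, ...) {
  cat(sprintf("<tree_skeleton> '%s': %d segments over %d shells (patch %.2f m), %d trunk segments\n",
              x$cloud_id, length(x$segments),
              length(unique(vapply(x$segments, `[[`, 0, "shell"))),
              x$patch_size_m, sum(x$is_trunk)))
  invisible(x)
}

#' Fit a cylinder model to a skeletonised tree
#'
#' One cylinder per skeleton segment. The axis runs from the parent
#' centroid to the segment centroid (root and tip segments are extended to
#' the extreme point projections so lengths telescope along each chain); the
#' radius is the least-squares solution of
#' \eqn{\min_r \sum_i (d_i - r)^2}, i.e. the mean point-to-axis distance.
#' Segments with fewer than `min_points` points inherit their parent's
#' radius. Volume is `sum(pi r^2 L)` and surface area the lateral
#' `sum(2 pi r L)` (no end caps — caps would double-count at joints).
#'
#' @param skeleton a [build_skeleton()] result.
#' @param min_points minimum points for an independent radius estimate.
#' @return Object of class `qsm_model` with `cylinders` (data frame),
#'   `total_volume_m3`, `trunk_volume_m3`, `branch_volume_m3`,
#'   `surface_area_m2`.
#' @export
fit_cylinders <- function(skeleton, min_points = 10L) {
  stopifnot(inherits(skeleton, "tree_skeleton"))
  segs <- skeleton$segments
  parent <- skeleton$parent
  pts <- skeleton$points
  ncyl <- length(segs)
  cents <- do.call(rbind, lapply(segs, `[[`, "centroid"))
  rows <- vector("list", ncyl)
  radius <- rep(NA_real_, ncyl)
  order_idx <- order(vapply(segs, `[[`, 0, "shell"))
  for (i in order_idx) {
    seg <- segs[[i]]
    p <- parent[i]
    start <- if (is.na(p)) {
      rp <- pts[skeleton$root, ]
      c(cents[i, 1], cents[i, 2], rp[3]) # root: drop axis to the lowest z
    } else cents[p, ]
    axis <- cents[i, ] - start
    L0 <- sqrt(sum(axis^2))
    if (L0 < 1e-9) axis <- c(0, 0, 1) else axis <- axis / L0
    mp <- pts[seg$members, , drop = FALSE]
    rel <- sweep(mp, 2, start)
    t_proj <- rel %*% axis
    # chain-consistent length: parent centroid -> own centroid, extended at
    # the chain ends so segment lengths telescope to the full path length
    has_child <- i %in% parent
    t_lo <- if (is.na(p)) min(0, min(t_proj)) else 0
    # branch base: start at the parent trunk's surface, not its axis, so the
    # overlap inside the trunk is not double-counted
    if (!is.na(p) && skeleton$is_trunk[p] && !skeleton$is_trunk[i] &&
        !is.na(radius[p]))
      t_lo <- min(radius[p], 0.9 * L0)
    t_hi <- if (has_child) L0 else max(L0, max(t_proj))
    L <- max(t_hi - t_lo, 1e-6)
    perp <- rel - t_proj %*% t(axis)
    d <- sqrt(rowSums(perp^2))
    # the cylinder spans [t_lo, t_hi]; estimate the radius from the points
    # that actually project into that span (own members plus the parent's,
    # whose upper half lies inside it), so tapered stems are unbiased
    cand <- seg$members
    if (!is.na(p)) cand <- c(cand, segs[[p]]$members)
    crel <- sweep(pts[cand, , drop = FALSE], 2, start)
    ct <- crel %*% axis
    inside <- ct >= t_lo - 1e-9 & ct <= t_hi + 1e-9
    d_span <- if (sum(inside) >= min_points) {
      cperp <- crel[inside, , drop = FALSE] -
        ct[inside, , drop = FALSE] %*% t(axis)
      sqrt(rowSums(cperp^2))
    } else d
    # guard against points of an attached branch stub inflating a trunk
    # radius: distances beyond twice the median are not this cylinder's
    # surface (flute peaks stay well inside the cutoff)
    d_span <- d_span[d_span <= 2 * median(d_span)]
    r_own <- if (length(d_span)) mean(d_span) else mean(d)
    if (seg$n >= min_points) {
      radius[i] <- r_own
    } else if (!is.na(p) && !is.na(radius[p])) {
      # sparse segment: constrain by the parent's radius rather than trust a
      # handful of points, but never let a thin branch inherit a fat trunk
      radius[i] <- min(r_own, radius[p])
      tb_log("segment %d has %d points; constraining radius by parent", i,
             seg$n)
    } else radius[i] <- max(r_own, 1e-4)
    rows[[i]] <- data.frame(
      id = i, parent_id = ifelse(is.na(p), NA_integer_, p),
      start_x = start[1] + t_lo * axis[1], start_y = start[2] + t_lo * axis[2],
      start_z = start[3] + t_lo * axis[3],
      axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
      length_m = L, radius_m = radius[i],
      is_trunk = skeleton$is_trunk[i], n_points = seg$n)
  }
  cyl <- do.call(rbind, rows)
  vol <- pi * cyl$radius_m^2 * cyl$length_m
  surf <- 2 * pi * cyl$radius_m * cyl$length_m
  structure(list(cylinders = cyl,
                 total_volume_m3 = sum(vol),
                 trunk_volume_m3 = sum(vol[cyl$is_trunk]),
                 branch_volume_m3 = sum(vol[!cyl$is_trunk]),
                 surface_area_m2 = sum(surf),
                 patch_size_m = skeleton$patch_size_m,
                 cloud_id = skeleton$cloud_id),
            class = "qsm_model")
}

#' @export
print.qsm_model <- function(x, ...) {
  cat(sprintf("<qsm_model> '%s': %d cylinders (patch %.2f m)\n", x$cloud_id,
              nrow(x$cylinders), x$patch_size_m))
  cat(sprintf("  volume %.2f m^3 (trunk %.2f + branch %.2f), surface %.1f m^2\n",
              x$total_volume_m3, x$trunk_volume_m3, x$branch_volume_m3,
              x$surface_area_m2))
  invisible(x)
}

#' Fit a single QSM to a cloud
#'
#' Convenience wrapper: [build_skeleton()] then [fit_cylinders()].
#' @inheritParams build_skeleton
#' @param ... passed to [build_skeleton()].
#' @return A `qsm_model`.
#' @export
fit_qsm <- function(cloud, patch_size_m = 0.5, ...) {
  fit_cylinders(build_skeleton(cloud, patch_size_m = patch_size_m, ...))
}

#' QSM ensemble over structure parameters
#'
#' Fits multiple cylinder models while varying the shell width over
#' `patch_sizes` and jittering the point set (a seeded ~2% random point
#' drop) between runs, mirroring the practice of fitting several structure
#' models per tree and reporting their mean and standard deviation. The
#' ensemble SD is the tree's TLS volume uncertainty used downstream.
#'
#' @param cloud a [tree_cloud()].
#' @param patch_sizes numeric vector of shell widths (m).
#' @param runs_per_size runs per shell width.
#' @param seed integer seed; the ensemble is deterministic given it.
#' @param jitter_frac fraction of points randomly dropped per run (the first
#'   run per patch size keeps all points).
#' @param ... passed to [build_skeleton()].
#' @return Object of class `qsm_ensemble`: `runs` (list of `qsm_model`),
#'   `volume_mean_m3`, `volume_sd_m3`, plus mean trunk/branch/surface
#'   summaries.
#' @export
qsm_ensemble <- function(cloud, patch_sizes = c(0.3, 0.5, 0.8),
                         runs_per_size = 3L, seed = 1L, jitter_frac = 0.02,
                         ...) {
  stopifnot(inherits(cloud, "tree_cloud"))
  if (length(patch_sizes) * runs_per_size < 2L)
    stopf("ensemble needs at least 2 runs")
  runs <- list()
  failures <- character(0)
  stream <- 0L
  for (ps in patch_sizes) {
    for (r in seq_len(runs_per_size)) {
      stream <- stream + 1L
      cl <- cloud
      if (r > 1L && jitter_frac > 0) {
        cl <- with_seed(sub_seed(seed, stream), {
          n <- nrow(cloud$points)
          keep <- runif(n) >= jitter_frac
          if (sum(keep) < 10L) keep[] <- TRUE
          tree_cloud(cloud$points[keep, , drop = FALSE], cloud$tree_id,
                     cloud$source)
        })
      }
      m <- tryCatch(fit_qsm(cl, patch_size_m = ps, ...),
                    error = function(e) conditionMessage(e))
      if (is.character(m)) {
        failures <- c(failures, sprintf("patch %.2f run %d: %s", ps, r, m))
      } else runs[[length(runs) + 1L]] <- m
    }
  }
  if (!length(runs))
    stopf("all QSM runs failed: %s", paste(failures, collapse = "; "))
  if (length(failures))
    tb_log("%d/%d QSM runs failed and were excluded", length(failures),
           length(failures) + length(runs))
  vols <- vapply(runs, `[[`, 0, "total_volume_m3")
  structure(list(
    runs = runs, n_runs = length(runs),
    volume_mean_m3 = mean(vols),
    volume_sd_m3 = if (length(vols) > 1) sd(vols) else 0,
    trunk_volume_m3 = mean(vapply(runs, `[[`, 0, "trunk_volume_m3")),
    branch_volume_m3 = mean(vapply(runs, `[[`, 0, "branch_volume_m3")),
    surface_area_m2 = mean(vapply(runs, `[[`, 0, "surface_area_m2")),
    failures = failures, cloud_id = cloud$tree_id),
    class = "qsm_ensemble")
}

#' @export
print.qsm_ensemble <- function(x, ...) {
  cat(sprintf("<qsm_ensemble> '%s': %d runs, volume %.2f +/- %.2f m^3\n",
              x$cloud_id, x$n_runs, x$volume_mean_m3, x$volume_sd_m3))
  cat(sprintf("  mean trunk %.2f m^3, branch %.2f m^3, surface %.1f m^2\n",
              x$trunk_volume_m3, x$branch_volume_m3, x$surface_area_m2))
  invisible(x)
}

#' @export
summary.qsm_ensemble <- function(object, ...) {
  vols <- vapply(object$runs, `[[`, 0, "total_volume_m3")
  data.frame(tree_id = object$cloud_id, n_runs = object$n_runs,
             volume_mean_m3 = object$volume_mean_m3,
             volume_sd_m3 = object$volume_sd_m3,
             volume_min_m3 = min(vols), volume_max_m3 = max(vols),
             trunk_volume_m3 = object$trunk_volume_m3,
             branch_volume_m3 = object$branch_volume_m3,
             surface_area_m2 = object$surface_area_m2)
}
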