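#' Extract a horizontal cross-section slab from a tree cloud
#'
#' Takes the points whose height above the cloud's lowest point lies in the
#' half-open slab `[z_lo, z_hi)` and collapses them onto the xy plane. All
#' slab heights in this package are relative to the lowest point of the
#' cloud, never to an external ground model.
#'
#' @param cloud a [tree_cloud()].
#' @param z_lo,z_hi slab bounds in m above the lowest point.
#' @param min_points minimum points required for downstream fitting.
#' @return Object of class `cross_section` with fields `points2d` (matrix
#'   x, y), `z_lo`, `z_hi`, `n`.
#' @export
extract_section <- function(cloud, z_lo, z_hi, min_points = 20L) {
  stopifnot(inherits(cloud, "tree_cloud"))
  if (z_lo >= z_hi) stopf("z_lo must be below z_hi")
  z <- cloud$points[, "z"] - min(cloud$points[, "z"])
  keep <- z >= z_lo & z < z_hi
  if (sum(keep) < min_points)
    stopf("insufficient points in slab [%g, %g): %d (need >= %d)",
          z_lo, z_hi, sum(keep), min_points)
  structure(list(points2d = cloud$points[keep, c("x", "y"), drop = FALSE],
                 z_lo = z_lo, z_hi = z_hi, n = sum(keep)),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> slab [%.2f, %.2f) m, %d points\n",
              x$z_lo, x$z_hi, x$n))
  invisible(x)
}

#' Least-squares circle fit to a cross-section
#'
#' Fits the circle minimising the geometric objective
#' \eqn{\sum_i (d_i - r)^2}, where \eqn{d_i} is the distance of point i from
#' the centre. A Taubin-style algebraic fit provides the initial estimate,
#' refined by Gauss-Newton on the geometric residuals. The reported `rmse`
#' is \eqn{\sqrt{\mathrm{mean}\,(d_i - r)^2}}, the quantity propagated as
#' diameter uncertainty into the allometric models.
#'
#' @param section a [extract_section()] result, or a 2-column matrix.
#' @return Object of class `circle_fit`: `center`, `radius`, `rmse`,
#'   `n_points`. The diameter is `2 * radius`.
#' @export
fit_circle <- function(section) {
  xy <- if (inherits(section, "cross_section")) section$points2d else
    as.matrix(section)
  if (nrow(xy) < 20L) stopf("need >= 20 points for a circle fit")
  x <- xy[, 1]; y <- xy[, 2]
  if (max(abs(x - mean(x))) < 1e-12 || max(abs(y - mean(y))) < 1e-12 ||
      abs(stats::cor(x, y)) > 1 - 1e-12)
    stopf("degenerate (collinear) points: circle fit undefined")
  init <- taubin_circle(x, y)
  fit <- geometric_circle(x, y, init)
  d <- sqrt((x - fit[1])^2 + (y - fit[2])^2)
  structure(list(center = c(x = fit[1], y = fit[2]), radius = fit[3],
                 rmse = sqrt(mean((d - fit[3])^2)), n_points = length(x)),
            class = "circle_fit")
}

# Taubin algebraic circle fit (SVD-free, moment form).
#' @noRd
taubin_circle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  u <- x - mx; v <- y - my
  Suu <- mean(u * u); Svv <- mean(v * v); Suv <- mean(u * v)
  z <- u * u + v * v
  Suz <- mean(u * z); Svz <- mean(v * z)
  A <- matrix(c(Suu, Suv, Suv, Svv), 2)
  b <- c(Suz, Svz) / 2
  sol <- tryCatch(solve(A, b), error = function(e) c(0, 0))
  r <- sqrt(sum(sol^2) + mean(z))
  c(mx + sol[1], my + sol[2], r)
}

# Gauss-Newton refinement of sum (d_i - r)^2 over (cx, cy, r).
#' @noRd
geometric_circle <- function(x, y, par, max_iter = 50L, tol = 1e-14) {
  for (it in seq_len(max_iter)) {
    dx <- x - par[1]; dy <- y - par[2]
    d <- sqrt(dx * dx + dy * dy)
    d[d < 1e-12] <- 1e-12
    r <- mean(d) # optimal r given centre is the mean distance
    res <- d - r
    J <- cbind(-dx / d + mean(dx / d), -dy / d + mean(dy / d))
    g <- crossprod(J, res)
    Hm <- crossprod(J)
    step <- tryCatch(solve(Hm + diag(1e-12, 2), g), error = function(e) c(0, 0))
    par <- c(par[1] - step[1], par[2] - step[2], r)
    if (sqrt(sum(step^2)) < tol * (1 + abs(r))) break
  }
  dx <- x - par[1]; dy <- y - par[2]
  par[3] <- mean(sqrt(dx * dx + dy * dy))
  par
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> centre (%.3f, %.3f) m, diameter %.3f m, RMSE %.4f m (n = %d)\n",
              x$center[1], x$center[2], 2 * x$radius, x$rmse, x$n_points))
  invisible(x)
}

#' Alpha-shape (concave hull) fit to a cross-section
#'
#' Builds the Delaunay triangulation of the section points and keeps the
#' triangles whose circumradius is at most `1/alpha`; the kept complex is the
#' alpha shape. Convention: `alpha` is in m^-1 and larger alpha means a
#' tighter shape (alpha = 0 limit is the convex hull). This matches the
#' Python `alphashape` toolbox semantics, so a tightness of 4.0 reproduces
#' the behaviour commonly used for 20-cm stem slabs; alpha conventions
#' differ between libraries, so the definition here is normative for this
#' package.
#'
#' Connected components of the kept complex smaller than `min_area_frac` of
#' the largest one are discarded as noise; the substantive components are
#' retained (an occluded slab legitimately splits into arcs). If nothing is
#' kept, or the kept complex covers less than a quarter of the section
#' points (the shape has disintegrated into fragments), the alpha is
#' considered degenerate and an error is raised.
#'
#' Because TLS samples only the stem *surface*, a slab is an annular band of
#' points and the kept complex is a ring; the reported cross-section `area`
#' is therefore the region enclosed by the complex's outer boundary loop
#' (shoelace area), i.e. the area of the non-circular section the band
#' outlines — solid sections (where the complex has no hole) give the same
#' number as the summed triangle area.
#'
#' The functional diameter is `fdbh = 2*sqrt(area/pi)` (diameter of the
#' circle of equivalent area). `rmse` is the root-mean-square distance to
#' the boundary polyline over the input points lying within `rmse_band` (5
#' cm) of the boundary — the package's documented convention for the
#' "RMSE of fit" of a concave hull.
#'
#' @param section a [extract_section()] result or 2-column matrix.
#' @param alpha tightness in m^-1 (> 0).
#' @param min_area_frac components below this fraction of the largest
#'   component's area are discarded.
#' @param rmse_band band width (m) around the boundary for the RMSE.
#' @param max_points sections larger than this are thinned deterministically
#'   before triangulation.
#' @return Object of class `alpha_shape_fit`: `boundary` (list of closed
#'   band-edge polygons), `outline` (closed outer-envelope polygon used for
#'   the area), `area` (m^2), `complex_area` (summed area of the kept
#'   triangles themselves), `fdbh` (m), `rmse` (m), `n_points`.
#' @export
fit_alpha_shape <- function(section, alpha = 4.0, min_area_frac = 0.15,
                            rmse_band = 0.05, max_points = 6000L) {
  xy <- if (inherits(section, "cross_section")) section$points2d else
    as.matrix(section)
  if (nrow(xy) < 20L) stopf("need >= 20 points for an alpha shape")
  assert_scalar_num(alpha, "alpha", 0, strict_lower = TRUE)
  xy_all <- xy
  if (nrow(xy) > max_points)
    xy <- xy[seq(1L, nrow(xy), length.out = max_points), , drop = FALSE]
  # deterministic symmetry-breaking jitter; regular grids and perfect rings
  # are cocircular, which degrades incremental Delaunay
  scale <- max(apply(xy, 2, function(c) diff(range(c))), 1e-9)
  n <- nrow(xy)
  jit <- ((seq_len(n) * 2654435761) %% 97L - 48L) / 48
  xy_j <- xy + cbind(jit, rev(jit)) * (1e-7 * scale)
  tri <- cpp_delaunay(xy_j[, 1], xy_j[, 2])
  keep <- tri$circumradius <= 1 / alpha
  if (!any(keep))
    stopf("degenerate alpha: no triangle has circumradius <= %g m", 1 / alpha)
  tri_m <- tri$triangles[keep, , drop = FALSE]
  areas <- tri_areas(xy, tri_m)
  complex_area <- sum(areas) # raw kept-complex area, monotone in alpha
  comp <- tri_components(tri_m)
  comp_area <- tapply(areas, comp, sum)
  # occlusion can split the band into arcs: keep every substantive
  # component (>= min_area_frac of the largest), discard noise slivers
  good <- as.integer(names(comp_area)[comp_area >=
                                        min_area_frac * max(comp_area)])
  sel <- comp %in% good
  tri_m <- tri_m[sel, , drop = FALSE]
  if (sum(areas[sel]) <= 0) stopf("degenerate alpha: zero-area shape")
  covered <- unique(as.vector(tri_m))
  if (length(covered) < 0.25 * nrow(xy))
    stopf("degenerate alpha: kept complex covers only %.0f%% of the section points",
          100 * length(covered) / nrow(xy))
  loops <- boundary_loops(tri_m)
  if (!length(loops)) stopf("degenerate alpha: no closed boundary")
  boundary <- lapply(loops, function(l) xy[c(l, l[1]), , drop = FALSE])
  # cross-section area: a laser samples only the stem surface, so the kept
  # complex is a band tracing the (star-shaped) section outline — possibly
  # open where occlusion removed a sector. The enclosed area is taken from
  # the band's outer envelope: boundary vertices are binned by azimuth about
  # their centroid, the outermost vertex per bin is kept, and the resulting
  # polygon's shoelace area is reported. Occlusion gaps and alpha-bridged
  # valleys are closed with chords; solid sections reduce to the outer
  # boundary polygon.
  bv <- unique(unlist(loops))
  # azimuth origin: algebraic circle-fit centre of the whole section, a
  # robust stand-in for the stem axis even when occlusion removes a sector
  # (the vertex centroid would shift and break star-shapedness)
  ctr <- taubin_circle(xy_all[, 1], xy_all[, 2])
  cx <- ctr[1]; cy <- ctr[2]
  ang <- atan2(xy[bv, 2] - cy, xy[bv, 1] - cx)
  rad <- sqrt((xy[bv, 1] - cx)^2 + (xy[bv, 2] - cy)^2)
  nbins <- min(720L, max(36L, length(bv) %/% 3L))
  bin <- floor((ang + pi) / (2 * pi) * nbins)
  outer_idx <- vapply(split(seq_along(bv), bin),
                      function(ii) ii[which.max(rad[ii])], 1L)
  ord <- bv[outer_idx[order(ang[outer_idx])]]
  px <- xy[ord, 1]; py <- xy[ord, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  area <- abs(sum(px * qy - qx * py)) / 2
  outline <- cbind(x = c(px, px[1]), y = c(py, py[1]))
  segs <- do.call(rbind, lapply(boundary, function(b)
    cbind(b[-nrow(b), 1], b[-nrow(b), 2], b[-1, 1], b[-1, 2])))
  d <- cpp_polyline_dist(xy_all[, 1], xy_all[, 2],
                         segs[, 1], segs[, 2], segs[, 3], segs[, 4])
  near <- d <= rmse_band
  rmse <- if (any(near)) sqrt(mean(d[near]^2)) else 0
  structure(list(boundary = boundary, outline = outline, area = area,
                 complex_area = complex_area,
                 fdbh = 2 * sqrt(area / pi), rmse = rmse,
                 n_points = nrow(xy_all), alpha = alpha),
            class = "alpha_shape_fit")
}

#' @noRd
tri_areas <- function(xy, tri_m) {
  x1 <- xy[tri_m[, 1], 1]; y1 <- xy[tri_m[, 1], 2]
  x2 <- xy[tri_m[, 2], 1]; y2 <- xy[tri_m[, 2], 2]
  x3 <- xy[tri_m[, 3], 1]; y3 <- xy[tri_m[, 3], 2]
  abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

# Connected components of a triangle set (triangles share an edge or vertex).
#' @noRd
tri_components <- function(tri_m) {
  n <- nrow(tri_m)
  if (n == 1L) return(1L)
  verts <- sort(unique(as.vector(tri_m)))
  vidx <- match(as.vector(tri_m), verts)
  g <- igraph::make_empty_graph(n = length(verts) + n, directed = FALSE)
  tri_nodes <- length(verts) + seq_len(n)
  edges <- rbind(cbind(vidx[seq_len(n)], tri_nodes),
                 cbind(vidx[n + seq_len(n)], tri_nodes),
                 cbind(vidx[2L * n + seq_len(n)], tri_nodes))
  g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  comp[tri_nodes]
}

# Boundary edges (used by exactly one triangle) ordered into closed loops.
#' @noRd
boundary_loops <- function(tri_m) {
  e <- rbind(tri_m[, c(1, 2)], tri_m[, c(2, 3)], tri_m[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bnd <- e[key %in% names(tab)[tab == 1L], , drop = FALSE]
  adj <- split(c(bnd[, 2], bnd[, 1]), c(bnd[, 1], bnd[, 2]))
  visited_edge <- character(0)
  loops <- list()
  remaining <- unique(as.vector(bnd))
  while (length(remaining)) {
    start <- remaining[1]
    loop <- start
    cur <- start; prev <- NA
    repeat {
      nbrs <- adj[[as.character(cur)]]
      nxt <- NA
      for (cand in nbrs) {
        ek <- paste(min(cur, cand), max(cur, cand))
        if (!ek %in% visited_edge) { nxt <- cand; visited_edge <- c(visited_edge, ek); break }
      }
      if (is.na(nxt)) break
      if (nxt == start) break
      loop <- c(loop, nxt)
      prev <- cur; cur <- nxt
    }
    loops[[length(loops) + 1L]] <- loop
    remaining <- setdiff(remaining, loop)
  }
  # keep only loops with >= 3 vertices
  loops[vapply(loops, length, 1L) >= 3L]
}

#' @export
print.alpha_shape_fit <- function(x, ...) {
  cat(sprintf("<alpha_shape_fit> alpha = %.2f /m, area %.4f m^2, fDBH %.3f m, RMSE %.4f m\n",
              x$alpha, x$area, x$fdbh, x$rmse))
  invisible(x)
}

#' @export
plot.alpha_shape_fit <- function(x, section = NULL, ...) {
  rng <- do.call(rbind, x$boundary)
  plot(rng[, 1], rng[, 2], type = "n", asp = 1, xlab = "x (m)", ylab = "y (m)",
       main = sprintf("alpha shape (fDBH %.2f m)", x$fdbh), ...)
  if (!is.null(section)) {
    xy <- if (inherits(section, "cross_section")) section$points2d else section
    points(xy[, 1], xy[, 2], pch = ".", col = "grey50")
  }
  for (b in x$boundary) lines(b[, 1], b[, 2], col = "blue")
  lines(x$outline[, 1], x$outline[, 2], col = "red", lwd = 2)
  invisible(x)
}

#' Measure the standard stem metrics of a tree cloud
#'
#' Derives, relative to the cloud's lowest point:
#' * `H` — height, the z-range of the cloud (highest minus lowest point);
#' * `DBH` — diameter from a least-squares circle fit to the 1.2–1.4 m slab;
#' * `fDBH` — functional DBH, the equivalent-area diameter of an alpha-shape
#'   fit to the same slab;
#' * `DTB` — diameter at top of buttress, a circle fit to the 4.0–4.5 m slab
#'   (above basal flare).
#'
#' Each diameter carries its fit RMSE as the uncertainty used downstream. A
#' quantity whose slab or fit fails (e.g. a tree shorter than the DTB slab)
#' is reported as `NA` with a warning; the others are still returned.
#'
#' @param cloud a [tree_cloud()].
#' @param cfg a [pipeline_config()].
#' @return Object of class `stem_metrics`: one-row data frame with columns
#'   tree_id, H_m, DBH_m, DBH_rmse_m, fDBH_m, fDBH_rmse_m, DTB_m, DTB_rmse_m.
#' @export
measure_tree <- function(cloud, cfg = pipeline_config()) {
  stopifnot(inherits(cloud, "tree_cloud"))
  z <- cloud$points[, "z"]
  H <- max(z) - min(z)
  dbh <- dbh_rmse <- fdbh <- fdbh_rmse <- dtb <- dtb_rmse <- NA_real_
  sec_dbh <- tryCatch(extract_section(cloud, cfg$slice_dbh[1], cfg$slice_dbh[2]),
                      error = function(e) { warning(conditionMessage(e)); NULL })
  if (!is.null(sec_dbh)) {
    cf <- tryCatch(fit_circle(sec_dbh),
                   error = function(e) { warning(conditionMessage(e)); NULL })
    if (!is.null(cf)) { dbh <- 2 * cf$radius; dbh_rmse <- cf$rmse }
    af <- tryCatch(fit_alpha_shape(sec_dbh, alpha = cfg$alpha),
                   error = function(e) { warning(conditionMessage(e)); NULL })
    if (!is.null(af)) { fdbh <- af$fdbh; fdbh_rmse <- af$rmse }
  }
  sec_dtb <- tryCatch(extract_section(cloud, cfg$slice_dtb[1], cfg$slice_dtb[2]),
                      error = function(e) { warning(conditionMessage(e)); NULL })
  if (!is.null(sec_dtb)) {
    cf <- tryCatch(fit_circle(sec_dtb),
                   error = function(e) { warning(conditionMessage(e)); NULL })
    if (!is.null(cf)) { dtb <- 2 * cf$radius; dtb_rmse <- cf$rmse }
  }
  out <- data.frame(tree_id = cloud$tree_id, H_m = H, DBH_m = dbh,
                    DBH_rmse_m = dbh_rmse, fDBH_m = fdbh,
                    fDBH_rmse_m = fdbh_rmse, DTB_m = dtb,
                    DTB_rmse_m = dtb_rmse, stringsAsFactors = FALSE)
  class(out) <- c("stem_metrics", "data.frame")
  out
}

#' Relative DBH vs fDBH difference over a cohort
#'
#' The convention is `100 * (DBH - fDBH) / fDBH`, so stems whose concave
#' (fluted) cross-sections make the equivalent-area diameter exceed the
#' circle-fit diameter give negative values.
#'
#' @param metrics a `stem_metrics` data frame (rows = trees).
#' @return List with `per_tree_percent`, `mean_percent`, `sd_percent`.
#' @export
dbh_fdbh_difference <- function(metrics) {
  d <- 100 * (metrics$DBH_m - metrics$fDBH_m) / metrics$fDBH_m
  d <- d[is.finite(d)]
  list(per_tree_percent = d, mean_percent = mean(d), sd_percent = sd(d))
}
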