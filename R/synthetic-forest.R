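#' Parametric specification of a synthetic conifer stem
#'
#' Defines an analytic tree whose trunk radius at height `z` and azimuth
#' `theta` is
#' \deqn{r(z, \theta) = r_0(z)\,(1 + b(z))\,\big(1 + \sum_k a_k \cos(k\theta + \phi_k)\big)}
#' with \eqn{r_0(z) = \code{base_radius_m}\,(1 - z/H)^{\code{taper_exponent}}},
#' and a basal buttress term \eqn{b(z) = \code{buttress_gain}\,(1 - z /
#' \code{buttress_height_m})} that decays linearly to zero at the top of the
#' buttress. The cosine harmonics emulate the fluted, non-circular
#' cross-sections of large redwood-type stems; branch whorls attach straight
#' cylindrical branches. The family is deliberately simple enough that
#' cross-section areas, and hence whole-trunk volume, are analytically
#' integrable, giving exact ground truth for every generated cloud.
#'
#' @param height_m total tree height H (m).
#' @param base_radius_m trunk radius scale at the ground (m), before buttress
#'   and flute modulation.
#' @param taper_exponent exponent of the taper profile; 0 gives an untapered
#'   column, 1 a cone, values in (0, 1) the convex profiles typical of
#'   conifers.
#' @param buttress_height_m height to which basal flare extends (m); 0
#'   disables the buttress.
#' @param buttress_gain relative radius increase at the ground (dimensionless,
#'   >= 0).
#' @param flutes data frame with columns `k` (integer harmonic >= 2),
#'   `a` (amplitude), `phi` (phase, radians), or NULL for a circular stem.
#'   The amplitudes must satisfy sum(|a|) < 1 so the radius stays positive.
#' @param whorls data frame of branch whorls with columns `z` (attachment
#'   height, m), `count`, `radius` (branch radius, m), `length` (branch
#'   length, m), `angle_deg` (insertion angle from the trunk axis), or NULL.
#' @param point_spacing_m target spacing between sampled surface points (m).
#' @param noise_sigma_m standard deviation of radial Gaussian range noise (m).
#' @param occlusion_fraction fraction of azimuth removed as contiguous
#'   shadow sectors, in `[0, 1)`.
#' @param seed integer RNG seed; the generated cloud is a deterministic
#'   function of the spec (including this seed).
#' @return An object of class `tree_spec`.
#' @seealso [generate_tree()], [trunk_radius()], [generate_plot()]
#' @export
tree_spec <- function(height_m, base_radius_m, taper_exponent = 0.8,
                      buttress_height_m = 0, buttress_gain = 0,
                      flutes = NULL, whorls = NULL,
                      point_spacing_m = 0.05, noise_sigma_m = 0,
                      occlusion_fraction = 0, seed = 1L) {
  assert_scalar_num(height_m, "height_m", 0, strict_lower = TRUE)
  assert_scalar_num(base_radius_m, "base_radius_m", 0, strict_lower = TRUE)
  assert_scalar_num(taper_exponent, "taper_exponent", 0)
  assert_scalar_num(buttress_height_m, "buttress_height_m", 0)
  assert_scalar_num(buttress_gain, "buttress_gain", 0)
  assert_scalar_num(point_spacing_m, "point_spacing_m", 0, strict_lower = TRUE)
  assert_scalar_num(noise_sigma_m, "noise_sigma_m", 0)
  assert_scalar_num(occlusion_fraction, "occlusion_fraction", 0, 0.999)
  if (buttress_height_m >= height_m)
    stopf("buttress_height_m must be below height_m")
  if (!is.null(flutes)) {
    flutes <- as.data.frame(flutes)
    if (!all(c("k", "a", "phi") %in% names(flutes)))
      stopf("flutes needs columns k, a, phi")
    if (any(flutes$k < 2)) stopf("flute harmonics k must be >= 2")
    if (sum(abs(flutes$a)) >= 1)
      stopf("sum of |flute amplitudes| must be < 1")
  }
  if (!is.null(whorls)) {
    whorls <- as.data.frame(whorls)
    need <- c("z", "count", "radius", "length", "angle_deg")
    if (!all(need %in% names(whorls)))
      stopf("whorls needs columns %s", paste(need, collapse = ", "))
    if (any(whorls$z <= 0 | whorls$z >= height_m))
      stopf("whorl attachment heights must lie inside (0, height_m)")
    if (any(whorls$radius <= 0 | whorls$length <= 0 | whorls$count < 1))
      stopf("whorl radius/length must be positive, count >= 1")
  }
  structure(list(
    height_m = height_m, base_radius_m = base_radius_m,
    taper_exponent = taper_exponent, buttress_height_m = buttress_height_m,
    buttress_gain = buttress_gain, flutes = flutes, whorls = whorls,
    point_spacing_m = point_spacing_m, noise_sigma_m = noise_sigma_m,
    occlusion_fraction = occlusion_fraction, seed = as.integer(seed)
  ), class = "tree_spec")
}

#' @export
print.tree_spec <- function(x, ...) {
  cat(sprintf("<tree_spec> H = %.1f m, base radius = %.2f m, taper = %.2f\n",
              x$height_m, x$base_radius_m, x$taper_exponent))
  cat(sprintf("  buttress: %.1f m x %.2f | flutes: %d | whorls: %d | spacing %.3g m, noise %.3g m, occlusion %.0f%%\n",
              x$buttress_height_m, x$buttress_gain,
              if (is.null(x$flutes)) 0L else nrow(x$flutes),
              if (is.null(x$whorls)) 0L else nrow(x$whorls),
              x$point_spacing_m, x$noise_sigma_m,
              100 * x$occlusion_fraction))
  invisible(x)
}

# Mean (azimuth-averaged) trunk radius profile, without flute modulation.
#' @noRd
mean_radius <- function(spec, z) {
  r0 <- spec$base_radius_m * (1 - z / spec$height_m)^spec$taper_exponent
  if (spec$buttress_height_m > 0 && spec$buttress_gain > 0) {
    b <- pmax(0, 1 - z / spec$buttress_height_m) * spec$buttress_gain
    r0 <- r0 * (1 + b)
  }
  r0
}

#' Analytic trunk radius of a synthetic stem
#'
#' Evaluates the generating radius function of a [tree_spec()] at height `z`
#' and azimuth `theta`. Deterministic: noise and occlusion apply only to
#' sampled clouds, never to the analytic surface.
#'
#' @param spec a [tree_spec()].
#' @param z height(s) above the ground (m), in `[0, height_m]`.
#' @param theta azimuth(s), radians. `z` and `theta` are recycled to a common
#'   length.
#' @return Radius in meters.
#' @export
trunk_radius <- function(spec, z, theta) {
  stopifnot(inherits(spec, "tree_spec"))
  if (any(z < 0 | z > spec$height_m))
    stopf("z must lie within [0, %g]", spec$height_m)
  n <- max(length(z), length(theta))
  z <- rep_len(z, n); theta <- rep_len(theta, n)
  r <- mean_radius(spec, z)
  if (!is.null(spec$flutes) && nrow(spec$flutes) > 0) {
    mod <- rep(1, n)
    for (i in seq_len(nrow(spec$flutes)))
      mod <- mod + spec$flutes$a[i] *
        cos(spec$flutes$k[i] * theta + spec$flutes$phi[i])
    r <- r * mod
  }
  r
}

# Exact cross-section area at height z:
#   A(z) = pi * R(z)^2 * (1 + sum(a_k^2)/2)
# (the cosine harmonics integrate to zero at first order).
#' @noRd
section_area_true <- function(spec, z) {
  s2 <- if (is.null(spec$flutes)) 0 else sum(spec$flutes$a^2)
  pi * mean_radius(spec, z)^2 * (1 + s2 / 2)
}

# Perimeter of the analytic cross-section by angular quadrature.
#' @noRd
section_perimeter_true <- function(spec, z, n_theta = 720L) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  R <- mean_radius(spec, z)
  if (is.null(spec$flutes) || nrow(spec$flutes) == 0) return(2 * pi * R)
  mod <- rep(1, n_theta); dmod <- rep(0, n_theta)
  for (i in seq_len(nrow(spec$flutes))) {
    k <- spec$flutes$k[i]; a <- spec$flutes$a[i]; ph <- spec$flutes$phi[i]
    mod <- mod + a * cos(k * th + ph)
    dmod <- dmod - a * k * sin(k * th + ph)
  }
  sum(sqrt((R * mod)^2 + (R * dmod)^2)) * (2 * pi / n_theta)
}

# Analytic/quadrature ground truth for a spec. Trunk volume integrates the
# exact section areas over z (trapezoid, dz <= 1 cm); branches are exact
# cylinders. Surface area integrates the section perimeter with a slant
# correction from the mean-radius profile.
#' @noRd
ground_truth <- function(spec, dz = 0.01) {
  H <- spec$height_m
  z <- seq(0, H, by = dz)
  if (z[length(z)] < H) z <- c(z, H)
  A <- section_area_true(spec, z)
  w <- diff(z)
  trunk_vol <- sum((A[-1] + A[-length(A)]) / 2 * w)
  P <- vapply(z, function(zz) section_perimeter_true(spec, zz), numeric(1))
  Rm <- mean_radius(spec, z)
  slant <- sqrt(1 + (diff(Rm) / w)^2)
  trunk_surf <- sum((P[-1] + P[-length(P)]) / 2 * w * slant)
  branch_vol <- 0; branch_surf <- 0
  if (!is.null(spec$whorls) && nrow(spec$whorls) > 0) {
    wh <- spec$whorls
    branch_vol <- sum(wh$count * pi * wh$radius^2 * wh$length)
    branch_surf <- sum(wh$count * 2 * pi * wh$radius * wh$length)
  }
  z_dbh <- min(1.3, H * 0.99)
  list(
    total_volume_m3 = trunk_vol + branch_vol,
    trunk_volume_m3 = trunk_vol,
    branch_volume_m3 = branch_vol,
    surface_area_m2 = trunk_surf + branch_surf,
    dbh_true_m = 2 * sqrt(section_area_true(spec, z_dbh) / pi),
    height_true_m = H
  )
}

#' Generate a synthetic single-tree TLS point cloud with ground truth
#'
#' Samples the analytic stem surface of a [tree_spec()] at approximately
#' `point_spacing_m`, attaches branch whorls as cylinders, adds radial
#' Gaussian range noise and removes contiguous azimuthal shadow sectors
#' (self-occlusion). Ground-truth volumes come from quadrature of the exact
#' cross-section areas (trunk) and closed-form cylinder volumes (branches),
#' never from the sampled points, so the cloud and its reference values are
#' independent. Deterministic for a fixed spec (the seed is part of the
#' spec).
#'
#' @param spec a [tree_spec()].
#' @param tree_id identifier stored on the returned cloud.
#' @return A list with elements `cloud` (a [tree_cloud()]) and `truth`
#'   (list: `total_volume_m3`, `trunk_volume_m3`, `branch_volume_m3`,
#'   `surface_area_m2`, `dbh_true_m`, `height_true_m`).
#' @examples
#' tr <- generate_tree(tree_spec(height_m = 12, base_radius_m = 0.3,
#'                               point_spacing_m = 0.08, seed = 7))
#' tr$truth$total_volume_m3
#' @export
generate_tree <- function(spec, tree_id = "tree_1") {
  stopifnot(inherits(spec, "tree_spec"))
  truth <- ground_truth(spec)
  pts <- with_seed(spec$seed, sample_tree_points(spec))
  cloud <- tree_cloud(pts, tree_id = tree_id, source = "synthetic")
  list(cloud = cloud, truth = truth)
}

#' @noRd
sample_tree_points <- function(spec) {
  H <- spec$height_m; sp <- spec$point_spacing_m
  # scanners stand on the ground: the lower trunk (which carries the DBH and
  # DTB slabs) is sampled at least finely enough to resolve a 20 cm slab,
  # even when the overall budget dictates a coarse spacing higher up
  r13 <- mean_radius(spec, min(1.3, 0.99 * H))
  sp_low <- min(sp, max(0.015, min(sqrt(0.4 * pi * r13 / 400), 0.08)))
  z_split <- min(5.5, H)
  zs <- unique(c(seq(0, z_split, by = sp_low),
                 if (z_split < H - 1e-9)
                   seq(z_split + sp, H - 1e-9, by = sp)))
  zs <- zs[zs < H]
  # fluting stretches the boundary: scale ring point counts by the maximum
  # angular speed of the outline so flute flanks stay resolved
  fmax <- flute_speed_max(spec$flutes)
  parts <- vector("list", length(zs) + 1L)
  for (i in seq_along(zs)) {
    z <- zs[i]
    sp_z <- if (z <= z_split) sp_low else sp
    rbar <- mean_radius(spec, z)
    n_th <- max(3L, as.integer(ceiling(2 * pi * max(rbar * fmax, sp_z) / sp_z)))
    th <- 2 * pi * (seq_len(n_th) - 1L) / n_th + runif(1, 0, 2 * pi / n_th)
    r <- trunk_radius(spec, z, th)
    if (spec$noise_sigma_m > 0) r <- r + rnorm(n_th, 0, spec$noise_sigma_m)
    parts[[i]] <- cbind(r * cos(th), r * sin(th), z, th)
  }
  # apex point so the generated height spans the full H
  parts[[length(zs) + 1L]] <- cbind(0, 0, H, 0)
  trunk <- do.call(rbind, parts)
  branch <- sample_branch_points(spec)
  all_pts <- if (is.null(branch)) trunk else
    rbind(trunk, cbind(branch, atan2(branch[, 2], branch[, 1])))
  if (spec$occlusion_fraction > 0) {
    # shadow sectors are re-drawn for every 5 m height band: multi-position
    # scanning shifts the occluded azimuth with height, so shadows are
    # stripes, not full-height cuts
    band <- floor(all_pts[, 3] / 5)
    keep <- rep(TRUE, nrow(all_pts))
    for (b in unique(band)) {
      sel <- band == b
      keep[sel] <- !in_occlusion_sector(all_pts[sel, 4],
                                        spec$occlusion_fraction)
    }
    keep[which.max(all_pts[, 3])] <- TRUE # never drop the apex
    all_pts <- all_pts[keep, , drop = FALSE]
  }
  m <- all_pts[, 1:3, drop = FALSE]
  colnames(m) <- c("x", "y", "z")
  m
}

# Maximum angular speed of the fluted outline, max over theta of
# sqrt(mod^2 + mod'^2); 1 for circular stems.
#' @noRd
flute_speed_max <- function(flutes) {
  if (is.null(flutes) || nrow(flutes) == 0) return(1)
  thg <- seq(0, 2 * pi, length.out = 361L)
  mod <- rep(1, 361L); dmod <- rep(0, 361L)
  for (j in seq_len(nrow(flutes))) {
    mod <- mod + flutes$a[j] * cos(flutes$k[j] * thg + flutes$phi[j])
    dmod <- dmod - flutes$a[j] * flutes$k[j] *
      sin(flutes$k[j] * thg + flutes$phi[j])
  }
  max(sqrt(mod^2 + dmod^2))
}

#' @noRd
sample_branch_points <- function(spec) {
  if (is.null(spec$whorls) || nrow(spec$whorls) == 0) return(NULL)
  sp <- spec$point_spacing_m
  out <- list()
  for (w in seq_len(nrow(spec$whorls))) {
    wh <- spec$whorls[w, ]
    az0 <- runif(1, 0, 2 * pi)
    for (b in seq_len(wh$count)) {
      az <- az0 + 2 * pi * (b - 1) / wh$count
      delta <- wh$angle_deg * pi / 180
      axis <- c(sin(delta) * cos(az), sin(delta) * sin(az), cos(delta))
      r_att <- mean_radius(spec, wh$z)
      base <- c(r_att * cos(az), r_att * sin(az), wh$z)
      # orthonormal frame around the branch axis
      u <- c(-sin(az), cos(az), 0)
      v <- c(axis[2] * u[3] - axis[3] * u[2],
             axis[3] * u[1] - axis[1] * u[3],
             axis[1] * u[2] - axis[2] * u[1])
      s <- seq(0, wh$length, by = sp)
      n_c <- max(3L, as.integer(ceiling(2 * pi * wh$radius / sp)))
      ph <- 2 * pi * (seq_len(n_c) - 1L) / n_c
      grid <- expand.grid(s = s, ph = ph)
      rr <- wh$radius
      if (spec$noise_sigma_m > 0)
        rr <- wh$radius + rnorm(nrow(grid), 0, spec$noise_sigma_m)
      px <- base[1] + grid$s * axis[1] + rr * (cos(grid$ph) * u[1] + sin(grid$ph) * v[1])
      py <- base[2] + grid$s * axis[2] + rr * (cos(grid$ph) * u[2] + sin(grid$ph) * v[2])
      pz <- base[3] + grid$s * axis[3] + rr * (cos(grid$ph) * u[3] + sin(grid$ph) * v[3])
      out[[length(out) + 1L]] <- cbind(px, py, pz)
    }
  }
  do.call(rbind, out)
}

# Contiguous occluded azimuth sectors totalling `frac` of the circle. One
# sector is placed inside each of n_sec equal arcs so sectors never overlap
# and the removed fraction is exact.
#' @noRd
in_occlusion_sector <- function(theta, frac) {
  n_sec <- sample(1:3, 1)
  arc <- 2 * pi / n_sec
  width <- frac * arc
  offs <- runif(n_sec, 0, arc - width)
  th <- theta %% (2 * pi)
  hit <- rep(FALSE, length(th))
  for (i in seq_len(n_sec)) {
    lo <- (i - 1) * arc + offs[i]
    hit <- hit | (th >= lo & th < lo + width)
  }
  hit
}

#' Generate a labelled synthetic plot cloud
#'
#' Places a list of synthetic trees at random positions inside a square plot
#' of the given area, rejecting placements whose trunks would overlap at
#' breast height (1.3 m). Every point carries an integer tree label and the
#' manifest ties labels to specs and ground truth.
#'
#' @param specs list of [tree_spec()] objects.
#' @param plot_area_ha plot area in hectares.
#' @param seed integer seed for tree placement.
#' @param max_retries placement attempts per tree before failing.
#' @return A list with `cloud` (matrix x, y, z, label), `manifest` (data
#'   frame: tree_id, x_m, y_m, height_true_m, dbh_true_m, total_volume_m3,
#'   trunk_volume_m3, branch_volume_m3, surface_area_m2, seed), and `trees`
#'   (list of per-tree [tree_cloud()]s in plot coordinates).
#' @export
generate_plot <- function(specs, plot_area_ha, seed = 1L, max_retries = 500L) {
  if (!length(specs)) stopf("specs must be non-empty")
  assert_scalar_num(plot_area_ha, "plot_area_ha", 0, strict_lower = TRUE)
  side <- sqrt(plot_area_ha * 1e4)
  n <- length(specs)
  r13 <- vapply(specs, function(s) mean_radius(s, min(1.3, s$height_m * 0.99)),
                numeric(1))
  pos <- with_seed(seed, {
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        x <- runif(1, r13[i], side - r13[i])
        y <- runif(1, r13[i], side - r13[i])
        if (i == 1L ||
            all(sqrt((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2) >
                r13[seq_len(i - 1)] + r13[i])) {
          xs[i] <- x; ys[i] <- y; ok <- TRUE; break
        }
      }
      if (!ok) stopf("could not place tree %d without trunk overlap after %d retries",
                     i, max_retries)
    }
    cbind(xs, ys)
  })
  clouds <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- generate_tree(specs[[i]], tree_id = sprintf("tree_%03d", i))
    p <- tr$cloud$points
    p[, 1] <- p[, 1] + pos[i, 1]; p[, 2] <- p[, 2] + pos[i, 2]
    clouds[[i]] <- tree_cloud(p, tree_id = tr$cloud$tree_id, source = "synthetic plot")
    man[[i]] <- data.frame(
      tree_id = tr$cloud$tree_id, x_m = pos[i, 1], y_m = pos[i, 2],
      height_true_m = tr$truth$height_true_m, dbh_true_m = tr$truth$dbh_true_m,
      total_volume_m3 = tr$truth$total_volume_m3,
      trunk_volume_m3 = tr$truth$trunk_volume_m3,
      branch_volume_m3 = tr$truth$branch_volume_m3,
      surface_area_m2 = tr$truth$surface_area_m2,
      seed = specs[[i]]$seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, man)
  cloud <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(clouds[[i]]$points, label = i)))
  list(cloud = cloud, manifest = manifest, trees = clouds)
}
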