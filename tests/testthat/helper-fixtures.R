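# Shared fixture builders: everything is generated in code at test time.

# points exactly on a circle
circle_points <- function(n = 360, r = 1, cx = 0, cy = 0, noise = 0,
                          arc = 2 * pi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- seq(0, arc, length.out = n + 1)[-(n + 1)]
  rr <- if (noise > 0) r + rnorm(n, 0, noise) else rep(r, n)
  cbind(cx + rr * cos(th), cy + rr * sin(th))
}

# analytic fluted boundary sampled at fine angular resolution
fluted_boundary <- function(r0 = 1, k = 5, a = 0.08, phi = 0,
                            step_deg = 0.1) {
  th <- seq(0, 2 * pi, by = step_deg * pi / 180)
  th <- th[-length(th)]
  r <- r0 * (1 + a * cos(k * th + phi))
  cbind(r * cos(th), r * sin(th))
}

shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# small noise-free circular test tree
simple_tree <- function(H = 20, r = 0.6, taper = 0.8, spacing = 0.02,
                        seed = 2, ...) {
  tree_spec(height_m = H, base_radius_m = r, taper_exponent = taper,
            point_spacing_m = spacing, seed = seed, ...)
}

# branched test tree: 3 whorls of 4 branches
branched_tree <- function(seed = 5, spacing = 0.04) {
  wh <- data.frame(z = c(4, 6, 8), count = 4, radius = 0.08, length = 2,
                   angle_deg = 85)
  tree_spec(height_m = 12, base_radius_m = 0.5, taper_exponent = 0.8,
            whorls = wh, point_spacing_m = spacing, seed = seed)
}
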