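# Synthetic emulation of the field campaign: three 0.25-ha redwood plots
# (26, 37 and 82 trees — 146 with the separately scanned giant) spanning
# 10-90 m heights, DBH 0.1-3.5 m, with basal buttress flare below ~4 m and
# strongly fluted (non-circular) cross-sections. Generator defaults define
# the study conditions for every cohort-level statistic in the package.

# Draw the flute harmonics of one stem so that the *measured*
# (DBH - fDBH)/fDBH lands near a per-tree target drawn from the cohort
# distribution N(-6.9%, 2.2%). Two regimes, set by how the alpha-shape ball
# (radius 1/alpha = 0.25 m) interacts with the flute valleys at the stem's
# breast-height radius r13:
#  - large stems (valley mouths wider than the ball, pi*r/k > 0.5):
#    valleys are traced, fDBH sees the full analytic area; the ratio is
#    1/sqrt(1 + s/2) - 1 with s = sum(a_k^2), so s = 2((1+rho)^-2 - 1);
#  - small stems (mouths narrower than the ball): valleys are bridged and
#    the concave hull rides the flute crests, giving ratio ~ -a1/(1+a1),
#    so a1 = -rho/(1+rho) with shallower absolute amplitudes.
# This mirrors real stems, where basal fluting deepens with size while a
# fixed field alpha is applied to every tree.
#' @noRd
draw_flutes <- function(r13) {
  rho <- rnorm(1, -0.069, 0.022)
  rho <- min(max(rho, -0.14), -0.015)
  if (r13 >= 0.55) {
    # broad lobes the alpha ball traces; the outer-envelope outline adds
    # about -1.2 points, which the amplitude target discounts, and depths
    # are capped where the measurement becomes unstable
    rho_eff <- max(rho + 0.012, -0.095)
    s <- 2 * ((1 + rho_eff)^-2 - 1)
    w <- c(0.9, 0.1)
    ks <- c(3L, sample(5:7, 1))
    a <- sqrt(s * w)
  } else {
    # bark-ridge regime: harmonics sharp enough (wavelength below ~8 cm)
    # that the ball bridges every valley and the outline rides the crests;
    # range noise alone already thickens the outline by ~1.5 sigma, which
    # the amplitude target discounts
    baseline <- 0.008 + 0.0075 / r13
    a1 <- max(0, (-rho - baseline) / 0.85)
    k1 <- max(6L, min(48L, as.integer(ceiling(78 * r13))))
    ks <- c(k1, k1 + 5L)
    a <- c(a1, 0.2 * a1)
  }
  fl <- data.frame(k = ks, a = a, phi = runif(2, 0, 2 * pi))
  fl[fl$a > 0, , drop = FALSE]
}

#' @noRd
draw_whorls <- function(H, base_radius) {
  # crown base: above 6 m (canopy competition) so the 4-4.5 m diameter slab
  # stays on clean trunk, or the upper two-thirds for short stems
  z0 <- max(0.35 * H, 6)
  if (z0 >= H - 2) return(NULL)
  zs <- seq(z0, H * 0.95, by = max(3, H / 14))
  if (!length(zs)) return(NULL)
  data.frame(z = zs,
             count = sample(4:6, length(zs), replace = TRUE),
             radius = pmax(0.02, base_radius * runif(length(zs), 0.08, 0.18)),
             length = pmin(pmax(H / 12, 1.5) * runif(length(zs), 0.8, 1.3),
                           12),
             angle_deg = runif(length(zs), 75, 95))
}

# One study tree of total height H; base radius back-solved so the
# azimuth-mean diameter at 1.3 m hits the target DBH.
#' @noRd
draw_tree_spec <- function(H, dbh_target, seed, point_budget = 20000,
                           noise_sigma_m = 0.005, occlusion = NULL) {
  taper <- runif(1, 0.7, 0.9)
  bh <- runif(1, 2.8, 4.0)
  gain <- runif(1, 0.3, 0.7)
  z13 <- min(1.3, 0.99 * H)
  butt13 <- 1 + gain * max(0, 1 - z13 / bh)
  base <- (dbh_target / 2) / ((1 - z13 / H)^taper * butt13)
  flutes <- draw_flutes(dbh_target / 2)
  whorls <- draw_whorls(H, base)
  # pick spacing so the sampled surface lands near the point budget; the
  # fluted boundary is longer than the mean circle by up to flute_speed_max
  trunk_area <- 2 * pi * base * H / (taper + 1) * 1.2 *
    flute_speed_max(flutes)
  branch_area <- if (is.null(whorls)) 0 else
    sum(whorls$count * 2 * pi * whorls$radius * whorls$length)
  spacing <- sqrt(max(trunk_area + branch_area, 1) / point_budget)
  spacing <- min(max(spacing, 0.01), 0.25)
  tree_spec(height_m = H, base_radius_m = base, taper_exponent = taper,
            buttress_height_m = bh, buttress_gain = gain, flutes = flutes,
            whorls = whorls, point_spacing_m = spacing,
            noise_sigma_m = noise_sigma_m,
            occlusion_fraction = occlusion %||% runif(1, 0.05, 0.2),
            seed = seed)
}

#' Synthetic counterpart of the largest scanned tree
#'
#' An ~88 m, DBH ~3.39 m redwood-class stem with heavy branching, buttress
#' flare and fluting — the synthetic stand-in used wherever a
#' giant-tree-scale cloud is needed.
#'
#' @param seed integer seed.
#' @param point_budget approximate number of surface points.
#' @return A [tree_spec()].
#' @export
colonel_class_spec <- function(seed = 421L, point_budget = 100000) {
  with_seed(seed, {
    taper <- 0.8; bh <- 3.8; gain <- 0.5; H <- 88
    butt13 <- 1 + gain * (1 - 1.3 / bh)
    base <- (3.39 / 2) / ((1 - 1.3 / H)^taper * butt13)
    zs <- seq(30, 84, by = 4)
    whorls <- data.frame(z = zs,
                         count = sample(5:6, length(zs), replace = TRUE),
                         radius = runif(length(zs), 0.2, 0.28),
                         length = runif(length(zs), 6, 10),
                         angle_deg = runif(length(zs), 78, 95))
    flutes <- draw_flutes(3.39 / 2)
    trunk_area <- 2 * pi * base * H / (taper + 1) * 1.25 *
      flute_speed_max(flutes)
    branch_area <- sum(whorls$count * 2 * pi * whorls$radius * whorls$length)
    spacing <- min(max(sqrt((trunk_area + branch_area) / point_budget), 0.02),
                   0.3)
    tree_spec(height_m = H, base_radius_m = base, taper_exponent = taper,
              buttress_height_m = bh, buttress_gain = gain, flutes = flutes,
              whorls = whorls, point_spacing_m = spacing,
              noise_sigma_m = 0.005, occlusion_fraction = 0.1,
              seed = sub_seed(seed, 99L))
  })
}

#' Specs for a synthetic three-plot study cohort
#'
#' Draws tree heights per plot (an old-growth plot of 26 trees up to ~88 m,
#' a reserve plot of 37, and an 82-tree secondary-growth plot of smaller
#' stems), assigns each a DBH from a power-law height-diameter relation with
#' lognormal scatter (clamped to 0.1-3.5 m), and attaches buttress, flutes,
#' whorls, range noise and occlusion. With `include_giant` the cohort also
#' contains one [colonel_class_spec()] tree (146 trees in total).
#'
#' @param seed master seed.
#' @param point_budget approximate points per tree (the giant gets 5x).
#' @param include_giant add the giant tree to the second plot's records?
#' @return Data frame with columns tree_id, plot_id and a list-column `spec`.
#' @export
study_specs <- function(seed = 1L, point_budget = 8000, include_giant = TRUE) {
  plots <- list(`CAL-01` = 26L, `CAL-02` = 37L, `CAL-07` = 82L)
  h_range <- list(`CAL-01` = c(25, 85), `CAL-02` = c(20, 80),
                  `CAL-07` = c(12, 60))
  rows <- list()
  idx <- 0L
  for (pid in names(plots)) {
    n <- plots[[pid]]
    for (i in seq_len(n)) {
      idx <- idx + 1L
      sd_i <- sub_seed(seed, idx)
      spec <- with_seed(sd_i, {
        H <- exp(runif(1, log(h_range[[pid]][1]), log(h_range[[pid]][2])))
        dbh <- 0.01 * H^1.3 * exp(rnorm(1, 0, 0.12))
        dbh <- min(max(dbh, 0.1), 3.5)
        draw_tree_spec(H, dbh, seed = sub_seed(sd_i, 7L),
                       point_budget = point_budget)
      })
      rows[[idx]] <- data.frame(tree_id = sprintf("%s_t%03d", pid, i),
                                plot_id = pid, stringsAsFactors = FALSE)
      rows[[idx]]$spec <- list(spec)
    }
  }
  if (include_giant) {
    idx <- idx + 1L
    rows[[idx]] <- data.frame(tree_id = "CAL-02_giant", plot_id = "CAL-02",
                              stringsAsFactors = FALSE)
    rows[[idx]]$spec <- list(colonel_class_spec(seed = sub_seed(seed, 5000L),
                                                point_budget = 5 * point_budget))
  }
  do.call(rbind, rows)
}

#' Run the full measurement pipeline over a cohort of specs
#'
#' For every spec: generate the cloud, measure the stem metrics, fit a QSM
#' ensemble, and convert the ensemble volume to TLS AGB. The workhorse
#' behind cohort-level summaries.
#'
#' @param specs data frame from [study_specs()].
#' @param cfg a [pipeline_config()].
#' @param patch_sizes,runs_per_size QSM ensemble settings (defaults come
#'   from `cfg`).
#' @param progress print one line per tree?
#' @return List with `metrics` (stem_metrics data frame), `tls` (per-tree
#'   TLS AGB data frame), `truth` (per-tree ground-truth data frame),
#'   `ensembles` (list of [qsm_ensemble()] summaries).
#' @export
run_study <- function(specs, cfg = pipeline_config(), patch_sizes = NULL,
                      runs_per_size = NULL, progress = FALSE) {
  patch_sizes <- patch_sizes %||% cfg$patch_sizes_m
  runs_per_size <- runs_per_size %||% cfg$runs_per_size
  met <- list(); tls <- list(); tru <- list(); ens <- list()
  for (i in seq_len(nrow(specs))) {
    id <- specs$tree_id[i]
    tr <- generate_tree(specs$spec[[i]], tree_id = id)
    m <- suppressWarnings(measure_tree(tr$cloud, cfg))
    met[[i]] <- m
    tru[[i]] <- data.frame(tree_id = id, plot_id = specs$plot_id[i],
                           total_volume_m3 = tr$truth$total_volume_m3,
                           trunk_volume_m3 = tr$truth$trunk_volume_m3,
                           dbh_true_m = tr$truth$dbh_true_m,
                           height_true_m = tr$truth$height_true_m,
                           stringsAsFactors = FALSE)
    e <- tryCatch(
      qsm_ensemble(tr$cloud, patch_sizes = patch_sizes,
                   runs_per_size = runs_per_size,
                   seed = sub_seed(cfg$seed, 31L + i)),
      error = function(err) {
        warning(sprintf("tree %s: QSM failed (%s); excluded from volumes",
                        id, conditionMessage(err)))
        NULL
      })
    if (is.null(e)) next
    tls[[i]] <- tls_agb(e, cfg$wood_density_kg_m3)
    ens[[i]] <- summary(e)
    if (progress)
      tb_log("tree %s: H %.1f m, V %.1f m^3 (%d pts)", id,
             tr$truth$height_true_m, e$volume_mean_m3, nrow(tr$cloud$points),
             level = "info")
  }
  list(metrics = do.call(rbind, met), tls = do.call(rbind, tls),
       truth = do.call(rbind, tru), ensembles = do.call(rbind, ens))
}
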