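test_that("extract_section takes the half-open slab above the lowest point", {
  sp <- simple_tree(H = 10, r = 0.4, taper = 0, spacing = 0.01, seed = 1)
  tr <- generate_tree(sp)
  sec <- extract_section(tr$cloud, 1.2, 1.4)
  z <- tr$cloud$points[, "z"] - min(tr$cloud$points[, "z"])
  expect_equal(sec$n, sum(z >= 1.2 & z < 1.4))
  dtb <- extract_section(tr$cloud, 4.0, 4.5)
  expect_equal(dtb$n, sum(z >= 4.0 & z < 4.5))
  short <- generate_tree(simple_tree(H = 1.0, r = 0.2, spacing = 0.02))
  expect_error(extract_section(short$cloud, 1.2, 1.4), "insufficient points")
  expect_error(extract_section(tr$cloud, 1.4, 1.2), "z_lo")
})

test_that("circle fit recovers an exact circle to machine precision", {
  xy <- circle_points(n = 360, r = 1.695, cx = 3, cy = -2)
  cf <- fit_circle(xy)
  expect_equal(cf$radius, 1.695, tolerance = 1e-10)
  expect_equal(unname(cf$center), c(3, -2), tolerance = 1e-10)
  expect_lt(cf$rmse, 1e-10)
  expect_equal(2 * cf$radius, 3.39, tolerance = 1e-9)
})

test_that("noisy circle fit beats a grid-search oracle on the LS objective", {
  xy <- circle_points(n = 2000, r = 1.695, noise = 0.005, seed = 31)
  cf <- fit_circle(xy)
  expect_lt(abs(cf$radius - 1.695), 3 * 0.005 / sqrt(2000))
  expect_equal(cf$rmse, 0.005, tolerance = 0.1)
  obj <- function(cx, cy, r) {
    d <- sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2)
    sum((d - r)^2)
  }
  grid <- expand.grid(cx = seq(-0.002, 0.002, length.out = 9),
                      cy = seq(-0.002, 0.002, length.out = 9),
                      r = seq(1.690, 1.700, length.out = 21))
  grid_min <- min(mapply(obj, grid$cx, grid$cy, grid$r))
  expect_lte(obj(cf$center[1], cf$center[2], cf$radius), grid_min + 1e-9)
})

test_that("circle fit is translation/rotation equivariant", {
  xy <- circle_points(n = 500, r = 0.8, noise = 0.01, seed = 7)
  cf <- fit_circle(xy)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy2 <- sweep(xy %*% R, 2, c(-5.5, 2.25), `+`)
  cf2 <- fit_circle(xy2)
  expect_equal(cf2$radius, cf$radius, tolerance = 1e-9)
  expect_equal(cf2$rmse, cf$rmse, tolerance = 1e-9)
})

test_that("adding points exactly on the fitted circle never raises rmse", {
  xy <- circle_points(n = 300, r = 1, noise = 0.02, seed = 3)
  cf <- fit_circle(xy)
  extra <- circle_points(n = 200, r = cf$radius, cx = cf$center[1],
                         cy = cf$center[2])
  cf2 <- fit_circle(rbind(xy, extra))
  expect_lte(cf2$rmse, cf$rmse + 1e-12)
})

test_that("degenerate circle inputs error", {
  line <- cbind(seq(0, 1, length.out = 30), 0.5 * seq(0, 1, length.out = 30))
  expect_error(fit_circle(line), "collinear")
  expect_error(fit_circle(circle_points(10)), ">= 20 points")
})

test_that("alpha shape recovers circle, square and fluted closed forms", {
  ring <- circle_points(n = 2000, r = 1.695, noise = 0.004, seed = 1)
  af <- fit_alpha_shape(ring, alpha = 4)
  expect_equal(af$fdbh, 3.39, tolerance = 0.01)
  expect_equal(af$fdbh, 2 * sqrt(af$area / pi))
  square <- as.matrix(expand.grid(x = seq(0, 1, by = 0.02),
                                  y = seq(0, 1, by = 0.02)))
  af2 <- fit_alpha_shape(square, alpha = 4)
  expect_equal(af2$area, 1, tolerance = 0.01)
  expect_equal(af2$fdbh, 2 / sqrt(pi), tolerance = 0.01)
  # fluted band vs shoelace oracle at 0.1 degree sampling
  band <- rbind(fluted_boundary(1, 5, 0.08, 0.3, step_deg = 0.5),
                fluted_boundary(1.003, 5, 0.08, 0.3, step_deg = 0.5))
  af3 <- fit_alpha_shape(band, alpha = 4)
  oracle <- shoelace_area(fluted_boundary(1, 5, 0.08, 0.3))
  expect_equal(af3$area, oracle, tolerance = 0.02)
  expect_gt(af3$fdbh, 0)
})

test_that("the kept alpha complex shrinks as alpha tightens", {
  sec <- circle_points(n = 1500, r = 0.9, noise = 0.01, seed = 5)
  areas <- vapply(c(0.5, 1, 2, 4, 8), function(a)
    fit_alpha_shape(sec, alpha = a)$complex_area, 0)
  expect_true(all(diff(areas) <= 1e-9))
  # the enclosed-section estimate stays stable while the complex shrinks
  encl <- vapply(c(1, 2, 4), function(a) fit_alpha_shape(sec, alpha = a)$area, 0)
  expect_lt(max(encl) / min(encl) - 1, 0.02)
})

test_that("hopelessly tight alpha is reported as degenerate", {
  sec <- circle_points(n = 400, r = 0.9, noise = 0.01, seed = 6)
  expect_error(fit_alpha_shape(sec, alpha = 1e5), "degenerate alpha")
})

test_that("measure_tree reproduces truth on a noise-free circular stem", {
  sp <- simple_tree(H = 20, r = 0.6, taper = 0.8, spacing = 0.02)
  tr <- generate_tree(sp)
  m <- measure_tree(tr$cloud)
  expect_equal(m$H_m, tr$truth$height_true_m, tolerance = 0.02 / 20)
  expect_equal(m$DBH_m, tr$truth$dbh_true_m, tolerance = 0.005)
  expect_equal(m$fDBH_m, tr$truth$dbh_true_m, tolerance = 0.005)
  expect_lt(abs(m$DBH_m - m$fDBH_m) / m$DBH_m, 0.005)
  r45 <- 0.6 * (1 - 4.25 / 20)^0.8
  expect_equal(m$DTB_m, 2 * r45, tolerance = 0.01)
})

test_that("fluted stems give fDBH above DBH, near the analytic prediction", {
  fl <- data.frame(k = c(3, 6), a = sqrt(0.3 * c(0.9, 0.1)), phi = c(0.2, 1.1))
  sp <- tree_spec(height_m = 30, base_radius_m = 0.8, taper_exponent = 0.8,
                  buttress_height_m = 3.5, buttress_gain = 0.5, flutes = fl,
                  point_spacing_m = 0.03, noise_sigma_m = 0.005, seed = 9)
  m <- measure_tree(generate_tree(sp)$cloud)
  expect_gt(m$fDBH_m, 0)
  analytic <- 100 * (1 / sqrt(1 + 0.3 / 2) - 1)
  measured <- 100 * (m$DBH_m - m$fDBH_m) / m$fDBH_m
  expect_lt(abs(measured - analytic), 3)
})

test_that("a failed quantity is NA while the others are still returned", {
  sp <- simple_tree(H = 3, r = 0.25, taper = 0.5, spacing = 0.02)
  tr <- generate_tree(sp)
  m <- suppressWarnings(measure_tree(tr$cloud))
  expect_true(is.na(m$DTB_m)) # tree shorter than the 4-4.5 m slab
  expect_false(is.na(m$DBH_m))
  expect_false(is.na(m$H_m))
})

test_that("cohort fDBH statistic has the fluted-stem sign structure", {
  set.seed(123)
  rows <- list()
  for (i in 1:12) {
    s <- runif(1, 0.2, 0.35)
    fl <- data.frame(k = c(3, 6), a = sqrt(s * c(0.9, 0.1)),
                     phi = runif(2, 0, 2 * pi))
    sp <- tree_spec(height_m = runif(1, 25, 40), base_radius_m = runif(1, 0.7, 1),
                    taper_exponent = 0.8, flutes = fl, point_spacing_m = 0.04,
                    noise_sigma_m = 0.004, seed = i)
    rows[[i]] <- suppressWarnings(measure_tree(generate_tree(sp)$cloud))
  }
  st <- dbh_fdbh_difference(do.call(rbind, rows))
  expect_lt(st$mean_percent, 0) # fDBH > DBH for concave-dominant flutes
  expect_gt(mean(st$per_tree_percent < 0), 0.8)
})
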