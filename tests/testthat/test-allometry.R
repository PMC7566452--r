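test_that("the shipped bank exposes seven models with their predictor sets", {
  mods <- load_models()
  expect_setequal(names(mods), c("jenkins", "chojnacky", "parks", "fujimori",
                                 "sillett2015", "sillett2019", "kizha_han"))
  expect_setequal(mods$parks$predictors, c("DBH", "H"))
  expect_setequal(mods$fujimori$predictors, c("DBH", "H"))
  expect_setequal(mods$sillett2015$predictors, c("DTB", "fDBH"))
  expect_setequal(mods$sillett2019$predictors, c("DTB", "H"))
  expect_equal(mods$kizha_han$predictors, "DBH")
  expect_equal(mods$jenkins$predictors, "DBH")
  expect_equal(mods$chojnacky$predictors, "DBH")
  expect_gte(mods$kizha_han$correction_factor, 1)
})

test_that("missing coefficients and bad forms are config errors", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("models:", "  jenkins:", "    form: log_log",
               "    predictors: [DBH]", "    coefficients:",
               "      beta0: -2.0336"), f)
  expect_error(load_models(f), "jenkins.*beta1")
  writeLines(c("models:", "  weird:", "    form: quadratic",
               "    predictors: [DBH]", "    coefficients: {beta0: 1}"), f)
  expect_error(load_models(f), "unknown or missing form")
  writeLines(c("models:", "  bad:", "    form: log_log",
               "    predictors: [DBH, H]",
               "    coefficients: {beta0: 1, beta1: 2}"), f)
  expect_error(load_models(f), "exactly one predictor")
})

test_that("a custom power-law model round-trips save -> load", {
  f <- withr::local_tempfile(fileext = ".yaml")
  m <- tlsbiomass:::build_model("custom", list(
    form = "power_product", predictors = c("DBH", "H"),
    predictor_units = "m", response = "volume_m3",
    coefficients = list(beta0 = 0.21, beta1 = 1.9, beta2 = 1.05),
    correction_factor = 1.0, wood_density_kg_m3 = 350, source = "test"))
  save_model(m, f)
  back <- load_models(f)$custom
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$predictors, m$predictors)
  expect_equal(back$wood_density_kg_m3, 350)
})

test_that("log-log prediction is exp(beta0 + beta1 log D) in config units", {
  mods <- load_models()
  met <- data.frame(tree_id = "t", H_m = 88, DBH_m = 3.39, DBH_rmse_m = 0,
                    fDBH_m = NA, fDBH_rmse_m = NA, DTB_m = NA, DTB_rmse_m = NA)
  est <- predict_agb(mods$jenkins, met, mc_n = 100, seed = 1)
  expect_equal(est$agb_t, exp(-2.0336 + 2.2592 * log(339)) / 1000,
               tolerance = 1e-10)
  expect_equal(est$agb_sd_t, 0, tolerance = 1e-12) # zero-noise limit
  expect_error(predict_agb(mods$sillett2015, met), "requires predictor")
})

test_that("Monte-Carlo propagation matches the delta method at small noise", {
  mods <- load_models()
  met <- data.frame(tree_id = "t", H_m = 60, DBH_m = 2.0,
                    DBH_rmse_m = 0.02 * 2.0, fDBH_m = 2.1, fDBH_rmse_m = 0.01,
                    DTB_m = 1.8, DTB_rmse_m = 0.02)
  est <- predict_agb(mods$jenkins, met, mc_n = 4000, seed = 3)
  delta <- est$agb_t * 2.2592 * 0.02
  expect_equal(est$agb_sd_t, delta, tolerance = 0.2)
})

test_that("MC uncertainty scales linearly with predictor RMSE", {
  mods <- load_models()
  base <- data.frame(tree_id = "t", H_m = 50, DBH_m = 1.5,
                     DBH_rmse_m = 0.015, fDBH_m = NA, fDBH_rmse_m = NA,
                     DTB_m = NA, DTB_rmse_m = NA)
  twice <- base; twice$DBH_rmse_m <- 0.03
  s1 <- predict_agb(mods$jenkins, base, mc_n = 4000, seed = 5)$agb_sd_t
  s2 <- predict_agb(mods$jenkins, twice, mc_n = 4000, seed = 5)$agb_sd_t
  expect_equal(s2 / s1, 2, tolerance = 0.15)
})

test_that("every log-log model is strictly increasing over 0.1-3.5 m DBH", {
  mods <- load_models()
  grid <- seq(0.1, 3.5, by = 0.1)
  for (m in mods) {
    if (!identical(m$predictors, "DBH")) next
    agb <- vapply(grid, function(d)
      tlsbiomass:::predict_mass_t(m, list(DBH = d)), 0)
    expect_true(all(diff(agb) > 0), info = m$model_id)
  }
})

test_that("tls_agb is the exact linear density map", {
  e <- list(cloud_id = "t", volume_mean_m3 = 100, volume_sd_m3 = 8)
  est <- tls_agb(e, wood_density_kg_m3 = 400)
  expect_equal(est$agb_t, 40)
  expect_equal(est$agb_sd_t, 3.2)
  e0 <- list(cloud_id = "t", volume_mean_m3 = 55, volume_sd_m3 = 0)
  expect_equal(tls_agb(e0, 330)$agb_sd_t, 0)
  # exact linearity: tls_agb(kV) = k tls_agb(V)
  k <- 3.7
  ek <- list(cloud_id = "t", volume_mean_m3 = k * 100, volume_sd_m3 = k * 8)
  expect_equal(tls_agb(ek, 400)$agb_t, k * est$agb_t)
  expect_equal(tls_agb(ek, 400)$agb_sd_t, k * est$agb_sd_t)
})

test_that("power-law fit recovers exact generating coefficients", {
  set.seed(4)
  D <- runif(50, 0.2, 3); H <- 12 * D^0.8 * exp(rnorm(50, 0, 0.2))
  V <- 0.3 * D^2.1 * H
  f <- suppressWarnings(fit_power_law(V ~ D + H, data.frame(V = V, D = D, H = H)))
  expect_equal(unname(coef(f)), c(0.3, 2.1, 1.0), tolerance = 1e-6)
  expect_lt(f$rmse_percent, 1e-6)
})

test_that("exponent is recovered within 2 SE under lognormal noise", {
  set.seed(9)
  n <- 146
  D <- exp(runif(n, log(0.1), log(3.5)))
  AGB <- 0.25 * D^2.3 * exp(rnorm(n, 0, 0.1))
  f <- fit_power_law(AGB ~ D, data.frame(AGB = AGB, D = D))
  se_b <- summary(f)$coefficients["b1", "Std. Error"]
  expect_lt(abs(coef(f)[["b1"]] - 2.3), 2 * se_b)
  # parametric bootstrap oracle for the SE
  boot <- replicate(120, {
    AGBb <- 0.25 * D^2.3 * exp(rnorm(n, 0, 0.1))
    coef(fit_power_law(AGBb ~ D, data.frame(AGBb = AGBb, D = D)))[["b1"]]
  })
  expect_equal(se_b, sd(boot), tolerance = 0.5)
})

test_that("an H-only allometry fits worse than the two-predictor form", {
  set.seed(11)
  n <- 60
  D <- exp(runif(n, log(0.2), log(3)))
  H <- 12 * D^0.8 * exp(rnorm(n, 0, 0.15))
  V <- 0.3 * D^2.1 * H * exp(rnorm(n, 0, 0.05))
  df <- data.frame(V = V, D = D, H = H)
  both <- fit_power_law(V ~ D + H, df)
  h_only <- fit_power_law(V ~ H, df)
  expect_gt(h_only$rmse_percent, both$rmse_percent)
})

test_that("fixed-coefficient evaluation matches the refit at the optimum", {
  set.seed(2)
  D <- runif(30, 0.3, 2); V <- 0.4 * D^2.2
  df <- data.frame(V = V, D = D)
  f <- suppressWarnings(fit_power_law(V ~ D, df))
  fixed <- power_law_rmse(V ~ D, df, c(a = 0.4, b1 = 2.2))
  expect_equal(fixed$rmse_percent, 0, tolerance = 1e-8)
  off <- power_law_rmse(V ~ D, df, c(a = 0.5, b1 = 2.2))
  expect_gt(off$rmse_percent, f$rmse_percent)
})

test_that("degenerate fits are rejected", {
  df <- data.frame(V = runif(20, 1, 2), D = rep(1, 20))
  expect_error(fit_power_law(V ~ D, df), "singular|failed")
  expect_error(fit_power_law(V ~ D, data.frame(V = c(-1, rep(1, 19)),
                                               D = runif(20, 1, 2))),
               "positive")
  expect_error(fit_power_law(V ~ D, data.frame(V = 1:5, D = 1:5)),
               ">= 10 records")
})
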