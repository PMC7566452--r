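ref_cohort <- function(n = 30, seed = 1) {
  set.seed(seed)
  data.frame(tree_id = sprintf("t%02d", 1:n),
             agb_t = exp(runif(n, log(0.5), log(100))))
}

test_that("identity candidate gives the identity regression", {
  ref <- ref_cohort()
  fit <- compare_regression(ref, ref)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept_t, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(fit$rmse_t, 0, tolerance = 1e-10)
  expect_equal(fit$cv_percent, 0, tolerance = 1e-10)
})

test_that("OLS matches the closed-form sum-of-products oracle to 1e-9", {
  ref <- ref_cohort(40, seed = 2)
  set.seed(3)
  cand <- ref; cand$agb_t <- 0.9 * ref$agb_t + rnorm(40, 0, 2)
  fit <- compare_regression(ref, cand, model_id = "m")
  x <- ref$agb_t; y <- cand$agb_t
  slope_o <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  int_o <- mean(y) - slope_o * mean(x)
  expect_equal(fit$slope, slope_o, tolerance = 1e-9)
  expect_equal(fit$intercept_t, int_o, tolerance = 1e-9)
  res <- y - int_o - slope_o * x
  expect_equal(fit$rmse_t, sqrt(mean(res^2)), tolerance = 1e-9)
  expect_equal(fit$cv_percent, 100 * fit$rmse_t / mean(x), tolerance = 1e-9)
  # slope within its CI of the generating 0.9
  se <- sqrt(sum(res^2) / (38)) / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(fit$slope - 0.9), 3 * se)
})

test_that("r2 is invariant under affine rescaling of the candidate", {
  ref <- ref_cohort(25, seed = 5)
  set.seed(6)
  cand <- ref; cand$agb_t <- 1.2 * ref$agb_t + rnorm(25, 0, 3) + 40
  f1 <- compare_regression(ref, cand)
  cand2 <- cand; cand2$agb_t <- 5 * cand$agb_t + 7
  f2 <- compare_regression(ref, cand2)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
  expect_equal(f2$slope, 5 * f1$slope, tolerance = 1e-9)
})

test_that("dropping the dominant tree moves the slope as expected", {
  set.seed(7)
  n <- 25
  ref <- data.frame(tree_id = sprintf("t%02d", 1:n),
                    agb_t = c(exp(runif(n - 1, log(1), log(30))), 110))
  cand <- ref
  cand$agb_t <- 0.95 * ref$agb_t + rnorm(n, 0, 3)
  with_big <- compare_regression(ref, cand, include_largest = TRUE)
  without <- compare_regression(ref, cand, include_largest = FALSE)
  expect_equal(without$n, with_big$n - 1)
  # the single large tree anchors the fit: r2 rises and the slope is pinned
  # down far more tightly (its standard error shrinks) when it is included
  expect_gt(with_big$r2, without$r2)
  se_of <- function(keep_big) {
    d <- merge(ref, cand, by = "tree_id")
    if (!keep_big) d <- d[-which.max(d$agb_t.x), ]
    summary(lm(agb_t.y ~ agb_t.x, d))$coefficients[2, 2]
  }
  expect_lt(se_of(TRUE), se_of(FALSE))
})

test_that("pairing is by tree_id and unmatched ids error", {
  ref <- ref_cohort(12)
  cand <- ref[-1, ]
  expect_error(compare_regression(ref, cand), "unmatched")
  shuffled <- ref[sample(nrow(ref)), ]
  expect_equal(compare_regression(ref, shuffled)$slope, 1)
  expect_error(compare_regression(ref_cohort(5), ref_cohort(5)),
               ">= 10 paired")
})

test_that("plot AGBD is the exact sum over area with quadrature SE", {
  rec <- data.frame(agb_t = 10, agb_sd_t = 1)
  s <- plot_agbd(rec, area_ha = 0.25, plot_id = "P", method_id = "tls")
  expect_equal(s$agbd_t_ha, 40)
  expect_equal(s$agbd_se_t_ha, 4)
  # linearity: duplicating every tree doubles the density exactly
  rec26 <- data.frame(agb_t = runif(26, 1, 60), agb_sd_t = runif(26, 0, 5))
  s1 <- plot_agbd(rec26, 0.25)
  s2 <- plot_agbd(rbind(rec26, rec26), 0.25)
  expect_equal(s2$agbd_t_ha, 2 * s1$agbd_t_ha)
  # direct-sum oracle
  expect_equal(s1$agbd_t_ha, sum(rec26$agb_t) / 0.25, tolerance = 1e-12)
  expect_equal(s1$agbd_se_t_ha, sqrt(sum(rec26$agb_sd_t^2)) / 0.25,
               tolerance = 1e-12)
  expect_error(plot_agbd(rec26[0, ], 0.25), "empty plot")
  # removing the largest tree never increases the total
  drop1 <- plot_agbd(rec26[-which.max(rec26$agb_t), ], 0.25)
  expect_lt(drop1$agbd_t_ha, s1$agbd_t_ha)
})

test_that("table1_report emits 2 rows per model in a stable order", {
  ref <- ref_cohort(20, seed = 9)
  agb <- ref; agb$method_id <- "tls"
  set.seed(10)
  for (m in c("parks", "fujimori", "sillett2015", "sillett2019", "kizha_han",
              "jenkins", "chojnacky")) {
    x <- ref
    x$agb_t <- runif(1, 0.5, 1.1) * ref$agb_t + rnorm(20, 0, 1)
    x$method_id <- m
    agb <- rbind(agb, x)
  }
  order_wanted <- c("parks", "fujimori", "sillett2015", "sillett2019",
                    "kizha_han", "jenkins", "chojnacky")
  t1 <- table1_report(agb, model_order = order_wanted)
  expect_equal(nrow(t1), 14)
  expect_equal(t1$model_id, rep(order_wanted, 2))
  expect_equal(t1$includes_largest, rep(c(TRUE, FALSE), each = 7))
  expect_true(all(t1$r2 >= 0 & t1$r2 <= 1))
  t1b <- table1_report(agb, model_order = order_wanted)
  expect_identical(t1, t1b) # bit-stable across runs
})

test_that("table2_report aggregates per plot and method", {
  set.seed(11)
  agb <- expand.grid(tree_id = sprintf("t%02d", 1:12),
                     method_id = c("tls", "jenkins"),
                     stringsAsFactors = FALSE)
  agb$agb_t <- runif(nrow(agb), 1, 50)
  agb$agb_sd_t <- runif(nrow(agb), 0, 2)
  plots <- data.frame(tree_id = sprintf("t%02d", 1:12),
                      plot_id = rep(c("A", "B"), each = 6))
  t2 <- table2_report(agb, plots, list(A = 0.25, B = 0.5))
  expect_equal(nrow(t2), 4)
  a_tls <- t2[t2$plot_id == "A" & t2$method_id == "tls", ]
  manual <- sum(agb$agb_t[agb$method_id == "tls" &
                            agb$tree_id %in% plots$tree_id[plots$plot_id == "A"]])
  expect_equal(a_tls$agbd_t_ha, manual / 0.25, tolerance = 1e-12)
  expect_error(table2_report(agb, plots, list(A = 0.25)), "no area")
})

test_that("end-to-end: generating allometry against density-scaled truth", {
  # TLS reference = rho * true volume; candidate = the generating power law
  # evaluated on true predictors; noise -> 0 so slope -> 1, r2 -> 1
  set.seed(12)
  n <- 20
  D <- exp(runif(n, log(0.3), log(3)))
  H <- 12 * D^0.8
  V <- 0.3 * D^2.1 * H
  rho <- 0.33
  ref <- data.frame(tree_id = sprintf("t%02d", 1:n), agb_t = rho * V)
  cand <- data.frame(tree_id = ref$tree_id, agb_t = rho * 0.3 * D^2.1 * H)
  fit <- compare_regression(ref, cand)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})
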