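#' Load a bank of allometric models from YAML configuration
#'
#' Allometric coefficients are data, not code: each model ships in a config
#' file with its functional form, predictor set, units, coefficients,
#' back-transformation correction factor and wood density. Supported forms:
#'
#' * `log_log` — `AGB_kg = CF * exp(beta0 + beta1 * log(D))` with the single
#'   predictor `D` in `predictor_units` (log-log linear with bias-correction
#'   factor CF >= 1);
#' * `power_product` — `Y = beta0 * X1^beta1 * X2^beta2 ...`; when
#'   `response` is `volume_m3` the result is multiplied by wood density to
#'   give AGB (volume-then-density models), when `agb_kg` it is mass
#'   directly.
#'
#' Predictors are any of `DBH`, `fDBH`, `DTB` (diameters) and `H` (height).
#'
#' @param paths character vector of YAML files; entries are merged in order.
#'   Defaults to the two files shipped with the package: the generalised
#'   models (published coefficients) and the species-specific stand-ins.
#' @return Named list of `allometric_model` objects.
#' @export
load_models <- function(paths = default_model_files()) {
  out <- list()
  for (p in paths) {
    y <- yaml::read_yaml(p)
    models <- y$models %||% y
    for (nm in names(models)) {
      out[[nm]] <- build_model(nm, models[[nm]], source_file = p)
    }
  }
  out
}

#' Paths of the model configuration files shipped with the package
#' @return Character vector of two YAML paths.
#' @export
default_model_files <- function() {
  c(system.file("extdata", "generalised_models.yaml", package = "tlsbiomass"),
    system.file("extdata", "speciesspecific_models_synthetic.yaml",
                package = "tlsbiomass"))
}

#' @noRd
build_model <- function(model_id, cfg, source_file = "") {
  form <- cfg$form
  if (is.null(form) || !form %in% c("log_log", "power_product"))
    stopf("model '%s': unknown or missing form '%s'", model_id,
          form %||% "<none>")
  predictors <- unlist(cfg$predictors)
  if (!length(predictors) || !all(predictors %in% c("DBH", "fDBH", "DTB", "H")))
    stopf("model '%s': predictors must be a non-empty subset of DBH, fDBH, DTB, H",
          model_id)
  co <- cfg$coefficients
  need <- if (form == "log_log") c("beta0", "beta1") else
    c("beta0", paste0("beta", seq_along(predictors)))
  for (f in need)
    if (is.null(co[[f]]))
      stopf("model '%s': missing coefficient '%s'", model_id, f)
  if (form == "log_log" && length(predictors) != 1L)
    stopf("model '%s': log_log form takes exactly one predictor", model_id)
  response <- cfg$response %||% "agb_kg"
  if (!response %in% c("agb_kg", "volume_m3"))
    stopf("model '%s': response must be agb_kg or volume_m3", model_id)
  cf <- cfg$correction_factor %||% 1
  if (cf < 1) stopf("model '%s': correction_factor must be >= 1", model_id)
  structure(list(
    model_id = model_id, form = form, predictors = predictors,
    predictor_units = cfg$predictor_units %||% "m",
    response = response,
    coefficients = unlist(co), correction_factor = cf,
    wood_density_kg_m3 = cfg$wood_density_kg_m3 %||% 330,
    source = cfg$source %||% "", source_file = source_file),
    class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("<allometric_model> %s: %s of (%s), response %s\n", x$model_id,
              x$form, paste(x$predictors, collapse = ", "), x$response))
  cat("  coefficients:", paste(sprintf("%s = %.5g", names(x$coefficients),
                                       x$coefficients), collapse = ", "),
      sprintf("| CF %.3f | rho %.0f kg/m^3\n", x$correction_factor,
              x$wood_density_kg_m3))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Save an allometric model back to YAML
#' @param model an `allometric_model`.
#' @param path output YAML path.
#' @export
save_model <- function(model, path) {
  y <- list(models = setNames(list(list(
    form = model$form, predictors = as.list(model$predictors),
    predictor_units = model$predictor_units, response = model$response,
    coefficients = as.list(model$coefficients),
    correction_factor = model$correction_factor,
    wood_density_kg_m3 = model$wood_density_kg_m3,
    source = model$source)), model$model_id))
  yaml::write_yaml(y, path)
  invisible(path)
}

# Diameter unit conversion from meters to the model's units.
#' @noRd
to_model_units <- function(model, name, value_m) {
  if (name == "H") return(value_m) # heights are always meters
  switch(model$predictor_units, m = value_m, cm = value_m * 100,
         stopf("model '%s': unsupported predictor_units '%s'",
               model$model_id, model$predictor_units))
}

# Point prediction in metric tons from named predictor values (meters).
#' @noRd
predict_mass_t <- function(model, values_m) {
  for (p in model$predictors)
    if (is.null(values_m[[p]]) || any(!is.finite(values_m[[p]])))
      stopf("model '%s' requires predictor %s", model$model_id, p)
  co <- model$coefficients
  if (model$form == "log_log") {
    d <- to_model_units(model, model$predictors[1],
                        values_m[[model$predictors[1]]])
    out_kg <- model$correction_factor * exp(co[["beta0"]] +
                                              co[["beta1"]] * log(d))
  } else {
    y <- co[["beta0"]]
    for (i in seq_along(model$predictors)) {
      x <- to_model_units(model, model$predictors[i],
                          values_m[[model$predictors[i]]])
      y <- y * x^co[[paste0("beta", i)]]
    }
    out_kg <- model$correction_factor *
      (if (model$response == "volume_m3") y * model$wood_density_kg_m3 else y)
  }
  out_kg / 1000
}

#' Predict per-tree AGB from an allometric model with uncertainty
#'
#' The point estimate applies the model's published form to the TLS-derived
#' stem metrics. The uncertainty propagates each diameter's geometric-fit
#' RMSE through the model by Monte Carlo: `mc_n` draws of every predictor
#' from a truncated-positive Normal centred on its measured value with the
#' fit RMSE as standard deviation (height has no fit RMSE and is held
#' fixed); `agb_sd_t` is the standard deviation of the resulting mass draws.
#'
#' @param model an `allometric_model`.
#' @param metrics a one-row `stem_metrics` data frame (or a row of one).
#' @param mc_n Monte-Carlo draws (>= 100).
#' @param seed integer seed.
#' @return One-row data frame (class `agb_estimate`): tree_id, method_id,
#'   agb_t, agb_sd_t.
#' @export
predict_agb <- function(model, metrics, mc_n = 1000L, seed = 1L) {
  stopifnot(inherits(model, "allometric_model"))
  if (mc_n < 100) stopf("mc_n must be >= 100")
  vals <- list(DBH = metrics$DBH_m, fDBH = metrics$fDBH_m,
               DTB = metrics$DTB_m, H = metrics$H_m)
  sds <- list(DBH = metrics$DBH_rmse_m %||% 0,
              fDBH = metrics$fDBH_rmse_m %||% 0,
              DTB = metrics$DTB_rmse_m %||% 0, H = 0)
  est <- predict_mass_t(model, vals)
  draws <- with_seed(seed, {
    sims <- matrix(NA_real_, mc_n, length(model$predictors),
                   dimnames = list(NULL, model$predictors))
    for (p in model$predictors) {
      s <- sds[[p]] %||% 0
      if (is.na(s)) s <- 0
      v <- rnorm(mc_n, vals[[p]], s)
      bad <- v <= 0
      while (any(bad)) { # truncate positive by redraw
        v[bad] <- rnorm(sum(bad), vals[[p]], s)
        bad <- v <= 0
      }
      sims[, p] <- v
    }
    # the model forms are elementwise arithmetic, so all draws evaluate in
    # one vectorised call
    predict_mass_t(model, as.list(as.data.frame(sims)))
  })
  out <- data.frame(tree_id = metrics$tree_id %||% "tree",
                    method_id = model$model_id,
                    agb_t = est, agb_sd_t = sd(draws),
                    stringsAsFactors = FALSE)
  class(out) <- c("agb_estimate", "data.frame")
  out
}

#' Convert a TLS QSM volume (ensemble) to AGB via wood density
#'
#' The linear map `AGB = rho * V`: mean and SD of the ensemble volume scale
#' identically, so the ensemble spread becomes the AGB uncertainty.
#'
#' @param ensemble a [qsm_ensemble()] (or any list with `volume_mean_m3`,
#'   `volume_sd_m3`, `cloud_id`).
#' @param wood_density_kg_m3 wood density (kg m^-3).
#' @return One-row `agb_estimate` data frame with method_id `"tls"`.
#' @export
tls_agb <- function(ensemble, wood_density_kg_m3 = 330) {
  assert_scalar_num(wood_density_kg_m3, "wood_density_kg_m3", 0,
                    strict_lower = TRUE)
  out <- data.frame(tree_id = ensemble$cloud_id %||% "tree", method_id = "tls",
                    agb_t = wood_density_kg_m3 * ensemble$volume_mean_m3 / 1000,
                    agb_sd_t = wood_density_kg_m3 *
                      (ensemble$volume_sd_m3 %||% 0) / 1000,
                    stringsAsFactors = FALSE)
  class(out) <- c("agb_estimate", "data.frame")
  out
}

#' AGB for a cohort of trees under every model in a bank
#'
#' @param models named list from [load_models()].
#' @param metrics multi-row `stem_metrics` data frame.
#' @param mc_n,seed passed to [predict_agb()]; each tree x model pair gets a
#'   derived sub-seed.
#' @return Data frame with one row per tree x model (tree_id, method_id,
#'   agb_t, agb_sd_t). Trees missing a model's predictors get NA with a
#'   warning.
#' @export
agb_table <- function(models, metrics, mc_n = 1000L, seed = 1L) {
  rows <- list()
  stream <- 0L
  for (mi in seq_along(models)) {
    for (ti in seq_len(nrow(metrics))) {
      stream <- stream + 1L
      r <- tryCatch(predict_agb(models[[mi]], metrics[ti, , drop = FALSE],
                                mc_n = mc_n, seed = sub_seed(seed, stream)),
                    error = function(e) {
                      warning(conditionMessage(e))
                      data.frame(tree_id = metrics$tree_id[ti],
                                 method_id = models[[mi]]$model_id,
                                 agb_t = NA_real_, agb_sd_t = NA_real_)
                    })
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

#' Fit a power-law allometry to TLS-derived data
#'
#' Fits `y = a * x1^b1 * x2^b2 * ...` by nonlinear least squares in
#' arithmetic space, initialised from the log-log linearisation (which is
#' exact when the data are noise-free). This is the machinery used to
#' recalibrate a published model form against TLS-derived volumes, and to
#' derive reduced (e.g. height-only) allometries for Earth-observation use.
#'
#' @param formula model formula, e.g. `volume ~ DTB + H`; each right-hand
#'   term enters as a multiplicative power.
#' @param data data frame with strictly positive response and predictors.
#' @param weights optional observation weights for the arithmetic-space fit.
#' @return Object of class `power_law_fit` with components `coefficients`
#'   (`a`, then one exponent per predictor), `rmse` (absolute),
#'   `rmse_percent` (100 * RMSE / mean response), `fitted`, `residuals`,
#'   `data`, `formula`. Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`.
#' @export
fit_power_law <- function(formula, data, weights = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  xs <- mf[, -1, drop = FALSE]
  if (nrow(mf) < 10L) stopf("need >= 10 records to fit an allometry")
  if (any(y <= 0) || any(as.matrix(xs) <= 0))
    stopf("power-law fit needs strictly positive response and predictors")
  # log-space linearisation for starting values
  ldf <- data.frame(ly = log(y), log(as.matrix(xs)))
  init <- tryCatch(lm(ly ~ ., data = ldf), error = function(e)
    stopf("singular design in power-law initialisation"))
  if (any(is.na(coef(init)))) stopf("singular design: collinear predictors")
  start <- c(a = unname(exp(coef(init)[1])),
             setNames(unname(coef(init)[-1]), paste0("b", seq_len(ncol(xs)))))
  pnames <- names(xs)
  rhs <- paste(sprintf("%s^b%d", pnames, seq_along(pnames)), collapse = " * ")
  nls_formula <- stats::as.formula(paste("y ~ a *", rhs))
  ndf <- cbind(data.frame(y = y), xs)
  fit <- tryCatch(
    nls(nls_formula, data = ndf, start = as.list(start), weights = weights,
        control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) stopf("power-law fit failed: %s", conditionMessage(e)))
  co <- coef(fit)
  fitted_y <- predict(fit)
  res <- y - fitted_y
  rmse <- sqrt(mean(res^2))
  structure(list(coefficients = co, rmse = rmse,
                 rmse_percent = 100 * rmse / mean(y),
                 fitted = fitted_y, residuals = res, data = ndf,
                 formula = formula, nls = fit, n = length(y)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit>", deparse(x$formula), "\n")
  cat("  ", paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
                  collapse = ", "), "\n")
  cat(sprintf("  n = %d, RMSE = %.4g (%.2f%% of mean response)\n", x$n,
              x$rmse, x$rmse_percent))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) object$coefficients

#' @export
residuals.power_law_fit <- function(object, ...) object$residuals

#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict(object$nls, newdata = newdata)
}

#' @export
summary.power_law_fit <- function(object, ...) {
  s <- summary(object$nls)
  list(coefficients = s$coefficients, rmse = object$rmse,
       rmse_percent = object$rmse_percent, n = object$n)
}

#' RMSE (percent of mean response) of fixed power-law coefficients on data
#'
#' Evaluates an already-parameterised power law on a data set without
#' refitting — used to compare original published coefficients against a
#' TLS recalibration on the same records.
#'
#' @param formula as in [fit_power_law()].
#' @param data data frame.
#' @param coefficients named vector `c(a = ..., b1 = ..., ...)`.
#' @return List with `rmse` and `rmse_percent`.
#' @export
power_law_rmse <- function(formula, data, coefficients) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  xs <- as.matrix(mf[, -1, drop = FALSE])
  pred <- rep(coefficients[["a"]], length(y))
  for (i in seq_len(ncol(xs)))
    pred <- pred * xs[, i]^coefficients[[paste0("b", i)]]
  rmse <- sqrt(mean((y - pred)^2))
  list(rmse = rmse, rmse_percent = 100 * rmse / mean(y))
}
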