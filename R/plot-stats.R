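#' Regression of allometric AGB against the TLS reference
#'
#' Ordinary least squares of the candidate (model) AGB on the reference
#' (TLS-derived) AGB, per tree, in arithmetic tons — the reference is the x
#' variable. Reports slope, intercept, r^2, the RMS residual in tons and the
#' coefficient of variation `CV% = 100 * RMSE / mean(reference)`. Setting
#' `include_largest = FALSE` drops the single largest-reference tree before
#' fitting, quantifying the leverage of one giant tree on the regression.
#'
#' @param reference data frame with `tree_id`, `agb_t` (the TLS reference).
#' @param candidate data frame with `tree_id`, `agb_t` (an allometric
#'   estimate); pairing is by `tree_id`.
#' @param include_largest keep the largest-reference tree?
#' @param log_space fit in log-log space instead of arithmetic tons
#'   (sensitivity option; the reported RMSE/CV then refer to log-tons).
#' @param model_id label stored on the result.
#' @return Object of class `comparison_fit` (one-row data frame): model_id,
#'   slope, intercept_t, r2, rmse_t, cv_percent, includes_largest, n.
#' @export
compare_regression <- function(reference, candidate, include_largest = TRUE,
                               log_space = FALSE, model_id = "model") {
  if (!all(reference$tree_id %in% candidate$tree_id))
    stopf("unmatched tree ids between reference and candidate")
  m <- merge(reference[, c("tree_id", "agb_t")],
             candidate[, c("tree_id", "agb_t")], by = "tree_id",
             suffixes = c("_ref", "_cand"))
  m <- m[is.finite(m$agb_t_ref) & is.finite(m$agb_t_cand), ]
  if (nrow(m) < 10L) stopf("need >= 10 paired trees, have %d", nrow(m))
  if (!include_largest) m <- m[-which.max(m$agb_t_ref), ]
  x <- m$agb_t_ref; y <- m$agb_t_cand
  if (log_space) { x <- log(x); y <- log(y) }
  fit <- lm(y ~ x)
  # suppressed: summary.lm warns on exact fits (identity candidates in tests)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  res <- residuals(fit)
  rmse <- sqrt(mean(res^2))
  out <- data.frame(model_id = model_id, slope = unname(coef(fit)[2]),
                    intercept_t = unname(coef(fit)[1]), r2 = r2,
                    rmse_t = rmse, cv_percent = 100 * rmse / mean(x),
                    includes_largest = include_largest, n = length(x),
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_fit", "data.frame")
  out
}

#' Plot-level AGB density with standard error
#'
#' `AGBD = sum(tree AGB) / area` exactly; the standard error combines the
#' per-tree uncertainties in quadrature under an independent-tree
#' assumption: `SE = sqrt(sum(sd_i^2)) / area`.
#'
#' @param records data frame of one plot's trees: `agb_t` and optionally
#'   `agb_sd_t`.
#' @param area_ha plot area (ha).
#' @param plot_id,method_id labels for the summary row.
#' @return One-row data frame (class `plot_summary`): plot_id, method_id,
#'   n_trees, agbd_t_ha, agbd_se_t_ha.
#' @export
plot_agbd <- function(records, area_ha, plot_id = "plot", method_id = "tls") {
  assert_scalar_num(area_ha, "area_ha", 0, strict_lower = TRUE)
  if (!nrow(records)) stopf("empty plot: no tree records")
  agb <- records$agb_t
  if (any(!is.finite(agb))) stopf("non-finite AGB in plot records")
  sds <- records$agb_sd_t %||% rep(0, length(agb))
  sds[!is.finite(sds)] <- 0
  out <- data.frame(plot_id = plot_id, method_id = method_id,
                    n_trees = length(agb),
                    agbd_t_ha = sum(agb) / area_ha,
                    agbd_se_t_ha = sqrt(sum(sds^2)) / area_ha,
                    stringsAsFactors = FALSE)
  class(out) <- c("plot_summary", "data.frame")
  out
}

#' Model-comparison table across a cohort (with/without the largest tree)
#'
#' Runs [compare_regression()] for every allometric method against the TLS
#' reference, once including and once excluding the single largest-reference
#' tree. Species-specific methods are listed before generalised ones when
#' `model_order` is given.
#'
#' @param agb long data frame of per-tree AGB: tree_id, method_id, agb_t
#'   (must contain the reference method and every candidate).
#' @param reference_method method_id to use as reference (default `"tls"`).
#' @param model_order optional character vector fixing row order.
#' @param log_space passed to [compare_regression()].
#' @return Data frame of `comparison_fit` rows, 2 per model.
#' @export
table1_report <- function(agb, reference_method = "tls", model_order = NULL,
                          log_space = FALSE) {
  ref <- agb[agb$method_id == reference_method, ]
  if (!nrow(ref)) stopf("reference method '%s' not present", reference_method)
  methods <- setdiff(unique(agb$method_id), reference_method)
  if (!is.null(model_order))
    methods <- c(intersect(model_order, methods),
                 setdiff(methods, model_order))
  rows <- list()
  for (keep in c(TRUE, FALSE)) {
    for (mm in methods) {
      cand <- agb[agb$method_id == mm, ]
      rows[[length(rows) + 1L]] <-
        compare_regression(ref, cand, include_largest = keep,
                           log_space = log_space, model_id = mm)
    }
  }
  do.call(rbind, rows)
}

#' Plot-level AGBD table across methods
#'
#' @param agb long data frame: tree_id, method_id, agb_t, agb_sd_t.
#' @param plots data frame mapping tree_id to plot_id.
#' @param areas_ha named vector of plot areas (ha) keyed by plot_id.
#' @return Data frame of `plot_summary` rows (plot x method).
#' @export
table2_report <- function(agb, plots, areas_ha) {
  m <- merge(agb, plots[, c("tree_id", "plot_id")], by = "tree_id")
  rows <- list()
  for (pid in unique(plots$plot_id)) {
    if (is.null(areas_ha[[pid]])) stopf("no area for plot '%s'", pid)
    for (mm in unique(m$method_id)) {
      rec <- m[m$plot_id == pid & m$method_id == mm &
                 is.finite(m$agb_t), ]
      if (!nrow(rec)) next
      rows[[length(rows) + 1L]] <-
        plot_agbd(rec, areas_ha[[pid]], plot_id = pid, method_id = mm)
    }
  }
  do.call(rbind, rows)
}
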