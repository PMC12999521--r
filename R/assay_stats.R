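#' Per-plot community summaries of critical thermal limits
#'
#' One row per plot x assay direction with sample size, mean, median and the
#' 10%/25% community quantiles (shared [ct_quantile()] rule), joined with
#' the plot climate normals bio1 (mean annual temperature) and bio5 (mean
#' daily maximum of the warmest month).
#'
#' @param records assay record data.frame (columns `plot_id`, `direction`,
#'   `ct_value`; other columns ignored).
#' @param normals plot table with `plot_id`, `elevation`, `bio1`, `bio5`.
#' @return data.frame of plot summaries.
#' @export
summarize_plots <- function(records, normals) {
  check_columns(records, c("plot_id", "direction", "ct_value"), "records")
  check_columns(normals, c("plot_id", "elevation", "bio1", "bio5"), "normals")
  missing <- setdiff(unique(records$plot_id), normals$plot_id)
  if (length(missing) > 0) {
    stop_classed("missing_metadata", "plots without climate normals: %s",
                 paste(missing, collapse = ", "))
  }
  grp <- split(records, list(records$plot_id, records$direction), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    q <- ct_quantile(g$ct_value, c(0.10, 0.25, 0.50))
    data.frame(plot_id = g$plot_id[1], direction = g$direction[1],
               n = nrow(g), mean = mean(g$ct_value), q10 = q[1], q25 = q[2],
               median = q[3], stringsAsFactors = FALSE)
  }))
  out <- join_on(out, normals[, c("plot_id", "elevation", "bio1", "bio5")],
                 by = "plot_id")
  out <- out[order(out$plot_id, out$direction), ]
  rownames(out) <- NULL
  out
}

#' Elevational (or thermal) trend in community thermal limits
#'
#' Linear mode is ordinary least squares and reports slope, intercept and
#' the overall F test. Spline mode fits a penalized regression spline with
#' basis dimension k = 5 (smoothness chosen by GCV) and evaluates the fitted
#' curve on a grid, reporting the smooth-term F and p.
#'
#' @param y response values (e.g. CTmax, degC).
#' @param x predictor (elevation in metres, or mean annual temperature degC).
#' @param mode `"linear"` or `"spline_k5"`.
#' @param grid_n number of grid points for the spline curve.
#' @return list of class `trend_fit`: `mode`, `slope`/`intercept` (linear),
#'   `grid` (data.frame x, fit), `F`, `p`, and the underlying model object.
#' @export
fit_elevation_trend <- function(y, x, mode = c("linear", "spline_k5"),
                                grid_n = 100L) {
  mode <- match.arg(mode)
  if (length(unique(x)) < 2) {
    stop_classed("degenerate_design", "predictor is constant")
  }
  n_min <- if (mode == "linear") 3L else 6L
  if (length(y) < n_min) {
    stop_classed("invalid_argument", "need >= %d points for mode %s", n_min, mode)
  }
  gx <- seq(min(x), max(x), length.out = grid_n)
  if (mode == "linear") {
    if (stats::var(y) == 0) {
      return(structure(list(mode = mode, slope = 0, intercept = y[1],
                            grid = data.frame(x = gx, fit = rep(y[1], grid_n)),
                            F = 0, p = 1, model = NULL), class = "trend_fit"))
    }
    fit <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(fit))
    Fv <- if (sm$sigma == 0 || is.null(sm$fstatistic)) 0 else sm$fstatistic[[1]]
    p <- if (Fv == 0) 1 else stats::pf(Fv, sm$fstatistic[[2]],
                                       sm$fstatistic[[3]], lower.tail = FALSE)
    structure(list(mode = mode, slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   grid = data.frame(x = gx, fit = stats::coef(fit)[1] +
                                       stats::coef(fit)[2] * gx),
                   F = Fv, p = p, model = fit), class = "trend_fit")
  } else {
    fit <- mgcv::gam(y ~ s(x, k = 5), method = "GCV.Cp")
    st <- summary(fit)$s.table
    structure(list(mode = mode,
                   grid = data.frame(
                     x = gx,
                     fit = as.numeric(stats::predict(fit,
                                                     newdata = data.frame(x = gx)))),
                   F = unname(st[1, "F"]), p = unname(st[1, "p-value"]),
                   model = fit), class = "trend_fit")
  }
}

#' Thermal tolerance range and safety margins per plot
#'
#' Range = mean CTmax - mean CTmin; upper thermal safety margins =
#' mean CTmax minus bio1 and minus bio5. Plots missing one assay direction
#' are skipped with a warning.
#'
#' @param summaries output of [summarize_plots()] containing both directions.
#' @return data.frame: `plot_id`, `elevation`, `range`, `margin_bio1`,
#'   `margin_bio5`.
#' @export
thermal_range_and_margin <- function(summaries) {
  check_columns(summaries, c("plot_id", "direction", "mean", "bio1", "bio5"),
                "summaries")
  out <- do.call(rbind, lapply(split(summaries, summaries$plot_id), function(g) {
    mx <- g[g$direction == "ctmax", ]
    mn <- g[g$direction == "ctmin", ]
    if (nrow(mx) == 0 || nrow(mn) == 0) {
      warning(sprintf("plot %s lacks one assay direction; skipped", g$plot_id[1]),
              call. = FALSE)
      return(NULL)
    }
    data.frame(plot_id = g$plot_id[1], elevation = mx$elevation[1],
               range = mx$mean - mn$mean,
               margin_bio1 = mx$mean - mx$bio1,
               margin_bio5 = mx$mean - mx$bio5, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Heat/cold-shock plasticity effect by elevation band
#'
#' Within each region x elevation band x direction cell, the effect is the
#' shocked-group mean minus the control mean for CTmax, and control minus
#' shocked for CTmin, so a positive effect always means increased tolerance.
#' Bands lacking either treatment group are omitted with a warning. The
#' reported `se` is the standard error of the difference of group means.
#'
#' @param records assay records with `region`, `elevation`, `direction`,
#'   `shocked` ("yes"/"no") and `ct_value`.
#' @param bands interior elevation cut points (metres), half-open bands
#'   `[0,600)`, `[600,1200)`, `[1200,Inf)` by default.
#' @return data.frame: `region`, `band`, `direction`, `effect`, `se`,
#'   `n_shock`, `n_control`.
#' @export
shock_effect <- function(records, bands = c(600, 1200)) {
  if (nrow(records) == 0) {
    return(data.frame(region = character(), band = character(),
                      direction = character(), effect = numeric(),
                      se = numeric(), n_shock = integer(),
                      n_control = integer(), stringsAsFactors = FALSE))
  }
  check_columns(records, c("region", "elevation", "direction", "shocked",
                           "ct_value"), "records")
  records$band <- elevation_band(records$elevation, cuts = bands)
  grp <- split(records, list(records$region, records$band, records$direction),
               drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    ys <- g$ct_value[g$shocked == "yes"]
    yc <- g$ct_value[g$shocked == "no"]
    if (length(ys) == 0 || length(yc) == 0) {
      warning(sprintf("band %s/%s/%s lacks a treatment group; omitted",
                      g$region[1], g$band[1], g$direction[1]), call. = FALSE)
      return(NULL)
    }
    eff <- mean(ys) - mean(yc)
    if (g$direction[1] == "ctmin") eff <- -eff
    se <- sqrt(stats::var(ys) / length(ys) + stats::var(yc) / length(yc))
    data.frame(region = g$region[1], band = as.character(g$band[1]),
               direction = g$direction[1], effect = eff, se = se,
               n_shock = length(ys), n_control = length(yc),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way observer ANOVA on CTmax
#'
#' Fixed-effects check that field observers do not differ in mean measured
#' CTmax (observer bias control).
#'
#' @param records assay records with `observer` and `ct_value`.
#' @return list: `F`, `df1`, `df2`, `p`.
#' @export
observer_anova <- function(records) {
  check_columns(records, c("observer", "ct_value"), "records")
  obs <- factor(records$observer)
  if (nlevels(obs) < 2) {
    stop_classed("invalid_argument", "need >= 2 observers")
  }
  counts <- table(obs)
  if (any(counts < 2)) {
    stop_classed("invalid_argument", "every observer needs >= 2 records")
  }
  fit <- stats::aov(ct_value ~ obs, data = data.frame(ct_value = records$ct_value,
                                                      obs = obs))
  tab <- summary(fit)[[1]]
  Fv <- tab["obs", "F value"]
  if (is.nan(Fv)) Fv <- 0  # zero residual variance with equal means
  list(F = unname(Fv), df1 = tab["obs", "Df"], df2 = tab["Residuals", "Df"],
       p = if (Fv == 0) 1 else unname(tab["obs", "Pr(>F)"]))
}

#' Record- or plot-level trend from assay records
#'
#' Convenience wrapper implementing both regression granularities: trends
#' fitted on individual records with plot-level predictors (default), or on
#' plot means.
#'
#' @param records assay records (one direction).
#' @param plots plot table with `plot_id`, `elevation`, `bio1`.
#' @param predictor `"elevation"` or `"mat"` (bio1).
#' @param level `"record"` or `"plot"`.
#' @param mode passed to [fit_elevation_trend()].
#' @return a `trend_fit`.
#' @export
trend_from_records <- function(records, plots, predictor = c("elevation", "mat"),
                               level = c("record", "plot"),
                               mode = c("linear", "spline_k5")) {
  predictor <- match.arg(predictor); level <- match.arg(level)
  mode <- match.arg(mode)
  xcol <- if (predictor == "elevation") "elevation" else "bio1"
  d <- join_on(records[, c("plot_id", "ct_value")],
               plots[, c("plot_id", xcol)], by = "plot_id")
  if (level == "plot") {
    d <- stats::aggregate(ct_value ~ plot_id, d, mean)
    d <- join_on(d, plots[, c("plot_id", xcol)], by = "plot_id")
  }
  fit_elevation_trend(d$ct_value, d[[xcol]], mode = mode)
}

# internal: schema check with a helpful message
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop_classed("schema_error", "%s is missing column(s): %s", what,
                 paste(miss, collapse = ", "))
  }
  invisible(df)
}
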