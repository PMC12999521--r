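#' Thermal-death-time parameters
#'
#' The static tolerance landscape: holding an insect at constant temperature
#' T, time to heat coma is `t_ref * 10^((T_L - T)/z)`. `z` is the thermal
#' sensitivity (degC that divides knockdown time by ten); `T_L` the static
#' temperature causing coma at the reference time `t_ref` (minutes).
#'
#' @param T_L static limit temperature (degC).
#' @param z thermal sensitivity (degC per decade of time), > 0.
#' @param t_ref reference time (minutes), > 0; 1 min by default.
#' @return list of class `tdt_params`.
#' @export
tdt_params <- function(T_L, z = 3, t_ref = 1) {
  if (z <= 0) stop_classed("invalid_argument", "z must be > 0")
  if (t_ref <= 0) stop_classed("invalid_argument", "t_ref must be > 0")
  structure(list(T_L = T_L, z = z, t_ref = t_ref), class = "tdt_params")
}

#' Estimate thermal sensitivity z from static knockdown data
#'
#' Least-squares fit of log10(time) on temperature; the TDT line has slope
#' -1/z, so z = -1/slope, and T_L is the temperature at which the fitted
#' time equals `t_ref`.
#'
#' @param knockdowns data.frame with `temp` (degC) and `time_min` (minutes).
#' @param t_ref reference time for `T_L` (minutes).
#' @return a [tdt_params()] with an `r2` attribute.
#' @export
fit_z <- function(knockdowns, t_ref = 1) {
  check_columns(knockdowns, c("temp", "time_min"), "knockdowns")
  if (length(unique(knockdowns$temp)) < 2) {
    stop_classed("invalid_argument", "need >= 2 distinct temperatures")
  }
  fit <- stats::lm(log10(time_min) ~ temp, data = knockdowns)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) {
    stop_classed("implausible_sensitivity",
                 "knockdown time does not decrease with temperature (slope %.3g)",
                 slope)
  }
  z <- -1 / slope
  T_L <- (log10(t_ref) - intercept) / slope
  out <- tdt_params(T_L = T_L, z = z, t_ref = t_ref)
  attr(out, "r2") <- suppressWarnings(summary(fit)$r.squared)
  out
}

#' Convert a dynamic (ramping) CTmax to a static limit temperature
#'
#' Under memoryless injury accumulation, a linear ramp from `start_temp` at
#' rate r reaches coma at `ct_dyn` when the accumulated injury equals one:
#' `(z / (r ln10 t_ref)) * (10^((ct_dyn - T_L)/z) - 10^((start - T_L)/z)) = 1`.
#' The full equation (default) is solved for `T_L` by root finding; setting
#' `approximate = TRUE` drops the start term, giving the closed form
#' `T_L = ct_dyn - z log10(r t_ref ln10 / z)`.
#'
#' @param ct_dyn dynamic CTmax from the ramping assay (degC).
#' @param ramp_rate ramp rate r (degC/min), > 0.
#' @param z thermal sensitivity (degC).
#' @param t_ref reference time (minutes).
#' @param start_temp ramp start temperature (degC), must be below `ct_dyn`.
#' @param approximate drop the start term (closed form).
#' @return static limit temperature T_L (degC), vectorized over `ct_dyn`.
#' @export
dynamic_to_static <- function(ct_dyn, ramp_rate, z = 3, t_ref = 1,
                              start_temp = 28, approximate = FALSE) {
  if (ramp_rate <= 0) stop_classed("invalid_argument", "ramp_rate must be > 0")
  if (any(ct_dyn <= start_temp)) {
    stop_classed("invalid_argument", "ct_dyn must exceed start_temp")
  }
  closed <- ct_dyn - z * log10(ramp_rate * t_ref * log(10) / z)
  if (approximate) return(closed)
  vapply(seq_along(ct_dyn), function(i) {
    ct <- ct_dyn[i]
    f <- function(T_L) {
      (z / (ramp_rate * log(10) * t_ref)) *
        (10^((ct - T_L) / z) - 10^((start_temp - T_L) / z)) - 1
    }
    lo <- closed[i] - 5 * z; hi <- ct + 5 * z
    if (!(f(lo) > 0 && f(hi) < 0)) {
      stop_classed("numerical_error",
                   "no root bracketed for ct_dyn = %.3f in [%.2f, %.2f]",
                   ct, lo, hi)
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' Simulate a linear ramping assay under a static tolerance landscape
#'
#' Forward model used as the quadrature oracle for [dynamic_to_static()]:
#' integrates the injury rate 1/t_coma(T(t)) along the ramp
#' `T(t) = start + r t` and returns the temperature at which accumulated
#' injury reaches one.
#'
#' @param params a [tdt_params()].
#' @param ramp_rate degC/min.
#' @param start_temp degC.
#' @param dt integration step (minutes).
#' @return coma temperature on the ramp (degC).
#' @export
ramp_to_coma <- function(params, ramp_rate, start_temp = 28, dt = 0.001) {
  injury <- 0; t <- 0
  repeat {
    Tmid <- start_temp + ramp_rate * (t + dt / 2)
    injury <- injury + dt / t_coma(Tmid, params)
    t <- t + dt
    if (injury >= 1) return(start_temp + ramp_rate * t)
    if (t > 1e6) stop_classed("numerical_error", "ramp never reaches coma")
  }
}

#' Time to heat coma at a constant temperature
#'
#' `t = t_ref * 10^((T_L - T)/z)`; strictly decreasing in T, exactly
#' log-linear with slope -1/z.
#'
#' @param T constant exposure temperature(s) (degC).
#' @param params a [tdt_params()].
#' @return minutes, same length as `T`.
#' @export
t_coma <- function(T, params) {
  params$t_ref * 10^((params$T_L - T) / params$z)
}

#' Critical temperature for a coma-time threshold
#'
#' The constant temperature at which predicted coma time equals the
#' threshold: `T_crit = T_L - z log10(threshold / t_ref)`.
#'
#' @param params a [tdt_params()].
#' @param threshold_min minutes (480 = 8 h by default).
#' @return degC.
#' @export
critical_temperature <- function(params, threshold_min = 480) {
  params$T_L - params$z * log10(threshold_min / params$t_ref)
}

#' Classify temperature measurements as critical
#'
#' A value is critical iff its predicted coma time is at or below the
#' threshold, i.e. value >= `critical_temperature(params, threshold)`. The
#' fraction is taken over all retained values, night temperatures included.
#'
#' @param series temperature series data.frame with a `value` column.
#' @param params a [tdt_params()].
#' @param threshold_min coma-time threshold in minutes (default 480 = 8 h).
#' @return list: `mask` (logical), `fraction`, `n`.
#' @export
classify_critical <- function(series, params, threshold_min = 480) {
  if (nrow(series) == 0) stop_classed("empty_input", "empty temperature series")
  tc <- critical_temperature(params, threshold_min)
  mask <- series$value >= tc
  list(mask = mask, fraction = mean(mask), n = nrow(series))
}

#' Shift a temperature series by a climate anomaly
#'
#' Adds the bio5 anomaly (future minus current mean daily maximum of the
#' warmest month) to every value; timestamps are untouched. Surface series
#' receive the same air-derived shift (a conservative choice; a multiplier
#' is exposed for sensitivity analysis).
#'
#' @param series temperature series data.frame with a `value` column.
#' @param bio5_now,bio5_future current and scenario normals (degC).
#' @param multiplier scaling of the anomaly (default 1).
#' @return the series with shifted values.
#' @export
project_series <- function(series, bio5_now, bio5_future, multiplier = 1) {
  if (is.na(bio5_now) || is.na(bio5_future)) {
    stop_classed("missing_metadata", "bio5 normals missing for projection")
  }
  series$value <- series$value + multiplier * (bio5_future - bio5_now)
  series
}

#' Community sensitivity levels as static tolerance landscapes
#'
#' Converts community CTmax quantiles of the (lowland) assay distribution -
#' the median (average insects), 25% quantile (more heat-sensitive) and 10%
#' quantile (most heat-sensitive) - into one [tdt_params()] each via
#' [dynamic_to_static()], to be applied gradient-wide.
#'
#' @param lowland_ctmax CTmax values (degC) of the reference community.
#' @param quantiles named or unnamed probabilities (default 0.10/0.25/0.50).
#' @param ramp_rate assay ramp rate (degC/min).
#' @param z,t_ref TDT parameters.
#' @param start_temp assay start temperature (degC).
#' @return named list of [tdt_params()] (`q10`, `q25`, `median`).
#' @export
community_sensitivity <- function(lowland_ctmax,
                                  quantiles = c(q10 = 0.10, q25 = 0.25,
                                                median = 0.50),
                                  ramp_rate = 0.5, z = 3, t_ref = 1,
                                  start_temp = 28) {
  if (length(lowland_ctmax) < 10) {
    warning("fewer than 10 community CTmax values", call. = FALSE)
  }
  qs <- ct_quantile(lowland_ctmax, unname(quantiles))
  nm <- if (!is.null(names(quantiles))) names(quantiles) else
    paste0("q", round(100 * quantiles))
  out <- lapply(qs, function(ct) {
    tdt_params(dynamic_to_static(ct, ramp_rate, z, t_ref, start_temp),
               z = z, t_ref = t_ref)
  })
  names(out) <- nm
  out
}

#' Critical-temperature fractions across plots, scenarios and sensitivities
#'
#' Cross product of plot x series kind x scenario x community sensitivity:
#' each series is anomaly-shifted to the scenario (via plot bio5 normals)
#' and the fraction of critical values computed with [classify_critical()].
#'
#' @param series_list named list (plot_id -> temperature series data.frame,
#'   each with `value` and `kind`).
#' @param sensitivity named list of [tdt_params()] (e.g. from
#'   [community_sensitivity()]).
#' @param plots plot table with `plot_id`, `bio5`, and one
#'   `bio5_<scenario>` column per future scenario.
#' @param scenarios character vector; `"current"` plus names matching the
#'   `bio5_*` columns (e.g. `"ssp126"`).
#' @param threshold_min coma-time threshold (minutes).
#' @return data.frame of class `coma_summary`: `plot_id`, `kind`,
#'   `scenario`, `sensitivity`, `fraction_critical`, `n`.
#' @export
summarize_coma <- function(series_list, sensitivity, plots,
                           scenarios = "current", threshold_min = 480) {
  out <- list(); idx <- 0L
  for (pid in names(series_list)) {
    ser <- series_list[[pid]]
    prow <- plots[plots$plot_id == pid, ]
    if (nrow(prow) != 1) {
      stop_classed("missing_metadata", "plot %s not in plots table", pid)
    }
    for (kind in unique(ser$kind)) {
      sk <- ser[ser$kind == kind, , drop = FALSE]
      for (sc in scenarios) {
        shifted <- if (sc == "current") sk else {
          col <- paste0("bio5_", sc)
          if (!col %in% names(plots)) {
            stop_classed("missing_metadata", "no column %s in plots", col)
          }
          project_series(sk, prow$bio5, prow[[col]])
        }
        for (sens in names(sensitivity)) {
          cc <- classify_critical(shifted, sensitivity[[sens]], threshold_min)
          idx <- idx + 1L
          out[[idx]] <- data.frame(plot_id = pid, kind = kind, scenario = sc,
                                   sensitivity = sens,
                                   fraction_critical = cc$fraction, n = cc$n,
                                   stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("coma_summary", class(res))
  res
}
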