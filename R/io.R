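# Readers/writers for the pipeline's delimited-text surfaces. CSV (UTF-8,
# comma, '.' decimal) is the only tabular dialect; Newick the only tree
# format; timestamps are ISO-8601 with explicit UTC offset.

# internal: read a CSV, tolerate '#'-prefixed header comments
read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop_classed("schema_error", "file not found: %s", path)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_columns(df, required, what)
  df
}

#' Read an assay record table
#'
#' Required columns: `individual_id`, `plot_id`, `elevation`, `direction`,
#' `ct_value`; unknown columns are preserved. Values outside the plausible
#' direction ranges (CTmax 25-60 degC, CTmin -10..28 degC) trigger a warning.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_assays <- function(path) {
  df <- read_table_checked(path, c("individual_id", "plot_id", "elevation",
                                   "direction", "ct_value"), "assays")
  if (nrow(df) == 0) return(df)
  bad_dir <- !df$direction %in% c("ctmax", "ctmin")
  if (any(bad_dir)) {
    stop_classed("schema_error", "unknown direction at rows: %s",
                 paste(utils::head(which(bad_dir), 10), collapse = ", "))
  }
  mx <- df$direction == "ctmax" & (df$ct_value < 25 | df$ct_value > 60)
  mn <- df$direction == "ctmin" & (df$ct_value < -10 | df$ct_value > 28)
  if (any(mx | mn)) {
    warning(sprintf("%d CT values outside the plausible range for their direction",
                    sum(mx | mn)), call. = FALSE)
  }
  if (any(df$elevation < 0)) {
    warning("negative elevations present", call. = FALSE)
  }
  df
}

#' Read a temperature time series table
#'
#' Required columns: `plot_id`, `timestamp` (ISO-8601), `value`, `kind`,
#' `qc`. Timestamps must parse and be strictly increasing within a plot.
#'
#' @param path CSV path.
#' @return data.frame with `timestamp` as POSIXct (UTC).
#' @export
read_series <- function(path) {
  df <- read_table_checked(path, c("plot_id", "timestamp", "value", "kind",
                                   "qc"), "series")
  if (nrow(df) == 0) {
    df$timestamp <- as.POSIXct(character(), tz = "UTC")
    return(df)
  }
  ts <- as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S%z", "%Y-%m-%dT%H:%M:%S",
                "%Y-%m-%d %H:%M:%S")) {
    idx <- is.na(ts)
    if (!any(idx)) break
    ts[idx] <- as.POSIXct(strptime(df$timestamp[idx], fmt, tz = "UTC"))
  }
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    stop_classed("schema_error", "unparseable timestamps at rows: %s",
                 paste(utils::head(bad, 10), collapse = ", "))
  }
  df$timestamp <- ts
  for (pid in unique(df$plot_id)) {
    tt <- df$timestamp[df$plot_id == pid]
    if (any(diff(as.numeric(tt)) <= 0)) {
      stop_classed("schema_error",
                   "timestamps not strictly increasing for plot %s", pid)
    }
  }
  if (any(!is.finite(df$value))) {
    stop_classed("schema_error", "non-finite temperature values present")
  }
  df
}

#' Read a plot table (elevations and climate normals)
#'
#' Required: `plot_id`, `elevation`, `bio1`, `bio5`; scenario normals as
#' `bio5_<scenario>` columns are preserved.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_plots <- function(path) {
  read_table_checked(path, c("plot_id", "elevation", "bio1", "bio5"), "plots")
}

#' Read a protein melting-temperature table
#'
#' Required: `species_id`, `family`, `order`, `protein_id`, `tm`;
#' (species, protein) pairs must be unique.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_tm <- function(path) {
  df <- read_table_checked(path, c("species_id", "family", "order",
                                   "protein_id", "tm"), "tm table")
  if (anyDuplicated(df[, c("species_id", "protein_id")])) {
    stop_classed("schema_error", "duplicated (species, protein) pairs")
  }
  df
}

#' Quality-control policy for temperature series
#'
#' @param keep_flags flag codes to retain (default best-quality `"0b00"`).
#' @param action `"drop"` (remove other rows) or `"warn"` (keep, warn).
#' @return list of class `qc_policy`.
#' @export
qc_policy <- function(keep_flags = "0b00", action = c("drop", "warn")) {
  if (length(keep_flags) == 0) {
    stop_classed("invalid_argument", "keep_flags must be non-empty")
  }
  structure(list(keep_flags = keep_flags, action = match.arg(action)),
            class = "qc_policy")
}

#' Apply a QC policy to a temperature series
#'
#' Retains only values whose flag is in the policy's keep set; the number
#' of dropped values is reported. Dropping everything is a warning, not an
#' error.
#'
#' @param series data.frame with a `qc` column.
#' @param policy a [qc_policy()].
#' @return filtered series.
#' @export
apply_qc <- function(series, policy = qc_policy()) {
  check_columns(series, "qc", "series")
  keep <- series$qc %in% policy$keep_flags
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    if (policy$action == "warn") {
      warning(sprintf("%d values fail QC (kept by policy action 'warn')", n_drop),
              call. = FALSE)
      return(series)
    }
    message(sprintf("apply_qc: dropped %d of %d values", n_drop, nrow(series)))
  }
  out <- series[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("all values dropped by QC", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a CSV with a provenance header
#'
#' Prepends '#'-prefixed comment lines (version, seed, config hash) that
#' the package readers skip.
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta named list written as header comments.
#' @return invisibly, `path`.
#' @export
write_output_csv <- function(df, path, meta = list()) {
  meta <- c(list(package = "thermotree",
                 version = as.character(utils::packageVersion("thermotree"))),
            meta)
  hdr <- sprintf("# %s: %s", names(meta), vapply(meta, function(x)
    paste(format(x), collapse = ","), character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Simulate (optional) -> assay statistics -> phylogenetic comparative
#' models -> thermal-death-time projections -> protein Tm summaries. Every
#' output CSV carries a header with version, seed and config hash; a log
#' file records each stage. A stage failure aborts with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param config list with at least `seed` and `out_dir`; either
#'   `simulate = TRUE` (with an optional `sim` list of [sim_config()]
#'   overrides) or input paths `assays`, `plots`, `tree`, `series`, `tm`.
#'   Optional knobs: `z`, `t_ref`, `threshold_min`, `ramp_rate`,
#'   `scenarios`, `quantiles`.
#' @return invisibly, a list of stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_core <- config[setdiff(names(config), "out_dir")]   # paths excluded
  cfg_hash <- sum(utf8ToInt(paste(deparse(cfg_core), collapse = "")))
  meta <- list(seed = config$seed, config_hash = cfg_hash)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf(...), "\n", file = logf, append = TRUE)
    message(sprintf(...))
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      stop_classed("stage_failure", "stage '%s' failed: %s", name,
                   conditionMessage(e))
    })
    log_line("stage %s done in %.2f s", name,
             as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  z <- config$z %||% 3
  t_ref <- config$t_ref %||% 1
  threshold <- config$threshold_min %||% 480
  ramp_rate <- config$ramp_rate %||% 0.5
  scenarios <- config$scenarios %||% c("current", "ssp126", "ssp370", "ssp585")

  if (isTRUE(config$simulate)) {
    sc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    bundle <- stage("simulate", simulate_all(sc, out_dir = out_dir))
    assays <- bundle$assays; plots <- bundle$plots
    tree <- bundle$tree; climate <- bundle$climate; tm <- bundle$tm
    trait <- bundle$trait; elev_tip <- bundle$tip_elevation
  } else {
    for (p in c(config$assays, config$plots, config$tree, config$series,
                config$tm)) {
      if (!is.null(p) && !file.exists(p)) {
        stop_classed("schema_error", "input path does not exist: %s", p)
      }
    }
    assays <- stage("read", read_assays(config$assays))
    plots <- read_plots(config$plots)
    tree <- ape::read.tree(config$tree)
    climate <- read_series(config$series)
    tm <- if (!is.null(config$tm)) read_tm(config$tm) else NULL
    trait <- tapply(assays$ct_value[assays$direction == "ctmax"],
                    assays$otu_id[assays$direction == "ctmax"], mean)
    trait <- trait[as_phylo(tree)$tip.label]
    elev_tip <- tapply(assays$elevation, assays$otu_id, mean)[names(trait)]
  }

  # assay statistics
  summaries <- stage("assay_stats", {
    s <- summarize_plots(assays, plots)
    write_output_csv(s, file.path(out_dir, "plot_summaries.csv"), meta)
    eff <- shock_effect(assays)
    write_output_csv(eff, file.path(out_dir, "shock_effects.csv"), meta)
    s
  })

  # comparative models
  phylo_out <- stage("phylo", {
    fits <- list(suppressWarnings(pgls_fit(tree, trait, data.frame(elevation = elev_tip),
                                           "BM")),
                 suppressWarnings(pgls_fit(tree, trait, data.frame(elevation = elev_tip),
                                           "OU")),
                 suppressWarnings(pgls_fit(tree, trait, data.frame(elevation = elev_tip),
                                           "star")))
    cmp <- compare_models(fits)
    write_output_csv(cmp, file.path(out_dir, "model_comparison.csv"), meta)
    opt <- fit_ou_optimum(tree, trait)
    sig <- pagel_lambda(tree, trait)
    K <- blomberg_k(tree, trait, n_perm = 999L, seed = config$seed)
    write_output_csv(
      data.frame(theta = opt$theta, alpha = opt$alpha, sigma2 = opt$sigma2,
                 lambda = sig$lambda, lambda_p = sig$p, K = K$K, K_p = K$p),
      file.path(out_dir, "phylo_signal.csv"), meta)
    list(compare = cmp, optimum = opt, lambda = sig, K = K)
  })

  # thermal-death-time projections
  tdt_out <- stage("tdt", {
    low_plot <- plots$plot_id[which.min(plots$elevation)]
    low_ct <- assays$ct_value[assays$plot_id == low_plot &
                                assays$direction == "ctmax"]
    sens <- community_sensitivity(low_ct, ramp_rate = ramp_rate, z = z,
                                  t_ref = t_ref)
    qc_series <- apply_qc(climate, qc_policy())
    series_list <- split(qc_series, qc_series$plot_id)
    sc_avail <- c("current",
                  intersect(sub("^bio5_", "", grep("^bio5_", names(plots),
                                                   value = TRUE)),
                            setdiff(scenarios, "current")))
    cs <- summarize_coma(series_list, sens, plots, scenarios = sc_avail,
                         threshold_min = threshold)
    write_output_csv(cs, file.path(out_dir, "coma_summary.csv"), meta)
    cs
  })

  # protein melting temperatures
  tm_out <- if (!is.null(tm)) stage("protein", {
    sp <- sensitive_quantile_mean(tm)
    write_output_csv(sp, file.path(out_dir, "tm_species.csv"), meta)
    vt <- tm_variance_tests(tm)
    write_output_csv(as.data.frame(vt), file.path(out_dir, "tm_tests.csv"), meta)
    list(species = sp, tests = vt)
  }) else NULL

  invisible(list(summaries = summaries, phylo = phylo_out, tdt = tdt_out,
                 protein = tm_out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
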