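#' Simulation configuration with known ground truth
#'
#' Bundles every knob of the synthetic-data module. The defaults describe a
#' tropical elevation-gradient study: a community phylogeny of a few hundred
#' barcode-delimited OTUs structured into families, CTmax evolving under
#' stationary Ornstein-Uhlenbeck pull towards a community optimum near
#' 42.2 degC with a linear elevation effect, a ramping assay discretized at
#' 1 degC per 2-min step from a 28 degC start, diurnal microclimate series
#' with an elevational lapse, and a log-linear thermal-death-time landscape.
#'
#' @param seed root integer seed; every generator derives a named substream
#'   from it via [substream_seed()].
#' @param n_tips number of OTUs on the simulated tree.
#' @param n_families number of family clades cut from the tree.
#' @param tree_depth total root-to-tip depth (relative time units).
#' @param elevation_grid plot elevations in metres above sea level.
#' @param trait_params list: `beta0` (intercept / optimum, degC), `beta_elev`
#'   (degC per metre), `alpha` (OU pull, 1/time), `sigma2` (degC^2/time).
#' @param assay_params list: `start_temp` (degC), `step` (degC),
#'   `interval_min` (minutes per step; the ramp rate is `step/interval_min`).
#' @param climate_params list: `sea_level_mean` (degC), `lapse` (degC/m),
#'   `diurnal_amp` (degC), `seasonal_amp` (degC), `ar1`, `noise_sd` (degC).
#' @param tdt_truth list: `T_L` (degC at `t_ref`), `z` (degC per tenfold
#'   time), `t_ref` (minutes).
#' @param ind_sd within-OTU standard deviation of individual thresholds
#'   (degC); the study design does not pin this down, 1 degC is used.
#' @param n_per_otu individuals assayed per OTU.
#' @param shock_effects named numeric, true heat-shock shift of the group
#'   mean by elevation band (`low`, `mid`, `high`), degC.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tips = 200L,
                       n_families = 20L,
                       tree_depth = 1,
                       elevation_grid = seq(0, 3000, by = 500),
                       trait_params = list(beta0 = 42.2, beta_elev = -0.0022,
                                           alpha = 0.3, sigma2 = 10),
                       assay_params = list(start_temp = 28, step = 1,
                                           interval_min = 2),
                       climate_params = list(sea_level_mean = 26,
                                             lapse = 0.0054,
                                             diurnal_amp = 5,
                                             seasonal_amp = 1,
                                             ar1 = 0.7, noise_sd = 1.5),
                       tdt_truth = list(T_L = 46, z = 3, t_ref = 1),
                       ind_sd = 1,
                       n_per_otu = 3L,
                       shock_effects = c(low = -1.61, mid = -0.25, high = 1.10)) {
  stopifnot(n_tips >= 1, n_families >= 1,
            trait_params$alpha >= 0, trait_params$sigma2 > 0,
            assay_params$step > 0, tdt_truth$z > 0, tdt_truth$t_ref > 0)
  structure(list(seed = as.integer(seed), n_tips = as.integer(n_tips),
                 n_families = as.integer(n_families), tree_depth = tree_depth,
                 elevation_grid = elevation_grid, trait_params = trait_params,
                 assay_params = assay_params, climate_params = climate_params,
                 tdt_truth = tdt_truth, ind_sd = ind_sd,
                 n_per_otu = as.integer(n_per_otu),
                 shock_effects = shock_effects),
            class = "sim_config")
}

#' Simulate an ultrametric community phylogeny with family structure
#'
#' Pure-birth (Yule) tree rescaled to a fixed depth, tips relabelled
#' `OTU_1..n`. Families (and, more coarsely, orders) are assigned by cutting
#' the tree at the time slice where the lineage count equals the requested
#' number of clades, so family membership is always monophyletic.
#'
#' @param n_tips number of tips (>= 1).
#' @param seed integer seed.
#' @param n_families target number of family clades (capped at `n_tips`).
#' @param depth root-to-tip depth of the output tree.
#' @param n_orders target number of order clades; default groups roughly
#'   four families per order.
#' @return a list of class `calibrated_tree` with elements `phy` (an
#'   [ape::phylo]) and `tips` (data.frame: `label`, `family`, `order`).
#' @export
simulate_tree <- function(n_tips, seed = 1L,
                          n_families = max(1L, round(n_tips / 10)),
                          depth = 1,
                          n_orders = max(1L, ceiling(n_families / 4))) {
  if (n_tips < 1) stop_classed("invalid_argument", "n_tips must be >= 1")
  n_families <- min(as.integer(n_families), n_tips)
  n_orders <- min(as.integer(n_orders), n_families)
  if (n_tips == 1L) {
    phy <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          edge.length = 0,
                          tip.label = "OTU_1", Nnode = 1L),
                     class = "phylo")
    tips <- data.frame(label = "OTU_1", family = "Fam_01", order = "Order_1",
                       stringsAsFactors = FALSE)
    return(structure(list(phy = phy, tips = tips), class = "calibrated_tree"))
  }
  set.seed(substream_seed(seed, "tree"))
  phy <- ape::rphylo(n_tips, birth = 1, death = 0)
  dep <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (depth / dep)
  phy$tip.label <- paste0("OTU_", seq_len(n_tips))
  fam <- clade_cut(phy, n_families, prefix = "Fam_")
  ord <- clade_cut(phy, n_orders, prefix = "Order_")
  tips <- data.frame(label = phy$tip.label, family = fam, order = ord,
                     stringsAsFactors = FALSE)
  structure(list(phy = phy, tips = tips), class = "calibrated_tree")
}

# internal: assign tips to k monophyletic groups by slicing the ultrametric
# tree where the lineage count equals k
clade_cut <- function(phy, k, prefix = "Fam_") {
  n <- length(phy$tip.label)
  if (k <= 1L) return(rep(paste0(prefix, "01"), n))
  if (k >= n) {
    return(paste0(prefix, formatC(seq_len(n), width = 2, flag = "0")))
  }
  depths <- ape::node.depth.edgelength(phy)
  age <- max(depths) - depths                     # time before present
  int_ages <- sort(age[(n + 1):(n + phy$Nnode)], decreasing = TRUE)
  t_cut <- (int_ages[k - 1] + int_ages[k]) / 2    # k lineages cross here
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  group_root <- vapply(seq_len(n), function(tip) {
    node <- tip
    while (parent[node] != 0 && age[parent[node]] < t_cut) node <- parent[node]
    node
  }, integer(1))
  ids <- match(group_root, unique(group_root))
  paste0(prefix, formatC(ids, width = 2, flag = "0"))
}

#' Simulate a trait under Ornstein-Uhlenbeck evolution on a tree
#'
#' Tip value = `beta0 + beta_elev * elevation + u`, where `u` is an OU
#' deviation around zero simulated branch by branch. The root deviation is
#' drawn from the stationary distribution N(0, sigma2/(2*alpha)); along a
#' branch of length t the deviation decays by `exp(-alpha*t)` and gains
#' variance `sigma2/(2*alpha) * (1 - exp(-2*alpha*t))`. With `alpha = 0` the
#' recursion reduces exactly to Brownian motion from a zero root.
#'
#' @param tree a `calibrated_tree` or [ape::phylo].
#' @param params list with `beta0`, `beta_elev`, `alpha`, `sigma2`.
#' @param elevations per-tip elevations (metres), aligned to the tip order
#'   (or named by tip label).
#' @param seed integer seed.
#' @return named numeric vector of tip trait values (degC).
#' @export
simulate_trait_ou <- function(tree, params, elevations, seed = 1L) {
  phy <- as_phylo(tree)
  n <- length(phy$tip.label)
  if (length(elevations) != n) {
    stop_classed("invalid_argument",
                 "elevations (%d) do not align with tips (%d)",
                 length(elevations), n)
  }
  if (!is.null(names(elevations))) {
    elevations <- elevations[phy$tip.label]
  }
  alpha <- params$alpha
  sigma2 <- params$sigma2
  set.seed(substream_seed(seed, "trait"))
  phy <- ape::reorder.phylo(phy, "cladewise")
  u <- numeric(n + phy$Nnode)
  root <- n + 1L
  u[root] <- if (alpha > 0) stats::rnorm(1, 0, sqrt(sigma2 / (2 * alpha))) else 0
  for (i in seq_len(nrow(phy$edge))) {
    par <- phy$edge[i, 1]; child <- phy$edge[i, 2]; t <- phy$edge.length[i]
    if (alpha > 0) {
      sd_t <- sqrt(sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * t)))
      u[child] <- u[par] * exp(-alpha * t) + stats::rnorm(1, 0, sd_t)
    } else {
      u[child] <- u[par] + stats::rnorm(1, 0, sqrt(sigma2 * t))
    }
  }
  out <- params$beta0 + params$beta_elev * elevations + u[seq_len(n)]
  names(out) <- phy$tip.label
  out
}

#' Discretize true thermal thresholds onto the assay temperature grid
#'
#' The ramping protocol checks mobility every step: for CTmax the insect is
#' first observed immobile at the smallest grid temperature at or above its
#' true threshold (ceiling-to-grid); for CTmin at the largest grid
#' temperature at or below it (floor-to-grid). The grid is anchored at the
#' acclimation start temperature.
#'
#' @param true_ct numeric vector of true thresholds (degC), one individual
#'   each; names become `individual_id` when present.
#' @param protocol list with `start_temp`, `step` (degC) and `interval_min`.
#' @param direction `"ctmax"` or `"ctmin"`.
#' @param meta optional data.frame of per-individual metadata columns
#'   (recycled checks apply), carried through unchanged.
#' @param seed unused by the deterministic protocol model; accepted so the
#'   generator interface is uniform. Within-individual variation belongs in
#'   `true_ct` itself.
#' @return data.frame of assay records with `ct_value` on the grid and the
#'   generating `true_ct`.
#' @export
simulate_assay_records <- function(true_ct, protocol, direction = c("ctmax", "ctmin"),
                                   meta = NULL, seed = NULL) {
  direction <- match.arg(direction)
  if (protocol$step <= 0) stop_classed("invalid_argument", "step must be > 0")
  s <- protocol$start_temp; st <- protocol$step
  eps <- 1e-9
  ct <- if (direction == "ctmax") {
    s + st * ceiling((true_ct - s) / st - eps)
  } else {
    s - st * ceiling((s - true_ct) / st - eps)
  }
  ids <- if (!is.null(names(true_ct))) names(true_ct) else
    paste0("ind_", seq_along(true_ct))
  out <- data.frame(individual_id = ids, direction = direction,
                    ct_value = ct, true_ct = as.numeric(true_ct),
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) out <- cbind(out, meta)
  rownames(out) <- NULL
  out
}

#' Simulate a plot-level microclimate temperature series
#'
#' 15-minute cadence: sea-level mean minus an elevational lapse, a diurnal
#' sinusoid peaking at 14:00 local time, a single annual sinusoid (tropical
#' seasonality is weak), and stationary AR(1) noise.
#'
#' @param elevation metres above sea level.
#' @param climate_params list: `sea_level_mean`, `lapse`, `diurnal_amp`,
#'   `seasonal_amp`, `ar1`, `noise_sd`.
#' @param n_days number of days (>= 1).
#' @param seed integer seed.
#' @param plot_id identifier stamped on every row.
#' @param start first timestamp (UTC).
#' @return data.frame: `plot_id`, `timestamp` (POSIXct UTC), `value` (degC),
#'   `kind` (`"air15cm"`), `qc` (`"0b00"`).
#' @export
simulate_microclimate <- function(elevation, climate_params, n_days, seed = 1L,
                                  plot_id = "plot_1",
                                  start = as.POSIXct("2023-01-01 00:00:00", tz = "UTC")) {
  if (n_days < 1) stop_classed("invalid_argument", "n_days must be >= 1")
  p <- climate_params
  n <- n_days * 96L
  ts <- start + 900 * (seq_len(n) - 1L)
  hours <- (as.numeric(ts - start, units = "hours")) %% 24
  doy <- as.numeric(ts - start, units = "days")
  base <- p$sea_level_mean - p$lapse * elevation
  diurnal <- p$diurnal_amp * sin(2 * pi * (hours - 8) / 24)
  seasonal <- p$seasonal_amp * sin(2 * pi * doy / 365.25)
  set.seed(substream_seed(seed, paste0("climate_", plot_id)))
  e <- numeric(n)
  if (p$noise_sd > 0) {
    e[1] <- stats::rnorm(1, 0, p$noise_sd)
    innov_sd <- p$noise_sd * sqrt(1 - p$ar1^2)
    innov <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) e[i] <- p$ar1 * e[i - 1] + innov[i - 1]
  }
  data.frame(plot_id = plot_id, timestamp = ts,
             value = base + diurnal + seasonal + e,
             kind = "air15cm", qc = "0b00", stringsAsFactors = FALSE)
}

#' Simulate static knockdown (thermal-death-time) observations
#'
#' Knockdown time at constant temperature T follows the TDT line
#' `log10(time) = (T_L - T)/z + log10(t_ref)`, plus optional Gaussian noise
#' on the log10 scale.
#'
#' @param tdt_truth list with `T_L`, `z`, `t_ref`.
#' @param temps test temperatures (degC); temperatures far below `T_L`
#'   give very long times.
#' @param n_per_temp replicates per temperature.
#' @param noise_sd_log10 sd of log10-time noise (0 = exact line).
#' @param seed integer seed.
#' @return data.frame with `temp` (degC) and `time_min` (minutes).
#' @export
simulate_static_knockdowns <- function(tdt_truth, temps, n_per_temp = 1L,
                                       noise_sd_log10 = 0, seed = 1L) {
  set.seed(substream_seed(seed, "knockdown"))
  temp <- rep(temps, each = n_per_temp)
  lt <- (tdt_truth$T_L - temp) / tdt_truth$z + log10(tdt_truth$t_ref)
  lt <- lt + stats::rnorm(length(temp), 0, noise_sd_log10)
  data.frame(temp = temp, time_min = 10^lt)
}

#' Simulate a family-structured protein melting-temperature table
#'
#' Hierarchical normal model: order, family-within-order and
#' species-within-family effects plus protein-level scatter, emulating a
#' per-species random draw of proteins from a genome.
#'
#' @param n_orders,families_per_order,species_per_family,proteins_per_species
#'   design counts.
#' @param grand_mean overall mean Tm (degC).
#' @param order_sd,family_sd,species_sd,protein_sd standard deviations of
#'   the hierarchy levels (degC).
#' @param seed integer seed.
#' @return data.frame of Tm records: `species_id`, `family`, `order`,
#'   `protein_id`, `tm`.
#' @export
simulate_tm_table <- function(n_orders = 4L, families_per_order = 4L,
                              species_per_family = 5L,
                              proteins_per_species = 50L,
                              grand_mean = 46.9, order_sd = 1.5,
                              family_sd = 1, species_sd = 0.5,
                              protein_sd = 3, seed = 1L) {
  set.seed(substream_seed(seed, "tm"))
  rows <- list(); idx <- 0L
  for (o in seq_len(n_orders)) {
    o_eff <- stats::rnorm(1, 0, order_sd)
    for (f in seq_len(families_per_order)) {
      f_eff <- stats::rnorm(1, 0, family_sd)
      fam <- sprintf("Fam_%d_%d", o, f)
      for (s in seq_len(species_per_family)) {
        s_eff <- stats::rnorm(1, 0, species_sd)
        sp <- sprintf("sp_%d_%d_%d", o, f, s)
        tm <- grand_mean + o_eff + f_eff + s_eff +
          stats::rnorm(proteins_per_species, 0, protein_sd)
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          species_id = sp, family = fam, order = sprintf("Order_%d", o),
          protein_id = paste0(sp, "_p", seq_len(proteins_per_species)),
          tm = tm, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator from one configuration and (optionally) writes the
#' standard file set: `tree.nwk`, `assays.csv`, `plots.csv`,
#' `microclimate.csv`, `knockdowns.csv`, `tm_table.csv`, `truth.json`,
#' `config.json`. Individuals are assigned to the plot nearest their OTU's
#' elevation; a balanced half of individuals per OTU receives the heat-shock
#' treatment with a band-specific true shift of the group mean.
#'
#' @param config a [sim_config()].
#' @param out_dir directory to write files to, or `NULL` to skip writing.
#' @param n_days_climate days of microclimate per plot.
#' @return invisibly, a list with all in-memory tables, the tree and the
#'   ground-truth parameter list.
#' @export
simulate_all <- function(config, out_dir = NULL, n_days_climate = 30L) {
  stopifnot(inherits(config, "sim_config"))
  tr <- simulate_tree(config$n_tips, seed = config$seed,
                      n_families = config$n_families,
                      depth = config$tree_depth)
  set.seed(substream_seed(config$seed, "plots"))
  elev_tip <- sample(config$elevation_grid, config$n_tips, replace = TRUE)
  names(elev_tip) <- tr$phy$tip.label
  trait <- simulate_trait_ou(tr, config$trait_params, elev_tip,
                             seed = config$seed)

  plots <- data.frame(plot_id = paste0("plot_", seq_along(config$elevation_grid)),
                      elevation = config$elevation_grid)
  plots$bio1 <- config$climate_params$sea_level_mean -
    config$climate_params$lapse * plots$elevation
  plots$bio5 <- plots$bio1 + 8
  plots$bio5_ssp126 <- plots$bio5 + 1.5
  plots$bio5_ssp370 <- plots$bio5 + 3.2
  plots$bio5_ssp585 <- plots$bio5 + 4.4

  # individuals: n_per_otu per OTU, balanced shock assignment, band-specific
  # true shock shift added to the threshold before assay discretization
  set.seed(substream_seed(config$seed, "individuals"))
  n_ind <- config$n_per_otu * config$n_tips
  otu <- rep(tr$phy$tip.label, each = config$n_per_otu)
  elev <- elev_tip[otu]
  band <- elevation_band(elev)
  shocked <- rep(c("no", "yes"), length.out = n_ind)
  true_ct <- trait[otu] + stats::rnorm(n_ind, 0, config$ind_sd) +
    ifelse(shocked == "yes", config$shock_effects[band], 0)
  names(true_ct) <- paste0("ind_", seq_len(n_ind))
  plot_id <- plots$plot_id[match(elev, plots$elevation)]
  fam <- tr$tips$family[match(otu, tr$tips$label)]
  ord <- tr$tips$order[match(otu, tr$tips$label)]
  meta <- data.frame(otu_id = otu, family = fam, order = ord,
                     region = "neotropics", plot_id = plot_id,
                     elevation = as.numeric(elev), shocked = shocked,
                     observer = paste0("obs_", rep_len(1:4, n_ind)),
                     stringsAsFactors = FALSE)
  assays <- simulate_assay_records(true_ct, config$assay_params, "ctmax",
                                   meta = meta)

  climate <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    simulate_microclimate(plots$elevation[i], config$climate_params,
                          n_days = n_days_climate, seed = config$seed,
                          plot_id = plots$plot_id[i])
  }))
  knockdowns <- simulate_static_knockdowns(config$tdt_truth, temps = 38:46,
                                           n_per_temp = 5L,
                                           noise_sd_log10 = 0.05,
                                           seed = config$seed)
  tm <- simulate_tm_table(seed = config$seed)
  truth <- list(trait_params = config$trait_params,
                tdt_truth = config$tdt_truth,
                shock_effects = as.list(config$shock_effects),
                climate_params = config$climate_params,
                ind_sd = config$ind_sd, seed = config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ape::write.tree(tr$phy, file.path(out_dir, "tree.nwk"))
    utils::write.csv(tr$tips, file.path(out_dir, "tree_tips.csv"), row.names = FALSE)
    utils::write.csv(assays, file.path(out_dir, "assays.csv"), row.names = FALSE)
    utils::write.csv(plots, file.path(out_dir, "plots.csv"), row.names = FALSE)
    cl <- climate
    cl$timestamp <- format(cl$timestamp, "%Y-%m-%dT%H:%M:%S+00:00")
    utils::write.csv(cl, file.path(out_dir, "microclimate.csv"), row.names = FALSE)
    utils::write.csv(knockdowns, file.path(out_dir, "knockdowns.csv"), row.names = FALSE)
    utils::write.csv(tm, file.path(out_dir, "tm_table.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg <- unclass(config)
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tree = tr, tip_elevation = elev_tip, trait = trait,
                 assays = assays, plots = plots, climate = climate,
                 knockdowns = knockdowns, tm = tm, truth = truth))
}

#' Simulate a trait under lambda-transformed Brownian motion
#'
#' Draws one multivariate-normal sample with covariance equal to the
#' Brownian matrix whose off-diagonal entries are scaled by `lambda`
#' (Pagel's transformation), around a constant mean.
#'
#' @param tree `calibrated_tree` or [ape::phylo].
#' @param lambda signal strength in \[0, 1\].
#' @param sigma2 Brownian rate.
#' @param mean trait mean.
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_trait_lambda <- function(tree, lambda, sigma2 = 1, mean = 0, seed = 1L) {
  stopifnot(lambda >= 0, lambda <= 1, sigma2 > 0)
  phy <- as_phylo(tree)
  C <- ape::vcv(phy)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  set.seed(substream_seed(seed, "trait_lambda"))
  z <- stats::rnorm(nrow(Cl))
  out <- mean + sqrt(sigma2) * drop(crossprod(chol(Cl), z))
  names(out) <- phy$tip.label
  out
}

#' Elevation band classification
#'
#' Half-open bands: lowland `[0, 600)`, mid `[600, 1200)`, high `[1200, Inf)`
#' metres above sea level.
#'
#' @param elevation numeric metres.
#' @param cuts the two interior cut points.
#' @return factor with levels `low`, `mid`, `high`.
#' @export
elevation_band <- function(elevation, cuts = c(600, 1200)) {
  cut(elevation, breaks = c(-Inf, cuts, Inf), labels = c("low", "mid", "high"),
      right = FALSE)
}

# internal: accept calibrated_tree or phylo
as_phylo <- function(tree) {
  if (inherits(tree, "calibrated_tree")) return(tree$phy)
  if (inherits(tree, "phylo")) return(tree)
  stop_classed("invalid_argument", "not a tree object")
}
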