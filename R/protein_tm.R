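#' Mean melting temperature of each species' most heat-sensitive proteins
#'
#' Per species, the mean Tm over the proteins at or below the species'
#' q-th empirical quantile of Tm (shared [ct_quantile()] rule). With q = 1
#' this is the ordinary per-species mean.
#'
#' @param records Tm table: `species_id`, `family`, `order`, `protein_id`,
#'   `tm` (degC).
#' @param q quantile level (default 0.25, the heat-sensitive fraction).
#' @return data.frame: `species_id`, `family`, `order`, `n_proteins`,
#'   `tm_sensitive_mean`.
#' @export
sensitive_quantile_mean <- function(records, q = 0.25) {
  check_columns(records, c("species_id", "family", "order", "tm"), "records")
  records <- records[!is.na(records$tm), ]
  grp <- split(records, records$species_id, drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    if (nrow(g) == 0) {
      warning(sprintf("species %s has no proteins; skipped", g$species_id[1]),
              call. = FALSE)
      return(NULL)
    }
    if (nrow(g) < 4) {
      warning(sprintf("species %s has < 4 proteins", g$species_id[1]),
              call. = FALSE)
    }
    thr <- ct_quantile(g$tm, q)
    data.frame(species_id = g$species_id[1], family = g$family[1],
               order = g$order[1], n_proteins = nrow(g),
               tm_sensitive_mean = mean(g$tm[g$tm <= thr]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Family-level regression of CTmax on protein melting temperature
#'
#' Fits both an unweighted linear model and one weighted by the number of
#' species with genomic data per family.
#'
#' @param family_tm named numeric (family -> mean Tm statistic, degC) or
#'   data.frame with `family` and `tm`.
#' @param family_ctmax named numeric (family -> mean CTmax, degC) or
#'   data.frame with `family` and `ctmax`.
#' @param weights named numeric (family -> species count); default equal.
#' @return data.frame with rows `unweighted` and `weighted`: `slope`,
#'   `intercept`, `r2`, `n_families`.
#' @export
family_tm_vs_ctmax <- function(family_tm, family_ctmax, weights = NULL) {
  as_named <- function(x, col) {
    if (is.data.frame(x)) stats::setNames(x[[col]], x$family) else x
  }
  tm <- as_named(family_tm, "tm")
  ctm <- as_named(family_ctmax, "ctmax")
  fams <- intersect(names(tm), names(ctm))
  if (length(fams) < 3) {
    stop_classed("invalid_argument", "need >= 3 families with both statistics")
  }
  w <- if (is.null(weights)) stats::setNames(rep(1, length(fams)), fams) else
    weights[fams]
  if (all(w == 0)) stop_classed("invalid_argument", "all weights are zero")
  d <- data.frame(tm = tm[fams], ctmax = ctm[fams], w = as.numeric(w))
  fit_u <- stats::lm(ctmax ~ tm, data = d)
  fit_w <- stats::lm(ctmax ~ tm, data = d, weights = w)
  row <- function(fit, label) data.frame(
    fit = label, slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = suppressWarnings(summary(fit)$r.squared), n_families = length(fams),
    stringsAsFactors = FALSE)
  out <- rbind(row(fit_u, "unweighted"), row(fit_w, "weighted"))
  rownames(out) <- NULL
  out
}

#' Taxonomic variance tests on protein melting temperatures
#'
#' Nested fixed-effects F-tests for order and family-within-order, with the
#' species as the exchangeable unit: protein Tm values are first aggregated
#' to species means, then `tm ~ order/family` is tested by ANOVA. (A mixed
#' model with protein identity as a random term would use the protein as
#' the unit; species aggregation is the conservative fixed-effects analogue.)
#'
#' @param records Tm table (see [sensitive_quantile_mean()]).
#' @return list: `F_order`, `df_order`, `p_order`, `F_family`, `df_family`,
#'   `p_family`, `df_resid`.
#' @export
tm_variance_tests <- function(records) {
  check_columns(records, c("species_id", "family", "order", "tm"), "records")
  sp <- stats::aggregate(tm ~ species_id + family + order, records, mean)
  if (length(unique(sp$order)) < 2 || length(unique(sp$family)) < 2) {
    stop_classed("invalid_argument", "need >= 2 orders and >= 2 families")
  }
  sp$order <- factor(sp$order); sp$family <- factor(sp$family)
  fit <- stats::lm(tm ~ order / family, data = sp)
  tab <- stats::anova(fit)
  list(F_order = tab["order", "F value"], df_order = tab["order", "Df"],
       p_order = tab["order", "Pr(>F)"],
       F_family = tab["order:family", "F value"],
       df_family = tab["order:family", "Df"],
       p_family = tab["order:family", "Pr(>F)"],
       df_resid = tab["Residuals", "Df"])
}
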