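# Comparative-model engine: all likelihoods are multivariate-normal GLS with
# the residual scale sigma2 profiled out. For correlation structure R,
#   beta_hat = (X' R^-1 X)^-1 X' R^-1 y,  s2_hat = rss/n  (ML),
#   logLik = -n/2 (log(2 pi s2) + 1) - 1/2 log|R|.

# internal: profiled GLS log-likelihood via Cholesky of the correlation matrix
gls_profile <- function(y, X, R) {
  n <- length(y)
  L <- tryCatch(chol(R), error = function(e)
    stop_classed("numerical_degeneracy", "covariance matrix not positive definite"))
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  s2 <- rss / n
  ll <- if (s2 <= 0) Inf else
    -n / 2 * (log(2 * pi * s2) + 1) - sum(log(diag(L)))
  list(beta = fit$coefficients, s2 = s2, logLik = ll, chol = L)
}

# internal: align a named trait/predictor vector to the tree tip order
align_to_tips <- function(x, phy, what = "trait") {
  n <- length(phy$tip.label)
  if (length(x) != n) {
    stop_classed("invalid_argument", "%s length %d does not match %d tips",
                 what, length(x), n)
  }
  if (!is.null(names(x))) {
    miss <- setdiff(phy$tip.label, names(x))
    if (length(miss) > 0) {
      stop_classed("invalid_argument", "%s missing for tips: %s", what,
                   paste(miss, collapse = ", "))
    }
    x <- x[phy$tip.label]
  }
  x
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' For each internal node the ML state equals the GLS phylogenetic mean of
#' the tip values under the covariance induced by re-rooting the tree at
#' that node: C_k\[i,j\] = (d(k,i) + d(k,j) - d(i,j)) / 2, with d patristic
#' distances. Variances are s2_ML / (1' C_k^-1 1), with s2 the ML Brownian
#' rate estimated at the root.
#'
#' @param tree `calibrated_tree` or [ape::phylo].
#' @param trait per-tip values (named by tip label or in tip order).
#' @return data.frame: `node` (number), `estimate`, `variance`.
#' @export
ancestral_states <- function(tree, trait) {
  phy <- as_phylo(tree)
  n <- length(phy$tip.label)
  if (anyNA(trait)) {
    bad <- if (!is.null(names(trait))) names(trait)[is.na(trait)] else
      which(is.na(trait))
    stop_classed("invalid_argument", "missing trait values for tips: %s",
                 paste(bad, collapse = ", "))
  }
  y <- align_to_tips(trait, phy)
  dn <- ape::dist.nodes(phy)
  Dtips <- dn[seq_len(n), seq_len(n)]
  ones <- rep(1, n)
  # Brownian rate from the root-rooted covariance
  Croot <- ape::vcv(phy)
  g0 <- gls_profile(y, matrix(1, n, 1), Croot)
  s2 <- g0$s2
  nodes <- (n + 1L):(n + phy$Nnode)
  est <- var <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    k <- nodes[i]
    dk <- dn[k, seq_len(n)]
    Ck <- (outer(dk, dk, "+") - Dtips) / 2
    diag(Ck) <- dk
    L <- tryCatch(chol(Ck), error = function(e)
      stop_classed("numerical_degeneracy", "singular covariance at node %d", k))
    w1 <- backsolve(L, ones, transpose = TRUE)
    wy <- backsolve(L, y, transpose = TRUE)
    denom <- sum(w1^2)
    est[i] <- sum(w1 * wy) / denom
    var[i] <- s2 / denom
  }
  data.frame(node = nodes, estimate = est, variance = var)
}

#' Pagel's lambda by maximum likelihood
#'
#' The off-diagonal entries of the Brownian covariance are scaled by
#' lambda in \[0, 1\]; lambda is estimated by bounded scalar ML with an
#' intercept-only mean, and tested against lambda = 0 by likelihood ratio
#' (chi-square, 1 df).
#'
#' @param tree `calibrated_tree` or [ape::phylo].
#' @param trait per-tip values.
#' @param fix_lambda evaluate at this fixed lambda instead of maximizing
#'   (the likelihood-ratio p is then against lambda = 0 at the fixed value).
#' @return list: `lambda`, `logLik`, `logLik0`, `p`, `sigma2`.
#' @export
pagel_lambda <- function(tree, trait, fix_lambda = NULL) {
  phy <- as_phylo(tree)
  n <- length(phy$tip.label)
  if (n < 10) warning("fewer than 10 tips: lambda is weakly identified",
                      call. = FALSE)
  y <- align_to_tips(trait, phy)
  C <- ape::vcv(phy)
  Cd <- diag(diag(C))
  X <- matrix(1, n, 1)
  ll_of <- function(lam) {
    R <- lam * C + (1 - lam) * Cd
    gls_profile(y, X, R)$logLik
  }
  ll0 <- ll_of(0)
  if (!is.null(fix_lambda)) {
    stopifnot(fix_lambda >= 0, fix_lambda <= 1)
    lam_hat <- fix_lambda
    ll_hat <- ll_of(fix_lambda)
  } else {
    opt <- stats::optimize(ll_of, c(0, 1), maximum = TRUE, tol = 1e-8)
    # the interior optimum can miss the boundary; keep the better of the two
    ll1 <- ll_of(1)
    cand_ll <- c(opt$objective, ll0, ll1)
    cand_lam <- c(opt$maximum, 0, 1)
    best <- which.max(cand_ll)
    ll_hat <- cand_ll[best]
    lam_hat <- cand_lam[best]
  }
  if (!is.finite(ll_hat)) {
    stop_classed("optimization_failure", "non-finite lambda likelihood")
  }
  lr <- 2 * (ll_hat - ll0)
  R <- lam_hat * C + (1 - lam_hat) * Cd
  g <- gls_profile(y, X, R)
  list(lambda = lam_hat, logLik = ll_hat, logLik0 = ll0,
       p = stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE),
       sigma2 = g$s2)
}

#' Blomberg's K with permutation test
#'
#' K = (MSE0/MSE) / E\[MSE0/MSE | BM\], where MSE0 is the mean square about
#' the phylogenetically corrected (GLS) mean, MSE the GLS mean square, and
#' the Brownian expectation is (tr(C) - n / (1'C^-1 1)) / (n - 1). The
#' p-value is the one-tailed fraction of tip-label permutations with a
#' variance ratio at least the observed one, with (b+1)/(m+1) smoothing.
#'
#' @param tree `calibrated_tree` or [ape::phylo].
#' @param trait per-tip values.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed (recorded in the output).
#' @return list: `K`, `p`, `n_perm`, `seed`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) stop_classed("invalid_argument", "n_perm must be >= 1")
  phy <- as_phylo(tree)
  n <- length(phy$tip.label)
  y <- align_to_tips(trait, phy)
  C <- ape::vcv(phy)
  L <- tryCatch(chol(C), error = function(e)
    stop_classed("numerical_degeneracy", "singular phylogenetic covariance"))
  Cinv <- chol2inv(L)
  ones <- rep(1, n)
  denom1 <- sum(Cinv)
  ratio <- function(v) {
    a <- sum(Cinv %*% v) / denom1
    r <- v - a
    mse0 <- sum(r^2) / (n - 1)
    mse <- drop(t(r) %*% Cinv %*% r) / (n - 1)
    mse0 / mse
  }
  expected <- (sum(diag(C)) - n / denom1) / (n - 1)
  obs <- ratio(y)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (ratio(sample(y)) >= obs) hits <- hits + 1L
  }
  list(K = obs / expected, p = (hits + 1) / (n_perm + 1),
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Phylogenetic correlogram (Moran's I by patristic-distance class)
#'
#' Pairwise weights 1/d binned into equal-frequency distance classes;
#' Moran's I per class with a one-tailed permutation p-value (positive
#' autocorrelation), (b+1)/(m+1) smoothing.
#'
#' @param tree `calibrated_tree` or [ape::phylo].
#' @param trait per-tip values.
#' @param n_classes number of distance classes (>= 2).
#' @param n_perm permutations per class.
#' @param seed integer seed.
#' @return data.frame: `class`, `d_lo`, `d_hi`, `moran_i`, `p`.
#' @export
phylo_correlogram <- function(tree, trait, n_classes = 4L, n_perm = 199L,
                              seed = 1L) {
  if (n_classes < 2) stop_classed("invalid_argument", "n_classes must be >= 2")
  phy <- as_phylo(tree)
  n <- length(phy$tip.label)
  y <- align_to_tips(trait, phy)
  D <- ape::cophenetic.phylo(phy)
  pairs_d <- D[upper.tri(D)]
  if (n < 3 || length(unique(pairs_d)) < n_classes) {
    if (length(unique(pairs_d)) == 1 && n >= 3) {
      warning("all pairwise distances equal; single-class fallback", call. = FALSE)
      n_classes <- 1L
    } else if (n < 3) {
      stop_classed("invalid_argument",
                   "insufficient tips (%d) for %d distance classes", n, n_classes)
    } else {
      n_classes <- length(unique(pairs_d))
    }
  }
  brks <- unique(ct_quantile(pairs_d, seq(0, 1, length.out = n_classes + 1)))
  brks <- brks[c(TRUE, diff(brks) > 1e-9 * max(pairs_d))]  # collapse tied breaks
  brks[length(brks)] <- max(pairs_d)
  brks[1] <- brks[1] - 1e-12
  cls <- matrix(cut(D, breaks = brks, labels = FALSE), n, n)
  diag(cls) <- NA
  moran <- function(v, W, S0) {
    z <- v - mean(v)
    (n / S0) * drop(t(z) %*% W %*% z) / sum(z^2)
  }
  set.seed(seed)
  out <- lapply(seq_len(length(brks) - 1L), function(k) {
    W <- matrix(0, n, n)
    sel <- which(cls == k)
    W[sel] <- 1 / D[sel]
    S0 <- sum(W)
    if (S0 == 0) return(NULL)
    obs <- moran(y, W, S0)
    hits <- 0L
    for (b in seq_len(n_perm)) if (moran(sample(y), W, S0) >= obs) hits <- hits + 1L
    data.frame(class = k, d_lo = brks[k], d_hi = brks[k + 1L],
               moran_i = obs, p = (hits + 1) / (n_perm + 1))
  })
  do.call(rbind, out)
}

#' Phylogenetic regression (PGLS) under BM, OU or star covariance
#'
#' ML fit of trait ~ predictors with correlated residuals: Brownian motion
#' (C_ij = sigma2 x shared path length), stationary Ornstein-Uhlenbeck
#' (C_ij = sigma2/(2 alpha) exp(-alpha d_ij), random root; a fixed-root
#' variant is available), or star (ordinary least squares). alpha is
#' profiled by a deterministic coarse grid plus bounded refinement on the
#' log scale. AIC counts coefficients + sigma2 (+ alpha for OU).
#'
#' @param tree `calibrated_tree` or [ape::phylo].
#' @param trait per-tip response.
#' @param predictors per-tip data.frame (rownames or a `label` column to
#'   align), or NULL for an intercept-only fit.
#' @param cov_model `"BM"`, `"OU"` or `"star"`.
#' @param ou_root `"stationary"` (random root, default) or `"fixed"`.
#' @return list of class `phylo_fit`: `model`, `coefficients`, `sigma2`,
#'   `alpha`, `theta`, `logLik`, `AIC`, `n`, `k`, `boundary`.
#' @export
pgls_fit <- function(tree, trait, predictors = NULL,
                     cov_model = c("BM", "OU", "star"),
                     ou_root = c("stationary", "fixed")) {
  cov_model <- match.arg(cov_model)
  ou_root <- match.arg(ou_root)
  phy <- as_phylo(tree)
  n <- length(phy$tip.label)
  y <- align_to_tips(trait, phy)
  X <- build_design(predictors, phy)
  depth <- max(ape::node.depth.edgelength(phy))

  if (cov_model == "star") {
    g <- gls_profile(y, X, diag(n))
    alpha <- NA_real_
  } else if (cov_model == "BM") {
    g <- gls_profile(y, X, ape::vcv(phy))
    alpha <- NA_real_
  } else {
    D <- ape::cophenetic.phylo(phy)
    Tsh <- if (ou_root == "fixed") ape::vcv(phy) else NULL
    R_of <- function(a) {
      R <- exp(-a * D) / (2 * a)
      if (!is.null(Tsh)) R <- R * (1 - exp(-2 * a * Tsh))
      R
    }
    ll_of <- function(loga) {
      g <- tryCatch(gls_profile(y, X, R_of(exp(loga))), error = function(e) NULL)
      if (is.null(g) || !is.finite(g$logLik)) -Inf else g$logLik
    }
    lo <- log(1e-3 / depth); hi <- log(1e3 / depth)
    grid <- seq(lo, hi, length.out = 25)
    lls <- vapply(grid, ll_of, numeric(1))
    if (all(!is.finite(lls))) {
      stop_classed("optimization_failure", "OU likelihood non-finite everywhere")
    }
    i <- which.max(lls)
    bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
    opt <- stats::optimize(ll_of, bracket, maximum = TRUE, tol = 1e-8)
    loga <- if (opt$objective >= lls[i]) opt$maximum else grid[i]
    alpha <- exp(loga)
    g <- gls_profile(y, X, R_of(alpha))
  }
  k <- ncol(X) + 1L + as.integer(cov_model == "OU")
  ll <- g$logLik
  beta <- g$beta
  names(beta) <- colnames(X)
  boundary <- cov_model == "OU" &&
    (alpha <= 1.05 * 1e-3 / depth || alpha >= 0.95 * 1e3 / depth)
  if (isTRUE(boundary)) {
    warning("OU alpha estimate at search boundary", call. = FALSE)
  }
  structure(list(model = cov_model, coefficients = beta, sigma2 = g$s2,
                 alpha = alpha,
                 theta = if (cov_model == "OU" && ncol(X) == 1L)
                   unname(beta[1]) else NA_real_,
                 logLik = ll, AIC = 2 * k - 2 * ll, n = n, k = k,
                 boundary = isTRUE(boundary),
                 data_checksum = sum(y) + sum(X)),
            class = "phylo_fit")
}

# internal: design matrix from a predictor table, aligned to tips
build_design <- function(predictors, phy) {
  n <- length(phy$tip.label)
  if (is.null(predictors)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (is.numeric(predictors) && is.null(dim(predictors))) {
    predictors <- data.frame(x = align_to_tips(predictors, phy, "predictor"))
  } else {
    predictors <- as.data.frame(predictors)
    if ("label" %in% names(predictors)) {
      rownames(predictors) <- predictors$label
      predictors$label <- NULL
    }
    if (!is.null(rownames(predictors)) &&
        all(phy$tip.label %in% rownames(predictors))) {
      predictors <- predictors[phy$tip.label, , drop = FALSE]
    } else if (nrow(predictors) != n) {
      stop_classed("invalid_argument", "predictors do not align with tips")
    }
    if (anyNA(predictors)) {
      stop_classed("invalid_argument", "predictors contain missing values")
    }
  }
  X <- cbind(1, as.matrix(predictors))
  colnames(X) <- c("(Intercept)", colnames(predictors))
  X
}

#' Evolutionary optimum under an intercept-only Ornstein-Uhlenbeck model
#'
#' Fits the stationary OU model with mean theta; theta equals the GLS mean
#' under the OU covariance at the profiled alpha.
#'
#' @param tree `calibrated_tree` or [ape::phylo].
#' @param trait per-tip values (degC).
#' @return list: `theta`, `alpha`, `sigma2`, `logLik`, `AIC`, `boundary`.
#' @export
fit_ou_optimum <- function(tree, trait) {
  phy <- as_phylo(tree)
  if (length(phy$tip.label) < 10) {
    warning("fewer than 10 tips: OU parameters weakly identified", call. = FALSE)
  }
  if (stats::sd(trait) == 0) {
    return(list(theta = trait[[1]], alpha = NA_real_, sigma2 = 0,
                logLik = Inf, AIC = -Inf, boundary = FALSE))
  }
  f <- suppressWarnings(pgls_fit(tree, trait, NULL, cov_model = "OU"))
  list(theta = f$theta, alpha = f$alpha, sigma2 = f$sigma2,
       logLik = f$logLik, AIC = f$AIC, boundary = f$boundary)
}

#' Rank phylogenetic-regression fits by AIC
#'
#' @param fits list of `phylo_fit` objects on identical data.
#' @return data.frame sorted by AIC (ties broken alphabetically by model):
#'   `model`, `logLik`, `AIC`, `dAIC`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, `[[`, numeric(1), "n")
  cks <- vapply(fits, `[[`, numeric(1), "data_checksum")
  if (length(unique(ns)) > 1 || max(cks) - min(cks) > 1e-6 * max(1, abs(cks[1]))) {
    stop_classed("invalid_comparison", "fits are not on identical data")
  }
  d <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                  logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                  AIC = vapply(fits, `[[`, numeric(1), "AIC"),
                  stringsAsFactors = FALSE)
  d <- d[order(d$AIC, d$model), ]
  d$dAIC <- d$AIC - d$AIC[1]
  rownames(d) <- NULL
  d
}

#' Likelihood-based variance partitioning (partial r-squared)
#'
#' For each component, partial r2 = 1 - exp(-(2/n) (logL_full - logL_reduced)):
#' predictors are dropped one at a time keeping the covariance model;
#' the phylogeny component replaces the covariance by the star (independent)
#' model keeping all predictors. Well-defined for correlated-error models.
#'
#' @param tree `calibrated_tree` or [ape::phylo].
#' @param trait per-tip response.
#' @param predictors per-tip data.frame of predictors.
#' @param cov_model covariance of the full model (`"OU"` or `"BM"`).
#' @return named numeric vector: `phylogeny`, then one entry per predictor.
#' @export
variance_partition <- function(tree, trait, predictors,
                               cov_model = c("OU", "BM")) {
  cov_model <- match.arg(cov_model)
  predictors <- as.data.frame(predictors)
  full <- suppressWarnings(pgls_fit(tree, trait, predictors, cov_model))
  n <- full$n
  partial <- function(ll_red) max(0, 1 - exp(-(2 / n) * (full$logLik - ll_red)))
  out <- numeric(0)
  star <- tryCatch(
    suppressWarnings(pgls_fit(tree, trait, predictors, "star")),
    error = function(e) NULL)
  out["phylogeny"] <- if (is.null(star)) NA_real_ else partial(star$logLik)
  pred_cols <- setdiff(names(predictors), "label")
  for (p in pred_cols) {
    keep <- setdiff(pred_cols, p)
    red <- tryCatch(suppressWarnings(pgls_fit(
      tree, trait,
      if (length(keep) > 0) predictors[, c(intersect("label", names(predictors)), keep), drop = FALSE] else NULL,
      cov_model)), error = function(e) NULL)
    out[p] <- if (is.null(red)) NA_real_ else partial(red$logLik)
  }
  out
}
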