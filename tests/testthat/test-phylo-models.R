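test_that("ancestral states: symmetry, star mean, and dense GLS oracle", {
  # two tips, equal branches: root is the midpoint
  tw <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(ancestral_states(tw, c(A = 40, B = 44))$estimate, 42)
  # star tree: root is the arithmetic mean
  st <- star_tree(6)
  y <- c(40, 41, 42, 43, 44, 46)
  names(y) <- st$tip.label
  expect_equal(ancestral_states(st, y)$estimate, mean(y))
  # root of the hand-assembled 6-tip tree equals (1'C^-1 y)/(1'C^-1 1)
  phy <- tree6(); C <- C6()
  set.seed(4)
  y6 <- stats::setNames(rnorm(6, 42, 2), phy$tip.label)
  a <- ancestral_states(phy, y6)
  Ci <- solve(C[phy$tip.label, phy$tip.label])
  root_gls <- sum(Ci %*% y6) / sum(Ci)
  expect_equal(a$estimate[a$node == 7], root_gls, tolerance = 1e-8)
  expect_error(ancestral_states(phy, c(y6[-1], X = NA)),
               class = "invalid_argument")
})

test_that("ancestral states agree with an independent ML implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(40, seed = 5)
  y <- simulate_trait_ou(tr, list(beta0 = 42, beta_elev = 0, alpha = 2,
                                  sigma2 = 4), rep(0, 40), seed = 5)
  mine <- ancestral_states(tr, y)
  ref <- phytools::fastAnc(tr$phy, y)
  expect_equal(mine$estimate, as.numeric(ref), tolerance = 1e-8)
})

test_that("Pagel's lambda: recovery, destruction, and the lambda=1 identity", {
  # BM data (lambda truth 1): high estimates; shuffling destroys the signal
  lam_bm <- lam_sh <- numeric(10)
  for (s in 1:10) {
    tr <- simulate_tree(200, seed = s)
    y <- simulate_trait_ou(tr, list(beta0 = 0, beta_elev = 0, alpha = 0,
                                    sigma2 = 1), rep(0, 200), seed = s)
    lam_bm[s] <- pagel_lambda(tr, y)$lambda
    set.seed(s)
    lam_sh[s] <- pagel_lambda(tr, sample(unname(y)))$lambda
  }
  expect_gt(mean(lam_bm), 0.95)
  expect_lt(mean(lam_sh), 0.1)
  # lambda = 1 likelihood equals the BM PGLS likelihood exactly
  tr <- simulate_tree(50, seed = 2)
  y <- simulate_trait_ou(tr, list(beta0 = 40, beta_elev = 0, alpha = 1,
                                  sigma2 = 2), rep(0, 50), seed = 2)
  expect_equal(pagel_lambda(tr, y, fix_lambda = 1)$logLik,
               pgls_fit(tr, y, NULL, "BM")$logLik, tolerance = 1e-10)
  expect_warning(pagel_lambda(star_tree(5), rnorm(5)), "fewer than 10")
})

test_that("Blomberg's K: null calibration and permutation p-values", {
  expect_error(blomberg_k(tree6(), rnorm(6), n_perm = 0),
               class = "invalid_argument")
  # shuffled (signal-free) traits: p roughly uniform, median comfortably > 0.3
  set.seed(6)
  ps <- replicate(40, {
    tr <- simulate_tree(40, seed = sample.int(1e6, 1))
    blomberg_k(tr, rnorm(40), n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  expect_gt(median(ps), 0.3)
  # K agrees with an independent implementation
  skip_if_not_installed("phytools")
  tr <- simulate_tree(60, seed = 7)
  y <- simulate_trait_ou(tr, list(beta0 = 40, beta_elev = 0, alpha = 2,
                                  sigma2 = 4), rep(0, 60), seed = 7)
  expect_equal(blomberg_k(tr, y, n_perm = 1)$K,
               unclass(phytools::phylosig(tr$phy, y, method = "K")),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("correlogram: signal decays with distance; flat for shuffled traits", {
  tr <- simulate_tree(80, seed = 3)
  y <- simulate_trait_ou(tr, list(beta0 = 42, beta_elev = 0, alpha = 4,
                                  sigma2 = 4), rep(0, 80), seed = 3)
  cg <- phylo_correlogram(tr, y, n_classes = 4, n_perm = 99, seed = 1)
  expect_gte(nrow(cg), 2)                # tied root-crossing distances may merge bins
  expect_gt(cg$moran_i[1], cg$moran_i[nrow(cg)])
  # shuffled traits: class-wise Moran's I averages to ~ -1/(n-1) (1/d weights
  # make single shuffles heavy-tailed in the shortest class, so average)
  set.seed(8)
  shuffles <- replicate(20, sample(unname(y)), simplify = FALSE)
  i_null <- rowMeans(vapply(shuffles, function(v) {
    phylo_correlogram(tr, v, n_classes = 4, n_perm = 1, seed = 1)$moran_i
  }, numeric(3)))
  expect_true(all(abs(i_null) < 0.15))
  expect_error(phylo_correlogram(ape::read.tree(text = "(A:1,B:1);"),
                                 c(1, 2), n_classes = 2),
               class = "invalid_argument")
})

test_that("PGLS: star = OLS, BM = dense oracle, OU(alpha large) -> star", {
  phy <- tree6(); C <- C6()
  set.seed(10)
  x <- stats::setNames(rnorm(6), phy$tip.label)
  y <- stats::setNames(42 + 0.5 * x + rnorm(6, 0, 0.5), phy$tip.label)
  # star reduces to OLS
  fs <- pgls_fit(phy, y, data.frame(x = x), "star")
  ols <- stats::lm(y ~ x)
  expect_equal(unname(fs$coefficients), unname(coef(ols)), tolerance = 1e-8)
  # BM equals brute-force GLS with the hand-assembled covariance
  fb <- pgls_fit(phy, y, data.frame(x = x), "BM")
  X <- cbind(1, x[phy$tip.label])
  oracle <- dense_gls(y[phy$tip.label], X, C[phy$tip.label, phy$tip.label])
  expect_equal(unname(fb$coefficients), unname(oracle$beta), tolerance = 1e-8)
  expect_equal(fb$sigma2, oracle$s2, tolerance = 1e-8)
  expect_equal(fb$logLik, oracle$logLik, tolerance = 1e-8)
  # strong pull forgets the phylogeny: OU coefficients approach the star fit
  tr <- simulate_tree(60, seed = 11)
  elev <- stats::setNames(runif(60, 0, 3000), tr$phy$tip.label)
  yy <- simulate_trait_ou(tr, list(beta0 = 45, beta_elev = -0.002,
                                   alpha = 1000, sigma2 = 10), elev, seed = 11)
  fo <- suppressWarnings(pgls_fit(tr, yy, data.frame(elevation = elev), "OU"))
  fst <- pgls_fit(tr, yy, data.frame(elevation = elev), "star")
  grid <- seq(0, 3000, length.out = 50)
  pred <- function(f) f$coefficients[1] + f$coefficients[2] * grid
  expect_lt(max(abs(pred(fo) - pred(fst))), 0.05)
})

test_that("OU optimum: constant trait, matrix oracle at the fitted alpha", {
  tr <- simulate_tree(30, seed = 12)
  cst <- fit_ou_optimum(tr, rep(41.5, 30))
  expect_equal(cst$theta, 41.5)
  expect_equal(cst$sigma2, 0)
  y <- simulate_trait_ou(tr, list(beta0 = 42.2, beta_elev = 0, alpha = 3,
                                  sigma2 = 6), rep(0, 30), seed = 12)
  fit <- fit_ou_optimum(tr, y)
  D <- ape::cophenetic.phylo(tr$phy)
  V <- exp(-fit$alpha * D) / (2 * fit$alpha)
  Vi <- solve(V)
  expect_equal(fit$theta, sum(Vi %*% y[tr$phy$tip.label]) / sum(Vi),
               tolerance = 1e-6)
})

test_that("model comparison ranks OU-generated data correctly by AIC", {
  reps <- 60
  wins <- 0
  for (s in seq_len(reps)) {
    tr <- simulate_tree(80, seed = s)
    y <- simulate_trait_ou(tr, list(beta0 = 42, beta_elev = 0, alpha = 3,
                                    sigma2 = 6), rep(0, 80), seed = s + 1000)
    fits <- list(pgls_fit(tr, y, NULL, "BM"),
                 suppressWarnings(pgls_fit(tr, y, NULL, "OU")))
    cmp <- compare_models(fits)
    if (cmp$model[1] == "OU") wins <- wins + 1
  }
  expect_gte(wins / reps, 0.8)
  # tie-break is alphabetical and dAIC is zero for identical fits
  tr <- simulate_tree(20, seed = 1)
  y <- simulate_trait_ou(tr, list(beta0 = 0, beta_elev = 0, alpha = 0,
                                  sigma2 = 1), rep(0, 20), seed = 1)
  f <- pgls_fit(tr, y, NULL, "BM")
  f2 <- f; f2$model <- "ZZ"
  cmp <- compare_models(list(f2, f))
  expect_equal(cmp$model, c("BM", "ZZ"))
  expect_equal(cmp$dAIC, c(0, 0))
  f3 <- pgls_fit(simulate_tree(10, seed = 2), rnorm(10), NULL, "BM")
  expect_error(compare_models(list(f, f3)), class = "invalid_comparison")
})

test_that("BM-generated data keep BM within 2 AIC of the best model", {
  reps <- 40
  close_calls <- 0
  for (s in seq_len(reps)) {
    tr <- simulate_tree(80, seed = s + 500)
    y <- simulate_trait_ou(tr, list(beta0 = 42, beta_elev = 0, alpha = 0,
                                    sigma2 = 4), rep(0, 80), seed = s)
    fits <- list(pgls_fit(tr, y, NULL, "BM"),
                 suppressWarnings(pgls_fit(tr, y, NULL, "OU")))
    cmp <- compare_models(fits)
    if (cmp$dAIC[cmp$model == "BM"] <= 2) close_calls <- close_calls + 1
  }
  expect_gte(close_calls / reps, 0.7)
})

test_that("variance partitioning isolates null components", {
  set.seed(14)
  tr <- simulate_tree(200, seed = 14)
  elev <- stats::setNames(runif(200, 0, 3000), tr$phy$tip.label)
  y <- simulate_trait_ou(tr, list(beta0 = 45, beta_elev = -0.0015, alpha = 2,
                                  sigma2 = 2), elev, seed = 14)
  noise <- stats::setNames(rnorm(200), tr$phy$tip.label)
  vp <- variance_partition(tr, y, data.frame(elevation = elev, junk = noise),
                           "OU")
  expect_lt(vp[["junk"]], 0.02)
  expect_gt(vp[["elevation"]], 0.05)
  # independent observations: predictor partial r2 matches classical r2
  st <- star_tree(120)
  x <- stats::setNames(rnorm(120), st$tip.label)
  ys <- stats::setNames(1 + 0.8 * x + rnorm(120, 0, 1), st$tip.label)
  vps <- variance_partition(st, ys, data.frame(x = x), "BM")
  r2 <- summary(stats::lm(ys ~ x))$r.squared
  expect_equal(vps[["x"]], r2, tolerance = 0.02)
  # star-tree data carry no phylogenetic component
  expect_lt(vps[["phylogeny"]], 0.02)
})
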