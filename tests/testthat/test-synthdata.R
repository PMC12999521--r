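test_that("simulated trees are binary, ultrametric and family-structured", {
  tr <- simulate_tree(50, seed = 1, n_families = 6)
  expect_equal(length(tr$phy$tip.label), 50)
  expect_equal(tr$phy$Nnode, 49)                 # binary: n - 1 internal nodes
  expect_true(is_ultrametric_tree(tr, tol = 1e-9))
  expect_equal(length(unique(tr$tips$family)), 6)
  # families are monophyletic: tips of one family form a clade
  for (f in unique(tr$tips$family)) {
    tips_f <- tr$tips$label[tr$tips$family == f]
    if (length(tips_f) > 1) {
      mrca <- ape::getMRCA(tr$phy, tips_f)
      clade <- ape::extract.clade(tr$phy, mrca)$tip.label
      expect_setequal(clade, tips_f)
    }
  }
  # degenerate single tip
  t1 <- simulate_tree(1)
  expect_equal(length(t1$phy$tip.label), 1)
  expect_equal(max(ape::node.depth.edgelength(t1$phy)), 0)
  expect_error(simulate_tree(0), class = "invalid_argument")
})

test_that("tree simulation is byte-identical under a fixed seed", {
  a <- simulate_tree(30, seed = 42)
  b <- simulate_tree(30, seed = 42)
  expect_identical(ape::write.tree(a$phy), ape::write.tree(b$phy))
  expect_identical(a$tips, b$tips)
  y1 <- simulate_trait_ou(a, list(beta0 = 40, beta_elev = 0, alpha = 2, sigma2 = 1),
                          rep(0, 30), seed = 9)
  y2 <- simulate_trait_ou(b, list(beta0 = 40, beta_elev = 0, alpha = 2, sigma2 = 1),
                          rep(0, 30), seed = 9)
  expect_identical(y1, y2)
})

test_that("OU trait generator honours its limits and stationary moments", {
  tr <- simulate_tree(40, seed = 3)
  elev <- seq(0, 3900, length.out = 40)
  # strong pull, vanishing noise: tips collapse onto the deterministic line
  y <- simulate_trait_ou(tr, list(beta0 = 42, beta_elev = 0.41 / 1000,
                                  alpha = 500, sigma2 = 1e-8), elev, seed = 1)
  expect_equal(unname(y), 42 + 0.41 / 1000 * elev, tolerance = 1e-3)
  # star tree, sigma2 -> 0: exactly linear in elevation
  st <- star_tree(5)
  ys <- simulate_trait_ou(st, list(beta0 = 10, beta_elev = 0.41, alpha = 1,
                                   sigma2 = 1e-18), c(0, 10, 20, 30, 40), seed = 1)
  expect_equal(unname(ys), 10 + 0.41 * c(0, 10, 20, 30, 40), tolerance = 1e-6)
  expect_error(
    simulate_trait_ou(tr, list(beta0 = 0, beta_elev = 0, alpha = 1, sigma2 = 1),
                      rep(0, 10), seed = 1),
    class = "invalid_argument")
})

test_that("alpha = 0 reduces to Brownian motion (Monte-Carlo tip variance)", {
  phy <- tree3()  # depth 2
  reps <- 1500
  tips <- replicate(reps, {
    simulate_trait_ou(phy, list(beta0 = 0, beta_elev = 0, alpha = 0, sigma2 = 2),
                      c(A = 0, B = 0, C = 0), seed = sample.int(1e8, 1))["A"]
  })
  # BM closed form: Var[tip] = sigma2 * depth = 4; MC error ~ 4*sqrt(2/reps)
  expect_equal(var(tips), 4, tolerance = 0.15)
})

test_that("stationary OU generator reproduces the OU tip covariance", {
  phy <- tree3()  # patristic d(A,B) = 2, depth 2
  alpha <- 1.5; sigma2 <- 3
  reps <- 2000
  set.seed(11)
  seeds <- sample.int(1e8, reps)
  ab <- vapply(seeds, function(s) {
    simulate_trait_ou(phy, list(beta0 = 0, beta_elev = 0, alpha = alpha,
                                sigma2 = sigma2), c(A = 0, B = 0, C = 0),
                      seed = s)[c("A", "B")]
  }, numeric(2))
  emp <- cov(t(ab))
  expect_equal(emp["A", "A"], sigma2 / (2 * alpha), tolerance = 0.12)
  expect_equal(emp["A", "B"], sigma2 / (2 * alpha) * exp(-alpha * 2),
               tolerance = 0.05)
})

test_that("assay discretization uses ceiling for CTmax and floor for CTmin", {
  prot <- list(start_temp = 28, step = 1, interval_min = 2)
  expect_equal(simulate_assay_records(41.3, prot, "ctmax")$ct_value, 42)
  expect_equal(simulate_assay_records(41.0, prot, "ctmax")$ct_value, 41)
  expect_equal(simulate_assay_records(7.6, prot, "ctmin")$ct_value, 7)
  expect_equal(simulate_assay_records(7.0, prot, "ctmin")$ct_value, 7)
  # bias property: recorded - true in [0, 1) for CTmax
  set.seed(2)
  tv <- runif(500, 29, 55)
  rec <- simulate_assay_records(tv, prot, "ctmax")$ct_value
  expect_true(all(rec - tv >= 0 & rec - tv < 1))
  expect_error(simulate_assay_records(40, list(start_temp = 28, step = 0), "ctmax"),
               class = "invalid_argument")
})

test_that("microclimate series has the configured diurnal range, lapse and mean", {
  p0 <- list(sea_level_mean = 25, lapse = 0.005, diurnal_amp = 5,
             seasonal_amp = 0, ar1 = 0.7, noise_sd = 0)
  s <- simulate_microclimate(0, p0, n_days = 3, seed = 1)
  expect_equal(nrow(s), 3 * 96)
  day1 <- s$value[1:96]
  expect_equal(max(day1) - min(day1), 10, tolerance = 1e-9)   # 2A exactly
  s1000 <- simulate_microclimate(1000, p0, n_days = 3, seed = 1)
  expect_equal(mean(s$value) - mean(s1000$value), 0.005 * 1000, tolerance = 1e-9)
  # long-run mean with noise and seasonality
  pn <- list(sea_level_mean = 25, lapse = 0.005, diurnal_amp = 5,
             seasonal_amp = 1, ar1 = 0.7, noise_sd = 1.5)
  long <- simulate_microclimate(0, pn, n_days = 3650, seed = 5)
  expect_equal(mean(long$value), 25, tolerance = 0.05)
  expect_error(simulate_microclimate(0, p0, n_days = 0), class = "invalid_argument")
})

test_that("knockdown generator follows the TDT closed form", {
  truth <- list(T_L = 46, z = 3, t_ref = 1)
  kd <- simulate_static_knockdowns(truth, c(46, 49, 40), noise_sd_log10 = 0)
  expect_equal(kd$time_min, c(1, 0.1, 100), tolerance = 1e-12)
  t2 <- simulate_static_knockdowns(list(T_L = 46, z = 3, t_ref = 2),
                                   46, noise_sd_log10 = 0)
  expect_equal(t2$time_min, 2)
})

test_that("full synthetic bundle is deterministic and writes all surfaces", {
  cfg <- sim_config(seed = 7, n_tips = 20, n_families = 4,
                    elevation_grid = c(0, 1500, 3000))
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  b1 <- simulate_all(cfg, out_dir = d1, n_days_climate = 2)
  b2 <- simulate_all(cfg, out_dir = d2, n_days_climate = 2)
  for (f in c("tree.nwk", "assays.csv", "plots.csv", "microclimate.csv",
              "knockdowns.csv", "tm_table.csv", "truth.json", "config.json")) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_identical(b1$assays, b2$assays)
  unlink(c(d1, d2), recursive = TRUE)
})
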