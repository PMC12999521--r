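test_that("z estimation inverts the TDT line", {
  # exact two points: t(40) = 100, t(43) = 10 -> z = 3, T_L(1 min) = 46
  kd <- data.frame(temp = c(40, 43), time_min = c(100, 10))
  p <- fit_z(kd)
  expect_equal(p$z, 3, tolerance = 1e-12)
  expect_equal(p$T_L, 46, tolerance = 1e-10)
  # noiseless synthetic curve at z = 2.16 recovered to 1e-6
  kd2 <- simulate_static_knockdowns(list(T_L = 46, z = 2.16, t_ref = 1), 38:46)
  p2 <- fit_z(kd2)
  expect_equal(p2$z, 2.16, tolerance = 1e-6)
  expect_equal(p2$T_L, 46, tolerance = 1e-6)
  expect_error(fit_z(data.frame(temp = c(40, 40), time_min = c(1, 2))),
               class = "invalid_argument")
  expect_error(fit_z(data.frame(temp = c(40, 43), time_min = c(10, 100))),
               class = "implausible_sensitivity")
})

test_that("z estimation is unbiased under log-normal noise", {
  set.seed(21)
  reps <- 500
  zs <- replicate(reps, {
    kd <- simulate_static_knockdowns(list(T_L = 46, z = 3, t_ref = 1),
                                     temps = seq(38, 46, length.out = 6),
                                     n_per_temp = 5, noise_sd_log10 = 0.15,
                                     seed = sample.int(1e8, 1))
    fit_z(kd)$z
  })
  expect_lt(abs(mean(zs) - 3) / 3, 0.02)
})

test_that("heat-coma time follows the closed form and is log-linear", {
  p <- tdt_params(T_L = 46, z = 3, t_ref = 1)
  expect_equal(t_coma(46, p), 1)
  expect_equal(t_coma(49, p), 0.1)
  expect_equal(t_coma(40, p), 100)
  # log10(t_coma) exactly linear in T with slope -1/z
  Ts <- seq(30, 50, by = 0.5)
  lt <- log10(t_coma(Ts, p))
  slopes <- diff(lt) / diff(Ts)
  expect_equal(slopes, rep(-1 / 3, length(slopes)), tolerance = 1e-12)
  expect_true(all(diff(t_coma(Ts, p)) < 0))
  expect_error(tdt_params(40, z = 0), class = "invalid_argument")
})

test_that("dynamic -> static conversion round-trips the ramp simulation", {
  for (z in c(1, 3, 5)) {
    for (r in c(0.06, 0.5, 1)) {
      p <- tdt_params(T_L = 44, z = z, t_ref = 1)
      ct <- ramp_to_coma(p, ramp_rate = r, start_temp = 28, dt = 5e-4)
      rec <- dynamic_to_static(ct, ramp_rate = r, z = z, t_ref = 1,
                               start_temp = 28)
      expect_equal(rec, 44, tolerance = 0.01)
    }
  }
})

test_that("closed-form conversion matches the full solution away from the start", {
  # start term negligible when start_temp <= ct_dyn - 3z
  for (z in c(2, 3)) {
    ct <- 28 + 3 * z + 2
    full <- dynamic_to_static(ct, 0.5, z = z, t_ref = 1, start_temp = 28)
    approx <- dynamic_to_static(ct, 0.5, z = z, t_ref = 1, start_temp = 28,
                                approximate = TRUE)
    expect_equal(full, approx, tolerance = 0.05)
  }
  # monotonicity: slower ramps give higher static limits
  TL_fast <- dynamic_to_static(42, 1, z = 3)
  TL_slow <- dynamic_to_static(42, 0.06, z = 3)
  expect_gt(TL_slow, TL_fast)
  expect_error(dynamic_to_static(27, 0.5, start_temp = 28),
               class = "invalid_argument")
})

test_that("critical classification counts all retained values", {
  p <- tdt_params(T_L = 45.25, z = 3, t_ref = 1)
  expect_equal(critical_temperature(p, 480), 45.25 - 3 * log10(480))
  tc <- critical_temperature(p, 480)            # 37.21 degC
  expect_equal(tc, 37.2063, tolerance = 1e-4)
  ser <- data.frame(value = c(rep(tc + 1, 3), rep(tc - 1, 7)))
  cc <- classify_critical(ser, p, 480)
  expect_equal(cc$fraction, 0.3)
  expect_equal(cc$n, 10)
  cold <- data.frame(value = rep(tc - 10, 5))
  expect_equal(classify_critical(cold, p, 480)$fraction, 0)
  expect_error(classify_critical(data.frame(value = numeric(0)), p),
               class = "empty_input")
})

test_that("anomaly projection shifts values and inverts exactly", {
  ser <- data.frame(value = c(20, 25, 30), timestamp = 1:3)
  expect_identical(project_series(ser, 30, 30), ser)
  up <- project_series(ser, 30, 33.5)
  expect_equal(up$value, ser$value + 3.5)
  expect_equal(mean(up$value) - mean(ser$value), 3.5)
  back <- project_series(up, 33.5, 30)
  expect_identical(back$value, ser$value)
  expect_error(project_series(ser, NA, 33), class = "missing_metadata")
})

test_that("community sensitivity maps quantiles to ordered static limits", {
  ct <- quantile_target_sample()
  sens <- community_sensitivity(ct, ramp_rate = 0.5, z = 3, t_ref = 1)
  expect_named(sens, c("q10", "q25", "median"))
  TLs <- vapply(sens, `[[`, numeric(1), "T_L")
  expect_true(all(diff(TLs) > 0))               # strictly increasing
  # conversion applied to each community quantile
  expect_equal(TLs[["median"]],
               dynamic_to_static(42, 0.5, 3, 1, 28), tolerance = 1e-9)
  same <- suppressWarnings(community_sensitivity(rep(41, 20)))
  expect_equal(length(unique(vapply(same, `[[`, numeric(1), "T_L"))), 1)
})

test_that("coma summaries compose classify + project over the cross product", {
  p_plots <- data.frame(plot_id = "p1", elevation = 0, bio1 = 26, bio5 = 34,
                        bio5_ssp126 = 35.5, bio5_ssp585 = 38.4)
  sens <- list(median = tdt_params(T_L = 45, z = 3, t_ref = 1))
  tc <- critical_temperature(sens$median, 480)
  ser <- data.frame(plot_id = "p1", value = c(tc + 0.5, tc - 0.5, tc - 3, tc - 6),
                    kind = "air15cm")
  cs <- summarize_coma(list(p1 = ser), sens, p_plots,
                       scenarios = c("current", "ssp126", "ssp585"))
  expect_equal(cs$fraction_critical[cs$scenario == "current"], 0.25)
  # manual composition oracle for a scenario
  man <- classify_critical(project_series(ser, 34, 38.4), sens$median, 480)
  expect_equal(cs$fraction_critical[cs$scenario == "ssp585"], man$fraction)
  # fractions are monotone non-decreasing in the anomaly
  f <- cs$fraction_critical[match(c("current", "ssp126", "ssp585"), cs$scenario)]
  expect_true(all(diff(f) >= 0))
})

test_that("raising z lowers the 8-h critical temperature for a fixed ramp CTmax", {
  ct_dyn <- 42
  tc_z <- vapply(c(2, 4), function(z) {
    TL <- dynamic_to_static(ct_dyn, 0.5, z = z, t_ref = 1, start_temp = 28)
    critical_temperature(tdt_params(TL, z = z, t_ref = 1), 480)
  }, numeric(1))
  expect_lt(tc_z[2], tc_z[1])
})
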