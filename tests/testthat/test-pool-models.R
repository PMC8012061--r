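test_that("closed-form trajectories match the ODE oracle to 1e-8 relative", {
  set.seed(42)
  for (rep in 1:5) {
    p1 <- model1_params(k1dp = runif(1, 0.5, 10),
                        k_minus1 = runif(1, 0.01, 0.3),
                        k_f = runif(1, 0, 0.1))
    o1 <- ode_oracle(p1, 120)
    cf1 <- model1_pool(o1$t, p1)
    expect_lt(max(abs(o1$pp - cf1)) / steady_state_pool(p1), 1e-8)

    p2 <- model2_params(k1dp = runif(1, 0.01, 0.2),
                        pp_max = runif(1, 50, 200),
                        k_minus1 = runif(1, 0.001, 0.1),
                        k_f = runif(1, 0, 0.05))
    o2 <- ode_oracle(p2, 120)
    cf2 <- model2_pool(o2$t, p2)
    expect_lt(max(abs(o2$pp - cf2)) / steady_state_pool(p2), 1e-8)
  }
})

test_that("pool trajectories start at pp0, grow monotonically, and reach steady state", {
  p1 <- model1_params(k1dp = 3.21, k_minus1 = 0.043)
  expect_equal(model1_pool(0, p1), 0)
  expect_equal(steady_state_pool(p1), 3.21 / 0.043, tolerance = 1e-12)
  t <- seq(0, 300, 0.5)
  expect_true(all(diff(model1_pool(t, p1)) >= 0))
  expect_equal(model1_pool(1e5, p1), 74.65116, tolerance = 1e-6)

  p2 <- model2_params(k1dp = 0.039, pp_max = 82.4, k_minus1 = 0.0043)
  expect_equal(model2_pool(0, p2), 0)
  expect_true(all(diff(model2_pool(t, p2)) >= 0))
  expect_equal(steady_state_pool(p2), 0.039 * 82.4 / 0.0433,
               tolerance = 1e-12)
  # printed worked example: these parameters restore a 74.2 fF pool
  expect_equal(steady_state_pool(p2), 74.2, tolerance = 1e-2)
  # nonzero initial pool relaxes from pp0
  expect_equal(model1_pool(0, p1, pp0 = 30), 30)
})

test_that("Model II reduces to Model I as pp_max grows with fixed k1dp product", {
  p1 <- model1_params(k1dp = 3.21, k_minus1 = 0.043)
  t <- seq(0, 120, 1)
  for (ppm in c(1e4, 1e6)) {
    p2 <- model2_params(k1dp = 3.21 / ppm, pp_max = ppm, k_minus1 = 0.043)
    expect_rel(model2_pool(t[-1], p2), model1_pool(t[-1], p1),
               10 * 3.21 / ppm / 0.043)
  }
})

test_that("fit_recovery is the identity on noiseless simulated curves", {
  p <- wt_model1()
  for (plateau_scale in c(1, 1.18, 0.62)) {
    rc <- simulate_recovery(p, k1dp_after = p$k1dp * plateau_scale,
                            intervals = recovery_intervals())
    fit <- fit_recovery(rc)
    expect_lt(rel_err(fit$rate, p$k_minus1), 1e-6)
    expect_lt(rel_err(fit$plateau, plateau_scale), 1e-6)
  }
  # degenerate curve is flagged, never silently fitted
  flat <- recovery_curve(c(1, 2, 5), rep(0.8, 3))
  expect_true(fit_recovery(flat)$degenerate)
  expect_error(fit_recovery(recovery_curve(c(1, 1, 1), c(0.1, 0.2, 0.3))),
               "3 distinct")
})

test_that("derive_rates reproduces the printed forward-rate products", {
  fit <- structure(list(plateau = 1, rate = 0.043, rss = 0,
                        converged = TRUE, degenerate = FALSE),
                   class = "recovery_fit")
  dr <- derive_rates(74.2, fit)
  expect_equal(dr$k_minus1, 0.043)
  expect_equal(dr$k1dp_before, 3.1906, tolerance = 1e-4)
  # the per-cell averaged value printed in the summary table is 3.21; the
  # direct product agrees within 1%
  expect_lt(rel_err(dr$k1dp_before, 3.21), 0.01)
  expect_equal(dr$k1dp_after, dr$k1dp_before)  # plateau = 1

  fit600 <- structure(list(plateau = 0.7, rate = 0.19, rss = 0,
                           converged = TRUE, degenerate = FALSE),
                      class = "recovery_fit")
  dr600 <- derive_rates(85.4, fit600)
  expect_lt(rel_err(dr600$k1dp_before, 15.8), 0.03)
  expect_equal(dr600$k1dp_after, dr600$k1dp_before * 0.7)
  expect_error(derive_rates(-1, fit), "non-negative")
})

test_that("release-site translation matches the worked example and is invertible", {
  p2 <- translate_to_release_site(74.2, 0.043, occupancy = 0.9)
  expect_equal(p2$pp_max, 82.4, tolerance = 1e-3)
  expect_equal(p2$k1dp, 0.0387, tolerance = 1e-12)
  expect_equal(round(p2$k1dp, 3), 0.039)
  expect_equal(p2$k_minus1, 0.0043, tolerance = 1e-12)
  # invertibility: relaxation rate and steady state recover the inputs
  expect_equal(p2$k1dp + p2$k_minus1, 0.043, tolerance = 1e-12)
  expect_equal(steady_state_pool(p2), 74.2, tolerance = 1e-9)

  p2b <- translate_to_release_site(145, 0.059, occupancy = 0.9)
  expect_equal(p2b$pp_max, 145 / 0.9, tolerance = 1e-9)
  expect_equal(p2b$k1dp, 0.0531, tolerance = 1e-9)
  expect_equal(p2b$k_minus1, 0.0059, tolerance = 1e-9)

  full <- translate_to_release_site(50, 0.1, occupancy = 1)
  expect_equal(full$k_minus1, 0)
  expect_equal(full$k1dp, 0.1)
  expect_error(translate_to_release_site(50, 0.1, occupancy = 1.2),
               "occupancy")
})

test_that("translated Model II recovery is identical to the Model I curve", {
  p1 <- wt_model1()
  p2 <- translate_to_release_site(steady_state_pool(p1), p1$k_minus1)
  iv <- c(0.5, recovery_intervals(), 300)
  r1 <- simulate_recovery(p1, intervals = iv)
  r2 <- simulate_recovery(p2, intervals = iv)
  expect_rel(r2$ratio, r1$ratio, 1e-9)
})

test_that("KO-derived rates in the release-site model slow recovery at the RRP readout", {
  # WT translated parameters
  p_wt <- translate_to_release_site(74.2, 0.043)
  wt_after <- p_wt$k1dp * 3.78 / 3.21
  # KO: depriming up 2.12-fold, priming rates as estimated, scaled into the
  # same release-site framework
  p_ko <- model2_params(k1dp = p_wt$k1dp * 3.07 / 3.21,
                        pp_max = p_wt$pp_max,
                        k_minus1 = p_wt$k_minus1 * 2.12)
  ko_after <- p_wt$k1dp * 1.90 / 3.21
  iv <- c(2, 5, 10, 22, 60, 240)
  r_wt <- simulate_recovery(p_wt, k1dp_after = wt_after, intervals = iv)
  r_ko <- simulate_recovery(p_ko, k1dp_after = ko_after, intervals = iv)
  # scaled to the same final amplitude, the KO trails the WT
  wt_n <- r_wt$ratio / r_wt$ratio[length(iv)]
  ko_n <- r_ko$ratio / r_ko$ratio[length(iv)]
  expect_true(all(ko_n[1:5] < wt_n[1:5]))
})

test_that("noisy cohorts at table-scale n recover the KO > WT depriming ordering", {
  n_rep <- 40
  ok <- vapply(seq_len(n_rep), function(r) {
    wt <- generate_recovery_experiment(wt_model1(), recovery_intervals(),
                                       n_cells_per_interval = 5,
                                       noise = noise_spec(sigma_cm = 2,
                                                          seed = 5000 + r))
    ko <- generate_recovery_experiment(ko_model1(), recovery_intervals(),
                                       n_cells_per_interval = 5,
                                       noise = noise_spec(sigma_cm = 2,
                                                          seed = 7000 + r))
    fit_recovery(ko)$rate > fit_recovery(wt)$rate
  }, logical(1))
  expect_gt(mean(ok), 0.95)
})
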