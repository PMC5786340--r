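# Protocol drivers: activation-curve machinery and scans

test_that("Boltzmann fit recovers parameters from a synthetic I-V set", {
  fx <- make_fixture("boltzmann_iv", params = list(V12 = -10, k = 6))
  drive <- single_channel_current(fx$data$v, 0.1)
  act <- fx$data$peak_ical / drive
  act <- act / max(act)
  fit <- boltzmann_fit(fx$data$v, act)
  expect_lt(abs(fit$V12 - (-10)), 0.1)
  expect_lt(abs(fit$k - 6), 0.1)
  expect_error(boltzmann_fit(fx$data$v, rep(0, length(fx$data$v))),
               "all-zero")
})

test_that("ionic I-V machinery: peak current grows with coupling strength", {
  pk <- vapply(c(0, 1, 5), function(wv) {
    p <- ionic_params(w = wv)
    r <- integrate_ionic(p, list(kind = "vclamp", v_hold = -80, v_test = 10,
                                 t_hold = 30, t_test = 120),
                         dt = 0.02, stride = 5)
    min(r$trace$ical_AF[r$trace$time_ms >= 30])
  }, numeric(1))
  expect_true(all(diff(pk) < 0))  # more negative peaks as w rises
})

test_that("ionic activation curve fits and shifts leftward with coupling", {
  a0 <- iv_activation_curves(ionic_params(w = 0),
                             v_test = seq(-40, 30, by = 10),
                             t_hold = 30, t_test = 120, dt = 0.02)
  a1 <- iv_activation_curves(ionic_params(w = 1),
                             v_test = seq(-40, 30, by = 10),
                             t_hold = 30, t_test = 120, dt = 0.02)
  expect_true(all(a0$curve$activation >= 0 & a0$curve$activation <= 1))
  expect_lt(a1$V12, a0$V12)
})

test_that("stability scan classifies the reference point as stable and
           flags the steep-release row as alternans", {
  sc <- stability_scan(ionic_params(), tau_f_grid = 45, u_grid = c(3, 15),
                       w_baseline = 0, w_perturbed = 0.03, pcl = 300,
                       max_beats = 120)
  g <- sc$grid
  ref <- g[g$u == 3 & g$w == 0, ]
  expect_equal(ref$class, "stable")
  steep <- g[g$u == 15 & g$w == 0, ]
  expect_equal(steep$class, "alternans")
  # stable-cell count does not increase with the coupling perturbation
  n0 <- sum(g$class[g$w == 0] == "stable")
  n1 <- sum(g$class[g$w == 0.03] == "stable")
  expect_lte(n1, n0)
})

test_that("G_Kr reduction control reduces to the baseline at scale 1", {
  sc <- gk_reduction_control(ionic_params(), gkr_scale = 1,
                             tau_f_grid = 45, u_grid = 3, pcl = 300,
                             max_beats = 100)
  base <- stability_scan(ionic_params(), tau_f_grid = 45, u_grid = 3,
                         w_baseline = 0, w_perturbed = 0, pcl = 300,
                         max_beats = 100)
  expect_equal(sc$grid$class[1], unique(base$grid$class))
  # halving G_Kr prolongs the APD at the stable reference point
  r1 <- pace_to_steady(ionic_params(), pcl = 300, max_beats = 120)
  p05 <- ionic_params(); p05$gkr_scale <- 0.5
  r2 <- pace_to_steady(p05, pcl = 300, max_beats = 120)
  expect_gt(tail(r2$beats$apd, 1), tail(r1$beats$apd, 1))
})

test_that("paired stochastic runs with shared seeds are bit-identical", {
  cell <- build_cell(test_geom(3, 3, 2), cell_params(), seed = 1)
  r1 <- run_voltage_clamp(cell, v_test = 0, t_hold = 20, t_test = 60,
                          seed = 8)
  r2 <- run_voltage_clamp(cell, v_test = 0, t_hold = 20, t_test = 60,
                          seed = 8)
  expect_identical(r1[[1]]$trace, r2[[1]]$trace)
  # commanded and realised potential agree exactly under clamp
  tr <- r1[[1]]$trace
  expect_true(all(tr$v_mV[tr$time_ms < 20] == -80))
  expect_true(all(tr$v_mV[tr$time_ms >= 20] == 0))
})

test_that("zero-permeability cell passes no whole-cell L-type current", {
  p <- cell_params(flux_scale = 0)
  p$ltcc$PCa <- 0
  cell <- build_cell(test_geom(3, 3, 2), p, seed = 2)
  r <- run_voltage_clamp(cell, v_test = 20, t_hold = 20, t_test = 80,
                         seed = 3)
  expect_true(all(r[[1]]$trace$ical_AF == 0))
})

test_that("AP clamp with a flat waveform and zero-amplitude pacing are
           quiescent", {
  cell <- build_cell(test_geom(3, 3, 2), cell_params(), seed = 4)
  flat <- rep(-80, 300)
  r <- run_ap_clamp(cell, flat, wave_dt = 1, pcl = 300, n_beats = 2,
                    seed = 5)
  expect_lt(max(r$trace$ci_uM), 0.3)     # no Ca transient
  expect_true(all(r$trace$v_mV == -80))
  rp <- run_paced(cell, pcl = 300, n_beats = 2, stim_amp = 0, seed = 5)
  expect_equal(nrow(measure_apd(rp$trace$time_ms, rp$trace$v_mV)), 0)
})
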