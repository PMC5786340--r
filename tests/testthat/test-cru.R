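# Release-unit lattice construction and local Ca dynamics

test_that("default geometry yields 19,305 CRUs and 1,930,500 RyRs", {
  cell <- build_cell(cell_geometry(), seed = 1)
  expect_identical(cell$n_cru, 65L * 27L * 11L)
  expect_identical(cell$n_cru, 19305L)
  expect_identical(cell$n_ryr_total, 1930500L)
  expect_length(cell$cluster_sizes, 19305L)
})

test_that("cluster sizes follow the clamped rounded Gaussian", {
  cell <- build_cell(cell_geometry(), seed = 42)
  sz <- cell$cluster_sizes
  expect_true(all(sz >= 1 & sz <= 25))
  expect_lt(abs(mean(sz) - 10), 0.1)
  expect_lt(abs(sd(sz) - 3), 0.15)
  # degenerate sd -> all clusters exactly the mean
  g0 <- cell_geometry(8, 8, 4, cluster_sd = 0)
  expect_true(all(build_cell(g0, seed = 1)$cluster_sizes == 10L))
  # reproducible from the seed
  expect_identical(build_cell(cell_geometry(6, 6, 3), seed = 5)$cluster_sizes,
                   build_cell(cell_geometry(6, 6, 3), seed = 5)$cluster_sizes)
  expect_error(cell_geometry(0, 5, 5))
})

test_that("RyR opening rate is zero at zero cleft Ca and monotone", {
  p <- cell_params()
  expect_equal(ryr_rates(0, 600, p)$open, 0)
  r1 <- ryr_rates(5, 600, p)$open
  r2 <- ryr_rates(10, 600, p)$open
  expect_gt(r2, r1)
  # increasing in JSR load as well
  expect_gt(ryr_rates(10, 800, p)$open, ryr_rates(10, 500, p)$open)
  expect_error(ryr_rates(-1, 600, p))
})

test_that("cru_rhs is at equilibrium when gradients and pumps vanish", {
  p <- cell_params(vup = 0, jcab = 0, vncx = 0, vpmca = 0, flux_scale = 0,
                   Ku_i = 0)
  c0 <- 0.25
  tn_eq <- with(p, BT * kon * c0 / (kon * c0 + koff))
  st <- c(ci = c0, cs = c0, cp = c0, cnsr = c0, cjsr = c0,
          tni = tn_eq, tns = tn_eq)
  out <- cru_rhs(st, NULL, V = -86, n_open_ltcc = 0, n_open_ryr = 10,
                 params = p)
  expect_equal(unname(out$deriv), rep(0, 7), tolerance = 1e-12)
})

test_that("diffusive exchange relaxes gradients with the right signs", {
  p <- cell_params(vup = 0, jcab = 0, vncx = 0, vpmca = 0, flux_scale = 0)
  st <- cru_resting_state(p)
  st["cs"] <- 1; st["ci"] <- 0.1
  out <- cru_rhs(st, NULL, params = p)
  expect_gt(out$deriv[["ci"]], 0)
  expect_lt(out$deriv[["cs"]], 0)
  expect_equal(out$fluxes$I_dsi, (1 - 0.1) / p$tau_si)
  # flux identities
  st2 <- cru_resting_state(p)
  st2["cp"] <- 4; st2["cnsr"] <- 700
  out2 <- cru_rhs(st2, NULL, params = p)
  expect_equal(out2$fluxes$I_dps, (4 - st2[["cs"]]) / p$tau_p)
  expect_equal(out2$fluxes$I_tr, (700 - st2[["cjsr"]]) / p$tau_tr)
})

test_that("neighbour diffusion is antisymmetric between a CRU pair", {
  p <- cell_params()
  a <- cru_resting_state(p); a["ci"] <- 0.3; a["cnsr"] <- 650
  b <- cru_resting_state(p); b["ci"] <- 0.1; b["cnsr"] <- 550
  nb_for_a <- matrix(c(b[["ci"]], b[["cs"]], b[["cnsr"]], 1), 1)
  nb_for_b <- matrix(c(a[["ci"]], a[["cs"]], a[["cnsr"]], 1), 1)
  fa <- cru_rhs(a, nb_for_a, params = p)$fluxes
  fb <- cru_rhs(b, nb_for_b, params = p)$fluxes
  expect_equal(fa$I_ci, -fb$I_ci, tolerance = 1e-12)
  expect_equal(fa$I_cNSR, -fb$I_cNSR, tolerance = 1e-12)
})

test_that("buffering factors lie in (0, 1]", {
  p <- cell_params()
  st <- cru_resting_state(p)
  f <- cru_rhs(st, NULL, params = p)$fluxes
  for (b in c("beta_i", "beta_s", "beta_p", "beta_JSR")) {
    expect_gt(f[[b]], 0)
    expect_lte(f[[b]], 1)
  }
})

test_that("closed-cell lattice conserves volume-weighted total calcium", {
  # sarcolemmal pathways off; release, uptake, diffusion and stochastic
  # channels all active: total Ca (free + buffered) must be conserved.
  p <- cell_params(vncx = 0, jcab = 0, vpmca = 0, flux_scale = 0)
  cell <- build_cell(test_geom(4, 4, 2), p, seed = 2)
  r <- coopgate:::run_lattice(cell, list(kind = "free", duration = 500),
                              seed = 3, dt = 0.01, stride = 100)
  tot <- r$trace$total_ca_uM
  expect_equal(r$clamped, 0)
  drift <- abs(tot - tot[1]) / tot[1]
  expect_lt(max(drift), 2e-3)
})

test_that("frozen-channel lattice update matches an independent ODE solve", {
  # single CRU, channels frozen shut: the explicit lattice integrator must
  # agree with deSolve applied to the exported right-hand side.
  p <- cell_params()
  cell <- build_cell(cell_geometry(1, 1, 1), p, seed = 1)
  dur <- 100
  r <- coopgate:::run_lattice(cell,
                              list(kind = "free", duration = dur,
                                   freeze_channels = TRUE),
                              seed = 1, dt = 0.005, stride = 200)
  tr <- r$trace
  st0 <- cru_resting_state(p)
  rhs <- function(t, y, parms) {
    names(y) <- names(st0)
    # membrane potential relaxes in the lattice too; clamp to its resting
    # value which the free run holds within a fraction of a mV
    list(cru_rhs(y, NULL, V = parms$V, n_open_ltcc = 0, n_open_ryr = 0,
                 params = p)$deriv)
  }
  out <- deSolve::lsoda(st0, seq(0, dur, by = 25), rhs,
                        list(V = tail(tr$v_mV, 1)),
                        rtol = 1e-8, atol = 1e-10)
  expect_equal(tail(tr$ci_uM, 1), unname(out[nrow(out), "ci"]),
               tolerance = 5e-3)
  expect_equal(tail(tr$cjsr_uM, 1), unname(out[nrow(out), "cjsr"]),
               tolerance = 5e-3)
  expect_equal(tail(tr$cnsr_uM, 1), unname(out[nrow(out), "cnsr"]),
               tolerance = 5e-3)
})

test_that("RyR counts always sum to the cluster size during simulation", {
  p <- cell_params()
  cell <- build_cell(cell_geometry(2, 2, 1), p, seed = 4)
  r <- coopgate:::run_lattice(cell, list(kind = "vclamp", v_hold = -80,
                                         v_test = 0, t_hold = 20,
                                         t_test = 80),
                              seed = 5, dt = 0.02, stride = 100)
  f <- r$final
  expect_true(all(f$ryrC + f$ryrO + f$ryrI + f$ryrR == p$n_ryr))
  expect_true(all(f$ryrC >= 0 & f$ryrO >= 0 & f$ryrI >= 0 & f$ryrR >= 0))
  # concentrations stayed nonnegative
  expect_true(all(c(f$ci, f$cs, f$cp, f$cnsr, f$cjsr) >= 0))
})

test_that("spark trials are reproducible and sized by calibration", {
  p <- cell_params()
  s1 <- spark_trials(n_trials = 50, seed = 9, params = p)
  s2 <- spark_trials(n_trials = 50, seed = 9, params = p)
  expect_identical(s1$peaks, s2$peaks)
  expect_true(all(s1$peaks >= 0 & s1$peaks <= p$n_ryr))
})
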