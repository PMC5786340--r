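# Deterministic whole-cell model

test_that("gamma_d obeys limits, midpoint value and monotonicity", {
  p <- ionic_params(w = 1, w_scale = 1, po_x = 0.4, cs_x = 2)
  expect_equal(gamma_d(0.5, 5, ionic_params(w = 0)), 1)
  expect_equal(gamma_d(p$po_x, p$cs_x, p), 1 + 1 / 4, tolerance = 1e-12)
  expect_equal(gamma_d(1, 1e3, p), 2, tolerance = 1e-3)
  g <- gamma_d(seq(0, 1, 0.1), 2, p)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 1 & g <= 1 + p$w_scale * p$w))
  # the printed bounded variant is available through w_scale
  p001 <- ionic_params(w = 1, w_scale = 0.01)
  expect_lte(max(gamma_d(1, 1e3, p001)), 1.01 + 1e-9)
  expect_error(gamma_d(-0.1, 1, p))
  expect_error(gamma_d(2, 1, p))
})

test_that("d-gate steady state and midpoint", {
  p <- ionic_params(w = 0)
  st <- ionic_initial_state(p, V0 = -5)
  # d_inf at V = -5 is exactly 1/2
  expect_equal(unname(st["d"]), 0.5, tolerance = 1e-12)
  # with w = 0 and V clamped the d derivative vanishes at d = d_inf
  d <- ionic_rhs(st, p, vclamp = TRUE)$deriv
  expect_equal(unname(d["d"]), 0, tolerance = 1e-12)
})

test_that("coupled d-gate fixed point matches a root-finder oracle", {
  p <- ionic_params(w = 2)
  V <- 0; cs <- 3
  st <- ionic_initial_state(p, V0 = V, cs0 = cs)
  f_fix <- unname(st["f"]); fca_fix <- unname(st["fca"])
  # scalar root of alpha_d gamma_d(d) (1-d) - beta_d d = 0
  d_inf <- 1 / (1 + exp(-(V + 5) / 6.24))
  dv <- V + 5
  tau_d <- p$tau_d_scale * d_inf * (1 - exp(-dv / 6.24)) / (0.035 * dv)
  alpha_d <- d_inf / tau_d; beta_d <- (1 - d_inf) / tau_d
  g <- function(d) alpha_d * gamma_d(min(d * f_fix * fca_fix, 1), cs, p) *
    (1 - d) - beta_d * d
  d_star <- uniroot(g, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  st["d"] <- d_star
  expect_equal(unname(ionic_rhs(st, p, vclamp = TRUE)$deriv["d"]), 0,
               tolerance = 1e-9)
})

test_that("with w = 0 the right-hand side reduces to the base model", {
  p0 <- ionic_params(w = 0)
  pg <- ionic_params(w = 7, w_scale = 0)  # gamma_d forced to 1
  st <- ionic_initial_state(p0, V0 = -20, cs0 = 2, cj0 = 100)
  st["d"] <- 0.4; st["f"] <- 0.7
  expect_identical(ionic_rhs(st, p0)$deriv, ionic_rhs(st, pg)$deriv)
  expect_equal(ionic_rhs(st, p0)$currents$gamma_d, 1)
})

test_that("the resting cell stays at rest and gates stay in bounds", {
  p <- ionic_params()
  r <- integrate_ionic(p, list(kind = "free", duration = 5000),
                       dt = 0.01, stride = 200)
  v <- r$trace$v_mV
  expect_lt(max(v) - min(v), 1.5)
  fin <- r$final
  gates <- fin[c("m", "h", "j", "xr", "xs", "xto", "yto", "d", "f", "fca")]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(fin[c("cs", "ci", "cj", "cjp")] >= 0))
})

test_that("paced APD converges in the integration step", {
  p <- ionic_params()
  a1 <- pace_ionic(p, pcl = 300, n_beats = 3, dt = 0.01)$beats$apd[3]
  a2 <- pace_ionic(p, pcl = 300, n_beats = 3, dt = 0.005)$beats$apd[3]
  expect_lt(abs(a1 - a2), 0.1)
})

test_that("reported I_CaL equals -2 alpha J_CaL re-derived in R", {
  p <- ionic_params(w = 0)
  st <- ionic_initial_state(p, V0 = 10, cs0 = 1.2, cj0 = 100)
  st["d"] <- 0.6; st["f"] <- 0.8; st["fca"] <- 0.5
  cur <- ionic_rhs(st, p, vclamp = TRUE)$currents
  V <- 10; cs <- 1.2
  a <- V * p$F / (p$R * p$T)
  ica <- 4 * p$F * a * (0.001 * cs * exp(2 * a) - 0.34 * p$Cao) /
    (exp(2 * a) - 1)
  jcal <- -p$gca * 0.6 * 0.8 * 0.5 * ica
  expect_equal(cur$ICaL, -2 * p$alpha_conv * jcal, tolerance = 1e-10)
  expect_lt(cur$ICaL, 0)  # inward at the plateau
})

test_that("paced model reaches a 1:1 steady state at the reference point", {
  res <- pace_to_steady(ionic_params(tau_f = 45, u = 3, w = 0), pcl = 400,
                        max_beats = 250)
  expect_true(res$steady)
  amp <- alternans_amplitudes(res$beats)
  expect_lt(max(abs(tail(amp$d_apd, 8))), 0.5)
})

test_that("steep SR release slope induces Ca-driven alternans", {
  r <- pace_ionic(ionic_params(u = 15), pcl = 300, n_beats = 70)
  d <- alternans_amplitudes(r$beats)$d_apd
  tail_d <- tail(d, 10)
  expect_gt(mean(abs(tail_d)), 1)
  # phase-coherent period-2, and the Ca peaks alternate with it
  expect_true(all(sign(tail_d) == sign(tail_d[1])))
  dca <- tail(alternans_amplitudes(r$beats)$d_ca, 10)
  expect_true(all(sign(dca) == sign(dca[1])))
})

test_that("coupling strength prolongs the steady-state APD", {
  ap <- apd_prolongation_curve(ionic_params(), w_values = c(0, 0.3, 1),
                               pcl = 400, max_beats = 200)
  expect_true(all(diff(ap$apd_ms) > 0))
  expect_true(all(diff(ap$ca_peak_uM) > 0))
})
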