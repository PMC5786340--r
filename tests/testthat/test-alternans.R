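# Beat-series analysis and coupled-map theory

test_that("APD90 of a square AP equals its width", {
  fx <- make_fixture("square_ap", params = list(width = 200, pcl = 300,
                                                n_beats = 5, dt = 0.5))
  ap <- measure_apd(fx$data$time_ms, fx$data$v_mV)
  expect_equal(nrow(ap), 5)
  expect_true(all(abs(ap$apd_ms - 200) <= 1))
})

test_that("flat trace yields no beats", {
  t <- seq(0, 1000, by = 1)
  expect_equal(nrow(measure_apd(t, rep(-85, length(t)))), 0)
})

test_that("triangle AP APD90 matches the closed-form crossing time", {
  fx <- make_fixture("triangle_ap", params = list(width = 250, dt = 0.25))
  ap <- measure_apd(fx$data$time_ms, fx$data$v_mV)
  expect_gt(nrow(ap), 0)
  expect_true(all(abs(ap$apd_ms - fx$truth$apd90) <= 2))
})

test_that("alternans amplitudes follow the (-1)^n convention", {
  expect_equal(alternans_amplitudes(list(apd = rep(150, 6)))$d_apd,
               rep(0, 5))
  am <- alternans_amplitudes(list(apd = rep(c(200, 180), 5)))
  expect_equal(am$d_apd, rep(-20, 9))
  # random series against a one-line independent recomputation
  set.seed(1)
  x <- 150 + rnorm(30, sd = 10)
  d <- alternans_amplitudes(list(apd = x))$d_apd
  n <- seq_len(29)
  expect_equal(d, (-1)^(n - 1) * (x[n + 1] - x[n]), tolerance = 1e-12)
  expect_error(alternans_amplitudes(list(apd = 1)), "2 beats")
})

test_that("Ca alternans amplitude supports difference and sum variants", {
  fx <- make_fixture("period2_beats")
  am <- alternans_amplitudes(fx$data)
  expect_equal(am$d_apd[1], fx$truth$d_apd)
  expect_true(all(abs(am$d_ca - abs(fx$truth$d_ca)) < 1e-12 |
                    abs(am$d_ca + abs(fx$truth$d_ca)) < 1e-12))
  am2 <- alternans_amplitudes(fx$data, ca_mode = "sum")
  ca <- fx$data$ca_peak
  expect_equal(am2$d_ca[1], ca[2] + ca[1])
})

test_that("sustained alternans onset requires a phase-coherent run", {
  # clean period-2 from beat 11
  apd <- c(rep(150, 10), rep(c(170, 150), 15))
  on <- alternans_onset(list(apd = apd), threshold = 1, sustain = 10)
  expect_equal(on, 10L)  # first pair index straddling the transition
  # phase-flipping noise of the same magnitude never qualifies
  set.seed(2)
  noise <- 150 + sample(c(-10, 10), 60, replace = TRUE)
  expect_true(is.na(alternans_onset(list(apd = noise + rnorm(60)),
                                    threshold = 1, sustain = 25)))
  expect_true(is.na(alternans_onset(list(apd = rep(150, 40)))))
})

test_that("map eigenvalues satisfy the closed form and its identities", {
  ev <- map_eigenvalues(0.5, 0.5, 0)
  expect_equal(sort(Re(ev)), c(-0.5, -0.5))
  expect_equal(max(abs(Im(ev))), 0)
  # lambda_v = lambda_c = lambda -> -lambda +- sqrt(C)
  ev2 <- map_eigenvalues(0.8, 0.8, 0.04)
  expect_equal(sort(Re(ev2)), sort(c(-0.8 + 0.2, -0.8 - 0.2)))
  # characteristic identities over random parameters, machine precision
  set.seed(3)
  n <- 1e4
  lv <- runif(n, -2, 2); lc <- runif(n, -2, 2); C <- runif(n, -1, 1)
  ev3 <- map_eigenvalues(lv, lc, C)
  expect_lt(max(Mod(ev3[, 1] + ev3[, 2] + lv + lc)), 1e-12)
  expect_lt(max(Mod(ev3[, 1] * ev3[, 2] - (lv * lc - C))), 1e-12)
  # complex case: squared modulus equals the product of roots
  ev4 <- map_eigenvalues(1.05, 1.05, -0.3)
  expect_gt(abs(Im(ev4[1, 1])), 0)
  expect_equal(unname(Mod(ev4[1, 1])^2), 1.05^2 + 0.3,
               tolerance = 1e-12)
})

test_that("map classification separates the three regimes", {
  expect_equal(classify_map(0.5, 0.5, 0), "stable")
  expect_equal(classify_map(1.2, 0.2, 0), "alternans")
  expect_equal(classify_map(1.05, 1.05, -0.3), "quasiperiodic")
  # vectorised
  cls <- classify_map(c(0.5, 1.2, 1.05), c(0.5, 0.2, 1.05), c(0, 0, -0.3))
  expect_equal(cls, c("stable", "alternans", "quasiperiodic"))
})

test_that("theoretical boundary: uncoupled square and shrinking stability", {
  lv <- seq(0, 1.4, by = 0.02)
  b0 <- theoretical_boundary(0, lv, lv)
  g <- b0$grid
  expect_true(all(g$class[g$lambda_v < 1 & g$lambda_c < 1] == "stable"))
  expect_true(all(g$class[g$lambda_v > 1 | g$lambda_c > 1] != "stable"))
  # positive coupling: stable area strictly shrinks from C=0.1 to C=0.15
  a1 <- theoretical_boundary(0.10, lv, lv)$stable_area
  a2 <- theoretical_boundary(0.15, lv, lv)$stable_area
  expect_lt(a2, a1)
  # negative coupling: from C=-0.1 to C=-0.05 the stable area also shrinks
  a3 <- theoretical_boundary(-0.10, lv, lv)$stable_area
  a4 <- theoretical_boundary(-0.05, lv, lv)$stable_area
  expect_lt(a4, a3)
  # points near the boundary have dominant modulus near 1
  bd <- g[abs(g$mod - 1) < 0.02, ]
  expect_gt(nrow(bd), 0)
  ev <- map_eigenvalues(bd$lambda_v, bd$lambda_c, 0)
  expect_true(all(abs(pmax(Mod(ev[, 1]), Mod(ev[, 2])) - 1) < 0.02))
})

test_that("coupling slope: exact OLS, order invariance, degeneracy", {
  d_ca <- c(-1, 0, 1, 2)
  cs <- coupling_slope(d_ca, 2.5 * d_ca)
  expect_equal(cs$slope, 2.5, tolerance = 1e-12)
  expect_equal(cs$sign, 1)
  o <- c(3, 1, 4, 2)
  expect_equal(coupling_slope(d_ca[o], (2.5 * d_ca)[o])$slope, 2.5,
               tolerance = 1e-12)
  expect_error(coupling_slope(rep(1, 4), 1:4), "degenerate")
  expect_error(coupling_slope(1:2, 1:2), "3 perturbation")
})

test_that("beat-series classifier separates period-2 from modulation", {
  p2 <- list(apd = 150 + rep(c(8, -8), 30))
  expect_equal(classify_beat_series(p2), "alternans")
  qp <- list(apd = 150 + 8 * cos(2 * pi * 0.23 * seq_len(60)))
  expect_equal(classify_beat_series(qp), "quasiperiodic")
  expect_equal(classify_beat_series(list(apd = rep(150, 60) +
                                           rnorm(60, sd = 0.05))), "stable")
})

test_that("restitution slope estimator recovers a known slope", {
  di <- seq(40, 200, by = 10)
  apd <- 100 + 0.8 * di
  expect_equal(restitution_eigenvalue(di, apd, at = 120), 0.8,
               tolerance = 1e-9)
})
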