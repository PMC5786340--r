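# Single-channel / cluster Markov model

test_that("coupling factors obey their limits and monotonicity", {
  p <- ltcc_params(w1 = 1, w2 = 2, po_x = 1 / 3, cp_x = 3)
  # disabled coupling
  p0 <- ltcc_params(w1 = 0, w2 = 0)
  cf0 <- coupling_factors(5, 50, p0)
  expect_equal(cf0$gamma1, 1)
  expect_equal(cf0$gamma2, 1)
  # both logistic terms at their midpoints -> 1 + w/4
  cf <- coupling_factors(3 * p$po_x, p$cp_x, p)
  expect_equal(cf$gamma1, 1 + p$w1 / 4, tolerance = 1e-12)
  expect_equal(cf$gamma2, 1 + p$w2 / 4, tolerance = 1e-12)
  # saturation
  cf_inf <- coupling_factors(25, 1e4, p)
  expect_equal(cf_inf$gamma1, 1 + p$w1, tolerance = 1e-6)
  expect_equal(cf_inf$gamma2, 1 + p$w2, tolerance = 1e-6)
  # monotone nondecreasing in both arguments, bounded in [1, 1+w]
  ns <- 0:10
  cps <- c(0, 0.5, 2, 5, 20, 100)
  for (cp in cps) {
    g <- coupling_factors(ns, cp, p)$gamma1
    expect_true(all(diff(g) >= 0))
    expect_true(all(g >= 1 & g <= 1 + p$w1))
  }
  for (n in ns) {
    g <- coupling_factors(n, cps, p)$gamma2
    expect_true(all(diff(g) >= 0))
  }
  expect_error(coupling_factors(-1, 1, p), "n_open")
  expect_error(coupling_factors(1, -1, p), "cp")
})

test_that("printed rate relations hold at reference points", {
  p <- ltcc_params(w1 = 0, w2 = 0)
  # V = 0: po_inf = 1/2 so alpha/beta = 1
  r <- ltcc_rates(0, 1, 0, p)
  expect_equal(r$alpha_eff / r$beta, 1, tolerance = 1e-12)
  # cp at the f(cp) midpoint: s1 = 0.01, k1 = 0.015
  r2 <- ltcc_rates(0, p$cpt, 0, p)
  expect_equal(r2$s1, 0.01, tolerance = 1e-12)
  expect_equal(r2$k1, 0.015, tolerance = 1e-12)
  # V = -40: both inactivation-recovery exponents vanish
  r3 <- ltcc_rates(-40, 1, 0, p)
  Pr <- 1 / (1 + exp(0))  # 1/2 by construction at V = -40
  expect_equal(Pr, 0.5)
  # k5p + k6p = 1/tau_ba and k5p = k6p there (Ps = 1/2)
  expect_equal(r3$k5p, r3$k6p, tolerance = 1e-12)
  # cp = 0 is allowed: the Ca-sensing rates vanish, everything else finite
  r0 <- ltcc_rates(0, 0, 0, p)
  expect_equal(r0$s1, 0)
  expect_equal(r0$k1, 0)
  expect_equal(r0$k6, 0)
  expect_true(all(is.finite(unlist(r0))))
})

test_that("rates match an independent re-derivation over a grid", {
  p <- ltcc_params(w1 = 1.5, w2 = 0.8)
  for (V in c(-80, -40, -10, 0, 20, 50)) {
    for (cp in c(0.1, 1, 3, 20, 80)) {
      for (n in c(0, 2, 5)) {
        got <- ltcc_rates(V, cp, n, p)
        want <- oracle_rates(V, cp, n, p)
        for (nm in names(want)) {
          expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10,
                       info = paste(nm, V, cp, n))
        }
      }
    }
  }
})

test_that("detailed-balance constraints hold with coupling applied", {
  p <- ltcc_params(w1 = 2, w2 = 2)
  r <- ltcc_rates(-10, 5, 3, p)
  # s2 = s1 (k2/k1) / (r1_eff/r2)
  expect_equal(r$s2, r$s1 * (r$k2 / r$k1) * r$r2 / r$r1_eff,
               tolerance = 1e-10)
  # k4 = k3 (alpha_eff/beta)(k1/k2)(k5/k6)
  expect_equal(r$k4, r$k3 * (r$alpha_eff / r$beta) * (r$k1 / r$k2) *
                 (r$k5 / r$k6), tolerance = 1e-10)
  expect_equal(r$k4p, r$k3p * (r$alpha_eff / r$beta) * (r$k1p / r$k2p) *
                 (r$k5p / r$k6p), tolerance = 1e-10)
})

test_that("generator rows sum to zero and off-diagonals are nonnegative", {
  p <- ltcc_params()
  for (V in c(-60, 0, 30)) {
    Q <- ltcc_generator(V, 2, 1, p)
    expect_equal(rowSums(Q), setNames(rep(0, 7), rownames(Q)),
                 tolerance = 1e-12)
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
  }
})

test_that("GHK single-channel current: limit, reversal and oracle match", {
  p <- ltcc_params()
  # analytic V -> 0 limit
  lim <- 2 * p$PCa * p$F * (0.001 * p$gamma_i * 1 - p$gamma_o * p$Cao)
  expect_equal(single_channel_current(0, 1, p), lim, tolerance = 1e-12)
  expect_equal(single_channel_current(1e-7, 1, p), lim, tolerance = 1e-6)
  # reversal potential is the root of the numerator
  cp <- 1
  Vrev <- (p$R * p$T / (2 * p$F)) *
    log(p$gamma_o * p$Cao / (0.001 * p$gamma_i * cp))
  expect_equal(single_channel_current(Vrev, cp, p), 0, tolerance = 1e-10)
  # inward at plateau potentials
  expect_true(all(single_channel_current(c(-20, 0, 20), 1, p) < 0))
  # strictly increasing in cp at fixed V; matches independent evaluation
  i3 <- single_channel_current(20, c(0.5, 5, 50), p)
  expect_true(all(diff(i3) > 0))
  for (k in seq_along(i3)) {
    expect_equal(i3[k], oracle_ghk(20, c(0.5, 5, 50)[k], p),
                 tolerance = 1e-12)
  }
})

test_that("cluster current is the single-channel current times n_open", {
  p <- ltcc_params()
  expect_equal(cluster_current(0, 10, 2, p), 0)
  expect_equal(cluster_current(5, 10, 2, p),
               5 * single_channel_current(10, 2, p))
})

test_that("1-channel empirical occupancy matches the master equation", {
  # short-horizon time-averaged occupancy from a point initial condition:
  # fully determined by the master equation (transient included), with
  # manageable Monte-Carlo variance; the chain's slowest states mix over
  # tens of seconds and are exercised through the same generator here.
  p <- ltcc_params(w1 = 0, w2 = 0)
  V <- 0; cp <- 10
  dur <- 100; dt <- 0.002
  n_rep <- 40
  occ <- sapply(seq_len(n_rep), function(s) {
    simulate_cluster(1, V, cp, dur, dt = dt, seed = 100 + s,
                     params = p)$occupancy
  })
  want <- oracle_time_avg_occupancy(
    oracle_generator(oracle_rates(V, cp, 0, p)), dur, init_state = 1)
  got <- rowMeans(occ)
  se <- apply(occ, 1, sd) / sqrt(n_rep)
  for (k in 1:7) {
    expect_lt(abs(got[k] - want[k]), 3 * se[k] + 0.005)
  }
})

test_that("2-channel coupled cluster matches the exact joint chain", {
  # Exact oracle: the 49-state generator of the ordered channel pair with
  # open-count dependent rates.  The chain's Ca/Ba-inactivated tails have
  # multi-second dwell times, so individual rare joint cells are extremely
  # skew-sampled on any practical horizon; the comparison therefore checks
  # (a) the distribution of the joint open count, which aggregates the
  # well-mixed fast states, at Monte-Carlo resolution, and (b) every
  # well-populated joint cell with a skew-robust tolerance.
  p <- ltcc_params(w1 = 3, w2 = 3, po_x = 0.2)
  V <- 0; cp <- 10
  dur <- 100; dt <- 0.002
  n_rep <- 40
  jocc <- array(0, c(7, 7, n_rep))
  for (s in seq_len(n_rep)) {
    sim <- simulate_cluster(2, V, cp, dur, dt = dt, seed = 300 + s,
                            params = p, record_joint = TRUE)
    jocc[, , s] <- sim$joint
  }
  Qj <- oracle_joint_generator(V, cp, p)
  want <- matrix(oracle_time_avg_occupancy(Qj, dur, init_state = 1), 7, 7,
                 byrow = TRUE)
  got <- apply(jocc, c(1, 2), mean)
  se <- apply(jocc, c(1, 2), sd) / sqrt(n_rep)

  n_of_cell <- outer(1:7, 1:7, function(a, b) (a == 3) + (b == 3))
  pn <- function(m) vapply(0:2, function(k) sum(m[n_of_cell == k]),
                           numeric(1))
  pn_runs <- apply(jocc, 3, function(m) pn(m))
  pn_se <- apply(pn_runs, 1, sd) / sqrt(n_rep)
  expect_true(all(abs(pn(got) - pn(want)) < 3 * pn_se + 0.005))

  big <- want > 0.03
  expect_true(sum(big) >= 6)
  expect_true(all(abs(got[big] - want[big]) < 4 * se[big] + 0.015))
})

test_that("mean open probability is nondecreasing in coupling strength", {
  po <- sapply(c(0, 2, 6), function(w) {
    p <- ltcc_params(w1 = w, w2 = w)
    mean(simulate_cluster(10, 0, 10, 2000, dt = 0.01, seed = 7,
                          params = p)$n_open) / 10
  })
  expect_true(all(diff(po) > 0))
})

test_that("coupling promotes simultaneous openings (2+ channels)", {
  frac_multi <- sapply(c(FALSE, TRUE), function(coupled) {
    p <- if (coupled) ltcc_params(w1 = 4, w2 = 4) else
      ltcc_params(w1 = 0, w2 = 0)
    sim <- simulate_cluster(10, 0, 10, 3000, dt = 0.01, seed = 11,
                            params = p)
    st <- opening_statistics(sim$n_open, dt = 0.01)
    mean(st$max_open >= 2)
  })
  expect_gt(frac_multi[2], frac_multi[1])
})

test_that("cluster simulation enforces the per-step probability bound", {
  p <- ltcc_params()
  expect_error(simulate_cluster(2, 0, 5, 10, dt = 0.2, seed = 1, params = p),
               "dt too large")
})

test_that("advance_cluster preserves occupancy and is reproducible", {
  p <- ltcc_params()
  st <- rep(0L, 10)
  a <- advance_cluster(st, V = 0, cp = 5, dt = 0.01, n_steps = 5000,
                       seed = 3, params = p)
  b <- advance_cluster(st, V = 0, cp = 5, dt = 0.01, n_steps = 5000,
                       seed = 3, params = p)
  expect_identical(a$states, b$states)
  expect_length(a$states, 10)
  expect_true(all(a$states %in% 0:6))
  expect_equal(a$n_open, sum(a$states == 2L))
})
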