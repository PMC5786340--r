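# Independent oracle implementations used by the tests.  These re-derive
# the rate expressions and master-equation solutions directly in R, without
# touching the package's compiled code paths.

# logistic
sig <- function(x) 1 / (1 + exp(-x))

# Full rate set of the 7-state scheme, written out independently.
oracle_rates <- function(V, cp, n_open, p) {
  g1 <- 1 + p$w1 * sig(15 * (n_open / 3 - p$po_x)) * sig(cp - p$cp_x)
  g2 <- 1 + p$w2 * sig(15 * (n_open / 3 - p$po_x)) * sig(cp - p$cp_x)
  po_inf <- sig(V / 8)
  alpha <- po_inf / p$tau_po
  beta <- (1 - po_inf) / p$tau_po
  fcp <- if (cp > 0) 1 / (1 + (p$cpt / cp)^3) else 0
  s1 <- 0.02 * fcp
  k1 <- 0.03 * fcp
  r1e <- p$r1 * g2
  s2 <- s1 * (p$k2 / k1) / (r1e / p$r2)
  if (fcp == 0) s2 <- (0.02 / 0.03) * p$k2 * p$r2 / r1e
  s2p <- p$s1p * (p$k2p / p$k1p) / (r1e / p$r2)
  ex <- exp(-(V + 40) / 3)
  k3 <- ex / (3 * (1 + ex))
  Pr <- 1 / (1 + exp((V + 40) / 4))
  Ps <- 1 / (1 + exp(-(V + 40) / 11.32))
  RV <- 10 + 4954 * exp(V / 15.6)
  TCa <- 114 / (1 + (cp / p$cpminus)^4)
  tau_ca <- (RV - TCa) * Pr + TCa
  tau_ba <- (RV - p$TBa) * Pr + p$TBa
  k5 <- (1 - Ps) / tau_ca
  k6 <- fcp * Ps / tau_ca
  k5p <- (1 - Ps) / tau_ba
  k6p <- Ps / tau_ba
  ae <- alpha * g1
  k4 <- if (k6 > 0) k3 * (ae / beta) * (k1 / p$k2) * (k5 / k6) else
    k3 * (ae / beta) * (0.03 / p$k2) * k5 * tau_ca / Ps
  k4p <- k3 * (ae / beta) * (p$k1p / p$k2p) * (k5p / k6p)
  list(alpha_eff = ae, beta = beta, r1_eff = r1e, r2 = p$r2, s1 = s1,
       s2 = s2, s1p = p$s1p, s2p = s2p, k1 = k1, k2 = p$k2, k1p = p$k1p,
       k2p = p$k2p, k3 = k3, k4 = k4, k3p = k3, k4p = k4p, k5 = k5,
       k6 = k6, k5p = k5p, k6p = k6p, gamma1 = g1, gamma2 = g2)
}

# Generator of the single-channel chain from an oracle rate list.
# State order: C2, C1, O, I1Ca, I2Ca, I1Ba, I2Ba.
oracle_generator <- function(r) {
  Q <- matrix(0, 7, 7,
              dimnames = rep(list(c("C2", "C1", "O", "I1Ca", "I2Ca",
                                    "I1Ba", "I2Ba")), 2))
  put <- function(from, to, rate) Q[from, to] <<- rate
  put("C2", "C1", r$alpha_eff); put("C1", "C2", r$beta)
  put("C1", "O", r$r1_eff);     put("O", "C1", r$r2)
  put("O", "I1Ca", r$s1);       put("I1Ca", "O", r$s2)
  put("C1", "I1Ca", r$k1);      put("I1Ca", "C1", r$k2)
  put("I1Ca", "I2Ca", r$k3);    put("I2Ca", "I1Ca", r$k4)
  put("C2", "I2Ca", r$k6);      put("I2Ca", "C2", r$k5)
  put("O", "I1Ba", r$s1p);      put("I1Ba", "O", r$s2p)
  put("C1", "I1Ba", r$k1p);     put("I1Ba", "C1", r$k2p)
  put("I1Ba", "I2Ba", r$k3p);   put("I2Ba", "I1Ba", r$k4p)
  put("C2", "I2Ba", r$k6p);     put("I2Ba", "C2", r$k5p)
  diag(Q) <- -rowSums(Q)
  Q
}

# Time-averaged occupancy of a Markov chain from the master equation,
# integrated with deSolve from a point mass on `init_state`.
oracle_time_avg_occupancy <- function(Q, duration, init_state = 1) {
  n <- nrow(Q)
  p0 <- numeric(n)
  p0[init_state] <- 1
  rhs <- function(t, y, parms) {
    p <- y[1:n]
    list(c(as.numeric(t(Q) %*% p), p))  # append running integral of p
  }
  out <- deSolve::lsoda(c(p0, numeric(n)), c(0, duration), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  as.numeric(out[2, (n + 2):(2 * n + 1)]) / duration
}

# Exact generator of the ordered 2-channel joint process with open-count
# dependent rates (the cluster feedback loop): state = (s1, s2), rates for
# channel i evaluated at the joint open count.
oracle_joint_generator <- function(V, cp, p) {
  idx <- function(a, b) (a - 1) * 7 + b
  Q <- matrix(0, 49, 49)
  for (a in 1:7) for (b in 1:7) {
    n_open <- (a == 3) + (b == 3)  # O is state 3 in 1-based order
    r <- oracle_rates(V, cp, n_open, p)
    G <- oracle_generator(r)
    for (a2 in 1:7) if (a2 != a) Q[idx(a, b), idx(a2, b)] <- G[a, a2]
    for (b2 in 1:7) if (b2 != b) Q[idx(a, b), idx(a, b2)] <- G[b, b2]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# independent GHK current evaluation
oracle_ghk <- function(V, cp, p) {
  z <- V * p$F / (p$R * p$T)
  if (abs(z) < 1e-9) return(2 * p$PCa * p$F * (0.001 * p$gamma_i * cp -
                                               p$gamma_o * p$Cao))
  4 * p$PCa * z * p$F * (0.001 * p$gamma_i * cp * exp(2 * z) -
                         p$gamma_o * p$Cao) / (exp(2 * z) - 1)
}

# reduced geometry used throughout the stochastic tests
test_geom <- function(nx = 6, ny = 6, nz = 3) cell_geometry(nx, ny, nz)
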