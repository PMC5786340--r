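# Reusable experiment drivers shared by the stochastic and ionic models:
# I-V / activation curves, APD prolongation, stability scans over
# (tau_f, u), the G_Kr-reduction control, and the SR-load perturbation
# protocol for the Ca-to-voltage coupling slope.

#' Least-squares Boltzmann fit of an activation curve
#'
#' Fits `act ~ 1/(1 + exp(-(V - V12)/k))` by nonlinear least squares.
#'
#' @param v test potentials (mV).
#' @param act normalised activation values.
#' @return List with `V12`, `k`, `fitted`.
#' @export
boltzmann_fit <- function(v, act) {
  stopifnot(length(v) == length(act), length(v) >= 4)
  if (all(act == 0)) stop("all-zero activation values: nothing to fit")
  start_v12 <- v[which.min(abs(act - 0.5))]
  fit <- stats::nls(act ~ 1 / (1 + exp(-(v - V12) / k)),
                    start = list(V12 = start_v12, k = 6),
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  co <- coef(fit)
  list(V12 = unname(co["V12"]), k = unname(co["k"]),
       fitted = stats::fitted(fit))
}

#' I-V and activation curves of the L-type current
#'
#' Runs step depolarisations from a holding potential to each test
#' potential, records the peak inward I_CaL, and converts the peaks to a
#' normalised activation curve by dividing by the single-channel (GHK)
#' driving force at each potential and rescaling to a maximum of 1.  The
#' half-activation voltage is obtained from a Boltzmann fit.
#'
#' @param model a `cell_lattice` (stochastic model, see [build_cell()]) or
#'   an `ionic_params` list (deterministic model).
#' @param v_test test potentials (mV).
#' @param v_hold holding potential (mV).
#' @param t_hold,t_test holding and step durations (ms).
#' @param seed seed (stochastic model only; share it between paired
#'   coupled/uncoupled runs).
#' @param dt integration step (ms).
#' @return List of class `iv_curve`: data.frame `curve` (v, peak_ical,
#'   activation), `V12`, `k`.
#' @export
iv_activation_curves <- function(model, v_test = seq(-60, 60, by = 10),
                                 v_hold = -80, t_hold = 50, t_test = 150,
                                 seed = 1, dt = NULL) {
  if (inherits(model, "cell_lattice")) {
    if (is.null(dt)) dt <- 0.02
    runs <- run_voltage_clamp(model, v_test = v_test, v_hold = v_hold,
                              t_hold = t_hold, t_test = t_test, seed = seed,
                              dt = dt)
    peaks <- vapply(runs, function(r) r$peak_ical, numeric(1))
    drive <- single_channel_current(v_test, model$params$cp0,
                                    model$params$ltcc)
  } else if (inherits(model, "ionic_params")) {
    if (is.null(dt)) dt <- 0.05
    peaks <- vapply(v_test, function(vt) {
      prot <- list(kind = "vclamp", v_hold = v_hold, v_test = vt,
                   t_hold = t_hold, t_test = t_test)
      r <- integrate_ionic(model, prot, dt = dt, stride = 2)
      min(r$trace$ical_AF[r$trace$time_ms >= t_hold])
    }, numeric(1))
    drive <- single_channel_current(v_test, 0.1)
  } else {
    stop("model must be a cell_lattice or ionic_params")
  }
  act <- peaks / drive          # both negative inward; ratio >= 0
  act <- pmax(act, 0)
  act <- act / max(act)
  fit <- boltzmann_fit(v_test, act)
  structure(list(curve = data.frame(v = v_test, peak_ical = peaks,
                                    activation = act),
                 V12 = fit$V12, k = fit$k),
            class = "iv_curve")
}

#' Steady-state APD as a function of coupling strength
#'
#' Paces the ionic model to steady state at each coupling strength `w` and
#' returns the steady-state APD.  Requires a 1:1 response: if sustained
#' alternans is detected at some `w` the protocol stops with an error.
#'
#' @param params base [ionic_params()] (its `w` is overridden).
#' @param w_values coupling strengths to scan.
#' @param pcl pacing cycle length (ms).
#' @param max_beats pacing budget per point.
#' @param dt integration step (ms).
#' @return Data frame with columns `w`, `apd_ms`, `ca_peak_uM`.
#' @export
apd_prolongation_curve <- function(params = ionic_params(),
                                   w_values = c(0, 0.3, 1),
                                   pcl = 400, max_beats = 300, dt = 0.05) {
  rows <- lapply(w_values, function(wv) {
    p <- params
    p$w <- wv
    res <- pace_to_steady(p, pcl = pcl, max_beats = max_beats, dt = dt)
    amp <- alternans_amplitudes(res$beats)
    if (mean(abs(utils::tail(amp$d_apd, 10))) > 1)
      stop("alternans detected at w = ", wv,
           "; APD prolongation protocol requires a 1:1 response")
    data.frame(w = wv,
               apd_ms = mean(utils::tail(res$beats$apd, 4), na.rm = TRUE),
               ca_peak_uM = mean(utils::tail(res$beats$ca_peak, 4),
                                 na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Stability scan over (tau_f, u)
#'
#' Paces the ionic model to steady state at every grid point and classifies
#' the resulting beat series as stable, alternans or quasiperiodic
#' ([classify_beat_series()]).  Run at a baseline and a perturbed coupling
#' strength to expose the effect of cooperativity on the stability
#' boundary.
#'
#' @param params base [ionic_params()].
#' @param tau_f_grid,u_grid grid axes.
#' @param w_baseline,w_perturbed coupling strengths compared.
#' @param pcl pacing cycle length (ms).
#' @param max_beats pacing budget per cell (early exit on steady state).
#' @param dt integration step (ms).
#' @return Object of class `scan_result`: data.frame `grid` with columns
#'   tau_f, u, w, class, amp (mean |dAPD| of the last 10 pairs, ms),
#'   converged.
#' @export
stability_scan <- function(params = ionic_params(),
                           tau_f_grid = c(30, 45, 60, 80),
                           u_grid = c(1, 3, 6, 9),
                           w_baseline = 0, w_perturbed = 0.03,
                           pcl = 300, max_beats = 400, dt = 0.05) {
  rows <- list()
  for (wv in c(w_baseline, w_perturbed)) {
    for (tf in tau_f_grid) {
      for (uu in u_grid) {
        p <- params
        p$tau_f <- tf
        p$u <- uu
        p$w <- wv
        res <- tryCatch(
          pace_to_steady(p, pcl = pcl, max_beats = max_beats, dt = dt),
          error = function(e) NULL)
        if (is.null(res) || length(res$beats$apd) < 12) {
          rows[[length(rows) + 1]] <- data.frame(
            tau_f = tf, u = uu, w = wv, class = "failed", amp = NA_real_,
            converged = FALSE)
          next
        }
        cls <- classify_beat_series(res$beats)
        amp <- mean(abs(utils::tail(
          alternans_amplitudes(res$beats)$d_apd, 10)))
        rows[[length(rows) + 1]] <- data.frame(
          tau_f = tf, u = uu, w = wv, class = cls, amp = amp,
          converged = res$steady || cls != "stable")
      }
    }
  }
  structure(list(grid = do.call(rbind, rows), pcl = pcl),
            class = "scan_result")
}

#' G_Kr-reduction control scan
#'
#' Repeats [stability_scan()] with the rapid delayed-rectifier conductance
#' scaled by `gkr_scale` at `w = 0`: simple AP prolongation without any
#' change in Ca-to-voltage coupling.  Used to show that APD prolongation by
#' potassium-current reduction does not promote Ca-driven alternans under
#' negative coupling, unlike cooperative gating.
#'
#' @inheritParams stability_scan
#' @param gkr_scale multiplicative G_Kr scale (0.5 = 50 percent block).
#' @return A `scan_result` (single `w = 0` layer, `gkr_scale` recorded).
#' @export
gk_reduction_control <- function(params = ionic_params(), gkr_scale = 0.5,
                                 tau_f_grid = c(30, 45, 60, 80),
                                 u_grid = c(1, 3, 6, 9), pcl = 300,
                                 max_beats = 400, dt = 0.05) {
  p <- params
  p$gkr_scale <- gkr_scale
  out <- stability_scan(p, tau_f_grid = tau_f_grid, u_grid = u_grid,
                        w_baseline = 0, w_perturbed = 0, pcl = pcl,
                        max_beats = max_beats, dt = dt)
  out$grid <- unique(out$grid)
  out$gkr_scale <- gkr_scale
  out
}

#' Measure the Ca-to-voltage coupling slope of the ionic model
#'
#' Paces to steady state, then perturbs the initial SR load by the given
#' relative amounts, paces a single beat from each perturbed state, and
#' regresses the change in APD on the change in Ca-transient peak
#' ([coupling_slope()]).
#'
#' @param params an [ionic_params()] list.
#' @param perturb relative SR-load perturbations.
#' @param pcl pacing cycle length (ms).
#' @param max_beats pre-pacing budget.
#' @param dt integration step (ms).
#' @return List with `slope` (ms/uM), `points` (data.frame d_ca, d_apd),
#'   `baseline` (APD and Ca peak of the unperturbed beat).
#' @export
measure_coupling_slope <- function(params = ionic_params(),
                                   perturb = c(-0.1, -0.05, 0.05, 0.1),
                                   pcl = 400, max_beats = 300, dt = 0.05) {
  base <- pace_to_steady(params, pcl = pcl, max_beats = max_beats, dt = dt)
  st0 <- base$final

  one_beat <- function(state) {
    r <- pace_ionic(params, pcl = pcl, n_beats = 1, init = state, dt = dt)
    if (length(r$beats$apd) < 1) stop("no AP elicited in perturbation beat")
    c(apd = r$beats$apd[1], ca = max(r$trace$ci_uM))
  }
  b0 <- one_beat(st0)
  pts <- t(vapply(perturb, function(pr) {
    st <- st0
    st["cj"] <- st["cj"] * (1 + pr)
    st["cjp"] <- st["cjp"] * (1 + pr)
    one_beat(st)
  }, c(apd = 0, ca = 0)))
  d_apd <- pts[, "apd"] - b0["apd"]
  d_ca <- pts[, "ca"] - b0["ca"]
  cs <- coupling_slope(as.numeric(d_ca), as.numeric(d_apd))
  list(slope = cs$slope, points = data.frame(d_ca = d_ca, d_apd = d_apd),
       baseline = b0)
}
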