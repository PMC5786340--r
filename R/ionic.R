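# Deterministic whole-cell ionic model with cooperative gating via gamma_d.

#' Cooperative-gating factor of the deterministic model
#'
#' \deqn{\gamma_d = 1 + w\,\sigma(15(po_{Ca} - po_x))\,\sigma(c_s - cs_x)}
#' (with the optional overall scale `w_scale`), where
#' \eqn{po_{Ca} = d f f_{Ca}} is the LTCC open probability and \eqn{c_s}
#' the submembrane Ca.  Monotone nondecreasing in both arguments, equal to
#' 1 at `w = 0` and bounded by `1 + w_scale * w`.
#'
#' @param po_ca open probability in [0, 1].
#' @param cs submembrane Ca (uM, >= 0).
#' @param params an [ionic_params()] list.
#' @return gamma_d (vectorised).
#' @export
#' @examples
#' gamma_d(0.4, 2, ionic_params(w = 1, po_x = 0.4, cs_x = 2))  # 1 + w/4
gamma_d <- function(po_ca, cs, params = ionic_params()) {
  if (any(po_ca < 0 | po_ca > 1)) stop("po_ca must be in [0, 1]")
  if (any(cs < 0)) stop("cs must be >= 0")
  so <- 1 / (1 + exp(-15 * (po_ca - params$po_x)))
  sc <- 1 / (1 + exp(-1 * (cs - params$cs_x)))
  1 + params$w_scale * params$w * so * sc
}

#' Initial (resting) state of the ionic model
#'
#' Gates at their steady-state values for `V0`; Ca compartments at the
#' supplied resting concentrations; release flux zero.
#'
#' @param params an [ionic_params()] list.
#' @param V0 resting potential (mV).
#' @param cs0,ci0 submembrane and cytosolic Ca (uM).
#' @param cj0 SR load (uM, cytosol-referred).
#' @return Named numeric state vector.
#' @export
ionic_initial_state <- function(params = ionic_params(), V0 = -86,
                                cs0 = 0.1, ci0 = 0.1, cj0 = 120) {
  .ionic_init_cpp(params, V0, cs0, ci0, cj0)
}

#' Right-hand side of the ionic model
#'
#' Time derivatives of the full state (membrane potential, sarcolemmal
#' gates, the LTCC gates d/f/fCa, and the Ca-cycling variables cs, ci, cj,
#' cj', J_rel) plus the individual membrane currents.  With `w = 0` the
#' model is exactly the base (uncoupled) formulation.
#'
#' @param state named state vector as from [ionic_initial_state()].
#' @param params an [ionic_params()] list.
#' @param vclamp if `TRUE` the V derivative is forced to zero.
#' @return List with `deriv` and `currents` (uA/uF; also `gamma_d`).
#' @export
ionic_rhs <- function(state, params = ionic_params(), vclamp = FALSE) {
  .ionic_rhs_cpp(state, params, vclamp)
}

#' Integrate the ionic model
#'
#' Fixed-step 4th-order Runge-Kutta.  Protocols: `free` (no stimulus),
#' `paced` (stimulus every `pcl`), `vclamp` (step from `v_hold` to
#' `v_test`), `apclamp` (forced waveform).
#'
#' @param params an [ionic_params()] list.
#' @param protocol list with `kind` and its fields (see Details in
#'   [run_voltage_clamp()] for the shared conventions).
#' @param init initial state; default [ionic_initial_state()].
#' @param dt integration step (ms).
#' @param stride recording stride in steps.
#' @return List with `trace` (data.frame) and `final` state.
#' @export
integrate_ionic <- function(params = ionic_params(),
                            protocol = list(kind = "free", duration = 1000),
                            init = NULL, dt = 0.05, stride = 5) {
  if (is.null(init)) init <- ionic_initial_state(params)
  .run_ionic_cpp(params, protocol, init, dt, as.integer(stride))
}

#' Pace the ionic model and extract the beat series
#'
#' Stimulates every `pcl` ms for `n_beats` beats (optionally continuing
#' from `init`), measures the per-beat APD and Ca peaks, and flags steady
#' state when |APD_{n+2} - APD_n| < 0.1 ms for 10 consecutive even-beat
#' comparisons.
#'
#' @inheritParams integrate_ionic
#' @param pcl pacing cycle length (ms).
#' @param n_beats maximum number of beats.
#' @param keep_trace if `FALSE`, only the last `trace_beats` beats of the
#'   dense trace are returned (memory control for long runs).
#' @param trace_beats beats of dense trace to keep when `keep_trace = FALSE`.
#' @return List with `beats` (a [beat_series()]), `steady` (logical),
#'   `trace` (dense trace of the kept beats) and `final` state.
#' @export
pace_ionic <- function(params = ionic_params(), pcl = 300, n_beats = 100,
                       init = NULL, dt = 0.05, stride = 5,
                       keep_trace = TRUE, trace_beats = 10) {
  stopifnot(n_beats >= 1)
  prot <- list(kind = "paced", pcl = pcl, n_beats = n_beats)
  out <- integrate_ionic(params, prot, init = init, dt = dt,
                         stride = stride)
  tr <- out$trace
  beats <- beat_series(tr$time_ms, tr$v_mV, tr$ci_uM, pcl = pcl)
  apd <- beats$apd
  steady <- FALSE
  if (length(apd) >= 22) {
    d2 <- abs(diff(apd, lag = 2))
    tail10 <- d2[seq(length(d2) - 9, length(d2))]
    steady <- isTRUE(all(tail10 < 0.1))
  }
  if (!keep_trace) {
    tr <- tr[tr$time_ms >= (n_beats - trace_beats) * pcl, , drop = FALSE]
  }
  list(beats = beats, steady = steady, trace = tr, final = out$final)
}

#' Pace to steady state (chunked, with early exit)
#'
#' Repeatedly paces in chunks until the steady-state criterion of
#' [pace_ionic()] is met or `max_beats` is reached.
#'
#' @inheritParams pace_ionic
#' @param max_beats hard cap on paced beats.
#' @param chunk beats per integration chunk.
#' @return As [pace_ionic()], plus `n_beats_run`; `beats` covers the final
#'   chunk only.
#' @export
pace_to_steady <- function(params = ionic_params(), pcl = 300,
                           max_beats = 1000, chunk = 50, dt = 0.05,
                           stride = 5, init = NULL) {
  run <- 0
  res <- NULL
  while (run < max_beats) {
    nb <- min(chunk, max_beats - run)
    res <- pace_ionic(params, pcl = pcl, n_beats = nb, init = init,
                      dt = dt, stride = stride)
    init <- res$final
    run <- run + nb
    if (res$steady) break
  }
  res$n_beats_run <- run
  res
}
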