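# Whole-cell stochastic simulation: the CRU lattice coupled to a shared
# membrane potential, under voltage-clamp, AP-clamp or pacing.

run_lattice <- function(cell, protocol, seed = 1, dt = 0.02, stride = 25,
                        init = NULL) {
  g <- cell$geometry
  if (is.null(init) && !is.null(cell$state)) init <- cell$state
  .run_lattice_cpp(g$nx, g$ny, g$nz, cell$cluster_sizes, cell$params,
                   protocol, if (is.null(init)) NULL else init,
                   as.integer(seed), dt, as.integer(stride))
}

#' Voltage-clamp protocol on the stochastic cell
#'
#' Depolarises the lattice from a holding potential to each test potential
#' and records the whole-cell L-type current (capacitance-normalised sum of
#' all cluster currents), the local Ca compartments and channel counts.
#' The commanded and realised membrane potentials are identical.
#'
#' @param cell a [build_cell()] lattice.
#' @param v_test vector of test potentials (mV).
#' @param v_hold holding potential (mV).
#' @param t_hold time at holding potential before the step (ms).
#' @param t_test step duration (ms).
#' @param seed integer seed (same seed + same cell gives bit-identical
#'   trajectories; paired coupled/uncoupled runs should share it).
#' @param dt time step (ms).
#' @param stride recording stride in steps.
#' @return List with one element per test potential, each containing
#'   `trace` (data.frame: time_ms, v_mV, ical_AF, ...), `v_test`, `peak_ical`
#'   (most negative I_CaL during the step).
#' @export
run_voltage_clamp <- function(cell, v_test = 20, v_hold = -80, t_hold = 50,
                              t_test = 150, seed = 1, dt = 0.02,
                              stride = 25) {
  out <- lapply(v_test, function(vt) {
    prot <- list(kind = "vclamp", v_hold = v_hold, v_test = vt,
                 t_hold = t_hold, t_test = t_test)
    r <- run_lattice(cell, prot, seed = seed, dt = dt, stride = stride)
    tr <- r$trace
    test_rows <- tr$time_ms >= t_hold
    list(trace = tr, v_test = vt,
         peak_ical = min(tr$ical_AF[test_rows]),
         final = r$final)
  })
  names(out) <- paste0("V", v_test)
  out
}

#' Pace the stochastic cell with a current stimulus
#'
#' Injects a stimulus current every pacing cycle length and integrates the
#' free-running membrane potential from the total membrane current.  The
#' per-beat APD and Ca-peak series are extracted with [measure_apd()] /
#' [beat_series()].
#'
#' @inheritParams run_voltage_clamp
#' @param pcl pacing cycle length (ms).
#' @param n_beats number of beats.
#' @param stim_amp stimulus amplitude (uA/uF, negative = depolarising).
#' @param stim_dur stimulus duration (ms).
#' @param chunk beats per C++ call (memory control; results identical).
#' @return List with `trace` (whole run), `beats` (a [beat_series()]),
#'   `final` state.
#' @export
run_paced <- function(cell, pcl = 300, n_beats = 10, stim_amp = -80,
                      stim_dur = 1, seed = 1, dt = 0.02, stride = 25,
                      chunk = 25) {
  stopifnot(pcl > stim_dur, n_beats >= 1)
  traces <- list()
  init <- cell$state
  done <- 0
  k <- 0
  while (done < n_beats) {
    nb <- min(chunk, n_beats - done)
    prot <- list(kind = "paced", pcl = pcl, n_beats = nb,
                 stim_amp = stim_amp, stim_dur = stim_dur)
    r <- run_lattice(cell, prot, seed = seed + 1000L * k, dt = dt,
                     stride = stride, init = init)
    tr <- r$trace
    tr$time_ms <- tr$time_ms + done * pcl
    traces[[k + 1]] <- tr
    init <- r$final
    done <- done + nb
    k <- k + 1
  }
  trace <- do.call(rbind, traces)
  beats <- beat_series(trace$time_ms, trace$v_mV, trace$ci_uM, pcl = pcl)
  list(trace = trace, beats = beats, final = init)
}

#' AP-clamp protocol on the stochastic cell
#'
#' Forces the membrane potential to a recorded AP waveform every beat and
#' returns the Ca transient series; used to expose Ca-cycling-driven
#' alternans independently of voltage dynamics.
#'
#' @inheritParams run_paced
#' @param waveform numeric vector, one AP waveform sampled at `wave_dt` ms
#'   covering one cycle length.
#' @param wave_dt sample interval of `waveform` (ms).
#' @return List with `trace`, `ca_peaks` (per-beat peak cytosolic Ca),
#'   `final`.
#' @export
run_ap_clamp <- function(cell, waveform, wave_dt = 1, pcl = 300,
                         n_beats = 10, seed = 1, dt = 0.02, stride = 25,
                         chunk = 25) {
  stopifnot(length(waveform) >= 2)
  traces <- list()
  init <- cell$state
  done <- 0
  k <- 0
  while (done < n_beats) {
    nb <- min(chunk, n_beats - done)
    prot <- list(kind = "apclamp", pcl = pcl, n_beats = nb,
                 waveform = waveform, wave_dt = wave_dt)
    r <- run_lattice(cell, prot, seed = seed + 1000L * k, dt = dt,
                     stride = stride, init = init)
    tr <- r$trace
    tr$time_ms <- tr$time_ms + done * pcl
    traces[[k + 1]] <- tr
    init <- r$final
    done <- done + nb
    k <- k + 1
  }
  trace <- do.call(rbind, traces)
  nb_tot <- floor(max(trace$time_ms) / pcl) + 1
  peaks <- vapply(seq_len(n_beats), function(b) {
    sel <- trace$time_ms >= (b - 1) * pcl & trace$time_ms < b * pcl
    if (!any(sel)) return(NA_real_)
    max(trace$ci_uM[sel])
  }, numeric(1))
  list(trace = trace, ca_peaks = peaks, final = init)
}

#' Equilibrate the stochastic cell at rest
#'
#' Runs the lattice without stimulus for `duration` ms and stores the final
#' state in the returned cell, so subsequent protocols start from a relaxed
#' state.
#'
#' @inheritParams run_voltage_clamp
#' @param duration quiescent time (ms).
#' @return The cell with `$state` set.
#' @export
equilibrate_cell <- function(cell, duration = 500, seed = 1, dt = 0.02) {
  prot <- list(kind = "free", duration = duration)
  r <- run_lattice(cell, prot, seed = seed, dt = dt,
                   stride = max(1L, as.integer(duration / dt / 10)))
  cell$state <- r$final
  cell
}
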