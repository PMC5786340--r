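# Ca release units: lattice construction, RyR kinetics, and the local
# five-compartment Ca ODE right-hand side.

#' Build a cell (lattice of Ca release units)
#'
#' Draws an LTCC cluster size for every CRU from the rounded Gaussian
#' (mean 10, sd 3 by default), clamped to [1, 25], and initialises all
#' compartments to their documented resting values.  Reproducible from
#' `seed`.
#'
#' @param geometry a [cell_geometry()] list.
#' @param params a [cell_params()] list.
#' @param seed integer seed.
#' @return List of class `cell_lattice` with `geometry`, `params`,
#'   `cluster_sizes` (integer vector of length nx*ny*nz), `n_cru`,
#'   `n_ryr_total`, and `state` (NULL until a simulation initialises it).
#' @export
#' @examples
#' cell <- build_cell(cell_geometry(8, 8, 4), seed = 1)
#' cell$n_cru
build_cell <- function(geometry = cell_geometry(), params = cell_params(),
                       seed = 1) {
  stopifnot(inherits(geometry, "cell_geometry"))
  n <- as.integer(geometry$nx * geometry$ny * geometry$nz)
  sizes <- .build_cluster_sizes_cpp(n, geometry$cluster_mean,
                                    geometry$cluster_sd,
                                    as.integer(geometry$cluster_min),
                                    as.integer(geometry$cluster_max),
                                    as.integer(seed))
  structure(list(geometry = geometry, params = params,
                 cluster_sizes = sizes, n_cru = n,
                 n_ryr_total = as.integer(n * params$n_ryr), seed = seed,
                 state = NULL),
            class = "cell_lattice")
}

#' RyR cluster opening rate
#'
#' Opening rate of a closed RyR,
#' \eqn{k_o = K_u\,\phi(c_{JSR})\,c_p^2 / (c_p^2 + K_{cp}^2)} with
#' \eqn{\phi(c) = 1/(1 + (K_{JSR}/c)^{h})}: zero at zero cleft Ca, strictly
#' increasing in both the cleft and junctional-SR Ca (the luminal sensor
#' \eqn{\phi} carries the steep release-load dependence).  Open channels
#' close through an inactivated and a refractory state with fixed time
#' constants.
#'
#' @param cp cleft Ca (uM, >= 0).
#' @param cjsr junctional SR Ca (uM, >= 0).
#' @param params a [cell_params()] list.
#' @return Opening rate (1/ms).
#' @export
ryr_rates <- function(cp, cjsr, params = cell_params()) {
  if (any(cp < 0) || any(cjsr < 0)) stop("cp and cjsr must be >= 0")
  ko <- vapply(seq_along(cp), function(i) {
    .ryr_open_rate_cpp(cp[[min(i, length(cp))]],
                       cjsr[[min(i, length(cjsr))]], params)
  }, numeric(1))
  list(open = ko, close = 1 / params$tau_o,
       inactivate = 1 / params$tau_i, recover = 1 / params$tau_rr)
}

#' Right-hand side of the local Ca ODEs of one CRU
#'
#' Evaluates the five concentration derivatives (ci, cs, cp, cNSR, cJSR) and
#' the two troponin buffer derivatives, together with every flux term
#' (diffusive exchanges I_dsi, I_dps, I_tr; uptake I_up; release I_r; LTCC
#' flux; NCX; sarcolemmal pump and background; nearest-neighbour diffusion
#' I_ci, I_cs, I_cNSR) and the instantaneous buffering factors.
#'
#' @param state named numeric vector with elements ci, cs, cp, cnsr, cjsr,
#'   tni, tns (uM).
#' @param neighbours `NULL` (isolated CRU) or a matrix with one row per
#'   neighbour and columns (ci, cs, cnsr, longitudinal) where
#'   `longitudinal` is 1 for x-direction neighbours and 0 otherwise.
#' @param V membrane potential (mV).
#' @param n_open_ltcc,n_open_ryr open channel counts used for the LTCC and
#'   release fluxes.
#' @param params a [cell_params()] list.
#' @return List with `deriv` (named derivatives, uM/ms) and `fluxes`.
#' @export
cru_rhs <- function(state, neighbours = NULL, V = -86, n_open_ltcc = 0,
                    n_open_ryr = 0, params = cell_params()) {
  need <- c("ci", "cs", "cp", "cnsr", "cjsr", "tni", "tns")
  stopifnot(all(need %in% names(state)))
  .cru_rhs_cpp(state[need], neighbours, V, as.integer(n_open_ltcc),
               as.integer(n_open_ryr), params)
}

#' Resting CRU state
#'
#' @param params a [cell_params()] list.
#' @return Named numeric vector accepted by [cru_rhs()].
#' @export
cru_resting_state <- function(params = cell_params()) {
  tn0 <- with(params, BT * kon * ci0 / (kon * ci0 + koff))
  c(ci = params$ci0, cs = params$cs0, cp = params$cp0, cnsr = params$cnsr0,
    cjsr = params$cjsr0, tni = tn0, tns = tn0)
}

#' Isolated-spark trials of the RyR cluster
#'
#' Clamps the cleft Ca of a single CRU to a rectangular pulse and records
#' the peak number of simultaneously open RyRs in each of `n_trials`
#' independently seeded trials.  Used to verify the spark-size calibration
#' (5--10 of 100 RyRs recruited per spark).
#'
#' @param cp_pulse pulse amplitude (uM).
#' @param pulse_dur pulse duration (ms).
#' @param duration trial duration (ms).
#' @param n_trials number of trials.
#' @param dt time step (ms).
#' @param seed integer seed.
#' @param params a [cell_params()] list.
#' @return List with `peaks` (integer vector) and `example_n_open` (the
#'   open-count trace of the first trial).
#' @export
spark_trials <- function(cp_pulse = 10, pulse_dur = 10, duration = 100,
                         n_trials = 200, dt = 0.01, seed = 1,
                         params = cell_params()) {
  .spark_trials_cpp(params, cp_pulse, pulse_dur, duration, dt,
                    as.integer(n_trials), as.integer(seed), params$cp0)
}
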