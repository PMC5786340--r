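# Single LTCC cluster: coupling factors, Markov rates, GHK current,
# stochastic cluster simulation and opening statistics.

#' Cooperative-gating coupling factors
#'
#' \eqn{\gamma_1 = 1 + w_1 \sigma(15(N_L/3 - po_x)) \sigma(c_p - cp_x)} and
#' the analogous \eqn{\gamma_2} with \eqn{w_2}.  Both are 1 with coupling
#' disabled, increase monotonically with the open count and cleft Ca, and
#' saturate at \eqn{1 + w}.
#'
#' @param n_open number of open channels in the cluster (>= 0).
#' @param cp cleft Ca concentration (uM, >= 0).
#' @param params an [ltcc_params()] list.
#' @return list with components `gamma1` and `gamma2` (vectorised).
#' @export
#' @examples
#' coupling_factors(3, 10, ltcc_params(w1 = 1, w2 = 1))
coupling_factors <- function(n_open, cp, params = ltcc_params()) {
  if (any(n_open < 0)) stop("n_open must be >= 0")
  if (any(cp < 0)) stop("cp must be >= 0")
  so <- 1 / (1 + exp(-15 * (n_open / 3 - params$po_x)))
  sc <- 1 / (1 + exp(-1 * (cp - params$cp_x)))
  list(gamma1 = 1 + params$w1 * so * sc, gamma2 = 1 + params$w2 * so * sc)
}

#' Instantaneous transition rates of the 7-state LTCC scheme
#'
#' Evaluates every transition rate of the Markov scheme at membrane
#' potential `V`, cleft Ca `cp` and cluster open count `n_open`, with the
#' coupling factor \eqn{\gamma_1} applied to the activation rate alpha and
#' \eqn{\gamma_2} to the opening rate r1 (and wherever r1 appears in the
#' detailed-balance expressions for s2, s2').  At `cp = 0` the Ca-sensing
#' rates s1, k1 and k6 vanish (f(0) = 0); this is valid input, not an error.
#'
#' @inheritParams coupling_factors
#' @param V membrane potential (mV).
#' @return Named list of rates (1/ms) plus the two gamma factors.
#' @export
ltcc_rates <- function(V, cp, n_open = 0, params = ltcc_params()) {
  stopifnot(is.finite(V), cp >= 0, n_open >= 0)
  .ltcc_rates_cpp(V, cp, n_open, params)
}

#' Generator matrix of the 7-state LTCC chain
#'
#' The 7 x 7 infinitesimal generator at fixed (V, cp, n_open); row sums are
#' zero.  Useful for master-equation computations (stationary distributions,
#' relaxation spectra) against which the stochastic simulation can be
#' checked.
#'
#' @inheritParams ltcc_rates
#' @return 7 x 7 matrix with dimnames C2, C1, O, I1Ca, I2Ca, I1Ba, I2Ba.
#' @export
ltcc_generator <- function(V, cp, n_open = 0, params = ltcc_params()) {
  stopifnot(is.finite(V), cp >= 0, n_open >= 0)
  .ltcc_generator_cpp(V, cp, n_open, params)
}

#' GHK-type single-channel L-type Ca current
#'
#' \deqn{i_{CaL} = 4 P_{Ca} z F \frac{0.001\,\gamma_i c_p e^{2z} -
#'   \gamma_o [Ca]_o}{e^{2z} - 1}, \qquad z = V F / (R T),}
#' with the removable singularity at V = 0 evaluated analytically.  The
#' current is negative (inward) at plateau potentials for physiological
#' cleft and extracellular Ca, and reverses at
#' \eqn{V_{rev} = (RT/2F)\ln(\gamma_o [Ca]_o / (0.001 \gamma_i c_p))}.
#'
#' @inheritParams ltcc_rates
#' @return Single-channel current (model units, negative = inward);
#'   vectorised over `V` and `cp`.
#' @export
#' @examples
#' single_channel_current(c(-20, 0, 20), 1)
single_channel_current <- function(V, cp, params = ltcc_params()) {
  if (any(cp < 0)) stop("cp must be >= 0")
  .ltcc_single_current_cpp(as.numeric(V), as.numeric(cp), params)
}

#' Whole-cluster L-type current
#'
#' `I_CaL = i_CaL * N_L`: the single-channel current times the number of
#' open channels.
#'
#' @param n_open open-channel count.
#' @inheritParams ltcc_rates
#' @return Cluster current (same units as [single_channel_current()]).
#' @export
cluster_current <- function(n_open, V, cp, params = ltcc_params()) {
  n_open * single_channel_current(V, cp, params)
}

#' Stochastic simulation of an LTCC cluster under clamped V and cp
#'
#' Simulates 1--25 channels of the 7-state scheme with fixed-timestep
#' per-channel Bernoulli transitions (at most one transition per channel
#' per step, probability rate * dt, bounded below 0.1).  The coupling
#' factors are evaluated with the open count at the start of each step,
#' so the update is explicit and order-independent within a step.
#' `V` and `cp` may be scalars or per-step waveforms.
#'
#' @param n_channels cluster size (1--25).
#' @param V membrane potential (mV), scalar or length-`n_steps` vector.
#' @param cp cleft Ca (uM), scalar or length-`n_steps` vector.
#' @param duration simulated time (ms).
#' @param dt time step (ms); total exit probability per step must stay
#'   below 0.1 or the simulation aborts with advice to reduce `dt`.
#' @param seed integer seed of the cluster's RNG stream.
#' @param params an [ltcc_params()] list.
#' @param init_states optional integer vector of initial per-channel states
#'   (0-based indices of C2, C1, O, I1Ca, I2Ca, I1Ba, I2Ba); default all C2.
#' @param record_joint if `TRUE` and `n_channels == 2`, also accumulate the
#'   joint 7 x 7 occupancy of the ordered channel pair.
#' @return List with `n_open` (per-step open count), `time_ms`, `occupancy`
#'   (time-averaged per-channel state occupancy, named), `joint` (matrix, if
#'   requested) and `final_states`.
#' @export
simulate_cluster <- function(n_channels, V, cp, duration, dt = 0.01,
                             seed = 1, params = ltcc_params(),
                             init_states = NULL, record_joint = FALSE) {
  stopifnot(n_channels >= 1, n_channels <= 25, duration > 0, dt > 0)
  n_steps <- as.integer(round(duration / dt))
  out <- .simulate_cluster_cpp(params, as.integer(n_channels),
                               as.numeric(V), as.numeric(cp), dt, n_steps,
                               as.integer(seed),
                               if (is.null(init_states)) integer(0)
                               else as.integer(init_states),
                               isTRUE(record_joint))
  names(out$occupancy) <- c("C2", "C1", "O", "I1Ca", "I2Ca", "I1Ba", "I2Ba")
  out$time_ms <- seq_len(n_steps) * dt
  out
}

#' Advance a cluster state by one (or more) stochastic steps
#'
#' Thin wrapper over [simulate_cluster()] for stepping an explicit cluster
#' state: runs `n_steps` steps from the supplied per-channel states and
#' returns the new state.
#'
#' @param states integer vector of per-channel Markov states (0-based).
#' @inheritParams simulate_cluster
#' @param n_steps number of steps of size `dt`.
#' @return List with `states` (new per-channel states), `n_open`.
#' @export
advance_cluster <- function(states, V, cp, dt = 0.01, n_steps = 1, seed = 1,
                            params = ltcc_params()) {
  out <- .simulate_cluster_cpp(params, length(states), as.numeric(V),
                               as.numeric(cp), dt, as.integer(n_steps),
                               as.integer(seed), as.integer(states), FALSE)
  list(states = out$final_states,
       n_open = sum(out$final_states == 2L))
}

#' Opening statistics of an n_open trace
#'
#' An \emph{event} is a maximal run of samples with `n_open >= 1`.  For each
#' event the duration (cluster open dwell time) and the maximum number of
#' simultaneously open channels are extracted; the histogram of per-event
#' maxima is the quantity that distinguishes cooperative from independent
#' gating (simultaneous openings of 2+ channels become common with
#' coupling).
#'
#' @param n_open integer vector sampled at fixed `dt`.
#' @param dt sample interval (ms).
#' @return List with `n_events`, `dwell_ms` (numeric vector of event
#'   durations), `max_open` (per-event maxima) and `max_open_hist` (table
#'   over 1..max).
#' @export
#' @examples
#' opening_statistics(c(0, 0, 1, 2, 1, 0), dt = 1)
opening_statistics <- function(n_open, dt = 0.01) {
  if (length(n_open) == 0) {
    return(list(n_events = 0L, dwell_ms = numeric(0),
                max_open = integer(0), max_open_hist = integer(0)))
  }
  open <- n_open >= 1
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) {
    return(list(n_events = 0L, dwell_ms = numeric(0),
                max_open = integer(0), max_open_hist = integer(0)))
  }
  starts <- starts[keep]
  ends <- ends[keep]
  dwell <- r$lengths[keep] * dt
  mx <- mapply(function(s, e) max(n_open[s:e]), starts, ends)
  hist <- tabulate(mx, nbins = max(mx))
  names(hist) <- seq_along(hist)
  list(n_events = length(dwell), dwell_ms = as.numeric(dwell),
       max_open = as.integer(mx), max_open_hist = hist)
}
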