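# Beat-series analysis: APD measurement, alternans amplitudes and
# classification, the coupled-map eigenvalue theory, and the Ca-to-voltage
# coupling slope.

#' Measure per-beat action potential duration
#'
#' APD is measured from the maximum-upstroke-velocity time of each beat to
#' the crossing of
#' `V_rest + (1 - repolarization_fraction) * (V_peak - V_rest)`
#' (APD90 by default), with linear interpolation of the crossing time.
#' Upstrokes are detected as upward crossings of a threshold voltage with a
#' refractory window to avoid double counting.
#'
#' @param time time stamps (ms), equally or unequally spaced.
#' @param vm membrane potential trace (mV).
#' @param repolarization_fraction repolarisation fraction defining APD
#'   (0.9 = APD90).
#' @param threshold upstroke detection threshold (mV).
#' @param min_separation minimum time between detected upstrokes (ms).
#' @return Data frame with one row per completed beat: `upstroke_ms`,
#'   `apd_ms`, `v_peak`.  Zero rows if no upstroke is found.
#' @export
#' @examples
#' t <- seq(0, 600, by = 1)
#' v <- ifelse(t %% 300 < 200 & t %% 300 > 5, 10, -85)  # square APs
#' measure_apd(t, v)
measure_apd <- function(time, vm, repolarization_fraction = 0.9,
                        threshold = -40, min_separation = 50) {
  stopifnot(length(time) == length(vm))
  n <- length(vm)
  if (n < 3) return(data.frame(upstroke_ms = numeric(0),
                               apd_ms = numeric(0), v_peak = numeric(0)))
  up <- which(vm[-1] >= threshold & vm[-n] < threshold)
  if (length(up) == 0)
    return(data.frame(upstroke_ms = numeric(0), apd_ms = numeric(0),
                      v_peak = numeric(0)))
  # enforce refractory separation
  keep <- c(TRUE, diff(time[up]) >= min_separation)
  up <- up[keep]
  v_rest <- stats::quantile(vm, 0.05, names = FALSE)

  res <- lapply(seq_along(up), function(k) {
    i0 <- up[k]
    i1 <- if (k < length(up)) up[k + 1] else n
    seg <- i0:i1
    # upstroke time: max dV/dt within the first part of the beat
    dseg <- seg[-length(seg)]
    dv <- diff(vm[seg]) / diff(time[seg])
    t_up <- time[dseg[which.max(dv)]]
    v_peak <- max(vm[seg])
    v_cross <- v_rest + (1 - repolarization_fraction) * (v_peak - v_rest)
    after_peak <- seg[seg >= seg[which.max(vm[seg])]]
    below <- which(vm[after_peak] <= v_cross)
    if (length(below) == 0) return(NULL)  # beat not repolarised in window
    ib <- after_peak[below[1]]
    if (ib == seg[1]) return(NULL)
    ia <- ib - 1
    frac <- (v_cross - vm[ia]) / (vm[ib] - vm[ia])
    t_cross <- time[ia] + frac * (time[ib] - time[ia])
    data.frame(upstroke_ms = t_up, apd_ms = t_cross - t_up, v_peak = v_peak)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) res <- data.frame(upstroke_ms = numeric(0),
                                      apd_ms = numeric(0),
                                      v_peak = numeric(0))
  res
}

#' Per-beat APD and Ca-peak series
#'
#' Combines [measure_apd()] on the voltage trace with per-cycle peak
#' extraction on the cytosolic Ca trace.
#'
#' @inheritParams measure_apd
#' @param ca cytosolic Ca trace (uM), same length as `time`.
#' @param pcl pacing cycle length used to window the Ca peaks (ms).
#' @param ... passed to [measure_apd()].
#' @return List of class `beat_series`: `apd` (ms), `ca_peak` (uM),
#'   `upstroke_ms`, `pcl`.
#' @export
beat_series <- function(time, vm, ca = NULL, pcl = NULL, ...) {
  ap <- measure_apd(time, vm, ...)
  apd <- ap$apd_ms
  up <- ap$upstroke_ms
  ca_peak <- NULL
  if (!is.null(pcl)) {
    # align beats to their stimulus number so that a missed or undetected
    # beat appears as NA instead of silently shifting the (-1)^n phase
    nb <- ceiling((max(time) + 1e-6) / pcl)
    slot <- pmin(pmax(floor(up / pcl) + 1, 1), nb)
    apd_al <- rep(NA_real_, nb)
    up_al <- rep(NA_real_, nb)
    keep <- !duplicated(slot)
    apd_al[slot[keep]] <- apd[keep]
    up_al[slot[keep]] <- up[keep]
    apd <- apd_al
    up <- up_al
    if (!is.null(ca)) {
      ca_peak <- vapply(seq_len(nb), function(b) {
        sel <- time >= (b - 1) * pcl & time < b * pcl
        if (!any(sel)) NA_real_ else max(ca[sel])
      }, numeric(1))
    }
  } else if (!is.null(ca)) {
    stop("pcl is required to window the Ca peaks")
  }
  structure(list(apd = apd, ca_peak = ca_peak, upstroke_ms = up, pcl = pcl),
            class = "beat_series")
}

#' Alternans amplitudes of a beat series
#'
#' \deqn{\Delta APD_n = (-1)^n (APD_{n+1} - APD_n)} and the analogous
#' \eqn{\Delta Ca_n} on the Ca-peak series (by default the difference; the
#' sum variant \eqn{(-1)^n(Ca_{n+1}+Ca_n)} is available via
#' `ca_mode = "sum"`).  A period-2 series gives a constant amplitude; a
#' period-1 series gives zeros.
#'
#' @param series a [beat_series()], or a list with `apd` and optionally
#'   `ca_peak`.
#' @param ca_mode `"difference"` (default) or `"sum"`.
#' @return List with `d_apd` and (if Ca peaks present) `d_ca`.
#' @export
#' @examples
#' alternans_amplitudes(list(apd = c(200, 180, 200, 180)))$d_apd  # -20 -20 -20
alternans_amplitudes <- function(series, ca_mode = c("difference", "sum")) {
  ca_mode <- match.arg(ca_mode)
  apd <- series$apd
  if (length(apd) < 2) stop("need at least 2 beats")
  n <- seq_len(length(apd) - 1)
  sgn <- (-1)^(n - 1)  # beat index n runs from 0 in the definition
  d_apd <- sgn * (apd[n + 1] - apd[n])
  out <- list(d_apd = d_apd)
  ca <- series$ca_peak
  if (!is.null(ca) && length(ca) >= 2) {
    m <- seq_len(length(ca) - 1)
    sgm <- (-1)^(m - 1)
    out$d_ca <- if (ca_mode == "difference") sgm * (ca[m + 1] - ca[m])
                else sgm * (ca[m + 1] + ca[m])
  }
  out
}

#' First beat of sustained alternans
#'
#' Returns the first beat index at which the alternans amplitude
#' \eqn{\Delta APD_n = (-1)^n(APD_{n+1}-APD_n)} exceeds `threshold` in
#' magnitude \emph{with a constant sign} for at least `sustain` consecutive
#' beat pairs, or `NA` if that never happens.  The constant-sign
#' requirement distinguishes true period-2 alternation from uncorrelated
#' beat-to-beat fluctuation, which in a stochastic cell can exceed a small
#' amplitude threshold but flips phase at random.
#'
#' @param series a [beat_series()].
#' @param threshold alternans threshold on |dAPD| (ms).
#' @param sustain number of consecutive beat pairs above threshold.
#' @return Integer beat index (1-based) or `NA`.
#' @export
alternans_onset <- function(series, threshold = 1, sustain = 10) {
  d <- alternans_amplitudes(series)$d_apd
  if (length(d) < sustain) return(NA_integer_)
  ok <- abs(d) > threshold
  ok[is.na(ok)] <- FALSE
  sgn <- sign(d)
  run_start <- 1L
  run_len <- 0L
  run_sign <- 0
  for (i in seq_along(d)) {
    if (ok[i] && (run_len == 0L || sgn[i] == run_sign)) {
      if (run_len == 0L) {
        run_start <- i
        run_sign <- sgn[i]
      }
      run_len <- run_len + 1L
      if (run_len >= sustain) return(as.integer(run_start))
    } else if (ok[i]) {
      run_start <- i
      run_sign <- sgn[i]
      run_len <- 1L
    } else {
      run_len <- 0L
    }
  }
  NA_integer_
}

#' Eigenvalues of the coupled voltage-calcium map
#'
#' Closed form for the two-variable linearised beat-to-beat map:
#' \deqn{\lambda_\pm = \tfrac12\left(-\lambda_v - \lambda_c \pm
#'   \sqrt{(\lambda_c - \lambda_v)^2 + 4C}\right)}
#' where \eqn{\lambda_v} and \eqn{\lambda_c} are the eigenvalues of the
#' uncoupled voltage (APD restitution) and Ca (release-load) maps and C is
#' the Ca-to-voltage coupling.  The pair is complex when
#' \eqn{(\lambda_c-\lambda_v)^2 + 4C < 0}.
#'
#' @param lambda_v,lambda_c,C map parameters (vectorised).
#' @return Complex matrix with columns `lambda_plus`, `lambda_minus`.
#' @export
#' @examples
#' map_eigenvalues(0.5, 0.5, 0)      # -0.5, -0.5
map_eigenvalues <- function(lambda_v, lambda_c, C) {
  disc <- as.complex((lambda_c - lambda_v)^2 + 4 * C)
  s <- sqrt(disc)
  cbind(lambda_plus = 0.5 * (-lambda_v - lambda_c + s),
        lambda_minus = 0.5 * (-lambda_v - lambda_c - s))
}

#' Classify the coupled map dynamics
#'
#' `stable` if both eigenvalues have modulus < 1; `alternans` if the
#' dominant eigenvalue is real with modulus > 1 (period doubling);
#' `quasiperiodic` if the dominant pair is complex with modulus > 1.
#'
#' @inheritParams map_eigenvalues
#' @return Character vector of classifications.
#' @export
classify_map <- function(lambda_v, lambda_c, C) {
  ev <- map_eigenvalues(lambda_v, lambda_c, C)
  mod <- pmax(Mod(ev[, 1]), Mod(ev[, 2]))
  is_complex <- abs(Im(ev[, 1])) > 1e-12
  out <- rep("stable", length(mod))
  out[mod >= 1 & !is_complex] <- "alternans"
  out[mod >= 1 & is_complex] <- "quasiperiodic"
  out
}

#' Theoretical stability map over a (lambda_v, lambda_c) grid
#'
#' Classifies every grid point at coupling `C`.  With C = 0 the stability
#' boundary is the square lambda_v = 1, lambda_c = 1; increasing positive C
#' (or less negative C) shrinks the stable region in the real-eigenvalue
#' (alternans) sectors, while the complex (quasiperiodic) boundary follows
#' \eqn{|\lambda|^2 = \lambda_v\lambda_c - C = 1}.
#'
#' @param C coupling.
#' @param lambda_v,lambda_c grid axes.
#' @return Object of class `stability_map`: list with `grid` (data.frame
#'   lambda_v, lambda_c, class, mod), `C`, `stable_area` (count of stable
#'   cells).
#' @export
theoretical_boundary <- function(C, lambda_v = seq(0, 1.5, by = 0.02),
                                 lambda_c = seq(0, 1.5, by = 0.02)) {
  g <- expand.grid(lambda_v = lambda_v, lambda_c = lambda_c)
  ev <- map_eigenvalues(g$lambda_v, g$lambda_c, C)
  g$mod <- pmax(Mod(ev[, 1]), Mod(ev[, 2]))
  g$class <- classify_map(g$lambda_v, g$lambda_c, C)
  structure(list(grid = g, C = C,
                 stable_area = sum(g$class == "stable")),
            class = "stability_map")
}

#' Ca-to-voltage coupling slope
#'
#' Ordinary least-squares slope of dAPD against dCa-peak over a set of
#' SR-load perturbation experiments.  A positive slope means larger Ca
#' transients prolong the APD (NCX-dominated, positive coupling); a
#' negative slope means Ca-induced LTCC inactivation dominates.
#'
#' @param d_ca change in Ca-transient amplitude per perturbation (uM).
#' @param d_apd corresponding change in APD (ms).
#' @return List with `slope` (ms/uM), `sign` (+1/-1), `fit` (the lm).
#' @export
#' @examples
#' coupling_slope(c(-1, 0, 1), c(-2.5, 0, 2.5))$slope  # 2.5
coupling_slope <- function(d_ca, d_apd) {
  stopifnot(length(d_ca) == length(d_apd))
  if (length(d_ca) < 3) stop("need at least 3 perturbation points")
  if (stats::sd(d_ca) == 0) stop("degenerate perturbations: zero variance in d_ca")
  fit <- stats::lm(d_apd ~ d_ca)
  slope <- unname(coef(fit)[2])
  list(slope = slope, sign = sign(slope), fit = fit)
}

#' Classify a simulated beat series
#'
#' Distinguishes period-2 alternans from quasiperiodic (Hopf-type)
#' modulation in an APD sequence: the discrete spectrum of the demeaned
#' series is examined over the last `window` beats; a dominant frequency
#' within `tol` of 0.5 cycles/beat with sufficient amplitude is alternans,
#' a dominant frequency away from 0.5 is quasiperiodic, otherwise stable.
#'
#' @param series a [beat_series()].
#' @param window number of final beats analysed.
#' @param amp_threshold minimum sustained oscillation amplitude (ms).
#' @param tol frequency tolerance around 0.5 (cycles/beat).
#' @return One of "stable", "alternans", "quasiperiodic".
#' @export
classify_beat_series <- function(series, window = 40, amp_threshold = 1,
                                 tol = 0.02) {
  apd <- series$apd
  if (sum(!is.na(apd)) < 8) return("stable")
  x <- utils::tail(apd, window)
  x <- x[!is.na(x)]
  if (length(x) < 8) return("stable")
  x <- x - mean(x)
  amp <- stats::quantile(abs(x), 0.9, names = FALSE)
  if (amp < amp_threshold / 2) return("stable")
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:floor(n / 2 + 1)]
  freqs <- seq_len(length(sp)) / n
  fdom <- freqs[which.max(sp)]
  if (abs(fdom - 0.5) <= tol) "alternans" else "quasiperiodic"
}

#' Voltage-map eigenvalue from an APD restitution curve (utility)
#'
#' Estimates \eqn{\lambda_v} as the slope of APD against the preceding
#' diastolic interval at the operating point, by finite differences on a
#' supplied restitution table.
#'
#' @param di diastolic intervals (ms).
#' @param apd corresponding APDs (ms).
#' @param at DI at which to evaluate the slope; default the median.
#' @return Estimated slope (dimensionless).
#' @export
restitution_eigenvalue <- function(di, apd, at = stats::median(di)) {
  stopifnot(length(di) == length(apd), length(di) >= 3)
  o <- order(di)
  di <- di[o]; apd <- apd[o]
  i <- which.min(abs(di - at))
  i <- min(max(i, 2), length(di) - 1)
  (apd[i + 1] - apd[i - 1]) / (di[i + 1] - di[i - 1])
}
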