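# Configuration, serialisation and synthetic fixtures.

.config_known_keys <- c("model", "protocol", "params", "seed", "out",
                        "stride", "dt", "geometry")

#' Load and validate a run configuration
#'
#' Reads a JSON (or YAML, if the yaml package is installed) configuration
#' with top-level keys `model` ("stochastic", "ionic" or "map"),
#' `protocol`, `params`, `geometry`, `seed`, `dt`, `stride`, `out`.
#' Unknown top-level keys are rejected by name; defaults are filled in and
#' recorded.
#'
#' @param path file path.
#' @return Validated config list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(cfg), .config_known_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$model) ||
      !cfg$model %in% c("stochastic", "ionic", "map"))
    stop("config must set model to one of stochastic, ionic, map")
  defaults <- list(seed = 1L, stride = 25L,
                   dt = if (cfg$model == "ionic") 0.05 else 0.02,
                   out = ".", params = list(), protocol = list(),
                   geometry = list())
  cfg <- modifyList(defaults, cfg)
  structure(cfg, class = "run_config")
}

#' Write a time-series trace as CSV
#'
#' Fixed column order, units in the header (column names carry their unit
#' suffixes), 12 significant digits so a read-back is numerically
#' identical at that precision.
#'
#' @param trace data.frame (nonempty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(trace, path) {
  if (!is.data.frame(trace) || nrow(trace) == 0)
    stop("trace must be a nonempty data.frame")
  out <- trace
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 12))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV time series written by [write_timeseries()]
#' @param path file path.
#' @return data.frame.
#' @export
read_timeseries <- function(path) utils::read.csv(path)

#' Write a run manifest
#'
#' Records the configuration, package version, timestamps, seeds and the
#' output files with their checksums, sufficient to reproduce the run.
#'
#' @param config the `run_config` used.
#' @param files character vector of output files.
#' @param path manifest path (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, files, path) {
  sums <- vapply(files, function(f) {
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  }, character(1))
  man <- list(config = unclass(config),
              package_version = as.character(utils::packageVersion("coopgate")),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
              seed = config$seed,
              files = data.frame(file = files, md5 = unname(sums)))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Synthetic fixtures with known ground truth
#'
#' Generators for the analysis-layer tests: square and triangular action
#' potentials, period-2 beat series, Boltzmann-generated I-V sets and
#' n_open traces with a known event structure.  Each fixture returns the
#' dataset together with its ground-truth descriptor.
#'
#' @param kind one of "square_ap", "triangle_ap", "period2_beats",
#'   "boltzmann_iv", "n_open_events".
#' @param params named list of kind-specific parameters (all have
#'   defaults).
#' @param seed integer seed for the stochastic kinds.
#' @return List with `data` and `truth`.
#' @export
#' @examples
#' fx <- make_fixture("period2_beats")
#' alternans_amplitudes(fx$data)$d_apd[1] == fx$truth$d_apd
make_fixture <- function(kind, params = list(), seed = 1) {
  kind <- match.arg(kind, c("square_ap", "triangle_ap", "period2_beats",
                            "boltzmann_iv", "n_open_events"))
  set.seed(seed)
  p <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  switch(kind,
    square_ap = {
      pcl <- p("pcl", 300); width <- p("width", 200); nb <- p("n_beats", 5)
      dt <- p("dt", 0.5)
      t <- seq(0, nb * pcl - dt, by = dt)
      v <- ifelse(t %% pcl >= 1 & t %% pcl < 1 + width, 10, -85)
      list(data = data.frame(time_ms = t, v_mV = v),
           truth = list(apd = width, n_beats = nb, pcl = pcl))
    },
    triangle_ap = {
      pcl <- p("pcl", 300); width <- p("width", 250); nb <- p("n_beats", 5)
      dt <- p("dt", 0.5); v_rest <- -85; v_peak <- p("v_peak", 15)
      t <- seq(0, nb * pcl - dt, by = dt)
      tb <- t %% pcl
      v <- ifelse(tb < 1, v_rest + (v_peak - v_rest) * tb,
             ifelse(tb < 1 + width,
                    v_peak - (v_peak - v_rest) * (tb - 1) / width, v_rest))
      # APD90: crossing of v_rest + 0.1 (v_peak - v_rest) on the linear decay
      apd90 <- 0.9 * width
      list(data = data.frame(time_ms = t, v_mV = v),
           truth = list(apd90 = apd90, pcl = pcl))
    },
    period2_beats = {
      a <- p("apd_long", 200); b <- p("apd_short", 180)
      ca_a <- p("ca_long", 1.0); ca_b <- p("ca_short", 0.8)
      nb <- p("n_beats", 20)
      apd <- rep(c(a, b), length.out = nb)
      ca <- rep(c(ca_a, ca_b), length.out = nb)
      list(data = structure(list(apd = apd, ca_peak = ca, pcl = p("pcl", 300)),
                            class = "beat_series"),
           truth = list(d_apd = b - a, d_ca = ca_b - ca_a))
    },
    boltzmann_iv = {
      v12 <- p("V12", -10); k <- p("k", 6)
      v <- p("v", seq(-60, 60, by = 10))
      act <- 1 / (1 + exp(-(v - v12) / k))
      drive <- single_channel_current(v, 0.1)
      list(data = data.frame(v = v, peak_ical = act * drive),
           truth = list(V12 = v12, k = k))
    },
    n_open_events = {
      n_ev <- p("n_events", 10); dt <- p("dt", 0.01)
      gap <- p("gap_samples", 50)
      lens <- sample(5:40, n_ev, replace = TRUE)
      maxes <- sample(1:5, n_ev, replace = TRUE)
      trace <- integer(gap)
      for (i in seq_len(n_ev)) {
        ev <- pmax(1, pmin(maxes[i],
                           round(maxes[i] * sin(seq(0, pi, length.out = lens[i])) + 0.5)))
        ev[which.max(ev)] <- maxes[i]
        trace <- c(trace, ev, integer(gap))
      }
      list(data = list(n_open = trace, dt = dt),
           truth = list(n_events = n_ev, dwell_ms = lens * dt,
                        max_open = maxes))
    })
}
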