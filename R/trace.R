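#' Fluorescence trace container
#'
#' The universal exchange object: uniformly sampled times, one (MTY) or two
#' (mT-Sapphire, Sirius) fluorescence channels in arbitrary units, the
#' Peltier setpoint track, timed event annotations, and free-form metadata.
#'
#' @param times Strictly increasing numeric vector, seconds.
#' @param channels Numeric matrix (or vector for one channel) with one
#'   column per channel; column names `f_main` (single-channel) or
#'   `f_sapphire`, `f_sirius`. All intensities must be >= 0.
#' @param setpoint Numeric setpoint track, degC, same length as `times`.
#' @param events Data frame with columns `time`, `label` (may be empty).
#' @param metadata Named list (ambient temperature, cell line, inhibitor,
#'   seed, ...).
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times, channels, setpoint,
                               events = data.frame(time = numeric(0),
                                                   label = character(0)),
                               metadata = list()) {
  if (is.null(dim(channels))) {
    channels <- matrix(channels, ncol = 1, dimnames = list(NULL, "f_main"))
  }
  channels <- as.matrix(channels)
  n <- length(times)
  if (nrow(channels) != n || length(setpoint) != n) {
    abort_validation("times, channels and setpoint must have equal length")
  }
  if (n < 2L || any(diff(times) <= 0)) {
    abort_validation("times must be strictly increasing")
  }
  if (any(!is.finite(channels)) || any(channels < 0)) {
    abort_validation("channel intensities must be finite and >= 0")
  }
  if (!ncol(channels) %in% c(1L, 2L)) {
    abort_validation("channels must have 1 or 2 columns")
  }
  if (is.null(colnames(channels))) {
    colnames(channels) <- if (ncol(channels) == 1L) "f_main" else c("f_sapphire", "f_sirius")
  }
  if (!is.data.frame(events)) abort_validation("events must be a data frame")
  if (nrow(events) && is.unsorted(events$time)) {
    events <- events[order(events$time), , drop = FALSE]
  }
  rownames(events) <- NULL
  structure(
    list(times = as.numeric(times), channels = channels,
         setpoint = as.numeric(setpoint), events = events,
         metadata = metadata),
    class = "fluorescence_trace"
  )
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat("<fluorescence_trace>\n")
  cat(sprintf("  %d samples, %.0f-%.0f s, channels: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(colnames(x$channels), collapse = ", ")))
  if (nrow(x$events)) {
    cat("  events:", paste(sprintf("%s@%.0fs", x$events$label, x$events$time),
                           collapse = ", "), "\n")
  }
  if (!is.null(x$metadata$cell_line)) cat("  cell line:", x$metadata$cell_line, "\n")
  invisible(x)
}

n_channels <- function(trace) ncol(trace$channels)

trace_dt <- function(trace) {
  dts <- diff(trace$times)
  stats::median(dts)
}

# time of the drug event: named label, or the first event whose label is not
# a calibration marker
drug_event_time <- function(trace, drug_event = NULL) {
  ev <- trace$events
  if (!nrow(ev)) return(NULL)
  if (!is.null(drug_event)) {
    hit <- ev$time[ev$label == drug_event]
    if (!length(hit)) abort_validation(sprintf("drug event '%s' not present", drug_event))
    return(hit[1L])
  }
  noncal <- ev[!grepl("^cal", ev$label), , drop = FALSE]
  if (!nrow(noncal)) return(NULL)
  noncal$time[1L]
}

first_cal_time <- function(trace) {
  ev <- trace$events
  cal <- ev$time[grepl("^cal", ev$label)]
  if (length(cal)) min(cal) else NULL
}

#' Render a single-channel MTY fluorescence trace from a scenario
#'
#' Evaluates the cuvette temperature under the scenario's Peltier protocol,
#' adds the ground-truth mitochondrial elevation, and renders MTY
#' fluorescence with the probe's linear (optionally mildly quadratic)
#' temperature response, photobleaching, optional post-drug leakage
#' artifact, and i.i.d. Gaussian noise with standard deviation
#' `noise_sd * gain`. During the terminal calibration staircase any
#' residual elevation rides on top of the imposed cuvette steps.
#'
#' @param scenario A [build_scenario()] object.
#' @param probe An [mty_probe()].
#' @param noise_sd Relative noise level (fraction of gain; >= 0).
#' @param seed Integer seed for the noise stream (`NULL` = current RNG).
#' @param dt Sampling interval, seconds.
#' @return A [fluorescence_trace()] with channel `f_main`.
#' @export
render_mty_trace <- function(scenario, probe, noise_sd = 0, seed = NULL, dt = 1) {
  if (!inherits(scenario, "thermal_scenario")) {
    abort_validation("scenario must be a thermal_scenario")
  }
  if (!inherits(probe, "mty_probe")) abort_validation("probe must be an mty_probe")
  if (!is_number(noise_sd) || noise_sd < 0) abort_validation("noise_sd must be >= 0")

  pelt <- build_peltier_trace(scenario$protocol, scenario$duration, dt)
  elev <- scenario$elevation(pelt$time)
  if (any(elev < -1e-9)) abort_validation("scenario elevation is negative")
  t_mito <- pelt$temperature + pmax(elev, 0)

  dT <- t_mito - probe$reference_temperature
  f <- probe$quench_factor * probe$gain *
    (1 - probe$relative_slope * dT - probe$quad_coeff * dT^2) *
    exp(-probe$bleach_rate * pelt$time) + probe$autofluorescence

  if (probe$leakage) {
    td <- drug_event_time_scenario(scenario)
    f <- f + probe$leak_rate * probe$gain * pmax(pelt$time - td, 0)
  }
  if (noise_sd > 0) {
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, noise_sd * probe$gain))
  }
  if (any(f < 0)) abort_validation("rendered intensity < 0: probe parameters unphysical")

  fluorescence_trace(
    times = pelt$time, channels = f, setpoint = pelt$setpoint,
    events = scenario$events,
    metadata = list(ambient = scenario$ambient, scenario = scenario$name,
                    cell_line = scenario$params$cell_line %||% NA,
                    inhibitor = scenario$params$drug %||% scenario$params$inhibitor %||% NA,
                    probe = "MTY", seed = seed, noise_sd = noise_sd,
                    truth_drop = scenario$truth_drop)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

drug_event_time_scenario <- function(scenario) {
  ev <- scenario$events
  noncal <- ev[!grepl("^cal", ev$label), , drop = FALSE]
  if (nrow(noncal)) noncal$time[1L] else 0
}

#' Render a two-channel mito-gTEMP fluorescence trace from a scenario
#'
#' Renders the mT-Sapphire (temperature-insensitive) and Sirius
#' (temperature-sensitive, strictly decreasing) channels per the
#' [gtemp_probe()] model, each with i.i.d. Gaussian noise of standard
#' deviation `noise_sd * expression`. With zero backgrounds the
#' Sapphire/Sirius ratio is affine in the sensed temperature and
#' independent of the expression level.
#'
#' @inheritParams render_mty_trace
#' @param probe A [gtemp_probe()].
#' @return A [fluorescence_trace()] with channels `f_sapphire`, `f_sirius`.
#' @export
render_gtemp_trace <- function(scenario, probe, noise_sd = 0, seed = NULL, dt = 1) {
  if (!inherits(scenario, "thermal_scenario")) {
    abort_validation("scenario must be a thermal_scenario")
  }
  if (!inherits(probe, "gtemp_probe")) abort_validation("probe must be a gtemp_probe")
  if (!is_number(noise_sd) || noise_sd < 0) abort_validation("noise_sd must be >= 0")

  pelt <- build_peltier_trace(scenario$protocol, scenario$duration, dt)
  elev <- scenario$elevation(pelt$time)
  if (any(elev < -1e-9)) abort_validation("scenario elevation is negative")
  t_mito <- pelt$temperature + pmax(elev, 0)

  dT <- t_mito - probe$reference_temperature
  denom <- 1 + probe$sirius_slope * dT
  if (any(denom <= 0)) abort_validation("temperature outside the probe's valid range")
  f_sap <- probe$expression * probe$sapphire_gain + probe$channel_backgrounds[["sapphire"]]
  f_sap <- rep(f_sap, length(dT))
  f_sir <- probe$expression / denom + probe$channel_backgrounds[["sirius"]]

  if (noise_sd > 0) {
    eps <- with_seed(seed, stats::rnorm(2L * length(dT), 0, noise_sd * probe$expression))
    f_sap <- f_sap + eps[seq_along(dT)]
    f_sir <- f_sir + eps[length(dT) + seq_along(dT)]
  }
  if (any(f_sap < 0) || any(f_sir < 0)) {
    abort_validation("rendered intensity < 0: probe parameters unphysical")
  }

  fluorescence_trace(
    times = pelt$time, channels = cbind(f_sapphire = f_sap, f_sirius = f_sir),
    setpoint = pelt$setpoint, events = scenario$events,
    metadata = list(ambient = scenario$ambient, scenario = scenario$name,
                    cell_line = scenario$params$cell_line %||% NA,
                    inhibitor = scenario$params$drug %||% scenario$params$inhibitor %||% NA,
                    probe = "GTEMP", seed = seed, noise_sd = noise_sd,
                    truth_drop = scenario$truth_drop)
  )
}

#' Render a cell-free two-channel blank, with or without a drug
#'
#' Used by the drug-background QC: the channels contain only the probe's
#' `channel_backgrounds`, plus the probe's `drug_background_shift` when
#' `drug = TRUE`, plus noise scaled to the background level.
#'
#' @param probe A [gtemp_probe()] whose `channel_backgrounds` are positive.
#' @param drug Apply the probe's `drug_background_shift`?
#' @param duration Record length, seconds.
#' @param noise_sd Relative noise (fraction of each channel's background).
#' @param seed Integer seed.
#' @param dt Sampling interval, seconds.
#' @return A two-channel [fluorescence_trace()] with `metadata$cell_free = TRUE`.
#' @export
render_gtemp_blank <- function(probe, drug = FALSE, duration = 300,
                               noise_sd = 0, seed = NULL, dt = 1) {
  if (!inherits(probe, "gtemp_probe")) abort_validation("probe must be a gtemp_probe")
  bg <- probe$channel_backgrounds
  if (any(bg <= 0)) abort_validation("blank rendering needs positive channel_backgrounds")
  shift <- if (isTRUE(drug)) probe$drug_background_shift else c(sapphire = 0, sirius = 0)
  times <- seq(0, duration, by = dt)
  n <- length(times)
  f_sap <- rep(bg[["sapphire"]] + shift[["sapphire"]], n)
  f_sir <- rep(bg[["sirius"]] + shift[["sirius"]], n)
  if (any(c(f_sap[1], f_sir[1]) <= 0)) {
    abort_validation("drug background shift drives a blank channel non-positive")
  }
  if (noise_sd > 0) {
    eps <- with_seed(seed, stats::rnorm(2L * n))
    f_sap <- f_sap + eps[seq_len(n)] * noise_sd * bg[["sapphire"]]
    f_sir <- f_sir + eps[n + seq_len(n)] * noise_sd * bg[["sirius"]]
  }
  if (any(f_sap < 0) || any(f_sir < 0)) abort_validation("rendered blank intensity < 0")
  fluorescence_trace(
    times = times, channels = cbind(f_sapphire = f_sap, f_sirius = f_sir),
    setpoint = rep(37, n),
    metadata = list(cell_free = TRUE, drug = drug, seed = seed, noise_sd = noise_sd)
  )
}
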