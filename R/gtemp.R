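#' Compute the mT-Sapphire/Sirius fluorescence ratio
#'
#' Elementwise ratio of the two channels. Samples where the Sirius
#' denominator falls below a floor (a fraction of that channel's median)
#' are masked (`NA`) and counted; if more than 10% of samples are masked
#' the denominator has collapsed and an error is raised.
#'
#' @param trace A two-channel [fluorescence_trace()].
#' @param floor_frac Sirius floor as a fraction of the channel median.
#' @return An object of class `ratio_series`: list with `times`, `ratio`
#'   (NA where masked) and `n_masked`.
#' @export
compute_ratio <- function(trace, floor_frac = 0.01) {
  if (!inherits(trace, "fluorescence_trace")) {
    abort_validation("trace must be a fluorescence_trace")
  }
  if (n_channels(trace) != 2L) {
    abort_validation("ratio requires a two-channel (mT-Sapphire, Sirius) trace")
  }
  sap <- trace$channels[, "f_sapphire"]
  sir <- trace$channels[, "f_sirius"]
  floor <- floor_frac * stats::median(sir)
  masked <- sir < floor
  if (mean(masked) > 0.10) abort_qc("denominator collapse: >10% of Sirius samples below floor")
  ratio <- sap / sir
  ratio[masked] <- NA_real_
  structure(list(times = trace$times, ratio = ratio, n_masked = sum(masked)),
            class = "ratio_series")
}

#' Drug-background compatibility check on cell-free blanks
#'
#' Some drugs fluoresce or quench at the recording wavelengths. A drug is
#' compatible with the ratiometric readout when the mean Sapphire/Sirius
#' ratio of a cell-free blank shifts by at most `ratio_tol` (relative)
#' upon drug addition — individual channels may shift as long as the ratio
#' is preserved (e.g. a proportional rise in both channels passes, while a
#' Sirius-specific shift fails).
#'
#' @param blank_with_drug,blank_without_drug Two-channel cell-free
#'   [fluorescence_trace()]s of equal duration.
#' @param ratio_tol Maximum tolerated relative mean-ratio shift.
#' @return List with `pass` (logical), `ratio_shift` (relative),
#'   `channel_shifts` (relative per-channel mean shifts), `ratio_tol`.
#' @export
check_drug_background <- function(blank_with_drug, blank_without_drug,
                                  ratio_tol = 0.02) {
  for (b in list(blank_with_drug, blank_without_drug)) {
    if (!inherits(b, "fluorescence_trace") || n_channels(b) != 2L) {
      abort_validation("blanks must be two-channel fluorescence traces")
    }
  }
  if (length(blank_with_drug$times) != length(blank_without_drug$times)) {
    abort_validation("blanks of unequal duration")
  }
  m_d <- colMeans(blank_with_drug$channels)
  m_0 <- colMeans(blank_without_drug$channels)
  r_d <- m_d[["f_sapphire"]] / m_d[["f_sirius"]]
  r_0 <- m_0[["f_sapphire"]] / m_0[["f_sirius"]]
  shift <- abs(r_d - r_0) / r_0
  list(pass = shift <= ratio_tol,
       ratio_shift = shift,
       channel_shifts = (m_d - m_0) / m_0,
       ratio_tol = ratio_tol)
}

#' Ratio calibration line
#'
#' Linear map from temperature to Sapphire/Sirius ratio,
#' `R = c0 + c1 * T`, valid over `calibrated_range` and invertible when
#' `c1 != 0`. The slope is expected positive: the ratio rises with
#' temperature because Sirius fluorescence falls.
#'
#' @param c0 Intercept (ratio units).
#' @param c1 Slope (ratio units per degC, non-zero for inversion).
#' @param calibrated_range Temperatures covered by the calibration, degC.
#' @param r_squared Fit quality.
#' @param n_replicates Number of pooled replicate staircases.
#' @return An object of class `ratio_calibration` (field `slope` aliases
#'   `c1` so shift estimation can consume either calibration type).
#' @export
ratio_calibration <- function(c0, c1, calibrated_range = c(30, 42),
                              r_squared = NA_real_, n_replicates = 1L) {
  stopifnot_number(c0, "c0")
  stopifnot_number(c1, "c1")
  if (c1 == 0) abort_validation("c1 = 0: calibration not invertible")
  if (calibrated_range[1] >= calibrated_range[2]) {
    abort_validation("calibrated_range must satisfy min < max")
  }
  structure(
    list(c0 = c0, c1 = c1, slope = c1, intercept = c0,
         calibrated_range = as.numeric(calibrated_range),
         r_squared = r_squared, n_replicates = n_replicates),
    class = "ratio_calibration"
  )
}

#' @export
print.ratio_calibration <- function(x, ...) {
  cat("<ratio_calibration>\n")
  cat(sprintf("  R = %.6g + %.6g * T over %.0f-%.0f degC (r^2 %s, %d replicate(s))\n",
              x$c0, x$c1, x$calibrated_range[1], x$calibrated_range[2],
              format(x$r_squared, digits = 4), x$n_replicates))
  invisible(x)
}

#' Fit the in-vivo ratio calibration from a staircase trace
#'
#' The calibration trace comes from oligomycin-treated cells (so residual
#' mitochondrial heat production is negligible and the probes sit at the
#' imposed cuvette temperature) stepped from 30 degC in 3 degC steps to
#' 42 degC. Each step is reduced to its ratio mean over the final
#' `averaging_window` seconds (after the equilibration discard) and the
#' means are regressed on imposed temperature by ordinary least squares.
#' UV photodamage limits the usable record: an analysis span of 35 min or
#' more is an error.
#'
#' @param trace A two-channel staircase [fluorescence_trace()] with
#'   calibration-step events.
#' @param equilibration_discard,averaging_window Seconds; see
#'   [segment_calibration_steps()].
#' @param max_span Photodamage limit on the staircase span, seconds.
#' @param min_interval Minimum step spacing before a diagnostic warning,
#'   seconds (the staircase protocol uses 3-min steps by design).
#' @return A [ratio_calibration()].
#' @export
fit_ratio_calibration <- function(trace, equilibration_discard = 120,
                                  averaging_window = 60, max_span = 35 * 60,
                                  min_interval = 180) {
  rs <- compute_ratio(trace)
  ev <- trace$events
  cal_times <- ev$time[grepl("^cal", ev$label)]
  if (length(cal_times) < 2L) abort_validation("staircase must contain >= 2 calibration steps")
  span <- max(trace$times) - min(cal_times)
  if (span >= max_span) abort_qc("photodamage window exceeded: staircase span >= 35 min")
  steps <- segment_calibration_steps(trace, equilibration_discard,
                                     averaging_window,
                                     min_interval = min_interval,
                                     series = rs$ratio)
  if (length(unique(steps$temperature)) < 2L) {
    abort_validation("singular design: < 2 distinct staircase temperatures")
  }
  fit <- stats::lm(value ~ temperature, data = steps)
  r2 <- rsq(steps$value, stats::fitted(fit))
  ratio_calibration(
    c0 = unname(stats::coef(fit)[[1L]]),
    c1 = unname(stats::coef(fit)[["temperature"]]),
    calibrated_range = range(steps$temperature),
    r_squared = r2, n_replicates = 1L
  )
}

#' Pool replicate ratio calibrations
#'
#' Averages coefficients across per-replicate fits (the default pooling);
#' `method = "pooled"` instead refits one line through all replicate step
#' points.
#'
#' @param fits List of [ratio_calibration()] objects (for `"average"`), or
#'   a list of step-point data frames (for `"pooled"`).
#' @param method `"average"` or `"pooled"`.
#' @return A [ratio_calibration()].
#' @export
pool_ratio_calibrations <- function(fits, method = c("average", "pooled")) {
  method <- match.arg(method)
  if (method == "average") {
    if (!length(fits)) abort_validation("no calibrations to pool")
    ratio_calibration(
      c0 = mean(vapply(fits, function(f) f$c0, numeric(1))),
      c1 = mean(vapply(fits, function(f) f$c1, numeric(1))),
      calibrated_range = range(vapply(fits, function(f) f$calibrated_range, numeric(2))),
      r_squared = mean(vapply(fits, function(f) f$r_squared, numeric(1))),
      n_replicates = length(fits)
    )
  } else {
    pts <- do.call(rbind, fits)
    fit <- stats::lm(value ~ temperature, data = pts)
    ratio_calibration(
      c0 = unname(stats::coef(fit)[[1L]]),
      c1 = unname(stats::coef(fit)[["temperature"]]),
      calibrated_range = range(pts$temperature),
      r_squared = rsq(pts$value, stats::fitted(fit)), n_replicates = length(fits)
    )
  }
}

#' Invert a ratio series to absolute mitochondrial temperature
#'
#' Applies the inverse calibration `T = (R - c0) / c1` sample by sample.
#' Temperatures outside the calibrated range are reported unchanged (never
#' clipped) but flagged in the `extrapolated` mask, mirroring the
#' dotted-line convention for extrapolated readings: the inference assumes
#' the linear ratio-temperature relation continues to hold there.
#'
#' @param ratio A `ratio_series` from [compute_ratio()], or a numeric
#'   ratio vector.
#' @param calibration A [ratio_calibration()].
#' @param times Time stamps when `ratio` is a bare numeric vector.
#' @return An object of class `temperature_trace`: list with `times`,
#'   `temperature` (degC), `extrapolated` (logical mask), `method`.
#' @export
infer_temperature_trace <- function(ratio, calibration, times = NULL) {
  if (!inherits(calibration, "ratio_calibration")) {
    abort_validation("calibration must be a ratio_calibration")
  }
  if (calibration$c1 == 0) abort_validation("c1 = 0: temperature non-identifiable")
  if (inherits(ratio, "ratio_series")) {
    times <- ratio$times
    r <- ratio$ratio
  } else {
    r <- as.numeric(ratio)
    if (is.null(times)) times <- seq_along(r) - 1
  }
  temp <- (r - calibration$c0) / calibration$c1
  rng <- calibration$calibrated_range
  extrap <- !is.na(temp) & (temp < rng[1] | temp > rng[2])
  structure(list(times = times, temperature = temp, extrapolated = extrap,
                 method = "GTEMP", calibration = calibration),
            class = "temperature_trace")
}

#' @export
print.temperature_trace <- function(x, ...) {
  ok <- is.finite(x$temperature)
  cat("<temperature_trace> GTEMP\n")
  cat(sprintf("  %d samples, %.1f-%.1f degC, %.1f%% extrapolated\n",
              length(x$times), min(x$temperature[ok]), max(x$temperature[ok]),
              100 * mean(x$extrapolated)))
  invisible(x)
}

#' Interval summaries of an inferred temperature trace
#'
#' Arithmetic mean and sample SD of the temperature samples in each
#' half-open interval `[start, end)` (minutes since the start of the
#' record), as used for reporting interval-averaged mitochondrial
#' temperatures.
#'
#' @param temps A `temperature_trace` from [infer_temperature_trace()].
#' @param intervals List of numeric `c(start_min, end_min)` pairs.
#' @return Data frame with columns `start_min`, `end_min`, `mean`, `sd`,
#'   `n`, `frac_extrapolated`.
#' @export
summarize_interval <- function(temps, intervals) {
  if (!inherits(temps, "temperature_trace")) {
    abort_validation("temps must be a temperature_trace")
  }
  if (!is.list(intervals)) intervals <- list(intervals)
  out <- data.frame(start_min = numeric(0), end_min = numeric(0),
                    mean = numeric(0), sd = numeric(0), n = integer(0),
                    frac_extrapolated = numeric(0))
  for (iv in intervals) {
    lo <- iv[1] * 60; hi <- iv[2] * 60
    if (hi <= lo) abort_validation("empty interval (end <= start)")
    if (lo < min(temps$times) || hi > max(temps$times) + 1) {
      abort_validation("interval extends beyond the record")
    }
    idx <- temps$times >= lo & temps$times < hi
    v <- temps$temperature[idx]
    v <- v[is.finite(v)]
    if (!length(v)) abort_validation("empty interval (no samples)")
    out <- rbind(out, data.frame(
      start_min = iv[1], end_min = iv[2], mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else NA_real_, n = length(v),
      frac_extrapolated = mean(temps$extrapolated[idx])
    ))
  }
  out
}
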