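#' Detect the onset of a fluorescence plateau
#'
#' Scans every sliding window of the requested duration and returns the
#' start time of the first window whose least-squares slope magnitude is
#' below `slope_tol` (the signal has "reached a stable value"). Returns
#' `NA` if no window qualifies.
#'
#' @param series Numeric intensity series (uniformly sampled).
#' @param window Window duration, seconds (> 0).
#' @param slope_tol Slope tolerance, AU per minute (> 0).
#' @param dt Sampling interval of `series`, seconds.
#' @param times Optional time stamps (overrides `dt`; must be uniform).
#' @return Plateau onset time in seconds (time of the first qualifying
#'   window's first sample, with the series starting at 0 when `times` is
#'   not given), or `NA_real_`.
#' @export
detect_plateau <- function(series, window = 300, slope_tol, dt = 1, times = NULL) {
  if (!is.null(times)) {
    if (length(times) != length(series)) abort_validation("times/series length mismatch")
    dt <- stats::median(diff(times))
  } else {
    times <- (seq_along(series) - 1) * dt
  }
  if (!is_number(window) || window <= 0) abort_validation("window must be > 0")
  if (!is_number(slope_tol) || slope_tol <= 0) abort_validation("slope_tol must be > 0")
  n <- as.integer(round(window / dt))
  if (n < 2L) abort_validation("window spans fewer than 2 samples")
  if (length(series) < n) abort_validation("series shorter than the plateau window")

  slopes <- rolling_slope(series, n, dt) * 60  # AU per minute
  ok <- which(abs(slopes) < slope_tol)
  if (!length(ok)) return(NA_real_)
  times[ok[1L]]
}

# OLS slope (AU per second) of every length-n window; value i corresponds to
# the window starting at sample i. Computed by convolution with the centred
# abscissa weights, which is algebraically identical to per-window lm().
rolling_slope <- function(y, n, dt) {
  x <- (seq_len(n) - 1) * dt
  w <- x - mean(x)
  sxx <- sum(w^2)
  # filter(..., sides = 1) at index i gives sum_k w_rev[k] * y[i - k + 1],
  # i.e. the window ending at i; shift so entry i is the window starting at i.
  ends <- stats::filter(y, rev(w), sides = 1) / sxx
  as.numeric(ends[seq(n, length(y))])
}

#' Screen a trace for post-drug stability
#'
#' A temperature-shift estimate is only meaningful once the post-drug
#' fluorescence has stabilised. The segment between the drug event and the
#' first calibration step (or end of record) is scanned with
#' [detect_plateau()]; the verdict is `FALSE` when no plateau is found —
#' e.g. a monotonically rising signal throughout a long record.
#'
#' @param trace A [fluorescence_trace()].
#' @param drug_event Event label of the drug addition (default: first
#'   non-calibration event).
#' @param min_span Minimum post-drug record required, seconds; a shorter
#'   record is an error ("insufficient post-drug record").
#' @param window Plateau window, seconds.
#' @param slope_tol Slope tolerance, AU/min; default 0.1% of the pre-drug
#'   baseline fluorescence per minute.
#' @param channel Channel index to screen (default 1).
#' @return A list with `stable` (logical), `plateau_onset` (seconds, or
#'   `NA`), `span` (seconds screened) and `slope_tol` used.
#' @export
check_stability <- function(trace, drug_event = NULL, min_span = 600,
                            window = 300, slope_tol = NULL, channel = 1L) {
  td <- drug_event_time(trace, drug_event)
  if (is.null(td)) abort_validation("no drug event present in trace")
  t_end <- first_cal_time(trace) %||% max(trace$times)
  span <- t_end - td
  if (span < min_span) abort_qc("insufficient post-drug record")
  y <- trace$channels[, channel]
  if (is.null(slope_tol)) {
    base_idx <- trace$times >= td - 60 & trace$times < td
    base <- if (any(base_idx)) mean(y[base_idx]) else mean(y[trace$times < td])
    slope_tol <- 0.001 * base
  }
  idx <- trace$times >= td & trace$times < t_end
  onset <- detect_plateau(y[idx], window = window, slope_tol = slope_tol,
                          dt = trace_dt(trace))
  list(stable = !is.na(onset),
       plateau_onset = if (is.na(onset)) NA_real_ else td + onset,
       span = span, slope_tol = slope_tol)
}

#' Segment the terminal calibration staircase into step means
#'
#' Each calibration step (event labels beginning `"cal"`) is reduced to one
#' point: the imposed temperature (from the setpoint track) and the mean
#' fluorescence over the final `averaging_window` seconds of the step,
#' after discarding the first `equilibration_discard` seconds of thermal
#' re-equilibration.
#'
#' @param trace A [fluorescence_trace()] (or any trace whose channel
#'   `channel` should be averaged; for ratio pipelines pass `series`).
#' @param equilibration_discard Seconds dropped at the start of each step.
#' @param averaging_window Seconds averaged at the end of each step.
#' @param min_interval Steps closer together than this (seconds) trigger a
#'   diagnostic warning; means are still computed.
#' @param channel Channel index.
#' @param series Optional numeric series to average instead of a channel
#'   (e.g. a fluorescence ratio); must align with `trace$times`.
#' @return A data frame with columns `temperature` (degC), `value` (mean
#'   AU or ratio), `n` (samples averaged); attribute `warnings` collects
#'   policy diagnostics.
#' @export
segment_calibration_steps <- function(trace, equilibration_discard = 120,
                                      averaging_window = 60,
                                      min_interval = 240, channel = 1L,
                                      series = NULL) {
  ev <- trace$events
  cal <- ev[grepl("^cal", ev$label), , drop = FALSE]
  if (nrow(cal) < 2L) abort_validation("trace must contain >= 2 calibration-step events")
  y <- if (is.null(series)) trace$channels[, channel] else series
  if (length(y) != length(trace$times)) abort_validation("series/trace length mismatch")

  diags <- character(0)
  gaps <- diff(cal$time)
  if (any(gaps < min_interval)) {
    msg <- sprintf("calibration steps spaced %.0f s, below the %.0f s minimum interval",
                   min(gaps), min_interval)
    diags <- c(diags, msg)
    warning(msg, call. = FALSE)
  }

  bounds <- c(cal$time, max(trace$times) + trace_dt(trace))
  out <- data.frame(temperature = numeric(0), value = numeric(0), n = integer(0))
  for (i in seq_len(nrow(cal))) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    win_lo <- max(t0 + equilibration_discard, t1 - averaging_window)
    idx <- trace$times >= win_lo & trace$times < t1
    if (!any(idx)) {  # step shorter than the discard: fall back to its tail
      idx <- trace$times >= t1 - averaging_window & trace$times < t1
      msg <- sprintf("calibration step %d shorter than the equilibration discard; averaged its final window", i)
      diags <- c(diags, msg)
      warning(msg, call. = FALSE)
    }
    seg_idx <- which(trace$times >= t0 & trace$times < t1)
    imposed <- trace$setpoint[seg_idx[length(seg_idx)]]
    out <- rbind(out, data.frame(temperature = imposed,
                                 value = mean(y[idx], na.rm = TRUE),
                                 n = sum(idx)))
  }
  if (length(unique(out$temperature)) < 2L) {
    abort_validation("calibration steps do not cover distinct setpoints")
  }
  attr(out, "warnings") <- diags
  out
}

#' Fit the internal step calibration line
#'
#' Ordinary least squares of step-mean fluorescence (or ratio) on imposed
#' temperature. For MTY the slope is expected to be negative; a
#' non-negative slope or r-squared below 0.9 marks the fit as suspicious
#' (flagged, never silently dropped).
#'
#' @param step_points Data frame with columns `temperature`, `value`
#'   (as returned by [segment_calibration_steps()]).
#' @return An object of class `calibration_fit` with fields `slope`
#'   (AU/degC), `intercept`, `r_squared`, `temperature_range`, `n_points`,
#'   `extrapolation_used`, `suspicious`.
#' @export
fit_step_calibration <- function(step_points) {
  if (!is.data.frame(step_points) || !all(c("temperature", "value") %in% names(step_points))) {
    abort_validation("step_points must have columns 'temperature' and 'value'")
  }
  if (nrow(step_points) < 2L) abort_validation("need >= 2 calibration points")
  if (length(unique(step_points$temperature)) < 2L) {
    abort_validation("singular design: all calibration temperatures identical")
  }
  fit <- stats::lm(value ~ temperature, data = step_points)
  r2 <- rsq(step_points$value, stats::fitted(fit))
  slope <- unname(stats::coef(fit)[["temperature"]])
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[[1L]]),
         r_squared = r2,
         temperature_range = range(step_points$temperature),
         n_points = nrow(step_points), extrapolation_used = FALSE,
         suspicious = slope >= 0 || r2 < 0.9),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>\n")
  cat(sprintf("  slope %.4g AU/degC, intercept %.4g, r^2 %.4f, %d points over %.1f-%.1f degC\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              x$temperature_range[1], x$temperature_range[2]))
  if (isTRUE(x$suspicious)) cat("  ** flagged suspicious (slope sign or poor fit)\n")
  invisible(x)
}

window_mean <- function(trace, window, channel = 1L) {
  idx <- trace$times >= window[1] & trace$times < window[2]
  if (!any(idx)) abort_validation("analysis window contains no samples")
  if (window[1] < min(trace$times) || window[2] > max(trace$times) + trace_dt(trace)) {
    abort_validation("analysis window extends beyond the record")
  }
  mean(trace$channels[idx, channel])
}

#' Estimate the mitochondrial temperature shift from an MTY trace
#'
#' Converts the fluorescence change between a baseline window and a
#' response window into degrees via the internal calibration:
#' `delta_t = (mean F_response - mean F_baseline) / slope`. Because MTY
#' fluorescence falls with temperature (negative slope), cooling — a
#' fluorescence *rise* — yields a negative `delta_t`; the magnitude is
#' what is reported as a "temperature decrease". The estimate carries the
#' post-drug stability verdict; an unstable trace is flagged
#' (`stable = FALSE`), not silently dropped.
#'
#' @param trace A single-channel [fluorescence_trace()].
#' @param fit A `calibration_fit`; if `NULL`, one is fitted from the
#'   trace's own calibration staircase.
#' @param baseline_window Numeric `c(start, end)` seconds; default the 60 s
#'   preceding the drug event.
#' @param response_window Numeric `c(start, end)` seconds; default the 60 s
#'   preceding the first calibration step.
#' @param drug_event Drug event label (default: first non-calibration event).
#' @param check Run [check_stability()]? (default `TRUE` when a drug event
#'   exists).
#' @param detrend Subtract a linear photobleaching trend, fitted to the
#'   pre-drug plateau (final 300 s before the drug) and extrapolated
#'   through the record, before converting? Default `FALSE` (no bleaching
#'   correction).
#' @return An object of class `temperature_shift` with fields `delta_t`,
#'   `magnitude`, `sd` (`NA` for a single trace), `method`, `windows`,
#'   `stable`, `fit`.
#' @export
estimate_temperature_shift <- function(trace, fit = NULL,
                                       baseline_window = NULL,
                                       response_window = NULL,
                                       drug_event = NULL, check = TRUE,
                                       detrend = FALSE) {
  td <- drug_event_time(trace, drug_event)
  tc <- first_cal_time(trace)
  if (isTRUE(detrend)) {
    if (is.null(td)) abort_validation("detrending needs a drug event to define the pre-drug plateau")
    pre <- trace$times >= td - 300 & trace$times < td
    if (sum(pre) < 10) abort_validation("pre-drug plateau too short to fit a bleaching trend")
    tf <- stats::lm(y ~ t, data = data.frame(y = trace$channels[pre, 1L],
                                             t = trace$times[pre]))
    drift <- unname(stats::coef(tf)[2L]) * (trace$times - td)
    trace$channels[, 1L] <- trace$channels[, 1L] - drift
  }
  if (is.null(baseline_window)) {
    if (is.null(td)) abort_validation("no drug event: supply baseline_window explicitly")
    baseline_window <- c(td - 60, td)
  }
  if (is.null(response_window)) {
    if (is.null(tc)) abort_validation("no calibration event: supply response_window explicitly")
    response_window <- c(tc - 60, tc)
  }
  if (is.null(fit)) {
    fit <- fit_step_calibration(segment_calibration_steps(trace))
  }
  if (!inherits(fit, "calibration_fit") && !inherits(fit, "ratio_calibration")) {
    abort_validation("fit must be a calibration_fit")
  }
  if (fit$slope == 0) abort_validation("zero calibration slope: shift non-identifiable")

  f_base <- window_mean(trace, baseline_window)
  f_resp <- window_mean(trace, response_window)
  delta_t <- (f_resp - f_base) / fit$slope

  stable <- NA
  if (isTRUE(check) && !is.null(td)) {
    stable <- tryCatch(check_stability(trace, drug_event = drug_event)$stable,
                       mitotherm_qc_error = function(e) NA)
  }
  structure(
    list(delta_t = delta_t, magnitude = abs(delta_t), sd = NA_real_,
         method = "MTY",
         windows = list(baseline = baseline_window, response = response_window),
         stable = stable, fit = fit),
    class = "temperature_shift"
  )
}

#' @export
print.temperature_shift <- function(x, ...) {
  cat("<temperature_shift>", x$method, "\n")
  dir <- if (is.na(x$delta_t)) "" else if (x$delta_t < 0) " (cooling)" else " (warming)"
  cat(sprintf("  delta_t %.3f degC%s, magnitude %.3f degC\n", x$delta_t, dir, x$magnitude))
  cat(sprintf("  stable: %s\n", format(x$stable)))
  invisible(x)
}

#' Quantify post-drug rewarming from an MTY trace
#'
#' In cells able to restore heat output (e.g. AOX-expressing cells after
#' respiratory-chain inhibition) the fluorescence reaches a peak (maximum
#' cooling) and then falls back as the mitochondria rewarm. The rewarming
#' at each requested timepoint is `(F_peak - F(t)) / |slope|`, zero before
#' the peak. The trace is smoothed with a running mean before the peak is
#' located, so the peak is not a noise excursion.
#'
#' @param trace A single-channel [fluorescence_trace()].
#' @param fit A `calibration_fit` (its `|slope|` converts AU to degC).
#' @param drug_event Drug event label (default: first non-calibration event).
#' @param timepoints Minutes after the drug event at which to evaluate
#'   rewarming; must fall before the calibration staircase.
#' @param smooth_window Running-mean window, seconds.
#' @return Data frame with columns `minutes`, `rewarming` (degC).
#' @export
quantify_rewarming <- function(trace, fit, drug_event = NULL, timepoints,
                               smooth_window = 60) {
  td <- drug_event_time(trace, drug_event)
  if (is.null(td)) abort_validation("no drug event present in trace")
  t_end <- first_cal_time(trace) %||% max(trace$times)
  idx <- which(trace$times >= td & trace$times < t_end)
  if (!length(idx)) abort_validation("no post-drug samples")
  if (fit$slope == 0) abort_validation("zero calibration slope")

  y <- trace$channels[idx, 1L]
  k <- max(1L, as.integer(round(smooth_window / trace_dt(trace))))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  pk <- which.max(ys)
  t_peak <- trace$times[idx][pk]
  f_peak <- ys[pk]

  out <- data.frame(minutes = timepoints, rewarming = NA_real_)
  for (i in seq_along(timepoints)) {
    tt <- td + timepoints[i] * 60
    if (tt > t_end) abort_validation("timepoint beyond the analysable post-drug record")
    if (tt <= t_peak) {
      out$rewarming[i] <- 0
    } else {
      j <- which.min(abs(trace$times[idx] - tt))
      out$rewarming[i] <- (f_peak - ys[j]) / abs(fit$slope)
    }
  }
  out
}
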