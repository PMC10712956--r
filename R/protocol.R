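#' Peltier temperature protocol
#'
#' Describes the programmed cuvette-jacket temperature: an initial setpoint,
#' an ordered sequence of setpoint changes, and a first-order lag time
#' constant with which the cuvette contents follow the jacket. The default
#' lag of 40 s gives ~2 min (about three time constants) to equilibrate
#' after a step, matching typical stirred-cuvette behaviour.
#'
#' @param initial_setpoint Initial setpoint in degrees C.
#' @param steps `NULL`, or a data frame with columns `time` (seconds,
#'   strictly increasing, non-negative) and `setpoint` (degrees C).
#' @param lag_time_constant First-order thermal lag, seconds (>= 0; 0 means
#'   the cuvette tracks the setpoint instantaneously).
#' @return An object of class `temperature_protocol`.
#' @examples
#' p <- temperature_protocol(37, data.frame(time = 600, setpoint = 40))
#' @export
temperature_protocol <- function(initial_setpoint, steps = NULL,
                                 lag_time_constant = 40) {
  stopifnot_number(initial_setpoint, "initial_setpoint", 0, 60)
  stopifnot_number(lag_time_constant, "lag_time_constant", 0)
  if (is.null(steps)) {
    steps <- data.frame(time = numeric(0), setpoint = numeric(0))
  }
  if (!is.data.frame(steps) || !all(c("time", "setpoint") %in% names(steps))) {
    abort_validation("steps must be a data frame with columns 'time' and 'setpoint'")
  }
  steps <- steps[, c("time", "setpoint"), drop = FALSE]
  if (nrow(steps)) {
    if (any(!is.finite(steps$time)) || any(steps$time < 0)) {
      abort_validation("step times must be finite and non-negative")
    }
    if (any(diff(steps$time) <= 0)) {
      abort_validation("step times must be strictly increasing")
    }
    if (any(steps$setpoint < 0 | steps$setpoint > 60)) {
      abort_validation("setpoints must lie within [0, 60] degrees C")
    }
  }
  structure(
    list(initial_setpoint = initial_setpoint, steps = steps,
         lag_time_constant = lag_time_constant),
    class = "temperature_protocol"
  )
}

#' @export
print.temperature_protocol <- function(x, ...) {
  cat("<temperature_protocol>\n")
  cat(sprintf("  initial setpoint: %.2f degC, lag tau: %.1f s, %d step(s)\n",
              x$initial_setpoint, x$lag_time_constant, nrow(x$steps)))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps))) {
      cat(sprintf("    t = %6.0f s -> %.2f degC\n",
                  x$steps$time[i], x$steps$setpoint[i]))
    }
  }
  invisible(x)
}

# Setpoint track sampled at given times (right-continuous: a step at t takes
# effect at samples >= t).
setpoint_at <- function(protocol, times) {
  sp <- rep(protocol$initial_setpoint, length(times))
  if (nrow(protocol$steps)) {
    for (i in seq_len(nrow(protocol$steps))) {
      sp[times >= protocol$steps$time[i]] <- protocol$steps$setpoint[i]
    }
  }
  sp
}

#' Simulate the cuvette temperature under a Peltier protocol
#'
#' First-order relaxation of the cuvette temperature toward the current
#' setpoint: within each constant-setpoint segment the exact exponential
#' solution `T(t) = sp + (T0 - sp) * exp(-(t - t0)/tau)` is evaluated at
#' every sample, so the trace is free of integration error for any `dt`.
#' With `lag_time_constant = 0` the output equals the setpoint track.
#'
#' @param protocol A [temperature_protocol()].
#' @param duration Record length in seconds; must cover all protocol steps.
#' @param dt Sampling interval in seconds (> 0; default 1 s, continuous
#'   fluorimeter acquisition).
#' @return A data frame with columns `time`, `setpoint`, `temperature`.
#' @examples
#' p <- temperature_protocol(37, data.frame(time = 0, setpoint = 40),
#'                           lag_time_constant = 60)
#' tr <- build_peltier_trace(p, duration = 300)
#' tr$temperature[tr$time == 120]  # 40 - 3*exp(-2)
#' @export
build_peltier_trace <- function(protocol, duration, dt = 1) {
  if (!inherits(protocol, "temperature_protocol")) {
    abort_validation("protocol must be a temperature_protocol")
  }
  if (!is_number(dt) || dt <= 0) abort_validation("dt must be a positive number")
  stopifnot_number(duration, "duration", 0)
  if (nrow(protocol$steps) && any(protocol$steps$time > duration)) {
    abort_validation("duration does not cover all protocol steps")
  }
  times <- seq(0, duration, by = dt)
  sp <- setpoint_at(protocol, times)
  tau <- protocol$lag_time_constant
  if (tau == 0) {
    temp <- sp
  } else {
    temp <- numeric(length(times))
    # segment boundaries: start of record plus each step time
    bounds <- c(0, protocol$steps$time, Inf)
    t0 <- 0
    T0 <- protocol$initial_setpoint
    for (seg in seq_len(length(bounds) - 1L)) {
      lo <- bounds[seg]
      hi <- bounds[seg + 1L]
      idx <- which(times >= lo & times < hi)
      seg_sp <- if (seg == 1L) protocol$initial_setpoint else protocol$steps$setpoint[seg - 1L]
      if (length(idx)) {
        temp[idx] <- seg_sp + (T0 - seg_sp) * exp(-(times[idx] - lo) / tau)
      }
      # state entering the next segment (continuous temperature)
      if (is.finite(hi)) T0 <- seg_sp + (T0 - seg_sp) * exp(-(hi - lo) / tau)
    }
  }
  data.frame(time = times, setpoint = sp, temperature = temp)
}
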