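#' Thermal scenario: ground-truth mitochondrial temperature trajectory
#'
#' A scenario couples a cuvette temperature protocol with a ground-truth
#' *elevation* trajectory `E(t)` — the number of degrees by which the
#' probe-sensed mitochondrial temperature exceeds the cuvette temperature —
#' plus the timed events (drug addition, substrate addition, calibration
#' steps) that the analysis pipelines key on. The probe senses
#' `T_mito(t) = T_cuvette(t) + E(t)`.
#'
#' `build_scenario()` constructs the named scenarios used throughout:
#'
#' * `baseline` — constant elevation, no perturbation.
#' * `inhibitor` — respiratory-chain/ATP-synthase inhibitor added after a
#'   baseline plateau; elevation decays exponentially to a residual
#'   (default 0, the calibration assumption that full inhibition abolishes
#'   mitochondrial heat output), followed by a terminal +3/-3 degC
#'   internal-calibration staircase.
#' * `starvation` — substrate-free incubation: elevation rises to a peak
#'   near 10 min, then declines slowly (~4 degC lower by 35 min).
#' * `substrate_rescue` — as starvation, but glucose/glutamine addition at
#'   10 min arrests the decline near the peak value.
#' * `bka` — adenine nucleotide translocase inhibition: slight transient
#'   rise then a minimal (~1 degC) decline.
#' * `aox_inhibitor` — AOX-expressing cells: fast initial cooling after the
#'   inhibitor, then gradual exponential rewarming toward the pre-drug
#'   elevation, with per-inhibitor presets (`rotenone`, `antimycin`, `kcn`),
#'   and a terminal calibration staircase late in the record.
#' * `anisomycin` — cytosolic protein-synthesis inhibition: a modest
#'   (~4 degC) transient Gaussian-shaped rise reverting over ~2-3 h.
#'
#' @param name Scenario label (one of the above).
#' @param params Named list overriding scenario defaults; common entries are
#'   `ambient` (degC), `initial_elevation` (degC), `drug_time` (s),
#'   `decay_tau` (s), `residual_elevation` (degC), `cal_time` (s),
#'   `cal_step` (degC), `cal_hold` (s), `duration` (s), `lag_time_constant`
#'   (s). Scenario-specific entries are documented in the package vignette.
#' @param protocol Optional [temperature_protocol()]; by default one is
#'   built from the scenario parameters (constant ambient, plus the
#'   calibration staircase where the scenario has one).
#' @return An object of class `thermal_scenario` with fields `name`,
#'   `ambient`, `elevation` (function of time, degC), `protocol`,
#'   `duration`, `events` (data frame `time`, `label`), `truth_drop`
#'   (configured elevation loss, degC) and `params`.
#' @examples
#' sc <- build_scenario("inhibitor", list(initial_elevation = 18))
#' sc$elevation(c(0, 1200))
#' @export
build_scenario <- function(name, params = list(), protocol = NULL) {
  known <- c("baseline", "inhibitor", "starvation", "substrate_rescue",
             "bka", "aox_inhibitor", "anisomycin")
  if (!is.character(name) || length(name) != 1L || !(name %in% known)) {
    abort_validation(sprintf("unknown scenario name; must be one of: %s",
                             paste(known, collapse = ", ")))
  }
  defaults <- scenario_defaults(name)
  p <- utils::modifyList(defaults, params)
  stopifnot_number(p$ambient, "ambient", 0, 60)
  stopifnot_number(p$initial_elevation, "initial_elevation", 0)
  if (!is.null(p$residual_elevation) && p$residual_elevation < 0) {
    abort_validation("negative elevation requested (residual_elevation < 0)")
  }

  built <- switch(
    name,
    baseline = scenario_baseline(p),
    inhibitor = scenario_inhibitor(p),
    starvation = scenario_starvation(p),
    substrate_rescue = scenario_substrate_rescue(p),
    bka = scenario_bka(p),
    aox_inhibitor = scenario_aox(p),
    anisomycin = scenario_anisomycin(p)
  )

  if (is.null(protocol)) protocol <- built$protocol
  ev <- built$events
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL

  structure(
    list(name = name, ambient = p$ambient, elevation = built$elevation,
         protocol = protocol, duration = built$duration, events = ev,
         truth_drop = built$truth_drop, params = p),
    class = "thermal_scenario"
  )
}

#' @export
print.thermal_scenario <- function(x, ...) {
  cat("<thermal_scenario>", x$name, "\n")
  cat(sprintf("  ambient %.1f degC, duration %.0f s, truth_drop %.2f degC\n",
              x$ambient, x$duration, x$truth_drop))
  if (nrow(x$events)) {
    cat("  events:", paste(sprintf("%s@%.0fs", x$events$label, x$events$time),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

scenario_defaults <- function(name) {
  base <- list(
    ambient = 37, initial_elevation = 18, lag_time_constant = 40,
    drug_time = 600, cal_step = 3, cal_hold = 360
  )
  extra <- switch(
    name,
    baseline = list(duration = 1800),
    inhibitor = list(drug = "oligomycin", residual_elevation = 0,
                     decay_tau = 180, cal_time = 2100),
    starvation = list(initial_elevation = 0, peak_elevation = 16.5,
                      rise_tau = 150, peak_time = 600, decline = 4,
                      decline_span = 1500, duration = 2160),
    substrate_rescue = list(initial_elevation = 0, peak_elevation = 18,
                            rise_tau = 120, substrate_time = 600,
                            settle = 2, settle_tau = 400, duration = 2160),
    bka = list(initial_elevation = 0, peak_elevation = 16.5, rise_tau = 150,
               drug_time = 660, drug = "bka", bump = 0.8, bump_tau = 300,
               decline = 1, decline_tau = 600, duration = 2160),
    aox_inhibitor = list(inhibitor = "rotenone", cal_time = 5400,
                         peak_lag = 600),
    anisomycin = list(initial_elevation = 16.5, drug_time = 0,
                      bump = 4, bump_time = 3600, bump_sd = 1500,
                      duration = 10800)
  )
  utils::modifyList(base, extra)
}

flat_protocol <- function(p, duration) {
  temperature_protocol(p$ambient, lag_time_constant = p$lag_time_constant)
}

# terminal +step / -step calibration staircase appended to a protocol
staircase_protocol <- function(p, cal_time, duration) {
  steps <- data.frame(
    time = c(cal_time, cal_time + p$cal_hold),
    setpoint = c(p$ambient + p$cal_step, p$ambient - p$cal_step)
  )
  temperature_protocol(p$ambient, steps, lag_time_constant = p$lag_time_constant)
}

cal_events <- function(p, cal_time) {
  data.frame(time = c(cal_time, cal_time + p$cal_hold),
             label = c("cal_up", "cal_down"))
}

scenario_baseline <- function(p) {
  e0 <- p$initial_elevation
  list(elevation = function(t) rep(e0, length(t)),
       protocol = flat_protocol(p, p$duration),
       duration = p$duration,
       events = data.frame(time = numeric(0), label = character(0)),
       truth_drop = 0)
}

scenario_inhibitor <- function(p) {
  e0 <- p$initial_elevation
  res <- p$residual_elevation
  if (res > e0) abort_validation("residual_elevation exceeds initial_elevation")
  td <- p$drug_time
  tau <- p$decay_tau
  duration <- if (is.null(p$duration)) p$cal_time + 2 * p$cal_hold else p$duration
  elev <- function(t) {
    ifelse(t < td, e0, res + (e0 - res) * exp(-(t - td) / tau))
  }
  list(elevation = elev,
       protocol = staircase_protocol(p, p$cal_time, duration),
       duration = duration,
       events = rbind(data.frame(time = td, label = p$drug),
                      cal_events(p, p$cal_time)),
       truth_drop = e0 - res)
}

scenario_starvation <- function(p) {
  pe <- p$peak_elevation
  tp <- p$peak_time
  rate <- p$decline / p$decline_span
  e_tp <- pe * (1 - exp(-tp / p$rise_tau))
  elev <- function(t) {
    ifelse(t <= tp,
           pe * (1 - exp(-t / p$rise_tau)),
           pmax(0, e_tp - rate * (t - tp)))
  }
  list(elevation = elev, protocol = flat_protocol(p, p$duration),
       duration = p$duration,
       events = data.frame(time = 0, label = "resuspension"),
       truth_drop = p$decline)
}

scenario_substrate_rescue <- function(p) {
  pe <- p$peak_elevation
  ts <- p$substrate_time
  e_ts <- pe * (1 - exp(-ts / p$rise_tau))
  floor_e <- e_ts - p$settle
  elev <- function(t) {
    ifelse(t <= ts,
           pe * (1 - exp(-t / p$rise_tau)),
           floor_e + p$settle * exp(-(t - ts) / p$settle_tau))
  }
  list(elevation = elev, protocol = flat_protocol(p, p$duration),
       duration = p$duration,
       events = data.frame(time = ts, label = "substrate"),
       truth_drop = p$settle)
}

scenario_bka <- function(p) {
  pe <- p$peak_elevation
  td <- p$drug_time
  e_td <- pe * (1 - exp(-td / p$rise_tau))
  elev <- function(t) {
    base <- pe * (1 - exp(-pmin(t, td) / p$rise_tau))
    post <- (t >= td) * (p$bump * exp(-(pmax(t, td) - td) / p$bump_tau) -
                           p$decline * (1 - exp(-(pmax(t, td) - td) / p$decline_tau)))
    pmax(0, base + post)
  }
  list(elevation = elev, protocol = flat_protocol(p, p$duration),
       duration = p$duration,
       events = data.frame(time = td, label = p$drug),
       truth_drop = p$decline)
}

aox_presets <- function() {
  list(
    rotenone = list(drop = 10, cool_tau = 120, rewarm_tau = 1800, rewarm_frac = 1),
    antimycin = list(drop = 5, cool_tau = 90, rewarm_tau = 1200, rewarm_frac = 0.8),
    kcn = list(drop = 6, cool_tau = 90, rewarm_tau = 1500, rewarm_frac = 0.7)
  )
}

scenario_aox <- function(p) {
  presets <- aox_presets()
  if (!p$inhibitor %in% names(presets)) {
    abort_validation(sprintf("unknown aox_inhibitor preset '%s'", p$inhibitor))
  }
  k <- utils::modifyList(presets[[p$inhibitor]],
                         p[intersect(names(p),
                                     c("drop", "cool_tau", "rewarm_tau", "rewarm_frac"))])
  e0 <- p$initial_elevation
  if (k$drop > e0) abort_validation("negative elevation requested (drop exceeds initial elevation)")
  td <- p$drug_time
  tpk <- td + p$peak_lag
  drop_eff <- k$drop * (1 - exp(-p$peak_lag / k$cool_tau))
  duration <- if (is.null(p$duration)) p$cal_time + 2 * p$cal_hold else p$duration
  elev <- function(t) {
    cool <- e0 - k$drop * (1 - exp(-(t - td) / k$cool_tau))
    rewarm <- e0 - drop_eff * ((1 - k$rewarm_frac) +
                                 k$rewarm_frac * exp(-(t - tpk) / k$rewarm_tau))
    ifelse(t < td, e0, ifelse(t < tpk, cool, rewarm))
  }
  list(elevation = elev,
       protocol = staircase_protocol(p, p$cal_time, duration),
       duration = duration,
       events = rbind(data.frame(time = td, label = p$inhibitor),
                      cal_events(p, p$cal_time)),
       truth_drop = k$drop)
}

scenario_anisomycin <- function(p) {
  e0 <- p$initial_elevation
  elev <- function(t) {
    e0 + p$bump * exp(-(t - p$bump_time)^2 / (2 * p$bump_sd^2))
  }
  list(elevation = elev, protocol = flat_protocol(p, p$duration),
       duration = p$duration,
       events = data.frame(time = p$drug_time, label = "anisomycin"),
       truth_drop = 0)
}

#' Default in-vivo gTEMP calibration staircase scenario
#'
#' The calibration protocol applied to oligomycin-treated cells: after a
#' settling period at ambient the cuvette is shifted to a base temperature
#' (default 30 degC) and then raised in 3 degC steps to 42 degC. The first
#' hold is longer (default 300 s) because the initial large downshift takes
#' longer to equilibrate than the subsequent 3 degC steps; each later step
#' lasts 180 s so that the "final minute after a 2-min discard" averaging
#' window is the step's third minute. The ground-truth elevation is zero
#' throughout (full ATP-synthase inhibition abolishes mitochondrial heat
#' output), so the probes report the imposed cuvette temperature.
#'
#' @param ambient Starting setpoint, degC.
#' @param base_temp First staircase temperature, degC.
#' @param top_temp Last staircase temperature, degC.
#' @param step Step size, degC.
#' @param settle Seconds at ambient before the staircase.
#' @param first_hold Hold at `base_temp`, seconds.
#' @param hold Hold at each subsequent step, seconds.
#' @param lag_time_constant Cuvette thermal lag, seconds.
#' @return A `thermal_scenario` whose events mark every staircase step.
#' @export
gtemp_calibration_scenario <- function(ambient = 38, base_temp = 30,
                                       top_temp = 42, step = 3,
                                       settle = 600, first_hold = 300,
                                       hold = 180, lag_time_constant = 40) {
  temps <- seq(base_temp, top_temp, by = step)
  times <- settle + c(0, first_hold + (seq_along(temps[-1]) - 1) * hold)
  duration <- times[length(times)] + hold
  protocol <- temperature_protocol(
    ambient, data.frame(time = times, setpoint = temps),
    lag_time_constant = lag_time_constant
  )
  events <- data.frame(time = times,
                       label = sprintf("cal_step_%g", temps))
  structure(
    list(name = "gtemp_calibration", ambient = ambient,
         elevation = function(t) rep(0, length(t)),
         protocol = protocol, duration = duration, events = events,
         truth_drop = 0,
         params = list(ambient = ambient, temps = temps,
                       first_hold = first_hold, hold = hold)),
    class = "thermal_scenario"
  )
}
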