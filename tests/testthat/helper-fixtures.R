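# Shared fixtures: idealised (zero-lag) protocols isolate the inference
# algebra; default protocols exercise the realistic thermal lag.

default_mty_probe <- function(...) mty_probe(...)

default_gtemp_probe <- function(...) gtemp_probe(...)

# oligomycin scenario with a long post-drug record so the exponential
# elevation tail is numerically extinct at the response window
ideal_inhibitor_scenario <- function(drop = 18, tau = 120, ...) {
  build_scenario("inhibitor", utils::modifyList(
    list(initial_elevation = drop, residual_elevation = 0, decay_tau = tau,
         cal_time = 4800, lag_time_constant = 0),
    list(...)
  ))
}

# gTEMP calibration staircase rendered without thermal lag
ideal_calibration_trace <- function(probe = default_gtemp_probe(),
                                    noise_sd = 0, seed = NULL) {
  sc <- gtemp_calibration_scenario(lag_time_constant = 0)
  render_gtemp_trace(sc, probe, noise_sd = noise_sd, seed = seed)
}

# brute-force sliding-window regression: scans every window with lm()
oracle_plateau <- function(series, window, slope_tol, dt = 1) {
  n <- as.integer(round(window / dt))
  times <- (seq_along(series) - 1) * dt
  for (i in seq_len(length(series) - n + 1L)) {
    y <- series[i:(i + n - 1L)]
    x <- times[i:(i + n - 1L)]
    sl <- unname(coef(lm(y ~ x))[2L]) * 60
    if (abs(sl) < slope_tol) return(times[i])
  }
  NA_real_
}

# from-scratch one-way ANOVA F via between/within sums of squares
oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- length(groups) - 1L
  df_w <- length(all_v) - length(groups)
  (ss_between / df_b) / (ss_within / df_w)
}
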