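test_that("plateau detection matches a brute-force every-window regression oracle", {
  # constant series: plateau at the very first window
  expect_equal(detect_plateau(rep(5, 500), window = 100, slope_tol = 0.1), 0)

  # strict ramp well above tolerance: no plateau
  expect_true(is.na(detect_plateau(0.1 * (0:499), window = 100,
                                   slope_tol = 0.1 * 60 / 10)))

  # saturating exponential: onset agrees with the oracle
  tau <- 150
  y <- 1 - exp(-(0:1999) / tau)
  for (tol in c(0.5, 0.05, 0.005)) {
    got <- detect_plateau(y, window = 300, slope_tol = tol)
    want <- oracle_plateau(y, window = 300, slope_tol = tol)
    expect_equal(got, want)
  }

  # noisy series up to 1e4 samples, several windows
  set.seed(42)
  y2 <- c(cumsum(rnorm(3000, 0.01, 0.02)), rnorm(7000, 30, 0.02))
  for (w in c(120, 300)) {
    expect_equal(detect_plateau(y2, window = w, slope_tol = 0.05),
                 oracle_plateau(y2, window = w, slope_tol = 0.05))
  }

  expect_error(detect_plateau(rep(1, 10), window = 100, slope_tol = 1),
               "shorter")
})

test_that("stability screening accepts plateaus and rejects drifting records", {
  # S2-style behaviour: fluorescence still rising hours after the drug
  pr <- mty_probe(leakage = TRUE, leak_rate = 5e-5)
  sc <- build_scenario("inhibitor", list(cal_time = 7800))
  drifting <- render_mty_trace(sc, pr, noise_sd = 0)
  expect_false(check_stability(drifting)$stable)

  # signal reaching and holding a plateau
  stable_tr <- render_mty_trace(build_scenario("inhibitor"), mty_probe(),
                                noise_sd = 0)
  verdict <- check_stability(stable_tr)
  expect_true(verdict$stable)
  expect_gt(verdict$plateau_onset, 600)

  # drug too close to the end of the record
  short <- build_scenario("inhibitor", list(drug_time = 1990, cal_time = 2100))
  short_tr <- render_mty_trace(short, mty_probe(), noise_sd = 0)
  expect_error(check_stability(short_tr), "insufficient post-drug record",
               class = "mitotherm_qc_error")
})

test_that("calibration step segmentation recovers generator step means", {
  pr <- mty_probe(gain = 1000, relative_slope = 0.025, autofluorescence = 50)
  sc <- ideal_inhibitor_scenario()
  tr <- render_mty_trace(sc, pr, noise_sd = 0)
  steps <- segment_calibration_steps(tr)
  expect_equal(steps$temperature, c(40, 34))
  # zero-noise means lie exactly on the generator line (elevation extinct)
  expect_equal(steps$value, 1000 * (1 - 0.025 * (steps$temperature - 37)) + 50,
               tolerance = 1e-9)

  # steps spaced closer than the 4-min policy: warning, means still computed
  tight <- build_scenario("inhibitor", list(cal_hold = 120, cal_time = 2100,
                                            lag_time_constant = 0))
  tight_tr <- render_mty_trace(tight, mty_probe(), noise_sd = 0)
  w <- capture_warnings(steps2 <- segment_calibration_steps(tight_tr))
  expect_match(w, "minimum interval", all = FALSE)
  expect_equal(nrow(steps2), 2L)

  # no calibration events at all
  flat <- render_mty_trace(build_scenario("baseline"), mty_probe(), 0)
  expect_error(segment_calibration_steps(flat), "calibration-step events")
})

test_that("step calibration OLS equals the closed form and flags degenerate input", {
  # collinear zero-noise points: slope is exactly -gain * relative_slope
  pr <- mty_probe(gain = 800, relative_slope = 0.02, autofluorescence = 10)
  temps <- c(34, 37, 40)
  pts <- data.frame(temperature = temps,
                    value = 800 * (1 - 0.02 * (temps - 37)) + 10)
  fit <- fit_step_calibration(pts)
  expect_equal(fit$slope, -800 * 0.02, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_false(fit$suspicious)

  # two points: interpolating line
  fit2 <- fit_step_calibration(data.frame(temperature = c(34, 40),
                                          value = c(550, 430)))
  expect_equal(fit2$slope, -20)
  expect_equal(fit2$r_squared, 1)

  # noisy points: OLS matches lm closed form
  set.seed(7)
  noisy <- data.frame(temperature = c(31, 34, 37, 40, 43),
                      value = 600 - 12 * c(31, 34, 37, 40, 43) + rnorm(5, 0, 4))
  fitn <- fit_step_calibration(noisy)
  ref <- lm(value ~ temperature, noisy)
  expect_equal(fitn$slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(fitn$intercept, unname(coef(ref)[1]), tolerance = 1e-12)

  expect_error(fit_step_calibration(data.frame(temperature = c(37, 37),
                                               value = c(500, 510))),
               "singular")
  # positive slope is flagged suspicious, not dropped
  sus <- fit_step_calibration(data.frame(temperature = c(34, 40),
                                         value = c(430, 550)))
  expect_true(sus$suspicious)
})

test_that("temperature shift conversion: sign, arithmetic and invariances", {
  # hand arithmetic: baseline 500, response 530, slope -10 => -3 degC
  times <- 0:999
  f <- c(rep(500, 500), rep(530, 500))
  tr <- fluorescence_trace(times, f, rep(37, 1000),
                           events = data.frame(time = 500, label = "drug"))
  fit <- structure(list(slope = -10, intercept = 900, r_squared = 1,
                        temperature_range = c(34, 40), n_points = 2,
                        extrapolation_used = FALSE, suspicious = FALSE),
                   class = "calibration_fit")
  est <- estimate_temperature_shift(tr, fit, baseline_window = c(400, 500),
                                    response_window = c(900, 1000),
                                    check = FALSE)
  expect_equal(est$delta_t, -3)
  expect_equal(est$magnitude, 3)

  # response = baseline => zero shift
  est0 <- estimate_temperature_shift(tr, fit, baseline_window = c(100, 200),
                                     response_window = c(300, 400),
                                     check = FALSE)
  expect_equal(est0$delta_t, 0)

  zero_fit <- fit; zero_fit$slope <- 0
  expect_error(estimate_temperature_shift(tr, zero_fit,
                                          baseline_window = c(400, 500),
                                          response_window = c(900, 1000),
                                          check = FALSE),
               "non-identifiable")

  # gain and offset invariance: the internal calibration cancels both
  sc <- ideal_inhibitor_scenario()
  base_tr <- render_mty_trace(sc, mty_probe(), noise_sd = 0)
  est_base <- estimate_temperature_shift(base_tr)
  for (tweak in list(function(x) 3.7 * x, function(x) x + 250)) {
    mod <- base_tr
    mod$channels[, 1] <- tweak(mod$channels[, 1])
    est_mod <- estimate_temperature_shift(mod)
    expect_equal(est_mod$delta_t, est_base$delta_t, tolerance = 1e-9)
  }
})

test_that("zero-noise round trip recovers truth_drop; recovery is monotone in the drop", {
  mags <- vapply(c(6, 12, 18), function(drop) {
    sc <- ideal_inhibitor_scenario(drop = drop)
    tr <- render_mty_trace(sc, mty_probe(), noise_sd = 0)
    est <- estimate_temperature_shift(tr)
    expect_equal(est$magnitude, drop, tolerance = 1e-6)
    expect_true(est$stable)
    expect_lt(est$delta_t, 0)  # cooling
    est$magnitude
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("rewarming quantification tracks the generator's elevation recovery", {
  # calibrate late in the record, once the rewarming drift is negligible,
  # so the staircase points are not biased by a still-changing elevation
  sc <- build_scenario("aox_inhibitor", list(inhibitor = "rotenone",
                                             cal_time = 9000))
  noise_sd <- 0.005
  tr <- render_mty_trace(sc, mty_probe(), noise_sd = noise_sd, seed = 21)
  fit <- fit_step_calibration(segment_calibration_steps(tr))
  tps <- c(20, 40, 60, 75)
  rw <- quantify_rewarming(tr, fit, timepoints = tps)

  elev <- sc$elevation
  peak_e <- min(elev(seq(600, 9000, by = 1)))
  truth <- pmax(0, elev(600 + tps * 60) - peak_e)
  # recovered curve within 3x the per-window noise SD (in degC)
  noise_c <- noise_sd * 1000 / sqrt(60) / abs(fit$slope)
  expect_true(all(abs(rw$rewarming - truth) < pmax(3 * noise_c, 0.15)))
  expect_true(all(diff(rw$rewarming) > 0))

  # a trace that holds its peak plateau shows zero rewarming
  hold <- ideal_inhibitor_scenario()
  tr2 <- render_mty_trace(hold, mty_probe(), noise_sd = 0)
  fit2 <- fit_step_calibration(segment_calibration_steps(tr2))
  rw2 <- quantify_rewarming(tr2, fit2, timepoints = c(30, 50, 65))
  expect_true(all(rw2$rewarming < 0.01))
})

test_that("optional bleaching detrend restores the zero-noise round trip", {
  # with mild bleaching and no correction the estimate is biased low; the
  # pre-drug linear detrend (an approximation to the multiplicative decay)
  # brings it closer to the truth
  sc <- ideal_inhibitor_scenario()
  pr <- mty_probe(bleach_rate = 5e-6)
  tr <- render_mty_trace(sc, pr, noise_sd = 0)
  raw <- estimate_temperature_shift(tr, check = FALSE)
  corrected <- estimate_temperature_shift(tr, check = FALSE, detrend = TRUE)
  expect_lt(raw$magnitude, 17.9)
  expect_lt(abs(corrected$magnitude - 18), abs(raw$magnitude - 18))
})
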