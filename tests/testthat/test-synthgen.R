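test_that("Peltier trace follows the first-order step response exactly", {
  # zero lag: output equals the setpoint track sample for sample
  p0 <- temperature_protocol(37, data.frame(time = 0, setpoint = 40),
                             lag_time_constant = 0)
  tr0 <- build_peltier_trace(p0, 300)
  expect_identical(tr0$temperature, tr0$setpoint)

  # closed-form relaxation: T(120) = 40 - 3 exp(-2) for tau = 60 s
  p1 <- temperature_protocol(37, data.frame(time = 0, setpoint = 40),
                             lag_time_constant = 60)
  tr1 <- build_peltier_trace(p1, 300)
  expect_equal(tr1$temperature[tr1$time == 120], 40 - 3 * exp(-2),
               tolerance = 1e-12)
  # closed form at every sample, not just one
  expect_equal(tr1$temperature, 40 - 3 * exp(-tr1$time / 60), tolerance = 1e-12)

  # constant setpoint stays at equilibrium
  pc <- temperature_protocol(37)
  trc <- build_peltier_trace(pc, 600)
  expect_true(all(trc$temperature == 37))

  # convergence: monotone approach, within 0.05 degC once equilibrated (~5 tau)
  p2 <- temperature_protocol(37, data.frame(time = 100, setpoint = 40),
                             lag_time_constant = 40)
  tr2 <- build_peltier_trace(p2, 600)
  post <- tr2$temperature[tr2$time >= 100]
  expect_true(all(diff(post) > 0))
  expect_lt(abs(tr2$temperature[tr2$time == 100 + 5 * 40] - 40), 0.05)

  expect_error(build_peltier_trace(p2, 50), "cover")
  expect_error(build_peltier_trace(p2, 600, dt = -1), "dt")
  expect_error(temperature_protocol(37, data.frame(time = c(10, 10),
                                                   setpoint = c(40, 34))),
               "strictly increasing")
  expect_error(temperature_protocol(70), class = "mitotherm_validation_error")
})

test_that("scenario elevation trajectories match their configured kinetics", {
  # inhibitor: >96% of the drop complete 10 min after the drug
  sc <- build_scenario("inhibitor", list(initial_elevation = 18,
                                         residual_elevation = 0,
                                         decay_tau = 180))
  td <- sc$events$time[sc$events$label == "oligomycin"]
  expect_equal(sc$elevation(td + 600), 18 * exp(-600 / 180), tolerance = 1e-12)
  expect_lt(sc$elevation(td + 600), 0.7)
  expect_equal(sc$truth_drop, 18)

  # starvation: peak near 10 min, ~4 degC lower at 35 min
  st <- build_scenario("starvation")
  tgrid <- seq(0, 2100, by = 1)
  e <- st$elevation(tgrid)
  t_peak <- tgrid[which.max(e)]
  expect_lt(abs(t_peak - 600), 60)
  expect_equal(max(e) - st$elevation(2100), 4, tolerance = 0.01)

  # aox rotenone preset: monotone rewarming toward the initial elevation
  ax <- build_scenario("aox_inhibitor", list(inhibitor = "rotenone"))
  t_rewarm <- seq(1300, 5300, by = 10)
  e_r <- ax$elevation(t_rewarm)
  expect_true(all(diff(e_r) > 0))
  expect_true(all(e_r < ax$elevation(0)))
  # most of the recovery happens over 40-70 min
  expect_gt(ax$elevation(1200 + 70 * 60) - min(e_r), 0.8 * (18 - min(e_r)))

  expect_error(build_scenario("unknown_thing"), "scenario name")
  expect_error(build_scenario("inhibitor", list(residual_elevation = -1)),
               "negative elevation")
})

test_that("rendered MTY fluorescence is a decreasing affine map of temperature", {
  pr <- mty_probe(gain = 1000, relative_slope = 0.025)
  sc <- build_scenario("baseline", list(initial_elevation = 10,
                                        lag_time_constant = 0))
  tr <- render_mty_trace(sc, pr, noise_sd = 0)
  # static input: constant fluorescence at the closed-form level
  expected <- 1000 * (1 - 0.025 * (47 - 37)) + 50
  expect_true(all(abs(tr$channels[, 1] - expected) < 1e-9))

  # a +3 degC step moves fluorescence by -gain * slope * 3
  pr2 <- mty_probe(gain = 100, relative_slope = 0.01, autofluorescence = 0)
  p <- temperature_protocol(37, data.frame(time = 300, setpoint = 40),
                            lag_time_constant = 0)
  sc2 <- build_scenario("baseline", list(initial_elevation = 0), protocol = p)
  tr2 <- render_mty_trace(sc2, pr2, noise_sd = 0)
  f_before <- unname(tr2$channels[tr2$times == 299, 1])
  f_after <- unname(tr2$channels[tr2$times == 400, 1])
  expect_equal(f_after - f_before, -100 * 0.01 * 3, tolerance = 1e-12)

  # finite-difference slope against temperature equals -gain * slope
  ramp <- temperature_protocol(30, data.frame(time = 1:20 * 30,
                                              setpoint = 30 + (1:20) * 0.5),
                               lag_time_constant = 0)
  sc3 <- build_scenario("baseline",
                        list(initial_elevation = 0, ambient = 30, duration = 660),
                        protocol = ramp)
  tr3 <- render_mty_trace(sc3, pr, noise_sd = 0)
  means <- tapply(tr3$channels[, 1], tr3$setpoint, mean)
  slopes <- diff(as.numeric(means)) / diff(as.numeric(names(means)))
  expect_equal(slopes, rep(-1000 * 0.025, length(slopes)), tolerance = 1e-9)
  expect_true(all(diff(as.numeric(means)) < 0))
})

test_that("MTY leakage artifact rises without bound and defeats stability screening", {
  pr <- mty_probe(leakage = TRUE, leak_rate = 5e-5)
  sc <- build_scenario("inhibitor", list(cal_time = 7800))  # ~2 h post drug
  tr <- render_mty_trace(sc, pr, noise_sd = 0)
  td <- 600
  post <- tr$channels[tr$times > td + 1800 & tr$times < 7800, 1]
  expect_true(all(diff(post) > 0))
  expect_false(check_stability(tr)$stable)
})

test_that("gTEMP rendering: ratio is expression-invariant, affine in temperature", {
  sc <- build_scenario("baseline", list(initial_elevation = 10,
                                        lag_time_constant = 0))
  p1 <- gtemp_probe(expression = 1000)
  p2 <- gtemp_probe(expression = 2000)
  t1 <- render_gtemp_trace(sc, p1, 0)
  t2 <- render_gtemp_trace(sc, p2, 0)
  r1 <- compute_ratio(t1)$ratio
  r2 <- compute_ratio(t2)$ratio
  expect_equal(r1, r2, tolerance = 1e-12)

  # +3 degC: Sirius falls, Sapphire unchanged, ratio rises
  p <- temperature_protocol(37, data.frame(time = 300, setpoint = 40),
                            lag_time_constant = 0)
  scs <- build_scenario("baseline", list(initial_elevation = 0), protocol = p)
  tr <- render_gtemp_trace(scs, p1, 0)
  i0 <- tr$times == 299; i1 <- tr$times == 400
  expect_lt(tr$channels[i1, "f_sirius"], tr$channels[i0, "f_sirius"])
  expect_equal(tr$channels[i1, "f_sapphire"], tr$channels[i0, "f_sapphire"])
  rr <- compute_ratio(tr)$ratio
  expect_gt(rr[i1], rr[i0])

  # zero-noise round trip through the matching closed-form calibration
  # recovers the sensed temperature to machine precision
  sc2 <- build_scenario("starvation", list(lag_time_constant = 0))
  tr2 <- render_gtemp_trace(sc2, p1, 0)
  temps <- infer_temperature_trace(compute_ratio(tr2),
                                   ratio_calibration_from_probe(p1))
  truth <- 37 + sc2$elevation(tr2$times)
  expect_equal(temps$temperature, truth, tolerance = 1e-12)
})

test_that("trace rendering is seed-deterministic", {
  sc <- build_scenario("inhibitor")
  pr <- mty_probe()
  a <- render_mty_trace(sc, pr, 0.01, seed = 11)
  b <- render_mty_trace(sc, pr, 0.01, seed = 11)
  c <- render_mty_trace(sc, pr, 0.01, seed = 12)
  expect_identical(a$channels, b$channels)
  expect_gt(max(abs(a$channels - c$channels)), 1)

  gp <- gtemp_probe()
  ga <- render_gtemp_trace(sc, gp, 0.01, seed = 5)
  gb <- render_gtemp_trace(sc, gp, 0.01, seed = 5)
  expect_identical(ga$channels, gb$channels)

  # seeding does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(render_mty_trace(sc, pr, 0.01, seed = 7)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("fractionation simulator reproduces configured retentions", {
  # limit case: all label in the pellet
  e0 <- simulate_fractionation(1, 1, autofluorescence = c(
    mitoplast_pellet = 0, om_ims_supernatant = 0, smp_pellet = 0,
    matrix_supernatant = 0), noise_sd = 0, n_trials = 1)
  r0 <- recovery_proportions(e0)
  expect_equal(r0$mean_percent, c(100, 100))

  # retention 0.92 with autofluorescence, zero noise: exactly 92%
  e1 <- simulate_fractionation(0.92, 0.9, noise_sd = 0, n_trials = 2)
  r1 <- recovery_proportions(e1)
  expect_equal(r1$mean_percent[r1$split == "mitoplast"], 92, tolerance = 1e-12)
  expect_equal(r1$mean_percent[r1$split == "smp"], 90, tolerance = 1e-12)

  expect_error(simulate_fractionation(1.2, 0.9), "\\[0, 1\\]")
})
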