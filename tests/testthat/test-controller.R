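test_that("control branches follow the reference decision structure", {
  cfg <- controller_config(p_max = 50, delta_p = 5)
  st <- init_controller(cfg, 10)
  # fist intent inside the band: pressurize
  s <- control_step(st, 1, cfg)
  expect_true(s$command$pump1_pressurize)
  expect_false(s$command$pump2_vacuum)
  expect_equal(s$state$mode, "pressurizing")
  # fist intent at or above the ceiling: vacuum (bang-bang)
  s2 <- control_step(update_pressure(st, 50), 1, cfg)
  expect_true(s2$command$pump2_vacuum)
  expect_false(s2$command$pump1_pressurize)
  # rest intent: no pump (hold behavior)
  s3 <- control_step(update_pressure(st, 30), 0, cfg)
  expect_false(s3$command$pump1_pressurize || s3$command$pump2_vacuum)
  expect_false(s3$command$vent_valve)
  # rest with vent behavior opens the vent
  cfg_v <- controller_config(rest_behavior = "vent")
  st_v <- init_controller(cfg_v, 10)
  expect_true(control_step(update_pressure(st_v, 30), 0,
                           cfg_v)$command$vent_valve)
  expect_error(control_step(st, 2, cfg), "s_t")
  expect_error(pump_command(TRUE, TRUE), "never")
})

test_that("safety venting triggers within one step and absorbs until reset", {
  cfg <- controller_config(p_max = 50, delta_p = 5)
  st <- init_controller(cfg, 10)
  spiked <- update_pressure(st, 55)
  s <- control_step(spiked, 1, cfg)
  expect_true(s$command$vent_valve)
  expect_false(s$command$pump1_pressurize || s$command$pump2_vacuum)
  expect_equal(s$state$mode, "vented_stopped")
  # absorbing: further steps command nothing
  s2 <- control_step(s$state, 1, cfg)
  expect_false(s2$command$pump1_pressurize || s2$command$pump2_vacuum ||
                 s2$command$vent_valve)
  expect_equal(s2$state$mode, "vented_stopped")
  # reset re-derives p_min from the reading and is idempotent
  r <- reset_controller(s$state, sensor_reading = 4, config = cfg)
  expect_equal(r$mode, "idle")
  expect_equal(r$p_min, 4)
  expect_equal(reset_controller(r, sensor_reading = 4, config = cfg), r)
  # below p_min: vent stabilization without stopping
  low <- control_step(update_pressure(st, 5), 0, cfg)
  expect_true(low$command$vent_valve)
  expect_false(low$state$mode == "vented_stopped")
})

test_that("the plant follows its recurrence exactly", {
  pp <- plant_params(gain = 2, leak_rate = 0, sensor_noise_sd = 0)
  # equilibrium: all-off at ambient stays put
  expect_equal(plant_step(0, pump_command(), pp)$pressure, 0)
  # pressurize n steps with no leak: start + n * gain
  p <- 3
  for (i in 1:7) p <- plant_step(p, pump_command(pump1_pressurize = TRUE),
                                 pp)$pressure
  expect_equal(p, 3 + 7 * 2)
  # vent relaxes monotonically toward ambient
  p <- 40; prev <- p
  for (i in 1:30) {
    p <- plant_step(p, pump_command(vent_valve = TRUE), pp)$pressure
    expect_lt(p, prev + 1e-12)
    prev <- p
  }
  expect_lt(p, 0.1)
  # leak pulls toward ambient from both sides
  lp <- plant_params(gain = 2, leak_rate = 0.5)
  expect_equal(plant_step(10, pump_command(), lp)$pressure, 9.5)
  expect_equal(plant_step(-10, pump_command(), lp)$pressure, -9.5)
})

test_that("ten thousand random-intent steps never co-activate pumps nor escape the safety envelope", {
  cfg <- controller_config(p_max = 50, delta_p = 5)
  pp <- plant_params(gain = 2, leak_rate = 0.1, sensor_noise_sd = 0)
  set.seed(606)
  state <- init_controller(cfg, 0)
  pressure <- 0
  n_steps <- 0L
  while (n_steps < 10000L) {
    n_steps <- n_steps + 1L
    s_t <- sample(0:1, 1)
    step <- control_step(state, s_t, cfg)
    expect_false(step$command$pump1_pressurize && step$command$pump2_vacuum)
    pl <- plant_step(pressure, step$command, pp)
    pressure <- pl$pressure
    # noise-free: pressure can never exceed p_max + gain
    expect_lte(pressure, cfg$p_max + pp$gain)
    state <- update_pressure(step$state, pl$reading)
    if (state$mode == "vented_stopped")
      state <- reset_controller(state, pl$reading, cfg)
  }
})

test_that("constant fist intent climbs into the bang-bang band around the ceiling", {
  cfg <- controller_config(p_max = 50, delta_p = 5)
  pp <- plant_params(gain = 2)
  state <- init_controller(cfg, 0)
  pressure <- 0
  traj <- numeric(0)
  for (i in 1:60) {
    step <- control_step(state, 1, cfg)
    pl <- plant_step(pressure, step$command, pp)
    # liveness: strictly increasing until the band is reached
    if (max(traj, 0) < cfg$p_max) expect_gt(pl$pressure, pressure - 1e-9)
    pressure <- pl$pressure
    traj <- c(traj, pressure)
    state <- update_pressure(step$state, pl$reading)
  }
  tail_band <- traj[31:60]
  expect_true(all(tail_band >= cfg$p_max - pp$gain - cfg$delta_p))
  expect_true(all(tail_band <= cfg$p_max + pp$gain))
  # it oscillates rather than sticking
  expect_gt(stats::sd(tail_band), 0)
})

test_that("closed-loop sessions behave per intent under a trained decoder", {
  dec <- get_trained_decoder()
  cfg <- controller_config(p_max = 20, delta_p = 2)
  pp <- plant_params(gain = 2)
  rest_traj <- simulate_session(dec, class_feature_stream("rest", 30), cfg,
                                pp, seed = 1)
  expect_lt(mean(rest_traj$s_t), 0.2)
  expect_true(all(rest_traj$pressure <= pp$gain + 1e-9))
  fist_traj <- simulate_session(dec, class_feature_stream("fist", 40), cfg,
                                pp, seed = 1)
  expect_gt(mean(fist_traj$s_t), 0.8)
  expect_gt(max(fist_traj$pressure), cfg$p_max - pp$gain - cfg$delta_p)
  expect_true(all(fist_traj$pressure <= cfg$p_max + pp$gain))
  expect_false(any(fist_traj$pump1 & fist_traj$pump2))
  # a forced spike above p_max vents and stops within one step
  cfg_fixed <- controller_config(p_max = 20, delta_p = 2, p_min = 0)
  spike <- simulate_session(dec, class_feature_stream("fist", 10), cfg_fixed,
                            pp, seed = 1,
                            initial_pressure = cfg_fixed$p_max + 5)
  # the very first step sees the over-pressure reading and must vent + stop
  expect_equal(spike$mode[1], "vented_stopped")
  expect_true(spike$vent[1])
  expect_false(spike$pump1[1] || spike$pump2[1])
  expect_equal(nrow(spike), 1)          # session terminates at the stop
})
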