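#' Pneumatic controller configuration
#'
#' Pressure limits and step size of the discrete-time glove controller.
#' `p_max` is the pre-defined safety ceiling; `p_min` defaults to the first
#' sensor reading at initialization (and after a reset). One controller
#' step corresponds to one decoder epoch hop (0.25 s). Units are kPa by
#' simulator convention.
#'
#' @param p_max maximum allowed pressure (kPa).
#' @param delta_p commanded pressure step per cycle (kPa, > 0).
#' @param p_min optional explicit lower limit; `NULL` = take the first
#'   sensor reading.
#' @param rest_behavior what the rest branch does: `"hold"` (pumps off,
#'   passive leak only) or `"vent"` (open the vent valve).
#' @param threshold decision threshold on `P(fist)` for intent decoding.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(p_max = 50, delta_p = 5, p_min = NULL,
                              rest_behavior = c("hold", "vent"),
                              threshold = 0.5) {
  stopifnot_scalar(p_max, "p_max")
  stopifnot_scalar(delta_p, "delta_p")
  if (delta_p <= 0) stop("`delta_p` must be positive", call. = FALSE)
  if (!is.null(p_min)) {
    stopifnot_scalar(p_min, "p_min")
    if (p_min >= p_max) stop("need p_min < p_max", call. = FALSE)
  }
  structure(list(p_max = p_max, delta_p = delta_p, p_min = p_min,
                 rest_behavior = match.arg(rest_behavior),
                 threshold = threshold),
            class = "controller_config")
}

#' Pump command
#'
#' On/off states of the two pumps (pressurize / vacuum) and the vent valve.
#' The two pumps are never commanded on together.
#'
#' @param pump1_pressurize,pump2_vacuum,vent_valve logical.
#' @return An object of class `pump_command`.
#' @export
pump_command <- function(pump1_pressurize = FALSE, pump2_vacuum = FALSE,
                         vent_valve = FALSE) {
  if (isTRUE(pump1_pressurize) && isTRUE(pump2_vacuum))
    stop("pump1 and pump2 must never be on in the same step", call. = FALSE)
  structure(list(pump1_pressurize = isTRUE(pump1_pressurize),
                 pump2_vacuum = isTRUE(pump2_vacuum),
                 vent_valve = isTRUE(vent_valve)),
            class = "pump_command")
}

#' Initialize the controller state from the first sensor reading
#'
#' Sets the current pressure and (unless fixed in the configuration) the
#' lower limit `p_min` to the initial reading, entering idle mode.
#'
#' @param config a [controller_config()].
#' @param sensor_reading first pressure-sensor reading (kPa).
#' @return An object of class `controller_state` with fields `p_t`,
#'   `p_min`, `mode`, `last_command`.
#' @export
init_controller <- function(config, sensor_reading = 0) {
  stopifnot(inherits(config, "controller_config"))
  stopifnot_scalar(sensor_reading, "sensor_reading")
  p_min <- config$p_min %||% sensor_reading
  if (p_min >= config$p_max)
    stop("initial reading leaves no room below p_max", call. = FALSE)
  structure(list(p_t = sensor_reading, p_min = p_min, mode = "idle",
                 last_command = pump_command()),
            class = "controller_state")
}

#' Record a new sensor reading in the controller state
#' @param state a `controller_state`.
#' @param sensor_reading latest pressure reading (kPa).
#' @return The updated state.
#' @export
update_pressure <- function(state, sensor_reading) {
  stopifnot(inherits(state, "controller_state"))
  stopifnot_scalar(sensor_reading, "sensor_reading")
  state$p_t <- sensor_reading
  state
}

#' One controller step
#'
#' The decision logic of the closed loop, exactly as the reference
#' procedure: on fist intent (`s_t = 1`) with `p_min < p_t < p_max` the
#' pressurizing pump runs; at or above `p_max` the vacuum pump runs
#' (bang-bang regulation around the ceiling); on rest intent the pressure
#' is held (or vented, per configuration). A safety check layered after the
#' branch then vents and stops the system if `p_t > p_max` (an absorbing
#' stop until [reset_controller()]) and opens the vent to stabilize if
#' `p_t < p_min`.
#'
#' @param state a `controller_state` (see [init_controller()]).
#' @param s_t decoded intent, 0 (rest) or 1 (fist).
#' @param config a [controller_config()].
#' @return List with `command` (a [pump_command()]) and the updated `state`.
#' @export
control_step <- function(state, s_t, config) {
  stopifnot(inherits(state, "controller_state"),
            inherits(config, "controller_config"))
  if (!(length(s_t) == 1L && s_t %in% c(0, 1)))
    stop("`s_t` must be 0 or 1", call. = FALSE)
  if (state$mode == "vented_stopped") {
    cmd <- pump_command()
    state$last_command <- cmd
    return(list(command = cmd, state = state))
  }
  p_t <- state$p_t
  if (s_t == 1) {
    # the lower bound is inclusive: p_min is initialized from the first
    # sensor reading, so a strict inequality would deadlock the very first
    # step of every session
    if (p_t < config$p_max && p_t >= state$p_min) {
      cmd <- pump_command(pump1_pressurize = TRUE)   # pressurize to close
      state$mode <- "pressurizing"
    } else if (p_t >= config$p_max) {
      cmd <- pump_command(pump2_vacuum = TRUE)       # vacuum to open
      state$mode <- "vacuuming"
    } else {                                         # p_t <= p_min
      cmd <- pump_command()
      state$mode <- "idle"
    }
  } else {
    # rest: maintain (pumps off) or vent, per configuration
    cmd <- pump_command(vent_valve = config$rest_behavior == "vent")
    state$mode <- "idle"
  }
  # safety check, layered after the branch
  if (p_t > config$p_max) {
    cmd <- pump_command(vent_valve = TRUE)
    state$mode <- "vented_stopped"
  } else if (p_t < state$p_min) {
    cmd <- pump_command(pump1_pressurize = cmd$pump1_pressurize,
                        pump2_vacuum = FALSE, vent_valve = TRUE)
  }
  state$last_command <- cmd
  list(command = cmd, state = state)
}

#' Pneumatic plant parameters
#'
#' First-order stand-in for pumps, tubing, and sensor: each step a running
#' pump changes the pressure by `gain`, a leak pulls it toward ambient by
#' `leak_rate`, an open vent relaxes it exponentially toward ambient with
#' time constant `vent_tau` steps, and the sensor adds Gaussian noise.
#'
#' @param gain kPa per step of pump action.
#' @param leak_rate kPa per step toward ambient.
#' @param sensor_noise_sd standard deviation of sensor noise (kPa).
#' @param ambient ambient pressure (kPa, gauge 0 by convention).
#' @param vent_tau vent relaxation time constant in steps.
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(gain = 2, leak_rate = 0, sensor_noise_sd = 0,
                         ambient = 0, vent_tau = 2) {
  for (nm in c("gain", "leak_rate", "sensor_noise_sd", "ambient", "vent_tau"))
    stopifnot_scalar(get(nm), nm)
  if (leak_rate < 0 || sensor_noise_sd < 0 || vent_tau <= 0)
    stop("invalid plant parameters", call. = FALSE)
  structure(list(gain = gain, leak_rate = leak_rate,
                 sensor_noise_sd = sensor_noise_sd, ambient = ambient,
                 vent_tau = vent_tau),
            class = "plant_params")
}

#' One plant step
#'
#' @param pressure current true pressure (kPa).
#' @param command a [pump_command()].
#' @param params a [plant_params()].
#' @return List with `pressure` (new true pressure) and `reading` (noisy
#'   sensor value); noise is drawn from the current RNG stream.
#' @export
plant_step <- function(pressure, command, params) {
  stopifnot(inherits(command, "pump_command"), inherits(params, "plant_params"))
  stopifnot_scalar(pressure, "pressure")
  if (command$vent_valve) {
    pressure <- params$ambient +
      (pressure - params$ambient) * exp(-1 / params$vent_tau)
  }
  pressure <- pressure +
    params$gain * (command$pump1_pressurize - command$pump2_vacuum)
  if (params$leak_rate > 0 && pressure != params$ambient) {
    adj <- min(params$leak_rate, abs(pressure - params$ambient))
    pressure <- pressure - adj * sign(pressure - params$ambient)
  }
  reading <- pressure +
    if (params$sensor_noise_sd > 0) stats::rnorm(1, 0, params$sensor_noise_sd)
    else 0
  list(pressure = pressure, reading = reading)
}

#' Reset the controller after a safety stop
#'
#' Returns an idle state with the current sensor reading as both the
#' pressure and (per the initialization rule) the new lower limit.
#'
#' @param state a `controller_state`.
#' @param sensor_reading current sensor reading (kPa).
#' @param config the [controller_config()] in force.
#' @return A fresh idle `controller_state`.
#' @export
reset_controller <- function(state, sensor_reading = state$p_t,
                             config = controller_config()) {
  init_controller(config, sensor_reading)
}

#' Simulate a closed-loop rehabilitation session
#'
#' Alternates intent decoding, the controller step, and the plant step over
#' a stream of spectral features, logging the full trajectory. The loop
#' terminates at stream end or when the safety stop absorbs the controller.
#'
#' @param decoder trained [mi_decoder()].
#' @param feature_stream list of `spectral_feature`s, or an `n x 44 x 16`
#'   array of raw magnitudes.
#' @param config a [controller_config()].
#' @param params a [plant_params()].
#' @param seed RNG seed for sensor noise.
#' @param initial_pressure starting true pressure (defaults to ambient).
#' @return Data frame with one row per executed step: `step`, `s_t`,
#'   `p_fist`, `pump1`, `pump2`, `vent`, `pressure`, `sensor_reading`,
#'   `mode`.
#' @export
simulate_session <- function(decoder, feature_stream,
                             config = controller_config(),
                             params = plant_params(), seed = 1L,
                             initial_pressure = params$ambient) {
  stopifnot(inherits(decoder, "mi_decoder"))
  if (is.array(feature_stream) && length(dim(feature_stream)) == 3L)
    feature_stream <- lapply(seq_len(dim(feature_stream)[1]),
                             function(i) feature_stream[i, , ])
  if (!length(feature_stream)) stop("empty feature stream", call. = FALSE)
  with_seed(seed, {
    pressure <- initial_pressure
    state <- init_controller(config, pressure)
    rows <- vector("list", length(feature_stream))
    for (t in seq_along(feature_stream)) {
      dec <- decode_intent(decoder, feature_stream[[t]], config$threshold)
      step <- control_step(state, dec$s_t, config)
      state <- step$state
      pl <- plant_step(pressure, step$command, params)
      pressure <- pl$pressure
      state <- update_pressure(state, pl$reading)
      rows[[t]] <- data.frame(
        step = t, s_t = dec$s_t, p_fist = dec$probabilities[["fist"]],
        pump1 = step$command$pump1_pressurize,
        pump2 = step$command$pump2_vacuum,
        vent = step$command$vent_valve,
        pressure = pressure, sensor_reading = pl$reading,
        mode = state$mode, stringsAsFactors = FALSE)
      if (state$mode == "vented_stopped") {
        rows <- rows[seq_len(t)]
        break
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
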