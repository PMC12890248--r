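#' Trial parameters for the wheel stopping task
#'
#' Bundles the physics of a single trial: how fast the segment rotates, how
#' large the visible segment is, and how braking decelerates the wheel.
#' A trial is won when the segment comes to rest overlapping the red break
#' zone.
#'
#' @param speed Angular speed in radians per time unit; must be positive.
#' @param segment_fraction Dimensionless value in (0, 1] encoding segment
#'   size. A *greater* value represents a *smaller* visible segment: the
#'   drawn angular width is `(1 - segment_fraction) * 2 * pi * base_width`.
#' @param deceleration_increment Angular deceleration in radians per time
#'   unit squared. In multi-press mode each press adds one increment of
#'   braking strength; in single-press mode it is the (single) deceleration
#'   applied after the press. Derived from `stopping_angle` when omitted in
#'   single-press mode.
#' @param stopping_angle Radians the segment travels after the brake press
#'   in single-press mode. A stopping angle of `pi/2` means the segment
#'   stops a quarter of a rotation after the press.
#' @param brake_mode `"single"` or `"multi"`.
#' @param break_zone Numeric length-2 vector `c(start, width)` in radians
#'   giving the break-zone arc; width must lie in (0, 2*pi).
#' @param base_width Base angular width scale for the segment, as a fraction
#'   of the full circle (default 0.5, so `segment_fraction = 0.5` draws a
#'   segment of `0.5 * pi` radians).
#'
#' @return An object of class `wheel_trial_params` (a named list).
#' @export
#' @examples
#' wheel_trial_params(speed = 2, segment_fraction = 0.7,
#'                    stopping_angle = pi / 2, brake_mode = "single")
wheel_trial_params <- function(speed,
                               segment_fraction,
                               deceleration_increment = NULL,
                               stopping_angle = NULL,
                               brake_mode = c("multi", "single"),
                               break_zone = c(0, pi / 4),
                               base_width = 0.5) {
  brake_mode <- match.arg(brake_mode)
  stopifnot(is.numeric(speed), length(speed) == 1L)
  if (speed <= 0) stop("`speed` must be positive.", call. = FALSE)
  if (segment_fraction <= 0 || segment_fraction > 1) {
    stop("`segment_fraction` must lie in (0, 1].", call. = FALSE)
  }
  if (length(break_zone) != 2L || break_zone[2] <= 0 || break_zone[2] >= 2 * pi) {
    stop("`break_zone` must be c(start, width) with width in (0, 2*pi).",
         call. = FALSE)
  }
  if (brake_mode == "single") {
    if (is.null(stopping_angle) && is.null(deceleration_increment)) {
      stop("single-press mode needs `stopping_angle` or `deceleration_increment`.",
           call. = FALSE)
    }
    if (!is.null(stopping_angle) && stopping_angle <= 0) {
      stop("`stopping_angle` must be positive.", call. = FALSE)
    }
    if (is.null(deceleration_increment)) {
      deceleration_increment <-
        deceleration_increment_single_press(speed, stopping_angle)
    }
  }
  if (is.null(deceleration_increment) || deceleration_increment <= 0) {
    stop("`deceleration_increment` must be positive.", call. = FALSE)
  }
  structure(
    list(
      speed = speed,
      segment_fraction = segment_fraction,
      deceleration_increment = deceleration_increment,
      stopping_angle = stopping_angle,
      brake_mode = brake_mode,
      break_zone = break_zone,
      base_width = base_width
    ),
    class = "wheel_trial_params"
  )
}

#' Single-press deceleration increment
#'
#' The deceleration increment assigned to a single-press trial given its
#' rotation speed and stopping angle: `sqrt(speed) / (2 * stopping_angle)`.
#' Note that under constant-deceleration kinematics this value does not make
#' the segment travel exactly `stopping_angle` after the press; use
#' [required_deceleration()] for the deceleration that enforces the
#' stopping-angle semantics. Both are exposed; the engine's default
#' single-press mode uses the latter.
#'
#' @param speed Angular speed (> 0), radians per time unit.
#' @param stopping_angle Radians travelled after the press (> 0).
#' @return Angular deceleration, radians per time unit squared.
#' @export
#' @examples
#' deceleration_increment_single_press(1, pi / 2)  # 1/pi
deceleration_increment_single_press <- function(speed, stopping_angle) {
  if (any(speed <= 0)) stop("`speed` must be positive.", call. = FALSE)
  if (any(stopping_angle <= 0)) {
    stop("`stopping_angle` must be positive.", call. = FALSE)
  }
  sqrt(speed) / (2 * stopping_angle)
}

#' Deceleration that stops the wheel after a given angle
#'
#' Constant deceleration such that a wheel rotating at `speed` comes to rest
#' exactly `stopping_angle` radians after the brake press:
#' `speed^2 / (2 * stopping_angle)`.
#'
#' @inheritParams deceleration_increment_single_press
#' @return Angular deceleration, radians per time unit squared.
#' @export
required_deceleration <- function(speed, stopping_angle) {
  if (any(speed <= 0)) stop("`speed` must be positive.", call. = FALSE)
  if (any(stopping_angle <= 0)) {
    stop("`stopping_angle` must be positive.", call. = FALSE)
  }
  speed^2 / (2 * stopping_angle)
}

#' Stopping distance under constant deceleration
#'
#' Closed-form angular distance travelled from the brake press until rest:
#' `speed^2 / (2 * deceleration)`.
#'
#' @param speed Angular speed at the press (>= 0).
#' @param deceleration Constant angular deceleration (> 0).
#' @return Radians travelled after the press.
#' @export
#' @examples
#' stop_distance(1, 1 / pi)  # pi/2: a quarter rotation
stop_distance <- function(speed, deceleration) {
  if (any(speed < 0)) stop("`speed` must be non-negative.", call. = FALSE)
  if (any(deceleration <= 0)) {
    stop("`deceleration` must be positive.", call. = FALSE)
  }
  speed^2 / (2 * deceleration)
}

normalize_angle <- function(theta) theta %% (2 * pi)

segment_width <- function(params) {
  (1 - params$segment_fraction) * 2 * pi * params$base_width
}

#' Did the stopped segment win the trial?
#'
#' A trial is won when the resting segment's arc overlaps the break zone.
#' The segment is centred on `stop_position` with angular width
#' `(1 - segment_fraction) * 2 * pi * base_width`; a zero-width segment is
#' treated as the point at its centre. With `criterion = "center"` the
#' segment centre itself must fall inside the zone.
#'
#' @param stop_position Resting angle of the segment centre, radians in
#'   `[0, 2*pi)` (normalized internally).
#' @param params A [wheel_trial_params()] object.
#' @param criterion `"overlap"` (default) or `"center"`.
#' @return Logical.
#' @export
trial_outcome <- function(stop_position, params,
                          criterion = c("overlap", "center")) {
  criterion <- match.arg(criterion)
  seg_w <- if (criterion == "center") 0 else segment_width(params)
  zone_start <- params$break_zone[1]
  zone_w <- params$break_zone[2]
  zone_center <- normalize_angle(zone_start + zone_w / 2)
  # two arcs on the circle overlap iff the circular distance between their
  # centres is at most half the sum of their widths
  d <- abs(normalize_angle(stop_position) - zone_center)
  d <- pmin(d, 2 * pi - d)
  d <= (seg_w + zone_w) / 2
}

#' Fixed-lead brake policy
#'
#' A simple deterministic braking policy for simulated agents: press the
#' brake when the segment centre is within `lead` radians (plus an angular
#' error from the reaction time, `speed * reaction_time`) of the break-zone
#' centre, approaching from behind. Reaction-time noise is injected by the
#' caller drawing `reaction_time` values (one per trial), which keeps the
#' policy deterministic given its inputs and makes common-random-number
#' comparisons across parameter cells exact.
#'
#' @param lead Angular lead in radians at which the press is triggered.
#' @param reaction_time Delay (time units, >= 0) between the trigger and the
#'   actual press.
#' @return A function `policy(state)` returning `TRUE` when the brake should
#'   be pressed at the current step, usable with [simulate_trial()].
#' @export
policy_fixed_lead <- function(lead = 0.3, reaction_time = 0) {
  trigger_time <- NA_real_
  function(state) {
    if (state$presses > 0 && state$params$brake_mode == "single") return(FALSE)
    zone_center <- normalize_angle(state$params$break_zone[1] +
                                     state$params$break_zone[2] / 2)
    gap <- normalize_angle(zone_center - state$angle)
    if (is.na(trigger_time) && gap <= lead) trigger_time <<- state$time
    !is.na(trigger_time) && state$time >= trigger_time + reaction_time &&
      state$presses == 0
  }
}

#' Simulate one wheel stopping trial
#'
#' Fixed-step simulation of the trial kinematics. At every step the brake
#' policy decides whether to press. In single-press mode the first press
#' engages constant deceleration until the wheel rests; in multi-press mode
#' the effective deceleration at each step is
#' `presses * deceleration_increment`. If the policy never presses, the
#' trial ends unsuccessfully after `max_rotations` full rotations.
#'
#' @param params A [wheel_trial_params()] object.
#' @param brake_policy Function of the trial state (a list with `time`,
#'   `angle`, `speed`, `presses`, `params`) returning `TRUE` to press at the
#'   current step, e.g. from [policy_fixed_lead()].
#' @param dt Time step (default 1/60).
#' @param start_angle Initial segment-centre angle in radians.
#' @param mode `"discrete"` steps the kinematics through to rest;
#'   `"closed"` uses the closed-form stopping distance from the (first)
#'   press onward (single-press mode only), eliminating time-discretisation
#'   error in the stop position.
#' @param single_press_deceleration `"required"` (default) chooses the
#'   deceleration that makes the segment stop exactly `stopping_angle` after
#'   the press; `"printed"` uses the trial's `deceleration_increment` (the
#'   `sqrt(speed)/(2*stopping_angle)` assignment) as-is.
#' @param max_rotations Rotations without a press before the trial times
#'   out.
#'
#' @return A one-row [tibble::tibble()] with `press_count`, `first_press_time`,
#'   `stop_position` (radians in `[0, 2*pi)`), `rotation_after_press`,
#'   `won`, and `duration`.
#' @export
simulate_trial <- function(params,
                           brake_policy,
                           dt = 1 / 60,
                           start_angle = 0,
                           mode = c("discrete", "closed"),
                           single_press_deceleration = c("required", "printed"),
                           max_rotations = 3) {
  mode <- match.arg(mode)
  single_press_deceleration <- match.arg(single_press_deceleration)
  stopifnot(inherits(params, "wheel_trial_params"), dt > 0)

  time <- 0
  angle_total <- start_angle
  speed <- params$speed
  presses <- 0L
  press_times <- numeric(0)
  first_press_angle <- NA_real_
  press_speed <- NA_real_
  max_angle <- start_angle + max_rotations * 2 * pi

  single_decel <- function(v) {
    if (single_press_deceleration == "required" &&
        !is.null(params$stopping_angle)) {
      required_deceleration(v, params$stopping_angle)
    } else {
      params$deceleration_increment
    }
  }

  repeat {
    state <- list(time = time, angle = normalize_angle(angle_total),
                  speed = speed, presses = presses, params = params)
    if (isTRUE(brake_policy(state))) {
      presses <- presses + 1L
      press_times <- c(press_times, time)
      if (presses == 1L) {
        first_press_angle <- angle_total
        press_speed <- speed
        if (mode == "closed" && params$brake_mode == "single") {
          a <- single_decel(press_speed)
          angle_total <- angle_total + stop_distance(press_speed, a)
          speed <- 0
          break
        }
      }
    }
    decel <- if (presses == 0L) {
      0
    } else if (params$brake_mode == "single") {
      single_decel(press_speed)
    } else {
      presses * params$deceleration_increment
    }
    speed <- max(0, speed - decel * dt)
    angle_total <- angle_total + speed * dt
    time <- time + dt
    if (speed == 0 && presses > 0L) break
    if (presses == 0L && angle_total >= max_angle) break
  }

  stop_position <- normalize_angle(angle_total)
  won <- presses > 0L && trial_outcome(stop_position, params)
  tibble::tibble(
    press_count = presses,
    first_press_time = if (presses > 0L) press_times[1] else NA_real_,
    stop_position = stop_position,
    rotation_after_press = if (presses > 0L) angle_total - first_press_angle
                           else NA_real_,
    won = won,
    duration = time
  )
}

#' Vectorised closed-form trial outcomes
#'
#' Fast path for simulating many trials played by a fixed-lead agent with
#' per-trial reaction times, using the closed-form stopping distance instead
#' of time stepping. The agent triggers its press `lead` radians before the
#' break-zone centre; the press lands `speed * reaction_time` radians late;
#' the segment then travels `speed^2 / (2 * deceleration)` further.
#'
#' @param trials A data frame with columns `speed`, `segment_fraction`,
#'   `deceleration_increment` (one row per trial).
#' @param lead Angular lead of the brake policy, radians.
#' @param reaction_time Numeric vector of per-trial reaction delays,
#'   recycled to the number of trials.
#' @param break_zone `c(start, width)` shared by all trials.
#' @param base_width Segment base-width scale (see [wheel_trial_params()]).
#' @return `trials` with added columns `stop_offset` (signed angular error
#'   of the segment centre relative to the zone centre) and `won`.
#' @export
simulate_trials_closed <- function(trials,
                                   lead = 0.3,
                                   reaction_time = 0,
                                   break_zone = c(0, pi / 4),
                                   base_width = 0.5) {
  stopifnot(all(c("speed", "segment_fraction", "deceleration_increment")
                %in% names(trials)))
  n <- nrow(trials)
  tau <- rep_len(reaction_time, n)
  offset <- stop_distance(trials$speed, trials$deceleration_increment) -
    lead + trials$speed * tau
  seg_w <- (1 - trials$segment_fraction) * 2 * pi * base_width
  tol <- (seg_w + break_zone[2]) / 2
  d <- abs(offset) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  dplyr::mutate(tibble::as_tibble(trials),
                stop_offset = offset, won = d <= tol)
}
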