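test_that("single-press deceleration increment follows the assignment formula", {
  expect_equal(deceleration_increment_single_press(1, pi / 2), 1 / pi)
  expect_equal(deceleration_increment_single_press(4, pi), 1 / pi)
  expect_equal(deceleration_increment_single_press(2.25, 0.75), 1)
  # strictly increasing in speed, decreasing in stopping angle
  sp <- seq(0.5, 4, by = 0.5)
  expect_true(all(diff(deceleration_increment_single_press(sp, 1)) > 0))
  ang <- seq(0.5, 3, by = 0.5)
  expect_true(all(diff(deceleration_increment_single_press(2, ang)) < 0))
  expect_error(deceleration_increment_single_press(0, 1), "positive")
  expect_error(deceleration_increment_single_press(1, -1), "positive")
})

test_that("stopping distance matches the constant-deceleration closed form", {
  expect_equal(stop_distance(1, 1 / pi), pi / 2)  # a quarter rotation
  expect_equal(stop_distance(0, 5), 0)
  expect_equal(stop_distance(2, required_deceleration(2, 1.2)), 1.2)
  expect_error(stop_distance(1, 0), "positive")
})

test_that("Euler integration converges to the closed-form stop distance", {
  # independent oracle: explicit forward-Euler of the braking kinematics
  euler_stop <- function(v0, a, dt) {
    v <- v0; theta <- 0
    while (v > 0) {
      v <- max(0, v - a * dt)
      theta <- theta + v * dt
    }
    theta
  }
  for (case in list(c(1, 1 / pi), c(3, 2), c(2.5, 0.7))) {
    v0 <- case[1]; a <- case[2]
    closed <- stop_distance(v0, a)
    for (dt in c(1e-2, 1e-3, 1e-4)) {
      expect_lt(abs(euler_stop(v0, a, dt) - closed), 2 * v0 * dt)
    }
  }
})

test_that("simulate_trial honours stopping-angle semantics and braking modes", {
  p <- wheel_trial_params(2, 0.7, stopping_angle = pi / 2,
                          brake_mode = "single")
  res <- simulate_trial(p, policy_fixed_lead(0.3, reaction_time = 0.05),
                        mode = "closed")
  expect_equal(res$rotation_after_press, pi / 2, tolerance = 1e-12)
  # stop position = press angle + stopping angle, normalized to [0, 2*pi)
  expect_equal(res$stop_position,
               (p$speed * res$first_press_time + pi / 2) %% (2 * pi))
  expect_true(res$stop_position >= 0 && res$stop_position < 2 * pi)

  # discrete mode approaches the same stop within O(dt)
  res_d <- simulate_trial(p, policy_fixed_lead(0.3, reaction_time = 0.05),
                          dt = 1e-3)
  expect_lt(abs(res_d$rotation_after_press - pi / 2), 2 * p$speed * 1e-3)

  # multi-press: two presses brake harder than one
  pm <- wheel_trial_params(2, 0.7, deceleration_increment = 0.8,
                           brake_mode = "multi")
  press_n_policy <- function(n) {
    pressed <- 0L
    function(state) {
      if (state$time >= 0.5 && pressed < n) {
        pressed <<- pressed + 1L
        TRUE
      } else FALSE
    }
  }
  one <- simulate_trial(pm, press_n_policy(1), dt = 1 / 240)
  two <- simulate_trial(pm, press_n_policy(2), dt = 1 / 240)
  expect_lt(two$rotation_after_press, one$rotation_after_press)

  # faster wheel, same reaction time and deceleration: longer travel
  slow <- wheel_trial_params(1, 0.7, deceleration_increment = 1,
                             brake_mode = "multi")
  fast <- wheel_trial_params(10, 0.7, deceleration_increment = 1,
                             brake_mode = "multi")
  r_slow <- simulate_trial(slow, press_n_policy(1), dt = 1 / 240)
  r_fast <- simulate_trial(fast, press_n_policy(1), dt = 1 / 240)
  expect_gt(r_fast$rotation_after_press, r_slow$rotation_after_press)

  # never pressing ends the trial after max_rotations, unsuccessfully
  idle <- simulate_trial(pm, function(state) FALSE, dt = 1 / 60,
                         max_rotations = 3)
  expect_identical(idle$press_count, 0L)
  expect_false(idle$won)
  expect_gte(idle$duration * pm$speed, 3 * 2 * pi - 1e-6)
})

test_that("trial outcome equals a brute-force angular grid overlap test", {
  grid_oracle <- function(stop_position, params, n_grid = 1e5) {
    seg_w <- (1 - params$segment_fraction) * 2 * pi * params$base_width
    ang <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
    circ_in <- function(theta, start, width) {
      ((theta - start) %% (2 * pi)) < width
    }
    in_seg <- circ_in(ang, (stop_position - seg_w / 2) %% (2 * pi), seg_w)
    in_zone <- circ_in(ang, params$break_zone[1], params$break_zone[2])
    any(in_seg & in_zone)
  }
  p_in <- wheel_trial_params(2, 0.6, deceleration_increment = 1,
                             break_zone = c(1, 0.5))
  expect_true(trial_outcome(1.25, p_in))             # centred inside the zone
  p_far <- wheel_trial_params(2, 0.9, deceleration_increment = 1,
                              break_zone = c(0, 0.3))
  expect_false(trial_outcome(pi + 0.15, p_far))      # diametrically opposite
  withr::with_seed(42, {
    for (rep in 1:25) {
      params <- wheel_trial_params(
        speed = runif(1, 1, 4),
        segment_fraction = runif(1, 0.3, 0.99),
        deceleration_increment = 1,
        break_zone = c(runif(1, 0, 2 * pi), runif(1, 0.1, 1.5))
      )
      pos <- runif(1, 0, 2 * pi)
      expect_equal(trial_outcome(pos, params), grid_oracle(pos, params))
    }
  })
})

test_that("session schedules reproduce the probe cadence and trial counts", {
  s1 <- build_session("study1", seed = 1)
  s2 <- build_session("study2", seed = 1)

  stress1 <- s1$probes[s1$probes$kind == "stress", ]
  expect_identical(nrow(stress1), 4L)
  expect_true(all(diff(stress1$after_trial) == 80))
  stress2 <- s2$probes[s2$probes$kind == "stress", ]
  expect_identical(nrow(stress2), 3L)
  expect_true(all(diff(stress2$after_trial) == 45))

  for (s in list(s1, s2)) {
    ctrl <- s$probes[s$probes$kind == "control", ]
    diffp <- s$probes[s$probes$kind == "difficulty", ]
    expect_true(all(diff(ctrl$after_trial) == 10))
    expect_true(all(diff(diffp$after_trial) == 10))
    expect_true(all(diff(s$probes$probe_index) > 0))
    expect_identical(nrow(s$trials), s$n_blocks * s$trials_per_block)
  }
  expect_identical(stress1$timepoint, 1:4)
})

test_that("schedules are deterministic under a seed and ease-ordered for study 2", {
  a <- build_session("study1", seed = 9)
  b <- build_session("study1", seed = 9)
  expect_identical(a$trials, b$trials)
  c <- build_session("study1", seed = 10)
  expect_false(identical(a$trials, c$trials))

  s2 <- build_session("study2", seed = 1)
  ease <- -scale(s2$trials$speed) - scale(s2$trials$segment_fraction) +
    scale(s2$trials$deceleration_increment)
  expect_true(all(diff(as.numeric(ease)) >= -1e-12))

  expect_error(build_session("study1", parameter_grid = default_parameter_grid()[0, ]),
               "empty")
  expect_error(build_session("study1", cycle = FALSE), "cycle")
})

test_that("win rate is monotone in speed, segment fraction and deceleration", {
  # fixed-lead agent with common random reaction times across all cells;
  # the grid keeps every stop within one rotation past the zone (no
  # wrap-around), the regime in which the difficulty ordering is defined
  taus <- withr::with_seed(11, abs(rnorm(400, 0.12, 0.06)))
  cells <- tidyr::expand_grid(speed = c(1.2, 1.6, 2.0),
                              segment_fraction = c(0.5, 0.7, 0.9),
                              deceleration_increment = c(0.8, 1.6, 3.2))
  win_rate <- purrr::pmap_dbl(cells, function(speed, segment_fraction,
                                              deceleration_increment) {
    trials <- tibble::tibble(
      speed = speed, segment_fraction = segment_fraction,
      deceleration_increment = deceleration_increment,
      .rows = length(taus)
    )
    mean(simulate_trials_closed(trials, lead = 0.2,
                                reaction_time = taus)$won)
  })
  cells$win_rate <- win_rate
  mono <- function(df, var, decreasing) {
    others <- setdiff(c("speed", "segment_fraction",
                        "deceleration_increment"), var)
    df |>
      dplyr::arrange(.data[[var]]) |>
      dplyr::summarise(ok = all(if (decreasing) diff(.data$win_rate) <= 0
                                else diff(.data$win_rate) >= 0),
                       .by = dplyr::all_of(others)) |>
      dplyr::pull(ok) |>
      all()
  }
  expect_true(mono(cells, "speed", decreasing = TRUE))
  expect_true(mono(cells, "segment_fraction", decreasing = TRUE))
  expect_true(mono(cells, "deceleration_increment", decreasing = FALSE))
})
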