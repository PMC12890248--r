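#' Default generating coefficients
#'
#' Coefficient sets and variance components used as generating truth by the
#' synthetic-cohort module. `coupling_coefs()` is the Study-1 within-task
#' coupling model of subjective stress on mean subjective control and mean
#' perceived difficulty; `stage_coefs()` are the Study-2 stress-induction
#' and stress-relief models (timepoint x control-condition x
#' stressor-intensity with a domain covariate). Values are the fitted
#' estimates reported for the original studies and serve as defaults that
#' can be overridden.
#'
#' @return `coupling_coefs()`: a named numeric vector with elements
#'   `intercept`, `control`, `difficulty`. `coupling_variances()`: named
#'   vector `residual`, `participant`, `timepoint` (slider units squared).
#'   `stage_coefs()`: named vector over the stage-model terms.
#'   `stage_variances()`: named vector `participant`, `residual`.
#' @export
coupling_coefs <- function() {
  c(intercept = 31.13, control = -0.13, difficulty = 0.38)
}

#' @rdname coupling_coefs
#' @export
coupling_variances <- function() {
  c(residual = 208.61, participant = 346.20, timepoint = 3.63)
}

stage_terms <- c(
  "intercept", "timepoint", "control_neutral", "stressor_low", "domain_loss",
  "timepoint:control_neutral", "timepoint:stressor_low",
  "control_neutral:stressor_low", "timepoint:control_neutral:stressor_low"
)

#' @rdname coupling_coefs
#' @param stage `"induction"` (timepoints before/after the stressor) or
#'   `"relief"` (after the stressor / after the stressor debrief).
#' @export
stage_coefs <- function(stage = c("induction", "relief")) {
  stage <- match.arg(stage)
  vals <- switch(
    stage,
    induction = c(12.99, 20.14, -12.35, 12.89, 10.64, 10.92, -14.66,
                  11.56, -6.28),
    relief = c(114.30, -29.91, -11.02, -56.19, 8.19, 9.65, 19.87,
               13.40, -7.19)
  )
  stats::setNames(vals, stage_terms)
}

#' @rdname coupling_coefs
#' @export
stage_variances <- function(stage = c("induction", "relief")) {
  stage <- match.arg(stage)
  switch(stage,
         induction = c(participant = 470.40, residual = 301.09),
         relief = c(participant = 510.27, residual = 222.45))
}

#' Default condition allocation weights
#'
#' Study 1 crosses control condition (high/low) with stressor intensity
#' (high/low) in the win domain: four equally weighted cells. Study 2 has
#' six cells: high-control wheel-task participants crossed over stressor
#' intensity and win/loss domain, plus neutral-control (video) participants
#' over stressor intensity; weights reflect the observed 201 (wheel) vs 94
#' (video) split.
#'
#' @param study `"study1"` or `"study2"`.
#' @return A tibble with columns `control_condition`, `stressor_intensity`,
#'   `domain`, `weight` (weights sum to 1).
#' @export
default_allocation <- function(study = c("study1", "study2")) {
  study <- match.arg(study)
  if (study == "study1") {
    tidyr::expand_grid(control_condition = c("high", "low"),
                       stressor_intensity = c("high", "low"),
                       domain = "win") |>
      dplyr::mutate(weight = 0.25)
  } else {
    ws <- tidyr::expand_grid(control_condition = "high",
                             stressor_intensity = c("high", "low"),
                             domain = c("win", "loss")) |>
      dplyr::mutate(weight = (201 / 295) / 4)
    video <- tidyr::expand_grid(control_condition = "neutral",
                                stressor_intensity = c("high", "low"),
                                domain = "win") |>
      dplyr::mutate(weight = (94 / 295) / 2)
    dplyr::bind_rows(ws, video)
  }
}

#' Assign participants to experimental conditions
#'
#' Deterministically splits `n` participants over the design cells so that
#' every cell count is within rounding of `n * weight` (largest-remainder
#' apportionment), then shuffles the assignment order with the seeded RNG.
#' Neutral-control (video) participants carry `domain = "win"`, the
#' reference level, since the win/loss manipulation exists only inside the
#' wheel task.
#'
#' @param n Number of participants.
#' @param study `"study1"` or `"study2"`.
#' @param allocation Data frame of cells and `weight`s (summing to 1);
#'   defaults to [default_allocation()].
#' @param seed Integer seed.
#' @return A tibble with `participant_id`, `study`, `control_condition`,
#'   `stressor_intensity`, `domain`.
#' @export
#' @examples
#' assign_conditions(4, "study1", seed = 1)
assign_conditions <- function(n, study = c("study1", "study2"),
                              allocation = NULL, seed = 1L) {
  study <- match.arg(study)
  stopifnot(n > 0)
  if (is.null(allocation)) allocation <- default_allocation(study)
  valid <- default_allocation(study)[c("control_condition",
                                       "stressor_intensity", "domain")]
  keys <- do.call(paste, c(valid, sep = "/"))
  got <- do.call(paste, c(allocation[names(valid)], sep = "/"))
  if (!all(got %in% keys)) {
    stop("unknown design cell(s): ",
         paste(setdiff(got, keys), collapse = ", "), call. = FALSE)
  }
  if (abs(sum(allocation$weight) - 1) > 1e-8) {
    stop("allocation weights must sum to 1.", call. = FALSE)
  }
  exact <- n * allocation$weight
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  cells <- allocation[rep(seq_len(nrow(allocation)), counts),
                      c("control_condition", "stressor_intensity", "domain")]
  cells <- withr::with_seed(seed, cells[sample(nrow(cells)), , drop = FALSE])
  dplyr::mutate(tibble::as_tibble(cells),
                participant_id = sprintf("p%03d", seq_len(n)),
                study = study, .before = 1)
}

#' Configuration for the probe-rating generators
#'
#' Collects the generating truth for control, difficulty and stress probe
#' ratings. Control ratings follow the smoothed-regressor linear model
#' (latent prediction plus Gaussian noise, clipped to the 0-100 slider);
#' difficulty is an affine function of the same latent
#' (`100 - latent + noise`), inducing the negative control-difficulty
#' coupling the analyses assume while leaving unique variance; stress
#' follows the coupling mixed model.
#'
#' @param gamma Smoothing weight of the generating control model.
#' @param betas Named regressor weights (slider units per SD).
#' @param intercept Control-model intercept, slider units.
#' @param noise_sd Control-rating noise SD, slider units.
#' @param difficulty_noise_sd Difficulty-rating noise SD, slider units.
#' @param stress_coefs,stress_variances Generating coupling model; defaults
#'   to [coupling_coefs()] / [coupling_variances()].
#' @param clip_ratings Clip generated control/difficulty ratings to
#'   `[0, 100]` (default `TRUE`).
#' @param clip_stress Clip generated stress ratings (default `FALSE`;
#'   clipping biases linear recovery).
#' @return A list of class `ws_rating_config`.
#' @export
ws_rating_config <- function(gamma = 0.4,
                             betas = c(deceleration = 2.33,
                                       segment_size = -2.25,
                                       speed = -3.09),
                             intercept = 50,
                             noise_sd = 10,
                             difficulty_noise_sd = 10,
                             stress_coefs = coupling_coefs(),
                             stress_variances = coupling_variances(),
                             clip_ratings = TRUE,
                             clip_stress = FALSE) {
  stopifnot(noise_sd >= 0, difficulty_noise_sd >= 0,
            all(stress_variances >= 0))
  structure(
    list(gamma = gamma, betas = betas, intercept = intercept,
         noise_sd = noise_sd, difficulty_noise_sd = difficulty_noise_sd,
         stress_coefs = stress_coefs, stress_variances = stress_variances,
         clip_ratings = clip_ratings, clip_stress = clip_stress),
    class = "ws_rating_config"
  )
}

clip01 <- function(x, clip) if (clip) pmin(100, pmax(0, x)) else x

#' Generate control and difficulty probe ratings for one session
#'
#' Evaluates the generating control model along the session's trials and
#' emits a rating at each control and difficulty probe. The control rating
#' at a probe is the model prediction at the probe's trial plus Gaussian
#' noise; the difficulty rating is `100 - latent` plus its own noise. Both
#' are clipped to the slider range when the config says so.
#'
#' @param schedule A [build_session()] schedule.
#' @param config A [ws_rating_config()].
#' @param seed Integer seed.
#' @return A tibble with `kind`, `probe_index`, `block`, `trial_global`,
#'   `timepoint`, `latent`, `rating`.
#' @export
generate_control_difficulty_ratings <- function(schedule,
                                                config = ws_rating_config(),
                                                seed = 1L) {
  stopifnot(inherits(schedule, "ws_schedule"))
  probes <- schedule$probes[schedule$probes$kind != "stress", ]
  if (min(probes$after_trial) < 2L) {
    stop("fewer than 2 trials before the first probe.", call. = FALSE)
  }
  X <- prepare_regressors(schedule$trials)
  Xs <- smooth_regressors(X, config$gamma)
  latent <- predict_ratings(Xs, config$betas, config$intercept)[probes$after_trial]
  withr::with_seed(seed, {
    is_ctrl <- probes$kind == "control"
    noise <- ifelse(is_ctrl,
                    stats::rnorm(nrow(probes), 0, config$noise_sd),
                    stats::rnorm(nrow(probes), 0, config$difficulty_noise_sd))
    rating <- ifelse(is_ctrl, latent, 100 - latent) + noise
    tibble::tibble(
      kind = probes$kind, probe_index = probes$probe_index,
      block = probes$after_block, trial_global = probes$after_trial,
      timepoint = probes$timepoint, latent = latent,
      rating = clip01(rating, config$clip_ratings)
    )
  })
}

#' Generate stress probe ratings from the coupling model
#'
#' For each stress timepoint the generating truth is the linear mixed
#' model: `stress = intercept + b_control * mean control + b_difficulty *
#' mean difficulty + participant intercept + timepoint intercept +
#' residual`, where the means are taken over the control/difficulty probes
#' since the previous stress probe (see [align_probes_to_stress()]).
#'
#' @param probe_data Long probe table for one or more participants with
#'   columns `participant_id`, `kind`, `probe_index`, `timepoint`, `rating`;
#'   rows with `kind == "stress"` mark the stress probe slots (their
#'   `rating` may be `NA`) and define the alignment windows.
#' @param config A [ws_rating_config()].
#' @param seed Integer seed.
#' @return A tibble with `participant_id`, `timepoint`, `control`,
#'   `difficulty`, `rating` (the stress rating).
#' @export
generate_stress_ratings <- function(probe_data,
                                    config = ws_rating_config(),
                                    seed = 1L) {
  aligned <- align_probes_to_stress(probe_data)
  co <- config$stress_coefs
  vc <- config$stress_variances
  if (!all(c("residual", "participant", "timepoint") %in% names(vc))) {
    stop("stress_variances must name residual, participant and timepoint.",
         call. = FALSE)
  }
  ppts <- unique(aligned$participant_id)
  tps <- sort(unique(aligned$timepoint))
  withr::with_seed(seed, {
    u <- stats::setNames(stats::rnorm(length(ppts), 0, sqrt(vc["participant"])),
                         ppts)
    v <- stats::setNames(stats::rnorm(length(tps), 0, sqrt(vc["timepoint"])),
                         tps)
    eps <- stats::rnorm(nrow(aligned), 0, sqrt(vc["residual"]))
    dplyr::mutate(
      aligned,
      rating = unname(clip01(
        co[["intercept"]] + co[["control"]] * .data$control +
          co[["difficulty"]] * .data$difficulty +
          unname(u[.data$participant_id]) +
          unname(v[as.character(.data$timepoint)]) + eps,
        config$clip_stress
      ))
    )
  })
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm((lower - mean) / sd)
  hi <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

#' Simulate a coupling-analysis cohort directly
#'
#' Generates the participant x stress-timepoint table assumed by the
#' within-task coupling analysis without simulating wheel trials: per-
#' timepoint mean control and difficulty predictors are drawn from a
#' truncated normal on the 0-100 slider range, and stress follows the
#' generating mixed model exactly (random participant and timepoint
#' intercepts plus residual noise). With clipping off this is precisely the
#' model the fitting stage assumes, so coefficient recovery is unbiased.
#'
#' @param n Number of participants (default 473).
#' @param n_timepoints Stress timepoints per participant (default 4).
#' @param coefs,variances Generating fixed effects and variance components;
#'   defaults [coupling_coefs()], [coupling_variances()].
#' @param predictor_mean,predictor_sd Truncated-normal location/scale of the
#'   control and difficulty predictors (defaults 50 and 20 on `[0, 100]`).
#' @param clip Clip stress ratings to the slider range (default `FALSE`).
#' @param seed Integer seed.
#' @return A tibble with `participant_id`, `timepoint`, `control`,
#'   `difficulty`, `stress`.
#' @export
simulate_coupling_cohort <- function(n = 473, n_timepoints = 4,
                                     coefs = coupling_coefs(),
                                     variances = coupling_variances(),
                                     predictor_mean = 50, predictor_sd = 20,
                                     clip = FALSE, seed = 1L) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      participant_id = sprintf("p%03d", seq_len(n)),
      timepoint = seq_len(n_timepoints)
    )
    m <- nrow(grid)
    u <- rep(stats::rnorm(n, 0, sqrt(variances["participant"])),
             each = n_timepoints)
    v <- stats::rnorm(n_timepoints, 0, sqrt(variances["timepoint"]))[grid$timepoint]
    dplyr::mutate(
      grid,
      control = rtruncnorm(m, predictor_mean, predictor_sd, 0, 100),
      difficulty = rtruncnorm(m, predictor_mean, predictor_sd, 0, 100),
      stress = unname(clip01(
        coefs[["intercept"]] + coefs[["control"]] * .data$control +
          coefs[["difficulty"]] * .data$difficulty + u + v +
          stats::rnorm(m, 0, sqrt(variances[["residual"]])),
        clip
      ))
    )
  })
}

#' Generate a stress-buffering stage dataset
#'
#' Simulates the two-timepoint stress ratings analysed by the induction and
#' relief stage models: `y = X beta + participant intercept + residual`,
#' with the fixed-effect design formed from the 0/1 timepoint dummy, the
#' control-condition and stressor-intensity dummies, the domain dummy, and
#' the stated interactions.
#'
#' @param assignments Condition table from [assign_conditions()] (study 2).
#' @param stage `"induction"` or `"relief"`.
#' @param coefs Named fixed-effect vector over the stage-model terms;
#'   default [stage_coefs()]. Unknown term names are an error.
#' @param variances Named vector with `participant` and `residual`;
#'   default [stage_variances()].
#' @param clip Clip ratings to `[0, 100]` (default `FALSE`).
#' @param seed Integer seed.
#' @return A long tibble: one row per participant x timepoint with
#'   `stress`, the condition columns, and `timepoint` coded 0/1.
#' @export
generate_buffering_dataset <- function(assignments,
                                       stage = c("induction", "relief"),
                                       coefs = NULL, variances = NULL,
                                       clip = FALSE, seed = 1L) {
  stage <- match.arg(stage)
  if (is.null(coefs)) coefs <- stage_coefs(stage)
  if (is.null(variances)) variances <- stage_variances(stage)
  if (!setequal(names(coefs), stage_terms)) {
    stop("coefficient names must be exactly: ",
         paste(stage_terms, collapse = ", "), call. = FALSE)
  }
  if (!all(c("participant", "residual") %in% names(variances))) {
    stop("variances must name participant and residual.", call. = FALSE)
  }
  long <- tidyr::expand_grid(assignments, timepoint = c(0, 1))
  cn <- as.numeric(long$control_condition == "neutral")
  sl <- as.numeric(long$stressor_intensity == "low")
  dl <- as.numeric(long$domain == "loss")
  tp <- long$timepoint
  mu <- coefs[["intercept"]] + coefs[["timepoint"]] * tp +
    coefs[["control_neutral"]] * cn + coefs[["stressor_low"]] * sl +
    coefs[["domain_loss"]] * dl +
    coefs[["timepoint:control_neutral"]] * tp * cn +
    coefs[["timepoint:stressor_low"]] * tp * sl +
    coefs[["control_neutral:stressor_low"]] * cn * sl +
    coefs[["timepoint:control_neutral:stressor_low"]] * tp * cn * sl
  n <- nrow(assignments)
  withr::with_seed(seed, {
    u <- rep(stats::rnorm(n, 0, sqrt(variances[["participant"]])), each = 2)
    eps <- stats::rnorm(nrow(long), 0, sqrt(variances[["residual"]]))
    dplyr::mutate(long, stress = unname(clip01(mu + u + eps, clip)))
  })
}

#' Simulate a complete wheel-task cohort
#'
#' Runs the full generative pipeline for one study: condition assignment,
#' per-participant session schedules (each participant's randomized trial
#' order gets its own derived seed), control/difficulty probe ratings from
#' the smoothed-regressor model, closed-form trial outcomes for the win
#' rate, and stress probe ratings from the coupling model.
#'
#' @param study `"study1"` or `"study2"`.
#' @param n Number of participants.
#' @param config A [ws_rating_config()].
#' @param allocation Optional allocation table (see [assign_conditions()]).
#' @param lead,reaction_mean,reaction_sd Fixed-lead agent parameters used
#'   for trial outcomes: per-trial reaction times are drawn as
#'   `abs(rnorm(reaction_mean, reaction_sd))`.
#' @param individual_differences Draw each participant's control-model
#'   parameters from a population around the config values (default
#'   `TRUE`): betas normal with SD `beta_sd`, intercept normal with SD
#'   `intercept_sd`, gamma uniform on `gamma_range`. With `FALSE` every
#'   participant shares the config parameters exactly.
#' @param beta_sd,intercept_sd,gamma_range Population spreads used when
#'   `individual_differences = TRUE`.
#' @param seed Master integer seed; per-participant streams use fixed
#'   offsets.
#' @return A list with `assignments`, `trials` (trial log with `won`), and
#'   `probes` (long probe table: the cohort interchange format).
#' @export
simulate_cohort <- function(study = c("study1", "study2"), n = 20,
                            config = ws_rating_config(clip_stress = TRUE),
                            allocation = NULL,
                            lead = 0.3, reaction_mean = 0.12,
                            reaction_sd = 0.06,
                            individual_differences = TRUE,
                            beta_sd = 3.5, intercept_sd = 10,
                            gamma_range = c(0.1, 0.7),
                            seed = 1L) {
  study <- match.arg(study)
  assignments <- assign_conditions(n, study, allocation, seed = seed)
  per_ppt <- purrr::map(seq_len(n), function(i) {
    pseed <- seed + 1000L * i
    sched <- build_session(study, seed = pseed)
    cfg_i <- config
    if (individual_differences) {
      cfg_i <- withr::with_seed(pseed + 3L, {
        betas_i <- stats::rnorm(length(config$betas), config$betas, beta_sd)
        names(betas_i) <- names(config$betas)
        ws_rating_config(
          gamma = stats::runif(1, gamma_range[1], gamma_range[2]),
          betas = betas_i,
          intercept = stats::rnorm(1, config$intercept, intercept_sd),
          noise_sd = config$noise_sd,
          difficulty_noise_sd = config$difficulty_noise_sd,
          stress_coefs = config$stress_coefs,
          stress_variances = config$stress_variances,
          clip_ratings = config$clip_ratings,
          clip_stress = config$clip_stress
        )
      })
    }
    ratings <- generate_control_difficulty_ratings(sched, cfg_i,
                                                   seed = pseed + 1L)
    taus <- withr::with_seed(pseed + 2L, {
      abs(stats::rnorm(nrow(sched$trials), reaction_mean, reaction_sd))
    })
    outcomes <- simulate_trials_closed(sched$trials, lead = lead,
                                       reaction_time = taus)
    list(sched = sched, ratings = ratings, outcomes = outcomes)
  })
  pid <- assignments$participant_id
  trials <- purrr::map2_dfr(per_ppt, pid, function(x, id) {
    dplyr::mutate(x$outcomes, participant_id = id, .before = 1)
  })
  probes <- purrr::map2_dfr(per_ppt, pid, function(x, id) {
    dplyr::mutate(x$ratings, participant_id = id, .before = 1)
  })
  stress_slots <- per_ppt[[1]]$sched$probes |>
    dplyr::filter(.data$kind == "stress") |>
    dplyr::select("timepoint", "probe_index",
                  block = "after_block", trial_global = "after_trial")
  slot_rows <- tidyr::expand_grid(participant_id = pid, stress_slots) |>
    dplyr::mutate(kind = "stress", rating = NA_real_)
  stress <- generate_stress_ratings(dplyr::bind_rows(probes, slot_rows),
                                    config, seed = seed + 7L) |>
    dplyr::mutate(kind = "stress") |>
    dplyr::left_join(stress_slots, by = "timepoint")
  probes_all <- dplyr::bind_rows(
    dplyr::select(probes, "participant_id", "kind", "probe_index",
                  "block", "trial_global", "timepoint", "rating"),
    dplyr::select(stress, "participant_id", "kind", "probe_index",
                  "block", "trial_global", "timepoint", "rating")
  ) |>
    dplyr::left_join(assignments, by = "participant_id") |>
    dplyr::arrange(.data$participant_id, .data$probe_index)
  win_rate <- trials |>
    dplyr::summarise(win_rate = 100 * mean(.data$won), .by = "participant_id")
  list(assignments = dplyr::left_join(assignments, win_rate,
                                      by = "participant_id"),
       trials = trials,
       probes = probes_all)
}
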