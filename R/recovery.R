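#' Parameter-recovery study for the control-rating model
#'
#' Simulates participants from known control-model parameters on a session
#' design, fits the full three-regressor model to each, and reports
#' per-parameter bias, RMSE and the truth-estimate correlation. True
#' parameters are drawn per participant: betas from normal distributions
#' centred on the group means with the population spread, gamma uniform,
#' intercept normal.
#'
#' @param design A [build_session()] schedule; the default recovery design
#'   is the Study-1 session (64 blocks, 32 control probes). Each
#'   participant gets a freshly randomized trial order (derived seed).
#' @param n_participants Number of simulated participants (default 100).
#' @param noise_sd Rating noise SD in slider units (default 10).
#' @param truth List of truth-distribution settings: `beta_mean` (named),
#'   `beta_sd`, `gamma_range`, `intercept_mean`, `intercept_sd`.
#' @param n_starts Optimisation starts per fit.
#' @param prior_nu Prior variance passed to [fit_control_model()]; use `Inf`
#'   to disable the ridge prior (e.g. for noiseless identifiability checks,
#'   where the MAP's mild shrinkage is a deliberate bias).
#' @param seed Integer master seed.
#' @return A list of class `ws_recovery`: `estimates` (tibble of truth and
#'   estimate per participant x parameter), `report` (tibble: parameter,
#'   bias, rmse, correlation), `n_failed` (fit failures, counted not
#'   propagated), and `unstable` (flag: fewer than 3 participants).
#' @export
recover_parameters <- function(design = NULL,
                               n_participants = 100,
                               noise_sd = 10,
                               truth = list(),
                               n_starts = 5L,
                               prior_nu = 1,
                               seed = 1L) {
  defaults <- list(
    beta_mean = c(deceleration = 2.33, segment_size = -2.25, speed = -3.09),
    beta_sd = 3.5, gamma_range = c(0.1, 0.7),
    intercept_mean = 50, intercept_sd = 10
  )
  truth <- utils::modifyList(defaults, truth)
  study <- if (is.null(design)) "study1" else design$study

  rows <- vector("list", n_participants)
  n_failed <- 0L
  for (i in seq_len(n_participants)) {
    pseed <- seed + 1000L * i
    sched <- if (is.null(design)) build_session("study1", seed = pseed)
             else design
    true <- withr::with_seed(pseed + 1L, list(
      gamma = stats::runif(1, truth$gamma_range[1], truth$gamma_range[2]),
      betas = stats::rnorm(3, truth$beta_mean, truth$beta_sd),
      intercept = stats::rnorm(1, truth$intercept_mean, truth$intercept_sd)
    ))
    names(true$betas) <- names(truth$beta_mean)
    config <- ws_rating_config(gamma = true$gamma, betas = true$betas,
                               intercept = true$intercept,
                               noise_sd = noise_sd, clip_ratings = FALSE)
    ratings <- generate_control_difficulty_ratings(sched, config,
                                                   seed = pseed + 2L)
    y <- rep(NA_real_, nrow(sched$trials))
    ctrl <- ratings[ratings$kind == "control", ]
    y[ctrl$trial_global] <- ctrl$rating
    X <- prepare_regressors(sched$trials)
    fit <- tryCatch(
      fit_control_model(X, y, n_starts = n_starts, prior_nu = prior_nu,
                        seed = pseed + 3L),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[i]] <- tibble::tibble(
      participant = i,
      parameter = c("gamma", names(true$betas), "intercept"),
      truth = c(true$gamma, unname(true$betas), true$intercept),
      estimate = c(fit$gamma, unname(fit$betas[names(true$betas)]),
                   fit$intercept)
    )
  }
  estimates <- dplyr::bind_rows(rows)
  unstable <- length(unique(estimates$participant)) < 3L
  report <- estimates |>
    dplyr::summarise(
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      correlation = if (dplyr::n() >= 3 && stats::sd(.data$truth) > 0) {
        stats::cor(.data$truth, .data$estimate)
      } else {
        NA_real_
      },
      .by = "parameter"
    )
  if (unstable) {
    warning("recovery report based on fewer than 3 participants; ",
            "estimates flagged unstable.", call. = FALSE)
  }
  structure(list(estimates = estimates, report = report,
                 n_failed = n_failed, unstable = unstable, study = study),
            class = "ws_recovery")
}

#' @export
print.ws_recovery <- function(x, ...) {
  cat("<ws_recovery> ", length(unique(x$estimates$participant)),
      " participants fit, ", x$n_failed, " failed\n", sep = "")
  print(as.data.frame(x$report), digits = 3, row.names = FALSE)
  invisible(x)
}
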