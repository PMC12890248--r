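#' Default task-parameter grid
#'
#' A 3 x 3 x 3 grid of trial parameters spanning easy to hard trials:
#' three rotation speeds, three segment-size fractions and three
#' deceleration increments. Units as in [wheel_trial_params()].
#'
#' @return A tibble with columns `speed`, `segment_fraction`,
#'   `deceleration_increment` (27 rows).
#' @export
default_parameter_grid <- function() {
  tidyr::expand_grid(
    speed = c(1.5, 2.5, 3.5),
    segment_fraction = c(0.5, 0.7, 0.9),
    deceleration_increment = c(0.8, 1.6, 3.2)
  )
}

ease_score <- function(grid) {
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  # easier trials: slower rotation, larger segment (small fraction), stronger braking
  -z(grid$speed) - z(grid$segment_fraction) + z(grid$deceleration_increment)
}

stress_cadence <- function(study) switch(study, study1 = 16L, study2 = 9L)

#' Build a session schedule
#'
#' Constructs the ordered trials and probe placements of one wheel-stopping
#' session. Trials come in fixed blocks of `trials_per_block` (default 5).
#' After every block a control or a perceived-difficulty slider probe is
#' placed, the two kinds alternating, so each kind recurs every 2 blocks
#' (10 trials). Subjective-stress probes are added every 16 blocks
#' (80 trials) for Study 1 and every 9 blocks (45 trials) for Study 2 and
#' carry the analysis timepoint labels.
#'
#' @param study `"study1"` or `"study2"`.
#' @param n_blocks Number of blocks; defaults to 64 (study 1) or 27
#'   (study 2), which realises 4 and 3 stress probes respectively.
#' @param ordering `"randomized"` (study-1 default) shuffles the parameter
#'   grid across trials with the seeded RNG; `"increasing_ease"` (study-2
#'   default) orders trials from hardest to easiest by an ease score
#'   (decreasing speed, decreasing segment fraction, increasing
#'   deceleration).
#' @param parameter_grid Data frame of candidate trial parameters; defaults
#'   to [default_parameter_grid()].
#' @param trials_per_block Trials per block (default 5).
#' @param cycle Recycle the grid when it holds fewer rows than the session
#'   needs trials (default `TRUE`); with `FALSE` this is an error.
#' @param seed Integer seed controlling the randomized ordering.
#'
#' @return An object of class `ws_schedule`: a list with `study`,
#'   `n_blocks`, `trials_per_block`, `trials` (tibble: `block`, `trial`,
#'   `trial_global`, parameter columns) and `probes` (tibble: `probe_index`,
#'   `kind`, `after_block`, `after_trial`, `timepoint`).
#' @export
#' @examples
#' sched <- build_session("study2", seed = 1)
#' table(sched$probes$kind)
build_session <- function(study = c("study1", "study2"),
                          n_blocks = NULL,
                          ordering = NULL,
                          parameter_grid = default_parameter_grid(),
                          trials_per_block = 5L,
                          cycle = TRUE,
                          seed = 1L) {
  study <- match.arg(study)
  if (is.null(n_blocks)) n_blocks <- switch(study, study1 = 64L, study2 = 27L)
  if (is.null(ordering)) {
    ordering <- switch(study, study1 = "randomized", study2 = "increasing_ease")
  }
  ordering <- match.arg(ordering, c("randomized", "increasing_ease"))
  if (nrow(parameter_grid) == 0L) stop("`parameter_grid` is empty.", call. = FALSE)
  n_trials <- n_blocks * trials_per_block
  if (nrow(parameter_grid) < n_trials && !cycle) {
    stop("parameter grid smaller than the session and `cycle = FALSE`.",
         call. = FALSE)
  }

  grid <- tibble::as_tibble(parameter_grid)
  rows <- rep_len(seq_len(nrow(grid)), n_trials)
  trials <- if (ordering == "randomized") {
    withr::with_seed(seed, grid[sample(rows), , drop = FALSE])
  } else {
    # hardest first: ascending ease, each grid row repeated contiguously
    ord <- order(ease_score(grid))
    counts <- table(factor(rep_len(ord, n_trials), levels = ord))
    grid[rep(ord, times = as.integer(counts)), , drop = FALSE]
  }
  trials <- dplyr::mutate(
    trials,
    block = rep(seq_len(n_blocks), each = trials_per_block),
    trial = rep(seq_len(trials_per_block), times = n_blocks),
    trial_global = dplyr::row_number(),
    .before = 1
  )

  blocks <- seq_len(n_blocks)
  probes <- tibble::tibble(
    kind = ifelse(blocks %% 2 == 0, "control", "difficulty"),
    after_block = blocks
  )
  stress_blocks <- seq(stress_cadence(study), n_blocks, by = stress_cadence(study))
  probes <- dplyr::bind_rows(
    probes,
    tibble::tibble(kind = "stress", after_block = stress_blocks)
  )
  # stress probes are presented after the slider probe of the same block
  probes <- dplyr::arrange(probes, .data$after_block, .data$kind == "stress")
  probes <- dplyr::mutate(
    probes,
    probe_index = dplyr::row_number(),
    after_trial = .data$after_block * trials_per_block,
    timepoint = ifelse(.data$kind == "stress",
                       cumsum(.data$kind == "stress"), NA_integer_),
    .before = 1
  )

  structure(
    list(study = study, n_blocks = n_blocks,
         trials_per_block = trials_per_block,
         trials = trials, probes = probes),
    class = "ws_schedule"
  )
}

#' @export
print.ws_schedule <- function(x, ...) {
  cat("<ws_schedule> ", x$study, ": ", x$n_blocks, " blocks x ",
      x$trials_per_block, " trials (", nrow(x$trials), " trials)\n", sep = "")
  cat("  probes:", paste(names(table(x$probes$kind)),
                         table(x$probes$kind), collapse = ", "), "\n")
  invisible(x)
}
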