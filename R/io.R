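cohort_required_cols <- c("participant_id", "study", "control_condition",
                          "stressor_intensity", "domain", "kind",
                          "timepoint", "rating")

#' Validate a cohort probe table
#'
#' Checks the long-format probe schema used as the interchange format:
#' required columns, known categorical codes, ratings inside the 0-100
#' slider range. Errors name the offending column and row.
#'
#' @param table A data frame.
#' @return The table, invisibly, as a tibble (with `timepoint` integer).
#' @export
validate_cohort <- function(table) {
  missing <- setdiff(cohort_required_cols, names(table))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  checks <- list(
    study = c("study1", "study2"),
    control_condition = c("high", "low", "neutral"),
    stressor_intensity = c("high", "low"),
    domain = c("win", "loss"),
    kind = c("control", "difficulty", "stress")
  )
  for (col in names(checks)) {
    bad <- which(!table[[col]] %in% checks[[col]])
    if (length(bad)) {
      stop("invalid value in column `", col, "` at row ", bad[1], ": \"",
           table[[col]][bad[1]], "\"", call. = FALSE)
    }
  }
  ratings <- table$rating
  bad <- which(!is.na(ratings) & (ratings < 0 | ratings > 100))
  if (length(bad)) {
    stop("rating out of [0, 100] in column `rating` at row ", bad[1], ": ",
         ratings[bad[1]], call. = FALSE)
  }
  out <- tibble::as_tibble(table)
  out$timepoint <- as.integer(out$timepoint)
  invisible(out)
}

#' Read / write a cohort probe table
#'
#' CSV round-trip of the cohort interchange format with schema validation
#' on both ends.
#'
#' @param path File path.
#' @param table Cohort probe table.
#' @return `read_cohort()`: a validated tibble. `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(tbl)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(table, path) {
  validate_cohort(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every choice the demo pipeline needs; all stage seeds are
#' derived from the single master seed by fixed offsets. The config
#' round-trips losslessly through YAML via [write_ws_config()] /
#' [read_ws_config()].
#'
#' @param study `"study1"` or `"study2"`.
#' @param n_participants Cohort size.
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if missing).
#' @param n_starts Optimisation starts per control-model fit.
#' @param rating Named list overriding [ws_rating_config()] fields.
#' @return A list of class `ws_config`.
#' @export
ws_config <- function(study = "study2", n_participants = 20, seed = 1L,
                      out_dir = tempfile("wheelstop-run-"),
                      n_starts = 5L, rating = list()) {
  # the demo pipeline is a realism mode: keep stress on the slider scale
  if (!"clip_stress" %in% names(rating)) rating$clip_stress <- TRUE
  rating_config <- do.call(ws_rating_config, rating)
  structure(
    list(study = study, n_participants = n_participants, seed = as.integer(seed),
         out_dir = out_dir, n_starts = as.integer(n_starts),
         rating = rating_config),
    class = "ws_config"
  )
}

#' @rdname ws_config
#' @param config A `ws_config`.
#' @param path YAML file path.
#' @export
write_ws_config <- function(config, path) {
  as_plain <- function(x) {
    if (is.list(x)) lapply(unclass(x), as_plain)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(as_plain(unclass(config)), path)
  invisible(path)
}

#' @rdname ws_config
#' @export
read_ws_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rating <- raw$rating
  rating$betas <- unlist(rating$betas)
  rating$stress_coefs <- unlist(rating$stress_coefs)
  rating$stress_variances <- unlist(rating$stress_variances)
  ws_config(study = raw$study, n_participants = raw$n_participants,
            seed = raw$seed, out_dir = raw$out_dir, n_starts = raw$n_starts,
            rating = rating)
}

#' Run the demonstration pipeline
#'
#' End-to-end deterministic run on a synthetic cohort: simulate the cohort,
#' write the cohort CSV, fit the 7-model control-rating family and select
#' the group winner, compute split-half ICCs, fit the coupling model, and
#' (study 2) generate and fit the stress induction and relief stage models.
#' Every artifact is a CSV in `config$out_dir` plus a JSON manifest holding
#' the seed and config; identical configs give byte-identical outputs.
#'
#' @param config A [ws_config()].
#' @return Named character vector of written file paths, invisibly.
#' @export
run_pipeline <- function(config = ws_config()) {
  stopifnot(inherits(config, "ws_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  emit <- function(obj, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    readr::write_csv(obj, p, progress = FALSE)
    paths[[name]] <<- p
    p
  }

  cohort <- simulate_cohort(config$study, config$n_participants,
                            config$rating, seed = config$seed)
  emit(cohort$probes, "cohort")
  emit(cohort$assignments, "assignments")

  ratings_long <- cohort$trials |>
    dplyr::select("participant_id", "speed", "segment_fraction",
                  "deceleration_increment") |>
    dplyr::mutate(trial_global = dplyr::row_number(),
                  .by = "participant_id") |>
    dplyr::left_join(
      cohort$probes |>
        dplyr::filter(.data$kind == "control") |>
        dplyr::select("participant_id", "trial_global", "rating"),
      by = c("participant_id", "trial_global")
    )
  fits <- fit_control_models(ratings_long, n_starts = config$n_starts,
                             seed = config$seed + 101L)
  emit(fits, "control_model_fits")
  emit(select_best_model(fits), "control_model_winner")

  emit(dplyr::bind_rows(
    icc_split_half(cohort$probes, scheme = "odd_even"),
    icc_split_half(cohort$probes, scheme = "first_second")
  ), "icc")

  aligned <- align_probes_to_stress(cohort$probes)
  coupling <- fit_coupling_model(aligned)
  emit(coupling$coefficients, "coupling_coefficients")

  if (config$study == "study2") {
    for (stage in c("induction", "relief")) {
      stage_data <- generate_buffering_dataset(
        cohort$assignments, stage, seed = config$seed + 211L +
          (stage == "relief")
      )
      fit <- fit_stage_model(stage_data)
      emit(fit$coefficients, paste0(stage, "_coefficients"))
      emit(emm_timepoint_contrasts(fit), paste0(stage, "_contrasts"))
    }
  }

  config_path <- file.path(config$out_dir, "config.yaml")
  write_ws_config(config, config_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("wheelstop")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(config_path)),
    files = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(unlist(paths))
}
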