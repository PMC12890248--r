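#' Align slider probes to stress timepoints
#'
#' For each stress probe, averages the control ratings and the difficulty
#' ratings given since the previous stress probe (or since the session
#' start for the first one), yielding one covariate row per stress
#' timepoint. A stress probe with no preceding control or difficulty probe
#' in its window gets `NA` for that mean (reported via a message).
#'
#' @param probe_data Long probe table with `participant_id`, `kind`
#'   (`"control"`, `"difficulty"`, `"stress"`), `probe_index` (chronological
#'   order within participant), `timepoint` (stress rows), `rating`.
#' @return A tibble with `participant_id`, `timepoint`, `control`,
#'   `difficulty` and, when the stress rows carry ratings, `stress`.
#' @export
align_probes_to_stress <- function(probe_data) {
  stopifnot(all(c("participant_id", "kind", "rating") %in% names(probe_data)))
  if (!"probe_index" %in% names(probe_data)) {
    probe_data <- dplyr::mutate(probe_data,
                                probe_index = dplyr::row_number(),
                                .by = "participant_id")
  }
  out <- probe_data |>
    dplyr::arrange(.data$participant_id, .data$probe_index) |>
    dplyr::mutate(
      window = cumsum(dplyr::lag(.data$kind == "stress", default = FALSE)),
      .by = "participant_id"
    ) |>
    dplyr::summarise(
      timepoint = .data$timepoint[.data$kind == "stress"][1],
      control = mean(.data$rating[.data$kind == "control"]),
      difficulty = mean(.data$rating[.data$kind == "difficulty"]),
      stress = .data$rating[.data$kind == "stress"][1],
      .by = c("participant_id", "window")
    ) |>
    dplyr::filter(!is.na(.data$timepoint)) |>
    dplyr::select(-"window")
  if (anyNA(out$control) || anyNA(out$difficulty)) {
    message(sum(is.na(out$control) | is.na(out$difficulty)),
            " stress timepoint(s) with an empty probe window (set to NA).")
  }
  if (all(is.na(out$stress))) out$stress <- NULL
  out
}

#' Assemble the coupling-analysis table from a simulated cohort
#'
#' Aligns the cohort's probe table to the stress timepoints and joins the
#' per-participant condition columns and win rate, producing the input
#' expected by [fit_coupling_model()] with covariates.
#'
#' @param cohort A list from [simulate_cohort()].
#' @return Aligned tibble with `stress`, `control`, `difficulty`,
#'   `win_rate`, `domain` and the condition columns.
#' @export
coupling_data <- function(cohort) {
  align_probes_to_stress(cohort$probes) |>
    dplyr::left_join(cohort$assignments, by = "participant_id")
}

wald_coef_table <- function(model, level = 0.95) {
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  z <- est / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    ci_low = unname(est - q * se), ci_high = unname(est + q * se),
    statistic = unname(z), p_value = unname(2 * stats::pnorm(-abs(z)))
  )
}

canonical_terms <- function(terms) {
  terms <- gsub("(Intercept)", "intercept", terms, fixed = TRUE)
  terms <- gsub("control_condition", "control_", terms, fixed = TRUE)
  terms <- gsub("stressor_intensity", "stressor_", terms, fixed = TRUE)
  gsub("domain", "domain_", terms, fixed = TRUE)
}

new_ws_mixed_fit <- function(model, data, singular_note = NULL) {
  vc <- as.data.frame(lme4::VarCorr(model))
  variance_components <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual",
                                                         "residual", vc$grp))
  coefs <- wald_coef_table(model)
  coefs$term <- canonical_terms(coefs$term)
  structure(
    list(model = model, coefficients = coefs,
         variance_components = variance_components,
         r2 = r2_pair_(model),
         n_obs = stats::nobs(model),
         n_groups = lme4::ngrps(model),
         data = data, singular_note = singular_note),
    class = "ws_mixed_fit"
  )
}

#' @export
print.ws_mixed_fit <- function(x, ...) {
  cat("<ws_mixed_fit> ", deparse(stats::formula(x$model)), "\n", sep = "")
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  cat("variance components:",
      paste(names(x$variance_components),
            signif(x$variance_components, 5), collapse = ", "), "\n")
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f, n = %d\n",
              x$r2[["marginal"]], x$r2[["conditional"]], x$n_obs))
  if (!is.null(x$singular_note)) cat("note:", x$singular_note, "\n")
  invisible(x)
}

#' Within-task stress-control coupling model
#'
#' REML linear mixed model of subjective stress on mean subjective control
#' and mean perceived difficulty (unstandardised), with random intercepts
#' for participant and, by default, timepoint. If the timepoint random
#' intercept makes the fit singular it is dropped with a warning. Optional
#' covariates: overall `win_rate` (percentage 0-100) and `domain`
#' (win/loss).
#'
#' @param data Aligned table with columns `stress`, `control`, `difficulty`,
#'   `participant_id`, `timepoint`, plus any requested covariates (see
#'   [align_probes_to_stress()]).
#' @param covariates Character subset of `c("win_rate", "domain")`.
#' @param random Character subset of `c("participant", "timepoint")`; must
#'   include `"participant"`.
#' @return A `ws_mixed_fit`.
#' @export
fit_coupling_model <- function(data, covariates = NULL,
                               random = c("participant", "timepoint")) {
  stopifnot(all(c("stress", "control", "difficulty", "participant_id",
                  "timepoint") %in% names(data)))
  if (!"participant" %in% random) {
    stop("the participant random intercept is required.", call. = FALSE)
  }
  covariates <- intersect(covariates, c("win_rate", "domain"))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("missing covariate column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  if ("domain" %in% covariates) {
    data$domain <- factor(data$domain, levels = c("win", "loss"))
  }
  rhs <- c("control", "difficulty", covariates, "(1 | participant_id)")
  if ("timepoint" %in% random) rhs <- c(rhs, "(1 | timepoint)")
  form <- stats::reformulate(rhs, response = "stress")
  data <- dplyr::filter(data, !is.na(.data$control), !is.na(.data$difficulty))
  fit <- suppressMessages(lme4::lmer(form, data = data, REML = TRUE))
  note <- NULL
  if (lme4::isSingular(fit) && "timepoint" %in% random) {
    warning("singular fit; dropping the timepoint random intercept.",
            call. = FALSE)
    rhs <- setdiff(rhs, "(1 | timepoint)")
    fit <- lme4::lmer(stats::reformulate(rhs, response = "stress"),
                      data = data, REML = TRUE)
    note <- "timepoint random intercept dropped (singular fit)"
  }
  new_ws_mixed_fit(fit, data, note)
}

#' Stress induction / relief stage model
#'
#' REML linear mixed model for one stage of the stressor phase: subjective
#' stress at two timepoints (coded 0/1) modelled by timepoint x
#' control-condition x stressor-intensity with a win/loss domain covariate
#' and a participant random intercept. Reference levels are high control,
#' high stressor intensity and the win domain, so the printed dummies are
#' `control_neutral`, `stressor_low`, `domain_loss`.
#'
#' @param data Long stage table: `stress`, `timepoint` (two values, coded
#'   to 0/1), `control_condition`, `stressor_intensity`, `domain`,
#'   `participant_id` (see [generate_buffering_dataset()]).
#' @param extra_terms Optional character vector of additional fixed-effect
#'   terms (e.g. `"initial_stress"`, `"total_time"`,
#'   `"domain:timepoint"`).
#' @param reml Fit by REML (default) or maximum likelihood (needed for
#'   AIC/BIC comparisons across fixed-effect structures).
#' @return A `ws_mixed_fit`.
#' @export
fit_stage_model <- function(data, extra_terms = NULL, reml = TRUE) {
  needed <- c("stress", "timepoint", "control_condition",
              "stressor_intensity", "domain", "participant_id")
  stopifnot(all(needed %in% names(data)))
  tps <- sort(unique(data$timepoint))
  if (length(tps) != 2L) {
    stop("stage data must contain exactly two timepoints.", call. = FALSE)
  }
  data$timepoint <- as.numeric(data$timepoint == tps[2])
  data$control_condition <- factor(data$control_condition,
                                   levels = c("high", "neutral"))
  data$stressor_intensity <- factor(data$stressor_intensity,
                                    levels = c("high", "low"))
  data$domain <- factor(data$domain, levels = c("win", "loss"))
  cells <- tidyr::expand_grid(control_condition = c("high", "neutral"),
                              stressor_intensity = c("high", "low"))
  present <- dplyr::distinct(data, .data$control_condition,
                             .data$stressor_intensity)
  empty <- dplyr::anti_join(
    cells, dplyr::mutate(present, dplyr::across(dplyr::everything(),
                                                as.character)),
    by = c("control_condition", "stressor_intensity")
  )
  if (nrow(empty)) {
    stop("empty design cell(s): ",
         paste(empty$control_condition, empty$stressor_intensity,
               sep = "/", collapse = ", "), call. = FALSE)
  }
  rhs <- c("timepoint * control_condition * stressor_intensity", "domain",
           extra_terms, "(1 | participant_id)")
  fit <- lme4::lmer(stats::reformulate(rhs, response = "stress"),
                    data = data, REML = reml)
  new_ws_mixed_fit(fit, data)
}

#' Estimated-marginal-means timepoint contrasts
#'
#' Model-implied change from the first to the second timepoint within each
#' level of a grouping factor, on a balanced reference grid (every level of
#' every other factor weighted equally), plus the difference of the two
#' group contrasts (the buffering statistic). Standard errors come from the
#' fixed-effect covariance; p-values are normal-theory and the per-group
#' contrast p-values are Benjamini-Hochberg adjusted.
#'
#' @param fit A `ws_mixed_fit` from [fit_stage_model()].
#' @param by Grouping factor: `"control_condition"` (default) or
#'   `"stressor_intensity"`.
#' @return A tibble of class `ws_contrasts`: one row per group level with
#'   the timepoint contrast, then one `difference` row (first level minus
#'   second level).
#' @export
emm_timepoint_contrasts <- function(fit, by = "control_condition") {
  stopifnot(inherits(fit, "ws_mixed_fit"))
  model <- fit$model
  data <- fit$data
  fixed_form <- lme4::nobars(stats::formula(model, fixed.only = TRUE))[-2]
  factors <- list(
    control_condition = levels(data$control_condition),
    stressor_intensity = levels(data$stressor_intensity),
    domain = levels(data$domain)
  )
  if (!by %in% names(factors)) {
    stop("`by` must be one of: ", paste(names(factors), collapse = ", "),
         call. = FALSE)
  }
  numeric_covs <- setdiff(
    names(data)[vapply(data, is.numeric, TRUE)],
    c("timepoint", "stress")
  )
  grid <- tidyr::expand_grid(!!!factors, timepoint = c(0, 1))
  for (v in numeric_covs) grid[[v]] <- mean(data[[v]], na.rm = TRUE)
  for (f in names(factors)) {
    grid[[f]] <- factor(grid[[f]], levels = factors[[f]])
  }
  mm <- stats::model.matrix(fixed_form, grid)
  beta <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))

  contrast_vec <- function(level) {
    in_group <- grid[[by]] == level
    row1 <- colMeans(mm[in_group & grid$timepoint == 1, , drop = FALSE])
    row0 <- colMeans(mm[in_group & grid$timepoint == 0, , drop = FALSE])
    row1 - row0
  }
  lv <- factors[[by]]
  vecs <- lapply(lv, contrast_vec)
  vecs <- c(vecs, list(vecs[[1]] - vecs[[2]]))
  labels <- c(lv, paste(lv[1], "-", lv[2]))
  out <- purrr::map2_dfr(vecs, labels, function(cv, lab) {
    est <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    tibble::tibble(group = lab, estimate = est, std_error = se,
                   statistic = est / se,
                   p_value = 2 * stats::pnorm(-abs(est / se)))
  })
  out$contrast <- c(rep("timepoint 2 - 1", length(lv)), "difference")
  out$p_adj <- NA_real_
  # normal-theory p-values can underflow to exactly 0; floor before BH
  out$p_adj[seq_along(lv)] <-
    adjust_pvalues(pmax(out$p_value[seq_along(lv)], 1e-300))
  class(out) <- c("ws_contrasts", class(out))
  out[c("group", "contrast", "estimate", "std_error", "statistic",
        "p_value", "p_adj")]
}

r2_pair_ <- function(model) {
  var_fixed <- stats::var(as.vector(
    stats::model.matrix(model) %*% lme4::fixef(model)
  ))
  vc <- as.data.frame(lme4::VarCorr(model))
  var_random <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  total <- var_fixed + var_random + var_resid
  c(marginal = var_fixed / total,
    conditional = (var_fixed + var_random) / total)
}

#' Marginal and conditional R-squared
#'
#' Variance-partition R-squared pair for a mixed model: the marginal value
#' is the fixed-effects variance over the total (fixed + random intercepts
#' + residual); the conditional value adds the random-intercept variance to
#' the numerator.
#'
#' @param fit A `ws_mixed_fit`.
#' @return Named numeric vector `c(marginal, conditional)`.
#' @export
r2_pair <- function(fit) {
  stopifnot(inherits(fit, "ws_mixed_fit"))
  fit$r2
}

#' Benjamini-Hochberg adjustment with bound tokens
#'
#' False-discovery-rate step-up adjustment. Inputs may be numeric p-values
#' in (0, 1] or character bound tokens such as `"<0.0001"`, which are
#' replaced by their upper limit (here 0.0001) before adjustment.
#'
#' @param p Numeric or character vector of p-values / bound tokens.
#' @return Numeric vector of BH-adjusted p-values.
#' @export
#' @examples
#' adjust_pvalues(c("<0.0001", "0.5"))
adjust_pvalues <- function(p) {
  if (is.character(p)) {
    p <- suppressWarnings(as.numeric(sub("^\\s*<\\s*", "", p)))
    if (anyNA(p)) stop("unparseable p-value token.", call. = FALSE)
    # bound tokens already equal their upper limit after stripping "<"
  }
  if (any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Sensitivity analyses for a stage model
#'
#' Refits the stage model under the reported sensitivity variants and
#' summarises whether the timepoint x control interaction survives:
#' adding the initial stress level as a covariate, adding total experiment
#' time, and replacing the domain covariate by its interactions with
#' timepoint and stressor intensity (compared to the base model by AIC/BIC
#' and a likelihood-ratio test on ML refits). Variants whose covariate
#' column is absent are skipped with a message.
#'
#' @param data Stage table as for [fit_stage_model()]; optional columns
#'   `initial_stress` and `total_time` enable those variants.
#' @return A list with `summary` (tibble: variant, estimate/se/p of the
#'   timepoint x control term, AIC, BIC) and `domain_lrt` (the
#'   likelihood-ratio comparison of the domain-interaction model against
#'   the base model, or `NULL`).
#' @export
sensitivity_suite <- function(data) {
  variants <- list(base = NULL)
  for (cov in c("initial_stress", "total_time")) {
    if (cov %in% names(data)) {
      variants[[cov]] <- cov
    } else {
      message("covariate `", cov, "` absent; variant skipped.")
    }
  }
  variants$domain_interaction <-
    c("domain:timepoint", "domain:stressor_intensity")

  fits_ml <- purrr::map(variants, function(extra) {
    fit_stage_model(data, extra_terms = extra, reml = FALSE)
  })
  summary <- purrr::imap_dfr(fits_ml, function(f, nm) {
    row <- dplyr::filter(f$coefficients,
                         .data$term == "timepoint:control_neutral")
    tibble::tibble(
      variant = nm,
      tp_x_control = row$estimate, std_error = row$std_error,
      p_value = row$p_value,
      aic = stats::AIC(f$model), bic = stats::BIC(f$model)
    )
  })
  domain_lrt <- NULL
  if (!is.null(fits_ml$domain_interaction)) {
    an <- stats::anova(fits_ml$base$model, fits_ml$domain_interaction$model)
    domain_lrt <- tibble::tibble(
      chisq = an$Chisq[2], df = an$Df[2], p_value = an$`Pr(>Chisq)`[2]
    )
  }
  list(summary = summary, domain_lrt = domain_lrt)
}
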