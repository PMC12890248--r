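test_that("probe alignment averages the window preceding each stress rating", {
  probes <- tibble::tibble(
    participant_id = "p1",
    kind = c("control", "difficulty", "control", "stress",
             "difficulty", "control", "stress"),
    probe_index = 1:7,
    timepoint = c(NA, NA, NA, 1L, NA, NA, 2L),
    rating = c(40, 70, 60, 55, 30, 20, 80)
  )
  out <- align_probes_to_stress(probes)
  expect_equal(out$control, c(50, 20))      # mean(40, 60); then 20
  expect_equal(out$difficulty, c(70, 30))
  expect_equal(out$stress, c(55, 80))

  # a stress probe with an empty window yields NA and a message
  probes2 <- tibble::tibble(
    participant_id = "p1", kind = c("stress", "control", "stress"),
    probe_index = 1:3, timepoint = c(1L, NA, 2L), rating = c(10, 50, 20)
  )
  expect_message(out2 <- align_probes_to_stress(probes2), "empty")
  expect_true(is.na(out2$control[1]))

  # study-1 cohorts give four aligned rows per participant
  cohort <- simulate_cohort("study1", n = 3, seed = 19)
  aligned <- align_probes_to_stress(cohort$probes)
  expect_true(all(table(aligned$participant_id) == 4))
})

test_that("a zero-variance coupling generator is recovered exactly", {
  d <- simulate_coupling_cohort(
    n = 60, n_timepoints = 4,
    variances = c(residual = 0, participant = 0, timepoint = 0), seed = 3
  )
  fit <- suppressWarnings(
    fit_coupling_model(d, random = "participant")
  )
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "control"], -0.13, tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "difficulty"], 0.38, tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "intercept"], 31.13, tolerance = 1e-6)
})

test_that("coupling fit reports variance components and the R2 pair", {
  d <- simulate_coupling_cohort(n = 250, n_timepoints = 4, seed = 5)
  fit <- fit_coupling_model(d)
  expect_true(all(fit$variance_components >= 0))
  r2 <- r2_pair(fit)
  expect_lt(r2[["marginal"]], r2[["conditional"]])
  expect_gt(r2[["conditional"]], 0.5)

  # all fixed effects zero -> marginal R2 ~ 0
  d0 <- simulate_coupling_cohort(
    n = 150, n_timepoints = 4,
    coefs = c(intercept = 50, control = 0, difficulty = 0), seed = 6
  )
  f0 <- fit_coupling_model(d0)
  expect_lt(r2_pair(f0)[["marginal"]], 0.01)

  expect_error(fit_coupling_model(d, random = "timepoint"), "participant")
  expect_error(fit_coupling_model(d, covariates = "win_rate"), "win_rate")
})

test_that("zero-variance stage data reproduce the generating fixed effects", {
  a <- assign_conditions(295, "study2", seed = 4)
  for (stage in c("induction", "relief")) {
    d <- generate_buffering_dataset(
      a, stage, variances = c(participant = 0, residual = 0), seed = 1
    )
    fit <- suppressWarnings(fit_stage_model(d))
    est <- fit$coefficients
    truth <- stage_coefs(stage)
    for (nm in names(truth)) {
      expect_equal(est$estimate[est$term == nm], unname(truth[nm]),
                   tolerance = 1e-6)
    }
  }
  # missing design cell is a structural error
  d_bad <- generate_buffering_dataset(a, "induction", seed = 2) |>
    dplyr::filter(control_condition != "neutral")
  expect_error(fit_stage_model(d_bad), "empty design cell")
})

test_that("timepoint contrasts follow the printed dummy-coding algebra", {
  a <- assign_conditions(295, "study2", seed = 4)
  d <- generate_buffering_dataset(
    a, "induction", variances = c(participant = 0, residual = 0), seed = 1
  )
  fit <- suppressWarnings(fit_stage_model(d))
  ct <- emm_timepoint_contrasts(fit, by = "control_condition")
  # balanced-grid contrasts: 20.14 - 14.66/2 = 12.81; + 10.92 - 6.28/2 = 20.59
  expect_equal(ct$estimate[ct$group == "high"], 12.81, tolerance = 1e-6)
  expect_equal(ct$estimate[ct$group == "neutral"], 20.59, tolerance = 1e-6)
  expect_equal(ct$estimate[ct$contrast == "difference"], -7.78,
               tolerance = 1e-6)
  # the difference row equals the difference of the group rows exactly
  expect_equal(ct$estimate[3], ct$estimate[1] - ct$estimate[2],
               tolerance = 1e-12)

  cs <- emm_timepoint_contrasts(fit, by = "stressor_intensity")
  expect_equal(cs$estimate[cs$group == "high"], 25.60, tolerance = 1e-6)
  expect_equal(cs$estimate[cs$group == "low"], 7.80, tolerance = 1e-6)
  expect_error(emm_timepoint_contrasts(fit, by = "nope"), "one of")
})

test_that("hand-rolled contrasts agree with emmeans on a noisy fit", {
  skip_if_not_installed("emmeans")
  a <- assign_conditions(200, "study2", seed = 8)
  d <- generate_buffering_dataset(a, "induction", seed = 9)
  fit <- fit_stage_model(d)
  ct <- emm_timepoint_contrasts(fit, by = "control_condition")
  emm <- emmeans::emmeans(fit$model, ~ timepoint | control_condition,
                          at = list(timepoint = c(0, 1)),
                          lmer.df = "asymptotic")
  emc <- summary(emmeans::contrast(emm, method = list("t2-t1" = c(-1, 1))))
  expect_equal(ct$estimate[1:2], emc$estimate, tolerance = 1e-8)
  expect_equal(ct$std_error[1:2], emc$SE, tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up oracle and honours bound tokens", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(0.37), 0.37)
  expect_equal(adjust_pvalues(c("<0.0001", "0.5")),
               stats::p.adjust(c(1e-4, 0.5), method = "BH"))
  withr::with_seed(23, {
    for (rep in 1:20) {
      p <- runif(sample(1:40, 1))
      expect_equal(adjust_pvalues(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
  expect_error(adjust_pvalues(c(0.2, 1.4)), "0, 1")
  expect_error(adjust_pvalues("<abc"), "token")
})

test_that("sensitivity variants keep the buffering term and rank model fit", {
  a <- assign_conditions(240, "study2", seed = 10)
  d <- generate_buffering_dataset(a, "relief", seed = 11)
  d <- d |>
    dplyr::mutate(
      initial_stress = withr::with_seed(12, rep(runif(240, 20, 80), each = 2)),
      total_time = withr::with_seed(13, rep(rnorm(240, 45, 10), each = 2))
    )
  out <- sensitivity_suite(d)
  expect_setequal(out$summary$variant,
                  c("base", "initial_stress", "total_time",
                    "domain_interaction"))
  # the buffering interaction keeps its sign in every variant
  expect_true(all(out$summary$tp_x_control > 0))
  expect_true(all(is.finite(out$summary$aic)))
  expect_false(is.null(out$domain_lrt))
  # domain interactions were generated at zero: the simpler model wins BIC
  expect_lt(out$summary$bic[out$summary$variant == "base"],
            out$summary$bic[out$summary$variant == "domain_interaction"])

  d2 <- dplyr::select(d, -"initial_stress", -"total_time")
  expect_message(out2 <- sensitivity_suite(d2), "skipped")
  expect_setequal(out2$summary$variant, c("base", "domain_interaction"))
})
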