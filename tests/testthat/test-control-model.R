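test_that("regressor preparation log-transforms, z-scores and keeps order", {
  # two trials with increments (e, e^2): log column (1, 2) -> z (-1/sqrt2, 1/sqrt2)
  d <- tibble::tibble(speed = c(1, 2), segment_fraction = c(0.5, 0.9),
                      deceleration_increment = c(exp(1), exp(2)))
  X <- prepare_regressors(d)
  expect_identical(colnames(X), c("deceleration", "segment_size", "speed"))
  expect_equal(unname(X[, "deceleration"]), c(-1, 1) / sqrt(2))

  trials <- toy_trials()
  X <- prepare_regressors(trials)
  expect_true(all(abs(colMeans(X)) < 1e-12))
  expect_equal(unname(apply(X, 2, sd)), c(1, 1, 1))

  # zero-variance column is zeroed with a warning, not dropped
  d2 <- dplyr::mutate(trials, speed = 2)
  expect_warning(X2 <- prepare_regressors(d2), "zero variance")
  expect_equal(unname(X2[, "speed"]), rep(0, nrow(d2)))
  expect_identical(ncol(X2), 3L)

  expect_error(prepare_regressors(trials[1, ]), "2 trials")
  expect_error(prepare_regressors(dplyr::mutate(trials,
                                                deceleration_increment = 0)),
               "positive")
})

test_that("exponential smoothing follows the discount recursion", {
  x <- c(1, -1, 0)
  expect_equal(smooth_regressors(x, 0), x)
  expect_equal(smooth_regressors(x, 0.5), c(1, -0.5, -0.25))
  expect_equal(smooth_regressors(rep(3, 5), 1), 3 * (1:5))
  # two-trial toy from the rating generator: z-scored (1, -1), gamma 0.5
  expect_equal(smooth_regressors(c(1, -1), 0.5), c(1, -0.5))
  m <- cbind(a = c(1, 0, 0), b = c(0, 1, 0))
  expect_equal(smooth_regressors(m, 0.5),
               cbind(a = c(1, 0.5, 0.25), b = c(0, 1, 0.5)))
})

test_that("the linear predictor and MAP objective match hand computation", {
  Xs <- cbind(deceleration = c(1, 0, 0), segment_size = c(0, 1, 0),
              speed = c(0, 0, 1))
  betas <- c(deceleration = 2.33, segment_size = -2.25, speed = -3.09)
  expect_equal(predict_ratings(Xs, betas, 50), c(52.33, 47.75, 46.91))
  expect_equal(predict_ratings(Xs, c(deceleration = 0, segment_size = 0,
                                     speed = 0), 7),
               rep(7, 3))
  expect_error(predict_ratings(Xs, c(1, 2, 3)), "named")

  # perfect predictions, zero betas -> objective 0
  X <- cbind(deceleration = c(0.5, -0.5), segment_size = c(0.5, -0.5),
             speed = c(0.5, -0.5))
  y <- c(10, 10)
  p0 <- list(gamma = 0, betas = c(deceleration = 0, segment_size = 0,
                                  speed = 0), intercept = 10)
  expect_equal(map_objective(p0, X, y), 0)
  # perfect predictions, betas (1,1,1) -> prior cost only
  Xz <- cbind(deceleration = c(0, 0), segment_size = c(0, 0),
              speed = c(0, 0))
  p1 <- list(gamma = 0, betas = c(deceleration = 1, segment_size = 1,
                                  speed = 1), intercept = 10)
  expect_equal(map_objective(p1, Xz, y), -3)
  # one rated trial with residual 2, betas 0 -> -4
  y2 <- c(NA, 12)
  expect_equal(map_objective(p0, X, y2), -4)
  expect_error(map_objective(p0, X, c(NA, NA)), "rated")
})

test_that("the model family enumerates all non-empty regressor subsets", {
  fam <- enumerate_model_family()
  expect_length(fam, 7L)
  sizes <- table(vapply(fam, function(s) length(s$regressors), 1L))
  expect_equal(unname(c(sizes)), c(3L, 3L, 1L))
  expect_true(all(vapply(fam, function(s) length(s$regressors) > 0, TRUE)))
  expect_identical(fam[[1]]$label, "deceleration")
  expect_identical(fam[[7]]$label, "deceleration+segment_size+speed")
})

test_that("noiseless data identify the generating parameters exactly", {
  ns <- noiseless_session()
  fit <- fit_control_model(ns$X, ns$y, n_starts = 5, prior_nu = Inf, seed = 3)
  expect_lt(abs(fit$gamma - ns$truth$gamma), 1e-3)
  expect_lt(max(abs(fit$betas - ns$truth$betas)), 1e-3)
  expect_lt(abs(fit$intercept - ns$truth$intercept), 1e-3)
  expect_equal(fit$r_fitted_actual, 1, tolerance = 1e-9)
})

test_that("the fit is deterministic and its objective self-consistent", {
  ns <- noiseless_session()
  y <- ns$y
  y[ns$idx] <- y[ns$idx] + withr::with_seed(2, rnorm(length(ns$idx), 0, 10))
  f1 <- fit_control_model(ns$X, y, n_starts = 5, seed = 7)
  f2 <- fit_control_model(ns$X, y, n_starts = 5, seed = 7)
  expect_identical(f1[c("gamma", "betas", "intercept", "objective")],
                   f2[c("gamma", "betas", "intercept", "objective")])
  re_eval <- map_objective(list(gamma = f1$gamma, betas = f1$betas,
                                intercept = f1$intercept), ns$X, y)
  expect_lt(abs(f1$objective - re_eval), 1e-8)
})

test_that("with gamma fixed and the prior disabled the fit is least squares", {
  ns <- noiseless_session()
  y <- ns$y
  y[ns$idx] <- y[ns$idx] + withr::with_seed(4, rnorm(length(ns$idx), 0, 8))
  fit <- fit_control_model(ns$X, y, gamma = ns$truth$gamma, prior_nu = Inf,
                           n_starts = 3, seed = 1)
  Xs <- smooth_regressors(ns$X, ns$truth$gamma)
  ols <- lm(y[ns$idx] ~ Xs[ns$idx, ])
  expect_equal(unname(c(fit$intercept, fit$betas)), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("a tighter prior shrinks the betas monotonically", {
  ns <- noiseless_session()
  y <- ns$y
  y[ns$idx] <- y[ns$idx] + withr::with_seed(5, rnorm(length(ns$idx), 0, 8))
  norms <- vapply(c(10, 1, 0.1, 0.01, 0.001), function(nu) {
    f <- fit_control_model(ns$X, y, gamma = ns$truth$gamma, prior_nu = nu,
                           n_starts = 3, seed = 1)
    sum(abs(f$betas))
  }, 1)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5], norms[1] / 10)
})

test_that("BIC uses the profiled-variance convention and breaks ties lexicographically", {
  # equal rss, parameter counts differing by one -> BIC gap log(n)
  expect_equal(bic_gaussian(100, 20, 5) - bic_gaussian(100, 20, 4), log(20))
  # rss floor keeps the criterion finite
  expect_true(is.finite(bic_gaussian(0, 20, 5)))

  fam <- vapply(enumerate_model_family(), `[[`, "", "label")
  fits <- tibble::tibble(participant_id = "p1", model = fam,
                         n_regressors = c(1, 1, 1, 2, 2, 2, 3),
                         bic = rep(5, 7))
  expect_identical(select_best_model(fits)$model, "deceleration")
})

test_that("the full model wins group BIC on data it generated", {
  betas <- c(deceleration = 2.33, segment_size = -2.25, speed = -3.09)
  fits <- purrr::map_dfr(1:12, function(i) {
    sched <- build_session("study2", seed = 100 + i)
    X <- prepare_regressors(sched$trials)
    truth_b <- withr::with_seed(200 + i, rnorm(3, betas, 1.5))
    names(truth_b) <- names(betas)
    pred <- predict_ratings(smooth_regressors(X, 0.4), truth_b, 50)
    idx <- sched$probes$after_trial[sched$probes$kind == "control"]
    y <- rep(NA_real_, nrow(X))
    y[idx] <- pred[idx] + withr::with_seed(300 + i, rnorm(length(idx), 0, 10))
    purrr::map_dfr(enumerate_model_family(), function(spec) {
      f <- suppressWarnings(
        fit_control_model(X, y, regressors = spec$regressors,
                          n_starts = 2, seed = 400 + i)
      )
      tibble::tibble(participant_id = paste0("p", i), model = spec$label,
                     n_regressors = length(spec$regressors), bic = f$bic)
    })
  })
  expect_identical(select_best_model(fits)$model,
                   "deceleration+segment_size+speed")
})

test_that("fitted-actual correlation behaves at the extremes", {
  ns <- noiseless_session()
  fit <- fit_control_model(ns$X, ns$y, n_starts = 3, prior_nu = Inf, seed = 2)
  expect_equal(fitted_actual_correlation(fit), 1, tolerance = 1e-9)
  # anti-correlated ratings
  y_neg <- ns$y
  y_neg[ns$idx] <- 100 - ns$y[ns$idx]
  fit_neg <- suppressWarnings(
    fit_control_model(ns$X, y_neg, gamma = ns$truth$gamma, prior_nu = Inf,
                      n_starts = 3, seed = 2)
  )
  # refitting flips the betas, so predictions track the flipped ratings
  expect_equal(fit_neg$r_fitted_actual, 1, tolerance = 1e-9)
  expect_equal(unname(fit_neg$betas), unname(-ns$truth$betas),
               tolerance = 1e-6)
  expect_error(fit_control_model(ns$X, ns$y, regressors = "speed",
                                 n_starts = 32, seed = 1,
                                 rating_mask = c(TRUE, TRUE, TRUE,
                                                 rep(FALSE, nrow(ns$X) - 3))),
               "rated trials")
})

test_that("parameter recovery is exact without noise and flags degenerate runs", {
  rec <- suppressWarnings(
    recover_parameters(n_participants = 3, noise_sd = 0, n_starts = 3,
                       prior_nu = Inf, seed = 5)
  )
  expect_lt(max(abs(rec$report$bias)), 1e-3)
  expect_identical(rec$n_failed, 0L)

  expect_warning(
    rec1 <- recover_parameters(n_participants = 1, noise_sd = 5,
                               n_starts = 2, seed = 6),
    "unstable"
  )
  expect_true(rec1$unstable)
})
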