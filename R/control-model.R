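#' Build the z-scored regressor matrix from trial parameters
#'
#' Turns a sequence of trial parameters into the three model regressors, in
#' the fixed column order `deceleration`, `segment_size`, `speed`.
#' Deceleration increments are natural-log transformed before
#' standardisation (their raw scale is strongly right-skewed); all columns
#' are then z-scored per participant over that participant's trials
#' (denominator `n - 1`). A zero-variance column is set to all zeros with a
#' warning rather than dropped, so the column order stays stable.
#'
#' @param trials Data frame with one row per trial and columns `speed`,
#'   `segment_fraction`, `deceleration_increment` (all increments > 0).
#' @return A numeric matrix (trials x 3) with columns `deceleration`,
#'   `segment_size`, `speed`.
#' @export
prepare_regressors <- function(trials) {
  stopifnot(all(c("speed", "segment_fraction", "deceleration_increment")
                %in% names(trials)))
  if (nrow(trials) < 2L) stop("need at least 2 trials.", call. = FALSE)
  if (any(trials$deceleration_increment <= 0)) {
    stop("deceleration increments must be positive.", call. = FALSE)
  }
  zsafe <- function(x, label) {
    s <- stats::sd(x)
    if (s == 0) {
      warning("zero variance in ", label, " regressor; column set to 0.",
              call. = FALSE)
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  cbind(
    deceleration = zsafe(log(trials$deceleration_increment), "deceleration"),
    segment_size = zsafe(trials$segment_fraction, "segment_size"),
    speed = zsafe(trials$speed, "speed")
  )
}

#' Exponentially smooth regressors
#'
#' Applies the recursive discount `xs[t] = x[t] + gamma * xs[t - 1]` down
#' each column, with `xs[1] = x[1]`. With `gamma = 0` the input is returned
#' unchanged; with `gamma = 1` each column becomes its cumulative sum.
#'
#' @param X Numeric matrix or vector of regressors (trials in rows).
#' @param gamma Discount weight applied to the running average.
#' @return Smoothed matrix (or vector) of the same shape.
#' @export
smooth_regressors <- function(X, gamma) {
  stopifnot(is.finite(gamma))
  out <- stats::filter(X, gamma, method = "recursive")
  if (is.matrix(X)) {
    attributes(out) <- list(dim = dim(X), dimnames = dimnames(X))
  } else {
    attributes(out) <- NULL
  }
  out
}

# d xs / d gamma, also a recursive filter of the lagged smoothed series
smooth_gradient <- function(Xs, gamma) {
  lagged <- rbind(0, Xs[-nrow(Xs), , drop = FALSE])
  out <- stats::filter(lagged, gamma, method = "recursive")
  attributes(out) <- list(dim = dim(Xs))
  out
}

#' Predicted control ratings
#'
#' Linear prediction from smoothed regressors: the weighted sum of the
#' included regressors plus the intercept. Predictions are not clipped to
#' the 0-100 slider range.
#'
#' @param Xs Smoothed regressor matrix (from [smooth_regressors()]).
#' @param betas Named numeric vector of weights; names select columns of
#'   `Xs`.
#' @param intercept Intercept in slider units.
#' @return Numeric vector of per-trial predictions.
#' @export
predict_ratings <- function(Xs, betas, intercept = 0) {
  if (is.null(names(betas)) || !all(names(betas) %in% colnames(Xs))) {
    stop("`betas` must be named after columns of `Xs`.", call. = FALSE)
  }
  drop(Xs[, names(betas), drop = FALSE] %*% betas) + intercept
}

#' MAP objective for the control-rating model
#'
#' The (to-be-maximised) log-posterior up to a constant: the negative sum of
#' squared prediction errors over rated trials from the second trial
#' onward, minus a Gaussian penalty `sum((beta - prior_mu)^2 / prior_nu)` on
#' the regressor weights. The intercept and the smoothing weight `gamma` are
#' unpenalised.
#'
#' @param params List with `gamma`, `betas` (named), `intercept`.
#' @param X Z-scored (unsmoothed) regressor matrix.
#' @param ratings Numeric vector of ratings, `NA` at unrated trials (or a
#'   full vector used with `rating_mask`).
#' @param rating_mask Logical vector marking rated trials; defaults to
#'   `!is.na(ratings)`.
#' @param prior_mu,prior_nu Gaussian prior mean and variance on each beta.
#' @return The objective value (a scalar; larger is better).
#' @export
map_objective <- function(params, X, ratings, rating_mask = NULL,
                          prior_mu = 0, prior_nu = 1) {
  if (is.null(rating_mask)) rating_mask <- !is.na(ratings)
  idx <- which(rating_mask)
  idx <- idx[idx >= 2L]
  if (length(idx) == 0L) stop("no rated trials at t >= 2.", call. = FALSE)
  Xs <- smooth_regressors(X, params$gamma)
  pred <- predict_ratings(Xs, params$betas, params$intercept)
  -sum((ratings[idx] - pred[idx])^2) -
    sum((params$betas - prior_mu)^2 / prior_nu)
}

#' Enumerate the model family
#'
#' All seven non-empty subsets of the three regressors, each with a
#' smoothing weight and an intercept. Specs are ordered by subset size and
#' then lexicographically (also the documented tie-break order).
#'
#' @return A list of 7 model specs, each a list with `regressors` (character
#'   vector) and `label`.
#' @export
enumerate_model_family <- function() {
  regs <- c("deceleration", "segment_size", "speed")
  subsets <- unlist(lapply(1:3, function(k) {
    utils::combn(regs, k, simplify = FALSE)
  }), recursive = FALSE)
  lapply(subsets, function(s) list(regressors = s,
                                   label = paste(s, collapse = "+")))
}

#' Fit the control-rating model for one participant
#'
#' Maximises the MAP objective over `gamma`, the selected regressor weights
#' and the intercept by multi-start unconstrained quasi-Newton optimisation
#' (BFGS with an analytic gradient). Start values are jittered: betas from
#' N(0, 1), the intercept from N(mean rating, 10), gamma from U(0, 0.9);
#' the best converged start wins. `gamma` is unconstrained; a warning is
#' emitted when the optimum falls outside [0, 1].
#'
#' @inheritParams map_objective
#' @param regressors Character vector naming the regressor subset to fit
#'   (default: all three columns of `X`).
#' @param n_starts Number of optimisation starts (default 10).
#' @param prior_nu Gaussian prior variance on the betas; `Inf` disables the
#'   penalty (ordinary least squares limit).
#' @param gamma Optional fixed smoothing weight: when supplied, `gamma` is
#'   held at this value and only betas and intercept are optimised.
#' @param seed Integer seed making the start jitter reproducible.
#' @return An object of class `ws_control_fit`: a list with `gamma`,
#'   `betas`, `intercept`, `objective`, `rss`, `n_obs`, `k`, `bic`,
#'   `r_fitted_actual`, `n_starts_converged`, and `regressors`.
#' @export
fit_control_model <- function(X, ratings, rating_mask = NULL,
                              regressors = colnames(X),
                              n_starts = 10L,
                              prior_mu = 0, prior_nu = 1,
                              gamma = NULL, seed = 1L) {
  if (is.null(rating_mask)) rating_mask <- !is.na(ratings)
  idx <- which(rating_mask)
  idx <- idx[idx >= 2L]
  n_obs <- length(idx)
  k <- length(regressors) + 1L + if (is.null(gamma)) 1L else 0L
  if (n_obs <= k) {
    stop("need more rated trials (", n_obs, ") than parameters (", k, ").",
         call. = FALSE)
  }
  y <- ratings[idx]
  Xr <- X[, regressors, drop = FALSE]
  p <- length(regressors)
  fixed_gamma <- !is.null(gamma)
  penal <- if (is.infinite(prior_nu)) 0 else 1 / prior_nu

  unpack <- function(par) {
    if (fixed_gamma) list(gamma = gamma, betas = par[seq_len(p)],
                          intercept = par[p + 1L])
    else list(gamma = par[1L], betas = par[1L + seq_len(p)],
              intercept = par[p + 2L])
  }
  fn <- function(par) {
    pp <- unpack(par)
    Xs <- smooth_regressors(Xr, pp$gamma)
    r <- y - drop(Xs[idx, , drop = FALSE] %*% pp$betas) - pp$intercept
    val <- sum(r^2) + penal * sum((pp$betas - prior_mu)^2)
    # |gamma| >> 1 makes the recursion blow up; keep the surface finite
    if (!is.finite(val)) val <- .Machine$double.xmax / 1e10
    val
  }
  gr <- function(par) {
    pp <- unpack(par)
    Xs <- smooth_regressors(Xr, pp$gamma)
    r <- y - drop(Xs[idx, , drop = FALSE] %*% pp$betas) - pp$intercept
    g_beta <- -2 * drop(crossprod(Xs[idx, , drop = FALSE], r)) +
      2 * penal * (pp$betas - prior_mu)
    g_int <- -2 * sum(r)
    g <- if (fixed_gamma) {
      c(g_beta, g_int)
    } else {
      D <- smooth_gradient(Xs, pp$gamma)
      c(-2 * sum(r * drop(D[idx, , drop = FALSE] %*% pp$betas)),
        g_beta, g_int)
    }
    ifelse(is.finite(g), g, 0)
  }

  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      st <- c(stats::rnorm(p), stats::rnorm(1, mean(y), 10))
      if (!fixed_gamma) st <- c(stats::runif(1, 0, 0.9), st)
      st
    })
  })

  best <- NULL
  converged <- 0L
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, fn, gr, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (opt$convergence == 0L) converged <- converged + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || converged == 0L) {
    stop("no optimisation start converged (", n_starts, " attempted).",
         call. = FALSE)
  }

  pp <- unpack(best$par)
  names(pp$betas) <- regressors
  if (pp$gamma < 0 || pp$gamma > 1) {
    warning("fitted gamma = ", signif(pp$gamma, 4), " outside [0, 1].",
            call. = FALSE)
  }
  Xs <- smooth_regressors(Xr, pp$gamma)
  pred <- drop(Xs[idx, , drop = FALSE] %*% pp$betas) + pp$intercept
  rss <- sum((y - pred)^2)
  r <- if (stats::sd(pred) == 0 || stats::sd(y) == 0) NA_real_
       else stats::cor(pred, y)

  structure(
    list(
      gamma = pp$gamma, betas = pp$betas, intercept = pp$intercept,
      objective = -best$value, rss = rss, n_obs = n_obs, k = k,
      bic = bic_gaussian(rss, n_obs, k),
      r_fitted_actual = r, n_starts_converged = converged,
      regressors = regressors,
      prior_mu = prior_mu, prior_nu = prior_nu,
      fitted = pred, observed = y, trial_index = idx
    ),
    class = "ws_control_fit"
  )
}

#' Gaussian profiled-variance BIC
#'
#' `n * log(rss / n) + k * log(n)`, the Bayesian Information Criterion for a
#' Gaussian regression with the residual variance profiled out. A zero (or
#' numerically zero) residual sum of squares is floored at `rss_floor` so
#' the criterion stays finite.
#'
#' @param rss Residual sum of squares over the rated trials.
#' @param n Number of rated observations.
#' @param k Number of free parameters (betas + intercept + gamma).
#' @param rss_floor Lower bound applied to `rss` (default 1e-10).
#' @return The BIC value.
#' @export
bic_gaussian <- function(rss, n, k, rss_floor = 1e-10) {
  n * log(max(rss, rss_floor) / n) + k * log(n)
}

#' @export
print.ws_control_fit <- function(x, ...) {
  cat("<ws_control_fit> regressors:", paste(x$regressors, collapse = "+"), "\n")
  cat("  gamma =", signif(x$gamma, 4),
      " intercept =", signif(x$intercept, 4), "\n")
  print(signif(x$betas, 4))
  cat("  n_obs =", x$n_obs, " BIC =", signif(x$bic, 6),
      " r(fitted, actual) =", signif(x$r_fitted_actual, 3), "\n")
  invisible(x)
}

#' Fit the full model family across participants
#'
#' Fits each of the seven regressor-subset models to every participant and
#' returns one row per participant x model.
#'
#' @param data Long trial table containing `participant_id`, the trial
#'   parameter columns (`speed`, `segment_fraction`,
#'   `deceleration_increment`) ordered by trial, and a `rating` column with
#'   `NA` at unrated trials.
#' @param n_starts,prior_mu,prior_nu,seed Passed to [fit_control_model()];
#'   each participant gets a seed offset for distinct start jitter.
#' @return A tibble with columns `participant_id`, `model`, `n_regressors`,
#'   `gamma`, `intercept`, beta columns (NA when a regressor is not in the
#'   model), `objective`, `rss`, `n_obs`, `k`, `bic`, `r_fitted_actual`.
#' @export
fit_control_models <- function(data, n_starts = 10L,
                               prior_mu = 0, prior_nu = 1, seed = 1L) {
  stopifnot("participant_id" %in% names(data), "rating" %in% names(data))
  family <- enumerate_model_family()
  split_data <- split(data, data$participant_id)
  purrr::imap_dfr(split_data, function(d, pid) {
    X <- prepare_regressors(d)
    purrr::map_dfr(family, function(spec) {
      fit <- fit_control_model(
        X, d$rating, regressors = spec$regressors, n_starts = n_starts,
        prior_mu = prior_mu, prior_nu = prior_nu,
        seed = seed + match(pid, names(split_data))
      )
      tibble::tibble(
        participant_id = pid, model = spec$label,
        n_regressors = length(spec$regressors),
        gamma = fit$gamma, intercept = fit$intercept,
        deceleration = unname(fit$betas["deceleration"]),
        segment_size = unname(fit$betas["segment_size"]),
        speed = unname(fit$betas["speed"]),
        objective = fit$objective, rss = fit$rss, n_obs = fit$n_obs,
        k = fit$k, bic = fit$bic, r_fitted_actual = fit$r_fitted_actual
      )
    })
  })
}

#' Select the group-level winning model
#'
#' Sums each model's BIC over participants and returns the model with the
#' lowest total. Ties are broken by the smaller parameter count, then by
#' the family's lexicographic order.
#'
#' @param fits Output of [fit_control_models()] (must cover every model for
#'   every participant).
#' @return A one-row tibble with `model`, `n_regressors`, `total_bic`.
#' @export
select_best_model <- function(fits) {
  family_order <- vapply(enumerate_model_family(), `[[`, "", "label")
  totals <- fits |>
    dplyr::summarise(total_bic = sum(.data$bic),
                     n_regressors = .data$n_regressors[1],
                     .by = "model") |>
    dplyr::mutate(rank_in_family = match(.data$model, family_order)) |>
    dplyr::arrange(.data$total_bic, .data$n_regressors, .data$rank_in_family)
  totals[1, c("model", "n_regressors", "total_bic")]
}

#' Correlation between fitted and observed ratings
#'
#' Pearson correlation between a fit's predictions and the observed ratings
#' at rated trials. Returns `NA` (with a message in the fit) when the
#' predictions have zero variance.
#'
#' @param fit A `ws_control_fit`.
#' @return A correlation in `[-1, 1]`, or `NA`.
#' @export
fitted_actual_correlation <- function(fit) {
  stopifnot(inherits(fit, "ws_control_fit"))
  if (fit$n_obs < 3L) stop("need at least 3 rated trials.", call. = FALSE)
  fit$r_fitted_actual
}
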