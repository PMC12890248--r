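#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted control-rating model
#'
#' @param x A `ws_control_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @method tidy ws_control_fit
#' @export
tidy.ws_control_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", names(x$betas), "intercept"),
    estimate = c(x$gamma, unname(x$betas), x$intercept)
  )
}

#' @rdname tidy.ws_control_fit
#' @method glance ws_control_fit
#' @export
glance.ws_control_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, k = x$k, rss = x$rss, objective = x$objective,
    bic = x$bic, r_fitted_actual = x$r_fitted_actual,
    n_starts_converged = x$n_starts_converged
  )
}

#' Tidy a mixed-model fit
#'
#' @param x A `ws_mixed_fit`.
#' @param ... Unused.
#' @return The Wald coefficient table (term, estimate, std_error, ci_low,
#'   ci_high, statistic, p_value).
#' @method tidy ws_mixed_fit
#' @export
tidy.ws_mixed_fit <- function(x, ...) x$coefficients

#' @rdname tidy.ws_mixed_fit
#' @method glance ws_mixed_fit
#' @export
glance.ws_mixed_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_participants = unname(x$n_groups["participant_id"]),
    sigma2 = unname(x$variance_components[["residual"]]),
    r2_marginal = unname(x$r2[["marginal"]]),
    r2_conditional = unname(x$r2[["conditional"]]),
    aic = stats::AIC(x$model), bic = stats::BIC(x$model)
  )
}

#' Tidy an ICC result
#'
#' @param x A `ws_icc`.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, CI, F test and mean squares.
#' @method tidy ws_icc
#' @export
tidy.ws_icc <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
    f_stat = x$f_stat, df1 = x$df1, df2 = x$df2, p_value = x$p_value,
    ms_rows = x$ms_rows, ms_columns = x$ms_columns, ms_error = x$ms_error,
    n_subjects = x$n_subjects
  )
}
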