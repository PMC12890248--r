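#' Split a rating sequence into two halves per participant
#'
#' Builds the per-participant half means used for split-half internal
#' consistency. `odd_even` takes the mean of the odd-indexed and of the
#' even-indexed sliders (1-based, in chronological order); `first_second`
#' splits the sequence in the middle, assigning the middle element of an
#' odd-length sequence to the first half. Participants with fewer than two
#' ratings are excluded with a warning.
#'
#' @param data Data frame with columns `participant_id` and `rating`, rows
#'   in chronological order within participant.
#' @param scheme `"odd_even"` or `"first_second"`.
#' @return A tibble with `participant_id`, `half_a`, `half_b`, `n_ratings`.
#' @export
#' @examples
#' d <- tibble::tibble(participant_id = "p1", rating = c(10, 20, 30, 40))
#' split_halves(d, "odd_even")     # halves 20 and 30
#' split_halves(d, "first_second") # halves 15 and 35
split_halves <- function(data, scheme = c("odd_even", "first_second")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("participant_id", "rating") %in% names(data)))
  out <- data |>
    dplyr::filter(!is.na(.data$rating)) |>
    dplyr::summarise(
      n_ratings = dplyr::n(),
      half_a = if (scheme == "odd_even") {
        mean(.data$rating[seq_along(.data$rating) %% 2 == 1])
      } else {
        mean(.data$rating[seq_len(ceiling(dplyr::n() / 2))])
      },
      half_b = if (scheme == "odd_even") {
        mean(.data$rating[seq_along(.data$rating) %% 2 == 0])
      } else {
        mean(.data$rating[-seq_len(ceiling(dplyr::n() / 2))])
      },
      .by = "participant_id"
    )
  dropped <- out$n_ratings < 2L
  if (any(dropped)) {
    warning(sum(dropped), " participant(s) with < 2 ratings excluded.",
            call. = FALSE)
    out <- out[!dropped, ]
  }
  out[c("participant_id", "half_a", "half_b", "n_ratings")]
}

#' Intraclass correlation ICC(A,1)
#'
#' Single-measure absolute-agreement intraclass correlation from the
#' two-way (subjects x measurements) ANOVA mean squares:
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))`
#' with `k = 2` measurement columns. Unlike a Pearson correlation it is
#' sensitive to mean offsets between the two halves. The F statistic and
#' the confidence interval use the absolute-agreement formulas with a
#' Satterthwaite denominator degrees-of-freedom.
#'
#' @param halves Output of [split_halves()] (columns `half_a`, `half_b`),
#'   or any data frame with those two columns; rows with a missing half are
#'   dropped.
#' @param alpha Two-sided confidence level is `1 - alpha` (default 0.05).
#' @return An object of class `ws_icc`: a list with `icc`, `ci_low`,
#'   `ci_high`, `f_stat`, `df1`, `df2`, `p_value`, `ms_rows`, `ms_columns`,
#'   `ms_error`, `n_subjects`, `k`.
#' @export
icc_a1 <- function(halves, alpha = 0.05) {
  stopifnot(all(c("half_a", "half_b") %in% names(halves)))
  m <- as.matrix(halves[c("half_a", "half_b")])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L) stop("need at least 3 subjects.", call. = FALSE)

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # F tests rho = 0 (null weights a = 0, b = 1, so F = MSR/MSE); the
  # Satterthwaite denominator df is evaluated at the estimated ICC
  f_stat <- msr / mse
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  df1 <- n - 1
  df2 <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  p_value <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)

  f_l <- stats::qf(1 - alpha / 2, df1, df2)
  f_u <- stats::qf(1 - alpha / 2, df2, df1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  structure(
    list(icc = icc, ci_low = ci_low, ci_high = ci_high,
         f_stat = f_stat, df1 = df1, df2 = df2, p_value = p_value,
         ms_rows = msr, ms_columns = msc, ms_error = mse,
         n_subjects = n, k = k, alpha = alpha),
    class = "ws_icc"
  )
}

#' @export
print.ws_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%d%% CI: %.3f, %.3f], F(%d, %.1f) = %.2f, p = %.3g\n",
              x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}

#' Split-half internal consistency of cohort ratings
#'
#' Convenience wrapper: for each rating kind in a cohort probe table,
#' splits each participant's chronological slider sequence into halves and
#' computes ICC(A,1).
#'
#' @param probes Cohort probe table (columns `participant_id`, `kind`,
#'   `rating`, ordered within participant).
#' @param kinds Rating kinds to assess (default all present).
#' @param scheme Passed to [split_halves()].
#' @param alpha Passed to [icc_a1()].
#' @return A tibble with one row per kind: `kind`, `scheme`, `icc`,
#'   `ci_low`, `ci_high`, `f_stat`, `df1`, `df2`, `p_value`, `n_subjects`.
#' @export
icc_split_half <- function(probes, kinds = NULL,
                           scheme = c("odd_even", "first_second"),
                           alpha = 0.05) {
  scheme <- match.arg(scheme)
  if (is.null(kinds)) kinds <- unique(probes$kind)
  purrr::map_dfr(kinds, function(kd) {
    halves <- split_halves(probes[probes$kind == kd, ], scheme)
    res <- icc_a1(halves, alpha)
    tibble::tibble(kind = kd, scheme = scheme, icc = res$icc,
                   ci_low = res$ci_low, ci_high = res$ci_high,
                   f_stat = res$f_stat, df1 = res$df1, df2 = res$df2,
                   p_value = res$p_value, n_subjects = res$n_subjects)
  })
}
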