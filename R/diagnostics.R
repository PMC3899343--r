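#' ANOVA partition for a (nonlinear) regression fit
#'
#' Sums of squares about the observed mean: total
#' \eqn{\sum (y_i-\bar y)^2} on `n - 1` degrees of freedom, model
#' \eqn{\sum (\hat y_i - \bar y)^2} on `p`, and error
#' \eqn{\sum (y_i - \hat y_i)^2} on `n - p`.  For a nonlinear model the
#' three sums need not be exactly additive; they are reported as defined,
#' never reconciled.  The F statistic is the ratio of model to error mean
#' squares with an upper-tail p-value from the F(`p`, `n - p`)
#' distribution.  A perfect fit (zero error SS) reports `F = Inf` with an
#' `exact_fit` flag.
#'
#' @param observed,fitted numeric vectors of equal length.
#' @param p number of free model parameters (`n > p`).
#' @return An object of class `"anova_table"`.
#' @export
anova_table <- function(observed, fitted, p) {
  if (length(observed) != length(fitted)) stop("length mismatch")
  n <- length(observed)
  if (n <= p) stop("need n > p")
  ybar <- mean(observed)
  ss_total <- sum((observed - ybar)^2)
  ss_model <- sum((fitted - ybar)^2)
  ss_error <- sum((observed - fitted)^2)
  anova_from_ss(ss_total, ss_model, ss_error,
                df_total = n - 1L, df_model = p, df_error = n - p)
}

#' @rdname anova_table
#' @param ss_total,ss_model,ss_error sums of squares (>= 0).
#' @param df_total,df_model,df_error their degrees of freedom.
#' @details `anova_from_ss()` assembles the same table directly from
#'   sums of squares and degrees of freedom, e.g. to recompute the
#'   derived columns (mean squares, F, p) of a published ANOVA table.
#' @export
anova_from_ss <- function(ss_total, ss_model, ss_error,
                          df_total, df_model, df_error) {
  if (min(ss_total, ss_model, ss_error) < 0) stop("negative sum of squares")
  ms_total <- ss_total / df_total
  ms_model <- ss_model / df_model
  ms_error <- ss_error / df_error
  exact_fit <- ss_error == 0
  f_stat <- if (exact_fit) Inf else ms_model / ms_error
  p_value <- if (exact_fit) 0 else
    stats::pf(f_stat, df_model, df_error, lower.tail = FALSE)
  structure(list(ss_total = ss_total, ss_model = ss_model,
                 ss_error = ss_error, df_total = df_total,
                 df_model = df_model, df_error = df_error,
                 ms_total = ms_total, ms_model = ms_model,
                 ms_error = ms_error, f_stat = f_stat,
                 p_value = p_value, exact_fit = exact_fit),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  tab <- data.frame(
    Source = c("Total", "Model", "Error"),
    SS = signif(c(x$ss_total, x$ss_model, x$ss_error), 5),
    df = c(x$df_total, x$df_model, x$df_error),
    MS = signif(c(x$ms_total, x$ms_model, x$ms_error), 6),
    F = c("", format(round(x$f_stat, 2)), ""),
    `P-value` = c("", format(signif(x$p_value, 6)), ""),
    check.names = FALSE)
  print(tab, row.names = FALSE)
  if (x$exact_fit) cat("(exact fit: zero error sum of squares)\n")
  invisible(x)
}

#' Model R-squared from an ANOVA partition
#'
#' The proportion of the total sum of squares captured by the model,
#' `ss_model / ss_total`, returned on the percentage scale (multiply by
#' 100; report to 2 decimal places).
#'
#' @param anova an [anova_table()].
#' @return R-squared as a percentage.
#' @export
model_r2 <- function(anova) {
  stopifnot(inherits(anova, "anova_table"))
  if (anova$ss_total <= 0) stop("zero total sum of squares")
  100 * anova$ss_model / anova$ss_total
}

#' Durbin-Watson statistic for residual autocorrelation
#'
#' \eqn{DW = \sum_{i \ge 2} (e_i - e_{i-1})^2 / \sum_i e_i^2}, near 2 for
#' uncorrelated residuals and near 0 under strong positive
#' autocorrelation.  When a grouping is supplied (residuals ordered field
#' by field), successive differences are taken within groups only: the
#' jump between the last residual of one field and the first of the next
#' does not contribute.  The one-sided p-value for positive
#' autocorrelation uses the large-sample normal approximation
#' `DW ~ N(2, 4/n)`; it is a screening value, not an exact Durbin-Watson
#' bound, and is flagged as approximate in the output.
#'
#' @param residuals numeric vector (length >= 3, not all zero).
#' @param groups optional grouping vector (e.g. field ids) of the same
#'   length; residuals must already be ordered by group then time.
#' @return A list of class `"dw_test"`: `statistic`, `p_value`,
#'   `n`, `n_diffs`, `approximation = "normal"`.
#' @examples
#' durbin_watson(c(1, 2, 0, -1, 1))$statistic  # 10/7
#' @export
durbin_watson <- function(residuals, groups = NULL) {
  n <- length(residuals)
  if (n < 3L) stop("need at least 3 residuals")
  if (all(residuals == 0)) stop("all-zero residuals")
  if (is.null(groups)) groups <- rep(1L, n)
  if (length(groups) != n) stop("groups length mismatch")
  same <- groups[-1] == groups[-n]
  d <- diff(residuals)[same]
  dw <- sum(d^2) / sum(residuals^2)
  z <- (dw - 2) / sqrt(4 / n)
  structure(list(statistic = dw, p_value = stats::pnorm(z),
                 n = n, n_diffs = sum(same), approximation = "normal"),
            class = "dw_test")
}

#' @export
print.dw_test <- function(x, ...) {
  cat("Durbin-Watson DW =", format(x$statistic, digits = 4),
      " one-sided P(positive autocorrelation) =",
      format(signif(x$p_value, 3)),
      "(normal approximation, n =", paste0(x$n, ")"), "\n")
  invisible(x)
}

#' Bisector R-squared: prediction quality without refitting
#'
#' Residuals are taken from the bisector (the line observed = predicted),
#' so the predictions are judged as-is:
#' \deqn{R^2 = 1 - \frac{\sum (y_i - \hat y_i)^2 / (N-1)}
#'                      {\sum (y_i - \bar y)^2 / (N-1)}.}
#' Both sums carry the same `N - 1` degrees-of-freedom correction (no
#' parameters are estimated from the validation data), so the correction
#' cancels; perfect prediction gives exactly 1, predicting the observed
#' mean gives 0, and the index can be negative for predictions worse than
#' the mean.
#'
#' @param observed,predicted numeric vectors, equal length >= 2;
#'   `observed` must not be constant.
#' @return The index (dimensionless, <= 1).
#' @export
bisector_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2L) stop("need at least 2 cases")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("constant observed vector")
  1 - sum((observed - predicted)^2) / sst
}

#' Origin-constrained regression of observed on predicted
#'
#' Least-squares slope of observed on predicted through the origin,
#' \eqn{\sum y_i \hat y_i / \sum \hat y_i^2}; a slope near 1 indicates
#' unbiased prediction.  The R-squared of the constrained line is
#' computed against the observed mean, on the same scale as
#' [bisector_r2()].
#'
#' @param observed,predicted numeric vectors; `sum(predicted^2) > 0`.
#' @return List with `slope` and `r2`.
#' @export
origin_regression <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (sum(predicted^2) == 0) stop("all-zero predictions")
  slope <- sum(observed * predicted) / sum(predicted^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- 1 - sum((observed - slope * predicted)^2) / sst
  list(slope = slope, r2 = r2)
}

#' Sign-error matrix of predicted population direction
#'
#' Cross-classifies the sign of the observed and predicted RGR: a sign
#' error means the model predicts a growing population when it actually
#' declines, or vice versa.  Exact zeros count as positive by default (a
#' flat population is not a decline); set `zero = "negative"` to flip the
#' convention.
#'
#' @param observed,predicted numeric vectors of equal, positive length.
#' @param zero how to classify exact zeros: `"positive"` (default) or
#'   `"negative"`.
#' @return An object of class `"sign_error_matrix"`: `counts` (2 x 2
#'   matrix, rows = observed sign, columns = predicted sign),
#'   `error_rate` (proportion of off-diagonal cases), `n_errors`, `n`.
#' @export
sign_error_matrix <- function(observed, predicted,
                              zero = c("positive", "negative")) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) == 0L) stop("empty input")
  zero <- match.arg(zero)
  cls <- function(x) {
    pos <- if (zero == "positive") x >= 0 else x > 0
    factor(ifelse(pos, "positive", "negative"),
           levels = c("positive", "negative"))
  }
  counts <- table(observed = cls(observed), predicted = cls(predicted))
  counts <- unclass(counts)
  sign_error_from_counts(counts["positive", "positive"],
                         counts["positive", "negative"],
                         counts["negative", "positive"],
                         counts["negative", "negative"])
}

#' @rdname sign_error_matrix
#' @param pos_pos,pos_neg,neg_pos,neg_neg cell counts, indexed observed
#'   sign then predicted sign; `sign_error_from_counts()` assembles the
#'   matrix directly from them (e.g. from a published error matrix).
#' @export
sign_error_from_counts <- function(pos_pos, pos_neg, neg_pos, neg_neg) {
  counts <- matrix(c(pos_pos, neg_pos, pos_neg, neg_neg), 2, 2,
                   dimnames = list(observed = c("positive", "negative"),
                                   predicted = c("positive", "negative")))
  if (any(counts < 0)) stop("negative cell count")
  n <- sum(counts)
  if (n == 0) stop("empty matrix")
  n_err <- counts["positive", "negative"] + counts["negative", "positive"]
  structure(list(counts = counts, error_rate = n_err / n,
                 n_errors = n_err, n = n),
            class = "sign_error_matrix")
}

#' @export
print.sign_error_matrix <- function(x, ...) {
  print(x$counts)
  cat(sprintf("%d sign errors of %d cases (%.2f%%)\n",
              x$n_errors, x$n, 100 * x$error_rate))
  invisible(x)
}

#' Location and skewness summary of residuals
#'
#' Arithmetic mean, median and the adjusted Fisher-Pearson sample
#' skewness (the `type = 2` estimator of [e1071::skewness()]): mean and
#' median near zero indicate unbiased prediction on average, while
#' nonzero skewness flags asymmetric errors.
#'
#' @param residuals numeric vector, length >= 3.
#' @return List with `mean`, `median`, `skewness`, `n`.
#' @export
residual_summary <- function(residuals) {
  if (length(residuals) < 3L) stop("need at least 3 residuals")
  list(mean = mean(residuals), median = stats::median(residuals),
       skewness = e1071::skewness(residuals, type = 2),
       n = length(residuals))
}

#' Held-out validation report for RGR predictions
#'
#' Summarises how well fixed parameters predict an independent set of
#' observed RGR values: the bisector R-squared, the origin-constrained
#' regression slope and R-squared, residual location/skewness, and the
#' sign-error matrix.
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @return An object of class `"validation_report"`.
#' @export
validate_predictions <- function(observed, predicted) {
  res <- observed - predicted
  orig <- origin_regression(observed, predicted)
  structure(list(n = length(observed),
                 r2_bisector = bisector_r2(observed, predicted),
                 origin_slope = orig$slope, origin_r2 = orig$r2,
                 residuals = residual_summary(res),
                 sign_errors = sign_error_matrix(observed, predicted)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation on", x$n, "held-out cases\n")
  cat(sprintf("  bisector R2        %.2f%%\n", 100 * x$r2_bisector))
  cat(sprintf("  origin slope / R2  %.3f / %.2f%%\n",
              x$origin_slope, 100 * x$origin_r2))
  cat(sprintf("  residual mean/median/skewness  %.4g / %.4g / %.3g\n",
              x$residuals$mean, x$residuals$median, x$residuals$skewness))
  print(x$sign_errors)
  invisible(x)
}
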