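#' Intraclass correlation for inter-observer agreement
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC — ICC(2,1)
#' in the Shrout-Fleiss nomenclature, ICC(A,1) in McGraw-Wong — computed
#' from the two-way ANOVA mean squares of a complete subjects x readers
#' table, with the F-based (Satterthwaite) 95% confidence interval. The
#' consistency form ICC(3,1)/ICC(C,1) is available as an option.
#'
#' The agreement band follows the conventional clinical cut-offs: poor
#' (< 0.40), fair (0.40-0.59), good (0.60-0.74), excellent (0.75-1.00).
#'
#' @param score_table Numeric matrix or data frame, subjects in rows and
#'   readers in columns; at least 5 subjects, 2 readers, no missing cells.
#' @param type `"agreement"` (default, ICC(2,1)) or `"consistency"`
#'   (ICC(3,1)).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An `icc_result`: `estimate`, `ci_lower`, `ci_upper`, `p`
#'   (F test of subject variance), `band`, `type`, `n_subjects`,
#'   `n_readers`.
#' @export
icc <- function(score_table, type = c("agreement", "consistency"),
                conf_level = 0.95) {
  type <- match.arg(type)
  x <- as.matrix(score_table)
  if (anyNA(x)) stop("score table must have no missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 readers")
  if (stats::var(rowMeans(x)) < .Machine$double.eps) {
    stop("zero between-subject variance; ICC degenerate")
  }
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((x - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (type == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    df2 <- (n - 1) * (k - 1)
    fl <- f_obs / stats::qf(1 - alpha / 2, n - 1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
    p <- stats::pf(f_obs, n - 1, df2, lower.tail = FALSE)
  } else if (mse < .Machine$double.eps && msc < .Machine$double.eps) {
    # perfect agreement: identical reader columns
    est <- 1; lo <- 1; hi <- 1; p <- 0
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # Satterthwaite df for the reader+error composite (McGraw & Wong 1996)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    nu <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, nu)
    f_u <- stats::qf(1 - alpha / 2, nu, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    f_obs <- msr / mse
    p <- stats::pf(f_obs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  band <- icc_band(est)
  structure(list(estimate = est, ci_lower = max(-1, lo), ci_upper = min(1, hi),
                 p = p, band = band, type = type,
                 n_subjects = n, n_readers = k,
                 mean_squares = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

#' Clinical agreement band for an ICC value
#'
#' @param value ICC estimate(s).
#' @return `"poor"` (< 0.40), `"fair"` (0.40-0.59), `"good"` (0.60-0.74) or
#'   `"excellent"` (0.75-1.00).
#' @export
icc_band <- function(value) {
  ifelse(value < 0.40, "poor",
         ifelse(value < 0.60, "fair",
                ifelse(value < 0.75, "good", "excellent")))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s, single rater): %.3f (95%% CI %.3f-%.3f), p = %.3g -> %s\n",
              if (x$type == "agreement") "2,1" else "3,1",
              x$estimate, x$ci_lower, x$ci_upper, x$p, x$band))
  invisible(x)
}
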