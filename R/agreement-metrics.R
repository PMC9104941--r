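adjusted_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (n < 3 || m2 == 0) return(NA_real_)
  m3 <- mean((x - mean(x))^3)
  # adjusted Fisher-Pearson standardized moment coefficient G1; the
  # standardization uses the population moments m2, m3
  (n^2 / ((n - 1) * (n - 2))) * m3 / m2^1.5
}

tukey_fences <- function(x) {
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

#' Descriptive statistics of a rate series
#'
#' Mean, sample variance/SD, adjusted Fisher-Pearson skewness, Tukey
#' boxplot fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR, linear-interpolation
#' quartiles) and the count of values outside them.
#'
#' @param values Numeric vector, length >= 2.
#' @return An object of class `metrics_report`.
#' @export
descriptive_report <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  fences <- tukey_fences(values)
  v <- var(values)
  structure(list(
    n = length(values),
    mean = mean(values),
    variance = v,
    sd = sqrt(v),
    skewness = adjusted_skewness(values),
    lower_bound = unname(fences["lower"]),
    upper_bound = unname(fences["upper"]),
    n_outliers = sum(values < fences["lower"] | values > fences["upper"])
  ), class = "metrics_report")
}

#' Agreement statistics between estimates and a reference
#'
#' Error metrics over `e_i = estimates_i - reference_i` (MSE, RMSE, MAE,
#' MedAE), the descriptive statistics of the estimates, and the
#' coefficient of determination
#' `R^2 = 1 - sum((y_i - yhat_i)^2) / sum((y_i - ybar)^2)`
#' where `y` are the estimates, `yhat` the paired reference readings and,
#' under the default `"estimate_mean"` convention, `ybar` the mean of the
#' estimates themselves (`"reference_mean"` uses the reference mean, the
#' textbook regression convention).
#'
#' @param estimates,reference Equal-length numeric vectors (>= 2).
#' @param r2_convention `"estimate_mean"` (default) or `"reference_mean"`.
#' @return A `metrics_report` with error and agreement fields added.
#' @export
agreement_report <- function(estimates, reference,
                             r2_convention = c("estimate_mean",
                                               "reference_mean")) {
  r2_convention <- match.arg(r2_convention)
  if (length(estimates) != length(reference))
    stop("estimates and reference must have equal length")
  stopifnot(length(estimates) >= 2)
  rep_ <- descriptive_report(estimates)
  e <- estimates - reference
  ss_reg <- sum((estimates - reference)^2)
  center <- if (r2_convention == "estimate_mean") mean(estimates)
            else mean(reference)
  ss_tot <- sum((estimates - center)^2)
  rep_$mse <- mean(e^2)
  rep_$rmse <- sqrt(mean(e^2))
  rep_$mae <- mean(abs(e))
  rep_$medae <- median(abs(e))
  rep_$r_squared <- if (ss_tot == 0) NA_real_ else 1 - ss_reg / ss_tot
  rep_
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(val)) "NA" else format(val, digits = 6)))
  }
  invisible(x)
}
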