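#' RR intervals from peak times
#'
#' @param peak_times Strictly increasing R-peak times (s); at least 3.
#' @return Vector of successive differences (s), all positive.
#' @export
rr_intervals <- function(peak_times) {
  if (length(peak_times) < 3)
    stop("need at least 3 peaks to form RR intervals")
  if (any(diff(peak_times) <= 0))
    stop("peak times must be strictly increasing")
  diff(peak_times)
}

#' RR-interval heart-rate-variability features
#'
#' Computes the five RR statistics used as classifier inputs, plus age and
#' gender:
#' \describe{
#'   \item{mean_rr}{mean interval (s)}
#'   \item{norm_max_diff}{`(max - min) / mean`}
#'   \item{rmssd}{root mean square of successive differences,
#'     `sqrt(sum_{i=2}^{n} (RR_i - RR_{i-1})^2 / (n - 2))` with `n` the
#'     number of intervals; `rmssd_denominator = "n_diff"` divides by the
#'     count of differences (`n - 1`) instead}
#'   \item{cov}{coefficient of variation, sample SD / mean}
#'   \item{nad}{normalized absolute deviation,
#'     `sum(|RR_i - mean|) / (mean * n)`}
#' }
#' With exactly 2 intervals the default RMSSD denominator is 0; the value
#' is then reported as `NA` rather than fabricated.
#'
#' @param intervals RR intervals in seconds (>= 2).
#' @param age Age in years.
#' @param gender_code 1 = male, 0 = female.
#' @param rmssd_denominator `"printed"` (n - 2, default) or `"n_diff"`
#'   (number of successive differences).
#' @return An object of class `rr_features`: named list of the 7 features.
#' @export
compute_features <- function(intervals, age = NA_real_,
                             gender_code = NA_integer_,
                             rmssd_denominator = c("printed", "n_diff")) {
  rmssd_denominator <- match.arg(rmssd_denominator)
  n <- length(intervals)
  stopifnot(n >= 2, all(intervals > 0))
  mu <- mean(intervals)
  d2 <- diff(intervals)^2
  denom <- if (rmssd_denominator == "printed") n - 2 else n - 1
  rmssd <- if (denom <= 0) NA_real_ else sqrt(sum(d2) / denom)
  structure(list(
    mean_rr = mu,
    norm_max_diff = (max(intervals) - min(intervals)) / mu,
    rmssd = rmssd,
    cov = sd(intervals) / mu,
    nad = sum(abs(intervals - mu)) / (mu * n),
    age = age,
    gender_code = gender_code
  ), class = "rr_features")
}

#' Feature matrix for a cohort
#'
#' @param cohort Output of [simulate_rr_cohort()], or any list of subjects
#'   with `rr`, `age`, `gender_code`, `label`.
#' @param ... Passed to [compute_features()].
#' @return List with numeric matrix `x` (rows = subjects, 7 columns) and
#'   numeric vector `y` (1 = arrhythmia, 0 = normal).
#' @export
cohort_features <- function(cohort, ...) {
  rows <- lapply(cohort, function(s) {
    f <- compute_features(s$rr, s$age, s$gender_code, ...)
    unlist(f[c("mean_rr", "norm_max_diff", "rmssd", "cov", "nad",
               "age", "gender_code")])
  })
  x <- do.call(rbind, rows)
  y <- vapply(cohort, function(s) as.numeric(s$label == "arrhythmia"),
              numeric(1))
  list(x = x, y = y)
}

#' Min-max feature scaler
#'
#' Fit on the training split only; applied to all splits.
#'
#' @param x Numeric matrix of training features.
#' @return A `feature_scaler`: list of per-column `min` and `range`.
#' @export
fit_scaler <- function(x) {
  mn <- apply(x, 2, min)
  rg <- apply(x, 2, max) - mn
  rg[rg == 0] <- 1
  structure(list(min = mn, range = rg), class = "feature_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler A [fit_scaler()] object.
#' @param x Feature matrix (or single row).
#' @return Scaled matrix with training columns mapped to `[0, 1]`.
#' @export
apply_scaler <- function(scaler, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(sweep(x, 2, scaler$min), 2, scaler$range, "/")
}
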