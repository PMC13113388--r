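#' Prediction interval nominal coverage (PINC)
#'
#' `PINC = 100 (1 - alpha)` percent: the coverage the intervals are built to
#' achieve.
#'
#' @param alpha Miscoverage probability in `[0, 1]`.
#' @return Percentage.
#' @export
pinc <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  100 * (1 - alpha)
}

#' Prediction interval coverage probability (PICP)
#'
#' The fraction of targets falling inside their (closed) prediction
#' intervals.
#'
#' @param y_true Observed values.
#' @param lower,upper Interval bounds (same length as `y_true`).
#' @return A fraction in `[0, 1]`.
#' @export
picp <- function(y_true, lower, upper) {
  n <- length(y_true)
  if (n == 0) stop("empty input", call. = FALSE)
  if (length(lower) != n || length(upper) != n) {
    stop("`y_true`, `lower` and `upper` must share a length", call. = FALSE)
  }
  mean(y_true >= lower & y_true <= upper)
}

#' Average coverage error (ACE)
#'
#' `ACE = PICP - PINC` on the fraction scale; zero means the intervals are
#' calibrated, positive values mean over-conservative intervals, negative
#' values mean intervals too narrow for the data's uncertainty.
#'
#' @param picp_value Empirical coverage fraction in `[0, 1]`.
#' @param pinc_fraction Nominal coverage as a fraction in `[0, 1]`.
#' @return Signed fraction.
#' @export
ace <- function(picp_value, pinc_fraction) {
  stopifnot(all(picp_value >= 0 & picp_value <= 1),
            all(pinc_fraction >= 0 & pinc_fraction <= 1))
  picp_value - pinc_fraction
}

#' Prediction interval normalised average width (PINAW)
#'
#' Mean interval width divided by the range `R` of the observed values: the
#' sharpness of the intervals on a dimensionless scale. Smaller is better as
#' long as calibration (ACE near zero) is maintained.
#'
#' @param lower,upper Interval bounds.
#' @param range Normalisation range `R > 0` of the actual values.
#' @return Dimensionless width.
#' @export
pinaw <- function(lower, upper, range) {
  if (length(lower) == 0) stop("empty input", call. = FALSE)
  if (!is.finite(range) || range <= 0) stop("`range` must be > 0", call. = FALSE)
  mean(upper - lower) / range
}

#' Mean squared error and R-squared of point predictions
#'
#' @param y_true Observed values (needs >= 2 values with positive variance).
#' @param y_pred Predictions.
#' @return A one-row tibble with `mse` and `r2`.
#' @export
regression_scores <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n < 2 || length(y_pred) != n) {
    stop("`y_true` and `y_pred` must share a length >= 2", call. = FALSE)
  }
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("R-squared undefined: `y_true` has zero variance", call. = FALSE)
  res <- y_true - y_pred
  tibble::tibble(mse = mean(res^2), r2 = 1 - sum(res^2) / sst)
}

#' Build a per-model interval performance report row
#'
#' Combines accuracy (MSE, R-squared of the point predictions) with the
#' prediction-interval figures of merit (PICP, ACE, PINAW) and the
#' min/mean/max lower and upper interval sizes — the row schema of the
#' five-model comparison table.
#'
#' @param intervals Interval tibble (`point`, `lower`, `upper`).
#' @param y_true Observed values for the same samples.
#' @param alpha Nominal miscoverage (default 0.05).
#' @param range Normalisation range for PINAW; defaults to
#'   `max(y_true) - min(y_true)`.
#' @param model Optional model label.
#' @return A one-row tibble.
#' @export
interval_report <- function(intervals, y_true, alpha = 0.05, range = NULL,
                            model = NA_character_) {
  range <- range %||% (max(y_true) - min(y_true))
  scores <- regression_scores(y_true, intervals$point)
  cov <- picp(y_true, intervals$lower, intervals$upper)
  dplyr::bind_cols(
    tibble::tibble(model = model),
    interval_size_summary(intervals),
    scores,
    tibble::tibble(picp = cov,
                   ace = ace(cov, pinc(alpha) / 100),
                   pinaw = pinaw(intervals$lower, intervals$upper, range),
                   n_test = length(y_true), range = range)
  )
}
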