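#' Jackknife+-after-bootstrap prediction intervals
#'
#' Model-agnostic, distribution-free 95% (by default) prediction intervals.
#' `B` models are trained on with-replacement bootstrap resamples of the
#' training set. Every training point receives an out-of-bag (OOB) aggregate
#' prediction — the mean over models whose resample excluded it — and an
#' absolute OOB residual. For each test point the interval is
#' `[q_alpha^-(loo_pred_i - R_i), q_alpha^+(loo_pred_i + R_i)]` over training
#' points `i`, where `loo_pred_i` is the mean prediction of the models not
#' containing `i` and the quantile rank is `ceiling((1 - alpha) * (n + 1))`.
#' The construction guarantees coverage at least `1 - 2 alpha` and in
#' practice concentrates near `1 - alpha`.
#'
#' The reported point prediction is from a refit of the learner on the full
#' training set (`point`); the bootstrap-aggregate mean is also returned
#' (`point_bagged`). The uncertainty proxy `sigma = (upper - lower) / (2 z)`
#' feeds the inverse-variance fusion stage.
#'
#' @param X_train,y_train Training spectra matrix and response (n >= 10).
#' @param X_test Test spectra matrix.
#' @param learner Function `(X, y) -> model`; `predict_fun(model, X)` must
#'   return numeric predictions.
#' @param B Number of bootstrap resamples (>= 20).
#' @param alpha Miscoverage probability in (0, 1).
#' @param z Normal quantile used for the sigma proxy (1.96 for 95%).
#' @param seed Integer seed.
#' @param predict_fun Prediction wrapper, default `predict`.
#' @param max_retries Reseeding attempts when some training point is never
#'   out-of-bag.
#' @return A tibble with one row per test sample: `point`, `point_bagged`,
#'   `lower`, `upper`, `sigma`.
#' @export
jab_intervals <- function(X_train, y_train, X_test, learner, B = 100,
                          alpha = 0.05, z = 1.96, seed = 1,
                          predict_fun = function(m, X) as.numeric(predict(m, X)),
                          max_retries = 10) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  y_train <- as.numeric(y_train)
  n <- nrow(X_train)
  if (n < 10) stop("jackknife+-after-bootstrap needs n_train >= 10", call. = FALSE)
  if (B < 20) stop("`B` must be >= 20", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)

  inbag <- NULL
  for (attempt in seq_len(max_retries)) {
    boot <- withr::with_seed(child_seed(seed, attempt - 1), {
      matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    })
    inbag <- t(apply(boot, 1, tabulate, nbins = n)) > 0 # B x n
    if (all(colSums(!inbag) > 0)) break
    inbag <- NULL
  }
  if (is.null(inbag)) {
    stop("some training point appeared in every bootstrap resample after ",
         max_retries, " reseeds; increase B", call. = FALSE)
  }

  P_train <- matrix(0, B, n)
  P_test <- matrix(0, B, nrow(X_test))
  for (b in seq_len(B)) {
    idx <- boot[b, ]
    m <- learner(X_train[idx, , drop = FALSE], y_train[idx])
    P_train[b, ] <- predict_fun(m, X_train)
    P_test[b, ] <- predict_fun(m, X_test)
  }
  oob <- !inbag                              # B x n
  n_oob <- colSums(oob)
  oob_pred <- colSums(oob * P_train) / n_oob # OOB aggregate per training point
  R <- abs(y_train - oob_pred)
  # leave-one-out aggregate predictions on the test set: n x n_test
  loo <- (t(oob) %*% P_test) / n_oob

  k_hi <- min(n, ceiling((1 - alpha) * (n + 1)))
  upper <- apply(loo + R, 2, function(v) sort(v)[k_hi])
  lower <- apply(loo - R, 2, function(v) sort(v)[n + 1 - k_hi])

  full <- learner(X_train, y_train)
  point <- predict_fun(full, X_test)
  tibble::tibble(point = point,
                 point_bagged = colMeans(P_test),
                 lower = lower, upper = upper,
                 sigma = (upper - lower) / (2 * z))
}

#' Lower and upper interval sizes
#'
#' Splits each prediction interval into its lower size (`point - lower`) and
#' upper size (`upper - point`), the two quantities summarised per model in
#' the comparison table.
#'
#' @param intervals Tibble with columns `point`, `lower`, `upper`.
#' @return A tibble with `lower_size` and `upper_size`.
#' @export
interval_sizes <- function(intervals) {
  stopifnot(all(c("point", "lower", "upper") %in% names(intervals)))
  tibble::tibble(lower_size = intervals$point - intervals$lower,
                 upper_size = intervals$upper - intervals$point)
}

#' Min/mean/max summary of interval sizes
#'
#' @param intervals Tibble with columns `point`, `lower`, `upper`.
#' @return A one-row tibble with `lower_min`, `lower_mean`, `lower_max`,
#'   `upper_min`, `upper_mean`, `upper_max`.
#' @export
interval_size_summary <- function(intervals) {
  s <- interval_sizes(intervals)
  tibble::tibble(lower_min = min(s$lower_size), lower_mean = mean(s$lower_size),
                 lower_max = max(s$lower_size),
                 upper_min = min(s$upper_size), upper_mean = mean(s$upper_size),
                 upper_max = max(s$upper_size))
}
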