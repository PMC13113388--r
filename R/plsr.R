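#' Fit a single-response PLS regression model
#'
#' NIPALS PLS1 on mean-centered spectra and target (no variance scaling —
#' SNV already puts the channels on a common scale). Components are nested:
#' the fitted object stores the weight/loading sequence so predictions can be
#' formed at any number of latent variables up to `n_lv`.
#'
#' @param X Numeric matrix, samples x channels.
#' @param y Numeric response (L/S ratios).
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @return An object of class `plsr_fit` with the centering vectors, weight
#'   matrix `W`, loadings `P`, inner regression coefficients `q`, the
#'   regression coefficient vector at `n_lv`, and fitted values.
#' @export
fit_plsr <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2) stop("`y` must take at least 2 distinct values", call. = FALSE)
  rank_bound <- min(n - 1, p)
  if (n_lv < 1 || n_lv > rank_bound) {
    stop("`n_lv` must lie in [1, ", rank_bound, "] for this problem", call. = FALSE)
  }
  fit <- nipals_pls1(X, y, n_lv)
  if (fit$n_lv < n_lv) {
    stop("rank exhausted after ", fit$n_lv,
         " latent variables; reduce `n_lv`", call. = FALSE)
  }
  fit
}

# Internal NIPALS PLS1 core: extracts up to `lv_max` components, stopping
# early (without error) once the deflated covariance with y is numerically
# exhausted. fit_plsr() wraps this with the strict complexity contract.
nipals_pls1 <- function(X, y, lv_max, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, lv_max); P <- matrix(0, p, lv_max); q <- numeric(lv_max)
  Xd <- Xc
  scale0 <- NULL
  a_done <- 0
  for (a in seq_len(lv_max)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w^2))
    scale0 <- scale0 %||% max(nw, 1)
    if (nw < tol * scale0) break
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    if (tt < tol) break
    p_a <- crossprod(Xd, t_a) / tt
    q[a] <- sum(yc * t_a) / tt
    Xd <- Xd - t_a %*% t(p_a)
    W[, a] <- w; P[, a] <- p_a
    a_done <- a
  }
  if (a_done == 0) stop("no latent variable extractable: X carries no covariance with y",
                        call. = FALSE)
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  q <- q[seq_len(a_done)]
  coef <- W %*% solve(crossprod(P, W), q)
  fitted <- as.numeric(Xc %*% coef) + y_mean
  structure(list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, q = q,
                 n_lv = a_done, coef = as.numeric(coef), fitted = fitted,
                 n = n, p = p, y = y),
            class = "plsr_fit")
}

# Internal: cumulative predictions for 1..A latent variables (n x A matrix).
plsr_predict_path <- function(object, X) {
  X <- as.matrix(X)
  if (ncol(X) != object$p) {
    stop("newdata has ", ncol(X), " channels; model was trained on ", object$p,
         call. = FALSE)
  }
  Xd <- sweep(X, 2, object$x_mean)
  A <- object$n_lv
  out <- matrix(0, nrow(X), A)
  acc <- rep(object$y_mean, nrow(X))
  for (a in seq_len(A)) {
    t_a <- Xd %*% object$W[, a]
    acc <- acc + as.numeric(t_a) * object$q[a]
    Xd <- Xd - t_a %*% t(object$P[, a])
    out[, a] <- acc
  }
  out
}

#' Predict from a fitted PLS regression model
#'
#' @param object A `plsr_fit`.
#' @param newdata Matrix with the training channel layout.
#' @param n_lv Number of latent variables to use (defaults to the fitted
#'   count; any value up to it is valid thanks to component nesting).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.plsr_fit <- function(object, newdata, n_lv = NULL, ...) {
  n_lv <- n_lv %||% object$n_lv
  if (n_lv < 1 || n_lv > object$n_lv) {
    stop("`n_lv` must lie in [1, ", object$n_lv, "]", call. = FALSE)
  }
  plsr_predict_path(object, newdata)[, n_lv]
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat("PLS regression fit:", x$n_lv, "latent variable(s),",
      x$n, "samples x", x$p, "channels\n")
  invisible(x)
}

#' @rdname fit_plsr
#' @param x A `plsr_fit`.
#' @param ... Unused.
#' @export
tidy.plsr_fit <- function(x, ...) {
  tibble::tibble(channel = seq_len(x$p), estimate = x$coef)
}

#' @rdname fit_plsr
#' @export
glance.plsr_fit <- function(x, ...) {
  res <- x$y - x$fitted
  tibble::tibble(n_lv = x$n_lv, n = x$n, p = x$p,
                 train_mse = mean(res^2),
                 train_r2 = 1 - sum(res^2) / sum((x$y - mean(x$y))^2))
}

#' Cross-validate PLS model complexity
#'
#' Repeatedly splits the training set 80/20 into cross-validation train and
#' test subsets (50 splits by default), fits one nested PLS model per split,
#' and records mean train/test MSE and R-squared for every latent-variable
#' count from 1 to `lv_max`. The identical splits are reused across all
#' latent-variable counts so the per-LV curves are directly comparable.
#'
#' @param X,y Training spectra matrix and response.
#' @param lv_max Largest latent-variable count examined (capped at the rank
#'   bound of the smallest CV training subset).
#' @param n_splits Number of random splits.
#' @param test_frac Fraction of samples held out per split.
#' @param seed Integer seed.
#' @return An object of class `plsr_cv`: tibble `metrics` (lv, train_mse,
#'   test_mse, train_r2, test_r2), the split list, and the total number of
#'   CV test predictions (the F-test degrees of freedom).
#' @export
cross_validate <- function(X, y, lv_max = 30, n_splits = 50, test_frac = 0.2,
                           seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  n_test <- max(1, round(test_frac * n))
  n_train <- n - n_test
  lv_eff <- min(lv_max, n_train - 1, ncol(X))
  if (n < 5 || lv_eff < 1) stop("too few samples for cross-validation", call. = FALSE)
  splits <- withr::with_seed(seed, {
    lapply(seq_len(n_splits), function(s) sort(sample.int(n, n_test)))
  })
  fits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    tr <- setdiff(seq_len(n), splits[[s]])
    fits[[s]] <- nipals_pls1(X[tr, , drop = FALSE], y[tr], lv_eff)
  }
  # the LV grid is capped at what every split could extract, so the per-LV
  # averages always pool the same number of splits
  lv_eff <- min(vapply(fits, function(f) f$n_lv, integer(1)))
  acc <- matrix(0, lv_eff, 4) # train_mse, test_mse, train_r2, test_r2
  for (s in seq_len(n_splits)) {
    te <- splits[[s]]; tr <- setdiff(seq_len(n), te)
    fit <- fits[[s]]
    path_tr <- plsr_predict_path(fit, X[tr, , drop = FALSE])
    path_te <- plsr_predict_path(fit, X[te, , drop = FALSE])
    sst_tr <- sum((y[tr] - mean(y[tr]))^2)
    sst_te <- sum((y[te] - mean(y[te]))^2)
    for (a in seq_len(lv_eff)) {
      r_tr <- y[tr] - path_tr[, a]
      r_te <- y[te] - path_te[, a]
      acc[a, 1] <- acc[a, 1] + mean(r_tr^2)
      acc[a, 2] <- acc[a, 2] + mean(r_te^2)
      acc[a, 3] <- acc[a, 3] + (1 - sum(r_tr^2) / sst_tr)
      acc[a, 4] <- acc[a, 4] + (1 - sum(r_te^2) / sst_te)
    }
  }
  acc <- acc / n_splits
  metrics <- tibble::tibble(lv = seq_len(lv_eff),
                            train_mse = acc[, 1], test_mse = acc[, 2],
                            train_r2 = acc[, 3], test_r2 = acc[, 4])
  structure(list(metrics = metrics, splits = splits, n_splits = n_splits,
                 n_test_total = n_splits * n_test, seed = seed),
            class = "plsr_cv")
}

#' @export
print.plsr_cv <- function(x, ...) {
  best <- x$metrics$lv[which.min(x$metrics$test_mse)]
  cat("PLS cross-validation:", x$n_splits, "splits, LV 1..",
      max(x$metrics$lv), "; minimum test MSE at", best, "LV\n")
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `plsr_cv`.
#' @param ... Unused.
#' @export
tidy.plsr_cv <- function(x, ...) x$metrics

#' Select a parsimonious latent-variable count by F-test
#'
#' Finds the latent-variable count with minimum mean cross-validation test
#' MSE, then returns the smallest count whose MSE ratio against that minimum
#' falls below the one-sided critical F value at level `alpha`, with degrees
#' of freedom equal to the total number of CV test predictions for each
#' model. This parsimony rule typically selects fewer latent variables than
#' the raw minimum-MSE choice.
#'
#' @param cv A `plsr_cv`.
#' @param alpha Significance level (default 0.05).
#' @return The selected latent-variable count (<= the argmin of test MSE).
#' @export
select_n_lv <- function(cv, alpha = 0.05) {
  stopifnot(inherits(cv, "plsr_cv"))
  mse <- cv$metrics$test_mse
  k_star <- which.min(mse)
  df <- cv$n_test_total
  crit <- stats::qf(1 - alpha, df, df)
  for (k in seq_len(k_star)) {
    if (mse[k] / mse[k_star] < crit) return(cv$metrics$lv[k])
  }
  cv$metrics$lv[k_star]
}

#' Plot cross-validation error curves
#'
#' @param object A `plsr_cv`.
#' @param ... Unused.
#' @return A ggplot of mean train/test MSE against latent-variable count.
#' @export
autoplot.plsr_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$metrics, c("train_mse", "test_mse"),
                            names_to = "set", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(.data$lv, .data$mse, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(train_mse = "grey50", test_mse = "firebrick"),
                                 labels = c(train_mse = "CV train", test_mse = "CV test"),
                                 name = NULL) +
    ggplot2::labs(x = "latent variables", y = "mean squared error") +
    ggplot2::theme_minimal()
}
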