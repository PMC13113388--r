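test_that("PLS fit matches the independently coded NIPALS reference", {
  withr::local_seed(101)
  X <- matrix(rnorm(8 * 20), 8, 20)
  y <- rnorm(8)
  for (a in 1:3) {
    fit <- fit_plsr(X, y, a)
    ref <- oracle_nipals(X, y, a)
    expect_equal(fit$coef, unname(ref$coef), tolerance = 1e-8)
    expect_equal(fit$fitted, ref$fitted, tolerance = 1e-8)
    Xn <- matrix(rnorm(5 * 20), 5, 20)
    expect_equal(predict(fit, Xn), ref$predict(Xn), tolerance = 1e-8)
  }
})

test_that("full-rank PLS equals direct least squares", {
  withr::local_seed(7)
  X <- matrix(rnorm(6 * 4), 6, 4)
  y <- rnorm(6)
  fit <- fit_plsr(X, y, 4)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_equal(fit$fitted, unname(ols$fitted.values), tolerance = 1e-8)
})

test_that("PLS fit agrees with an external PLS implementation", {
  skip_if_not_installed("mixOmics")
  withr::local_seed(33)
  X <- matrix(rnorm(12 * 15), 12, 15,
              dimnames = list(NULL, paste0("ch", 1:15)))
  y <- rnorm(12)
  fit <- fit_plsr(X, y, 3)
  mo <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  mo_pred <- predict(mo, X)$predict[, 1, 3]
  expect_equal(fit$fitted, unname(mo_pred), tolerance = 1e-6)
})

test_that("exact low-rank structure is recovered and rank violations error", {
  withr::local_seed(5)
  n <- 12; p <- 30
  T2 <- matrix(rnorm(n * 2), n, 2)
  P2 <- matrix(rnorm(p * 2), 2, p)
  X <- T2 %*% P2
  y <- drop(T2 %*% c(1.5, -2))
  fit <- fit_plsr(X, y, 2)
  expect_lt(mean((y - fit$fitted)^2), 1e-12)
  expect_error(fit_plsr(X, y, 5), "rank exhausted")
  expect_error(fit_plsr(X, y, 0), "n_lv")
  expect_error(fit_plsr(X, y, n), "n_lv")
  expect_error(fit_plsr(X, rep(1, n), 1), "distinct")
})

test_that("prediction is an affine map anchored at the training means", {
  withr::local_seed(9)
  X <- matrix(rnorm(10 * 12), 10, 12)
  y <- rnorm(10)
  fit <- fit_plsr(X, y, 3)
  # the training-mean spectrum maps to the training-mean response
  expect_equal(predict(fit, matrix(fit$x_mean, 1)), fit$y_mean)
  # training data reproduce the fitted values
  expect_equal(predict(fit, X), fit$fitted)
  # doubling the centred inputs doubles the centred predictions
  Xc2 <- sweep(sweep(X, 2, fit$x_mean), 1, rep(0, 10)) * 2
  expect_equal(predict(fit, sweep(Xc2, 2, fit$x_mean, `+`)),
               2 * (fit$fitted - fit$y_mean) + fit$y_mean, tolerance = 1e-10)
  expect_error(predict(fit, X[, 1:5]), "channels")
  td <- tidy(fit)
  expect_equal(nrow(td), 12)
  expect_equal(glance(fit)$n_lv, 3)
})

test_that("cross-validation reuses identical splits and yields monotone train error", {
  withr::local_seed(77)
  n <- 40; p <- 25
  Tm <- matrix(rnorm(n * 3), n, 3)
  X <- Tm %*% matrix(rnorm(3 * p), 3, p) + 0.05 * matrix(rnorm(n * p), n, p)
  y <- drop(Tm %*% c(1, -1, 0.5)) + 0.05 * rnorm(n)
  cv <- cross_validate(X, y, lv_max = 8, n_splits = 12, seed = 4)
  expect_equal(nrow(cv$metrics), 8)
  expect_true(all(diff(cv$metrics$train_mse) <= 1e-10)) # nested fits
  expect_equal(cv$n_test_total, 12 * 8) # 20% of 40 = 8 per split
  cv2 <- cross_validate(X, y, lv_max = 8, n_splits = 12, seed = 4)
  expect_identical(cv$metrics, cv2$metrics)
  expect_true(all(is.finite(unlist(cv$metrics))))
  expect_error(cross_validate(X[1:3, ], y[1:3], lv_max = 8, n_splits = 5, seed = 1))
})

test_that("F-test selection is parsimonious and finds true factor counts", {
  # degenerate and tie cases
  fake_cv <- function(mse) {
    structure(list(metrics = tibble::tibble(lv = seq_along(mse), test_mse = mse),
                   n_splits = 50, n_test_total = 400),
              class = "plsr_cv")
  }
  expect_equal(select_n_lv(fake_cv(c(0.5, 0.6, 0.7))), 1)
  expect_equal(select_n_lv(fake_cv(c(0.9, 0.3, 0.3001, 0.3))), 2) # tie with k* = 4
  expect_equal(select_n_lv(fake_cv(c(10, 5, 1))), 3) # steep descent -> k*
  # simulation with 3 informative spectral factors whose variances differ by
  # an order of magnitude each, so every extra component buys a real error
  # reduction and the parsimony rule must still take all three
  hits <- 0; n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    withr::local_seed(1000 + s)
    n <- 45; p <- 40
    scales <- c(10, 3.2, 1)
    Tm <- matrix(rnorm(n * 3), n, 3) %*% diag(scales)
    P3 <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
    X <- Tm %*% t(P3) + 0.05 * matrix(rnorm(n * p), n, p)
    y <- drop(Tm %*% (1 / scales)) + 0.05 * rnorm(n) # equal y-share per factor
    cv <- cross_validate(X, y, lv_max = 10, n_splits = 15, seed = s)
    k <- select_n_lv(cv)
    k_star <- cv$metrics$lv[which.min(cv$metrics$test_mse)]
    expect_lte(k, k_star)
    if (k >= 3) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("the CV LV grid is capped by what every split can extract", {
  withr::local_seed(13)
  # rank-2 signal with no noise: deflation exhausts quickly
  n <- 20; p <- 15
  Tm <- matrix(rnorm(n * 2), n, 2)
  X <- Tm %*% matrix(rnorm(2 * p), 2, p)
  y <- drop(Tm %*% c(1, -1))
  cv <- cross_validate(X, y, lv_max = 10, n_splits = 6, seed = 2)
  expect_lte(max(cv$metrics$lv), 3)
  expect_true(all(is.finite(cv$metrics$test_mse)))
})
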