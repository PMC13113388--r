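# Independent reference implementations and tiny fixtures, coded separately
# from the package internals so the tests have a second route to every
# numerical claim.

# Textbook NIPALS PLS1 reference: deflates both X and y, accumulates scores,
# and recovers the coefficient vector numerically from the affine prediction
# map (predict unit impulses) rather than from the closed-form identity the
# package uses.
oracle_nipals <- function(X, y, a_max) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- NULL; P <- NULL; Q <- NULL
  for (a in seq_len(a_max)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t_ <- drop(E %*% w)
    p_ <- drop(crossprod(E, t_)) / sum(t_^2)
    q_ <- sum(f * t_) / sum(t_^2)
    E <- E - tcrossprod(t_, p_)
    f <- f - t_ * q_
    W <- cbind(W, w); P <- cbind(P, p_); Q <- c(Q, q_)
  }
  pred <- function(Xnew) {
    Ed <- sweep(as.matrix(Xnew), 2, xm)
    out <- rep(ym, nrow(Ed))
    for (a in seq_along(Q)) {
      t_ <- drop(Ed %*% W[, a])
      out <- out + t_ * Q[a]
      Ed <- Ed - tcrossprod(t_, P[, a])
    }
    out
  }
  p <- ncol(X)
  base <- pred(matrix(xm, 1))
  coef <- vapply(seq_len(p), function(j) {
    xj <- xm; xj[j] <- xj[j] + 1
    pred(matrix(xj, 1)) - base
  }, numeric(1))
  list(predict = pred, coef = coef, fitted = pred(X), y_mean = ym)
}

# Plain jackknife+ (leave-one-out) reference intervals.
oracle_jackknife_plus <- function(X_train, y_train, X_test, fit, pred, alpha = 0.05) {
  n <- nrow(X_train)
  loo_pred_test <- matrix(0, n, nrow(X_test))
  R <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit(X_train[-i, , drop = FALSE], y_train[-i])
    R[i] <- abs(y_train[i] - pred(m, X_train[i, , drop = FALSE]))
    loo_pred_test[i, ] <- pred(m, X_test)
  }
  k <- min(n, ceiling((1 - alpha) * (n + 1)))
  list(
    lower = apply(loo_pred_test - R, 2, function(v) sort(v)[n + 1 - k]),
    upper = apply(loo_pred_test + R, 2, function(v) sort(v)[k])
  )
}

# Closed-form linear least-squares learner used in conformal simulations.
lm_learner <- function(X, y) {
  Z <- cbind(1, as.matrix(X))
  structure(list(beta = qr.coef(qr(Z), y)), class = "lm_learner")
}
predict.lm_learner <- function(object, newdata, ...) {
  drop(cbind(1, as.matrix(newdata)) %*% object$beta)
}
registerS3method("predict", "lm_learner", predict.lm_learner)

# Broad, low-amplitude Raman-like template: per-channel slopes are shallow
# enough that a running-median replacement reconstructs any channel to well
# under the noise scale, isolating the despiking contract from line-shape
# steepness.
gentle_raman <- function(noise_sd = 0.01) {
  L <- dplyr::bind_rows(peak_spec(2850, 380, 0.40), peak_spec(1440, 340, 0.30))
  S <- dplyr::bind_rows(peak_spec(2930, 380, 0.55), peak_spec(1670, 340, 0.35))
  art <- dplyr::bind_rows(peak_spec(960, 220, 0.20))
  modality_template("raman", seq(400, 3200, by = 10), L, S, art,
                    baseline_coef = c(0.05, -0.02), noise_sd = noise_sd)
}

# Small zero-noise templates satisfying the strict modality invariants,
# cheap enough for per-test generation.
tiny_ftir <- function(noise_sd = 0, scatter_sd = 0, artifact_jitter_sd = 0,
                      ratio_sd = 0) {
  L <- dplyr::bind_rows(peak_spec(2918, 160, 1.0), peak_spec(1738, 140, 0.6),
                        peak_spec(1085, 150, 0.4))
  S <- dplyr::bind_rows(peak_spec(2852, 160, 0.8), peak_spec(1545, 150, 0.9),
                        peak_spec(1230, 150, 0.5))
  art <- dplyr::bind_rows(peak_spec(3430, 300, -0.8), peak_spec(1650, 150, -0.3),
                          peak_spec(820, 160, -0.2))
  modality_template("ftir", seq(700, 4000, by = 20), L, S, art,
                    noise_sd = noise_sd, scatter_sd = scatter_sd,
                    artifact_jitter_sd = artifact_jitter_sd, ratio_sd = ratio_sd)
}

tiny_raman <- function(noise_sd = 0, scatter_sd = 0, artifact_jitter_sd = 0,
                       ratio_sd = 0) {
  L <- dplyr::bind_rows(peak_spec(2882, 130, 0.5), peak_spec(1440, 130, 0.35))
  S <- dplyr::bind_rows(peak_spec(2885, 130, 1.2), peak_spec(1670, 130, 0.6))
  art <- dplyr::bind_rows(peak_spec(955, 120, 0.3))
  modality_template("raman", seq(400, 3200, by = 10), L, S, art,
                    baseline_coef = c(0.05, -0.02),
                    noise_sd = noise_sd, scatter_sd = scatter_sd,
                    artifact_jitter_sd = artifact_jitter_sd, ratio_sd = ratio_sd)
}

# Deterministic clean trace of a template at a given ratio, recomputed here
# from first principles (sum of gaussian/lorentzian bands) so generator
# tests do not reuse the package's own evaluator.
oracle_clean_trace <- function(template, ls_ratio) {
  fr <- if (identical(ls_ratio, "pure_L")) c(1, 0)
        else if (identical(ls_ratio, "pure_S")) c(0, 1)
        else { r <- as.numeric(ls_ratio); c(r / (1 + r), 1 / (1 + r)) }
  x <- template$axis
  shape <- function(p) {
    v <- numeric(length(x))
    for (i in seq_len(nrow(p))) {
      if (p$shape[i] == "gaussian") {
        v <- v + p$amplitude[i] * exp(-4 * log(2) * ((x - p$center[i]) / p$width[i])^2)
      } else {
        hw <- p$width[i] / 2
        v <- v + p$amplitude[i] * hw^2 / ((x - p$center[i])^2 + hw^2)
      }
    }
    v
  }
  u <- (x - x[1]) / (x[length(x)] - x[1])
  base <- numeric(length(x))
  for (k in seq_along(template$baseline_coef)) {
    base <- base + template$baseline_coef[k] * u^(k - 1)
  }
  fr[1] * shape(template$lipid_L_peaks) + fr[2] * shape(template$lipid_S_peaks) +
    shape(template$artifact_peaks) + base
}
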