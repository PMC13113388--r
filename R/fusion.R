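#' Low-level fusion: concatenate paired SNV-normalised spectra
#'
#' Concatenates each sample's FTIR and Raman intensity vectors (FTIR block
#' first) into one fused trace on a sequential datapoint index. The fused
#' index is positional, not physical: it cannot be read as wavenumber or
#' Raman shift. Both inputs should already be SNV-normalised so the two
#' blocks carry comparable intensity scales.
#'
#' @param data Long paired spectra tibble holding both modalities for the
#'   same set of samples.
#' @return A tibble with columns `sample_id`, `ls_label`, `ls_ratio`,
#'   `fused_index` (1-based) and `intensity`, with attribute
#'   `block_boundary` = index of the first Raman position.
#' @export
fuse_low_level <- function(data) {
  check_spectra_tbl(data)
  ids_f <- sort(unique(data$sample_id[data$modality == "ftir"]))
  ids_r <- sort(unique(data$sample_id[data$modality == "raman"]))
  off <- c(setdiff(ids_f, ids_r), setdiff(ids_r, ids_f))
  if (length(off) > 0) {
    stop("cannot fuse: unpaired sample_id(s): ", paste(off, collapse = ", "),
         call. = FALSE)
  }
  ordered <- data |>
    dplyr::mutate(modality = factor(.data$modality, levels = c("ftir", "raman"))) |>
    dplyr::arrange(.data$sample_id, .data$modality, .data$wavenumber)
  n_ftir <- sum(ordered$modality[ordered$sample_id == ids_f[1]] == "ftir")
  out <- ordered |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fused_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c("sample_id", "ls_label", "ls_ratio")),
                  "fused_index", "intensity")
  attr(out, "block_boundary") <- n_ftir + 1L
  out
}

# Internal: fused tibble -> samples x channels matrix (mirrors spectra_matrix).
fused_matrix <- function(fused) {
  wide <- fused |>
    dplyr::select("sample_id", "fused_index", "intensity") |>
    tidyr::pivot_wider(names_from = "fused_index", values_from = "intensity") |>
    dplyr::arrange(.data$sample_id)
  X <- as.matrix(wide[, -1])
  rownames(X) <- wide$sample_id
  y <- NULL
  if ("ls_ratio" %in% names(fused)) {
    lab <- dplyr::distinct(fused, .data$sample_id, .data$ls_ratio)
    y <- lab$ls_ratio[match(wide$sample_id, lab$sample_id)]
  }
  list(X = X, y = y, sample_id = wide$sample_id,
       block_boundary = attr(fused, "block_boundary"))
}

#' High-level fusion by unweighted mean
#'
#' The simplest decision-level fusion: the fused prediction is the
#' arithmetic mean of the two modality models' predictions. Coincides with
#' [fuse_weighted()] when the two uncertainties are equal.
#'
#' @param pred_ftir,pred_raman Numeric prediction vectors for the same
#'   samples.
#' @return Numeric fused predictions.
#' @export
fuse_high_level_mean <- function(pred_ftir, pred_raman) {
  stopifnot(length(pred_ftir) == length(pred_raman))
  (pred_ftir + pred_raman) / 2
}

#' Uncertainty proxy from a prediction interval
#'
#' Converts an interval width to a standard-deviation proxy,
#' `sigma = (upper - lower) / (2 z)` with `z = 1.96` for 95% intervals.
#' Conformal intervals carry no parametric variance, so this proxy is what
#' feeds inverse-variance weighting.
#'
#' @param lower,upper Interval bounds (vectors allowed).
#' @param z Normal quantile, > 0.
#' @return Numeric sigma values (>= 0).
#' @export
sigma_from_interval <- function(lower, upper, z = 1.96) {
  if (z <= 0) stop("`z` must be > 0", call. = FALSE)
  if (any(upper < lower)) stop("invalid interval: upper < lower", call. = FALSE)
  (upper - lower) / (2 * z)
}

#' Inverse-variance fusion weights
#'
#' `w = 1 / sigma^2` per modality. A single zero sigma yields infinite
#' weight, i.e. that modality takes all of the fused prediction (handled
#' without division in [fuse_weighted()]); two zero sigmas are degenerate.
#'
#' @param sigma_ftir,sigma_raman Non-negative uncertainty proxies.
#' @return A tibble with columns `w_ftir`, `w_raman`.
#' @export
inverse_variance_weights <- function(sigma_ftir, sigma_raman) {
  if (any(sigma_ftir < 0) || any(sigma_raman < 0)) {
    stop("sigmas must be >= 0", call. = FALSE)
  }
  if (any(sigma_ftir == 0 & sigma_raman == 0)) {
    stop("degenerate weights: both sigmas are zero", call. = FALSE)
  }
  tibble::tibble(w_ftir = 1 / sigma_ftir^2, w_raman = 1 / sigma_raman^2)
}

#' High-level inverse-variance weighted fusion
#'
#' Fuses two modality predictions per sample with weights `1 / sigma^2`,
#' where each sigma comes from that sample's prediction-interval width. The
#' fused prediction is `(w_F p_F + w_R p_R) / (w_F + w_R)`; the fused
#' uncertainty is the inverse-variance pooled
#' `sigma_fused = (1/sigma_F^2 + 1/sigma_R^2)^(-1/2)`, reported as the
#' symmetric interval `point +/- z sigma_fused`. The pooled sigma never
#' exceeds the smaller of the two input sigmas, so weighted fusion always
#' sharpens the narrower modality.
#'
#' @param pi_ftir,pi_raman Interval tibbles (`point`, `lower`, `upper`) for
#'   the same samples in the same order.
#' @param z Normal quantile (1.96 for 95%).
#' @return An interval tibble (`point`, `lower`, `upper`, `sigma`).
#' @export
fuse_weighted <- function(pi_ftir, pi_raman, z = 1.96) {
  stopifnot(nrow(pi_ftir) == nrow(pi_raman))
  s_f <- sigma_from_interval(pi_ftir$lower, pi_ftir$upper, z)
  s_r <- sigma_from_interval(pi_raman$lower, pi_raman$upper, z)
  if (any(s_f == 0 & s_r == 0)) {
    stop("degenerate weights: both sigmas are zero", call. = FALSE)
  }
  # weighted mean computed via the ratio s_r^2 : s_f^2 so that a zero sigma
  # takes the limit (all weight on that modality) without dividing by zero
  denom <- s_f^2 + s_r^2
  lam <- ifelse(denom == 0, 0.5, s_r^2 / denom) # weight on FTIR
  point <- lam * pi_ftir$point + (1 - lam) * pi_raman$point
  sigma <- sqrt(s_f^2 * s_r^2 / denom)
  tibble::tibble(point = point,
                 lower = point - z * sigma,
                 upper = point + z * sigma,
                 sigma = sigma)
}

#' High-level mean fusion with pooled intervals
#'
#' Interval-carrying counterpart of [fuse_high_level_mean()]: the fused point
#' is the unweighted mean of the two predictions and its uncertainty is that
#' of an average of two independent predictions,
#' `sigma = sqrt(sigma_F^2 + sigma_R^2) / 2`, reported as a symmetric
#' z-interval. Coincides with [fuse_weighted()] when the sigmas are equal.
#'
#' @inheritParams fuse_weighted
#' @return An interval tibble (`point`, `lower`, `upper`, `sigma`).
#' @export
fuse_mean <- function(pi_ftir, pi_raman, z = 1.96) {
  stopifnot(nrow(pi_ftir) == nrow(pi_raman))
  s_f <- sigma_from_interval(pi_ftir$lower, pi_ftir$upper, z)
  s_r <- sigma_from_interval(pi_raman$lower, pi_raman$upper, z)
  point <- fuse_high_level_mean(pi_ftir$point, pi_raman$point)
  sigma <- sqrt(s_f^2 + s_r^2) / 2
  tibble::tibble(point = point,
                 lower = point - z * sigma,
                 upper = point + z * sigma,
                 sigma = sigma)
}
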