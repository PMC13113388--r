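#' Region-anchored standard normal variate (SNV) normalisation
#'
#' SNV operates on each spectrum independently: the location (mean) and scale
#' (sd) are estimated over a designated anchor region chosen to be free of
#' substrate or environmental character, then applied to every channel, i.e.
#' `(x - mean_region) / sd_region`. After the transform, the anchor region has
#' mean 0 and sd 1. Because the statistics are per-spectrum, normalising one
#' spectrum can never leak information into another.
#'
#' @param data Long spectra tibble; each (`sample_id`, `modality`) group is
#'   one spectrum.
#' @param region Closed interval `c(lo, hi)` on the axis, or `NULL` for the
#'   full axis.
#' @return The tibble with `intensity` replaced by its SNV transform.
#' @export
snv_region <- function(data, region = NULL) {
  check_spectra_tbl(data)
  if (!is.null(region) && (length(region) != 2 || region[2] <= region[1])) {
    stop("`region` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  data |>
    dplyr::group_by(.data$sample_id, .data$modality) |>
    dplyr::group_modify(function(df, key) {
      inside <- if (is.null(region)) rep(TRUE, nrow(df)) else
        df$wavenumber >= region[1] & df$wavenumber <= region[2]
      if (sum(inside) < 3) {
        stop("SNV region holds fewer than 3 channels for spectrum ",
             key$sample_id, " (", key$modality, ")", call. = FALSE)
      }
      s <- stats::sd(df$intensity[inside])
      if (!is.finite(s) || s == 0) {
        stop("degenerate spectrum: zero variance in SNV region for ",
             key$sample_id, " (", key$modality, ")", call. = FALSE)
      }
      df$intensity <- (df$intensity - mean(df$intensity[inside])) / s
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::all_of(names(data)))
}

#' Baseline offset correction at an anchor wavenumber
#'
#' Subtracts from every channel the intensity at the grid point nearest the
#' anchor (ties broken toward the lower wavenumber), so the spectrum is zero
#' at the anchor channel. Used for ATR-FTIR spectra, which are anchored at
#' 2500 cm^-1, a region free of lipid and water bands.
#'
#' @param data Long spectra tibble.
#' @param anchor Anchor position (cm^-1); must lie within each spectrum's
#'   axis range.
#' @return The tibble with offset-corrected intensities.
#' @export
baseline_offset <- function(data, anchor = 2500) {
  check_spectra_tbl(data)
  data |>
    dplyr::group_by(.data$sample_id, .data$modality) |>
    dplyr::group_modify(function(df, key) {
      rng <- range(df$wavenumber)
      if (anchor < rng[1] || anchor > rng[2]) {
        stop("baseline anchor ", anchor, " outside axis range [", rng[1], ", ",
             rng[2], "] for ", key$sample_id, " (", key$modality, ")", call. = FALSE)
      }
      d <- abs(df$wavenumber - anchor)
      # which.min returns the first (lowest-wavenumber) minimiser on the
      # ascending grid, implementing the tie rule.
      df$intensity <- df$intensity - df$intensity[which.min(d)]
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::all_of(names(data)))
}

#' Remove cosmic spikes with a running-median filter
#'
#' A channel is flagged when its deviation from the running median (computed
#' over shrinking partial windows at the spectrum boundaries, so an edge
#' spike cannot mask itself) exceeds `threshold` robust standard deviations,
#' where the
#' robust sd is 1.4826 times the median absolute deviation of all channel
#' deviations. Flagged channels are replaced by the running median; all
#' others are untouched. The robust scale is floored at 2% of the spectrum's
#' intensity range: on noiseless data the MAD collapses to zero and any
#' smooth curvature would otherwise be flagged, whereas true cosmic spikes
#' are large relative to the whole trace.
#'
#' @param data Long spectra tibble.
#' @param window Odd window length (channels), >= 3.
#' @param threshold Robust z-score cut-off.
#' @return The despiked tibble.
#' @export
despike <- function(data, window = 7, threshold = 8) {
  check_spectra_tbl(data)
  if (window < 3 || window %% 2 == 0) stop("`window` must be odd and >= 3", call. = FALSE)
  half <- (window - 1) / 2
  data |>
    dplyr::group_by(.data$sample_id, .data$modality) |>
    dplyr::group_modify(function(df, key) {
      x <- df$intensity
      n <- length(x)
      med <- numeric(n)
      med[(half + 1):(n - half)] <- zoo::rollmedian(x, k = window, align = "center")
      for (i in c(seq_len(half), (n - half + 1):n)) {
        med[i] <- stats::median(x[max(1, i - half):min(n, i + half)])
      }
      dev <- x - med
      s <- max(stats::mad(dev), 0.02 * diff(range(x)))
      bad <- abs(dev) > threshold * s
      x[bad] <- med[bad]
      df$intensity <- x
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::all_of(names(data)))
}

#' Pair FTIR and Raman spectra by sample identity
#'
#' Matches the two modality tables so that every sample contributes exactly
#' one spectrum per modality sharing an L/S label, and assigns a dense pair
#' index. The pairing is order-independent and is preserved through all later
#' train/test and cross-validation splits.
#'
#' @param ftir,raman Long spectra tibbles of the respective modalities.
#' @return One combined tibble with a `pair_index` column.
#' @export
pair_and_index <- function(ftir, raman) {
  check_spectra_tbl(ftir); check_spectra_tbl(raman)
  ids_f <- sort(unique(ftir$sample_id))
  ids_r <- sort(unique(raman$sample_id))
  off <- c(setdiff(ids_f, ids_r), setdiff(ids_r, ids_f))
  if (length(off) > 0) {
    stop("unpaired sample_id(s): ", paste(off, collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(ftir, raman) |>
    dplyr::arrange(.data$sample_id, .data$modality, .data$wavenumber) |>
    dplyr::mutate(pair_index = match(.data$sample_id, ids_f))
}

#' Run the full spectral conditioning chain
#'
#' Applies, in order: despiking (Raman only by default — cosmic spikes are a
#' CCD phenomenon), baseline offset correction (FTIR only by default,
#' anchored at 2500 cm^-1), then region-anchored SNV (FTIR over 850-2000
#' cm^-1, a window free of water and CO2 interference; Raman over the whole
#' spectrum). At zero noise the chain is idempotent: conditioning an already
#' conditioned dataset changes nothing.
#'
#' @param data Long paired spectra tibble.
#' @param despike_window,despike_threshold Despiking parameters.
#' @param baseline_anchor FTIR anchor wavenumber (cm^-1).
#' @param ftir_snv_region,raman_snv_region SNV anchor intervals (`NULL` =
#'   full axis).
#' @param despike_modalities,baseline_modalities Which modalities each step
#'   touches.
#' @return The conditioned spectra tibble.
#' @export
preprocess_spectra <- function(data,
                               despike_window = 7, despike_threshold = 8,
                               baseline_anchor = 2500,
                               ftir_snv_region = c(850, 2000),
                               raman_snv_region = NULL,
                               despike_modalities = "raman",
                               baseline_modalities = "ftir") {
  check_spectra_tbl(data)
  step <- function(d, mods, f) {
    if (length(mods) == 0) return(d)
    touched <- dplyr::filter(d, .data$modality %in% mods)
    if (nrow(touched) == 0) return(d)
    rest <- dplyr::filter(d, !.data$modality %in% mods)
    dplyr::bind_rows(f(touched), rest)
  }
  out <- step(data, despike_modalities,
              function(d) despike(d, despike_window, despike_threshold))
  out <- step(out, baseline_modalities,
              function(d) baseline_offset(d, baseline_anchor))
  out <- step(out, "ftir", function(d) snv_region(d, ftir_snv_region))
  out <- step(out, "raman", function(d) snv_region(d, raman_snv_region))
  dplyr::arrange(out, .data$sample_id, .data$modality, .data$wavenumber)
}
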