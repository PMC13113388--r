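#' Map an L/S ratio to lecithin / sphingomyelin mixing fractions
#'
#' The generator mixes the two lipid templates at constant total lipid, so a
#' ratio label r corresponds to fractions f_L = r/(1+r) and f_S = 1/(1+r).
#' The pure endpoints are encoded by the markers `"pure_L"` and `"pure_S"`.
#'
#' @param ls_ratio Numeric ratios (> 0) and/or the character markers
#'   `"pure_L"` / `"pure_S"`.
#' @return A tibble with columns `ls_ratio` (input, as character for the
#'   markers), `f_L` and `f_S`; the fractions sum to one.
#' @examples
#' component_fractions(c(1, 3))
#' component_fractions("pure_S")
#' @export
component_fractions <- function(ls_ratio) {
  one <- function(r) {
    if (is.character(r)) {
      if (r == "pure_L") return(c(1, 0))
      if (r == "pure_S") return(c(0, 1))
      r <- suppressWarnings(as.numeric(r))
    }
    if (!is.finite(r) || r <= 0) {
      stop("`ls_ratio` must be > 0 and finite, or 'pure_L'/'pure_S'", call. = FALSE)
    }
    c(r / (1 + r), 1 / (1 + r))
  }
  fr <- vapply(as.list(ls_ratio), one, numeric(2))
  tibble::tibble(ls_ratio = as.character(ls_ratio), f_L = fr[1, ], f_S = fr[2, ])
}

#' Synthesise one spectrum from a modality template
#'
#' The clean analyte signal is the fraction-weighted sum of the two lipid
#' peak libraries, evaluated at the effective composition of this
#' modality's aliquot (the nominal ratio perturbed by `N(0, ratio_sd)`);
#' artifact peaks and the polynomial baseline are added on top, each
#' artifact peak scaled by a per-spectrum relative jitter
#' `1 + N(0, artifact_jitter_sd)`; a per-spectrum multiplicative gain
#' `1 + N(0, scatter_sd)` and additive offset `N(0, scatter_sd)` emulate
#' scatter variation; i.i.d. Gaussian channel noise is added last. With all
#' stochastic scales zero the output is exactly the deterministic mixture
#' `f_L * L + f_S * S + artifacts + baseline`. Identical
#' `(template, ls_ratio, seed)` give bitwise-identical output.
#'
#' @param template A [modality_template()].
#' @param ls_ratio Ratio label (numeric > 0, or `"pure_L"`/`"pure_S"`).
#' @param seed Integer seed.
#' @param sample_id Identifier attached to the spectrum.
#' @return A long spectra tibble (`sample_id`, `modality`, `ls_label`,
#'   `ls_ratio`, `wavenumber`, `intensity`).
#' @export
generate_spectrum <- function(template, ls_ratio, seed, sample_id = "s001") {
  stopifnot(inherits(template, "modality_template"))
  fr <- component_fractions(ls_ratio)
  axis <- template$axis
  n_art <- nrow(template$artifact_peaks)
  withr::with_seed(seed, {
    gain <- 1 + stats::rnorm(1, 0, template$scatter_sd)
    offset <- stats::rnorm(1, 0, template$scatter_sd)
    # aliquot-level composition error: the L/S ratio actually probed by this
    # instrument deviates slightly from the preparation's nominal value
    # (pure endpoints carry no ratio and are not perturbed)
    delta <- stats::rnorm(1, 0, template$ratio_sd)
    f_L <- fr$f_L
    r_nominal <- suppressWarnings(as.numeric(ls_ratio))
    if (is.finite(r_nominal)) {
      r_eff <- max(0.01, r_nominal + delta)
      f_L <- r_eff / (1 + r_eff)
    }
    jitter <- 1 + stats::rnorm(n_art, 0, template$artifact_jitter_sd)
    noise <- stats::rnorm(length(axis), 0, template$noise_sd)
    analyte <- f_L * eval_peaks(template$lipid_L_peaks, axis) +
      (1 - f_L) * eval_peaks(template$lipid_S_peaks, axis)
    art <- template$artifact_peaks
    art$amplitude <- art$amplitude * jitter
    clean <- analyte + eval_peaks(art, axis) +
      eval_baseline(template$baseline_coef, axis)
    intensity <- gain * clean + offset + noise
  })
  tibble::tibble(
    sample_id = sample_id,
    modality = template$modality,
    ls_label = as.character(ls_ratio),
    ls_ratio = suppressWarnings(as.numeric(ls_ratio)),
    wavenumber = axis,
    intensity = intensity
  )
}

#' Add cosmic-ray spikes to Raman spectra
#'
#' Cosmic spikes are a CCD detector phenomenon, so only Raman spectra may be
#' spiked. Each spectrum receives a Poisson(`rate`) number of single-channel
#' positive excursions of the given magnitude at seeded random positions.
#'
#' @param data Long spectra tibble containing Raman spectra only.
#' @param rate Expected spikes per spectrum (>= 0).
#' @param magnitude Spike height (a.u.).
#' @param seed Integer seed.
#' @return The spectra tibble with spikes added.
#' @export
inject_cosmic_spikes <- function(data, rate, magnitude, seed) {
  check_spectra_tbl(data)
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  if (any(data$modality != "raman")) {
    stop("cosmic spikes are a CCD artifact: only Raman spectra can be spiked",
         call. = FALSE)
  }
  if (rate == 0) return(data)
  withr::with_seed(seed, {
    data |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_modify(function(df, key) {
        n_spikes <- stats::rpois(1, rate)
        if (n_spikes > 0) {
          pos <- sample.int(nrow(df), min(n_spikes, nrow(df)))
          df$intensity[pos] <- df$intensity[pos] + magnitude
        }
        df
      }) |>
      dplyr::ungroup() |>
      dplyr::relocate(dplyr::all_of(names(data)))
  })
}

#' Generate a paired FTIR + Raman dataset
#'
#' For every (ratio, replicate) combination one FTIR and one Raman spectrum
#' are generated sharing a `sample_id` and L/S label — the pairing contract
#' that all later splits preserve. The default ratio panel is the thirteen
#' mixtures 0.25, 0.5, ..., 3.25; pure endpoints can be appended with
#' `include_pure = TRUE` (they carry `ls_ratio = NA` and are excluded from
#' regression by default).
#'
#' @param ratios Numeric ratio panel.
#' @param replicates Spectra per ratio per modality.
#' @param seed Master seed; every spectrum and the spike stage derive child
#'   seeds from it.
#' @param ftir,raman Modality templates.
#' @param spike_rate,spike_magnitude Cosmic-spike contamination of the Raman
#'   spectra (rate 0 disables).
#' @param include_pure Append pure-L and pure-S samples.
#' @return A long spectra tibble with both modalities.
#' @export
generate_paired_spectra <- function(ratios = seq(0.25, 3.25, by = 0.25),
                                    replicates = 6, seed = 1,
                                    ftir = ftir_template(), raman = raman_template(),
                                    spike_rate = 1, spike_magnitude = 8,
                                    include_pure = FALSE) {
  if (length(ratios) == 0) stop("`ratios` must be non-empty", call. = FALSE)
  labels <- as.character(ratios)
  if (include_pure) labels <- c(labels, "pure_L", "pure_S")
  grid <- tidyr::expand_grid(label = labels, rep = seq_len(replicates))
  grid$sample_id <- sprintf("s%03d", seq_len(nrow(grid)))
  spectra <- purrr::pmap(grid, function(label, rep, sample_id) {
    k <- match(sample_id, grid$sample_id)
    dplyr::bind_rows(
      generate_spectrum(ftir, label, child_seed(seed, 2 * k), sample_id),
      generate_spectrum(raman, label, child_seed(seed, 2 * k + 1), sample_id)
    )
  }) |> purrr::list_rbind()
  if (spike_rate > 0) {
    raman_part <- dplyr::filter(spectra, .data$modality == "raman")
    spiked <- inject_cosmic_spikes(raman_part, spike_rate, spike_magnitude,
                                   child_seed(seed, 999983))
    spectra <- dplyr::bind_rows(dplyr::filter(spectra, .data$modality == "ftir"), spiked) |>
      dplyr::arrange(.data$sample_id, .data$modality, .data$wavenumber)
  }
  spectra
}

#' Write spectra to two-column CSV files plus a manifest
#'
#' Each spectrum becomes one CSV (`wavenumber,intensity` for FTIR,
#' `raman_shift,intensity` for Raman); `manifest.csv` maps each `sample_id`
#' and L/S label to its two files.
#'
#' @param data Long paired spectra tibble.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_spectra <- function(data, dir) {
  check_spectra_tbl(data)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(unique(data$sample_id))
  rows <- purrr::map(ids, function(id) {
    sub <- dplyr::filter(data, .data$sample_id == id)
    paths <- c(ftir = NA_character_, raman = NA_character_)
    for (m in intersect(c("ftir", "raman"), unique(sub$modality))) {
      sp <- dplyr::filter(sub, .data$modality == m)
      axis_name <- if (m == "ftir") "wavenumber" else "raman_shift"
      out <- stats::setNames(sp[, c("wavenumber", "intensity")], c(axis_name, "intensity"))
      paths[[m]] <- file.path(dir, paste0(id, "_", m, ".csv"))
      readr::write_csv(out, paths[[m]])
    }
    tibble::tibble(sample_id = id,
                   ls_ratio = sub$ls_label[1],
                   ftir_path = paths[["ftir"]], raman_path = paths[["raman"]])
  }) |> purrr::list_rbind()
  readr::write_csv(rows, file.path(dir, "manifest.csv"))
  invisible(rows)
}

#' Read a spectra dataset written by [write_spectra()]
#'
#' @param manifest Path to `manifest.csv` (or the directory containing it).
#' @return A long paired spectra tibble.
#' @export
read_spectra <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  man <- readr::read_csv(manifest, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  purrr::pmap(man, function(sample_id, ls_ratio, ftir_path, raman_path) {
    one <- function(path, m) {
      if (is.na(path)) return(NULL)
      sp <- readr::read_csv(path, show_col_types = FALSE)
      tibble::tibble(sample_id = sample_id, modality = m,
                     ls_label = ls_ratio,
                     ls_ratio = suppressWarnings(as.numeric(ls_ratio)),
                     wavenumber = sp[[1]], intensity = sp[[2]])
    }
    dplyr::bind_rows(one(ftir_path, "ftir"), one(raman_path, "raman"))
  }) |> purrr::list_rbind()
}
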