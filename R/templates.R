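#' Describe one spectral band
#'
#' A peak is parameterised by its centre position, full width at half maximum,
#' signed amplitude per unit component fraction and line shape. Negative
#' amplitudes encode subtractive artifacts such as the water bands left by
#' background correction of ATR-FTIR spectra.
#'
#' @param center Band centre (cm^-1).
#' @param width Full width at half maximum (cm^-1), must be positive.
#' @param amplitude Signed peak height (arbitrary units per unit fraction).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A one-row tibble; rows from several calls can be bound into a peak
#'   library.
#' @export
peak_spec <- function(center, width, amplitude, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (!is.finite(width) || width <= 0) stop("peak `width` must be > 0", call. = FALSE)
  tibble::tibble(center = center, width = width, amplitude = amplitude, shape = shape)
}

# Internal: evaluate a peak library on an axis; fractions scale each row's
# amplitude. Returns the summed trace.
eval_peaks <- function(peaks, axis) {
  if (is.null(peaks) || nrow(peaks) == 0) return(numeric(length(axis)))
  out <- numeric(length(axis))
  for (i in seq_len(nrow(peaks))) {
    c0 <- peaks$center[i]; w <- peaks$width[i]; a <- peaks$amplitude[i]
    if (peaks$shape[i] == "gaussian") {
      out <- out + a * exp(-4 * log(2) * ((axis - c0) / w)^2)
    } else {
      hw <- w / 2
      out <- out + a * hw^2 / ((axis - c0)^2 + hw^2)
    }
  }
  out
}

# Internal: polynomial baseline on the unit-scaled axis.
eval_baseline <- function(coef, axis) {
  if (is.null(coef) || length(coef) == 0) return(numeric(length(axis)))
  u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
  Reduce(`+`, lapply(seq_along(coef), function(k) coef[k] * u^(k - 1)))
}

#' Construct a modality template for the synthetic generator
#'
#' A template bundles everything needed to synthesise one modality's spectra:
#' the axis grid, per-lipid peak libraries for lecithin (L) and sphingomyelin
#' (S), modality-specific artifact peaks, a polynomial baseline (fluorescence
#' for Raman), and the noise model (additive sd plus per-spectrum
#' multiplicative gain / additive offset sd).
#'
#' With `strict = TRUE` the constructor enforces the phenomenology the two
#' modalities must reproduce: FTIR templates carry at least one
#' negative-amplitude water artifact in each of 3200-3600 and 1600-1700
#' cm^-1 and lipid bands in the phosphate region (1000-1300 cm^-1); Raman
#' templates carry a positive substrate band within 920-1000 cm^-1 (silicon
#' 2TO) and no lipid bands in the phosphate region.
#'
#' @param modality `"ftir"` or `"raman"`.
#' @param axis Strictly increasing numeric grid (cm^-1).
#' @param lipid_L_peaks,lipid_S_peaks,artifact_peaks Peak libraries built
#'   from [peak_spec()] rows.
#' @param baseline_coef Polynomial coefficients (intercept first) evaluated on
#'   the unit-scaled axis.
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param scatter_sd Sd of the per-spectrum multiplicative gain deviation and
#'   of the additive offset (dimensionless / a.u.).
#' @param artifact_jitter_sd Sd of the per-spectrum relative amplitude jitter
#'   applied to each artifact peak (dimensionless). Water-band mismatch and
#'   substrate/fluorescence contributions vary from deposition to deposition
#'   in real measurements; this jitter is what makes the interference
#'   subspace multi-dimensional, so realistic models need several latent
#'   variables to orthogonalise it. Zero by default (artifacts fixed).
#' @param ratio_sd Sd of the per-spectrum perturbation of the effective L/S
#'   ratio probed by this modality (ratio units). Each instrument measures
#'   its own aliquot of a preparation, so the composition actually deposited
#'   deviates slightly and independently per modality (pipetting, deposition
#'   and drying heterogeneity); this is the irreducible sample-presentation
#'   error that data fusion averages down. Zero by default.
#' @param strict Enforce modality-specific artifact invariants.
#' @return An object of class `modality_template`.
#' @export
modality_template <- function(modality, axis, lipid_L_peaks, lipid_S_peaks,
                              artifact_peaks = NULL, baseline_coef = 0,
                              noise_sd = 0, scatter_sd = 0,
                              artifact_jitter_sd = 0, ratio_sd = 0,
                              strict = TRUE) {
  modality <- match.arg(tolower(modality), c("ftir", "raman"))
  if (any(diff(axis) <= 0)) stop("`axis` must be strictly increasing", call. = FALSE)
  if (noise_sd < 0 || scatter_sd < 0 || artifact_jitter_sd < 0 || ratio_sd < 0) {
    stop("noise scales must be >= 0", call. = FALSE)
  }
  all_peaks <- dplyr::bind_rows(lipid_L_peaks, lipid_S_peaks, artifact_peaks)
  if (nrow(all_peaks) > 0) {
    if (any(all_peaks$width <= 0)) stop("all peak widths must be > 0", call. = FALSE)
    rng <- range(axis)
    if (any(all_peaks$center < rng[1] | all_peaks$center > rng[2])) {
      stop("all peak centers must lie within the axis range", call. = FALSE)
    }
  }
  if (strict) {
    in_band <- function(p, lo, hi) !is.null(p) && nrow(p) > 0 &&
      any(p$center >= lo & p$center <= hi)
    neg_in_band <- function(p, lo, hi) !is.null(p) && nrow(p) > 0 &&
      any(p$center >= lo & p$center <= hi & p$amplitude < 0)
    if (modality == "ftir") {
      if (!neg_in_band(artifact_peaks, 3200, 3600) ||
          !neg_in_band(artifact_peaks, 1600, 1700)) {
        stop("FTIR template needs negative water artifacts in 3200-3600 and 1600-1700 cm^-1",
             call. = FALSE)
      }
      if (!in_band(lipid_L_peaks, 1000, 1300) || !in_band(lipid_S_peaks, 1000, 1300)) {
        stop("FTIR lipid templates need phosphate-region bands (1000-1300 cm^-1)",
             call. = FALSE)
      }
    } else {
      pos <- !is.null(artifact_peaks) && nrow(artifact_peaks) > 0 &&
        any(artifact_peaks$center >= 920 & artifact_peaks$center <= 1000 &
              artifact_peaks$amplitude > 0)
      if (!pos) stop("Raman template needs a positive substrate band in 920-1000 cm^-1",
                     call. = FALSE)
      if (in_band(lipid_L_peaks, 1000, 1300) || in_band(lipid_S_peaks, 1000, 1300)) {
        stop("Raman lipid templates must not carry phosphate-region bands", call. = FALSE)
      }
    }
  }
  structure(list(modality = modality, axis = axis,
                 lipid_L_peaks = lipid_L_peaks, lipid_S_peaks = lipid_S_peaks,
                 artifact_peaks = artifact_peaks %||% peak_spec(axis[1], 1, 0)[0, ],
                 baseline_coef = baseline_coef,
                 noise_sd = noise_sd, scatter_sd = scatter_sd,
                 artifact_jitter_sd = artifact_jitter_sd,
                 ratio_sd = ratio_sd),
            class = "modality_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default ATR-FTIR template
#'
#' 700-4000 cm^-1 at 4 cm^-1 spacing. Lipid bands sit at literature-typical
#' positions: CH2 stretches near 2850/2920, the DPPC ester carbonyl at 1738,
#' sphingomyelin amide I/II near 1645/1545, and the phosphate bands
#' (1085-1235 cm^-1) both lipids share. Artifacts are the negative water
#' bands (OH stretch 3200-3600, OH bend ~1645, libration ~800) left after
#' backgrounding against water. Default noise and artifact jitter are set
#' higher than Raman's:
#' water-background subtraction dominates the FTIR error budget.
#'
#' @param noise_sd,scatter_sd,artifact_jitter_sd,ratio_sd Override the
#'   default noise model.
#' @return A `modality_template`.
#' @export
ftir_template <- function(noise_sd = 0.012, scatter_sd = 0.1,
                          artifact_jitter_sd = 0.3, ratio_sd = 0.25) {
  L <- dplyr::bind_rows(
    peak_spec(2918, 30, 0.60),  # CH2 asymmetric stretch
    peak_spec(2850, 26, 0.42),  # CH2 symmetric stretch
    peak_spec(1738, 24, 0.64),  # ester C=O (glycerophospholipid marker)
    peak_spec(1467, 28, 0.38),  # CH2 scissoring
    peak_spec(1232, 42, 0.48),  # PO2- asymmetric stretch
    peak_spec(1087, 40, 0.58),  # PO2- symmetric stretch
    peak_spec(970, 24, 0.32),   # choline N+(CH3)3
    peak_spec(822, 30, 0.32)    # P-O asymmetric stretch
  )
  S <- dplyr::bind_rows(
    peak_spec(3298, 80, 0.09),  # amide A (NH stretch)
    peak_spec(2920, 32, 0.54),
    peak_spec(2852, 27, 0.36),
    peak_spec(1645, 34, 4.16),  # amide I (sphingomyelin marker)
    peak_spec(1545, 36, 2.88),  # amide II
    peak_spec(1468, 28, 1.76),
    peak_spec(1228, 44, 2.08),
    peak_spec(1085, 40, 2.24)
  )
  art <- dplyr::bind_rows(
    peak_spec(3430, 230, -0.72), # OH stretch mismatch (negative after backgrounding)
    peak_spec(1645, 60, -0.96),  # OH bend
    peak_spec(800, 70, -1.12)    # libration band
  )
  modality_template("ftir", seq(700, 4000, by = 4), L, S, art,
                    baseline_coef = 0, noise_sd = noise_sd,
                    scatter_sd = scatter_sd,
                    artifact_jitter_sd = artifact_jitter_sd,
                    ratio_sd = ratio_sd)
}

#' Default Raman template
#'
#' 400-3200 cm^-1 at 2 cm^-1 spacing (instrument-typical grid). Lipid bands:
#' CH stretches near 2850/2885, CH2 deformation ~1440, CH2 twist ~1302,
#' choline C-N ~718; sphingomyelin adds amide I / trans C=C near 1670. The
#' phosphate bands prominent in FTIR are absent here. Artifacts: the silicon
#' substrate 2TO band near 955 cm^-1 and a broad fluorescence hump plus a
#' gentle polynomial baseline.
#'
#' @param noise_sd,scatter_sd,artifact_jitter_sd,ratio_sd Override the
#'   default noise model.
#' @return A `modality_template`.
#' @export
raman_template <- function(noise_sd = 0.008, scatter_sd = 0.1,
                           artifact_jitter_sd = 0.2, ratio_sd = 0.20) {
  L <- dplyr::bind_rows(
    peak_spec(2882, 30, 0.22),  # CH2 asymmetric stretch
    peak_spec(2848, 26, 0.18),
    peak_spec(1440, 30, 0.14),  # CH2 deformation
    peak_spec(1302, 26, 0.10),  # CH2 twist
    peak_spec(890, 26, 0.05),   # choline skeletal
    peak_spec(718, 20, 0.08)    # choline C-N stretch
  )
  S <- dplyr::bind_rows(
    peak_spec(3062, 40, 0.25),  # =CH stretch
    peak_spec(2885, 32, 1.60),
    peak_spec(2850, 27, 1.30),
    peak_spec(1670, 30, 0.70),  # amide I / trans C=C (sphingosine backbone)
    peak_spec(1442, 30, 0.90),
    peak_spec(718, 20, 0.55)
  )
  art <- dplyr::bind_rows(
    peak_spec(955, 45, 0.25),    # Si substrate 2TO band
    peak_spec(1600, 1800, 0.20, shape = "lorentzian") # broad fluorescence hump
  )
  modality_template("raman", seq(400, 3200, by = 2), L, S, art,
                    baseline_coef = c(0.10, -0.06),
                    noise_sd = noise_sd, scatter_sd = scatter_sd,
                    artifact_jitter_sd = artifact_jitter_sd,
                    ratio_sd = ratio_sd)
}
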