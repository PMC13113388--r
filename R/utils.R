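#' @importFrom rlang .data
#' @importFrom stats predict
NULL

#' Derive a stage-specific child seed from a master seed
#'
#' Each randomised stage of the workflow (generation, splitting,
#' cross-validation, bootstrapping) draws its own seed from the master seed
#' and a fixed stage offset, so changing one stage's configuration never
#' perturbs another stage's random stream.
#'
#' @param master Master seed (integer).
#' @param stage Integer stage offset.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid 32-bit integers
  as.integer(((abs(master) %% m) * 48271 + stage * 16807) %% (m - 1) + 1)
}

#' Re-export of generics::tidy
#' @importFrom generics tidy
#' @export
generics::tidy

#' Re-export of generics::glance
#' @importFrom generics glance
#' @export
generics::glance

#' Re-export of ggplot2::autoplot
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Internal: check that a data frame carries the long spectra columns.
check_spectra_tbl <- function(data, cols = c("sample_id", "modality", "wavenumber", "intensity")) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame of spectra.", call. = FALSE)
  }
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop("`data` is missing spectra column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(data)
}

#' Convert long spectra to a samples-by-channels matrix
#'
#' Reshapes the long spectra table of one modality into the wide matrix used
#' by the regression stage: one row per sample (ordered by `sample_id`), one
#' column per channel (ascending axis position).
#'
#' @param data Long spectra tibble (`sample_id`, `modality`, `wavenumber`,
#'   `intensity`, optionally `ls_ratio`).
#' @param modality Which modality to extract; if `NULL`, `data` must contain a
#'   single modality.
#' @return A list with `X` (numeric matrix, rownames = sample ids), `y`
#'   (numeric L/S ratios, `NA` for pure endpoints, in row order), `axis`
#'   (channel positions) and `sample_id`.
#' @export
spectra_matrix <- function(data, modality = NULL) {
  check_spectra_tbl(data)
  if (!is.null(modality)) {
    data <- dplyr::filter(data, .data$modality == !!modality)
  }
  if (nrow(data) == 0) stop("no spectra for requested modality", call. = FALSE)
  if (length(unique(data$modality)) > 1) {
    stop("`data` holds several modalities; pass `modality` explicitly.", call. = FALSE)
  }
  wide <- data |>
    dplyr::select("sample_id", "wavenumber", "intensity") |>
    dplyr::arrange(.data$sample_id, .data$wavenumber) |>
    tidyr::pivot_wider(names_from = "wavenumber", values_from = "intensity")
  X <- as.matrix(wide[, -1])
  rownames(X) <- wide$sample_id
  y <- NULL
  if ("ls_ratio" %in% names(data)) {
    lab <- dplyr::distinct(data, .data$sample_id, .data$ls_ratio) |>
      dplyr::arrange(.data$sample_id)
    y <- lab$ls_ratio[match(wide$sample_id, lab$sample_id)]
  }
  list(X = X, y = y, axis = as.numeric(colnames(wide)[-1]), sample_id = wide$sample_id)
}
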