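#' Configuration for the five-model comparison experiment
#'
#' Collects every tunable of the workflow with its default: nominal
#' miscoverage 0.05 (z = 1.96), 80/20 train/test split, 50 cross-validation
#' splits at 80/20 within the training set, latent variables examined from 1
#' to 30, 100 bootstrap resamples for the conformal intervals, the
#' modality-specific SNV regions, the 2500 cm^-1 FTIR baseline anchor, and
#' the synthetic generator settings (13-ratio panel, 6 replicates).
#'
#' @param alpha Miscoverage probability.
#' @param z Normal quantile for sigma proxies.
#' @param train_frac Training fraction of the outer split.
#' @param n_cv_splits,cv_test_frac,lv_max Cross-validation settings.
#' @param n_bootstrap Bootstrap resamples for the interval stage.
#' @param seed Master seed; all stages derive child seeds from it.
#' @param ftir_snv_region,raman_snv_region SNV anchor regions.
#' @param baseline_anchor FTIR baseline anchor (cm^-1).
#' @param despike_window,despike_threshold Despiking parameters.
#' @param ratios,replicates Synthetic panel (used when `data = NULL`).
#' @param ftir,raman Modality templates for the generator.
#' @param spike_rate,spike_magnitude Cosmic-spike contamination.
#' @param data Optional pre-generated long paired spectra tibble; `NULL`
#'   generates synthetic data from the settings above.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(alpha = 0.05, z = 1.96, train_frac = 0.8,
                              n_cv_splits = 50, cv_test_frac = 0.2, lv_max = 30,
                              n_bootstrap = 100, seed = 1,
                              ftir_snv_region = c(850, 2000),
                              raman_snv_region = NULL,
                              baseline_anchor = 2500,
                              despike_window = 7, despike_threshold = 8,
                              ratios = seq(0.25, 3.25, by = 0.25), replicates = 6,
                              ftir = ftir_template(), raman = raman_template(),
                              spike_rate = 1, spike_magnitude = 8,
                              data = NULL) {
  stopifnot(alpha > 0, alpha < 1, train_frac > 0, train_frac < 1,
            cv_test_frac > 0, cv_test_frac < 1)
  structure(as.list(environment()), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment configuration: alpha", x$alpha, "| train", x$train_frac,
      "| CV", x$n_cv_splits, "splits | LV <=", x$lv_max,
      "| B", x$n_bootstrap, "| seed", x$seed, "\n")
  invisible(x)
}

#' Split paired samples into train and test sets
#'
#' Samples are assigned atomically: both modalities of a pair travel
#' together, so the pairing established at generation time survives the
#' split.
#'
#' @param data Long paired spectra tibble.
#' @param train_frac Training fraction.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test` (disjoint, union = input).
#' @export
split_train_test <- function(data, train_frac = 0.8, seed = 1) {
  check_spectra_tbl(data)
  ids <- sort(unique(data$sample_id))
  n <- length(ids)
  if (n < 5) stop("need at least 5 paired samples to split", call. = FALSE)
  n_train <- round(train_frac * n)
  if (n_train < 1 || n_train >= n) stop("degenerate split", call. = FALSE)
  train_ids <- withr::with_seed(seed, sort(sample(ids, n_train)))
  list(train = dplyr::filter(data, .data$sample_id %in% train_ids),
       test = dplyr::filter(data, !.data$sample_id %in% train_ids))
}

# Internal: CV + F-test selection + full-training refit + JAB intervals for
# one spectra matrix.
run_plsr_branch <- function(X_tr, y_tr, X_te, config, cv_seed, jab_seed) {
  cv <- cross_validate(X_tr, y_tr, lv_max = config$lv_max,
                       n_splits = config$n_cv_splits,
                       test_frac = config$cv_test_frac, seed = cv_seed)
  k <- select_n_lv(cv, alpha = config$alpha)
  # bootstrap resamples can carry duplicated rows with lower effective rank,
  # so the interval-stage learner extracts up to k components gracefully
  learner <- function(X, y) nipals_pls1(X, y, min(k, nrow(X) - 1, ncol(X)))
  intervals <- jab_intervals(X_tr, y_tr, X_te, learner,
                             B = config$n_bootstrap, alpha = config$alpha,
                             z = config$z, seed = jab_seed)
  list(cv = cv, n_lv = k, intervals = intervals)
}

#' Run the full five-model comparison experiment
#'
#' Executes the whole workflow from one master seed: generate (or take)
#' paired spectra; condition them (despike, baseline offset, region SNV);
#' split 80/20 by pair; for each of FTIR, Raman and the low-level fused
#' (concatenated) spectra run cross-validated PLS with F-test latent-variable
#' selection, refit on the full training set and build
#' jackknife+-after-bootstrap intervals on the identical test set; then form
#' the two high-level fusion models (unweighted mean and inverse-variance
#' weighted) from the FTIR and Raman test outputs without refitting.
#' Pure-endpoint samples (non-numeric L/S labels) are excluded from
#' modelling.
#'
#' @param config An [experiment_config()].
#' @return An object of class `ls_experiment`: `$report` (five rows of
#'   [interval_report()] columns plus `n_lv`), `$intervals` (per-sample,
#'   per-model test intervals with `y_true`), `$cv` (the three `plsr_cv`
#'   objects), `$config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  data <- config$data %||% generate_paired_spectra(
    ratios = config$ratios, replicates = config$replicates,
    seed = child_seed(seed, 1),
    ftir = config$ftir, raman = config$raman,
    spike_rate = config$spike_rate, spike_magnitude = config$spike_magnitude)
  data <- dplyr::filter(data, is.finite(.data$ls_ratio)) # drop pure endpoints
  pre <- preprocess_spectra(data,
                            despike_window = config$despike_window,
                            despike_threshold = config$despike_threshold,
                            baseline_anchor = config$baseline_anchor,
                            ftir_snv_region = config$ftir_snv_region,
                            raman_snv_region = config$raman_snv_region)
  split <- split_train_test(pre, config$train_frac, seed = child_seed(seed, 2))

  mats <- function(d) list(ftir = spectra_matrix(d, "ftir"),
                           raman = spectra_matrix(d, "raman"),
                           fused = fused_matrix(fuse_low_level(d)))
  tr <- mats(split$train); te <- mats(split$test)
  stopifnot(length(intersect(rownames(tr$ftir$X), rownames(te$ftir$X))) == 0)

  branches <- purrr::imap(list(ftir = 1, raman = 2, low_level = 3), function(i, nm) {
    key <- c(ftir = "ftir", raman = "raman", low_level = "fused")[[nm]]
    run_plsr_branch(tr[[key]]$X, tr[[key]]$y, te[[key]]$X, config,
                    cv_seed = child_seed(seed, 10 + i),
                    jab_seed = child_seed(seed, 20 + i))
  })

  pi_f <- branches$ftir$intervals
  pi_r <- branches$raman$intervals
  hl_mean <- fuse_mean(pi_f, pi_r, z = config$z)
  hl_weighted <- fuse_weighted(pi_f, pi_r, z = config$z)

  y_test <- te$ftir$y
  model_intervals <- list(ftir = pi_f, raman = pi_r,
                          high_level_mean = hl_mean,
                          low_level = branches$low_level$intervals,
                          high_level_weighted = hl_weighted)
  n_lv <- c(ftir = branches$ftir$n_lv, raman = branches$raman$n_lv,
            high_level_mean = NA_integer_,
            low_level = branches$low_level$n_lv,
            high_level_weighted = NA_integer_)
  rng <- max(y_test) - min(y_test)
  report <- purrr::imap(model_intervals, function(pi, nm) {
    interval_report(pi, y_test, alpha = config$alpha, range = rng, model = nm)
  }) |> purrr::list_rbind() |>
    dplyr::mutate(n_lv = unname(n_lv), .after = "model")

  intervals <- purrr::imap(model_intervals, function(pi, nm) {
    dplyr::bind_cols(tibble::tibble(model = nm, sample_id = te$ftir$sample_id,
                                    y_true = y_test),
                     dplyr::select(pi, dplyr::any_of(c("point", "lower", "upper", "sigma"))))
  }) |> purrr::list_rbind()

  structure(list(report = report, intervals = intervals,
                 cv = purrr::map(branches, "cv"),
                 n_lv = n_lv, config = config,
                 train_ids = rownames(tr$ftir$X), test_ids = te$ftir$sample_id),
            class = "ls_experiment")
}

#' @export
print.ls_experiment <- function(x, ...) {
  cat("Five-model L/S comparison (seed ", x$config$seed, "), ",
      length(x$train_ids), " train / ", length(x$test_ids), " test pairs\n\n", sep = "")
  print(as.data.frame(dplyr::select(x$report, "model", "n_lv", "mse", "r2",
                                    "picp", "ace", "pinaw")), digits = 3,
        row.names = FALSE)
  invisible(x)
}

#' @rdname run_experiment
#' @param x,object An `ls_experiment`.
#' @param ... Unused.
#' @export
tidy.ls_experiment <- function(x, ...) x$report

#' @rdname run_experiment
#' @export
glance.ls_experiment <- function(x, ...) {
  tibble::tibble(n_train = length(x$train_ids), n_test = length(x$test_ids),
                 best_mse_model = x$report$model[which.min(x$report$mse)],
                 best_pinaw_model = x$report$model[which.min(x$report$pinaw)],
                 seed = x$config$seed)
}

#' @rdname run_experiment
#' @export
autoplot.ls_experiment <- function(object, ...) {
  df <- dplyr::mutate(object$intervals,
                      model = factor(.data$model, levels = unique(.data$model)))
  ggplot2::ggplot(df, ggplot2::aes(.data$y_true, .data$point)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "firebrick") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.05, colour = "grey40") +
    ggplot2::geom_point(size = 1.3) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "actual L/S ratio", y = "predicted L/S ratio") +
    ggplot2::theme_minimal()
}

#' Write a comparison report to disk
#'
#' Writes `report.csv` (five model rows, metric columns in the comparison
#' table's order), `intervals.csv` (per-sample test intervals) and
#' `report.json` (report plus configuration echo and seeds).
#'
#' @param x An `ls_experiment`.
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "ls_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("model", "n_lv", "lower_min", "lower_mean", "lower_max",
            "upper_min", "upper_mean", "upper_max",
            "mse", "picp", "ace", "pinaw", "r2", "n_test", "range")
  readr::write_csv(dplyr::select(x$report, dplyr::all_of(cols)),
                   file.path(dir, "report.csv"))
  readr::write_csv(x$intervals, file.path(dir, "intervals.csv"))
  cfg <- x$config[setdiff(names(x$config), c("data", "ftir", "raman"))]
  cfg$raman_snv_region <- cfg$raman_snv_region %||% "full"
  jsonlite::write_json(list(report = x$report, n_lv = as.list(x$n_lv),
                            config = cfg,
                            train_ids = x$train_ids, test_ids = x$test_ids),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a report written by [write_report()]
#'
#' @param dir Directory written by [write_report()].
#' @return A list with tibbles `report` and `intervals`.
#' @export
read_report <- function(dir) {
  list(report = readr::read_csv(file.path(dir, "report.csv"), show_col_types = FALSE),
       intervals = readr::read_csv(file.path(dir, "intervals.csv"),
                                   show_col_types = FALSE))
}

#' Plot spectra coloured by composition
#'
#' @param data Long spectra tibble.
#' @return A ggplot faceted by modality.
#' @export
plot_spectra <- function(data) {
  check_spectra_tbl(data)
  ggplot2::ggplot(data, ggplot2::aes(.data$wavenumber, .data$intensity,
                                     group = .data$sample_id,
                                     colour = .data$ls_ratio)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~modality, scales = "free") +
    ggplot2::scale_colour_viridis_c(name = "L/S") +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}
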