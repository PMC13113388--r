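small_config <- function(seed = 1) {
  experiment_config(seed = seed, replicates = 2, n_cv_splits = 8, lv_max = 6,
                    n_bootstrap = 30,
                    ftir = tiny_ftir(noise_sd = 0.01, artifact_jitter_sd = 0.2,
                                     ratio_sd = 0.15),
                    raman = tiny_raman(noise_sd = 0.01, artifact_jitter_sd = 0.2,
                                       ratio_sd = 0.12))
}

test_that("train/test split assigns pairs atomically and is seeded", {
  d <- generate_paired_spectra(ratios = seq(0.25, 3.25, 0.25), replicates = 2,
                               seed = 1, ftir = tiny_ftir(), raman = tiny_raman(),
                               spike_rate = 0)
  sp <- split_train_test(d, 0.8, seed = 9)
  ids_tr <- unique(sp$train$sample_id); ids_te <- unique(sp$test$sample_id)
  expect_length(ids_tr, round(0.8 * 26))
  expect_length(ids_te, 26 - round(0.8 * 26))
  expect_length(intersect(ids_tr, ids_te), 0)
  expect_setequal(c(ids_tr, ids_te), unique(d$sample_id))
  # both modalities of a pair travel together
  expect_true(all(table(dplyr::distinct(sp$train, sample_id, modality)$sample_id) == 2))
  expect_identical(split_train_test(d, 0.8, seed = 9)$test$sample_id[1],
                   sp$test$sample_id[1])
  sp2 <- split_train_test(d, 0.8, seed = 10)
  expect_false(setequal(ids_te, unique(sp2$test$sample_id)))
  expect_error(split_train_test(dplyr::filter(d, sample_id %in% c("s001", "s002")),
                                0.8, 1), "at least 5")
})

test_that("the experiment produces a complete, reproducible five-model report", {
  ex <- run_experiment(small_config(seed = 3))
  expect_s3_class(ex, "ls_experiment")
  expect_equal(ex$report$model,
               c("ftir", "raman", "high_level_mean", "low_level",
                 "high_level_weighted"))
  expect_true(all(c("mse", "r2", "picp", "ace", "pinaw", "lower_min", "lower_mean",
                    "lower_max", "upper_min", "upper_mean", "upper_max", "n_lv",
                    "n_test", "range") %in% names(ex$report)))
  expect_true(all(is.finite(ex$report$mse)))
  expect_true(all(ex$report$picp >= 0 & ex$report$picp <= 1))
  expect_equal(ex$report$ace, ex$report$picp - 0.95)
  expect_true(all(is.na(ex$report$n_lv[c(3, 5)]))) # decision-level rows refit nothing
  expect_true(all(ex$report$n_lv[c(1, 2, 4)] >= 1))
  # identical config + seed -> identical report
  ex2 <- run_experiment(small_config(seed = 3))
  expect_equal(ex$report, ex2$report)
  expect_equal(ex$intervals, ex2$intervals)
  # no test pair ever enters training
  expect_length(intersect(ex$train_ids, ex$test_ids), 0)
  # all five models share the identical test set
  per_model <- dplyr::summarise(ex$intervals,
                                ids = paste(sort(unique(sample_id)), collapse = ","),
                                .by = model)
  expect_length(unique(per_model$ids), 1)
})

test_that("high-level rows are pure functions of the individual models' outputs", {
  ex <- run_experiment(small_config(seed = 5))
  pf <- dplyr::filter(ex$intervals, model == "ftir")
  pr <- dplyr::filter(ex$intervals, model == "raman")
  hm <- dplyr::filter(ex$intervals, model == "high_level_mean")
  hw <- dplyr::filter(ex$intervals, model == "high_level_weighted")
  expect_equal(hm$point, (pf$point + pr$point) / 2)
  re_w <- fuse_weighted(dplyr::select(pf, point, lower, upper),
                        dplyr::select(pr, point, lower, upper))
  expect_equal(hw$point, re_w$point)
  expect_equal(hw$lower, re_w$lower)
  # pooled widths never exceed either parent's width
  expect_true(all(hw$upper - hw$lower <=
                    pmin(pf$upper - pf$lower, pr$upper - pr$lower) + 1e-12))
})

test_that("reports round-trip through CSV/JSON on disk", {
  ex <- run_experiment(small_config(seed = 2))
  dir <- withr::local_tempdir()
  write_report(ex, dir)
  expect_true(all(file.exists(file.path(dir, c("report.csv", "intervals.csv",
                                               "report.json")))))
  back <- read_report(dir)
  expect_equal(back$report$model, ex$report$model)
  expect_equal(back$report$mse, ex$report$mse, tolerance = 1e-10)
  expect_equal(back$report$n_lv, ex$report$n_lv)
  expect_equal(names(back$report)[1:2], c("model", "n_lv"))
  cols <- names(back$report)
  expect_true(which(cols == "mse") < which(cols == "picp"))
  expect_true(which(cols == "picp") < which(cols == "ace"))
  expect_true(which(cols == "ace") < which(cols == "pinaw"))
  expect_equal(back$intervals$point,
               ex$intervals$point, tolerance = 1e-10)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$config$seed, 2)
  expect_length(js$report, 5)
})

test_that("summary methods and plots expose the report", {
  ex <- run_experiment(small_config(seed = 4))
  expect_equal(tidy(ex), ex$report)
  g <- glance(ex)
  expect_equal(g$n_test, length(ex$test_ids))
  expect_true(g$best_pinaw_model %in% ex$report$model)
  expect_s3_class(autoplot(ex), "ggplot")
  expect_s3_class(autoplot(ex$cv$ftir), "ggplot")
  expect_s3_class(plot_spectra(generate_paired_spectra(ratios = 1, replicates = 1,
                                                       seed = 1, ftir = tiny_ftir(),
                                                       raman = tiny_raman(),
                                                       spike_rate = 0)), "ggplot")
  expect_output(print(ex), "five-model|Five-model")
})
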