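test_that("component fractions follow the constant-total-lipid mixing rule", {
  fr <- component_fractions(c(1, 3, 0.25))
  expect_equal(fr$f_L, c(0.5, 0.75, 0.2))
  expect_equal(fr$f_S, c(0.5, 0.25, 0.8))
  expect_equal(fr$f_L + fr$f_S, rep(1, 3))
  pure <- component_fractions(c("pure_L", "pure_S"))
  expect_equal(pure$f_L, c(1, 0))
  expect_equal(pure$f_S, c(0, 1))
  expect_error(component_fractions(0), "pure_L")
  expect_error(component_fractions(-2), "pure_L")
  expect_error(component_fractions(Inf))
})

test_that("spectrum generation is seeded, deterministic and matches the clean mixture", {
  tpl <- tiny_ftir()
  a <- generate_spectrum(tpl, 1.5, seed = 42)
  b <- generate_spectrum(tpl, 1.5, seed = 42)
  expect_identical(a, b)
  noisy <- tiny_ftir(noise_sd = 0.01)
  expect_false(identical(generate_spectrum(noisy, 1.5, seed = 42)$intensity,
                         generate_spectrum(noisy, 1.5, seed = 43)$intensity))
  expect_true(all(is.finite(a$intensity)))
  expect_equal(nrow(a), length(tpl$axis))
  # zero stochastic scales: output equals the independently computed mixture
  expect_equal(a$intensity, oracle_clean_trace(tpl, 1.5), tolerance = 1e-12)
})

test_that("pure endpoints carry no contribution from the other lipid", {
  tpl <- tiny_ftir()
  pure_s <- generate_spectrum(tpl, "pure_S", seed = 1)
  expect_equal(pure_s$intensity, oracle_clean_trace(tpl, "pure_S"), tolerance = 1e-12)
  # a template with the L library emptied produces the identical pure-S
  # spectrum: zero contribution from lipid_L_peaks
  no_L <- modality_template("ftir", tpl$axis, tpl$lipid_L_peaks[0, ],
                            tpl$lipid_S_peaks, tpl$artifact_peaks, strict = FALSE)
  expect_equal(pure_s$intensity, generate_spectrum(no_L, "pure_S", seed = 1)$intensity,
               tolerance = 1e-12)
  expect_equal(pure_s$ls_label, rep("pure_S", nrow(pure_s)))
  expect_true(all(is.na(pure_s$ls_ratio)))
})

test_that("analyte signal is affine in the mixing fractions at zero noise", {
  tpl <- tiny_raman()
  r1 <- 0.5; r2 <- 3.0
  f_mid <- (r1 / (1 + r1) + r2 / (1 + r2)) / 2 # midpoint in fraction space
  r_mid <- f_mid / (1 - f_mid)
  s1 <- generate_spectrum(tpl, r1, seed = 1)$intensity
  s2 <- generate_spectrum(tpl, r2, seed = 2)$intensity
  sm <- generate_spectrum(tpl, r_mid, seed = 3)$intensity
  expect_equal(sm, (s1 + s2) / 2, tolerance = 1e-10)
})

test_that("cosmic spikes are Raman-only, Poisson-seeded and dominant when large", {
  tpl <- tiny_raman()
  base <- generate_spectrum(tpl, 1, seed = 5)
  expect_identical(inject_cosmic_spikes(base, rate = 0, magnitude = 10, seed = 1), base)
  sp1 <- inject_cosmic_spikes(base, rate = 3, magnitude = 10, seed = 9)
  sp2 <- inject_cosmic_spikes(base, rate = 3, magnitude = 10, seed = 9)
  expect_identical(sp1, sp2)
  big <- inject_cosmic_spikes(base, rate = 4, magnitude = 50 * max(base$intensity),
                              seed = 2)
  hit <- big$intensity != base$intensity
  expect_gt(sum(hit), 0)
  expect_true(all(big$intensity[hit] > max(base$intensity)))
  ftir <- generate_spectrum(tiny_ftir(), 1, seed = 1)
  expect_error(inject_cosmic_spikes(ftir, 1, 10, 1), "Raman")
})

test_that("paired generation yields index-matched FTIR/Raman datasets", {
  d <- generate_paired_spectra(ratios = seq(0.25, 3.25, by = 0.25), replicates = 3,
                               seed = 7, ftir = tiny_ftir(), raman = tiny_raman(),
                               spike_rate = 0)
  ids <- unique(d$sample_id)
  expect_length(ids, 39) # 13 ratios x 3 replicates
  per_sample <- dplyr::count(dplyr::distinct(d, sample_id, modality), sample_id)
  expect_true(all(per_sample$n == 2)) # 78 spectra in 39 pairs
  lab <- dplyr::distinct(d, sample_id, modality, ls_label) |>
    tidyr::pivot_wider(names_from = modality, values_from = ls_label)
  expect_equal(lab$ftir, lab$raman) # every pair shares its L/S label
  expect_setequal(unique(d$ls_ratio), seq(0.25, 3.25, by = 0.25))
  expect_identical(d, generate_paired_spectra(ratios = seq(0.25, 3.25, by = 0.25),
                                              replicates = 3, seed = 7,
                                              ftir = tiny_ftir(), raman = tiny_raman(),
                                              spike_rate = 0))
})

test_that("default FTIR spectra go negative in the OH-stretch window, Raman do not", {
  d <- generate_paired_spectra(ratios = c(0.5, 1.5, 3), replicates = 2, seed = 3)
  oh <- dplyr::filter(d, wavenumber >= 3200, wavenumber <= 3600)
  ftir_min <- dplyr::summarise(dplyr::filter(oh, modality == "ftir"),
                               m = min(intensity), .by = sample_id)
  expect_true(all(ftir_min$m < 0))
  raman_oh <- dplyr::filter(oh, modality == "raman")
  expect_true(all(raman_oh$intensity >= 0))
})

test_that("spectra round-trip through the CSV + manifest format", {
  d <- generate_paired_spectra(ratios = c(0.5, 2), replicates = 1, seed = 11,
                               ftir = tiny_ftir(0.01), raman = tiny_raman(0.01))
  dir <- withr::local_tempdir()
  man <- write_spectra(d, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_named(man, c("sample_id", "ls_ratio", "ftir_path", "raman_path"))
  # modality-specific axis headers
  expect_equal(names(readr::read_csv(man$ftir_path[1], show_col_types = FALSE))[1],
               "wavenumber")
  expect_equal(names(readr::read_csv(man$raman_path[1], show_col_types = FALSE))[1],
               "raman_shift")
  back <- read_spectra(dir)
  expect_equal(
    dplyr::arrange(back, sample_id, modality, wavenumber)$intensity,
    dplyr::arrange(d, sample_id, modality, wavenumber)$intensity,
    tolerance = 1e-8)
})
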