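---
title: "Predicting lipid composition by fusing FTIR and Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lipid composition by fusing FTIR and Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibrafuse)
```

## The problem

Lipid vesicles built from lecithin (DPPC, "L") and sphingomyelin ("S") are a
standard physicochemical model both for pulmonary lamellar bodies — whose
lecithin/sphingomyelin (L/S) ratio falls below roughly 2.2 in neonatal
respiratory distress syndrome — and for liposomal drug formulations, where
composition control is a quality attribute. Vibrational spectroscopy offers
a rapid, label-free route to the L/S ratio, but each modality is imperfect
in its own way: ATR-FTIR of aqueous samples is backgrounded against water,
leaving negative residual water bands (OH stretch near 3200–3600 cm⁻¹, OH
bend near 1645 cm⁻¹, libration near 800 cm⁻¹) that overlap lipid features,
while Raman spectra are clean of water but carry a silicon substrate band
(the 2TO phonon near 920–1000 cm⁻¹), broad fluorescence, and cosmic-ray
spikes. The two error structures are largely independent, which is exactly
the situation in which data fusion pays off.

`vibrafuse` implements the complete comparison of five regression
strategies for the L/S ratio from paired FTIR + Raman spectra:

1. **FTIR** — partial least squares regression (PLSR) on the FTIR block;
2. **Raman** — PLSR on the Raman block;
3. **high-level mean fusion** — the unweighted mean of the two models'
   predictions;
4. **low-level fusion** — PLSR on the row-wise concatenation of the two
   SNV-normalised blocks;
5. **high-level inverse-variance weighted fusion** — a per-sample weighted
   combination with weights `w = 1/σ²`, where σ is derived from each
   model's conformal prediction-interval width.

Every model is evaluated on an identical held-out test set with both
accuracy metrics (MSE, R²) and prediction-interval figures of merit.

## The statistical machinery

### PLSR with cross-validated, F-test-based complexity selection

The regression core is single-response NIPALS PLS on mean-centred spectra
(no variance scaling — SNV already fixes the intensity scale; the target is
mean-centred only). Components are nested, so one fit yields predictions at
every latent-variable (LV) count up to the maximum. Model complexity is
chosen by `cross_validate()` + `select_n_lv()`:

* the training set is split 80%/20% into cross-validation train/test
  subsets, 50 times, with the identical splits reused for every LV count;
* mean train/test MSE and R² are recorded for LV counts 1–30 (capped at the
  rank every split supports);
* the selected count is the *smallest* k whose mean CV-test MSE is not
  significantly worse than the minimum-MSE count k\*, judged by a one-sided
  F ratio `MSE_k / MSE_k*` against `qf(1 − α; df, df)` with df equal to the
  total number of CV-test predictions. This is a deliberately parsimonious
  rule: it typically returns fewer LVs than the raw argmin, trading a
  statistically invisible amount of CV error for better generalisation.

The deployed model is then refit on the full training set at the selected
complexity.

### Jackknife+-after-bootstrap prediction intervals

Intervals come from the jackknife+-after-bootstrap construction
(`jab_intervals()`), which is model-agnostic and distribution-free: B = 100
bootstrap models are trained on with-replacement resamples; each training
point gets an out-of-bag (OOB) aggregate prediction and absolute residual
Rᵢ; a test point's interval is formed from the order statistics of
`{ŷ₋ᵢ(x) ± Rᵢ}` at rank `⌈(1 − α)(n + 1)⌉`. Coverage is guaranteed at
`1 − 2α` and concentrates near `1 − α` in practice; the package's test
suite verifies empirical coverage of ~0.95 at α = 0.05 on linear-Gaussian
simulations. The reported point prediction is the full-training-set refit
(the bootstrap-aggregate mean is returned alongside as `point_bagged`).

### Fusion rules and the σ proxy

Conformal intervals carry no parametric variance, so the uncertainty proxy
is `σ = (upper − lower)/(2z)` with z = 1.96 for 95% intervals
(`sigma_from_interval()`). Weighted fusion combines per-sample predictions
with weights `1/σ²`; its own interval is the symmetric z-interval around
the pooled `σ_fused = (1/σ_F² + 1/σ_R²)^(−1/2)`. Two consequences are worth
stating because the tests rely on them: the fused point always lies between
the two parent predictions, and the fused width never exceeds the smaller
parent width. Mean fusion (`fuse_mean()`) is the equal-weight special case,
with `σ = sqrt(σ_F² + σ_R²)/2` — the standard deviation of an average of
two independent predictions. The choice of interval rule for the two
high-level models is a package design decision (no canonical rule exists
for combining conformal intervals); inverse-variance pooling was chosen
because it reproduces the near-constant, narrowest interval widths that
weighted fusion exhibits empirically, and because the two rules coincide
when the σs are equal, keeping mean fusion a genuine special case.

A σ of exactly zero in one modality sends all weight to that modality (the
limit of `1/σ²`), implemented without dividing by zero; both σs zero is a
degenerate-weights error.

### Figures of merit

`pinc(α) = 100(1 − α)%` is the nominal coverage; `picp()` the empirical
fraction of targets inside their (closed) intervals; `ace() = PICP − PINC`
(fractions) the calibration error; `pinaw()` the mean interval width
normalised by the range R of the observed test values. R is taken as
`max(y_test) − min(y_test)`: with the full 0.25–3.25 panel this is 3.0,
which is the normalisation under which the published per-model widths and
PINAW values are mutually consistent. Coverage uses closed bounds (ties
count as covered).

## The synthetic data generator

The package is exercised end-to-end on synthetic paired spectra
(`generate_paired_spectra()`), so no download is needed. The generator
emulates the named phenomenology of each modality:

* two-component linear mixing at constant total lipid: a ratio label r maps
  to fractions `f_L = r/(1+r)`, `f_S = 1/(1+r)`; the default panel is the
  thirteen ratios 0.25, 0.50, …, 3.25 with 6 replicates; pure endpoints are
  non-numeric markers excluded from regression;
* FTIR: negative water bands at 3430, 1645 and 800 cm⁻¹; lipid bands at
  literature-typical positions including the phosphate region
  (1000–1300 cm⁻¹), which the Raman templates deliberately lack; axis
  700–4000 cm⁻¹ at 4 cm⁻¹;
* Raman: silicon 2TO substrate band near 955 cm⁻¹, a broad fluorescence
  hump plus a gentle polynomial baseline, cosmic spikes
  (Poisson-distributed single-channel positive excursions, Raman-only — a
  CCD phenomenon); axis 400–3200 cm⁻¹ at 2 cm⁻¹;
* per-spectrum multiplicative gain and additive offset (scatter variation),
  i.i.d. channel noise, per-spectrum artifact-amplitude jitter, and an
  aliquot-level composition error on the ratio scale.

The last two terms deserve explanation, because they go beyond the minimal
"fixed artifacts + white noise" model. With fixed artifacts and i.i.d.
noise only, the spectra are strictly affine in a single analyte direction;
every model then hits the same nonlinear-inversion floor for r and the
five models' errors are almost perfectly correlated, so no fusion strategy
can beat the better individual modality — qualitatively unlike real data,
where the fused models win. Two physically grounded variance sources
restore realism:

* **artifact jitter** — the residual water-band amplitude, substrate
  exposure and fluorescence level vary from deposition to deposition;
* **aliquot composition error** (`ratio_sd`, in ratio units) — each
  instrument measures its *own* aliquot of a preparation (a droplet dried
  on silicon for Raman, a film on the ATR crystal for FTIR), so the
  composition actually probed deviates independently per modality. This is
  the irreducible, modality-independent error that fusion averages down.

Both scales are zero in the bare `modality_template()` constructor — all
zero-noise contracts (affine mixing, endpoint purity, determinism) hold
exactly — and are enabled in the laboratory defaults `ftir_template()`
(noise 0.012, jitter 0.30, ratio error 0.25) and `raman_template()` (noise
0.008, jitter 0.20, ratio error 0.20). FTIR carries the larger error
budget because water-background subtraction dominates it in practice. The
defaults were calibrated once so that the individual-modality test R²
falls in the 0.90–0.95 band reported for bench instruments on this system,
and then frozen.

Two template-design choices matter for the science and are deliberate:

* **Sphingomyelin bands dominate the SNV anchor-region variance.** The SNV
  scale then tracks `f_S`, and since `1/f_S = 1 + r` and `f_L/f_S = r`, the
  normalised channels become nearly linear in the ratio itself. This
  mirrors why real PLSR calibrations of ratio-type targets work as well as
  they do; without it, a linear model faces a strongly convex inversion
  problem.
* **The two SNV'd blocks carry comparable total variance.** FTIR is
  normalised on 850–2000 cm⁻¹, so its out-of-region channels are divided
  by the in-region scale; amplitudes were balanced so that neither block
  numerically dominates the concatenated model.

What the generator does *not* emulate: ATR penetration-depth dispersion,
instrument line-shape convolution, wavenumber calibration drift,
atmospheric CO₂/water-vapour lines, detector nonlinearity, and any
non-lipid matrix. Passing tests therefore demonstrate that the *workflow*
behaves as published under a faithful error structure — not that the
package reproduces instrument-specific absolute performance on real
vesicle preparations.

## Preprocessing choices

The conditioning chain is fixed as despike → baseline offset → SNV:

* **Despiking** (Raman only, window 7 channels, robust-z threshold 8):
  channels deviating from the running median by more than
  `threshold × 1.4826 × MAD` of the deviations are replaced by the running
  median. Two numerical details: the robust scale is floored at 2% of the
  spectrum's intensity range, because on noiseless data the MAD collapses
  and smooth curvature would be flagged (cosmic spikes are large relative
  to the whole trace, so the floor costs no sensitivity that matters); and
  boundary channels use shrinking partial windows, so an edge spike cannot
  mask itself through replicated padding.
* **Baseline offset** (FTIR only) subtracts the intensity at the grid point
  nearest 2500 cm⁻¹ — a region free of lipid and water bands — with ties
  broken toward the lower wavenumber, a deterministic grid-independent
  rule.
* **Region-anchored SNV**: location and scale are estimated on 850–2000
  cm⁻¹ for FTIR (clear of the strong OH-stretch artifact and of CO₂ lines
  near 2349 cm⁻¹) and on the whole spectrum for Raman, then applied to all
  channels. SNV is strictly per-spectrum, so no information leaks between
  samples, and it removes the generator's per-spectrum gain/offset exactly
  at zero noise. At zero noise the full chain is idempotent.

## Reproducibility and numerical choices

* Every stage derives a child seed from the master seed with fixed stage
  offsets (`child_seed()`), so the generator, the outer split, each CV run
  and each bootstrap are individually reproducible and insensitive to
  changes elsewhere in the configuration.
* Pairing is structural: both modalities of a sample share a `sample_id`
  and travel together through every split; the experiment asserts that
  train and test identifiers are disjoint.
* NIPALS deflation stops (without error in internal use; with an
  invalid-complexity error in `fit_plsr()`) when the residual covariance
  with the target falls below 1e−12 of its initial scale; the CV grid is
  capped at the count every split could extract, so per-LV averages always
  pool the same number of splits.
* The jackknife+ quantile rank `⌈(1 − α)(n + 1)⌉` is clamped to n for very
  small training sets; with the default study sizes the clamp is inactive.
* Bootstrap resampling retries with a derived seed (bounded at 10
  attempts) in the vanishingly rare event that some training point appears
  in every resample.

## Problem sizes

The shipped study sizes are those of the default configuration: 13 ratios
× 6 replicates = 78 pairs (156 spectra), an 80/20 outer split (62/16
pairs), 50 CV splits over LV counts 1–30, and B = 100 bootstrap models per
interval stage. The package's own validation uses 20 master seeds of this
configuration for the model-ordering checks, 200 replicates of an
n = 100/50 linear-Gaussian simulation for conformal coverage, and small
random matrices (8 × 20, 6 × 4) for the algebraic PLS checks.

## Known limitations

* The aliquot-error and artifact-jitter scales are stylised: they were set
  to reproduce the reported accuracy band, not measured from real
  replicate series.
* The weighted and mean high-level fusion intervals assume independent
  modality errors when pooling σ; residual shared bias (the two models are
  trained on the same split of the same preparations) makes the pooled
  intervals slightly anti-conservative, which shows up as PICP values a
  few points below nominal for the weighted model on some seeds.
* Inverse-variance weighting uses the per-sample σ proxy; with B = 100 the
  OOB aggregates are stable, but much smaller B makes the weights noisy.
* The F-test selection rule treats CV-test MSEs as if they came from
  independent samples of size df; CV reuse makes this approximate, which
  is acceptable for a parsimony heuristic but not for formal inference.

## A worked run

```{r example, eval = FALSE}
library(vibrafuse)

experiment <- run_experiment(experiment_config(seed = 1))
experiment            # five-model comparison table
tidy(experiment)      # the same table as a tibble
autoplot(experiment)  # predicted vs actual with intervals, per model
write_report(experiment, "ls-comparison")
```
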