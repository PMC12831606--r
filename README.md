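# optodesens

Simulation and analysis of channelrhodopsin response desensitization in
two-photon **all-optical interrogation** experiments.

All-optical experiments image a green calcium reporter (GCaMP6s, 920 nm)
while photostimulating a red-shifted opsin (C1V1, 1035 nm) in the same
neurons. The two excitation spectra overlap, so the imaging laser weakly
excites the opsin, and channelrhodopsins desensitize under light: molecules
accumulate in a low-efficiency desensitized photocycle and return to the
ground photocycle only slowly in darkness. The observable consequence is a
trial-by-trial decline of photostimulation responses that depends on the
inter-stimulus interval (ISI) and on the imaging dose — a confound for any
experiment that interprets response amplitudes causally.

`optodesens` provides, as a tidyverse-style R package:

* **A mean-field two-photocycle kinetic model.** Each cell carries a ground
  photocycle occupancy *g* ∈ [0, 1]. A stimulation train applies
  *g* ← *g*(1 − d_stim·ρ_s^γ); darkness relaxes
  *g* ← 1 − (1 − *g*)e^(−Δt/τ_r); imaging light adds a desensitizing rate
  k = k_im·ρ_i^γ, relaxing *g* toward g_eq = (1/τ_r)/(1/τ_r + k) with rate
  λ = 1/τ_r + k. All segments use exact closed forms. The per-trial
  *drive* (relative response amplitude) is *g* just before each train.
* **Protocol and dose tooling**: holographic stimulation trains (two
  alternating SLM phase-mask groups, 10 ms spirals every 15 ms, 300 ms per
  trial; single-mask 250 ms calibration variant), session schedules with
  constant or windowed imaging, and a per-cell imaging dwell calculator
  (frame period × duty factor × soma/FOV area fraction).
* **A synthetic-session generator**: labelled cell populations (targets,
  supralinearly-driven excited cells, inhibited cells, background),
  GCaMP6s-like transients sampled at 15 Hz with shot noise, drift, missing
  frames outside imaging windows, and multi-animal cohorts with
  deterministic seed derivation.
* **The quantification chain**: stimulus-triggered ΔF/F with a 1 s
  pre-stimulation baseline, responsiveness screening (mean post-stim
  ΔF/F ≥ 0.1), population response as the AUC of the mean ΔF/F over the 1 s
  post-stimulation, ΔResponse (trial 10 − trial 1), normalized decay curves
  with a fixed averaging order, two-term exponential and linear fits with
  broom-style `tidy()`/`glance()` methods, and ggplot2 plot functions.
* **Classification and cohort statistics**: beamlet-geometry target
  assignment with exclusion of ambiguous cells, dual Pearson-correlation
  network classification (all trials concatenated *and* trial 1 alone, both
  p < 0.05), exact Wilcoxon signed-rank and Kruskal–Wallis tests with the
  animal as the statistical unit, and `run_grid_analysis()` for the full
  (ISI × imaging-dose) comparison battery.

## Worked example

The canonical condition — 10 trials at a 15 s ISI with a 6 s imaging window
centered on each stimulation, default calibration (τ_r = 50 s,
d_stim = 0.15, k_im = 0.004 s⁻¹):

```r
library(optodesens)

sched <- build_session_schedule(stim_protocol(isi = 15),
                                imaging_config(dose_duration = 6))
drives <- simulate_trial_responses(sched, kinetic_params())
drives
#> # A tibble: 10 × 3
#>    trial onset_s drive
#>    <int>   <dbl> <dbl>
#>  1     1       3 1
#>  2     2      18 0.871
#>  3     3      33 0.792
#>  4     4      48 0.743
#>  5     5      63 0.713
#>  6     6      78 0.694
#>  7     7      93 0.683
#>  8     8     108 0.676
#>  9     9     123 0.672
#> 10    10     138 0.669
```

The response falls by about 26% over the first four trials and plateaus
near 68% of the first trial from trial five — the decline of an initially
fully sensitized opsin population toward the periodic steady state of
stimulation, imaging and dark recovery. A full synthetic cohort, analyzed
with the same pipeline used on real sessions:

```r
cohort <- generate_cohort(
  n_animals = 9,
  conditions = condition_grid(isi = 10, dose = "constant"),
  n_cells = 60, seed = 1)
responses <- cohort_responses(cohort, network = FALSE)

pairs <- responses |>
  dplyr::filter(class == "target", trial %in% c(1, 10)) |>
  dplyr::select(animal, trial, response) |>
  tidyr::pivot_wider(names_from = trial, values_from = response,
                     names_prefix = "t")
wilcoxon_signed_rank(pairs$t10, pairs$t1)
#> # A tibble: 1 × 6
#>   statistic     v p_value n_used method undefined
#>       <dbl> <dbl>   <dbl>  <int> <chr>  <lgl>
#> 1       -45     0 0.00391      9 exact  FALSE
```

Every animal's trial-10 target response is below its trial-1 response at a
10 s ISI under constant imaging, giving the exact two-sided signed-rank
floor p = 2/2⁹ ≈ 0.0039. `run_grid_analysis()` extends this to the full
condition grid: per-class decay curves, trial-1 vs trial-10 tests, ΔResponse
vs ISI trends, dose comparisons, and the opsin⁺/opsin⁻ excited-cell
comparison.

See `vignettes/all-optical-desensitization.Rmd` for the model, its
calibration, and every analysis convention in detail.

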