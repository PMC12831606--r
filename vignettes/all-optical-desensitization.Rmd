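---
title: "Modeling and quantifying opsin desensitization in all-optical experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying opsin desensitization in all-optical experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(optodesens)
library(dplyr)
```

## The problem

All-optical interrogation pairs two-photon calcium imaging of a green
reporter (GCaMP6s, imaged at 920 nm) with targeted two-photon optogenetic
stimulation of a red-shifted opsin (C1V1, stimulated at 1035 nm) in the same
cortical neurons. The two excitation spectra overlap: the imaging laser
weakly excites the opsin. Channelrhodopsins desensitize — molecules
accumulate in a low-efficiency desensitized photocycle under illumination
and only slowly return to the ground photocycle in darkness — so both the
repeated stimulation trains and the continuous imaging light can push a
cell's opsin population toward the desensitized state. The experimental
signature is a trial-by-trial decline of photostimulation responses that
depends on the inter-stimulus interval (ISI) and on the imaging dose.

`optodesens` packages three things:

1. a **mean-field two-photocycle kinetic model** of the ground-photocycle
   occupancy of a cell, driven by stimulation pulses and imaging exposure;
2. a **synthetic-session generator** that renders that model into labelled
   ROI fluorescence traces (targets, excited / inhibited network cells,
   non-responders, realistic noise, multi-animal cohorts);
3. the **quantification chain** used on real recordings: stimulus-triggered
   ΔF/F, responsiveness screening, population response AUC, ΔResponse,
   normalized decay curves, decay-curve fits, beamlet-based target
   assignment, correlation-based network classification, and nonparametric
   cohort statistics with the animal as the statistical unit.

Because the generator and the analysis share nothing but the session data
structure, every stage of the analysis is testable against known ground
truth without any experimental data.

## The kinetic model

Each cell carries a single state $g \in [0,1]$, the fraction of its opsin
population in the ground photocycle. Three processes act on it:

* **Stimulation trains** are instantaneous multiplicative hits:
  $g \leftarrow g\,(1 - d_\mathrm{stim}\, \rho_s^{\,\gamma_p})$,
  where $\rho_s$ is stimulation power relative to the 6 mW reference and
  $\gamma_p$ is the power-scaling exponent (default 2, the approximate
  quadratic dependence of two-photon excitation on average power). A train
  lasts 300 ms against ISIs of 10–40 s, so within-train dynamics are not
  modeled.
* **Darkness** relaxes $g$ back to 1 with time constant $\tau_r$:
  $g \leftarrow 1 - (1-g)\,e^{-\Delta t/\tau_r}$.
* **Imaging light** adds a desensitizing rate
  $k = k_\mathrm{im}\,\rho_i^{\,\gamma_p}$ ($\rho_i$ relative to the 50 mW
  reference), giving a first-order relaxation toward the equilibrium
  $g_\mathrm{eq} = \frac{1/\tau_r}{1/\tau_r + k}$ with rate
  $\lambda = 1/\tau_r + k$.

All segments use the exact closed forms, so trajectories carry no
integration error; the test suite cross-checks them against a forward-Euler
integrator at $dt = 10^{-4}$ s. The per-trial **drive** — the model's
prediction of relative response amplitude — is $g$ sampled immediately
before each train. The state is initialized to 1 at the *first* stimulation
onset: a naive preparation is taken as fully sensitized at the start of the
experiment proper, so imaging delivered before trial 1 does not
pre-desensitize it and the first trial's drive is exactly 1.

### Calibration of the defaults

The defaults are `tau_r = 50` s, `d_stim = 0.15`, `k_im = 0.004` s⁻¹. They
were chosen once so that the canonical condition — 15 s ISI with a 6 s
imaging window centered on each stimulation — reproduces the reported
phenomenology: a 20–30% drop within the first few trials and a plateau near
70% of the initial response from around trial five, while preserving the
dose × ISI interaction (constant imaging worsens desensitization, more so at
short ISIs, with the effect disappearing by a 40 s ISI). In vitro,
one-photon C1V1 measurements suggest full resensitization within ~30 s, but
in vivo desensitization persists even at a 30 s ISI, implying a slower
effective recovery; `tau_r` is therefore 50 s rather than a value implied by
the in vitro number. The in vitro "~30× slower" ratio between the
photocycle-return directions describes one-photon kinetics and has no
quantitative mapping onto 920 nm two-photon rates; it is not used as a
constraint.

```{r drive-curve}
sched <- build_session_schedule(stim_protocol(isi = 15),
                                imaging_config(dose_duration = 6))
drives <- simulate_trial_responses(sched, kinetic_params())
drives$norm <- drives$drive / drives$drive[1]
drives
100 * mean(drives$norm[5:10])   # plateau, % of trial 1
100 * (1 - drives$norm[4])      # drop by trial 4, %
```

`steady_state_drive()` finds the fixed point of the per-trial map by
iteration to $|\Delta g| < 10^{-10}$; it is monotone increasing in ISI and
decreasing in `k_im`, `d_stim`, imaging dose, and `tau_r` (a longer recovery
time constant means deeper steady-state depletion).
`fit_kinetic_params()` inverts the model: given noiseless drive curves from
three or more (ISI, dose) conditions it recovers $(\tau_r, d_\mathrm{stim},
k_\mathrm{im})$ by least squares (on log/logit scales for conditioning)
within 5% relative error — the model is identifiable from the kind of
condition grid the experiment actually uses.

## Protocols and imaging dose

`stim_protocol()` encodes the two-group holographic design: 16 targets split
across two SLM phase masks, the mask switching every 15 ms so that each
group receives 10 blocks of 10 ms spirals — 300 ms of stimulation per trial.
`calibration_protocol()` encodes the single-mask response-mapping variant
(25 contiguous 10 ms spirals, 250 ms). `build_session_schedule()` lays out
trial onsets, spiral events and imaging windows on a continuous session
clock with half-open `[start, end)` intervals; in windowed mode the imaging
dose window is **centered on the trial's stimulation onset** (the design
only states "centered around photostimulation"; onset-centering is the
simpler anchor and is what the generator and analysis both use).

Per-cell imaging dose uses an area-fraction model:
`imaging_dwell_per_cell()` returns
$\text{frame period} \times \text{duty} \times \frac{\pi r_\mathrm{soma}^2}{\text{FOV area}}$,
with defaults soma 15 μm and duty factor 0.5 (neither is stated in typical
protocols; both are configurable). For the 1.4 × 1.4 mm, 15 Hz
configuration this gives ≈ 3 μs per frame. The dwell is interpreted as *per
frame* (the natural unit for a resonant scanner; a per-window figure is the
per-frame value times frames per window). It is linear in duty factor and
soma area and independent of pixel resolution at fixed field of view and
frame rate.

## The synthetic generator

`make_population()` places cells uniformly with a minimum centre spacing of
two radii, marks a configurable fraction opsin-positive, draws the 16
targets from the opsin-positive pool, and assigns excited / inhibited /
background roles to the rest. `simulate_session()` then:

1. runs the kinetic model along the schedule to get per-trial target drives
   (per-cell drive = shared ground-fraction trajectory × that cell's
   expression level);
2. maps the mean target drive through the network transfer: excited cells
   get $w\,\max(0, \bar d - \theta)^{\gamma}$ with $\theta = 0.2$,
   $\gamma = 2$ — thresholded and supralinear, so excited responses fall
   *relatively* faster than target responses whenever target drive falls —
   and inhibited cells get $-0.5\,w\,\bar d$;
3. renders each cell's drive sequence into fluorescence: every trial adds
   $F_0\, A\, d_k \,(1 - e^{-t/\tau_\mathrm{rise}})\,e^{-t/\tau_\mathrm{decay}}$
   (GCaMP6s-like, $\tau_\mathrm{rise} = 0.18$ s,
   $\tau_\mathrm{decay} = 1.5$ s) on a baseline $F_0 = 100$, applies slow
   sinusoidal drift and per-frame multiplicative shot noise, clips at zero,
   and samples at 15 Hz. Frames outside imaging windows are recorded as
   explicitly missing (`NA`), never dropped, so windowed-dose analyses align
   by time rather than index. Inhibited cells get an elevated baseline
   (1.5 × $F_0$) so their negative deflections survive the zero clip.
   Stimulation-train frames are not blanked by default (no artifact model is
   assumed); the analysis window options allow excluding them.

`generate_cohort()` draws one population and one multiplicative response
factor per animal (between-animal sd 0.15, truncated at 0.2) and then
stimulates *the same cells* under every condition of the (ISI × dose) grid,
with all per-animal and per-session seeds derived deterministically from one
master seed. Noise defaults — 3% shot noise, 2% drift over a 60 s period,
15% between-animal sd — were fixed once as values typical of cortical
GCaMP6s ROI traces at this frame rate.

What the generator deliberately does **not** emulate: spiking statistics and
spike-to-calcium nonlinearity, neuropil contamination, motion, bleaching,
spatial optics (the movie writer is a toy), and any adaptation of the
underlying circuit. Passing tests therefore demonstrate that the analysis
chain is correct and internally consistent — not that it is robust to every
artifact of real recordings.

## The quantification chain

* `compute_dff()`: $\Delta F/F = (F - F_0)/F_0$ with $F_0$ the mean raw
  fluorescence over the 1 s before the stimulation onset. Relative frame
  times are quantized to nanoseconds so that equivalent offsets align
  exactly across trials.
* `is_responsive()`: a cell is responsive when its mean ΔF/F over the 1 s
  post-stimulation windows, pooled across trials, is **at least 0.1** — the
  boundary is inclusive, and 0.0999 is not responsive.
* `population_response()`: the response of a cell set on a trial is the
  trapezoidal AUC of the *mean* ΔF/F trace across the set over the 1 s
  post-stimulation (mean first, then integrate). The window edges are padded
  with the nearest inside-frame values, so a constant trace integrates to
  value × 1 s. A window keeping fewer than 50% of its nominal frames is
  flagged invalid; an empty cell set yields a flagged undefined response,
  never a silent zero.
* `delta_response()`: trial-10 minus trial-1 response; negative means
  desensitization.
* `normalized_decay_curve()`: averages per-trial responses across ISIs
  within animal, then across animals, then divides by the same-ordered
  trial-1 value — the order matters and is fixed; an incomplete
  animal × ISI × trial grid is a hard error that lists the missing cells.
* `fit_two_term_exponential()`: least squares of
  $y = a e^{bx} + c e^{dx}$ with the amplitudes profiled out (for fixed
  rates they solve a linear problem) and the rate pair multi-started over
  $\{-2, -0.5, -0.1, 0\}^2$. Degenerate rate pairs are flagged non-unique;
  if no start converges the result is flagged rather than thrown.
  `fit_linear()` is the first-degree polynomial for ΔResponse vs ISI.

## Cell classification

`assign_targets()` applies the beamlet-geometry rule: a cell overlaps a
beamlet when centroid distance < beamlet radius + cell radius; per beamlet
the nearest overlapping centroid becomes the target (ties to the lowest cell
index) and all other overlapping cells are excluded from every downstream
statistic. Beamlets are processed in index order and cannot re-claim an
existing target.

`classify_network()` applies the dual-correlation rule to every remaining
cell: Pearson correlation against each target's ΔF/F over the 2 s around
stimulation — interpreted as the symmetric window $[-1, +1)$ s about the
stimulation onset — both concatenated across all trials *and* on trial 1
alone. The cell is excited or inhibited if for at least one target both
tests give two-sided $p < 0.05$ *and* the two coefficients share a sign
(the sign-consistency requirement is an interpretation: it prevents a cell
that is positively correlated overall but negatively on trial 1 from
counting as excited). The reported coefficient — and the excited/inhibited
sign — comes from the all-trials correlation of the qualifying target with
the largest absolute coefficient. The trial-1 requirement ensures
classified cells are active on trial 1, so trial-1 vs trial-10 comparisons
are meaningful. Correlations are computed on ΔF/F (consistent with the
pipeline ordering), p-values via the t-transform with n = frames in the
tested window, and no multiple-testing correction is applied by default
(matching the original analysis; `alpha` is configurable and a correction
can be layered on the returned p-values). Zero-variance windows skip that
cell-target pair with a warning.

## Cohort statistics

The animal is the statistical unit throughout: cell-class responses are
averaged within animal before any test. `wilcoxon_signed_rank()` drops zero
differences (Wilcoxon's original convention; differences below $10^{-12}$
count as zeros so that floating-point noise in a no-effect pipeline does not
masquerade as signal), uses the exact signed-rank distribution for up to 25
untied pairs, and the tie- and continuity-corrected normal approximation
otherwise. `kruskal_wallis()` is the rank-based H test with tie correction.
`run_grid_analysis()` assembles the full battery: per-class decay curves,
trial-1 vs trial-10 tests per dose / per ISI / per condition, ΔResponse
linear trends against ISI per class and dose, the paired dose comparison,
the first-trial Kruskal–Wallis across doses (a no-baseline-difference
control), and the opsin⁺ vs opsin⁻ excited-cell ΔResponse comparison. No
correction is applied across the battery; per-comparison p-values are
reported.

```{r cohort, message = FALSE}
cohort <- generate_cohort(
  n_animals = 9,
  conditions = condition_grid(isi = 10, dose = "constant"),
  n_cells = 60, seed = 1)
responses <- cohort_responses(cohort, network = FALSE)
pairs <- responses |>
  filter(class == "target", trial %in% c(1, 10)) |>
  select(animal, trial, response) |>
  tidyr::pivot_wider(names_from = trial, values_from = response,
                     names_prefix = "t")
wilcoxon_signed_rank(pairs$t10, pairs$t1)
```

## Numerical and design choices

* Intervals are half-open `[start, end)` on a continuous session clock;
  group A's block precedes group B's within every mask period; the trial
  onset is the first spiral onset.
* Clipping (not an error) enforces $g \in [0,1]$.
* The steady-state solver tolerance is $10^{-10}$; the exponential-fit
  multi-start grid and the 50% valid-frame threshold are arguments with the
  defaults above.
* The post-stimulation response window includes the 300 ms stimulation
  train (no blanking rule is assumed); exclusion is available through the
  window arguments.
* Baselines at short ISIs include the tail of the previous trial's calcium
  transient; no exclusion is applied (none is applied in the original
  analysis either), which slightly compresses measured responses relative
  to drives at 10 s ISIs — the end-to-end consistency checks bound this
  effect below 2% under the default conditions.
* Problem sizes in the examples and tests (tens of cells, 9 animals, one or
  a few conditions) were chosen as the smallest cohorts at which every
  qualitative effect of the full design is already resolvable; all
  generators scale to larger sessions by argument.

## Known limitations

The kinetic formulation is a mean-field, single-state summary of a
multi-state photocycle: it reproduces trial-scale desensitization and
recovery but not sub-train dynamics, spectral detail (wavelength enters
only through the value of `k_im`), or channel-level stochasticity. The
network transfer is a static nonlinearity, not a circuit model. Classifier
performance quoted by the tests (e.g. ≥ 95% excited-cell recall) is
performance on the generator's noise model, and real two-photon data with
neuropil contamination, motion, or overlapping ROIs will be harder.
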