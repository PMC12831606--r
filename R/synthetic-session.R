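#' Calcium indicator kernel parameters
#'
#' GCaMP6s-like double-exponential impulse response,
#' `(1 - exp(-t / tau_rise)) * exp(-t / tau_decay)`.
#'
#' @param tau_rise Rise time constant, seconds.
#' @param tau_decay Decay time constant, seconds.
#' @param amplitude Peak-normalizing scale applied to a unit drive, as a
#'   fraction of baseline fluorescence.
#' @return A list of class `calcium_params`.
#' @export
calcium_params <- function(tau_rise = 0.18, tau_decay = 1.5, amplitude = 1) {
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 amplitude = amplitude), class = "calcium_params")
}

calcium_kernel <- function(t, calcium) {
  ifelse(t < 0, 0, (1 - exp(-t / calcium$tau_rise)) * exp(-t / calcium$tau_decay))
}

#' Render a per-trial drive sequence into a fluorescence trace
#'
#' Each trial adds `F0 * amplitude * drive * kernel(t - onset)` to the
#' baseline `F0`; slow sinusoidal drift and per-frame multiplicative shot
#' noise are applied; frames outside imaging windows are recorded as `NA`
#' (explicitly missing, so windowed-dose analyses align by time).
#' Fluorescence is clipped at zero.
#'
#' @param drives Numeric drive per trial (may be negative, for inhibited
#'   cells).
#' @param onsets Trial stimulation onsets, seconds.
#' @param times Frame times, seconds.
#' @param imaged Logical per frame: was the frame acquired?
#' @param f0 Baseline fluorescence, arbitrary units.
#' @param calcium A [calcium_params()].
#' @param noise A [noise_model()]; `NULL` disables noise and drift.
#' @param drift_phase Phase of the drift sinusoid, radians.
#' @return Numeric fluorescence per frame (`NA` where not imaged).
#' @export
drive_to_fluorescence <- function(drives, onsets, times, imaged = NULL,
                                  f0 = 100, calcium = calcium_params(),
                                  noise = NULL, drift_phase = 0) {
  stopifnot(length(drives) == length(onsets))
  f <- rep(f0, length(times))
  for (k in seq_along(onsets)) {
    if (drives[k] != 0) {
      f <- f + f0 * calcium$amplitude * drives[k] *
        calcium_kernel(times - onsets[k], calcium)
    }
  }
  if (!is.null(noise)) {
    if (noise$drift_amp > 0) {
      f <- f * (1 + noise$drift_amp *
                  sin(2 * pi * times / noise$drift_period + drift_phase))
    }
    if (noise$shot_sd > 0) {
      f <- f * (1 + rnorm(length(f), sd = noise$shot_sd))
    }
  }
  f <- pmax(f, 0)
  if (!is.null(imaged)) f[!imaged] <- NA_real_
  f
}

#' Simulate one labelled all-optical session
#'
#' Builds the session schedule, runs the two-photocycle model to get
#' per-trial target drives, maps them through the network transfer
#' ([network_drive()]) for every cell, and renders GCaMP6s-like fluorescence
#' traces at the imaging frame rate with the configured noise. Inhibited
#' cells get an elevated baseline (`1.5 * f0`) so their negative deflections
#' remain observable after the zero clip.
#'
#' @param population A [make_population()] result.
#' @param protocol A [stim_protocol()].
#' @param imaging An [imaging_config()].
#' @param params A [kinetic_params()].
#' @param noise A [noise_model()] or `NULL` for a noiseless session.
#' @param calcium A [calcium_params()].
#' @param gain A [gain_params()].
#' @param seed Integer seed for the session's noise draws.
#' @param animal Animal identifier.
#' @param response_factor Animal-level multiplicative response amplitude.
#' @param f0 Baseline fluorescence.
#' @return An object of class `opto_session`: list with `traces` (cells x
#'   frames matrix, `NA` outside imaging windows), `frame_times`, `schedule`,
#'   `beamlets`, `population` (ground-truth labels), `drives` (per cell x
#'   trial firing drives), `animal`, `seed`, and the configs.
#' @export
simulate_session <- function(population, protocol = stim_protocol(),
                             imaging = imaging_config(),
                             params = kinetic_params(),
                             noise = noise_model(),
                             calcium = calcium_params(),
                             gain = gain_params(), seed = 1, animal = 1L,
                             response_factor = 1, f0 = 100) {
  schedule <- build_session_schedule(protocol, imaging)
  times <- frame_times(schedule)
  imaged <- frames_imaged(schedule, times)
  onsets <- schedule$trials$onset_s
  kin <- simulate_trial_responses(schedule, params)
  is_target <- population$role == "target"
  # per-target drive: shared ground-fraction trajectory scaled by expression
  target_drive_mat <- outer(population$expression[is_target], kin$drive)
  mean_target_drive <- colMeans(target_drive_mat)
  local_rng(seed)
  n_cells <- nrow(population)
  drives <- matrix(0, n_cells, length(onsets))
  ti <- 0
  for (i in seq_len(n_cells)) {
    role <- population$role[i]
    drives[i, ] <- if (role == "target") {
      ti <- ti + 1
      target_drive_mat[ti, ]
    } else {
      network_drive(mean_target_drive, role, population$weight[i], gain)
    }
  }
  drives <- drives * response_factor
  traces <- matrix(NA_real_, n_cells, length(times))
  for (i in seq_len(n_cells)) {
    base <- if (population$role[i] == "inhibited") 1.5 * f0 else f0
    traces[i, ] <- drive_to_fluorescence(
      drives[i, ], onsets, times, imaged, f0 = base, calcium = calcium,
      noise = noise, drift_phase = runif(1, 0, 2 * pi)
    )
  }
  structure(
    list(traces = traces, frame_times = times, imaged = imaged,
         schedule = schedule, beamlets = target_beamlets(population, protocol),
         population = population, drives = drives, animal = animal,
         seed = seed, response_factor = response_factor, f0 = f0,
         protocol = protocol, imaging = imaging, params = params,
         noise = noise, calcium = calcium, gain = gain,
         format_version = "1.0"),
    class = "opto_session"
  )
}

#' @export
print.opto_session <- function(x, ...) {
  cat(sprintf(
    "<opto_session> animal %s: %d cells x %d frames, %d trials, ISI %g s, %s imaging\n",
    x$animal, nrow(x$traces), ncol(x$traces), x$protocol$n_trials,
    x$protocol$isi, x$imaging$dose_mode))
  invisible(x)
}

#' Condition grid used by the desensitization cohort
#'
#' @param isi Vector of inter-stimulus intervals, seconds.
#' @param dose Vector of dose descriptors: `"constant"` or a number of
#'   seconds for a windowed dose.
#' @return A tibble with `condition`, `isi`, `dose_mode`, `dose_duration`.
#' @export
condition_grid <- function(isi = c(10, 20, 30, 40), dose = c("constant", "2")) {
  g <- tidyr::expand_grid(isi = isi, dose = dose)
  mutate(g,
    dose_mode = ifelse(.data$dose == "constant", "constant", "windowed"),
    dose_duration = suppressWarnings(as.numeric(.data$dose)),
    condition = paste0("isi", .data$isi, "_",
                       ifelse(.data$dose_mode == "constant", "constant",
                              paste0("dose", .data$dose))),
    dose = NULL
  )
}

# Deterministic per-animal / per-session seed scheme: offsets from the
# master seed on a counter grid, kept within 32-bit integer range.
derive_seed <- function(master, animal, condition_index = 0) {
  as.integer((master + 104729 * animal + 7919 * condition_index) %%
               .Machine$integer.max)
}

#' Generate a multi-animal, multi-condition synthetic cohort
#'
#' Each animal gets an independent cell population and a multiplicative
#' response factor drawn from the between-animal noise model; the same
#' population (the same cells) is then stimulated under every condition of
#' the grid. All per-animal and per-session seeds derive deterministically
#' from the master seed.
#'
#' @param n_animals Number of animals.
#' @param conditions A [condition_grid()]-style tibble.
#' @param n_cells Cells per animal.
#' @param protocol Base [stim_protocol()]; its `isi` is overridden per
#'   condition.
#' @param imaging Base [imaging_config()]; `dose_mode`/`dose_duration` are
#'   overridden per condition.
#' @param params A [kinetic_params()].
#' @param noise A [noise_model()] or `NULL` (noiseless cohort: no trace
#'   noise and unit response factors).
#' @param seed Master seed.
#' @param ... Passed to [simulate_session()] (`calcium`, `gain`, `f0`).
#' @return A tibble with one row per session: `animal`, `condition`, `isi`,
#'   `dose_mode`, `dose_duration`, `session` (list column of
#'   `opto_session`).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_animals = 2,
#'                           conditions = condition_grid(isi = 10, dose = "constant"),
#'                           n_cells = 40, seed = 1)
#' }
#' @export
generate_cohort <- function(n_animals = 9,
                            conditions = condition_grid(),
                            n_cells = 120,
                            protocol = stim_protocol(),
                            imaging = imaging_config(),
                            params = kinetic_params(),
                            noise = noise_model(),
                            seed = 1, ...) {
  stopifnot(n_animals >= 1)
  rows <- list()
  for (a in seq_len(n_animals)) {
    pop_seed <- derive_seed(seed, a, 0)
    pop <- make_population(n_cells = n_cells, protocol = protocol,
                           seed = pop_seed)
    factor_a <- 1
    if (!is.null(noise) && noise$animal_sd > 0) {
      local_rng(derive_seed(seed, a, 9999))
      factor_a <- max(0.2, 1 + rnorm(1, sd = noise$animal_sd))
    }
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      prot <- structure(modifyList(unclass(protocol), list(isi = cond$isi)),
                        class = "stim_protocol")
      img <- unclass(imaging)
      img$dose_mode <- cond$dose_mode
      if (!is.na(cond$dose_duration)) img$dose_duration <- cond$dose_duration
      img <- structure(img, class = "imaging_config")
      sess <- simulate_session(
        pop, prot, img, params, noise = noise,
        seed = derive_seed(seed, a, ci), animal = a,
        response_factor = factor_a, ...
      )
      rows[[length(rows) + 1]] <- mutate(
        select(cond, "condition", "isi", "dose_mode", "dose_duration"),
        animal = a, session = list(sess)
      )
    }
  }
  relocate(list_rbind(rows), "animal")
}
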