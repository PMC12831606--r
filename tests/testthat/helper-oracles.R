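# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form code paths: the Euler integrator steps the ODE
# directly, and the signed-rank enumerator walks all 2^n sign assignments.

# Forward-Euler integration of the ground-fraction ODE along a schedule:
# dg/dt = (1 - g)/tau_r - k(t) g, with k(t) = k_im * ratio^ps inside imaging
# windows and 0 outside, plus an instantaneous multiplicative pulse at each
# trial onset. Walks from the first stim onset with g = 1 and records g just
# before each pulse.
euler_drive <- function(schedule, params, dt = 1e-4) {
  onsets <- schedule$trials$onset_s
  iv <- schedule$imaging
  stim_ratio <- schedule$protocol$stim_power / params$ref_stim_power
  im_ratio <- schedule$imaging_config$power / params$ref_imaging_power
  k_on <- params$k_im * im_ratio^params$power_scaling
  pulse_factor <- 1 - params$d_stim * stim_ratio^params$power_scaling
  g <- 1
  drives <- numeric(length(onsets))
  for (tr in seq_along(onsets)) {
    drives[tr] <- g
    g <- g * pulse_factor
    if (tr < length(onsets)) {
      t <- onsets[tr]
      t_end <- onsets[tr + 1]
      n_steps <- round((t_end - t) / dt)
      ts <- t + (seq_len(n_steps) - 1) * dt
      lit <- rep(FALSE, n_steps)
      for (j in seq_len(nrow(iv))) {
        lit <- lit | (ts >= iv$start_s[j] & ts < iv$end_s[j])
      }
      for (s in seq_len(n_steps)) {
        k <- if (lit[s]) k_on else 0
        g <- g + dt * ((1 - g) / params$tau_r - k * g)
      }
    }
  }
  drives
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign assignments
# (zeros dropped, no ties assumed). Usable for n <= 12.
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- combos %*% r
  min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
}

# Small default fixtures shared across tests.
default_schedule <- function(isi = 15, dose_mode = "windowed",
                             dose_duration = 6, n_trials = 10) {
  build_session_schedule(
    stim_protocol(isi = isi, n_trials = n_trials),
    imaging_config(dose_mode = dose_mode, dose_duration = dose_duration)
  )
}

# Ten-trial default drive curve, hand-iterated from the closed-form
# per-segment recursion (pulse x0.85; 3 s imaging; 9 s dark; 3 s imaging)
# with tau_r = 50, d_stim = 0.15, k_im = 0.004.
HAND_DRIVES <- c(1, 0.87094, 0.79159, 0.74281, 0.71283,
                 0.69439, 0.68306, 0.67609, 0.67181, 0.66918)

small_session <- function(n_cells = 40, seed = 3, noise = noise_model(),
                          isi = 15, dose_mode = "windowed",
                          dose_duration = 6, session_seed = 5) {
  prot <- stim_protocol(isi = isi)
  pop <- make_population(n_cells = n_cells, protocol = prot, seed = seed)
  simulate_session(pop, prot,
                   imaging_config(dose_mode = dose_mode,
                                  dose_duration = dose_duration),
                   kinetic_params(), noise = noise, seed = session_seed)
}
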