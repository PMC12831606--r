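#' Noise model for synthetic sessions
#'
#' @param shot_sd Per-frame multiplicative noise sd (fraction of F).
#' @param drift_amp Amplitude of the slow multiplicative baseline drift
#'   (fraction of F0; one sinusoidal cycle per `drift_period` seconds).
#' @param drift_period Drift period, seconds.
#' @param animal_sd Between-animal multiplicative response-amplitude sd.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(shot_sd = 0.03, drift_amp = 0.02, drift_period = 60,
                        animal_sd = 0.15) {
  if (any(c(shot_sd, drift_amp, drift_period, animal_sd) < 0)) {
    abort("All noise-model parameters must be >= 0.",
          class = "optodesens_config_error")
  }
  structure(list(shot_sd = shot_sd, drift_amp = drift_amp,
                 drift_period = drift_period, animal_sd = animal_sd),
            class = "noise_model")
}

#' Transfer parameters from target drive to network firing drive
#'
#' Excited cells receive a thresholded supralinear transform of the mean
#' target drive, `weight * max(0, drive - theta)^gamma` with `gamma > 1`,
#' so their responses fall proportionally faster than targets' when target
#' drive declines. Inhibited cells deflect negatively in proportion to the
#' mean target drive.
#'
#' @param theta Activation threshold on mean target drive.
#' @param gamma Supralinearity exponent (> 1).
#' @param inhib_scale Scale of the inhibited cells' negative deflection.
#' @return A list of class `gain_params`.
#' @export
gain_params <- function(theta = 0.2, gamma = 2, inhib_scale = 0.5) {
  structure(list(theta = theta, gamma = gamma, inhib_scale = inhib_scale),
            class = "gain_params")
}

#' Generate a labelled cell population for one field of view
#'
#' Cells are placed uniformly at random with a minimum centre spacing of
#' twice the cell radius (rejection sampling with a bounded retry budget).
#' Opsin expression is assigned at random; stimulation targets are drawn
#' from opsin-positive cells and split across the protocol's phase-mask
#' groups; remaining cells become excited / inhibited / background in the
#' configured proportions, independently of opsin status.
#'
#' @param n_cells Total number of cells.
#' @param fov Field of view, micrometers (`c(x, y)`); origin top-left, y
#'   increasing downward.
#' @param protocol A [stim_protocol()] (sets the number of targets).
#' @param seed Integer RNG seed; the population is deterministic given it.
#' @param cell_radius Cell radius, micrometers.
#' @param opsin_frac Fraction of cells expressing opsin.
#' @param excited_frac,inhibited_frac Fractions of non-target cells assigned
#'   the excited / inhibited roles.
#' @param max_tries Placement attempts per cell before giving up.
#' @return A tibble of class `cell_population`: `cell`, `x`, `y`, `radius`,
#'   `opsin` (logical), `expression` (0 for opsin-negative), `role`
#'   (`target`/`excited`/`inhibited`/`background`), `group` (target group,
#'   NA otherwise), `weight`.
#' @export
make_population <- function(n_cells = 120, fov = c(1400, 1400),
                            protocol = stim_protocol(), seed = 1,
                            cell_radius = 7.5, opsin_frac = 0.4,
                            excited_frac = 0.15, inhibited_frac = 0.1,
                            max_tries = 200) {
  n_targets <- protocol$n_groups * protocol$targets_per_group
  if (n_cells < n_targets) {
    abort("n_cells must be at least the number of targets.",
          class = "optodesens_argument_error")
  }
  rng <- local_rng(seed)
  xs <- numeric(n_cells); ys <- numeric(n_cells)
  placed <- 0
  tries <- 0
  while (placed < n_cells) {
    x <- runif(1, cell_radius, fov[1] - cell_radius)
    y <- runif(1, cell_radius, fov[2] - cell_radius)
    ok <- placed == 0 ||
      all((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2 >=
            (2 * cell_radius)^2)
    if (ok) {
      placed <- placed + 1
      xs[placed] <- x; ys[placed] <- y
      tries <- 0
    } else {
      tries <- tries + 1
      if (tries > max_tries) {
        abort("Could not place cells with the required spacing; FOV too crowded.",
              class = "optodesens_packing_error")
      }
    }
  }
  n_opsin <- max(n_targets, round(opsin_frac * n_cells))
  opsin <- rep(FALSE, n_cells)
  opsin[sample.int(n_cells, n_opsin)] <- TRUE
  targets <- sample(which(opsin), n_targets)
  role <- rep("background", n_cells)
  role[targets] <- "target"
  group <- rep(NA_integer_, n_cells)
  group[targets] <- as.integer((seq_len(n_targets) - 1L) %% protocol$n_groups)
  non_targets <- setdiff(seq_len(n_cells), targets)
  n_exc <- round(excited_frac * length(non_targets))
  n_inh <- round(inhibited_frac * length(non_targets))
  picks <- sample(non_targets, n_exc + n_inh)
  role[picks[seq_len(n_exc)]] <- "excited"
  if (n_inh > 0) role[picks[n_exc + seq_len(n_inh)]] <- "inhibited"
  expression <- ifelse(opsin, runif(n_cells, 0.7, 1), 0)
  weight <- runif(n_cells, 0.8, 1.2)
  pop <- tibble(
    cell = seq_len(n_cells), x = xs, y = ys, radius = cell_radius,
    opsin = opsin, expression = expression, role = role, group = group,
    weight = weight
  )
  class(pop) <- c("cell_population", class(pop))
  pop
}

local_rng <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(seed)
}

#' Beamlet coordinates for a population's targets
#'
#' One beamlet per target cell, centered on its centroid, with radius half
#' the protocol's spiral diameter.
#'
#' @param population A [make_population()] result.
#' @param protocol The matching [stim_protocol()].
#' @param jitter_sd Optional Gaussian jitter (micrometers) applied to
#'   beamlet centres, emulating imperfect targeting; 0 disables.
#' @param seed Seed used when `jitter_sd > 0`.
#' @return A tibble: `beamlet`, `group`, `x`, `y`, `radius`,
#'   `true_target` (ground-truth cell id).
#' @export
target_beamlets <- function(population, protocol, jitter_sd = 0, seed = 1) {
  tg <- filter(population, .data$role == "target")
  jx <- jy <- rep(0, nrow(tg))
  if (jitter_sd > 0) {
    local_rng(seed)
    jx <- rnorm(nrow(tg), sd = jitter_sd)
    jy <- rnorm(nrow(tg), sd = jitter_sd)
  }
  tibble(
    beamlet = seq_len(nrow(tg)), group = tg$group,
    x = tg$x + jx, y = tg$y + jy,
    radius = protocol$spiral_diameter / 2,
    true_target = tg$cell
  )
}

#' Map a per-trial target drive to a cell's firing drive
#'
#' @param target_drive Numeric vector of mean target ground fractions per
#'   trial (each in `[0, 1]`). For `role = "target"` supply the cell's own
#'   ground fraction.
#' @param role One of `"target"`, `"excited"`, `"inhibited"`, `"background"`.
#' @param weight Cell-specific transfer weight.
#' @param gain A [gain_params()].
#' @return Numeric drive per trial (negative for inhibited cells).
#' @export
network_drive <- function(target_drive, role, weight = 1, gain = gain_params()) {
  if (any(target_drive < 0 | target_drive > 1)) {
    abort("target_drive must lie in [0, 1].", class = "optodesens_argument_error")
  }
  switch(role,
    target = target_drive,
    excited = weight * pmax(0, target_drive - gain$theta)^gain$gamma,
    inhibited = -gain$inhib_scale * weight * target_drive,
    background = rep(0, length(target_drive)),
    abort(sprintf("Unknown role '%s'.", role),
          class = "optodesens_argument_error")
  )
}
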