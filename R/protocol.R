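#' Define a holographic photostimulation protocol
#'
#' A protocol describes how a session of spiral photostimulation trials is
#' laid out: how many trials, how far apart (the inter-stimulus interval,
#' ISI), how targets are split across SLM phase-mask groups, and the timing
#' of the spiral train delivered on every trial. The default reproduces the
#' two-group experimental design: 16 targets split over two phase masks, the
#' mask switching every 15 ms so each group receives 10 blocks of 10 ms
#' spirals, 300 ms of stimulation in total per trial.
#'
#' @param n_trials Number of stimulation trials.
#' @param isi Inter-stimulus interval in seconds (trial onset to onset).
#' @param n_groups Number of SLM phase-mask groups stimulated in alternation.
#' @param targets_per_group Number of beamlet targets per group.
#' @param spiral_duration Duration of one spiral over a cell body, seconds.
#' @param mask_interval Phase-mask switch period, seconds. Must be at least
#'   `spiral_duration`.
#' @param blocks_per_group Number of spiral blocks each group receives per
#'   trial.
#' @param stim_power Photostimulation power per cell in milliwatts.
#' @param spiral_diameter Spiral diameter in micrometers.
#'
#' @return An object of class `stim_protocol` (a validated list).
#' @seealso [calibration_protocol()], [build_stim_train()],
#'   [build_session_schedule()]
#' @examples
#' p <- stim_protocol()
#' train_duration(p) # 0.3 s
#' @export
stim_protocol <- function(n_trials = 10, isi = 15, n_groups = 2,
                          targets_per_group = 8, spiral_duration = 0.010,
                          mask_interval = 0.015, blocks_per_group = 10,
                          stim_power = 6, spiral_diameter = 10) {
  p <- structure(
    list(
      n_trials = as.integer(n_trials), isi = isi, n_groups = as.integer(n_groups),
      targets_per_group = as.integer(targets_per_group),
      spiral_duration = spiral_duration, mask_interval = mask_interval,
      blocks_per_group = as.integer(blocks_per_group),
      stim_power = stim_power, spiral_diameter = spiral_diameter
    ),
    class = "stim_protocol"
  )
  validate_stim_protocol(p)
}

validate_stim_protocol <- function(p) {
  durs <- c(isi = p$isi, spiral_duration = p$spiral_duration,
            mask_interval = p$mask_interval)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    abort("All protocol durations (isi, spiral_duration, mask_interval) must be positive.",
          class = "optodesens_config_error")
  }
  if (p$mask_interval < p$spiral_duration) {
    abort("mask_interval must be >= spiral_duration (spirals cannot outlast their mask period).",
          class = "optodesens_config_error")
  }
  if (p$n_groups < 1 || p$blocks_per_group < 1 || p$n_trials < 1 ||
      p$targets_per_group < 1) {
    abort("n_groups, blocks_per_group, n_trials and targets_per_group must all be >= 1.",
          class = "optodesens_config_error")
  }
  p
}

#' The single-group response-mapping calibration protocol
#'
#' One phase mask, 25 contiguous 10 ms spirals per trial (250 ms of
#' stimulation), used to identify photoresponsive cells before the
#' desensitization experiment proper.
#'
#' @param n_trials Number of calibration trials.
#' @param isi Inter-stimulus interval, seconds.
#' @param targets_per_group Targets on the single mask.
#' @return A `stim_protocol`.
#' @export
calibration_protocol <- function(n_trials = 10, isi = 15, targets_per_group = 10) {
  stim_protocol(
    n_trials = n_trials, isi = isi, n_groups = 1,
    targets_per_group = targets_per_group,
    spiral_duration = 0.010, mask_interval = 0.010, blocks_per_group = 25
  )
}

#' Total stimulation-train duration of a protocol
#'
#' The span of the per-trial block schedule,
#' `n_groups * blocks_per_group * mask_interval`.
#'
#' @param protocol A [stim_protocol()].
#' @return Duration in seconds.
#' @export
train_duration <- function(protocol) {
  validate_stim_protocol(protocol)
  protocol$n_groups * protocol$blocks_per_group * protocol$mask_interval
}

#' Define an imaging configuration
#'
#' Describes the resonant-scanning calcium-imaging acquisition and, through
#' `dose_mode`, the imaging-dose paradigm: `"constant"` scanning for the whole
#' session, or `"windowed"` acquisition restricted to a `dose_duration`
#' window centered on each trial's stimulation onset. Defaults match a
#' large-FOV GCaMP6s acquisition: 1.4 x 1.4 mm, 1024 x 1024 pixels, 15 Hz,
#' 50 mW on sample.
#'
#' @param fov Field of view, micrometers; length-2 numeric `c(x, y)`.
#' @param resolution Pixels, length-2 integer `c(x, y)`.
#' @param frame_rate Frames per second (Hz).
#' @param power Average imaging power on sample, milliwatts.
#' @param dose_mode `"constant"` or `"windowed"`.
#' @param dose_duration Length of the per-trial imaging window in seconds
#'   (windowed mode; ignored for constant). Centered on each stim onset.
#' @param duty_factor Effective fraction of the frame period during which a
#'   point in the FOV can receive illumination, in (0, 1]. Enters the
#'   per-cell dwell-time model linearly.
#'
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(fov = c(1400, 1400), resolution = c(1024, 1024),
                           frame_rate = 15, power = 50,
                           dose_mode = c("windowed", "constant"),
                           dose_duration = 6, duty_factor = 0.5) {
  dose_mode <- match.arg(dose_mode)
  cfg <- structure(
    list(fov = as.numeric(fov), resolution = as.integer(resolution),
         frame_rate = frame_rate, power = power, dose_mode = dose_mode,
         dose_duration = dose_duration, duty_factor = duty_factor),
    class = "imaging_config"
  )
  validate_imaging_config(cfg)
}

validate_imaging_config <- function(cfg) {
  if (length(cfg$fov) != 2 || any(cfg$fov <= 0) ||
      length(cfg$resolution) != 2 || any(cfg$resolution <= 0)) {
    abort("fov and resolution must be length-2 positive (pixel size must be positive).",
          class = "optodesens_config_error")
  }
  if (!is.finite(cfg$frame_rate) || cfg$frame_rate <= 0) {
    abort("frame_rate must be a positive number of Hz.",
          class = "optodesens_config_error")
  }
  if (cfg$duty_factor <= 0 || cfg$duty_factor > 1) {
    abort("duty_factor must lie in (0, 1].", class = "optodesens_config_error")
  }
  if (cfg$dose_mode == "windowed" &&
      (!is.finite(cfg$dose_duration) || cfg$dose_duration <= 0)) {
    abort("windowed dose_mode requires a positive dose_duration.",
          class = "optodesens_config_error")
  }
  cfg
}

#' Build the spiral-stimulation event train for one trial
#'
#' Groups are interleaved (A, B, A, B, ...) at `mask_interval` spacing: block
#' `j` of group `g` starts at `t0 + (j * n_groups + g) * mask_interval`, each
#' event lasting `spiral_duration`. The trial onset is the first spiral onset.
#'
#' @param protocol A [stim_protocol()].
#' @param t0 Onset of the trial's first spiral, seconds from session start.
#' @param trial 0-based trial index recorded on the events.
#' @return A tibble with columns `time_s`, `kind` (`"stim"`), `group`
#'   (0-based), `trial` (0-based), `duration_s`, sorted by time with no
#'   overlapping events.
#' @examples
#' ev <- build_stim_train(stim_protocol(), t0 = 0)
#' nrow(ev)                              # 20 events
#' max(ev$time_s + ev$duration_s)        # within 0.3 s
#' @export
build_stim_train <- function(protocol, t0 = 0, trial = 0L) {
  validate_stim_protocol(protocol)
  slots <- 0:(protocol$n_groups * protocol$blocks_per_group - 1)
  tibble(
    time_s = t0 + slots * protocol$mask_interval,
    kind = "stim",
    group = as.integer(slots %% protocol$n_groups),
    trial = as.integer(trial),
    duration_s = protocol$spiral_duration
  )
}

#' Build the full session timeline
#'
#' Lays out `n_trials` trial onsets spaced by the ISI, the stimulation events
#' of every trial, and the imaging on-intervals. In windowed mode each trial
#' gets one interval of `dose_duration` centered on its stimulation onset; in
#' constant mode a single interval covers the whole session. All intervals
#' are half-open `[start, end)` in continuous seconds from session start.
#'
#' The first trial onset defaults to `dose_duration / 2` (windowed) or 2 s
#' (constant) so the session never needs negative times and the 1 s
#' pre-stimulus baseline is always imaged.
#'
#' @param protocol A [stim_protocol()].
#' @param imaging An [imaging_config()].
#' @param t0 First trial onset, seconds; `NULL` picks the default above.
#' @return An object of class `session_schedule`: a list with `trials`
#'   (tibble: `trial`, `onset_s`), `stims` (tibble of all spiral events),
#'   `imaging` (tibble: `start_s`, `end_s`), `session_end`, and the two
#'   configs.
#' @export
build_session_schedule <- function(protocol, imaging, t0 = NULL) {
  validate_stim_protocol(protocol)
  validate_imaging_config(imaging)
  windowed <- imaging$dose_mode == "windowed"
  if (windowed && imaging$dose_duration > protocol$isi) {
    abort(sprintf(
      "Imaging dose window (%g s) exceeds the ISI (%g s): adjacent trials' windows would overlap.",
      imaging$dose_duration, protocol$isi), class = "optodesens_config_error")
  }
  if (is.null(t0)) t0 <- if (windowed) imaging$dose_duration / 2 else 2
  onsets <- t0 + (seq_len(protocol$n_trials) - 1) * protocol$isi
  trials <- tibble(trial = seq_along(onsets) - 1L, onset_s = onsets)
  stims <- list_rbind(map2(onsets, trials$trial,
                           ~build_stim_train(protocol, t0 = .x, trial = .y)))
  session_end <- onsets[length(onsets)] + protocol$isi
  imaging_iv <- if (windowed) {
    tibble(start_s = onsets - imaging$dose_duration / 2,
           end_s = onsets + imaging$dose_duration / 2)
  } else {
    tibble(start_s = 0, end_s = session_end)
  }
  if (any(imaging_iv$start_s[-1] < imaging_iv$end_s[-nrow(imaging_iv)])) {
    abort("Imaging windows overlap between adjacent trials.",
          class = "optodesens_config_error")
  }
  structure(
    list(trials = trials, stims = stims, imaging = imaging_iv,
         session_end = session_end, protocol = protocol,
         imaging_config = imaging),
    class = "session_schedule"
  )
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf(
    "<session_schedule> %d trials, ISI %g s, %s imaging (%s), %d stim events, end %g s\n",
    nrow(x$trials), x$protocol$isi, x$imaging_config$dose_mode,
    if (x$imaging_config$dose_mode == "windowed")
      sprintf("%g s window", x$imaging_config$dose_duration) else "whole session",
    nrow(x$stims), x$session_end))
  invisible(x)
}

#' Flatten a schedule to a single event table
#'
#' @param schedule A `session_schedule`.
#' @return A tibble with columns `time_s`, `kind` (`trial_onset`, `stim`,
#'   `imaging`), `group`, `trial`, `duration_s`, sorted by time.
#' @export
schedule_events <- function(schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  ev <- bind_rows(
    tibble(time_s = schedule$trials$onset_s, kind = "trial_onset",
           group = NA_integer_, trial = schedule$trials$trial, duration_s = 0),
    schedule$stims,
    tibble(time_s = schedule$imaging$start_s, kind = "imaging",
           group = NA_integer_, trial = NA_integer_,
           duration_s = schedule$imaging$end_s - schedule$imaging$start_s)
  )
  arrange(ev, .data$time_s, .data$kind)
}

#' Frame times of a schedule's acquisition clock
#'
#' The frame clock runs for the whole session at `1/frame_rate` spacing;
#' whether a frame is actually acquired (inside an imaging window) is a
#' separate mask, see [frames_imaged()].
#'
#' @param schedule A `session_schedule`.
#' @return Numeric vector of frame times, seconds.
#' @export
frame_times <- function(schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  seq(0, schedule$session_end, by = 1 / schedule$imaging_config$frame_rate)
}

#' Which frames fall inside an imaging window
#'
#' @param schedule A `session_schedule`.
#' @param times Frame times; default [frame_times()] of the schedule.
#' @return Logical vector, `TRUE` where the frame is acquired.
#' @export
frames_imaged <- function(schedule, times = frame_times(schedule)) {
  iv <- schedule$imaging
  Reduce(`|`, map2(iv$start_s, iv$end_s, ~times >= .x & times < .y))
}

#' Per-frame imaging dwell time over one cell body
#'
#' Area-fraction model: during each frame the scanned illumination spends
#' `frame_period * duty_factor * (soma disc area / FOV area)` seconds on a
#' soma. Linear in duty factor and soma area, and independent of pixel
#' resolution at fixed FOV and frame rate.
#'
#' @param imaging An [imaging_config()].
#' @param soma_diameter Soma diameter, micrometers (default 15).
#' @return Dwell time in seconds per frame.
#' @examples
#' # large-FOV defaults give roughly 3 microseconds per frame
#' imaging_dwell_per_cell(imaging_config()) * 1e6
#' @export
imaging_dwell_per_cell <- function(imaging, soma_diameter = 15) {
  validate_imaging_config(imaging)
  if (soma_diameter < 0 || soma_diameter >= min(imaging$fov)) {
    abort("soma_diameter must be non-negative and smaller than the FOV.",
          class = "optodesens_config_error")
  }
  soma_area <- pi * (soma_diameter / 2)^2
  (1 / imaging$frame_rate) * imaging$duty_factor *
    soma_area / prod(imaging$fov)
}
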