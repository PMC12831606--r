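#' Write a session to disk
#'
#' One plain-text trace table (`traces.csv`: cells x frames, first column
#' the cell id, `NA` for frames outside imaging windows) plus a JSON sidecar
#' (`session.json`) carrying frame times, stimulation events, beamlets,
#' ground-truth labels, configs and seeds. The format is versioned; the
#' reader validates invariants.
#'
#' @param session An `opto_session`.
#' @param dir Directory to write into (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "opto_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- as.data.frame(session$traces)
  names(tr) <- paste0("f", seq_len(ncol(tr)))
  write.csv(cbind(cell = seq_len(nrow(tr)), tr),
            file.path(dir, "traces.csv"), row.names = FALSE)
  meta <- list(
    format_version = session$format_version %||% "1.0",
    animal = session$animal,
    seed = session$seed,
    response_factor = session$response_factor,
    f0 = session$f0,
    frame_times = session$frame_times,
    imaged = session$imaged,
    stim_events = session$schedule$stims,
    trial_onsets = session$schedule$trials,
    imaging_intervals = session$schedule$imaging,
    session_end = session$schedule$session_end,
    beamlets = session$beamlets,
    population = as.data.frame(session$population),
    drives = session$drives,
    protocol = unclass(session$protocol),
    imaging = unclass(session$imaging),
    params = unclass(session$params),
    noise = if (!is.null(session$noise)) unclass(session$noise),
    calcium = unclass(session$calcium),
    gain = unclass(session$gain)
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' Validates the invariants of the format: strictly increasing frame times
#' at the configured frame spacing, beamlet radius equal to half the spiral
#' diameter, and trace dimensions consistent with the metadata.
#'
#' @param dir Directory containing `traces.csv` and `session.json`.
#' @return An `opto_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  tr <- read.csv(file.path(dir, "traces.csv"))
  traces <- as.matrix(tr[, -1, drop = FALSE])
  dimnames(traces) <- NULL
  ft <- as.numeric(meta$frame_times)
  if (is.unsorted(ft, strictly = TRUE)) {
    abort("Corrupt session: frame times are not strictly increasing.",
          class = "optodesens_data_error")
  }
  spacing <- diff(ft)
  if (max(abs(spacing - 1 / meta$imaging$frame_rate)) > 1e-6) {
    abort("Corrupt session: frame spacing does not match the frame rate.",
          class = "optodesens_data_error")
  }
  if (ncol(traces) != length(ft)) {
    abort("Corrupt session: trace columns do not match frame times.",
          class = "optodesens_data_error")
  }
  beamlets <- as_tibble(meta$beamlets)
  if (any(abs(beamlets$radius - meta$protocol$spiral_diameter / 2) > 1e-9)) {
    abort("Corrupt session: beamlet radius must be half the spiral diameter.",
          class = "optodesens_data_error")
  }
  protocol <- structure(meta$protocol, class = "stim_protocol")
  protocol$n_trials <- as.integer(protocol$n_trials)
  protocol$n_groups <- as.integer(protocol$n_groups)
  protocol$targets_per_group <- as.integer(protocol$targets_per_group)
  protocol$blocks_per_group <- as.integer(protocol$blocks_per_group)
  imaging <- structure(meta$imaging, class = "imaging_config")
  imaging$fov <- as.numeric(imaging$fov)
  imaging$resolution <- as.integer(imaging$resolution)
  pop <- as_tibble(meta$population)
  class(pop) <- c("cell_population", class(pop))
  schedule <- structure(
    list(trials = as_tibble(meta$trial_onsets),
         stims = as_tibble(meta$stim_events),
         imaging = as_tibble(meta$imaging_intervals),
         session_end = meta$session_end,
         protocol = protocol, imaging_config = imaging),
    class = "session_schedule"
  )
  structure(
    list(traces = traces, frame_times = ft, imaged = as.logical(meta$imaged),
         schedule = schedule, beamlets = beamlets, population = pop,
         drives = if (!is.null(meta$drives)) as.matrix(meta$drives),
         animal = meta$animal, seed = meta$seed,
         response_factor = meta$response_factor, f0 = meta$f0,
         protocol = protocol, imaging = imaging,
         params = structure(meta$params, class = "kinetic_params"),
         noise = if (!is.null(meta$noise))
           structure(meta$noise, class = "noise_model"),
         calcium = structure(meta$calcium, class = "calcium_params"),
         gain = structure(meta$gain, class = "gain_params"),
         format_version = meta$format_version),
    class = "opto_session"
  )
}

#' Write a toy movie rendering of a session (format smoke test)
#'
#' Renders Gaussian cell profiles modulated by the session's traces into a
#' small multi-page grayscale TIFF. This is a toy visualization for format
#' interoperability checks only — the generator's primary output is ROI
#' traces, not movies.
#'
#' @param session An `opto_session`.
#' @param path Output TIFF path.
#' @param frames Indices of frames to render (default the first 10).
#' @param px Image size in pixels (square).
#' @return `path`, invisibly. Requires the `tiff` package.
#' @export
write_toy_movie <- function(session, path, frames = seq_len(10), px = 64) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The 'tiff' package is required for write_toy_movie().")
  }
  fov <- session$imaging$fov
  sc <- px / fov[1]
  xg <- (seq_len(px) - 0.5) / sc
  pop <- session$population
  frames <- frames[frames <= ncol(session$traces)]
  fmax <- max(session$traces, na.rm = TRUE)
  pages <- map(frames, function(fr) {
    img <- matrix(0, px, px)
    for (i in seq_len(nrow(pop))) {
      f <- session$traces[i, fr]
      if (is.na(f)) next
      dx2 <- outer((xg - pop$y[i])^2, (xg - pop$x[i])^2, "+")
      img <- img + (f / fmax) * exp(-dx2 / (2 * pop$radius[i]^2))
    }
    pmin(img, 1)
  })
  tiff::writeTIFF(pages, path)
  invisible(path)
}
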