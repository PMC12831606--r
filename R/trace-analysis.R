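#' Stimulus-triggered delta-F/F for one trace and one trial
#'
#' `dF/F = (F - F0) / F0`, where `F0` is the mean raw fluorescence over the
#' 1 s immediately preceding the stimulation onset (`[onset - 1, onset)`).
#' Frames recorded as `NA` (outside imaging windows) are dropped from the
#' baseline mean and propagate as `NA` in the output.
#'
#' @param trace Numeric raw-fluorescence vector.
#' @param times Frame times, seconds (same length as `trace`).
#' @param onset Stimulation onset, seconds.
#' @param pre Extent of the window before onset, seconds (the baseline
#'   second is always the last 1 s before onset).
#' @param post Extent of the window after onset, seconds.
#' @return A tibble with `time_s`, `t_rel` (time minus onset) and `dff` for
#'   frames in `[onset - pre, onset + post)`.
#' @export
compute_dff <- function(trace, times, onset, pre = 1, post = 2) {
  stopifnot(length(trace) == length(times))
  base_idx <- which(times >= onset - 1 & times < onset & !is.na(trace))
  if (length(base_idx) == 0) {
    abort("No valid frames in the 1 s pre-stimulation baseline.",
          class = "optodesens_data_error")
  }
  f0 <- mean(trace[base_idx])
  if (!is.finite(f0) || f0 <= 0) {
    abort("Baseline fluorescence must be positive to form dF/F.",
          class = "optodesens_data_error")
  }
  win <- which(times >= onset - pre & times < onset + post)
  # quantize to nanoseconds so equivalent frame offsets align exactly
  # across trials (frame periods are tens of milliseconds)
  tibble(time_s = times[win], t_rel = round(times[win] - onset, 9),
         dff = (trace[win] - f0) / f0)
}

#' Per-cell, per-trial delta-F/F windows for a whole session
#'
#' Applies [compute_dff()] to every cell and every trial of a session,
#' returning a long table — the tidy equivalent of a cells x trials x
#' in-window-frames tensor.
#'
#' @param session An `opto_session` (or any list with `traces`,
#'   `frame_times` and a `schedule`).
#' @param pre,post Window extent around each stimulation onset, seconds.
#' @return A tibble `cell`, `trial` (1-based), `t_rel`, `dff`, with the
#'   session frame rate attached as attribute `frame_rate`.
#' @export
trial_dff <- function(session, pre = 1, post = 2) {
  onsets <- session$schedule$trials$onset_s
  times <- session$frame_times
  out <- list_rbind(map(seq_len(nrow(session$traces)), function(i) {
    tr <- session$traces[i, ]
    d <- list_rbind(map(seq_along(onsets), function(k) {
      d <- compute_dff(tr, times, onsets[k], pre = pre, post = post)
      d$trial <- k
      d
    }))
    d$cell <- i
    d
  }))
  out <- select(out, "cell", "trial", "time_s", "t_rel", "dff")
  attr(out, "frame_rate") <- session$schedule$imaging_config$frame_rate
  out
}

#' Screen cells for responsiveness
#'
#' A cell is responsive if its mean delta-F/F over the 1 s post-stimulation
#' windows, pooled across all trials of the session, is at least
#' `threshold`. The boundary is inclusive (a mean of exactly 0.1 counts as
#' responsive).
#'
#' @param dff A [trial_dff()] table.
#' @param threshold Responsiveness threshold on mean post-stim delta-F/F.
#' @return A tibble `cell`, `mean_post`, `responsive`.
#' @export
is_responsive <- function(dff, threshold = 0.1) {
  post <- filter(dff, .data$t_rel >= 0, .data$t_rel < 1, !is.na(.data$dff))
  if (nrow(post) == 0) {
    abort("No frames in the 1 s post-stimulation window.",
          class = "optodesens_data_error")
  }
  summarize(group_by(post, .data$cell),
            mean_post = mean(.data$dff),
            responsive = .data$mean_post >= threshold,
            .groups = "drop")
}

# Trapezoidal AUC over [lo, hi) using frames inside the window; the window
# edges are padded with the nearest inside-frame value so a constant trace
# integrates to value * (hi - lo).
auc_window <- function(t, y, lo = 0, hi = 1) {
  keep <- !is.na(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) == 0) return(NA_real_)
  o <- order(t)
  t <- t[o]; y <- y[o]
  if (t[1] > lo) { t <- c(lo, t); y <- c(y[1], y) }
  n <- length(t)
  if (t[n] < hi) { t <- c(t, hi); y <- c(y, y[n]) }
  pracma::trapz(t, y)
}

#' Population photostimulation response per trial
#'
#' The response of a set of cells on a trial is the area under the curve of
#' their mean delta-F/F trace over the 1 s post-stimulation window
#' (trapezoidal rule over the actual frame times, window edges padded with
#' the nearest inside frames). An empty cell subset yields a flagged
#' undefined response (`NA`), never a silent zero; a trial whose window
#' retains fewer than `min_frame_frac` of its nominal frames is flagged
#' invalid.
#'
#' @param dff A [trial_dff()] table.
#' @param cells Integer vector of cell ids to average over; `NULL` means all
#'   cells present.
#' @param window Post-stimulation integration window `c(lo, hi)`, seconds
#'   relative to onset.
#' @param min_frame_frac Minimum fraction of nominal frames required for a
#'   valid window.
#' @param frame_rate Frames per second; defaults to the attribute attached
#'   by [trial_dff()].
#' @return A tibble `trial`, `response` (delta-F/F seconds), `n_cells`,
#'   `n_frames`, `valid`.
#' @export
population_response <- function(dff, cells = NULL, window = c(0, 1),
                                min_frame_frac = 0.5,
                                frame_rate = attr(dff, "frame_rate")) {
  if (!is.null(cells) && length(cells) == 0) {
    warn("Empty cell subset: population response is undefined.")
    return(tibble(trial = sort(unique(dff$trial)), response = NA_real_,
                  n_cells = 0L, n_frames = 0L, valid = FALSE))
  }
  d <- if (is.null(cells)) dff else filter(dff, .data$cell %in% cells)
  d <- filter(d, .data$t_rel >= window[1], .data$t_rel < window[2])
  mean_trace <- summarize(group_by(d, .data$trial, .data$t_rel),
                          n_cells = sum(!is.na(.data$dff)),
                          dff = mean(.data$dff, na.rm = TRUE),
                          .groups = "drop")
  mean_trace$dff[is.nan(mean_trace$dff)] <- NA_real_
  nominal <- if (is.null(frame_rate)) NA_real_ else
    (window[2] - window[1]) * frame_rate
  summarize(
    group_by(mean_trace, .data$trial),
    response = auc_window(.data$t_rel, .data$dff, window[1], window[2]),
    n_cells = max(.data$n_cells),
    n_frames = sum(!is.na(.data$dff)),
    valid = is.na(nominal) | .data$n_frames >= min_frame_frac * nominal,
    .groups = "drop"
  )
}

#' Trial-10 minus trial-1 response
#'
#' The change in response between the last and first trial; negative values
#' indicate desensitization. Grouping columns other than `trial` and
#' `response` are preserved, one delta per group.
#'
#' @param data A tibble with columns `trial`, `response`, plus any grouping
#'   columns (animal, condition, class, ...).
#' @param first,last Trial numbers being differenced (defaults 1 and 10).
#' @return A tibble with the grouping columns and `delta_response`.
#' @export
delta_response <- function(data, first = 1, last = 10) {
  keys <- setdiff(names(data), c("trial", "response"))
  g <- group_by(data, across(all_of(keys)))
  out <- summarize(
    g,
    delta_response = {
      r1 <- .data$response[.data$trial == first]
      r2 <- .data$response[.data$trial == last]
      if (length(r1) != 1 || length(r2) != 1) {
        abort(sprintf("Trials %d and %d must each appear exactly once per group.",
                      first, last), class = "optodesens_data_error")
      }
      r2 - r1
    },
    .groups = "drop"
  )
  out
}

#' Normalized decay curve across ISIs and animals
#'
#' Reproduces the fixed averaging order of the cross-condition decay curve:
#' per-trial responses are averaged across ISIs within animal, then across
#' animals, and finally divided by the trial-1 value of the same averaged
#' curve — so trial 1 maps to exactly 1.
#'
#' @param data A tibble with columns `animal`, `isi`, `trial`, `response`
#'   covering a complete `animal x isi x trial` grid.
#' @return A tibble `trial`, `mean_response`, `norm_response`.
#' @export
normalized_decay_curve <- function(data) {
  stopifnot(all(c("animal", "isi", "trial", "response") %in% names(data)))
  full <- tidyr::expand_grid(animal = unique(data$animal),
                             isi = unique(data$isi),
                             trial = unique(data$trial))
  missing <- anti_join(full, data, by = c("animal", "isi", "trial"))
  if (nrow(missing) > 0) {
    abort(paste0(
      "Incomplete condition grid; missing (animal, isi, trial) cells: ",
      paste(sprintf("(%s, %s, %s)", missing$animal, missing$isi,
                    missing$trial), collapse = ", ")),
      class = "optodesens_data_error")
  }
  by_animal <- summarize(group_by(data, .data$animal, .data$trial),
                         response = mean(.data$response), .groups = "drop")
  curve <- summarize(group_by(by_animal, .data$trial),
                     mean_response = mean(.data$response), .groups = "drop")
  r1 <- curve$mean_response[curve$trial == min(curve$trial)]
  mutate(curve, norm_response = .data$mean_response / r1)
}
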