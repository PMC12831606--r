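make_frames <- function(rate = 15, t_end = 20) seq(0, t_end, by = 1 / rate)

test_that("delta-F/F uses the mean of the 1 s pre-stimulation baseline", {
  times <- make_frames()
  onset <- 5
  # constant trace -> all zeros
  d <- compute_dff(rep(100, length(times)), times, onset)
  expect_true(all(d$dff == 0))
  # baseline mean 100, post frame 120 -> 0.2
  tr <- rep(100, length(times))
  tr[times >= onset] <- 120
  d <- compute_dff(tr, times, onset)
  expect_equal(unique(d$dff[d$t_rel >= 0]), 0.2)
  # mixed baseline {90, 110} averages to 100 (even frame count in the
  # baseline second at 16 Hz)
  times16 <- make_frames(rate = 16)
  tr2 <- rep(c(90, 110), length.out = length(times16))
  tr2[times16 >= onset] <- 150
  d2 <- compute_dff(tr2, times16, onset)
  expect_equal(unique(d2$dff[d2$t_rel >= 0]), 0.5)
})

test_that("delta-F/F rejects invalid baselines and is gain invariant", {
  times <- make_frames()
  expect_error(compute_dff(rep(0, length(times)), times, 5),
               class = "optodesens_data_error")
  tr <- rep(NA_real_, length(times))
  tr[times >= 5] <- 100
  expect_error(compute_dff(tr, times, 5), class = "optodesens_data_error")
  # multiplying the raw trace by any positive gain leaves dF/F unchanged
  set.seed(1)
  tr <- 100 + cumsum(rnorm(length(times)))
  d1 <- compute_dff(tr, times, 5)
  d2 <- compute_dff(3.7 * tr, times, 5)
  expect_equal(d1$dff, d2$dff)
})

test_that("the responsiveness threshold is 0.1 inclusive", {
  times <- make_frames(t_end = 12)
  onset <- 5
  sess <- function(level) {
    tr <- rep(100, length(times))
    tr[times >= onset & times < onset + 1] <- 100 * (1 + level)
    list(traces = matrix(tr, nrow = 1), frame_times = times,
         schedule = list(trials = tibble::tibble(trial = 0L, onset_s = onset),
                         imaging_config = list(frame_rate = 15)))
  }
  at <- is_responsive(trial_dff(sess(0.1)))
  expect_true(at$responsive)
  expect_equal(at$mean_post, 0.1)
  below <- is_responsive(trial_dff(sess(0.0999)))
  expect_false(below$responsive)
  zero <- is_responsive(trial_dff(sess(0)))
  expect_false(zero$responsive)
})

test_that("population response integrates the mean trace over the post second", {
  times <- make_frames(t_end = 12)
  onset <- 5
  build_dff <- function(shape) {
    # two cells with identical windows; mean equals the shape
    d <- purrr::list_rbind(purrr::map(1:2, function(cl) {
      sel <- times >= onset - 1 & times < onset + 2
      tibble::tibble(cell = cl, trial = 1L, time_s = times[sel],
                     t_rel = times[sel] - onset,
                     dff = shape(times[sel] - onset))
    }))
    attr(d, "frame_rate") <- 15
    d
  }
  # constant 0.5 for the full second -> rectangle 0.5
  r <- population_response(build_dff(function(t) rep(0.5, length(t))))
  expect_equal(r$response, 0.5)
  expect_true(r$valid)
  # zero trace -> 0
  expect_equal(population_response(
    build_dff(function(t) rep(0, length(t))))$response, 0)
  # linear ramp 0 -> 1 over the second: trapezoid-exact triangle
  r2 <- population_response(build_dff(function(t) pmax(0, pmin(t, 1))))
  expect_equal(r2$response, 0.5, tolerance = 5e-3)
  # empty subset is flagged undefined, never silently zero
  expect_warning(r3 <- population_response(build_dff(function(t) t * 0),
                                           cells = integer(0)))
  expect_true(all(is.na(r3$response)))
  expect_false(any(r3$valid))
})

test_that("population response is linear and permutation invariant", {
  sess <- small_session(n_cells = 30, noise = NULL)
  d <- trial_dff(sess)
  cells <- sess$population$cell[sess$population$role == "target"]
  r1 <- population_response(d, cells = cells)
  r2 <- population_response(d, cells = rev(cells))
  expect_equal(r1, r2)
  # doubling the mean trace doubles the AUC
  d2 <- d
  d2$dff <- 2 * d2$dff
  attr(d2, "frame_rate") <- attr(d, "frame_rate")
  r3 <- population_response(d2, cells = cells)
  expect_equal(r3$response, 2 * r1$response)
})

test_that("delta response differences trial 10 and trial 1 and negates on reversal", {
  tab <- tibble::tibble(animal = 1, trial = 1:10, response = 1)
  expect_equal(delta_response(tab)$delta_response, 0)
  tab2 <- tibble::tibble(animal = 1, trial = 1:10,
                         response = seq(1, 0.7, length.out = 10))
  expect_equal(delta_response(tab2)$delta_response, -0.3)
  rev2 <- dplyr::mutate(tab2, trial = 11 - trial)
  expect_equal(delta_response(rev2)$delta_response, 0.3)
  expect_error(delta_response(tibble::tibble(animal = 1, trial = 1:9,
                                             response = 1)),
               class = "optodesens_data_error")
})

test_that("normalized decay curves pin trial 1 to 1 and enforce the grid", {
  tab <- tidyr::expand_grid(animal = 1:3, isi = c(10, 20), trial = 1:10)
  tab$response <- 1 / tab$trial + 0.1 * tab$animal
  curve <- normalized_decay_curve(tab)
  expect_equal(curve$norm_response[curve$trial == 1], 1)
  # single animal, single ISI: proportional to raw responses
  one <- dplyr::filter(tab, animal == 1, isi == 10)
  c1 <- normalized_decay_curve(one)
  expect_equal(c1$norm_response, one$response / one$response[1])
  # a missing grid cell is a hard, informative error
  expect_error(normalized_decay_curve(tab[-1, ]),
               class = "optodesens_data_error",
               regexp = "missing")
})

test_that("noiseless target responses recover the kinetic drive curve", {
  sess <- small_session(n_cells = 30, noise = NULL)
  res <- analyze_session(sess, network = FALSE)
  tr <- res$responses[res$responses$class == "target", ]
  drv <- simulate_trial_responses(sess$schedule, kinetic_params())$drive
  norm_resp <- tr$response / tr$response[1]
  expect_lt(max(abs(norm_resp - drv / drv[1])), 0.02)
  expect_gt(cor(norm_resp, drv), 0.999)
})
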