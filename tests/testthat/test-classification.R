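test_that("target assignment picks the nearest overlapping cell per beamlet", {
  beam <- tibble::tibble(beamlet = 1L, x = 0, y = 0, radius = 5)
  cells <- tibble::tibble(cell = 1:3, x = c(4, 2, 30), y = 0, radius = 7.5)
  ta <- assign_targets(beam, cells)
  expect_equal(ta$label, c("excluded", "target", "none"))
  expect_equal(ta$beamlet[2], 1L)
  # single overlapping cell becomes the target
  one <- assign_targets(beam, cells[1, ])
  expect_equal(one$label, "target")
  # non-overlap: distance >= beamlet radius + cell radius
  far <- tibble::tibble(cell = 1L, x = 12.6, y = 0, radius = 7.5)
  expect_equal(suppressWarnings(assign_targets(beam, far))$label, "none")
  # tie in distance breaks to the lowest cell index
  tie <- tibble::tibble(cell = 1:2, x = c(3, -3), y = 0, radius = 7.5)
  expect_equal(assign_targets(beam, tie)$label, c("target", "excluded"))
  # empty beamlet warns and stays unmatched
  lonely <- tibble::tibble(beamlet = 1L, x = 500, y = 500, radius = 5)
  expect_warning(assign_targets(lonely, far), "unmatched")
})

# A deterministic miniature session for correlation-rule tests: one target
# plus constructed companions, 10 trials at 15 Hz.
corr_fixture <- function() {
  rate <- 15
  isi <- 6
  onsets <- 3 + (0:9) * isi
  times <- seq(0, max(onsets) + 3, by = 1 / rate)
  kernel <- function(t) ifelse(t < 0, 0, (1 - exp(-t / 0.18)) * exp(-t / 1.5))
  target <- rep(100, length(times))
  for (k in seq_along(onsets)) {
    target <- target + 60 * (1 - 0.05 * k) * kernel(times - onsets[k])
  }
  follower <- 100 + (target - 100) * 0.8          # scaled copy -> excited
  mirror <- 200 - (target - 100) * 0.6            # negated -> inhibited
  # correlated on trials >= 2 but near-flat, alternating on trial 1
  late <- target
  t1_win <- times >= onsets[1] - 1 & times < onsets[1] + 1
  late[t1_win] <- 100 + rep_len(c(0.05, -0.05), sum(t1_win))
  flat <- rep(100, length(times))
  traces <- rbind(target, follower, mirror, late, flat)
  pop <- tibble::tibble(cell = 1:5, x = c(10, 100, 200, 300, 400), y = 10,
                        radius = 7.5)
  sess <- list(traces = traces, frame_times = times,
               schedule = list(
                 trials = tibble::tibble(trial = 0:9, onset_s = onsets),
                 imaging_config = list(frame_rate = rate)))
  list(session = sess,
       dff = trial_dff(sess),
       assignment = tibble::tibble(
         cell = 1:5,
         label = c("target", "none", "none", "none", "none"),
         beamlet = c(1L, NA, NA, NA, NA), dist = c(0, NA, NA, NA, NA)))
}

test_that("the dual-correlation rule separates excited, inhibited and trial-1-silent cells", {
  fx <- corr_fixture()
  labs <- suppressWarnings(classify_network(fx$dff, fx$assignment))
  lab <- setNames(labs$label, labs$cell)
  expect_equal(unname(lab["2"]), "excited")
  expect_gt(labs$r[labs$cell == 2], 0.9)
  expect_lt(labs$p_all[labs$cell == 2], 0.05)
  expect_equal(unname(lab["3"]), "inhibited")
  expect_lt(labs$r[labs$cell == 3], 0)
  # correlated across all trials but not active on trial 1 -> non-responder
  expect_equal(unname(lab["4"]), "non_responder")
  # sanity of the construction: all-trials r is significant, trial 1 is not
  all_w <- dplyr::arrange(dplyr::filter(fx$dff, t_rel >= -1, t_rel < 1),
                          cell, trial, t_rel)
  v_t <- all_w$dff[all_w$cell == 1]
  v_l <- all_w$dff[all_w$cell == 4]
  expect_lt(cor.test(v_t, v_l)$p.value, 0.05)
  t1 <- dplyr::filter(fx$dff, trial == 1, t_rel >= -1, t_rel < 1)
  expect_gte(cor.test(t1$dff[t1$cell == 1], t1$dff[t1$cell == 4])$p.value,
             0.05)
})

test_that("classification is invariant to trace gain and affine dF/F maps", {
  fx <- corr_fixture()
  # multiplicative gain on the raw trace cancels exactly in dF/F
  sess2 <- fx$session
  sess2$traces[2, ] <- 4 * sess2$traces[2, ]
  labs1 <- suppressWarnings(classify_network(fx$dff, fx$assignment))
  labs2 <- suppressWarnings(classify_network(trial_dff(sess2), fx$assignment))
  expect_equal(labs1$label, labs2$label)
  expect_equal(labs1$r, labs2$r, tolerance = 1e-12)
  # positive affine maps of the dF/F vector leave Pearson labels untouched
  dff3 <- fx$dff
  sel <- dff3$cell == 2
  dff3$dff[sel] <- 0.25 + 3 * dff3$dff[sel]
  labs3 <- suppressWarnings(classify_network(dff3, fx$assignment))
  expect_equal(labs1$label, labs3$label)
  expect_equal(labs1$r, labs3$r, tolerance = 1e-12)
})

test_that("excluded cells never enter the network classification", {
  fx <- corr_fixture()
  asg <- fx$assignment
  asg$label[2] <- "excluded"   # perfect follower, but geometrically excluded
  labs <- suppressWarnings(classify_network(fx$dff, asg))
  expect_false(2 %in% labs$cell)
})

test_that("the partition covers every cell exactly once", {
  sess <- small_session(n_cells = 40, seed = 3)
  labs <- classify_cells(sess)
  expect_equal(nrow(labs), 40)
  expect_equal(sort(labs$cell), 1:40)
  counts <- partition_summary(labs)
  expect_equal(sum(counts$n), 40)
  expect_true(all(counts$label %in%
                    c("target", "excluded", "excited", "inhibited",
                      "non_responder")))
})

test_that("an all-background noiseless session yields no network labels", {
  prot <- stim_protocol()
  pop <- make_population(n_cells = 30, protocol = prot, seed = 2,
                         excited_frac = 0, inhibited_frac = 0)
  sess <- simulate_session(pop, prot, imaging_config(), noise = NULL,
                           seed = 4)
  labs <- suppressWarnings(classify_cells(sess))
  counts <- partition_summary(labs)
  expect_equal(sum(counts$n[counts$label %in% c("excited", "inhibited")],
                   na.rm = TRUE), 0)
})

test_that("ground-truth excited cells are recovered from noisy sessions", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    sess <- small_session(n_cells = 60, seed = s, session_seed = 100 + s)
    labs <- classify_cells(sess)
    truth_exc <- sess$population$cell[sess$population$role == "excited"]
    hits <- hits + sum(labs$label[labs$cell %in% truth_exc] == "excited")
    total <- total + length(truth_exc)
  }
  expect_gt(total, 10)
  expect_gte(hits / total, 0.95)
})
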