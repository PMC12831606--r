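test_that("stim pulses scale the ground fraction by the depletion factor", {
  p <- kinetic_params()
  expect_equal(apply_stim_pulse(1, p), 0.85)
  expect_equal(apply_stim_pulse(0.5, p), 0.425)
  p0 <- kinetic_params(d_stim = 0)
  expect_equal(apply_stim_pulse(0.7, p0), 0.7)
  # power scaling: half power at exponent 2 quarters the depletion
  expect_equal(apply_stim_pulse(1, p, power_ratio = 0.5),
               1 - 0.15 / 4)
})

test_that("dark relaxation follows the exact exponential recovery", {
  p <- kinetic_params(tau_r = 50)
  expect_equal(integrate_dark(1, p, 123), 1)
  expect_equal(integrate_dark(0.3, p, 1e6), 1)
  expect_equal(integrate_dark(0.8488, p, 9), 0.8737, tolerance = 1e-4)
  expect_error(integrate_dark(0.5, p, -1),
               class = "optodesens_argument_error")
})

test_that("imaging relaxation reduces to dark when k_im = 0 and hits its equilibrium", {
  p0 <- kinetic_params(k_im = 0)
  g <- runif(5)
  expect_equal(integrate_imaging(g, p0, 7), integrate_dark(g, p0, 7))
  p <- kinetic_params(tau_r = 50, k_im = 0.004)
  g_eq <- (1 / 50) / (1 / 50 + 0.004)
  expect_equal(g_eq, 0.8333, tolerance = 1e-4)
  expect_equal(integrate_imaging(0.2, p, 1e6), g_eq)
  expect_equal(integrate_imaging(g_eq, p, 13), g_eq)
})

test_that("relaxation operators form a semigroup in duration", {
  set.seed(42)
  p <- kinetic_params()
  for (i in 1:20) {
    g <- runif(1)
    a <- runif(1, 0, 30)
    b <- runif(1, 0, 30)
    expect_equal(integrate_dark(g, p, a + b),
                 integrate_dark(integrate_dark(g, p, a), p, b),
                 tolerance = 1e-12)
    expect_equal(integrate_imaging(g, p, a + b),
                 integrate_imaging(integrate_imaging(g, p, a), p, b),
                 tolerance = 1e-12)
  }
})

test_that("the default drive curve matches the hand-iterated recursion", {
  k <- simulate_trial_responses(default_schedule(), kinetic_params())
  expect_equal(k$drive, HAND_DRIVES, tolerance = 1e-4)
  expect_equal(k$drive[1], 1)
})

test_that("closed-form trajectories agree with forward Euler on random schedules", {
  set.seed(7)
  p <- kinetic_params()
  for (i in 1:3) {
    isi <- runif(1, 2, 5)
    dose <- runif(1, 0.5, isi)
    windowed <- i %% 2 == 0
    sched <- build_session_schedule(
      stim_protocol(isi = isi, n_trials = 4),
      imaging_config(dose_mode = if (windowed) "windowed" else "constant",
                     dose_duration = dose))
    closed <- simulate_trial_responses(sched, p)$drive
    euler <- euler_drive(sched, p, dt = 1e-4)
    expect_lt(max(abs(closed - euler)), 1e-5)
  }
})

test_that("the ground fraction stays in [0, 1] under random schedules", {
  set.seed(11)
  for (i in 1:10) {
    p <- kinetic_params(tau_r = runif(1, 5, 100),
                        d_stim = runif(1, 0, 0.9),
                        k_im = runif(1, 0, 0.05))
    sched <- build_session_schedule(
      stim_protocol(isi = runif(1, 1, 20), n_trials = 8),
      imaging_config(dose_mode = sample(c("constant", "windowed"), 1),
                     dose_duration = 0.5))
    d <- simulate_trial_responses(sched, p)$drive
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("steady state agrees with the long-run simulation and is monotone", {
  p <- kinetic_params()
  prot <- stim_protocol()
  img <- imaging_config()
  ss <- steady_state_drive(prot, img, p)
  # independent check: run the trial recursion far past the plateau
  long <- simulate_trial_responses(
    build_session_schedule(stim_protocol(n_trials = 200), img), p)
  expect_equal(ss, long$drive[200], tolerance = 1e-6)
  expect_equal(ss, 0.665, tolerance = 1e-3)

  # no desensitization, no decay
  expect_equal(steady_state_drive(prot, img, kinetic_params(d_stim = 0, k_im = 0)), 1)

  # monotonicity in protocol and kinetic parameters
  ss_isi <- sapply(c(10, 15, 30, 40), function(i)
    steady_state_drive(stim_protocol(isi = i), img, p))
  expect_true(all(diff(ss_isi) > 0))
  ss_kim <- sapply(c(0, 0.002, 0.004, 0.01), function(k)
    steady_state_drive(prot, img, kinetic_params(k_im = k)))
  expect_true(all(diff(ss_kim) < 0))
  ss_d <- sapply(c(0.05, 0.15, 0.3), function(d)
    steady_state_drive(prot, img, kinetic_params(d_stim = d)))
  expect_true(all(diff(ss_d) < 0))
  # slower recovery (larger tau_r) deepens the steady-state depletion
  ss_tau <- sapply(c(20, 50, 100), function(tau)
    steady_state_drive(prot, img, kinetic_params(tau_r = tau)))
  expect_true(all(diff(ss_tau) < 0))
  # longer imaging dose (more light) lowers the plateau
  ss_dose <- sapply(c(2, 6, 12), function(dd)
    steady_state_drive(prot, imaging_config(dose_duration = dd), p))
  expect_true(all(diff(ss_dose) < 0))
  expect_lt(steady_state_drive(prot, imaging_config(dose_mode = "constant"), p),
            ss_dose[3])
})

test_that("ten-second constant-imaging sessions plateau near half drive", {
  ss <- steady_state_drive(stim_protocol(isi = 10),
                           imaging_config(dose_mode = "constant"),
                           kinetic_params())
  expect_equal(ss, 0.537, tolerance = 1e-3)
})

test_that("kinetic parameters are recoverable from noiseless multi-condition curves", {
  truth <- kinetic_params()
  conds <- list(
    isi15_dose6 = default_schedule(15, "windowed", 6),
    isi10_const = default_schedule(10, "constant"),
    isi30_dose2 = default_schedule(30, "windowed", 2)
  )
  curves <- purrr::list_rbind(purrr::imap(conds, function(s, nm) {
    d <- simulate_trial_responses(s, truth)
    tibble::tibble(condition = nm, trial = d$trial, drive = d$drive)
  }))
  fit <- fit_kinetic_params(curves, conds)
  expect_true(fit$convergence)
  expect_lt(abs(fit$params$tau_r - 50) / 50, 0.05)
  expect_lt(abs(fit$params$d_stim - 0.15) / 0.15, 0.05)
  expect_lt(abs(fit$params$k_im - 0.004) / 0.004, 0.05)
})
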