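#' Recover kinetic parameters from drive curves across conditions
#'
#' Least-squares estimation of `(tau_r, d_stim, k_im)` from per-trial drive
#' curves measured under several (ISI, imaging-dose) conditions. Identifying
#' all three parameters needs curves from at least three conditions that
#' separate the stimulation and imaging channels (e.g. two dose durations and
#' two ISIs). Optimization is L-BFGS-B on `(log tau_r, logit-free d_stim,
#' log k_im)`-like box-constrained raw scales, minimizing the summed squared
#' deviation between observed and model drives.
#'
#' @param curves A tibble with columns `condition` (identifier), `trial`,
#'   `drive` — e.g. stacked outputs of [simulate_trial_responses()].
#' @param schedules Named list of `session_schedule` objects, one per
#'   condition level in `curves`.
#' @param start Numeric vector of starting values `c(tau_r, d_stim, k_im)`.
#' @param power_scaling Fixed power-scaling exponent (not estimated).
#' @return A list with `params` (a [kinetic_params()]), `rss`, `convergence`
#'   (TRUE if the optimizer reported success).
#' @export
fit_kinetic_params <- function(curves, schedules,
                               start = c(tau_r = 30, d_stim = 0.10, k_im = 0.002),
                               power_scaling = 2) {
  stopifnot(all(c("condition", "trial", "drive") %in% names(curves)))
  conds <- unique(as.character(curves$condition))
  if (!all(conds %in% names(schedules))) {
    abort("Every condition in `curves` needs a schedule in `schedules`.",
          class = "optodesens_argument_error")
  }
  obs <- split(curves, curves$condition)
  # optimize on log/logit scales so the three parameters (tens of seconds,
  # a fraction, a small rate) are comparably conditioned
  to_theta <- function(p) c(log(p[1]), stats::qlogis(p[2] / 0.9),
                            log(p[3] + 1e-8))
  from_theta <- function(th) c(exp(th[1]), 0.9 * stats::plogis(th[2]),
                               exp(th[3]))
  objective <- function(theta) {
    pv <- from_theta(theta)
    p <- kinetic_params(tau_r = pv[1], d_stim = pv[2], k_im = pv[3],
                        power_scaling = power_scaling)
    sum(map_dbl(conds, function(cn) {
      o <- obs[[cn]]
      sim <- simulate_trial_responses(schedules[[cn]], p)
      sum((o$drive - sim$drive[match(o$trial, sim$trial)])^2)
    }))
  }
  fit <- optim(to_theta(start), objective, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  pv <- from_theta(fit$par)
  list(
    params = kinetic_params(tau_r = pv[1], d_stim = pv[2], k_im = pv[3],
                            power_scaling = power_scaling),
    rss = fit$value,
    convergence = fit$convergence == 0
  )
}
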