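#' Fit a two-term exponential decay model
#'
#' Least squares of `y = a * exp(b * x) + c * exp(d * x)` against trial
#' numbers, the standard description of a response-decay curve with a fast
#' early component and a plateau (rate ~ 0). Rates `(b, d)` are profiled:
#' for fixed rates the amplitudes `(a, c)` solve a linear least-squares
#' problem, and the rate pair is optimized by Nelder-Mead from a multi-start
#' grid over `b, d` in `{-2, -0.5, -0.1, 0}`. The convergence flag is
#' honest: if no start converges, a flagged (non-converged) result is
#' returned rather than an error.
#'
#' @param x Trial numbers (numeric, >= 5 points).
#' @param y Normalized responses.
#' @param rate_grid Multi-start grid for both rates.
#' @return An object of class `decay_fit` with fields `model`,
#'   `coefficients` (`a`, `b`, `c`, `d`), `rss`, `converged`, `flags`.
#' @examples
#' x <- 1:10
#' y <- 0.3 * exp(-0.5 * x) + 0.7
#' fit <- fit_two_term_exponential(x, y)
#' coef(fit)
#' @export
fit_two_term_exponential <- function(x, y, rate_grid = c(-2, -0.5, -0.1, 0)) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) {
    abort("At least 5 points are required for a two-term exponential fit.",
          class = "optodesens_argument_error")
  }
  profile_fit <- function(b, d) {
    X <- cbind(exp(b * x), exp(d * x))
    if (any(!is.finite(X))) return(NULL)
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    beta[is.na(beta)] <- 0
    res <- y - X %*% beta
    list(a = beta[1], c = beta[2], rss = sum(res^2), rank = qrX$rank)
  }
  obj <- function(th) {
    f <- profile_fit(th[1], th[2])
    if (is.null(f)) Inf else f$rss
  }
  best <- NULL
  for (b0 in rate_grid) for (d0 in rate_grid) {
    opt <- tryCatch(
      optim(c(b0, d0), obj, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(new_decay_fit("two_term_exponential",
                         c(a = NA_real_, b = NA_real_, c = NA_real_,
                           d = NA_real_),
                         rss = NA_real_, converged = FALSE,
                         flags = "no start converged", x = x, y = y))
  }
  f <- profile_fit(best$par[1], best$par[2])
  flags <- character()
  if (f$rank < 2 || abs(best$par[1] - best$par[2]) < 1e-6) {
    flags <- c(flags, "non-unique (degenerate rates)")
  }
  new_decay_fit(
    "two_term_exponential",
    c(a = unname(f$a), b = best$par[1], c = unname(f$c), d = best$par[2]),
    rss = f$rss, converged = best$convergence == 0, flags = flags,
    x = x, y = y
  )
}

#' Fit a first-degree polynomial
#'
#' Ordinary least squares of `y` on `x`; used for the linear relation of
#' mean delta-response to ISI.
#'
#' @param x Predictor (e.g. ISI in seconds); at least two distinct values.
#' @param y Response (e.g. mean delta-response per ISI).
#' @return A `decay_fit` with coefficients `slope` and `intercept`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2) {
    abort("At least two distinct x values are required for a linear fit.",
          class = "optodesens_argument_error")
  }
  fit <- lm(y ~ x)
  new_decay_fit(
    "linear",
    c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1])),
    rss = sum(fit$residuals^2), converged = TRUE, flags = character(),
    x = x, y = y
  )
}

new_decay_fit <- function(model, coefficients, rss, converged, flags, x, y) {
  structure(
    list(model = model, coefficients = coefficients, rss = rss,
         converged = converged, flags = flags,
         data = tibble(x = x, y = y)),
    class = "decay_fit"
  )
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' Fitted values of a decay fit
#' @param object A `decay_fit`.
#' @param x Points at which to evaluate; default the fitted data's x.
#' @param ... Unused.
#' @export
predict.decay_fit <- function(object, x = object$data$x, ...) {
  cf <- object$coefficients
  if (object$model == "two_term_exponential") {
    cf[["a"]] * exp(cf[["b"]] * x) + cf[["c"]] * exp(cf[["d"]] * x)
  } else {
    cf[["intercept"]] + cf[["slope"]] * x
  }
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit: %s>%s\n", x$model,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$coefficients, 6))
  cat(sprintf("RSS: %.3g\n", x$rss))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy a decay fit into a one-row-per-term tibble
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' One-row summary of a decay fit
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `rss`, `converged`, `n`, `flags`.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(model = x$model, rss = x$rss, converged = x$converged,
         n = nrow(x$data),
         flags = if (length(x$flags)) paste(x$flags, collapse = "; ")
                 else NA_character_)
}
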