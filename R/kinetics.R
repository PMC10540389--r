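#' Pulse-phase enrichment model
#'
#' Exponential-plateau build-up of 13C enrichment during the labeling pulse,
#' constrained through the origin: delta(t) = A * (1 - exp(-k * t)). Before
#' the pulse the tissue carries no excess label, so delta(0) = 0 by
#' construction and delta(t) -> A as t -> infinity.
#'
#' @param t Hours since the start of the pulse (vector, >= 0).
#' @param A Plateau enrichment in per mil (>= 0).
#' @param k Rate constant in 1/h (> 0).
#' @return delta-13C in per mil, same length as `t`.
#' @examples
#' pulse_delta(24, A = 459.17, k = 0.01730)
#' @export
pulse_delta <- function(t, A, k) {
  stopifnot(is.numeric(t), is.numeric(A), is.numeric(k))
  if (any(t < 0)) abort("`t` must be >= 0 h (pre-pulse times are not modeled).")
  if (A < 0) abort("plateau `A` must be >= 0 per mil.")
  if (k <= 0) abort("rate `k` must be > 0 per hour.")
  A * (1 - exp(-k * t))
}

#' Chase-phase enrichment model
#'
#' One-phase exponential decay of 13C enrichment after the pulse ends at
#' `t0` (48 h): delta(t) = delta48 * exp(-k_c * (t - t0)). The decay plateau
#' is fixed at 0 per mil: with only two chase time points a free plateau is
#' unidentifiable, and fully turned-over tissue relaxes to the natural
#' reference ratio (0 per mil) by definition of the delta scale.
#'
#' @param t Hours since the start of the pulse (vector, >= `t0`).
#' @param delta48 Enrichment at the start of the chase, per mil (>= 0).
#' @param k_c Decay rate constant in 1/h (> 0).
#' @param t0 Start of the chase in hours (default 48).
#' @return delta-13C in per mil.
#' @export
chase_delta <- function(t, delta48, k_c, t0 = 48) {
  stopifnot(is.numeric(t), is.numeric(delta48), is.numeric(k_c))
  if (any(t < t0)) abort(sprintf("`t` must be >= %g h (chase phase only).", t0))
  if (delta48 < 0) abort("`delta48` must be >= 0 per mil.")
  if (k_c <= 0) abort("rate `k_c` must be > 0 per hour.")
  delta48 * exp(-k_c * (t - t0))
}

new_silksims_fit <- function(model, par, data, rss, flags = character()) {
  structure(
    list(model = model, par = par, data = data, rss = rss,
         n_points = nrow(data), flags = flags),
    class = "silksims_fit"
  )
}

#' @export
print.silksims_fit <- function(x, ...) {
  cat("<silksims_fit> model:", x$model, "\n")
  cat("  ", paste(sprintf("%s = %.6g", names(x$par), x$par), collapse = ", "), "\n")
  cat("   rss =", format(x$rss, digits = 6), " n =", x$n_points, "\n")
  if (length(x$flags)) cat("   flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the exponential-plateau pulse model
#'
#' Least-squares fit of delta(t) = A (1 - exp(-k t)) to cohort means (or
#' per-cell values) observed during the pulse phase. The origin (0, 0) is
#' appended as a data point because the delta scale is defined against
#' unlabeled tissue. With exactly two distinct positive times where
#' t2 = 2 * t1 the closed-form solution seeds the optimizer; otherwise a
#' grid of rate constants does. Fitting uses Levenberg-Marquardt
#' (minpack.lm), and is deterministic given the data.
#'
#' @param times Hours since pulse start (> 0; the origin is added internally).
#' @param deltas Observed delta-13C, per mil.
#' @return A `silksims_fit` with parameters `A` (per mil) and `k` (1/h);
#'   use [tidy()]/[glance()] to extract them as tibbles.
#' @examples
#' fit_pulse(c(24, 48), c(156, 259))
#' @export
fit_pulse <- function(times, deltas) {
  stopifnot(length(times) == length(deltas))
  if (any(times <= 0)) abort("`times` must be positive; the origin is appended internally.")
  if (length(unique(times)) < 2) abort("need >= 2 distinct positive times.")
  flags <- character()
  o <- order(times)
  if (is.unsorted(deltas[o])) flags <- c(flags, "non_increasing_data")

  dat <- tibble(t = c(0, times), delta = c(0, deltas))
  start <- pulse_start_values(times, deltas)
  if (max(abs(deltas)) < sqrt(.Machine$double.eps)) {
    return(new_silksims_fit("pulse_plateau", c(A = 0, k = start["k"][[1]]),
                            dat, rss = 0, flags = c(flags, "degenerate")))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(delta ~ A * (1 - exp(-k * t)), data = dat,
                      start = as.list(start),
                      lower = c(A = 0, k = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_silksims_fit("pulse_plateau", start, dat, rss = NA_real_,
                            flags = c(flags, "fit_failed")))
  }
  par <- coef(fit)
  new_silksims_fit("pulse_plateau", c(A = unname(par["A"]), k = unname(par["k"])),
                   dat, rss = sum(resid(fit)^2), flags = flags)
}

# Closed-form two-point seed: with observations (t1, d1) and (2 t1, d2),
# x = exp(-k t1) satisfies 1 + x = d2/d1, so k = -log(d2/d1 - 1)/t1 and
# A = d1 / (1 - x). Falls back to a coarse grid otherwise.
pulse_start_values <- function(times, deltas) {
  ts <- sort(unique(times))
  if (length(ts) == 2 && isTRUE(all.equal(ts[2], 2 * ts[1]))) {
    d1 <- mean(deltas[times == ts[1]])
    d2 <- mean(deltas[times == ts[2]])
    x <- d2 / d1 - 1
    if (is.finite(x) && x > 0 && x < 1) {
      return(c(A = d1 / (1 - x), k = -log(x) / ts[1]))
    }
  }
  ks <- 10^seq(-4, 0, length.out = 25)
  sse <- vapply(ks, function(k) {
    w <- 1 - exp(-k * times)
    A <- max(0, sum(w * deltas) / sum(w^2))
    sum((deltas - A * w)^2)
  }, numeric(1))
  k0 <- ks[which.min(sse)]
  A0 <- max(max(deltas), 1e-6)
  c(A = A0, k = k0)
}

#' Fit the one-phase exponential chase decay
#'
#' Fits delta(t) = delta48 * exp(-k_c (t - 48)) to chase-phase observations.
#' With exactly two points the closed form
#' k_c = log(d1/d2) / (t2 - t1), delta48 = d1 * exp(k_c (t1 - 48))
#' is returned directly; with more points it seeds a Levenberg-Marquardt
#' refinement.
#'
#' @param times Hours (>= 48).
#' @param deltas Observed delta-13C, per mil (> 0).
#' @param t0 Chase start, hours (default 48).
#' @return A `silksims_fit` with parameters `delta48` (per mil) and `k_c`
#'   (1/h). `glance()` reports the half-life log(2)/k_c.
#' @examples
#' fit_chase(c(48, 96), c(259, 156))
#' @export
fit_chase <- function(times, deltas, t0 = 48) {
  stopifnot(length(times) == length(deltas))
  if (any(times < t0)) abort(sprintf("`times` must be >= %g h.", t0))
  if (any(deltas <= 0)) abort("chase `deltas` must be positive per mil values.")
  if (length(times) < 2) abort("need >= 2 chase points.")
  flags <- character()
  dat <- tibble(t = times, delta = deltas)

  if (length(times) == 2) {
    o <- order(times)
    t1 <- times[o[1]]; t2 <- times[o[2]]
    d1 <- deltas[o[1]]; d2 <- deltas[o[2]]
    if (isTRUE(all.equal(d1, d2))) {
      return(new_silksims_fit("one_phase_decay",
                              c(delta48 = d1, k_c = 0), dat, rss = 0,
                              flags = c(flags, "degenerate")))
    }
    k_c <- log(d1 / d2) / (t2 - t1)
    if (k_c <= 0) flags <- c(flags, "non_decreasing_data")
    delta48 <- d1 * exp(k_c * (t1 - t0))
    return(new_silksims_fit("one_phase_decay",
                            c(delta48 = delta48, k_c = k_c), dat, rss = 0,
                            flags = flags))
  }

  # log-linear seed, then refine on the original scale
  lf <- stats::lm(log(deltas) ~ I(times - t0))
  k0 <- max(1e-8, -unname(coef(lf)[2]))
  d0 <- exp(unname(coef(lf)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(delta ~ delta48 * exp(-k_c * (t - t0)), data = dat,
                      start = list(delta48 = d0, k_c = k0),
                      lower = c(delta48 = 0, k_c = 0)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_silksims_fit("one_phase_decay", c(delta48 = d0, k_c = k0),
                            dat, rss = NA_real_, flags = c(flags, "fit_failed")))
  }
  par <- coef(fit)
  new_silksims_fit("one_phase_decay",
                   c(delta48 = unname(par["delta48"]), k_c = unname(par["k_c"])),
                   dat, rss = sum(resid(fit)^2), flags = flags)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinetics fit
#'
#' @param x A `silksims_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @export
tidy.silksims_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = unname(x$par))
}

#' One-row summary of a kinetics fit
#'
#' @param x A `silksims_fit`.
#' @param ... Unused.
#' @return A tibble with the model name, residual sum of squares, number of
#'   points, flags, and (for decay fits) the half-life in hours.
#' @export
glance.silksims_fit <- function(x, ...) {
  half_life <- if (x$model == "one_phase_decay" && x$par[["k_c"]] > 0) {
    log(2) / x$par[["k_c"]]
  } else {
    NA_real_
  }
  tibble(model = x$model, rss = x$rss, n_points = x$n_points,
         half_life_h = half_life,
         flags = paste(x$flags, collapse = ";"))
}

#' Predicted enrichment from a kinetics fit
#'
#' @param object A `silksims_fit`.
#' @param t Hours at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of delta-13C, per mil.
#' @export
predict.silksims_fit <- function(object, t, ...) {
  p <- object$par
  switch(object$model,
    pulse_plateau = p[["A"]] * (1 - exp(-p[["k"]] * t)),
    one_phase_decay = p[["delta48"]] * exp(-pmax(0, p[["k_c"]]) * (t - 48)),
    abort(paste("unknown model", object$model))
  )
}
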