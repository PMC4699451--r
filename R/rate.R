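#' Rate functions on a uniform grid
#'
#' A `rate_function` holds a non-negative intensity \eqn{\lambda(t)} sampled
#' on a uniform time grid. Between grid points it is interpreted as
#' piecewise-linear; outside the grid it extrapolates as a constant equal to
#' the nearest endpoint value.
#'
#' @param grid strictly increasing, uniformly spaced times (seconds).
#' @param values non-negative intensities (per second), same length as `grid`.
#' @return An object of class `rate_function`.
#' @export
rate_function <- function(grid, values) {
  grid <- as.numeric(grid); values <- as.numeric(values)
  if (length(grid) != length(values) || length(grid) < 2L) {
    stop("grid and values must have equal length >= 2")
  }
  steps <- diff(grid)
  if (any(steps <= 0)) stop("grid must be strictly increasing")
  if (diff(range(steps)) > 1e-8 * mean(steps)) stop("grid must be uniform")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("rate values must be finite and non-negative")
  }
  structure(list(grid = grid, values = values), class = "rate_function")
}

#' @export
print.rate_function <- function(x, ...) {
  cat(sprintf("rate_function: %d points on [%.4g, %.4g], mean rate %.4g /s\n",
              length(x$grid), x$grid[1L], x$grid[length(x$grid)],
              mean(x$values)))
  invisible(x)
}

#' Evaluate a rate function
#'
#' @param rate a [rate_function].
#' @param t times at which to evaluate (constant extrapolation outside the
#'   grid).
#' @return Numeric vector of intensities.
#' @export
eval_rate <- function(rate, t) {
  stopifnot(inherits(rate, "rate_function"))
  approx(rate$grid, rate$values, xout = t, rule = 2)$y
}

#' Density-function estimate of the release rate
#'
#' Replaces each spike by a unit-mass Gaussian kernel of standard deviation
#' `bandwidth` and sums:
#' \eqn{\lambda(t) = \sum_n \omega(t - t_n)}. The integral of the estimate
#' over `[0, T]` equals the spike count up to the kernel mass leaking past
#' the interval boundaries (no boundary correction is applied).
#'
#' @param seq a [spike_sequence] with at least one event.
#' @param bandwidth kernel standard deviation, seconds. The default (10 s)
#'   suits experimental-scale trains with rates near 1 Hz over several
#'   hundred seconds.
#' @param grid_step grid spacing, seconds; defaults to `bandwidth / 10`.
#' @return A [rate_function] whose grid covers `[0, T]`.
#' @export
estimate_rate <- function(seq, bandwidth = 10, grid_step = bandwidth / 10) {
  stopifnot(inherits(seq, "spike_sequence"))
  if (length(seq$times) < 1L) stop("need at least one event to estimate a rate")
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be positive")
  if (!is.numeric(grid_step) || grid_step <= 0) stop("grid_step must be positive")
  n_step <- ceiling(seq$duration / grid_step)
  grid <- seq(0, by = grid_step, length.out = n_step + 1L)
  grid[n_step + 1L] <- max(grid[n_step + 1L], seq$duration)
  # grid must stay uniform: stretch the step marginally if T is not a multiple
  grid <- seq(0, grid[n_step + 1L], length.out = n_step + 1L)
  vals <- numeric(length(grid))
  chunks <- split(seq$times, ceiling(seq_along(seq$times) / 2000L))
  for (ch in chunks) {
    vals <- vals + colSums(dnorm(outer(ch, grid, "-"), sd = bandwidth))
  }
  rate_function(grid, vals)
}

#' Cumulative intensity (time-rescaling transform)
#'
#' \eqn{\Lambda(t) = \int_0^t \lambda(s)\,ds} by the trapezoid rule on the
#' rate grid, with exact linear-in-between handling of off-grid `t`.
#'
#' @param rate a [rate_function].
#' @param t evaluation time(s), within the grid range.
#' @return Numeric vector of cumulative intensities (dimensionless counts).
#' @export
cumulative_intensity <- function(rate, t) {
  stopifnot(inherits(rate, "rate_function"))
  g <- rate$grid; v <- rate$values
  if (any(t < g[1L] - 1e-12) || any(t > g[length(g)] + 1e-12)) {
    stop("t outside the rate-function domain [",
         g[1L], ", ", g[length(g)], "]")
  }
  t <- pmin(pmax(t, g[1L]), g[length(g)])
  Lam <- c(pracma::cumtrapz(g, v))
  i <- findInterval(t, g, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(g) - 1L)
  frac <- t - g[i]
  vi <- v[i] + (v[i + 1L] - v[i]) * frac / (g[i + 1L] - g[i])
  Lam[i] + frac * (v[i] + vi) / 2
}

#' Time-rescale a spike sequence
#'
#' Maps event times through the cumulative intensity of `rate`:
#' \eqn{\tau_i = \Lambda(t_i)}, with rescaled interspike times
#' \eqn{u_i = \Lambda(t_i) - \Lambda(t_{i-1})}. When the rate was estimated
#' from the sequence itself, the rescaled sequence has unit rate and
#' `mean(u)` is approximately 1.
#'
#' @param seq a [spike_sequence].
#' @param rate a [rate_function], strictly positive over the span of the
#'   spikes.
#' @return An object of class `rescaled_sequence` with elements
#'   `rescaled_times` (\eqn{\tau_i}), `u` (rescaled interspikes),
#'   `duration` (\eqn{\Lambda(T)}) and `source` (provenance).
#' @export
rescale_sequence <- function(seq, rate) {
  stopifnot(inherits(seq, "spike_sequence"), inherits(rate, "rate_function"))
  span <- rate$grid >= seq$times[1L] & rate$grid <= seq$times[length(seq$times)]
  if (any(rate$values[span] <= 0)) {
    stop("degenerate rescaling: rate vanishes over an interval containing spikes")
  }
  tau <- cumulative_intensity(rate, seq$times)
  structure(list(rescaled_times = tau,
                 u = diff(tau),
                 duration = cumulative_intensity(rate, min(seq$duration,
                                                           max(rate$grid))),
                 source = seq$label),
            class = "rescaled_sequence")
}

#' @export
print.rescaled_sequence <- function(x, ...) {
  cat(sprintf("rescaled_sequence: %d events, mean rescaled interspike %.4g\n",
              length(x$rescaled_times), mean(x$u)))
  invisible(x)
}

#' Convert a rescaled sequence to a spike sequence
#'
#' @param x a `rescaled_sequence`.
#' @return A [spike_sequence] in rescaled (dimensionless) time.
#' @export
as_spike_sequence <- function(x) {
  stopifnot(inherits(x, "rescaled_sequence"))
  spike_sequence(x$rescaled_times, duration = max(x$duration,
                                                  max(x$rescaled_times)),
                 label = paste0(x$source, " (rescaled)"))
}

#' Map a unit-rate sequence back through a rate function
#'
#' The inverse of the time-rescaling transform: given rescaled times
#' \eqn{\tau_i}, returns \eqn{t_i = \Lambda^{-1}(\tau_i)} by monotone
#' interpolation of the trapezoid cumulative intensity. Used by the
#' synthetic generator to impose a target rate profile on a unit-rate
#' renewal train.
#'
#' @param unit_seq a [spike_sequence] in rescaled time.
#' @param rate a strictly positive [rate_function] with
#'   \eqn{\Lambda(T) \ge \max \tau_i}.
#' @return A [spike_sequence] in original time.
#' @export
inverse_rescale <- function(unit_seq, rate) {
  stopifnot(inherits(unit_seq, "spike_sequence"), inherits(rate, "rate_function"))
  if (any(rate$values <= 0)) {
    stop("rate must be strictly positive for inversion")
  }
  Lam <- c(pracma::cumtrapz(rate$grid, rate$values))
  tau <- unit_seq$times
  if (max(tau) > Lam[length(Lam)] + 1e-12) {
    stop("rate function exhausted: max rescaled time ", max(tau),
         " exceeds total intensity ", Lam[length(Lam)])
  }
  t_new <- approx(Lam, rate$grid, xout = tau, ties = "ordered")$y
  dur <- if (unit_seq$duration <= Lam[length(Lam)]) {
    approx(Lam, rate$grid, xout = unit_seq$duration, ties = "ordered")$y
  } else {
    rate$grid[length(rate$grid)]
  }
  spike_sequence(t_new, duration = max(dur, t_new[length(t_new)]),
                 label = paste0(unit_seq$label, " (inverse-rescaled)"))
}

#' Logistic rate model
#'
#' \eqn{r(t) = r_0 / (1 + e^{-\beta_r (t - \mu_r)}) + r_f}: a plateau
#' followed by an S-shaped decay when \eqn{\beta_r < 0}. The sign of
#' \eqn{\beta_r} is unconstrained so both growing and decaying rates are
#' representable; which sign was fitted is part of the result.
#'
#' @param r0 initial-rate amplitude, per second.
#' @param rf final rate, per second (non-negative).
#' @param beta_r decay constant, per second (either sign).
#' @param mu_r midpoint time, seconds.
#' @return An object of class `logistic_rate_params`.
#' @export
logistic_rate_params <- function(r0, rf, beta_r, mu_r) {
  if (rf < 0) stop("rf must be non-negative")
  if (r0 + rf < 0) stop("r0 + rf must be non-negative")
  structure(list(r0 = r0, rf = rf, beta_r = beta_r, mu_r = mu_r),
            class = "logistic_rate_params")
}

#' Evaluate the logistic rate model
#'
#' @param params a [logistic_rate_params].
#' @param t times, seconds.
#' @return Rate values, per second.
#' @export
logistic_rate <- function(params, t) {
  params$r0 / (1 + exp(-params$beta_r * (t - params$mu_r))) + params$rf
}

#' Fit the logistic rate model to an estimated rate
#'
#' Least squares on the sampled rate curve via Levenberg-Marquardt, with a
#' deterministic start (the logistic is multimodal in its parameters):
#' amplitude and offset from the rate range, midpoint from the half-range
#' crossing, decay-constant magnitude from the quartile-crossing spread and
#' its sign from the end-to-end slope.
#'
#' @param rate a [rate_function] with at least 10 grid points.
#' @return A [logistic_rate_params] with attributes `sse` (residual sum of
#'   squares) and `convergence` (optimizer message).
#' @export
fit_logistic_rate <- function(rate) {
  stopifnot(inherits(rate, "rate_function"))
  g <- rate$grid; v <- rate$values
  if (length(g) < 10L) stop("need at least 10 grid points")
  rng <- range(v)
  r0_0 <- max(rng[2L] - rng[1L], 1e-8)
  rf_0 <- rng[1L]
  half <- rf_0 + r0_0 / 2
  # the estimated rate can wobble around the half level, so both the first
  # and the last crossing (and the grid midpoint) are tried as midpoints
  crossing <- which(diff(sign(v - half)) != 0)
  mu_cands <- unique(c(g[min(c(crossing, length(g)))],
                       g[max(c(crossing, 1L))],
                       g[ceiling(length(g) / 2)]))
  q1 <- g[which.min(abs(v - (rf_0 + 0.25 * r0_0)))]
  q3 <- g[which.min(abs(v - (rf_0 + 0.75 * r0_0)))]
  spread <- max(abs(q3 - q1), g[2L] - g[1L])
  beta_base <- 2.197 / spread * sign(v[length(v)] - v[1L] + 1e-30)
  resid_fn <- function(par) {
    params <- list(r0 = par[1L], rf = par[2L], beta_r = par[3L], mu_r = par[4L])
    logistic_rate(params, g) - v
  }
  fit <- NULL
  for (mu_0 in mu_cands) {
    for (bscale in c(1, 0.25, 4)) {
      cand <- tryCatch(
        minpack.lm::nls.lm(par = c(r0_0, rf_0, beta_base * bscale, mu_0),
                           fn = resid_fn, lower = c(-Inf, 0, -Inf, -Inf),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 1000, maxfev = 5000)),
        error = function(e) NULL)
      if (is.null(cand) || !cand$info %in% 1:4) next
      if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
    }
  }
  if (is.null(fit)) {
    stop("logistic rate fit did not converge from any deterministic start")
  }
  out <- logistic_rate_params(fit$par[1L], max(fit$par[2L], 0),
                              fit$par[3L], fit$par[4L])
  attr(out, "sse") <- sum(fit$fvec^2)
  attr(out, "convergence") <- fit$message
  out
}

#' @export
print.logistic_rate_params <- function(x, ...) {
  cat(sprintf("logistic rate: r0=%.4g /s, rf=%.4g /s, beta_r=%.4g /s, mu_r=%.4g s\n",
              x$r0, x$rf, x$beta_r, x$mu_r))
  invisible(x)
}
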