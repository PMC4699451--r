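#' Summary statistics of interspike times or counts
#'
#' Mean, median, unbiased variance, standard deviation and coefficient of
#' variation; for count series additionally the index of dispersion
#' (Fano factor) \eqn{\sigma^2/\mu}, which is 1 for a Poisson process and
#' below 1 for regular (underdispersed) trains.
#'
#' @param x an `interspike_times` vector, a `count_series`, or a plain
#'   numeric vector with at least 2 values.
#' @return An object of class `summary_stats`.
#' @export
summary_stats <- function(x) {
  is_counts <- inherits(x, "count_series")
  v <- if (is_counts) x$counts else unclass(x)
  if (length(v) < 2L) stop("need at least 2 values")
  m <- mean(v); s2 <- var(v)
  out <- list(mean = m, median = median(v), variance = s2, sd = sqrt(s2),
              cv = if (m > 0) sqrt(s2) / m else NA_real_)
  if (is_counts) out$dispersion <- if (m > 0) s2 / m else NA_real_
  structure(out, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("mean %.4g, median %.4g, var %.4g, sd %.4g, CV %.4g",
              x$mean, x$median, x$variance, x$sd, x$cv))
  if (!is.null(x$dispersion)) cat(sprintf(", dispersion %.4g", x$dispersion))
  cat("\n")
  invisible(x)
}

#' Interspike-time histogram bin width
#'
#' For a sequence with interspike mean \eqn{\mu}, standard deviation
#' \eqn{\sigma} and spike count \eqn{N}, the bin width is
#' \eqn{h = (\mu + 2.85\sigma)/\sqrt{N}} for \eqn{N < 1000} and the scaled
#' Scott's-rule blend
#' \eqn{h = (\mu + 2.85\sigma)\,(1/(2\sqrt{N}) + 1/(2N^{1/3}))} for larger
#' sequences.
#'
#' @param mu interspike mean, seconds.
#' @param sigma interspike standard deviation, seconds.
#' @param n number of spikes in the sequence.
#' @return Bin width in seconds.
#' @export
interspike_bin_width <- function(mu, sigma, n) {
  stopifnot(mu > 0, sigma >= 0, n >= 2)
  a <- mu + 2.85 * sigma
  if (n < 1000) a / sqrt(n) else a * (1 / (2 * sqrt(n)) + 1 / (2 * n^(1 / 3)))
}

#' Equal-width interspike-time histogram
#'
#' Bins run from 0 to `ceiling(max/h) * h` in steps of `h`; values at a bin
#' edge belong to the left (lower) bin, i.e. bins are `(a, a+h]`, natural
#' for strictly positive interspike times. The `density` column normalizes
#' the counts to unit area.
#'
#' @param x positive values (an `interspike_times` vector or plain numeric).
#' @param h bin width.
#' @return An object of class `histogram_data` with `bin_edges`, `counts`,
#'   `density` and `mids`.
#' @export
make_histogram <- function(x, h) {
  v <- unclass(x)
  stopifnot(is.numeric(v), length(v) >= 1L, all(v > 0), h > 0)
  nb <- max(ceiling(max(v) / h), 1L)
  edges <- seq(0, by = h, length.out = nb + 1L)
  idx <- pmin(pmax(ceiling(v / h), 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges = edges, counts = counts,
                 density = counts / (sum(counts) * h),
                 mids = edges[-1L] - h / 2),
            class = "histogram_data")
}

#' @export
print.histogram_data <- function(x, ...) {
  cat(sprintf("histogram_data: %d bins of width %.4g, %d observations\n",
              length(x$counts), x$bin_edges[2L] - x$bin_edges[1L],
              sum(x$counts)))
  invisible(x)
}

#' Frequency table of a count series
#'
#' The empirical pmf of window counts: frequencies at `k = 0, 1, ...,
#' max(count)`.
#'
#' @param x a `count_series` or a non-negative integer vector.
#' @return An object of class `count_histogram` with `k`, `counts`, `prop`
#'   and the count `window` (if known).
#' @export
make_count_histogram <- function(x) {
  window <- NA_real_
  v <- if (inherits(x, "count_series")) {
    window <- x$window
    x$counts
  } else x
  stopifnot(is.numeric(v), length(v) >= 1L, all(v >= 0))
  kmax <- max(v)
  counts <- tabulate(v + 1L, nbins = kmax + 1L)
  structure(list(k = 0:kmax, counts = counts, prop = counts / sum(counts),
                 window = window),
            class = "count_histogram")
}

# ---- candidate probability models -----------------------------------------

#' Candidate interspike and count models
#'
#' Thin, explicitly named wrappers around the model densities the analysis
#' compares: the exponential interspike density and Poisson count pmf of a
#' purely random (Poisson) process, the two-parameter gamma interspike
#' density (shape `p`, scale `theta`; mean \eqn{p\theta}), the gamma-count
#' pmf of window counts under gamma-renewal interspikes, and the log-normal
#' density.
#'
#' The gamma-count pmf is
#' \eqn{P(k) = G(pk, \beta T) - G(pk + p, \beta T)} with
#' \eqn{G(a, x)} the regularized lower incomplete gamma function,
#' \eqn{\beta = 1/\theta}, and the convention \eqn{G(0, x) = 1} (so the pmf
#' telescopes to total mass 1 and reduces exactly to the Poisson pmf at
#' `p = 1`).
#'
#' @param dt interspike time(s), seconds.
#' @param lambda rate, per second.
#' @param k non-negative integer count(s).
#' @param lambdaT dimensionless Poisson mean (rate times window).
#' @param p gamma shape.
#' @param theta gamma scale, seconds.
#' @param beta gamma rate `1/theta`, per second.
#' @param T_window count window, seconds.
#' @param log_mean,log_sd log-normal parameters.
#' @return Densities or probabilities.
#' @name candidate_models
NULL

#' @rdname candidate_models
#' @export
exponential_pdf <- function(dt, lambda) {
  stopifnot(lambda > 0, all(dt >= 0))
  dexp(dt, rate = lambda)
}

#' @rdname candidate_models
#' @export
poisson_pmf <- function(k, lambdaT) {
  stopifnot(lambdaT > 0, all(k >= 0), all(k == round(k)))
  dpois(k, lambdaT)
}

#' @rdname candidate_models
#' @export
gamma_pdf <- function(dt, p, theta) {
  stopifnot(p > 0, theta > 0)
  dgamma(dt, shape = p, scale = theta)
}

#' @rdname candidate_models
#' @export
gamma_count_pmf <- function(k, p, beta, T_window) {
  stopifnot(p > 0, beta > 0, T_window > 0, all(k >= 0), all(k == round(k)))
  x <- beta * T_window
  # pgamma(x, shape = 0) is 1, which is exactly the G(0, x) := 1 convention
  pgamma(x, shape = p * k) - pgamma(x, shape = p * k + p)
}

#' @rdname candidate_models
#' @export
lognormal_pdf <- function(dt, log_mean, log_sd) {
  stopifnot(log_sd > 0)
  dlnorm(dt, meanlog = log_mean, sdlog = log_sd)
}

# ---- least-squares model fitting ------------------------------------------

.fit_families <- c("exponential", "gamma", "lognormal", "poisson", "gamma_count")

.moment_from_hist <- function(hist) {
  h <- hist$bin_edges[2L] - hist$bin_edges[1L]
  m1 <- sum(hist$mids * hist$density) * h
  m2 <- sum(hist$mids^2 * hist$density) * h
  c(mean = m1, var = max(m2 - m1^2, 1e-12))
}

.model_curve <- function(family, par, xs, window = NULL) {
  switch(family,
    exponential = exponential_pdf(xs, par[1L]),
    gamma       = gamma_pdf(xs, par[1L], par[2L]),
    lognormal   = lognormal_pdf(xs, par[1L], par[2L]),
    poisson     = poisson_pmf(xs, par[1L]),
    gamma_count = gamma_count_pmf(xs, par[1L], 1 / par[2L], window))
}

.lsq_fit <- function(start, resid_fn, lower) {
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4) {
    stop("histogram fit did not converge (", fit$message,
         "); start: ", paste(signif(start, 5), collapse = ", "),
         "; last: ", paste(signif(fit$par, 5), collapse = ", "))
  }
  fit
}

.fit_result <- function(family, params, sse, observed) {
  sst <- sum((observed - mean(observed))^2)
  r2 <- 1 - sse / sst
  clamped <- FALSE
  if (!is.finite(r2) || r2 < 0) {
    warning("negative/undefined R^2 clamped to 0 for family ", family)
    r2 <- 0; clamped <- TRUE
  }
  structure(list(family = family, params = params, sse = sse,
                 r_squared = min(r2, 1), r2_clamped = clamped),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: %s | SSE %.4g, R^2 %.4g\n", x$family,
              paste(names(x$params), signif(unlist(x$params), 4),
                    sep = "=", collapse = ", "),
              x$sse, x$r_squared))
  invisible(x)
}

#' Least-squares fit of a model family to a histogram
#'
#' Nonlinear least squares of the family's density (pdf evaluated at bin
#' centers for continuous families; pmf at integer counts for the count
#' families) against the density-normalized histogram, unweighted and
#' including empty bins. Starts are moment estimates from the histogram
#' itself, which keep the gamma fits in the right basin; for the gamma
#' families the exponential-equivalent start (`p = 1`) is also tried and the
#' lower-SSE solution kept, so the nested exponential/Poisson solution is
#' never missed.
#'
#' @param hist a `histogram_data` (continuous families) or a
#'   `count_histogram` (count families).
#' @param family one of `"exponential"`, `"gamma"`, `"lognormal"`,
#'   `"poisson"`, `"gamma_count"`.
#' @param window count window, required for `"gamma_count"` (taken from the
#'   histogram when it carries one).
#' @return A `fit_result`: family, named parameters, SSE and
#'   \eqn{R^2 = 1 - SSE/SST}.
#' @export
fit_histogram <- function(hist, family = .fit_families, window = NULL) {
  family <- match.arg(family)
  discrete <- family %in% c("poisson", "gamma_count")
  if (discrete) {
    stopifnot(inherits(hist, "count_histogram"))
    if (is.null(window)) window <- hist$window
    if (family == "gamma_count" && (is.null(window) || is.na(window))) {
      stop("gamma_count fit requires the count window")
    }
    xs <- hist$k; y <- hist$prop
    m1 <- sum(xs * y); v1 <- max(sum(xs^2 * y) - m1^2, 1e-12)
  } else {
    stopifnot(inherits(hist, "histogram_data"))
    if (sum(hist$counts > 0) < 3L) stop("need at least 3 non-empty bins")
    xs <- hist$mids; y <- hist$density
    mom <- .moment_from_hist(hist)
    m1 <- unname(mom["mean"]); v1 <- unname(mom["var"])
  }
  starts <- switch(family,
    exponential = list(c(lambda = 1 / m1)),
    gamma       = list(c(p = unname(m1^2 / v1), theta = unname(v1 / m1)),
                       c(p = 1, theta = unname(m1))),
    lognormal   = list(c(log_mean = unname(log(m1) - log(1 + v1 / m1^2) / 2),
                         log_sd = unname(sqrt(log(1 + v1 / m1^2))))),
    poisson     = list(c(lambdaT = max(m1, 1e-6))),
    gamma_count = list(c(p = unname(max(m1 / v1, 0.05)),
                         theta = unname(window / max(m1, 1e-6) /
                                          max(m1 / v1, 0.05))),
                       c(p = 1, theta = unname(window / max(m1, 1e-6)))))
  lower <- rep(1e-8, length(starts[[1L]]))
  if (family == "lognormal") lower <- c(-Inf, 1e-8)
  resid_fn <- function(par) .model_curve(family, par, xs, window) - y
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(.lsq_fit(s, resid_fn, lower), error = function(e) e)
    if (inherits(fit, "error")) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) stop("histogram fit failed from all starts for ", family)
  par <- setNames(as.list(best$par), names(starts[[1L]]))
  out <- .fit_result(family, par, sum(best$fvec^2), y)
  out$window <- if (discrete) window else NULL
  out
}

#' Combined interspike + count fit with shared parameters
#'
#' Fits one parameter set to both histograms of the same sequence by
#' minimizing the summed SSE: `poisson_pair` shares a single rate
#' \eqn{\lambda} between the exponential interspike density and the Poisson
#' count pmf; `gamma_pair` shares \eqn{(p, \theta)} between the gamma
#' density and the gamma-count pmf (\eqn{\beta = 1/\theta}). Both histograms
#' enter density-normalized so the two residual blocks are commensurate.
#'
#' @param isi_hist a `histogram_data` of interspike times.
#' @param count_hist a `count_histogram` from the same sequence.
#' @param model `"gamma_pair"` or `"poisson_pair"`.
#' @param window the count window \eqn{\Delta T} (defaults to the one the
#'   count histogram carries).
#' @return A `fit_result` with per-block SSE components in `$components`.
#' @export
combined_fit <- function(isi_hist, count_hist,
                         model = c("gamma_pair", "poisson_pair"),
                         window = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(isi_hist, "histogram_data"),
            inherits(count_hist, "count_histogram"))
  if (is.null(window)) window <- count_hist$window
  if (is.null(window) || is.na(window)) stop("count window must be known")
  xs_i <- isi_hist$mids; y_i <- isi_hist$density
  xs_k <- count_hist$k; y_k <- count_hist$prop
  mom <- .moment_from_hist(isi_hist)
  if (model == "poisson_pair") {
    resid_fn <- function(par) c(exponential_pdf(xs_i, par[1L]) - y_i,
                                poisson_pmf(xs_k, par[1L] * window) - y_k)
    starts <- list(c(lambda = unname(1 / mom["mean"])))
    lower <- 1e-8
  } else {
    resid_fn <- function(par) {
      c(gamma_pdf(xs_i, par[1L], par[2L]) - y_i,
        gamma_count_pmf(xs_k, par[1L], 1 / par[2L], window) - y_k)
    }
    starts <- list(c(p = unname(mom["mean"]^2 / mom["var"]),
                     theta = unname(mom["var"] / mom["mean"])),
                   c(p = 1, theta = unname(mom["mean"])))
    lower <- c(1e-8, 1e-8)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(.lsq_fit(s, resid_fn, lower), error = function(e) e)
    if (inherits(fit, "error")) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) stop("combined fit failed from all starts for ", model)
  par <- setNames(as.list(best$par), names(starts[[1L]]))
  n_i <- length(y_i)
  out <- .fit_result(model, par, sum(best$fvec^2), c(y_i, y_k))
  out$components <- c(isi = sum(best$fvec[seq_len(n_i)]^2),
                      count = sum(best$fvec[-seq_len(n_i)]^2))
  out$window <- window
  out
}

#' Full renewal-statistics report for a spike sequence
#'
#' Runs the whole analysis chain on one sequence: interspike summary
#' statistics, the prescribed-bin-width interspike histogram, window counts
#' at \eqn{\Delta T = 4\mu} (or a caller-supplied window, e.g. 4.0 for
#' rescaled sequences), the exponential/Poisson and gamma/gamma-count fits
#' (per histogram and combined), \eqn{R^2} values and the dispersion index.
#'
#' @param seq a [spike_sequence] with at least 100 events.
#' @param window count window; default \eqn{4\mu} with \eqn{\mu} the
#'   interspike mean.
#' @return An object of class `model_report` (a nested list, JSON-ready).
#' @export
model_report <- function(seq, window = NULL) {
  stopifnot(inherits(seq, "spike_sequence"))
  if (length(seq$times) < 100L) stop("need at least 100 events")
  isi <- interspike_times(seq)
  st <- summary_stats(isi)
  h <- interspike_bin_width(st$mean, st$sd, length(seq$times))
  isi_hist <- make_histogram(isi, h)
  if (is.null(window)) window <- 4 * st$mean
  cs <- spike_counts(seq, window)
  cst <- summary_stats(cs)
  count_hist <- make_count_histogram(cs)
  fits <- list(
    exponential = fit_histogram(isi_hist, "exponential"),
    gamma       = fit_histogram(isi_hist, "gamma"),
    poisson     = fit_histogram(count_hist, "poisson"),
    gamma_count = fit_histogram(count_hist, "gamma_count", window = window),
    poisson_pair = combined_fit(isi_hist, count_hist, "poisson_pair", window),
    gamma_pair   = combined_fit(isi_hist, count_hist, "gamma_pair", window)
  )
  structure(list(n_spikes = length(seq$times),
                 duration = seq$duration,
                 label = seq$label,
                 stats_isi = unclass(st),
                 binning = list(h = h, window = window),
                 stats_counts = unclass(cst),
                 dispersion = cst$dispersion,
                 isi_hist = unclass(isi_hist),
                 count_hist = unclass(count_hist),
                 fits = lapply(fits, unclass)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model_report: %d spikes, ISI mean %.4g, dispersion %.4g\n",
              x$n_spikes, x$stats_isi$mean, x$dispersion))
  cat(sprintf("  gamma fit: p=%.4g, theta=%.4g (R^2 %.3f)\n",
              x$fits$gamma$params$p, x$fits$gamma$params$theta,
              x$fits$gamma$r_squared))
  cat(sprintf("  exponential fit: lambda=%.4g (R^2 %.3f)\n",
              x$fits$exponential$params$lambda,
              x$fits$exponential$r_squared))
  invisible(x)
}
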