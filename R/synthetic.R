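#' Gamma-renewal spike train
#'
#' Event times are cumulative sums of i.i.d. Gamma(shape `p`, scale
#' `theta`) interspike draws: the stationary renewal process the analysis
#' pipeline assumes for sustained release. `p = 1` gives a homogeneous
#' Poisson process; `p > 1` gives an underdispersed (more regular) train.
#'
#' @param p gamma shape (> 0).
#' @param theta gamma scale, seconds (> 0); mean interspike is `p * theta`.
#' @param n_spikes number of events (>= 2).
#' @param seed optional RNG seed.
#' @return A [spike_sequence].
#' @export
generate_gamma_renewal <- function(p, theta, n_spikes, seed = NULL) {
  stopifnot(p > 0, theta > 0, n_spikes >= 2)
  if (!is.null(seed)) set.seed(seed)
  times <- cumsum(rgamma(n_spikes, shape = p, scale = theta))
  spike_sequence(times, label = sprintf("gamma renewal p=%.3g theta=%.3g",
                                        p, theta))
}

#' Spike train with gamma interspikes under a logistic decaying rate
#'
#' Emulates the structure of sustained-release recordings: a unit-rate
#' gamma-renewal train (interspikes Gamma(`p`, 1/`p`), unit mean) is mapped
#' through the inverse cumulative intensity of a logistic rate profile
#' (plateau followed by an S-shaped decay). The estimated rate of the
#' output tracks the logistic curve, and time-rescaling it by that rate
#' recovers the gamma interspike statistics.
#'
#' The default conditions are one plausible recording: initial rate
#' 2 Hz decaying to 0.2 Hz around `mu_r = 400` s (a ~7 min plateau),
#' shape `p = 1.6`, 900 spikes.
#'
#' @param params a [logistic_rate_params]; the rate must stay strictly
#'   positive (`rf > 0` or a long plateau) so the needed cumulative
#'   intensity is reachable.
#' @param p gamma shape of the rescaled interspikes.
#' @param n_spikes number of events.
#' @param seed optional RNG seed.
#' @param grid_step rate-grid resolution, seconds.
#' @return A [spike_sequence]; attribute `true_params` records the inputs.
#' @export
generate_inhomogeneous_sequence <- function(params = logistic_rate_params(2, 0.2, -0.05, 400),
                                            p = 1.6, n_spikes = 900,
                                            seed = NULL, grid_step = 0.5) {
  stopifnot(inherits(params, "logistic_rate_params"), p > 0, n_spikes >= 2)
  if (!is.null(seed)) set.seed(seed)
  u <- rgamma(n_spikes, shape = p, rate = p)  # unit-mean interspikes
  tau <- cumsum(u)
  target <- tau[n_spikes]
  # extend the horizon until the cumulative intensity covers the train
  horizon <- max(2 * params$mu_r, 100)
  repeat {
    grid <- seq(0, horizon, by = grid_step)
    vals <- logistic_rate(params, grid)
    if (any(vals <= 0)) stop("rate function exhausted: logistic rate is not strictly positive")
    total <- pracma::trapz(grid, vals)
    if (total >= target * 1.001) break
    if (horizon > 1e7) stop("rate function exhausted before ", n_spikes, " spikes")
    horizon <- horizon * 2
  }
  rate <- rate_function(grid, vals)
  unit_seq <- spike_sequence(tau, label = "unit-rate gamma train")
  out <- inverse_rescale(unit_seq, rate)
  out$label <- sprintf("logistic-gamma synthetic (p=%.3g)", p)
  attr(out, "true_params") <- list(params = params, p = p)
  out
}

#' Synthetic amperometric trace configuration
#'
#' @param sampling_rate samples per second.
#' @param rms_noise baseline Gaussian noise RMS, pA (realistic recordings
#'   sit between 0.2 and 0.5 pA).
#' @param spike_amplitude peak current of one release event, pA.
#' @param spike_rise rise time, s (0 = instantaneous).
#' @param spike_decay exponential decay constant, s.
#' @param drift_amplitude slow baseline-drift amplitude, pA.
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(sampling_rate = 1000, rms_noise = 0.3,
                         spike_amplitude = 10, spike_rise = 0,
                         spike_decay = 0.03, drift_amplitude = 0.5) {
  stopifnot(sampling_rate > 0, rms_noise > 0, spike_amplitude >= 0,
            spike_rise >= 0, spike_decay > 0, drift_amplitude >= 0)
  structure(list(sampling_rate = sampling_rate, rms_noise = rms_noise,
                 spike_amplitude = spike_amplitude, spike_rise = spike_rise,
                 spike_decay = spike_decay,
                 drift_amplitude = drift_amplitude),
            class = "trace_config")
}

#' Synthesize an amperometric current trace
#'
#' Baseline + slow sinusoidal drift + Gaussian noise of the configured RMS,
#' with one template peak per spike: a (near-)instantaneous rise to
#' `spike_amplitude` followed by a single-exponential decay. The template
#' is deliberately simple — the detector only uses event times and
#' amplitudes, not peak shapes.
#'
#' @param seq a [spike_sequence]; all spikes must lie in `(0, T]`.
#' @param config a [trace_config].
#' @param seed optional RNG seed.
#' @return An object of class `amperometric_trace` with `times` (uniform
#'   grid, s) and `current` (pA).
#' @export
synthesize_trace <- function(seq, config = trace_config(), seed = NULL) {
  stopifnot(inherits(seq, "spike_sequence"), inherits(config, "trace_config"))
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sampling_rate
  times <- seq(0, seq$duration, by = 1 / fs)
  current <- config$drift_amplitude * sin(2 * pi * times / (2 * seq$duration)) +
    rnorm(length(times), sd = config$rms_noise)
  extent <- ceiling((config$spike_rise + 12 * config$spike_decay) * fs)
  for (ts in seq$times) {
    i0 <- round(ts * fs) + 1L
    i0 <- min(max(i0, 1L), length(times))
    i1 <- min(i0 + extent, length(times))
    rel <- times[i0:i1] - times[i0]
    peak <- if (config$spike_rise > 0) {
      ifelse(rel <= config$spike_rise,
             config$spike_amplitude * rel / config$spike_rise,
             config$spike_amplitude *
               exp(-(rel - config$spike_rise) / config$spike_decay))
    } else {
      config$spike_amplitude * exp(-rel / config$spike_decay)
    }
    current[i0:i1] <- current[i0:i1] + peak
  }
  structure(list(times = times, current = current),
            class = "amperometric_trace")
}

#' @export
print.amperometric_trace <- function(x, ...) {
  cat(sprintf("amperometric_trace: %d samples over %.4g s\n",
              length(x$times), x$times[length(x$times)]))
  invisible(x)
}

#' Threshold spike detection on a current trace
#'
#' Smooths with a moving average, removes a rolling-median baseline, and
#' estimates the baseline RMS robustly (median absolute deviation of the
#' raw baseline-subtracted trace, so sparse peaks do not inflate it).
#' Local maxima of runs of at least `min_width` consecutive smoothed
#' samples exceeding `threshold_factor` times that RMS are returned as
#' exocytotic peaks.
#'
#' @param trace an `amperometric_trace`.
#' @param smoothing moving-average window, s.
#' @param baseline_window rolling-median window, s.
#' @param threshold_factor detection threshold in units of baseline RMS
#'   (default 3).
#' @param min_width minimum number of consecutive supra-threshold samples.
#' @return A [spike_sequence] of peak times (possibly empty — a flat trace
#'   yields no detections, not an error).
#' @export
detect_spikes <- function(trace, smoothing = 0.005, baseline_window = 2,
                          threshold_factor = 3, min_width = 3L) {
  stopifnot(inherits(trace, "amperometric_trace"))
  fs <- 1 / mean(diff(trace$times))
  n <- length(trace$current)
  w <- max(1L, round(smoothing * fs))
  if (n <= w) stop("trace shorter than the smoothing window")
  sm <- as.numeric(filter(trace$current, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- trace$current[is.na(sm)]
  bw <- min(2L * floor(baseline_window * fs / 2) + 1L,
            2L * floor((n - 1) / 2) + 1L)
  baseline <- runmed(sm, bw)
  resid <- sm - baseline
  # the 3x criterion refers to the raw baseline noise, not the (quieter)
  # smoothed residual
  rms <- mad(trace$current - baseline)
  if (rms <= 0) rms <- sd(trace$current - baseline)
  if (!is.finite(rms) || rms <= 0) {
    return(spike_sequence(numeric(0),
                          duration = trace$times[length(trace$times)],
                          label = "detected (flat trace)"))
  }
  above <- resid > threshold_factor * rms
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_width
  peaks <- vapply(which(keep), function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(resid[seg])]
  }, integer(1L))
  peaks <- sort(peaks)
  spike_sequence(trace$times[peaks],
                 duration = trace$times[length(trace$times)],
                 label = "detected spikes")
}
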