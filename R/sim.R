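#' Langevin simulation configuration
#'
#' Physical and numerical parameters of the vesicle-transport simulator.
#' Inputs are SI (metres, seconds, kelvin, newtons); internally the
#' simulator works in micrometres and seconds so coordinates are O(1).
#'
#' The defaults are the sub-membrane active-zone conditions the package is
#' built around: diffusion coefficient `D = 3.22e-14` m²/s, `T = 296` K,
#' vesicle radius 150 nm, density 2.09 vesicles/μm³ in a 4.4 × 1 × 4.4 μm
#' cuboid (40 vesicles), membrane on the `y = 0` face.
#'
#' @param D diffusion coefficient, m²/s.
#' @param temperature absolute temperature, K.
#' @param radius vesicle radius, m.
#' @param density vesicles per μm³ (used when `n_vesicles` is `NULL`;
#'   `n_vesicles = round(density × volume)`).
#' @param n_vesicles explicit vesicle count, overriding `density`.
#' @param box cuboid edge lengths `c(Lx, Ly, Lz)`, m; the membrane is the
#'   `Lx × Lz` face at `y = 0`, the other five faces reflect.
#' @param alpha harmonic force constant, N/m (`0` disables the potential).
#'   The force is `F_y = -alpha * y`, attracting vesicles toward the
#'   membrane plane; lateral components are zero.
#' @param dt integration step, s. Must satisfy
#'   `sqrt(2 D dt) < radius / 3` so a step cannot jump across a vesicle.
#' @param stop_events stop after this many membrane events (default 16000
#'   for free-Brownian runs, 4500 when `alpha > 0`, matching the intended
#'   study sizes).
#' @param max_time stop after this much simulated time, s.
#' @param noise_convention `"standard"`: per-axis step variance `2 D dt`
#'   and Einstein drift mobility `D / (kB T)`. `"halved"`: per-axis step
#'   variance `D dt` (a literal reading of a noise coupling `σ/γ = √D`
#'   that appears in parts of the overdamped-Langevin literature), same
#'   mobility. Surfaced because the noise-factor convention is the dominant
#'   cross-implementation risk for absolute time scales.
#' @param replacement where an absorbed vesicle re-enters: `"uniform"`
#'   (anywhere in the radius-inset cuboid) or `"far_wall"` (on the inset
#'   face opposite the membrane).
#' @param membrane `"absorbing"` records membrane contacts as release
#'   events; `"reflecting"` turns the membrane into a sixth hard wall
#'   (used for equilibrium checks of the potential).
#' @param seed RNG seed used by [run_simulation()] unless overridden.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(D = 3.22e-14, temperature = 296, radius = 150e-9,
                       density = 2.09, n_vesicles = NULL,
                       box = c(4.4e-6, 1e-6, 4.4e-6),
                       alpha = 0, dt = 1e-3,
                       stop_events = NULL, max_time = Inf,
                       noise_convention = c("standard", "halved"),
                       replacement = c("uniform", "far_wall"),
                       membrane = c("absorbing", "reflecting"),
                       seed = NULL) {
  noise_convention <- match.arg(noise_convention)
  replacement <- match.arg(replacement)
  membrane <- match.arg(membrane)
  stopifnot(D > 0, temperature > 0, radius > 0, dt > 0, alpha >= 0,
            length(box) == 3L, all(box > 2 * radius))
  box_um <- box * 1e6
  r_um <- radius * 1e6
  D_um <- D * 1e12
  if (is.null(n_vesicles)) {
    stopifnot(density > 0)
    n_vesicles <- round(density * prod(box_um))
  }
  n_vesicles <- as.integer(n_vesicles)
  stopifnot(n_vesicles >= 1L)
  sphere_vol <- 4 / 3 * pi * r_um^3
  if (n_vesicles * sphere_vol >= 0.5 * prod(box_um)) {
    stop("infeasible packing: vesicles would fill over half the volume")
  }
  sd_step <- switch(noise_convention,
                    standard = sqrt(2 * D_um * dt),
                    halved = sqrt(D_um * dt))
  if (sqrt(2 * D_um * dt) >= r_um / 3) {
    stop("dt too large: rms step must stay below radius/3")
  }
  if (is.null(stop_events)) stop_events <- if (alpha > 0) 4500L else 16000L
  drift_rate <- alpha * D / (.kB * temperature)  # 1/s, Einstein mobility
  structure(list(D = D, temperature = temperature, radius = radius,
                 n_vesicles = n_vesicles, box = box, alpha = alpha,
                 dt = dt, stop_events = as.integer(stop_events),
                 max_time = max_time,
                 noise_convention = noise_convention,
                 replacement = replacement, membrane = membrane,
                 seed = seed,
                 box_um = box_um, r_um = r_um, D_um = D_um,
                 sd_step = sd_step, drift_rate = drift_rate),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d vesicles in %.3g x %.3g x %.3g um, ",
                     "D=%.3g m^2/s, alpha=%.3g N/m, dt=%.3g s (%s noise)\n"),
              x$n_vesicles, x$box_um[1L], x$box_um[2L], x$box_um[3L],
              x$D, x$alpha, x$dt, x$noise_convention))
  invisible(x)
}

#' Initial vesicle ensemble
#'
#' Draws uniform non-overlapping vesicle positions in the radius-inset
#' cuboid by rejection sampling. Positions are in simulation units (μm).
#'
#' @param config a [sim_config].
#' @return An object of class `ensemble_state` with `positions`
#'   (`n_vesicles × 3` matrix, columns x, y, z in μm) and `time = 0`.
#' @export
initialize_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_vesicles
  r <- config$r_um
  lo <- rep(r, 3L)
  hi <- config$box_um - r
  pos <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  dmin2 <- (2 * r)^2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(10000L)) {
      p <- lo + runif(3L) * (hi - lo)
      if (i == 1L) { placed <- TRUE }
      else {
        d2 <- colSums((t(pos[seq_len(i - 1L), , drop = FALSE]) - p)^2)
        placed <- all(d2 >= dmin2)
      }
      if (placed) { pos[i, ] <- p; break }
    }
    if (!placed) stop("packing error: could not place vesicle ", i)
  }
  structure(list(positions = pos, time = 0), class = "ensemble_state")
}

#' @export
print.ensemble_state <- function(x, ...) {
  cat(sprintf("ensemble_state: %d vesicles at t = %.6g s\n",
              nrow(x$positions), x$time))
  invisible(x)
}

#' Harmonic attraction toward the membrane
#'
#' The force field of the membrane-directed transport model:
#' `F_x = F_z = 0`, `F_y = -alpha * (y - y0)` with the membrane plane at
#' `y0 = 0`, i.e. magnitude `alpha * |y - y0|` pointing toward the membrane
#' everywhere in the box.
#'
#' @param position numeric length-3 vector (x, y, z) or an `n × 3` matrix,
#'   metres.
#' @param config a [sim_config] (supplies `alpha`).
#' @return Force vector(s), newtons, same shape as `position`.
#' @export
harmonic_force <- function(position, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.matrix(position)) {
    f <- matrix(0, nrow(position), 3L, dimnames = list(NULL, c("x", "y", "z")))
    f[, 2L] <- -config$alpha * position[, 2L]
    f
  } else {
    c(x = 0, y = -config$alpha * position[2L], z = 0)
  }
}

#' Specular wall reflection and hard-sphere overlap resolution
#'
#' Folds positions back through the five reflecting radius-inset faces
#' (six when the membrane is reflecting), then pushes overlapping pairs
#' apart symmetrically along their centre line to contact distance
#' `2 * radius` (up to 10 sweeps; a warning reports unresolved pairs).
#'
#' @param state an `ensemble_state`.
#' @param config a [sim_config].
#' @return The corrected `ensemble_state`.
#' @export
reflect_and_resolve <- function(state, config) {
  stopifnot(inherits(state, "ensemble_state"), inherits(config, "sim_config"))
  pos <- reflect_positions_cpp(state$positions,
                               config$box_um[1L], config$box_um[2L],
                               config$box_um[3L], config$r_um,
                               config$membrane == "reflecting")
  res <- resolve_overlaps_cpp(pos, config$r_um, 10L)
  if (res$unresolved > 0L) {
    warning(res$unresolved, " vesicle pair(s) still overlapping after 10 sweeps")
  }
  state$positions <- res$positions
  dimnames(state$positions) <- dimnames(pos)
  state
}

#' Membrane-event detection and vesicle replacement
#'
#' Any vesicle whose centre is within one radius of the membrane plane
#' (`y <= radius` in simulation units) generates one release event
#' timestamped at the current simulated time and is replaced at a fresh
#' non-overlapping position, keeping the vesicle count constant.
#'
#' @param state an `ensemble_state`.
#' @param config a [sim_config].
#' @return A list with the updated `state` and the vector of `events`
#'   (times, s).
#' @export
detect_and_replace <- function(state, config) {
  stopifnot(inherits(state, "ensemble_state"), inherits(config, "sim_config"))
  r <- config$r_um
  hits <- which(state$positions[, 2L] <= r)
  events <- rep(state$time, length(hits))
  if (length(hits)) {
    lo <- rep(r, 3L)
    hi <- config$box_um - r
    dmin2 <- (2 * r)^2
    for (i in hits) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        p <- lo + runif(3L) * (hi - lo)
        if (config$replacement == "far_wall") p[2L] <- hi[2L]
        d2 <- colSums((t(state$positions[-i, , drop = FALSE]) - p)^2)
        if (all(d2 >= dmin2)) {
          state$positions[i, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("replacement packing failure for vesicle ", i)
    }
  }
  list(state = state, events = events)
}

#' Advance the ensemble by Euler-Maruyama steps
#'
#' Per axis and step: displacement = drift × dt + noise × sqrt(dt), then
#' wall reflection, overlap resolution, and membrane-event detection with
#' replacement. Exposed mainly for inspection and testing; long runs should
#' use [run_simulation()], which drives the same compiled core.
#'
#' @param state an `ensemble_state`.
#' @param config a [sim_config].
#' @param n_steps number of steps to take.
#' @param noise set `FALSE` to switch the thermal noise off (deterministic
#'   drift test hook).
#' @param resolve set `FALSE` to skip hard-sphere overlap resolution
#'   (useful for dilute free-diffusion checks).
#' @return A list with the advanced `state` and `events` (times, s).
#' @export
step_overdamped <- function(state, config, n_steps = 1L, noise = TRUE,
                            resolve = TRUE) {
  stopifnot(inherits(state, "ensemble_state"), inherits(config, "sim_config"))
  res <- sim_core(state$positions,
                  config$box_um[1L], config$box_um[2L], config$box_um[3L],
                  config$r_um, config$sd_step, config$drift_rate, 0,
                  config$dt, -1L, Inf, as.integer(n_steps),
                  config$membrane == "absorbing",
                  config$replacement == "far_wall",
                  noise, resolve, 0L, state$time)
  state$positions <- res$positions
  dimnames(state$positions) <- list(NULL, c("x", "y", "z"))
  state$time <- res$time
  list(state = state, events = res$events)
}

#' Run a vesicle-transport simulation
#'
#' Initializes the ensemble and integrates the overdamped Langevin dynamics
#' until the stop criterion (event count or simulated time) is met,
#' recording every membrane arrival as a release event.
#'
#' @param config a [sim_config].
#' @param seed RNG seed (defaults to `config$seed`; `NULL` leaves the RNG
#'   state alone).
#' @param sample_y_every if positive, record every vesicle's membrane
#'   distance every that many steps (returned as attribute `y_samples`,
#'   μm; used for equilibrium diagnostics).
#' @param state optional pre-built `ensemble_state` to continue from.
#' @return A [spike_sequence] of membrane-arrival times with
#'   `duration = ` total simulated time; attributes `config`, `seed`,
#'   `final_state`, `unresolved` and (optionally) `y_samples`.
#' @export
run_simulation <- function(config, seed = config$seed, sample_y_every = 0L,
                           state = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- initialize_ensemble(config)
  res <- sim_core(state$positions,
                  config$box_um[1L], config$box_um[2L], config$box_um[3L],
                  config$r_um, config$sd_step, config$drift_rate, 0,
                  config$dt, config$stop_events, config$max_time, -1L,
                  config$membrane == "absorbing",
                  config$replacement == "far_wall",
                  TRUE, TRUE, as.integer(sample_y_every), state$time)
  label <- sprintf("langevin sim (alpha=%.3g N/m, %s noise)",
                   config$alpha, config$noise_convention)
  out <- spike_sequence(res$events, duration = res$time, label = label)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "final_state") <- structure(list(positions = res$positions,
                                             time = res$time),
                                        class = "ensemble_state")
  attr(out, "unresolved") <- res$unresolved
  if (sample_y_every > 0L) attr(out, "y_samples") <- res$y_samples
  out
}
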