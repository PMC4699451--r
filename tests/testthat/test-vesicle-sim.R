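test_that("the default active-zone configuration holds 40 vesicles", {
  cfg <- sim_config()
  expect_equal(cfg$n_vesicles, 40L)
  expect_equal(cfg$n_vesicles, round(2.09 * 4.4 * 1 * 4.4))
  expect_error(sim_config(dt = 1), "dt too large")
  expect_error(sim_config(box = c(1e-7, 1e-6, 1e-6)), "box")
})

test_that("ensemble initialization is uniform, inset, non-overlapping and seeded", {
  cfg <- sim_config()
  set.seed(2); st1 <- initialize_ensemble(cfg)
  set.seed(2); st2 <- initialize_ensemble(cfg)
  expect_identical(st1$positions, st2$positions)

  pos <- st1$positions
  r <- cfg$r_um
  expect_true(all(pos >= r - 1e-12))
  expect_true(all(t(pos) <= cfg$box_um - r + 1e-12))
  d <- as.matrix(dist(pos))
  expect_true(all(d[upper.tri(d)] >= 2 * r - 1e-9))

  one <- sim_config(n_vesicles = 1)
  expect_equal(nrow(initialize_ensemble(one)$positions), 1L)
})

test_that("the harmonic force points toward the membrane with the right magnitude", {
  cfg0 <- sim_config(alpha = 0)
  expect_equal(harmonic_force(c(1e-6, 5e-7, 2e-6), cfg0),
               c(x = 0, y = 0, z = 0))

  cfg <- sim_config(alpha = 1.275e-13)
  f <- harmonic_force(c(1e-6, 5e-7, 2e-6), cfg)
  expect_equal(unname(f[2L]), -6.375e-20, tolerance = 1e-12)
  expect_equal(unname(f[c(1L, 3L)]), c(0, 0))
  expect_equal(unname(harmonic_force(c(0, 0, 0), cfg)[2L]), 0)
})

test_that("walls reflect specularly and overlaps resolve to contact distance", {
  cfg <- sim_config(n_vesicles = 2)
  r <- cfg$r_um; Ly <- cfg$box_um[2L]
  d <- 0.04
  st <- structure(list(positions = rbind(c(1, Ly - r + d, 1),
                                         c(3, 0.5, 3)),
                       time = 0), class = "ensemble_state")
  out <- reflect_and_resolve(st, cfg)
  expect_equal(out$positions[1L, 2L], (Ly - r) - d)

  # symmetric push-apart: centres end exactly 2r apart, midpoint preserved
  st2 <- structure(list(positions = rbind(c(2, 0.5, 2),
                                          c(2 + 1.8 * r, 0.5, 2)),
                        time = 0), class = "ensemble_state")
  out2 <- reflect_and_resolve(st2, cfg)
  expect_equal(dist(out2$positions)[1L], 2 * r, tolerance = 1e-12)
  expect_equal(colMeans(out2$positions), colMeans(st2$positions),
               tolerance = 1e-12)

  # no-overlap state is untouched
  st3 <- structure(list(positions = rbind(c(1, 0.5, 1), c(3, 0.5, 3)),
                        time = 0), class = "ensemble_state")
  expect_identical(reflect_and_resolve(st3, cfg)$positions, st3$positions)
})

test_that("membrane contacts are detected at one radius and vesicles replaced", {
  cfg <- sim_config(n_vesicles = 2)
  r <- cfg$r_um
  st <- structure(list(positions = rbind(c(1, r / 2, 1), c(3, 0.5, 3)),
                       time = 7.25), class = "ensemble_state")
  set.seed(4)
  out <- detect_and_replace(st, cfg)
  expect_equal(out$events, 7.25)
  expect_equal(nrow(out$state$positions), 2L)
  expect_gt(out$state$positions[1L, 2L], r)

  st2 <- structure(list(positions = rbind(c(1, 1.01 * r, 1), c(3, 0.5, 3)),
                        time = 1), class = "ensemble_state")
  expect_length(detect_and_replace(st2, cfg)$events, 0L)
})

test_that("simulations are deterministic under a fixed seed", {
  cfg <- quick_sim_config(stop_events = 150L)
  s1 <- run_simulation(cfg, seed = 5)
  s2 <- run_simulation(cfg, seed = 5)
  expect_identical(s1$times, s2$times)
  expect_identical(attr(s1, "final_state")$positions,
                   attr(s2, "final_state")$positions)
})

test_that("with the noise switched off the drift is the deterministic Euler step", {
  alpha <- 1.27e-10                      # relaxation rate near 1 /s
  cfg <- sim_config(alpha = alpha, n_vesicles = 1, box = rep(4e-6, 3))
  k <- cfg$drift_rate
  y0 <- 2.0
  st <- structure(list(positions = rbind(c(2, y0, 2)), time = 0),
                  class = "ensemble_state")
  out <- step_overdamped(st, cfg, n_steps = 1L, noise = FALSE)
  expect_equal(unname(out$state$positions[1L, 2L]), y0 - k * y0 * cfg$dt,
               tolerance = 1e-12)
  expect_equal(unname(out$state$positions[1L, c(1L, 3L)]), c(2, 2))
})

test_that("free diffusion reproduces the per-axis mean-squared displacement 2 D t", {
  cfg <- sim_config(n_vesicles = 4000, box = rep(1e-4, 3),
                    membrane = "reflecting", dt = 1e-3)
  set.seed(6)
  st <- initialize_ensemble(cfg)
  n_steps <- 100L
  out <- step_overdamped(st, cfg, n_steps = n_steps, resolve = FALSE)
  disp <- out$state$positions - st$positions
  msd <- mean(c(disp^2))
  expect_equal(msd, 2 * cfg$D_um * n_steps * cfg$dt, tolerance = 0.03)
})

test_that("the alternative noise convention halves the step variance", {
  cfg_std <- sim_config()
  cfg_alt <- sim_config(noise_convention = "halved")
  expect_equal(cfg_alt$sd_step^2, cfg_std$sd_step^2 / 2)
})

test_that("a reflecting membrane with the potential reaches the Boltzmann profile", {
  alpha <- 1.27e-10                      # k = alpha D / (kB T) ~ 1 /s
  set.seed(8)
  burn_cfg <- sim_config(alpha = alpha, membrane = "reflecting",
                         stop_events = 0L, max_time = 8)
  burn <- attr(run_simulation(burn_cfg, seed = NULL), "final_state")
  cfg <- sim_config(alpha = alpha, membrane = "reflecting",
                    stop_events = 0L, max_time = burn$time + 250)
  k <- cfg$drift_rate
  s <- run_simulation(cfg, seed = NULL, sample_y_every = 500L, state = burn)
  ys <- attr(s, "y_samples")
  r <- cfg$r_um; top <- cfg$box_um[2L] - r
  edges <- seq(r, top, length.out = 8)
  obs <- tabulate(findInterval(ys, edges, rightmost.closed = TRUE),
                  nbins = 7) / length(ys)
  dens <- function(y) exp(-k * y^2 / (2 * cfg$D_um))
  Z <- integrate(dens, r, top)$value
  expected <- vapply(seq_len(7), function(i) {
    integrate(dens, edges[i], edges[i + 1L])$value / Z
  }, numeric(1))
  expect_lt(max(abs(obs - expected)), 0.05)
})

test_that("halving the time step leaves the interspike mean within 5%", {
  m <- vapply(c(1e-3, 5e-4), function(dt) {
    s <- run_simulation(sim_config(dt = dt, stop_events = 1500L), seed = 10)
    mean(interspike_times(s))
  }, numeric(1))
  expect_lt(abs(m[1L] - m[2L]) / m[2L], 0.05)
})

test_that("event bookkeeping conserves counts and strict ordering", {
  s <- run_simulation(quick_sim_config(stop_events = 400L), seed = 12)
  expect_gte(length(s$times), 400L)
  expect_true(all(diff(s$times) > 0))
  expect_lte(max(s$times), s$duration)
})
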