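test_that("summary statistics use unbiased sample moments", {
  s1 <- summary_stats(c(1, 1, 1))
  expect_equal(s1$mean, 1); expect_equal(s1$sd, 0); expect_equal(s1$cv, 0)

  s2 <- summary_stats(c(2, 4))
  expect_equal(s2$mean, 3); expect_equal(s2$variance, 2)

  expect_error(summary_stats(1), "at least 2")

  set.seed(13)
  s3 <- summary_stats(rexp(1e5, rate = 2))
  expect_equal(s3$cv, 1, tolerance = 0.02)

  cs <- spike_counts(generate_gamma_renewal(1, 0.5, 5000, seed = 13), 2)
  expect_equal(summary_stats(cs)$dispersion, 1, tolerance = 0.1)
})

test_that("interspike bin width follows the prescribed small/large-N rules", {
  expect_equal(interspike_bin_width(0.68, 0.56, 914),
               (0.68 + 2.85 * 0.56) / sqrt(914))
  expect_equal(interspike_bin_width(0.68, 0.56, 914), 0.0753, tolerance = 1e-3)
  expect_equal(interspike_bin_width(0.68, 0.67, 15504), 0.0623,
               tolerance = 1e-3)
  expect_equal(interspike_bin_width(1, 0, 4), 0.5)
})

test_that("interspike histograms bin right-closed from zero and normalize to unit area", {
  hst <- make_histogram(c(0.1, 0.2, 0.3), h = 0.2)
  expect_equal(hst$bin_edges, c(0, 0.2, 0.4))
  expect_equal(hst$counts, c(2, 1))

  set.seed(19)
  x <- rgamma(500, 2, 1)
  hst2 <- make_histogram(x, h = 0.3)
  expect_equal(sum(hst2$density) * 0.3, 1, tolerance = 1e-12)

  # histogram-implied cdf tracks the true cdf
  x3 <- rexp(1e4)
  hst3 <- make_histogram(x3, h = interspike_bin_width(mean(x3), sd(x3), 1e4))
  cdf_emp <- cumsum(hst3$counts) / sum(hst3$counts)
  cdf_true <- pexp(hst3$bin_edges[-1L])
  expect_lt(max(abs(cdf_emp - cdf_true)), 0.05)
})

test_that("gamma at shape 1 is exponential; gamma-count at shape 1 is Poisson", {
  dt <- seq(0.01, 5, by = 0.07)
  expect_equal(gamma_pdf(dt, p = 1, theta = 1 / 1.14),
               exponential_pdf(dt, 1.14), tolerance = 1e-14)
  for (bT in c(0.5, 2, 7)) {
    expect_equal(gamma_count_pmf(0:20, p = 1, beta = bT, T_window = 1),
                 poisson_pmf(0:20, bT), tolerance = 1e-12)
  }
})

test_that("model densities match closed-form anchor values", {
  expect_equal(exponential_pdf(0, 1.14), 1.14)
  expect_equal(exponential_pdf(1 / 1.14, 1.14), 1.14 / exp(1))
  expect_equal(poisson_pmf(0, 1), exp(-1))
  expect_equal(gamma_count_pmf(0, p = 2, beta = 1, T_window = 2), 3 * exp(-2),
               tolerance = 1e-12)
  # mean of the gamma density with one reported parameter pair
  m <- integrate(function(x) x * gamma_pdf(x, 1.58, 0.36), 0, Inf)$value
  expect_equal(m, 1.58 * 0.36, tolerance = 1e-6)
  expect_equal(m, 0.5688, tolerance = 1e-4)
  # mode at theta (p - 1)
  opt <- optimize(function(x) gamma_pdf(x, 1.58, 0.36), c(0.01, 2),
                  maximum = TRUE)
  expect_equal(opt$maximum, 0.36 * 0.58, tolerance = 1e-4)
})

test_that("densities integrate to one and pmfs telescope to one", {
  expect_equal(integrate(exponential_pdf, 0, Inf, lambda = 1.31)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(gamma_pdf, 0, Inf, p = 1.63, theta = 0.30)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(lognormal_pdf, 0, Inf, log_mean = -0.5,
                         log_sd = 0.8)$value, 1, tolerance = 1e-6)
  for (pars in list(c(2, 2), c(1.7, 6), c(0.8, 3))) {
    total <- sum(gamma_count_pmf(0:400, p = pars[1L], beta = pars[2L],
                                 T_window = 1))
    expect_lt(abs(1 - total), 1e-10)
  }
})

test_that("log-space Poisson pmf agrees with the direct log formula at large k", {
  k <- 100; lt <- 100
  oracle <- exp(k * log(lt) - lt - sum(log(seq_len(k))))
  expect_equal(poisson_pmf(k, lt), oracle, tolerance = 1e-12)
})

test_that("log-normal density matches an independent quadrature-checked formula", {
  set.seed(23)
  x <- runif(10, 0.05, 3)
  mu <- -0.4; sg <- 0.7
  direct <- exp(-(log(x) - mu)^2 / (2 * sg^2)) / (x * sg * sqrt(2 * pi))
  expect_equal(lognormal_pdf(x, mu, sg), direct, tolerance = 1e-12)
  # median at exp(log_mean)
  half <- integrate(lognormal_pdf, 0, exp(mu), log_mean = mu, log_sd = sg)$value
  expect_equal(half, 0.5, tolerance = 1e-6)
})

test_that("histogram least squares recovers generating parameters", {
  set.seed(29)
  x <- rexp(1e5, rate = 1.5)
  hst <- make_histogram(x, interspike_bin_width(mean(x), sd(x), length(x)))
  fit <- fit_histogram(hst, "exponential")
  expect_gte(fit$params$lambda, 1.45); expect_lte(fit$params$lambda, 1.55)

  y <- rgamma(1e5, shape = 1.6, scale = 0.4)
  hst2 <- make_histogram(y, interspike_bin_width(mean(y), sd(y), length(y)))
  fit2 <- fit_histogram(hst2, "gamma")
  expect_gte(fit2$params$p, 1.5); expect_lte(fit2$params$p, 1.7)
  expect_gte(fit2$params$theta, 0.37); expect_lte(fit2$params$theta, 0.43)
  expect_gt(fit2$r_squared, 0.97)
})

test_that("histogram least squares agrees with a maximum-likelihood oracle on clean data", {
  set.seed(53)
  y <- rgamma(1e5, shape = 1.6, scale = 0.4)
  hst <- make_histogram(y, interspike_bin_width(mean(y), sd(y), length(y)))
  lsq <- fit_histogram(hst, "gamma")
  mle <- MASS::fitdistr(y, "gamma")
  expect_equal(lsq$params$p, unname(mle$estimate["shape"]), tolerance = 0.05)
  expect_equal(lsq$params$theta, 1 / unname(mle$estimate["rate"]),
               tolerance = 0.05)
})

test_that("fitting an exactly evaluated density returns the generating parameters", {
  edges <- seq(0, 4, by = 0.1)
  mids <- edges[-1L] - 0.05
  hst <- manual_histogram(edges, gamma_pdf(mids, 1.6, 0.4))
  fit <- fit_histogram(hst, "gamma")
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_equal(fit$params$p, 1.6, tolerance = 1e-4)
})

test_that("combined interspike+count fit shares one parameter set", {
  set.seed(31)
  s <- generate_gamma_renewal(p = 1.6, theta = 0.4, n_spikes = 2e4)
  isi <- interspike_times(s)
  st <- summary_stats(isi)
  hst <- make_histogram(isi, interspike_bin_width(st$mean, st$sd, 2e4))
  cs <- spike_counts(s, 4 * st$mean)
  chs <- make_count_histogram(cs)
  fit <- combined_fit(hst, chs, "gamma_pair")
  expect_equal(fit$params$p, 1.6, tolerance = 0.15 / 1.6)

  # Poisson data: shared gamma fit collapses to shape near 1
  sp <- generate_gamma_renewal(p = 1, theta = 0.6, n_spikes = 2e4, seed = 37)
  isip <- interspike_times(sp); stp <- summary_stats(isip)
  hstp <- make_histogram(isip, interspike_bin_width(stp$mean, stp$sd, 2e4))
  chp <- make_count_histogram(spike_counts(sp, 4 * stp$mean))
  fitp <- combined_fit(hstp, chp, "gamma_pair")
  expect_gte(fitp$params$p, 0.9); expect_lte(fitp$params$p, 1.15)

  # nesting: the gamma pair can always do at least as well as the Poisson pair
  for (seq_i in list(s, sp)) {
    isi_i <- interspike_times(seq_i); st_i <- summary_stats(isi_i)
    h_i <- make_histogram(isi_i,
                          interspike_bin_width(st_i$mean, st_i$sd,
                                               length(seq_i$times)))
    c_i <- make_count_histogram(spike_counts(seq_i, 4 * st_i$mean))
    sse_g <- combined_fit(h_i, c_i, "gamma_pair")$sse
    sse_p <- combined_fit(h_i, c_i, "poisson_pair")$sse
    expect_lte(sse_g, sse_p + 1e-9)
  }
})

test_that("count dispersion tracks the gamma shape of the interspikes", {
  for (cfg in list(c(p = 0.7, lo = 1.05, hi = Inf),
                   c(p = 1.0, lo = 0.9, hi = 1.1),
                   c(p = 2.5, lo = 0, hi = 0.85))) {
    s <- generate_gamma_renewal(cfg[["p"]], 0.4, 1e5, seed = 41)
    mu <- mean(interspike_times(s))
    disp <- summary_stats(spike_counts(s, 10 * mu))$dispersion
    expect_gt(disp, cfg[["lo"]]); expect_lt(disp, cfg[["hi"]])
  }
})

test_that("gamma-count pmf mean is consistent with gamma-renewal counts", {
  # At p = 1 the count pmf is Poisson and matches stationary counts exactly.
  s1 <- generate_gamma_renewal(1, 0.4, 5e4, seed = 43)
  emp1 <- mean(spike_counts(s1, 3)$counts)
  m1 <- sum((0:300) * gamma_count_pmf(0:300, 1, 1 / 0.4, 3))
  expect_equal(emp1, m1, tolerance = 0.02)

  # For p != 1 the pmf describes counts in a window opened at an event
  # (ordinary renewal), so it differs from the stationary mean T/(p theta)
  # by a bounded start-of-window correction of order (1 - CV^2)/2.
  p <- 1.6; theta <- 0.4; Tw <- 3
  s <- generate_gamma_renewal(p, theta, 5e4, seed = 43)
  emp <- mean(spike_counts(s, Tw)$counts)
  expect_equal(emp, Tw / (p * theta), tolerance = 0.02)
  model_mean <- sum((0:300) * gamma_count_pmf(0:300, p, 1 / theta, Tw))
  expect_lt(abs(model_mean - Tw / (p * theta)), 0.5)
})

test_that("model_report runs the full chain and is internally consistent", {
  s <- generate_gamma_renewal(p = 1, theta = 0.7, n_spikes = 3000, seed = 47)
  rep <- model_report(s)
  expect_s3_class(rep, "model_report")
  expect_equal(rep$binning$window, 4 * rep$stats_isi$mean)
  # at p = 1 the Poisson and gamma descriptions agree
  expect_equal(rep$fits$gamma$params$p, 1, tolerance = 0.1)
  expect_equal(rep$dispersion, 1, tolerance = 0.12)
  expect_equal(1 / rep$fits$gamma$params$theta * rep$fits$gamma$params$p,
               rep$fits$exponential$params$lambda, tolerance = 0.15)
})
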