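test_that("stretched-exponential fit recovers noiseless parameters exactly", {
  tr <- gen_quench_trace(f0 = 1, finf = 0.2, tau = 0.2, beta = 0.8,
                         noise_sigma = 0, seed = 1)
  fit <- fit_stretched_exponential(tr)
  expect_equal(fit$f0, 1, tolerance = 1e-6)
  expect_equal(fit$finf, 0.2, tolerance = 1e-6)
  expect_equal(fit$tau, 0.2, tolerance = 1e-6)
  expect_equal(fit$beta, 0.8, tolerance = 1e-6)
  expect_false(fit$flagged)

  # beta = 1 input collapses to a single exponential, tau recovered
  tr1 <- gen_quench_trace(1, 0, tau = 0.05, beta = 1, noise_sigma = 0)
  fit1 <- fit_stretched_exponential(tr1)
  expect_equal(fit1$tau, 0.05, tolerance = 1e-6)
  expect_equal(fit1$beta, 1, tolerance = 1e-6)
})

test_that("stretched-exponential fit tolerates 1% noise within 5% on tau, beta", {
  tr <- gen_quench_trace(1, 0.2, tau = 0.2, beta = 0.8,
                         noise_sigma = 0.01, seed = 99)
  fit <- fit_stretched_exponential(tr)
  expect_lt(abs(fit$tau - 0.2) / 0.2, 0.05)
  expect_lt(abs(fit$beta - 0.8) / 0.8, 0.05)
})

test_that("stretched-exponential fit flags and rejects pathological traces", {
  rising <- quench_trace(seq(0, 1, length.out = 200),
                         seq(0.2, 1, length.out = 200))
  expect_warning(fit <- fit_stretched_exponential(rising), "does not decay")
  expect_true(fit$flagged)
  expect_equal(fit$beta, 1)

  short <- quench_trace(seq(0, 1, length.out = 30),
                        exp(-seq(0, 1, length.out = 30)))
  expect_error(fit_stretched_exponential(short, window = 0.1),
               "fewer than 10")
})

test_that("influx rate follows the stretched-exponential derivative", {
  # beta = 1: rate is 1/tau at any evaluation time
  expect_equal(influx_rate(list(tau = 0.1, beta = 1), 0.002), 10)
  expect_equal(influx_rate(list(tau = 0.1, beta = 1), 0.05), 10)

  # numerical-derivative oracle for (t/tau)^beta at t = 2 ms
  tau <- 0.1; beta <- 0.8; t0 <- 0.002; h <- 1e-7
  oracle <- ((((t0 + h) / tau)^beta) - (((t0 - h) / tau)^beta)) / (2 * h)
  expect_equal(influx_rate(list(tau = tau, beta = beta)), oracle,
               tolerance = 1e-6)
  expect_equal(influx_rate(list(tau = tau, beta = beta)), 17.49, # ~17.5
               tolerance = 1e-3)

  # monotone in 1/tau at fixed beta
  rates <- vapply(c(0.5, 0.2, 0.1, 0.05),
                  function(tt) influx_rate(list(tau = tt, beta = 0.8)),
                  numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("double-exponential fit recovers the printed legend parameters", {
  # activation time course with amplitudes 0.5/0.45 and rates 160/2 s^-1
  d <- gen_parametric_dataset(
    "double_exp", list(a1 = 0.5, k1 = 160, a2 = 0.45, k2 = 2),
    x = default_delays())
  fit <- fit_double_exponential(d$x, d$y)
  expect_false(fit$degenerate)
  expect_equal(fit$a1, 0.5, tolerance = 1e-6)
  expect_equal(fit$k1, 160, tolerance = 1e-6)
  expect_equal(fit$a2, 0.45, tolerance = 1e-6)
  expect_equal(fit$k2, 2, tolerance = 1e-6)

  # permuting the input point order leaves the fit unchanged
  perm <- c(5, 1, 8, 3, 7, 2, 6, 4)
  fit2 <- fit_double_exponential(d$x[perm], d$y[perm])
  expect_equal(fit2$k1, fit$k1, tolerance = 1e-12)
  expect_equal(fit2$k2, fit$k2, tolerance = 1e-12)
})

test_that("single-exponential input is flagged degenerate", {
  t <- default_delays()
  y <- 0.9 * (1 - exp(-3 * t))
  fit <- fit_double_exponential(t, y)
  expect_true(fit$degenerate)
  expect_equal(fit$k1, 3, tolerance = 1e-4)
  expect_equal(fit$a1, 0.9, tolerance = 1e-4)
  expect_equal(fit$a2, 0)
})

test_that("Hill fit recovers printed dose-response parameter sets exactly", {
  x <- 10^seq(0, log10(300), length.out = 8)
  for (truth in list(list(ec50 = 24, n_h = 2.9, k_over_kmax = 1),
                     list(ec50 = 59, n_h = 3, k_over_kmax = 0.8))) {
    d <- gen_parametric_dataset("hill", truth, x)
    fit <- fit_hill(d$x, d$y)
    expect_equal(fit$ec50, truth$ec50, tolerance = 1e-6)
    expect_equal(fit$n_h, truth$n_h, tolerance = 1e-6)
    expect_equal(fit$k_over_kmax, truth$k_over_kmax, tolerance = 1e-6)
  }
  # identity: at [cAMP] = EC50 the response is half of k/k_max
  d <- gen_parametric_dataset("hill",
                              list(ec50 = 24, n_h = 2.9, k_over_kmax = 0.7),
                              x = 24)
  expect_equal(d$y, 0.35)
  expect_warning(fit_hill(c(1, 3, 10, 30, 100), c(1, 0.8, 0.5, 0.3, 0.05)),
                 "monotone")
})

test_that("four-parameter logistic fit recovers the inhibition legend set", {
  x <- 10^seq(log10(0.01), log10(16), length.out = 8)
  d <- gen_parametric_dataset("inhibition",
                              list(ic50 = 4, s = 0.9, k_max = 1, k0 = 0), x)
  fit <- fit_inhibition(d$x, d$y)
  expect_equal(fit$ic50, 4, tolerance = 1e-6)
  expect_equal(fit$slope, 0.9, tolerance = 1e-6)
  expect_equal(fit$k_max - fit$k0, 1, tolerance = 1e-6)
  expect_false(fit$unbounded)

  # midpoint identity of the printed form: y(IC50) = (k_max - k0)/2
  d50 <- gen_parametric_dataset("inhibition",
                                list(ic50 = 4, s = 0.9, k_max = 3, k0 = 1),
                                x = 4)
  expect_equal(d50$y, 1)

  # conventional variant with a nonzero floor
  yc <- 0.2 + (1.2 - 0.2) / (1 + (x / 2)^1.3)
  fc <- fit_inhibition(x, yc, conventional = TRUE)
  expect_equal(fc$ic50, 2, tolerance = 1e-6)
  expect_equal(fc$k0, 0.2, tolerance = 1e-6)
  expect_equal(fc$k_max, 1.2, tolerance = 1e-6)

  # flat data: no inhibition detectable
  expect_warning(flat <- fit_inhibition(x, rep(1, 8)), "no inhibition")
  expect_true(flat$unbounded)
})

test_that("catalytic efficiency is the slope of rate vs enzyme", {
  fit <- fit_catalytic_efficiency(c(0, 100), c(0.05, 0.15))
  expect_equal(fit$k0, 0.05, tolerance = 1e-12)
  expect_equal(fit$efficiency, 0.001, tolerance = 1e-12)

  # all-zero enzyme: no slope, intercept is the mean
  fit0 <- fit_catalytic_efficiency(rep(0, 4), c(0.04, 0.05, 0.06, 0.05))
  expect_equal(fit0$efficiency, 0)
  expect_equal(fit0$k0, 0.05)

  # noisy series, fixed seed: slope within 5%
  enz <- seq(0, 200, by = 25)
  k_true <- 0.05 + enz * 2e-3
  k_obs <- k_true + withr::with_seed(7, rnorm(length(enz), sd = 0.005))
  fit <- fit_catalytic_efficiency(enz, k_obs)
  expect_lt(abs(fit$efficiency - 2e-3) / 2e-3, 0.05)

  expect_warning(fit_catalytic_efficiency(c(0, 100), c(0.2, 0.1)),
                 "negative")
})

test_that("replicate aggregation normalizes within experiment before averaging", {
  d <- rbind(
    data.frame(experiment = "e1", condition = c(1, 1, 2, 2), k = c(2, 4, 8, 8)),
    data.frame(experiment = "e2", condition = c(1, 1, 2, 2), k = c(1, 1, 4, 4)))
  # per-experiment means: e1 (3, 8), e2 (1, 4); normalized (3/8, 1), (1/4, 1)
  out <- aggregate_replicates(d)
  expect_equal(out$mean[out$condition == 1], mean(c(3 / 8, 1 / 4)))
  expect_equal(out$mean[out$condition == 2], 1)
  expect_equal(out$sd[out$condition == 1], sd(c(3 / 8, 1 / 4)))
  expect_equal(out$n_experiments, c(2, 2))
  raw <- aggregate_replicates(d, normalize = FALSE)
  expect_equal(raw$mean, c(2, 6))
})

test_that("fitters are deterministic functions of their inputs", {
  d <- gen_parametric_dataset(
    "double_exp", list(a1 = 0.5, k1 = 160, a2 = 0.45, k2 = 2),
    x = default_delays(), noise = 0.01, seed = 5)
  f1 <- fit_double_exponential(d$x, d$y)
  f2 <- fit_double_exponential(d$x, d$y)
  expect_identical(f1, f2)
  tr <- gen_quench_trace(1, 0.2, 0.1, 0.8, noise_sigma = 0.01, seed = 5)
  expect_identical(fit_stretched_exponential(tr),
                   fit_stretched_exponential(tr))
})
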