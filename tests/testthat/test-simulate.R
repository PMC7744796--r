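test_that("relax solves the two-state closed form exactly", {
  times <- seq(0, 1, length.out = 500)
  tr <- relax(two_state(), 0, c(1, 0), times)
  expect_lt(max(abs(tr$conducting_fraction - 0.1 * (1 - exp(-10 * times)))),
            1e-12)
  expect_equal(tr$equilibrium_level, 0.1, tolerance = 1e-12)
  # k - 1 = 1 spectrum component: amplitude -0.1, tau 0.1 s
  expect_equal(nrow(tr$spectrum), 1)
  expect_equal(tr$spectrum$amplitude, -0.1, tolerance = 1e-12)
  expect_equal(tr$spectrum$tau, 0.1, tolerance = 1e-12)
})

test_that("relaxation from equilibrium is constant", {
  m <- build_modulatory_model()
  p_eq <- equilibrium_occupancy(build_rate_matrix(m, 100))
  tr <- relax(m, 100, unname(p_eq), times = seq(0, 5, length.out = 50))
  expect_lt(max(abs(tr$conducting_fraction - tr$equilibrium_level)), 1e-10)
})

test_that("eigen solution matches dense ODE integration on the six-state scheme", {
  m <- build_modulatory_model()
  p0 <- unname(equilibrium_occupancy(build_rate_matrix(m, 0)))
  times <- exp(seq(log(1e-4), log(10), length.out = 60))
  tr <- relax(m, 100, p0, times)
  expect_false(tr$flagged)
  occ_ode <- ode_occupancy(m, 100, p0, times)
  expect_lt(max(abs(tr$occupancy - occ_ode)), 1e-6)
  # every occupancy row is a probability vector
  expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
  expect_true(all(tr$conducting_fraction >= -1e-12 &
                    tr$conducting_fraction <= 1 + 1e-12))
})

test_that("spectrum amplitudes sum to I(0) - I(eq) and count k - 1 components", {
  for (lig in c(0, 30, 100, 1000)) {
    m <- build_modulatory_model()
    p0 <- unname(equilibrium_occupancy(build_rate_matrix(m, 0)))
    tr <- relax(m, lig, p0, times = c(0, 1))
    expect_equal(nrow(tr$spectrum), n_states(m) - 1)
    expect_equal(sum(tr$spectrum$amplitude),
                 tr$conducting_fraction[1] - tr$equilibrium_level,
                 tolerance = 1e-9)
    expect_true(all(tr$spectrum$tau > 0))
  }
})

test_that("trajectories are invariant under output-grid refinement", {
  m <- build_modulatory_model()
  p0 <- unname(equilibrium_occupancy(build_rate_matrix(m, 0)))
  coarse <- c(0.01, 0.1, 1)
  fine <- sort(unique(c(coarse, seq(0.001, 1, length.out = 400))))
  cf_coarse <- relax(m, 100, p0, coarse)$conducting_fraction
  cf_fine <- relax(m, 100, p0, fine)$conducting_fraction
  expect_equal(cf_coarse, cf_fine[match(coarse, fine)], tolerance = 1e-12)
})

test_that("concentration jump equals relax from the pre-ligand equilibrium", {
  m <- build_modulatory_model()
  times <- c(0.012, 0.1, 1)
  same <- concentration_jump(m, 100, 100, times)
  expect_lt(max(abs(same$conducting_fraction - same$equilibrium_level)),
            1e-10)
  jump <- concentration_jump(m, 0, 100, times)
  p0 <- unname(equilibrium_occupancy(build_rate_matrix(m, 0)))
  expect_equal(jump$conducting_fraction,
               relax(m, 100, p0, times)$conducting_fraction,
               tolerance = 1e-12)
})

test_that("ensemble current scales linearly with channel count and amplitude", {
  tr <- relax(two_state(), 0, c(1, 0), times = seq(0, 1, length.out = 20))
  flat <- relax(two_state(), 0, c(0.9, 0.1), times = seq(0, 1, length.out = 20))
  i1 <- ensemble_current(flat, 10000, 1)
  expect_equal(i1$current, rep(1000, 20), tolerance = 1e-9)
  i2 <- ensemble_current(tr, 5000, 2)
  i4 <- ensemble_current(tr, 10000, 2)
  expect_equal(2 * i2$current, i4$current, tolerance = 1e-12)
  # no conducting state -> identically zero
  ctrl <- state_model(c("a", "b"), c(FALSE, FALSE), data.frame(
    from = c("a", "b"), to = c("b", "a"), rate = 1, ligand_dependent = FALSE))
  tr0 <- relax(ctrl, 0, c(1, 0), times = c(0, 0.5, 1))
  expect_equal(ensemble_current(tr0, 10000, 1)$current, rep(0, 3))
})

test_that("gillespie is seed-deterministic and handles frozen models", {
  r1 <- gillespie(two_state(), 0, duration = 5, seed = 7)
  r2 <- gillespie(two_state(), 0, duration = 5, seed = 7)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$durations, r2$durations)
  expect_equal(sum(r1$durations), 5, tolerance = 1e-12)
  expect_true(all(diff(r1$states) != 0))
  expect_true(all(r1$durations > 0))

  frozen <- state_model(c("a", "b"), c(FALSE, TRUE), data.frame(
    from = c("a", "b"), to = c("b", "a"), rate = 0, ligand_dependent = FALSE))
  rec <- gillespie(frozen, 0, duration = 3, seed = 1, p0 = c(1, 0))
  expect_equal(rec$states, 1L)
  expect_equal(rec$durations, 3)
})

test_that("mean open dwell matches the exponential-dwell oracle", {
  rec <- gillespie(two_state(), 0, duration = 12000, seed = 11)
  dw <- dwell_times(rec)
  n <- length(dw$open_dwells)
  expect_gt(n, 1e4)
  se <- (1 / 9) / sqrt(n)
  expect_lt(abs(mean(dw$open_dwells) - 1 / 9), 3 * se)
})

test_that("open probability integrates conducting dwell time", {
  always_open <- state_model(c("o1", "o2"), c(TRUE, TRUE), data.frame(
    from = c("o1", "o2"), to = c("o2", "o1"), rate = 5,
    ligand_dependent = FALSE))
  rec <- gillespie(always_open, 0, 10, seed = 3, p0 = c(1, 0))
  expect_equal(open_probability(rec), 1)

  rec <- gillespie(two_state(), 0, duration = 500, seed = 5)
  # equilibrium oracle 0.1 with MC error from the relaxation time (0.1 s)
  se <- sqrt(0.1 * 0.9 / (500 / 0.2))
  expect_lt(abs(open_probability(rec) - 0.1), 3 * se)
})

test_that("gillespie ensemble mean tracks the eigen relaxation", {
  # two-state from all-closed: binomial standard errors at each time
  times <- c(0.05, 0.15, 0.4)
  n <- 3000
  ens <- gillespie_ensemble(two_state(), 0, times, n_channels = n,
                            seed = 100, p0 = c(1, 0))
  det <- relax(two_state(), 0, c(1, 0), times)$conducting_fraction
  se <- sqrt(pmax(det * (1 - det), 1e-6) / n)
  expect_true(all(abs(ens$conducting_fraction - det) < 4 * se))

  # six-state modulatory scheme during a 0 -> 100 uM jump
  m <- build_modulatory_model()
  p0 <- unname(equilibrium_occupancy(build_rate_matrix(m, 0)))
  times <- c(0.005, 0.02, 0.05)
  n <- 1500
  ens <- gillespie_ensemble(m, 100, times, n_channels = n, seed = 200,
                            p0 = p0)
  det <- relax(m, 100, p0, times)$conducting_fraction
  se <- sqrt(pmax(det * (1 - det), 1e-6) / n)
  expect_true(all(abs(ens$conducting_fraction - det) < 4 * se))
})
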