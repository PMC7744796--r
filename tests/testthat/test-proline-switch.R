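test_that("scheme builders produce the documented topologies", {
  m <- build_modulatory_model()
  expect_equal(n_states(m), 6)
  expect_equal(nrow(m$transitions), 12)
  expect_equal(m$states[m$conducting], c("open_trans", "open_cis"))

  mb <- build_modulatory_model(include_bound_isomerization = TRUE)
  expect_equal(nrow(mb$transitions), 14)

  s <- build_switch_model()
  expect_equal(n_states(s), 5)
  expect_equal(s$states[s$conducting], "open_trans")
  expect_true(validate_model(s)$ok)

  t3 <- build_trans_only_model()
  expect_equal(n_states(t3), 3)
  expect_equal(nrow(t3$transitions), 4)
})

test_that("apo isomerization balance sets the resting trans fraction", {
  # k_ct_apo / (k_ct_apo + k_tc_apo) = 0.4 for any absolute scale
  r <- proline_rates(k_ct_apo = 0.004, k_tc_apo = 0.006)
  p <- equilibrium_occupancy(build_rate_matrix(build_modulatory_model(r), 0))
  expect_equal(unname(p[["apo_trans"]]), 0.4, tolerance = 1e-9)
  expect_equal(unname(p[["apo_cis"]]), 0.6, tolerance = 1e-9)
})

test_that("bound-layer isomerization changes simulated outputs by < 1%", {
  off <- build_modulatory_model(include_bound_isomerization = FALSE)
  on <- build_modulatory_model(include_bound_isomerization = TRUE)
  tc_off <- simulate_activation_time_course(off)
  tc_on <- simulate_activation_time_course(on)
  expect_lt(max(abs(tc_on$activity - tc_off$activity) / tc_off$activity),
            0.01)
  conc <- 10^seq(0, 3, length.out = 8)
  dr_off <- simulate_dose_response(off, conc)
  dr_on <- simulate_dose_response(on, conc)
  expect_lt(max(abs(dr_on$response - dr_off$response) /
                  pmax(dr_off$response, 1e-6)), 0.01)
})

test_that("trans-only scheme activates completely within the mixing dead time", {
  tc <- simulate_activation_time_course(build_trans_only_model())
  expect_gte(tc$activity[1], 0.95)   # 12 ms point
  # saturating-binding limit: conducting occupancy = opening/(opening+closing)
  p <- equilibrium_occupancy(build_rate_matrix(build_trans_only_model(), 1e7))
  expect_equal(unname(p[["open"]]), 100 / (100 + 900), tolerance = 1e-4)
})

test_that("isomerase catalysis preserves every equilibrium occupancy", {
  models <- list(build_modulatory_model(), build_switch_model())
  for (m in models) {
    p_ref <- equilibrium_occupancy(build_rate_matrix(m, 100))
    for (f in c(1, 10, 1e3, 1e6)) {
      p <- equilibrium_occupancy(build_rate_matrix(apply_ppiase(m, f), 100))
      expect_lt(max(abs(p - p_ref)), 1e-9)
    }
  }
  # factor 1 is the identity
  m <- build_modulatory_model()
  expect_equal(apply_ppiase(m, 1)$transitions$rate, m$transitions$rate)
  expect_error(apply_ppiase(m, 0.5), ">= 1")
  # only isomerization rates are touched
  mp <- apply_ppiase(m, 100)
  iso <- m$transitions$kind == "isomerization"
  expect_equal(mp$transitions$rate[!iso], m$transitions$rate[!iso])
  expect_equal(mp$transitions$rate[iso], 100 * m$transitions$rate[iso])
})

test_that("isomerase catalysis abolishes the slow activation phase", {
  wt <- build_modulatory_model()
  tc_wt <- simulate_activation_time_course(wt)
  fit_wt <- fit_double_exponential(tc_wt$delay_s, tc_wt$activity)
  expect_false(fit_wt$degenerate)
  slow_share_wt <- fit_wt$a2 / (fit_wt$a1 + fit_wt$a2)
  expect_gt(slow_share_wt, 0.2)      # wild type is clearly bi-phasic

  cat_tc <- simulate_activation_time_course(apply_ppiase(wt))
  expect_gte(cat_tc$activity[1], 0.95)   # maximal at 12 ms
  fit_cat <- fit_double_exponential(cat_tc$delay_s, cat_tc$activity)
  slow_amp <- if (fit_cat$degenerate) 0 else
    abs(fit_cat$a2) / (abs(fit_cat$a1) + abs(fit_cat$a2))
  expect_lt(slow_amp, 0.05)
})

test_that("wild-type activation is bi-phasic with well-separated components", {
  tc <- simulate_activation_time_course(build_modulatory_model())
  fit <- fit_double_exponential(tc$delay_s, tc$activity)
  expect_false(fit$degenerate)
  expect_gte(fit$k1 / fit$k2, 10)
  expect_lt(1 / fit$k1, 0.1)              # millisecond-range fast phase
  expect_gt(1 / fit$k2, 0.2)              # second-range slow phase
  expect_lt(1 / fit$k2, 10)
})

test_that("EC50 decreases with delay for the modulatory but not the switch scheme", {
  conc <- 10^seq(0, 3, length.out = 10)
  ec50 <- function(m, delay)
    fit_hill(simulate_dose_response(m, conc, delay))$ec50

  wt <- build_modulatory_model()
  e_short <- ec50(wt, 2.5)
  e_long <- ec50(wt, 2700)
  expect_lt(e_long, 0.9 * e_short)        # clear decrease

  sw <- build_switch_model()
  s_short <- ec50(sw, 2.5)
  s_long <- ec50(sw, 2700)
  expect_gte(s_long, 0.9 * s_short)       # no decrease beyond tolerance

  # ordering at 2.5 s: trans-only <= catalyzed WT < untreated WT
  e_trans <- ec50(build_trans_only_model(), 2.5)
  e_ppiase <- ec50(apply_ppiase(wt), 2.5)
  expect_lte(e_trans, e_ppiase)
  expect_lt(e_ppiase, e_short)
})

test_that("switch scheme still shows bi-phasic activation", {
  tc <- simulate_activation_time_course(build_switch_model(), camp = 100)
  fit <- fit_double_exponential(tc$delay_s, tc$activity)
  expect_false(fit$degenerate)
  expect_gte(fit$k1 / fit$k2, 10)
  # conducting occupancy at saturating ligand is all trans-branch
  p <- equilibrium_occupancy(build_rate_matrix(build_switch_model(), 1000))
  expect_gte(unname(p[["open_trans"]]) / sum(p[build_switch_model()$conducting]),
             0.99)
})

test_that("single-species dose-response half-activates at its equilibrium EC50", {
  # trans-only scheme at long delay: closed-form half-activation at
  # Kd * closing / (opening + closing)
  m <- build_trans_only_model()
  conc <- 10^seq(-0.5, 3, length.out = 12)
  dr <- simulate_dose_response(m, conc, delay = 1000, normalize = FALSE)
  half_conc <- 24 * 900 / 1000        # Kd * closing/(opening + closing)
  y_half <- concentration_jump(m, 0, half_conc, times = 1000)$conducting_fraction
  expect_equal(fit_hill(dr)$ec50, half_conc, tolerance = 0.02)
  expect_equal(y_half, 0.1 / 2, tolerance = 1e-6)  # half the Po asymptote
})

test_that("mixture-affinity algebra reproduces the printed worked cases", {
  # solving for the cis affinity of a 40% trans mixture
  res <- solve_mixture_affinity(X = 0.4, ec50_trans = 24, ec50_apparent = 107)
  expect_equal(res$ec50_cis, (107 - 0.4 * 24) / 0.6, tolerance = 1e-12)
  expect_equal(res$ec50_cis, 162.33, tolerance = 1e-4)

  # solving for the trans content of the isomerase-equilibrated state
  res <- solve_mixture_affinity(ec50_trans = 24, ec50_cis = 160,
                                ec50_apparent = 35)
  expect_equal(res$X, 125 / 136, tolerance = 1e-12)
  expect_equal(round(res$X, 3), 0.919)

  # pure-trans limit: apparent equals trans for any cis value
  for (cis in c(50, 160, 1e4)) {
    res <- solve_mixture_affinity(X = 1, ec50_trans = 24, ec50_cis = cis)
    expect_equal(res$ec50_apparent, 24)
  }
})

test_that("mixture-affinity solutions round-trip and reject impossible inputs", {
  set.seed(1)
  for (i in 1:25) {
    x <- runif(1, 0.05, 0.95)
    et <- runif(1, 5, 50)
    ec <- et + runif(1, 10, 500)
    ea <- x * et + (1 - x) * ec
    expect_equal(solve_mixture_affinity(X = x, ec50_trans = et,
                                        ec50_cis = ec)$ec50_apparent,
                 ea, tolerance = 1e-9)
    expect_equal(solve_mixture_affinity(X = x, ec50_trans = et,
                                        ec50_apparent = ea)$ec50_cis,
                 ec, tolerance = 1e-9)
    expect_equal(solve_mixture_affinity(X = x, ec50_cis = ec,
                                        ec50_apparent = ea)$ec50_trans,
                 et, tolerance = 1e-9)
    expect_equal(solve_mixture_affinity(ec50_trans = et, ec50_cis = ec,
                                        ec50_apparent = ea)$X,
                 x, tolerance = 1e-9)
  }
  # apparent outside the [trans, cis] bracket implies X outside [0, 1]
  expect_error(solve_mixture_affinity(ec50_trans = 24, ec50_cis = 160,
                                      ec50_apparent = 300), "outside")
  expect_error(solve_mixture_affinity(X = 0.9, ec50_trans = 200,
                                      ec50_apparent = 10), "nonpositive")
  expect_error(solve_mixture_affinity(X = 0.4, ec50_trans = 24), "exactly three")
})

test_that("isomerization free energy matches the 60/40 -> 10/90 shift", {
  dd <- isomerization_free_energy(0.4, 0.9)
  expect_equal(dd, 8.314 * 298.15 * log(13.5) / 1000, tolerance = 1e-12)
  expect_equal(round(dd, 1), 6.5)
  # no shift, antisymmetry, domain errors
  expect_equal(isomerization_free_energy(0.55, 0.55), 0)
  expect_equal(isomerization_free_energy(0.9, 0.4),
               -isomerization_free_energy(0.4, 0.9), tolerance = 1e-12)
  expect_error(isomerization_free_energy(0, 0.9), "strictly inside")
  expect_error(isomerization_free_energy(0.4, 1), "strictly inside")
})

test_that("the default rate set passes the full calibration suite", {
  cc <- calibration_check()
  expect_true(cc$biphasic_activation$pass)
  expect_true(cc$single_channel_gating$pass)
  expect_true(cc$ec50_shift$pass)
})
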