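#' Microscopic rate set for the proline-switch gating schemes
#'
#' Collects the rate constants of the six-state modulatory scheme: a slow
#' cis/trans isomerization layer (apo and open states), per-species cAMP
#' binding, and per-species open/close gating.  All first-order rates in
#' s^-1, binding rates in uM^-1 s^-1.
#'
#' The defaults are a calibrated set chosen to satisfy, qualitatively, the
#' three requirements the experiments impose on any candidate mechanism:
#' (1) bi-phasic macroscopic activation with millisecond and second
#' components, (2) millisecond single-channel gating at open probability
#' ~0.1, and (3) an apparent cAMP affinity that improves as the cis pool
#' converts to trans over delay time.  The apo isomerization equilibrium
#' puts 40% of channels in the trans form
#' (`k_ct_apo / (k_ct_apo + k_tc_apo) = 0.4`), and the open-state
#' isomerization favours trans 9:1.  When `opening_cis`/`closing_cis` are
#' left `NULL` the cis gating equilibrium is derived from thermodynamic
#' cycle closure,
#' \deqn{K_{gate}^{cis} = K_{gate}^{trans}
#'       \frac{K_d^{cis}/K_d^{trans}}{K_{iso}^{open}/K_{iso}^{apo}},}
#' so the six-state cycle satisfies microscopic reversibility exactly and
#' isomerase catalysis (see [apply_ppiase()]) provably leaves every
#' stationary occupancy unchanged.  `cis_gating_total` then sets the cis
#' opening + closing sum, i.e. the time scale of the slow activation
#' phase (default 1.24 s^-1, a ~1 s phase).
#'
#' @param k_ct_apo,k_tc_apo apo-state isomerization rates (cis->trans,
#'   trans->cis), s^-1.
#' @param k_on_trans,k_off_trans trans-species binding, uM^-1 s^-1 and
#'   s^-1 (default Kd 24 uM).
#' @param opening_trans,closing_trans trans-species gating, s^-1
#'   (default Po 0.1, millisecond dwells).
#' @param k_on_cis,k_off_cis cis-species binding (default Kd 800 uM).
#' @param opening_cis,closing_cis cis-species gating; `NULL` (default)
#'   derives them from cycle closure and `cis_gating_total`.
#' @param cis_gating_total summed cis opening + closing rate, s^-1.
#' @param k_ct_open,k_tc_open open-state isomerization rates, s^-1
#'   (default sum 1e-3 s^-1: re-equilibration over tens of minutes).
#' @return list of class `proline_rates`.
#' @seealso [build_modulatory_model()], [build_switch_model()],
#'   [build_trans_only_model()]
#' @export
proline_rates <- function(k_ct_apo = 0.02, k_tc_apo = 0.03,
                          k_on_trans = 10, k_off_trans = 240,
                          opening_trans = 100, closing_trans = 900,
                          k_on_cis = 10, k_off_cis = 8000,
                          opening_cis = NULL, closing_cis = NULL,
                          cis_gating_total = 1.24,
                          k_ct_open = 9e-4, k_tc_open = 1e-4) {
  if (is.null(opening_cis) != is.null(closing_cis))
    stop("supply both opening_cis and closing_cis, or neither")
  if (is.null(opening_cis)) {
    kd_t <- k_off_trans / k_on_trans
    kd_c <- k_off_cis / k_on_cis
    shift <- (k_ct_open / k_tc_open) / (k_ct_apo / k_tc_apo)
    k_gate_cis <- (opening_trans / closing_trans) * (kd_c / kd_t) / shift
    opening_cis <- cis_gating_total * k_gate_cis / (1 + k_gate_cis)
    closing_cis <- cis_gating_total - opening_cis
  }
  r <- list(k_ct_apo = k_ct_apo, k_tc_apo = k_tc_apo,
            k_on_trans = k_on_trans, k_off_trans = k_off_trans,
            opening_trans = opening_trans, closing_trans = closing_trans,
            k_on_cis = k_on_cis, k_off_cis = k_off_cis,
            opening_cis = opening_cis, closing_cis = closing_cis,
            k_ct_open = k_ct_open, k_tc_open = k_tc_open)
  bad <- names(r)[vapply(r, function(x) !is.numeric(x) || is.na(x) || x < 0,
                         TRUE)]
  if (length(bad) > 0)
    stop("rates must be nonnegative numbers: ", paste(bad, collapse = ", "))
  class(r) <- "proline_rates"
  r
}

#' @export
print.proline_rates <- function(x, ...) {
  cat("<proline_rates>\n")
  cat(sprintf("  apo iso    cis->trans %g, trans->cis %g s^-1 (trans frac %.2f)\n",
              x$k_ct_apo, x$k_tc_apo, x$k_ct_apo / (x$k_ct_apo + x$k_tc_apo)))
  cat(sprintf("  trans      Kd %g uM, gating %g/%g s^-1\n",
              x$k_off_trans / x$k_on_trans, x$opening_trans, x$closing_trans))
  cat(sprintf("  cis        Kd %g uM, gating %g/%g s^-1\n",
              x$k_off_cis / x$k_on_cis, x$opening_cis, x$closing_cis))
  cat(sprintf("  open iso   cis->trans %g, trans->cis %g s^-1\n",
              x$k_ct_open, x$k_tc_open))
  invisible(x)
}

# internal: reversible transition pair
pair_df <- function(from, to, fwd, bwd, ligand_dep = FALSE, kind = NA) {
  data.frame(from = c(from, to), to = c(to, from), rate = c(fwd, bwd),
             ligand_dependent = ligand_dep, kind = kind)
}

#' Build the six-state modulatory proline-switch scheme
#'
#' Both the cis and the trans Pro species bind ligand and open, with
#' different affinities and kinetics; isomerization connects the two
#' branches in the apo layer and in the open layer.  States (in order):
#' apo_trans, apo_cis, bound_trans, bound_cis, open_trans, open_cis, with
#' reversible pairs apo_trans<->apo_cis, apo_trans<->bound_trans,
#' apo_cis<->bound_cis, bound_trans<->open_trans, bound_cis<->open_cis,
#' open_trans<->open_cis.  Bound-layer isomerization is omitted by
#' default; when `include_bound_isomerization = TRUE` it is added with the
#' open-layer rates (the bound and open layers are both liganded, so equal
#' rates are the natural assumption) and changes simulated outputs by well
#' under 1%.
#'
#' @param rates a [proline_rates()] set.
#' @param include_bound_isomerization add the bound_trans<->bound_cis pair.
#' @return a [state_model()] with 6 states (2 conducting) and 12 (or 14)
#'   directed transitions.
#' @examples
#' m <- build_modulatory_model()
#' equilibrium_occupancy(build_rate_matrix(m, 0))  # 40% trans at rest
#' @export
build_modulatory_model <- function(rates = proline_rates(),
                                   include_bound_isomerization = FALSE) {
  r <- rates
  tr <- rbind(
    pair_df("apo_trans", "apo_cis", r$k_tc_apo, r$k_ct_apo,
            kind = "isomerization"),
    pair_df("apo_trans", "bound_trans", r$k_on_trans, NA, kind = "binding"),
    pair_df("apo_cis", "bound_cis", r$k_on_cis, NA, kind = "binding"),
    pair_df("bound_trans", "open_trans", r$opening_trans, r$closing_trans,
            kind = "gating"),
    pair_df("bound_cis", "open_cis", r$opening_cis, r$closing_cis,
            kind = "gating"),
    pair_df("open_trans", "open_cis", r$k_tc_open, r$k_ct_open,
            kind = "isomerization"))
  # binding forward legs are ligand-dependent; unbinding is first order
  tr$rate[3] <- r$k_on_trans; tr$rate[4] <- r$k_off_trans
  tr$rate[5] <- r$k_on_cis;   tr$rate[6] <- r$k_off_cis
  tr$ligand_dependent <- FALSE
  tr$ligand_dependent[c(3, 5)] <- TRUE
  if (include_bound_isomerization)
    tr <- rbind(tr, pair_df("bound_trans", "bound_cis", r$k_tc_open,
                            r$k_ct_open, kind = "isomerization"))
  state_model(
    states = c("apo_trans", "apo_cis", "bound_trans", "bound_cis",
               "open_trans", "open_cis"),
    conducting = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    transitions = tr,
    metadata = list(mechanism = "modulatory",
                    bound_isomerization = include_bound_isomerization))
}

#' Build the on/off-switch variant of the proline scheme
#'
#' The alternative mechanism in which the cis Pro channel form essentially
#' never opens: the cis open state is removed (cis opening rate 0), so all
#' conducting occupancy comes from the trans branch and channel
#' recruitment is tied directly to isomerization.  This scheme reproduces
#' bi-phasic activation but, unlike the modulatory scheme, produces no
#' delay-dependent decrease of the apparent cAMP EC50 - the
#' model-discrimination result.
#'
#' @inheritParams build_modulatory_model
#' @return a [state_model()] with 5 states (1 conducting).
#' @export
build_switch_model <- function(rates = proline_rates()) {
  r <- rates
  tr <- rbind(
    pair_df("apo_trans", "apo_cis", r$k_tc_apo, r$k_ct_apo,
            kind = "isomerization"),
    pair_df("apo_trans", "bound_trans", r$k_on_trans, r$k_off_trans,
            kind = "binding"),
    pair_df("apo_cis", "bound_cis", r$k_on_cis, r$k_off_cis,
            kind = "binding"),
    pair_df("bound_trans", "open_trans", r$opening_trans, r$closing_trans,
            kind = "gating"))
  tr$ligand_dependent[c(3, 5)] <- TRUE
  state_model(
    states = c("apo_trans", "apo_cis", "bound_trans", "bound_cis",
               "open_trans"),
    conducting = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    transitions = tr,
    metadata = list(mechanism = "switch"))
}

#' Build the trans-only three-state scheme (P300A-like mimic)
#'
#' Models a channel locked in the trans Pro configuration (as when the
#' proline is substituted by alanine): a single apo -> bound -> open
#' branch using the trans-species rates.  Activation is complete within
#' the shortest stopped-flow mixing time.
#'
#' @inheritParams build_modulatory_model
#' @return a [state_model()] with 3 states (1 conducting), 4 directed
#'   transitions.
#' @export
build_trans_only_model <- function(rates = proline_rates()) {
  r <- rates
  tr <- rbind(
    pair_df("apo", "bound", r$k_on_trans, r$k_off_trans, kind = "binding"),
    pair_df("bound", "open", r$opening_trans, r$closing_trans,
            kind = "gating"))
  tr$ligand_dependent[1] <- TRUE
  state_model(states = c("apo", "bound", "open"),
              conducting = c(FALSE, FALSE, TRUE),
              transitions = tr,
              metadata = list(mechanism = "trans_only"))
}

#' Apply peptidyl-prolyl isomerase catalysis to a scheme
#'
#' Multiplies every isomerization transition rate (both directions, in
#' every layer that has them) by the same acceleration factor, leaving all
#' binding and gating rates untouched.  Catalysis lowers the kinetic
#' barrier without moving the equilibrium, so for the thermodynamically
#' closed default schemes every stationary occupancy is unchanged for any
#' factor.
#'
#' The default factor of 1e6 is chosen so that catalyzed isomerization
#' out-runs ligand capture of the cis species and re-equilibrates the
#' cis/trans pools within the shortest mixing delay (12 ms), which is the
#' observed phenotype with micromolar isomerase; see the methods vignette
#' for the competition argument.
#'
#' @param model a scheme from one of the builders (transitions must carry
#'   the `kind` annotation).
#' @param acceleration multiplicative factor >= 1.
#' @return the modified [state_model()].
#' @export
apply_ppiase <- function(model, acceleration = 1e6) {
  if (!is.numeric(acceleration) || acceleration < 1)
    stop("acceleration factor must be >= 1")
  iso <- !is.na(model$transitions$kind) &
    model$transitions$kind == "isomerization"
  if (!any(iso) && acceleration > 1)
    warning("model has no isomerization transitions; nothing to accelerate")
  model$transitions$rate[iso] <- model$transitions$rate[iso] * acceleration
  model$metadata$ppiase_acceleration <-
    (model$metadata$ppiase_acceleration %||% 1) * acceleration
  model
}

#' Mixture-affinity algebra for a two-species channel population
#'
#' For a population that is a frozen mixture of a trans fraction `X` with
#' apparent affinity `ec50_trans` and a cis fraction `1 - X` with
#' `ec50_cis`, the measured apparent affinity is the weighted sum
#' \deqn{X \cdot EC_{50}^{trans} + (1 - X) \cdot EC_{50}^{cis} =
#'       EC_{50}^{apparent}.}
#' Given any three of the four quantities this solves for the fourth.
#'
#' @param X trans fraction in [0, 1], or `NULL` to solve for it.
#' @param ec50_trans,ec50_cis,ec50_apparent affinities in uM (> 0), or
#'   `NULL` for the unknown.  Exactly one argument must be `NULL`.
#' @return list of class `mixture_affinity` with all four fields and
#'   `solved_for` naming the computed one.  Inputs implying X outside
#'   [0, 1] or a nonpositive EC50 are an error, not a clamp.
#' @examples
#' # apparent affinity 107 uM for a 40% trans mixture with trans at 24 uM
#' solve_mixture_affinity(X = 0.4, ec50_trans = 24, ec50_apparent = 107)
#' @export
solve_mixture_affinity <- function(X = NULL, ec50_trans = NULL,
                                   ec50_cis = NULL, ec50_apparent = NULL) {
  given <- list(X = X, ec50_trans = ec50_trans, ec50_cis = ec50_cis,
                ec50_apparent = ec50_apparent)
  unknown <- names(given)[vapply(given, is.null, TRUE)]
  if (length(unknown) != 1)
    stop("supply exactly three of X, ec50_trans, ec50_cis, ec50_apparent")
  for (nm in setdiff(names(given), unknown)) {
    val <- given[[nm]]
    if (!is.numeric(val) || length(val) != 1 || is.na(val))
      stop(nm, " must be a single number")
    if (nm == "X") {
      if (val < 0 || val > 1) stop("X must lie in [0, 1]")
    } else if (val <= 0) stop(nm, " must be positive")
  }
  out <- given
  out[[unknown]] <- switch(
    unknown,
    ec50_apparent = X * ec50_trans + (1 - X) * ec50_cis,
    ec50_trans = {
      if (X == 0) stop("X = 0: ec50_trans is unconstrained")
      (ec50_apparent - (1 - X) * ec50_cis) / X
    },
    ec50_cis = {
      if (X == 1) stop("X = 1: ec50_cis is unconstrained")
      (ec50_apparent - X * ec50_trans) / (1 - X)
    },
    X = (ec50_apparent - ec50_cis) / (ec50_trans - ec50_cis))
  if (unknown == "X" && (out$X < 0 || out$X > 1))
    stop(sprintf("inputs imply trans fraction %.4f outside [0, 1]", out$X))
  if (unknown != "X" && out[[unknown]] <= 0)
    stop(sprintf("inputs imply nonpositive %s (%.4f uM)", unknown,
                 out[[unknown]]))
  structure(c(out, list(solved_for = unknown)), class = "mixture_affinity")
}

#' @export
print.mixture_affinity <- function(x, ...) {
  cat("<mixture_affinity>\n")
  for (nm in c("X", "ec50_trans", "ec50_cis", "ec50_apparent"))
    cat(sprintf("  %-13s %.4g%s%s\n", nm, x[[nm]],
                if (nm == "X") "" else " uM",
                if (nm == x$solved_for) "   (solved)" else ""))
  invisible(x)
}

#' Free-energy shift of a cis/trans equilibrium between two channel states
#'
#' The difference in isomerization free energy between two conformational
#' states of the channel (e.g. resting/apo vs open), computed from the
#' trans fractions in each:
#' \deqn{\Delta\Delta G = R T \ln\frac{X_{open}/(1 - X_{open})}
#'                                    {X_{apo}/(1 - X_{apo})}}
#' with R = 8.314 J mol^-1 K^-1.  A shift from 40% trans at rest to 90%
#' trans in the open state at 25 C corresponds to ~6.5 kJ/mol, the scale
#' of about two hydrogen bonds.
#'
#' @param trans_frac_apo,trans_frac_open trans fractions strictly inside
#'   (0, 1).
#' @param temperature absolute temperature in K (default 298.15, i.e.
#'   25 C assay temperature).
#' @return free-energy difference in kJ/mol (positive when the open state
#'   favours trans more than the apo state does).
#' @examples
#' isomerization_free_energy(0.4, 0.9)  # ~6.5 kJ/mol
#' @export
isomerization_free_energy <- function(trans_frac_apo, trans_frac_open,
                                      temperature = 298.15) {
  for (f in c(trans_frac_apo, trans_frac_open))
    if (!is.numeric(f) || is.na(f) || f <= 0 || f >= 1)
      stop("trans fractions must lie strictly inside (0, 1)")
  if (temperature <= 0) stop("temperature must be positive (K)")
  R <- 8.314
  odds <- (trans_frac_open / (1 - trans_frac_open)) /
    (trans_frac_apo / (1 - trans_frac_apo))
  R * temperature * log(odds) / 1000
}

#' Simulated activation time course over stopped-flow delay times
#'
#' Runs a 0 -> `camp` concentration jump and reads the conducting fraction
#' at each delay, normalized to its long-time (equilibrium) maximum - the
#' in-silico analogue of plotting initial flux rates against the delay
#' between ligand mixing and the flux read-out.
#'
#' @param model a [state_model()].
#' @param camp cAMP concentration after the jump, uM.
#' @param delays positive, sorted delay times in s; default 8
#'   logarithmically spaced points spanning 12 ms to 10 s.
#' @param normalize divide by the equilibrium conducting fraction.
#' @return data frame with columns `delay_s` and `activity`.
#' @export
simulate_activation_time_course <- function(model, camp = 100,
                                            delays = default_delays(),
                                            normalize = TRUE) {
  if (any(delays <= 0) || is.unsorted(delays))
    stop("delays must be positive and sorted")
  traj <- concentration_jump(model, 0, camp, times = delays)
  act <- traj$conducting_fraction
  if (normalize) {
    if (traj$equilibrium_level <= 0)
      stop("model has no conducting occupancy at this concentration")
    act <- act / traj$equilibrium_level
  }
  data.frame(delay_s = delays, activity = act)
}

#' Default stopped-flow delay grid: 8 log-spaced points, 12 ms to 10 s
#' @param n number of delay points.
#' @param from,to first and last delay, s.
#' @return numeric vector of delays.
#' @export
default_delays <- function(n = 8, from = 0.012, to = 10)
  exp(seq(log(from), log(to), length.out = n))

#' Simulated cAMP dose-response curve at a fixed delay time
#'
#' For each concentration, equilibrates the scheme ligand-free, applies
#' the concentration, and reads the conducting fraction after `delay`
#' seconds; responses are normalized to the within-curve maximum, making
#' the result directly Hill-fittable (see [fit_hill()]).
#'
#' @param model a [state_model()].
#' @param concentrations cAMP concentrations in uM (> 0).
#' @param delay incubation time before the read-out, s (default 2.5 s,
#'   the short-delay protocol).
#' @param normalize divide by the curve maximum.
#' @return data frame of class `dose_response` with columns `camp_uM` and
#'   `response`, attribute `delay_s`.
#' @export
simulate_dose_response <- function(model, concentrations, delay = 2.5,
                                   normalize = TRUE) {
  if (any(concentrations <= 0)) stop("concentrations must be positive (uM)")
  resp <- vapply(concentrations, function(cc)
    concentration_jump(model, 0, cc, times = delay)$conducting_fraction,
    numeric(1))
  if (normalize && max(resp) > 0) resp <- resp / max(resp)
  out <- data.frame(camp_uM = concentrations, response = resp)
  attr(out, "delay_s") <- delay
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Check a rate set against the three mechanism-calibration requirements
#'
#' Any candidate rate set for the modulatory scheme must reproduce three
#' qualitative signatures: (1) bi-phasic macroscopic activation with the
#' fast and slow components in the millisecond and second ranges, (2)
#' open probability near 0.1 with millisecond openings at saturating
#' ligand, and (3) an apparent EC50 that decreases as the incubation
#' delay grows, with the isomerase-equilibrated and trans-only curves
#' left-shifted relative to the short-delay wild-type curve.
#'
#' @param rates a [proline_rates()] set.
#' @param camp concentration used for the activation time course, uM.
#' @param concentrations grid for the dose-response fits, uM.
#' @return list of class `calibration_check` with per-requirement pass
#'   flags and the measured quantities.
#' @export
calibration_check <- function(rates = proline_rates(), camp = 100,
                              concentrations = 10^seq(0, 3, length.out = 10)) {
  wt <- build_modulatory_model(rates)

  # (1) bi-phasic activation
  tc <- simulate_activation_time_course(wt, camp = camp)
  fit <- fit_double_exponential(tc$delay_s, tc$activity)
  biphasic <- !fit$degenerate && fit$k1 / fit$k2 >= 10 &&
    1 / fit$k1 < 0.1 && 1 / fit$k2 > 0.2 && 1 / fit$k2 < 10

  # (2) Po ~ 0.1, millisecond openings (deterministic: equilibrium +
  # dominant open-state exit rate)
  Q <- build_rate_matrix(wt, 1000)
  p <- equilibrium_occupancy(Q)
  po <- sum(p[wt$conducting])
  main_open <- which(wt$conducting)[which.max(p[wt$conducting])]
  dwell <- 1 / -unclass_rate_matrix(Q)[main_open, main_open]
  gating_ok <- po >= 0.05 && po <= 0.15 && dwell < 0.01

  # (3) EC50 ordering and delay shift
  ec50 <- function(m, delay) fit_hill(
    simulate_dose_response(m, concentrations, delay))$ec50
  e_wt_short <- ec50(wt, 2.5)
  e_wt_long <- ec50(wt, 2700)
  e_ppiase <- ec50(apply_ppiase(wt), 2.5)
  e_trans <- ec50(build_trans_only_model(rates), 2.5)
  shift_ok <- e_wt_long < 0.9 * e_wt_short &&
    e_ppiase < e_wt_short && e_trans <= e_ppiase

  structure(list(
    biphasic_activation = list(pass = biphasic, k_fast = fit$k1,
                               k_slow = fit$k2),
    single_channel_gating = list(pass = gating_ok, po = po,
                                 main_open_dwell_s = dwell),
    ec50_shift = list(pass = shift_ok, wt_short = e_wt_short,
                      wt_long = e_wt_long, ppiase = e_ppiase,
                      trans_only = e_trans),
    pass = biphasic && gating_ok && shift_ok),
    class = "calibration_check")
}

#' @export
print.calibration_check <- function(x, ...) {
  mark <- function(ok) if (ok) "PASS" else "FAIL"
  cat("<calibration_check>", mark(x$pass), "\n")
  cat(sprintf("  bi-phasic activation  %s (k_fast %.3g, k_slow %.3g s^-1)\n",
              mark(x$biphasic_activation$pass), x$biphasic_activation$k_fast,
              x$biphasic_activation$k_slow))
  cat(sprintf("  single-channel gating %s (Po %.3f, dwell %.3g s)\n",
              mark(x$single_channel_gating$pass), x$single_channel_gating$po,
              x$single_channel_gating$main_open_dwell_s))
  cat(sprintf(
    "  EC50 shift            %s (WT 2.5 s %.3g -> long %.3g; +PPIase %.3g; trans-only %.3g uM)\n",
    mark(x$ec50_shift$pass), x$ec50_shift$wt_short, x$ec50_shift$wt_long,
    x$ec50_shift$ppiase, x$ec50_shift$trans_only))
  invisible(x)
}
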