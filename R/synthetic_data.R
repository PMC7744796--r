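#' Stopped-flow assay protocol description
#'
#' Bundles the acquisition parameters shared by the synthetic trace
#' generators: the delay-time series between ligand mixing and the flux
#' read-out, the ligand series, trace length and sampling, and the noise
#' level.  Defaults mirror the standard acquisition: 5000 points over
#' 1 s, delays log-spaced from 12 ms to 10 s.
#'
#' @param delays delay times in s (positive).
#' @param camp cAMP concentration series in uM (positive).
#' @param trace_duration length of each quench trace, s.
#' @param n_points samples per trace (>= 100).
#' @param noise_sigma Gaussian noise standard deviation as a fraction of
#'   the quench amplitude.
#' @param seed base integer seed for the generators.
#' @return list of class `assay_protocol`.
#' @export
assay_protocol <- function(delays = default_delays(), camp = 100,
                           trace_duration = 1, n_points = 5000,
                           noise_sigma = 0.01, seed = 1) {
  if (any(delays <= 0)) stop("delays must be positive")
  if (any(camp <= 0)) stop("cAMP concentrations must be positive")
  if (n_points < 100) stop("need at least 100 points per trace")
  structure(list(delays = delays, camp = camp,
                 trace_duration = trace_duration,
                 n_points = as.integer(n_points),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "assay_protocol")
}

#' Generate a synthetic stretched-exponential quench trace
#'
#' Evaluates the stretched-exponential quench curve on the protocol's
#' time grid and adds i.i.d. Gaussian noise scaled to the quench
#' amplitude.  The generator is a pure function of its parameters and the
#' seed; with `noise_sigma = 0` the trace equals the noiseless curve and
#' the seed is irrelevant.
#'
#' @param f0,finf initial and final fluorescence (a.u., `f0 >= finf`).
#' @param tau time constant in s (> 0).
#' @param beta stretching exponent in (0, 1].
#' @param protocol an [assay_protocol()] providing the time grid.
#' @param noise_sigma noise SD as a fraction of `f0 - finf`; defaults to
#'   the protocol's value.
#' @param seed integer seed; defaults to the protocol's.
#' @param delay,camp optional metadata stored on the trace.
#' @return a [quench_trace()].
#' @export
gen_quench_trace <- function(f0, finf, tau, beta,
                             protocol = assay_protocol(),
                             noise_sigma = protocol$noise_sigma,
                             seed = protocol$seed,
                             delay = NA, camp = NA) {
  if (tau <= 0) stop("tau must be positive")
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  if (f0 < finf) stop("f0 must be >= finf for a quenching trace")
  times <- seq(0, protocol$trace_duration,
               length.out = protocol$n_points)
  f <- finf + (f0 - finf) * exp(-(times / tau)^beta)
  if (noise_sigma > 0)
    f <- f + withr::with_seed(as.integer(seed),
      stats::rnorm(length(f), sd = noise_sigma * (f0 - finf)))
  quench_trace(times, f, delay = delay, camp = camp, seed = seed)
}

#' Simulate a full stopped-flow flux experiment from a gating model
#'
#' Couples a kinetic scheme to the quench read-out: for every
#' (delay, cAMP) combination in the protocol the conducting fraction
#' after a 0 -> cAMP concentration jump sets the target initial influx
#' rate
#' \deqn{k^* = k_{leak} + k_{max} \cdot conducting\_fraction(delay),}
#' the stretched-exponential time constant is obtained by inverting the
#' influx-rate relation at fixed beta
#' (\eqn{\tau = (\beta t_{eval}^{\beta-1}/k^*)^{1/\beta}}), and a noisy
#' trace is generated.  A model with no conducting occupancy yields
#' leak-only traces, the analogue of the protein-free or ligand-free
#' controls.
#'
#' @param model a [state_model()].
#' @param protocol an [assay_protocol()].
#' @param k_max_rate influx rate at conducting fraction 1, s^-1.  The
#'   default (250) puts saturating channel activity near 15-20 s^-1 at
#'   the 2 ms evaluation time, i.e. quench largely complete within the
#'   100 ms analysis window, matching the dynamic range of the assay;
#'   much slower traces leave the stretched-exponential inversion
#'   ill-conditioned under noise.
#' @param leak leak quench rate in the absence of channel activity, s^-1.
#' @param beta stretching exponent used for all traces.
#' @param f0,finf trace fluorescence limits.
#' @param seed base seed; trace `i` uses `seed + i`.
#' @return list of class `stopped_flow_experiment`: `traces` (list of
#'   [quench_trace()]) and `manifest` (data frame with per-trace delay,
#'   cAMP, target rate, tau, seed - the generation truth).
#' @export
gen_stopped_flow_experiment <- function(model, protocol = assay_protocol(),
                                        k_max_rate = 250, leak = 0.5,
                                        beta = 0.8, f0 = 1, finf = 0.2,
                                        seed = protocol$seed) {
  assert_valid_model(model)
  grid <- expand.grid(delay = protocol$delays, camp = protocol$camp,
                      KEEP.OUT.ATTRS = FALSE)
  # conducting fraction at each delay for each concentration
  cf <- numeric(nrow(grid))
  for (cc in unique(grid$camp)) {
    rows <- which(grid$camp == cc)
    traj <- concentration_jump(model, 0, cc, times = grid$delay[rows])
    cf[rows] <- traj$conducting_fraction
  }
  k_target <- leak + k_max_rate * cf
  k_target[k_target <= 0] <- leak
  tau <- (beta * 0.002^(beta - 1) / k_target)^(1 / beta)

  traces <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid)))
    traces[[i]] <- gen_quench_trace(
      f0 = f0, finf = finf, tau = tau[i], beta = beta, protocol = protocol,
      seed = seed + i, delay = grid$delay[i], camp = grid$camp[i])
  manifest <- data.frame(delay_s = grid$delay, camp_uM = grid$camp,
                         conducting_fraction = cf, k_target = k_target,
                         tau = tau, beta = beta, seed = seed + seq_len(nrow(grid)),
                         noise_sigma = protocol$noise_sigma)
  structure(list(traces = traces, manifest = manifest),
            class = "stopped_flow_experiment")
}

#' @export
print.stopped_flow_experiment <- function(x, ...) {
  cat(sprintf("<stopped_flow_experiment> %d traces (%d delays x %d [cAMP])\n",
              length(x$traces), length(unique(x$manifest$delay_s)),
              length(unique(x$manifest$camp_uM))))
  invisible(x)
}

#' Generate a synthetic peptide-isomerization trace
#'
#' Rising mono-exponential fluorescence, as in the solvent-jump
#' peptide assay where the fluorescence increase reports the cis/trans
#' re-equilibration of an Xaa-Pro bond, plus Gaussian noise.
#'
#' @param k_app apparent isomerization rate, s^-1 (> 0).
#' @param amplitude fluorescence amplitude (a.u.).
#' @param noise Gaussian noise SD in absolute units.
#' @param duration trace length, s.
#' @param seed integer seed.
#' @param f0 baseline fluorescence.
#' @param n_points samples.
#' @return data frame with `time_s` and `fluorescence`, attribute
#'   `k_app`.
#' @export
gen_isomerization_trace <- function(k_app, amplitude = 1, noise = 0,
                                    duration = NULL, seed = 1, f0 = 0,
                                    n_points = 500) {
  if (k_app <= 0) stop("k_app must be positive")
  if (is.null(duration)) duration <- 5 / k_app
  times <- seq(0, duration, length.out = n_points)
  f <- f0 + amplitude * (1 - exp(-k_app * times))
  if (noise > 0)
    f <- f + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(f), sd = noise))
  out <- data.frame(time_s = times, fluorescence = f)
  attr(out, "k_app") <- k_app
  out
}

#' Generate a parametric dataset for one of the standard curve forms
#'
#' Fixture factory for the dose-response, inhibition and activation
#' fitters: evaluates the named functional form exactly on the given
#' x grid and adds Gaussian noise.  The seed affects only the noise.
#'
#' Kinds and their parameters:
#' \describe{
#'   \item{`hill`}{`ec50`, `n_h`, `k_over_kmax`; x = ligand (uM).}
#'   \item{`inhibition`}{`ic50`, `s`, `k_max`, `k0` (printed 4PL form);
#'     x = inhibitor (uM).}
#'   \item{`double_exp`}{`a1`, `k1`, `a2`, `k2`; x = delay (s).}
#' }
#'
#' @param kind one of `"hill"`, `"inhibition"`, `"double_exp"`.
#' @param params named list of parameters for the chosen form.
#' @param x evaluation grid.
#' @param noise Gaussian noise SD (absolute units).
#' @param seed integer seed.
#' @return data frame with columns `x`, `y`; attributes `kind` and
#'   `truth` (the generating parameters).
#' @examples
#' d <- gen_parametric_dataset("hill",
#'   list(ec50 = 24, n_h = 2.9, k_over_kmax = 1),
#'   x = 10^seq(0, log10(300), length.out = 8))
#' fit_hill(d$x, d$y)$ec50
#' @export
gen_parametric_dataset <- function(kind, params, x, noise = 0, seed = 1) {
  x <- as.numeric(x)
  y <- switch(
    kind,
    hill = with(params, k_over_kmax * x^n_h / (ec50^n_h + x^n_h)),
    inhibition = with(params, (k_max - k0) / (1 + (x / ic50)^s)),
    double_exp = with(params,
                      a1 * (1 - exp(-k1 * x)) + a2 * (1 - exp(-k2 * x))),
    stop("unknown dataset kind: ", kind))
  if (noise > 0)
    y <- y + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(y), sd = noise))
  out <- data.frame(x = x, y = y)
  attr(out, "kind") <- kind
  attr(out, "truth") <- params
  out
}
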