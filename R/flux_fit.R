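#' Construct a stopped-flow quench trace
#'
#' A fluorescence-versus-time record from the thallium-flux assay: Tl+
#' entry through open channels quenches an encapsulated fluorophore, so
#' the initial quench rate reports channel activity.
#'
#' @param times strictly increasing times in s.
#' @param fluorescence fluorescence values (arbitrary units).
#' @param delay,camp,ppiase,csa,seed optional protocol metadata: delay
#'   time (s), cAMP (uM), isomerase (uM), cyclosporin A (uM), generator
#'   seed.
#' @return list of class `quench_trace` with `times`, `fluorescence`,
#'   `metadata`.
#' @export
quench_trace <- function(times, fluorescence, delay = NA, camp = NA,
                         ppiase = NA, csa = NA, seed = NA) {
  if (length(times) != length(fluorescence))
    stop("times and fluorescence must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  structure(list(times = as.numeric(times),
                 fluorescence = as.numeric(fluorescence),
                 metadata = list(delay = delay, camp = camp,
                                 ppiase = ppiase, csa = csa, seed = seed)),
            class = "quench_trace")
}

#' @export
print.quench_trace <- function(x, ...) {
  cat(sprintf("<quench_trace> %d points over %.3g s", length(x$times),
              max(x$times)))
  md <- x$metadata
  if (!is.na(md$camp)) cat(sprintf(", %g uM cAMP", md$camp))
  if (!is.na(md$delay)) cat(sprintf(", delay %g s", md$delay))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.quench_trace <- function(x, ...)
  data.frame(time_s = x$times, fluorescence = x$fluorescence)

# internal: deterministic bounded Levenberg-Marquardt least squares
lm_fit <- function(par, fn, lower = NULL, upper = NULL) {
  minpack.lm::nls.lm(
    par = par, fn = fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 0))
}

#' Fit a stretched-exponential quench to a fluorescence trace
#'
#' Least-squares fit of
#' \deqn{F(t) = F_\infty + (F_0 - F_\infty) e^{-(t/\tau)^\beta}}
#' to the early part of a quench trace.  The stretching exponent beta is
#' bounded to (0, 1]: liposome populations are heterogeneous in size and
#' channel count, which broadens (never compresses) the decay.  Only the
#' initial window is analysed (default 100 ms of a 1 s trace) because the
#' initial influx rate is the quantity of interest.
#'
#' Initialisation is deterministic (tau from the time to half-quench,
#' beta starting at 0.8), so the fit is a pure function of its input.
#'
#' @param trace a [quench_trace()].
#' @param window analysis window in s (default 0.1).
#' @return list of class `stretched_exp_fit`: `f0`, `finf`, `tau`, `beta`,
#'   `k_t` (influx rate at 2 ms, see [influx_rate()]), `residual_norm`,
#'   `flagged` (TRUE when the trace did not decay and beta was pinned
#'   at 1), `n_points`.
#' @examples
#' tr <- gen_quench_trace(f0 = 1, finf = 0.2, tau = 0.2, beta = 0.8,
#'                        noise_sigma = 0, seed = 1)
#' fit_stretched_exponential(tr)$tau
#' @export
fit_stretched_exponential <- function(trace, window = 0.1) {
  keep <- trace$times <= window
  t <- trace$times[keep]; y <- trace$fluorescence[keep]
  if (length(t) < 10)
    stop("fewer than 10 points inside the analysis window")

  # non-decay check on noise-robust block means of the window ends; a
  # slow but clean decay (tau >> window) must not be flagged
  nb <- max(3L, length(y) %/% 10)
  decay <- mean(y[seq_len(nb)]) - mean(y[seq.int(length(y) - nb + 1, length(y))])
  flagged <- FALSE
  if (decay <= 0) {
    warning("trace does not decay over the window; beta pinned at 1")
    flagged <- TRUE
  }

  half <- y[1] - 0.5 * (y[1] - min(y))
  i_half <- which(y <= half)[1]
  tau0 <- if (!is.na(i_half) && i_half > 1) t[i_half] / log(2)^(1 / 0.8)
          else max(t) / 2
  model <- function(par, tt)
    par[2] + (par[1] - par[2]) * exp(-(tt / par[3])^par[4])
  start <- c(f0 = y[1], finf = min(y), tau = max(tau0, 1e-6), beta = 0.8)
  lower <- c(-Inf, -Inf, 1e-9, 1e-3)
  upper <- c(Inf, Inf, Inf, 1)
  if (flagged) { start[4] <- 1; lower[4] <- 1 }
  fit <- lm_fit(start, function(par) y - model(par, t), lower, upper)
  par <- fit$par
  structure(list(f0 = par[[1]], finf = par[[2]], tau = par[[3]],
                 beta = par[[4]],
                 k_t = influx_rate_params(par[[3]], par[[4]]),
                 residual_norm = sqrt(fit$deviance),
                 flagged = flagged, n_points = length(t)),
            class = "stretched_exp_fit")
}

#' @export
print.stretched_exp_fit <- function(x, ...) {
  cat(sprintf(
    "<stretched_exp_fit> tau %.4g s, beta %.3f, F0 %.4g -> Finf %.4g, k(2 ms) %.4g s^-1%s\n",
    x$tau, x$beta, x$f0, x$finf, x$k_t,
    if (x$flagged) " [non-decaying]" else ""))
  invisible(x)
}

#' Initial influx rate from a stretched-exponential fit
#'
#' The instantaneous quench rate of the stretched exponential evaluated
#' at an early time,
#' \deqn{k_t = (\beta/\tau) (t/\tau)^{\beta - 1},}
#' conventionally at t = 2 ms, used as the per-trace measure of channel
#' activity.
#'
#' @param fit a `stretched_exp_fit`, or a list with `tau` and `beta`.
#' @param eval_time evaluation time in s (> 0, default 0.002).
#' @return rate in s^-1.
#' @examples
#' influx_rate(list(tau = 0.1, beta = 1))  # 10 s^-1 at any eval time
#' @export
influx_rate <- function(fit, eval_time = 0.002) {
  if (eval_time <= 0) stop("eval_time must be positive")
  influx_rate_params(fit$tau, fit$beta, eval_time)
}

influx_rate_params <- function(tau, beta, eval_time = 0.002)
  (beta / tau) * (eval_time / tau)^(beta - 1)

#' Fit a rising double exponential to an activation time course
#'
#' Fits \eqn{y(t) = a_1 (1 - e^{-k_1 t}) + a_2 (1 - e^{-k_2 t})} to
#' normalized rates versus delay time, with components ordered so that
#' `k1 > k2`.  A deterministic multi-start over log-spaced rate pairs
#' (1e3, 1e1, 1e-1 s^-1), with amplitudes initialised by linear least
#' squares at each rate pair, guards against local minima; the best
#' start wins, so the fit is order-invariant and reproducible.
#'
#' Data indistinguishable from a single exponential (rate ratio < 3 or a
#' vanishing amplitude) are refit with one component and flagged
#' `degenerate`.
#'
#' @param delays delay times in s (>= 6 points spanning both phases).
#' @param rates normalized activity at each delay.
#' @param include_offset also fit a constant offset (default FALSE; the
#'   activation protocol starts from zero activity).
#' @return list of class `double_exp_fit`: `a1`, `k1`, `a2`, `k2`,
#'   `offset`, `degenerate`, `residual_norm`.
#' @export
fit_double_exponential <- function(delays, rates, include_offset = FALSE) {
  ord <- order(delays)
  t <- as.numeric(delays)[ord]; y <- as.numeric(rates)[ord]
  if (length(t) < 6) stop("need at least 6 delay points")

  basis <- function(k1, k2) cbind(1 - exp(-k1 * t), 1 - exp(-k2 * t))
  resid_fun <- function(par) {
    k1 <- exp(par[1]); k2 <- exp(par[2])
    yhat <- par[3] * (1 - exp(-k1 * t)) + par[4] * (1 - exp(-k2 * t))
    if (include_offset) yhat <- yhat + par[5]
    y - yhat
  }

  k_grid <- c(1e3, 1e1, 1e-1)
  starts <- list()
  for (i in 1:2) for (j in (i + 1):3)
    starts[[length(starts) + 1L]] <- c(k_grid[i], k_grid[j])
  # data-driven extra start: fastest from first point, slowest from span
  starts[[length(starts) + 1L]] <- c(1 / t[1], 1 / t[length(t)])

  best <- NULL
  for (st in starts) {
    B <- basis(st[1], st[2])
    amp <- tryCatch(stats::coef(stats::lm.fit(B, y)),
                    error = function(e) c(0.5, 0.5))
    amp[!is.finite(amp)] <- 0.5
    par0 <- c(log(st[1]), log(st[2]), pmax(amp, 0))
    if (include_offset) par0 <- c(par0, 0)
    lower <- c(-Inf, -Inf, 0, 0, if (include_offset) -Inf)
    fit <- tryCatch(lm_fit(par0, resid_fun, lower = lower),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("double-exponential fit failed to converge")

  k <- unname(exp(best$par[1:2])); a <- unname(best$par[3:4])
  o <- order(k, decreasing = TRUE)
  k <- k[o]; a <- a[o]
  offset <- if (include_offset) unname(best$par[5]) else 0

  degenerate <- k[1] / k[2] < 3 || min(a) < 1e-3 * max(sum(a), 1e-12)
  if (degenerate) {
    sfit <- lm_fit(c(log(1 / t[which.min(abs(y - max(y) / 2))[1]]), max(y)),
                   function(par) {
                     yhat <- par[2] * (1 - exp(-exp(par[1]) * t))
                     if (include_offset) yhat <- yhat + par[3]
                     y - yhat
                   }, lower = c(-Inf, 0, if (include_offset) -Inf))
    if (include_offset && length(sfit$par) < 3) sfit$par <- c(sfit$par, 0)
    k <- c(unname(exp(sfit$par[1])), NA_real_)
    a <- c(unname(sfit$par[2]), 0)
    offset <- if (include_offset) unname(sfit$par[3]) else 0
    best <- sfit
  }
  structure(list(a1 = a[1], k1 = k[1], a2 = a[2], k2 = k[2],
                 offset = offset, degenerate = degenerate,
                 residual_norm = sqrt(best$deviance)),
            class = "double_exp_fit")
}

#' @export
print.double_exp_fit <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("<double_exp_fit> degenerate: single component a %.4g, k %.4g s^-1\n",
                x$a1, x$k1))
  else
    cat(sprintf("<double_exp_fit> a1 %.4g k1 %.4g s^-1 | a2 %.4g k2 %.4g s^-1\n",
                x$a1, x$k1, x$a2, x$k2))
  invisible(x)
}

#' Fit the modified Hill equation to a dose-response curve
#'
#' Fits
#' \deqn{y([cAMP]) = \frac{(k/k_{max}) [cAMP]^{n_H}}
#'                        {EC_{50}^{n_H} + [cAMP]^{n_H}}}
#' to normalized rates versus ligand concentration.  Initialisation is
#' deterministic: EC50 starts at the concentration nearest half-maximum
#' and the Hill coefficient at 2.
#'
#' @param dr a `dose_response` data frame (columns `camp_uM`, `response`),
#'   or a two-column data frame of concentration and response.
#' @param response optional response vector when `dr` is a plain
#'   concentration vector.
#' @return list of class `hill_fit`: `ec50` (uM), `n_h`, `k_over_kmax`,
#'   `residual_norm`.  A response decreasing with concentration beyond
#'   fit noise triggers a warning.
#' @export
fit_hill <- function(dr, response = NULL) {
  if (is.null(response)) {
    dr <- as.data.frame(dr)
    conc <- dr[[1]]; y <- dr[[2]]
  } else {
    conc <- as.numeric(dr); y <- as.numeric(response)
  }
  if (length(conc) < 5) stop("need at least 5 concentrations")
  if (any(conc <= 0)) stop("concentrations must be positive")

  ymax <- max(y)
  ec50_0 <- conc[which.min(abs(y - ymax / 2))]
  fit <- lm_fit(
    c(log(ec50_0), log(2), ymax),
    function(par) y - par[3] * conc^exp(par[2]) /
      (exp(par[1])^exp(par[2]) + conc^exp(par[2])))
  mono <- suppressWarnings(stats::cor(conc, y, method = "spearman"))
  if (isTRUE(mono < 0) && sqrt(fit$deviance) > 0.05 * max(abs(y)))
    warning("response is not monotone increasing in concentration")
  structure(list(ec50 = exp(fit$par[1]), n_h = exp(fit$par[2]),
                 k_over_kmax = fit$par[3],
                 residual_norm = sqrt(fit$deviance)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> EC50 %.4g uM, n_H %.3g, k/k_max %.4g\n",
              x$ec50, x$n_h, x$k_over_kmax))
  invisible(x)
}

#' Fit a four-parameter logistic inhibition curve
#'
#' Fits the inhibition of activity by an inhibitor (e.g. cyclosporin A
#' acting on a cyclophilin) in the printed four-parameter-logistic form
#' \deqn{y([CsA]) = \frac{k_{max} - k_0}{1 + ([CsA]/IC_{50})^s},}
#' which decays to 0 at saturating inhibitor.  The conventional 4PL
#' variant with a nonzero floor,
#' \eqn{y = k_0 + (k_{max} - k_0)/(1 + ([CsA]/IC_{50})^s)}, is available
#' via `conventional = TRUE`.
#'
#' @param csa inhibitor concentrations in uM (>= 5 values including a
#'   near-zero point).
#' @param rates measured rates (s^-1).
#' @param conventional use the nonzero-floor variant.
#' @return list of class `inhibition_fit`: `k_max`, `k0`, `ic50` (uM),
#'   `slope`, `unbounded` (TRUE when no inhibition is detectable inside
#'   the tested range), `residual_norm`.
#' @export
fit_inhibition <- function(csa, rates, conventional = FALSE) {
  csa <- as.numeric(csa); y <- as.numeric(rates)
  if (length(csa) < 5) stop("need at least 5 inhibitor concentrations")
  if (min(csa) > 0.05 * max(csa))
    warning("no near-zero inhibitor concentration; amplitude poorly anchored")

  xpos <- pmax(csa, 1e-12)
  amp0 <- max(y) - min(y)
  ic0 <- xpos[which.min(abs(y - (min(y) + amp0 / 2)))]
  if (conventional) {
    fit <- lm_fit(
      c(log(ic0), log(1), max(y), min(y)),
      function(par) y - (par[4] + (par[3] - par[4]) /
                           (1 + (xpos / exp(par[1]))^exp(par[2]))))
    k_max <- fit$par[3]; k0 <- fit$par[4]
  } else {
    fit <- lm_fit(
      c(log(ic0), log(1), max(y)),
      function(par) y - par[3] / (1 + (xpos / exp(par[1]))^exp(par[2])))
    k_max <- fit$par[3]; k0 <- 0
  }
  ic50 <- exp(fit$par[1])
  # undetectable inhibition shows up as a diverging IC50, a vanishing
  # amplitude, or a slope collapsing to zero (flat logistic)
  unbounded <- ic50 > 50 * max(csa) ||
    abs(k_max - k0) < 1e-10 * max(abs(y)) || exp(fit$par[2]) < 0.05
  if (unbounded)
    warning("no inhibition detectable within the tested concentration range")
  structure(list(k_max = k_max, k0 = k0, ic50 = ic50,
                 slope = exp(fit$par[2]), unbounded = unbounded,
                 residual_norm = sqrt(fit$deviance)),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("<inhibition_fit> IC50 %.4g uM, slope %.3g, amplitude %.4g s^-1%s\n",
              x$ic50, x$slope, x$k_max - x$k0,
              if (x$unbounded) " [unbounded]" else ""))
  invisible(x)
}

#' Catalytic efficiency from enzyme-concentration dependence
#'
#' Linear fit of the apparent isomerization rate versus enzyme
#' concentration, \eqn{k_{app} = k_0 + [E] \cdot k_{cat}/K_M}: the slope
#' is the catalytic efficiency and the intercept the uncatalyzed rate.
#'
#' @param enzyme enzyme concentrations in nM (>= 2 values, ideally
#'   including 0).
#' @param k_app apparent rates in s^-1.
#' @return list of class `catalysis_fit`: `k0` (s^-1), `efficiency`
#'   (nM^-1 s^-1), `efficiency_se`, `residual_norm`.  A negative fitted
#'   slope triggers a warning (no catalysis).
#' @examples
#' fit_catalytic_efficiency(c(0, 100), c(0.05, 0.15))
#' @export
fit_catalytic_efficiency <- function(enzyme, k_app) {
  enzyme <- as.numeric(enzyme); k_app <- as.numeric(k_app)
  if (length(enzyme) < 2) stop("need at least 2 enzyme concentrations")
  if (stats::var(enzyme) == 0) {
    return(structure(list(k0 = mean(k_app), efficiency = 0,
                          efficiency_se = NA_real_,
                          residual_norm = sqrt(sum((k_app - mean(k_app))^2))),
                     class = "catalysis_fit"))
  }
  fit <- stats::lm(k_app ~ enzyme)
  slope <- unname(stats::coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  se <- if (length(enzyme) <= 2) NA_real_
        else if (rss < 1e-24) 0    # exact fit: summary.lm would warn
        else summary(fit)$coefficients[2, 2]
  if (slope < 0) warning("negative fitted slope: no catalysis detected")
  structure(list(k0 = unname(stats::coef(fit)[1]), efficiency = slope,
                 efficiency_se = se,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2))),
            class = "catalysis_fit")
}

#' @export
print.catalysis_fit <- function(x, ...) {
  cat(sprintf("<catalysis_fit> k0 %.4g s^-1, kcat/KM %.4g nM^-1 s^-1\n",
              x$k0, x$efficiency))
  invisible(x)
}

#' Aggregate per-repeat influx rates across experiments
#'
#' Replicate protocol of the stopped-flow assay: several technical
#' repeats per condition are fit separately and averaged within an
#' experiment, then each experiment is normalized by its own maximum
#' mean rate before averaging across independent experiments.
#'
#' @param data data frame with columns `experiment` (id), `condition`
#'   (e.g. delay time or concentration) and `k` (per-repeat influx rate,
#'   s^-1).
#' @param normalize divide each experiment by its maximum within-condition
#'   mean before cross-experiment averaging.
#' @return data frame with one row per condition: `condition`, `mean`,
#'   `sd`, `n_experiments`.
#' @export
aggregate_replicates <- function(data, normalize = TRUE) {
  stopifnot(all(c("experiment", "condition", "k") %in% names(data)))
  # technical repeats -> per-experiment, per-condition mean
  per_exp <- stats::aggregate(k ~ experiment + condition, data = data,
                              FUN = mean)
  if (normalize) {
    mx <- stats::aggregate(k ~ experiment, data = per_exp, FUN = max)
    names(mx)[2] <- "k_max"
    per_exp <- merge(per_exp, mx, by = "experiment")
    per_exp$k <- per_exp$k / per_exp$k_max
  }
  out <- stats::aggregate(k ~ condition, data = per_exp, FUN = mean)
  names(out)[2] <- "mean"
  out$sd <- stats::aggregate(k ~ condition, data = per_exp,
                             FUN = stats::sd)$k
  out$n_experiments <- stats::aggregate(k ~ condition, data = per_exp,
                                        FUN = length)$k
  out[order(out$condition), , drop = FALSE]
}
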