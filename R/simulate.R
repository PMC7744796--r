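#' Deterministic ensemble relaxation of a kinetic scheme
#'
#' Solves the master equation dp/dt = p Q exactly by eigen-decomposition
#' of the generator, so the macroscopic observable is the standard
#' weighted sum of k-1 exponential components
#' \deqn{I(t) = I(eq) + \sum_i b_i e^{-t/\tau_i}}
#' whose amplitudes `b_i` and time constants `tau_i` are returned as the
#' relaxation spectrum of the conducting fraction.  Complex eigenvalue
#' pairs (possible in non-reversible schemes) are combined into single
#' real damped components using the real part of the eigenvalue; if the
#' generator is defective (non-diagonalizable) the trajectory falls back
#' to stiff numerical integration and is flagged.
#'
#' @param model a [state_model()].
#' @param ligand ligand concentration in uM held constant during the
#'   relaxation.
#' @param p0 initial probability vector over states (sums to 1).
#' @param times nonnegative, increasing output time grid in s.  Default:
#'   5000 points over 1 s, mirroring a stopped-flow acquisition.
#' @return An object of class `occupancy_trajectory`: list with `times`,
#'   `occupancy` (length(times) x k matrix), `conducting_fraction`,
#'   `spectrum` (data frame `amplitude`, `tau`), `equilibrium_level`
#'   (conducting fraction at t = Inf), `equilibrium` (full stationary
#'   vector), `ligand`, and `flagged` (TRUE when the eigen solver was
#'   bypassed).
#' @examples
#' tr <- relax(two_state_example(), ligand = 0, p0 = c(1, 0),
#'             times = seq(0, 1, length.out = 101))
#' max(abs(tr$conducting_fraction - 0.1 * (1 - exp(-10 * tr$times))))
#' @export
relax <- function(model, ligand, p0,
                  times = seq(0, 1, length.out = 5000)) {
  k <- n_states(model)
  if (length(p0) != k) stop("p0 must have one entry per state")
  if (abs(sum(p0) - 1) > 1e-8) stop("p0 must sum to 1")
  if (any(times < 0) || is.unsorted(times, strictly = FALSE))
    stop("times must be nonnegative and increasing")
  Q <- build_rate_matrix(model, ligand)
  Qm <- unclass_rate_matrix(Q)
  p_eq <- equilibrium_occupancy(Q)
  w <- as.numeric(model$conducting)

  eig <- eigen(t(Qm))
  V <- eig$vectors
  flagged <- FALSE
  coef <- tryCatch({
    if (is.complex(V)) solve(V, as.complex(p0))
    else as.complex(solve(V, as.numeric(p0)))
  }, error = function(e) NULL)
  if (is.null(coef) || rcond_complex(V) < 1e-12) {
    # defective generator: dense stiff integration
    flagged <- TRUE
    occ <- integrate_master(Qm, p0, times)
  } else {
    growth <- exp(outer(eig$values, times))     # k x T
    occ <- t(Re(V %*% (coef * growth)))         # T x k
  }
  colnames(occ) <- model$states
  cf <- as.numeric(occ %*% w)

  spectrum <- if (!flagged)
    relaxation_spectrum(eig$values, V, coef, w, scale = max(abs(Qm)))
  else data.frame(amplitude = numeric(), tau = numeric())

  structure(
    list(times = times, occupancy = occ, conducting_fraction = cf,
         spectrum = spectrum,
         equilibrium_level = as.numeric(w %*% p_eq),
         equilibrium = p_eq, ligand = ligand, flagged = flagged),
    class = "occupancy_trajectory")
}

# internal: reciprocal condition number usable for complex matrices
rcond_complex <- function(V) {
  d <- svd(V, nu = 0, nv = 0)$d
  if (max(d) == 0) 0 else min(d) / max(d)
}

# internal: decaying components of the conducting-fraction relaxation.
# Conjugate eigenvalue pairs are merged (amplitudes of the pair sum to a
# real number); amplitudes are the t = 0 contributions so that
# sum(b_i) = I(0) - I(eq).
relaxation_spectrum <- function(lambda, V, coef, w, scale) {
  contrib <- as.complex(w %*% V) * coef   # per-mode conducting amplitude
  tol <- max(scale, 1) * 1e-10
  decaying <- which(Re(lambda) < -tol)
  used <- logical(length(lambda))
  amp <- numeric(0); tau <- numeric(0)
  for (j in decaying) {
    if (used[j]) next
    used[j] <- TRUE
    b <- contrib[j]
    if (abs(Im(lambda[j])) > tol) {
      mate <- which(!used & abs(lambda - Conj(lambda[j])) < tol *
                      (1 + abs(lambda[j])))
      if (length(mate) > 0) {
        used[mate[1]] <- TRUE
        b <- b + contrib[mate[1]]
      }
    }
    amp <- c(amp, Re(b))
    tau <- c(tau, -1 / Re(lambda[j]))
  }
  ord <- order(tau)
  data.frame(amplitude = amp[ord], tau = tau[ord])
}

# internal: fallback master-equation integration (stiff solver)
integrate_master <- function(Qm, p0, times) {
  t_out <- times
  prepend <- t_out[1] > 0
  if (prepend) t_out <- c(0, t_out)
  sol <- deSolve::lsoda(
    y = as.numeric(p0), times = t_out,
    func = function(t, y, parms) list(as.numeric(y %*% Qm)),
    rtol = 1e-10, atol = 1e-12)
  occ <- unname(sol[, -1, drop = FALSE])
  if (prepend) occ <- occ[-1, , drop = FALSE]
  occ
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  cat(sprintf(
    "<occupancy_trajectory> %d time points, %d states, ligand %g uM%s\n",
    length(x$times), ncol(x$occupancy), x$ligand,
    if (x$flagged) " [numerical fallback]" else ""))
  cat(sprintf("  conducting fraction: %.4g (t0) -> %.4g (eq)\n",
              x$conducting_fraction[1], x$equilibrium_level))
  invisible(x)
}

#' @export
as.data.frame.occupancy_trajectory <- function(x, ...) {
  out <- data.frame(time_s = x$times)
  out <- cbind(out, as.data.frame(x$occupancy))
  out$conducting_fraction <- x$conducting_fraction
  out
}

#' Relaxation after a ligand concentration jump
#'
#' Equilibrates the scheme at `pre_ligand`, then relaxes it at
#' `post_ligand`: the canonical stopped-flow / fast-perfusion protocol.
#'
#' @inheritParams relax
#' @param pre_ligand,post_ligand concentrations in uM before and after the
#'   jump (both >= 0).
#' @return an `occupancy_trajectory` (see [relax()]).
#' @examples
#' jump <- concentration_jump(build_trans_only_model(), 0, 100,
#'                            times = c(0.001, 0.012, 0.1))
#' jump$conducting_fraction
#' @export
concentration_jump <- function(model, pre_ligand, post_ligand,
                               times = seq(0, 1, length.out = 5000)) {
  p0 <- equilibrium_occupancy(build_rate_matrix(model, pre_ligand))
  relax(model, post_ligand, p0, times)
}

#' Macroscopic current from an occupancy trajectory
#'
#' @param traj an `occupancy_trajectory`.
#' @param n_channels number of channels in the ensemble (> 0).
#' @param unit_amplitude single-channel current amplitude (arbitrary
#'   units); conducting states share one amplitude (no subconductance).
#' @return data frame with columns `time_s` and `current`.
#' @export
ensemble_current <- function(traj, n_channels, unit_amplitude = 1) {
  if (n_channels <= 0) stop("n_channels must be positive")
  data.frame(time_s = traj$times,
             current = n_channels * unit_amplitude * traj$conducting_fraction)
}

#' Stochastic single-channel simulation (Gillespie algorithm)
#'
#' Exact stochastic simulation of the continuous-time Markov chain at a
#' fixed ligand concentration.  The random number stream is controlled by
#' an explicit integer seed and the caller's global RNG state is left
#' untouched; identical seed and inputs give a bit-identical record.
#'
#' @param model a [state_model()].
#' @param ligand concentration in uM.
#' @param duration total simulated time in s (> 0).
#' @param seed integer seed.
#' @param p0 initial-state distribution; default is the apo (0 uM)
#'   equilibrium, falling back to uniform when that is not unique (e.g.
#'   all-zero-rate models).
#' @return An object of class `single_channel_record`: list with `states`
#'   (integer indices), `state_names`, `durations` (s, sum to `duration`),
#'   `conducting` (per-dwell logical), `ligand`, `duration`, `seed`.
#'   Absorbing states are allowed; the record then ends in one long dwell.
#' @examples
#' rec <- gillespie(two_state_example(), 0, duration = 10, seed = 1)
#' open_probability(rec)
#' @export
gillespie <- function(model, ligand, duration, seed, p0 = NULL) {
  if (duration <= 0) stop("duration must be positive")
  Q <- build_rate_matrix(model, ligand)
  Qm <- unclass_rate_matrix(Q)
  k <- nrow(Qm)
  if (is.null(p0)) {
    p0 <- tryCatch(
      equilibrium_occupancy(build_rate_matrix(model, 0)),
      error = function(e) rep(1 / k, k))
  }
  if (length(p0) != k || abs(sum(p0) - 1) > 1e-8)
    stop("p0 must be a probability vector over the states")

  exit_rate <- -diag(Qm)
  # per-state cumulative jump distribution
  jump_cum <- vector("list", k)
  jump_to <- vector("list", k)
  for (s in seq_len(k)) {
    targets <- which(Qm[s, ] > 0 & seq_len(k) != s)
    if (length(targets) > 0) {
      pr <- Qm[s, targets] / sum(Qm[s, targets])
      jump_cum[[s]] <- cumsum(pr)
      jump_to[[s]] <- targets
    }
  }

  res <- withr::with_seed(as.integer(seed), {
    cap <- 4096L
    st <- integer(cap); du <- numeric(cap)
    n <- 0L
    s <- sample.int(k, 1L, prob = p0)
    t_now <- 0
    repeat {
      lam <- exit_rate[s]
      dwell <- if (lam > 0) stats::rexp(1L, lam) else Inf
      if (t_now + dwell >= duration) {
        dwell <- duration - t_now
        n <- n + 1L
        if (n > cap) { cap <- cap * 2L; length(st) <- cap; length(du) <- cap }
        st[n] <- s; du[n] <- dwell
        break
      }
      n <- n + 1L
      if (n > cap) { cap <- cap * 2L; length(st) <- cap; length(du) <- cap }
      st[n] <- s; du[n] <- dwell
      t_now <- t_now + dwell
      u <- stats::runif(1L)
      idx <- findInterval(u, jump_cum[[s]]) + 1L
      idx <- min(idx, length(jump_to[[s]]))
      s <- jump_to[[s]][idx]
    }
    list(states = st[seq_len(n)], durations = du[seq_len(n)])
  })

  structure(
    list(states = res$states, state_names = model$states[res$states],
         durations = res$durations,
         conducting = model$conducting[res$states],
         ligand = ligand, duration = duration, seed = as.integer(seed)),
    class = "single_channel_record")
}

#' @export
print.single_channel_record <- function(x, ...) {
  cat(sprintf(
    "<single_channel_record> %d dwells over %g s at %g uM (seed %d)\n",
    length(x$durations), x$duration, x$ligand, x$seed))
  cat(sprintf("  open probability: %.4f\n", open_probability(x)))
  invisible(x)
}

#' @export
as.data.frame.single_channel_record <- function(x, ...) {
  data.frame(state = x$state_names, duration_s = x$durations,
             conducting = x$conducting)
}

#' Open probability of a single-channel record
#'
#' Fraction of total time spent in conducting states.
#'
#' @param record a `single_channel_record` from [gillespie()].
#' @return scalar in [0, 1].
#' @export
open_probability <- function(record) {
  if (length(record$durations) == 0) stop("empty record")
  sum(record$durations[record$conducting]) / sum(record$durations)
}

#' Dwell-time summary of a single-channel record
#'
#' @param record a `single_channel_record`.
#' @return list with `open_dwells` and `closed_dwells` (numeric vectors,
#'   s).  The final (truncated) dwell is included.
#' @export
dwell_times <- function(record) {
  list(open_dwells = record$durations[record$conducting],
       closed_dwells = record$durations[!record$conducting])
}

#' Ensemble mean conducting fraction from repeated Gillespie runs
#'
#' Simulates `n_channels` independent channels and evaluates the fraction
#' conducting at each requested time; the stochastic cross-check for the
#' deterministic eigen-relaxation.
#'
#' @inheritParams gillespie
#' @param times evaluation times in s.
#' @param n_channels ensemble size.
#' @return list with `times`, `conducting_fraction` (ensemble mean) and
#'   `n_channels` (for binomial standard errors).
#' @export
gillespie_ensemble <- function(model, ligand, times, n_channels, seed,
                               p0 = NULL) {
  duration <- max(times)
  counts <- numeric(length(times))
  for (i in seq_len(n_channels)) {
    rec <- gillespie(model, ligand, duration, seed = seed + i - 1L, p0 = p0)
    edges <- cumsum(rec$durations)
    idx <- findInterval(times, edges, left.open = TRUE) + 1L
    idx <- pmin(idx, length(rec$states))
    counts <- counts + as.numeric(rec$conducting[idx])
  }
  list(times = times, conducting_fraction = counts / n_channels,
       n_channels = n_channels)
}
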