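# shared fixtures: small schemes and oracle helpers built in code

# two-state closed<->open, opening 1 s^-1, closing 9 s^-1 (Po 0.1)
two_state <- function() two_state_example()

# three-state linear chain with known Boltzmann weights (1, 2, 1)/4
three_state_chain <- function() {
  state_model(
    states = c("a", "b", "c"), conducting = c(FALSE, FALSE, TRUE),
    transitions = data.frame(
      from = c("a", "b", "b", "c"), to = c("b", "a", "c", "b"),
      rate = c(2, 1, 4, 8), ligand_dependent = FALSE))
}

# independent equilibrium oracle for detailed-balance models: Boltzmann
# weights accumulated along a breadth-first spanning tree of pair ratios
spanning_tree_equilibrium <- function(model, ligand) {
  Q <- build_rate_matrix(model, ligand)
  Qm <- matrix(as.numeric(Q), nrow(Q))
  k <- nrow(Qm)
  w <- rep(NA_real_, k); w[1] <- 1
  repeat {
    done <- TRUE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (!is.na(w[i]) && is.na(w[j]) && Qm[i, j] > 0 && Qm[j, i] > 0) {
        w[j] <- w[i] * Qm[i, j] / Qm[j, i]
        done <- FALSE
      }
    }
    if (done) break
  }
  w[is.na(w)] <- 0
  w / sum(w)
}

# dense master-equation integration oracle (independent of the eigen path)
ode_occupancy <- function(model, ligand, p0, times) {
  Q <- build_rate_matrix(model, ligand)
  Qm <- matrix(as.numeric(Q), nrow(Q))
  t_out <- c(0, times)
  sol <- deSolve::lsoda(as.numeric(p0), t_out,
                        function(t, y, parms) list(as.numeric(y %*% Qm)),
                        rtol = 1e-11, atol = 1e-13)
  unname(sol[-1, -1, drop = FALSE])
}

# fraction of time a long single-channel record spends in each state
record_occupancy <- function(rec, k) {
  occ <- numeric(k)
  for (s in seq_len(k)) occ[s] <- sum(rec$durations[rec$states == s])
  occ / sum(occ)
}
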