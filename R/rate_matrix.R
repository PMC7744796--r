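#' Build the generator matrix at a fixed ligand concentration
#'
#' Turns a [state_model()] into the infinitesimal generator Q of the
#' continuous-time Markov chain at ligand concentration `ligand` (uM).
#' `Q[i, j]` for `i != j` is the effective rate of the `i -> j` transition
#' (the stored rate multiplied by `ligand` when the transition is
#' ligand-dependent); the diagonal makes every row sum to zero.
#'
#' @param model a [state_model()] passing structural validation.
#' @param ligand ligand concentration in uM, >= 0.
#' @return A square numeric matrix of class `rate_matrix` with state names
#'   as dimnames and attributes `ligand` (uM) and `conducting` (logical
#'   vector aligned with the state order).
#' @examples
#' m <- two_state_example()
#' build_rate_matrix(m, ligand = 0)
#' @export
build_rate_matrix <- function(model, ligand) {
  if (!is.numeric(ligand) || length(ligand) != 1 || is.na(ligand) ||
      ligand < 0)
    stop("ligand concentration must be a single nonnegative number (uM)")
  assert_valid_model(model)
  k <- n_states(model)
  Q <- matrix(0, k, k, dimnames = list(model$states, model$states))
  tr <- model$transitions
  eff <- tr$rate * ifelse(tr$ligand_dependent, ligand, 1)
  for (i in seq_len(nrow(tr)))
    Q[tr$from[i], tr$to[i]] <- Q[tr$from[i], tr$to[i]] + eff[i]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(Q, class = c("rate_matrix", "matrix"),
            ligand = ligand, conducting = model$conducting)
}

#' Stationary occupancy of a generator matrix
#'
#' Solves \eqn{p Q = 0}, \eqn{\sum p = 1} from the null space of the
#' transposed generator (singular value decomposition), not by long-time
#' integration.  Chains whose stationary distribution is not unique (more
#' than one closed communicating class on the positive-rate graph) are an
#' error; chains with transient states but a single closed class are
#' accepted, which is what a liganded scheme at 0 uM ligand becomes (all
#' bound and open states are transient and the stationary mass sits on the
#' apo states).
#'
#' @param Q a `rate_matrix` from [build_rate_matrix()], or a plain square
#'   generator matrix.
#' @return Named numeric probability vector over states.
#' @examples
#' Q <- build_rate_matrix(two_state_example(), 0)
#' equilibrium_occupancy(Q)  # (0.9, 0.1)
#' @export
equilibrium_occupancy <- function(Q) {
  Q <- unclass_rate_matrix(Q)
  k <- nrow(Q)
  scale <- max(abs(Q))
  if (scale == 0)
    stop("all rates are zero: stationary distribution is not unique")
  dec <- svd(t(Q))
  null_dim <- sum(dec$d < k * scale * 1e-12)
  if (null_dim == 0) null_dim <- 1  # smallest singular value is the null one
  if (null_dim > 1) {
    classes <- closed_classes(Q)
    stop("stationary distribution is not unique; closed communicating ",
         "classes: ",
         paste(vapply(classes, paste, "", collapse = "+"), collapse = " | "))
  }
  p <- dec$v[, k]
  p <- p / sum(p)
  if (min(p) < -1e-8)
    stop("null-space solution has negative mass; generator is ill-conditioned")
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- rownames(Q)
  p
}

# internal: closed communicating classes (recurrent classes) of the
# positive-rate graph; used only for error reporting
closed_classes <- function(Q) {
  adj <- (Q > 0) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  out <- list()
  for (cl in seq_len(comp$no)) {
    members <- which(comp$membership == cl)
    leaves <- any(adj[members, -members, drop = FALSE] > 0)
    if (!leaves) out[[length(out) + 1L]] <-
        rownames(Q)[members] %||% as.character(members)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unclass_rate_matrix <- function(Q) {
  m <- unclass(Q)
  attr(m, "ligand") <- NULL
  attr(m, "conducting") <- NULL
  class(m) <- NULL
  matrix(as.numeric(m), nrow(Q), ncol(Q), dimnames = dimnames(Q))
}

#' Check detailed balance of a scheme at a given ligand concentration
#'
#' Detailed balance (microscopic reversibility) holds when every edge flux
#' balances at stationarity: \eqn{p_i Q_{ij} = p_j Q_{ji}}.  Cyclic
#' schemes need not satisfy it; this reports rather than enforces, and the
#' scheme builders in this package do produce thermodynamically closed
#' cycles by construction.
#'
#' @param model a [state_model()].
#' @param ligand concentration in uM.
#' @param tol relative tolerance on the flux mismatch.
#' @return list with `balanced` (logical) and `max_relative_flux_error`.
#' @export
detailed_balance_check <- function(model, ligand, tol = 1e-8) {
  Q <- build_rate_matrix(model, ligand)
  p <- equilibrium_occupancy(Q)
  Qm <- unclass_rate_matrix(Q)
  flux <- p * Qm            # flux[i, j] = p_i q_ij
  mism <- abs(flux - t(flux))
  ref <- max(flux - diag(diag(flux)))
  err <- if (ref > 0) max(mism[upper.tri(mism)]) / ref else 0
  list(balanced = err <= tol, max_relative_flux_error = err)
}
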