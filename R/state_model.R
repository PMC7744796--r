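#' Define a ligand-gated channel kinetic scheme
#'
#' A state model is an ordered set of named kinetic states, each flagged as
#' conducting or not, plus a list of directed transitions between them.
#' Transition rates are first-order (s^-1) unless `ligand_dependent` is
#' `TRUE`, in which case the stored rate is a second-order binding rate
#' (uM^-1 s^-1) and the effective rate at ligand concentration `L` uM is
#' `rate * L`.
#'
#' Units are fixed package-wide: time in s, first-order rates in s^-1,
#' second-order rates in uM^-1 s^-1, concentrations in uM.
#'
#' @param states character vector of unique state names, in display order.
#' @param conducting logical vector, one entry per state; `TRUE` marks an
#'   open (ion-conducting) state.
#' @param transitions data frame with columns `from`, `to` (state names),
#'   `rate` (numeric, >= 0) and `ligand_dependent` (logical).  An optional
#'   `kind` column labels each transition (e.g. "isomerization", "binding",
#'   "gating"); the scheme builders fill it in and [apply_ppiase()] relies
#'   on it.
#' @param metadata free-form named list of labels (mechanism name,
#'   cis/trans annotations, ...).
#'
#' @return An object of class `state_model`.
#' @seealso [validate_model()], [build_rate_matrix()],
#'   [build_modulatory_model()]
#' @examples
#' m <- state_model(
#'   states = c("closed", "open"),
#'   conducting = c(FALSE, TRUE),
#'   transitions = data.frame(
#'     from = c("closed", "open"), to = c("open", "closed"),
#'     rate = c(1, 9), ligand_dependent = FALSE
#'   )
#' )
#' validate_model(m)
#' @export
state_model <- function(states, conducting, transitions, metadata = list()) {
  stopifnot(is.character(states), is.logical(conducting),
            length(states) == length(conducting))
  transitions <- as.data.frame(transitions)
  required <- c("from", "to", "rate", "ligand_dependent")
  missing_cols <- setdiff(required, names(transitions))
  if (length(missing_cols) > 0)
    stop("transitions is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"kind" %in% names(transitions))
    transitions$kind <- NA_character_
  transitions <- transitions[, c(required, "kind")]
  transitions$from <- as.character(transitions$from)
  transitions$to <- as.character(transitions$to)
  transitions$rate <- as.numeric(transitions$rate)
  transitions$ligand_dependent <- as.logical(transitions$ligand_dependent)
  rownames(transitions) <- NULL
  structure(
    list(states = states, conducting = conducting,
         transitions = transitions, metadata = metadata),
    class = "state_model"
  )
}

#' @export
print.state_model <- function(x, ...) {
  cond <- sum(x$conducting)
  cat(sprintf("<state_model> %d states (%d conducting), %d transitions\n",
              length(x$states), cond, nrow(x$transitions)))
  cat("  states:", paste0(x$states, ifelse(x$conducting, "*", "")), "\n")
  if (!is.null(x$metadata$mechanism))
    cat("  mechanism:", x$metadata$mechanism, "\n")
  invisible(x)
}

#' Number of states in a model
#' @param model a [state_model()].
#' @return integer
#' @export
n_states <- function(model) length(model$states)

#' Diagnostic validation of a state model
#'
#' Checks the structural invariants of a kinetic scheme and reports all
#' violations.  This function never throws: it is a diagnostic and returns
#' pass/fail plus named findings.
#'
#' Checks performed: duplicate state names; transitions referencing
#' undefined ("dangling") states; self-transitions (`from == to`); negative
#' rates; connectivity of the directed graph restricted to strictly
#' positive rates (an effective rate of 0 keeps the transition in the model
#' but removes the edge from the connectivity check); presence of at least
#' one conducting state.  The last check is reported at severity
#' `"warning"` because non-conducting schemes are legitimate controls
#' (e.g. protein-free liposomes); all others are `"error"`.
#'
#' @param model a [state_model()].
#' @return A list of class `model_validation` with elements `ok` (logical:
#'   no error-level violations), `violations` (data frame with columns
#'   `check`, `severity`, `message`).
#' @examples
#' m <- state_model("a", TRUE,
#'   data.frame(from = "a", to = "b", rate = -1, ligand_dependent = FALSE))
#' validate_model(m)$ok
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(check, severity, message)
    v[[length(v) + 1L]] <<- data.frame(check = check, severity = severity,
                                       message = message)

  if (anyDuplicated(model$states))
    add("duplicate state", "error",
        paste("duplicate state name(s):",
              paste(unique(model$states[duplicated(model$states)]),
                    collapse = ", ")))

  tr <- model$transitions
  dangling <- setdiff(unique(c(tr$from, tr$to)), model$states)
  if (length(dangling) > 0)
    add("dangling state", "error",
        paste("transition references undefined state(s):",
              paste(dangling, collapse = ", ")))

  if (any(tr$from == tr$to))
    add("self transition", "error",
        paste("self-transition on state(s):",
              paste(unique(tr$from[tr$from == tr$to]), collapse = ", ")))

  if (any(is.na(tr$rate)) || any(tr$rate < 0, na.rm = TRUE))
    add("negative rate", "error",
        paste("negative or missing rate on transition(s):",
              paste(which(is.na(tr$rate) | tr$rate < 0), collapse = ", ")))

  # connectivity on the strictly-positive-rate graph only
  if (length(dangling) == 0 && length(model$states) > 1) {
    pos <- tr[!is.na(tr$rate) & tr$rate > 0 & tr$from != tr$to, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      pos[, c("from", "to")], directed = TRUE,
      vertices = data.frame(name = model$states))
    if (!igraph::is_connected(g, mode = "strong"))
      add("disconnected graph", "error",
          "positive-rate transition graph is not strongly connected")
  }

  if (!any(model$conducting))
    add("no conducting state", "warning", "model has no conducting state")

  violations <- if (length(v) > 0) do.call(rbind, v) else
    data.frame(check = character(), severity = character(),
               message = character())
  structure(list(ok = !any(violations$severity == "error"),
                 violations = violations),
            class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  cat("<model_validation>", if (x$ok) "PASS" else "FAIL", "\n")
  if (nrow(x$violations) > 0)
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s: %s\n", x$violations$severity[i],
                  x$violations$check[i], x$violations$message[i]))
  invisible(x)
}

#' Minimal two-state closed/open example model
#'
#' A ligand-independent closed <-> open scheme with opening rate 1 s^-1 and
#' closing rate 9 s^-1 (equilibrium open probability 0.1), used throughout
#' the documentation and tests.
#'
#' @param opening,closing gating rates in s^-1.
#' @return a [state_model()].
#' @export
two_state_example <- function(opening = 1, closing = 9) {
  state_model(
    states = c("closed", "open"),
    conducting = c(FALSE, TRUE),
    transitions = data.frame(
      from = c("closed", "open"), to = c("open", "closed"),
      rate = c(opening, closing), ligand_dependent = FALSE,
      kind = "gating"),
    metadata = list(mechanism = "two_state")
  )
}

# internal: stop unless the model is structurally sound.  Connectivity is
# deliberately not required here: absorbing or frozen chains are legal for
# stochastic simulation, and reducibility is diagnosed where uniqueness of
# the stationary distribution actually matters (equilibrium_occupancy).
assert_valid_model <- function(model) {
  val <- validate_model(model)
  errs <- val$violations[val$violations$severity == "error" &
                           val$violations$check != "disconnected graph", ,
                         drop = FALSE]
  if (nrow(errs) > 0)
    stop("invalid state model: ", paste(errs$message, collapse = "; "))
  invisible(model)
}
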