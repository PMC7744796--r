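#' Write a state model to a JSON specification file
#'
#' The on-disk format is a JSON document with `states` (objects with
#' `name` and `conducting`), `transitions` (objects with `from`, `to`,
#' `rate`, `ligand_dependent` and optional `kind`) and `metadata`.
#' Load -> save -> load is the identity.
#'
#' @param model a [state_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_state_model <- function(model, path) {
  doc <- list(
    states = data.frame(name = model$states, conducting = model$conducting),
    transitions = model$transitions,
    metadata = model$metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a state model from a JSON specification file
#'
#' Schema-validated: unknown top-level or transition fields are an error
#' naming the offending field.  In strict mode (the default) rates must
#' be JSON numbers; with `strict = FALSE` numeric strings such as
#' `"1e2"` are coerced.
#'
#' @param path JSON file written by [write_state_model()] or by hand.
#' @param strict reject string-encoded numbers.
#' @return a [state_model()].
#' @export
read_state_model <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(doc), c("states", "transitions", "metadata"))
  if (length(extra) > 0)
    stop("unknown field(s) in model specification: ",
         paste(extra, collapse = ", "))
  if (is.null(doc$states) || is.null(doc$transitions))
    stop("model specification must contain 'states' and 'transitions'")

  st <- as.data.frame(doc$states)
  extra <- setdiff(names(st), c("name", "conducting"))
  if (length(extra) > 0)
    stop("unknown state field(s): ", paste(extra, collapse = ", "))

  tr <- as.data.frame(doc$transitions)
  extra <- setdiff(names(tr),
                   c("from", "to", "rate", "ligand_dependent", "kind"))
  if (length(extra) > 0)
    stop("unknown transition field(s): ", paste(extra, collapse = ", "))
  if (is.character(tr$rate)) {
    if (strict)
      stop("transition rates must be numbers, not strings ",
           "(use strict = FALSE to coerce)")
    tr$rate <- as.numeric(tr$rate)
    if (anyNA(tr$rate)) stop("non-numeric rate string in specification")
  }
  md <- doc$metadata %||% list()
  state_model(states = as.character(st$name),
              conducting = as.logical(st$conducting),
              transitions = tr, metadata = as.list(md))
}

#' Export an occupancy trajectory to CSV (and its spectrum to JSON)
#'
#' CSV columns: `time_s`, one column per state, `conducting_fraction`.
#'
#' @param traj an `occupancy_trajectory` from [relax()] or
#'   [concentration_jump()].
#' @param csv_path output CSV path.
#' @param spectrum_path optional path for a JSON record of the relaxation
#'   spectrum (amplitudes, time constants, equilibrium level).
#' @return `csv_path`, invisibly.
#' @export
write_trajectory <- function(traj, csv_path, spectrum_path = NULL) {
  utils::write.csv(as.data.frame(traj), csv_path, row.names = FALSE)
  if (!is.null(spectrum_path))
    jsonlite::write_json(
      list(equilibrium_level = traj$equilibrium_level,
           ligand_uM = traj$ligand,
           components = traj$spectrum,
           flagged = traj$flagged),
      spectrum_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}

#' Write a quench trace to CSV
#'
#' Columns `time_s`, `fluorescence`.
#'
#' @param trace a [quench_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_quench_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read a quench trace from CSV
#'
#' Expects columns `time_s` and `fluorescence` (extra columns ignored).
#'
#' @param path CSV file.
#' @param ... metadata passed to [quench_trace()].
#' @return a [quench_trace()].
#' @export
read_quench_trace <- function(path, ...) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "fluorescence") %in% names(d)))
    stop("trace CSV must have columns 'time_s' and 'fluorescence'")
  quench_trace(d$time_s, d$fluorescence, ...)
}

#' Write a synthetic stopped-flow experiment to disk
#'
#' One CSV per trace plus a JSON manifest holding the per-trace protocol
#' metadata, seeds and generation truth, so the whole experiment can be
#' re-generated and re-analysed bit-exactly.
#'
#' @param experiment a `stopped_flow_experiment` from
#'   [gen_stopped_flow_experiment()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_stopped_flow_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- experiment$manifest
  manifest$file <- sprintf("trace_%03d.csv", seq_len(nrow(manifest)))
  for (i in seq_along(experiment$traces))
    write_quench_trace(experiment$traces[[i]],
                       file.path(dir, manifest$file[i]))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
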