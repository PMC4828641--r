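# JSON serialization of recording sessions and flat CSV spike tables.

#' Write a recording session to JSON
#'
#' Losslessly serializes the spike trains, per-event windows and the evoking
#' sequence (events, SOA, seed, kind).  Empty-trial sessions are preserved.
#'
#' @param session A `recording_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  obj <- list(
    neuron_id = session$neuron_id,
    condition_id = session$condition_id,
    seed = session$seed,
    soa_ms = session$sequence$soa,
    gap_ms = session$sequence$gap_ms,
    kind = session$sequence$kind,
    events = session$sequence$events,
    windows_ms = session$windows,
    spikes_ms = lapply(session$spikes, as.numeric)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a recording session from JSON
#'
#' Validates the schema written by [write_session()]; violations raise a
#' parse error naming the offending key.
#'
#' @param path JSON file path.
#' @return A `recording_session`.
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("neuron_id", "seed", "soa_ms", "kind", "events", "windows_ms",
            "spikes_ms")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    stop_invalid("session file '%s': missing key(s) %s", path,
                 paste(missing, collapse = ", "))
  ev <- as.data.frame(obj$events)
  for (col in c("onset_ms", "freq_khz", "level_db", "duration_ms",
                "ramp_ms", "role")) {
    if (!col %in% names(ev))
      stop_invalid("session file '%s': events missing column '%s'",
                   path, col)
  }
  ev$freq_khz <- as.numeric(ev$freq_khz)
  ev$level_db <- as.numeric(ev$level_db)
  bad <- setdiff(unique(ev$role), TONE_ROLES)
  if (length(bad))
    stop_invalid("session file '%s': invalid value in key 'events$role': %s",
                 path, paste(bad, collapse = ", "))
  validate_events(ev)
  spikes <- obj$spikes_ms
  if (is.null(spikes)) spikes <- list()
  if (!is.list(spikes)) spikes <- as.list(spikes)
  spikes <- lapply(spikes, function(s) as.numeric(unlist(s)))
  if (length(spikes) != nrow(ev))
    stop_invalid("session file '%s': key 'spikes_ms' has %d entries for %d events",
                 path, length(spikes), nrow(ev))
  sq <- new_sequence(ev, soa = obj$soa_ms, seed = obj$seed,
                     kind = obj$kind, gap_ms = obj$gap_ms %||% 0)
  new_session(obj$neuron_id, sq, spikes, as.numeric(obj$windows_ms),
              obj$seed, condition_id = obj$condition_id %||% NA_character_)
}

#' Flat spike table from sessions
#'
#' One row per spike: `neuron_id`, `condition`, `trial` (event index),
#' `role`, `spike_time_ms` (relative to event onset).
#'
#' @param sessions A `recording_session` or list of them.
#' @return A data frame.
#' @export
session_spike_table <- function(sessions) {
  if (inherits(sessions, "recording_session")) sessions <- list(sessions)
  do.call(rbind, lapply(sessions, function(s) {
    n <- lengths(s$spikes)
    data.frame(
      neuron_id = s$neuron_id,
      condition = s$condition_id,
      trial = rep(seq_along(s$spikes), n),
      role = rep(s$sequence$events$role, n),
      spike_time_ms = unlist(s$spikes, use.names = FALSE) %||% numeric(0),
      stringsAsFactors = FALSE
    )
  }))
}
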