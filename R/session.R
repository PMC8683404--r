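#' Spike train of one sorted unit
#'
#' @param cell_id character identifier, unique within a session.
#' @param channel_id integer recording channel the unit was isolated on.
#' @param unit_index 0-based index of the unit within its channel.
#' @param times numeric spike times in seconds, sorted strictly ascending,
#'   non-negative and finite.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(cell_id, channel_id, unit_index = 0L, times = numeric()) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times)))
    stopf("spike train '%s': non-finite spike time", cell_id)
  if (length(times) && min(times) < 0)
    stopf("spike train '%s': negative spike time", cell_id)
  if (is.unsorted(times, strictly = TRUE))
    stopf("spike train '%s': spike times must be strictly increasing", cell_id)
  structure(
    list(cell_id = as.character(cell_id),
         channel_id = as.integer(channel_id),
         unit_index = as.integer(unit_index),
         times = times),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s> channel %d unit %d, %d spikes",
              x$cell_id, x$channel_id, x$unit_index, length(x$times)))
  if (length(x$times))
    cat(sprintf(" over [%.3f, %.3f] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Stimulation protocol block
#'
#' One block of either full-field light alternation or a train of
#' charge-balanced biphasic current pulses delivered through a single MEA
#' electrode. Electrical pulses are symmetric cathodic-first biphasic;
#' `amplitude` is the per-phase current and `phase_duration` the per-phase
#' width.
#'
#' @param protocol_id character identifier.
#' @param kind `"light"` or `"electrical"`.
#' @param onsets numeric vector of trial/pulse onset times, seconds, strictly
#'   increasing. Electrical onsets must be at least 1 s apart.
#' @param amplitude per-phase current, microamperes (electrical only).
#' @param phase_duration per-phase duration, milliseconds (electrical only).
#' @param on_duration,off_duration light phase durations, seconds.
#' @param polarity pulse shape descriptor (fixed for electrical protocols).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(protocol_id, kind = c("light", "electrical"),
                              onsets,
                              amplitude = NULL, phase_duration = NULL,
                              on_duration = 2, off_duration = 2,
                              polarity = "cathodic-first biphasic, symmetric") {
  kind <- match.arg(kind)
  onsets <- as.numeric(onsets)
  if (anyNA(onsets) || any(!is.finite(onsets)))
    stopf("protocol '%s': non-finite onset", protocol_id)
  if (is.unsorted(onsets, strictly = TRUE))
    stopf("protocol '%s': onsets must be strictly increasing", protocol_id)
  p <- list(protocol_id = as.character(protocol_id), kind = kind,
            onsets = onsets)
  if (kind == "electrical") {
    if (is.null(amplitude) || is.null(phase_duration))
      stopf("protocol '%s': electrical protocols need amplitude and phase_duration",
            protocol_id)
    if (amplitude <= 0 || phase_duration <= 0)
      stopf("protocol '%s': amplitude and phase_duration must be positive",
            protocol_id)
    if (length(onsets) > 1L && min(diff(onsets)) < 1 - 1e-9)
      stopf("protocol '%s': electrical pulses must be at least 1 s apart",
            protocol_id)
    p$amplitude <- amplitude
    p$phase_duration <- phase_duration
    p$polarity <- polarity
  } else {
    if (on_duration <= 0 || off_duration <= 0)
      stopf("protocol '%s': light phase durations must be positive", protocol_id)
    p$on_duration <- on_duration
    p$off_duration <- off_duration
  }
  structure(p, class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  if (x$kind == "electrical") {
    cat(sprintf("<stimulus_protocol %s> electrical: %g uA x %g ms, %d pulses\n",
                x$protocol_id, x$amplitude, x$phase_duration, length(x$onsets)))
  } else {
    cat(sprintf("<stimulus_protocol %s> light: %g s ON / %g s OFF, %d repeats\n",
                x$protocol_id, x$on_duration, x$off_duration, length(x$onsets)))
  }
  invisible(x)
}

#' Channel map of the 60-channel MEA
#'
#' 8 x 8 grid without the four corner positions (60 sites); channel 15 is the
#' large internal reference electrode, represented in the map but never
#' carrying spike trains. 59 sites are active recording/stimulation
#' electrodes.
#'
#' @return data.frame with columns `channel_id`, `grid_row`, `grid_col`,
#'   `is_reference`.
#' @export
default_channel_map <- function() {
  grid <- expand.grid(grid_row = 1:8, grid_col = 1:8)
  corner <- (grid$grid_row %in% c(1, 8)) & (grid$grid_col %in% c(1, 8))
  grid <- grid[!corner, , drop = FALSE]
  grid <- grid[order(grid$grid_col, grid$grid_row), , drop = FALSE]
  data.frame(channel_id = seq_len(nrow(grid)),
             grid_row = grid$grid_row,
             grid_col = grid$grid_col,
             is_reference = seq_len(nrow(grid)) == 15L,
             row.names = NULL)
}

#' Recording session
#'
#' Container for one retinal patch on the MEA: its spike trains, stimulation
#' protocols, channel geometry and (optionally) raw per-channel traces.
#'
#' @param session_id character identifier.
#' @param spike_trains list of [spike_train] objects.
#' @param protocols list of [stimulus_protocol] objects.
#' @param sampling_rate acquisition rate, Hz.
#' @param channel_map data.frame as produced by [default_channel_map()].
#' @param group_label `"normal"` (untreated) or `"mnu_treated"`
#'   (MNU-induced retinal degeneration).
#' @param raw_traces optional named list (by channel id) of numeric sample
#'   vectors, microvolts.
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(session_id,
                              spike_trains = list(),
                              protocols = list(),
                              sampling_rate = 25000,
                              channel_map = default_channel_map(),
                              group_label = c("normal", "mnu_treated"),
                              raw_traces = NULL) {
  group_label <- match.arg(group_label)
  if (sampling_rate <= 0) stopf("sampling_rate must be positive")
  if (length(spike_trains) && is.null(names(spike_trains)))
    names(spike_trains) <- vapply(spike_trains, `[[`, "", "cell_id")
  if (length(protocols) && is.null(names(protocols)))
    names(protocols) <- vapply(protocols, `[[`, "", "protocol_id")
  for (st in spike_trains) {
    if (!inherits(st, "spike_train")) stopf("spike_trains must be spike_train objects")
    if (!st$channel_id %in% channel_map$channel_id)
      stopf("spike train '%s': channel %d not in channel map",
            st$cell_id, st$channel_id)
    ref <- channel_map$is_reference[match(st$channel_id, channel_map$channel_id)]
    if (isTRUE(ref))
      stopf("spike train '%s': reference channel %d cannot carry units",
            st$cell_id, st$channel_id)
  }
  for (p in protocols)
    if (!inherits(p, "stimulus_protocol")) stopf("protocols must be stimulus_protocol objects")
  structure(
    list(session_id = as.character(session_id),
         sampling_rate = sampling_rate,
         channel_map = channel_map,
         spike_trains = spike_trains,
         protocols = protocols,
         group_label = group_label,
         raw_traces = raw_traces),
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  ne <- sum(vapply(x$protocols, function(p) p$kind == "electrical", logical(1)))
  cat(sprintf(
    "<recording_session %s> %s, %d units, %d protocols (%d electrical), %g Hz\n",
    x$session_id, x$group_label, length(x$spike_trains), length(x$protocols),
    ne, x$sampling_rate))
  invisible(x)
}

electrical_protocols <- function(session) {
  Filter(function(p) p$kind == "electrical", session$protocols)
}

light_protocols <- function(session) {
  Filter(function(p) p$kind == "light", session$protocols)
}

#' Locate an electrical protocol by amplitude and duration
#'
#' @param session a [recording_session].
#' @param amplitude per-phase current, microamperes.
#' @param phase_duration per-phase duration, milliseconds.
#' @param tol matching tolerance.
#' @return The matching [stimulus_protocol], or `NULL` if absent.
#' @export
find_protocol <- function(session, amplitude, phase_duration, tol = 1e-6) {
  for (p in electrical_protocols(session)) {
    if (abs(p$amplitude - amplitude) < tol &&
        abs(p$phase_duration - phase_duration) < tol) return(p)
  }
  NULL
}
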