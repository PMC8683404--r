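# Quantification of electrically evoked responses. Spontaneous activity is
# the rate over twenty 100-ms bins immediately before the first pulse of a
# protocol block; evoked activity is the mean per-trial spike count in the
# 10--100 ms post-pulse window (the first 10 ms are blanked: stimulus
# artifact and direct somatic activation). The relative response
# (evoked rate / baseline rate) is the quantity thresholded at 1.5x, both
# for responsiveness calls and, downstream, for threshold estimation.

#' Baseline (spontaneous) firing rate of a protocol block
#'
#' In `"per_pulse"` mode (the default), the spontaneous rate is the average
#' spike count in the `baseline_bin_width` (100 ms) bin immediately
#' preceding each pulse, over all trials, divided by the bin width; a
#' 50-pulse train therefore contributes 5 s of baseline, and slow drift is
#' tracked across the train. In `"block"` mode it is the total count in the
#' single `baseline_n_bins` x `baseline_bin_width` window (2 s) ending at
#' the first pulse onset, divided by the window length. With evoked
#' responses confined to 10--100 ms after each pulse and pulses 1 s apart,
#' the pre-pulse bins are uncontaminated in either mode.
#'
#' @param train a [spike_train].
#' @param protocol an electrical [stimulus_protocol].
#' @param config an [analysis_config]; `baseline_mode` selects the
#'   convention, and per-pulse baselines respect `max_trials`.
#' @return Spikes per second.
#' @export
baseline_rate <- function(train, protocol, config = analysis_config()) {
  config <- as_config(config)
  span <- config$baseline_n_bins * config$baseline_bin_width
  t0 <- protocol$onsets[1]
  if (t0 < span)
    stopf("protocol '%s': needs %.1f s of pre-stimulus recording, first onset at %.2f s",
          protocol$protocol_id, span, t0)
  if (config$baseline_mode == "block") {
    return(count_left_closed(train$times, t0 - span, t0) / span)
  }
  onsets <- protocol$onsets
  if (is.finite(config$max_trials) && length(onsets) > config$max_trials)
    onsets <- onsets[seq_len(config$max_trials)]
  w <- config$baseline_bin_width
  mean(count_left_closed(train$times, onsets - w, onsets)) / w
}

#' Evoked firing rate in the indirect-response window
#'
#' Mean spike count per trial in `(onset + 10 ms, onset + 100 ms]`,
#' divided by the window width (90 ms). Spikes in the artifact blank never
#' contribute.
#'
#' @inheritParams baseline_rate
#' @return Spikes per second.
#' @export
evoked_rate <- function(train, protocol, config = analysis_config()) {
  config <- as_config(config)
  if (!length(protocol$onsets)) stopf("protocol '%s' has no onsets",
                                      protocol$protocol_id)
  onsets <- protocol$onsets
  if (is.finite(config$max_trials) && length(onsets) > config$max_trials)
    onsets <- onsets[seq_len(config$max_trials)]
  win <- config$evoked_window
  counts <- count_right_closed(train$times, onsets + win[1], onsets + win[2])
  mean(counts) / diff(win)
}

#' Relative response
#'
#' Ratio of evoked to baseline rate. A silent-baseline cell with any evoked
#' spikes returns `Inf` (responsive by construction); 0/0 is 0.
#'
#' @param baseline,evoked rates in spikes per second, non-negative.
#' @return Dimensionless ratio.
#' @export
relative_response <- function(baseline, evoked) {
  if (any(baseline < 0) || any(evoked < 0))
    stopf("rates must be non-negative")
  ifelse(baseline > 0, evoked / baseline, ifelse(evoked > 0, Inf, 0))
}

#' Per-protocol trial response of one cell
#'
#' @inheritParams baseline_rate
#' @return A one-row data.frame: `cell_id`, `protocol_id`, `amplitude`,
#'   `phase_duration`, `baseline_rate`, `evoked_rate`, `evoked_count`
#'   (mean spikes per trial), `relative_response`, `n_trials`.
#' @export
trial_response <- function(train, protocol, config = analysis_config()) {
  config <- as_config(config)
  b <- baseline_rate(train, protocol, config)
  e <- evoked_rate(train, protocol, config)
  n <- min(length(protocol$onsets), config$max_trials)
  data.frame(cell_id = train$cell_id,
             protocol_id = protocol$protocol_id,
             amplitude = protocol$amplitude,
             phase_duration = protocol$phase_duration,
             baseline_rate = b,
             evoked_rate = e,
             evoked_count = e * diff(config$evoked_window),
             relative_response = relative_response(b, e),
             n_trials = n)
}

#' Is a cell responsive to electrical stimulation?
#'
#' Judged at the strongest tested stimulus (30 uA, 2 ms by default): the
#' cell is ES-responsive iff its relative response there reaches the
#' configured threshold factor (1.5).
#'
#' @param train a [spike_train].
#' @param session a [recording_session] containing the strongest-stimulus
#'   protocol.
#' @param config an [analysis_config].
#' @param amplitude,phase_duration the judging stimulus (uA, ms).
#' @return Logical.
#' @export
is_es_responsive <- function(train, session, config = analysis_config(),
                             amplitude = 30, phase_duration = 2) {
  config <- as_config(config)
  p <- find_protocol(session, amplitude, phase_duration)
  if (is.null(p))
    stopf("session has no %g uA / %g ms protocol", amplitude, phase_duration)
  tr <- trial_response(train, p, config)
  tr$relative_response >= config$response_threshold_factor
}

#' Peri-stimulus time histogram with confidence bound
#'
#' 20-ms bins spanning 0.5 s either side of pulse onset, counts averaged
#' over trials. The confidence bound is the pre-stimulus bin mean plus the
#' two-sided Student-t quantile (99\%, df = number of baseline bins - 1)
#' times the pre-stimulus bin SD; post-stimulus bins exceeding it mark
#' significant evoked activity. The t quantile (2.797 for 25 baseline bins)
#' rather than the normal one (2.576) accounts for the bound's mean and SD
#' being estimated from only ~25 baseline bins; with the normal quantile the
#' bound is anticonservative (~1.7\% of null bins exceed it instead of the
#' intended ~1\%).
#'
#' @param train a [spike_train].
#' @param protocol an electrical [stimulus_protocol] with at least 5 trials.
#' @param config an [analysis_config].
#' @return An object of class `stim_psth`: `bin_edges`, `bin_centers`,
#'   `counts` (mean spikes per bin per trial), `baseline_mean`,
#'   `confidence_bound`, `confidence_level`, `n_trials`.
#' @export
stim_psth <- function(train, protocol, config = analysis_config()) {
  config <- as_config(config)
  onsets <- protocol$onsets
  if (length(onsets) < 5L) stopf("stim_psth needs at least 5 trials")
  if (is.finite(config$max_trials) && length(onsets) > config$max_trials)
    onsets <- onsets[seq_len(config$max_trials)]
  edges <- seq(config$psth_window[1], config$psth_window[2],
               by = config$psth_bin)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  for (o in onsets)
    acc <- acc + count_left_closed(train$times, o + edges[-length(edges)],
                                   o + edges[-1L])
  counts <- acc / length(onsets)
  base_idx <- which(edges[-1L] <= 0 + 1e-12)
  bmean <- mean(counts[base_idx])
  bsd <- stats::sd(counts[base_idx])
  z <- stats::qt(1 - (1 - config$psth_confidence) / 2,
                 df = length(base_idx) - 1L)
  structure(
    list(bin_edges = edges,
         bin_centers = (edges[-1L] + edges[-length(edges)]) / 2,
         counts = counts,
         baseline_mean = bmean,
         confidence_bound = bmean + z * bsd,
         confidence_level = config$psth_confidence,
         bin_width = config$psth_bin,
         n_trials = length(onsets),
         cell_id = train$cell_id,
         protocol_id = protocol$protocol_id),
    class = "stim_psth"
  )
}

#' @export
print.stim_psth <- function(x, ...) {
  cat(sprintf(
    "<stim_psth %s/%s> %d bins of %.0f ms, %d trials, bound %.3f spikes/bin\n",
    x$cell_id, x$protocol_id, length(x$counts), x$bin_width * 1000,
    x$n_trials, x$confidence_bound))
  invisible(x)
}

#' @export
plot.stim_psth <- function(x, ...) {
  graphics::plot(x$bin_centers, x$counts, type = "h", lwd = 3,
                 xlab = "time from pulse onset (s)",
                 ylab = "mean spikes per bin",
                 main = sprintf("%s / %s", x$cell_id, x$protocol_id), ...)
  graphics::abline(h = x$confidence_bound, col = "red")
  graphics::abline(v = 0, col = "red", lty = 2)
  invisible(x)
}

#' Pulse-amplitude and pulse-duration response curves of one cell
#'
#' Measures the cell on the full amplitude-by-duration stimulus grid and
#' arranges the same measurements in two views: PAM curves (relative
#' response vs amplitude at each fixed duration) and PDM curves (vs duration
#' at each fixed amplitude). Mean evoked spike counts are carried alongside
#' the relative responses.
#'
#' @param train a [spike_train].
#' @param session a [recording_session] holding the complete stimulus grid.
#' @param config an [analysis_config].
#' @return An object of class `response_curve_set`: `measurements` (long
#'   data.frame), `pam` and `pdm` (lists of `response_curve` objects with
#'   fields `mode`, `fixed_value`, `x`, `y_relative`, `y_count`).
#' @export
response_curves <- function(train, session, config = analysis_config()) {
  config <- as_config(config)
  protos <- electrical_protocols(session)
  if (!length(protos)) stopf("session has no electrical protocols")
  meas <- do.call(rbind, lapply(protos, trial_response,
                                train = train, config = config))
  rownames(meas) <- NULL
  amps <- sort(unique(meas$amplitude))
  durs <- sort(unique(meas$phase_duration))
  if (length(amps) < 2L || length(durs) < 2L)
    stopf("need at least 2 amplitudes and 2 durations for response curves")
  missing <- list()
  for (a in amps) for (d in durs) {
    if (!any(abs(meas$amplitude - a) < 1e-9 &
             abs(meas$phase_duration - d) < 1e-9))
      missing[[length(missing) + 1L]] <- c(a, d)
  }
  if (length(missing))
    stopf("incomplete stimulus grid; missing (amplitude, duration): %s",
          paste(vapply(missing, function(m) sprintf("(%g, %g)", m[1], m[2]),
                       ""), collapse = " "))
  curve <- function(mode, fixed, x, rows) {
    rows <- rows[order(x), , drop = FALSE]
    structure(list(cell_id = train$cell_id, mode = mode, fixed_value = fixed,
                   x = sort(x), y_relative = rows$relative_response,
                   y_count = rows$evoked_count),
              class = "response_curve")
  }
  pam <- lapply(durs, function(d) {
    rows <- meas[abs(meas$phase_duration - d) < 1e-9, , drop = FALSE]
    curve("PAM", d, rows$amplitude, rows)
  })
  names(pam) <- sprintf("D%g", durs)
  pdm <- lapply(amps, function(a) {
    rows <- meas[abs(meas$amplitude - a) < 1e-9, , drop = FALSE]
    curve("PDM", a, rows$phase_duration, rows)
  })
  names(pdm) <- sprintf("A%g", amps)
  structure(list(cell_id = train$cell_id, measurements = meas,
                 pam = pam, pdm = pdm),
            class = "response_curve_set")
}

#' @export
print.response_curve_set <- function(x, ...) {
  cat(sprintf("<response_curve_set %s> %d PAM + %d PDM curves over %d stimuli\n",
              x$cell_id, length(x$pam), length(x$pdm), nrow(x$measurements)))
  invisible(x)
}

# Spearman rank correlation with the conventions the modulation classifier
# needs: infinite responses are rank-ordered naturally, constant curves get 0.
curve_rho <- function(x, y) {
  if (length(unique(y)) < 2L) return(0)
  suppressWarnings(r <- stats::cor(x, y, method = "spearman"))
  if (is.na(r)) 0 else r
}

#' Classify a cell's stimulus modulation
#'
#' A cell is *well-modulated* when every one of its response curves (3 PAM +
#' 5 PDM in the standard design) is proportional -- Spearman rank
#' correlation between stimulus strength and relative response at least
#' `rho_threshold` -- and the cell is ES-responsive at the strongest
#' stimulus. It is *unmodulated* when no curve is proportional or it is not
#' ES-responsive; otherwise *poorly modulated*. Rank-based, so invariant to
#' any monotone rescaling of the responses.
#'
#' @param curves a `response_curve_set` from [response_curves()].
#' @param es_responsive logical from [is_es_responsive()].
#' @param config an [analysis_config] (supplies `rho_threshold`).
#' @return A list of class `modulation_label`: `cell_id`, `label`
#'   (`"well"`, `"poor"`, `"unmodulated"`) and the per-curve `rho` vector.
#' @export
classify_modulation <- function(curves, es_responsive,
                                config = analysis_config()) {
  config <- as_config(config)
  all_curves <- c(curves$pam, curves$pdm)
  rho <- vapply(all_curves, function(cv) curve_rho(cv$x, cv$y_relative),
                numeric(1))
  thr <- config$rho_threshold
  label <- if (all(rho >= thr) && isTRUE(es_responsive)) "well"
           else if (!any(rho >= thr) || !isTRUE(es_responsive)) "unmodulated"
           else "poor"
  structure(list(cell_id = curves$cell_id, label = label, rho = rho,
                 es_responsive = es_responsive),
            class = "modulation_label")
}

#' @export
print.modulation_label <- function(x, ...) {
  cat(sprintf("<modulation_label %s> %s (rho in [%.2f, %.2f], ES %s)\n",
              x$cell_id, x$label, min(x$rho), max(x$rho),
              ifelse(isTRUE(x$es_responsive), "responsive", "unresponsive")))
  invisible(x)
}
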