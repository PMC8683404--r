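# Light-response classification and degeneration-severity calls. A cell is
# scored on the 0.5 s after light onset and after light offset; a phase is
# responsive when its spike count over all repeats exceeds the 99% Poisson
# upper bound implied by the cell's whole-block mean rate. ON / OFF / ON-OFF
# labels follow from the two flags, and a patch with no light-responsive
# cells in a treated retina is called severely degenerated.

#' Classify a cell's light response
#'
#' @param train a [spike_train].
#' @param protocol a light [stimulus_protocol] with at least 5 repeats.
#' @param config an [analysis_config]; uses `light_window` (scored window
#'   after each transition) and `light_confidence` (Poisson bound).
#' @return A list of class `light_classification`: `cell_id`, `label`
#'   (`"ON"`, `"OFF"`, `"ON_OFF"` or `"none"`), `onset_score` and
#'   `offset_score` (rate ratios relative to the whole-block mean).
#' @export
classify_light <- function(train, protocol, config = analysis_config()) {
  if (protocol$kind != "light") stopf("classify_light needs a light protocol")
  n <- length(protocol$onsets)
  if (n < 5L) stopf("need at least 5 light repeats, got %d", n)
  config <- as_config(config)
  w <- config$light_window
  block_start <- protocol$onsets[1]
  block_end <- max(protocol$onsets) + protocol$on_duration + protocol$off_duration
  block_dur <- block_end - block_start

  times <- train$times
  total <- count_left_closed(times, block_start, block_end)
  out <- function(label, on_score, off_score) {
    structure(list(cell_id = train$cell_id, label = label,
                   onset_score = on_score, offset_score = off_score),
              class = "light_classification")
  }
  if (total == 0L) return(out("none", 0, 0))

  block_rate <- total / block_dur
  offs <- protocol$onsets + protocol$on_duration
  n_on <- sum(count_left_closed(times, protocol$onsets, protocol$onsets + w))
  n_off <- sum(count_left_closed(times, offs, offs + w))
  expected <- block_rate * w * n
  crit <- stats::qpois(config$light_confidence, expected)
  sig_on <- n_on > crit
  sig_off <- n_off > crit
  label <- if (sig_on && sig_off) "ON_OFF"
           else if (sig_on) "ON"
           else if (sig_off) "OFF"
           else "none"
  out(label,
      (n_on / (w * n)) / block_rate,
      (n_off / (w * n)) / block_rate)
}

#' @export
print.light_classification <- function(x, ...) {
  cat(sprintf("<light_classification %s> %s (onset %.2f, offset %.2f)\n",
              x$cell_id, x$label, x$onset_score, x$offset_score))
  invisible(x)
}

#' Fraction of light-responsive cells in a patch
#'
#' @param labels character vector of light labels (one per cell), or a
#'   data.frame with a `label` column as produced by the pipeline.
#' @return Percentage of cells labeled other than `"none"`.
#' @export
ls_fraction <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  if (!length(labels)) {
    warnf("ls_fraction undefined for an empty patch")
    return(NA_real_)
  }
  100 * mean(labels != "none")
}

#' Assign retinal-degeneration severity to a patch
#'
#' Untreated patches are `"normal"` by definition; treated patches with no
#' light-responsive cells are `"severe"`, otherwise `"non_severe"`.
#'
#' @param group_label `"normal"` or `"mnu_treated"` (or a
#'   [recording_session], whose label is used).
#' @param ls_percent light-responsive percentage from [ls_fraction()].
#' @param patch_id identifier carried into the result.
#' @return A list of class `severity_call`.
#' @export
classify_severity <- function(group_label, ls_percent, patch_id = NA_character_) {
  if (inherits(group_label, "recording_session")) {
    if (is.na(patch_id)) patch_id <- group_label$session_id
    group_label <- group_label$group_label
  }
  group_label <- match.arg(group_label, c("normal", "mnu_treated"))
  severity <- if (group_label == "normal") "normal"
              else if (!is.na(ls_percent) && ls_percent == 0) "severe"
              else "non_severe"
  structure(list(patch_id = patch_id, group_label = group_label,
                 ls_fraction = ls_percent, severity = severity),
            class = "severity_call")
}

#' @export
print.severity_call <- function(x, ...) {
  cat(sprintf("<severity_call %s> %s (%s, %.1f%% light-responsive)\n",
              x$patch_id, x$severity, x$group_label, x$ls_fraction))
  invisible(x)
}
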