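# End-to-end analysis: light classification, severity, per-stimulus evoked
# responses, modulation labels, thresholds, strength-duration fits and
# charge metrics for every cell of a session.

#' Run the full analysis pipeline on one session
#'
#' For each cell: classify the light response (if a light protocol is
#' present), measure baseline/evoked/relative responses on every electrical
#' protocol, call ES-responsiveness at the strongest stimulus, build PAM and
#' PDM response curves, classify modulation, estimate thresholds on every
#' curve, fit the strength-duration law to the pooled (duration, current)
#' threshold pairs, and convert thresholds to per-phase charge and charge
#' density. All outputs are data.frames keyed by `cell_id`; the run is
#' deterministic given session, configuration and seed.
#'
#' @param session a [recording_session] with at least one electrical
#'   protocol.
#' @param config an [analysis_config].
#' @param seed integer seed (the analysis itself is deterministic; the seed
#'   is fixed for any stochastic components such as k-means restarts in
#'   optional re-sorting).
#' @return A list of class `report_bundle` with elements: `light`
#'   (per-cell label and scores), `severity` (a `severity_call`), `responses`
#'   (long per-cell-per-stimulus table), `cells` (per-cell ES-responsiveness,
#'   modulation label, minimum curve rho), `thresholds` (non-censored
#'   per-cell thresholds with charge metrics), `censored` (count of censored
#'   curves per cell), `sd_fits` (per-cell rheobase/chronaxie), and
#'   `summary` ([report_tables()] over this session's single group).
#' @export
run_pipeline <- function(session, config = analysis_config(), seed = 1L) {
  config <- as_config(config)
  eprotos <- electrical_protocols(session)
  if (!length(eprotos))
    stopf("session '%s' has no electrical protocols", session$session_id)
  lproto <- light_protocols(session)
  lproto <- if (length(lproto)) lproto[[1L]] else NULL
  group <- if (session$group_label == "normal") "normal" else "mnu_treated"

  judge <- judging_stimulus(eprotos)
  light_rows <- list(); resp_rows <- list(); cell_rows <- list()
  thr_rows <- list(); cens_rows <- list(); fit_rows <- list()

  with_seed(seed, for (st in session$spike_trains) {
    cid <- st$cell_id
    if (!is.null(lproto)) {
      lc <- classify_light(st, lproto, config)
      light_rows[[cid]] <- data.frame(cell_id = cid, label = lc$label,
                                      onset_score = lc$onset_score,
                                      offset_score = lc$offset_score)
    }
    curves <- response_curves(st, session, config)
    resp_rows[[cid]] <- curves$measurements
    es <- is_es_responsive(st, session, config,
                           amplitude = judge[1L], phase_duration = judge[2L])
    ml <- classify_modulation(curves, es, config)

    ths <- lapply(c(curves$pam, curves$pdm), threshold_from_curve,
                  level = config$response_threshold_factor)
    thr_df <- do.call(rbind, lapply(ths, function(th) data.frame(
      cell_id = cid, mode = th$mode, fixed_value = th$fixed_value,
      threshold_value = th$threshold_value, method = th$method)))
    rownames(thr_df) <- NULL
    cens_rows[[cid]] <- data.frame(cell_id = cid,
                                   n_censored = sum(thr_df$method == "censored"))
    ok <- thr_df[thr_df$method != "censored", , drop = FALSE]
    if (nrow(ok)) {
      amp_mode <- ok$mode == "amplitude_at_fixed_duration"
      ok$threshold_current <- ifelse(amp_mode, ok$threshold_value, ok$fixed_value)
      ok$threshold_duration <- ifelse(amp_mode, ok$fixed_value, ok$threshold_value)
      ok$charge_nC <- charge_per_phase(ok$threshold_current,
                                       ok$threshold_duration)
      ok$charge_density <- charge_density(ok$charge_nC,
                                          config$electrode_diameter)
      thr_rows[[cid]] <- ok
      # SD fitting uses grid-supported (interpolated) thresholds only:
      # extrapolated values are convention-clamped and carry high leverage;
      # they stay in the threshold tables but would distort the hyperbola.
      fit_pts <- ok[ok$method == "interpolated", , drop = FALSE]
      if (length(unique(fit_pts$threshold_duration)) < 2L) fit_pts <- ok
      fit <- suppressWarnings(
        fit_sd(fit_pts$threshold_duration, fit_pts$threshold_current, cid))
      if (!is.null(fit)) {
        fit_rows[[cid]] <- data.frame(
          cell_id = cid, rheobase = fit$rheobase, chronaxie = fit$chronaxie,
          rss = fit$rss, n_points = fit$n_points, converged = fit$converged,
          method = fit$method)
      }
    }
    cell_rows[[cid]] <- data.frame(cell_id = cid, es_responsive = es,
                                   modulation = ml$label,
                                   rho_min = min(ml$rho), rho_max = max(ml$rho))
  })

  bind <- function(rows, proto) {
    if (length(rows)) {
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    } else proto
  }
  light <- bind(light_rows, data.frame(cell_id = character(),
                                       label = character(),
                                       onset_score = numeric(),
                                       offset_score = numeric()))
  cells <- bind(cell_rows, data.frame(cell_id = character(),
                                      es_responsive = logical(),
                                      modulation = character(),
                                      rho_min = numeric(), rho_max = numeric()))
  thresholds <- bind(thr_rows, data.frame(
    cell_id = character(), mode = character(), fixed_value = numeric(),
    threshold_value = numeric(), method = character(),
    threshold_current = numeric(), threshold_duration = numeric(),
    charge_nC = numeric(), charge_density = numeric()))
  sd_fits <- bind(fit_rows, data.frame(
    cell_id = character(), rheobase = numeric(), chronaxie = numeric(),
    rss = numeric(), n_points = integer(), converged = logical(),
    method = character()))
  censored <- bind(cens_rows, data.frame(cell_id = character(),
                                         n_censored = integer()))

  ls_pct <- if (!is.null(lproto) && nrow(light)) ls_fraction(light) else NA_real_
  severity <- classify_severity(session$group_label, ls_pct,
                                session$session_id)

  # report over this session's single group, restricted to well-modulated
  # cells for the threshold and SD summaries (the convention for
  # prosthetics-relevant parameter reporting)
  well_ids <- cells$cell_id[cells$modulation == "well"]
  thr_rep <- thresholds[thresholds$cell_id %in% well_ids, , drop = FALSE]
  fits_rep <- sd_fits[sd_fits$cell_id %in% well_ids, , drop = FALSE]
  summary_tabs <- if (nrow(cells)) {
    report_tables(
      cbind(thr_rep, group = rep(group, nrow(thr_rep))),
      cbind(fits_rep, group = rep(group, nrow(fits_rep))),
      data.frame(cell_id = cells$cell_id, group = group,
                 label = cells$modulation),
      diameter_um = config$electrode_diameter)
  } else NULL

  structure(list(session_id = session$session_id, group_label = group,
                 light = light, severity = severity, responses = bind(
                   resp_rows, data.frame()),
                 cells = cells, thresholds = thresholds, censored = censored,
                 sd_fits = sd_fits, summary = summary_tabs, config = config),
            class = "report_bundle")
}

# Strongest stimulus available in a protocol set (largest charge).
judging_stimulus <- function(eprotos) {
  q <- vapply(eprotos, function(p) p$amplitude * p$phase_duration, numeric(1))
  p <- eprotos[[which.max(q)]]
  c(p$amplitude, p$phase_duration)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle %s> %s\n", x$session_id, x$group_label))
  cat(sprintf("  cells analysed: %d\n", nrow(x$cells)))
  if (nrow(x$light))
    cat(sprintf("  light-responsive: %.1f%%\n", ls_fraction(x$light)))
  cat(sprintf("  severity: %s\n", x$severity$severity))
  if (nrow(x$cells)) {
    tab <- table(x$cells$modulation)
    cat("  modulation:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = " "), "\n")
  }
  cat(sprintf("  thresholds: %d, SD fits: %d\n", nrow(x$thresholds),
              nrow(x$sd_fits)))
  invisible(x)
}
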