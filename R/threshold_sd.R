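# Threshold estimation, strength-duration fitting and charge bookkeeping.
# A threshold is the stimulus value (amplitude for PAM curves, duration for
# PDM curves) at which the relative-response curve crosses the 1.5x-baseline
# criterion; (duration, current) threshold pairs are then fitted with the
# classical hyperbolic strength-duration law I = R (1 + C/D) to extract the
# rheobase R and chronaxie C, and thresholds are converted to per-phase
# charge and to charge density over the geometric electrode area.

#' Threshold from a response curve
#'
#' Finds the first upward crossing of `level` along the curve and linearly
#' interpolates between the bracketing tested points. If the response
#' already exceeds `level` at the smallest tested stimulus, the crossing is
#' linearly extrapolated from the first two points, floored at
#' `floor_frac` times the smallest tested value. A curve that never reaches
#' `level` is censored (no threshold value). Infinite relative responses
#' (silent-baseline cells) are capped at a large finite value first.
#'
#' @param curve a `response_curve` from [response_curves()].
#' @param level response criterion (1.5 times baseline by default).
#' @param floor_frac extrapolation floor as a fraction of the smallest
#'   tested stimulus.
#' @param cap replacement for infinite relative responses.
#' @return An object of class `threshold_estimate`: `cell_id`, `mode`
#'   (`"amplitude_at_fixed_duration"` or `"duration_at_fixed_amplitude"`),
#'   `fixed_value`, `threshold_value` (uA or ms; `NA` when censored) and
#'   `method` (`"interpolated"`, `"extrapolated"`, `"censored"`).
#' @export
threshold_from_curve <- function(curve, level = 1.5, floor_frac = 0.1,
                                 cap = 1e6) {
  x <- curve$x
  y <- curve$y_relative
  if (length(x) < 2L) stopf("threshold_from_curve needs at least 2 points")
  if (any(!is.finite(y))) {
    y <- pmin(y, cap)
    message("threshold_from_curve: infinite relative responses capped")
  }
  mode <- if (identical(curve$mode, "PDM")) "duration_at_fixed_amplitude"
          else "amplitude_at_fixed_duration"
  res <- function(value, method) {
    structure(list(cell_id = curve$cell_id, mode = mode,
                   fixed_value = curve$fixed_value,
                   threshold_value = value, method = method),
              class = "threshold_estimate")
  }
  up <- which(y[-length(y)] < level & y[-1L] >= level)
  if (y[1L] >= level) {
    # already responsive at the weakest stimulus
    slope <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    if (slope > 0) {
      # rising curve: extrapolate the first segment back to the criterion
      value <- max(x[1L] + (level - y[1L]) / slope, floor_frac * x[1L])
      return(res(value, "extrapolated"))
    }
    if (length(up)) {
      # starts above the level but falls below and re-crosses: the initial
      # exceedance is not the recruitment threshold; use the upward crossing
      warnf("non-monotone curve for '%s': first upward crossing used",
            curve$cell_id)
      i <- up[1L]
      value <- x[i] + (level - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
      return(res(value, "interpolated"))
    }
    if (all(y >= level)) {
      # supra-threshold everywhere with a flat/falling start: the threshold
      # lies below the tested range but the first segment carries no slope
      # information, so report the extrapolation floor
      return(res(floor_frac * x[1L], "extrapolated"))
    }
    # the initial exceedance is inconsistent with the rest of the curve
    # (later points fall below the level and never recover): noise, censor
    return(res(NA_real_, "censored"))
  }
  if (!length(up)) return(res(NA_real_, "censored"))
  if (length(up) > 1L)
    warnf("non-monotone curve for '%s': first upward crossing used",
          curve$cell_id)
  i <- up[1L]
  value <- x[i] + (level - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
  res(value, "interpolated")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate %s> %s @ %g: %s (%s)\n",
              x$cell_id, x$mode, x$fixed_value,
              ifelse(is.na(x$threshold_value), "censored",
                     sprintf("%.3f", x$threshold_value)), x$method))
  invisible(x)
}

#' Fit the strength-duration law
#'
#' Nonlinear least squares on `I(D) = R (1 + C/D)` over (duration, current)
#' threshold pairs, initialised from the Weiss charge linearisation
#' (regressing `Q = I D` on `D`: slope = R, intercept = R C) and constrained
#' to positive parameters. With `weighting = "charge"` (the default) the
#' residuals are duration-weighted (`w = D^2`), i.e. least squares in
#' per-phase-charge coordinates `Q(D) = R D + R C`: threshold currents at
#' short durations are large and noisy (their error scales with `I` itself),
#' so charge weighting handles the heteroscedasticity and is substantially
#' more stable. `weighting = "none"` is ordinary least squares on the
#' currents. On non-convergence the linearised estimate is returned,
#' flagged. Two points give the exact hyperbola through both.
#'
#' @param durations pulse durations, ms.
#' @param currents threshold currents, uA.
#' @param cell_id identifier carried into the result.
#' @param weighting `"charge"` (duration-weighted, default) or `"none"`.
#' @return An object of class `sd_fit`: `rheobase` (uA), `chronaxie` (ms),
#'   `rss` (in the weighted objective), `n_points`, `converged`, `method`;
#'   or `NULL` (with a warning) when fewer than 2 usable pairs with distinct
#'   durations exist.
#' @export
fit_sd <- function(durations, currents, cell_id = NA_character_,
                   weighting = c("charge", "none")) {
  weighting <- match.arg(weighting)
  keep <- is.finite(durations) & is.finite(currents) &
    durations > 0 & currents > 0
  d <- durations[keep]
  i <- currents[keep]
  if (length(d) < 2L || length(unique(d)) < 2L) {
    warnf("fit_sd: fewer than 2 usable (duration, current) pairs for '%s'; fit refused",
          cell_id)
    return(NULL)
  }
  w <- if (weighting == "charge") d^2 else rep(1, length(d))
  out <- function(R, C, rss, converged, method) {
    structure(list(cell_id = cell_id, rheobase = R, chronaxie = C, rss = rss,
                   n_points = length(d), converged = converged,
                   method = method, weighting = weighting),
              class = "sd_fit")
  }
  # Weiss linearisation for starting values
  q <- i * d
  lin <- stats::lm(q ~ d)
  R0 <- unname(stats::coef(lin)[2L])
  C0 <- unname(stats::coef(lin)[1L]) / R0
  if (!is.finite(R0) || R0 <= 0) R0 <- stats::median(i)
  if (!is.finite(C0) || C0 <= 0) C0 <- stats::median(d)
  fit <- tryCatch(
    stats::nls(i ~ R * (1 + C / d), start = list(R = R0, C = C0),
               weights = w, algorithm = "port", lower = c(R = 1e-9, C = 1e-9),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    R0 <- max(R0, 1e-9); C0 <- max(C0, 1e-9)
    rss <- sum(w * (i - R0 * (1 + C0 / d))^2)
    return(out(R0, C0, rss, FALSE, "weiss_linearized"))
  }
  cf <- stats::coef(fit)
  out(unname(cf["R"]), unname(cf["C"]), sum(w * stats::resid(fit)^2),
      TRUE, "nls")
}

#' @export
print.sd_fit <- function(x, ...) {
  cat(sprintf(
    "<sd_fit %s> rheobase %.3f uA, chronaxie %.3f ms (%d points, rss %.3g, %s)\n",
    x$cell_id, x$rheobase, x$chronaxie, x$n_points, x$rss, x$method))
  invisible(x)
}

#' Per-phase charge of a biphasic pulse
#'
#' @param amplitude per-phase current, microamperes.
#' @param duration per-phase duration, milliseconds.
#' @return Charge in nanocoulombs (uA x ms = nC). Vectorised.
#' @examples
#' charge_per_phase(8, 0.5)  # 4 nC
#' @export
charge_per_phase <- function(amplitude, duration) {
  if (any(amplitude < 0) || any(duration < 0))
    stopf("amplitude and duration must be non-negative")
  amplitude * duration
}

#' Geometric area of a disc electrode
#'
#' @param diameter_um electrode diameter, micrometres.
#' @return Area in cm^2 (7.0686e-6 cm^2 for the 30-um electrode).
#' @export
electrode_area_cm2 <- function(diameter_um = 30) {
  if (any(diameter_um <= 0)) stopf("diameter must be positive")
  pi * (diameter_um / 2 * 1e-4)^2
}

#' Charge density over the electrode's geometric area
#'
#' @param charge_nC per-phase charge, nanocoulombs.
#' @param diameter_um electrode diameter, micrometres.
#' @return Charge density in mC cm^-2 per phase. Vectorised over
#'   `charge_nC`. Rounding to 2 decimals is left to report time.
#' @examples
#' charge_density(charge_per_phase(7.93, 0.5))  # ~0.56
#' @export
charge_density <- function(charge_nC, diameter_um = 30) {
  if (any(charge_nC < 0)) stopf("charge must be non-negative")
  charge_nC * 1e-6 / electrode_area_cm2(diameter_um)
}

#' Group means with one-way ANOVA and Tukey HSD
#'
#' @param values numeric per-cell values (e.g. rheobase).
#' @param groups group membership, same length.
#' @return A list of class `group_summary`: `summary` (per-group n, mean,
#'   SEM), `anova` (`F`, `p`), `tukey` (pairwise adjusted p-values with
#'   significance stars: `***` p < 0.001, `*` p < 0.05, `n.s` otherwise).
#'   Groups with fewer than 2 values are excluded with a warning; with
#'   fewer than 2 surviving groups the ANOVA slots are `NA`.
#' @export
group_summary <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  tab <- table(groups)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warnf("excluding groups with n < 2: %s", paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]
    groups <- groups[keep]
  }
  gs <- sort(unique(groups))
  summ <- data.frame(
    group = gs,
    n = vapply(gs, function(g) sum(groups == g), integer(1)),
    mean = vapply(gs, function(g) mean(values[groups == g]), numeric(1)),
    sem = vapply(gs, function(g) {
      v <- values[groups == g]
      stats::sd(v) / sqrt(length(v))
    }, numeric(1)),
    row.names = NULL)
  star <- function(p) ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                      ifelse(p < 0.05, "*", "n.s")))
  if (length(gs) < 2L) {
    return(structure(list(summary = summ,
                          anova = list(F = NA_real_, p = NA_real_),
                          tukey = NULL),
                     class = "group_summary"))
  }
  df <- data.frame(value = values, group = factor(groups))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  Fv <- an[["F value"]][1L]
  pv <- an[["Pr(>F)"]][1L]
  if (is.na(Fv)) { Fv <- 0; pv <- 1 }  # zero between-group variance
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      stars = star(tk[, "p adj"]),
                      row.names = NULL)
  structure(list(summary = summ,
                 anova = list(F = Fv, p = pv, stars = star(pv)),
                 tukey = tukey),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group summary (mean ± SEM):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s n = %3d   %.3f ± %.3f\n",
                x$summary$group[i], x$summary$n[i], x$summary$mean[i],
                x$summary$sem[i]))
  if (!is.na(x$anova$F))
    cat(sprintf("  one-way ANOVA: F = %.3f, p = %.4g (%s)\n",
                x$anova$F, x$anova$p, x$anova$stars))
  if (!is.null(x$tukey)) {
    for (i in seq_len(nrow(x$tukey)))
      cat(sprintf("  Tukey %-24s p_adj = %.4g %s\n", x$tukey$comparison[i],
                  x$tukey$p_adj[i], x$tukey$stars[i]))
  }
  invisible(x)
}

#' Format a well-modulated percentage
#'
#' @param k,n counts (well-modulated over total).
#' @return A string `"P% (k/n)"` with P at two decimals, e.g.
#'   `format_percent_count(75, 432)` is `"17.36% (75/432)"`.
#' @export
format_percent_count <- function(k, n) {
  if (n <= 0) stopf("n must be positive")
  sprintf("%.2f%% (%d/%d)", 100 * k / n, as.integer(k), as.integer(n))
}

#' Summary tables for thresholds, SD fits and modulation labels
#'
#' Produces the group-level report: well-modulated percentages, threshold
#' mean +/- SEM per stimulation mode with charge densities, and
#' rheobase/chronaxie summaries. Censored thresholds are excluded from the
#' means (their counts are reported). Charge density is reported both as the
#' mean of per-cell densities (`density_mean_cells`, the per-cell averaging
#' convention) and as the density of the group-mean threshold
#' (`density_of_mean`).
#'
#' @param thresholds data.frame with columns `cell_id`, `group`, `mode`,
#'   `fixed_value`, `threshold_value`, `method` (censored rows may carry
#'   `NA` threshold values).
#' @param fits data.frame with columns `cell_id`, `group`, `rheobase`,
#'   `chronaxie`.
#' @param labels data.frame with columns `cell_id`, `group`, `label`
#'   (modulation classes).
#' @param diameter_um electrode diameter for the density conversion.
#' @return A list of class `report_tables`: `well_modulated`, `thresholds`,
#'   `sd_fits` data.frames.
#' @export
report_tables <- function(thresholds, fits, labels, diameter_um = 30) {
  wm_proto <- data.frame(group = character(), n_well = integer(),
                         n_cells = integer(), formatted = character())
  thr_proto <- data.frame(group = character(), mode = character(),
                          fixed_value = numeric(), n = integer(),
                          n_censored = integer(), mean = numeric(),
                          sem = numeric(), density_mean_cells = numeric(),
                          density_of_mean = numeric())
  sd_proto <- data.frame(group = character(), n = integer(),
                         rheobase_mean = numeric(), rheobase_sem = numeric(),
                         chronaxie_mean = numeric(), chronaxie_sem = numeric())
  wm <- do.call(rbind, c(list(wm_proto),
                         lapply(split(labels, labels$group), function(g) {
    k <- sum(g$label == "well")
    n <- nrow(g)
    data.frame(group = g$group[1L], n_well = k, n_cells = n,
               formatted = format_percent_count(k, n))
  })))
  rownames(wm) <- NULL

  key <- interaction(thresholds$group, thresholds$mode,
                     thresholds$fixed_value, drop = TRUE)
  thr_tab <- do.call(rbind, c(list(thr_proto),
                              lapply(split(thresholds, key), function(g) {
    ok <- !is.na(g$threshold_value)
    v <- g$threshold_value[ok]
    amp_mode <- g$mode[1L] == "amplitude_at_fixed_duration"
    # per-cell charge: threshold x fixed partner value (uA x ms either way)
    qs <- charge_per_phase(if (amp_mode) v else g$fixed_value[1L],
                           if (amp_mode) g$fixed_value[1L] else v)
    m <- if (length(v)) mean(v) else NA_real_
    q_of_mean <- if (length(v)) {
      charge_per_phase(if (amp_mode) m else g$fixed_value[1L],
                       if (amp_mode) g$fixed_value[1L] else m)
    } else NA_real_
    data.frame(
      group = g$group[1L], mode = g$mode[1L], fixed_value = g$fixed_value[1L],
      n = length(v), n_censored = sum(!ok),
      mean = m,
      sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      density_mean_cells = if (length(v)) mean(charge_density(qs, diameter_um))
                           else NA_real_,
      density_of_mean = if (length(v)) charge_density(q_of_mean, diameter_um)
                        else NA_real_)
  })))
  rownames(thr_tab) <- NULL
  thr_tab <- thr_tab[order(thr_tab$group, thr_tab$mode, thr_tab$fixed_value), ,
                     drop = FALSE]

  sd_tab <- do.call(rbind, c(list(sd_proto),
                             lapply(split(fits, fits$group), function(g) {
    sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    data.frame(group = g$group[1L], n = nrow(g),
               rheobase_mean = mean(g$rheobase), rheobase_sem = sem(g$rheobase),
               chronaxie_mean = mean(g$chronaxie),
               chronaxie_sem = sem(g$chronaxie))
  })))
  rownames(sd_tab) <- NULL
  structure(list(well_modulated = wm, thresholds = thr_tab, sd_fits = sd_tab),
            class = "report_tables")
}

#' @export
print.report_tables <- function(x, ...) {
  cat("Well-modulated cells:\n")
  for (i in seq_len(nrow(x$well_modulated)))
    cat(sprintf("  %-12s %s\n", x$well_modulated$group[i],
                x$well_modulated$formatted[i]))
  cat("Thresholds (mean ± SEM; density in mC cm^-2 phase^-1):\n")
  print(x$thresholds, digits = 3)
  cat("Strength-duration fits:\n")
  print(x$sd_fits, digits = 3)
  invisible(x)
}
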