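# Synthetic retinal patches. Each simulated RGC is a homogeneous Poisson
# process (spontaneous firing) on which light transients and electrically
# evoked indirect responses are superimposed. Electrical recruitment is a
# logistic function of per-phase charge Q = I*D, positioned so that the
# stimulus amplitude solving the strength-duration law I = R(1 + C/D) lands
# exactly at the 1.5x-baseline crossing of the expected relative-response
# curve: the SD law is therefore the ground truth the estimation pipeline
# must recover.

#' Generative model of one simulated RGC
#'
#' @param cell_id character identifier.
#' @param spont_rate spontaneous firing rate, Hz.
#' @param light_type `"ON"`, `"OFF"`, `"ON_OFF"` or `"none"`.
#' @param light_gain added transient Poisson rate after a light transition, Hz.
#' @param rheobase asymptotic minimum threshold current R, microamperes.
#' @param chronaxie duration at which threshold current doubles, C,
#'   milliseconds.
#' @param evoked_max expected evoked spikes per trial in the 10--100 ms
#'   window at saturating stimulus strength.
#' @param recruit_slope dimensionless logistic steepness, as a fraction of
#'   the threshold charge at the stimulus duration.
#' @param saturating if `TRUE` (degeneration phenotype) the recruitment curve
#'   plateaus at `saturation_charge` instead of growing to `evoked_max`.
#' @param saturation_charge per-phase charge (nC) beyond which a saturating
#'   cell's response stops growing; defaults to 1.5x the threshold charge at
#'   a 1-ms pulse.
#' @param latency_mode mode of the evoked-spike latency distribution,
#'   seconds; must lie inside the 10--100 ms indirect-response window.
#' @return An object of class `synthetic_cell_model`.
#' @export
synthetic_cell_model <- function(cell_id, spont_rate = 5,
                                 light_type = c("none", "ON", "OFF", "ON_OFF"),
                                 light_gain = 20,
                                 rheobase = 3.37, chronaxie = 4.21,
                                 evoked_max = 8, recruit_slope = 0.15,
                                 saturating = FALSE, saturation_charge = NULL,
                                 latency_mode = 0.040) {
  light_type <- match.arg(light_type)
  if (spont_rate < 0) stopf("spont_rate must be non-negative")
  if (rheobase <= 0 || chronaxie <= 0)
    stopf("rheobase and chronaxie must be positive")
  if (evoked_max < 0) stopf("evoked_max must be non-negative")
  if (recruit_slope <= 0) stopf("recruit_slope must be positive")
  if (latency_mode <= 0.010 || latency_mode >= 0.100)
    stopf("latency_mode must lie inside the (0.010, 0.100) s window")
  if (is.null(saturation_charge))
    saturation_charge <- 1.5 * rheobase * (1 + chronaxie / 1) * 1
  structure(
    list(cell_id = as.character(cell_id), spont_rate = spont_rate,
         light_type = light_type, light_gain = light_gain,
         rheobase = rheobase, chronaxie = chronaxie,
         evoked_max = evoked_max, recruit_slope = recruit_slope,
         saturating = saturating, saturation_charge = saturation_charge,
         latency_mode = latency_mode),
    class = "synthetic_cell_model"
  )
}

#' Specification of a simulated retinal patch
#'
#' Group defaults mirror the observed population structure of untreated and
#' MNU-treated porcine retina: about 66\% light-responsive cells in normal
#' patches, 48\% in non-severe degeneration, none in severe degeneration
#' (which is what defines the severe class), and electrically responsive
#' fractions of about 56\%, 59\% and 28\% respectively. Degenerated groups
#' additionally get saturating recruitment and a lower evoked ceiling.
#'
#' @param group `"normal"`, `"non_severe"` or `"severe"`.
#' @param n_cells number of simulated cells.
#' @param fraction_light_responsive,fraction_es_responsive overrides of the
#'   group defaults, in `[0, 1]`. A severe patch forces the light fraction
#'   to 0.
#' @param seed integer RNG seed for the patch.
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(group = c("normal", "non_severe", "severe"),
                       n_cells = 50,
                       fraction_light_responsive = NULL,
                       fraction_es_responsive = NULL,
                       seed = 1L) {
  group <- match.arg(group)
  defaults <- switch(group,
    normal     = list(ls = 0.661, es = 0.561),
    non_severe = list(ls = 0.484, es = 0.593),
    severe     = list(ls = 0.000, es = 0.278))
  ls <- fraction_light_responsive %||% defaults$ls
  es <- fraction_es_responsive %||% defaults$es
  if (group == "severe" && ls != 0)
    stopf("a severe patch has no light-responsive cells; fraction must be 0")
  if (ls < 0 || ls > 1 || es < 0 || es > 1)
    stopf("fractions must lie in [0, 1]")
  if (n_cells < 0) stopf("n_cells must be non-negative")
  structure(list(group = group, n_cells = as.integer(n_cells),
                 fraction_light_responsive = ls,
                 fraction_es_responsive = es,
                 seed = as.integer(seed)),
            class = "patch_spec")
}

#' Simulate a homogeneous Poisson spike train
#'
#' @param rate firing rate, Hz (may be 0).
#' @param t0,t1 interval bounds, seconds, `t1 > t0`.
#' @return Sorted spike times in `[t0, t1)`.
#' @export
simulate_spontaneous <- function(rate, t0, t1) {
  if (rate < 0) stopf("rate must be non-negative")
  if (t1 <= t0) stopf("t1 must exceed t0")
  n <- stats::rpois(1, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

# Threshold charge (nC) at pulse duration D (ms) under the SD law.
threshold_charge <- function(model, duration) {
  model$rheobase * (1 + model$chronaxie / duration) * duration
}

#' Expected evoked spikes per trial
#'
#' The recruitment curve underlying the generator: a logistic function of
#' per-phase charge `Q = amplitude * duration`, with scale
#' `recruit_slope * Q_th(D)` where `Q_th(D) = R(1 + C/D) D` is the threshold
#' charge of the strength-duration law. The curve is positioned so that at
#' `amplitude = R(1 + C/D)` the expected number of *added* spikes in the
#' evoked window equals exactly what lifts the relative response to the
#' 1.5x-baseline criterion, i.e. `0.5 * spont_rate * window_width` extra
#' spikes. For cells whose ceiling `evoked_max` cannot reach that criterion
#' (or with zero spontaneous rate, where the relative response is a sentinel
#' anyway) the logistic is centred at `Q_th` instead. Saturating cells
#' plateau at `saturation_charge`.
#'
#' @param model a [synthetic_cell_model].
#' @param amplitude per-phase current, microamperes (vectorised).
#' @param duration per-phase duration, milliseconds (scalar).
#' @param config an [analysis_config]; supplies the response criterion and
#'   evoked-window width used by the calibration.
#' @return Expected evoked spikes per trial (same length as `amplitude`).
#' @export
evoked_mean <- function(model, amplitude, duration,
                        config = analysis_config()) {
  config <- as_config(config)
  if (any(amplitude <= 0) || duration <= 0)
    stopf("amplitude and duration must be positive")
  if (model$evoked_max <= 0) return(rep(0, length(amplitude)))
  qth <- threshold_charge(model, duration)
  q <- amplitude * duration
  width <- diff(config$evoked_window)
  m_th <- (config$response_threshold_factor - 1) * model$spont_rate * width
  scale <- model$recruit_slope * qth
  q0 <- if (m_th > 0 && m_th < model$evoked_max) {
    qth - scale * stats::qlogis(m_th / model$evoked_max)
  } else {
    qth
  }
  if (model$saturating) q <- pmin(q, model$saturation_charge)
  model$evoked_max * stats::plogis((q - q0) / scale)
}

#' Simulate evoked spikes for one electrical protocol
#'
#' Per pulse, a Poisson number of indirect-response spikes (mean given by
#' [evoked_mean()]) is placed at latencies drawn from a normal distribution
#' centred at the cell's `latency_mode` (SD 15 ms) truncated to the 10--100
#' ms window, so no generated spike falls in the artifact blank.
#'
#' @param model a [synthetic_cell_model].
#' @param protocol an electrical [stimulus_protocol].
#' @param config an [analysis_config].
#' @param latency_sd latency spread before truncation, seconds.
#' @return Sorted spike times to merge into the cell's train.
#' @export
simulate_electrical_trials <- function(model, protocol,
                                       config = analysis_config(),
                                       latency_sd = 0.015) {
  if (protocol$kind != "electrical")
    stopf("simulate_electrical_trials needs an electrical protocol")
  config <- as_config(config)
  mu <- evoked_mean(model, protocol$amplitude, protocol$phase_duration, config)
  if (mu <= 0) return(numeric())
  counts <- stats::rpois(length(protocol$onsets), mu)
  total <- sum(counts)
  if (total == 0) return(numeric())
  lat <- truncnorm::rtruncnorm(total, a = config$evoked_window[1],
                               b = config$evoked_window[2],
                               mean = model$latency_mode, sd = latency_sd)
  sort(rep(protocol$onsets, counts) + lat)
}

#' Simulate light-transient spikes for one light protocol
#'
#' ON and ON/OFF cells fire an extra Poisson transient of rate `light_gain`
#' for 0.5 s after light onset; OFF and ON/OFF cells after light offset.
#' Cells of type `"none"` are unchanged.
#'
#' @param model a [synthetic_cell_model].
#' @param protocol a light [stimulus_protocol].
#' @param config an [analysis_config] (supplies the transient window width).
#' @return Sorted spike times to merge into the cell's train.
#' @export
simulate_light_trials <- function(model, protocol, config = analysis_config()) {
  if (protocol$kind != "light")
    stopf("simulate_light_trials needs a light protocol")
  config <- as_config(config)
  if (model$light_type == "none" || model$light_gain <= 0) return(numeric())
  w <- config$light_window
  out <- numeric()
  for (o in protocol$onsets) {
    if (model$light_type %in% c("ON", "ON_OFF"))
      out <- c(out, simulate_spontaneous(model$light_gain, o, o + w))
    if (model$light_type %in% c("OFF", "ON_OFF"))
      out <- c(out, simulate_spontaneous(model$light_gain,
                                         o + protocol$on_duration,
                                         o + protocol$on_duration + w))
  }
  sort(out)
}

# Sample one cell's generative parameters for a patch group.
sample_cell_model <- function(cell_id, group, ls_responsive, es_responsive) {
  lnorm_mean <- function(mean, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(1, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  r_mean <- switch(group, normal = 3.37, non_severe = 3.94, severe = 4.80)
  c_mean <- switch(group, normal = 4.21, non_severe = 6.32, severe = 6.84)
  emax_mean <- switch(group, normal = 10, non_severe = 5, severe = 5)
  light_type <- "none"
  if (ls_responsive)
    light_type <- sample(c("ON", "OFF", "ON_OFF"), 1, prob = c(0.4, 0.3, 0.3))
  synthetic_cell_model(
    cell_id,
    spont_rate = lnorm_mean(5, 0.4),
    light_type = light_type,
    light_gain = lnorm_mean(20, 0.3),
    rheobase = lnorm_mean(r_mean, 0.5),
    chronaxie = lnorm_mean(c_mean, 0.5),
    evoked_max = if (es_responsive) lnorm_mean(emax_mean, 0.4) else 0,
    recruit_slope = 0.15,
    saturating = group != "normal" && es_responsive,
    latency_mode = truncnorm::rtruncnorm(1, a = 0.015, b = 0.090,
                                         mean = 0.040, sd = 0.010)
  )
}

#' Stimulus design of one experiment
#'
#' The full protocol set applied to every patch: one light block (2 s ON /
#' 2 s OFF, 20 repeats) followed by the 5 x 3 grid of electrical blocks
#' (amplitudes 10, 15, 20, 25, 30 uA by durations 0.5, 1, 2 ms), each a
#' train of `n_pulses` identical cathodic-first biphasic pulses at 1-s
#' spacing. Blocks are separated by a 3-s gap so each electrical block has
#' the full 2-s pre-stimulus baseline window available.
#'
#' @param n_pulses pulses per electrical train.
#' @param amplitudes,durations tested grids (uA, ms).
#' @param light_repeats number of ON/OFF cycles.
#' @return Named list of [stimulus_protocol] objects.
#' @export
standard_protocols <- function(n_pulses = 50,
                               amplitudes = c(10, 15, 20, 25, 30),
                               durations = c(0.5, 1, 2),
                               light_repeats = 20) {
  protos <- list()
  t <- 5
  if (light_repeats > 0) {
    onsets <- t + 4 * seq_len(light_repeats) - 4
    protos[["light"]] <- stimulus_protocol("light", "light", onsets)
    t <- max(onsets) + 4 + 3
  }
  for (d in durations) {
    for (a in amplitudes) {
      pid <- sprintf("estim_A%g_D%g", a, d)
      onsets <- t + seq_len(n_pulses) - 1
      protos[[pid]] <- stimulus_protocol(pid, "electrical", onsets,
                                         amplitude = a, phase_duration = d)
      t <- max(onsets) + 1 + 3
    }
  }
  protos
}

#' Realise spike trains for a given set of cell models
#'
#' Lower-level companion of [make_patch()]: takes explicit
#' [synthetic_cell_model] objects instead of sampling them, applies the
#' standard stimulus design, and realises each train (spontaneous Poisson
#' firing plus light transients plus evoked responses) from a per-cell
#' substream of `seed`.
#'
#' @param models list of [synthetic_cell_model] objects.
#' @param config an [analysis_config].
#' @param n_pulses pulses per electrical train.
#' @param light_repeats ON/OFF cycles (0 omits the light block).
#' @param seed integer seed.
#' @param group_label session label.
#' @return A [recording_session].
#' @export
simulate_session <- function(models, config = analysis_config(),
                             n_pulses = 50, light_repeats = 20, seed = 1L,
                             group_label = "normal") {
  config <- as_config(config)
  protos <- standard_protocols(n_pulses = n_pulses,
                               light_repeats = light_repeats)
  t_end <- max(vapply(protos, function(p) max(p$onsets), 0)) + 5
  light <- Filter(function(p) p$kind == "light", protos)
  electrical <- Filter(function(p) p$kind == "electrical", protos)
  trains <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    with_seed(derive_seed(seed, i), {
      tt <- simulate_spontaneous(m$spont_rate, 0, t_end)
      for (p in light) tt <- c(tt, simulate_light_trials(m, p, config))
      for (p in electrical) tt <- c(tt, simulate_electrical_trials(m, p, config))
      tt <- sort(tt)
      tt <- tt[!duplicated(tt)]
      ch <- sample(setdiff(seq_len(60), 15L), 1)
      trains[[m$cell_id]] <- spike_train(m$cell_id, ch, 0L, tt)
    })
  }
  recording_session(sprintf("simulated_seed%d", seed), trains, protos,
                    group_label = group_label)
}

#' Generate a simulated retinal patch with ground truth
#'
#' Draws `n_cells` generative cell models according to the patch
#' specification, applies the full stimulus design, and realises each cell's
#' spike train as spontaneous Poisson firing plus light transients plus
#' electrically evoked indirect responses. A single RNG stream is seeded per
#' patch; each cell draws from a substream derived from its index, so
#' patches are reproducible cell-by-cell.
#'
#' @param spec a [patch_spec].
#' @param config an [analysis_config].
#' @param n_pulses pulses per electrical train (50 in the standard design).
#' @param light_repeats ON/OFF cycles in the light block.
#' @return A list of class `synthetic_patch` with elements `session` (a
#'   [recording_session]) and `truth` (a data.frame of generative parameters,
#'   one row per cell, keyed by `cell_id`).
#' @examples
#' patch <- make_patch(patch_spec("normal", n_cells = 5, seed = 42),
#'                     n_pulses = 5, light_repeats = 5)
#' patch$truth[, c("cell_id", "light_type", "rheobase", "chronaxie")]
#' @export
make_patch <- function(spec, config = analysis_config(), n_pulses = 50,
                       light_repeats = 20) {
  if (!inherits(spec, "patch_spec")) stopf("make_patch needs a patch_spec")
  config <- as_config(config)
  protos <- standard_protocols(n_pulses = n_pulses,
                               light_repeats = light_repeats)
  t_end <- max(vapply(protos, function(p) max(p$onsets), 0)) + 5
  light <- Filter(function(p) p$kind == "light", protos)
  electrical <- Filter(function(p) p$kind == "electrical", protos)

  trains <- list()
  models <- list()
  with_seed(spec$seed, {
    n <- spec$n_cells
    flags_ls <- if (n) stats::runif(n) < spec$fraction_light_responsive else logical()
    flags_es <- if (n) stats::runif(n) < spec$fraction_es_responsive else logical()
    for (i in seq_len(n)) {
      with_seed(derive_seed(spec$seed, i), {
        cid <- sprintf("cell_%03d", i)
        m <- sample_cell_model(cid, spec$group, flags_ls[i], flags_es[i])
        tt <- simulate_spontaneous(m$spont_rate, 0, t_end)
        for (p in light) tt <- c(tt, simulate_light_trials(m, p, config))
        for (p in electrical)
          tt <- c(tt, simulate_electrical_trials(m, p, config))
        tt <- sort(tt)
        tt <- tt[!duplicated(tt)]
        ch <- sample(setdiff(seq_len(60), 15L), 1)
        trains[[cid]] <- spike_train(cid, ch, 0L, tt)
        models[[cid]] <- m
      })
    }
  })
  truth <- do.call(rbind, c(list(data.frame(
    cell_id = character(), spont_rate = numeric(), light_type = character(),
    light_gain = numeric(), rheobase = numeric(), chronaxie = numeric(),
    evoked_max = numeric(), recruit_slope = numeric(), saturating = logical(),
    saturation_charge = numeric(), latency_mode = numeric())),
    lapply(models, function(m) data.frame(
      cell_id = m$cell_id, spont_rate = m$spont_rate,
      light_type = m$light_type, light_gain = m$light_gain,
      rheobase = m$rheobase, chronaxie = m$chronaxie,
      evoked_max = m$evoked_max, recruit_slope = m$recruit_slope,
      saturating = m$saturating, saturation_charge = m$saturation_charge,
      latency_mode = m$latency_mode))))
  rownames(truth) <- NULL
  session <- recording_session(
    sprintf("synthetic_%s_seed%d", spec$group, spec$seed),
    trains, protos,
    group_label = if (spec$group == "normal") "normal" else "mnu_treated")
  structure(list(session = session, truth = truth, spec = spec,
                 models = models),
            class = "synthetic_patch")
}

#' Default extracellular spike waveform template
#'
#' A biphasic (negative-then-positive) somatic waveform, 1.6 ms long at
#' 25 kHz, normalised to a negative peak of -1 and scaled by `amplitude`.
#'
#' @param sampling_rate Hz.
#' @param amplitude negative peak amplitude, microvolts (given as a positive
#'   magnitude).
#' @return Numeric template with attribute `peak_index` (1-based sample of
#'   the negative peak).
#' @export
default_spike_template <- function(sampling_rate = 25000, amplitude = 40) {
  n <- round(0.0016 * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate * 1000  # ms
  w <- -exp(-((t - 0.3) / 0.12)^2) + 0.35 * exp(-((t - 0.8) / 0.28)^2)
  w <- w / abs(min(w)) * amplitude
  structure(w, peak_index = which.min(w))
}

#' Render raw extracellular traces from a session's spike trains
#'
#' Inserts the waveform template at every spike time (negative peak aligned
#' to the spike sample) and adds white Gaussian noise. Overlapping template
#' placements are summed. The ground-truth spike sample indices are retained
#' per channel as an attribute, enabling detection benchmarks against known
#' truth.
#'
#' @param session a [recording_session].
#' @param template waveform in microvolts, e.g. [default_spike_template()].
#' @param noise_sd noise standard deviation, microvolts.
#' @param duration trace length, seconds; defaults to covering every spike.
#' @param channels channel ids to render; defaults to all channels carrying
#'   spikes.
#' @return Named list of numeric traces (microvolts), one per channel, each
#'   with attribute `truth_indices` (1-based spike samples).
#' @export
render_raw_trace <- function(session, template = default_spike_template(),
                             noise_sd = 5, duration = NULL, channels = NULL) {
  fs <- session$sampling_rate
  if (is.null(fs) || fs <= 0) stopf("session must have a positive sampling rate")
  all_ch <- unique(vapply(session$spike_trains, `[[`, 0L, "channel_id"))
  if (is.null(channels)) channels <- all_ch
  if (is.null(duration)) {
    tmax <- max(c(0, unlist(lapply(session$spike_trains, `[[`, "times"))))
    duration <- tmax + 0.01
  }
  nsamp <- ceiling(duration * fs)
  peak <- attr(template, "peak_index") %||% which.min(template)
  ntemp <- length(template)
  if (ntemp >= nsamp) stopf("template longer than trace")
  out <- list()
  n_overlap <- 0L
  for (ch in channels) {
    x <- stats::rnorm(nsamp, 0, noise_sd)
    idx_all <- integer()
    for (st in session$spike_trains) {
      if (st$channel_id != ch) next
      idx <- round(st$times * fs) + 1L
      idx <- idx[idx - peak + 1L >= 1L & idx - peak + ntemp <= nsamp]
      for (i in idx) {
        sel <- (i - peak + 1L):(i - peak + ntemp)
        x[sel] <- x[sel] + template
      }
      idx_all <- c(idx_all, idx)
    }
    idx_all <- sort(idx_all)
    if (length(idx_all) > 1L)
      n_overlap <- n_overlap + sum(diff(idx_all) < ntemp)
    attr(x, "truth_indices") <- idx_all
    out[[as.character(ch)]] <- x
  }
  if (n_overlap > 0L)
    message(sprintf("render_raw_trace: %d overlapping template placements summed",
                    n_overlap))
  out
}
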