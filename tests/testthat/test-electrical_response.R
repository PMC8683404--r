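cfg <- analysis_config()
cfg_block <- analysis_config(baseline_mode = "block")

proto_at <- function(a, d, t0 = 10, n = 5) {
  stimulus_protocol(sprintf("e_A%g_D%g", a, d), "electrical",
                    t0 + seq_len(n) - 1, amplitude = a, phase_duration = d)
}

test_that("baseline_rate implements both pre-stimulus conventions", {
  p <- proto_at(30, 2, t0 = 10, n = 5)
  # 10 spikes uniformly in the 2 s before the first onset -> 5 spikes/s (block)
  st <- spike_train("c", 1, 0, seq(8.1, 9.9, by = 0.2))
  expect_equal(baseline_rate(st, p, cfg_block), 5)
  # per-pulse: same spikes all inside the 100 ms pre-pulse bins?
  st2 <- spike_train("c", 1, 0, c(9.95, 10.95, 11.95, 12.95, 13.95))
  expect_equal(baseline_rate(st2, p, cfg), 10)  # 1 spike per 0.1 s bin
  # empty window -> 0
  expect_equal(baseline_rate(spike_train("z", 1, 0, numeric()), p, cfg), 0)
  expect_equal(baseline_rate(spike_train("z", 1, 0, numeric()), p, cfg_block), 0)
  # insufficient pre-stimulus span errors with the protocol name
  early <- proto_at(30, 2, t0 = 1)
  expect_error(baseline_rate(st, early, cfg_block), "e_A30_D2")
  # Poisson consistency: 20 Hz cell, block estimate within 4*sqrt(40)/2
  set.seed(21)
  stp <- spike_train("p", 1, 0, simulate_spontaneous(20, 0, 15))
  expect_lt(abs(baseline_rate(stp, p, cfg_block) - 20), 4 * sqrt(40) / 2)
})

test_that("evoked_rate counts only the 10-100 ms window", {
  p <- proto_at(30, 2, t0 = 10, n = 5)
  # one spike at +50 ms on every trial -> 1 / 0.090 spikes/s
  st <- spike_train("c", 1, 0, p$onsets + 0.05)
  expect_equal(evoked_rate(st, p, cfg), 1 / 0.09)
  # spikes at +5 ms only -> blanked -> 0
  st_blank <- spike_train("c", 1, 0, p$onsets + 0.005)
  expect_equal(evoked_rate(st_blank, p, cfg), 0)
  # window is half-open: a spike exactly at +10 ms is blanked, at +100 ms kept
  st_edges <- spike_train("c", 1, 0, sort(c(p$onsets + 0.01, p$onsets + 0.1)))
  expect_equal(evoked_rate(st_edges, p, cfg), 1 / 0.09)
})

test_that("evoked_rate matches the generator's evoked_mean by Monte Carlo", {
  m <- synthetic_cell_model("c", spont_rate = 0, rheobase = 3, chronaxie = 1,
                            evoked_max = 3.5)
  p <- stimulus_protocol("e", "electrical", 10 + 0:799, amplitude = 40,
                         phase_duration = 2)
  mu <- evoked_mean(m, 40, 2, cfg)  # ~evoked_max at this strong stimulus
  set.seed(22)
  st <- spike_train("c", 1, 0, simulate_electrical_trials(m, p, cfg))
  got <- evoked_rate(st, p, cfg) * diff(cfg$evoked_window)
  expect_lt(abs(got - mu), 4 * sqrt(mu / 800))
})

test_that("relative_response follows the ratio conventions", {
  expect_equal(relative_response(10, 15), 1.5)
  expect_equal(relative_response(4, 10), 2.5)
  expect_equal(relative_response(0, 0), 0)
  expect_equal(relative_response(0, 3), Inf)
  expect_error(relative_response(-1, 2), "non-negative")
})

test_that("is_es_responsive judges at the strongest stimulus with >= factor", {
  protos <- standard_protocols(n_pulses = 20, light_repeats = 0)
  t_end <- max(vapply(protos, function(p) max(p$onsets), 0)) + 2
  # baseline 10 Hz everywhere; evoked response only for the strong stimulus
  p30_2 <- protos[["estim_A30_D2"]]
  # one spike 50 ms before every integer second: measured per-pulse baseline
  # is exactly 1 spike / 100-ms bin = 10 Hz, and no spike ever falls in an
  # evoked window (all onsets in the standard design are integers)
  base <- seq(0.95, t_end, by = 1)
  # responsive cell: add 3 evoked spikes per trial at the strongest stimulus
  ev <- as.vector(outer(c(0.03, 0.05, 0.07), p30_2$onsets, `+`))
  st_resp <- spike_train("r", 1, 0, sort(c(base, ev)))
  ses <- recording_session("s", list(st_resp), protos)
  expect_true(is_es_responsive(st_resp, ses, cfg))
  # relative response below 1.5 -> not responsive (exactly one evoked
  # spike per trial: evoked 11.1 Hz vs baseline 10 Hz -> 1.11 < 1.5)
  ev1 <- p30_2$onsets + 0.05
  st_weak <- spike_train("w", 1, 0, sort(c(base, ev1)))
  expect_false(is_es_responsive(st_weak, ses, cfg))
  # silent-baseline cell with any evoked spikes -> responsive (Inf sentinel)
  st_silent <- spike_train("q", 1, 0, ev1)
  expect_true(is_es_responsive(st_silent, ses, cfg))
  # protocol absent -> error
  ses2 <- recording_session("s2", list(st_resp), protos[1:3])
  expect_error(is_es_responsive(st_resp, ses2, cfg), "30 uA")
})

test_that("threshold-factor consistency holds for any factor", {
  protos <- standard_protocols(n_pulses = 20, light_repeats = 0)
  patch <- make_patch(patch_spec("normal", n_cells = 3, seed = 8),
                      n_pulses = 20, light_repeats = 0)
  for (st in patch$session$spike_trains) {
    for (fac in c(1.2, 1.5, 3)) {
      cfg_f <- analysis_config(response_threshold_factor = fac)
      tr <- trial_response(st, patch$session$protocols[["estim_A30_D2"]], cfg_f)
      expect_equal(is_es_responsive(st, patch$session, cfg_f),
                   tr$relative_response >= fac)
    }
  }
})

test_that("evoked window never includes artifact-blank spikes (property)", {
  set.seed(23)
  p <- proto_at(20, 1, t0 = 5, n = 20)
  for (k in 1:10) {
    tt <- sort(c(runif(50, 0, 30), p$onsets + runif(20, 0, 0.01)))
    tt <- tt[!duplicated(tt)]
    st <- spike_train("c", 1, 0, tt)
    counted <- evoked_rate(st, p, cfg) * diff(cfg$evoked_window) * 20
    in_window <- sum(vapply(p$onsets, function(o)
      sum(tt > o + 0.01 & tt <= o + 0.1), numeric(1)))
    expect_equal(counted, in_window)
  }
})

test_that("stim_psth is calibrated and detects strong evoked responses", {
  p <- stimulus_protocol("e", "electrical", 10 + 0:49, amplitude = 30,
                         phase_duration = 2)
  # zero-spike cell: all-zero counts, bound finite and >= 0
  ps0 <- stim_psth(spike_train("z", 1, 0, numeric()), p, cfg)
  expect_true(all(ps0$counts == 0))
  expect_gte(ps0$confidence_bound, 0)
  expect_length(ps0$counts, 50L)
  # strong evoked cell: at least one post-stimulus bin above the bound
  m <- synthetic_cell_model("c", spont_rate = 5, rheobase = 3, chronaxie = 1,
                            evoked_max = 8)
  set.seed(24)
  tt <- sort(c(simulate_spontaneous(5, 0, 70),
               simulate_electrical_trials(m, p, cfg)))
  ps <- stim_psth(spike_train("c", 1, 0, tt[!duplicated(tt)]), p, cfg)
  post <- ps$counts[ps$bin_centers > 0]
  expect_gt(max(post), ps$confidence_bound)
  expect_gte(ps$confidence_bound, ps$baseline_mean)
  expect_error(stim_psth(spike_train("z", 1, 0, numeric()),
                         proto_at(30, 2, n = 3), cfg), "5 trials")
})

test_that("response_curves shares measurements between PAM and PDM views", {
  patch <- make_patch(patch_spec("normal", n_cells = 2, seed = 9),
                      n_pulses = 10, light_repeats = 0)
  st <- patch$session$spike_trains[[1]]
  cs <- response_curves(st, patch$session, cfg)
  expect_length(cs$pam, 3L)
  expect_length(cs$pdm, 5L)
  pam2 <- cs$pam[["D2"]]
  pdm30 <- cs$pdm[["A30"]]
  expect_equal(pam2$y_relative[pam2$x == 30], pdm30$y_relative[pdm30$x == 2])
  # missing combination errors with the missing pair listed
  ses_missing <- patch$session
  ses_missing$protocols[["estim_A20_D1"]] <- NULL
  expect_error(response_curves(st, ses_missing, cfg), "\\(20, 1\\)")
})

test_that("classify_modulation applies the Spearman rule over all 8 curves", {
  m <- synthetic_cell_model("mono", spont_rate = 5, rheobase = 2,
                            chronaxie = 0.8, evoked_max = 10,
                            recruit_slope = 0.4)
  curves <- list(cell_id = "mono",
                 pam = noiseless_curves(m)[1:3],
                 pdm = noiseless_curves(m)[4:8])
  ml <- classify_modulation(curves, es_responsive = TRUE, cfg)
  expect_equal(ml$label, "well")
  expect_true(all(ml$rho >= 0.999))
  # flat curves -> unmodulated regardless of responsiveness
  flat <- lapply(curves$pam, function(cv) { cv$y_relative[] <- 1; cv })
  curves_flat <- list(cell_id = "flat", pam = flat,
                      pdm = lapply(curves$pdm, function(cv) {
                        cv$y_relative[] <- 1; cv }))
  expect_equal(classify_modulation(curves_flat, TRUE, cfg)$label, "unmodulated")
  # not ES-responsive -> unmodulated even with monotone curves
  expect_equal(classify_modulation(curves, FALSE, cfg)$label, "unmodulated")
  # rank-based: uniform scaling leaves the label unchanged
  scaled <- list(cell_id = "s",
                 pam = lapply(curves$pam, function(cv) {
                   cv$y_relative <- cv$y_relative * 7; cv }),
                 pdm = lapply(curves$pdm, function(cv) {
                   cv$y_relative <- cv$y_relative * 7; cv }))
  expect_equal(classify_modulation(scaled, TRUE, cfg)$label, "well")
  # mixed: monotone PAM, flat PDM -> poor
  mixed <- list(cell_id = "m", pam = curves$pam, pdm = curves_flat$pdm)
  expect_equal(classify_modulation(mixed, TRUE, cfg)$label, "poor")
})
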