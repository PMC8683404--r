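# Shared fixtures: all synthetic, built in code at test time.

# A tiny but complete session: full 5x3 electrical grid plus a light block,
# with deterministic (non-random) spike trains unless a generator is asked for.
tiny_session <- function(n_pulses = 5, light_repeats = 5) {
  protos <- standard_protocols(n_pulses = n_pulses,
                               light_repeats = light_repeats)
  t_end <- max(vapply(protos, function(p) max(p$onsets), 0)) + 2
  st <- spike_train("c1", 1L, 0L, seq(0.5, t_end, by = 0.4))
  recording_session("tiny", list(st), protos)
}

# Regular-spaced spike train covering [0, t_end] at a given rate.
regular_train <- function(cell_id, rate, t_end, channel = 1L) {
  spike_train(cell_id, channel, 0L, seq(1 / rate / 2, t_end, by = 1 / rate))
}

# Match detected event indices against ground truth within +/- tol samples.
detection_scores <- function(detected, truth, tol) {
  if (!length(detected) || !length(truth)) {
    return(c(recall = 0, precision = 0))
  }
  recall <- mean(vapply(truth, function(i) any(abs(detected - i) <= tol),
                        logical(1)))
  precision <- mean(vapply(detected, function(i) any(abs(truth - i) <= tol),
                           logical(1)))
  c(recall = recall, precision = precision)
}

# Expected relative response of a generative cell on the stimulus grid
# (the analytic curve the estimators should recover, no Monte-Carlo noise).
expected_relative <- function(model, amplitude, duration,
                              config = analysis_config()) {
  mu <- evoked_mean(model, amplitude, duration, config)
  width <- diff(config$evoked_window)
  if (model$spont_rate <= 0) return(ifelse(mu > 0, Inf, 0))
  ((model$spont_rate * width + mu) / width) / model$spont_rate
}

# Build the 3 PAM + 5 PDM response curves from the analytic expectations.
noiseless_curves <- function(model, amplitudes = c(10, 15, 20, 25, 30),
                             durations = c(0.5, 1, 2),
                             config = analysis_config()) {
  pam <- lapply(durations, function(d) structure(
    list(cell_id = model$cell_id, mode = "PAM", fixed_value = d,
         x = amplitudes,
         y_relative = vapply(amplitudes, expected_relative, numeric(1),
                             model = model, duration = d, config = config)),
    class = "response_curve"))
  pdm <- lapply(amplitudes, function(a) structure(
    list(cell_id = model$cell_id, mode = "PDM", fixed_value = a,
         x = durations,
         y_relative = vapply(durations, function(d)
           expected_relative(model, a, d, config), numeric(1))),
    class = "response_curve"))
  c(pam, pdm)
}

# Independent global minimiser of fit_sd's (weighted) objective. The model
# I(D) = R + a/D with a = R*C is linear in (R, a), so the weighted least
# squares minimum has a closed form via the normal equations; a dense local
# grid around it confirms it is the minimum. Fully independent of nls.
brute_force_sd <- function(durations, currents, weighting = "charge") {
  w <- if (weighting == "charge") durations^2 else rep(1, length(durations))
  X <- cbind(1, 1 / durations)
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% currents)
  R <- beta[1]
  a <- beta[2]
  obj <- function(R, C) sum(w * (currents - R * (1 + C / durations))^2)
  best <- c(R = R, C = a / R)
  # confirm optimality on a dense grid around the closed-form solution
  stopifnot(R > 0, a > 0)
  grid_vals <- outer(best["R"] * seq(0.98, 1.02, length.out = 21),
                     best["C"] * seq(0.98, 1.02, length.out = 21),
                     Vectorize(obj))
  stopifnot(obj(best["R"], best["C"]) <= min(grid_vals) + 1e-9)
  best
}
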