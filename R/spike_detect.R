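# Spike recovery from raw traces: zero-phase high-pass filtering, threshold
# detection at a multiple of the noise SD, waveform extraction, and a
# simplified PCA + k-means unit separation standing in for a full commercial
# spike sorter.

#' Zero-phase high-pass filter
#'
#' FFT-domain filter with a raised-cosine transition band from
#' `cutoff / 2` (full stop) to `cutoff` (full pass). Being real and
#' symmetric in the frequency domain the filter is exactly zero-phase, so
#' spike timing is preserved; the DC component is removed entirely. The
#' filter is circular, so a few milliseconds at either end of the trace can
#' show wrap-around edge effects.
#'
#' @param trace numeric sample vector.
#' @param cutoff high-pass cutoff, Hz; must be below the Nyquist frequency.
#' @param sampling_rate Hz.
#' @return Filtered trace of the same length.
#' @export
highpass <- function(trace, cutoff = 100, sampling_rate = 25000) {
  if (cutoff >= sampling_rate / 2)
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff, sampling_rate / 2)
  n <- length(trace)
  if (n < 2L) return(trace - mean(trace))
  f <- (seq_len(n) - 1) * sampling_rate / n
  f <- pmin(f, sampling_rate - f)  # fold to [0, fs/2]
  lo <- cutoff / 2
  h <- ifelse(f <= lo, 0,
              ifelse(f >= cutoff, 1,
                     0.5 - 0.5 * cos(pi * (f - lo) / (cutoff - lo))))
  Re(stats::fft(stats::fft(trace) * h, inverse = TRUE)) / n
}

#' Estimate the noise standard deviation of a filtered trace
#'
#' `"plain"` is the sample SD, which the classical 4xSD detection rule
#' refers to but which is biased upward by the spikes themselves; `"mad"`
#' is the robust median-based estimator `median(|x|) / 0.6745` commonly used
#' in extracellular spike detection.
#'
#' @param trace filtered trace, at least 1000 samples.
#' @param method `"mad"` or `"plain"`.
#' @return Estimated noise SD (same units as the trace). An all-constant
#'   trace returns 0, which downstream detection refuses.
#' @export
estimate_noise_sd <- function(trace, method = c("mad", "plain")) {
  method <- match.arg(method)
  if (length(trace) < 1000L)
    stopf("need at least 1000 samples to estimate the noise SD")
  switch(method,
         plain = stats::sd(trace),
         mad = stats::median(abs(trace)) / 0.6745)
}

#' Detect spikes by threshold crossing
#'
#' Events are negative-going excursions beyond `sd_multiple` times the
#' estimated noise SD (extracellular somatic spikes are negative at the
#' soma); `polarity = "both"` also accepts positive excursions. Within each
#' refractory window only the extremal crossing is kept. A fixed-length
#' waveform snippet (0.6 ms before to 1.0 ms after the peak by default, 40
#' samples at 25 kHz) is extracted per event; events too close to the trace
#' edges for a full snippet are dropped.
#'
#' @param trace filtered trace, microvolts.
#' @param sampling_rate Hz.
#' @param sd_multiple detection threshold in noise SDs.
#' @param refractory minimum event separation, seconds.
#' @param polarity `"neg"` or `"both"`.
#' @param noise_method passed to [estimate_noise_sd()].
#' @param snippet_pre,snippet_post snippet extent around the peak, seconds.
#' @param channel_id carried through to the result.
#' @return An object of class `detection_result`: sorted
#'   `spike_sample_indices` (1-based peak samples), `waveforms` (matrix, one
#'   row per event), `noise_sd_estimate`, `threshold_used` (signed,
#'   microvolts) and provenance fields.
#' @export
detect_spikes <- function(trace, sampling_rate = 25000, sd_multiple = 4,
                          refractory = 0.001, polarity = c("neg", "both"),
                          noise_method = c("mad", "plain"),
                          snippet_pre = 0.0006, snippet_post = 0.0010,
                          channel_id = NA_integer_) {
  polarity <- match.arg(polarity)
  noise_method <- match.arg(noise_method)
  sigma <- estimate_noise_sd(trace, noise_method)
  if (sigma <= 0) stopf("degenerate trace: noise SD is zero")
  thr <- sd_multiple * sigma
  mag <- if (polarity == "neg") -trace else abs(trace)
  over <- which(mag > thr)
  peaks <- integer()
  if (length(over)) {
    run_start <- c(1L, which(diff(over) > 1L) + 1L)
    run_end <- c(run_start[-1L] - 1L, length(over))
    peaks <- vapply(seq_along(run_start), function(k) {
      seg <- over[run_start[k]:run_end[k]]
      seg[which.max(mag[seg])]
    }, integer(1))
    # refractory: merge events closer than the window, keeping the extremum
    ref_n <- round(refractory * sampling_rate)
    if (length(peaks) > 1L && ref_n > 0L) {
      kept <- peaks[1L]
      for (p in peaks[-1L]) {
        last <- kept[length(kept)]
        if (p - last < ref_n) {
          if (mag[p] > mag[last]) kept[length(kept)] <- p
        } else kept <- c(kept, p)
      }
      peaks <- kept
    }
  }
  n_pre <- round(snippet_pre * sampling_rate)
  n_post <- round(snippet_post * sampling_rate)
  ok <- peaks - n_pre >= 1L & peaks + n_post - 1L <= length(trace)
  peaks <- peaks[ok]
  wf <- if (length(peaks)) {
    t(vapply(peaks, function(p) trace[(p - n_pre):(p + n_post - 1L)],
             numeric(n_pre + n_post)))
  } else {
    matrix(numeric(), 0L, n_pre + n_post)
  }
  structure(
    list(channel_id = channel_id,
         spike_sample_indices = peaks,
         spike_times = (peaks - 1L) / sampling_rate,
         waveforms = wf,
         noise_sd_estimate = sigma,
         threshold_used = if (polarity == "neg") -thr else thr,
         sd_multiple = sd_multiple,
         noise_method = noise_method,
         sampling_rate = sampling_rate),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> channel %s: %d events, noise SD %.2f uV (%s), threshold %.2f uV\n",
    x$channel_id, length(x$spike_sample_indices), x$noise_sd_estimate,
    x$noise_method, x$threshold_used))
  invisible(x)
}

#' Separate detected events into putative units
#'
#' Projects snippets onto their first two principal components and clusters
#' with k-means for k = 1..`max_units`, choosing k by mean silhouette width
#' (k = 1 is assigned a baseline silhouette of 0.5, so multiple units are
#' declared only when the clustering is convincingly better than a single
#' blob). Deterministic given `seed`.
#'
#' @param waveforms event-by-sample matrix from [detect_spikes()].
#' @param max_units maximum number of units considered.
#' @param seed integer seed for k-means restarts.
#' @return Integer vector of 0-based unit labels, one per event, with
#'   attributes `k` (number of units) and `silhouette` (per-k scores).
#' @export
sort_units <- function(waveforms, max_units = 3, seed = 1L) {
  n <- nrow(waveforms)
  if (n < max(10L, max_units)) {
    warnf("too few events (%d) to sort; all labeled unit 0", n)
    return(structure(rep(0L, n), k = 1L, silhouette = NA_real_))
  }
  pcs <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  d <- min(2L, ncol(pcs$x))
  scores <- pcs$x[, seq_len(d), drop = FALSE]
  sil <- c(`1` = 0.5)
  fits <- list()
  dm <- stats::dist(scores)
  for (k in seq_len(max_units)[-1L]) {
    km <- with_seed(derive_seed(seed, k), tryCatch(
      stats::kmeans(scores, centers = k, nstart = 10, iter.max = 50),
      error = function(e) NULL))
    if (is.null(km) || length(unique(km$cluster)) < k) {
      sil[as.character(k)] <- -Inf
      next
    }
    sw <- mean(cluster::silhouette(km$cluster, dm)[, "sil_width"])
    sil[as.character(k)] <- if (is.finite(sw)) sw else -Inf
    fits[[as.character(k)]] <- km
  }
  best <- names(sil)[which.max(sil)]
  labels <- if (best == "1") rep(0L, n) else as.integer(fits[[best]]$cluster) - 1L
  structure(labels, k = as.integer(best), silhouette = sil)
}
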