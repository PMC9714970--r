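#' Blackman-windowed tone pip
#'
#' A sinusoid of the requested frequency multiplied by a Blackman window
#' spanning the full duration — the standard short stimulus for larval
#' zebrafish auditory-evoked-potential recordings (10 ms pips at 100-1000 Hz).
#'
#' @param frequency Hz; must be below the Nyquist frequency.
#' @param sample_rate Hz.
#' @param duration seconds (default 10 ms).
#' @param amplitude peak amplitude of the underlying sinusoid.
#' @return list of class `waveform`: `samples`, `sample_rate`, `frequency`.
#' @export
make_tone_pip <- function(frequency, sample_rate, duration = 0.01,
                          amplitude = 1) {
  if (frequency >= sample_rate / 2)
    stop("frequency ", frequency, " Hz aliases at sample rate ", sample_rate,
         " Hz (Nyquist ", sample_rate / 2, " Hz)")
  n <- round(duration * sample_rate)
  stopifnot(n >= 2)
  k <- seq_len(n) - 1L
  w <- 0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
  s <- amplitude * sin(2 * pi * frequency * k / sample_rate) * w
  structure(list(samples = s, sample_rate = sample_rate, frequency = frequency),
            class = "waveform")
}

#' Specification of a simulated evoked-potential recording
#'
#' The response amplitude follows a logistic function of stimulus level,
#' `A(level) = a_max * plogis((level - threshold_db) / slope_db)`, so the true
#' threshold is the logistic midpoint. The response waveform defaults to one
#' cycle of the stimulus frequency under a Blackman window (matching the
#' stimulus bandwidth).
#'
#' @param sample_rate Hz; must exceed twice the highest stimulus frequency.
#' @param frequencies stimulus frequencies (Hz).
#' @param levels tested sound levels in dB, strictly descending.
#' @param epochs stimulus repetitions per (frequency, level).
#' @param threshold_db true threshold, scalar or one value per frequency.
#' @param a_max maximal response amplitude (trace units).
#' @param slope_db logistic slope in dB; small values approach a hard
#'   threshold.
#' @param latency_ms response latency after stimulus onset.
#' @param isi_ms inter-stimulus onset interval.
#' @param noise_sd Gaussian trace noise standard deviation.
#' @param seed integer seed.
#' @return validated list of class `aep_sim_spec`.
#' @export
aep_sim_spec <- function(sample_rate = 10000,
                         frequencies = c(100, 200, 400, 600, 800, 1000),
                         levels = seq(160, 120, by = -5),
                         epochs = 20,
                         threshold_db = 140,
                         a_max = 1,
                         slope_db = 2,
                         latency_ms = 5,
                         isi_ms = 60,
                         noise_sd = 0.04,
                         seed = 1) {
  if (any(diff(levels) >= 0)) stop("levels must be strictly descending")
  if (sample_rate <= 2 * max(frequencies))
    stop("sample rate must exceed twice the maximum stimulus frequency")
  stopifnot(epochs >= 1, a_max >= 0, slope_db >= 0, noise_sd >= 0)
  if (length(threshold_db) == 1L)
    threshold_db <- rep(threshold_db, length(frequencies))
  stopifnot(length(threshold_db) == length(frequencies))
  structure(list(sample_rate = sample_rate, frequencies = frequencies,
                 levels = levels, epochs = as.integer(epochs),
                 threshold_db = stats::setNames(threshold_db,
                                                as.character(frequencies)),
                 a_max = a_max, slope_db = slope_db, latency_ms = latency_ms,
                 isi_ms = isi_ms, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "aep_sim_spec")
}

# Logistic level-response relation; slope 0 is the hard-threshold limit.
.aep_amplitude <- function(level, theta, a_max, slope) {
  if (slope <= 0) return(ifelse(level >= theta, a_max, 0))
  a_max * stats::plogis((level - theta) / slope)
}

#' Simulate a stimulus-locked evoked-potential recording
#'
#' Tone pips are presented in blocks, descending in level within each
#' frequency; at each onset plus latency the response template scaled by the
#' logistic amplitude is added to Gaussian noise.
#'
#' @param spec an [aep_sim_spec()].
#' @return list with `recording` (class `aep_recording`: `trace`,
#'   `sample_rate`, `events` data.frame of onset_s/frequency/level) and
#'   `true_thresholds` (named by frequency).
#' @export
simulate_aep <- function(spec) {
  stopifnot(inherits(spec, "aep_sim_spec"))
  fs <- spec$sample_rate
  isi <- spec$isi_ms / 1000
  n_events <- length(spec$frequencies) * length(spec$levels) * spec$epochs
  total_s <- n_events * isi + 0.1
  n <- ceiling(total_s * fs)
  set.seed(spec$seed)
  trace <- stats::rnorm(n, 0, spec$noise_sd)
  lat <- round(spec$latency_ms / 1000 * fs)
  onsets <- numeric(n_events); freqs <- numeric(n_events)
  lvls <- numeric(n_events)
  ev <- 0L
  t0 <- 0.02
  for (fi in seq_along(spec$frequencies)) {
    f <- spec$frequencies[fi]
    tpl <- make_tone_pip(f, fs, duration = 1 / f)$samples
    for (L in spec$levels) {
      amp <- .aep_amplitude(L, spec$threshold_db[fi], spec$a_max, spec$slope_db)
      for (e in seq_len(spec$epochs)) {
        ev <- ev + 1L
        onset <- t0 + (ev - 1L) * isi
        i0 <- round(onset * fs) + lat
        ii <- i0 + seq_along(tpl)
        if (max(ii) > n) stop("epoch window exceeds trace length")
        trace[ii] <- trace[ii] + amp * tpl
        onsets[ev] <- onset; freqs[ev] <- f; lvls[ev] <- L
      }
    }
  }
  rec <- structure(list(trace = trace, sample_rate = fs,
                        events = data.frame(onset_s = onsets,
                                            frequency = freqs, level = lvls)),
                   class = "aep_recording")
  list(recording = rec, true_thresholds = spec$threshold_db)
}

#' @export
print.aep_recording <- function(x, ...) {
  cat("aep_recording:", length(x$trace), "samples at", x$sample_rate, "Hz;",
      nrow(x$events), "stimulus events\n")
  invisible(x)
}

#' Stimulus-locked epoch averaging
#'
#' Epochs sharing a (frequency, level) condition are extracted around each
#' onset (`pre_ms` before to `post_ms` after) and averaged arithmetically.
#'
#' @param rec an `aep_recording`.
#' @param pre_ms,post_ms epoch window in milliseconds around stimulus onset.
#' @return list of class `aep_epochs`; one element per condition with fields
#'   `frequency`, `level`, `n_epochs`, `avg` (numeric), `pre_samples`, and
#'   attribute `epoch_pre_rms` (pooled RMS of unaveraged pre-stimulus
#'   samples, the raw noise floor).
#' @export
average_epochs <- function(rec, pre_ms = 10, post_ms = 30) {
  stopifnot(inherits(rec, "aep_recording"))
  fs <- rec$sample_rate
  npre <- round(pre_ms / 1000 * fs)
  npost <- round(post_ms / 1000 * fs)
  n <- length(rec$trace)
  key <- interaction(rec$events$frequency, rec$events$level, drop = TRUE)
  out <- list()
  pre_sq <- 0; pre_n <- 0
  for (k in levels(key)) {
    idx <- which(key == k)
    acc <- numeric(npre + npost)
    for (i in idx) {
      c0 <- round(rec$events$onset_s[i] * fs)
      lo <- c0 - npre + 1L; hi <- c0 + npost
      if (lo < 1L || hi > n)
        stop("epoch for event at ", rec$events$onset_s[i],
             " s exceeds the trace")
      seg <- rec$trace[lo:hi]
      acc <- acc + seg
      pre_sq <- pre_sq + sum(seg[seq_len(npre)]^2)
      pre_n <- pre_n + npre
    }
    out[[k]] <- list(frequency = rec$events$frequency[idx[1]],
                     level = rec$events$level[idx[1]],
                     n_epochs = length(idx), avg = acc / length(idx),
                     pre_samples = npre)
  }
  structure(out, class = "aep_epochs",
            epoch_pre_rms = sqrt(pre_sq / max(pre_n, 1)))
}

#' Response detection on an averaged trace
#'
#' Amplitude is the peak-to-peak excursion of the post-stimulus window;
#' a response is detected iff amplitude >= k times the baseline RMS (a tie
#' counts as detected). The criterion multiplier is a declared convention.
#'
#' @param avg numeric averaged epoch (pre-stimulus samples first).
#' @param baseline_rms positive noise-floor estimate.
#' @param k criterion multiplier (default 2).
#' @param pre_samples number of leading pre-stimulus samples in `avg`.
#' @return list `detected` (logical), `amplitude`.
#' @export
detect_response <- function(avg, baseline_rms, k = 2, pre_samples = 0) {
  stopifnot(baseline_rms > 0)
  if (length(avg) <= pre_samples) stop("empty post-stimulus window")
  post <- avg[(pre_samples + 1L):length(avg)]
  amp <- diff(range(post))
  list(detected = amp >= k * baseline_rms, amplitude = amp)
}

#' Threshold from per-level detections over descending levels
#'
#' The threshold is the lowest tested level L such that a response was
#' detected at L and at every tested level above L (the contiguous-from-top
#' audiometric convention). If the highest level is undetected the threshold
#' is not reached (`NA`). A detection sequence that resumes below a gap
#' triggers a warning and the gap terminates the run.
#'
#' @param detected logical vector, one flag per level.
#' @param levels numeric dB levels, strictly descending, same length.
#' @return numeric threshold in dB, or `NA` with attribute `reached = FALSE`.
#' @export
estimate_threshold <- function(detected, levels) {
  stopifnot(length(detected) == length(levels))
  if (any(diff(levels) >= 0)) stop("levels must be strictly descending")
  if (!detected[1]) {
    if (any(detected))
      warning("non-monotone detections: responses below an undetected level")
    return(structure(NA_real_, reached = FALSE))
  }
  run <- which(!detected)
  last <- if (length(run)) run[1] - 1L else length(levels)
  if (length(run) && any(detected[run[1]:length(detected)]))
    warning("non-monotone detections: using the contiguous run from the top")
  structure(levels[last], reached = TRUE)
}

#' Per-frequency threshold estimation for a recording
#'
#' Full pipeline: stimulus-locked averaging, response detection against the
#' raw per-epoch pre-stimulus noise floor, and the contiguous-from-top
#' threshold rule applied per frequency.
#'
#' @param rec an `aep_recording`.
#' @param k detection criterion multiplier.
#' @param pre_ms,post_ms epoch window (milliseconds).
#' @return data.frame of class `aep_threshold_result`: frequency,
#'   threshold_db, reached; averaged epochs in attribute `epochs`.
#' @export
aep_thresholds <- function(rec, k = 2, pre_ms = 10, post_ms = 30) {
  ep <- average_epochs(rec, pre_ms, post_ms)
  # raw per-epoch pre-stimulus RMS; floor guards the noise-free limit
  baseline <- max(attr(ep, "epoch_pre_rms"), 1e-12)
  freqs <- sort(unique(vapply(ep, `[[`, 0, "frequency")))
  rows <- lapply(freqs, function(f) {
    es <- Filter(function(e) e$frequency == f, ep)
    lv <- vapply(es, `[[`, 0, "level")
    ord <- order(lv, decreasing = TRUE)
    es <- es[ord]; lv <- lv[ord]
    det <- vapply(es, function(e)
      detect_response(e$avg, baseline, k, e$pre_samples)$detected, FALSE)
    th <- estimate_threshold(det, lv)
    data.frame(frequency = f, threshold_db = as.numeric(th),
               reached = isTRUE(attr(th, "reached")))
  })
  out <- do.call(rbind, rows)
  attr(out, "epochs") <- ep
  class(out) <- c("aep_threshold_result", class(out))
  out
}

#' @export
print.aep_threshold_result <- function(x, ...) {
  cat("AEP thresholds (contiguous-from-top rule):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %6g Hz : %s\n", x$frequency[i],
                if (x$reached[i]) paste0(x$threshold_db[i], " dB")
                else "not reached"))
  invisible(x)
}
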