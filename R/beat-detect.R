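#' Construct an ECG signal object
#'
#' @param samples Numeric vector of ECG samples (mV).
#' @param fs Sampling rate in samples per second (default 250, the front
#'   end's configured rate).
#' @param record_id Optional label.
#' @return A list of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, fs = 250, record_id = "unnamed") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (any(!is.finite(samples))) stop("ECG samples must be finite")
  structure(list(samples = samples, fs = fs,
                 record_id = as.character(record_id)[1]),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("ecg_signal '%s': %d samples @ %g sps (%.1f s)\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Front-end configuration
#'
#' Mirrors the wearable analog front end's digital settings: a 0.5--40 Hz
#' band-pass, a 96 ms R-to-R integration window, and the Pan-Tompkins
#' constants (200 ms refractory period, search-back at 1.66x the running RR
#' mean, threshold adaptation coefficient 0.125 with the signal/noise mix
#' 0.25/0.75 of the classic recipe).
#'
#' @param hp_cutoff_hz High-pass cutoff (Hz).
#' @param lp_cutoff_hz Low-pass cutoff (Hz).
#' @param rtor_window_ms Moving-window integration width (ms).
#' @param refractory_ms Minimum separation between detected beats (ms).
#' @param searchback_factor Search-back triggers when the gap since the last
#'   beat exceeds this multiple of the running mean RR.
#' @return A list of class `frontend_config`.
#' @export
frontend_config <- function(hp_cutoff_hz = 0.5, lp_cutoff_hz = 40,
                            rtor_window_ms = 96, refractory_ms = 200,
                            searchback_factor = 1.66) {
  if (!(hp_cutoff_hz > 0 && hp_cutoff_hz < lp_cutoff_hz)) {
    stop("require 0 < hp_cutoff_hz < lp_cutoff_hz")
  }
  structure(list(hp_cutoff_hz = hp_cutoff_hz, lp_cutoff_hz = lp_cutoff_hz,
                 rtor_window_ms = rtor_window_ms,
                 refractory_ms = refractory_ms,
                 searchback_factor = searchback_factor),
            class = "frontend_config")
}

#' Band-pass condition an ECG signal
#'
#' Applies the front end's 0.5--40 Hz band limit as a zero-phase (forward-
#' backward) Butterworth cascade: 2nd-order high-pass, 5th-order low-pass
#' (the forward-backward pass squares each magnitude response, giving a
#' steep stop-band above 40 Hz that suppresses mains interference at 50 Hz
#' by more than 20 dB). Zero-phase filtering is used
#' rather than the chip's causal filters because only beat *times* matter
#' downstream and a fixed group delay would cancel in the RR differences
#' anyway.
#'
#' @param ecg An [ecg_signal()].
#' @param cfg A [frontend_config()].
#' @return A conditioned [ecg_signal()] of the same length and rate.
#' @export
condition_ecg <- function(ecg, cfg = frontend_config()) {
  stopifnot(inherits(ecg, "ecg_signal"))
  nyq <- ecg$fs / 2
  if (cfg$lp_cutoff_hz >= nyq) {
    stop("low-pass cutoff (", cfg$lp_cutoff_hz,
         " Hz) must be below Nyquist (", nyq, " Hz)")
  }
  x <- ecg$samples - mean(ecg$samples)  # keep filter edge transients small
  if (length(x) < 12) return(ecg_signal(x, ecg$fs, ecg$record_id))
  hp <- signal::butter(2, cfg$hp_cutoff_hz / nyq, type = "high")
  lp <- signal::butter(5, cfg$lp_cutoff_hz / nyq, type = "low")
  y <- signal::filtfilt(hp, x)
  y <- signal::filtfilt(lp, y)
  ecg_signal(y, ecg$fs, ecg$record_id)
}

# magnitude response (dB) of the conditioning cascade at frequency f_hz;
# used by tests to verify stop-band/pass-band behaviour from the designed
# transfer function rather than from signal measurements
condition_response_db <- function(f_hz, fs = 250, cfg = frontend_config()) {
  nyq <- fs / 2
  hp <- signal::butter(2, cfg$hp_cutoff_hz / nyq, type = "high")
  lp <- signal::butter(5, cfg$lp_cutoff_hz / nyq, type = "low")
  w <- pi * f_hz / nyq
  h <- function(flt) {
    z <- exp(-1i * w)
    num <- sum(flt$b * z^(seq_along(flt$b) - 1))
    den <- sum(flt$a * z^(seq_along(flt$a) - 1))
    num / den
  }
  # forward-backward filtering squares the magnitude response
  20 * log10(abs(h(hp) * h(lp))^2)
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Runs the classic chain on the conditioned signal: five-point derivative,
#' squaring, moving-window integration (window `rtor_window_ms`), then peak
#' picking with dual adaptive thresholds, a refractory period, and
#' search-back at `searchback_factor` times the running mean RR when a beat
#' appears to have been missed. Candidate peaks from the integrated waveform
#' are refined to the local maximum of the band-passed ECG.
#'
#' @param ecg An [ecg_signal()] (raw; conditioning is applied internally).
#' @param cfg A [frontend_config()].
#' @return An [rr_series()] of detected beats. Fewer than two detected beats
#'   give an empty series, not an error.
#' @export
detect_rpeaks <- function(ecg, cfg = frontend_config()) {
  stopifnot(inherits(ecg, "ecg_signal"))
  fs <- ecg$fs
  if (length(ecg$samples) < 2 * fs) {
    stop("need at least 2 s of signal (got ",
         round(length(ecg$samples) / fs, 2), " s)")
  }
  bp <- condition_ecg(ecg, cfg)$samples
  # derivative emphasises QRS slope; squaring rectifies and sharpens
  der <- c(0, 0, diff(bp, lag = 4) / 4, 0, 0) * fs / 2
  sq <- der^2
  wn <- max(1L, as.integer(round(cfg$rtor_window_ms / 1000 * fs)))
  mwi <- stats::filter(sq, rep(1 / wn, wn), sides = 1)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  refr <- as.integer(round(cfg$refractory_ms / 1000 * fs))
  n <- length(mwi)
  # local maxima of the integrated waveform
  is_peak <- c(FALSE, mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                      mwi[2:(n - 1)] >= mwi[3:n], FALSE)
  cand <- which(is_peak)
  if (length(cand) == 0) {
    return(rr_series(numeric(0), numeric(0), ecg$record_id))
  }

  # adaptive thresholds (classic recipe), initialised from the first 2 s
  init <- mwi[seq_len(min(n, as.integer(2 * fs)))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  beats <- integer(0)
  rr_hist <- numeric(0)
  last_beat <- -Inf
  for (p in cand) {
    if (p - last_beat < refr) next
    if (mwi[p] > thr1) {
      beats <- c(beats, p)
      if (length(beats) >= 2) {
        rr_hist <- c(rr_hist, p - last_beat)
        if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
      }
      last_beat <- p
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else {
      # search-back: if the expected beat is overdue, accept the candidate
      # against the lower threshold
      overdue <- length(rr_hist) > 0 &&
        (p - last_beat) > cfg$searchback_factor * mean(rr_hist)
      if (overdue && mwi[p] > 0.5 * thr1) {
        beats <- c(beats, p)
        rr_hist <- c(rr_hist, p - last_beat)
        if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
        last_beat <- p
        spki <- 0.25 * mwi[p] + 0.75 * spki
      } else {
        npki <- 0.125 * mwi[p] + 0.875 * npki
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (length(beats) < 2) {
    return(rr_series(numeric(0), numeric(0), ecg$record_id))
  }

  # refine: MWI peaks lag the R wave by up to the integration window; take
  # the maximum of the band-passed ECG in the preceding window
  half <- wn
  refined <- vapply(beats, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p)
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce refractory after refinement
  keep <- c(TRUE, diff(refined) >= refr)
  refined <- refined[keep]
  if (length(refined) < 2) {
    return(rr_series(numeric(0), numeric(0), ecg$record_id))
  }
  times <- (refined - 1) / fs
  rr_ms <- diff(times) * 1000
  # the first beat has no preceding R peak; back-fill its interval with the
  # first measured RR so every detected beat stays in the series
  rr_series(times, c(rr_ms[1], rr_ms), ecg$record_id)
}
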