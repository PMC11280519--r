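# run expr with a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

# deterministic per-segment sub-seed, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

# physiological clipping bounds for generated RR intervals (ms); keep deltaRR
# mostly inside the +/-620 ms grid while still exercising edge-bin saturation
RR_CLIP_MIN <- 300
RR_CLIP_MAX <- 2000

rr_from_intervals <- function(intervals_ms, t0 = 0, record_id = "synthetic") {
  beat_times <- t0 + cumsum(intervals_ms) / 1000
  rr_series(beat_times, intervals_ms, record_id)
}

#' Generate a normal-sinus-rhythm RR series
#'
#' RR intervals follow a stationary Gaussian AR(1) process with mean
#' `mean_rr_ms`, marginal standard deviation `sdnn_ms` and lag-1 correlation
#' `ar1_rho`, clipped to the physiological range 300--2000 ms. With SDNN of
#' 30 ms or less the successive differences concentrate well inside the
#' 80 ms origin region of the Lorenz plot, which is what makes the rhythm
#' read as NSR to the detector.
#'
#' @param mean_rr_ms Mean RR interval (ms).
#' @param sdnn_ms Marginal RR standard deviation (ms), >= 0.
#' @param ar1_rho Lag-1 autocorrelation, |rho| < 1.
#' @param duration_s Duration to fill (s).
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param record_id Label for the series.
#' @return An [rr_series()] whose beats all lie in `[0, duration_s)`.
#' @export
gen_nsr_rr <- function(mean_rr_ms = 800, sdnn_ms = 30, ar1_rho = 0.9,
                       duration_s = 120, seed = 1, record_id = "nsr") {
  if (mean_rr_ms <= 0) stop("mean_rr_ms must be positive")
  if (sdnn_ms < 0) stop("sdnn_ms must be >= 0")
  if (abs(ar1_rho) >= 1) stop("|ar1_rho| must be < 1")
  n <- ceiling(duration_s * 1000 / max(mean_rr_ms - 4 * sdnn_ms, 250)) + 8
  iv <- with_seed(seed, {
    innov_sd <- sdnn_ms * sqrt(1 - ar1_rho^2)
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sdnn_ms)
    e <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- ar1_rho * x[i - 1] + e[i - 1]
    pmin(pmax(mean_rr_ms + x, RR_CLIP_MIN), RR_CLIP_MAX)
  })
  truncate_to_duration(iv, duration_s, record_id)
}

#' Generate an atrial-fibrillation RR series
#'
#' AF is modelled as a serially uncorrelated RR stream drawn uniformly on
#' `[mean_rr_ms - spread_ms, mean_rr_ms + spread_ms]`, clipped to 300--2000
#' ms: maximal beat-to-beat irregularity with no short-range structure,
#' matching the dispersed, sparse Lorenz scatter of fibrillating rhythm.
#'
#' @param mean_rr_ms Centre of the RR distribution (ms).
#' @param spread_ms Half-width of the uniform support (ms), > 0.
#' @param duration_s Duration to fill (s).
#' @param seed Integer seed.
#' @param record_id Label.
#' @return An [rr_series()].
#' @export
gen_af_rr <- function(mean_rr_ms = 800, spread_ms = 400, duration_s = 120,
                      seed = 1, record_id = "af") {
  if (mean_rr_ms <= 0) stop("mean_rr_ms must be positive")
  if (spread_ms <= 0) stop("spread_ms must be positive (degenerate support)")
  lo <- mean_rr_ms - spread_ms
  hi <- mean_rr_ms + spread_ms
  n <- ceiling(duration_s * 1000 / max(lo, 250)) + 8
  iv <- with_seed(seed, {
    pmin(pmax(stats::runif(n, lo, hi), RR_CLIP_MIN), RR_CLIP_MAX)
  })
  truncate_to_duration(iv, duration_s, record_id)
}

truncate_to_duration <- function(intervals_ms, duration_s, record_id) {
  t <- cumsum(intervals_ms) / 1000
  keep <- t < duration_s
  rr_series(t[keep], intervals_ms[keep], record_id)
}

#' Insert a premature atrial contraction with full compensatory pause
#'
#' Shortens interval `beat_index` to `prematurity_c` times its value and
#' stretches the next interval to `(2 - prematurity_c)` times the original
#' value, so the local two-beat time is preserved: the short-then-long RR
#' signature of a PAC followed by a compensatory pause. Beat times are
#' recomputed from the first beat so times and intervals stay consistent.
#'
#' @param series An [rr_series()].
#' @param beat_index Index of the interval to make premature; must be
#'   interior (`2 <= beat_index <= n - 1`).
#' @param prematurity_c Prematurity coefficient in (0, 1); 1 would leave the
#'   series unchanged.
#' @return A modified [rr_series()].
#' @export
insert_pac <- function(series, beat_index, prematurity_c = 0.7) {
  stopifnot(inherits(series, "rr_series"))
  n <- length(series$intervals)
  if (!(prematurity_c > 0 && prematurity_c < 1)) {
    stop("prematurity_c must lie strictly between 0 and 1")
  }
  if (beat_index < 2 || beat_index > n - 1) {
    stop("beat_index must be interior (2..", n - 1, "); got ", beat_index)
  }
  iv <- series$intervals
  base <- iv[beat_index]
  iv[beat_index] <- prematurity_c * base
  iv[beat_index + 1] <- (2 - prematurity_c) * base
  t0 <- series$beat_times[1]
  beat_times <- t0 + c(0, cumsum(iv[-1]) / 1000)
  rr_series(beat_times, iv, series$record_id)
}

#' Generate a synthetic single-lead ECG from an RR series
#'
#' Places a Gaussian-kernel P-QRS-T complex at each beat time (the P wave is
#' omitted when `include_p = FALSE`, as in AF where coordinated atrial
#' activity is absent) and adds white Gaussian noise. The true beat times are
#' carried in the RR series and serve as the oracle for beat-detector tests.
#'
#' @param rr An [rr_series()] giving the beat schedule.
#' @param fs Sampling rate (samples/s), >= 100.
#' @param r_amp_mv R-wave amplitude (mV).
#' @param noise_sd White-noise standard deviation (mV).
#' @param include_p Whether to draw P waves.
#' @param seed Integer seed for the noise.
#' @return An [ecg_signal()] covering the series plus a 0.5 s tail.
#' @export
gen_ecg <- function(rr, fs = 250, r_amp_mv = 1.0, noise_sd = 0,
                    include_p = TRUE, seed = 1) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 100) stop("fs must be >= 100 samples/s")
  dur <- if (length(rr$beat_times) > 0) max(rr$beat_times) + 0.5 else 1
  n <- as.integer(ceiling(dur * fs))
  t <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  gauss <- function(center, amp, sigma) {
    lo <- max(1L, as.integer(floor((center - 4 * sigma) * fs)) + 1L)
    hi <- min(n, as.integer(ceiling((center + 4 * sigma) * fs)) + 1L)
    if (lo <= hi) {
      idx <- lo:hi
      sig[idx] <<- sig[idx] + amp * exp(-((t[idx] - center)^2) /
                                          (2 * sigma^2))
    }
  }
  for (i in seq_along(rr$beat_times)) {
    bt <- rr$beat_times[i]
    rr_s <- rr$intervals[i] / 1000
    # QRS: fixed morphology; P and T placed as fractions of the local RR so
    # complexes stay separated at high heart rates
    gauss(bt, r_amp_mv, 0.012)
    gauss(bt - 0.035, -0.12 * r_amp_mv, 0.010)
    gauss(bt + 0.035, -0.20 * r_amp_mv, 0.010)
    gauss(bt + 0.32 * rr_s, 0.22 * r_amp_mv, 0.045)
    if (include_p) gauss(bt - 0.20 * rr_s, 0.12 * r_amp_mv, 0.022)
  }
  if (noise_sd > 0) {
    sig <- sig + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  ecg_signal(sig, fs, rr$record_id)
}

#' Describe a multi-segment synthetic rhythm recording
#'
#' @param segments A list of segments, each a list with `rhythm` (one of
#'   `"NSR"`, `"AF"`, `"PAC"`), `duration_s`, and optional `params` passed to
#'   the segment generator. `"PAC"` segments are NSR with
#'   `params$pacs_per_window` premature beats per 2 minutes (default 10) at
#'   prematurity `params$prematurity` (default 0.7).
#' @param seed Integer master seed; each segment derives its own sub-seed.
#' @return A list of class `rhythm_spec`.
#' @export
rhythm_spec <- function(segments, seed = 1) {
  for (s in segments) {
    if (!s$rhythm %in% c("NSR", "AF", "PAC")) {
      stop("unknown rhythm '", s$rhythm, "'")
    }
    if (is.null(s$duration_s) || s$duration_s <= 0) {
      stop("each segment needs duration_s > 0")
    }
  }
  structure(list(segments = segments, seed = as.integer(seed)),
            class = "rhythm_spec")
}

#' Generate a full synthetic record with ground-truth annotations
#'
#' Concatenates the spec's rhythm segments into one RR series and builds the
#' matching rhythm annotation (`AFIB` for AF segments, `N` otherwise) whose
#' interval boundaries are exactly the segment boundaries. Optionally also
#' renders the ECG.
#'
#' @param spec A [rhythm_spec()].
#' @param record_id Label for the record.
#' @param with_ecg If `TRUE`, also generate the synthetic ECG (P waves
#'   omitted during AF segments).
#' @param fs Sampling rate for the ECG.
#' @return A list with `rr` ([rr_series()]), `annotation` (a
#'   [rhythm_annotation()]), and `ecg` (an [ecg_signal()] or `NULL`).
#' @export
gen_record <- function(spec, record_id = "synthetic", with_ecg = FALSE,
                       fs = 250) {
  stopifnot(inherits(spec, "rhythm_spec"))
  t0 <- 0
  all_times <- numeric(0)
  all_iv <- numeric(0)
  ann <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    rhythm = character(0), stringsAsFactors = FALSE)
  ecg_parts <- if (with_ecg) list() else NULL
  for (i in seq_along(spec$segments)) {
    s <- spec$segments[[i]]
    p <- if (is.null(s$params)) list() else s$params
    sseed <- derive_seed(spec$seed, i)
    seg <- switch(s$rhythm,
      NSR = gen_nsr_rr(
        mean_rr_ms = p$mean_rr_ms %||% 800, sdnn_ms = p$sdnn_ms %||% 30,
        ar1_rho = p$ar1_rho %||% 0.9, duration_s = s$duration_s,
        seed = sseed, record_id = record_id),
      AF = gen_af_rr(
        mean_rr_ms = p$mean_rr_ms %||% 800, spread_ms = p$spread_ms %||% 400,
        duration_s = s$duration_s, seed = sseed, record_id = record_id),
      PAC = {
        base <- gen_nsr_rr(
          mean_rr_ms = p$mean_rr_ms %||% 800, sdnn_ms = p$sdnn_ms %||% 30,
          ar1_rho = p$ar1_rho %||% 0.9, duration_s = s$duration_s,
          seed = sseed, record_id = record_id)
        n_pac <- round((p$pacs_per_window %||% 10) * s$duration_s / 120)
        nb <- length(base$intervals)
        if (n_pac > 0 && nb >= 6) {
          pos <- with_seed(derive_seed(sseed, 1),
                           sort(sample(3:(nb - 2), min(n_pac, nb %/% 4))))
          # keep PACs separated so pauses do not overlap
          pos <- pos[c(TRUE, diff(pos) >= 3)]
          for (k in pos) {
            base <- insert_pac(base, k, p$prematurity %||% 0.7)
          }
        }
        base
      })
    label <- if (s$rhythm == "AF") "AFIB" else "N"
    ann <- rbind(ann, data.frame(start_s = t0, end_s = t0 + s$duration_s,
                                 rhythm = label, stringsAsFactors = FALSE))
    if (with_ecg) {
      ecg_parts[[i]] <- gen_ecg(seg, fs = fs,
                                include_p = s$rhythm != "AF",
                                noise_sd = p$noise_sd %||% 0,
                                seed = derive_seed(sseed, 2))
      # trim/pad the segment ECG to exactly duration_s samples
      want <- as.integer(round(s$duration_s * fs))
      x <- ecg_parts[[i]]$samples
      ecg_parts[[i]] <- if (length(x) >= want) x[seq_len(want)] else
        c(x, numeric(want - length(x)))
    }
    all_times <- c(all_times, t0 + seg$beat_times)
    all_iv <- c(all_iv, seg$intervals)
    t0 <- t0 + s$duration_s
  }
  rr <- rr_series(all_times, all_iv, record_id)
  annotation <- rhythm_annotation(ann, record_id)
  ecg <- if (with_ecg) {
    ecg_signal(unlist(ecg_parts), fs, record_id)
  } else NULL
  list(rr = rr, annotation = annotation, ecg = ecg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
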