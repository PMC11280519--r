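test_that("generators are deterministic under a fixed seed", {
  a <- gen_nsr_rr(800, 30, 0.9, 120, seed = 7)
  b <- gen_nsr_rr(800, 30, 0.9, 120, seed = 7)
  expect_identical(a$intervals, b$intervals)
  expect_identical(a$beat_times, b$beat_times)
  c1 <- gen_af_rr(800, 400, 120, seed = 7)
  c2 <- gen_af_rr(800, 400, 120, seed = 7)
  expect_identical(c1$intervals, c2$intervals)
  e1 <- gen_ecg(a, noise_sd = 0.05, seed = 3)
  e2 <- gen_ecg(a, noise_sd = 0.05, seed = 3)
  expect_identical(e1$samples, e2$samples)
  # generators restore the caller's RNG state
  set.seed(99); before <- .Random.seed
  invisible(gen_af_rr(800, 400, 30, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("NSR generator degenerates to a metronome at zero SDNN", {
  rr <- gen_nsr_rr(800, 0, 0.9, 30, seed = 1)
  expect_true(all(rr$intervals == 800))
  expect_error(gen_nsr_rr(-800, 30, 0.9, 30, 1), "positive")
  expect_error(gen_nsr_rr(800, -1, 0.9, 30, 1), ">= 0")
  expect_error(gen_nsr_rr(800, 30, 1.2, 30, 1), "rho")
})

test_that("NSR windows concentrate deltas inside the origin region", {
  for (seed in 1:20) {
    rr <- gen_nsr_rr(800, 30, 0.9, 120, seed = seed)
    expect_equal(classify_window(rr)$verdict, "NSR")
  }
})

test_that("AF windows read as AF, near-constant ones as NSR", {
  for (seed in 1:20) {
    rr <- gen_af_rr(800, 400, 120, seed = seed)
    expect_equal(classify_window(rr)$verdict, "AF")
  }
  expect_equal(classify_window(gen_af_rr(800, 1, 120, seed = 1))$verdict,
               "NSR")
  expect_error(gen_af_rr(800, 0, 120, 1), "degenerate")
})

test_that("generated intervals respect the physiological clip bounds", {
  rr <- gen_af_rr(600, 900, 300, seed = 5)
  expect_true(all(rr$intervals >= 300 & rr$intervals <= 2000))
  rr2 <- gen_nsr_rr(400, 200, 0.5, 300, seed = 5)
  expect_true(all(rr2$intervals >= 300 & rr2$intervals <= 2000))
})

test_that("insert_pac shortens the beat and compensates the next", {
  rr <- rr_series(c(0.8, 1.6, 2.4), c(800, 800, 800))
  out <- insert_pac(rr, 2, 0.7)
  expect_equal(out$intervals, c(800, 560, 1040))
  # beat times remain consistent with intervals
  expect_equal(diff(out$beat_times) * 1000, out$intervals[-1])
  # c -> 1 approaches the identity
  near <- insert_pac(rr, 2, 1 - 1e-9)
  expect_equal(near$intervals, rr$intervals, tolerance = 1e-6)
  expect_error(insert_pac(rr, 1, 0.7), "interior")
  expect_error(insert_pac(rr, 3, 0.7), "interior")
  expect_error(insert_pac(rr, 2, 1.5), "between 0 and 1")
})

test_that("PAC-laden NSR stays below the AF threshold", {
  base <- gen_nsr_rr(800, 30, 0.9, 120, seed = 2)
  nb <- length(base$intervals)
  pos <- round(seq(5, nb - 3, length.out = 10))
  for (k in pos) base <- insert_pac(base, k, 0.7)
  cls <- classify_window(base)
  expect_gt(cls$indices$pac_evidence, 0)
  expect_equal(cls$verdict, "NSR")
})

test_that("synthetic ECG places one dominant peak per beat", {
  rr <- rr_series(c(1, 2, 3), c(1000, 1000, 1000))
  ecg <- gen_ecg(rr, fs = 250, noise_sd = 0)
  x <- ecg$samples
  n <- length(x)
  peaks <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                 x[2:(n - 1)] > 0.5) + 1
  expect_equal(length(peaks), 3)
  expect_equal((peaks - 1) / 250, rr$beat_times, tolerance = 0.01)
})

test_that("ECG round trip recovers the RR series within 8 ms", {
  rr <- gen_nsr_rr(750, 40, 0.8, 90, seed = 6)
  det <- detect_rpeaks(gen_ecg(rr, fs = 250))
  expect_equal(length(det$beat_times), length(rr$beat_times))
  # compare RR against truth beat-matched
  expect_lt(max(abs(det$beat_times - rr$beat_times)) * 1000, 8)
  expect_lt(max(abs(det$intervals[-1] - rr$intervals[-1])), 8)
})

test_that("gen_record stitches segments with exact annotation boundaries", {
  spec <- rhythm_spec(list(
    list(rhythm = "NSR", duration_s = 600),
    list(rhythm = "AF", duration_s = 600)
  ), seed = 9)
  rec <- gen_record(spec, record_id = "two-seg")
  expect_equal(rec$annotation$intervals$start_s, c(0, 600))
  expect_equal(rec$annotation$intervals$end_s, c(600, 1200))
  expect_equal(rec$annotation$intervals$rhythm, c("N", "AFIB"))
  # every beat lies inside exactly one annotated tract
  iv <- rec$annotation$intervals
  n_in <- vapply(rec$rr$beat_times, function(t) {
    sum(t >= iv$start_s & t < iv$end_s)
  }, numeric(1))
  expect_true(all(n_in == 1))
  # total duration within one mean RR of the spec total
  expect_lt(abs(max(rec$rr$beat_times) - 1200), 2 * 800 / 1000)
  expect_error(rhythm_spec(list(list(rhythm = "VT", duration_s = 60))),
               "unknown rhythm")
})

test_that("a mixed NSR/AF record yields a diagonal-dominant confusion", {
  spec <- rhythm_spec(list(
    list(rhythm = "NSR", duration_s = 1200),
    list(rhythm = "AF", duration_s = 1200)
  ), seed = 31)
  rec <- gen_record(spec)
  det <- detect_rr(rec$rr)
  wins <- segment_windows(rec$rr, 120)
  truths <- label_windows(wins, rec$annotation)
  cc <- confusion(det$verdict, truths)
  expect_gt(cc$tp + cc$tn, 4 * (cc$fp + cc$fn))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 20)
})
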