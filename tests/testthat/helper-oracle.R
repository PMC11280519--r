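# Independent brute-force reference for the Lorenz AF indices: plain nested
# loops, no shared code with the package implementation. Used to cross-check
# histogram binning, region counting and the evidence arithmetic.

naive_af_indices <- function(intervals_ms, mask, bin_width_ms = 40,
                             saturate = TRUE) {
  d <- diff(intervals_ms)
  stopifnot(length(d) >= 2)
  counts <- matrix(0L, 31, 31)
  for (i in 2:length(d)) {
    ix <- round(d[i] / bin_width_ms) + 15
    iy <- round(d[i - 1] / bin_width_ms) + 15
    if (saturate) {
      ix <- min(max(ix, 0), 30)
      iy <- min(max(iy, 0), 30)
    } else if (ix < 0 || ix > 30 || iy < 0 || iy > 30) {
      next
    }
    counts[ix + 1, iy + 1] <- counts[ix + 1, iy + 1] + 1L
  }
  bin_count <- integer(13)
  point_count <- integer(13)
  for (xb in 1:31) {
    for (yb in 1:31) {
      r <- mask$labels[xb, yb] + 1L
      point_count[r] <- point_count[r] + counts[xb, yb]
      if (counts[xb, yb] > 0L) bin_count[r] <- bin_count[r] + 1L
    }
  }
  irr <- 0L
  for (n in 2:13) irr <- irr + bin_count[n]
  origin <- point_count[1]
  pac <- 0L
  for (n in c(1, 2, 3, 4, 5, 6, 10)) {
    pac <- pac + (point_count[n + 1] - bin_count[n + 1])
  }
  for (n in c(7, 8, 12)) {
    pac <- pac - (point_count[n + 1] - bin_count[n + 1])
  }
  list(counts = counts, bin_count = bin_count, point_count = point_count,
       irregularity_evidence = irr, origin_count = origin,
       pac_evidence = pac,
       af_evidence = irr - origin - 2L * pac)
}

# a constant-rate RR series filling duration_s at mean_rr_ms
constant_rr <- function(mean_rr_ms = 800, duration_s = 120,
                        n = NULL, record_id = "const") {
  if (is.null(n)) n <- floor(duration_s * 1000 / mean_rr_ms)
  rr_series(seq(0, by = mean_rr_ms / 1000, length.out = n),
            rep(mean_rr_ms, n), record_id)
}

# evaluate expr under a fixed seed without disturbing the session RNG
with_seed_local <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

builtin_mask_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- builtin_segment_mask()
    m
  }
})
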