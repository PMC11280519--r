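#' Detector configuration
#'
#' Bundles the tunable parameters of the Lorenz AF detector. Defaults follow
#' the published algorithm: 2-minute windows, 40 ms bins on a 31x31 grid,
#' an 80 ms origin region, and an AFThreshold of 50.
#'
#' @param af_threshold Integer decision threshold; a window is called AF when
#'   `AFEvidence >= af_threshold`.
#' @param window_s Analysis window duration in seconds.
#' @param bin_width_ms Lorenz histogram bin width in milliseconds.
#' @param origin_radius_ms Chebyshev radius of the origin region (region 0):
#'   a bin belongs to region 0 when both its center coordinates have absolute
#'   value at most this radius.
#' @param mask_source `"builtin"` or a path to a 31x31 mask file (see
#'   [load_segment_mask()]).
#' @param min_intervals Windows with fewer intervals than this are classified
#'   `"undetermined"` and excluded from scoring.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(af_threshold = 50L, window_s = 120,
                            bin_width_ms = 40, origin_radius_ms = 80,
                            mask_source = "builtin", min_intervals = 4L) {
  stopifnot(is.finite(af_threshold), window_s > 0, bin_width_ms > 0,
            origin_radius_ms >= 0, min_intervals >= 1)
  structure(
    list(af_threshold = as.integer(af_threshold), window_s = window_s,
         bin_width_ms = bin_width_ms, origin_radius_ms = origin_radius_ms,
         mask_source = mask_source, min_intervals = as.integer(min_intervals)),
    class = "detector_config"
  )
}

# number of bins per axis; the grid spans [-620, +620) ms at 40 ms bins with
# bin centers at multiples of the bin width and the origin at bin index 15
# (0-based)
LORENZ_NBINS <- 31L
LORENZ_CENTER <- 15L  # 0-based index of the origin bin on each axis

#' Bin centers of the Lorenz grid (ms)
#'
#' @param bin_width_ms Bin width in milliseconds.
#' @return Numeric vector of 31 bin-center coordinates, symmetric about 0.
#' @export
lorenz_bin_centers <- function(bin_width_ms = 40) {
  (seq_len(LORENZ_NBINS) - 1 - LORENZ_CENTER) * bin_width_ms
}

#' Build the Lorenz scatter-plot histogram for one window
#'
#' Forms the successive-difference pairs (x = deltaRR(i), y = deltaRR(i-1))
#' and accumulates them into a 31x31 occupancy histogram. Each coordinate is
#' quantized to the nearest bin center (`round(x / w)`), and out-of-range
#' pairs are saturated into the edge bins so that the total count always
#' equals the number of pairs.
#'
#' @param deltas A [delta_rr()] object (or plain numeric vector of deltaRR
#'   values in ms).
#' @param bin_width_ms Bin width in milliseconds.
#' @param saturate If `TRUE` (default) clamp out-of-range pairs to the edge
#'   bins; if `FALSE` drop them.
#' @return A list of class `lorenz_grid` with `counts` (31x31 integer matrix,
#'   rows = x bins, cols = y bins, both ordered from most negative),
#'   `bin_width_ms` and `n_points`.
#' @export
build_histogram <- function(deltas, bin_width_ms = 40, saturate = TRUE) {
  v <- if (inherits(deltas, "delta_rr")) deltas$values else as.numeric(deltas)
  if (length(v) < 2) {
    stop("insufficient data: need at least 2 deltaRR values to form a ",
         "Lorenz pair (got ", length(v), ")")
  }
  x <- v[-1]           # deltaRR(i)
  y <- v[-length(v)]   # deltaRR(i-1)
  ix <- as.integer(round(x / bin_width_ms)) + LORENZ_CENTER
  iy <- as.integer(round(y / bin_width_ms)) + LORENZ_CENTER
  if (saturate) {
    ix <- pmin(pmax(ix, 0L), LORENZ_NBINS - 1L)
    iy <- pmin(pmax(iy, 0L), LORENZ_NBINS - 1L)
  } else {
    keep <- ix >= 0L & ix <= LORENZ_NBINS - 1L &
            iy >= 0L & iy <= LORENZ_NBINS - 1L
    ix <- ix[keep]; iy <- iy[keep]
  }
  counts <- matrix(0L, LORENZ_NBINS, LORENZ_NBINS)
  if (length(ix) > 0) {
    flat <- ix + LORENZ_NBINS * iy + 1L  # column-major: [x + 1, y + 1]
    tab <- tabulate(flat, nbins = LORENZ_NBINS * LORENZ_NBINS)
    counts[] <- as.integer(tab)
  }
  structure(
    list(counts = counts, bin_width_ms = bin_width_ms,
         n_points = length(ix)),
    class = "lorenz_grid"
  )
}

#' @export
print.lorenz_grid <- function(x, ...) {
  cat("lorenz_grid: ", x$n_points, " points, ", x$bin_width_ms,
      " ms bins, ", sum(x$counts > 0), " occupied bins\n", sep = "")
  invisible(x)
}

#' The built-in 13-region segmentation of the Lorenz domain
#'
#' Region 0 is the square of bins whose centers satisfy
#' `max(|x|, |y|) <= origin_radius_ms`. The remainder is split into four
#' quadrant blocks (1: x>r,y>r; 2: x<-r,y>r; 3: x<-r,y<-r; 4: x>r,y<-r) and
#' four axis corridors each divided at `split_ms` into a near and a far half
#' (5/9: north, 6/10: west, 7/11: south, 8/12: east). This geometry is a
#' documented reconstruction of the published region figure; the mask is a
#' loadable data resource so an alternative geometry can be supplied without
#' touching the algorithm.
#'
#' @param bin_width_ms Bin width in milliseconds.
#' @param origin_radius_ms Origin-region radius in milliseconds.
#' @param split_ms Near/far corridor split in milliseconds.
#' @return A list of class `segment_mask` with `labels` (31x31 integer matrix
#'   in 0..12, rows = x bins, cols = y bins) and `origin_radius_ms`.
#' @export
builtin_segment_mask <- function(bin_width_ms = 40, origin_radius_ms = 80,
                                 split_ms = 340) {
  ctr <- lorenz_bin_centers(bin_width_ms)
  cx <- matrix(ctr, LORENZ_NBINS, LORENZ_NBINS, byrow = FALSE)
  cy <- matrix(ctr, LORENZ_NBINS, LORENZ_NBINS, byrow = TRUE)
  r <- origin_radius_ms
  lab <- matrix(NA_integer_, LORENZ_NBINS, LORENZ_NBINS)
  lab[abs(cx) <= r & abs(cy) <= r] <- 0L
  lab[cx >  r & cy >  r] <- 1L
  lab[cx < -r & cy >  r] <- 2L
  lab[cx < -r & cy < -r] <- 3L
  lab[cx >  r & cy < -r] <- 4L
  north <- abs(cx) <= r & cy >  r
  west  <- cx < -r & abs(cy) <= r
  south <- abs(cx) <= r & cy < -r
  east  <- cx >  r & abs(cy) <= r
  lab[north & cy <=  split_ms] <- 5L
  lab[north & cy >   split_ms] <- 9L
  lab[west  & cx >= -split_ms] <- 6L
  lab[west  & cx <  -split_ms] <- 10L
  lab[south & cy >= -split_ms] <- 7L
  lab[south & cy <  -split_ms] <- 11L
  lab[east  & cx <=  split_ms] <- 8L
  lab[east  & cx >   split_ms] <- 12L
  mask <- structure(
    list(labels = lab, origin_radius_ms = origin_radius_ms,
         bin_width_ms = bin_width_ms),
    class = "segment_mask"
  )
  validate_segment_mask(mask)
  mask
}

#' Validate a segment mask against the detector's geometric invariants
#'
#' Checks shape (31x31), label range (0..12), full coverage, and that the
#' region-0 bins are exactly those within the origin radius.
#'
#' @param mask A `segment_mask`.
#' @return `mask`, invisibly; signals an error on violation.
#' @export
validate_segment_mask <- function(mask) {
  lab <- mask$labels
  if (!is.matrix(lab) || any(dim(lab) != LORENZ_NBINS)) {
    stop("segment mask must be a ", LORENZ_NBINS, "x", LORENZ_NBINS,
         " matrix; got ", paste(dim(lab), collapse = "x"))
  }
  if (anyNA(lab) || any(lab < 0L) || any(lab > 12L) ||
      any(lab != as.integer(lab))) {
    stop("segment mask labels must be integers in 0..12")
  }
  ctr <- lorenz_bin_centers(mask$bin_width_ms)
  cx <- matrix(ctr, LORENZ_NBINS, LORENZ_NBINS, byrow = FALSE)
  cy <- matrix(ctr, LORENZ_NBINS, LORENZ_NBINS, byrow = TRUE)
  in_origin <- abs(cx) <= mask$origin_radius_ms &
               abs(cy) <= mask$origin_radius_ms
  if (!identical(unname(lab == 0L), unname(in_origin))) {
    stop("region-0 bins must be exactly those with |center| <= ",
         mask$origin_radius_ms, " ms on both axes")
  }
  invisible(mask)
}

#' Load a segment mask
#'
#' `source = "builtin"` returns the package's default geometry
#' ([builtin_segment_mask()]). Otherwise `source` is a path to a plain-text
#' file of 31 rows by 31 whitespace-separated integers in 0..12, where row 1
#' is the most-negative y bin and columns run from the most-negative x bin.
#'
#' @param source `"builtin"` or a file path.
#' @param bin_width_ms Bin width used to verify the region-0 geometry.
#' @param origin_radius_ms Origin radius used to verify the region-0 geometry.
#' @return A validated `segment_mask`.
#' @export
load_segment_mask <- function(source = "builtin", bin_width_ms = 40,
                              origin_radius_ms = 80) {
  if (identical(source, "builtin")) {
    return(builtin_segment_mask(bin_width_ms, origin_radius_ms))
  }
  if (!file.exists(source)) stop("mask file not found: ", source)
  rows <- utils::read.table(source, header = FALSE,
                            colClasses = "integer")
  m <- as.matrix(rows)
  if (nrow(m) != LORENZ_NBINS || ncol(m) != LORENZ_NBINS) {
    stop("mask file must contain a ", LORENZ_NBINS, "x", LORENZ_NBINS,
         " grid; got ", nrow(m), "x", ncol(m), " in ", source)
  }
  # file rows are y bins (most negative first); internal layout is [x, y]
  lab <- t(m)
  dimnames(lab) <- NULL
  mask <- structure(
    list(labels = lab, origin_radius_ms = origin_radius_ms,
         bin_width_ms = bin_width_ms),
    class = "segment_mask"
  )
  validate_segment_mask(mask)
  mask
}

#' Write a segment mask to the plain-text interchange format
#'
#' @param mask A `segment_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_mask <- function(mask, path) {
  utils::write.table(t(mask$labels), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Per-region bin and point counts
#'
#' `point_count[n]` is the total number of Lorenz points falling in region
#' `n`; `bin_count[n]` is the number of that region's bins populated at least
#' once. Vectors are indexed by region 0..12 (R index `n + 1`).
#'
#' @param grid A [build_histogram()] result.
#' @param mask A `segment_mask`.
#' @return List with integer vectors `bin_count` and `point_count`, each of
#'   length 13.
#' @export
region_counts <- function(grid, mask) {
  if (!identical(dim(grid$counts), dim(mask$labels))) {
    stop("grid and mask shapes disagree")
  }
  f <- factor(as.vector(mask$labels), levels = 0:12)
  point_count <- as.integer(tapply(as.vector(grid$counts), f, sum,
                                   default = 0L))
  bin_count <- as.integer(tapply(as.vector(grid$counts) > 0L, f, sum,
                                 default = 0L))
  list(bin_count = bin_count, point_count = point_count)
}

#' IrregularityEvidence: sparsity of the Lorenz distribution
#'
#' The number of populated bins outside the origin region, summed over
#' regions 1..12. High during AF (sparse, dispersed scatter), low during
#' normal sinus rhythm (points concentrated at the origin).
#'
#' @param bin_count Per-region bin counts from [region_counts()].
#' @return Integer.
#' @export
irregularity_evidence <- function(bin_count) {
  as.integer(sum(bin_count[2:13]))
}

#' PACEvidence: evidence of compensatory pauses
#'
#' Premature atrial contractions produce a short-then-long RR signature whose
#' Lorenz points stack repeatedly in the same bins of specific regions. The
#' index sums the per-region excess of points over populated bins
#' (PointCount - BinCount) with positive weight over the quadrants (1..4) and
#' regions 5, 6, 10, and negative weight over regions 7, 8, 12.
#'
#' @param bin_count,point_count Per-region counts from [region_counts()].
#' @return Integer (may be negative).
#' @export
pac_evidence <- function(bin_count, point_count) {
  excess <- point_count - bin_count  # indexed by region + 1
  plus <- c(1:4, 5, 6, 10) + 1L
  minus <- c(7, 8, 12) + 1L
  as.integer(sum(excess[plus]) - sum(excess[minus]))
}

#' AFEvidence: the detector's decision statistic
#'
#' `AFEvidence = IrregularityEvidence - OriginCount - 2 * PACEvidence`, where
#' OriginCount is the number of points in the origin region. All-integer
#' arithmetic.
#'
#' @param irregularity,origin_count,pac Integer components.
#' @return Integer.
#' @export
af_evidence <- function(irregularity, origin_count, pac) {
  as.integer(irregularity - origin_count - 2L * pac)
}

#' Compute all AF indices for one window of RR intervals
#'
#' @param series An [rr_series()] holding one window's intervals.
#' @param mask A `segment_mask`.
#' @param bin_width_ms Histogram bin width (ms).
#' @return A list of class `af_indices` with `irregularity_evidence`,
#'   `pac_evidence`, `origin_count`, `af_evidence`, `bin_count`,
#'   `point_count` and `n_points`.
#' @export
af_indices <- function(series, mask, bin_width_ms = 40) {
  grid <- build_histogram(delta_rr(series), bin_width_ms = bin_width_ms)
  rc <- region_counts(grid, mask)
  irr <- irregularity_evidence(rc$bin_count)
  origin <- as.integer(rc$point_count[1])
  pac <- pac_evidence(rc$bin_count, rc$point_count)
  structure(
    list(irregularity_evidence = irr,
         pac_evidence = pac,
         origin_count = origin,
         af_evidence = af_evidence(irr, origin, pac),
         bin_count = rc$bin_count,
         point_count = rc$point_count,
         n_points = grid$n_points),
    class = "af_indices"
  )
}

#' @export
print.af_indices <- function(x, ...) {
  cat(sprintf(
    "af_indices: irregularity %d, PAC %d, origin %d -> AFEvidence %d (%d points)\n",
    x$irregularity_evidence, x$pac_evidence, x$origin_count,
    x$af_evidence, x$n_points))
  invisible(x)
}

#' Classify one window as AF, NSR or undetermined
#'
#' Windows with fewer than `config$min_intervals` intervals are
#' `"undetermined"` (their indices are undefined); otherwise the verdict is
#' `"AF"` when `AFEvidence >= af_threshold` and `"NSR"` otherwise.
#'
#' @param series An [rr_series()] holding the window's intervals.
#' @param config A [detector_config()].
#' @param mask A `segment_mask`; defaults to the config's `mask_source`.
#' @return A list of class `window_classification` with `verdict` (one of
#'   `"AF"`, `"NSR"`, `"undetermined"`), `indices` (possibly `NULL`), and
#'   `n_rr`.
#' @export
classify_window <- function(series, config = detector_config(),
                            mask = NULL) {
  if (is.null(mask)) {
    mask <- load_segment_mask(config$mask_source, config$bin_width_ms,
                              config$origin_radius_ms)
  }
  n <- length(series$intervals)
  if (n < config$min_intervals) {
    return(structure(list(verdict = "undetermined", indices = NULL,
                          n_rr = n),
                     class = "window_classification"))
  }
  ind <- af_indices(series, mask, config$bin_width_ms)
  verdict <- if (ind$af_evidence >= config$af_threshold) "AF" else "NSR"
  structure(list(verdict = verdict, indices = ind, n_rr = n),
            class = "window_classification")
}

#' @export
print.window_classification <- function(x, ...) {
  if (is.null(x$indices)) {
    cat("window: undetermined (", x$n_rr, " intervals)\n", sep = "")
  } else {
    cat(sprintf("window: %s (AFEvidence %d, %d intervals)\n",
                x$verdict, x$indices$af_evidence, x$n_rr))
  }
  invisible(x)
}

#' Run the detector over a whole record
#'
#' Tiles the record into windows ([segment_windows()]) and classifies each
#' one. deltaRR pairs never straddle window boundaries: each window is
#' processed from its own intervals only, mirroring the per-window packets
#' the device transmits.
#'
#' @param series An [rr_series()] for the whole record.
#' @param config A [detector_config()].
#' @return A data frame with one row per window: `record`, `window_start_s`,
#'   `n_rr`, `irregularity`, `pac`, `origin`, `af_evidence` (NA when
#'   undetermined) and `verdict`.
#' @export
detect_rr <- function(series, config = detector_config()) {
  mask <- load_segment_mask(config$mask_source, config$bin_width_ms,
                            config$origin_radius_ms)
  wins <- segment_windows(series, config$window_s)
  if (length(wins) == 0) {
    return(data.frame(record = character(0), window_start_s = numeric(0),
                      n_rr = integer(0), irregularity = integer(0),
                      pac = integer(0), origin = integer(0),
                      af_evidence = integer(0), verdict = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(wins, function(w) {
    cls <- classify_window(window_series(series, w), config, mask)
    data.frame(
      record = series$record_id,
      window_start_s = w$start,
      n_rr = cls$n_rr,
      irregularity = if (is.null(cls$indices)) NA_integer_ else
        cls$indices$irregularity_evidence,
      pac = if (is.null(cls$indices)) NA_integer_ else
        cls$indices$pac_evidence,
      origin = if (is.null(cls$indices)) NA_integer_ else
        cls$indices$origin_count,
      af_evidence = if (is.null(cls$indices)) NA_integer_ else
        cls$indices$af_evidence,
      verdict = cls$verdict,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
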