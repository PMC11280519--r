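#' Construct an RR-interval series
#'
#' An `rr_series` holds the timestamped inter-beat intervals produced by a
#' beat detector: `beat_times` are the times of the R peaks (seconds from
#' record start, strictly increasing) and `intervals` the corresponding RR
#' durations in milliseconds. Interval `i` is the time elapsed between beat
#' `i - 1` and beat `i`; the first interval may come from a beat before the
#' record start and is kept as supplied.
#'
#' @param beat_times Numeric vector of beat times in seconds, strictly
#'   increasing.
#' @param intervals Numeric vector of RR intervals in milliseconds, one per
#'   beat, all strictly positive.
#' @param record_id Optional character label for the source record.
#' @return An object of class `rr_series` with fields `beat_times`,
#'   `intervals` and `record_id`.
#' @examples
#' rr <- rr_series(c(0.8, 1.6, 2.4), c(800, 800, 800))
#' delta_rr(rr)$values
#' @export
rr_series <- function(beat_times, intervals, record_id = "unnamed") {
  beat_times <- as.numeric(beat_times)
  intervals <- as.numeric(intervals)
  if (length(beat_times) != length(intervals)) {
    stop("beat_times and intervals must have equal length (",
         length(beat_times), " vs ", length(intervals), ")")
  }
  if (anyNA(beat_times) || anyNA(intervals)) {
    stop("beat_times and intervals must not contain NA")
  }
  bad <- which(intervals <= 0)
  if (length(bad) > 0) {
    stop("non-positive RR interval at index ", bad[1],
         " (", intervals[bad[1]], " ms)")
  }
  if (length(beat_times) > 1 && any(diff(beat_times) <= 0)) {
    stop("beat_times must be strictly increasing")
  }
  structure(
    list(beat_times = beat_times, intervals = intervals,
         record_id = as.character(record_id)[1]),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat("rr_series '", x$record_id, "': ", n, " intervals", sep = "")
  if (n > 0) {
    cat(sprintf(", span %.1f s, mean RR %.0f ms",
                diff(range(x$beat_times)), mean(x$intervals)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Successive RR-interval differences
#'
#' Computes the first difference of the RR series,
#' \eqn{\delta RR(i) = RR(i) - RR(i-1)}, the quantity whose successive pairs
#' populate the Lorenz scatter plot. Each difference is anchored at the time
#' of the later beat.
#'
#' @param series An [rr_series()].
#' @return A list of class `delta_rr` with `values` (signed milliseconds,
#'   length `max(0, n - 1)`) and `anchor_times` (seconds).
#' @export
delta_rr <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  n <- length(series$intervals)
  if (n <= 1) {
    values <- numeric(0)
    anchor <- numeric(0)
  } else {
    values <- diff(series$intervals)
    anchor <- series$beat_times[-1]
  }
  structure(list(values = values, anchor_times = anchor),
            class = "delta_rr")
}

#' Tile a record into fixed-duration analysis windows
#'
#' Splits the time axis of a record into consecutive half-open windows
#' `[k*d, (k+1)*d)` aligned to time 0, and assigns each RR interval to the
#' window containing its terminating beat time. Windows tile the record with
#' no overlap: every interval lands in exactly one window.
#'
#' @param series An [rr_series()].
#' @param duration_s Window duration in seconds (default 120, the 2-minute
#'   transmit cycle of the device).
#' @return A list of windows, each a list with `start` (s), `duration` (s)
#'   and `rr_indices` (integer indices into `series$intervals`). Empty series
#'   give an empty list.
#' @export
segment_windows <- function(series, duration_s = 120) {
  stopifnot(inherits(series, "rr_series"))
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    stop("duration_s must be a single positive number")
  }
  n <- length(series$beat_times)
  if (n == 0) return(list())
  k <- floor(series$beat_times / duration_s)
  n_win <- max(k) + 1
  out <- vector("list", n_win)
  idx_by_win <- split(seq_len(n), factor(k, levels = 0:(n_win - 1)))
  for (w in seq_len(n_win)) {
    out[[w]] <- list(
      start = (w - 1) * duration_s,
      duration = duration_s,
      rr_indices = as.integer(idx_by_win[[w]])
    )
  }
  out
}

#' Extract one window of a series as a standalone rr_series
#'
#' @param series An [rr_series()].
#' @param window One element of the list returned by [segment_windows()].
#' @return An [rr_series()] containing only the window's intervals.
#' @export
window_series <- function(series, window) {
  idx <- window$rr_indices
  if (length(idx) == 0) {
    return(rr_series(numeric(0), numeric(0), series$record_id))
  }
  rr_series(series$beat_times[idx], series$intervals[idx], series$record_id)
}

#' Read an RR series from CSV
#'
#' Expects a header `time_s,rr_ms` and one beat per row; lines beginning with
#' `#` are comments.
#'
#' @param path Path to the CSV file.
#' @param record_id Label for the series; defaults to the file stem.
#' @return An [rr_series()].
#' @export
read_rr_csv <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("RR CSV file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("time_s", "rr_ms")
  if (!all(need %in% names(df))) {
    stop("RR CSV must have columns 'time_s,rr_ms'; got: ",
         paste(names(df), collapse = ","))
  }
  if (is.null(record_id)) {
    record_id <- tools::file_path_sans_ext(basename(path))
  }
  rr_series(df$time_s, df$rr_ms, record_id)
}

#' Write an RR series to CSV (`time_s,rr_ms`)
#'
#' @param series An [rr_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  df <- data.frame(time_s = series$beat_times, rr_ms = series$intervals)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
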