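#' Construct a rhythm annotation
#'
#' Ground-truth rhythm intervals for a record: an ordered, non-overlapping
#' set of `(start_s, end_s, rhythm)` tracts with rhythm labels `AFIB`, `N`
#' or `OTHER`.
#'
#' @param intervals Data frame with columns `start_s`, `end_s`, `rhythm`.
#' @param record_id Label.
#' @return A list of class `rhythm_annotation`.
#' @export
rhythm_annotation <- function(intervals, record_id = "unnamed") {
  need <- c("start_s", "end_s", "rhythm")
  if (!all(need %in% names(intervals))) {
    stop("annotation needs columns start_s,end_s,rhythm")
  }
  intervals <- intervals[order(intervals$start_s), need, drop = FALSE]
  rownames(intervals) <- NULL
  if (nrow(intervals) > 0) {
    if (any(intervals$end_s <= intervals$start_s)) {
      stop("annotation intervals must have end_s > start_s")
    }
    if (nrow(intervals) > 1 &&
        any(intervals$start_s[-1] < intervals$end_s[-nrow(intervals)] - 1e-9)) {
      stop("annotation intervals must not overlap")
    }
    bad <- setdiff(unique(intervals$rhythm), c("AFIB", "N", "OTHER"))
    if (length(bad) > 0) {
      stop("rhythm labels must be AFIB, N or OTHER; got: ",
           paste(bad, collapse = ","))
    }
  }
  structure(list(intervals = intervals,
                 record_id = as.character(record_id)[1]),
            class = "rhythm_annotation")
}

#' @export
print.rhythm_annotation <- function(x, ...) {
  cat("rhythm_annotation '", x$record_id, "': ", nrow(x$intervals),
      " tracts\n", sep = "")
  if (nrow(x$intervals) > 0) print(x$intervals)
  invisible(x)
}

#' Read/write rhythm annotations as CSV (`start_s,end_s,rhythm`)
#'
#' @param path File path.
#' @param record_id Label; defaults to the file stem.
#' @return [read_annotation_csv()] returns a [rhythm_annotation()];
#'   [write_annotation_csv()] returns `path` invisibly.
#' @export
read_annotation_csv <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("annotation CSV not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        stringsAsFactors = FALSE)
  if (is.null(record_id)) {
    record_id <- tools::file_path_sans_ext(basename(path))
  }
  rhythm_annotation(df, record_id)
}

#' @rdname read_annotation_csv
#' @param ann A [rhythm_annotation()].
#' @export
write_annotation_csv <- function(ann, path) {
  stopifnot(inherits(ann, "rhythm_annotation"))
  utils::write.csv(ann$intervals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## WFDB records (.hea + .dat), formats 212 and 16

#' Read a WFDB record's first ECG channel
#'
#' Parses the `.hea` header for the sampling rate, gain and storage format
#' and decodes the first signal from the `.dat` file. Formats 212 (packed
#' 12-bit pairs) and 16 (little-endian 16-bit) are supported — enough for
#' the MIT-BIH family and for this package's own fixtures.
#'
#' @param path Record path with or without the `.hea` extension.
#' @return An [ecg_signal()] in millivolts with `fs` from the header.
#' @export
read_wfdb_record <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- rec[1]
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  n_samp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA
  if (n_sig < 1) stop("record ", record_name, " has no signals")
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  dat_name <- sig[1]
  fmt <- as.integer(sub("x.*", "", sig[2]))
  gain_field <- sig[3]
  gain <- as.numeric(sub("[(/].*", "", gain_field))
  baseline <- if (grepl("\\(", gain_field)) {
    as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
  } else 0
  if (is.na(gain) || gain == 0) gain <- 200
  dat <- file.path(dirname(hea), dat_name)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat)
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  adc <- switch(as.character(fmt),
    "212" = decode_fmt212(raw),
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                   endian = "little", signed = TRUE)
      v
    },
    stop("unsupported WFDB format ", fmt, " in ", hea))
  if (fmt == 212 && n_sig == 2) {
    # interleaved channels: take channel 1
    adc <- adc[seq(1, length(adc), by = 2)]
  } else if (fmt == 16 && n_sig > 1) {
    adc <- adc[seq(1, length(adc), by = n_sig)]
  }
  if (!is.na(n_samp) && n_samp > 0 && length(adc) >= n_samp) {
    adc <- adc[seq_len(n_samp)]
  }
  ecg_signal((adc - baseline) / gain, fs, record_name)
}

# format 212: each 3-byte group packs two 12-bit two's-complement samples
decode_fmt212 <- function(raw) {
  n3 <- (length(raw) %/% 3) * 3
  b <- as.integer(raw[seq_len(n3)])
  b0 <- b[seq(1, n3, by = 3)]
  b1 <- b[seq(2, n3, by = 3)]
  b2 <- b[seq(3, n3, by = 3)]
  s1 <- b0 + 256L * (b1 %% 16L)
  s2 <- b2 + 256L * (b1 %/% 16L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

encode_fmt212 <- function(adc) {
  if (any(adc < -2048L | adc > 2047L)) {
    stop("format 212 samples must fit 12 bits (got range ",
         min(adc), "..", max(adc), ")")
  }
  if (length(adc) %% 2 == 1) adc <- c(adc, 0L)
  u <- ifelse(adc < 0L, adc + 4096L, adc)
  s1 <- u[seq(1, length(u), by = 2)]
  s2 <- u[seq(2, length(u), by = 2)]
  out <- integer(3 * length(s1))
  out[seq(1, length(out), by = 3)] <- s1 %% 256L
  out[seq(2, length(out), by = 3)] <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
  out[seq(3, length(out), by = 3)] <- s2 %% 256L
  as.raw(out)
}

#' Write an ECG signal as a WFDB record (format 212)
#'
#' Quantizes to 12 bits at the given gain and writes `<name>.hea` and
#' `<name>.dat` in the target directory.
#'
#' @param ecg An [ecg_signal()].
#' @param dir Output directory.
#' @param name Record name; defaults to the signal's `record_id`.
#' @param gain ADC units per millivolt.
#' @return The header path, invisibly.
#' @export
write_wfdb_record <- function(ecg, dir, name = NULL, gain = 200) {
  stopifnot(inherits(ecg, "ecg_signal"))
  if (is.null(name)) name <- ecg$record_id
  adc <- as.integer(round(ecg$samples * gain))
  adc <- pmin(pmax(adc, -2048L), 2047L)
  dat <- paste0(name, ".dat")
  writeBin(encode_fmt212(adc), file.path(dir, dat))
  chk <- sum(adc) %% 65536L
  if (chk > 32767L) chk <- chk - 65536L
  hea <- file.path(dir, paste0(name, ".hea"))
  writeLines(c(
    sprintf("%s 1 %g %d", name, ecg$fs, length(adc)),
    sprintf("%s 212 %g/mV 12 0 %d %d 0 ECG", dat, gain,
            if (length(adc) > 0) adc[1] else 0L, chk)
  ), hea)
  invisible(hea)
}

## ---------------------------------------------------------------------------
## WFDB annotations (MIT format), rhythm subset

# MIT annotation word codes used here
ANN_RHYTHM <- 28L
ANN_AUX <- 63L
ANN_SKIP <- 59L

#' Read rhythm annotations from a WFDB annotation file
#'
#' Decodes the MIT annotation format and extracts rhythm-change labels
#' (aux strings such as `"(AFIB"` and `"(N"`). Each rhythm label opens an
#' interval that closes at the next rhythm change, or at `record_end_s`.
#' Labels map `(AFIB` to `AFIB`, `(N` to `N`, and anything else to `OTHER`.
#' Beat annotations and modifier words are skipped over correctly but
#' ignored.
#'
#' @param path Annotation file path.
#' @param fs Sampling rate used to convert sample indices to seconds.
#' @param record_end_s End of record (s); defaults to the last annotation
#'   time.
#' @param record_id Label; defaults to the file stem.
#' @return A [rhythm_annotation()]; empty (with a warning) when the file has
#'   no rhythm labels.
#' @export
read_rhythm_annotations <- function(path, fs = 250, record_end_s = NULL,
                                    record_id = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(record_id)) {
    record_id <- tools::file_path_sans_ext(basename(path))
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  b <- as.integer(raw)
  i <- 1L
  t_samp <- 0
  changes <- list()
  last_time <- 0
  while (i + 1L <= length(b)) {
    lo <- b[i]; hi <- b[i + 1L]
    i <- i + 2L
    code <- hi %/% 4L
    tfield <- (hi %% 4L) * 256L + lo
    if (code == 0L && tfield == 0L) break  # end of file
    if (code == ANN_SKIP) {
      if (i + 3L > length(b)) break
      high <- b[i + 1L] * 256L + b[i]       # high 16 bits, little-endian word
      low <- b[i + 3L] * 256L + b[i + 2L]
      i <- i + 4L
      skip <- high * 65536 + low
      if (skip > 2^31) skip <- skip - 2^32
      t_samp <- t_samp + skip + tfield
      next
    }
    if (code == ANN_AUX) {
      nbytes <- tfield
      aux_raw <- raw[seq.int(i, length.out = nbytes)]
      i <- i + nbytes + (nbytes %% 2L)  # aux padded to even length
      aux <- rawToChar(aux_raw[aux_raw != as.raw(0)])
      changes[[length(changes) + 1L]] <-
        list(time_s = t_samp / fs, label = aux)
      next
    }
    if (code %in% c(60L, 61L, 62L)) next  # num/sub/chan modifiers
    t_samp <- t_samp + tfield
    last_time <- t_samp / fs
  }
  if (length(changes) == 0) {
    warning("no rhythm labels found in ", path)
    return(rhythm_annotation(
      data.frame(start_s = numeric(0), end_s = numeric(0),
                 rhythm = character(0)), record_id))
  }
  starts <- vapply(changes, `[[`, numeric(1), "time_s")
  labels <- vapply(changes, `[[`, character(1), "label")
  ord <- order(starts)
  starts <- starts[ord]; labels <- labels[ord]
  if (is.null(record_end_s)) record_end_s <- max(last_time, max(starts) + 1)
  ends <- c(starts[-1], record_end_s)
  keep <- ends > starts
  mapped <- ifelse(labels == "(AFIB", "AFIB",
                   ifelse(labels == "(N", "N", "OTHER"))
  rhythm_annotation(
    data.frame(start_s = starts[keep], end_s = ends[keep],
               rhythm = mapped[keep], stringsAsFactors = FALSE),
    record_id)
}

#' Write rhythm annotations in the MIT annotation format
#'
#' Emits one rhythm-change annotation (with its `(AFIB` / `(N` / label aux
#' string) at the start of each interval. Inverse of
#' [read_rhythm_annotations()] on this package's fixtures.
#'
#' @param ann A [rhythm_annotation()].
#' @param path Output path.
#' @param fs Sampling rate used to convert seconds to sample indices.
#' @return `path`, invisibly.
#' @export
write_rhythm_annotations <- function(ann, path, fs = 250) {
  stopifnot(inherits(ann, "rhythm_annotation"))
  out <- raw(0)
  word <- function(code, tfield) {
    as.raw(c(tfield %% 256L, (tfield %/% 256L) + 4L * code))
  }
  t_prev <- 0L
  for (k in seq_len(nrow(ann$intervals))) {
    samp <- as.integer(round(ann$intervals$start_s[k] * fs))
    delta <- samp - t_prev
    if (delta > 1023L || delta < 0L) {
      out <- c(out, word(ANN_SKIP, 0L),
               as.raw(c((delta %/% 65536L) %% 256L, delta %/% 16777216L,
                        delta %% 256L, (delta %/% 256L) %% 256L)))
      delta <- 0L
    }
    out <- c(out, word(ANN_RHYTHM, delta))
    lab <- ann$intervals$rhythm[k]
    aux <- switch(lab, AFIB = "(AFIB", N = "(N", paste0("(", lab))
    aux_b <- charToRaw(aux)
    nb <- length(aux_b)
    out <- c(out, word(ANN_AUX, nb), aux_b,
             if (nb %% 2L == 1L) as.raw(0L) else raw(0))
    t_prev <- samp
  }
  out <- c(out, as.raw(c(0L, 0L)))
  writeBin(out, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Device packet codec: 2 bytes per interval

PACKET_MAGIC <- charToRaw("AFPK")

#' Encode one window of RR intervals as a device packet
#'
#' Each interval is rounded to integer milliseconds and stored as an
#' unsigned 16-bit little-endian value, so the payload is exactly
#' `2 * n_intervals` bytes — the compact representation that lets a 2-minute
#' window travel in a few hundred bytes instead of a full ECG strip.
#'
#' @param intervals_ms Numeric RR intervals (ms), each in `[0, 65535]`.
#' @param record_id Record label (hashed into the packet header).
#' @param window_start_s Window start time (s).
#' @return A list of class `af_packet` with `record_id`, `window_start_s`,
#'   `n_intervals` and `payload` (raw).
#' @export
encode_packet <- function(intervals_ms, record_id = "unnamed",
                          window_start_s = 0) {
  v <- as.integer(round(intervals_ms))
  if (any(v < 0L | v > 65535L)) {
    stop("interval out of encodable range [0, 65535] ms")
  }
  payload <- as.raw(rbind(v %% 256L, v %/% 256L))
  structure(list(record_id = record_id,
                 window_start_s = window_start_s,
                 n_intervals = length(v), payload = payload),
            class = "af_packet")
}

#' Decode a device packet back to integer-millisecond RR intervals
#'
#' Exact inverse of [encode_packet()] on integer-ms inputs.
#'
#' @param packet An `af_packet`.
#' @return Integer vector of RR intervals (ms).
#' @export
decode_packet <- function(packet) {
  stopifnot(inherits(packet, "af_packet"))
  b <- as.integer(packet$payload)
  if (length(b) != 2L * packet$n_intervals) {
    stop("payload length ", length(b), " does not match n_intervals ",
         packet$n_intervals)
  }
  if (length(b) == 0) return(integer(0))
  b[seq(1, length(b), by = 2)] + 256L * b[seq(2, length(b), by = 2)]
}

#' @export
print.af_packet <- function(x, ...) {
  cat(sprintf("af_packet '%s' @ %gs: %d intervals, %d payload bytes\n",
              x$record_id, x$window_start_s, x$n_intervals,
              length(x$payload)))
  invisible(x)
}

#' Write/read a packet to a binary file with a 16-byte header
#'
#' Header layout: 4-byte magic `AFPK`, 4-byte record-id hash, 4-byte window
#' start (integer seconds, little-endian), 2-byte interval count, 2 reserved
#' bytes; then the payload.
#'
#' @param packet An `af_packet`.
#' @param path File path.
#' @return [write_packet()] returns `path` invisibly; [read_packet()]
#'   returns an `af_packet` (with the original `record_id` replaced by its
#'   hash rendering).
#' @export
write_packet <- function(packet, path) {
  stopifnot(inherits(packet, "af_packet"))
  h <- record_hash32(packet$record_id)
  ws <- as.integer(round(packet$window_start_s))
  n <- packet$n_intervals
  header <- c(PACKET_MAGIC,
              as.raw(c(h %% 256, (h %/% 256) %% 256,
                       (h %/% 65536) %% 256, (h %/% 16777216) %% 256)),
              as.raw(c(ws %% 256L, (ws %/% 256L) %% 256L,
                       (ws %/% 65536L) %% 256L, (ws %/% 16777216L) %% 256L)),
              as.raw(c(n %% 256L, n %/% 256L)), as.raw(c(0L, 0L)))
  writeBin(c(header, packet$payload), path)
  invisible(path)
}

#' @rdname write_packet
#' @export
read_packet <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 16 || !identical(raw[1:4], PACKET_MAGIC)) {
    stop("not a packet file (bad magic): ", path)
  }
  b <- as.integer(raw)
  h <- b[5] + 256 * b[6] + 65536 * b[7] + 16777216 * b[8]
  ws <- b[9] + 256L * b[10] + 65536L * b[11] + 16777216L * b[12]
  n <- b[13] + 256L * b[14]
  payload <- raw[seq.int(17, length.out = 2L * n)]
  structure(list(record_id = sprintf("rec#%08x", as.integer(h %% 2^31)),
                 window_start_s = ws, n_intervals = n, payload = payload),
            class = "af_packet")
}

record_hash32 <- function(id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 4294967296
  h
}
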