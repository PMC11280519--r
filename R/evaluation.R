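#' Label analysis windows with ground truth
#'
#' A window's truth is `"AF"` when the summed overlap of `AFIB` annotation
#' tracts with the window is at least `af_fraction_threshold` of the window
#' duration (default half), and `"nonAF"` otherwise; `OTHER` rhythms count
#' as nonAF. Windows not fully covered by the annotation are labeled from
#' the covered portion only, with a warning.
#'
#' @param windows List of windows from [segment_windows()], or a numeric
#'   vector of window start times (then `duration_s` applies).
#' @param annotation A [rhythm_annotation()].
#' @param af_fraction_threshold Fraction of the window that must be AFIB.
#' @param duration_s Window duration when `windows` is a numeric vector.
#' @return Character vector of `"AF"` / `"nonAF"`, one per window.
#' @export
label_windows <- function(windows, annotation, af_fraction_threshold = 0.5,
                          duration_s = 120) {
  stopifnot(inherits(annotation, "rhythm_annotation"))
  if (is.numeric(windows)) {
    windows <- lapply(windows, function(s) {
      list(start = s, duration = duration_s)
    })
  }
  iv <- annotation$intervals
  gap_warned <- FALSE
  out <- vapply(windows, function(w) {
    w0 <- w$start; w1 <- w$start + w$duration
    ov <- pmax(0, pmin(iv$end_s, w1) - pmax(iv$start_s, w0))
    covered <- sum(ov)
    if (covered < w$duration - 1e-9 && !gap_warned) {
      gap_warned <<- TRUE
      warning("annotation does not fully cover all windows of record '",
              annotation$record_id, "'; labeling by covered portion")
    }
    af_ov <- sum(ov[iv$rhythm == "AFIB"])
    if (af_ov >= af_fraction_threshold * w$duration) "AF" else "nonAF"
  }, character(1))
  out
}

#' Tally a 2x2 confusion table (AF = positive class)
#'
#' @param predictions Character vector of detector verdicts (`"AF"`,
#'   `"NSR"`, `"undetermined"`); undetermined windows are excluded together
#'   with their truths.
#' @param truths Character vector of `"AF"` / `"nonAF"` of the same length.
#' @return A list of class `confusion_counts` with integers `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths differ in length (",
         length(predictions), " vs ", length(truths), ")")
  }
  keep <- predictions != "undetermined"
  p <- predictions[keep] == "AF"
  t <- truths[keep] == "AF"
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  TN %d  FP %d  FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN); sensitivity = TP/(TP+FN);
#' specificity = TN/(TN+FP). A metric with a zero denominator is undefined
#' and returned as `NA` (rendered `"//"` in reports).
#'
#' @param counts A [confusion()] result.
#' @return A one-row data frame with `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
af_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  data.frame(
    tp = counts$tp, tn = counts$tn, fp = counts$fp, fn = counts$fn,
    accuracy = if (tot > 0) (counts$tp + counts$tn) / tot else NA_real_,
    sensitivity = if (counts$tp + counts$fn > 0)
      counts$tp / (counts$tp + counts$fn) else NA_real_,
    specificity = if (counts$tn + counts$fp > 0)
      counts$tn / (counts$tn + counts$fp) else NA_real_
  )
}

#' Evaluate the detector over a set of annotated records
#'
#' Runs [detect_rr()] on each record, labels its windows from the matching
#' annotation, and reports per-record metrics plus a pooled row computed
#' from the summed confusion counts across records (not from averaging
#' per-record metrics). Records named in `exclude` are dropped from the
#' roster before evaluation; records without an annotation are skipped with
#' a warning.
#'
#' @param records Named list: each element is a list with `rr` (an
#'   [rr_series()]) and `annotation` (a [rhythm_annotation()]).
#' @param config A [detector_config()].
#' @param af_fraction_threshold Window-truth overlap rule (see
#'   [label_windows()]).
#' @param exclude Character vector of record ids to drop.
#' @return A data frame of class `metrics_report`: one row per record plus a
#'   final `record == "pooled"` row.
#' @export
run_benchmark <- function(records, config = detector_config(),
                          af_fraction_threshold = 0.5, exclude = character(0)) {
  rows <- list()
  pooled <- list(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (id in names(records)) {
    if (id %in% exclude) next
    rec <- records[[id]]
    if (is.null(rec$annotation)) {
      warning("record '", id, "' has no annotation; skipped")
      next
    }
    det <- detect_rr(rec$rr, config)
    wins <- segment_windows(rec$rr, config$window_s)
    truths <- label_windows(wins, rec$annotation, af_fraction_threshold)
    cc <- confusion(det$verdict, truths)
    m <- af_metrics(cc)
    m <- cbind(record = id, m, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- m
    for (f in c("tp", "tn", "fp", "fn")) pooled[[f]] <- pooled[[f]] + cc[[f]]
  }
  per <- do.call(rbind, rows)
  pooled_row <- cbind(record = "pooled",
                      af_metrics(structure(pooled,
                                           class = "confusion_counts")),
                      stringsAsFactors = FALSE)
  out <- rbind(per, pooled_row)
  rownames(out) <- NULL
  class(out) <- c("metrics_report", class(out))
  out
}

#' Format a metrics report as an aligned text table
#'
#' Columns Patient / Accuracy / Sensitivity / Specificity, with undefined
#' metrics rendered `"//"`, mirroring the conventional per-patient results
#' table for this detector.
#'
#' @param report A [run_benchmark()] result (or any data frame with
#'   `record`, `accuracy`, `sensitivity`, `specificity`).
#' @param digits Number of decimal places.
#' @return Character vector of lines.
#' @export
format_metrics_table <- function(report, digits = 3) {
  fmt <- function(x) {
    ifelse(is.na(x), "//", formatC(x, digits = digits, format = "f"))
  }
  body <- sprintf("%-8s %11s %11s %11s", report$record,
                  fmt(report$accuracy), fmt(report$sensitivity),
                  fmt(report$specificity))
  c(sprintf("%-8s %11s %11s %11s", "Patient", "Accuracy", "Sensitivity",
            "Specificity"), body)
}

#' The 23-record MIT-BIH atrial fibrillation roster
#'
#' Record names of the public AF database; the detector's published
#' evaluation drops record 07859 (atypically regular AF), leaving 22.
#'
#' @param exclude Records to drop (default `"07859"`).
#' @return Character vector of record names.
#' @export
afdb_roster <- function(exclude = "07859") {
  roster <- c("04015", "04043", "04048", "04126", "04746", "04908",
              "04936", "05091", "05121", "05261", "06426", "06453",
              "06995", "07162", "07859", "07879", "07910", "08215",
              "08219", "08378", "08405", "08434", "08455")
  setdiff(roster, exclude)
}
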