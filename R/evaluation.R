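#' Signal-to-noise ratio of a record given useful intervals
#'
#' `SNR = 10 * log10(Ps / Pn)` where `Ps` is the mean square of the samples
#' inside the useful intervals and `Pn` the mean square of everything else.
#' With coarse bursts present the useless portion carries far more power
#' than the ECG and the SNR is strongly negative.
#'
#' @param series A [cecg_ts].
#' @param useful Data frame with `start`, `end` (0-based half-open sample
#'   ranges) marking the useful portions, or a [cecg_annotation] whose
#'   `"useful"` intervals are used.
#' @return SNR in decibels, or `NaN` with a warning when either class is
#'   empty or the useless power is zero.
#' @export
snr <- function(series, useful) {
  stopifnot(inherits(series, "cecg_ts"))
  if (inherits(useful, "cecg_annotation")) {
    useful <- useful$intervals[useful$intervals$label == "useful", ,
      drop = FALSE
    ]
  }
  N <- length(series)
  in_useful <- rep(FALSE, N)
  for (i in seq_len(nrow(useful))) {
    s <- max(0L, useful$start[i])
    e <- min(N, useful$end[i])
    if (e > s) in_useful[(s + 1L):e] <- TRUE
  }
  if (!any(in_useful) || all(in_useful)) {
    warning("SNR undefined: one of the classes is empty", call. = FALSE)
    return(NaN)
  }
  ps <- mean(series$samples[in_useful]^2)
  pn <- mean(series$samples[!in_useful]^2)
  if (pn == 0) {
    warning("SNR undefined: zero useless power", call. = FALSE)
    return(NaN)
  }
  10 * log10(ps / pn)
}

#' Segment-level confusion counts for artifact reduction
#'
#' A segment's true label is *useful* iff it contains at least one
#' ground-truth R peak (the operational definition: useful means R peaks can
#' be read there).  Counted against the keep/eliminate decisions:
#' TP = kept and useful, TN = eliminated and useless, FP = kept and useless,
#' FN = eliminated and useful.
#'
#' @param decisions Logical vector (`TRUE` = kept), one per forward segment,
#'   or a `reduction_result`.
#' @param truth A [cecg_annotation] (ground truth or expert annotation).
#' @param grid The matching [make_segment_grid()] grid (taken from the
#'   `reduction_result` when one is passed).
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
segment_confusion <- function(decisions, truth, grid = NULL) {
  if (inherits(decisions, "reduction_result")) {
    grid <- decisions$grid
    decisions <- decisions$decisions
  }
  stopifnot(inherits(grid, "segment_grid"), inherits(truth, "cecg_annotation"))
  n <- grid$n_forward
  if (length(decisions) != n) {
    stop("decisions are not aligned to the segment grid", call. = FALSE)
  }
  useful <- segment_has_peak(truth$r_peaks, grid)
  counts <- list(
    TP = sum(decisions & useful),
    FP = sum(decisions & !useful),
    TN = sum(!decisions & !useful),
    FN = sum(!decisions & useful)
  )
  structure(counts, class = "confusion_counts")
}

segment_has_peak <- function(r_peaks, grid) {
  SL <- grid$SL_samples
  n <- grid$n_forward
  has <- rep(FALSE, n)
  seg_of <- r_peaks %/% SL
  seg_of <- seg_of[seg_of < n]
  has[seg_of + 1L] <- TRUE
  has
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN
  ))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity and the two predictive values, each as
#' a percentage.  A metric whose denominator is zero is undefined and
#' reported as `NaN`, never silently as 0.
#'
#' @param counts A [segment_confusion()] result or a list/vector with
#'   `TP`, `FP`, `TN`, `FN`.
#' @return List of class `metric_set`: `accuracy`, `sensitivity`,
#'   `specificity`, `positive_prediction`, `negative_prediction` (percent).
#' @export
classification_metrics <- function(counts) {
  cnt <- as.list(counts)[c("TP", "FP", "TN", "FN")]
  if (any(vapply(cnt, is.null, logical(1)))) {
    stop("counts must provide TP, FP, TN, FN", call. = FALSE)
  }
  cnt <- lapply(cnt, as.numeric)
  if (any(unlist(cnt) < 0)) stop("counts must be non-negative", call. = FALSE)
  rate <- function(num, den) if (den == 0) NaN else 100 * num / den
  with(cnt, structure(
    list(
      accuracy = rate(TP + TN, TP + FP + FN + TN),
      sensitivity = rate(TP, TP + FN),
      specificity = rate(TN, FP + TN),
      positive_prediction = rate(TP, TP + FP),
      negative_prediction = rate(TN, TN + FN)
    ),
    class = "metric_set"
  ))
}

#' @export
print.metric_set <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-20s %6.2f %%\n", nm, x[[nm]]))
  invisible(x)
}

#' Percentage of R peaks preserved by a reduction
#'
#' @param decisions Logical keep flags per forward segment, or a
#'   `reduction_result`.
#' @param r_peaks 0-based R-peak sample indices.
#' @param grid The matching segment grid (from the result when given).
#' @return List with `preserved` and `lost` percentages; `NaN` with a
#'   warning when there are no R peaks.  Peaks beyond the last full segment
#'   are counted as preserved (that tail is never eliminated).
#' @export
r_peak_retention <- function(decisions, r_peaks, grid = NULL) {
  if (inherits(decisions, "reduction_result")) {
    grid <- decisions$grid
    decisions <- decisions$decisions
  }
  stopifnot(inherits(grid, "segment_grid"))
  if (length(r_peaks) == 0L) {
    warning("no R peaks: retention undefined", call. = FALSE)
    return(list(preserved = NaN, lost = NaN))
  }
  seg_of <- r_peaks %/% grid$SL_samples
  kept <- ifelse(seg_of < grid$n_forward, decisions[seg_of + 1L], TRUE)
  preserved <- 100 * sum(kept) / length(kept)
  list(preserved = preserved, lost = 100 - preserved)
}

#' Beat-to-beat heart rate and pNN50 from R-peak indices
#'
#' `RR_i = (peak_{i+1} - peak_i) / fs`, `HR_i = 60 / RR_i`.  pNN50 is the
#' percentage of successive RR-interval differences whose absolute value
#' exceeds 50 ms (the standard HRV definition); `pnn50_loose` additionally
#' reports the percentage of RR intervals themselves exceeding 50 ms, a
#' looser reading sometimes seen in applied work.  When an `index_map` from
#' [extract_clean()] is supplied (peaks given as cleaned-series indices),
#' RR intervals spanning an elimination gap are excluded.
#'
#' @param r_peaks 0-based R-peak sample indices (at least 2; at least 3 for
#'   pNN50).
#' @param fs Sampling rate in Hz.
#' @param index_map Optional 0-based map from cleaned to original sample
#'   indices.
#' @return List with `rr_s` (RR intervals, s), `hr_bpm` (one per interval),
#'   `pnn50`, `pnn50_loose` (percent).
#' @export
rr_features <- function(r_peaks, fs, index_map = NULL) {
  r_peaks <- as.numeric(r_peaks)
  if (length(r_peaks) < 2L) {
    stop("at least 2 R peaks are needed for heart rate", call. = FALSE)
  }
  if (!is.null(index_map)) {
    # translate to original indices; an interval whose span in the original
    # series exceeds its span in the cleaned one crosses an eliminated gap
    orig <- index_map[r_peaks + 1L]
    rr_clean <- diff(r_peaks)
    rr_orig <- diff(orig)
    valid <- rr_orig == rr_clean
    rr <- diff(orig)[valid] / fs
  } else {
    rr <- diff(r_peaks) / fs
  }
  if (length(rr) < 1L) {
    stop("no valid RR intervals (all span elimination gaps)", call. = FALSE)
  }
  hr <- 60 / rr
  pnn50 <- if (length(rr) >= 2L) {
    100 * mean(abs(diff(rr)) > 0.050)
  } else {
    NaN
  }
  list(
    rr_s = rr, hr_bpm = hr,
    pnn50 = pnn50,
    pnn50_loose = 100 * mean(rr > 0.050)
  )
}

#' Spectral power split across frequency bands
#'
#' Periodogram-based fractions of total power per requested band,
#' normalized so the fractions over the requested bands sum to 100%.
#'
#' @param series A [cecg_ts] or numeric vector plus `fs`.
#' @param bands List of two-element Hz ranges, e.g.
#'   `list(c(0, 5), c(5, 15), c(15, 50))`; treated as half-open `[lo, hi)`
#'   except the last band, which includes its upper edge.
#' @param fs Sampling rate when `series` is a bare vector.
#' @return Numeric vector of percentages, one per band.
#' @export
band_power_fractions <- function(series, bands, fs = NULL) {
  if (inherits(series, "cecg_ts")) {
    x <- series$samples
    fs <- series$fs
  } else {
    x <- as.numeric(series)
    if (is.null(fs)) stop("'fs' required for a bare vector", call. = FALSE)
  }
  hi <- max(vapply(bands, function(b) b[2], numeric(1)))
  if (hi > fs / 2 + 1e-9) {
    stop("band exceeds the Nyquist frequency", call. = FALSE)
  }
  lo <- min(vapply(bands, function(b) b[1], numeric(1)))
  if (lo > 0 && length(x) < 2 * fs / lo) {
    stop("series shorter than 2 periods of the lowest band edge",
      call. = FALSE
    )
  }
  pg <- stats::spec.pgram(stats::ts(x, frequency = fs),
    taper = 0, detrend = FALSE, plot = FALSE
  )
  power <- numeric(length(bands))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    inb <- pg$freq >= b[1] &
      (if (i == length(bands)) pg$freq <= b[2] else pg$freq < b[2])
    power[i] <- sum(pg$spec[inb])
  }
  if (sum(power) == 0) {
    warning("no spectral power inside the requested bands", call. = FALSE)
    return(rep(NaN, length(bands)))
  }
  100 * power / sum(power)
}
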