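#' Test for the presence of coarse artifacts
#'
#' Coarse (movement) artifacts show up as sparse, very-high-amplitude
#' excursions.  The criterion compares the half-range of the signal with the
#' root of its uncentralized second moment: sparse large spikes inflate the
#' range while barely moving the overall power, so the difference
#' `(max(x) - min(x))/2 - sqrt(M)` with `M = mean(x^2)` exceeds 1 (volt)
#' only when such spikes are present.  Dense, equal-magnitude swings (a
#' square wave, say) raise both terms alike and do not trigger it.
#'
#' @param series A [cecg_ts] with amplitudes in volts.
#' @return List with `flag` (`TRUE` when the statistic exceeds 1, strictly)
#'   and `statistic` (volts).
#' @export
coarse_artifact_present <- function(series) {
  stopifnot(inherits(series, "cecg_ts"))
  x <- series$samples
  M <- mean(x^2)
  statistic <- (max(x) - min(x)) / 2 - sqrt(M)
  list(flag = statistic > 1, statistic = statistic)
}

#' Data-driven artifact thresholds
#'
#' Derives the three decision thresholds from the statistics of the signal
#' and of its per-segment fluctuation values:
#' \deqn{TH1 = (((\max x - \min x)/2)^2 - M)\, C\, \mathrm{median}(F_D)
#'       + \frac{SD(F_D) + SD(x)}{SD(F_D)\, SD(x)}\, C_1,}
#' `TH2 = TH1/2` (spill-over into neighbouring segments) and `TH3 = 0.1`
#' (slow-changing artifacts; the fluctuation of a segment deviating from its
#' trend by at most 0.1 at every sample).  `M` is the uncentralized second
#' moment `mean(x^2)` in V^2; `C` (units 1/V^2) is an empirical constant with
#' best-performing range 0.15–0.35, and `C1` = 1 V makes the second term
#' dimensionless in the same way.  Standard deviations use the unbiased
#' (n-1) form.
#'
#' @param series A [cecg_ts].
#' @param profile A [fluctuation_series()] result, or a bare numeric vector
#'   of per-segment fluctuation values.
#' @param C Empirical scale constant (1/V^2), default 0.25.
#' @param C1 Dimensional constant, default 1 (V).
#' @return An object of class `threshold_set`: `TH1`, `TH2`, `TH3`, the
#'   constants, and the signal/fluctuation statistics they derive from.
#' @export
compute_thresholds <- function(series, profile, C = 0.25, C1 = 1) {
  stopifnot(inherits(series, "cecg_ts"))
  fd <- if (inherits(profile, "fluctuation_profile")) profile$values else as.numeric(profile)
  if (length(fd) < 1L) stop("empty fluctuation profile", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("'C' must be a positive scalar", call. = FALSE)
  }
  x <- series$samples
  x_max <- max(x)
  x_min <- min(x)
  M <- mean(x^2)
  sd_x <- stats::sd(x)
  sd_fd <- stats::sd(fd)
  if (length(fd) < 2L || !is.finite(sd_fd)) sd_fd <- 0
  if (sd_x == 0 || sd_fd == 0) {
    stop(structure(
      class = c("cecg_degenerate_error", "error", "condition"),
      list(
        message = paste(
          "degenerate signal: zero variance in the samples or the",
          "fluctuation values; artifact reduction should be skipped"
        ),
        call = NULL
      )
    ))
  }
  med_fd <- stats::median(fd)
  TH1 <- (((x_max - x_min) / 2)^2 - M) * C * med_fd +
    (sd_fd + sd_x) / (sd_fd * sd_x) * C1
  structure(
    list(
      TH1 = TH1, TH2 = TH1 / 2, TH3 = 0.1,
      C = C, C1 = C1,
      x_max = x_max, x_min = x_min, M = M, rms = sqrt(M),
      median_FD = med_fd, sd_FD = sd_fd, sd_x = sd_x, mean_FD = mean(fd)
    ),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> TH1=%.4g TH2=%.4g TH3=%.2g (C=%g, C1=%g)\n",
    x$TH1, x$TH2, x$TH3, x$C, x$C1
  ))
  invisible(x)
}

#' Constant threshold for slow-changing artifacts
#'
#' The RMS fluctuation of a segment whose deviation from its linear trend is
#' at most 0.1 at every sample; segments at or below it carry no usable ECG.
#' @export
TH3_SLOW <- 0.1

#' Segment-wise artifact reduction
#'
#' Full reduction pipeline for a record: segment the cumulative-sum profile,
#' compute the per-segment fluctuation `F_D`, derive the data-driven
#' thresholds, and eliminate artifact segments:
#' \enumerate{
#'   \item When [coarse_artifact_present()] fires, every segment with
#'     `F_D > TH1` is eliminated (reason `"coarse"`); each immediate
#'     neighbour of a coarse segment is additionally eliminated when the
#'     adjacency rule fires (reason `"adjacent"`, single hop — adjacency
#'     does not propagate; see the `adjacency` argument for the two
#'     variants of the rule).
#'   \item Independently, when `mean(F_D) - SD(F_D) > TH3`, every still-kept
#'     segment with `F_D <= TH3` is eliminated (reason `"slow"`).  The guard
#'     protects low-amplitude records, where legitimate ECG fluctuation is
#'     itself small, from wholesale elimination.
#' }
#' Decisions are made on the forward segment grid, which tiles the series;
#' when the grid mode resolves to bidirectional (short series) the
#' end-aligned segments contribute to the fluctuation statistics behind the
#' thresholds but carry no decisions of their own.  Samples after the last
#' full segment are never classified and are carried into the cleaned
#' output.
#'
#' On a degenerate record (zero variance) the thresholds are undefined; the
#' result keeps every segment and sets `degenerate = TRUE`, with a warning.
#'
#' @param series A [cecg_ts].
#' @param SL_seconds Segment length in seconds (default 0.5).
#' @param C Threshold constant, see [compute_thresholds()].
#' @param form Fluctuation form, see [fluctuation_value()].
#' @param grid_mode Segment grid mode, see [make_segment_grid()].
#' @param adjacency `"difference"` (default, the rule of the elimination
#'   pseudocode): the neighbour of a coarse segment is eliminated when the
#'   coarse segment's `F_D` exceeds the neighbour's by more than `TH2` —
#'   which catches low-fluctuation slivers of a burst spilling into the
#'   next segment.  `"own"`: prose variant that instead requires the
#'   neighbour's own `F_D` to exceed `TH2`.
#' @param C1 Dimensional constant (V), default 1.
#' @return An object of class `reduction_result`: `grid`, `fd` (forward
#'   segment fluctuations), `decisions` (logical, `TRUE` = kept), `reasons`
#'   (`"kept"`, `"coarse"`, `"adjacent"`, `"slow"`), `thresholds`,
#'   `coarse_present`, `statistic`, `cleaned` ([cecg_ts]), `index_map`
#'   (0-based original index of every cleaned sample), `mask` (data frame
#'   `segment,start,end,kept,reason`, 0-based half-open) and `degenerate`.
#' @examples
#' rec <- generate_cecg(synthetic_config(duration = 120, seed = 1))
#' res <- reduce_artifacts(rec$series)
#' table(res$reasons)
#' @export
reduce_artifacts <- function(series, SL_seconds = 0.5, C = 0.25,
                             form = c("rms", "mean_square"),
                             grid_mode = c("auto", "forward", "bidirectional"),
                             adjacency = c("difference", "own"),
                             C1 = 1) {
  form <- match.arg(form)
  grid_mode <- match.arg(grid_mode)
  adjacency <- match.arg(adjacency)
  stopifnot(inherits(series, "cecg_ts"))
  N <- length(series)
  SL <- as.integer(round(SL_seconds * series$fs))
  if (N %/% SL < 2L) {
    stop("series must span at least 2 segments at the given segment length",
      call. = FALSE
    )
  }
  grid <- make_segment_grid(N, SL, mode = grid_mode, fs = series$fs)
  fp <- fluctuation_series(series, grid, form = form)
  fd <- fp$values[seq_len(grid$n_forward)] # decisions on the tiling grid

  th <- tryCatch(compute_thresholds(series, fp, C = C, C1 = C1),
    cecg_degenerate_error = function(e) e
  )
  cp <- coarse_artifact_present(series)
  n <- grid$n_forward
  reasons <- rep("kept", n)

  degenerate <- inherits(th, "cecg_degenerate_error")
  if (degenerate) {
    warning("degenerate signal: thresholds undefined, keeping all segments",
      call. = FALSE
    )
    th <- NULL
  } else {
    if (cp$flag) {
      coarse <- fd > th$TH1
      reasons[coarse] <- "coarse"
      for (j in which(coarse)) {
        for (nb in c(j - 1L, j + 1L)) {
          if (nb >= 1L && nb <= n && reasons[nb] == "kept") {
            hit <- switch(adjacency,
              own = fd[nb] > th$TH2,
              difference = (fd[j] - fd[nb]) > th$TH2
            )
            if (hit) reasons[nb] <- "adjacent"
          }
        }
      }
    }
    if (th$mean_FD - th$sd_FD > th$TH3) {
      reasons[reasons == "kept" & fd <= th$TH3] <- "slow"
    }
  }

  decisions <- reasons == "kept"
  starts <- (seq_len(n) - 1L) * SL
  mask <- data.frame(
    segment = seq_len(n) - 1L,
    start = starts,
    end = starts + SL,
    kept = decisions,
    reason = reasons,
    fd = fd,
    stringsAsFactors = FALSE
  )
  ec <- extract_clean(series, decisions, grid)
  structure(
    list(
      grid = grid, fd = fd, decisions = decisions, reasons = reasons,
      thresholds = th, coarse_present = cp$flag, statistic = cp$statistic,
      cleaned = ec$cleaned, index_map = ec$index_map, mask = mask,
      degenerate = degenerate, form = form
    ),
    class = "reduction_result"
  )
}

#' @export
print.reduction_result <- function(x, ...) {
  tab <- table(factor(x$reasons, c("kept", "coarse", "adjacent", "slow")))
  cat(sprintf(
    "<reduction_result> %d/%d segments kept (coarse %d, adjacent %d, slow %d)%s\n",
    tab[["kept"]], length(x$reasons), tab[["coarse"]], tab[["adjacent"]],
    tab[["slow"]], if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Concatenate the kept segments of a record
#'
#' Builds the cleaned series from per-segment keep decisions, together with
#' an index map giving, for every cleaned sample, its 0-based index in the
#' original series — so that any beat interval spanning an elimination gap
#' can be recognised and discarded downstream.  Samples beyond the last full
#' segment (the unsegmented tail) are appended unchanged.
#'
#' @param series A [cecg_ts].
#' @param decisions Logical vector, one per forward segment, `TRUE` = kept.
#' @param grid The matching [make_segment_grid()] grid.
#' @return List with `cleaned` (a [cecg_ts]) and `index_map` (0-based
#'   integer vector, strictly increasing).
#' @export
extract_clean <- function(series, decisions, grid) {
  stopifnot(inherits(series, "cecg_ts"), inherits(grid, "segment_grid"))
  n <- grid$n_forward
  if (length(decisions) != n) {
    stop("'decisions' must have one entry per forward segment", call. = FALSE)
  }
  SL <- grid$SL_samples
  keep_idx <- unlist(lapply(which(decisions), function(j) {
    ((j - 1L) * SL):((j - 1L) * SL + SL - 1L)
  }), use.names = FALSE)
  tail_start <- n * SL
  if (tail_start < grid$N) keep_idx <- c(keep_idx, tail_start:(grid$N - 1L))
  keep_idx <- as.integer(keep_idx)
  samples <- series$samples[keep_idx + 1L]
  if (length(samples) == 0L) {
    cleaned <- NULL # an all-eliminated record has no valid series
  } else {
    cleaned <- cecg_ts(samples, fs = series$fs,
      id = paste0(series$id, "_clean"))
  }
  list(cleaned = cleaned, index_map = keep_idx)
}

#' Online (streaming) artifact reduction
#'
#' Streaming counterpart of [reduce_artifacts()].  The first `init_seconds`
#' of signal provide the initial fluctuation statistics and thresholds, and
#' the decisions for the segments inside that window are exactly the batch
#' decisions on the window.  Each subsequent full segment appends its
#' fluctuation value to the running collection; the running signal mean (and
#' hence the cumulative-sum profile), the signal statistics and all three
#' thresholds are then recomputed over everything seen so far, and the new
#' segment is classified with the current thresholds.  When a new segment is
#' eliminated as coarse, its already-emitted predecessor is retroactively
#' marked `"adjacent"` if the adjacency rule fires; old fluctuation values
#' are never discarded.
#'
#' @param chunks A single [cecg_ts] or a list of them (consecutive pieces of
#'   one stream at a common sampling rate).
#' @param init_seconds Initialization window in seconds (default 50).
#' @param SL_seconds,C,form,adjacency,C1 As in [reduce_artifacts()].
#' @return A data frame with one row per full segment: `segment`, `start`,
#'   `end` (0-based, half-open), `fd`, `kept`, `reason`, plus attributes
#'   `thresholds` (final [compute_thresholds()] result) and `init_segments`
#'   (number of segments decided by the batch initialization).
#' @export
reduce_online <- function(chunks, init_seconds = 50, SL_seconds = 0.5,
                          C = 0.25, form = c("rms", "mean_square"),
                          adjacency = c("difference", "own"), C1 = 1) {
  form <- match.arg(form)
  adjacency <- match.arg(adjacency)
  if (inherits(chunks, "cecg_ts")) chunks <- list(chunks)
  if (!length(chunks) || !all(vapply(chunks, inherits, logical(1), "cecg_ts"))) {
    stop("'chunks' must be a cecg_ts or a list of cecg_ts pieces",
      call. = FALSE
    )
  }
  fs <- chunks[[1L]]$fs
  if (!all(vapply(chunks, function(s) s$fs, numeric(1)) == fs)) {
    stop("all chunks must share one sampling rate", call. = FALSE)
  }
  x <- unlist(lapply(chunks, function(s) s$samples), use.names = FALSE)
  N <- length(x)
  SL <- as.integer(round(SL_seconds * fs))
  init_n <- as.integer(floor(init_seconds * fs))
  if (N < init_n) {
    stop(sprintf(
      "stream too short: %.1f s available, %.1f s needed for initialization",
      N / fs, init_seconds
    ), call. = FALSE)
  }
  n0 <- init_n %/% SL # segments fully inside the init window
  if (n0 < 2L) {
    stop("initialization window must span at least 2 segments", call. = FALSE)
  }

  prefix <- cecg_ts(x[seq_len(n0 * SL)], fs = fs, id = "online_init")
  batch <- reduce_artifacts(prefix,
    SL_seconds = SL_seconds, C = C, form = form,
    grid_mode = "forward", adjacency = adjacency, C1 = C1
  )
  fd_all <- batch$fd
  reasons <- batch$reasons
  th <- batch$thresholds

  n_total <- N %/% SL
  for (j in seq.int(n0 + 1L, length.out = max(0L, n_total - n0))) {
    seen <- x[seq_len(j * SL)]
    Y <- cumsum(seen - mean(seen)) # running mean updates the whole profile
    seg <- Y[((j - 1L) * SL + 1L):(j * SL)]
    fd_j <- fluctuation_value(detrend_segment(seg)$residuals, form)
    fd_all <- c(fd_all, fd_j)
    seen_ts <- cecg_ts(seen, fs = fs, id = "online_seen")
    th <- tryCatch(compute_thresholds(seen_ts, fd_all, C = C, C1 = C1),
      cecg_degenerate_error = function(e) NULL
    )
    reason <- "kept"
    if (!is.null(th)) {
      cp <- coarse_artifact_present(seen_ts)
      if (cp$flag && fd_j > th$TH1) {
        reason <- "coarse"
        prev <- j - 1L
        if (reasons[prev] == "kept") {
          hit <- switch(adjacency,
            own = fd_all[prev] > th$TH2,
            difference = (fd_j - fd_all[prev]) > th$TH2
          )
          if (hit) reasons[prev] <- "adjacent"
        }
      } else if (cp$flag && reasons[j - 1L] == "coarse") {
        hit <- switch(adjacency,
          own = fd_j > th$TH2,
          difference = (fd_all[j - 1L] - fd_j) > th$TH2
        )
        if (hit) reason <- "adjacent"
      }
      if (reason == "kept" && th$mean_FD - th$sd_FD > th$TH3 &&
        fd_j <= th$TH3) {
        reason <- "slow"
      }
    }
    reasons <- c(reasons[seq_len(j - 1L)], reason)
  }

  starts <- (seq_len(n_total) - 1L) * SL
  out <- data.frame(
    segment = seq_len(n_total) - 1L,
    start = starts,
    end = starts + SL,
    fd = fd_all[seq_len(n_total)],
    kept = reasons == "kept",
    reason = reasons,
    stringsAsFactors = FALSE
  )
  attr(out, "thresholds") <- th
  attr(out, "init_segments") <- n0
  out
}
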