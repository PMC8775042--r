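#' Cumulative-sum profile of a time series
#'
#' First step of the detrended-fluctuation computation: the running sum of
#' mean-centred samples, `Y(i) = sum_{k<=i} (x_k - mean(x))`.  The last
#' element is zero up to rounding because the centred samples telescope.
#'
#' @param series A [cecg_ts] (or bare numeric vector).
#' @return Numeric vector of length `N` with the profile values.
#' @export
compute_profile <- function(series) {
  x <- if (inherits(series, "cecg_ts")) series$samples else as.numeric(series)
  if (length(x) < 1L) stop("empty series", call. = FALSE)
  cumsum(x - mean(x))
}

#' Build a non-overlapping segment grid
#'
#' Divides `N` samples into consecutive segments of `SL_samples` each.  In
#' `forward` mode the grid starts at the beginning of the series and the
#' trailing remainder (fewer than `SL_samples` samples) is dropped.  In
#' `bidirectional` mode — used for short series, where dropping the remainder
#' would cost reliability — the segmentation is repeated from the end of the
#' series, doubling the number of segments; the two passes coincide when
#' `SL_samples` divides `N` exactly, and the duplicates are retained.
#' `auto` selects `bidirectional` for series shorter than 10,000 samples and
#' `forward` otherwise.
#'
#' @param N Series length in samples.
#' @param SL_samples Segment length in samples (at least 2: a linear fit
#'   needs two points).
#' @param mode One of `"forward"`, `"bidirectional"`, `"auto"`.
#' @param fs Optional sampling rate, only used to record the segment length
#'   in seconds on the returned grid.
#' @return An object of class `segment_grid` with fields `SL_samples`,
#'   `SL_seconds`, `mode` (resolved), `offsets` (0-based segment starts) and
#'   `n_segments`.
#' @export
make_segment_grid <- function(N, SL_samples,
                              mode = c("auto", "forward", "bidirectional"),
                              fs = NULL) {
  mode <- match.arg(mode)
  N <- as.integer(N)
  SL_samples <- as.integer(SL_samples)
  if (SL_samples < 2L) {
    stop("'SL_samples' must be at least 2 (a linear fit needs two points)",
      call. = FALSE
    )
  }
  if (SL_samples > N) {
    stop("'SL_samples' exceeds the series length", call. = FALSE)
  }
  if (mode == "auto") mode <- if (N < 10000L) "bidirectional" else "forward"
  n_fwd <- N %/% SL_samples
  fwd <- (seq_len(n_fwd) - 1L) * SL_samples
  offsets <- fwd
  if (mode == "bidirectional") {
    bwd <- N - rev(seq_len(n_fwd)) * SL_samples
    offsets <- c(fwd, bwd)
  }
  structure(
    list(
      SL_samples = SL_samples,
      SL_seconds = if (is.null(fs)) NA_real_ else SL_samples / fs,
      mode = mode,
      offsets = as.integer(offsets),
      n_segments = length(offsets),
      n_forward = n_fwd,
      N = N
    ),
    class = "segment_grid"
  )
}

#' @export
print.segment_grid <- function(x, ...) {
  cat(sprintf(
    "<segment_grid> %d segments of %d samples (%s mode) over N=%d\n",
    x$n_segments, x$SL_samples, x$mode, x$N
  ))
  invisible(x)
}

#' Remove the least-squares linear trend from a segment
#'
#' Fits an ordinary least-squares line over within-segment positions
#' `1..SL` and subtracts it.  Residuals are invariant to any affine
#' reindexing of the positions, sum to zero, and are orthogonal to the
#' position vector.
#'
#' @param values Numeric vector of length at least 2.
#' @return List with `residuals`, `slope`, `intercept`.
#' @export
detrend_segment <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) {
    stop("a segment must have at least 2 samples to fit a line",
      call. = FALSE
    )
  }
  k <- seq_len(n)
  # closed-form simple OLS: avoids lm() overhead in the per-segment loop
  kbar <- (n + 1) / 2
  vbar <- mean(values)
  kc <- k - kbar
  slope <- sum(kc * values) / sum(kc * kc)
  intercept <- vbar - slope * kbar
  list(
    residuals = values - (intercept + slope * k),
    slope = slope,
    intercept = intercept
  )
}

#' Fluctuation of an already-detrended segment
#'
#' Reduces the residuals of one segment to the scalar fluctuation value:
#' the root mean square of the residuals (`form = "rms"`, the default) or
#' the unsquare-rooted mean of their squares (`form = "mean_square"`).
#' A segment whose squared residual is 0.01 at every sample has an RMS
#' fluctuation of exactly 0.1 regardless of segment length — the anchor for
#' the slow-artifact threshold `TH3`.
#'
#' @param detrended Numeric vector of residuals from a linear detrend.
#' @param form `"rms"` or `"mean_square"`.
#' @return Non-negative scalar.
#' @export
fluctuation_value <- function(detrended, form = c("rms", "mean_square")) {
  form <- match.arg(form)
  ms <- mean(as.numeric(detrended)^2)
  if (form == "rms") sqrt(ms) else ms
}

#' Per-segment detrended fluctuation of a series
#'
#' Computes the cumulative-sum profile of the series, cuts it on the segment
#' grid, removes a least-squares line from each profile segment and returns
#' one fluctuation value per segment.  High values flag segments whose
#' profile deviates strongly from a local line (coarse, high-amplitude
#' artifacts); values at or below 0.1 flag segments with almost no deviation
#' (slow-changing artifacts).
#'
#' @param series A [cecg_ts].
#' @param grid A [make_segment_grid()] grid consistent with the series
#'   length; by default a grid with `SL` = 0.5 s in `auto` mode.
#' @param form Fluctuation form, see [fluctuation_value()].
#' @return An object of class `fluctuation_profile`: list with `grid`,
#'   `values` (one per segment), `form` and `profile` (the cumulative-sum
#'   vector).
#' @examples
#' x <- cecg_ts(rnorm(4000), fs = 400)
#' fp <- fluctuation_series(x)
#' summary(fp$values)
#' @export
fluctuation_series <- function(series, grid = NULL,
                               form = c("rms", "mean_square")) {
  form <- match.arg(form)
  stopifnot(inherits(series, "cecg_ts"))
  N <- length(series)
  if (is.null(grid)) {
    grid <- make_segment_grid(N, round(0.5 * series$fs),
      mode = "auto", fs = series$fs
    )
  }
  if (!inherits(grid, "segment_grid") || grid$N != N) {
    stop("segment grid does not match the series length", call. = FALSE)
  }
  Y <- compute_profile(series)
  SL <- grid$SL_samples
  values <- vapply(grid$offsets, function(off) {
    seg <- Y[(off + 1L):(off + SL)]
    fluctuation_value(detrend_segment(seg)$residuals, form)
  }, numeric(1))
  structure(
    list(grid = grid, values = values, form = form, profile = Y),
    class = "fluctuation_profile"
  )
}

#' @export
print.fluctuation_profile <- function(x, ...) {
  cat(sprintf(
    "<fluctuation_profile> %d segments (SL=%d, %s form); F_D range [%.3g, %.3g]\n",
    x$grid$n_segments, x$grid$SL_samples, x$form,
    min(x$values), max(x$values)
  ))
  invisible(x)
}
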