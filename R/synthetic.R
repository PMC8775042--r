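#' Configuration for the synthetic cECG generator
#'
#' Captures the statistical structure the generator emulates: a
#' low-amplitude ECG (R peak of order 0.2–2 V), sparse coarse bursts of
#' several volts, and slow-changing disturbances whose power lies in the
#' 0.5–15 Hz band at amplitudes comparable to the ECG itself.
#'
#' @param fs Sampling rate in Hz (default 400).
#' @param duration Record duration in seconds (default 300).
#' @param hr_bpm Mean heart rate (default 70).
#' @param rr_jitter Relative standard deviation of beat-to-beat RR intervals
#'   (default 0.05).
#' @param ecg_amp R-peak amplitude in volts (default 0.5).
#' @param baseline_noise_sd White measurement-noise SD in volts (default 0.02).
#' @param coarse_count Number of coarse bursts (default 10); ignored when
#'   `protocol = "bed"`, where the movement schedule drives the bursts.
#' @param coarse_amp Burst peak-amplitude range in volts (default `c(2, 8)`).
#' @param coarse_duration Burst duration range in seconds (default `c(0.2, 2)`).
#' @param coarse_shapes Character vector of burst shapes to draw from:
#'   `"spike_train"` (dense biphasic spikes, the default — movement
#'   artifacts appear as bursts of large amplitude peaks), `"step"`
#'   (baseline jump) and/or `"clip"` (rail saturation).
#' @param slow_count Number of slow-changing artifact intervals (default 6).
#' @param slow_duration Slow-interval duration range in seconds
#'   (default `c(3, 8)`).
#' @param slow_band Frequency band of the slow disturbance in Hz
#'   (default `c(0.5, 15)`).
#' @param slow_amp_ratio RMS of the slow disturbance relative to the RMS of
#'   the clean ECG (default 1: comparable amplitude).
#' @param protocol `"none"` or `"bed"` (movement schedule of the lying
#'   protocol, see [protocol_schedule()]).
#' @param seed Integer seed; the same seed yields a bit-identical record.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(fs = 400, duration = 300, hr_bpm = 70,
                             rr_jitter = 0.05, ecg_amp = 0.5,
                             baseline_noise_sd = 0.02,
                             coarse_count = 10, coarse_amp = c(2, 8),
                             coarse_duration = c(0.2, 2),
                             coarse_shapes = "spike_train",
                             slow_count = 6, slow_duration = c(3, 8),
                             slow_band = c(0.5, 15), slow_amp_ratio = 1,
                             protocol = c("none", "bed"), seed = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(
    fs > 0, duration > 0, hr_bpm > 0, ecg_amp > 0,
    length(coarse_amp) == 2L, diff(coarse_amp) >= 0,
    length(coarse_duration) == 2L, diff(coarse_duration) >= 0,
    length(slow_duration) == 2L, diff(slow_duration) >= 0,
    length(slow_band) == 2L, slow_band[1] > 0, slow_band[2] > slow_band[1]
  )
  if (fs * duration < 2 * round(0.5 * fs)) {
    stop("record must span at least 2 segments at SL = 0.5 s", call. = FALSE)
  }
  structure(
    list(
      fs = fs, duration = duration, hr_bpm = hr_bpm, rr_jitter = rr_jitter,
      ecg_amp = ecg_amp, baseline_noise_sd = baseline_noise_sd,
      coarse_count = coarse_count, coarse_amp = coarse_amp,
      coarse_duration = coarse_duration, coarse_shapes = coarse_shapes,
      slow_count = slow_count, slow_duration = slow_duration,
      slow_band = slow_band, slow_amp_ratio = slow_amp_ratio,
      protocol = protocol, seed = seed
    ),
    class = "synthetic_config"
  )
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# P-QRS-T beat template sampled at fs, as a sum of Gaussian bumps centred on
# the R peak; normalized so the R peak has amplitude 1 at offset 0.
beat_template <- function(fs) {
  t <- seq(-0.35, 0.45, by = 1 / fs)
  bump <- function(a, mu, s) a * exp(-0.5 * ((t - mu) / s)^2)
  w <- bump(0.15, -0.20, 0.025) + # P
    bump(-0.12, -0.028, 0.010) + # Q
    bump(1.00, 0.000, 0.012) + # R
    bump(-0.18, 0.030, 0.011) + # S
    bump(0.30, 0.22, 0.050) # T
  list(values = w / max(w), r_offset = which.max(w) - 1L, t = t)
}

# Gaussian white noise spectrally confined to [band[1], band[2]] Hz via FFT
# masking, rescaled to unit RMS.
bandlimited_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freq <- (seq_len(n) - 1L) * fs / n
  alias <- fs - freq # negative-frequency half of the spectrum
  keep <- (freq >= band[1] & freq <= band[2]) |
    (alias >= band[1] & alias <= band[2])
  W[!keep] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r == 0) stop("degenerate band: no spectral lines inside it", call. = FALSE)
  x / r
}

# Draw `count` non-overlapping [start, end) intervals (samples, 0-based)
# with durations from dur_range (seconds), avoiding `occupied` intervals.
place_intervals <- function(count, dur_range, fs, N, occupied = NULL) {
  if (count == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  placed <- occupied
  out <- vector("list", count)
  for (i in seq_len(count)) {
    len <- as.integer(round(stats::runif(1, dur_range[1], dur_range[2]) * fs))
    len <- max(len, 1L)
    if (len > N) stop("artifact longer than the record", call. = FALSE)
    ok <- FALSE
    for (try in seq_len(2000L)) {
      s <- as.integer(floor(stats::runif(1, 0, N - len + 1)))
      e <- s + len
      clash <- !is.null(placed) && nrow(placed) > 0 &&
        any(s < placed$end & e > placed$start)
      if (!clash) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("impossible placement: artifact intervals do not fit the record",
        call. = FALSE
      )
    }
    out[[i]] <- data.frame(start = s, end = e)
    placed <- rbind(placed, out[[i]])
  }
  do.call(rbind, out)
}

drop_peaks_inside <- function(r_peaks, intervals) {
  if (length(r_peaks) == 0L || is.null(intervals) || nrow(intervals) == 0L) {
    return(r_peaks)
  }
  inside <- vapply(r_peaks, function(p) {
    any(p >= intervals$start & p < intervals$end)
  }, logical(1))
  r_peaks[!inside]
}

#' Movement schedule of the bed protocol
#'
#' During the recording-in-bed protocol the volunteers moved every 60 s in
#' the first half of the measurement; in the second half they lay still for
#' 120 s, moved for 60 s, then lay still again for 120 s.  This helper turns
#' that protocol into concrete movement intervals: short repositioning
#' movements (`move_seconds`, default 5 s) at a 60 s cadence over the first
#' half, and a single 60 s movement flanked by 120 s rests in the second
#' half.
#'
#' @param kind Protocol name; only `"bed"` is defined.
#' @param duration Record duration in seconds; at least 360 so the second
#'   half can hold the 120/60/120 s rest-move-rest pattern.
#' @param move_seconds Duration of each first-half movement (default 5).
#' @return Data frame with `start`, `end` in seconds, non-overlapping and
#'   within `[0, duration)`.
#' @export
protocol_schedule <- function(kind = "bed", duration, move_seconds = 5) {
  kind <- match.arg(kind)
  if (duration < 360) {
    stop("the bed protocol needs at least 360 s: the second half holds a ",
      "120 s rest, a 60 s movement and another 120 s rest",
      call. = FALSE
    )
  }
  half <- duration / 2
  first <- seq(60, half, by = 60)
  first_iv <- data.frame(start = first, end = first + move_seconds)
  second_iv <- data.frame(start = half + 120, end = half + 180)
  iv <- rbind(first_iv, second_iv)
  iv <- iv[iv$end <= duration & iv$end > iv$start, , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Superimpose coarse (movement) bursts on a record
#'
#' Adds high-amplitude transients over the chosen intervals and updates the
#' ground truth: intervals are labelled `"coarse"` and R peaks falling
#' inside them are removed (an expert could not read them there).  Shapes:
#' `"spike_train"` adds dense biphasic spikes whose largest peak reaches the
#' drawn amplitude; `"step"` adds a baseline jump of that amplitude;
#' `"clip"` saturates the samples at the (signed) amplitude rail.
#'
#' @param series A [cecg_ts].
#' @param truth A [cecg_annotation] ground truth (or `NULL`).
#' @param intervals Data frame `start`, `end` (0-based samples, half-open),
#'   or `NULL` to draw `count` placements at random.
#' @param count Number of bursts when `intervals` is `NULL`.
#' @param amp Amplitude range in volts.
#' @param duration Duration range in seconds (for random placement).
#' @param shapes Shapes to draw from, see above.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return List with updated `series` and `truth`.
#' @export
inject_coarse_artifacts <- function(series, truth = NULL, intervals = NULL,
                                    count = 10, amp = c(2, 8),
                                    duration = c(0.2, 2),
                                    shapes = "spike_train", seed = NULL) {
  stopifnot(inherits(series, "cecg_ts"))
  with_local_seed(seed, {
    N <- length(series)
    fs <- series$fs
    if (is.null(intervals)) {
      occupied <- if (!is.null(truth)) {
        truth$intervals[truth$intervals$label %in% c("coarse", "slow"),
          c("start", "end"),
          drop = FALSE
        ]
      } else {
        NULL
      }
      intervals <- place_intervals(count, duration, fs, N, occupied)
    }
    if (nrow(intervals) == 0L) {
      return(list(series = series, truth = truth))
    }
    x <- series$samples
    for (i in seq_len(nrow(intervals))) {
      s <- intervals$start[i]
      e <- intervals$end[i]
      idx <- (s + 1L):e
      len <- length(idx)
      A <- stats::runif(1, amp[1], amp[2])
      shape <- if (length(shapes) == 1L) shapes else sample(shapes, 1L)
      if (shape == "spike_train") {
        # electrode-displacement swing (sub-3 Hz, the time scale of a body
        # movement) carrying a train of sharp contact spikes; the swing is
        # what lifts the segment fluctuation far above the ECG level
        tt <- (seq_len(len) - 1) / fs
        f_swing <- stats::runif(1, 0.7, 2.5)
        swing <- sample(c(-1, 1), 1L) *
          sin(2 * pi * f_swing * tt + stats::runif(1, 0, 0.3))
        swing <- swing / max(abs(swing)) * 0.85
        spikes <- numeric(len)
        n_spk <- max(2L, as.integer(round(20 * len / fs))) # ~20 spikes/s
        centers <- sort(sample.int(len, min(n_spk, len)))
        amps <- stats::runif(length(centers), 0.3, 0.6)
        signs <- sample(c(-1, 1), length(centers), replace = TRUE)
        hw <- max(1L, as.integer(round(0.004 * fs))) # ~4 ms half-width
        for (k in seq_along(centers)) {
          span <- max(1L, centers[k] - hw):min(len, centers[k] + hw)
          tri <- 1 - abs(span - centers[k]) / (hw + 1)
          spikes[span] <- spikes[span] + signs[k] * amps[k] * tri
        }
        burst <- swing + spikes
        burst <- burst / max(abs(burst)) * A # peak magnitude exactly A
        x[idx] <- x[idx] + burst
      } else if (shape == "step") {
        x[idx] <- x[idx] + sample(c(-1, 1), 1L) * A
      } else if (shape == "clip") {
        x[idx] <- sample(c(-1, 1), 1L) * A
      } else {
        stop("unknown coarse shape: ", shape, call. = FALSE)
      }
    }
    series <- cecg_ts(x, fs = fs, id = series$id)
    truth <- append_artifact_truth(truth, intervals, "coarse", N)
    list(series = series, truth = truth)
  })
}

#' Replace intervals of a record with slow-changing artifacts
#'
#' Overwrites the chosen intervals with band-limited (default 0.5–15 Hz)
#' Gaussian noise whose RMS is `amp_ratio` times the RMS of the clean ECG —
#' modelling disturbances of amplitude comparable to the useful signal in
#' which no R peaks can be read.  The ground truth is updated as for
#' [inject_coarse_artifacts()], with label `"slow"`.
#'
#' @inheritParams inject_coarse_artifacts
#' @param count Number of intervals when `intervals` is `NULL`.
#' @param band Frequency band in Hz.
#' @param amp_ratio Target RMS relative to the record's current RMS outside
#'   artifact intervals.
#' @return List with updated `series` and `truth`.
#' @export
inject_slow_artifacts <- function(series, truth = NULL, intervals = NULL,
                                  count = 6, duration = c(3, 8),
                                  band = c(0.5, 15), amp_ratio = 1,
                                  seed = NULL) {
  stopifnot(inherits(series, "cecg_ts"))
  with_local_seed(seed, {
    N <- length(series)
    fs <- series$fs
    if (is.null(intervals)) {
      occupied <- if (!is.null(truth)) {
        truth$intervals[truth$intervals$label %in% c("coarse", "slow"),
          c("start", "end"),
          drop = FALSE
        ]
      } else {
        NULL
      }
      intervals <- place_intervals(count, duration, fs, N, occupied)
    }
    if (nrow(intervals) == 0L) {
      return(list(series = series, truth = truth))
    }
    if (band[2] > fs / 2) {
      stop("slow-artifact band exceeds the Nyquist frequency", call. = FALSE)
    }
    x <- series$samples
    # reference RMS from samples outside any artifact interval
    mask <- rep(TRUE, N)
    all_iv <- rbind(
      intervals,
      if (!is.null(truth)) {
        truth$intervals[truth$intervals$label %in% c("coarse", "slow"),
          c("start", "end"),
          drop = FALSE
        ]
      }
    )
    for (i in seq_len(nrow(all_iv))) {
      mask[(all_iv$start[i] + 1L):all_iv$end[i]] <- FALSE
    }
    ref_rms <- sqrt(mean(x[mask]^2))
    for (i in seq_len(nrow(intervals))) {
      idx <- (intervals$start[i] + 1L):intervals$end[i]
      x[idx] <- bandlimited_noise(length(idx), fs, band) * amp_ratio * ref_rms
    }
    series <- cecg_ts(x, fs = fs, id = series$id)
    truth <- append_artifact_truth(truth, intervals, "slow", N)
    list(series = series, truth = truth)
  })
}

append_artifact_truth <- function(truth, intervals, label, N) {
  if (is.null(truth)) {
    truth <- cecg_annotation(integer(), NULL, n = N)
  }
  iv <- truth$intervals[truth$intervals$label != "useful", , drop = FALSE]
  iv <- rbind(iv, data.frame(
    start = intervals$start, end = intervals$end, label = label,
    stringsAsFactors = FALSE
  ))
  iv <- iv[order(iv$start), , drop = FALSE]
  peaks <- drop_peaks_inside(truth$r_peaks, intervals)
  rebuild_truth(peaks, iv, N)
}

# Full [0, N) partition: artifact intervals plus the useful gaps between them.
rebuild_truth <- function(r_peaks, artifact_iv, N) {
  artifact_iv <- artifact_iv[order(artifact_iv$start), , drop = FALSE]
  pieces <- list()
  cursor <- 0L
  for (i in seq_len(nrow(artifact_iv))) {
    s <- artifact_iv$start[i]
    if (s > cursor) {
      pieces[[length(pieces) + 1L]] <-
        data.frame(start = cursor, end = s, label = "useful")
    }
    pieces[[length(pieces) + 1L]] <- artifact_iv[i, , drop = FALSE]
    cursor <- max(cursor, artifact_iv$end[i])
  }
  if (cursor < N) {
    pieces[[length(pieces) + 1L]] <-
      data.frame(start = cursor, end = N, label = "useful")
  }
  iv <- do.call(rbind, pieces)
  rownames(iv) <- NULL
  cecg_annotation(r_peaks, iv, n = N)
}

#' Generate a synthetic cECG record with ground truth
#'
#' Builds a clean ECG from a P-QRS-T bump template placed at jittered RR
#' intervals, adds white measurement noise, replaces intervals with
#' slow-changing band-limited noise, and superimposes coarse movement bursts
#' (at random positions, or on the bed-protocol movement schedule).  The
#' ground truth records every surviving R-peak index and a typed partition
#' of the record into useful / coarse / slow intervals; R peaks inside
#' artifact intervals are removed, mirroring the expert convention that a
#' segment is useful only where R peaks can be read.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `series` (a [cecg_ts]) and `truth` (a
#'   [cecg_annotation] whose intervals partition the record).
#' @examples
#' rec <- generate_cecg(synthetic_config(duration = 60, seed = 42))
#' rec$series
#' rec$truth
#' @export
generate_cecg <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_local_seed(cfg$seed, {
    fs <- cfg$fs
    N <- as.integer(round(cfg$duration * fs))
    rr_mean <- 60 / cfg$hr_bpm

    # beat placement with relative RR jitter
    t_beats <- numeric()
    t <- 0.3
    while (t < cfg$duration) {
      t_beats <- c(t_beats, t)
      t <- t + rr_mean * max(0.3, 1 + cfg$rr_jitter * stats::rnorm(1))
    }
    r_idx <- as.integer(round(t_beats * fs))
    r_idx <- r_idx[r_idx < N]

    tmpl <- beat_template(fs)
    x <- numeric(N)
    for (p in r_idx) {
      s <- p - tmpl$r_offset # 0-based start of the template
      span <- seq_along(tmpl$values) + s # 1-based sample positions
      inside <- span >= 1L & span <= N
      x[span[inside]] <- x[span[inside]] +
        cfg$ecg_amp * tmpl$values[inside]
    }
    x <- x + stats::rnorm(N, sd = cfg$baseline_noise_sd)
    series <- cecg_ts(x, fs = fs, id = sprintf("synthetic_%s",
      if (is.null(cfg$seed)) "r" else cfg$seed))
    truth <- rebuild_truth(
      r_idx,
      data.frame(start = integer(), end = integer(), label = character()),
      N
    )

    total_art <- cfg$slow_count * mean(cfg$slow_duration) +
      cfg$coarse_count * mean(cfg$coarse_duration)
    if (cfg$protocol == "none" && total_art > cfg$duration) {
      stop("impossible placement: artifact intervals exceed the record",
        call. = FALSE
      )
    }

    if (cfg$protocol == "bed") {
      # the movement schedule fixes the coarse positions, so place those
      # first and fit the slow intervals around them
      sched <- protocol_schedule("bed", cfg$duration)
      iv <- data.frame(
        start = as.integer(round(sched$start * fs)),
        end = pmin(as.integer(round(sched$end * fs)), N)
      )
      upd <- inject_coarse_artifacts(series, truth,
        intervals = iv,
        amp = cfg$coarse_amp, shapes = cfg$coarse_shapes
      )
      upd <- inject_slow_artifacts(upd$series, upd$truth,
        count = cfg$slow_count, duration = cfg$slow_duration,
        band = cfg$slow_band, amp_ratio = cfg$slow_amp_ratio
      )
    } else {
      upd <- inject_slow_artifacts(series, truth,
        count = cfg$slow_count, duration = cfg$slow_duration,
        band = cfg$slow_band, amp_ratio = cfg$slow_amp_ratio
      )
      upd <- inject_coarse_artifacts(upd$series, upd$truth,
        count = cfg$coarse_count, amp = cfg$coarse_amp,
        duration = cfg$coarse_duration, shapes = cfg$coarse_shapes
      )
    }
    list(series = upd$series, truth = upd$truth)
  })
}
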