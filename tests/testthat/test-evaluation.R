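test_that("SNR follows its defining power ratio", {
  # equal power in both classes: 0 dB
  x <- cecg_ts(rep(c(1, -1), 100), fs = 10)
  useful <- data.frame(start = 0, end = 100)
  expect_equal(snr(x, useful), 0)

  # tenfold power ratio: 10 dB
  y <- cecg_ts(c(rep(sqrt(10), 100), rep(1, 100)), fs = 10)
  expect_equal(snr(y, data.frame(start = 0, end = 100)), 10)

  # matches a direct transcription on a synthetic record with ground truth
  rec <- generate_cecg(synthetic_config(duration = 60, seed = 5))
  iv <- rec$truth$intervals
  uix <- unlist(lapply(which(iv$label == "useful"), function(i) {
    (iv$start[i] + 1):iv$end[i]
  }))
  ps <- mean(rec$series$samples[uix]^2)
  pn <- mean(rec$series$samples[-uix]^2)
  expect_equal(snr(rec$series, rec$truth), 10 * log10(ps / pn),
    tolerance = 1e-9
  )

  # invariant to rescaling the whole record
  scaled <- cecg_ts(3 * rec$series$samples, rec$series$fs)
  expect_equal(snr(scaled, rec$truth), snr(rec$series, rec$truth),
    tolerance = 1e-12
  )

  expect_warning(out <- snr(x, data.frame(start = 0, end = 200)), "empty")
  expect_true(is.nan(out))
})

test_that("segment confusion counts follow the R-peak definition of useful", {
  grid <- make_segment_grid(1000, 100, "forward")
  # peaks in segments 0, 2, 9 -> 3 useful, 7 useless
  truth <- cecg_annotation(r_peaks = c(5, 250, 910), n = 1000)

  all_kept <- segment_confusion(rep(TRUE, 10), truth, grid)
  expect_equal(unclass(all_kept)[c("TP", "FP", "TN", "FN")],
    list(TP = 3L, FP = 7L, TN = 0L, FN = 0L),
    ignore_attr = TRUE
  )

  # perfect policy: keep exactly the useful segments
  perfect <- rep(FALSE, 10)
  perfect[c(1, 3, 10)] <- TRUE
  cc <- segment_confusion(perfect, truth, grid)
  expect_equal(cc$FP + cc$FN, 0)
  expect_equal(cc$TP, 3)
  expect_equal(cc$TN, 7)

  # hand-enumerated mixed policy
  mixed <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  cm <- segment_confusion(mixed, truth, grid)
  expect_equal(unclass(cm)[c("TP", "FP", "TN", "FN")],
    list(TP = 2L, FP = 4L, TN = 3L, FN = 1L),
    ignore_attr = TRUE
  )

  expect_error(segment_confusion(rep(TRUE, 9), truth, grid), "aligned")
})

test_that("classification metrics compute the five standard percentages", {
  m <- classification_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_true(all(unlist(m) == 100))

  m2 <- classification_metrics(list(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_true(all(unlist(m2) == 50))

  m3 <- classification_metrics(list(TP = 80, FN = 20, FP = 0, TN = 0))
  expect_equal(m3$sensitivity, 80)
  expect_true(is.nan(m3$specificity))
  expect_equal(m3$negative_prediction, 0) # defined: 0/(0+20)

  # label symmetry: swapping the positive class swaps the paired metrics
  set.seed(1)
  for (rep in 1:10) {
    cnt <- as.list(setNames(sample(1:50, 4), c("TP", "FP", "TN", "FN")))
    a <- classification_metrics(cnt)
    b <- classification_metrics(list(
      TP = cnt$TN, FP = cnt$FN, TN = cnt$TP, FN = cnt$FP
    ))
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$positive_prediction, b$negative_prediction)
    expect_equal(a$accuracy, b$accuracy)
    # accuracy is the prevalence-weighted mean of sensitivity and specificity
    w <- (cnt$TP + cnt$FN) / Reduce(`+`, cnt)
    expect_equal(a$accuracy, w * a$sensitivity + (1 - w) * a$specificity)
  }
})

test_that("R-peak retention counts peaks in kept segments", {
  grid <- make_segment_grid(1000, 100, "forward")
  peaks <- c(50, 150, 250, 850)
  expect_equal(r_peak_retention(rep(TRUE, 10), peaks, grid)$preserved, 100)
  expect_equal(r_peak_retention(rep(FALSE, 10), peaks, grid)$preserved, 0)
  half <- rep(c(TRUE, FALSE), 5) # keeps segments 0,2,4,6,8
  ret <- r_peak_retention(half, peaks, grid)
  expect_equal(ret$preserved, 75) # only the peak at 150 (segment 1) is lost
  expect_equal(ret$lost, 25)
  expect_warning(out <- r_peak_retention(half, integer(), grid), "no R peaks")
  expect_true(is.nan(out$preserved))
})

test_that("RR features give heart rate and both pNN50 readings", {
  fs <- 1000
  # RR 800, 860, 865, 920 ms: successive diffs 60, 5, 55 -> pNN50 = 2/3
  peaks <- cumsum(c(0, 800, 860, 865, 920))
  f <- rr_features(peaks, fs)
  expect_equal(f$rr_s, c(0.8, 0.86, 0.865, 0.92))
  expect_equal(f$pnn50, 200 / 3, tolerance = 1e-9)
  expect_equal(f$pnn50_loose, 100) # every RR exceeds 50 ms

  const <- rr_features(seq(0, 10000, by = 1000), fs)
  expect_true(all(const$hr_bpm == 60))
  expect_equal(const$pnn50, 0)

  expect_error(rr_features(c(100), fs), "at least 2")
})

test_that("RR intervals spanning elimination gaps are excluded via the index map", {
  ts <- cecg_ts(rnorm(1000), fs = 100)
  grid <- make_segment_grid(1000, 100, "forward")
  keep <- rep(TRUE, 10)
  keep[3] <- FALSE # removes original samples 200..299
  ec <- extract_clean(ts, keep, grid)
  # peaks every 100 samples in cleaned coordinates
  peaks_clean <- seq(50, 850, by = 100)
  f <- rr_features(peaks_clean, 100, index_map = ec$index_map)
  # one of the 8 intervals crosses the gap and is dropped
  expect_length(f$rr_s, 7)
  expect_true(all(f$rr_s == 1))
})

test_that("band power fractions localize spectral content and normalize", {
  fs <- 400
  t <- seq(0, 10 - 1 / fs, by = 1 / fs) # integer number of 3 Hz periods
  sine <- cecg_ts(sin(2 * pi * 3 * t), fs)
  frac <- band_power_fractions(sine, list(c(0, 5), c(5, 15), c(15, 200)))
  expect_gte(frac[1], 99)
  expect_equal(sum(frac), 100, tolerance = 1e-9)

  # white noise spreads its power evenly across equal-width bands
  set.seed(9)
  devs <- replicate(20, {
    w <- cecg_ts(rnorm(4000), fs)
    f <- band_power_fractions(w, list(c(0, 50), c(50, 100), c(100, 150), c(150, 200)))
    max(abs(f - 25))
  })
  expect_lt(mean(devs), 5)

  expect_error(
    band_power_fractions(sine, list(c(0, 300))),
    "Nyquist"
  )
})
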