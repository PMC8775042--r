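test_that("the coarse-artifact criterion separates sparse spikes from dense swings", {
  # constant series: half-range 0, minus rms |c|
  cst <- coarse_artifact_present(cecg_ts(rep(2, 100), 10))
  expect_equal(cst$statistic, -2)
  expect_false(cst$flag)

  # dense equal-magnitude square wave: range and rms cancel exactly
  sq <- coarse_artifact_present(cecg_ts(rep(c(5, -5), 500), 10))
  expect_equal(sq$statistic, 0)
  expect_false(sq$flag)

  # 999 zeros plus a +4 V and a -4 V sample: sparse spikes dominate the range
  x <- c(rep(0, 999), 4, -4)
  sp <- coarse_artifact_present(cecg_ts(x, 10))
  expect_equal(sp$statistic, 4 - sqrt(32 / 1001), tolerance = 1e-12)
  expect_true(sp$flag)
})

test_that("one large spike flips the coarse criterion on a quiet record", {
  for (seed in 1:50) {
    set.seed(seed)
    rec <- generate_cecg(synthetic_config(
      duration = 10, ecg_amp = 0.3,
      coarse_count = 0, slow_count = 0, seed = seed
    ))
    expect_false(coarse_artifact_present(rec$series)$flag)
    x <- rec$series$samples
    i <- sample(length(x), 1)
    x[i] <- x[i] + sample(c(-5, 5), 1)
    expect_true(coarse_artifact_present(cecg_ts(x, rec$series$fs))$flag)
  }
})

test_that("thresholds reproduce the defining formula and its exact identities", {
  rec <- generate_cecg(synthetic_config(seed = 7, duration = 120))
  fp <- fluctuation_series(rec$series)
  th <- compute_thresholds(rec$series, fp, C = 0.25, C1 = 1)

  # independent straight-line transcription of the threshold formula
  x <- rec$series$samples
  fd <- fp$values
  TH1_ref <- (((max(x) - min(x)) / 2)^2 - mean(x^2)) * 0.25 * median(fd) +
    (sd(fd) + sd(x)) / (sd(fd) * sd(x)) * 1
  expect_equal(th$TH1, TH1_ref, tolerance = 1e-9)

  expect_identical(th$TH2, th$TH1 / 2)
  expect_identical(th$TH3, 0.1)
  expect_identical(TH3_SLOW, 0.1)

  # TH1 is linear in C1 with slope (sd_FD + sd_x)/(sd_FD * sd_x)
  th2 <- compute_thresholds(rec$series, fp, C = 0.25, C1 = 2)
  expect_equal(th2$TH1 - th$TH1,
    (th$sd_FD + th$sd_x) / (th$sd_FD * th$sd_x),
    tolerance = 1e-12
  )

  # degenerate input refuses with the dedicated condition class
  const <- cecg_ts(rep(1, 4000), 400)
  expect_error(
    compute_thresholds(const, fluctuation_series(const)),
    class = "cecg_degenerate_error"
  )
})

test_that("reduction leaves a burst-free record untouched by the coarse path", {
  rec <- generate_cecg(synthetic_config(
    duration = 60, coarse_count = 0,
    slow_count = 2, seed = 12
  ))
  res <- reduce_artifacts(rec$series)
  expect_false(res$coarse_present)
  expect_false(any(res$reasons %in% c("coarse", "adjacent")))
})

test_that("a lone high-amplitude burst is eliminated with its spill-over", {
  rec <- generate_cecg(synthetic_config(
    duration = 60, coarse_count = 0,
    slow_count = 0, seed = 9
  ))
  x <- rec$series$samples
  fs <- rec$series$fs
  # one 1 s burst of +-5 V spikes centred at t = 30 s
  idx <- (30 * fs + 1):(31 * fs)
  set.seed(1)
  spikes <- numeric(length(idx))
  ctr <- seq(8, length(idx) - 8, by = 16)
  for (ck in ctr) {
    spikes[(ck - 2):(ck + 2)] <- 5 * sample(c(-1, 1), 1)
  }
  x[idx] <- x[idx] + spikes
  ts <- cecg_ts(x, fs)
  res <- reduce_artifacts(ts)
  expect_true(res$coarse_present)
  burst_segs <- 61:62 # 0-based segments 60 and 61 cover [30 s, 31 s)
  expect_true(all(res$reasons[burst_segs] == "coarse"))
  # decisions agree with the independent transcription, decision for decision
  orc <- oracle_reduce(x, fs)
  expect_identical(res$decisions, orc$kept)
  expect_identical(res$reasons, orc$reason)
})

test_that("batch reduction matches the independent transcription on synthetic records", {
  for (seed in 1:20) {
    rec <- generate_cecg(synthetic_config(
      duration = 60, coarse_count = 3,
      slow_count = 2, seed = 100 + seed
    ))
    for (adj in c("difference", "own")) {
      res <- reduce_artifacts(rec$series, adjacency = adj)
      orc <- oracle_reduce(rec$series$samples, rec$series$fs, adjacency = adj)
      expect_identical(res$decisions, orc$kept)
      expect_identical(res$reasons, orc$reason)
      expect_equal(res$thresholds$TH1, orc$TH1, tolerance = 1e-9)
    }
  }
})

test_that("prose adjacency variant gates on the neighbour's own fluctuation", {
  rec <- generate_cecg(synthetic_config(duration = 120, seed = 31))
  res <- reduce_artifacts(rec$series, adjacency = "own")
  th <- res$thresholds
  adj <- which(res$reasons == "adjacent")
  for (j in adj) {
    expect_gt(res$fd[j], th$TH2)
    expect_true(any(res$reasons[c(j - 1, j + 1)] == "coarse", na.rm = TRUE))
  }
})

test_that("raising C within its recommended range never eliminates more coarse segments", {
  for (seed in c(2, 5, 8)) {
    rec <- generate_cecg(synthetic_config(duration = 120, seed = seed))
    x <- rec$series$samples
    sign_ok <- (((max(x) - min(x)) / 2)^2 - mean(x^2)) > 0
    expect_true(sign_ok) # study condition for the monotonicity claim
    n_coarse <- sapply(c(0.15, 0.25, 0.35), function(C) {
      sum(reduce_artifacts(rec$series, C = C)$reasons == "coarse")
    })
    expect_true(all(diff(n_coarse) <= 0))
  }
})

test_that("reduction is idempotent at the original thresholds", {
  rec <- generate_cecg(synthetic_config(duration = 120, seed = 17))
  res <- reduce_artifacts(rec$series)
  fd_clean <- fluctuation_series(res$cleaned)$values
  expect_false(any(fd_clean > res$thresholds$TH1))
})

test_that("extract_clean concatenates kept segments and maps indices faithfully", {
  ts <- cecg_ts(seq_len(1000) / 100, fs = 10)
  grid <- make_segment_grid(1000, 100, "forward")
  all_kept <- extract_clean(ts, rep(TRUE, 10), grid)
  expect_equal(all_kept$cleaned$samples, ts$samples)
  expect_identical(all_kept$index_map, 0:999)

  none <- extract_clean(ts, rep(FALSE, 10), grid)
  expect_null(none$cleaned)
  expect_length(none$index_map, 0)

  alt <- extract_clean(ts, rep(c(TRUE, FALSE), 5), grid)
  jumps <- diff(alt$index_map)
  expect_true(all(jumps %in% c(1L, 101L))) # gaps of exactly one segment
  expect_equal(sum(jumps == 101L), 4L)
  expect_true(all(diff(alt$index_map) > 0))

  # unsegmented tail is carried through
  ts2 <- cecg_ts(rnorm(1050), fs = 10)
  grid2 <- make_segment_grid(1050, 100, "forward")
  tail_kept <- extract_clean(ts2, rep(FALSE, 10), grid2)
  expect_equal(tail_kept$index_map, 1000:1049)
})

test_that("a degenerate record is kept whole with a warning, not an error", {
  const <- cecg_ts(rep(1, 4000), 400)
  expect_warning(res <- reduce_artifacts(const), "degenerate")
  expect_true(res$degenerate)
  expect_true(all(res$decisions))
  expect_equal(res$cleaned$samples, const$samples)
})

test_that("online decisions equal batch on the initialization window and track it after", {
  rec <- generate_cecg(synthetic_config(duration = 300, seed = 3))
  dec <- reduce_online(rec$series, init_seconds = 50)
  n0 <- attr(dec, "init_segments")
  SL <- 200
  prefix <- cecg_ts(rec$series$samples[seq_len(n0 * SL)], rec$series$fs)
  batch_prefix <- reduce_artifacts(prefix, grid_mode = "forward")
  expect_identical(dec$kept[seq_len(n0)], batch_prefix$decisions)
  expect_identical(dec$reason[seq_len(n0)], batch_prefix$reasons)

  # stationary record: online agrees with full batch on >= 95% of the
  # segments after the initialization window
  batch <- reduce_artifacts(rec$series, grid_mode = "forward")
  after <- (n0 + 1):nrow(dec)
  expect_gte(mean(dec$kept[after] == batch$decisions[after]), 0.95)

  # a 10 s stream cannot initialize a 50 s window
  short <- cecg_ts(rnorm(4000), 400)
  expect_error(reduce_online(short, init_seconds = 50), "too short")
})

test_that("online accepts an equivalent stream of chunks", {
  rec <- generate_cecg(synthetic_config(duration = 120, seed = 23))
  whole <- reduce_online(rec$series, init_seconds = 50)
  cut <- 61 * 400
  chunks <- list(
    cecg_ts(rec$series$samples[1:cut], 400),
    cecg_ts(rec$series$samples[(cut + 1):length(rec$series)], 400)
  )
  split <- reduce_online(chunks, init_seconds = 50)
  expect_identical(whole$kept, split$kept)
})
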