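# Independent brute-force oracles, written as straight transcriptions of the
# defining formulas (explicit loops, lm() fits) and kept free of the package's
# own computational paths.

# Per-segment detrended fluctuation of the cumulative-sum profile.
oracle_fd <- function(x, SL, mode = c("forward", "bidirectional"),
                      form = c("rms", "mean_square")) {
  mode <- match.arg(mode)
  form <- match.arg(form)
  N <- length(x)
  mu <- sum(x) / N
  Y <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + (x[i] - mu)
    Y[i] <- acc
  }
  n_seg <- floor(N / SL)
  starts <- (seq_len(n_seg) - 1L) * SL + 1L
  if (mode == "bidirectional") {
    starts <- c(starts, N - rev(seq_len(n_seg)) * SL + 1L)
  }
  vapply(starts, function(s) {
    seg <- Y[s:(s + SL - 1L)]
    k <- seq_len(SL)
    res <- stats::residuals(stats::lm(seg ~ k))
    ms <- sum(res^2) / SL
    if (form == "rms") sqrt(ms) else ms
  }, numeric(1))
}

# Naive O(n^2) pairwise binarized-entropy oracle: explicit windows, direct
# elementwise Hamming comparisons, per-window log proportions.
oracle_binen <- function(x, m, r, tau = 1, type = c("apen", "sampen")) {
  type <- match.arg(type)
  code <- as.integer(diff(x) > 0)
  phi_naive <- function(mm, exclude_self) {
    nw <- length(code) - (mm - 1L) * tau
    stopifnot(nw >= 1L)
    W <- matrix(0L, nrow = mm, ncol = nw)
    for (i in seq_len(nw)) W[, i] <- code[i + (0:(mm - 1L)) * tau]
    logs <- numeric(nw)
    for (i in seq_len(nw)) {
      d <- colSums(W != W[, i])
      cnt <- sum(d <= r)
      p <- if (exclude_self) (cnt - 1) / (nw - 1) else cnt / nw
      logs[i] <- log(p)
    }
    mean(logs)
  }
  if (type == "apen") {
    phi_naive(m, FALSE) - phi_naive(m + 1L, FALSE)
  } else {
    pm <- phi_naive(m, TRUE)
    pm1 <- phi_naive(m + 1L, TRUE)
    ratio <- pm1 / pm
    if (!is.finite(pm) || !is.finite(pm1) || pm == 0 ||
      !is.finite(ratio) || ratio <= 0) {
      NaN
    } else {
      -10 * log10(ratio)
    }
  }
}

# Step-by-step transcription of the elimination procedure: segment, compute
# fluctuations, derive thresholds, apply the coarse / adjacent / slow rules.
oracle_reduce <- function(x, fs, SL_seconds = 0.5, C = 0.25, C1 = 1,
                          adjacency = c("difference", "own")) {
  adjacency <- match.arg(adjacency)
  SL <- as.integer(round(SL_seconds * fs))
  N <- length(x)
  mode <- if (N < 10000) "bidirectional" else "forward"
  fd_all <- oracle_fd(x, SL, mode)
  n_fwd <- floor(N / SL)
  fd <- fd_all[seq_len(n_fwd)]
  M <- sum(x^2) / N
  stat <- (max(x) - min(x)) / 2 - sqrt(M)
  TH1 <- (((max(x) - min(x)) / 2)^2 - M) * C * stats::median(fd_all) +
    (stats::sd(fd_all) + stats::sd(x)) / (stats::sd(fd_all) * stats::sd(x)) * C1
  TH2 <- TH1 / 2
  TH3 <- 0.1
  reason <- rep("kept", n_fwd)
  if (stat > 1) {
    coarse <- which(fd > TH1)
    reason[coarse] <- "coarse"
    for (j in coarse) {
      for (nb in c(j - 1L, j + 1L)) {
        if (nb >= 1L && nb <= n_fwd && reason[nb] == "kept") {
          hit <- if (adjacency == "difference") {
            (fd[j] - fd[nb]) > TH2
          } else {
            fd[nb] > TH2
          }
          if (hit) reason[nb] <- "adjacent"
        }
      }
    }
  }
  if (mean(fd_all) - stats::sd(fd_all) > TH3) {
    reason[reason == "kept" & fd <= TH3] <- "slow"
  }
  list(kept = reason == "kept", reason = reason, TH1 = TH1, statistic = stat)
}

# Segment truth labels and pooled reduction scores against ground truth.
score_reduction <- function(res, truth) {
  SL <- res$grid$SL_samples
  n <- res$grid$n_forward
  seg_s <- (seq_len(n) - 1) * SL
  seg_e <- seg_s + SL
  civ <- truth$intervals[truth$intervals$label == "coarse", , drop = FALSE]
  is_coarse <- vapply(seq_len(n), function(j) {
    any(seg_s[j] < civ$end & seg_e[j] > civ$start)
  }, logical(1))
  is_useful <- vapply(seq_len(n), function(j) {
    any(truth$r_peaks >= seg_s[j] & truth$r_peaks < seg_e[j])
  }, logical(1))
  list(
    coarse_total = sum(is_coarse),
    coarse_eliminated = sum(is_coarse & !res$decisions),
    useful_total = sum(is_useful),
    useful_kept = sum(is_useful & res$decisions)
  )
}
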