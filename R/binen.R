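#' Binary differential encoding of a series
#'
#' Maps each successive sample difference to one bit: 1 for a strict
#' increase, 0 otherwise (ties count as non-increase).  The code has length
#' `N - 1` and is invariant to adding a constant to, or positively rescaling,
#' the signal — which is what makes the binarized entropies usable on
#' artifact-laden recordings without prior amplitude cleaning.
#'
#' @param series A [cecg_ts] or numeric vector with at least 2 samples.
#' @return Integer vector of 0/1 of length `N - 1`.
#' @export
binarize <- function(series) {
  x <- if (inherits(series, "cecg_ts")) series$samples else as.numeric(series)
  if (length(x) < 2L) {
    stop("binarization needs at least 2 samples", call. = FALSE)
  }
  as.integer(diff(x) > 0)
}

#' Occurrence histogram of m-bit code words
#'
#' Slides a window of `m` bits (elements `tau` apart) over the binary code,
#' reads each window as the integer `k = sum c[i + n*tau] * 2^n`, and counts
#' occurrences of each of the `2^m` possible words.  The counts divided by
#' the number of windows are the empirical word probabilities.
#'
#' @param code Integer 0/1 vector (see [binarize()]).
#' @param m Word size in bits (>= 1).
#' @param tau Delay between bits in a word (>= 1, default 1).
#' @return List with `counts` (length `2^m`, words `0 .. 2^m - 1`), `pmf`,
#'   and `n_windows`.
#' @export
vector_histogram <- function(code, m, tau = 1L) {
  code <- as.integer(code)
  m <- as.integer(m)
  tau <- as.integer(tau)
  if (m < 1L || tau < 1L) stop("'m' and 'tau' must be >= 1", call. = FALSE)
  np <- length(code)
  n_win <- np - (m - 1L) * tau
  if (n_win < 1L) {
    stop(sprintf(
      "code too short: need at least (m-1)*tau + 1 = %d bits, got %d",
      (m - 1L) * tau + 1L, np
    ), call. = FALSE)
  }
  k <- integer(n_win)
  for (nbit in 0:(m - 1L)) {
    k <- k + code[(1L + nbit * tau):(n_win + nbit * tau)] * 2L^nbit
  }
  counts <- tabulate(k + 1L, nbins = 2L^m)
  list(counts = counts, pmf = counts / n_win, n_windows = n_win)
}

#' Hamming-distance matrix over m-bit words
#'
#' Entry `[k+1, n+1]` is the number of differing bits between the words with
#' values `k` and `n` (popcount of `k XOR n`): symmetric, zero diagonal,
#' entries in `0..m`.
#'
#' @param m Word size in bits, 1..16.
#' @return Integer matrix of dimension `2^m` x `2^m`.
#' @export
hamming_matrix <- function(m) {
  m <- as.integer(m)
  if (m < 1L || m > 16L) stop("'m' must be in 1..16", call. = FALSE)
  k <- 0:(2L^m - 1L)
  xi <- bitwXor(rep(k, each = length(k)), rep(k, times = length(k)))
  pop <- integer(length(xi))
  for (b in 0:(m - 1L)) pop <- pop + bitwAnd(bitwShiftR(xi, b), 1L)
  matrix(pop, nrow = length(k), byrow = TRUE)
}

# Shared phi kernel.  pmf over 2^m words, H the matching Hamming matrix.
# For each word k, p_hat(k) is the probability mass within Hamming distance
# r of k; phi is the pmf-weighted mean of log(p_hat).  exclude_self
# implements the sample-entropy convention: each window's own occurrence is
# removed from both numerator and denominator of p_hat.
phi_from_hist <- function(counts, n_windows, H, r, exclude_self = FALSE) {
  pmf <- counts / n_windows
  within <- (H <= r)
  mass <- as.vector(within %*% counts) # windows within distance r of each word
  if (exclude_self) {
    if (n_windows < 2L) return(NaN)
    p_hat <- (mass - 1) / (n_windows - 1)
  } else {
    p_hat <- mass / n_windows
  }
  active <- pmf > 0
  if (any(active & p_hat <= 0)) return(-Inf)
  sum(pmf[active] * log(p_hat[active]))
}

#' Word-probability similarity sum
#'
#' The average, over occupied words, of the natural log of the probability
#' of finding another window within Hamming distance `r`:
#' `phi = sum_k pmf(k) * ln(p_hat_k(r))` with
#' `p_hat_k(r) = sum_n pmf(n) * I(h_kn <= r)`.  Always `<= 0`; equals 0 when
#' every occupied word sees all probability mass within distance `r` (e.g.
#' `r >= m`, or a single-word code).
#'
#' @param pmf Probability vector over the `2^m` words.
#' @param H Matching [hamming_matrix()].
#' @param r Integer tolerance (Hamming distance), `>= 0`.
#' @return Scalar `phi` (non-positive).
#' @export
phi_similarity <- function(pmf, H, r) {
  pmf <- as.numeric(pmf)
  if (abs(sum(pmf) - 1) > 1e-9 || any(pmf < 0)) {
    stop("'pmf' must be a probability vector", call. = FALSE)
  }
  if (length(pmf) != nrow(H)) {
    stop("'pmf' length must match the Hamming matrix", call. = FALSE)
  }
  r <- check_r(r)
  p_hat <- as.vector((H <= r) %*% pmf)
  active <- pmf > 0
  # every word is within distance 0 of itself, so p_hat > 0 wherever pmf > 0
  stopifnot(all(p_hat[active] > 0))
  sum(pmf[active] * log(p_hat[active]))
}

check_r <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || r < 0) {
    stop("'r' must be a non-negative scalar", call. = FALSE)
  }
  if (r != floor(r)) {
    warning("non-integer tolerance 'r' floored (Hamming distances are integers)",
      call. = FALSE
    )
    r <- floor(r)
  }
  as.integer(r)
}

binen_config <- function(m, r, tau) {
  m <- as.integer(m)
  tau <- as.integer(tau)
  if (m < 1L) stop("'m' must be >= 1", call. = FALSE)
  if (tau < 1L) stop("'tau' must be >= 1", call. = FALSE)
  list(m = m, r = check_r(r), tau = tau)
}

#' Binarized approximate entropy
#'
#' Approximate entropy on the binary differential code of the series:
#' `BinApEn = phi(m) - phi(m+1)` with both terms at the same tolerance `r`
#' (a Hamming distance) and delay `tau`.  Zero for a constant series and
#' whenever `r >= m + 1` (every pair of words is then within tolerance at
#' both orders).
#'
#' @param series A [cecg_ts] or numeric vector.
#' @param m Word size (typical 1..4).
#' @param r Integer Hamming-distance tolerance, `0 <= r`.
#' @param tau Delay (default 1).
#' @return List of class `binen_result`: `bin_ap_en`, `phi_m`, `phi_m1`,
#'   `counts_m`, `pmf_m`, `m`, `r`, `tau`.
#' @examples
#' set.seed(1)
#' x <- cecg_ts(runif(500), fs = 100)
#' bin_ap_en(x, m = 2, r = 2)$bin_ap_en
#' @export
bin_ap_en <- function(series, m = 2, r = 2, tau = 1) {
  cfg <- binen_config(m, r, tau)
  code <- binarize(series)
  if (length(code) < cfg$m * cfg$tau + 1L) {
    stop("series too short for order m+1 windows", call. = FALSE)
  }
  h_m <- vector_histogram(code, cfg$m, cfg$tau)
  h_m1 <- vector_histogram(code, cfg$m + 1L, cfg$tau)
  phi_m <- phi_from_hist(h_m$counts, h_m$n_windows, hamming_matrix(cfg$m), cfg$r)
  phi_m1 <- phi_from_hist(
    h_m1$counts, h_m1$n_windows, hamming_matrix(cfg$m + 1L), cfg$r
  )
  structure(
    list(
      bin_ap_en = phi_m - phi_m1, phi_m = phi_m, phi_m1 = phi_m1,
      counts_m = h_m$counts, pmf_m = h_m$pmf,
      m = cfg$m, r = cfg$r, tau = cfg$tau
    ),
    class = "binen_result"
  )
}

#' Binarized sample entropy
#'
#' Sample-entropy analogue on the binary differential code, excluding
#' self-similarity: each window's own occurrence is removed from its
#' neighbour count (numerator and denominator) before the log-average.
#' The reported value is `-10 * log10(phi(m+1) / phi(m))`, a decibel-style
#' ratio of the two orders' similarity sums; it is undefined — returned as
#' `NaN` with a warning — when `phi(m) = 0` or the ratio is non-positive.
#'
#' @inheritParams bin_ap_en
#' @return List of class `binen_result`: `bin_samp_en`, `phi_m`, `phi_m1`,
#'   `m`, `r`, `tau`.
#' @export
bin_samp_en <- function(series, m = 2, r = 2, tau = 1) {
  cfg <- binen_config(m, r, tau)
  code <- binarize(series)
  if (length(code) < cfg$m * cfg$tau + 1L) {
    stop("series too short for order m+1 windows", call. = FALSE)
  }
  h_m <- vector_histogram(code, cfg$m, cfg$tau)
  h_m1 <- vector_histogram(code, cfg$m + 1L, cfg$tau)
  phi_m <- phi_from_hist(
    h_m$counts, h_m$n_windows, hamming_matrix(cfg$m), cfg$r,
    exclude_self = TRUE
  )
  phi_m1 <- phi_from_hist(
    h_m1$counts, h_m1$n_windows, hamming_matrix(cfg$m + 1L), cfg$r,
    exclude_self = TRUE
  )
  ratio <- phi_m1 / phi_m
  if (!is.finite(phi_m) || !is.finite(phi_m1) || phi_m == 0 ||
    !is.finite(ratio) || ratio <= 0) {
    warning("BinSampEn undefined (phi(m) = 0 or non-positive ratio)",
      call. = FALSE
    )
    value <- NaN
  } else {
    value <- -10 * log10(ratio)
  }
  structure(
    list(
      bin_samp_en = value, phi_m = phi_m, phi_m1 = phi_m1,
      m = cfg$m, r = cfg$r, tau = cfg$tau
    ),
    class = "binen_result"
  )
}

#' @export
print.binen_result <- function(x, ...) {
  cat(sprintf(
    "<binen_result m=%d r=%d tau=%d> %s\n", x$m, x$r, x$tau,
    paste(
      c(
        if (!is.null(x$bin_ap_en)) sprintf("BinApEn=%.6g", x$bin_ap_en),
        if (!is.null(x$bin_samp_en)) sprintf("BinSampEn=%.6g", x$bin_samp_en)
      ),
      collapse = ", "
    )
  ))
  invisible(x)
}
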