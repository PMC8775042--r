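#' Construct a cECG time series
#'
#' The basic container consumed by every stage of the pipeline: a vector of
#' voltage samples together with its sampling rate.  Amplitudes are
#' interpreted in volts throughout, because the coarse-artifact criterion and
#' the threshold constant `C1` are dimensional (1 V); rescale other units
#' before constructing the object.
#'
#' @param samples Numeric vector of voltage samples (volts). Must be finite
#'   and non-empty.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param id Free-text record identifier.
#' @return An object of class `cecg_ts` with fields `samples`, `fs`, `id`.
#' @examples
#' x <- cecg_ts(sin(seq(0, 2 * pi, length.out = 400)), fs = 400)
#' x
#' @export
cecg_ts <- function(samples, fs, id = "record") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("a time series needs at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), id = as.character(id)[1L]),
    class = "cecg_ts"
  )
}

#' @export
print.cecg_ts <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf(
    "<cecg_ts '%s'> %d samples @ %g Hz (%.1f s), range [%.3g, %.3g] V\n",
    x$id, n, x$fs, n / x$fs, min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
length.cecg_ts <- function(x) length(x$samples)

#' Construct an annotation set for a record
#'
#' Holds expert-style annotations: R-peak sample positions and labelled
#' intervals.  All sample indices are 0-based and intervals are half-open
#' `[start, end)` — the convention used consistently by the package and by its
#' on-disk sidecar format; add 1 when using an index to subset an R vector.
#'
#' @param r_peaks Integer vector of 0-based R-peak sample indices, strictly
#'   increasing.
#' @param intervals Data frame with columns `start`, `end` (0-based, half-open
#'   sample range) and `label` (one of `"useful"`, `"useless"`, `"coarse"`,
#'   `"slow"`), or `NULL` for none.
#' @param n Optional series length; when given, all indices are validated
#'   against `[0, n)` (intervals may end at `n`).
#' @return An object of class `cecg_annotation`.
#' @export
cecg_annotation <- function(r_peaks = integer(), intervals = NULL, n = NULL) {
  r_peaks <- as.integer(round(r_peaks))
  if (is.null(intervals)) {
    intervals <- data.frame(
      start = integer(), end = integer(), label = character(),
      stringsAsFactors = FALSE
    )
  }
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (!all(c("start", "end", "label") %in% names(intervals))) {
    stop("'intervals' needs columns start, end, label", call. = FALSE)
  }
  rownames(intervals) <- NULL
  intervals$start <- as.integer(round(intervals$start))
  intervals$end <- as.integer(round(intervals$end))
  intervals$label <- as.character(intervals$label)
  ok_labels <- c("useful", "useless", "coarse", "slow")
  if (!all(intervals$label %in% ok_labels)) {
    stop("interval labels must be one of: ", paste(ok_labels, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(intervals$end < intervals$start)) {
    stop("intervals must have non-negative length", call. = FALSE)
  }
  if (length(r_peaks) > 1L && any(diff(r_peaks) <= 0L)) {
    stop("'r_peaks' must be strictly increasing", call. = FALSE)
  }
  if (any(r_peaks < 0L) || any(intervals$start < 0L)) {
    stop("sample indices are 0-based and must be non-negative", call. = FALSE)
  }
  if (!is.null(n)) {
    n <- as.integer(n)
    if (any(r_peaks >= n)) {
      stop("R-peak index out of range: annotation indices must lie in [0, N)",
        call. = FALSE
      )
    }
    if (any(intervals$end > n)) {
      stop("interval end exceeds series length N", call. = FALSE)
    }
  }
  structure(
    list(r_peaks = r_peaks, intervals = intervals),
    class = "cecg_annotation"
  )
}

#' @export
print.cecg_annotation <- function(x, ...) {
  cat(sprintf(
    "<cecg_annotation> %d R peaks, %d labelled intervals\n",
    length(x$r_peaks), nrow(x$intervals)
  ))
  invisible(x)
}

#' Read a record (signal + optional sidecar) from disk
#'
#' The signal file is plain text with one voltage value per line (a first
#' time/index column, if present, is ignored).  The sampling rate comes from
#' the JSON sidecar or the `fs_override` argument; the override wins when both
#' are given.
#'
#' @param signal_path Path to the signal file (CSV / one value per line).
#' @param sidecar_path Optional path to the JSON sidecar
#'   (`{"fs":..,"id":..,"r_peaks":[..],"intervals":[[start,end,"label"],..]}`).
#'   Defaults to `<signal_path minus extension>.json` when that file exists.
#' @param fs_override Optional sampling rate in Hz, overriding the sidecar.
#' @param scale Multiplicative factor applied to the raw values to convert
#'   them to volts (default 1).
#' @return A list with elements `series` (a [cecg_ts]) and `annotation`
#'   (a [cecg_annotation] or `NULL` when the sidecar carries none).
#' @export
load_record <- function(signal_path, sidecar_path = NULL, fs_override = NULL,
                        scale = 1) {
  if (!file.exists(signal_path)) {
    stop("signal file not found: ", signal_path, call. = FALSE)
  }
  if (is.null(sidecar_path)) {
    guess <- paste0(sub("\\.[^.]+$", "", signal_path), ".json")
    if (file.exists(guess)) sidecar_path <- guess
  }
  side <- NULL
  if (!is.null(sidecar_path)) {
    if (!file.exists(sidecar_path)) {
      stop("sidecar file not found: ", sidecar_path, call. = FALSE)
    }
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  fs <- if (!is.null(fs_override)) fs_override else side$fs
  if (is.null(fs)) {
    stop("sampling rate unavailable: provide a sidecar with \"fs\" or ",
      "an fs_override",
      call. = FALSE
    )
  }

  lines <- readLines(signal_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # keep the last comma/tab/space-separated field: an optional leading
  # time column is ignored for computation
  first <- strsplit(trimws(lines[1L]), "[,\t ]+")[[1L]]
  header_skip <- suppressWarnings(is.na(as.numeric(first[length(first)])))
  if (header_skip) lines <- lines[-1L]
  fields <- strsplit(trimws(lines), "[,\t ]+")
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[length(f)]), numeric(1))
  )
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L] + as.integer(header_skip)
    stop(sprintf("non-numeric value in %s at line %d", signal_path, bad),
      call. = FALSE
    )
  }
  id <- if (!is.null(side$id)) side$id else sub("\\.[^.]+$", "", basename(signal_path))
  series <- cecg_ts(vals * scale, fs = fs, id = id)

  annotation <- NULL
  if (!is.null(side) && (!is.null(side$r_peaks) || !is.null(side$intervals))) {
    iv <- side$intervals
    iv_df <- NULL
    if (!is.null(iv) && length(iv) > 0) {
      if (is.matrix(iv)) iv <- split(iv, seq_len(nrow(iv)))
      if (is.data.frame(iv)) iv <- split(as.matrix(iv), seq_len(nrow(iv)))
      iv_df <- data.frame(
        start = vapply(iv, function(r) as.numeric(r[[1L]]), numeric(1)),
        end = vapply(iv, function(r) as.numeric(r[[2L]]), numeric(1)),
        label = vapply(iv, function(r) as.character(r[[3L]]), character(1)),
        stringsAsFactors = FALSE
      )
    }
    annotation <- cecg_annotation(
      r_peaks = if (is.null(side$r_peaks)) integer() else side$r_peaks,
      intervals = iv_df, n = length(series)
    )
  }
  list(series = series, annotation = annotation)
}

#' Write a record (and optionally a segment mask) to disk
#'
#' Writes `<out_prefix>.csv` (one voltage per line), `<out_prefix>.json`
#' (sampling rate, id and annotations) and, when a mask is supplied,
#' `<out_prefix>_mask.csv` with columns
#' `segment,start,end,kept,reason`.
#'
#' @param series A [cecg_ts].
#' @param annotation Optional [cecg_annotation].
#' @param mask Optional data frame with columns `segment`, `start`, `end`,
#'   `kept`, `reason` (as produced by [reduce_artifacts()]'s `$mask`).
#' @param out_prefix Output path prefix (directory must exist).
#' @return Invisibly, the character vector of files written.
#' @export
save_record <- function(series, annotation = NULL, mask = NULL, out_prefix) {
  stopifnot(inherits(series, "cecg_ts"))
  sig_path <- paste0(out_prefix, ".csv")
  side_path <- paste0(out_prefix, ".json")
  written <- c(sig_path, side_path)
  ok <- tryCatch(
    {
      writeLines(format(series$samples, digits = 17, trim = TRUE,
        scientific = FALSE), sig_path)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stop("cannot write signal file: ", sig_path, call. = FALSE)

  iv <- if (is.null(annotation)) NULL else annotation$intervals
  side <- list(
    fs = series$fs,
    id = series$id,
    r_peaks = if (is.null(annotation)) integer() else annotation$r_peaks,
    intervals = if (is.null(iv) || nrow(iv) == 0L) {
      list()
    } else {
      lapply(seq_len(nrow(iv)), function(i) {
        list(iv$start[i], iv$end[i], iv$label[i])
      })
    }
  )
  jsonlite::write_json(side, side_path, auto_unbox = TRUE, digits = NA)

  if (!is.null(mask)) {
    mask_path <- paste0(out_prefix, "_mask.csv")
    utils::write.csv(
      mask[, c("segment", "start", "end", "kept", "reason")],
      mask_path,
      row.names = FALSE, quote = FALSE
    )
    written <- c(written, mask_path)
  }
  invisible(written)
}
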