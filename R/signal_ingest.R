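#' ECG record
#'
#' @param samples numeric vector of ECG samples (mV).
#' @param fs sampling frequency (Hz), > 0.
#' @param subject_id,sex metadata.
#' @param beat_times optional ground-truth beat times (s), carried by the
#'   synthetic generator for round-trip testing.
#' @return Object of class \code{ecg_record}.
#' @export
ecg_record <- function(samples, fs, subject_id = NA_character_,
                       sex = NA_character_, beat_times = NULL) {
  samples <- as.numeric(samples)
  if (fs <= 0) stop("fs must be positive")
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("ECG samples must be finite")
  }
  structure(
    list(samples = samples, fs = fs, subject_id = subject_id, sex = sex,
         beat_times = beat_times),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record: %d samples @ %g Hz (%.1f s), subject %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$subject_id))
  invisible(x)
}

#' Write / read an ECG record as delimited text
#'
#' The signal is a single column of samples; acquisition metadata (sampling
#' frequency, subject, sex) travels in a sidecar header file
#' \code{<path>.hdr} with \code{key: value} lines.
#'
#' @param ecg an \code{ecg_record}.
#' @param path output file path for the sample column.
#' @return \code{write_ecg} returns \code{path} invisibly; \code{read_ecg}
#'   returns an \code{ecg_record}.
#' @export
write_ecg <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg_record"))
  utils::write.table(data.frame(mv = ecg$samples), path,
                     row.names = FALSE, col.names = FALSE)
  writeLines(c(
    sprintf("fs: %.10g", ecg$fs),
    sprintf("subject_id: %s", ecg$subject_id),
    sprintf("sex: %s", ecg$sex)
  ), paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname write_ecg
#' @param fs sampling frequency (Hz); if \code{NULL}, read from the sidecar
#'   header.
#' @export
read_ecg <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("ECG file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("ECG file is empty: ", path)
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) {
    bad <- which(is.na(x))[1]
    stop(sprintf("non-numeric ECG sample at row %d of %s", bad, path))
  }
  subject_id <- NA_character_; sex <- NA_character_
  hdr_path <- paste0(path, ".hdr")
  if (file.exists(hdr_path)) {
    hdr <- readLines(hdr_path)
    get <- function(key) {
      ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
      if (length(ln)) trimws(sub(paste0("^", key, ":"), "", ln[1])) else NA_character_
    }
    if (is.null(fs)) fs <- as.numeric(get("fs"))
    subject_id <- get("subject_id"); sex <- get("sex")
  }
  if (is.null(fs) || is.na(fs)) {
    stop("sampling frequency not given and no sidecar header for ", path)
  }
  ecg_record(x, fs, subject_id, sex)
}

#' Detect R peaks with a Pan-Tompkins-style chain
#'
#' Band-pass filtering (5-15 Hz Butterworth, zero-phase), differentiation,
#' squaring, 150 ms moving-window integration, then adaptive thresholding at
#' a fraction of a running amplitude estimate with a 200 ms refractory
#' period. Each detection is refined to the local maximum of the raw signal
#' in a +/- 50 ms neighbourhood. Detection is invariant to constant offset
#' and positive rescaling of the input.
#'
#' @param ecg an \code{ecg_record} at least 2 s long.
#' @return List of class \code{rpeak_series}: \code{peak_indices} (0-based
#'   sample indices, strictly increasing) and \code{fs}. A flat or peak-free
#'   record yields zero indices with a warning.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$fs
  x <- ecg$samples
  if (length(x) / fs < 2) stop("record must be at least 2 s long")
  if (stats::sd(x) == 0) {
    warning("flat signal: no R peaks found")
    return(structure(list(peak_indices = integer(0), fs = fs),
                     class = "rpeak_series"))
  }
  # band-pass 5-15 Hz, zero-phase to preserve peak timing
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  d <- c(0, diff(xf))
  sq <- d^2
  w <- max(1L, round(0.150 * fs))
  integ <- stats::filter(sq, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  refr <- round(0.200 * fs)
  n <- length(integ)
  # candidate peaks: all local maxima of the integrated energy
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  # adaptive signal/noise level estimates seeded from the first 2 s
  lead <- integ[seq_len(min(n, round(2 * fs)))]
  spki <- max(lead)
  npki <- mean(lead)
  peaks <- integer(0)
  last <- -refr
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] > thr) {
      if (i - last >= refr) {
        peaks <- c(peaks, i)
        last <- i
        spki <- 0.125 * integ[i] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  if (length(peaks) == 0) {
    warning("no R peaks found")
    return(structure(list(peak_indices = integer(0), fs = fs),
                     class = "rpeak_series"))
  }
  # refine: local maximum of the raw signal around each integrated-energy
  # peak; the moving-window integration lags the R wave, so the search
  # window reaches further back than forward
  back <- as.integer(round(0.200 * fs))
  fwd <- as.integer(round(0.100 * fs))
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - back); hi <- min(length(x), p + fwd)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce refractory after refinement
  keep <- c(TRUE, diff(refined) >= refr)
  refined <- refined[keep]
  structure(list(peak_indices = refined - 1L, fs = fs),
            class = "rpeak_series")
}

#' RR intervals from detected R peaks
#'
#' \code{interval_i = (index_{i+1} - index_i) / fs * 1000} ms; \code{n} peaks
#' yield \code{n - 1} intervals. The first timestamp is the time of the first
#' peak, so the sum of intervals equals the span between first and last peak
#' exactly.
#'
#' @param peaks an \code{rpeak_series} with at least 2 peaks.
#' @return An \code{rr_series}.
#' @export
rr_from_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (length(peaks$peak_indices) < 2) {
    stop("need at least 2 R peaks to form RR intervals")
  }
  iv <- diff(peaks$peak_indices) / peaks$fs * 1000
  rr_series(iv, t0 = peaks$peak_indices[1] / peaks$fs)
}

#' Median-filter artifact correction for RR series
#'
#' Intervals deviating from the local median (11-beat window) by more than
#' \code{rel_threshold} of that median are treated as artifacts and replaced
#' by cubic-spline interpolation over their neighbours. Off by default in the
#' analysis pipeline; provided as an opt-in cleaning stage.
#'
#' @param rr an \code{rr_series}.
#' @param rel_threshold relative deviation threshold in (0, 1].
#' @return An \code{rr_series} with attribute \code{n_corrected}.
#' @export
correct_artifacts <- function(rr, rel_threshold = 0.3) {
  stopifnot(inherits(rr, "rr_series"))
  if (rel_threshold <= 0 || rel_threshold > 1) {
    stop("rel_threshold must be in (0, 1]")
  }
  iv <- rr$intervals
  n <- length(iv)
  if (n < 3) {
    out <- rr
    attr(out, "n_corrected") <- 0L
    return(out)
  }
  half <- 5L
  locmed <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::median(iv[lo:hi])
  }, numeric(1))
  bad <- abs(iv - locmed) > rel_threshold * locmed
  n_bad <- sum(bad)
  if (n_bad > 0 && n_bad < n) {
    good <- which(!bad)
    iv[bad] <- stats::spline(good, iv[good], xout = which(bad),
                             method = "natural")$y
    iv <- pmax(iv, 1)
  }
  out <- rr_series(iv, t0 = rr$timestamps[1])
  attr(out, "n_corrected") <- as.integer(n_bad)
  out
}

#' Write / read an RR series as two-column delimited text
#'
#' Columns: cumulative beat time (s) and the RR interval (ms) ending at that
#' beat; the first beat carries \code{NA} for the interval.
#'
#' @param rr an \code{rr_series}; \code{path} a file path.
#' @return \code{write_rr} returns \code{path} invisibly; \code{read_rr}
#'   returns an \code{rr_series}.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  df <- data.frame(time_s = rr$timestamps,
                   rr_ms = c(NA, rr$intervals))
  utils::write.table(df, path, row.names = FALSE, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_rr
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) stop("RR file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (nrow(df) < 2) stop("RR file has fewer than 2 beats: ", path)
  rr_series(df$rr_ms[-1], t0 = df$time_s[1])
}
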