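#' RR-interval series
#'
#' Container for a sequence of successive inter-beat (RR) intervals together
#' with the cumulative beat timestamps. Timestamps are in seconds from the
#' start of the recording and include the onset of the first beat, so a
#' series of \code{n} intervals carries \code{n + 1} timestamps.
#'
#' @param intervals numeric vector of RR intervals in milliseconds; all > 0.
#' @param t0 time of the first beat in seconds (default 0).
#' @return An object of class \code{rr_series} with elements
#'   \code{intervals} (ms) and \code{timestamps} (s).
#' @examples
#' rr <- rr_series(c(800, 820, 810))
#' rr$timestamps  # 0.00 0.80 1.62 2.43
#' @export
rr_series <- function(intervals, t0 = 0) {
  intervals <- as.numeric(intervals)
  if (anyNA(intervals) || any(!is.finite(intervals))) {
    stop("RR intervals must be finite and non-missing")
  }
  if (any(intervals <= 0)) {
    stop("RR intervals must be strictly positive (ms)")
  }
  structure(
    list(
      intervals = intervals,
      timestamps = t0 + c(0, cumsum(intervals) / 1000)
    ),
    class = "rr_series"
  )
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf(
    "RR series: %d intervals, %.1f s, mean RR %.1f ms\n",
    n, diff(range(x$timestamps)), if (n) mean(x$intervals) else NA_real_
  ))
  invisible(x)
}

#' Restrict an RR series to a time window
#'
#' Keeps the intervals whose onset timestamp lies in the half-open window
#' \code{[start_s, end_s)}. The half-open convention makes window membership
#' deterministic and prevents double counting of boundary beats when windows
#' tile or overlap.
#'
#' @param rr an \code{rr_series}.
#' @param start_s,end_s window bounds in seconds.
#' @return An \code{rr_series} whose first timestamp is the onset of the first
#'   retained beat.
#' @export
rr_window <- function(rr, start_s, end_s) {
  stopifnot(inherits(rr, "rr_series"), end_s > start_s)
  onset <- rr$timestamps[seq_along(rr$intervals)]
  keep <- onset >= start_s & onset < end_s
  if (!any(keep)) {
    return(structure(list(intervals = numeric(0), timestamps = numeric(0)),
                     class = "rr_series"))
  }
  rr_series(rr$intervals[keep], t0 = onset[which(keep)[1]])
}
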