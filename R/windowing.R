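#' Cut a recording into overlapping analysis windows
#'
#' Windows start at \code{0, step_s, 2*step_s, ...} and the last window ends
#' at or before \code{duration_s}, giving
#' \code{floor((duration_s - window_s) / step_s) + 1} windows: a 60-minute
#' recording cut into 2-minute windows with 50% overlap yields 59. Beats are
#' assigned to a window when their onset timestamp falls in
#' \code{[start, end)}.
#'
#' @param rr an \code{rr_series} covering the recording.
#' @param duration_s recording duration (s).
#' @param window_s window length (s), default 120.
#' @param step_s step between window starts (s), default 60 (50% overlap).
#' @param subject_id,sex metadata attached to each segment.
#' @return List of \code{segment} objects: \code{subject_id}, \code{sex},
#'   \code{window_index} (0-based), \code{start_s}, \code{end_s}, \code{rr},
#'   \code{label} (unset, \code{NA}).
#' @export
segment_recording <- function(rr, duration_s, window_s = 120, step_s = 60,
                              subject_id = NA_character_,
                              sex = NA_character_) {
  stopifnot(inherits(rr, "rr_series"))
  if (window_s > duration_s) {
    stop("window_s must not exceed the recording duration")
  }
  if (step_s <= 0 || step_s > window_s) {
    stop("step_s must satisfy 0 < step_s <= window_s")
  }
  n_win <- floor((duration_s - window_s) / step_s) + 1
  lapply(seq_len(n_win) - 1L, function(k) {
    start_s <- k * step_s
    end_s <- start_s + window_s
    structure(
      list(subject_id = subject_id, sex = sex, window_index = k,
           start_s = start_s, end_s = end_s,
           rr = rr_window(rr, start_s, end_s), label = NA_character_),
      class = "segment"
    )
  })
}

#' Consensus label for a two-minute window from expert votes
#'
#' A window is \code{alert} when three or more of the five raters voted
#' \code{alert} in \emph{both} of its minutes; \code{fatigued} when three or
#' more voted \code{fatigued} or \code{very_fatigued} (pooled) in both
#' minutes; otherwise \code{discordant}. The rule depends only on vote
#' counts, so it is invariant to permuting raters.
#'
#' @param votes_min1,votes_min2 character vectors of exactly 5 ratings each,
#'   values in \code{c("alert", "fatigued", "very_fatigued")}.
#' @return \code{"alert"}, \code{"fatigued"} or \code{"discordant"}.
#' @export
consensus_label <- function(votes_min1, votes_min2) {
  ok <- c("alert", "fatigued", "very_fatigued")
  for (v in list(votes_min1, votes_min2)) {
    if (length(v) != 5) stop("each minute needs exactly 5 ratings")
    if (!all(v %in% ok)) stop("unknown rating category")
  }
  n_alert <- c(sum(votes_min1 == "alert"), sum(votes_min2 == "alert"))
  n_fat <- c(sum(votes_min1 %in% c("fatigued", "very_fatigued")),
             sum(votes_min2 %in% c("fatigued", "very_fatigued")))
  if (all(n_alert >= 3)) "alert"
  else if (all(n_fat >= 3)) "fatigued"
  else "discordant"
}

#' Label the segments of one subject from the vote matrix
#'
#' Applies \code{consensus_label} to each segment using the votes of the two
#' minutes the window spans. Windows whose minutes extend beyond the vote
#' matrix are labelled \code{discordant}. Requires whole-minute window
#' alignment (the study design: 120 s windows on a 60 s grid).
#'
#' @param segments list of \code{segment}s from \code{segment_recording}.
#' @param votes vote matrix from \code{generate_expert_votes} (one row per
#'   minute).
#' @return The segments with \code{label} filled in.
#' @export
label_segments <- function(segments, votes) {
  lapply(segments, function(seg) {
    m1 <- seg$start_s / 60 + 1
    m2 <- m1 + 1
    if (m1 != round(m1) || seg$end_s - seg$start_s != 120) {
      stop("consensus labelling requires 120 s windows aligned to minutes")
    }
    seg$label <- if (m2 > nrow(votes)) "discordant"
    else consensus_label(votes[m1, ], votes[m2, ])
    seg
  })
}

#' Drop discordant segments
#'
#' Retains only the segments carrying an \code{alert} or \code{fatigued}
#' consensus; discordant windows are excluded from all further analysis.
#'
#' @param segments list of labelled \code{segment}s.
#' @param quiet suppress the per-label count message.
#' @return Filtered list; warns if nothing survives.
#' @export
filter_discordant <- function(segments, quiet = FALSE) {
  labels <- vapply(segments, function(s) s$label, character(1))
  keep <- labels %in% c("alert", "fatigued")
  if (!quiet) {
    sexes <- vapply(segments, function(s) s$sex, character(1))
    tab <- table(label = labels, sex = sexes)
    message("segment labels by sex:\n",
            paste(utils::capture.output(print(tab)), collapse = "\n"))
  }
  out <- segments[keep]
  if (length(out) == 0) warning("all segments are discordant")
  out
}

#' Segment table
#'
#' Summarises a list of segments as a data frame (subject, sex, window index,
#' start time, label, beat count), the interchange format written between
#' pipeline stages.
#'
#' @param segments list of \code{segment}s.
#' @return A \code{data.frame}, one row per segment.
#' @export
segment_table <- function(segments) {
  data.frame(
    subject_id = vapply(segments, function(s) s$subject_id, character(1)),
    sex = vapply(segments, function(s) s$sex, character(1)),
    window_index = vapply(segments, function(s) s$window_index, numeric(1)),
    start_s = vapply(segments, function(s) s$start_s, numeric(1)),
    label = vapply(segments, function(s) s$label, character(1)),
    n_beats = vapply(segments, function(s) length(s$rr$intervals), numeric(1)),
    stringsAsFactors = FALSE
  )
}
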