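#' State parameters for the RR-interval generator
#'
#' Parameters of the interval-domain model used to synthesise RR series for
#' one mental state:
#' \deqn{RR_i = \mu + A_{LF} \sin(2\pi f_{LF} t_i) + A_{HF} \sin(2\pi f_{HF} t_i) + \epsilon_i}
#' with \eqn{t_i} the cumulative beat time, \eqn{f_{LF} = 0.1} Hz,
#' \eqn{f_{HF} = 0.25} Hz and \eqn{\epsilon_i} white Gaussian noise. A pure
#' sinusoidal modulation of amplitude \eqn{A} contributes band power
#' \eqn{A^2/2} (ms^2), which is how the defaults are calibrated: amplitudes
#' are \eqn{\sqrt{2 P}} for a target band power \eqn{P}, and the white-noise
#' SD tops the interval SD up to the target overall SDNN.
#'
#' @param mean_rr_ms mean RR interval (ms), > 0.
#' @param sd_noise_ms SD of the additive white noise (ms), >= 0.
#' @param amp_lf_ms amplitude of the 0.1 Hz (low-frequency) modulation (ms).
#' @param amp_hf_ms amplitude of the 0.25 Hz (high-frequency) modulation (ms).
#' @return A list of class \code{state_params}.
#' @export
state_params <- function(mean_rr_ms, sd_noise_ms, amp_lf_ms, amp_hf_ms) {
  if (!is.numeric(mean_rr_ms) || mean_rr_ms <= 0) {
    stop("mean_rr_ms must be positive")
  }
  if (sd_noise_ms < 0 || amp_lf_ms < 0 || amp_hf_ms < 0) {
    stop("noise SD and modulation amplitudes must be non-negative")
  }
  structure(
    list(mean_rr_ms = mean_rr_ms, sd_noise_ms = sd_noise_ms,
         amp_lf_ms = amp_lf_ms, amp_hf_ms = amp_hf_ms),
    class = "state_params"
  )
}

#' Default generator parameters per mental state and sex
#'
#' Defaults are calibrated so the synthetic alert and fatigued groups shift in
#' the directions reported for real drivers: fatigue lengthens the mean RR
#' interval, inflates overall and band-limited variability, and does so more
#' strongly in males than in females. Sinusoid amplitudes follow
#' \eqn{A = \sqrt{2 P}} from the target LF/HF band powers; the white-noise SD
#' completes the target SDNN.
#'
#' @param state \code{"alert"} or \code{"fatigued"}.
#' @param sex \code{"male"}, \code{"female"}, or \code{"any"} for the
#'   sex-independent calibration (alert mean 801 ms, fatigued mean 870 ms).
#' @return A \code{state_params} object.
#' @export
default_state_params <- function(state = c("alert", "fatigued"),
                                 sex = c("any", "male", "female")) {
  state <- match.arg(state)
  sex <- match.arg(sex)
  tab <- list(
    any = list(
      alert    = state_params(801.4, 28.3, 38.2, 32.2),
      fatigued = state_params(869.9, 44.0, 53.1, 38.7)
    ),
    male = list(
      alert    = state_params(815.9, 29.6, 43.6, 34.7),
      fatigued = state_params(907.0, 52.0, 62.6, 41.3)
    ),
    female = list(
      alert    = state_params(788.2, 27.6, 32.4, 29.8),
      fatigued = state_params(835.3, 37.7, 42.4, 36.2)
    )
  )
  tab[[sex]][[state]]
}

#' Cohort configuration for the synthetic study
#'
#' Describes the simulated cohort: number of male and female subjects, the
#' recording duration, and the range (as fractions of the duration) in which
#' each subject's single alert-to-fatigued changepoint falls. At the default
#' 60-minute duration the default onset range corresponds to minutes 15-30,
#' so every subject contributes both alert and fatigued time with fatigue in
#' the majority.
#'
#' @param n_male,n_female subject counts (>= 0, at least one subject total).
#' @param duration_s recording duration in seconds (default 3600).
#' @param onset_range fraction of \code{duration_s} in which the fatigue
#'   onset is drawn uniformly per subject; length-2 numeric in [0, 1].
#' @param error_rate per-rating probability that a simulated expert reports a
#'   state inconsistent with the true one (default 0.1), must be in [0, 0.5).
#' @param seed integer seed controlling all randomness in the cohort.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_male = 9, n_female = 9, duration_s = 3600,
                          onset_range = c(0.25, 0.5), error_rate = 0.1,
                          seed = 1L) {
  if (n_male < 0 || n_female < 0 || n_male + n_female < 1) {
    stop("cohort needs n_male >= 0, n_female >= 0 and at least one subject")
  }
  if (duration_s <= 0) stop("duration_s must be positive")
  if (length(onset_range) != 2 || any(onset_range < 0) ||
      any(onset_range > 1) || onset_range[1] > onset_range[2]) {
    stop("onset_range must be increasing fractions within [0, 1]")
  }
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  structure(
    list(n_male = as.integer(n_male), n_female = as.integer(n_female),
         duration_s = duration_s, onset_range = onset_range,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic RR-interval series for one mental state
#'
#' Interval-domain model: each interval is the state's mean RR plus sinusoidal
#' modulation at 0.1 Hz (LF) and 0.25 Hz (HF) evaluated at the cumulative beat
#' time, plus white Gaussian noise, floored at a positive minimum so intervals
#' stay physiological. Beats are appended until the cumulative time covers the
#' requested duration.
#'
#' Because beats sample the tachogram with density inversely proportional to
#' the local interval, the beat-averaged mean of such a series falls below
#' the programmed offset by approximately the time-modulated variance (the
#' sum of \code{amp^2/2} terms) divided by the mean (harmonic-sampling
#' bias). The generator compensates the offset by that amount so the
#' configured \code{mean_rr_ms} is the expected \emph{measured} mean RR;
#' with all amplitudes at zero the compensation vanishes and every interval
#' equals \code{mean_rr_ms} exactly (plus noise).
#'
#' @param duration_s duration to cover, in seconds (> 0).
#' @param params a \code{state_params} object.
#' @param seed optional integer seed; if supplied the output is reproducible.
#' @param floor_ms lower truncation for intervals (ms), default 300.
#' @param t0 start time offset in seconds; modulation phase is tied to
#'   absolute time so consecutive chunks of one recording join coherently.
#' @return An \code{rr_series} spanning at least \code{duration_s} seconds.
#' @export
generate_rr_series <- function(duration_s, params, seed = NULL,
                               floor_ms = 300, t0 = 0) {
  if (!inherits(params, "state_params")) stop("params must be state_params")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  # generous preallocation: shortest plausible beat is floor_ms
  n_max <- ceiling(duration_s * 1000 / floor_ms) + 2
  iv <- numeric(n_max)
  t <- t0
  n <- 0
  # harmonic-sampling bias compensation (see Details); only the
  # time-modulated components bias the beat-averaged mean -- per-beat white
  # noise is drawn after the beat arrives and carries no density weighting
  var_mod <- params$amp_lf_ms^2 / 2 + params$amp_hf_ms^2 / 2
  mu <- params$mean_rr_ms + var_mod / params$mean_rr_ms
  while (t - t0 < duration_s) {
    rr <- mu +
      params$amp_lf_ms * sin(2 * pi * 0.10 * t) +
      params$amp_hf_ms * sin(2 * pi * 0.25 * t) +
      (if (params$sd_noise_ms > 0) stats::rnorm(1, 0, params$sd_noise_ms) else 0)
    rr <- max(rr, floor_ms)
    n <- n + 1
    iv[n] <- rr
    t <- t + rr / 1000
  }
  rr_series(iv[seq_len(n)], t0 = t0)
}

#' Generate a synthetic ECG waveform from an RR series
#'
#' Places one stereotyped QRS-like template at each cumulative beat time. The
#' template is a tall positive R deflection (a narrow Gaussian) flanked by
#' small negative Q and S waves and a low, broad T wave, so the R peak
#' strictly dominates every other deflection. Intended to exercise the
#' 1 kHz ECG ingest and R-peak detection path, not to model ECG morphology.
#'
#' @param rr an \code{rr_series}.
#' @param fs sampling frequency in Hz, >= 100.
#' @param subject_id,sex metadata carried on the record.
#' @param pad_s quiet lead-in/lead-out (s) so boundary QRS complexes are not
#'   truncated by the record edges.
#' @return An \code{ecg_record}: list with \code{samples} (mV), \code{fs},
#'   \code{subject_id}, \code{sex}, and \code{beat_times} (s, ground-truth
#'   R-peak times on the record's own time axis).
#' @export
generate_ecg <- function(rr, fs = 1000, subject_id = "synthetic",
                         sex = "any", pad_s = 0.5) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 100) stop("fs must be >= 100 Hz to resolve the QRS complex")
  if (length(rr$intervals) == 0) {
    return(ecg_record(numeric(0), fs, subject_id, sex, beat_times = numeric(0)))
  }
  beat_times <- rr$timestamps - rr$timestamps[1] + pad_s
  dur <- max(beat_times) + pad_s
  n <- ceiling(dur * fs)
  x <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  # template components, widths in seconds
  add_wave <- function(x, centre, amp, width) {
    lo <- max(1, floor((centre - 4 * width) * fs) + 1)
    hi <- min(n, ceiling((centre + 4 * width) * fs) + 1)
    idx <- lo:hi
    x[idx] <- x[idx] + amp * exp(-((tt[idx] - centre)^2) / (2 * width^2))
    x
  }
  for (bt in beat_times) {
    x <- add_wave(x, bt, 1.0, 0.012)            # R
    x <- add_wave(x, bt - 0.025, -0.15, 0.010)  # Q
    x <- add_wave(x, bt + 0.025, -0.20, 0.010)  # S
    x <- add_wave(x, bt + 0.18, 0.25, 0.045)    # T
  }
  ecg_record(x, fs, subject_id, sex, beat_times = beat_times)
}

#' Simulate per-minute expert mental-state votes
#'
#' Five independent raters report the driver's state once per minute. Each
#' rating matches the true state with probability \code{1 - error_rate};
#' otherwise the rater reports the opposite binary state (\code{fatigued}
#' for an alert minute, \code{alert} for a fatigued minute). A correct
#' rating of a fatigued minute is reported as \code{very_fatigued} with
#' probability 0.3: the deeper fatigue level appears only during true
#' fatigue, and downstream labelling pools it with \code{fatigued}.
#'
#' @param true_timeline character vector, one of \code{"alert"}/\code{"fatigued"}
#'   per minute of the recording.
#' @param error_rate probability of an inconsistent rating, in [0, 0.5).
#' @param seed optional integer seed.
#' @param n_raters number of raters per minute (default 5).
#' @param p_very probability a correct fatigued rating is reported as
#'   \code{very_fatigued} (default 0.3).
#' @return Character matrix of votes, \code{length(true_timeline)} rows by
#'   \code{n_raters} columns, values in
#'   \code{c("alert", "fatigued", "very_fatigued")}.
#' @export
generate_expert_votes <- function(true_timeline, error_rate = 0.1,
                                  seed = NULL, n_raters = 5, p_very = 0.3) {
  if (!all(true_timeline %in% c("alert", "fatigued"))) {
    stop("true_timeline values must be 'alert' or 'fatigued'")
  }
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_min <- length(true_timeline)
  votes <- matrix("", nrow = n_min, ncol = n_raters)
  for (i in seq_len(n_min)) {
    for (j in seq_len(n_raters)) {
      wrong <- stats::runif(1) < error_rate
      votes[i, j] <- if (true_timeline[i] == "alert") {
        if (wrong) "fatigued" else "alert"
      } else {
        if (wrong) "alert"
        else if (stats::runif(1) < p_very) "very_fatigued" else "fatigued"
      }
    }
  }
  colnames(votes) <- paste0("rater", seq_len(n_raters))
  votes
}

#' Simulate one subject's recording
#'
#' Concatenates an alert RR stretch and a fatigued stretch at the subject's
#' fatigue-onset changepoint (modulation phase continuous across the join),
#' builds the true per-minute state timeline, and simulates the expert votes.
#'
#' @param subject_id identifier string.
#' @param sex \code{"male"} or \code{"female"}.
#' @param duration_s recording duration (s).
#' @param onset_s fatigue onset time (s), within \code{[0, duration_s]}.
#' @param error_rate rater error rate.
#' @param seed integer seed for this subject.
#' @param params_alert,params_fatigued \code{state_params}; defaults are the
#'   sex-specific calibrations.
#' @return List with \code{subject_id}, \code{sex}, \code{rr} (rr_series),
#'   \code{onset_s}, \code{timeline} (per-minute truth), \code{votes}.
#' @export
simulate_subject <- function(subject_id, sex, duration_s, onset_s,
                             error_rate = 0.1, seed = 1L,
                             params_alert = default_state_params("alert", sex),
                             params_fatigued = default_state_params("fatigued", sex)) {
  stopifnot(onset_s >= 0, onset_s <= duration_s)
  set.seed(as.integer(seed))
  if (onset_s == 0) {
    rr <- generate_rr_series(duration_s, params_fatigued)
  } else if (onset_s >= duration_s) {
    rr <- generate_rr_series(duration_s, params_alert)
  } else {
    rr_a <- generate_rr_series(onset_s, params_alert)
    t_join <- rr_a$timestamps[length(rr_a$timestamps)]
    rr_f <- generate_rr_series(duration_s - t_join, params_fatigued, t0 = t_join)
    rr <- rr_series(c(rr_a$intervals, rr_f$intervals))
  }
  n_min <- floor(duration_s / 60)
  minute_mid <- (seq_len(n_min) - 0.5) * 60
  timeline <- ifelse(minute_mid < onset_s, "alert", "fatigued")
  votes <- generate_expert_votes(timeline, error_rate)
  list(subject_id = subject_id, sex = sex, rr = rr, onset_s = onset_s,
       timeline = timeline, votes = votes)
}

#' Simulate a full cohort
#'
#' Draws each subject's fatigue onset uniformly from the configured range and
#' simulates the RR recording and expert votes. All randomness derives from
#' \code{config$seed}, so identical configurations reproduce identical
#' cohorts.
#'
#' @param config a \code{cohort_config}.
#' @param params optional named list with elements \code{male} and
#'   \code{female}, each a list with \code{alert} and \code{fatigued}
#'   \code{state_params}; defaults to the sex-specific calibrations.
#' @return List of subject records as returned by \code{simulate_subject}.
#' @export
simulate_cohort <- function(config, params = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  sexes <- c(rep("male", config$n_male), rep("female", config$n_female))
  ids <- sprintf("S%02d", seq_along(sexes))
  set.seed(config$seed)
  onsets <- stats::runif(length(sexes),
                         config$onset_range[1] * config$duration_s,
                         config$onset_range[2] * config$duration_s)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, length(sexes))
  lapply(seq_along(sexes), function(i) {
    sx <- sexes[i]
    pa <- if (is.null(params)) default_state_params("alert", sx) else params[[sx]]$alert
    pf <- if (is.null(params)) default_state_params("fatigued", sx) else params[[sx]]$fatigued
    simulate_subject(ids[i], sx, config$duration_s, onsets[i],
                     error_rate = config$error_rate, seed = subj_seeds[i],
                     params_alert = pa, params_fatigued = pf)
  })
}
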