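#' Spectral analysis configuration
#'
#' Settings for the frequency-domain HRV features: the tachogram is resampled
#' evenly (cubic interpolation), linearly detrended, and its power spectral
#' density estimated by an averaged (Welch) periodogram; band powers are
#' integrated over the VLF, LF and HF bands. Short segments make the VLF band
#' physiologically unreliable, so VLF contributes only to the total power and
#' the normalized units are band/(LF+HF)*100.
#'
#' @param resample_hz even resampling rate (Hz), default 4.
#' @param vlf,lf,hf band edges in Hz (length-2 each); contiguous and
#'   increasing, HF upper edge at most the Nyquist rate.
#' @param window_s periodogram window length (s), default 64.
#' @param overlap window overlap fraction, default 0.5.
#' @return A list of class \code{spectral_config}.
#' @export
spectral_config <- function(resample_hz = 4,
                            vlf = c(0.0033, 0.04),
                            lf = c(0.04, 0.15),
                            hf = c(0.15, 0.40),
                            window_s = 64, overlap = 0.5) {
  edges <- c(vlf, lf, hf)
  if (!(vlf[1] > 0 && vlf[2] == lf[1] && lf[2] == hf[1] &&
        all(diff(edges[c(1, 2, 4, 6)]) > 0) && hf[2] <= resample_hz / 2)) {
    stop("band edges must be contiguous, increasing, and below Nyquist")
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  structure(
    list(resample_hz = resample_hz, vlf = vlf, lf = lf, hf = hf,
         window_s = window_s, overlap = overlap),
    class = "spectral_config"
  )
}

#' Time-domain HRV features
#'
#' @param rr an \code{rr_series} with at least 2 intervals.
#' @param threshold_ms difference threshold for NNN/pNN (ms), default 15: the
#'   count of successive pairs differing by more than the threshold and its
#'   percentage of all intervals.
#' @return Named list: \code{MRR} (ms, mean RR), \code{DRR} (ms, sample SD of
#'   RR), \code{MHR} (1/min, mean of the instantaneous rates 60000/RR),
#'   \code{DRMS} (ms, RMS of successive differences), \code{NNN15} (beats),
#'   \code{pNN15} (\%, NNN15 / number of intervals * 100).
#' @export
time_domain <- function(rr, threshold_ms = 15) {
  stopifnot(inherits(rr, "rr_series"))
  iv <- rr$intervals
  if (length(iv) < 2) stop("time-domain features need at least 2 intervals")
  d <- diff(iv)
  nnn <- sum(abs(d) > threshold_ms)
  list(
    MRR = mean(iv),
    DRR = stats::sd(iv),
    MHR = mean(60000 / iv),
    DRMS = sqrt(mean(d^2)),
    NNN15 = nnn,
    pNN15 = nnn / length(iv) * 100
  )
}

# Averaged (Welch) one-sided periodogram with a Hann window.
# Returns freq (Hz) and psd (ms^2/Hz) scaled so that sum(psd) * df
# estimates the variance of x.
welch_psd <- function(x, fs, window_s, overlap) {
  nw <- min(length(x), round(window_s * fs))
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hann
  scale <- fs * sum(w^2)
  acc <- numeric(nw)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2 / scale
  }
  p <- acc / length(starts)
  half <- floor(nw / 2)
  psd <- p[seq_len(half + 1)]
  # one-sided: double everything except DC (and Nyquist when nw even)
  dbl <- 2:(half + if (nw %% 2 == 0) 0 else 1)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (0:half) * fs / nw, psd = psd, df = fs / nw)
}

# Resample the tachogram evenly and detrend linearly.
resample_tachogram <- function(rr, resample_hz) {
  t_end <- rr$timestamps[-1]
  iv <- rr$intervals
  tt <- seq(t_end[1], t_end[length(t_end)], by = 1 / resample_hz)
  x <- stats::spline(t_end, iv, xout = tt, method = "fmm")$y
  fit <- stats::lm.fit(cbind(1, tt), x)
  list(t = tt, x = as.numeric(fit$residuals))
}

#' Frequency-domain HRV features
#'
#' Resamples the RR tachogram evenly, detrends it linearly, estimates the PSD
#' with an averaged periodogram and integrates band powers.
#'
#' @param rr an \code{rr_series} spanning at least 60 s with at least 30
#'   beats.
#' @param cfg a \code{spectral_config}.
#' @return Named list: \code{PLF_abs}, \code{PHF_abs}, \code{Ptot_abs}
#'   (ms^2; total = VLF + LF + HF), \code{PLF_nu}, \code{PHF_nu}
#'   (normalized units, band/(LF+HF)*100), \code{rLF_HF}. Normalized units
#'   and the ratio are \code{NA} when LF + HF power is zero.
#' @export
frequency_domain <- function(rr, cfg = spectral_config()) {
  stopifnot(inherits(rr, "rr_series"), inherits(cfg, "spectral_config"))
  span <- rr$timestamps[length(rr$timestamps)] - rr$timestamps[1]
  if (span < 60 || length(rr$intervals) < 30) {
    stop("frequency-domain features need >= 60 s of data and >= 30 beats")
  }
  rs <- resample_tachogram(rr, cfg$resample_hz)
  ps <- welch_psd(rs$x, cfg$resample_hz, cfg$window_s, cfg$overlap)
  band_power <- function(band) {
    sel <- ps$freq > band[1] & ps$freq <= band[2]
    sum(ps$psd[sel]) * ps$df
  }
  p_vlf <- band_power(cfg$vlf)
  p_lf <- band_power(cfg$lf)
  p_hf <- band_power(cfg$hf)
  # a numerically flat tachogram has no band power at all
  if (p_vlf + p_lf + p_hf < 1e-12) p_vlf <- p_lf <- p_hf <- 0
  denom <- p_lf + p_hf
  list(
    PLF_abs = p_lf,
    PHF_abs = p_hf,
    PLF_nu = if (denom > 0) p_lf / denom * 100 else NA_real_,
    PHF_nu = if (denom > 0) p_hf / denom * 100 else NA_real_,
    rLF_HF = if (p_hf > 0) p_lf / p_hf else NA_real_,
    Ptot_abs = p_vlf + p_lf + p_hf
  )
}

#' Poincare-plot HRV features
#'
#' Dispersion of the lagged scatterplot of successive RR intervals:
#' \code{LSD1^2} is half the population variance of the successive
#' differences (short-term variability, perpendicular to the identity line)
#' and \code{LSD2^2 = 2 * popvar(RR) - LSD1^2} (long-term, along the
#' identity line). Population (1/n) variances are used so the decomposition
#' \code{LSD1^2 + LSD2^2 = 2 var(RR)} is exact.
#'
#' @param rr an \code{rr_series} with at least 3 intervals.
#' @return Named list \code{LSD1}, \code{LSD2} (ms), \code{rSD2_SD1}
#'   (\code{NA} when LSD1 is zero).
#' @export
poincare <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  iv <- rr$intervals
  if (length(iv) < 3) stop("Poincare features need at least 3 intervals")
  popvar <- function(x) mean((x - mean(x))^2)
  d <- diff(iv)
  sd1 <- sqrt(popvar(d) / 2)
  sd2sq <- 2 * popvar(iv) - sd1^2
  sd2 <- sqrt(max(sd2sq, 0))
  list(
    LSD1 = sd1,
    LSD2 = sd2,
    rSD2_SD1 = if (sd1 > 0) sd2 / sd1 else NA_real_
  )
}

# Logical match matrix between all pairs of m-length templates under
# Chebyshev distance <= r. x is the series; returns matrix over template
# start indices 1..(length(x) - m + 1).
template_matches <- function(x, m, r) {
  n <- length(x)
  nt <- n - m + 1
  d1 <- abs(outer(x, x, "-")) <= r
  acc <- d1[seq_len(nt), seq_len(nt), drop = FALSE]
  if (m > 1) {
    for (k in seq_len(m - 1)) {
      acc <- acc & d1[seq_len(nt) + k, seq_len(nt) + k, drop = FALSE]
    }
  }
  acc
}

#' Approximate entropy (ApEn)
#'
#' Standard Pincus definition with self-matches included and Chebyshev
#' distance: \code{ApEn(m, r) = Phi_m - Phi_(m+1)} where \code{Phi_m} is the
#' mean log fraction of templates within tolerance \code{r}.
#'
#' @param rr an \code{rr_series} (or plain numeric vector) of length at least
#'   \code{m + 2}.
#' @param m template length (default 2).
#' @param r tolerance in ms; must be non-negative.
#' @return ApEn value (dimensionless); 0 for a constant series.
#' @export
approximate_entropy <- function(rr, m = 2, r = NULL) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  if (r < 0) stop("tolerance r must be non-negative")
  n <- length(x)
  if (n < m + 2) stop("series too short for ApEn: need length >= m + 2")
  phi <- function(mm) {
    mm_match <- template_matches(x, mm, r)
    mean(log(rowSums(mm_match) / ncol(mm_match)))
  }
  phi(m) - phi(m + 1)
}

#' Sample entropy (SampEn)
#'
#' \code{SampEn(m, r) = -ln(A / B)} where \code{B} counts template pairs of
#' length \code{m} within tolerance \code{r} and \code{A} the pairs still
#' matching at length \code{m + 1}; self-matches are excluded and both counts
#' run over the same \code{N - m} templates (Chebyshev distance).
#'
#' @inheritParams approximate_entropy
#' @return SampEn value; 0 for a constant series; \code{NA} with a warning
#'   when no matches exist at either length.
#' @export
sample_entropy <- function(rr, m = 2, r = NULL) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  if (r < 0) stop("tolerance r must be non-negative")
  n <- length(x)
  if (n < m + 2) stop("series too short for SampEn: need length >= m + 2")
  nt <- n - m  # templates used at both lengths
  count_pairs <- function(mm) {
    mat <- template_matches(x, mm, r)[seq_len(nt), seq_len(nt), drop = FALSE]
    (sum(mat) - nt) / 2  # exclude self-matches, unordered pairs
  }
  b <- count_pairs(m)
  a <- count_pairs(m + 1)
  if (b == 0 || a == 0) {
    warning("SampEn undefined: no template matches at tolerance r")
    return(NA_real_)
  }
  -log(a / b)
}

#' Detrended fluctuation analysis scaling exponents
#'
#' The mean-centered series is integrated; for each box size the integrated
#' profile is cut into boxes covered from both the start and the end of the
#' series, each box is linearly detrended, and \code{F(n)} is the RMS
#' residual. \code{alpha} is the least-squares slope of \code{log F(n)} vs
#' \code{log n} over each box-size range: 4-16 beats for the short-range
#' exponent, 16-64 for the long-range one.
#'
#' @param rr an \code{rr_series} or numeric vector.
#' @param short_range,long_range inclusive box-size ranges (beats).
#' @return Named list \code{alpha1}, \code{alpha2}; an exponent is \code{NA}
#'   when the series is too short for its range (fewer than 2 boxes at the
#'   largest size, or minimum lengths of 20 / 70 beats) or has zero variance.
#' @export
dfa <- function(rr, short_range = c(4, 16), long_range = c(16, 64)) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  n <- length(x)
  if (stats::sd(x) == 0) return(list(alpha1 = NA_real_, alpha2 = NA_real_))
  y <- cumsum(x - mean(x))
  fluct <- function(box) {
    nb <- n %/% box
    if (nb < 2) return(NA_real_)
    qrd <- qr(cbind(1, seq_len(box)))
    fwd <- matrix(y[seq_len(nb * box)], nrow = box)
    bwd <- matrix(y[(n - nb * box + 1):n], nrow = box)
    res2 <- sum(qr.resid(qrd, fwd)^2) + sum(qr.resid(qrd, bwd)^2)
    sqrt(res2 / (2 * nb * box))
  }
  slope_over <- function(range, min_len) {
    if (n < min_len) return(NA_real_)
    sizes <- seq(range[1], range[2])
    sizes <- sizes[n %/% sizes >= 2]
    if (length(sizes) < 3) return(NA_real_)
    fn <- vapply(sizes, fluct, numeric(1))
    ok <- is.finite(fn) & fn > 0
    if (sum(ok) < 3) return(NA_real_)
    stats::coef(stats::lm.fit(cbind(1, log(sizes[ok])), log(fn[ok])))[2]
  }
  list(alpha1 = unname(slope_over(short_range, 20)),
       alpha2 = unname(slope_over(long_range, 70)))
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Delay-embeds the series, computes correlation sums \code{C(rho)} over
#' Euclidean pair distances (pairs closer than the Theiler window \code{tau}
#' in time are excluded), and estimates \code{D2} as the least-squares slope
#' of \code{log C} vs \code{log rho} over an automatically selected scaling
#' region (radii where \code{C} lies in [0.005, 0.5], widened if too few
#' points qualify).
#'
#' On ~150-beat windows with the default 10-dimensional embedding the
#' estimate is data-starved; the result then carries
#' \code{attr(, "reliable") = FALSE} rather than being suppressed.
#'
#' @param rr an \code{rr_series} or numeric vector.
#' @param m embedding dimension (default 10).
#' @param tau embedding delay in beats (default 1); also the Theiler
#'   exclusion window.
#' @param max_points cap on embedded vectors used (pairs grow quadratically);
#'   vectors are thinned evenly beyond it.
#' @param n_radii number of log-spaced radii evaluated.
#' @return \code{D2} estimate with attribute \code{reliable}; \code{NA} when
#'   fewer than \code{m * tau + 10} points are available or the distances are
#'   degenerate.
#' @export
correlation_dimension <- function(rr, m = 10, tau = 1, max_points = 1200,
                                  n_radii = 30) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  n <- length(x)
  if (n < m * tau + 10) return(structure(NA_real_, reliable = FALSE))
  nv <- n - (m - 1) * tau
  emb <- sapply(seq_len(m), function(k) x[seq_len(nv) + (k - 1) * tau])
  idx <- seq_len(nv)
  if (nv > max_points) {
    idx <- round(seq(1, nv, length.out = max_points))
    emb <- emb[idx, , drop = FALSE]
  }
  dmat <- as.matrix(stats::dist(emb))
  sep <- abs(outer(idx, idx, "-"))
  keep <- upper.tri(dmat) & sep > tau
  d <- dmat[keep]
  d <- d[d > 0]
  if (length(d) < 50) return(structure(NA_real_, reliable = FALSE))
  rho <- exp(seq(log(stats::quantile(d, 0.005)), log(max(d)),
                 length.out = n_radii))
  cc <- vapply(rho, function(r) mean(d <= r), numeric(1))
  sel <- cc >= 0.005 & cc <= 0.5
  if (sum(sel) < 5) sel <- cc > 0 & cc < 1
  if (sum(sel) < 3) return(structure(NA_real_, reliable = FALSE))
  slope <- stats::coef(stats::lm.fit(cbind(1, log(rho[sel])),
                                     log(cc[sel])))[2]
  nv_used <- nrow(emb)
  structure(unname(slope), reliable = nv_used >= 1000)
}

#' Names of the twenty HRV features, in report order
#' @return Character vector of length 20.
#' @export
hrv_feature_names <- function() {
  c("MRR", "DRR", "MHR", "DRMS", "NNN15", "pNN15",
    "PLF_abs", "PHF_abs", "PLF_nu", "PHF_nu", "rLF_HF", "Ptot_abs",
    "LSD1", "LSD2", "rSD2_SD1", "EAP", "ESamp", "alpha1", "alpha2", "D2")
}

#' Extract the full 20-feature HRV vector from one segment
#'
#' Entropy tolerance follows the common convention \code{r = 0.2 * SD} of the
#' segment's intervals (with a tiny positive floor so constant segments are
#' handled); embedding and box-size defaults are stated in the individual
#' feature functions.
#'
#' @param segment a \code{segment} (or bare \code{rr_series}) with at least
#'   60 beats.
#' @param cfg a \code{spectral_config}.
#' @param m_entropy embedding length for ApEn/SampEn (default 2).
#' @return Named list of the 20 features in \code{hrv_feature_names()} order.
#' @export
extract_features <- function(segment, cfg = spectral_config(),
                             m_entropy = 2) {
  rr <- if (inherits(segment, "rr_series")) segment else segment$rr
  seg_id <- if (inherits(segment, "segment")) {
    sprintf("%s/w%d", segment$subject_id, segment$window_index)
  } else "rr"
  if (length(rr$intervals) < 60) {
    stop(sprintf("segment %s has %d beats; need >= 60", seg_id,
                 length(rr$intervals)))
  }
  out <- tryCatch({
    td <- time_domain(rr)
    fd <- frequency_domain(rr, cfg)
    pc <- poincare(rr)
    r_tol <- max(0.2 * stats::sd(rr$intervals), .Machine$double.eps)
    ent <- list(
      EAP = approximate_entropy(rr, m = m_entropy, r = r_tol),
      ESamp = suppressWarnings(sample_entropy(rr, m = m_entropy, r = r_tol))
    )
    df_ <- dfa(rr)
    d2 <- suppressWarnings(correlation_dimension(rr))
    c(td, fd, pc, ent,
      list(alpha1 = df_$alpha1, alpha2 = df_$alpha2, D2 = as.numeric(d2)))
  }, error = function(e) {
    stop(sprintf("feature extraction failed for segment %s: %s",
                 seg_id, conditionMessage(e)))
  })
  out[hrv_feature_names()]
}

#' Feature matrix for a list of labelled segments
#'
#' One row per segment: subject, sex, label, then the twenty features in
#' report order. The interchange table between the feature-extraction and
#' statistics/classification stages.
#'
#' @param segments list of labelled \code{segment}s.
#' @param cfg a \code{spectral_config}.
#' @return A \code{data.frame}.
#' @export
feature_matrix <- function(segments, cfg = spectral_config()) {
  rows <- lapply(segments, function(seg) {
    fv <- extract_features(seg, cfg)
    cbind(
      data.frame(subject_id = seg$subject_id, sex = seg$sex,
                 window_index = seg$window_index, label = seg$label,
                 stringsAsFactors = FALSE),
      as.data.frame(fv)
    )
  })
  do.call(rbind, rows)
}
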