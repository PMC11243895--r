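#' Descriptive statistics for one feature in one group
#'
#' Mean, sample SD, and quartiles. Quartiles use linear interpolation between
#' order statistics (\code{quantile} type 7, the common default convention).
#'
#' @param values numeric sample, non-empty.
#' @return One-row \code{data.frame}: \code{n}, \code{mean}, \code{sd},
#'   \code{q1}, \code{median}, \code{q3}. \code{sd} is 0 for a single value.
#' @export
describe <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("cannot describe an empty sample")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  data.frame(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else 0,
    q1 = q[1], median = q[2], q3 = q[3]
  )
}

# Exact two-sided p by full enumeration of the C(n1+n2, n1) group labelings
# of the pooled values (handles ties, since the actual values are permuted).
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  r <- rank(pooled)
  combs <- utils::combn(n, n1)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(combs, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midranks for ties. For small samples
#' (\code{n1 + n2 <= exact_max}) the two-sided p-value comes from exact
#' enumeration of all group labelings; otherwise from the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @param alpha significance level used to call the direction of change
#'   (default 0.01).
#' @param exact_max largest pooled size for the exact-enumeration path
#'   (default 12).
#' @return List of class \code{mw_test}: \code{U} (statistic for sample
#'   \code{x}), \code{z}, \code{p} (two-sided), \code{exact},
#'   \code{tie_corrected}, and \code{direction} — \code{"increase"} /
#'   \code{"decrease"} of \code{y}'s median relative to \code{x}'s when
#'   \code{p < alpha}, else \code{"none"}.
#' @export
mann_whitney_u <- function(x, y, alpha = 0.01, exact_max = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (length(unique(pooled)) == 1) {
    p <- 1; z <- 0; exact <- FALSE
  } else if (n1 + n2 <= exact_max) {
    p <- mw_exact_p(x, y)
    z <- NA_real_
    exact <- TRUE
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    cc <- sign(u - mu) * 0.5
    z <- (u - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  direction <- if (p < alpha) {
    if (stats::median(y) > stats::median(x)) "increase"
    else if (stats::median(y) < stats::median(x)) "decrease"
    else "none"
  } else "none"
  structure(
    list(U = u, z = z, p = p, exact = exact, tie_corrected = has_ties,
         direction = direction, n1 = n1, n2 = n2),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), p = %.4g%s, %s\n",
              x$U, x$n1, x$n2, x$p, if (x$exact) " (exact)" else "",
              x$direction))
  invisible(x)
}

#' Alert-vs-fatigued comparison of all HRV features in one group
#'
#' For the chosen group (all subjects, males only, or females only), computes
#' descriptive statistics of every feature per mental state and the
#' Mann-Whitney comparison with the direction of change from alert to
#' fatigued. Segments are pooled across subjects; overlapping windows make
#' them statistically dependent, which this segment-wise design inherits
#' deliberately (see the package vignette). No multiple-testing correction is
#' applied across the twenty features.
#'
#' @param features feature matrix from \code{feature_matrix} (needs columns
#'   \code{sex}, \code{label} and the twenty features).
#' @param group \code{"all"}, \code{"male"} or \code{"female"}.
#' @param alpha significance level for flagging (default 0.01).
#' @return A \code{data.frame}, one row per feature: group sizes,
#'   alert/fatigued descriptives (mean, sd, q1, median, q3), \code{U},
#'   \code{p}, \code{significant}, \code{direction} (of the fatigued group
#'   relative to alert), and \code{arrow} (up/down/NS summary notation).
#' @export
compare_states <- function(features, group = c("all", "male", "female"),
                           alpha = 0.01) {
  group <- match.arg(group)
  df <- if (group == "all") features else features[features$sex == group, ]
  for (lab in c("alert", "fatigued")) {
    if (!any(df$label == lab)) {
      stop(sprintf("group '%s' has no '%s' segments", group, lab))
    }
  }
  rows <- lapply(hrv_feature_names(), function(f) {
    a <- df[[f]][df$label == "alert"]
    fa <- df[[f]][df$label == "fatigued"]
    da <- describe(a); dfat <- describe(fa)
    mt <- mann_whitney_u(a, fa, alpha = alpha)
    data.frame(
      feature = f, group = group,
      n_alert = da$n, mean_alert = da$mean, sd_alert = da$sd,
      q1_alert = da$q1, med_alert = da$median, q3_alert = da$q3,
      n_fatigued = dfat$n, mean_fatigued = dfat$mean, sd_fatigued = dfat$sd,
      q1_fatigued = dfat$q1, med_fatigued = dfat$median, q3_fatigued = dfat$q3,
      U = mt$U, p = mt$p, significant = mt$p < alpha,
      direction = mt$direction,
      arrow = switch(mt$direction, increase = "up", decrease = "down", "NS"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Direction-of-change summary across groups
#'
#' Condenses per-group comparison tables into one row per feature with the
#' up/down/NS arrow per group, the cross-group summary format.
#'
#' @param ... one or more tables from \code{compare_states}.
#' @return A \code{data.frame}: \code{feature} plus one arrow column per
#'   group.
#' @export
direction_summary <- function(...) {
  tabs <- list(...)
  out <- data.frame(feature = hrv_feature_names(), stringsAsFactors = FALSE)
  for (tb in tabs) {
    g <- tb$group[1]
    out[[g]] <- tb$arrow[match(out$feature, tb$feature)]
  }
  out
}
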