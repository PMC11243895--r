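# Independent brute-force oracles used to validate the package
# implementations on small fixtures. Deliberately naive (double loops,
# exhaustive enumeration) and kept separate from the code paths they check.

# Approximate entropy, Pincus definition, O(n^2 m) double loop,
# self-matches included, Chebyshev distance.
oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    cs <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      cs[i] <- cnt / nt
    }
    mean(log(cs))
  }
  phi(m) - phi(m + 1)
}

# Sample entropy: pair counting over the N - m templates at both lengths,
# self-matches excluded.
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  count <- function(mm) {
    cnt <- 0
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  b <- count(m)
  a <- count(m + 1)
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# Exhaustive (feature, midpoint) scan minimising weighted child Gini with
# the same deterministic tie-breaking contract as the implementation:
# feature order first, then lower threshold, strict improvement only.
oracle_best_split <- function(x, y) {
  x <- as.matrix(x)
  g <- function(z) {
    if (length(z) == 0) return(0)
    p <- mean(z)
    1 - p^2 - (1 - p)^2
  }
  parent <- g(y)
  best <- list(feature = NA_character_, threshold = NA_real_,
               impurity = NA_real_)
  best_w <- parent
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (thr in utils::head(v, -1) + diff(v) / 2) {
      l <- y[x[, j] <= thr]
      r <- y[x[, j] > thr]
      w <- (length(l) * g(l) + length(r) * g(r)) / length(y)
      if (w < best_w - 1e-12) {
        best_w <- w
        best <- list(feature = colnames(x)[j], threshold = thr, impurity = w)
      }
    }
  }
  best
}

# Constant-interval RR segment of a given duration.
constant_rr <- function(rr_ms = 800, duration_s = 120) {
  n <- ceiling(duration_s * 1000 / rr_ms)
  rr_series(rep(rr_ms, n))
}
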