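test_that("time-domain features match hand-evaluated formulas", {
  rr <- rr_series(rep(800, 10))
  td <- time_domain(rr)
  expect_equal(td$MRR, 800)
  expect_equal(td$DRR, 0)
  expect_equal(td$MHR, 75)
  expect_equal(td$DRMS, 0)
  expect_equal(td$NNN15, 0)
  expect_equal(td$pNN15, 0)

  td2 <- time_domain(rr_series(c(800, 820, 824, 850)))
  expect_equal(td2$DRMS, sqrt((20^2 + 4^2 + 26^2) / 3))
  expect_equal(td2$DRMS, 19.0788, tolerance = 1e-4)
  expect_equal(td2$NNN15, 2)
  expect_equal(td2$pNN15, 50)  # denominator is all 4 intervals
  expect_error(time_domain(rr_series(800)), "2 intervals")
})

test_that("time-domain features are homogeneous under rescaling", {
  set.seed(6)
  iv <- 800 + rnorm(120, 0, 40)
  for (k in c(0.5, 2)) {
    a <- time_domain(rr_series(iv))
    b <- time_domain(rr_series(k * iv))
    expect_equal(b$MRR, k * a$MRR)
    expect_equal(b$DRR, k * a$DRR)
    expect_equal(b$DRMS, k * a$DRMS)
  }
})

test_that("normalized spectral units close to 100 on real segments", {
  set.seed(23)
  for (i in 1:5) {
    rr <- generate_rr_series(125, default_state_params("alert", "any"))
    fd <- frequency_domain(rr)
    expect_equal(fd$PLF_nu + fd$PHF_nu, 100)
    expect_equal(fd$rLF_HF, fd$PLF_abs / fd$PHF_abs)
    expect_gte(fd$Ptot_abs, fd$PLF_abs + fd$PHF_abs)
  }
})

test_that("a pure 0.25 Hz modulation lands in the HF band", {
  p <- state_params(800, 0, 0, 30)
  rr <- generate_rr_series(125, p)
  fd <- frequency_domain(rr)
  expect_gte(fd$PHF_nu, 95)
  expect_lte(fd$rLF_HF, 0.05)
  # band power of a sinusoid of amplitude A is about A^2/2
  expect_equal(fd$PHF_abs, 30^2 / 2, tolerance = 0.15)
})

test_that("total spectral power is Parseval-consistent with the variance", {
  set.seed(77)
  rr <- generate_rr_series(125, default_state_params("fatigued", "male"))
  rs <- hrvfatigue:::resample_tachogram(rr, 4)
  ps <- hrvfatigue:::welch_psd(rs$x, 4, 64, 0.5)
  total <- sum(ps$psd) * ps$df
  expect_equal(total, mean(rs$x^2), tolerance = 0.05)
})

test_that("frequency-domain contract rejects short series", {
  expect_error(frequency_domain(constant_rr(800, 30)), "60 s")
  expect_error(spectral_config(hf = c(0.15, 3)), "Nyquist")
  expect_error(spectral_config(lf = c(0.05, 0.15)), "band edges")
})

test_that("Poincare features follow the stated identities", {
  # constant series: no dispersion, undefined axis ratio
  pc <- poincare(constant_rr(800, 30))
  expect_equal(pc$LSD1, 0)
  expect_equal(pc$LSD2, 0)
  expect_true(is.na(pc$rSD2_SD1))

  # strict alternation: all dispersion perpendicular to identity line
  # (odd interval count: the +50/-50 differences pair up and center exactly)
  alt <- rr_series(c(rep(c(800, 850), 30), 800))
  pa <- poincare(alt)
  expect_equal(pa$LSD1, sqrt(2500 / 2))
  expect_equal(pa$LSD1, 35.3553, tolerance = 1e-4)

  # identity chain on random series: LSD1 = pop-RMS(diff)/sqrt(2) when the
  # differences are centered; LSD1^2 + LSD2^2 = 2 * popvar(RR)
  set.seed(30)
  for (i in 1:10) {
    iv <- 800 + rnorm(150, 0, 50)
    rr <- rr_series(iv)
    pc <- poincare(rr)
    d <- diff(iv)
    popvar <- function(z) mean((z - mean(z))^2)
    expect_equal(pc$LSD1, sqrt(popvar(d) / 2))
    expect_equal(pc$LSD1^2 + pc$LSD2^2, 2 * popvar(iv))
    # relation to DRMS up to mean-centering and the n/(n-1) convention
    td <- time_domain(rr)
    expect_equal(pc$LSD1, td$DRMS / sqrt(2), tolerance = 0.02)
  }
})

test_that("extract_features returns the 20 named features per segment", {
  rr <- generate_rr_series(125, default_state_params("alert", "female"),
                           seed = 3)
  fv <- extract_features(rr)
  expect_named(fv, hrv_feature_names())
  expect_length(fv, 20)
  expect_true(all(vapply(fv, is.numeric, logical(1))))
  expect_error(extract_features(rr_series(rep(800, 10))), ">= 60")
})

test_that("fatigued synthetic segments have larger DRR than alert ones", {
  set.seed(55)
  pa <- default_state_params("alert", "any")
  pf <- default_state_params("fatigued", "any")
  drr_a <- replicate(100, time_domain(generate_rr_series(120, pa))$DRR)
  drr_f <- replicate(100, time_domain(generate_rr_series(120, pf))$DRR)
  expect_gt(mean(drr_f), mean(drr_a))
  expect_gt(t.test(drr_f, drr_a)$statistic, 3)
})
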