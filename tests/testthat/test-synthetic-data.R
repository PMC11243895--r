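test_that("noiseless generator produces exactly the configured interval", {
  p <- state_params(800, 0, 0, 0)
  rr <- generate_rr_series(120, p)
  expect_true(all(rr$intervals == 800))
  expect_gte(rr$timestamps[length(rr$timestamps)], 120)
  expect_equal(diff(rr$timestamps), rr$intervals / 1000)
})

test_that("generator validates its inputs", {
  expect_error(generate_rr_series(0, state_params(800, 10, 5, 5)))
  expect_error(state_params(-1, 10, 5, 5), "positive")
  expect_error(state_params(800, -1, 5, 5), "non-negative")
  expect_error(cohort_config(0, 0), "at least one subject")
  expect_error(cohort_config(2, 2, onset_range = c(0.5, 0.2)))
})

test_that("per-series mean RR concentrates on the configured mean", {
  p <- default_state_params("fatigued", "any")
  set.seed(41)
  mrr <- replicate(100, mean(generate_rr_series(120, p)$intervals))
  # each series mean has SE ~ total SD / sqrt(n_beats); the replicate
  # average must fall within 3 SE of its own spread around the target
  expect_lt(abs(mean(mrr) - p$mean_rr_ms), 3 * sd(mrr) / sqrt(length(mrr)))
})

test_that("sex-independent fatigued calibration targets the 870 ms scale", {
  expect_equal(default_state_params("fatigued", "any")$mean_rr_ms, 869.9)
  expect_equal(default_state_params("alert", "any")$mean_rr_ms, 801.4)
})

test_that("identical seeds reproduce byte-identical RR output", {
  p <- default_state_params("alert", "male")
  a <- generate_rr_series(300, p, seed = 99)
  b <- generate_rr_series(300, p, seed = 99)
  expect_identical(a, b)
  d <- generate_rr_series(300, p, seed = 100)
  expect_false(identical(a$intervals, d$intervals))
})

test_that("increasing HF modulation amplitude raises extracted HF power", {
  amps <- c(5, 20, 40)
  set.seed(17)
  mean_phf <- vapply(amps, function(a) {
    p <- state_params(850, 15, 20, a)
    mean(replicate(50, frequency_domain(generate_rr_series(130, p))$PHF_abs))
  }, numeric(1))
  expect_true(all(diff(mean_phf) > 0))
})

test_that("expert votes are exact at zero error rate and reproducible", {
  tl <- c(rep("alert", 10), rep("fatigued", 10))
  v <- generate_expert_votes(tl, error_rate = 0, seed = 5)
  expect_equal(dim(v), c(20, 5))
  expect_true(all(v[1:10, ] == "alert"))
  expect_true(all(v[11:20, ] %in% c("fatigued", "very_fatigued")))
  expect_identical(v, generate_expert_votes(tl, error_rate = 0, seed = 5))
  expect_error(generate_expert_votes(tl, error_rate = 0.6), "0.5")
})

test_that("majority-correct minutes match the binomial tail prediction", {
  err <- 0.4
  tl <- rep("alert", 4000)
  v <- generate_expert_votes(tl, error_rate = err, seed = 21)
  frac <- mean(rowSums(v == "alert") >= 3)
  pred <- sum(dbinom(3:5, 5, 1 - err))  # P(>= 3 of 5 correct)
  mc_se <- sqrt(pred * (1 - pred) / length(tl))
  expect_lt(abs(frac - pred), 4 * mc_se)
})

test_that("very_fatigued appears only while truly fatigued", {
  tl <- c(rep("alert", 30), rep("fatigued", 30))
  v <- generate_expert_votes(tl, error_rate = 0.2, seed = 3)
  expect_false(any(v[1:30, ] == "very_fatigued"))
  expect_true(any(v[31:60, ] == "very_fatigued"))
})

test_that("cohort simulation is deterministic and honours the config", {
  cfg <- cohort_config(2, 3, duration_s = 600, seed = 7)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  expect_equal(vapply(co1, `[[`, character(1), "sex"),
               c("male", "male", "female", "female", "female"))
  onsets <- vapply(co1, `[[`, numeric(1), "onset_s")
  expect_true(all(onsets >= 150 & onsets <= 300))
})

test_that("zero-modulation cohort has zero variability features", {
  p <- state_params(800, 0, 0, 0)
  rr <- generate_rr_series(120, p)
  fv <- extract_features(rr)
  zero_feats <- c("DRR", "DRMS", "NNN15", "pNN15", "PLF_abs", "PHF_abs",
                  "Ptot_abs", "LSD1", "LSD2", "EAP", "ESamp")
  for (f in zero_feats) expect_equal(fv[[f]], 0, info = f)
  expect_equal(fv$MRR, 800)
})
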