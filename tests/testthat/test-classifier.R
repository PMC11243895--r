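# small labelled fixture: two informative features, one noise feature
make_fixture <- function(n = 12, seed = 50) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  data.frame(
    f1 = ifelse(y == 1, 5, 1) + rnorm(n, 0, 0.5),
    f2 = rnorm(n),
    f3 = ifelse(y == 1, -2, 2) + rnorm(n, 0, 2),
    label = y
  )
}

test_that("Gini impurity follows 1 - sum(p^2)", {
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(2, 8)), 0.32)
  expect_error(gini_impurity(c(0, 0)), "empty")
})

test_that("best_split separates 1-D data at the midpoint", {
  x <- matrix(c(1, 2, 9, 10), dimnames = list(NULL, "v"))
  s <- best_split(x, c(0, 0, 1, 1))
  expect_equal(s$feature, "v")
  expect_equal(s$threshold, 5.5)
  expect_equal(s$impurity, 0)
})

test_that("best_split matches exhaustive enumeration on random fixtures", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    x <- matrix(round(rnorm(n * 3), 1), n, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    got <- best_split(x, y)
    want <- oracle_best_split(x, y)
    expect_equal(got$feature, want$feature)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$impurity, want$impurity, tolerance = 1e-12)
  }
})

test_that("a constant feature column is never selected", {
  set.seed(52)
  x <- cbind(flat = rep(3, 10), info = c(rnorm(5), rnorm(5, 4)))
  y <- rep(0:1, each = 5)
  expect_equal(best_split(x, y)$feature, "info")
  expect_true(is.na(best_split(cbind(flat = rep(3, 10)), y)$feature))
})

test_that("linearly separable data yields a depth-1 tree, perfect training fit", {
  x <- data.frame(v = c(1, 1.5, 2, 9, 9.5, 10))
  y <- c("alert", "alert", "alert", "fatigued", "fatigued", "fatigued")
  tree <- build_tree(x, y, min_samples = 2)
  expect_equal(nrow(tree$nodes), 3)  # root + two leaves
  expect_equal(predict(tree, x), y)
})

test_that("min_samples >= n yields a single majority leaf with fatigued ties", {
  x <- data.frame(v = rnorm(10))
  tree <- build_tree(x, rep(c("alert", "fatigued"), 5), min_samples = 11)
  expect_equal(nrow(tree$nodes), 1)
  expect_equal(unique(predict(tree, x)), "fatigued")  # tie -> fatigued
})

test_that("child class counts always sum to the parent's", {
  fx <- make_fixture(40)
  tree <- build_tree(fx[, 1:3], fx$label, min_samples = 5)
  nd <- tree$nodes
  for (i in which(nd$feature > 0)) {
    expect_equal(nd$n_alert[nd$left[i]] + nd$n_alert[nd$right[i]],
                 nd$n_alert[i])
    expect_equal(nd$n_fatigued[nd$left[i]] + nd$n_fatigued[nd$right[i]],
                 nd$n_fatigued[i])
  }
  expect_true(all(nd$gini >= 0 & nd$gini <= 0.5))
})

test_that("training accuracy is non-decreasing as min_samples decreases", {
  fx <- make_fixture(60, seed = 53)
  acc <- vapply(c(60, 20, 10, 5, 2), function(ms) {
    tree <- build_tree(fx[, 1:3], fx$label, min_samples = ms)
    mean(predict(tree, fx[, 1:3]) ==
           c("alert", "fatigued")[fx$label + 1])
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("tree training predictions match an independent CART reference", {
  skip_if_not_installed("rpart")
  fx <- make_fixture(12, seed = 54)
  tree <- build_tree(fx[, 1:3], fx$label, min_samples = 4)
  ref <- rpart::rpart(factor(label) ~ f1 + f2 + f3, data = fx,
                      method = "class",
                      control = rpart::rpart.control(minsplit = 4,
                                                     minbucket = 1, cp = 0,
                                                     maxsurrogate = 0,
                                                     xval = 0))
  ours <- predict(tree, fx[, 1:3])
  theirs <- c("alert", "fatigued")[as.integer(
    predict(ref, fx, type = "class"))]
  expect_equal(ours, theirs)
})

test_that("prediction routes by threshold and validates features", {
  x <- data.frame(v = c(1, 2, 9, 10))
  tree <- build_tree(x, c(0, 0, 1, 1), min_samples = 2)
  probes <- data.frame(v = c(-5, 5.49, 5.51, 100, 5.5))
  expect_equal(predict(tree, probes),
               c("alert", "alert", "fatigued", "fatigued", "alert"))
  expect_error(predict(tree, data.frame(w = 1)), "missing feature")
})

test_that("train/test split is reproducible, stratified and 8:2", {
  sp <- train_test_split(100, rep(c("alert", "fatigued"), 50), seed = 9)
  expect_length(sp$test, 20)
  expect_length(sp$train, 80)
  labels <- c(rep("alert", 60), rep("fatigued", 140))
  sp2 <- train_test_split(200, labels, seed = 9)
  expect_equal(sum(labels[sp2$test] == "alert"), 12)
  expect_equal(sum(labels[sp2$test] == "fatigued"), 28)
  expect_identical(sp2, train_test_split(200, labels, seed = 9))
  expect_false(identical(sp2, train_test_split(200, labels, seed = 10)))
  expect_error(train_test_split(3, c("a", "a", "b")), "fewer than 2")
})

test_that("confusion metrics follow the stated formulas", {
  cm <- confusion_counts(tp = 9, tn = 8, fp = 1, fn = 2)
  expect_equal(cm$SEN, 9 / 11 * 100, tolerance = 1e-10)
  expect_equal(round(cm$SEN, 1), 81.8)
  expect_equal(round(cm$SPE, 1), 88.9)
  expect_equal(cm$PPV, 90)
  expect_equal(cm$ACC, 85)
  perfect <- confusion_counts(10, 10, 0, 0)
  expect_true(all(unlist(perfect[c("SEN", "SPE", "PPV", "ACC")]) == 100))
  none_alert <- confusion_counts(30, 0, 10, 0)  # all-fatigued predictor
  expect_equal(none_alert$SEN, 100)
  expect_equal(none_alert$SPE, 0)
  expect_equal(none_alert$PPV, 75)
  expect_equal(none_alert$ACC, 75)
  undef <- confusion_counts(0, 5, 0, 5)
  expect_true(is.na(undef$PPV))  # zero denominator flagged undefined
})

test_that("evaluate counts every test row exactly once", {
  fx <- make_fixture(50, seed = 56)
  sp <- train_test_split(50, fx$label, seed = 1)
  tree <- build_tree(fx[sp$train, 1:3], fx$label[sp$train])
  cm <- evaluate(tree, fx[sp$test, 1:3], fx$label[sp$test])
  expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, length(sp$test))
  expect_error(evaluate(tree, fx[0, 1:3], integer(0)), "empty")
})

test_that("subset search enumerates C(20, k) subsets and ranks by accuracy", {
  set.seed(57)
  n <- 80
  feats <- as.data.frame(matrix(rnorm(n * 20), n, 20,
                                dimnames = list(NULL, hrv_feature_names())))
  y <- rbinom(n, 1, 0.6)
  feats$MRR <- feats$MRR + 2.5 * y  # one informative feature
  feats$label <- c("alert", "fatigued")[y + 1]
  res1 <- exhaustive_subset_search(feats, 1, seed = 3)
  expect_equal(nrow(res1), 20)
  res2 <- exhaustive_subset_search(feats, 2, seed = 3)
  expect_equal(nrow(res2), choose(20, 2))
  expect_equal(res2$rank, seq_len(190))
  expect_true(all(diff(res2$ACC) <= 0))
  # the informative feature dominates the top subsets
  expect_true(grepl("MRR", res2$subset[1]))
  # same seed, same result
  expect_identical(res2, exhaustive_subset_search(feats, 2, seed = 3))
})
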