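algorithms <- c("DT", "DF", "RF", "kNN", "SVM", "LDA", "LR")

test_that("every algorithm reaches training accuracy 1 on a separable toy set", {
  ds <- separable_dataset(n_per_class = 25, gap = 8)
  for (a in algorithms) {
    # with 2 descriptors the decision forest legitimately stops at 2 trees
    fit <- suppressWarnings(fit_learner(learner_spec(a, seed = 1), ds))
    p <- predict_proba(fit, ds)
    expect_true(all(p >= 0 & p <= 1), info = a)
    expect_equal(mean(classify(p) == ds$label), 1, info = a)
  }
})

test_that("single-class training data and unknown algorithms are rejected", {
  ds <- separable_dataset()
  one_class <- labeled_dataset(ds$x, rep("positive", nrow(ds$x)))
  for (a in algorithms)
    expect_error(fit_learner(learner_spec(a, seed = 1), one_class), "class")
  expect_error(learner_spec("MLP"), "arg")
})

test_that("fits are deterministic given the spec seed", {
  st <- generate_study(quick_config(seed = 21))
  probe <- st$external
  for (a in algorithms) {
    f1 <- fit_learner(learner_spec(a, seed = 5), st$train)
    f2 <- fit_learner(learner_spec(a, seed = 5), st$train)
    expect_identical(predict_proba(f1, probe), predict_proba(f2, probe),
                     info = a)
  }
})

test_that("kNN probability is the fraction of positive neighbors", {
  # probe equidistant cluster: 5 nearest neighbors are known by construction
  x <- rbind(matrix(0.01 * rnorm(10), 5, 2), matrix(10 + rnorm(10), 5, 2))
  colnames(x) <- c("d1", "d2"); rownames(x) <- paste0("c", 1:10)
  # among the 5 chemicals near the origin, 3 are positive
  ds <- labeled_dataset(x, c("positive", "positive", "positive", "negative",
                             "negative", rep("negative", 5)))
  fit <- fit_learner(learner_spec("kNN", list(k = 5), seed = 1), ds)
  probe <- matrix(0, 1, 2, dimnames = list("q", c("d1", "d2")))
  expect_equal(unname(predict_proba(fit, probe)), 3 / 5)
})

test_that("decision-tree probability is the terminal-node positive proportion", {
  # one binary split separates groups; left leaf holds 4 positives and 1
  # negative placed strictly between them so it cannot be split away
  x <- matrix(c(0.00, 0.01, 0.02, 0.03, 0.04, 10 + 0:19), ncol = 1,
              dimnames = list(paste0("c", 1:25), "d1"))
  ds <- labeled_dataset(x, c("positive", "positive", "negative", "positive",
                             "positive", rep("negative", 20)))
  fit <- fit_learner(learner_spec("DT", list(maxdepth = 1, minbucket = 1, cp = 0), seed = 1), ds)
  probe <- matrix(0, 1, 1, dimnames = list("q", "d1"))
  expect_equal(unname(predict_proba(fit, probe)), 4 / 5)
})

test_that("Platt sigmoid maps margins as specified", {
  expect_equal(platt_probability(c(-3, 0, 2.7), A = 0, B = 0), rep(0.5, 3))
  expect_equal(platt_probability(0, A = 1, B = 0), 0.5)
  # negative A: larger margin => higher probability, bounded in (0, 1)
  p <- platt_probability(seq(-5, 5, by = 0.5), A = -2, B = 0.3)
  expect_true(all(diff(p) > 0) && all(p > 0 & p < 1))
})

test_that("decision forest trees use pairwise-disjoint descriptor sets", {
  st <- generate_study(quick_config(seed = 30, n_descriptors = 20,
                                    n_informative = 6, n_sparse = 0))
  fit <- fit_decision_forest(st$train, n_trees = 3, seed = 2)
  feats <- df_tree_features(fit)
  expect_gte(length(feats), 2)
  for (i in seq_along(feats))
    for (j in seq_len(i - 1))
      expect_length(intersect(feats[[i]], feats[[j]]), 0)
})

test_that("a dominant descriptor is consumed by exactly one tree", {
  set.seed(5)
  n <- 80
  champ <- c(rnorm(n / 2), rnorm(n / 2) + 10)      # perfectly separating
  weak <- matrix(rnorm(4 * n) + 0.4 * rep(c(0, 1), each = n / 2), n, 4)
  x <- cbind(champ = champ, weak)
  colnames(x)[2:5] <- paste0("w", 1:4)
  rownames(x) <- paste0("c", 1:n)
  ds <- labeled_dataset(x, rep(c("negative", "positive"), each = n / 2))
  fit <- suppressWarnings(fit_decision_forest(ds, n_trees = 3, seed = 1))
  feats <- df_tree_features(fit)
  expect_equal(sum(vapply(feats, function(f) "champ" %in% f, NA)), 1L)
})

test_that("decision forest stops early when descriptors run out", {
  ds <- separable_dataset(n_per_class = 30, gap = 8)  # only 2 descriptors
  expect_warning(fit <- fit_decision_forest(ds, n_trees = 6, seed = 1),
                 "stopped early")
  expect_gte(fit$fit$n_trees, 2)
  expect_error(fit_decision_forest(ds, n_trees = 1), "n_trees >= 2")
})

test_that("classification threshold calls 0.5 positive", {
  expect_equal(as.character(classify(c(0.5, 0.499, 1.0, 0))),
               c("positive", "negative", "positive", "negative"))
  expect_error(classify(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("thresholded probabilities agree with native class predictions", {
  st <- generate_study(quick_config(seed = 31))
  train <- st$train; probe <- st$external
  # DT native
  dt <- fit_learner(learner_spec("DT", seed = 1), train)
  native <- predict(dt$fit, data.frame(probe$x, check.names = FALSE), type = "class")
  p <- predict_proba(dt, probe)
  keep <- p != 0.5   # at exactly 0.5 the package rule is positive by fiat
  expect_equal(as.character(classify(p))[keep], as.character(native)[keep])
  # RF native
  rf <- fit_learner(learner_spec("RF", seed = 1), train)
  native_rf <- predict(rf$fit, probe$x, type = "response")
  p_rf <- predict_proba(rf, probe)
  keep <- p_rf != 0.5
  expect_equal(as.character(classify(p_rf))[keep], as.character(native_rf)[keep])
  # LR native (glmnet class prediction)
  lr <- fit_learner(learner_spec("LR", seed = 1), train)
  xs <- scale(probe$x[, lr$features], lr$standardizer$center, lr$standardizer$scale)
  native_lr <- predict(lr$fit, newx = xs, type = "class")
  p_lr <- predict_proba(lr, probe)
  keep <- p_lr != 0.5
  expect_equal(as.character(classify(p_lr))[keep], as.character(native_lr)[keep])
})

test_that("prediction requires the learner's descriptor columns", {
  ds <- separable_dataset()
  fit <- fit_learner(learner_spec("kNN", seed = 1), ds)
  expect_error(predict_proba(fit, ds$x[, "d1", drop = FALSE]), "d2")
})

test_that("SVM Platt calibration learns an increasing probability in the margin", {
  ds <- separable_dataset(n_per_class = 30, gap = 5)
  fit <- fit_learner(learner_spec("SVM", seed = 3), ds)
  p <- predict_proba(fit, ds)
  expect_gt(mean(p[ds$label == "positive"]), mean(p[ds$label == "negative"]))
  expect_true(all(p > 0 & p < 1))
})
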