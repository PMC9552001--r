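test_that("fold plans have near-equal sizes and cover every chemical once", {
  plan <- make_folds(275, folds = 5, seed = 1)
  expect_equal(unname(table(plan)), rep(55L, 5), ignore_attr = TRUE)
  plan7 <- make_folds(7, folds = 5, seed = 2)
  expect_setequal(as.integer(table(plan7)), c(2L, 2L, 1L, 1L, 1L))
  expect_equal(length(plan7), 7)
  expect_identical(make_folds(100, 5, seed = 9), make_folds(100, 5, seed = 9))
  expect_error(make_folds(100, folds = 1), ">= 2")
  expect_error(make_folds(3, folds = 5), "at least")
  # stratified folds keep classes balanced across folds
  ds <- noise_dataset(n = 100, seed = 3)
  plan_s <- make_folds(ds, folds = 5, seed = 4, stratified = TRUE)
  per_fold_pos <- tapply(ds$label == "positive", plan_s, sum)
  expect_lte(diff(range(per_fold_pos)), 1)
})

test_that("metrics match hand values in perfect and chance cases", {
  perfect <- compute_metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unname(perfect[c("accuracy", "mcc", "balanced_accuracy")]),
               c(1, 1, 1))
  chance <- compute_metrics(c(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(unname(chance[c("accuracy", "mcc", "balanced_accuracy")]),
               c(0.5, 0, 0.5))
})

test_that("metrics agree with a brute-force oracle on random confusion data", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:60, 1)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    pred <- sample(c("positive", "negative"), n, replace = TRUE)
    got <- compute_metrics(confusion_counts(truth, pred))
    want <- oracle_metrics(truth, pred)
    expect_equal(got, want, tolerance = 1e-12)
    # identities: BA = (sens+spec)/2, PPR * (TP+FP) = TP
    cc <- confusion_counts(truth, pred)
    if (!is.na(got[["positive_predictive_rate"]]))
      expect_equal(got[["positive_predictive_rate"]] * (cc[["TP"]] + cc[["FP"]]),
                   cc[["TP"]], tolerance = 1e-12)
  }
})

test_that("degenerate confusion denominators follow the stated conventions", {
  m <- compute_metrics(c(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_true(is.na(m[["sensitivity"]]))        # no positives: undefined
  expect_true(is.na(m[["positive_predictive_rate"]]))
  expect_equal(m[["mcc"]], 0)                   # zero denominator => 0
  expect_error(compute_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "at least")
})

test_that("each chemical is predicted once per model per iteration", {
  st <- generate_study(quick_config(seed = 50))
  cv <- run_repeated_cv(st$train, default_learner_specs(seed = 1),
                        iterations = 2, folds = 5, seed = 7)
  counts <- table(cv$log$id, cv$log$model)
  expect_true(all(counts == 2))   # 2 iterations, once each
  expect_equal(sort(unique(cv$log$model)),
               sort(c("DT", "DF", "RF", "kNN", "SVM", "LDA", "LR", "consensus")))
  # per-iteration metrics recomputable from the log
  sub <- cv$log[cv$log$iteration == 1 & cv$log$model == "consensus", ]
  met <- compute_metrics(confusion_counts(sub$truth, sub$predicted))
  row <- cv$metrics[cv$metrics$iteration == 1 & cv$metrics$model == "consensus", ]
  expect_equal(row$balanced_accuracy, met[["balanced_accuracy"]])
  expect_equal(row$mcc, met[["mcc"]])
})

test_that("aggregate mean and sd are recomputable from per-iteration values", {
  st <- generate_study(quick_config(seed = 51))
  cv <- run_repeated_cv(st$train, default_learner_specs(seed = 1),
                        iterations = 3, folds = 5, seed = 3, keep_log = FALSE)
  for (m in c("DT", "consensus")) {
    v <- cv$metrics$mcc[cv$metrics$model == m]
    s <- cv$summary[cv$summary$model == m & cv$summary$metric == "mcc", ]
    expect_equal(s$mean, mean(v), tolerance = 1e-12)
    expect_equal(s$sd, sd(v), tolerance = 1e-12)
  }
})

test_that("LOAEL stratification splits sensitivities by dose cutoff", {
  st <- generate_study(quick_config(seed = 52))
  cv <- run_repeated_cv(st$train, default_learner_specs(seed = 1),
                        iterations = 2, folds = 5, seed = 2)
  out <- loael_stratified_sensitivity(cv, st$train, cutoff = 100)
  expect_equal(nrow(out), 8)
  expect_equal(out$n_strong[1] + out$n_weak[1],
               sum(st$train$label == "positive"))
  expect_true(all(out$strong_sensitivity >= 0 & out$strong_sensitivity <= 1,
                  na.rm = TRUE))
  # cutoff below every LOAEL: strong stratum empty and undefined, not 0
  low <- loael_stratified_sensitivity(cv, st$train,
                                      cutoff = min(st$train$loael, na.rm = TRUE) / 2)
  expect_true(all(is.na(low$strong_sensitivity)))
  expect_false(any(is.na(low$weak_sensitivity)))
})

test_that("stratified sensitivity is exact on a hand-built prediction log", {
  x <- random_descriptor_matrix(n = 4, d = 2, seed = 1)
  ds <- labeled_dataset(x, c("positive", "positive", "negative", "negative"),
                        loael = c(10, 1000, NA, NA))
  log <- data.frame(id = rownames(x), iteration = 1, model = "consensus",
                    probability = c(0.9, 0.1, 0.2, 0.1),
                    predicted = c("positive", "negative", "negative", "negative"),
                    truth = as.character(ds$label))
  cv <- structure(list(log = log), class = "cv_result")
  out <- loael_stratified_sensitivity(cv, ds, cutoff = 100)
  expect_equal(out$strong_sensitivity, 1.0)  # the strong positive was caught
  expect_equal(out$weak_sensitivity, 0.0)    # the weak positive was missed
})

test_that("external validation refuses overlapping chemical IDs", {
  st <- generate_study(quick_config(seed = 53))
  bad <- st$external
  rownames(bad$x)[1] <- rownames(st$train$x)[1]
  expect_error(external_validate(st$train, bad, default_learner_specs()),
               rownames(st$train$x)[1])
})

test_that("external validation produces all eight models' metrics", {
  st <- generate_study(quick_config(seed = 54, effect_size = 3,
                                    shift_magnitude = 0))
  ev <- external_validate(st$train, st$external, default_learner_specs(seed = 1),
                          seed = 4)
  expect_equal(nrow(ev$metrics), 8)
  expect_true("consensus" %in% ev$metrics$model)
  expect_true(all(ev$metrics$balanced_accuracy >= 0 &
                    ev$metrics$balanced_accuracy <= 1, na.rm = TRUE))
  # strongly separable, unshifted external data: models carry real signal
  cons <- ev$metrics[ev$metrics$model == "consensus", ]
  expect_gt(cons$balanced_accuracy, 0.8)
})
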