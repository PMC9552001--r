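# Independent entropy oracle: brute-force per-value bin assignment over 20
# even bins ([min, max], left-closed, top bin closed) and direct evaluation
# of -sum p log2 p. Deliberately loop-based and separate from the package path.
oracle_entropy <- function(v, n_bins = 20) {
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(0)
  edges <- lo + (0:n_bins) * (hi - lo) / n_bins
  counts <- rep(0, n_bins)
  for (val in v) {
    b <- n_bins
    for (k in seq_len(n_bins)) {
      if (val >= edges[k] && (k == n_bins || val < edges[k + 1])) { b <- k; break }
    }
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

test_that("sparse filter removes by strict zero-fraction inequality", {
  set.seed(1)
  x <- cbind(d_91 = c(rep(0, 91), rnorm(9)),
             d_90 = c(rep(0, 90), rnorm(10)),
             d_full = rnorm(100))
  rownames(x) <- sprintf("c%03d", 1:100)
  out <- drop_sparse_descriptors(descriptor_matrix(x))
  expect_equal(out$report$removed$name, "d_91")
  expect_setequal(out$report$kept, c("d_90", "d_full"))
  expect_equal(out$report$removed$reason, "sparse")
  all_sparse <- descriptor_matrix(matrix(0, 10, 2,
                                         dimnames = list(letters[1:10], c("a", "b"))))
  expect_error(drop_sparse_descriptors(all_sparse), "degenerate")
})

test_that("Shannon entropy matches limits and direct evaluation", {
  expect_equal(shannon_entropy(rep(3.7, 50)), 0)
  # 20 values occupying all 20 bins exactly once
  expect_equal(shannon_entropy(seq(0, 1, length.out = 20)), log2(20))
  # occupancies (0.5, 0.25, 0.25, 0 x 17) over [0, 20]
  expect_equal(shannon_entropy(c(0, 0.5, 1.5, 20)), 1.5)
  expect_error(shannon_entropy(numeric(0)), "finite")
  # random descriptors agree with an independent histogram-based oracle
  set.seed(7)
  for (i in 1:20) {
    v <- switch(1 + i %% 3, rnorm(137), rpois(137, 4), rlnorm(137))
    expect_equal(shannon_entropy(v), oracle_entropy(v), tolerance = 1e-12)
  }
})

test_that("entropy is bounded by [0, log2(n_bins)] on generated data", {
  train <- generate_training_set(quick_config(seed = 6))
  h <- entropy_profile(train, n_bins = 20)
  expect_true(all(h >= 0 & h <= log2(20) + 1e-12))
})

test_that("entropy filter partitions at 2.5 bits, keeping exact ties", {
  set.seed(11)
  n <- 400
  # constant, low-entropy (2 bins), near-uniform, and an exact-threshold case
  two_bins <- c(rep(0, 200), rep(10, 200))            # H = 1
  uniform <- runif(n)                                  # H close to log2(20)
  x <- cbind(const = rep(1, n), two_bins = two_bins, uniform = uniform)
  rownames(x) <- sprintf("c%03d", 1:n)
  out <- drop_low_entropy(descriptor_matrix(x), threshold = 2.5)
  expect_setequal(out$report$removed$name, c("const", "two_bins"))
  expect_equal(out$report$kept, "uniform")
  # partition agrees with the oracle on a generated table
  train <- generate_training_set(quick_config(seed = 12))
  h_oracle <- apply(train$x, 2, oracle_entropy)
  out2 <- drop_low_entropy(train, threshold = 2.5)
  expect_setequal(out2$report$kept, names(h_oracle)[h_oracle >= 2.5])
  # a descriptor at exactly the threshold is kept
  fake <- setNames(c(2.5, 2.49), c("at", "below"))
  expect_true("at" %in% names(fake)[!(fake < 2.5)])
  expect_equal(out2$report$thresholds$at_threshold, "kept")
})

test_that("overall importance is the mean of frequency ratios", {
  # descriptor used by every DT, half of DF, no RF models (max = 10 each)
  freq <- rbind(probe = c(DT = 10, DF = 5, RF = 0),
                champ = c(DT = 10, DF = 10, RF = 10))
  imp <- importance_from_frequencies(freq)
  expect_equal(unname(imp$overall["probe"]), (1 + 0.5 + 0) / 3)
  expect_equal(unname(imp$overall["champ"]), 1)
  expect_true(all(imp$per_algorithm >= 0 & imp$per_algorithm <= 1))
})

test_that("one iteration of five folds fits exactly five models per algorithm", {
  train <- generate_training_set(quick_config(seed = 2))
  prof <- suppressWarnings(
    tree_frequency_importance(train, iterations = 1, folds = 5, seed = 1))
  expect_equal(prof$models_per_algorithm, 5L)
  expect_true(all(prof$frequency <= 5))
  expect_true(all(prof$overall >= 0 & prof$overall <= 1))
})

test_that("informative descriptors dominate noise in importance selection", {
  hits <- keep_all <- logical(10)
  for (s in 1:10) {
    cfg <- synthetic_config(n_train = 150, n_descriptors = 50,
                            n_informative = 5, n_sparse = 0,
                            effect_size = 3, seed = s)
    train <- generate_training_set(cfg)
    informative <- attr(train, "informative")
    prof <- suppressWarnings(
      tree_frequency_importance(train, iterations = 5, folds = 5, seed = s))
    noise <- setdiff(names(prof$overall), informative)
    hits[s] <- median(prof$overall[noise]) < 0.2
    keep_all[s] <- all(informative %in% select_by_importance(prof, 0.2)$kept)
  }
  expect_gte(mean(hits), 0.9)
  expect_gte(mean(keep_all), 0.8)
})

test_that("importance selection applies a strict greater-than threshold", {
  overall <- setNames(c(0.200, 0.21, 0.19), c("at", "above", "below"))
  rep <- select_by_importance(overall, threshold = 0.2)
  expect_equal(rep$kept, "above")
  expect_setequal(rep$removed$name, c("at", "below"))
})

test_that("stages 1-2 are label-blind: any label permutation gives identical output", {
  st <- generate_study(quick_config(seed = 13))
  s1 <- drop_sparse_descriptors(st$train)
  s2 <- drop_low_entropy(s1$dataset)
  for (seed in 1:3) {
    perm <- shuffle_labels(st$train, seed = seed)
    p1 <- drop_sparse_descriptors(perm)
    p2 <- drop_low_entropy(p1$dataset)
    expect_identical(p2$dataset$x, s2$dataset$x)
    expect_identical(p2$report$kept, s2$report$kept)
  }
})

test_that("full filter pipeline never increases descriptor count across stages", {
  train <- generate_training_set(quick_config(seed = 14))
  out <- suppressWarnings(filter_descriptors(train, iterations = 2, seed = 3))
  cnt <- out$stage_counts
  expect_true(all(diff(cnt) <= 0))
  expect_equal(unname(cnt["post_importance"]), ncol(out$dataset$x))
  # kept + removed partition the input descriptors
  expect_setequal(c(out$report$kept, out$report$removed$name),
                  colnames(train$x))
  expect_length(intersect(out$report$kept, out$report$removed$name), 0)
})
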