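# Shared fixtures: small synthetic configurations and constructed toy
# datasets used across test files. Everything is generated in code.

# compact study config for fast pipeline-level tests
quick_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_train = 120, n_external = 30, n_descriptors = 30,
         n_informative = 8, n_sparse = 5, effect_size = 2,
         shift_magnitude = 2, seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

# linearly separable two-descriptor toy set
separable_dataset <- function(n_per_class = 20, gap = 6, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
             matrix(rnorm(2 * n_per_class) + gap, ncol = 2))
  colnames(x) <- c("d1", "d2")
  rownames(x) <- sprintf("C%03d", seq_len(2 * n_per_class))
  labeled_dataset(x, rep(c("negative", "positive"), each = n_per_class))
}

# dataset of pure noise with labels carrying no signal
noise_dataset <- function(n = 60, d = 6, positive_fraction = 0.4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d,
              dimnames = list(sprintf("N%03d", seq_len(n)),
                              sprintf("d%02d", seq_len(d))))
  labeled_dataset(x, sample(c("positive", "negative"), n, replace = TRUE,
                            prob = c(positive_fraction, 1 - positive_fraction)))
}

random_descriptor_matrix <- function(n = 8, d = 5, seed = 1) {
  set.seed(seed)
  descriptor_matrix(matrix(rnorm(n * d) * 10^sample(-3:3, n * d, TRUE), n, d,
                           dimnames = list(sprintf("ID%02d", seq_len(n)),
                                           sprintf("desc_%d", seq_len(d)))))
}

# shuffle labels of a dataset (destroys any descriptor-label association)
shuffle_labels <- function(dataset, seed) {
  set.seed(seed)
  i <- sample(nrow(dataset$x))
  labeled_dataset(dataset$x, dataset$label[i],
                  ifelse(as.character(dataset$label[i]) == "positive",
                         dataset$loael[i], NA_real_))
}
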