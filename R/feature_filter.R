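# Three-stage descriptor selection:
#   1. sparse filter     — drop descriptors zero in > 90% of chemicals
#   2. entropy filter    — drop descriptors with Shannon entropy < 2.5 bits
#                          over 20 equal-width bins
#   3. importance filter — drop descriptors whose tree-usage importance,
#                          averaged over DT/DF/RF across repeated 5-fold
#                          CV fits, is <= 0.2
# Stages 1-2 never see the labels; stage 3 legitimately does.

.filter_report <- function(kept, removed, reason, thresholds) {
  structure(list(kept = kept,
                 removed = data.frame(name = removed,
                                      reason = rep_len(reason, length(removed)),
                                      stringsAsFactors = FALSE),
                 thresholds = thresholds),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d kept, %d removed\n",
              length(x$kept), nrow(x$removed)))
  if (nrow(x$removed)) print(table(x$removed$reason))
  invisible(x)
}

#' Drop sparse (mostly-zero) descriptors
#'
#' Removes descriptors whose fraction of exactly-zero values is strictly
#' greater than `zero_fraction_threshold` (default: zero for more than 90%
#' of chemicals). A descriptor zero in exactly 90 of 100 chemicals is kept.
#'
#' @param dataset `labeled_dataset` or descriptor matrix.
#' @param zero_fraction_threshold fraction in \[0, 1\].
#' @return list with the reduced `dataset` and a `report` (`filter_report`).
#' @export
drop_sparse_descriptors <- function(dataset, zero_fraction_threshold = 0.90) {
  x <- if (inherits(dataset, "labeled_dataset")) dataset$x else dataset
  zero_frac <- colMeans(x == 0)
  drop <- zero_frac > zero_fraction_threshold
  if (all(drop)) stop("all descriptors are sparse; degenerate input")
  report <- .filter_report(colnames(x)[!drop], colnames(x)[drop], "sparse",
                           list(zero_fraction = zero_fraction_threshold))
  out <- if (inherits(dataset, "labeled_dataset"))
    subset_dataset(dataset, descriptors = which(!drop))
  else x[, !drop, drop = FALSE]
  list(dataset = out, report = report)
}

#' Shannon entropy of one descriptor over equal-width bins
#'
#' The value range (minimum to maximum over the supplied training values)
#' is divided into `n_bins` even bins; chemicals are assigned to bins and
#' the entropy H = -sum p_i log2 p_i of the bin occupancies is returned,
#' with 0 * log2(0) taken as 0. The top bin is right-closed so the maximum
#' value lands in bin `n_bins`. A constant descriptor occupies a single
#' bin and has entropy 0.
#'
#' @param values numeric vector (>= 1 finite value).
#' @param n_bins number of bins (default 20).
#' @return entropy in bits, in \[0, log2(n_bins)\].
#' @export
shannon_entropy <- function(values, n_bins = 20) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values")
  stopifnot(n_bins >= 2)
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(0)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE)
  p <- tabulate(bin, nbins = n_bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-descriptor entropy profile
#'
#' @param dataset `labeled_dataset` or descriptor matrix.
#' @param n_bins bins per descriptor.
#' @return named numeric vector of entropies (bits).
#' @export
entropy_profile <- function(dataset, n_bins = 20) {
  x <- if (inherits(dataset, "labeled_dataset")) dataset$x else dataset
  apply(x, 2, shannon_entropy, n_bins = n_bins)
}

#' Drop low-entropy descriptors
#'
#' Removes descriptors with Shannon entropy strictly below `threshold`
#' bits (default 2.5 over 20 bins). A descriptor with entropy exactly at
#' the threshold is kept; the convention is recorded in the report.
#'
#' @param dataset `labeled_dataset` or descriptor matrix.
#' @param threshold entropy threshold in bits.
#' @param n_bins bins per descriptor.
#' @return list with reduced `dataset`, `report`, and the `entropy` profile.
#' @export
drop_low_entropy <- function(dataset, threshold = 2.5, n_bins = 20) {
  h <- entropy_profile(dataset, n_bins)
  drop <- h < threshold
  report <- .filter_report(names(h)[!drop], names(h)[drop], "low_entropy",
                           list(entropy = threshold, n_bins = n_bins,
                                at_threshold = "kept"))
  out <- if (inherits(dataset, "labeled_dataset"))
    subset_dataset(dataset, descriptors = which(!drop))
  else dataset[, !drop, drop = FALSE]
  list(dataset = out, report = report, entropy = h)
}

# descriptors actually split on by an rpart tree
.rpart_vars_used <- function(fit) {
  v <- as.character(fit$frame$var)
  unique(v[v != "<leaf>"])
}

#' Combine per-algorithm usage frequencies into overall importance
#'
#' Per algorithm, a descriptor's importance is its usage frequency divided
#' by the maximum frequency over all descriptors for that algorithm; the
#' overall importance is the mean over the algorithms.
#'
#' @param freq numeric matrix, descriptors x algorithms, of counts of
#'   fitted model instances that used each descriptor.
#' @return list with `per_algorithm` (matrix of normalized importances)
#'   and `overall` (named vector).
#' @export
importance_from_frequencies <- function(freq) {
  freq <- as.matrix(freq)
  per <- sweep(freq, 2, pmax(apply(freq, 2, max), 1), "/")
  list(per_algorithm = per, overall = rowMeans(per))
}

#' Tree-usage importance of descriptors from repeated cross-validation
#'
#' For each iteration the chemicals are randomly divided into `folds`
#' folds; for every leave-one-fold-out training part a decision tree (DT),
#' a decision forest (DF: trees with pairwise-disjoint descriptor sets) and
#' a random forest (RF) are fitted, and the set of descriptors each fitted
#' model actually splits on is recorded. A descriptor's frequency per
#' algorithm is the number of fitted model instances that used it; its
#' importance per algorithm is frequency / maximum frequency, and the
#' overall importance is the mean over DT, DF and RF.
#'
#' A descriptor is "used" by a model if it appears in any split (for DT)
#' or in any split of any tree (DF/RF), counted once per fitted model
#' instance.
#'
#' @param dataset labeled dataset (post entropy filter).
#' @param iterations number of CV repetitions (the emulated study used
#'   500; small values suffice for exploration).
#' @param folds folds per repetition.
#' @param seed RNG seed.
#' @param stratified stratify folds by class (default `FALSE`: plain
#'   random division).
#' @param dt_params,df_params,rf_params list of parameters for the three
#'   tree fits. `rf_params` defaults to a shallow forest
#'   (`ntree = 10, maxnodes = 4`): because usage is counted once per fitted
#'   model, a deep many-tree forest would touch nearly every descriptor
#'   and carry no contrast.
#' @return object of class `importance_profile`: list with `frequency`
#'   (descriptors x 3 counts), `per_algorithm`, `overall`, `models_per_algorithm`.
#' @export
tree_frequency_importance <- function(dataset, iterations = 500, folds = 5,
                                      seed = 1, stratified = FALSE,
                                      dt_params = list(cp = 0.01),
                                      df_params = list(n_trees = 3),
                                      rf_params = list(ntree = 10, maxnodes = 4)) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (iterations < 1) stop("iterations must be >= 1")
  vars <- colnames(dataset$x)
  freq <- matrix(0L, length(vars), 3, dimnames = list(vars, c("DT", "DF", "RF")))
  n_models <- 0L
  .with_seed(seed, {
    for (it in seq_len(iterations)) {
      plan <- make_folds(dataset, folds = folds,
                         seed = sample.int(.Machine$integer.max, 1),
                         stratified = stratified)
      for (f in seq_len(folds)) {
        tr <- subset_dataset(dataset, chemicals = which(plan != f))
        df_tr <- data.frame(.y = tr$label, tr$x, check.names = FALSE)
        # DT
        ctrl <- do.call(rpart::rpart.control, dt_params)
        dt <- rpart::rpart(.y ~ ., data = df_tr, method = "class", control = ctrl)
        used_dt <- .rpart_vars_used(dt)
        # DF (disjoint-feature forest); may fail on degenerate folds
        used_df <- tryCatch({
          dfit <- do.call(fit_decision_forest,
                          c(list(dataset = tr,
                                 seed = sample.int(.Machine$integer.max, 1)),
                            df_params))
          unique(unlist(lapply(dfit$fit$trees, .rpart_vars_used)))
        }, error = function(e) character(), warning = function(w) {
          dfit <- suppressWarnings(do.call(fit_decision_forest,
                          c(list(dataset = tr, seed = 1L), df_params)))
          unique(unlist(lapply(dfit$fit$trees, .rpart_vars_used)))
        })
        # RF
        rf <- do.call(randomForest::randomForest,
                      c(list(x = tr$x, y = tr$label), rf_params))
        used_rf <- vars[randomForest::varUsed(rf, count = TRUE) > 0]
        freq[used_dt, "DT"] <- freq[used_dt, "DT"] + 1L
        freq[used_df, "DF"] <- freq[used_df, "DF"] + 1L
        freq[used_rf, "RF"] <- freq[used_rf, "RF"] + 1L
        n_models <- n_models + 1L
      }
    }
  })
  imp <- importance_from_frequencies(freq)
  structure(list(frequency = freq,
                 per_algorithm = imp$per_algorithm,
                 overall = imp$overall,
                 models_per_algorithm = n_models,
                 iterations = iterations, folds = folds, seed = seed),
            class = "importance_profile")
}

#' Select descriptors by overall importance
#'
#' Keeps descriptors whose overall importance is strictly greater than
#' `threshold` (default 0.2); a descriptor at exactly the threshold is
#' removed.
#'
#' @param profile an `importance_profile` (or named numeric vector of
#'   overall importances).
#' @param threshold importance cutoff in \[0, 1\].
#' @return a `filter_report`.
#' @export
select_by_importance <- function(profile, threshold = 0.2) {
  overall <- if (inherits(profile, "importance_profile")) profile$overall else profile
  keep <- overall > threshold
  .filter_report(names(overall)[keep], names(overall)[!keep], "low_importance",
                 list(importance = threshold, at_threshold = "removed"))
}

#' Run the full three-stage descriptor selection
#'
#' Sparse filter, entropy filter, then tree-frequency importance selection.
#' Stages 1-2 use only the descriptor values (label-blind); stage 3 fits
#' label-aware tree models.
#'
#' @param dataset labeled training dataset.
#' @param zero_fraction_threshold stage-1 threshold (default 0.90).
#' @param entropy_threshold stage-2 threshold in bits (default 2.5).
#' @param n_bins entropy bins (default 20).
#' @param importance_threshold stage-3 threshold (default 0.2).
#' @param iterations stage-3 CV repetitions.
#' @param folds stage-3 folds.
#' @param seed stage-3 seed.
#' @param ... further arguments to [tree_frequency_importance()].
#' @return list with `dataset` (reduced), `report` (combined
#'   `filter_report`), `stage_counts` (descriptor count after each stage),
#'   `entropy`, `importance`.
#' @export
filter_descriptors <- function(dataset,
                               zero_fraction_threshold = 0.90,
                               entropy_threshold = 2.5, n_bins = 20,
                               importance_threshold = 0.2,
                               iterations = 20, folds = 5, seed = 1, ...) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n0 <- ncol(dataset$x)
  s1 <- drop_sparse_descriptors(dataset, zero_fraction_threshold)
  s2 <- drop_low_entropy(s1$dataset, entropy_threshold, n_bins)
  imp <- tree_frequency_importance(s2$dataset, iterations = iterations,
                                   folds = folds, seed = seed, ...)
  s3 <- select_by_importance(imp, importance_threshold)
  ds <- subset_dataset(s2$dataset, descriptors = s3$kept)
  removed <- rbind(s1$report$removed, s2$report$removed, s3$removed)
  report <- .filter_report(s3$kept, removed$name, removed$reason,
                           list(zero_fraction = zero_fraction_threshold,
                                entropy = entropy_threshold, n_bins = n_bins,
                                importance = importance_threshold,
                                iterations = iterations, folds = folds,
                                seed = seed))
  report$removed <- removed
  list(dataset = ds, report = report,
       stage_counts = c(input = n0,
                        post_sparse = ncol(s1$dataset$x),
                        post_entropy = ncol(s2$dataset$x),
                        post_importance = length(s3$kept)),
       entropy = s2$entropy, importance = imp)
}
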