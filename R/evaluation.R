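# Repeated 5-fold cross-validation engine, external validation, the seven
# performance metrics, and LOAEL-stratified sensitivity.

.fold_assignment <- function(n, folds, seed, stratified = FALSE, label = NULL) {
  .with_seed(seed, {
    if (stratified) {
      if (is.null(label)) stop("stratified folds need labels")
      fold <- integer(n)
      for (cl in unique(as.character(label))) {
        i <- which(label == cl)
        fold[i] <- sample(rep_len(seq_len(folds), length(i)))
      }
      fold
    } else {
      sample(rep_len(seq_len(folds), n))
    }
  })
}

#' Random fold plan for cross-validation
#'
#' Chemicals are randomly divided into `folds` folds of near-equal size
#' (sizes differ by at most 1); every chemical is assigned exactly once.
#' Plain random division by default, matching the evaluated design;
#' class-stratified folds are available by flag.
#'
#' @param dataset `labeled_dataset` (or an integer count of chemicals).
#' @param folds number of folds (>= 2).
#' @param seed RNG seed; identical seeds give identical plans.
#' @param stratified stratify by class.
#' @return integer vector of fold indices in `1..folds`.
#' @export
make_folds <- function(dataset, folds = 5, seed = 1, stratified = FALSE) {
  n <- if (inherits(dataset, "labeled_dataset")) nrow(dataset$x) else as.integer(dataset)
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many chemicals as folds")
  label <- if (inherits(dataset, "labeled_dataset")) dataset$label else NULL
  .fold_assignment(n, folds, seed, stratified, label)
}

#' Confusion counts from true and predicted labels
#'
#' @param truth,pred factors/characters of `"positive"`/`"negative"`.
#' @return named numeric vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  c(TP = sum(truth == "positive" & pred == "positive"),
    TN = sum(truth == "negative" & pred == "negative"),
    FP = sum(truth == "negative" & pred == "positive"),
    FN = sum(truth == "positive" & pred == "negative"))
}

.metric_names <- c("accuracy", "sensitivity", "specificity",
                   "balanced_accuracy", "positive_predictive_rate",
                   "negative_predictive_rate", "mcc")

#' The seven performance metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, balanced accuracy (mean of
#' sensitivity and specificity), positive predictive rate, negative
#' predictive rate, and the Matthews correlation coefficient with its
#' standard denominator `sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. MCC with a
#' zero denominator is defined as 0; the ratio metrics with a zero
#' denominator are reported as `NA` (undefined), never as 0.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN` (sum >= 1).
#' @return named numeric vector of the seven metrics.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  n <- tp + tn + fp + fn
  if (n < 1) stop("at least one prediction required")
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  c(accuracy = (tp + tn) / n,
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = mean(c(sens, spec)),
    positive_predictive_rate = div(tp, tp + fp),
    negative_predictive_rate = div(tn, tn + fn),
    mcc = mcc)
}

.metrics_from_log <- function(truth, pred) {
  compute_metrics(confusion_counts(truth, pred))
}

# Fit the 7 learners on `train`, return positive probabilities on `test`.
.fit_predict_all <- function(specs, train, test, seed_offset = 0L) {
  p <- vapply(seq_along(specs), function(m) {
    sp <- specs[[m]]
    sp$seed <- as.integer((sp$seed + seed_offset + m) %% .Machine$integer.max)
    predict_proba(fit_learner(sp, train), test)
  }, numeric(nrow(test$x)))
  matrix(p, nrow = nrow(test$x))  # keep matrix shape for single-chemical tables
}

#' Repeated k-fold cross-validation of the seven base models and consensus
#'
#' For each iteration a fresh random fold plan is drawn (seeded from the
#' master seed plus the iteration index); within the iteration all seven
#' models are fitted on each leave-one-fold-out training part and applied
#' to the held-out fold, so every chemical is predicted exactly once per
#' model per iteration. The consensus prediction is computed per chemical
#' from the seven votes of the same iteration. Per-iteration metrics are
#' computed on the pooled predictions of all folds; aggregates (mean, sd)
#' are taken over iterations.
#'
#' @param dataset labeled training dataset.
#' @param specs named list of 7 `learner_spec`s (see
#'   [default_learner_specs()]).
#' @param iterations number of repetitions (the emulated study used 500).
#' @param folds folds per repetition.
#' @param seed master seed.
#' @param stratified stratify folds by class.
#' @param keep_log keep the full prediction log (default `TRUE`).
#' @return object of class `cv_result`: list with `metrics` (long data
#'   frame: iteration, model, the seven metrics), `summary` (per-model
#'   mean/sd per metric), `log` (chemical, iteration, model, probability,
#'   predicted and true label), `folds`, `seed`.
#' @export
run_repeated_cv <- function(dataset, specs = default_learner_specs(),
                            iterations = 500, folds = 5, seed = 1,
                            stratified = FALSE, keep_log = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (iterations < 1) stop("iterations must be >= 1")
  if (length(specs) != 7) stop("exactly 7 learner specs required")
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, "", "algorithm")
  n <- nrow(dataset$x)
  ids <- rownames(dataset$x)
  model_names <- c(names(specs), "consensus")
  metrics_rows <- vector("list", iterations)
  log_rows <- if (keep_log) vector("list", iterations) else NULL
  for (it in seq_len(iterations)) {
    plan <- make_folds(dataset, folds = folds, seed = seed + it,
                       stratified = stratified)
    stopifnot(length(plan) == n)  # every chemical held out exactly once
    probs <- matrix(NA_real_, n, 7, dimnames = list(ids, names(specs)))
    for (f in seq_len(folds)) {
      test_i <- which(plan == f)
      train <- subset_dataset(dataset, chemicals = which(plan != f))
      if (length(unique(as.character(train$label))) < 2) {
        warning(sprintf("iteration %d fold %d: single-class training part", it, f))
      }
      test <- subset_dataset(dataset, chemicals = test_i)
      probs[test_i, ] <- .fit_predict_all(specs, train, test,
                                          seed_offset = it * 1000L + f * 10L)
    }
    votes <- matrix(ifelse(probs >= 0.5, "positive", "negative"), ncol = 7)
    cons <- consensus_vote(votes)
    all_prob <- cbind(probs, consensus = cons$probability)
    all_pred <- cbind(ifelse(probs >= 0.5, "positive", "negative"),
                      consensus = as.character(cons$label))
    met <- t(vapply(model_names, function(m)
      .metrics_from_log(dataset$label, all_pred[, m]), numeric(7)))
    metrics_rows[[it]] <- data.frame(iteration = it, model = model_names, met,
                                     row.names = NULL)
    if (keep_log)
      log_rows[[it]] <- data.frame(
        id = rep(ids, times = 8),
        iteration = it,
        model = rep(model_names, each = n),
        probability = as.numeric(all_prob),
        predicted = as.character(all_pred),
        truth = rep(as.character(dataset$label), times = 8),
        n_positive_votes = c(rep(NA_integer_, n * 7), cons$n_positive_votes),
        stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, metrics_rows)
  summary <- do.call(rbind, lapply(model_names, function(m) {
    sub <- metrics[metrics$model == m, .metric_names, drop = FALSE]
    data.frame(model = m, metric = .metric_names,
               mean = vapply(sub, function(v) mean(v, na.rm = TRUE), 0),
               sd = vapply(sub, function(v) sd(v, na.rm = TRUE), 0),
               row.names = NULL)
  }))
  structure(list(metrics = metrics, summary = summary,
                 log = if (keep_log) do.call(rbind, log_rows),
                 folds = folds, seed = seed, iterations = iterations),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d iterations x %d-fold CV\n", x$iterations, x$folds))
  ba <- x$summary[x$summary$metric == "balanced_accuracy", ]
  cat("mean balanced accuracy:\n")
  print(setNames(round(ba$mean, 3), ba$model))
  invisible(x)
}

#' Mean of one metric per model from a `cv_result`
#' @param cv_result a [run_repeated_cv()] result.
#' @param metric one of the seven metric names.
#' @return named numeric vector (7 base models + consensus).
#' @export
cv_mean_metric <- function(cv_result, metric = "balanced_accuracy") {
  stopifnot(inherits(cv_result, "cv_result"), metric %in% .metric_names)
  s <- cv_result$summary[cv_result$summary$metric == metric, ]
  setNames(s$mean, s$model)
}

#' Sensitivity stratified by LOAEL
#'
#' Positive chemicals are divided into a strong stratum (LOAEL <= cutoff,
#' highly toxic) and a weak stratum (LOAEL > cutoff); the sensitivity of
#' each model is computed separately in each stratum from the pooled
#' cross-validation prediction log. An empty stratum yields `NA`
#' (undefined), never 0.
#'
#' @param cv_result a [run_repeated_cv()] result with a prediction log.
#' @param dataset the dataset that was cross-validated (carries LOAELs).
#' @param cutoff LOAEL cutoff in mg/kg/day (default 100).
#' @return data frame with `model`, `strong_sensitivity`,
#'   `weak_sensitivity`, `n_strong`, `n_weak`.
#' @export
loael_stratified_sensitivity <- function(cv_result, dataset, cutoff = 100) {
  stopifnot(inherits(cv_result, "cv_result"), inherits(dataset, "labeled_dataset"))
  if (is.null(cv_result$log)) stop("cv_result has no prediction log")
  pos_ids <- rownames(dataset$x)[dataset$label == "positive"]
  if (any(is.na(dataset$loael[dataset$label == "positive"])))
    stop("all positive chemicals must carry a LOAEL")
  loael <- setNames(dataset$loael, rownames(dataset$x))
  strong <- pos_ids[loael[pos_ids] <= cutoff]
  weak <- setdiff(pos_ids, strong)
  log <- cv_result$log
  models <- unique(log$model)
  sens_in <- function(m, ids) {
    if (length(ids) == 0) return(NA_real_)
    sub <- log[log$model == m & log$id %in% ids, ]
    mean(sub$predicted == "positive")
  }
  data.frame(model = models,
             strong_sensitivity = vapply(models, sens_in, 0, ids = strong),
             weak_sensitivity = vapply(models, sens_in, 0, ids = weak),
             n_strong = length(strong), n_weak = length(weak),
             row.names = NULL)
}

#' External validation of the seven models and consensus
#'
#' All seven models are fitted on the full training dataset and applied to
#' the external set; consensus predictions are derived from the seven
#' votes. External IDs overlapping the training set are refused (reported
#' by ID).
#'
#' @param train labeled training dataset.
#' @param external labeled external dataset (disjoint IDs).
#' @param specs named list of 7 `learner_spec`s.
#' @param seed fit seed.
#' @return list with `metrics` (data frame: one row per model including
#'   consensus, the seven metrics) and `predictions` (per-chemical log).
#' @export
external_validate <- function(train, external, specs = default_learner_specs(),
                              seed = 1) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(external, "labeled_dataset"))
  overlap <- intersect(rownames(train$x), rownames(external$x))
  if (length(overlap))
    stop("external chemicals overlap the training set: ",
         paste(overlap, collapse = ", "))
  if (length(specs) != 7) stop("exactly 7 learner specs required")
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, "", "algorithm")
  probs <- .fit_predict_all(specs, train, external, seed_offset = seed)
  colnames(probs) <- names(specs)
  votes <- matrix(ifelse(probs >= 0.5, "positive", "negative"), ncol = 7)
  cons <- consensus_vote(votes)
  all_prob <- cbind(probs, consensus = cons$probability)
  all_pred <- cbind(ifelse(probs >= 0.5, "positive", "negative"),
                    consensus = as.character(cons$label))
  model_names <- colnames(all_prob)
  met <- t(vapply(model_names, function(m)
    .metrics_from_log(external$label, all_pred[, m]), numeric(7)))
  n <- nrow(external$x)
  preds <- data.frame(id = rep(rownames(external$x), times = 8),
                      model = rep(model_names, each = n),
                      probability = as.numeric(all_prob),
                      predicted = as.character(all_pred),
                      truth = rep(as.character(external$label), times = 8),
                      stringsAsFactors = FALSE)
  list(metrics = data.frame(model = model_names, met, row.names = NULL),
       predictions = preds)
}
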