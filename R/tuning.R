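# Hyperparameter selection by repeated inner cross-validation maximizing
# the Matthews correlation coefficient (MCC): five repeats of 5-fold CV on
# a class-stratified 80% tuning subset; per repeat the MCC is computed on
# the pooled held-out predictions; settings are ranked by the mean of the
# repeat MCCs, ties broken by grid order.

#' Mean MCC of one learner setting under repeated inner cross-validation
#'
#' For each repeat the tuning data are randomly split into `folds` folds;
#' the model is fitted on each leave-one-fold-out part and applied to the
#' held-out fold until every fold has been held out once, and the MCC is
#' computed on the pooled predictions of the repeat. The mean over the
#' repeat MCCs is returned. A fold whose training part is single-class
#' raises a warning and contributes chance-level (0.5) probabilities for
#' that fold.
#'
#' @param spec a `learner_spec`.
#' @param dataset the tuning subset (a `labeled_dataset`).
#' @param repeats number of repeats (default 5).
#' @param folds folds per repeat (default 5).
#' @param seed RNG seed.
#' @param stratified stratify inner folds by class (default `FALSE`).
#' @return list with `mean_mcc` and the per-repeat `mcc` vector.
#' @export
inner_cv_mcc <- function(spec, dataset, repeats = 5, folds = 5, seed = 1,
                         stratified = FALSE) {
  stopifnot(inherits(spec, "learner_spec"), inherits(dataset, "labeled_dataset"))
  n <- nrow(dataset$x)
  mccs <- vapply(seq_len(repeats), function(r) {
    plan <- make_folds(dataset, folds = folds, seed = seed + 7919L * r,
                       stratified = stratified)
    prob <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      tr_i <- which(plan != f)
      if (length(unique(as.character(dataset$label[tr_i]))) < 2) {
        warning(sprintf("repeat %d fold %d: single-class training part", r, f))
        prob[plan == f] <- 0.5
        next
      }
      sp <- spec
      sp$seed <- as.integer((spec$seed + r * 100L + f) %% .Machine$integer.max)
      fit <- fit_learner(sp, subset_dataset(dataset, chemicals = tr_i))
      prob[plan == f] <- predict_proba(fit, subset_dataset(dataset,
                                                           chemicals = which(plan == f)))
    }
    pred <- classify(prob)
    compute_metrics(confusion_counts(dataset$label, pred))[["mcc"]]
  }, numeric(1))
  list(mean_mcc = mean(mccs), mcc = mccs)
}

#' Default hyperparameter grids for the seven algorithms
#'
#' Conventional search ranges (the recognized names match
#' [default_hyperparameters()]); all values are recorded verbatim in the
#' tuning result.
#'
#' @return named list: per algorithm, a list of hyperparameter settings.
#' @export
default_grids <- function() {
  expand_settings <- function(...) {
    g <- expand.grid(..., stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
  list(
    DT = expand_settings(maxdepth = c(3, 5, 10, 30), minbucket = c(1, 3, 5)),
    DF = expand_settings(n_trees = c(3, 5, 7)),
    RF = expand_settings(ntree = c(100, 500), mtry = c("sqrt", "third")),
    kNN = expand_settings(k = c(3, 5, 7, 9)),
    SVM = expand_settings(cost = c(0.1, 1, 10), gamma = c("scale", 0.01, 0.001)),
    LR = expand_settings(lambda = c(0.01, 0.1, 1, 10)),
    LDA = list(list())
  )
}

#' Exhaustive grid search maximizing mean inner-CV MCC
#'
#' Every setting in the grid is evaluated by [inner_cv_mcc()] with a
#' shared seed (so all settings see identical fold plans); the setting
#' with the highest mean MCC is chosen, ties broken by the first-listed
#' setting (recorded in the result).
#'
#' @param algorithm algorithm code.
#' @param settings list of hyperparameter settings (named lists).
#' @param dataset tuning subset.
#' @param repeats,folds,seed,stratified passed to [inner_cv_mcc()].
#' @return object of class `tuning_result`: `chosen` (a `learner_spec`),
#'   `table` (per-setting mean MCC and per-repeat MCCs), `tie` flag.
#' @export
grid_search <- function(algorithm, settings, dataset, repeats = 5, folds = 5,
                        seed = 1, stratified = FALSE) {
  if (length(settings) == 0) stop("empty grid")
  res <- lapply(seq_along(settings), function(i) {
    sp <- learner_spec(algorithm, settings[[i]], seed = seed)
    inner_cv_mcc(sp, dataset, repeats = repeats, folds = folds, seed = seed,
                 stratified = stratified)
  })
  mean_mcc <- vapply(res, `[[`, 0, "mean_mcc")
  best <- which.max(mean_mcc)  # first maximum: grid-order tie-breaking
  tie <- sum(mean_mcc == mean_mcc[best]) > 1
  table <- data.frame(setting = vapply(settings, function(s)
    if (length(s) == 0) "(default)" else
      paste(names(s), unlist(lapply(s, format)), sep = "=", collapse = ", "),
    ""), mean_mcc = mean_mcc)
  table$repeat_mcc <- lapply(res, `[[`, "mcc")
  structure(list(algorithm = algorithm,
                 chosen = learner_spec(algorithm, settings[[best]], seed = seed),
                 chosen_index = best, tie = tie, table = table, seed = seed),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %s: chose setting %d (%s), mean MCC %.3f%s\n",
              x$algorithm, x$chosen_index, x$table$setting[x$chosen_index],
              x$table$mean_mcc[x$chosen_index],
              if (x$tie) " [tie, first-listed kept]" else ""))
  invisible(x)
}

#' Tune all seven algorithms on a held-aside tuning subset
#'
#' A class-stratified subset of `subset_fraction` (default 80%) of the
#' chemicals is drawn once with the master seed and used for all grids;
#' the tuning subset IDs are returned so callers can verify segregation
#' from any final evaluation data flow.
#'
#' @param dataset full labeled training dataset.
#' @param grids named list of per-algorithm settings lists
#'   (default [default_grids()]).
#' @param subset_fraction fraction of chemicals used for tuning.
#' @param repeats,folds,stratified passed to [grid_search()].
#' @param seed master seed.
#' @return list with `specs` (7 tuned `learner_spec`s, in DT, DF, RF, kNN,
#'   SVM, LDA, LR order), `results` (per-algorithm `tuning_result`),
#'   `tuning_ids`.
#' @export
tune_learners <- function(dataset, grids = default_grids(),
                          subset_fraction = 0.8, repeats = 5, folds = 5,
                          seed = 1, stratified = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  idx <- .with_seed(seed + 17L, {
    unlist(lapply(levels(dataset$label), function(cl) {
      i <- which(dataset$label == cl)
      sample(i, round(length(i) * subset_fraction))
    }))
  })
  tuning <- subset_dataset(dataset, chemicals = sort(idx))
  algos <- intersect(.algorithms, names(grids))
  results <- lapply(algos, function(a)
    grid_search(a, grids[[a]], tuning, repeats = repeats, folds = folds,
                seed = seed, stratified = stratified))
  names(results) <- algos
  specs <- lapply(results, `[[`, "chosen")[.algorithms[.algorithms %in% algos]]
  list(specs = specs, results = results,
       tuning_ids = rownames(tuning$x))
}
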