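# Prediction-confidence analysis: distance of the positive-class
# probability from the 0.5 decision boundary, rescaled to [0, 1], binned
# into 10 equal ranges, with per-bin accuracy and a weighted
# confidence-accuracy trend statistic.

#' Prediction confidence from a positive-class probability
#'
#' Confidence is `|prob - 0.5| / 0.5`: 0 at the decision boundary, 1 for a
#' certain prediction of either class. Predictions with probability `p`
#' and `1 - p` have equal confidence.
#'
#' @param prob probabilities in \[0, 1\].
#' @return confidence values in \[0, 1\].
#' @export
prediction_confidence <- function(prob) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  abs(prob - 0.5) / 0.5
}

#' Bin prediction records by confidence
#'
#' Records are partitioned into 10 groups of equal confidence range
#' (\[0, 0.1), ..., \[0.9, 1\]; the top bin is right-closed so confidence
#' exactly 1 falls in bin 10). Per bin the prediction count and accuracy
#' (fraction of records whose predicted label equals the true label) are
#' computed; optionally the full seven-metric set. Empty bins are
#' reported with `NA` accuracy (undefined), never 0.
#'
#' @param records data frame with columns `predicted`, `truth`, and
#'   either `confidence` or `probability` (confidence is then derived).
#' @param full_metrics also compute the seven metrics per bin.
#' @return object of class `confidence_profile`: data frame with `bin`,
#'   `lower`, `upper`, `count`, `accuracy` (and the other metrics when
#'   requested).
#' @export
bin_by_confidence <- function(records, full_metrics = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("predicted", "truth") %in% colnames(records)))
  conf <- records$confidence
  if (is.null(conf)) conf <- prediction_confidence(records$probability)
  bin <- pmin(floor(conf * 10) + 1L, 10L)
  correct <- records$predicted == records$truth
  out <- data.frame(bin = 1:10,
                    lower = seq(0, 0.9, by = 0.1),
                    upper = seq(0.1, 1.0, by = 0.1))
  out$count <- vapply(1:10, function(b) sum(bin == b), 0L)
  out$accuracy <- vapply(1:10, function(b)
    if (out$count[b] == 0) NA_real_ else mean(correct[bin == b]), 0)
  if (full_metrics) {
    met <- t(vapply(1:10, function(b) {
      if (out$count[b] == 0) return(rep(NA_real_, 7))
      compute_metrics(confusion_counts(records$truth[bin == b],
                                       records$predicted[bin == b]))
    }, numeric(7)))
    colnames(met) <- .metric_names
    out <- cbind(out, met[, setdiff(.metric_names, "accuracy")])
  }
  structure(out, class = c("confidence_profile", "data.frame"))
}

#' Confidence-accuracy trend of a confidence profile
#'
#' Rank correlation between bin index and bin accuracy over non-empty
#' bins, weighted by the bin prediction counts, quantifying whether
#' accuracy increases with confidence. Bins holding under 1% of the
#' predictions (or fewer than 5) are flagged as sparsely populated, since
#' accuracies there are statistically fragile.
#'
#' @param profile a [bin_by_confidence()] result with >= 2 non-empty bins.
#' @return list with `weighted_rank_correlation`, `n_bins_used`,
#'   `sparse_bins` (bin indices).
#' @export
confidence_accuracy_trend <- function(profile) {
  stopifnot(inherits(profile, "confidence_profile"))
  use <- which(profile$count > 0 & !is.na(profile$accuracy))
  if (length(use) < 2) stop("need at least 2 non-empty confidence bins")
  idx <- rank(profile$bin[use])
  acc <- rank(profile$accuracy[use])
  w <- profile$count[use]
  if (sd(profile$accuracy[use]) == 0) {
    rho <- 0  # constant accuracy: no trend
  } else {
    cw <- stats::cov.wt(cbind(idx, acc), wt = w / sum(w), cor = TRUE)
    rho <- cw$cor[1, 2]
  }
  total <- sum(profile$count)
  sparse <- profile$bin[profile$count > 0 &
                          (profile$count < 5 | profile$count < 0.01 * total)]
  list(weighted_rank_correlation = rho,
       n_bins_used = length(use),
       sparse_bins = sparse)
}

#' Confidence profiles for every model in a cross-validation result
#'
#' Pools the prediction log across iterations (the default analysis) and
#' returns one confidence profile per model.
#'
#' @param cv_result a [run_repeated_cv()] result with a prediction log.
#' @param full_metrics compute all seven metrics per bin.
#' @return named list of `confidence_profile`s.
#' @export
cv_confidence_profiles <- function(cv_result, full_metrics = FALSE) {
  stopifnot(inherits(cv_result, "cv_result"))
  if (is.null(cv_result$log)) stop("cv_result has no prediction log")
  log <- cv_result$log
  log$confidence <- prediction_confidence(log$probability)
  models <- unique(log$model)
  setNames(lapply(models, function(m)
    bin_by_confidence(log[log$model == m, ], full_metrics = full_metrics)),
    models)
}
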