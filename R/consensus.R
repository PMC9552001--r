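# Majority-vote consensus of the seven base models.
#
# A chemical is predicted positive iff more than three of the seven models
# vote positive. The consensus positive-class probability is a function of
# the positive vote count N+:
#   N+ > 3 :  1 - (7 - N+) / 8
#   N+ <= 3:  N+ / 6
# Note the printed rule yields probability 0.5 at N+ = 3 while the vote
# rule labels that chemical negative; this edge is preserved as specified
# and flagged in reports.

.n_models <- 7L

#' Consensus positive-class probability from the vote count
#'
#' @param n_positive number of the seven base models voting positive,
#'   vectorized over predictions; each value must lie in 0..7.
#' @return probability in \[0, 1\]: `1 - (7 - N+) / 8` when `N+ > 3`,
#'   `N+ / 6` otherwise.
#' @export
consensus_probability <- function(n_positive) {
  n_positive <- as.numeric(n_positive)
  if (any(is.na(n_positive) | n_positive < 0 | n_positive > .n_models |
          n_positive != round(n_positive)))
    stop("n_positive must be an integer count in 0..", .n_models)
  ifelse(n_positive > 3, 1 - (.n_models - n_positive) / 8, n_positive / 6)
}

#' Majority-vote consensus prediction from seven base-model labels
#'
#' @param labels the seven base-model class labels for one chemical
#'   (character or factor of `"positive"`/`"negative"`), or a 7-column
#'   matrix/data frame with one row per chemical.
#' @return data frame with columns `n_positive_votes`, `label`,
#'   `probability` (one row per chemical).
#' @export
consensus_vote <- function(labels) {
  if (is.matrix(labels) || is.data.frame(labels)) {
    m <- as.matrix(labels)
  } else {
    m <- matrix(as.character(labels), nrow = 1)
  }
  if (ncol(m) != .n_models)
    stop("consensus requires exactly ", .n_models, " base-model votes, got ",
         ncol(m))
  if (!all(m %in% .classes)) stop("votes must be 'positive' or 'negative'")
  n_pos <- rowSums(m == "positive")
  data.frame(n_positive_votes = as.integer(n_pos),
             label = factor(ifelse(n_pos > 3, "positive", "negative"),
                            levels = .classes),
             probability = consensus_probability(n_pos))
}

#' Consensus predictions from seven fitted base learners
#'
#' Fits are applied to the table, each base probability is thresholded at
#' 0.5 into a vote, and votes are combined by [consensus_vote()].
#'
#' @param learners named list of exactly 7 `trained_learner`s.
#' @param table descriptor matrix or `labeled_dataset`.
#' @return data frame with `id`, `n_positive_votes`, `label`,
#'   `probability`, `confidence`, plus one `prob_<algorithm>` column per
#'   base model.
#' @export
predict_consensus <- function(learners, table) {
  if (length(learners) != .n_models)
    stop("consensus requires exactly ", .n_models, " base models, got ",
         length(learners))
  probs <- vapply(learners, predict_proba, table = table,
                  numeric(if (inherits(table, "labeled_dataset"))
                    nrow(table$x) else nrow(table)))
  probs <- matrix(probs, ncol = .n_models,
                  dimnames = list(NULL, names(learners)))
  votes <- matrix(ifelse(probs >= 0.5, "positive", "negative"),
                  ncol = .n_models)
  cons <- consensus_vote(votes)
  ids <- if (inherits(table, "labeled_dataset")) rownames(table$x) else rownames(table)
  out <- data.frame(id = ids, cons,
                    confidence = prediction_confidence(cons$probability),
                    stringsAsFactors = FALSE)
  colnames(probs) <- paste0("prob_", colnames(probs))
  cbind(out, probs)
}
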