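# Brute-force metric oracle: rebuild every metric from an explicit
# prediction list, one comparison at a time.
oracle_metrics <- function(truth, pred) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "positive" && pred[i] == "positive") tp <- tp + 1
    if (truth[i] == "negative" && pred[i] == "negative") tn <- tn + 1
    if (truth[i] == "negative" && pred[i] == "positive") fp <- fp + 1
    if (truth[i] == "positive" && pred[i] == "negative") fn <- fn + 1
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    positive_predictive_rate = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    negative_predictive_rate = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}
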