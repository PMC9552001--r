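# Applicability-domain analysis: principal-component model of the
# training descriptors (standardized), Euclidean distance of each chemical
# to the training centroid in retained-component space, and a rank-based
# comparison of training vs external distance distributions.

#' Fit a principal-component model of the training descriptor space
#'
#' Descriptors are standardized by training mean/sd (zero-variance
#' descriptors are dropped with a warning), then rotated by PCA. The
#' smallest number of leading components whose cumulative variance
#' fraction reaches `variance_target` is retained, unless a fixed
#' `n_components` is requested. Training-score centroid and training
#' distances are stored so new chemicals can be placed relative to the
#' training distribution.
#'
#' @param train_table descriptor matrix or `labeled_dataset` (>= 2
#'   chemicals, >= 2 usable descriptors).
#' @param variance_target cumulative variance fraction to cover
#'   (default 0.95).
#' @param n_components optional fixed component count (overrides the
#'   variance target).
#' @return object of class `pc_model`: `center`, `scale`, `rotation`,
#'   `variance_fraction`, `n_components`, `centroid`, `train_distance`,
#'   `train_ids`.
#' @export
fit_pc_model <- function(train_table, variance_target = 0.95,
                         n_components = NULL) {
  x <- if (inherits(train_table, "labeled_dataset")) train_table$x else train_table
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  sds <- apply(x, 2, sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate)) {
    warning("dropping zero-variance descriptor(s): ",
            paste(colnames(x)[degenerate], collapse = ", "))
    x <- x[, !degenerate, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 usable descriptors")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  nondeg <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (is.null(n_components)) {
    n_components <- which(cumsum(vf) >= variance_target - 1e-12)[1]
    if (is.na(n_components)) n_components <- nondeg
    n_components <- min(n_components, nondeg)
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  centroid <- colMeans(scores)
  train_distance <- sqrt(rowSums(sweep(scores, 2, centroid)^2))
  structure(list(center = pc$center, scale = pc$scale,
                 rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
                 variance_fraction = vf,
                 cumulative_variance = cumsum(vf)[n_components],
                 n_components = n_components,
                 centroid = centroid,
                 train_distance = train_distance,
                 train_ids = rownames(x)),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d components retained (%.1f%% variance), %d descriptors\n",
              x$n_components, 100 * x$cumulative_variance, nrow(x$rotation)))
  invisible(x)
}

#' Centroid distances in retained principal-component space
#'
#' Projects chemicals into the model's retained-component space and
#' reports the Euclidean distance of each chemical to the training-score
#' centroid, together with the training-distance quantile of that distance
#' (the fraction of training chemicals at or below it — e.g. a quantile of
#' 0.95 reads "farther than 95% of the training chemicals").
#'
#' @param model a [fit_pc_model()].
#' @param table descriptor matrix or `labeled_dataset` containing the
#'   model's descriptors.
#' @param group label recorded in the output (e.g. `"train"`,
#'   `"external"`).
#' @return data frame with `id`, `group`, `distance`, `train_quantile`.
#' @export
centroid_distance <- function(model, table, group = "external") {
  stopifnot(inherits(model, "pc_model"))
  x <- if (inherits(table, "labeled_dataset")) table$x else table
  missing <- setdiff(rownames(model$rotation), colnames(x))
  if (length(missing))
    stop("table lacks descriptor(s): ", paste(missing, collapse = ", "))
  x <- x[, rownames(model$rotation), drop = FALSE]
  z <- scale(x, center = model$center, scale = model$scale)
  scores <- z %*% model$rotation
  d <- sqrt(rowSums(sweep(scores, 2, model$centroid)^2))
  q <- ecdf(model$train_distance)(d)
  data.frame(id = rownames(x), group = group, distance = as.numeric(d),
             train_quantile = q, stringsAsFactors = FALSE)
}

#' Compare training and external centroid-distance distributions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the external
#' distances against the training distances, with group medians and the
#' effect direction. With a group smaller than 3 chemicals only the
#' descriptive part is returned (with a warning).
#'
#' @param train_distance numeric vector (or `centroid_distance()` data
#'   frame) of training distances.
#' @param external_distance numeric vector or data frame of external
#'   distances.
#' @return list with `p_value`, `statistic`, `median_train`,
#'   `median_external`, `direction` (`"external_larger"`,
#'   `"external_smaller"` or `"none"`).
#' @export
compare_distance_distributions <- function(train_distance, external_distance) {
  if (is.data.frame(train_distance)) train_distance <- train_distance$distance
  if (is.data.frame(external_distance)) external_distance <- external_distance$distance
  stopifnot(length(train_distance) > 0, length(external_distance) > 0)
  med_t <- median(train_distance); med_e <- median(external_distance)
  direction <- if (med_e > med_t) "external_larger"
               else if (med_e < med_t) "external_smaller" else "none"
  if (min(length(train_distance), length(external_distance)) < 3) {
    warning("a group has fewer than 3 chemicals; descriptive output only")
    return(list(p_value = NA_real_, statistic = NA_real_,
                median_train = med_t, median_external = med_e,
                direction = direction))
  }
  wt <- suppressWarnings(wilcox.test(external_distance, train_distance,
                                     alternative = "two.sided", exact = FALSE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       median_train = med_t, median_external = med_e, direction = direction)
}

#' One-call applicability-domain analysis
#'
#' Fits the PC model on the training descriptors, computes centroid
#' distances for both cohorts, and compares the distributions.
#'
#' @param train,external labeled datasets (post descriptor filtering).
#' @param variance_target,n_components passed to [fit_pc_model()].
#' @return list with `model`, `distances` (stacked data frame),
#'   `comparison`.
#' @export
applicability_domain <- function(train, external, variance_target = 0.95,
                                 n_components = NULL) {
  model <- fit_pc_model(train, variance_target = variance_target,
                        n_components = n_components)
  d_train <- centroid_distance(model, train, group = "train")
  d_ext <- centroid_distance(model, external, group = "external")
  list(model = model,
       distances = rbind(d_train, d_ext),
       comparison = compare_distance_distributions(d_train, d_ext))
}
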