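# Seven base classifiers behind one fit/predict-probability contract.
#
# Positive-class probability semantics per algorithm:
#   DT   — proportion of positive training chemicals in the terminal node
#   DF   — mean of per-tree leaf proportions over disjoint-feature trees
#   RF   — fraction of trees voting positive
#   kNN  — fraction of positive chemicals among the k nearest neighbors
#   SVM  — Platt-calibrated margin, 1 / (1 + exp(A f + B)), A and B fitted
#          by maximum likelihood on cross-validated decision values
#   LDA  — two-class posterior (sigmoid of the linear discriminant)
#   LR   — logistic 1 / (1 + exp(-(a.x + b))) (ridge-regularized fit)
#
# Distance/margin-based learners (kNN, SVM, LDA, LR) consume descriptors
# standardized by training mean/sd; tree learners consume raw values.

.algorithms <- c("DT", "DF", "RF", "kNN", "SVM", "LDA", "LR")
.scaled_algorithms <- c("kNN", "SVM", "LDA", "LR")

#' Specify a base learner
#'
#' @param algorithm one of `"DT"`, `"DF"`, `"RF"`, `"kNN"`, `"SVM"`,
#'   `"LDA"`, `"LR"`.
#' @param hyperparameters named list of algorithm hyperparameters; see
#'   [default_grids()] for the recognized names.
#' @param seed seed used at fit time (tree resampling, Platt folds).
#' @return a `learner_spec`.
#' @export
learner_spec <- function(algorithm, hyperparameters = list(), seed = 1) {
  algorithm <- match.arg(algorithm, .algorithms)
  structure(list(algorithm = algorithm,
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

#' Default learner specifications for the seven algorithms
#'
#' Conventional hyperparameter defaults, used when tuning is skipped.
#'
#' @param seed common fit seed.
#' @return named list of 7 `learner_spec`s (DT, DF, RF, kNN, SVM, LDA, LR).
#' @export
default_learner_specs <- function(seed = 1) {
  setNames(lapply(.algorithms, function(a)
    learner_spec(a, default_hyperparameters(a), seed = seed)), .algorithms)
}

#' @rdname default_learner_specs
#' @param algorithm algorithm code.
#' @export
default_hyperparameters <- function(algorithm) {
  switch(algorithm,
         DT  = list(maxdepth = 10, minbucket = 3, cp = 0.01),
         DF  = list(n_trees = 3, maxdepth = 10, minbucket = 3, cp = 0.01),
         RF  = list(ntree = 100, mtry = NULL),
         kNN = list(k = 5),
         SVM = list(cost = 1, gamma = "scale"),
         LDA = list(),
         LR  = list(lambda = 0.01),
         stop("unknown algorithm: ", algorithm))
}

.standardizer <- function(x) {
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = center, scale = scl)
}

.apply_standardizer <- function(std, x) {
  scale(x, center = std$center, scale = std$scale)
}

.check_two_classes <- function(label) {
  tab <- table(label)
  if (any(tab < 2) || length(unique(as.character(label[!is.na(label)]))) < 2)
    stop("training data must contain at least 2 chemicals of each class")
}

#' Fit a base learner
#'
#' @param spec a [learner_spec()].
#' @param dataset labeled training dataset (>= 2 chemicals per class, no
#'   missing values).
#' @return a `trained_learner` carrying the fitted state, descriptor names
#'   used, and the probability contract identifier.
#' @export
fit_learner <- function(spec, dataset) {
  stopifnot(inherits(spec, "learner_spec"), inherits(dataset, "labeled_dataset"))
  .check_two_classes(dataset$label)
  hp <- utils::modifyList(default_hyperparameters(spec$algorithm),
                          spec$hyperparameters)
  x <- dataset$x
  y <- dataset$label
  features <- colnames(x)
  if (spec$algorithm == "LDA") {
    # LDA requires non-degenerate within-class variance; drop descriptors
    # constant within the classes (e.g. all-zero sparse columns in a fold)
    wvar <- (colSums(scale(x[y == "positive", , drop = FALSE], scale = FALSE)^2) +
             colSums(scale(x[y == "negative", , drop = FALSE], scale = FALSE)^2)) /
            (nrow(x) - 2)
    keep <- sqrt(wvar) > 1e-8
    if (!any(keep)) stop("no descriptor varies within classes; LDA undefined")
    features <- features[keep]
    x <- x[, keep, drop = FALSE]
  }
  std <- NULL
  if (spec$algorithm %in% .scaled_algorithms) {
    std <- .standardizer(x)
    x <- .apply_standardizer(std, x)
  }
  fit <- .with_seed(spec$seed, switch(
    spec$algorithm,
    DT = {
      ctrl <- rpart::rpart.control(maxdepth = hp$maxdepth,
                                   minbucket = hp$minbucket, cp = hp$cp)
      rpart::rpart(.y ~ ., data = data.frame(.y = y, x, check.names = FALSE),
                   method = "class", control = ctrl)
    },
    DF = .df_fit(x, y, n_trees = hp$n_trees, maxdepth = hp$maxdepth,
                 minbucket = hp$minbucket, cp = hp$cp),
    RF = {
      mtry <- hp$mtry
      if (is.null(mtry) || identical(mtry, "sqrt")) mtry <- max(1, floor(sqrt(ncol(x))))
      else if (identical(mtry, "third")) mtry <- max(1, floor(ncol(x) / 3))
      else mtry <- as.numeric(mtry)
      randomForest::randomForest(x = x, y = y, ntree = hp$ntree, mtry = mtry)
    },
    kNN = list(x = x, y = y, k = hp$k),
    SVM = .svm_platt_fit(x, y, cost = hp$cost, gamma = hp$gamma,
                         seed = spec$seed),
    LDA = MASS::lda(x, grouping = y),
    LR = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = hp$lambda)
  ))
  structure(list(spec = spec, algorithm = spec$algorithm, fit = fit,
                 features = features, standardizer = std,
                 probability_contract = switch(spec$algorithm,
                   DT = "leaf_proportion", DF = "tree_average",
                   RF = "tree_average", kNN = "neighbor_fraction",
                   SVM = "platt_margin", LDA = "posterior",
                   LR = "logistic")),
            class = "trained_learner")
}

#' @export
print.trained_learner <- function(x, ...) {
  cat(sprintf("<trained_learner> %s (%d descriptors, contract: %s)\n",
              x$algorithm, length(x$features), x$probability_contract))
  invisible(x)
}

# ---- Decision Forest (disjoint-feature tree ensemble) ----------------------

.df_fit <- function(x, y, n_trees, maxdepth = 10, minbucket = 3, cp = 0.01) {
  if (n_trees < 2) stop("a decision forest needs n_trees >= 2")
  remaining <- colnames(x)
  trees <- list()
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, minbucket = minbucket, cp = cp)
  while (length(trees) < n_trees && length(remaining) >= 1) {
    df_tr <- data.frame(.y = y, x[, remaining, drop = FALSE], check.names = FALSE)
    tree <- rpart::rpart(.y ~ ., data = df_tr, method = "class", control = ctrl)
    used <- .rpart_vars_used(tree)
    if (length(used) == 0) break  # stump: no usable signal left
    trees[[length(trees) + 1]] <- tree
    remaining <- setdiff(remaining, used)
  }
  if (length(trees) < 2)
    stop("decision forest could not grow 2 trees with disjoint descriptors")
  if (length(trees) < n_trees)
    warning(sprintf("decision forest stopped early: %d of %d trees grown (descriptors exhausted)",
                    length(trees), n_trees))
  list(trees = trees, n_trees = length(trees))
}

#' Fit a Decision Forest
#'
#' An ensemble of decision trees constrained to use pairwise-disjoint
#' descriptor sets: trees are grown sequentially and the descriptors used
#' by each tree are withheld from all subsequent trees. The ensemble
#' positive-class probability is the mean of the per-tree terminal-node
#' positive proportions. If descriptors are exhausted before `n_trees`
#' trees are grown the forest stops early with a warning (at least two
#' trees are required).
#'
#' @param dataset labeled training dataset.
#' @param n_trees requested number of trees (>= 2).
#' @param maxdepth,minbucket,cp tree-growing controls (see
#'   [rpart::rpart.control()]).
#' @param seed fit seed.
#' @return a `trained_learner` with algorithm `"DF"`.
#' @export
fit_decision_forest <- function(dataset, n_trees = 3, maxdepth = 10,
                                minbucket = 3, cp = 0.01, seed = 1) {
  spec <- learner_spec("DF", list(n_trees = n_trees, maxdepth = maxdepth,
                                  minbucket = minbucket, cp = cp), seed = seed)
  fit_learner(spec, dataset)
}

#' Descriptor sets used by each tree of a Decision Forest
#' @param learner a trained `"DF"` learner.
#' @return list of character vectors (one per tree), pairwise disjoint.
#' @export
df_tree_features <- function(learner) {
  stopifnot(inherits(learner, "trained_learner"), learner$algorithm == "DF")
  lapply(learner$fit$trees, .rpart_vars_used)
}

# ---- SVM with explicit Platt calibration -----------------------------------

#' Platt-calibrated probability from an uncalibrated margin
#'
#' The sigmoid map `1 / (1 + exp(A * f + B))` taking an SVM decision value
#' `f` to a positive-class probability. With `A = 0, B = 0` every margin
#' maps to 0.5.
#'
#' @param f uncalibrated decision value(s).
#' @param A,B calibration parameters.
#' @return probability in (0, 1).
#' @export
platt_probability <- function(f, A, B) {
  1 / (1 + exp(A * f + B))
}

# Platt (1999) maximum-likelihood sigmoid fit with regularized targets.
.platt_fit <- function(f, y_pos) {
  n_pos <- sum(y_pos); n_neg <- sum(!y_pos)
  t <- ifelse(y_pos, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    p <- platt_probability(f, par[1], par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  start <- c(A = 0, B = log((n_neg + 1) / (n_pos + 1)))
  fit <- optim(start, nll, method = "BFGS")
  list(A = fit$par[[1]], B = fit$par[[2]])
}

.svm_decision_values <- function(model, x) {
  pr <- predict(model, x, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values"))
}

.svm_platt_fit <- function(x, y, cost, gamma, seed, calib_folds = 5) {
  if (identical(gamma, "scale")) {
    v <- mean(apply(x, 2, var)); if (!is.finite(v) || v == 0) v <- 1
    gamma <- 1 / (ncol(x) * v)
  } else {
    gamma <- as.numeric(gamma)
  }
  svm_args <- list(type = "C-classification", kernel = "radial",
                   cost = cost, gamma = gamma, scale = FALSE)
  model <- do.call(e1071::svm, c(list(x = x, y = y), svm_args))
  # cross-validated decision values for calibration (Platt's procedure)
  fold <- .fold_assignment(length(y), calib_folds,
                           seed = seed + 101L, stratified = TRUE, label = y)
  f_cv <- numeric(length(y))
  for (k in sort(unique(fold))) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2) { f_cv[!tr] <- 0; next }
    m_k <- do.call(e1071::svm, c(list(x = x[tr, , drop = FALSE], y = y[tr]),
                                 svm_args))
    f_cv[!tr] <- .svm_decision_values(m_k, x[!tr, , drop = FALSE])
  }
  platt <- .platt_fit(f_cv, y == "positive")
  list(model = model, platt = platt)
}

# ---- prediction ------------------------------------------------------------

.knn_predict <- function(fit, xq) {
  k <- min(fit$k, nrow(fit$x))
  pos <- fit$y == "positive"
  apply(xq, 1, function(q) {
    d <- sqrt(colSums((t(fit$x) - q)^2))
    nn <- order(d)[seq_len(k)]   # ties broken by training order: deterministic
    mean(pos[nn])
  })
}

#' Positive-class probability predictions
#'
#' Applies the learner's probability contract to every chemical in the
#' table (see the algorithm semantics in [fit_learner()]).
#'
#' @param learner a `trained_learner`.
#' @param table descriptor matrix (or `labeled_dataset`) containing the
#'   learner's descriptor columns.
#' @return named numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(learner, table) {
  stopifnot(inherits(learner, "trained_learner"))
  x <- if (inherits(table, "labeled_dataset")) table$x else table
  missing <- setdiff(learner$features, colnames(x))
  if (length(missing))
    stop("table lacks descriptor(s): ", paste(missing, collapse = ", "))
  x <- x[, learner$features, drop = FALSE]
  if (!is.null(learner$standardizer))
    x <- .apply_standardizer(learner$standardizer, x)
  p <- switch(learner$algorithm,
    DT = predict(learner$fit, data.frame(x, check.names = FALSE),
                 type = "prob")[, "positive"],
    DF = {
      probs <- vapply(learner$fit$trees, function(tr)
        predict(tr, data.frame(x, check.names = FALSE), type = "prob")[, "positive"],
        numeric(nrow(x)))
      if (nrow(x) == 1) mean(probs) else rowMeans(matrix(probs, nrow = nrow(x)))
    },
    RF = predict(learner$fit, x, type = "prob")[, "positive"],
    kNN = .knn_predict(learner$fit, x),
    SVM = platt_probability(.svm_decision_values(learner$fit$model, x),
                            learner$fit$platt$A, learner$fit$platt$B),
    LDA = predict(learner$fit, x)$posterior[, "positive"],
    LR = as.numeric(predict(learner$fit, newx = x, type = "response"))
  )
  setNames(pmin(pmax(as.numeric(p), 0), 1), rownames(x))
}

#' Classify from positive-class probabilities
#'
#' A chemical is predicted positive iff its probability is at least 0.5
#' (0.5 is the minimum probability at which a chemical is called toxic).
#'
#' @param probabilities numeric vector in \[0, 1\].
#' @return factor with levels `negative`, `positive`.
#' @export
classify <- function(probabilities) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  factor(ifelse(probabilities >= 0.5, "positive", "negative"),
         levels = .classes)
}
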