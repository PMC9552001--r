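# Synthetic descriptor-table generator.
#
# Emulates the statistical structure of a Mold2-style QSAR study: a
# 275 x 777 numeric descriptor table with heterogeneous column scales, a
# mixture of continuous and count-like marginals, a block of near-constant
# (mostly-zero) descriptors, an imbalanced binary toxicity label
# (94 positive / 181 negative), LOAEL doses spanning four orders of
# magnitude for positives only, and an external validation set whose
# descriptor distribution can be shifted away from the training centroid.

# run `code` with a private, seeded RNG stream; caller's RNG state untouched
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic study generator
#'
#' The defaults reproduce the composition of the emulated study: 275
#' training chemicals at positive fraction 94/275, 29 external chemicals,
#' 777 descriptors of which a large block is mostly-zero, and positive
#' LOAELs covering four orders of magnitude (1 to 10,000 mg/kg/day).
#'
#' @param n_train number of training chemicals.
#' @param n_external number of external-validation chemicals.
#' @param n_descriptors total descriptor count.
#' @param n_informative descriptors whose class-conditional mean differs.
#' @param n_sparse descriptors that are zero for most chemicals.
#' @param sparse_zero_fraction probability of a zero in a sparse descriptor
#'   (> 0.90 so the sparse filter removes them at its default threshold).
#' @param positive_fraction expected fraction of positives, in (0, 1).
#' @param external_positive_fraction positive fraction of the external set;
#'   `NULL` = same as `positive_fraction`.
#' @param effect_size standardized mean shift of informative descriptors in
#'   positive chemicals.
#' @param loael_log10_range numeric length-2, log10(mg/kg/day) bounds of
#'   assigned LOAELs.
#' @param loael_rank_correlation target rank correlation between LOAEL and
#'   the latent toxicity score (negative: more toxic = lower dose).
#'   `-1` reverses the score rank order exactly.
#' @param shift_magnitude standardized mean shift applied to the external
#'   set's informative descriptors (covariate shift).
#' @param exact_counts if `TRUE` (default) class counts are assigned
#'   exactly as `round(n * positive_fraction)`; otherwise labels are
#'   i.i.d. Bernoulli.
#' @param seed master seed; all sub-streams are derived from it by fixed
#'   offsets, so identical configs give byte-identical studies.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_train = 275,
                             n_external = 29,
                             n_descriptors = 777,
                             n_informative = 30,
                             n_sparse = 270,
                             sparse_zero_fraction = 0.95,
                             positive_fraction = 94 / 275,
                             external_positive_fraction = NULL,
                             effect_size = 1,
                             loael_log10_range = c(0, 4),
                             loael_rank_correlation = -0.7,
                             shift_magnitude = 2,
                             exact_counts = TRUE,
                             seed = 1) {
  stopifnot(n_train >= 2, n_external >= 0, n_descriptors >= 1,
            n_informative >= 0, n_sparse >= 0)
  if (n_informative + n_sparse > n_descriptors)
    stop("n_informative + n_sparse must not exceed n_descriptors")
  if (!(positive_fraction > 0 && positive_fraction < 1))
    stop("positive_fraction must lie in (0, 1)")
  if (!is.null(external_positive_fraction) &&
      !(external_positive_fraction > 0 && external_positive_fraction < 1))
    stop("external_positive_fraction must lie in (0, 1)")
  if (length(loael_log10_range) != 2 ||
      loael_log10_range[1] >= loael_log10_range[2])
    stop("loael_log10_range must be an ordered pair")
  if (loael_rank_correlation > 0)
    stop("loael_rank_correlation must be <= 0 (toxic chemicals get low doses)")
  if (effect_size < 0) stop("effect_size must be >= 0")
  structure(list(n_train = as.integer(n_train),
                 n_external = as.integer(n_external),
                 n_descriptors = as.integer(n_descriptors),
                 n_informative = as.integer(n_informative),
                 n_sparse = as.integer(n_sparse),
                 sparse_zero_fraction = sparse_zero_fraction,
                 positive_fraction = positive_fraction,
                 external_positive_fraction = external_positive_fraction,
                 effect_size = effect_size,
                 loael_log10_range = loael_log10_range,
                 loael_rank_correlation = loael_rank_correlation,
                 shift_magnitude = shift_magnitude,
                 exact_counts = isTRUE(exact_counts),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Fixed per-stream seed offsets (master-seed policy).
.seed_offsets <- c(scheme = 11L, train = 23L, loael_train = 37L,
                   external = 53L, loael_external = 71L)

# Descriptor "scheme": per-descriptor family, scale, baseline. Drawn once
# per config so training and external sets share marginals.
.descriptor_scheme <- function(config) {
  .with_seed(config$seed + .seed_offsets[["scheme"]], {
    d <- config$n_descriptors
    names <- sprintf("D%03d", seq_len(d))
    role <- rep("noise", d)
    if (config$n_informative > 0)
      role[seq_len(config$n_informative)] <- "informative"
    if (config$n_sparse > 0)
      role[config$n_informative + seq_len(config$n_sparse)] <- "sparse"
    # continuous vs count-like marginals among non-sparse descriptors
    family <- ifelse(role == "sparse", "count",
                     ifelse(runif(d) < 0.5, "continuous", "count"))
    family[role == "informative"] <- "continuous"
    scale <- rlnorm(d, meanlog = 0, sdlog = 1.2)   # heterogeneous scales
    center <- rnorm(d, 0, 2) * scale
    lambda <- rlnorm(d, meanlog = 1, sdlog = 0.8)  # count-like intensity
    list(names = names, role = role, family = family,
         scale = scale, center = center, lambda = lambda)
  })
}

# Draw one cohort given a scheme. `mean_shift` is the standardized shift
# applied to informative descriptors of every chemical (covariate shift);
# effect_size is added on top for positives.
.draw_cohort <- function(config, scheme, n, pf, id_prefix, mean_shift, seed) {
  .with_seed(seed, {
    d <- config$n_descriptors
    if (isTRUE(config$exact_counts)) {
      n_pos <- round(n * pf)
      label <- rep("negative", n)
      label[sample.int(n, n_pos)] <- "positive"
    } else {
      label <- ifelse(rbinom(n, 1, pf) == 1, "positive", "negative")
    }
    pos <- label == "positive"
    x <- matrix(0, n, d, dimnames = list(sprintf("%s%04d", id_prefix, seq_len(n)),
                                         scheme$names))
    for (j in seq_len(d)) {
      role <- scheme$role[j]
      if (role == "sparse") {
        nz <- runif(n) >= config$sparse_zero_fraction
        v <- numeric(n)
        v[nz] <- rpois(sum(nz), scheme$lambda[j]) + 1
      } else if (scheme$family[j] == "count") {
        v <- as.numeric(rpois(n, scheme$lambda[j]))
      } else {
        v <- rnorm(n, scheme$center[j], scheme$scale[j])
      }
      if (role == "informative") {
        v <- v + mean_shift * scheme$scale[j]
        v[pos] <- v[pos] + config$effect_size * scheme$scale[j]
      }
      x[, j] <- v
    }
    # latent toxicity score: realized standardized signal on the
    # informative block (drives LOAEL assignment and separability)
    inf <- which(scheme$role == "informative")
    if (length(inf)) {
      z <- scale(x[, inf, drop = FALSE])
      z[!is.finite(z)] <- 0
      score <- rowMeans(z)
    } else {
      score <- rnorm(n)
    }
    list(dataset = labeled_dataset(x, label), score = score)
  })
}

#' Generate a synthetic training set
#'
#' Draws `n_train` chemicals: informative descriptors are shifted by
#' `effect_size` (in units of the descriptor's own scale) in positives,
#' sparse descriptors are zero for at least the configured fraction of
#' chemicals, and the remaining descriptors are uninformative noise with
#' heterogeneous scales and mixed continuous/count-like marginals.
#'
#' @param config a [synthetic_config()].
#' @return a `labeled_dataset` with attribute `"score"` holding each
#'   chemical's latent toxicity score (realized mean informative signal).
#' @export
generate_training_set <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  scheme <- .descriptor_scheme(config)
  out <- .draw_cohort(config, scheme, config$n_train, config$positive_fraction,
                      "TR", mean_shift = 0,
                      seed = config$seed + .seed_offsets[["train"]])
  ds <- out$dataset
  attr(ds, "score") <- out$score
  attr(ds, "informative") <- scheme$names[scheme$role == "informative"]
  ds
}

#' Assign LOAEL doses to positive chemicals
#'
#' Every positive chemical receives a LOAEL (mg/kg/day) whose log10 value
#' spans `config$loael_log10_range`; doses are rank-anti-correlated with the
#' latent toxicity score so that strongly toxic chemicals (high score) get
#' low doses. At `loael_rank_correlation = -1` the dose rank order is the
#' exact reverse of the score rank order. Negatives receive no LOAEL.
#'
#' @param dataset a `labeled_dataset` carrying a `"score"` attribute (as
#'   produced by [generate_training_set()]); if absent, an independent
#'   latent score is drawn.
#' @param config a [synthetic_config()].
#' @return the dataset with `loael` filled in for positives.
#' @export
assign_loael <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "synthetic_config"))
  pos <- which(dataset$label == "positive")
  if (length(pos) == 0) return(dataset)
  score <- attr(dataset, "score")
  .with_seed(config$seed + .seed_offsets[["loael_train"]], {
    if (is.null(score)) score <- rnorm(nrow(dataset$x))
    s <- score[pos]
    r <- config$loael_rank_correlation
    # normal scores of the (negated) toxicity ranks, plus noise tuned to the
    # target rank correlation; r = -1 gives the exact reversed order
    z <- qnorm((rank(s, ties.method = "first") - 0.5) / length(s))
    y <- -abs(r) * z + sqrt(max(0, 1 - r^2)) * rnorm(length(s))
    lo <- config$loael_log10_range[1]; hi <- config$loael_log10_range[2]
    if (length(y) == 1) {
      log10_loael <- mean(c(lo, hi))
    } else if (diff(range(y)) == 0) {
      log10_loael <- rep(mean(c(lo, hi)), length(y))
    } else {
      log10_loael <- lo + (y - min(y)) / diff(range(y)) * (hi - lo)
    }
    dataset$loael[pos] <- 10^log10_loael
  })
  dataset
}

#' Generate a covariate-shifted external validation set
#'
#' Chemicals come from the same generative family as the training set but
#' with informative-descriptor means shifted by `shift_magnitude` standard
#' units, emulating an external cohort drawn from a different region of
#' chemical space. IDs are disjoint from the training set by construction
#' (and verified).
#'
#' @param config a [synthetic_config()].
#' @param train the generated training `labeled_dataset` (same config).
#' @return a `labeled_dataset` with `"score"` attribute.
#' @export
generate_external_set <- function(config, train) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(train, "labeled_dataset"))
  scheme <- .descriptor_scheme(config)
  pf <- config$external_positive_fraction
  if (is.null(pf)) pf <- config$positive_fraction
  out <- .draw_cohort(config, scheme, config$n_external, pf, "EX",
                      mean_shift = config$shift_magnitude,
                      seed = config$seed + .seed_offsets[["external"]])
  ds <- out$dataset
  overlap <- intersect(rownames(ds$x), rownames(train$x))
  if (length(overlap))
    stop("external IDs collide with training set: ",
         paste(overlap, collapse = ", "))
  # LOAELs for external positives, from an independent sub-stream
  pos <- which(ds$label == "positive")
  if (length(pos)) {
    cfg2 <- config
    cfg2$seed <- config$seed + .seed_offsets[["loael_external"]]
    attr(ds, "score") <- out$score
    ds <- assign_loael(ds, cfg2)
  }
  attr(ds, "score") <- out$score
  attr(ds, "informative") <- scheme$names[scheme$role == "informative"]
  ds
}

#' Generate a complete synthetic study
#'
#' Training set with LOAELs plus external set, with ground-truth record of
#' the informative descriptors and latent toxicity scores.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `train`, `external` (both `labeled_dataset`)
#'   and `ground_truth` (informative descriptor names, per-chemical latent
#'   scores).
#' @export
generate_study <- function(config = synthetic_config()) {
  train <- generate_training_set(config)
  train <- assign_loael(train, config)
  external <- generate_external_set(config, train)
  list(train = train,
       external = external,
       ground_truth = list(
         informative = attr(train, "informative"),
         train_score = setNames(attr(train, "score"), rownames(train$x)),
         external_score = setNames(attr(external, "score"),
                                   rownames(external$x))))
}
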