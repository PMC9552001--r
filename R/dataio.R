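#' @importFrom stats predict sd quantile cor rnorm runif rbinom rpois
#'   rlnorm qnorm plogis optim ecdf wilcox.test median var complete.cases
#'   setNames binomial
#' @importFrom utils read.table write.table head
NULL

# Class labels used throughout. "positive" = reproductive-toxic.
.classes <- c("negative", "positive")

#' Construct a descriptor matrix
#'
#' Validates and normalizes a chemicals-by-descriptors table into the
#' numeric matrix representation used throughout the package: rows are
#' chemicals (rownames = unique chemical IDs), columns are named numeric
#' descriptors.
#'
#' @param x numeric matrix or data frame of descriptor values.
#' @param ids chemical identifiers; defaults to `rownames(x)`.
#' @param allow_missing logical; if `FALSE` (default) any non-finite value
#'   is an error.
#' @return numeric matrix with unique rownames and colnames.
#' @export
descriptor_matrix <- function(x, ids = rownames(x), allow_missing = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("descriptor values must be numeric")
  if (is.null(ids)) stop("chemical IDs are required (rownames or `ids`)")
  ids <- as.character(ids)
  if (length(ids) != nrow(x)) stop("length of `ids` must equal nrow(x)")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated chemical ID(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(colnames(x))) stop("descriptor names are required (colnames)")
  dupc <- colnames(x)[duplicated(colnames(x))]
  if (length(dupc)) stop("duplicated descriptor name(s): ", paste(unique(dupc), collapse = ", "))
  if (!allow_missing && any(!is.finite(x)))
    stop("non-finite descriptor values present and allow_missing = FALSE")
  rownames(x) <- ids
  x
}

#' Construct a labeled dataset
#'
#' Bundles a descriptor matrix with aligned binary toxicity labels and
#' optional LOAEL doses (mg/kg/day). Positives are chemicals with an
#' observed reproductive LOAEL; negatives carry no LOAEL.
#'
#' @param x descriptor matrix (see [descriptor_matrix()]).
#' @param label character/factor vector of `"positive"`/`"negative"`,
#'   one per chemical, aligned with `rownames(x)`.
#' @param loael numeric vector of LOAEL doses (mg/kg/day), `NA` where
#'   absent. Must be positive where present, and present only for positives.
#' @return object of class `labeled_dataset` with elements `x`, `label`,
#'   `loael`.
#' @export
labeled_dataset <- function(x, label, loael = NULL) {
  x <- descriptor_matrix(x)
  label <- factor(as.character(label), levels = .classes)
  if (anyNA(label)) stop("labels must be 'positive' or 'negative'")
  if (length(label) != nrow(x)) stop("one label per chemical required")
  if (is.null(loael)) loael <- rep(NA_real_, nrow(x))
  loael <- as.numeric(loael)
  if (length(loael) != nrow(x)) stop("one (possibly NA) LOAEL per chemical required")
  if (any(!is.na(loael) & loael <= 0)) stop("LOAEL must be > 0 where present")
  if (any(!is.na(loael) & label == "negative"))
    stop("negative chemicals must not carry a LOAEL")
  structure(list(x = x, label = label, loael = loael),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d chemicals x %d descriptors (%d positive, %d negative)\n",
              nrow(x$x), ncol(x$x),
              sum(x$label == "positive"), sum(x$label == "negative")))
  invisible(x)
}

#' Subset a labeled dataset by row (chemical) or column (descriptor)
#'
#' @param dataset a `labeled_dataset`.
#' @param chemicals row index (integer, logical, or ID character vector).
#' @param descriptors column index; defaults to all.
#' @return a `labeled_dataset`.
#' @export
subset_dataset <- function(dataset, chemicals = NULL, descriptors = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(chemicals)) chemicals <- seq_len(nrow(dataset$x))
  if (is.null(descriptors)) descriptors <- seq_len(ncol(dataset$x))
  if (is.character(chemicals)) chemicals <- match(chemicals, rownames(dataset$x))
  labeled_dataset(dataset$x[chemicals, descriptors, drop = FALSE],
                  dataset$label[chemicals],
                  dataset$loael[chemicals])
}

.detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

#' Read a descriptor table from delimited text
#'
#' Expects a header row of descriptor names, first column holding chemical
#' IDs, remaining columns numeric. The delimiter is auto-detected from the
#' file extension (`.csv` = comma; `.tsv`/`.tab`/`.txt` = tab) and can be
#' overridden.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) = auto-detect.
#' @param na_token optional string treated as missing; by default missing
#'   values are disallowed and non-numeric cells raise an error.
#' @return descriptor matrix.
#' @export
read_descriptor_table <- function(path, sep = NULL, na_token = NULL) {
  sep <- .detect_sep(path, sep)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", quote = "\"",
                   comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("descriptor table needs an ID column and >=1 descriptor")
  ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- vals[[j]]
    if (!is.null(na_token)) v[v == na_token] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in descriptor '%s' (row %d)",
                   v[bad[1]], colnames(vals)[j], bad[1]))
    m[, j] <- num
  }
  descriptor_matrix(m, ids, allow_missing = !is.null(na_token))
}

#' Write a descriptor table as delimited text
#'
#' @param x descriptor matrix.
#' @param path output path; delimiter auto-detected from extension unless
#'   `sep` given.
#' @param sep field delimiter override.
#' @param digits significant digits used when formatting (default 15, so
#'   a write/read round trip reproduces doubles to well under 1e-12
#'   relative error).
#' @export
write_descriptor_table <- function(x, path, sep = NULL, digits = 15) {
  sep <- .detect_sep(path, sep)
  df <- data.frame(id = rownames(x),
                   apply(x, 2, function(col) formatC(col, digits = digits, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(x))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label table
#'
#' Delimited text with columns `id`, `label` (`positive`/`negative`) and
#' optional `loael` (mg/kg/day; empty or `NA` where absent).
#'
#' @param path file path.
#' @param sep delimiter override.
#' @return data frame with columns `id`, `label`, `loael`.
#' @export
read_label_table <- function(path, sep = NULL) {
  sep <- .detect_sep(path, sep)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  if (!all(c("id", "label") %in% colnames(df)))
    stop("label table must have columns 'id' and 'label'")
  df$id <- as.character(df$id)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicated ID(s) in label table: ",
                        paste(unique(dup), collapse = ", "))
  if (!all(df$label %in% .classes))
    stop("labels must be 'positive' or 'negative'")
  if (is.null(df$loael)) df$loael <- NA_real_
  df[, c("id", "label", "loael")]
}

#' Write a label table
#' @param labels data frame with `id`, `label`, `loael` (as from
#'   [read_label_table()]) or a `labeled_dataset`.
#' @param path output path.
#' @param sep delimiter override.
#' @export
write_label_table <- function(labels, path, sep = NULL) {
  if (inherits(labels, "labeled_dataset"))
    labels <- data.frame(id = rownames(labels$x),
                         label = as.character(labels$label),
                         loael = labels$loael, stringsAsFactors = FALSE)
  sep <- .detect_sep(path, sep)
  write.table(labels, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join a descriptor table with labels into a labeled dataset
#'
#' Alignment is by chemical ID, not row order. In strict mode every table
#' ID must appear in the label table and vice versa.
#'
#' @param x descriptor matrix.
#' @param labels label data frame (`id`, `label`, optional `loael`).
#' @param strict if `TRUE` (default) missing or surplus label IDs are
#'   errors, reported by ID.
#' @return a `labeled_dataset`, ordered as the descriptor table.
#' @export
join_dataset <- function(x, labels, strict = TRUE) {
  x <- descriptor_matrix(x)
  ids <- rownames(x)
  missing <- setdiff(ids, labels$id)
  if (length(missing))
    stop("no label for chemical ID(s): ", paste(missing, collapse = ", "))
  surplus <- setdiff(labels$id, ids)
  if (strict && length(surplus))
    stop("label table has surplus ID(s): ", paste(surplus, collapse = ", "))
  i <- match(ids, labels$id)
  loael <- if (is.null(labels$loael)) rep(NA_real_, length(i)) else labels$loael[i]
  labeled_dataset(x, labels$label[i], loael)
}

#' Write prediction records as delimited text
#'
#' One row per prediction with chemical ID, predicted label, positive-class
#' probability, prediction confidence, and (for consensus predictions) the
#' positive vote count.
#'
#' @param records data frame with at least `id`, `label`, `probability`;
#'   `confidence` and `n_positive_votes` are added/kept when present.
#' @param path output path.
#' @param sep delimiter override.
#' @export
write_predictions <- function(records, path, sep = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("id", "label", "probability")
  if (nrow(records) > 0 && !all(need %in% colnames(records)))
    stop("prediction records need columns: ", paste(need, collapse = ", "))
  if (nrow(records) > 0 && is.null(records$confidence))
    records$confidence <- prediction_confidence(records$probability)
  if (nrow(records) == 0)
    records <- data.frame(id = character(), label = character(),
                          probability = numeric(), confidence = numeric())
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], function(v) formatC(v, digits = 15, format = "g"))
  sep <- .detect_sep(path, sep)
  write.table(records, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cross-validation metrics report
#'
#' Serializes per-iteration metrics and aggregates of a [run_repeated_cv()]
#' result to JSON (machine-readable) for downstream consumption.
#'
#' @param cv_result object from [run_repeated_cv()].
#' @param path output `.json` path.
#' @export
write_metrics_report <- function(cv_result, path) {
  stopifnot(inherits(cv_result, "cv_result"))
  out <- list(iterations = max(cv_result$metrics$iteration),
              folds = cv_result$folds,
              seed = cv_result$seed,
              per_iteration = cv_result$metrics,
              aggregate = cv_result$summary)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
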