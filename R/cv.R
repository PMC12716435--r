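#' Select samples and labels for a screening or diagnostic context
#'
#' The screening context contrasts healthy donors with ovarian cancer
#' patients; the diagnostic context contrasts benign adnexal masses with
#' cancer. Cancer is the positive class in both.
#'
#' @param table A [feature_table()].
#' @param metadata Metadata data frame (`sample_id`, `prefix`, `batch`,
#'   `cohort`, `condition`) covering the table's samples.
#' @param context `"screening"` (healthy vs cancer) or `"diagnostic"`
#'   (benign vs cancer).
#' @param cohort Optional cohort filter (`"discovery"` or `"validation"`).
#' @param features Optional character vector restricting the feature columns.
#' @return List with `features` (numeric matrix), `labels` (integer 0/1,
#'   1 = cancer) and `metadata` (the retained rows).
#' @export
select_context <- function(table, metadata, context = c("screening", "diagnostic"),
                           cohort = NULL, features = NULL) {
  context <- match.arg(context)
  stopifnot(inherits(table, "feature_table"))
  metadata <- validate_metadata(metadata)
  metadata <- metadata[match(rownames(table$values), metadata$sample_id), , drop = FALSE]
  if (anyNA(metadata$sample_id))
    stop("metadata does not cover all samples in the feature table")
  negative <- if (context == "screening") "healthy" else "benign"
  keep <- metadata$condition %in% c(negative, "cancer")
  if (!is.null(cohort)) keep <- keep & metadata$cohort == cohort
  md <- metadata[keep, , drop = FALSE]
  y <- as.integer(md$condition == "cancer")
  if (sum(y) == 0L) stop("no cancer samples in the ", context, " context")
  if (sum(y == 0L) == 0L) stop("no ", negative, " samples in the ", context, " context")
  x <- table$values[keep, , drop = FALSE]
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(x))
    if (length(missing) > 0L)
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  list(features = x, labels = y, metadata = md)
}

stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop("class ", cls, " has fewer than k = ", k, " members")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Repeated stratified cross-validation of a penalised logistic model
#'
#' Runs k-fold stratified cross-validation `repeats` times. Within each
#' repeat, every sample is scored exactly once by the model fitted without
#' its fold; the primary output is each sample's mean held-out score across
#' repeats. The default protocol is 5-fold, repeated 10 times. Fold
#' partitions for repeat `r` derive from `seed + r`, so repeats differ but
#' the whole run is reproducible.
#'
#' @param x Feature matrix (samples x features).
#' @param y Binary labels (0/1, 1 = positive).
#' @param k Number of folds (default 5).
#' @param repeats Number of repeats (default 10).
#' @param seed Base seed for the fold partitions.
#' @param ... Further arguments passed to [plr()] (e.g. `C`, `class_weight`).
#' @return Object of class `"plr_cv"`: `scores` (per-sample means),
#'   `per_repeat` (n x repeats matrix of held-out scores), `folds`
#'   (n x repeats matrix of fold assignments), `labels`, `auc` (AUC of the
#'   mean scores), `k`, `repeats`, `seed`.
#' @export
repeated_stratified_cv <- function(x, y, k = 5L, repeats = 10L, seed = 1L, ...) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(k >= 2L, repeats >= 1L, nrow(x) == length(y))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  n <- length(y)
  scores <- matrix(NA_real_, n, repeats)
  folds <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, k, seed + r)
    folds[, r] <- fold
    for (f in seq_len(k)) {
      test <- fold == f
      fit <- plr(x[!test, , drop = FALSE], y[!test], ...)
      scores[test, r] <- predict(fit, x[test, , drop = FALSE])
    }
  }
  mean_scores <- rowMeans(scores)
  names(mean_scores) <- rownames(x)
  structure(list(
    scores = mean_scores, per_repeat = scores, folds = folds,
    labels = y, auc = auc_rank(mean_scores, y),
    k = as.integer(k), repeats = as.integer(repeats), seed = as.integer(seed)
  ), class = "plr_cv")
}

#' @export
print.plr_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation, %d repeats (seed %d)\n",
              x$k, x$repeats, x$seed))
  cat(sprintf("n = %d (%d positive); AUC of mean held-out scores: %.4f\n",
              length(x$labels), sum(x$labels), x$auc))
  invisible(x)
}

#' Exclude a sample prefix and rerun the modelling protocol
#'
#' Drops every sample whose ID prefix equals `exclude_prefix` from both the
#' cross-validation and the full refit, leaving the protocol otherwise
#' unchanged. This is the "restricted" model used to test whether a
#' batch-confounded subset of training samples drives a model's apparent
#' performance.
#'
#' @param table A [feature_table()].
#' @param metadata Metadata data frame.
#' @param exclude_prefix Prefix whose samples are removed (e.g. `"PGDX"`).
#'   An empty string removes nothing.
#' @param context `"screening"` or `"diagnostic"`.
#' @param cohort Cohort used for training (default `"discovery"`).
#' @param features Optional feature subset.
#' @param k,repeats,seed Cross-validation protocol parameters.
#' @param ... Further arguments passed to [plr()].
#' @return List with `model` (full refit on the restricted data), `cv`
#'   (a `"plr_cv"` object), and `data` (the restricted context selection).
#' @export
restrict_and_refit <- function(table, metadata, exclude_prefix,
                               context = c("screening", "diagnostic"),
                               cohort = "discovery", features = NULL,
                               k = 5L, repeats = 10L, seed = 1L, ...) {
  context <- match.arg(context)
  metadata <- validate_metadata(metadata)
  if (nzchar(exclude_prefix)) {
    keep_ids <- metadata$sample_id[metadata$prefix != exclude_prefix]
    table <- table[rownames(table$values) %in% keep_ids, ]
    metadata <- metadata[metadata$prefix != exclude_prefix, , drop = FALSE]
  }
  sel <- select_context(table, metadata, context, cohort = cohort,
                        features = features)
  cv <- repeated_stratified_cv(sel$features, sel$labels, k = k,
                               repeats = repeats, seed = seed, ...)
  model <- plr(sel$features, sel$labels, ...)
  list(model = model, cv = cv, data = sel)
}
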