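# Mann-Whitney / rank AUC with midranks for ties: probability that a random
# positive scores above a random negative (ties get half credit).
auc_rank <- function(values, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty to compute an AUC")
  r <- rank(values, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Orientation-free single-feature AUC
#'
#' Computes the rank (Mann-Whitney) AUC `a` of a single feature against a
#' binary label, with midranks for ties, and reports `max(a, 1 - a)`: a
#' feature that must be multiplied by -1 to correlate positively with the
#' label is treated as equally discriminative, so 0.5 is the minimum
#' reportable value.
#'
#' @param values Numeric feature values.
#' @param labels Binary labels (0/1 or logical; 1 = positive class).
#' @param threshold Importance threshold; the result carries an `important`
#'   attribute, `TRUE` when the reported AUC strictly exceeds it (default
#'   0.75).
#' @return Reported AUC in \[0.5, 1\], with attribute `important`.
#' @export
single_feature_auc <- function(values, labels, threshold = 0.75) {
  a <- auc_rank(values, labels)
  rep_auc <- max(a, 1 - a)
  attr(rep_auc, "important") <- rep_auc > threshold
  rep_auc
}

feature_auc_table <- function(x, labels, context, threshold = 0.75) {
  auc <- vapply(seq_len(ncol(x)), function(j) {
    a <- auc_rank(x[, j], labels)
    max(a, 1 - a)
  }, numeric(1))
  data.frame(feature = colnames(x), context = context, auc = auc,
             important = auc > threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Screen features for prefix (batch) confounding
#'
#' Restricts to the cancer samples of the discovery cohort and computes each
#' feature's orientation-free AUC for predicting the sample prefix. A high
#' AUC means the feature separates processing eras rather than biology;
#' features exceeding the 0.75 threshold are flagged as confounded.
#'
#' @param table A [feature_table()].
#' @param metadata Metadata data frame.
#' @param positive_prefix Prefix treated as the positive class; defaults to
#'   the rarer of the two prefixes present. With exactly two prefixes the
#'   orientation-free AUC does not depend on this choice.
#' @param condition Condition the screen is restricted to (default
#'   `"cancer"`).
#' @param cohort Cohort restriction (default `"discovery"`).
#' @param threshold Importance threshold (default 0.75).
#' @return Data frame: `feature`, `context` (`"prefix"`), `auc`, `important`.
#' @export
prefix_confounding_screen <- function(table, metadata, positive_prefix = NULL,
                                      condition = "cancer", cohort = "discovery",
                                      threshold = 0.75) {
  stopifnot(inherits(table, "feature_table"))
  metadata <- validate_metadata(metadata)
  metadata <- metadata[match(rownames(table$values), metadata$sample_id), , drop = FALSE]
  keep <- metadata$condition == condition & metadata$cohort == cohort
  md <- metadata[keep, , drop = FALSE]
  prefixes <- unique(md$prefix)
  if (length(prefixes) < 2L)
    stop("need at least two prefixes among ", cohort, " ", condition,
         " samples; found ", length(prefixes))
  if (is.null(positive_prefix)) {
    tab <- sort(base::table(md$prefix))
    positive_prefix <- names(tab)[1L]
  }
  labels <- as.integer(md$prefix == positive_prefix)
  feature_auc_table(table$values[keep, , drop = FALSE], labels,
                    context = "prefix", threshold = threshold)
}

#' Single-feature AUCs for cancer prediction in a clinical context
#'
#' Computes each feature's orientation-free AUC for separating cancer from
#' the context's negative condition, optionally within a single sample
#' prefix (to remove the batch-confounded subset from the evaluation).
#'
#' @param table A [feature_table()].
#' @param metadata Metadata data frame.
#' @param context `"screening"` or `"diagnostic"`.
#' @param prefix_filter Optional prefix; only samples with this prefix are
#'   used.
#' @param cohort Cohort restriction (default `"discovery"`).
#' @param threshold Importance threshold (default 0.75).
#' @return Data frame: `feature`, `context`, `auc`, `important`.
#' @export
condition_auc_screen <- function(table, metadata,
                                 context = c("screening", "diagnostic"),
                                 prefix_filter = NULL, cohort = "discovery",
                                 threshold = 0.75) {
  context <- match.arg(context)
  metadata <- validate_metadata(metadata)
  if (!is.null(prefix_filter)) {
    keep_ids <- metadata$sample_id[metadata$prefix == prefix_filter]
    if (length(keep_ids) == 0L) stop("no samples with prefix '", prefix_filter, "'")
    table <- table[rownames(table$values) %in% keep_ids, ]
    metadata <- metadata[metadata$prefix == prefix_filter, , drop = FALSE]
  }
  sel <- select_context(table, metadata, context, cohort = cohort)
  feature_auc_table(sel$features, sel$labels, context = context,
                    threshold = threshold)
}

#' Order features by one-way ANOVA evidence of group differences
#'
#' For each feature, performs a classical equal-variance one-way ANOVA
#' F-test across groups (by default: sample prefix, within the cancer
#' samples) and returns the features in ascending p-value order -- the most
#' batch-affected features first. With two groups, F equals the square of
#' the pooled-variance t statistic.
#'
#' @param table A [feature_table()].
#' @param metadata Metadata data frame.
#' @param group_by Metadata column defining the groups (default `"prefix"`).
#' @param within Optional condition restriction (default `"cancer"`); `NULL`
#'   keeps all samples.
#' @param cohort Optional cohort restriction (default `NULL`: all).
#' @return Data frame (`feature`, `f_statistic`, `p_value`) sorted by
#'   ascending p-value; ties keep the original feature order.
#' @export
anova_order <- function(table, metadata, group_by = "prefix", within = "cancer",
                        cohort = NULL) {
  stopifnot(inherits(table, "feature_table"), group_by %in% c("prefix", "batch", "cohort", "condition"))
  metadata <- validate_metadata(metadata)
  metadata <- metadata[match(rownames(table$values), metadata$sample_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(metadata))
  if (!is.null(within)) keep <- keep & metadata$condition == within
  if (!is.null(cohort)) keep <- keep & metadata$cohort == cohort
  g <- factor(metadata[[group_by]][keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups for ANOVA; found ", nlevels(g))
  if (any(table(g) < 2L)) stop("every group needs at least 2 samples")
  x <- table$values[keep, , drop = FALSE]
  res <- t(vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    # one-way ANOVA decomposition
    gm <- tapply(v, g, mean)
    ng <- tabulate(g)
    ssb <- sum(ng * (gm - mean(v))^2)
    ssw <- sum((v - gm[as.integer(g)])^2)
    df1 <- nlevels(g) - 1L
    df2 <- length(v) - nlevels(g)
    if (ssw == 0) {
      f <- if (ssb == 0) 0 else Inf
    } else f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    c(f, p)
  }, numeric(2)))
  out <- data.frame(feature = colnames(x), f_statistic = res[, 1],
                    p_value = res[, 2], stringsAsFactors = FALSE)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize a feature table to per-feature z-scores
#'
#' Subtracts each feature's mean and divides by its standard deviation
#' (sample SD with the n-1 denominator by default; a population-SD option is
#' provided because either convention appears in heatmap pipelines).
#'
#' @param table A [feature_table()] or numeric matrix.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator).
#' @return Same type as the input, each column with mean 0 and SD 1.
#' @export
standardize_features <- function(table, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  m <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  if (sd_type == "population") s <- s * sqrt((nrow(x) - 1) / nrow(x))
  zero <- s == 0 | !is.finite(s)
  if (any(zero))
    stop("zero-SD feature(s) cannot be standardized: ",
         paste(colnames(x)[zero], collapse = ", "))
  z <- sweep(sweep(x, 2L, m), 2L, s, "/")
  if (inherits(table, "feature_table")) feature_table(z, table$categories) else z
}

#' Per-batch composition, leakage and homogeneity flags
#'
#' Tabulates samples per (batch, condition, cohort). A batch containing both
#' discovery and validation samples is flagged as leakage (shared processing
#' between training and evaluation data); a batch containing exactly one
#' condition is flagged as homogeneous (case status is then inseparable from
#' any technical batch effect).
#'
#' @param metadata Metadata data frame.
#' @return List with `counts` (data frame: batch, condition, cohort, n) and
#'   `flags` (data frame per batch: `n`, `leakage`, `homogeneous`,
#'   `conditions`, `cohorts`).
#' @export
batch_composition <- function(metadata) {
  metadata <- validate_metadata(metadata)
  counts <- as.data.frame(table(batch = metadata$batch,
                                condition = metadata$condition,
                                cohort = metadata$cohort),
                          responseName = "n", stringsAsFactors = FALSE)
  counts <- counts[counts$n > 0, , drop = FALSE]
  counts$batch <- as.integer(counts$batch)
  counts <- counts[order(counts$batch, counts$condition, counts$cohort), , drop = FALSE]
  rownames(counts) <- NULL
  batches <- sort(unique(metadata$batch))
  flags <- do.call(rbind, lapply(batches, function(b) {
    md <- metadata[metadata$batch == b, , drop = FALSE]
    data.frame(batch = b, n = nrow(md),
               leakage = length(unique(md$cohort)) > 1L,
               homogeneous = length(unique(md$condition)) == 1L,
               conditions = paste(sort(unique(md$condition)), collapse = ","),
               cohorts = paste(sort(unique(md$cohort)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(flags) <- NULL
  list(counts = counts, flags = flags)
}

#' Full batch-effect audit of a cohort
#'
#' Bundles the three single-feature AUC screens (screening, diagnostic,
#' prefix-prediction), the ANOVA feature ordering within cancer samples, the
#' standardized feature matrix in that order, and the per-batch
#' composition/leakage/homogeneity flags into one report.
#'
#' @param table A [feature_table()]; typically copy-number features plus the
#'   zlog protein features.
#' @param metadata Metadata data frame.
#' @param prefix_filter Prefix used for the condition screens (default the
#'   unaffected majority prefix, i.e. the most common one); `NA` uses all
#'   samples.
#' @param threshold Importance threshold for the AUC screens (default 0.75).
#' @param features Optional feature subset used throughout (default: all
#'   copy-number and protein-zlog columns if present, else everything).
#' @return Object of class `"audit_report"`: `feature_auc` (long data
#'   frame over the three contexts), `anova` (ordered p-value table),
#'   `standardized` (matrix, features in ANOVA order), `batch` (output of
#'   [batch_composition()]), `threshold`.
#' @export
audit_cohort <- function(table, metadata, prefix_filter = NULL,
                         threshold = 0.75, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  metadata <- validate_metadata(metadata)
  if (is.null(features)) {
    keep <- table$categories %in% c("copy_number", "protein_zlog")
    features <- if (any(keep)) names(table$categories)[keep] else colnames(table$values)
  }
  tab <- table[, features]
  if (is.null(prefix_filter)) {
    tabp <- sort(base::table(metadata$prefix), decreasing = TRUE)
    prefix_filter <- names(tabp)[1L]
  }
  pf <- if (is.na(prefix_filter)) NULL else prefix_filter
  auc_scr <- condition_auc_screen(tab, metadata, "screening", prefix_filter = pf,
                                  threshold = threshold)
  auc_dia <- tryCatch(
    condition_auc_screen(tab, metadata, "diagnostic", prefix_filter = pf,
                         threshold = threshold),
    error = function(e) NULL)
  auc_pre <- prefix_confounding_screen(tab, metadata, threshold = threshold)
  an <- anova_order(tab, metadata, group_by = "prefix", within = "cancer")
  std <- standardize_features(tab)$values[, an$feature, drop = FALSE]
  structure(list(
    feature_auc = rbind(auc_scr, auc_dia, auc_pre),
    anova = an,
    standardized = std,
    batch = batch_composition(metadata),
    threshold = threshold,
    prefix_filter = prefix_filter
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Batch-effect audit report\n")
  for (ctx in unique(x$feature_auc$context)) {
    sub <- x$feature_auc[x$feature_auc$context == ctx, , drop = FALSE]
    cat(sprintf("  %-11s: %d/%d features with AUC > %.2f\n",
                ctx, sum(sub$important), nrow(sub), x$threshold))
  }
  cat(sprintf("  batches    : %d, leakage in %d, single-condition in %d\n",
              nrow(x$batch$flags), sum(x$batch$flags$leakage),
              sum(x$batch$flags$homogeneous)))
  invisible(x)
}

#' Write an audit report to a directory of TSV files
#'
#' Writes `feature_auc.tsv`, `anova_order.tsv`, `standardized_matrix.tsv`,
#' `batch_composition.tsv` and `flags.tsv`.
#'
#' @param report An [audit_cohort()] report.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_audit_report <- function(report, dir) {
  stopifnot(inherits(report, "audit_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(report$feature_auc, "feature_auc.tsv")
  write_tsv(report$anova, "anova_order.tsv")
  std <- data.frame(sample_id = rownames(report$standardized),
                    report$standardized, check.names = FALSE)
  write_tsv(std, "standardized_matrix.tsv")
  write_tsv(report$batch$counts, "batch_composition.tsv")
  write_tsv(report$batch$flags, "flags.tsv")
  invisible(dir)
}
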