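#' Feature table
#'
#' A samples-by-features numeric matrix with a category tag per feature.
#' Categories are one of `protein_concentration`, `protein_zlog`,
#' `copy_number`, `fragmentation_pc`. Row names are sample IDs.
#'
#' @param values Numeric matrix, samples in rows (row names = sample IDs),
#'   features in columns (column names = feature names).
#' @param categories Named character vector, one tag per feature column.
#' @return An object of class `"feature_table"`.
#' @export
feature_table <- function(values, categories) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature table requires sample IDs as row names and feature names as column names")
  if (anyDuplicated(rownames(values))) stop("duplicate sample IDs in feature table")
  if (anyDuplicated(colnames(values))) stop("duplicate feature names")
  if (anyNA(values)) stop("feature table contains missing values")
  categories <- unlist(categories)
  if (!setequal(names(categories), colnames(values)))
    stop("categories must be named by the feature columns")
  categories <- categories[colnames(values)]
  allowed <- c("protein_concentration", "protein_zlog", "copy_number", "fragmentation_pc")
  bad <- setdiff(unique(categories), allowed)
  if (length(bad) > 0L) stop("unknown feature categories: ", paste(bad, collapse = ", "))
  conc <- values[, categories == "protein_concentration", drop = FALSE]
  if (length(conc) > 0L && any(conc <= 0))
    stop("protein concentrations must be strictly positive")
  structure(list(values = values, categories = categories), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$categories))
  invisible(x)
}

#' Subset a feature table
#'
#' @param x A [feature_table()].
#' @param i Sample (row) index or names.
#' @param j Feature (column) index or names.
#' @param ... Unused.
#' @return A [feature_table()].
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  feature_table(v, x$categories[colnames(v)])
}

arm_names <- function(n) {
  if (n == 39L) {
    # autosomal chromosome arms, dropping the acrocentric short arms
    arms <- unlist(lapply(1:22, function(ch) paste0(ch, c("p", "q"))))
    arms <- setdiff(arms, c("13p", "14p", "15p", "21p", "22p"))
    paste0("cn_", arms)
  } else {
    paste0("cn_", seq_len(n))
  }
}

default_batch_affected <- function(features) {
  pick <- c("cn_11p", "cn_18p", "cn_19q", "cn_1p", "cn_2q", "cn_3p", "cn_4q",
            "cn_5p", "cn_6q", "cn_7p", "cn_8q", "cn_9p", "cn_10q", "cn_12p",
            "cn_16q", "cn_17p", "cn_20q")
  if (all(pick %in% features)) pick else features[seq_len(min(17L, length(features)))]
}

default_cancer_affected <- function(features) {
  pick <- c("cn_3q", "cn_5q", "cn_6p", "cn_8p", "cn_10p", "cn_12q", "cn_18q",
            "cn_21q")
  if (all(pick %in% features)) pick else features[seq_len(min(8L, length(features)))]
}

#' Specification of a synthetic case-control cohort with batch structure
#'
#' Describes a two-cohort (discovery/validation), three-condition
#' (healthy/benign/cancer) study in which a subset of samples ("affected",
#' identified by a sample-ID prefix) was processed in its own early library
#' batches, carrying an additive technical offset on a subset of copy-number
#' features. When the affected batches contain only cancer and benign
#' discovery samples, the technical offset is confounded with case status.
#'
#' Protein concentrations follow a bivariate log-normal model expressed on
#' the zlog scale: healthy samples are standard normal on that scale and the
#' per-condition shifts are additive in log concentration (multiplicative in
#' concentration), in units of the healthy log-SD.
#'
#' @param counts Data frame with columns `cohort` (`discovery`/`validation`),
#'   `condition` (`healthy`/`benign`/`cancer`), `affected` (logical) and `n`
#'   (non-negative integer counts).
#' @param n_copy_number_features Number of copy-number features (default 39,
#'   named by chromosome arm).
#' @param n_fragmentation_pcs Number of fragmentation principal components
#'   (default 0).
#' @param affected_batches,unaffected_batches Disjoint integer batch ID sets
#'   (defaults 1:16 and 17:38).
#' @param affected_prefix,unaffected_prefix Sample-ID prefixes (defaults
#'   `"PGDX"`, `"CGPL"`).
#' @param protein_shift Named list per condition of length-2 numeric vectors
#'   `(ca125, he4)`: additive shifts of log concentration in healthy log-SD
#'   (zlog) units.
#' @param protein_scale Named numeric vector per condition: multiplier of the
#'   healthy log-SD (pathological ranges are wider).
#' @param protein_cor Correlation of the two log concentrations (default
#'   0.57, matching the observed discovery-cohort correlation of zlog values).
#' @param batch_affected_features Copy-number feature names receiving the
#'   batch offset (default 17 of 39 arms, including 11p, 18p, 19q; the
#'   identity of the set is illustrative).
#' @param copy_number_batch_offset Additive offset, in baseline SD units,
#'   applied to `batch_affected_features` for samples in affected batches
#'   (default -2: affected samples sit low).
#' @param cancer_affected_features Copy-number feature names carrying a true
#'   cancer signal (default 8 arms disjoint from the batch set).
#' @param copy_number_cancer_effect Additive shift, in SD units, applied to
#'   `cancer_affected_features` for cancer samples (default 0.3: individually
#'   weak, below the 0.75 single-feature AUC importance threshold).
#' @param restrict_affected If `TRUE` (default), affected batches receive no
#'   healthy-condition and no validation-cohort samples, reproducing the
#'   confounded composition.
#' @param leakage_mode If `TRUE` (default), discovery and validation samples
#'   share the unaffected batches (a form of data leakage); if `FALSE` the
#'   unaffected batch range is split between cohorts.
#' @param mix_batch10 If `TRUE`, affected batch 10 holds both cancer and
#'   benign samples; by default every affected batch is single-condition.
#' @return An object of class `"cohort_spec"`.
#' @seealso [default_cohort_spec()], [simulate_cohort()]
#' @export
cohort_spec <- function(counts,
                        n_copy_number_features = 39L,
                        n_fragmentation_pcs = 0L,
                        affected_batches = 1:16,
                        unaffected_batches = 17:38,
                        affected_prefix = "PGDX",
                        unaffected_prefix = "CGPL",
                        protein_shift = list(
                          healthy = c(ca125 = 0, he4 = 0),
                          benign  = c(ca125 = 1.5, he4 = 0.3),
                          cancer  = c(ca125 = 3.0, he4 = 2.6)),
                        protein_scale = c(healthy = 1, benign = 1, cancer = 1.5),
                        protein_cor = 0.57,
                        batch_affected_features = NULL,
                        copy_number_batch_offset = -2,
                        cancer_affected_features = NULL,
                        copy_number_cancer_effect = 0.3,
                        restrict_affected = TRUE,
                        leakage_mode = TRUE,
                        mix_batch10 = FALSE) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("cohort", "condition", "affected", "n") %in% names(counts)))
  counts$cohort <- match.arg(as.character(counts$cohort), c("discovery", "validation"),
                             several.ok = TRUE)
  counts$condition <- match.arg(as.character(counts$condition),
                                c("healthy", "benign", "cancer"), several.ok = TRUE)
  counts$affected <- as.logical(counts$affected)
  counts$n <- as.integer(counts$n)
  if (any(counts$n < 0)) stop("counts must be non-negative")
  if (length(intersect(affected_batches, unaffected_batches)) > 0L)
    stop("affected and unaffected batch ID sets must be disjoint")
  if (restrict_affected) {
    bad <- counts$affected & counts$n > 0 &
      (counts$condition == "healthy" | counts$cohort == "validation")
    if (any(bad))
      stop("affected batches may hold no healthy and no validation samples ",
           "(set restrict_affected = FALSE to override)")
  }
  features <- arm_names(as.integer(n_copy_number_features))
  if (is.null(batch_affected_features))
    batch_affected_features <- default_batch_affected(features)
  if (is.null(cancer_affected_features))
    cancer_affected_features <- default_cancer_affected(features)
  bad <- setdiff(c(batch_affected_features, cancer_affected_features), features)
  if (length(bad) > 0L)
    stop("affected feature names not among copy-number features: ",
         paste(bad, collapse = ", "))
  stopifnot(protein_cor > -1, protein_cor < 1,
            all(c("healthy", "benign", "cancer") %in% names(protein_shift)),
            all(c("healthy", "benign", "cancer") %in% names(protein_scale)))
  structure(list(
    counts = counts,
    n_copy_number_features = as.integer(n_copy_number_features),
    n_fragmentation_pcs = as.integer(n_fragmentation_pcs),
    copy_number_features = features,
    affected_batches = as.integer(affected_batches),
    unaffected_batches = as.integer(unaffected_batches),
    affected_prefix = affected_prefix,
    unaffected_prefix = unaffected_prefix,
    protein_shift = protein_shift,
    protein_scale = protein_scale,
    protein_cor = protein_cor,
    batch_affected_features = batch_affected_features,
    copy_number_batch_offset = copy_number_batch_offset,
    cancer_affected_features = cancer_affected_features,
    copy_number_cancer_effect = copy_number_cancer_effect,
    restrict_affected = isTRUE(restrict_affected),
    leakage_mode = isTRUE(leakage_mode),
    mix_batch10 = isTRUE(mix_batch10)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort specification:", sum(x$counts$n), "samples\n")
  print(stats::xtabs(n ~ cohort + condition + affected, data = x$counts))
  cat(sprintf("%d copy-number features (%d batch-affected at %+g SD, %d with cancer effect %+g SD)\n",
              x$n_copy_number_features, length(x$batch_affected_features),
              x$copy_number_batch_offset, length(x$cancer_affected_features),
              x$copy_number_cancer_effect))
  invisible(x)
}

#' Default cohort specification emulating the published study structure
#'
#' Marginal counts match the printed structure of the study this package
#' audits: 85 affected ("PGDX"-prefixed) samples, all in discovery batches
#' 1-16 (42 cancer, 43 benign; no healthy, no validation), and 394 unaffected
#' ("CGPL"-prefixed) samples including 182 discovery healthy and 52 discovery
#' cancer. Validation-cohort condition counts are not published; the defaults
#' (60 healthy, 30 benign, 30 cancer) and the 40 unaffected discovery benign
#' samples are documented choices that preserve the published totals.
#'
#' @param ... Overrides passed on to [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(...) {
  counts <- data.frame(
    cohort    = c("discovery", "discovery", "discovery", "discovery", "discovery",
                  "validation", "validation", "validation"),
    condition = c("healthy", "benign", "cancer", "benign", "cancer",
                  "healthy", "benign", "cancer"),
    affected  = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    n         = c(182L, 40L, 52L, 43L, 42L, 60L, 30L, 30L)
  )
  cohort_spec(counts = counts, ...)
}

# Deterministic batch assignment honouring the composition rules.
assign_batches <- function(meta, spec) {
  batch <- integer(nrow(meta))
  aff <- meta$affected
  if (any(aff)) {
    ab <- spec$affected_batches
    # single-condition affected batches: split the batch range by condition
    conds <- unique(meta$condition[aff])
    n_per <- table(factor(meta$condition[aff], levels = conds))
    n_batches <- pmax(1L, round(length(ab) * as.numeric(n_per) / sum(n_per)))
    while (sum(n_batches) > length(ab)) n_batches[which.max(n_batches)] <- n_batches[which.max(n_batches)] - 1L
    while (sum(n_batches) < length(ab)) n_batches[which.max(n_per)] <- n_batches[which.max(n_per)] + 1L
    start <- cumsum(c(0L, n_batches[-length(n_batches)]))
    for (i in seq_along(conds)) {
      idx <- which(aff & meta$condition == conds[i])
      pool <- ab[start[i] + seq_len(n_batches[i])]
      batch[idx] <- rep(pool, length.out = length(idx))
    }
    if (spec$mix_batch10 && 10L %in% ab && length(conds) >= 2L) {
      # move a few samples of a second condition into batch 10
      donors <- which(aff & meta$condition == conds[2] & batch != 10L)
      batch[utils::head(donors, 2L)] <- 10L
    }
  }
  if (any(!aff)) {
    ub <- spec$unaffected_batches
    if (spec$leakage_mode) {
      idx <- which(!aff)
      batch[idx] <- rep(ub, length.out = length(idx))
    } else {
      n_disc <- sum(!aff & meta$cohort == "discovery")
      n_val <- sum(!aff & meta$cohort == "validation")
      k <- max(1L, round(length(ub) * n_disc / max(1L, n_disc + n_val)))
      k <- min(k, length(ub) - (n_val > 0L))
      disc_b <- ub[seq_len(k)]
      val_b <- if (n_val > 0L) ub[(k + 1L):length(ub)] else integer()
      idx <- which(!aff & meta$cohort == "discovery")
      batch[idx] <- rep(disc_b, length.out = length(idx))
      idx <- which(!aff & meta$cohort == "validation")
      batch[idx] <- rep(val_b, length.out = length(idx))
    }
  }
  batch
}

#' Simulate a cohort from a specification
#'
#' Draws protein concentrations from the bivariate log-normal model (on the
#' zlog scale: correlated standard normals, shifted and scaled per
#' condition, then mapped through the inverse zlog transform), copy-number
#' features from a standard normal baseline plus the cancer effect and -- for
#' samples in affected batches -- the batch offset, and assigns batches
#' honouring the affected-batch composition rules. Identical `(spec, seed)`
#' pairs reproduce identical output.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; all randomness flows from it.
#' @param ranges Protein reference ranges used to map zlog draws to
#'   concentrations (default [default_reference_ranges()]).
#' @return List with elements `features` (a [feature_table()] of protein
#'   concentrations, copy-number features and optional fragmentation PCs)
#'   and `metadata` (data frame: `sample_id`, `prefix`, `batch`, `cohort`,
#'   `condition`).
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(), seed = 1)
#' table(cohort$metadata$cohort, cohort$metadata$condition)
#' @export
simulate_cohort <- function(spec, seed, ranges = default_reference_ranges()) {
  stopifnot(inherits(spec, "cohort_spec"), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  cnt <- spec$counts[spec$counts$n > 0, , drop = FALSE]
  meta <- data.frame(
    cohort    = rep(cnt$cohort, cnt$n),
    condition = rep(cnt$condition, cnt$n),
    affected  = rep(cnt$affected, cnt$n),
    stringsAsFactors = FALSE
  )
  n <- nrow(meta)
  if (n == 0L) stop("spec requests zero samples")
  meta$prefix <- ifelse(meta$affected, spec$affected_prefix, spec$unaffected_prefix)
  # affected samples carry the latest IDs in each prefix, mirroring the
  # "final 85 samples" layout; IDs are unique by construction
  id_no <- stats::ave(seq_len(n), meta$prefix, FUN = seq_along)
  meta$sample_id <- sprintf("%s%04d", meta$prefix, id_no)
  meta$batch <- assign_batches(meta, spec)

  # proteins: correlated standard normals on the zlog scale
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  rho <- spec$protein_cor
  z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  shift <- t(vapply(meta$condition, function(cc) spec$protein_shift[[cc]], numeric(2)))
  scale <- spec$protein_scale[meta$condition]
  z <- z * scale + shift
  ca125 <- inverse_zlog(z[, 1], ranges$ca125)
  he4 <- inverse_zlog(z[, 2], ranges$he4)

  cn <- matrix(stats::rnorm(n * spec$n_copy_number_features), nrow = n,
               dimnames = list(meta$sample_id, spec$copy_number_features))
  if (spec$copy_number_cancer_effect != 0 && length(spec$cancer_affected_features)) {
    is_cancer <- meta$condition == "cancer"
    cn[is_cancer, spec$cancer_affected_features] <-
      cn[is_cancer, spec$cancer_affected_features] + spec$copy_number_cancer_effect
  }
  if (spec$copy_number_batch_offset != 0 && length(spec$batch_affected_features)) {
    in_aff <- meta$batch %in% spec$affected_batches
    cn[in_aff, spec$batch_affected_features] <-
      cn[in_aff, spec$batch_affected_features] + spec$copy_number_batch_offset
  }

  vals <- cbind(ca125 = ca125, he4 = he4, cn)
  cats <- c(ca125 = "protein_concentration", he4 = "protein_concentration",
            stats::setNames(rep("copy_number", ncol(cn)), colnames(cn)))
  if (spec$n_fragmentation_pcs > 0L) {
    fp <- matrix(stats::rnorm(n * spec$n_fragmentation_pcs), nrow = n)
    colnames(fp) <- paste0("frag_pc", seq_len(spec$n_fragmentation_pcs))
    vals <- cbind(vals, fp)
    cats <- c(cats, stats::setNames(rep("fragmentation_pc", ncol(fp)), colnames(fp)))
  }
  rownames(vals) <- meta$sample_id

  list(
    features = feature_table(vals, cats),
    metadata = meta[, c("sample_id", "prefix", "batch", "cohort", "condition")]
  )
}
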