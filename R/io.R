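CONDITIONS <- c("healthy", "benign", "cancer")
COHORTS <- c("discovery", "validation")

# Strict-by-default normalization of metadata labels. Case variants and a
# few documented synonyms are mapped; anything else errors.
normalize_condition <- function(x) {
  key <- tolower(trimws(x))
  map <- c(healthy = "healthy", "no known lesions" = "healthy",
           normal = "healthy", benign = "benign", cancer = "cancer",
           malignant = "cancer")
  out <- unname(map[key])
  if (anyNA(out))
    stop("unknown condition label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

normalize_cohort <- function(x) {
  key <- tolower(trimws(x))
  map <- c(discovery = "discovery", training = "discovery",
           validation = "validation", test = "validation")
  out <- unname(map[key])
  if (anyNA(out))
    stop("unknown cohort label(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Validate (and normalize) a sample metadata table
#'
#' Checks the required columns (`sample_id`, `prefix`, `batch`, `cohort`,
#' `condition`), uniqueness of sample IDs, that each prefix is a leading
#' substring of its sample ID, and normalizes condition/cohort labels
#' (case-insensitively, with a small documented synonym map).
#'
#' @param metadata Data frame.
#' @return The normalized metadata data frame.
#' @export
validate_metadata <- function(metadata) {
  metadata <- as.data.frame(metadata)
  req <- c("sample_id", "prefix", "batch", "cohort", "condition")
  missing <- setdiff(req, names(metadata))
  if (length(missing) > 0L)
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample IDs: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  bad <- !startsWith(as.character(metadata$sample_id), as.character(metadata$prefix))
  if (any(bad))
    stop("prefix is not a leading substring of sample_id for: ",
         paste(metadata$sample_id[bad], collapse = ", "))
  metadata$condition <- normalize_condition(metadata$condition)
  metadata$cohort <- normalize_cohort(metadata$cohort)
  metadata$batch <- as.integer(metadata$batch)
  metadata[, req, drop = FALSE]
}

#' Read and write feature tables and metadata as TSV
#'
#' The feature table TSV has samples in rows: a `sample_id` column followed
#' by one column per feature, with a second header line of the form
#' `#categories<TAB>...` recording the per-feature category tags. Metadata
#' TSVs have the columns `sample_id`, `prefix`, `batch`, `cohort`,
#' `condition`.
#'
#' @param path File path.
#' @param table A [feature_table()] (for writing).
#' @param metadata A metadata data frame (for writing).
#' @return `read_feature_table` returns a [feature_table()];
#'   `read_metadata` a validated data frame; the writers return the path,
#'   invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(table$values)), collapse = "\t"), con)
  writeLines(paste(c("#categories", unname(table$categories)), collapse = "\t"), con)
  df <- data.frame(sample_id = rownames(table$values), table$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_feature_table <- function(path) {
  header <- readLines(path, n = 2L)
  cols <- strsplit(header[1L], "\t", fixed = TRUE)[[1L]]
  if (cols[1L] != "sample_id") stop("feature table must start with a sample_id column")
  has_cats <- length(header) > 1L && startsWith(header[2L], "#categories")
  df <- utils::read.delim(path, skip = if (has_cats) 2L else 1L, header = FALSE,
                          col.names = cols, check.names = FALSE,
                          colClasses = c("character", rep("numeric", length(cols) - 1L)))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample_id
  feats <- cols[-1L]
  cats <- if (has_cats) {
    v <- strsplit(header[2L], "\t", fixed = TRUE)[[1L]][-1L]
    stats::setNames(v, feats)
  } else {
    # infer tags from conventional column-name prefixes
    stats::setNames(ifelse(startsWith(feats, "zlog_"), "protein_zlog",
                    ifelse(startsWith(feats, "cn_"), "copy_number",
                    ifelse(startsWith(feats, "frag_"), "fragmentation_pc",
                           "protein_concentration"))), feats)
  }
  feature_table(m, cats)
}

#' @rdname table_io
#' @export
write_metadata <- function(metadata, path) {
  metadata <- validate_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  validate_metadata(df)
}

check_match <- function(table, metadata) {
  ids_t <- rownames(table$values)
  ids_m <- metadata$sample_id
  only_t <- setdiff(ids_t, ids_m)
  only_m <- setdiff(ids_m, ids_t)
  if (length(only_t) || length(only_m))
    stop("feature table / metadata sample mismatch; only in table: [",
         paste(only_t, collapse = ", "), "], only in metadata: [",
         paste(only_m, collapse = ", "), "]")
  invisible(TRUE)
}

#' Serialize a fitted model to JSON and back
#'
#' The JSON records feature names, coefficients, intercept, training-set
#' SDs and the fitting configuration, so importances are reproducible from
#' the file alone.
#'
#' @param model A fitted [plr()] model.
#' @param path JSON file path.
#' @return `write_model` returns the path invisibly; `read_model` a `"plr"`
#'   object.
#' @name model_io
NULL

#' @rdname model_io
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "plr"))
  obj <- list(
    feature_names = model$feature_names,
    coefficients = unname(model$coefficients[-1L]),
    intercept = unname(model$coefficients[1L]),
    feature_sd = if (is.null(model$feature_sd)) NULL else unname(model$feature_sd),
    C = model$C, class_weight = model$class_weight,
    positive_class = model$levels[2L]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname model_io
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as_plr(obj$coefficients, intercept = obj$intercept,
              features = obj$feature_names, feature_sd = obj$feature_sd)
  m$C <- obj$C
  m$class_weight <- obj$class_weight
  m
}

#' Serialize a cohort specification as YAML
#'
#' @param spec A [cohort_spec()].
#' @param path YAML file path.
#' @return `write_cohort_spec` returns the path invisibly;
#'   `read_cohort_spec` a `"cohort_spec"`.
#' @name spec_io
NULL

#' @rdname spec_io
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  obj <- unclass(spec)
  obj$counts <- lapply(seq_len(nrow(spec$counts)), function(i) as.list(spec$counts[i, ]))
  obj$copy_number_features <- NULL  # derived
  obj$protein_shift <- lapply(obj$protein_shift, as.list)
  obj$protein_scale <- as.list(obj$protein_scale)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname spec_io
#' @export
read_cohort_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  counts <- do.call(rbind, lapply(obj$counts, as.data.frame))
  cohort_spec(
    counts = counts,
    n_copy_number_features = obj$n_copy_number_features,
    n_fragmentation_pcs = obj$n_fragmentation_pcs,
    affected_batches = obj$affected_batches,
    unaffected_batches = obj$unaffected_batches,
    affected_prefix = obj$affected_prefix,
    unaffected_prefix = obj$unaffected_prefix,
    protein_shift = lapply(obj$protein_shift, unlist),
    protein_scale = unlist(obj$protein_scale),
    protein_cor = obj$protein_cor,
    batch_affected_features = obj$batch_affected_features,
    copy_number_batch_offset = obj$copy_number_batch_offset,
    cancer_affected_features = obj$cancer_affected_features,
    copy_number_cancer_effect = obj$copy_number_cancer_effect,
    restrict_affected = obj$restrict_affected,
    leakage_mode = obj$leakage_mode,
    mix_batch10 = obj$mix_batch10
  )
}
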