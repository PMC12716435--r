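#' Configuration for a full end-to-end analysis run
#'
#' Exactly one of a simulation spec or a pair of input paths must be given.
#'
#' @param spec A [cohort_spec()] to simulate from, or `NULL`.
#' @param feature_path,metadata_path TSV paths to an existing cohort, or
#'   `NULL`.
#' @param context `"screening"` or `"diagnostic"`.
#' @param features Optional model feature subset (default: all protein-zlog
#'   and copy-number columns).
#' @param exclude_prefix Prefix removed for the restricted model (default:
#'   the spec's affected prefix, else `"PGDX"`).
#' @param ranges Protein reference ranges (default
#'   [default_reference_ranges()]).
#' @param C,k,repeats Model and cross-validation parameters.
#' @param floor,prevalence Clinical threshold parameters.
#' @param seed Integer seed, recorded in every output.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(spec = NULL, feature_path = NULL, metadata_path = NULL,
                       context = c("screening", "diagnostic"), features = NULL,
                       exclude_prefix = NULL, ranges = default_reference_ranges(),
                       C = 1, k = 5L, repeats = 10L, floor = 0.99,
                       prevalence = 0.00145, seed = 1L) {
  context <- match.arg(context)
  has_spec <- !is.null(spec)
  has_paths <- !is.null(feature_path) || !is.null(metadata_path)
  if (has_spec == has_paths)
    stop("supply exactly one of a simulation spec or input table paths")
  if (has_paths && (is.null(feature_path) || is.null(metadata_path)))
    stop("both feature_path and metadata_path are required")
  if (is.null(exclude_prefix))
    exclude_prefix <- if (has_spec) spec$affected_prefix else "PGDX"
  structure(list(
    spec = spec, feature_path = feature_path, metadata_path = metadata_path,
    context = context, features = features, exclude_prefix = exclude_prefix,
    ranges = ranges, C = C, k = as.integer(k), repeats = as.integer(repeats),
    floor = floor, prevalence = prevalence, seed = as.integer(seed)
  ), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full confounding-audit analysis and write a report directory
#'
#' Executes, in order: (optional) cohort simulation, the zlog transform of
#' the protein concentrations, repeated stratified cross-validation on the
#' discovery cohort, a full refit, external scoring of the validation cohort
#' (when present), the batch-effect audit, the restricted (prefix-excluded)
#' refit, the feature-importance comparison between the two models, and the
#' clinical threshold report at the specificity floor. Every artifact is a
#' plain-text TSV/JSON/YAML file; the seed and configuration are echoed so a
#' rerun with the same config reproduces every number bit-for-bit.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`cohort`, `cv`,
#'   `model`, `restricted`, `audit`, `importance`, `thresholds`, `summary`).
#' @export
run_full_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log_add <- function(...) log_lines <<- c(log_lines, sprintf(...))

  cohort <- stage("input", {
    if (!is.null(config$spec)) {
      simulate_cohort(config$spec, seed = config$seed, ranges = config$ranges)
    } else {
      tab <- read_feature_table(config$feature_path)
      md <- read_metadata(config$metadata_path)
      check_match(tab, md)
      list(features = tab, metadata = md)
    }
  })
  log_add("input: %d samples, %d features, seed %d",
          nrow(cohort$features$values), ncol(cohort$features$values), config$seed)

  tab <- stage("zlog", {
    if (any(cohort$features$categories == "protein_concentration"))
      add_zlog_features(cohort$features, config$ranges)
    else cohort$features
  })
  md <- cohort$metadata

  model_features <- config$features
  if (is.null(model_features)) {
    keep <- tab$categories %in% c("protein_zlog", "copy_number", "fragmentation_pc")
    model_features <- names(tab$categories)[keep]
  }
  log_add("model features: %d (%s context)", length(model_features), config$context)

  disc <- stage("select", select_context(tab, md, config$context,
                                         cohort = "discovery",
                                         features = model_features))
  cv <- stage("cv", repeated_stratified_cv(disc$features, disc$labels,
                                           k = config$k, repeats = config$repeats,
                                           seed = config$seed, C = config$C))
  model <- stage("fit", plr(disc$features, disc$labels, C = config$C))
  log_add("discovery: n=%d (%d cancer), CV AUC %.4f", length(disc$labels),
          sum(disc$labels), cv$auc)

  has_validation <- any(md$cohort == "validation")
  val_scores <- NULL; val_auc <- NA_real_
  if (has_validation) {
    val <- stage("validation", select_context(tab, md, config$context,
                                              cohort = "validation",
                                              features = model_features))
    val_scores <- score_external(model, val$features)
    val_auc <- auc_rank(val_scores, val$labels)
    log_add("validation: n=%d (%d cancer), AUC %.4f", length(val$labels),
            sum(val$labels), val_auc)
  }

  audit <- stage("audit", audit_cohort(tab, md))
  restricted <- stage("restricted", restrict_and_refit(
    tab, md, config$exclude_prefix, context = config$context,
    features = model_features, k = config$k, repeats = config$repeats,
    seed = config$seed, C = config$C))
  rest_val_auc <- NA_real_
  if (has_validation) {
    rest_val_scores <- score_external(restricted$model, val$features)
    rest_val_auc <- auc_rank(rest_val_scores, val$labels)
  }
  log_add("restricted model: CV AUC %.4f, validation AUC %s",
          restricted$cv$auc,
          if (is.na(rest_val_auc)) "NA" else sprintf("%.4f", rest_val_auc))

  imp_full <- stage("importance", importance_table(model, tab))
  imp_rest <- importance_table(restricted$model, tab)
  imp_cmp <- compare_importances(imp_full, imp_rest)

  thr <- stage("thresholds", threshold_at_specificity(
    cv$scores, cv$labels, floor = config$floor, prevalence = config$prevalence))
  thr_rest <- threshold_at_specificity(
    restricted$cv$scores, restricted$cv$labels,
    floor = config$floor, prevalence = config$prevalence)

  # single-marker CA125 report with concentration conversion, when available
  ca125_report <- NULL
  if ("zlog_ca125" %in% colnames(tab$values)) {
    ca_fit <- plr(disc$features[, "zlog_ca125", drop = FALSE], disc$labels,
                  C = config$C)
    ca_cv <- repeated_stratified_cv(disc$features[, "zlog_ca125", drop = FALSE],
                                    disc$labels, k = config$k,
                                    repeats = config$repeats,
                                    seed = config$seed, C = config$C)
    ca125_report <- clinical_report(ca_cv$scores, ca_cv$labels,
                                    floor = config$floor,
                                    prevalence = config$prevalence,
                                    model = ca_fit, range = config$ranges$ca125)
  }

  # ---- write artifacts -------------------------------------------------
  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  write_feature_table(tab, file.path(out_dir, "features.tsv"))
  write_metadata(md, file.path(out_dir, "metadata.tsv"))
  wt(data.frame(sample_id = names(cv$scores), label = cv$labels,
                mean_score = unname(cv$scores)), "cv_scores.tsv")
  write_model(model, file.path(out_dir, "model.json"))
  write_model(restricted$model, file.path(out_dir, "restricted_model.json"))
  if (has_validation)
    wt(data.frame(sample_id = names(val_scores), label = val$labels,
                  score = unname(val_scores)), "validation_scores.tsv")
  write_audit_report(audit, out_dir)
  wt(as.data.frame(imp_full), "importance.tsv")
  wt(as.data.frame(imp_rest), "importance_restricted.tsv")
  wt(imp_cmp, "importance_comparison.tsv")
  thr_row <- function(r, label) data.frame(
    model = label, floor = r$floor, threshold = r$threshold,
    spec_k = r$spec_k, spec_n = r$spec_n, specificity = r$specificity,
    sensitivity = r$sensitivity, ppv = r$ppv,
    zlog = if (is.null(r$zlog)) NA_real_ else r$zlog,
    concentration = if (is.null(r$concentration)) NA_real_ else r$concentration)
  thr_tab <- rbind(thr_row(thr, "full"), thr_row(thr_rest, "restricted"))
  if (!is.null(ca125_report)) thr_tab <- rbind(thr_tab, thr_row(ca125_report, "ca125"))
  wt(thr_tab, "thresholds.tsv")

  summary <- list(
    seed = config$seed, context = config$context,
    n_samples = nrow(tab$values), n_model_features = length(model_features),
    cv_auc = cv$auc, validation_auc = val_auc,
    restricted_cv_auc = restricted$cv$auc,
    restricted_validation_auc = rest_val_auc,
    sensitivity_at_floor = thr$sensitivity,
    restricted_sensitivity_at_floor = thr_rest$sensitivity,
    ppv = thr$ppv
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_echo <- list(context = config$context, exclude_prefix = config$exclude_prefix,
                   C = config$C, k = config$k, repeats = config$repeats,
                   floor = config$floor, prevalence = config$prevalence,
                   seed = config$seed, features = model_features)
  yaml::write_yaml(cfg_echo, file.path(out_dir, "config.yaml"))
  if (!is.null(config$spec))
    write_cohort_spec(config$spec, file.path(out_dir, "cohort_spec.yaml"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  invisible(list(cohort = cohort, table = tab, cv = cv, model = model,
                 validation_auc = val_auc, restricted = restricted,
                 restricted_validation_auc = rest_val_auc, audit = audit,
                 importance = list(full = imp_full, restricted = imp_rest,
                                   comparison = imp_cmp),
                 thresholds = list(full = thr, restricted = thr_rest,
                                   ca125 = ca125_report),
                 summary = summary))
}
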