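test_that("single-feature AUC implements the orientation-free rank rule", {
  expect_equal(as.numeric(single_feature_auc(rep(1, 10), rep(0:1, 5))), 0.5)
  # all negatives above all positives: the max rule flips orientation
  expect_equal(as.numeric(single_feature_auc(c(5, 6, 1, 2), c(0, 0, 1, 1))), 1.0)
  a <- single_feature_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(as.numeric(a), 0.75)  # raw a = 0.75, already above 0.5
  expect_equal(as.numeric(single_feature_auc(c(1, 2, 3, 4), c(1, 0, 1, 0))), 0.75)
  expect_false(attr(a, "important"))
  expect_error(single_feature_auc(1:4, rep(1, 4)), "both classes")
})

test_that("single-feature AUC equals brute-force pairwise concordance", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    v <- sample(round(rnorm(n), 1))  # rounded values force ties
    y <- rbinom(n, 1, 0.5)
    y[1:2] <- 0:1
    a <- auc_bruteforce(v, y)
    expect_equal(as.numeric(single_feature_auc(v, y)), max(a, 1 - a),
                 tolerance = 1e-12)
  }
})

test_that("the reported AUC is invariant to monotone transforms and sign flips", {
  set.seed(8)
  v <- rnorm(40); y <- rep(0:1, 20)
  base <- as.numeric(single_feature_auc(v, y))
  expect_equal(as.numeric(single_feature_auc(exp(v), y)), base)
  expect_equal(as.numeric(single_feature_auc(-v, y)), base)
  expect_equal(as.numeric(single_feature_auc(rank(v), y)), base)
})

test_that("the prefix screen flags exactly the strongly offset features", {
  counts <- data.frame(cohort = "discovery", condition = "cancer",
                       affected = c(TRUE, FALSE), n = c(42L, 52L))
  spec <- cohort_spec(counts, copy_number_batch_offset = 10)
  co <- simulate_cohort(spec, seed = 21)
  screen <- prefix_confounding_screen(co$features, co$metadata)
  cn <- screen[startsWith(screen$feature, "cn_"), ]
  expect_setequal(cn$feature[cn$important], spec$batch_affected_features)
  expect_true(all(cn$auc[cn$important] > 0.99))
  expect_equal(round(mean(cn$important), 2), round(17 / 39, 2))
  # proteins are generated without any batch dependence
  prot <- screen[!startsWith(screen$feature, "cn_"), ]
  expect_true(all(prot$auc < 0.6))
  # a single prefix cannot be screened
  one <- co$metadata[co$metadata$prefix == "PGDX", ]
  tab_one <- co$features[rownames(co$features$values) %in% one$sample_id, ]
  expect_error(prefix_confounding_screen(tab_one, one), "two prefixes")
})

test_that("condition AUC screens respect context, filter and the 0.75 flag", {
  spec <- small_spec(copy_number_cancer_effect = 0)
  co <- simulate_cohort(spec, seed = 13)
  tab <- add_zlog_features(co$features)
  scr <- condition_auc_screen(tab, co$metadata, "screening",
                              prefix_filter = "CGPL")
  cn <- scr[startsWith(scr$feature, "cn_"), ]
  expect_false(any(cn$important))  # no cancer effect on copy number
  prot <- scr[scr$feature %in% c("zlog_ca125", "zlog_he4"), ]
  expect_true(all(prot$auc > 0.9))  # strong protein shifts at the defaults
  expect_error(condition_auc_screen(tab, co$metadata, "screening",
                                    prefix_filter = "XXXX"), "no samples")
  # a feature identical to the label has AUC exactly 1
  sel <- select_context(tab, co$metadata, "screening")
  expect_equal(as.numeric(single_feature_auc(sel$labels, sel$labels)), 1.0)
})

test_that("ANOVA ordering matches the pooled t-test in the two-group case", {
  co <- simulate_cohort(small_spec(), seed = 17)
  ao <- anova_order(co$features, co$metadata)
  md <- co$metadata
  cancer <- md$condition == "cancer"
  g <- md$prefix[cancer]
  for (f in sample(ao$feature, 8)) {
    v <- co$features$values[cancer, f]
    tt <- t.test(v ~ g, var.equal = TRUE)
    row <- ao[ao$feature == f, ]
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(row$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  }
  expect_false(is.unsorted(ao$p_value))
})

test_that("ANOVA ordering puts injected offsets first and constants last", {
  co <- simulate_cohort(small_spec(), seed = 23)
  vals <- co$features$values
  md <- co$metadata
  aff <- md$prefix == "PGDX"
  vals <- cbind(vals, big_offset = rnorm(nrow(vals)) + 10 * aff,
                flat = rep(1.5, nrow(vals)))
  cats <- c(co$features$categories,
            big_offset = "copy_number", flat = "copy_number")
  tab <- feature_table(vals, cats)
  ao <- anova_order(tab, md)
  expect_equal(ao$feature[1], "big_offset")
  expect_equal(ao$feature[nrow(ao)], "flat")
  expect_equal(ao$f_statistic[nrow(ao)], 0)
  # permutation equivariance: shuffling input columns shuffles nothing in the order
  perm <- sample(colnames(vals))
  ao2 <- anova_order(tab[, perm], md)
  expect_equal(ao2$feature, ao$feature)
  expect_equal(ao2$p_value, ao$p_value)
})

test_that("standardization gives zero-mean unit-SD columns and is idempotent", {
  set.seed(3)
  m <- matrix(rnorm(60, 5, 3), 20, dimnames = list(paste0("s", 1:20), c("a", "b", "c")))
  z <- standardize_features(m)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3))
  expect_equal(standardize_features(z), z, tolerance = 1e-12)
  # hand computation: sample SD of {1,2,3} is 1, population SD is sqrt(2/3)
  expect_equal(unname(standardize_features(cbind(v = c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))
  expect_equal(unname(standardize_features(cbind(v = c(1, 2, 3)),
                                           sd_type = "population")[, 1]),
               c(-1, 0, 1) / sqrt(2 / 3))
  expect_error(standardize_features(cbind(a = 1:5, bad = rep(2, 5))), "bad")
})

test_that("batch composition reports leakage and homogeneity", {
  co <- simulate_cohort(default_cohort_spec(), seed = 2)
  bc <- batch_composition(co$metadata)
  aff <- bc$counts$batch %in% 1:16
  expect_false(any(bc$counts$condition[aff] == "healthy"))
  expect_false(any(bc$counts$cohort[aff] == "validation"))
  expect_true(all(bc$flags$homogeneous[bc$flags$batch %in% 1:16]))
  expect_false(any(bc$flags$leakage[bc$flags$batch %in% 1:16]))
  # unaffected batches mix cohorts under the default leakage mode
  expect_true(any(bc$flags$leakage[bc$flags$batch %in% 17:38]))
  md <- data.frame(sample_id = c("A1", "A2", "A3"), prefix = "A",
                   batch = c(1L, 1L, 2L),
                   cohort = c("discovery", "validation", "discovery"),
                   condition = c("cancer", "cancer", "benign"))
  fl <- batch_composition(md)$flags
  expect_true(fl$leakage[fl$batch == 1])
  expect_true(fl$homogeneous[fl$batch == 1])
  expect_true(fl$homogeneous[fl$batch == 2])  # single sample
})

test_that("audit_cohort bundles the screens and writes a report directory", {
  co <- simulate_cohort(small_spec(), seed = 29)
  tab <- add_zlog_features(co$features)
  rep <- audit_cohort(tab, co$metadata)
  expect_s3_class(rep, "audit_report")
  expect_setequal(unique(rep$feature_auc$context),
                  c("screening", "diagnostic", "prefix"))
  # only copy-number + protein-zlog features are audited
  expect_false(any(rep$feature_auc$feature %in% c("ca125", "he4")))
  expect_equal(colnames(rep$standardized), rep$anova$feature)
  dir <- withr::local_tempdir()
  write_audit_report(rep, dir)
  expect_setequal(list.files(dir),
                  c("feature_auc.tsv", "anova_order.tsv", "standardized_matrix.tsv",
                    "batch_composition.tsv", "flags.tsv"))
  fa <- read.delim(file.path(dir, "feature_auc.tsv"))
  expect_equal(nrow(fa), nrow(rep$feature_auc))
})
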