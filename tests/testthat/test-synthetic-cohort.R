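test_that("the default cohort specification reproduces the published counts", {
  spec <- default_cohort_spec()
  cnt <- spec$counts
  n_of <- function(cohort, condition, affected)
    sum(cnt$n[cnt$cohort == cohort & cnt$condition == condition &
                cnt$affected == affected])
  expect_equal(n_of("discovery", "cancer", TRUE), 42)   # affected discovery cancer
  expect_equal(n_of("discovery", "cancer", FALSE), 52)  # unaffected discovery cancer
  expect_equal(sum(cnt$n[cnt$cohort == "discovery" & cnt$condition == "healthy"]), 182)
  n_aff <- sum(cnt$n[cnt$affected]); n_unaff <- sum(cnt$n[!cnt$affected])
  expect_equal(n_aff, 85)
  expect_equal(n_unaff, 394)
  expect_equal(round(n_unaff / n_aff, 1), 4.6)
})

test_that("simulation is deterministic and honors the requested structure", {
  spec <- small_spec()
  a <- simulate_cohort(spec, seed = 7)
  b <- simulate_cohort(spec, seed = 7)
  expect_identical(a, b)
  c <- simulate_cohort(spec, seed = 8)
  expect_false(identical(a$features$values, c$features$values))

  md <- a$metadata
  expect_equal(nrow(md), sum(spec$counts$n))
  expect_false(anyDuplicated(md$sample_id) > 0)
  expect_true(all(startsWith(md$sample_id, md$prefix)))
  expect_true(all(md$condition %in% c("healthy", "benign", "cancer")))
  expect_true(all(md$cohort %in% c("discovery", "validation")))
  # affected batches contain no healthy and no validation samples
  in_aff <- md$batch %in% spec$affected_batches
  expect_true(all(md$prefix[in_aff] == "PGDX"))
  expect_true(all(md$condition[in_aff] != "healthy"))
  expect_true(all(md$cohort[in_aff] == "discovery"))
  expect_true(all(md$batch[md$prefix == "CGPL"] %in% spec$unaffected_batches))
  # feature table invariants
  ft <- a$features
  expect_false(anyNA(ft$values))
  conc <- ft$values[, ft$categories == "protein_concentration"]
  expect_true(all(conc > 0))
})

test_that("spec validation rejects inconsistent requests", {
  counts <- data.frame(cohort = "discovery", condition = "cancer",
                       affected = FALSE, n = -1L)
  expect_error(cohort_spec(counts), "non-negative")
  counts$n <- 10L
  expect_error(cohort_spec(counts, affected_batches = 1:16,
                           unaffected_batches = 10:20), "disjoint")
  expect_error(cohort_spec(counts, batch_affected_features = "cn_nonsense"),
               "cn_nonsense")
  bad <- data.frame(cohort = "validation", condition = "cancer",
                    affected = TRUE, n = 5L)
  expect_error(cohort_spec(bad), "no healthy and no validation")
  expect_silent(cohort_spec(bad, restrict_affected = FALSE))
})

test_that("a null spec gives no discriminative features", {
  spec <- small_spec(
    protein_shift = list(healthy = c(ca125 = 0, he4 = 0),
                         benign = c(ca125 = 0, he4 = 0),
                         cancer = c(ca125 = 0, he4 = 0)),
    protein_scale = c(healthy = 1, benign = 1, cancer = 1),
    copy_number_batch_offset = 0, copy_number_cancer_effect = 0)
  co <- simulate_cohort(spec, seed = 11)
  sel <- select_context(co$features, co$metadata, "screening")
  aucs <- apply(sel$features, 2, single_feature_auc, labels = sel$labels)
  # Monte-Carlo error around 0.5; nothing should look strongly predictive
  expect_true(all(aucs < 0.75))
  expect_lt(mean(aucs), 0.60)
})

test_that("null calibration: under zero effects almost no feature is flagged", {
  counts <- data.frame(
    cohort = "discovery", condition = c("healthy", "cancer"),
    affected = FALSE, n = c(60L, 60L))
  spec <- cohort_spec(counts, n_copy_number_features = 250L,
                      protein_shift = list(healthy = c(ca125 = 0, he4 = 0),
                                           benign = c(ca125 = 0, he4 = 0),
                                           cancer = c(ca125 = 0, he4 = 0)),
                      copy_number_batch_offset = 0,
                      copy_number_cancer_effect = 0)
  co <- simulate_cohort(spec, seed = 3)
  sel <- select_context(co$features, co$metadata, "screening")
  cn <- sel$features[, startsWith(colnames(sel$features), "cn_")]
  flagged <- apply(cn, 2, function(v) single_feature_auc(v, sel$labels) > 0.75)
  expect_lt(mean(flagged), 0.01)
})

test_that("a large batch offset separates prefixes completely by construction", {
  counts <- data.frame(
    cohort = "discovery", condition = "cancer",
    affected = c(TRUE, FALSE), n = c(50L, 50L))
  spec <- cohort_spec(counts, batch_affected_features = "cn_18p",
                      copy_number_batch_offset = 10)
  co <- simulate_cohort(spec, seed = 5)
  screen <- prefix_confounding_screen(co$features, co$metadata)
  expect_equal(screen$auc[screen$feature == "cn_18p"], 1.0)
})

test_that("prefix-prediction AUC of an affected feature grows with the offset", {
  counts <- data.frame(
    cohort = "discovery", condition = "cancer",
    affected = c(TRUE, FALSE), n = c(40L, 40L))
  mean_auc <- vapply(c(0, 0.75, 1.5, 3), function(off) {
    spec <- cohort_spec(counts, batch_affected_features = "cn_18p",
                        copy_number_batch_offset = off)
    mean(vapply(1:5, function(s) {
      co <- simulate_cohort(spec, seed = 100 + s)
      screen <- prefix_confounding_screen(co$features, co$metadata)
      screen$auc[screen$feature == "cn_18p"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_auc) >= 0))
})

test_that("leakage_mode controls whether cohorts share batches", {
  leaky <- simulate_cohort(small_spec(leakage_mode = TRUE), seed = 2)
  clean <- simulate_cohort(small_spec(leakage_mode = FALSE), seed = 2)
  expect_true(any(batch_composition(leaky$metadata)$flags$leakage))
  expect_false(any(batch_composition(clean$metadata)$flags$leakage))
})
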