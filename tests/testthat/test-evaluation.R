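test_that("confusion metrics are exact fractions of the 2x2 counts", {
  # 4 detected of 7 carriers, no false positives, 94-sample cohort
  cf <- confusion_from_counts(tp = 4, fp = 0, tn = 87, fn = 3,
                              fusion_id = "CBFB-MYH11")
  expect_equal(cf$sensitivity, 4 / 7)
  expect_equal(cf$specificity, 1)
  expect_equal(cf$ppv, 1)
  expect_equal(cf$npv, 87 / 90)
  expect_equal(cf$fractions$npv, c(87, 90))
  expect_equal(cf$n, 7)

  # control-only situation: no carriers, sensitivity and PPV undefined
  cf0 <- confusion_from_counts(tp = 0, fp = 0, tn = 19, fn = 0)
  expect_true(is.na(cf0$sensitivity))
  expect_true(is.na(cf0$ppv))
  expect_equal(format_percent(cf0$fractions$sensitivity), "N/A")
  expect_equal(cf0$specificity, 1)

  # all-correct fusion: every metric 1
  cf1 <- confusion_from_counts(tp = 8, fp = 0, tn = 86, fn = 0)
  expect_equal(c(cf1$sensitivity, cf1$specificity, cf1$ppv, cf1$npv),
               rep(1, 4))

  expect_error(confusion_from_counts(tp = -1, fp = 0, tn = 0, fn = 0),
               class = "fusioncounter_validation_error")
})

test_that("percent formatting distinguishes truncation from rounding", {
  expect_equal(format_percent(c(4, 7), "truncate"), "57")
  expect_equal(format_percent(c(6, 7), "truncate"), "85")
  expect_equal(format_percent(c(6, 7), "round_half_up"), "86")
  expect_equal(format_percent(c(87, 90), "round_half_up"), "97")
  expect_equal(format_percent(c(87, 90), "truncate"), "96")
  expect_equal(format_percent(c(1, 8), "truncate"), "12")
  expect_equal(format_percent(c(3, 4), "truncate"), "75")
  expect_equal(format_percent(c(1, 2), "round_half_up"), "50")
  # plain proportions and undefined inputs
  expect_equal(format_percent(6 / 7, "truncate"), "85")
  expect_equal(format_percent(NA), "N/A")
  expect_error(format_percent(1.2), class = "fusioncounter_validation_error")
})

test_that("confusion from calls equals a per-sample tally on small instances", {
  cs <- mini_codeset()
  set.seed(88)
  for (rep in 1:10) {
    ids <- c("p1", "p2", paste0("n", 1:3))
    over <- list(`BCR-ABL1_junction` = rpois(5, 40),
                 `PML-RARA_junction` = rpois(5, 40))
    m <- mini_counts(cs, ids, fill = 0, override = over)
    nm <- subtract_background(m)
    ann <- mini_annotations(
      list(ALL = c("p1", "p2"), normal_marrow = paste0("n", 1:3)),
      fusion_ids(cs), list(p1 = "BCR-ABL1", p2 = "PML-RARA"))
    ct <- call_cohort(nm, ann, threshold = 2)
    truth <- truth_matrix(ann)
    for (f in fusion_ids(cs)) {
      cf <- confusion(ct, ann, f)
      oc <- oracle_confusion(ct$fusion_call, truth, f)
      expect_equal(c(tp = cf$tp, fp = cf$fp, tn = cf$tn, fn = cf$fn), oc)
      expect_equal(cf$tp + cf$fp + cf$tn + cf$fn, nrow(ann))
    }
  }
})

test_that("cohort rows carry both specificity definitions", {
  sim <- simulate_cohort(reference_scenario())
  nm <- normalize_counts(sim$counts)
  ann <- sim$truth$annotations
  ct <- call_cohort(nm, ann)

  ck <- cohort_row(ct, ann, "AML_complex_karyotype")
  expect_equal(ck$n, 21)
  expect_equal(ck$samples_with_any_positive_call, 1)
  expect_equal(ck$per_sample_specificity, 20 / 21)
  expect_equal(ck$per_test_specificity, 1 - 1 / (21 * 7))
  # one FP in 21 samples: per-sample prints 95, per-test prints 99
  expect_equal(format_percent(ck$per_sample_fraction, "truncate"), "95")
  expect_equal(format_percent(ck$per_test_fraction, "truncate"), "99")

  nk <- cohort_row(ct, ann, "AML_normal_karyotype")
  expect_equal(nk$per_sample_specificity, 1)
  expect_error(cohort_row(ct, ann, "ALL"),
               class = "fusioncounter_validation_error")
})

test_that("the full report reproduces the reference result pattern", {
  res <- run_pipeline(pipeline_config(simulation = reference_scenario(),
                                      out_dir = withr::local_tempdir()),
                      quiet = TRUE)
  rep <- res$report
  expect_equal(rep$fusion_rows$row, panel_fusions())
  expect_equal(c(rep$fusion_rows$result, rep$cohort_rows$result),
               expected_result_cells)
  expect_equal(rep$fusion_rows$result[rep$fusion_rows$row == "BCR-ABL1"],
               "7/0")
  expect_equal(rep$fusion_rows$result[rep$fusion_rows$row == "TCF3-PBX1"],
               "3/1")
  # zero positive calls anywhere -> all specificity cells 100
  cfg0 <- simulation_config(seed = 6)
  sim0 <- simulate_cohort(cfg0)
  ct0 <- call_cohort(normalize_counts(sim0$counts),
                     sim0$truth$annotations)
  rep0 <- diagnostic_report(ct0, sim0$truth$annotations)
  expect_true(all(rep0$fusion_rows$specificity_pct_trunc == "100"))
  expect_true(all(rep0$cohort_rows$per_sample_specificity_pct_trunc ==
                    "100"))
  expect_true(all(rep0$fusion_rows$sensitivity == 1))
})

test_that("PCA QC separates detectable carriers and is sign-stable", {
  sim <- simulate_cohort(reference_scenario())
  nm <- normalize_counts(sim$counts)
  ann <- sim$truth$annotations
  pc <- pca_qc(nm, ann)
  expect_equal(nrow(pc$coords), 94)
  expect_equal(ncol(pc$coords), 2)

  # coordinates agree across runs up to component sign
  pc2 <- pca_qc(nm, ann)
  agree <- vapply(1:2, function(j) {
    isTRUE(all.equal(pc$coords[, j], pc2$coords[, j])) ||
      isTRUE(all.equal(pc$coords[, j], -pc2$coords[, j]))
  }, logical(1))
  expect_true(all(agree))

  # detectable truth-positives cluster by fusion on PC1-2
  tm <- truth_matrix(ann)
  drop <- unlist(sim$truth$dropout_assignments)
  det <- ann$sample_id[rowSums(tm) > 0 & !ann$sample_id %in% drop]
  sil <- cluster::silhouette(as.integer(factor(pc$labels[det])),
                             dist(pc$coords[det, ]))
  expect_gt(mean(sil[, 3]), 0)

  # degenerate input: identical samples collapse to one point
  cs <- mini_codeset()
  m <- mini_counts(cs, c("a", "b", "c"), fill = 7)
  pcd <- pca_qc(subtract_background(m))
  expect_equal(max(abs(pcd$coords)), 0)
  expect_error(pca_qc(subtract_background(mini_counts(cs, c("a", "b"),
                                                      fill = 1))),
               class = "fusioncounter_validation_error")
})
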