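test_that("background subtraction follows the mean-of-negatives rule", {
  cs <- mini_codeset()
  # negatives [2,4,6,8,2,4,6,8]: mean 5; endogenous 12 -> 7; 3 -> floored 0
  m <- mini_counts(cs, "s1", fill = 0, override = list(
    NEG_A = 2, NEG_B = 4, NEG_C = 6, NEG_D = 8,
    NEG_E = 2, NEG_F = 4, NEG_G = 6, NEG_H = 8,
    `BCR-ABL1_junction` = 12, `PML-RARA_junction` = 3, TBP = 20))
  nm <- subtract_background(m)
  expect_equal(unname(nm$background_per_sample), 5)
  expect_equal(nm$values["BCR-ABL1_junction", "s1"], 7)
  expect_equal(nm$values["PML-RARA_junction", "s1"], 0)
  expect_equal(nm$values["TBP", "s1"], 15)
  # negative-control rows are carried unchanged for audit
  expect_equal(nm$values["NEG_A", "s1"], 2)

  # all negatives zero: everything else unchanged
  m0 <- mini_counts(cs, c("s1", "s2"), fill = 9)
  for (p in probes_of_class(cs, "negative")) m0$counts[p, ] <- 0L
  nm0 <- subtract_background(m0)
  expect_equal(nm0$values["TBP", ], c(s1 = 9, s2 = 9))
})

test_that("control factors equalize lanes to the cohort average", {
  cs <- mini_codeset()
  pos <- probes_of_class(cs, "positive")

  # all samples identical on the subset -> all factors 1
  v <- matrix(50, nrow = nrow(cs), ncol = 3,
              dimnames = list(cs$probe_id, c("a", "b", "c")))
  expect_equal(control_factor(v, pos)$factors, c(a = 1, b = 1, c = 1))

  # sample b exactly 2x sample a (offset disabled): factors 1.5 and 0.75
  v <- matrix(0, nrow = nrow(cs), ncol = 2,
              dimnames = list(cs$probe_id, c("a", "b")))
  v[pos, "a"] <- c(120, 60, 30, 16, 8, 4)
  v[pos, "b"] <- 2 * v[pos, "a"]
  f <- control_factor(v, pos, offset = 0)$factors
  expect_equal(f, c(a = 1.5, b = 0.75))

  # a lane far off the cohort average is flagged but still gets a factor:
  # five lanes at g and one at 10g give factor mean(1,1,1,1,1,10)/10 = 0.25
  v10 <- cbind(v[, rep("a", 5)], 10 * v[, "a", drop = FALSE])
  colnames(v10) <- letters[1:6]
  cf <- control_factor(v10, pos, offset = 0)
  expect_true(cf$flagged[["f"]])
  expect_equal(cf$factors[["f"]], 0.25)
  expect_false(any(cf$flagged[letters[1:5]]))

  # an all-zero subset gives factor 1 and the zero_controls flag
  vz <- v
  vz[pos, "b"] <- 0
  cf <- control_factor(vz, pos)
  expect_true(cf$zero_controls[["b"]])
  expect_equal(cf$factors[["b"]], 1)
})

test_that("a globally doubled lane normalizes to the same endogenous values", {
  cs <- mini_codeset()
  set.seed(31)
  # controls and signal well above the negative-control background so the
  # zero floor never engages
  base <- ifelse(cs$probe_class == "negative", rpois(nrow(cs), 15),
                 rpois(nrow(cs), 2000) + 500)
  m <- count_matrix(
    cbind(a = base, b = 2L * base) |>
      (\(x) {rownames(x) <- cs$probe_id; x})(), cs)
  nm <- normalize_counts(m, offset = 0)
  ev <- endogenous_values(nm)
  expect_equal(ev[, "a"], ev[, "b"])
  bv <- endogenous_values(nm, "binding")
  expect_equal(bv[, "a"], bv[, "b"])
})

test_that("scaling preserves the within-sample rank order of probes", {
  cs <- mini_codeset()
  set.seed(32)
  for (rep in 1:5) {
    m <- count_matrix(
      matrix(rpois(nrow(cs) * 4, 80), nrow = nrow(cs),
             dimnames = list(cs$probe_id, paste0("s", 1:4))), cs)
    nm <- normalize_counts(m)
    sub <- subtract_background(m)
    for (s in colnames(nm$values)) {
      expect_equal(order(nm$values[, s]), order(sub$values[, s]))
    }
  }
})

test_that("normalization is idempotent in the audit sense", {
  sim <- simulate_cohort(reference_scenario())
  a <- normalize_counts(sim$counts)
  b <- normalize_counts(sim$counts)
  expect_identical(a, b)
})

test_that("normalized output is non-negative and flagged lanes are retained", {
  sim <- simulate_cohort(reference_scenario())
  nm <- normalize_counts(sim$counts)
  expect_true(all(nm$values >= 0))
  expect_true(all(nm$pos_ctrl_factor_per_sample > 0))
  expect_true(all(nm$hk_factor_per_sample > 0))
  expect_equal(ncol(nm$values), 94)

  # a lane scaled 10x gets factor-flagged, not dropped
  cts <- sim$counts$counts
  cts[, 1] <- as.integer(pmin(cts[, 1] * 10, .Machine$integer.max))
  nm10 <- normalize_counts(count_matrix(cts, sim$counts$codeset))
  s1 <- colnames(cts)[1]
  expect_true("pos_ctrl_factor_out_of_range" %in% nm10$qc_flags[[s1]])
  expect_equal(ncol(nm10$values), 94)
})

test_that("both step orders run and agree on a variation-free cohort", {
  ann <- default_cohort()
  cfg <- simulation_config(annotations = ann, nb_dispersion = 0,
                           lane_factor_sd = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  a <- normalize_counts(sim$counts, order = "background-first")
  b <- normalize_counts(sim$counts, order = "posctrl-first")
  # with no lane variation both orders leave values essentially unscaled
  expect_equal(a$values["TBP", ], b$values["TBP", ], tolerance = 0.05)
})
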