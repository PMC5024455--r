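# Calling fixtures: a mini codeset whose negative controls are zero, so
# subtract_background() leaves values untouched and both the subtracted
# and binding value matrices equal the raw counts — noise and SNR then
# follow directly from the numbers written into the fixture.
calling_fixture <- function(endo_values, cohorts, positive_for = list()) {
  cs <- mini_codeset()
  ids <- unlist(cohorts, use.names = FALSE)
  m <- mini_counts(cs, ids, fill = 0, override = endo_values)
  nm <- subtract_background(m)
  ann <- mini_annotations(cohorts, fusion_ids(cs), positive_for)
  list(nm = nm, ann = ann, cs = cs)
}

test_that("noise is the floored median over true-negative samples", {
  fx <- calling_fixture(
    list(`BCR-ABL1_junction` = c(1, 2, 3, 4, 100),
         `PML-RARA_junction` = c(0, 0, 0, 0, 0)),
    cohorts = list(normal_marrow = paste0("n", 1:5)))
  ns <- estimate_noise(fx$nm, fx$ann)
  expect_equal(ns$noise[["BCR-ABL1_junction"]], 3)   # median by definition
  expect_equal(ns$noise[["PML-RARA_junction"]], 1)   # floor rule
  expect_setequal(ns$negatives_used[["BCR-ABL1_junction"]],
                  paste0("n", 1:5))

  # even negative count: mean of the two middle values
  fx2 <- calling_fixture(
    list(`BCR-ABL1_junction` = c(2, 4)),
    cohorts = list(normal_marrow = c("n1", "n2")))
  expect_equal(estimate_noise(fx2$nm, fx2$ann)$noise[["BCR-ABL1_junction"]],
               3)
})

test_that("noise policies use the documented negative sets", {
  fx <- calling_fixture(
    list(`BCR-ABL1_junction` = c(1000, 2, 4, 6, 8),
         `PML-RARA_junction` = c(3, 1, 1, 1, 1)),
    cohorts = list(ALL = "p1", normal_marrow = paste0("n", 1:4)),
    positive_for = list(p1 = "BCR-ABL1"))
  ctrl <- estimate_noise(fx$nm, fx$ann, policy = "controls_only")
  allnc <- estimate_noise(fx$nm, fx$ann, policy = "all_non_carriers")
  # controls_only: the four control samples, for every probe
  expect_setequal(ctrl$negatives_used[["PML-RARA_junction"]],
                  paste0("n", 1:4))
  # all_non_carriers additionally uses p1 for probes of fusions p1 lacks
  expect_setequal(allnc$negatives_used[["PML-RARA_junction"]],
                  c("p1", paste0("n", 1:4)))
  expect_setequal(allnc$negatives_used[["BCR-ABL1_junction"]],
                  paste0("n", 1:4))
  expect_equal(ctrl$noise[["PML-RARA_junction"]], 1)
  expect_equal(allnc$noise[["PML-RARA_junction"]], 1)

  # empty negative set is a configuration error
  fx_nopos <- calling_fixture(
    list(`BCR-ABL1_junction` = c(10, 20)),
    cohorts = list(ALL = c("p1", "p2")),
    positive_for = list(p1 = "BCR-ABL1", p2 = "PML-RARA"))
  expect_error(estimate_noise(fx_nopos$nm, fx_nopos$ann),
               class = "fusioncounter_config_error")
})

test_that("SNR is value over noise and the ten-fold cutoff is inclusive", {
  fx <- calling_fixture(
    list(`BCR-ABL1_junction` = c(50, 49, 0, 5, 5, 5, 5, 5),
         `PML-RARA_junction` = c(5, 5, 5, 5, 5, 5, 5, 5)),
    cohorts = list(ALL = c("p1", "p2", "p3"),
                   normal_marrow = paste0("n", 1:5)),
    positive_for = list(p1 = "BCR-ABL1", p2 = "BCR-ABL1",
                        p3 = "BCR-ABL1"))
  # noise over the five control samples is exactly 5
  ct <- compute_snr(fx$nm, estimate_noise(fx$nm, fx$ann))
  expect_equal(ct$snr["BCR-ABL1_junction", "p1"], 10)    # 50 / 5
  expect_equal(ct$snr["BCR-ABL1_junction", "p3"], 0)     # zero value
  expect_equal(ct$snr["PML-RARA_junction", "n1"], 1)     # value == noise
  expect_true(all(is.finite(ct$snr)) && all(ct$snr >= 0))

  ct <- call_fusions(ct, threshold = 10)
  expect_true(ct$probe_call["BCR-ABL1_junction", "p1"])   # SNR exactly 10
  expect_false(ct$probe_call["BCR-ABL1_junction", "p2"])  # SNR 9.8
  expect_true(ct$fusion_call["BCR-ABL1", "p1"])
  expect_error(call_fusions(ct, threshold = 0),
               class = "fusioncounter_config_error")
})

test_that("a fusion is positive when any of its probes is", {
  cs <- default_codeset(multiprobe_cbfb = TRUE)
  probes <- c("CBFB-MYH11_junction_typeA", "CBFB-MYH11_junction_typeD",
              "CBFB-MYH11_junction_typeE")
  ids <- c("p1", paste0("n", 1:5))
  over <- list()
  over[[probes[1]]] <- c(250, 5, 5, 5, 5, 5)  # SNR 50 in p1
  over[[probes[2]]] <- c(10, 5, 5, 5, 5, 5)   # SNR 2
  over[[probes[3]]] <- c(5, 5, 5, 5, 5, 5)    # SNR 1
  m <- count_matrix(
    matrix(0L, nrow = nrow(cs), ncol = length(ids),
           dimnames = list(cs$probe_id, ids)) |>
      (\(x) {for (p in names(over)) x[p, ] <- over[[p]]; x})(), cs)
  nm <- subtract_background(m)
  ann <- mini_annotations(list(AML_translocated = "p1",
                               normal_marrow = paste0("n", 1:5)),
                          fusion_ids(cs), list(p1 = "CBFB-MYH11"))
  ct <- call_cohort(nm, ann)
  expect_equal(unname(ct$snr[probes, "p1"]), c(50, 2, 1))
  expect_true(ct$fusion_call["CBFB-MYH11", "p1"])
  expect_false(any(ct$fusion_call[, paste0("n", 1:5)]))
})

test_that("raising the threshold never increases the number of calls", {
  sim <- simulate_cohort(reference_scenario())
  nm <- normalize_counts(sim$counts)
  noise <- estimate_noise(nm, sim$truth$annotations)
  ct <- compute_snr(nm, noise)
  n_calls <- vapply(c(1, 2, 5, 10, 50, 150, 1000), function(th) {
    sum(call_fusions(ct, threshold = th)$fusion_call)
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("both noise policies give identical calls on the reference scenario", {
  sim <- simulate_cohort(reference_scenario())
  nm <- normalize_counts(sim$counts)
  ann <- sim$truth$annotations
  ct_ctrl <- call_cohort(nm, ann, policy = "controls_only")
  ct_all <- call_cohort(nm, ann, policy = "all_non_carriers")
  expect_identical(ct_ctrl$fusion_call, ct_all$fusion_call)
  # and the policies' negative sets are nested
  n_ctrl <- estimate_noise(nm, ann, policy = "controls_only")
  n_all <- estimate_noise(nm, ann, policy = "all_non_carriers")
  for (p in names(n_ctrl$noise)) {
    expect_true(all(n_ctrl$negatives_used[[p]] %in%
                      n_all$negatives_used[[p]]))
  }
})

test_that("pipeline calls equal a naive loop implementation on small instances", {
  cs <- mini_codeset()
  set.seed(77)
  for (rep in 1:10) {
    ids <- c("p1", paste0("n", 1:4))  # 5 samples, 2 endogenous probes
    over <- list(`BCR-ABL1_junction` = rpois(5, 30),
                 `PML-RARA_junction` = rpois(5, 30))
    m <- mini_counts(cs, ids, fill = 0, override = over)
    nm <- subtract_background(m)
    ann <- mini_annotations(list(ALL = "p1",
                                 normal_marrow = paste0("n", 1:4)),
                            fusion_ids(cs), list(p1 = "BCR-ABL1"))
    threshold <- sample(c(1, 2, 10), 1)
    ct <- call_cohort(nm, ann, threshold = threshold)

    v <- endogenous_values(nm, "binding")
    noise <- vapply(rownames(v), function(p) {
      max(1, median(v[p, paste0("n", 1:4)]))
    }, numeric(1))
    probe_fusion <- setNames(cs$fusion_id[match(rownames(v), cs$probe_id)],
                             rownames(v))
    expect_identical(
      ct$fusion_call[rownames(ct$fusion_call), ],
      oracle_calls(v, noise, probe_fusion, threshold)[
        rownames(ct$fusion_call), ])
  }
})
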