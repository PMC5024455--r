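# Fixtures are built in code: a miniature two-fusion codeset with the
# standard 6 positive / 8 negative / 2 housekeeping control layout, plus
# builders for toy count matrices and annotation tables.

mini_codeset <- function(fusions = c("BCR-ABL1", "PML-RARA"),
                         n_positive = 6, n_negative = 8) {
  probes <- rbind(
    data.frame(probe_id = paste0(fusions, "_junction"),
               probe_class = "endogenous", fusion_id = fusions,
               pos_ctrl_concentration = NA_real_),
    data.frame(probe_id = paste0("POS_", LETTERS[seq_len(n_positive)]),
               probe_class = "positive", fusion_id = NA_character_,
               pos_ctrl_concentration = c(128, 32, 8, 2, 0.5,
                                          0.125)[seq_len(n_positive)]),
    data.frame(probe_id = paste0("NEG_", LETTERS[seq_len(n_negative)]),
               probe_class = "negative", fusion_id = NA_character_,
               pos_ctrl_concentration = NA_real_),
    data.frame(probe_id = c("TBP", "GUSB"), probe_class = "housekeeping",
               fusion_id = NA_character_, pos_ctrl_concentration = NA_real_)
  )
  codeset(probes, n_positive = n_positive, n_negative = n_negative)
}

# count matrix over a mini codeset with every probe at `fill`, overridden
# per probe by rows of `override` (probe_id -> numeric vector per sample)
mini_counts <- function(cs, sample_ids, fill = 0, override = list()) {
  m <- matrix(fill, nrow = nrow(cs), ncol = length(sample_ids),
              dimnames = list(cs$probe_id, sample_ids))
  for (p in names(override)) m[p, ] <- override[[p]]
  count_matrix(m, cs)
}

# annotation table: named list cohort -> sample ids; `positive_for` maps
# sample id -> fusion id
mini_annotations <- function(cohorts, fusions, positive_for = list()) {
  rows <- do.call(rbind, lapply(names(cohorts), function(co) {
    data.frame(sample_id = cohorts[[co]], cohort = co)
  }))
  for (f in fusions) {
    rows[[f]] <- vapply(rows$sample_id, function(s) {
      identical(positive_for[[s]], f)
    }, logical(1))
  }
  sample_annotations(rows, fusions = fusions)
}

# independent naive implementation of the calling rule: explicit loops,
# no matrix algebra shared with the package internals
oracle_calls <- function(values, noise_by_probe, probe_fusion, threshold) {
  fusions <- unique(probe_fusion)
  out <- matrix(FALSE, nrow = length(fusions), ncol = ncol(values),
                dimnames = list(fusions, colnames(values)))
  for (f in fusions) {
    for (s in colnames(values)) {
      pos <- FALSE
      for (p in names(probe_fusion)[probe_fusion == f]) {
        if (values[p, s] / noise_by_probe[p] >= threshold) pos <- TRUE
      }
      out[f, s] <- pos
    }
  }
  out
}

# independent per-sample tally of 2x2 confusion counts
oracle_confusion <- function(calls, truth, fusion) {
  tp <- fp <- tn <- fn <- 0
  for (s in colnames(calls)) {
    if (calls[fusion, s] && truth[s, fusion]) tp <- tp + 1
    if (calls[fusion, s] && !truth[s, fusion]) fp <- fp + 1
    if (!calls[fusion, s] && truth[s, fusion]) fn <- fn + 1
    if (!calls[fusion, s] && !truth[s, fusion]) tn <- tn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

expected_result_cells <- c("8/0", "8/0", "4/3", "3/1", "6/1", "7/0", "1/7",
                           "0/19", "1/20", "0/5")
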