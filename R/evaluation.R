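# Diagnostic evaluation against the karyotype/FISH reference: exact 2x2
# confusion counts per fusion over the whole cohort, sensitivity /
# specificity / PPV / NPV as exact fractions, per-cohort specificity rows
# for the fusion-negative cohorts, and an assay-validation-style summary
# table. Integer-percent formatting is presentation only and carries an
# explicit convention, because published validation tables mix truncation
# and rounding; exact fractions are always reported alongside.

#' Exact 2x2 confusion statistics for one fusion
#'
#' Counts are taken over the whole cohort: every sample truth-positive for
#' the fusion contributes to TP/FN, every other sample (including carriers
#' of different fusions) to FP/TN. Metrics are exact fractions; a metric
#' with a zero denominator is undefined and formats as "N/A".
#'
#' @param ct A completed `call_table` (or a logical fusions x samples call
#'   matrix).
#' @param ann A `sample_annotations` covering the same samples.
#' @param fusion_id Which fusion to tabulate.
#' @return A `confusion_stats` list: `fusion_id`, `n` (truth-positives),
#'   `tp`, `fp`, `tn`, `fn`, numeric `sensitivity`/`specificity`/`ppv`/
#'   `npv` (NA when undefined) and `fractions` (metric -> c(num, den)).
#' @export
confusion <- function(ct, ann, fusion_id) {
  stopifnot(inherits(ann, "sample_annotations"))
  calls <- if (inherits(ct, "call_table")) ct$fusion_call else ct
  if (is.null(calls)) stop_config("calls not made yet; run call_fusions()")
  if (!fusion_id %in% rownames(calls) ||
      !fusion_id %in% attr(ann, "fusions")) {
    stop_validation("fusion '", fusion_id, "' not covered by calls and ",
                    "annotations")
  }
  if (!setequal(colnames(calls), ann$sample_id)) {
    stop_validation("calls and annotations cover different samples")
  }
  truth <- truth_matrix(ann)[colnames(calls), fusion_id]
  call <- calls[fusion_id, ]
  tp <- sum(call & truth); fn <- sum(!call & truth)
  fp <- sum(call & !truth); tn <- sum(!call & !truth)
  frac <- list(sensitivity = c(tp, tp + fn),
               specificity = c(tn, tn + fp),
               ppv = c(tp, tp + fp),
               npv = c(tn, tn + fn))
  metric <- vapply(frac, function(x) {
    if (x[2] == 0) NA_real_ else x[1] / x[2]
  }, numeric(1))
  structure(list(fusion_id = fusion_id, n = tp + fn,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = metric[["sensitivity"]],
                 specificity = metric[["specificity"]],
                 ppv = metric[["ppv"]], npv = metric[["npv"]],
                 fractions = frac),
            class = "confusion_stats")
}

#' Build confusion statistics directly from printed 2x2 counts
#'
#' Convenience entry for re-deriving a published validation table's
#' percent cells from its confusion counts.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @param fusion_id Optional label.
#' @return A `confusion_stats`.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn, fusion_id = NA_character_) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0 | counts != round(counts))) {
    stop_validation("confusion counts must be non-negative integers")
  }
  frac <- list(sensitivity = c(tp, tp + fn), specificity = c(tn, tn + fp),
               ppv = c(tp, tp + fp), npv = c(tn, tn + fn))
  metric <- vapply(frac, function(x) {
    if (x[2] == 0) NA_real_ else x[1] / x[2]
  }, numeric(1))
  structure(list(fusion_id = fusion_id, n = tp + fn,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = metric[["sensitivity"]],
                 specificity = metric[["specificity"]],
                 ppv = metric[["ppv"]], npv = metric[["npv"]],
                 fractions = frac),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat("Confusion for ", x$fusion_id, ": TP ", x$tp, ", FP ", x$fp,
      ", TN ", x$tn, ", FN ", x$fn, "\n", sep = "")
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    fr <- x$fractions[[m]]
    cat(sprintf("  %-11s %s  (%s)\n", m,
                format_percent_frac(fr[1], fr[2], "truncate"),
                paste0(fr[1], "/", fr[2])))
  }
  invisible(x)
}

# exact integer-percent of num/den under a stated convention
format_percent_frac <- function(num, den,
                                convention = c("truncate",
                                               "round_half_up")) {
  convention <- match.arg(convention)
  if (den == 0) return("N/A")
  if (convention == "truncate") {
    as.character((100 * num) %/% den)
  } else {
    as.character((200 * num + den) %/% (2 * den))
  }
}

#' Format a proportion as an integer-percent string
#'
#' `truncate` drops the fractional percent (6/7 -> "85"); `round_half_up`
#' rounds it, halves away from zero (87/90 -> "97"). Undefined values
#' (NA, or a `confusion_stats` metric with zero denominator) give "N/A".
#' When `x` is given as a length-2 `c(numerator, denominator)` vector the
#' percent is computed in exact integer arithmetic.
#'
#' @param x Proportion in [0, 1], or `c(num, den)` integer fraction, or NA.
#' @param convention `"truncate"` or `"round_half_up"`.
#' @return Character scalar.
#' @export
format_percent <- function(x, convention = c("truncate", "round_half_up")) {
  convention <- match.arg(convention)
  if (length(x) == 2 && !anyNA(x)) {
    return(format_percent_frac(x[1], x[2], convention))
  }
  if (length(x) != 1 || is.na(x)) return("N/A")
  if (x < 0 || x > 1) stop_validation("proportion must be in [0, 1]")
  # route through a high-resolution fraction so float noise cannot flip
  # the truncation boundary
  format_percent_frac(round(x * 1e9), 1e9, convention)
}

#' Per-cohort specificity row for a fusion-negative cohort
#'
#' Two specificity definitions are computed: per-sample, the fraction of
#' cohort samples with no positive call on any fusion; per-test, the
#' fraction of sample x fusion tests that stayed negative. Published
#' validation tables may print either (a single false positive among 21
#' samples gives 95 per-sample but 99 per-test over 7 fusions).
#'
#' @param ct A completed `call_table`.
#' @param ann A `sample_annotations`.
#' @param cohort One of the control cohort labels.
#' @return List: `cohort`, `n`, `samples_with_any_positive_call`,
#'   `positive_calls`, `per_sample_specificity`, `per_test_specificity`
#'   and their fractions.
#' @export
cohort_row <- function(ct, ann, cohort) {
  stopifnot(inherits(ct, "call_table"), inherits(ann, "sample_annotations"))
  if (!cohort %in% CONTROL_COHORTS) {
    stop_validation("'", cohort, "' is not a control cohort")
  }
  ids <- ann$sample_id[ann$cohort == cohort]
  calls <- ct$fusion_call[, ids, drop = FALSE]
  n <- length(ids)
  n_fus <- nrow(calls)
  affected <- sum(apply(calls, 2, any))
  pos_calls <- sum(calls)
  list(cohort = cohort, n = n,
       samples_with_any_positive_call = affected,
       positive_calls = pos_calls,
       per_sample_specificity = if (n > 0) (n - affected) / n else NA_real_,
       per_sample_fraction = c(n - affected, n),
       per_test_specificity = if (n > 0) 1 - pos_calls / (n * n_fus)
       else NA_real_,
       per_test_fraction = c(n * n_fus - pos_calls, n * n_fus))
}

#' Assay-validation summary table
#'
#' One row per fusion (n truth-positives, "Pos/Neg" result string among
#' them, sensitivity/specificity/PPV/NPV) followed by one row per
#' fusion-negative cohort (result string = samples with any positive call
#' / clean samples; sensitivity and PPV are N/A, specificity under both
#' the per-sample and per-test definitions). Percent columns are given
#' under both formatting conventions next to the exact fractions.
#'
#' @param ct A completed `call_table`.
#' @param ann A `sample_annotations`.
#' @return A `diagnostic_report`: list with `fusion_rows` and
#'   `cohort_rows` data.frames and `confusions` (per-fusion
#'   `confusion_stats`).
#' @export
diagnostic_report <- function(ct, ann) {
  stopifnot(inherits(ct, "call_table"), inherits(ann, "sample_annotations"))
  fus <- rownames(ct$fusion_call)
  confs <- lapply(fus, function(f) confusion(ct, ann, f))
  names(confs) <- fus
  frow <- do.call(rbind, lapply(confs, function(cf) {
    fr <- cf$fractions
    data.frame(
      row = cf$fusion_id, n = cf$n,
      result = paste0(cf$tp, "/", cf$fn),
      sensitivity = cf$sensitivity, specificity = cf$specificity,
      ppv = cf$ppv, npv = cf$npv,
      sensitivity_frac = paste0(fr$sensitivity[1], "/", fr$sensitivity[2]),
      specificity_frac = paste0(fr$specificity[1], "/", fr$specificity[2]),
      ppv_frac = paste0(fr$ppv[1], "/", fr$ppv[2]),
      npv_frac = paste0(fr$npv[1], "/", fr$npv[2]),
      sensitivity_pct_trunc = format_percent_frac(fr$sensitivity[1],
                                                  fr$sensitivity[2],
                                                  "truncate"),
      specificity_pct_trunc = format_percent_frac(fr$specificity[1],
                                                  fr$specificity[2],
                                                  "truncate"),
      ppv_pct_trunc = format_percent_frac(fr$ppv[1], fr$ppv[2], "truncate"),
      npv_pct_trunc = format_percent_frac(fr$npv[1], fr$npv[2], "truncate"),
      sensitivity_pct_round = format_percent_frac(fr$sensitivity[1],
                                                  fr$sensitivity[2],
                                                  "round_half_up"),
      specificity_pct_round = format_percent_frac(fr$specificity[1],
                                                  fr$specificity[2],
                                                  "round_half_up"),
      ppv_pct_round = format_percent_frac(fr$ppv[1], fr$ppv[2],
                                          "round_half_up"),
      npv_pct_round = format_percent_frac(fr$npv[1], fr$npv[2],
                                          "round_half_up"),
      stringsAsFactors = FALSE)
  }))
  crow <- do.call(rbind, lapply(
    intersect(CONTROL_COHORTS, unique(ann$cohort)), function(co) {
      r <- cohort_row(ct, ann, co)
      data.frame(
        row = co, n = r$n,
        result = paste0(r$samples_with_any_positive_call, "/",
                        r$n - r$samples_with_any_positive_call),
        samples_with_any_positive_call = r$samples_with_any_positive_call,
        positive_calls = r$positive_calls,
        per_sample_specificity = r$per_sample_specificity,
        per_test_specificity = r$per_test_specificity,
        per_sample_specificity_pct_trunc = format_percent_frac(
          r$per_sample_fraction[1], r$per_sample_fraction[2], "truncate"),
        per_test_specificity_pct_trunc = format_percent_frac(
          r$per_test_fraction[1], r$per_test_fraction[2], "truncate"),
        per_sample_specificity_pct_round = format_percent_frac(
          r$per_sample_fraction[1], r$per_sample_fraction[2],
          "round_half_up"),
        per_test_specificity_pct_round = format_percent_frac(
          r$per_test_fraction[1], r$per_test_fraction[2], "round_half_up"),
        stringsAsFactors = FALSE)
    }))
  rownames(frow) <- rownames(crow) <- NULL
  structure(list(fusion_rows = frow, cohort_rows = crow,
                 confusions = confs, threshold = ct$threshold,
                 n_samples = ncol(ct$fusion_call)),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic report over", x$n_samples, "samples (SNR threshold",
      x$threshold, ")\n\n")
  f <- x$fusion_rows
  print(data.frame(row = f$row, n = f$n, result = f$result,
                   sens = f$sensitivity_pct_trunc,
                   spec = f$specificity_pct_trunc,
                   ppv = f$ppv_pct_trunc, npv = f$npv_pct_round),
        row.names = FALSE)
  cat("\n")
  cc <- x$cohort_rows
  print(data.frame(row = cc$row, n = cc$n, result = cc$result,
                   spec_per_sample = cc$per_sample_specificity_pct_trunc,
                   spec_per_test = cc$per_test_specificity_pct_trunc),
        row.names = FALSE)
  invisible(x)
}

#' Write a diagnostic report as TSV and/or JSON
#'
#' @param report A `diagnostic_report`.
#' @param tsv_path,json_path Output paths (`NULL` skips either).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "diagnostic_report"))
  if (!is.null(tsv_path)) {
    f <- report$fusion_rows
    cc <- report$cohort_rows
    all_cols <- union(names(f), names(cc))
    pad <- function(df) {
      for (col in setdiff(all_cols, names(df))) df[[col]] <- NA
      df[all_cols]
    }
    utils::write.table(rbind(pad(f), pad(cc)), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_samples = report$n_samples, threshold = report$threshold,
           fusion_rows = report$fusion_rows,
           cohort_rows = report$cohort_rows),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
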