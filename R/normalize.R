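# Three-step count normalization for digital counting lanes:
#   1. background subtraction — the arithmetic mean of the 8 negative
#      controls of each lane is subtracted from every probe of that lane
#      (floored at zero);
#   2. positive-control scaling — each lane is multiplied by a factor that
#      equalizes the geometric mean of its 6 spiked positive controls to
#      the cohort average;
#   3. housekeeping scaling — likewise for the housekeeping genes
#      (TBP and GUSB in the default panel), correcting for RNA input.
# The step order follows the assay's analysis description
# (background first); the vendor-style order (positive-control scaling
# before background subtraction) is available via `order`.

QC_FLAG_LEVELS <- c("pos_ctrl_factor_out_of_range", "hk_factor_out_of_range",
                    "zero_controls")

new_normalized_matrix <- function(values, binding, background, pos_f, hk_f,
                                  flags, cs, order, offset) {
  structure(list(values = values, binding = binding,
                 background_per_sample = background,
                 pos_ctrl_factor_per_sample = pos_f,
                 hk_factor_per_sample = hk_f,
                 qc_flags = flags, codeset = cs,
                 order = order, offset = offset),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  n_flag <- sum(lengths(x$qc_flags) > 0)
  cat("Normalized matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples;", n_flag, "sample(s) QC-flagged\n")
  invisible(x)
}

#' Subtract per-lane negative-control background
#'
#' For each sample the background is the arithmetic mean of its negative
#' control counts; every other probe's count is replaced by
#' `max(0, count - background)`. Negative-control rows are carried through
#' unchanged for audit.
#'
#' @param m A `count_matrix` (or a numeric probes x samples matrix inside a
#'   partially normalized object).
#' @param cs The `codeset`.
#' @return A `normalized_matrix` with only the background step applied
#'   (scale factors set to 1).
#' @export
subtract_background <- function(m, cs = m$codeset) {
  stopifnot(inherits(m, "count_matrix"))
  v <- apply_background(m$counts * 1.0, cs)
  ones <- stats::setNames(rep(1, ncol(m$counts)), colnames(m$counts))
  new_normalized_matrix(v$values, m$counts * 1.0, v$background,
                        ones, ones,
                        empty_flags(colnames(m$counts)), cs,
                        order = "background-only", offset = 1)
}

apply_background <- function(values, cs) {
  neg <- probes_of_class(cs, "negative")
  if (length(neg) == 0) stop_config("codeset has no negative control probes")
  background <- colMeans(values[neg, , drop = FALSE])
  out <- pmax(sweep(values, 2, background, "-"), 0)
  out[neg, ] <- values[neg, , drop = FALSE]  # audit: negatives unchanged
  list(values = out, background = background)
}

empty_flags <- function(sample_ids) {
  stats::setNames(rep(list(character(0)), length(sample_ids)), sample_ids)
}

#' Per-sample scaling factors from a control probe subset
#'
#' Summarizes each sample by the geometric mean of its control values
#' (with a `+offset` pseudocount so zero counts are tolerated) and returns
#' `factor_s = mean(g) / g_s`, the multiplier that brings sample `s` to the
#' cohort average. Samples whose control values are all zero (or whose
#' geometric mean is zero when the offset is disabled) get factor 1 and a
#' `zero_controls` flag and are excluded from the cohort average. Factors
#' outside `range` are flagged but still applied — flagged lanes are
#' retained, never dropped.
#'
#' @param values Numeric probes x samples matrix.
#' @param probe_ids Control subset (e.g. the positive-control probe ids).
#' @param offset Pseudocount added before the geometric mean (default 1; 0
#'   disables).
#' @param range Acceptable factor range, default `c(0.3, 3)`.
#' @return List with `factors` (named numeric), `flagged` (named logical,
#'   out-of-range), `zero_controls` (named logical).
#' @export
control_factor <- function(values, probe_ids, offset = 1,
                           range = c(0.3, 3)) {
  if (length(probe_ids) == 0) stop_config("control probe subset is empty")
  sub <- values[probe_ids, , drop = FALSE]
  g <- exp(colMeans(log(sub + offset)))
  zero <- colSums(sub) == 0 | g <= 0 | !is.finite(g)
  usable <- g[!zero]
  factors <- rep(1, ncol(values))
  names(factors) <- colnames(values)
  if (length(usable) > 0) {
    factors[!zero] <- mean(usable) / usable
  }
  flagged <- factors < range[1] | factors > range[2]
  list(factors = factors, flagged = flagged & !zero, zero_controls = zero)
}

#' Full three-step normalization
#'
#' Runs background subtraction, positive-control scaling and housekeeping
#' scaling in the configured order and records every factor and QC flag.
#' Besides the background-subtracted expression values, the scaled but
#' unsubtracted *binding* values (raw counts times both scale factors) are
#' kept: the fusion-calling stage measures signal-to-noise on binding
#' values by default, because its noise term is itself a background
#' estimate (see [estimate_noise()]).
#'
#' @param m A `count_matrix`.
#' @param cs The `codeset` (default: the one bound to `m`).
#' @param order `"background-first"` (background subtraction, then
#'   positive-control scaling, then housekeeping scaling — the default) or
#'   `"posctrl-first"` (positive-control scaling on raw counts first, then
#'   background subtraction, then housekeeping scaling).
#' @param offset Pseudocount for the geometric-mean control summaries
#'   (default 1; 0 disables).
#' @param factor_range QC range for scale factors, default `c(0.3, 3)`;
#'   out-of-range lanes are flagged, never excluded.
#' @return A `normalized_matrix`: `values` (background-subtracted, scaled,
#'   non-negative), `binding` (scaled, unsubtracted),
#'   `background_per_sample`, `pos_ctrl_factor_per_sample`,
#'   `hk_factor_per_sample`, `qc_flags` (sample -> character vector of
#'   flags).
#' @export
normalize_counts <- function(m, cs = m$codeset,
                             order = c("background-first", "posctrl-first"),
                             offset = 1, factor_range = c(0.3, 3)) {
  stopifnot(inherits(m, "count_matrix"))
  order <- match.arg(order)
  pos <- probes_of_class(cs, "positive")
  hk <- probes_of_class(cs, "housekeeping")
  if (length(hk) == 0) stop_config("codeset has no housekeeping probes")
  samples <- colnames(m$counts)
  flags <- empty_flags(samples)
  add_flag <- function(flags, which_samples, flag) {
    for (s in samples[which_samples]) flags[[s]] <- union(flags[[s]], flag)
    flags
  }

  v <- m$counts * 1.0
  if (order == "background-first") {
    b <- apply_background(v, cs)
    v <- b$values
    background <- b$background
  }
  pf <- control_factor(v, pos, offset = offset, range = factor_range)
  v <- sweep(v, 2, pf$factors, "*")
  if (order == "posctrl-first") {
    b <- apply_background(v, cs)
    v <- b$values
    background <- b$background
  }
  hf <- control_factor(v, hk, offset = offset, range = factor_range)
  v <- sweep(v, 2, hf$factors, "*")

  flags <- add_flag(flags, pf$flagged, "pos_ctrl_factor_out_of_range")
  flags <- add_flag(flags, hf$flagged, "hk_factor_out_of_range")
  flags <- add_flag(flags, pf$zero_controls | hf$zero_controls,
                    "zero_controls")

  binding <- sweep(sweep(m$counts * 1.0, 2, pf$factors, "*"),
                   2, hf$factors, "*")
  new_normalized_matrix(v, binding, background, pf$factors, hf$factors,
                        flags, cs, order, offset)
}

#' Normalized values of the endogenous (fusion junction) probes
#' @param nm A `normalized_matrix`.
#' @param values `"subtracted"` (background-subtracted expression values)
#'   or `"binding"` (scaled, unsubtracted).
#' @return Numeric matrix, endogenous probes x samples.
#' @export
endogenous_values <- function(nm, values = c("subtracted", "binding")) {
  stopifnot(inherits(nm, "normalized_matrix"))
  values <- match.arg(values)
  endo <- probes_of_class(nm$codeset, "endogenous")
  src <- if (values == "binding") nm$binding else nm$values
  src[endo, , drop = FALSE]
}

#' Write normalized values and the normalization audit trail
#'
#' @param nm A `normalized_matrix`.
#' @param values_path CSV destination for the normalized value matrix
#'   (CodeClass, Name, one column per sample), or `NULL` to skip.
#' @param audit_path JSON destination for backgrounds, factors and QC
#'   flags, or `NULL` to skip.
#' @return `nm`, invisibly.
#' @export
write_normalized <- function(nm, values_path = NULL, audit_path = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  cs <- nm$codeset
  if (!is.null(values_path)) {
    df <- cbind(
      data.frame(CodeClass = unname(CODECLASS_LABELS[cs$probe_class]),
                 Name = cs$probe_id, check.names = FALSE),
      as.data.frame(nm$values, check.names = FALSE))
    utils::write.csv(df, values_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(audit_path)) {
    audit <- list(order = nm$order, offset = nm$offset,
                  background_per_sample = as.list(nm$background_per_sample),
                  pos_ctrl_factor_per_sample =
                    as.list(nm$pos_ctrl_factor_per_sample),
                  hk_factor_per_sample = as.list(nm$hk_factor_per_sample),
                  qc_flags = nm$qc_flags[lengths(nm$qc_flags) > 0])
    jsonlite::write_json(audit, audit_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(nm)
}
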