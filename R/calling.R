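# The decision rule: for each endogenous junction probe, "noise" is the
# median binding value over true-negative samples; a sample is positive on
# a probe when its signal-to-noise ratio (binding value / noise) reaches
# ten-fold or more (inclusive), and positive for a fusion when any of the
# fusion's probes is positive. The median binding level of true negatives
# is itself the background of the test, which is why SNR is computed on
# scaled unsubtracted binding values by default; computing it on
# background-subtracted values instead is available for sensitivity
# analysis.

#' Estimate per-probe noise from true-negative samples
#'
#' Noise for a probe is the median of its normalized values over the
#' negative sample set, floored from below. Under the default
#' `controls_only` policy the negative set is the three fusion-negative
#' control cohorts (normal karyotype, complex karyotype, normal marrow) —
#' the cohort's designated true negatives, used for every probe. Under
#' `all_non_carriers` each probe uses every sample whose truth status
#' lacks that probe's fusion (a per-probe superset of the control set).
#' A true-negative sample's own value is part of its probe's median; the
#' median is the usual mean-of-middle-two for even sample counts.
#'
#' @param nm A `normalized_matrix`.
#' @param ann A `sample_annotations` covering the same samples.
#' @param policy `"controls_only"` (default) or `"all_non_carriers"`.
#' @param floor Lower bound for the noise (default 1 normalized count),
#'   guarding the SNR denominator when negatives sit at zero.
#' @param values Which normalized values noise (and later SNR) is measured
#'   on: `"binding"` (scaled, unsubtracted; default) or `"subtracted"`.
#' @return A `noise_estimates`: `noise` (named numeric per endogenous
#'   probe), `negatives_used` (named list of sample ids), `policy`,
#'   `floor`, `values`.
#' @export
estimate_noise <- function(nm, ann,
                           policy = c("controls_only", "all_non_carriers"),
                           floor = 1, values = c("binding", "subtracted")) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(ann, "sample_annotations"))
  policy <- match.arg(policy)
  values <- match.arg(values)
  if (floor <= 0) stop_config("noise floor must be > 0")
  v <- endogenous_values(nm, values = values)
  if (!setequal(colnames(v), ann$sample_id)) {
    stop_validation("normalized matrix and annotations cover different ",
                    "samples")
  }
  cs <- nm$codeset
  truth <- truth_matrix(ann)
  endo <- rownames(v)
  noise <- stats::setNames(numeric(length(endo)), endo)
  used <- stats::setNames(vector("list", length(endo)), endo)
  controls <- ann$sample_id[ann$cohort %in% CONTROL_COHORTS]
  for (p in endo) {
    f <- cs$fusion_id[cs$probe_id == p]
    neg <- if (policy == "controls_only") controls else
      ann$sample_id[!truth[, f]]
    if (length(neg) == 0) {
      stop_config("no negative samples for probe '", p, "' under policy ",
                  policy)
    }
    used[[p]] <- neg
    noise[p] <- max(floor, stats::median(v[p, neg]))
  }
  structure(list(noise = noise, negatives_used = used, policy = policy,
                 floor = floor, values = values),
            class = "noise_estimates")
}

#' Signal-to-noise ratios for every sample x endogenous probe
#'
#' @param nm A `normalized_matrix`.
#' @param noise A `noise_estimates` covering all endogenous probes; the
#'   SNR is measured on the same value type (`binding` or `subtracted`)
#'   the noise was estimated on.
#' @return A `call_table` with the `snr` matrix filled and calls empty.
#' @export
compute_snr <- function(nm, noise) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(noise, "noise_estimates"))
  v <- endogenous_values(nm, values = noise$values)
  missing <- setdiff(rownames(v), names(noise$noise))
  if (length(missing) > 0) {
    stop_config("noise estimates missing for probe(s): ",
                paste(missing, collapse = ", "))
  }
  snr <- v / noise$noise[rownames(v)]
  structure(list(snr = snr, probe_call = NULL, fusion_call = NULL,
                 threshold = NULL, noise = noise, codeset = nm$codeset),
            class = "call_table")
}

#' Apply the ten-fold SNR threshold and aggregate probes to fusions
#'
#' A probe call is positive when its SNR is at least `threshold`
#' (inclusive — "ten-fold or more"); a fusion call is positive when any of
#' its probes is.
#'
#' @param ct A `call_table` from [compute_snr()].
#' @param threshold Positive SNR cutoff (default 10).
#' @return The `call_table` with `probe_call` (logical probes x samples)
#'   and `fusion_call` (logical fusions x samples) filled.
#' @export
call_fusions <- function(ct, threshold = 10) {
  stopifnot(inherits(ct, "call_table"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop_config("threshold must be a single positive number")
  }
  ct$threshold <- threshold
  ct$probe_call <- ct$snr >= threshold
  cs <- ct$codeset
  fus <- fusion_ids(cs)
  fc <- matrix(FALSE, nrow = length(fus), ncol = ncol(ct$snr),
               dimnames = list(fus, colnames(ct$snr)))
  for (f in fus) {
    p <- probes_for_fusion(cs, f)
    fc[f, ] <- apply(ct$probe_call[p, , drop = FALSE], 2, any)
  }
  ct$fusion_call <- fc
  ct
}

#' @export
print.call_table <- function(x, ...) {
  cat("Call table:", nrow(x$snr), "probes x", ncol(x$snr), "samples")
  if (!is.null(x$fusion_call)) {
    cat(";", sum(x$fusion_call), "positive fusion call(s) at SNR >=",
        x$threshold)
  }
  cat("\n")
  invisible(x)
}

#' Normalize, estimate noise, compute SNR and call in one step
#'
#' @param nm A `normalized_matrix`.
#' @param ann A `sample_annotations`.
#' @param threshold SNR cutoff (default 10).
#' @inheritParams estimate_noise
#' @return A completed `call_table`.
#' @export
call_cohort <- function(nm, ann, threshold = 10,
                        policy = c("controls_only", "all_non_carriers"),
                        floor = 1, values = c("binding", "subtracted")) {
  noise <- estimate_noise(nm, ann, policy = policy, floor = floor,
                          values = values)
  call_fusions(compute_snr(nm, noise), threshold = threshold)
}

#' Per-fusion maximum SNR and call, in long format
#'
#' @param ct A completed `call_table`.
#' @return data.frame with columns `sample_id`, `fusion_id`, `snr_max`
#'   (largest SNR over the fusion's probes) and `call`.
#' @export
calls_long <- function(ct) {
  stopifnot(inherits(ct, "call_table"))
  if (is.null(ct$fusion_call)) stop_config("calls not made yet; run call_fusions()")
  cs <- ct$codeset
  fus <- rownames(ct$fusion_call)
  out <- do.call(rbind, lapply(fus, function(f) {
    p <- probes_for_fusion(cs, f)
    data.frame(sample_id = colnames(ct$snr), fusion_id = f,
               snr_max = apply(ct$snr[p, , drop = FALSE], 2, max),
               call = ct$fusion_call[f, ])
  }))
  rownames(out) <- NULL
  out
}
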