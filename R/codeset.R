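#' @keywords internal
"_PACKAGE"

PROBE_CLASSES <- c("endogenous", "positive", "negative", "housekeeping")

#' The seven recurrent fusion transcripts targeted by the default panel
#'
#' Junction-probe targets for the recurrent acute-leukemia translocations:
#' t(8;21) AML1-ETO (RUNX1-RUNX1T1), t(15;17) PML-RARA, inv(16) CBFB-MYH11,
#' t(1;19) TCF3-PBX1, t(4;11) MLL-AF4, t(9;22) BCR-ABL1 and t(12;21)
#' ETV6-RUNX1.
#'
#' @return Character vector of fusion identifiers, AML targets first.
#' @export
panel_fusions <- function() {
  c("AML1-ETO", "PML-RARA", "CBFB-MYH11",
    "TCF3-PBX1", "MLL-AF4", "BCR-ABL1", "ETV6-RUNX1")
}

# disease group each fusion belongs to; drives the cohort label of its
# truth-positive samples
fusion_disease_group <- function(fusion_id) {
  grp <- c("AML1-ETO" = "AML_translocated", "PML-RARA" = "AML_translocated",
           "CBFB-MYH11" = "AML_translocated", "TCF3-PBX1" = "ALL",
           "MLL-AF4" = "ALL", "BCR-ABL1" = "ALL", "ETV6-RUNX1" = "ALL")
  unname(grp[fusion_id])
}

#' Construct and validate a CodeSet (probe inventory)
#'
#' A CodeSet is the probe inventory of a digital counting assay: endogenous
#' junction probes (each targeting one fusion transcript), spiked positive
#' controls at a known titration series, target-free negative controls used
#' for background estimation, and housekeeping probes used to normalize for
#' RNA input.
#'
#' @param probes data.frame with columns `probe_id`, `probe_class` (one of
#'   `"endogenous"`, `"positive"`, `"negative"`, `"housekeeping"`),
#'   `fusion_id` (required exactly for endogenous probes, `NA` otherwise)
#'   and `pos_ctrl_concentration` (fM; required positive exactly for
#'   positive-control probes, `NA` otherwise).
#' @param n_positive,n_negative Required number of positive / negative
#'   control probes (the standard lane configuration has 6 positive and 8
#'   negative controls). Set either to `NA` to skip the count check.
#' @return A `codeset`: the validated data.frame with attribute
#'   `fusion_ids` (distinct endogenous targets, in order of appearance).
#' @export
codeset <- function(probes, n_positive = 6L, n_negative = 8L) {
  required <- c("probe_id", "probe_class", "fusion_id",
                "pos_ctrl_concentration")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols) > 0) {
    stop_validation("codeset is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  probes <- as.data.frame(probes)[required]
  probes$probe_id <- as.character(probes$probe_id)
  probes$probe_class <- as.character(probes$probe_class)
  probes$fusion_id <- as.character(probes$fusion_id)
  probes$pos_ctrl_concentration <- as.numeric(probes$pos_ctrl_concentration)

  bad_class <- !probes$probe_class %in% PROBE_CLASSES
  if (any(bad_class)) {
    stop_validation("unknown probe_class '",
                    probes$probe_class[which(bad_class)[1]],
                    "' in row ", which(bad_class)[1],
                    " (probe '", probes$probe_id[which(bad_class)[1]], "')")
  }
  dup <- duplicated(probes$probe_id)
  if (any(dup)) {
    stop_validation("duplicate probe_id '", probes$probe_id[which(dup)[1]],
                    "' in row ", which(dup)[1])
  }

  is_endo <- probes$probe_class == "endogenous"
  has_fusion <- !is.na(probes$fusion_id) & nzchar(probes$fusion_id)
  off <- which(is_endo != has_fusion)
  if (length(off) > 0) {
    stop_validation("fusion_id must be present exactly for endogenous ",
                    "probes; violated in row ", off[1],
                    " (probe '", probes$probe_id[off[1]], "')")
  }

  is_pos <- probes$probe_class == "positive"
  has_conc <- !is.na(probes$pos_ctrl_concentration) &
    probes$pos_ctrl_concentration > 0
  off <- which(is_pos != has_conc)
  if (length(off) > 0) {
    stop_validation("pos_ctrl_concentration must be a positive number ",
                    "exactly for positive-control probes; violated in row ",
                    off[1], " (probe '", probes$probe_id[off[1]], "')")
  }

  n_pos <- sum(is_pos)
  n_neg <- sum(probes$probe_class == "negative")
  if (!is.na(n_positive) && n_pos != n_positive) {
    stop_validation("codeset has ", n_pos, " positive control probe(s); ",
                    "expected exactly ", n_positive)
  }
  if (!is.na(n_negative) && n_neg != n_negative) {
    stop_validation("codeset has ", n_neg, " negative control probe(s); ",
                    "expected exactly ", n_negative)
  }
  if (sum(probes$probe_class == "housekeeping") < 1) {
    stop_validation("codeset needs at least one housekeeping probe")
  }
  if (sum(is_endo) < 1) {
    stop_validation("codeset needs at least one endogenous probe")
  }

  rownames(probes) <- NULL
  structure(probes,
            fusion_ids = unique(probes$fusion_id[is_endo]),
            class = c("codeset", "data.frame"))
}

#' @export
print.codeset <- function(x, ...) {
  tab <- table(factor(x$probe_class, levels = PROBE_CLASSES))
  cat("CodeSet with", nrow(x), "probes (",
      paste(paste0(names(tab), ": ", as.integer(tab)), collapse = ", "),
      ")\n")
  cat("Fusion targets:", paste(attr(x, "fusion_ids"), collapse = ", "), "\n")
  invisible(x)
}

#' Fusion targets of a CodeSet
#' @param cs A `codeset`.
#' @return Character vector of distinct fusion identifiers.
#' @export
fusion_ids <- function(cs) {
  stopifnot(inherits(cs, "codeset"))
  attr(cs, "fusion_ids")
}

#' Probe ids of a given class
#' @param cs A `codeset`.
#' @param class One of `"endogenous"`, `"positive"`, `"negative"`,
#'   `"housekeeping"`.
#' @return Character vector of probe ids.
#' @export
probes_of_class <- function(cs, class) {
  class <- match.arg(class, PROBE_CLASSES)
  cs$probe_id[cs$probe_class == class]
}

# endogenous probe ids for one fusion
probes_for_fusion <- function(cs, fusion_id) {
  cs$probe_id[cs$probe_class == "endogenous" &
                !is.na(cs$fusion_id) & cs$fusion_id == fusion_id]
}

#' Default CodeSet for the seven-fusion acute-leukemia panel
#'
#' One junction probe per fusion, six positive-control probes on the
#' standard geometric titration series (128, 32, 8, 2, 0.5, 0.125 fM),
#' eight negative controls, and the two housekeeping genes TBP and GUSB.
#' With `multiprobe_cbfb = TRUE` the CBFB-MYH11 target carries three
#' isoform-specific junction probes instead of one, reflecting the
#' breakpoint heterogeneity of inv(16) (more than ten differently sized
#' CBFB-MYH11 fusion transcripts are known); this exercises probe-to-fusion
#' aggregation.
#'
#' @param multiprobe_cbfb Use three CBFB-MYH11 isoform probes.
#' @return A `codeset`.
#' @export
default_codeset <- function(multiprobe_cbfb = FALSE) {
  endo <- data.frame(fusion_id = panel_fusions(),
                     probe_id = paste0(panel_fusions(), "_junction"))
  if (multiprobe_cbfb) {
    i <- endo$fusion_id == "CBFB-MYH11"
    endo <- rbind(
      endo[seq_len(which(i) - 1), ],
      data.frame(fusion_id = "CBFB-MYH11",
                 probe_id = paste0("CBFB-MYH11_junction_",
                                   c("typeA", "typeD", "typeE"))),
      endo[seq(which(i) + 1, nrow(endo)), ]
    )
  }
  conc <- c(128, 32, 8, 2, 0.5, 0.125)
  probes <- rbind(
    data.frame(probe_id = endo$probe_id, probe_class = "endogenous",
               fusion_id = endo$fusion_id, pos_ctrl_concentration = NA_real_),
    data.frame(probe_id = paste0("POS_", LETTERS[1:6]),
               probe_class = "positive", fusion_id = NA_character_,
               pos_ctrl_concentration = conc),
    data.frame(probe_id = paste0("NEG_", LETTERS[1:8]),
               probe_class = "negative", fusion_id = NA_character_,
               pos_ctrl_concentration = NA_real_),
    data.frame(probe_id = c("TBP", "GUSB"), probe_class = "housekeeping",
               fusion_id = NA_character_,
               pos_ctrl_concentration = NA_real_)
  )
  codeset(probes)
}

#' Read a CodeSet from a tab-separated file
#'
#' Expects a header line with columns `probe_id`, `probe_class`,
#' `fusion_id`, `pos_ctrl_concentration`; empty `fusion_id` /
#' `pos_ctrl_concentration` cells stand for "not applicable".
#'
#' @param path Path to a TSV file.
#' @inheritParams codeset
#' @return A validated `codeset`.
#' @export
load_codeset <- function(path, n_positive = 6L, n_negative = 8L) {
  if (!file.exists(path)) stop_io("codeset file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  codeset(df, n_positive = n_positive, n_negative = n_negative)
}

#' Write a CodeSet to a tab-separated file
#' @param cs A `codeset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codeset <- function(cs, path) {
  stopifnot(inherits(cs, "codeset"))
  df <- as.data.frame(cs)
  df$pos_ctrl_concentration <-
    ifelse(is.na(df$pos_ctrl_concentration), "",
           format(df$pos_ctrl_concentration, trim = TRUE, scientific = FALSE))
  df$fusion_id[is.na(df$fusion_id)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
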