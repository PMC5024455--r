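# Sample annotations: cohort label plus the karyotype/FISH reference
# ("truth") status for every fusion in the panel. Samples from the three
# fusion-negative cohorts (normal karyotype, complex karyotype, normal
# marrow) are the assay's true negatives.

COHORT_LEVELS <- c("AML_translocated", "ALL", "AML_normal_karyotype",
                   "AML_complex_karyotype", "normal_marrow")
CONTROL_COHORTS <- c("AML_normal_karyotype", "AML_complex_karyotype",
                     "normal_marrow")

#' Construct sample annotations with karyotype/FISH truth labels
#'
#' @param df data.frame with columns `sample_id`, `cohort` (one of
#'   `r paste0('\x60', COHORT_LEVELS, '\x60', collapse = ", ")`) and one
#'   logical column per fusion giving the reference (karyotype/FISH)
#'   status.
#' @param fusions Fusion ids the truth map must cover (default: the fusion
#'   columns present).
#' @param single_fusion Require that each translocated (AML_translocated /
#'   ALL) sample is truth-positive for exactly one fusion. The generator
#'   can relax this for hypothetical co-occurring rearrangements.
#' @return A `sample_annotations` data.frame.
#' @export
sample_annotations <- function(df, fusions = NULL, single_fusion = TRUE) {
  df <- as.data.frame(df)
  if (!all(c("sample_id", "cohort") %in% names(df))) {
    stop_validation("annotations need sample_id and cohort columns")
  }
  if (is.null(fusions)) {
    fusions <- setdiff(names(df), c("sample_id", "cohort"))
  }
  missing <- setdiff(fusions, names(df))
  if (length(missing) > 0) {
    stop_validation("annotations lack truth column(s) for fusion(s): ",
                    paste(missing, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  dup <- duplicated(df$sample_id)
  if (any(dup)) {
    stop_validation("duplicate sample_id '", df$sample_id[which(dup)[1]],
                    "' in row ", which(dup)[1])
  }
  bad <- !df$cohort %in% COHORT_LEVELS
  if (any(bad)) {
    stop_validation("unknown cohort label '", df$cohort[which(bad)[1]],
                    "' in row ", which(bad)[1],
                    " (sample '", df$sample_id[which(bad)[1]], "')")
  }
  for (f in fusions) {
    v <- df[[f]]
    if (is.character(v)) v <- tolower(v) == "true"
    if (!is.logical(v) || anyNA(v)) {
      stop_validation("truth column '", f, "' must be boolean with no ",
                      "missing values")
    }
    df[[f]] <- v
  }
  truth <- as.matrix(df[fusions])
  ctrl <- df$cohort %in% CONTROL_COHORTS
  off <- which(ctrl & rowSums(truth) > 0)
  if (length(off) > 0) {
    stop_validation("control-cohort sample '", df$sample_id[off[1]],
                    "' (", df$cohort[off[1]], ") is marked truth-positive ",
                    "for ", fusions[which(truth[off[1], ])[1]])
  }
  if (single_fusion) {
    off <- which(!ctrl & rowSums(truth) != 1)
    if (length(off) > 0) {
      stop_validation("translocated sample '", df$sample_id[off[1]],
                      "' must be truth-positive for exactly one fusion ",
                      "(has ", rowSums(truth)[off[1]], ")")
    }
  }
  df <- df[c("sample_id", "cohort", fusions)]
  rownames(df) <- NULL
  structure(df, fusions = fusions,
            class = c("sample_annotations", "data.frame"))
}

#' @export
print.sample_annotations <- function(x, ...) {
  cat("Annotations for", nrow(x), "samples (",
      paste(paste0(names(table(x$cohort)), ": ", table(x$cohort)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Truth matrix of an annotation table
#' @param ann A `sample_annotations`.
#' @return Logical matrix, samples x fusions, rownames = sample ids.
#' @export
truth_matrix <- function(ann) {
  stopifnot(inherits(ann, "sample_annotations"))
  m <- as.matrix(as.data.frame(ann)[attr(ann, "fusions")])
  rownames(m) <- ann$sample_id
  m
}

#' Read sample annotations from CSV
#'
#' @param path CSV with columns `sample_id`, `cohort` and one true/false
#'   column per fusion.
#' @param cs Optional `codeset`; when given, the truth map must cover every
#'   fusion in it.
#' @inheritParams sample_annotations
#' @return A `sample_annotations`.
#' @export
read_annotations <- function(path, cs = NULL, single_fusion = TRUE) {
  if (!file.exists(path)) stop_io("annotation file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fusions <- if (is.null(cs)) NULL else fusion_ids(cs)
  sample_annotations(df, fusions = fusions, single_fusion = single_fusion)
}

#' Write sample annotations to CSV
#' @param ann A `sample_annotations`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "sample_annotations"))
  df <- as.data.frame(ann)
  for (f in attr(ann, "fusions")) {
    df[[f]] <- ifelse(df[[f]], "true", "false")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default study cohort: 94 bone-marrow samples
#'
#' The validation cohort the generator emulates: 49 samples with a
#' recurrent translocation (23 AML: 8 AML1-ETO, 8 PML-RARA, 7 CBFB-MYH11;
#' 26 ALL: 4 TCF3-PBX1, 7 MLL-AF4, 7 BCR-ABL1, 8 ETV6-RUNX1) and 45
#' fusion-negative controls (19 AML normal karyotype, 21 AML complex
#' karyotype, 5 normal bone marrow).
#'
#' @param positives Named integer vector: truth-positive count per fusion.
#' @param controls Named integer vector: size of each control cohort.
#' @return A `sample_annotations` with one row per sample.
#' @export
default_cohort <- function(
    positives = c("AML1-ETO" = 8L, "PML-RARA" = 8L, "CBFB-MYH11" = 7L,
                  "TCF3-PBX1" = 4L, "MLL-AF4" = 7L, "BCR-ABL1" = 7L,
                  "ETV6-RUNX1" = 8L),
    controls = c(AML_normal_karyotype = 19L, AML_complex_karyotype = 21L,
                 normal_marrow = 5L)) {
  fusions <- names(positives)
  if (is.null(fusions) || anyNA(fusion_disease_group(fusions))) {
    stop_config("positives must be named by panel fusions")
  }
  if (!all(names(controls) %in% CONTROL_COHORTS)) {
    stop_config("controls must be named by control cohorts")
  }
  rows <- list()
  for (f in fusions) {
    n <- positives[[f]]
    if (n == 0) next
    id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", f), seq_len(n))
    r <- data.frame(sample_id = id, cohort = fusion_disease_group(f))
    for (g in fusions) r[[g]] <- g == f
    rows[[f]] <- r
  }
  ctrl_prefix <- c(AML_normal_karyotype = "NK", AML_complex_karyotype = "CK",
                   normal_marrow = "NBM")
  for (co in names(controls)) {
    n <- controls[[co]]
    if (n == 0) next
    r <- data.frame(sample_id = sprintf("%s_%02d", ctrl_prefix[[co]],
                                        seq_len(n)),
                    cohort = co)
    for (g in fusions) r[[g]] <- FALSE
    rows[[co]] <- r
  }
  sample_annotations(do.call(rbind, c(rows, make.row.names = FALSE)),
                     fusions = fusions)
}
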