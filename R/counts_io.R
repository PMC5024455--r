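# Raw count matrices in the tabular dialect of digital-counter exports:
# one header row, a CodeClass and a Name column, then one column per sample.

CODECLASS_LABELS <- c(endogenous = "Endogenous", positive = "Positive",
                      negative = "Negative", housekeeping = "Housekeeping")

#' Construct a raw count matrix bound to a CodeSet
#'
#' @param counts Numeric matrix of non-negative integer counts,
#'   probes x samples; rownames must equal the CodeSet probe ids (any
#'   order; rows are re-aligned to CodeSet order), colnames are the sample
#'   ids.
#' @param cs The `codeset` the rows belong to.
#' @return A `count_matrix`: list with elements `counts` (integer matrix in
#'   CodeSet probe order) and `codeset`.
#' @export
count_matrix <- function(counts, cs) {
  stopifnot(inherits(cs, "codeset"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop_validation("count matrix needs probe rownames and sample colnames")
  }
  if (anyDuplicated(colnames(counts))) {
    stop_validation("duplicate sample id '",
                    colnames(counts)[duplicated(colnames(counts))][1], "'")
  }
  if (!setequal(rownames(counts), cs$probe_id) ||
      nrow(counts) != nrow(cs)) {
    extra <- setdiff(rownames(counts), cs$probe_id)
    missing <- setdiff(cs$probe_id, rownames(counts))
    stop_validation(
      "count matrix rows do not match codeset probes",
      if (length(extra)) paste0("; unknown probe(s): ",
                                paste(extra, collapse = ", ")),
      if (length(missing)) paste0("; missing probe(s): ",
                                  paste(missing, collapse = ", ")))
  }
  counts <- counts[cs$probe_id, , drop = FALSE]
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_validation("count for probe '", rownames(counts)[bad[1, 1]],
                    "', sample '", colnames(counts)[bad[1, 2]],
                    "' is not a non-negative integer: ",
                    counts[bad[1, 1], bad[1, 2]])
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, codeset = cs), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Raw count matrix:", nrow(x$counts), "probes x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Sample ids of a count matrix
#' @param m A `count_matrix`.
#' @return Character vector of sample ids, in column order.
#' @export
sample_ids <- function(m) colnames(m$counts)

#' Read a raw count matrix from CSV
#'
#' The expected dialect mirrors common digital-counter tabular exports:
#' columns `CodeClass`, `Name`, then one column per sample; counts are
#' non-negative integers. The `CodeClass` column is cross-checked against
#' the probe classes declared in the CodeSet.
#'
#' @param path CSV path.
#' @param cs The `codeset` to validate against.
#' @return A `count_matrix`.
#' @export
read_counts <- function(path, cs) {
  stopifnot(inherits(cs, "codeset"))
  if (!file.exists(path)) stop_io("counts file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || !identical(names(df)[1:2], c("CodeClass", "Name"))) {
    stop_parse("counts file must start with columns CodeClass, Name: ", path)
  }
  unknown <- setdiff(df$Name, cs$probe_id)
  if (length(unknown) > 0) {
    stop_parse("probe '", unknown[1], "' (row ",
               which(df$Name == unknown[1])[1],
               ") is not in the codeset")
  }
  expected_class <- CODECLASS_LABELS[cs$probe_class[match(df$Name,
                                                          cs$probe_id)]]
  mism <- which(df$CodeClass != expected_class)
  if (length(mism) > 0) {
    stop_parse("CodeClass mismatch in row ", mism[1], ": probe '",
               df$Name[mism[1]], "' declared '", df$CodeClass[mism[1]],
               "' but codeset says '", expected_class[mism[1]], "'")
  }
  val <- df[, -(1:2), drop = FALSE]
  for (j in seq_along(val)) {
    v <- suppressWarnings(as.numeric(val[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop_parse("non-integer or negative count at row ", bad[1],
                 ", sample column '", names(val)[j], "': ",
                 val[[j]][bad[1]])
    }
    val[[j]] <- v
  }
  m <- as.matrix(val)
  rownames(m) <- df$Name
  count_matrix(m, cs)
}

#' Write a raw count matrix to CSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(m, p), cs)`
#' recovers `m` exactly.
#'
#' @param m A `count_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  cs <- m$codeset
  df <- data.frame(
    CodeClass = unname(CODECLASS_LABELS[cs$probe_class]),
    Name = cs$probe_id,
    check.names = FALSE
  )
  df <- cbind(df, as.data.frame(m$counts, check.names = FALSE))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write counts to ", path)
  invisible(path)
}
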