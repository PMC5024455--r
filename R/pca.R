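utils::globalVariables(c("PC1", "PC2", "label"))

# PCA quality control: samples with a strongly expressed fusion junction
# probe separate from fusion-negative samples in the first components of
# log-scale endogenous expression, mirroring the discrete clustering seen
# in panel validations.

#' Principal components of log-scale endogenous expression
#'
#' Runs centered (unscaled) PCA on `log2(value + 1)` of the
#' background-subtracted endogenous values, samples as observations.
#' Component signs follow the eigenvector convention of [stats::prcomp()]
#' and are arbitrary: compare coordinates up to sign.
#'
#' @param nm A `normalized_matrix`.
#' @param ann Optional `sample_annotations`; when given, each sample is
#'   labeled with its truth fusion (or "negative") for plotting.
#' @param n_components Number of components to keep (default 2).
#' @return A `pca_qc` list: `coords` (samples x components),
#'   `sdev` (component standard deviations), `var_explained`, `labels`.
#' @export
pca_qc <- function(nm, ann = NULL, n_components = 2) {
  stopifnot(inherits(nm, "normalized_matrix"))
  x <- t(log2(endogenous_values(nm, "subtracted") + 1))
  if (nrow(x) < 3) stop_validation("PCA QC needs at least 3 samples")
  if (n_components > nrow(x)) {
    stop_validation("fewer samples (", nrow(x), ") than requested ",
                    "components (", n_components, ")")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  labels <- NULL
  if (!is.null(ann)) {
    stopifnot(inherits(ann, "sample_annotations"))
    truth <- truth_matrix(ann)[rownames(coords), , drop = FALSE]
    labels <- apply(truth, 1, function(r) {
      if (any(r)) colnames(truth)[which(r)[1]] else "negative"
    })
  }
  structure(list(coords = coords, sdev = pc$sdev,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 labels = labels),
            class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat("PCA QC:", nrow(x$coords), "samples;",
      sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$var_explained[1],
              if (length(x$var_explained) > 1)
                100 * x$var_explained[2] else 0))
  invisible(x)
}

#' Plot PCA QC coordinates colored by truth fusion
#'
#' @param x A `pca_qc` (computed with annotations so points carry labels).
#' @param path Optional file to save to (format from extension, via
#'   [ggplot2::ggsave()]).
#' @param ... Unused.
#' @return The ggplot object, invisibly.
#' @export
plot.pca_qc <- function(x, path = NULL, ...) {
  df <- data.frame(PC1 = x$coords[, 1],
                   PC2 = if (ncol(x$coords) > 1) x$coords[, 2] else 0,
                   label = if (is.null(x$labels)) "sample" else x$labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = PC1, y = PC2,
                                        colour = label)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)",
                  100 * if (length(x$var_explained) > 1)
                    x$var_explained[2] else 0),
      colour = "truth fusion",
      title = "PCA of log2 endogenous junction-probe expression") +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 7, height = 5)
  invisible(p)
}
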