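# Orchestration: one call (or one YAML config) runs
# simulate -> normalize -> call -> evaluate, persists every intermediate
# artifact, and logs every factor, flag, noise value and threshold used,
# so each number in the final report is recomputable from the files on
# disk.

#' Pipeline configuration
#'
#' Exactly one input source must be given: either real input paths
#' (`counts_path` + `annotations_path`) or a simulation block
#' (`simulation`).
#'
#' @param codeset_path Optional TSV path; default panel codeset when NULL.
#' @param counts_path,annotations_path CSV paths for real input data.
#' @param simulation A `simulation_config` (or a plain list of
#'   [simulation_config()] arguments) for synthetic input.
#' @param multiprobe_cbfb Use the three-probe CBFB-MYH11 variant of the
#'   default codeset (ignored when `codeset_path` is given).
#' @param order Normalization step order, see [normalize_counts()].
#' @param offset Geometric-mean pseudocount, see [normalize_counts()].
#' @param policy Noise policy, see [estimate_noise()].
#' @param threshold SNR decision threshold (default 10).
#' @param snr_values `"binding"` or `"subtracted"`, see [estimate_noise()].
#' @param out_dir Output directory (created if missing).
#' @param seed Seed for simulation runs; overrides the simulation block's
#'   own seed when given.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(codeset_path = NULL, counts_path = NULL,
                            annotations_path = NULL, simulation = NULL,
                            multiprobe_cbfb = FALSE,
                            order = "background-first", offset = 1,
                            policy = "controls_only", threshold = 10,
                            snr_values = "binding",
                            out_dir = tempfile("fusioncounter_run_"),
                            seed = NULL) {
  real <- !is.null(counts_path) || !is.null(annotations_path)
  if (real && !is.null(simulation)) {
    stop_config("give either real input paths or a simulation block, ",
                "not both")
  }
  if (!real && is.null(simulation)) {
    stop_config("one of {counts_path + annotations_path, simulation} ",
                "is required")
  }
  if (real && (is.null(counts_path) || is.null(annotations_path))) {
    stop_config("real input needs both counts_path and annotations_path")
  }
  if (!is.null(simulation) && !inherits(simulation, "simulation_config")) {
    simulation <- do.call(simulation_config, as.list(simulation))
  }
  if (!is.null(simulation) && is.null(seed)) seed <- simulation$seed
  structure(list(codeset_path = codeset_path, counts_path = counts_path,
                 annotations_path = annotations_path,
                 simulation = simulation,
                 multiprobe_cbfb = isTRUE(multiprobe_cbfb),
                 order = order, offset = offset, policy = policy,
                 threshold = threshold, snr_values = snr_values,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `simulation` block holds [simulation_config()] arguments, with
#' `scenario: reference` standing for [reference_scenario()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim <- y$simulation
  if (!is.null(sim)) {
    if (identical(sim$scenario, "reference")) {
      extra <- sim[setdiff(names(sim), "scenario")]
      sim <- do.call(reference_scenario, coerce_sim_args(extra))
    } else {
      sim <- do.call(simulation_config, coerce_sim_args(sim))
    }
  }
  args <- y[setdiff(names(y), "simulation")]
  do.call(pipeline_config, c(args, list(simulation = sim)))
}

# YAML gives plain lists; rebuild the named vectors / data.frames the
# simulator expects
coerce_sim_args <- function(args) {
  if (!is.null(args$dropout_counts)) {
    args$dropout_counts <- unlist(args$dropout_counts)
  }
  if (!is.null(args$dropout_probs)) {
    args$dropout_probs <- unlist(args$dropout_probs)
  }
  if (!is.null(args$crossreact_counts)) {
    args$crossreact_counts <-
      do.call(rbind, lapply(args$crossreact_counts, as.data.frame))
  }
  args
}

#' Run the whole pipeline
#'
#' Stages: obtain inputs (read or simulate), normalize, estimate noise and
#' call fusions, evaluate against the truth annotations, and write every
#' artifact under `config$out_dir`: `counts.csv`, `annotations.csv`,
#' `normalized.csv`, `audit.json`, `noise.json`, `calls.csv`,
#' `report.tsv`, `report.json`, `pca.csv` and `run.log`. Runs are
#' deterministic given the seed.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress the final printed report.
#' @return Invisibly, a list with `counts`, `annotations`, `normalized`,
#'   `noise`, `calls`, `report`, `pca` and `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- lapply(
    c(counts = "counts.csv", annotations = "annotations.csv",
      normalized = "normalized.csv", audit = "audit.json",
      noise = "noise.json", calls = "calls.csv", report_tsv = "report.tsv",
      report_json = "report.json", pca = "pca.csv", log = "run.log"),
    function(f) file.path(config$out_dir, f))
  logline <- local({
    con <- paths$log
    cat("", file = con)  # truncate
    function(...) cat(paste0(..., "\n"), file = con, append = TRUE)
  })

  cs <- if (!is.null(config$codeset_path)) {
    load_codeset(config$codeset_path)
  } else {
    default_codeset(multiprobe_cbfb = config$multiprobe_cbfb)
  }
  logline("codeset: ", nrow(cs), " probes, fusions: ",
          paste(fusion_ids(cs), collapse = ", "))

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    if (!is.null(config$seed)) sim$seed <- as.integer(config$seed)
    logline("input: simulation, seed ", sim$seed)
    simd <- simulate_cohort(sim, cs)
    cm <- simd$counts
    ann <- simd$truth$annotations
    write_counts(cm, paths$counts)
    write_annotations(ann, paths$annotations)
  } else {
    logline("input: ", config$counts_path, " + ", config$annotations_path)
    cm <- read_counts(config$counts_path, cs)
    ann <- read_annotations(config$annotations_path, cs)
    file.copy(config$counts_path, paths$counts, overwrite = TRUE)
    write_annotations(ann, paths$annotations)
  }
  if (!setequal(sample_ids(cm), ann$sample_id)) {
    stop_validation("counts and annotations cover different samples")
  }

  nm <- normalize_counts(cm, cs, order = config$order,
                         offset = config$offset)
  write_normalized(nm, paths$normalized, paths$audit)
  logline("normalization order ", config$order, ", offset ", config$offset)
  for (s in names(nm$qc_flags)) {
    if (length(nm$qc_flags[[s]]) > 0) {
      logline("qc flag ", s, ": ", paste(nm$qc_flags[[s]], collapse = ", "))
    }
  }

  noise <- estimate_noise(nm, ann, policy = config$policy,
                          values = config$snr_values)
  jsonlite::write_json(list(policy = noise$policy, floor = noise$floor,
                            values = noise$values,
                            noise = as.list(noise$noise)),
                       paths$noise, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  logline("noise policy ", noise$policy, " on ", noise$values,
          " values; per-probe noise: ",
          paste(sprintf("%s=%.3f", names(noise$noise), noise$noise),
                collapse = ", "))
  ct <- call_fusions(compute_snr(nm, noise), threshold = config$threshold)
  utils::write.csv(calls_long(ct), paths$calls, row.names = FALSE,
                   quote = FALSE)
  logline("SNR threshold ", config$threshold, "; ",
          sum(ct$fusion_call), " positive fusion call(s)")

  report <- diagnostic_report(ct, ann)
  write_report(report, paths$report_tsv, paths$report_json)

  pca <- pca_qc(nm, ann)
  utils::write.csv(
    data.frame(sample_id = rownames(pca$coords), pca$coords,
               label = if (is.null(pca$labels)) NA else pca$labels,
               check.names = FALSE),
    paths$pca, row.names = FALSE, quote = FALSE)
  logline("done")

  if (!quiet) print(report)
  invisible(list(counts = cm, annotations = ann, normalized = nm,
                 noise = noise, calls = ct, report = report, pca = pca,
                 paths = paths))
}
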