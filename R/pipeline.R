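#' Run the end-to-end copy-number pipeline
#'
#' Ties the modules together: preprocessing (when coverage tables are
#' given) or a precomputed log-ratio table, per-chromosome
#' segmentation, segment classification, and — when truth segments
#' are supplied — exon-level evaluation. Writes the log-ratio table,
#' SEG table, calls table, metrics JSON and a run manifest into
#' `out_dir`. Deterministic: running the same configuration twice
#' produces identical outputs.
#'
#' Only autosomes are processed unless `autosomes_only = FALSE`.
#'
#' @param lr_file Precomputed log-ratio TSV (`chrom start end name
#'   lr`); alternatively supply `tumor_file` and `normal_file`.
#' @param tumor_file,normal_file Per-exon coverage TSVs
#'   (see [read_coverage()]).
#' @param truth_file Optional ground-truth segment TSV
#'   (see [read_truth()]).
#' @param out_dir Output directory (created if missing).
#' @param sample Sample label used in the SEG output.
#' @param params A [segmentation_params()] object.
#' @param amp_threshold,del_threshold Classification thresholds.
#' @param lr_tolerance Evaluation log-ratio tolerance.
#' @param gc_correction,min_normal_arc Preprocessing options
#'   (see [preprocess_pair()]).
#' @param autosomes_only Restrict to autosomes (default `TRUE`).
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic; the seed governs upstream simulation).
#' @return Invisibly, a list with the `seg` table, `calls`, per-
#'   chromosome `segmentations`, `metrics` (or `NULL`) and the
#'   `manifest`.
#' @export
run_pipeline <- function(lr_file = NULL, tumor_file = NULL,
                         normal_file = NULL, truth_file = NULL,
                         out_dir = ".", sample = "sample",
                         params = segmentation_params(),
                         amp_threshold = 0.35, del_threshold = -0.25,
                         lr_tolerance = 0.15, gc_correction = TRUE,
                         min_normal_arc = 0.1, autosomes_only = TRUE,
                         seed = NA_integer_) {
  if (is.null(lr_file) && (is.null(tumor_file) || is.null(normal_file))) {
    stop("run_pipeline: supply either lr_file or both tumor_file and ",
         "normal_file")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  excluded <- NULL
  if (is.null(lr_file)) {
    tumor <- read_coverage(tumor_file)
    normal <- read_coverage(normal_file)
    pre <- preprocess_pair(tumor, normal, gc_correction = gc_correction,
                           min_normal_arc = min_normal_arc)
    lr <- pre$lr
    excluded <- pre$excluded
    write_lr(lr, file.path(out_dir, "lr.tsv"))
  } else {
    lr <- read_lr(lr_file)
  }

  fit <- segment_genome(lr, params = params, sample = sample,
                        autosomes_only = autosomes_only)
  write_seg(fit$seg, file.path(out_dir, "segments.tsv"))

  calls <- classify_segments(fit$seg, amp_threshold, del_threshold)
  write_seg(calls, file.path(out_dir, "calls.tsv"))

  metrics <- NULL
  if (!is.null(truth_file)) {
    truth <- read_truth(truth_file)
    metrics <- precision_recall_fscore(
      calls, truth, exons = lr, lr_tolerance = lr_tolerance,
      amp_threshold = amp_threshold, del_threshold = del_threshold)
    jsonlite::write_json(
      metrics[c("precision_gain", "recall_gain", "precision_loss",
                "recall_loss", "fscore", "n_excluded")],
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
      digits = NA)
  }

  manifest <- list(
    package = "vegawes",
    version = as.character(utils::packageVersion("vegawes")),
    sample = sample,
    inputs = Filter(Negate(is.null),
                    list(lr_file = lr_file, tumor_file = tumor_file,
                         normal_file = normal_file,
                         truth_file = truth_file)),
    params = unclass(params),
    thresholds = list(amp = amp_threshold, del = del_threshold,
                      lr_tolerance = lr_tolerance),
    seed = seed,
    n_exons = nrow(lr),
    n_excluded_exons = if (is.null(excluded)) 0L else nrow(excluded),
    chromosomes = lapply(fit$segmentations, function(s) {
      list(n_exons = length(s$lr), n_regions = nrow(s$regions),
           n_lambda_advances = length(s$lambda_trace),
           nu = s$nu)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(seg = fit$seg, calls = calls,
                 segmentations = fit$segmentations,
                 metrics = metrics, manifest = manifest))
}

#' Write a simulated chromosome as fixture files
#'
#' Emits the log-ratio TSV, the tiling truth TSV, the target table and
#' a JSON manifest (configuration and seed) for one
#' [simulate_chromosome()] result.
#'
#' @param sim A `synthetic_chromosome`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "synthetic_chromosome"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(lr = file.path(out_dir, "lr.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             targets = file.path(out_dir, "targets.tsv"),
             manifest = file.path(out_dir, "sim_manifest.json"))
  write_lr(sim$lr, paths[["lr"]])
  write_truth(sim$truth, paths[["truth"]])
  write_targets(sim$targets, paths[["targets"]])
  jsonlite::write_json(c(unclass(sim$config), list(seed = sim$seed)),
                       paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
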