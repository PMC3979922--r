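#' Write a run manifest
#'
#' Records, as JSON next to a run's outputs, everything needed to
#' reproduce it: the command name, the configuration snapshot, the seed,
#' md5 checksums of the input files, the package version and a
#' timestamp. Re-running with an identical manifest reproduces the
#' primary outputs byte for byte (all randomness is seed-driven).
#'
#' @param command Name of the analysis step.
#' @param config A configuration object (coerced to a list).
#' @param seed The seed used.
#' @param inputs Character vector of input file paths (may be empty).
#' @param path Output path for the manifest JSON.
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(command, config = NULL, seed = NA, inputs = character(0),
                         path) {
  manifest <- list(
    command = command,
    seed = seed,
    config = if (is.null(config)) NULL else unclass(config),
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    tool = "genetier",
    version = as.character(utils::packageVersion("genetier")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Write a full simulation to an output directory
#'
#' Emits `genome.fa`, one GFF3 per predictor source, `counts.tsv`,
#' `lengths.tsv`, `libsizes.tsv`, `model_truth.tsv` and
#' `expression_truth.tsv`, plus a run manifest.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param t A [thresholds()] object used for the model truth labels.
#' @return Invisibly, the list returned by the simulators
#'   (`genome`, `models`, `expression`).
#' @export
write_simulation <- function(cfg = simulation_config(), dir, t = thresholds()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(cfg)
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  sim <- simulate_predictor_sets(cfg, genome, t)
  models <- sim$collection$models
  for (src in unique(models$source)) {
    write_gff3(models[models$source == src, , drop = FALSE],
               file.path(dir, paste0(tolower(src), ".gff3")))
  }
  utils::write.table(sim$truth, file.path(dir, "model_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  final <- consolidate(sim$collection, t)
  gene_ids <- paste(final$set3$source, final$set3$id, sep = ":")
  expr <- simulate_counts(cfg, gene_ids,
                          gene_lengths = transcript_length(final$set3))
  cnt <- data.frame(gene_id = expr$em$gene_ids, expr$em$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = expr$em$gene_ids, length = expr$em$gene_lengths),
    file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(condition = expr$em$conditions,
               library_size = expr$em$library_sizes),
    file.path(dir, "libsizes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(expr$truth, file.path(dir, "expression_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  run_manifest("simulate", cfg, cfg$seed, character(0),
               file.path(dir, "manifest.json"))
  invisible(list(genome = genome, models = sim, consolidation = final,
                 expression = expr))
}
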