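#' Analysis thresholds
#'
#' Bundles the tunable constants used across the pipeline: the predictor
#' score cutoff for homology-based models, the minimum fraction of a
#' transcript that its coding region must cover, the fold-change and peak
#' cutoffs for expression specificity flags, the genomic window size for
#' GC/gene-density tracks, and the minimum read count that defines
#' "expressed".
#'
#' @param min_score Minimum predictor score for a homology-based model to
#'   be retained (unitless predictor score; default 100).
#' @param min_cds_coverage Minimum fraction of a transcript covered by its
#'   coding region, in (0, 1] (default 0.5).
#' @param fold_change Linear fold-change a peak condition must show over
#'   the next-highest condition for a specificity flag (default 2).
#' @param peak_log2 log2-scale expression a flagged peak must reach to
#'   count as "peaked" (default 5.5).
#' @param window_size Window size in bp for GC-content and gene-density
#'   tracks (default 100000).
#' @param expressed_min_count Minimum raw read count for a gene to count
#'   as expressed in a condition (default 1).
#'
#' @return An object of class `thresholds` (a validated named list).
#' @export
#' @examples
#' th <- thresholds()
#' th$min_score
thresholds <- function(min_score = 100,
                       min_cds_coverage = 0.5,
                       fold_change = 2,
                       peak_log2 = 5.5,
                       window_size = 100000,
                       expressed_min_count = 1) {
  th <- list(
    min_score = as.numeric(min_score),
    min_cds_coverage = as.numeric(min_cds_coverage),
    fold_change = as.numeric(fold_change),
    peak_log2 = as.numeric(peak_log2),
    window_size = as.numeric(window_size),
    expressed_min_count = as.numeric(expressed_min_count)
  )
  for (nm in names(th)) {
    v <- th[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      .stopf("threshold '%s' must be a single positive finite number", nm)
  }
  if (th$min_cds_coverage > 1)
    .stopf("min_cds_coverage must lie in (0, 1], got %g", th$min_cds_coverage)
  structure(th, class = "thresholds")
}

#' Read thresholds from a JSON configuration file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a JSON file whose keys are `thresholds()` arguments.
#' @return A `thresholds` object.
#' @export
read_thresholds <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(thresholds))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    .stopf("unknown threshold key(s): %s", paste(bad, collapse = ", "))
  do.call(thresholds, cfg)
}

#' @export
print.thresholds <- function(x, ...) {
  cat("Analysis thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}
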