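#' @importFrom methods is
NULL

#' Recognised predictor sources
#'
#' Gene models carry a source tag naming the predictor that produced them:
#' ab initio prediction (`FGENESH`), homology-based prediction against two
#' reference species (`FGENESH_PLUS_CC`, `FGENESH_PLUS_LB`),
#' transcript-assembly models (`CUFFLINKS`), or `OTHER`.
#'
#' @format A character vector of the five recognised source tags.
#' @export
GENE_SOURCES <- c("FGENESH", "FGENESH_PLUS_CC", "FGENESH_PLUS_LB",
                  "CUFFLINKS", "OTHER")

.empty_models <- function() {
  df <- data.frame(
    id = character(0), source = character(0), scaffold = character(0),
    strand = character(0), start = integer(0), end = integer(0),
    score = numeric(0), stringsAsFactors = FALSE
  )
  df$exons <- list()
  df$cds <- list()
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Construct a table of gene models
#'
#' A gene model is one predicted gene from one predictor source: a genomic
#' span on a scaffold, an ordered set of exons, an optional coding-sequence
#' (CDS) span, and an optional predictor score. Coordinates are 1-based
#' inclusive throughout (the GFF3 convention).
#'
#' @param id Character vector of model identifiers, unique within a source.
#' @param source Source tag(s), one of [GENE_SOURCES] (recycled if scalar).
#' @param scaffold Scaffold (sequence) name per model.
#' @param start,end Genomic span, 1-based inclusive, `end >= start >= 1`.
#' @param exons List of two-column matrices (`start`, `end` per exon row),
#'   sorted, pairwise disjoint, within the model span. `NULL` entries get a
#'   single exon equal to the model span.
#' @param cds List of length-2 numeric vectors giving the CDS genomic span,
#'   or `NULL` per model for non-coding transcripts. Spans are normalised
#'   to the exon-covered part and must intersect at least one exon.
#' @param score Optional numeric predictor score (`NA` = no score; models
#'   without a score fail any score threshold).
#' @param strand `"+"`, `"-"`, or `"*"` (unknown).
#'
#' @return A `gene_models` data frame with list-columns `exons` and `cds`.
#' @export
#' @examples
#' gene_models(id = "g1", source = "FGENESH", scaffold = "scf1",
#'             start = 100, end = 400,
#'             exons = list(rbind(c(100, 200), c(300, 400))))
gene_models <- function(id, source, scaffold, start, end,
                        exons = NULL, cds = NULL, score = NA_real_,
                        strand = "+") {
  n <- length(id)
  if (n == 0L) return(.empty_models())
  df <- data.frame(
    id = as.character(id),
    source = rep_len(as.character(source), n),
    scaffold = rep_len(as.character(scaffold), n),
    strand = rep_len(as.character(strand), n),
    start = as.integer(start), end = as.integer(end),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  if (is.null(exons)) exons <- rep(list(NULL), n)
  if (is.null(cds)) cds <- rep(list(NULL), n)
  if (!is.list(exons) || length(exons) != n)
    .stopf("exons must be a list of length %d", n)
  if (!is.list(cds) || length(cds) != n)
    .stopf("cds must be a list of length %d", n)
  df$exons <- lapply(seq_len(n), function(i) {
    ex <- exons[[i]]
    if (is.null(ex)) ex <- cbind(df$start[i], df$end[i])
    ex <- matrix(as.integer(ex), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    ex[order(ex[, 1L]), , drop = FALSE]
  })
  df$cds <- lapply(cds, function(x) if (is.null(x)) NULL else as.integer(x))
  class(df) <- c("gene_models", "data.frame")
  validate_gene_models(df)
}

#' Validate a gene-model table
#'
#' Checks the structural invariants: positive 1-based coordinates,
#' `end >= start`, exons sorted and pairwise disjoint within the span,
#' positive transcript length, CDS intersecting the exons with
#' `cds_length <= transcript_length`, unique ids within each source, and a
#' recognised source tag. CDS spans are normalised to their exon-covered
#' extent so that writing and re-reading is the identity.
#'
#' @param models A `gene_models` data frame.
#' @return The validated (possibly CDS-normalised) table, invisibly usable.
#' @export
validate_gene_models <- function(models) {
  if (nrow(models) == 0L) return(models)
  bad <- setdiff(unique(models$source), GENE_SOURCES)
  if (length(bad))
    .stopf("unknown source tag(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(paste(models$source, models$id)))
    .stopf("duplicate model id within a source")
  if (any(models$start < 1L))
    .stopf("coordinates are 1-based: start must be >= 1")
  if (any(models$end < models$start))
    .stopf("model end < start for id(s): %s",
           paste(models$id[models$end < models$start], collapse = ", "))
  if (!all(models$strand %in% c("+", "-", "*")))
    .stopf("strand must be '+', '-' or '*'")
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2L || nrow(ex) == 0L)
      .stopf("model %s: exons must be a non-empty two-column matrix",
             models$id[i])
    if (any(ex[, 2L] < ex[, 1L]))
      .stopf("model %s: exon end < start", models$id[i])
    if (is.unsorted(ex[, 1L], strictly = TRUE) && nrow(ex) > 1L)
      .stopf("model %s: exons not sorted by start", models$id[i])
    if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
      .stopf("model %s: exons overlap or touch", models$id[i])
    if (ex[1L, 1L] < models$start[i] || ex[nrow(ex), 2L] > models$end[i])
      .stopf("model %s: exons outside the model span", models$id[i])
    cd <- models$cds[[i]]
    if (!is.null(cd)) {
      if (length(cd) != 2L || cd[2L] < cd[1L])
        .stopf("model %s: cds must be a (start, end) pair", models$id[i])
      seg <- .cds_segments(ex, cd)
      if (nrow(seg) == 0L)
        .stopf("model %s: CDS span does not intersect any exon",
               models$id[i])
      models$cds[[i]] <- c(seg[1L, 1L], seg[nrow(seg), 2L])
    }
  }
  models
}

# Intersections of the CDS genomic span with the exon set, as a matrix of
# (start, end) segments in transcript order.
.cds_segments <- function(exons, cds) {
  s <- pmax(exons[, 1L], cds[1L])
  e <- pmin(exons[, 2L], cds[2L])
  keep <- s <= e
  cbind(s[keep], e[keep])
}

#' Transcript length of each model
#'
#' Sum of exon lengths in bp (1-based inclusive spans).
#'
#' @param models A `gene_models` data frame.
#' @return Integer vector of transcript lengths.
#' @export
transcript_length <- function(models) {
  vapply(models$exons, function(ex) sum(ex[, 2L] - ex[, 1L] + 1L), 1L)
}

#' CDS length of each model
#'
#' Length in bp of the exonic part of the CDS span; 0 for models without a
#' CDS.
#'
#' @param models A `gene_models` data frame.
#' @return Integer vector.
#' @export
cds_length <- function(models) {
  vapply(seq_len(nrow(models)), function(i) {
    cd <- models$cds[[i]]
    if (is.null(cd)) return(0L)
    seg <- .cds_segments(models$exons[[i]], cd)
    as.integer(sum(seg[, 2L] - seg[, 1L] + 1L))
  }, 1L)
}

#' Fraction of each transcript covered by its coding region
#'
#' `cds_length / transcript_length`, in (0, 1]. Transcript-assembly models
#' frequently carry truncated coding regions (e.g. from frameshifts), and
#' the consolidation rules filter such models by this fraction.
#'
#' @param models A `gene_models` data frame; every model must have a CDS.
#' @return Numeric vector of coverage fractions.
#' @export
#' @examples
#' m <- gene_models(id = "t1", source = "CUFFLINKS", scaffold = "s",
#'                  start = 1, end = 600, cds = list(c(1, 300)))
#' cds_coverage(m)  # 0.5
cds_coverage <- function(models) {
  noncoding <- vapply(models$cds, is.null, TRUE)
  if (any(noncoding))
    .stopf("non-coding transcript(s) without a CDS: %s",
           paste(models$id[noncoding], collapse = ", "))
  cds_length(models) / transcript_length(models)
}

#' Do two gene models overlap?
#'
#' Overlap is strand-agnostic and span-based: two models overlap iff they
#' lie on the same scaffold and their genomic spans share at least one bp
#' (coordinates are 1-based inclusive, so spans ending and starting on the
#' same base do overlap).
#'
#' @param a,b Single-row `gene_models` data frames (or rows of one).
#' @return Logical scalar.
#' @export
overlaps <- function(a, b) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  a$scaffold == b$scaffold && .span_overlap(a$start, a$end, b$start, b$end)
}

#' Build a multi-source gene-set collection with an interval index
#'
#' Bundles models from several predictor sources and indexes their genomic
#' spans for fast overlap queries (an NCList-backed index via
#' \pkg{GenomicRanges}).
#'
#' @param ... Either a single `gene_models` data frame (sources taken from
#'   its `source` column) or several, each carrying its own sources.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) nrow(p) > 0L, TRUE)]
  models <- if (length(parts)) do.call(rbind, parts) else .empty_models()
  rownames(models) <- NULL
  class(models) <- c("gene_models", "data.frame")
  models <- validate_gene_models(models)
  structure(
    list(models = models, index = .models_granges(models)),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  tab <- table(x$models$source)
  cat(sprintf("gene_set_collection: %d models from %d source(s)\n",
              nrow(x$models), length(tab)))
  for (nm in names(tab)) cat(sprintf("  %-16s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Models of one source in a collection
#'
#' @param x A `gene_set_collection`.
#' @param source A source tag.
#' @return A `gene_models` data frame (possibly empty).
#' @export
collection_models <- function(x, source = NULL) {
  stopifnot(is(x, "gene_set_collection"))
  m <- x$models
  if (is.null(source)) return(m)
  out <- m[m$source == source, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interval-index lookup on a collection
#'
#' Returns every model whose genomic span intersects `[start, end]` on the
#' given scaffold (1-based inclusive).
#'
#' @param x A `gene_set_collection`.
#' @param scaffold Scaffold name.
#' @param start,end Query span.
#' @return A `gene_models` data frame of the hits, in input order.
#' @export
collection_lookup <- function(x, scaffold, start, end) {
  stopifnot(is(x, "gene_set_collection"))
  if (nrow(x$models) == 0L) return(x$models)
  q <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, x$index)
  out <- x$models[sort(S4Vectors::subjectHits(hits)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
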