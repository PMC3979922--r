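#' Read gene models from a GFF3 file
#'
#' Expects the standard gene/mRNA/exon/CDS feature hierarchy and builds
#' one gene model per mRNA (or `transcript`) feature, with exon and CDS
#' children attached. Coordinates are kept 1-based inclusive as in the
#' file. The numeric score column of the mRNA feature, when present,
#' becomes the model's predictor score.
#'
#' @param path Path to a GFF3 file.
#' @param source_tag Optional source tag from [GENE_SOURCES] applied to
#'   every model; if `NULL`, the file's source column is used and must
#'   contain recognised tags.
#' @return A `gene_models` data frame.
#' @export
read_gff3 <- function(path, source_tag = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(.empty_models())
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  tx_ids <- as.character(gr$ID[is_tx])
  if (anyNA(tx_ids)) .stopf("mRNA feature without an ID attribute")

  parent1 <- function(i) {
    p <- gr$Parent[[i]]
    if (length(p) == 0L)
      .stopf("feature of type '%s' at %s:%d-%d has no Parent", type[i],
             as.character(GenomicRanges::seqnames(gr))[i],
             GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
    as.character(p)
  }

  child_rows <- which(type %in% c("exon", "CDS"))
  kids <- lapply(child_rows, function(i) {
    for (p in parent1(i)) {
      if (!p %in% tx_ids)
        .stopf("%s feature at %s:%d-%d names unknown parent '%s'", type[i],
               as.character(GenomicRanges::seqnames(gr))[i],
               GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i], p)
    }
    data.frame(parent = parent1(i)[1L], type = type[i],
               start = GenomicRanges::start(gr)[i],
               end = GenomicRanges::end(gr)[i], stringsAsFactors = FALSE)
  })
  kids <- if (length(kids)) do.call(rbind, kids) else
    data.frame(parent = character(0), type = character(0),
               start = integer(0), end = integer(0))

  tx_idx <- which(is_tx)
  n <- length(tx_idx)
  exons <- vector("list", n)
  cds <- vector("list", n)
  starts <- GenomicRanges::start(gr)[tx_idx]
  ends <- GenomicRanges::end(gr)[tx_idx]
  for (k in seq_len(n)) {
    mine <- kids[kids$parent == tx_ids[k], , drop = FALSE]
    ex <- mine[mine$type == "exon", , drop = FALSE]
    exons[[k]] <- if (nrow(ex)) {
      ex <- ex[order(ex$start), , drop = FALSE]
      cbind(ex$start, ex$end)
    } else NULL
    cd <- mine[mine$type == "CDS", , drop = FALSE]
    if (nrow(cd)) {
      span <- c(min(cd$start), max(cd$end))
      if (span[1L] < starts[k] || span[2L] > ends[k])
        .stopf("model %s: CDS outside transcript bounds", tx_ids[k])
      cds[[k]] <- span
    }
  }
  score <- suppressWarnings(as.numeric(gr$score[tx_idx]))
  src <- if (is.null(source_tag)) as.character(gr$source)[tx_idx] else
    rep(source_tag, n)
  gene_models(
    id = tx_ids, source = src,
    scaffold = as.character(GenomicRanges::seqnames(gr))[tx_idx],
    strand = sub("\\*", "*", as.character(GenomicRanges::strand(gr))[tx_idx]),
    start = starts, end = ends, exons = exons, cds = cds, score = score
  )
}

#' Write gene models to a GFF3 file
#'
#' Emits the gene/mRNA/exon/CDS hierarchy with a `##gff-version 3` pragma.
#' CDS features are the exon-intersected segments of the model's CDS span,
#' with phase computed in translation order. `write_gff3` followed by
#' [read_gff3()] reproduces the models exactly.
#'
#' @param models A `gene_models` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- list()
  for (i in seq_len(nrow(models))) {
    id <- models$id[i]
    gid <- paste0(id, "-gene")
    base <- list(scaffold = models$scaffold[i], strand = models$strand[i],
                 source = models$source[i])
    rows[[length(rows) + 1L]] <- c(base, list(
      type = "gene", start = models$start[i], end = models$end[i],
      score = NA_real_, phase = NA_integer_, ID = gid, Parent = NA_character_))
    rows[[length(rows) + 1L]] <- c(base, list(
      type = "mRNA", start = models$start[i], end = models$end[i],
      score = models$score[i], phase = NA_integer_, ID = id, Parent = gid))
    ex <- models$exons[[i]]
    for (j in seq_len(nrow(ex)))
      rows[[length(rows) + 1L]] <- c(base, list(
        type = "exon", start = ex[j, 1L], end = ex[j, 2L],
        score = NA_real_, phase = NA_integer_, ID = NA_character_,
        Parent = id))
    cd <- models$cds[[i]]
    if (!is.null(cd)) {
      seg <- .cds_segments(ex, cd)
      ord <- if (models$strand[i] == "-") order(-seg[, 1L]) else
        order(seg[, 1L])
      seg <- seg[ord, , drop = FALSE]
      len <- seg[, 2L] - seg[, 1L] + 1L
      phase <- c(0L, cumsum(len)[-nrow(seg)] %% 3L)
      phase <- (3L - phase) %% 3L
      for (j in seq_len(nrow(seg)))
        rows[[length(rows) + 1L]] <- c(base, list(
          type = "CDS", start = seg[j, 1L], end = seg[j, 2L],
          score = NA_real_, phase = phase[j], ID = NA_character_,
          Parent = id))
    }
  }
  if (length(rows) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  gr <- GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  gr$source <- df$source
  gr$type <- df$type
  gr$score <- df$score
  gr$phase <- df$phase
  gr$ID <- ifelse(is.na(df$ID), NA_character_, df$ID)
  gr$Parent <- S4Vectors::unname(IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
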