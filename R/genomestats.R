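#' N50 and L50 of a set of sequence lengths
#'
#' N50 is the length of the sequence at which the cumulative length of
#' the longest sequences first reaches half the total assembly length;
#' L50 is the number of sequences needed to get there.
#'
#' @param lengths Positive numeric vector of sequence lengths (bp); order
#'   does not matter.
#' @return `list(n50, l50)`.
#' @export
#' @examples
#' nx_stats(c(8, 7, 5, 5))  # n50 = 7, l50 = 2
nx_stats <- function(lengths) {
  if (length(lengths) == 0L) .stopf("empty length list")
  if (any(lengths <= 0)) .stopf("lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  k <- which(cum >= sum(s) / 2)[1L]
  list(n50 = s[k], l50 = k)
}

#' Assembly summary statistics from genome sequences
#'
#' @param genome A [Biostrings::DNAStringSet] (or object coercible to
#'   one).
#' @return `list(n_sequences, total_length, n50, l50, gc_percent)` where
#'   `gc_percent` is 100 x (G+C)/(A+C+G+T) over called bases only
#'   (ambiguity codes excluded).
#' @export
assembly_stats <- function(genome) {
  genome <- Biostrings::DNAStringSet(genome)
  if (length(genome) == 0L) .stopf("empty genome")
  lens <- Biostrings::width(genome)
  nx <- nx_stats(lens)
  freq <- Biostrings::letterFrequency(genome, c("A", "C", "G", "T"))
  called <- sum(freq)
  gc <- if (called > 0) 100 * sum(freq[, c("C", "G")]) / called else NA_real_
  list(n_sequences = length(genome), total_length = sum(lens),
       n50 = nx$n50, l50 = nx$l50, gc_percent = gc)
}

# Tile [0, len) with `window`-sized 0-based half-open windows (last may be
# short); returns start offsets.
.window_starts <- function(len, window) seq(0L, max(len - 1L, 0L), by = window)

#' GC content in non-overlapping genomic windows
#'
#' Each scaffold is tiled with fixed-size non-overlapping windows
#' (0-based half-open; the last window may be short) and the percentage
#' of G+C among called bases (A, C, G, T) is computed per window.
#' Ambiguity codes are excluded from both numerator and denominator, with
#' a warning when present; windows with no called base carry `NA`.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param window Window size in bp (default 100000).
#' @return Data frame with columns `scaffold`, `window_start`,
#'   `window_size`, `value` (GC percent).
#' @export
gc_windows <- function(genome, window = 100000) {
  genome <- Biostrings::DNAStringSet(genome)
  if (window <= 0) .stopf("window must be positive")
  nms <- names(genome)
  if (is.null(nms)) nms <- paste0("seq", seq_along(genome))
  out <- vector("list", length(genome))
  warned <- FALSE
  for (i in seq_along(genome)) {
    len <- Biostrings::width(genome)[i]
    starts <- .window_starts(len, window)
    v <- Biostrings::Views(genome[[i]],
                           start = starts + 1L,
                           end = pmin(starts + window, len))
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    called <- rowSums(freq)
    if (!warned && sum(called) < len) {
      warning("non-ACGT characters present; excluded from GC computation",
              call. = FALSE)
      warned <- TRUE
    }
    value <- ifelse(called > 0,
                    100 * rowSums(freq[, c("C", "G"), drop = FALSE]) / called,
                    NA_real_)
    out[[i]] <- data.frame(scaffold = nms[i], window_start = starts,
                           window_size = as.integer(pmin(window, len - starts)),
                           value = value, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Gene counts in non-overlapping genomic windows
#'
#' Each gene is counted exactly once, in the window containing its start
#' coordinate (genes are not fractionally split across windows).
#'
#' @param models A `gene_models` data frame.
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bp).
#' @param window Window size in bp (default 100000).
#' @return Data frame with columns `scaffold`, `window_start`,
#'   `window_size`, `value` (gene count); every window of every scaffold
#'   is present, zeros included.
#' @export
gene_density_windows <- function(models, scaffold_lengths, window = 100000) {
  if (window <= 0) .stopf("window must be positive")
  unknown <- setdiff(unique(models$scaffold), names(scaffold_lengths))
  if (length(unknown))
    .stopf("gene(s) on unknown scaffold(s): %s",
           paste(unknown, collapse = ", "))
  out <- lapply(names(scaffold_lengths), function(nm) {
    len <- scaffold_lengths[[nm]]
    starts <- .window_starts(len, window)
    g <- models$start[models$scaffold == nm]
    idx <- floor((g - 1) / window) + 1L
    counts <- tabulate(idx, nbins = length(starts))
    data.frame(scaffold = nm, window_start = starts,
               window_size = as.integer(pmin(window, len - starts)),
               value = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene-set summary statistics
#'
#' Means over genes, exons and introns. Introns are the gaps between
#' consecutive exons in transcript order (gap length = next start -
#' previous end - 1 on 1-based inclusive coordinates); single-exon genes
#' contribute nothing to the intron mean, which is `NA` when no gene has
#' an intron.
#'
#' @param models A `gene_models` data frame (at least one model).
#' @param total_length Total assembly length in bp (for per-Mb densities).
#' @return `list(n_genes, mean_gene_length, mean_transcript_length,
#'   mean_exons_per_gene, mean_exon_length, mean_intron_length,
#'   genes_per_mb, kb_per_gene)`.
#' @export
gene_set_stats <- function(models, total_length) {
  if (nrow(models) == 0L) .stopf("no gene models")
  exon_lens <- unlist(lapply(models$exons, function(ex)
    ex[, 2L] - ex[, 1L] + 1L))
  intron_lens <- unlist(lapply(models$exons, function(ex) {
    if (nrow(ex) < 2L) return(numeric(0))
    ex[-1L, 1L] - ex[-nrow(ex), 2L] - 1L
  }))
  list(
    n_genes = nrow(models),
    mean_gene_length = mean(models$end - models$start + 1),
    mean_transcript_length = mean(transcript_length(models)),
    mean_exons_per_gene = mean(vapply(models$exons, nrow, 1L)),
    mean_exon_length = mean(exon_lens),
    mean_intron_length = if (length(intron_lens)) mean(intron_lens)
      else NA_real_,
    genes_per_mb = nrow(models) / (total_length / 1e6),
    kb_per_gene = total_length / nrow(models) / 1000
  )
}

#' Write a window track as BEDGRAPH
#'
#' Windows are emitted in 0-based half-open coordinates; `NA` values are
#' skipped.
#'
#' @param track A window-track data frame from [gc_windows()] or
#'   [gene_density_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  ok <- !is.na(track$value)
  df <- data.frame(chrom = track$scaffold[ok],
                   start = track$window_start[ok],
                   end = track$window_start[ok] + track$window_size[ok],
                   value = track$value[ok])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
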