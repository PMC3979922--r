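#' Canonical developmental conditions
#'
#' The four expression conditions profiled across fruiting-body
#' development: vegetative mycelium, primordium, and the two mature
#' fruiting-body tissues (stipe and pileus).
#'
#' @format Character vector of length 4.
#' @export
CANONICAL_CONDITIONS <- c("mycelium", "primordium", "stipe", "pileus")

.CONDITION_ABBREV <- c(mycelium = "M", primordium = "Pr", stipe = "S",
                       pileus = "P")

#' Construct an expression matrix
#'
#' Raw read counts per gene and condition together with per-condition
#' library sizes (total mapped reads) and per-gene lengths (sum of exon
#' lengths in bp) — everything RPKM needs.
#'
#' @param counts Non-negative integer matrix, genes x conditions; row
#'   names are gene ids unless `gene_ids` is given.
#' @param library_sizes Positive integer vector, one per condition; each
#'   must be at least its column sum of counts.
#' @param gene_lengths Positive integer vector of transcript lengths (bp),
#'   one per gene.
#' @param conditions Condition names (default: `colnames(counts)`, else
#'   [CANONICAL_CONDITIONS]).
#' @param gene_ids Gene identifiers (default: `rownames(counts)`).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, library_sizes, gene_lengths,
                              conditions = NULL, gene_ids = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(conditions)) conditions <- colnames(counts)
  if (is.null(conditions)) {
    if (ncol(counts) != length(CANONICAL_CONDITIONS))
      .stopf("conditions must be named when not the canonical four")
    conditions <- CANONICAL_CONDITIONS
  }
  if (length(gene_ids) != nrow(counts) ||
      length(conditions) != ncol(counts))
    .stopf("counts dimensions do not match gene_ids/conditions")
  if (any(counts < 0) || any(counts != round(counts)))
    .stopf("counts must be non-negative integers")
  library_sizes <- as.numeric(library_sizes)
  gene_lengths <- as.numeric(gene_lengths)
  if (length(library_sizes) != ncol(counts) || any(library_sizes <= 0))
    .stopf("library_sizes must be positive, one per condition")
  if (length(gene_lengths) != nrow(counts) || any(gene_lengths <= 0))
    .stopf("gene_lengths must be positive, one per gene")
  if (any(library_sizes < colSums(counts)))
    .stopf("library_sizes must be >= column sums of counts")
  dimnames(counts) <- list(gene_ids, conditions)
  structure(list(counts = counts, library_sizes = library_sizes,
                 gene_lengths = gene_lengths, gene_ids = gene_ids,
                 conditions = conditions),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d conditions (%s)\n",
              length(x$gene_ids), length(x$conditions),
              paste(x$conditions, collapse = ", ")))
  invisible(x)
}

.normalized <- function(values, stage) {
  structure(list(values = values, stage = stage),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d genes x %d conditions\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' `rpkm[g, c] = counts[g, c] * 1e9 / (library_sizes[c] * gene_lengths[g])`.
#'
#' @param m An [expression_matrix()].
#' @return A `normalized_matrix` at stage `"RPKM"`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1000, 1, 4), rep(1e7, 4), 2000)
#' rpkm(m)$values  # all 50
rpkm <- function(m) {
  stopifnot(is(m, "expression_matrix"))
  v <- sweep(m$counts, 2, m$library_sizes, "/")
  v <- sweep(v, 1, m$gene_lengths, "/") * 1e9
  .normalized(v, "RPKM")
}

#' Quantile normalization across conditions
#'
#' Forces every column to the same distribution: rank each column and
#' replace rank r by the mean of the r-th order statistics across
#' columns. Tied values receive the mean of the tied ranks' target
#' quantiles, so the map is well defined and permutation-equivariant.
#'
#' @param v A `normalized_matrix` (any stage with non-negative values).
#' @return A `normalized_matrix` at stage `"QUANTILE"`.
#' @export
quantile_normalize <- function(v) {
  stopifnot(is(v, "normalized_matrix"))
  x <- v$values
  if (ncol(x) < 1L) .stopf("need at least one condition")
  target <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "min")
    for (g in unique(r)) {
      idx <- which(r == g)
      out[idx, j] <- mean(target[g:(g + length(idx) - 1L)])
    }
  }
  .normalized(out, "QUANTILE")
}

#' log2 transformation with a pseudocount
#'
#' `value -> log2(value + pseudocount)`; the pseudocount (default 1) keeps
#' zero expression at 0 on the log2 scale.
#'
#' @param v A `normalized_matrix` with non-negative values.
#' @param pseudocount Positive offset added before taking logs.
#' @return A `normalized_matrix` at stage `"LOG2"`.
#' @export
log2_transform <- function(v, pseudocount = 1) {
  stopifnot(is(v, "normalized_matrix"))
  if (any(v$values < 0)) .stopf("negative values cannot be log2-transformed")
  .normalized(log2(v$values + pseudocount), "LOG2")
}

.region_label <- function(abbrevs) {
  if (length(abbrevs) == 0L) return("none")
  paste(.CONDITION_ABBREV[.CONDITION_ABBREV %in% abbrevs], collapse = "+")
}

.all_region_labels <- function() {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  vapply(seq_len(nrow(combos)), function(i) {
    .region_label(.CONDITION_ABBREV[unlist(combos[i, ])])
  }, "")
}

#' Four-condition expressed/not-expressed Venn partition
#'
#' A gene counts as expressed in a condition when its raw read count
#' reaches `t$expressed_min_count` (default: at least one read). Every
#' gene is assigned to exactly one of the 16 regions of the
#' mycelium/primordium/stipe/pileus Venn diagram; genes expressed nowhere
#' form the `"none"` region. Stage-specific sets collapse stipe and
#' pileus into the fruiting body: a gene is fruiting-body specific when
#' its region is a non-empty subset of \{stipe, pileus\}.
#'
#' @param m An [expression_matrix()] whose conditions include the four
#'   canonical labels.
#' @param t A [thresholds()] object.
#' @return An object of class `venn_partition`: `region_of` (named
#'   character vector of region labels like `"M+Pr+S+P"`), `region_counts`
#'   (named integer vector over all 16 regions), `stage_specific`
#'   (gene-id sets for mycelium, primordium, fruiting_body),
#'   `tissue_specific` (stipe, pileus), `region3_of` and `region3_counts`
#'   (the collapsed three-stage partition over \{M, Pr, F\}), and the
#'   summary counts `n_expressed_any` / `n_expressed_all` /
#'   `n_never_expressed`.
#' @export
venn_partition <- function(m, t = thresholds()) {
  stopifnot(is(m, "expression_matrix"))
  missing <- setdiff(CANONICAL_CONDITIONS, m$conditions)
  if (length(missing))
    .stopf("missing canonical condition(s) %s; conditions found: %s",
           paste(missing, collapse = ", "),
           paste(m$conditions, collapse = ", "))
  expressed <- m$counts[, CANONICAL_CONDITIONS, drop = FALSE] >=
    t$expressed_min_count
  region_of <- apply(expressed, 1, function(e)
    .region_label(.CONDITION_ABBREV[e]))
  names(region_of) <- m$gene_ids
  labels <- .all_region_labels()
  region_counts <- table(factor(region_of, levels = labels))
  region_counts <- stats::setNames(as.integer(region_counts),
                                   names(region_counts))
  only <- function(abbrev) names(region_of)[region_of == abbrev]
  fb_labels <- c("S", "P", "S+P")
  stage_specific <- list(
    mycelium = only("M"),
    primordium = only("Pr"),
    fruiting_body = names(region_of)[region_of %in% fb_labels]
  )
  tissue_specific <- list(stipe = only("S"), pileus = only("P"))
  fb <- expressed[, "stipe"] | expressed[, "pileus"]
  e3 <- cbind(M = expressed[, "mycelium"], Pr = expressed[, "primordium"],
              F = fb)
  region3_of <- apply(e3, 1, function(e) {
    if (!any(e)) "none" else paste(colnames(e3)[e], collapse = "+")
  })
  names(region3_of) <- m$gene_ids
  labels3 <- c("none", "M", "Pr", "F", "M+Pr", "M+F", "Pr+F", "M+Pr+F")
  region3_counts <- table(factor(region3_of, levels = labels3))
  region3_counts <- stats::setNames(as.integer(region3_counts),
                                    names(region3_counts))
  structure(list(
    region_of = region_of, region_counts = region_counts,
    stage_specific = stage_specific, tissue_specific = tissue_specific,
    region3_of = region3_of, region3_counts = region3_counts,
    n_expressed_any = sum(region_of != "none"),
    n_expressed_all = sum(region_of == "M+Pr+S+P"),
    n_never_expressed = sum(region_of == "none")
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  n <- length(x$region_of)
  cat(sprintf("venn_partition over %d genes:\n", n))
  cat(sprintf("  expressed at least once: %d\n", x$n_expressed_any))
  cat(sprintf("  expressed at all stages: %d\n", x$n_expressed_all))
  cat(sprintf("  never expressed: %d (%.1f%%)\n", x$n_never_expressed,
              100 * x$n_never_expressed / max(n, 1L)))
  invisible(x)
}

#' Peak fold-change and peaked-expression flags
#'
#' On the log2 scale, a gene gets a `fold_peak` at its (unique) maximum
#' condition when the maximum exceeds the second-highest condition by at
#' least `log2(t$fold_change)` — i.e. a `t$fold_change`-fold increase over
#' the next-highest expression level on the linear scale. `high_peak`
#' additionally requires the flagged peak to reach `t$peak_log2`.
#'
#' @param log2m A `normalized_matrix` at stage `"LOG2"` with at least two
#'   conditions.
#' @param t A [thresholds()] object.
#' @return Data frame with columns `gene_id`, `fold_peak` (peak condition
#'   name or `NA`), `peak_value`, `gap` (log2 difference to the
#'   next-highest condition) and `high_peak` (logical).
#' @export
fold_peak_flags <- function(log2m, t = thresholds()) {
  stopifnot(is(log2m, "normalized_matrix"))
  x <- log2m$values
  if (ncol(x) < 2L) .stopf("need at least two conditions")
  conds <- colnames(x)
  if (is.null(conds)) conds <- paste0("cond", seq_len(ncol(x)))
  gap_needed <- log2(t$fold_change)
  p <- apply(x, 1L, max)
  q <- apply(x, 1L, function(row) sort(row, decreasing = TRUE)[2L])
  unique_max <- rowSums(x == p) == 1L
  argmax <- max.col(x, ties.method = "first")
  fired <- unique_max & (p - q) >= gap_needed
  gene_id <- rownames(x)
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_len(nrow(x)))
  data.frame(
    gene_id = gene_id,
    fold_peak = ifelse(fired, conds[argmax], NA_character_),
    peak_value = unname(p), gap = unname(p - q),
    high_peak = fired & p >= t$peak_log2,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Genes above their family's average in every condition
#'
#' Within a gene family, a member is flagged when, in every condition, its
#' value strictly exceeds the mean of all *other* family members in that
#' condition.
#'
#' @param log2m A `normalized_matrix` (log2 stage by convention).
#' @param family Character vector of at least two gene ids, all present in
#'   the matrix.
#' @return Data frame with columns `gene_id` and `above_family_average`.
#' @export
above_family_average <- function(log2m, family) {
  stopifnot(is(log2m, "normalized_matrix"))
  x <- log2m$values
  if (length(family) < 2L)
    .stopf("family must have at least two members (no 'other' genes otherwise)")
  if (!all(family %in% rownames(x)))
    .stopf("family member(s) absent from the matrix: %s",
           paste(setdiff(family, rownames(x)), collapse = ", "))
  fx <- x[family, , drop = FALSE]
  csum <- colSums(fx)
  k <- length(family)
  flagged <- vapply(seq_len(k), function(i) {
    others_mean <- (csum - fx[i, ]) / (k - 1L)
    all(fx[i, ] > others_mean)
  }, TRUE)
  data.frame(gene_id = family, above_family_average = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read an expression matrix from TSV files
#'
#' @param counts_path TSV with a header of condition names and gene ids in
#'   the first column.
#' @param lengths_path Two-column TSV `gene_id`, `length`.
#' @param libsizes_path Two-column TSV `condition`, `library_size`.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(counts_path, lengths_path, libsizes_path) {
  cnt <- utils::read.delim(counts_path, check.names = FALSE)
  gene_ids <- as.character(cnt[[1L]])
  counts <- as.matrix(cnt[, -1L, drop = FALSE])
  len <- utils::read.delim(lengths_path, check.names = FALSE)
  lib <- utils::read.delim(libsizes_path, check.names = FALSE)
  lens <- stats::setNames(as.numeric(len[[2L]]), as.character(len[[1L]]))
  libs <- stats::setNames(as.numeric(lib[[2L]]), as.character(lib[[1L]]))
  if (!all(gene_ids %in% names(lens)))
    .stopf("gene length(s) missing for some genes")
  if (!all(colnames(counts) %in% names(libs)))
    .stopf("library size(s) missing for some conditions")
  expression_matrix(counts, libs[colnames(counts)], lens[gene_ids],
                    conditions = colnames(counts), gene_ids = gene_ids)
}

#' Write Venn region membership to a TSV file
#'
#' Columns: `gene_id`, `region` (four-condition label), `region3`
#' (collapsed three-stage label).
#'
#' @param vp A [venn_partition()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_tsv <- function(vp, path) {
  utils::write.table(
    data.frame(gene_id = names(vp$region_of), region = unname(vp$region_of),
               region3 = unname(vp$region3_of), stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
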