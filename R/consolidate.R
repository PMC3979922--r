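#' @name consolidate-module
#' @title Tiered consolidation of multi-source gene models
#'
#' @description
#' Gene models from four predictor sources are merged into a single
#' non-redundant set by three precedence tiers:
#'
#' 1. **Set 1** — homology-based models (two reference species) with a
#'    predictor score at or above the score cutoff; when a model based on
#'    the first reference overlaps one based on the second, the first is
#'    kept.
#' 2. **Set 2** — set 1 plus every transcript-assembly model that overlaps
#'    no set-1 member and whose coding region covers at least the required
#'    fraction of its transcript (truncated coding regions, e.g. from
#'    frameshifted transcripts, are filtered here).
#' 3. **Set 3** — set 2 plus every ab initio model that overlaps no set-2
#'    member.
#'
#' Overlap is strand-agnostic and span-based (at least one shared bp).
#' Every input model receives exactly one provenance decision.
NULL

.DECISIONS <- c("KEPT_CC", "KEPT_LB", "KEPT_CUFFLINKS", "KEPT_ABINITIO",
                "DROPPED_SCORE", "DROPPED_OVERLAP", "DROPPED_COVERAGE")

# For each candidate row, the row index of the first `kept` model whose
# span overlaps it (NA when none). Backed by the interval index.
.first_overlap <- function(candidates, kept) {
  n <- nrow(candidates)
  if (n == 0L) return(integer(0))
  if (nrow(kept) == 0L) return(rep(NA_integer_, n))
  lv <- union(unique(candidates$scaffold), unique(kept$scaffold))
  hits <- GenomicRanges::findOverlaps(.models_granges(candidates, lv),
                                      .models_granges(kept, lv))
  out <- rep(NA_integer_, n)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  first <- tapply(s, q, min)
  out[as.integer(names(first))] <- as.integer(first)
  out
}

.prov_row <- function(models, tier, decision, reason = NA_character_) {
  if (nrow(models) == 0L)
    return(data.frame(model_id = character(0), source = character(0),
                      tier = integer(0), decision = character(0),
                      reason_model_id = character(0),
                      stringsAsFactors = FALSE))
  data.frame(model_id = models$id, source = models$source, tier = tier,
             decision = decision,
             reason_model_id = rep_len(reason, nrow(models)),
             stringsAsFactors = FALSE)
}

#' Build gene set 1 from the two homology-based sources
#'
#' Keeps every first-reference (`cc`) model with score at or above
#' `t$min_score`, and every second-reference (`lb`) model at or above the
#' cutoff that overlaps no kept `cc` model. Models without a score fail
#' the cutoff. All drops are labelled `DROPPED_SCORE` or
#' `DROPPED_OVERLAP` (with the blocking model's id).
#'
#' @param cc,lb `gene_models` data frames for the two homology-based
#'   sources.
#' @param t A [thresholds()] object.
#' @return A tier result: `list(kept, provenance)` where `kept` is a
#'   `gene_models` data frame and `provenance` has columns `model_id`,
#'   `source`, `tier`, `decision`, `reason_model_id`.
#' @export
build_set1 <- function(cc, lb, t = thresholds()) {
  pass_cc <- !is.na(cc$score) & cc$score >= t$min_score
  kept_cc <- cc[pass_cc, , drop = FALSE]
  prov <- rbind(
    .prov_row(kept_cc, 1L, "KEPT_CC"),
    .prov_row(cc[!pass_cc, , drop = FALSE], 1L, "DROPPED_SCORE")
  )
  pass_lb <- !is.na(lb$score) & lb$score >= t$min_score
  prov <- rbind(prov,
                .prov_row(lb[!pass_lb, , drop = FALSE], 1L, "DROPPED_SCORE"))
  lb_cand <- lb[pass_lb, , drop = FALSE]
  blocker <- .first_overlap(lb_cand, kept_cc)
  kept_lb <- lb_cand[is.na(blocker), , drop = FALSE]
  dropped_lb <- lb_cand[!is.na(blocker), , drop = FALSE]
  prov <- rbind(prov,
                .prov_row(kept_lb, 1L, "KEPT_LB"),
                .prov_row(dropped_lb, 1L, "DROPPED_OVERLAP",
                          kept_cc$id[blocker[!is.na(blocker)]]))
  kept <- rbind(kept_cc, kept_lb)
  rownames(kept) <- NULL
  class(kept) <- c("gene_models", "data.frame")
  list(kept = kept, provenance = prov)
}

#' Extend set 1 with transcript-assembly models (gene set 2)
#'
#' Adds each transcript-assembly model that (a) overlaps no set-1 member
#' and (b) has CDS coverage at or above `t$min_cds_coverage`; (a) is
#' tested before (b) and the failing rule is recorded. A model without a
#' CDS counts as coverage 0 (`DROPPED_COVERAGE`). Under the default
#' frozen-tier mode, candidates are tested against set 1 only — additions
#' within the tier are not tested against each other; `incremental = TRUE`
#' also tests each candidate against earlier additions.
#'
#' @param set1 A tier result from [build_set1()].
#' @param cufflinks Transcript-assembly `gene_models`.
#' @param t A [thresholds()] object.
#' @param incremental Test candidates against earlier same-tier additions
#'   as well (default `FALSE`).
#' @return A tier result (`kept` spans tiers 1-2).
#' @export
extend_set2 <- function(set1, cufflinks, t = thresholds(),
                        incremental = FALSE) {
  .extend_tier(set1, cufflinks, tier = 2L, keep_label = "KEPT_CUFFLINKS",
               incremental = incremental, coverage_threshold =
                 t$min_cds_coverage)
}

#' Extend set 2 with ab initio models (gene set 3)
#'
#' Adds each ab initio model that overlaps no set-2 member. No score or
#' coverage filter applies at this tier.
#'
#' @param set2 A tier result from [extend_set2()].
#' @param abinitio Ab initio `gene_models`.
#' @param incremental As in [extend_set2()].
#' @return A tier result (`kept` spans tiers 1-3).
#' @export
extend_set3 <- function(set2, abinitio, incremental = FALSE) {
  .extend_tier(set2, abinitio, tier = 3L, keep_label = "KEPT_ABINITIO",
               incremental = incremental, coverage_threshold = NULL)
}

.extend_tier <- function(prev, candidates, tier, keep_label, incremental,
                         coverage_threshold) {
  prov <- prev$provenance
  kept <- prev$kept
  frozen <- kept
  added <- candidates[0L, , drop = FALSE]
  cov <- NULL
  if (!is.null(coverage_threshold) && nrow(candidates)) {
    noncoding <- vapply(candidates$cds, is.null, TRUE)
    cov <- numeric(nrow(candidates))
    if (any(!noncoding))
      cov[!noncoding] <- cds_coverage(candidates[!noncoding, , drop = FALSE])
  }
  if (incremental) {
    for (i in seq_len(nrow(candidates))) {
      cand <- candidates[i, , drop = FALSE]
      against <- rbind(frozen, added)
      blk <- .first_overlap(cand, against)
      if (!is.na(blk)) {
        prov <- rbind(prov, .prov_row(cand, tier, "DROPPED_OVERLAP",
                                      against$id[blk]))
      } else if (!is.null(cov) && cov[i] < coverage_threshold) {
        prov <- rbind(prov, .prov_row(cand, tier, "DROPPED_COVERAGE"))
      } else {
        prov <- rbind(prov, .prov_row(cand, tier, keep_label))
        added <- rbind(added, cand)
      }
    }
  } else {
    blk <- .first_overlap(candidates, frozen)
    over <- !is.na(blk)
    prov <- rbind(prov, .prov_row(candidates[over, , drop = FALSE], tier,
                                  "DROPPED_OVERLAP", frozen$id[blk[over]]))
    rest <- candidates[!over, , drop = FALSE]
    if (!is.null(cov)) {
      cov <- cov[!over]
      low <- cov < coverage_threshold
      prov <- rbind(prov, .prov_row(rest[low, , drop = FALSE], tier,
                                    "DROPPED_COVERAGE"))
      rest <- rest[!low, , drop = FALSE]
    }
    prov <- rbind(prov, .prov_row(rest, tier, keep_label))
    added <- rest
  }
  kept <- rbind(frozen, added)
  rownames(kept) <- NULL
  class(kept) <- c("gene_models", "data.frame")
  list(kept = kept, provenance = prov)
}

#' Run the full three-tier consolidation
#'
#' Applies [build_set1()], [extend_set2()] and [extend_set3()] to the
#' homology-based, transcript-assembly and ab initio sources of a
#' collection and returns the nested tier sets with complete provenance.
#'
#' @param collection A [gene_set_collection()] holding models from the
#'   sources `FGENESH_PLUS_CC`, `FGENESH_PLUS_LB`, `CUFFLINKS` and
#'   `FGENESH` (any may be empty).
#' @param t A [thresholds()] object.
#' @param incremental Test within-tier additions against each other
#'   (default `FALSE`, the frozen-tier mode, which is input-order
#'   independent).
#' @param within_source_filter Optional post-filter dropping later
#'   same-source models that overlap an earlier kept model of the same
#'   source (default `FALSE`; the tier rules only arbitrate across
#'   sources).
#' @return An object of class `consolidation_result`:
#'   `set1`/`set2`/`set3` (`gene_models` data frames, nested), `provenance`
#'   (one row per input model) and `counts` (named integer vector).
#' @export
#' @examples
#' cc <- gene_models(id = c("g1", "g2"), source = "FGENESH_PLUS_CC",
#'                   scaffold = "s", start = c(1, 2000),
#'                   end = c(1000, 3000), score = c(120, 90))
#' lb <- gene_models(id = c("h1", "h2"), source = "FGENESH_PLUS_LB",
#'                   scaffold = "s", start = c(500, 5000),
#'                   end = c(1500, 6000), score = c(150, 200))
#' res <- consolidate(gene_set_collection(cc, lb))
#' res$counts
consolidate <- function(collection, t = thresholds(), incremental = FALSE,
                        within_source_filter = FALSE) {
  stopifnot(is(collection, "gene_set_collection"))
  src <- function(tag) collection_models(collection, tag)
  s1 <- build_set1(src("FGENESH_PLUS_CC"), src("FGENESH_PLUS_LB"), t)
  set1 <- s1$kept
  s2 <- extend_set2(s1, src("CUFFLINKS"), t, incremental = incremental)
  set2 <- s2$kept
  s3 <- extend_set3(s2, src("FGENESH"), incremental = incremental)
  set3 <- s3$kept
  prov <- s3$provenance
  if (within_source_filter) {
    keep <- rep(TRUE, nrow(set3))
    for (srcname in unique(set3$source)) {
      rows <- which(set3$source == srcname)
      for (k in seq_along(rows)[-1L]) {
        i <- rows[k]
        earlier <- set3[rows[seq_len(k - 1L)][keep[rows[seq_len(k - 1L)]]], ,
                        drop = FALSE]
        blk <- .first_overlap(set3[i, , drop = FALSE], earlier)
        if (!is.na(blk)) {
          keep[i] <- FALSE
          hit <- prov$model_id == set3$id[i] & prov$source == srcname
          prov$decision[hit] <- "DROPPED_OVERLAP"
          prov$reason_model_id[hit] <- earlier$id[blk]
        }
      }
    }
    set3 <- set3[keep, , drop = FALSE]
    set1 <- set1[paste(set1$source, set1$id) %in%
                   paste(set3$source, set3$id), , drop = FALSE]
    set2 <- set2[paste(set2$source, set2$id) %in%
                   paste(set3$source, set3$id), , drop = FALSE]
  }
  res <- list(
    set1 = set1, set2 = set2, set3 = set3, provenance = prov,
    counts = c(set1 = nrow(set1), set2 = nrow(set2), set3 = nrow(set3))
  )
  class(res) <- "consolidation_result"
  res
}

#' @export
print.consolidation_result <- function(x, ...) {
  cat("Tiered gene-model consolidation:\n")
  cat(sprintf("  set 1 (homology-based, score-filtered): %d\n",
              x$counts[["set1"]]))
  cat(sprintf("  set 2 (+ transcript models, coverage-filtered): %d\n",
              x$counts[["set2"]]))
  cat(sprintf("  set 3 (+ ab initio fill-in): %d\n", x$counts[["set3"]]))
  tab <- table(x$provenance$decision)
  cat("  decisions:\n")
  for (nm in names(tab)) cat(sprintf("    %-18s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Write a consolidation provenance table
#'
#' Tab-separated columns: `model_id`, `source`, `tier`, `decision`,
#' `reason_model_id`.
#'
#' @param result A `consolidation_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(result, path) {
  utils::write.table(result$provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
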