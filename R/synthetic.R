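#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a small fungal genome
#' annotation project at desk scale: ~5.8 Mb of sequence on 11 scaffolds
#' at 49% GC, 2,000 true genes (about one gene per 2.9 kb) with on
#' average 5.8 exons of ~246 bp separated by ~180 bp introns, four
#' predictor sources emitting jittered copies with their own score
#' draws, transcript-assembly models with a configurable fraction of
#' truncated coding regions, and a four-condition negative-binomial count
#' matrix with planted never-expressed (8.4%) and condition-specific
#' (10%) genes.
#'
#' @param seed Integer master seed; every generator derives its stream
#'   from it, so equal configs give byte-identical outputs.
#' @param n_scaffolds,scaffold_length Number and length (bp) of
#'   scaffolds.
#' @param gc Genome GC fraction in `[0, 1]`.
#' @param n_true_genes Number of non-overlapping true genes to place.
#' @param exon_count_lambda Exons per gene = 1 + Poisson(lambda).
#' @param exon_length_mean,intron_length_mean Mean exon/intron lengths
#'   (bp, gamma-distributed with `length_shape`).
#' @param length_shape Gamma shape for exon/intron lengths.
#' @param emission_prob Named per-source probabilities that a true gene
#'   is emitted by that source.
#' @param score_mean,score_sd Normal location/scale of predictor scores
#'   (truncated at 0); transcript-assembly models carry no score.
#' @param truncation_prob Probability that a transcript-assembly copy has
#'   a truncated coding region.
#' @param truncated_coverage,intact_coverage Uniform ranges the CDS
#'   coverage of truncated/intact transcript models is drawn from.
#' @param jitter Maximum uniform shift (bp) applied to emitted copies.
#' @param min_gap Minimum gap (bp) between placed true genes.
#' @param baseline_mean Mean read count of a constitutively expressed
#'   gene per condition.
#' @param dispersion Negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2); 0 gives Poisson counts.
#' @param never_frac Fraction of genes planted as never expressed.
#' @param specific_frac Fraction planted as specific to one condition.
#' @param specific_fold Fold-increase of a specific gene's on-condition
#'   mean over `baseline_mean`.
#' @param leak_mean Mean off-condition read count of a specific gene
#'   (near-zero leakage).
#' @param mapped_fraction Fraction of each library's reads that map to
#'   genes (library size = column sum / mapped_fraction).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_scaffolds = 11,
                              scaffold_length = 530000,
                              gc = 0.49,
                              n_true_genes = 2000,
                              exon_count_lambda = 4.8,
                              exon_length_mean = 245.7,
                              intron_length_mean = 180.4,
                              length_shape = 4,
                              emission_prob = c(FGENESH = 0.85,
                                                FGENESH_PLUS_CC = 0.80,
                                                FGENESH_PLUS_LB = 0.80,
                                                CUFFLINKS = 0.75),
                              score_mean = 300,
                              score_sd = 120,
                              truncation_prob = 0.3,
                              truncated_coverage = c(0.05, 0.45),
                              intact_coverage = c(0.55, 0.95),
                              jitter = 60,
                              min_gap = 50,
                              baseline_mean = 500,
                              dispersion = 0.2,
                              never_frac = 0.084,
                              specific_frac = 0.1,
                              specific_fold = 8,
                              leak_mean = 0.01,
                              mapped_fraction = 0.9) {
  cfg <- as.list(environment())
  if (any(cfg$emission_prob < 0 | cfg$emission_prob > 1))
    .stopf("emission probabilities must lie in [0, 1]")
  if (cfg$gc < 0 || cfg$gc > 1) .stopf("gc must lie in [0, 1]")
  for (nm in c("n_scaffolds", "scaffold_length", "n_true_genes",
               "exon_length_mean", "intron_length_mean", "baseline_mean"))
    if (cfg[[nm]] <= 0) .stopf("'%s' must be positive", nm)
  if (cfg$never_frac + cfg$specific_frac > 1)
    .stopf("never_frac + specific_frac must not exceed 1")
  structure(cfg, class = "simulation_config")
}

# Derive a component sub-seed from the master seed (kept within the
# 32-bit integer range).
.subseed <- function(seed, k) (as.numeric(seed) * 1000003 + k) %% 2147483629

#' Simulate a genome
#'
#' I.i.d. bases at the configured GC fraction (G and C equally likely,
#' likewise A and T); deterministic under the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return A [Biostrings::DNAStringSet] with scaffolds named
#'   `scf01, scf02, ...`.
#' @export
simulate_genome <- function(cfg = simulation_config()) {
  .with_seed(.subseed(cfg$seed, 1), {
    p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
           T = (1 - cfg$gc) / 2)
    seqs <- vapply(seq_len(cfg$n_scaffolds), function(i) {
      paste(sample(names(p), cfg$scaffold_length, replace = TRUE, prob = p),
            collapse = "")
    }, "")
    names(seqs) <- sprintf("scf%02d", seq_len(cfg$n_scaffolds))
    Biostrings::DNAStringSet(seqs)
  })
}

# One true gene structure: exon matrix anchored at `at`.
.random_gene_structure <- function(cfg, at) {
  n_exons <- 1L + stats::rpois(1L, cfg$exon_count_lambda)
  exon_len <- pmax(30L, round(stats::rgamma(
    n_exons, shape = cfg$length_shape,
    scale = cfg$exon_length_mean / cfg$length_shape)))
  intron_len <- if (n_exons > 1L)
    pmax(20L, round(stats::rgamma(
      n_exons - 1L, shape = cfg$length_shape,
      scale = cfg$intron_length_mean / cfg$length_shape)))
    else integer(0)
  starts <- at + cumsum(c(0L, exon_len[-n_exons] + intron_len))
  ends <- starts + exon_len - 1L
  cbind(start = starts, end = ends)
}

# Shift a copy of a gene structure by a uniform jitter, clamped to the
# scaffold.
.jittered_copy <- function(exons, shift, scaffold_len) {
  ex <- exons + shift
  ex[ex < 1L] <- 1L
  ex[ex > scaffold_len] <- scaffold_len
  ex[ex[, 2L] >= ex[, 1L], , drop = FALSE]
}

# CDS span covering approximately `coverage` of the transcript, walking
# exons from the 5' end.
.cds_for_coverage <- function(exons, coverage) {
  lens <- exons[, 2L] - exons[, 1L] + 1L
  target <- max(1L, round(coverage * sum(lens)))
  cum <- cumsum(lens)
  k <- which(cum >= target)[1L]
  within <- target - if (k > 1L) cum[k - 1L] else 0L
  c(exons[1L, 1L], exons[k, 1L] + within - 1L)
}

#' Simulate multi-source predictor gene sets with known ground truth
#'
#' Places non-overlapping true genes on the genome, emits per-source
#' jittered copies with per-source score draws (transcript-assembly
#' copies additionally get a CDS whose coverage is drawn from the
#' configured truncated/intact mixture), and labels every emitted model
#' with its intended consolidation decision. Truth labels are assigned by
#' an independent quadratic rule evaluator (no interval index) and
#' re-verified directly against the rule definitions; generation aborts
#' on any inconsistency.
#'
#' @param cfg A [simulation_config()].
#' @param genome A genome from [simulate_genome()] (supplies scaffold
#'   names/lengths).
#' @param t A [thresholds()] object used to derive the truth labels.
#' @return `list(collection, truth, true_genes)`: the
#'   [gene_set_collection()], a truth data frame (`model_id`, `source`,
#'   `tier`, `decision`, `gene`), and the placed true-gene table.
#' @export
simulate_predictor_sets <- function(cfg = simulation_config(),
                                    genome = simulate_genome(cfg),
                                    t = thresholds()) {
  scaffold_len <- stats::setNames(Biostrings::width(genome), names(genome))
  .with_seed(.subseed(cfg$seed, 2), {
    per_scaffold <- diff(round(seq(0, cfg$n_true_genes,
                                   length.out = cfg$n_scaffolds + 1L)))
    true_genes <- list()
    gi <- 0L
    for (si in seq_along(scaffold_len)) {
      L <- scaffold_len[[si]]
      k <- per_scaffold[si]
      if (k == 0L) next
      structs <- lapply(seq_len(k), function(i)
        .random_gene_structure(cfg, 1L))
      widths <- vapply(structs, function(ex) ex[nrow(ex), 2L], 1)
      fixed_gap <- cfg$min_gap + cfg$jitter
      slack <- L - sum(widths) - (k + 1L) * fixed_gap
      if (slack < 0)
        .stopf(paste("infeasible placement: %d genes do not fit on the",
                     "configured genome"), cfg$n_true_genes)
      # spread the slack over the k+1 inter-gene gaps at random
      cuts <- sort(stats::runif(k))
      parts <- floor(slack * diff(c(0, cuts, 1)))
      cursor <- 0
      for (i in seq_len(k)) {
        gi <- gi + 1L
        s <- cursor + fixed_gap + parts[i] + 1
        true_genes[[gi]] <- list(gene = sprintf("tg%04d", gi),
                                 scaffold = names(scaffold_len)[si],
                                 exons = structs[[i]] + (s - 1))
        cursor <- s + widths[i] - 1
      }
    }

    sources <- names(cfg$emission_prob)
    rows <- list()
    for (tg in true_genes) {
      L <- scaffold_len[[tg$scaffold]]
      for (src in sources) {
        if (stats::runif(1L) > cfg$emission_prob[[src]]) next
        shift <- sample(seq(-cfg$jitter, cfg$jitter), 1L)
        ex <- .jittered_copy(tg$exons, shift, L)
        if (nrow(ex) == 0L) next
        span <- c(ex[1L, 1L], ex[nrow(ex), 2L])
        if (src == "CUFFLINKS") {
          score <- NA_real_
          rng <- if (stats::runif(1L) < cfg$truncation_prob)
            cfg$truncated_coverage else cfg$intact_coverage
          cds <- .cds_for_coverage(ex, stats::runif(1L, rng[1L], rng[2L]))
        } else {
          score <- max(0, stats::rnorm(1L, cfg$score_mean, cfg$score_sd))
          cds <- span
        }
        rows[[length(rows) + 1L]] <- list(
          id = sprintf("%s_%s", tolower(sub("FGENESH_PLUS_", "",
                                            sub("^FGENESH$", "abinitio",
                                                src))), tg$gene),
          source = src, scaffold = tg$scaffold, start = span[1L],
          end = span[2L], exons = ex, cds = cds, score = score,
          gene = tg$gene)
      }
    }
    models <- gene_models(
      id = vapply(rows, `[[`, "", "id"),
      source = vapply(rows, `[[`, "", "source"),
      scaffold = vapply(rows, `[[`, "", "scaffold"),
      start = vapply(rows, function(r) as.numeric(r$start), 1),
      end = vapply(rows, function(r) as.numeric(r$end), 1),
      exons = lapply(rows, `[[`, "exons"),
      cds = lapply(rows, `[[`, "cds"),
      score = vapply(rows, function(r) r$score, 1)
    )
    truth <- .brute_consolidate(models, t)
    truth$gene <- vapply(rows, `[[`, "", "gene")[
      match(paste(truth$source, truth$model_id),
            paste(models$source, models$id))]
    .verify_truth(models, truth, t)
    tg_df <- data.frame(
      gene = vapply(true_genes, `[[`, "", "gene"),
      scaffold = vapply(true_genes, `[[`, "", "scaffold"),
      start = vapply(true_genes, function(g) as.numeric(g$exons[1L, 1L]), 1),
      end = vapply(true_genes,
                   function(g) as.numeric(g$exons[nrow(g$exons), 2L]), 1),
      stringsAsFactors = FALSE)
    list(collection = gene_set_collection(models), truth = truth,
         true_genes = tg_df)
  })
}

# Independent quadratic evaluator of the tier rules: plain loops and span
# arithmetic, no interval index, no shared code with consolidate().
.brute_consolidate <- function(models, t) {
  ov_any <- function(i, kept_idx) {
    if (length(kept_idx) == 0L) return(NA_integer_)
    hit <- models$scaffold[kept_idx] == models$scaffold[i] &
      models$start[kept_idx] <= models$end[i] &
      models$start[i] <= models$end[kept_idx]
    if (any(hit)) kept_idx[which(hit)[1L]] else NA_integer_
  }
  n <- nrow(models)
  decision <- character(n)
  tier <- integer(n)
  cc <- which(models$source == "FGENESH_PLUS_CC")
  lb <- which(models$source == "FGENESH_PLUS_LB")
  cuff <- which(models$source == "CUFFLINKS")
  abin <- which(models$source == "FGENESH")
  kept <- integer(0)
  for (i in cc) {
    tier[i] <- 1L
    ok <- !is.na(models$score[i]) && models$score[i] >= t$min_score
    decision[i] <- if (ok) "KEPT_CC" else "DROPPED_SCORE"
    if (ok) kept <- c(kept, i)
  }
  kept_cc <- kept
  for (i in lb) {
    tier[i] <- 1L
    if (is.na(models$score[i]) || models$score[i] < t$min_score) {
      decision[i] <- "DROPPED_SCORE"
    } else if (!is.na(ov_any(i, kept_cc))) {
      decision[i] <- "DROPPED_OVERLAP"
    } else {
      decision[i] <- "KEPT_LB"
      kept <- c(kept, i)
    }
  }
  set1 <- kept
  for (i in cuff) {
    tier[i] <- 2L
    if (!is.na(ov_any(i, set1))) {
      decision[i] <- "DROPPED_OVERLAP"
    } else {
      cvg <- if (is.null(models$cds[[i]])) 0 else
        cds_coverage(models[i, , drop = FALSE])
      if (cvg >= t$min_cds_coverage) {
        decision[i] <- "KEPT_CUFFLINKS"
        kept <- c(kept, i)
      } else decision[i] <- "DROPPED_COVERAGE"
    }
  }
  set2 <- kept
  for (i in abin) {
    tier[i] <- 3L
    if (!is.na(ov_any(i, set2))) {
      decision[i] <- "DROPPED_OVERLAP"
    } else {
      decision[i] <- "KEPT_ABINITIO"
      kept <- c(kept, i)
    }
  }
  data.frame(model_id = models$id, source = models$source, tier = tier,
             decision = decision, stringsAsFactors = FALSE)
}

# Direct re-verification of truth labels against the rule definitions;
# aborts on the first inconsistency.
.verify_truth <- function(models, truth, t) {
  dec <- truth$decision[match(paste(models$source, models$id),
                              paste(truth$source, truth$model_id))]
  kept <- dec %in% c("KEPT_CC", "KEPT_LB", "KEPT_CUFFLINKS",
                     "KEPT_ABINITIO")
  fail <- function(msg) .stopf("generator truth inconsistency: %s", msg)
  scored <- !is.na(models$score) & models$score >= t$min_score
  hom <- models$source %in% c("FGENESH_PLUS_CC", "FGENESH_PLUS_LB")
  if (any(hom & !scored & dec != "DROPPED_SCORE"))
    fail("sub-threshold homology model not dropped for score")
  if (any(hom & kept & !scored))
    fail("kept homology model below the score threshold")
  tier_of <- c(KEPT_CC = 1L, KEPT_LB = 1L, KEPT_CUFFLINKS = 2L,
               KEPT_ABINITIO = 3L)
  kept_idx <- which(kept)
  ktier <- tier_of[dec[kept_idx]]
  for (a in seq_along(kept_idx)) {
    lower <- kept_idx[ktier < ktier[a]]
    if (length(lower) == 0L) next
    i <- kept_idx[a]
    if (any(models$scaffold[i] == models$scaffold[lower] &
            models$start[i] <= models$end[lower] &
            models$start[lower] <= models$end[i]))
      fail("kept model overlaps an earlier-tier kept model")
  }
  cuffk <- models$source == "CUFFLINKS" & kept
  if (any(cuffk)) {
    cvg <- cds_coverage(models[cuffk, , drop = FALSE])
    if (any(cvg < t$min_cds_coverage))
      fail("kept transcript model below the coverage threshold")
  }
  invisible(TRUE)
}

#' Simulate a count matrix with planted expression classes
#'
#' Draws negative-binomial read counts for each gene and condition.
#' Genes are planted as never expressed (all-zero), constitutively
#' expressed, or specific to one condition (baseline x fold on their
#' condition, near-zero leakage elsewhere).
#'
#' @param cfg A [simulation_config()].
#' @param gene_ids Character vector of gene identifiers.
#' @param gene_lengths Optional transcript lengths (bp); drawn from a
#'   gamma distribution with mean 1425 bp when absent.
#' @param conditions Condition names (default [CANONICAL_CONDITIONS]).
#' @return `list(em, truth)`: an [expression_matrix()] and a truth data
#'   frame with columns `gene_id`, `class` (`never` / `constitutive` /
#'   `specific`), `condition` (for specific genes).
#' @export
simulate_counts <- function(cfg = simulation_config(), gene_ids,
                            gene_lengths = NULL,
                            conditions = CANONICAL_CONDITIONS) {
  n <- length(gene_ids)
  .with_seed(.subseed(cfg$seed, 3), {
    if (is.null(gene_lengths))
      gene_lengths <- pmax(200, round(stats::rgamma(n, shape = 6,
                                                    scale = 1425 / 6)))
    class <- sample(c("never", "specific", "constitutive"), n,
                    replace = TRUE,
                    prob = c(cfg$never_frac, cfg$specific_frac,
                             1 - cfg$never_frac - cfg$specific_frac))
    condition <- rep(NA_character_, n)
    condition[class == "specific"] <-
      sample(conditions, sum(class == "specific"), replace = TRUE)
    rnb <- function(mu) {
      out <- integer(length(mu))
      pos <- mu > 0
      if (any(pos)) {
        out[pos] <- if (cfg$dispersion <= 1e-12)
          stats::rpois(sum(pos), mu[pos])
        else
          stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / cfg$dispersion)
      }
      out
    }
    counts <- matrix(0L, n, length(conditions),
                     dimnames = list(gene_ids, conditions))
    for (j in seq_along(conditions)) {
      mu <- numeric(n)
      mu[class == "constitutive"] <- cfg$baseline_mean
      sp <- class == "specific"
      mu[sp] <- ifelse(condition[sp] == conditions[j],
                       cfg$baseline_mean * cfg$specific_fold,
                       cfg$leak_mean)
      counts[, j] <- rnb(mu)
    }
    library_sizes <- pmax(1, ceiling(colSums(counts) / cfg$mapped_fraction))
    em <- expression_matrix(counts, library_sizes, gene_lengths,
                            conditions = conditions, gene_ids = gene_ids)
    truth <- data.frame(gene_id = gene_ids, class = class,
                        condition = condition, stringsAsFactors = FALSE)
    list(em = em, truth = truth)
  })
}
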