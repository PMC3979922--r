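# Independent brute-force oracles and random-instance generators used by
# the property and equivalence tests. These deliberately share no code
# with the package: plain loops, plain arithmetic.

# Sort/average quantile normalization: target distribution is the row
# mean of the column-sorted matrix; each value is replaced by the mean of
# the target values at the ranks its tie group occupies.
oracle_quantile <- function(x) {
  sorted <- apply(x, 2, sort)
  target <- rowMeans(as.matrix(sorted))
  out <- x
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    col <- numeric(nrow(x))
    i <- 1L
    while (i <= nrow(x)) {
      grp <- i
      while (grp < nrow(x) && x[ord[grp + 1L], j] == x[ord[i], j])
        grp <- grp + 1L
      col[ord[i:grp]] <- mean(target[i:grp])
      i <- grp + 1L
    }
    out[, j] <- col
  }
  out
}

# Prefix-enumeration N50/L50: walk the sorted lengths until half the
# total is covered.
oracle_nx <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (k in seq_along(s)) {
    acc <- acc + s[k]
    if (acc >= half) return(list(n50 = s[k], l50 = k))
  }
}

# Quadratic rule evaluator for the tiered consolidation; no interval
# index, candidate-by-candidate loops.
oracle_consolidate <- function(models, t) {
  span_hits <- function(i, idx) {
    for (j in idx) {
      if (models$scaffold[i] == models$scaffold[j] &&
          !(models$end[i] < models$start[j] ||
            models$end[j] < models$start[i])) return(TRUE)
    }
    FALSE
  }
  decision <- setNames(character(nrow(models)),
                       paste(models$source, models$id))
  kept <- integer(0)
  cc <- which(models$source == "FGENESH_PLUS_CC")
  for (i in cc) {
    if (!is.na(models$score[i]) && models$score[i] >= t$min_score) {
      decision[i] <- "KEPT_CC"; kept <- c(kept, i)
    } else decision[i] <- "DROPPED_SCORE"
  }
  kept_cc <- kept
  for (i in which(models$source == "FGENESH_PLUS_LB")) {
    if (is.na(models$score[i]) || models$score[i] < t$min_score) {
      decision[i] <- "DROPPED_SCORE"
    } else if (span_hits(i, kept_cc)) {
      decision[i] <- "DROPPED_OVERLAP"
    } else {
      decision[i] <- "KEPT_LB"; kept <- c(kept, i)
    }
  }
  set1 <- kept
  for (i in which(models$source == "CUFFLINKS")) {
    if (span_hits(i, set1)) {
      decision[i] <- "DROPPED_OVERLAP"
    } else {
      cov <- 0
      if (!is.null(models$cds[[i]])) {
        ex <- models$exons[[i]]
        cd <- models$cds[[i]]
        s <- pmax(ex[, 1], cd[1]); e <- pmin(ex[, 2], cd[2])
        cov <- sum(pmax(e - s + 1, 0)) / sum(ex[, 2] - ex[, 1] + 1)
      }
      if (cov >= t$min_cds_coverage) {
        decision[i] <- "KEPT_CUFFLINKS"; kept <- c(kept, i)
      } else decision[i] <- "DROPPED_COVERAGE"
    }
  }
  set2 <- kept
  for (i in which(models$source == "FGENESH")) {
    if (span_hits(i, set2)) decision[i] <- "DROPPED_OVERLAP"
    else { decision[i] <- "KEPT_ABINITIO"; kept <- c(kept, i) }
  }
  data.frame(model_id = models$id, source = models$source,
             decision = unname(decision[paste(models$source, models$id)]),
             stringsAsFactors = FALSE)
}

# Random multi-source model instance for equivalence/property tests.
random_models <- function(n, seed, n_scaffolds = 3, span_max = 20000) {
  set.seed(seed)
  source <- sample(c("FGENESH", "FGENESH_PLUS_CC", "FGENESH_PLUS_LB",
                     "CUFFLINKS"), n, replace = TRUE)
  scaffold <- paste0("s", sample.int(n_scaffolds, n, replace = TRUE))
  start <- sample.int(span_max, n, replace = TRUE)
  len <- sample(50:800, n, replace = TRUE)
  score <- round(stats::rnorm(n, 150, 80), 1)
  score[sample.int(n, max(1, n %/% 10))] <- NA
  exons <- vector("list", n)
  cds <- vector("list", n)
  for (i in seq_len(n)) {
    if (len[i] > 300 && stats::runif(1) < 0.5) {
      b <- start[i] + sort(sample(seq(40, len[i] - 40, by = 10), 2))
      exons[[i]] <- rbind(c(start[i], b[1]), c(b[2], start[i] + len[i]))
    } else {
      exons[[i]] <- cbind(start[i], start[i] + len[i])
    }
    if (source[i] != "CUFFLINKS" || stats::runif(1) < 0.9) {
      tl <- sum(exons[[i]][, 2] - exons[[i]][, 1] + 1)
      frac <- stats::runif(1, 0.1, 1)
      cds[[i]] <- c(exons[[i]][1, 1],
                    exons[[i]][1, 1] + max(1, round(frac * tl)) - 1)
      cds[[i]][2] <- min(cds[[i]][2], start[i] + len[i])
    }
  }
  gene_models(id = paste0("m", seq_len(n)), source = source,
              scaffold = scaffold, start = start, end = start + len,
              exons = exons, cds = cds, score = score)
}

canonical_em <- function(counts, lengths = NULL) {
  colnames(counts) <- CANONICAL_CONDITIONS
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  expression_matrix(counts, pmax(colSums(counts), 1e6), lengths)
}
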