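test_that("RPKM follows the counts x 1e9 / (library x length) formula", {
  m <- expression_matrix(matrix(c(0, 1000), 1, 2,
                                dimnames = list("g", c("a", "b"))),
                         library_sizes = c(1e7, 1e7), gene_lengths = 2000)
  v <- rpkm(m)
  expect_equal(unname(v$values[1, ]), c(0, 50))
  expect_equal(v$stage, "RPKM")

  # scaling counts and library sizes together leaves RPKM unchanged
  m2 <- expression_matrix(2 * m$counts, 2 * m$library_sizes,
                          m$gene_lengths)
  expect_equal(rpkm(m2)$values, v$values)

  one <- function(x) matrix(x, 1, 1, dimnames = list("g", "c1"))
  expect_error(expression_matrix(one(1), 0, 100), "positive")
  expect_error(expression_matrix(one(1), 10, 0), "positive")
  expect_error(expression_matrix(one(5), 2, 100), "column sums")
  expect_error(expression_matrix(one(-1), 10, 100), "non-negative")
})

test_that("quantile normalization matches hand examples and fixed points", {
  nm <- function(x) genetier:::.normalized(x, "RPKM")
  two <- quantile_normalize(nm(cbind(a = c(1, 2, 3), b = c(4, 5, 6))))
  expect_equal(unname(two$values),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  same <- cbind(x = c(3, 1, 2), y = c(3, 1, 2))
  expect_equal(quantile_normalize(nm(same))$values, same)
  one <- cbind(x = c(9, 4, 7))
  expect_equal(quantile_normalize(nm(one))$values, one)
})

test_that("quantile normalization equalises columns and matches the oracle", {
  set.seed(21)
  for (k in 1:10) {
    # tie-free draws: every column ends up with the identical multiset
    x <- matrix(stats::rexp(sample(20:200, 1) * 4, 0.1), ncol = 4)
    q <- quantile_normalize(genetier:::.normalized(x, "RPKM"))$values
    for (j in 2:4)
      expect_equal(sort(q[, 1]), sort(q[, j]))
    expect_equal(q, oracle_quantile(x))
    expect_equal(diff(range(colMeans(q))), 0, tolerance = 1e-12)
  }
  # tied values: column means stay equal and the oracle agrees
  for (k in 1:5) {
    x <- matrix(rpois(60 * 4, 3), ncol = 4)
    q <- quantile_normalize(genetier:::.normalized(x, "RPKM"))$values
    expect_equal(q, oracle_quantile(x))
    expect_lt(diff(range(colMeans(q))), 1e-12)
  }
  # tie-free case agrees with limma's implementation
  x <- matrix(stats::rnorm(600), ncol = 3)
  q <- quantile_normalize(genetier:::.normalized(x, "RPKM"))$values
  expect_equal(q, unname(limma::normalizeQuantiles(x)), tolerance = 1e-12)
})

test_that("log2 transform applies the pseudocount and rejects negatives", {
  nm <- genetier:::.normalized(cbind(a = c(0, 3, 49)), "QUANTILE")
  lg <- log2_transform(nm)
  expect_equal(unname(lg$values[, 1]), c(0, 2, log2(50)))
  expect_equal(lg$stage, "LOG2")
  expect_error(log2_transform(genetier:::.normalized(cbind(-1), "RPKM")),
               "negative")
})

test_that("venn partition enumerates all 16 regions and checks totals", {
  combos <- as.matrix(expand.grid(rep(list(0:1), 4)))
  counts <- combos * 5
  em <- canonical_em(counts)
  vp <- venn_partition(em)
  expect_equal(sum(vp$region_counts), 16L)
  expect_true(all(vp$region_counts == 1L))
  expect_equal(vp$n_expressed_any + vp$n_never_expressed, 16L)
  expect_equal(vp$n_expressed_all, 1L)
  expect_equal(sum(vp$region3_counts), 16L)

  all4 <- canonical_em(matrix(3, 1, 4))
  expect_equal(unname(venn_partition(all4)$region_of), "M+Pr+S+P")
  none <- canonical_em(matrix(0, 1, 4))
  expect_equal(unname(venn_partition(none)$region_of), "none")

  em_bad <- expression_matrix(matrix(1, 1, 2), c(10, 10), 100,
                              conditions = c("mycelium", "stipe"))
  expect_error(venn_partition(em_bad), "primordium")
})

test_that("venn region counts are invariant under gene reordering", {
  set.seed(31)
  counts <- matrix(rpois(200 * 4, 0.8), 200, 4)
  em <- canonical_em(counts)
  vp <- venn_partition(em)
  perm <- sample.int(200)
  em2 <- canonical_em(counts[perm, , drop = FALSE])
  vp2 <- venn_partition(em2)
  expect_equal(vp$region_counts, vp2$region_counts)
  expect_equal(vp$region3_counts, vp2$region3_counts)
})

test_that("stage-specific sets collapse stipe and pileus into fruiting body", {
  counts <- rbind(m = c(2, 0, 0, 0), pr = c(0, 2, 0, 0),
                  s = c(0, 0, 2, 0), p = c(0, 0, 0, 2),
                  sp = c(0, 0, 2, 2), all = c(2, 2, 2, 2))
  vp <- venn_partition(canonical_em(counts))
  expect_setequal(vp$stage_specific$mycelium, "m")
  expect_setequal(vp$stage_specific$primordium, "pr")
  expect_setequal(vp$stage_specific$fruiting_body, c("s", "p", "sp"))
  expect_setequal(vp$tissue_specific$stipe, "s")
  expect_setequal(vp$tissue_specific$pileus, "p")
  expect_equal(unname(vp$region3_of[c("s", "p", "sp")]),
               rep("F", 3))
})

test_that("fold-peak flags implement the 2-fold and peak rules", {
  nm <- function(x) {
    colnames(x) <- CANONICAL_CONDITIONS
    genetier:::.normalized(x, "LOG2")
  }
  flags <- fold_peak_flags(nm(rbind(g1 = c(6.0, 4.9, 4.0, 3.0))))
  expect_equal(flags$fold_peak, "mycelium")
  expect_true(flags$high_peak)

  expect_true(is.na(fold_peak_flags(nm(rbind(c(2, 2, 2, 2))))$fold_peak))

  low <- fold_peak_flags(nm(rbind(c(4.0, 2.0, 2.0, 2.0))))
  expect_equal(low$fold_peak, "mycelium")
  expect_false(low$high_peak)

  # a log2 gap of exactly 1.0 is a 2-fold increase and fires the flag
  exact <- fold_peak_flags(nm(rbind(c(5.0, 4.0, 3.0, 1.0))))
  expect_equal(exact$fold_peak, "mycelium")

  expect_error(fold_peak_flags(genetier:::.normalized(cbind(1), "LOG2")),
               "two conditions")
})

test_that("fold-change limits flag all unique maxima or nothing", {
  set.seed(41)
  x <- matrix(round(runif(50 * 4, 0, 8), 2), 50, 4)
  colnames(x) <- CANONICAL_CONDITIONS
  nm <- genetier:::.normalized(x, "LOG2")
  everyone <- fold_peak_flags(nm, thresholds(fold_change = 1))
  unique_max <- apply(x, 1, function(r) sum(r == max(r)) == 1)
  expect_equal(!is.na(everyone$fold_peak), unique_max)
  nobody <- fold_peak_flags(nm, thresholds(fold_change = 1e9))
  expect_true(all(is.na(nobody$fold_peak)))
})

test_that("family-average flags require strict dominance in every condition", {
  x <- rbind(hi = c(5, 5, 5, 5), lo = c(1, 1, 1, 1))
  colnames(x) <- CANONICAL_CONDITIONS
  nm <- genetier:::.normalized(x, "LOG2")
  f <- above_family_average(nm, c("hi", "lo"))
  expect_equal(f$above_family_average, c(TRUE, FALSE))

  # equality with the others' mean in one condition blocks the flag
  y <- rbind(a = c(5, 2, 5, 5), b = c(2, 2, 2, 2), c = c(2, 2, 2, 2))
  colnames(y) <- CANONICAL_CONDITIONS
  f2 <- above_family_average(genetier:::.normalized(y, "LOG2"),
                             c("a", "b", "c"))
  expect_false(f2$above_family_average[1])

  expect_error(above_family_average(nm, "hi"), "at least two")

  set.seed(51)
  z <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(paste0("g", 1:5), CANONICAL_CONDITIONS))
  fz <- above_family_average(genetier:::.normalized(z, "LOG2"),
                             rownames(z))
  brute <- sapply(1:5, function(i)
    all(sapply(1:4, function(j) z[i, j] > mean(z[-i, j]))))
  expect_equal(fz$above_family_average, brute)
})

test_that("expression TSVs round-trip through read_expression_tsv", {
  dir <- withr::local_tempdir()
  counts <- matrix(rpois(40, 20), 10, 4,
                   dimnames = list(paste0("g", 1:10),
                                   CANONICAL_CONDITIONS))
  em <- expression_matrix(counts, colSums(counts) + 100,
                          rep(1500, 10))
  write.table(data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE),
              file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = rownames(counts), length = 1500),
              file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(condition = colnames(counts),
                         library_size = colSums(counts) + 100),
              file.path(dir, "libsizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_expression_tsv(file.path(dir, "counts.tsv"),
                              file.path(dir, "lengths.tsv"),
                              file.path(dir, "libsizes.tsv"))
  expect_equal(unname(back$counts), unname(em$counts))
  expect_equal(back$conditions, em$conditions)
  expect_equal(back$library_sizes, unname(em$library_sizes))
})
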