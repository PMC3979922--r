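# The worked toy instance used throughout: two homology sources, a
# transcript source with varying CDS coverage, and an ab initio source.
toy_sources <- function() {
  cc <- gene_models(id = c("g1", "g2"), source = "FGENESH_PLUS_CC",
                    scaffold = "s", start = c(1, 2000),
                    end = c(1000, 3000), score = c(120, 90))
  lb <- gene_models(id = c("h1", "h2"), source = "FGENESH_PLUS_LB",
                    scaffold = "s", start = c(500, 5000),
                    end = c(1500, 6000), score = c(150, 200))
  cuff <- gene_models(id = c("t1", "t2", "t3"), source = "CUFFLINKS",
                      scaffold = "s", start = c(2000, 5000, 7000),
                      end = c(2999, 5500, 7999),
                      cds = list(c(2000, 2599), c(5000, 5450),
                                 c(7000, 7299)))
  abinitio <- gene_models(id = c("f1", "f2"), source = "FGENESH",
                          scaffold = "s", start = c(7000, 2500),
                          end = c(8000, 3500), score = c(50, 60))
  list(cc = cc, lb = lb, cuff = cuff, abinitio = abinitio)
}

decision_of <- function(prov, id) prov$decision[prov$model_id == id]

.subset_empty <- function() {
  gene_models(id = character(0), source = character(0),
              scaffold = character(0), start = integer(0), end = integer(0))
}

test_that("tier 1 keeps scored models and prefers the first reference", {
  src <- toy_sources()
  s1 <- build_set1(src$cc, src$lb)
  expect_setequal(s1$kept$id, c("g1", "h2"))
  expect_equal(decision_of(s1$provenance, "g2"), "DROPPED_SCORE")
  expect_equal(decision_of(s1$provenance, "h1"), "DROPPED_OVERLAP")
  expect_equal(s1$provenance$reason_model_id[
    s1$provenance$model_id == "h1"], "g1")

  empty <- build_set1(.subset_empty(), .subset_empty())
  expect_equal(nrow(empty$kept), 0L)
})

test_that("a score of exactly the cutoff is kept", {
  cc <- gene_models(id = "b", source = "FGENESH_PLUS_CC", scaffold = "s",
                    start = 1, end = 100, score = 100)
  s1 <- build_set1(cc, .subset_empty())
  expect_equal(s1$kept$id, "b")
  unscored <- gene_models(id = "u", source = "FGENESH_PLUS_CC",
                          scaffold = "s", start = 1, end = 100)
  expect_equal(build_set1(unscored, .subset_empty())$provenance$decision,
               "DROPPED_SCORE")
})

test_that("tier 2 applies overlap before coverage and honours the 50% boundary", {
  src <- toy_sources()
  s1 <- build_set1(src$cc, src$lb)
  s2 <- extend_set2(s1, src$cuff)
  # t1 covers 600/1000 = 0.6 and is clear of set 1; t2 overlaps h2;
  # t3 covers 300/1000 = 0.3
  expect_setequal(s2$kept$id, c("g1", "h2", "t1"))
  expect_equal(decision_of(s2$provenance, "t2"), "DROPPED_OVERLAP")
  expect_equal(decision_of(s2$provenance, "t3"), "DROPPED_COVERAGE")

  boundary <- gene_models(id = "tb", source = "CUFFLINKS", scaffold = "z",
                          start = 1, end = 1000, cds = list(c(1, 500)))
  expect_equal(cds_coverage(boundary), 0.5)
  s2b <- extend_set2(s1, boundary)
  expect_true("tb" %in% s2b$kept$id)

  no_cds <- gene_models(id = "nc", source = "CUFFLINKS", scaffold = "z",
                        start = 1, end = 1000)
  expect_equal(decision_of(extend_set2(s1, no_cds)$provenance, "nc"),
               "DROPPED_COVERAGE")
})

test_that("tier 3 fills gaps left by set 2 and the toy resolves to 4 models", {
  src <- toy_sources()
  s2 <- extend_set2(build_set1(src$cc, src$lb), src$cuff)
  s3 <- extend_set3(s2, src$abinitio)
  expect_setequal(s3$kept$id, c("g1", "h2", "t1", "f1"))
  expect_equal(decision_of(s3$provenance, "f2"), "DROPPED_OVERLAP")

  identity <- extend_set3(s2, .subset_empty())
  expect_equal(identity$kept$id, s2$kept$id)

  coll <- gene_set_collection(src$cc, src$lb, src$cuff, src$abinitio)
  res <- consolidate(coll)
  expect_equal(unname(res$counts), c(2L, 3L, 4L))
})

test_that("consolidation equals the quadratic brute-force oracle", {
  th <- thresholds()
  for (seed in 1:12) {
    models <- random_models(sample(40:250, 1), seed = 1000 + seed)
    res <- consolidate(gene_set_collection(models), th)
    want <- oracle_consolidate(models, th)
    got <- res$provenance
    key <- paste(got$source, got$model_id)
    expect_identical(
      got$decision,
      want$decision[match(key, paste(want$source, want$model_id))])
  }
})

test_that("tier sets nest, provenance partitions the input, counts match", {
  models <- random_models(300, seed = 77)
  res <- consolidate(gene_set_collection(models))
  key <- function(m) paste(m$source, m$id)
  expect_true(all(key(res$set1) %in% key(res$set2)))
  expect_true(all(key(res$set2) %in% key(res$set3)))
  expect_setequal(paste(res$provenance$source, res$provenance$model_id),
                  key(models))
  expect_equal(nrow(res$provenance), nrow(models))
  expect_equal(unname(res$counts),
               c(nrow(res$set1), nrow(res$set2), nrow(res$set3)))
  # no tier-2/3 addition overlaps an earlier-tier member
  tier_of <- c(KEPT_CC = 1, KEPT_LB = 1, KEPT_CUFFLINKS = 2,
               KEPT_ABINITIO = 3)
  kept <- res$set3
  ktier <- tier_of[res$provenance$decision[
    match(key(kept), paste(res$provenance$source,
                           res$provenance$model_id))]]
  for (i in seq_len(nrow(kept))) {
    lower <- which(ktier < ktier[i])
    if (!length(lower)) next
    expect_false(any(kept$scaffold[i] == kept$scaffold[lower] &
                       kept$start[i] <= kept$end[lower] &
                       kept$start[lower] <= kept$end[i]))
  }
})

test_that("raising thresholds never grows the kept sets", {
  models <- random_models(250, seed = 5)
  coll <- gene_set_collection(models)
  sizes1 <- sapply(c(50, 100, 150, 220), function(s)
    consolidate(coll, thresholds(min_score = s))$counts[["set1"]])
  expect_true(all(diff(sizes1) <= 0))
  sizes2 <- sapply(c(0.2, 0.5, 0.8, 0.99), function(cv)
    consolidate(coll, thresholds(min_cds_coverage = cv))$counts[["set2"]])
  expect_true(all(diff(sizes2) <= 0))
})

test_that("frozen-tier results are invariant under input order", {
  models <- random_models(200, seed = 9)
  res <- consolidate(gene_set_collection(models))
  set.seed(99)
  shuffled <- models[sample.int(nrow(models)), ]
  rownames(shuffled) <- NULL
  class(shuffled) <- c("gene_models", "data.frame")
  res2 <- consolidate(gene_set_collection(shuffled))
  key <- function(m) sort(paste(m$source, m$id))
  expect_identical(key(res$set3), key(res2$set3))
  expect_identical(key(res$set1), key(res2$set1))
})

test_that("provenance TSV has the documented columns", {
  src <- toy_sources()
  res <- consolidate(gene_set_collection(src$cc, src$lb, src$cuff,
                                         src$abinitio))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_provenance(res, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("model_id", "source", "tier", "decision",
                             "reason_model_id"))
  expect_equal(nrow(tab), 9L)
})
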