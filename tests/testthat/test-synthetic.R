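# Small configs keep the simulator tests quick; the full default scale is
# exercised by the acceptance suite.
small_cfg <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_scaffolds = 3, scaffold_length = 120000,
                    n_true_genes = 120, ...)
}

test_that("simulated genomes honour GC and are seed-deterministic", {
  pure <- simulation_config(seed = 2, n_scaffolds = 1,
                            scaffold_length = 2000, gc = 1.0)
  g <- simulate_genome(pure)
  freq <- Biostrings::letterFrequency(g, c("A", "C", "G", "T"))
  expect_equal(sum(freq[, c("A", "T")]), 0)

  half <- simulation_config(seed = 3, n_scaffolds = 1,
                            scaffold_length = 1e6, gc = 0.5)
  gh <- simulate_genome(half)
  st <- assembly_stats(gh)
  # binomial standard error at n = 1e6 is 0.05%; allow 10 SE
  expect_lt(abs(st$gc_percent - 50), 0.5)

  expect_identical(as.character(simulate_genome(small_cfg(seed = 7))),
                   as.character(simulate_genome(small_cfg(seed = 7))))
  expect_false(identical(as.character(simulate_genome(small_cfg(seed = 7))),
                         as.character(simulate_genome(small_cfg(seed = 8)))))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_genome(small_cfg()))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("predictor emission follows the configured probabilities", {
  cfg <- small_cfg(seed = 4,
                   emission_prob = c(FGENESH = 0, FGENESH_PLUS_CC = 1,
                                     FGENESH_PLUS_LB = 0.5, CUFFLINKS = 0))
  sim <- simulate_predictor_sets(cfg)
  tab <- table(sim$collection$models$source)
  expect_false("FGENESH" %in% names(tab))
  expect_false("CUFFLINKS" %in% names(tab))
  expect_equal(tab[["FGENESH_PLUS_CC"]], 120)
  expect_gt(tab[["FGENESH_PLUS_LB"]], 25)
  expect_lt(tab[["FGENESH_PLUS_LB"]], 95)
})

test_that("a degenerate config drops nothing for score or coverage", {
  cfg <- small_cfg(seed = 5, score_mean = 5000, score_sd = 1,
                   truncation_prob = 0, intact_coverage = c(0.8, 0.95))
  sim <- simulate_predictor_sets(cfg)
  expect_false(any(sim$truth$decision %in%
                     c("DROPPED_SCORE", "DROPPED_COVERAGE")))
  # every first-reference homology model is kept
  cc <- sim$truth[sim$truth$source == "FGENESH_PLUS_CC", ]
  expect_true(all(cc$decision == "KEPT_CC"))
})

test_that("simulator truth equals the pipeline's decisions", {
  sim <- simulate_predictor_sets(small_cfg(seed = 6))
  res <- consolidate(sim$collection)
  m <- merge(res$provenance, sim$truth, by = c("model_id", "source"))
  expect_equal(nrow(m), nrow(sim$collection$models))
  expect_identical(m$decision.x, m$decision.y)
})

test_that("infeasible placements abort with a clear error", {
  cfg <- simulation_config(seed = 1, n_scaffolds = 1,
                           scaffold_length = 5000, n_true_genes = 50)
  expect_error(simulate_predictor_sets(cfg), "infeasible placement")
})

test_that("counts honour planted classes and the dispersion model", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_counts(cfg, paste0("g", 1:2000))
  expect_equal(dim(sim$em$counts), c(2000, 4))
  never <- sim$truth$gene_id[sim$truth$class == "never"]
  expect_true(all(sim$em$counts[never, ] == 0))
  vp <- venn_partition(sim$em)
  expect_true(all(vp$region_of[never] == "none"))

  # Poisson limit: variance approaches the mean as dispersion -> 0
  pois <- simulate_counts(small_cfg(seed = 10, dispersion = 0,
                                    specific_frac = 0, never_frac = 0),
                          paste0("g", 1:5000))
  cnt <- pois$em$counts[, 1]
  expect_equal(var(cnt) / mean(cnt), 1, tolerance = 0.1)

  nb <- simulate_counts(small_cfg(seed = 10, dispersion = 0.2,
                                  specific_frac = 0, never_frac = 0),
                        paste0("g", 1:5000))
  cntnb <- nb$em$counts[, 1]
  mu <- mean(cntnb)
  expect_equal(var(cntnb), mu + 0.2 * mu^2, tolerance = 0.15)
})

test_that("counts and predictor sets are deterministic under the seed", {
  a <- simulate_counts(small_cfg(seed = 11), paste0("g", 1:50))
  b <- simulate_counts(small_cfg(seed = 11), paste0("g", 1:50))
  expect_identical(a$em$counts, b$em$counts)
  expect_identical(a$truth, b$truth)
  s1 <- simulate_predictor_sets(small_cfg(seed = 11))
  s2 <- simulate_predictor_sets(small_cfg(seed = 11))
  expect_identical(s1$collection$models, s2$collection$models)
  expect_identical(s1$truth, s2$truth)
})

test_that("gene-set statistics recover the simulator's length settings", {
  sim <- simulate_predictor_sets(small_cfg(seed = 12))
  cc <- collection_models(sim$collection, "FGENESH_PLUS_CC")
  st <- gene_set_stats(cc, total_length = 3 * 120000)
  # configured means: 245.7 bp exons, 180.4 bp introns, 5.8 exons/gene;
  # clamping at the 30/20 bp minima biases the means up slightly
  expect_equal(st$mean_exon_length, 245.7, tolerance = 0.08)
  expect_equal(st$mean_intron_length, 180.4, tolerance = 0.08)
  expect_equal(st$mean_exons_per_gene, 5.8, tolerance = 0.15)
})

test_that("write_simulation emits a complete, readable bundle", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 13)
  out <- write_simulation(cfg, dir)
  files <- list.files(dir)
  for (f in c("genome.fa", "counts.tsv", "lengths.tsv", "libsizes.tsv",
              "model_truth.tsv", "expression_truth.tsv", "manifest.json"))
    expect_true(f %in% files, info = f)
  expect_true(any(grepl("\\.gff3$", files)))

  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(length(genome), 3)
  back <- read_gff3(file.path(dir, "fgenesh_plus_cc.gff3"))
  cc <- collection_models(out$models$collection, "FGENESH_PLUS_CC")
  expect_equal(nrow(back), nrow(cc))
  em <- read_expression_tsv(file.path(dir, "counts.tsv"),
                            file.path(dir, "lengths.tsv"),
                            file.path(dir, "libsizes.tsv"))
  expect_equal(unname(em$counts), unname(out$expression$em$counts))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$command, "simulate")
  expect_equal(manifest$seed, cfg$seed)
})
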