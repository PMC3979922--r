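---
title: "Methods: tiered gene-model consolidation, stage-specific expression, and genome summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered gene-model consolidation, stage-specific expression, and genome summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetier)
```

## Scope

`genetier` re-implements, as tested and reusable functions, three
computational procedures that recur in fungal genome-annotation projects
such as the *Flammulina velutipes* (winter mushroom) genome: (i)
consolidating gene models from several prediction programs into one
non-redundant gene set with tiered precedence rules; (ii) turning a
genes × conditions read-count matrix into normalized expression values
and classifying genes by the developmental stages in which they are
expressed; and (iii) assembly- and gene-set-level summary statistics.
Because the raw predictor outputs and read alignments of such projects
are generally not deposited in runnable form, the package ships a seeded
simulator that generates all inputs with known ground truth; every
pipeline stage is validated against that truth and against independent
brute-force oracles.

## The consolidation model

Each predictor source emits *gene models*: a genomic span on a scaffold,
an ordered set of exons, an optional CDS span, and an optional score.
Coordinates are 1-based inclusive (the GFF3 convention); any BED-style
output converts to 0-based half-open at the boundary. Four sources are
distinguished: two homology-based predictions (`FGENESH_PLUS_CC`,
`FGENESH_PLUS_LB`, guided by two different reference species), a
transcript-assembly source (`CUFFLINKS`), and a pure ab initio source
(`FGENESH`).

Consolidation proceeds in three tiers:

1. **Set 1.** Homology-based models with predictor score ≥ `min_score`
   (default 100) are collected; where a first-reference and a
   second-reference model overlap, the first-reference model is kept.
2. **Set 2.** A transcript-assembly model is added when it (a) overlaps
   no set-1 member and (b) its coding region covers ≥ `min_cds_coverage`
   (default 0.5) of its transcript. Rule (a) is tested before (b), and
   the failing rule is recorded in the provenance. The coverage filter
   exists because transcript assemblies often contain frameshifted
   transcripts with truncated coding regions; a model without any CDS
   counts as coverage 0.
3. **Set 3.** An ab initio model is added when it overlaps no set-2
   member. No score filter applies at this tier.

Design choices that the rule text leaves open, fixed here and exposed as
options:

* **Overlap** is strand-agnostic, span-based (gene spans, not exon
  chains), and requires ≥ 1 shared bp — the default behaviour of
  standard interval-intersection tools. Exon-level or
  minimum-fraction overlap would be stricter; the span rule is the
  simplest reading and is the package default.
* **Models without scores fail the score filter** (fail-closed: the rule
  conditions on the score, so an unscored model cannot pass it).
* **Within-source overlaps are not resolved**: the tiers arbitrate
  *across* sources only. An optional post-filter
  (`within_source_filter = TRUE`) collapses same-source overlaps.
* **Frozen-tier semantics**: candidates at tiers 2 and 3 are tested
  against the previous tier only, then the tier freezes — additions
  within a tier are not tested against each other. This makes results
  independent of input order (asserted by a shuffle test). An
  incremental mode (`incremental = TRUE`) tests candidates against
  earlier same-tier additions as well.
* **Boundary semantics** are inclusive: score exactly 100 and coverage
  exactly 0.50 are kept.

Overlap queries run on an NCList interval index
(`GenomicRanges::findOverlaps`); correctness is checked against an
index-free quadratic evaluator on random instances.

## Expression analysis

Counts are converted to RPKM (reads per kilobase of exon model per
million mapped reads):

$$\mathrm{RPKM}_{gc} = \frac{n_{gc} \cdot 10^9}{N_c \, L_g}$$

with $n_{gc}$ the read count of gene $g$ in condition $c$, $N_c$ the
condition's library size, and $L_g$ the gene's summed exon length.
Columns are then quantile-normalized: each column's rank $r$ value is
replaced by the mean of the $r$-th order statistics across columns, and
tied values receive the mean of the tied ranks' target quantiles. (That
tie rule differs from interpolation at the average tied rank — the
behaviour of some library implementations — whenever three or more
values tie; the package implements the direct tied-quantile mean and
cross-checks against `limma::normalizeQuantiles` on tie-free input.)
Values are finally log2-transformed with a pseudocount of 1, so that
zero expression maps to 0.

**Expressed** is defined on raw counts — at least `expressed_min_count`
(default 1) read in a condition — because RPKM thresholds would entangle
expression breadth with gene length. The threshold is configurable.
Every gene is assigned to exactly one of the 16 regions of the
{mycelium, primordium, stipe, pileus} Venn diagram; a collapsed
three-stage view merges stipe and pileus into the fruiting body. A gene
is *stage-specific* for the fruiting body when its region is a
non-empty subset of {stipe, pileus}.

Two specificity flags operate on the log2 matrix:

* **Peak fold-change**: a gene is flagged at its maximum condition when
  the maximum exceeds the second-highest condition by ≥
  `log2(fold_change)` (default: 1, i.e. 2-fold on the linear scale; a
  gap of exactly 1.0 fires). A tied maximum never fires — with the
  fold-change at its lower limit of 1 the flag reduces to "has a unique
  maximum". The *peaked* variant additionally requires the flagged
  maximum to reach `peak_log2` (default 5.5).
* **Above family average**: within a gene family (e.g. the
  lignin-active auxiliary-activity enzymes), a member is flagged when in
  *every* condition it strictly exceeds the mean of all *other* family
  members. Strict inequality means equality in any one condition blocks
  the flag; a singleton family is rejected (there are no "other" genes).

## Genome summaries

* **N50/L50**: sort lengths descending, accumulate until half the total;
  N50 is the length at that point, L50 the number of sequences used. For
  assemblies whose published tables print a length under the "L50"
  label, note that L50 here is a count, as is standard.
* **Windowed GC** and **gene density** use non-overlapping fixed-size
  windows (default 100 kb; 0-based half-open; the last window may be
  short). GC is computed over called bases only — ambiguity codes are
  excluded from numerator and denominator (windows of no called bases
  carry `NA`). Each gene is counted once, in the window containing its
  start coordinate; genes are not fractionally split.
* **Gene-set means**: introns are the gaps between consecutive exons
  (`next start − previous end − 1`); single-exon genes contribute
  nothing to the intron mean, which is `NA` when no intron exists.

## The simulator: what it emulates, and what it does not

The default `simulation_config()` is a desk-scale model of a fungal
annotation project: 11 scaffolds of 530 kb (≈ 5.8 Mb) of i.i.d. sequence
at 49% GC; 2,000 non-overlapping true genes (about one gene per 2.9 kb)
with 1 + Poisson(4.8) exons per gene and gamma-distributed exon
(mean 245.7 bp) and intron (mean 180.4 bp) lengths, matching the
published per-gene structure statistics of the *F. velutipes*
annotation; per-source emission probabilities of 0.75–0.85; normal
predictor scores (mean 300, sd 120, truncated at 0) so a realistic
minority falls below the score cutoff; 30% of transcript models carry
truncated coding regions (coverage drawn uniformly from 0.05–0.45,
intact models from 0.55–0.95); and copies jittered uniformly within
±60 bp. Counts are negative-binomial (the standard RNA-seq noise model;
variance $\mu + 0.2\mu^2$) with a baseline mean of 500 reads; 8.4% of
genes are planted never-expressed (the published never-expressed
fraction) and 10% condition-specific at 8× baseline with an
off-condition leakage mean of 0.01 reads — a near-zero
cross-contamination level at which a specific gene occasionally shows a
stray off-condition read, so recovery sensitivity is high but not
trivially 1.

Ground-truth consolidation labels are assigned by an independent
quadratic rule evaluator at generation time and re-verified directly
against the rule definitions; generation aborts on any inconsistency.
All randomness flows from the master seed through per-component
sub-streams, and the caller's RNG state is left untouched.

What the simulator does **not** model: sequence composition structure
(isochores, repeats), alternative isoforms, partially overlapping true
genes, correlated errors between predictors, positionally biased read
coverage, or between-replicate variability (each condition is a single
library, as in the motivating design). Passing recovery tests therefore
demonstrates the correctness of the rule implementations under the
stated noise model, not robustness to every artefact of real data.

## Numerical and degenerate-input choices

* Quantile normalization of a single column is the identity; identical
  columns are a fixed point.
* `log2_transform` rejects negative input; RPKM of a zero count is 0.
* `venn_partition` requires the four canonical condition names and
  reports the ones it found otherwise.
* `fold_peak_flags` requires ≥ 2 conditions; `nx_stats` rejects empty
  or non-positive length lists; `gene_set_stats` rejects empty model
  sets.
* Gene placement distributes measured slack over inter-gene gaps, so a
  configuration fails fast ("infeasible placement") exactly when the
  drawn gene structures cannot physically fit.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
default desk-scale configuration: 2,000 true genes (≈ 6,400 emitted
models) on 5.8 Mb, 2,000-gene count matrices, and window tracks at
20 kb on the simulated scaffolds. Oracle-equivalence suites use 100
random consolidation instances of 40–400 models, 50 random matrices up
to 200 × 6, and 100 random length lists — sizes chosen so the quadratic
oracles remain exact references while the whole suite stays fast.

## Known limitations

* The package consolidates by span arithmetic only; it does not merge
  splice graphs, re-predict ORFs, or repair frameshifted transcripts —
  such models are simply filtered by the coverage rule.
* Differential-expression testing, GO/KEGG enrichment, and read
  alignment are out of scope; counts are taken as input.
* The published genome-scale tier counts of any particular project are
  not reproducible without its exact predictor outputs; the package's
  evidence of correctness is oracle equivalence and simulator-truth
  recovery, plus the printed-count arithmetic that *is* fully
  specified by published tables.
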