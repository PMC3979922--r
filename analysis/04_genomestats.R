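#!/usr/bin/env Rscript
# Step 4: assembly and gene-set summary statistics.
#
# Computes N50/L50 and global GC for the simulated assembly, windowed
# GC-content and gene-density tracks (100-kb non-overlapping windows,
# scaled to 20 kb here because the simulated scaffolds are ~0.5 Mb),
# and the gene-set means (exon/intron lengths, exons per gene, genes
# per Mb, kb per gene).

suppressMessages(library(genetier))

genome <- Biostrings::readDNAStringSet("results/sim/genome.fa")
models <- read_gff3("results/final_models.gff3")

ast <- assembly_stats(genome)
cat(sprintf("Assembly: %d scaffolds, %.2f Mb, N50 %.0f bp (L50 %d), GC %.2f%%\n",
            ast$n_sequences, ast$total_length / 1e6, ast$n50, ast$l50,
            ast$gc_percent))

window <- 20000
gc <- gc_windows(genome, window)
write_bedgraph(gc, "results/gc_windows.bedgraph")
lens <- setNames(Biostrings::width(genome), names(genome))
gd <- gene_density_windows(models, lens, window)
write_bedgraph(gd, "results/gene_density.bedgraph")
cat(sprintf("Windowed tracks at %d bp: GC in [%.1f, %.1f]%%, gene counts in [%d, %d]\n",
            window, min(gc$value, na.rm = TRUE), max(gc$value, na.rm = TRUE),
            min(gd$value), max(gd$value)))

gst <- gene_set_stats(models, ast$total_length)
cat(sprintf("Gene set: %d genes; mean gene %.0f bp, transcript %.0f bp,\n",
            gst$n_genes, gst$mean_gene_length, gst$mean_transcript_length))
cat(sprintf("  %.2f exons/gene (mean exon %.1f bp, intron %.1f bp); 1 gene per %.2f kb\n",
            gst$mean_exons_per_gene, gst$mean_exon_length,
            gst$mean_intron_length, gst$kb_per_gene))

jsonlite::write_json(c(ast, gst), "results/genome_stats.json",
                     auto_unbox = TRUE, digits = NA)
write.table(data.frame(statistic = names(c(ast, gst)),
                       value = unlist(c(ast, gst))),
            "results/genome_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote gc_windows.bedgraph, gene_density.bedgraph, genome_stats.{json,tsv}\n")
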