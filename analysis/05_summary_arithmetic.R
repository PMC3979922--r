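#!/usr/bin/env Rscript
# Step 5: headline summary arithmetic from the published annotation
# counts shipped with the package (Flammulina velutipes KACC42780):
# expression breadth percentages, genomic space per gene, inparalog and
# database-annotation percentages, and lignocellulolytic enzyme totals.

suppressMessages(library(genetier))

q <- annotation_summary_arithmetic()
cat(sprintf("Never expressed: %.1f%%  (expressed at least once: %d genes)\n",
            q$never_expressed_percent, q$expressed_at_least_once))
cat(sprintf("Genomic space per gene: %.1f kb\n", q$kb_per_gene))
cat(sprintf("Unique genes with inparalogs: %.1f%%\n", q$inparalog_percent))
cat(sprintf("NR-annotated: %.1f%%   KOG-annotated: %.2f%%\n",
            q$nr_annotated_percent, q$kog_annotated_percent))
cat(sprintf("AA genes (families AA1-AA10): %d   CAZymes (GH+GT+PL+CE): %d\n",
            q$aa_gene_total, q$cazyme_class_total))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(q, "results/summary_arithmetic.json",
                     auto_unbox = TRUE, digits = NA)
cat("Wrote results/summary_arithmetic.json\n")
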