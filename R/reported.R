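#' Published annotation counts shipped with the package
#'
#' Summary counts from the published Flammulina velutipes KACC42780
#' genome annotation (total predicted genes, never-expressed genes,
#' assembly length, ortholog-group and database-annotation counts),
#' stored as plain-text package data. They serve as worked-example
#' inputs for the summary arithmetic in
#' [annotation_summary_arithmetic()].
#'
#' @return A named list of counts.
#' @export
reference_annotation_counts <- function() {
  jsonlite::read_json(system.file("extdata",
                                  "fvelutipes_annotation_counts.json",
                                  package = "genetier", mustWork = TRUE),
                      simplifyVector = TRUE)
}

#' Published lignocellulolytic enzyme family counts
#'
#' Gene counts per auxiliary-activity (AA) family and per CAZyme class
#' (GH, GT, PL, CE) for the Flammulina velutipes genome, as plain-text
#' package data.
#'
#' @return A data frame with columns `group`, `family`, `count`.
#' @export
reference_enzyme_families <- function() {
  utils::read.delim(system.file("extdata",
                                "fvelutipes_enzyme_family_counts.tsv",
                                package = "genetier", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Derived summary quantities from annotation counts
#'
#' Computes the headline descriptive quantities of a genome annotation
#' from its raw counts: the percentage of genes never expressed across
#' the profiled conditions, the number expressed at least once, the
#' average genomic space per gene (kb per gene), the percentage of
#' species-unique genes with inparalogs, database-annotation
#' percentages, and the totals of the AA-family and CAZyme-class gene
#' counts.
#'
#' @param counts A named list as returned by
#'   [reference_annotation_counts()].
#' @param families A data frame as returned by
#'   [reference_enzyme_families()].
#' @return A named list of numeric quantities (percentages on the 0-100
#'   scale, kb_per_gene in kb).
#' @export
#' @examples
#' annotation_summary_arithmetic(reference_annotation_counts(),
#'                               reference_enzyme_families())
annotation_summary_arithmetic <- function(counts = reference_annotation_counts(),
                                          families = reference_enzyme_families()) {
  list(
    never_expressed_percent =
      100 * counts$never_expressed_genes / counts$total_genes,
    expressed_at_least_once =
      counts$total_genes - counts$never_expressed_genes,
    kb_per_gene = counts$assembly_length_bp / counts$total_genes / 1000,
    inparalog_percent =
      100 * counts$inparalog_genes / counts$unique_genes,
    nr_annotated_percent =
      100 * counts$nr_annotated_genes / counts$total_genes,
    kog_annotated_percent =
      100 * counts$kog_annotated_genes / counts$total_genes,
    aa_gene_total = sum(families$count[families$group == "AA"]),
    cazyme_class_total = sum(families$count[families$group == "CAZyme"])
  )
}
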