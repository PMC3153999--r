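#' Regulation-of-autophagy pathway reference tables
#'
#' Published association values for the regulation-of-autophagy (ROA)
#' pathway and wrist/arm bone mineral density, bundled as plain-text
#' tables: the pathway's 25 member genes (core autophagy ATG machinery,
#' type I/II interferons, and autophagy-modulating kinases), the 13
#' best SNPs representing its discovery-cohort leading-edge genes (with
#' two-sided p values and sample minor allele frequencies), and the 8
#' leading-edge genes of the family-based replication cohort with their
#' best-SNP p values. Useful as a worked example for [gene_statistics()]
#' and [leading_edge_overlap()] and as a realism anchor for choosing
#' simulation effect sizes (best-SNP p values in the 1e-3 to 1e-2 band,
#' MAF 0.08-0.39).
#'
#' @return A list of three data.frames: `pathway_genes` (gene, entrez_id,
#'   location), `discovery_leading_edge` (snp_id, gene, p_value, role,
#'   alleles, maf), `replication_leading_edge` (gene, p_value).
#' @export
roa_reference <- function() {
  f <- function(name) {
    read.delim(system.file("extdata", name, package = "pathgwas",
                           mustWork = TRUE),
               stringsAsFactors = FALSE)
  }
  list(pathway_genes = f("roa_pathway_genes.tsv"),
       discovery_leading_edge = f("roa_leading_edge_discovery.tsv"),
       replication_leading_edge = f("roa_leading_edge_replication.tsv"))
}
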