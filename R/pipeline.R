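#' Configure an end-to-end pipeline run
#'
#' Exactly one of `simulate` (a [sim_config()]) or the four input paths
#' (`genotypes`, `phenotypes`, `genes`, `sets`) must be given. Input paths
#' use the plain-text formats written by [write_cohort()]: genotype TSV
#' (subject rows, SNP columns) plus a SNP metadata TSV, phenotype TSV,
#' gene BED, and a GMT collection.
#'
#' @param simulate a [sim_config()], or `NULL` to read inputs from files.
#' @param genotypes,snps,phenotypes,genes,sets input paths (genotype TSV,
#'   SNP metadata TSV, phenotype TSV, gene BED, GMT).
#' @param stats_in optional TSV of externally computed per-SNP statistics
#'   (see [load_external_stats()]); skips adjustment and association and
#'   implies `mode = "statistic"`.
#' @param qc a [qc_thresholds()] object.
#' @param covariates candidate covariate terms for [select_covariates()].
#' @param alpha_covariate covariate retention threshold.
#' @param window_bp SNP-to-gene mapping window.
#' @param coverage_min,set_size_range gene-set testability filter (see
#'   [filter_sets()]).
#' @param mode permutation mode, `"phenotype"` or `"statistic"`.
#' @param n_perm,weight_exponent,alpha_fdr,alpha_fwer enrichment settings.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param seed integer seed governing permutations (and simulation, unless
#'   the `simulate` block carries its own seed).
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = NULL,
                       genotypes = NULL, snps = NULL, phenotypes = NULL,
                       genes = NULL, sets = NULL,
                       stats_in = NULL,
                       qc = qc_thresholds(),
                       covariates = c("age", "age2", "sex", "age_sex",
                                      "age2_sex", "height", "weight"),
                       alpha_covariate = 0.05,
                       window_bp = 500000,
                       coverage_min = 0.85,
                       set_size_range = c(10, 200),
                       mode = c("phenotype", "statistic"),
                       n_perm = 1000,
                       weight_exponent = 1,
                       alpha_fdr = 0.05,
                       alpha_fwer = 0.05,
                       outdir = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  from_files <- !is.null(genotypes)
  .assert(xor(!is.null(simulate), from_files),
          "exactly one of a simulate block or input paths must be given")
  if (from_files) {
    .assert(!is.null(snps) && !is.null(phenotypes) && !is.null(genes) &&
              !is.null(sets),
            "file input needs genotypes, snps, phenotypes, genes, and sets paths")
  }
  if (!is.null(stats_in)) mode <- "statistic"
  structure(list(simulate = simulate, genotypes = genotypes, snps = snps,
                 phenotypes = phenotypes, genes = genes, sets = sets,
                 stats_in = stats_in, qc = qc, covariates = covariates,
                 alpha_covariate = alpha_covariate, window_bp = window_bp,
                 coverage_min = coverage_min, set_size_range = set_size_range,
                 mode = mode, n_perm = n_perm,
                 weight_exponent = weight_exponent,
                 alpha_fdr = alpha_fdr, alpha_fwer = alpha_fwer,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the pathway-GWAS pipeline end to end
#'
#' Simulate (or load) -> SNP QC -> covariate selection and trait
#' adjustment -> per-SNP Wald scan (or external statistics) -> SNP-to-gene
#' mapping and best-SNP gene statistics -> gene-set testability filter ->
#' permutation enrichment analysis. Stage outputs are written to
#' `config$outdir` as TSVs when it is set; reruns with the same config and
#' seed are reproducible.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return A list bundle with elements `cohort` (when simulated),
#'   `qc_report`, `covariate_selection`, `adjusted`, `snp_results`,
#'   `mapping`, `gene_stats`, `set_filter_report`, `results`
#'   (the [pathway_enrichment()] table), and `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  say <- function(...) if (!quiet) message(sprintf(...))
  bundle <- list(config = config)

  if (!is.null(config$simulate)) {
    say("stage simulate: seed %d", config$simulate$seed)
    cohort <- .stage("simulate", simulate_cohort(config$simulate))
    bundle$cohort <- cohort
    geno <- cohort$genotypes
    pheno <- cohort$phenotypes
    gene_map <- cohort$gene_map
    sets <- cohort$gene_sets
  } else {
    say("stage load: %s", config$genotypes)
    geno <- .stage("load", {
      gt <- read.delim(config$genotypes, check.names = FALSE,
                       stringsAsFactors = FALSE)
      calls <- as.matrix(gt[, -1, drop = FALSE])
      rownames(calls) <- gt[[1]]
      storage.mode(calls) <- "double"
      genotype_matrix(calls, read.delim(config$snps, stringsAsFactors = FALSE))
    })
    pheno <- .stage("load", read.delim(config$phenotypes,
                                       stringsAsFactors = FALSE))
    gene_map <- .stage("load", read_gene_bed(config$genes))
    sets <- .stage("load", read_gmt(config$sets))
  }

  qcres <- .stage("qc", apply_qc(geno, gene_map, config$qc))
  say("stage qc: %d -> %d SNPs (call rate %d, HWE %d, MAF %d, distance %d)",
      qcres$report$n_input, qcres$report$n_retained,
      qcres$report$n_fail_callrate, qcres$report$n_fail_hwe,
      qcres$report$n_fail_maf, qcres$report$n_fail_distance)
  geno <- qcres$genotypes
  bundle$qc_report <- qcres$report

  if (is.null(config$stats_in)) {
    sel <- .stage("adjust", select_covariates(pheno, config$covariates,
                                              alpha = config$alpha_covariate))
    say("stage adjust: retained {%s}", paste(sel$retained, collapse = ", "))
    adjusted <- .stage("adjust", adjust_trait(pheno, sel))
    bundle$covariate_selection <- sel
    bundle$adjusted <- adjusted
    snp_results <- .stage("assoc", snp_association(geno, adjusted))
    say("stage assoc: %d SNPs tested", sum(is.finite(snp_results$statistic)))
  } else {
    say("stage assoc: external statistics from %s", config$stats_in)
    adjusted <- NULL
    snp_results <- .stage("assoc", load_external_stats(config$stats_in))
  }
  bundle$snp_results <- snp_results

  mapping <- .stage("map", map_snps_to_genes(geno$snp_meta, gene_map,
                                             window = config$window_bp))
  gene_stats <- .stage("map", gene_statistics(mapping, snp_results))
  say("stage map: %d SNP-gene assignments, %d genes scored",
      nrow(mapping), nrow(gene_stats))
  bundle$mapping <- mapping
  bundle$gene_stats <- gene_stats

  filtered <- .stage("sets", filter_sets(sets, gene_stats$gene_id,
                                         coverage_min = config$coverage_min,
                                         size_range = config$set_size_range))
  say("stage sets: %d of %d sets testable", length(filtered$sets),
      length(if (inherits(sets, "gene_set_collection")) sets$sets else sets))
  bundle$set_filter_report <- attr(filtered, "filter_report")

  results <- .stage("enrich", pathway_enrichment(
    gene_stats = gene_stats, sets = filtered, mode = config$mode,
    geno = geno, adjusted = adjusted, mapping = mapping,
    n_perm = config$n_perm, weight_exponent = config$weight_exponent,
    seed = config$seed, alpha_fdr = config$alpha_fdr,
    alpha_fwer = config$alpha_fwer))
  say("stage enrich: %d sets, %d significant (FDR <= %g & FWER <= %g)",
      nrow(results), sum(results$significant),
      config$alpha_fdr, config$alpha_fwer)
  bundle$results <- results

  if (!is.null(config$outdir)) .stage("write", .write_bundle(bundle))
  invisible(bundle)
}

.write_bundle <- function(bundle) {
  dir <- bundle$config$outdir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$cohort)) {
    write_cohort(bundle$cohort, file.path(dir, "cohort"))
  }
  .write_tsv(as.data.frame(bundle$qc_report), file.path(dir, "qc_report.tsv"))
  if (!is.null(bundle$covariate_selection)) {
    .write_tsv(bundle$covariate_selection$table,
               file.path(dir, "covariate_selection.tsv"))
  }
  if (!is.null(bundle$adjusted)) {
    .write_tsv(as.data.frame(bundle$adjusted),
               file.path(dir, "adjusted_phenotype.tsv"))
  }
  write_snp_results(bundle$snp_results, file.path(dir, "snp_results.tsv"))
  .write_tsv(bundle$gene_stats, file.path(dir, "gene_stats.tsv"))
  .write_tsv(bundle$set_filter_report, file.path(dir, "set_filter.tsv"))
  .write_tsv(as.data.frame(bundle$results),
             file.path(dir, "pathway_results.tsv"))
  invisible(dir)
}

#' Top pathways table
#'
#' Top `k` pathways ordered by NES (ties broken by set name), showing the
#' enrichment score, NES, nominal p, FDR q, FWER p, and the significance
#' flag — so a set with the best nominal p but failing multiple-testing
#' control is visible but unflagged.
#'
#' @param results a [pathway_enrichment()] table.
#' @param k number of rows (capped at the number of sets).
#' @return data.frame of the top rows.
#' @export
report_top_table <- function(results, k = 10) {
  .assert(k >= 1, "k must be >= 1")
  ord <- order(-results$nes, results$set_name)
  out <- as.data.frame(results)[ord, c("set_name", "size", "es", "nes",
                                       "p_nominal", "p_nominal_label",
                                       "q_fdr", "p_fwer", "significant")]
  rownames(out) <- NULL
  head(out, min(k, nrow(out)))
}
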