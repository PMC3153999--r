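#' Configure a synthetic GWAS cohort
#'
#' Defines the generative model for [simulate_cohort()]: unrelated subjects,
#' biallelic SNPs in Hardy-Weinberg proportions laid out in genes on
#' synthetic chromosomes, a quantitative trait built from covariates plus
#' small additive per-gene effects concentrated in one designated causal
#' pathway, and an overlapping gene-set annotation.
#'
#' Genotypes at each SNP are Binomial(2, MAF) draws, independent across
#' subjects and (by default) across SNPs; `ld_rho` optionally introduces
#' first-order correlation by copying the previous SNP's genotype with that
#' probability. The trait is
#' `intercept + covariate effects + sum_g beta_g * z_g + N(0, noise_sd^2)`
#' where `z_g` is the standardized dosage of one causal SNP per causal gene
#' and `beta_g` is sized so each causal gene explains `per_gene_h2` of the
#' covariate-adjusted trait variance.
#'
#' @param n_subjects number of unrelated subjects.
#' @param n_genes number of genes in the synthetic genome.
#' @param snps_per_gene scalar count, or length-2 range sampled per gene.
#' @param maf_range minor-allele-frequency range, within (0, 0.5]. The
#'   default (0.10, 0.50) keeps all variants common, in the MAF band
#'   typically retained after a 5% MAF filter.
#' @param gene_length_bp,intergenic_gap_bp gene interval length and the gap
#'   between consecutive genes, in base pairs.
#' @param n_pathways number of gene sets to draw.
#' @param pathway_size_range gene-set size range, within [10, 200]. Sizes
#'   default to 10-50 on the ~1000-gene synthetic universe, the same
#'   fraction of the universe as 10-200 sets on a genome-scale gene list.
#' @param causal_set_index index of the pathway whose genes carry trait
#'   effects, or `NA` for a complete-null cohort.
#' @param per_gene_h2 fraction of adjusted-trait variance explained by each
#'   causal gene (0 for no genetic effect).
#' @param covariate_effects named numeric vector of linear covariate slopes;
#'   names may be base columns (`age`, `sex`, `weight`, `height`), squares
#'   (`age2`), or products (`age_sex`).
#' @param noise_sd residual standard deviation of the trait.
#' @param missing_rate per-call missingness probability in [0, 1).
#' @param ld_rho probability of copying the previous SNP's genotype
#'   (within-chromosome); 0 = linkage equilibrium.
#' @param genes_per_chromosome genes placed per synthetic chromosome.
#' @param seed integer seed; all outputs are reproducible from it.
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_subjects = 500L,
                       n_genes = 1000L,
                       snps_per_gene = 2L,
                       maf_range = c(0.10, 0.50),
                       gene_length_bp = 20000L,
                       intergenic_gap_bp = 50000L,
                       n_pathways = 50L,
                       pathway_size_range = c(10L, 50L),
                       causal_set_index = NA_integer_,
                       per_gene_h2 = 0,
                       covariate_effects = c(age = -0.0015, sex = -0.09,
                                             weight = 0.0015),
                       noise_sd = 0.05,
                       missing_rate = 0.02,
                       ld_rho = 0,
                       genes_per_chromosome = 250L,
                       seed = 1L) {
  .assert(n_subjects >= 2, "n_subjects must be >= 2")
  .assert(n_genes >= 2, "n_genes must be >= 2")
  .assert(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
            maf_range[1] <= maf_range[2],
          "maf_range must be an increasing pair within (0, 0.5]")
  .assert(length(pathway_size_range) == 2 &&
            pathway_size_range[1] >= 10 && pathway_size_range[2] <= 200 &&
            pathway_size_range[1] <= pathway_size_range[2],
          "pathway_size_range must be an increasing pair within [10, 200]")
  .assert(pathway_size_range[2] <= n_genes,
          "pathway sizes cannot exceed the gene universe")
  .assert(per_gene_h2 >= 0 && per_gene_h2 < 1, "per_gene_h2 must be in [0, 1)")
  if (!is.na(causal_set_index)) {
    .assert(causal_set_index >= 1 && causal_set_index <= n_pathways,
            "causal_set_index out of range")
    .assert(pathway_size_range[2] * per_gene_h2 < 1,
            "heritability budget >= 1: max causal genes x per_gene_h2 must be < 1")
  }
  .assert(missing_rate >= 0 && missing_rate < 1, "missing_rate must be in [0, 1)")
  .assert(noise_sd > 0, "noise_sd must be positive")
  .assert(ld_rho >= 0 && ld_rho < 1, "ld_rho must be in [0, 1)")
  spg <- as.integer(snps_per_gene)
  .assert(length(spg) %in% 1:2 && all(spg >= 1), "snps_per_gene must be a count or range")
  .assert(max(spg) <= gene_length_bp,
          "infeasible geometry: more SNPs than positions in a gene")
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_genes = as.integer(n_genes),
              snps_per_gene = spg,
              maf_range = as.numeric(maf_range),
              gene_length_bp = as.integer(gene_length_bp),
              intergenic_gap_bp = as.integer(intergenic_gap_bp),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              causal_set_index = as.integer(causal_set_index),
              per_gene_h2 = as.numeric(per_gene_h2),
              covariate_effects = covariate_effects,
              noise_sd = as.numeric(noise_sd),
              missing_rate = as.numeric(missing_rate),
              ld_rho = as.numeric(ld_rho),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Construct a genotype matrix object
#'
#' Bundles additive dosage calls (subjects x SNPs, values 0/1/2/`NA`) with
#' per-SNP metadata (chromosome, 1-based position, alleles).
#'
#' @param calls numeric matrix, subjects in rows, SNPs in columns; dimnames
#'   give subject and SNP ids.
#' @param snp_meta data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, one row per column of `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snp_meta) {
  .assert(is.matrix(calls), "calls must be a matrix")
  .assert(nrow(snp_meta) == ncol(calls), "snp_meta rows must match calls columns")
  .assert(ncol(calls) == 0 || !is.null(colnames(calls)),
          "calls must have SNP column names")
  .assert(!anyDuplicated(colnames(calls)), "snp ids must be unique")
  cn <- colnames(calls)
  if (is.null(cn)) cn <- character(0)
  .assert(identical(as.character(snp_meta$snp_id), cn),
          "snp_meta$snp_id must match calls column names, in order")
  .assert(all(snp_meta$pos >= 1), "positions must be positive")
  ok <- calls %in% c(0, 1, 2) | is.na(calls)
  .assert(all(ok), "calls must be in {0, 1, 2, NA}")
  structure(list(calls = calls,
                 subject_ids = rownames(calls),
                 snp_ids = cn,
                 snp_meta = as.data.frame(snp_meta)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

# resolve derived covariate columns: "age2" -> age^2, "age_sex" -> age*sex
.term_column <- function(tab, term) {
  if (term %in% names(tab)) return(as.numeric(tab[[term]]))
  if (grepl("_", term, fixed = TRUE)) {
    parts <- strsplit(term, "_", fixed = TRUE)[[1]]
    cols <- lapply(parts, .term_column, tab = tab)
    return(Reduce(`*`, cols))
  }
  if (grepl("2$", term)) {
    base <- sub("2$", "", term)
    if (base %in% names(tab)) return(as.numeric(tab[[base]])^2)
  }
  stop(sprintf("cannot resolve covariate term '%s'", term), call. = FALSE)
}

#' Simulate a GWAS cohort with an embedded causal pathway
#'
#' Generates genotypes, phenotypes, gene coordinates, and gene sets with the
#' statistical structure the downstream pipeline assumes; see [sim_config()]
#' for the generative model. The `truth` element records the causal set,
#' the causal SNP chosen per causal gene, and the effect sizes actually used,
#' so recovery can be scored.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `genotypes` ([genotype_matrix()]), `phenotypes` (data.frame with
#'   `subject_id`, `trait`, `age`, `sex`, `weight`, `height`), `gene_map`
#'   (data.frame of 1-based inclusive gene intervals), `gene_sets`
#'   ([gene_set_collection()]), `truth`, and `config`.
#' @export
simulate_cohort <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_subjects
  ng <- config$n_genes

  ## gene layout: fixed spacing along synthetic chromosomes, 1-based inclusive
  chrom <- paste0("chr", (seq_len(ng) - 1L) %/% config$genes_per_chromosome + 1L)
  within <- (seq_len(ng) - 1L) %% config$genes_per_chromosome
  start <- config$intergenic_gap_bp + 1L +
    within * (config$gene_length_bp + config$intergenic_gap_bp)
  gene_map <- data.frame(gene_id = sprintf("G%04d", seq_len(ng)),
                         chrom = chrom,
                         start = start,
                         end = start + config$gene_length_bp - 1L,
                         strand = "+",
                         stringsAsFactors = FALSE)

  ## SNP placement within genes
  spg <- config$snps_per_gene
  k <- if (length(spg) == 2L) {
    sample(spg[1]:spg[2], ng, replace = TRUE)
  } else rep(spg, ng)
  snp_gene <- rep(seq_len(ng), k)
  offsets <- unlist(lapply(k, function(ki)
    sort(sample.int(config$gene_length_bp, ki))), use.names = FALSE)
  m <- length(snp_gene)
  snp_meta <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                         chrom = gene_map$chrom[snp_gene],
                         pos = gene_map$start[snp_gene] - 1L + offsets,
                         allele_a = "A",
                         allele_b = "B",
                         stringsAsFactors = FALSE)

  ## genotypes: HWE by construction, Binomial(2, MAF)
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  calls <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
  storage.mode(calls) <- "double"
  if (config$ld_rho > 0 && m > 1) {
    same_chr <- snp_meta$chrom[-1] == snp_meta$chrom[-m]
    for (j in which(same_chr) + 1L) {
      copy <- runif(n) < config$ld_rho
      calls[copy, j] <- calls[copy, j - 1L]
    }
  }
  dimnames(calls) <- list(sprintf("S%04d", seq_len(n)), snp_meta$snp_id)

  ## gene sets: overlapping draws from the gene universe
  sizes <- sample(config$pathway_size_range[1]:config$pathway_size_range[2],
                  config$n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(s) sort(sample(gene_map$gene_id, s)))
  names(sets) <- sprintf("SET_%03d", seq_len(config$n_pathways))
  gsc <- gene_set_collection(sets, description = rep("synthetic", length(sets)))

  ## covariates
  age <- runif(n, 20, 80)
  sex <- rbinom(n, 1L, 0.5)
  height <- rnorm(n, 170 - 10 * sex, 7)
  weight <- rnorm(n, 80 - 10 * sex, 12)
  pheno <- data.frame(subject_id = rownames(calls),
                      trait = NA_real_, age = age, sex = sex,
                      weight = weight, height = height,
                      stringsAsFactors = FALSE)
  eff <- config$covariate_effects
  cov_part <- 0
  for (term in names(eff)) cov_part <- cov_part + eff[[term]] * .term_column(pheno, term)

  ## causal genetic architecture: one causal SNP per causal gene
  truth <- list(causal_set = NA_character_, causal_genes = character(0),
                causal_snps = character(0), beta = numeric(0),
                per_gene_h2 = config$per_gene_h2,
                covariate_effects = as.list(eff),
                noise_sd = config$noise_sd,
                maf = setNames(maf, snp_meta$snp_id),
                seed = config$seed)
  genetic <- 0
  if (!is.na(config$causal_set_index) && config$per_gene_h2 > 0) {
    set_name <- names(sets)[config$causal_set_index]
    causal_genes <- sets[[set_name]]
    kg <- length(causal_genes)
    .assert(kg * config$per_gene_h2 < 1,
            "heritability budget >= 1 for the realized causal set size (%d genes)", kg)
    gidx <- match(causal_genes, gene_map$gene_id)
    causal_snps <- vapply(gidx, function(g) {
      cand <- which(snp_gene == g)
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    beta <- config$noise_sd *
      sqrt(config$per_gene_h2 / (1 - kg * config$per_gene_h2))
    for (s in causal_snps) {
      d <- calls[, s]
      z <- (d - mean(d)) / sd(d)
      genetic <- genetic + beta * z
    }
    truth$causal_set <- set_name
    truth$causal_genes <- causal_genes
    truth$causal_snps <- setNames(snp_meta$snp_id[causal_snps], causal_genes)
    truth$beta <- setNames(rep(beta, kg), causal_genes)
  }

  pheno$trait <- 0.5 + cov_part + genetic + rnorm(n, 0, config$noise_sd)

  ## missingness is measurement error, applied after trait construction
  if (config$missing_rate > 0) {
    calls[runif(n * m) < config$missing_rate] <- NA
  }

  structure(list(genotypes = genotype_matrix(calls, snp_meta),
                 phenotypes = pheno,
                 gene_map = gene_map,
                 gene_sets = gsc,
                 truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d subjects, %d genes, %d SNPs, ",
                     "%d gene sets\n"),
              nrow(x$genotypes$calls), nrow(x$gene_map),
              ncol(x$genotypes$calls), length(x$gene_sets$sets)))
  if (!is.na(x$truth$causal_set))
    cat(sprintf("  causal set: %s (%d genes, per-gene h2 = %g)\n",
                x$truth$causal_set, length(x$truth$causal_genes),
                x$truth$per_gene_h2))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `genotypes.tsv` (subject rows, SNP columns, calls 0/1/2/NA),
#' `snps.tsv` (SNP metadata), `phenotypes.tsv`, `genes.bed` (0-based
#' half-open), `pathways.gmt`, and `truth.json`. Optionally a PLINK
#' `.ped`/`.map` pair (white-space dialect, A/B alleles).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param plink also write `cohort.ped` / `cohort.map`.
#' @return Invisibly, the vector of files written.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir, plink = FALSE) {
  .assert(inherits(cohort, "synthetic_cohort"), "cohort must be a synthetic_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- cohort$genotypes
  gt <- data.frame(subject_id = g$subject_ids, g$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  files <- c(genotypes = file.path(dir, "genotypes.tsv"),
             snps = file.path(dir, "snps.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             genes = file.path(dir, "genes.bed"),
             sets = file.path(dir, "pathways.gmt"),
             truth = file.path(dir, "truth.json"))
  .write_tsv(gt, files["genotypes"])
  .write_tsv(g$snp_meta, files["snps"])
  .write_tsv(cohort$phenotypes, files["phenotypes"])
  bed <- data.frame(cohort$gene_map$chrom,
                    cohort$gene_map$start - 1L,  # BED is 0-based half-open
                    cohort$gene_map$end,
                    cohort$gene_map$gene_id,
                    0L,
                    cohort$gene_map$strand)
  write.table(bed, files["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_gmt(cohort$gene_sets, files["sets"])
  truth <- cohort$truth
  for (f in c("causal_snps", "beta", "maf")) {
    truth[[f]] <- as.list(truth[[f]])  # keep names in JSON
  }
  jsonlite::write_json(truth, files["truth"],
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (plink) {
    files <- c(files, ped = file.path(dir, "cohort.ped"),
               map = file.path(dir, "cohort.map"))
    .write_plink(cohort, file.path(dir, "cohort"))
  }
  invisible(files)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

.write_plink <- function(cohort, prefix) {
  g <- cohort$genotypes
  tr <- cohort$phenotypes$trait[match(g$subject_ids, cohort$phenotypes$subject_id)]
  al <- function(calls) {  # additive B-allele count -> allele pair
    out <- matrix("0", nrow(calls), 2 * ncol(calls))
    for (j in seq_len(ncol(calls))) {
      cj <- calls[, j]
      a <- ifelse(is.na(cj), "0", ifelse(cj >= 1, "B", "A"))
      b <- ifelse(is.na(cj), "0", ifelse(cj == 2, "B", "A"))
      out[, 2 * j - 1] <- a
      out[, 2 * j] <- b
    }
    out
  }
  ped <- cbind(g$subject_ids, g$subject_ids, "0", "0",
               cohort$phenotypes$sex + 1L, format(tr, digits = 17), al(g$calls))
  write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  mp <- data.frame(sub("^chr", "", g$snp_meta$chrom), g$snp_meta$snp_id,
                   0L, g$snp_meta$pos)
  write.table(mp, paste0(prefix, ".map"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the files written by [write_cohort()].
#' @return A `synthetic_cohort` (without the `config` element, which is not
#'   serialized; `truth` is restored from `truth.json`).
#' @export
read_cohort <- function(dir) {
  gt <- read.delim(file.path(dir, "genotypes.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  snp_meta <- read.delim(file.path(dir, "snps.tsv"), stringsAsFactors = FALSE)
  calls <- as.matrix(gt[, -1, drop = FALSE])
  rownames(calls) <- gt$subject_id
  storage.mode(calls) <- "double"
  pheno <- read.delim(file.path(dir, "phenotypes.tsv"), stringsAsFactors = FALSE)
  gene_map <- read_gene_bed(file.path(dir, "genes.bed"))
  gsc <- read_gmt(file.path(dir, "pathways.gmt"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  structure(list(genotypes = genotype_matrix(calls, snp_meta),
                 phenotypes = pheno,
                 gene_map = gene_map,
                 gene_sets = gsc,
                 truth = truth,
                 config = NULL),
            class = "synthetic_cohort")
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to the 1-based
#' inclusive convention used internally.
#'
#' @param path BED file (>= 4 columns: chrom, start, end, name; optional
#'   score and strand).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(bed) >= 4, "BED file needs at least 4 columns (chrom,start,end,name)")
  data.frame(gene_id = as.character(bed[[4]]),
             chrom = as.character(bed[[1]]),
             start = bed[[2]] + 1L,
             end = bed[[3]],
             strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "*",
             stringsAsFactors = FALSE)
}
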