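# Independent brute-force oracles used to pin the package's statistics.
# These deliberately avoid the implementation's code paths: explicit loops,
# lm() fits, and exhaustive counting.

# running-sum enrichment score: recompute each prefix sum from scratch
bf_enrichment_score <- function(r_sorted, member, p = 1) {
  N <- length(r_sorted)
  ns <- sum(member)
  nr <- sum(abs(r_sorted[member])^p)
  prefix <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(i)) {
      s <- s + if (member[j]) abs(r_sorted[j])^p / nr else -1 / (N - ns)
    }
    prefix[i] <- s
  }
  list(es = max(max(prefix), 0), prefix = prefix)
}

# simple-OLS Wald t via lm() on complete cases
bf_wald <- function(dosage, trait) {
  cc <- !is.na(dosage) & !is.na(trait)
  fit <- lm(trait[cc] ~ dosage[cc])
  sm <- summary(fit)$coefficients
  list(beta = sm[2, 1], se = sm[2, 2], t = sm[2, 3], p = sm[2, 4],
       n = sum(cc))
}

# nearest-gene scan with boundary-offset distances (0 inside a gene)
bf_snp_gene_distances <- function(pos, chrom, gene_map) {
  d <- rep(NA_real_, length(gene_map$gene_id))
  for (g in seq_along(gene_map$gene_id)) {
    if (gene_map$chrom[g] != chrom) next
    d[g] <- max(gene_map$start[g] - pos, pos - gene_map$end[g], 0)
  }
  d
}

# exhaustive-counting permutation FDR q and FWER p on a NES matrix
bf_fdr_q <- function(nes_obs, nes_null) {
  n_sets <- length(nes_obs)
  n_perm <- ncol(nes_null)
  q <- numeric(n_sets)
  for (s in seq_len(n_sets)) {
    num <- 0
    for (i in seq_len(nrow(nes_null))) {
      for (b in seq_len(n_perm)) {
        if (nes_null[i, b] >= nes_obs[s]) num <- num + 1
      }
    }
    den <- 0
    for (i in seq_len(n_sets)) if (nes_obs[i] >= nes_obs[s]) den <- den + 1
    q[s] <- min(1, (num / (nrow(nes_null) * n_perm)) / (den / n_sets))
  }
  q
}

bf_fwer_p <- function(nes_obs, nes_null) {
  n_perm <- ncol(nes_null)
  p <- numeric(length(nes_obs))
  for (s in seq_along(nes_obs)) {
    cnt <- 0
    for (b in seq_len(n_perm)) {
      if (max(nes_null[, b]) > nes_obs[s]) cnt <- cnt + 1
    }
    p[s] <- cnt / n_perm
  }
  p
}

# hand-rolled HWE chi-square from genotype counts
bf_hwe_chisq_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

# a ranked_gene_list from a named statistic vector
make_ranked <- function(r) {
  pathgwas::rank_genes(data.frame(gene_id = names(r), r = unname(r),
                                  stringsAsFactors = FALSE))
}

# tiny genotype_matrix with SNPs laid on one chromosome
make_geno <- function(calls, pos = NULL, chrom = "chr1") {
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("s%03d", seq_len(ncol(calls)))
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("I%03d", seq_len(nrow(calls)))
  }
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000L
  pathgwas::genotype_matrix(
    calls,
    data.frame(snp_id = colnames(calls), chrom = chrom, pos = pos,
               allele_a = "A", allele_b = "B", stringsAsFactors = FALSE))
}
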