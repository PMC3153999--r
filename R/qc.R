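#' Per-SNP call rate
#'
#' Fraction of subjects with a non-missing genotype call, per SNP.
#'
#' @param calls numeric vector of additive calls for one SNP, or a
#'   subjects x SNPs matrix.
#' @return A fraction in [0, 1] (vector of fractions for a matrix input).
#' @export
snp_call_rate <- function(calls) {
  if (is.matrix(calls)) {
    .assert(nrow(calls) >= 1, "empty genotype matrix")
    return(colMeans(!is.na(calls)))
  }
  .assert(length(calls) >= 1, "empty call vector")
  mean(!is.na(calls))
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson chi-square goodness-of-fit (1 df) of the observed genotype
#' counts against the HWE proportions `p^2 : 2pq : q^2` implied by the
#' observed allele frequency. Monomorphic SNPs return p = 1. A mid-p exact
#' test (enumeration of heterozygote counts conditional on the allele
#' count) is available as an alternative for small or unbalanced counts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectorized).
#' @param method `"chisq"` (default) or `"exact-midp"`.
#' @return HWE p value(s).
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact-midp")) {
  method <- match.arg(method)
  .assert(all(n_AA >= 0) && all(n_Aa >= 0) && all(n_aa >= 0),
          "genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  .assert(all(n > 0), "total genotype count must be positive")
  if (method == "exact-midp") {
    return(mapply(.hwe_exact_midp, n_AA, n_Aa, n_aa))
  }
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e_AA <- n * p^2
  e_Aa <- n * 2 * p * q
  e_aa <- n * q^2
  chi2 <- ifelse(p == 0 | q == 0, 0,
                 (n_AA - e_AA)^2 / e_AA +
                   (n_Aa - e_Aa)^2 / e_Aa +
                   (n_aa - e_aa)^2 / e_aa)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

# Exact HWE mid-p: enumerate heterozygote counts with the observed allele
# count; mid-p = P(config less probable than observed) + half P(equally
# probable, including the observed one).
.hwe_exact_midp <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- lfactorial(n) -
    lfactorial((nA - hets) / 2) - lfactorial(hets) - lfactorial((nB - hets) / 2) +
    hets * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  tol <- 1e-12
  less <- sum(pr[pr < p_obs * (1 - tol)])
  equal <- sum(pr[abs(pr - p_obs) <= p_obs * tol])
  min(1, less + 0.5 * equal)
}

#' Minor allele frequency
#'
#' Computed on non-missing calls only: `min(p, 1 - p)` where `p` is the
#' frequency of the counted allele.
#'
#' @param calls numeric vector of additive calls for one SNP, or a
#'   subjects x SNPs matrix.
#' @return A frequency in [0, 0.5] (vector for a matrix input; `NA` for
#'   all-missing columns).
#' @export
minor_allele_frequency <- function(calls) {
  if (is.matrix(calls)) {
    n <- colSums(!is.na(calls))
    p <- colSums(calls, na.rm = TRUE) / (2 * n)
    return(ifelse(n == 0, NA_real_, pmin(p, 1 - p)))
  }
  .assert(any(!is.na(calls)), "all calls missing")
  p <- sum(calls, na.rm = TRUE) / (2 * sum(!is.na(calls)))
  min(p, 1 - p)
}

#' QC thresholds
#'
#' Defaults follow common GWAS practice for array data: per-SNP call rate
#' >= 95%, HWE p >= 0.001, MAF >= 5%, and SNPs no more than 500 kb from the
#' nearest gene ("more than 500 kb away" is strictly greater than 500,000
#' bp from the nearest gene boundary; distance is 0 inside a gene).
#'
#' @param call_rate minimum per-SNP call rate.
#' @param hwe_p minimum HWE p value.
#' @param maf minimum minor allele frequency.
#' @param max_gene_distance_bp maximum distance to the nearest gene (bp);
#'   `NA` disables the distance filter.
#' @param hwe_exact use the mid-p exact HWE test instead of chi-square.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(call_rate = 0.95, hwe_p = 0.001, maf = 0.05,
                          max_gene_distance_bp = 500000, hwe_exact = FALSE) {
  structure(list(call_rate = call_rate, hwe_p = hwe_p, maf = maf,
                 max_gene_distance_bp = max_gene_distance_bp,
                 hwe_exact = isTRUE(hwe_exact)),
            class = "qc_thresholds")
}

#' Apply SNP-level quality control
#'
#' Filters are applied sequentially — call rate, then HWE, then MAF, then
#' gene distance — and each SNP is attributed to the first filter it fails,
#' so the per-step counts mirror how marker attrition is conventionally
#' reported. The retained matrix preserves column order.
#'
#' @param geno a [genotype_matrix()].
#' @param gene_map data.frame of gene intervals (`gene_id`, `chrom`,
#'   `start`, `end`), required when the distance filter is enabled.
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (class `qc_report`: input/step-failure/retained counts and
#'   the thresholds used).
#' @export
apply_qc <- function(geno, gene_map = NULL, thresholds = qc_thresholds()) {
  .assert(inherits(geno, "genotype_matrix"), "geno must be a genotype_matrix")
  calls <- geno$calls
  m <- ncol(calls)
  dist_on <- !is.na(thresholds$max_gene_distance_bp)
  .assert(!dist_on || (!is.null(gene_map) && nrow(gene_map) > 0),
          "gene_map required (and non-empty) when the distance filter is enabled")

  cr <- snp_call_rate(calls)
  fail_cr <- cr < thresholds$call_rate
  alive <- !fail_cr

  n0 <- colSums(calls == 0, na.rm = TRUE)
  n1 <- colSums(calls == 1, na.rm = TRUE)
  n2 <- colSums(calls == 2, na.rm = TRUE)
  hwe_p <- rep(NA_real_, m)
  idx <- which(alive & (n0 + n1 + n2) > 0)
  if (length(idx)) {
    hwe_p[idx] <- hwe_test(n0[idx], n1[idx], n2[idx],
                           method = if (thresholds$hwe_exact) "exact-midp" else "chisq")
  }
  fail_hwe <- alive & (is.na(hwe_p) | hwe_p < thresholds$hwe_p)
  alive <- alive & !fail_hwe

  maf <- minor_allele_frequency(calls)
  fail_maf <- alive & (is.na(maf) | maf < thresholds$maf)
  alive <- alive & !fail_maf

  if (dist_on) {
    d <- snp_gene_distance(geno$snp_meta, gene_map)
    fail_dist <- alive & (is.na(d) | d > thresholds$max_gene_distance_bp)
  } else {
    fail_dist <- rep(FALSE, m)
  }
  alive <- alive & !fail_dist

  keep <- which(alive)
  out <- genotype_matrix(calls[, keep, drop = FALSE],
                         geno$snp_meta[keep, , drop = FALSE])
  report <- structure(list(n_input = m,
                           n_fail_callrate = sum(fail_cr),
                           n_fail_hwe = sum(fail_hwe),
                           n_fail_maf = sum(fail_maf),
                           n_fail_distance = sum(fail_dist),
                           n_retained = length(keep),
                           thresholds = thresholds),
                      class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("SNP quality control: %d input\n",
                     "  failed call rate : %d\n",
                     "  failed HWE       : %d\n",
                     "  failed MAF       : %d\n",
                     "  failed distance  : %d\n",
                     "  retained         : %d\n"),
              x$n_input, x$n_fail_callrate, x$n_fail_hwe,
              x$n_fail_maf, x$n_fail_distance, x$n_retained))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(step = c("input", "call_rate", "hwe", "maf", "distance", "retained"),
             n = c(x$n_input, x$n_fail_callrate, x$n_fail_hwe,
                   x$n_fail_maf, x$n_fail_distance, x$n_retained),
             stringsAsFactors = FALSE)
}
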