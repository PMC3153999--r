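test_that("snp_call_rate counts non-missing fractions", {
  expect_equal(snp_call_rate(c(rep(1, 95), rep(NA, 5))), 0.95)
  expect_equal(snp_call_rate(rep(NA_real_, 10)), 0)
  expect_equal(snp_call_rate(rep(2, 10)), 1)
  m <- cbind(c(0, 1, NA, 2), c(NA, NA, NA, NA))
  expect_equal(unname(snp_call_rate(m)), c(0.75, 0))
})

test_that("HWE chi-square matches hand computation", {
  # exact HWE proportions: chi-square 0
  expect_equal(hwe_test(25, 50, 25), 1)
  # maximal heterozygote deficit
  expect_lt(hwe_test(50, 0, 50), 1e-10)
  # (30, 40, 30): allele freq 0.5, expected counts 25 / 50 / 25, chi2 = 4
  chi2 <- (30 - 25)^2 / 25 + (40 - 50)^2 / 50 + (30 - 25)^2 / 25
  expect_equal(chi2, 4)
  expect_equal(hwe_test(30, 40, 30), pchisq(chi2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # monomorphic SNPs are not flagged
  expect_equal(hwe_test(100, 0, 0), 1)
  expect_equal(hwe_test(0, 0, 100), 1)
  expect_error(hwe_test(-1, 5, 5), "non-negative")
})

test_that("HWE chi-square agrees with an independent oracle on random triples", {
  set.seed(42)
  for (i in 1:1000) {
    cnt <- as.vector(rmultinom(1, sample(10:500, 1), prob = runif(3)))
    expect_equal(hwe_test(cnt[1], cnt[2], cnt[3]),
                 bf_hwe_chisq_p(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-10)
  }
})

test_that("exact mid-p HWE test behaves sensibly", {
  # equilibrium counts: high p under both tests
  expect_gt(hwe_test(25, 50, 25, method = "exact-midp"), 0.5)
  # gross disequilibrium: tiny p
  expect_lt(hwe_test(50, 0, 50, method = "exact-midp"), 1e-10)
  # chi-square and exact agree to first order for large balanced counts
  p1 <- hwe_test(240, 520, 240)
  p2 <- hwe_test(240, 520, 240, method = "exact-midp")
  expect_equal(p1, p2, tolerance = 0.1)
})

test_that("minor allele frequency is computed on non-missing calls", {
  expect_equal(minor_allele_frequency(rep(0, 10)), 0)
  expect_equal(minor_allele_frequency(c(0, 1, 2, 0, 1, 2)), 0.5)
  expect_equal(minor_allele_frequency(c(2, 2, 2, NA, NA)), 0)
  expect_equal(minor_allele_frequency(c(0, 0, 2, NA)), 1 / 3)
  expect_error(minor_allele_frequency(c(NA_real_, NA_real_)), "missing")
})

test_that("apply_qc attributes each planted failure to the first filter it violates", {
  set.seed(1)
  n <- 200
  good <- function() rbinom(n, 2, 0.3)
  calls <- cbind(good(), good(), good(), good(), good(), good())
  # SNP 2: low call rate (and also low MAF -> must be attributed to call rate)
  calls[1:20, 2] <- NA
  calls[, 2][!is.na(calls[, 2])] <- 0
  calls[1, 2] <- 1
  # SNP 3: gross HWE violation (all heterozygotes)
  calls[, 3] <- 1
  # SNP 4: rare variant
  calls[, 4] <- c(rep(1, 4), rep(0, n - 4))
  geno <- make_geno(calls, pos = c(1500L, 2500L, 3500L, 4500L, 5500L, 700001L))
  # genes cover bp 1000-6000; SNP 6 sits 694001 bp past the gene end
  gene_map <- data.frame(gene_id = "g1", chrom = "chr1",
                         start = 1000L, end = 6000L, stringsAsFactors = FALSE)
  res <- apply_qc(geno, gene_map)
  rep <- res$report
  expect_equal(rep$n_input, 6)
  expect_equal(rep$n_fail_callrate, 1)
  expect_equal(rep$n_fail_hwe, 1)
  expect_equal(rep$n_fail_maf, 1)
  expect_equal(rep$n_fail_distance, 1)
  expect_equal(rep$n_retained, 2)
  expect_identical(res$genotypes$snp_ids, c("s001", "s005"))
  # brute-force re-check: each flagged SNP really violates its filter
  expect_lt(snp_call_rate(calls[, 2]), 0.95)
  expect_lt(hwe_test(sum(calls[, 3] == 0), sum(calls[, 3] == 1),
                     sum(calls[, 3] == 2)), 0.001)
  expect_lt(minor_allele_frequency(calls[, 4]), 0.05)
  expect_gt(bf_snp_gene_distances(700001, "chr1", gene_map)[1], 500000)
})

test_that("the 500 kb distance rule is strict", {
  set.seed(2)
  calls <- matrix(rbinom(400, 2, 0.4), nrow = 200)
  gene_map <- data.frame(gene_id = "g1", chrom = "chr1",
                         start = 1000L, end = 2000L, stringsAsFactors = FALSE)
  # SNP at exactly 500,000 bp beyond the gene end is kept; 500,001 is not
  geno <- make_geno(calls, pos = c(2000L + 500000L, 2000L + 500001L))
  res <- apply_qc(geno, gene_map)
  expect_equal(res$report$n_fail_distance, 1)
  expect_identical(res$genotypes$snp_ids, "s001")
})

test_that("apply_qc is idempotent and its accounting balances", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(50:150, 1)
    m <- sample(5:25, 1)
    maf <- runif(m, 0.01, 0.5)
    calls <- sapply(maf, function(p) rbinom(n, 2, p))
    calls[runif(n * m) < 0.08] <- NA
    geno <- make_geno(calls)
    gene_map <- data.frame(gene_id = "g1", chrom = "chr1", start = 1L,
                           end = max(geno$snp_meta$pos) + 10L,
                           stringsAsFactors = FALSE)
    res <- apply_qc(geno, gene_map)
    rep <- res$report
    expect_equal(rep$n_retained,
                 rep$n_input - rep$n_fail_callrate - rep$n_fail_hwe -
                   rep$n_fail_maf - rep$n_fail_distance)
    again <- apply_qc(res$genotypes, gene_map)
    expect_identical(again$genotypes$calls, res$genotypes$calls)
    expect_equal(again$report$n_retained, again$report$n_input)
  }
})
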