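genes3 <- data.frame(
  gene_id = c("gA", "gB", "gC"),
  chrom = c("chr1", "chr1", "chr2"),
  start = c(100L, 250L, 1000L),
  end = c(200L, 400L, 2000L),
  stringsAsFactors = FALSE)

snp_row <- function(id, chrom, pos) {
  data.frame(snp_id = id, chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

test_that("a SNP inside one gene maps to it at distance 0", {
  m <- map_snps_to_genes(snp_row("s1", "chr1", 150), genes3)
  expect_identical(m$gene_id, "gA")
  expect_equal(m$distance, 0)
})

test_that("a SNP in the shared region of overlapping genes maps to both", {
  ov <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                   start = c(100L, 250L), end = c(300L, 400L),
                   stringsAsFactors = FALSE)
  m <- map_snps_to_genes(snp_row("s1", "chr1", 260), ov)
  expect_setequal(m$gene_id, c("g1", "g2"))
  expect_equal(m$distance, c(0, 0))
})

test_that("outside SNPs map to the closest gene; exact ties go to all", {
  # gA ends at 200, gB starts at 250: SNP at 210 is 10 bp from gA, 40 from gB
  m <- map_snps_to_genes(snp_row("s1", "chr1", 210), genes3)
  expect_identical(m$gene_id, "gA")
  expect_equal(m$distance, 10)
  # equidistant: 1000 bp beyond gB end (1400) vs 1000 before a gene at 2400
  tie <- data.frame(gene_id = c("gL", "gR"), chrom = "chr1",
                    start = c(100L, 2400L), end = c(400L, 2600L),
                    stringsAsFactors = FALSE)
  m2 <- map_snps_to_genes(snp_row("s1", "chr1", 1400), tie)
  expect_setequal(m2$gene_id, c("gL", "gR"))
  expect_equal(m2$distance, c(1000, 1000))
})

test_that("window and chromosome rules unmap distant SNPs", {
  one <- data.frame(gene_id = "gA", chrom = "chr1", start = 100L, end = 200L,
                    stringsAsFactors = FALSE)
  meta <- rbind(snp_row("far", "chr1", 200 + 500001),
                snp_row("edge", "chr1", 200 + 500000),
                snp_row("wrongchr", "chr9", 150))
  m <- map_snps_to_genes(meta, one)
  expect_false("far" %in% m$snp_id)
  expect_true("edge" %in% m$snp_id)
  expect_false("wrongchr" %in% m$snp_id)
})

test_that("mapping agrees with a brute-force nearest-gene scan on random layouts", {
  set.seed(30)
  for (rep in 1:25) {
    ngen <- sample(3:8, 1)
    starts <- sort(sample.int(50000, ngen))
    gm <- data.frame(gene_id = sprintf("g%02d", seq_len(ngen)),
                     chrom = sample(c("chr1", "chr2"), ngen, replace = TRUE),
                     start = starts,
                     end = starts + sample(500:5000, ngen, replace = TRUE),
                     stringsAsFactors = FALSE)
    meta <- data.frame(snp_id = sprintf("s%02d", 1:15),
                       chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
                       pos = sample.int(60000, 15),
                       stringsAsFactors = FALSE)
    window <- 3000
    m <- map_snps_to_genes(meta, gm, window = window)
    for (i in seq_len(nrow(meta))) {
      d <- bf_snp_gene_distances(meta$pos[i], meta$chrom[i], gm)
      got <- m[m$snp_id == meta$snp_id[i], ]
      if (all(is.na(d)) || min(d, na.rm = TRUE) > window) {
        expect_equal(nrow(got), 0)
      } else if (any(d == 0, na.rm = TRUE)) {
        expect_setequal(got$gene_id, gm$gene_id[which(d == 0)])
        expect_true(all(got$distance == 0))
      } else {
        expect_setequal(got$gene_id, gm$gene_id[which(d == min(d, na.rm = TRUE))])
        expect_true(all(got$distance == min(d, na.rm = TRUE)))
      }
    }
  }
})

test_that("gene statistics take the best SNP and respect shared SNPs", {
  mapping <- data.frame(snp_id = c("s1", "s2", "s3", "s3"),
                        gene_id = c("gA", "gA", "gA", "gB"),
                        distance = 0, stringsAsFactors = FALSE)
  sr <- data.frame(snp_id = c("s1", "s2", "s3"),
                   statistic = c(1.2, -3.4, 0.5),
                   p_value = c(0.2, 0.001, 0.6),
                   stringsAsFactors = FALSE)
  gs <- gene_statistics(mapping, sr)
  expect_equal(gs$r[gs$gene_id == "gA"], 3.4)
  expect_identical(gs$best_snp[gs$gene_id == "gA"], "s2")
  expect_equal(gs$n_snps[gs$gene_id == "gA"], 3L)
  # the shared SNP contributes to both genes
  expect_equal(gs$r[gs$gene_id == "gB"], 0.5)
  # permutation invariance to input order
  gs2 <- gene_statistics(mapping[c(3, 1, 4, 2), ], sr[c(2, 3, 1), ])
  expect_identical(gs2, gs)
  # adding a weaker SNP never changes the representative statistic
  mapping3 <- rbind(mapping, data.frame(snp_id = "s4", gene_id = "gA",
                                        distance = 0))
  sr3 <- rbind(sr, data.frame(snp_id = "s4", statistic = 0.1, p_value = 0.9))
  gs3 <- gene_statistics(mapping3, sr3)
  expect_equal(gs3$r[gs3$gene_id == "gA"], 3.4)
  # SNPs with unusable statistics are dropped
  sr$statistic[2] <- NA
  gs4 <- gene_statistics(mapping, sr)
  expect_equal(gs4$r[gs4$gene_id == "gA"], 1.2)
})
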