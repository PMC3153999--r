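test_that("rank_genes sorts descending with deterministic ties", {
  gs <- data.frame(gene_id = c("a", "b", "c"), r = c(1, 3, 2))
  expect_identical(rank_genes(gs)$gene_id, c("b", "c", "a"))
  ties <- data.frame(gene_id = c("z", "m", "a"), r = c(1, 1, 1))
  expect_identical(rank_genes(ties)$gene_id, c("a", "m", "z"))
  rr <- rank_genes(gs)
  expect_identical(rank_genes(rr)$gene_id, rr$gene_id)
  expect_error(rank_genes(data.frame(gene_id = c("a", "a"), r = 1:2)),
               "duplicate")
})

test_that("enrichment score identities hold", {
  ranked <- make_ranked(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))
  # single top gene: running sum hits 1 immediately
  top <- enrichment_score(ranked, "g1")
  expect_equal(top$es, 1)
  expect_equal(top$peak_index, 1L)
  # contiguous top block: all increments precede any decrement
  blk <- enrichment_score(ranked, c("g1", "g2", "g3"))
  expect_equal(blk$es, 1)
  expect_identical(blk$leading_edge, c("g1", "g2", "g3"))
  # walk always returns to zero
  expect_equal(blk$running_sum[5], 0, tolerance = 1e-12)
  expect_error(enrichment_score(ranked, character(0)), "no genes")
  expect_error(enrichment_score(ranked, paste0("g", 1:5)), "whole")
})

test_that("the worked 5-gene example matches hand-enumerated prefix sums", {
  ranked <- make_ranked(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))
  res <- enrichment_score(ranked, c("g1", "g3"), weight_exponent = 1)
  # N_R = 5 + 3 = 8; decrement 1/3
  expect_equal(res$running_sum,
               c(5 / 8, 5 / 8 - 1 / 3, 5 / 8 - 1 / 3 + 3 / 8,
                 5 / 8 + 3 / 8 - 2 / 3, 0),
               tolerance = 1e-12)
  expect_equal(res$es, 2 / 3, tolerance = 1e-12)
  expect_equal(res$peak_index, 3L)
  expect_setequal(res$leading_edge, c("g1", "g3"))
})

test_that("enrichment_score agrees with the brute-force oracle on random instances", {
  set.seed(50)
  for (i in 1:300) {
    N <- sample(8:60, 1)
    r <- sort(abs(rnorm(N, 0, 2)), decreasing = TRUE)
    names(r) <- sprintf("g%03d", seq_len(N))
    ns <- sample(1:(N - 1), 1)
    members <- sample(names(r), ns)
    p <- sample(c(0, 1, 2), 1)
    ranked <- make_ranked(r)
    res <- enrichment_score(ranked, members, weight_exponent = p)
    oracle <- bf_enrichment_score(unname(r), names(r) %in% members, p)
    expect_lt(abs(res$es - oracle$es), 1e-12)
    expect_lt(max(abs(res$running_sum - oracle$prefix)), 1e-12)
    # structural identities on every fuzzed instance
    expect_gte(res$es, 0)
    expect_lte(res$es, 1 + 1e-12)
    expect_lt(abs(res$running_sum[N]), 1e-9)
  }
})

test_that("enrichment_score matches fgsea's positive-score statistic", {
  skip_if_not_installed("fgsea")
  set.seed(51)
  for (i in 1:50) {
    N <- sample(20:100, 1)
    r <- sort(abs(rnorm(N)), decreasing = TRUE)
    names(r) <- sprintf("g%03d", seq_len(N))
    members <- sample(names(r), sample(3:10, 1))
    mine <- enrichment_score(make_ranked(r), members)$es
    ref <- fgsea::calcGseaStat(unname(r), selectedStats = which(names(r) %in% members),
                               gseaParam = 1, scoreType = "pos")
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("nominal p counts strict exceedances and reports the bound", {
  null <- seq(0.1, 0.9, length.out = 1000)
  top <- nominal_p(0.95, null)
  expect_equal(top$p, 0)
  expect_identical(top$label, "< 0.001")
  bottom <- nominal_p(0.05, null)
  expect_equal(bottom$p, 1)
  mid <- nominal_p(median(null) + 1e-9, null)
  expect_equal(mid$p, 0.5, tolerance = 1 / 1000 + 1e-9)
})

test_that("score normalization uses the population-SD null convention", {
  null <- matrix(c(0, 2), nrow = 1)  # mean 1, population SD 1
  nrm <- normalize_scores(null, es_obs = c(set1 = 3))
  expect_equal(unname(nrm$nes_obs), 2)
  expect_equal(unname(nrm$null_sd), 1)
  # observed equal to the null mean gives NES 0
  expect_equal(unname(normalize_scores(null, es_obs = c(s = 1))$nes_obs), 0)
  # permuted NES rows are standardized by construction
  set.seed(52)
  big <- matrix(runif(5 * 400), nrow = 5,
                dimnames = list(paste0("s", 1:5), NULL))
  nrm2 <- normalize_scores(big, es_obs = setNames(runif(5), paste0("s", 1:5)))
  expect_equal(unname(rowMeans(nrm2$nes_null)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(sqrt(rowMeans(nrm2$nes_null^2))), rep(1, 5),
               tolerance = 1e-10)
  # degenerate null SD is flagged
  degen <- rbind(s1 = rep(0.5, 10), s2 = runif(10))
  expect_warning(out <- normalize_scores(degen, es_obs = c(s1 = 1, s2 = 1)),
                 "zero null SD")
  expect_true(is.na(out$nes_obs[["s1"]]))
})

test_that("FDR q and FWER p match exhaustive counting on toy matrices", {
  nes_null <- rbind(sA = c(1.0, -0.5, 0.2, 0.8),
                    sB = c(0.3, 1.4, -1.0, 0.1),
                    sC = c(-0.2, 0.6, 0.9, -0.3))
  nes_obs <- c(sA = 1.2, sB = 0.25, sC = -0.1)
  expect_equal(unname(fdr_q(nes_obs, nes_null)),
               bf_fdr_q(nes_obs, nes_null), tolerance = 1e-12)
  expect_equal(unname(fwer_p(nes_obs, nes_null)),
               bf_fwer_p(nes_obs, nes_null), tolerance = 1e-12)
  # randomized toys
  set.seed(53)
  for (i in 1:50) {
    nn <- matrix(rnorm(12), nrow = 3,
                 dimnames = list(c("sA", "sB", "sC"), NULL))
    no <- setNames(rnorm(3), c("sA", "sB", "sC"))
    expect_equal(unname(fdr_q(no, nn)), bf_fdr_q(no, nn), tolerance = 1e-12)
    expect_equal(unname(fwer_p(no, nn)), bf_fwer_p(no, nn), tolerance = 1e-12)
  }
  # boundary identities
  hi <- setNames(c(10, 0), c("sA", "sB"))
  nn <- matrix(rnorm(20), nrow = 2, dimnames = list(c("sA", "sB"), NULL))
  expect_equal(unname(fdr_q(hi, nn))[1], 0)
  expect_equal(unname(fwer_p(hi, nn))[1], 0)
  lo <- setNames(c(-10, 0), c("sA", "sB"))
  expect_equal(unname(fwer_p(lo, nn))[1], 1)
})

test_that("the joint significance call requires both criteria", {
  res <- data.frame(q_fdr = c(0.043, 0.04, 0.05, 0.06),
                    p_fwer = c(0.016, 0.06, 0.05, 0.04))
  out <- call_significance(res)
  expect_identical(out$significant, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("leading-edge overlap intersects the two runs", {
  a <- data.frame(set_name = "S", leading_edge = "g1;g2;g3;g4",
                  stringsAsFactors = FALSE)
  b <- data.frame(set_name = "S", leading_edge = "g3;g4;g5",
                  stringsAsFactors = FALSE)
  expect_setequal(leading_edge_overlap(a, b, "S"), c("g3", "g4"))
  expect_setequal(leading_edge_overlap(a, a, "S"), c("g1", "g2", "g3", "g4"))
  disj <- data.frame(set_name = "S", leading_edge = "x1;x2",
                     stringsAsFactors = FALSE)
  expect_length(leading_edge_overlap(a, disj, "S"), 0)
  expect_error(leading_edge_overlap(a, b, "missing"), "absent")
})

test_that("statistic-mode nulls are seed-reproducible and size-exchangeable", {
  set.seed(54)
  gs <- data.frame(gene_id = sprintf("g%03d", 1:120),
                   r = abs(rnorm(120)), stringsAsFactors = FALSE)
  sets <- list(A = sample(gs$gene_id, 15), B = sample(gs$gene_id, 15),
               C = sample(gs$gene_id, 40))
  n1 <- null_es_statistic(gs, sets, n_perm = 100, seed = 9)
  n2 <- null_es_statistic(gs, sets, n_perm = 100, seed = 9)
  expect_identical(n1$es_null, n2$es_null)
  # null ES for a set depends only on its size: same-size sets have
  # indistinguishable null distributions
  n3 <- null_es_statistic(gs, sets, n_perm = 600, seed = 10)
  expect_gt(suppressWarnings(
    ks.test(n3$es_null["A", ], n3$es_null["B", ]))$p.value, 0.01)
  expect_lt(abs(mean(n3$es_null["A", ]) - mean(n3$es_null["B", ])), 0.05)
})

test_that("phenotype-mode nulls reproduce from seed and match the observed chain", {
  cfg <- sim_config(n_subjects = 120, n_genes = 80, n_pathways = 8,
                    pathway_size_range = c(10, 20), seed = 55)
  co <- simulate_cohort(cfg)
  adj <- suppressWarnings(adjust_trait(co$phenotypes, c("age", "sex", "weight")))
  mapping <- map_snps_to_genes(co$genotypes$snp_meta, co$gene_map)
  n1 <- null_es_phenotype(co$genotypes, adj, mapping, co$gene_sets,
                          n_perm = 30, seed = 8)
  n2 <- null_es_phenotype(co$genotypes, adj, mapping, co$gene_sets,
                          n_perm = 30, seed = 8)
  expect_identical(n1$es_null, n2$es_null)
  # engine's observed ES equals the user-facing enrichment_score chain
  sr <- snp_association(co$genotypes, adj)
  gstats <- gene_statistics(mapping, sr)
  ranked <- rank_genes(gstats)
  for (nm in rownames(n1$es_null)) {
    expect_equal(n1$es_obs[[nm]],
                 enrichment_score(ranked, co$gene_sets$sets[[nm]])$es,
                 tolerance = 1e-12)
  }
})

test_that("pathway_enrichment composes the statistics coherently", {
  set.seed(56)
  gs <- data.frame(gene_id = sprintf("g%03d", 1:150),
                   r = abs(rnorm(150)), stringsAsFactors = FALSE)
  # plant a strong set at the top of the ranking
  top_genes <- rank_genes(gs)$gene_id[1:12]
  sets <- list(TOP = top_genes, R1 = sample(gs$gene_id, 20),
               R2 = sample(gs$gene_id, 30), R3 = sample(gs$gene_id, 15))
  res <- pathway_enrichment(gs, sets, mode = "statistic", n_perm = 200,
                            seed = 57)
  expect_s3_class(res, "pathway_result")
  expect_identical(res$set_name[1], "TOP")
  expect_equal(res$es[res$set_name == "TOP"], 1, tolerance = 1e-12)
  expect_true(res$significant[res$set_name == "TOP"])
  expect_true(all(res$q_fdr >= 0 & res$q_fdr <= 1, na.rm = TRUE))
  expect_true(all(res$p_fwer >= 0 & res$p_fwer <= 1, na.rm = TRUE))
  # NES/nominal consistency with the attached null object
  null <- attr(res, "null")
  i <- match("R1", res$set_name)
  expect_equal(res$p_nominal[i],
               mean(null$es_null["R1", ] > null$es_obs[["R1"]]))
})
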