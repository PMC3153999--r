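## Weighted Kolmogorov-Smirnov running-sum enrichment for ranked gene
## statistics, with permutation null distributions, normalized enrichment
## scores, and permutation-based FDR/FWER control.
##
## With genes ranked r_(1) >= ... >= r_(N) and a set S of N_S genes, the
## walk adds r_(i)^p / N_R at a member (N_R = sum of member r^p) and
## subtracts 1/(N - N_S) at a non-member; since increments and decrements
## each total 1 the walk ends at 0, and ES — the maximum deviation, taken
## as the positive maximum because the statistic scans for
## over-representation at the top — lies in [0, 1].

#' Rank genes by their representative statistics
#'
#' Descending by `r`; ties are broken by gene id lexicographic order so the
#' ranking is deterministic.
#'
#' @param gene_stats data.frame from [gene_statistics()] (needs `gene_id`
#'   and `r`).
#' @return An object of class `ranked_gene_list`: data.frame `gene_id`,
#'   `r`, ordered.
#' @export
rank_genes <- function(gene_stats) {
  .assert(nrow(gene_stats) >= 2, "need at least 2 genes")
  .assert(!anyDuplicated(gene_stats$gene_id), "duplicate gene ids")
  ord <- order(-gene_stats$r, gene_stats$gene_id)
  out <- data.frame(gene_id = as.character(gene_stats$gene_id[ord]),
                    r = as.numeric(gene_stats$r[ord]),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

# ES from sorted member positions; w = unnormalized member weights (r^p at
# those positions). Peaks occur immediately after a member is added, and
# the walk ends at 0, so the positive running-sum maximum is
# max(peak values, 0).
.es_from_positions <- function(pos, w, N) {
  ns <- length(pos)
  nr <- sum(w)
  w <- if (nr > 0) w / nr else rep.int(1 / ns, ns)
  peaks <- cumsum(w) - (pos - seq_len(ns)) / (N - ns)
  mx <- max(peaks)
  if (mx > 0) mx else 0
}

#' Weighted KS enrichment score for one gene set
#'
#' Walks down the ranked gene list, increasing the running sum at members
#' of `set_genes` (by `r^weight_exponent`, normalized to total 1) and
#' decreasing it at non-members (by `1/(N - N_S)`). Returns the full
#' running-sum trace, the enrichment score (maximum positive deviation),
#' and the leading-edge subset: the members ranked at or before the peak.
#'
#' @param ranked a [rank_genes()] result.
#' @param set_genes character vector of member gene ids (restricted to the
#'   ranked universe; must leave at least one member and at least one
#'   non-member).
#' @param weight_exponent weight on the gene statistic (default 1; 0 gives
#'   the unweighted KS statistic).
#' @return An object of class `enrichment_result`: list with `es`,
#'   `running_sum` (length-N trace), `peak_index`, `leading_edge`,
#'   `size` (members in the universe).
#' @export
enrichment_score <- function(ranked, set_genes, weight_exponent = 1) {
  .assert(inherits(ranked, "ranked_gene_list"), "ranked must be a ranked_gene_list")
  .assert(weight_exponent >= 0, "weight_exponent must be non-negative")
  gid <- ranked$gene_id
  N <- length(gid)
  mem <- gid %in% set_genes
  ns <- sum(mem)
  .assert(ns >= 1, "set has no genes in the ranked list")
  .assert(ns < N, "set covers the whole ranked list")
  w <- abs(ranked$r)^weight_exponent
  nr <- sum(w[mem])
  step <- numeric(N)
  step[mem] <- if (nr > 0) w[mem] / nr else 1 / ns
  step[!mem] <- -1 / (N - ns)
  rs <- cumsum(step)
  mx <- max(rs)
  if (mx > 0) {
    peak <- which.max(rs)
    es <- mx
  } else {
    peak <- N
    es <- 0
  }
  structure(list(es = es,
                 running_sum = rs,
                 peak_index = peak,
                 leading_edge = gid[seq_len(peak)][mem[seq_len(peak)]],
                 size = ns),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: ES = %.4f at rank %d; %d/%d members in leading edge\n",
              x$es, x$peak_index, length(x$leading_edge), x$size))
  invisible(x)
}

# shared set-up: universe (sorted gene ids), member index list, checks
.prep_sets <- function(gene_ids, sets) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  .assert(is.list(sets) && !is.null(names(sets)), "sets must be named")
  mi <- lapply(sets, function(s) which(gene_ids %in% s))
  usable <- lengths(mi) >= 1 & lengths(mi) < length(gene_ids)
  if (any(!usable)) {
    warning(sprintf("dropping %d set(s) with no members or full coverage in the universe",
                    sum(!usable)), call. = FALSE)
  }
  mi[usable]
}

.new_null_distributions <- function(es_null, es_obs, mode, n_perm, weight_exponent) {
  structure(list(es_null = es_null, es_obs = es_obs, mode = mode,
                 n_perm = n_perm, weight_exponent = weight_exponent),
            class = "null_distributions")
}

#' @export
print.null_distributions <- function(x, ...) {
  cat(sprintf("null_distributions (%s mode): %d sets x %d permutations\n",
              x$mode, nrow(x$es_null), x$n_perm))
  invisible(x)
}

#' Statistic-shuffling permutation null
#'
#' Each permutation randomly reassigns the observed vector of gene
#' statistics to gene labels and recomputes every set's enrichment score.
#' Because only gene labels move, this mode is valid when phenotypes are
#' not exchangeable across subjects (e.g. family samples whose per-SNP
#' statistics were computed by a family-based test). One label permutation
#' per iteration is shared by all sets, so the joint null across sets is
#' preserved for FDR/FWER pooling.
#'
#' @param gene_stats data.frame with `gene_id` and `r` (from
#'   [gene_statistics()] or external).
#' @param sets a [gene_set_collection()] or named list of member vectors.
#' @param n_perm number of permutations (default 1000).
#' @param weight_exponent weight on the gene statistic (default 1).
#' @param seed integer seed for reproducibility.
#' @return An object of class `null_distributions`: `es_null`
#'   (sets x permutations matrix), `es_obs` (named observed ES), `mode`,
#'   `n_perm`, `weight_exponent`.
#' @export
null_es_statistic <- function(gene_stats, sets, n_perm = 1000,
                              weight_exponent = 1, seed = NULL) {
  .assert(n_perm >= 1, "n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- sort(as.character(gene_stats$gene_id))
  r <- gene_stats$r[match(gene_ids, gene_stats$gene_id)]
  N <- length(gene_ids)
  mi <- .prep_sets(gene_ids, sets)
  .assert(length(mi) > 0, "no usable sets")
  ranked <- rank_genes(gene_stats)
  s_sorted <- abs(ranked$r)
  es_obs <- vapply(names(mi), function(nm) {
    enrichment_score(ranked, gene_ids[mi[[nm]]], weight_exponent)$es
  }, 0)
  es_null <- matrix(NA_real_, length(mi), n_perm,
                    dimnames = list(names(mi), NULL))
  for (b in seq_len(n_perm)) {
    rk <- sample.int(N)  # random gene -> rank bijection
    for (s in seq_along(mi)) {
      pos <- sort.int(rk[mi[[s]]])
      es_null[s, b] <- .es_from_positions(pos, s_sorted[pos]^weight_exponent, N)
    }
  }
  .new_null_distributions(es_null, es_obs, "statistic", n_perm, weight_exponent)
}

#' Phenotype-shuffling permutation null
#'
#' Each permutation shuffles the adjusted trait residuals across subjects
#' (covariate adjustment is not redone: residuals are exchangeable under
#' the null of no genotype effect) and recomputes the full chain — per-SNP
#' Wald scan, best-SNP gene statistics, genome-wide ranking, and every
#' set's enrichment score.
#'
#' @param geno a QC'd [genotype_matrix()].
#' @param adjusted an [adjust_trait()] result (or data.frame with
#'   `subject_id`, `residual`).
#' @param mapping data.frame from [map_snps_to_genes()].
#' @param sets a [gene_set_collection()] or named list.
#' @param n_perm number of permutations (default 1000).
#' @param weight_exponent weight on the gene statistic (default 1).
#' @param seed integer seed.
#' @return An object of class `null_distributions` (see
#'   [null_es_statistic()]).
#' @export
null_es_phenotype <- function(geno, adjusted, mapping, sets, n_perm = 1000,
                              weight_exponent = 1, seed = NULL) {
  .assert(n_perm >= 1, "n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- match(geno$subject_ids, adjusted$subject_id)
  .assert(!anyNA(idx), "all genotyped subjects must have an adjusted trait value")
  y0 <- as.numeric(adjusted$residual[idx])
  eng <- .perm_engine(geno, mapping, sets)

  obs <- .gene_max_abs(eng, .assoc_scan(eng$pre, y0)$t)
  es_obs <- .perm_all_es(eng, obs, weight_exponent)
  es_null <- matrix(NA_real_, length(eng$mi), n_perm,
                    dimnames = list(names(eng$mi), NULL))
  # permutations are processed in blocks so the Wald scans run as one
  # matrix product per block
  block <- 128L
  done <- 0L
  while (done < n_perm) {
    bs <- min(block, n_perm - done)
    Y <- vapply(seq_len(bs), function(b) sample(y0), y0)
    tmat <- .assoc_scan_batch(eng$pre, Y)
    for (j in seq_len(bs)) {
      r <- .gene_max_abs(eng, tmat[, j])
      es_null[, done + j] <- .perm_all_es(eng, r, weight_exponent)
    }
    done <- done + bs
  }
  .new_null_distributions(es_null, es_obs, "phenotype", n_perm, weight_exponent)
}

# Precompute everything reusable across permutations: association masks,
# usable SNPs, gene grouping (padded index matrix for vectorized per-gene
# maxima), and member indices in the fixed gene universe.
.perm_engine <- function(geno, mapping, sets) {
  pre <- .assoc_precompute(geno$calls)
  usable_snp <- which(pre$ok)
  .assert(length(usable_snp) > 0, "no usable SNPs")
  pre$X <- pre$X[, usable_snp, drop = FALSE]
  if (!is.null(pre$M)) pre$M <- pre$M[, usable_snp, drop = FALSE]
  pre$n <- pre$n[usable_snp]
  pre$Sx <- pre$Sx[usable_snp]
  pre$Sxx <- pre$Sxx[usable_snp]
  pre$ssx <- pre$ssx[usable_snp]
  pre$ok <- pre$ok[usable_snp]

  snp_ids <- geno$snp_ids[usable_snp]
  map <- mapping[mapping$snp_id %in% snp_ids, , drop = FALSE]
  .assert(nrow(map) > 0, "mapping contains no usable SNPs")
  map$col <- match(map$snp_id, snp_ids)
  gene_ids <- sort(unique(map$gene_id))
  map$g <- match(map$gene_id, gene_ids)
  # pad per-gene SNP-column lists into a matrix for pmax-based maxima
  by_gene <- split(map$col, map$g)
  kmax <- max(lengths(by_gene))
  idxmat <- matrix(length(snp_ids) + 1L, length(gene_ids), kmax)
  for (g in seq_along(by_gene)) {
    idxmat[g, seq_along(by_gene[[g]])] <- by_gene[[g]]
  }
  mi <- .prep_sets(gene_ids, sets)
  .assert(length(mi) > 0, "no usable sets")
  list(pre = pre, idxmat = idxmat, kmax = kmax,
       gene_ids = gene_ids, N = length(gene_ids), mi = mi)
}

# per-gene max |t| from a vector of per-SNP statistics
.gene_max_abs <- function(eng, t) {
  a <- c(abs(t), -Inf)  # sentinel for padding
  r <- a[eng$idxmat[, 1]]
  if (eng$kmax > 1) {
    for (k in 2:eng$kmax) r <- pmax(r, a[eng$idxmat[, k]])
  }
  r
}

# ES for every set given per-gene statistics (universe order = gene_ids)
.perm_all_es <- function(eng, r, weight_exponent) {
  ord <- order(-r, eng$gene_ids)
  ro <- integer(eng$N)
  ro[ord] <- seq_len(eng$N)
  s_sorted <- r[ord]
  vapply(eng$mi, function(idx) {
    pos <- sort.int(ro[idx])
    .es_from_positions(pos, s_sorted[pos]^weight_exponent, eng$N)
  }, 0)
}

#' Nominal permutation p value
#'
#' Fraction of permutations whose null enrichment score is strictly
#' greater than the observed one. When no permutation exceeds the observed
#' score the value is 0 and the label reports the resolution bound
#' `"< 1/n_perm"`.
#'
#' @param observed observed ES (scalar).
#' @param null_es numeric vector of permuted ES for the same set.
#' @return list with `p` (numeric), `n_exceed`, and `label` (character
#'   probability statement).
#' @export
nominal_p <- function(observed, null_es) {
  .assert(length(null_es) >= 1, "need at least one permutation")
  k <- sum(null_es > observed)
  n <- length(null_es)
  list(p = k / n,
       n_exceed = k,
       label = if (k == 0) sprintf("< %g", 1 / n) else sprintf("%g", k / n))
}

#' Normalize enrichment scores against their permutation null
#'
#' `NES = (ES - mean(null ES)) / sd(null ES)` per set, using the population
#' SD convention (divide by the number of permutations). Each permuted ES
#' is normalized by its own set's null mean/SD, yielding the permuted NES
#' matrix pooled by [fdr_q()] and [fwer_p()]. Sets with a degenerate
#' (zero) null SD are flagged with `NA` and excluded from the pools with a
#' warning.
#'
#' @param null a [null_es_statistic()] / [null_es_phenotype()] result, or a
#'   sets x permutations ES matrix (then `es_obs` must be supplied).
#' @param es_obs named observed ES vector (taken from `null` if absent).
#' @return list with `nes_obs` (named vector), `nes_null` (matrix),
#'   `null_mean`, `null_sd`.
#' @export
normalize_scores <- function(null, es_obs = NULL) {
  if (inherits(null, "null_distributions")) {
    if (is.null(es_obs)) es_obs <- null$es_obs
    null <- null$es_null
  }
  .assert(is.matrix(null), "null must be a matrix (sets x permutations)")
  .assert(!is.null(es_obs) && length(es_obs) == nrow(null),
          "es_obs must match the null matrix rows")
  mu <- rowMeans(null)
  sdv <- sqrt(rowMeans(null * null) - mu^2)  # population SD
  degen <- sdv <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  if (any(degen)) {
    warning(sprintf("%d set(s) with zero null SD flagged and excluded: %s",
                    sum(degen), paste(rownames(null)[degen], collapse = ", ")),
            call. = FALSE)
  }
  sdv[degen] <- NA_real_
  nes_obs <- (es_obs - mu) / sdv
  nes_null <- (null - mu) / sdv
  list(nes_obs = nes_obs, nes_null = nes_null, null_mean = mu, null_sd = sdv)
}

#' Permutation FDR q value
#'
#' For each set, the ratio of the fraction of all permuted (set,
#' permutation) NES values at or above the observed NES to the fraction of
#' observed sets with NES at or above it, clipped to [0, 1]. Not
#' monotonized across the NES ranking.
#'
#' @param nes_obs named observed NES vector.
#' @param nes_null permuted NES matrix (sets x permutations).
#' @return Named numeric vector of q values (`NA` for flagged sets).
#' @export
fdr_q <- function(nes_obs, nes_null) {
  .assert(length(nes_obs) >= 2, "need at least 2 sets for FDR")
  ok <- is.finite(nes_obs)
  pool <- nes_null[is.finite(rowMeans(nes_null)), , drop = FALSE]
  vapply(seq_along(nes_obs), function(i) {
    if (!ok[i]) return(NA_real_)
    num <- mean(pool >= nes_obs[i])
    den <- mean(nes_obs[ok] >= nes_obs[i])
    min(1, num / den)
  }, 0) -> q
  names(q) <- names(nes_obs)
  q
}

#' Permutation FWER p value
#'
#' Fraction of permutations whose maximum NES across all sets strictly
#' exceeds the observed NES of the set under test.
#'
#' @inheritParams fdr_q
#' @return Named numeric vector of FWER p values.
#' @export
fwer_p <- function(nes_obs, nes_null) {
  .assert(length(nes_obs) >= 1, "need at least 1 set")
  pool <- nes_null[is.finite(rowMeans(nes_null)), , drop = FALSE]
  colmax <- apply(pool, 2, max)
  p <- vapply(nes_obs, function(x) {
    if (!is.finite(x)) return(NA_real_)
    mean(colmax > x)
  }, 0)
  names(p) <- names(nes_obs)
  p
}

#' Apply the pathway significance criteria
#'
#' A pathway is called significant when both its FDR q value and FWER p
#' value are at or below their thresholds (default 0.05 each).
#'
#' @param results data.frame with `q_fdr` and `p_fwer` columns.
#' @param alpha_fdr,alpha_fwer thresholds.
#' @return `results` with a logical `significant` column.
#' @export
call_significance <- function(results, alpha_fdr = 0.05, alpha_fwer = 0.05) {
  .assert(all(c("q_fdr", "p_fwer") %in% names(results)),
          "results must have q_fdr and p_fwer")
  results$significant <- !is.na(results$q_fdr) & !is.na(results$p_fwer) &
    results$q_fdr <= alpha_fdr & results$p_fwer <= alpha_fwer
  results
}

#' Leading-edge overlap between two analyses
#'
#' Intersection of the leading-edge gene lists a named set obtained in two
#' runs (e.g. discovery and replication cohorts).
#'
#' @param results_a,results_b [pathway_enrichment()] results (or any
#'   data.frame with `set_name` and semicolon-joined `leading_edge`).
#' @param set_name the pathway to compare.
#' @return Character vector of shared leading-edge gene ids.
#' @export
leading_edge_overlap <- function(results_a, results_b, set_name) {
  le <- function(res) {
    i <- match(set_name, res$set_name)
    .assert(!is.na(i), "set '%s' absent from one of the runs", set_name)
    strsplit(res$leading_edge[i], ";", fixed = TRUE)[[1]]
  }
  intersect(le(results_a), le(results_b))
}

#' Pathway enrichment analysis with permutation significance
#'
#' End-to-end pathway scoring: observed enrichment scores and leading
#' edges per set, a permutation null (`mode = "phenotype"` shuffles
#' adjusted trait residuals and recomputes the whole chain;
#' `mode = "statistic"` shuffles the observed gene statistics across gene
#' labels), normalized enrichment scores, nominal p values, FDR q, FWER p,
#' and the joint significance call.
#'
#' @param gene_stats data.frame from [gene_statistics()]; required for
#'   `mode = "statistic"`, recomputed internally from `geno`/`adjusted`/
#'   `mapping` for `mode = "phenotype"` if omitted.
#' @param sets a [gene_set_collection()] or named list of member vectors
#'   (ideally already passed through [filter_sets()]).
#' @param mode `"phenotype"` or `"statistic"`.
#' @param geno,adjusted,mapping required for `mode = "phenotype"`; see
#'   [null_es_phenotype()].
#' @param n_perm number of permutations (default 1000).
#' @param weight_exponent weight on the gene statistic (default 1).
#' @param seed integer seed.
#' @param alpha_fdr,alpha_fwer significance thresholds (default 0.05).
#' @return An object of classes `pathway_result` and `data.frame`, one row
#'   per set: `set_name`, `size`, `es`, `nes`, `p_nominal`,
#'   `p_nominal_label`, `n_exceed`, `q_fdr`, `p_fwer`, `significant`,
#'   `peak_index`, `leading_edge` (semicolon-joined). The
#'   `null_distributions` object is attached as attribute `"null"`.
#' @export
pathway_enrichment <- function(gene_stats = NULL, sets, mode = c("phenotype", "statistic"),
                               geno = NULL, adjusted = NULL, mapping = NULL,
                               n_perm = 1000, weight_exponent = 1, seed = NULL,
                               alpha_fdr = 0.05, alpha_fwer = 0.05) {
  mode <- match.arg(mode)
  if (mode == "phenotype") {
    .assert(!is.null(geno) && !is.null(adjusted) && !is.null(mapping),
            "phenotype mode needs geno, adjusted, and mapping")
    if (is.null(gene_stats)) {
      snp_res <- snp_association(geno, adjusted)
      gene_stats <- gene_statistics(mapping, snp_res)
    }
    null <- null_es_phenotype(geno, adjusted, mapping, sets,
                              n_perm = n_perm,
                              weight_exponent = weight_exponent, seed = seed)
  } else {
    .assert(!is.null(gene_stats), "statistic mode needs gene_stats")
    null <- null_es_statistic(gene_stats, sets, n_perm = n_perm,
                              weight_exponent = weight_exponent, seed = seed)
  }
  set_names <- rownames(null$es_null)

  ranked <- rank_genes(gene_stats)
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  detail <- lapply(set_names, function(nm)
    enrichment_score(ranked, sets[[nm]], weight_exponent))
  names(detail) <- set_names

  nom <- lapply(set_names, function(nm)
    nominal_p(null$es_obs[[nm]], null$es_null[nm, ]))
  nrm <- normalize_scores(null)
  q <- fdr_q(nrm$nes_obs, nrm$nes_null)
  pf <- fwer_p(nrm$nes_obs, nrm$nes_null)

  res <- data.frame(set_name = set_names,
                    size = vapply(detail, function(d) d$size, 0L),
                    es = unname(null$es_obs),
                    nes = unname(nrm$nes_obs),
                    p_nominal = vapply(nom, function(x) x$p, 0),
                    p_nominal_label = vapply(nom, function(x) x$label, ""),
                    n_exceed = vapply(nom, function(x) x$n_exceed, 0L),
                    q_fdr = unname(q),
                    p_fwer = unname(pf),
                    peak_index = vapply(detail, function(d) d$peak_index, 0L),
                    leading_edge = vapply(detail, function(d)
                      paste(d$leading_edge, collapse = ";"), ""),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  res <- call_significance(res, alpha_fdr, alpha_fwer)
  res <- res[order(-res$nes, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "null") <- null
  attr(res, "mode") <- mode
  class(res) <- c("pathway_result", "data.frame")
  res
}

#' @export
print.pathway_result <- function(x, n = 10, ...) {
  cat(sprintf("pathway_result (%s-mode permutations): %d sets, %d significant\n",
              attr(x, "mode"), nrow(x), sum(x$significant)))
  cols <- c("set_name", "size", "es", "nes", "p_nominal_label",
            "q_fdr", "p_fwer", "significant")
  print.data.frame(head(as.data.frame(x)[, cols], n), digits = 3)
  if (nrow(x) > n) cat(sprintf("... and %d more sets\n", nrow(x) - n))
  invisible(x)
}
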