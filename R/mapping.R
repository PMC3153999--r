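## SNP-to-gene mapping on 1-based inclusive gene intervals.
##
## Distance convention: 0 for a SNP inside a gene; otherwise the base-pair
## offset from the nearest gene boundary (a SNP immediately adjacent to a
## gene is at distance 1). "More than 500 kb away" is therefore strict at
## 500,001 bp.

.snp_granges <- function(snp_meta) {
  GenomicRanges::GRanges(seqnames = snp_meta$chrom,
                         ranges = IRanges::IRanges(start = snp_meta$pos,
                                                   width = 1L))
}

.gene_granges <- function(gene_map) {
  GenomicRanges::GRanges(seqnames = gene_map$chrom,
                         ranges = IRanges::IRanges(start = gene_map$start,
                                                   end = gene_map$end))
}

# distance (bp offset convention) from each SNP to its nearest gene;
# NA when no gene shares the SNP's chromosome
snp_gene_distance <- function(snp_meta, gene_map) {
  sg <- .snp_granges(snp_meta)
  gg <- .gene_granges(gene_map)
  d <- rep(NA_real_, nrow(snp_meta))
  hit <- suppressWarnings(GenomicRanges::distanceToNearest(sg, gg))
  qh <- S4Vectors::queryHits(hit)
  d[qh] <- S4Vectors::mcols(hit)$distance
  inside <- suppressWarnings(IRanges::overlapsAny(sg, gg))
  ifelse(inside, 0, ifelse(is.na(d), NA_real_, d + 1))
}

#' Map SNPs to genes
#'
#' A SNP inside one gene maps to that gene; a SNP inside the shared region
#' of overlapping genes maps to all of them; a SNP outside every gene but
#' within `window` of at least one maps to its closest gene by boundary
#' distance (exact ties map to all tied genes); a SNP farther than `window`
#' from every gene, or on a chromosome with no genes, is unmapped.
#'
#' @param snp_meta data.frame with `snp_id`, `chrom`, `pos` (1-based bp).
#' @param gene_map data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive); strand is ignored for distance.
#' @param window maximum SNP-gene distance in bp (default 500,000).
#' @return data.frame with columns `snp_id`, `gene_id`, `distance` (bp,
#'   0 inside a gene), one row per (SNP, gene) assignment.
#' @export
map_snps_to_genes <- function(snp_meta, gene_map, window = 500000) {
  .assert(nrow(gene_map) > 0, "gene_map is empty")
  .assert(!anyDuplicated(gene_map$gene_id), "gene ids must be unique")
  sg <- .snp_granges(snp_meta)
  gg <- .gene_granges(gene_map)

  ov <- suppressWarnings(GenomicRanges::findOverlaps(sg, gg))
  inside <- data.frame(snp = S4Vectors::queryHits(ov),
                       gene = S4Vectors::subjectHits(ov),
                       distance = rep(0, length(ov)))

  out_idx <- setdiff(seq_along(sg), unique(inside$snp))
  near <- NULL
  if (length(out_idx)) {
    so <- sg[out_idx]
    # candidate nearest genes on each side (precede/follow each return all
    # same-side ties); cross-side ties are resolved by taking per-SNP minima
    cand <- lapply(c(GenomicRanges::precede, GenomicRanges::follow),
                   function(fun) {
                     h <- suppressWarnings(fun(so, gg, select = "all"))
                     data.frame(snp = out_idx[S4Vectors::queryHits(h)],
                                gene = S4Vectors::subjectHits(h))
                   })
    cand <- do.call(rbind, cand)
    if (nrow(cand)) {
      d <- suppressWarnings(
        GenomicRanges::distance(sg[cand$snp], gg[cand$gene])) + 1
      cand$distance <- d
      cand <- cand[!is.na(d) & d <= window, , drop = FALSE]
      dmin <- tapply(cand$distance, cand$snp, min)
      cand <- cand[cand$distance == dmin[as.character(cand$snp)], , drop = FALSE]
      near <- cand
    }
  }
  map <- rbind(inside, near)
  map <- map[order(map$snp, map$gene), , drop = FALSE]
  data.frame(snp_id = snp_meta$snp_id[map$snp],
             gene_id = gene_map$gene_id[map$gene],
             distance = map$distance,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Best-SNP gene statistics
#'
#' Reduces per-SNP association results to one representative statistic per
#' gene: the largest absolute statistic among the SNPs mapped to the gene
#' (for a two-sided test the sign encodes allele direction, not strength).
#' A SNP mapped to several genes contributes to each of them. SNPs with an
#' unusable (non-finite) statistic are dropped; genes left with no usable
#' SNP are omitted.
#'
#' @param mapping data.frame from [map_snps_to_genes()].
#' @param snp_results data.frame of per-SNP results with at least `snp_id`,
#'   `statistic`, `p_value` (from [snp_association()] or
#'   [load_external_stats()]).
#' @return data.frame with columns `gene_id`, `r` (representative
#'   statistic, non-negative), `best_snp`, `best_p`, `n_snps`, sorted by
#'   `gene_id`. Ties in absolute statistic are broken by `snp_id` so the
#'   result is independent of input order.
#' @export
gene_statistics <- function(mapping, snp_results) {
  .assert(nrow(mapping) > 0, "empty mapping")
  m <- merge(mapping[, c("snp_id", "gene_id")],
             snp_results[, c("snp_id", "statistic", "p_value")],
             by = "snp_id")
  m <- m[is.finite(m$statistic), , drop = FALSE]
  if (nrow(m) == 0) {
    return(data.frame(gene_id = character(0), r = numeric(0),
                      best_snp = character(0), best_p = numeric(0),
                      n_snps = integer(0), stringsAsFactors = FALSE))
  }
  m$abs_stat <- abs(m$statistic)
  m <- m[order(m$gene_id, -m$abs_stat, m$snp_id), , drop = FALSE]
  first <- !duplicated(m$gene_id)
  n_snps <- as.integer(table(m$gene_id)[m$gene_id[first]])
  data.frame(gene_id = m$gene_id[first],
             r = m$abs_stat[first],
             best_snp = m$snp_id[first],
             best_p = m$p_value[first],
             n_snps = n_snps,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
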