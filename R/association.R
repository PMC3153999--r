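## Single-SNP additive association of the adjusted trait.
##
## The per-SNP model is an intercept + dosage OLS fit on complete cases;
## the Wald t statistic is beta/se with n-2 df. The scan is vectorized
## with per-SNP missingness masks so the same engine can be reused inside
## phenotype permutations without refitting R model objects.

# cap for numerically infinite statistics from perfect fits
.stat_cap <- 1e15
# dosage columns with centered sum of squares below this are monomorphic
# in sample / near-singular and are flagged rather than reported
.var_floor <- 1e-12

.assoc_precompute <- function(calls) {
  M <- !is.na(calls)
  X <- calls
  X[!M] <- 0
  n <- colSums(M)
  Sx <- colSums(X)
  Sxx <- colSums(X * X)
  ssx <- Sxx - Sx^2 / pmax(n, 1)
  ok <- n >= 3 & ssx > .var_floor * pmax(n, 1)
  # mask kept as double so BLAS sees it without per-call coercion
  list(X = X, M = if (any(!M)) M + 0 else NULL, n = n,
       Sx = Sx, Sxx = Sxx, ssx = ssx, ok = ok)
}

# Wald t per SNP for trait vector y; returns beta, se, t, df
.assoc_scan <- function(pre, y) {
  n <- pre$n
  if (is.null(pre$M)) {
    Sy <- sum(y)
    Syy <- sum(y * y)
    Sxy <- drop(crossprod(pre$X, y))
  } else {
    Sy <- drop(crossprod(pre$M, y))
    Syy <- drop(crossprod(pre$M, y * y))
    Sxy <- drop(crossprod(pre$X, y))
  }
  sxy <- Sxy - pre$Sx * Sy / n
  syy <- Syy - Sy^2 / n
  beta <- sxy / pre$ssx
  df <- n - 2
  sse <- pmax(syy - beta * sxy, 0)
  se <- sqrt(sse / df / pre$ssx)
  t <- beta / se
  inf <- is.finite(beta) & !is.finite(t)
  t[inf] <- sign(beta[inf]) * .stat_cap
  bad <- !pre$ok
  beta[bad] <- NA_real_
  se[bad] <- NA_real_
  t[bad] <- NA_real_
  list(beta = beta, se = se, t = t, df = df)
}

# batched Wald t for several trait vectors at once (columns of Y);
# returns an m x B matrix of t statistics. Used by the permutation loop.
.assoc_scan_batch <- function(pre, Y) {
  n <- pre$n
  if (is.null(pre$M)) {
    Sy <- matrix(colSums(Y), nrow = length(n), ncol = ncol(Y), byrow = TRUE)
    Syy <- matrix(colSums(Y * Y), nrow = length(n), ncol = ncol(Y),
                  byrow = TRUE)
  } else {
    Sy <- crossprod(pre$M, Y)
    Syy <- crossprod(pre$M, Y * Y)
  }
  Sxy <- crossprod(pre$X, Y)
  sxy <- Sxy - (pre$Sx / n) * Sy
  syy <- Syy - Sy^2 / n
  beta <- sxy / pre$ssx
  sse <- pmax(syy - beta * sxy, 0)
  se <- sqrt(sse / (n - 2) / pre$ssx)
  t <- beta / se
  inf <- is.finite(beta) & !is.finite(t)
  t[inf] <- sign(beta[inf]) * .stat_cap
  t[!pre$ok, ] <- NA_real_
  t
}

#' Genome-wide single-SNP Wald scan
#'
#' Ordinary least squares of the adjusted trait on each SNP's additive
#' dosage (with intercept), complete-case per SNP; the Wald statistic is
#' `t = beta/se` with `n_used - 2` df and a two-sided p value. SNPs that
#' are monomorphic in sample (dosage variance below a small floor) or have
#' fewer than 3 complete cases are reported with `NA` statistics and are
#' excluded downstream rather than raising errors. Numerically perfect
#' fits are reported with a capped statistic and p = 0.
#'
#' @param geno a [genotype_matrix()].
#' @param adjusted an [adjust_trait()] result, or a data.frame with
#'   `subject_id` and `residual`.
#' @return data.frame with columns `snp_id`, `n_used`, `beta`, `se`,
#'   `statistic`, `p_value`.
#' @export
snp_association <- function(geno, adjusted) {
  .assert(inherits(geno, "genotype_matrix"), "geno must be a genotype_matrix")
  .assert(all(c("subject_id", "residual") %in% names(adjusted)),
          "adjusted must have subject_id and residual columns")
  idx <- match(geno$subject_ids, adjusted$subject_id)
  .assert(!anyNA(idx), "all genotyped subjects must have an adjusted trait value")
  y <- as.numeric(adjusted$residual[idx])
  pre <- .assoc_precompute(geno$calls)
  sc <- .assoc_scan(pre, y)
  p <- 2 * pt(-abs(sc$t), df = pmax(sc$df, 1))
  data.frame(snp_id = geno$snp_ids,
             n_used = as.integer(pre$n),
             beta = sc$beta,
             se = sc$se,
             statistic = sc$t,
             p_value = p,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Single-SNP Wald test
#'
#' Convenience scalar form of [snp_association()] for one dosage vector.
#'
#' @param dosage additive calls (0/1/2, `NA` allowed).
#' @param trait adjusted trait values, same length.
#' @param snp_id id used in the result row.
#' @return One-row data.frame in the [snp_association()] layout. A SNP
#'   monomorphic in sample yields `NA` statistics (flagged, not an error).
#' @export
wald_test <- function(dosage, trait, snp_id = "snp") {
  .assert(length(dosage) == length(trait), "dosage and trait lengths differ")
  cc <- !is.na(dosage) & !is.na(trait)
  .assert(sum(cc) >= 3, "need >= 3 subjects with non-missing dosage and trait")
  calls <- matrix(ifelse(cc, dosage, NA_real_), ncol = 1,
                  dimnames = list(NULL, snp_id))
  y <- ifelse(cc, trait, 0)
  pre <- .assoc_precompute(calls)
  sc <- .assoc_scan(pre, y)
  p <- 2 * pt(-abs(sc$t), df = pmax(sc$df, 1))
  data.frame(snp_id = snp_id, n_used = as.integer(pre$n),
             beta = sc$beta, se = sc$se, statistic = sc$t, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write per-SNP association results
#'
#' @param results data.frame in the [snp_association()] layout.
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
write_snp_results <- function(results, path) {
  .write_tsv(results[, intersect(.snp_result_cols, names(results))], path)
  invisible(path)
}

#' Load externally computed per-SNP statistics
#'
#' Ingests per-SNP statistics produced outside the package (for example
#' family-based association Z statistics, where phenotype permutation is
#' invalid and the statistic-shuffling permutation mode is used instead).
#' Rows with a missing/duplicate id, a non-finite statistic, or a p value
#' outside (0, 1] are rejected with a warning naming their line numbers.
#'
#' @param path TSV with header columns `snp_id`, `statistic`, `p_value`
#'   (extra columns such as `beta`/`se`/`n_used` are carried through).
#' @return data.frame in the [snp_association()] layout, usable by
#'   [gene_statistics()] identically to internally computed results.
#' @export
load_external_stats <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("snp_id", "statistic", "p_value") %in% names(raw)),
          "stats file must have snp_id, statistic, p_value columns")
  stat <- suppressWarnings(as.numeric(raw$statistic))
  pv <- suppressWarnings(as.numeric(raw$p_value))
  ok <- !is.na(raw$snp_id) & nzchar(raw$snp_id) &
    is.finite(stat) & is.finite(pv) & pv > 0 & pv <= 1 &
    !duplicated(raw$snp_id)
  if (any(!ok)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(!ok), paste(which(!ok) + 1L, collapse = ", ")),
            call. = FALSE)
  }
  raw <- raw[ok, , drop = FALSE]
  out <- data.frame(snp_id = as.character(raw$snp_id),
                    n_used = if ("n_used" %in% names(raw))
                      as.integer(raw$n_used) else NA_integer_,
                    beta = if ("beta" %in% names(raw))
                      as.numeric(raw$beta) else NA_real_,
                    se = if ("se" %in% names(raw))
                      as.numeric(raw$se) else NA_real_,
                    statistic = stat[ok],
                    p_value = pv[ok],
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
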