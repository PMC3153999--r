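#' Select significant trait covariates
#'
#' Fits one full ordinary-least-squares model of the raw trait on all
#' candidate terms and retains the terms whose coefficient p values are at
#' or below `alpha` (single-pass marginal significance within the full
#' model, not stepwise selection). If an interaction term is retained its
#' main effects are retained too, so the adjustment model is well-formed.
#'
#' Candidate terms are named after phenotype columns, with `name2` meaning
#' the square of a column and `a_b` the product of two (possibly derived)
#' terms; e.g. `c("age", "age2", "sex", "age_sex", "age2_sex", "height",
#' "weight")`.
#'
#' @param pheno data.frame with `subject_id`, the trait column, and
#'   covariate columns.
#' @param candidates character vector of candidate term names.
#' @param alpha retention threshold on the coefficient p value (default
#'   0.05).
#' @param trait_col name of the trait column (default `"trait"`).
#' @return An object of class `covariate_selection`: list with `retained`
#'   (character vector of term names), `table` (term, estimate, p value,
#'   retained flag), and `alpha`.
#' @export
select_covariates <- function(pheno, candidates, alpha = 0.05,
                              trait_col = "trait") {
  .assert(trait_col %in% names(pheno), "trait column '%s' not found", trait_col)
  .assert(length(candidates) > 0, "no candidate terms")
  y <- as.numeric(pheno[[trait_col]])
  .assert(!anyNA(y), "missing raw trait values among analyzed subjects")
  X <- vapply(candidates, function(tm) .term_column(pheno, tm),
              numeric(nrow(pheno)))
  d <- data.frame(.trait = y, X, check.names = FALSE)
  fit <- lm(.trait ~ ., data = d)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop(sprintf("rank-deficient design; aliased terms: %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  rows <- match(paste0("`", candidates, "`"), rownames(sm))
  rows[is.na(rows)] <- match(candidates, rownames(sm))[is.na(rows)]
  est <- sm[rows, "Estimate"]
  pv <- sm[rows, "Pr(>|t|)"]
  retained <- pv <= alpha
  names(retained) <- candidates
  # heredity: an interaction brings in its constituent terms
  for (tm in candidates[retained]) {
    if (grepl("_", tm, fixed = TRUE)) {
      parts <- strsplit(tm, "_", fixed = TRUE)[[1]]
      retained[candidates %in% parts] <- TRUE
    }
  }
  structure(list(retained = candidates[retained],
                 table = data.frame(term = candidates,
                                    estimate = unname(est),
                                    p_value = unname(pv),
                                    retained = unname(retained),
                                    stringsAsFactors = FALSE),
                 alpha = alpha),
            class = "covariate_selection")
}

#' @export
print.covariate_selection <- function(x, ...) {
  cat(sprintf("covariate selection (alpha = %g): %s\n", x$alpha,
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "<none>"))
  print(x$table, digits = 4)
  invisible(x)
}

#' Adjust the raw trait for covariates
#'
#' Refits an OLS model of the raw trait on the retained terms and takes its
#' residuals as the adjusted trait used for association. Residual normality
#' is checked with the Lilliefors test (Kolmogorov-Smirnov against the
#' fitted normal, with a null distribution calibrated for the estimated
#' mean and SD); `shapiro.test` is available as an alternative. A warning
#' (not an error) is issued when the normality p value is 0.1 or below.
#'
#' @param pheno data.frame with `subject_id`, the trait column, and
#'   covariate columns.
#' @param terms character vector of term names (possibly empty, giving
#'   mean-centering only) or a [select_covariates()] result.
#' @param trait_col name of the trait column.
#' @param normality `"lilliefors"` (default) or `"shapiro"`.
#' @return An object of class `adjusted_phenotype`: data.frame with
#'   `subject_id` and `residual`, plus attributes `retained_terms`
#'   (term/coefficient table of the adjustment fit) and `normality_p`.
#' @export
adjust_trait <- function(pheno, terms = character(0), trait_col = "trait",
                         normality = c("lilliefors", "shapiro")) {
  normality <- match.arg(normality)
  if (inherits(terms, "covariate_selection")) terms <- terms$retained
  y <- as.numeric(pheno[[trait_col]])
  .assert(!anyNA(y), "missing raw trait values among analyzed subjects")
  n <- length(y)
  .assert(n > length(terms) + 1, "need n > number of terms + 1")
  if (length(terms) == 0) {
    res <- y - mean(y)
    tab <- data.frame(term = "(Intercept)", estimate = mean(y),
                      stringsAsFactors = FALSE)
  } else {
    X <- vapply(terms, function(tm) .term_column(pheno, tm), numeric(n))
    d <- data.frame(.trait = y, X, check.names = FALSE)
    fit <- lm(.trait ~ ., data = d)
    res <- unname(residuals(fit))
    tab <- data.frame(term = c("(Intercept)", terms),
                      estimate = unname(coef(fit)),
                      stringsAsFactors = FALSE)
  }
  norm_p <- .residual_normality_p(res, normality)
  if (!is.na(norm_p) && norm_p <= 0.1) {
    warning(sprintf("adjusted trait deviates from normality (p = %.3g)", norm_p),
            call. = FALSE)
  }
  out <- data.frame(subject_id = pheno$subject_id, residual = res,
                    stringsAsFactors = FALSE)
  attr(out, "retained_terms") <- tab
  attr(out, "normality_p") <- norm_p
  class(out) <- c("adjusted_phenotype", "data.frame")
  out
}

.residual_normality_p <- function(res, method) {
  if (length(res) < 5 || sd(res) < 1e-12 * (abs(mean(res)) + 1)) {
    return(NA_real_)
  }
  if (method == "shapiro") {
    return(shapiro.test(res)$p.value)
  }
  nortest::lillie.test(res)$p.value
}
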