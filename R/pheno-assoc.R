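#' Phenotype derivations, qPCR quantities and trait association
#'
#' Utilities for the association stage: the fillet whiteness index from
#' colorimeter L*/a*/b* readings, delta-delta-Ct relative quantification
#' against a reference small RNA (U6), rank-based inverse normal
#' transformation of traits, expression- and genotype-phenotype regression
#' with signed squared correlations, multi-predictor variance, pairwise
#' trait correlations, identity-by-state multidimensional scaling, and
#' Welch group comparison.
#'
#' Throughout, "signed r2" is the squared Pearson correlation carrying the
#' sign of the regression slope, matching reporting conventions where
#' negative table entries denote negative correlations.
#'
#' @name pheno_assoc
NULL

#' Fillet whiteness index
#'
#' `100 - sqrt((100 - L)^2 + a^2 + b^2)` from colorimeter lightness (L*),
#' redness (a*) and yellowness (b*).
#'
#' @param L,a,b colorimeter readings (vectorized).
#' @return whiteness index values (<= 100).
#' @export
#' @examples
#' whiteness_index(50, 3, 4)
whiteness_index <- function(L, a, b) {
  100 - sqrt((100 - L)^2 + a^2 + b^2)
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' `2^-(dct_case - dct_control)` where each delta-Ct is the target Ct minus
#' the endogenous-control (U6) Ct.
#'
#' @param dct_case,dct_control delta-Ct values.
#' @return fold change of case relative to control.
#' @export
#' @examples
#' ddct_fold_change(5, 6)  # 2
ddct_fold_change <- function(dct_case, dct_control) {
  2^(-(dct_case - dct_control))
}

#' Rank-based inverse normal (Blom) transform
#'
#' `qnorm((rank - 3/8) / (n + 1/4))` with average ranks for ties. The
#' output is invariant to strictly monotone transforms of the input and
#' passes standard normality screens for continuous input.
#'
#' @param values numeric vector, n >= 3, not constant.
#' @return transformed values (NA preserved).
#' @export
rank_inverse_normal <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3L)
    stop("need at least 3 non-missing values", call. = FALSE)
  if (length(unique(x)) == 1L)
    stop("constant input: ranks undefined up to ties", call. = FALSE)
  n <- length(x)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}

# Shared simple-regression core: signed r2 and correlation-test p.
.assoc_core <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(n = n, signed_r2 = NA_real_, r = NA_real_, p = NA_real_,
                untestable = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(n = n, signed_r2 = sign(r) * r^2, r = r, p = ct$p.value,
       untestable = FALSE)
}

#' Regress a phenotype on miRNA expression (delta-Ct)
#'
#' Simple linear regression / Pearson correlation between per-fish
#' delta-Ct values and a quantitative trait. Note that a lower delta-Ct
#' means higher expression; the sign reported is that of the delta-Ct
#' slope (set `expression_scale = TRUE` to flip to the expression scale,
#' i.e. correlate against -delta-Ct).
#'
#' @param dct per-fish delta-Ct values.
#' @param trait per-fish trait values.
#' @param expression_scale correlate against `-dct` (default FALSE).
#' @return one-row data.frame: `n`, `signed_r2`, `r`, `p`, `untestable`.
#' @export
regress_expression_phenotype <- function(dct, trait,
                                         expression_scale = FALSE) {
  x <- if (expression_scale) -dct else dct
  as.data.frame(.assoc_core(x, trait))
}

#' Variance explained jointly by several predictors
#'
#' Coefficient of determination of the multiple regression of a trait on a
#' predictor matrix. Collinear predictors are dropped with a warning and
#' the retained set reported.
#'
#' @param predictors numeric matrix or data.frame (fish x predictors).
#' @param trait per-fish trait values.
#' @return list with `r2`, `n`, `retained` (predictor names used).
#' @export
combined_variance <- function(predictors, trait) {
  X <- as.matrix(predictors)
  ok <- stats::complete.cases(X, trait)
  X <- X[ok, , drop = FALSE]
  y <- trait[ok]
  if (nrow(X) <= ncol(X) + 1L)
    stop("need n > number of predictors + 1", call. = FALSE)
  fit <- stats::lm(y ~ X)
  coefs <- stats::coef(fit)[-1L]
  dropped <- is.na(coefs)
  if (any(dropped)) {
    warning(sprintf("dropped %d collinear predictor(s)", sum(dropped)))
  }
  retained <- colnames(X)[!dropped] %||% which(!dropped)
  list(r2 = summary(fit)$r.squared, n = length(y), retained = retained)
}

#' Pairwise trait correlations
#'
#' Signed squared Pearson correlations and p-values for every pair of
#' traits, with pairwise deletion of missing values.
#'
#' @param phenotypes data.frame of trait columns.
#' @param traits trait column names (default: all numeric columns).
#' @return list of matrices `signed_r2`, `p`, `n` (traits x traits).
#' @export
pairwise_trait_correlation <- function(phenotypes, traits = NULL) {
  if (is.null(traits))
    traits <- names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))]
  k <- length(traits)
  r2 <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        r2[i, j] <- 1
        p[i, j] <- 0
        n[i, j] <- sum(!is.na(phenotypes[[traits[i]]]))
      } else {
        a <- .assoc_core(phenotypes[[traits[i]]], phenotypes[[traits[j]]])
        r2[i, j] <- a$signed_r2
        p[i, j] <- a$p
        n[i, j] <- a$n
      }
    }
  }
  list(signed_r2 = r2, p = p, n = n)
}

#' Association between a SNP genotype and a quantitative trait
#'
#' Ordinary least squares of the (optionally rank-inverse-normal
#' transformed) trait on additive genotype dosage (0/1/2). The signed
#' squared correlation and the correlation-test p-value are reported;
#' monomorphic SNPs are flagged untestable.
#'
#' @param genotypes per-fish dosages (0/1/2, NA allowed).
#' @param trait per-fish trait values.
#' @param transform apply [rank_inverse_normal()] to the trait (default
#'   TRUE).
#' @return one-row data.frame: `n`, `signed_r2`, `r`, `p`, `untestable`.
#' @export
snp_association <- function(genotypes, trait, transform = TRUE) {
  ok <- stats::complete.cases(genotypes, trait)
  g <- genotypes[ok]
  y <- trait[ok]
  if (length(unique(g)) < 2L)
    return(data.frame(n = length(g), signed_r2 = NA_real_, r = NA_real_,
                      p = NA_real_, untestable = TRUE))
  if (transform) y <- rank_inverse_normal(y)
  as.data.frame(.assoc_core(g, y))
}

#' Associate a SNP panel with one trait
#'
#' Runs [snp_association()] per SNP and BH-adjusts p-values across the
#' panel.
#'
#' @param genotype_matrix data.frame or matrix (fish x SNPs, dosage
#'   0/1/2).
#' @param trait per-fish trait values.
#' @inheritParams snp_association
#' @return data.frame with `predictor`, `n`, `signed_r2`, `r`, `p`, `q`,
#'   `untestable`.
#' @export
snp_association_panel <- function(genotype_matrix, trait, transform = TRUE) {
  G <- as.data.frame(genotype_matrix)
  rows <- lapply(names(G), function(s) {
    cbind(predictor = s, snp_association(G[[s]], trait, transform))
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  testable <- !out$untestable
  out$q[testable] <- bh_fdr(out$p[testable])
  out
}

#' Conditional association of a focal SNP given covariate SNPs
#'
#' Regression of the (transformed) trait on the focal dosage with the
#' covariate dosages included; the focal SNP's effect is judged
#' independent of the covariates when its adjusted p-value stays below
#' `level`. Covariates collinear with the retained design are dropped with
#' a warning.
#'
#' @param focal per-fish focal-SNP dosages.
#' @param covariates data.frame/matrix of covariate-SNP dosages.
#' @param trait per-fish trait values.
#' @param transform apply [rank_inverse_normal()] (default TRUE).
#' @param level significance level for the independence call (default
#'   0.05).
#' @return list with `p_adjusted`, `independent`, `dropped` (covariate
#'   names removed for collinearity).
#' @export
conditional_association <- function(focal, covariates, trait,
                                    transform = TRUE, level = 0.05) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("cov", seq_len(ncol(X)))
  ok <- stats::complete.cases(focal, X, trait)
  focal <- focal[ok]
  X <- X[ok, , drop = FALSE]
  y <- trait[ok]
  if (transform) y <- rank_inverse_normal(y)
  fit <- stats::lm(y ~ focal + X)
  cf <- stats::coef(fit)
  dropped <- character(0)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased)) {
    dropped <- sub("^X", "", aliased)
    warning(sprintf("dropped collinear covariate(s): %s",
                    paste(dropped, collapse = ", ")))
    keep <- setdiff(colnames(X), dropped)
    fit <- stats::lm(y ~ focal + X[, keep, drop = FALSE])
  }
  sm <- summary(fit)$coefficients
  if (!"focal" %in% rownames(sm))
    stop("focal genotype collinear with covariates", call. = FALSE)
  p <- sm["focal", 4L]
  list(p_adjusted = p, independent = p < level, dropped = dropped)
}

#' Identity-by-state distances and multidimensional scaling
#'
#' Pairwise IBS distance between individuals: 1 minus the mean number of
#' shared alleles per locus divided by 2, over non-missing loci (for
#' dosage data this is the mean absolute dosage difference divided by 2).
#' Classical (metric) MDS of the distance matrix returns the first `k`
#' coordinates.
#'
#' @param genotype_matrix matrix/data.frame (individuals x loci, dosage
#'   0/1/2, NA allowed).
#' @param k number of coordinates (reduced with a warning if the distance
#'   matrix supports fewer).
#' @return list with `dist` (the distance matrix) and `coords`
#'   (individuals x k).
#' @export
ibs_mds <- function(genotype_matrix, k = 2L) {
  G <- as.matrix(genotype_matrix)
  if (nrow(G) < k + 1L)
    stop("need at least k + 1 individuals", call. = FALSE)
  d <- stats::dist(G, method = "manhattan") / (2 * ncol(G))
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  got <- ncol(fit$points)
  if (got < k) warning(sprintf("MDS rank supports only %d coordinate(s)", got))
  list(dist = as.matrix(d), coords = fit$points)
}

#' Welch comparison of high- and low-ranked family values
#'
#' Descriptive mean and SD per group plus a Welch two-sample t-test.
#' Degenerate inputs (a single value in a group, or two identical constant
#' groups) return descriptives with `p = NA` or `p = 1` respectively.
#'
#' @param high_values,low_values numeric vectors.
#' @return list with `mean_high`, `sd_high`, `mean_low`, `sd_low`, `p`.
#' @export
group_compare <- function(high_values, low_values) {
  out <- list(mean_high = mean(high_values), sd_high = stats::sd(high_values),
              mean_low = mean(low_values), sd_low = stats::sd(low_values))
  if (length(high_values) < 2L || length(low_values) < 2L) {
    out$p <- NA_real_
    return(out)
  }
  out$p <- tryCatch(
    stats::t.test(high_values, low_values)$p.value,
    error = function(e) {
      if (isTRUE(all.equal(mean(high_values), mean(low_values)))) 1
      else NA_real_
    })
  out
}

#' Correlated miRNA-target expression pairs
#'
#' Pearson correlation between a miRNA's normalized counts and its target
#' gene's TPM across shared samples; pairs are retained when `r > 0` and
#' `r^2 > threshold`. Zero-variance series are skipped and tallied.
#'
#' @param mirna_expr matrix (miRNAs x samples) of normalized counts.
#' @param tpm matrix (genes x samples) of transcript-per-million values.
#' @param pairs data.frame with columns `mirna`, `gene_id`.
#' @param threshold squared-correlation cutoff (default 0.70).
#' @return data.frame of retained pairs with `r`, `r2`, `n`; attribute
#'   `n_skipped` counts zero-variance pairs.
#' @export
correlate_expression_pairs <- function(mirna_expr, tpm, pairs,
                                       threshold = 0.70) {
  shared <- intersect(colnames(mirna_expr), colnames(tpm))
  if (length(shared) < 4L)
    stop("need at least 4 shared samples", call. = FALSE)
  skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$mirna[i]
    g <- pairs$gene_id[i]
    if (!m %in% rownames(mirna_expr) || !g %in% rownames(tpm)) next
    x <- mirna_expr[m, shared]
    y <- tpm[g, shared]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      skipped <- skipped + 1L
      next
    }
    r <- stats::cor(x, y)
    if (r > 0 && r^2 > threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(mirna = m, gene_id = g, r = r, r2 = r^2,
                   n = length(shared))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), gene_id = character(), r = numeric(),
               r2 = numeric(), n = integer())
  attr(out, "n_skipped") <- skipped
  out
}
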