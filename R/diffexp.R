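#' Differential expression between divergent family pools
#'
#' With a single pooled sequencing library per family group, biological
#' dispersion is not estimable; differential expression is therefore
#' assessed with the conditional exact binomial test on pooled counts (the
#' one-library-per-group analogue of the exact negative-binomial test),
#' Benjamini-Hochberg adjusted, and a miRNA is called differentially
#' expressed when FDR-adjusted p < 0.05 and the signed fold change is below
#' -2 or above +2.
#'
#' @name diffexp
NULL

#' Counts-per-million normalization
#'
#' @param counts non-negative integer matrix (miRNAs x samples).
#' @return matrix of `cell * 1e6 / column sum`; errors naming the first
#'   column whose library sum is zero.
#' @export
normalize_cpm <- function(counts) {
  libs <- colSums(counts)
  if (any(libs == 0)) {
    bad <- colnames(counts)[which(libs == 0)[1L]] %||%
      as.character(which(libs == 0)[1L])
    stop(sprintf("library sum is zero in column %s", bad), call. = FALSE)
  }
  sweep(counts, 2L, libs, "/") * 1e6
}

#' Exact binomial count test between two pooled libraries
#'
#' Two-sided exact test of `count_a` against
#' `Binomial(count_a + count_b, lib_a / (lib_a + lib_b))`. Both counts zero
#' gives p = 1 (no evidence).
#'
#' @param count_a,count_b read counts in the two pools (vectorized).
#' @param lib_a,lib_b library sizes (> 0).
#' @return p-values in (0, 1].
#' @export
exact_count_test <- function(count_a, count_b, lib_a, lib_b) {
  if (any(lib_a <= 0) || any(lib_b <= 0))
    stop("library sizes must be > 0", call. = FALSE)
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, n)
  count_b <- rep_len(count_b, n)
  lib_a <- rep_len(lib_a, n)
  lib_b <- rep_len(lib_b, n)
  vapply(seq_len(n), function(i) {
    tot <- count_a[i] + count_b[i]
    if (tot == 0) return(1)
    stats::binom.test(count_a[i], tot,
                      p = lib_a[i] / (lib_a[i] + lib_b[i]))$p.value
  }, numeric(1))
}

#' Signed fold change between group means
#'
#' Ratio `r = mean_high / mean_low`, reported as `r` when `r >= 1` and
#' `-1/r` otherwise, so calls can use the symmetric "below -2 or above +2"
#' convention. The pseudocount is added to both means only when either is
#' zero, keeping fold changes finite.
#'
#' @param mean_high,mean_low non-negative group means (vectorized).
#' @param pseudocount added when a mean is zero (default 0.5).
#' @return signed fold changes.
#' @export
#' @examples
#' fold_change(40, 10)  # +4
#' fold_change(10, 40)  # -4
fold_change <- function(mean_high, mean_low, pseudocount = 0.5) {
  n <- max(length(mean_high), length(mean_low))
  h <- rep_len(mean_high, n)
  l <- rep_len(mean_low, n)
  zero <- h == 0 | l == 0
  h[zero] <- h[zero] + pseudocount
  l[zero] <- l[zero] + pseudocount
  r <- h / l
  ifelse(r >= 1, r, -1 / r)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in p-rank, capped at 1), computed
#' with [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted values, empty input giving an empty vector.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  check_fraction(pvals, "pvals")
  stats::p.adjust(pvals, method = "BH")
}

#' Call differential expression
#'
#' @param results data.frame with columns `fold_change` and `q`.
#' @param fc_cut,q_cut thresholds (defaults 2 and 0.05): DE iff
#'   `q < q_cut` and `|fold_change| > fc_cut`.
#' @return `results` with logical `is_de` added; attribute `de_counts`
#'   holds the number of up- and down-regulated calls.
#' @export
call_de <- function(results, fc_cut = 2, q_cut = 0.05) {
  results$is_de <- results$q < q_cut & abs(results$fold_change) > fc_cut
  attr(results, "de_counts") <-
    c(up = sum(results$is_de & results$fold_change > 0),
      down = sum(results$is_de & results$fold_change < 0))
  results
}

#' Differential-expression table for one high-vs-low contrast
#'
#' Sums counts over the samples of each group, runs the exact count test
#' per miRNA, computes CPM group means and signed fold changes
#' (high relative to low), BH-adjusts within the contrast and applies the
#' DE thresholds.
#'
#' @param counts integer matrix (miRNAs x samples).
#' @param design data.frame with columns `sample`, `group`.
#' @param high_group,low_group group labels of the contrast.
#' @inheritParams call_de
#' @return data.frame with `mirna`, `mean_high`, `mean_low`,
#'   `fold_change`, `p`, `q`, `is_de` (plus the `de_counts` attribute).
#' @export
run_de <- function(counts, design, high_group = "high", low_group = "low",
                   fc_cut = 2, q_cut = 0.05) {
  hi <- design$sample[design$group == high_group]
  lo <- design$sample[design$group == low_group]
  if (!length(hi) || !length(lo))
    stop("both contrast groups need at least one sample", call. = FALSE)
  ch <- rowSums(counts[, hi, drop = FALSE])
  cl <- rowSums(counts[, lo, drop = FALSE])
  lib_h <- sum(ch)
  lib_l <- sum(cl)
  cpm <- normalize_cpm(cbind(high = ch, low = cl))
  res <- data.frame(mirna = rownames(counts),
                    mean_high = cpm[, "high"],
                    mean_low = cpm[, "low"],
                    fold_change = fold_change(cpm[, "high"], cpm[, "low"]),
                    p = exact_count_test(ch, cl, lib_h, lib_l),
                    row.names = NULL)
  res$q <- bh_fdr(res$p)
  call_de(res, fc_cut, q_cut)
}
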