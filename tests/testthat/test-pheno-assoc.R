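test_that("whiteness index matches its closed form", {
  expect_equal(whiteness_index(100, 0, 0), 100)
  expect_equal(whiteness_index(50, 3, 4), 100 - sqrt(2525))
  # strictly decreasing in |a| at fixed L and b
  expect_lt(whiteness_index(50, 5, 4), whiteness_index(50, 3, 4))
})

test_that("delta-delta-Ct fold changes are powers of two", {
  expect_equal(ddct_fold_change(5, 6), 2)
  expect_equal(ddct_fold_change(6, 6), 1)
  expect_equal(ddct_fold_change(8, 6), 0.25)
})

test_that("Blom rank-inverse-normal transform uses the 3/8 offsets", {
  z <- rank_inverse_normal(c(3.2, 9.9, 7.1))
  expect_equal(sort(z), qnorm((c(1, 2, 3) - 3 / 8) / 3.25))
  expect_equal(sort(z)[2], 0)
  # invariant to strictly monotone transforms
  x <- rnorm(50)
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(exp(2 * x)))
  expect_equal(mean(rank_inverse_normal(x)), 0, tolerance = 1e-12)
  expect_error(rank_inverse_normal(rep(1, 5)), "constant")
  # transformed continuous data pass a normality screen
  y <- rank_inverse_normal(rexp(200))
  expect_gt(shapiro.test(y)$p.value, 0.05)
})

test_that("expression-phenotype regression reports signed r2 and p", {
  x <- seq(1, 10, length.out = 20)
  r <- regress_expression_phenotype(x, 2 * x)
  expect_equal(r$signed_r2, 1)
  expect_lt(r$p, 1e-10)
  r2 <- regress_expression_phenotype(x, -2 * x + rnorm(20, sd = 1e-8))
  expect_equal(r2$signed_r2, -1, tolerance = 1e-6)
  # the expression scale flips the sign (lower delta-Ct = more expression)
  r3 <- regress_expression_phenotype(x, 2 * x, expression_scale = TRUE)
  expect_equal(r3$signed_r2, -1)
  z <- regress_expression_phenotype(rep(1, 10), rnorm(10))
  expect_true(z$untestable)
})

test_that("combined variance reduces to r2 for one predictor and never shrinks", {
  set.seed(23)
  n <- 120
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.5 * x1 + 0.3 * x2 + rnorm(n)
  single <- combined_variance(cbind(x1 = x1), y)
  expect_equal(single$r2,
               regress_expression_phenotype(x1, y)$signed_r2,
               tolerance = 1e-12)
  both <- combined_variance(cbind(x1 = x1, x2 = x2), y)
  expect_gte(both$r2, single$r2)
  expect_warning(
    dup <- combined_variance(cbind(x1 = x1, x1b = x1, x2 = x2), y),
    "collinear")
  expect_equal(sort(dup$retained), c("x1", "x2"))
})

test_that("pairwise trait correlations are symmetric with unit diagonal", {
  set.seed(29)
  ph <- data.frame(t1 = rnorm(80), t2 = rnorm(80))
  ph$t3 <- ph$t1 * 0.8 + rnorm(80, sd = 0.4)
  pc <- pairwise_trait_correlation(ph)
  expect_equal(diag(pc$signed_r2), c(t1 = 1, t2 = 1, t3 = 1))
  expect_equal(pc$signed_r2, t(pc$signed_r2))
  expect_gt(pc$signed_r2["t1", "t3"], 0.3)
  # missing values are pairwise deleted with n reported
  ph$t2[1:10] <- NA
  pc2 <- pairwise_trait_correlation(ph)
  expect_equal(unname(pc2$n["t1", "t2"]), 70)
})

test_that("SNP association uses additive dosage on the transformed trait", {
  set.seed(37)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  y <- 0.4 * g + rnorm(n)
  a <- snp_association(g, y)
  expect_false(a$untestable)
  expect_gt(a$signed_r2, 0)
  expect_lt(a$p, 1e-4)
  # signed r2 equals the squared dosage-trait correlation with slope sign
  yy <- rank_inverse_normal(y)
  expect_equal(a$signed_r2, sign(cor(g, yy)) * cor(g, yy)^2)
  mono <- snp_association(rep(2, n), y)
  expect_true(mono$untestable)
  panel <- snp_association_panel(data.frame(g = g, h = rbinom(n, 2, 0.4)),
                                 y)
  expect_equal(nrow(panel), 2)
  expect_true(all(panel$q >= panel$p - 1e-12))
})

test_that("conditional association distinguishes independent and mediated effects", {
  set.seed(41)
  n <- 500
  focal <- rbinom(n, 2, 0.3)
  covar <- rbinom(n, 2, 0.4)
  y_ind <- 0.4 * focal + 0.3 * covar + rnorm(n)
  ca <- conditional_association(focal, cbind(c1 = covar), y_ind)
  expect_true(ca$independent)
  marg <- snp_association(focal, y_ind)
  expect_lt(abs(log10(ca$p_adjusted) - log10(marg$p)), 3)
  # fully mediated: the "focal" signal is the covariate's
  y_med <- 0.6 * covar + rnorm(n)
  cm <- conditional_association(covar + rbinom(n, 1, 0.02),
                                cbind(c1 = covar), y_med)
  expect_false(cm$independent)
  # duplicated focal as covariate exercises the collinearity path
  expect_warning(
    cd <- conditional_association(focal, cbind(c1 = focal, c2 = covar),
                                  y_ind),
    "collinear")
  expect_equal(cd$dropped, "c1")
})

test_that("IBS distances are metric-like and MDS separates subpopulations", {
  G <- rbind(a = c(0, 1, 2, 0), b = c(0, 1, 2, 0), c = c(2, 1, 0, 2))
  m <- ibs_mds(G, k = 1)
  expect_equal(m$dist["a", "b"], 0)
  expect_equal(m$dist, t(m$dist))
  expect_equal(unname(diag(m$dist)), rep(0, 3))
  set.seed(43)
  n_loci <- 60
  p1 <- runif(n_loci, 0.05, 0.3)
  p2 <- runif(n_loci, 0.7, 0.95)
  pop1 <- sapply(p1, function(p) rbinom(30, 2, p))
  pop2 <- sapply(p2, function(p) rbinom(30, 2, p))
  mm <- ibs_mds(rbind(pop1, pop2), k = 2)
  x <- mm$coords[, 1]
  lab <- rep(c(1, 2), each = 30)
  # silhouette-style separation on the first coordinate
  within <- c(sd(x[lab == 1]), sd(x[lab == 2]))
  between <- abs(mean(x[lab == 1]) - mean(x[lab == 2]))
  expect_gt(between, 4 * max(within))
})

test_that("group comparison handles degenerate and symmetric inputs", {
  g <- group_compare(c(5, 5, 5), c(5, 5, 5))
  expect_equal(g$p, 1)
  set.seed(47)
  hi <- rnorm(4, 20); lo <- rnorm(4, 10)
  a <- group_compare(hi, lo)
  b <- group_compare(lo, hi)
  expect_lt(a$p, 0.01)
  expect_equal(a$p, b$p)
  expect_equal(a$mean_high - a$mean_low, -(b$mean_high - b$mean_low))
  expect_true(is.na(group_compare(5, c(1, 2))$p))
})

test_that("expression-pair screening gates on positive correlation", {
  set.seed(53)
  base <- matrix(rnorm(40), 4, 10,
                 dimnames = list(sprintf("m%d", 1:4), sprintf("s%d", 1:10)))
  tpm <- rbind(g1 = base["m1", ] * 3 + rnorm(10, sd = 0.1),
               g2 = -base["m2", ] * 3 + rnorm(10, sd = 0.1),
               g3 = rnorm(10))
  colnames(tpm) <- colnames(base)
  pairs <- data.frame(mirna = c("m1", "m2", "m3"),
                      gene_id = c("g1", "g2", "g3"))
  got <- correlate_expression_pairs(base, tpm, pairs)
  expect_equal(got$mirna, "m1")        # anti-correlated m2/g2 excluded
  expect_gt(got$r2, 0.7)
  expect_error(correlate_expression_pairs(base[, 1:3], tpm[, 1:3], pairs),
               "4 shared samples")
})
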