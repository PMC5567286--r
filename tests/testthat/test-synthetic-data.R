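test_that("miRNA generation is deterministic with unique names and bounded lengths", {
  m <- gen_mirnas(1, length_range = c(22, 22), rng_seed = 7)
  expect_equal(nchar(m$sequence), 22)
  expect_equal(gen_mirnas(5, rng_seed = 7), gen_mirnas(5, rng_seed = 7))
  big <- gen_mirnas(100, rng_seed = 1)
  expect_equal(length(unique(big$name)), 100)
  expect_true(all(grepl("^[ACGU]+$", big$sequence)))
  expect_true(all(nchar(big$sequence) >= 18 & nchar(big$sequence) <= 26))
  expect_error(gen_mirnas(0), "integer >= 1")
  expect_error(gen_mirnas(3, length_range = c(10, 22)), "within")
})

test_that("planting self-verifies every SNP class and is deterministic", {
  mirnas <- gen_mirnas(10, rng_seed = 3)
  utrs <- gen_utrs(8, rng_seed = 3)
  b <- plant_sites_and_snps(utrs, mirnas, 6, 6, 4, rng_seed = 9)
  expect_equal(as.integer(table(b$snps$class)[c("create", "destroy",
                                                "neutral")]),
               c(6L, 6L, 4L))
  # re-classification recovers the planted classes exactly
  imp <- classify_snps(b$snps, b$utrs, b$mirnas, keep_none = TRUE)
  per_snp <- tapply(imp$classification, imp$snp_id, function(x) {
    if (any(x == "destroyed")) "destroyed"
    else if (any(x == "created")) "created" else "none"
  })
  want <- c(destroy = "destroyed", create = "created", neutral = "none")
  expect_equal(as.character(per_snp[b$snps$snp_id]),
               unname(want[b$snps$class]))
  # planted site intervals lie within their UTRs
  utr_len <- stats::setNames(nchar(b$utrs$sequence), b$utrs$gene_id)
  expect_true(all(b$planted_sites$start >= 0))
  expect_true(all(b$planted_sites$end <=
                    utr_len[b$planted_sites$gene_id]))
  b2 <- plant_sites_and_snps(utrs, mirnas, 6, 6, 4, rng_seed = 9)
  expect_identical(b, b2)
  # empty request yields a valid empty bundle
  b0 <- plant_sites_and_snps(utrs, mirnas, 0, 0, 0, rng_seed = 1)
  expect_equal(nrow(b0$snps), 0L)
})

test_that("simulated counts follow the planted fold change and dispersion", {
  mir <- data.frame(name = sprintf("m%d", 1:8))
  # unit fold change: Monte-Carlo mean ratio within 3 SE of 1
  reps <- 400
  set.seed(1)
  ratios <- vapply(seq_len(reps), function(r) {
    m <- simulate_counts(mir, depth = 5e3, dispersion = 0.05, rng_seed = r)
    mean(m[, "high"]) / mean(m[, "low"])
  }, numeric(1))
  se <- sd(ratios) / sqrt(reps)
  expect_lt(abs(mean(ratios) - 1), 3 * se)
  # dispersion zero is Poisson: variance about equal to the mean
  pois <- vapply(1:2000, function(r)
    simulate_counts(mir[1, , drop = FALSE], depth = 200, dispersion = 0,
                    rng_seed = r)[1, "high"], numeric(1))
  expect_lt(abs(var(pois) / mean(pois) - 1), 0.2)
  # planted fold change shifts the group-mean ratio
  fc <- stats::setNames(rep(3, 8), mir$name)
  m3 <- simulate_counts(mir, depth = 1e5, de_truth = fc, dispersion = 0,
                        rng_seed = 2)
  expect_equal(sum(m3[, "high"]) / sum(m3[, "low"]), 3, tolerance = 0.05)
  # degenerate depth
  expect_true(all(simulate_counts(mir, depth = 0, rng_seed = 1) == 0))
  expect_error(simulate_counts(mir, depth = -1), "depth")
  expect_error(simulate_counts(mir, dispersion = -1), "dispersion")
})

test_that("pooled allele depths concentrate on the true frequencies", {
  snps <- data.frame(snp_id = c("a", "b"))
  fbg <- data.frame(snp_id = rep(c("a", "b"), each = 2),
                    group = rep(c("high", "low"), 2),
                    freq = c(0.5, 0.5, 0, 0.4))
  d <- simulate_pooled_alleles(snps, fbg, depth_range = c(1e5, 1e5),
                               rng_seed = 4)
  fa <- d$alt_depth / (d$ref_depth + d$alt_depth)
  ratio <- fa[d$snp_id == "a" & d$group == "high"] /
    fa[d$snp_id == "a" & d$group == "low"]
  expect_gt(ratio, 0.97)
  expect_lt(ratio, 1.03)
  expect_equal(d$alt_depth[d$snp_id == "b" & d$group == "high"], 0L)
  expect_identical(d, simulate_pooled_alleles(snps, fbg,
                                              depth_range = c(1e5, 1e5),
                                              rng_seed = 4))
  expect_error(
    simulate_pooled_alleles(snps, transform(fbg, freq = freq + 1)),
    "\\[0, 1\\]")
})

test_that("phenotype simulation recovers planted variance components", {
  # no effects: standardized trait variance = family_sd^2 + residual_sd^2
  spec1 <- data.frame(trait = "t", mean = 0, sd = 1)
  p0 <- simulate_phenotypes(n_families = 300, fish_per_family = 5,
                            family_sd = 0.6, residual_sd = 0.8,
                            n_null_snps = 0, trait_spec = spec1,
                            rng_seed = 5)
  expect_equal(var(p0$phenotypes$t), 1, tolerance = 0.1)
  expect_equal(nrow(p0$phenotypes), 1500)
  # family effect is shared within families
  fam_means <- tapply(p0$phenotypes$t, p0$phenotypes$family, mean)
  expect_gt(var(fam_means), 0.2)   # ~ 0.36 + 0.64/5

  # a SNP planted at 5% of variance is recovered by the association stage
  ge <- data.frame(snp_id = "qtl", trait = "t", frac = 0.05, maf = 0.3)
  r2 <- vapply(1:10, function(s) {
    p <- simulate_phenotypes(n_families = 160, fish_per_family = 5,
                             genotype_effects = ge, n_null_snps = 0,
                             trait_spec = spec1, rng_seed = s)
    snp_association(p$genotypes$qtl, p$phenotypes$t)$signed_r2
  }, numeric(1))
  expect_gt(mean(r2), 0.03)
  expect_lt(mean(r2), 0.07)

  # study-shaped output: 98 families x 5 fish with derived whiteness
  full <- simulate_phenotypes(rng_seed = 6)
  expect_equal(nrow(full$phenotypes), 490)
  expect_equal(full$phenotypes$whiteness,
               whiteness_index(full$phenotypes$L, full$phenotypes$a,
                               full$phenotypes$b))
  expect_error(
    simulate_phenotypes(genotype_effects = data.frame(
      snp_id = c("a", "b"), trait = "t", frac = c(0.6, 0.5), maf = 0.3),
      trait_spec = data.frame(trait = "t", mean = 0, sd = 1)),
    "sum to < 1")
  expect_error(simulate_phenotypes(family_sd = -1), "non-negative")
})

test_that("the assembled truth bundle carries consistent truth slots", {
  b <- make_truth_bundle(n_mirnas = 12, n_utrs = 10, n_destroy = 4,
                         n_create = 4, n_neutral = 2, rng_seed = 8)
  expect_s3_class(data.frame(), "data.frame")
  expect_true(all(b$de_truth > 0))
  expect_equal(nrow(b$imbalance_truth), nrow(b$snps))
  neutral <- b$snps$class == "neutral"
  expect_true(all(b$imbalance_truth$freq_high[neutral] ==
                    b$imbalance_truth$freq_low[neutral]))
  eff <- b$imbalance_truth[!neutral, ]
  expect_true(all(pmax(eff$freq_high / eff$freq_low,
                       eff$freq_low / eff$freq_high) >= 2))
  expect_true(all(b$effect_truth$frac < 1))
})
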