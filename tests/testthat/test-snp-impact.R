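# Worked example: seed 2-8 = AGGCACU with mature position 9 = A; the UTR
# hosts the perfect 7-mer window AGTGCCT preceded by G so the position-9
# pairing is a hard mismatch (keeping the 8-mer allowance spent).
mir_panel <- data.frame(name = "mir-x",
                        sequence = "AAGGCACUAAUCGAUCGAUCGA")
utr_host <- paste0("AAAAA", "G", "AGTGCCT", "AAAAA")  # site window at [6,13)

test_that("apply_allele substitutes a single base and validates its inputs", {
  expect_equal(apply_allele("AGTGCCT", 5, "C", "A", "C"), "AGTGCCT")
  expect_equal(apply_allele("AGTGCCT", 5, "C", "A", "A"), "AGTGACT")
  expect_error(apply_allele("AGTGCCT", 9, "C", "A", "A"), "outside")
  expect_error(apply_allele("AGTGCCT", 2, "C", "A", "A"),
               "reference mismatch")
})

test_that("a SNP breaking a seed pairing destroys the site", {
  snp <- list(snp_id = "s1", gene_id = "g1", position = 11L,
              ref = "C", alt = "A")
  imp <- classify_snp(snp, utr_host, mir_panel)
  expect_equal(imp$classification, "destroyed")
  expect_equal(imp$effect_allele, "A")
  expect_false(is.na(imp$ref_site_start))
  expect_true(is.na(imp$alt_site_start))
})

test_that("the symmetric SNP creates the site under the alternate allele", {
  utr_broken <- sub("AGTGCCT", "AGTGACT", utr_host)
  snp <- list(snp_id = "s2", gene_id = "g1", position = 11L,
              ref = "A", alt = "C")
  imp <- classify_snp(snp, utr_broken, mir_panel)
  expect_equal(imp$classification, "created")
  expect_equal(imp$effect_allele, "C")
})

test_that("a SNP outside any seed window has no effect", {
  snp <- list(snp_id = "s3", gene_id = "g1", position = 2L,
              ref = "A", alt = "T")
  imp <- classify_snp(snp, utr_host, mir_panel)
  expect_equal(imp$classification, "none")
})

test_that("classification is symmetric under ref/alt swap", {
  snp <- list(snp_id = "s1", gene_id = "g1", position = 11L,
              ref = "C", alt = "A")
  swapped <- list(snp_id = "s1", gene_id = "g1", position = 11L,
                  ref = "A", alt = "C")
  utr_alt <- apply_allele(utr_host, 11L, "C", "A", "A")
  a <- classify_snp(snp, utr_host, mir_panel)
  b <- classify_snp(swapped, utr_alt, mir_panel)
  expect_equal(b$classification, "created")   # same site, seen from alt side
  expect_equal(a$effect_allele, "A")
  expect_equal(b$effect_allele, "C")          # allele carrying the site
})

test_that("classification ignores sequence edits far from the SNP", {
  snp <- list(snp_id = "s1", gene_id = "g1", position = 11L,
              ref = "C", alt = "A")
  # appended sequence starts more than (max seed length - 1) nt away
  edited <- paste0(utr_host, "CGCG", paste(rep("T", 30), collapse = ""))
  a <- classify_snp(snp, utr_host, mir_panel)
  b <- classify_snp(snp, edited, mir_panel)
  expect_equal(a$classification, b$classification)
})

test_that("mress_bracket renders the site with the SNP in brackets", {
  expect_equal(mress_bracket("AAAAAGAGTGCCTAAAAA", 5L, 13L, 11L, "C", "A"),
               "GAGTG[C/A]CT")
})

test_that("pooled frequency filters apply strict thresholds", {
  d <- data.frame(snp_id = rep(c("a", "b", "c", "d"), each = 2),
                  group = rep(c("high", "low"), 4),
                  ref_depth = c(5, 4,  48, 48,  20, 10,  0, 0),
                  alt_depth = c(1, 0,   2,  2,   5,  5,  0, 0))
  f <- allele_frequencies(d)
  expect_equal(f$filter_reason[f$snp_id == "a"], "min_reads")   # total 10
  expect_equal(f$filter_reason[f$snp_id == "b"], "min_minor")   # minor 4
  expect_true(f$pass[f$snp_id == "c"])                          # 10/40 = 0.25
  expect_equal(f$maf[f$snp_id == "c"], 0.25)
  expect_equal(f$filter_reason[f$snp_id == "d"], "no coverage")
  expect_error(allele_frequencies(transform(d, alt_depth = -1)),
               "non-negative")
})

test_that("imbalance ratios and flags follow the inclusive convention", {
  r <- imbalance_ratio(0.25, 0.75)
  expect_equal(r$ratio, 1 / 3)
  expect_equal(r$flag, "LOH")
  expect_equal(imbalance_ratio(0.5, 0.5)$flag, "none")
  expect_equal(imbalance_ratio(0.5, 0.25)$flag, "amplification")  # exactly 2
  expect_equal(imbalance_ratio(0.5, 0.25, strict = TRUE)$flag, "none")
  z <- imbalance_ratio(0.25, 0)
  expect_true(is.infinite(z$ratio))
  expect_equal(z$flag, "amplification")
  expect_true(z$low_freq_zero)
  expect_equal(z$ratio_str, "0.25/0")
  expect_equal(imbalance_ratio(0, 0)$flag, "none")
  expect_true(is.na(imbalance_ratio(0, 0)$ratio))
  # reciprocal symmetry where both ratios are defined
  a <- imbalance_ratio(0.6, 0.2)$ratio
  b <- imbalance_ratio(0.2, 0.6)$ratio
  expect_equal(a, 1 / b)
})

test_that("candidates require both an impact class and an imbalance flag", {
  impacts <- data.frame(snp_id = c("a", "b", "c"),
                        mirna = "mir-x",
                        classification = c("destroyed", "destroyed",
                                           "created"),
                        effect_allele = c("T", "T", "G"))
  freqs <- data.frame(snp_id = c("a", "b", "c"),
                      freq_high = c(0.6, 0.4, 0.1),
                      freq_low = c(0.1, 0.4, 0.6),
                      pass = TRUE)
  snps <- data.frame(snp_id = c("a", "b", "c"),
                     ref = c("C", "C", "G"), alt = c("T", "T", "A"))
  sc <- screen_candidates(impacts, freqs, snps)
  expect_true(sc$is_candidate[sc$snp_id == "a"])     # destroyed + amp
  expect_false(sc$is_candidate[sc$snp_id == "b"])    # destroyed, balanced
  # effect allele of c is ref (G): effect frequency = 1 - alt frequency
  expect_equal(sc$effect_freq_high[sc$snp_id == "c"], 0.9)
  expect_true(sc$is_candidate[sc$snp_id == "c"])
  expect_equal(unname(attr(sc, "class_counts")["destroyed"]), 1L)
  # unmatched keys are excluded with a warning
  expect_warning(
    screen_candidates(rbind(impacts,
                            data.frame(snp_id = "zz", mirna = "mir-x",
                                       classification = "destroyed",
                                       effect_allele = "T")),
                      freqs, snps),
    "no pooled record")
})

test_that("tightening any filter never admits a previously rejected record", {
  set.seed(9)
  d <- data.frame(snp_id = rep(sprintf("s%d", 1:40), each = 2),
                  group = rep(c("high", "low"), 40),
                  ref_depth = sample(0:60, 80, replace = TRUE),
                  alt_depth = sample(0:20, 80, replace = TRUE))
  loose <- allele_frequencies(d, min_reads = 10, min_minor = 4,
                              min_maf = 0.05)
  tight <- allele_frequencies(d, min_reads = 20, min_minor = 6,
                              min_maf = 0.10)
  expect_true(all(!loose$pass | !tight$pass | (loose$pass & tight$pass)))
  expect_true(all(tight$pass <= loose$pass))
})
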