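#' Synthetic study generator with planted ground truth
#'
#' Generates every input the pipeline consumes - mature miRNAs, 3'UTRs
#' with planted seed sites and site-destroying/creating/neutral SNPs,
#' pooled small-RNA counts and reads, pooled allele depths for divergent
#' family groups, and family-structured phenotypes with planted genotype
#' and expression effects - together with a truth record, so every stage
#' is testable without external data. The design emulates a pooled
#' family study: phenotypes over ~98 families of ~5 fish, one pooled
#' sequencing library per divergent family group.
#'
#' All generators are deterministic for a fixed `rng_seed`.
#'
#' @name synthetic_data
NULL

.sample_bases <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# DNA bases pairing a miRNA (RNA) base neither Watson-Crick nor wobble
.hard_mismatch <- function(mir_base) {
  switch(mir_base,
         A = c("A", "C", "G"),
         C = c("A", "C", "T"),
         G = c("A", "G"),
         U = c("C", "T"),
         stop("bad base"))
}

#' Generate mature miRNA sequences
#'
#' Random RNA sequences of mature-miRNA length (study reads averaged 22
#' nt) with unique names and, for planting robustness, pairwise-distinct
#' 6-mer seeds.
#'
#' @param n number of miRNAs (>= 1).
#' @param length_range inclusive length bounds within \[18, 26\] (default
#'   21-23).
#' @param rng_seed integer seed.
#' @return data.frame with columns `name`, `sequence`.
#' @export
gen_mirnas <- function(n, length_range = c(21L, 23L), rng_seed = 1L) {
  n <- check_scalar_count(n, "n", min = 1L)
  if (length_range[1L] < 18L || length_range[2L] > 26L ||
      length_range[1L] > length_range[2L])
    stop("length_range must lie within [18, 26]", call. = FALSE)
  set.seed(rng_seed)
  seqs <- character(n)
  seen_seeds <- character(0)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      len <- resample(seq.int(length_range[1L], length_range[2L]))
      s <- .sample_bases(len, RNA_BASES)
      seed6 <- substr(s, 2L, 7L)
      if (!seed6 %in% seen_seeds) break
      if (try == 1000) stop("could not generate distinct seeds")
    }
    seqs[i] <- s
    seen_seeds <- c(seen_seeds, seed6)
  }
  data.frame(name = sprintf("syn-mir-%d", seq_len(n)), sequence = seqs)
}

#' Generate random 3'UTR sequences
#'
#' @param n number of UTRs.
#' @param length_range inclusive length bounds (default 250-350 nt).
#' @param rng_seed integer seed.
#' @return data.frame with columns `gene_id`, `sequence` (DNA).
#' @export
gen_utrs <- function(n, length_range = c(250L, 350L), rng_seed = 1L) {
  n <- check_scalar_count(n, "n", min = 1L)
  set.seed(rng_seed)
  lens <- resample(seq.int(length_range[1L], length_range[2L]), n)
  data.frame(gene_id = sprintf("gene_%d", seq_len(n)),
             sequence = vapply(lens, .sample_bases, character(1),
                               alphabet = DNA_BASES))
}

# A destroy segment hosts an 8-mer site whose miRNA-position-9 pairing is a
# hard mismatch (so the site survives only through the 8-mer's one-mismatch
# allowance, or as the nested perfect 7-mer): one further seed mismatch
# removes the site at every length. A create segment additionally breaks
# one seed-region pairing; restoring it with the alternate allele creates
# the site.
.build_segment <- function(mir_chars, kind) {
  c9 <- sample(.hard_mismatch(mir_chars[9L]), 1L)
  w7 <- revcomp_dna(rna_to_dna(paste(mir_chars[2:8], collapse = "")))
  seg <- paste0(c9, w7)
  q <- sample(2:7, 1L)                 # seed position carrying the SNP
  jj <- 10L - q                        # 1-based offset within the segment
  wc <- .DNA_COMP[rna_to_dna(mir_chars[q])]
  hard <- sample(.hard_mismatch(mir_chars[q]), 1L)
  if (kind == "destroy") {
    ref <- wc
    alt <- hard
  } else {
    substr(seg, jj, jj) <- hard
    ref <- hard
    alt <- wc
  }
  list(segment = seg, snp_offset = jj, ref = unname(ref), alt = unname(alt))
}

.place_interval <- function(occupied, utr_len, seg_len, margin = 10L) {
  lo <- margin + 1L
  hi <- utr_len - seg_len - margin
  if (hi < lo) return(NULL)
  for (try in 1:50) {
    start <- resample(seq.int(lo, hi))
    iv <- c(start, start + seg_len - 1L)
    clash <- any(occupied[, 1L] <= iv[2L] + margin &
                   occupied[, 2L] >= iv[1L] - margin)
    if (!clash) return(iv)
  }
  NULL
}

#' Plant seed sites and classified SNPs into UTRs
#'
#' Embeds, for each requested SNP, a seed-site segment (destroy: site
#' present under the reference allele only; create: site appears under the
#' alternate allele only) or a site-free position (neutral). Every planted
#' SNP is self-verified by [classify_snp()] against the full miRNA panel:
#' the intended miRNA must give the intended class and all other miRNAs
#' class `none`; failed placements are retried up to `max_attempts` times
#' before a generation error names the constraint.
#'
#' @param utrs data.frame from [gen_utrs()] (background sequences are
#'   modified in the returned bundle).
#' @param mirnas data.frame from [gen_mirnas()].
#' @param n_destroy,n_create,n_neutral SNP counts per intended class.
#' @param rng_seed integer seed.
#' @param max_attempts placement retries per SNP (default 1000).
#' @return a `truth_bundle` list: `mirnas`, `utrs` (reference-allele
#'   sequences after planting), `snps` (snp_id, gene_id, position, ref,
#'   alt, class, mirna, effect_allele), `planted_sites` (reference-allele
#'   sites of destroy SNPs: mirna, gene_id, start, end, seed_len),
#'   and empty `de_truth`/`imbalance_truth`/`effect_truth` slots filled by
#'   the downstream simulators.
#' @export
plant_sites_and_snps <- function(utrs, mirnas, n_destroy, n_create,
                                 n_neutral, rng_seed = 1L,
                                 max_attempts = 1000L) {
  n_destroy <- check_scalar_count(n_destroy, "n_destroy")
  n_create <- check_scalar_count(n_create, "n_create")
  n_neutral <- check_scalar_count(n_neutral, "n_neutral")
  set.seed(rng_seed)
  seqs <- stats::setNames(utrs$sequence, utrs$gene_id)
  occupied <- lapply(seqs, function(x) matrix(numeric(0), ncol = 2L))
  mir_chars <- lapply(mirnas$sequence, function(s) split_chars(s))
  classes <- c(rep("destroy", n_destroy), rep("create", n_create),
               rep("neutral", n_neutral))
  snps <- list()
  sites <- list()
  for (s in seq_along(classes)) {
    kind <- classes[s]
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      mi <- sample(nrow(mirnas), 1L)
      gi <- sample(length(seqs), 1L)
      gene <- names(seqs)[gi]
      if (kind == "neutral") {
        iv <- .place_interval(occupied[[gi]], nchar(seqs[gi]), 1L)
        if (is.null(iv)) next
        pos <- iv[1L]
        ref <- substr(seqs[gi], pos, pos)
        alt <- sample(setdiff(DNA_BASES, ref), 1L)
        cand_seq <- seqs[gi]
      } else {
        built <- .build_segment(mir_chars[[mi]], kind)
        iv <- .place_interval(occupied[[gi]], nchar(seqs[gi]),
                              nchar(built$segment))
        if (is.null(iv)) next
        cand_seq <- seqs[gi]
        substr(cand_seq, iv[1L], iv[2L]) <- built$segment
        pos <- iv[1L] + built$snp_offset - 1L
        if (kind == "destroy") {
          # reference allele is already in place; record it
          ref <- built$ref
          alt <- built$alt
        } else {
          ref <- built$ref
          alt <- built$alt
        }
      }
      snp <- list(snp_id = sprintf("snp_%d", s), gene_id = gene,
                  position = pos, ref = ref, alt = alt)
      impacts <- classify_snp(snp, cand_seq, mirnas)
      want <- switch(kind, destroy = "destroyed", create = "created",
                     neutral = "none")
      target_ok <- if (kind == "neutral") TRUE else
        impacts$classification[impacts$mirna == mirnas$name[mi]] == want
      others <- if (kind == "neutral") impacts else
        impacts[impacts$mirna != mirnas$name[mi], , drop = FALSE]
      if (target_ok && all(others$classification == "none")) {
        seqs[gi] <- cand_seq
        occupied[[gi]] <- rbind(occupied[[gi]], matrix(iv, ncol = 2L))
        snps[[s]] <- data.frame(
          snp_id = snp$snp_id, gene_id = gene, position = pos,
          ref = ref, alt = alt, class = kind,
          mirna = if (kind == "neutral") NA_character_ else mirnas$name[mi],
          effect_allele = if (kind == "neutral") NA_character_ else alt)
        if (kind == "destroy") {
          row <- impacts[impacts$mirna == mirnas$name[mi], ]
          sites[[length(sites) + 1L]] <- data.frame(
            mirna = mirnas$name[mi], gene_id = gene,
            start = row$ref_site_start, end = row$ref_site_end,
            seed_len = row$ref_seed_len)
        }
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place a %s SNP after %d attempts (UTRs too short or too crowded)",
        kind, max_attempts), call. = FALSE)
  }
  out <- list(
    mirnas = mirnas,
    utrs = data.frame(gene_id = names(seqs), sequence = unname(seqs)),
    snps = if (length(snps)) do.call(rbind, snps) else
      data.frame(snp_id = character(), gene_id = character(),
                 position = integer(), ref = character(),
                 alt = character(), class = character(),
                 mirna = character(), effect_allele = character()),
    planted_sites = if (length(sites)) do.call(rbind, sites) else
      data.frame(mirna = character(), gene_id = character(),
                 start = integer(), end = integer(), seed_len = integer()),
    de_truth = NULL, imbalance_truth = NULL, effect_truth = NULL)
  class(out) <- "truth_bundle"
  out
}

#' Simulate pooled small-RNA counts
#'
#' Negative-binomial counts per miRNA per pool with mean `mu` and variance
#' `mu + dispersion * mu^2`; `dispersion = 0` gives Poisson counts
#' (technical sampling only, the regime of one pooled library per group).
#' Baseline abundances are gamma-distributed and the expected ratio of
#' high- to low-group means equals the planted fold change.
#'
#' @param mirnas data.frame with `name`.
#' @param groups two group labels (default `c("high", "low")`).
#' @param depth expected total reads of the low pool (>= 0).
#' @param de_truth named vector of true high/low fold changes (positive
#'   reals; default 1 for every miRNA).
#' @param dispersion NB dispersion `d` in `var = mu + d mu^2` (>= 0,
#'   default 0.05).
#' @param n_reps pools per group (default 1, mirroring pooled sequencing).
#' @param rng_seed integer seed.
#' @return integer count matrix, miRNAs x pools (columns `<group>` or
#'   `<group>_<rep>` when `n_reps > 1`).
#' @export
simulate_counts <- function(mirnas, groups = c("high", "low"), depth = 1e5,
                            de_truth = NULL, dispersion = 0.05,
                            n_reps = 1L, rng_seed = 1L) {
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  stopifnot(length(groups) == 2L)
  set.seed(rng_seed)
  n <- nrow(mirnas)
  fc <- rep(1, n)
  names(fc) <- mirnas$name
  if (!is.null(de_truth)) {
    if (any(de_truth <= 0)) stop("fold changes must be positive", call. = FALSE)
    fc[names(de_truth)] <- de_truth
  }
  w <- stats::rgamma(n, shape = 0.8)
  w <- w / sum(w)
  mu_low <- depth * w
  mu_high <- mu_low * fc
  draw <- function(mu) {
    if (depth == 0) return(rep(0L, n))
    if (dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  cols <- list()
  for (r in seq_len(n_reps)) {
    cols[[length(cols) + 1L]] <- draw(mu_high)
    cols[[length(cols) + 1L]] <- draw(mu_low)
  }
  m <- do.call(cbind, cols)
  colnames(m) <- if (n_reps == 1L) groups else
    as.vector(vapply(seq_len(n_reps),
                     function(r) paste0(groups, "_", r), character(2)))
  rownames(m) <- mirnas$name
  storage.mode(m) <- "integer"
  m
}

#' Simulate adapter-containing small-RNA reads for one pool
#'
#' Emits `counts[i]` reads per miRNA: the canonical mature sequence (as
#' DNA) or, at rate `isomir_rate`, an isomiR variant with end shifts of up
#' to 1 nt and/or one internal substitution - always within the
#' annotation tolerance. The 3' sequencing adapter is appended to every
#' read.
#'
#' @param mirnas data.frame with `name`, `sequence`.
#' @param counts named integer vector of reads per miRNA.
#' @param adapter 3' adapter appended to each read.
#' @param isomir_rate fraction of variant reads (default 0.2).
#' @param rng_seed integer seed.
#' @return data.frame with `id`, `sequence` in randomized order.
#' @export
simulate_reads <- function(mirnas, counts, adapter = default_adapter(),
                           isomir_rate = 0.2, rng_seed = 1L) {
  set.seed(rng_seed)
  seqs <- list()
  for (i in seq_len(nrow(mirnas))) {
    k <- counts[[mirnas$name[i]]] %||% 0L
    if (k == 0L) next
    base <- rna_to_dna(mirnas$sequence[i])
    reads <- rep(base, k)
    nv <- stats::rbinom(1L, k, isomir_rate)
    if (nv > 0L) {
      for (j in seq_len(nv)) {
        s <- base
        if (stats::runif(1) < 0.5) {       # 5' shift
          if (stats::runif(1) < 0.5) s <- substr(s, 2L, nchar(s))
          else s <- paste0(sample(DNA_BASES, 1L), s)
        }
        if (stats::runif(1) < 0.5) {       # 3' shift
          if (stats::runif(1) < 0.5) s <- substr(s, 1L, nchar(s) - 1L)
          else s <- paste0(s, sample(DNA_BASES, 1L))
        }
        if (stats::runif(1) < 0.4) {       # one internal substitution
          p <- sample(nchar(s), 1L)
          substr(s, p, p) <- sample(setdiff(DNA_BASES,
                                            substr(s, p, p)), 1L)
        }
        reads[j] <- s
      }
    }
    seqs[[i]] <- reads
  }
  all <- unlist(seqs)
  if (is.null(all)) all <- character(0)
  all <- sample(all)
  data.frame(id = sprintf("read_%d", seq_along(all)),
             sequence = paste0(all, adapter))
}

#' Simulate pooled allele depths per family group
#'
#' Binomial alternate-allele read counts at each SNP in each group, at the
#' group's true alternate-allele frequency and a uniformly drawn total
#' depth.
#'
#' @param snps data.frame with `snp_id`.
#' @param freq_by_group data.frame with `snp_id`, `group`, `freq`
#'   (alternate-allele frequency in \[0, 1\]).
#' @param depth_range inclusive bounds for per-SNP per-group total depth
#'   (default 150-250 reads).
#' @param rng_seed integer seed.
#' @return data.frame with `snp_id`, `group`, `ref_depth`, `alt_depth`.
#' @export
simulate_pooled_alleles <- function(snps, freq_by_group,
                                    depth_range = c(150L, 250L),
                                    rng_seed = 1L) {
  check_fraction(freq_by_group$freq, "freq")
  set.seed(rng_seed)
  fb <- freq_by_group[freq_by_group$snp_id %in% snps$snp_id, , drop = FALSE]
  depth <- resample(seq.int(depth_range[1L], depth_range[2L]), nrow(fb))
  alt <- stats::rbinom(nrow(fb), depth, fb$freq)
  data.frame(snp_id = fb$snp_id, group = fb$group,
             ref_depth = depth - alt, alt_depth = alt)
}

#' Default trait scales for the phenotype simulator
#'
#' Means and SD scales in the units of a growth-selected trout
#' population: whole body weight in grams, muscle yield and crude fat as
#' percentages, shear force in g force/g, and colorimeter L*/a*/b* from
#' which the whiteness index is derived.
#'
#' @return data.frame with `trait`, `mean`, `sd`.
#' @export
default_trait_spec <- function() {
  data.frame(
    trait = c("WBW", "muscle_yield", "crude_fat", "shear_force",
              "L", "a", "b"),
    mean = c(860, 47, 7, 425, 46, 2.5, 6),
    sd = c(250, 3, 2, 80, 2, 0.8, 1.2))
}

#' Simulate family-structured phenotypes, genotypes and qPCR Ct values
#'
#' Each measured trait is `mean + sd * z` with standardized composite
#' `z = family effect + sum(effects) + residual`: the family effect is
#' `N(0, family_sd^2)` shared within full-sib families, effects are scaled
#' so each planted predictor explains its stated fraction of the total
#' trait variance, and genotypes follow Hardy-Weinberg proportions with
#' additive 0/1/2 coding. Expression predictors are per-fish delta-Ct
#' values (target Ct minus U6 reference Ct). The whiteness index is always
#' derived from the simulated L*/a*/b* readings via the closed form;
#' effects planted on `"whiteness"` are routed through L*.
#'
#' @param n_families,fish_per_family study size (defaults 98 and 5).
#' @param genotype_effects data.frame with `snp_id`, `trait`, `frac`
#'   (fraction of trait variance in \[0,1)), `maf`; or NULL.
#' @param expression_effects data.frame with `mirna`, `trait`, `frac`; or
#'   NULL.
#' @param family_sd,residual_sd SD of the family and residual components
#'   of the standardized composite (defaults 0.6 and 0.8).
#' @param n_null_snps,null_maf additional effect-free SNPs (default 10 at
#'   MAF 0.3).
#' @param trait_spec data.frame as [default_trait_spec()].
#' @param rng_seed integer seed.
#' @return list with `phenotypes` (fish_id, family, traits, whiteness),
#'   `genotypes` (fish_id + one dosage column per SNP), `ct` (long table:
#'   fish_id, mirna, ct_target, ct_reference, dct), `effect_truth`.
#' @export
simulate_phenotypes <- function(n_families = 98L, fish_per_family = 5L,
                                genotype_effects = NULL,
                                expression_effects = NULL,
                                family_sd = 0.6, residual_sd = 0.8,
                                n_null_snps = 10L, null_maf = 0.3,
                                trait_spec = default_trait_spec(),
                                rng_seed = 1L) {
  if (family_sd < 0 || residual_sd < 0)
    stop("variance components must be non-negative", call. = FALSE)
  set.seed(rng_seed)
  n <- n_families * fish_per_family
  fam <- rep(sprintf("fam_%d", seq_len(n_families)), each = fish_per_family)
  fish <- sprintf("fish_%d", seq_len(n))

  eff <- rbind(
    if (!is.null(genotype_effects))
      data.frame(predictor = genotype_effects$snp_id, type = "snp",
                 trait = genotype_effects$trait,
                 frac = genotype_effects$frac,
                 maf = genotype_effects$maf),
    if (!is.null(expression_effects))
      data.frame(predictor = expression_effects$mirna, type = "mirna",
                 trait = expression_effects$trait,
                 frac = expression_effects$frac, maf = NA_real_))
  if (!is.null(eff)) {
    check_fraction(eff$frac, "frac")
    tot <- tapply(eff$frac, eff$trait, sum)
    if (any(tot >= 1))
      stop("effect fractions for a trait must sum to < 1", call. = FALSE)
  }

  # predictors: genotype dosages and standardized delta-Ct values
  snp_ids <- unique(c(if (!is.null(eff)) eff$predictor[eff$type == "snp"],
                      if (n_null_snps > 0) sprintf("null_snp_%d",
                                                   seq_len(n_null_snps))))
  G <- matrix(NA_integer_, n, length(snp_ids),
              dimnames = list(NULL, snp_ids))
  for (s in snp_ids) {
    maf <- if (!is.null(eff) && s %in% eff$predictor[eff$type == "snp"])
      eff$maf[match(s, eff$predictor)] else null_maf
    G[, s] <- stats::rbinom(n, 2L, maf)
  }
  mir_ids <- if (!is.null(eff)) unique(eff$predictor[eff$type == "mirna"])
             else character(0)
  DCT <- matrix(stats::rnorm(n * length(mir_ids), mean = 5, sd = 1), n,
                length(mir_ids), dimnames = list(NULL, mir_ids))

  std_pred <- function(type, id) {
    if (type == "snp") {
      maf <- eff$maf[match(id, eff$predictor)]
      (G[, id] - 2 * maf) / sqrt(2 * maf * (1 - maf))
    } else {
      DCT[, id] - 5
    }
  }

  base_var <- family_sd^2 + residual_sd^2
  pheno <- data.frame(fish_id = fish, family = fam)
  for (k in seq_len(nrow(trait_spec))) {
    tr <- trait_spec$trait[k]
    fam_eff <- stats::rnorm(n_families, 0, family_sd)[as.integer(
      factor(fam, levels = unique(fam)))]
    z <- fam_eff + stats::rnorm(n, 0, residual_sd)
    rows <- if (!is.null(eff))
      which(eff$trait == tr | (tr == "L" & eff$trait == "whiteness"))
    else integer(0)
    f_tot <- if (length(rows)) sum(eff$frac[rows]) else 0
    v_tot <- base_var / (1 - f_tot)
    for (r in rows) {
      beta <- sqrt(eff$frac[r] * v_tot)
      z <- z + beta * std_pred(eff$type[r], eff$predictor[r])
    }
    pheno[[tr]] <- trait_spec$mean[k] +
      trait_spec$sd[k] * z / sqrt(base_var)
  }
  if (all(c("L", "a", "b") %in% names(pheno)))
    pheno$whiteness <- whiteness_index(pheno$L, pheno$a, pheno$b)

  ct <- NULL
  if (length(mir_ids)) {
    ct_ref <- stats::rnorm(n, 18, 0.3)
    ct <- do.call(rbind, lapply(mir_ids, function(m) {
      data.frame(fish_id = fish, mirna = m,
                 ct_target = ct_ref + DCT[, m], ct_reference = ct_ref,
                 dct = DCT[, m])
    }))
  }
  list(phenotypes = pheno,
       genotypes = data.frame(fish_id = fish, G, check.names = FALSE),
       ct = ct,
       effect_truth = eff)
}

#' Build a complete synthetic study with planted truth
#'
#' Convenience constructor chaining [gen_mirnas()], [gen_utrs()],
#' [plant_sites_and_snps()], and attaching the differential-expression,
#' allelic-imbalance and phenotype-effect truths used by the simulators:
#' a subset of miRNAs receives true fold changes, destroy/create SNPs
#' receive divergent effect-allele frequencies between the high and low
#' family groups (half as amplification, half as loss of heterozygosity),
#' and neutral SNPs stay balanced.
#'
#' @param n_mirnas,n_utrs panel sizes.
#' @param n_destroy,n_create,n_neutral planted SNP counts.
#' @param n_de number of miRNAs given a true fold change `de_fc`.
#' @param de_fc true high/low fold change of the DE miRNAs (default 4).
#' @param effect_frac variance fraction of each planted effect SNP
#'   (default 0.05 on `muscle_yield`).
#' @param rng_seed integer seed.
#' @return a `truth_bundle` with `de_truth`, `imbalance_truth` and
#'   `effect_truth` populated.
#' @export
make_truth_bundle <- function(n_mirnas = 15L, n_utrs = 12L, n_destroy = 10L,
                              n_create = 10L, n_neutral = 5L, n_de = 4L,
                              de_fc = 4, effect_frac = 0.05,
                              rng_seed = 1L) {
  mirnas <- gen_mirnas(n_mirnas, rng_seed = derive_seed(rng_seed, "mirnas"))
  utrs <- gen_utrs(n_utrs, rng_seed = derive_seed(rng_seed, "utrs"))
  bundle <- plant_sites_and_snps(utrs, mirnas, n_destroy, n_create,
                                 n_neutral,
                                 rng_seed = derive_seed(rng_seed, "plant"))
  de <- rep(de_fc, min(n_de, n_mirnas))
  names(de) <- mirnas$name[seq_along(de)]
  bundle$de_truth <- de

  snps <- bundle$snps
  eff_rows <- snps$class != "neutral"
  amp <- rep(c(TRUE, FALSE), length.out = sum(eff_rows))
  f_hi <- ifelse(amp, 0.6, 0.1)
  f_lo <- ifelse(amp, 0.1, 0.6)
  freq_high <- freq_low <- rep(0.35, nrow(snps))   # balanced neutral SNPs
  freq_high[eff_rows] <- f_hi
  freq_low[eff_rows] <- f_lo
  # stated as effect-allele frequencies; effect allele is alt by
  # construction, so these are alternate-allele frequencies directly
  bundle$imbalance_truth <- data.frame(snp_id = snps$snp_id,
                                       freq_high = freq_high,
                                       freq_low = freq_low)
  ge <- snps$snp_id[snps$class == "destroy"][1:2]
  ge <- ge[!is.na(ge)]
  bundle$effect_truth <- if (length(ge))
    data.frame(snp_id = ge, trait = "muscle_yield", frac = effect_frac,
               maf = 0.3)
  else NULL
  bundle
}
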