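#' Pipeline configuration
#'
#' Collects paths, thresholds and the RNG seed for [run_pipeline()]. When
#' `simulate = TRUE` (default) all inputs are generated by the
#' synthetic-study generator into `out_dir/inputs`; otherwise every input
#' path must exist.
#'
#' @param out_dir output directory (created if needed).
#' @param simulate generate synthetic inputs (default TRUE).
#' @param mirna_fasta,utr_fasta,reads_high,reads_low,vcf,design_tsv,
#'   phenotype_tsv,genotype_tsv user input paths (ignored when
#'   `simulate = TRUE`).
#' @param adapter 3' sequencing adapter.
#' @param min_len,max_len read length filter bounds.
#' @param energy_cutoff duplex-energy threshold for site reporting
#'   (kcal/mol, default -15).
#' @param fc_cut,q_cut differential-expression thresholds (default 2 and
#'   0.05).
#' @param imbalance_upper,imbalance_lower allelic-imbalance flag
#'   thresholds (default 2.0 and 0.5, inclusive).
#' @param min_reads,min_minor,min_maf pooled variant filters (strict
#'   inequalities; defaults 10, 4, 0.05).
#' @param traits traits to associate (default `c("WBW", "muscle_yield")`).
#' @param sim list of generator settings overriding
#'   [make_truth_bundle()] / simulator defaults: `n_mirnas`, `n_utrs`,
#'   `n_destroy`, `n_create`, `n_neutral`, `n_de`, `de_fc`, `read_depth`, `dispersion`, `n_families`, `fish_per_family`.
#' @param rng_seed master seed; every stage derives its own stream from
#'   it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, mirna_fasta = NULL,
                            utr_fasta = NULL, reads_high = NULL,
                            reads_low = NULL, vcf = NULL,
                            design_tsv = NULL, phenotype_tsv = NULL,
                            genotype_tsv = NULL,
                            adapter = default_adapter(), min_len = 16L,
                            max_len = 28L, energy_cutoff = -15,
                            fc_cut = 2, q_cut = 0.05,
                            imbalance_upper = 2.0, imbalance_lower = 0.5,
                            min_reads = 10, min_minor = 4, min_maf = 0.05,
                            traits = c("WBW", "muscle_yield"),
                            sim = list(), rng_seed = 1L) {
  cfg <- as.list(environment())
  sim_defaults <- list(n_mirnas = 60L, n_utrs = 12L, n_destroy = 10L,
                       n_create = 10L, n_neutral = 5L, n_de = 5L,
                       de_fc = 4, read_depth = 1e4,
                       dispersion = 0, n_families = 98L,
                       fish_per_family = 5L)
  cfg$sim <- utils::modifyList(sim_defaults, sim)
  if (!simulate) {
    paths <- c(mirna_fasta, utr_fasta, reads_high, reads_low, vcf,
               design_tsv, phenotype_tsv, genotype_tsv)
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing))
      stop(sprintf("missing input file(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Executes quantify -> differential expression -> seed-site scan -> SNP
#' impact classification -> imbalance screen -> phenotype association,
#' writing one TSV per stage plus a machine-readable `summary.json` to
#' `out_dir`. Fully deterministic for a fixed `rng_seed`. A stage failure
#' halts the run with the failing stage named; outputs of completed
#' stages are retained.
#'
#' @param config a [pipeline_config()] list.
#' @return the summary list, invisibly; side effect: per-stage TSVs,
#'   `summary.json`, and (in synthetic mode) the generated inputs and a
#'   truth TSV (never read by the pipeline itself).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$rng_seed
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    .log_stage(name, "done in %.2fs",
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  summary <- list(seed = seed)

  # ---- inputs ------------------------------------------------------------
  if (config$simulate) {
    inp <- file.path(out_dir, "inputs")
    dir.create(inp, showWarnings = FALSE)
    sim <- config$sim
    gen <- stage("simulate", {
      bundle <- make_truth_bundle(
        n_mirnas = sim$n_mirnas, n_utrs = sim$n_utrs,
        n_destroy = sim$n_destroy, n_create = sim$n_create,
        n_neutral = sim$n_neutral, n_de = sim$n_de, de_fc = sim$de_fc,
        rng_seed = derive_seed(seed, "bundle"))
      counts_true <- simulate_counts(
        bundle$mirnas, depth = sim$read_depth, de_truth = bundle$de_truth,
        dispersion = sim$dispersion,
        rng_seed = derive_seed(seed, "counts"))
      reads <- list(
        high = simulate_reads(bundle$mirnas, counts_true[, "high"],
                              config$adapter,
                              rng_seed = derive_seed(seed, "reads_high")),
        low = simulate_reads(bundle$mirnas, counts_true[, "low"],
                             config$adapter,
                             rng_seed = derive_seed(seed, "reads_low")))
      fbg <- rbind(
        data.frame(snp_id = bundle$imbalance_truth$snp_id, group = "high",
                   freq = bundle$imbalance_truth$freq_high),
        data.frame(snp_id = bundle$imbalance_truth$snp_id, group = "low",
                   freq = bundle$imbalance_truth$freq_low))
      depths <- simulate_pooled_alleles(
        bundle$snps, fbg, rng_seed = derive_seed(seed, "alleles"))
      phe <- simulate_phenotypes(
        n_families = sim$n_families,
        fish_per_family = sim$fish_per_family,
        genotype_effects = if (!is.null(bundle$effect_truth))
          data.frame(snp_id = bundle$effect_truth$snp_id,
                     trait = bundle$effect_truth$trait,
                     frac = bundle$effect_truth$frac,
                     maf = bundle$effect_truth$maf) else NULL,
        rng_seed = derive_seed(seed, "phenotypes"))
      write_fasta(bundle$mirnas, file.path(inp, "mirnas.fa"))
      write_fasta(bundle$utrs, file.path(inp, "utrs.fa"))
      write_fastq(reads$high, file.path(inp, "reads_high.fastq"))
      write_fastq(reads$low, file.path(inp, "reads_low.fastq"))
      write_pooled_vcf(bundle$snps, depths, file.path(inp, "snps.vcf"))
      write_tsv(data.frame(sample = c("pool_high", "pool_low"),
                           group = c("high", "low")),
                file.path(inp, "design.tsv"))
      write_tsv(phe$phenotypes, file.path(inp, "phenotypes.tsv"))
      write_tsv(phe$genotypes, file.path(inp, "genotypes.tsv"))
      if (!is.null(phe$ct)) write_tsv(phe$ct, file.path(inp, "ct.tsv"))
      write_tsv(bundle$snps, file.path(inp, "truth_snps.tsv"))
      list(bundle = bundle, phe = phe)
    })
    mirnas <- gen$bundle$mirnas
    utr_tab <- gen$bundle$utrs
    reads_paths <- c(pool_high = file.path(inp, "reads_high.fastq"),
                     pool_low = file.path(inp, "reads_low.fastq"))
    vcf_path <- file.path(inp, "snps.vcf")
    design <- read_tsv(file.path(inp, "design.tsv"))
    phenotypes <- gen$phe$phenotypes
    genotypes <- gen$phe$genotypes
  } else {
    mir_raw <- read_fasta(config$mirna_fasta)
    mirnas <- data.frame(name = mir_raw$id, sequence = mir_raw$sequence)
    utr_raw <- read_fasta(config$utr_fasta)
    utr_tab <- data.frame(gene_id = utr_raw$id,
                          sequence = utr_raw$sequence)
    reads_paths <- c(pool_high = config$reads_high,
                     pool_low = config$reads_low)
    vcf_path <- config$vcf
    design <- read_tsv(config$design_tsv)
    phenotypes <- read_tsv(config$phenotype_tsv)
    genotypes <- read_tsv(config$genotype_tsv)
  }

  # ---- quantify ----------------------------------------------------------
  q <- stage("quantify", quantify_samples(
    as.list(reads_paths), mirnas, adapter = config$adapter,
    min_len = config$min_len, max_len = config$max_len))
  counts <- q$counts
  write_tsv(data.frame(mirna = rownames(counts), counts,
                       check.names = FALSE),
            file.path(out_dir, "counts.tsv"))
  summary$quantify <- as.list(rowSums(q$stats))

  # ---- differential expression -------------------------------------------
  de <- stage("de", run_de(counts, design, fc_cut = config$fc_cut,
                           q_cut = config$q_cut))
  write_tsv(de, file.path(out_dir, "de.tsv"))
  summary$de <- list(n_de = sum(de$is_de),
                     up = unname(attr(de, "de_counts")["up"]),
                     down = unname(attr(de, "de_counts")["down"]))

  # ---- seed-site scan -----------------------------------------------------
  sites <- stage("scan", scan_all_sites(
    mirnas, utr_tab, energy_cutoff = config$energy_cutoff))
  sites_out <- data.frame(gene = sites$gene_id, start = sites$start + 1L,
                          end = sites$end, mirna = sites$mirna,
                          seed_len = sites$seed_len,
                          wobble = sites$n_wobble,
                          mismatch = sites$n_mismatch,
                          energy = sites$duplex_energy,
                          passes_energy = sites$passes_energy)
  write_tsv(sites_out, file.path(out_dir, "sites.tsv"))
  summary$scan <- list(n_sites = nrow(sites),
                       n_pass_energy = sum(sites$passes_energy))

  # ---- SNP impact ---------------------------------------------------------
  vcf <- stage("snp-impact", read_vcf_pooled(vcf_path, design))
  impacts <- stage("snp-impact", classify_snps(
    vcf$snps, utr_tab, mirnas, keep_none = TRUE))
  per_snp <- tapply(impacts$classification, impacts$snp_id, function(x) {
    if (any(x == "destroyed")) "destroyed"
    else if (any(x == "created")) "created" else "none"
  })
  utr_seqs <- stats::setNames(utr_tab$sequence, utr_tab$gene_id)
  hit <- impacts[impacts$classification != "none", , drop = FALSE]
  hit$mress <- vapply(seq_len(nrow(hit)), function(i) {
    s <- vcf$snps[match(hit$snp_id[i], vcf$snps$snp_id), ]
    st <- if (!is.na(hit$ref_site_start[i])) hit$ref_site_start[i]
          else hit$alt_site_start[i]
    en <- if (!is.na(hit$ref_site_end[i])) hit$ref_site_end[i]
          else hit$alt_site_end[i]
    mress_bracket(utr_seqs[[s$gene_id]], st, en, s$position, s$ref, s$alt)
  }, character(1))
  write_tsv(hit[, c("mirna", "mress", "snp_id", "effect_allele",
                    "classification")],
            file.path(out_dir, "impact.tsv"))
  summary$impact <- list(
    destroyed = sum(per_snp == "destroyed"),
    created = sum(per_snp == "created"),
    none = sum(per_snp == "none"))

  # ---- imbalance screen ---------------------------------------------------
  screen <- stage("screen", {
    freqs <- allele_frequencies(vcf$depths, min_reads = config$min_reads,
                                min_minor = config$min_minor,
                                min_maf = config$min_maf)
    screen_candidates(hit, freqs, vcf$snps,
                      upper = config$imbalance_upper,
                      lower = config$imbalance_lower)
  })
  write_tsv(screen[, c("snp_id", "mirna", "classification",
                       "effect_allele", "effect_freq_high",
                       "effect_freq_low", "ratio_str", "flag",
                       "is_candidate")],
            file.path(out_dir, "candidates.tsv"))
  cc <- attr(screen, "class_counts")
  summary$screen <- list(
    n_pass_filters = sum(screen$pass_filters),
    n_candidates = sum(screen$is_candidate),
    destroyed = unname(cc["destroyed"]), created = unname(cc["created"]))

  # ---- association --------------------------------------------------------
  geno_cols <- setdiff(names(genotypes), "fish_id")
  assoc_summary <- list()
  for (tr in config$traits) {
    if (!tr %in% names(phenotypes)) next
    y <- phenotypes[[tr]][match(genotypes$fish_id, phenotypes$fish_id)]
    tab <- stage("associate",
                 snp_association_panel(genotypes[geno_cols], y))
    write_tsv(tab, file.path(out_dir, sprintf("assoc_%s.tsv", tr)))
    assoc_summary[[tr]] <- list(
      n_tested = sum(!tab$untestable),
      n_significant = sum(tab$q < 0.05, na.rm = TRUE))
  }
  summary$assoc <- assoc_summary

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
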