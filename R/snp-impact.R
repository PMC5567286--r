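#' SNP impact on miRNA target sites and pooled allelic imbalance
#'
#' A 3'UTR SNP is classified against each miRNA by scanning both allele
#' variants of the UTR: a site present under one allele and absent under
#' the other means the site was destroyed (reference-allele site lost) or a
#' novel illegitimate site was created (alternate-allele site gained).
#' Independently, pooled allele counts from divergent high/low family
#' groups are screened for allelic imbalance of the putative effect allele.
#'
#' @name snp_impact
NULL

#' Substitute one allele into a UTR sequence
#'
#' @param utr_seq UTR sequence (DNA, sense strand).
#' @param position 1-based position on the UTR.
#' @param ref,alt reference and alternate alleles (single bases).
#' @param allele the base to substitute (must be `ref` or `alt`).
#' @return the sequence with the single base substituted; length preserved.
#'   Errors if `position` is out of range or the current base matches
#'   neither allele (reference mismatch).
#' @export
apply_allele <- function(utr_seq, position, ref, alt, allele) {
  n <- nchar(utr_seq)
  if (position < 1L || position > n)
    stop(sprintf("position %d outside UTR of length %d", position, n),
         call. = FALSE)
  cur <- substr(utr_seq, position, position)
  if (!cur %in% c(ref, alt))
    stop(sprintf(
      "reference mismatch at position %d: UTR has %s, alleles are %s/%s",
      position, cur, ref, alt), call. = FALSE)
  if (!allele %in% c(ref, alt))
    stop("`allele` must be the ref or alt base", call. = FALSE)
  substr(utr_seq, position, position) <- allele
  utr_seq
}

# Sites overlapping a 1-based SNP position.
.sites_at <- function(sites, position) {
  pos0 <- position - 1L
  sites[sites$start <= pos0 & sites$end > pos0, , drop = FALSE]
}

#' Classify one SNP against a miRNA panel
#'
#' Scans windows overlapping the SNP under both alleles and compares site
#' presence per miRNA: present then absent = `destroyed` (effect allele =
#' the allele without the site); absent then present = `created` (effect
#' allele = the allele with the novel site); identical calls = `none`.
#'
#' By default site presence is decided by the seed rules alone
#' (`energy_cutoff = NULL`); passing a cutoff additionally requires
#' `duplex_energy <= energy_cutoff`.
#'
#' @param snp one-row data.frame (or list) with `snp_id`, `gene_id`,
#'   `position` (1-based), `ref`, `alt`.
#' @param utr_seq the host 3'UTR sequence (DNA).
#' @param mirnas data.frame with `name`, `sequence`.
#' @inheritParams scan_sites
#' @return data.frame, one row per miRNA, with columns `snp_id`, `mirna`,
#'   `classification`, `effect_allele`, and the ref/alt site coordinates
#'   (`NA` where absent).
#' @export
classify_snp <- function(snp, utr_seq, mirnas, rules = default_seed_rules(),
                         energy_table = load_stack_energies(),
                         energy_cutoff = NULL) {
  seq_ref <- apply_allele(utr_seq, snp$position, snp$ref, snp$alt, snp$ref)
  seq_alt <- apply_allele(utr_seq, snp$position, snp$ref, snp$alt, snp$alt)
  # classification is local: only windows overlapping the SNP can change,
  # so scanning is restricted to the SNP neighbourhood (margin covers the
  # longest seed plus the 3' energy extension of any overlapping site)
  margin <- 40L
  off <- max(0L, snp$position - 1L - margin)       # bases clipped at 5'
  lo <- off + 1L
  hi <- min(nchar(utr_seq), snp$position + margin)
  sub_ref <- substr(seq_ref, lo, hi)
  sub_alt <- substr(seq_alt, lo, hi)
  local_pos <- snp$position - off
  out <- vector("list", nrow(mirnas))
  for (i in seq_len(nrow(mirnas))) {
    s_ref <- scan_sites(mirnas$name[i], mirnas$sequence[i], snp$gene_id,
                        sub_ref, rules, energy_table,
                        energy_cutoff %||% -15)
    s_alt <- scan_sites(mirnas$name[i], mirnas$sequence[i], snp$gene_id,
                        sub_alt, rules, energy_table,
                        energy_cutoff %||% -15)
    if (!is.null(energy_cutoff)) {
      s_ref <- s_ref[s_ref$passes_energy, , drop = FALSE]
      s_alt <- s_alt[s_alt$passes_energy, , drop = FALSE]
    }
    s_ref <- .sites_at(s_ref, local_pos)
    s_alt <- .sites_at(s_alt, local_pos)
    if (nrow(s_ref)) {
      s_ref$start <- s_ref$start + off
      s_ref$end <- s_ref$end + off
    }
    if (nrow(s_alt)) {
      s_alt$start <- s_alt$start + off
      s_alt$end <- s_alt$end + off
    }
    has_ref <- nrow(s_ref) > 0L
    has_alt <- nrow(s_alt) > 0L
    if (has_ref && !has_alt) {
      cls <- "destroyed"; eff <- snp$alt
    } else if (!has_ref && has_alt) {
      cls <- "created"; eff <- snp$alt    # the allele carrying the novel site
    } else {
      cls <- "none"; eff <- NA_character_
    }
    out[[i]] <- data.frame(
      snp_id = snp$snp_id, mirna = mirnas$name[i], classification = cls,
      effect_allele = eff,
      ref_site_start = if (has_ref) s_ref$start[1L] else NA_integer_,
      ref_site_end = if (has_ref) s_ref$end[1L] else NA_integer_,
      ref_seed_len = if (has_ref) s_ref$seed_len[1L] else NA_integer_,
      alt_site_start = if (has_alt) s_alt$start[1L] else NA_integer_,
      alt_site_end = if (has_alt) s_alt$end[1L] else NA_integer_,
      alt_seed_len = if (has_alt) s_alt$seed_len[1L] else NA_integer_)
  }
  do.call(rbind, out)
}

#' Classify a SNP table against a miRNA panel
#'
#' @param snps data.frame with `snp_id`, `gene_id`, `position`, `ref`,
#'   `alt`.
#' @param utrs data.frame with `gene_id`, `sequence`.
#' @inheritParams classify_snp
#' @param keep_none keep `classification == "none"` rows (default FALSE).
#' @return row-bound [classify_snp()] results; SNPs destroying one miRNA's
#'   site while creating another's yield one row per miRNA.
#' @export
classify_snps <- function(snps, utrs, mirnas, rules = default_seed_rules(),
                          energy_table = load_stack_energies(),
                          energy_cutoff = NULL, keep_none = FALSE) {
  utr_seq <- stats::setNames(utrs$sequence, utrs$gene_id)
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    snp <- snps[i, , drop = FALSE]
    if (!snp$gene_id %in% names(utr_seq))
      stop(sprintf("SNP %s references unknown gene %s", snp$snp_id,
                   snp$gene_id), call. = FALSE)
    out[[i]] <- classify_snp(snp, utr_seq[[snp$gene_id]], mirnas, rules,
                             energy_table, energy_cutoff)
  }
  res <- do.call(rbind, out)
  if (!keep_none) res <- res[res$classification != "none", , drop = FALSE]
  row.names(res) <- NULL
  res
}

#' MRESS bracket notation for a SNP inside a site
#'
#' Renders the site sequence with the SNP in `[ref/alt]` brackets, e.g.
#' `"TGTC[C/T]TGT"`, for reporting tables.
#'
#' @param utr_seq UTR sequence; `site_start`,`site_end` 0-based half-open;
#'   `position` 1-based SNP position; `ref`,`alt` alleles.
#' @return character scalar.
#' @export
mress_bracket <- function(utr_seq, site_start, site_end, position, ref, alt) {
  site <- substr(utr_seq, site_start + 1L, site_end)
  off <- position - site_start          # 1-based offset within site
  paste0(substr(site, 1L, off - 1L), "[", ref, "/", alt, "]",
         substr(site, off + 1L, nchar(site)))
}

#' Pooled allele frequencies with coverage filters
#'
#' Computes per-group allele frequencies from pooled read depths and applies
#' the coverage filters used for pooled variant screens: total reads
#' strictly greater than `min_reads`, minor allele count strictly greater
#' than `min_minor`, and minor allele frequency strictly greater than
#' `min_maf` (all computed over the pooled depths of both groups).
#'
#' @param depths data.frame with columns `snp_id`, `group`, `ref_depth`,
#'   `alt_depth` (one row per SNP per group).
#' @param min_reads,min_minor,min_maf filter thresholds (defaults 10, 4,
#'   0.05; strict inequalities).
#' @return data.frame with one row per SNP: per-group alternate-allele
#'   frequencies (`freq_<group>`), `total_reads`, `minor_allele_count`,
#'   `maf`, `pass` and `filter_reason` (`"no coverage"`, `"min_reads"`,
#'   `"min_minor"`, `"min_maf"` or `""`).
#' @export
allele_frequencies <- function(depths, min_reads = 10, min_minor = 4,
                               min_maf = 0.05) {
  stopifnot(all(c("snp_id", "group", "ref_depth", "alt_depth") %in%
                  names(depths)))
  if (any(depths$ref_depth < 0 | depths$alt_depth < 0))
    stop("depths must be non-negative", call. = FALSE)
  groups <- unique(depths$group)
  ids <- unique(depths$snp_id)
  out <- data.frame(snp_id = ids)
  for (g in groups) {
    d <- depths[depths$group == g, , drop = FALSE]
    d <- d[match(ids, d$snp_id), , drop = FALSE]
    tot <- d$ref_depth + d$alt_depth
    out[[paste0("freq_", g)]] <- ifelse(tot > 0, d$alt_depth / tot, NA_real_)
    out[[paste0("depth_", g)]] <- tot
  }
  agg_ref <- tapply(depths$ref_depth, depths$snp_id, sum)[ids]
  agg_alt <- tapply(depths$alt_depth, depths$snp_id, sum)[ids]
  out$total_reads <- as.integer(agg_ref + agg_alt)
  out$minor_allele_count <- as.integer(pmin(agg_ref, agg_alt))
  out$maf <- ifelse(out$total_reads > 0,
                    out$minor_allele_count / out$total_reads, NA_real_)
  reason <- character(length(ids))
  reason[out$total_reads <= min_reads] <- "min_reads"
  reason[out$total_reads == 0] <- "no coverage"
  ok <- reason == ""
  reason[ok & out$minor_allele_count <= min_minor] <- "min_minor"
  ok <- reason == ""
  reason[ok & out$maf <= min_maf] <- "min_maf"
  out$pass <- reason == ""
  out$filter_reason <- reason
  out
}

#' Allelic-imbalance ratio between high and low family groups
#'
#' `ratio = freq_high / freq_low`, flagged `"amplification"` when the ratio
#' meets the upper threshold and `"LOH"` (loss of heterozygosity) when it
#' meets the lower one. With `strict = FALSE` (default) the thresholds are
#' inclusive (>= 2.0, <= 0.5); with `strict = TRUE` they are exclusive.
#' A zero low-group frequency with a nonzero high-group frequency yields an
#' infinite ratio flagged as amplification with `low_freq_zero = TRUE` and
#' a `"high/0"` display string; both frequencies zero yield `NA` and no
#' flag.
#'
#' @param freq_high,freq_low effect-allele frequencies in the two groups.
#' @param upper,lower flag thresholds (defaults 2.0, 0.5).
#' @param strict use strict inequalities (default FALSE, matching the
#'   inclusive convention).
#' @return data.frame with `ratio`, `ratio_str`, `flag`
#'   (`"amplification"`, `"LOH"`, `"none"`), `low_freq_zero`.
#' @export
#' @examples
#' imbalance_ratio(0.25, 0.75)
imbalance_ratio <- function(freq_high, freq_low, upper = 2.0, lower = 0.5,
                            strict = FALSE) {
  check_fraction(freq_high, "freq_high", allow_na = TRUE)
  check_fraction(freq_low, "freq_low", allow_na = TRUE)
  n <- max(length(freq_high), length(freq_low))
  freq_high <- rep_len(freq_high, n)
  freq_low <- rep_len(freq_low, n)
  ratio <- ifelse(freq_low > 0, freq_high / freq_low,
                  ifelse(freq_high > 0, Inf, NA_real_))
  amp <- if (strict) ratio > upper else ratio >= upper
  loh <- if (strict) ratio < lower else ratio <= lower
  flag <- rep("none", n)
  flag[!is.na(ratio) & amp] <- "amplification"
  flag[!is.na(ratio) & loh] <- "LOH"
  low_zero <- !is.na(freq_low) & !is.na(freq_high) &
    freq_low == 0 & freq_high > 0
  ratio_str <- ifelse(is.na(ratio), "NA",
                      ifelse(low_zero,
                             paste0(sprintf("%g", freq_high), "/0"),
                             sprintf("%g", ratio)))
  data.frame(ratio = ratio, ratio_str = ratio_str, flag = flag,
             low_freq_zero = low_zero)
}

#' Screen candidate SNPs: impact class joined with allelic imbalance
#'
#' Joins impact classifications with pooled-frequency records by `snp_id`.
#' The imbalance ratio is computed on the putative effect allele's
#' frequency (the allele destroying or carrying the novel site); a
#' candidate is a SNP with a non-`none` classification and a non-`none`
#' imbalance flag. Records present on only one side are excluded with a
#' warning tally.
#'
#' @param impacts data.frame from [classify_snps()] (with `snp_id`,
#'   `classification`, `effect_allele`).
#' @param freqs data.frame from [allele_frequencies()]; must carry
#'   `freq_<high_group>` and `freq_<low_group>` alternate-allele frequency
#'   columns plus `pass`. `snps` supplies `ref`/`alt` so frequencies can be
#'   expressed on the effect allele.
#' @param snps data.frame with `snp_id`, `ref`, `alt`.
#' @param high_group,low_group group labels (defaults "high", "low").
#' @inheritParams imbalance_ratio
#' @return data.frame of joined records with `effect_freq_high`,
#'   `effect_freq_low`, `ratio`, `ratio_str`, `flag`, `is_candidate`;
#'   attribute `class_counts` tabulates candidates by classification.
#' @export
screen_candidates <- function(impacts, freqs, snps, high_group = "high",
                              low_group = "low", upper = 2.0, lower = 0.5,
                              strict = FALSE) {
  keep <- impacts$snp_id %in% freqs$snp_id
  if (any(!keep))
    warning(sprintf("%d impact rows had no pooled record and were excluded",
                    sum(!keep)))
  impacts <- impacts[keep, , drop = FALSE]
  f <- freqs[match(impacts$snp_id, freqs$snp_id), , drop = FALSE]
  s <- snps[match(impacts$snp_id, snps$snp_id), , drop = FALSE]
  fh <- f[[paste0("freq_", high_group)]]
  fl <- f[[paste0("freq_", low_group)]]
  # frequencies are of the alt allele; flip where the effect allele is ref
  eff_is_ref <- !is.na(impacts$effect_allele) & impacts$effect_allele == s$ref
  fh <- ifelse(eff_is_ref, 1 - fh, fh)
  fl <- ifelse(eff_is_ref, 1 - fl, fl)
  imb <- imbalance_ratio(fh, fl, upper, lower, strict)
  out <- cbind(impacts,
               data.frame(effect_freq_high = fh, effect_freq_low = fl),
               imb, pass_filters = f$pass)
  out$is_candidate <- out$classification != "none" & out$flag != "none" &
    out$pass_filters
  attr(out, "class_counts") <-
    table(factor(out$classification[out$is_candidate],
                 levels = c("destroyed", "created")))
  out
}
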