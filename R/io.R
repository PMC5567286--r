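#' File-format readers and writers
#'
#' FASTA/FASTQ handling is backed by Biostrings; VCF reading by vcfR. All
#' tabular outputs are tab-separated with a single header line and `#`
#' comments. Coordinates in emitted tables are 1-based closed (the VCF
#' convention); internal arithmetic is 0-based half-open.
#'
#' @name cli_io
NULL

#' Read a FASTA file
#'
#' @param path FASTA file (plain or gzipped). The first non-empty line
#'   must be a `>` header (malformed input errors with the line number);
#'   duplicate record ids are rejected; an empty file returns an empty
#'   table with a warning. CRLF line endings are accepted.
#' @return data.frame with columns `id` (first whitespace token of the
#'   header) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- sub("\r$", "", first)
  nonempty <- which(nzchar(trimws(first)))
  if (!length(nonempty)) {
    if (length(readLines(path, warn = FALSE)) == 0L ||
        all(!nzchar(trimws(readLines(path, warn = FALSE))))) {
      warning(sprintf("empty FASTA file: %s", path))
      return(data.frame(id = character(), sequence = character()))
    }
  }
  if (length(nonempty) && !startsWith(first[nonempty[1L]], ">"))
    stop(sprintf("malformed FASTA header at line %d of %s", nonempty[1L],
                 path), call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate FASTA id: %s", dup[1L]), call. = FALSE)
  data.frame(id = ids, sequence = as.character(x), row.names = NULL)
}

#' Write a FASTA file
#'
#' @param records data.frame with `id` (or `name`/`gene_id`) and
#'   `sequence`.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  id_col <- intersect(c("id", "name", "gene_id"), names(records))[1L]
  if (is.na(id_col)) stop("records need an id/name/gene_id column",
                          call. = FALSE)
  x <- Biostrings::BStringSet(stats::setNames(records$sequence,
                                              records[[id_col]]))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (plain or gzipped).
#' @return data.frame with `id`, `sequence` (qualities are not retained;
#'   the pipeline does not use them).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), sequence = as.character(x), row.names = NULL)
}

#' Write a FASTQ file
#'
#' Constant placeholder qualities are written (the downstream stages are
#' quality-agnostic).
#'
#' @param reads data.frame with `id`, `sequence`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$id))
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' Single header line, `#` comment lines ignored, never quoted.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv
#' @param table data.frame to write.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read pooled SNP records from a VCF
#'
#' Reads a VCF 4.2 with per-sample allele depths (`AD`) and sums depths
#' into family groups via the design table. Indel and multiallelic
#' records are skipped and tallied.
#'
#' @param path VCF file.
#' @param design data.frame with columns `sample`, `group`; every VCF
#'   sample must appear.
#' @return list with `snps` (snp_id, gene_id, position, ref, alt) and
#'   `depths` (snp_id, group, ref_depth, alt_depth); attribute
#'   `n_skipped` counts non-SNP records.
#' @export
read_vcf_pooled <- function(path, design) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || all(is.na(ad)))
    stop("VCF has no per-sample AD (allele depth) field", call. = FALSE)
  samples <- colnames(ad)
  missing <- setdiff(samples, design$sample)
  if (length(missing))
    stop(sprintf("sample %s not in design", missing[1L]), call. = FALSE)
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  n_skipped <- sum(!is_snp)
  fix <- fix[is_snp, , drop = FALSE]
  ad <- ad[is_snp, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  snps <- data.frame(snp_id = ids, gene_id = fix$CHROM,
                     position = as.integer(fix$POS), ref = fix$REF,
                     alt = fix$ALT, row.names = NULL)
  groups <- unique(design$group)
  depths <- do.call(rbind, lapply(groups, function(g) {
    gs <- design$sample[design$group == g]
    gs <- intersect(gs, samples)
    ref_d <- alt_d <- rep(0L, nrow(snps))
    for (s in gs) {
      parts <- strsplit(ad[, s], ",", fixed = TRUE)
      take <- function(p, k) {
        v <- suppressWarnings(as.integer(p[k]))
        if (is.na(v)) 0L else v
      }
      ref_d <- ref_d + vapply(parts, take, integer(1), k = 1L)
      alt_d <- alt_d + vapply(parts, take, integer(1), k = 2L)
    }
    data.frame(snp_id = snps$snp_id, group = g, ref_depth = ref_d,
               alt_depth = alt_d)
  }))
  out <- list(snps = snps, depths = depths)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write pooled SNP records as VCF 4.2
#'
#' One sample column per group, with allele depths in the `AD` FORMAT
#' field. Inverse of [read_vcf_pooled()] on its own output (with a design
#' mapping each written sample to its group).
#'
#' @param snps data.frame with `snp_id`, `gene_id`, `position`, `ref`,
#'   `alt`.
#' @param depths data.frame with `snp_id`, `group`, `ref_depth`,
#'   `alt_depth`.
#' @param path output file.
#' @return the written path; sample columns are named `pool_<group>`.
#' @export
write_pooled_vcf <- function(snps, depths, path) {
  groups <- unique(depths$group)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("pool_", groups)),
                 collapse = "\t"))
  rows <- vapply(seq_len(nrow(snps)), function(i) {
    cells <- vapply(groups, function(g) {
      d <- depths[depths$snp_id == snps$snp_id[i] & depths$group == g, ]
      if (nrow(d) == 0L) "./.:0,0"
      else sprintf("./.:%d,%d", d$ref_depth[1L], d$alt_depth[1L])
    }, character(1))
    paste(c(snps$gene_id[i], snps$position[i], snps$snp_id[i],
            snps$ref[i], snps$alt[i], ".", "PASS", ".", "GT:AD", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
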