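#' Small-RNA read quantification
#'
#' Turns adapter-containing small-RNA reads into a per-miRNA count matrix:
#' 3' adapter trimming, length/N filtering, tolerant ungapped annotation
#' against a mature-miRNA reference (mismatches <= 2, up to 2 additional or
#' missing bases at either end), and isomiR collapsing so that all sequence
#' variants of a miRNA are counted under its canonical name.
#'
#' @name smallrna_quant
NULL

#' Default 3' sequencing adapter
#' @return adapter sequence (DNA) used by the small-RNA library protocol.
#' @export
default_adapter <- function() "GCCTTGGCACCCGAGAATTCCA"

#' Trim the 3' sequencing adapter from reads
#'
#' Each read is cut at the leftmost full occurrence of the adapter; when no
#' full occurrence exists, a terminal prefix of the adapter of at least
#' `min_overlap` nt at the read's 3' end is removed (longest such prefix).
#' Reads without either are returned unchanged. `N` bases never match the
#' adapter.
#'
#' @param sequences character vector of read sequences (DNA).
#' @param adapter adapter sequence; non-empty.
#' @param min_overlap minimum 3'-end partial-adapter overlap (default 6).
#' @return trimmed sequences (possibly empty strings).
#' @export
#' @examples
#' trim_adapter(paste0("ACGTACGT", default_adapter()))
trim_adapter <- function(sequences, adapter = default_adapter(),
                         min_overlap = 6L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty", call. = FALSE)
  out <- sequences
  hit <- regexpr(adapter, out, fixed = TRUE)
  full <- hit > 0L
  out[full] <- substr(out[full], 1L, hit[full] - 1L)
  # partial adapter prefix at the 3' end of reads with no full occurrence
  pending <- which(!full)
  alen <- nchar(adapter)
  if (alen - 1L >= min_overlap) {
    for (k in seq.int(alen - 1L, min_overlap, by = -1L)) {
      if (length(pending) == 0L) break
      cand <- pending[nchar(out[pending]) >= k]
      if (length(cand)) {
        tail_k <- substr(out[cand], nchar(out[cand]) - k + 1L,
                         nchar(out[cand]))
        cut <- tail_k == substr(adapter, 1L, k)
        out[cand[cut]] <- substr(out[cand[cut]], 1L,
                                 nchar(out[cand[cut]]) - k)
        pending <- setdiff(pending, cand[cut])
      }
    }
  }
  out
}

#' Filter reads by trimmed length and N content
#'
#' Retains reads whose length lies in `[min_len, max_len]` and which
#' contain no `N`.
#'
#' @param sequences character vector of trimmed read sequences.
#' @param min_len,max_len inclusive length bounds (defaults 16 and 28 nt,
#'   the typical mature-miRNA range).
#' @return the retained subset.
#' @export
filter_reads <- function(sequences, min_len = 16L, max_len = 28L) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  len <- nchar(sequences)
  sequences[len >= min_len & len <= max_len &
              !grepl("N", sequences, fixed = TRUE)]
}

# Score one read against one reference: best ungapped alignment over 5'
# offsets d in -2..2 (d > 0: read missing d upstream bases; d < 0: read has
# extra upstream bases); the 3' shift is determined by the lengths and must
# also be within 2. Returns c(mismatch, shift) or NULL.
.align_read <- function(read_chars, ref_chars, max_mismatch = 2L,
                        max_shift = 2L) {
  rl <- length(read_chars)
  fl <- length(ref_chars)
  best <- NULL
  for (d in seq.int(-max_shift, max_shift)) {
    e <- rl + d - fl                      # 3' end shift
    if (abs(e) > max_shift) next
    i0 <- max(1L, 1L - d)
    i1 <- min(rl, fl - d)
    if (i1 < i0) next
    mm <- sum(read_chars[i0:i1] != ref_chars[(i0:i1) + d])
    if (mm > max_mismatch) next
    shift <- abs(d) + abs(e)
    if (is.null(best) || mm < best[1L] ||
        (mm == best[1L] && shift < best[2L]))
      best <- c(mm, shift, d, e)
  }
  best
}

#' Annotate reads against a mature-miRNA reference
#'
#' Each unique read sequence is aligned, ungapped and with T/U equivalence,
#' against every reference miRNA allowing up to `max_mismatch`
#' substitutions and up to `max_shift` additional or missing bases at
#' either end. The best assignment has the fewest mismatches, ties broken
#' by the smallest total end shift; a residual tie between distinct miRNAs
#' leaves the read unassigned and counted as ambiguous.
#'
#' @param sequences character vector of trimmed, filtered read sequences.
#' @param reference data.frame with `name` and `sequence` (RNA or DNA).
#' @param max_mismatch,max_shift tolerances (defaults 2 and 2).
#' @return data.frame with one row per input read: `sequence`, `mirna`
#'   (`NA` if unassigned), `n_mismatch`, `shift5`, `shift3`, `status`
#'   (`assigned`, `ambiguous` or `unassigned`).
#' @export
annotate_reads <- function(sequences, reference, max_mismatch = 2L,
                           max_shift = 2L) {
  ref_chars <- lapply(rna_to_dna(reference$sequence), split_chars)
  uniq <- unique(sequences)
  res <- lapply(uniq, function(s) {
    rc <- split_chars(s)
    best <- NULL
    best_i <- NA_integer_
    tie <- FALSE
    for (i in seq_along(ref_chars)) {
      a <- .align_read(rc, ref_chars[[i]], max_mismatch, max_shift)
      if (is.null(a)) next
      if (is.null(best) || a[1L] < best[1L] ||
          (a[1L] == best[1L] && a[2L] < best[2L])) {
        best <- a; best_i <- i; tie <- FALSE
      } else if (a[1L] == best[1L] && a[2L] == best[2L]) {
        tie <- TRUE
      }
    }
    if (is.null(best)) {
      c(NA_character_, NA, NA, NA, "unassigned")
    } else if (tie) {
      c(NA_character_, NA, NA, NA, "ambiguous")
    } else {
      c(reference$name[best_i], best[1L], best[3L], best[4L], "assigned")
    }
  })
  tab <- do.call(rbind, res)
  idx <- match(sequences, uniq)
  data.frame(sequence = sequences,
             mirna = tab[idx, 1L],
             n_mismatch = as.integer(tab[idx, 2L]),
             shift5 = as.integer(tab[idx, 3L]),
             shift3 = as.integer(tab[idx, 4L]),
             status = tab[idx, 5L])
}

#' Collapse isomiR assignments into one count column
#'
#' Read counts from all sequence variants (isomiRs) of the same miRNA are
#' summed into that miRNA's canonical row.
#'
#' @param assignments data.frame from [annotate_reads()].
#' @param mirna_names canonical row order (reference miRNA names).
#' @return named integer vector of counts, one per canonical miRNA.
#' @export
collapse_isomirs <- function(assignments, mirna_names) {
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  counts <- table(factor(asg$mirna, levels = mirna_names))
  stats::setNames(as.integer(counts), mirna_names)
}

#' Quantify one small-RNA sample
#'
#' Runs trim, filter, annotate and collapse for one FASTQ (or in-memory
#' read vector) and returns the count column plus read-accounting totals.
#'
#' @param reads character vector of raw read sequences, or a FASTQ path
#'   (optionally gzipped).
#' @param reference data.frame with `name`, `sequence`.
#' @param adapter,min_overlap see [trim_adapter()].
#' @param min_len,max_len see [filter_reads()].
#' @param max_mismatch,max_shift see [annotate_reads()].
#' @return list with `counts` (named integer vector), and `stats`
#'   (`n_raw`, `n_filtered`, `n_assigned`, `n_ambiguous`, `n_unassigned`).
#' @export
quantify_sample <- function(reads, reference, adapter = default_adapter(),
                            min_overlap = 6L, min_len = 16L, max_len = 28L,
                            max_mismatch = 2L, max_shift = 2L) {
  if (length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)$sequence
  n_raw <- length(reads)
  trimmed <- trim_adapter(reads, adapter, min_overlap)
  kept <- filter_reads(trimmed, min_len, max_len)
  asg <- annotate_reads(kept, reference, max_mismatch, max_shift)
  counts <- collapse_isomirs(asg, reference$name)
  list(counts = counts,
       stats = c(n_raw = n_raw, n_filtered = length(kept),
                 n_assigned = sum(asg$status == "assigned"),
                 n_ambiguous = sum(asg$status == "ambiguous"),
                 n_unassigned = sum(asg$status == "unassigned")))
}

#' Quantify several samples into a count matrix
#'
#' @param read_sets named list: sample label -> read vector or FASTQ path.
#' @inheritParams quantify_sample
#' @return list with `counts` (integer matrix, miRNAs x samples) and
#'   `stats` (matrix of per-sample accounting totals).
#' @export
quantify_samples <- function(read_sets, reference, ...) {
  res <- lapply(read_sets, quantify_sample, reference = reference, ...)
  counts <- do.call(cbind, lapply(res, `[[`, "counts"))
  colnames(counts) <- names(read_sets)
  stats <- do.call(cbind, lapply(res, `[[`, "stats"))
  colnames(stats) <- names(read_sets)
  list(counts = counts, stats = stats)
}
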