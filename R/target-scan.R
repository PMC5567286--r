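#' Seed-site scanning of 3'UTR sequences
#'
#' The scanner locates microRNA recognition element seed sites (MRESS) in
#' 3'UTR sequences. A seed of length 6, 7 or 8 nt starts at mature-miRNA
#' position 2 (positions 2-7, 2-8 and 2-9), and pairs antiparallel against a
#' UTR window: seed position `i` pairs window position `seed_len - 1 - i`
#' (0-based). Each opposing pair is Watson-Crick, a G:U wobble (seed G
#' against target T, or seed U against target G), or a mismatch. Matching
#' tolerances per seed length follow the PITA-style rule set used for
#' salmonid target prediction: 6-mers admit no wobble and no mismatch,
#' 7-mers one wobble and no mismatch, 8-mers one wobble and one mismatch.
#' Gaps (loops) are never allowed.
#'
#' @name target_scan
NULL

#' Seed matching rule set
#'
#' One row per seed length with the maximum number of G:U wobbles and
#' mismatches tolerated. The defaults implement the rule set described in
#' \link{target_scan}.
#'
#' @return data.frame with columns `seed_len`, `max_wobble`, `max_mismatch`.
#' @export
#' @examples
#' default_seed_rules()
default_seed_rules <- function() {
  data.frame(seed_len = c(6L, 7L, 8L),
             max_wobble = c(0L, 1L, 1L),
             max_mismatch = c(0L, 0L, 1L))
}

#' Extract seed subsequences from a mature miRNA
#'
#' Seeds are anchored at mature position 2: positions 2-7 (6-mer), 2-8
#' (7-mer) and 2-9 (8-mer), 5'->3' in the RNA alphabet.
#'
#' @param sequence mature miRNA sequence, RNA alphabet, length >= 9.
#' @return named character vector with elements `seed6`, `seed7`, `seed8`.
#' @export
#' @examples
#' mirna_seeds("UAGGCACUGAUCGAUCGAUCGA")
mirna_seeds <- function(sequence) {
  sequence <- dna_to_rna(sequence)
  if (nchar(sequence) < 9L)
    stop("mature miRNA must be at least 9 nt so all three seeds exist",
         call. = FALSE)
  c(seed6 = substr(sequence, 2L, 7L),
    seed7 = substr(sequence, 2L, 8L),
    seed8 = substr(sequence, 2L, 9L))
}

#' Match one seed against one UTR window
#'
#' Pairs the seed antiparallel against the window (seed position `i` against
#' window position `seed_len - 1 - i`, 0-based) and classifies every
#' opposing pair as Watson-Crick, G:U wobble or mismatch. `N` in the window
#' never pairs.
#'
#' @param seed seed subsequence, RNA alphabet, 5'->3'.
#' @param window UTR window, DNA alphabet, sense strand 5'->3'; same length
#'   as `seed`.
#' @param max_wobble,max_mismatch tolerances; the window matches iff both
#'   counts are within bounds.
#' @return list with elements `matched` (logical), `n_wobble`, `n_mismatch`.
#' @export
#' @examples
#' seed_match("AGGCACU", "AGTGCCT", max_wobble = 1, max_mismatch = 0)
seed_match <- function(seed, window, max_wobble, max_mismatch) {
  s <- split_chars(dna_to_rna(seed))
  w <- split_chars(window)
  if (length(s) != length(w))
    stop("seed and window must have equal length", call. = FALSE)
  cls <- pair_class(s, rev(w))
  n_wobble <- sum(cls == "U")
  n_mismatch <- sum(cls == "M")
  list(matched = n_wobble <= max_wobble && n_mismatch <= max_mismatch,
       n_wobble = n_wobble, n_mismatch = n_mismatch)
}

# Vectorized single-length scan: returns 0-based starts plus wobble and
# mismatch counts of matching windows.
.scan_one_length <- function(mir_chars, utr_chars, seed_len, max_wobble,
                             max_mismatch) {
  n <- length(utr_chars)
  if (n < seed_len) return(NULL)
  starts <- seq_len(n - seed_len + 1L)         # 1-based window starts
  nw <- integer(length(starts))
  nm <- integer(length(starts))
  # seed position p (1-based along the mature, p = 2..seed_len+1) pairs the
  # window base at offset seed_len - (p - 1) from the window start
  for (p in seq.int(2L, seed_len + 1L)) {
    tb <- utr_chars[starts + (seed_len - (p - 1L))]
    cls <- .PAIR_CLASS[cbind(rep(mir_chars[p], length(tb)), tb)]
    nw <- nw + (cls == "U")
    nm <- nm + (cls == "M")
  }
  keep <- nw <= max_wobble & nm <= max_mismatch
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep] - 1L, seed_len = seed_len,
             n_wobble = nw[keep], n_mismatch = nm[keep])
}

#' Scan a UTR for seed sites of one miRNA
#'
#' Tests every window of every seed length. Sites of different seed lengths
#' anchored at the same mature position 2 share their 3'-most UTR
#' coordinate; such nested matches are reported once, at the longest
#' matching seed length. Each reported site carries its nearest-neighbor
#' duplex energy (see [duplex_energy()]) and a `passes_energy` flag against
#' `energy_cutoff`.
#'
#' @param mirna_name,mirna_seq name and mature sequence (RNA) of the miRNA.
#' @param gene_id,utr_seq identifier and sense-strand sequence (DNA) of the
#'   3'UTR.
#' @param rules data.frame as [default_seed_rules()].
#' @param energy_table stacking parameters, see [load_stack_energies()].
#' @param energy_cutoff duplex-energy threshold in kcal/mol (default -15);
#'   sites are reported regardless, with `passes_energy` set accordingly.
#' @return data.frame with columns `mirna`, `gene_id`, `start`, `end`
#'   (0-based half-open on the UTR sense strand), `seed_len`, `n_wobble`,
#'   `n_mismatch`, `duplex_energy`, `passes_energy`, sorted by `start`.
#'   Windows containing `N` never match.
#' @export
scan_sites <- function(mirna_name, mirna_seq, gene_id, utr_seq,
                       rules = default_seed_rules(),
                       energy_table = load_stack_energies(),
                       energy_cutoff = -15) {
  if (nchar(utr_seq) == 0L)
    stop("UTR sequence must be non-empty", call. = FALSE)
  mir_chars <- split_chars(dna_to_rna(mirna_seq))
  utr_chars <- split_chars(utr_seq)
  hits <- NULL
  for (k in seq_len(nrow(rules))) {
    h <- .scan_one_length(mir_chars, utr_chars, rules$seed_len[k],
                          rules$max_wobble[k], rules$max_mismatch[k])
    if (!is.null(h)) hits <- rbind(hits, h)
  }
  empty <- data.frame(mirna = character(), gene_id = character(),
                      start = integer(), end = integer(),
                      seed_len = integer(), n_wobble = integer(),
                      n_mismatch = integer(), duplex_energy = numeric(),
                      passes_energy = logical())
  if (is.null(hits)) return(empty)
  hits$end <- hits$start + hits$seed_len
  # nested seed lengths share the 3' anchor (end); keep the longest
  hits <- hits[order(hits$end, -hits$seed_len), , drop = FALSE]
  hits <- hits[!duplicated(hits$end), , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$duplex_energy <- vapply(seq_len(nrow(hits)), function(i) {
    duplex_energy(mirna_seq, utr_seq, hits$end[i], energy_table)
  }, numeric(1))
  hits$passes_energy <- hits$duplex_energy <= energy_cutoff
  data.frame(mirna = mirna_name, gene_id = gene_id,
             hits[, c("start", "end", "seed_len", "n_wobble", "n_mismatch",
                      "duplex_energy", "passes_energy")],
             row.names = NULL)
}

#' Scan a set of miRNAs against a set of UTRs
#'
#' @param mirnas data.frame with columns `name`, `sequence` (RNA).
#' @param utrs data.frame with columns `gene_id`, `sequence` (DNA).
#' @inheritParams scan_sites
#' @return row-bound [scan_sites()] tables for all (miRNA, UTR) pairs.
#' @export
scan_all_sites <- function(mirnas, utrs, rules = default_seed_rules(),
                           energy_table = load_stack_energies(),
                           energy_cutoff = -15) {
  out <- vector("list", nrow(mirnas) * nrow(utrs))
  k <- 1L
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(utrs))) {
      out[[k]] <- scan_sites(mirnas$name[i], mirnas$sequence[i],
                             utrs$gene_id[j], utrs$sequence[j],
                             rules, energy_table, energy_cutoff)
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}

.energy_cache <- new.env(parent = emptyenv())

#' Load nearest-neighbor stacking parameters
#'
#' Reads a tab-separated resource of RNA/RNA stacking free energies
#' (kcal/mol at 37 degC). Columns: `top5p` (two adjacent duplex-strand bases
#' read 5'->3'), `bottom3p` (the two paired bases read 3'->5', first base
#' pairing the first of `top5p`), `dG37`. A special row `INIT` holds the
#' duplex initiation penalty. The default file ships the Turner 2004
#' Watson-Crick and G:U values.
#'
#' @param path resource file; defaults to the table shipped with the
#'   package.
#' @return list with `stacks` (named numeric, keys `"XY/ZW"`) and `init`.
#' @export
load_stack_energies <- function(path = system.file("extdata",
                                                   "stack_energies.tsv",
                                                   package = "mirtrait")) {
  if (!is.null(.energy_cache[[path]])) return(.energy_cache[[path]])
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  init <- tab$dG37[tab$top5p == "INIT"]
  if (length(init) != 1L)
    stop("stacking table must contain exactly one INIT row", call. = FALSE)
  tab <- tab[tab$top5p != "INIT", , drop = FALSE]
  stacks <- stats::setNames(tab$dG37, paste0(tab$top5p, "/", tab$bottom3p))
  out <- list(stacks = stacks, init = init)
  .energy_cache[[path]] <- out
  out
}

#' Nearest-neighbor energy of a seed-anchored miRNA:UTR duplex
#'
#' The duplex is anchored with mature position 2 paired to the UTR base at
#' `site_end - 1` (0-based) and extended 3'-ward along the miRNA, without
#' gaps, for as long as consecutive pairs are Watson-Crick or G:U wobble.
#' The reported energy is the duplex initiation penalty plus the sum of
#' stacking terms over adjacent pairs; an isolated pair has no stack and
#' scores the (positive) initiation penalty alone.
#'
#' @param mirna_seq mature miRNA sequence (RNA).
#' @param utr_seq UTR sequence (DNA, sense strand).
#' @param site_end 0-based exclusive end of the site on the UTR (the 3'
#'   anchor shared by all seed lengths, as reported by [scan_sites()]).
#' @param energy_table list from [load_stack_energies()].
#' @return energy in kcal/mol.
#' @export
duplex_energy <- function(mirna_seq, utr_seq, site_end,
                          energy_table = load_stack_energies()) {
  mir <- split_chars(dna_to_rna(mirna_seq))
  utr <- split_chars(dna_to_rna(utr_seq))      # RNA alphabet for the table
  # mature position p pairs UTR index (1-based) site_end - (p - 2)
  utr_pos <- function(p) site_end - (p - 2L)
  pmax_ <- length(mir)
  paired <- integer(0)
  for (p in seq.int(2L, pmax_)) {
    i <- utr_pos(p)
    if (i < 1L) break
    cls <- .PAIR_CLASS[dna_to_rna(mir[p]), rna_to_dna(utr[i])]
    if (cls == "M") break
    paired <- c(paired, p)
  }
  if (length(paired) < 1L) return(energy_table$init)
  e <- energy_table$init
  if (length(paired) >= 2L) {
    for (j in seq_len(length(paired) - 1L)) {
      p <- paired[j]
      key <- paste0(mir[p], mir[p + 1L], "/", utr[utr_pos(p)],
                    utr[utr_pos(p + 1L)])
      val <- energy_table$stacks[key]
      if (is.na(val))
        stop(sprintf("no stacking entry for %s in the energy table", key),
             call. = FALSE)
      e <- e + unname(val)
    }
  }
  e
}

#' Intersect site lists for multi-tool consensus
#'
#' A site from the first list is consensus iff every other list contains a
#' site for the same (miRNA, gene) whose interval midpoint lies within
#' `slack` nt of its own midpoint. Used to reproduce "predicted by all
#' tools" consensus from externally produced site tables sharing the
#' [scan_sites()] column layout (`mirna`, `gene_id`, `start`, `end`).
#'
#' @param lists list of >= 2 site data.frames.
#' @param slack maximum midpoint distance in nt (default 5).
#' @return the consensus subset of the first list.
#' @export
intersect_site_lists <- function(lists, slack = 5) {
  stopifnot(is.list(lists), length(lists) >= 2L)
  base <- lists[[1L]]
  if (nrow(base) == 0L) return(base)
  mids <- lapply(lists, function(l) (l$start + l$end) / 2)
  keep <- rep(TRUE, nrow(base))
  for (k in seq_along(lists)[-1L]) {
    other <- lists[[k]]
    for (i in which(keep)) {
      same <- other$mirna == base$mirna[i] & other$gene_id == base$gene_id[i]
      if (!any(same) || !any(abs(mids[[k]][same] - mids[[1L]][i]) <= slack))
        keep[i] <- FALSE
    }
  }
  base[keep, , drop = FALSE]
}
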