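# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Pair classification written out explicitly: returns "wc", "wobble" or
# "mismatch" for a miRNA (RNA) base against a target (DNA) base.
oracle_pair <- function(mir, tgt) {
  if (mir == "A" && tgt == "T") return("wc")
  if (mir == "U" && tgt == "A") return("wc")
  if (mir == "G" && tgt == "C") return("wc")
  if (mir == "C" && tgt == "G") return("wc")
  if (mir == "G" && tgt == "T") return("wobble")
  if (mir == "U" && tgt == "G") return("wobble")
  "mismatch"
}

# Enumerate every window of every seed length, classify every opposing
# pair (seed position i against window position len - 1 - i, 0-based),
# apply the tolerance table, and keep the longest match per shared 3' end.
oracle_scan <- function(mirna_seq, utr_seq) {
  rules <- list(`6` = c(0, 0), `7` = c(1, 0), `8` = c(1, 1))
  mir <- strsplit(chartr("T", "U", mirna_seq), "")[[1]]
  utr <- strsplit(utr_seq, "")[[1]]
  found <- list()
  for (len in c(6L, 7L, 8L)) {
    tol <- rules[[as.character(len)]]
    seed <- mir[2:(len + 1L)]
    if (length(utr) < len) next
    for (start in 0:(length(utr) - len)) {
      nw <- 0L; nm <- 0L
      for (i in 0:(len - 1L)) {
        cls <- oracle_pair(seed[i + 1L], utr[start + len - i])
        if (cls == "wobble") nw <- nw + 1L
        if (cls == "mismatch") nm <- nm + 1L
      }
      if (nw <= tol[1L] && nm <= tol[2L]) {
        key <- as.character(start + len)      # shared 3' anchor
        prev <- found[[key]]
        if (is.null(prev) || prev["seed_len"] < len)
          found[[key]] <- c(start = start, end = start + len,
                            seed_len = len, n_wobble = nw, n_mismatch = nm)
      }
    }
  }
  if (!length(found))
    return(data.frame(start = integer(), end = integer(),
                      seed_len = integer(), n_wobble = integer(),
                      n_mismatch = integer()))
  out <- as.data.frame(do.call(rbind, found))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive ungapped read-vs-reference alignment: enumerate 5' and 3'
# shifts in -2..2 independently, keep the length-consistent combinations,
# score mismatches over the overlap.
oracle_align <- function(read, ref) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(chartr("U", "T", ref), "")[[1]]
  best <- NULL
  for (d5 in -2:2) {
    for (d3 in -2:2) {
      if (length(rd) != length(rf) - d5 + d3) next
      i <- seq_along(rd)
      ri <- i + d5
      keep <- ri >= 1 & ri <= length(rf)
      mm <- sum(rd[keep] != rf[ri[keep]])
      if (mm > 2) next
      shift <- abs(d5) + abs(d3)
      if (is.null(best) || mm < best[1] ||
          (mm == best[1] && shift < best[2]))
        best <- c(mm, shift)
    }
  }
  best
}

# Step-up false-discovery-rate adjustment straight from the definition:
# q_i = min over j with p_(j) >= p_(i) of m * p_(j) / rank(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  adj <- m * p[o] / seq_len(m)
  for (i in seq_len(m)) q[o[i]] <- min(1, min(adj[i:m]))
  q
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
          collapse = ""), character(1))
}

# Single-length window enumerator (no cross-length dedup): every matching
# window of the given seed length with its wobble/mismatch counts.
oracle_scan_length <- function(mirna_seq, utr_seq, len) {
  tol <- list(`6` = c(0, 0), `7` = c(1, 0), `8` = c(1, 1))[[as.character(len)]]
  mir <- strsplit(chartr("T", "U", mirna_seq), "")[[1]]
  utr <- strsplit(utr_seq, "")[[1]]
  seed <- mir[2:(len + 1L)]
  out <- list()
  if (length(utr) >= len) {
    for (start in 0:(length(utr) - len)) {
      nw <- 0L; nm <- 0L
      for (i in 0:(len - 1L)) {
        cls <- oracle_pair(seed[i + 1L], utr[start + len - i])
        if (cls == "wobble") nw <- nw + 1L
        if (cls == "mismatch") nm <- nm + 1L
      }
      if (nw <= tol[1L] && nm <= tol[2L])
        out[[length(out) + 1L]] <- c(start = start, end = start + len,
                                     n_wobble = nw, n_mismatch = nm)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      n_wobble = integer(), n_mismatch = integer()))
  d <- as.data.frame(do.call(rbind, out))
  rownames(d) <- NULL
  d
}
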