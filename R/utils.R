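# Internal sequence helpers shared across modules.
#
# Convention: mature miRNAs are RNA strings 5'->3' ({A,C,G,U}); UTRs and
# sequencing reads are DNA sense-strand strings 5'->3' ({A,C,G,T,N}).
# Coordinates are 0-based half-open internally and 1-based closed in every
# user-facing table (VCF convention).

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

# DNA complement (N self-complements; U treated as T)
.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' @noRd
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    b <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    paste(.DNA_COMP[b], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Pair classification between a miRNA (RNA) base and a target (DNA) base:
# "W" Watson-Crick, "U" G:U wobble (miRNA G : target T, or miRNA U : target G),
# "M" mismatch. N never pairs.
.PAIR_CLASS <- local({
  m <- matrix("M", nrow = 4, ncol = 5,
              dimnames = list(RNA_BASES, c(DNA_BASES, "N")))
  m["A", "T"] <- "W"
  m["C", "G"] <- "W"
  m["G", "C"] <- "W"
  m["U", "A"] <- "W"
  m["G", "T"] <- "U"
  m["U", "G"] <- "U"
  m
})

pair_class <- function(mir_base, target_base) {
  .PAIR_CLASS[cbind(mir_base, target_base)]
}

split_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

#' @noRd
check_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_fraction <- function(x, name, allow_na = FALSE) {
  bad <- !is.numeric(x) || (!allow_na && any(is.na(x))) ||
    any(x < 0, na.rm = TRUE) || any(x > 1, na.rm = TRUE)
  if (bad)
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  x
}

# Derive a stage-specific RNG seed from a master seed, kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) * 1009L
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() that never interprets a length-1 vector as 1:n
resample <- function(x, size = 1L) x[sample.int(length(x), size,
                                                replace = size > length(x))]
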