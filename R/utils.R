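# Internal sequence and coordinate helpers. All genomic coordinates in this
# package are 0-based half-open; conversion to 1-based happens only at the
# SAM/BED boundary and in human-readable reports.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement for plain character DNA (delegates to
#' Biostrings).
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substr with 0-based half-open coordinates
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# Circular substring: offsets taken modulo the sequence length, so the
# extracted window may wrap around the origin. `start`/`end` are 0-based on the
# unrolled molecule with end > start; end - start must not exceed 2 * nchar.
subseq_circular <- function(seq, start, end) {
  len <- nchar(seq)
  stopifnot(end > start, end - start <= 2L * len + 16L)
  doubled <- paste0(seq, seq, substr(seq, 1L, min(len, end - start)))
  s <- start %% len
  substr(doubled, s + 1L, s + (end - start))
}

# Longest common prefix length of two strings (compared left to right),
# binary-searched so each comparison is a single C-level substring equality.
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L || substr(a, 1L, 1L) != substr(b, 1L, 1L)) return(0L)
  if (substr(a, 1L, n) == substr(b, 1L, n)) return(n)
  lo <- 1L # known match length
  hi <- n  # known mismatch at this length
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (substr(a, 1L, mid) == substr(b, 1L, mid)) lo <- mid else hi <- mid
  }
  lo
}

# Longest common suffix length of two strings (binary search, no reversal).
common_suffix_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n == 0L || substr(a, na, na) != substr(b, nb, nb)) return(0L)
  if (substr(a, na - n + 1L, na) == substr(b, nb - n + 1L, nb)) return(n)
  lo <- 1L
  hi <- n
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (substr(a, na - mid + 1L, na) == substr(b, nb - mid + 1L, nb)) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  lo
}

# Seed the RNG locally when a seed is supplied; otherwise use the caller's RNG
# stream unchanged.
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = env)
  invisible(NULL)
}

assert_contigs <- function(contig, known, what = "segment") {
  bad <- setdiff(unique(contig), names(known))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s references unknown contig(s): %s",
      what, paste(bad, collapse = ", ")
    ))
  }
  invisible(NULL)
}

#' Canonical register of a circle junction
#'
#' A circle excised from `[start, end)` is the same molecule as one excised
#' from `[start + k, end + k)` whenever the k entering bases agree
#' (`genome[start + i] == genome[end + i]`): direct repeats at the junction
#' make the cut pair ambiguous up to rotation. This function shifts a cut pair
#' to its rightmost equivalent register, the register a maximal-prefix split
#' alignment reports, so truth and calls can be compared exactly.
#'
#' @param genome A genome model (see [sim_genome()]) or a named character
#'   vector of contig sequences.
#' @param contig Contig name.
#' @param start,end 0-based half-open cut coordinates.
#' @return Integer vector `c(start, end)` in canonical register.
#' @export
canonical_junction <- function(genome, contig, start, end) {
  contigs <- contig_seqs(genome)
  assert_contigs(contig, contigs, "junction")
  seq <- contigs[[contig]]
  len <- nchar(seq)
  while (end < len &&
         substr(seq, start + 1L, start + 1L) == substr(seq, end + 1L, end + 1L)) {
    start <- start + 1L
    end <- end + 1L
  }
  c(start = start, end = end)
}

# Accept either an ecc_genome or a plain named character vector of contigs.
contig_seqs <- function(genome) {
  if (inherits(genome, "ecc_genome")) genome$contigs else genome
}

contig_lengths <- function(genome) {
  seqs <- contig_seqs(genome)
  setNames(nchar(seqs), names(seqs))
}
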