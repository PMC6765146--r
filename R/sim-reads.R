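#' Convert circles and genomic fragments to a molecule table
#'
#' Molecule tables are the common currency of the read simulator: one row per
#' DNA molecule with its sequence, topology and (where applicable) genomic
#' origin.
#'
#' @param circles An `ecc_circles` tibble from [excise_circles()].
#' @return A tibble with columns `molecule_id`, `seq`, `circular`, `contig`,
#'   `start`, `end`, `category`.
#' @export
as_molecules <- function(circles) {
  circles |>
    transmute(
      molecule_id = .data$circle_id, seq = .data$seq, circular = TRUE,
      contig = .data$origin_contig, start = .data$left_cut,
      end = .data$right_cut, category = .data$category
    )
}

#' Linear genomic background molecules
#'
#' Random linear fragments of the MIC genome standing in for sheared
#' chromosomes, unexcised precursors and other linear contaminants that the
#' exonuclease step depletes.
#'
#' @param genome An `ecc_genome`.
#' @param n Number of fragments.
#' @param length_range Min/max fragment length (bp).
#' @param seed Optional seed.
#' @return A molecule tibble (see [as_molecules()]) with `circular = FALSE`.
#' @export
sim_linear_background <- function(genome, n, length_range = c(800L, 4000L),
                                  seed = NULL) {
  local_seed_if(seed)
  lens <- contig_lengths(genome)
  ctg <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  flen <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  flen <- pmin(flen, lens[ctg])
  start <- as.integer(floor(runif(n) * (lens[ctg] - flen + 1)))
  tibble(
    molecule_id = sprintf("lin%05d", seq_len(n)),
    seq = substr(genome$contigs[ctg], start + 1L, start + flen),
    circular = FALSE, contig = ctg, start = start, end = start + flen,
    category = "linear"
  )
}

#' Exonuclease enrichment of circular molecules
#'
#' Models the successive exonuclease digestions of a +exo library: circular
#' molecules are always retained; each linear molecule survives independently
#' with probability `survival`.
#'
#' @param molecules A molecule tibble.
#' @param survival Survival probability for linear molecules, in \[0, 1\].
#' @param seed Optional seed.
#' @return The filtered molecule tibble.
#' @export
exonuclease_filter <- function(molecules, survival, seed = NULL) {
  stopifnot(survival >= 0, survival <= 1)
  local_seed_if(seed)
  keep <- molecules$circular | (runif(nrow(molecules)) < survival)
  molecules[keep, ]
}

#' Tagment molecules and emit paired-end reads with ground truth
#'
#' Models Tn5 tagmentation: cut positions fall as a Poisson process along each
#' molecule, every cut is a 9 bp staggered cut, so each fragment carries a
#' 9 bp duplication of the next cut site at its end. A circle receiving
#' exactly one cut linearizes into a fragment whose two ends are the same cut,
#' so the resulting read pair carries the matching 9 bp 5' duplication; a
#' circle cut two or more times yields fragments, one of which spans the
#' circle junction. Fragments are then size-selected with a Gaussian kernel
#' centred on the configured insert size and sequenced from both ends.
#'
#' @param molecules Molecule tibble (circles; see [as_molecules()]).
#' @param linear_background Optional second molecule tibble appended before
#'   tagmentation (apply [exonuclease_filter()] first for +exo libraries).
#' @param config A [sim_config()] (read length, insert size, depth).
#' @param library Library label stamped on every read pair.
#' @param depth Fold coverage for these molecules; defaults to
#'   `config$depth`.
#' @param force_single_cut If `TRUE`, every circular molecule receives exactly
#'   one cut, placed so that neither mate crosses the circle's own junction,
#'   and size selection is bypassed; isolates the 9 bp duplication signature.
#' @param seed Optional seed.
#' @return A tibble of read pairs: `pair_id`, `mate1_seq`, `mate2_seq`,
#'   `library`, plus ground-truth columns `molecule_id`, `category`,
#'   `circular`, `frag_start` (0-based offset on the molecule), `frag_len`
#'   (including the 9 bp duplication), `spans_junction`, `has_9bp_dup`,
#'   `truncated`.
#' @export
tagment_and_read <- function(molecules, linear_background = NULL,
                             config = sim_config(), library = "lib",
                             depth = config$depth,
                             force_single_cut = FALSE, seed = NULL) {
  local_seed_if(seed)
  mol <- bind_rows(molecules, linear_background)
  rl <- config$read_length
  frags <- map(seq_len(nrow(mol)), function(i) {
    fragment_molecule(
      len = nchar(mol$seq[i]), circular = mol$circular[i],
      depth = depth, read_length = rl,
      insert = config$insert_size, force_single_cut = force_single_cut
    )
  })
  n_per <- map_int(frags, function(f) length(f$start))
  if (sum(n_per) == 0) return(empty_read_pairs())
  idx <- rep(seq_len(nrow(mol)), n_per)
  fr <- tibble(
    molecule_id = mol$molecule_id[idx],
    category = mol$category[idx],
    circular = mol$circular[idx],
    mol_len = nchar(mol$seq)[idx],
    frag_start = unlist(map(frags, "start")),
    frag_len = unlist(map(frags, "len")),
    has_9bp_dup = unlist(map(frags, "single_cut_circle"))
  )
  fr <- fr |>
    mutate(
      spans_junction = .data$circular &
        (.data$frag_start + .data$frag_len > .data$mol_len),
      seq = map_chr(seq_len(n()), function(j) {
        s <- mol$seq[idx[j]]
        if (fr$circular[j]) {
          subseq_circular(s, fr$frag_start[j], fr$frag_start[j] + fr$frag_len[j])
        } else {
          substr(s, fr$frag_start[j] + 1L, fr$frag_start[j] + fr$frag_len[j])
        }
      }),
      truncated = .data$frag_len < rl,
      mate1_seq = substr(.data$seq, 1L, pmin(rl, .data$frag_len)),
      mate2_seq = revcomp(substr(.data$seq,
                                 pmax(1L, .data$frag_len - rl + 1L),
                                 .data$frag_len)),
      library = library,
      pair_id = sprintf("%s:%s:%04d", library, .data$molecule_id,
                        ave(seq_len(n()), .data$molecule_id, FUN = seq_along))
    )
  fr |>
    select("pair_id", "mate1_seq", "mate2_seq", "library", "molecule_id",
           "category", "circular", "mol_len", "frag_start", "frag_len",
           "spans_junction", "has_9bp_dup", "truncated")
}

empty_read_pairs <- function() {
  tibble(
    pair_id = character(), mate1_seq = character(), mate2_seq = character(),
    library = character(), molecule_id = character(), category = character(),
    circular = logical(), mol_len = integer(), frag_start = integer(),
    frag_len = integer(), spans_junction = logical(), has_9bp_dup = logical(),
    truncated = logical()
  )
}

# Tagmentation cuts for one molecule. Returns 0-based fragment starts on the
# (unrolled) molecule and fragment lengths inclusive of the 9 bp duplication
# copied from the cut at the fragment's far end.
#
# Cut positions fall at rate 1/insert_mean per bp per molecule copy; circular
# molecules are present in enough copies to approach the target fold
# coverage, linear molecules are individual (one copy each). Size selection
# keeps a fragment with probability given by a Gaussian kernel centred on the
# configured insert size, so realized coverage is depth scaled by the
# retention fraction.
fragment_molecule <- function(len, circular, depth, read_length, insert,
                              force_single_cut = FALSE) {
  none <- list(start = integer(0), len = integer(0),
               single_cut_circle = logical(0))
  if (circular && force_single_cut) {
    lo <- max(0L, read_length - 9L)
    hi <- len - read_length
    if (hi < lo) return(none) # too small for both mates to clear the junction
    cut <- sample(seq(lo, hi), 1L)
    return(list(start = cut, len = len + 9L, single_cut_circle = TRUE))
  }
  rate <- 1 / insert[1]
  copies <- if (circular) max(1L, ceiling(depth * insert[1] / (2 * read_length))) else 1L
  starts <- integer(0); lens <- integer(0); single <- logical(0)
  ncuts_all <- rpois(copies, len * rate)
  for (ncuts in ncuts_all[ncuts_all > 0L]) {
    # coincident cut positions collapse to one cut
    cuts <- sort(unique(as.integer(floor(runif(ncuts) * len))))
    ncuts <- length(cuts)
    if (circular) {
      if (ncuts == 1L) {
        s <- cuts; l <- len + 9L
      } else {
        nxt <- c(cuts[-1L], cuts[1L] + len)
        s <- cuts; l <- nxt - cuts + 9L
      }
      sc <- rep(ncuts == 1L, length(s))
    } else {
      bounds <- unique(c(0L, cuts, len))
      s <- bounds[-length(bounds)]
      ends <- bounds[-1L]
      l <- pmin(ends + ifelse(ends < len, 9L, 0L), len) - s
      sc <- rep(FALSE, length(s))
    }
    starts <- c(starts, s); lens <- c(lens, l); single <- c(single, sc)
  }
  if (length(starts) == 0L) return(none)
  keep <- lens >= 30L &
    runif(length(lens)) < exp(-0.5 * ((lens - insert[1]) / insert[2])^2)
  list(start = starts[keep], len = lens[keep], single_cut_circle = single[keep])
}
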