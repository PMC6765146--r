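#' Simulate RNA-seq reads over circle-transcription and genic background
#'
#' Emulates the transcriptional design of a rearrangement time course. Genic
#' transcription (reads over MDS intervals, the strongest component) and a
#' weak basal transcription uniform across the whole germline genome are
#' present at every time point; at mid-rearrangement a fixed subset of
#' circles is additionally transcribed from transcription start sites
#' clustered near the circle junction, on either strand, with transcripts
#' that may read through the junction (circular template), so some reads map
#' chimerically across it. Pre-rearrangement libraries contain background
#' only. Circle transcription is set below genic levels: restricted to IES
#' space it stands far above the basal floor, but shuffled genome-wide it is
#' swamped by genic reads.
#'
#' @param genome An `ecc_genome`.
#' @param circles `ecc_circles` truth (TBE circles are not transcribed here).
#' @param fraction_transcribed Fraction of eligible circles transcribed at
#'   mid-rearrangement.
#' @param circle_depth Fold read coverage of a transcribed circle per mid
#'   library.
#' @param genic_depth Fold read coverage of MDS (genic) space per library.
#' @param genic_edge_margin Genic reads are kept this many bp away from MDS
#'   boundaries: mature somatic transcripts crossing an MDS-MDS junction do
#'   not align contiguously to the germline, and reads over the duplicated
#'   pointer ends are ambiguous, so mappable genic coverage is modeled on
#'   MDS interiors only.
#' @param basal_depth Fold coverage of genome-wide basal transcription.
#' @param tss_sd Sd (bp) of TSS placement around the circle junction.
#' @param read_length RNA read length (bp).
#' @param n_replicates Replicates per time point.
#' @param seed Optional seed.
#' @return A list with `reads` (tibble: `read_id`, `seq`, `library`,
#'   `timepoint`, `origin`, `circle_id`, `strand`), `segments` (ground-truth
#'   single-end alignments: `read_id`, `library`, `timepoint`, `contig`,
#'   `start`, `end`, `strand`, `chimeric`, `seg_index`), and `transcribed`
#'   (circle ids transcribed at mid-rearrangement).
#' @export
sim_rnaseq <- function(genome, circles, fraction_transcribed = 0.3,
                       circle_depth = 10, genic_depth = 12,
                       genic_edge_margin = 40L, basal_depth = 0.5,
                       tss_sd = 20, read_length = 75L, n_replicates = 3L,
                       seed = NULL) {
  local_seed_if(seed)
  eligible <- circles |> filter(.data$category != "tbe")
  n_tx <- round(fraction_transcribed * nrow(eligible))
  transcribed <- if (n_tx > 0) sample(eligible$circle_id, n_tx) else character(0)

  libs <- tidyr::expand_grid(
    timepoint = c("pre", "mid"),
    replicate = seq_len(n_replicates)
  ) |>
    mutate(library = paste(.data$timepoint, .data$replicate, sep = "_"))

  mds <- genome$mds |>
    mutate(start = .data$start + genic_edge_margin,
           end = .data$end - genic_edge_margin) |>
    filter(.data$end - .data$start >= read_length + 1L)
  mds_w <- (mds$end - mds$start)
  out_reads <- list(); out_segs <- list()
  clens <- contig_lengths(genome)
  for (i in seq_len(nrow(libs))) {
    lib <- libs$library[i]; tp <- libs$timepoint[i]
    # genic background over MDS space
    n_bg <- rpois(1L, genic_depth * sum(mds_w) / read_length)
    bi <- sample(seq_len(nrow(mds)), n_bg, replace = TRUE, prob = mds_w)
    bstart <- mds$start[bi] +
      as.integer(floor(runif(n_bg) * pmax(1L, mds_w[bi] - read_length)))
    # basal genome-wide transcription
    n_bs <- rpois(1L, basal_depth * sum(clens) / read_length)
    bs_ctg <- sample(names(clens), n_bs, replace = TRUE,
                     prob = clens / sum(clens))
    bs_start <- as.integer(floor(runif(n_bs) *
                                   (clens[bs_ctg] - read_length + 1)))
    bctg <- c(mds$contig[bi], bs_ctg)
    bstart <- c(bstart, bs_start)
    n_all <- n_bg + n_bs
    blen <- pmin(read_length, clens[bctg] - bstart)
    bstrand <- sample(c("+", "-"), n_all, replace = TRUE)
    bseq <- substr(genome$contigs[bctg], bstart + 1L, bstart + blen)
    bseq[bstrand == "-"] <- revcomp(bseq[bstrand == "-"])
    bid <- sprintf("%s:bg%05d", lib, seq_len(n_all))
    out_reads[[length(out_reads) + 1L]] <- tibble(
      read_id = bid, seq = bseq, library = lib, timepoint = tp,
      origin = rep(c("background", "basal"), c(n_bg, n_bs)),
      circle_id = NA_character_, strand = bstrand
    )
    out_segs[[length(out_segs) + 1L]] <- tibble(
      read_id = bid, library = lib, timepoint = tp, contig = unname(bctg),
      start = unname(bstart), end = unname(bstart + blen), strand = bstrand,
      chimeric = FALSE, seg_index = 1L
    )
    if (tp != "mid" || length(transcribed) == 0) next
    # circle transcription at mid-rearrangement
    tx <- eligible |> filter(.data$circle_id %in% transcribed)
    for (j in seq_len(nrow(tx))) {
      len <- tx$length[j]
      if (len < read_length + 2L) next
      n_r <- rpois(1L, circle_depth * len / read_length)
      if (n_r == 0L) next
      tss <- as.integer(round(rnorm(n_r, 0, tss_sd)))
      elong <- as.integer(floor(stats::rexp(n_r, rate = 2 / len)))
      off <- (tss + elong) %% len
      strand <- sample(c("+", "-"), n_r, replace = TRUE)
      dbl <- paste0(tx$seq[j], tx$seq[j])
      rseq <- substring(dbl, off + 1L, off + read_length)
      rseq[strand == "-"] <- revcomp(rseq[strand == "-"])
      rid <- sprintf("%s:%s:tx%04d", lib, tx$circle_id[j], seq_len(n_r))
      out_reads[[length(out_reads) + 1L]] <- tibble(
        read_id = rid, seq = rseq, library = lib, timepoint = tp,
        origin = "circle", circle_id = tx$circle_id[j], strand = strand
      )
      segs <- map(seq_len(n_r), function(r) {
        mate_segments(tx$origin_contig[j], tx$left_cut[j], len, off[r],
                      read_length, circular = TRUE, strand = strand[r]) |>
          mutate(read_id = rid[r])
      }) |> list_rbind()
      out_segs[[length(out_segs) + 1L]] <- segs |>
        mutate(library = lib, timepoint = tp, chimeric = .data$n_seg > 1L) |>
        select("read_id", "library", "timepoint", "contig", "start", "end",
               "strand", "chimeric", "seg_index")
    }
  }
  list(
    reads = list_rbind(out_reads),
    segments = list_rbind(out_segs),
    transcribed = transcribed
  )
}

#' Study configuration for circle-transcription analyses
#'
#' A [sim_config()] preset for transcription permutation studies: a larger
#' IES universe with sparse excision (roughly a third of non-scrambled IESs
#' circularize, one isoform each), so the circle set is a genuine subset of
#' the IES space it is shuffled against -- the design the permutation test
#' presumes. Circulome-seq detection studies use the denser [sim_config()]
#' defaults instead.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
transcription_study_config <- function(...) {
  sim_config(
    n_contigs = 8L, contig_length = 30000L, n_mac_loci = 32L,
    mds_per_locus = 8L,
    p_excise = c(non_scrambled = 0.35, scrambled = 0.05, intergenic = 0.1),
    circles_per_ies = 1L,
    ...
  )
}
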