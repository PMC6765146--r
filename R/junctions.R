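# The three sequencing signatures of circularity: TBE circular-junction motif
# reads, split reads mapping the MIC in permuted order, and read pairs
# carrying the 9 bp tagmentation duplication.

#' The TBE circular-junction pattern
#'
#' 33-mer regular expression matched by reads spanning a circularized TBE
#' junction: the telomeric end of the right TIR, the 5 bp junction
#' (N-A-N-T-N, central ANT = target-site duplication), and the telomeric
#' start of the left TIR.
#' @export
TBE_JUNCTION_PATTERN <- "GGTTTTGGGGTTTT.A.T.AAAACCCCAAAACC"

#' Count reads containing circular TBE junctions
#'
#' Matches the 33-mer TBE junction pattern against each read sequence and its
#' reverse complement (junctions are strandless), counting each read at most
#' once, and classifies matches by the final base of the junction 5-mer:
#' GANTC, GANTG, GANTA; junctions ending in T are tallied as `other` rather
#' than silently dropped. Mapping is not required.
#'
#' @param reads Read tibble (`read_id`, `seq`), a read-pair tibble
#'   (`pair_id`, `mate1_seq`, `mate2_seq`; mates counted independently), or a
#'   character vector.
#' @param library Optional library label; defaults to a `library` column when
#'   present.
#' @return A tibble with `library`, `class` (GANTC/GANTG/GANTA/other) and
#'   `n_reads`, including zero rows for absent classes.
#' @export
count_tbe_junction_reads <- function(reads, library = NULL) {
  long <- as_single_end(reads)
  if (!is.null(library)) long$library <- library
  if (!"library" %in% names(long)) long$library <- "all"
  long$class <- tbe_junction_class(long$seq)
  classes <- c("GANTC", "GANTG", "GANTA", "other")
  long |>
    filter(!is.na(.data$class)) |>
    distinct(.data$library, .data$read_id, .keep_all = TRUE) |>
    count(.data$library, .data$class, name = "n_reads") |>
    tidyr::complete(library = unique(long$library),
                    class = classes, fill = list(n_reads = 0L)) |>
    mutate(class = factor(.data$class, levels = classes)) |>
    arrange(.data$library, .data$class)
}

# Junction class of each read (NA when the pattern is absent from both
# strands). The class base is position 19 of the match: G-A-N-T-[base].
#
# The 33-mer pattern is nearly reverse-complement symmetric: a junction read
# also matches as its own reverse complement, where position 19 reads C (the
# complement of the junction's constant G) regardless of the true class. The
# true orientation is the one with G at match position 15; when both
# orientations show it (a GANTC junction) the class is C either way.
tbe_junction_class <- function(seqs) {
  cls <- rep(NA_character_, length(seqs))
  anchored <- rep(FALSE, length(seqs)) # match with the constant G seen
  for (s in list(identity, revcomp)) {
    seqx <- s(seqs)
    todo <- which(!anchored)
    if (length(todo) == 0) break
    m <- regexpr(TBE_JUNCTION_PATTERN, seqx[todo])
    hit <- m > 0
    if (!any(hit)) next
    matched <- substr(seqx[todo][hit], m[hit], m[hit] + 32L)
    good <- substr(matched, 15L, 15L) == "G"
    base <- substr(matched, 19L, 19L)
    class_here <- ifelse(base %in% c("C", "G", "A"),
                         paste0("GANT", base), "other")
    idx <- todo[hit]
    take <- good | is.na(cls[idx])
    cls[idx[take]] <- class_here[take]
    anchored[idx[good]] <- TRUE
  }
  cls
}

# Normalize read input to a long (read_id, seq[, mate][, library]) tibble;
# read-pair tibbles are collapsed so each mate is handled single-end.
as_single_end <- function(reads) {
  if (is.character(reads)) {
    return(tibble(read_id = sprintf("read%05d", seq_along(reads)),
                  seq = unname(reads)))
  }
  if ("mate1_seq" %in% names(reads)) {
    keep <- intersect("library", names(reads))
    base <- reads[, c("pair_id", keep)]
    return(bind_rows(
      base |> mutate(read_id = paste0(.data$pair_id, "/1"), mate = 1L,
                     seq = reads$mate1_seq),
      base |> mutate(read_id = paste0(.data$pair_id, "/2"), mate = 2L,
                     seq = reads$mate2_seq)
    ) |> select(-"pair_id"))
  }
  reads
}

standard_filters <- function(seg, min_mapq) {
  seg |>
    filter(!.data$unmapped, !.data$secondary, !.data$duplicate,
           .data$mapq >= min_mapq)
}

#' Detect circle junctions from permuted split reads
#'
#' Retains reads (mates handled single-end) with exactly one primary and one
#' supplementary segment on the same contig and strand, partitioning the read
#' between them, where the read-prefix segment (in aligned orientation) maps
#' *downstream* of the read-suffix segment: a permuted mapping diagnostic of
#' a circular junction. The call's coordinates are
#' `circle_start = ref_start` of the suffix segment and
#' `circle_end = ref_end` of the prefix segment, normalized to forward-contig
#' coordinates and (when the genome is supplied) to the canonical rightmost
#' junction register. Standard filters: MAPQ >= `min_mapq` on both segments,
#' no duplicates or secondary alignments, and both coordinates at least
#' `end_filter` bp from the contig ends (assembly-edge artifacts).
#'
#' @param segments Alignment-segment tibble ([map_reads()] or [read_sam()]).
#' @param lengths Named contig lengths.
#' @param library Optional library label for the calls.
#' @param genome Optional genome for canonical junction registers.
#' @param min_mapq MAPQ threshold (default 5, multi-mapper cut).
#' @param end_filter Minimum distance of both coordinates from contig ends.
#' @return Junction-call tibble: `contig`, `circle_start`, `circle_end`,
#'   `evidence = "split_read"`, `read_id`, `library`.
#' @export
detect_split_junctions <- function(segments, lengths, library = NA_character_,
                                   genome = NULL, min_mapq = 5L,
                                   end_filter = 150L) {
  assert_contigs(segments$contig[!segments$unmapped], setNames(
    as.list(lengths), names(lengths)), "alignment segment")
  seg <- standard_filters(segments, min_mapq) |>
    mutate(unit = paste(.data$read_id,
                        ifelse(is.na(.data$mate), 0L, .data$mate)))
  cand <- seg |>
    group_by(.data$unit) |>
    filter(n() == 2L, sum(.data$supplementary) == 1L,
           n_distinct(.data$contig) == 1L, n_distinct(.data$strand) == 1L) |>
    arrange(.data$read_start, .by_group = TRUE) |>
    summarise(
      read_id = .data$read_id[1], contig = .data$contig[1],
      prefix_ref_start = .data$ref_start[1], prefix_ref_end = .data$ref_end[1],
      suffix_ref_start = .data$ref_start[2], suffix_ref_end = .data$ref_end[2],
      contiguous = .data$read_end[1] == .data$read_start[2],
      .groups = "drop"
    ) |>
    filter(.data$contiguous,
           .data$prefix_ref_start > .data$suffix_ref_start) |>
    mutate(circle_start = .data$suffix_ref_start,
           circle_end = .data$prefix_ref_end) |>
    filter(.data$circle_end > .data$circle_start)
  if (!is.null(genome) && nrow(cand) > 0) {
    canon <- pmap(list(cand$contig, cand$circle_start, cand$circle_end),
                  function(ctg, s, e) canonical_junction(genome, ctg, s, e))
    cand$circle_start <- map_int(canon, function(x) as.integer(x[["start"]]))
    cand$circle_end <- map_int(canon, function(x) as.integer(x[["end"]]))
  }
  cand |>
    filter(.data$circle_start >= end_filter,
           .data$circle_end <= lengths[.data$contig] - end_filter) |>
    transmute(
      contig = .data$contig, circle_start = .data$circle_start,
      circle_end = .data$circle_end, evidence = "split_read",
      read_id = .data$read_id, library = library
    )
}

#' Detect read pairs carrying the 9 bp tagmentation duplication
#'
#' A small circle cut exactly once by the tagmentase yields a read pair whose
#' 5'-terminal 9-mers are the same genomic 9-mer: the mates map to the same
#' contig on opposite strands, oriented outward, with their 5' mapped ends
#' overlapping by exactly 9 bp. Requires the sequence-level duplication
#' (mate1 5' 9-mer equals the reverse complement of mate2's), the mapped
#' geometry (minus-mate `ref_end` minus plus-mate `ref_start` == 9), and the
#' standard filters (MAPQ, duplicates, secondary/supplementary, contig-end
#' distance).
#'
#' @param reads Read-pair tibble (`pair_id`, `mate1_seq`, `mate2_seq`).
#' @param segments Alignment-segment tibble for these pairs (mate 1 and 2).
#' @param lengths Named contig lengths.
#' @param library Optional library label.
#' @param min_mapq,end_filter As in [detect_split_junctions()].
#' @return Junction-call tibble: `contig`, `circle_start`, `circle_end` (the
#'   locus covered by the pair), `cut_start`, `cut_end` (the shared 9-mer
#'   locus), `evidence = "nine_bp_dup"`, `read_id`, `library`.
#' @export
detect_9bp_duplications <- function(reads, segments, lengths,
                                    library = NA_character_, min_mapq = 5L,
                                    end_filter = 150L) {
  if (!all(c("mate1_seq", "mate2_seq") %in% names(reads))) {
    abort("detect_9bp_duplications requires paired reads (mate1_seq/mate2_seq)")
  }
  seq_ok <- nchar(reads$mate1_seq) >= 9L & nchar(reads$mate2_seq) >= 9L &
    substr(reads$mate1_seq, 1L, 9L) == revcomp(substr(reads$mate2_seq, 1L, 9L))
  cand_ids <- reads$pair_id[seq_ok]
  if (length(cand_ids) == 0) return(empty_junction_calls(library, nine_bp = TRUE))
  seg <- standard_filters(segments, min_mapq) |>
    filter(!.data$supplementary, .data$read_id %in% cand_ids,
           !is.na(.data$mate))
  pairs <- seg |>
    group_by(.data$read_id) |>
    filter(n() == 2L, n_distinct(.data$mate) == 2L,
           n_distinct(.data$contig) == 1L, n_distinct(.data$strand) == 2L) |>
    summarise(
      contig = .data$contig[1],
      plus_start = .data$ref_start[.data$strand == "+"],
      plus_end = .data$ref_end[.data$strand == "+"],
      minus_start = .data$ref_start[.data$strand == "-"],
      minus_end = .data$ref_end[.data$strand == "-"],
      .groups = "drop"
    ) |>
    filter(.data$minus_end - .data$plus_start == 9L) |>
    mutate(circle_start = pmin(.data$plus_start, .data$minus_start),
           circle_end = pmax(.data$plus_end, .data$minus_end)) |>
    filter(.data$circle_start >= end_filter,
           .data$circle_end <= lengths[.data$contig] - end_filter)
  pairs |>
    transmute(
      contig = .data$contig, circle_start = .data$circle_start,
      circle_end = .data$circle_end, cut_start = .data$plus_start,
      cut_end = .data$minus_end, evidence = "nine_bp_dup",
      read_id = .data$read_id, library = library
    )
}

empty_junction_calls <- function(library, nine_bp = FALSE) {
  out <- tibble(contig = character(), circle_start = integer(),
                circle_end = integer())
  if (nine_bp) {
    out$cut_start <- integer(); out$cut_end <- integer()
  }
  out$evidence <- character(); out$read_id <- character()
  out$library <- character()
  out
}

TIR_LEFT_MOTIF <- "AACCCCAAAACCCC"   # A2C4A4C4
TIR_RIGHT_MOTIF <- "GGGGTTTTGGGGTT"  # G4T4G4T2

#' Position frequency table of TBE TIR ends and flanking bases
#'
#' Anchors each TBE locus by locating the partially conserved telomeric
#' motifs A2C4A4C4 (left TIR start) and G4T4G4T2 (right TIR end), allowing
#' up to `max_mismatch` mismatches per motif, then tabulates per-position
#' nucleotide frequencies around the two target-site-duplication copies.
#' Positions are numbered per side from outside in: 1-4 flanking genomic
#' bases (4 immediately outside the TSD -- the "position -4" base on the left
#' side), 5-7 the TSD read in its A-N-T orientation, 8 the first/last TIR
#' base. Loci where either anchor is missing are skipped and counted.
#'
#' @param sequences Character vector of TBE locus sequences including
#'   flanking genomic bases (see [tbe_locus_sequences()]).
#' @param max_mismatch Mismatch tolerance per telomeric anchor motif.
#' @return A tibble `side`, `position`, `base`, `n`, `freq` with attributes
#'   `n_used` and `n_skipped`.
#' @export
tir_consensus <- function(sequences, max_mismatch = 2L) {
  used <- 0L; skipped <- 0L
  rows <- list()
  for (s in sequences) {
    ds <- Biostrings::DNAString(s)
    mL <- Biostrings::matchPattern(TIR_LEFT_MOTIF, ds,
                                   max.mismatch = max_mismatch)
    mR <- Biostrings::matchPattern(TIR_RIGHT_MOTIF, ds,
                                   max.mismatch = max_mismatch)
    if (length(mL) == 0 || length(mR) == 0) { skipped <- skipped + 1L; next }
    tir_start <- IRanges::start(mL)[1] - 2L          # 1-based first TIR base
    tir_end <- IRanges::end(mR)[length(mR)] + 2L     # 1-based last TIR base
    # left: [f1 f2 f3 f4][A N T][TIR ...
    lpos <- c(tir_start - 7L + 0:3, tir_start - 3L + 0:2, tir_start)
    # right: ... TIR][A N T][g1 g2 g3 g4] (position 4 adjacent to TSD)
    rpos <- c(tir_end + 7L - 0:3, tir_end + 1:3, tir_end)
    if (min(lpos) < 1L || max(rpos) > nchar(s)) { skipped <- skipped + 1L; next }
    used <- used + 1L
    rows[[length(rows) + 1L]] <- tibble(
      side = rep(c("left", "right"), each = 8L),
      position = rep(c(1:4, 5:7, 8L), 2L),
      base = c(substring(s, lpos, lpos), substring(s, rpos, rpos))
    )
  }
  if (length(rows) == 0) {
    out <- tibble(side = character(), position = integer(),
                  base = character(), n = integer(), freq = double())
  } else {
    out <- list_rbind(rows) |>
      count(.data$side, .data$position, .data$base) |>
      group_by(.data$side, .data$position) |>
      mutate(freq = .data$n / sum(.data$n)) |>
      ungroup()
  }
  attr(out, "n_used") <- used
  attr(out, "n_skipped") <- skipped
  out
}

#' Extract TBE locus sequences with flanks
#'
#' @param genome An `ecc_genome`.
#' @param flank Flanking genomic bases to include on each side.
#' @return Character vector, one sequence per annotated TBE.
#' @export
tbe_locus_sequences <- function(genome, flank = 20L) {
  tb <- genome$tbes
  map_chr(seq_len(nrow(tb)), function(i) {
    len <- nchar(genome$contigs[[tb$contig[i]]])
    subseq0(genome$contigs[[tb$contig[i]]],
            max(0L, tb$start[i] - flank), min(len, tb$end[i] + flank))
  })
}
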