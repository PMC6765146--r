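# Rearrangement-specific transcription of circles from RNA-seq:
# length-normalized counts against interval-shuffle permutation nulls, and
# horizontal RNA coverage.

#' Length-normalized read counts in intervals
#'
#' Counts reads (distinct read ids; a split read overlapping twice counts
#' once) with at least 1 bp intersection per interval, divided by interval
#' length (per-bp counts).
#'
#' @param rna_segments Mapped RNA alignment tibble (`read_id`, `contig`,
#'   `start`/`ref_start`, `end`/`ref_end`).
#' @param intervals Tibble with `contig`, `start`, `end` (positive lengths).
#' @return `intervals` with `n_reads` and `norm_count` columns.
#' @export
count_reads_in_intervals <- function(rna_segments, intervals) {
  if (any(intervals$end <= intervals$start)) {
    abort("count_reads_in_intervals: zero-length interval")
  }
  seg <- normalize_segment_cols(rna_segments)
  n_reads <- integer(nrow(intervals))
  for (ctg in unique(intervals$contig)) {
    ii <- which(intervals$contig == ctg)
    sc <- seg |> filter(.data$contig == ctg)
    if (nrow(sc) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(intervals$start[ii] + 1L, intervals$end[ii]),
      IRanges::IRanges(sc$start + 1L, sc$end)
    )
    if (length(hits) == 0) next
    cnt <- tapply(sc$read_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  function(x) length(unique(x)))
    n_reads[ii[as.integer(names(cnt))]] <- as.integer(cnt)
  }
  intervals |>
    mutate(n_reads = n_reads,
           norm_count = n_reads / (.data$end - .data$start))
}

normalize_segment_cols <- function(seg) {
  if ("ref_start" %in% names(seg)) {
    seg <- seg |> rename(start = "ref_start", end = "ref_end")
  }
  if ("unmapped" %in% names(seg)) seg <- seg |> filter(!.data$unmapped)
  seg |> select("read_id", "contig", "start", "end")
}

#' Permutation percentile of mean circle transcription
#'
#' Shuffles the circle coordinates `n` times over the chosen domain
#' (genome-wide, or restricted to IES intervals), recomputing the mean
#' length-normalized read count each time. The percentile is the fraction of
#' replicates whose mean falls strictly below the observed mean (ties count
#' as not-below); it is invariant under global scaling of all counts.
#'
#' @param intervals Circle coordinate tibble (`contig`, `start`, `end`).
#' @param rna_segments Mapped RNA alignments of one condition.
#' @param domain `"ies_only"` or `"genome_wide"`, or a domain tibble.
#' @param genome An `ecc_genome` (required when `domain` is a keyword).
#' @param n Number of permutations (>= 1; default 1000).
#' @param seed Optional seed.
#' @param ies_pad Padding (bp) added around IES segments for the
#'   IES-restricted domain, mirroring the boundary imprecision of the
#'   circles being shuffled.
#' @return An [null_distribution()] object (`ecc_null`).
#' @export
permutation_percentile <- function(intervals, rna_segments,
                                   domain = c("ies_only", "genome_wide"),
                                   genome = NULL, n = 1000L, seed = NULL,
                                   ies_pad = 25L) {
  if (n < 1L) abort("permutation_percentile: n must be >= 1")
  anchor <- "within"
  clens <- NULL
  if (is.character(domain)) {
    domain <- match.arg(domain)
    if (is.null(genome)) abort("genome required for a keyword domain")
    if (domain == "ies_only") {
      # circles slightly longer than the largest padded IES fall back to
      # start-anchored placement, preserving interval lengths
      domain <- ies_domain(genome, pad = ies_pad)
      anchor <- "auto"
      clens <- contig_lengths(genome)
    } else {
      domain <- genome_domain(genome)
    }
  }
  observed <- mean(count_reads_in_intervals(rna_segments,
                                            intervals)$norm_count)
  sh <- shuffle_intervals(intervals, domain, n = n, seed = seed,
                          anchor = anchor, contig_lengths = clens)
  cnt <- count_reads_in_intervals(rna_segments, sh)
  reps <- cnt |>
    group_by(.data$rep) |>
    summarise(m = mean(.data$norm_count), .groups = "drop")
  null_distribution(observed, reps$m)
}

#' Horizontal RNA coverage of circles
#'
#' The fraction of each circle's length covered by at least one RNA read
#' (same geometric definition as DNA horizontal coverage), with the standard
#' summary fractions: no coverage, more than 20%, more than 80%.
#'
#' @param circles Tibble with `contig`, `start`, `end`.
#' @param rna_segments Mapped RNA alignments.
#' @return A list: `per_circle` (`circles` plus `rna_coverage`) and
#'   `summary` (one row: `fraction_zero`, `fraction_gt_20`,
#'   `fraction_gt_80`).
#' @export
horizontal_rna_coverage <- function(circles, rna_segments) {
  seg <- normalize_segment_cols(rna_segments) |>
    mutate(ref_start = .data$start, ref_end = .data$end, unmapped = FALSE)
  cov <- horizontal_coverage(circles, seg)
  list(
    per_circle = circles |> mutate(rna_coverage = cov),
    summary = tibble(
      fraction_zero = mean(cov == 0),
      fraction_gt_20 = mean(cov > 0.2),
      fraction_gt_80 = mean(cov > 0.8)
    )
  )
}

#' Depth-normalize libraries by binomial subsampling
#'
#' Downsamples each library to the size of the smallest: every read is kept
#' independently with probability `min(mapped) / mapped(library)`; the
#' smallest library passes unchanged (factor 1).
#'
#' @param segments Alignment tibble with a `library` column (all segments of
#'   a kept read are retained).
#' @param seed Optional seed.
#' @return A list: `segments` (subsampled) and `factors` (per-library
#'   tibble of `mapped_reads` and `factor`).
#' @export
subsample_normalize <- function(segments, seed = NULL) {
  local_seed_if(seed)
  sizes <- segments |>
    distinct(.data$library, .data$read_id) |>
    count(.data$library, name = "mapped_reads")
  sizes$factor <- min(sizes$mapped_reads) / sizes$mapped_reads
  keep <- segments |>
    distinct(.data$library, .data$read_id) |>
    left_join(sizes, by = "library") |>
    filter(runif(n()) < .data$factor) |>
    select("library", "read_id")
  list(
    segments = segments |> semi_join(keep, by = c("library", "read_id")),
    factors = sizes
  )
}
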