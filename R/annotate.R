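# Characterize high-confidence circles against the rearrangement map:
# distance to MDS boundaries, cut-site compartments around pointers,
# flanking direct repeats, eliminated-sequence categories, and the
# shuffle-null / test statistics that go with them.

#' Distance from circle boundaries to the nearest MDS boundary
#'
#' For each circle, the distance from each cut coordinate to the nearest MDS
#' start or end on the same contig, and their minimum (0 if a boundary
#' coincides). Circles on contigs without MDS annotations get `Inf` (binned
#' as ">2000/none" downstream).
#'
#' @param circles Tibble with `contig`, `start`, `end`.
#' @param mds MDS annotation tibble (`contig`, `start`, `end`), e.g.
#'   `genome$mds`.
#' @return `circles` with `dist_start`, `dist_end`, `dist_mds` columns.
#' @export
distance_to_mds <- function(circles, mds) {
  bounds <- lapply(split(mds, mds$contig),
                   function(m) sort(unique(c(m$start, m$end))))
  nearest <- function(ctg, pos) {
    out <- rep(Inf, length(pos))
    for (c1 in unique(ctg)) {
      b <- bounds[[c1]]
      if (is.null(b)) next
      ii <- which(ctg == c1)
      k <- findInterval(pos[ii], b)
      lo <- ifelse(k >= 1L, abs(pos[ii] - b[pmax(k, 1L)]), Inf)
      hi <- ifelse(k < length(b), abs(b[pmin(k + 1L, length(b))] - pos[ii]), Inf)
      out[ii] <- pmin(lo, hi)
    }
    out
  }
  circles |>
    ungroup() |>
    mutate(
      dist_start = nearest(.data$contig, .data$start),
      dist_end = nearest(.data$contig, .data$end),
      dist_mds = pmin(.data$dist_start, .data$dist_end)
    )
}

#' Bin MDS distances into the standard report bins
#'
#' Default bins: 0-49, 50-249, 250-999, 1000-2000, and >2000 bp or
#' MDS-lacking contig (`Inf`). Frequencies sum to one.
#'
#' @param distances Numeric distances (may contain `Inf`).
#' @param breaks Upper bin bounds (inclusive), last bin open-ended.
#' @param labels Bin labels.
#' @return Tibble `bin`, `n`, `freq`.
#' @export
bin_distances <- function(distances,
                          breaks = c(49, 249, 999, 2000),
                          labels = c("0-49", "50-249", "250-999",
                                     "1000-2000", ">2000/none")) {
  if (length(distances) == 0) abort("bin_distances: empty input")
  stopifnot(length(labels) == length(breaks) + 1L)
  idx <- findInterval(distances, c(breaks + 0.5), left.open = FALSE) + 1L
  counts <- tabulate(idx, nbins = length(labels))
  tibble(bin = factor(labels, levels = labels), n = counts,
         freq = counts / sum(counts))
}

#' Observed vs shuffled MDS-distance bin frequencies
#'
#' Shuffles the circle set across the assembly `n` times, re-binning the
#' distance to the nearest MDS boundary each time, and reports the observed
#' frequency per bin with the null mean and sd (plot with a three-sd
#' envelope).
#'
#' @param circles Tibble with `contig`, `start`, `end`.
#' @param genome An `ecc_genome`.
#' @param n Number of shuffles (default 500).
#' @param seed Optional seed.
#' @inheritParams bin_distances
#' @return Tibble `bin`, `observed`, `null_mean`, `null_sd` of class
#'   `ecc_distance_bins`.
#' @export
mds_distance_bins <- function(circles, genome, n = 500L, seed = NULL,
                              breaks = c(49, 249, 999, 2000),
                              labels = c("0-49", "50-249", "250-999",
                                         "1000-2000", ">2000/none")) {
  local_seed_if(seed)
  obs <- bin_distances(
    distance_to_mds(circles, genome$mds)$dist_mds, breaks, labels)
  sh <- shuffle_intervals(circles, genome_domain(genome), n = n)
  null_freq <- sh |>
    distance_to_mds(genome$mds) |>
    group_by(.data$rep) |>
    group_map(function(df, key) bin_distances(df$dist_mds, breaks, labels)$freq)
  nm <- do.call(rbind, null_freq)
  out <- obs |>
    transmute(bin = .data$bin, observed = .data$freq,
              null_mean = colMeans(nm),
              null_sd = apply(nm, 2, sd))
  class(out) <- c("ecc_distance_bins", class(out))
  out
}

#' Classify inferred cut sites around pointers
#'
#' Each circle contributes two inferred cut sites (its boundaries). Cuts
#' within `window` bp of an MDS boundary are classified by interval
#' membership into pointer / IES / MDS compartments (a cut on a pointer's
#' edge counts as pointer), with a signed offset from the nearest pointer
#' copy's IES-facing edge: positive into the IES, negative into the MDS,
#' zero at the edge. Cuts on loci lacking pointer annotations are flagged
#' unclassifiable.
#'
#' @param circles Tibble with `contig`, `start`, `end` (plus optional id
#'   columns carried through).
#' @param genome An `ecc_genome` (pointer, MDS and eliminated annotations).
#' @param window Maximum distance (bp) from an MDS boundary for a cut to be
#'   classified.
#' @return One row per qualifying cut: carried id columns, `side`, `cut`,
#'   `dist_mds`, `compartment`, `offset_from_pointer`, `within_window`,
#'   `unclassifiable`.
#' @export
classify_cut_sites <- function(circles, genome, window = 50L) {
  mds <- genome$mds; ptr <- genome$pointers; elim <- genome$eliminated
  cuts <- bind_rows(
    circles |> mutate(side = "left", cut = .data$start),
    circles |> mutate(side = "right", cut = .data$end)
  )
  cuts <- distance_to_mds(
    cuts |> mutate(start = .data$cut, end = .data$cut + 1L) |>
      select(-any_of(c("dist_start", "dist_end", "dist_mds"))),
    mds
  ) |>
    mutate(dist_mds = .data$dist_start) |> # distance of the cut itself
    select(-"dist_start", -"dist_end") |>
    mutate(within_window = .data$dist_mds <= window) |>
    filter(.data$within_window)
  if (nrow(cuts) == 0) {
    return(cuts |> mutate(compartment = character(0),
                          offset_from_pointer = integer(0),
                          unclassifiable = logical(0)))
  }
  n <- nrow(cuts)
  compartment <- character(n); offset <- rep(NA_integer_, n)
  unclass <- logical(n)
  for (i in seq_len(n)) {
    ctg <- cuts$contig[i]; p <- cuts$cut[i]
    pc <- ptr |> filter(.data$contig == ctg)
    in_ptr <- pc |> filter(.data$start <= p, p <= .data$end)
    in_elim <- any(elim$contig == ctg & elim$start <= p & p < elim$end)
    in_mds <- any(mds$contig == ctg & mds$start <= p & p < mds$end)
    compartment[i] <- if (nrow(in_ptr) > 0) "pointer"
      else if (in_elim) "IES" else if (in_mds) "MDS" else "IES"
    if (nrow(pc) == 0) { unclass[i] <- TRUE; next }
    # IES-facing edge: copy 1 sits at the end of MDS n (IES to its right),
    # copy 2 at the start of MDS n+1 (IES to its left)
    edge <- ifelse(pc$copy == 1L, pc$end, pc$start)
    j <- which.min(abs(edge - p))
    offset[i] <- if (pc$copy[j] == 1L) p - edge[j] else edge[j] - p
  }
  cuts |>
    mutate(compartment = compartment, offset_from_pointer = offset,
           unclassifiable = unclass) |>
    select(-"start", -"end")
}

#' Length of the direct repeat flanking a circle junction
#'
#' The junction register (fixed by the junction read; see
#' [canonical_junction()]) defines two genomic points, `start` and `end`.
#' The flanking direct repeat is the maximal exact extension in both
#' directions from the junction point: bases entering the junction
#' (`genome[start - i] == genome[end - i]`) plus bases leaving it
#' (`genome[start + j] == genome[end + j]`), capped at `max_len`. A length
#' of 0 means no flanking repeat; searches truncated by a contig end are
#' flagged.
#'
#' @param genome An `ecc_genome` or named contig vector.
#' @param circles Tibble with `contig`, `start`, `end`.
#' @param max_len Search cap (bp); in vivo repeats top out well below this.
#' @return `circles` with `repeat_len`, `repeat_left`, `repeat_right`,
#'   `repeat_truncated`.
#' @export
flanking_direct_repeat <- function(genome, circles, max_len = 25L) {
  contigs <- contig_seqs(genome)
  n <- nrow(circles)
  left <- integer(n); right <- integer(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    seq <- contigs[[circles$contig[i]]]
    clen <- nchar(seq)
    s <- circles$start[i]; e <- circles$end[i]
    len <- e - s
    wl <- min(max_len, s, len)
    left[i] <- if (wl > 0) common_suffix_len(
      subseq0(seq, s - wl, s), subseq0(seq, e - wl, e)) else 0L
    wr <- min(max_len, clen - e, len)
    right[i] <- if (wr > 0) common_prefix_len(
      subseq0(seq, s, s + wr), subseq0(seq, e, e + wr)) else 0L
    trunc[i] <- (left[i] == wl && wl < min(max_len, len)) ||
      (right[i] == wr && wr < min(max_len, len))
  }
  circles |>
    mutate(repeat_left = left, repeat_right = right,
           repeat_len = pmin(left + right, max_len),
           repeat_truncated = trunc)
}

#' Classify the eliminated-sequence type a circle removes
#'
#' For circles whose two ends each lie within `window` bp of an MDS
#' boundary: `non_scrambled_ies` when the flanking MDSs are MAC-consecutive
#' (indices n and n+1 of the same locus), `scrambled_ies` when they belong to
#' the same locus but are non-consecutive or inverted, `intergenic` when they
#' belong to different MAC loci. Circles whose span contains one or more
#' complete MDSs are additionally flagged `mds_bearing`. Ends not near any
#' MDS boundary leave the category `NA`.
#'
#' @param circles Tibble with `contig`, `start`, `end`.
#' @param genome An `ecc_genome`.
#' @param window Maximum boundary distance (bp).
#' @return `circles` with `category`, `mds_bearing`.
#' @export
classify_eliminated_type <- function(circles, genome, window = 50L) {
  mds <- genome$mds
  n <- nrow(circles)
  category <- rep(NA_character_, n); bearing <- logical(n)
  for (i in seq_len(n)) {
    ctg <- circles$contig[i]
    s <- min(circles$start[i], circles$end[i])
    e <- max(circles$start[i], circles$end[i])
    m <- mds |> filter(.data$contig == ctg)
    if (nrow(m) == 0) next
    dl <- abs(m$end - s)
    dr <- abs(m$start - e)
    if (min(dl) > window || min(dr) > window) {
      bearing[i] <- any(m$start >= s & m$end <= e)
      next
    }
    left <- m[which.min(dl), ]
    right <- m[which.min(dr), ]
    category[i] <- if (left$mac_locus != right$mac_locus) "intergenic"
      else if (right$mds_index == left$mds_index + 1L) "non_scrambled_ies"
      else "scrambled_ies"
    bearing[i] <- any(m$start >= s & m$end <= e)
  }
  circles |> mutate(category = category, mds_bearing = bearing)
}

#' Eliminated-site summary with chi-squared test
#'
#' Given, per eliminated-sequence category, the number of eliminated sites
#' in the germline and the number observed to give rise to eccDNA, computes
#' the percentage of sites with eccDNA (two decimals at report precision)
#' and a chi-squared test on the 2x2 table of scrambled vs non-scrambled
#' sites with/without eccDNA.
#'
#' @param counts Tibble with `category` (must include `non_scrambled` and
#'   `scrambled`), `sites_with_eccdna`, `total_sites`.
#' @return A list: `summary` (with `pct_with_eccdna`), `chisq_statistic`,
#'   `chisq_p`.
#' @export
eliminated_site_summary <- function(counts) {
  summary <- counts |>
    mutate(pct_with_eccdna = round(
      .data$sites_with_eccdna / .data$total_sites * 100, 2))
  need <- c("non_scrambled", "scrambled")
  if (!all(need %in% counts$category)) {
    abort("eliminated_site_summary: need non_scrambled and scrambled rows")
  }
  ns <- counts[match("non_scrambled", counts$category), ]
  sc <- counts[match("scrambled", counts$category), ]
  tab <- matrix(c(ns$sites_with_eccdna, ns$total_sites - ns$sites_with_eccdna,
                  sc$sites_with_eccdna, sc$total_sites - sc$sites_with_eccdna),
                nrow = 2, byrow = TRUE)
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(summary = summary,
       chisq_statistic = unname(ht$statistic),
       chisq_p = unname(ht$p.value))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' the standard asymptotic two-sample approximation.
#'
#' @param sample_a,sample_b Numeric samples.
#' @return A list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  ht <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}
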