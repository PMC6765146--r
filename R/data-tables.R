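#' Published Circulome-seq library statistics
#'
#' Per-library read statistics from a published genome-wide Circulome-seq
#' survey of *Oxytricha* development (two asexual, two early-, two
#' mid-rearrangement exonuclease-enriched replicates, one mid-rearrangement
#' unenriched library and one late replicate): total mapped reads, raw counts
#' of TBE junction reads, non-repetitive circle junction reads (with unique
#' isoform counts) and 9 bp duplication read pairs, and their reported RPM
#' values. The raw counts and totals let every RPM value, and the ~67-fold
#' mid-vs-asexual rise in junction reads, be recomputed with [rpm()].
#'
#' @return A tibble, one row per library.
#' @export
circulome_library_stats <- function() {
  readr::read_tsv(
    system.file("extdata", "circulome_library_stats.tsv",
                package = "circulome"),
    show_col_types = FALSE
  )
}

#' Published eliminated-site census
#'
#' Counts of eliminated germline sites by category (non-scrambled IESs,
#' scrambled IESs, intergenic regions near chromosome breakage sites) and how
#' many of each were observed to give rise to high-confidence eccDNA in the
#' same survey; input for [eliminated_site_summary()].
#'
#' @return A tibble, one row per category.
#' @export
eliminated_site_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "eliminated_site_counts.tsv",
                package = "circulome"),
    show_col_types = FALSE
  )
}
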