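#' Simulation configuration
#'
#' Bundles every tunable of the synthetic germline (MIC) genome and
#' Circulome-seq read simulator. Defaults describe a desk-scale caricature of
#' a rearranging ciliate genome: a handful of MIC contigs carrying MAC loci
#' split into MDSs separated by IESs with short pointer repeats at
#' MAC-consecutive MDS boundaries, plus a few telomere-bearing-element (TBE)
#' transposons with ANT target-site duplications.
#'
#' @param n_contigs Number of MIC contigs.
#' @param contig_length Length of each contig (bp).
#' @param n_mac_loci Total number of MAC loci, distributed round-robin over
#'   contigs.
#' @param mds_per_locus MDSs per MAC locus.
#' @param mds_length_range Min/max MDS core length (bp).
#' @param ies_length_range Min/max IES length (bp). The minimum must be at
#'   least 57 bp, the smallest circularly excised IES observed in vivo.
#' @param pointer_length_nonscrambled Min/max pointer length at non-scrambled
#'   boundaries (mean ~5 bp).
#' @param pointer_length_scrambled Min/max pointer length at scrambled-locus
#'   boundaries (mean ~11 bp).
#' @param fraction_scrambled Proportion of MAC loci with permuted MIC order.
#' @param n_tbe Number of TBE transposons placed in intergenic space.
#' @param tbe_length Approximate TBE element length (bp, ~4000 in vivo).
#' @param tbe_flank_probs Named probabilities (A/C/G/T) for the base
#'   immediately 5' of the upstream TSD copy (the "position -4" base copied
#'   into the circular junction 5-mer). Defaults to the observed genomic
#'   composition C 19 / G 52 / A 22 / T 7 %.
#' @param read_length Read length (bp) for simulated paired-end reads.
#' @param insert_size Mean and sd (bp pair) of the sequenced insert; used as a
#'   Gaussian size-selection kernel on tagmentation fragments.
#' @param depth Target per-molecule fold coverage for circular molecules in a
#'   fully rearranging (mid) library.
#' @param cut_offset_sd Sd (bp) of the truncated-normal imprecision of IES
#'   excision cuts around the pointer anchors; independent per side.
#' @param circles_per_ies Independent excision events drawn per excisable IES
#'   (isoform heterogeneity).
#' @param p_excise Named probabilities that a non_scrambled / scrambled /
#'   intergenic eliminated locus circularizes at all.
#' @param exo_linear_survival Probability a linear molecule survives the
#'   exonuclease treatment in +exo libraries.
#' @param n_linear_background Number of linear genomic background fragments
#'   per library before exonuclease treatment.
#' @param seed Optional integer seed recorded in the config; generator
#'   functions also accept per-call seeds.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_contigs = 6L,
                       contig_length = 20000L,
                       n_mac_loci = 12L,
                       mds_per_locus = 5L,
                       mds_length_range = c(150L, 400L),
                       ies_length_range = c(80L, 400L),
                       pointer_length_nonscrambled = c(3L, 7L),
                       pointer_length_scrambled = c(8L, 14L),
                       fraction_scrambled = 0.15,
                       n_tbe = 3L,
                       tbe_length = 4000L,
                       tbe_flank_probs = c(A = 0.22, C = 0.19, G = 0.52, T = 0.07),
                       read_length = 75L,
                       insert_size = c(400L, 80L),
                       depth = 30,
                       cut_offset_sd = 8,
                       circles_per_ies = 3L,
                       p_excise = c(non_scrambled = 0.8, scrambled = 0.08,
                                    intergenic = 0.15),
                       exo_linear_survival = 0.03,
                       n_linear_background = 400L,
                       seed = NULL) {
  cfg <- list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_mac_loci = as.integer(n_mac_loci),
    mds_per_locus = as.integer(mds_per_locus),
    mds_length_range = as.integer(mds_length_range),
    ies_length_range = as.integer(ies_length_range),
    pointer_length_nonscrambled = as.integer(pointer_length_nonscrambled),
    pointer_length_scrambled = as.integer(pointer_length_scrambled),
    fraction_scrambled = fraction_scrambled,
    n_tbe = as.integer(n_tbe),
    tbe_length = as.integer(tbe_length),
    tbe_flank_probs = tbe_flank_probs,
    read_length = as.integer(read_length),
    insert_size = as.numeric(insert_size),
    depth = depth,
    cut_offset_sd = cut_offset_sd,
    circles_per_ies = as.integer(circles_per_ies),
    p_excise = p_excise,
    exo_linear_survival = exo_linear_survival,
    n_linear_background = as.integer(n_linear_background),
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  lens <- c(
    cfg$n_contigs, cfg$contig_length, cfg$n_mac_loci, cfg$mds_per_locus,
    cfg$mds_length_range, cfg$ies_length_range,
    cfg$pointer_length_nonscrambled, cfg$pointer_length_scrambled,
    cfg$n_tbe >= 0, cfg$tbe_length, cfg$read_length, cfg$insert_size
  )
  if (any(lens <= 0)) abort("all sim_config lengths and counts must be positive")
  props <- c(cfg$fraction_scrambled, cfg$p_excise, cfg$exo_linear_survival)
  if (any(props < 0 | props > 1)) {
    abort("sim_config proportions must lie in [0, 1]")
  }
  if (cfg$ies_length_range[1] < 57L) {
    abort("ies_length_range minimum must be >= 57 bp (smallest circularly excised IES)")
  }
  if (abs(sum(cfg$tbe_flank_probs) - 1) > 1e-8 ||
      !setequal(names(cfg$tbe_flank_probs), DNA_BASES)) {
    abort("tbe_flank_probs must be named A/C/G/T probabilities summing to 1")
  }
  if (!setequal(names(cfg$p_excise),
                c("non_scrambled", "scrambled", "intergenic"))) {
    abort("p_excise must name non_scrambled, scrambled and intergenic")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.null(val)) val <- "NULL"
    cat(sprintf("  %-28s %s\n", nm, paste(format(val), collapse = " ")))
  }
  invisible(x)
}

#' Read or write a simulation configuration file
#'
#' Configs round-trip through a flat YAML file so a simulation is fully
#' described by one small text file plus a seed.
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  # named vectors go out as YAML maps so names survive the round trip
  out <- lapply(unclass(cfg), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, lapply(raw, function(x) {
    if (is.list(x)) unlist(x) else x
  }))
}

#' The Circulome-seq library grid
#'
#' The fixed developmental design the downstream filters reference: two
#' asexual replicates, two early- and two mid-rearrangement +exo replicates,
#' one mid-rearrangement library without exonuclease treatment, and one late
#' replicate. `circle_factor` scales circular-molecule abundance relative to
#' the mid-rearrangement peak.
#'
#' @return A tibble with columns `library`, `timepoint`, `replicate`, `exo`,
#'   `circle_factor`.
#' @export
library_grid <- function() {
  tibble(
    library = c("asexual_1", "asexual_2", "early_1", "early_2",
                "mid_1", "mid_2", "mid_noexo_1", "late_1"),
    timepoint = c("asexual", "asexual", "early", "early",
                  "mid", "mid", "mid", "late"),
    replicate = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L),
    exo = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    circle_factor = c(0, 0, 0.1, 0.1, 1, 1, 1, 0.35)
  )
}
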