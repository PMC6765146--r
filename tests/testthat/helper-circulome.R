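# Shared fixtures, built once per test run. Everything is generated in code;
# nothing is read from disk except the shipped reference tables.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# default desk-scale genome + index
fix_genome <- function() cached("genome", sim_genome(sim_config(), seed = 101))
fix_index <- function() cached("index", build_genome_index(fix_genome()))

# map a read-pair tibble single-end (each mate independently)
map_pairs <- function(pairs, genome, index) {
  long <- tibble::tibble(
    read_id = rep(pairs$pair_id, 2),
    mate = rep(1:2, each = nrow(pairs)),
    seq = c(pairs$mate1_seq, pairs$mate2_seq)
  )
  map_reads(long, genome, index = index)
}

# a minimal hand-built alignment segment row
seg <- function(read_id, contig, ref_start, ref_end, read_start, read_end,
                strand = "+", mapq = 60L, mate = NA_integer_,
                secondary = FALSE, supplementary = FALSE, duplicate = FALSE,
                unmapped = FALSE) {
  tibble::tibble(read_id = read_id, mate = mate, contig = contig,
                 ref_start = as.integer(ref_start),
                 ref_end = as.integer(ref_end),
                 read_start = as.integer(read_start),
                 read_end = as.integer(read_end), strand = strand,
                 mapq = as.integer(mapq), secondary = secondary,
                 supplementary = supplementary, duplicate = duplicate,
                 unmapped = unmapped)
}

# configuration used for planted-circle recovery studies: 52 non-scrambled
# IESs excised precisely (one isoform each), IESs long enough that size
# selection retains junction fragments
recovery_config <- function(cut_offset_sd = 0) {
  sim_config(
    n_contigs = 6L, contig_length = 22000L, n_mac_loci = 13L,
    mds_per_locus = 5L, ies_length_range = c(200L, 400L),
    fraction_scrambled = 0, n_tbe = 0L,
    p_excise = c(non_scrambled = 1, scrambled = 1, intergenic = 0),
    circles_per_ies = 1L, cut_offset_sd = cut_offset_sd, depth = 60
  )
}
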