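#' Simulate a full Circulome-seq experiment over the library grid
#'
#' Runs excision, exonuclease enrichment and tagmentation for every library in
#' [library_grid()]: two asexual replicates (no circles), two early and two
#' mid-rearrangement +exo replicates, one mid-rearrangement library without
#' exonuclease treatment and one late replicate. Circle abundance scales with
#' the grid's `circle_factor`; linear genomic background is drawn fresh per
#' library and exonuclease-filtered in +exo libraries.
#'
#' @param genome An `ecc_genome`.
#' @param circles An `ecc_circles` tibble; defaults to a fresh
#'   [excise_circles()] draw.
#' @param config A [sim_config()].
#' @param seed Optional integer seed governing all randomness.
#' @return A list with `reads` (row-bound read-pair tibble over all
#'   libraries), `circles` (the truth circles), and `grid` (the library
#'   design).
#' @export
sim_circulome <- function(genome, circles = NULL, config = genome$config,
                          seed = NULL) {
  local_seed_if(seed)
  if (is.null(circles)) circles <- excise_circles(genome, config)
  grid <- library_grid()
  reads <- map(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    bg <- sim_linear_background(genome, config$n_linear_background)
    if (row$exo) bg <- exonuclease_filter(bg, config$exo_linear_survival)
    bg$molecule_id <- paste(row$library, bg$molecule_id, sep = ":")
    mol <- if (row$circle_factor > 0) as_molecules(circles) else NULL
    rp <- tagment_and_read(
      mol, linear_background = bg, config = config, library = row$library,
      depth = config$depth * max(row$circle_factor, 0.01)
    )
    list(reads = rp, molecules = bind_rows(mol, bg))
  })
  molecules <- list_rbind(map(reads, "molecules")) |>
    distinct(.data$molecule_id, .keep_all = TRUE)
  list(
    reads = list_rbind(map(reads, "reads")),
    circles = circles,
    molecules = molecules,
    grid = grid
  )
}

#' Ground-truth alignments for simulated read pairs
#'
#' Computes, from the simulator's bookkeeping alone, where each mate of each
#' read pair should align on the MIC genome: contig, 0-based half-open
#' interval and strand, split into multiple segments when the mate crosses a
#' circle junction (chimeric). TBE circles are skipped (their junction 5-mer
#' is not a genome substring); so are truncated pairs.
#'
#' @param reads Read-pair tibble from [tagment_and_read()].
#' @param molecules Molecule tibble the reads were generated from (e.g.
#'   `sim_circulome()$molecules`, or `bind_rows(as_molecules(circles), bg)`).
#' @return A tibble with `pair_id`, `mate`, `seg_index`, `contig`, `start`,
#'   `end`, `strand`, `chimeric`.
#' @export
truth_alignments <- function(reads, molecules) {
  mol_info <- molecules |>
    transmute(molecule_id = .data$molecule_id, contig = .data$contig,
              mstart = .data$start, circular = .data$circular,
              skip = .data$category == "tbe")
  rd <- reads |>
    filter(!.data$truncated) |>
    select("pair_id", "molecule_id", "mol_len", "frag_start", "frag_len",
           "mate1_seq", "mate2_seq") |>
    left_join(mol_info, by = "molecule_id")
  if (anyNA(rd$circular)) {
    abort("truth_alignments: reads reference molecules absent from `molecules`")
  }
  rd <- rd |> filter(!.data$skip)
  if (nrow(rd) == 0) {
    return(tibble(pair_id = character(), mate = integer(), seg_index = integer(),
                  contig = character(), start = integer(), end = integer(),
                  strand = character(), chimeric = logical()))
  }
  out <- pmap(
    list(rd$pair_id, rd$contig, rd$mstart, rd$mol_len, rd$frag_start,
         rd$frag_len, rd$circular, nchar(rd$mate1_seq), nchar(rd$mate2_seq)),
    function(pid, ctg, ms, ml, fs, fl, circ, rl1, rl2) {
      m1 <- mate_segments(ctg, ms, ml, fs, rl1, circ, strand = "+")
      m2 <- mate_segments(ctg, ms, ml, fs + fl - rl2, rl2, circ, strand = "-")
      bind_rows(
        m1 |> mutate(pair_id = pid, mate = 1L),
        m2 |> mutate(pair_id = pid, mate = 2L)
      )
    }
  ) |> list_rbind()
  out |>
    mutate(chimeric = .data$n_seg > 1L) |>
    select("pair_id", "mate", "seg_index", "contig", "start", "end",
           "strand", "chimeric")
}

# Genomic segments covered by molecule offsets [off, off + n) (mod mlen for
# circular molecules anchored at genome position mstart).
mate_segments <- function(contig, mstart, mlen, off, n, circular, strand) {
  if (!circular) {
    return(tibble(contig = contig, start = mstart + off,
                  end = mstart + off + n, strand = strand,
                  seg_index = 1L, n_seg = 1L))
  }
  o1 <- off %% mlen
  if (o1 + n <= mlen) {
    segs <- tibble(contig = contig, start = mstart + o1,
                   end = mstart + o1 + n, strand = strand)
  } else {
    first <- mlen - o1
    rest <- n - first
    # may wrap more than once for molecules shorter than a read
    segs <- tibble(contig = contig,
                   start = c(mstart + o1, mstart),
                   end = c(mstart + mlen, mstart + min(rest, mlen)),
                   strand = strand)
  }
  segs |> mutate(seg_index = seq_len(n()), n_seg = n())
}
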