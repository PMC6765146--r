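#' Excise circular molecules from a synthetic genome
#'
#' TBE transposons are excised precisely: the circle carries one copy of the
#' ANT target-site duplication and a junction 5-mer `G + ANT + X`, where `X`
#' is the genomic base immediately outside the upstream TSD (the position -4
#' base), yielding the GANTC / GANTG / GANTA junction classes. Eliminated
#' non-repetitive loci (IESs and intergenic spacers) are excised imprecisely:
#' each cut is drawn from a normal distribution (sd = `config$cut_offset_sd`)
#' around its anchor, independently per side, re-sampled until the circle
#' retains at least 1 bp and stays within the contig. At zero noise a
#' non-scrambled IES circle is exactly the IES plus one pointer copy.
#'
#' @param genome An `ecc_genome` from [sim_genome()].
#' @param config A [sim_config()]; defaults to the genome's own.
#' @param seed Optional integer seed.
#' @return A tibble of class `ecc_circles`: one row per circular molecule with
#'   `circle_id`, `origin_contig`, `left_cut`, `right_cut` (0-based,
#'   `nchar(seq) == right_cut - left_cut` for eliminated-locus circles),
#'   canonical cut register (`canon_start`, `canon_end`), `category`,
#'   `junction_motif` (TBE 5-mer, otherwise `NA`), `source_id`, `seq`,
#'   `length`, and `topology` (always `"relaxed_circle"`).
#' @export
excise_circles <- function(genome, config = genome$config, seed = NULL) {
  stopifnot(inherits(genome, "ecc_genome"))
  local_seed_if(seed)

  tbe_circles <- NULL
  if (nrow(genome$tbes) > 0) {
    tbe_circles <- genome$tbes |>
      rowwise() |>
      mutate(
        seq = tbe_circle_seq(genome, .data$contig, .data$start, .data$end,
                             .data$tsd, .data$flank_minus4,
                             .data$tir_left_start, .data$tir_left_end,
                             .data$tir_right_start, .data$tir_right_end),
        junction_motif = paste0("G", .data$tsd, .data$flank_minus4)
      ) |>
      ungroup() |>
      transmute(
        origin_contig = .data$contig,
        left_cut = .data$start - 2L,
        right_cut = .data$tir_right_end,
        category = "tbe",
        junction_motif = .data$junction_motif,
        source_id = .data$tbe_id,
        seq = .data$seq
      )
  }

  elim_circles <- NULL
  if (nrow(genome$eliminated) > 0) {
    excisable <- genome$eliminated |>
      mutate(p = unname(config$p_excise[.data$type])) |>
      filter(runif(n()) < .data$p)
    reps <- excisable[rep(seq_len(nrow(excisable)), each = config$circles_per_ies), ]
    if (nrow(reps) > 0) {
      lens <- contig_lengths(genome)
      cuts <- pmap(
        list(reps$contig, reps$anchor_left, reps$anchor_right),
        function(ctg, al, ar) {
          draw_cut_pair(al, ar, config$cut_offset_sd, lens[[ctg]])
        }
      )
      elim_circles <- reps |>
        mutate(
          left_cut = map_int(cuts, 1L),
          right_cut = map_int(cuts, 2L)
        ) |>
        transmute(
          origin_contig = .data$contig,
          left_cut = .data$left_cut, right_cut = .data$right_cut,
          category = ifelse(.data$type == "intergenic", "intergenic",
                            paste0(.data$type, "_ies")),
          junction_motif = NA_character_,
          source_id = .data$elim_id,
          seq = unname(substr(genome$contigs[.data$contig],
                              .data$left_cut + 1L, .data$right_cut))
        )
    }
  }

  circles <- bind_rows(tbe_circles, elim_circles)
  if (is.null(circles) || nrow(circles) == 0) {
    circles <- tibble(
      origin_contig = character(), left_cut = integer(), right_cut = integer(),
      category = character(), junction_motif = character(),
      source_id = character(), seq = character()
    )
  }
  circles <- circles |>
    mutate(
      circle_id = sprintf("circ%04d", seq_len(n())),
      length = nchar(.data$seq),
      topology = "relaxed_circle"
    )
  canon <- pmap(
    list(circles$origin_contig, circles$left_cut, circles$right_cut),
    function(ctg, l, r) canonical_junction(genome, ctg, l, r)
  )
  circles <- circles |>
    mutate(
      canon_start = map_int(canon, function(x) as.integer(x[["start"]])),
      canon_end = map_int(canon, function(x) as.integer(x[["end"]]))
    ) |>
    relocate("circle_id", "origin_contig", "left_cut", "right_cut",
             "canon_start", "canon_end", "category")
  class(circles) <- c("ecc_circles", class(circles))
  circles
}

# Circle sequence of an excised TBE: one TSD copy plus the element, with the
# fixed G and the copied position -4 base forming the junction 5-mer. One
# resolved strand is emitted (the heteroduplex is not modelled).
tbe_circle_seq <- function(genome, contig, start, end, tsd, flank,
                           tl_s, tl_e, tr_s, tr_e) {
  seq <- genome$contigs[[contig]]
  inner <- subseq0(seq, tl_s, tr_e) # tir_left + body + tir_right
  paste0("G", tsd, flank, inner)
}

# Truncated-normal cut pair around the two anchors; degenerate draws (circle
# shorter than 1 bp or out of contig bounds) are re-sampled.
draw_cut_pair <- function(anchor_left, anchor_right, sd, contig_len) {
  for (i in 1:100) {
    l <- as.integer(round(rnorm(1, anchor_left, sd)))
    r <- as.integer(round(rnorm(1, anchor_right, sd)))
    if (r - l >= 1L && l >= 0L && r <= contig_len) return(c(l, r))
  }
  c(anchor_left, anchor_right)
}
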