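#' Build a synthetic germline (MIC) genome with rearrangement annotations
#'
#' Generates random MIC contigs carrying MAC loci split into MDSs separated by
#' IESs, with pointer direct repeats at MAC-consecutive MDS boundaries,
#' intergenic spacers holding chromosome breakage sites between loci, and TBE
#' transposons (telomeric-motif TIRs, ANT target-site duplication on both
#' flanks) in intergenic space. Scrambled loci have their MDSs laid down in
#' permuted MIC order. Every eliminated locus records the cut anchors its
#' excision would use, so downstream ground truth is exhaustive.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   genomes.
#' @return An object of class `ecc_genome`: a list with `contigs` (named
#'   character vector), tibbles `mds`, `pointers`, `eliminated`, `tbes`,
#'   `breakage_sites`, `mac_loci`, and the `config` used. All intervals are
#'   0-based half-open.
#' @export
sim_genome <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  local_seed_if(seed)

  n_scrambled <- round(config$fraction_scrambled * config$n_mac_loci)
  scrambled_ids <- sample(seq_len(config$n_mac_loci), n_scrambled)

  loci <- map(seq_len(config$n_mac_loci), function(i) {
    build_locus(i, scrambled = i %in% scrambled_ids, config)
  })
  tbes <- map(seq_len(config$n_tbe), function(i) build_tbe(i, config))

  # round-robin feature assignment to contigs
  contig_names <- sprintf("MIC_%02d", seq_len(config$n_contigs))
  locus_contig <- ((seq_along(loci) - 1L) %% config$n_contigs) + 1L
  tbe_contig <- ((seq_along(tbes) - 1L) %% config$n_contigs) + 1L

  built <- map(seq_len(config$n_contigs), function(ci) {
    layout_contig(
      name = contig_names[ci],
      loci = loci[locus_contig == ci],
      tbes = tbes[tbe_contig == ci],
      config = config
    )
  })

  genome <- list(
    contigs = setNames(map_chr(built, "seq"), contig_names),
    mds = list_rbind(map(built, "mds")),
    pointers = list_rbind(map(built, "pointers")),
    eliminated = list_rbind(map(built, "eliminated")),
    tbes = list_rbind(map(built, "tbes")),
    breakage_sites = list_rbind(map(built, "breakage_sites")),
    mac_loci = list_rbind(map(built, "mac_loci")),
    config = config
  )
  class(genome) <- "ecc_genome"
  genome
}

# One MAC locus, position-free: MDS blocks (pointer-flanked cores) in MIC
# order, with the IES sequences between MIC-adjacent blocks.
build_locus <- function(idx, scrambled, config) {
  m <- config$mds_per_locus
  prange <- if (scrambled) config$pointer_length_scrambled else
    config$pointer_length_nonscrambled
  plen <- sample(seq(prange[1], prange[2]), m - 1L, replace = TRUE)
  ptr <- map_chr(plen, random_dna)
  core_len <- sample(seq(config$mds_length_range[1], config$mds_length_range[2]),
                     m, replace = TRUE)
  cores <- map_chr(core_len, random_dna)

  # block for MAC index k carries pointer k-1 as prefix, pointer k as suffix
  blocks <- map_chr(seq_len(m), function(k) {
    paste0(if (k > 1L) ptr[k - 1L] else "", cores[k],
           if (k < m) ptr[k] else "")
  })
  mic_order <- seq_len(m)
  if (scrambled) {
    while (identical(mic_order, seq_len(m))) mic_order <- sample(m)
  }
  ies_len <- sample(seq(config$ies_length_range[1], config$ies_length_range[2]),
                    m - 1L, replace = TRUE)
  list(
    id = sprintf("L%02d", idx),
    scrambled = scrambled,
    blocks = blocks,          # indexed by MAC index
    mic_order = mic_order,    # MAC indices in MIC left-to-right order
    ptr = ptr, plen = plen,
    ies = map_chr(ies_len, random_dna)
  )
}

build_tbe <- function(idx, config) {
  tir_arm <- paste0("AAAACCCCAAAACCCC", random_dna(14L)) # 30 bp arm
  n_base <- sample(DNA_BASES, 1L)
  tsd <- paste0("A", n_base, "T")
  flank <- sample(names(config$tbe_flank_probs), 1L,
                  prob = config$tbe_flank_probs)
  body_len <- max(config$tbe_length - 66L, 40L)
  list(
    id = sprintf("TBE%02d", idx),
    tir_left = tir_arm,
    tir_right = revcomp(tir_arm),
    tsd = tsd,
    flank_minus4 = flank,
    body = random_dna(body_len)
  )
}

# Lay features onto one contig, tracking coordinates as chunks are appended.
layout_contig <- function(name, loci, tbes, config) {
  chunks <- character(0)
  cursor <- 0L
  push <- function(seq) {
    chunks[[length(chunks) + 1L]] <<- seq
    start <- cursor
    cursor <<- cursor + nchar(seq)
    start
  }
  mds_rows <- list(); ptr_rows <- list(); elim_rows <- list()
  tbe_rows <- list(); brk_rows <- list(); locus_rows <- list()

  push(random_dna(sample(300:500, 1L))) # margin beyond the contig-end filter

  prev_locus_tail <- NULL # (locus_id, end of last MDS block) for intergenic site
  elim_i <- 0L

  for (lc in loci) {
    m <- length(lc$blocks)
    block_start <- integer(m); block_end <- integer(m) # by MAC index

    if (!is.null(prev_locus_tail)) {
      gap_len <- sample(120:250, 1L)
      gap_start <- push(random_dna(gap_len))
      brk_rows[[length(brk_rows) + 1L]] <- tibble(
        contig = name, position = gap_start + gap_len %/% 2L
      )
      elim_i <- elim_i + 1L
      elim_rows[[length(elim_rows) + 1L]] <- tibble(
        contig = name, start = prev_locus_tail$end, end = gap_start + gap_len,
        elim_id = NA_character_, # filled below once anchors are known
        type = "intergenic", mac_locus = NA_character_,
        left_mac = NA_integer_, right_mac = NA_integer_,
        anchor_left = prev_locus_tail$end, anchor_right = gap_start + gap_len,
        pointer_len = 0L, .tmp_right_open = TRUE
      )
    }

    for (j in seq_len(m)) {
      k <- lc$mic_order[j] # MAC index of the j-th MIC block
      s <- push(lc$blocks[k])
      block_start[k] <- s
      block_end[k] <- s + nchar(lc$blocks[k])
      if (j < m) {
        left_mac <- k
        right_mac <- lc$mic_order[j + 1L]
        ies_seq <- lc$ies[j]
        ies_start <- push(ies_seq)
        ies_end <- ies_start + nchar(ies_seq)
        non_scr <- right_mac == left_mac + 1L
        plen <- if (non_scr) lc$plen[left_mac] else 0L
        elim_rows[[length(elim_rows) + 1L]] <- tibble(
          contig = name, start = ies_start, end = ies_end,
          elim_id = NA_character_,
          type = if (non_scr) "non_scrambled" else "scrambled",
          mac_locus = lc$id, left_mac = left_mac, right_mac = right_mac,
          # non-scrambled anchors: start of each pointer copy, so the
          # zero-noise circle is IES plus one pointer copy
          anchor_left = if (non_scr) ies_start - plen else ies_start,
          anchor_right = if (non_scr) ies_end else ies_end,
          pointer_len = plen, .tmp_right_open = FALSE
        )
      }
    }
    for (k in seq_len(m)) {
      mds_rows[[length(mds_rows) + 1L]] <- tibble(
        contig = name, start = block_start[k], end = block_end[k],
        mac_locus = lc$id, mds_index = k,
        mic_rank = match(k, lc$mic_order), orientation = "+"
      )
      if (k < m) { # pointer k: suffix of block k, prefix of block k+1
        pl <- lc$plen[k]
        ptr_rows[[length(ptr_rows) + 1L]] <- tibble(
          contig = name,
          start = c(block_end[k] - pl, block_start[k + 1L]),
          end = c(block_end[k], block_start[k + 1L] + pl),
          seq = lc$ptr[k], mac_locus = lc$id, boundary = k, copy = 1:2
        )
      }
    }
    first_mac <- lc$mic_order[1L]
    last_mac <- lc$mic_order[length(lc$mic_order)]
    # patch the intergenic row created before this locus with its right anchor
    for (r in seq_along(elim_rows)) {
      if (isTRUE(elim_rows[[r]]$.tmp_right_open)) {
        elim_rows[[r]]$end <- block_start[first_mac]
        elim_rows[[r]]$anchor_right <- block_start[first_mac]
        elim_rows[[r]]$.tmp_right_open <- FALSE
      }
    }
    locus_rows[[length(locus_rows) + 1L]] <- tibble(
      mac_locus = lc$id, contig = name, scrambled = lc$scrambled,
      n_mds = m
    )
    prev_locus_tail <- list(id = lc$id, end = block_end[last_mac])
    push(random_dna(sample(200:400, 1L)))
  }

  for (tb in tbes) {
    push(random_dna(sample(200:400, 1L)))
    pre <- push(tb$flank_minus4) # the position -4 base
    el_start <- pre + 1L
    push(tb$tsd); push(tb$tir_left); push(tb$body); push(tb$tir_right)
    tsd2_start <- push(tb$tsd)
    el_end <- tsd2_start + 3L
    tbe_rows[[length(tbe_rows) + 1L]] <- tibble(
      contig = name, start = el_start, end = el_end, tbe_id = tb$id,
      tsd = tb$tsd, flank_minus4 = tb$flank_minus4,
      tir_left_start = el_start + 3L,
      tir_left_end = el_start + 3L + nchar(tb$tir_left),
      tir_right_start = el_end - 3L - nchar(tb$tir_right),
      tir_right_end = el_end - 3L
    )
  }

  push(random_dna(sample(300:500, 1L)))
  if (cursor > config$contig_length) {
    abort(sprintf(
      "contig %s too short (%d bp) for requested features (need %d bp)",
      name, config$contig_length, cursor
    ))
  }
  push(random_dna(config$contig_length - cursor))

  elim <- list_rbind(elim_rows)
  if (nrow(elim) > 0) {
    elim$elim_id <- sprintf("%s_E%03d", name, seq_len(nrow(elim)))
    elim$.tmp_right_open <- NULL
  }
  list(
    seq = paste(chunks, collapse = ""),
    mds = list_rbind(mds_rows),
    pointers = list_rbind(ptr_rows),
    eliminated = elim,
    tbes = list_rbind(tbe_rows),
    breakage_sites = list_rbind(brk_rows),
    mac_loci = list_rbind(locus_rows)
  )
}

#' @export
print.ecc_genome <- function(x, ...) {
  cat(sprintf(
    "<ecc_genome> %d contigs (%s bp total), %d MAC loci (%d scrambled), %d MDSs, %d eliminated loci, %d TBEs\n",
    length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ","),
    nrow(x$mac_loci), sum(x$mac_loci$scrambled), nrow(x$mds),
    nrow(x$eliminated), nrow(x$tbes)
  ))
  invisible(x)
}

#' Stitch MAC locus sequences from the MIC genome
#'
#' Reconstructs each somatic (MAC) locus by concatenating its MDS blocks in
#' MAC order, dropping the duplicated pointer prefix at each junction so one
#' pointer copy is retained per MDS-MDS junction.
#'
#' @param genome An `ecc_genome`.
#' @return Named character vector of MAC locus sequences.
#' @export
mac_sequences <- function(genome) {
  stopifnot(inherits(genome, "ecc_genome"))
  ptr_len <- genome$pointers |>
    filter(.data$copy == 1L) |>
    select("mac_locus", "boundary", plen = "seq") |>
    mutate(plen = nchar(.data$plen))
  out <- genome$mds |>
    arrange(.data$mac_locus, .data$mds_index) |>
    group_by(.data$mac_locus) |>
    group_map(function(df, key) {
      seqs <- map_chr(seq_len(nrow(df)), function(k) {
        s <- subseq0(genome$contigs[[df$contig[k]]], df$start[k], df$end[k])
        if (k > 1L) {
          pl <- ptr_len$plen[ptr_len$mac_locus == key$mac_locus &
                               ptr_len$boundary == df$mds_index[k] - 1L]
          s <- substr(s, pl + 1L, nchar(s))
        }
        s
      })
      setNames(paste(seqs, collapse = ""), key$mac_locus)
    }) |>
    unlist()
  out[sort(names(out))]
}
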