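# Desk-scale read mapper: exact-match k-mer seeding with ungapped extension.
# Simulated reads are error-free, so exact matching is lossless; real-data
# users supply external SAM from a production aligner instead. The mapq model
# is deliberately binary (60 unique / 0 ambiguous) because the only use
# downstream is the MAPQ >= 5 multi-mapper cut.

#' Build an exact k-mer index of a genome
#'
#' @param genome An `ecc_genome` or named character vector of contigs.
#' @param k Seed length (bp).
#' @return A `genome_index` object used by [map_reads()].
#' @export
build_genome_index <- function(genome, k = 16L) {
  contigs <- contig_seqs(genome)
  if (length(contigs) == 0 || sum(nchar(contigs)) == 0) {
    abort("cannot index an empty genome")
  }
  keys <- character(0); ctg <- integer(0); pos <- integer(0)
  for (ci in seq_along(contigs)) {
    seq <- contigs[[ci]]
    n <- nchar(seq) - k + 1L
    if (n < 1L) next
    starts <- seq_len(n)
    keys <- c(keys, substring(seq, starts, starts + k - 1L))
    ctg <- c(ctg, rep(ci, n)); pos <- c(pos, starts - 1L)
  }
  packed <- split(ctg * 2^32 + pos, keys)
  structure(
    list(env = list2env(packed, hash = TRUE, size = length(packed)),
         contigs = contigs, k = as.integer(k)),
    class = "genome_index"
  )
}

index_hits <- function(index, kmer) {
  h <- get0(kmer, envir = index$env, ifnotfound = NULL)
  if (is.null(h)) return(NULL)
  h <- sort(h)
  list(ctg = as.integer(h %/% 2^32), pos = as.integer(h %% 2^32))
}

#' Map reads to a genome by exact k-mer seeding and ungapped extension
#'
#' Each read (and its reverse complement) is seeded with its first and last
#' k-mer; seeds are extended exactly. A read matching the genome end-to-end
#' yields one primary segment (mapq 60 if the placement is unique, 0 if two
#' or more placements tie, deterministic tie-break by (contig, position)). A
#' read whose prefix and suffix map to discontiguous loci yields one primary
#' plus one supplementary segment, split at the maximal prefix extension
#' (which fixes the junction register when direct repeats make it ambiguous).
#' `read_start`/`read_end` are offsets into the read *as aligned* (i.e. into
#' the reverse complement for minus-strand segments), matching SAM
#' conventions. Reads containing N are tolerated; N never seed-matches.
#'
#' @param reads A tibble with columns `read_id` and `seq` (optionally
#'   `mate`), or a named character vector of sequences.
#' @param genome An `ecc_genome` or named character vector of contigs.
#' @param seed_kmer Seed length (bp).
#' @param index Optional prebuilt [build_genome_index()] (must match
#'   `seed_kmer`).
#' @return A tibble of alignment segments: `read_id`, `mate`, `contig`,
#'   `ref_start`, `ref_end` (0-based half-open), `read_start`, `read_end`,
#'   `strand`, `mapq`, `secondary`, `supplementary`, `duplicate`, `unmapped`.
#' @export
map_reads <- function(reads, genome, seed_kmer = 16L, index = NULL) {
  reads <- as_read_tbl(reads)
  if (nrow(reads) == 0) abort("no reads supplied")
  if (is.null(index)) index <- build_genome_index(genome, seed_kmer)
  stopifnot(index$k == seed_kmer)
  contigs <- index$contigs
  cnames <- names(contigs)
  rc_all <- revcomp(reads$seq)

  # collector: one numeric matrix row per segment, strings handled via codes
  n_guess <- nrow(reads) * 2L
  out <- matrix(NA_integer_, nrow = n_guess, ncol = 8L)
  colnames(out) <- c("read_i", "contig_i", "ref_start", "ref_end",
                     "read_start", "read_end", "strand_i", "mapq")
  flags <- matrix(FALSE, nrow = n_guess, ncol = 2L) # supplementary, unmapped
  nrow_used <- 0L
  push <- function(row, supp, unm) {
    nrow_used <<- nrow_used + 1L
    if (nrow_used > nrow(out)) {
      out <<- rbind(out, matrix(NA_integer_, nrow = nrow(out), ncol = 8L))
      flags <<- rbind(flags, matrix(FALSE, nrow = nrow(flags), ncol = 2L))
    }
    out[nrow_used, ] <<- row
    flags[nrow_used, ] <<- c(supp, unm)
  }

  for (i in seq_len(nrow(reads))) {
    map_one(i, reads$seq[i], rc_all[i], index, contigs, push)
  }
  out <- out[seq_len(nrow_used), , drop = FALSE]
  flags <- flags[seq_len(nrow_used), , drop = FALSE]
  col <- function(nm) as.integer(unname(out[, nm]))
  tibble(
    read_id = reads$read_id[col("read_i")],
    mate = reads$mate[col("read_i")],
    contig = unname(cnames[col("contig_i")]),
    ref_start = col("ref_start"), ref_end = col("ref_end"),
    read_start = col("read_start"), read_end = col("read_end"),
    strand = c("+", "-")[col("strand_i")],
    mapq = col("mapq"),
    secondary = FALSE,
    supplementary = unname(flags[, 1]), duplicate = FALSE,
    unmapped = unname(flags[, 2])
  )
}

as_read_tbl <- function(reads) {
  if (is.character(reads)) {
    reads <- tibble(read_id = names(reads) %||%
                      sprintf("read%05d", seq_along(reads)),
                    seq = unname(reads))
  }
  if (!all(c("read_id", "seq") %in% names(reads))) {
    abort("reads must have columns read_id and seq")
  }
  if (!"mate" %in% names(reads)) reads$mate <- NA_integer_
  reads
}

# Candidate placements of the maximal exactly-matching prefix of s.
best_prefix <- function(s, index, contigs) {
  k <- index$k
  n <- nchar(s)
  if (n < k) return(NULL)
  hits <- index_hits(index, substr(s, 1L, k))
  if (is.null(hits)) return(NULL)
  ml <- integer(length(hits$pos))
  for (j in seq_along(hits$pos)) {
    window <- substr(contigs[[hits$ctg[j]]], hits$pos[j] + 1L, hits$pos[j] + n)
    ml[j] <- common_prefix_len(s, window)
  }
  best <- max(ml)
  keep <- which(ml == best)
  list(len = best, ctg = hits$ctg[keep], pos = hits$pos[keep])
}

# Candidate placements of the maximal exactly-matching suffix of s; `pos` is
# the 0-based ref start of the matched suffix.
best_suffix <- function(s, index, contigs) {
  k <- index$k
  n <- nchar(s)
  if (n < k) return(NULL)
  hits <- index_hits(index, substr(s, n - k + 1L, n))
  if (is.null(hits)) return(NULL)
  ml <- integer(length(hits$pos))
  ref_start <- integer(length(hits$pos))
  for (j in seq_along(hits$pos)) {
    end <- hits$pos[j] + k # ref end (exclusive) of the matched seed
    wstart <- max(0L, end - n)
    window <- substr(contigs[[hits$ctg[j]]], wstart + 1L, end)
    ml[j] <- common_suffix_len(s, window)
    ref_start[j] <- end - ml[j]
  }
  best <- max(ml)
  keep <- which(ml == best)
  list(len = best, ctg = hits$ctg[keep], pos = ref_start[keep],
       end = ref_start[keep] + best)
}

map_one <- function(i, fw, rc, index, contigs, push) {
  n <- nchar(fw)
  pf <- best_prefix(fw, index, contigs)
  pr <- best_prefix(rc, index, contigs)

  full_f <- !is.null(pf) && pf$len == n
  full_r <- !is.null(pr) && pr$len == n
  if (full_f || full_r) {
    n_place <- (if (full_f) length(pf$pos) else 0L) +
      (if (full_r) length(pr$pos) else 0L)
    hit <- if (full_f) pf else pr
    strand_i <- if (full_f) 1L else 2L
    push(c(i, hit$ctg[1], hit$pos[1], hit$pos[1] + n, 0L, n, strand_i,
           if (n_place == 1L) 60L else 0L), FALSE, FALSE)
    return(invisible(NULL))
  }

  sf <- best_suffix(fw, index, contigs)
  sr <- best_suffix(rc, index, contigs)
  score <- function(p, s) if (is.null(p) || is.null(s)) -1L else p$len + s$len
  use_fw <- score(pf, sf) >= score(pr, sr)
  p <- if (use_fw) pf else pr
  sx <- if (use_fw) sf else sr
  strand_i <- if (use_fw) 1L else 2L

  if (!is.null(p) && !is.null(sx) && p$len + sx$len >= n &&
      p$len < n && sx$len < n) {
    split <- p$len
    suf_len <- n - split
    trim <- sx$len - suf_len
    pri_first <- p$len >= suf_len
    push(c(i, p$ctg[1], p$pos[1], p$pos[1] + p$len, 0L, split, strand_i,
           if (length(p$pos) == 1L) 60L else 0L), !pri_first, FALSE)
    push(c(i, sx$ctg[1], sx$pos[1] + trim, sx$end[1], split, n, strand_i,
           if (length(sx$pos) == 1L) 60L else 0L), pri_first, FALSE)
    return(invisible(NULL))
  }

  # partial: best single anchored segment, else unmapped
  cands <- list(list(p = pf, st = 1L, from_start = TRUE),
                list(p = pr, st = 2L, from_start = TRUE),
                list(p = sf, st = 1L, from_start = FALSE),
                list(p = sr, st = 2L, from_start = FALSE))
  cands <- cands[!map_lgl(cands, function(x) is.null(x$p))]
  if (length(cands) == 0) {
    push(c(i, NA_integer_, NA_integer_, NA_integer_, NA_integer_,
           NA_integer_, NA_integer_, 0L), FALSE, TRUE)
    return(invisible(NULL))
  }
  b <- cands[[which.max(map_int(cands, function(x) x$p$len))]]
  L <- b$p$len
  qs <- if (b$from_start) 0L else n - L
  push(c(i, b$p$ctg[1], b$p$pos[1], b$p$pos[1] + L, qs, qs + L, b$st,
         if (length(b$p$pos) == 1L) 60L else 0L), FALSE, FALSE)
  invisible(NULL)
}

#' Flag PCR-duplicate read pairs
#'
#' Pairs whose two primary alignments share (contig, ref_start, strand) for
#' both mates are considered PCR duplicates; all but one representative are
#' flagged. The survivor is the lexicographically smallest `read_id`, so the
#' result does not depend on input order.
#'
#' @param segments Alignment-segment tibble from [map_reads()].
#' @return The tibble with the `duplicate` flag set.
#' @export
mark_duplicates <- function(segments) {
  prim <- segments |>
    filter(!.data$secondary, !.data$supplementary, !.data$unmapped,
           !is.na(.data$mate))
  if (nrow(prim) == 0) return(segments)
  keys <- prim |>
    mutate(mate_key = paste(.data$contig, .data$ref_start, .data$strand,
                            sep = "/")) |>
    group_by(.data$read_id) |>
    summarise(
      key = paste(.data$mate_key[order(.data$mate)], collapse = "|"),
      n_mates = n(), .groups = "drop"
    ) |>
    filter(.data$n_mates == 2L)
  dup_ids <- keys |>
    group_by(.data$key) |>
    arrange(.data$read_id, .by_group = TRUE) |>
    mutate(is_dup = row_number() > 1L) |>
    ungroup() |>
    filter(.data$is_dup) |>
    pull(.data$read_id)
  segments |> mutate(duplicate = .data$read_id %in% dup_ids)
}
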