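# Standard-format I/O. FASTA/FASTQ go through Biostrings; SAM is a minimal
# text implementation of the ungapped subset this package produces (flags
# 0x1/0x4/0x10/0x40/0x80/0x100/0x400/0x800, CIGAR soft clips + match), since
# external SAM from real aligners is accepted as alternative input to every
# downstream module. BED6+ tables are written as plain tab-separated text.

#' Write / read a genome as FASTA
#'
#' @param genome An `ecc_genome` or named character vector of contigs.
#' @param path Output file (".gz" suffix compresses).
#' @return `write_genome_fasta()` returns `path` invisibly;
#'   `read_genome_fasta()` returns a named character vector of contigs.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(contig_seqs(genome))
  Biostrings::writeXStringSet(seqs, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Write / read paired FASTQ
#'
#' Writes the two mates of a read-pair tibble as `<prefix>_1.fastq[.gz]` and
#' `<prefix>_2.fastq[.gz]` with constant qualities (the simulator is
#' error-free).
#'
#' @param reads Read-pair tibble from [tagment_and_read()].
#' @param prefix Output path prefix.
#' @param gzip Compress outputs.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, prefix, gzip = TRUE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(reads[[paste0("mate", m, "_seq")]])
    names(seqs) <- reads$pair_id
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, paths[m], compress = gzip,
                                format = "fastq", qualities = quals)
  }
  invisible(paths)
}

#' Read FASTQ into a read tibble
#'
#' @param path FASTQ file (optionally gzipped).
#' @param mate Optional mate number stamped on all reads.
#' @return Tibble with `read_id`, `seq` (and `mate` if given).
#' @export
read_fastq <- function(path, mate = NULL) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- tibble(read_id = names(seqs), seq = unname(as.character(seqs)))
  if (!is.null(mate)) out$mate <- as.integer(mate)
  out
}

sam_flag <- function(seg) {
  flag <- integer(nrow(seg))
  paired <- !is.na(seg$mate)
  flag <- flag + 1L * paired
  flag <- flag + 64L * (paired & seg$mate == 1L) +
    128L * (paired & seg$mate == 2L)
  flag <- flag + 4L * seg$unmapped
  flag <- flag + 16L * (!seg$unmapped & seg$strand == "-")
  flag <- flag + 256L * seg$secondary + 1024L * seg$duplicate +
    2048L * seg$supplementary
  as.integer(flag)
}

#' Write / read alignment segments as SAM text
#'
#' Round-trips the package's alignment-segment tibbles through SAM. The
#' writer emits soft-clipped ungapped records (`xS yM zS`); the reader
#' accepts any SAM whose CIGAR uses M/=/X/I/D/N/S/H operations, so output
#' from external aligners can feed the downstream modules. Records naming a
#' contig absent from the header are rejected.
#'
#' @param segments Alignment-segment tibble (see [map_reads()]).
#' @param lengths Named contig lengths for the header.
#' @param path SAM file path.
#' @param read_lengths Optional named (by `read_id`) read lengths used to
#'   emit the trailing soft clip; omitted otherwise (the segment fields do
#'   not depend on it).
#' @return `write_sam()` returns `path` invisibly; `read_sam()` returns a
#'   list with `segments` and `contig_lengths`.
#' @export
write_sam <- function(segments, lengths, path, read_lengths = NULL) {
  assert_contigs(segments$contig[!segments$unmapped], setNames(
    as.list(lengths), names(lengths)), "SAM record")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lengths), as.integer(lengths)))
  seg <- segments
  cigar <- rep("*", nrow(seg))
  mapped <- !seg$unmapped
  lead <- ifelse(seg$read_start[mapped] > 0,
                 sprintf("%dS", seg$read_start[mapped]), "")
  mid <- sprintf("%dM", seg$read_end[mapped] - seg$read_start[mapped])
  trail <- rep("", sum(mapped))
  if (!is.null(read_lengths)) {
    rl <- read_lengths[seg$read_id[mapped]]
    z <- rl - seg$read_end[mapped]
    trail <- ifelse(!is.na(z) & z > 0, sprintf("%dS", z), "")
  }
  cigar[mapped] <- paste0(lead, mid, trail)
  qname <- seg$read_id # mate number travels in the FLAG, qname is the pair id
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
    qname, sam_flag(seg),
    ifelse(mapped, seg$contig, "*"),
    ifelse(mapped, seg$ref_start + 1L, 0L),
    ifelse(is.na(seg$mapq), 0L, seg$mapq),
    cigar
  )
  readr::write_lines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  lens <- setNames(ln, sn)
  if (length(body) == 0) {
    return(list(segments = tibble(), contig_lengths = lens))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  qname <- map_chr(f, 1L)
  flag <- as.integer(map_chr(f, 2L))
  rname <- map_chr(f, 3L)
  pos <- as.integer(map_chr(f, 4L))
  mapq <- as.integer(map_chr(f, 5L))
  cigar <- map_chr(f, 6L)
  unmapped <- bitwAnd(flag, 4L) > 0L
  bad <- !unmapped & !(rname %in% sn)
  if (any(bad)) {
    abort(sprintf("SAM record(s) name unknown contig(s): %s",
                  paste(unique(rname[bad]), collapse = ", ")))
  }
  parsed <- parse_cigars(cigar)
  paired <- bitwAnd(flag, 1L) > 0L
  mate <- ifelse(!paired, NA_integer_,
                 ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L))
  segments <- tibble(
    read_id = qname,
    mate = mate,
    contig = ifelse(unmapped, NA_character_, rname),
    ref_start = ifelse(unmapped, NA_integer_, pos - 1L),
    ref_end = ifelse(unmapped, NA_integer_, pos - 1L + parsed$ref_span),
    read_start = ifelse(unmapped, NA_integer_, parsed$lead_clip),
    read_end = ifelse(unmapped, NA_integer_,
                      parsed$lead_clip + parsed$read_span),
    strand = ifelse(unmapped, NA_character_,
                    ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")),
    mapq = mapq,
    secondary = bitwAnd(flag, 256L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    unmapped = unmapped
  )
  list(segments = segments, contig_lengths = lens)
}

parse_cigars <- function(cigar) {
  lead_clip <- integer(length(cigar))
  read_span <- integer(length(cigar))
  ref_span <- integer(length(cigar))
  for (i in seq_along(cigar)) {
    if (cigar[i] == "*") next
    ops <- regmatches(cigar[i], gregexpr("[0-9]+[MIDNSHP=X]", cigar[i]))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    first_aln <- which(!op %in% c("S", "H"))[1]
    lead_clip[i] <- sum(n[seq_len(first_aln - 1L)][
      op[seq_len(first_aln - 1L)] == "S"])
    read_span[i] <- sum(n[op %in% c("M", "I", "=", "X")])
    ref_span[i] <- sum(n[op %in% c("M", "D", "N", "=", "X")])
  }
  list(lead_clip = lead_clip, read_span = read_span, ref_span = ref_span)
}

#' Write an interval table as BED6(+)
#'
#' Writes `contig`/`start`/`end` plus optional name, score and strand
#' columns, then any extra columns, as tab-separated BED with no header.
#'
#' @param df Tibble with at least `contig`, `start`, `end`.
#' @param path Output path.
#' @param name,score,strand Column names (or `NULL`) feeding BED fields 4-6.
#' @param extra Character vector of additional column names to append.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, name = NULL, score = NULL, strand = NULL,
                      extra = character(0)) {
  out <- tibble(
    chrom = df$contig,
    start = as.integer(df$start),
    end = as.integer(df$end),
    name = if (is.null(name)) "." else df[[name]],
    score = if (is.null(score)) 0 else df[[score]],
    strand = if (is.null(strand)) "." else df[[strand]]
  )
  for (col in extra) out[[col]] <- df[[col]]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Export a per-base coverage track as bedGraph
#'
#' @param segments Mapped alignment-segment tibble.
#' @param lengths Named contig lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(segments, lengths, path) {
  seg <- segments |> filter(!.data$unmapped)
  rows <- map(names(lengths), function(ctg) {
    sc <- seg |> filter(.data$contig == ctg)
    if (nrow(sc) == 0) return(NULL)
    cov <- IRanges::coverage(
      IRanges::IRanges(sc$ref_start + 1L, sc$ref_end),
      width = lengths[[ctg]]
    )
    rl <- S4Vectors::runLength(cov)
    ends <- cumsum(rl)
    tibble(contig = ctg, start = ends - rl, end = ends,
           score = as.numeric(S4Vectors::runValue(cov)))
  }) |> list_rbind()
  rows <- rows |> filter(.data$score > 0)
  readr::write_tsv(rows, path, col_names = FALSE)
  invisible(path)
}

#' Export a genome's annotation tracks and sequence
#'
#' Writes the MIC contigs as FASTA and the MDS, pointer, TBE and
#' breakage-site annotations as BED6+ tracks into a directory.
#'
#' @param genome An `ecc_genome`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_genome_tracks <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "genome.fasta"),
    mds = file.path(dir, "mds.bed"),
    pointers = file.path(dir, "pointers.bed"),
    tbes = file.path(dir, "tbes.bed"),
    breakage = file.path(dir, "breakage_sites.bed")
  )
  write_genome_fasta(genome, paths[["fasta"]])
  write_bed(genome$mds |> mutate(name = paste0(.data$mac_locus, ".",
                                               .data$mds_index)),
            paths[["mds"]], name = "name", strand = "orientation",
            extra = "mic_rank")
  write_bed(genome$pointers |> mutate(name = paste0(.data$mac_locus, ".b",
                                                    .data$boundary)),
            paths[["pointers"]], name = "name", extra = c("seq", "copy"))
  write_bed(genome$tbes, paths[["tbes"]], name = "tbe_id",
            extra = c("tsd", "flank_minus4"))
  write_bed(genome$breakage_sites |>
              mutate(start = .data$position, end = .data$position + 1L),
            paths[["breakage"]])
  invisible(paths)
}

#' Export simulator ground truth as TSV
#'
#' One row per circular molecule (`circles`) or per read pair (`reads`),
#' with every truth column the simulator recorded.
#'
#' @param x An `ecc_circles` tibble or a read-pair tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path)
  invisible(path)
}
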