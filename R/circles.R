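# From junction calls to circle isoforms: exact-coordinate merging,
# horizontal coverage, the coverage-based high-confidence rule and
# reads-per-million normalization.

#' Assemble junction calls into circle isoforms
#'
#' Split-read junction calls with identical (contig, start, end) are merged
#' into one isoform; the unique isoform count is the number of distinct
#' coordinate pairs. Merging is exact-coordinate only: the heterogeneity of
#' circle boundaries is a real signal, and fuzzy clustering would erase it
#' (use [group_isoforms()] for windowed summaries).
#'
#' @param junction_calls Junction-call tibble ([detect_split_junctions()]),
#'   possibly row-bound over libraries.
#' @return Tibble with `contig`, `start`, `end`, `isoform_id`, `length`,
#'   `n_reads` (total junction-read support) and `support` (a list column of
#'   per-library counts).
#' @export
assemble_circles <- function(junction_calls) {
  if (nrow(junction_calls) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  isoform_id = character(), length = integer(),
                  n_reads = integer(),
                  support = list()))
  }
  junction_calls |>
    group_by(.data$contig, start = .data$circle_start,
             end = .data$circle_end) |>
    summarise(
      n_reads = n(),
      support = list(count(pick("library"), .data$library,
                           name = "n_reads")),
      .groups = "drop"
    ) |>
    arrange(.data$contig, .data$start, .data$end) |>
    mutate(isoform_id = sprintf("iso%05d", row_number()),
           length = .data$end - .data$start) |>
    relocate("isoform_id")
}

#' Per-library junction-read support in long form
#'
#' @param circles Output of [assemble_circles()].
#' @return Tibble `isoform_id`, `library`, `n_reads`.
#' @export
support_by_library <- function(circles) {
  circles |>
    select("isoform_id", "support") |>
    tidyr::unnest("support")
}

#' Group isoforms within a coordinate window (summary report)
#'
#' Optional companion to [assemble_circles()]: clusters isoforms whose
#' boundaries both fall within `window` bp of a cluster representative, for
#' summarising boundary heterogeneity. Detection and filtering always run on
#' exact isoforms.
#'
#' @param circles Output of [assemble_circles()].
#' @param window Maximum per-boundary distance (bp).
#' @return `circles` with a `group_id` column.
#' @export
group_isoforms <- function(circles, window = 10L) {
  circles <- circles |> arrange(.data$contig, .data$start, .data$end)
  gid <- integer(nrow(circles))
  cur <- 0L
  rep_start <- rep_end <- NA_integer_; rep_ctg <- NA_character_
  for (i in seq_len(nrow(circles))) {
    if (is.na(rep_ctg) || circles$contig[i] != rep_ctg ||
        abs(circles$start[i] - rep_start) > window ||
        abs(circles$end[i] - rep_end) > window) {
      cur <- cur + 1L
      rep_ctg <- circles$contig[i]
      rep_start <- circles$start[i]; rep_end <- circles$end[i]
    }
    gid[i] <- cur
  }
  circles |> mutate(group_id = sprintf("grp%04d", gid))
}

#' Horizontal coverage of intervals
#'
#' Fraction of each interval's positions overlapped by at least one mapped
#' segment: the "fraction of the circle body covered with >= 1 read".
#'
#' @param intervals Tibble with `contig`, `start`, `end` (0-based half-open).
#' @param segments Mapped alignment-segment tibble (full-length reads of one
#'   library).
#' @return Numeric vector of coverage fractions in \[0, 1\], one per interval
#'   row.
#' @export
horizontal_coverage <- function(intervals, segments) {
  if (any(intervals$end <= intervals$start)) {
    abort("horizontal_coverage: zero- or negative-length interval")
  }
  seg <- segments |> filter(!.data$unmapped)
  out <- numeric(nrow(intervals))
  for (ctg in unique(intervals$contig)) {
    ii <- which(intervals$contig == ctg)
    sc <- seg |> filter(.data$contig == ctg)
    if (nrow(sc) == 0) next
    covered <- IRanges::reduce(IRanges::IRanges(sc$ref_start + 1L, sc$ref_end))
    q <- IRanges::IRanges(intervals$start[ii] + 1L, intervals$end[ii])
    hits <- IRanges::findOverlaps(q, covered)
    covered_bp <- tapply(
      IRanges::width(IRanges::pintersect(
        q[S4Vectors::queryHits(hits)], covered[S4Vectors::subjectHits(hits)]
      )),
      S4Vectors::queryHits(hits), sum
    )
    idx <- as.integer(names(covered_bp))
    out[ii[idx]] <- as.numeric(covered_bp) /
      (intervals$end[ii[idx]] - intervals$start[ii[idx]])
  }
  pmin(out, 1)
}

#' Apply the high-confidence circle filter
#'
#' A circle isoform is high confidence iff (i) horizontal coverage is at
#' least `min_mid` in *both* mid-rearrangement +exo replicates, (ii) coverage
#' is at most `max_asexual` in *both* asexual replicates, and (iii) at least
#' one split-read junction supports the isoform. Thresholds are inclusive.
#' The -exo and early/late libraries do not participate in the rule.
#'
#' @param circles Output of [assemble_circles()].
#' @param coverage Long tibble `isoform_id`, `library`, `coverage` holding
#'   horizontal coverage of every isoform in at least the four required
#'   libraries.
#' @param mid_libraries,asexual_libraries Library labels of the two
#'   mid-rearrangement +exo and two asexual replicates.
#' @param min_mid,max_asexual Coverage thresholds (default 25% / 15%).
#' @return `circles` with a logical `high_confidence` column.
#' @export
call_high_confidence <- function(circles, coverage,
                                 mid_libraries = c("mid_1", "mid_2"),
                                 asexual_libraries = c("asexual_1", "asexual_2"),
                                 min_mid = 0.25, max_asexual = 0.15) {
  required <- c(mid_libraries, asexual_libraries)
  missing <- setdiff(required, unique(coverage$library))
  if (length(missing) > 0) {
    abort(sprintf("call_high_confidence: missing required library: %s",
                  paste(missing, collapse = ", ")))
  }
  wide <- coverage |>
    filter(.data$library %in% required) |>
    tidyr::pivot_wider(id_cols = "isoform_id", names_from = "library",
                       values_from = "coverage", values_fill = 0)
  for (lib in required) if (!lib %in% names(wide)) wide[[lib]] <- 0
  pass <- wide$isoform_id[
    wide[[mid_libraries[1]]] >= min_mid & wide[[mid_libraries[2]]] >= min_mid &
      wide[[asexual_libraries[1]]] <= max_asexual &
      wide[[asexual_libraries[2]]] <= max_asexual
  ]
  circles |>
    mutate(high_confidence = .data$isoform_id %in% pass & .data$n_reads >= 1L)
}

#' Reads-per-million normalization
#'
#' `raw / total_mapped * 1e6`, reported to one decimal to match standard
#' library-statistics tables; full precision via `digits = NA`.
#'
#' @param raw Raw read count(s).
#' @param total_mapped Total mapped reads in the library (must be positive).
#' @param digits Decimal places for reporting (`NA` for full precision).
#' @return Numeric RPM value(s).
#' @export
rpm <- function(raw, total_mapped, digits = 1L) {
  if (any(total_mapped <= 0)) abort("rpm: total_mapped must be positive")
  x <- raw / total_mapped * 1e6
  if (is.na(digits)) x else round(x, digits)
}

#' Per-library summary of Circulome-seq metrics
#'
#' Mirrors a standard circle-sequencing statistics table: per library, total
#' mapped reads, TBE junction reads (+RPM), split-read circle junction reads,
#' unique circle isoforms (+RPM of junction reads), and 9 bp duplication
#' pairs (+RPM).
#'
#' @param total_mapped Named vector: mapped reads per library.
#' @param tbe_counts Output of [count_tbe_junction_reads()] over libraries.
#' @param split_calls Split-read junction calls (all libraries, one row per
#'   retained junction read).
#' @param dup_calls 9 bp duplication calls (all libraries).
#' @return One row per library.
#' @export
library_summary <- function(total_mapped, tbe_counts, split_calls, dup_calls) {
  libs <- names(total_mapped)
  tbe <- tbe_counts |>
    group_by(.data$library) |>
    summarise(tbe_junction_reads = sum(.data$n_reads), .groups = "drop")
  spl <- split_calls |>
    group_by(.data$library) |>
    summarise(
      circle_junction_reads = n(),
      unique_circle_isoforms = n_distinct(
        paste(.data$contig, .data$circle_start, .data$circle_end)),
      .groups = "drop"
    )
  dup <- dup_calls |>
    group_by(.data$library) |>
    summarise(nine_bp_dup_reads = n(), .groups = "drop")
  tibble(library = libs, mapped_reads = unname(total_mapped)) |>
    left_join(tbe, by = "library") |>
    left_join(spl, by = "library") |>
    left_join(dup, by = "library") |>
    mutate(across(c("tbe_junction_reads", "circle_junction_reads",
                    "unique_circle_isoforms", "nine_bp_dup_reads"),
                  function(x) tidyr::replace_na(x, 0L))) |>
    mutate(
      tbe_junction_rpm = rpm(.data$tbe_junction_reads, .data$mapped_reads),
      circle_junction_rpm = rpm(.data$circle_junction_reads,
                                .data$mapped_reads),
      nine_bp_dup_rpm = rpm(.data$nine_bp_dup_reads, .data$mapped_reads)
    )
}
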