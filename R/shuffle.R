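# Interval-shuffle permutation nulls: length-preserving uniform placement of
# intervals on a target domain (whole assembly or a restricted interval set),
# with overlaps between placed intervals permitted.

#' Shuffle intervals uniformly over a domain
#'
#' Each replicate places every interval, length preserved, uniformly at
#' random among all positions where it fits entirely inside one domain
#' segment (segments weighted by their number of valid placements). Overlaps
#' between placed intervals are permitted; placement is deterministic under
#' `seed`.
#'
#' @param intervals Tibble with `start`, `end` (only lengths are used).
#' @param domain Tibble with `contig`, `start`, `end` (e.g.
#'   [genome_domain()] or [ies_domain()]), or named contig lengths.
#' @param n Number of shuffle replicates.
#' @param seed Optional seed.
#' @param anchor `"within"` (default) requires the placed interval to fit
#'   entirely inside a domain segment; `"start"` draws only the interval
#'   *start* uniformly within a segment (segments weighted by width), letting
#'   the interval extend beyond it; `"auto"` uses `"within"` for interval
#'   lengths that fit in at least one segment and falls back to `"start"`
#'   for longer ones -- used for domains of short segments (e.g.
#'   IES-restricted nulls) that cannot contain the longest interval.
#' @param contig_lengths Optional named lengths; with `anchor = "start"`,
#'   placements are shifted left if needed so intervals stay within their
#'   contig.
#' @return Tibble `rep`, `interval` (input row), `contig`, `start`, `end`.
#' @export
shuffle_intervals <- function(intervals, domain, n = 1L, seed = NULL,
                              anchor = c("within", "start", "auto"),
                              contig_lengths = NULL) {
  local_seed_if(seed)
  anchor <- match.arg(anchor)
  if (!is.data.frame(domain)) {
    domain <- tibble(contig = names(domain), start = 0L,
                     end = as.integer(domain))
  }
  widths <- domain$end - domain$start
  lens <- intervals$end - intervals$start
  out_contig <- character(0); out_start <- integer(0)
  out_rep <- integer(0); out_int <- integer(0)
  for (L in unique(lens)) {
    mode <- anchor
    if (mode == "auto") mode <- if (any(widths >= L)) "within" else "start"
    if (mode == "within") {
      fits <- which(widths >= L)
      if (length(fits) == 0) {
        abort(sprintf("interval of length %d fits in no domain segment", L))
      }
      w <- widths[fits] - L + 1
    } else {
      fits <- seq_along(widths)
      w <- widths
    }
    which_int <- which(lens == L)
    k <- length(which_int) * n
    seg <- fits[sample.int(length(fits), k, replace = TRUE, prob = w)]
    room <- if (mode == "within") widths[seg] - L + 1 else widths[seg]
    st <- domain$start[seg] + as.integer(floor(runif(k) * room))
    if (mode == "start" && !is.null(contig_lengths)) {
      lim <- unname(contig_lengths[domain$contig[seg]]) - L
      st <- pmax(0L, pmin(st, as.integer(lim)))
    }
    out_contig <- c(out_contig, domain$contig[seg])
    out_start <- c(out_start, st)
    out_rep <- c(out_rep, rep(seq_len(n), each = length(which_int)))
    out_int <- c(out_int, rep(which_int, times = n))
  }
  tibble(rep = out_rep, interval = out_int, contig = out_contig,
         start = out_start, end = out_start + lens[out_int]) |>
    arrange(.data$rep, .data$interval)
}

#' Shuffle domains
#'
#' `genome_domain()` is the whole MIC assembly; `ies_domain()` restricts
#' placement to annotated IES intervals (non-scrambled and scrambled; the
#' domain used for IES-restricted transcription nulls).
#'
#' @param genome An `ecc_genome`.
#' @return Domain tibble (`contig`, `start`, `end`).
#' @export
genome_domain <- function(genome) {
  lens <- contig_lengths(genome)
  tibble(contig = names(lens), start = 0L, end = as.integer(lens))
}

#' @rdname genome_domain
#' @param pad Bases added on each side of every IES segment (allowance for
#'   the boundary imprecision of circular excision); clipped to contig
#'   bounds.
#' @export
ies_domain <- function(genome, pad = 0L) {
  lens <- contig_lengths(genome)
  genome$eliminated |>
    filter(.data$type != "intergenic") |>
    transmute(
      contig = .data$contig,
      start = pmax(0L, .data$anchor_left - pad),
      end = pmin(unname(lens[.data$contig]), .data$anchor_right + pad)
    )
}

#' Observed statistic with its permutation null
#'
#' @param observed Observed scalar statistic.
#' @param replicates Numeric vector of the statistic over shuffle replicates.
#' @return An `ecc_null` object: observed value, replicates, `n_shuffles`,
#'   null mean and sd, and the empirical percentile of the observed value
#'   (fraction of replicates strictly below it; ties count as not-below).
#' @export
null_distribution <- function(observed, replicates) {
  stopifnot(length(observed) == 1L, length(replicates) >= 1L)
  structure(
    list(
      observed = observed,
      replicates = as.numeric(replicates),
      n_shuffles = length(replicates),
      mean = mean(replicates),
      sd = sd(replicates),
      percentile = mean(replicates < observed)
    ),
    class = "ecc_null"
  )
}

#' @export
print.ecc_null <- function(x, ...) {
  cat(sprintf(
    "<ecc_null> observed %.4g vs %d shuffles (mean %.4g, sd %.4g); percentile %.3f\n",
    x$observed, x$n_shuffles, x$mean, x$sd, x$percentile
  ))
  invisible(x)
}

#' @rdname null_distribution
#' @param x An `ecc_null`.
#' @param ... Unused.
#' @export
tidy.ecc_null <- function(x, ...) {
  tibble(rep = seq_len(x$n_shuffles), statistic = x$replicates)
}

#' @rdname null_distribution
#' @export
glance.ecc_null <- function(x, ...) {
  tibble(observed = x$observed, n_shuffles = x$n_shuffles,
         null_mean = x$mean, null_sd = x$sd, percentile = x$percentile)
}
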