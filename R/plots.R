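# ggplot2 displays for the main result types.

#' @importFrom ggplot2 ggplot aes geom_histogram geom_vline geom_col
#'   geom_point geom_errorbar labs theme_minimal position_dodge
NULL

#' Plot a permutation null against its observed statistic
#'
#' @param object An `ecc_null` from [null_distribution()].
#' @param ... Unused.
#' @return A ggplot: histogram of shuffle replicates with the observed value
#'   as a vertical line.
#' @export
autoplot.ecc_null <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$statistic)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed, colour = "red",
               linewidth = 0.8) +
    labs(
      x = "statistic (shuffle replicates)", y = "replicates",
      title = sprintf("observed at percentile %.3f of %d shuffles",
                      object$percentile, object$n_shuffles)
    ) +
    theme_minimal()
}

#' Plot observed vs shuffled MDS-distance bin frequencies
#'
#' @param object Output of [mds_distance_bins()].
#' @param ... Unused.
#' @return A ggplot: observed frequencies as points, null mean with a
#'   three-sd error bar per bin.
#' @export
autoplot.ecc_distance_bins <- function(object, ...) {
  ggplot(object, aes(x = .data$bin)) +
    geom_errorbar(aes(ymin = pmax(.data$null_mean - 3 * .data$null_sd, 0),
                      ymax = .data$null_mean + 3 * .data$null_sd),
                  width = 0.2, colour = "steelblue") +
    geom_point(aes(y = .data$null_mean), colour = "steelblue", size = 2) +
    geom_point(aes(y = .data$observed), colour = "red", size = 2) +
    labs(x = "distance to nearest MDS boundary (bp)", y = "frequency",
         title = "observed (red) vs shuffled (blue, mean ± 3 sd)") +
    theme_minimal()
}

#' Bar plot of TBE junction classes per library
#'
#' @param tbe_counts Output of [count_tbe_junction_reads()].
#' @return A ggplot of per-class junction-read counts by library.
#' @export
plot_junction_classes <- function(tbe_counts) {
  ggplot(tbe_counts, aes(x = .data$library, y = .data$n_reads,
                         fill = .data$class)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "TBE junction reads", fill = "junction class") +
    theme_minimal()
}

#' Histogram of circle lengths
#'
#' @param circles Output of [assemble_circles()].
#' @param binwidth Bin width (bp).
#' @return A ggplot.
#' @export
plot_circle_lengths <- function(circles, binwidth = 50) {
  ggplot(circles, aes(x = .data$length)) +
    geom_histogram(binwidth = binwidth, fill = "grey60", colour = "grey30") +
    labs(x = "circle length (bp)", y = "isoforms") +
    theme_minimal()
}

#' Histogram of horizontal RNA coverage fractions
#'
#' @param per_circle `per_circle` element of [horizontal_rna_coverage()],
#'   possibly row-bound over conditions with a `condition` column.
#' @return A ggplot.
#' @export
plot_rna_coverage <- function(per_circle) {
  p <- ggplot(per_circle, aes(x = .data$rna_coverage)) +
    geom_histogram(breaks = seq(0, 1, 0.05), fill = "purple4",
                   colour = "grey30", alpha = 0.7) +
    labs(x = "fraction of circle covered by ≥ 1 RNA read",
         y = "circles") +
    theme_minimal()
  if ("condition" %in% names(per_circle)) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}
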