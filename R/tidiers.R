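# broom-style tidiers and ggplot2 methods for result objects.

#' Tidy a permutation test
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return One-row tibble with observed count, null mean/sd, z, normal and
#'   empirical p-values, tail and number of permutations.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, z = x$z, p_value = x$p,
         p_empirical = x$p_empirical, tail = x$tail, n_perm = x$n_perm)
}

#' Glance at a permutation test
#'
#' @inheritParams tidy.perm_test
#' @return One-row tibble with the headline statistics and test metadata.
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(n_query = x$n_query, observed = x$observed, z = x$z,
         p_value = x$p, n_perm = x$n_perm, seed = x$seed,
         shuffled_set = x$shuffled_set,
         same_chromosome = x$same_chromosome,
         non_overlapping = x$non_overlapping)
}

#' Plot the permutation null with the observed overlap count
#'
#' Histogram of the shuffled overlap counts with the observed count marked;
#' the standard visual check that the normal-tail p is sensible for the
#' null at hand.
#'
#' @param object A `perm_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble(count = object$null_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = "overlapping query intervals per shuffle",
      y = "shuffles",
      title = sprintf("observed = %d, z = %.2f, p[%s] = %.3g",
                      object$observed,
                      ifelse(is.na(object$z), NaN, object$z),
                      object$tail, object$p)) +
    ggplot2::theme_minimal()
}

#' Plot a donor-coordinate breakpoint histogram
#'
#' Per-nucleotide junction counts along the donor, coloured by signature
#' class, with the pble outer termini marked — proper junctions pile up
#' exactly on the termini, truncations just inside, backbone carryover
#' just outside.
#'
#' @param hist Tibble from [breakpoint_histogram()].
#' @param donor Optional `donor_construct` for the termini marks (taken
#'   from the histogram attributes when omitted).
#' @return A ggplot object.
#' @export
plot_breakpoint_histogram <- function(hist, donor = NULL) {
  pble_start <- if (!is.null(donor)) donor$pble_start else
    attr(hist, "pble_start")
  pble_end <- if (!is.null(donor)) donor$pble_end else
    attr(hist, "pble_end")
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$donor_bp, y = .data$n,
                                          fill = .data$klass)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "donor coordinate (bp)", y = "unique junctions",
                  fill = "signature") +
    ggplot2::theme_minimal()
  if (!is.null(pble_start)) {
    p <- p + ggplot2::geom_vline(xintercept = c(pble_start, pble_end),
                                 linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot junction class summaries
#'
#' Bar chart of the four-way signature percentages produced by
#' [summarize_junction_classes()].
#'
#' @param summary Tibble from [summarize_junction_classes()] (rows from
#'   several donors may be bound together if a `donor` column is present).
#' @return A ggplot object.
#' @export
plot_class_summary <- function(summary) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$klass, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of unique junctions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if ("donor" %in% names(summary)) {
    p <- p + ggplot2::facet_wrap(~donor)
  }
  p
}
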