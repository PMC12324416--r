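# Synthetic peak / annotation interval sets with planted enrichment.

#' Generate peak and annotation interval sets with planted overlap
#'
#' Builds an annotation set (if not supplied) and a peak set in which
#' exactly `ceiling(enrichment_fraction * n_peaks)` peaks overlap an
#' annotation by at least 1 bp. The remaining peaks are placed uniformly at
#' random, either avoiding annotations entirely (`background = "avoid"`,
#' which makes the planted overlap count exact) or without regard to them
#' (`background = "uniform"`, the null of [permutation_test()]; use this
#' for calibration experiments). Peaks are mutually non-overlapping.
#'
#' @param genome_lengths Named integer vector of contig lengths.
#' @param n_peaks Number of peaks.
#' @param peak_width Single width or `c(min, max)` for uniform widths.
#' @param annotations Interval tibble to overlap with, or `NULL` to
#'   generate `n_annotations` intervals of width `annotation_width`.
#' @param enrichment_fraction Fraction of peaks planted on annotations, in
#'   `[0, 1]`.
#' @param background `"avoid"` or `"uniform"` (see above).
#' @param n_annotations,annotation_width Used when `annotations` is `NULL`.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap per interval.
#' @return List with `peaks` and `annotations` interval tibbles; peak
#'   `name` records whether the peak was planted on an annotation.
#' @export
make_interval_sets <- function(genome_lengths, n_peaks = 100L,
                               peak_width = 300L, annotations = NULL,
                               enrichment_fraction = 0,
                               background = c("avoid", "uniform"),
                               n_annotations = 50L, annotation_width = 500L,
                               seed = 1L, max_tries = 10000L) {
  background <- match.arg(background)
  stopifnot(enrichment_fraction >= 0, enrichment_fraction <= 1,
            !is.null(names(genome_lengths)))
  withr::with_seed(seed, {
    if (is.null(annotations)) {
      ann <- place_random_intervals(
        n_annotations, annotation_width, genome_lengths,
        avoid = NULL, max_tries = max_tries)
      annotations <- intervals(ann$contig, ann$start, ann$end,
                               name = "annotation")
    } else {
      annotations <- validate_intervals(annotations)
    }
    n_over <- as.integer(ceiling(enrichment_fraction * n_peaks))
    widths <- if (length(peak_width) == 2L) {
      sample(seq.int(peak_width[1], peak_width[2]), n_peaks, replace = TRUE)
    } else rep(as.integer(peak_width), n_peaks)

    placed <- list()
    taken <- annotations[0, ]
    # planted overlapping peaks: anchor on a random annotation, offset so
    # that the overlap is >= 1 bp
    for (i in seq_len(n_over)) {
      w <- widths[i]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        a <- annotations[sample.int(nrow(annotations), 1L), ]
        L <- genome_lengths[[a$contig]]
        lo <- max(0L, a$start - w + 1L)
        hi <- min(L - w, a$end - 1L)
        if (hi < lo) next
        s <- sample(seq.int(lo, hi), 1L)
        cand <- tibble(contig = a$contig, start = s, end = s + w)
        if (overlaps_any(cand, bind_rows(placed))) next
        placed[[length(placed) + 1L]] <- mutate(cand, name = "planted")
        ok <- TRUE
        break
      }
      if (!ok) abort("could not place a planted overlapping peak")
    }
    # background peaks
    placed_df <- if (length(placed)) {
      bind_rows(placed)[, c("contig", "start", "end")]
    } else {
      tibble(contig = character(), start = integer(), end = integer())
    }
    avoid <- if (background == "avoid") {
      bind_rows(annotations[, c("contig", "start", "end")], placed_df)
    } else {
      placed_df
    }
    for (i in seq_len(n_peaks - n_over)) {
      w <- widths[n_over + i]
      bg <- place_random_intervals(1L, w, genome_lengths, avoid = avoid,
                                   max_tries = max_tries)
      bg <- mutate(bg, name = "background")
      placed[[length(placed) + 1L]] <- bg
      avoid <- bind_rows(avoid, bg[, c("contig", "start", "end")])
    }
    peaks <- bind_rows(placed) %>%
      mutate(score = NA_real_, strand = ".") %>%
      arrange(.data$contig, .data$start)
    list(peaks = validate_intervals(peaks), annotations = annotations)
  })
}

# Place n intervals of width w uniformly at random, not overlapping `avoid`
# (tibble or NULL) nor each other.
#' @keywords internal
place_random_intervals <- function(n, w, genome_lengths, avoid = NULL,
                                   max_tries = 10000L) {
  out <- list()
  taken <- avoid
  probs <- genome_lengths / sum(genome_lengths)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample(length(genome_lengths), 1L, prob = probs)
      L <- genome_lengths[[ci]]
      if (L < w) next
      s <- sample.int(L - w + 1L, 1L) - 1L
      cand <- tibble(contig = names(genome_lengths)[ci], start = s,
                     end = s + w)
      if (!is.null(taken) && nrow(taken) && overlaps_any(cand, taken)) next
      out[[i]] <- cand
      taken <- if (is.null(taken)) cand else bind_rows(taken, cand)
      ok <- TRUE
      break
    }
    if (!ok) abort("interval placement infeasible (density too high)")
  }
  bind_rows(out)
}

# Does the single interval `x` overlap any interval in `set` by >= 1 bp?
#' @keywords internal
overlaps_any <- function(x, set) {
  if (is.null(set) || !nrow(set)) return(FALSE)
  same <- set[set$contig == x$contig, ]
  any(same$start < x$end & x$start < same$end)
}
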