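# Interval overlap statistics: exclusion-list filtering, overlap counting,
# chromosome-preserving non-overlapping shuffles, and the permutation test
# used to score peak/annotation co-occurrence.

#' Remove peaks overlapping an exclusion list
#'
#' Drops every peak overlapping an exclusion interval by >= 1 bp
#' (half-open arithmetic: intervals that merely touch are kept). This is
#' the ENCODE-exclusion-list style filter applied to peak sets before
#' overlap analysis.
#'
#' @param peaks,exclusion Interval tibbles on the same genome.
#' @return Filtered peak tibble.
#' @export
filter_exclusion <- function(peaks, exclusion) {
  peaks <- validate_intervals(peaks)
  if (!nrow(exclusion)) return(peaks)
  exclusion <- validate_intervals(exclusion)
  hits <- IRanges::overlapsAny(intervals_to_granges(peaks),
                               intervals_to_granges(exclusion))
  peaks[!hits, ]
}

#' Count query intervals overlapping any annotation
#'
#' Number of query intervals with >= 1 bp overlap with at least one
#' annotation interval; each query is counted at most once.
#'
#' @param query,annotations Interval tibbles.
#' @return Integer count.
#' @export
count_overlapping <- function(query, annotations) {
  query <- validate_intervals(query)
  if (!nrow(annotations) || !nrow(query)) return(0L)
  annotations <- validate_intervals(annotations)
  sum(IRanges::overlapsAny(intervals_to_granges(query),
                           intervals_to_granges(annotations)))
}

#' Fraction of peaks overlapping inverted-repeat annotations
#'
#' @param peaks Interval tibble of peaks.
#' @param ir_annotations Interval tibble (e.g. IR arms-plus-spacer spans
#'   from the IR scanner, or any annotation set).
#' @return Percentage of peaks with >= 1 bp overlap, in `[0, 100]`.
#' @export
ir_overlap_fraction <- function(peaks, ir_annotations) {
  if (!nrow(peaks)) return(NA_real_)
  100 * count_overlapping(peaks, ir_annotations) / nrow(peaks)
}

#' Shuffle intervals, preserving lengths and (optionally) chromosomes
#'
#' Random re-placement of each interval: lengths are always preserved;
#' with `same_chromosome = TRUE` (the shuffleBed `-chromFirst` behaviour)
#' each interval stays on its contig; with `non_overlapping = TRUE` the
#' shuffled intervals are mutually non-overlapping (rejection sampling with
#' a retry cap; exceeding the cap is an error, never a silent overlap).
#'
#' @param x Interval tibble.
#' @param genome_lengths Named integer vector of contig lengths.
#' @param same_chromosome Keep each interval on its original contig.
#' @param non_overlapping Require mutually non-overlapping placements.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @param max_tries Retry cap.
#' @return Interval tibble with new starts/ends.
#' @export
shuffle_intervals <- function(x, genome_lengths, same_chromosome = TRUE,
                              non_overlapping = TRUE, seed = NULL,
                              max_tries = 10000L) {
  x <- validate_intervals(x)
  run <- function() {
    widths <- x$end - x$start
    contig <- if (same_chromosome) x$contig else {
      probs <- genome_lengths / sum(genome_lengths)
      sample(names(genome_lengths), nrow(x), replace = TRUE, prob = probs)
    }
    starts <- integer(nrow(x))
    for (cn in unique(contig)) {
      idx <- which(contig == cn)
      L <- genome_lengths[[cn]]
      if (sum(widths[idx]) > L && non_overlapping) {
        abort(sprintf("intervals do not fit on contig %s without overlap", cn))
      }
      starts[idx] <- place_on_contig(widths[idx], L, non_overlapping,
                                     max_tries)
    }
    tibble(contig = contig, start = starts, end = starts + widths,
           name = x$name, score = x$score, strand = x$strand)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Uniform starts for a set of widths on one contig; whole-set rejection
# until mutually non-overlapping (when required).
#' @keywords internal
place_on_contig <- function(widths, L, non_overlapping, max_tries) {
  k <- length(widths)
  for (try in seq_len(max_tries)) {
    starts <- vapply(widths, function(w) {
      if (L < w) abort("interval longer than contig")
      sample.int(L - w + 1L, 1L) - 1L
    }, integer(1))
    if (!non_overlapping || k == 1L) return(starts)
    o <- order(starts)
    if (all(starts[o][-1] >= (starts + widths)[o][-k])) return(starts)
  }
  abort(sprintf("no non-overlapping placement found in %d tries", max_tries))
}

#' Permutation test of peak/annotation overlap
#'
#' Shuffles the query set `n_perm` times with [shuffle_intervals()]
#' (annotations held fixed), recomputes the overlap count each time, and
#' summarises the observed count against the null as a Z score with a
#' normal-tail probability. The empirical permutation rank p-value is also
#' reported for comparison. When the null is degenerate (`null_sd == 0`)
#' `z` and both p-values are `NA`.
#'
#' @param query Interval tibble (the set that is shuffled, typically peaks).
#' @param annotations Interval tibble held fixed.
#' @param genome_lengths Named integer vector of contig lengths.
#' @param n_perm Number of shuffles (>= 2 for a defined sd).
#' @param tail `"greater"` (enrichment, default), `"less"`, or
#'   `"two_sided"`.
#' @param seed Integer seed for the shuffle stream.
#' @param same_chromosome,non_overlapping Passed to the shuffler.
#' @return A `perm_test` object; see [tidy.perm_test()] /
#'   [glance.perm_test()] / [autoplot.perm_test()].
#' @export
permutation_test <- function(query, annotations, genome_lengths,
                             n_perm = 10000L,
                             tail = c("greater", "less", "two_sided"),
                             seed = 1L, same_chromosome = TRUE,
                             non_overlapping = TRUE) {
  tail <- match.arg(tail)
  stopifnot(n_perm >= 2L)
  query <- validate_intervals(query, genome = NULL)
  annotations <- validate_intervals(annotations)

  merged <- merge_by_contig(annotations)
  observed <- count_overlap_fast(query$contig, query$start, query$end, merged)

  widths_by <- split(query$end - query$start, query$contig)
  null_counts <- integer(n_perm)
  withr::with_seed(seed, {
    for (p in seq_len(n_perm)) {
      total <- 0L
      for (cn in names(widths_by)) {
        L <- genome_lengths[[cn]]
        s <- place_on_contig_fast(widths_by[[cn]], L, non_overlapping)
        total <- total + count_overlap_fast(
          rep(cn, length(s)), s, s + widths_by[[cn]], merged)
      }
      null_counts[p] <- total
    }
  })
  null_mean <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  if (null_sd > 0) {
    z <- (observed - null_mean) / null_sd
    p_normal <- switch(tail,
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z),
      two_sided = 2 * pnorm(-abs(z)))
    p_empirical <- switch(tail,
      greater = (1 + sum(null_counts >= observed)) / (n_perm + 1),
      less = (1 + sum(null_counts <= observed)) / (n_perm + 1),
      two_sided = min(1, 2 * min(
        (1 + sum(null_counts >= observed)) / (n_perm + 1),
        (1 + sum(null_counts <= observed)) / (n_perm + 1))))
  } else {
    z <- NA_real_; p_normal <- NA_real_; p_empirical <- NA_real_
  }
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z, p = p_normal,
                 p_empirical = p_empirical, tail = tail, n_perm = n_perm,
                 seed = seed, n_query = nrow(query),
                 null_counts = null_counts,
                 shuffled_set = "query",
                 same_chromosome = same_chromosome,
                 non_overlapping = non_overlapping),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> observed=%d, null=%.2f +/- %.2f over %d shuffles\n",
    x$observed, x$null_mean, x$null_sd, x$n_perm))
  if (is.na(x$z)) {
    cat("  degenerate null (sd = 0); z and p undefined\n")
  } else {
    cat(sprintf("  z=%.3f, p[%s]=%.3g (empirical %.3g)\n",
                x$z, x$tail, x$p, x$p_empirical))
  }
  invisible(x)
}

# --- fast internal interval machinery (plain integer vectors) ----------
# The permutation loop runs tens of thousands of shuffle+count rounds;
# building GRanges per round is far too slow, so the loop works on sorted
# merged annotation boundaries and vectorised placement. count_overlapping()
# (IRanges route) is cross-checked against this path in the tests.

#' @keywords internal
merge_by_contig <- function(x) {
  lapply(split(x[, c("start", "end")], x$contig), function(df) {
    o <- order(df$start)
    s <- df$start[o]; e <- df$end[o]
    ms <- s[1]; me <- e[1]
    outs <- numeric(0); oute <- numeric(0)
    if (length(s) > 1L) {
      for (i in 2L:length(s)) {
        if (s[i] <= me) me <- max(me, e[i]) else {
          outs <- c(outs, ms); oute <- c(oute, me); ms <- s[i]; me <- e[i]
        }
      }
    }
    list(start = c(outs, ms), end = c(oute, me))
  })
}

#' @keywords internal
count_overlap_fast <- function(contig, start, end, merged) {
  total <- 0L
  for (cn in unique(contig)) {
    m <- merged[[cn]]
    idx <- contig == cn
    if (is.null(m)) next
    qs <- start[idx]; qe <- end[idx]
    nmerged <- length(m$start)
    j <- findInterval(qs, m$start)
    hit1 <- j >= 1L
    hit1[hit1] <- m$end[j[hit1]] > qs[hit1]
    hit2 <- j < nmerged
    hit2[hit2] <- m$start[j[hit2] + 1L] < qe[hit2]
    total <- total + sum(hit1 | hit2)
  }
  total
}

#' @keywords internal
place_on_contig_fast <- function(widths, L, non_overlapping,
                                 max_tries = 10000L) {
  k <- length(widths)
  ub <- L - widths + 1L
  for (try in seq_len(max_tries)) {
    starts <- as.integer(floor(runif(k) * ub))
    if (!non_overlapping || k == 1L) return(starts)
    o <- order(starts)
    if (all(starts[o][-1] >= (starts + widths)[o][-k])) return(starts)
  }
  abort(sprintf("no non-overlapping placement found in %d tries", max_tries))
}

#' Per-peak width, read count and density summaries
#'
#' Density is read count divided by peak width (arbitrary units), the
#' peak-level statistic used to compare repeat categories.
#'
#' @param peaks Interval tibble; `score` is interpreted as the supporting
#'   read count unless `reads` is given.
#' @param reads Optional numeric vector of per-peak read counts.
#' @param category Optional character vector of per-peak category labels.
#' @return List with `peaks` (tibble incl. `width`, `reads`, `density`,
#'   `category`) and `medians` (per-category medians of width, reads and
#'   density).
#' @export
peak_summaries <- function(peaks, reads = NULL, category = NULL) {
  peaks <- validate_intervals(peaks)
  reads <- reads %||% peaks$score
  if (any(is.na(reads))) abort("read counts missing")
  category <- category %||% rep("all", nrow(peaks))
  tab <- peaks %>%
    mutate(width = .data$end - .data$start, reads = reads,
           density = reads / .data$width, category = category)
  med <- tab %>%
    group_by(.data$category) %>%
    summarise(n = n(), median_width = median(.data$width),
              median_reads = median(.data$reads),
              median_density = median(.data$density), .groups = "drop")
  list(peaks = tab, medians = med)
}
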