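# Inverted-repeat, motif and tandem-run annotation.
#
# The IR scanner reproduces the pal2gff-style filter used for pble-like
# inner inverted repeats: arm length 5-15 bp, spacer 2-10 bp, and a mismatch
# budget of 0 for 5-bp arms rising to 1 for arms of >= 6 bp.

#' Find inverted repeats with mismatch tolerance
#'
#' Scans a single sequence for arm pairs `left-spacer-right` where the left
#' arm equals the reverse complement of the right arm up to a Hamming
#' mismatch budget. The budget is 0 for arms shorter than
#' `mismatch_min_arm` and `max_mismatch` otherwise. `N` never matches any
#' base, including `N`.
#'
#' By default only the maximal arm per (left start, spacer) locus is
#' reported: shorter arms nested at the same locus are suppressed. Set
#' `all_pairs = TRUE` for the exhaustive enumeration (used by oracle tests).
#'
#' @param seq A single nucleotide string (A/C/G/T/N).
#' @param min_arm,max_arm Arm length bounds in bp.
#' @param min_spacer,max_spacer Spacer length bounds in bp.
#' @param max_mismatch Mismatch budget for arms of at least
#'   `mismatch_min_arm` bp.
#' @param mismatch_min_arm Arm length from which `max_mismatch` applies;
#'   shorter arms must match exactly.
#' @param all_pairs Report every admissible (start, arm, spacer) triple
#'   instead of applying the maximality rule.
#' @param contig Contig name recorded in the output.
#' @return Tibble with columns `contig`, `left_start`, `left_end`,
#'   `right_start`, `right_end` (0-based half-open), `arm_len`,
#'   `spacer_len`, `mismatches`, sorted by (left_start, arm_len,
#'   spacer_len).
#' @examples
#' find_inverted_repeats("ACGTAGGTACGT")
#' @export
find_inverted_repeats <- function(seq, min_arm = 5L, max_arm = 15L,
                                  min_spacer = 2L, max_spacer = 10L,
                                  max_mismatch = 1L, mismatch_min_arm = 6L,
                                  all_pairs = FALSE, contig = "seq") {
  stopifnot(length(seq) == 1L, min_arm >= 1L, min_arm <= max_arm,
            min_spacer >= 0L, min_spacer <= max_spacer, max_mismatch >= 0L)
  check_dna_alphabet(seq)
  L <- nchar(seq)
  if (L == 0L) abort("empty sequence")
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T", "N"))
  # complement codes; N -> 0 sentinel that equals nothing (codes are >= 1)
  comp <- c(4L, 3L, 2L, 1L, 0L)[code]

  res <- vector("list", 64L)
  k <- 0L
  for (a in seq.int(min_arm, max_arm)) {
    allowed <- if (a < mismatch_min_arm) 0L else max_mismatch
    for (s in seq.int(min_spacer, max_spacer)) {
      span <- 2L * a + s
      n_i <- L - span + 1L
      if (n_i < 1L) next
      i <- seq_len(n_i)                       # 1-based left-arm starts
      mism <- integer(n_i)
      for (j in seq_len(a)) {
        # left arm base j vs complement of right arm base (a - j + 1)
        lj <- i + j - 1L
        rj <- i + 2L * a + s - j
        mism <- mism + as.integer(code[lj] != comp[rj] |
                                  code[lj] == 5L | comp[rj] == 0L)
      }
      hit <- which(mism <= allowed)
      if (length(hit)) {
        k <- k + 1L
        if (k > length(res)) res <- c(res, vector("list", length(res)))
        res[[k]] <- tibble(left_start = hit - 1L, arm_len = a,
                           spacer_len = s, mismatches = mism[hit])
      }
    }
  }
  out <- if (k) bind_rows(res[seq_len(k)]) else
    tibble(left_start = integer(), arm_len = integer(),
           spacer_len = integer(), mismatches = integer())
  if (!all_pairs && nrow(out)) {
    out <- out %>%
      group_by(.data$left_start, .data$spacer_len) %>%
      filter(.data$arm_len == max(.data$arm_len)) %>%
      ungroup()
  }
  out %>%
    mutate(contig = contig,
           left_end = .data$left_start + .data$arm_len,
           right_start = .data$left_end + .data$spacer_len,
           right_end = .data$right_start + .data$arm_len) %>%
    select("contig", "left_start", "left_end", "right_start", "right_end",
           "arm_len", "spacer_len", "mismatches") %>%
    arrange(.data$left_start, .data$arm_len, .data$spacer_len)
}

#' Count exact non-overlapping motif occurrences
#'
#' Greedy left-to-right scan: after a match at position i the scan resumes
#' at i + motif length. With `both_strands = TRUE` the reverse complement of
#' the motif is counted in a second, independent scan and the two counts are
#' summed.
#'
#' @param seq A single nucleotide string, or a genome
#'   ([Biostrings::DNAStringSet] / named character vector), in which case
#'   per-contig counts are summed per contig row.
#' @param motif Motif over A/C/G/T.
#' @param both_strands Also count the reverse-complement motif.
#' @return Tibble with columns `contig`, `motif`, `count`, `strands`.
#' @examples
#' count_motif_nonoverlapping("TTAACCCTTAACCC", "TTAACCC")
#' @export
count_motif_nonoverlapping <- function(seq, motif, both_strands = FALSE) {
  stopifnot(nchar(motif) >= 1L)
  if (grepl("[^ACGT]", motif)) abort("motif must be over A/C/G/T")
  seqs <- if (is.character(seq) && is.null(names(seq)) && length(seq) == 1L) {
    c(seq = seq)
  } else {
    s <- as_genome(seq)
    setNames(as.character(s), names(s))
  }
  count_one <- function(s, m) {
    # gregexpr with fixed = TRUE is exactly the greedy leftmost
    # non-overlapping scan
    hits <- gregexpr(m, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }
  counts <- vapply(seqs, function(s) {
    n <- count_one(s, motif)
    if (both_strands) n <- n + count_one(s, revcomp(motif))
    n
  }, integer(1))
  tibble(contig = names(seqs), motif = motif, count = unname(counts),
         strands = if (both_strands) "both" else "plus")
}

#' Find maximal tandem runs of a repeat unit
#'
#' Reports maximal runs of at least `min_copies` exact head-to-tail copies
#' of `unit`: a reported run cannot be extended by a full unit on either
#' side. Runs at a shifted phase overlapping a reported run are suppressed
#' (greedy leftmost scan).
#'
#' @param seq A single nucleotide string.
#' @param unit Repeat unit (length >= 2, A/C/G/T).
#' @param min_copies Minimum number of exact copies.
#' @param contig Contig name recorded in the output.
#' @return Interval tibble; `score` holds the copy number, `name` the unit.
#' @examples
#' find_tandem_runs(paste0("AC", strrep("TGGAA", 4), "GT"), "TGGAA", 3)
#' @export
find_tandem_runs <- function(seq, unit, min_copies = 3L, contig = "seq") {
  stopifnot(length(seq) == 1L, nchar(unit) >= 2L, min_copies >= 1L)
  if (grepl("[^ACGT]", unit)) abort("unit must be over A/C/G/T")
  pat <- sprintf("(?:%s){%d,}", unit, as.integer(min_copies))
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character()))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tibble(contig = contig, start = start, end = start + len,
         name = unit, score = len / nchar(unit), strand = ".")
}

#' Annotate inverted repeats at the ends of a donor construct
#'
#' Runs the IR scanner over the two subterminal blocks of a donor construct
#' (coordinates reported on the full construct) and, in addition, searches
#' for cross-end arm pairs: a subterminal arm near the 5' TIR whose reverse
#' complement sits in the 3' subterminal block, the geometry of piggyBac
#' subterminal inverted repeats. Cross-end pairs have no spacer constraint
#' (the cassette lies between the arms); their offsets from the TIR inner
#' ends are reported.
#'
#' @param donor A `donor_construct` from [make_donor()].
#' @inheritParams find_inverted_repeats
#' @return Tibble as [find_inverted_repeats()] plus columns `scope`
#'   (`"within_block"` or `"cross_end"`), `block` (`"subterminal5"`,
#'   `"subterminal3"` or `"both"`), `offset5`, `offset3` (bp from the 5'/3'
#'   TIR inner end to the nearest base of the respective arm; `NA` for
#'   within-block IRs of the other end).
#' @export
annotate_donor_ends <- function(donor, min_arm = 5L, max_arm = 15L,
                                min_spacer = 2L, max_spacer = 10L,
                                max_mismatch = 1L, mismatch_min_arm = 6L) {
  stopifnot(inherits(donor, "donor_construct"))
  blk <- donor$blocks
  b5 <- blk[blk$block == "subterminal5", ]
  b3 <- blk[blk$block == "subterminal3", ]
  tir5_inner <- blk$end[blk$block == "tir5"]     # first base after 5' TIR
  tir3_inner <- blk$start[blk$block == "tir3"]   # first base of 3' TIR
  seq5 <- substr(donor$sequence, b5$start + 1L, b5$end)
  seq3 <- substr(donor$sequence, b3$start + 1L, b3$end)

  local_scan <- function(s, offset, block_name) {
    ir <- find_inverted_repeats(s, min_arm, max_arm, min_spacer, max_spacer,
                                max_mismatch, mismatch_min_arm,
                                contig = "donor")
    ir <- ir %>% mutate(
      left_start = .data$left_start + offset,
      left_end = .data$left_end + offset,
      right_start = .data$right_start + offset,
      right_end = .data$right_end + offset,
      scope = rep("within_block", n()), block = rep(block_name, n())
    )
    if (block_name == "subterminal5") {
      ir %>% mutate(offset5 = .data$left_start - tir5_inner,
                    offset3 = NA_integer_)
    } else {
      ir %>% mutate(offset5 = NA_integer_,
                    offset3 = tir3_inner - .data$right_end)
    }
  }

  # Cross-end pairs: maximal arm per (position in 5' block, position in 3'
  # block) diagonal; compare 5' arm to revcomp of 3' arm.
  cross <- cross_end_pairs(seq5, seq3, min_arm,
                           max(max_arm, min_arm), max_mismatch,
                           mismatch_min_arm)
  if (nrow(cross)) {
    cross <- cross %>% mutate(
      contig = "donor",
      left_start = .data$i5 + b5$start, left_end = .data$left_start + .data$arm_len,
      right_start = .data$i3 + b3$start, right_end = .data$right_start + .data$arm_len,
      spacer_len = .data$right_start - .data$left_end,
      scope = "cross_end", block = "both",
      offset5 = .data$left_start - tir5_inner,
      offset3 = tir3_inner - .data$right_end
    ) %>%
      select("contig", "left_start", "left_end", "right_start", "right_end",
             "arm_len", "spacer_len", "mismatches", "scope", "block",
             "offset5", "offset3")
  }
  bind_rows(local_scan(seq5, b5$start, "subterminal5"),
            local_scan(seq3, b3$start, "subterminal3"),
            cross) %>%
    arrange(.data$left_start, .data$arm_len)
}

# Exhaustive cross-block arm pairing with per-diagonal maximality: for each
# (i5, i3) anchor keep the longest arm a with hamming(seq5[i5, i5+a),
# revcomp(seq3[i3, i3+a))) within budget. Arm length is searched downward
# from max_arm. Blocks are short (tens of bp) so the cubic scan is cheap.
#' @keywords internal
cross_end_pairs <- function(seq5, seq3, min_arm, max_arm, max_mismatch,
                            mismatch_min_arm) {
  n5 <- nchar(seq5); n3 <- nchar(seq3)
  c5 <- strsplit(seq5, "", fixed = TRUE)[[1]]
  c3r <- strsplit(chartr("ACGTN", "TGCAX", seq3), "", fixed = TRUE)[[1]]
  out <- list()
  for (i5 in seq_len(n5)) {
    for (i3 in seq_len(n3)) {
      amax <- min(max_arm, n5 - i5 + 1L, n3 - i3 + 1L)
      if (amax < min_arm) next
      best <- NULL
      for (a in seq.int(amax, min_arm)) {
        allowed <- if (a < mismatch_min_arm) 0L else max_mismatch
        # left arm j-th base vs complement of right arm (a-j+1)-th base
        mm <- sum(c5[i5 + seq_len(a) - 1L] != c3r[i3 + a - seq_len(a)])
        if (mm <= allowed) { best <- c(a, mm); break }
      }
      if (!is.null(best)) {
        out[[length(out) + 1L]] <-
          tibble(i5 = i5 - 1L, i3 = i3 - 1L,
                 arm_len = best[1], mismatches = best[2])
      }
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(i5 = integer(), i3 = integer(), arm_len = integer(),
           mismatches = integer())
}
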