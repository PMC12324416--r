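# Junction calling and four-way TSD/TIR classification.
#
# The caller implements the logic of the published two-stage breakend
# strategy with an exact-seed split aligner that is valid for the
# substitution-only synthetic error model: reads fully contained in the
# donor are vector-internal and discarded; remaining reads are split into
# the longest exact donor prefix (either strand) and the longest exact
# genome suffix (either strand). Micro-homology between the donor terminus
# and the target flank (notably the TTAA duplication) makes several exact
# splits explain one read; the resolution rule snaps to a TIR outer
# terminus when one lies in the admissible window and otherwise assigns the
# ambiguous bases to the genome side.

JUNCTION_CLASSES <- c("proper_tsd_tir", "proper_tsd_improper_tir",
                      "improper_tsd_proper_tir", "improper_both")

#' @keywords internal
donor_index <- function(donor) {
  stopifnot(inherits(donor, "donor_construct"))
  list(fwd = donor$sequence, rev = revcomp(donor$sequence),
       len = nchar(donor$sequence))
}

#' @keywords internal
genome_index <- function(genome) {
  g <- as_genome(genome)
  chr <- setNames(as.character(g), names(g))
  list(fwd = chr, rev = vapply(chr, revcomp, character(1)),
       len = nchar(chr))
}

# Longest common suffix length of two plain strings.
#' @keywords internal
common_suffix_len <- function(x, y) {
  nmax <- min(nchar(x), nchar(y))
  if (nmax == 0L) return(0L)
  lo <- 0L; hi <- nmax
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (substr(x, nchar(x) - mid + 1L, nchar(x)) ==
        substr(y, nchar(y) - mid + 1L, nchar(y))) lo <- mid else hi <- mid - 1L
  }
  lo
}

# Split one read into donor prefix + genome suffix and resolve the
# breakpoint pair. Returns a list with $type in {"junction", "internal",
# "unsplit"}.
#' @keywords internal
split_read_call <- function(read, gidx, didx, pble_start, pble_end,
                            min_seed = 20L, allowed_slack = 2L) {
  rl <- nchar(read)
  if (rl < 2L * min_seed) return(list(type = "unsplit"))
  # stage 1: vector-internal reads (exact full-length match in the donor)
  if (grepl(read, didx$fwd, fixed = TRUE) ||
      grepl(read, didx$rev, fixed = TRUE)) {
    return(list(type = "internal"))
  }

  # longest exact donor prefix over both strands
  p_anchor <- substr(read, 1L, min_seed)
  read_tail <- substr(read, min_seed + 1L, rl)
  best_p <- 0L; p_strand <- NA_character_; p_pos <- NA_integer_; p_nbest <- 0L
  for (strand in c("+", "-")) {
    subject <- if (strand == "+") didx$fwd else didx$rev
    for (pos in find_all_exact(subject, p_anchor)) {
      ext <- common_prefix_len(
        read_tail, substr(subject, pos + min_seed, nchar(subject)))
      plen <- min_seed + ext
      if (plen > best_p) {
        best_p <- plen; p_strand <- strand; p_pos <- pos; p_nbest <- 1L
      } else if (plen == best_p && best_p > 0L) p_nbest <- p_nbest + 1L
    }
  }
  # longest exact genome suffix over contigs and strands
  s_anchor <- substr(read, rl - min_seed + 1L, rl)
  read_head <- substr(read, 1L, rl - min_seed)
  best_s <- 0L; s_strand <- NA_character_; s_contig <- NA_character_
  s_pos <- NA_integer_; s_nbest <- 0L
  for (cn in names(gidx$fwd)) {
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") gidx$fwd[[cn]] else gidx$rev[[cn]]
      for (pos in find_all_exact(subject, s_anchor)) {
        ext <- common_suffix_len(read_head, substr(subject, 1L, pos - 1L))
        slen <- min_seed + ext
        if (slen > best_s) {
          best_s <- slen; s_strand <- strand; s_contig <- cn; s_pos <- pos
          s_nbest <- 1L
        } else if (slen == best_s && best_s > 0L) s_nbest <- s_nbest + 1L
      }
    }
  }
  if (best_p < min_seed || best_s < min_seed ||
      best_p + best_s < rl - allowed_slack) {
    return(list(type = "unsplit"))
  }

  donor_end <- if (p_strand == "-") "five_prime" else "three_prime"
  bp_of_s <- function(s) {
    if (p_strand == "+") p_pos - 1L + s else didx$len - p_pos - s + 1L
  }
  s_lo <- max(rl - best_s, min_seed)
  s_hi <- min(best_p, rl - min_seed)
  if (s_lo > s_hi) {
    s_star <- min(best_p, rl - min_seed)   # small unassigned gap
  } else {
    term <- if (donor_end == "five_prime") pble_start else pble_end
    s_term <- if (p_strand == "+") term - (p_pos - 1L) else
      didx$len - p_pos - term + 1L
    s_star <- if (s_term >= s_lo && s_term <= s_hi) s_term else s_lo
  }
  K <- min(best_s, rl - s_star)
  chrom_bp <- if (s_strand == "+") {
    s_pos - 1L + min_seed - K
  } else {
    gidx$len[[s_contig]] - (s_pos + min_seed - K) + 1L
  }
  list(type = "junction", contig = s_contig, chrom_bp = as.integer(chrom_bp),
       genome_strand = s_strand, donor_end = donor_end,
       donor_bp = as.integer(bp_of_s(s_star)),
       donor_extent = as.integer(bp_of_s(s_star)),
       prefix_len = best_p, suffix_len = best_s,
       ambiguous = (p_nbest > 1L || s_nbest > 1L))
}

#' Call chromosome-donor junctions from junction reads
#'
#' Two-stage caller for LAM-PCR style junction reads (donor-side primer,
#' read runs across the junction into chromosomal sequence). Stage 1
#' discards reads with a full-length exact match in the donor construct
#' (vector-internal). Stage 2 finds the longest exact donor prefix and the
#' longest exact genome suffix (each on either strand); a read is split
#' when prefix + suffix cover the read up to `allowed_slack` bases, and
#' the breakpoint pair is resolved as described in
#' \code{vignette("pble-junction-analysis")}. Reads whose donor and genome
#' matches tie at several loci are flagged `ambiguous`.
#'
#' @param reads Tibble with `read_id`/`sequence` (from
#'   [simulate_reads()] or [read_reads_fastq()]) or a FASTQ path.
#' @param genome Reference genome ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param donor A `donor_construct`.
#' @param min_seed Minimum exact match on each side of the split, bp.
#' @param allowed_slack Maximum unassigned bases between prefix and suffix.
#' @return Tibble of per-read calls with columns `read_id`, `contig`,
#'   `chrom_bp`, `genome_strand`, `donor_end`, `donor_bp`, `donor_extent`
#'   (the donor-side alignment end of the resolved split; per-read values
#'   that disagree within one junction drive the spread filter),
#'   `prefix_len`, `suffix_len`, `ambiguous`. Attributes `n_internal` and
#'   `n_unsplit` count discarded reads.
#' @export
call_junctions <- function(reads, genome, donor, min_seed = 20L,
                           allowed_slack = 2L) {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_reads_fastq(reads)
  }
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  gidx <- genome_index(genome)
  didx <- donor_index(donor)
  n_internal <- 0L; n_unsplit <- 0L
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    res <- split_read_call(reads$sequence[i], gidx, didx,
                           donor$pble_start, donor$pble_end,
                           min_seed, allowed_slack)
    if (res$type == "internal") { n_internal <- n_internal + 1L; next }
    if (res$type == "unsplit") { n_unsplit <- n_unsplit + 1L; next }
    res$type <- NULL
    rows[[i]] <- as_tibble(c(list(read_id = reads$read_id[i]), res))
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(read_id = character(), contig = character(),
                  chrom_bp = integer(), genome_strand = character(),
                  donor_end = character(), donor_bp = integer(),
                  donor_extent = integer(), prefix_len = integer(),
                  suffix_len = integer(), ambiguous = logical())
  }
  attr(out, "n_internal") <- n_internal
  attr(out, "n_unsplit") <- n_unsplit
  out
}

#' Deduplicate junction calls and apply the spread filter
#'
#' Per-read calls are grouped into unique junctions by (contig, chromosome
#' breakpoint, genome strand, donor end) with summed support. A junction
#' is retained iff the largest absolute difference between its consensus
#' donor-side breakpoint and any supporting read's donor-side alignment
#' extent is strictly below `max_spread_diff` (the "difference below 3"
#' filter at its default). Reads flagged ambiguous are dropped (and
#' counted) before grouping.
#'
#' @param calls Tibble from [call_junctions()] (or with the same columns).
#' @param max_spread_diff Strict upper bound on the breakpoint/extent
#'   difference in bp.
#' @return Tibble of unique junctions: `contig`, `chrom_bp`,
#'   `genome_strand`, `donor_end`, `donor_bp` (consensus = most supported
#'   value), `support`, `spread` (max minus min extent), `spread_diff`.
#'   Attribute `n_ambiguous` counts dropped ambiguous calls,
#'   `n_spread_filtered` the junctions removed by the filter.
#' @export
dedupe_and_filter <- function(calls, max_spread_diff = 3L) {
  n_amb <- sum(calls$ambiguous)
  calls <- filter(calls, !.data$ambiguous)
  uniq <- calls %>%
    group_by(.data$contig, .data$chrom_bp, .data$genome_strand,
             .data$donor_end) %>%
    summarise(
      donor_bp_mode = {
        tab <- sort(table(.data$donor_bp), decreasing = TRUE)
        as.integer(names(tab)[1])
      },
      support = n(),
      spread = max(.data$donor_extent) - min(.data$donor_extent),
      spread_diff = max(abs(.data$donor_extent - donor_bp_mode)),
      .groups = "drop") %>%
    dplyr::rename(donor_bp = "donor_bp_mode")
  kept <- filter(uniq, .data$spread_diff < max_spread_diff)
  attr(kept, "n_ambiguous") <- n_amb
  attr(kept, "n_spread_filtered") <- nrow(uniq) - nrow(kept)
  kept
}

#' Extract chromosomal flanks and the TSD call at a breakpoint
#'
#' Returns the 10 bp of reference chromosome ending at `position`
#' (`flank_up`), the 10 bp starting at `position` (`flank_down`), and the
#' target-site tetranucleotide on the chromosome-retained side of the
#' junction, oriented so that a canonical insertion reads `TTAA`
#' regardless of event orientation: with `genome_strand = "-"` (chromosome
#' retained upstream) the last 4 bp of `flank_up` reverse-complemented;
#' with `"+"` the first 4 bp of `flank_down`. Near contig edges flanks are
#' returned shorter and flagged `clipped`.
#'
#' @param genome Reference genome.
#' @param contig,position Breakpoint coordinates (0-based).
#' @param genome_strand `"-"` or `"+"`, the strand of the genome-side
#'   alignment at the junction (vectorised along `contig`/`position`).
#' @param flank Flank length in bp.
#' @return Tibble with `flank_up`, `flank_down`, `tsd_call`, `clipped`.
#' @export
extract_flanks <- function(genome, contig, position, genome_strand = "-",
                           flank = 10L) {
  chr <- setNames(as.character(as_genome(genome)), names(as_genome(genome)))
  n <- length(position)
  genome_strand <- rep_len(genome_strand, n)
  contig <- rep_len(contig, n)
  purrr::pmap_dfr(
    list(contig, position, genome_strand),
    function(cn, pos, strand) {
      s <- chr[[cn]]
      L <- nchar(s)
      up_start <- max(0L, pos - flank)
      down_end <- min(L, pos + flank)
      flank_up <- substr(s, up_start + 1L, pos)
      flank_down <- substr(s, pos + 1L, down_end)
      clipped <- (pos - up_start) < flank || (down_end - pos) < flank
      tsd <- if (strand == "-") {
        if (pos >= 4L) revcomp(substr(s, pos - 3L, pos)) else NA_character_
      } else {
        if (pos + 4L <= L) substr(s, pos + 1L, pos + 4L) else NA_character_
      }
      tibble(flank_up = flank_up, flank_down = flank_down,
             tsd_call = tsd, clipped = clipped)
    })
}

#' Classify unique junctions by TSD and TIR propriety
#'
#' The four-way signature: a junction has a *proper TIR* iff its
#' donor-side breakpoint lies exactly at the outer terminus of the
#' relevant TIR (no truncation, no backbone carryover; a 1-bp slip is
#' improper), and a *proper TSD* iff the target-site tetranucleotide is
#' `TTAA`. Junctions whose donor-side breakpoint falls inside the cassette
#' are `unclassified` and excluded from class summaries.
#'
#' @param junctions Tibble from [dedupe_and_filter()].
#' @param donor The `donor_construct` the reads were called against.
#' @param genome Reference genome (for flank/TSD extraction).
#' @return Input tibble plus `flank_up`, `flank_down`, `clipped`,
#'   `tsd_call`, `proper_tsd`, `proper_tir`, `orientation` (inferred event
#'   orientation) and `klass`.
#' @export
classify_junctions <- function(junctions, donor, genome) {
  fl <- extract_flanks(genome, junctions$contig, junctions$chrom_bp,
                       junctions$genome_strand)
  cass <- donor$blocks[donor$blocks$block == "cassette", ]
  out <- bind_cols(junctions, fl) %>%
    mutate(
      proper_tsd = !is.na(.data$tsd_call) &
        .data$tsd_call == donor$tsd_motif,
      proper_tir = ifelse(.data$donor_end == "five_prime",
                          .data$donor_bp == donor$pble_start,
                          .data$donor_bp == donor$pble_end),
      orientation = ifelse(.data$donor_end == "five_prime",
                           ifelse(.data$genome_strand == "-", "+", "-"),
                           .data$genome_strand),
      in_cassette = .data$donor_bp > cass$start & .data$donor_bp < cass$end,
      klass = dplyr::case_when(
        in_cassette ~ "unclassified",
        proper_tsd & proper_tir ~ "proper_tsd_tir",
        proper_tsd & !proper_tir ~ "proper_tsd_improper_tir",
        !proper_tsd & proper_tir ~ "improper_tsd_proper_tir",
        TRUE ~ "improper_both")) %>%
    select(-"in_cassette")
  out
}

#' Summarise junction classes (counts, percentages, total)
#'
#' Produces the per-donor class summary: counts and percentages (rounded
#' to 1 decimal) of the four TSD/TIR signature categories among unique,
#' classified junctions. Accepts either a classified junction tibble or a
#' named count vector (e.g. published counts), so printed tables can be
#' re-derived.
#'
#' @param junctions Tibble with a `klass` column, or `NULL`.
#' @param counts Named numeric vector of per-class counts (names in
#'   `JUNCTION_CLASSES`); used when `junctions` is `NULL`.
#' @param donor_label Optional label recorded in a `donor` column.
#' @return Tibble with one row per class: `klass`, `count`, `pct`;
#'   attribute `total` holds the unique-junction total. `unclassified`
#'   junctions are excluded.
#' @export
summarize_junction_classes <- function(junctions = NULL, counts = NULL,
                                       donor_label = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(junctions), "klass" %in% names(junctions))
    kl <- junctions$klass[junctions$klass != "unclassified"]
    counts <- vapply(JUNCTION_CLASSES, function(k) sum(kl == k), numeric(1))
  } else {
    stopifnot(all(names(counts) %in% JUNCTION_CLASSES))
    counts <- counts[JUNCTION_CLASSES]
    counts[is.na(counts)] <- 0
    names(counts) <- JUNCTION_CLASSES
  }
  total <- sum(counts)
  counts <- unname(counts)
  out <- tibble(klass = JUNCTION_CLASSES, count = as.numeric(counts),
                pct = if (total > 0) round(100 * counts / total, 1)
                      else rep(NA_real_, 4L))
  if (!is.null(donor_label)) out <- mutate(out, donor = donor_label,
                                           .before = 1L)
  attr(out, "total") <- total
  out
}

#' Random-placement baseline for the proper-signature percentage
#'
#' If junction breakpoints were distributed uniformly over a window of
#' `window_len` positions around a transposon end, the chance that one
#' falls on a position scored as proper is
#' `100 * proper_positions / window_len` percent. The window spans from
#' the LAM-PCR primer to roughly 100 bp of plasmid backbone beyond the
#' transposon end; its exact length depends on the primer position and is
#' therefore an input.
#'
#' @param window_len Window length in bp (> `proper_positions`).
#' @param proper_positions Number of positions scored as proper (default
#'   4, the TSD tetranucleotide).
#' @return Expected percentage (not rounded).
#' @export
expected_random_fraction <- function(window_len, proper_positions = 4L) {
  stopifnot(window_len >= proper_positions, proper_positions > 0L)
  100 * proper_positions / window_len
}

#' Fold change of an observed percentage over the random baseline
#'
#' @param observed_pct,expected_pct Percentages; `expected_pct > 0`.
#' @return `observed_pct / expected_pct`, rounded to 1 decimal.
#' @export
fold_over_random <- function(observed_pct, expected_pct) {
  stopifnot(expected_pct > 0)
  round(observed_pct / expected_pct, 1)
}

#' Per-position histogram of donor-side breakpoints
#'
#' Counts unique junctions per donor coordinate, keeping the signature
#' class per position (the per-nucleotide breakpoint distribution along
#' the donor, with proper/improper classes distinguishable by colour in
#' [plot_breakpoint_histogram()]).
#'
#' @param junctions Classified junction tibble.
#' @param donor The `donor_construct` (recorded for plotting annotations).
#' @return Tibble with `donor_bp`, `donor_end`, `klass`, `n`.
#' @export
breakpoint_histogram <- function(junctions, donor) {
  stopifnot("klass" %in% names(junctions))
  out <- junctions %>%
    group_by(.data$donor_bp, .data$donor_end, .data$klass) %>%
    summarise(n = n(), .groups = "drop") %>%
    arrange(.data$donor_bp)
  attr(out, "pble_start") <- donor$pble_start
  attr(out, "pble_end") <- donor$pble_end
  out
}
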