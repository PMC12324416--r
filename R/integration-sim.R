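# Simulation of integration events and LAM-PCR style junction reads.
#
# Each event inserts the donor's pble (optionally truncated, or carrying
# plasmid backbone) at a chromosomal site. Proper-TSD events sit at a TTAA
# occurrence with the tetranucleotide duplicated on both flanks; improper-
# TSD events sit at a non-TTAA position without duplication. The two ends
# of an event are observed through two independent LAM-PCR reactions, so
# junction sequence templates are emitted per end and never paired within
# a read.

#' Simulate integration events with known ground truth
#'
#' Draws `n` events of the four signature classes from `class_mixture`
#' (the class vector is the first random draw under `seed`, so counts can
#' be checked against an independent multinomial with the same seed),
#' places each at an admissible chromosomal site and derives, for each
#' event end, the junction sequence template an LAM-PCR read would
#' traverse (donor-side primer anchor to chromosomal flank).
#'
#' Improper-TIR events remove `truncation` bp from the pble's outer ends
#' XOR retain `carryover` bp of plasmid backbone (one mechanism per event,
#' the same amount at both ends). Sites whose local sequence context makes
#' the true breakpoint formally non-identifiable from an error-free read
#' (micro-homology between donor terminus and target flank) are rejected
#' and redrawn; see the methods vignette.
#'
#' @param genome Target genome ([Biostrings::DNAStringSet] or named
#'   character vector); must contain enough TTAA sites and margin.
#' @param donor A `donor_construct`.
#' @param n Number of events.
#' @param class_mixture Probabilities of the four classes, in the order
#'   `proper_tsd_tir`, `proper_tsd_improper_tir`, `improper_tsd_proper_tir`,
#'   `improper_both`; must sum to 1.
#' @param truncation_range,carryover_range Integer ranges (min, max) for
#'   the improper-TIR mechanisms, bp.
#' @param flank_len Chromosomal flank captured in each template, bp; must
#'   be at least the read length later simulated.
#' @param read_len Read length used for the identifiability check, bp
#'   (match the `read_len` later passed to [simulate_reads()]).
#' @param seed Integer seed.
#' @param max_site_tries Site redraws per event before failing.
#' @return List with `events` (one row per event: `event_id`, `contig`,
#'   `position`, `orientation`, `true_class`, `tir_truncation`,
#'   `backbone_carryover`, `tsd_at_site`) and `junctions` (one row per
#'   event end: truth coordinates `contig`, `chrom_bp`, `genome_strand`,
#'   `donor_end`, `donor_bp`, class, plus the `donor_part`/`genome_part`
#'   template sequences consumed by [simulate_reads()]).
#' @export
simulate_integrations <- function(genome, donor, n,
                                  class_mixture = c(0.25, 0.25, 0.25, 0.25),
                                  truncation_range = c(1L, 10L),
                                  carryover_range = c(5L, 40L),
                                  flank_len = 250L, read_len = 250L,
                                  seed = 1L, max_site_tries = 200L) {
  stopifnot(abs(sum(class_mixture) - 1) < 1e-8, length(class_mixture) == 4L,
            n >= 1L, flank_len >= read_len, truncation_range[1] >= 1L,
            truncation_range[2] < donor$pble_end - donor$pble_start - 13L,
            carryover_range[1] >= 1L)
  blk <- donor$blocks
  if (carryover_range[2] > blk$end[blk$block == "backbone_left"] -
      blk$start[blk$block == "backbone_left"]) {
    abort("carryover_range exceeds the backbone flank length")
  }
  gidx <- genome_index(genome)
  didx <- donor_index(donor)
  chr <- gidx$fwd
  lens <- gidx$len
  margin <- flank_len + 8L
  a5 <- donor$anchors[["five_prime"]]
  a3 <- donor$anchors[["three_prime"]]

  # admissible TTAA sites per contig (0-based starts, inside the margins)
  ttaa <- purrr::imap(chr, function(s, cn) {
    hits <- gregexpr("TTAA", s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(integer(0))
    p <- as.integer(hits) - 1L
    p[p >= margin & p + 4L <= lens[[cn]] - margin]
  })
  if (sum(lengths(ttaa)) < n) {
    abort("genome does not contain enough admissible TTAA sites")
  }

  withr::with_seed(seed, {
    klass <- sample(JUNCTION_CLASSES, n, replace = TRUE,
                    prob = class_mixture)
    orientation <- sample(c("+", "-"), n, replace = TRUE)
    used <- lapply(chr, function(x) integer(0))
    events <- vector("list", n)
    junctions <- vector("list", 2L * n)
    for (ev in seq_len(n)) {
      kl <- klass[ev]
      ori <- orientation[ev]
      proper_tsd <- kl %in% c("proper_tsd_tir", "proper_tsd_improper_tir")
      improper_tir <- kl %in% c("proper_tsd_improper_tir", "improper_both")
      placed <- FALSE
      for (try in seq_len(max_site_tries)) {
        # improper-TIR mechanism redrawn with the site so rejected
        # combinations do not bias the amounts
        trunc_bp <- 0L; carry_bp <- 0L
        if (improper_tir) {
          if (sample(c(TRUE, FALSE), 1L)) {
            trunc_bp <- sample(seq.int(truncation_range[1],
                                       truncation_range[2]), 1L)
          } else {
            carry_bp <- sample(seq.int(carryover_range[1],
                                       carryover_range[2]), 1L)
          }
        }
        b5 <- donor$pble_start + trunc_bp - carry_bp
        b3 <- donor$pble_end - trunc_bp + carry_bp
        cn <- sample(names(chr), 1L,
                     prob = if (proper_tsd) lengths(ttaa) else lens)
        s <- chr[[cn]]
        if (proper_tsd) {
          if (!length(ttaa[[cn]])) next
          pos <- sample(ttaa[[cn]], 1L)
        } else {
          pos <- sample.int(lens[[cn]] - 2L * margin, 1L) + margin
          # the site must not look like a canonical TSD from either side
          if (substr(s, pos - 3L, pos) == "TTAA" ||
              substr(s, pos + 1L, pos + 4L) == "TTAA") next
        }
        if (any(abs(used[[cn]] - pos) < 8L)) next
        p_L <- if (proper_tsd) pos + 4L else pos
        p_R <- pos
        left <- substr(s, p_L - flank_len + 1L, p_L)
        right <- substr(s, p_R + 1L, p_R + flank_len)
        d5 <- revcomp(substr(donor$sequence, b5 + 1L, a5))
        d3 <- substr(donor$sequence, a3 + 1L, b3)
        if (ori == "+") {
          j5 <- list(genome_part = revcomp(left), genome_strand = "-",
                     chrom_bp = p_L)
          j3 <- list(genome_part = right, genome_strand = "+",
                     chrom_bp = p_R)
        } else {
          j5 <- list(genome_part = right, genome_strand = "+",
                     chrom_bp = p_R)
          j3 <- list(genome_part = revcomp(left), genome_strand = "-",
                     chrom_bp = p_L)
        }
        jt <- tibble(
          event_id = ev,
          donor_end = c("five_prime", "three_prime"),
          contig = cn,
          chrom_bp = c(j5$chrom_bp, j3$chrom_bp),
          genome_strand = c(j5$genome_strand, j3$genome_strand),
          donor_bp = c(b5, b3),
          true_class = kl,
          donor_part = c(d5, d3),
          genome_part = c(j5$genome_part, j3$genome_part))
        # identifiability: an error-free read over this template must
        # resolve to the planted breakpoint pair
        ok <- all(vapply(seq_len(2L), function(i) {
          tmpl <- paste0(jt$donor_part[i], jt$genome_part[i])
          read <- substr(tmpl, 1L, min(nchar(tmpl), read_len))
          res <- split_read_call(read, gidx, didx, donor$pble_start,
                                 donor$pble_end)
          res$type == "junction" && !res$ambiguous &&
            res$contig == jt$contig[i] &&
            res$chrom_bp == jt$chrom_bp[i] &&
            res$donor_end == jt$donor_end[i] &&
            res$donor_bp == jt$donor_bp[i]
        }, logical(1)))
        if (!ok) next
        used[[cn]] <- c(used[[cn]], pos)
        if (proper_tsd) ttaa[[cn]] <- setdiff(ttaa[[cn]], pos)
        events[[ev]] <- tibble(
          event_id = ev, contig = cn, position = pos, orientation = ori,
          true_class = kl, tir_truncation = trunc_bp,
          backbone_carryover = carry_bp,
          tsd_at_site = if (proper_tsd) donor$tsd_motif
                        else substr(s, pos + 1L, pos + 4L))
        junctions[[2L * ev - 1L]] <- jt[1L, ]
        junctions[[2L * ev]] <- jt[2L, ]
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf("no admissible site found for event %d (class %s)",
                      ev, kl))
      }
    }
    list(events = bind_rows(events), junctions = bind_rows(junctions))
  })
}

#' Simulate LAM-PCR junction reads
#'
#' Emits `per_event_depth` reads per event end. Each read starts at the
#' donor-side primer anchor, runs across the junction into chromosomal
#' sequence, and is truncated to `read_len`. Sequencing errors are i.i.d.
#' substitutions at `substitution_rate` (no indels).
#'
#' @param sim Result of [simulate_integrations()] (or its `junctions`
#'   tibble).
#' @param read_len Read length in bp (MiSeq-250 by default).
#' @param per_event_depth Reads per event end.
#' @param substitution_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Tibble with `read_id`, `sequence`, plus provenance columns
#'   `event_id` and `donor_end` (ignored by the caller; dropped on FASTQ
#'   export/import).
#' @export
simulate_reads <- function(sim, read_len = 250L, per_event_depth = 3L,
                           substitution_rate = 0, seed = 1L) {
  junctions <- if (is.data.frame(sim)) sim else sim$junctions
  stopifnot(all(c("donor_part", "genome_part") %in% names(junctions)),
            read_len >= 40L, per_event_depth >= 1L,
            substitution_rate >= 0, substitution_rate < 1)
  tmpl <- paste0(junctions$donor_part, junctions$genome_part)
  if (any(nchar(tmpl) < read_len)) {
    abort("junction template shorter than read_len; regenerate events with a larger flank_len")
  }
  base <- substr(tmpl, 1L, read_len)
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(junctions)), function(i) {
      reads <- vapply(seq_len(per_event_depth), function(k) {
        mutate_read(base[i], substitution_rate)
      }, character(1))
      tibble(
        read_id = sprintf("ev%04d_%s_r%02d", junctions$event_id[i],
                          sub("_prime", "", junctions$donor_end[i]),
                          seq_len(per_event_depth)),
        sequence = reads,
        event_id = junctions$event_id[i],
        donor_end = junctions$donor_end[i])
    })
    bind_rows(rows)
  })
}

# i.i.d. substitutions: each chosen base is replaced by one of the three
# other bases uniformly.
#' @keywords internal
mutate_read <- function(seq, rate) {
  if (rate == 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  alphabet <- c("A", "C", "G", "T")
  for (i in hit) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}
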