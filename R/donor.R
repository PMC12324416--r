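# Synthetic donor plasmid model.
#
# Layout of the modelled donor region (0-based, contiguous blocks):
#   backbone_left | tsd_left | tir5 | subterminal5 | cassette |
#   subterminal3 | tir3 | tsd_right | backbone_right
# The pble spans tir5..tir3; the TSD tetranucleotides flank the pble in the
# plasmid just as they would flank a chromosomal copy. The 5' TIR is the
# reverse complement of the 3' TIR, and both pble ends therefore read
# TSD+TIR start as TTAACCC, the boundary motif shared by piggyBac-family
# ends.

DONOR_TEMPLATES <- c("ifp2_like", "mer75_like", "mer75b_like",
                     "mer85_like", "looper_like", "plain")

# Per-template subterminal geometry: cross-end STIR arm offsets from the
# TIR inner ends (ifp2 values are the published piggyBac geometry; the
# human-pble templates reproduce the structure, not literal sequences) and
# which ends carry subterminal IRs.
stir_geometry <- function(template) {
  switch(template,
    ifp2_like   = list(offset5 = 3L,  offset3 = 31L, ends = c(TRUE, TRUE)),
    mer75_like  = list(offset5 = 5L,  offset3 = 25L, ends = c(TRUE, TRUE)),
    mer75b_like = list(offset5 = NA,  offset3 = 25L, ends = c(FALSE, TRUE)),
    mer85_like  = list(offset5 = 6L,  offset3 = 20L, ends = c(TRUE, TRUE)),
    looper_like = list(offset5 = 4L,  offset3 = 28L, ends = c(TRUE, TRUE)),
    plain       = list(offset5 = NA,  offset3 = NA,  ends = c(FALSE, FALSE))
  )
}

#' Build a synthetic donor construct
#'
#' Generates a donor plasmid region: 100-bp backbone flanks, TTAA target
#' site duplications, 13-bp terminal inverted repeats (the 5' TIR is the
#' reverse complement of the 3' TIR and both pble ends carry the TTAACCC
#' boundary motif), subterminal blocks, and a cassette. Templates other
#' than `"plain"` plant subterminal structure: a 19-bp cross-end
#' subterminal inverted-repeat (STIR) arm pair at template-specific offsets
#' from the TIR inner ends (3 and 31 bp for `"ifp2_like"`, the piggyBac
#' geometry) plus a short local palindrome inside each STIR-bearing block.
#' `"mer75b_like"` carries subterminal IRs at its 3' end only; `"plain"`
#' plants none. For planting templates the subterminal blocks are
#' resampled until a stringent IR scan (arm >= 7 bp, no mismatches) finds
#' no structure other than what was planted, so end asymmetry is
#' guaranteed by construction at those parameters. At the permissive
#' pal2gff-style defaults (arm >= 5, 1 mismatch) short chance IRs occur in
#' essentially any 60-bp sequence — exactly why genome-wide scans at those
#' parameters yield tens of millions of records — so asymmetry claims are
#' made at the stringent parameters.
#'
#' @param template One of `"ifp2_like"`, `"mer75_like"`, `"mer75b_like"`,
#'   `"mer85_like"`, `"looper_like"`, `"plain"`.
#' @param cassette_len Cassette length in bp (>= 200).
#' @param seed Integer seed; the construct is a pure function of its
#'   arguments.
#' @param tir_len TIR length in bp.
#' @param flank_len Backbone flank length in bp.
#' @param subterminal_len Length of each subterminal block in bp.
#' @param stir_arm_len STIR arm length in bp.
#' @return An object of class `donor_construct`: a list with elements
#'   `sequence` (character), `blocks` (tibble of block/start/end, 0-based
#'   half-open), `tsd_motif`, `template`, `tir_len`, `pble_start`,
#'   `pble_end`, `anchors` (named vector of LAM-PCR primer anchor
#'   positions, `five_prime`/`three_prime`), and `stir` (tibble describing
#'   the planted cross-end arm pair, empty when none was planted).
#' @export
make_donor <- function(template = DONOR_TEMPLATES, cassette_len = 600L,
                       seed = 1L, tir_len = 13L, flank_len = 100L,
                       subterminal_len = 60L, stir_arm_len = 19L) {
  template <- match.arg(template)
  stopifnot(cassette_len >= 200L, tir_len >= 7L, subterminal_len >= 60L,
            flank_len >= 20L)
  geo <- stir_geometry(template)
  parts <- withr::with_seed(seed, {
    tir5 <- paste0("CCC", random_dna(tir_len - 3L))
    subs <- build_subterminals(subterminal_len, geo, stir_arm_len)
    c(backbone_left = random_dna(flank_len),
      tsd_left = "TTAA", tir5 = tir5, subterminal5 = subs$sub5,
      cassette = random_dna(cassette_len), subterminal3 = subs$sub3,
      tir3 = revcomp(tir5), tsd_right = "TTAA",
      backbone_right = random_dna(flank_len))
  })
  lens <- nchar(parts)
  ends <- cumsum(lens)
  blocks <- tibble(block = names(parts),
                   start = as.integer(ends - lens), end = as.integer(ends))
  pble_start <- blocks$start[blocks$block == "tir5"]
  pble_end <- blocks$end[blocks$block == "tir3"]
  tir5_inner <- blocks$end[blocks$block == "tir5"]
  tir3_inner <- blocks$start[blocks$block == "tir3"]
  anchors <- c(five_prime = tir5_inner + 45L, three_prime = tir3_inner - 45L)
  stir <- if (all(geo$ends)) {
    tibble(arm_len = stir_arm_len,
           left_start = tir5_inner + geo$offset5,
           right_end = tir3_inner - geo$offset3,
           offset5 = geo$offset5, offset3 = geo$offset3)
  } else {
    tibble(arm_len = integer(), left_start = integer(),
           right_end = integer(), offset5 = integer(), offset3 = integer())
  }
  structure(list(sequence = paste(parts, collapse = ""), blocks = blocks,
                 tsd_motif = "TTAA", template = template, tir_len = tir_len,
                 pble_start = pble_start, pble_end = pble_end,
                 anchors = anchors, stir = stir),
            class = "donor_construct")
}

# Subterminal blocks with planted STIR arms and local palindromes.
# Draws arm + backgrounds jointly and retries until the default IR scan of
# each block reports exactly the planted palindromes (and nothing else), so
# planted structure is the only within-block structure. "plain" blocks are
# plain background.
#' @keywords internal
build_subterminals <- function(len, geo, stir_arm_len, max_tries = 500L) {
  if (!any(geo$ends)) {
    return(list(sub5 = random_dna(len), sub3 = random_dna(len)))
  }
  pal_at5 <- 33L
  pal_at3 <- 40L
  for (try in seq_len(max_tries)) {
    arm <- random_dna(stir_arm_len)
    build_block <- function(arm_at, arm_seq, pal_at) {
      pal_arm <- random_dna(7L)
      pal <- paste0(pal_arm, random_dna(4L), revcomp(pal_arm))
      s <- strsplit(random_dna(len), "", fixed = TRUE)[[1]]
      if (!is.null(arm_seq)) {
        s[arm_at + seq_len(nchar(arm_seq))] <-
          strsplit(arm_seq, "", fixed = TRUE)[[1]]
      }
      s[pal_at + seq_len(18L)] <- strsplit(pal, "", fixed = TRUE)[[1]]
      list(seq = paste(s, collapse = ""), pal_span = c(pal_at, pal_at + 18L))
    }
    strict_scan <- function(s) {
      find_inverted_repeats(s, min_arm = 7L, max_arm = 15L,
                            min_spacer = 2L, max_spacer = 10L,
                            max_mismatch = 0L)
    }
    block_clean <- function(b) {
      ir <- strict_scan(b$seq)
      inside <- ir$left_start >= b$pal_span[1] & ir$right_end <= b$pal_span[2]
      all(inside) && nrow(ir) >= 1L
    }
    if (geo$ends[1]) {
      b5 <- build_block(geo$offset5, arm, pal_at5)
      if (!block_clean(b5)) next
      sub5 <- b5$seq
    } else {
      sub5 <- random_dna(len)
      if (nrow(strict_scan(sub5)) > 0L) next
    }
    arm3 <- if (geo$ends[1]) revcomp(arm) else arm
    b3 <- build_block(len - geo$offset3 - stir_arm_len, arm3, pal_at3)
    if (!block_clean(b3)) next
    return(list(sub5 = sub5, sub3 = b3$seq))
  }
  abort("could not build IR-clean subterminal blocks")
}

#' @export
print.donor_construct <- function(x, ...) {
  cat(sprintf("<donor_construct> template=%s, %d bp\n", x$template,
              nchar(x$sequence)))
  cat(sprintf("  pble [%d, %d), TIR %d bp, TSD %s\n", x$pble_start,
              x$pble_end, x$tir_len, x$tsd_motif))
  print(x$blocks)
  invisible(x)
}

#' Validate donor construct invariants
#'
#' Checks block contiguity, the terminal-inverted-repeat property (the 5'
#' TIR equals the reverse complement of the 3' TIR) and the TSD
#' tetranucleotides flanking the pble.
#'
#' @param donor A `donor_construct`.
#' @return `donor`, invisibly; errors if an invariant is violated.
#' @export
validate_donor <- function(donor) {
  stopifnot(inherits(donor, "donor_construct"))
  b <- donor$blocks
  if (!all(b$start[-1] == b$end[-nrow(b)]) || b$start[1] != 0L ||
      b$end[nrow(b)] != nchar(donor$sequence)) {
    abort("donor blocks are not contiguous")
  }
  if (donor_block_seq(donor, "tir5") != revcomp(donor_block_seq(donor, "tir3"))) {
    abort("5' TIR is not the reverse complement of the 3' TIR")
  }
  if (donor_block_seq(donor, "tsd_left") != donor$tsd_motif ||
      donor_block_seq(donor, "tsd_right") != donor$tsd_motif) {
    abort("TSD motifs do not flank the pble")
  }
  invisible(donor)
}

#' Sequence of one donor block
#'
#' @param donor A `donor_construct`.
#' @param block Block name as in `donor$blocks`.
#' @return The block's nucleotide string.
#' @export
donor_block_seq <- function(donor, block) {
  b <- donor$blocks
  i <- which(b$block == block)
  if (!length(i)) abort(sprintf("no block '%s'", block))
  substr(donor$sequence, b$start[i] + 1L, b$end[i])
}
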