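#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over the alphabet A/C/G/T/N. `N` maps to
#' `N`; any other character is an error (ambiguity codes are rejected rather
#' than silently mapped).
#'
#' @param seq Character vector of nucleotide strings (may include `""`).
#' @return Character vector of the same length.
#' @examples
#' revcomp("ACGTA")
#' revcomp(c("TTAA", "N", ""))
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  check_dna_alphabet(seq)
  out <- chartr("ACGTN", "TGCAN", seq)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @keywords internal
check_dna_alphabet <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside the A/C/G/T/N alphabet", what
    ))
  }
  invisible(seq)
}

#' Random nucleotide sequence with a given GC fraction
#'
#' i.i.d. background model used by the synthetic-data generators. Draws from
#' the current RNG state; wrap in [withr::with_seed()] (or pass `seed` to the
#' generator that calls it) for reproducibility.
#'
#' @param n Length in bp.
#' @param gc_fraction Expected G+C fraction, split evenly between G and C.
#' @return A single nucleotide string.
#' @export
random_dna <- function(n, gc_fraction = 0.41) {
  stopifnot(n >= 0, gc_fraction >= 0, gc_fraction <= 1)
  if (n == 0) return("")
  at <- (1 - gc_fraction) / 2
  gc <- gc_fraction / 2
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at, gc, gc, at)), collapse = "")
}

# Positions (1-based starts) of all exact occurrences of `pattern` in
# `subject`, overlapping allowed. Used by the junction caller for anchors.
#' @keywords internal
find_all_exact <- function(subject, pattern) {
  if (nchar(pattern) == 0 || nchar(pattern) > nchar(subject)) return(integer(0))
  hits <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (m == -1L) break
    pos <- from + as.integer(m) - 1L
    hits <- c(hits, pos)
    from <- pos + 1L  # step by 1 so overlapping occurrences are found
  }
  hits
}

# Length of the longest common prefix of x and y (plain strings).
#' @keywords internal
common_prefix_len <- function(x, y) {
  nmax <- min(nchar(x), nchar(y))
  if (nmax == 0L) return(0L)
  # binary search: prefix equality is monotone in length
  lo <- 0L; hi <- nmax
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (substr(x, 1L, mid) == substr(y, 1L, mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}
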