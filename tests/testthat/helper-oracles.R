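# Independent brute-force oracles used to check the package's scanners and
# counters. These deliberately share no code with the implementations: plain
# nested loops over every candidate, then the same reporting rules applied
# on top.

# Exhaustive inverted-repeat enumeration: every (left start, arm, spacer)
# triple, Hamming condition on left arm vs reverse complement of right arm,
# N matches nothing.
oracle_find_ir <- function(seq, min_arm = 5L, max_arm = 15L,
                           min_spacer = 2L, max_spacer = 10L,
                           max_mismatch = 1L, mismatch_min_arm = 6L,
                           maximal = TRUE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  L <- length(chars)
  rows <- list()
  for (i in seq_len(L)) {
    for (a in min_arm:max_arm) {
      for (s in min_spacer:max_spacer) {
        if (i + 2L * a + s - 1L > L) next
        left <- chars[i:(i + a - 1L)]
        right <- chars[(i + a + s):(i + 2L * a + s - 1L)]
        rc_right <- rev(unname(comp_map[right]))
        mism <- sum(left != rc_right | left == "N")
        allowed <- if (a < mismatch_min_arm) 0L else max_mismatch
        if (mism <= allowed) {
          rows[[length(rows) + 1L]] <-
            data.frame(left_start = i - 1L, arm_len = a, spacer_len = s,
                       mismatches = mism)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(left_start = integer(), arm_len = integer(),
               spacer_len = integer(), mismatches = integer())
  if (maximal && nrow(out)) {
    keep <- logical(nrow(out))
    for (grp in split(seq_len(nrow(out)),
                      paste(out$left_start, out$spacer_len))) {
      keep[grp[which.max(out$arm_len[grp])]] <- TRUE
    }
    out <- out[keep, ]
  }
  out <- out[order(out$left_start, out$arm_len, out$spacer_len), ]
  rownames(out) <- NULL
  out
}

# Greedy non-overlapping motif count by explicit walking.
oracle_count_motif <- function(seq, motif) {
  n <- 0L
  i <- 1L
  w <- nchar(motif)
  while (i + w - 1L <= nchar(seq)) {
    if (substr(seq, i, i + w - 1L) == motif) {
      n <- n + 1L
      i <- i + w
    } else {
      i <- i + 1L
    }
  }
  n
}

# Quadratic overlap check: how many query intervals overlap >= 1 bp with
# any annotation.
oracle_count_overlapping <- function(query, annotations) {
  hit <- vapply(seq_len(nrow(query)), function(i) {
    any(annotations$contig == query$contig[i] &
          annotations$start < query$end[i] &
          query$start[i] < annotations$end)
  }, logical(1))
  sum(hit)
}

# Comparable subset of IR columns for oracle equivalence checks.
ir_key <- function(df) {
  k <- as.data.frame(df[, c("left_start", "arm_len", "spacer_len",
                            "mismatches")])
  k <- k[order(k$left_start, k$arm_len, k$spacer_len), , drop = FALSE]
  rownames(k) <- NULL
  k
}

random_seq_fixture <- function(n, len, seed, gc = 0.5) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) random_dna(len, gc), character(1))
  })
}
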