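# Synthetic genome generator: i.i.d. background with planted features and
# an exact truth table.

#' Generate a synthetic genome with planted features
#'
#' Background is i.i.d. nucleotides at the requested GC fraction; planted
#' features overwrite the background at non-overlapping positions chosen
#' uniformly at random (bounded rejection sampling). Supported feature
#' kinds mirror the repeat classes relevant to pble biology:
#'
#' * `ttaa_sites` — `TTAA` tetranucleotide insertion targets,
#' * `tggaa_arrays` — `(TGGAA)n` tandem arrays (satellite-DNA-III-like);
#'   `copies` per array,
#' * `ssr_runs` — simple-sequence-repeat runs; `unit` and `copies`,
#' * `ir_pairs` — inverted-repeat arm pairs `arm + spacer + revcomp(arm)`;
#'   `arm_len` and `spacer_len`,
#' * `pble_copies` — the pble region (TIR to TIR) of a donor construct;
#'   `template` selects the donor template.
#'
#' @param lengths Named integer vector of contig lengths (>= 500 bp each);
#'   names become contig names (defaults `chr1`, `chr2`, ...).
#' @param gc_fraction Background G+C fraction.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param planted Named list, e.g. `list(tggaa_arrays = list(n = 2, copies
#'   = 50), ir_pairs = list(n = 10, arm_len = 10, spacer_len = 5))`. Each
#'   element needs `n` (number of features, spread over contigs at random)
#'   plus the kind-specific parameters above.
#' @param max_tries Placement retries per feature before failing.
#' @return A list with `genome` (a [Biostrings::DNAStringSet]) and `truth`
#'   (interval tibble; `name` holds the feature kind, `score` the copy
#'   number for runs/arrays and the arm length for IR pairs).
#' @export
make_genome <- function(lengths = c(chr1 = 10000L), gc_fraction = 0.41,
                        seed = 1L, planted = list(), max_tries = 1000L) {
  stopifnot(all(lengths >= 500L))
  if (is.null(names(lengths))) {
    names(lengths) <- paste0("chr", seq_along(lengths))
  }
  known <- c("ttaa_sites", "tggaa_arrays", "ssr_runs", "ir_pairs",
             "pble_copies")
  if (!all(names(planted) %in% known)) {
    abort(sprintf("unknown planted feature kind; use one of: %s",
                  paste(known, collapse = ", ")))
  }
  withr::with_seed(seed, {
    contigs <- lapply(lengths, function(L)
      strsplit(random_dna(L, gc_fraction), "", fixed = TRUE)[[1]])
    occupied <- lapply(lengths, function(L) logical(L))
    truth <- list()
    for (kind in names(planted)) {
      spec <- planted[[kind]]
      n <- spec$n %||% 1L
      for (i in seq_len(n)) {
        feat <- switch(kind,
          ttaa_sites = "TTAA",
          tggaa_arrays = strrep("TGGAA", spec$copies %||% 50L),
          ssr_runs = strrep(spec$unit %||% "CA", spec$copies %||% 30L),
          ir_pairs = {
            arm <- random_dna(spec$arm_len %||% 10L, gc_fraction)
            paste0(arm, random_dna(spec$spacer_len %||% 5L, gc_fraction),
                   revcomp(arm))
          },
          pble_copies = {
            d <- make_donor(spec$template %||% "ifp2_like",
                            seed = sample.int(.Machine$integer.max, 1L))
            substr(d$sequence, d$pble_start + 1L, d$pble_end)
          })
        w <- nchar(feat)
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          ci <- sample(length(lengths), 1L)
          L <- lengths[[ci]]
          if (L < w) next
          at <- sample.int(L - w + 1L, 1L) - 1L      # 0-based start
          idx <- at + seq_len(w)
          if (any(occupied[[ci]][idx])) next
          contigs[[ci]][idx] <- strsplit(feat, "", fixed = TRUE)[[1]]
          occupied[[ci]][idx] <- TRUE
          score <- switch(kind,
            tggaa_arrays = spec$copies %||% 50L,
            ssr_runs = spec$copies %||% 30L,
            ir_pairs = spec$arm_len %||% 10L,
            NA_real_)
          truth[[length(truth) + 1L]] <-
            tibble(contig = names(lengths)[ci], start = at,
                   end = at + w, name = kind, score = as.numeric(score),
                   strand = ".")
          placed <- TRUE
          break
        }
        if (!placed) {
          abort(sprintf(
            "could not place a %d-bp %s feature after %d tries",
            w, kind, max_tries))
        }
      }
    }
    genome <- Biostrings::DNAStringSet(
      vapply(contigs, paste, character(1), collapse = ""))
    names(genome) <- names(lengths)
    truth <- if (length(truth)) {
      bind_rows(truth) %>% arrange(.data$contig, .data$start)
    } else {
      intervals(character(), integer(), integer())[0, ]
    }
    list(genome = genome, truth = truth)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
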