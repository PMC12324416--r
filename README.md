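# pbletools

Toolkit for analysing the genomic integration behaviour of
**piggyBac-like elements (pbles)** — the cut-and-paste DNA transposon
family that inserts at TTAA tetranucleotides, duplicating them on both
flanks, and whose domesticated transposases (PGBD5 in particular)
mobilise cassettes flanked by pble ends. It is aimed at researchers
analysing LAM-PCR junction libraries and ChIP-seq peak/repeat overlap in
transposon-biology studies.

The package implements three analysis procedures plus a fully
ground-truthed synthetic-data generator:

* **Junction pipeline** — calls chromosome–donor breakpoint pairs from
  junction reads with an exact-seed split aligner (longest exact donor
  prefix + longest exact genome suffix, either strand), deduplicates
  them into unique junctions with a strict spread filter (consensus
  donor breakpoint vs. read alignment extents, difference < 3 bp), and
  classifies every unique junction into the 2×2 signature

  | | proper TIR | improper TIR |
  |---|---|---|
  | **TSD = TTAA** | proper TSD and TIR | proper TSD / improper TIR |
  | **TSD ≠ TTAA** | improper TSD / proper TIR | improper TSD and TIR |

  where *proper TIR* means the donor breakpoint sits byte-exactly at a
  terminal-inverted-repeat outer terminus (no truncation, no plasmid
  backbone carryover). Summaries report per-class counts and
  percentages, the uniform random-placement baseline
  (`100·4/window_len` %) and the observed/expected fold.
* **Inverted-repeat annotator** — exhaustive scan for pble-like IRs
  (arm 5–15 bp, spacer 2–10 bp, 0 mismatches for 5-bp arms, up to 1
  from 6 bp; N matches nothing), greedy non-overlapping motif census
  (e.g. TTAACCC, single- or double-stranded), maximal tandem-unit runs
  (e.g. the centromeric satellite unit (TGGAA)n), and donor-end
  annotation that recovers subterminal IR (STIR) arm pairs — 19 bp at
  offsets 3 and 31 from the TIR inner ends in piggyBac-type donors.
* **Overlap statistics** — exclusion-list filtering, overlap counting,
  and a permutation test that shuffles the peak set with
  length-preserving, chromosome-preserving, non-overlapping random
  placements and reports `z = (obs − mean)/sd` with a normal-tail
  probability (plus the empirical permutation p).

Everything tabular flows through tibbles and pipes; permutation results
have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate 100 integration events at the class mixture observed for a
MER75 donor, recover and classify the junctions, and test peak/repeat
overlap:

```r
library(pbletools)
library(dplyr)

donor  <- make_donor("ifp2_like", seed = 1)
genome <- make_genome(c(chr1 = 50000L, chr2 = 50000L), seed = 2)
sim    <- simulate_integrations(genome$genome, donor, n = 100,
                                class_mixture = c(0.112, 0.016, 0.039, 0.833),
                                seed = 3)
reads  <- simulate_reads(sim, per_event_depth = 3, seed = 4)

junctions <- reads[, c("read_id", "sequence")] |>
  call_junctions(genome$genome, donor) |>
  dedupe_and_filter() |>
  classify_junctions(donor, genome$genome)

summarize_junction_classes(junctions)
#> # A tibble: 4 × 3
#>   klass                   count   pct
#>   <chr>                   <dbl> <dbl>
#> 1 proper_tsd_tir             22    11
#> 2 proper_tsd_improper_tir     2     1
#> 3 improper_tsd_proper_tir     4     2
#> 4 improper_both             172    86
```

All 200 planted junctions (two ends per event) are recovered; 11% carry
the clean transposition signature (TTAA target-site duplication and
byte-exact TIR terminus), matching the planted 11.2% mixture, and
`fold_over_random(11, 3.1)` reports a 3.5-fold excess over a 3.1%
random-placement baseline. The donor's planted 19-bp STIR arm pair is
recovered at its canonical geometry:

```r
annotate_donor_ends(donor, max_arm = 19) |>
  filter(scope == "cross_end", arm_len == 19, mismatches == 0)
#>   contig left_start left_end right_start right_end arm_len ... offset5 offset3
#> 1 donor         120      139         787       806      19 ...       3      31
```

and a peak set with 30% planted annotation overlap is called enriched:

```r
gl <- c(chr1 = 500000L, chr2 = 500000L)
ds <- make_interval_sets(gl, n_peaks = 100, enrichment_fraction = 0.3, seed = 5)
permutation_test(ds$peaks, ds$annotations, gl, n_perm = 1000, seed = 6) |> tidy()
#>   observed null_mean null_sd     z  p_value p_empirical tail    n_perm
#> 1       30      3.85    1.89  13.9 4.67e-44    0.000999 greater   1000
```

Thirty of 100 peaks overlap an annotation, against 3.85 ± 1.89 expected
under random placement.

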