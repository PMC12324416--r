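---
title: "Junction signatures, inverted repeats and overlap statistics for piggyBac-like elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction signatures, inverted repeats and overlap statistics for piggyBac-like elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbletools)
library(dplyr)
```

## The biology in brief

piggyBac-like elements (pbles) are cut-and-paste DNA transposons that
insert at the tetranucleotide TTAA, duplicating it on both flanks (the
target-site duplication, TSD). Each element is bounded by ~13-bp terminal
inverted repeats (TIRs): the 5' TIR is the reverse complement of the 3'
TIR, and in the piggyBac family both element ends read `TTAACCC` across
the TSD/TIR boundary. Just inside the TIRs, many pbles carry subterminal
inverted repeats (STIRs): in piggyBac itself these are 19 bp long and sit
3 bp and 31 bp inside the 5' and 3' TIR inner ends. Domesticated piggyBac
transposases (PGBD5 in particular) mobilise cassettes flanked by pble
ends, but most recovered chromosome-donor junctions do not show the clean
transposition signature, which motivates the three procedures this
package implements:

1. a **junction pipeline** that calls chromosome-donor breakpoint pairs
   from LAM-PCR style junction reads, deduplicates them, and classifies
   each unique junction into the 2x2 signature *proper/improper TSD* x
   *proper/improper TIR*;
2. an **inverted-repeat annotator** that scans sequence for pble-like IRs
   (arm 5-15 bp, spacer 2-10 bp, 0 mismatches for 5-bp arms and up to 1
   for arms of 6 bp or more), counts exact non-overlapping motifs, and
   annotates tandem-unit runs such as `(TGGAA)n`;
3. **overlap statistics** that score the co-occurrence of peak intervals
   with repeat annotations against a null of chromosome-preserving,
   length-preserving, non-overlapping random placement, summarised as a Z
   score with a normal-tail probability.

A synthetic-data generator produces genomes, donor constructs,
integration events, reads and interval sets with exact ground truth, so
every stage is testable without external data.

## The donor model

`make_donor()` builds the region of a donor plasmid that matters for
junction analysis, as contiguous blocks:

```
backbone_left(100) | TTAA | TIR5(13) | subterminal5(60) | cassette |
subterminal3(60) | TIR3(13) | TTAA | backbone_right(100)
```

Defaults (100-bp backbone flanks, 13-bp TIRs, TTAA TSD) are the geometry
of the assayed constructs; all are arguments. The TIR pair is generated
once and reverse-complemented, and starts with `CCC` so both ends carry
the family's `TTAACCC` boundary motif. Templates `ifp2_like`,
`mer75_like`, `mer85_like` and `looper_like` plant a 19-bp cross-end STIR
arm pair (the two arms are reverse complements, one per subterminal
block) at template-specific offsets from the TIR inner ends — 3 and 31 bp
for `ifp2_like`, the published piggyBac geometry — plus one short local
palindrome per STIR-bearing block; `mer75b_like` carries subterminal
structure only at its 3' end, mirroring the reported asymmetry of MER75B;
`plain` plants nothing. The human-pble end sequences themselves are not
modelled: the templates reproduce the *structure* of the reported ends,
not literal sequences, and anything keyed to literal sequence content is
out of scope.

One numerical subtlety: at the permissive pble-like scan parameters,
short chance IRs occur in essentially any 60-bp sequence (which is why a
genome-wide scan yields tens of millions of records). Donor templates
that plant subterminal structure therefore resample their block
backgrounds until a *stringent* scan (arm >= 7, 0 mismatches) finds
nothing but the planted palindromes. End asymmetry claims (e.g. "IRs at
exactly one end" for `mer75b_like`) are made at those stringent
parameters.

## The integration and read model

`simulate_integrations()` draws event classes from a four-way mixture
(the class vector is the first random draw under the seed, so class
counts can be validated against an independent multinomial draw), then
places each event:

* **proper TSD** classes insert at a TTAA occurrence with the
  tetranucleotide duplicated on both flanks; **improper TSD** classes
  insert at a position whose flanking tetranucleotides are not TTAA,
  without duplication.
* **improper TIR** classes either truncate the pble's outer ends
  (default 1-10 bp) or retain plasmid backbone (default 5-40 bp) — one
  mechanism per event (XOR), the same amount at both ends, so the truth
  class of the event equals the per-junction class at both ends.
* events may insert in either orientation; the two ends are emitted as
  separate junction templates, mirroring the two independent LAM-PCR
  reactions (one per transposon end), and are never paired in a read.

Reads (`simulate_reads()`) start at a donor-side primer anchor placed 45
bp inside each subterminal block, run across the junction into
chromosomal sequence, and are truncated to 250 nt (MiSeq-250). Errors
are i.i.d. substitutions only; indel robustness is a non-goal, keeping
the exact-seed caller's assumptions honest. The background genome is
i.i.d. with a specified GC fraction (default 0.41, human-like); planted
features override the background. This emulates the statistical
structure the analysis relies on (TTAA density, unique flanks) but not
real genomic repeat structure, so passing tests demonstrate correctness
of the logic, not performance on repetitive genomic DNA.

### Breakpoint identifiability

At a proper junction the TSD is micro-homologous between donor and
target: the donor plasmid carries `TTAA` immediately outside the TIR and
the chromosome carries the duplicated `TTAA` at the junction, so several
exact splits explain the same error-free read. The caller resolves the
admissible split window with a deterministic rule: **snap to a TIR outer
terminus when one lies in the window, otherwise assign the ambiguous
bases to the genome side**. For proper junctions the terminus is always
in the window, so they resolve exactly; for improper junctions chance
micro-homology between the wounded donor end and the target flank
(probability ~1/4 per boundary base) can make the true split formally
unidentifiable from any read. The simulator rejects such sites and
redraws — these events are intrinsically ambiguous in the assay itself,
not a caller weakness — and documents the remaining guarantee: on
identifiable sites, error-free reads recover the planted breakpoint
pairs and classes exactly.

### The spread filter

Unique junctions are keyed by (contig, chromosome breakpoint, genome
strand, donor end); two calls 1 bp apart are distinct junctions (no
fuzzing), and the consensus donor breakpoint is the modal value among
supporting reads. A junction is retained iff the largest absolute
difference between the consensus donor breakpoint and any supporting
read's resolved donor-side alignment extent is **strictly below** 3 bp
(`max_spread_diff = 3`). The extent is taken after split resolution;
taking the raw maximal donor-side match instead would count the TSD
micro-homology overrun (4 bp at every proper junction) as disagreement
and discard precisely the cleanest junctions.

### Classification and summaries

Proper TIR requires the donor breakpoint byte-exactly at the TIR outer
terminus (a 1-bp slip is improper); proper TSD requires the
target tetranucleotide to equal TTAA, judged from the single junction
side visible to LAM-PCR and oriented so a canonical insertion reads TTAA
in either orientation; any non-TTAA tetranucleotide counts as improper.
Donor breakpoints inside the cassette are `unclassified` and excluded
from the four-way summary. `summarize_junction_classes()` reports counts
and percentages rounded to one decimal, and accepts published count
vectors directly so printed tables can be re-derived;
`expected_random_fraction(window_len, 4)` gives the uniform-placement
baseline (the window length depends on unpublished primer positions and
is therefore an input, not a constant), and `fold_over_random()` the
observed/expected ratio at one decimal.

## The IR scanner

`find_inverted_repeats()` reports arm pairs `left + spacer + right` with
`left` equal to the reverse complement of `right` up to a Hamming budget:
0 mismatches below `mismatch_min_arm` (default 6) and `max_mismatch`
(default 1) above it, arms 5-15 bp, spacers 2-10 bp. `N` matches nothing,
including `N`. By default, for each (left start, spacer) locus only the
longest admissible arm is reported; shorter arms nested at the same locus
are suppressed. The exhaustive enumeration is available via
`all_pairs = TRUE` and is what the brute-force oracle tests compare
against (the two modes are checked to agree with an independent
nested-loop enumeration on random sequences). Whether the published
genome-wide annotation used maximal or exhaustive reporting is not
stated, so reproducing its record count is not a target.

Motif counting is a greedy left-to-right scan (after a match at *i* the
scan resumes at *i* + motif length); with `both_strands = TRUE` the
reverse-complement motif is counted in a second independent scan and the
two counts are summed, ties resolved leftmost-first. Tandem-run
annotation reports maximal runs of at least `min_copies` exact
head-to-tail unit copies; a run cannot be extended by a full unit on
either side, and phase-shifted runs overlapping a reported run are
suppressed.

## The permutation test

`permutation_test()` shuffles the *query* set (annotations held fixed —
the choice is recorded in the result object), preserving each interval's
length and contig and requiring mutual non-overlap (rejection sampling
with a capped retry count; exceeding the cap is an error, never a silent
overlap). The observed overlap count is compared to the shuffled null via
`z = (observed - mean) / sd` and a normal-tail probability (default tail:
enrichment), as in Z-score-based permutation reporting; the empirical
permutation rank p-value is also returned for comparison. When the null
is degenerate (`sd = 0`, e.g. annotations covering a whole contig) `z`
and `p` are `NA` rather than infinite. The permutation loop uses a
vectorised placement/counting path on plain integer vectors (building
range objects per shuffle is orders of magnitude too slow for 10,000
shuffles); this fast path is cross-checked against the IRanges-based
`count_overlapping()` and a quadratic brute force in the tests.

`make_interval_sets()` plants exactly `ceiling(f * n)` overlapping peaks.
Its background mode matters for calibration: `"avoid"` keeps background
peaks off the annotations so the planted overlap count is exact, but such
datasets are *depleted*, not null — the null of the permutation test is
uniform placement, so type-I calibration uses `background = "uniform"`.
With 100 peaks of 300 bp and fifty 500-bp annotations on two 500-kb
contigs (5% occupancy, null mean overlap ~10), 500 null datasets at 1000
shuffles give an empirical type-I rate within [0.03, 0.08] at alpha =
0.05, and 90% planted enrichment is detected in >= 95% of replicates;
these problem sizes are the package's standard calibration conditions
and are what the tests and `scripts/acceptance.R` run.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; GFF3 (1-based closed) is
  converted at the I/O boundary. IUPAC ambiguity codes other than N are
  rejected on input rather than silently mapped.
* The caller requires `min_seed` = 20 exactly matching bases on each side
  of a split and allows 2 bp of unassigned slack between prefix and
  suffix; reads failing this are counted, not silently dropped. Reads
  whose best donor or genome match ties at several loci are flagged
  ambiguous and excluded from deduplication.
* Percentages are rounded to one decimal at the reporting boundary only;
  a class row always sums to 100 +/- 0.1 after rounding.
* Generators are pure functions of their seed and parameters
  (byte-identical reruns); infeasible placements (features that do not
  fit, interval sets too dense to shuffle without overlap) raise errors
  after bounded retries.

## Known limitations

* The caller is an exact-seed split aligner valid for the
  substitution-only error model; it is not a general-purpose aligner and
  real LAM-PCR data (adapter chemistry, indels, PCR duplicates,
  repetitive targets) is out of scope.
* The synthetic genome has no repeat structure beyond what is planted;
  ambiguity handling is exercised only lightly.
* Shuffles place intervals over full contig lengths; gap- or
  GC-aware shuffling models are not implemented.
* Donor templates reproduce end architecture, not literal pble
  sequences.
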