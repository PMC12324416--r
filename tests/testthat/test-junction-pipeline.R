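# A small shared scenario keeps the pipeline tests fast.
local_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- make_donor("ifp2_like", seed = 2)
      g <- make_genome(c(chr1 = 50000L, chr2 = 50000L), seed = 3)
      sim <- simulate_integrations(g$genome, d, n = 50,
                                   class_mixture = c(0.3, 0.2, 0.2, 0.3),
                                   seed = 11)
      cache <<- list(d = d, g = g, sim = sim)
    }
    cache
  }
})

test_that("an error-free read across a proper junction splits exactly at the
          TIR terminus and insertion base", {
  sc <- local_scenario()
  prop <- sc$sim$junctions[sc$sim$junctions$true_class == "proper_tsd_tir", ]
  j <- prop[1, ]
  read <- substr(paste0(j$donor_part, j$genome_part), 1, 250)
  calls <- call_junctions(tibble::tibble(read_id = "r", sequence = read),
                          sc$g$genome, sc$d)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$donor_bp,
               if (j$donor_end == "five_prime") sc$d$pble_start
               else sc$d$pble_end)
  expect_equal(calls$contig, j$contig)
  expect_equal(calls$chrom_bp, j$chrom_bp)
  expect_equal(calls$genome_strand, j$genome_strand)
})

test_that("vector-internal reads are discarded at stage 1", {
  sc <- local_scenario()
  cass <- donor_block_seq(sc$d, "cassette")
  inside <- substr(cass, 11, 260)        # read fully within the cassette
  bb <- substr(sc$d$sequence, 1, 250)    # read within backbone + pble start
  calls <- call_junctions(
    tibble::tibble(read_id = c("cassette", "backbone"),
                   sequence = c(inside, bb)),
    sc$g$genome, sc$d)
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "n_internal"), 2L)
})

test_that("reads matching neither donor prefix nor genome suffix are dropped", {
  sc <- local_scenario()
  random_read <- withr::with_seed(1, random_dna(250))
  calls <- call_junctions(
    tibble::tibble(read_id = "noise", sequence = random_read),
    sc$g$genome, sc$d)
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "n_unsplit"), 1L)
})

test_that("duplicate reads collapse to one junction with summed support", {
  sc <- local_scenario()
  reads <- simulate_reads(sc$sim$junctions[1:2, ], per_event_depth = 5,
                          seed = 31)
  calls <- call_junctions(reads[, c("read_id", "sequence")],
                          sc$g$genome, sc$d)
  uniq <- dedupe_and_filter(calls)
  expect_equal(nrow(uniq), 2L)
  expect_equal(sort(uniq$support), c(5L, 5L))
  expect_true(all(uniq$spread == 0L))
})

test_that("the spread filter is strict: difference 3 removed, 2 retained", {
  base <- tibble::tibble(
    read_id = sprintf("r%d", 1:6),
    contig = "chr1", chrom_bp = rep(c(100L, 900L), each = 3),
    genome_strand = "+", donor_end = "three_prime",
    donor_bp = rep(c(500L, 700L), each = 3),
    donor_extent = c(500L, 500L, 503L,    # max |extent - bp| = 3 -> removed
                     700L, 700L, 702L),   # max |extent - bp| = 2 -> retained
    prefix_len = 100L, suffix_len = 150L, ambiguous = FALSE)
  uniq <- dedupe_and_filter(base, max_spread_diff = 3L)
  expect_equal(nrow(uniq), 1L)
  expect_equal(uniq$chrom_bp, 900L)
  expect_equal(uniq$spread_diff, 2L)
  expect_equal(attr(uniq, "n_spread_filtered"), 1L)
})

test_that("flank extraction returns 10-bp flanks, TSD call, clipping flag", {
  genome <- c(c1 = paste0(strrep("G", 26), "TTAA", strrep("C", 20)))
  # breakpoint just after the TTAA, chromosome retained upstream
  fl <- extract_flanks(genome, "c1", 30L, genome_strand = "-")
  expect_equal(nchar(fl$flank_up), 10L)
  expect_equal(substr(fl$flank_up, 7, 10), "TTAA")
  expect_equal(fl$tsd_call, "TTAA")
  expect_false(fl$clipped)
  # downstream-retained junction at the TTAA start
  fl2 <- extract_flanks(genome, "c1", 26L, genome_strand = "+")
  expect_equal(fl2$tsd_call, "TTAA")
  # near the contig edge flanks are shortened and flagged
  fl3 <- extract_flanks(genome, "c1", 5L, genome_strand = "+")
  expect_equal(nchar(fl3$flank_up), 5L)
  expect_true(fl3$clipped)
})

test_that("classification implements the 2x2 TSD/TIR signature", {
  sc <- local_scenario()
  d <- sc$d
  mk <- function(donor_bp, donor_end, tsd_site_seq) {
    genome <- c(c1 = paste0(strrep("G", 300), tsd_site_seq, strrep("C", 300)))
    j <- tibble::tibble(contig = "c1", chrom_bp = 304L,
                        genome_strand = "-", donor_end = donor_end,
                        donor_bp = donor_bp, support = 1L, spread = 0L,
                        spread_diff = 0L)
    classify_junctions(j, d, genome)$klass
  }
  expect_equal(mk(d$pble_start, "five_prime", "TTAA"), "proper_tsd_tir")
  expect_equal(mk(d$pble_start - 12L, "five_prime", "TTAA"),
               "proper_tsd_improper_tir")   # 12 bp backbone carryover
  expect_equal(mk(d$pble_start + 1L, "five_prime", "TTAA"),
               "proper_tsd_improper_tir")   # 1-bp slip is improper
  expect_equal(mk(d$pble_start, "five_prime", "TGCA"),
               "improper_tsd_proper_tir")
  expect_equal(mk(d$pble_start + 5L, "five_prime", "TGCA"), "improper_both")
  # cassette breakpoints are excluded from the four-way classification
  cass <- d$blocks[d$blocks$block == "cassette", ]
  expect_equal(mk(cass$start + 50L, "five_prime", "TTAA"), "unclassified")
})

test_that("end-to-end: error-free reads reproduce the planted truth exactly", {
  sc <- local_scenario()
  reads <- simulate_reads(sc$sim, per_event_depth = 3, seed = 41)
  calls <- call_junctions(reads[, c("read_id", "sequence")],
                          sc$g$genome, sc$d)
  uniq <- dedupe_and_filter(calls)
  cl <- classify_junctions(uniq, sc$d, sc$g$genome)
  expect_equal(nrow(cl), nrow(sc$sim$junctions))
  j <- dplyr::inner_join(
    cl, sc$sim$junctions,
    by = c("contig", "chrom_bp", "genome_strand", "donor_end"),
    suffix = c("", ".truth"))
  expect_equal(nrow(j), nrow(sc$sim$junctions))
  expect_true(all(j$donor_bp == j$donor_bp.truth))
  expect_true(all(j$klass == j$true_class))
  expect_true(all(j$support == 3L))
})

test_that("most events survive and classify correctly at a realistic
          substitution rate", {
  d <- make_donor("ifp2_like", seed = 2)
  g <- make_genome(c(chr1 = 50000L, chr2 = 50000L), seed = 5)
  sim <- simulate_integrations(g$genome, d, n = 60,
                               class_mixture = c(0.25, 0.25, 0.25, 0.25),
                               seed = 43)
  reads <- simulate_reads(sim, per_event_depth = 8,
                          substitution_rate = 0.005, seed = 47)
  calls <- call_junctions(reads[, c("read_id", "sequence")], g$genome, d)
  cl <- classify_junctions(dedupe_and_filter(calls), d, g$genome)
  j <- dplyr::inner_join(
    cl, sim$junctions,
    by = c("contig", "chrom_bp", "genome_strand", "donor_end"),
    suffix = c("", ".truth"))
  good <- j[j$donor_bp == j$donor_bp.truth & j$klass == j$true_class, ]
  recovered_events <- unique(sim$junctions$event_id[
    paste(sim$junctions$contig, sim$junctions$chrom_bp,
          sim$junctions$donor_end) %in%
      paste(good$contig, good$chrom_bp, good$donor_end)])
  expect_gte(length(recovered_events) / nrow(sim$events), 0.95)
})

test_that("class summaries partition the junction total", {
  sc <- local_scenario()
  reads <- simulate_reads(sc$sim, per_event_depth = 2, seed = 53)
  cl <- classify_junctions(
    dedupe_and_filter(call_junctions(reads[, c("read_id", "sequence")],
                                     sc$g$genome, sc$d)),
    sc$d, sc$g$genome)
  sm <- summarize_junction_classes(cl)
  expect_equal(sum(sm$count), attr(sm, "total"))
  expect_equal(sum(sm$count), sum(cl$klass != "unclassified"))
  expect_lt(abs(sum(sm$pct) - 100), 0.1 + 1e-9)
})

test_that("degenerate and simple summaries behave", {
  one <- summarize_junction_classes(counts = c(proper_tsd_tir = 1))
  expect_equal(one$pct, c(100, 0, 0, 0))
  expect_equal(attr(one, "total"), 1)
})

test_that("random-placement baseline and fold-over-random arithmetic", {
  expect_equal(expected_random_fraction(100, 4), 4)
  expect_equal(expected_random_fraction(4, 4), 100)
  expect_equal(expected_random_fraction(400, 4), 1)
  expect_error(expected_random_fraction(2, 4))
  expect_equal(fold_over_random(3.1, 3.1), 1)
})

test_that("breakpoint histograms conserve counts and localise proper mass", {
  sc <- local_scenario()
  reads <- simulate_reads(sc$sim, per_event_depth = 2, seed = 59)
  cl <- classify_junctions(
    dedupe_and_filter(call_junctions(reads[, c("read_id", "sequence")],
                                     sc$g$genome, sc$d)),
    sc$d, sc$g$genome)
  h <- breakpoint_histogram(cl, sc$d)
  expect_equal(sum(h$n), nrow(cl))
  prop <- h[h$klass == "proper_tsd_tir", ]
  expect_setequal(prop$donor_bp, c(sc$d$pble_start, sc$d$pble_end))
  p <- plot_breakpoint_histogram(h)
  expect_s3_class(p, "ggplot")
})
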