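#' Read a genome (or any set of contigs) from FASTA
#'
#' Sequences are uppercased on read and must use the A/C/G/T/N alphabet;
#' other IUPAC ambiguity codes are rejected rather than silently mapped.
#' Contig names are the first whitespace-delimited token of each header and
#' must be unique; empty records are an error.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per contig.
#' @seealso [write_genome_fasta()]
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    abort(sprintf("duplicate contig name in %s", path))
  }
  if (any(Biostrings::width(x) == 0L)) {
    abort(sprintf("empty record in %s", path))
  }
  chr <- toupper(as.character(x))
  check_dna_alphabet(chr, what = path)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Write a genome to FASTA
#'
#' Inverse of [read_genome_fasta()]: uppercase A/C/G/T/N input round-trips
#' byte-identically (one sequence line per record).
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

# Coerce a named character vector or DNAStringSet to a validated DNAStringSet.
#' @keywords internal
as_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome)) || anyDuplicated(names(genome))) {
      abort("genome character vector must have unique names")
    }
    check_dna_alphabet(genome, "genome")
    genome <- Biostrings::DNAStringSet(genome)
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Contig lengths of a genome
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  genome <- as_genome(genome)
  setNames(Biostrings::width(genome), names(genome))
}

#' Read junction reads from FASTQ
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `read_id` and `sequence`.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)))
}

#' Write junction reads to FASTQ
#'
#' Qualities are constant (`I`, Phred 40): the synthetic error model is
#' substitution-only and the caller never consults base qualities.
#'
#' @param reads Tibble with columns `read_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

interval_cols <- c("contig", "start", "end", "name", "score", "strand")

#' Construct an interval tibble
#'
#' Intervals are 0-based half-open throughout the package; GFF3 input/output
#' is converted at the boundary. Strand is one of `+`, `-`, `.`.
#'
#' @param contig,start,end,name,score,strand Vectors recycled to a common
#'   length; `name`, `score`, `strand` are optional.
#' @return A tibble with columns contig/start/end/name/score/strand.
#' @export
intervals <- function(contig, start, end, name = NA_character_,
                      score = NA_real_, strand = ".") {
  out <- tibble(contig = as.character(contig),
                start = as.integer(start), end = as.integer(end),
                name = as.character(name), score = as.numeric(score),
                strand = as.character(strand))
  validate_intervals(out)
}

#' @keywords internal
validate_intervals <- function(x, genome = NULL) {
  stopifnot(all(interval_cols %in% names(x)))
  if (any(x$start < 0L)) abort("negative interval coordinate")
  if (any(x$end <= x$start)) abort("interval start must be < end")
  if (!all(x$strand %in% c("+", "-", "."))) abort("strand must be +, - or .")
  if (!is.null(genome)) {
    len <- genome_lengths(genome)
    if (!all(x$contig %in% names(len))) abort("interval on unknown contig")
    if (any(x$end > len[x$contig])) abort("interval beyond contig end")
  }
  x
}

#' Read intervals from BED or GFF3
#'
#' BED is 0-based half-open and used as-is; GFF3 is 1-based closed and
#' converted on read, so both formats yield the same internal representation.
#'
#' @param path Path to the interval file.
#' @param format `"bed"` or `"gff3"`.
#' @return An interval tibble (see [intervals()]).
#' @export
read_intervals <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- if (format == "bed") {
    rtracklayer::import(path, format = "BED")
  } else {
    rtracklayer::import(path, format = "GFF3")
  }
  meta <- as.data.frame(GenomicRanges::mcols(gr))
  nm <- if ("name" %in% names(meta)) as.character(meta$name)
        else if ("Name" %in% names(meta)) as.character(meta$Name)
        else if ("ID" %in% names(meta)) as.character(meta$ID)
        else if ("type" %in% names(meta)) as.character(meta$type)
        else NA_character_
  sc <- if ("score" %in% names(meta)) as.numeric(meta$score) else NA_real_
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  out <- tibble(contig = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr),
                name = if (length(nm)) nm else NA_character_,
                score = if (length(sc)) sc else NA_real_,
                strand = strand)
  validate_intervals(out)
}

#' Write intervals to BED6 or GFF3
#'
#' @param x Interval tibble (0-based half-open).
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  x <- validate_intervals(x)
  strand <- ifelse(x$strand == ".", "*", x$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = x$contig,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  if (format == "bed") {
    gr$name <- ifelse(is.na(x$name), ".", x$name)
    gr$score <- ifelse(is.na(x$score), 0, x$score)
    rtracklayer::export(gr, path, format = "BED")
  } else {
    gr$source <- "pbletools"
    gr$type <- ifelse(is.na(x$name), "region", x$name)
    gr$score <- x$score
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

# Interval tibble -> GRanges (0-based half-open -> 1-based closed).
#' @keywords internal
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$contig,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}
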