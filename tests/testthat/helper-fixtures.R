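# Shared fixtures: tiny hand-built annotations and a cached default
# simulation (generated once per test run).

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
  library(GenomicAlignments)
})

# two-exon plus-strand and minus-strand transcripts with CDS
toy_annotation <- function() {
  exons <- GRanges(
    "chr1",
    IRanges(c(101, 301, 1001, 1401), c(200, 500, 1200, 1600)),
    strand = c("+", "+", "-", "-"),
    gene_id = c("gA", "gA", "gB", "gB"),
    transcript_id = c("tA", "tA", "tB", "tB"))
  cds <- GRanges(
    "chr1",
    IRanges(c(151, 301, 1051, 1401), c(200, 450, 1200, 1550)),
    strand = c("+", "+", "-", "-"),
    transcript_id = c("tA", "tA", "tB", "tB"))
  build_annotation(exons, cds, seqlengths = c(chr1 = 5000L))
}

# simple GAlignments constructor for tests
aln <- function(chrom, pos, cigar, strand = "+", read_id = NULL,
                library = "L1") {
  n <- length(pos)
  read_id <- read_id %||% sprintf("r%03d", seq_len(n))
  GenomicAlignments::GAlignments(
    seqnames = rep_len(chrom, n), pos = as.integer(pos),
    cigar = rep_len(as.character(cigar), n),
    strand = factor(rep_len(strand, n), levels = c("+", "-", "*")),
    read_id = read_id, library = rep_len(library, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one default simulation shared across test files (cheap enough to build
# once; deterministic under its own seed, independent of the test RNG)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_genome(simulation_config(seed = 11))
    cache
  }
})

default_clip <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_clip_reads(default_sim())
    cache
  }
})
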