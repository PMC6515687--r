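# annotation with one 1,000-nt plus-strand intron [1201, 2200] and its
# mirrored minus-strand twin [5201, 6200]
splice_toy <- function() {
  exons <- GRanges(
    "chr1",
    IRanges(c(1001, 2201, 5001, 6201), c(1200, 2400, 5200, 6400)),
    strand = c("+", "+", "-", "-"),
    gene_id = c("gP", "gP", "gM", "gM"),
    transcript_id = c("tP", "tP", "tM", "tM"))
  cds <- GRanges("chr1",
                 IRanges(c(1051, 2201, 5001, 6201), c(1200, 2350, 5150, 6350)),
                 strand = c("+", "+", "-", "-"),
                 transcript_id = c("tP", "tP", "tM", "tM"))
  build_annotation(exons, cds, seqlengths = c(chr1 = 10000L))
}

site_at <- function(pos, strand = "+", residues = 1L) {
  GRanges("chr1", IRanges(pos, width = 1), strand = strand,
          residues = residues)
}

test_that("offsets into the intron follow the 1-based convention", {
  ann <- splice_toy()
  # site 50 nt into the intron from the 5' splice site
  h <- map_crosslinks_to_splice_sites(site_at(1250), ann)
  expect_equal(h$five_prime$site_count[50], 1L)
  expect_equal(sum(h$five_prime$site_count), 1L)
  expect_equal(sum(h$three_prime$site_count), 0L)
  # site 50 nt upstream of the 3' splice site (intron end 2200)
  h3 <- map_crosslinks_to_splice_sites(site_at(2151), ann)
  expect_equal(h3$three_prime$site_count[50], 1L)
  # site 250 nt from both ends of an intron is excluded from both histograms
  mk_ann <- function(exon2_start, exon2_end) {
    exons2 <- GRanges("chr1", IRanges(c(101, exon2_start), c(200, exon2_end)),
                      strand = "+", gene_id = "g", transcript_id = "t")
    cds2 <- GRanges("chr1", IRanges(c(151, exon2_start), c(200, exon2_end - 50)),
                    strand = "+", transcript_id = "t")
    build_annotation(exons2, cds2)
  }
  ann2 <- mk_ann(700, 800)                 # intron [201, 699], width 499
  hx <- map_crosslinks_to_splice_sites(site_at(450), ann2, window = 200)
  expect_equal(sum(hx$five_prime$site_count) + sum(hx$three_prime$site_count), 0L)
  # short-intron tie at equal distance goes to the 5' side
  ann3 <- mk_ann(600, 700)                 # intron [201, 599], width 399
  ht <- map_crosslinks_to_splice_sites(site_at(400), ann3, window = 200)
  expect_equal(ht$five_prime$site_count[200], 1L)
  expect_equal(sum(ht$three_prime$site_count), 0L)
})

test_that("minus-strand introns mirror the plus-strand construction", {
  ann <- splice_toy()
  # plus intron [1201,2200]: 5'SS offset d is position 1200+d
  # minus intron [5201,6200]: 5' splice site is at 6201; offset d is 6201-d
  for (d in c(1, 37, 150)) {
    hp <- map_crosslinks_to_splice_sites(site_at(1200 + d), ann)
    hm <- map_crosslinks_to_splice_sites(site_at(6201 - d, "-"), ann)
    expect_equal(hp$five_prime$site_count, hm$five_prime$site_count)
    expect_equal(hp$five_prime$site_count[d], 1L)
  }
})

test_that("unique positions count once; residues accumulate; totals are bounded", {
  ann <- splice_toy()
  sites <- suppressWarnings(c(site_at(1250, residues = 3L),
                              site_at(1250, "-", residues = 2L),
                              site_at(1300, residues = 1L)))
  # the minus-strand site is not inside any minus-strand intron there
  h <- map_crosslinks_to_splice_sites(sites, ann)
  expect_equal(h$five_prime$site_count[50], 1L)
  expect_equal(h$five_prime$residue_count[50], 3L)
  expect_equal(h$five_prime$site_count[100], 1L)
  expect_lte(sum(h$five_prime$site_count) + sum(h$three_prime$site_count),
             h$n_intronic_sites)
})

test_that("shifting planted sites shifts the recovered histogram mode exactly", {
  cfg <- simulation_config(seed = 61, binding = list(
    n_intron_sites = 40, n_utr3_sites = 0,
    splice_offset_mean = 50, splice_offset_sd = 0))
  sim <- generate_genome(cfg)
  s <- sim$truth$binding_sites
  sites <- GRanges(s$chrom, IRanges(s$pos, width = 1), strand = s$strand)
  h <- map_crosslinks_to_splice_sites(sites, sim$annotation)
  expect_equal(h$three_prime$offset[which.max(h$three_prime$site_count)], 50)
  # shift all sites 10 nt deeper into the intron (strand-aware)
  shifted <- GenomicRanges::shift(sites,
                                  ifelse(as.character(strand(sites)) == "+",
                                         -10L, 10L))
  h2 <- map_crosslinks_to_splice_sites(shifted, sim$annotation)
  expect_equal(h2$three_prime$offset[which.max(h2$three_prime$site_count)], 60)
})

test_that("junction composition separates exonic and intronic halves", {
  # AT-rich intron, uniform-ish exons
  set.seed(3)
  seqv <- sample(c("A", "C", "G", "T"), 10000, replace = TRUE)
  seqv[1201:2200] <- sample(c("A", "T"), 1000, replace = TRUE, prob = c(.5, .5))
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(seqv, collapse = "")))
  ann <- splice_toy()
  sites <- site_at(1250)   # intronic-side site for the 5' junction
  comp <- splice_flank_composition(ann, sites, genome, flank = 100)
  five <- comp$five_prime
  at <- five$A + five$U
  expect_gt(mean(at[five$side == "intron"]), mean(at[five$side == "exon"]) + 0.2)
  # junction windows without intronic-side sites are excluded entirely
  expect_error(splice_flank_composition(ann, site_at(1100), genome),
               "no junction window")
  # brute-force letter tally at a handful of offsets
  for (off in c(-100, -1, 0, 50)) {
    base <- substr(as.character(genome[[1]]), 1201 + off, 1201 + off)
    want <- c(A = 0, C = 0, G = 0, U = 0)
    want[[chartr("T", "U", base)]] <- 1
    row <- five[five$offset == off, c("A", "C", "G", "U")]
    expect_equal(as.numeric(row), unname(want[c("A", "C", "G", "U")]))
  }
})
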