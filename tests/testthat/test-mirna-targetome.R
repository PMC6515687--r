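# one hand-built hairpin: [1001, 1078] on +, mature [1004, 1025], flank 100
toy_hairpins <- function(strand = "+") {
  hp <- GRanges("chr1", IRanges(1001, 1078), strand = strand)
  names(hp) <- "mirX"
  mat <- GRangesList(mirX = GRanges("chr1", IRanges(1004, 1025),
                                    strand = strand))
  mirna_hairpin_set(hp, mat)
}

test_that("window collection uses >= 1 nt overlap on the closed window", {
  hp <- toy_hairpins()
  # window is [901, 1178]; a read ending at 900 misses, at 901 hits
  r <- aln("chr1", c(871, 872, 1178, 1179), "30M")
  pairs <- collect_hairpin_reads(r, hp, flank = 100)
  expect_setequal(pairs$read, c(2, 3))
  # wrong strand is never collected
  rm <- aln("chr1", 1000, "30M", strand = "-")
  expect_equal(nrow(collect_hairpin_reads(rm, hp)), 0)
})

test_that("window retention matches brute-force interval arithmetic on 2000 reads", {
  sim <- default_sim()
  set.seed(55)
  pos <- sample(1:250000, 2000, replace = TRUE)
  strnd <- sample(c("+", "-"), 2000, replace = TRUE)
  reads <- aln("chrS1", pos, "30M", strand = strnd)
  pairs <- collect_hairpin_reads(reads, sim$hairpins, flank = 100)
  hp <- sim$truth$hairpins
  want <- 0L
  for (j in which(hp$chrom == "chrS1")) {
    lo <- hp$start[j] - 100L; hi <- hp$end[j] + 100L
    want <- want + sum(pos <= hi & (pos + 29L) >= lo & strnd == hp$strand[j])
  }
  expect_equal(nrow(pairs), want)
})

test_that("category rules match their definitions", {
  hp <- toy_hairpins()
  cases <- list(
    list(pos = 1004, cigar = "22M", cat = "I"),    # exactly the mature
    list(pos = 1003, cigar = "23M", cat = "I"),    # 1 nt excess total
    list(pos = 1003, cigar = "24M", cat = "II"),   # 2 nt excess, inside, mature overlap
    list(pos = 1020, cigar = "30M", cat = "II"),
    list(pos = 1030, cigar = "25M", cat = "III"),  # inside, 3' of mature
    list(pos = 1074, cigar = "10M", cat = "IV"),   # straddles 3' boundary
    list(pos = 996,  cigar = "10M", cat = "IV"),   # straddles 5' boundary
    list(pos = 1080, cigar = "20M", cat = "V"),    # outside, in flank
    list(pos = 950,  cigar = "20M", cat = "V"))
  r <- aln("chr1", vapply(cases, `[[`, numeric(1), "pos"),
           vapply(cases, `[[`, character(1), "cigar"))
  pairs <- collect_hairpin_reads(r, hp)
  cats <- classify_mirna_reads(r, pairs, hp)
  expect_equal(as.character(cats$category[order(cats$read)]),
               vapply(cases, `[[`, character(1), "cat"))
})

test_that("simulated hairpin reads are classified 100% like the truth", {
  sim <- default_sim()
  clip <- default_clip()
  pairs <- collect_hairpin_reads(clip$reads, sim$hairpins)
  cats <- classify_mirna_reads(clip$reads, pairs, sim$hairpins)
  truth <- clip$truth[!is.na(clip$truth$category),
                      c("read_id", "mirna_id", "category")]
  m <- merge(truth, cats, by = c("read_id", "mirna_id"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(as.character(m$category.y), m$category.x)
  # categories partition the retained pairs
  expect_equal(sum(table(cats$category)), nrow(pairs))
})

test_that("form calls respect the five-read rule and threshold monotonicity", {
  mk <- function(I = 0, II = 0, III = 0, IV = 0, V = 0) {
    data.frame(mirna_id = "m",
               category = factor(rep(c("I", "II", "III", "IV", "V"),
                                     c(I, II, III, IV, V)),
                                 levels = c("I", "II", "III", "IV", "V")))
  }
  expect_equal(call_mirna_forms(mk(I = 5))$forms, "mature")
  expect_equal(call_mirna_forms(mk(II = 3, III = 2))$forms, "pre")
  expect_equal(call_mirna_forms(mk(I = 4, IV = 2, V = 2))$forms, "")
  # monotonicity: raising min_reads never adds a form
  set.seed(71)
  for (rep_i in 1:10) {
    cats <- mk(I = sample(0:8, 1), II = sample(0:8, 1), III = sample(0:8, 1),
               IV = sample(0:8, 1), V = sample(0:8, 1))
    prev <- NULL
    for (thr in 1:10) {
      f <- call_mirna_forms(cats, min_reads = thr)
      now <- c(f$mature, f$pre, f$pri)
      if (!is.null(prev)) expect_true(all(now <= prev))
      prev <- now
    }
  }
})

test_that("pri calls dominate when binding is planted on primary-transcript flanks", {
  sim <- default_sim()          # default category weights are IV/V-heavy
  clip <- default_clip()
  pairs <- collect_hairpin_reads(clip$reads, sim$hairpins)
  cats <- classify_mirna_reads(clip$reads, pairs, sim$hairpins)
  forms <- call_mirna_forms(cats, mirna_ids = names(sim$hairpins$hairpins))
  expect_gte(sum(forms$pri), sum(forms$pre))
  expect_gte(sum(forms$pri), sum(forms$mature))
})

test_that("hairpin meta-profile localizes coverage and normalizes to unit area", {
  hp <- toy_hairpins()
  # single read at the midpoint -> all mass in the central bins
  mid <- 1001 + 39
  r <- aln("chr1", mid - 10, "21M")
  p <- hairpin_meta_profile(r, hp)
  expect_equal(sum(p$depth), 1, tolerance = 1e-9)
  expect_true(all(p$depth[abs(p$offset_mid) > 30] == 0))
  # uniform coverage -> flat profile
  rflat <- aln("chr1", 700, "1000M")
  pf <- hairpin_meta_profile(rflat, hp)
  expect_true(all(abs(pf$depth - 1 / 30) < 1e-9))
  # strand mirror: minus-strand hairpin with mirrored read placement
  hpm <- toy_hairpins("-")
  midm <- 1078 - 39
  pm <- hairpin_meta_profile(aln("chr1", midm - 10, "21M", strand = "-"), hpm)
  expect_true(all(pm$depth[abs(pm$offset_mid) > 30] == 0))
  expect_warning(hairpin_meta_profile(aln("chr2", 1, "10M"), hp), "no read")
})

test_that("small-RNA length histogram percentages behave", {
  out <- small_rna_length_profile(c(22L, 22L, 30L))
  expect_equal(out$share, 200 / 3, tolerance = 1e-9)
  expect_equal(sum(out$histogram$percent), 100)
  expect_equal(small_rna_length_profile(rep(22L, 10))$share, 100)
  # brute-force tally on a simulated library
  sim <- default_sim()
  sm <- simulate_small_rna(sim, "control")
  prof <- small_rna_length_profile(sm)
  tab <- table(sm$length)
  expect_equal(prof$histogram$n, as.integer(tab))
  expect_equal(prof$share,
               100 * sum(sm$length >= 21 & sm$length <= 25) / nrow(sm))
  expect_error(small_rna_length_profile(integer(0)), "no small-RNA")
})
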