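test_that("deletion sites follow CIGAR arithmetic and collapse per position", {
  # 10M1D10M starting at 1-based 101 -> deleted base at 111
  a <- aln("chr1", c(101, 101), c("10M1D10M", "10M1D10M"))
  s <- extract_deletion_sites(a)
  expect_equal(length(s), 1)
  expect_equal(start(s), 111)
  expect_equal(s$residues, 2L)
  sm <- attr(s, "summary")
  expect_equal(sm$n_sites, 1L)
  expect_equal(sm$n_residues, 2L)
  # opposite strands do not collapse
  b <- aln("chr1", c(101, 101), c("10M1D10M", "10M1D10M"), strand = c("+", "-"))
  expect_equal(length(extract_deletion_sites(b)), 2)
  # multi-nt deletion: per-base mode vs event-start mode
  m <- aln("chr1", 101, "10M3D10M")
  expect_equal(start(extract_deletion_sites(m)), c(111, 112, 113))
  es <- extract_deletion_sites(m, mode = "event_start")
  expect_equal(start(es), 111)
  expect_equal(attr(es, "summary")$n_residues, 1L)
})

test_that("site calling matches the brute-force residue oracle on simulated reads", {
  clip <- default_clip()
  reads <- clip$reads[seq_len(500)]
  s <- extract_deletion_sites(reads)
  want <- oracle_deletion_residues(
    as.character(seqnames(reads)), start(reads), cigar(reads),
    as.character(strand(reads)))
  got <- setNames(s$residues, paste(as.character(seqnames(s)), start(s),
                                    as.character(strand(s)), sep = ":"))
  expect_equal(length(got), length(want))
  expect_equal(got[sort(names(got))], want[sort(names(want))])
  # planted-site recovery: every called site is a planted position
  truth <- clip$truth[seq_len(500), ]
  planted <- unique(truth$del_start[truth$has_deletion])
  expect_setequal(start(s), planted)
  # invariants: residues >= sites; order independence
  expect_gte(attr(s, "summary")$n_residues, attr(s, "summary")$n_sites)
  sh <- extract_deletion_sites(reads[sample(length(reads))])
  expect_equal(as.data.frame(granges(s)), as.data.frame(granges(sh)))
  expect_equal(s$residues, sh$residues)
})

test_that("base composition profiles are strand-aware and match a letter tally", {
  genome <- Biostrings::DNAStringSet(c(
    chrA = paste(rep("A", 500), collapse = "")))
  sites <- GRanges("chrA", IRanges(251, width = 1), strand = "+")
  p <- base_composition_profile(sites, genome, flank = 10)
  expect_true(all(p$A == 1))
  expect_true(all(p$U == 0))
  # same site on the minus strand: window is reverse-complemented -> all U
  pm <- base_composition_profile(
    GRanges("chrA", IRanges(251, width = 1), strand = "-"), genome, flank = 10)
  expect_true(all(pm$U == 1))
  # GC island on AT background: offset 0 is GC-richer than the edges
  set.seed(3)
  at_bg <- sample(c("A", "T"), 2000, replace = TRUE)
  at_bg[951:1050] <- sample(c("G", "C"), 100, replace = TRUE)
  genome2 <- Biostrings::DNAStringSet(c(chrB = paste(at_bg, collapse = "")))
  s2 <- GRanges("chrB", IRanges(1000, width = 1), strand = "+")
  p2 <- base_composition_profile(s2, genome2, flank = 100)
  gc <- p2$G + p2$C
  expect_gt(gc[p2$offset == 0], gc[p2$offset == -100])
  expect_gt(gc[p2$offset == 0], gc[p2$offset == 100])
  # brute-force tally over 50 random sites
  sim <- default_sim()
  set.seed(8)
  s50 <- GRanges("chrS1", IRanges(sample(200:200000, 50), width = 1),
                 strand = sample(c("+", "-"), 50, replace = TRUE))
  p50 <- base_composition_profile(s50, sim$genome, flank = 5)
  chr <- as.character(sim$genome[["chrS1"]])
  comp <- function(x) chartr("ACGT", "TGCA", x)
  for (off in c(-5, 0, 5)) {
    letters_at <- vapply(seq_along(s50), function(i) {
      if (as.character(strand(s50))[i] == "+")
        substr(chr, start(s50)[i] + off, start(s50)[i] + off)
      else comp(substr(chr, start(s50)[i] - off, start(s50)[i] - off))
    }, character(1))
    tab <- table(factor(letters_at, levels = c("A", "C", "G", "T")))
    want <- as.numeric(tab) / 50
    row <- p50[p50$offset == off, c("A", "C", "G", "U")]
    expect_equal(as.numeric(row), want, tolerance = 1e-12)
  }
  expect_error(base_composition_profile(GRanges(), genome), "no sites")
})

test_that("edge sites whose windows leave the chromosome are dropped with a message", {
  genome <- Biostrings::DNAStringSet(c(chrA = paste(rep("A", 300), collapse = "")))
  sites <- GRanges("chrA", IRanges(c(5, 150, 298), width = 1), strand = "+")
  expect_message(w <- extract_windows(genome, sites, flank = 10), "dropped")
  expect_equal(length(w), 1)
  expect_equal(attr(w, "n_dropped"), 2L)
})

test_that("maximum-pairing DP agrees with exhaustive enumeration for n <= 12", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    dp <- sum(targetome:::nussinov_partners(s, 3) > 0) / 2
    expect_equal(dp, oracle_max_pairs(s, 3), label = s)
  }
})

test_that("structure profiles show forced stems and silent poly-A", {
  # perfect 20-nt stem + 4-nt A loop
  stem <- "GCGCGCGCGCGCGCGCGCGC"
  hp <- paste0(stem, "AAAA",
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(stem))))
  p <- structure_potential_profile(Biostrings::DNAStringSet(hp))
  expect_true(all(p$pairing[c(1:20, 25:44)] == 1))
  expect_true(all(p$pairing[21:24] == 0))
  pa <- structure_potential_profile(Biostrings::DNAStringSet(
    paste(rep("A", 30), collapse = "")))
  expect_true(all(pa$pairing == 0))
  expect_error(structure_potential_profile(Biostrings::DNAStringSet("ACGT")),
               "shorter")
  expect_error(structure_potential_profile(
    Biostrings::DNAStringSet(c("ACGTACGTA", "ACGTACGTAC"))), "uniform")
})

test_that("generator hairpins pair on the stem and not on the loop", {
  sim <- default_sim()
  seqs <- get_stranded_sequences(sim$genome, sim$hairpins$hairpins)
  p <- structure_potential_profile(seqs)
  stem <- c(1:30, 49:78); loop <- 31:48
  expect_gt(mean(p$pairing[stem]) - mean(p$pairing[loop]), 0.5)
})
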