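test_that("same seed gives byte-identical simulation outputs", {
  cfg <- simulation_config(seed = 7, n_genes = 10,
                           chrom_lengths = c(c1 = 120000L, c2 = 90000L),
                           clip = list(n_reads = 300L))
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_simulation(generate_genome(cfg), d1)
  p2 <- write_simulation(generate_genome(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readBin(p1[[k]], "raw", 2e7),
                     readBin(p2[[k]], "raw", 2e7), label = k)
  }
  s1 <- simulate_clip_reads(generate_genome(cfg))
  s2 <- simulate_clip_reads(generate_genome(cfg))
  expect_identical(cigar(s1$reads), cigar(s2$reads))
  expect_identical(s1$truth, s2$truth)
})

test_that("hairpin bookkeeping and stem construction hold", {
  cfg <- simulation_config(seed = 2,
                           mirna_counts = c(intronic = 5, utr3 = 2, intergenic = 2))
  sim <- generate_genome(cfg)
  expect_equal(sum(sim$truth$hairpins$context == "intronic"), 5)
  expect_equal(unname(table(sim$context)[c("intergenic", "intronic", "utr3")]),
               c(2L, 5L, 2L), ignore_attr = TRUE)
  # arms are exact reverse complements; loop has no canonical partner bases
  seqs <- get_stranded_sequences(sim$genome, sim$hairpins$hairpins)
  for (s in as.character(seqs)) {
    left <- substr(s, 1, 30); right <- substr(s, 49, 78)
    expect_equal(right, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(left))))
    expect_true(grepl("^[AC]+$", substr(s, 31, 48)))
  }
  # mature intervals sit inside their hairpins (class invariant re-checked)
  expect_s3_class(sim$hairpins, "MirnaHairpinSet")
})

test_that("deletion probability 1 and 0 are honored exactly", {
  base <- list(seed = 5, n_genes = 12,
               chrom_lengths = c(c1 = 150000L, c2 = 100000L))
  cfg1 <- do.call(simulation_config, c(base, list(
    clip = list(n_reads = 300L, deletion_prob = 1, site_fraction = 1,
                hairpin_fraction = 0))))
  sim <- generate_genome(cfg1)
  r1 <- simulate_clip_reads(sim)
  expect_true(all(grepl("D", cigar(r1$reads))))
  # deletion lands exactly on the planted site position
  del <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar(r1$reads), pos = start(r1$reads), ops = "D")
  expect_equal(unname(unlist(lapply(del, start))), r1$truth$del_start)
  st <- sim$truth$binding_sites
  expect_equal(r1$truth$del_start,
               st$pos[match(r1$truth$site_id, st$site_id)])
  cfg0 <- do.call(simulation_config, c(base, list(
    clip = list(n_reads = 300L, deletion_prob = 0))))
  r0 <- simulate_clip_reads(generate_genome(cfg0))
  expect_false(any(grepl("D", cigar(r0$reads))))
})

test_that("observed deletion fraction falls in the binomial 99% CI of 0.3", {
  cfg <- simulation_config(seed = 9, clip = list(
    n_reads = 2000L, site_fraction = 1, hairpin_fraction = 0,
    deletion_prob = 0.3))
  r <- simulate_clip_reads(generate_genome(cfg))
  k <- sum(r$truth$has_deletion)
  ci <- qbinom(c(0.005, 0.995), 2000, 0.3)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("generated files round-trip through the package readers", {
  sim <- default_sim()
  d <- tempfile()
  p <- write_simulation(sim, d)
  ann2 <- parse_gtf(p[["gtf"]], seqlengths = sim$config$chrom_lengths)
  expect_setequal(ann2$transcripts$transcript_id,
                  sim$annotation$transcripts$transcript_id)
  hp2 <- parse_mirna_gff(p[["mirna"]])
  ids <- names(sim$hairpins$hairpins)
  expect_setequal(names(hp2$hairpins), ids)
  expect_equal(start(hp2$hairpins[ids]), start(sim$hairpins$hairpins))
  expect_equal(as.character(strand(hp2$hairpins[ids])),
               as.character(strand(sim$hairpins$hairpins)))
  for (id in ids)
    expect_equal(as.data.frame(hp2$mature[[id]])[, c("start", "end")],
                 as.data.frame(sim$hairpins$mature[[id]])[, c("start", "end")])
  g2 <- Biostrings::readDNAStringSet(p[["genome"]])
  expect_identical(as.character(g2), as.character(sim$genome))
  # SAM round-trip for a simulated CLIP library
  clip <- default_clip()
  sam <- tempfile(fileext = ".sam")
  write_sam(clip$reads, sam, sim$config$chrom_lengths)
  r2 <- parse_alignments(sam, seqlengths = sim$config$chrom_lengths)
  expect_identical(cigar(r2), cigar(clip$reads))
  expect_identical(start(r2), start(clip$reads))
  expect_identical(as.character(strand(r2)), as.character(strand(clip$reads)))
})

test_that("RNA-seq honors planted levels and retention fractions at the extremes", {
  cfg <- simulation_config(seed = 13, mirna_counts = c(intronic = 2, utr3 = 0,
                                                       intergenic = 2))
  sim <- generate_genome(cfg)
  # force one intergenic miRNA to zero level: its window must stay empty
  j <- which(sim$truth$hairpins$context == "intergenic")[1]
  sim$truth$mirna_levels$control[j] <- 0
  sim$truth$mirna_levels$knockdown[j] <- 0
  rc <- simulate_rnaseq(sim, "control")
  hp <- sim$truth$hairpins[j, ]
  win <- GRanges(hp$chrom, IRanges(hp$start - 200, hp$end + 200),
                 strand = hp$strand)
  expect_equal(sum(countOverlaps(granges(rc$reads), win,
                                 ignore.strand = FALSE) > 0), 0)
  # PIR 1.0 -> no junction reads over mirtron introns
  cfg2 <- simulation_config(seed = 13,
                            mirna_counts = c(intronic = 2, utr3 = 0, intergenic = 2),
                            pir = list(mirtron_control = 1.0))
  sim2 <- generate_genome(cfg2)
  rc2 <- simulate_rnaseq(sim2, "control")
  mt <- sim2$truth$introns[sim2$truth$introns$mirtron, ]
  jx <- unlist(GenomicAlignments::junctions(rc2$reads))
  for (i in seq_len(nrow(mt)))
    expect_false(any(start(jx) == mt$start[i] & end(jx) == mt$end[i]))
  expect_error(simulate_rnaseq(sim, "weird"))
})

test_that("a planted 0.5 level ratio is recovered as ~ -1 log2 window density", {
  cfg <- simulation_config(
    seed = 17, mirna_counts = c(intronic = 0, utr3 = 0, intergenic = 6),
    mirna = list(control_levels = c(40, 80), fold_choices = 0.5,
                 fold_weights = 1),
    rnaseq = list(reads_per_level = 10, gene_reads_per_level = 200))
  sim <- generate_genome(cfg)
  rc <- simulate_rnaseq(sim, "control")
  rk <- simulate_rnaseq(sim, "knockdown")
  dc <- mirna_window_density(rc$reads, sim$hairpins, rc$library_size)
  dk <- mirna_window_density(rk$reads, sim$hairpins, rk$library_size)
  lr <- log2(dk$density / dc$density)
  expect_true(all(abs(lr - (-1)) < 0.45))
  expect_lt(abs(mean(lr) - (-1)), 0.2)
})

test_that("small-RNA generator respects length distribution and planted levels", {
  cfg <- simulation_config(seed = 21, smallrna = list(
    lengths = 22L, length_weights = 1, background_weight = 0, n_reads = 2000L))
  sim <- generate_genome(cfg)
  sm <- simulate_small_rna(sim, "control")
  expect_true(all(sm$length == 22L))
  expect_equal(nchar(sm$sequence), sm$length)
  # zero-level miRNA emits nothing
  sim$truth$mirna_levels$control[2] <- 0
  sm2 <- simulate_small_rna(sim, "control")
  expect_equal(sum(sm2$mirna_id == sim$truth$mirna_levels$mirna_id[2],
                   na.rm = TRUE), 0)
  # planted 2-fold count ratio between two miRNAs recovered multinomially
  sim3 <- generate_genome(simulation_config(seed = 23))
  sim3$truth$mirna_levels$control[] <- c(40, 20, rep(10, 8))
  cfg3 <- sim3$config
  sm3 <- simulate_small_rna(sim3, "control",
                            config = local({
                              x <- unclass(cfg3)
                              x$smallrna$n_reads <- 20000L
                              x$smallrna$background_weight <- 0
                              structure(x, class = "SimulationConfig")
                            }))
  tab <- table(sm3$mirna_id)
  ratio <- tab[["mirS01"]] / tab[["mirS02"]]
  expect_lt(abs(ratio - 2), 0.3)
})

test_that("clip read truth labels are consistent with independent re-derivation", {
  cfg <- simulation_config(seed = 31, clip = list(
    n_reads = 1000L, site_fraction = 0, hairpin_fraction = 0))
  sim <- generate_genome(cfg)
  clip <- simulate_clip_reads(sim)
  out <- classify_read_regions(clip$reads, sim$annotation)
  expect_equal(out$labels, clip$truth$region)
})
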