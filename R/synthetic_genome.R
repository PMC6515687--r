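#' Generate a synthetic genome with planted ground truth
#'
#' Builds a toy genome end-to-end: random chromosome sequence; multi-exon
#' coding genes (first/last exons sized to hold the 5'/3' UTRs, so every
#' transcript has all five region labels); miRNA hairpins placed in introns,
#' in long 3'-UTRs and in intergenic space, with stem-forming sequence
#' written into the genome (the two 30-nt arms are exact reverse
#' complements; the 18-nt loop is drawn from {A,C} only, which has no
#' canonical pairing partner, so maximum-base-pairing folding shows a clean
#' stem-vs-loop contrast); repeat and piRNA-cluster intervals; planted
#' protein-binding sites in 3'-UTRs (placement probability proportional to
#' 3'-UTR length to a configurable power) and in introns at a configurable
#' offset upstream of the 3' splice site; and per-condition miRNA transcript
#' levels and intron-retention fractions.
#'
#' @param config a [simulation_config()].
#' @return a `TargetomeSim` list: `genome` (DNAStringSet), `annotation`
#'   (GenomeAnnotation), `hairpins` (MirnaHairpinSet), `context` (named
#'   host-context vector), `repeats`, `clusters` (GRanges), `truth` (planted
#'   parameters), `config`.
#' @export
generate_genome <- function(config = simulation_config()) {
  validate_config(config)
  set.seed(stage_seed(config, "genome"))
  chrlen <- config$chrom_lengths
  chroms <- names(chrlen)

  n_utr3_mirna <- config$mirna_counts[["utr3"]]
  n_genes <- config$n_genes

  ## ---- gene placement -----------------------------------------------------
  cursor <- setNames(rep(1L, length(chroms)), chroms)
  gaps <- list()
  exon_rows <- list(); cds_rows <- list(); tx_meta <- list()
  for (g in seq_len(n_genes)) {
    chrom <- chroms[(g - 1L) %% length(chroms) + 1L]
    strand_g <- sample(c("+", "-"), 1)
    utr3_len <- if (g <= n_utr3_mirna) sample(800:2000, 1)
                else max(60L, min(2500L, round(rlnorm(1, log(300), 0.9))))
    utr5_len <- sample(80:200, 1)
    n_exons <- sample(3:5, 1)
    mid_w <- if (n_exons > 2) sample(150:300, n_exons - 2, replace = TRUE) else integer(0)
    first_w <- utr5_len + sample(60:150, 1)
    last_w <- utr3_len + sample(120:250, 1)
    exon_w_tx <- c(first_w, mid_w, last_w)           # transcript 5'->3'
    exon_w <- if (strand_g == "+") exon_w_tx else rev(exon_w_tx)
    intron_w <- sample(700:1500, n_exons - 1, replace = TRUE)

    gap <- sample(2500:6000, 1)
    gstart <- cursor[[chrom]] + gap
    span <- sum(exon_w) + sum(intron_w)
    if (gstart + span - 1L > chrlen[[chrom]] - 1000L)
      stop("sizing error: gene ", g, " exceeds capacity of ", chrom,
           " (", chrlen[[chrom]], " nt); enlarge chrom_lengths or reduce n_genes")
    gaps[[length(gaps) + 1L]] <- data.frame(
      chrom = chrom, start = cursor[[chrom]] + 1L, end = gstart - 1L)
    cursor[[chrom]] <- gstart + span - 1L

    starts <- integer(n_exons)
    pos <- gstart
    for (k in seq_len(n_exons)) {
      starts[k] <- pos
      pos <- pos + exon_w[k] + if (k < n_exons) intron_w[k] else 0L
    }
    gene_id <- sprintf("geneS%02d", g)
    tx_id <- paste0(gene_id, ".t1")
    exon_rows[[g]] <- data.frame(
      chrom = chrom, start = starts, end = starts + exon_w - 1L,
      strand = strand_g, gene_id = gene_id, transcript_id = tx_id)
    exonic_len <- sum(exon_w)
    cds_tx <- c(utr5_len + 1L, exonic_len - utr3_len)   # transcript coords
    tx_meta[[g]] <- data.frame(
      gene_id = gene_id, transcript_id = tx_id, chrom = chrom,
      strand = strand_g, utr5_len = utr5_len, utr3_len = utr3_len,
      cds_from = cds_tx[1], cds_to = cds_tx[2])
    }
  for (ch in chroms)
    gaps[[length(gaps) + 1L]] <- data.frame(
      chrom = ch, start = cursor[[ch]] + 1L, end = chrlen[[ch]])
  gaps <- do.call(rbind, gaps)
  gaps <- gaps[gaps$end - gaps$start + 1L > 0, ]

  exons <- do.call(rbind, exon_rows)
  exons_gr <- GRanges(exons$chrom, IRanges(exons$start, exons$end),
                      strand = exons$strand, gene_id = exons$gene_id,
                      transcript_id = exons$transcript_id)
  cds_list <- lapply(seq_len(n_genes), function(g) {
    m <- tx_meta[[g]]
    ex <- exons_gr[exons_gr$transcript_id == m$transcript_id]
    cd <- tx_to_genomic(sort(granges(ex)), m$strand, m$cds_from, m$cds_to)
    cd$transcript_id <- m$transcript_id
    cd$gene_id <- m$gene_id
    cd
  })
  cds_gr <- suppressWarnings(do.call(c, cds_list))
  annotation <- build_annotation(exons_gr, cds_gr, seqlengths = chrlen)

  ## ---- miRNA hairpin placement -------------------------------------------
  arm <- 30L; loop <- 18L; hp_w <- 2L * arm + loop   # 78 nt
  mature_local <- c(4L, 25L)                          # 22 nt on the 5' arm
  hp_rows <- list()

  introns_flat <- unlist(annotation$introns)
  introns_flat$transcript_id <- rep(names(annotation$introns),
                                    lengths(annotation$introns))
  intr_ok <- introns_flat[width(introns_flat) >= hp_w + 420L + 20L]
  n_intr_mir <- config$mirna_counts[["intronic"]]
  if (length(intr_ok) < n_intr_mir)
    stop("sizing error: not enough wide introns for ", n_intr_mir,
         " intronic hairpins")
  pick <- sample(seq_along(intr_ok), n_intr_mir)
  for (i in seq_len(n_intr_mir)) {
    it <- intr_ok[pick[i]]
    lo <- start(it) + 210L
    hi <- end(it) - 210L - hp_w + 1L
    s <- if (hi > lo) sample(lo:hi, 1) else lo
    hp_rows[[length(hp_rows) + 1L]] <- data.frame(
      mirna_id = sprintf("mirS%02d", length(hp_rows) + 1L),
      chrom = as.character(seqnames(it)), start = s, end = s + hp_w - 1L,
      strand = as.character(strand(it)), context = "intronic",
      host_transcript = it$transcript_id)
  }

  tx_df <- do.call(rbind, tx_meta)
  utr3_hosts <- tx_df$transcript_id[seq_len(n_utr3_mirna)]
  for (txi in utr3_hosts) {
    u3 <- annotation$utr3[[txi]]
    u3 <- u3[which.max(width(u3))]
    lo <- start(u3) + 30L
    hi <- end(u3) - 30L - hp_w + 1L
    s <- sample(lo:hi, 1)
    hp_rows[[length(hp_rows) + 1L]] <- data.frame(
      mirna_id = sprintf("mirS%02d", length(hp_rows) + 1L),
      chrom = as.character(seqnames(u3)), start = s, end = s + hp_w - 1L,
      strand = as.character(strand(u3)), context = "utr3",
      host_transcript = txi)
  }

  n_ig <- config$mirna_counts[["intergenic"]]
  big_gaps <- gaps[gaps$end - gaps$start + 1L >= hp_w + 2L * 260L, ]
  if (nrow(big_gaps) < 1 && n_ig > 0)
    stop("sizing error: no intergenic gap can host a hairpin")
  for (i in seq_len(n_ig)) {
    gp <- big_gaps[sample(nrow(big_gaps), 1), ]
    lo <- gp$start + 250L
    hi <- gp$end - 250L - hp_w + 1L
    s <- sample(lo:hi, 1)
    hp_rows[[length(hp_rows) + 1L]] <- data.frame(
      mirna_id = sprintf("mirS%02d", length(hp_rows) + 1L),
      chrom = gp$chrom, start = s, end = s + hp_w - 1L,
      strand = sample(c("+", "-"), 1), context = "intergenic",
      host_transcript = NA_character_)
  }
  hp_df <- do.call(rbind, hp_rows)

  ## ---- genome sequence with stem constructs -------------------------------
  genome <- DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), chrlen[[ch]], replace = TRUE),
          collapse = "")
  }, character(1)))
  names(genome) <- chroms
  for (i in seq_len(nrow(hp_df))) {
    left <- paste(sample(c("A", "C", "G", "T"), arm, replace = TRUE),
                  collapse = "")
    lp <- paste(sample(c("A", "C"), loop, replace = TRUE), collapse = "")
    construct <- DNAString(paste0(
      left, lp, as.character(reverseComplement(DNAString(left)))))
    if (hp_df$strand[i] == "-") construct <- reverseComplement(construct)
    subseq(genome[[hp_df$chrom[i]]], hp_df$start[i], hp_df$end[i]) <- construct
  }

  # mature interval: hairpin-local 5'->3' positions [4, 25]
  mat_start <- ifelse(hp_df$strand == "+", hp_df$start + mature_local[1] - 1L,
                      hp_df$end - mature_local[2] + 1L)
  mat_end <- ifelse(hp_df$strand == "+", hp_df$start + mature_local[2] - 1L,
                    hp_df$end - mature_local[1] + 1L)
  hp_gr <- GRanges(hp_df$chrom, IRanges(hp_df$start, hp_df$end),
                   strand = hp_df$strand)
  names(hp_gr) <- hp_df$mirna_id
  mat_grl <- GRangesList(lapply(seq_len(nrow(hp_df)), function(i)
    GRanges(hp_df$chrom[i], IRanges(mat_start[i], mat_end[i]),
            strand = hp_df$strand[i])))
  names(mat_grl) <- hp_df$mirna_id
  hairpins <- mirna_hairpin_set(hp_gr, mat_grl)

  ## ---- repeats and piRNA clusters -----------------------------------------
  rep_n <- 25L
  rep_chrom <- sample(chroms, rep_n, replace = TRUE,
                      prob = chrlen / sum(chrlen))
  rep_w <- sample(150:800, rep_n, replace = TRUE)
  rep_s <- vapply(seq_len(rep_n), function(i)
    sample(seq_len(chrlen[[rep_chrom[i]]] - rep_w[i]), 1), integer(1))
  repeats <- GRanges(rep_chrom, IRanges(rep_s, width = rep_w),
                     strand = sample(c("+", "-"), rep_n, replace = TRUE),
                     name = sample(c("LINE1", "LTR", "SINE"), rep_n,
                                   replace = TRUE, prob = c(.5, .3, .2)))
  clus_gaps <- gaps[gaps$end - gaps$start + 1L >= 6000, ]
  n_clus <- min(3L, nrow(clus_gaps))
  clusters <- GRanges()
  if (n_clus > 0) {
    rows <- clus_gaps[sample(nrow(clus_gaps), n_clus), , drop = FALSE]
    w <- pmin(rows$end - rows$start - 200L, sample(3000:6000, n_clus, replace = TRUE))
    clusters <- GRanges(rows$chrom, IRanges(rows$start + 100L, width = w),
                        strand = "*",
                        name = sprintf("piCluster%02d", seq_len(n_clus)))
  }

  ## ---- planted binding sites ----------------------------------------------
  site_rows <- list()
  cand <- tx_df[tx_df$utr3_len >= 120, ]
  wts <- cand$utr3_len ^ config$binding$utr3_bias_exponent
  for (i in seq_len(config$binding$n_utr3_sites)) {
    txi <- cand$transcript_id[sample(nrow(cand), 1, prob = wts)]
    u3 <- annotation$utr3[[txi]]
    u3 <- u3[which.max(width(u3))]
    pos <- sample((start(u3) + 45L):(end(u3) - 45L), 1)
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(u3)), pos = pos,
      strand = as.character(strand(u3)), kind = "utr3",
      lo = start(u3), hi = end(u3), offset3ss = NA_integer_,
      transcript_id = txi)
  }
  intr_site_pool <- introns_flat[width(introns_flat) >= 300]
  n_is <- min(config$binding$n_intron_sites, length(intr_site_pool))
  ipick <- sample(seq_along(intr_site_pool), n_is)
  for (i in seq_len(n_is)) {
    it <- intr_site_pool[ipick[i]]
    w <- width(it)
    o <- round(rnorm(1, config$binding$splice_offset_mean,
                     config$binding$splice_offset_sd))
    o <- max(45L, min(as.integer(o), w - 45L))
    pos <- if (as.character(strand(it)) == "+") end(it) - o + 1L
           else start(it) + o - 1L
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(it)), pos = pos,
      strand = as.character(strand(it)), kind = "intron",
      lo = start(it), hi = end(it), offset3ss = as.integer(o),
      transcript_id = it$transcript_id)
  }
  sites <- do.call(rbind, site_rows)
  sites <- sites[!duplicated(sites[, c("chrom", "pos", "strand")]), ]
  sites$site_id <- sprintf("siteS%03d", seq_len(nrow(sites)))

  ## ---- planted expression / retention parameters --------------------------
  mir_ids <- hp_df$mirna_id
  control <- runif(length(mir_ids), config$mirna$control_levels[1],
                   config$mirna$control_levels[2])
  fold <- sample_from(config$mirna$fold_choices, length(mir_ids),
                      prob = config$mirna$fold_weights)
  mirna_levels <- data.frame(mirna_id = mir_ids, control = control,
                             fold = fold, knockdown = control * fold)

  intron_df <- data.frame(
    intron_id = sprintf("%s.i%d", introns_flat$transcript_id,
                        unlist(lapply(lengths(annotation$introns), seq_len))),
    transcript_id = introns_flat$transcript_id,
    chrom = as.character(seqnames(introns_flat)),
    start = start(introns_flat), end = end(introns_flat),
    strand = as.character(strand(introns_flat)), width = width(introns_flat))
  host_mir <- rep(NA_character_, nrow(intron_df))
  hp_intr <- hp_df[hp_df$context == "intronic", ]
  for (i in seq_len(nrow(hp_intr))) {
    j <- which(intron_df$chrom == hp_intr$chrom[i] &
               intron_df$start <= hp_intr$start[i] &
               intron_df$end >= hp_intr$end[i])
    host_mir[j] <- hp_intr$mirna_id[i]
  }
  intron_df$host_mirna <- host_mir
  intron_df$mirtron <- !is.na(host_mir)
  bg <- rep_len(config$pir$background, sum(!intron_df$mirtron))
  intron_df$pir_control <- ifelse(intron_df$mirtron, config$pir$mirtron_control, NA)
  intron_df$pir_knockdown <- ifelse(intron_df$mirtron, config$pir$mirtron_knockdown, NA)
  intron_df$pir_control[!intron_df$mirtron] <- bg
  intron_df$pir_knockdown[!intron_df$mirtron] <- bg

  gene_levels <- data.frame(
    gene_id = tx_df$gene_id,
    level = runif(n_genes, config$rnaseq$gene_level[1], config$rnaseq$gene_level[2]))

  truth <- list(
    transcripts = tx_df, hairpins = hp_df, binding_sites = sites,
    mirna_levels = mirna_levels, introns = intron_df,
    gene_levels = gene_levels)
  structure(list(genome = genome, annotation = annotation,
                 hairpins = hairpins,
                 context = setNames(hp_df$context, hp_df$mirna_id),
                 repeats = repeats, clusters = clusters,
                 truth = truth, config = config),
            class = "TargetomeSim")
}

#' @export
print.TargetomeSim <- function(x, ...) {
  cat("TargetomeSim: ", sum(lengths(x$genome)), " nt genome, ",
      nrow(x$truth$transcripts), " genes, ", length(x$hairpins$hairpins),
      " hairpins (", paste(names(table(x$context)), table(x$context),
                           sep = ":", collapse = ", "),
      "), ", nrow(x$truth$binding_sites), " planted sites\n", sep = "")
  invisible(x)
}

# map a transcript-coordinate interval [from, to] (1-based, 5'->3') to
# genomic intervals over sorted exons
tx_to_genomic <- function(exons_sorted, strand, from, to) {
  w <- width(exons_sorted)
  n <- length(exons_sorted)
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  b <- cumsum(w[ord]); a <- b - w[ord] + 1L
  pieces <- list()
  for (k in seq_len(n)) {
    f <- max(from, a[k]); t <- min(to, b[k])
    if (f > t) next
    j <- ord[k]
    gs <- start(exons_sorted)[j]; ge <- end(exons_sorted)[j]
    if (strand == "+") {
      pieces[[length(pieces) + 1L]] <- c(gs + (f - a[k]), gs + (t - a[k]))
    } else {
      pieces[[length(pieces) + 1L]] <- c(ge - (t - a[k]), ge - (f - a[k]))
    }
  }
  m <- do.call(rbind, pieces)
  sort(GRanges(as.character(seqnames(exons_sorted))[1],
               IRanges(m[, 1], m[, 2]), strand = strand))
}
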