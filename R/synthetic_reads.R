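#' Simulate CLIP alignments with crosslink deletions
#'
#' Three read classes are produced, in configurable proportions:
#' \itemize{
#'   \item site-derived reads placed around planted binding sites, with a
#'     deletion of `deletion_len` nt written into the CIGAR exactly at the
#'     planted position with probability `deletion_prob` (the site always
#'     falls in the read interior, flanked by match segments, and the read
#'     stays within the site's host region so its true region label is known
#'     by construction);
#'   \item hairpin-window reads constructed to satisfy exactly one of the
#'     five positional categories I-V relative to a miRNA hairpin;
#'   \item background reads placed wholly inside single labelled pieces of
#'     the transcribed regions.
#' }
#' Reads are split uniformly across three CLIP replicate libraries.
#'
#' @param sim a `TargetomeSim` from [generate_genome()].
#' @param config optional override; defaults to `sim$config`.
#' @return list with `reads` (`GAlignments`) and `truth` (data.frame:
#'   read_id, class, site_id, mirna_id, category, region, has_deletion,
#'   del_start, del_end).
#' @export
simulate_clip_reads <- function(sim, config = sim$config) {
  validate_config(config)
  set.seed(stage_seed(config, "clip"))
  cl <- config$clip
  n <- cl$n_reads
  n_site <- round(n * cl$site_fraction)
  n_hp <- round(n * cl$hairpin_fraction)
  n_bg <- n - n_site - n_hp
  lmin <- cl$read_length[1]; lmax <- cl$read_length[2]
  dl <- as.integer(cl$deletion_len)

  sites <- sim$truth$binding_sites
  if (n_site > 0 && nrow(sites) == 0)
    stop("no planted binding sites available for site-derived reads")
  df_site <- NULL
  if (n_site > 0) {
    s <- sites[sample(nrow(sites), n_site, replace = TRUE), ]
    len <- sample(lmin:lmax, n_site, replace = TRUE)
    del <- runif(n_site) < cl$deletion_prob
    span <- len + ifelse(del, dl, 0L)
    d_lo <- pmax(2L, s$pos + span - s$hi)
    d_hi <- pmin(span - dl, s$pos - s$lo + 1L)
    d <- d_lo + floor(runif(n_site) * pmax(1L, d_hi - d_lo + 1L))
    d <- pmin(d, pmax(d_lo, d_hi))
    rstart <- s$pos - d + 1L
    cig <- ifelse(del, sprintf("%dM%dD%dM", d - 1L, dl, span - d - dl + 1L),
                  sprintf("%dM", span))
    df_site <- data.frame(
      chrom = s$chrom, start = rstart, cigar = cig, strand = s$strand,
      class = "site", site_id = s$site_id, mirna_id = NA_character_,
      category = NA_character_, region = s$kind, has_deletion = del,
      del_start = ifelse(del, s$pos, NA_integer_),
      del_end = ifelse(del, s$pos + dl - 1L, NA_integer_))
  }

  hp <- sim$truth$hairpins
  mat <- sim$hairpins$mature
  cw <- cl$category_weights / sum(cl$category_weights)
  df_hp <- NULL
  if (n_hp > 0) {
    j <- sample(nrow(hp), n_hp, replace = TRUE)
    cat_i <- sample(names(cw), n_hp, replace = TRUE, prob = cw)
    placed <- t(vapply(seq_len(n_hp), function(q) {
      m <- mat[[hp$mirna_id[j[q]]]][1]
      place_category_read(cat_i[q], hp$start[j[q]], hp$end[j[q]],
                          start(m), end(m), lmin, lmax)
    }, numeric(2)))
    df_hp <- data.frame(
      chrom = hp$chrom[j], start = as.integer(placed[, 1]),
      cigar = sprintf("%dM", as.integer(placed[, 2])),
      strand = hp$strand[j], class = "hairpin", site_id = NA_character_,
      mirna_id = hp$mirna_id[j], category = cat_i, region = NA_character_,
      has_deletion = FALSE, del_start = NA_integer_, del_end = NA_integer_)
  }

  df_bg <- NULL
  if (n_bg > 0) {
    idx <- region_index(sim$annotation)
    pieces <- idx[width(idx) >= lmax + 20L]
    pi <- sample(length(pieces), n_bg, replace = TRUE, prob = width(pieces))
    len <- sample(lmin:lmax, n_bg, replace = TRUE)
    room <- width(pieces)[pi] - len + 1L
    rstart <- start(pieces)[pi] + floor(runif(n_bg) * room)
    df_bg <- data.frame(
      chrom = as.character(seqnames(pieces))[pi], start = rstart,
      cigar = sprintf("%dM", len), strand = as.character(strand(pieces))[pi],
      class = "background", site_id = NA_character_,
      mirna_id = NA_character_, category = NA_character_,
      region = pieces$region[pi], has_deletion = FALSE,
      del_start = NA_integer_, del_end = NA_integer_)
  }

  df <- rbind(df_site, df_hp, df_bg)
  df$read_id <- sprintf("clip%05d", seq_len(nrow(df)))
  df$library <- sample(c("CLIP1", "CLIP2", "CLIP3"), nrow(df), replace = TRUE)
  reads <- make_galignments(df$chrom, df$start, df$cigar, df$strand,
                            df$read_id, df$library,
                            seqlengths = config$chrom_lengths)
  list(reads = reads,
       truth = df[, c("read_id", "library", "class", "site_id", "mirna_id",
                      "category", "region", "has_deletion", "del_start",
                      "del_end")])
}

# construct (start, length) of a plain-match read that falls into a given
# positional category relative to hairpin [hs, he] and mature [ms, me]
place_category_read <- function(category, hs, he, ms, me, lmin, lmax) {
  pick <- function(lo, hi) if (hi > lo) sample(lo:hi, 1) else lo
  switch(category,
    I = {
      # the mature interval itself, optionally with 1 nt excess on one end
      if (runif(1) < 0.5) c(ms, me - ms + 1L)
      else if (runif(1) < 0.5) c(ms - 1L, me - ms + 2L)
      else c(ms, me - ms + 2L)
    },
    II = {
      len <- pick(lmin, min(35L, he - hs + 1L))
      s <- pick(max(hs, ms - len + 1L), min(me, he - len + 1L))
      c(s, len)
    },
    III = {
      # inside the hairpin, 3' of the mature arm (the only mature-free space)
      glo <- if (me < he - 25L) me + 1L else hs          # mature on 5' arm
      ghi <- if (me < he - 25L) he else ms - 1L
      len <- pick(lmin, min(lmax, ghi - glo + 1L - 2L))
      s <- pick(glo, ghi - len + 1L)
      c(s, len)
    },
    IV = {
      len <- pick(lmin, lmax)
      o <- pick(2L, min(15L, len - 2L))
      if (runif(1) < 0.5) c(hs + o - 1L - len + 1L, len)   # straddle 5' edge
      else c(he - o + 1L, len)                              # straddle 3' edge
    },
    V = {
      len <- pick(lmin, min(lmax, 90L))
      if (runif(1) < 0.5) c(pick(hs - 100L, hs - 1L - len + 1L), len)
      else c(pick(he + 1L, he + 100L - len + 1L), len)
    },
    stop("unknown category ", category))
}

#' Simulate an RNA-seq library for one condition
#'
#' Emulates the read populations the window-density and splicing analyses
#' consume:
#' \itemize{
#'   \item per miRNA, `Poisson(level * reads_per_level)` reads placed to
#'     overlap the hairpin +/-200 nt window (these are the primary-transcript
#'     signal; for an intron-hosted miRNA they double as retention evidence
#'     for the host intron). Reads fully contained in the pre-miRNA would be
#'     removed by library size selection; with 100-nt reads and ~80-nt
#'     hairpins none arise, but the filter is applied regardless;
#'   \item for each intron-hosted miRNA, exclusion (junction-spanning) reads
#'     in the proportion implied by the planted retention fraction;
#'   \item for every other intron, `n_informative` reads split between
#'     intron-internal (retention) and exact junction-spanning (exclusion)
#'     reads by the planted retention fraction;
#'   \item exon-internal background reads per gene, proportional to the
#'     planted gene level.
#' }
#'
#' @param sim a `TargetomeSim`.
#' @param condition `"control"` or `"knockdown"`.
#' @param config optional override; defaults to `sim$config`.
#' @return list with `reads` (`GAlignments`, library id =
#'   `paste0("RNA_", condition)`) and `library_size` (read count).
#' @export
simulate_rnaseq <- function(sim, condition = c("control", "knockdown"),
                            config = sim$config) {
  condition <- match.arg(condition)
  validate_config(config)
  set.seed(stage_seed(config, paste0("rnaseq_", condition)))
  rl <- config$rnaseq$read_length
  chrlen <- config$chrom_lengths
  rows <- list()

  add <- function(chrom, start, cigar, strand) {
    if (length(start) == 0) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(start), cigar = cigar,
      strand = strand, stringsAsFactors = FALSE)
  }

  hp <- sim$truth$hairpins
  lev <- sim$truth$mirna_levels
  lev_now <- if (condition == "control") lev$control else lev$knockdown
  intr <- sim$truth$introns
  for (j in seq_len(nrow(hp))) {
    w0 <- hp$start[j] - 200L; w1 <- hp$end[j] + 200L
    n_w <- rpois(1, lev_now[j] * config$rnaseq$reads_per_level)
    if (n_w > 0) {
      lo <- max(1L, w0 - rl + 1L)
      hi <- min(chrlen[[hp$chrom[j]]] - rl + 1L, w1)
      s <- sample(lo:hi, n_w, replace = TRUE)
      # library size selection: drop anything fully inside the hairpin
      inside <- s >= hp$start[j] & (s + rl - 1L) <= hp$end[j]
      add(hp$chrom[j], s[!inside], sprintf("%dM", rl), hp$strand[j])
    }
    if (hp$context[j] == "intronic") {
      it <- intr[!is.na(intr$host_mirna) & intr$host_mirna == hp$mirna_id[j], ]
      p <- if (condition == "control") it$pir_control else it$pir_knockdown
      n_exc <- rpois(1, lev_now[j] * config$rnaseq$reads_per_level * (1 - p) / p)
      if (n_exc > 0) {
        a <- sample(20:(rl - 20L), n_exc, replace = TRUE)
        add(it$chrom, it$start - a,
            sprintf("%dM%dN%dM", a, it$width, rl - a), it$strand)
      }
    }
  }

  bg_intr <- intr[!intr$mirtron, ]
  for (j in seq_len(nrow(bg_intr))) {
    it <- bg_intr[j, ]
    p <- if (condition == "control") it$pir_control else it$pir_knockdown
    n_inf <- config$rnaseq$n_informative
    n_ret <- rbinom(1, n_inf, p)
    if (n_ret > 0 && it$width >= rl)
      add(it$chrom, sample(it$start:(it$end - rl + 1L), n_ret, replace = TRUE),
          sprintf("%dM", rl), it$strand)
    n_exc <- n_inf - n_ret
    if (n_exc > 0) {
      a <- sample(20:(rl - 20L), n_exc, replace = TRUE)
      add(it$chrom, it$start - a,
          sprintf("%dM%dN%dM", a, it$width, rl - a), it$strand)
    }
  }

  gl <- sim$truth$gene_levels
  ann <- sim$annotation
  for (j in seq_len(nrow(gl))) {
    txs <- ann$transcripts$transcript_id[ann$transcripts$gene_id == gl$gene_id[j]]
    ex <- unlist(ann$exons[txs])
    ex <- ex[width(ex) >= rl]
    if (length(ex) == 0) next
    n_g <- rpois(1, gl$level[j] * config$rnaseq$gene_reads_per_level)
    if (n_g == 0) next
    pickex <- sample(length(ex), n_g, replace = TRUE, prob = width(ex) - rl + 1L)
    off <- floor(runif(n_g) * (width(ex)[pickex] - rl + 1L))
    add(as.character(seqnames(ex))[pickex], start(ex)[pickex] + off,
        sprintf("%dM", rl), as.character(strand(ex))[pickex])
  }

  df <- do.call(rbind, rows)
  lib <- paste0("RNA_", condition)
  df$read_id <- sprintf("%s_%06d", lib, seq_len(nrow(df)))
  reads <- make_galignments(df$chrom, df$start, df$cigar, df$strand,
                            df$read_id, rep(lib, nrow(df)),
                            seqlengths = chrlen)
  list(reads = reads, library_size = length(reads))
}

#' Simulate a small-RNA library for one condition
#'
#' Per-miRNA read counts are multinomial around the planted mature levels
#' for the condition; read lengths follow the configured distribution
#' (peaked at 21-25 nt); sequences start at the mature 5' end.
#'
#' @param sim a `TargetomeSim`.
#' @param condition `"control"` or `"knockdown"`.
#' @param config optional override.
#' @return data.frame: `read_id`, `mirna_id`, `length`, `sequence`,
#'   `library`.
#' @export
simulate_small_rna <- function(sim, condition = c("control", "knockdown"),
                               config = sim$config) {
  condition <- match.arg(condition)
  validate_config(config)
  set.seed(stage_seed(config, paste0("smallrna_", condition)))
  lev <- sim$truth$mirna_levels
  lev_now <- if (condition == "control") lev$control else lev$knockdown
  bg_level <- config$smallrna$background_weight * sum(lev$control)
  if (sum(lev_now) + bg_level == 0)
    return(data.frame(read_id = character(), mirna_id = character(),
                      length = integer(), sequence = character(),
                      library = character()))
  counts <- as.integer(rmultinom(1, config$smallrna$n_reads,
                                 prob = c(lev_now, bg_level)))
  n_bg <- counts[length(counts)]
  counts <- counts[-length(counts)]
  total <- sum(counts)
  mir <- rep(lev$mirna_id, counts)
  lens <- sample_from(config$smallrna$lengths, total,
                      prob = config$smallrna$length_weights)
  hp <- sim$truth$hairpins
  mat5 <- 4L  # mature starts at hairpin-local position 4
  hpseqs <- vapply(seq_len(nrow(hp)), function(j) {
    s <- subseq(sim$genome[[hp$chrom[j]]], hp$start[j], hp$end[j])
    if (hp$strand[j] == "-") s <- reverseComplement(s)
    as.character(s)
  }, character(1))
  names(hpseqs) <- hp$mirna_id
  seqs <- substr(hpseqs[mir], mat5, mat5 + lens - 1L)
  # constant piRNA-like background, longer (26-31 nt) and condition-invariant
  if (n_bg > 0) {
    bg_lens <- sample_from(config$smallrna$bg_lengths, n_bg,
                           prob = config$smallrna$bg_length_weights)
    bg_seqs <- vapply(bg_lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    mir <- c(mir, rep(NA_character_, n_bg))
    lens <- c(lens, bg_lens)
    seqs <- c(unname(seqs), bg_seqs)
    total <- total + n_bg
  } else seqs <- unname(seqs)
  data.frame(read_id = sprintf("sm_%s_%05d", condition, seq_len(total)),
             mirna_id = mir, length = as.integer(lens),
             sequence = seqs,
             library = paste0("smallRNA_", condition))
}

#' Write a simulation to standard-format files
#'
#' Emits genome FASTA, gene-model GTF, miRBase-style miRNA GFF3, repeat and
#' piRNA-cluster BED6, and the planted truth as JSON. Everything is
#' plain text, deterministic for a given config (byte-identical reruns).
#'
#' @param sim a `TargetomeSim`.
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(outdir, "genome.fa"),
    gtf = file.path(outdir, "genes.gtf"),
    mirna = file.path(outdir, "mirna.gff3"),
    repeats = file.path(outdir, "repeats.bed"),
    clusters = file.path(outdir, "clusters.bed"),
    truth = file.path(outdir, "truth.json"))
  writeXStringSet(sim$genome, paths[["genome"]])
  write_gtf(sim$annotation, paths[["gtf"]])
  write_mirna_gff(sim$hairpins, paths[["mirna"]])
  rtracklayer::export(sim$repeats, paths[["repeats"]], format = "BED")
  rtracklayer::export(sim$clusters, paths[["clusters"]], format = "BED")
  jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
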