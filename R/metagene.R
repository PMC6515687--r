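#' Genomic region distribution of reads
#'
#' Assigns each read one label from {utr5, cds, utr3, intron, intergenic}
#' by the majority of its aligned reference bases (ties broken by the
#' precedence CDS > 3'UTR > 5'UTR > intron), then tabulates per-library
#' fractions.
#'
#' @param reads `GAlignments` with mcol `library`.
#' @param annotation a `GenomeAnnotation`.
#' @return list with `labels` (character per read) and `distribution`
#'   (data.frame: library, region, n, fraction; fractions sum to 1 per
#'   library).
#' @export
classify_read_regions <- function(reads, annotation) {
  idx <- region_index(annotation)
  labs <- region_labels(annotation, aligned_blocks(reads), majority = TRUE,
                        idx = idx)
  dt <- data.table::data.table(library = mcols(reads)$library,
                               region = factor(labs, levels = REGION_LABELS))
  dist <- dt[, list(n = .N), by = c("library", "region")]
  dist[, "fraction" := n / sum(n), by = "library"]
  list(labels = labs,
       distribution = as.data.frame(dist[order(dist$library, dist$region)]))
}

#' Metagene coverage profile over 5'-UTR, CDS and 3'-UTR
#'
#' Scans read depth along each selected transcript, rescales each of its
#' three mRNA regions to `bins` bins in 5' to 3' transcript orientation
#' (minus-strand transcripts are flipped), sums across transcripts, and
#' normalizes the concatenated `3*bins` curve to unit area. Transcripts
#' missing a region contribute only to the regions they have.
#'
#' @param reads `GAlignments`.
#' @param annotation a `GenomeAnnotation`.
#' @param transcripts character vector of transcript ids (default: all
#'   coding transcripts).
#' @param bins bins per region (default 100).
#' @param per_transcript_normalize divide each transcript's depth by its
#'   own total before summation (default FALSE).
#' @return data.frame: `region` (utr5/cds/utr3), `bin` (1..bins), `depth`.
#' @export
region_coverage_profile <- function(reads, annotation, transcripts = NULL,
                                    bins = 100, per_transcript_normalize = FALSE) {
  tx <- annotation$transcripts
  transcripts <- transcripts %||% tx$transcript_id[tx$cds_length > 0]
  if (length(transcripts) == 0) stop("empty transcript set")
  cov_by_strand <- list(
    "+" = GenomicRanges::coverage(aligned_blocks(reads[strand(reads) == "+"])),
    "-" = GenomicRanges::coverage(aligned_blocks(reads[strand(reads) == "-"])))
  acc <- matrix(0, nrow = 3, ncol = bins,
                dimnames = list(c("utr5", "cds", "utr3"), NULL))
  for (id in transcripts) {
    strand_t <- tx$strand[tx$transcript_id == id]
    cov <- cov_by_strand[[strand_t]]
    tx_depth <- list()
    for (reg in rownames(acc)) {
      gr <- annotation[[reg]][[id]]
      if (is.null(gr) || length(gr) == 0) { tx_depth[[reg]] <- NULL; next }
      gr <- sort(gr)
      v <- unlist(lapply(seq_along(gr), function(i) {
        cov_window(cov, as.character(seqnames(gr))[i], start(gr)[i], end(gr)[i])
      }))
      if (strand_t == "-") v <- rev(v)
      tx_depth[[reg]] <- bin_means(v, bins)
    }
    if (per_transcript_normalize) {
      tot <- sum(unlist(tx_depth))
      if (tot > 0) tx_depth <- lapply(tx_depth, function(v) v / tot)
    }
    for (reg in names(tx_depth))
      if (!is.null(tx_depth[[reg]])) acc[reg, ] <- acc[reg, ] + tx_depth[[reg]]
  }
  total <- sum(acc)
  if (total > 0) acc <- acc / total
  data.frame(region = rep(rownames(acc), each = bins),
             bin = rep(seq_len(bins), 3), depth = as.numeric(t(acc)))
}

# mean depth per bin after rescaling a length-L vector to `bins` bins;
# when L < bins each bin samples the base covering its midpoint, so short
# regions upsample instead of leaving empty bins
bin_means <- function(v, bins) {
  L <- length(v)
  if (L >= bins) {
    idx <- floor((seq_along(v) - 1L) * bins / L) + 1L
    as.numeric(tapply(v, factor(idx, levels = seq_len(bins)), mean,
                      default = 0))
  } else {
    pos <- floor((seq_len(bins) - 0.5) * L / bins) + 1L
    as.numeric(v[pmin(pos, L)])
  }
}

# coverage over [lo, hi] on one chromosome, zero-padded outside the Rle
cov_window <- function(cov, chrom, lo, hi) {
  out <- numeric(hi - lo + 1L)
  if (!chrom %in% names(cov)) return(out)
  rle <- cov[[chrom]]
  ok_lo <- max(1L, lo); ok_hi <- min(length(rle), hi)
  if (ok_hi >= ok_lo)
    out[(ok_lo - lo + 1L):(ok_hi - lo + 1L)] <-
      as.numeric(S4Vectors::window(rle, ok_lo, ok_hi))
  out
}

#' Tercile partition by 3'-UTR length
#'
#' Sorts transcripts by decreasing 3'-UTR length (ties by transcript id)
#' and splits the ranking into three contiguous groups as equal as
#' possible; the remainder goes to the short group, the only assignment
#' consistent with the published split of 32,617 transcripts into
#' 10,872 / 10,872 / 10,873.
#'
#' @param utr3_length named numeric vector (names = transcript ids) or a
#'   `GenomeAnnotation` (its coding transcripts are used).
#' @return list with `group` (named factor long/medium/short in rank
#'   order), `sizes`, and `members` (list of id vectors).
#' @export
tercile_partition <- function(utr3_length) {
  if (is(utr3_length, "GenomeAnnotation")) {
    tx <- utr3_length$transcripts
    utr3_length <- setNames(tx$utr3_length, tx$transcript_id)
  }
  n <- length(utr3_length)
  if (n < 3) stop("at least 3 transcripts required for a tercile partition")
  ord <- order(-utr3_length, names(utr3_length))
  base <- n %/% 3L
  sizes <- c(long = base, medium = base, short = base + n %% 3L)
  group <- factor(rep(names(sizes), sizes), levels = names(sizes))
  names(group) <- names(utr3_length)[ord]
  list(group = group, sizes = sizes,
       members = split(names(group), group))
}

#' Read overlap with an interval set (repeats, piRNA clusters)
#'
#' A read overlaps when at least one aligned base intersects any interval;
#' attribution goes to the interval with the largest overlap (ties: first
#' interval in file order).
#'
#' @param reads `GAlignments`.
#' @param intervals `GRanges`, e.g. imported from BED; an mcol `name`
#'   provides the family/cluster label.
#' @param stranded require same-strand overlap (default FALSE: repeat and
#'   cluster annotations are commonly unstranded).
#' @return list: `fraction` overlapping, `n_overlapping`, `per_family`
#'   (data.frame family/n), `per_interval` (counts in `intervals` order).
#' @export
interval_overlap_summary <- function(reads, intervals, stranded = FALSE) {
  blocks <- aligned_blocks(reads)
  hits <- findOverlaps(blocks, intervals, ignore.strand = !stranded)
  if (length(hits) == 0) {
    fam <- data.frame(family = character(), n = integer())
    return(list(fraction = 0, n_overlapping = 0L, per_family = fam,
                per_interval = integer(length(intervals))))
  }
  ov <- vapply(seq_along(hits), function(i) {
    sum(width(GenomicRanges::intersect(
      blocks[[queryHits(hits)[i]]],
      granges(intervals)[subjectHits(hits)[i]], ignore.strand = !stranded)))
  }, numeric(1))
  dt <- data.table::data.table(read = queryHits(hits),
                               interval = subjectHits(hits), w = ov)
  data.table::setorderv(dt, c("read", "w", "interval"), order = c(1L, -1L, 1L))
  best <- dt[!duplicated(dt$read), ]
  fam_names <- intervals$name %||% as.character(seq_along(intervals))
  per_interval <- tabulate(best$interval, nbins = length(intervals))
  fam <- data.table::data.table(family = fam_names[best$interval])[
    , list(n = .N), by = "family"]
  list(fraction = nrow(best) / length(reads),
       n_overlapping = nrow(best),
       per_family = as.data.frame(fam[order(-fam$n)]),
       per_interval = per_interval)
}
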