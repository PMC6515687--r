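#' Count intron retention vs exclusion evidence
#'
#' Exclusion evidence: reads whose alignment skips exactly this intron
#' (an N segment with both boundaries on the intron's). Retention
#' evidence: reads overlapping the intron interior by at least
#' `min_overlap` aligned nt (default 6, so junction-adjacent exonic reads
#' do not count) without skipping it.
#'
#' @param reads `GAlignments`.
#' @param intron width-1+ `GRanges` of the intron (single interval).
#' @param annotation a `GenomeAnnotation`; used to check the intron is
#'   bounded by annotated exons.
#' @param min_overlap minimum intron-interior overlap for retention
#'   evidence (default 6 nt).
#' @return named integer vector c(retention =, exclusion =).
#' @export
count_isoform_evidence <- function(reads, intron, annotation,
                                   min_overlap = 6) {
  stopifnot(is(intron, "GRanges"), length(intron) == 1)
  known <- unlist(annotation$introns)
  if (countOverlaps(intron, known, type = "equal", ignore.strand = FALSE) == 0)
    stop("validation error: interval is not an annotated intron ",
         "(not flanked by exons)")
  jx <- junctions(reads)
  jflat <- unlist(jx, use.names = FALSE)
  jgrp <- rep(seq_along(reads), lengths(jx))
  skip <- logical(length(reads))
  hitj <- jgrp[start(jflat) == start(intron) & end(jflat) == end(intron) &
                 as.character(seqnames(jflat)) == as.character(seqnames(intron))]
  skip[hitj] <- TRUE
  same_strand <- as.character(strand(reads)) == as.character(strand(intron))
  exclusion <- sum(skip & same_strand)
  blocks <- aligned_blocks(reads)
  flat <- unlist(blocks, use.names = FALSE)
  grp <- rep(seq_along(reads), lengths(blocks))
  sel <- as.character(seqnames(flat)) == as.character(seqnames(intron))
  ovw_flat <- pmax(0L, pmin(end(flat), end(intron)) -
                     pmax(start(flat), start(intron)) + 1L)
  ovw <- numeric(length(reads))
  agg <- rowsum(ovw_flat[sel], grp[sel])
  ovw[as.integer(rownames(agg))] <- agg[, 1]
  retention <- sum(ovw >= min_overlap & !skip & same_strand)
  c(retention = as.integer(retention), exclusion = as.integer(exclusion))
}

#' Percent intron retention
#'
#' `PIR = 100 * retention / (retention + exclusion)`; undefined (NA) when
#' both counts are zero.
#'
#' @param retention,exclusion non-negative evidence counts (vectorized).
#' @return numeric PIR in `[0, 100]`, NA where undefined.
#' @export
compute_pir <- function(retention, exclusion) {
  stopifnot(all(retention >= 0), all(exclusion >= 0))
  tot <- retention + exclusion
  ifelse(tot > 0, 100 * retention / tot, NA_real_)
}

#' Relative whole transcript level of a mirtron host across conditions
#'
#' Ratio of library-size-normalized (per-million) totals of retention plus
#' exclusion evidence, knockdown over control. NA when the control total
#' is zero.
#'
#' @param counts_control,counts_knockdown vectors `c(retention, exclusion)`
#'   from [count_isoform_evidence()].
#' @param lib_control,lib_knockdown library sizes (total mapped reads).
#' @return numeric ratio (knockdown / control).
#' @export
mirtron_transcript_change <- function(counts_control, counts_knockdown,
                                      lib_control, lib_knockdown) {
  tc <- sum(counts_control) / (lib_control / 1e6)
  tk <- sum(counts_knockdown) / (lib_knockdown / 1e6)
  if (tc == 0) return(NA_real_)
  tk / tc
}

#' Long-isoform ratio from isoform-specific vs shared region coverage
#'
#' Long-isoform evidence is the mean per-base read depth over the region
#' unique to the long isoform; short-isoform evidence is the mean depth
#' over the region shared by both isoforms minus the long evidence,
#' floored at zero. The ratio long/(long+short) estimates the fraction of
#' transcripts carrying the long 3'-UTR.
#'
#' @param reads `GAlignments`.
#' @param unique_region `GRanges` present only in the long isoform.
#' @param shared_region `GRanges` common to both isoforms.
#' @return list: `long`, `short` (mean depths), `ratio` in `[0,1]`
#'   (NA when total evidence is zero).
#' @export
long_isoform_ratio <- function(reads, unique_region, shared_region) {
  if (length(unique_region) == 0 || sum(width(unique_region)) == 0)
    stop("validation error: empty long-isoform-specific region")
  mean_depth <- function(region) {
    st <- as.character(strand(region))[1]
    cov <- GenomicRanges::coverage(aligned_blocks(reads[strand(reads) == st]))
    tot <- 0
    for (i in seq_along(region)) {
      tot <- tot + sum(cov_window(cov, as.character(seqnames(region))[i],
                                  start(region)[i], end(region)[i]))
    }
    tot / sum(width(region))
  }
  long_ev <- mean_depth(unique_region)
  shared <- mean_depth(shared_region)
  short_ev <- max(shared - long_ev, 0)
  tot <- long_ev + short_ev
  list(long = long_ev, short = short_ev,
       ratio = if (tot > 0) long_ev / tot else NA_real_)
}
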