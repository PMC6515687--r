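#' Collect reads in hairpin-flanking windows
#'
#' Retains every (read, miRNA) pair where the read overlaps the window
#' `[hairpin_start - flank, hairpin_end + flank]` by at least one
#' nucleotide on the same strand. A read near two hairpins is paired with
#' each independently.
#'
#' @param reads `GAlignments`.
#' @param hairpins a `MirnaHairpinSet`.
#' @param flank window extension in nt (default 100).
#' @return data.frame: `read` (index into `reads`), `read_id`, `mirna_id`.
#' @export
collect_hairpin_reads <- function(reads, hairpins, flank = 100) {
  win <- hairpins$hairpins + flank
  hits <- findOverlaps(granges(reads), win, ignore.strand = FALSE,
                       minoverlap = 1L)
  data.frame(read = queryHits(hits),
             read_id = mcols(reads)$read_id[queryHits(hits)],
             mirna_id = names(win)[subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Classify hairpin-window reads into positional categories I-V
#'
#' First matching rule wins, in order:
#' \describe{
#'   \item{I}{read maps to the mature miRNA with no more than 1 nt total
#'     excess sequence beyond the mature boundaries;}
#'   \item{II}{read fully inside the hairpin, overlapping the mature
#'     sequence by >= 1 nt;}
#'   \item{III}{read fully inside the hairpin, no mature overlap;}
#'   \item{IV}{read crossing a hairpin boundary with >= 1 nt inside;}
#'   \item{V}{read entirely outside the hairpin, within the flank window.}
#' }
#' Categories II+III are evidence for the precursor, IV+V for the primary
#' transcript.
#'
#' @param reads `GAlignments`.
#' @param pairs data.frame from [collect_hairpin_reads()].
#' @param hairpins a `MirnaHairpinSet`.
#' @param flank flank used at collection (sanity bound; default 100).
#' @param excess_per_end if TRUE, interpret the 1 nt tolerance of category
#'   I per read end instead of summed over both ends.
#' @return `pairs` with a `category` factor column (levels I-V).
#' @export
classify_mirna_reads <- function(reads, pairs, hairpins, flank = 100,
                                 excess_per_end = FALSE) {
  hp <- hairpins$hairpins
  rs <- start(reads)[pairs$read]
  re <- end(reads)[pairs$read]
  i <- match(pairs$mirna_id, names(hp))
  hs <- start(hp)[i]; he <- end(hp)[i]
  if (any(re < hs - flank | rs > he + flank))
    stop("contract violation: pair whose read does not intersect the flank window")
  # against the first (5') mature interval; multi-mature hairpins use any
  mats <- hairpins$mature[pairs$mirna_id]
  excess <- vapply(seq_len(nrow(pairs)), function(k) {
    m <- mats[[k]]
    e <- pmax(0L, start(m) - rs[k]) + pmax(0L, re[k] - end(m))
    ep <- pmax(pmax(0L, start(m) - rs[k]), pmax(0L, re[k] - end(m)))
    if (excess_per_end) min(ep) else min(e)
  }, numeric(1))
  mat_ov <- vapply(seq_len(nrow(pairs)), function(k) {
    m <- mats[[k]]
    any(rs[k] <= end(m) & re[k] >= start(m))
  }, logical(1))
  inside <- rs >= hs & re <= he
  hp_ov <- rs <= he & re >= hs
  category <- ifelse(excess <= 1, "I",
               ifelse(inside & mat_ov, "II",
                ifelse(inside, "III",
                 ifelse(hp_ov, "IV", "V"))))
  pairs$category <- factor(category, levels = c("I", "II", "III", "IV", "V"))
  pairs
}

#' Call bound miRNA forms from category counts
#'
#' A form is called when its category evidence reaches `min_reads`
#' (default 5): mature from category I, precursor (pre) from II+III,
#' primary (pri) from IV+V. A miRNA may carry zero to three forms.
#'
#' @param categories data.frame from [classify_mirna_reads()].
#' @param min_reads minimum supporting reads per form (default 5).
#' @param mirna_ids optional universe of miRNA ids (so zero-read miRNAs
#'   appear with empty calls).
#' @return data.frame: mirna_id, I..V counts, logical `mature`, `pre`,
#'   `pri`, and a comma-separated `forms` string.
#' @export
call_mirna_forms <- function(categories, min_reads = 5, mirna_ids = NULL) {
  ids <- mirna_ids %||% sort(unique(categories$mirna_id))
  tab <- table(factor(categories$mirna_id, levels = ids),
               factor(categories$category, levels = c("I", "II", "III", "IV", "V")))
  m <- as.matrix(tab)
  out <- data.frame(mirna_id = ids,
                    I = m[, "I"], II = m[, "II"], III = m[, "III"],
                    IV = m[, "IV"], V = m[, "V"], row.names = NULL)
  out$mature <- out$I >= min_reads
  out$pre <- (out$II + out$III) >= min_reads
  out$pri <- (out$IV + out$V) >= min_reads
  out$forms <- apply(out[, c("mature", "pre", "pri")], 1, function(f)
    paste(c("mature", "pre", "pri")[f], collapse = ","))
  out
}

#' Meta-profile of read coverage around hairpin midpoints
#'
#' Per-base coverage in the strand-oriented window `midpoint +/- flank`
#' (the midpoint of an even-length hairpin is `start + floor(width/2)` in
#' hairpin coordinates), summed across hairpins, aggregated into `bins`
#' equal bins and normalized to unit area.
#'
#' @param reads `GAlignments`.
#' @param hairpins a `MirnaHairpinSet`.
#' @param flank half-window (default 200 nt).
#' @param bins number of bins (default 30).
#' @return data.frame: `bin`, `offset_mid` (window offset at bin center),
#'   `depth` (sums to 1 when any coverage exists).
#' @export
hairpin_meta_profile <- function(reads, hairpins, flank = 200, bins = 30) {
  mids <- hairpin_midpoints(hairpins)
  w <- 2L * flank + 1L
  cov_by_strand <- list(
    "+" = GenomicRanges::coverage(aligned_blocks(reads[strand(reads) == "+"])),
    "-" = GenomicRanges::coverage(aligned_blocks(reads[strand(reads) == "-"])))
  acc <- numeric(w)
  for (i in seq_along(mids)) {
    st <- as.character(strand(mids))[i]
    v <- cov_window(cov_by_strand[[st]], as.character(seqnames(mids))[i],
                    start(mids)[i] - flank, start(mids)[i] + flank)
    if (st == "-") v <- rev(v)
    acc <- acc + v
  }
  if (sum(acc) == 0) warning("no read coverage in any hairpin window")
  binned <- bin_means(acc, bins)
  if (sum(binned) > 0) binned <- binned / sum(binned)
  centers <- bin_means(seq(-flank, flank), bins)
  data.frame(bin = seq_len(bins), offset_mid = centers, depth = binned)
}

#' Small-RNA read length histogram
#'
#' @param lengths integer vector of read lengths, or a data.frame with a
#'   `length` column (e.g. from [simulate_small_rna()]).
#' @param mirna_range length range regarded as mature-miRNA sized
#'   (default 21-25 nt).
#' @return list: `histogram` (data.frame length/n/percent, percents sum to
#'   100) and `share` (percent of reads in `mirna_range`).
#' @export
small_rna_length_profile <- function(lengths, mirna_range = c(21, 25)) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (length(lengths) == 0) stop("no small-RNA reads supplied")
  tab <- table(lengths)
  hist <- data.frame(length = as.integer(names(tab)), n = as.integer(tab))
  hist$percent <- 100 * hist$n / sum(hist$n)
  share <- sum(hist$percent[hist$length >= mirna_range[1] &
                            hist$length <= mirna_range[2]])
  list(histogram = hist, share = share)
}
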