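#' Call crosslinked sites from read-level deletions
#'
#' Every genomic base covered by a deletion (`D`) segment of any read is a
#' deletion residue; distinct `(chrom, strand, position)` triples collapse
#' to one crosslinked site whose score is the residue count. With
#' `mode = "event_start"` a multi-nt deletion contributes a single residue
#' at its first deleted base instead of one per base.
#'
#' @param reads `GAlignments` with mcols `read_id`, `library`.
#' @param mode `"per_base"` (default) or `"event_start"`.
#' @return `GRanges` of width-1 sites sorted by position, with mcols
#'   `residues` (supporting deleted bases) and `libraries`
#'   (comma-collapsed contributing library ids); attribute `summary` =
#'   `list(n_sites, n_residues)`.
#' @export
extract_deletion_sites <- function(reads, mode = c("per_base", "event_start")) {
  mode <- match.arg(mode)
  dels <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar(reads), pos = start(reads), ops = "D")
  nper <- lengths(dels)
  flat <- unlist(dels, use.names = FALSE)
  if (length(flat) == 0) {
    out <- GRanges()
    attr(out, "summary") <- list(n_sites = 0L, n_residues = 0L)
    return(out)
  }
  which_read <- rep(seq_along(reads), nper)
  if (mode == "event_start") flat <- IRanges::resize(flat, 1L, fix = "start")
  # expand multi-nt deletions to per-base residues
  per_base <- unlist(IRanges::tile(flat, width = 1L), use.names = FALSE)
  which_read2 <- rep(which_read, width(flat))
  dt <- data.table::data.table(
    chrom = as.character(seqnames(reads))[which_read2],
    pos = start(per_base),
    strand = as.character(strand(reads))[which_read2],
    library = mcols(reads)$library[which_read2])
  n_residues <- nrow(dt)
  agg <- dt[, list(residues = .N,
                   libraries = paste(sort(unique(library)), collapse = ",")),
            by = c("chrom", "pos", "strand")]
  out <- GRanges(agg$chrom, IRanges(agg$pos, width = 1L),
                 strand = agg$strand, residues = agg$residues,
                 libraries = agg$libraries)
  out <- sort(out, ignore.strand = TRUE)
  attr(out, "summary") <- list(n_sites = length(out),
                               n_residues = as.integer(n_residues))
  out
}

#' Strand-oriented sequence windows around anchors
#'
#' Extracts `2*flank + 1` nt windows centered on width-1 anchors; windows
#' on the minus strand are reverse-complemented so that offset -flank is
#' 5' of the anchor. Anchors whose window runs off the chromosome are
#' dropped with a message.
#'
#' @param genome `DNAStringSet` keyed by chromosome.
#' @param anchors width-1 `GRanges`.
#' @param flank half-window size in nt.
#' @return `DNAStringSet` of uniform-width windows; attribute `n_dropped`.
#' @export
extract_windows <- function(genome, anchors, flank = 100) {
  stopifnot(all(width(anchors) == 1))
  lens <- setNames(lengths(genome), names(genome))
  keep <- start(anchors) - flank >= 1 &
    start(anchors) + flank <= lens[as.character(seqnames(anchors))]
  if (any(!keep))
    message(sum(!keep), " anchor(s) dropped: window outside chromosome")
  a <- anchors[keep]
  seqs <- DNAStringSet(vapply(seq_along(a), function(i) {
    as.character(subseq(genome[[as.character(seqnames(a))[i]]],
                        start(a)[i] - flank, start(a)[i] + flank))
  }, character(1)))
  neg <- as.character(strand(a)) == "-"
  if (any(neg)) seqs[neg] <- reverseComplement(seqs[neg])
  attr(seqs, "n_dropped") <- sum(!keep)
  seqs
}

#' Strand-oriented sequences of arbitrary genomic intervals
#'
#' @param genome `DNAStringSet` keyed by chromosome.
#' @param gr `GRanges`; minus-strand intervals are reverse-complemented.
#' @return `DNAStringSet`, named from `names(gr)` when present.
#' @export
get_stranded_sequences <- function(genome, gr) {
  seqs <- DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(subseq(genome[[as.character(seqnames(gr))[i]]],
                        start(gr)[i], end(gr)[i]))
  }, character(1)))
  neg <- as.character(strand(gr)) == "-"
  if (any(neg)) seqs[neg] <- reverseComplement(seqs[neg])
  names(seqs) <- names(gr)
  seqs
}

#' Base composition around crosslinked sites
#'
#' Nucleotide fractions at every offset in `[-flank, +flank]` relative to
#' the site (offset 0 = the deleted base), strand-oriented. Reported in RNA
#' alphabet (T counted as U).
#'
#' @param sites width-1 `GRanges` (e.g. from [extract_deletion_sites()]).
#' @param genome `DNAStringSet`.
#' @param flank half-window (default 100 nt).
#' @return data.frame `offset`, `A`, `C`, `G`, `U`; attribute `n_anchors`.
#' @export
base_composition_profile <- function(sites, genome, flank = 100) {
  if (length(sites) == 0) stop("no sites: base composition profile undefined")
  wins <- extract_windows(genome, sites, flank)
  if (length(wins) == 0) stop("all site windows fell off-chromosome")
  composition_of_windows(wins, offsets = seq(-flank, flank))
}

composition_of_windows <- function(wins, offsets) {
  cm <- consensusMatrix(wins, as.prob = TRUE, baseOnly = TRUE)
  base <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  # renormalize over called bases (robust to rare Ns)
  tot <- colSums(base)
  base <- sweep(base, 2, ifelse(tot > 0, tot, 1), "/")
  out <- data.frame(offset = offsets, A = base["A", ], C = base["C", ],
                    G = base["G", ], U = base["T", ], row.names = NULL)
  attr(out, "n_anchors") <- length(wins)
  out
}

#' Base-pairing potential profile
#'
#' Folds each window with a maximum-base-pairing dynamic program (canonical
#' AU/GC/GU pairs, minimum hairpin loop of `min_loop` unpaired bases) and
#' reports, per offset, the fraction of windows in which that position is
#' paired — a dependency-free proxy for local secondary-structure
#' potential. Deterministic: traceback ties resolve toward the leftmost
#' partner.
#'
#' @param windows `DNAStringSet` of uniform-width, strand-oriented windows
#'   (e.g. [extract_windows()] output anchored at sites or hairpin
#'   midpoints).
#' @param min_loop minimum loop length (default 3).
#' @return data.frame `offset` (centered when width is odd, else 1-based),
#'   `pairing`; attribute `n_windows`.
#' @export
structure_potential_profile <- function(windows, min_loop = 3) {
  if (length(windows) == 0) stop("no windows supplied")
  w <- unique(width(windows))
  if (length(w) != 1) stop("windows must have uniform width")
  if (w < 2 * (min_loop + 1)) stop("window shorter than 2*(min_loop+1)")
  paired <- vapply(as.character(windows), function(s)
    nussinov_partners(s, min_loop) > 0L, logical(w))
  frac <- rowMeans(paired)
  offsets <- if (w %% 2 == 1) seq(-(w - 1) / 2, (w - 1) / 2) else seq_len(w)
  out <- data.frame(offset = offsets, pairing = as.numeric(frac))
  attr(out, "n_windows") <- length(windows)
  out
}

#' Write crosslinked sites as BED6
#'
#' Score column carries the residue count; coordinates follow the BED
#' 0-based half-open convention via rtracklayer.
#'
#' @param sites output of [extract_deletion_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  x <- granges(sites)
  x$name <- sprintf("site%05d", seq_along(x))
  x$score <- sites$residues
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}
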