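#' Map crosslinked sites to splice-site-proximal intron windows
#'
#' Unique introns (per genomic interval, collapsed across transcripts that
#' share them) define two windows: the first `window` nt downstream of the
#' 5' splice site and the last `window` nt upstream of the 3' splice site,
#' measured into the intron with 1-based offsets. Each intronic site is
#' assigned to the nearer side only (tie goes to the 5' side), and each
#' unique genomic position contributes once per histogram; residue counts
#' are accumulated separately.
#'
#' @param sites width-1 `GRanges` from [extract_deletion_sites()] (mcol
#'   `residues` optional, default 1).
#' @param annotation a `GenomeAnnotation`.
#' @param window nt into the intron (default 200).
#' @return list of two data.frames `five_prime` and `three_prime`
#'   (`offset` 1..window, `site_count`, `residue_count`) plus
#'   `n_intronic_sites`.
#' @export
map_crosslinks_to_splice_sites <- function(sites, annotation, window = 200) {
  introns <- unique(granges(unlist(annotation$introns)))
  hits <- findOverlaps(sites, introns, ignore.strand = FALSE)
  res <- sites$residues %||% rep(1L, length(sites))
  empty <- data.frame(offset = seq_len(window), site_count = 0L,
                      residue_count = 0L)
  if (length(hits) == 0)
    return(list(five_prime = empty, three_prime = empty, n_intronic_sites = 0L))
  q <- queryHits(hits); s <- subjectHits(hits)
  plus <- as.character(strand(introns))[s] == "+"
  d5 <- ifelse(plus, start(sites)[q] - start(introns)[s] + 1L,
               end(introns)[s] - start(sites)[q] + 1L)
  d3 <- width(introns)[s] - d5 + 1L
  dt <- data.table::data.table(
    q = q, d5 = d5, d3 = d3,
    pos_key = paste(as.character(seqnames(sites))[q], start(sites)[q],
                as.character(strand(sites))[q]))
  # one assignment per unique genomic position: the nearest junction over
  # all introns containing it
  dt[, "best5" := min(d5), by = "pos_key"]
  dt[, "best3" := min(d3), by = "pos_key"]
  u <- unique(dt[, c("pos_key", "q", "best5", "best3")])
  u <- u[!duplicated(u$pos_key), ]
  to5 <- u$best5 <= u$best3 & u$best5 <= window
  to3 <- u$best3 < u$best5 & u$best3 <= window
  mk <- function(sel, off) {
    data.frame(offset = seq_len(window),
               site_count = tabulate(off[sel], nbins = window),
               residue_count = as.integer(tabulate_weighted(
                 off[sel], res[u$q[sel]], window)))
  }
  list(five_prime = mk(to5, u$best5), three_prime = mk(to3, u$best3),
       n_intronic_sites = nrow(u))
}

tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  keep <- idx >= 1 & idx <= nbins
  if (any(keep)) {
    agg <- rowsum(as.numeric(w[keep]), idx[keep])
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Base composition of junction-flanking windows with intronic-side sites
#'
#' Scans `+/- flank` nt windows around each exon-intron junction, keeps the
#' windows whose intronic half contains at least one crosslinked site, and
#' reports strand-oriented base composition separately for the exonic and
#' intronic halves. Offsets are negative on the exonic side and positive
#' (1-based) on the intronic side.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param sites width-1 `GRanges` of crosslinked sites.
#' @param genome `DNAStringSet`.
#' @param flank half-window (default 100 nt).
#' @return list of data.frames `five_prime` and `three_prime` (columns
#'   offset, A, C, G, U, side = exon/intron) with `n_junctions` attributes.
#' @export
splice_flank_composition <- function(annotation, sites, genome, flank = 100) {
  introns <- unique(granges(unlist(annotation$introns)))
  plus <- as.character(strand(introns)) == "+"
  # junction anchor = first / last intronic base
  j5 <- ifelse(plus, start(introns), end(introns))
  j3 <- ifelse(plus, end(introns), start(introns))
  one_side <- function(anchor, into_sign) {
    # intronic half: offsets 1..flank from the junction, into the intron
    intron_half <- GRanges(seqnames(introns),
                           IRanges(pmin(anchor, anchor + into_sign * (flank - 1L)),
                                   pmax(anchor, anchor + into_sign * (flank - 1L))),
                           strand = strand(introns))
    has_site <- countOverlaps(intron_half, sites, ignore.strand = FALSE) > 0
    if (!any(has_site)) return(NULL)
    centers <- GRanges(seqnames(introns)[has_site],
                       IRanges(anchor[has_site], width = 1L),
                       strand = strand(introns)[has_site])
    wins <- extract_windows(genome, centers, flank)
    # orientation: extract_windows gives 5'->3'; on both sides the window
    # center is the first intronic base. Exonic half precedes it for the 5'
    # junction and follows it for the 3' junction.
    comp <- composition_of_windows(wins, offsets = seq(-flank, flank))
    comp
  }
  sgn5 <- ifelse(plus, 1L, -1L)   # into the intron, genomically
  five <- one_side(j5, sgn5)
  three <- one_side(j3, -sgn5)
  if (is.null(five) && is.null(three))
    stop("no junction window contains an intronic-side site")
  annotate <- function(comp, junction) {
    if (is.null(comp)) return(NULL)
    # for the 5' junction the intron lies at offsets >= 0; for the 3'
    # junction the transcript-oriented window has the intron at offsets <= 0
    if (junction == "five_prime") {
      comp$side <- ifelse(comp$offset >= 0, "intron", "exon")
    } else {
      comp$side <- ifelse(comp$offset <= 0, "intron", "exon")
    }
    comp
  }
  list(five_prime = annotate(five, "five_prime"),
       three_prime = annotate(three, "three_prime"))
}
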