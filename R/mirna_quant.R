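#' RNA-seq read density in hairpin-flanking windows
#'
#' The whole level of a miRNA transcript (primary transcript plus its
#' truncated processing fragments) is measured as read density in the
#' window `hairpin +/- flank`: a read counts when at least one aligned
#' base overlaps the window on the same strand; reads fully contained in
#' the pre-miRNA are excluded (absent from a size-selected library).
#' Density is reads per million library reads per kilobase of window, so
#' windows of unequal hairpin length stay comparable.
#'
#' @param reads `GAlignments` for one condition.
#' @param hairpins a `MirnaHairpinSet`.
#' @param library_size total mapped reads in the library (default:
#'   `length(reads)`).
#' @param flank half-window (default 200 nt).
#' @param condition optional label carried into the output.
#' @return data.frame: mirna_id, window_width, count, density, condition,
#'   library_size.
#' @export
mirna_window_density <- function(reads, hairpins, library_size = length(reads),
                                 flank = 200, condition = NA_character_) {
  if (library_size <= 0) stop("zero library size: density undefined")
  win <- hairpins$hairpins + flank
  blocks <- aligned_blocks(reads)
  hits <- findOverlaps(blocks, win, ignore.strand = FALSE)
  # exclude reads fully contained in the pre-miRNA hairpin
  span <- granges(reads)
  contained <- queryHits(findOverlaps(span, hairpins$hairpins,
                                      type = "within", ignore.strand = FALSE))
  keep <- !(queryHits(hits) %in% contained)
  # a read overlapping two windows counts once in each
  dt <- unique(data.table::data.table(r = queryHits(hits)[keep],
                                      w = subjectHits(hits)[keep]))
  counts <- tabulate(dt$w, nbins = length(win))
  data.frame(mirna_id = names(win), window_width = width(win),
             count = counts,
             density = counts / (library_size / 1e6) / (width(win) / 1000),
             condition = condition, library_size = library_size,
             row.names = NULL)
}

#' Differential calls for mature miRNAs from small-RNA TPM
#'
#' down: control/knockdown exceeds `fold_min` and the larger of the two
#' TPMs exceeds `tpm_min`; up is symmetric; everything else unchanged.
#' The TPM floor can instead use the min or mean of the conditions.
#'
#' @param tpm_control,tpm_knockdown named numeric TPM vectors over the same
#'   miRNA ids.
#' @param fold_min fold-change threshold (default 1.5, strict inequality).
#' @param tpm_min expression floor (default 1.5).
#' @param floor_on which summary the floor applies to: "max" (default),
#'   "min" or "mean".
#' @return data.frame: id, control, knockdown, log2_ratio
#'   (knockdown/control), class factor (down/unchanged/up).
#' @export
differential_mirna <- function(tpm_control, tpm_knockdown, fold_min = 1.5,
                               tpm_min = 1.5,
                               floor_on = c("max", "min", "mean")) {
  floor_on <- match.arg(floor_on)
  if (any(tpm_control < 0) || any(tpm_knockdown < 0))
    stop("negative expression values")
  ids <- names(tpm_control) %||% seq_along(tpm_control)
  tpm_knockdown <- tpm_knockdown[ids]
  fl <- switch(floor_on,
               max = pmax(tpm_control, tpm_knockdown),
               min = pmin(tpm_control, tpm_knockdown),
               mean = (tpm_control + tpm_knockdown) / 2)
  down <- tpm_control > fold_min * tpm_knockdown & fl > tpm_min
  up <- tpm_knockdown > fold_min * tpm_control & fl > tpm_min
  cls <- ifelse(down, "down", ifelse(up, "up", "unchanged"))
  data.frame(id = ids, control = as.numeric(tpm_control),
             knockdown = as.numeric(tpm_knockdown),
             log2_ratio = log2(tpm_knockdown / tpm_control),
             class = factor(cls, levels = c("down", "unchanged", "up")),
             row.names = NULL)
}

#' Differential calls for miRNA transcripts from window densities
#'
#' Same classification as [differential_mirna()] but on hairpin-window
#' densities, without an expression floor unless one is supplied. Fold
#' changes use a pseudocount (in read units, default 0.5) to avoid
#' division by zero.
#'
#' @param density_control,density_knockdown data.frames from
#'   [mirna_window_density()].
#' @param fold_min fold-change threshold (default 1.5).
#' @param tpm_min optional density floor (default 0 = off).
#' @param pseudocount reads added to each count before density and ratio
#'   formation (default 0.5).
#' @return data.frame: mirna_id, control, knockdown (pseudocounted
#'   densities), log2_ratio (knockdown/control), class.
#' @export
differential_mirna_transcripts <- function(density_control, density_knockdown,
                                           fold_min = 1.5, tpm_min = 0,
                                           pseudocount = 0.5) {
  m <- merge(density_control, density_knockdown, by = "mirna_id",
             suffixes = c("_c", "_k"))
  dens <- function(count, lib, w) (count + pseudocount) / (lib / 1e6) / (w / 1000)
  dc <- dens(m$count_c, m$library_size_c, m$window_width_c)
  dk <- dens(m$count_k, m$library_size_k, m$window_width_k)
  fl <- pmax(dc, dk)
  cls <- ifelse(dc > fold_min * dk & fl > tpm_min, "down",
          ifelse(dk > fold_min * dc & fl > tpm_min, "up", "unchanged"))
  data.frame(mirna_id = m$mirna_id, control = dc, knockdown = dk,
             log2_ratio = log2(dk / dc),
             class = factor(cls, levels = c("down", "unchanged", "up")),
             row.names = NULL)
}

#' Genomic origin of each miRNA
#'
#' Context is the majority region label of the mature miRNA's bases:
#' intron -> intronic, 3'UTR -> utr3, CDS/5'UTR -> exonic, otherwise
#' intergenic.
#'
#' @param hairpins a `MirnaHairpinSet`.
#' @param annotation a `GenomeAnnotation`.
#' @return named character vector over miRNA ids with values in
#'   {intronic, utr3, exonic, intergenic}.
#' @export
classify_mirna_origin <- function(hairpins, annotation) {
  mat1 <- unlist(endoapply(hairpins$mature, function(g) g[1]))
  labs <- region_labels(annotation, mat1, majority = TRUE)
  out <- c(intron = "intronic", utr3 = "utr3", cds = "exonic",
           utr5 = "exonic", intergenic = "intergenic")[labs]
  setNames(unname(out), names(hairpins$hairpins))
}
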