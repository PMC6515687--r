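#' Transcript-level expression from aligned fragments
#'
#' Deliberately simple counting scheme (no isoform deconvolution): a
#' fragment is counted once for every same-strand transcript whose exonic
#' bases it overlaps by at least one nucleotide. FPKM uses the number of
#' fragments counted toward at least one transcript in that library as the
#' per-million denominator; TPM rescales length-normalized counts to 1e6.
#'
#' @param reads `GAlignments` with mcols `read_id`, `library`.
#' @param annotation a `GenomeAnnotation`.
#' @param by `"transcript"` (default) or `"gene"`: counting unit. Gene-level
#'   counts a fragment once per gene (union of its transcripts' exons) and
#'   uses the union exonic length.
#' @return data.frame with columns `transcript_id` (or `gene_id`),
#'   `library`, `count`, `fpkm`, `tpm`.
#' @export
compute_expression <- function(reads, annotation, by = c("transcript", "gene")) {
  by <- match.arg(by)
  tx <- annotation$transcripts
  if (by == "transcript") {
    feats <- annotation$exons[tx$transcript_id]
    ids <- tx$transcript_id
    len <- setNames(tx$exonic_length, ids)
  } else {
    ids <- unique(tx$gene_id)
    feats <- GRangesList(lapply(ids, function(g) {
      GenomicRanges::reduce(unlist(annotation$exons[
        tx$transcript_id[tx$gene_id == g]]))
    }))
    names(feats) <- ids
    len <- setNames(vapply(feats, function(g) sum(width(g)), integer(1)), ids)
  }
  libs <- unique(mcols(reads)$library)
  out <- list()
  blocks <- aligned_blocks(reads)
  hits <- findOverlaps(blocks, feats, ignore.strand = FALSE)
  hdt <- data.table::data.table(
    read = queryHits(hits), feat = subjectHits(hits),
    library = mcols(reads)$library[queryHits(hits)]
  )
  hdt <- unique(hdt)
  for (lb in libs) {
    sub <- hdt[hdt$library == lb, ]
    total <- length(unique(sub$read))
    counts <- setNames(integer(length(ids)), ids)
    if (total == 0) {
      warning("no fragments assigned to any feature in library ", lb)
      fpkm <- tpm <- counts * 0
    } else {
      tab <- table(factor(ids[sub$feat], levels = ids))
      counts[] <- as.integer(tab)
      fpkm <- counts * 1e9 / (total * len[ids])
      rate <- counts / len[ids]
      tpm <- if (sum(rate) > 0) rate / sum(rate) * 1e6 else rate * 0
    }
    out[[lb]] <- data.frame(id = ids, library = lb, count = as.integer(counts),
                            fpkm = as.numeric(fpkm), tpm = as.numeric(tpm),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  names(res)[1] <- if (by == "transcript") "transcript_id" else "gene_id"
  rownames(res) <- NULL
  res
}

#' Select reproducibly expressed ("bound") transcripts
#'
#' Retains a transcript when its FPKM reaches `fpkm_min` in at least
#' `min_libraries` libraries — the reproducibility filter applied to CLIP
#' expression before metagene analyses.
#'
#' @param quant data.frame from [compute_expression()] (long format) or a
#'   numeric matrix of FPKM with transcripts in rows, libraries in columns.
#' @param fpkm_min FPKM floor (default 0.5).
#' @param min_libraries minimum number of libraries meeting the floor
#'   (default 2).
#' @return character vector of retained transcript ids.
#' @export
select_bound_transcripts <- function(quant, fpkm_min = 0.5, min_libraries = 2) {
  if (is.data.frame(quant)) {
    idcol <- intersect(c("transcript_id", "gene_id"), names(quant))[1]
    m <- data.table::dcast(data.table::as.data.table(quant),
                           paste(idcol, "~ library"), value.var = "fpkm",
                           fill = 0)
    ids <- m[[idcol]]
    m <- as.matrix(m[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    m <- as.matrix(quant)
  }
  if (ncol(m) < min_libraries)
    stop("min_libraries (", min_libraries, ") exceeds number of libraries (",
         ncol(m), ")")
  keep <- rowSums(m >= fpkm_min) >= min_libraries
  rownames(m)[keep]
}
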