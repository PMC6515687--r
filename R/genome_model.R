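#' Parse a GTF file into a genome annotation
#'
#' Reads an Ensembl-dialect GTF (exon and CDS features grouped by
#' `transcript_id` / `gene_id` attributes) and derives, per transcript,
#' introns (the gaps between consecutive exons) and 5'/3' UTRs (exonic
#' sequence outside the CDS span, oriented by strand). Coordinates are
#' handled by rtracklayer, i.e. 1-based closed intervals internally.
#'
#' @param path path to a GTF file.
#' @param seqlengths optional named integer vector of chromosome lengths
#'   (e.g. from the genome FASTA); enables full intergenic accounting.
#' @return a `GenomeAnnotation` object: a list with `transcripts`
#'   (data.frame: transcript_id, gene_id, chrom, strand, exonic_length,
#'   cds_length, utr5_length, utr3_length), and `GRangesList`s `exons`,
#'   `cds`, `utr5`, `utr3`, `introns` keyed by transcript id.
#' @export
parse_gtf <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF '", path, "': ", conditionMessage(e))
  )
  if (any(width(gr) < 1)) stop("GTF validation error: interval with end < start")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id) || is.null(md$gene_id))
    stop("GTF records must carry gene_id and transcript_id attributes")
  build_annotation(
    exons = gr[md$type == "exon"],
    cds   = gr[md$type == "CDS"],
    seqlengths = seqlengths
  )
}

#' Build a genome annotation from exon and CDS ranges
#'
#' Workhorse behind [parse_gtf()]; also used by the synthetic generator so
#' in-memory annotations and file round-trips share one code path.
#'
#' @param exons `GRanges` of exons with mcols `transcript_id`, `gene_id`.
#' @param cds `GRanges` of CDS intervals with mcol `transcript_id` (may be
#'   empty; transcripts without CDS get no UTRs and do not enter the region
#'   index).
#' @param seqlengths optional named chromosome lengths.
#' @return a `GenomeAnnotation`.
#' @export
build_annotation <- function(exons, cds = GRanges(), seqlengths = NULL) {
  stopifnot(is(exons, "GRanges"), length(exons) > 0)
  tx_ids <- as.character(exons$transcript_id)
  exons_by_tx <- S4Vectors::split(granges(exons), tx_ids)
  exons_by_tx <- endoapply(exons_by_tx, function(g) sort(g))
  # strand consistency / non-overlap within a transcript
  bad <- vapply(exons_by_tx, function(g) {
    length(unique(as.character(strand(g)))) > 1 ||
      length(IRanges::reduce(ranges(g), min.gapwidth = 0L)) != length(g)
  }, logical(1))
  if (any(bad))
    stop("exons overlap or mix strands within transcript(s): ",
         paste(head(names(exons_by_tx)[bad]), collapse = ", "))

  gene_of <- tapply(as.character(exons$gene_id), tx_ids, function(x) x[[1]])
  introns_by_tx <- psetdiff(unlist(range(exons_by_tx)), exons_by_tx)

  ids <- names(exons_by_tx)
  cds_by_tx <- setNames(vector("list", length(ids)), ids)
  utr5_by_tx <- cds_by_tx; utr3_by_tx <- cds_by_tx
  empty <- GRanges()
  if (length(cds) > 0) {
    cds_split <- S4Vectors::split(granges(cds), as.character(cds$transcript_id))
  } else cds_split <- GRangesList()
  for (id in ids) {
    ex <- exons_by_tx[[id]]
    str <- as.character(strand(ex))[1]
    if (id %in% names(cds_split)) {
      cd <- sort(granges(cds_split[[id]]))
      cds_span <- range(cd)
      # exonic sequence genomically left / right of the CDS span
      left  <- intersect_keep(ex, GRanges(seqnames(ex)[1],
                IRanges(1, max(1L, start(cds_span) - 1L)), strand = str))
      right <- intersect_keep(ex, GRanges(seqnames(ex)[1],
                IRanges(end(cds_span) + 1L, .Machine$integer.max %/% 2L), strand = str))
      if (str == "+") { utr5_by_tx[[id]] <- left;  utr3_by_tx[[id]] <- right }
      else            { utr5_by_tx[[id]] <- right; utr3_by_tx[[id]] <- left  }
      cds_by_tx[[id]] <- cd
    } else {
      cds_by_tx[[id]] <- empty; utr5_by_tx[[id]] <- empty; utr3_by_tx[[id]] <- empty
    }
  }
  to_grl <- function(lst) GRangesList(lst)
  cds_grl <- to_grl(cds_by_tx); utr5_grl <- to_grl(utr5_by_tx); utr3_grl <- to_grl(utr3_by_tx)

  transcripts <- data.frame(
    transcript_id = ids,
    gene_id = as.character(gene_of[ids]),
    chrom = vapply(exons_by_tx, function(g) as.character(seqnames(g))[1], character(1)),
    strand = vapply(exons_by_tx, function(g) as.character(strand(g))[1], character(1)),
    exonic_length = vapply(exons_by_tx, function(g) sum(width(g)), integer(1)),
    cds_length  = vapply(cds_by_tx,  function(g) sum(width(g)), integer(1)),
    utr5_length = vapply(utr5_by_tx, function(g) sum(width(g)), integer(1)),
    utr3_length = vapply(utr3_by_tx, function(g) sum(width(g)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ann <- list(
    transcripts = transcripts,
    exons = exons_by_tx, cds = cds_grl, utr5 = utr5_grl, utr3 = utr3_grl,
    introns = introns_by_tx, seqlengths = seqlengths
  )
  class(ann) <- "GenomeAnnotation"
  ann
}

# strand-preserving intersection of a transcript's exons with a span
intersect_keep <- function(gr, span) {
  hits <- pintersect(findOverlapPairs(gr, span, ignore.strand = TRUE))
  out <- granges(hits)
  strand(out) <- as.character(strand(gr))[1]
  sort(out)
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes on",
      length(unique(x$transcripts$chrom)), "chromosome(s)\n")
  cat("  with CDS:", sum(x$transcripts$cds_length > 0),
      "| median 3'-UTR length:",
      stats::median(x$transcripts$utr3_length), "nt\n")
  invisible(x)
}

#' Disjoint labelled region index
#'
#' Flattens the annotation into strand-specific, non-overlapping intervals
#' labelled with one of `utr5`, `cds`, `utr3`, `intron` under the precedence
#' rule CDS > 3'UTR > 5'UTR > intron (intergenic is the complement). Only
#' coding transcripts contribute. The index is cached on the annotation.
#'
#' @param annotation a `GenomeAnnotation`.
#' @return `GRanges` with mcol `region`.
#' @export
region_index <- function(annotation) {
  stopifnot(is(annotation, "GenomeAnnotation"))
  coding <- annotation$transcripts$transcript_id[annotation$transcripts$cds_length > 0]
  pool <- list(
    cds  = GenomicRanges::reduce(unlist(annotation$cds[coding])),
    utr3 = GenomicRanges::reduce(unlist(annotation$utr3[coding])),
    utr5 = GenomicRanges::reduce(unlist(annotation$utr5[coding])),
    intron = GenomicRanges::reduce(unlist(annotation$introns[coding]))
  )
  taken <- GRanges()
  out <- GRanges()
  for (lab in c("cds", "utr3", "utr5", "intron")) {   # precedence order
    piece <- GenomicRanges::setdiff(pool[[lab]], taken, ignore.strand = FALSE)
    if (length(piece) > 0) {
      piece$region <- lab
      out <- c(out, piece)
      taken <- GenomicRanges::reduce(c(taken, granges(piece)))
    }
  }
  sort(out)
}

#' Label arbitrary positions by genomic region
#'
#' @param annotation a `GenomeAnnotation`.
#' @param gr `GRanges` of query positions/intervals.
#' @param majority logical; label each query by the region covering the
#'   most of its bases (ties by precedence), else by any-overlap precedence.
#' @param idx optional precomputed [region_index()], to amortize repeated
#'   calls.
#' @return character vector of labels (`intergenic` when no same-strand
#'   annotated region overlaps).
#' @export
region_labels <- function(annotation, gr, majority = TRUE, idx = NULL) {
  if (is.null(idx)) idx <- region_index(annotation)
  n <- length(gr)
  labs <- rep("intergenic", n)
  if (is(gr, "GRangesList")) {
    grp <- rep(seq_along(gr), lengths(gr))
    flat <- unlist(gr, use.names = FALSE)
  } else {
    grp <- seq_len(n)
    flat <- granges(gr)
  }
  hits <- findOverlaps(flat, idx, ignore.strand = FALSE)
  if (length(hits) == 0) return(labs)
  ov <- width(pintersect(flat[queryHits(hits)], granges(idx)[subjectHits(hits)]))
  dt <- data.table::data.table(
    q = grp[queryHits(hits)],
    region = idx$region[subjectHits(hits)],
    w = ov
  )
  dt <- dt[, list(w = sum(w)), by = c("q", "region")]
  # unannotated aligned bases vote for "intergenic"
  total_w <- rowsum(as.numeric(width(flat)), grp)
  labelled_w <- rowsum(as.numeric(dt$w), dt$q)
  inter_q <- as.integer(rownames(labelled_w))
  inter_w <- total_w[as.character(inter_q), 1] - labelled_w[, 1]
  dt <- rbind(dt, data.table::data.table(
    q = inter_q[inter_w > 0], region = "intergenic",
    w = inter_w[inter_w > 0]))
  dt[, "prec" := match(dt$region, REGION_PRECEDENCE)]
  if (majority) {
    data.table::setorderv(dt, c("q", "w", "prec"), order = c(1L, -1L, 1L))
  } else {
    data.table::setorderv(dt, c("q", "prec"), order = c(1L, 1L))
  }
  top <- dt[!duplicated(dt$q), ]
  labs[top$q] <- top$region
  labs
}

#' Write an annotation back to GTF
#'
#' Emits exon and CDS features only (the derived features are recomputed on
#' re-parse), which makes GTF round-trips exact.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  rows <- list()
  tx <- annotation$transcripts
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    feat <- function(gr, type) {
      if (length(gr) == 0) return(NULL)
      data.frame(chrom = as.character(seqnames(gr)), src = "targetome",
                 type = type, start = start(gr), end = end(gr), score = ".",
                 strand = as.character(strand(gr)), frame = ".",
                 attr = sprintf('gene_id "%s"; transcript_id "%s";',
                                tx$gene_id[i], id))
    }
    rows[[length(rows) + 1L]] <- feat(annotation$exons[[id]], "exon")
    rows[[length(rows) + 1L]] <- feat(annotation$cds[[id]], "CDS")
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$type), ]
  con <- file(path, "wb")  # binary mode: fixed LF endings => reproducible bytes
  on.exit(close(con))
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}
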