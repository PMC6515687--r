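#' Parse CLIP/RNA-seq alignments from SAM or the tabular dialect
#'
#' Two input dialects are supported:
#' \describe{
#'   \item{SAM}{plain-text SAM, header optional. Records flagged unmapped
#'     (0x4) are dropped; "uniquely mapped" is enforced as mapping quality
#'     `>= min_mapq` (default 1) and, when an `NH:i:` tag is present,
#'     `NH == 1`.}
#'   \item{TSV}{a dependency-free tabular dialect with header line
#'     `read_id  chrom  start  strand  cigar  library`; `start` is the
#'     1-based leftmost reference position (as in SAM).}
#' }
#'
#' @param path input file.
#' @param format `"auto"` (default), `"sam"` or `"tsv"`.
#' @param library library identifier attached to every read lacking one
#'   (default: file base name).
#' @param min_mapq minimum mapping quality for SAM records (default 1).
#' @param seqlengths optional named chromosome lengths; when given, a CIGAR
#'   whose reference span runs past the chromosome end is a validation error.
#' @return a [GenomicAlignments::GAlignments] with mcols `read_id`,
#'   `library`.
#' @export
parse_alignments <- function(path, format = c("auto", "sam", "tsv"),
                             library = NULL, min_mapq = 1,
                             seqlengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path)
  if (format == "auto") {
    first <- lines[!startsWith(lines, "@")][1]
    format <- if (!is.na(first) && startsWith(first, "read_id\t")) "tsv" else "sam"
  }
  library <- library %||% tools::file_path_sans_ext(basename(path))

  if (format == "tsv") {
    df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "integer",
                                           "character", "character", "character"))
    needed <- c("read_id", "chrom", "start", "strand", "cigar", "library")
    if (!all(needed %in% names(df)))
      stop("tabular alignment dialect requires columns: ",
           paste(needed, collapse = ", "))
    aln <- make_galignments(df$chrom, df$start, df$cigar, df$strand,
                            df$read_id, df$library, seqlengths)
    return(aln)
  }

  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0) return(make_galignments(character(), integer(),
                                                 character(), character(),
                                                 character(), character(),
                                                 seqlengths))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed SAM record at line ",
         which(!startsWith(lines, "@") & nzchar(lines))[which(nf < 11)[1]])
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2))
  rname <- get(3)
  pos <- as.integer(get(4))
  mapq <- as.integer(get(5))
  cig <- get(6)
  nh <- vapply(fields, function(f) {
    tagf <- grep("^NH:i:", f[-seq_len(11)], value = TRUE)
    if (length(tagf) == 0) NA_integer_ else as.integer(sub("^NH:i:", "", tagf[1]))
  }, integer(1))
  keep <- bitwAnd(flag, 4L) == 0L & rname != "*" & cig != "*" &
    mapq >= min_mapq & (is.na(nh) | nh == 1L)
  strnd <- ifelse(bitwAnd(flag, 16L) == 16L, "-", "+")
  make_galignments(rname[keep], pos[keep], cig[keep], strnd[keep],
                   get(1)[keep], rep(library, sum(keep)), seqlengths)
}

make_galignments <- function(chrom, pos, cig, strnd, read_id, lib, seqlengths) {
  if (length(chrom) > 0 && !is.null(seqlengths)) {
    if (!all(chrom %in% names(seqlengths)))
      stop("alignment references unknown chromosome(s): ",
           paste(unique(setdiff(chrom, names(seqlengths))), collapse = ", "))
    ends <- pos + GenomicAlignments::cigarWidthAlongReferenceSpace(cig) - 1L
    over <- ends > seqlengths[chrom] | pos < 1L
    if (any(over))
      stop("CIGAR reference span exceeds chromosome bounds for read(s): ",
           paste(head(read_id[over]), collapse = ", "))
  }
  aln <- GenomicAlignments::GAlignments(
    seqnames = chrom, pos = as.integer(pos), cigar = as.character(cig),
    strand = factor(strnd, levels = c("+", "-", "*")),
    read_id = as.character(read_id), library = as.character(lib)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(aln) <- names(seqlengths)
    seqlengths(aln) <- seqlengths
  }
  aln
}

#' Write alignments as plain-text SAM
#'
#' Minimal SAM writer for simulated libraries (header `@SQ` lines from
#' `seqlengths`, mapped single-end records, MAPQ 255, `*` sequence).
#'
#' @param aln `GAlignments` with mcols `read_id`, `library`.
#' @param path output path.
#' @param seqlengths named chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seqlengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths)))
  flag <- ifelse(as.character(strand(aln)) == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*\tRG:Z:%s",
                 mcols(aln)$read_id, flag, as.character(seqnames(aln)),
                 start(aln), cigar(aln), mcols(aln)$library)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, rec), con)
  invisible(path)
}

#' Per-read reference ranges (match segments, N skips excluded)
#' @keywords internal
aligned_blocks <- function(aln) {
  GenomicAlignments::grglist(aln)  # D stays inside blocks, N splits them
}
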