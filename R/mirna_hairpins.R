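#' Construct a miRNA hairpin set
#'
#' @param hairpins `GRanges` of pre-miRNA (hairpin) intervals, named by
#'   miRNA id.
#' @param mature `GRangesList` of mature miRNA interval(s), keyed by the
#'   same ids; every mature interval must lie inside its hairpin, same
#'   strand.
#' @return `MirnaHairpinSet` (list with `hairpins`, `mature`).
#' @export
mirna_hairpin_set <- function(hairpins, mature) {
  stopifnot(is(hairpins, "GRanges"), !is.null(names(hairpins)))
  mature <- mature[names(hairpins)]
  ok <- vapply(seq_along(hairpins), function(i) {
    m <- mature[[i]]
    length(m) >= 1 &&
      all(start(m) >= start(hairpins)[i] & end(m) <= end(hairpins)[i]) &&
      all(as.character(strand(m)) == as.character(strand(hairpins))[i])
  }, logical(1))
  if (!all(ok))
    stop("mature interval outside its hairpin (or strand mismatch): ",
         paste(head(names(hairpins)[!ok]), collapse = ", "))
  structure(list(hairpins = hairpins, mature = mature),
            class = "MirnaHairpinSet")
}

#' @export
print.MirnaHairpinSet <- function(x, ...) {
  cat("MirnaHairpinSet:", length(x$hairpins), "hairpins, width",
      paste(range(width(x$hairpins)), collapse = "-"), "nt\n")
  invisible(x)
}

#' Parse a miRBase-style GFF3 of miRNA coordinates
#'
#' Expects `miRNA_primary_transcript` features (hairpins) and `miRNA`
#' features (mature) linked by `Derives_from` (falling back to `Parent`).
#' Hairpin ids are taken from the `Name` attribute when present, else `ID`.
#'
#' @param path GFF3 file.
#' @return a `MirnaHairpinSet`.
#' @export
parse_mirna_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_hp <- gr$type == "miRNA_primary_transcript"
  is_mat <- gr$type == "miRNA"
  if (!any(is_hp)) stop("no miRNA_primary_transcript features in ", path)
  hp <- gr[is_hp]
  ids <- as.character(hp$Name %||% hp$ID)
  ids[is.na(ids)] <- as.character(hp$ID)[is.na(ids)]
  hpg <- granges(hp)
  names(hpg) <- ids
  id_of <- setNames(ids, as.character(hp$ID))
  mat <- gr[is_mat]
  parent <- as.character(mat$Derives_from %||% unlist(mat$Parent))
  mat_by <- S4Vectors::split(granges(mat), id_of[parent])
  # hairpins with no annotated mature interval are dropped with a note
  missing <- setdiff(ids, names(mat_by))
  if (length(missing) > 0) {
    message("dropping ", length(missing), " hairpin(s) without mature coordinates")
    hpg <- hpg[setdiff(ids, missing)]
  }
  mirna_hairpin_set(hpg, mat_by)
}

#' Write a miRNA hairpin set as miRBase-style GFF3
#'
#' @param hairpins a `MirnaHairpinSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mirna_gff <- function(hairpins, path) {
  hp <- hairpins$hairpins
  lines <- c("##gff-version 3")
  for (i in seq_along(hp)) {
    id <- names(hp)[i]
    lines <- c(lines, sprintf(
      "%s\ttargetome\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      as.character(seqnames(hp))[i], start(hp)[i], end(hp)[i],
      as.character(strand(hp))[i], id, id))
    m <- hairpins$mature[[id]]
    for (j in seq_along(m)) {
      lines <- c(lines, sprintf(
        "%s\ttargetome\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s-mat%d;Name=%s-mat%d;Derives_from=%s",
        as.character(seqnames(m))[j], start(m)[j], end(m)[j],
        as.character(strand(m))[j], id, j, id, j, id))
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Hairpin midpoints
#'
#' Midpoint of an even-length hairpin is `start + floor(width/2)` in
#' hairpin-local 5' to 3' orientation (so on the minus strand it is
#' `end - floor(width/2)` genomically).
#'
#' @param hairpins a `MirnaHairpinSet`.
#' @return `GRanges` of width-1 midpoints, named by miRNA id.
#' @export
hairpin_midpoints <- function(hairpins) {
  hp <- hairpins$hairpins
  off <- floor(width(hp) / 2)
  pos <- ifelse(as.character(strand(hp)) == "-", end(hp) - off, start(hp) + off)
  GRanges(seqnames(hp), IRanges(pos, width = 1), strand = strand(hp),
          seqinfo = seqinfo(hp)) |> setNames(names(hp))
}
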