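# Independent brute-force oracles. These deliberately avoid the package's
# GenomicRanges/GenomicAlignments code paths: plain string parsing and
# per-base loops over integer vectors.

# parse a CIGAR into reference-consuming segments; returns data.frame
# op/len/ref_start for ops that consume reference (M, D, N, =, X)
oracle_cigar_ref <- function(cigar, pos) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  ref_ops <- ops %in% c("M", "D", "N", "=", "X")
  cur <- pos
  out <- data.frame(op = character(0), len = integer(0), ref_start = integer(0))
  for (i in seq_along(ops)) {
    if (ref_ops[i]) {
      out <- rbind(out, data.frame(op = ops[i], len = lens[i], ref_start = cur))
      cur <- cur + lens[i]
    }
  }
  out
}

oracle_ref_span <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  sum(lens[ops %in% c("M", "D", "N", "=", "X")])
}

# per-base deletion residue counts: named vector "chrom:pos:strand" -> count
oracle_deletion_residues <- function(chrom, pos, cigar, strand) {
  counts <- new.env()
  for (i in seq_along(cigar)) {
    segs <- oracle_cigar_ref(cigar[i], pos[i])
    dd <- segs[segs$op == "D", , drop = FALSE]
    for (j in seq_len(nrow(dd))) {
      for (p in seq(dd$ref_start[j], length.out = dd$len[j])) {
        key <- paste(chrom[i], p, strand[i], sep = ":")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  unlist(as.list(counts))
}

# majority-vote region label of one read from per-base label lookup
# labels_at: function(chrom, pos, strand) -> label for a single base
oracle_region_label <- function(chrom, pos, cigar, strand, labels_at) {
  segs <- oracle_cigar_ref(cigar, pos)
  segs <- segs[segs$op %in% c("M", "D"), , drop = FALSE]  # aligned ref bases
  votes <- character(0)
  for (j in seq_len(nrow(segs)))
    for (p in seq(segs$ref_start[j], length.out = segs$len[j]))
      votes <- c(votes, labels_at(chrom, p, strand))
  tab <- table(votes)
  prec <- c("cds", "utr3", "utr5", "intron", "intergenic")
  winners <- names(tab)[tab == max(tab)]
  prec[min(match(winners, prec))]
}

# per-base label lookup table built by brute force from an annotation
oracle_label_table <- function(annotation, chrom_lengths) {
  envs <- list()
  for (ch in names(chrom_lengths)) {
    envs[[ch]] <- list(
      "+" = rep("intergenic", chrom_lengths[[ch]]),
      "-" = rep("intergenic", chrom_lengths[[ch]]))
  }
  paint <- function(grl, lab) {
    gr <- unlist(grl)
    for (i in seq_along(gr)) {
      ch <- as.character(seqnames(gr))[i]; st <- as.character(strand(gr))[i]
      v <- envs[[ch]][[st]]
      for (p in start(gr)[i]:end(gr)[i]) {
        cur <- v[p]
        prec <- c(cds = 1, utr3 = 2, utr5 = 3, intron = 4, intergenic = 5)
        if (prec[[lab]] < prec[[cur]]) v[p] <- lab
      }
      envs[[ch]][[st]] <<- v
    }
  }
  coding <- annotation$transcripts$transcript_id[annotation$transcripts$cds_length > 0]
  paint(annotation$cds[coding], "cds")
  paint(annotation$utr3[coding], "utr3")
  paint(annotation$utr5[coding], "utr5")
  paint(annotation$introns[coding], "intron")
  function(chrom, pos, strand) envs[[chrom]][[strand]][pos]
}

# does read (pos..pos+span-1) overlap interval [lo, hi] by >= 1 nt?
oracle_overlaps <- function(pos, span, lo, hi) {
  pos <= hi && (pos + span - 1) >= lo
}

# exhaustive maximum nested base-pair count for short sequences (n <= 12)
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(toupper(seq), "")[[1]]
  can <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "AT", "TA", "GC", "CG",
                        "GU", "UG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (can(s[i], s[k])) {
        v <- 1L + (if (k > i + 1L) rec(i + 1L, k - 1L) else 0L) +
          (if (k < j) rec(k + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    best
  }
  if (length(s) < 2) return(0L)
  rec(1L, length(s))
}
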