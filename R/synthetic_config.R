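#' Simulation configuration
#'
#' Central parameter set for the synthetic genome and the three simulated
#' libraries (CLIP, RNA-seq, small-RNA). Defaults describe a small but
#' structurally complete world: multi-exon coding genes with widely varying
#' 3'-UTR lengths, miRNA hairpins placed in introns, 3'-UTRs and intergenic
#' space, protein-binding sites biased toward long 3'-UTRs and toward ~50 nt
#' upstream of 3' splice sites, a global shift of miRNA levels downward in
#' the knockdown condition, and mirtron intron retention that rises on
#' knockdown. All randomness is controlled by `seed`; the same seed gives
#' byte-identical outputs.
#'
#' @param seed integer master seed (stage seeds are derived as seed + k).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_genes number of coding genes to place.
#' @param mirna_counts named counts of hairpins per genomic context,
#'   `c(intronic=, utr3=, intergenic=)`.
#' @param clip list: `n_reads`, fractions `site_fraction` /
#'   `hairpin_fraction` (remainder is transcribed background),
#'   `deletion_prob` (per site-derived read), `deletion_len` (1 nt, the
#'   dominant reverse-transcription signature), `read_length` range, and
#'   `category_weights` over categories I-V (pri-dominant by default).
#' @param binding list: `n_utr3_sites`, `utr3_bias_exponent` (site placement
#'   probability proportional to 3'-UTR length to this power),
#'   `n_intron_sites`, `splice_offset_mean`/`splice_offset_sd` (nt upstream
#'   of the 3' splice site).
#' @param mirna list: `control_levels` range (arbitrary transcription units),
#'   `fold_choices`/`fold_weights` for per-miRNA knockdown/control ratios
#'   (down-shifted, as in a helicase knockdown that depresses miRNA output).
#' @param rnaseq list: `read_length`, `reads_per_level` (expected window
#'   reads per level unit), `gene_level` range, `gene_reads_per_level`,
#'   `n_informative` intron-informative reads per intron.
#' @param pir list: `mirtron_control`, `mirtron_knockdown`, `background`
#'   retention fractions in `[0,1]`.
#' @param smallrna list: `n_reads`, `lengths`, `length_weights` (peaked at
#'   21-25 nt, mode 22, as in a germ-cell small-RNA library).
#' @return a validated `SimulationConfig` list.
#' @export
simulation_config <- function(
    seed = 1L,
    chrom_lengths = c(chrS1 = 260000L, chrS2 = 170000L),
    n_genes = 30L,
    mirna_counts = c(intronic = 4L, utr3 = 3L, intergenic = 3L),
    clip = list(),
    binding = list(),
    mirna = list(),
    rnaseq = list(),
    pir = list(),
    smallrna = list()) {
  merge_block <- function(user, defaults, block) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad) > 0)
      stop("unknown ", block, " config key(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  clip <- merge_block(clip, list(
    n_reads = 4000L, site_fraction = 0.5, hairpin_fraction = 0.15,
    deletion_prob = 0.3, deletion_len = 1L, read_length = c(25L, 40L),
    category_weights = c(I = 0.06, II = 0.08, III = 0.06, IV = 0.4, V = 0.4)
  ), "clip")
  binding <- merge_block(binding, list(
    n_utr3_sites = 60L, utr3_bias_exponent = 1,
    n_intron_sites = 40L, splice_offset_mean = 50, splice_offset_sd = 12
  ), "binding")
  mirna <- merge_block(mirna, list(
    control_levels = c(10, 60),
    fold_choices = c(0.25, 0.4, 0.5, 1, 2),
    fold_weights = c(0.15, 0.2, 0.3, 0.25, 0.1)
  ), "mirna")
  rnaseq <- merge_block(rnaseq, list(
    read_length = 100L, reads_per_level = 10,
    gene_level = c(1, 5), gene_reads_per_level = 200,
    n_informative = 60L
  ), "rnaseq")
  pir <- merge_block(pir, list(
    mirtron_control = 0.15, mirtron_knockdown = 0.55, background = 0.1
  ), "pir")
  smallrna <- merge_block(smallrna, list(
    n_reads = 5000L,
    lengths = 18:30,
    length_weights = c(0.5, 1, 2, 6, 30, 25, 12, 8, 5, 3, 2, 1, 0.5),
    # constant non-miRNA background (piRNA-like, 26-31 nt), expressed as a
    # multiple of the summed control miRNA levels; it anchors the TPM
    # denominator so a global miRNA shift remains visible
    background_weight = 1.5,
    bg_lengths = 26:31,
    bg_length_weights = c(2, 5, 8, 8, 5, 2)
  ), "smallrna")

  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_genes = as.integer(n_genes), mirna_counts = mirna_counts,
              clip = clip, binding = binding, mirna = mirna,
              rnaseq = rnaseq, pir = pir, smallrna = smallrna)
  validate_config(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validate_config <- function(cfg) {
  in01 <- function(x) all(x >= 0 & x <= 1)
  stopifnot(
    length(cfg$seed) == 1, !is.na(cfg$seed),
    all(cfg$chrom_lengths > 0), !is.null(names(cfg$chrom_lengths)),
    cfg$n_genes >= 3,
    all(c("intronic", "utr3", "intergenic") %in% names(cfg$mirna_counts)),
    in01(cfg$clip$deletion_prob), in01(cfg$clip$site_fraction),
    in01(cfg$clip$hairpin_fraction),
    cfg$clip$site_fraction + cfg$clip$hairpin_fraction <= 1,
    all(cfg$clip$category_weights >= 0),
    in01(c(cfg$pir$mirtron_control, cfg$pir$mirtron_knockdown, cfg$pir$background)),
    length(cfg$smallrna$lengths) == length(cfg$smallrna$length_weights),
    all(cfg$smallrna$length_weights >= 0)
  )
  invisible(cfg)
}

# deterministic stage seeds: genome 0, clip 1, rnaseq ctrl/kd 2/3, smallrna 4/5
stage_seed <- function(cfg, stage) {
  offs <- c(genome = 0L, clip = 1L, rnaseq_control = 2L, rnaseq_knockdown = 3L,
            smallrna_control = 4L, smallrna_knockdown = 5L)
  (cfg$seed + offs[[stage]]) %% .Machine$integer.max
}
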