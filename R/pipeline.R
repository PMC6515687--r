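#' Resolved pipeline run configuration
#'
#' Central defaults for every analysis stage (values follow the thresholds
#' used throughout the package: collection flank 100 nt, density window
#' flank 200 nt, 100 region bins, 30 hairpin bins, 1.5-fold change, TPM
#' floor 1.5, 5 reads per miRNA form, FPKM floor 0.5 in >= 2 libraries).
#' Unknown keys are rejected.
#'
#' @param simulate a [simulation_config()] (or its argument list).
#' @param stages named logical toggles: clip, rnaseq, smallrna, splicing,
#'   splice_map.
#' @param flank_hairpin,flank_window,flank_composition window sizes (nt).
#' @param bins_region,bins_hairpin bin counts.
#' @param fold_min,tpm_floor,min_reads,fpkm_min,min_libraries thresholds.
#' @param splice_window nt into introns for the splice-distance histograms.
#' @return a validated `RunConfig` list.
#' @export
run_config <- function(simulate = simulation_config(),
                       stages = list(),
                       flank_hairpin = 100, flank_window = 200,
                       flank_composition = 100,
                       bins_region = 100, bins_hairpin = 30,
                       fold_min = 1.5, tpm_floor = 1.5, min_reads = 5,
                       fpkm_min = 0.5, min_libraries = 2,
                       splice_window = 200) {
  if (!is(simulate, "SimulationConfig")) simulate <- do.call(simulation_config, simulate)
  stage_defaults <- list(clip = TRUE, rnaseq = TRUE, smallrna = TRUE,
                         splicing = TRUE, splice_map = TRUE)
  bad <- setdiff(names(stages), names(stage_defaults))
  if (length(bad) > 0) stop("unknown stage toggle(s): ", paste(bad, collapse = ", "))
  stages <- utils::modifyList(stage_defaults, stages)
  cfg <- list(simulate = simulate, stages = stages,
              flank_hairpin = flank_hairpin, flank_window = flank_window,
              flank_composition = flank_composition,
              bins_region = bins_region, bins_hairpin = bins_hairpin,
              fold_min = fold_min, tpm_floor = tpm_floor,
              min_reads = min_reads, fpkm_min = fpkm_min,
              min_libraries = min_libraries, splice_window = splice_window)
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full simulate-quantify-analyze pipeline
#'
#' Executes the stages in dependency order on a freshly simulated dataset,
#' writes TSV tables plus a JSON summary (with the fully resolved
#' parameter set echoed for audit), and returns all in-memory results.
#' Reruns with the same configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @param outdir output directory; `NULL` keeps everything in memory.
#' @param seed optional override of the simulation master seed.
#' @return (invisibly) a list of stage results plus `summary`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL, seed = NULL) {
  stopifnot(is(config, "RunConfig"))
  if (!is.null(seed)) {
    sim_args <- unclass(config$simulate)
    sim_args$seed <- as.integer(seed)
    config$simulate <- do.call(simulation_config, sim_args)
  }
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  res <- list(config = config)
  summary <- list(parameters = serialize_config(config))

  sim <- stage("simulate", generate_genome(config$simulate))
  clip <- stage("simulate", simulate_clip_reads(sim))
  rna <- list(control = stage("simulate", simulate_rnaseq(sim, "control")),
              knockdown = stage("simulate", simulate_rnaseq(sim, "knockdown")))
  sm <- list(control = stage("simulate", simulate_small_rna(sim, "control")),
             knockdown = stage("simulate", simulate_small_rna(sim, "knockdown")))
  res$sim <- sim
  summary$simulate <- list(
    genome_nt = sum(lengths(sim$genome)),
    n_transcripts = nrow(sim$truth$transcripts),
    n_hairpins = nrow(sim$truth$hairpins),
    n_planted_sites = nrow(sim$truth$binding_sites),
    n_clip_reads = length(clip$reads),
    n_rnaseq_reads = c(control = rna$control$library_size,
                       knockdown = rna$knockdown$library_size),
    n_smallrna_reads = c(control = nrow(sm$control),
                         knockdown = nrow(sm$knockdown)))

  if (config$stages$clip) {
    sites <- stage("clip", extract_deletion_sites(clip$reads))
    comp <- stage("clip", base_composition_profile(sites, sim$genome, flank = 100))
    hp_seqs <- stage("clip", extract_windows(
      sim$genome, hairpin_midpoints(sim$hairpins), flank = config$flank_window))
    struct <- stage("clip", structure_potential_profile(hp_seqs))
    regions <- stage("clip", classify_read_regions(clip$reads, sim$annotation))
    quant <- stage("clip", compute_expression(clip$reads, sim$annotation))
    bound <- stage("clip", select_bound_transcripts(
      quant, config$fpkm_min, config$min_libraries))
    terc <- stage("clip", tercile_partition(setNames(
      sim$annotation$transcripts$utr3_length,
      sim$annotation$transcripts$transcript_id)))
    prof <- stage("clip", region_coverage_profile(
      clip$reads, sim$annotation, bins = config$bins_region))
    rep_ov <- stage("clip", interval_overlap_summary(clip$reads, sim$repeats))
    clus_ov <- stage("clip", interval_overlap_summary(clip$reads, sim$clusters))
    pairs <- stage("clip", collect_hairpin_reads(
      clip$reads, sim$hairpins, flank = config$flank_hairpin))
    cats <- stage("clip", classify_mirna_reads(
      clip$reads, pairs, sim$hairpins, flank = config$flank_hairpin))
    forms <- stage("clip", call_mirna_forms(
      cats, min_reads = config$min_reads,
      mirna_ids = names(sim$hairpins$hairpins)))
    meta <- stage("clip", hairpin_meta_profile(
      clip$reads, sim$hairpins, flank = config$flank_window,
      bins = config$bins_hairpin))
    res$clip <- list(sites = sites, composition = comp, structure = struct,
                     regions = regions$distribution, expression = quant,
                     bound_transcripts = bound, terciles = terc,
                     region_profile = prof, repeat_overlap = rep_ov,
                     cluster_overlap = clus_ov, categories = cats,
                     forms = forms, hairpin_profile = meta)
    summary$clip <- list(
      n_deletion_sites = attr(sites, "summary")$n_sites,
      n_deletion_residues = attr(sites, "summary")$n_residues,
      region_fractions = setNames(regions$distribution$fraction,
                                  paste(regions$distribution$library,
                                        regions$distribution$region)),
      n_bound_transcripts = length(bound),
      tercile_sizes = as.list(terc$sizes),
      repeat_overlap_fraction = rep_ov$fraction,
      n_mature = sum(forms$mature), n_pre = sum(forms$pre),
      n_pri = sum(forms$pri))
  }

  if (config$stages$rnaseq) {
    dens <- lapply(c(control = "control", knockdown = "knockdown"), function(cc)
      stage("rnaseq", mirna_window_density(
        rna[[cc]]$reads, sim$hairpins, rna[[cc]]$library_size,
        flank = config$flank_window, condition = cc)))
    diff_tx <- stage("rnaseq", differential_mirna_transcripts(
      dens$control, dens$knockdown, fold_min = config$fold_min))
    origin <- stage("rnaseq", classify_mirna_origin(sim$hairpins, sim$annotation))
    diff_tx$origin <- origin[diff_tx$mirna_id]
    res$rnaseq <- list(density = dens, differential = diff_tx, origin = origin)
    summary$rnaseq <- list(
      n_transcript_down = sum(diff_tx$class == "down"),
      n_transcript_up = sum(diff_tx$class == "up"),
      origin_counts = as.list(table(origin)))
  }

  if (config$stages$smallrna) {
    prof <- stage("smallrna", small_rna_length_profile(sm$control))
    tpm <- lapply(sm, function(df) {
      counts <- table(factor(df$mirna_id, levels = names(sim$hairpins$hairpins)))
      as.numeric(counts) / nrow(df) * 1e6   # denominator: whole library
    })
    names(tpm$control) <- names(tpm$knockdown) <- names(sim$hairpins$hairpins)
    diff_m <- stage("smallrna", differential_mirna(
      tpm$control, tpm$knockdown, fold_min = config$fold_min,
      tpm_min = config$tpm_floor))
    res$smallrna <- list(length_profile = prof, tpm = tpm, differential = diff_m)
    summary$smallrna <- list(
      share_21_25 = prof$share,
      n_mirna_down = sum(diff_m$class == "down"),
      n_mirna_up = sum(diff_m$class == "up"))
  }

  if (config$stages$splicing) {
    mirtrons <- sim$truth$introns[sim$truth$introns$mirtron, ]
    rows <- lapply(seq_len(nrow(mirtrons)), function(i) {
      it <- GRanges(mirtrons$chrom[i],
                    IRanges(mirtrons$start[i], mirtrons$end[i]),
                    strand = mirtrons$strand[i])
      cc <- count_isoform_evidence(rna$control$reads, it, sim$annotation)
      ck <- count_isoform_evidence(rna$knockdown$reads, it, sim$annotation)
      data.frame(intron_id = mirtrons$intron_id[i],
                 retention_control = cc[["retention"]],
                 exclusion_control = cc[["exclusion"]],
                 retention_knockdown = ck[["retention"]],
                 exclusion_knockdown = ck[["exclusion"]],
                 pir_control = compute_pir(cc[["retention"]], cc[["exclusion"]]),
                 pir_knockdown = compute_pir(ck[["retention"]], ck[["exclusion"]]),
                 transcript_change = mirtron_transcript_change(
                   cc, ck, rna$control$library_size, rna$knockdown$library_size))
    })
    pir_tab <- stage("splicing", do.call(rbind, rows))
    res$splicing <- pir_tab
    summary$splicing <- list(
      n_mirtrons = nrow(pir_tab),
      mean_pir_shift = mean(pir_tab$pir_knockdown - pir_tab$pir_control),
      mean_transcript_change = mean(pir_tab$transcript_change, na.rm = TRUE))
  }

  if (config$stages$splice_map) {
    sites <- res$clip$sites %||% stage("splice_map",
                                       extract_deletion_sites(clip$reads))
    hist <- stage("splice_map", map_crosslinks_to_splice_sites(
      sites, sim$annotation, window = config$splice_window))
    res$splice_map <- hist
    summary$splice_map <- list(
      n_intronic_sites = hist$n_intronic_sites,
      mode_5prime = with(hist$five_prime,
                         if (sum(site_count) > 0) offset[which.max(site_count)] else NA),
      mode_3prime = with(hist$three_prime,
                         if (sum(site_count) > 0) offset[which.max(site_count)] else NA))
  }

  summary$runtime_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res$summary <- summary

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_simulation(sim, file.path(outdir, "simulated"))
    tsv <- function(df, name) {
      utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$clip)) {
      write_sites_bed(res$clip$sites, file.path(outdir, "crosslink_sites.bed"))
      tsv(res$clip$composition, "site_composition")
      tsv(res$clip$regions, "region_distribution")
      tsv(res$clip$region_profile, "region_profile")
      tsv(res$clip$forms, "mirna_forms")
      tsv(res$clip$hairpin_profile, "hairpin_profile")
    }
    if (!is.null(res$rnaseq)) tsv(res$rnaseq$differential, "mirna_transcript_diff")
    if (!is.null(res$smallrna)) tsv(res$smallrna$differential, "mirna_mature_diff")
    if (!is.null(res$splicing)) tsv(res$splicing, "mirtron_pir")
    if (!is.null(res$splice_map)) {
      tsv(cbind(side = "five_prime", res$splice_map$five_prime), "splice_hist_5p")
      tsv(cbind(side = "three_prime", res$splice_map$three_prime), "splice_hist_3p")
    }
    sm_out <- summary
    sm_out$runtime_sec <- NULL  # keep report bytes reproducible
    jsonlite::write_json(sm_out, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

serialize_config <- function(config) {
  x <- unclass(config)
  x$simulate <- unclass(x$simulate)
  x
}
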