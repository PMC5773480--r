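#' Configuration for an end-to-end synthetic run
#'
#' Bundles a genome specification, simulation parameters and analysis
#' settings. The configuration is validated on construction and a
#' serialised copy is written into the output directory by
#' [run_pipeline()].
#'
#' @param genome a [genome_spec()].
#' @param params a [sim_params()].
#' @param out_dir output directory (created if missing).
#' @param n_permutations permutations per feature set.
#' @param cutoff_motif SCE size cutoff for motif-scale features (10 kb).
#' @param cutoff_gene SCE size cutoff for gene/promoter features (100 kb).
#' @param shift_min,shift_max circular-shift range in bases.
#' @param promoter_length promoter length upstream of the TSS.
#' @param gc_window,gc_top_fraction high-GC control construction.
#' @param min_reads,eps SCE caller settings.
#' @param recurrence_max_fraction recurrent-region filter threshold.
#' @param subsample optional SCE count to subsample to before enrichment.
#' @param flanks flank widths (bases) at which the motif enrichment is
#'   additionally evaluated.
#' @param f1 simulate an F1 hybrid and run the allelic/LOH analyses.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome = genome_spec(), params = sim_params(),
                            out_dir = tempfile("sceG4_run_"),
                            n_permutations = 1000L,
                            cutoff_motif = 1e4, cutoff_gene = 1e5,
                            shift_min = 2e6, shift_max = 50e6,
                            promoter_length = 1000L,
                            gc_window = 1000L, gc_top_fraction = 0.1,
                            min_reads = 10L, eps = 0.02,
                            recurrence_max_fraction = 0.05,
                            subsample = NULL, flanks = c(0),
                            f1 = FALSE, seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"), inherits(params, "sim_params"))
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (cutoff_motif <= 0 || cutoff_gene <= 0) stop("cutoffs must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(seed, k) as.integer((seed %% 2147483L) * 100L + k)

#' Run the full synthetic analysis pipeline
#'
#' simulate -> call -> classify -> enrich -> report. Generates a synthetic
#' genome, simulates Strand-seq libraries, calls and filters SCEs, scans G4
#' and control features, runs the circular-permutation enrichment over the
#' full feature grid (genes, genes with/without G4 by activity, promoters
#' with/without G4, G4 loop-size families, A-rich and high-GC controls,
#' intergenic and intragenic G4 by strandedness and activity), detects
#' hotspots, and (optionally, `f1 = TRUE`) runs the homolog-concordance and
#' LOH analyses. All tables are written as TSV and a JSON manifest records
#' seeds, a config hash and record counts for every stage.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with all result tables (invisibly also written to
#'   `config$out_dir`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[sceG4] ", ...)
  counts <- list()

  config_file <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(serialise_config(config), config_file)
  config_hash <- unname(tools::md5sum(config_file))

  # stage 1: genome
  g_spec <- config$genome
  g_spec$seed <- stage_seed(config$seed, 1L)
  genome <- generate_genome(g_spec)
  say("genome: ", length(genome$sequences), " chromosomes, ",
      nrow(genome$g4_truth), " planted G4 motifs, ",
      nrow(genome$genes), " genes")

  # stage 2: features
  motifs <- scan_g4(genome$sequences, 1L, 7L)
  motifs13 <- scan_g4(genome$sequences, 1L, 3L)
  motifs112 <- scan_g4(genome$sequences, 1L, 12L)
  arich <- scan_a_rich(genome$sequences)
  gcw <- gc_windows(genome$sequences, config$gc_window,
                    config$gc_top_fraction)
  motifs <- classify_motif_context(motifs, genome$genes)
  promoters <- promoter_regions(genome$genes, config$promoter_length,
                                genome$index)
  say("features: ", nrow(motifs), " canonical G4 motifs (",
      nrow(motifs13), " loop 1-3, ", nrow(motifs112), " loop 1-12), ",
      nrow(arich), " A-rich, ", nrow(gcw), " high-GC windows")
  counts$motifs <- nrow(motifs)

  # stage 3: cells
  params <- config$params
  params$seed <- stage_seed(config$seed, 2L)
  f1 <- NULL
  if (config$f1) {
    f1 <- simulate_f1_hybrid(genome, params,
                             allelic_seed_fraction =
                               if (params$g4_enrichment_factor > 1) 0.3 else 0,
                             concordance_rate = 0.7)
    reads <- f1$reads; truth <- f1$truth
  } else {
    sim <- simulate_cells(genome, params, motifs = motifs)
    reads <- sim$reads; truth <- sim$truth
  }
  say("cells: ", params$n_cells, " libraries, ", nrow(reads), " reads, ",
      nrow(truth$true_sces), " true SCEs")
  counts$reads <- nrow(reads)
  counts$true_sces <- nrow(truth$true_sces)

  # stage 4: SCE calling
  segments <- infer_strand_states_all(reads, genome$index,
                                      min_reads = config$min_reads,
                                      eps = config$eps)
  sces <- call_sces(segments)
  filt <- filter_recurrent(sces, params$n_cells,
                           config$recurrence_max_fraction)
  sces_kept <- drop_gap_regions(filt$kept, genome$index)
  counts$sces_called <- nrow(sces)
  counts$sces_removed_recurrent <- nrow(filt$removed)
  counts$sces_removed_gap <- nrow(filt$kept) - nrow(sces_kept)
  counts$sces_kept <- nrow(sces_kept)
  say("SCE calling: ", nrow(sces), " called = ", nrow(sces_kept),
      " kept + ", nrow(filt$removed), " recurrent + ",
      counts$sces_removed_gap, " gap-overlapping")
  res_summary <- resolution_summary(sces_kept)
  say(sprintf("resolution: median %.1f kb, %.1f%% below 100 kb",
              res_summary$median_resolution / 1e3,
              100 * res_summary$fraction_below_100kb))

  if (config$f1)
    sces_kept <- assign_homolog(sces_kept, reads)

  if (!is.null(config$subsample))
    sces_kept <- subsample_sces(sces_kept, config$subsample,
                                stage_seed(config$seed, 3L))

  # stage 5: enrichment grid
  map <- build_gapless_map(genome$index)
  fois <- build_foi_grid(motifs, motifs13, motifs112, arich, gcw,
                         genome$genes, promoters)
  enr <- list()
  for (i in seq_along(fois)) {
    foi <- fois[[i]]
    cutoff <- if (attr(foi, "scale") == "motif") config$cutoff_motif else
      config$cutoff_gene
    use <- apply_size_cutoff(sces_kept, cutoff)
    enr[[names(fois)[i]]] <- permute_overlap(
      use, foi, map, config$n_permutations, config$shift_min,
      config$shift_max, seed = stage_seed(config$seed, 10L + i),
      foi_name = names(fois)[i])
  }
  enrichment <- data.frame(
    foi = names(enr),
    n_sces_used = vapply(enr, `[[`, 0, "n_sces_used"),
    observed = vapply(enr, `[[`, 0, "observed_overlap"),
    median_permuted = vapply(enr, `[[`, 0, "median_permuted"),
    relative_enrichment = vapply(enr, `[[`, 0, "relative_enrichment"),
    p_enrich = vapply(enr, `[[`, 0, "p_enrich"),
    p_enrich_label = vapply(enr, `[[`, "", "p_enrich_label"),
    p_deplete = vapply(enr, `[[`, 0, "p_deplete"),
    seed = vapply(enr, `[[`, 0L, "seed"), row.names = NULL,
    stringsAsFactors = FALSE)
  say("enrichment: ", nrow(enrichment), " feature sets, ",
      sum(enrichment$p_enrich < 0.05), " with p(enrich) < 0.05")

  # flank sensitivity on the canonical motif FOI
  flank_tab <- NULL
  if (length(config$flanks)) {
    use0 <- apply_size_cutoff(sces_kept, config$cutoff_motif)
    flank_tab <- data.frame(flank = config$flanks,
                            relative_enrichment = NA_real_,
                            p_enrich = NA_real_)
    for (j in seq_along(config$flanks)) {
      wide <- drop_gap_regions(
        add_flanks(use0, config$flanks[j], genome$index), genome$index)
      r <- permute_overlap(wide, motifs, map, config$n_permutations,
                           config$shift_min, config$shift_max,
                           seed = stage_seed(config$seed, 50L + j),
                           foi_name = sprintf("g4_flank_%d",
                                              config$flanks[j]))
      flank_tab$relative_enrichment[j] <- r$relative_enrichment
      flank_tab$p_enrich[j] <- r$p_enrich
    }
  }

  # stage 6: hotspots
  hotspots <- detect_hotspots(sces_kept)
  if (nrow(hotspots))
    hotspots <- score_hotspots(hotspots, map, nrow(sces_kept),
                               params$n_cells)
  say("hotspots: ", nrow(hotspots), " candidate(s)")

  # stage 7: expression quartiles + chromosome-size correlation
  quart <- expression_quartile_correlation(sces_kept, genome$genes,
                                           genome$expression)
  size_r2 <- tryCatch(
    chromosome_size_correlation(sces_kept, genome$index, params$n_cells),
    error = function(e) NA_real_)

  # stage 8 (optional): allelic G4 concordance + LOH + ploidy
  concordance <- loh <- ploidy <- allelic <- NULL
  if (config$f1) {
    allelic <- find_allelic_g4(f1$hap_a, f1$hap_b)
    concordance <- concordance_test(sces_kept, allelic)
    ploidy <- naive_ploidy(reads, genome$index)
    loh_list <- lapply(split(data.table::as.data.table(reads),
                             by = "cell_id"), function(r) {
      bins <- bin_haplotype_reads(r, genome$index)
      cs <- ploidy[ploidy$cell_id == r$cell_id[1L], ]
      call_loh(bins, copy_state =
                 cs$copy_state[match(bins$chrom, cs$chrom)])
    })
    keep <- vapply(loh_list, nrow, 0L) > 0
    loh <- if (any(keep))
      data.frame(cell_id = rep(names(loh_list)[keep],
                               vapply(loh_list[keep], nrow, 0L)),
                 do.call(rbind, loh_list[keep]), row.names = NULL)
    else data.frame()
    say("allelic: ", nrow(allelic), " allele-specific G4 motifs; ",
        concordance$n_informative, " informative SCEs, ",
        sprintf("%.0f%%", 100 * concordance$fraction_concordant),
        " concordant; ", nrow(loh), " LOH segment(s)")
  }

  # outputs
  out <- config$out_dir
  write_bed(transform(sces_kept, name = cell_id, score = resolution),
            file.path(out, "sces.bed"))
  data.table::fwrite(enrichment, file.path(out, "enrichment.tsv"),
                     sep = "\t")
  data.table::fwrite(as.data.frame(hotspots),
                     file.path(out, "hotspots.tsv"), sep = "\t")
  if (!is.null(flank_tab))
    data.table::fwrite(flank_tab, file.path(out, "flank_sensitivity.tsv"),
                       sep = "\t")
  manifest <- list(
    package = "sceG4",
    package_version = as.character(utils::packageVersion("sceG4")),
    r_version = R.version.string,
    seed = config$seed, config_hash = config_hash,
    stage_seeds = list(genome = g_spec$seed, cells = params$seed),
    counts = counts,
    resolution = res_summary[c("median_resolution",
                               "fraction_below_100kb")],
    chromosome_size_r2 = size_r2,
    expression_quartile = quart,
    outputs = list.files(out))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(genome = genome, motifs = motifs, reads = reads,
                 truth = truth, segments = segments, sces = sces_kept,
                 removed = filt$removed, enrichment = enrichment,
                 results = enr, flanks = flank_tab, hotspots = hotspots,
                 resolution = res_summary, quartiles = quart,
                 chromosome_size_r2 = size_r2, concordance = concordance,
                 allelic_g4 = allelic, loh = loh, ploidy = ploidy,
                 manifest = manifest, out_dir = out))
}

serialise_config <- function(config) {
  lapply(unclass(config), function(x)
    if (inherits(x, c("genome_spec", "sim_params"))) unclass(x) else x)
}

# the Fig 2/3-style feature grid
build_foi_grid <- function(motifs, motifs13, motifs112, arich, gcw,
                           genes, promoters) {
  gb <- gene_bodies(genes)
  gb$activity <- genes$activity
  with_g4 <- overlaps_feature(gb, motifs)
  prom_with_g4 <- overlaps_feature(promoters, motifs)
  grid <- list(
    genes = scale_attr(gb, "gene"),
    genes_active = scale_attr(gb[gb$activity == "active", ], "gene"),
    genes_silent = scale_attr(gb[gb$activity == "silent", ], "gene"),
    genes_active_with_g4 =
      scale_attr(gb[gb$activity == "active" & with_g4, ], "gene"),
    genes_active_without_g4 =
      scale_attr(gb[gb$activity == "active" & !with_g4, ], "gene"),
    genes_silent_with_g4 =
      scale_attr(gb[gb$activity == "silent" & with_g4, ], "gene"),
    genes_silent_without_g4 =
      scale_attr(gb[gb$activity == "silent" & !with_g4, ], "gene"),
    promoters = scale_attr(promoters, "gene"),
    promoters_with_g4 = scale_attr(promoters[prom_with_g4, ], "gene"),
    promoters_without_g4 = scale_attr(promoters[!prom_with_g4, ], "gene"),
    g4_canonical = scale_attr(motifs, "motif"),
    g4_loop_1_3 = scale_attr(motifs13, "motif"),
    g4_loop_1_12 = scale_attr(motifs112, "motif"),
    a_rich = scale_attr(arich, "motif"),
    gc_top_windows = scale_attr(gcw, "motif"),
    g4_intergenic = scale_attr(motifs[motifs$context == "intergenic", ],
                               "motif"),
    g4_transcribed_strand =
      scale_attr(motifs[motifs$context == "transcribed_strand", ], "motif"),
    g4_non_transcribed_strand =
      scale_attr(motifs[motifs$context == "non_transcribed_strand", ],
                 "motif"),
    g4_transcribed_active =
      scale_attr(motifs[motifs$context == "transcribed_strand" &
                          motifs$gene_activity == "active", ], "motif"),
    g4_non_transcribed_active =
      scale_attr(motifs[motifs$context == "non_transcribed_strand" &
                          motifs$gene_activity == "active", ], "motif"),
    g4_transcribed_silent =
      scale_attr(motifs[motifs$context == "transcribed_strand" &
                          motifs$gene_activity == "silent", ], "motif"),
    g4_non_transcribed_silent =
      scale_attr(motifs[motifs$context == "non_transcribed_strand" &
                          motifs$gene_activity == "silent", ], "motif"))
  grid[vapply(grid, nrow, 0L) > 0L]
}

scale_attr <- function(x, scale) { attr(x, "scale") <- scale; x }

overlaps_feature <- function(x, feat) {
  hit <- logical(nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch); fi <- which(feat$chrom == ch)
    if (!length(xi) || !length(fi)) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(x$start[xi] + 1L, x$end[xi]),
      IRanges::IRanges(feat$start[fi] + 1L, feat$end[fi]))
    hit[xi] <- ov
  }
  hit
}

#' Recover a planted G4 enrichment with the full pipeline
#'
#' Generates independent synthetic datasets with a planted relative SCE
#' excess at canonical G4 motifs, runs genome generation, motif scanning,
#' read simulation, SCE calling, recurrence and gap filtering, the size
#' cutoff and the circular-permutation test, and reports the relative
#' enrichment per replicate. The median percent enrichment across
#' replicates is the pipeline's estimate of the planted excess.
#'
#' @param n_seeds number of independent replicates.
#' @param base_seed integer seed from which per-replicate seeds derive.
#' @param n_cells libraries per replicate.
#' @param factor planted enrichment factor (1.2 = 20% over expected).
#' @param spec genome specification (default: the standard 3 x 30 Mb
#'   genome).
#' @param cutoff SCE size cutoff (default 10 kb).
#' @param n_permutations permutations per replicate.
#' @param quiet suppress progress messages.
#' @return data.frame per replicate: `seed`, `n_sces_used`,
#'   `observed`, `median_permuted`, `relative_enrichment`, `p_enrich`.
#' @export
enrichment_recovery <- function(n_seeds = 10L, base_seed = 1L,
                                n_cells = 300L, factor = 1.2,
                                spec = genome_spec(), cutoff = 1e4,
                                n_permutations = 1000L, quiet = FALSE) {
  out <- data.frame(seed = integer(n_seeds), n_sces_used = integer(n_seeds),
                    observed = integer(n_seeds),
                    median_permuted = numeric(n_seeds),
                    relative_enrichment = numeric(n_seeds),
                    p_enrich = numeric(n_seeds))
  for (i in seq_len(n_seeds)) {
    sd <- as.integer((base_seed %% 214748L) * 1000L + i)
    spec_i <- spec; spec_i$seed <- sd
    genome <- generate_genome(spec_i)
    motifs <- scan_g4(genome$sequences, 1L, 7L)
    params <- sim_params(n_cells = n_cells, g4_enrichment_factor = factor,
                         sce_size_cutoff = cutoff, seed = sd + 500000L)
    sim <- simulate_cells(genome, params, motifs = motifs)
    segments <- infer_strand_states_all(sim$reads, genome$index)
    sces <- call_sces(segments)
    filt <- filter_recurrent(sces, n_cells)
    kept <- apply_size_cutoff(drop_gap_regions(filt$kept, genome$index),
                              cutoff)
    map <- build_gapless_map(genome$index)
    r <- permute_overlap(kept, motifs, map, n_permutations,
                         seed = sd + 900000L, foi_name = "g4_canonical")
    out$seed[i] <- sd
    out$n_sces_used[i] <- r$n_sces_used
    out$observed[i] <- r$observed_overlap
    out$median_permuted[i] <- r$median_permuted
    out$relative_enrichment[i] <- r$relative_enrichment
    out$p_enrich[i] <- r$p_enrich
    if (!quiet)
      message(sprintf("[sceG4] replicate %d/%d: RE %.3f (p %s)", i, n_seeds,
                      r$relative_enrichment, format(r$p_enrich)))
    rm(genome, motifs, sim, segments, sces, filt, kept, map, r)
    gc(verbose = FALSE)
  }
  out
}
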