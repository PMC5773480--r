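#' Simulate an F1-hybrid Strand-seq experiment
#'
#' Extends [simulate_cells()] with two aligned haplotypes: heterozygous SNPs
#' are scattered over the genome (haplotype B carries the alternative
#' allele), a subset of planted G4 motifs is made allele-specific by
#' G-run-breaking substitutions on one haplotype, reads overlapping a SNP
#' carry their homolog's haplotype tag, and copy-neutral LOH segments and
#' trisomies can be planted. SCE breakpoints can be seeded inside
#' allele-specific motifs, landing on the motif-carrying homolog with a
#' tunable concordance rate.
#'
#' @param genome a [generate_genome()] result.
#' @param params a [sim_params()]; `g4_enrichment_factor` is ignored here
#'   (seeding is controlled by `allelic_seed_fraction`).
#' @param snp_rate heterozygous positions per base (default from the genome
#'   spec).
#' @param allelic_fraction fraction of planted motifs made allele-specific.
#' @param allelic_seed_fraction probability that an SCE breakpoint is placed
#'   inside an allele-specific motif (0 = uniform placement).
#' @param concordance_rate probability that a seeded SCE occurs on the
#'   homolog carrying the intact motif (0.5 = no relationship).
#' @param planted_loh optional data.frame (`chrom`, `start`, `end`,
#'   `haplotype_retained`) of copy-neutral LOH segments present in every
#'   cell.
#' @param planted_trisomy optional character vector of trisomic chromosomes
#'   (all cells; the extra copy is haplotype A).
#' @return list with `reads` (haplotype-tagged), `truth` (including
#'   `allelic_g4` and planted LOH/trisomy), `hap_a`/`hap_b` haplotype
#'   sequences (`DNAStringSet`) and the SNP table.
#' @export
simulate_f1_hybrid <- function(genome, params,
                               snp_rate = genome$spec$snp_rate,
                               allelic_fraction = 0.3,
                               allelic_seed_fraction = 0,
                               concordance_rate = 0.5,
                               planted_loh = NULL, planted_trisomy = NULL) {
  if (snp_rate <= 0) stop("snp_rate must be positive")
  set.seed(params$seed)
  map <- build_gapless_map(genome$index)
  chroms <- names(map$effective_length)
  EL <- map$effective_length

  # --- haplotype sequences ------------------------------------------------
  raw_a <- lapply(chroms, function(ch)
    charToRaw(as.character(genome$sequences[[ch]])))
  names(raw_a) <- chroms
  raw_b <- raw_a

  # allele-specific motifs: break every G-run on one haplotype
  g4 <- genome$g4_truth
  n_allelic <- round(allelic_fraction * nrow(g4))
  allelic_idx <- sort(sample.int(nrow(g4), n_allelic))
  allelic <- g4[allelic_idx, , drop = FALSE]
  allelic$haplotype <- sample(c("A", "B"), n_allelic, replace = TRUE)
  break_snps <- vector("list", n_allelic)
  for (i in seq_len(n_allelic)) {
    ch <- allelic$chrom[i]
    s <- allelic$start[i]; e <- allelic$end[i]
    seg <- rawToChar(raw_a[[ch]][(s + 1):e])
    run_char <- if (allelic$strand[i] == "+") "G" else "C"
    runs <- gregexpr(sprintf("%s{3,}", run_char), seg)[[1L]]
    pos <- s + as.integer(runs) - 1L +
      floor(attr(runs, "match.length") / 2)       # 0-based, run centres
    alt <- charToRaw(if (run_char == "G") "A" else "T")
    broken_hap <- if (allelic$haplotype[i] == "A") "B" else "A"
    if (broken_hap == "B")
      raw_b[[ch]][pos + 1L] <- alt
    else
      raw_a[[ch]][pos + 1L] <- alt
    break_snps[[i]] <- data.frame(chrom = ch, pos = pos,
                                  stringsAsFactors = FALSE)
  }

  # background SNPs over non-gap bases, masked away from planted motifs
  bg <- list()
  for (ch in chroms) {
    n_snp <- stats::rpois(1, snp_rate * EL[[ch]])
    gl <- floor(stats::runif(n_snp, 0, EL[[ch]]))
    pos <- unique(gapless_to_genomic(map, ch, gl))
    m <- g4[g4$chrom == ch, , drop = FALSE]
    if (nrow(m)) {
      near <- IRanges::overlapsAny(
        IRanges::IRanges(pos + 1L, pos + 1L),
        IRanges::IRanges(m$start - 24L, m$end + 25L))
      pos <- pos[!near]
    }
    if (!length(pos)) next
    ref <- raw_a[[ch]][pos + 1L]
    alt <- vapply(rawToChar(ref, multiple = TRUE), function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    raw_b[[ch]][pos + 1L] <- charToRaw(paste(alt, collapse = ""))
    bg[[ch]] <- data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }
  snps <- rbind(do.call(rbind, bg), do.call(rbind, break_snps))
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  snp_pos <- split(snps$pos, snps$chrom)

  hap_a <- Biostrings::DNAStringSet(vapply(raw_a, rawToChar, character(1)))
  hap_b <- Biostrings::DNAStringSet(vapply(raw_b, rawToChar, character(1)))
  names(hap_a) <- names(hap_b) <- chroms

  # --- cells --------------------------------------------------------------
  cumEL <- c(0, cumsum(EL))
  total_EL <- sum(EL)
  n_reads_mean <- params$coverage_fraction * total_EL / params$read_length
  tris <- planted_trisomy %||% character(0)
  cells <- sprintf("cell%03d", seq_len(params$n_cells))
  read_list <- sce_list <- vector("list", params$n_cells)

  for (i in seq_len(params$n_cells)) {
    states <- sample(c("WW", "WC", "CC"), length(chroms), replace = TRUE)
    hapA_t <- hapB_t <- character(length(chroms))
    for (k in seq_along(chroms)) {
      if (states[k] == "WW") { hapA_t[k] <- "W"; hapB_t[k] <- "W" }
      else if (states[k] == "CC") { hapA_t[k] <- "C"; hapB_t[k] <- "C" }
      else if (stats::runif(1) < 0.5) { hapA_t[k] <- "W"; hapB_t[k] <- "C" }
      else { hapA_t[k] <- "C"; hapB_t[k] <- "W" }
    }
    # SCEs: optionally seeded inside allele-specific motifs
    n_sce <- stats::rpois(1, params$sce_rate_per_cell)
    seeded <- stats::runif(n_sce) < allelic_seed_fraction & n_allelic > 0
    chrom_v <- character(n_sce); pos_v <- numeric(n_sce)
    hom_v <- character(n_sce); motif_hap <- rep(NA_character_, n_sce)
    if (any(!seeded)) {
      gl <- stats::runif(sum(!seeded), 0, total_EL)
      ci <- findInterval(gl, cumEL, rightmost.closed = TRUE)
      ci[ci > length(chroms)] <- length(chroms)
      up <- numeric(sum(!seeded))
      for (k in unique(ci))
        up[ci == k] <- gapless_to_genomic(map, chroms[k],
                                          floor(gl[ci == k] - cumEL[k]))
      chrom_v[!seeded] <- chroms[ci]
      pos_v[!seeded] <- up
      hom_v[!seeded] <- sample(c("A", "B"), sum(!seeded), replace = TRUE)
    }
    if (any(seeded)) {
      mi <- sample.int(n_allelic, sum(seeded), replace = TRUE,
                       prob = allelic$end - allelic$start)
      chrom_v[seeded] <- allelic$chrom[mi]
      pos_v[seeded] <- floor(stats::runif(sum(seeded), allelic$start[mi],
                                          allelic$end[mi]))
      motif_hap[seeded] <- allelic$haplotype[mi]
      conc <- stats::runif(sum(seeded)) < concordance_rate
      hom_v[seeded] <- ifelse(conc, motif_hap[seeded],
                              ifelse(motif_hap[seeded] == "A", "B", "A"))
    }
    sces <- data.frame(chrom = chrom_v, pos = pos_v, homolog = hom_v,
                       seeded = seeded, motif_haplotype = motif_hap,
                       stringsAsFactors = FALSE)

    # reads: trisomic chromosomes get 1.5x density, extra copy is hap A
    dens_w <- ifelse(chroms %in% tris, 1.5, 1)
    n_reads <- stats::rpois(1, n_reads_mean * sum(EL * dens_w) / total_EL)
    gl <- stats::runif(n_reads, 0, sum(EL * dens_w))
    cumW <- c(0, cumsum(EL * dens_w))
    ci <- findInterval(gl, cumW, rightmost.closed = TRUE)
    ci[ci > length(chroms)] <- length(chroms)
    gl_local <- (gl - cumW[ci]) / dens_w[ci]
    start <- numeric(n_reads)
    homolog <- character(n_reads)
    label <- character(n_reads)
    for (k in seq_along(chroms)) {
      sel <- which(ci == k)
      if (!length(sel)) next
      start[sel] <- gapless_to_genomic(map, chroms[k], floor(gl_local[sel]))
      pA <- if (chroms[k] %in% tris) 2 / 3 else 0.5
      homolog[sel] <- ifelse(stats::runif(length(sel)) < pA, "A", "B")
      # planted LOH: reads in the segment all come from the retained homolog
      if (!is.null(planted_loh)) {
        lo <- planted_loh[planted_loh$chrom == chroms[k], , drop = FALSE]
        for (j in seq_len(nrow(lo))) {
          inside <- sel[start[sel] >= lo$start[j] & start[sel] < lo$end[j]]
          homolog[inside] <- lo$haplotype_retained[j]
        }
      }
      bp <- sces[sces$chrom == chroms[k], , drop = FALSE]
      for (h in c("A", "B")) {
        hs <- sel[homolog[sel] == h]
        if (!length(hs)) next
        init <- if (h == "A") hapA_t[k] else hapB_t[k]
        flips <- sort(bp$pos[bp$homolog == h])
        nflip <- findInterval(start[hs], flips)
        label[hs] <- ifelse(nflip %% 2 == 0, init, flip_label(init))
      }
    }
    flip <- stats::runif(n_reads) < params$background_noise
    label[flip] <- flip_label(label[flip])
    # haplotype tag only for reads covering a SNP
    tag <- rep(".", n_reads)
    for (k in seq_along(chroms)) {
      sel <- which(ci == k)
      sp <- snp_pos[[chroms[k]]]
      if (!length(sel) || is.null(sp)) next
      iv <- findInterval(start[sel] + params$read_length - 1, sp) -
        findInterval(start[sel] - 1, sp)
      tag[sel[iv > 0]] <- homolog[sel[iv > 0]]
    }
    read_list[[i]] <- data.table::data.table(
      chrom = chroms[ci], start = start,
      end = pmin(start + params$read_length,
                 map$chrom_lengths[chroms[ci]]),
      label = label, haplotype = tag, cell_id = cells[i])
    if (nrow(sces))
      sce_list[[i]] <- data.table::data.table(cell_id = cells[i], sces)
  }
  reads <- data.table::rbindlist(read_list)
  data.table::setkey(reads, cell_id, chrom, start)
  truth <- list(true_sces = as.data.frame(data.table::rbindlist(sce_list)),
                allelic_g4 = allelic[, c("chrom", "start", "end", "strand",
                                         "haplotype")],
                true_loh = planted_loh %||% data.frame(),
                true_trisomies = tris,
                snp_count = nrow(snps))
  list(reads = reads, truth = truth, hap_a = hap_a, hap_b = hap_b,
       snps = snps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
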