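#' Specification for a synthetic genome
#'
#' Parameters of the synthetic genome generator. Defaults emulate the study
#' conditions scaled to a desk-sized genome: three 30 Mb chromosomes, 2%
#' assembly gaps, planted canonical G4 motifs every ~8.6 kb on average, and
#' 600 genes covering ~20% of the genome of which 60% are transcribed
#' (FPKM > 1), so that gene-dense and gene-poor sequence are both
#' represented.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_lengths integer vector of chromosome lengths (recycled to
#'   `n_chromosomes`).
#' @param gap_fraction fraction of each chromosome covered by assembly gaps,
#'   in `[0, 0.5)`.
#' @param g4_spacing_target mean bases between planted G4 motifs.
#' @param gene_count number of genes across the genome.
#' @param active_fraction fraction of genes with FPKM > 1.
#' @param snp_rate heterozygous positions per base (used by
#'   [simulate_f1_hybrid()]).
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 3L, chrom_lengths = 30e6,
                        gap_fraction = 0.02, g4_spacing_target = 8600,
                        gene_count = 600L, active_fraction = 0.6,
                        snp_rate = 0.008, seed = 1L) {
  chrom_lengths <- as.numeric(rep_len(chrom_lengths, n_chromosomes))
  if (any(chrom_lengths <= 0)) stop("chrom_lengths must be positive")
  if (gap_fraction < 0 || gap_fraction >= 0.5)
    stop("gap_fraction must be in [0, 0.5)")
  if (active_fraction < 0 || active_fraction > 1)
    stop("active_fraction must be in [0, 1]")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_lengths = chrom_lengths,
                 gap_fraction = gap_fraction,
                 g4_spacing_target = g4_spacing_target,
                 gene_count = as.integer(gene_count),
                 active_fraction = active_fraction,
                 snp_rate = snp_rate, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome with planted G4 motifs and genes
#'
#' Builds uniform-random chromosome sequences, carves assembly gaps (N
#' blocks), plants canonical G4 motifs (four G-runs of 3-5 bases, loops of
#' 1-7 bases drawn from A/C/T, random strand) at exponentially distributed
#' spacings, places non-overlapping genes, and assigns FPKM values so that
#' `active_fraction` of genes is transcribed. Twenty bases flanking each
#' planted motif are kept free of G and C so that every planted motif is
#' recovered by [scan_g4()] at its exact coordinates.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `synthetic_genome`: list with `sequences`
#'   (named `DNAStringSet`), `index` ([genome_index()]), `genes`,
#'   `g4_truth`, `expression` and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  min_len <- max(50e3, 4 * spec$g4_spacing_target)
  if (any(spec$chrom_lengths < min_len))
    stop("chromosome too short to host requested features (need >= ",
         min_len, " bases)")
  bases <- charToRaw("ACGT")
  seqs <- vector("list", length(chroms))
  gap_rows <- list(); g4_rows <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    L <- spec$chrom_lengths[ci]
    raw <- sample(bases, L, replace = TRUE)

    # assembly gaps: blocks of N totalling ~gap_fraction of the chromosome
    gaps <- place_gaps(L, spec$gap_fraction)
    if (nrow(gaps)) {
      for (gi in seq_len(nrow(gaps)))
        raw[(gaps$start[gi] + 1):gaps$end[gi]] <- charToRaw("N")
      gaps$chrom <- ch
      gap_rows[[ci]] <- gaps[, c("chrom", "start", "end")]
    }

    # planted G4 motifs at ~exponential spacing, avoiding gaps
    plant <- plant_g4_motifs(raw, L, gaps, spec$g4_spacing_target)
    raw <- plant$raw
    if (nrow(plant$motifs)) {
      plant$motifs$chrom <- ch
      g4_rows[[ci]] <- plant$motifs[, c("chrom", "start", "end", "strand")]
    }
    seqs[[ci]] <- rawToChar(raw)
  }
  gaps_all <- if (length(gap_rows)) do.call(rbind, gap_rows) else NULL
  index <- genome_index(stats::setNames(spec$chrom_lengths, chroms), gaps_all)
  g4_truth <- do.call(rbind, g4_rows)
  rownames(g4_truth) <- NULL
  g4_truth$width <- g4_truth$end - g4_truth$start

  genes <- place_genes(spec, index)
  n_active <- round(spec$active_fraction * nrow(genes))
  is_active <- seq_len(nrow(genes)) %in% sample.int(nrow(genes), n_active)
  fpkm <- ifelse(is_active,
                 1 + stats::rlnorm(nrow(genes), meanlog = 1.5, sdlog = 1),
                 stats::runif(nrow(genes), 0, 0.999))
  expression <- data.frame(gene_id = genes$gene_id, fpkm = fpkm,
                           stringsAsFactors = FALSE)
  genes$fpkm <- fpkm
  genes$activity <- unname(classify_gene_activity(expression))

  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequences) <- chroms
  structure(list(sequences = sequences, index = index, genes = genes,
                 g4_truth = g4_truth, expression = expression, spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", length(x$sequences), "chromosomes,",
      sum(as.numeric(x$index$chrom_lengths)), "bp;",
      nrow(x$g4_truth), "planted G4 motifs;",
      nrow(x$genes), "genes (",
      sum(x$genes$activity == "active"), "active )\n")
  invisible(x)
}

place_gaps <- function(L, gap_fraction) {
  if (gap_fraction <= 0)
    return(data.frame(start = integer(), end = integer()))
  total <- round(gap_fraction * L)
  gap_w <- min(1e5, max(1000, round(total / 4)))
  n_gaps <- max(1L, round(total / gap_w))
  widths <- rep(gap_w, n_gaps)
  widths[n_gaps] <- total - gap_w * (n_gaps - 1L)
  margin <- round(0.02 * L)
  starts <- numeric(0)
  tries <- 0L
  while (length(starts) < n_gaps && tries < 200L) {
    cand <- round(stats::runif(1, margin, L - margin - max(widths)))
    if (!length(starts) ||
        all(abs(cand - starts) > max(widths) + 1000)) {
      starts <- c(starts, cand)
    }
    tries <- tries + 1L
  }
  if (length(starts) < n_gaps)
    stop("chromosome too short to host requested gap fraction")
  starts <- sort(starts)
  data.frame(start = starts, end = starts + widths[seq_along(starts)])
}

plant_g4_motifs <- function(raw, L, gaps, spacing) {
  margin <- 100L
  pos <- margin + round(stats::rexp(1, 1 / spacing))
  starts <- integer(); ends <- integer(); strands <- character()
  loop_alpha <- charToRaw("ACT")
  while (pos < L - margin) {
    runs <- sample(3:5, 4L, replace = TRUE)
    loops <- sample.int(7L, 3L, replace = TRUE)
    w <- sum(runs) + sum(loops)
    s <- pos; e <- pos + w
    in_gap <- nrow(gaps) && any(gaps$start < e + 25 & gaps$end > s - 25)
    if (!in_gap) {
      motif <- raw_g4_motif(runs, loops, loop_alpha)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-")
        motif <- rev(charToRaw(chartr("ACGT", "TGCA", rawToChar(motif))))
      raw[(s + 1):e] <- motif
      # keep 20 bp flanks free of G/C so the planted coordinates are exact
      for (fl in list((s - 20):(s - 1) + 1L, (e + 1):(e + 20))) {
        bad <- fl[raw[fl] %in% charToRaw("GC")]
        if (length(bad))
          raw[bad] <- sample(charToRaw("AT"), length(bad), replace = TRUE)
      }
      starts <- c(starts, s); ends <- c(ends, e); strands <- c(strands, strand)
    }
    pos <- pos + max(200, round(stats::rexp(1, 1 / spacing)))
  }
  list(raw = raw,
       motifs = data.frame(start = starts, end = ends, strand = strands,
                           stringsAsFactors = FALSE))
}

raw_g4_motif <- function(runs, loops, loop_alpha) {
  parts <- list(rep(charToRaw("G"), runs[1]))
  for (i in 1:3) {
    parts <- c(parts, list(sample(loop_alpha, loops[i], replace = TRUE)),
               list(rep(charToRaw("G"), runs[i + 1])))
  }
  do.call(c, parts)
}

place_genes <- function(spec, index) {
  chroms <- names(index$chrom_lengths)
  lens <- index$chrom_lengths
  prob <- lens / sum(lens)
  n <- spec$gene_count
  chrom <- sample(chroms, n, replace = TRUE, prob = prob)
  body_len <- pmin(pmax(round(stats::rlnorm(n, log(2.5e4), 0.7)), 5e3), 1.5e5)
  out <- data.frame(gene_id = sprintf("gene%04d", seq_len(n)), chrom = chrom,
                    start = NA_real_, end = NA_real_,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  for (ch in chroms) {
    idx <- which(out$chrom == ch)
    if (!length(idx)) next
    L <- lens[[ch]]
    g <- index$gaps[index$gaps$chrom == ch, , drop = FALSE]
    placed_s <- g$start; placed_e <- g$end   # avoid gaps
    for (i in idx) {
      w <- body_len[i]
      ok <- FALSE
      for (try in 1:400) {
        s <- round(stats::runif(1, 2000, L - w - 2000))
        if (!length(placed_s) || all(s + w + 500 <= placed_s | s - 500 >= placed_e)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("chromosome too short to host requested gene count")
      out$start[i] <- s; out$end[i] <- s + w
      placed_s <- c(placed_s, s); placed_e <- c(placed_e, s + w)
    }
  }
  # tss/tes by strand: tss is the 5' end of the gene body
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out$tes <- ifelse(out$strand == "+", out$end, out$start)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("gene_id", "chrom", "tss", "tes", "strand")]
}
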