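#' Parameters for simulating Strand-seq libraries
#'
#' Defaults emulate the study conditions: ~1.5% genome coverage per library,
#' 100-base reads, a 2% strand-label error rate, and a Bloom-syndrome-like
#' SCE load giving a few thousand events across a 300-cell line on the
#' default synthetic genome.
#'
#' @param n_cells number of single-cell libraries.
#' @param sce_rate_per_cell mean SCEs per cell (Poisson).
#' @param g4_enrichment_factor target relative enrichment of SCE regions at
#'   canonical G4 motifs in the downstream permutation analysis (1.0 =
#'   uniform null). See Details.
#' @param coverage_fraction fraction of the genome covered by reads per
#'   cell, in `(0, 1]`.
#' @param read_length read length in bases.
#' @param background_noise probability that a read carries the wrong strand
#'   label, in `[0, 0.5)`.
#' @param sce_size_cutoff SCE region size cutoff (bases) at which the
#'   enrichment factor is calibrated (default 10 kb, the cutoff used for
#'   G4 analyses).
#' @param hotspot optional list `(chrom, pos, fraction, width)`: each cell
#'   gains an extra SCE with probability `fraction`, placed uniformly in
#'   the `width` bases (default 1e5) around `pos` - a planted fragile-site
#'   hotspot. The regional spread mirrors fragile sites, whose breakpoints
#'   scatter over many kilobases, and distinguishes a hotspot from a
#'   stable rearrangement (always the exact same breakpoint), which the
#'   recurrence filter removes.
#' @param stable_breakpoints optional data.frame `(chrom, pos)` of stable
#'   rearrangement breakpoints present in every cell; these produce
#'   recurrent state switches but are not SCEs.
#' @param seed integer seed.
#'
#' @details The factor is defined at the level of the readout: the
#' breakpoint mixture is calibrated (see [sce_seed_probability()]) so that
#' the expected number of called SCE regions (at the stated size cutoff)
#' overlapping at least one G4 motif is `g4_enrichment_factor` times the
#' circular-permutation expectation. Because the binary overlap statistic
#' saturates for region sizes comparable to the motif spacing, not every
#' factor is representable at every coverage; infeasible factors raise an
#' error stating the maximum achievable value.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_cells = 100L, sce_rate_per_cell = 8,
                       g4_enrichment_factor = 1.2,
                       coverage_fraction = 0.015, read_length = 100L,
                       background_noise = 0.02, sce_size_cutoff = 10e3,
                       hotspot = NULL, stable_breakpoints = NULL,
                       seed = 1L) {
  if (coverage_fraction <= 0 || coverage_fraction > 1)
    stop("coverage_fraction must be in (0, 1]")
  if (background_noise < 0 || background_noise >= 0.5)
    stop("background_noise must be in [0, 0.5)")
  if (g4_enrichment_factor < 1)
    stop("g4_enrichment_factor must be >= 1 (depletion seeding not supported)")
  if (sce_rate_per_cell < 0) stop("sce_rate_per_cell must be >= 0")
  structure(list(n_cells = as.integer(n_cells),
                 sce_rate_per_cell = sce_rate_per_cell,
                 g4_enrichment_factor = g4_enrichment_factor,
                 coverage_fraction = coverage_fraction,
                 read_length = as.integer(read_length),
                 background_noise = background_noise,
                 sce_size_cutoff = sce_size_cutoff,
                 hotspot = hotspot, stable_breakpoints = stable_breakpoints,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Calibrated probability of seeding an SCE at a G4 motif
#'
#' Computes the mixture weight `p` with which SCE breakpoints must be placed
#' inside G4 motifs so that the expected relative enrichment of called SCE
#' regions at the motif feature set equals a target factor `f`.
#'
#' The model: reads are a homogeneous Poisson process of rate
#' `lambda = coverage_fraction / read_length` per non-gap base, so the
#' inter-read gap containing a breakpoint is Gamma(2, lambda) (size-biased)
#' and ordinary gaps are Exp(lambda). Two caller effects displace the called
#' region off the breakpoint: (i) maximum-likelihood changepoints absorb
#' reads that follow the breakpoint but carry the pre-switch label - under
#' the mixed (WC) state this happens per read with probability 1/2; (ii) a
#' noise-flipped read among the first `j` reads on the pure-state side drags
#' the boundary past the breakpoint, where
#' `j = 1 + floor(log(0.5/eps) / log((1-eps)/0.5))` is the depth at which
#' the reassignment still gains likelihood (`j = 5`, capture probability
#' `1-(1-eps)^5 ~ 0.096` at the default `eps = 0.02`). The called region
#' therefore contains the breakpoint with probability
#' `w0 = (1 - capture)/2` (its own size-biased gap), else it is a
#' neighbouring ordinary gap. Motif starts are treated as Poisson with rate
#' `r = n_motifs / effective_length`; a region of gapless length `g`
#' overlaps a motif with probability `1 - exp(-(g + w) r)` (`w` = mean motif
#' width). Regions longer than the size cutoff `c` are discarded. Writing
#' `pi1 = P(Exp <= c)`, `pi2 = P(Gamma2 <= c)` and `A`, `B` for the
#' truncated-mean overlap probabilities of the two gap types, the expected
#' relative enrichment is
#' `1 + p * w0 pi2 (1 - A) / (w0 pi2 A + (1-w0) pi1 B)` and `p` solves it
#' for `f`.
#'
#' @param map a [build_gapless_map()].
#' @param motifs motif table (the feature set the factor refers to).
#' @param params a [sim_params()].
#' @return list with `p` (seeding probability), `q_null` (expected null
#'   overlap fraction of kept regions), `max_factor`, and the model pieces.
#' @export
sce_seed_probability <- function(map, motifs, params) {
  lambda <- params$coverage_fraction / params$read_length
  cc <- params$sce_size_cutoff
  EL <- sum(map$effective_length)
  r <- nrow(motifs) / EL
  w <- mean(motifs$end - motifs$start)
  f <- params$g4_enrichment_factor
  pi1 <- 1 - exp(-lambda * cc)
  pi2 <- 1 - (1 + lambda * cc) * exp(-lambda * cc)
  q <- function(g) 1 - exp(-(g + w) * r)
  A <- stats::integrate(function(g) q(g) * lambda^2 * g * exp(-lambda * g),
                        0, cc, rel.tol = 1e-9)$value / pi2
  B <- stats::integrate(function(g) q(g) * lambda * exp(-lambda * g),
                        0, cc, rel.tol = 1e-9)$value / pi1
  eps <- params$background_noise
  capture <- if (eps > 0)
    1 - (1 - eps)^(1 + floor(log(0.5 / eps) / log((1 - eps) / 0.5))) else 0
  w0 <- 0.5 * (1 - capture)
  denom <- w0 * pi2 * A + (1 - w0) * pi1 * B
  max_factor <- 1 + w0 * pi2 * (1 - A) / denom
  p <- (f - 1) * denom / (w0 * pi2 * (1 - A))
  if (p > 1)
    stop(sprintf(paste0("g4_enrichment_factor %.3g is not representable at ",
                        "this coverage/cutoff (max achievable ~%.3g); ",
                        "increase coverage_fraction or lower the factor"),
                 f, max_factor))
  list(p = p,
       q_null = denom / (w0 * pi2 + (1 - w0) * pi1),
       max_factor = max_factor, w0 = w0, capture = capture,
       pi1 = pi1, pi2 = pi2, A = A, B = B, lambda = lambda, r = r, w = w)
}

#' Simulate Strand-seq libraries with planted SCEs
#'
#' For each cell, draws a template-strand state per chromosome (uniform over
#' WW/WC/CC), plants Poisson-distributed SCE breakpoints (each toggling one
#' homolog's template), and samples directional reads as a homogeneous
#' Poisson process over non-gap bases. Breakpoints are seeded inside G4
#' motifs overlapping active genes with the calibrated probability
#' (see [sce_seed_probability()]); the remainder are uniform over non-gap
#' bases. Read labels follow the template strand of the read's homolog at
#' its position, then flip with probability `background_noise`.
#'
#' @param genome a [generate_genome()] result.
#' @param params a [sim_params()].
#' @param motifs motif table used for enrichment seeding and calibration;
#'   defaults to the planted motifs (`genome$g4_truth`). Pass the scanned
#'   motif set to calibrate against the feature set used downstream.
#' @return list with `reads` (data.table: `chrom`, `start`, `end`, `label`,
#'   `haplotype`, `cell_id`) and `truth` (list with `true_sces`,
#'   `initial_states`, calibration info, empty LOH/trisomy slots).
#' @export
simulate_cells <- function(genome, params, motifs = genome$g4_truth) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  map <- build_gapless_map(genome$index)
  chroms <- names(map$effective_length)
  EL <- map$effective_length
  cumEL <- c(0, cumsum(EL))
  total_EL <- sum(EL)

  # seeding targets: motifs overlapping active gene bodies
  seed_targets <- motifs_in_active_genes(motifs, genome$genes)
  cal <- list(p = 0, q_null = NA_real_)
  if (params$g4_enrichment_factor > 1) {
    if (!nrow(seed_targets))
      stop("no G4 motifs overlap active genes; cannot seed enrichment")
    cal <- sce_seed_probability(map, motifs, params)
  }

  n_reads_per_cell <- params$coverage_fraction * total_EL / params$read_length
  cells <- sprintf("cell%03d", seq_len(params$n_cells))
  read_list <- vector("list", params$n_cells)
  sce_list <- vector("list", params$n_cells)
  state_list <- vector("list", params$n_cells)

  for (i in seq_len(params$n_cells)) {
    sim <- simulate_one_cell(cells[i], map, chroms, EL, cumEL, total_EL,
                             params, cal$p, seed_targets, n_reads_per_cell)
    read_list[[i]] <- sim$reads
    sce_list[[i]] <- sim$sces
    state_list[[i]] <- sim$states
  }
  reads <- data.table::rbindlist(read_list)
  data.table::setkey(reads, cell_id, chrom, start)
  true_sces <- data.table::rbindlist(sce_list)
  truth <- list(true_sces = as.data.frame(true_sces),
                initial_states = data.table::rbindlist(state_list),
                true_loh = data.frame(), true_trisomies = data.frame(),
                allelic_g4 = NULL,
                p_seed = cal$p, q_null = cal$q_null,
                expected_re = params$g4_enrichment_factor)
  list(reads = reads, truth = truth)
}

motifs_in_active_genes <- function(motifs, genes) {
  if (!nrow(motifs)) return(motifs)
  act <- genes[genes$activity == "active", , drop = FALSE]
  if (!nrow(act)) return(motifs[0, , drop = FALSE])
  gb <- gene_bodies(act)
  keep <- logical(nrow(motifs))
  for (ch in unique(motifs$chrom)) {
    mi <- which(motifs$chrom == ch)
    gi <- which(gb$chrom == ch)
    if (!length(mi) || !length(gi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(motifs$start[mi] + 1L, motifs$end[mi]),
      IRanges::IRanges(gb$start[gi] + 1L, gb$end[gi]))
    keep[mi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  motifs[keep, , drop = FALSE]
}

simulate_one_cell <- function(cell_id, map, chroms, EL, cumEL, total_EL,
                              params, p_seed, seed_targets, n_reads_mean) {
  # template-strand state per chromosome, uniform over WW/WC/CC
  states <- sample(c("WW", "WC", "CC"), length(chroms), replace = TRUE)
  # homolog templates: hapA, hapB in {W, C}
  hapA <- hapB <- character(length(chroms))
  for (k in seq_along(chroms)) {
    if (states[k] == "WW") { hapA[k] <- "W"; hapB[k] <- "W" }
    else if (states[k] == "CC") { hapA[k] <- "C"; hapB[k] <- "C" }
    else {
      if (stats::runif(1) < 0.5) { hapA[k] <- "W"; hapB[k] <- "C" }
      else { hapA[k] <- "C"; hapB[k] <- "W" }
    }
  }

  # SCE breakpoints
  n_sce <- stats::rpois(1, params$sce_rate_per_cell)
  sces <- draw_breakpoints(n_sce, p_seed, seed_targets, map, chroms,
                           EL, cumEL, total_EL)
  if (!is.null(params$hotspot) &&
      stats::runif(1) < params$hotspot$fraction) {
    w <- params$hotspot$width %||% 1e5
    sces <- rbind(sces, data.frame(
      chrom = params$hotspot$chrom,
      pos = round(params$hotspot$pos + stats::runif(1, -w / 2, w / 2)),
      seeded = FALSE, stringsAsFactors = FALSE))
  }
  sces$homolog <- sample(c("A", "B"), nrow(sces), replace = TRUE)
  sces$is_sce <- rep(TRUE, nrow(sces))
  if (!is.null(params$stable_breakpoints)) {
    sb <- params$stable_breakpoints
    sces <- rbind(sces, data.frame(chrom = sb$chrom, pos = sb$pos,
                                   seeded = FALSE,
                                   homolog = rep("A", nrow(sb)),
                                   is_sce = FALSE, stringsAsFactors = FALSE))
  }

  # reads: homogeneous Poisson over the gapless genome
  n_reads <- stats::rpois(1, n_reads_mean)
  gl <- stats::runif(n_reads, 0, total_EL)
  ci <- findInterval(gl, cumEL, rightmost.closed = TRUE)
  ci[ci > length(chroms)] <- length(chroms)
  gl_local <- gl - cumEL[ci]
  homolog <- sample(c("A", "B"), n_reads, replace = TRUE)
  label <- character(n_reads)
  start <- numeric(n_reads)
  for (k in seq_along(chroms)) {
    sel <- which(ci == k)
    if (!length(sel)) next
    start[sel] <- gapless_to_genomic(map, chroms[k], floor(gl_local[sel]))
    bp <- sces[sces$chrom == chroms[k], , drop = FALSE]
    for (h in c("A", "B")) {
      hs <- sel[homolog[sel] == h]
      if (!length(hs)) next
      init <- if (h == "A") hapA[k] else hapB[k]
      flips <- sort(bp$pos[bp$homolog == h])
      nflip <- findInterval(start[hs], flips)
      lab <- ifelse(nflip %% 2 == 0, init, flip_label(init))
      label[hs] <- lab
    }
  }
  per_chr <- tabulate(ci, nbins = length(chroms))
  if (any(per_chr < 2))
    warning("cell ", cell_id, ": fewer than 2 reads on ",
            paste(chroms[per_chr < 2], collapse = ","),
            "; cell still emitted")
  flip <- stats::runif(n_reads) < params$background_noise
  label[flip] <- flip_label(label[flip])
  reads <- data.table::data.table(
    chrom = chroms[ci], start = start,
    end = pmin(start + params$read_length, map$chrom_lengths[chroms[ci]]),
    label = label, haplotype = ".", cell_id = cell_id)
  truth_sces <- if (nrow(sces)) {
    s <- sces[sces$is_sce, , drop = FALSE]
    if (nrow(s)) data.table::data.table(cell_id = cell_id, chrom = s$chrom,
                                        pos = s$pos, homolog = s$homolog,
                                        seeded = s$seeded) else NULL
  } else NULL
  list(reads = reads, sces = truth_sces,
       states = data.table::data.table(cell_id = cell_id, chrom = chroms,
                                       state = states, hapA = hapA,
                                       hapB = hapB))
}

draw_breakpoints <- function(n, p_seed, seed_targets, map, chroms,
                             EL, cumEL, total_EL) {
  if (n == 0)
    return(data.frame(chrom = character(), pos = numeric(),
                      seeded = logical(), stringsAsFactors = FALSE))
  seeded <- stats::runif(n) < p_seed
  chrom <- character(n); pos <- numeric(n)
  n_uni <- sum(!seeded)
  if (n_uni) {
    gl <- stats::runif(n_uni, 0, total_EL)
    ci <- findInterval(gl, cumEL, rightmost.closed = TRUE)
    ci[ci > length(chroms)] <- length(chroms)
    upos <- numeric(n_uni)
    for (k in unique(ci)) {
      s <- which(ci == k)
      upos[s] <- gapless_to_genomic(map, chroms[k], floor(gl[s] - cumEL[k]))
    }
    chrom[!seeded] <- chroms[ci]
    pos[!seeded] <- upos
  }
  if (any(seeded)) {
    wts <- seed_targets$end - seed_targets$start
    mi <- sample.int(nrow(seed_targets), sum(seeded), replace = TRUE,
                     prob = wts)
    chrom[seeded] <- seed_targets$chrom[mi]
    pos[seeded] <- floor(stats::runif(sum(seeded), seed_targets$start[mi],
                                      seed_targets$end[mi]))
  }
  data.frame(chrom = chrom, pos = pos, seeded = seeded,
             stringsAsFactors = FALSE)
}

flip_label <- function(x) ifelse(x == "W", "C", "W")
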