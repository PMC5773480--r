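#' Circular-shift permutation test of SCE/feature overlap
#'
#' The core enrichment statistic: for each of `n_permutations` permutations
#' a single random shift `n` (uniform integer in `[shift_min, shift_max]`)
#' is applied to all SCE regions in gap-excluded (gapless) coordinates,
#' wrapping around each chromosome's effective length as if it were
#' circular; the number of SCE regions overlapping at least one feature by
#' at least one base is recorded. A region overlapping several features
#' counts once. The observed overlap is normalised to the median permuted
#' value (relative enrichment), and empirical p-values are the fraction of
#' permutations with overlap greater/less than or equal to the observed
#' count, floored at `1/n_permutations` (reported as e.g. "< 0.001" when no
#' permutation reaches the observed overlap).
#'
#' @param sces SCE table (`chrom`, `start`, `end`); regions must not
#'   intersect assembly gaps.
#' @param foi feature-of-interest table (`chrom`, `start`, `end`).
#' @param map a [build_gapless_map()].
#' @param n_permutations number of permutations (default 1000).
#' @param shift_min,shift_max shift range in bases (defaults 2 and 50 Mb);
#'   shifts exceeding a chromosome's effective length simply wrap.
#' @param seed integer seed recorded in the result.
#' @param per_chromosome draw an independent shift per chromosome in each
#'   permutation instead of one global shift (the default mirrors the
#'   single-random-number construction).
#' @param foi_name label stored in the result.
#' @return an object of class `permutation_result`.
#' @export
permute_overlap <- function(sces, foi, map, n_permutations = 1000L,
                            shift_min = 2e6, shift_max = 50e6, seed = 1L,
                            per_chromosome = FALSE, foi_name = "foi") {
  stopifnot(inherits(map, "gapless_map"))
  if (shift_min < 0 || shift_max < shift_min)
    stop("need 0 <= shift_min <= shift_max")
  gl <- sces_to_gapless(sces, map)
  fg <- prepare_foi_gapless(foi, map)
  chroms <- unique(gl$chrom)
  set.seed(seed)

  count_overlaps <- function(shift_by_chrom) {
    total <- 0L
    for (ch in chroms) {
      g <- gl[gl$chrom == ch, ]
      EL <- map$effective_length[[ch]]
      ns <- (g$gl_start + shift_by_chrom[[ch]]) %% EL
      ne <- ns + g$len
      wrap <- ne > EL
      fb <- numeric(nrow(g))
      if (any(!wrap))
        fb[!wrap] <- feat_bases(fg, ch, ns[!wrap], ne[!wrap])
      if (any(wrap))
        fb[wrap] <- feat_bases(fg, ch, ns[wrap], rep(EL, sum(wrap))) +
          feat_bases(fg, ch, rep(0, sum(wrap)), ne[wrap] - EL)
      total <- total + sum(fb > 0)
    }
    total
  }

  zero <- stats::setNames(rep(0, length(chroms)), chroms)
  observed <- count_overlaps(as.list(zero))
  span <- shift_max - shift_min + 1
  permuted <- integer(n_permutations)
  for (p in seq_len(n_permutations)) {
    if (per_chromosome) {
      n_shift <- as.list(stats::setNames(
        shift_min - 1 + ceiling(stats::runif(length(chroms)) * span), chroms))
    } else {
      one <- shift_min - 1 + ceiling(stats::runif(1) * span)
      n_shift <- as.list(stats::setNames(rep(one, length(chroms)), chroms))
    }
    permuted[p] <- count_overlaps(n_shift)
  }
  med <- stats::median(permuted)
  p_enrich <- sum(permuted >= observed) / n_permutations
  p_deplete <- sum(permuted <= observed) / n_permutations
  floor_p <- 1 / n_permutations
  res <- list(foi_name = foi_name, n_sces_used = nrow(sces),
              observed_overlap = observed, permuted_overlaps = permuted,
              median_permuted = med,
              relative_enrichment = if (med > 0) observed / med else NA_real_,
              p_enrich = max(p_enrich, floor_p),
              p_deplete = max(p_deplete, floor_p),
              p_enrich_label = if (p_enrich == 0)
                sprintf("< %.3g", floor_p) else sprintf("%.3g", p_enrich),
              p_deplete_label = if (p_deplete == 0)
                sprintf("< %.3g", floor_p) else sprintf("%.3g", p_deplete),
              n_permutations = n_permutations, shift_min = shift_min,
              shift_max = shift_max, per_chromosome = per_chromosome,
              seed = seed)
  class(res) <- "permutation_result"
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result [%s]: %d SCEs, observed overlap %d, median permuted %s\n",
    x$foi_name, x$n_sces_used, x$observed_overlap,
    format(x$median_permuted)))
  cat(sprintf("  relative enrichment %.3f; p(enrich) %s; p(deplete) %s (%d permutations)\n",
              x$relative_enrichment, x$p_enrich_label, x$p_deplete_label,
              x$n_permutations))
  invisible(x)
}

# map SCE regions to gapless coordinates; a region intersecting a gap
# cannot be mapped and is an error
sces_to_gapless <- function(sces, map) {
  n <- nrow(sces)
  gl_start <- numeric(n); ok <- logical(n)
  for (ch in unique(sces$chrom)) {
    i <- which(sces$chrom == ch)
    a <- genomic_to_gapless(map, ch, sces$start[i])
    b <- genomic_to_gapless(map, ch, sces$end[i] - 1)
    good <- !is.na(a) & !is.na(b) & (b - a == sces$end[i] - 1 - sces$start[i])
    gl_start[i] <- a
    ok[i] <- good
  }
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("SCE region %s:%d-%d overlaps an assembly gap",
                 sces$chrom[bad], sces$start[bad], sces$end[bad]))
  }
  data.frame(chrom = sces$chrom, gl_start = gl_start,
             len = sces$end - sces$start, stringsAsFactors = FALSE)
}

# features mapped to gapless coordinates (gap-intersecting parts dropped),
# reduced to disjoint sorted intervals, with cumulative feature bases for
# O(log m) interval queries
prepare_foi_gapless <- function(foi, map) {
  out <- list()
  for (ch in names(map$blocks)) {
    f <- foi[foi$chrom == ch, , drop = FALSE]
    if (!nrow(f)) { out[[ch]] <- NULL; next }
    b <- map$blocks[[ch]]
    fr <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
    br <- IRanges::IRanges(b$gstart + 1L, b$gend)
    parts <- IRanges::intersect(fr, br)
    if (!length(parts)) { out[[ch]] <- NULL; next }
    gs <- genomic_to_gapless(map, ch, IRanges::start(parts) - 1L)
    ge <- gs + IRanges::width(parts)
    r <- IRanges::reduce(IRanges::IRanges(gs + 1, ge))
    s <- IRanges::start(r) - 1; e <- IRanges::end(r)
    out[[ch]] <- list(s = s, e = e, w = e - s, cum0 = c(0, cumsum(e - s)))
  }
  out
}

# feature bases in gapless interval [a, b)
feat_bases <- function(fg, chrom, a, b) {
  f <- fg[[chrom]]
  if (is.null(f)) return(numeric(length(a)))
  cfun <- function(x) {
    k <- findInterval(x, f$s)
    kk <- pmax(k, 1L)
    v <- f$cum0[kk] + pmin(pmax(x - f$s[kk], 0), f$w[kk])
    v[k == 0L] <- 0
    v
  }
  cfun(b) - cfun(a)
}

#' Shift SCE regions circularly in gap-excluded coordinates
#'
#' Moves each region `n` bases downstream in gapless coordinates on its own
#' chromosome, wrapping modulo the effective length. Regions wrapping the
#' origin are split into two arcs. Per-region gapless lengths are preserved.
#'
#' @inheritParams permute_overlap
#' @param n shift in bases (>= 0).
#' @return data.frame of genomic pieces: `region_id`, `chrom`, `start`,
#'   `end`, `arc` (1 or 2; a piece may additionally be split at assembly
#'   gaps when mapped back to genomic coordinates).
#' @export
shift_regions <- function(sces, n, map) {
  if (n < 0) stop("shift must be >= 0")
  gl <- sces_to_gapless(sces, map)
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(gl))) {
    ch <- gl$chrom[i]
    EL <- map$effective_length[[ch]]
    ns <- (gl$gl_start[i] + n) %% EL
    ne <- ns + gl$len[i]
    arcs <- if (ne <= EL) list(c(ns, ne)) else
      list(c(ns, EL), c(0, ne - EL))
    for (a in seq_along(arcs)) {
      pieces <- gapless_interval_to_genomic(map, ch, arcs[[a]][1], arcs[[a]][2])
      k <- k + 1L
      rows[[k]] <- data.frame(region_id = i, chrom = ch,
                              start = pieces$start, end = pieces$end,
                              arc = a, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Apply an SCE region size cutoff
#'
#' Regions with resolution strictly greater than the cutoff are excluded
#' (boundary inclusive: resolution equal to the cutoff is kept). The
#' analyses use 10 kb for G4 motifs and 100 kb for genes/promoters.
#'
#' @param sces SCE table with a `resolution` column (or `end - start` used).
#' @param cutoff size cutoff in bases.
#' @return filtered SCE table.
#' @export
apply_size_cutoff <- function(sces, cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive")
  res <- if (!is.null(sces$resolution)) sces$resolution else
    sces$end - sces$start
  sces[res <= cutoff, , drop = FALSE]
}

#' Widen SCE regions by flanking sequence
#'
#' @param sces SCE table.
#' @param flank bases added on each side.
#' @param index a [genome_index()] used for clipping.
#' @return widened SCE table (resolution updated).
#' @export
add_flanks <- function(sces, flank, index) {
  if (flank < 0) stop("flank must be >= 0")
  sces$start <- pmax(sces$start - flank, 0)
  sces$end <- pmin(sces$end + flank, index$chrom_lengths[sces$chrom])
  if (!is.null(sces$resolution)) sces$resolution <- sces$end - sces$start
  sces
}

#' Subsample SCE regions
#'
#' Uniform sample without replacement, e.g. to match the event count of the
#' smallest library set when comparing lines.
#'
#' @param sces SCE table.
#' @param target_n sample size (<= nrow).
#' @param seed integer seed.
#' @return subsampled SCE table (original order preserved).
#' @export
subsample_sces <- function(sces, target_n, seed = 1L) {
  if (target_n > nrow(sces)) stop("target_n exceeds number of SCEs")
  set.seed(seed)
  keep <- sort(sample.int(nrow(sces), target_n))
  sces[keep, , drop = FALSE]
}

#' SCE load across gene-expression quartiles
#'
#' Splits active genes into four expression quartiles and regresses the
#' number of SCE regions overlapping each quartile's genes on quartile rank.
#'
#' @param sces SCE table.
#' @param genes gene table with `activity`.
#' @param expression expression table (`gene_id`, `fpkm`).
#' @return list with `counts` (per quartile) and `r_squared`.
#' @export
expression_quartile_correlation <- function(sces, genes, expression) {
  act <- genes[genes$activity == "active", , drop = FALSE]
  if (nrow(act) < 4L) stop("need at least 4 active genes")
  fpkm <- expression$fpkm[match(act$gene_id, expression$gene_id)]
  qs <- stats::quantile(fpkm, c(0.25, 0.5, 0.75))
  quart <- findInterval(fpkm, qs) + 1L   # 1..4
  gb <- gene_bodies(act)
  counts <- integer(4L)
  for (q in 1:4) {
    g <- gb[quart == q, , drop = FALSE]
    hit <- logical(nrow(sces))
    for (ch in unique(g$chrom)) {
      gi <- which(g$chrom == ch); si <- which(sces$chrom == ch)
      if (!length(si)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(sces$start[si] + 1L, sces$end[si]),
        IRanges::IRanges(g$start[gi] + 1L, g$end[gi]))
      hit[si[unique(S4Vectors::queryHits(ov))]] <- TRUE
    }
    counts[q] <- sum(hit)
  }
  r2 <- if (stats::var(counts) == 0) 0 else
    summary(stats::lm(counts ~ seq_len(4L)))$r.squared
  list(counts = counts, r_squared = r2)
}
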