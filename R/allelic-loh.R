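#' Find allele-specific G4 motifs between two haplotype sequences
#'
#' Scans both haplotype sequences (aligned base-for-base; SNP-only model)
#' and reports motifs present on exactly one haplotype. Presence on the
#' other haplotype is judged by same-strand overlap, so a motif whose match
#' merely shifts or changes length across haplotypes is not called
#' allele-specific.
#'
#' @param seq_a,seq_b haplotype sequences (single chromosome or named sets,
#'   same names and lengths).
#' @param loop_min,loop_max loop-size family (defaults 1-7).
#' @return data.frame of motifs with a `haplotype` column (`"A"` or `"B"`,
#'   the homolog carrying the intact motif).
#' @export
find_allelic_g4 <- function(seq_a, seq_b, loop_min = 1L, loop_max = 7L) {
  ma <- scan_g4(seq_a, loop_min, loop_max)
  mb <- scan_g4(seq_b, loop_min, loop_max)
  only_a <- drop_overlapping(ma, mb)
  only_b <- drop_overlapping(mb, ma)
  if (nrow(only_a)) only_a$haplotype <- "A"
  else only_a$haplotype <- character(0)
  if (nrow(only_b)) only_b$haplotype <- "B"
  else only_b$haplotype <- character(0)
  res <- rbind(only_a, only_b)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# rows of x with no same-strand same-chromosome overlap in y
drop_overlapping <- function(x, y) {
  if (!nrow(x) || !nrow(y)) return(x)
  keep <- rep(TRUE, nrow(x))
  for (ch in unique(x$chrom)) {
    for (st in c("+", "-")) {
      xi <- which(x$chrom == ch & x$strand == st)
      yi <- which(y$chrom == ch & y$strand == st)
      if (!length(xi) || !length(yi)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(x$start[xi] + 1L, x$end[xi]),
        IRanges::IRanges(y$start[yi] + 1L, y$end[yi]))
      keep[xi[unique(S4Vectors::queryHits(ov))]] <- FALSE
    }
  }
  x[keep, , drop = FALSE]
}

#' Homolog concordance of SCEs with allele-specific G4 motifs
#'
#' Informative SCEs are those overlapping exactly one allele-specific G4
#' motif and carrying a homolog assignment. An informative SCE is concordant
#' when it occurred on the homolog carrying the intact motif. Under the null
#' of no relationship each informative SCE is concordant with probability
#' 1/2; the p-value is the binomial tail (one-sided by default: probability
#' of at least the observed number of concordant events).
#'
#' @param sces SCE table with `homolog` filled (see [assign_homolog()]).
#' @param allelic_g4 table from [find_allelic_g4()] (or the generator truth).
#' @param alternative `"one.sided"` (default) or `"two.sided"`.
#' @return list of class `concordance_result`: `n_informative`,
#'   `n_concordant`, `fraction_concordant`, `p_value`, `alternative`,
#'   `by_haplotype` breakdown. With zero informative SCEs the p-value is
#'   `NA` and `flagged` is TRUE.
#' @export
concordance_test <- function(sces, allelic_g4,
                             alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  assigned <- sces[sces$homolog %in% c("A", "B"), , drop = FALSE]
  n_hit <- integer(nrow(assigned))
  hit_hap <- character(nrow(assigned))
  for (ch in unique(assigned$chrom)) {
    si <- which(assigned$chrom == ch)
    ai <- which(allelic_g4$chrom == ch)
    if (!length(si) || !length(ai)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(assigned$start[si] + 1L, assigned$end[si]),
      IRanges::IRanges(allelic_g4$start[ai] + 1L, allelic_g4$end[ai]))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    cnt <- tabulate(qh, nbins = length(si))
    n_hit[si] <- cnt
    one <- which(cnt == 1L)
    hit_hap[si[one]] <- allelic_g4$haplotype[ai[sh[match(one, qh)]]]
  }
  informative <- n_hit == 1L
  n_inf <- sum(informative)
  n_conc <- sum(informative & assigned$homolog == hit_hap)
  res <- list(n_informative = n_inf, n_concordant = n_conc,
              fraction_concordant = if (n_inf) n_conc / n_inf else NA_real_,
              p_value = concordance_pvalue(n_conc, n_inf, alternative),
              alternative = alternative,
              by_haplotype = table(hap = hit_hap[informative],
                                   concordant = (assigned$homolog ==
                                                   hit_hap)[informative]),
              flagged = n_inf == 0L)
  class(res) <- "concordance_result"
  res
}

concordance_pvalue <- function(k, n, alternative = "one.sided") {
  if (n == 0L) return(NA_real_)
  p1 <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  if (alternative == "one.sided") return(p1)
  # two-sided: double the smaller tail, capped at 1
  p2 <- stats::pbinom(k, n, 0.5)
  min(1, 2 * min(p1, p2))
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance_result: %d/%d informative SCEs concordant (%.1f%%), %s p = %s\n",
              x$n_concordant, x$n_informative,
              100 * x$fraction_concordant, x$alternative,
              format(x$p_value, digits = 3)))
  invisible(x)
}

#' Bin haplotype-tagged reads
#'
#' @param reads read table of one cell with `haplotype` tags.
#' @param index a [genome_index()].
#' @param bin_width bin width in bases (default 1 Mb).
#' @return data.frame per bin: `chrom`, `start`, `end`, `count_a`,
#'   `count_b`, `total_reads` (tagged + untagged).
#' @export
bin_haplotype_reads <- function(reads, index, bin_width = 1e6) {
  reads <- data.table::as.data.table(reads)
  out <- list(); k <- 0L
  for (ch in names(index$chrom_lengths)) {
    L <- index$chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = bin_width)
    r <- reads[reads$chrom == ch]
    bin <- findInterval(r$start, starts)
    k <- k + 1L
    out[[k]] <- data.frame(
      chrom = ch, start = starts, end = pmin(starts + bin_width, L),
      count_a = tabulate(bin[r$haplotype == "A"], length(starts)),
      count_b = tabulate(bin[r$haplotype == "B"], length(starts)),
      total_reads = tabulate(bin, length(starts)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Call copy-neutral loss of heterozygosity from binned haplotype counts
#'
#' LOH appears as a switch from mixed haplotype background to a pure single
#' haplotype without a copy-number change. Maximal runs of at least
#' `min_bins` consecutive bins in which one haplotype holds at least
#' `purity` of the informative reads, and which are diploid, are reported.
#' Bins without informative reads are skipped; copy-abnormal bins (from
#' `copy_state`, e.g. [naive_ploidy()]) break runs so that deletions are
#' not called as LOH.
#'
#' @param bins data.frame from [bin_haplotype_reads()].
#' @param min_bins minimal run length in bins (default 3).
#' @param purity minimal fraction of informative reads from one haplotype
#'   (default 0.95).
#' @param copy_state optional character vector per bin (`"diploid"` or
#'   other); `NULL` assumes diploid everywhere.
#' @return data.frame of LOH segments: `chrom`, `start`, `end`,
#'   `haplotype_retained`, `n_bins`, `copy_state`.
#' @export
call_loh <- function(bins, min_bins = 3L, purity = 0.95, copy_state = NULL) {
  if (is.null(copy_state)) copy_state <- rep("diploid", nrow(bins))
  inf <- bins$count_a + bins$count_b
  lab <- rep("mixed", nrow(bins))
  lab[inf == 0] <- "skip"
  lab[inf > 0 & bins$count_a / pmax(inf, 1) >= purity] <- "A"
  lab[inf > 0 & bins$count_b / pmax(inf, 1) >= purity] <- "B"
  lab[copy_state != "diploid"] <- "abnormal"
  out <- list(); k <- 0L
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    use <- idx[lab[idx] != "skip"]    # uninformative bins do not break runs
    if (!length(use)) next
    rl <- rle(lab[use])
    ends <- cumsum(rl$lengths); starts <- c(1L, ends[-length(ends)] + 1L)
    for (j in seq_along(rl$values)) {
      if (!rl$values[j] %in% c("A", "B") || rl$lengths[j] < min_bins) next
      b0 <- use[starts[j]]; b1 <- use[ends[j]]
      k <- k + 1L
      out[[k]] <- data.frame(chrom = ch, start = bins$start[b0],
                             end = bins$end[b1],
                             haplotype_retained = rl$values[j],
                             n_bins = rl$lengths[j],
                             copy_state = "diploid",
                             stringsAsFactors = FALSE)
    }
  }
  if (!k)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), haplotype_retained = character(),
                      n_bins = integer(), copy_state = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Naive per-chromosome ploidy estimate
#'
#' Copy state from total read density per chromosome relative to the
#' per-cell diploid baseline (the median chromosome density): ratio at or
#' above 1.25 is trisomy, at or below 0.75 monosomy, otherwise diploid.
#' A deliberately simple stand-in sufficient to exclude copy-abnormal
#' regions from LOH calling. The median baseline presumes most
#' chromosomes are diploid; with very few chromosomes (or aneuploidy of
#' half of them) the baseline itself shifts and calls are unreliable.
#'
#' @param reads read table with `cell_id`.
#' @param index a [genome_index()].
#' @return data.frame per (cell, chromosome): `cell_id`, `chrom`,
#'   `density_ratio`, `copy_state`.
#' @export
naive_ploidy <- function(reads, index) {
  reads <- data.table::as.data.table(reads)
  eff <- vapply(names(index$chrom_lengths), function(ch)
    index$chrom_lengths[[ch]] - gap_bases(index, ch), numeric(1))
  counts <- reads[, .N, by = .(cell_id, chrom)]
  counts$density <- counts$N / eff[counts$chrom]
  counts[, baseline := stats::median(density), by = cell_id]
  counts$density_ratio <- counts$density / counts$baseline
  counts$copy_state <- ifelse(counts$density_ratio >= 1.25, "trisomy",
                              ifelse(counts$density_ratio <= 0.75,
                                     "monosomy", "diploid"))
  as.data.frame(counts[, .(cell_id, chrom, density_ratio, copy_state)])
}
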