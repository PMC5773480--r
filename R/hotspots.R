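#' Detect candidate SCE hotspots
#'
#' A candidate hotspot is a maximal interval covered by SCE regions from at
#' least `min_cells` distinct cells simultaneously; the reported interval is
#' the intersection of the contributing regions (the region of maximal
#' distinct-cell coverage).
#'
#' @param sces SCE table across all cells of a line.
#' @param min_cells minimal number of distinct cells (default 3).
#' @return data.frame `chrom`, `start`, `end`, `n_libraries_with_sce`,
#'   `total_sces`.
#' @export
detect_hotspots <- function(sces, min_cells = 3L) {
  out <- list(); k <- 0L
  for (ch in unique(sces$chrom)) {
    s <- sces[sces$chrom == ch, , drop = FALSE]
    # one interval per cell and locus: reduce each cell's regions first
    percell <- lapply(split(s, s$cell_id), function(x)
      IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end)))
    ir <- do.call(c, unname(percell))
    cov <- IRanges::coverage(ir)
    runs <- IRanges::slice(cov, lower = min_cells, rangesOnly = TRUE)
    if (!length(runs)) next
    all_ir <- IRanges::IRanges(s$start + 1L, s$end)
    for (j in seq_along(runs)) {
      hit <- IRanges::findOverlaps(runs[j], all_ir)
      sh <- S4Vectors::subjectHits(hit)
      k <- k + 1L
      out[[k]] <- data.frame(
        chrom = ch, start = IRanges::start(runs[j]) - 1L,
        end = IRanges::end(runs[j]),
        n_libraries_with_sce = length(unique(s$cell_id[sh])),
        total_sces = length(sh), stringsAsFactors = FALSE)
    }
  }
  if (!k)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_libraries_with_sce = integer(),
                      total_sces = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Bin probability for an SCE hotspot
#'
#' The genome is divided into bins of the hotspot's size and the chance of
#' finding the observed number of SCEs in one bin is computed from the total
#' SCE count of the line: the upper-tail probability
#' `P(X >= observed)` with `X ~ Binomial(total_sces,
#' hotspot_length / genome_effective_length)`. A Poisson tail is available
#' as an approximation.
#'
#' @param hotspot_length hotspot size in bases.
#' @param genome_effective_length gap-excluded genome size in bases.
#' @param total_sces total SCEs detected in the cell line.
#' @param observed_in_hotspot SCEs inside the hotspot.
#' @param method `"binomial"` (exact, default) or `"poisson"`.
#' @return p-value in (0, 1].
#' @export
hotspot_pvalue <- function(hotspot_length, genome_effective_length,
                           total_sces, observed_in_hotspot,
                           method = c("binomial", "poisson")) {
  method <- match.arg(method)
  if (total_sces <= 0 || genome_effective_length <= 0)
    stop("total_sces and genome_effective_length must be positive")
  if (hotspot_length > genome_effective_length)
    stop("hotspot longer than the effective genome")
  if (observed_in_hotspot > total_sces)
    stop("observed count exceeds total")
  if (observed_in_hotspot == 0) return(1)
  pr <- hotspot_length / genome_effective_length
  if (method == "binomial")
    stats::pbinom(observed_in_hotspot - 1, total_sces, pr,
                  lower.tail = FALSE)
  else
    stats::ppois(observed_in_hotspot - 1, total_sces * pr,
                 lower.tail = FALSE)
}

#' Score detected hotspots
#'
#' Convenience wrapper attaching [hotspot_pvalue()] to each candidate from
#' [detect_hotspots()], with optional Bonferroni correction over the number
#' of hotspot-sized bins.
#'
#' @param hotspots output of [detect_hotspots()].
#' @param map a [build_gapless_map()].
#' @param total_sces total SCEs in the line.
#' @param n_libraries_total number of libraries in the line.
#' @param bonferroni correct each p over `effective genome / hotspot length`
#'   bins (default FALSE; raw p-values are reported by default).
#' @return `hotspots` with `n_libraries_total`, `p_value` (and
#'   `p_adjusted` if requested).
#' @export
score_hotspots <- function(hotspots, map, total_sces, n_libraries_total,
                           bonferroni = FALSE) {
  EL <- sum(map$effective_length)
  hotspots$n_libraries_total <- n_libraries_total
  hotspots$p_value <- vapply(seq_len(nrow(hotspots)), function(i)
    hotspot_pvalue(hotspots$end[i] - hotspots$start[i], EL, total_sces,
                   hotspots$total_sces[i]), numeric(1))
  if (bonferroni) {
    n_bins <- EL / (hotspots$end - hotspots$start)
    hotspots$p_adjusted <- pmin(hotspots$p_value * n_bins, 1)
  }
  hotspots
}
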