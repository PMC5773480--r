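#' Infer template-strand states for one cell
#'
#' Segments each chromosome of a single Strand-seq library into
#' template-strand states WW, WC or CC. Reads are sorted by position and the
#' state path maximising the per-read binomial label likelihood (expected
#' Watson fraction 1-eps / 0.5 / eps) under a fixed penalty per state change
#' is found by dynamic programming. Segments supported by fewer than
#' `min_reads` reads are merged into their better-supported neighbour.
#'
#' @param reads read table for one cell (`chrom`, `start`, `end`, `label`,
#'   optionally `cell_id`).
#' @param index a [genome_index()].
#' @param min_reads minimal reads per segment and per callable chromosome
#'   (default 10); chromosomes with fewer reads are reported uncallable.
#' @param eps assumed strand-label error rate (default 0.02).
#' @param penalty log-likelihood cost per state change (default 7). The
#'   penalty is the log prior odds against a switch at any given inter-read
#'   position: a few SCEs among a few thousand read positions per
#'   chromosome gives odds ~1/1000, i.e. a penalty of ~7. A BIC-style
#'   `2 log(n)` is twice as conservative and was found to miss state
#'   islands shorter than ~50 reads, whose per-read evidence against the
#'   flanking WC state is only `log((1-eps)/0.5)`.
#' @return data.frame of segments: `cell_id`, `chrom`, `start`, `end`,
#'   `state`, `n_reads`, `first_read_start`, `last_read_end`. Segments
#'   partition each callable chromosome; internal boundaries sit at the end
#'   of the left segment's last read.
#' @export
infer_strand_states <- function(reads, index, min_reads = 10L, eps = 0.02,
                                penalty = 7) {
  reads <- data.table::as.data.table(reads)
  if (is.null(reads$cell_id)) reads$cell_id <- "cell"
  if (length(unique(reads$cell_id)) > 1L)
    stop("infer_strand_states expects reads from a single cell; ",
         "use infer_strand_states_all()")
  cell <- reads$cell_id[1L]
  out <- list()
  for (ch in names(index$chrom_lengths)) {
    r <- reads[reads$chrom == ch]
    data.table::setorder(r, start)
    n <- nrow(r)
    if (n < min_reads) next   # uncallable chromosome
    isW <- r$label == "W"
    logem <- cbind(ifelse(isW, log(1 - eps), log(eps)),   # WW
                   rep(log(0.5), n),                      # WC
                   ifelse(isW, log(eps), log(1 - eps)))   # CC
    path <- viterbi_states(logem, penalty)
    path <- enforce_min_reads(path, min_reads)
    segs <- path_to_segments(path, r, ch, cell,
                             index$chrom_lengths[[ch]])
    out[[ch]] <- segs
  }
  if (!length(out))
    return(data.frame(cell_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), state = character(),
                      n_reads = integer(), first_read_start = numeric(),
                      last_read_end = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

STATES <- c("WW", "WC", "CC")

# merge segments supported by fewer than min_reads reads into the
# neighbouring segment with more reads (ties: left)
enforce_min_reads <- function(path, min_reads) {
  repeat {
    rl <- rle(path)
    if (length(rl$lengths) <= 1L) break
    small <- which(rl$lengths < min_reads)
    if (!length(small)) break
    i <- small[which.min(rl$lengths[small])]
    left_n <- if (i > 1L) rl$lengths[i - 1L] else -1L
    right_n <- if (i < length(rl$lengths)) rl$lengths[i + 1L] else -1L
    take <- if (left_n >= right_n) rl$values[i - 1L] else rl$values[i + 1L]
    rl$values[i] <- take
    path <- inverse.rle(rl)
  }
  path
}

path_to_segments <- function(path, r, chrom, cell, chrom_len) {
  rl <- rle(path)
  k <- length(rl$lengths)
  idx_end <- cumsum(rl$lengths)
  idx_start <- c(1L, idx_end[-k] + 1L)
  first_start <- r$start[idx_start]
  last_end <- r$end[idx_end]
  seg_start <- c(0, last_end[-k])
  seg_end <- c(last_end[-k], chrom_len)
  data.frame(cell_id = cell, chrom = chrom, start = seg_start, end = seg_end,
             state = STATES[rl$values], n_reads = rl$lengths,
             first_read_start = first_start, last_read_end = last_end,
             stringsAsFactors = FALSE)
}

#' Infer strand states for every cell in a read table
#'
#' @inheritParams infer_strand_states
#' @param reads read table with a `cell_id` column.
#' @return row-bound segment table across cells.
#' @export
infer_strand_states_all <- function(reads, index, min_reads = 10L,
                                    eps = 0.02, penalty = 7) {
  reads <- data.table::as.data.table(reads)
  segs <- lapply(split(reads, by = "cell_id"), infer_strand_states,
                 index = index, min_reads = min_reads, eps = eps,
                 penalty = penalty)
  res <- do.call(rbind, segs)
  rownames(res) <- NULL
  res
}

#' Call SCEs from adjacent strand-state segments
#'
#' One SCE region per adjacent segment pair within a cell/chromosome:
#' `[end of the left segment's last read, start of the right segment's
#' first read)`. Adjacent segments two steps apart (WW to CC) are emitted as
#' two stacked SCEs with a warning. Abutting or overlapping boundary reads
#' yield resolution 1.
#'
#' @param segments segment table from [infer_strand_states()] /
#'   [infer_strand_states_all()].
#' @return data.frame of SCE regions: `cell_id`, `chrom`, `start`, `end`,
#'   `resolution`, `left_state`, `right_state`, `homolog` (`"none"` until
#'   [assign_homolog()] is run).
#' @export
call_sces <- function(segments) {
  out <- list(); ko <- 0L
  segments <- segments[order(segments$cell_id, segments$chrom,
                             segments$start), , drop = FALSE]
  groups <- split(segments,
                  list(segments$cell_id, segments$chrom), drop = TRUE)
  n_double <- 0L
  for (g in groups) {
    k <- nrow(g)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) {
      a <- g[i, ]; b <- g[i + 1L, ]
      s <- a$last_read_end; e <- b$first_read_start
      if (e <= s) s <- e - 1
      step <- abs(match(a$state, STATES) - match(b$state, STATES))
      reps <- if (step == 2L) 2L else 1L
      if (step == 2L) n_double <- n_double + 1L
      for (j in seq_len(reps)) {
        ko <- ko + 1L
        out[[ko]] <- data.frame(cell_id = a$cell_id, chrom = a$chrom,
                                start = s, end = e, resolution = e - s,
                                left_state = a$state, right_state = b$state,
                                homolog = "none", stringsAsFactors = FALSE)
      }
    }
  }
  if (n_double)
    warning(n_double, " WW<->CC double switch(es) emitted as stacked SCEs")
  if (!ko)
    return(data.frame(cell_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      resolution = numeric(), left_state = character(),
                      right_state = character(), homolog = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove recurrent SCE regions (putative stable rearrangements)
#'
#' SCE regions recurring at the same location in more than `max_fraction`
#' of cells are stable chromosomal rearrangements, not SCEs. "Same location"
#' is operationalised as clusters under >= `reciprocal_overlap` mutual
#' overlap (single linkage).
#'
#' @param sces SCE table from [call_sces()].
#' @param cell_count number of cells in the line (denominator of the
#'   recurrence fraction).
#' @param max_fraction recurrence threshold; clusters seen in strictly more
#'   than this fraction of cells are removed (default 0.05).
#' @param reciprocal_overlap minimal mutual overlap fraction for clustering
#'   (default 0.25). Region boundaries are read-sampled, so two calls of
#'   the same breakpoint have roughly independent exponential sizes and
#'   differ by more than two-fold about two thirds of the time; demanding
#'   50% mutual overlap therefore fragments true recurrence clusters,
#'   while 25% removes the bulk of a planted stable rearrangement without
#'   touching unique events.
#' @return list with `kept` and `removed` SCE tables.
#' @export
filter_recurrent <- function(sces, cell_count, max_fraction = 0.05,
                             reciprocal_overlap = 0.25) {
  if (cell_count <= 0) stop("cell_count must be positive")
  n <- nrow(sces)
  if (!n) return(list(kept = sces, removed = sces))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ch in unique(sces$chrom)) {
    idx <- which(sces$chrom == ch)
    ir <- IRanges::IRanges(sces$start[idx] + 1L, sces$end[idx])
    ov <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    wi <- IRanges::width(IRanges::pintersect(ir[qh], ir[sh]))
    rec <- wi >= reciprocal_overlap * IRanges::width(ir[qh]) &
      wi >= reciprocal_overlap * IRanges::width(ir[sh])
    for (p in which(rec)) {
      a <- find(idx[qh[p]]); b <- find(idx[sh[p]])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  n_cells_in_cluster <- vapply(split(sces$cell_id, root),
                               function(x) length(unique(x)), integer(1))
  bad_roots <- as.integer(names(n_cells_in_cluster)[
    n_cells_in_cluster > max_fraction * cell_count])
  removed <- root %in% bad_roots
  list(kept = sces[!removed, , drop = FALSE],
       removed = sces[removed, , drop = FALSE])
}

#' Assign an SCE to a homolog using haplotype-tagged reads
#'
#' Re-runs single-homolog state inference (template W vs C) separately on
#' haplotype-A and haplotype-B reads in a window around each SCE region.
#' If exactly one haplotype's reads switch template state, that homolog is
#' assigned; if neither or both switch, or tagged reads are too sparse, the
#' SCE stays uninformative (`"none"`).
#'
#' @param sces SCE table from [call_sces()].
#' @param reads read table with `haplotype` in `A`/`B`/`.`.
#' @param window bases added on each side of the SCE region (default 2 Mb).
#' @param min_reads minimal tagged reads per haplotype in the window.
#' @param eps assumed label error rate.
#' @return `sces` with the `homolog` column filled.
#' @export
assign_homolog <- function(sces, reads, window = 2e6, min_reads = 5L,
                           eps = 0.02) {
  reads <- data.table::as.data.table(reads)
  tagged <- reads[reads$haplotype %in% c("A", "B")]
  for (i in seq_len(nrow(sces))) {
    r <- tagged[tagged$cell_id == sces$cell_id[i] &
                  tagged$chrom == sces$chrom[i] &
                  tagged$start >= sces$start[i] - window &
                  tagged$start < sces$end[i] + window]
    switched <- c(A = FALSE, B = FALSE)
    informative <- c(A = FALSE, B = FALSE)
    for (h in c("A", "B")) {
      rh <- r[r$haplotype == h]
      data.table::setorder(rh, start)
      if (nrow(rh) < min_reads) next
      informative[h] <- TRUE
      isW <- rh$label == "W"
      logem <- cbind(ifelse(isW, log(1 - eps), log(eps)),   # template W
                     ifelse(isW, log(eps), log(1 - eps)))   # template C
      path <- viterbi_states(logem, 2 * log(nrow(rh)))
      switched[h] <- length(rle(path)$lengths) > 1L
    }
    sces$homolog[i] <- if (sum(switched) == 1L && all(informative))
      names(switched)[switched] else "none"
  }
  sces
}

#' Summarise SCE mapping resolution
#'
#' @param sces SCE table.
#' @return list with `median_resolution`, `fraction_below_100kb` and a
#'   `per_cell_counts` data.frame.
#' @export
resolution_summary <- function(sces) {
  if (!nrow(sces)) stop("no SCEs to summarise")
  counts <- as.data.frame(table(cell_id = sces$cell_id),
                          stringsAsFactors = FALSE)
  names(counts)[2L] <- "n_sces"
  list(median_resolution = stats::median(sces$resolution),
       fraction_below_100kb = mean(sces$resolution < 1e5),
       per_cell_counts = counts)
}

#' Correlation of SCE load with chromosome size
#'
#' Ordinary least-squares R-squared of mean SCEs per chromosome per cell
#' against chromosome length.
#'
#' @param sces SCE table.
#' @param index a [genome_index()].
#' @param n_cells number of cells (cells without SCEs count in the mean).
#' @return R-squared (numeric scalar).
#' @export
chromosome_size_correlation <- function(sces, index, n_cells) {
  lens <- index$chrom_lengths
  if (length(lens) < 3L) stop("need at least 3 chromosomes")
  if (stats::var(as.numeric(lens)) == 0) {
    warning("all chromosomes have the same length; R-squared undefined")
    return(NA_real_)
  }
  counts <- table(factor(sces$chrom, levels = names(lens)))
  mean_per_cell <- as.numeric(counts) / n_cells
  if (stats::var(mean_per_cell) == 0) return(0)
  fit <- stats::lm(mean_per_cell ~ as.numeric(lens))
  summary(fit)$r.squared
}

#' Match called SCEs to planted truth
#'
#' A call matches a planted SCE when the true breakpoint lies within the
#' called region extended by `margin` on both sides, in the same cell and
#' chromosome. The margin accounts for the caller's locational uncertainty:
#' maximum-likelihood changepoints absorb post-breakpoint reads that carry
#' the pre-switch label (probability 1/2 per read under the mixed state), so
#' the call can sit a geometric(1/2) number of inter-read gaps away from the
#' breakpoint (displacement tail `P(S > d) = exp(-d / (2 mean_gap)) / 2`);
#' the default margin is the 99.5% quantile of that displacement,
#' `2 ln(100) ~ 9.2` mean inter-read gaps.
#'
#' @param sces called SCE table.
#' @param truth truth table with `cell_id`, `chrom`, `pos`.
#' @param mean_gap mean inter-read distance in bases
#'   (`read_length / coverage_fraction`).
#' @param margin matching margin in bases; default `2 * log(100) * mean_gap`.
#' @return list with `recall`, `precision`, `n_true`, `n_called`.
#' @export
match_sces_to_truth <- function(sces, truth, mean_gap = 100 / 0.015,
                                margin = NULL) {
  if (is.null(margin)) margin <- 2 * log(100) * mean_gap
  truth_hit <- logical(nrow(truth))
  call_hit <- logical(nrow(sces))
  key_t <- paste(truth$cell_id, truth$chrom)
  key_c <- paste(sces$cell_id, sces$chrom)
  for (k in unique(key_c)) {
    ti <- which(key_t == k); ci <- which(key_c == k)
    if (!length(ti)) next
    for (j in ci) {
      hit <- truth$pos[ti] >= sces$start[j] - margin &
        truth$pos[ti] < sces$end[j] + margin
      if (any(hit)) {
        call_hit[j] <- TRUE
        truth_hit[ti[hit]] <- TRUE
      }
    }
  }
  list(recall = mean(truth_hit), precision = mean(call_hit),
       n_true = nrow(truth), n_called = nrow(sces))
}
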