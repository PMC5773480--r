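#' Scan a sequence for canonical G-quadruplex motifs
#'
#' Finds matches of the canonical quadruplex pattern
#' G3+ N(loop_min..loop_max) G3+ N(..) G3+ N(..) G3+ on one or both strands.
#' Matching convention: leftmost match first, G-runs taken greedily
#' (maximal runs), matches non-overlapping per strand (scanning resumes at
#' the end of each match). Loops may contain any of A/C/G/T; a candidate
#' containing N anywhere is rejected. Minus-strand motifs are found by
#' scanning the reverse complement and mapping coordinates back.
#'
#' @param sequence a character scalar, `DNAString`, or named list/
#'   `DNAStringSet` of per-chromosome sequences.
#' @param loop_min,loop_max allowed loop lengths in bases (defaults 1 and 7;
#'   the loop-size families used genome-wide are 1-3, 1-7 and 1-12).
#' @param strand_mode `"both"`, `"plus"` or `"minus"`.
#' @param chrom chromosome name used when `sequence` is a single sequence.
#' @param run_char base forming the runs (`"G"` for quadruplex motifs;
#'   [scan_a_rich()] uses `"A"`).
#' @param min_run minimal run length (3 for the canonical pattern).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), `strand`, `width`, `loop_min`, `loop_max`, sorted by
#'   chromosome and start.
#' @export
scan_g4 <- function(sequence, loop_min = 1L, loop_max = 7L,
                    strand_mode = c("both", "plus", "minus"),
                    chrom = "chr1", run_char = "G", min_run = 3L) {
  strand_mode <- match.arg(strand_mode)
  if (loop_min < 1L || loop_min > loop_max)
    stop("need 1 <= loop_min <= loop_max")
  seqs <- as_named_character_seqs(sequence, chrom)
  out <- vector("list", 2L * length(seqs))
  k <- 0L
  for (ch in names(seqs)) {
    s <- toupper(seqs[[ch]])
    check_alphabet(s, ch)
    L <- nchar(s)
    if (strand_mode %in% c("both", "plus")) {
      m <- scan_run_chain(s, run_char, min_run, loop_min, loop_max)
      if (nrow(m)) {
        k <- k + 1L
        out[[k]] <- data.frame(chrom = ch, start = m$start, end = m$end,
                               strand = "+", stringsAsFactors = FALSE)
      }
    }
    if (strand_mode %in% c("both", "minus")) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      m <- scan_run_chain(rc, run_char, min_run, loop_min, loop_max)
      if (nrow(m)) {
        k <- k + 1L
        out[[k]] <- data.frame(chrom = ch, start = L - m$end, end = L - m$start,
                               strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res$width <- res$end - res$start
  res$loop_min <- rep(loop_min, nrow(res))
  res$loop_max <- rep(loop_max, nrow(res))
  res
}

#' Scan for A-rich control motifs
#'
#' Same pattern and conventions as [scan_g4()] with A-runs in place of
#' G-runs (T-runs on the minus strand); used as a base-composition control
#' feature set.
#'
#' @inheritParams scan_g4
#' @export
scan_a_rich <- function(sequence, loop_min = 1L, loop_max = 7L,
                        strand_mode = "both", chrom = "chr1") {
  scan_g4(sequence, loop_min, loop_max, strand_mode, chrom,
          run_char = "A", min_run = 3L)
}

# Backtracking scanner over the maximal-run table. Implements the match
# convention exactly: leftmost start, greedy runs (longest first, so a long
# run of >= 2*min_run + 1 bases may split into two quartet runs joined by
# an all-G loop), lazy loops (shortest first), loops over any of A/C/G/T,
# candidates containing N rejected, matches non-overlapping per strand
# (scanning resumes at the end of each match).
scan_run_chain <- function(s, run_char, min_run, loop_min, loop_max) {
  pat <- sprintf("%s{%d,}", run_char, min_run)
  m <- gregexpr(pat, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), end = integer()))
  rs <- as.integer(m) - 1L                       # run starts, 0-based
  re <- rs + attr(m, "match.length")             # run ends, half-open
  out <- scan_chain_cpp(s, rs, re, as.integer(min_run),
                        as.integer(loop_min), as.integer(loop_max))
  data.frame(start = out$start, end = out$end)
}

check_alphabet <- function(s, chrom) {
  bad <- regexpr("[^ACGTN]", s, perl = TRUE)
  if (bad != -1L)
    stop(sprintf("non-ACGTN character '%s' at position %d on %s",
                 substr(s, bad, bad), as.integer(bad) - 1L, chrom))
  invisible(TRUE)
}

as_named_character_seqs <- function(sequence, chrom) {
  if (methods::is(sequence, "DNAStringSet")) {
    out <- as.character(sequence)
    if (is.null(names(out))) names(out) <- paste0("chr", seq_along(out))
    return(as.list(out))
  }
  if (methods::is(sequence, "DNAString"))
    return(stats::setNames(list(as.character(sequence)), chrom))
  if (is.character(sequence) && length(sequence) == 1L && is.null(names(sequence)))
    return(stats::setNames(list(sequence), chrom))
  if (is.character(sequence))
    return(as.list(sequence))
  if (is.list(sequence)) {
    if (is.null(names(sequence))) stop("list of sequences must be named")
    return(lapply(sequence, as.character))
  }
  stop("unsupported sequence input")
}

#' Rank tiling windows by GC content
#'
#' Tiles each chromosome with non-overlapping fixed-width windows, ranks them
#' by GC fraction and returns the top fraction. This is the "high-GC" control
#' feature construction; it is parameterised because no standard construction
#' exists.
#'
#' @inheritParams scan_g4
#' @param window window width in bases (>= 100). A window wider than the
#'   chromosome yields a single window covering it.
#' @param top_fraction fraction of windows to keep (by GC rank).
#' @return data.frame `chrom`, `start`, `end`, `gc`, sorted by position.
#' @export
gc_windows <- function(sequence, window = 1000L, top_fraction = 0.1,
                       chrom = "chr1") {
  if (window < 100L) stop("window must be >= 100 bases")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  seqs <- as_named_character_seqs(sequence, chrom)
  rows <- lapply(names(seqs), function(ch) {
    s <- toupper(seqs[[ch]])
    check_alphabet(s, ch)
    L <- nchar(s)
    w <- min(window, L)
    starts <- seq.int(0L, L - w, by = w)
    v <- Biostrings::Views(Biostrings::DNAString(s), start = starts + 1L,
                           width = w)
    counts <- Biostrings::letterFrequency(v, letters = c("G", "C", "N"))
    denom <- w - counts[, "N"]
    gc <- ifelse(denom > 0, (counts[, "G"] + counts[, "C"]) / denom, 0)
    data.frame(chrom = ch, start = starts, end = starts + w, gc = gc,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  n_top <- max(1L, ceiling(top_fraction * nrow(all)))
  ord <- order(-all$gc, all$chrom, all$start)
  sel <- all[ord[seq_len(n_top)], , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}
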