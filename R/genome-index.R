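#' Genome index: chromosome sizes and assembly gaps
#'
#' A light-weight container for chromosome names/lengths and assembly-gap
#' intervals. All coordinates in this package are 0-based, half-open
#' (BED convention).
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bases.
#' @param gaps data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open) giving assembly-gap intervals, or `NULL` for none.
#' @return an object of class `genome_index`.
#' @export
genome_index <- function(chrom_lengths, gaps = NULL) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(gaps)) {
    gaps <- data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  }
  gaps <- as.data.frame(gaps)[, c("chrom", "start", "end")]
  if (nrow(gaps)) {
    if (!all(gaps$chrom %in% names(chrom_lengths)))
      stop("gap on unknown chromosome")
    if (any(gaps$start < 0) ||
        any(gaps$end > chrom_lengths[gaps$chrom]))
      stop("gap outside chromosome bounds")
    if (any(gaps$end <= gaps$start)) stop("empty or inverted gap interval")
    gaps <- gaps[order(gaps$chrom, gaps$start), , drop = FALSE]
    # gaps must be disjoint within a chromosome
    by_chr <- split(gaps, gaps$chrom)
    for (g in by_chr) {
      if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)]))
        stop("overlapping gap intervals on ", g$chrom[1L])
    }
    rownames(gaps) <- NULL
  }
  structure(list(chrom_lengths = chrom_lengths, gaps = gaps),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$chrom_lengths), "chromosomes,",
      sum(as.numeric(x$chrom_lengths)), "bp,",
      nrow(x$gaps), "assembly gaps\n")
  invisible(x)
}

gap_bases <- function(index, chrom) {
  g <- index$gaps[index$gaps$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(0)
  sum(g$end - g$start)
}

#' Map between genomic and gap-excluded ("gapless") coordinates
#'
#' Assembly gaps are excluded before the permutation analysis; circular
#' shifts operate on the concatenated non-gap bases of each chromosome.
#' The map is a bijection between non-gap genomic bases and
#' `[0, effective_length)` per chromosome.
#'
#' @param index a [genome_index()].
#' @return an object of class `gapless_map`: per chromosome, the non-gap
#'   blocks with their genomic and gapless start coordinates, and the
#'   effective (gap-excluded) length.
#' @export
build_gapless_map <- function(index) {
  stopifnot(inherits(index, "genome_index"))
  chroms <- names(index$chrom_lengths)
  blocks <- lapply(chroms, function(ch) {
    L <- index$chrom_lengths[[ch]]
    g <- index$gaps[index$gaps$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    starts <- c(0, g$end)
    ends <- c(g$start, L)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    w <- ends - starts
    data.frame(gstart = starts, gend = ends,
               glstart = cumsum(c(0, w[-length(w)])),
               stringsAsFactors = FALSE)
  })
  names(blocks) <- chroms
  eff <- vapply(blocks, function(b) sum(b$gend - b$gstart), numeric(1))
  structure(list(blocks = blocks, effective_length = eff,
                 chrom_lengths = index$chrom_lengths),
            class = "gapless_map")
}

#' @export
print.gapless_map <- function(x, ...) {
  cat("gapless_map over", length(x$blocks), "chromosomes; effective lengths:",
      paste(x$effective_length, collapse = ", "), "\n")
  invisible(x)
}

#' Convert genomic positions to gapless coordinates
#'
#' @param map a [build_gapless_map()] result.
#' @param chrom chromosome name (scalar).
#' @param pos integer vector of genomic positions (0-based). Positions inside
#'   a gap yield `NA`.
#' @return numeric vector of gapless coordinates.
#' @export
genomic_to_gapless <- function(map, chrom, pos) {
  b <- map$blocks[[chrom]]
  if (is.null(b)) stop("unknown chromosome: ", chrom)
  i <- findInterval(pos, b$gstart)
  out <- rep(NA_real_, length(pos))
  ok <- i >= 1L
  okk <- ok & pos < b$gend[pmax(i, 1L)]
  out[okk] <- b$glstart[i[okk]] + (pos[okk] - b$gstart[i[okk]])
  out
}

#' Convert gapless coordinates back to genomic positions
#'
#' @inheritParams genomic_to_gapless
#' @param pos gapless positions in `[0, effective_length)`.
#' @return numeric vector of genomic positions.
#' @export
gapless_to_genomic <- function(map, chrom, pos) {
  b <- map$blocks[[chrom]]
  if (is.null(b)) stop("unknown chromosome: ", chrom)
  if (any(pos < 0 | pos >= map$effective_length[[chrom]], na.rm = TRUE))
    stop("gapless position out of range on ", chrom)
  i <- findInterval(pos, b$glstart)
  b$gstart[i] + (pos - b$glstart[i])
}

#' Split a gapless interval into genomic pieces
#'
#' A contiguous gapless interval may map to several genomic intervals,
#' split at assembly gaps.
#'
#' @inheritParams genomic_to_gapless
#' @param start,end gapless half-open interval bounds, `end <= effective
#'   length`.
#' @return data.frame of genomic `start`, `end` pieces.
#' @keywords internal
gapless_interval_to_genomic <- function(map, chrom, start, end) {
  b <- map$blocks[[chrom]]
  w <- b$gend - b$gstart
  glend <- b$glstart + w
  i0 <- findInterval(start, b$glstart)
  i1 <- findInterval(end - 1, b$glstart)
  idx <- seq.int(i0, i1)
  ps <- pmax(b$glstart[idx], start)
  pe <- pmin(glend[idx], end)
  data.frame(start = b$gstart[idx] + (ps - b$glstart[idx]),
             end = b$gstart[idx] + (pe - b$glstart[idx]),
             stringsAsFactors = FALSE)
}
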