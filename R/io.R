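#' Write chromosome sequences as FASTA
#'
#' @param sequences named character vector/list or `DNAStringSet`.
#' @param path output file.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(sequences, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTA file
#'
#' Multi-record, wrapped-line, N-tolerant (delegates to Biostrings).
#'
#' @param path FASTA file.
#' @return named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write intervals as BED
#'
#' Emits BED3/BED6 (0-based, half-open) with deterministic ordering.
#' Optional `name`, `score` and `strand` columns are used when present.
#'
#' @param x data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- data.frame(chrom = x$chrom, start = format_pos(x$start),
                    end = format_pos(x$end), stringsAsFactors = FALSE)
  if (!is.null(x$strand)) {
    out$name <- if (!is.null(x$name)) x$name else "."
    out$score <- if (!is.null(x$score)) x$score else 0
    out$strand <- x$strand
  } else if (!is.null(x$name)) {
    out$name <- x$name
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_pos <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a BED file
#'
#' @param path BED3+ file.
#' @return data.frame with `chrom`, `start`, `end` (+ `name`, `score`,
#'   `strand` when present).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(x) > 3L)
    names(x)[4:min(6L, ncol(x))] <- extra[seq_len(min(3L, ncol(x) - 3L))]
  x
}

#' Write directional reads as TSV
#'
#' Columns: chrom, start, end, label (W/C), haplotype (A/B/.), cell_id;
#' deterministic ordering by cell, chromosome, start.
#'
#' @param reads read table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  reads <- data.table::as.data.table(reads)
  data.table::setorder(reads, cell_id, chrom, start)
  data.table::fwrite(reads, path, sep = "\t")
  invisible(path)
}

#' Read directional reads from TSV
#'
#' @param path TSV written by [write_reads_tsv()].
#' @return data.table of reads.
#' @export
read_reads_tsv <- function(path) {
  data.table::fread(path)
}

#' Drop SCE regions overlapping assembly gaps
#'
#' Observed SCE regions spanning an assembly gap cannot be placed in
#' gap-excluded coordinates and are excluded before the permutation
#' analysis.
#'
#' @param sces SCE table.
#' @param index a [genome_index()].
#' @return filtered SCE table.
#' @export
drop_gap_regions <- function(sces, index) {
  if (!nrow(index$gaps) || !nrow(sces)) return(sces)
  keep <- rep(TRUE, nrow(sces))
  for (ch in unique(sces$chrom)) {
    g <- index$gaps[index$gaps$chrom == ch, , drop = FALSE]
    si <- which(sces$chrom == ch)
    if (!nrow(g) || !length(si)) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(sces$start[si] + 1L, sces$end[si]),
      IRanges::IRanges(g$start + 1L, g$end))
    keep[si[ov]] <- FALSE
  }
  sces[keep, , drop = FALSE]
}
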