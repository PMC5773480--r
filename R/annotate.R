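#' Classify genes as active or silent from expression values
#'
#' Genes with FPKM strictly above the threshold are active, all others
#' (including FPKM exactly at the threshold) silent.
#'
#' @param expression data.frame with columns `gene_id` and `fpkm`.
#' @param threshold FPKM threshold (default 1).
#' @param gene_ids optional vector of gene ids that must be classified;
#'   ids missing from `expression` are reported silent with a warning.
#' @return named character vector (`"active"`/`"silent"`) indexed by gene id.
#' @export
classify_gene_activity <- function(expression, threshold = 1,
                                   gene_ids = NULL) {
  if (any(expression$fpkm < 0)) stop("fpkm must be non-negative")
  act <- ifelse(expression$fpkm > threshold, "active", "silent")
  names(act) <- expression$gene_id
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, expression$gene_id)
    if (length(missing)) {
      warning(length(missing),
              " gene(s) missing from expression table; classified silent")
      act <- c(act, stats::setNames(rep("silent", length(missing)), missing))
    }
    act <- act[gene_ids]
  }
  act
}

#' Promoter regions upstream of transcription start sites
#'
#' For a plus-strand gene the promoter is `[tss - length, tss)`; for a
#' minus-strand gene `[tss, tss + length)`; clipped at chromosome ends.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`, `tes`,
#'   `strand`.
#' @param length promoter length in bases (default 1000).
#' @param index optional [genome_index()] used for clipping at chromosome
#'   ends.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_regions <- function(genes, length = 1000L, index = NULL) {
  if (length <= 0) stop("promoter length must be positive")
  start <- ifelse(genes$strand == "+", genes$tss - length, genes$tss)
  end <- start + length
  start <- pmax(start, 0)
  if (!is.null(index))
    end <- pmin(end, index$chrom_lengths[genes$chrom])
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = start, end = end, stringsAsFactors = FALSE)
}

gene_bodies <- function(genes) {
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmin(genes$tss, genes$tes),
             end = pmax(genes$tss, genes$tes),
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Assign genomic context to motifs
#'
#' Each motif is classified as `intergenic` (outside every gene body) or, if
#' inside a gene body, by the strand it occupies relative to transcription:
#' a motif on the strand opposite the gene's annotated (sense) strand lies on
#' the transcribed (template) strand; a motif on the same strand lies on the
#' non-transcribed strand. The host gene's activity is copied onto the motif.
#' A motif overlapping two gene bodies is assigned to the gene with the
#' larger overlap; ties go to the gene with the smaller genomic start
#' (5'-most in reference orientation).
#'
#' @param motifs data.frame from [scan_g4()].
#' @param genes gene table with columns `gene_id`, `chrom`, `tss`, `tes`,
#'   `strand` and `activity` (see [classify_gene_activity()]).
#' @return `motifs` with added columns `context`
#'   (`intergenic`/`transcribed_strand`/`non_transcribed_strand`),
#'   `gene_activity` (`active`/`silent`/`none`) and `gene_id`.
#' @export
classify_motif_context <- function(motifs, genes) {
  if (is.null(genes$activity)) stop("genes must carry an 'activity' column")
  motifs$context <- "intergenic"
  motifs$gene_activity <- "none"
  motifs$gene_id <- NA_character_
  if (!nrow(motifs) || !nrow(genes)) return(motifs)
  gb <- gene_bodies(genes)
  gb$activity <- genes$activity
  for (ch in unique(motifs$chrom)) {
    mi <- which(motifs$chrom == ch)
    gi <- which(gb$chrom == ch)
    if (!length(mi) || !length(gi)) next
    mr <- IRanges::IRanges(start = motifs$start[mi] + 1L, end = motifs$end[mi])
    gr <- IRanges::IRanges(start = gb$start[gi] + 1L, end = gb$end[gi])
    ov <- IRanges::findOverlaps(mr, gr)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(mr[qh], gr[sh]))
    # larger overlap wins; ties -> smaller gene start
    ord <- order(qh, -w, gb$start[gi][sh])
    pick <- ord[!duplicated(qh[ord])]
    midx <- mi[qh[pick]]; gidx <- gi[sh[pick]]
    same <- motifs$strand[midx] == gb$strand[gidx]
    motifs$context[midx] <- ifelse(same, "non_transcribed_strand",
                                   "transcribed_strand")
    motifs$gene_activity[midx] <- gb$activity[gidx]
    motifs$gene_id[midx] <- gb$gene_id[gidx]
  }
  motifs
}
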