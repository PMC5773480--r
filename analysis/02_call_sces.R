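#!/usr/bin/env Rscript

# Stage 2: template-strand state inference and SCE calling.
#
# For each simulated line: segment every cell's chromosomes into WW/WC/CC
# states, call SCEs as the read gaps between adjacent states, remove
# recurrent regions (>5% of cells at the same location = stable
# rearrangements), drop gap-spanning regions, and summarise mapping
# resolution and the SCE-per-chromosome-size correlation.

suppressPackageStartupMessages(library(sceG4))

inp <- "results/01_simulate"
out <- "results/02_call_sces"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome_seqs <- read_fasta(file.path(inp, "genome.fa"))
gaps <- read_bed(file.path(inp, "gaps.bed"))
index <- genome_index(stats::setNames(Biostrings::width(genome_seqs),
                                      names(genome_seqs)), gaps)

for (nm in c("wt", "bs")) {
  reads <- read_reads_tsv(file.path(inp, sprintf("reads_%s.tsv", nm)))
  n_cells <- length(unique(reads$cell_id))
  segs <- infer_strand_states_all(reads, index)
  sces <- call_sces(segs)
  filt <- filter_recurrent(sces, n_cells)
  kept <- drop_gap_regions(filt$kept, index)
  truth <- utils::read.table(file.path(inp,
                                       sprintf("truth_sces_%s.tsv", nm)),
                             header = TRUE, sep = "\t")
  m <- match_sces_to_truth(kept, truth)
  rs <- resolution_summary(kept)
  r2 <- chromosome_size_correlation(kept, index, n_cells)
  message(sprintf(
    "%s: %d called, %d kept (%d recurrent, %d gap); recall %.3f precision %.3f",
    nm, nrow(sces), nrow(kept), nrow(filt$removed),
    nrow(filt$kept) - nrow(kept), m$recall, m$precision))
  message(sprintf(
    "%s: median resolution %.1f kb; %.1f%% of SCEs below 100 kb; SCEs/chrom vs size R2 = %.2f",
    nm, rs$median_resolution / 1e3, 100 * rs$fraction_below_100kb, r2))
  write_bed(transform(kept, name = cell_id, score = resolution),
            file.path(out, sprintf("sces_%s.bed", nm)))
  utils::write.table(kept, file.path(out, sprintf("sces_%s.tsv", nm)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
message("SCE tables written to ", out)
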