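#!/usr/bin/env Rscript

# Stage 3: feature sets for the enrichment analysis.
#
# Scans the genome for canonical G4 motifs in the three loop-size families
# (1-3, 1-7, 1-12), A-rich control motifs and top-decile GC windows;
# classifies genes as active/silent (FPKM > 1), builds 1 kb promoters, and
# annotates every motif with its genomic context (intergenic vs intragenic
# on the transcribed or non-transcribed strand, host-gene activity).

suppressPackageStartupMessages(library(sceG4))

inp <- "results/01_simulate"
out <- "results/03_features"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seqs <- read_fasta(file.path(inp, "genome.fa"))
gaps <- read_bed(file.path(inp, "gaps.bed"))
index <- genome_index(stats::setNames(Biostrings::width(seqs), names(seqs)),
                      gaps)
genes <- utils::read.table(file.path(inp, "genes.tsv"), header = TRUE,
                           sep = "\t")
expression <- utils::read.table(file.path(inp, "expression.tsv"),
                                header = TRUE, sep = "\t")
genes$activity <- unname(classify_gene_activity(expression,
                                                gene_ids = genes$gene_id))

for (lp in list(c(1, 3), c(1, 7), c(1, 12))) {
  m <- scan_g4(seqs, lp[1], lp[2])
  message(sprintf("G4 loop %d-%d: %d motifs (mean spacing %.0f bp)",
                  lp[1], lp[2], nrow(m),
                  sum(as.numeric(index$chrom_lengths)) / nrow(m)))
  if (lp[2] == 7) {
    m <- classify_motif_context(m, genes)
    print(table(context = m$context, activity = m$gene_activity))
  }
  write_bed(transform(m, name = sprintf("g4_%d_%d", lp[1], lp[2])),
            file.path(out, sprintf("g4_loop_%d_%d.bed", lp[1], lp[2])))
}

arich <- scan_a_rich(seqs)
gcw <- gc_windows(seqs, 1000, 0.1)
write_bed(transform(arich, name = "a_rich"), file.path(out, "a_rich.bed"))
write_bed(gcw, file.path(out, "gc_top_decile.bed"))
write_bed(transform(promoter_regions(genes, 1000, index),
                    name = gene_id),
          file.path(out, "promoters.bed"))
utils::write.table(genes, file.path(out, "genes_classified.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("A-rich: %d; GC top-decile windows: %d; genes: %d (%d active)",
                nrow(arich), nrow(gcw), nrow(genes),
                sum(genes$activity == "active")))
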