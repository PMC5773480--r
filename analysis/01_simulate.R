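#!/usr/bin/env Rscript

# Stage 1: build the synthetic study system.
#
# Generates the default desk-scale genome (3 x 30 Mb chromosomes, 2%
# assembly gaps, canonical G4 motifs planted every ~8.6 kb, 600 genes with
# 60% transcribed) and simulates two Strand-seq cell lines:
#   - "WT-like":  low SCE load, no G4 association (factor 1.0)
#   - "BS-like":  Bloom-syndrome-like load with a 1.2-fold excess of SCE
#                 formation at G4 motifs in active genes
# Writes FASTA/BED/TSV inputs plus ground truth for the later stages.

suppressPackageStartupMessages(library(sceG4))

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260925

spec <- genome_spec(seed = seed)
genome <- generate_genome(spec)
print(genome)
write_fasta(genome$sequences, file.path(out, "genome.fa"))
write_bed(genome$index$gaps, file.path(out, "gaps.bed"))
write_bed(transform(genome$g4_truth, name = "planted_g4"),
          file.path(out, "g4_truth.bed"))
utils::write.table(genome$genes, file.path(out, "genes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(genome$expression, file.path(out, "expression.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

motifs <- scan_g4(genome$sequences)
message(sprintf("scanned %d canonical G4 motifs (planted %d); mean spacing %.0f bp",
                nrow(motifs), nrow(genome$g4_truth),
                sum(as.numeric(spec$chrom_lengths)) / nrow(motifs)))

lines <- list(
  wt = sim_params(n_cells = 150, sce_rate_per_cell = 1,
                  g4_enrichment_factor = 1, seed = seed + 1),
  bs = sim_params(n_cells = 300, sce_rate_per_cell = 8,
                  g4_enrichment_factor = 1.2, seed = seed + 2))

for (nm in names(lines)) {
  sim <- simulate_cells(genome, lines[[nm]], motifs = motifs)
  write_reads_tsv(sim$reads, file.path(out, sprintf("reads_%s.tsv", nm)))
  utils::write.table(sim$truth$true_sces,
                     file.path(out, sprintf("truth_sces_%s.tsv", nm)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s line: %d cells, %d reads, %d true SCEs (seed prob %.3f)",
                  nm, lines[[nm]]$n_cells, nrow(sim$reads),
                  nrow(sim$truth$true_sces), sim$truth$p_seed))
}
message("inputs written to ", out)
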