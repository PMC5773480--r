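#!/usr/bin/env Rscript

# Stage 6: haplotype-resolved analyses on an F1-hybrid line.
#
# Simulates an F1-hybrid experiment (heterozygous SNPs, allele-specific G4
# motifs, haplotype-tagged reads) with SCEs seeded at allele-specific G4s
# on the motif-carrying homolog 70% of the time, then: identifies
# allele-specific motifs from the two haplotype sequences, assigns SCEs to
# homologs from tagged reads, tests SCE/G4 homolog concordance against the
# 50% null (binomial, one-sided), calls copy-neutral LOH, and estimates
# per-chromosome ploidy for a line with a planted trisomy.

suppressPackageStartupMessages(library(sceG4))

out <- "results/06_allelic_loh"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260925

genome <- generate_genome(genome_spec(n_chromosomes = 2,
                                      chrom_lengths = 20e6,
                                      gene_count = 300, seed = seed))
params <- sim_params(n_cells = 150, sce_rate_per_cell = 6,
                     coverage_fraction = 0.02, seed = seed + 6)
f1 <- simulate_f1_hybrid(genome, params, allelic_fraction = 0.4,
                         allelic_seed_fraction = 0.8,
                         concordance_rate = 0.7,
                         planted_loh = data.frame(chrom = "chr2",
                                                  start = 5e6, end = 10e6,
                                                  haplotype_retained = "A"))

allelic <- find_allelic_g4(f1$hap_a, f1$hap_b)
truth_al <- f1$truth$allelic_g4
message(sprintf("allele-specific G4s: %d called, %d planted (%d on hap A / %d on hap B)",
                nrow(allelic), nrow(truth_al),
                sum(truth_al$haplotype == "A"),
                sum(truth_al$haplotype == "B")))
write_bed(transform(allelic, name = haplotype), file.path(out, "allelic_g4.bed"))

segs <- infer_strand_states_all(f1$reads, genome$index)
sces <- call_sces(segs)
sces <- assign_homolog(sces, f1$reads)
message(sprintf("SCEs: %d called, %d homolog-assigned", nrow(sces),
                sum(sces$homolog != "none")))

conc <- concordance_test(sces, allelic)
print(conc)
jsonlite::write_json(unclass(conc)[c("n_informative", "n_concordant",
                                     "fraction_concordant", "p_value",
                                     "alternative")],
                     file.path(out, "concordance.json"), auto_unbox = TRUE,
                     digits = NA, force = TRUE)

# LOH per cell (planted: chr2:5-10 Mb in every cell, copy-neutral)
ploidy <- naive_ploidy(f1$reads, genome$index)
loh_hits <- 0L
for (cl in unique(f1$reads$cell_id)) {
  bins <- bin_haplotype_reads(f1$reads[f1$reads$cell_id == cl, ],
                              genome$index)
  cs <- ploidy[ploidy$cell_id == cl, ]
  seg <- call_loh(bins, copy_state = cs$copy_state[match(bins$chrom,
                                                         cs$chrom)])
  if (any(seg$chrom == "chr2" & seg$start < 10e6 & seg$end > 5e6 &
            seg$haplotype_retained == "A"))
    loh_hits <- loh_hits + 1L
}
message(sprintf("planted LOH recovered in %d/%d cells", loh_hits,
                length(unique(f1$reads$cell_id))))

# trisomy detection on a separate small line; the median-density baseline
# needs a majority of diploid chromosomes, so use a three-chromosome genome
genome3 <- generate_genome(genome_spec(n_chromosomes = 3,
                                       chrom_lengths = 10e6,
                                       gene_count = 200, seed = seed + 1))
f1t <- simulate_f1_hybrid(genome3,
                          sim_params(n_cells = 30, sce_rate_per_cell = 0,
                                     seed = seed + 7),
                          planted_trisomy = "chr1")
pl <- naive_ploidy(f1t$reads, genome3$index)
message(sprintf("planted trisomy flagged in %.0f%% of cells",
                100 * mean(pl$copy_state[pl$chrom == "chr1"] == "trisomy")))
utils::write.table(pl, file.path(out, "ploidy_trisomy_line.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
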