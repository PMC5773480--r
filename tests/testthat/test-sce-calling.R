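mk_reads <- function(starts, labels, chrom = "chr1", cell = "cellA") {
  data.frame(chrom = chrom, start = starts, end = starts + 100,
             label = labels, haplotype = ".", cell_id = cell,
             stringsAsFactors = FALSE)
}

test_that("noiseless state switches are segmented exactly", {
  idx <- genome_index(c(chr1 = 1e6))
  set.seed(1)
  # 40 reads at W-fraction 0.5 then 40 reads all C -> WC then CC
  # (the WC block ends on a W read: a trailing C is indistinguishable from
  # the CC segment and would correctly be absorbed by it)
  starts <- sort(sample.int(9e5, 80))
  labels <- c(rep(c("C", "W"), 20), rep("C", 40))
  segs <- infer_strand_states(mk_reads(starts, labels), idx)
  expect_equal(segs$state, c("WC", "CC"))
  expect_equal(segs$n_reads, c(40L, 40L))
  expect_equal(segs$start, c(0, segs$last_read_end[1]))
  expect_equal(segs$end[2], 1e6)

  # all W -> single WW segment
  segs <- infer_strand_states(mk_reads(starts, rep("W", 80)), idx)
  expect_equal(segs$state, "WW")
  expect_equal(nrow(segs), 1L)
})

test_that("chromosomes with too few reads are uncallable", {
  idx <- genome_index(c(chr1 = 1e6))
  segs <- infer_strand_states(mk_reads(c(10, 2000), c("W", "W")), idx,
                              min_reads = 10)
  expect_equal(nrow(segs), 0L)
})

test_that("SCE regions span the gap between boundary reads", {
  segs <- data.frame(
    cell_id = "c1", chrom = "chr1",
    start = c(0, 350000), end = c(350000, 1e6), state = c("WW", "WC"),
    n_reads = c(50L, 50L), first_read_start = c(100, 361000),
    last_read_end = c(350000, 999000))
  sce <- call_sces(segs)
  expect_equal(sce$start, 350000)
  expect_equal(sce$end, 361000)
  expect_equal(sce$resolution, 11000)

  # abutting boundary reads give resolution 1
  segs$first_read_start[2] <- 350001
  sce <- call_sces(segs)
  expect_equal(sce$resolution, 1)

  # a WW -> CC jump is emitted as two stacked SCEs with a warning
  segs$state <- c("WW", "CC")
  segs$first_read_start[2] <- 361000
  expect_warning(sce2 <- call_sces(segs), "double switch")
  expect_equal(nrow(sce2), 2L)
  expect_equal(sce2$start, rep(350000, 2))
})

test_that("caller is symmetric under global W/C label swap", {
  idx <- genome_index(c(chr1 = 2e6))
  set.seed(21)
  starts <- sort(sample.int(2e6 - 100, 300))
  labels <- c(sample(c("W", "C"), 150, replace = TRUE),
              sample(c("W", "C"), 150, replace = TRUE, prob = c(0.98, 0.02)))
  segs_a <- infer_strand_states(mk_reads(starts, labels), idx)
  flipped <- ifelse(labels == "W", "C", "W")
  segs_b <- infer_strand_states(mk_reads(starts, flipped), idx)
  mirror <- c(WW = "CC", WC = "WC", CC = "WW")
  expect_equal(unname(mirror[segs_a$state]), segs_b$state)
  expect_equal(segs_a$start, segs_b$start)
  expect_equal(call_sces(segs_a)[, c("start", "end")],
               call_sces(segs_b)[, c("start", "end")])
})

test_that("with zero noise and dense reads recovery is exact", {
  g <- make_test_genome(chrom_lengths = 5e6, gene_count = 30, seed = 31)
  p <- sim_params(n_cells = 20, sce_rate_per_cell = 1.5,
                  g4_enrichment_factor = 1, background_noise = 0,
                  coverage_fraction = 0.05, seed = 32)
  sim <- suppressWarnings(simulate_cells(g, p))
  segs <- infer_strand_states_all(sim$reads, g$index)
  sces <- suppressWarnings(call_sces(segs))
  truth <- sim$truth$true_sces
  # zero noise removes false switches and boundary capture, but the mixed
  # (WC) state still absorbs pre-switch-labelled reads, so matching uses
  # the standard displacement margin
  m <- match_sces_to_truth(sces, truth, mean_gap = 100 / 0.05)
  expect_gte(m$precision, 0.98)
  expect_gte(m$recall, 0.98)
})

test_that("recurrent regions are filtered at the strict >5% rule", {
  base <- data.frame(chrom = "chr1", start = 1e5, end = 1.1e5,
                     resolution = 1e4, homolog = "none")
  mk <- function(n, offset = 0)
    do.call(rbind, lapply(seq_len(n), function(i)
      transform(base, cell_id = sprintf("c%03d", i + offset),
                start = start, end = end)))
  # identical region in 6 of 100 cells -> removed
  out <- filter_recurrent(mk(6), cell_count = 100)
  expect_equal(nrow(out$kept), 0L)
  expect_equal(nrow(out$removed), 6L)
  # identical region in 5 of 100 cells -> kept (strict >)
  out <- filter_recurrent(mk(5), cell_count = 100)
  expect_equal(nrow(out$removed), 0L)
})

test_that("a planted stable breakpoint is removed, true SCEs kept", {
  g <- make_test_genome(chrom_lengths = 5e6, gene_count = 30, seed = 41)
  p <- sim_params(n_cells = 100, sce_rate_per_cell = 1,
                  g4_enrichment_factor = 1, coverage_fraction = 0.03,
                  stable_breakpoints = data.frame(chrom = "chr1",
                                                  pos = 2.5e6),
                  seed = 42)
  sim <- suppressWarnings(simulate_cells(g, p))
  segs <- infer_strand_states_all(sim$reads, g$index)
  sces <- suppressWarnings(call_sces(segs))
  out <- filter_recurrent(sces, cell_count = 100)
  # calls at the planted breakpoint (within the caller's displacement
  # uncertainty) are removed in bulk; a small residue displaced off the
  # breakpoint is indistinguishable from unique SCEs by location
  near <- function(x) abs((x$start + x$end) / 2 - 2.5e6) < 3.1e4
  n_near <- sum(near(sces))
  expect_gt(n_near, 80)
  expect_lte(sum(near(out$kept)), 0.25 * n_near)
  # the region containing the breakpoint itself never survives
  at_bp <- function(x) x$start <= 2.5e6 & x$end > 2.5e6
  expect_lte(sum(at_bp(out$kept)), 2)
  # true SCEs are untouched: recall unchanged by the filter
  m_pre <- match_sces_to_truth(sces, sim$truth$true_sces,
                               mean_gap = 100 / 0.03)
  m_post <- match_sces_to_truth(out$kept, sim$truth$true_sces,
                                mean_gap = 100 / 0.03)
  expect_gt(m_post$recall, 0.9)
  expect_equal(m_post$recall, m_pre$recall, tolerance = 0.02)
})

test_that("resolution summary and chromosome-size correlation", {
  sces <- data.frame(cell_id = "c1", chrom = "chr1",
                     start = 0, end = c(5e3, 1e4, 1.5e4),
                     resolution = c(5e3, 1e4, 1.5e4))
  rs <- resolution_summary(sces)
  expect_equal(rs$median_resolution, 1e4)
  expect_equal(rs$fraction_below_100kb, 1)

  idx <- genome_index(c(chr1 = 1e6, chr2 = 2e6, chr3 = 3e6))
  prop <- data.frame(chrom = rep(c("chr1", "chr2", "chr3"), times = 1:3))
  expect_equal(chromosome_size_correlation(prop, idx, n_cells = 10), 1)
  flat <- data.frame(chrom = rep(c("chr1", "chr2", "chr3"), each = 2))
  expect_equal(chromosome_size_correlation(flat, idx, n_cells = 10), 0)
  expect_error(chromosome_size_correlation(
    prop, genome_index(c(chr1 = 1e6, chr2 = 2e6)), 10), "3 chromosomes")
})

test_that("SCE load scales with chromosome size under uniform simulation", {
  g <- generate_genome(genome_spec(3, c(10e6, 20e6, 30e6),
                                   gene_count = 120, seed = 51))
  p <- sim_params(n_cells = 150, sce_rate_per_cell = 4,
                  g4_enrichment_factor = 1, seed = 52)
  sim <- suppressWarnings(simulate_cells(g, p))
  r2 <- chromosome_size_correlation(sim$truth$true_sces, g$index, 150)
  expect_gt(r2, 0.9)
})
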