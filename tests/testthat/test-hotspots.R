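test_that("hotspot candidates are intersections of overlapping regions", {
  sces <- data.frame(cell_id = c("c1", "c2", "c3"), chrom = "chr1",
                     start = c(10, 20, 25), end = c(30, 40, 35))
  h <- detect_hotspots(sces, min_cells = 3)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(25, 30))
  expect_equal(h$n_libraries_with_sce, 3L)
  expect_equal(h$total_sces, 3L)

  # non-overlapping regions yield no candidates
  apart <- data.frame(cell_id = c("c1", "c2", "c3"), chrom = "chr1",
                      start = c(10, 100, 200), end = c(20, 120, 220))
  expect_equal(nrow(detect_hotspots(apart)), 0L)

  # two regions from the same cell count once
  dup <- rbind(sces, data.frame(cell_id = "c1", chrom = "chr1",
                                start = 26, end = 34))
  h2 <- detect_hotspots(dup, min_cells = 4)
  expect_equal(nrow(h2), 0L)
})

test_that("hotspot bin probability matches closed forms and the oracle", {
  # length ratio 0.5, total 2, observed 2 -> 0.25
  expect_equal(hotspot_pvalue(50, 100, 2, 2), 0.25)
  expect_equal(hotspot_pvalue(50, 100, 2, 0), 1)

  # fragile-site-scale inputs: 366 kb hotspot, 2128 SCEs, 15 observed
  # (an EBV-transformed line); oracle = explicit sum of binomial masses
  len <- 60601404 - 60235449
  eff <- 2.88e9
  p <- hotspot_pvalue(len, eff, 2128, 15)
  oracle <- sum(stats::dbinom(15:2128, 2128, len / eff))
  expect_equal(p, oracle, tolerance = 1e-12)
  # Poisson approximation agrees to leading order
  expect_equal(hotspot_pvalue(len, eff, 2128, 15, method = "poisson"), p,
               tolerance = 0.05)

  # monotone: more observed events -> smaller p; longer hotspot -> larger p
  ps <- vapply(1:10, function(k) hotspot_pvalue(1e5, 1e9, 500, k),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  pl <- vapply(c(1e5, 2e5, 4e5), function(L) hotspot_pvalue(L, 1e9, 500, 5),
               numeric(1))
  expect_true(all(diff(pl) > 0))

  expect_error(hotspot_pvalue(10, 100, 0, 0))
  expect_error(hotspot_pvalue(200, 100, 10, 2))
})

test_that("a planted hotspot is detected; a uniform line yields none", {
  g <- make_test_genome(chrom_lengths = 8e6, gene_count = 50, seed = 61)
  p <- sim_params(n_cells = 150, sce_rate_per_cell = 1,
                  g4_enrichment_factor = 1,
                  hotspot = list(chrom = "chr1", pos = 4e6, fraction = 0.1,
                                 width = 1e5),
                  seed = 62)
  sim <- suppressWarnings(simulate_cells(g, p))
  segs <- infer_strand_states_all(sim$reads, g$index)
  sces <- suppressWarnings(call_sces(segs))
  h <- detect_hotspots(sces, min_cells = 3)
  expect_gt(nrow(h), 0L)
  in_window <- h$end > 3.94e6 & h$start < 4.06e6
  expect_true(any(in_window))
  hs <- score_hotspots(h, build_gapless_map(g$index), nrow(sces), 150)
  expect_true(all(hs$p_value > 0 & hs$p_value <= 1))
  expect_lt(min(hs$p_value[in_window]), 1e-4)
  # a fragile-site-scale hotspot (hit in ~4.5% of libraries, as reported
  # for FRA3B-like sites) coexists with the >5% recurrence filter: the
  # locus recurs in fewer cells than the removal threshold
  p2 <- sim_params(n_cells = 150, sce_rate_per_cell = 1,
                   g4_enrichment_factor = 1,
                   hotspot = list(chrom = "chr1", pos = 4e6,
                                  fraction = 0.045, width = 1e5),
                   seed = 63)
  sim2 <- suppressWarnings(simulate_cells(g, p2))
  sces2 <- suppressWarnings(call_sces(
    infer_strand_states_all(sim2$reads, g$index)))
  kept2 <- filter_recurrent(sces2, 150)$kept
  hk <- detect_hotspots(kept2, min_cells = 3)
  expect_true(any(hk$end > 3.94e6 & hk$start < 4.06e6))

  # sparse WT-like uniform lines: no 3-cell co-occurring locus across seeds
  n_candidates <- 0L
  for (sd in 1:8) {
    pu <- sim_params(n_cells = 25, sce_rate_per_cell = 1,
                     g4_enrichment_factor = 1, seed = 600 + sd)
    simu <- suppressWarnings(simulate_cells(g, pu))
    segu <- infer_strand_states_all(simu$reads, g$index)
    sceu <- suppressWarnings(call_sces(segu))
    n_candidates <- n_candidates + nrow(detect_hotspots(sceu, min_cells = 3))
  }
  expect_equal(n_candidates, 0L)
})
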