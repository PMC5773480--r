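# Independent regular-expression oracle for the quadruplex scanner.
# Lazy loops + greedy runs reproduce the leftmost / greedy-run /
# non-overlapping convention; candidates containing N are rejected because
# the loop class excludes it.
g4_regex_oracle <- function(s, loop_min = 1, loop_max = 7, run_char = "G",
                            min_run = 3) {
  pat <- sprintf("%s{%d,}(?:[ACGT]{%d,%d}?%s{%d,}){3}",
                 run_char, min_run, loop_min, loop_max, run_char, min_run)
  m <- gregexpr(pat, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

# oracle applied to both strands, coordinates mapped like the scanner
g4_regex_oracle_both <- function(s, loop_min = 1, loop_max = 7,
                                 run_char = "G") {
  plus <- g4_regex_oracle(s, loop_min, loop_max, run_char)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  minus <- g4_regex_oracle(rc, loop_min, loop_max, run_char)
  L <- nchar(s)
  rbind(
    if (nrow(plus)) cbind(plus, strand = "+") else NULL,
    if (nrow(minus)) data.frame(start = L - minus$end, end = L - minus$start,
                                strand = "-") else NULL)
}

rand_seq <- function(n, prob = c(0.25, 0.25, 0.25, 0.25), with_n = 0) {
  alpha <- c("A", "C", "G", "T")
  s <- sample(alpha, n, replace = TRUE, prob = prob)
  if (with_n > 0) {
    k <- max(1L, round(with_n * n))
    s[sample.int(n, k)] <- "N"
  }
  paste(s, collapse = "")
}

motif_key <- function(x) {
  if (!nrow(x)) return(character())
  sort(paste(x$start, x$end, x$strand))
}

# small default-like genome for caller tests
make_test_genome <- function(chrom_lengths = 8e6, gene_count = 50,
                             seed = 1, ...) {
  generate_genome(genome_spec(n_chromosomes = length(chrom_lengths),
                              chrom_lengths = chrom_lengths,
                              gene_count = gene_count, seed = seed, ...))
}

# exact one-sided binomial tail by enumeration over outcome counts
# (choose-sum over the 2^n equally likely outcomes)
enum_binom_tail <- function(k, n) {
  if (k <= 0) return(1)
  sum(choose(n, k:n)) / 2^n
}

expect_same_regions <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    oa <- order(a$chrom, a$start); ob <- order(b$chrom, b$start)
    expect_equal(a$start[oa], b$start[ob])
    expect_equal(a$end[oa], b$end[ob])
  }
}

# fraction of homolog-assigned calls whose nearest truth event (within
# margin) carries the same homolog
homolog_assignment_accuracy <- function(calls, truth, margin) {
  n <- 0L; ok <- 0L
  for (j in seq_len(nrow(calls))) {
    ti <- which(truth$cell_id == calls$cell_id[j] &
                  truth$chrom == calls$chrom[j] &
                  truth$pos >= calls$start[j] - margin &
                  truth$pos < calls$end[j] + margin)
    if (length(ti) != 1L) next
    n <- n + 1L
    ok <- ok + (truth$homolog[ti] == calls$homolog[j])
  }
  list(accuracy = if (n) ok / n else NA_real_, n = n)
}
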