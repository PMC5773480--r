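---
title: "Mapping sister chromatid exchanges onto G-quadruplex motifs: methods and design"
author: "sceG4"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sister chromatid exchanges onto G-quadruplex motifs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bloom syndrome (BS) cells, which lack the BLM helicase, display roughly
ten-fold elevated rates of sister chromatid exchange (SCE). Strand-seq —
single-cell sequencing of parental DNA template strands — turns each SCE
into an observable switch of the template-strand state (WW, WC or CC)
along a chromosome, mapping events at kilobase rather than cytogenetic
resolution. With SCEs mapped, the question becomes locational: are they
enriched at G-quadruplex (G4) motifs, in transcribed genes, at fragile
sites? This package implements that analysis chain — strand-state
segmentation and SCE calling, motif scanning, a circular-shift permutation
test in assembly-gap-excluded coordinates, hotspot statistics,
haplotype-resolved concordance testing and copy-neutral LOH calling —
together with a synthetic Strand-seq generator that plants every signal
with known ground truth, so that each stage is testable without any
external data.

# Strand-state segmentation and SCE calling

A diploid chromosome inherits two template strands, giving three
observable states: WW, WC, CC. Each read is a Bernoulli observation with
expected Watson fraction $1-\varepsilon$, $1/2$ or $\varepsilon$ under the
three states, where $\varepsilon$ is the strand-label error rate (default
0.02). `infer_strand_states()` finds the state path maximising the summed
per-read log-likelihood minus a fixed penalty $\lambda$ per state change
(dynamic programming in C++). An SCE is the interval between the last read
of one state and the first read of the next (`call_sces()`); its width is
the mapping resolution.

**The switch penalty.** $\lambda$ is the log prior odds against a switch
at any given inter-read position. A few SCEs among a few thousand read
positions per chromosome gives odds of order $10^{-3}$, hence the default
$\lambda = 7$. A BIC-style $2\log n \approx 17$ is markedly more
conservative and, because a WW or CC island embedded in WC carries only
$\log(0.98/0.5) = 0.67$ of evidence per read, it misses islands shorter
than $\sim 50$ reads ($\sim 350$ kb at default coverage); at $\lambda = 7$
the detection floor is $\sim 21$ reads while the expected number of false
switches per 300-cell dataset stays below $10^{-1}$. Segments supported by
fewer than `min_reads` (default 10) reads are merged into their
better-supported neighbour; chromosomes with fewer than `min_reads` reads
are reported uncallable. WW→CC jumps are emitted as two stacked SCEs with
a warning rather than dropped.

**Boundary bias, not a bug.** Under the mixed WC state every read is
consistent with either flanking pure state, so the maximum-likelihood
changepoint absorbs post-breakpoint reads that happen to carry the
pre-switch label: per event the called region sits a geometric(1/2)
number of inter-read gaps away from the true breakpoint, and a
noise-flipped read within the first
$j = 1+\lfloor\log(0.5/\varepsilon)/\log((1-\varepsilon)/0.5)\rfloor = 5$
reads of the pure side drags the boundary past the breakpoint with
probability $1-(1-\varepsilon)^5 \approx 0.096$. Consequently the called
region contains the true breakpoint with probability
$w_0 = (1-0.096)/2 \approx 0.45$ — a property of maximum-likelihood
changepoints under these emissions, shared by any caller of this type.
Three design choices follow:

* resolution summaries and the enrichment analysis use the *tight* region
  (this is what gives the ~10 kb median resolution);
* the truth-matching oracle used by the recall/precision gates counts a
  planted event as recovered when its breakpoint lies within the called
  region extended by the 99.5% quantile of the displacement,
  $2\ln(100) \approx 9.2$ mean inter-read gaps (~61 kb at default
  coverage);
* the generator's enrichment calibration incorporates $w_0$ (below).

**Recurrence filter.** Stable rearrangements produce a state switch at the
same location in every cell. Regions clustering under reciprocal overlap
(single linkage) in strictly more than 5% of cells are removed. The
default mutual-overlap requirement is 25%: two read-bounded calls of the
same breakpoint have roughly independent exponential sizes, which differ
by more than two-fold about two thirds of the time, so a 50% requirement
fragments true recurrence clusters (measured: 40% of a planted stable
rearrangement's calls survive at 50%, 15% at 25%). Calls displaced off
the shared breakpoint by the boundary bias are not recoverable by any
location-based clustering and a small residue of a stable rearrangement
therefore always survives the filter.

# Motif scanning

Canonical quadruplex motifs are matches of
$G_{3+} N_{1..x} G_{3+} N_{1..x} G_{3+} N_{1..x} G_{3+}$ with loop classes
$x \in \{3, 7, 12\}$. The scanner chains maximal G-runs (length $\ge 3$)
whose inter-run gaps lie within the loop class, with a leftmost-first,
greedy-run, non-overlapping-per-strand convention: after a reported match,
scanning resumes at its end. On a dead end the search backtracks to the
next reachable run, which makes the convention exactly equivalent to a
lazy-loop regular expression — the test suite verifies identity against an
independently written regex oracle on random sequence. Minus-strand motifs
come from scanning the reverse complement and mapping coordinates back;
candidates containing N are rejected; non-ACGTN input is an error naming
the offending position. A-rich control motifs use the same machinery with
A-runs. "High GC" control regions are the top decile of non-overlapping
1 kb windows ranked by GC fraction — the construction is a package choice
(no standard definition exists) and both window size and fraction are
parameters.

Genes are active when FPKM strictly exceeds 1, silent otherwise (FPKM
exactly 1 is silent — the threshold's boundary is otherwise undefined).
Promoters are the 1 kb upstream of the TSS, strand-aware and clipped at
chromosome ends. An intragenic motif on the strand opposite the gene's
annotated strand lies on the transcribed (template) strand. A motif
spanning two gene bodies is assigned to the larger overlap, ties to the
gene with the smaller genomic start.

# The circular-shift permutation test

All coordinates are first mapped into gap-excluded ("gapless") space: a
bijection between non-gap bases and $[0, L_{\mathrm{eff}})$ per
chromosome, so no shifted base can land in an assembly gap. For each of
1,000 permutations one random integer $n \in [2\,\mathrm{Mb},
50\,\mathrm{Mb}]$ shifts *all* SCE regions downstream on their own
chromosomes, wrapping circularly modulo the effective length (regions
wrapping the origin are split into two arcs; per-region gapless length is
conserved — asserted by tests). The statistic is binary per region: the
number of SCE regions overlapping at least one feature by at least one
base. Relative enrichment is the observed count divided by the median
permuted count; the empirical p-value is the fraction of permutations
with overlap at least (enrichment) or at most (depletion) the observed
count, floored at $1/1000$ and reported as "< 0.001" when no permutation
reaches it. Size cutoffs are boundary-inclusive: 10 kb for motif-scale
features (motifs recur every ~8.6 kb, so larger regions overlap one by
chance), 100 kb for gene/promoter-scale features. One shift per
permutation shared by all regions is the default; a per-chromosome-shift
variant is available (`per_chromosome = TRUE`) since the construction is
ambiguous on this point. Whether observed regions should themselves be
gap-filtered is equally open; `drop_gap_regions()` applies that filter
before the test, since a region spanning an assembly gap has no gapless
image. No multiple-testing correction is applied across feature sets —
raw p-values are reported, as is conventional for this permutation
readout. Because the overlap count is integer-valued and ties count as
exceedances, the empirical p is slightly conservative when only a few
dozen regions enter the test; at the region counts of a real line
(hundreds to thousands) the null p-value is uniform to Kolmogorov–Smirnov
precision.

# The synthetic generator and its enrichment calibration

`generate_genome()` builds uniform-random chromosomes (default 3 × 30 Mb),
carves ~2% into N-gaps, plants canonical G4 motifs (runs 3–5 bases, loops
1–7 from A/C/T) at exponential spacings averaging 8.6 kb, keeps 20 bp
flanks G/C-free so every planted motif is recovered by the scanner at its
exact coordinates, and places 600 non-overlapping genes (lognormal bodies
5–150 kb, ~20% genome coverage) of which 60% are transcribed. The gene
complement is deliberately sized so that transcribed gene bodies cover a
realistic fraction of the genome: if active genes covered only a few
percent, motif-seeded SCEs would concentrate there, close opposite-homolog
pairs would fall under the segment floor of the caller and seeded events
would be destroyed selectively.

`simulate_cells()` draws each chromosome's initial state uniformly from
{WW, WC, CC}, plants Poisson SCEs (default mean 8 per cell — chosen so a
300-cell line yields a few thousand events, the scale of a BS line),
toggles one homolog per SCE, and samples reads as a homogeneous Poisson
process over non-gap bases (default coverage 1.5% of the genome per cell,
100 b reads), flipping each label with probability 0.02. Neither the
read-level noise rate nor the inter-read gap law is reported for the real
assay; both are calibration choices here — the homogeneous Poisson model
is the simplest consistent with "a few percent coverage", and a small
symmetric label noise is what the caller must tolerate.

**What `g4_enrichment_factor` means.** The factor is defined at the level
of the readout the permutation test produces: with factor $f$, the
expected relative enrichment of called SCE regions (after the 10 kb
cutoff) at the canonical-G4 feature set is $f$. A base-level definition —
multiplying the probability mass of breakpoint placement at G4 bases by
$f$ — cannot produce a region-level enrichment of $f$: G4 bases are ~0.4%
of the genome while kilobase regions already overlap a motif ~40% of the
time by chance, so a 1.2× base-level excess would change the overlap
count by ~0.1%. The generator therefore solves for the seeding mixture
weight $p$ (probability that a breakpoint is placed inside a G4 motif in
an active gene) that yields relative enrichment $f$:

$$p = (f-1)\,\frac{w_0\pi_2 A + (1-w_0)\pi_1 B}{w_0\pi_2(1-A)},$$

where $\pi_2, \pi_1$ are the cutoff-survival probabilities of
breakpoint-containing gaps (size-biased Gamma(2, $\lambda$), $\lambda$ =
reads per base) and displaced ordinary gaps (Exp($\lambda$)), $A, B$ the
corresponding truncated-mean chance overlap probabilities under a Poisson
motif field, and $w_0$ the containment probability from the boundary-bias
model above (`sce_seed_probability()` documents the full derivation).
Measured containment of seeded motifs in called regions matches this
model to two decimals. Because the binary statistic saturates, not every
$f$ is representable at every coverage: at 1.5% coverage and the 10 kb
cutoff the maximum is $f \approx 1.4$; requesting more is an error that
reports the achievable maximum. Properties that exercise factors up to
2.0 therefore run at 5% coverage, where the whole range is representable.

The F1-hybrid mode adds a second haplotype: heterozygous SNPs at the
specified rate (default 0.008/base, the density of a 129Sv × Cast/EiJ
hybrid) with haplotype B carrying the alternative allele; a chosen
fraction of planted motifs is made allele-specific by substituting the
centre of every G-run on one haplotype (SNP-only model — indels and
structural differences are out of scope); reads covering at least one SNP
carry their homolog's tag. SCEs can be seeded at allele-specific motifs,
landing on the motif-carrying homolog with a tunable concordance rate;
copy-neutral LOH segments force both read copies onto the retained
haplotype without changing coverage, and trisomies multiply a chromosome's
read density by 1.5.

# Homolog assignment, concordance, hotspots, LOH

`assign_homolog()` re-runs two-state (template W vs C) inference on each
haplotype's tagged reads in a ±2 Mb window around the SCE; the homolog
whose reads switch is assigned, and events where neither or both switch
stay uninformative. The window default reflects the tagged-read density
(roughly a quarter of reads at default SNP rate): a switch needs several
reads of evidence on each side.

`concordance_test()` restricts to informative SCEs — homolog assigned and
overlapping exactly one allele-specific G4 — and tests the concordant
fraction against the 50% null with a binomial tail, one-sided by default
(the direction of interest is excess concordance); a two-sided variant
doubles the smaller tail. The estimate is diluted toward 1/2 by events
whose called region drifted off the seeded motif and by incidental
single-motif overlaps, so parameter-recovery tests compare the estimate
with the truth-derived expectation for the same informative set rather
than with the seeded rate itself.

`detect_hotspots()` reports maximal loci covered by SCE regions from at
least three distinct cells; the reported interval is the intersection of
the contributing regions. Hotspots and the recurrence filter interact:
any location clustering tight enough to catch stable rearrangements also
flags a locus recurring in more than the removal threshold (5%) of
cells, so hotspots are only separable from rearrangements below that
rate — which is where the reported fragile-site hotspots mostly sit
(2–9% of libraries, with the filter's exact-location matching presumably
stricter than read-resolution clustering for the few above 5%). `hotspot_pvalue()` is the binomial bin
probability: divide the effective genome into bins of the hotspot's size
and compute $P(X \ge k)$, $X \sim \mathrm{Bin}(\text{total SCEs},
\text{len}/L_{\mathrm{eff}})$ (a Poisson tail is available). Because
candidates are selected by scanning for maximal overlaps and then scored
on the same data, the raw p-value is anti-conservative for the smallest
intersections even after a Bonferroni factor over bins — the p-values
should be read as ranking scores, not calibrated error rates. Event-level
counting is the default; library-level counting is an option.

`call_loh()` scans binned haplotype read counts for runs of at least
`min_bins` (default 3 × 1 Mb) bins in which one haplotype holds at least
95% of informative reads, and reports them only where the copy state is
diploid — `naive_ploidy()` classifies each (cell, chromosome) from total
read density relative to the per-cell median, with thresholds at 1.25×
(trisomy) and 0.75× (monosomy). This deliberately simple density ratio
exists to keep deletions out of the LOH calls, not to be a CNV caller;
bin width and purity are parameters since no reference values exist for
them.

# Problem sizes and what the tests show

The bundled experiments run at a deliberately desk-sized scale: 90 Mb
genomes, 150–500 cells, 400–1,000 permutations, ten replicates for the
enrichment-recovery experiment. At that scale the planted 1.2× excess is
recovered as a median relative enrichment within a few percentage points
of 20%, the caller's recall and precision against planted truth exceed
95%, the permutation test's type-I error at $\alpha = 0.05$ sits within
[0.03, 0.07] under the uniform null, and planted enrichments of 1.0×,
1.2×, 1.5× and 2.0× order correctly. What passing these tests shows is
that the *statistical machinery* is correct and calibrated under the
generator's assumptions — homogeneous coverage, symmetric label noise,
SNP-only haplotype differences, uniform random base composition. Real
Strand-seq libraries violate several of these (GC-dependent coverage,
chimeric reads, uneven BrdU incorporation, motif clustering in GC-rich
isochores), so synthetic recovery rates are not a performance claim for
real data; they bound what the method can do when its own assumptions
hold.

# Known limitations

* The scanner targets canonical G4 motifs only — no bulged or
  two-quartet variants, no thermodynamic stability scoring.
* The segmentation assumes a shared error rate $\varepsilon$ across
  cells and no position-dependent coverage bias.
* The hotspot p-value inherits the scan-then-test selection bias
  described above.
* The LOH caller reports bin-resolution boundaries and assumes the
  SNP-only haplotype model.
* Relative enrichments are attenuated readouts: because kilobase regions
  overlap frequent motifs by chance, the region-level excess understates
  the base-level association strength by an order of magnitude — the
  saturation analysis in `sce_seed_probability()` quantifies exactly how.
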