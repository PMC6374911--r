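---
title: "Models and methods behind methdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdyn)
library(dplyr)
```

methdyn analyses DNA methylation dynamics from whole-genome bisulfite
sequencing (WGBS) count data: it calls differentially methylated sites
(DMSs) and regions (DMRs) between two methylomes, measures how those
calls distribute over genomic annotation, profiles methylation around
anchors and along genes, groups differential sites into co-methylation
modules across a panel of methylomes, and tests transcription-factor
motif enrichment in the module sequences. This vignette explains the
statistical models, the tunable parameters, and the design decisions
made where the choices were genuinely open. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` compute.

## Data model and coordinate conventions

A *methylome* is a tibble of per-cytosine records: chromosome, 1-based
position, strand, context (CpG / CHG / CHH), and methylated /
unmethylated read counts, the layout of a Bismark-style per-cytosine
report. A record with zero total coverage is *missing* — no level is
observed — which is distinct from an observed level of 0. All interval
tables (compartments, enhancers, DMRs, gene spans) are BED-style,
0-based and half-open; a 1-based cytosine at position $p$ lies in
$[s, e)$ iff $s < p \le e$. `pos_in_interval()` is the single place
this conversion is defined, and it is tested exhaustively on a 100 bp
toy genome.

CpG methylation is symmetric across the dyad, so CpG analysis operates
on dyad-merged plus-strand sites: `merge_symmetric_cpg()` sums the
plus-strand C at $p$ with the minus-strand C at $p+1$. CH methylation
is not symmetric and stays stranded. Gene models store TSS and TES in
transcription order (for a minus-strand gene the TSS is the larger
genomic coordinate), which makes windows like "10 kb upstream of the
TSS" unambiguous.

## Differential methylation sites

For every CpG covered by at least `min_cov` reads (default 10, applied
in *both* samples) the two methylomes form a 2x2 table of methylated
versus unmethylated counts. The two-sided Fisher exact p-value is
computed from the hypergeometric pmf with fixed margins: the sum of
probabilities of all tables at most as probable as the observed one,
with a relative tie tolerance of 1e-7 (the dominant convention, and the
one the reference implementation in `stats::fisher.test()` uses — the
test suite checks agreement exhaustively for all tables with total
$\le 30$).

False-discovery control is adaptive. The number of true null
hypotheses $m_0$ is estimated by a histogram method: with $B$
equal-width bins of the p-values (default $B = 20$), find the smallest
bin $i$ whose count does not exceed the mean count of bins $i..B$, and
set $m_0 = \frac{B}{B-i+1}\sum_{j \ge i} c_j$, capped at $m$. Uniform
p-values give $m_0 \approx m$; a 90/10 null/alternative mixture gives
$m_0/m \approx 0.9$. The adjusted p-value is the step-up quantity
$\min_{p_{(j)} \ge p_{(i)}} \min(1, m_0\, p_{(j)}/j)$; with $m_0 = m$
this is exactly Benjamini–Hochberg, which the tests verify against
`stats::p.adjust()`. Sites with adjusted $p \le 0.05$ are DMSs.

A sequential permutation route is provided as a cross-check of the
exact path (`fdr = "permutation"`). The permutation null redraws the
table from the hypergeometric distribution with the observed margins —
equivalent to permuting read labels without storing reads — and the
statistic is the exact-test p-value. Sampling stops early once $h = 10$
permuted statistics at or below the observed one have accumulated
(Besag–Clifford rule), reporting $h/n$; otherwise after the cap of
1000 draws it reports $(\text{exceedances}+1)/1001$. Because the exact
p-value is available, the permutation adds calibration rather than
information, so the exact path is the default. Note the early-stopped
estimator has coefficient of variation $\approx 1/\sqrt{h}$, which the
property tests account for.

Observed levels are classified hypermethylated at $\ge 0.8$ and
hypomethylated at $\le 0.2$.

## Differential methylation regions

DMRs form in two steps. First, adjacent DMSs at most `max_gap = 500` bp
apart chain into candidate clusters (single linkage; a gap of exactly
500 bp still chains, and clusters never span chromosomes). Second, a
cluster survives iff (i) it holds at least `min_dms` DMSs, (ii) at
least 80% of its DMSs change in the majority direction, and (iii) at
least 80% of *all* covered CpGs in the cluster hull change by at least
0.1 in that direction. Three choices deserve comment:

* `min_dms` defaults to 5, the headline definition; 4 is supported as a
  documented alternative because both counts circulate for this rule
  set.
* The "500 bp window" is implemented as an inter-DMS gap bound, not a
  fixed sliding window — the operational reading of the merge rule.
* Criterion (iii)'s denominator counts only CpGs with an observed level
  in both samples: a delta is undefined otherwise. An exact 50/50
  direction tie can never reach 80% and is rejected.

Genes are associated with DMRs when a DMR overlaps the gene body or the
strand-aware 10 kb window upstream of the TSS; promoter overlap uses
the 2 kb window ending at the TSS, optionally filtered by DMR
direction.

## Enrichment statistics

Compartment enrichment builds, per labelled interval set, the 2x2 table
of foreground/background sites inside/outside the compartment and
reports the odds ratio $ad/bc$ and the two-sided Fisher p. The
background is the set of all tested (coverage-filtered) CpGs minus the
foreground, which removes coverage as a confounder. A site overlapping
several compartments counts in each. BH-adjusted q-values are reported
across labels alongside the raw p.

Cell-type-specific sites come from all pairwise DMS comparisons within
a methylome panel, each run with its own FDR calibration. A site is
hyper-specific for type T when it is a significant DMS with T-higher
methylation in at least 75% of the pairwise comparisons involving T in
which the site was testable (3 of 4 in a five-type panel; untestable
comparisons drop out of the denominator). DMR enrichment on these sites
uses the entire pool of cell-type-specific sites as the control and
reports both the fold enrichment (hit-rate ratio against the pool) and
a Fisher test of the set against the rest of the pool, since either
statistic may be wanted.

TF-binding-site enrichment of DMSs is a binomial test: the null hit
probability is the fraction of control CpGs (covered but not
differential) inside the TF intervals, and the p-value is the upper
binomial tail of the DMS hit count. A degenerate zero background rate
is floored at $1/(2 n_{\mathrm{control}})$.

## Metaprofiles

`anchored_methylation_profile()` bins sites by signed offset from
anchor centres (default +-5 kb in 50 bins of 100 bp; the axis span is a
display choice, exposed as configuration) and reports the per-bin mean
site level with its SEM — site-level averaging, because an SEM band is
defined over sites. `dms_frequency_profile()` reports, per bin, the DMS
fraction among tested sites divided by the genome-wide fraction, so a
uniform scatter normalises to 1. `scaled_gene_profile()` rescales each
gene body to a fixed number of bins between TSS and TES (strand-aware,
TSS always left) with absolute-coordinate flanks, and uses
read-weighted bin levels ($\sum \mathrm{meth} / \sum \mathrm{cov}$),
the appropriate summary for pooled counts; CH profiles combine both
strands relative to gene orientation. Expression grouping splits genes
at a TPM threshold (default 1.0, a conventional not-expressed cutoff)
and then into terciles by rank, ties broken by gene id and remainders
assigned to the lower groups (301 expressed genes give 101/100/100). A
fold-change utility keeps genes with
$|\log((b+pc)/(a+pc))| \ge \log 1.5$; the default pseudocount of 1
stabilises low counts but moves a 10-vs-15 boundary case below
threshold, so the boundary is only exact as the pseudocount approaches
0.

## Co-methylation modules

Module discovery follows the weighted-correlation-network recipe in a
transparent reimplementation. Preprocessing keeps DMSs inside the
TSS−10 kb..TES window of at least one gene, chain-merges loci within
200 bp (merged level = coverage-weighted mean per methylome), and drops
loci missing in any methylome, logging the count after each step. The
unsigned adjacency is $|\mathrm{cor}|^\beta$ with soft threshold
$\beta = 6$; the topological overlap matrix is

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}},$$

verified against a brute-force triple loop to 1e-10. Modules come from
average-linkage clustering on $1-\mathrm{TOM}$ with a static cut at
0.75; clusters below 30 loci stay unassigned (label 0). A module's
eigen-profile is the first right singular vector of its row-standardised
level matrix, sign-oriented to follow the module mean. Modules whose
eigen-profiles correlate at $\ge 0.75$ merge iteratively (largest
correlation first, ties to smaller ids). The canonical network defaults
are used because no parameters were otherwise fixed; all are exposed.
Dynamic tree cutting is deliberately not reimplemented — the static cut
is a documented simplification. For large inputs an optional blockwise
mode pre-partitions loci by k-means (seeded deterministically along the
first principal component) and merges modules across blocks; the
clustering itself uses no randomness, so identical inputs give
identical assignments.

## Motif enrichment

Known-motif testing mirrors the flank-background design: for each
target region of width $w$, two same-width background regions are taken
at $\pm(2\,\mathrm{kb} + w)$ so each sits 2 kb away, doubling the
target count; regions off-chromosome or overlapping any target are
dropped and counted. PWMs (JASPAR PFM text) are scanned by log2-odds
against the background base frequencies with a per-cell pseudocount of
0.01, on both strands; `N` contributes zero. A sequence is a hit when
its best score reaches 80% of the maximum achievable score — a
conventional proportional threshold, exposed as configuration since hit
definitions vary between scanners. Enrichment is the upper binomial
tail of the target hit count at the background hit rate, significant at
1e-10. Per-module reports extend module loci to a fixed 200 bp around
their centres and group motifs into families by the letter prefix of
the motif id.

## The synthetic-data generator

The generator exists so every pipeline stage can be validated against
known truth; its defaults are the package's study conditions.

* **Genome**: random sequence with incidental CG dyads removed and CG
  planted at `cpg_density` (default 0.01/bp), so the CpG map is exact.
* **Baseline levels**: a bimodal Beta mixture — 70% Beta(30, 2), 25%
  Beta(2, 30), 5% Beta(2, 2) — placing most mass near 0 and 1 with
  under 10% at intermediate levels, the shape bulk CpG methylomes show.
* **Reads**: per-strand coverage is negative binomial (mean 20, size
  5) and methylated counts are binomial at the true level — a
  beta-binomial observation model whose level dispersion comes from the
  Beta baseline. CpG records are emitted *stranded*, as a per-cytosine
  report would be, and analysis merges the dyads; the merged per-CpG
  coverage is therefore about twice the per-strand mean.
* **Spiked DMRs**: non-overlapping windows (default 20 windows of 1 kb
  holding at least 10 CpGs, separated by at least 2 kb so neighbouring
  truth regions stay resolvable by the 500 bp gap rule) in which
  condition B shifts by `dmr_delta` (default 0.3), clipped to [0, 1].
  Hyper shifts are seeded on hypomethylated baseline and hypo shifts on
  hypermethylated baseline so the contrast survives clipping — the
  ground truth is detectable by construction, which is the point of a
  spike-in.
* **Cell-type panel**: five methylomes sharing the baseline except at
  designated sites where one type is shifted by `celltype_delta`
  (default 0.4) against all others; a configurable fraction of entries
  is masked as missing.
* **Motifs / expression**: consensus motif instances embedded at
  chosen rates; zero-inflated lognormal TPM tables with recoverable
  tercile structure.

Every generator is a pure function of its configuration and seed.

What the generator does *not* emulate: read-level artefacts (incomplete
bisulfite conversion, mapping bias, PCR duplicates), spatial
autocorrelation of methylation outside the spiked regions, realistic
chromatin-driven CpG clustering (CpG islands), and biological
covariance between compartments and methylation. Passing tests
therefore demonstrate that the statistical machinery is correct and
well calibrated under its assumed sampling model, not that the pipeline
is robust to upstream artefacts in real libraries.

## Validation scenarios and problem sizes

The test suite and `scripts/acceptance.R` use desk-scale designs chosen
once: a 5 Mb null genome (~50,000 tested CpGs) for false-discovery
calibration; a 100 kb, ~1,000-CpG chromosome carrying the 20 spiked
regions for DMR recovery, where roughly a fifth of sites are truly
differential — a deliberately signal-dense spike-in, sized so region
recovery measures the rule set rather than raw per-site power; a 200 kb
genome with 60 designated sites per type and direction for the
cell-type rule; 200-locus, 20-methylome matrices for module recovery;
and 200 target / 400 background sequences of 200 bp for motif
enrichment. Numerical tolerances follow the oracles: exact enumeration
to 1e-7 relative (the tie tolerance), TOM to 1e-10, Monte-Carlo
quantities to bounds derived from their sampling variance.

## Known limitations

* The DMR caller is rule-based, by design; it does not smooth, shrink
  dispersions, or re-test regions, so single-CpG resolution depends
  entirely on per-site power.
* CH-context differential testing is out of scope (profiling only).
* The static tree cut can split one gradient-structured module where
  dynamic cutting would not.
* The PWM scanner's proportional score threshold is not calibrated to a
  sequence-composition null; enrichment conclusions should rest on the
  target-versus-flank contrast, which shares the composition.
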