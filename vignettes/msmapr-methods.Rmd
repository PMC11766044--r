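---
title: "Mapping a recessive male-sterility locus and its lipidome deficit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive male-sterility locus and its lipidome deficit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmapr)
```

This vignette explains the models behind each stage of the package, the
parameters that matter and their defaults, what the synthetic-data
generators emulate (and what they do not), and the numerical and design
choices made where conventions were genuinely open.

## The genetic model

All mapping stages assume a single recessive nuclear locus: an F2 plant is
male-sterile iff it is homozygous for the mutant-parent allele (`M/M`) at
the causal site. A chi-square goodness-of-fit test against the 3:1
fertile:sterile expectation (`chi_square_segregation()`) checks that
assumption on progeny counts; the allelism test (`allelism_test()`) checks
a 1:1 ratio in the progeny of a homozygous-mutant × heterozygous-carrier
cross, the classical design for asking whether two recessive mutations hit
the same gene. Both use the uncorrected statistic `sum((O − E)^2 / E)`
with one degree of freedom, so the 5% cutoff is `qchisq(0.95, 1) = 3.841`.
No Yates continuity correction is applied: the conventional printed
df = 1 cutoff refers to the uncorrected statistic, and at the progeny
sizes involved (hundreds of plants) the correction is immaterial. A
simulation test in the suite confirms the test holds its nominal 5% size
at that cutoff for n = 712 progeny.

## Bulked-segregant association: ED^5, LOESS, median + 3 SD

At each segregating locus the two bulks (pooled sterile plants, pooled
fertile plants) yield read counts over the four bases. With frequencies
`f_mut` and `f_wt` (4-vectors summing to 1), the association statistic is
the Euclidean distance

```
ED = sqrt( sum_b (f_mut,b − f_wt,b)^2 ),   0 <= ED <= sqrt(2),
```

computed over all four bases rather than a biallelic difference — the
pipeline counts per-base depths, and the biallelic case is recovered as a
special case. ED is raised to the 5th power (`power = 5`) to shrink
background noise relative to linked signal, the fitted curve is a LOESS of
ED^5 against position, and the genome-wide threshold is
`median(fitted) + 3 * sd(fitted)` with the sample (n − 1) SD. Runs of
consecutive loci with fitted values at or above the threshold become
candidate intervals; by default runs are not merged across below-threshold
gaps (`min_gap_loci = 0`, conservative since a clean single-locus signal
yields one region).

At the causal locus itself the expected frequencies are instructive: the
sterile bulk is fixed for the mutant allele (frequency 1), while the
fertile bulk — selected purely by phenotype, hence a 2:1 mix of
heterozygotes and homozygous-reference plants — has expected mutant-allele
frequency 1/3, giving `ED = sqrt((2/3)^2 + (2/3)^2) = 0.943` at infinite
depth, not the `sqrt(0.5)` that a naive 1-vs-0.5 contrast would suggest.
The test suite asserts the 0.943 value by simulation at depth 10,000.

### LOESS details

`loess_fit()` implements local linear regression directly, because the
smoother's exact behaviour is part of the method: for each locus the
window is its `q = max(3, ceiling(span * n))` nearest neighbours by
position (contiguous in sorted order, found with an amortized two-pointer
scan), weights are tricube `w = (1 − (d/d_max)^3)^3` with `d_max` the
largest distance in the window, and the fit is the closed-form weighted
linear regression evaluated at the locus. One pass is used (no robustness
reweighting). Degenerate windows (all weight on one position) fall back to
the weighted mean, and chromosomes with fewer than three informative loci
fall back to the chromosome mean, with a message. The default
`span = 0.1` is applied per chromosome — positions are only comparable
within a chromosome — and the test suite requires agreement with an
independently coded brute-force weighted-least-squares oracle to 1e-8.

### Filtering

The only locus filter is depth: a locus is informative when both bulks
carry at least `min_depth = 4` reads. Real pipelines apply additional
"high quality" variant filters upstream; depth is the minimal faithful
stand-in and is exposed as a parameter. Zero-depth and shallow loci are
excluded from ED/LOESS and reported via a message.

### Intervals and genes

All coordinates are 1-based inclusive. Interval width is `end − start`
(the distance between the first and last locus of the run). Gene
extraction (`genes_in_interval()`) parses GFF3 through `rtracklayer` and
uses inclusive overlap: a gene ending exactly at the interval start, or
starting exactly at its end, is counted. BED export converts to 0-based
half-open coordinates.

## Fine mapping with recombinants

`refine_interval()` partitions the mapped chromosome into bins — each
marker position and each inter-marker gap. For a sterile plant, a marker
bin is feasible iff its genotype there is `M` (or missing, `?`, treated as
an uninformative wildcard); a gap bin is feasible iff at least one
flanking marker is `M`/`?`. The gap rule encodes the standard assumption
of at most one crossover per inter-marker gap; with double crossovers
inside a gap nothing could be inferred from flanking markers at all. The
candidate region is the intersection of feasible bins over sterile plants,
reported with exclusive flanking markers (the innermost markers bounding
the region) and the flank-to-flank width in bp.

Fertile plants never shrink the interval: under phenotype-only selection a
fertile plant may be `M/H` or `H/H` across the region, so only sterile
plants are fully informative for a recessive locus. Fertile plants that
are `M` at every marker inside the final interval are reported as
potential double recombinants (or phenotyping errors). An empty
intersection produces an inconsistency report naming sterile plant pairs
with no common feasible bin — the signature of phenotyping/genotyping
error or two-locus genetics.

The shipped example table (`inst/extdata/finemap_*.tsv`) is a synthetic
four-recombinant fixture whose flanking markers are 112 kb apart; it
illustrates the typical endpoint of such a mapping exercise and doubles as
a regression fixture. An enumeration oracle (checking every bin against
every sterile plant naively) must agree exactly with the implementation on
1,000 random tables in the acceptance suite. Interval width is monotone —
more markers or more sterile recombinants can only shrink it — for
single-`M`-run genotype vectors; revealed `?` wildcards or double
recombinants can legitimately widen it, which is why the monotonicity
property test generates single-run tables.

## Transposon-insertion characterization

`detect_insertion()` compares a WT/mutant allele pair via the longest
common prefix `P` and suffix `S`. A clean insertion requires
`P + S >= nchar(wt)`; the insertion is placed at the end of the common
prefix (`pos = P`, insert = `mut[(P+1)..(P+L)]`). When flanking repeats
make several placements equivalent the full valid range is recorded in the
report, so downstream consumers can be convention-agnostic; the prefix
placement was chosen because it makes the report's reconstruction
invariant (`wt[1..pos] + insert + wt[(pos+1)..] == mut`) direct, and it is
deterministic.

A cut-and-paste transposon duplicates its target site: the simulator
builds `mut = wt[1..pos] + TE + TSD + wt[(pos+1)..]` with
`TSD = wt[(pos−k+1)..pos]`, i.e. the element sits between two copies of
the k-bp target site (the 5' copy being the original flank).
`find_tsd()` inverts this: the largest `k <= max_tsd` (default 12,
spanning the hAT family's typical 8 bp) such that the k bases 5' of the
insert equal the insert's last k bases. A duplication inside a
single-base homopolymer run has no unique length and is flagged
ambiguous. `find_tir()` reports the longest arm `L >= min_len` (default
5, capped at half the element) whose 5' arm and reverse-complemented 3'
arm disagree at no more than `floor(max_mismatch_frac * L)` positions.

Two identifiability choices in the simulator are worth spelling out.
First, the element's terminal bases are drawn to differ from the adjacent
host bases, and the base pair just inside the declared TIR is drawn
non-complementary; without this, about a quarter of random draws admit
shifted placements or longer apparent TSDs/TIRs, and "the" insertion
position, TSD and TIR lengths of a simulated allele would not be
well-defined truth values. Second, exact round-trip recovery of an
`L`-bp TIR is only meaningful at `max_mismatch_frac = 0`: at the default
0.1 tolerance, an 11-bp exact TIR is indistinguishable from a 12-bp TIR
with one mismatch (`floor(0.1 × 12) = 1`), so the round-trip tests run
the TIR search with zero tolerance on the error-free simulated sequences.
The mismatch tolerance exists for real, diverged elements.

The default simulated element is 548 bp with an 8-bp TSD and 11-bp TIRs —
an hAT/Ac-like geometry — so the mutant allele is 556 bp longer than WT.

## Restriction-site genotyping

`find_iupac_sites()` expands an IUPAC motif (e.g. Ban I, `GGYRCC`) into
per-position base classes and reports all (overlapping) forward-strand
matches; an `N` in the sequence never matches. Only the forward strand is
searched: Ban I's recognition site is its own reverse complement under
IUPAC, so forward search is lossless for the genotyping assay this
supports, and the limitation is documented for other motifs.
`digestion_fragments()` cuts `cut_offset` bases into each site (Ban I:
offset 1, `G^GYRCC`) and always returns fragments partitioning the
sequence.

## Lipidomics

The lipid dataset is a long tidy table: species × sample intensities with
a two-group design (mutant vs WT, ≥2 replicates each; the default design
is 4 + 4). Lipid shorthand `SUBCLASS(C:D)` is parsed into subclass, total
acyl carbons and double-bond count; unparseable names are retained for all
intensity statistics and excluded only from chain-length/saturation
profiles.

* **Totals.** `total_content()` sums all species over all replicates per
  group and reports `100 × total_mutant / total_WT` (equal to the
  mean-based ratio with equal replicate counts, asserted in tests).
* **Subclass tests.** Per-replicate subclass sums compared by a Welch
  t-test. Welch was chosen over the classical pooled test (and over
  one-way ANOVA, which with two groups is the pooled t-test) as the safer
  default; `pooled = TRUE` restores the classical behaviour. Tests run on
  raw intensities by default to mirror intensity-scale group comparisons;
  `log_transform` switches to log10. Degenerate inputs follow a
  documented rule: both groups constant and equal → p = 1, constant and
  different → p = 0 with a `degenerate` flag.
* **PLS-DA / VIP.** The two-class partial-least-squares fit is implemented
  directly (NIPALS for a single response: `w = X'y/|X'y|`, `t = Xw`,
  deflation of X, response variance `SSY_a = q_a² t_a't_a`), on autoscaled
  species with the class coded ±1. VIP is
  `VIP_j = sqrt(J Σ_a SSY_a (w_aj/‖w_a‖)² / Σ_a SSY_a)`; mean squared VIP
  is 1 by construction (`Σ_j VIP_j² = J`), which the tests assert on every
  fit, alongside 1e-8 agreement with an explicit-deflation oracle and a
  latent-space cross-check against mixOmics. Two components and
  autoscaling are the de facto metabolomics defaults; both are exposed.
  Zero-variance species are removed (VIP 0, warned), and component counts
  beyond the data's rank are truncated with a warning.
* **Differential species.** The joint screen `VIP > 1 & p < 0.05` on raw
  p-values, the conventional metabolomics rule; direction is the sign of
  the mutant/WT fold-change, so up + down always partitions the set. No
  multiple-testing correction is applied by default (the screen is a raw-p
  rule); `fdr = TRUE` adds Benjamini–Hochberg.
* **Profiles and clustering.** Chain-length and saturation profiles bin
  parseable species of the subclasses of interest (default PE, PC, DG,
  MGDG — the dominant membrane classes) by carbons and by double bonds,
  testing per bin. The heatmap helper z-scores each species row
  (zero-variance rows become zero rows, flagged) and clusters with
  Euclidean distance and average linkage via `stats::hclust`.

## What the generators emulate — and what they do not

`simulate_f2()` draws each plant as two independent gametes with
Poisson-process crossovers and no interference (Haldane), so the
recombination fraction between loci at distance d bp is
`(1 − exp(−2 r d))/2`; the default `r = 1.6e-8` crossovers/bp/meiosis
matches the maize genome-wide average of roughly 1.6 cM/Mb, on a
ten-chromosome genome with B73-like lengths and 2,000 loci per chromosome.
The causal position is always included among the simulated loci (the
causal variant is itself observable in RNA-seq data).
`sample_bulk_counts()` draws Poisson read depth per locus per bulk
(mean 30 by default), bulk allele frequencies as the mean allele dosage of
the 50 sampled plants per bulk, and base miscalls uniformly over the other
three bases at rate 0.01. The fertile bulk is drawn from all
phenotypically fertile plants (heterozygotes and homozygous B73 mixed 2:1
in expectation), matching phenotype-based selection. Each bulk is emitted
as one merged pool; designs that pool replicate RNA samples per bulk
converge to the same allele-count table, so replicate structure below the
pool is not modelled.

The lipidome generator assigns every species a log2-normal baseline and
adds the subclass log2 fold-change to the mutant group; `noise_sigma`
(default 0.3) is the SD of log2 intensity, coherent with effects stated
as log2 fold-changes. The default subclass table has 49 subclasses and
1,088 species with 15 down-regulated subclasses (the four dominant ones,
PE/PC/DG/MGDG, at log2FC −1.5; eleven minor ones at −1), 4 up-regulated
at +1, and 30 unchanged — the scale and direction mix of a real tassel
lipidome experiment.

Passing tests on these generators show that the statistics recover the
structure they assume: crossovers without interference, independent
log-normal species noise, Poisson depth, honest phenotyping. They do not
show robustness to features of real data the generators omit — expression
variation and allele-specific expression in RNA-seq pools, linkage
disequilibrium from population structure, correlated lipid species within
pathways, batch and drift effects in MS intensities, or mis-phenotyped
plants. The fine-mapping inconsistency report and the double-recombinant
flag are the only places where such violations surface explicitly.

## Problem sizes and determinism

The recovery checks use the full default design: 100 seeded runs of the
10 × 2,000-locus genome with an F2 of 700 (about 2.5 s per run), 1,000
random recombinant tables against the fine-mapping oracle, 200 lipidome
seeds for subclass direction and 20 for the species-level screen, and
10,000 progeny draws for the chi-square calibration. Every generator
takes an explicit seed and restores the caller's RNG state; bulk counts
use a sub-seed (`seed + 1`) so the population and the reads come from
distinct deterministic streams. `run_pipeline()` writes a config hash and
seed into its run report, and reruns of the same configuration are
bit-identical.

## Known limitations

* The association stage models a single causal locus; two-locus sterility
  would dilute the ED signal and is flagged only downstream, by the
  fine-mapping inconsistency report.
* LOESS is fitted per chromosome with a fixed span; very sparse
  chromosomes fall back to coarse fits (mean below 3 loci).
* The IUPAC search is forward-strand only (lossless for palindromic sites
  such as Ban I's).
* PLS-DA is the two-class, single-response variant; multi-class designs
  are out of scope.
* Welch tests on 4 + 4 replicates have limited power for subtle
  (|log2FC| < 0.5) effects; the acceptance characteristics quoted in the
  test suite are for |log2FC| ≥ 1.
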