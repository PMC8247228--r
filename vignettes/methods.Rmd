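---
title: "Methods: within-host probiotic evolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-host probiotic evolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gutevolve)
```

`gutevolve` analyses the within-host adaptive evolution of a clonal
bacterial strain — a probiotic passing through the gut of one or more
host species — from multi-isolate whole-genome resequencing, and the
evolutionary response of the resident microbiome from shotgun
metagenomic summaries. This vignette explains the models and the
decisions behind every stage.

## The SNP filter cascade

The unit of evidence is a *cell*: one isolate's stranded base counts at
one genomic site, plus an opaque site-quality score. Quality follows the
bcftools-FQ convention — **lower is stronger variant evidence** — and a
cell passes at quality strictly below 60. The other cell filters are at
least 7 reads on the forward strand *and* 7 on the reverse (guards
against strand artefacts), and a major-allele frequency of at least 90%
(isolates are clonal colonies; intermediate frequencies signal
contamination or mismapping). An exact 50/50 tie has no majority allele
and can never reach 90%, so tied cells are uncallable by construction.

A candidate site is then retained only if

1. at least one pair of isolates with passing calls disagrees on the
   called base (a fixed difference between isolates, the definition of a
   segregating SNP in a clonal population);
2. the median total coverage across isolates is at least 10 reads, with
   missing isolates contributing zero (a site most isolates cannot see
   is untrustworthy); and
3. the fraction of isolates failing the cell filters is strictly below
   1/3, compared in exact rationals (`3 * n_fail < n_isolates`) so the
   printed closed bound "33% or more fail → discard" has no
   floating-point boundary ambiguity.

The quality rule is applied **per isolate-site cell**, not per site: the
pass condition is attached to each member of the discordant pair. Failing
isolates become `ambiguous` in the genotype matrix rather than being
guessed; every downstream statistic (distances, dMRCA, trajectories)
excludes ambiguous calls from both numerator and denominator. Retained
sites are treated as bi-allelic: the alternate allele is the most common
non-ancestral allele among passing calls, and any further alleles are
recorded in the audit log and called ambiguous. The audit log keeps one
row per input site with the rejection reasons, so a filtering decision is
never silent.

The cascade is deliberately order-independent — sites and isolates can
be presented in any order — and the test suite checks it against a
literal brute-force enumeration of the rules on randomized matrices
(200 matrices of 8 isolates × 12 sites in the acceptance suite).

## Coding effects and the mutation spectrum

Coding effects use the standard genetic code on the annotated gene
containing the SNP, respecting strand; amino-acid changes are reported
as `X<pos>Y` with a 1-based protein position. A SNP overlapping two
annotations is annotated against the first gene in coordinate order (a
deterministic choice, logged); a gene whose length is not a multiple of
three yields a warning and an `ambiguous` effect rather than a guess.

Substitutions fall into the six strand-symmetric classes
(A:T→G:C, G:C→A:T, A:T→C:G, G:C→T:A, A:T→T:A, G:C→C:G); a substitution
and its reverse complement are the same event read from opposite
strands, so the 12 ordered base pairs partition exactly two-per-class.
The spectrum is exposed under two weightings, because they answer
different questions and can rank classes differently: `per_snp` counts
each confirmed SNP once (a mutational-input view), `per_isolate` weights
each SNP by the number of isolates carrying it (an abundance view, which
amplifies classes that hitch-hiked on successful sublineages). Both are
reported with mean and standard deviation across host species; neither
ranking is asserted as canonical.

## dMRCA

For a set of isolates from one time point, the distance to their most
recent common ancestor is estimated as: restrict to SNP positions
polymorphic *within that set* (both ancestral and derived calls
present), count each isolate's derived alleles at those positions, and
average. Fixed-derived positions are excluded — they predate the
sampled diversity — and a single-isolate set therefore has dMRCA 0.
Ambiguous calls participate in neither the polymorphism determination
nor the counts.

## Parallel evolution

A gene is under parallel evolution when it carries at least two
independent SNPs whose maximum pairwise genomic span is at most 2000 bp.
The span formulation (rather than a SNPs-per-gene-length density) is
primary because it directly captures "repeated hits in the same small
functional neighbourhood" and is insensitive to annotation length; the
density per 2000 bp of mutated span is reported as a diagnostic, and the
two formulations agree whenever the mutated span is within the window
(property-tested). When a genotype matrix is available, a gene whose
SNPs all have identical derived-isolate sets is excluded: mutations that
always travel together are one historical event. Without genotype data
the exclusion cannot be evaluated; it is skipped and flagged in the
output rather than silently assumed. The rule is additionally evaluated
within each host species (`parallel_any_host`), since repeated evolution
within a single host is the stronger signal; both scopes are reported.

## Mobile elements

Accessory contigs are assembled-contig survivors of two alignment
screens: removal of contigs matching the reference at ≥ 90% identity
over ≥ 85% of their length (with a 100 bp alignment-length floor playing
the role a database search's e-value cutoff would), then mutual
deduplication at 90% identity / 85% aligned fraction. The alignment
engine is an injected dependency with this stated contract; the bundled
default wraps `Biostrings::pairwiseAlignment` and is adequate at desk
scale, while production users can substitute a BLAST wrapper without
touching the module.

Presence calls follow the printed thresholds exactly: present iff
coverage > 80% *and* depth > 60×; absent iff coverage < 20% *or* depth
< 60×. These rules leave a gap (intermediate coverage at high depth) and
an overlap (full coverage at depth ≤ 60 satisfies the absent rule while
failing the present rule). Rather than invent a binary call, the package
adds an explicit `ambiguous` state for the gap and gives the absent rule
priority on the overlap; presence trajectories report the fraction
present among *definite* calls and return missing (not zero) for days
where every isolate is ambiguous. The call is monotone in both coverage
and depth (property-tested).

## Lineage dynamics and Muller decomposition

SNP trajectories start from isolate genotypes: the frequency of a SNP on
a day is the derived fraction among unambiguous calls. Only SNPs
observed derived in at least 4 isolates overall are tracked — below
that, a trajectory is mostly sampling noise. Frequencies can be computed
pooled, per host species, or per subject; pooled is the default since
isolate counts per subject-day are small. A read-weighted variant is the
natural alternative when allele-level read counts are trusted, and the
isolate-based default is what the bundled generator can ground-truth.

Missing time points are bridged by piecewise-cubic **Bézier
interpolation**: each interval is a cubic Bézier whose control handles
derive from Catmull-Rom tangents, limited by the Fritsch–Carlson
monotonicity rule and clamped to [0, 1]. The testable contracts are:
the curve passes exactly through every observation, preserves monotone
runs, and never leaves the unit interval. A single observation yields a
constant curve with a warning.

Sublineages are nested by derived-isolate-set inclusion. SNPs whose
derived sets agree on every jointly-unambiguous isolate are grouped as
one branch (this tolerance to missing calls is what makes the recovery
robust at realistic error rates); branches are ordered by strict set
inclusion into a tree and named E1, E1-A, E1-B, E1-B-1, … with siblings
ordered by decreasing isolate count. Overlapping-but-incomparable sets
violate the clonal assumption: the conflicting isolates are removed from
the smaller set (majority assignment) and reported, and if conflicts
touch more than 10% of isolates the function stops and demands manual
curation instead of fabricating a tree.

The Muller decomposition is the printed rule: a parent's exclusive
frequency is its raw (cumulative) frequency minus the sum of its
children's raw frequencies, clamped at zero when children overshoot
(sampling noise can make children sum past their parent). Leaves keep
their raw frequency. Conservation — per-day root mass never exceeding
1 + 1e-9 — is asserted in the tests rather than enforced by
renormalisation.

Cross-host similarity of dynamics uses a Mantel test between the two
hosts' Jaccard distance matrices over time points; a SNP/lineage is "in"
a day's set when its frequency exceeds a configurable threshold
(default 0, i.e. any presence). With five time points the permutation
null is completely enumerable, which the implementation accepts
deliberately; degenerate (constant) distance matrices are reported as
undefined rather than coerced to a number.

## Community co-evolution

Relative abundances are CLR-transformed per sample
(`log(x / geometric mean)`), after zero replacement by the
multiplicative strategy with δ = 0.65 × the smallest nonzero value (a
standard compositional default; a pseudocount strategy is also
exposed). The co-occurrence stage is a documented stand-in for sparse
inverse-covariance network inference: Spearman correlations on CLR
values, permutation p-values (samples permuted jointly), and
Benjamini–Hochberg FDR at q = 0.05. Species with a significant negative
edge to the probiotic are labelled competitors, positive edges
positive-associates, the rest non-competitors; externally computed edge
lists can replace this stage. The network is inferred on probiotic-group
samples — the probiotic's associations are defined where it actually
occurs — and one compositional caveat is inherited from CLR itself:
strong negative coupling of several competitors shifts the per-sample
geometric mean, which can lend uninvolved species a spurious positive
association with the probiotic. The false-positive calibration test in
the suite therefore uses genuinely independent compositions.

SNP accumulation consumes per-species counts referenced to a zero day-0
baseline (the upstream intra-species diversity caller is consumed as a
table, not reimplemented). Reported statistics: group/label/day mean
counts, per-subject Euclidean distance of the species-count vector from
day 0, per-day rates (count / elapsed days — the exact normalisation
behind published per-day figures is not derivable from printed values,
so the package reports this transparent definition), and a one-sided
Wilcoxon rank-sum contrast of competitor vs non-competitor counts.

## The synthetic-data generator

The generator is first-class, tested code, and defines the study
conditions the pipeline is validated under. It emulates:

* a reference genome of one chromosome (60 kb) and four plasmids
  (4 kb each) with 40 uniformly spaced 900 bp genes — a miniature of a
  real 3 Mb genome, sized so the full pipeline runs in seconds;
* a scripted plan of five nested sublineages (E1; E1-A and E1-B; E1-B-1
  and E1-B-2) born on days 0–7 with selection coefficients 0.12–0.22 per
  day and joint ownership of 22 SNPs across 12 genes — five genes hit
  2–4 times from *different* branches (so the parallel rule and the
  co-occurrence exclusion are both exercised), seven genes hit once,
  three intergenic sites. Each sublineage's frequency evolves by
  Wright–Fisher multinomial resampling (Ne = 2000, one generation per
  day) with multiplicative selection, independently per host subject:
  the same mutations arise in every subject at the same times, which is
  the convergent-evolution scenario the pipeline is meant to detect.
  In stochastic mode, births instead occur at a per-lineage per-day
  probability and add exactly one SNP each (infinite-sites, no
  back-mutation), keeping truth unambiguous; a scripted plan event may
  carry a block of SNPs, read as a collapsed chain of single-SNP births
  along one branch;
* isolate sampling: 20 isolates per host species per day on days 3, 7,
  14, 21, 28, drawn multinomially from the subject's lineage
  frequencies; per-site depth negative-binomial (mean 60×, size 10),
  strands split binomially at 1/2, bases miscalled at 0.5%;
* two mobile elements (1.2 and 1.5 kb) riding on the E1-B and E1-A
  branches, emitted both as accessory contigs and as coverage/depth
  evidence (carriers ~95% coverage at > 60×, non-carriers < 5%
  coverage);
* a resident community of 37 species (the scale of prevalent-strain
  panels in such studies) with 8 competitors whose log-abundances are
  negatively coupled to the probiotic's, and per-species SNP counts
  accumulating by Poisson increments to day-28 means of 70
  (competitors), 2 (non-competitors) and 2 (placebo) — the one-to-two
  orders-of-magnitude contrast the co-evolution stage must detect.

Everything is reproducible bit-for-bit from the seed. What the generator
does **not** emulate — and what passing tests therefore do not
demonstrate about real data: mapping and assembly artefacts (counts are
generated, not aligned), within-read error correlation, recombination
and back-mutation, host immune dynamics, compositional sequencing depth
effects in the metagenome, and realistic phylogenetic structure among
resident species.

## Numerical and degenerate-input choices

* The 1/3 failure bound and the quality/coverage thresholds are compared
  with the printed strict/non-strict senses exactly; the failure
  fraction uses integer arithmetic.
* External coordinates are 1-based inclusive everywhere; 0-based
  arithmetic exists only inside the I/O module.
* NJ agglomeration is delegated to `ape::nj` (deterministic); negative
  NJ branch lengths are clamped to zero with the deficit reported.
  Fewer than three taxa yield the trivial two-leaf tree.
* Missing count cells are distinct from observed zero coverage, so the
  failure-fraction rule can count absent isolates as failing.
* Interpolation evaluates on the regular grid plus the observation
  days, and observation values are written through exactly to be immune
  to floating-point drift.
* Permutation p-values use the add-one estimator `(b + 1)/(B + 1)`;
  seeds are explicit arguments everywhere, and omitting a seed never
  silently falls back to the clock.

## Problem sizes

The default scenario used throughout the tests and the acceptance
script: 200 isolates (2 species × 2 subjects × 5 days × 10), 52 sites,
22 true SNPs, 5 sublineages, 37 community species × 12 subjects. The
oracle-equivalence check runs 200 random 8 × 12 matrices; the
competitor-contrast calibration runs 100 simulated replicates. These
sizes were chosen so the entire suite exercises every stage at full
fidelity in about a minute.

## Known limitations

Indels, recombination and copy-number changes are out of scope; the
caller is bi-allelic by design; the co-occurrence stage is a correlation
stand-in, not conditional-independence inference; Muller output is a
table, not a styled plot; and the lineage-nesting step assumes an
essentially clonal population — datasets violating nesting beyond the
conflict threshold are refused, not repaired.
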