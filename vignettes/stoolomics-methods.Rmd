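---
title: "Methods: faecal sncRNA quantification, cluster-based normalization and per-sample differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: faecal sncRNA quantification, cluster-based normalization and per-sample differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoolomics)
```

## The analysis problem

Stool samples contain two information layers that interact: the microbial
community (profiled as OTU count tables with taxonomic lineages) and
host-derived small non-coding RNAs — miRNAs and piRNAs — released into the
gut lumen, where they can modulate bacterial growth. Profiling both from the
same faecal samples poses three statistical problems that this package
addresses in one pipeline: reads must be assigned to highly similar ncRNA
references (multireads), between-sample scaling must survive strong
per-reference expression heterogeneity, and cohorts are typically too small
and too heterogeneous for group-level tests, pushing the analysis to
per-sample comparisons.

## Read mapping and EM multiread allocation

Mapping is ungapped, forward-strand, full containment of the read in the
reference, with at most one mismatch in the leftmost `min(20, read length)`
nt; mismatches beyond the seed are unlimited by default (`max_total_mm`
caps them if wanted). Small ncRNA references are strand-resolved, which is
why no reverse-complement pass exists. Candidate positions come from a
10-mer index: with one allowed seed mismatch, one of the two disjoint
10-mers covering the seed must match exactly, so candidate generation is
lossless for reads of length ≥ 20; shorter reads (15–19 nt) fall back to an
exhaustive offset scan. The test suite checks the full hit set against an
independent all-offsets scorer on random read/reference pairs.

All tied and non-tied hits of a read are kept; the EM allocator is the tie
resolver. Its model is the standard multinomial mixture: reference
abundances `θ` are the parameters, each read contributes likelihood
`Σ_{r ∈ hits} θ_r`. The E-step splits each read's unit mass across its hit
set proportional to `θ`; the M-step sets abundances to the summed masses.
Uniform initialization, convergence when expected counts move < 1e-8
(absolute), 200-iteration cap. These values are stated so they are
testable: the 8-unique/2-unique/10-shared configuration must reach its
closed-form fixed point (16, 4) within 1e-6, and total mass equals the
aligned-read count to 1e-9 at every iteration. Multireads may cross ncRNA
classes (miRNA vs piRNA); nothing in the data forbids it, so EM decides.

## Greedy clustering and TMM on cluster cardinalities

Per-reference counts in stool are heterogeneous enough that TMM computed on
them is dominated by sample-private signal. The pipeline therefore clusters
the *observed sequences* (reference-free): members differ from their
cluster's virtual centre by at most 3 substitutions and at most 3
overhanging residues. "Overhanging residues" is read as the combined
unaligned termini of both sequences at the best ungapped shift; a flag
(`overhang_per_end`) switches to a per-end budget, since the rule's
granularity is genuinely ambiguous. Processing order is decreasing total
abundance with lexicographic tie-break — abundant sequences make natural
centres and the partition becomes order-independent and deterministic; the
suite verifies both the determinism and agreement with a brute-force
checker on random variant families.

Cluster cardinalities (summed member counts per sample) are the input to
TMM. The implementation follows the canonical trimmed-mean-of-M-values
recipe: reference sample = closest-to-mean upper quartile of positive
count proportions; M and A over features positive in both samples; double
trimming (drop the top/bottom 30% by M and 5% by A, keeping the
intersection, with first-occurrence rank tie-breaks); weights = inverse
asymptotic binomial variance; factors rescaled to geometric mean 1
(enforced to 1e-9). Trim fractions are the method's standard defaults; the
source procedure names TMM without parameters. One property worth stating
precisely: multiplying a single sample's column by a constant leaves every
M and A unchanged but *not* the binomial weights, so factors are scale
invariant only up to the weight perturbation — well under 1% in the test
fixtures — and the suite asserts invariance at that tolerance rather than
exactly.

Normalized counts are `raw / (library size × factor) × mean(effective
library size)`, i.e. counts per effective library rescaled so magnitudes
stay on the raw-count scale (tens to thousands), matching how the sibling
pair reference table prints them. Effective library sizes are recorded as
the normalized table's library sizes.

## Per-sample differential expression

Fold change is `log2((a + 1)/(b + 1))`. The unit pseudocount is not
arbitrary: it is the only offset that reproduces the reference table's
printed fold changes from its printed count pairs (e.g. 27.1 vs 79.7 →
−1.52), and it gives zero-count features a finite, monotone fold change.
Reported values round half-up to 2 decimals (`round_half_up()`); all
internal logic uses full precision.

The test is Fisher's exact test on the minimal 2×2 consistent with count
data: feature count vs the remainder of the library, in both conditions,
with fractional normalized counts rounded half-up to integers. Two-sided
p-values use the point-probability rule (sum of all tables as or less
probable than the observed one), which the suite verifies against a direct
hypergeometric enumeration over every 2×2 table with total ≤ 60 (reduced by
the row-swap/column-swap/transpose symmetries that provably preserve the
p-value). For case-vs-control-pool comparisons the pool contributes its
summed counts against its summed effective library sizes — pooling counts,
not p-values. BH adjustment runs within each comparison. Significance
requires both p < 0.05 and |log2FC| ≥ 1: with single samples per condition
the Fisher p is exquisitely sensitive at high counts, and the fold-change
gate is what keeps biologically negligible shifts out. Presence categories
(common / only-case / only-control / absent) mirror the sibling-pair
reporting layout; cross-couple intersection keeps features significant in
every couple with a consistent sign.

Two caveats are deliberate. First, Fisher's test assumes binomial sampling;
biological overdispersion inflates its type-I error, which is why the
calibration test runs at dispersion 0 and why the |log2FC| gate matters in
practice. Second, when TMM factors differ strongly between samples, pairing
each normalized count with its own effective library size distorts the
tested proportions slightly; fold changes are unaffected, and in the
simulated regimes the effect is absorbed by the fold-change gate.

## Target intersection and gene sets

miRNA target maps keep experimentally validated entries only; piRNA maps
keep, per piRNA, the targets with that piRNA's maximum alignment support
(ties included). Maps are consumed from TSV snapshots — the upstream target
databases are unversioned web resources, so live queries would not be
reproducible. Per-sample target sets are unions over significant
(direction-filtered) ncRNAs; `common_targets()` thresholds on the number of
supporting samples (the threshold is a parameter because both
"three or more samples" and "more than two samples" style analyses are
useful). Gene-set annotation is pure membership against GMT collections —
no enrichment p-value is computed, because the downstream report is a
membership count, and an over-representation statistic would require a
background model the sample sizes cannot support.

## Microbiome summaries

Shannon entropy uses natural log and Simpson is reported as Gini–Simpson
`1 − Σ p²` (both on a 0–1 axis for Simpson; inverse Simpson behind a
flag) — the conventions of the common community-ecology toolchain; the
computation itself delegates to vegan. Rank aggregation pools
rank-unassigned OTUs under `unassigned_<deepest assigned ancestor>` so
column totals are conserved exactly. The Bacteroidetes/Firmicutes group
ratio is the mean of per-sample ratios; a pooled-fraction convention is the
obvious alternative, and published group percentages are not always
consistent with either, so the ratio is reported as a descriptive summary
and never asserted against external values. Family prevalence
("mainly present in a group") means relative abundance above 1e-4 in more
than 50% of the group's samples; the partition into both / case-only /
control-only is exactly label-symmetric, which the suite asserts.

## The synthetic-data generators

The generators produce the statistical structure the pipeline assumes, not
realistic sequencer output. References are uniform-random 15–51 nt
sequences (the trimmed-read window) with optional planted families sharing
an identical 5'-20-mer core, so seed-constrained mapping yields genuine
multireads. Reads are whole references with i.i.d. substitution errors and
a constant quality string — no quality profiles, indels or chimeras, since
nothing downstream consumes qualities. Two-group counts are gamma-Poisson
with default dispersion 0.1 (a realistic biological CV for small-RNA
counts), library sizes spread over a 4-fold range (a free choice; no
per-sample library list is published for the reference study), and spiked
effects applied symmetrically up/down in case samples. OTU tables are
Dirichlet-multinomial with group-exclusive families zeroed by construction.
One root seed drives fixed per-generator sub-streams, so a configuration is
byte-reproducible and generators do not perturb each other. Passing tests
on these inputs demonstrate algorithmic correctness and recovery under the
assumed model — they do not certify behaviour on real stool libraries,
where adapter artefacts, cross-mapping to microbial RNA and compositional
effects are all harsher.

Problem sizes in the test-suite simulations are deliberately desk-scale:
20-seed batches, 100–200 features, 6+6 samples, hundreds to a few thousand
reads, ≤ 50 sequences for clustering oracles. The spiked-recovery check
(effect log2FC 3, base mean 50, 6 cases vs pooled 6 controls, 20 seeds)
requires ≥ 90% sensitivity and ≤ 10% false positives at the significance
rule above.

## Known limitations

- No SAM/BAM emission and no quality-aware scoring; the aligner exists to
  feed EM, not to replace a general-purpose mapper.
- The clustering is quadratic in unique sequences and intended for
  unique-sequence tables of desk scale, not tens of millions of raw reads.
- Fisher p-values on single samples treat counts as the only noise source;
  they are anti-conservative under biological replication and should be
  read together with the fold-change gate and FDR.
- The bundled sibling-pair table prints normalized counts at 1-decimal
  precision; fold changes recomputed from it match the printed values
  within the quantization that rounding implies, which the acceptance
  tests quantify explicitly.
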