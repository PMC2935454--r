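---
title: "Models and methods behind meleagris"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meleagris}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meleagris)
```

This vignette is the package's own account of its statistics: the models
and procedures, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where more than one reading was defensible.

## Tiered SNV classification

A pileup column is the multiset of per-read observations (symbol, Phred
quality, platform tag) over one position of an assembled contig. The
classifier distinguishes genuine heterozygous variation from sequencing
error with two tiers of evidence:

* **strong**: at least two alleles, each supported by ≥ 3 reads with a
  top-three quality sum ≥ 60, and overall column depth ≤ 30;
* **weak**: at least two alleles, each supported by ≥ 2 reads with a
  top-two quality sum ≥ 45, no depth cap.

Three reads at Phred 20 give a chance-error probability of about 10⁻⁶,
which is what the quality-sum threshold encodes; the depth cap rejects
apparent variants created by collapsed near-identical repeats, which
inflate coverage. Reporting is inclusive: a strong site is never
relabelled weak, and the weak catalogue contains the strong one.

Supporting rules:

* **Gap qualities.** A gap in a multiple alignment has no base quality;
  it takes the minimum quality of the same read's flanking bases. At a
  read end only one flank exists and is used alone (the minimum-of-flanks
  rule is undefined there; using the single available flank is the least
  surprising completion).
* **Homopolymer indels.** Pyrosequencing miscounts homopolymer run
  lengths, so an indel whose base, together with equal consensus
  neighbours, forms a run of length ≥ `homopolymer_min_run` (default 2)
  requires one short-read observation per allele, in both tiers. The run
  count includes the column's own indel base: inserting an `A` beside a
  single consensus `A` is the classic one-base overcall and is treated as
  a run of 2. The run-length threshold is configurable because no
  canonical value exists.
* **Depth** counts all non-N observations at the column across both
  platforms (one depth per position). Whether the original cap counted
  all reads or only variant-supporting reads is not decidable from the
  published criteria; all-reads is the reading consistent with "overall
  depth of coverage".
* **N observations** are uncallable and excluded from evidence and depth.
* Coordinates are 0-based half-open internally and 1-based only in the
  VCF writer, which also left-normalizes single-base indels through
  mononucleotide runs. Evidence ties break by allele lexicographic order
  for determinism.

**A monotonicity caveat.** "Adding a supporting read never demotes a
called column to none" holds only when the read is added to an allele
already in the qualifying set and the strong depth cap is not crossed.
Two genuine counterexamples exist under the literal criteria: a read that
promotes a third, short-read-free allele into the qualifying set of a
homopolymer indel column fails the per-allele short-read rule; and a
strong column at exactly depth 30 whose alleles have top-three sums ≥ 60
but top-two sums < 45 (e.g. three reads at Phred 20) leaves both tiers
when one extra read breaches the cap. The property test is scoped
accordingly; the classifier itself is checked against a literal
brute-force evaluation of the criteria on 10⁴ random columns.

Diversity uses the Watterson estimator θ = S/(a·L) with
a = Σ_{i=1}^{n−1} 1/i. The estimator behind the published per-chromosome
diversity values is not stated in the source material; Watterson's is the
standard segregating-sites estimator and is what the package provides.

## Platform coverage

A position is *covered* at depth ≥ 1 (no threshold is published; 1 is the
natural reading of "covered only by reads from a single platform"). The
partition into both/exclusive/neither classes is emitted as canonical
0-based half-open intervals, matching BED directly. Under uniform
coverage, read starts are Poisson and the uncovered fraction at mean
fold-coverage c is the zero class e^(−c); at 5× this is 0.67%. The
module exposes c as an explicit argument and takes no position on
published per-platform effective coverages.

## Chromosome anchoring

Marker observations from microsatellite-linkage, SNP-linkage and
BAC-end-sequence physical maps merge into one ranked order per
chromosome. When sources disagree about a marker's chromosome, linkage
wins: genetic maps anchor chromosomes, the physical map refines local
placement. Conflicts are logged, never silently dropped.

Each scaffold's hits, sorted by scaffold coordinate, are segmented
greedily left-to-right into maximal blocks that are single-chromosome and
strictly monotone in chromosome rank. Any sub-interval of a valid block
is valid, so the greedy maximal segmentation provably attains the minimum
block count; the test suite confirms this against a dynamic-programming
minimum on all instances up to 12 hits. One block means the scaffold is
consistent with the map; more blocks mean a misjoin, and the scaffold is
split midway between the flanking conflicting hits — the true breakpoint
is unobservable between markers, so the midpoint is the minimax choice.

Orientation is the sign of the Kendall rank correlation between scaffold
position and chromosome rank; single-marker or tied blocks are reported
forward with an explicit unknown flag (no orientation rule is published;
Kendall's sign is the assumption-free choice). Pieces order along a
chromosome by the median rank of their markers, ties broken by piece id.
`min_markers` defaults to 1 — single-marker scaffolds are placeable in
map context — and can be raised for conservative placements. Scaffolds
with no qualifying block pool into ChrUn. The published inconsistency
criterion that produced the original splits (distance thresholds, marker
weighting) is unstated; this package's criterion is exactly the
monotone-block segmentation above.

## Devog acceleration statistics

For each gene, the avian-pair log ω is compared with the gene's
mammalian pairwise log ω sample by a two-sided one-sample t test
(mammal sample against the avian value as hypothesized mean, df = pairs −
1). A two-sample test is impossible with a single avian pair per gene;
the one-sample orientation is the only coherent form. The six mammalian
pairs default to all unordered pairs of {human, mouse, dog, opossum}.
Genes with ω = 0 or undefined ω (dS = 0) cannot be log transformed and
are excluded under the default policy (no pseudocount), with an explicit
`excluded` flag.

P values are adjusted by the Benjamini–Hochberg step-up; genes with
adjusted p < q (default 0.05) are *Devogs*. Each Devog is assigned a
lineage by a paired t test of turkey–mammal versus chicken–mammal
log ω, paired by mammal: positive mean difference → turkey, negative →
chicken. All tests are two-sided.

Group comparisons (innate-immune vs other genes; Z-linked vs autosomal ω
for the fast-Z effect) use the Wilcoxon rank sum with midranks.
Because ω tables contain ties, the exact two-sided p is computed by
complete enumeration of group assignments (deviation from the null mean
of W at least as large as observed) up to pooled size 12, and by the
tie-corrected normal approximation with continuity correction beyond.
Chromosome-size trends summarize each chromosome by its median statistic
and report Pearson and Spearman correlations plus the least-squares
slope against log2 length.

GO over-representation replaces the original tool's modified Fisher
score with the standard one-sided hypergeometric upper tail — the
external scoring tool is not reimplementable from its description, and
the hypergeometric is the canonical test of the same null. GO-term
dissimilarity is fixed to d(X,Y) = 1 − |N(X)∩N(Y)| / min(|N(X)|,|N(Y)|)
over Devog sets: the published formula is unreadable in the source
material, so this is a design decision (the closest reading of the cited
construction), and the function is pluggable. Average-linkage (UPGMA)
clustering is implemented in-package with a deterministic lowest-index
tie-break and verified against `stats::hclust` on random matrices.

## Gene families

Family assignment propagates the best similarity hit passing strict
thresholds (similarity > 75%, alignment coverage > 25% — strict because
the published wording is "higher than"). Copy-number change rates are
R_ij = (n_ij − n_ih)/T_jh copies per million years relative to the
reference species h; the published equation is an unrendered image, so
the unnormalized difference is a design decision, and a
reference-normalized alternative ((n_ij − n_ih)/(n_ih + 1)/T_jh) is
selectable. Rate-pattern groups key families by their per-species sign
vector by default — the weaker, more robust reading of "sorting the
species based on R values" — with a species-ranking mode available.
Lineage-specific reports use the strict rule: present in *every* focal
species (n ≥ 1) and absent from *every* background species, or the
converse; partial presence lands in neither list.

## Synthetic data: what it emulates and what it does not

The generators state a world and keep it fixed:

* `gen_diploid_truth` plants heterozygous substitutions and single-base
  indels on a uniform-random reference; indel placement probability is
  multiplied by `homopolymer_bias` inside mononucleotide runs, mirroring
  where pyrosequencing errors concentrate. Alternate alleles are drawn
  uniformly, so **no transition bias is planted**: a simulated ts/tv near
  0.5 is expected and says nothing about the classifier.
* `gen_columns` produces truth-aligned columns: no read simulation,
  mapping or assembly. Per-position per-platform depth is
  Poisson(profile mean), haplotypes are sampled 1:1, qualities are
  uniform within the profile's Phred bounds (the simplest model that
  exercises quality-sum thresholds), and error modes are per-platform
  substitution errors plus homopolymer gap errors. Default platform pair:
  5× long reads and 25× short reads, the fold-coverages of the projects
  this emulates. GC bias, quality-by-cycle structure and mapping
  artifacts are deliberately absent — a green recovery test establishes
  correctness of the classifier, not robustness to real-data noise.
* `gen_marker_scenario` builds chromosome layouts whose non-misjoined
  scaffolds always admit a zero-split placement, plants reversals and
  misjoins with recorded interior breakpoints, and assigns marker sources
  at random.
* `gen_omega_table` draws a per-gene log ω level (Normal(log 0.15,
  0.4) — predominantly purifying selection) and scatters mammalian pairs
  around it with SD 0.3. **The avian pair reports the gene level
  exactly** (plus the planted shift): with avian noise the one-sample t
  statistic has inflated variance (factor 1 + 1/n) and its null p values
  are provably non-uniform, contradicting the intended null-calibration
  property. Planting the avian value at the gene level is therefore part
  of the stated world, not a tuning choice. Accelerated genes shift the
  avian pair — and, in their assigned lineage, the corresponding
  avian–mammal pairs — by log(effect).
* `gen_family_matrix` starts each family at 1 + Poisson(2) copies and
  applies, per non-reference species, an expansion/contraction of
  1 + Poisson(1) copies with probability `event_rate`, floored at zero.

Every generator is deterministic under its seed; child seeds are derived
from the one user seed so module boundaries do not break reproducibility.

## Numerical notes and limitations

* Exact Wilcoxon enumeration is O(C(n, n_a)) and restricted to pooled
  size ≤ 12 by default; beyond that the tie-corrected normal
  approximation is used automatically.
* Degenerate t tests (zero-variance samples) are flagged rather than
  returning NaN: t = 0, p = 1 when the means agree, ±Inf with p = 0
  otherwise.
* `adjust_bh` carries NA p values through unchanged and adjusts the rest.
* The AGP writer uses fixed-size unknown gaps (100 bases, "U" rows);
  component coordinates are recomputed on write, so write → read → write
  is idempotent.
* The brute-force oracles in the test suite (literal criterion checker,
  per-position coverage labelling, DP block minimum, bitmask Wilcoxon
  enumeration) are deliberately naive and slow; they exist to pin the
  fast implementations, not for use at scale.
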