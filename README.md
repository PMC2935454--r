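# meleagris

Downstream analysis toolkit for draft genomes assembled from a mixture of
long-read pyrosequencing (moderate coverage, homopolymer indel errors) and
deep short-read sequencing (substitution errors) — the data mix used by the
early avian genome projects, where an extensively heterozygous individual
is sequenced on two platforms and the assembly is anchored to chromosomes
with marker maps. It is aimed at genome-project analysts who need the
bespoke statistics of such projects as tested, reusable functions.

## What it implements

**Tiered SNV classification** from read pileups. A column is a *strong* SNV
when at least two alleles each have support ≥ 3 reads with a top-three
quality sum ≥ 60, and column depth ≤ 30; a *weak* SNV relaxes this to
support ≥ 2 and top-two sum ≥ 45 with no depth cap. Gaps take the minimum
flanking base quality; an indel inside a homopolymer run additionally
requires one short-read observation per allele (filtering the
pyrosequencing homopolymer error mode). Calls export to VCF 4.2 with
left-normalized indels. Nucleotide diversity uses the Watterson estimator
θ = S/(a·L), a = Σ_{i<n} 1/i.

**Platform coverage analysis**: partition of contig positions into
both/exclusive/neither coverage classes (BED-convention intervals), gap
length statistics, and the Poisson uniform-coverage expectation
e^(−c) for the uncovered fraction at fold-coverage c.

**Chromosome anchoring**: merging linkage and physical marker maps into a
combined map (linkage wins chromosome conflicts), greedy segmentation of
each scaffold's marker hits into single-chromosome monotone blocks
(provably minimal), placement and Kendall-sign orientation of scaffold
pieces, misjoin splitting at the midpoint between conflicting hits, AGP 2.0
export and per-chromosome contig/base tables.

**Accelerated-evolution statistics** on per-gene pairwise dN/dS (ω)
tables: the differentially-evolved-gene (Devog) test — a one-sample t of
the mammalian-pair log ω sample against the avian-pair value — with
Benjamini–Hochberg FDR control, paired-t lineage assignment
(turkey vs chicken), exact-with-ties Wilcoxon rank-sum group comparisons
(innate-immune vs other genes, Z-linked vs autosomal), chromosome-size
trends of dS/dN/ω against log2 length, hypergeometric GO
over-representation, and average-linkage clustering of GO terms under the
dissimilarity d(X,Y) = 1 − |N(X)∩N(Y)| / min(|N(X)|,|N(Y)|).

**Gene-family copy-number dynamics**: similarity-threshold family
assignment (> 75% similar, > 25% coverage), rates of change
R_ij = (n_ij − n_ih)/T_jh relative to a reference species, rate-pattern
groups, and strict presence/absence lineage-specific family reports.

**Synthetic data with planted truth**: seeded generators for heterozygous
diploid pileups over two platforms, marker scenarios with planted scaffold
misjoins, ω tables with planted lineage acceleration, and copy-number
matrices with planted expansions/contractions — used throughout the test
suite for truth-recovery checks.

## Worked example

```r
library(meleagris)

truth  <- gen_diploid_truth(20000, snp_rate = 0.01, indel_rate = 0.003,
                            homopolymer_bias = 4, seed = 1)
pileup <- gen_columns(truth, default_platforms(long_depth = 5,
                                               short_depth = 25), seed = 2)
calls  <- call_snvs(pileup)
summarize_calls(calls, tier = "strong")
```

On this simulated 20 kb heterozygote the pipeline reports 341 calls for
the 341 planted variants (no false positives), of which 188 are strong —
the rest fall to the weak tier, mostly where the Poisson column depth
exceeds the strong cap of 30 (mean strong depth here is 26.0 ± 3.1). Of
the substitution calls, 67 are transitions and 137 transversions (ratio
0.5: the generator draws alternate alleles uniformly, so no transition
bias is planted), and 137 calls are single-base indels.
`watterson_theta(341, 20000, 2)` gives θ = 0.017, and the coverage
module reports 0.6% of positions covered by one platform only, against
`expected_uncovered_fraction(5)` = 0.67% expected missed at a uniform
5×.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline pipeline from scratch at the given
seed — simulated pileup → SNV calls and summary → coverage partition →
marker-map anchoring with planted misjoins → Devog catalogue →
gene-family rate patterns — and writes the acceptance JSON to `--out`.
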