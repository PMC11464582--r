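---
title: "Models and methods behind popgenpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popgenpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenpipe)
```

popgenpipe implements the analysis chain used to characterize small,
labelled diploid populations from SNP-array genotypes — the situation of
livestock conservation nuclei, where a handful of breeds are represented by
5–50 individuals each and every question (diversity, inbreeding, effective
size, structure, admixture, selection) must be answered from one PED/MAP
panel. This vignette states the models, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Genotype representation

A dataset is a samples × variants matrix of counted-allele dosages
(0/1/2, `NA` missing) with population labels and sorted map positions. The
counted allele is always the minor allele at read time, ties broken to the
lexicographically later character, so the per-variant MAF is `mean(g)/2`.
PED/MAP carries no allele-coding metadata, so this convention *is* the
canonical coding: generators and the merge routine re-canonicalize their
output, which makes write-then-read the identity.

Merging two panels resolves variants on (chromosome, position). Allele
pairs that only agree under strand complementation are flipped; palindromic
A/T and C/G variants are dropped outright because their strand cannot be
inferred from the data, and a silent strand error at such sites corrupts
every frequency-based statistic downstream. Duplicated sample ids across
panels act as a merge control: their genotype concordance is reported, then
the right-hand copies are removed.

## Quality control

Thresholds are exclusive throughout (`> 0.95` call rate, `> 0.05` MAF), and
variants are filtered *before* samples, so an individual penalized only by
bad assays survives. LD pruning is the classic 50-SNP window advanced by 10
SNPs at an r² ceiling of 0.20, using the same genotype-correlation r² as
every other module; within a window the lower-MAF member of the worst pair
is removed (tie: the later position), and passes repeat until stable, which
guarantees the audit property that no surviving within-window pair exceeds
the ceiling. The tie-break is fixed here for determinism; published
pruning tools differ in this detail and none documents it fully.

The ROH analysis deliberately consumes the call-rate-filtered but *not*
MAF-filtered data: autozygous stretches are largely monomorphic in the
carrier, and a MAF filter would delete the very evidence being scanned for.

## Diversity and F-statistics

Observed homozygosity is the fraction of homozygous calls; expected
homozygosity uses the unbiased small-sample estimator
`1 − 2p(1−p)·2n/(2n−1)`. Note the direction of the correction: it scales
expected *heterozygosity* up by `2n/(2n−1)`, so expected homozygosity can
only move down relative to the plug-in value — at the n = 5–11 typical of
conservation nuclei the difference is material for F_IS. F_IS is the
heterozygosity-ratio form `1 − (1−Ho)/(1−He)`, and per-individual excess
homozygosity is `F_HOM = (O − E)/(L − E)` with `E` the sample's expected
homozygous count under Hardy–Weinberg across its called variants — the
conventional definition of the excess-homozygosity statistic, which the
literature cites more often than it writes out.

Per-marker F_ST is the Weir–Cockerham (1984) two-level estimator with
variance components a (among populations), b (among individuals within)
and c (within individuals); the global value is the ratio of sums
Σa / Σ(a+b+c), the standard recommendation for averaging W&C over loci.
Pairwise population F_ST uses the same estimator restricted to each pair,
with Slatkin's linearization F_ST/(1−F_ST), the island-model migrant number
Nm = ((1/F_ST) − 1)/4, and a permutation p-value from shuffled labels
(1,000 permutations by default, seeded). The AMOVA-based "paired F_ST" of
haplotype software needs phase that array genotypes lack; W&C + Slatkin
linearization is the deliberate unphased substitute.

One practical observation the test suite encodes: pruning a *pooled*
structured panel preferentially removes differentiated variants, because
differentiation itself generates admixture LD. Pruned-panel F_ST is
therefore systematically below unpruned per-marker F_ST; the two are
different estimands and the package reports them from the stages the
analysis chain prescribes.

## LD decay and effective population size

LD between two variants is the squared Pearson correlation of dosages over
pairwise-complete samples (composite LD), defined for ≥ 3 complete pairs
with both variants polymorphic among them. The decay curve uses *all*
intra-chromosomal pairs up to 1 Mb — a decay-over-distance curve requires
all pairs, and "adjacent pairs only" cannot populate distance bins.

Ne per past generation uses the LD–recombination relation for unphased
panels: a pair at recombination distance c Morgans (physical distance ×
1 cM/Mb by default) reflects the population about t = 1/(2c) generations
ago; with the sample-size correction `r2_adj = mean(r²) − 1/n` (1/n, not
1/(2n), because dosage correlation on unphased genotypes already averages
the two haplotypes), `Ne(t) = (1/(4c))·(1/r2_adj − α)`. α defaults to 1
(no mutation correction) and is configurable to 2.2. Generations map to
relative c-bins of ±20 % half-width — absolute bins starve large-t points;
the reported t honours t = 1/(2c) at each bin's realized mean c. Points
with non-positive adjusted r² (no information above sampling noise) are
dropped with a warning rather than reported as negative sizes.

## Runs of homozygosity

The caller is the sliding-window algorithm: 50-SNP windows scored
homozygous when they contain no heterozygote and at most 5 missing calls;
each variant's hit fraction is the proportion of covering windows scored
homozygous, and variants at or above 0.05 are ROH-eligible. Maximal
eligible non-heterozygous runs, split at gaps above 1,000 kb, become
segments if ≥ 1,000 kb long with ≥ 20 SNPs at ≤ 150 kb/SNP. Segment
coordinates are the first/last SNPs of the run — deterministic and directly
comparable to an exhaustive reference scan, which the suite runs on every
small fixture.

Two resolution consequences follow from the window rule and are worth
knowing when interpreting output. First, a run shorter than the window can
never certify a homozygous window, so the effective detection floor is the
window span (~1 Mb at 20 kb spacing, coarser on sparser maps). Second, the
hit-fraction threshold trims up to `ceil(0.05 × 50) = 3` SNPs at each run
edge, so called boundaries sit a few SNPs inside the true autozygous run —
and conversely, chance-homozygous background SNPs adjacent to a true
segment legitimately extend it. The window hit-fraction reading of the
"overlap ratio" is one of two possible interpretations of that setting in
the emulated toolchain; the alternative (group-overlap pooling across
individuals) belongs to consensus-ROH analysis, which this package does not
perform.

F_ROH divides summed segment length by the autosomal genome length
(2,265,770 kb for the pig Sscrofa11.1 assembly, the package default) and
decomposes it into 1–4, 4–8, 8–12 and > 12 Mb classes, lower bound
inclusive, whose shares sum to the total exactly. Under the
recombination-clock model segment lengths are exponential with mean 1/(2g)
Morgans for an ancestor g generations back, giving `g = 100/(2·length_Mb)`
at 1 cM/Mb — 4.17 generations for 12 Mb segments.

## Structure: PCA, IBS, trees, networks

PCA standardizes each variant by `(g − 2p)/sqrt(2p(1−p))`, imputes missing
cells to 0 (the post-centering mean; the imputed count is reported) and
eigendecomposes the sample covariance; monomorphic variants are refused
with an instruction to MAF-filter, since their scale factor is zero. IBS is
the mean of `(2 − |gi − gj|)/2` over pairwise-complete variants; nearest
neighbours rank 1 − IBS with lexicographic tie-breaks. Nei's (1972)
standard distance is computed from both alleles' frequencies per variant;
an infinite distance (zero cross-identity) is capped at a configurable
ceiling with a warning. Neighbour-joining delegates to the canonical
Saitou–Nei implementation and then clamps negative branch lengths to zero,
moving the deficit onto the sister branch so path lengths are preserved as
closely as possible. The kNN population network symmetrizes directed
k-nearest-neighbour edges into an undirected graph; plain kNN replaces the
superparamagnetic clustering of the emulated workflow, whose Potts-model
annealing is a separate algorithm out of scope here.

## Admixture

The model is the standard binomial mixture: `g_ij ~ Bin(2, Σ_k q_ik f_kj)`
with simplex rows Q and ancestral frequencies F. Fitting uses the
multiplicative EM updates rather than the original block-relaxation
quasi-Newton scheme: the stationary points are identical and EM's
monotone log-likelihood is asserted on every run in the test suite.
Defaults: tol 1e−6 on relative log-likelihood change, max 2,000 iterations,
5 seeded restarts keeping the best likelihood (EM has local optima), F
clipped to [1e−6, 1−1e−6]. Component labels are arbitrary; alignment
between fits maximizes summed column correlation, exhaustively for k ≤ 8.

Cross-validation masks a fraction (default 10 %) of non-missing genotype
*entries* per fold — an explicit rendering of the emulated tool's held-out
concept — refits, and scores masked entries by mean binomial deviance
against the fitted dose. Entry masking rather than individual masking keeps
every sample's ancestry estimable in every fold, which matters at n = 5–11
per population. The k scan covers 2–15 by default.

## Selection scan

Each variant's standardized genotype vector is regressed on the first K
(default 3) PC score vectors; orthogonality of scores reduces this to
per-PC simple regressions, and the z-scores are summarized by a robust
Mahalanobis distance: coordinate-wise median location, MAD scale, a
sign-based (quadrant) correlation mapped through `sin(π/2 ·)`, shrunk 5 %
toward the identity so the matrix inverts stably. This
deterministic estimator replaces the minimum-covariance-determinant search
of the reference implementation — at K = 3 the difference is negligible and
determinism is worth more; the strategy is exposed as an argument. The
genomic inflation factor λ = median(d²)/χ²₀.₅(K) rescales distances;
p-values are upper-tail χ²(K), q-values Benjamini–Hochberg, flags at
q ≤ α = 0.05. A degenerate (constant-d²) panel is mapped to p = 0.5
everywhere: a distribution with no spread ranks nothing. The scan runs on
the dense MAF-filtered panel with PCs from the pruned one — outlier scans
need dense coverage while structure estimation prefers pruned markers;
whether the emulated analysis pruned before scanning is not recoverable,
so the score source is an argument. F_ST flags use the strict
threshold F_ST > 0.5, and candidate windows extend ±500 kb from each
flagged variant, clamped at zero, merged when overlapping, exported as
0-based half-open BED.

## The synthetic generators, and what the tests show

Every stage is tested against data with known truth:

* **Balding–Nichols**: ancestral frequencies Uniform(0.05, 0.95), deme
  frequencies Beta-distributed around them with variance parameter F, an
  optional per-variant elevated F for outlier loci, optional within-deme
  inbreeding, uniform missingness. Truth frequencies are emitted on the
  same allele coding as the data.
* **Forward Wright–Fisher**: discrete generations, random mating under a
  step-wise size history, Poisson crossovers at 1 cM/Mb, standing variation
  initialized in linkage equilibrium at Uniform(0.1, 0.9) — no new
  mutation. Desk-scale by design (N ≤ ~200, tens of generations, ≤ 20 Mb),
  which keeps each replicate in seconds.
* **ROH implants** overwrite heterozygotes with seeded random homozygotes
  inside chosen intervals; **admixture mixtures** draw genotypes from
  Binomial(2, qᵀf) with a retained truth Q.

Test problem sizes were chosen as the smallest at which the estimators'
sampling noise is comfortably inside the asserted tolerances: F_ST recovery
uses 2 demes × 50 samples × 5,000 variants (±0.02); Ne recovery 20 × 1 Mb
chromosomes, N = 50, 30 sampled, 10 replicate seeds (factor 1.5 on the
median at the generations a 1 Mb map resolves, t ≈ 50); F_ROH recovery a
30 Mb genome at ~20 kb spacing with 10 % implanted (±1.5 % absolute);
admixture 60 samples × 2,000 variants from F_ST = 0.2 sources (Q RMSE
< 0.05) and CV model selection on 3 × 15 samples at F_ST = 0.3; the null
scan 60 samples × 5,000 variants (λ ∈ [0.8, 1.2], flagged fraction ≤ α).

What these tests do *not* show: the generators draw unlinked variants
(except the Wright–Fisher genome), have no ascertainment bias, no
site-frequency-spectrum realism (standing variation only), and no linked
selection — so passing recovery tests demonstrates estimator correctness,
not robustness to every pathology of real array data. Two caveats
uncovered by the tests themselves are documented above: the ROH window
rule's ~1 Mb detection floor and edge trim, and the fact that a
Balding–Nichols outlier draw at F = 0.8 occasionally realizes
near-identical deme frequencies, leaving that implant undetectable in
principle — power is therefore reported both over all implants and over
those whose realized differentiation is elevated.

## Degenerate inputs and tie-breaks, collected

* Half-missing PED genotypes become missing; monomorphic variants carry
  `allele_b = NA` and dosage 0.
* Minor-allele ties break to the lexicographically later character;
  pruning removes the lower-MAF variant, then the later position; neighbour
  ties break lexicographically by sample id.
* r² is undefined below 3 complete pairs or off a polymorphic pair;
  callers skip such pairs.
* F_ST is undefined at variants monomorphic across all populations
  (excluded from means) — but *not* at variants fixed for opposite alleles,
  which are maximally informative (F_ST = 1).
* Nm at F_ST ≤ 0 is reported infinite with a warning; Nei distance at zero
  cross-identity is capped; negative NJ branches are clamped with the
  deficit moved to the sister branch.
* ROH length classes are lower-inclusive; ties at class bounds therefore
  land deterministically.
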