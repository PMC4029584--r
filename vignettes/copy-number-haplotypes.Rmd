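---
title: "Copy-number haplotypes from SNP-array intensities: methods notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number haplotypes from SNP-array intensities: methods notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the model implemented by `haplocn`, the tunable
parameters and their defaults, what the synthetic cohort generator does and
does not emulate, and the numerical and design choices made where the
method description left room.

## Model

### Hidden states

Each haplotype at a SNP locus is in one of six allelic states: `A-`, `A`,
`A+`, `B-`, `B`, `B+` (deletion, one copy, amplification of either allele).
Gain states never neighbour loss states on the same haplotype — a segment
of amplification directly abutting a deletion is biologically possible but
rare enough that the degrees of freedom are better spent elsewhere — so 28
of the 36 ordered state transitions are allowed. The diploid hidden state
is the *ordered* pair of haplotype states (36 states); keeping the order
lets haplotype identity be tracked across loci, which is the whole point of
phased copy-number calling. At the first locus, ties between the two
orderings of a pair are broken toward the state earlier in the canonical
enumeration, so runs are reproducible.

### Transitions: the haplotype tree

Population linkage disequilibrium enters through a probabilistic haplotype
tree per chromosome. For each pair of adjacent loci the four haplotype-set
proportions α(A–A), α(A–B), α(B–A), α(B–B) are estimated from the cohort's
3×3 genotype-pair table by EM: only the double heterozygote is
phase-ambiguous, its A–A/B–B resolution probability `q` starts at 0.5 and
iterates with the proportions until |Δq| < 1e-5 (`tol`), at most 1000
iterations. Convergence is judged on `q` because that is the quantity the
stopping rule is stated on. Branch conditionals are
C(y|x) = α(x–y)/(α(x–A)+α(x–B)); a zero marginal yields a flagged uniform
(0.5, 0.5) row so the chain stays stochastic.

Nodes at a level are merged greedily, smallest similarity score first,
whenever the score — the maximum absolute difference of conditional
probabilities over parallel descendants — falls below
`sqrt(1/M_u + 1/M_v)`, roughly twice the standard deviation of such a
difference under a purely random transition process at p = 1/2. Merged
conditionals are count-weighted averages; haplotype counts `M` are carried
as *expected* (fractional) counts, since before the first global iteration
phases are only probabilistic. Merging is restricted to nodes with the same
allele label: the label is what the HMM state at that locus emits, so
cross-label merging would discard the observable the model needs. Scoring
looks one level ahead while merging cascades recursively through parallel
descendants; this one-level scoring horizon is a deliberate simplification
and is flagged for sensitivity analysis.

Because the initial tables are pairwise, histories with identical futures
collapse and the built tree carries two nodes per level — the machinery
matters when nodes with genuinely different futures appear, which the unit
tests exercise on constructed trees.

The merged binary tree is branched into the six states with exponential
distance decay. With inter-locus distance `d` (bp) the persistence of a
normal state is `exp(-d/D_norm)`, of an aberrant state `exp(-d/D_var)`,
with defaults `D_norm = 1e8` and `D_var = 1e5` reflecting that normal
stretches are far longer than aberrant ones. From a normal state the
non-persistent mass is split equally between the gain and the loss target
(symmetry; nothing in the data prefers one direction a priori). Aberrant
states return only to normal. At the first locus there is no distance, so a
configurable prior `p_aberrant` (default 0.01, split between gain and loss)
seeds the aberrant states; 0.01 corresponds to an expected few hundred
kilobases of aberration on a typical chromosome arm, consistent with the
decay-scale assumptions above.

### Emissions: eleven models per SNP

The AA/AB/BB seed clusters anchor a grid in (A-signal, B-signal) space;
eleven bivariate normal models sit on it, one per group of genotype states
with indistinguishable expected signals (`A|A` and `A-|A+` both present two
A copies and no B). M0 and M10 extend the grid one spacing beyond the
homozygote clusters, with the documented equal-distance constraints. The
covariance of a derived model is inherited from the nearest seed cluster
(ties to AB): this preserves cluster-specific noise anisotropy without
introducing free parameters, and is the package's choice where the original
parameter table was not recoverable. Degenerate seed geometry (cluster
means not strictly ordered along an axis) flags the SNP and substitutes a
grid built from cohort-median seed parameters.

Decoding restricts each locus to the member states of the model with the
smallest Mahalanobis distance to the signal (ties to the lower model
index). If the restriction makes a locus unreachable — e.g. adjacent loci
restricted to pure-gain and pure-loss groups — the candidate set expands to
all 36 states at that locus with a warning, rather than failing.

### Global iterations

The pipeline runs `global_iters = 2` passes: the first uses EM tables and
seeded models; before the second, emission models are refit from the
decoded state assignments (models with fewer than two members are re-seeded
by extending the updated M1/M5/M9 grid) and transition tables are
re-estimated from the phased haplotype counts, after which the
distance-decay redistribution is reapplied — the decay structure encodes
prior knowledge about aberrant-segment lengths that raw decoded counts at
one cohort's size cannot replace.

### Regions and copy numbers

Candidate regions are maximal same-direction runs where either haplotype is
aberrant; a locus carrying a gain on one haplotype and a loss on the other
(possible but rare) separates runs of both directions. Filters apply in
order: singletons dropped; same-direction regions separated by at most two
SNPs merged (absorbing the gap); regions with more than 4/5 of SNPs inside
the shaded region dropped; regions of fewer than four SNPs dropped if any
SNP is shaded. The shaded region is realised as the union of the 99%
Mahalanobis ellipses (chi-square with 2 df, boundary inclusive) of M1, M5
and M9 — the picture in the method description is a region covering the
normal clusters, and a quantile ellipse union is its natural parametric
form; the quantile is configurable.

Fractional allele copy numbers interpolate on the model grid anchored at
the heterozygous cluster; when the two per-copy increments differ, the
larger divides, deliberately shrinking estimates toward normal. Negative
estimates clip to zero (copy numbers are physical counts); a non-positive
increment flags the SNP and its copy numbers are reported missing.
Per-haplotype summaries average, across the region, the copy number of the
allele each haplotype carries. At loci where both haplotypes carry the same
allele the combined allele copy number enters both series — the
interpolation cannot split a single allele's intensity between two
chromosomes — so the two haplotype means only sum to the region total where
the haplotypes carry opposite alleles throughout. A region is reported as a
CNV event when its mean total copy number exceeds 3 or falls below 1; for
integer comparisons, fractional values round to the nearest integer with
half-points resolved by the reporting convention 0.5 → 1, 1.5 → 1, 2.5 → 2
(a value of exactly 1.5 is deemed one copy, everything up to 2.5 two
copies). Note the two conventions interact at the boundary: a single-copy
event measured exactly (total 3.0 or 1.0) is *not* reported as an event;
only regions measurably beyond one extra or one missing copy are. This
makes the caller conservative, which shows up in the evaluation as high
region precision at reduced sensitivity.

## The simulator

`simulate_cohort()` builds a stated world: haploid chromosomes as founder
mosaics (8 founders, geometric block switching with mean block length 20
SNPs — block-structured linkage is the statistical skeleton the
tree-based phasing assumes), each haploid implanted with 3 non-overlapping
CNV events of 10–50 SNPs (gains and losses equally likely), paired at
random into 90 diploids of two *distinct* haploids, over 2000 SNPs spaced
uniformly 500–3500 bp apart. Intensities are drawn from the bivariate
normal of the true state's emission model on a per-SNP jittered center grid
(grid spacing 0.9 intensity units, isotropic noise SD 0.2 — a 4.5 SD
cluster separation, i.e. clean modern-array data); the 3-copy grid position
extrapolates the spacing exactly as the M0/M10 model extension does. The
rough genotype input is a naive nearest-cluster call with a 1% no-call
rate, standing in for an external genotyping algorithm whose error model is
not otherwise specified.

What a green end-to-end test does *not* establish: the generator emits from
the same distributional family the caller assumes (no GC waves, no batch
effects, no tumour-normal admixture, no LRR/BAF transformation losses), so
recovery ratios here are an upper bound on real-array behaviour. Truth
regions are defined directly on the implanted states, and the evaluation is
nested — region overlap (Rregion), correct rounded total CN among
overlapping regions (Rtotal), correct rounded allele CNs among SNPs of
correct-total regions (Rspecific), correct phase among correct-allele SNPs
with haplotype labels matched by the better of the two global assignments
per region (Rhap, labels being arbitrary up to a swap).

## Numerical choices

- All Viterbi arithmetic is in log space; chains of 1e5 loci cannot
  underflow.
- Conditional tables feeding the tree are floored (1e-4 after EM, a
  half-count pseudocount on phased-count tables) so that no haplotype
  transition is ever strictly impossible: a hard zero would force the
  decoder to move an aberration to the other haplotype rather than cross
  the zero, manufacturing switch errors from sampling noise.
- Singular covariances (degenerate member sets, identical signals) are
  ridge-regularised with `1e-6 * trace/2` (floored at 1e-8) on the
  diagonal, with a warning.
- Mahalanobis and density computations use the closed-form 2×2 inverse.
- Ties everywhere resolve to the lowest index (genotype code, model id,
  state enumeration) so all outputs are deterministic; re-running with the
  same seed and configuration reproduces outputs byte for byte.

## Known limitations

- Phasing accuracy at zero-copy loci: when an allele is fully deleted the
  signal carries no information about *which* allele was lost at
  homozygous-looking sites, so the decoded letter rests entirely on
  first-order linkage; residual phase errors concentrate there and at
  re-entry points after a mis-decoded normal SNP inside a region, where a
  first-order chain has no memory of which haplotype carried the event.
- The tree collapses to a first-order chain under pairwise re-estimation;
  longer-context clustering (true variable-length contexts from sampled
  haplotypes) would sharpen phasing but is not implemented.
- CN-only (non-SNP) probes, array preprocessing/normalisation, pedigree
  constraints and tumour-purity deconvolution are out of scope.
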