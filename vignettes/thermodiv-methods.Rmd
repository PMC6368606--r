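---
title: "Methods behind thermodiv: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind thermodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodiv)
```

`thermodiv` compares chemosynthetic hot-spring community metagenomes
along three axes: how many protein families they encode, how their KO
(KEGG Orthology) functional profiles differ, and how their recovered
genomes partition metabolic labor within lineages. This vignette
documents the models and conventions behind each stage, the parameters a
user might want to change, and what the synthetic validation does — and
does not — establish about behavior on real data.

## Protein-family binning

Predicted proteins longer than 50 amino acids (strictly; a 50-residue
protein is excluded) are clustered greedily: sequences are sorted by
decreasing length, ties broken lexicographically by identifier, and each
sequence either joins the best-matching existing cluster representative
or founds a new cluster. A sequence may join a representative when the
optimal local alignment between them has identity at or above the level
threshold *and* covers at least 80% of the shorter sequence. Among
qualifying representatives the highest-identity one wins (best-fit
rather than first-fit assignment), with ties resolved toward the longer
representative and then lexicographically, so the procedure is fully
deterministic.

Alignments use BLOSUM62 with affine gap penalties (open 11, extend 1;
a gap of length L costs 11 + L). The scheme is stated explicitly because
the identity criterion inherits it: identity is the fraction of
identical residue pairs over all aligned columns, *including* internal
gap columns in the denominator — a conservative and symmetric
convention. When no positive-scoring local alignment exists, identity
and coverage are reported as 0 and the pair can never co-cluster.

The cascade clusters the full data set at 90% identity, the resulting
representatives at 60%, and their representatives at 30%, propagating
membership downward; each level is therefore a coarsening of the level
above, and family counts can only decrease along the cascade. All three
levels apply the same alignment criterion; at 30% the criterion is a
positive-scoring local alignment at ≥30% identity and ≥80% coverage of
the shorter sequence (an alignment-significance cutoff by e-value would
require a database-size model, which is out of scope here; the
alignment-based criterion is the documented, configurable alternative).
No k-mer prescreening is applied: correctness is defined by the
alignment criterion alone, and at the problem sizes this package
targets the exact computation is affordable.

Family abundance is the per-metagenome member count of each final
family, with explicit zeros. An alternative reading of
"abundance-weighted" counts — weighting members by read coverage — is
not implemented; member counts are the convention used throughout.

## Rarefaction and the diversity–geochemistry regression

Rarefied richness subsamples each metagenome's proteins *without
replacement* and counts distinct families, reporting the mean and
standard deviation over `n_reps` replicates (default 100; the acceptance
analyses use 1000). The analytic companion `expected_richness()` is the
hypergeometric expectation

$$E[S] = \sum_f \left[1 - \frac{\binom{N-N_f}{d}}{\binom{N}{d}}\right],$$

evaluated in log space via `lchoose()` so large counts do not overflow.
The Monte-Carlo mean is an unbiased estimator of this quantity; the test
suite verifies agreement within three Monte-Carlo standard errors across
randomized fixtures, with a small absolute floor (1e-4) for
near-exhaustive depths where the replicate richness is almost surely
constant and the standard-error band degenerates to zero.

Fixed-depth comparison across springs uses a common subsampling depth
(the field convention is on the order of 10,000 proteins per metagenome;
at the scales of this package's examples, depths are set relative to the
smallest sample). The regression of richness on the fluid-mixing proxy
log10(SO4/Cl) is ordinary least squares with a single predictor, as the
comparison is deliberately univariate: temperature and pH are carried in
the geochemistry table but not modeled. Reported statistics are the
slope, intercept, R², adjusted R² $= 1-(1-R^2)(n-1)/(n-2)$, the model
F-test p-value, and n after listwise deletion of springs lacking either
richness or defined geochemistry (deletions are counted in the fit
object).

## KO profiles: normalization, enrichment, ordination

KO counts are normalized within each metagenome to frequencies summing
to 1, compensating for unequal sequencing effort. The enrichment of KO
k in sample s is

$$E_{k,s} = \frac{a_{k,s} - \bar a_k}{\bar a_k},$$

with $\bar a_k$ the across-sample mean of the normalized abundance. Two
analytic bounds follow directly and are used as acceptance checks: a KO
present in exactly one of S samples attains $E = S-1$ there (14 for 15
samples), and a KO absent from a sample scores exactly −1 there. KOs
with zero abundance everywhere would give 0/0 and are dropped (and
reported) before the computation.

Category subsetting restricts a table to KOs labeled with a top-level
category or subcategory (e.g. the "Energy Metabolism" subcategory of
Metabolism). Subsetting does not commute with normalization — the
totals differ — so the order is left to the caller and both orders are
legitimate for different questions.

Bray–Curtis dissimilarity $\sum_k|x_k-y_k| / \sum_k(x_k+y_k)$ is
computed on normalized frequencies by default (`vegan::vegdist`
underneath), and ordinated by classical PCoA: Gower double-centering of
$-d^2/2$, eigendecomposition, coordinates scaled by the square root of
the positive eigenvalues. Bray–Curtis matrices are generally
non-Euclidean, so negative eigenvalues occur; they are reported and
their axes omitted, with no Cailliez/Lingoes correction — the simplest
documented convention, adequate at this scale. Axis signs are fixed by
forcing the largest-magnitude coordinate on each axis positive, so
repeated runs produce identical ordinations. Whether to ordinate
normalized frequencies or a further per-KO standardization is a genuine
modeling fork; the normalized-frequency reading is implemented.

## MAG filtering, abundance and within-lineage differentiation

Quality filtering keeps bins with completeness strictly above 50% and
contamination strictly below 7%. Relative abundance follows a
three-step recipe: coverage = mapped reads / assembled length; the
estimated genome size multiplies coverage back up, where genome size is
estimated as assembled length divided by the completeness fraction (a
first-order correction; if an external size estimate is available it can
replace the column); each bin's product is then expressed as a fraction
of the summed products. Abundances sum to 1 and are invariant to
uniform rescaling of read counts.

Differentiation between two related genomes is summarized per KO
category as the ratio of unshared to shared KOs, where "unshared" is the
symmetric difference of the two KO sets (both directions pooled, giving
one ratio per pair; per-genome unique counts are also emitted for
inspection). Plotting the Metabolism ratio against the Genetic
Information Processing ratio separates metabolic differentiation from
the conserved-background expectation: genetic-processing complements of
close relatives should differ little, so points above the 1:1 line
indicate genuine metabolic differentiation. A category with no shared
KO yields an undefined ratio (flagged, not infinite). KOs missing from
the category map are ignored and counted, since the statistic is defined
over annotated proteins only.

AAI aligns all proteins of one genome against all of the other,
takes reciprocal best hits by alignment score, discards hits under 20%
identity or 50% coverage of the shorter sequence (the cited toolkit
convention; both configurable), and reports the mean ± sd best-hit
identity as percent.

## Tree metrics

Root-to-tip distance sums branch lengths along the unique root-to-tip
path. The branch-length contribution of a tagged tip set is reported in
two modes because the natural-language notion ("these genomes contribute
x% of the branch length") is ambiguous: `"exclusive"` counts every edge
whose entire descendant tip set lies within the tagged set (terminal
branches plus internal edges of wholly tagged clades), `"tip_only"`
counts only the tagged terminal branches. Exclusive mode dominates
tip-only and is monotone under tip-set inclusion; it is the default,
and neither mode is asserted to be *the* published computation.
Unrooted input is accepted with its basal node treated as the root,
with a warning.

## The synthetic-study generator

The generator exists so that every downstream stage can be validated
against known truth. Its defaults define the package's reference study
conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `n_springs` | 40 | springs/metagenomes per study |
| `pool_size` | 120 | global protein-family pool |
| `richness_intercept` / `richness_slope` | 30 / 8 | families, families per log10(SO4/Cl) unit |
| `richness_noise_sd` | 2 | Gaussian noise on planted richness (families) |
| `abundance_shape` | 1 | lognormal σ of family member counts |
| `family_identity` | 0.95 | member identity to family founder |
| `between_identity_max` | 0.25 | ceiling on founder pairwise identity |
| `seq_length` | 150 | protein length (aa) |
| `n_ko` / `n_categories` | 200 / 4 | KO universe, category count |
| `exclusive_ko_count` | 3 | planted single-metagenome KOs |
| `pair_shared_fraction_met` / `_gen` | 0.5 / 0.8 | shared-KO fractions of planted genome pairs |
| `tree_tips` / `tagged_fraction` | 60 / 0.1 | tree size, tagged tip proportion |

Choices worth explaining:

- **Geochemistry** is drawn log-uniform (sulfate 5–200 mg/L, chloride
  0.5–500 mg/L), spanning roughly −2 to +2.6 in log10(SO4/Cl) — the
  full vapor-to-reservoir mixing axis observed across such spring
  systems, bracketing the high-sulfate/low-chloride regime typical of
  vapor-influenced springs.
- **Family abundances** are lognormal (σ = `abundance_shape`, counts
  rounded up to at least one member). Field data show strongly skewed
  rank–abundance structure, which lognormal captures qualitatively; no
  specific distribution is canonical for protein-family member counts,
  so this is a documented stand-in.
- **Planted richness** is the linear link plus Gaussian noise, rounded
  and clamped to [1, pool_size] rather than erroring, so extreme noise
  draws remain usable. With default settings the clamp is never active,
  leaving the regression target unbiased.
- **Family structure**: members are generated by substituting exactly
  `round((1-identity)·length)` positions of the founder, each to a
  different residue, so planted identities are exact by construction;
  founders are rejection-sampled until all pairwise ungapped identities
  fall below `between_identity_max`. Members of one family are then
  mutually ≥ ~0.90 identical while cross-family alignments cannot reach
  the 30% identity / 80% coverage criterion, so the cascade is expected
  to recover the planted partition exactly — which the validation
  verifies rather than assumes.
- **KO tables** draw Poisson(3) counts, then force every non-exclusive
  KO to occur in at least two metagenomes and every exclusive KO in
  exactly one, so "columns with a single nonzero entry" identifies the
  planted exclusives exactly. KO→category assignment is balanced then
  shuffled, so category sizes are a deterministic property of the
  configuration.
- **Determinism**: a study is a pure function of its configuration
  (seed included); generation saves and restores the caller's RNG
  state.

What the generator does *not* emulate: read-level error, assembly
fragmentation and chimerism, binning contamination, paralogy and domain
shuffling within families, annotation error in KO assignment, or
phylogenetic correlation between the tree and the proteomes. Passing
validation on synthetic studies therefore establishes the correctness of
the computations under clean, well-separated conditions — not robustness
of the upstream reconstruction steps, which are outside this package's
scope (it consumes their outputs).

## Validation design and problem sizes

The test suite pairs every computation with an independent oracle: a
hand-rolled affine-gap Smith–Waterman dynamic program for alignment
scores; direct character comparison for planted identities; exhaustive
or closed-form enumeration for rarefaction; normal-equation algebra for
the regression; the textbook formula for Bray–Curtis; Euclidean
reconstruction for PCoA; set arithmetic for differentiation; naive
recursive edge enumeration for tree fractions. Statistical recovery is
checked at moderate scale — 50 clustering fixtures of ≤30 sequences,
100 replicate 40-spring studies for slope recovery, 100 seeds for the
differentiation geometry, 100 random 20-tip trees — sizes chosen so the
full suite completes within a few minutes while the Monte-Carlo checks
retain enough replication (1000 rarefaction replicates, 3-standard-error
bands) to be diagnostic.

## Known limitations

- Greedy incremental clustering is order-dependent in principle; the
  length-then-identifier processing order makes it deterministic, and
  order-invariance is guaranteed (and tested) only for well-separated
  inputs whose identity structure straddles the thresholds cleanly.
- The alignment-criterion 30% stage is a deliberate, documented
  replacement for an e-value cutoff; at very short sequence lengths the
  two can disagree.
- `expected_richness` assumes exchangeable draws within a metagenome;
  it says nothing about spatial or library-preparation structure.
- Bray–Curtis PCoA discards negative-eigenvalue axes; with strongly
  non-Euclidean matrices the retained axes understate total structure.
- AAI here is alignment-exhaustive and intended for the package's
  proteome sizes; for genome-scale proteomes a heuristic search tool
  would be used upstream and its hits fed to the same RBH logic.
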