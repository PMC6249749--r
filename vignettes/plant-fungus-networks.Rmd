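---
title: "Community-scale structure of below-ground plant-fungus networks"
author: "mycorrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-scale structure of below-ground plant-fungus networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycorrnet)
```

## The analysis in one paragraph

Root metabarcoding surveys yield, per forest, a matrix of sequencing read
counts with one row per terminal-root sample and one column per fungal OTU,
plus the host plant species/taxon of each sample. `mycorrnet` turns such
tables into plant-by-fungus *association matrices* (cell = number of
samples linking a plant to an OTU), partitions them by fungal functional
guild, quantifies their architecture with four structural indices
(connectance, H2' interaction specificity, weighted NODF nestedness, and
the checkerboard C-score), standardizes each index against a sample-level
host-label-shuffle null model, and compares the resulting "relative
indices" across forests and network categories with ANOVA and
correlation-matrix PCA. A synthetic-data generator emulating this sampling
design makes the whole pipeline testable end to end.

## Preprocessing

Three steps, applied in this order per forest:

1. **Rare-entry filter.** A cell is zeroed iff its reads are *less than*
   0.1% of its sample's total (strict inequality; cells exactly at the
   threshold are kept). Such entries typically derive from soil
   carry-over or PCR/sequencing error. The comparison always uses the
   pre-filter sample total, and filtered columns are retained (all-zero
   columns are only pruned when species matrices are built) so that
   sample-level label shuffling remains well defined.
2. **Rarefaction.** Samples with fewer than 1000 reads are dropped; the
   rest are subsampled without replacement (multivariate hypergeometric)
   to exactly 1000 reads, removing depth as a confounder of richness.
3. **Equal sampling effort.** Each forest is reduced to 240 samples drawn
   uniformly without replacement (or all samples when fewer are at depth),
   so cross-forest comparisons are not driven by sample counts.

Applying the pipeline twice with the same parameters and seed changes
nothing after the first pass: all totals already equal the depth, so the
0.1% threshold corresponds to less than one read, and the subsample is the
identity.

Accumulation curves use the analytic expectation of OTU richness in a
uniformly drawn subset of k samples (the deterministic, sample-based
rarefaction formula) rather than random permutations, so curves carry no
Monte-Carlo noise.

## Network categories

The `ALL` matrix contains every plant and OTU. Guild-specific partial
networks keep the OTUs of one guild: `AM`, `ECM`, `PATHO`, `SAPENDO`.
Two further categories restrict the plant side as well: `AM_EX` keeps
arbuscular-mycorrhizal fungi with `AM_PLANT` and `DUAL` hosts only, and
`ECM_EX` keeps ectomycorrhizal fungi with `ECM_PLANT` and `DUAL` hosts,
representing the classically defined symbioses. Plants documented to host
both symbiosis types (`DUAL`) are retained in both exclusive networks,
because exclusion lists name non-arbuscular-mycorrhizal and
non-ectomycorrhizal plants only; plants without an annotation are treated
as non-mycorrhizal (conservative exclusion) with a warning. Guild strings
from functional-guild databases are mapped to the five-value vocabulary
with precedence ECM > AM > PATHO > SAPENDO, so combined annotations
resolve to one exclusive guild and saprotroph-endophyte combinations pool
into `SAPENDO`.

## The structural indices

Let $a_{ij}$ be the association count of plant $i$ and OTU $j$, $m =
\sum a_{ij}$.

**Connectance** is the fraction of realized links, $\sum [a_{ij} > 0] /
(IJ)$.

**H2'** measures network-level interaction specificity. With $p_{ij} =
a_{ij}/m$, the two-dimensional entropy is $H_2 = -\sum p_{ij} \ln
p_{ij}$, and
$$H_2' = \frac{H_{2,max} - H_2}{H_{2,max} - H_{2,min}} \in [0, 1],$$
where the extremes are the minimum and maximum entropy achievable by
*integer* matrices with the observed marginal totals. The maximum is
found by an even-distribution heuristic — largest-remainder rounding of
the continuous expectation $r_i c_j / m$ under the marginal constraints,
then 2x2 swap moves that increase entropy until none improves — and the
minimum by a greedy concentration heuristic (repeatedly place
$\min(\text{row remainder}, \text{column remainder})$ at the largest
remaining marginals), followed on small matrices by entropy-decreasing
swap moves. On matrices small enough to enumerate exhaustively the
heuristics agree with the true extremes to well under 0.01 on the H2'
scale (the test suite checks this); on large matrices the same rules are
applied consistently to the observed and all randomized matrices, which
is what the relative index needs. Entropies are in natural log; H2' is
scale-free so the base cancels. Two caveats follow from the integer
constraint: H2' is exactly invariant under row/column permutation but
only approximately invariant under multiplying all cells by a constant,
and matrices whose marginals admit a single distribution (e.g. one
nonzero row) have no defined H2'.

**Weighted NODF** (0-100) asks whether poorer rows/columns are weighted
subsets of richer ones. For each unordered pair of rows (and of columns),
the member with the *strictly* larger marginal total is the richer; the
pair scores $100 \times \#\{j : 0 < a_{vj} < a_{uj}\} / \#\{j : a_{vj} >
0\}$ and tied totals score 0. The index is the mean over all row and
column pairs. Note that a popular implementation gates pairs on binary
fill rather than marginal totals; the two agree whenever the orderings
coincide (the tests cross-check on such matrices) but differ on ties, so
the totals-based rule used here is stated explicitly.

**Checkerboard C-score** measures host-range differentiation within the
fungal community. The matrix is binarized; an OTU pair with host ranges
$r_i, r_j$ and $S_{ij}$ shared hosts contributes $(r_i - S_{ij})(r_j -
S_{ij})$ checkerboard units, and the score is the raw mean over OTU
pairs. Binarization is the standard convention for this index; no
per-pair normalization is applied because only null-standardized values
are interpreted, and any constant factor cancels in the z-score.

Degenerate matrices (fewer than two plants or two OTUs) are refused by
all indices; `networkSummary()` still reports their node counts and
records the failure reason, encoding undefined indices as missing rather
than zero.

## The null model and relative indices

Randomized matrices are obtained by permuting the host plant labels
across samples within a forest and re-aggregating, leaving every sample's
OTU profile intact. This conserves per-sample read totals, per-OTU
prevalence, and the number of samples per plant — the null keeps
everything about the data except which plant each root fragment belonged
to. An observed index $I$ is standardized as
$$z = \frac{I_{obs} - \mathrm{mean}(I_{rand})}{\mathrm{SD}(I_{rand})},$$
with the sample (n-1) standard deviation, the standard convention for
null-model z-scores (fixed by a regression test). Scores above roughly 2
(below -2) indicate an index larger (smaller) than expected by chance;
negative relative nestedness is the "anti-nested" signature. Conventional
randomization counts are 1000 for H2' and nestedness and 100 for the
costlier checkerboard score; each metric draws its own ensemble.
Randomizations that produce degenerate matrices are skipped and counted,
never imputed, and an ensemble with more than half failures is rejected.

For the exclusive categories the default (`nullScope = "full"`) shuffles
labels first and then applies the plant-exclusion rules to the randomized
table, staying faithful to "shuffle, then convert"; a `"within-category"`
scope that removes excluded plants before shuffling is provided as a
logged switch.

Determinism is engineered in: every stochastic stage keys its randomness
on child seeds derived from stable identifiers (sample ids for
rarefaction and subsampling, permutation indices for ensembles), so
results are independent of input row order, the first $k$ ensemble values
never depend on the total count, and serial and parallel execution of
permutations agree bit-for-bit.

## Cross-site comparison

The property table holds one row per (forest, category) with node counts,
the fungus/plant ratio, connectance, and the three relative indices. Each
relative index is modelled as
`response ~ n_plants + n_otus + connectance + locality + category`
with sequential (type-I) sums of squares in that order — diversity and
connectance first, so the factors are tested on what remains — and
Bonferroni correction across the five terms of each model. Marginal
(drop-one) tests are available as an option; the degrees of freedom
(locality: forests - 1, category: 6, covariates: 1) depend only on the
design. Rows with missing values are dropped listwise per response. The
PCA uses the correlation matrix (all seven descriptors standardized), with
a deterministic sign convention making each component's largest loading
positive.

## The synthetic generator

`syntheticConfig()` emulates the intended sampling design: 8 forests, 383
root samples collected per forest, 17-55 plant species/taxa per forest
drawn from a 55-taxon pool with geometric abundances (a few dominant
hosts, many rare), 1120 OTUs across the guilds (including a deliberately
small pathogen guild, mirroring how few pathogenic OTUs such surveys
annotate), negative-binomial read depths with mean 1500 (so rarefaction
at 1000 drops a realistic minority of samples), and Poisson contamination
adding single-read entries that the 0.1% filter should remove. A plant's
affinity over OTUs combines a guild-compatibility mask (mycorrhizal fungi
require hosts of their symbiosis type; other guilds are unrestricted),
power-law OTU generalism weights, per-plant Dirichlet noise whose
concentration `specialization_alpha` tunes host specificity, optional
per-plant host breadths (nested regimes), optional block compartments
(anti-nested, host-differentiated regimes), and a leakage mass `eps`
placed outside the compatible set.

`exchangeableConfig()` overrides all of this with one shared affinity
vector, making fungal composition independent of the host — the
host-label-shuffle null is then *exactly* true, which is what the
calibration tests exploit: across 200 replicate datasets the relative
indices must stay within ±2 for at least 90% of replicates.

Two honest limitations of the generator. First, it produces no
phylogenetic signal, no spatial autocorrelation between neighboring
samples, and no sequence-level artifacts, so passing tests say nothing
about those features of real surveys. Second, under a sample-level
label-shuffle null, *any* host-structured affinity — compartmentalized or
nested — reduces the number of distinct plant-OTU combinations relative
to its randomizations and therefore tends to depress relative nestedness;
positive relative wNODF is only approached in the host-independent limit.
This matches the empirical observation that below-ground networks
assessed against this null rarely look nested, and it is why the
structure-recovery tests anchor on the anti-nested and specialized
regimes rather than on a strongly nested one.

## Problem sizes used by the tests

The test suite exercises the pipeline at deliberately reduced scale:
calibration uses 200 replicates of 240 samples x 300 OTUs x 20 plants
with 200/200/50 randomizations, and structure recovery uses 50 replicates
per setting of 120 samples x 150 OTUs x 12 plants with 100/50
randomizations. These sizes keep the full suite comfortably fast while
leaving every code path — including the rarefaction drop and degenerate
category handling — exercised; analyses of real data would use the
conventional 1000/100 randomizations via the defaults.
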