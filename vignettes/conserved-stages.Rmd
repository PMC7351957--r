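---
title: "Methods: scoring cross-species stage conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring cross-species stage conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The question and the statistic

Comparative developmental transcriptomics asks which part of embryogenesis
is most conserved across related species. Stages do not align one-to-one
across species — development is heterochronic and stage counts differ — so
instead of fixing an alignment the analysis scores *stage combinations*:
every way of choosing one developmental stage per species. A combination
whose expression profiles are mutually similar is evidence that those
stages correspond to a conserved transcriptomic state.

Dissimilarity between two whole-embryo profiles over shared ortholog
groups is the expression distance

```
expdist(x, y) = 1 - rho(x, y),
```

with `rho` the Spearman correlation, computed as the Pearson correlation
of average ranks. Ranks make the measure invariant under strictly
monotone transforms, so no log transform and no expression-level
prefilter are applied: they would not change any result. `expdist` lies
in [0, 2]; a constant profile has all-tied ranks and an undefined
correlation, which is raised as an error (never silently treated as 0).

## Tree-aware combination scoring

Scoring a combination by the mean of all pairwise distances
over-weights densely sampled clades: two sister species contribute as
much as two deeply diverged ones. The package therefore scores each
combination along the rooted binary species tree by progressive profile
averaging. In a post-order traversal, each internal node

1. accumulates `expdist(left profile, right profile)`, and
2. passes the element-wise arithmetic mean of the two child profiles
   (on the TPM scale) to its parent.

The combination's score is the sum over internal nodes; each split of
the tree contributes exactly one comparison. For two species this
reduces identically to the pairwise `expdist`. The mean-profile rule is
the package's own formulation of tree-aware comparison: it is the
simplest ancestral-profile proxy, is exactly testable against a naive
re-implementation, and keeps every node comparison on the same [0, 2]
scale. Branch lengths are deliberately ignored (topology only): the
published analyses this mirrors name only the topology, and weighting
by uncertain branch lengths would add a free parameter with no oracle
to check it against.

All `prod(stages per species)` combinations are scored exhaustively, in
lexicographic stage-index order over the tree's left-to-right leaf
order. A guard (`cap`, default 1e7) forces the user to acknowledge
combinatorially large products. The exhaustive scorer shares
intermediate node profiles across combinations and ranks profile columns
in compiled code; it is exact, not approximate, and a unit test pins it
bitwise (on ranks) to a naive double loop.

## Ptop, BRI resampling and the Friedman test

For a top fraction `q` (default 0.01), the top set is the
`n_top = max(1, round(q * N))` combinations with the smallest total
distance; distance ties at the cutoff are broken by enumeration order so
results are exactly reproducible (reproducibility is preferred over
statistical purity here; ties are measure-zero for continuous data).
`Ptop(species, stage)` is the percentage of top combinations containing
that stage. Because every combination contributes exactly one stage per
species, Ptop sums to 100 within each species — an invariant asserted in
the tests to 1e-9.

Replicate-level uncertainty is quantified by biological-replicate-
included (BRI) resampling: `B = 100` tables, each picking one replicate
uniformly at random per (species, stage), independently across stages,
species and tables (the same replicate may be picked in many tables —
independence is the natural reading of random picking). Ptop is computed
independently within each BRI table; the mean and sample SD over tables
are reported. Stage effects are tested per species with a Friedman rank
test — blocks are the B BRI tables, treatments that species' stages —
using the tie-corrected statistic

```
chi2_F = (k - 1) * sum_j (R_j - B(k+1)/2)^2 / (A - B k (k+1)^2 / 4)
```

(`R_j` rank sums, `A` the sum of squared ranks), which reduces to the
classical `12/(Bk(k+1)) * sum R_j^2 - 3B(k+1)` without ties and is
verified against `stats::friedman.test` on random matrices. If every
block is completely tied the denominator vanishes and the statistic is
reported as 0 with a warning.

### What the Friedman test does and does not test

The blocks of this test are resamples of *one* dataset, not independent
datasets. The test therefore answers: "in this dataset, do stages differ
in Ptop beyond what replicate choice explains?" It does *not* test
whether the generative process favours any stage. The distinction
matters under a flat (null) divergence profile: each simulated dataset
still has realized, noise-induced stage differences — the divergence
draws and the two or three replicate values per stage are fixed once the
dataset exists — and every BRI table sees those same differences. The
test then rejects essentially always, and correctly so for its own null.
The acceptance computations measure this dataset-level rejection rate
under a flat profile explicitly; a reader should not interpret the
per-dataset Friedman p-value as evidence about the evolutionary process,
only about stage structure in the data at hand. Calibration at the
process level would require independent datasets as blocks, which is a
different design than BRI resampling.

## Group membership and aggregation choices

- A group enters a taxon level's analysis only if present in **all**
  species of that level (set intersection) — the strictest reproducible
  membership rule; level-specific group counts then fall out of the data
  rather than an imputation scheme. Imputing zeros for missing groups
  was rejected because zeros carry rank information that absent
  measurements do not have.
- When a group maps to several genes in a species, the group value is
  the **sum** of member-gene TPMs per stage-replicate: it preserves
  total signal and is what a collapsed ortholog-group quantification
  produces.
- Ptop's top set is selected within each BRI table separately, then
  summarized across tables; the SD therefore reflects replicate-choice
  uncertainty of the whole top-set computation, not merely of the
  distances.

## The synthetic-data generator

The generator emulates the study design the package targets: four
species related as `(Anj,(Apj,(Sp,Lv)))`, ten stages per species, two
biological replicates, 1000 ortholog groups, TPM-scale values. Per
group, an ancestral log-expression trajectory over a common pseudo-time
in [0, 1] is drawn as a smooth random curve (standard-normal values at
10 equispaced knots, natural cubic spline onto a 100-point grid; one
basis matrix serves all groups, so generation is vectorized and exactly
reproducible). Along each tree branch the trajectory is perturbed by an
independent smooth Gaussian curve scaled pointwise by
`divergence_profile(t) * branch length`; a shared profile across species
keeps the number of free knobs small. Species stage `i` of `S` sits at
pseudo-time `(i - 1)/(S - 1)` — the simplest alignment of heterochronic
stage grids. Replicates receive multiplicative lognormal noise
(`noise_sd = 0.3` on the log scale, a typical bulk RNA-seq
replicate-level dispersion), and every stage-replicate column is
rescaled to 1e6, matching TPM semantics.

The hourglass profile is a Gaussian dip,
`sigma(t) = sigma_max - (sigma_max - sigma_min) * exp(-(t - 0.5)^2 / (2 * 0.15^2))`
with `sigma_min = 0.1`, `sigma_max = 0.8` per unit branch length: strong
enough that mid-development is clearly most conserved, weak enough that
replicate noise is not negligible. The designated conserved window is
the set of stages whose divergence scale is within 25% of the profile's
range above its minimum; with ten stages this yields the two central
stages. The flat profile uses the mid-range constant `sigma = 0.45`.

What the generator does **not** emulate: paralog expression divergence,
alternative splicing, read-level artefacts (no indels, no quality-score
model in the read simulator), library-composition biases, or missing
stages. Passing tests therefore demonstrate the statistical machinery on
clean, correctly normalized input — not robustness to quantification or
annotation error in real data.

Proteome simulation draws one random 200-aa sequence per group, mutates
it along the tree (substitution only, uniform over the other 19
residues), and emits all-vs-all 12-column hit tables in which
within-group hits carry `bitscore = 2 * matching residues`, optional
decoy paralogs are extra-mutated copies scoring below their source, and
cross-group background hits score in a clearly lower band. Read
simulation samples fixed-length reads uniformly from both strands of a
uniform-random genome with per-base substitution errors.

All generators run from one root seed with fixed per-component offsets
(+1 expression, +2 proteomes, +3 reads), so components are individually
reproducible.

## Orthology, rates, loss and genome size

**RBBH.** Best hits use bitscore as the primary criterion (length-
normalized and the community default; e-value ties, then lexicographic
subject order break the remaining ties deterministically), after an
e-value ≤ 1e-5 filter. Multiple HSPs of a query-subject pair collapse to
the best-scoring row. One-to-one sets are anchored on a reference
species and require a reciprocal partner in every other species. No
additional identity or coverage floors are imposed beyond the e-value
filter — adding them would silently change set counts.

**Relative rates.** Tajima's test is implemented in its simple
count-based form at the residue level: sites with any gap/ambiguity in
the triplet are skipped; `chi2 = (m_A - m_B)^2 / (m_A + m_B)` with one
degree of freedom, no continuity and no multiple-hit correction. With
`m_A + m_B = 0` the test is flagged undefined rather than given a
p-value.

**Loss screen.** A gene is "present" on a strictly-greater-than basis
(identity > 50%, align ratio > 30%); the align-ratio denominator is the
query (anchor-side) length, the convention for detecting partial
homology of the anchor. A gene is "lost" iff present in at least one
comparison species and in no ingroup species; genes absent everywhere
are not reported. The screen operates on whatever anchor identifiers the
input uses (genes or domains).

**Genome size.** Canonical (strand-neutral) k-mers, odd `k = 17`. The
error valley is the first depth where the count rises
(`count(d) < count(d+1)`); the coverage peak is the argmax above the
valley, ties to the smaller depth. The k-mer number excludes the error
mass at and below the valley before applying
`size = kmer_number / peak_depth`; without that exclusion the error mass
inflates the estimate on any realistic error rate. Counting is
in-memory (sorted-token tallying), intended for survey-scale inputs up
to a few tens of Mb of reads, not for full vertebrate-genome libraries.

## Problem sizes used by the checks

The package's own verification uses: hourglass recovery on 20 datasets
of 1000 groups × 10 stages × 2 replicates with B = 100 (argmax of mean
Ptop inside the designated window); flat-profile behaviour on 100
datasets of 600 groups × 8 stages with B = 100; exact-match oracles on 3
species × 4 stages (64 combinations); RBBH truth recovery on 40 groups
with and without decoys; and genome-size recovery on a 100 kb genome at
40× coverage with and without 0.5% substitution error. These sizes were
chosen so that every property is exercised end to end while the whole
suite stays comfortably runnable on a laptop.

## Known limitations

- The progressive-averaging tree score is a declared design choice, not
  a reconstruction of any particular published formula; other tree-aware
  weightings (branch-length-weighted averages, ancestral-state
  reconstruction under a model) would be drop-in replacements at the
  node-comparison step.
- The per-dataset Friedman test's null is conditional on the dataset
  (see above); it cannot certify process-level flatness.
- Exhaustive enumeration is exponential in the number of species; four
  species with 10–17 stages each is comfortable, ten species is not.
- `expdist` requires at least three shared groups and errors on constant
  profiles; combinations touching a constant profile are excluded from
  the top-set computation with a warning rather than imputed.
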