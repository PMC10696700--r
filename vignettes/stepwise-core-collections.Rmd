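---
title: "Stepwise core collections from pedigree-genomic relationships: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise core collections from pedigree-genomic relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcore)
```

# The model

`stepcore` builds a core collection — a minimal subset of a breeding
program's germplasm that represents its genetic variation — in two
stages: a *manual* stage that fixes mandatory entries, and an
*optimization* stage that fills the remaining slots by minimizing the
accession-to-nearest-entry criterion on a hybrid pedigree-genomic
distance matrix. This vignette records the statistical model, the
tunable parameters, and every place where the design was genuinely open.

## Pedigree relationships (A)

The additive relationship between genotypes $i$ and $j$ is the expected
identity-by-descent sharing of their alleles,
$$a_{ij} = \tfrac12\left[(i_1,j_1)+(i_1,j_2)+(i_2,j_1)+(i_2,j_2)\right],$$
where $(x,y)$ is the probability that alleles $x$ and $y$ descend from
the same ancestral copy. `amatrix()` evaluates this exactly by the
tabular recursion in canonical (parents-before-offspring) order;
inbreeding enters through the diagonal $a_{ii} = 1 + F_i$. No
Meuwissen–Luo style sparse optimization is used: the dense recursion is
$O(n^2)$ in memory and entirely adequate at breeding-program scale
($n \approx 10^3$–$10^4$).

Unknown parents contribute zero. Both the empty field and `"0"` are
accepted as unknown-parent sentinels, because both conventions occur in
breeding exports; individuals appearing only as parents are registered
as founders, since real programs span many decades and the oldest
generations are routinely unrecorded.

**Pedigree completeness** is the row sum of the directional matrix
$A^*$, which keeps an individual's relationships to its own ancestors
(any depth) and zeroes everything else. In a non-inbred fully recorded
pedigree every ancestral generation contributes exactly 1 (two parents
at 0.5, four grandparents at 0.25, ...), so the value reads as "number
of fully known generations". "Ancestor" means reachable through parent
links at any depth — not only parents — which is the reading consistent
with counting grandparent contributions; the alternative parents-only
reading that sometimes appears in figure captions would simply truncate
the sum at one generation.

## Genomic relationships (G) and curation

`vanraden_g()` computes $G = ZZ'/(2\sum_i p_i(1-p_i))$ with
$Z = M - 2P$ and $p_i$ the alternate-allele frequency of marker $i$
*in the analyzed set itself* (no external frequency panel is assumed).
Dosages are diploid-coded 0/1/2 even for polyploid crops whose arrays
deliver diploid-coded calls. Monomorphic markers are excluded from both
numerator and denominator.

Curation defaults (all exposed in `run_config()`):

| parameter | default | rationale |
|---|---|---|
| `maf_min` | 0.05 | standard array-curation floor; rarer alleles are mostly call errors at this scale |
| `miss_max` | 0.10 | markers with worse call rates are unreliable |
| `concordance` | 0.7 on r² | cross-platform merge keeps markers whose dosages agree across the genotypes present on both platforms |
| `ld_r2_max`, `ld_window` | 0.5, 50 markers | greedy first-kept-wins pruning toward independently segregating markers |

Two things are deliberate: filters operate on **raw** calls and mean
imputation happens **after** filtering (imputed fractional dosages never
influence MAF or missingness); and the merge threshold applies to r² by
default with an `"r"` mode flag, since both conventions circulate —
the squared form is the default because concordance should not depend
on strand/allele orientation. The LD window and threshold have no
authoritative published values for this workflow; the defaults above are
the package's own choice and are recorded in every run log.

A caveat worth knowing: with a *narrow founder base*, centering at
sample-estimated frequencies leaves a structured offset between G and
the pedigree expectation that no number of markers removes. This is why
pedigree-vs-genomic correlations plateau well below 1 in real programs,
and why the package's G-to-A convergence test simulates a wide founder
base.

## Fusion (Ga, H, Hcor, D)

Pedigree and genomic matrices estimate the same relationships on
different bases, so G is first rescaled, $G_a = \beta G + \alpha$, with
$(\beta,\alpha)$ solving the two-equation system that matches the mean
diagonal and the overall mean of $A_{22}$ (the pedigree block of the
genotyped individuals). The direction of the scaling — G toward the
pedigree base, not the reverse — follows the standard compatibility
argument for single-step evaluation; the constraints are verified to
1e-10 after the fact.

The hybrid matrix is the single-step block formula
$$H = \begin{bmatrix}
A_{11} + A_{12}A_{22}^{-1}(G_a - A_{22})A_{22}^{-1}A_{21} &
A_{12}A_{22}^{-1}G_a\\
G_aA_{22}^{-1}A_{21} & G_a
\end{bmatrix},$$
which leaves $H_{22} = G_a$ exactly and propagates the genomic
correction to ungenotyped relatives through the regression
$A_{12}A_{22}^{-1}$. Individuals with no pedigree path to any genotyped
individual are left at their pedigree values — the fusion cannot invent
information. Numerical choices: $A_{22}$ is inverted by a symmetric
solve; if it is singular (clones, duplicated individuals) a ridge
$\varepsilon I$ with $\varepsilon = 10^{-6}$ is applied *only then*, with
a warning (set `ridge = 0` to make singularity a hard error); H is
symmetrized as $(H + H')/2$ to absorb floating-point asymmetry.

For distance-based selection H is converted to a correlation matrix
(`cov_to_cor()`, diagonal exactly 1) and then to distances. Two
conversion formulas circulate:

* `normalized` (default): $D = (1 - H_{cor}) / (1 - \min H_{cor})$,
  which provably has zero diagonal and off-diagonal values in $[0,1]$
  for any correlation matrix;
* `as_printed`: $D = ((1-H_{cor}) + |\min H_{cor}|)/(1 + |\min H_{cor}|)$,
  an alternative published form that satisfies those properties only
  when $\min H_{cor} = 0$ — whenever the minimum correlation is
  negative it shifts the diagonal to $|\min|/(1+|\min|) \ne 0$.

The default implements the *stated properties* rather than the verbatim
alternative, because the properties (zero self-distance, bounded range,
strictly decreasing in correlation) are what the nearest-entry criterion
actually relies on; both modes agree exactly when the minimum
correlation is 0, and both induce the same nearest-neighbor ranking.

## Core selection (A-NE)

For a core $C$ inside collection $W$,
$$\mathrm{A\text{-}NE}(C) = \frac{1}{|W|}\sum_{a \in W} \min_{e \in C} D(a, e),$$
with entries contributing 0. Averaging over *all* members (not only
non-entries) is the cited criterion's standard form; at fixed subset
size the two conventions rank subsets identically. The whole collection
$W$ is always an explicit id list in the configuration — the tool never
infers it, because the choice (e.g. excluding advanced selections to
avoid sibling-family overrepresentation) is a program-policy decision.

**Mandatory entries.** `select_recent_parents()` counts parental
*slots* (mother and father separately, so a self-cross counts twice)
within a `window_years = 3` window ending at `reference_year`, and
returns parents with ≥ `min_uses = 4` uses. Users who prefer per-cross
counting can deduplicate records upstream.

**Optimizer.** The subset search is a seeded best-improvement swap
descent: random initial free slots, then repeatedly apply the single
(entry out, candidate in) swap that most decreases A-NE until none
improves, restarted from `restarts` random starts plus one descent from
a greedy forward construction. This is deliberately simpler than
parallel-tempering samplers used by established core-selection software:
it is deterministic given the seed, fast through incremental
nearest/second-nearest bookkeeping ($O(n)$ per swap evaluation), and is
verified against exhaustive enumeration on every instance with
$n \le 12$, size $\le 5$ in the acceptance suite. Value ties keep the
earliest (seed-dependent) optimum so that interchangeable genotypes
genuinely alternate across runs — which the consensus stage needs.

**Consensus.** `consensus_core()` repeats the optimization `n_iter`
times (seeds `base_seed + 0 .. n_iter-1`), records per-candidate
selection frequencies, and fills the free slots with the
highest-frequency candidates. Frequency ties are broken by the breeder
preference list if supplied, then lexicographically; the count of slots
whose occupant appeared in every run is reported. The slot-equivalence
refinement (grouping candidates that alternate within one slot before
ranking) was considered and not implemented: frequency ranking plus
preference reproduces the intended behavior in all test scenarios and
keeps the rule auditable.

**Stopping.** Each descent stops at a local optimum (no improving swap),
with a hard cap of `100 * size` swaps as a safety budget; published
descriptions of the reference tools do not state their internal stopping
conditions, so this budget is the package's own choice.

## Diagnostics

All matrix-level correlations use the strict upper triangle, and the
per-genotype correlation between a genotype's $A_{22}$ and $G_a$ columns
excludes the self entry: self-relationships are nearly constant and
would inflate every correlation. (Whether published overall figures
include the diagonal is usually unstated; the convention here is
explicit and configurable via `include_diagonal`.) Outlier rules:
pairs with pedigree > 0.8 & genomic < 0.2 or the converse; genotypes
with per-genotype correlation < 0.2 despite completeness > 5. The
marker-subsampling analysis redraws marker subsets (default 50–3000 by
50, 200 replicates) and reports the smallest size whose *minimum*
correlation with the full-marker G reaches 0.95. PCA of a relationship
matrix is classical multidimensional scaling: eigendecomposition of the
double-centered kernel, coordinates scaled by the square roots of the
eigenvalues.

# The synthetic world

Because no real accession data ship with the package, the
`synthetic_data` functions generate the world the method was designed
for, and the defaults state that world once:

* 3 sub-populations (emulating June bearing / everbearing /
  Mediterranean program structure) of 8 unrelated founders each;
* 4 generations, 8 crosses per sub-population per generation, 2
  offspring per cross, with a 10% chance that a cross reaches into
  another sub-population (the programs are weakly connected);
* 1000 unlinked biallelic markers with founder frequencies uniform on
  $[0.05, 0.5]$;
* half the individuals genotyped, 20% of parent links missing from the
  records, and sample swaps only when explicitly injected.

Gene dropping assigns two globally unique allele labels per founder and
per unknown-parent slot, and each non-founder inherits one uniformly
chosen allele per parent, independently per locus. Labels give *exact*
realized IBD — the package's ground-truth oracle — and label states give
dosages. Loci are unlinked by design: every consumed statistic is
per-locus, and curation prunes toward independently segregating markers
anyway. What the generator does **not** emulate: linkage and LD decay,
selection and drift of allele frequencies over generations, genotyping
error beyond missingness, phenotypes. A green test therefore establishes
the correctness of the relationship/selection machinery, not the
field-level behavior of any particular crop.

The default sample-swap scenario (`default_swap_design()`) pairs
individuals with the deepest recorded pedigrees across different
sub-populations. That is the detectable end of the swap spectrum — a
swap between two full sibs is essentially invisible to any
relationship-based check — so the reported sensitivity bounds what the
diagnostics can do under favorable, but realistic, conditions.

Two stated-world values interact with the genomic noise floor and were
set from the method's own reliability analysis rather than convenience:
fixtures that feed G into H use ≥ 1200 markers, above the ~850-marker
threshold at which subsampling shows the G matrix stabilizing
(min correlation ≥ 0.95); and the G-to-A convergence check uses a wide
founder base (25 founders) because the narrow-base offset described
above is a property of the estimator, not an implementation defect.

# Numerical conventions and degenerate inputs

* Swap-descent improvement threshold: $10^{-12}$ absolute (strict
  improvement required; equal-value swaps are not taken).
* `scale_g` refuses inputs with `mean(diag G) = mean(G)` (degenerate
  2×2 system — in practice: too few genotypes or markers).
* `cor_to_dist` refuses constant correlation matrices (zero range).
* `ane` requires a non-empty core; an empty crossing list yields an
  empty mandatory set with a warning, not an error.
* All RNG consumers (`optimize_core`, `consensus_core`, `ane_curve`,
  `subsample_analysis`, the simulator) require an explicit seed; reruns
  with identical configuration are bit-identical.
* Mean-matching in `scale_g` holds to 1e-10; H-collapse
  (`build_h(A, A22, S) = A`) holds to 1e-8; both are asserted in the
  acceptance suite.

# Known limitations

* No weighted/blended single-step variants (the $\tau, \omega$ weights
  of the later literature).
* No pedigree reconstruction or correction from markers; outlier flags
  point at suspects but do not propose fixes.
* No probe-to-genome alignment or consensus-map validation for
  cross-platform merging; concordance is purely statistical.
* The optimizer guarantees a local optimum and matches the exhaustive
  optimum at oracle-verified sizes; at large sizes the consensus
  frequencies, not a global-optimality certificate, are the practical
  quality signal.
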