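---
title: "Random Bits Forest: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random Bits Forest: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Random Bits Forest addresses two structural weaknesses of plain random
forests: axis-parallel splits (wasteful when the decision boundary is
oblique) and the shallowness of single-feature tests (fatal when class
membership depends on a *relation* between features, as in the hill/valley
benchmark where a bump must be compared to a random baseline level). It
does so by manufacturing features first and letting an otherwise ordinary
forest consume them.

A **Random Bit** is a binary feature emitted by a 3-layer sparse threshold
network. Hidden node $k$ reads `twist1` distinct input features $j \in S_k$
through i.i.d. standard normal weights and computes
$z_k(x) = \sum_{j \in S_k} w_{kj} x_j$ on standardized inputs. Every node is
a threshold unit with a *data-driven* threshold: $\theta_k = z_k(x_{i_k})$
for one uniformly drawn training sample $i_k$, so the split is always
anchored inside the data cloud regardless of scale. The top node thresholds
the weighted sum of the hidden bits the same way. Both layers use a strict
`>`; the sample that donated the threshold therefore emits 0, and no
training column can be constant 1. With `twist1 = 1, twist2 = 1` the network
collapses to a single-feature threshold — the axis-parallel ablation used as
the internal baseline.

**Boosted selection.** Naive random projections waste most of a ~10,000-bit
budget; selection is what makes the pool informative. The pool is built by
`chains` independent least-squares gradient-boosting chains of `steps` steps
each. A chain keeps a residual (initialized once per chain to the working
target); each step draws `cands` fresh candidate networks, scores each by
the between-group sum of squares of the current residual split by its bit,

$$\mathrm{Var} = n_0(m_0-\bar m)^2 + n_1(m_1-\bar m)^2,$$

keeps the strict maximum (first candidate encountered wins ties), and
updates $r_i \leftarrow r_i - m_{b(i)}$ with the groupwise means. Subtracting
the selected bit's effect decorrelates subsequent selections. The chain SSE
is non-increasing by construction: the update removes exactly the
between-group component. Classification targets enter the boosting recoded
to $-1/2, +1/2$ so the first grand-mean subtraction is symmetric; class
probabilities come from the forest, never from the boosting.

**The packed-bit forest.** Training bits are stored one bit per sample per
feature (column-major 64-bit words, least-significant bit = lowest sample
index, padding zeroed) and shared immutably by all trees; bootstrap
multiplicity travels in index multisets. Each tree draws
$\lfloor \texttt{sample\_fraction} \cdot n \rfloor$ samples with replacement
and `bits_per_tree` bit indices with replacement (duplicates collapse to the
unique set), then splits greedily on the best bit of that set — variance
reduction for regression, Gini decrease for classification — until a node is
pure, smaller than `2 * min_node_size`, or no candidate bit attains a
positive decrease. Leaves store the bootstrap-member mean (class-1 fraction
for classification); predictions average leaves across trees, so they are
convex in the training targets and classification outputs are genuine
scores in $[0, 1]$.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `chains` (B) | 256 | independent boosting chains; many short chains parallelize and avoid a single chain's local optimum. 256 is the stated small-data setting. |
| `steps` (S) | 40 | steps per chain; B·S = 10,240 matches the "~10,000 bits" budget. |
| `cands` (C) | 128 | candidates per step; the selection pressure. The method calls for C > 100. C = 1 degenerates to unselected random projections (kept available as the ablation). |
| `twist1` | 3 | features per hidden node. The benchmark values were never published; 3 keeps the network sparse while allowing oblique contrasts. |
| `twist2` | 3 | hidden nodes; with `twist1 = 3` a bit can express relations among up to 9 raw features — enough depth for hill/valley-type tasks. |
| `n_trees` | 500 | forest size; errors plateau well before this on desk-scale data. |
| `bits_per_tree` | ⌈√pool⌉·8 | per-tree bit bootstrap (~800 for a 10k pool); the per-tree analogue of mtry, scaled up because bits are weak individually. |
| `sample_fraction` | 1.0 | bootstrap size; lowering it regularizes small datasets by decorrelating (individually biased) trees. |
| `min_node_size` | 1 (class) / 5 (reg) | the canonical forest defaults for each task. |

All randomness flows from one integer seed through derived substreams
(split-mix derivation, xoshiro generators), one per chain and one per tree,
so chains and trees may be computed in any order with byte-identical
results.

## Synthetic data: what it emulates, what it does not

The generators reproduce the *statistical structure* of the regimes the
method was designed for, so every claim-style test runs without downloads:

* `gen_hill_valley()` — length-100 series, flat baseline U(0, 10), Gaussian
  bump (amplitude U(1, 5), center in the middle 60% of the series, width
  U(5, 15)) added for hills and subtracted for valleys, Gaussian noise per
  point. Depth task: sign(bump) is invisible to any single time point.
* `gen_oblique()` — standard normal features, labels from a fixed random
  hyperplane through the origin, optional label flips. The cleanest
  axis-parallel-vs-oblique contrast.
* `gen_surface()` — $y = \sin(4\pi x_1)\cos(4\pi x_2) + 0.5 x_1 + \epsilon$
  on the unit square: a smooth, shallow regression target.
* `gen_genotypes()` — biallelic SNPs with MAF ~ U(0.05, 0.5), genotypes
  Binomial(2, maf) (Hardy-Weinberg), an additive log-odds liability on a
  random causal subset with per-SNP effects centered at $2\,\mathrm{maf}$,
  and a Bernoulli(logistic) phenotype.

They deliberately do **not** mimic linkage disequilibrium, population
stratification, genotyping artifacts, or any real disease architecture; nor
the heavy-tailed and heteroscedastic noise of real benchmark tables. Passing
tests therefore demonstrate the algorithmic properties (depth, selection,
oblique advantage, ranking recovery) under clean conditions — not field
performance on any particular real dataset.

One consequence surfaced by the test suite is worth stating plainly: on the
synthetic hill/valley task the axis-parallel ablation reaches roughly 8%
test error, far better than the ~40% a plain random forest shows on the
real benchmark. The synthetic bumps are wide and smooth and the baseline is
bounded, so *boosting-selected* single-feature bits recover much of the
signal. The full model is still an order of magnitude better (≈0.7%), and
the oblique study shows the expected 5-point gap, but the synthetic suite
understates how badly axis-parallel learners fail on the real task.

## Numerical choices

* **Thresholds and ties.** Strict `>` at both network layers; ties emit 0.
  One convention, applied everywhere and pinned by tests.
* **Degenerate boosting steps.** A candidate constant on the training set
  scores 0. If *every* candidate of a step scores 0 the first one is stored
  (keeping the pool size exactly B·S) and the residual is left unchanged.
  Means over empty groups are defined as 0; no sample receives them.
* **Tie-breaks.** Boosting keeps the first strict maximum; the forest scans
  candidate bits in ascending index with a strict improvement, so the
  lowest bit index wins. Both choices make refits bit-identical.
* **Standardization.** Sample (n−1) standard deviation; zero-variance
  features keep sd = 1 and map to an all-zero column, which no hidden node
  can use informatively — rejecting such columns would break real tables.
* **Statistics conventions.** AUC is the midrank Mann-Whitney form (exactly
  pairwise counting with ties at 1/2); its CI uses the Hanley-McNeil
  moments with ±1.96 SE clipped to [0, 1] (DeLong would be the variance
  -estimating alternative; the published comparison tables are consistent
  with Hanley-McNeil). The "optimal threshold" maximizes Youden's J over
  observed cuts, lower cut on ties. The paired Wilcoxon drops zero
  differences, uses midranks, the tie-corrected normal variance and a 0.5
  continuity correction — this exact convention reproduces the published
  benchmark-table p-value (0.007185) from the bundled 14 RMSE pairs, and is
  cross-checked in tests against both an exact enumeration oracle and the
  reference implementation.
* **Cross-validation.** Deterministic seeded folds; classification folds
  are stratified by dealing each shuffled class cyclically across folds
  (class ratios within one sample, no single-class folds; the fold builder
  refuses k larger than the smallest class).
* **GWAS.** The allelic (allele-count) 2×2 chi-square, not a genotypic or
  trend test; odds ratios unadjusted, reported as missing when a cell is
  zero. SNPs are ranked on the training cohort only. The top-K sweep
  selects K on the independent test set — reproduced because that is the
  published procedure, but labeled optimistically biased in the output.
* **Persistence.** Models are written with R's native serialization (XDR,
  platform independent) carrying an explicit `format_version`; loading
  validates the container and version and fails loudly on truncation or
  foreign files. The packed-bit convention (64-bit words, LSB-first) is
  part of the documented model format.

## Problem sizes used by the test and acceptance runs

The simulation studies use a reduced pool — 64 chains × 20 steps,
128 candidates (1,280 bits) — with five seeded replicates of the
n = 1212 hill/valley task and the n = 2000 oblique task, and a synthetic
GWAS of 1,000 SNPs with 2,000 training / 1,000 testing subjects. These
sizes keep a full desk run in minutes while leaving every measured contrast
far from its decision boundary (except the hill/valley ablation bound
discussed above). The full 256 × 40 default pool behaves identically in
kind; only the error levels shift slightly downward.

## Known limitations

* Binary classification and univariate regression only; no multiclass, no
  missing-value handling (inputs are rejected, not imputed), no GPU path.
* The forest consumes bits only — raw features never enter a split, so a
  task that is genuinely axis-parallel pays a small price relative to a
  plain random forest at equal tree count.
* Training cost scales with B·S·C·n network evaluations; the compiled core
  makes desk-scale runs fast, but the method is not competitive below a few
  hundred samples, where trees are weaker than regularized linear models.
* The GWAS pipeline performs no genotype QC, imputation, or covariate
  adjustment; it expects clean 0/1/2 matrices.
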