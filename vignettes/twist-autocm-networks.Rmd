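---
title: "Methods: TWIST selection and Auto-CM similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TWIST selection and Auto-CM similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

twistmap maps the joint structure of risk factors, genotypes and a binary
disease outcome in a case-control cohort. The pipeline has four stages:
recode every variable into binary indicator variables; select a minimal
predictive indicator subset with an evolutionary wrapper (TWIST); learn a
variable-similarity matrix with an Auto Contractive Map (Auto-CM); and
summarise that matrix as graphs — the minimum spanning tree (MST), its
resampling-stability filter (Meta-MST), and the maximally regular graph
(MRG) with its complexity indices. This vignette explains each model, the
parameters that matter, and the design choices made where the design was
genuinely open.

## Indicator recoding

Genotypes are carried as three classes (1 = common homozygote,
2 = heterozygote, 3 = rare homozygote) and recoded as three 0/1 indicator
columns. Continuous traits are first cut into tertiles — by rank against
the empirical 1/3 and 2/3 quantiles, so the three classes mirror the
genotype coding — and likewise expanded into three columns. Binary traits
(e.g. smoking) become a no/yes pair. No reference category is dropped:
the downstream selection stage is prediction-oriented and can discard a
redundant complement on its own; keeping both lets non-linear
interactions use either level. For every parent variable the indicator
columns partition each record (they sum to one row-wise), and each column
carries metadata mapping it back to its parent and category. The binary
outcome can be appended as the complementary pair `Event` / `No_Event`,
so both outcome states appear as nodes in the whole-cohort map.

Ties in the tertile cut are broken by original row order; this keeps the
binning deterministic and the class sizes as equal as `n` permits. Rows
with missing values are dropped (with a reported count) rather than
imputed — imputation, association scans and genotype QC are upstream of
this package's scope.

## The synthetic cohort generator

The study the package emulates is not deposited, so the generator is a
first-class module. It draws SNP genotypes from Hardy-Weinberg proportions
($p^2$, $2pq$, $q^2$; one SNP per locus, no linkage disequilibrium),
builds continuous phenotypes as additive per-allele effects plus
correlated Gaussian noise (block-exchangeable correlation by default,
emulating clusters of related biomarkers), and assigns the outcome by a
liability-threshold model: a latent liability sums indicator-level weights
plus standard normal noise, and the threshold is set at the empirical
quantile hitting the target prevalence. Cases are oversampled in a
population pool and then sampled down to the exact case/control design.

Weights are placed on *indicator categories* — the top tertile of a
biomarker, a rare homozygote class, the smoking yes level — so the
generator can return the exact set of informative indicator columns as
planted truth, which the selection tests score against.

`nphs2_like_config()` reproduces the emulated design: 102 cases, 150
controls, 37 SNPs, 14 continuous phenotypes and smoking (155 indicator
columns with the outcome pair), one hub SNP with effects on six
phenotypes, and eight indicator categories carrying liability weight
between 0.3 and 0.5 SD. `recovery_sim_config()` is a compact benchmark
(600 records, 34 indicator columns, 4 informative at 0.8 SD each) used by
the recovery tests; with `effect = 0` it yields pure-noise cohorts.

What the generator does **not** emulate: linkage disequilibrium,
gene-gene epistasis, non-Gaussian phenotype distributions, and
measurement error. Tests passing on these cohorts therefore show that the
pipeline recovers planted additive-liability structure under realistic
sizes and correlation, not that it handles every artefact of real cohort
data.

## TWIST: evolutionary split and indicator selection

TWIST couples two genetic-algorithm searches scored by a bank of
learners.

The **T&T stage** evolves a train/test membership vector so that each
half is statistically representative: the fitness of a split is the
*worse* of its two cross-prediction accuracies (train on A predict B, and
the reverse), averaged over the enabled learners. Taking the minimum of
the two directions is robust to one-sided luck; a split can only score
well if models generalise both ways. The split fraction defaults to
50/50, and a repair step keeps both classes present on both sides.

The **IS stage** evolves a 0/1 mask over the indicator columns (outcome
columns are excluded from the search space by construction). Fitness is
`1 - cost` on the frozen testing half, averaged over the bank, where the
cost is the confusion-matrix misclassification rate (root mean square
error is selectable). Each generation keeps an elite, selects parents by
binary tournament in which the weaker contestant still wins with
probability 0.25, applies uniform crossover and per-bit mutation
(default rate 1/L), and replaces 10% of the population with random
immigrant masks. The immigrants and the lossy tournament play the role of
doping: deliberately injected instability that keeps sub-optimal material
in the population and guards against premature convergence. The
best-ever mask and a non-decreasing best-fitness trace are returned.

The learner bank implements four classifiers from first principles
(naive Bayes with Laplace smoothing; logistic regression by gradient
ascent with a small ridge; k-nearest neighbours under Hamming distance;
a one-hidden-layer sigmoid network trained by backpropagation) and is
pluggable — the protocol's logic is learner-agnostic, and any nonempty
subset can be enabled. Naive Bayes is the default workhorse for large
searches: on binary indicators it is exact, fast, and its fitness is a
deterministic function of the split and mask.

**A known property of the protocol:** the returned best-ever fitness is a
maximum over thousands of noisy held-out evaluations. On data where the
outcome is independent of all indicators, that maximum sits
systematically above chance — around $0.5 + \sigma\sqrt{2\ln K}$ for $K$
evaluations with per-mask standard error $\sigma$ (about 0.61 at 300
held-out records and $K \approx 2\times10^4$). This test-set selection
bias is intrinsic to optimising a mask against a fixed testing half; the
mask itself is near-chance on genuinely fresh data. Users comparing the
reported fitness against chance should account for it.

## The Auto Contractive Map

The Auto-CM is a three-layer adaptive network with one unit per variable
and a positive contraction parameter $C$. For each record $x \in [0,1]^p$:

$$m^h_i = x_i\,(1 - v_i/C), \qquad
  \mathrm{Net}_i = \frac{1}{C}\sum_j m^h_j\,W_{ji}, \qquad
  m^t_i = m^h_i\,(1 - \mathrm{Net}_i/C)$$

with learning updates

$$\Delta v_i = (x_i - m^h_i)(1 - v_i/C), \qquad
  \Delta W_{ji} = (m^h_i - m^t_i)(1 - W_{ji}/C)\, m^h_j .$$

Updates are averaged over records and applied once per epoch, in two
phases: the mono-connections $v$ first, then $W$ with the hidden layer
recomputed under the updated $v$. Batch accumulation makes training
invariant to record order and fully deterministic given the uniform
initial value (`init_eps = 0.01`; exact zeros stall the dynamics because
every update is proportional to the current weight path). Under this
scheme each $v_i$ increases monotonically toward $C$ (the per-epoch map
$v \mapsto v + \bar{x}(v/C)(1-v/C)$ has fixed point $C$ and never
overshoots for $C > 1$), the output signal contracts toward zero, and
training stops when the mean output falls below `tol` (default $10^{-6}$)
or at `max_epochs` (default 1000).

While the output dies, $W$ absorbs the co-activation structure: the
weight $W_{ji}$ grows only in records where both variables are active, so
the symmetrised, rescaled matrix
$S_{ij} = (W_{ij} + W_{ji})/(2C)$ reads as a similarity — the degree of
membership of the two indicator variables in the same fuzzy set. Only
positive association is represented. Similarities are interpreted on the
conventional verbal scale (null or very low up to 0.33, quite low to
0.66, quite high to 0.84, very high above), and `D = 1 - S` turns them
into distances for tree building.

**Choosing `C`.** The scale of the trained weights depends strongly on
$C$. The relative growth rate of $W$ during training scales like
$p/(C\bar{x})$ against the decay of the hidden signal, so for large $C$
(e.g. the number of columns) the weights never leave the neighbourhood of
their initial value and all similarities collapse toward zero — the
ranking is preserved, but the 0.33/0.66/0.84 bands and any fixed
similarity floor become meaningless. For very small $C$ the network
over-contracts ($\mathrm{Net} > C$) and the dynamics wobble. The default
therefore adapts to the data: $C = \max(2,\ \overline{\text{row sum}}
\times \overline{x})$, one "co-activation unit". Empirically (tertile
indicator matrices of 18-60 columns, dense binary matrices of 10-20
columns) this keeps the dynamics stable while letting strongly co-active
pairs saturate, so similarities span the unit scale the verbal bands
assume. `C` remains a user parameter; the pairwise similarity *ranking*
is stable across a wide range of `C` (the package tests it at Spearman
correlation above 0.5 between the default and `C = ncol`), so the MST is
essentially invariant to the choice — only scale-dependent readings (the
bands, the MRG floor) need the adaptive default. In the strongly
saturated regime the mean output signal can transiently rise while parts
of the network over-contract; in the tame regime (`C` of the order of the
column count) contraction is strictly monotone.

Constant columns carry no co-activation information and make the
similarity ranking degenerate, so the trainer rejects them; the per-group
pipeline drops the outcome columns (constant within a group) and any
indicator with zero within-group variance, with a message.

## Graphs and complexity

**MST.** Kruskal's algorithm on `1 - S` with fully deterministic
tie-breaking (edges sorted by distance, then by the lexicographic order
of their node-label pair). The tree keeps, among all connected acyclic
graphs, the maximal total similarity; every link that would close a
cycle is eliminated regardless of strength.

**Meta-MST.** The Auto-CM and MST are rebuilt on `k = 10` record
subsamples, each dropping 10% of the records at random (optionally
stratified, e.g. by outcome, so a rare class is never lost), and only
edges present in at least 9 of the 10 trees are kept. The result is the
stability backbone of the map and may be disconnected. With
`drop_fraction = 0` every resample is identical and the Meta-MST equals
the MST exactly; support thresholds are nested by construction.

**Complexity indices.** For a graph with $N$ nodes, $A$ arcs and degree
sequence $d$:

* hubness $H = \sum_i \max(0, d_i - 2) / (N - 2)$ — zero for a path,
  $(N-3)/(N-2)$ for a star. Defined for connected graphs with
  $N \ge 3$. Note that $H \le 1$ is guaranteed only on trees; on dense
  graphs the per-node excess over degree 2 can push $H$ above 1.
* pruning cycles $P$: waves of deleting all nodes of degree $\le 1$,
  and, once only cycles remain, all nodes of the current minimum degree;
  $P$ counts the waves needed to empty the graph.
* topological entropy $E_G = (A/P)\, H_S$ with
  $H_S = -\sum_i p_i \log_2 p_i$, $p_i = d_i / \sum_j d_j$: arcs per
  pruning wave, weighted by the Shannon information of the degree
  distribution.

The exact closed forms for $H$ and $E_G$ are this package's
operationalization of their verbal definitions (the reference formulas
live in an inaccessible supplement); they are exposed behind ordinary
functions so alternative formulas can be swapped without touching the
MRG search, and the headline values they produce should be compared
*directionally*, not numerically, with published ones.

**MRG.** Candidate non-tree links with similarity above a floor (default
0.33, the null/very-low bound — re-introduced links should not be
noise-level) are sorted by descending similarity and added one at a time
to a copy of the MST, recording $H$ after each addition; the graph of
maximal $H$ along this sequence (earliest on ties) is returned with its
complexity report. Since adding an edge never lowers $H$, this keeps the
shortest prefix achieving the maximal hubness; when no candidate clears
the floor the MRG is the MST itself. Whether a broader search over
non-monotone addition orders could score higher is deliberately out of
scope — the monotone sequence is the documented contract.

**Per-group contrast.** The Auto-CM, MST and MRG are run separately on
case rows and control rows (outcome columns excluded), and the two
complexity reports are differenced (control minus case). A group whose
variables are more densely correlated yields more candidate links above
the floor, hence a denser MRG and a larger $E_G$; the package's tests
verify this direction on paired synthetic groups with planted
correlation-density differences.

## Numerical choices and degenerate inputs

* All RNG flows from a single integer seed per entry point; stage seeds
  in the pipeline are fixed offsets of the pipeline seed, and every
  helper restores the caller's RNG state.
* Tertiles require at least three distinct values; fewer is an error,
  not a silent 2-bin fallback.
* GA populations are repaired rather than rejected: empty masks get one
  random bit, splits are rebalanced to the target size with both classes
  on both sides.
* Edge and candidate orderings use radix (byte-wise) string order
  everywhere, so results do not depend on the session locale.
* The degenerate GA configuration (singleton population, no variation
  operators) is a supported identity check, not an error.

## Problem sizes used by the tests

The package's own test battery runs at deliberately compact sizes chosen
to exercise every code path at full fidelity: exhaustive MST
verification on up to 8 nodes (all $n^{n-2}$ spanning trees via Prufer
enumeration), Auto-CM batteries on up to 200 x 20 binary matrices,
selection benchmarks at 600 records x 34 indicators with 200 GA
generations, and end-to-end runs at the emulated 252-record design.
These sizes are the package's reference conditions; the algorithms
themselves have no intrinsic size limits beyond $O(p^2)$ memory in the
number of indicator columns.

## Known limitations

* The similarity scale (not its ranking) depends on `C`; cross-study
  comparisons of raw similarities require a common `C` policy.
* $H$ and $E_G$ are operationalized formulas; their absolute values are
  not comparable with implementations using different closed forms.
* The reported TWIST fitness carries test-set selection bias (see
  above); treat it as an optimisation score, not an unbiased accuracy
  estimate.
* The MLP learner draws its initial weights from the ambient RNG stream;
  it is reproducible under the pipeline seed but, unlike the other three
  learners, not a deterministic function of the data alone.
* Meta-MST edge weights are means over the supporting resamples only,
  so they are not directly comparable with whole-sample MST weights when
  support is below `k`.
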