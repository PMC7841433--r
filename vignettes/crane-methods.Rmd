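---
title: "Methods: constrained network randomization and disease-module significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained network randomization and disease-module significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crane)
```

## Scope and model

This package evaluates the statistical significance of candidate disease
modules found by comparing two weighted bipartite gene regulatory networks
(TFs x genes, PANDA-style z-score edge weights, possibly negative). The
logic has three layers:

1. **Differential modularity.** With disease adjacency $A^d$ and control
   adjacency $A^c$ (both nonnegative; see the transform below), define
   $$D_{ij} = \hat A^d_{ij} - \hat s^c_i \hat d^c_j,$$
   where $\hat A^d = A^d / W^d$, and $\hat s^c, \hat d^c$ are control TF
   and gene strengths divided by the control total weight $W^c$. Since
   both terms sum to one, $\sum_{ij} D_{ij} = 0$. Module detection
   maximizes the total within-module sum of $D$ over joint TF/gene
   partitions; a node's score $S^0$ is its within-module row (TF) or
   column (gene) sum of $D$ — its contribution to its module's
   differential modularity.

2. **Null ensemble.** A randomizer perturbs the *control* network $K$
   times. For each replicate, $D^P$ is computed against the original
   control and every node re-scored under the *fixed* module assignment,
   giving each node a null sample $T_{node}$ of size $K$.

3. **Normal-fit p-values.**
   $p = 1 - \Phi\!\left((S^0 - \mathrm{mean}(T))/\mathrm{sd}(T)\right)$,
   BH-adjusted per module by default (a global family is available when
   one wants a single network-wide ranking), and ranked ascending with
   ties broken by descending $S^0$, then label. The normal fit uses the
   sample mean and sample sd ($n-1$); it is an approximation, which is why
   the calibration test below checks the realized false-positive fraction
   rather than exact uniformity.

The significance statement is conditional on the module assignment: the
null ensemble asks "how large would this node's contribution to *this*
module be under perturbation noise alone?"

## The CRANE randomizer

CRANE perturbs a weighted bipartite network while conserving every node
strength and keeping all weights inside the observed global range
$[\min A, \max A]$. Rows and columns are put in random order; row 1 is
copied; then for each row $l = 1, \dots, m-1$:

* add Gaussian noise with sd $\alpha \cdot \mathrm{sd}(A_{l\cdot})$ — the
  sd of the *original* row, not the evolving one, so the perturbation
  scale does not drift;
* rescale the row to its strength target;
* give row $l+1$ the column residual
  $\sum_{i \le l+1} A_{ij} - \sum_{i \le l} B_{ij}$, which keeps all gene
  strengths on track; the final row receives only residuals, and its row
  strength follows from column conservation.

**Deviation correction.** The residual row can escape the global weight
range. Absorbing the excess into row $l$ and re-rescaling
multiplicatively, iterated, does not terminate on zero-centered weights:
the rescale keeps re-ejecting entries, and the perturbed row $l$ itself
can sit outside the range. Both constraints together confine row $l$
entrywise to $[L_j, U_j] = [\min A, \max A] \cap [c_j - \max A,
c_j - \min A]$ (where $c_j$ is the fixed pair sum of rows $l, l+1$) with
$\sum_j B_{lj}$ fixed. The implementation therefore projects the proposal
onto this box-and-sum polytope directly — an additive shift-and-clip with
the shift found by bisection — which is the minimal adjustment that
restores strength and containment at once, and terminates by
construction. If the polytope is empty (residual mass that no in-range
row can absorb, which large $\alpha$ can produce), the draw fails loudly
with the offending row rather than clipping silently.

Numerical care: the residual is accumulated as an explicit drift
$\delta_l = \sum_{i\le l}(A_{i\cdot} - B_{i\cdot})$ so that $\alpha = 0$
reproduces the input bit-for-bit (no telescoping cancellation), and the
row rescale is skipped when the factor is exactly 1.

**Unipartite variant.** For symmetric co-expression networks no row-by-row
scheme can work: each row is also a column, so the sequential
residual-passing construction cannot satisfy both constraint sets at
once. The package instead adds a symmetric Gaussian perturbation (zero
diagonal, per-edge sd $\alpha(\sigma_i + \sigma_j)/2$ from the adjoining
rows' weight sds) and restores strengths *exactly* with the additive
symmetric correction $\Delta_{ij} = x_i + x_j$, $x = $ the unique solution
of the resulting linear system; out-of-range entries are clipped and the
correction re-applied until both constraints hold. This is a documented
interpretation: the bipartite algorithm is the method's core, the
unipartite variant an extension satisfying the same contracts.

**Strength noise.** Optionally, Gaussian noise is added to the TF strength
targets before the loop (for ensembles where strengths should be conserved
only on average), and the gene-side targets are scaled by a common factor
to keep the totals balanced. The noise sd is a user parameter; no formula
for estimating it from data is imposed.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.1 | Perturbation magnitude (unitless multiplier on per-row weight sd). 0.1–0.4 brackets the edge-weight variance of networks re-inferred from subsampled expression data; 0.1 is the default because the benchmark gain saturates while runtime grows with `alpha` (more correction work). |
| `K` (`--replicates`) | 1000 | Null ensemble size; the normal fit is already stable at a few hundred. |
| `range_tol` | 1e-9 | Slack on range containment; floating-point guard, not a model parameter. |
| `max_correction_iters` | 100 | Bisection depth cap in the projection; also the cap on the unipartite clip/restore loop. |
| `strength_noise_sd` | off | See above. |

Community detection and module detection take a `seed` and `n_restarts`
(default 20): the label optimizer alternates simultaneous best moves
(each side's objective is separable given the other side), accepts only
nonnegative gains, keeps the current community on ties, and ends each
round with greedy pairwise merges. Zero-gain merges are accepted so that
fully degenerate inputs (uniform weights, $Q \equiv 0$) coalesce into one
community instead of arbitrary singletons.

## Edge-weight transform and NMI

Z-score weights are mapped to positive weights with the softplus
$W_{ij} = \ln(e^{w_{ij}} + 1)$, evaluated as
$\max(w, 0) + \mathrm{log1p}(e^{-|w|})$ so magnitudes up to several
hundred neither overflow nor underflow. Modularity-based steps and the
configuration model require it; CRANE itself does not.

Partition similarity uses NMI with arithmetic-mean normalization,
$2I/(H_1 + H_2)$ — the default of igraph's `compare()` and fixed here so
reported values are comparable; zero-entropy corner cases are defined
(identical trivial partitions give 1, a trivial partition against any
other gives 0). Tests cross-check against igraph on random partitions.

## Baseline null models

* **Configuration model** (maximum-entropy, exponential edge weights,
  rate $\theta_i + \theta_j$): the multipliers solve
  $\sum_j (\theta_i + \theta_j)^{-1} = S_i$. The solver alternates sides;
  given one side, each node's equation is a strictly monotone scalar root
  problem, solved for all nodes at once by safeguarded Newton steps with
  positivity projection ($\theta_i + \theta_j > 0$ throughout),
  initialized at $\theta_i = n/(2S_i)$. Convergence is declared at maximum
  relative residual below 1e-8 (contract: 1e-6). Strengths must be
  strictly positive — transform first.
* **SBM**: block structure is taken from a modularity partition (the
  standard modularity/SBM-likelihood equivalence shortcut rather than SBM
  inference); each (TF-community, gene-community) bundle gets a normal
  distribution with the bundle's sample mean and sd. One-edge bundles
  fall back to the global edge sd and are flagged. Samples are *not*
  clipped to the observed range.
* **Stratified permutation**: weights shuffle only within
  {intra, inter-community} x {motif-positive, motif-negative} strata, so
  each stratum's weight multiset is exactly preserved. Node strengths are
  not preserved — the property that separates this baseline from CRANE.

## The synthetic generator and what it does (not) emulate

`simulate_baseline()` draws $N(0, \sigma)$ weights plus `block_boost` on
intra-block pairs (defaults $\sigma = 1$, boost 3, five blocks), with a
motif prior that is certain inside blocks and Bernoulli(0.2) outside;
`simulate_replicate()` adds independent $N(0, 0.2)$ edge noise, standing
in for re-inference from an independent 50-subject expression subsample;
`plant_disease_module()` sets all edges between `n_tf` random TFs and
$5 n_{tf}$ random genes to weight 5. Defaults were fixed once as
plausible analogs of inferred cancer regulatory networks at desk scale
(100 TFs x 500 genes in the benchmark).

What the generator does **not** emulate: correlations between edges.
Real re-inferred networks vary in a correlated way (shared latent
expression), while both the generator's replicate noise and CRANE's
perturbations are edge-independent. Passing benchmarks here therefore
shows the pipeline's ranking behavior under independent noise, not that
CRANE reproduces the full covariance of subsampled networks. TF identity
effects (binding-site counts, hub structure) beyond strengths are also
not modeled.

One scale effect is worth stating: with positives defined as the top 1%
of the ranked list, a 500-gene benchmark has at most 5 positives against
15–100 planted genes, so the F-score is bounded well below 1 and its
*maximum attainable value decreases* with module size. At these sizes the
Wilcoxon rank-sum comparison carries the recovery signal; F-scores are
reported as bounded sanity values.

## Degenerate inputs and tie rules

* Null sd of zero (e.g. an identity randomizer): p collapses to 0/0.5/1
  by the sign of $S^0 - \mathrm{mean}$, with a warning.
* A row whose weights sum to exactly zero cannot be rescaled
  multiplicatively; CRANE reports the degenerate row instead of dividing.
* Ranking ties: descending $S^0$, then lexicographic label — a total
  order, so fixed seeds give byte-identical outputs.
* Missing edges in an edge list default to 0 (inferred regulatory
  networks are complete); `strict = TRUE` rejects incomplete files.
* The enrichment sweep drops thresholds beyond the ranked-list length
  with a warning; the hypergeometric test is unconditioned (no gene
  annotation hierarchy).

## Problem sizes used by the tests and acceptance script

The shipped checks run at desk scale, chosen as the package's own test
conditions: conservation/containment on 20x100 networks over 50 draws and
$\alpha \in \{0.1, \dots, 0.4\}$; the $\alpha$ response on a 20x100
4-block network with 200-draw ensembles and 10 seeds; calibration on a
50x250 network with $K = 200$ nulls and 5 seeds (expected fraction of
genes at $p < 0.05$ in the 1–12% band); and the planted-module benchmark
at 100x500 with a 10-TF/50-gene module, $K = 200$, 10 trials. At those
conditions the CRANE-ranked Wilcoxon p-values beat raw-score ranking by
about nine orders of magnitude in the median.

## Known limitations

* CRANE perturbs edges independently given the strength constraints; it
  underestimates the correlated variability of truly re-inferred
  networks, and no single $\alpha$ reproduces all moments of that
  distribution.
* The normal fit of $T_{node}$ is an approximation; extreme tail
  p-values (far below machine precision of the fit) should be read as
  rankings, not literal probabilities.
* Module detection is a stochastic local optimizer; different seeds can
  give different local optima on hard instances. Consensus clustering
  stabilizes membership at a cost in resolution.
* The differential-modularity score variant here is self-contained and
  documented (unit-total-weight normalization, within-module row/column
  sums); numeric compatibility with other published implementations is
  not claimed, and all downstream steps depend only on the
  (partition, scores) interface.
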