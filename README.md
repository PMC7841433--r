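# crane

Constrained randomization of weighted networks and disease-module
significance.

## The problem

Differential network analysis compares a gene regulatory network inferred
under a disease condition against a matched control to find *disease
modules*: groups of transcription factors (TFs) and genes that interact
more strongly in disease. Module detection maximizes a modularity-style
score, but network inference is noisy and the optimizer has many local
optima, so a candidate module is not evidence by itself. The question this
package answers is: **which nodes of a candidate disease module are
significant relative to the noise one would see with no disease effect at
all?**

The core of the package is CRANE (Constrained Random Alteration of Network
Edges), an algorithm that randomizes a weighted bipartite (TF x gene)
network while *exactly preserving every node strength*
`S_i = sum_j w_ij` and keeping all edge weights inside the observed global
range `[min(A), max(A)]`. Row by row, Gaussian noise scaled by
`alpha * sd(A[l, ])` is added, the row is rescaled to its strength target,
and the next row absorbs the column-wise residual so gene strengths stay
on track; a deviation-correction step projects each row back into the
admissible range. The single tuning parameter `alpha` controls the
perturbation magnitude. A symmetric variant handles unipartite
(co-expression) networks.

Around CRANE, the package implements the full significance pipeline:

- **Differential modularity** `D_ij = Ahat^d_ij - shat^c_i dhat^c_j`
  (disease adjacency normalized to unit weight, minus the control
  strength-product expectation) and Louvain-style module detection on `D`
  with per-node scores `S0_node` (ALPACA-style).
- **Null ensembles**: `K` randomized copies of the control network (CRANE,
  or three baselines: a maximum-likelihood configuration model with
  exponential edge weights, a per-block normal SBM, and stratified
  edge-weight permutation), each scored under the fixed module assignment.
- **Node p-values** `p = 1 - Phi((S0 - mean(T)) / sd(T))` from a normal
  fit of each node's null scores, BH-adjusted per module (or globally),
  with deterministic ranking.
- **Evaluation**: bipartite (Barber-type) modularity community detection,
  normalized mutual information, consensus clustering, a planted-module
  simulation benchmark (Wilcoxon rank-sum, F-score), and a hypergeometric
  gene-set enrichment threshold sweep over GMT collections.

## Worked example

```r
library(crane)

# a synthetic control network and a disease copy with a planted module
spec <- simulation_spec(m = 30, n = 150, n_blocks = 3, seed = 5)
control <- simulate_baseline(spec)
disease <- simulate_replicate(control, spec, replicate_seed = 77)
planted <- plant_disease_module(disease, n_tf = 5, planted_weight = 5, seed = 9)

# end-to-end: transform, detect modules, CRANE null (K draws), p-values
scored <- score_disease_modules(planted$net, control, method = "crane",
                                alpha = 0.1, K = 50, seed = 3)
head(scored$result, 3)
#>   node module       score   null_mean      null_sd            p        p_adj rank
#> 1  G18      2 0.002756649 0.002117141 5.220662e-05 8.446431e-35 5.067858e-33    1
#> 2 TF24      1 0.011240389 0.009704447 1.642889e-04 4.422846e-21 2.653708e-19    2
#> 3 G133      2 0.002479909 0.001982602 5.573989e-05 2.291361e-19 6.874083e-18    3
```

The top-ranked gene G18 is a planted-module member: its observed
differential modularity score sits a dozen null standard deviations above
its CRANE null mean (z about 12), giving an upper-tail p-value of 8e-35.
Checking the whole ranking against the planted truth:

```r
genes <- subset(scored$result, node %in% control$gene_ids)
ranked <- genes$node[order(genes$rank)]
head(ranked %in% planted$truth$planted_genes, 25)   # 23 of top 25 planted
wilcoxon_eval(which(ranked %in% planted$truth$planted_genes),
              which(!ranked %in% planted$truth$planted_genes))
#> [1] 5.886732e-15
```

A Wilcoxon rank-sum p of 5.9e-15 says the 25 planted genes are ranked far
above the 125 background genes. The same pair ranked by raw differential
modularity score alone (`method = "alpaca"`) gives 7.1e-9: the CRANE null
sharpens the ranking by normalizing each node's score by its own
null variability.

## Command line

```sh
crane simulate --m 100 --n 500 --n-tf 10 --seed 1 --out-dir sim/
crane score --disease sim/disease.tsv --control sim/control.tsv \
      --method crane --alpha 0.1 --replicates 1000 --seed 1 --out sig.tsv
crane enrich --ranking sig.tsv --gmt sets.gmt --out enrich.tsv
```

Every run writes a YAML manifest (parameters, seeds, input checksums).

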