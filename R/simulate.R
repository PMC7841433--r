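#' Specification for synthetic PANDA-like networks
#'
#' Parametric stand-in for regulatory networks inferred from patient
#' expression data: z-score-like Gaussian edge weights with a latent block
#' (community) structure, a motif prior enriched inside blocks, and
#' edge-level replicate noise emulating the variation between networks
#' inferred from independent expression subsamples.
#'
#' @param m,n TF and gene counts.
#' @param n_blocks Number of latent communities (TFs and genes split
#'   round-robin after shuffling).
#' @param weight_base_sd Sd of the baseline z-score-like edge noise.
#' @param block_boost Mean weight added to intra-block edges; around three
#'   times `weight_base_sd` gives clearly recoverable communities.
#' @param replicate_noise_sd Edge-level sd BETWEEN replicate networks,
#'   emulating inference noise across expression subsamples.
#' @param motif_density Probability of a motif-prior edge outside blocks
#'   (all intra-block edges are motif-positive).
#' @param seed Integer seed.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(m = 100L, n = 500L, n_blocks = 5L,
                            weight_base_sd = 1, block_boost = 3,
                            replicate_noise_sd = 0.2, motif_density = 0.2,
                            seed = 1L) {
  stopifnot(m >= 2L, n >= 1L, n_blocks >= 1L, n_blocks <= min(m, n),
            weight_base_sd >= 0, replicate_noise_sd >= 0,
            motif_density > 0, motif_density < 1)
  structure(list(m = as.integer(m), n = as.integer(n),
                 n_blocks = as.integer(n_blocks),
                 weight_base_sd = weight_base_sd, block_boost = block_boost,
                 replicate_noise_sd = replicate_noise_sd,
                 motif_density = motif_density, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a baseline weighted bipartite network
#'
#' Edge weights are `Normal(0, weight_base_sd)` plus `block_boost` on
#' intra-block TF-gene pairs; the motif prior is Bernoulli(`motif_density`)
#' with all intra-block edges motif-positive. The latent block assignment
#' is attached as attribute `"blocks"` (a partition over all nodes) for
#' benchmarking recovery.
#'
#' @param spec A [simulation_spec()].
#' @return A [bipartite_network()] with motif prior and a `"blocks"`
#'   attribute.
#' @export
simulate_baseline <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    m <- spec$m; n <- spec$n
    tf_block <- sample(rep_len(seq_len(spec$n_blocks), m))
    gene_block <- sample(rep_len(seq_len(spec$n_blocks), n))
    same <- outer(tf_block, gene_block, "==")
    w <- matrix(stats::rnorm(m * n, sd = spec$weight_base_sd), m, n) +
      spec$block_boost * same
    prior <- matrix(stats::runif(m * n) < spec$motif_density, m, n) | same
    net <- bipartite_network(w, tf_ids = paste0("TF", seq_len(m)),
                             gene_ids = paste0("G", seq_len(n)),
                             motif_prior = prior)
    attr(net, "blocks") <- as_partition(stats::setNames(
      c(tf_block, gene_block), c(net$tf_ids, net$gene_ids)))
    net
  })
}

#' Simulate a replicate network around a baseline
#'
#' Adds independent `Normal(0, replicate_noise_sd)` noise per edge,
#' emulating a network re-inferred from an independent expression
#' subsample of the same condition.
#'
#' @param base A [bipartite_network()].
#' @param spec The [simulation_spec()] (for the noise sd).
#' @param replicate_seed Integer seed of this replicate.
#' @return A [bipartite_network()].
#' @export
simulate_replicate <- function(base, spec, replicate_seed) {
  stopifnot(inherits(base, "bipartite_network"), inherits(spec, "simulation_spec"))
  w <- base$weights
  if (spec$replicate_noise_sd > 0) {
    w <- w + with_seed(replicate_seed,
                       matrix(stats::rnorm(length(w), sd = spec$replicate_noise_sd),
                              nrow(w), ncol(w)))
  }
  bipartite_network(w, tf_ids = base$tf_ids, gene_ids = base$gene_ids,
                    motif_prior = base$motif_prior)
}

#' Plant an artificial disease module into a network
#'
#' Selects `n_tf` TFs and `5 * n_tf` genes uniformly without replacement
#' and sets every edge between the selected TFs and genes to
#' `planted_weight` (default 5), leaving all other edges untouched - the
#' standard planted disease module used to benchmark module-recovery
#' methods.
#'
#' @param net A [bipartite_network()].
#' @param n_tf Number of planted TFs (3 to 20 in the usual benchmark).
#' @param planted_weight Weight assigned to every planted edge.
#' @param seed Integer seed for the selection.
#' @return A list: `net` (the modified network) and `truth` (class
#'   `simulation_truth`: `planted_tfs`, `planted_genes`, `planted_weight`).
#' @export
plant_disease_module <- function(net, n_tf, planted_weight = 5, seed = 1L) {
  stopifnot(inherits(net, "bipartite_network"))
  n_gene <- 5L * as.integer(n_tf)
  if (n_tf > length(net$tf_ids) || n_gene > length(net$gene_ids)) {
    stop(sprintf("planted module (%d TFs, %d genes) larger than network (%d x %d)",
                 n_tf, n_gene, length(net$tf_ids), length(net$gene_ids)),
         call. = FALSE)
  }
  sel <- with_seed(seed, list(
    tfs = sample(net$tf_ids, n_tf),
    genes = sample(net$gene_ids, n_gene)))
  w <- net$weights
  w[sel$tfs, sel$genes] <- planted_weight
  out <- bipartite_network(w, tf_ids = net$tf_ids, gene_ids = net$gene_ids,
                           motif_prior = net$motif_prior)
  truth <- structure(list(planted_tfs = sel$tfs, planted_genes = sel$genes,
                          planted_weight = planted_weight),
                     class = "simulation_truth")
  list(net = out, truth = truth)
}

# Gene-level evaluation of one ranking against the planted truth:
# two-sided Wilcoxon rank-sum p of planted-gene ranks vs background-gene
# ranks, and the F-score with positives = top 1% (min 1) of ranked genes.
evaluate_ranking <- function(ranked_genes, truth) {
  planted <- truth$planted_genes
  is_planted <- ranked_genes %in% planted
  ranks <- seq_along(ranked_genes)
  wp <- wilcoxon_eval(ranks[is_planted], ranks[!is_planted])
  n_pos <- max(1L, round(0.01 * length(ranked_genes)))
  positives <- ranked_genes[seq_len(n_pos)]
  tp <- sum(positives %in% planted)
  fp <- n_pos - tp
  fn <- length(planted) - tp
  list(wilcoxon_p = wp, f_score = f_score(tp, fp, fn))
}

# Gene ranking from a scored pipeline result (genes only, best first).
ranked_gene_list <- function(result, gene_ids) {
  res <- result$result
  res <- res[res$node %in% gene_ids, , drop = FALSE]
  res$node[order(res$rank)]
}

#' Planted-module recovery benchmark
#'
#' Per trial: a baseline network is simulated; a replicate with planted
#' disease module (and replicate noise) plays the disease network; each
#' method ranks the genes; the ranking is scored by the Wilcoxon rank-sum
#' p-value of planted-gene ranks against background genes, and by the
#' F-score of the top 1% of ranked genes. TFs are excluded from the
#' gene-level evaluation.
#'
#' @param spec A [simulation_spec()].
#' @param n_tf_grid Planted module sizes (number of TFs; genes are 5x).
#' @param methods Subset of `"alpaca"`, `"crane"`, `"config"`, `"sbm"`,
#'   `"permute"`.
#' @param n_trials Trials per grid point.
#' @param seed Integer master seed.
#' @param K Null ensemble size for null-based methods.
#' @param alpha CRANE perturbation magnitude.
#' @param planted_weight Planted edge weight (0 gives a no-signal control
#'   run).
#' @return A tidy data frame: `method`, `n_tf`, `trial`, `wilcoxon_p`,
#'   `f_score`.
#' @export
run_benchmark <- function(spec, n_tf_grid = c(3L, 10L, 20L),
                          methods = c("alpaca", "crane"), n_trials = 3L,
                          seed = 1L, K = 200L, alpha = 0.1,
                          planted_weight = 5) {
  stopifnot(inherits(spec, "simulation_spec"))
  methods <- match.arg(methods, c("alpaca", "crane", "config", "sbm", "permute"),
                       several.ok = TRUE)
  grid <- expand.grid(n_tf = n_tf_grid, trial = seq_len(n_trials))
  seeds <- matrix(derive_seeds(seed, 3L * nrow(grid)), ncol = 3L)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    n_tf <- grid$n_tf[g]
    trial <- grid$trial[g]
    sp <- spec
    sp$seed <- seeds[g, 1L]
    base <- simulate_baseline(sp)
    disease <- simulate_replicate(base, sp, replicate_seed = seeds[g, 2L])
    if (planted_weight != 0) {
      planted <- plant_disease_module(disease, n_tf,
                                      planted_weight = planted_weight,
                                      seed = seeds[g, 3L])
      disease <- planted$net
      truth <- planted$truth
    } else {
      truth <- with_seed(seeds[g, 3L], structure(
        list(planted_tfs = sample(base$tf_ids, n_tf),
             planted_genes = sample(base$gene_ids, 5L * n_tf),
             planted_weight = 0),
        class = "simulation_truth"))
    }
    for (method in methods) {
      scored <- score_disease_modules(disease, base, method = method,
                                      alpha = alpha, K = K,
                                      seed = seeds[g, 1L], transform = TRUE)
      ev <- tryCatch(
        evaluate_ranking(ranked_gene_list(scored, base$gene_ids), truth),
        error = function(e) {
          stop(sprintf("benchmark failed (method %s, n_tf %d, trial %d): %s",
                       method, n_tf, trial, conditionMessage(e)), call. = FALSE)
        })
      out[[length(out) + 1L]] <- data.frame(
        method = method, n_tf = n_tf, trial = trial,
        wilcoxon_p = ev$wilcoxon_p, f_score = ev$f_score,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
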