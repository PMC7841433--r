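#' Fit a weighted stochastic block model on a fixed partition
#'
#' Rather than maximizing an SBM likelihood over block structure, the block
#' structure is taken from a modularity partition (the community structure
#' of the network, e.g. from [detect_communities()]) under the standard
#' modularity/SBM equivalence shortcut, and edge weights within each
#' (TF-community, gene-community) bundle are modeled as normal with the
#' bundle's sample mean and sample standard deviation (n-1 denominator).
#' A bundle with a single edge has no sample sd; it falls back to the
#' global edge-weight sd and is flagged.
#'
#' @param net A [bipartite_network()].
#' @param partition Partition covering all TF and gene nodes.
#' @return A list of class `sbm_params`: `mean` and `sd` matrices indexed
#'   by TF-community x gene-community, `fallback` (logical matrix marking
#'   bundles whose sd fell back to the global sd), `tf_comm`, `gene_comm`
#'   (per-node block labels) and ids.
#' @export
fit_sbm <- function(net, partition) {
  stopifnot(inherits(net, "bipartite_network"))
  partition <- as_partition(partition)
  miss <- setdiff(c(net$tf_ids, net$gene_ids), names(partition))
  if (length(miss) > 0L) {
    stop("partition is missing nodes: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  tf_comm <- partition[net$tf_ids]
  gene_comm <- partition[net$gene_ids]
  ta <- sort(unique(tf_comm))
  gb <- sort(unique(gene_comm))
  w <- net$weights
  fa <- factor(tf_comm, levels = ta)
  fb <- factor(gene_comm, levels = gb)
  cnt <- outer(tabulate(fa), tabulate(fb))
  sums <- rowsum(t(rowsum(w, fa)), fb)            # |gb| x |ta|
  mu <- t(sums) / cnt
  sq <- rowsum(t(rowsum(w^2, fa)), fb)
  vv <- (t(sq) - cnt * mu^2) / pmax(cnt - 1, 1)   # sample variance
  sdm <- sqrt(pmax(vv, 0))
  fallback <- cnt == 1L
  sdm[fallback] <- stats::sd(as.vector(w))
  dimnames(mu) <- dimnames(sdm) <- dimnames(fallback) <- list(ta, gb)
  structure(list(mean = mu, sd = sdm, fallback = fallback,
                 tf_comm = tf_comm, gene_comm = gene_comm,
                 tf_ids = net$tf_ids, gene_ids = net$gene_ids),
            class = "sbm_params")
}

#' Sample a network from fitted SBM block parameters
#'
#' Each edge weight is drawn independently from the normal distribution of
#' its (TF-community, gene-community) bundle. Sampled weights are not
#' clipped to the observed weight range.
#'
#' @param params An `sbm_params` from [fit_sbm()].
#' @param seed Integer seed; deterministic given the seed.
#' @return A [bipartite_network()].
#' @export
sample_sbm <- function(params, seed = 1L) {
  stopifnot(inherits(params, "sbm_params"))
  ia <- match(params$tf_comm, as.integer(rownames(params$mean)))
  ib <- match(params$gene_comm, as.integer(colnames(params$mean)))
  mu <- params$mean[ia, ib, drop = FALSE]
  sdm <- params$sd[ia, ib, drop = FALSE]
  m <- length(params$tf_ids)
  n <- length(params$gene_ids)
  w <- with_seed(seed,
                 matrix(stats::rnorm(m * n, mean = as.vector(mu),
                                     sd = as.vector(sdm)), m, n))
  bipartite_network(w, tf_ids = params$tf_ids, gene_ids = params$gene_ids)
}

#' Stratified random permutation of edge weights
#'
#' The naive randomization baseline: edge weights are shuffled, but only
#' within strata that preserve the prior biological structure. Edges are
#' stratified by motif status (motif-positive vs motif-negative, from the
#' network's motif prior) crossed with community placement (intra- vs
#' inter-community under the supplied partition); weights are permuted
#' within each stratum, so every stratum's weight multiset is exactly
#' preserved. Node strengths are generally not preserved, which is what
#' distinguishes this baseline from CRANE.
#'
#' @param net A [bipartite_network()] with a motif prior (or
#'   `allow_no_prior = TRUE` to fall back to motif-agnostic strata).
#' @param partition Partition covering all TF and gene nodes.
#' @param seed Integer seed; deterministic given the seed.
#' @param allow_no_prior Permit a network without motif prior, stratifying
#'   by community placement only.
#' @return A [bipartite_network()] with permuted weights.
#' @export
permute_edge_weights <- function(net, partition, seed = 1L,
                                 allow_no_prior = FALSE) {
  stopifnot(inherits(net, "bipartite_network"))
  partition <- as_partition(partition)
  miss <- setdiff(c(net$tf_ids, net$gene_ids), names(partition))
  if (length(miss) > 0L) {
    stop("partition is missing nodes: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(net$motif_prior) && !allow_no_prior) {
    stop("permute_edge_weights needs a motif prior (or allow_no_prior = TRUE ",
         "for community-only strata)", call. = FALSE)
  }
  tf_comm <- partition[net$tf_ids]
  gene_comm <- partition[net$gene_ids]
  intra <- outer(tf_comm, gene_comm, "==")
  strata <- if (is.null(net$motif_prior)) {
    as.integer(intra)
  } else {
    2L * as.integer(intra) + as.integer(net$motif_prior)
  }
  w <- net$weights
  w_new <- with_seed(seed, {
    for (sid in unique(as.vector(strata))) {
      idx <- which(strata == sid)
      if (length(idx) > 1L) w[idx] <- w[idx][sample.int(length(idx))]
    }
    w
  })
  bipartite_network(w_new, tf_ids = net$tf_ids, gene_ids = net$gene_ids,
                    motif_prior = net$motif_prior)
}
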