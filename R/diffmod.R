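#' Differential modularity matrix between a disease and a control network
#'
#' `D_ij = Ahat^d_ij - shat^c_i * dhat^c_j`, where `Ahat^d` is the disease
#' adjacency divided by its total weight and `shat^c`, `dhat^c` are the
#' control TF and gene strengths, each divided by the control total weight.
#' The entry measures how much more of the (unit-normalized) disease edge
#' weight falls on the pair (i, j) than expected from the control network's
#' strength product; by construction the matrix sums to zero.
#'
#' @param disease,control [bipartite_network()] objects over identical node
#'   sets in identical order, with nonnegative weights (use
#'   [transform_weights()] on z-score networks first).
#' @return An `m x n` matrix `D` with TF rows and gene columns.
#' @export
differential_modularity <- function(disease, control) {
  stopifnot(inherits(disease, "bipartite_network"),
            inherits(control, "bipartite_network"))
  if (!identical(disease$tf_ids, control$tf_ids) ||
      !identical(disease$gene_ids, control$gene_ids)) {
    stop("disease and control networks must share the same TF and gene ids ",
         "in the same order", call. = FALSE)
  }
  check_nonnegative(disease)
  check_nonnegative(control)
  Wd <- sum(disease$weights)
  Wc <- sum(control$weights)
  shat <- rowSums(control$weights) / Wc
  dhat <- colSums(control$weights) / Wc
  disease$weights / Wd - outer(shat, dhat)
}

# Per-node within-module sums of a differential modularity matrix under a
# fixed partition: TF nodes sum D over the genes of their module, gene nodes
# over the TFs of theirs.
module_scores <- function(D, partition, tf_ids, gene_ids) {
  partition <- as_partition(partition)
  tfc <- partition[tf_ids]
  gc <- partition[gene_ids]
  k <- max(partition)
  byg <- D %*% indicator_matrix(gc, k)                      # m x k
  byt <- crossprod(indicator_matrix(tfc, k), D)             # k x n
  s_tf <- byg[cbind(seq_along(tf_ids), tfc)]
  s_gene <- byt[cbind(gc, seq_along(gene_ids))]
  stats::setNames(c(s_tf, s_gene), c(tf_ids, gene_ids))
}

#' Detect differential modules and score nodes (ALPACA-style)
#'
#' Computes the differential modularity matrix [differential_modularity()]
#' of the disease network against the control, then finds the joint TF/gene
#' partition maximizing the total within-module differential modularity by
#' Louvain-style optimization (simultaneous best moves with randomized
#' restarts plus greedy agglomeration; only nonnegative gains are accepted
#' and ties keep the current community). Each node's score is its
#' within-module row (TF) or column (gene) sum of `D` - its contribution to
#' the differential modularity of its own module.
#'
#' @inheritParams differential_modularity
#' @param seed Integer seed; results are deterministic given the seed but
#'   vary across seeds (the optimizer is stochastic).
#' @param n_restarts Random restarts for the optimizer.
#' @return A list of class `alpaca_result`: `partition` (module assignment
#'   over all nodes), `scores` (named per-node differential modularity
#'   scores), and `objective` (total within-module differential modularity).
#' @export
alpaca_detect <- function(disease, control, seed = 1L, n_restarts = 20L) {
  D <- differential_modularity(disease, control)
  res <- optimize_bipartite_labels(D, seed = seed, n_restarts = n_restarts)
  partition <- as_partition(
    stats::setNames(c(res$tfc, res$gc), c(disease$tf_ids, disease$gene_ids)))
  scores <- module_scores(D, partition, disease$tf_ids, disease$gene_ids)
  structure(list(partition = partition, scores = scores,
                 objective = res$objective),
            class = "alpaca_result")
}

#' @export
print.alpaca_result <- function(x, ...) {
  cat(sprintf("alpaca_result: %d nodes in %d modules, objective = %.6g\n",
              length(x$partition), max(x$partition), x$objective))
  invisible(x)
}

#' Consensus matrix of a set of partitions
#'
#' `C_ij` is the fraction of partitions in which nodes i and j share a
#' community; `C_ii = 1`.
#'
#' @param partitions List of at least two partitions over a common node set.
#' @return A list of class `consensus_matrix`: `C` (symmetric matrix with
#'   entries in `[0, 1]`) and `n_partitions`.
#' @export
consensus_matrix <- function(partitions) {
  if (length(partitions) < 2L) stop("need at least 2 partitions", call. = FALSE)
  partitions <- lapply(partitions, as_partition)
  nodes <- names(partitions[[1L]])
  C <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (p in partitions) {
    if (!setequal(names(p), nodes)) {
      stop("all partitions must cover the same node set", call. = FALSE)
    }
    lab <- p[nodes]
    C <- C + outer(lab, lab, "==")
  }
  C <- C / length(partitions)
  structure(list(C = C, n_partitions = length(partitions)),
            class = "consensus_matrix")
}

#' Consensus clustering of stochastic partitions
#'
#' Builds the co-membership consensus matrix over all supplied partitions
#' and applies the Louvain algorithm (igraph) to the weighted graph whose
#' edge weights are the co-assignment frequencies, returning the consensus
#' membership.
#'
#' @param partitions List of at least two partitions over a common node set.
#' @param seed Integer seed for the Louvain run.
#' @return A canonicalized consensus partition (named vector).
#' @export
consensus_cluster <- function(partitions, seed = 1L) {
  cm <- consensus_matrix(partitions)
  C <- cm$C
  diag(C) <- 0
  g <- igraph::graph_from_adjacency_matrix(C, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- with_seed(seed, igraph::membership(igraph::cluster_louvain(g)))
  as_partition(stats::setNames(as.integer(memb), rownames(cm$C)))
}
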