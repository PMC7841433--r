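# Label-optimization engine shared by bipartite community detection and
# differential-modularity module detection.
#
# Given an m x n "gain" matrix M over (TF, gene) pairs, find a joint labeling
# of the m + n nodes maximizing sum_{c(tf_i) == c(gene_j)} M[i, j].
# Alternating scheme: holding gene labels fixed, every TF's objective
# contribution is separable, so all TFs move simultaneously to their best
# community (ties keep the current label; a node whose best attainable gain
# is negative goes to its own singleton); then the same for genes. Each
# half-sweep is a coordinate-wise maximum, so the objective is nondecreasing
# and the sweep converges. A greedy community-merge phase (accept the best
# positive pairwise merge until none remains) escapes the singleton traps
# local moves cannot, mirroring the agglomeration step of Louvain-type
# algorithms. Best result over random restarts is returned.

indicator_matrix <- function(labels, k) {
  ind <- matrix(0, length(labels), k)
  ind[cbind(seq_along(labels), labels)] <- 1
  ind
}

cross_community_sums <- function(M, tfc, gc, k) {
  # S[a, b] = sum of M over TFs with label a and genes with label b
  crossprod(indicator_matrix(tfc, k), M %*% indicator_matrix(gc, k))
}

bipartite_label_objective <- function(M, tfc, gc) {
  k <- max(tfc, gc)
  sum(diag(cross_community_sums(M, tfc, gc, k)))
}

# One simultaneous best-move update for the row side given column labels.
# Returns new row labels in 1..(k + m) space (fresh singletons get new ids).
move_side <- function(M, own, other, k) {
  gains <- M %*% indicator_matrix(other, k)                     # m x k
  best_lab <- max.col(gains, ties.method = "first")
  best_raw <- gains[cbind(seq_along(own), best_lab)]
  best_gain <- pmax(best_raw, 0)
  cur_gain <- gains[cbind(seq_along(own), own)]
  new <- ifelse(best_raw <= 0,
                k + seq_along(own),              # nothing positive: singleton
                best_lab)
  keep <- cur_gain >= best_gain - 1e-13          # tie-break: keep current
  new[keep] <- own[keep]
  new
}

relabel_joint <- function(tfc, gc) {
  all <- c(tfc, gc)
  new <- match(all, unique(all))
  list(tfc = new[seq_along(tfc)], gc = new[-seq_along(tfc)])
}

optimize_bipartite_labels_once <- function(M, tfc, gc, max_sweeps = 200L) {
  m <- nrow(M)
  n <- ncol(M)
  lab <- relabel_joint(tfc, gc)
  obj <- bipartite_label_objective(M, lab$tfc, lab$gc)
  repeat {
    improved <- FALSE
    for (sweep in seq_len(max_sweeps)) {
      k <- max(lab$tfc, lab$gc)
      tfc_new <- move_side(M, lab$tfc, lab$gc, k)
      lab <- relabel_joint(tfc_new, lab$gc)
      k <- max(lab$tfc, lab$gc)
      gc_new <- move_side(t(M), lab$gc, lab$tfc, k)
      lab <- relabel_joint(lab$tfc, gc_new)
      new_obj <- bipartite_label_objective(M, lab$tfc, lab$gc)
      if (new_obj > obj + 1e-13) {
        obj <- new_obj
        improved <- TRUE
      } else break
    }
    # merge phase
    merged <- FALSE
    repeat {
      k <- max(lab$tfc, lab$gc)
      if (k == 1L) break
      S <- cross_community_sums(M, lab$tfc, lab$gc, k)
      G <- S + t(S)
      diag(G) <- -Inf
      best <- which.max(G)
      if (G[best] < -1e-13) break  # zero-gain merges accepted (degenerate ties)
      ab <- arrayInd(best, dim(G))
      a <- ab[1L]; b <- ab[2L]
      lab$tfc[lab$tfc == b] <- a
      lab$gc[lab$gc == b] <- a
      lab <- relabel_joint(lab$tfc, lab$gc)
      obj <- obj + G[best]
      merged <- TRUE
    }
    if (!merged && !improved) break
  }
  list(tfc = lab$tfc, gc = lab$gc,
       objective = bipartite_label_objective(M, lab$tfc, lab$gc))
}

optimize_bipartite_labels <- function(M, seed = 1L, n_restarts = 20L,
                                      init = NULL) {
  m <- nrow(M)
  n <- ncol(M)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      if (r == 1L && !is.null(init)) {
        tfc <- init$tfc
        gc <- init$gc
      } else if (r <= 2L) {
        # singleton start
        tfc <- seq_len(m)
        gc <- m + seq_len(n)
      } else {
        k0 <- sample.int(max(2L, ceiling(sqrt(m + n))), 1L)
        tfc <- sample.int(k0, m, replace = TRUE)
        gc <- sample.int(k0, n, replace = TRUE)
      }
      res <- optimize_bipartite_labels_once(M, tfc, gc)
      if (is.null(best) || res$objective > best$objective) best <- res
    }
    best
  })
}

#' Weighted bipartite (Barber-type) modularity of a partition
#'
#' `Q = (1/W) * sum_ij (A_ij - s_i d_j / W) * delta(c(tf_i), c(gene_j))`,
#' where `s_i`, `d_j` are TF and gene strengths and `W` the total network
#' weight. Only TF-gene pairs sharing a community contribute, the bipartite
#' analog of Newman-Girvan modularity.
#'
#' @param net A [bipartite_network()] with nonnegative weights.
#' @param partition Partition over all TF and gene nodes.
#' @return Modularity value (at most 1).
#' @export
bipartite_modularity <- function(net, partition) {
  stopifnot(inherits(net, "bipartite_network"))
  partition <- as_partition(partition)
  check_nonnegative(net)
  miss <- setdiff(c(net$tf_ids, net$gene_ids), names(partition))
  if (length(miss) > 0L) {
    stop("partition is missing nodes: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  A <- net$weights
  W <- sum(A)
  s <- rowSums(A)
  d <- colSums(A)
  M <- (A - outer(s, d) / W) / W
  tfc <- partition[net$tf_ids]
  gc <- partition[net$gene_ids]
  sum(M[outer(tfc, gc, "==")])
}

check_nonnegative <- function(net) {
  if (min(net$weights) < 0) {
    stop("negative edge weights: apply transform_weights() before ",
         "modularity-based community detection", call. = FALSE)
  }
  if (sum(net$weights) <= 0) stop("total network weight must be positive", call. = FALSE)
  invisible(net)
}

#' Community detection on a weighted bipartite network
#'
#' Maximizes the weighted bipartite (Barber-type) modularity by alternating
#' label optimization with greedy community merging (the CONDOR-style
#' approach for TF-gene networks), best of `n_restarts` random restarts.
#' Weights must be nonnegative; z-score networks should be passed through
#' [transform_weights()] first.
#'
#' @param net A [bipartite_network()] with nonnegative weights.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param n_restarts Number of random restarts.
#' @return A list of class `community_result`: `partition` (named vector
#'   over all TF and gene nodes) and `modularity` (the achieved Q).
#' @export
detect_communities <- function(net, seed = 1L, n_restarts = 20L) {
  stopifnot(inherits(net, "bipartite_network"))
  check_nonnegative(net)
  A <- net$weights
  W <- sum(A)
  M <- (A - outer(rowSums(A), colSums(A)) / W) / W
  res <- optimize_bipartite_labels(M, seed = seed, n_restarts = n_restarts)
  partition <- as_partition(
    stats::setNames(c(res$tfc, res$gc), c(net$tf_ids, net$gene_ids)))
  structure(list(partition = partition, modularity = res$objective),
            class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  cat(sprintf("community_result: %d nodes in %d communities, Q = %.6g\n",
              length(x$partition), max(x$partition), x$modularity))
  invisible(x)
}
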