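#' Weighted bipartite TF-gene network
#'
#' Container for a complete weighted bipartite network with transcription
#' factors (TFs) as rows and target genes as columns, the object produced by
#' regulatory network inference tools such as PANDA. Edge weights are
#' unitless z-score-like quantities and may be negative. An optional binary
#' motif prior of the same shape marks edges supported by a TF binding-site
#' motif.
#'
#' @param weights Numeric matrix, `m x n`, all entries finite. Row and
#'   column names, when present, are used as TF and gene identifiers.
#' @param tf_ids Character vector of `m` unique TF identifiers.
#' @param gene_ids Character vector of `n` unique gene identifiers. Must be
#'   disjoint from `tf_ids`.
#' @param motif_prior Optional logical matrix of the same dimensions as
#'   `weights`; `TRUE` marks a motif-supported edge.
#' @return An object of class `bipartite_network`: a list with elements
#'   `tf_ids`, `gene_ids`, `weights` (dimnamed matrix) and `motif_prior`
#'   (matrix or `NULL`).
#' @examples
#' net <- bipartite_network(matrix(rnorm(6), 2, 3),
#'                          tf_ids = c("TF1", "TF2"),
#'                          gene_ids = c("G1", "G2", "G3"))
#' node_strengths(net)
#' @export
bipartite_network <- function(weights,
                              tf_ids = rownames(weights),
                              gene_ids = colnames(weights),
                              motif_prior = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  m <- nrow(weights)
  n <- ncol(weights)
  if (m < 2L) stop("a bipartite network needs at least 2 TFs (rows)", call. = FALSE)
  if (n < 1L) stop("a bipartite network needs at least 1 gene (column)", call. = FALSE)
  if (!all(is.finite(weights))) stop("all edge weights must be finite", call. = FALSE)
  if (is.null(tf_ids)) tf_ids <- paste0("TF", seq_len(m))
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(n))
  tf_ids <- as.character(tf_ids)
  gene_ids <- as.character(gene_ids)
  if (length(tf_ids) != m) stop("`tf_ids` length must equal nrow(weights)", call. = FALSE)
  if (length(gene_ids) != n) stop("`gene_ids` length must equal ncol(weights)", call. = FALSE)
  if (anyDuplicated(tf_ids)) stop("duplicated TF identifiers", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicated gene identifiers", call. = FALSE)
  if (length(intersect(tf_ids, gene_ids)) > 0L) {
    stop("TF and gene identifiers must be disjoint", call. = FALSE)
  }
  if (!is.null(motif_prior)) {
    if (!is.matrix(motif_prior) || !identical(dim(motif_prior), dim(weights))) {
      stop("`motif_prior` must be a matrix with the same dimensions as `weights`",
           call. = FALSE)
    }
    motif_prior <- matrix(as.logical(motif_prior), m, n)
    if (anyNA(motif_prior)) stop("`motif_prior` must be logical 0/1 without NA", call. = FALSE)
    dimnames(motif_prior) <- list(tf_ids, gene_ids)
  }
  dimnames(weights) <- list(tf_ids, gene_ids)
  structure(
    list(tf_ids = tf_ids, gene_ids = gene_ids,
         weights = weights, motif_prior = motif_prior),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d TFs x %d genes%s\n",
              length(x$tf_ids), length(x$gene_ids),
              if (is.null(x$motif_prior)) "" else " (with motif prior)"))
  cat(sprintf("  weight range: [%.4g, %.4g], total weight: %.6g\n",
              min(x$weights), max(x$weights), sum(x$weights)))
  invisible(x)
}

#' Symmetric weighted unipartite network
#'
#' Container for a symmetric weighted network without self-loops, such as a
#' WGCNA-style gene co-expression network.
#'
#' @param weights Symmetric numeric matrix (within 1e-12) with zero diagonal.
#' @param node_ids Character vector of unique node identifiers.
#' @return An object of class `unipartite_network`.
#' @export
unipartite_network <- function(weights, node_ids = rownames(weights)) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  q <- nrow(weights)
  if (ncol(weights) != q) stop("`weights` must be square", call. = FALSE)
  if (q < 2L) stop("a network needs at least 2 nodes", call. = FALSE)
  if (!all(is.finite(weights))) stop("all edge weights must be finite", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("`weights` must be symmetric (tolerance 1e-12)", call. = FALSE)
  }
  if (any(diag(weights) != 0)) {
    stop("self-loops are not allowed: diagonal must be exactly zero", call. = FALSE)
  }
  if (is.null(node_ids)) node_ids <- paste0("N", seq_len(q))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != q) stop("`node_ids` length must equal nrow(weights)", call. = FALSE)
  if (anyDuplicated(node_ids)) stop("duplicated node identifiers", call. = FALSE)
  weights <- (weights + t(weights)) / 2  # exact symmetry
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, weights = weights),
            class = "unipartite_network")
}

#' @export
print.unipartite_network <- function(x, ...) {
  cat(sprintf("unipartite_network: %d nodes, weight range [%.4g, %.4g]\n",
              length(x$node_ids), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Node strengths of a network
#'
#' The strength of a node is the sum of the edge weights adjoining it, the
#' weighted generalization of degree. For a bipartite network the TF
#' strengths are the row sums and the gene strengths the column sums of the
#' adjacency matrix; both sides sum to the total network weight.
#'
#' @param net A `bipartite_network` or `unipartite_network`.
#' @return For bipartite input, a list with named numeric vectors `tf` and
#'   `gene`; for unipartite input, a single named numeric vector.
#' @export
node_strengths <- function(net) {
  UseMethod("node_strengths")
}

#' @export
node_strengths.bipartite_network <- function(net) {
  list(tf = rowSums(net$weights), gene = colSums(net$weights))
}

#' @export
node_strengths.unipartite_network <- function(net) {
  rowSums(net$weights)
}

#' Softplus transform of edge weights
#'
#' Maps z-score-like edge weights `w` to strictly positive weights
#' `W = log(exp(w) + 1)`. This is the standard transform applied to PANDA
#' networks before methods that require positive weights (community
#' detection, the configuration model). Evaluated in a numerically stable
#' form so that `|w|` up to several hundred neither overflows nor
#' underflows.
#'
#' @param net A `bipartite_network` or `unipartite_network` (the unipartite
#'   diagonal is left at zero).
#' @return A network of the same class with transformed weights; the motif
#'   prior, when present, is carried over unchanged.
#' @export
transform_weights <- function(net) {
  UseMethod("transform_weights")
}

softplus <- function(w) {
  # log(1 + exp(w)) = max(w, 0) + log1p(exp(-|w|))
  pmax(w, 0) + log1p(exp(-abs(w)))
}

#' @export
transform_weights.bipartite_network <- function(net) {
  bipartite_network(softplus(net$weights),
                    tf_ids = net$tf_ids, gene_ids = net$gene_ids,
                    motif_prior = net$motif_prior)
}

#' @export
transform_weights.unipartite_network <- function(net) {
  w <- softplus(net$weights)
  diag(w) <- 0
  unipartite_network(w, node_ids = net$node_ids)
}

# Evaluate a stochastic computation under a caller-supplied seed without
# disturbing the global RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive per-replicate seeds from one user seed: a fixed-size draw from the
# seeded stream, so replicate k is reproducible given (seed, K).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
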