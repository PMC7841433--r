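#' Make a network randomizer for null-ensemble construction
#'
#' Wraps each randomization method as a uniform `(net, seed) -> net`
#' function, the interface consumed by [build_null()] and
#' [randomize_ensemble()]. `"config"` and `"sbm"` fit their model to the
#' supplied network once, up front; `"sbm"` and `"permute"` need a
#' partition of that network (e.g. from [detect_communities()]).
#'
#' @param method One of `"crane"`, `"config"`, `"sbm"`, `"permute"`.
#' @param net The (control) network the nulls will perturb; used here for
#'   up-front model fitting.
#' @param alpha CRANE perturbation magnitude.
#' @param partition Partition of `net` (required for `"sbm"` and
#'   `"permute"`).
#' @param allow_no_prior Passed to [permute_edge_weights()].
#' @return A function `(net, seed) -> bipartite_network`.
#' @export
make_randomizer <- function(method = c("crane", "config", "sbm", "permute"),
                            net = NULL, alpha = 0.1, partition = NULL,
                            allow_no_prior = FALSE) {
  method <- match.arg(method)
  switch(method,
    crane = function(net, seed) {
      crane_bipartite(net, crane_config(alpha = alpha, seed = seed))
    },
    config = {
      stopifnot(!is.null(net))
      st <- node_strengths(net)
      params <- fit_configuration_model(st$tf, st$gene)
      function(net, seed) sample_configuration_network(params, seed = seed)
    },
    sbm = {
      stopifnot(!is.null(net), !is.null(partition))
      params <- fit_sbm(net, partition)
      function(net, seed) sample_sbm(params, seed = seed)
    },
    permute = {
      stopifnot(!is.null(partition))
      part <- partition
      function(net, seed) {
        permute_edge_weights(net, part, seed = seed,
                             allow_no_prior = allow_no_prior)
      }
    })
}

#' Build a null ensemble of node scores from randomized networks
#'
#' For each of `K` replicates, the control network is randomized, the
#' differential modularity matrix of the perturbed network against the
#' original control is computed, and every node is scored by its
#' within-module sum under the FIXED module assignment found on the true
#' disease/control pair. The resulting per-node score vectors form the null
#' distribution of the differential modularity score under "no disease
#' effect, only perturbation noise".
#'
#' @param control A [bipartite_network()] with nonnegative weights.
#' @param partition Module assignment from [alpaca_detect()] on the true
#'   pair; held fixed across replicates.
#' @param randomizer Function `(net, seed) -> net`, see [make_randomizer()].
#' @param K Number of replicates (at least 2).
#' @param seed Integer seed; per-replicate seeds are derived from it by a
#'   fixed-size draw from the seeded stream.
#' @return A list of class `null_ensemble`: `scores` (`K x n_nodes` matrix,
#'   columns named by node) and `K`.
#' @export
build_null <- function(control, partition, randomizer, K, seed = 1L) {
  stopifnot(inherits(control, "bipartite_network"))
  if (K < 2L) stop("need at least K = 2 null replicates", call. = FALSE)
  partition <- as_partition(partition)
  seeds <- derive_seeds(seed, K)
  nodes <- c(control$tf_ids, control$gene_ids)
  scores <- matrix(NA_real_, K, length(nodes), dimnames = list(NULL, nodes))
  for (k in seq_len(K)) {
    np <- tryCatch(randomizer(control, seeds[k]), error = function(e) {
      stop(sprintf("randomizer failed at replicate %d: %s", k, conditionMessage(e)),
           call. = FALSE)
    })
    D <- differential_modularity(np, control)
    scores[k, ] <- module_scores(D, partition, control$tf_ids, control$gene_ids)
  }
  structure(list(scores = scores, K = K), class = "null_ensemble")
}

#' Normal-fit node p-values against a null ensemble
#'
#' Fits each node's null score distribution as normal with the ensemble
#' sample mean and sample sd (n-1), and computes the upper-tail p-value
#' `p = 1 - Phi((S0 - mean) / sd)` for the node's observed differential
#' modularity score. P-values are Benjamini-Hochberg adjusted, by default
#' within each module (pass `family = "global"` to adjust across all nodes
#' together), and nodes are ranked by ascending p-value with ties broken by
#' descending observed score, then by label.
#'
#' A degenerate null (sd = 0) yields p = 0, 1 or 0.5 according to the sign
#' of `S0 - mean`, with a warning.
#'
#' @param scores Named vector of observed node scores (e.g.
#'   `alpaca_detect(...)$scores`).
#' @param ensemble A `null_ensemble` from [build_null()] covering every
#'   scored node.
#' @param partition Optional module assignment; required for per-module
#'   adjustment and reported in the output.
#' @param family `"module"` (default, requires `partition`) or `"global"`.
#' @return A data frame of class `node_significance` with columns `node`,
#'   `module`, `score`, `null_mean`, `null_sd`, `p`, `p_adj`, `rank`,
#'   ordered by rank.
#' @export
node_pvalues <- function(scores, ensemble, partition = NULL,
                         family = c("module", "global")) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  family <- match.arg(family)
  nodes <- names(scores)
  miss <- setdiff(nodes, colnames(ensemble$scores))
  if (length(miss) > 0L) {
    stop("ensemble is missing nodes: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  null_scores <- ensemble$scores[, nodes, drop = FALSE]
  mu <- colMeans(null_scores)
  sdv <- apply(null_scores, 2L, stats::sd)
  z <- (as.numeric(scores) - mu) / sdv
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (any(sdv == 0)) {
    warning("degenerate null (sd = 0) for ", sum(sdv == 0), " node(s)")
    diff0 <- as.numeric(scores)[sdv == 0] - mu[sdv == 0]
    p[sdv == 0] <- ifelse(diff0 > 0, 0, ifelse(diff0 < 0, 1, 0.5))
  }
  if (family == "module") {
    if (is.null(partition)) {
      stop("per-module adjustment needs `partition`; ",
           "use family = \"global\" otherwise", call. = FALSE)
    }
    partition <- as_partition(partition)
    mod <- partition[nodes]
    p_adj <- stats::ave(p, mod, FUN = function(x) stats::p.adjust(x, "BH"))
  } else {
    mod <- if (is.null(partition)) rep(NA_integer_, length(nodes)) else
      as_partition(partition)[nodes]
    p_adj <- stats::p.adjust(p, "BH")
  }
  ord <- order(p, -as.numeric(scores), nodes)
  rank <- integer(length(nodes))
  rank[ord] <- seq_along(nodes)
  out <- data.frame(node = nodes, module = as.integer(mod),
                    score = as.numeric(scores), null_mean = mu, null_sd = sdv,
                    p = p, p_adj = p_adj, rank = rank,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("node_significance", "data.frame")
  out
}

#' Rank-sum comparison of planted-module ranks against background
#'
#' Two-sided Wilcoxon rank-sum test (exact for small tie-free samples,
#' normal approximation with continuity and tie correction otherwise)
#' comparing the rank positions of true-module genes against the remaining
#' genes. A Kolmogorov-Smirnov variant is available; the two give similar
#' answers on well-separated rankings.
#'
#' @param ranks_true,ranks_background Numeric rank vectors, both nonempty.
#' @param method `"wilcoxon"` (default) or `"ks"`.
#' @return The two-sided p-value.
#' @export
wilcoxon_eval <- function(ranks_true, ranks_background,
                          method = c("wilcoxon", "ks")) {
  method <- match.arg(method)
  if (length(ranks_true) == 0L || length(ranks_background) == 0L) {
    stop("both rank groups must be nonempty", call. = FALSE)
  }
  if (method == "ks") {
    return(suppressWarnings(
      stats::ks.test(ranks_true, ranks_background)$p.value))
  }
  suppressWarnings(
    stats::wilcox.test(ranks_true, ranks_background,
                       alternative = "two.sided")$p.value)
}

#' F-score from confusion counts
#'
#' `F = TP / (TP + 0.5 * (FP + FN))`, the harmonic-mean F1 written in
#' confusion-count form; positives are conventionally the top 1% of the
#' ranked node list.
#'
#' @param tp,fp,fn Nonnegative counts, not all zero.
#' @return A number in `[0, 1]`.
#' @export
f_score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) {
    stop("F-score undefined: no positives or true-module members", call. = FALSE)
  }
  tp / (tp + 0.5 * (fp + fn))
}

#' Hypergeometric enrichment sweep over ranking thresholds
#'
#' Threshold-independent gene-set enrichment of a ranked gene list: at each
#' threshold `t` (top 25, 50, ..., 500 genes by default) the overlap of the
#' top-`t` genes with each gene set is tested with the hypergeometric
#' upper-tail p-value against the supplied universe; p-values are BH
#' adjusted across sets within each threshold. The per-set summary is the
#' mean of `-log10(p)` across thresholds (20 values per set when all
#' thresholds apply).
#'
#' @param ranked_genes Character vector of genes, best first.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gene_sets()]).
#' @param universe Character vector of all candidate genes; must contain
#'   `ranked_genes`.
#' @param thresholds Integer thresholds; those exceeding
#'   `length(ranked_genes)` are dropped with a warning.
#' @return A list of class `enrichment_sweep`: `table` (long data frame:
#'   set, threshold, overlap, set_size, p, p_adj) and `summary` (per-set
#'   mean `-log10(p)`, descending).
#' @export
enrichment_sweep <- function(ranked_genes, gene_sets, universe,
                             thresholds = seq(25L, 500L, by = 25L)) {
  if (length(gene_sets) == 0L) stop("empty gene set collection", call. = FALSE)
  if (!all(ranked_genes %in% universe)) {
    stop("`universe` must contain every ranked gene", call. = FALSE)
  }
  drop <- thresholds > length(ranked_genes)
  if (any(drop)) {
    warning(sum(drop), " threshold(s) exceed the ranked list length; dropped")
    thresholds <- thresholds[!drop]
  }
  if (length(thresholds) == 0L) stop("no usable thresholds", call. = FALSE)
  N <- length(unique(universe))
  sets <- lapply(gene_sets, function(g) intersect(g, universe))
  rows <- lapply(thresholds, function(t) {
    top <- ranked_genes[seq_len(t)]
    ov <- vapply(sets, function(g) length(intersect(top, g)), integer(1))
    K <- vapply(sets, length, integer(1))
    p <- stats::phyper(ov - 1L, K, N - K, t, lower.tail = FALSE)
    data.frame(set = names(sets), threshold = t, overlap = ov, set_size = K,
               p = p, p_adj = stats::p.adjust(p, "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mean_nlp <- tapply(-log10(tab$p), tab$set, mean)
  summary <- data.frame(set = names(mean_nlp),
                        mean_neglog10_p = as.numeric(mean_nlp),
                        row.names = NULL, stringsAsFactors = FALSE)
  summary <- summary[order(-summary$mean_neglog10_p, summary$set), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(table = tab, summary = summary), class = "enrichment_sweep")
}

#' End-to-end disease-module scoring pipeline
#'
#' The full workflow: (optionally) softplus-transform both networks,
#' detect differential modules on the disease/control pair, build a null
#' ensemble of node scores by randomizing the control network, and return
#' per-node significance. With `method = "alpaca"` no null is built and
#' nodes are ranked by their raw differential modularity score.
#'
#' @param disease,control [bipartite_network()] objects over the same
#'   nodes.
#' @param method `"crane"`, `"config"`, `"sbm"`, `"permute"` (null-based
#'   ranking) or `"alpaca"` (raw-score ranking).
#' @param alpha CRANE perturbation magnitude.
#' @param K Null ensemble size.
#' @param seed Integer seed driving module detection and the ensemble.
#' @param transform Apply [transform_weights()] to both networks first
#'   (required when weights may be negative).
#' @param family BH adjustment family, see [node_pvalues()].
#' @param allow_no_prior Passed to the permutation randomizer.
#' @return A list of class `crane_scores`: `result` (the
#'   `node_significance` data frame, or a score-ranked frame for
#'   `"alpaca"`), `partition`, `scores`, `method`.
#' @export
score_disease_modules <- function(disease, control,
                                  method = c("crane", "alpaca", "config",
                                             "sbm", "permute"),
                                  alpha = 0.1, K = 1000L, seed = 1L,
                                  transform = TRUE,
                                  family = c("module", "global"),
                                  allow_no_prior = FALSE) {
  method <- match.arg(method)
  family <- match.arg(family)
  if (transform) {
    disease <- transform_weights(disease)
    control <- transform_weights(control)
  }
  det <- alpaca_detect(disease, control, seed = seed)
  if (method == "alpaca") {
    nodes <- names(det$scores)
    ord <- order(-det$scores, nodes)
    rank <- integer(length(nodes))
    rank[ord] <- seq_along(nodes)
    res <- data.frame(node = nodes, module = as.integer(det$partition[nodes]),
                      score = as.numeric(det$scores), rank = rank,
                      row.names = NULL, stringsAsFactors = FALSE)
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
  } else {
    part_control <- NULL
    if (method %in% c("sbm", "permute")) {
      part_control <- detect_communities(control, seed = seed)$partition
    }
    randomizer <- make_randomizer(method, net = control, alpha = alpha,
                                  partition = part_control,
                                  allow_no_prior = allow_no_prior)
    ens <- build_null(control, det$partition, randomizer, K = K, seed = seed)
    res <- node_pvalues(det$scores, ens, partition = det$partition,
                        family = family)
  }
  structure(list(result = res, partition = det$partition,
                 scores = det$scores, method = method),
            class = "crane_scores")
}

#' @export
print.crane_scores <- function(x, ...) {
  cat(sprintf("crane_scores (%s): %d nodes, %d modules\n",
              x$method, nrow(x$result), max(x$partition)))
  print(utils::head(x$result))
  invisible(x)
}
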