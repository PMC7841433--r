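# Programmatic fixtures shared across test files.

random_net <- function(m, n, seed, sd = 1, motif = FALSE) {
  withr::with_seed(seed, {
    w <- matrix(rnorm(m * n, sd = sd), m, n)
    prior <- if (motif) matrix(runif(m * n) < 0.3, m, n)
    bipartite_network(w, tf_ids = paste0("TF", seq_len(m)),
                      gene_ids = paste0("G", seq_len(n)), motif_prior = prior)
  })
}

random_sym_net <- function(q, seed, sd = 1) {
  withr::with_seed(seed, {
    w <- matrix(rnorm(q * q, sd = sd), q, q)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    unipartite_network(w, node_ids = paste0("N", seq_len(q)))
  })
}

random_partition <- function(nodes, k, seed) {
  withr::with_seed(seed, as_partition(
    setNames(sample.int(k, length(nodes), replace = TRUE), nodes)))
}

# All set partitions of a character vector (Bell-number enumeration),
# used as the exhaustive oracle on tiny instances.
all_partitions <- function(els) {
  if (length(els) == 0L) return(list(list()))
  rest <- all_partitions(els[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], els[1L])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(els[1L]))
  }
  out
}

blocks_to_partition <- function(blocks, nodes) {
  lab <- integer(length(nodes))
  names(lab) <- nodes
  for (i in seq_along(blocks)) lab[blocks[[i]]] <- i
  lab
}

max_rel_strength_err <- function(out, ref) {
  s1 <- node_strengths(ref)
  s2 <- node_strengths(out)
  v1 <- c(s1$tf, s1$gene)
  v2 <- c(s2$tf, s2$gene)
  max(abs(v2 - v1) / pmax(abs(v1), 1e-12))
}
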