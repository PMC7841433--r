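#' Fit the maximum-entropy configuration model to a strength sequence
#'
#' For a complete weighted bipartite network with positive weights, the
#' strength-constrained maximum-entropy ensemble has independent exponential
#' edge weights with rate `theta_i + theta_j` (one Lagrange multiplier per
#' TF and per gene). The multipliers solve the maximum-likelihood system
#' `sum_j 1 / (theta_i + theta_j) = S_i` for every node, i.e. each node's
#' expected strength matches its observed strength.
#'
#' The solver alternates between the TF side and the gene side: holding one
#' side fixed, every node's equation is an independent scalar root problem
#' (strictly monotone in its own multiplier), solved for all nodes at once
#' by safeguarded Newton steps with positivity projection
#' (`theta_i + theta_j > 0` throughout). Convergence is declared when the
#' maximum relative residual drops below `tol`.
#'
#' @param tf_strengths,gene_strengths Strictly positive named strength
#'   vectors (apply [transform_weights()] to z-score networks first; the
#'   model is undefined for nonpositive strengths). Their sums must agree
#'   (both equal the total network weight).
#' @param tol Maximum relative residual for convergence.
#' @param max_iter Maximum number of alternating sweeps.
#' @return A list of class `config_model` with `theta_tf`, `theta_gene`
#'   (named multiplier vectors) and `residual` (worst relative residual).
#' @export
fit_configuration_model <- function(tf_strengths, gene_strengths,
                                    tol = 1e-8, max_iter = 10000L) {
  s <- as.numeric(tf_strengths)
  d <- as.numeric(gene_strengths)
  if (any(s <= 0) || any(d <= 0)) {
    stop("configuration model requires strictly positive strengths; ",
         "transform the network weights first (see transform_weights)",
         call. = FALSE)
  }
  if (abs(sum(s) - sum(d)) > 1e-6 * max(sum(s), sum(d))) {
    stop("TF and gene strengths must have equal totals", call. = FALSE)
  }
  m <- length(s)
  n <- length(d)
  theta <- n / (2 * s)
  eta <- m / (2 * d)
  newton_side <- function(own, other, S) {
    # solve sum_j 1/(own_i + other_j) = S_i for each i independently
    floor_own <- -min(other)
    for (k in seq_len(60L)) {
      R <- 1 / outer(own, other, "+")
      F <- rowSums(R) - S
      if (max(abs(F) / S) < tol / 4) break
      J <- rowSums(R^2)            # -dF/d(own)
      step <- F / J
      prop <- own + step
      bad <- prop <= floor_own
      prop[bad] <- (own[bad] + floor_own) / 2  # safeguard: bisect toward floor
      own <- prop
    }
    own
  }
  for (iter in seq_len(max_iter)) {
    theta <- newton_side(theta, eta, s)
    eta <- newton_side(eta, theta, d)
    R <- 1 / outer(theta, eta, "+")
    res <- max(abs(rowSums(R) - s) / s, abs(colSums(R) - d) / d)
    if (res < tol) break
  }
  if (res >= tol) {
    stop(sprintf("configuration model fit did not converge (residual %.3g)",
                 res), call. = FALSE)
  }
  nm_tf <- names(tf_strengths)
  nm_gene <- names(gene_strengths)
  structure(list(theta_tf = stats::setNames(theta, nm_tf),
                 theta_gene = stats::setNames(eta, nm_gene),
                 residual = res),
            class = "config_model")
}

#' Sample a network from a fitted configuration model
#'
#' Each edge weight is drawn independently from an exponential distribution
#' with rate `theta_i + theta_j`, so the expected strength of every node
#' equals its fitted target.
#'
#' @param params A `config_model` from [fit_configuration_model()].
#' @param seed Integer seed; deterministic given the seed.
#' @return A [bipartite_network()].
#' @export
sample_configuration_network <- function(params, seed = 1L) {
  stopifnot(inherits(params, "config_model"))
  theta <- params$theta_tf
  eta <- params$theta_gene
  m <- length(theta)
  n <- length(eta)
  rate <- outer(as.numeric(theta), as.numeric(eta), "+")
  w <- with_seed(seed, matrix(stats::rexp(m * n, rate = as.vector(rate)), m, n))
  bipartite_network(w,
                    tf_ids = names(theta) %||% paste0("TF", seq_len(m)),
                    gene_ids = names(eta) %||% paste0("G", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
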