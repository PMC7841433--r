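#' CRANE configuration
#'
#' Parameters for Constrained Random Alteration of Network Edges. `alpha`
#' scales the magnitude of the row-wise Gaussian perturbation (the method's
#' single scientific tuning knob; values of 0.1-0.4 give ensembles whose
#' edge-weight variance brackets that of networks re-inferred from
#' subsampled expression data). Optional strength noise perturbs the target
#' node-strength sequence itself, for ensembles in which strengths are only
#' conserved on average.
#'
#' @param alpha Nonnegative perturbation magnitude.
#' @param strength_noise_sd Optional nonnegative sd of Gaussian noise added
#'   to each TF strength target (`NULL` = strengths conserved exactly).
#' @param max_correction_iters Cap on the deviation-correction loop per row.
#' @param range_tol Slack allowed on the global min/max weight containment.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of class `crane_config`.
#' @export
crane_config <- function(alpha = 0.1, strength_noise_sd = NULL,
                         max_correction_iters = 100L, range_tol = 1e-9,
                         seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(range_tol), range_tol > 0,
            max_correction_iters >= 1L)
  if (!is.null(strength_noise_sd)) {
    stopifnot(is.numeric(strength_noise_sd), strength_noise_sd >= 0)
  }
  structure(list(alpha = alpha, strength_noise_sd = strength_noise_sd,
                 max_correction_iters = as.integer(max_correction_iters),
                 range_tol = range_tol, seed = as.integer(seed)),
            class = "crane_config")
}

# Deviation-correction for one row pair. `b` is the perturbed current row
# (already rescaled to target); the next row is `base + (a_cur - b)`, where
# `a_cur` is the (strength-scaled) input row l and `base` collects the
# residual drift of rows 1..l-1 plus the input row l+1. Writing it this way
# keeps the zero-perturbation case exact (no telescoping cancellation).
#
# Both the current row and the residual row must end up inside the global
# weight range, which confines b entrywise to
#   [L_j, U_j] = [lo, hi] intersect [c_j - hi, c_j - lo],  c = base + a_cur,
# while keeping sum(b) = target. The correction projects the proposal onto
# this box-and-sum polytope by an additive shift-and-clip
# (b <- clip(b + lambda, L, U), lambda by bisection): the minimal
# edge-weight adjustment that restores strength and containment at once.
# Iterating the literal excess-shift/rescale mechanism does not terminate on
# zero-centered weights (the multiplicative rescale keeps re-ejecting
# entries), so the projection is used as the correction step; infeasibility
# (residual mass that no in-range row can absorb) fails loudly.
correct_row_pair <- function(b, a_cur, base, target, lo, hi, tol, max_iters, row) {
  nxt <- base + (a_cur - b)
  if (!any(nxt > hi + tol | nxt < lo - tol | b > hi + tol | b < lo - tol)) {
    return(b)
  }
  cvec <- base + a_cur
  L <- pmax(lo, cvec - hi)
  U <- pmin(hi, cvec - lo)
  if (any(L > U + tol) || sum(L) > target + tol || sum(U) < target - tol) {
    worst <- max(c(L - U, sum(L) - target, target - sum(U)))
    stop(sprintf(paste0("CRANE: deviation correction infeasible at row %d ",
                        "(residual excess %.3g cannot be absorbed in range); ",
                        "consider a smaller alpha"), row, worst), call. = FALSE)
  }
  U <- pmax(U, L)
  shift_clip <- function(lambda) pmin(pmax(b + lambda, L), U)
  f <- function(lambda) sum(shift_clip(lambda)) - target
  span <- (hi - lo) + max(abs(b - pmin(pmax(b, L), U)))
  lower <- -span; upper <- span
  while (f(lower) > 0) lower <- lower * 2
  while (f(upper) < 0) upper <- upper * 2
  for (iter in seq_len(max_iters)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (abs(fm) <= tol * max(1, abs(target))) break
    if (fm > 0) upper <- mid else lower <- mid
  }
  b <- shift_clip(mid)
  # distribute any residual sum defect over the entries with slack
  defect <- target - sum(b)
  if (defect != 0) {
    slack <- if (defect > 0) U - b else b - L
    tot <- sum(slack)
    if (tot > 0) b <- b + defect * slack / tot
  }
  b
}

#' CRANE randomization of a weighted bipartite network
#'
#' Produces a perturbed copy of the input network in which every TF and
#' gene strength is conserved (exactly, up to floating-point rescaling
#' error) and every edge weight stays within the global `[min(A), max(A)]`
#' range of the input. Rows and columns are first placed in random order;
#' the first row is copied from the input; then row by row, Gaussian noise
#' with sd `alpha * sd(A[l, ])` (the sd of the original row) is added, the
#' row is rescaled to its strength target, and the next row is set to the
#' column-wise residual that keeps all gene strengths on track. Residual
#' entries escaping the global weight range are corrected by moving the
#' excess back into the current row and re-rescaling until contained. The
#' final row receives only residuals; its strength conservation follows
#' from column conservation. The output is mapped back to the input row and
#' column order.
#'
#' @param net A [bipartite_network()].
#' @param config A [crane_config()].
#' @return A [bipartite_network()] with the same labels, dimensions and
#'   motif prior.
#' @export
crane_bipartite <- function(net, config = crane_config()) {
  stopifnot(inherits(net, "bipartite_network"), inherits(config, "crane_config"))
  A_in <- net$weights
  m <- nrow(A_in)
  n <- ncol(A_in)
  out <- with_seed(config$seed, {
    row_ord <- sample.int(m)
    col_ord <- sample.int(n)
    A <- A_in[row_ord, col_ord, drop = FALSE]
    lo <- min(A)
    hi <- max(A)
    row_sd <- apply(A, 1L, stats::sd)
    row_sd[is.na(row_sd)] <- 0         # single-gene networks: sd undefined
    targets <- vapply(seq_len(m), function(i) sum(A[i, ]), numeric(1))
    kappa <- 1
    if (!is.null(config$strength_noise_sd) && config$strength_noise_sd > 0) {
      noised <- targets + stats::rnorm(m, 0, config$strength_noise_sd)
      # rescale gene-side targets so total weight stays balanced
      kappa <- sum(noised) / sum(targets)
      targets <- noised
    }
    B <- matrix(0, m, n)
    B[1L, ] <- kappa * A[1L, ]
    delta <- numeric(n)   # column drift: kappa * colsums A[1..l-1] - colsums B[1..l-1]
    for (l in seq_len(m - 1L)) {
      a_cur <- kappa * A[l, ]
      b <- B[l, ]
      b <- b + config$alpha * row_sd[l] * stats::rnorm(n)
      sb <- sum(b)
      if (sb != targets[l]) {
        if (sb == 0) {
          stop(sprintf("CRANE: degenerate row %d (zero sum during rescale)", l),
               call. = FALSE)
        }
        b <- b * (targets[l] / sb)
      }
      base <- delta + kappa * A[l + 1L, ]
      b <- correct_row_pair(b, a_cur, base, targets[l], lo, hi,
                            config$range_tol, config$max_correction_iters, l)
      B[l, ] <- b
      delta <- delta + (a_cur - b)
      B[l + 1L, ] <- kappa * A[l + 1L, ] + delta
    }
    inv_r <- order(row_ord)
    inv_c <- order(col_ord)
    B[inv_r, inv_c, drop = FALSE]
  })
  bipartite_network(out, tf_ids = net$tf_ids, gene_ids = net$gene_ids,
                    motif_prior = net$motif_prior)
}

#' CRANE randomization of a symmetric unipartite network
#'
#' Symmetric counterpart of [crane_bipartite()] for WGCNA-style
#' co-expression networks. A symmetric Gaussian perturbation (per-edge sd =
#' `alpha` times the mean of the two adjoining rows' original weight sds,
#' zero diagonal) is added, node strengths are restored exactly by the
#' additive symmetric correction `Delta_ij = x_i + x_j` (the unique such
#' correction with prescribed row sums), and out-of-range off-diagonal
#' entries are clipped back into the global `[min(A), max(A)]` range; the
#' clip and strength-restoration steps alternate until both constraints
#' hold.
#'
#' @param net A [unipartite_network()].
#' @param config A [crane_config()] (`strength_noise_sd` is ignored).
#' @return A [unipartite_network()] with conserved node strengths.
#' @export
crane_unipartite <- function(net, config = crane_config()) {
  stopifnot(inherits(net, "unipartite_network"), inherits(config, "crane_config"))
  A <- net$weights
  q <- nrow(A)
  if (q < 3L) stop("unipartite CRANE needs at least 3 nodes", call. = FALSE)
  off_entries <- A[row(A) != col(A)]   # the diagonal is structural, not an edge
  lo <- min(off_entries)
  hi <- max(off_entries)
  S <- rowSums(A)
  B <- with_seed(config$seed, {
    row_sd <- apply(A, 1L, stats::sd)
    sd_pair <- outer(row_sd, row_sd, function(a, b) (a + b) / 2)
    N <- matrix(stats::rnorm(q * q), q, q)
    E <- config$alpha * sd_pair * (N + t(N)) / sqrt(2)
    diag(E) <- 0
    B <- A + E
    off <- !diag(q)
    for (iter in seq_len(config$max_correction_iters)) {
      # exact additive strength restoration: Delta_ij = x_i + x_j (i != j)
      e <- S - rowSums(B)
      x <- (e - sum(e) / (2 * (q - 1))) / (q - 2)
      Delta <- outer(x, x, "+")
      diag(Delta) <- 0
      B <- B + Delta
      in_range <- B[off] >= lo - config$range_tol & B[off] <= hi + config$range_tol
      e2 <- S - rowSums(B)
      ok_strength <- max(abs(e2) / pmax(abs(S), 1)) <= config$range_tol
      if (all(in_range) && ok_strength) break
      Bc <- pmin(pmax(B, lo), hi)
      diag(Bc) <- 0
      B <- Bc
      if (iter == config$max_correction_iters) {
        stop(sprintf(paste0("unipartite CRANE: constraints not satisfied after ",
                            "%d iterations (worst strength error %.3g)"),
                     iter, max(abs(e2))), call. = FALSE)
      }
    }
    (B + t(B)) / 2
  })
  unipartite_network(B, node_ids = net$node_ids)
}

#' Generate an ensemble of randomized networks
#'
#' Applies a randomizer repeatedly with per-replicate seeds derived from a
#' single user seed (a fixed-size draw from the seeded stream), so replicate
#' `k` is reproducible given `(seed, K)`.
#'
#' @param net A [bipartite_network()].
#' @param K Number of replicates.
#' @param randomizer Function `(net, seed) -> net`; see
#'   [make_randomizer()].
#' @param seed Integer seed.
#' @return List of `K` networks.
#' @export
randomize_ensemble <- function(net, K, randomizer, seed = 1L) {
  seeds <- derive_seeds(seed, K)
  lapply(seq_len(K), function(k) randomizer(net, seeds[k]))
}
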