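# Baseline null models: configuration model, SBM, stratified permutation.

test_that("configuration model solves the symmetric case in closed form", {
  # m = n = 4, all strengths 2: theta = n / (2 S) = 1 for every node
  s <- setNames(rep(2, 4), paste0("TF", 1:4))
  d <- setNames(rep(2, 4), paste0("G", 1:4))
  fit <- fit_configuration_model(s, d)
  expect_equal(unname(fit$theta_tf), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(fit$theta_gene), rep(1, 4), tolerance = 1e-9)
})

test_that("configuration model ML residuals vanish on transformed networks", {
  net <- transform_weights(random_net(10, 15, seed = 12))
  st <- node_strengths(net)
  fit <- fit_configuration_model(st$tf, st$gene)
  # independent residual check: plug the solution back into the ML system
  R <- 1 / outer(unname(fit$theta_tf), unname(fit$theta_gene), "+")
  expect_lt(max(abs(rowSums(R) - st$tf) / st$tf), 1e-6)
  expect_lt(max(abs(colSums(R) - st$gene) / st$gene), 1e-6)
  expect_true(all(outer(fit$theta_tf, fit$theta_gene, "+") > 0))
})

test_that("configuration model rejects nonpositive strengths", {
  s <- setNames(c(1, 0, 2), paste0("TF", 1:3))
  d <- setNames(rep(1, 3), paste0("G", 1:3))
  expect_error(fit_configuration_model(s, d), "positive strengths")
})

test_that("configuration sampling is exponential with the fitted rates", {
  fit <- structure(list(theta_tf = setNames(rep(1, 2), c("T1", "T2")),
                        theta_gene = setNames(rep(1, 2), c("g1", "g2")),
                        residual = 0),
                   class = "config_model")
  draws <- vapply(1:4000, function(s) {
    as.vector(sample_configuration_network(fit, seed = s)$weights)
  }, numeric(4))
  # every edge Exponential(rate 2): mean 0.5 within Monte Carlo error
  expect_equal(mean(draws), 0.5, tolerance = 0.02)
  expect_true(all(draws > 0))
  # determinism
  expect_identical(sample_configuration_network(fit, seed = 5)$weights,
                   sample_configuration_network(fit, seed = 5)$weights)
})

test_that("configuration ensemble strengths match targets within 3 SE", {
  net <- transform_weights(random_net(10, 15, seed = 12))
  st <- node_strengths(net)
  fit <- fit_configuration_model(st$tf, st$gene)
  K <- 400
  tf_draws <- matrix(0, K, 10)
  for (k in seq_len(K)) {
    tf_draws[k, ] <- rowSums(sample_configuration_network(fit, seed = k)$weights)
  }
  se <- apply(tf_draws, 2L, sd) / sqrt(K)
  expect_true(all(abs(colMeans(tf_draws) - st$tf) < 3.5 * se + 1e-9))
})

test_that("SBM fit reproduces per-bundle statistics", {
  # two weight-homogeneous blocks: intra 5, inter 0
  w <- matrix(0, 4, 6)
  w[1:2, 1:3] <- 5
  w[3:4, 4:6] <- 5
  net <- bipartite_network(w)
  part <- as_partition(setNames(c(1, 1, 2, 2, 1, 1, 1, 2, 2, 2),
                                c(net$tf_ids, net$gene_ids)))
  fit <- fit_sbm(net, part)
  expect_equal(unname(diag(fit$mean)), c(5, 5))
  expect_equal(unname(fit$mean[1, 2]), 0)
  expect_equal(max(fit$sd[!fit$fallback]), 0)
  # sd = 0 everywhere: sample equals the bundle-mean network
  samp <- sample_sbm(fit, seed = 1)
  expect_equal(samp$weights, net$weights, ignore_attr = TRUE)

  # random network: brute-force per-bundle statistics
  net2 <- random_net(8, 12, seed = 31)
  part2 <- random_partition(c(net2$tf_ids, net2$gene_ids), 3, seed = 5)
  fit2 <- fit_sbm(net2, part2)
  tfc <- part2[net2$tf_ids]
  gc <- part2[net2$gene_ids]
  for (a in unique(tfc)) for (b in unique(gc)) {
    vals <- net2$weights[tfc == a, gc == b]
    expect_equal(unname(fit2$mean[as.character(a), as.character(b)]),
                 mean(vals), tolerance = 1e-12)
    if (length(vals) > 1) {
      expect_equal(unname(fit2$sd[as.character(a), as.character(b)]),
                   sd(vals), tolerance = 1e-12)
    }
  }
})

test_that("singleton SBM bundles fall back to the global sd and are flagged", {
  net <- bipartite_network(matrix(c(1, 2, 3, 4, 5, 6), 2, 3),
                           tf_ids = c("T1", "T2"), gene_ids = paste0("g", 1:3))
  # T1 alone with g1 alone forms a one-edge bundle
  part <- as_partition(c(T1 = 1, T2 = 2, g1 = 1, g2 = 2, g3 = 2))
  fit <- fit_sbm(net, part)
  expect_true(fit$fallback["1", "1"])
  expect_equal(unname(fit$sd["1", "1"]), sd(as.vector(net$weights)))
})

test_that("SBM ensemble means match fitted bundle means within 3 SE", {
  net <- random_net(6, 10, seed = 17)
  part <- random_partition(c(net$tf_ids, net$gene_ids), 2, seed = 2)
  fit <- fit_sbm(net, part)
  K <- 500
  acc <- matrix(0, K, length(net$weights))
  for (k in seq_len(K)) acc[k, ] <- as.vector(sample_sbm(fit, seed = k)$weights)
  tfc <- part[net$tf_ids]
  gc <- part[net$gene_ids]
  # per-edge expected mean from the bundle of that edge
  ia <- match(tfc, as.integer(rownames(fit$mean)))
  ib <- match(gc, as.integer(colnames(fit$mean)))
  mu <- as.vector(fit$mean[ia, ib])
  se <- apply(acc, 2L, sd) / sqrt(K)
  expect_true(all(abs(colMeans(acc) - mu) < 4 * se + 1e-9))
  expect_identical(sample_sbm(fit, seed = 3)$weights,
                   sample_sbm(fit, seed = 3)$weights)
})

test_that("stratified permutation preserves per-stratum weight multisets", {
  net <- random_net(10, 20, seed = 23, motif = TRUE)
  part <- random_partition(c(net$tf_ids, net$gene_ids), 3, seed = 7)
  out <- permute_edge_weights(net, part, seed = 11)
  intra <- outer(part[net$tf_ids], part[net$gene_ids], "==")
  strata <- 2L * as.integer(intra) + as.integer(net$motif_prior)
  for (sid in unique(as.vector(strata))) {
    expect_identical(sort(out$weights[strata == sid]),
                     sort(net$weights[strata == sid]))
  }
  # strengths are NOT generally preserved (this is what separates it from CRANE)
  s_in <- node_strengths(net)
  s_out <- node_strengths(out)
  expect_gt(max(abs(c(s_out$tf - s_in$tf, s_out$gene - s_in$gene))), 1e-6)
  # determinism
  expect_identical(out$weights,
                   permute_edge_weights(net, part, seed = 11)$weights)
})

test_that("permutation degenerate strata and missing prior are handled", {
  # every stratum has one edge: output equals input
  w <- matrix(c(1, 2, 3, 4), 2, 2)
  prior <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  net <- bipartite_network(w, c("T1", "T2"), c("g1", "g2"), motif_prior = prior)
  part <- as_partition(c(T1 = 1, T2 = 2, g1 = 1, g2 = 2))
  # strata: (intra, motif) all distinct -> untouched
  out <- permute_edge_weights(net, part, seed = 1)
  expect_identical(out$weights, net$weights)

  noprior <- bipartite_network(w, c("T1", "T2"), c("g1", "g2"))
  expect_error(permute_edge_weights(noprior, part, seed = 1), "motif prior")
  expect_silent(permute_edge_weights(noprior, part, seed = 1,
                                     allow_no_prior = TRUE))
})
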