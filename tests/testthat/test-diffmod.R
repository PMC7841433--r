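# Community detection, differential modularity, module detection, consensus.

test_that("community detection recovers block-diagonal structure", {
  w <- matrix(0, 6, 10)
  w[1:3, 1:5] <- 1
  w[4:6, 6:10] <- 1
  net <- bipartite_network(w)
  res <- detect_communities(net, seed = 1)
  expect_equal(max(res$partition), 2L)
  expect_equal(length(unique(res$partition[net$tf_ids[1:3]])), 1L)
  expect_equal(res$partition[net$tf_ids[1]], res$partition[net$gene_ids[1]],
               ignore_attr = TRUE)
  expect_equal(res$modularity,
               bipartite_modularity(net, res$partition), tolerance = 1e-12)

  uni <- detect_communities(bipartite_network(matrix(1, 4, 6)), seed = 1)
  expect_equal(max(uni$partition), 1L)
  expect_equal(uni$modularity, 0, tolerance = 1e-12)

  neg <- bipartite_network(matrix(c(-1, 1, 1, 1), 2, 2))
  expect_error(detect_communities(neg), "transform_weights")
})

test_that("detected partitions attain the exhaustive modularity optimum on toys", {
  for (trial in 1:20) {
    net <- withr::with_seed(trial, bipartite_network(
      matrix(runif(9), 3, 3), paste0("T", 1:3), paste0("g", 1:3)))
    nodes <- c(net$tf_ids, net$gene_ids)
    best <- -Inf
    for (p in all_partitions(nodes)) {  # all 203 partitions of 6 nodes
      q <- bipartite_modularity(net, blocks_to_partition(p, nodes))
      if (q > best) best <- q
    }
    got <- detect_communities(net, seed = trial)
    expect_equal(got$modularity, best, tolerance = 1e-12)
  }
})

test_that("modularity is invariant under relabeling and row/column permutation", {
  net <- transform_weights(random_net(6, 9, seed = 44))
  res <- detect_communities(net, seed = 2)
  p <- res$partition
  relab <- as_partition(setNames(max(p) + 1L - p, names(p)))
  expect_equal(bipartite_modularity(net, relab), res$modularity,
               tolerance = 1e-12)
  perm <- withr::with_seed(9, {
    bipartite_network(net$weights[sample(6), sample(9)])
  })
  expect_equal(bipartite_modularity(perm, p), res$modularity, tolerance = 1e-12)
})

test_that("differential modularity matches hand computation and sums to zero", {
  ctrl <- bipartite_network(matrix(1, 2, 2), c("T1", "T2"), c("g1", "g2"))
  dis <- bipartite_network(matrix(c(2, 0, 0, 2), 2, 2), c("T1", "T2"),
                           c("g1", "g2"))
  D <- differential_modularity(dis, ctrl)
  expect_equal(unname(D), matrix(c(1, -1, -1, 1) / 4, 2, 2))

  # self-null: disease = rank-one strength product of the control
  ctrl2 <- transform_weights(random_net(5, 8, seed = 3))
  s <- rowSums(ctrl2$weights)
  d <- colSums(ctrl2$weights)
  rank1 <- bipartite_network(outer(s, d) / sum(ctrl2$weights),
                             ctrl2$tf_ids, ctrl2$gene_ids)
  expect_lt(max(abs(differential_modularity(rank1, ctrl2))), 1e-12)

  for (sd in 1:3) {
    a <- transform_weights(random_net(6, 11, seed = sd))
    b <- transform_weights(random_net(6, 11, seed = sd + 50))
    expect_lt(abs(sum(differential_modularity(a, b))), 1e-9)
  }
  wrong <- transform_weights(random_net(6, 12, seed = 1))
  expect_error(differential_modularity(a, wrong), "same TF and gene ids")
})

test_that("module detection concentrates a planted module and is stable", {
  ctrl <- transform_weights(random_net(12, 60, seed = 21))
  w <- ctrl$weights
  tfs <- ctrl$tf_ids[1:4]
  genes <- ctrl$gene_ids[1:20]
  w[tfs, genes] <- w[tfs, genes] + 5
  dis <- bipartite_network(w, ctrl$tf_ids, ctrl$gene_ids)
  res <- alpaca_detect(dis, ctrl, seed = 5)
  planted_mod <- res$partition[tfs]
  expect_equal(length(unique(planted_mod)), 1L)
  expect_true(all(res$partition[genes] == planted_mod[1]))
  planted_nodes <- c(tfs, genes)
  others <- setdiff(names(res$scores), planted_nodes)
  expect_gt(mean(res$scores[planted_nodes]), mean(res$scores[others]))

  # stability: two seeds agree on an easy instance
  res2 <- alpaca_detect(dis, ctrl, seed = 6)
  expect_gt(nmi(res$partition, res2$partition), 0.8)

  # disease == control: no module dominates
  null_res <- alpaca_detect(ctrl, ctrl, seed = 5)
  expect_lt(max(abs(null_res$scores)), max(res$scores[planted_nodes]) / 5)
})

test_that("module detection matches the exhaustive optimum of D on toys", {
  for (trial in 1:10) {
    dis <- withr::with_seed(trial + 300, bipartite_network(
      matrix(runif(9), 3, 3), paste0("T", 1:3), paste0("g", 1:3)))
    ctrl <- withr::with_seed(trial + 600, bipartite_network(
      matrix(runif(9), 3, 3), paste0("T", 1:3), paste0("g", 1:3)))
    D <- differential_modularity(dis, ctrl)
    nodes <- c(dis$tf_ids, dis$gene_ids)
    best <- -Inf
    for (p in all_partitions(nodes)) {
      lab <- blocks_to_partition(p, nodes)
      val <- sum(D[outer(lab[dis$tf_ids], lab[dis$gene_ids], "==")])
      if (val > best) best <- val
    }
    got <- alpaca_detect(dis, ctrl, seed = trial)
    expect_equal(got$objective, best, tolerance = 1e-12)
  }
})

test_that("consensus clustering recovers identical and majority partitions", {
  p <- as_partition(c(A = 1, B = 1, C = 2, D = 2))
  many <- rep(list(p), 100)
  cons <- consensus_cluster(many, seed = 1)
  expect_equal(nmi(cons, p), 1)

  q <- as_partition(c(A = 1, B = 2, C = 1, D = 2))
  mixed <- c(rep(list(p), 90), rep(list(q), 10))
  cm <- consensus_matrix(mixed)
  expect_equal(cm$C["A", "B"], 0.9)
  expect_equal(cm$C["A", "C"], 0.1)
  expect_equal(cm$C["A", "D"], 0)
  expect_true(all(diag(cm$C) == 1))
  cons2 <- consensus_cluster(mixed, seed = 1)
  expect_equal(nmi(cons2, p), 1)

  expect_error(consensus_cluster(list(p)), "at least 2")
  expect_error(consensus_cluster(list(p, as_partition(c(A = 1, X = 2, C = 1, D = 2)))),
               "same node set")
})

test_that("consensus of R identical partitions is that partition for any R", {
  base <- random_partition(paste0("n", 1:30), 4, seed = 3)
  for (R in c(2, 5, 20)) {
    cons <- consensus_cluster(rep(list(base), R), seed = 2)
    expect_equal(nmi(cons, base), 1)
  }
})
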