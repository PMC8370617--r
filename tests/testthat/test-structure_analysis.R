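test_that("PCA eigenvalues match a dense eigendecomposition oracle", {
  set.seed(401)
  G <- random_genotype_fixture(5, 3, miss = 0)
  p <- pca_genotypes(G)
  X <- scale(matrix(as.numeric(G), 5, 3), center = TRUE, scale = FALSE)
  ev_oracle <- sort(eigen(stats::cov(X), symmetric = TRUE)$values,
                    decreasing = TRUE)
  expect_equal(p$eigenvalues[seq_along(ev_oracle)], ev_oracle,
               tolerance = 1e-10)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
})

test_that("variance fractions sum to one and scores are orthogonal", {
  set.seed(402)
  G <- random_genotype_fixture(20, 40, miss = 0.05)
  p <- pca_genotypes(G)
  expect_equal(sum(p$var_fraction), 1, tolerance = 1e-10)
  expect_equal(p$cum_var_fraction[p$n_axes], 1, tolerance = 1e-10)
  gram <- crossprod(p$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
})

test_that("a rank-one matrix loads entirely on the first axis", {
  base <- c(0, 1, 2, 1, 0, 2)
  G <- genotype_matrix(rbind(a = base, b = base, c = rep(0, 6), d = base),
                       locus_ids = paste0("L", 1:6))
  p <- pca_genotypes(G)
  expect_equal(p$var_fraction[1], 1, tolerance = 1e-10)
})

test_that("requesting more axes than the rank truncates with a warning", {
  G <- random_genotype_fixture(4, 10, miss = 0)
  expect_warning(p <- pca_genotypes(G, n_axes = 10), "rank")
  expect_lte(p$n_axes, 3)
})

test_that("DAPC separates distinct populations and respects rank limits", {
  set.seed(403)
  # two zones with a strong frequency shift at 200 loci
  p1 <- runif(200, 0.1, 0.4)
  p2 <- pmin(p1 + 0.3, 0.95)
  G <- rbind(t(replicate(25, rbinom(200, 2, p1))),
             t(replicate(25, rbinom(200, 2, p2))))
  rownames(G) <- sprintf("s%02d", 1:50)
  colnames(G) <- sprintf("L%03d", 1:200)
  storage.mode(G) <- "integer"
  grp <- setNames(rep(c("A", "B"), each = 25), rownames(G))
  fit <- dapc(G, grp, n_pca_axes = 20)
  expect_equal(fit$accuracy, 1)
  expect_equal(ncol(fit$scores), 1)  # 2 groups -> 1 discriminant function

  sim <- simulate_population(sim_config(seed = 404, n_loci = 300,
                                        clones_per_zone = 6,
                                        copies_dist = c("1" = 1),
                                        shared_clone_fraction = 0))
  coll <- sim$metadata$sample_id[sim$metadata$category == "collected"]
  grp7 <- setNames(sim$metadata$zone, sim$metadata$sample_id)[coll]
  fit7 <- dapc(sim$genotypes[coll, ], grp7, n_pca_axes = 15)
  expect_equal(ncol(fit7$scores), 6)  # 7 groups -> 6 functions
  expect_error(dapc(G[1:26, ], setNames(c(rep("A", 25), "B"), rownames(G)[1:26])),
               "single sample")
})

test_that("DAPC assignment is equivariant to sample order", {
  set.seed(405)
  sim <- simulate_population(sim_config(seed = 405, n_loci = 200,
                                        n_zones = 3, clones_per_zone = 8,
                                        copies_dist = c("1" = 1),
                                        shared_clone_fraction = 0))
  coll <- sim$metadata$sample_id[sim$metadata$category == "collected"]
  G <- sim$genotypes[coll, ]
  grp <- setNames(sim$metadata$zone, sim$metadata$sample_id)[coll]
  fit <- dapc(G, grp, n_pca_axes = 10)
  perm <- sample(nrow(G))
  fit_p <- dapc(G[perm, ], grp[perm], n_pca_axes = 10)
  expect_equal(as.character(fit_p$assignment),
               as.character(fit$assignment[perm]))
})

test_that("UPGMA dendrogram heights follow average linkage", {
  ids <- c("A", "B", "C")
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3, dimnames = list(ids, ids))
  tr <- sample_dendrogram(D)
  coph <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_equal(coph, D)  # ((A:1,B:1):2,C:3) path lengths
  # two samples: a single cherry at half the distance
  tr2 <- sample_dendrogram(D[1:2, 1:2])
  expect_equal(sort(tr2$edge.length), c(1, 1))
  # clone duplicates at distance zero form a zero-height cherry
  D0 <- D
  D0["A", "B"] <- D0["B", "A"] <- 0
  tr0 <- sample_dendrogram(D0)
  expect_equal(ape::cophenetic.phylo(tr0)["A", "B"], 0)
  expect_error(sample_dendrogram(D[1, 1, drop = FALSE]), "at least 2")
  # nj method delegates to the NJ builder
  trnj <- sample_dendrogram(D, method = "nj")
  expect_setequal(trnj$tip.label, ids)
})

test_that("minimum spanning network matches brute force and flags ties", {
  ids <- c("a", "b", "c")
  D <- matrix(0, 3, 3, dimnames = list(ids, ids))
  D["a", "b"] <- D["b", "a"] <- 1
  D["b", "c"] <- D["c", "b"] <- 2
  D["a", "c"] <- D["c", "a"] <- 3
  net <- minimum_spanning_network(D)
  expect_equal(net$mst_weight, 3)
  expect_equal(sum(net$edges$type == "reticulation"), 0)

  De <- matrix(1, 3, 3, dimnames = list(ids, ids))
  diag(De) <- 0
  net_e <- minimum_spanning_network(De)
  expect_equal(nrow(net_e$edges), 3)
  expect_equal(sum(net_e$edges$type == "mst"), 2)
  expect_equal(sum(net_e$edges$type == "reticulation"), 1)
})

test_that("MST weight equals the exhaustive spanning-tree minimum", {
  set.seed(406)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    ids <- letters[seq_len(n)]
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 1)
    D <- D + t(D)
    net <- minimum_spanning_network(D)
    expect_equal(net$mst_weight, mst_weight_oracle(D), tolerance = 1e-12)
  }
  # n = 7 spot check
  n <- 7
  ids <- letters[1:7]
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[upper.tri(D)] <- runif(21, 0.1, 1)
  D <- D + t(D)
  expect_equal(minimum_spanning_network(D)$mst_weight, mst_weight_oracle(D),
               tolerance = 1e-12)
})

test_that("every reticulation ties the max edge on its tree path", {
  set.seed(407)
  # quantised weights force ties
  n <- 8
  ids <- sprintf("n%d", 1:n)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[upper.tri(D)] <- sample(seq(0.1, 0.5, by = 0.1), 28, replace = TRUE)
  D <- D + t(D)
  net <- minimum_spanning_network(D)
  mst_edges <- net$edges[net$edges$type == "mst", ]
  g <- igraph::graph_from_data_frame(mst_edges, directed = FALSE,
                                     vertices = ids)
  rets <- net$edges[net$edges$type == "reticulation", ]
  for (k in seq_len(nrow(rets))) {
    ep <- igraph::shortest_paths(g, rets$from[k], rets$to[k],
                                 output = "epath")$epath[[1]]
    expect_equal(rets$weight[k], max(mst_edges$weight[as.integer(ep)]),
                 tolerance = 1e-9)
  }
})
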