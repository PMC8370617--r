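test_that("Shannon index matches hand values and its bounds", {
  expect_equal(shannon_index(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(shannon_index(10), 0)
  expect_equal(shannon_index(c(3, 0, 2)), shannon_index(c(3, 2)))
  expect_error(shannon_index(c(0, 0)), "zero")
  expect_error(shannon_index(c(-1, 2)), "non-negative")
  # 0 <= H <= log(k), equality at uniform
  set.seed(301)
  for (i in 1:10) {
    k <- sample(2:20, 1)
    cnt <- sample(1:50, k, replace = TRUE)
    H <- shannon_index(cnt)
    expect_gte(H, 0)
    expect_lte(H, log(k) + 1e-12)
  }
})

test_that("allele frequencies are dosage sums over called diploids", {
  G <- genotype_matrix(rbind(a = c(0L, 2L, NA), b = c(1L, 2L, NA),
                             c = c(2L, 2L, NA)),
                       locus_ids = paste0("L", 1:3))
  af <- allele_frequencies(G, c(a = "Lake", b = "Lake", c = "Lake"))
  expect_equal(unname(af$p["Lake", ]), c(0.5, 1, NA))
  expect_equal(unname(af$n_called["Lake", ]), c(3L, 3L, 0L))
})

test_that("WC84 theta matches the mean-squares oracle", {
  # fixed differences: pop1 all reference homozygote, pop2 all alternate
  G1 <- matrix(0L, 10, 1)
  G2 <- matrix(2L, 10, 1)
  G <- rbind(G1, G2)
  rownames(G) <- sprintf("s%d", 1:20)
  colnames(G) <- "L1"
  grp <- setNames(rep(c("A", "B"), each = 10), rownames(G))
  fst <- pairwise_fst(G, grp)
  expect_equal(fst["A", "B"], wc84_ms_oracle(G1, G2))
  expect_equal(fst["A", "B"], 1)

  # random multilocus data, with missing calls
  set.seed(302)
  for (rep in 1:5) {
    Ga <- random_genotype_fixture(12, 30, miss = 0.1)
    Gb <- random_genotype_fixture(12, 30, miss = 0.1)
    rownames(Gb) <- sprintf("T%02d", 1:12)
    G <- rbind(Ga, Gb)
    grp <- setNames(rep(c("A", "B"), each = 12), rownames(G))
    fst <- pairwise_fst(G, grp)
    expect_equal(fst["A", "B"], wc84_ms_oracle(Ga, Gb), tolerance = 1e-10)
  }
})

test_that("theta is near zero for samples from one population", {
  set.seed(303)
  p <- runif(500, 0.05, 0.95)
  G <- t(replicate(400, rbinom(500, 2, p)))
  rownames(G) <- sprintf("s%03d", 1:400)
  colnames(G) <- sprintf("L%03d", 1:500)
  storage.mode(G) <- "integer"
  grp <- setNames(rep(c("A", "B"), each = 200), rownames(G))
  expect_lt(abs(pairwise_fst(G, grp)["A", "B"]), 0.01)
  # invariant to locus order
  perm <- sample(500)
  expect_equal(pairwise_fst(G[, perm], grp), pairwise_fst(G, grp))
  # label permutation of one population's samples keeps theta ~ 0
  expect_lt(abs(pairwise_fst(G, sample(grp))["A", "B"]), 0.01)
})

test_that("zones with fewer than two samples are rejected", {
  G <- random_genotype_fixture(3, 10, miss = 0)
  expect_error(pairwise_fst(G, c("A", "A", "B")), "B")
})

test_that("Nei87 Gst option differentiates fixed populations", {
  G <- rbind(matrix(0L, 10, 5), matrix(2L, 10, 5))
  rownames(G) <- sprintf("s%d", 1:20)
  colnames(G) <- sprintf("L%d", 1:5)
  grp <- setNames(rep(c("A", "B"), each = 10), rownames(G))
  fst <- pairwise_fst(G, grp, estimator = "Nei87")
  expect_equal(fst["A", "B"], 1)  # Hs = 0, Ht > 0
  set.seed(304)
  Gr <- random_genotype_fixture(20, 50, miss = 0)
  grp_r <- setNames(rep(c("A", "B"), each = 10), rownames(Gr))
  f2 <- pairwise_fst(Gr, grp_r, estimator = "Nei87")
  expect_true(f2["A", "B"] > -0.05 && f2["A", "B"] < 1)
})

test_that("Nei standard distance reproduces hand computations", {
  expect_equal(nei_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # single locus, x = 0.9, y = 0.5
  jxy <- 0.9 * 0.5 + 0.1 * 0.5
  I <- jxy / sqrt(0.82 * 0.5)
  expect_equal(nei_distance(0.9, 0.5), -log(I))
  expect_equal(round(nei_distance(0.9, 0.5), 4), 0.2473)
  expect_warning(d <- nei_distance(1, 0), "clamped")
  expect_equal(d, 10)
  # symmetry and monotone divergence at a single locus
  expect_equal(nei_distance(0.9, 0.5), nei_distance(0.5, 0.9))
  ys <- seq(0.9, 0.1, by = -0.2)
  ds <- vapply(ys, function(y) nei_distance(0.9, y), numeric(1))
  expect_true(all(diff(ds) > 0))
  expect_error(nei_distance(NA, 0.5), "no shared defined loci")
})

test_that("neighbor joining satisfies the three-taxon closed form", {
  ids <- c("A", "B", "C")
  D <- matrix(0, 3, 3, dimnames = list(ids, ids))
  D["A", "B"] <- D["B", "A"] <- 0.4
  D["A", "C"] <- D["C", "A"] <- 0.6
  D["B", "C"] <- D["C", "B"] <- 0.8
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (0.4 + 0.6 - 0.8) / 2)
  expect_equal(bl[["B"]], (0.4 + 0.8 - 0.6) / 2)
  expect_equal(bl[["C"]], (0.6 + 0.8 - 0.4) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(305)
  for (rep in 1:20) {
    D <- random_additive_4taxon()
    tr <- neighbor_joining(D)
    coph <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(coph - D)), 1e-9)
  }
  # equidistant star: zero-length internal branch
  ids <- letters[1:4]
  D <- matrix(1, 4, 4, dimnames = list(ids, ids))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  internal <- tr$edge.length[tr$edge[, 2] > ape::Ntip(tr)]
  expect_true(all(abs(internal) < 1e-12))
})

test_that("hand-rolled NJ agrees with ape's on a larger additive tree", {
  set.seed(306)
  ref <- ape::rtree(8, br = runif)
  ref$edge.length <- ref$edge.length + 0.05
  D <- ape::cophenetic.phylo(ref)
  ours <- neighbor_joining(D)
  theirs <- ape::nj(D)
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs))[1], 0)
  expect_lt(max(abs(ape::cophenetic.phylo(ours)[rownames(D), colnames(D)] - D)),
            1e-8)
})

test_that("zone diversity and dedup Fst run on simulated collections", {
  sim <- simulate_population(sim_config(seed = 10, n_loci = 500,
                                        clones_per_zone = 8))
  D <- hamming_distance(sim$genotypes)
  part <- call_clones(D, 0.02, G = sim$genotypes)
  H <- zone_diversity(part, sim$metadata)
  expect_length(H, 7)
  expect_true(all(H >= 0))
  coll <- sim$metadata$sample_id[sim$metadata$category == "collected"]
  grp <- setNames(sim$metadata$zone, sim$metadata$sample_id)[coll]
  fst <- pairwise_fst(sim$genotypes[coll, ], grp, partition = part)
  expect_equal(fst, t(fst))
  expect_true(all(fst[upper.tri(fst)] > -0.05 & fst[upper.tri(fst)] < 1))
  nei <- pairwise_nei(sim$genotypes[coll, ], grp, partition = part)
  expect_true(all(diag(nei) == 0) && all(nei >= 0))
  tr <- neighbor_joining(nei)
  expect_setequal(tr$tip.label, rownames(nei))
})
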