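test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(seed = 42, n_loci = 200, clones_per_zone = 3,
                    n_reference_landraces = 4, n_breeding_lines = 2)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$truth$clone_of, s2$truth$clone_of)
  expect_identical(simulate_survey(cfg), simulate_survey(cfg))
  s3 <- simulate_population(sim_config(seed = 43, n_loci = 200,
                                       clones_per_zone = 3))
  expect_false(identical(s1$genotypes[, 1], s3$genotypes[, 1]))
})

test_that("a noise-free simulation yields identical clone copies", {
  cfg <- sim_config(seed = 5, n_loci = 300, clones_per_zone = 4,
                    copies_dist = c("2" = 1),
                    het_miscall_rate = 0, mutation_rate = 0, missing_rate = 0)
  sim <- simulate_population(cfg)
  D <- hamming_distance(sim$genotypes)
  for (cl in unique(sim$truth$clone_of)) {
    ids <- names(sim$truth$clone_of)[sim$truth$clone_of == cl]
    if (length(ids) > 1)
      expect_true(all(D[ids, ids] == 0))
  }
  rd <- replicate_pair_distances(D, sim$metadata)
  expect_true(all(rd$pairs$distance == 0))
})

test_that("infeasible and invalid configurations are rejected", {
  expect_error(sim_config(n_zones = 1, clones_per_zone = 2,
                          n_bio_replicate_groups = 2,
                          n_tech_replicate_groups = 2),
               "more replicate groups")
  bad <- diag(2)
  bad[1, 2] <- bad[2, 1] <- 1.5  # not PSD
  tr <- matrix(0, 9, 9, dimnames = list(SURVEY <- survey_traits(), SURVEY))
  diag(tr) <- 1
  tr["taste", "yield"] <- tr["yield", "taste"] <- 1.2
  expect_error(sim_config(survey = list(target_correlation = tr)),
               "positive semi-definite")
  expect_error(sim_config(fst = 0), "fst")
})

test_that("replicate distances grow with the genotyping error rates", {
  mean_rep <- function(eps, mu) {
    cfg <- sim_config(seed = 11, n_loci = 800, clones_per_zone = 6,
                      copies_dist = c("1" = 1), shared_clone_fraction = 0,
                      het_miscall_rate = eps, mutation_rate = mu,
                      missing_rate = 0,
                      n_bio_replicate_groups = 6, n_tech_replicate_groups = 6)
    sim <- simulate_population(cfg)
    D <- hamming_distance(sim$genotypes)
    mean(replicate_pair_distances(D, sim$metadata)$pairs$distance)
  }
  m <- c(mean_rep(0.002, 0), mean_rep(0.01, 0), mean_rep(0.05, 0))
  expect_true(all(diff(m) > 0))
  expect_gt(mean_rep(0.01, 0.01), mean_rep(0.01, 0))
})

test_that("biological replicates drift further apart than technical ones", {
  cfg <- sim_config(seed = 13, n_loci = 1000, clones_per_zone = 10,
                    copies_dist = c("1" = 1), shared_clone_fraction = 0,
                    het_miscall_rate = 0.01, mutation_rate = 0.01,
                    missing_rate = 0,
                    n_bio_replicate_groups = 15, n_tech_replicate_groups = 15)
  sim <- simulate_population(cfg)
  D <- hamming_distance(sim$genotypes)
  s <- replicate_pair_distances(D, sim$metadata)$summary
  expect_gt(s$mean[s$type == "biological"], s$mean[s$type == "technical"])
})

test_that("realized differentiation tracks the Balding-Nichols target", {
  cfg <- sim_config(seed = 17, n_loci = 1000, n_zones = 2,
                    clones_per_zone = 50, copies_dist = c("1" = 1),
                    shared_clone_fraction = 0, het_miscall_rate = 0,
                    mutation_rate = 0, missing_rate = 0, fst = 0.05)
  sim <- simulate_population(cfg)
  grp <- setNames(sim$metadata$zone, sim$metadata$sample_id)
  fst <- pairwise_fst(sim$genotypes, grp)
  expect_lt(abs(fst[1, 2] - 0.05), 0.015)
})

test_that("adjusted Rand index follows the contingency formula", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1), c(1, 2, 3)), 0)
  set.seed(601)
  for (rep in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("recovery metrics count merges and splits correctly", {
  truth <- list(clone_of = setNames(rep(c("X", "Y"), each = 5),
                                    sprintf("s%02d", 1:10)))
  # perfect recovery
  D <- matrix(0.5, 10, 10, dimnames = list(names(truth$clone_of),
                                           names(truth$clone_of)))
  diag(D) <- 0
  D[1:5, 1:5] <- 0.001
  D[6:10, 6:10] <- 0.001
  diag(D) <- 0
  part <- call_clones(D, 0.01)
  rec <- evaluate_recovery(part, truth)
  expect_equal(rec$ari, 1)
  expect_equal(rec$false_merges + rec$false_splits, 0)
  # everything split apart
  part_split <- call_clones(matrix(0.5, 10, 10,
                                   dimnames = dimnames(D)) - diag(0.5, 10), 0.01)
  rec_split <- evaluate_recovery(part_split, truth)
  expect_equal(rec_split$false_splits, 2)
  expect_equal(rec_split$ari,
               mclust::adjustedRandIndex(part_split$membership,
                                         truth$clone_of[names(part_split$membership)]))
  # everything merged together
  part_merge <- call_clones(matrix(0.001, 10, 10, dimnames = dimnames(D)) -
                              diag(0.001, 10), 0.01)
  rec_merge <- evaluate_recovery(part_merge, truth)
  expect_equal(rec_merge$false_merges, 1)  # one called group mixes both clones
  expect_equal(rec_merge$false_splits, 0)
  expect_error(evaluate_recovery(part, list(clone_of = c(a = "X"))),
               "different samples")
})

test_that("survey scores carry the configured latent correlation", {
  cfg <- sim_config(seed = 23, survey = list(n = 5000, dont_know_rate = 0))
  srv <- simulate_survey(cfg)
  # Monte-Carlo oracle for the threshold-attenuated correlation
  set.seed(999)
  z1 <- rnorm(40000)
  z2 <- 0.9 * z1 + sqrt(1 - 0.9^2) * rnorm(40000)
  cuts <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  att <- cor(findInterval(z1, cuts), findInterval(z2, cuts))
  emp <- trait_correlation(srv, "cooking_quality", "taste",
                           dont_know = "include")$r
  expect_lt(abs(emp - att), 0.05)
  # independent traits stay uncorrelated
  emp0 <- trait_correlation(srv, "storability", "maturity",
                            dont_know = "include")$r
  expect_lt(abs(emp0), 0.05)
})

test_that("don't-know saturation zeroes every score", {
  cfg <- sim_config(seed = 29, survey = list(n = 50, dont_know_rate = 1))
  srv <- simulate_survey(cfg)
  expect_true(all(srv$taste == 0 & srv$yield == 0))
})

test_that("the survey emulates the collection's structure", {
  cfg <- sim_config(seed = 31, survey = list(n = 2000))
  srv <- simulate_survey(cfg)
  expect_equal(nrow(srv), 2000)
  ud <- use_distribution(srv)
  # zone propensities put fresh-only and dual in the expected ballpark
  expect_gt(ud$pct[ud$class == "fresh"], 25)
  expect_gt(ud$pct[ud$class == "dual"], 25)
  expect_lt(ud$pct[ud$class == "unknown"], 10)
  pr <- profile_summary(srv)
  expect_lt(abs(pr$gender[["female"]] - 26), 12)
})
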