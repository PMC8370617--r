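#' Default latent correlation matrix for survey trait scores
#'
#' Nine ordinal traits; the block linking cooking quality, taste,
#' processing quality, market demand and yield carries the structure seen
#' in farmer ratings of cassava landraces: cooking quality and taste are
#' strongly associated, market demand moderately follows cooking quality,
#' taste and yield, and processing quality runs weakly against the
#' fresh-eating traits (flour landraces are the bitter ones).
#'
#' @return symmetric positive-definite 9 x 9 correlation matrix.
#' @export
default_trait_correlation <- function() {
  R <- diag(9)
  dimnames(R) <- list(SURVEY_TRAITS, SURVEY_TRAITS)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("cooking_quality", "taste", 0.90)
  set2("cooking_quality", "market_demand", 0.45)
  set2("taste", "market_demand", 0.40)
  set2("yield", "market_demand", 0.38)
  set2("cooking_quality", "processing_quality", -0.10)
  set2("taste", "processing_quality", -0.15)
  R
}

#' Simulation configuration for a synthetic germplasm collection
#'
#' Defaults emulate a seven-zone national collection: zone allele
#' frequencies follow the Balding-Nichols model around a target Fst,
#' founder clones are drawn per zone, a fraction of clones is planted in
#' two zones (sharing), each clone is collected a random number of times
#' (mean ~1.5 copies), and every observed copy carries
#' heterozygote-to-homozygote miscalls (the read-depth artifact of
#' sequence-based genotyping), random missing calls and, for biological
#' replicates, rare somatic mutations. Replicate groups (extra samples of
#' designated clones) provide the threshold-calibration pairs.
#'
#' @param seed integer root seed (all components derive their RNG stream
#'   from it; survey generation uses `seed + 8191`).
#' @param n_loci number of biallelic SNP loci.
#' @param n_zones number of collection zones (up to 7, named).
#' @param fst Balding-Nichols target Fst among zones.
#' @param ancestral_maf_range range of the ancestral minor allele frequency
#'   (uniform draw).
#' @param clones_per_zone founder clones whose home is each zone.
#' @param copies_dist named probability vector: number of collected copies
#'   per clone (names "1", "2", ... are the copy counts).
#' @param shared_clone_fraction fraction of clones also planted (and
#'   collected) in a second zone.
#' @param het_miscall_rate probability a true heterozygote is recorded as a
#'   homozygote (split evenly between the two homozygotes).
#' @param mutation_rate per-locus somatic mutation probability applied to
#'   each biological-replicate plant (dosage resampled from the zone
#'   frequency).
#' @param missing_rate per-call missing probability.
#' @param n_bio_replicate_groups,n_tech_replicate_groups number of
#'   biological / technical replicate groups.
#' @param replicate_group_size samples per replicate group.
#' @param n_reference_landraces,n_breeding_lines reference panel sizes
#'   (0 = no panel).
#' @param ref_match_fraction fraction of reference landraces that duplicate
#'   a collected clone (the rest are novel genotypes).
#' @param n_breeding_matches collected clones that are secretly identical
#'   to a breeding line (misfiled improved material).
#' @param survey list of survey-generator settings: `n` landraces,
#'   `zone_weights` (relative collection intensity per zone),
#'   `target_correlation` (latent trait correlation),
#'   `dont_know_rate` (score replaced by 0), `unknown_use_rate`,
#'   `fresh_primary_by_zone` (probability the cited primary use is fresh
#'   consumption rather than flour), `secondary_other_rate` (probability
#'   the other use is also cited), `n_respondents`.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_loci = 1000,
                       n_zones = 7,
                       fst = 0.05,
                       ancestral_maf_range = c(0.05, 0.5),
                       clones_per_zone = 40,
                       copies_dist = c("1" = 0.73, "2" = 0.09, "3" = 0.09,
                                       "4" = 0.045, "5" = 0.045),
                       shared_clone_fraction = 0.12,
                       het_miscall_rate = 0.01,
                       mutation_rate = 0.001,
                       missing_rate = 0.02,
                       n_bio_replicate_groups = 3,
                       n_tech_replicate_groups = 2,
                       replicate_group_size = 2,
                       n_reference_landraces = 0,
                       n_breeding_lines = 0,
                       ref_match_fraction = 0.5,
                       n_breeding_matches = 0,
                       survey = list()) {
  stopifnot(n_loci >= 1, n_zones >= 1, n_zones <= 7,
            fst > 0, fst < 1,
            length(ancestral_maf_range) == 2,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            clones_per_zone >= 1,
            abs(sum(copies_dist) - 1) < 1e-8, all(copies_dist >= 0),
            shared_clone_fraction >= 0, shared_clone_fraction <= 1,
            het_miscall_rate >= 0, het_miscall_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            replicate_group_size >= 2,
            ref_match_fraction >= 0, ref_match_fraction <= 1)
  n_clones <- n_zones * clones_per_zone
  if (n_bio_replicate_groups + n_tech_replicate_groups + n_breeding_matches > n_clones)
    stop("more replicate groups / breeding matches than clones")
  sv <- utils::modifyList(list(
    n = 427,
    zone_weights = c(Central = 79, Coastal = 53, Lake = 62, Northern = 69,
                     SouthernHighlands = 81, Western = 30, Zanzibar = 53),
    target_correlation = default_trait_correlation(),
    dont_know_rate = 0.08,
    unknown_use_rate = 0.04,
    fresh_primary_by_zone = c(Central = 0.24, Coastal = 0.91, Lake = 0.53,
                              Northern = 0.90, SouthernHighlands = 0.34,
                              Western = 0.46, Zanzibar = 0.96),
    secondary_other_rate = 0.354,
    n_respondents = 193
  ), survey)
  ev <- eigen(sv$target_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("target trait correlation matrix is not positive semi-definite")
  structure(list(seed = as.integer(seed), n_loci = n_loci, n_zones = n_zones,
                 fst = fst, ancestral_maf_range = ancestral_maf_range,
                 clones_per_zone = clones_per_zone, copies_dist = copies_dist,
                 shared_clone_fraction = shared_clone_fraction,
                 het_miscall_rate = het_miscall_rate,
                 mutation_rate = mutation_rate, missing_rate = missing_rate,
                 n_bio_replicate_groups = n_bio_replicate_groups,
                 n_tech_replicate_groups = n_tech_replicate_groups,
                 replicate_group_size = replicate_group_size,
                 n_reference_landraces = n_reference_landraces,
                 n_breeding_lines = n_breeding_lines,
                 ref_match_fraction = ref_match_fraction,
                 n_breeding_matches = n_breeding_matches,
                 survey = sv),
            class = "sim_config")
}

# observe one copy of a founder genotype: het miscalls then missing calls
observe_copy <- function(founder, eps, miss) {
  g <- founder
  hets <- which(g == 1L)
  if (length(hets) && eps > 0) {
    u <- stats::runif(length(hets))
    g[hets[u < eps / 2]] <- 0L
    g[hets[u >= eps / 2 & u < eps]] <- 2L
  }
  if (miss > 0) g[stats::runif(length(g)) < miss] <- NA_integer_
  g
}

# somatic mutation: per-locus resample from zone frequency
mutate_plant <- function(founder, p_zone, mu) {
  if (mu <= 0) return(founder)
  hit <- which(stats::runif(length(founder)) < mu)
  if (length(hit)) founder[hit] <- stats::rbinom(length(hit), 2, p_zone[hit])
  founder
}

#' Simulate a zone-structured clonal germplasm collection
#'
#' Generative model: an ancestral allele frequency per locus is drawn
#' uniformly from `ancestral_maf_range`; zone frequencies follow the
#' Balding-Nichols construction `p_z ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`;
#' founder clone dosages are `Binomial(2, p_z)` at the clone's home zone;
#' every collected copy independently records heterozygotes as homozygotes
#' with probability `het_miscall_rate` (split evenly between the two
#' homozygotes) and drops calls with probability `missing_rate`. Biological
#' replicates are distinct plants of one clone, so each additionally
#' carries per-locus somatic mutations at `mutation_rate`; technical
#' replicates are re-genotypings of one plant (genotyping error only).
#' Output is deterministic in `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_population`: list with `genotypes`
#'   (genotype matrix), `metadata` (see [sample_metadata()]) and `truth`
#'   (list: `clone_of` named vector sample -> true clone id, `zone_freqs`,
#'   `founders`, `clone_zones`, `config`).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  zones <- ZONES[seq_len(cfg$n_zones)]
  L <- cfg$n_loci
  p_anc <- stats::runif(L, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  Fst <- cfg$fst
  p_zone <- matrix(NA_real_, cfg$n_zones, L, dimnames = list(zones, NULL))
  for (z in seq_len(cfg$n_zones))
    p_zone[z, ] <- stats::rbeta(L, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst)

  n_clones <- cfg$n_zones * cfg$clones_per_zone
  clone_ids <- sprintf("CL%03d", seq_len(n_clones))
  home <- rep(zones, each = cfg$clones_per_zone)
  founders <- matrix(NA_integer_, n_clones, L,
                     dimnames = list(clone_ids, sprintf("SNP%05d", seq_len(L))))
  for (k in seq_len(n_clones))
    founders[k, ] <- stats::rbinom(L, 2, p_zone[home[k], ])

  # breeding-line matches: designated clones are truly improved material
  match_breeding <- integer(0)
  if (cfg$n_breeding_matches > 0)
    match_breeding <- sample(n_clones, cfg$n_breeding_matches)

  # zone placement: every clone is collected in its home zone; shared
  # clones also in one other zone
  clone_zones <- lapply(seq_len(n_clones), function(k) home[k])
  n_shared <- round(cfg$shared_clone_fraction * n_clones)
  shared <- if (n_shared > 0) sample(n_clones, n_shared) else integer(0)
  for (k in shared)
    clone_zones[[k]] <- c(home[k], sample(setdiff(zones, home[k]), 1))
  names(clone_zones) <- clone_ids

  copies <- as.integer(names(cfg$copies_dist))[
    sample.int(length(cfg$copies_dist), n_clones, replace = TRUE,
               prob = cfg$copies_dist)]
  copies <- pmax(copies, lengths(clone_zones))  # shared clones need a copy per zone

  sample_id <- character(0); s_zone <- character(0); s_clone <- character(0)
  s_cat <- character(0); s_group <- character(0); s_type <- character(0)
  dosages <- list()
  eps <- cfg$het_miscall_rate; mss <- cfg$missing_rate

  for (k in seq_len(n_clones)) {
    zs <- clone_zones[[k]]
    zone_of_copy <- c(zs, sample(zs, copies[k] - length(zs), replace = TRUE))
    for (cp in seq_len(copies[k])) {
      id <- sprintf("%s-%02d", clone_ids[k], cp)
      sample_id <- c(sample_id, id)
      s_zone <- c(s_zone, zone_of_copy[cp])
      s_clone <- c(s_clone, clone_ids[k])
      s_cat <- c(s_cat, "collected")
      s_group <- c(s_group, NA); s_type <- c(s_type, NA)
      dosages[[id]] <- observe_copy(founders[k, ], eps, mss)
    }
  }

  # replicate groups: extra samples of designated clones
  n_rep <- cfg$n_bio_replicate_groups + cfg$n_tech_replicate_groups
  rep_clones <- sample(setdiff(seq_len(n_clones), match_breeding), n_rep)
  rep_type <- rep(c("biological", "technical"),
                  c(cfg$n_bio_replicate_groups, cfg$n_tech_replicate_groups))
  for (g in seq_len(n_rep)) {
    k <- rep_clones[g]
    gid <- sprintf("%s%02d", if (rep_type[g] == "biological") "BR" else "TR", g)
    for (m in seq_len(cfg$replicate_group_size)) {
      id <- sprintf("%s-%s%s", clone_ids[k], gid, letters[m])
      base <- founders[k, ]
      if (rep_type[g] == "biological")
        base <- mutate_plant(base, p_zone[home[k], ], cfg$mutation_rate)
      sample_id <- c(sample_id, id)
      s_zone <- c(s_zone, home[k])
      s_clone <- c(s_clone, clone_ids[k])
      s_cat <- c(s_cat, "collected")
      s_group <- c(s_group, gid); s_type <- c(s_type, rep_type[g])
      dosages[[id]] <- observe_copy(base, eps, mss)
    }
  }

  # reference landrace panel
  if (cfg$n_reference_landraces > 0) {
    n_match <- round(cfg$ref_match_fraction * cfg$n_reference_landraces)
    pool <- setdiff(seq_len(n_clones), match_breeding)
    match_ref <- sample(pool, min(n_match, length(pool)))
    for (r in seq_len(cfg$n_reference_landraces)) {
      id <- sprintf("REF%02d", r)
      if (r <= length(match_ref)) {
        k <- match_ref[r]
        base <- founders[k, ]
        s_clone <- c(s_clone, clone_ids[k])
      } else {
        z <- sample(cfg$n_zones, 1)
        base <- stats::rbinom(L, 2, p_zone[z, ])
        s_clone <- c(s_clone, sprintf("REFCL%02d", r))
      }
      sample_id <- c(sample_id, id)
      s_zone <- c(s_zone, NA)
      s_cat <- c(s_cat, "reference_landrace")
      s_group <- c(s_group, NA); s_type <- c(s_type, NA)
      dosages[[id]] <- observe_copy(as.integer(base), eps, mss)
    }
  }

  # breeding-line panel; the first n_breeding_matches lines duplicate the
  # designated "collected" clones (misfiled improved material)
  if (cfg$n_breeding_lines > 0) {
    for (r in seq_len(cfg$n_breeding_lines)) {
      id <- sprintf("BL%02d", r)
      if (r <= length(match_breeding)) {
        k <- match_breeding[r]
        base <- founders[k, ]
        s_clone <- c(s_clone, clone_ids[k])
      } else {
        z <- sample(cfg$n_zones, 1)
        base <- stats::rbinom(L, 2, p_zone[z, ])
        s_clone <- c(s_clone, sprintf("BLCL%02d", r))
      }
      sample_id <- c(sample_id, id)
      s_zone <- c(s_zone, NA)
      s_cat <- c(s_cat, "reference_breeding")
      s_group <- c(s_group, NA); s_type <- c(s_type, NA)
      dosages[[id]] <- observe_copy(as.integer(base), eps, mss)
    }
  }

  G <- do.call(rbind, dosages)
  rownames(G) <- sample_id
  colnames(G) <- sprintf("SNP%05d", seq_len(L))

  # farmer-given names: collide across copies only by chance
  name_pool <- sprintf("Landrace%03d", seq_len(max(200, n_clones)))
  given <- ifelse(s_cat == "collected",
                  sample(name_pool, length(sample_id), replace = TRUE),
                  sub("-.*$", "", sample_id))
  meta <- sample_metadata(data.frame(
    sample_id = sample_id, given_name = given, zone = s_zone,
    category = s_cat, replicate_group = s_group, replicate_type = s_type,
    stringsAsFactors = FALSE))
  truth <- list(clone_of = stats::setNames(s_clone, sample_id),
                zone_freqs = p_zone,
                founders = founders,
                clone_zones = clone_zones,
                breeding_match_clones = clone_ids[match_breeding],
                config = cfg)
  structure(list(genotypes = genotype_matrix(G), metadata = meta,
                 truth = truth),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("Simulated collection: %d samples x %d loci, %d zones, %d true clones\n",
              nrow(x$genotypes), ncol(x$genotypes),
              x$truth$config$n_zones, length(unique(x$truth$clone_of))))
  invisible(x)
}

#' Simulate a key-informant survey table
#'
#' Trait scores arise from a latent multivariate Gaussian with the
#' configured correlation matrix, thresholded into scores 1-5 at
#' equal-probability cut points, then independently replaced by 0 ("don't
#' know") with `dont_know_rate`. Cited uses are drawn from zone-specific
#' fresh/flour propensities with a configurable chance of citing the other
#' use among secondary/tertiary uses. Respondent attributes (gender,
#' education, land access, years growing, seed source, growing trend)
#' follow the marginal percentages typical of such surveys. Uses the
#' `cfg$seed + 8191` RNG substream so population and survey generation are
#' independently reproducible.
#'
#' @param cfg a [sim_config()].
#' @return survey data.frame, one row per collected landrace.
#' @export
simulate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sv <- cfg$survey
  set.seed(cfg$seed + 8191L)
  n <- sv$n
  zones <- names(sv$zone_weights)
  zone <- sample(zones, n, replace = TRUE,
                 prob = sv$zone_weights / sum(sv$zone_weights))

  R <- sv$target_correlation
  Lch <- chol(R + diag(1e-10, nrow(R)))
  Z <- matrix(stats::rnorm(n * nrow(R)), n) %*% Lch
  cuts <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8))
  scores <- apply(Z, 2, function(col) 1L + findInterval(col, cuts))
  scores[matrix(stats::runif(length(scores)) < sv$dont_know_rate,
                nrow(scores))] <- 0L
  colnames(scores) <- colnames(R)

  fresh_p <- sv$fresh_primary_by_zone[zone]
  primary_fresh <- stats::runif(n) < fresh_p
  cite_other <- stats::runif(n) < sv$secondary_other_rate
  unknown <- stats::runif(n) < sv$unknown_use_rate
  use_primary <- ifelse(primary_fresh, "household food roots",
                        "household food processed")
  use_secondary <- ifelse(cite_other,
                          ifelse(primary_fresh, "household food processed",
                                 "household food roots"),
                          sample(c("leaves", "fodder", NA), n, replace = TRUE))
  use_tertiary <- sample(c("leaves", NA, NA), n, replace = TRUE)
  use_primary[unknown] <- NA
  use_secondary[unknown] <- NA
  use_tertiary[unknown] <- NA

  resp <- sample.int(sv$n_respondents, n, replace = TRUE)
  rgender <- sample(c("female", "male"), sv$n_respondents, replace = TRUE,
                    prob = c(0.26, 0.74))
  rage <- sample(18:86, sv$n_respondents, replace = TRUE)
  redu <- sample(c("none", "primary", "secondary", "tertiary"),
                 sv$n_respondents, replace = TRUE,
                 prob = c(0.22, 0.66, 0.10, 0.02))
  rland <- vapply(sample.int(5, sv$n_respondents, replace = TRUE,
                             prob = c(0.135, 0.427, 0.245, 0.177, 0.016)),
                  function(b) switch(b, stats::runif(1, 0.1, 1),
                                     stats::runif(1, 1, 4.9),
                                     stats::runif(1, 5, 9.9),
                                     stats::runif(1, 10, 30), NA_real_),
                  numeric(1))
  ryears <- vapply(sample.int(5, sv$n_respondents, replace = TRUE,
                              prob = c(0.25, 0.31, 0.40, 0.02, 0.02)),
                   function(b) switch(b, stats::runif(1, 0, 4.9),
                                      stats::runif(1, 5, 19.9),
                                      stats::runif(1, 20, 49.9),
                                      stats::runif(1, 50, 70), NA_real_),
                   numeric(1))
  rseed <- sample(c("own", "own_plus_gift", "own_plus_purchase", "gift", "other"),
                  sv$n_respondents, replace = TRUE,
                  prob = c(0.63, 0.13, 0.01, 0.20, 0.03))
  trend <- sample(c("increase", "stable", "decrease", "unknown"), n,
                  replace = TRUE, prob = c(0.55, 0.20, 0.15, 0.10))

  df <- data.frame(collector_id = sprintf("LR%04d", seq_len(n)),
                   zone = zone,
                   use_primary = use_primary,
                   use_secondary = use_secondary,
                   use_tertiary = use_tertiary,
                   scores,
                   respondent_id = sprintf("KI%03d", resp),
                   gender = rgender[resp],
                   age = rage[resp],
                   education = redu[resp],
                   land_acres = rland[resp],
                   years_growing = ryears[resp],
                   seed_source = rseed[resp],
                   growing_trend = trend,
                   stringsAsFactors = FALSE)
  df
}

#' Adjusted Rand index between two partitions
#'
#' Standard contingency-table formula; 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param a,b label vectors over the same elements.
#' @return ARI (scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Compare a called clone partition with the simulation truth
#'
#' @param partition a `clone_partition` over the simulated samples.
#' @param truth the `truth` element of a [simulate_population()] result (or
#'   the `sim_population` itself).
#' @return object of class `recovery_metrics`: list with `ari`,
#'   `false_merges` (called groups mixing several true clones),
#'   `false_splits` (true clones split across called groups), `n_samples`.
#' @export
evaluate_recovery <- function(partition, truth) {
  if (inherits(truth, "sim_population")) truth <- truth$truth
  ids <- names(partition$membership)
  if (!setequal(ids, names(truth$clone_of)))
    stop("partition and truth cover different samples")
  called <- partition$membership[ids]
  true <- truth$clone_of[ids]
  tab <- table(called, true)
  structure(list(
    ari = adjusted_rand_index(called, true),
    false_merges = sum(rowSums(tab > 0) > 1),
    false_splits = sum(colSums(tab > 0) > 1),
    n_samples = length(ids)), class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("Clone recovery: ARI %.4f, %d false merge(s), %d false split(s) over %d samples\n",
              x$ari, x$false_merges, x$false_splits, x$n_samples))
  invisible(x)
}
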