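# Independent oracles used across the suite. Each is deliberately written
# with different algebra / algorithms than the package implementation.

# per-pair double loop Hamming distance with pairwise-complete deletion
hamming_oracle <- function(G) {
  n <- nrow(G)
  d <- matrix(0, n, n, dimnames = list(rownames(G), rownames(G)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    ok <- !is.na(G[i, ]) & !is.na(G[j, ])
    d[i, j] <- d[j, i] <- if (!any(ok)) NA_real_ else
      sum(abs(G[i, ok] - G[j, ok])) / (2 * sum(ok))
  }
  d
}

# transitive-closure connected components under d < thr
components_oracle <- function(D, thr) {
  n <- nrow(D)
  adj <- (D < thr)
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) reach <- (reach %*% adj) > 0  # Floyd-style closure
  grp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) if (grp[i] == 0L) {
    nxt <- nxt + 1L
    grp[reach[i, ] & grp == 0L] <- nxt
  }
  stats::setNames(grp, rownames(D))
}

# Weir-Cockerham theta via the ANOVA mean-squares formulation (distinct
# algebra from the package's direct variance-component code). `pops` is a
# list of dosage vectors (one per population), one locus.
wc84_ms_oracle_locus <- function(pops) {
  r <- length(pops)
  pops <- lapply(pops, function(g) g[!is.na(g)])
  n <- vapply(pops, length, 0L)
  if (any(n == 0) || sum(n) <= r) return(c(a = NA, b = NA, c = NA))
  p_i <- vapply(pops, function(g) sum(g) / (2 * length(g)), 0)
  pbar <- sum(n * p_i) / sum(n)
  # within-individual SS: 0.5 per heterozygote
  SSG <- sum(vapply(pops, function(g) sum(g == 1) * 0.5, 0))
  MSG <- SSG / sum(n)
  SSI <- sum(unlist(mapply(function(g, p) 2 * (g / 2 - p)^2, pops, p_i,
                           SIMPLIFY = FALSE)))
  MSI <- SSI / (sum(n) - r)
  SSP <- sum(2 * n * (p_i - pbar)^2)
  MSP <- SSP / (r - 1)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  c(a = a, b = b, c = MSG)
}

wc84_ms_oracle <- function(G1, G2) {
  L <- ncol(G1)
  acc <- c(a = 0, b = 0, c = 0)
  for (l in seq_len(L)) {
    v <- wc84_ms_oracle_locus(list(G1[, l], G2[, l]))
    if (!anyNA(v)) acc <- acc + v
  }
  acc[["a"]] / sum(acc)
}

# exhaustive minimum spanning tree weight: try all (n-1)-edge subsets
mst_weight_oracle <- function(D) {
  n <- nrow(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  best <- Inf
  for (s in utils::combn(nrow(idx), n - 1, simplify = FALSE)) {
    # connectivity check on the chosen edges
    adj <- matrix(FALSE, n, n)
    adj[idx[s, , drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    reach <- adj[1, ]
    reach[1] <- TRUE
    for (k in seq_len(n)) reach <- reach | (reach %*% adj > 0)
    if (all(reach)) best <- min(best, sum(w[s]))
  }
  best
}

# random additive 4-taxon tree -> (distance matrix, path-length function)
random_additive_4taxon <- function() {
  b <- stats::runif(5, 0.1, 2)  # A, B, C, D terminals + internal
  labs <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  D["A", "B"] <- D["B", "A"] <- b[1] + b[2]
  D["C", "D"] <- D["D", "C"] <- b[3] + b[4]
  for (i in 1:2) for (j in 3:4)
    D[i, j] <- D[j, i] <- b[i] + b[5] + b[j]
  D
}

# small simulated dosage matrix with missing cells
random_genotype_fixture <- function(n, L, miss = 0.1) {
  G <- matrix(sample(0:2, n * L, replace = TRUE), n, L,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("L%03d", seq_len(L))))
  G[matrix(stats::runif(n * L) < miss, n, L)] <- NA
  storage.mode(G) <- "integer"
  G
}

# metadata for a plain collected panel
meta_fixture <- function(ids, zones, category = "collected",
                         group = NA, type = NA, names = ids) {
  sample_metadata(data.frame(
    sample_id = ids, given_name = names,
    zone = zones, category = category,
    replicate_group = group, replicate_type = type,
    stringsAsFactors = FALSE))
}
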