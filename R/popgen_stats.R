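#' Shannon diversity index on clone abundances
#'
#' `H = -sum(p_i * log(p_i))` in nats, with `p_i` the relative abundance of
#' clone i; zero-count clones are excluded. `H` ranges from 0 (one clone)
#' to `log(k)` (k clones, uniform abundances).
#'
#' @param abundances non-negative counts (clone -> number of samples).
#' @return Shannon index (nats).
#' @export
shannon_index <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  total <- sum(abundances)
  if (total <= 0) stop("total abundance is zero")
  p <- abundances[abundances > 0] / total
  -sum(p * log(p))
}

#' Per-zone Shannon diversity of clone abundances
#'
#' Counts, within each zone, how many collected samples fall in each clone
#' group and applies [shannon_index()].
#'
#' @param partition a `clone_partition`.
#' @param meta sample metadata.
#' @return named numeric vector, zone -> H (nats).
#' @export
zone_diversity <- function(partition, meta) {
  coll <- meta[meta$category == "collected" &
                 meta$sample_id %in% names(partition$membership), ]
  coll$group <- partition$membership[coll$sample_id]
  vapply(split(coll$group, coll$zone),
         function(g) shannon_index(as.numeric(table(g))), numeric(1))
}

#' Per-zone allele frequencies from dosages
#'
#' `p = sum(dosages) / (2 * n_called)` per zone and locus; `NA` where a zone
#' has no call at a locus.
#'
#' @param G genotype matrix.
#' @param grouping named character vector or factor, sample -> zone
#'   (names matching rownames of `G`; unnamed vectors are taken in row
#'   order).
#' @return list with `p` (zones x loci frequency matrix) and `n_called`
#'   (zones x loci count matrix).
#' @export
allele_frequencies <- function(G, grouping) {
  grouping <- align_grouping(G, grouping)
  zs <- sort(unique(as.character(grouping)))
  p <- matrix(NA_real_, length(zs), ncol(G), dimnames = list(zs, colnames(G)))
  nc <- matrix(0L, length(zs), ncol(G), dimnames = list(zs, colnames(G)))
  for (z in zs) {
    Gz <- G[grouping == z, , drop = FALSE]
    n <- colSums(!is.na(Gz))
    nc[z, ] <- n
    p[z, ] <- ifelse(n > 0, colSums(Gz, na.rm = TRUE) / (2 * n), NA_real_)
  }
  list(p = p, n_called = nc)
}

align_grouping <- function(G, grouping) {
  if (!is.null(names(grouping))) {
    if (!all(rownames(G) %in% names(grouping)))
      stop("grouping missing for sample(s): ",
           paste(setdiff(rownames(G), names(grouping)), collapse = ", "))
    grouping <- grouping[rownames(G)]
  } else if (length(grouping) != nrow(G)) {
    stop("grouping length does not match number of samples")
  }
  as.character(grouping)
}

# Weir & Cockerham (1984) variance components for one pair of populations,
# vectorised over loci. Inputs are per-population called sample sizes,
# allele frequencies and observed heterozygote frequencies.
wc84_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  ok <- n1 > 0 & n2 > 0 & (n1 + n2) > 2 & !is.na(p1) & !is.na(p2)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- ok & nc > 0 & is.finite(a) & is.finite(b) & is.finite(cc)
  list(a = a[ok], b = b[ok], c = cc[ok])
}

#' Pairwise Fst between zones
#'
#' Default estimator is the Weir & Cockerham (1984) theta: the multilocus
#' ratio of averages `sum(a) / sum(a + b + c)` of the among-population (a),
#' among-individual (b) and within-individual (c) variance components
#' computed from dosage-derived genotype counts. `"Nei87"` instead computes
#' a Gst-based Fst, `(Ht - Hs) / Ht` with gene diversities summed across
#' loci. Loci without calls in either zone of a pair are skipped.
#'
#' By default the estimate uses one representative per clone group per zone
#' when a `partition` is supplied (deduplicated set); pass `partition =
#' NULL` to use all samples.
#'
#' @param G genotype matrix.
#' @param grouping sample -> zone (see [allele_frequencies()]).
#' @param estimator `"WC84"` (default) or `"Nei87"`.
#' @param partition optional `clone_partition`; when given, the samples are
#'   deduplicated to one collected representative per clone group per zone
#'   before estimation.
#' @return symmetric zone x zone matrix of Fst estimates (diagonal 0).
#' @export
pairwise_fst <- function(G, grouping, estimator = c("WC84", "Nei87"),
                         partition = NULL) {
  estimator <- match.arg(estimator)
  grouping <- align_grouping(G, grouping)
  names(grouping) <- rownames(G)
  if (!is.null(partition)) {
    keep <- dedup_by_zone(partition, grouping, G)
    G <- G[keep, , drop = FALSE]
    grouping <- grouping[keep]
  }
  zs <- sort(unique(grouping))
  sizes <- table(grouping)
  if (any(sizes < 2))
    stop("zone(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  het <- (!is.na(G) & G == 1L) * 1
  called <- !is.na(G)
  fst <- matrix(0, length(zs), length(zs), dimnames = list(zs, zs))
  stats_z <- lapply(zs, function(z) {
    Gz <- G[grouping == z, , drop = FALSE]
    n <- colSums(!is.na(Gz))
    list(n = n,
         p = ifelse(n > 0, colSums(Gz, na.rm = TRUE) / (2 * n), NA_real_),
         h = ifelse(n > 0, colSums(het[grouping == z, , drop = FALSE]) / n, NA_real_))
  })
  names(stats_z) <- zs
  for (i in seq_along(zs)) for (j in seq_along(zs)) if (i < j) {
    s1 <- stats_z[[i]]; s2 <- stats_z[[j]]
    if (estimator == "WC84") {
      vc <- wc84_components(s1$n, s2$n, s1$p, s2$p, s1$h, s2$h)
      denom <- sum(vc$a + vc$b + vc$c)
      fst[i, j] <- fst[j, i] <- if (denom > 0) sum(vc$a) / denom else NA_real_
    } else {
      ok <- s1$n > 0 & s2$n > 0 & !is.na(s1$p) & !is.na(s2$p)
      hs <- s1$p[ok] * (1 - s1$p[ok]) + s2$p[ok] * (1 - s2$p[ok])  # sum of 2pq / 2
      pb <- (s1$p[ok] + s2$p[ok]) / 2
      ht <- 2 * pb * (1 - pb)
      Ht <- sum(ht)
      fst[i, j] <- fst[j, i] <- if (Ht > 0) (Ht - sum(hs)) / Ht else NA_real_
    }
  }
  fst
}

# One collected representative per clone group per zone (falls back to any
# member when the group has no collected sample in that zone's subset).
dedup_by_zone <- function(partition, grouping, G) {
  ids <- intersect(names(partition$membership), names(grouping))
  df <- data.frame(id = ids,
                   group = partition$membership[ids],
                   zone = grouping[ids], stringsAsFactors = FALSE)
  picks <- lapply(split(df, list(df$group, df$zone), drop = TRUE),
                  function(s) select_representative(s$id, G))
  unlist(picks, use.names = FALSE)
}

#' Nei's (1972) standard genetic distance for biallelic loci
#'
#' With per-locus frequencies x, y of the same allele in two populations,
#' the gene identities are `J_xy = sum(x*y + (1-x)*(1-y))`, `J_x = sum(x^2 +
#' (1-x)^2)`, `J_y` likewise, summed across loci (ratio-of-sums
#' aggregation); the normalised identity is `I = J_xy / sqrt(J_x * J_y)` and
#' `D = -log(I)`. When `I` underflows to 0 (fixed opposite alleles at every
#' locus) `D` is clamped to `max_d` with a warning.
#'
#' @param x,y allele-frequency vectors over the same loci (`NA`s dropped
#'   pairwise).
#' @param max_d clamp for infinite distances (default 10).
#' @return Nei's standard distance D (scalar, >= 0).
#' @export
nei_distance <- function(x, y, max_d = 10) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no shared defined loci")
  x <- x[ok]; y <- y[ok]
  jxy <- sum(x * y + (1 - x) * (1 - y))
  jx <- sum(x^2 + (1 - x)^2)
  jy <- sum(y^2 + (1 - y)^2)
  I <- jxy / sqrt(jx * jy)
  if (I <= exp(-max_d)) {
    warning("identity ~ 0; distance clamped to ", max_d)
    return(max_d)
  }
  max(0, -log(I))
}

#' Pairwise Nei distance matrix between zones
#'
#' @inheritParams pairwise_fst
#' @param max_d clamp passed to [nei_distance()].
#' @return symmetric zone x zone matrix of Nei distances.
#' @export
pairwise_nei <- function(G, grouping, partition = NULL, max_d = 10) {
  grouping <- align_grouping(G, grouping)
  names(grouping) <- rownames(G)
  if (!is.null(partition)) {
    keep <- dedup_by_zone(partition, grouping, G)
    G <- G[keep, , drop = FALSE]
    grouping <- grouping[keep]
  }
  af <- allele_frequencies(G, grouping)
  zs <- rownames(af$p)
  D <- matrix(0, length(zs), length(zs), dimnames = list(zs, zs))
  for (i in seq_along(zs)) for (j in seq_along(zs)) if (i < j)
    D[i, j] <- D[j, i] <- nei_distance(af$p[i, ], af$p[j, ], max_d = max_d)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q criterion. A
#' negative branch length arising at a join is clamped to zero and its
#' deficit transferred to the sister branch, so path lengths through the
#' join are preserved. On additive (tree-like) distance matrices the input
#' tree is recovered exactly.
#'
#' @param D complete symmetric distance matrix, n >= 3.
#' @return unrooted tree of class `phylo` (ape).
#' @export
neighbor_joining <- function(D) {
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(D[upper.tri(D)])) stop("distance matrix has undefined entries")
  d <- as.matrix(D)
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  node <- labs  # newick fragment per active node
  active <- seq_len(n)
  clamp_pair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  while (length(active) > 3) {
    r <- length(active)
    dm <- d[active, active]
    R <- rowSums(dm)
    Q <- (r - 2) * dm - outer(R, R, `+`)
    diag(Q) <- Inf
    w <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- w[1]; j <- w[2]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    bi <- dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- dm[i, j] - bi
    b <- clamp_pair(bi, bj)
    ai <- active[i]; aj <- active[j]
    new_lab <- sprintf("(%s:%.12g,%s:%.12g)", node[ai], b[1], node[aj], b[2])
    dnew <- (d[ai, active] + d[aj, active] - d[ai, aj]) / 2
    # reuse slot ai for the merged node
    d[ai, active] <- dnew
    d[active, ai] <- dnew
    d[ai, ai] <- 0
    node[ai] <- new_lab
    active <- setdiff(active, aj)
  }
  a <- active
  b1 <- (d[a[1], a[2]] + d[a[1], a[3]] - d[a[2], a[3]]) / 2
  b2 <- (d[a[1], a[2]] + d[a[2], a[3]] - d[a[1], a[3]]) / 2
  b3 <- (d[a[1], a[3]] + d[a[2], a[3]] - d[a[1], a[2]]) / 2
  bs <- c(b1, b2, b3)
  if (any(bs < 0)) {  # transfer deficit to the longest remaining branch
    deficit <- sum(bs[bs < 0])
    bs[bs < 0] <- 0
    k <- which.max(bs)
    bs[k] <- max(0, bs[k] + deficit)
  }
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    node[a[1]], bs[1], node[a[2]], bs[2], node[a[3]], bs[3])
  ape::read.tree(text = newick)
}
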