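#' Principal component analysis of a genotype matrix
#'
#' Missing calls are mean-imputed per locus, loci are centred (not scaled)
#' and the sample covariance is eigendecomposed (via SVD). Eigenvalues are
#' reported for all axes; the cumulative variance fraction is given for the
#' retained axis count.
#'
#' @param G genotype matrix.
#' @param n_axes number of axes to retain (default: all).
#' @return object of class `genotype_pca`: list with `scores` (samples x
#'   retained axes), `eigenvalues` (all axes), `var_fraction`,
#'   `cum_var_fraction` (cumulative fraction at each retained axis count),
#'   `n_axes`.
#' @export
pca_genotypes <- function(G, n_axes = NULL) {
  X <- impute_locus_means(G)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (is.null(n_axes)) n_axes <- rank
  if (n_axes > rank) {
    warning("n_axes (", n_axes, ") exceeds rank (", rank, "); truncated")
    n_axes <- rank
  }
  vf <- ev / sum(ev)
  structure(list(scores = pr$x[, seq_len(n_axes), drop = FALSE],
                 eigenvalues = ev,
                 var_fraction = vf,
                 cum_var_fraction = cumsum(vf)[seq_len(n_axes)],
                 n_axes = n_axes),
            class = "genotype_pca")
}

impute_locus_means <- function(G) {
  X <- G
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("Genotype PCA: %d axes retained, %.1f%% of variance\n",
              x$n_axes, 100 * x$cum_var_fraction[x$n_axes]))
  invisible(x)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Linear discriminant analysis on retained PCA scores of the genotype
#' matrix, with the grouping (e.g. collection zone) as prior classes. At
#' most `n_groups - 1` discriminant functions exist; all are retained. Each
#' sample is assigned to the class with the highest posterior.
#'
#' @param G genotype matrix.
#' @param grouping sample -> group (named, or in row order).
#' @param n_pca_axes PCA axes retained before the discriminant step
#'   (default 100, truncated to the available rank).
#' @return object of class `dapc`: list with `pca` (the `genotype_pca`),
#'   `lda` (the MASS fit), `scores` (discriminant coordinates),
#'   `posterior`, `assignment` (factor), `grouping`, `accuracy`
#'   (fraction of samples assigned to their prior group),
#'   `pca_var_fraction` (cumulative variance of the retained PCA axes).
#' @export
dapc <- function(G, grouping, n_pca_axes = 100) {
  grouping <- factor(align_grouping(G, grouping))
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  sizes <- table(grouping)
  if (any(sizes < 2))
    stop("group(s) with a single sample (within-group covariance undefined): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  pca <- suppressWarnings(pca_genotypes(G, n_axes = n_pca_axes))
  fit <- MASS::lda(pca$scores, grouping = grouping)
  pred <- stats::predict(fit, pca$scores)
  structure(list(pca = pca, lda = fit,
                 scores = pred$x,
                 posterior = pred$posterior,
                 assignment = pred$class,
                 grouping = grouping,
                 accuracy = mean(pred$class == grouping),
                 pca_var_fraction = pca$cum_var_fraction[pca$n_axes]),
            class = "dapc")
}

#' @export
print.dapc <- function(x, ...) {
  cat(sprintf("DAPC: %d PCA axes (%.1f%% of variance), %d discriminant functions, %d groups\n",
              x$pca$n_axes, 100 * x$pca_var_fraction, ncol(x$scores),
              nlevels(x$grouping)))
  cat(sprintf("Reassignment accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Plot DAPC discriminant scores
#' @param x a `dapc` object.
#' @param axes which two discriminant functions to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dapc <- function(x, axes = c(1, 2), ...) {
  if (ncol(x$scores) == 1L) {
    graphics::plot(x$scores[, 1], col = as.integer(x$grouping),
                   ylab = "LD1", xlab = "sample", ...)
  } else {
    graphics::plot(x$scores[, axes[1]], x$scores[, axes[2]],
                   col = as.integer(x$grouping),
                   xlab = paste0("LD", axes[1]), ylab = paste0("LD", axes[2]), ...)
  }
  invisible(x)
}

#' Hierarchical dendrogram of samples
#'
#' UPGMA (average linkage; default, ultrametric) or neighbor joining over a
#' complete sample distance matrix. UPGMA heights are the average distances
#' divided equally, so two samples at distance d form a cherry at height
#' d/2.
#'
#' @param D complete distance matrix.
#' @param method `"upgma"` (default) or `"nj"`.
#' @return tree of class `phylo`.
#' @export
sample_dendrogram <- function(D, method = c("upgma", "nj")) {
  method <- match.arg(method)
  if (nrow(D) < 2) stop("need at least 2 samples")
  if (method == "upgma") {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    ape::as.phylo(hc)
  } else {
    neighbor_joining(D)
  }
}

#' Minimum spanning network over clone representatives
#'
#' Computes the minimum spanning tree of the complete weighted graph given
#' by `D`, then adds as *reticulations* every non-tree edge whose weight
#' ties (within `tie_tolerance`) the maximum-weight edge on the tree path
#' between its endpoints -- i.e. alternative edges that could equally be
#' part of a minimum spanning tree.
#'
#' @param D complete distance matrix (typically between clone-group
#'   representatives, one node per multilocus genotype).
#' @param tie_tolerance absolute tolerance for weight ties.
#' @return object of class `msn`: list with `nodes` (character vector) and
#'   `edges` (data.frame: from, to, weight, type in \{"mst",
#'   "reticulation"\}).
#' @export
minimum_spanning_network <- function(D, tie_tolerance = 1e-9) {
  ids <- rownames(D)
  g <- igraph::graph_from_adjacency_matrix(as.matrix(D), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, algorithm = "prim")
  mst_ends <- igraph::as_edgelist(mst)
  mst_df <- data.frame(from = mst_ends[, 1], to = mst_ends[, 2],
                       weight = igraph::E(mst)$weight,
                       type = "mst", stringsAsFactors = FALSE)
  # max edge weight on the unique tree path between every node pair:
  # one traversal per root over the tree adjacency (O(n^2) total)
  n <- length(ids)
  iid <- stats::setNames(seq_len(n), ids)
  adj <- vector("list", n)
  for (e in seq_len(nrow(mst_df))) {
    u <- iid[[mst_df$from[e]]]; v <- iid[[mst_df$to[e]]]
    adj[[u]] <- rbind(adj[[u]], c(v, mst_df$weight[e]))
    adj[[v]] <- rbind(adj[[v]], c(u, mst_df$weight[e]))
  }
  maxw <- matrix(0, n, n)
  for (root in seq_len(n)) {
    visited <- logical(n)
    visited[root] <- TRUE
    frontier <- root
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        nb <- adj[[u]]
        for (k in seq_len(NROW(nb))) {
          v <- nb[k, 1]
          if (!visited[v]) {
            visited[v] <- TRUE
            maxw[root, v] <- max(maxw[root, u], nb[k, 2])
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
    }
  }
  on_tree <- matrix(FALSE, n, n)
  on_tree[cbind(iid[mst_df$from], iid[mst_df$to])] <- TRUE
  on_tree <- on_tree | t(on_tree)
  Dm <- as.matrix(D)
  cand <- which(upper.tri(Dm) & !on_tree & Dm <= maxw + tie_tolerance,
                arr.ind = TRUE)
  ret <- if (nrow(cand)) data.frame(from = ids[cand[, 1]], to = ids[cand[, 2]],
                                    weight = Dm[cand], type = "reticulation",
                                    stringsAsFactors = FALSE)
  edges <- rbind(mst_df, ret)
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges,
                 mst_weight = sum(mst_df$weight)),
            class = "msn")
}

#' @export
print.msn <- function(x, ...) {
  cat(sprintf("Minimum spanning network: %d nodes, %d tree edges (total weight %.4g), %d reticulation(s)\n",
              length(x$nodes), sum(x$edges$type == "mst"), x$mst_weight,
              sum(x$edges$type == "reticulation")))
  invisible(x)
}

#' Plot a minimum spanning network
#' @param x an `msn` object.
#' @param ... passed to igraph's plot.
#' @export
plot.msn <- function(x, ...) {
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = x$nodes)
  igraph::plot.igraph(g, edge.lty = ifelse(igraph::E(g)$type == "mst", 1, 2), ...)
  invisible(x)
}
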