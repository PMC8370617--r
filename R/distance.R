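#' Pairwise Hamming (allele-sharing) genetic distance
#'
#' For samples i, j the distance is `sum_l |g_il - g_jl| / (2 * n_ij)`, the
#' sum running over loci called in *both* samples and `n_ij` counting those
#' loci (pairwise-complete normalisation). A heterozygote/homozygote
#' mismatch contributes 1, opposite homozygotes contribute 2, so the
#' distance is the fraction of mismatching alleles and lies in \[0, 1\].
#' Pairs sharing no called locus get `NA` and are reported in the
#' `undefined_pairs` attribute (with a warning).
#'
#' Implemented with dosage-class indicator matrix products, so it scales to
#' collection-sized inputs (hundreds of samples, tens of thousands of loci).
#'
#' @param G genotype matrix (samples x loci).
#' @return symmetric distance matrix with zero diagonal; attribute
#'   `n_shared` holds the per-pair count of jointly called loci.
#' @export
hamming_distance <- function(G) {
  if (nrow(G) < 2L) stop("need at least two samples")
  if (ncol(G) < 1L) stop("need at least one locus")
  I0 <- (!is.na(G) & G == 0L) * 1
  I1 <- (!is.na(G) & G == 1L) * 1
  I2 <- (!is.na(G) & G == 2L) * 1
  W <- I0 + I1 + I2
  mism <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  n_shared <- tcrossprod(W)
  d <- ifelse(n_shared > 0, mism / (2 * n_shared), NA_real_)
  diag(d) <- 0
  dimnames(d) <- list(rownames(G), rownames(G))
  und <- which(upper.tri(d) & is.na(d), arr.ind = TRUE)
  if (nrow(und)) {
    warning(nrow(und), " sample pair(s) share no called locus; distance undefined")
    attr(d, "undefined_pairs") <- data.frame(
      id1 = rownames(G)[und[, 1]], id2 = rownames(G)[und[, 2]],
      stringsAsFactors = FALSE)
  }
  attr(n_shared, "dimnames") <- dimnames(d)
  attr(d, "n_shared") <- n_shared
  d
}

#' Distances between replicate pairs
#'
#' Enumerates every within-group pair of samples sharing a
#' `replicate_group`, and summarises distances per replicate type
#' (biological / technical) and pooled. These distances calibrate the
#' duplicate-calling threshold: see [calibrate_threshold()].
#'
#' @param D distance matrix over all samples.
#' @param meta sample metadata (see [sample_metadata()]).
#' @return object of class `replicate_distances`: list with `pairs`
#'   (data.frame: group, id1, id2, replicate_type, distance) and `summary`
#'   (data.frame: type, n_pairs, mean, max).
#' @export
replicate_pair_distances <- function(D, meta) {
  meta <- meta[!is.na(meta$replicate_group) & meta$sample_id %in% rownames(D), ]
  groups <- split(meta, meta$replicate_group)
  groups <- groups[vapply(groups, nrow, 0L) >= 2L]
  if (!length(groups))
    stop("no replicate group with >= 2 genotyped members; cannot calibrate")
  rows <- lapply(groups, function(g) {
    cmb <- utils::combn(g$sample_id, 2)
    data.frame(group = g$replicate_group[1],
               id1 = cmb[1, ], id2 = cmb[2, ],
               replicate_type = g$replicate_type[1],
               distance = D[cbind(cmb[1, ], cmb[2, ])],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (anyNA(pairs$distance))
    stop("undefined distance within replicate group(s): ",
         paste(unique(pairs$group[is.na(pairs$distance)]), collapse = ", "))
  summ <- do.call(rbind, lapply(split(pairs, pairs$replicate_type), function(p)
    data.frame(type = p$replicate_type[1], n_pairs = nrow(p),
               mean = mean(p$distance), max = max(p$distance))))
  summ <- rbind(summ, data.frame(type = "pooled", n_pairs = nrow(pairs),
                                 mean = mean(pairs$distance),
                                 max = max(pairs$distance)))
  rownames(summ) <- NULL
  structure(list(pairs = pairs, summary = summ),
            class = "replicate_distances")
}

#' @export
print.replicate_distances <- function(x, ...) {
  cat("Replicate pair distances (", nrow(x$pairs), " pairs)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
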