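#' Calibrate the duplicate-calling threshold from replicate distances
#'
#' The threshold is the smallest integer multiple of `granularity` strictly
#' greater than the maximum replicate-pair distance, so every known
#' replicate pair falls strictly below it. A maximum of 0.02112 with the
#' default 0.001 grid yields 0.022.
#'
#' @param rep_distances numeric vector of replicate-pair distances, or a
#'   `replicate_distances` object.
#' @param granularity grid step for the threshold (default 0.001).
#' @return the threshold (scalar).
#' @export
calibrate_threshold <- function(rep_distances, granularity = 0.001) {
  if (inherits(rep_distances, "replicate_distances"))
    rep_distances <- rep_distances$pairs$distance
  if (!length(rep_distances)) stop("no replicate distances to calibrate from")
  if (anyNA(rep_distances)) stop("replicate distances contain NA")
  m <- max(rep_distances)
  # +1e-6 grid tolerance: a maximum sitting exactly on the grid steps up to
  # the next multiple (strictly-greater rule)
  granularity * (floor(m / granularity + 1e-6) + 1)
}

#' Partition samples into clone groups by single linkage
#'
#' Two samples are duplicates when their distance is strictly below the
#' threshold; clone groups are the connected components of the resulting
#' duplicate graph (single linkage, so merging is transitive). This is the
#' package's core estimator: the returned `clone_partition` is the set of
#' putative unique clones (multilocus genotypes) in the collection.
#'
#' @param D complete distance matrix (no `NA` off-diagonal entries).
#' @param threshold duplicate-calling distance threshold, typically from
#'   [calibrate_threshold()].
#' @param G optional genotype matrix; when given, group representatives
#'   (fewest missing calls, ties broken by lexicographically smallest id)
#'   are selected immediately.
#' @return object of class `clone_partition`: list with `threshold`,
#'   `membership` (named integer vector sample -> group), `groups` (list of
#'   character vectors), `n_groups`, `representatives` (or `NULL`), and the
#'   input `distance` matrix (used by `plot`).
#' @seealso [select_representatives()], [match_references()],
#'   [zone_summary()], [evaluate_recovery()]
#' @export
call_clones <- function(D, threshold, G = NULL) {
  und <- which(upper.tri(D) & is.na(D), arr.ind = TRUE)
  if (nrow(und))
    stop("undefined distance for pair(s): ",
         paste(paste(rownames(D)[und[, 1]], rownames(D)[und[, 2]], sep = " / "),
               collapse = ", "))
  adj <- D < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  membership <- as.integer(comp$membership)
  names(membership) <- rownames(D)
  groups <- split(names(membership), membership)
  names(groups) <- NULL
  stopifnot(sum(lengths(groups)) == nrow(D),
            !anyDuplicated(unlist(groups)))
  obj <- structure(list(threshold = threshold,
                        membership = membership,
                        groups = groups,
                        n_groups = comp$no,
                        representatives = NULL,
                        distance = D),
                   class = "clone_partition")
  if (!is.null(G)) obj <- select_representatives(obj, G)
  obj
}

#' Select one representative sample per clone group
#'
#' The representative is the member with the fewest missing genotype calls;
#' ties break to the lexicographically smallest sample id.
#'
#' @param partition a `clone_partition`.
#' @param G genotype matrix covering the partitioned samples.
#' @return the partition with `representatives` filled (character vector,
#'   one id per group).
#' @export
select_representatives <- function(partition, G) {
  partition$representatives <- vapply(partition$groups, select_representative,
                                      character(1), G = G)
  partition
}

#' @rdname select_representatives
#' @param group character vector of sample ids forming one group.
#' @export
select_representative <- function(group, G) {
  if (!length(group)) stop("empty group")
  nmiss <- rowSums(is.na(G[group, , drop = FALSE]))
  group[order(nmiss, group)][1]
}

#' Identify clone groups through reference panels
#'
#' A group is *identified* when it contains at least one reference landrace;
#' its identity labels are the reference names. Groups holding two or more
#' distinct reference landraces are flagged as reference synonym sets.
#' Groups where a collected sample is identical to a reference breeding line
#' are flagged for exclusion from landrace-uniqueness accounting.
#'
#' @param partition a `clone_partition`.
#' @param meta sample metadata.
#' @return object of class `reference_match`: list with `groups`
#'   (data.frame: group, size, n_collected, identity, identified,
#'   synonym_refs, breeding_match) and `counts` (n_groups_identified,
#'   n_collected_identified, n_reference_synonym_groups,
#'   n_breeding_matched_groups).
#' @export
match_references <- function(partition, meta) {
  meta <- meta[match(names(partition$membership), meta$sample_id), ]
  if (anyNA(meta$sample_id))
    stop("metadata missing for sample(s): ",
         paste(setdiff(names(partition$membership), meta$sample_id), collapse = ", "))
  per_group <- lapply(seq_along(partition$groups), function(k) {
    ids <- partition$groups[[k]]
    m <- meta[meta$sample_id %in% ids, ]
    refs <- unique(m$given_name[m$category == "reference_landrace"])
    n_coll <- sum(m$category == "collected")
    data.frame(group = k, size = length(ids), n_collected = n_coll,
               identity = if (length(refs)) paste(sort(refs), collapse = "/") else NA_character_,
               identified = length(refs) > 0L,
               synonym_refs = length(refs) >= 2L,
               breeding_match = n_coll > 0L && any(m$category == "reference_breeding"),
               stringsAsFactors = FALSE)
  })
  gdf <- do.call(rbind, per_group)
  counts <- list(
    n_groups_identified = sum(gdf$identified),
    n_collected_identified = sum(gdf$n_collected[gdf$identified & gdf$n_collected > 0]),
    n_reference_synonym_groups = sum(gdf$synonym_refs),
    n_breeding_matched_groups = sum(gdf$breeding_match))
  structure(list(groups = gdf, counts = counts), class = "reference_match")
}

#' @export
print.reference_match <- function(x, ...) {
  cat(sprintf("Reference matching: %d group(s) identified (%d collected samples), %d reference synonym set(s), %d group(s) matching breeding lines\n",
              x$counts$n_groups_identified, x$counts$n_collected_identified,
              x$counts$n_reference_synonym_groups,
              x$counts$n_breeding_matched_groups))
  invisible(x)
}

#' Zone-level uniqueness and sharing accounting
#'
#' A unique landrace in a zone is any clone group with at least one
#' collected member in that zone; a landrace found in several zones is
#' counted once in each. Per zone the table reports the number of collected
#' entries, how many of its landraces were collected more than once
#' (anywhere) vs exactly once, the unique count, the number shared with
#' other zones and the shared percentage. Groups whose collected members
#' match a reference breeding line are excluded from landrace accounting
#' (they are misfiled breeding material, not landraces) when
#' `drop_breeding_matches` is `TRUE`.
#'
#' @param partition a `clone_partition`.
#' @param meta sample metadata; every collected sample needs a zone.
#' @param drop_breeding_matches exclude breeding-line-matching groups.
#' @return object of class `zone_summary`: list with `zones` (data.frame)
#'   and `global` (n_unique_excl_references, n_unique_incl_references,
#'   n_collected_entries, n_collected_more_than_once).
#' @export
zone_summary <- function(partition, meta, drop_breeding_matches = TRUE) {
  meta <- meta[meta$sample_id %in% names(partition$membership), ]
  if (any(meta$category == "collected" & is.na(meta$zone)))
    stop("collected sample(s) without zone")
  memb <- partition$membership
  ref <- match_references(partition, meta)
  excluded <- which(ref$groups$breeding_match)
  groups <- seq_along(partition$groups)
  if (drop_breeding_matches) groups <- setdiff(groups, excluded)

  coll <- meta[meta$category == "collected", ]
  coll$group <- memb[coll$sample_id]
  coll <- coll[coll$group %in% groups, ]
  gz <- split(coll$zone, coll$group)            # zones of collected members
  gn <- lengths(split(coll$sample_id, coll$group))  # collected copies per group

  zones <- sort(unique(coll$zone))
  per_zone <- lapply(zones, function(z) {
    in_zone <- names(gz)[vapply(gz, function(v) z %in% v, logical(1))]
    n_unique <- length(in_zone)
    multi <- sum(gn[in_zone] > 1L)
    shared <- sum(vapply(gz[in_zone], function(v) length(unique(v)) > 1L, logical(1)))
    data.frame(zone = z,
               n_entries = sum(coll$zone == z),
               n_collected_more_than_once = multi,
               n_collected_once = n_unique - multi,
               n_unique = n_unique,
               n_shared_across_zones = shared,
               pct_shared = if (n_unique > 0) 100 * shared / n_unique else 0,
               stringsAsFactors = FALSE)
  })
  zdf <- do.call(rbind, per_zone)

  has_coll <- vapply(partition$groups[groups],
                     function(ids) any(ids %in% coll$sample_id), logical(1))
  ref_only <- vapply(groups, function(k) {
    ids <- partition$groups[[k]]
    m <- meta[meta$sample_id %in% ids, ]
    !any(m$category == "collected") && any(m$category == "reference_landrace")
  }, logical(1))
  global <- list(
    n_unique_excl_references = sum(has_coll),
    n_unique_incl_references = sum(has_coll) + sum(ref_only),
    n_collected_entries = nrow(coll),
    n_collected_more_than_once = sum(gn > 1L))
  structure(list(zones = zdf, global = global,
                 excluded_breeding_groups = excluded),
            class = "zone_summary")
}

#' @export
print.zone_summary <- function(x, ...) {
  cat("Unique landraces per zone:\n")
  print(x$zones, row.names = FALSE, digits = 3)
  cat(sprintf("Unique landraces: %d excluding references, %d including reference-only groups\n",
              x$global$n_unique_excl_references, x$global$n_unique_incl_references))
  invisible(x)
}

#' @export
print.clone_partition <- function(x, ...) {
  cat(sprintf("Clone partition: %d samples in %d groups (threshold %g)\n",
              length(x$membership), x$n_groups, x$threshold))
  sizes <- table(lengths(x$groups))
  cat("Group sizes: ", paste(sprintf("%sx size %s", sizes, names(sizes)),
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.clone_partition <- function(object, ...) {
  sizes <- lengths(object$groups)
  out <- list(threshold = object$threshold,
              n_samples = length(object$membership),
              n_groups = object$n_groups,
              n_singletons = sum(sizes == 1L),
              n_duplicated = sum(sizes > 1L),
              max_group_size = max(sizes),
              representatives = object$representatives)
  class(out) <- "summary.clone_partition"
  out
}

#' @export
print.summary.clone_partition <- function(x, ...) {
  cat(sprintf("Clone partition at threshold %g\n", x$threshold))
  cat(sprintf("  %d samples -> %d clone groups (%d singletons, %d duplicated, largest %d)\n",
              x$n_samples, x$n_groups, x$n_singletons, x$n_duplicated,
              x$max_group_size))
  if (!is.null(x$representatives))
    cat("  representatives selected (fewest missing calls)\n")
  invisible(x)
}

#' Plot a clone partition as a dendrogram with the calling threshold
#'
#' Average-linkage dendrogram of the distance matrix with a horizontal line
#' at the duplicate threshold; cherries below the line are called
#' duplicates.
#'
#' @param x a `clone_partition`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.clone_partition <- function(x, ...) {
  hc <- stats::hclust(stats::as.dist(x$distance), method = "average")
  graphics::plot(hc, labels = FALSE, main = "Clone calling", sub = "",
                 xlab = "", ylab = "Hamming distance", ...)
  graphics::abline(h = x$threshold, col = "red", lty = 2)
  invisible(x)
}
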