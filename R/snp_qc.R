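#' Per-locus missingness, allele frequency and MAF
#'
#' Allele frequency is computed on non-missing calls, `p = sum(g) / (2 *
#' n_called)`; MAF is `min(p, 1 - p)`.
#'
#' @param G genotype matrix (samples x loci).
#' @return data.frame with one row per locus: `missingness`, `p`, `maf`,
#'   `n_called`.
#' @export
locus_stats <- function(G) {
  n_called <- colSums(!is.na(G))
  p <- ifelse(n_called > 0, colSums(G, na.rm = TRUE) / (2 * n_called), NA_real_)
  data.frame(locus_id = colnames(G),
             missingness = colMeans(is.na(G)),
             p = p,
             maf = pmin(p, 1 - p),
             n_called = n_called,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter SNPs on missingness, monomorphy and minor allele frequency
#'
#' Loci are retained when their missing-call fraction is at most
#' `max_missing`, they are polymorphic, and MAF is at least `min_maf`. A
#' locus is monomorphic when all non-missing dosages are identical *and*
#' homozygous (all 0 or all 2); an all-heterozygote locus carries both
#' alleles and is kept. Each removed locus is attributed to the first failing
#' filter in the order missing, monomorphic, MAF.
#'
#' @param G genotype matrix.
#' @param max_missing maximum per-locus missing fraction (default 0.05).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (a `qc_report`).
#' @export
filter_snps <- function(G, max_missing = 0.05, min_maf = 0.05) {
  st <- locus_stats(G)
  fail_missing <- st$missingness > max_missing
  mono <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j][!is.na(G[, j])]
    length(g) == 0L || (length(unique(g)) == 1L && g[1] %in% c(0L, 2L))
  }, logical(1))
  fail_mono <- !fail_missing & mono
  fail_maf <- !fail_missing & !fail_mono & (is.na(st$maf) | st$maf < min_maf)
  keep <- !(fail_missing | fail_mono | fail_maf)
  if (!any(keep)) warning("all loci removed by SNP filters")
  report <- structure(list(
    stage = "snp",
    n_snps_in = ncol(G),
    n_removed_missing = sum(fail_missing),
    n_removed_monomorphic = sum(fail_mono),
    n_removed_maf = sum(fail_maf),
    n_snps_out = sum(keep),
    n_samples_in = nrow(G), n_samples_removed = 0L, n_samples_out = nrow(G),
    locus_stats = st,
    params = list(max_missing = max_missing, min_maf = min_maf)
  ), class = "qc_report")
  list(genotypes = G[, keep, drop = FALSE], report = report)
}

#' Filter samples on missing-call fraction
#'
#' Removes samples whose fraction of missing calls over the current loci
#' exceeds `max_missing`. Intended to run after [filter_snps()] (the
#' [apply_qc()] pipeline order), but usable on its own.
#'
#' @param G genotype matrix.
#' @param max_missing maximum per-sample missing fraction (default 0.055).
#' @return list with `genotypes` and `report`.
#' @export
filter_samples <- function(G, max_missing = 0.055) {
  frac <- rowMeans(is.na(G))
  keep <- frac <= max_missing
  report <- structure(list(
    stage = "sample",
    n_snps_in = ncol(G), n_removed_missing = 0L, n_removed_monomorphic = 0L,
    n_removed_maf = 0L, n_snps_out = ncol(G),
    n_samples_in = nrow(G),
    n_samples_removed = sum(!keep),
    n_samples_out = sum(keep),
    sample_missingness = frac,
    removed_samples = rownames(G)[!keep],
    params = list(max_missing = max_missing)
  ), class = "qc_report")
  list(genotypes = G[keep, , drop = FALSE], report = report)
}

#' Full QC pipeline: SNP filters then sample filter
#'
#' @inheritParams filter_snps
#' @param max_sample_missing maximum per-sample missing fraction.
#' @return list with `genotypes`, `snp_report`, `sample_report`.
#' @export
apply_qc <- function(G, max_missing = 0.05, min_maf = 0.05,
                     max_sample_missing = 0.055) {
  s1 <- filter_snps(G, max_missing = max_missing, min_maf = min_maf)
  s2 <- filter_samples(s1$genotypes, max_missing = max_sample_missing)
  list(genotypes = s2$genotypes, snp_report = s1$report,
       sample_report = s2$report)
}

#' @export
print.qc_report <- function(x, ...) {
  if (x$stage == "snp") {
    cat(sprintf("SNP QC: %d loci in; removed %d high-missing, %d monomorphic, %d low-MAF; %d retained\n",
                x$n_snps_in, x$n_removed_missing, x$n_removed_monomorphic,
                x$n_removed_maf, x$n_snps_out))
  } else {
    cat(sprintf("Sample QC: %d samples in; removed %d (> %.3g%% missing); %d retained\n",
                x$n_samples_in, x$n_samples_removed,
                100 * x$params$max_missing, x$n_samples_out))
  }
  invisible(x)
}
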