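#' clonecall: germplasm deduplication and diversity analysis from SNP dosages
#'
#' Tools for identifying unique clones in a clonally propagated germplasm
#' collection genotyped at biallelic SNPs, and for summarising the genetic
#' diversity and geographic sharing of the resulting unique set. The core
#' estimator is a clone partition obtained by single-linkage merging of
#' samples whose pairwise Hamming (allele-sharing) distance falls below a
#' threshold calibrated on replicate pairs; see [call_clones()].
#'
#' @keywords internal
#' @aliases clonecall-package
"_PACKAGE"

ZONES <- c("Central", "Coastal", "Lake", "Northern", "SouthernHighlands",
           "Western", "Zanzibar")
CATEGORIES <- c("collected", "reference_landrace", "reference_breeding")

#' Construct and validate a genotype dosage matrix
#'
#' A genotype matrix is a plain integer matrix of allele dosages (counts of
#' the alternate allele: 0, 1 or 2, `NA` for a missing call) with unique
#' sample ids as row names and unique locus ids as column names. All
#' downstream operations accept the plain matrix; this constructor enforces
#' the invariants once.
#'
#' @param dosage numeric matrix of dosages in \{0, 1, 2, NA\}.
#' @param sample_ids,locus_ids optional character vectors overriding the
#'   dimnames of `dosage`.
#' @return the validated integer matrix with dimnames set.
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            locus_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids) || is.null(locus_ids))
    stop("genotype matrix needs sample and locus ids")
  if (length(sample_ids) != nrow(dosage) || length(locus_ids) != ncol(dosage))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  bad <- which(!is.na(dosage) & !(dosage %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(dosage)) + 1
    j <- ((bad[1] - 1) %/% nrow(dosage)) + 1
    stop(sprintf("invalid dosage %s at sample '%s', locus '%s' (must be 0, 1, 2 or missing)",
                 format(dosage[bad[1]]), sample_ids[i], locus_ids[j]))
  }
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(sample_ids, locus_ids)
  dosage
}

#' Read an allele-dosage matrix from CSV
#'
#' The file must carry one header row and one leading id column. Missing
#' calls may be encoded as empty cells, `NA` or `-9` (all accepted on read;
#' [write_dosage_matrix()] writes `NA`). Orientation is never guessed:
#' `dialect` states whether rows or columns are samples.
#'
#' @param path CSV file path.
#' @param dialect `"samples_as_rows"` (default) or `"samples_as_cols"`.
#' @param missing_codes strings coerced to missing.
#' @return a validated genotype matrix (samples in rows).
#' @export
read_dosage_matrix <- function(path,
                               dialect = c("samples_as_rows", "samples_as_cols"),
                               missing_codes = c("", "NA", "-9")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = missing_codes)
  if (ncol(raw) < 2) stop("dosage CSV needs an id column plus at least one data column")
  ids <- raw[[1]]
  x <- suppressWarnings(vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(raw)[-1]))
  nonnum <- which(is.na(x) & !is.na(as.matrix(raw[-1])))
  if (length(nonnum)) {
    i <- ((nonnum[1] - 1) %% nrow(x)) + 1
    j <- ((nonnum[1] - 1) %/% nrow(x)) + 1
    stop(sprintf("non-numeric dosage '%s' at row id '%s', column '%s'",
                 as.matrix(raw[-1])[nonnum[1]], ids[i], colnames(x)[j]))
  }
  rownames(x) <- ids
  if (dialect == "samples_as_cols") x <- t(x)
  genotype_matrix(x)
}

#' Write an allele-dosage matrix to CSV
#'
#' @param G genotype matrix.
#' @param path output path.
#' @param dialect orientation to write, as in [read_dosage_matrix()].
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(G, path,
                                dialect = c("samples_as_rows", "samples_as_cols")) {
  dialect <- match.arg(dialect)
  out <- if (dialect == "samples_as_cols") t(G) else G
  df <- data.frame(id = rownames(out), out, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Construct and validate a square distance matrix
#'
#' @param d square numeric matrix of distances in \[0, 1\] (NA allowed for
#'   pairs with no shared loci), zero diagonal.
#' @param ids optional ids overriding dimnames.
#' @param tol maximum tolerated asymmetry; the matrix is symmetrised by
#'   averaging when within tolerance, rejected otherwise.
#' @return validated symmetric matrix with dimnames.
#' @export
distance_matrix <- function(d, ids = rownames(d), tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(ids)) stop("distance matrix needs ids")
  if (anyDuplicated(ids)) stop("duplicate ids in distance matrix")
  asym <- abs(d - t(d))
  if (any(asym > tol, na.rm = TRUE)) {
    w <- which(asym == max(asym, na.rm = TRUE), arr.ind = TRUE)[1, ]
    stop(sprintf("distance matrix asymmetric beyond tolerance at (%s, %s): %g vs %g",
                 ids[w[1]], ids[w[2]], d[w[1], w[2]], d[w[2], w[1]]))
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (any(d < -tol | d > 1 + tol, na.rm = TRUE))
    stop("distances must lie in [0, 1]")
  d[d < 0] <- 0
  d[d > 1] <- 1
  dimnames(d) <- list(ids, ids)
  d
}

#' Read / write a square pairwise distance matrix (CSV)
#'
#' The CSV has a header row and a leading id column holding the same ids in
#' the same order. Symmetry is enforced on read (tolerance `tol`).
#'
#' @param path CSV path.
#' @param tol asymmetry tolerance.
#' @return validated distance matrix.
#' @export
read_distance_matrix <- function(path, tol = 1e-8) {
  raw <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(raw[[1]])
  d <- as.matrix(raw[-1])
  if (nrow(d) != ncol(d)) stop("distance CSV is not square")
  if (!identical(ids, colnames(d)))
    stop("distance CSV header ids and first-column ids differ")
  rownames(d) <- ids
  distance_matrix(d, tol = tol)
}

#' @rdname read_distance_matrix
#' @param D distance matrix to write.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(id = rownames(D), D, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate sample metadata
#'
#' @param df data.frame with columns `sample_id`, `given_name`, `zone`,
#'   `category`, `replicate_group`, `replicate_type`. `zone` must be one of
#'   the seven collection zones for collected samples and `NA` for reference
#'   panels; `replicate_type` (`"biological"` / `"technical"`) must be present
#'   exactly when `replicate_group` is.
#' @return validated data.frame.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "given_name", "zone", "category",
            "replicate_group", "replicate_type")
  miss <- setdiff(need, names(df))
  for (m in miss) df[[m]] <- NA_character_
  df <- df[need]
  for (m in need) df[[m]] <- as.character(df[[m]])
  df$zone[!is.na(df$zone) & df$zone == ""] <- NA_character_
  df$replicate_group[!is.na(df$replicate_group) & df$replicate_group == ""] <- NA_character_
  df$replicate_type[!is.na(df$replicate_type) & df$replicate_type == ""] <- NA_character_
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad_zone <- !is.na(df$zone) & !(df$zone %in% ZONES)
  if (any(bad_zone))
    stop("unknown zone(s): ", paste(unique(df$zone[bad_zone]), collapse = ", "))
  if (!all(df$category %in% CATEGORIES))
    stop("category must be one of: ", paste(CATEGORIES, collapse = ", "))
  if (any(df$category == "collected" & is.na(df$zone)))
    stop("collected samples must have a zone")
  if (any(is.na(df$replicate_group) != is.na(df$replicate_type)))
    stop("replicate_type must be present exactly when replicate_group is")
  bad_rt <- !is.na(df$replicate_type) & !(df$replicate_type %in% c("biological", "technical"))
  if (any(bad_rt)) stop("replicate_type must be 'biological' or 'technical'")
  rownames(df) <- NULL
  df
}

#' Read / write sample metadata (TSV)
#' @param path TSV path.
#' @return validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(utils::read.delim(path, colClasses = "character",
                                    na.strings = c("", "NA")))
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a key-informant survey table (TSV)
#' @param path TSV path.
#' @return data.frame with trait scores as integers.
#' @export
read_survey_table <- function(path) {
  df <- utils::read.delim(path, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  for (tr in intersect(SURVEY_TRAITS, names(df))) df[[tr]] <- as.integer(df[[tr]])
  df
}

#' @rdname read_survey_table
#' @param survey survey data.frame.
#' @export
write_survey_table <- function(survey, path) {
  utils::write.table(survey, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Collector-number prefix map for the Tanzanian zones
#'
#' Collection missions assigned collector numbers whose alphabetic prefix
#' (and, for some prefixes, numeric range) identifies the geographic zone:
#' KS 1-42 and 65-75 Coastal, KS 43-64 Northern, KSF 1-62 Lake, KSF 63-92
#' Western, KSF 93-103 Central, EPM Central, BKP Southern Highlands, Horti
#' Northern, SMS Zanzibar.
#'
#' @return data.frame with columns `prefix`, `from`, `to`, `zone`; `from`/`to`
#'   are `NA` when the prefix alone decides.
#' @export
tanzania_prefix_map <- function() {
  data.frame(
    prefix = c("KS", "KS", "KS", "KSF", "KSF", "KSF", "EPM", "BKP", "Horti", "SMS"),
    from   = c(1, 65, 43, 1, 63, 93, NA, NA, NA, NA),
    to     = c(42, 75, 64, 62, 92, 103, NA, NA, NA, NA),
    zone   = c("Coastal", "Coastal", "Northern", "Lake", "Western", "Central",
               "Central", "SouthernHighlands", "Northern", "Zanzibar"),
    stringsAsFactors = FALSE
  )
}

#' Assign collection zones from collector-number prefixes
#'
#' The numeric suffix is the longest trailing digit run, so zero-padded and
#' unpadded forms are equal (`"KS05"` matches the same rule as `"KS5"`).
#' Prefix comparison is case-insensitive and ignores separating `_`/`-`.
#' Longer prefixes win (so `"KSF70"` matches `KSF`, not `KS`).
#'
#' @param sample_ids character vector of collector numbers.
#' @param prefix_map rule table as returned by [tanzania_prefix_map()].
#' @return character vector of zones, named by `sample_ids`.
#' @export
assign_zones_by_prefix <- function(sample_ids, prefix_map = tanzania_prefix_map()) {
  pm <- prefix_map[order(-nchar(prefix_map$prefix)), , drop = FALSE]
  num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1",
                                         sample_ids, perl = TRUE)))
  num[!grepl("[0-9]$", sample_ids)] <- NA_integer_
  stem <- toupper(gsub("[-_ ]", "", sub("[0-9]+$", "", sample_ids)))
  zones <- rep(NA_character_, length(sample_ids))
  for (k in seq_len(nrow(pm))) {
    hit <- is.na(zones) & stem == toupper(pm$prefix[k]) &
      (is.na(pm$from[k]) | (!is.na(num) & num >= pm$from[k] & num <= pm$to[k]))
    zones[hit] <- pm$zone[k]
  }
  if (anyNA(zones))
    stop("no prefix rule matches sample id(s): ",
         paste(sample_ids[is.na(zones)], collapse = ", "))
  names(zones) <- sample_ids
  zones
}
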