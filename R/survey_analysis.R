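SURVEY_TRAITS <- c("storability", "maturity", "drought", "pest_disease",
                   "cooking_quality", "taste", "processing_quality",
                   "market_demand", "yield")

# free-text use vocabulary -> controlled terms
USE_VOCAB <- c(
  "fresh_consumption" = "fresh_consumption",
  "household food roots" = "fresh_consumption",
  "fresh roots" = "fresh_consumption",
  "fresh" = "fresh_consumption",
  "flour_processing" = "flour_processing",
  "household food processed" = "flour_processing",
  "flour" = "flour_processing",
  "processing" = "flour_processing"
)

normalize_use <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- unname(USE_VOCAB[x])
  out[is.na(out) & !is.na(x) & x != ""] <- x[is.na(out) & !is.na(x) & x != ""]
  out
}

#' Classify a landrace's use from its cited uses
#'
#' A landrace whose primary, secondary or tertiary uses include *both* fresh
#' consumption and processing into flour is dual purpose; fresh consumption
#' alone is `fresh`; flour alone is `flour`; neither is `unknown`. The
#' classification is order-invariant over the use list. Free-text use terms
#' (e.g. "household food roots") are normalised first.
#'
#' @param primary,secondary,tertiary character vectors of cited uses
#'   (vectorised over landraces; `NA` / empty allowed).
#' @return factor with levels `fresh`, `dual`, `flour`, `unknown`.
#' @export
classify_use <- function(primary, secondary = NA, tertiary = NA) {
  n <- max(length(primary), length(secondary), length(tertiary))
  u <- cbind(rep_len(normalize_use(primary), n),
             rep_len(normalize_use(secondary), n),
             rep_len(normalize_use(tertiary), n))
  fresh <- rowSums(u == "fresh_consumption", na.rm = TRUE) > 0
  flour <- rowSums(u == "flour_processing", na.rm = TRUE) > 0
  cls <- ifelse(fresh & flour, "dual",
                ifelse(fresh, "fresh", ifelse(flour, "flour", "unknown")))
  factor(cls, levels = c("fresh", "dual", "flour", "unknown"))
}

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Distribution of landrace use classes
#'
#' @param survey survey data.frame with columns `use_primary`,
#'   `use_secondary`, `use_tertiary`.
#' @return data.frame with class, count, percentage (raw) and rounded
#'   percentage (half-up, integer, the convention of field reports).
#' @export
use_distribution <- function(survey) {
  if (!nrow(survey)) stop("empty survey table")
  cls <- classify_use(survey$use_primary, survey$use_secondary,
                      survey$use_tertiary)
  cnt <- table(cls)
  data.frame(class = names(cnt),
             count = as.integer(cnt),
             pct = 100 * as.integer(cnt) / nrow(survey),
             pct_rounded = round_half_up(100 * as.integer(cnt) / nrow(survey)),
             stringsAsFactors = FALSE)
}

#' Distribution of an ordinal trait score
#'
#' Scores run 0-5 with 0 meaning "don't know".
#'
#' @param survey survey data.frame.
#' @param trait one of the trait column names (see `survey_traits()`).
#' @return named integer vector of counts for scores 0-5 (sums to the table
#'   size).
#' @export
score_distribution <- function(survey, trait) {
  if (!nrow(survey)) stop("empty survey table")
  if (!trait %in% names(survey)) stop("unknown trait: ", trait)
  s <- survey[[trait]]
  if (any(!is.na(s) & !(s %in% 0:5))) stop("scores must be integers 0-5")
  table(factor(s, levels = 0:5))
}

#' Trait column names of the survey table
#' @return character vector of the nine ordinal trait names.
#' @export
survey_traits <- function() SURVEY_TRAITS

#' Pearson correlation between two ordinal trait scores
#'
#' Computed on pairwise-complete records. Under the default policy a score
#' of 0 ("don't know") is treated as missing; `dont_know = "include"` keeps
#' the zeros as numeric values.
#'
#' @param survey survey data.frame.
#' @param trait_a,trait_b trait column names.
#' @param dont_know `"exclude"` (default) or `"include"`.
#' @return list with `r`, `r_squared`, `n` (complete pairs used).
#' @export
trait_correlation <- function(survey, trait_a, trait_b,
                              dont_know = c("exclude", "include")) {
  dont_know <- match.arg(dont_know)
  for (tr in c(trait_a, trait_b))
    if (!tr %in% names(survey)) stop("unknown trait: ", tr)
  x <- as.numeric(survey[[trait_a]])
  y <- as.numeric(survey[[trait_b]])
  if (dont_know == "exclude") {
    x[x == 0] <- NA
    y[y == 0] <- NA
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 complete score pairs")
  r <- stats::cor(x[ok], y[ok])
  list(r = r, r_squared = r * r, n = sum(ok))
}

#' Respondent profile summary
#'
#' Percentages of respondents by gender, education, land-access band (<1,
#' 1-4.9, 5-9.9, >=10 acres, with "not stated" as its own category), years
#' growing cassava (<5, 5-19, 20-49, >=50 years, plus "not stated"), seed
#' source and growing trend. If the table carries a `respondent_id` column,
#' rows are deduplicated to one per respondent first (the survey lists one
#' row per landrace and one respondent describes several).
#'
#' @param survey survey data.frame.
#' @return object of class `respondent_profile`: list of named percentage
#'   vectors plus `n_respondents`.
#' @export
profile_summary <- function(survey) {
  if (!nrow(survey)) stop("empty survey table")
  df <- survey
  if ("respondent_id" %in% names(df))
    df <- df[!duplicated(df$respondent_id), , drop = FALSE]
  n <- nrow(df)
  pct_table <- function(x, levels = NULL) {
    x <- as.character(x)
    if (is.null(levels)) levels <- sort(unique(x[!is.na(x)]))
    cnt <- table(factor(x, levels = levels))
    stats::setNames(100 * as.vector(cnt) / sum(cnt), levels)
  }
  band <- function(x, breaks, labels) {
    b <- as.character(cut(x, breaks = breaks, labels = labels, right = FALSE))
    b[is.na(x)] <- "not stated"
    factor(b, levels = c(labels, "not stated"))
  }
  out <- list(n_respondents = n)
  if ("gender" %in% names(df)) out$gender <- pct_table(df$gender)
  if ("education" %in% names(df))
    out$education <- pct_table(df$education,
                               c("none", "primary", "secondary", "tertiary"))
  if ("land_acres" %in% names(df)) {
    b <- band(df$land_acres, c(-Inf, 1, 5, 10, Inf),
              c("<1", "1-4.9", "5-9.9", ">=10"))
    out$land <- 100 * as.vector(table(b)) / n
    names(out$land) <- levels(b)
  }
  if ("years_growing" %in% names(df)) {
    b <- band(df$years_growing, c(-Inf, 5, 20, 50, Inf),
              c("<5", "5-19", "20-49", ">=50"))
    out$years_growing <- 100 * as.vector(table(b)) / n
    names(out$years_growing) <- levels(b)
  }
  if ("seed_source" %in% names(df)) out$seed_source <- pct_table(df$seed_source)
  if ("growing_trend" %in% names(df)) out$growing_trend <- pct_table(df$growing_trend)
  structure(out, class = "respondent_profile")
}

#' @export
print.respondent_profile <- function(x, ...) {
  cat("Respondent profile (n = ", x$n_respondents, ")\n", sep = "")
  for (nm in setdiff(names(x), "n_respondents")) {
    cat("  ", nm, ": ",
        paste(sprintf("%s %.0f%%", names(x[[nm]]), x[[nm]]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
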