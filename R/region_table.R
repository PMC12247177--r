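#' Areal count tables for regional health-indicator analysis
#'
#' A `region_table` is a validated data frame with one row per areal unit
#' (country, province, lattice cell, ...) carrying a binomial outcome as a
#' numerator/denominator pair: `sample` women surveyed in the unit and
#' `events` women meeting the indicator (here, the recommended number of
#' antenatal-care contacts). Optional columns: `country`, `region_label`
#' (sub-regional grouping, e.g. West/East/Southern/Central), `survey_year`,
#' `n_provinces`, and any number of numeric covariate columns holding
#' community-level percentages in [0, 100].
#'
#' @param x data frame with at least `unit_id`, `sample`, `events`.
#' @param covariates character vector naming covariate columns; by default
#'   every numeric column other than the reserved ones is treated as a
#'   covariate.
#' @return `x` with class `region_table` and attribute `covariates`.
#' @examples
#' region_table(data.frame(unit_id = c("a", "b"),
#'                         sample = c(100L, 200L),
#'                         events = c(40L, 10L)))
#' @export
region_table <- function(x, covariates = NULL) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("unit_id", "sample", "events")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0L) stop("region table has no rows")
  x$unit_id <- as.character(x$unit_id)
  if (anyDuplicated(x$unit_id))
    stop("duplicate unit_id: ",
         paste(unique(x$unit_id[duplicated(x$unit_id)]), collapse = ", "))
  for (col in c("sample", "events")) {
    if (!is.numeric(x[[col]])) stop("column '", col, "' must be numeric")
    if (any(is.na(x[[col]])) || any(x[[col]] < 0))
      stop("column '", col, "' must be non-negative and complete")
  }
  bad <- which(x$events > x$sample)
  if (length(bad) > 0L)
    stop("events exceed sample in row(s): ",
         paste(x$unit_id[bad], collapse = ", "))
  if ("survey_year" %in% names(x) && !all(is.na(x$survey_year))) {
    yr <- x$survey_year[!is.na(x$survey_year)]
    if (any(yr != round(yr)) || any(yr < 1980) || any(yr > 2100))
      stop("survey_year values must be integer years in [1980, 2100]")
  }
  reserved <- c(required, "country", "region_label", "survey_year",
                "n_provinces", "y", "proportion")
  if (is.null(covariates)) {
    covariates <- names(x)[vapply(x, is.numeric, logical(1L))]
    covariates <- setdiff(covariates, reserved)
  } else {
    missing_cov <- setdiff(covariates, names(x))
    if (length(missing_cov) > 0L)
      stop("covariate column(s) not found: ",
           paste(missing_cov, collapse = ", "))
  }
  for (cov in covariates) {
    v <- x[[cov]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop("covariate '", cov, "' has values outside [0, 100]")
  }
  attr(x, "covariates") <- covariates
  class(x) <- c("region_table", "data.frame")
  x
}

#' @export
print.region_table <- function(x, ...) {
  cat("region_table:", nrow(x), "areal units,",
      length(attr(x, "covariates")), "covariate column(s)\n")
  NextMethod()
}

#' Country-level antenatal-care utilization fixture
#'
#' The packaged 34-country table of women surveyed (most recent Demographic
#' and Health Survey per country, 2010-2023), the number of first-level
#' administrative provinces, and the count of women meeting the recommended
#' number of ANC contacts (at least 4 for surveys run under the pre-2016 WHO
#' guideline, at least 8 thereafter). The `region_label` column is a
#' package-supplied sub-regional grouping of the 34 countries into West,
#' East, Southern and Central sub-Saharan Africa, chosen so that the four
#' sub-regional pooled proportions match the published regional summaries.
#'
#' @return a [region_table] with 34 rows and columns `unit_id` (ISO3),
#'   `country`, `region_label`, `survey_year`, `sample`, `n_provinces`,
#'   `events`.
#' @examples
#' t2 <- load_table2_fixture()
#' sum(t2$sample)       # 223155 women
#' sum(t2$n_provinces)  # 429 provinces
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_anc.csv", package = "ancspatial",
                      mustWork = TRUE)
  read_region_csv(path)
}

#' Classify a survey year by WHO antenatal-care guideline era
#'
#' Surveys up to 2016 measured the pre-2016 recommendation of at least four
#' ANC contacts; surveys from 2017 onward measured the revised
#' recommendation of at least eight contacts.
#'
#' @param year integer vector of 4-digit survey years.
#' @return character vector, `"Before 2017"` or `"After 2017 (included)"`.
#' @examples
#' assign_survey_era(c(2016, 2017))
#' @export
assign_survey_era <- function(year) {
  if (!is.numeric(year) || any(is.na(year)) || any(year != round(year)))
    stop("year must be integer-valued")
  if (any(year < 1980) || any(year > 2100))
    stop("implausible survey year (outside [1980, 2100])")
  ifelse(year <= 2016, "Before 2017", "After 2017 (included)")
}

#' Sample-size-weighted pooled proportions by group
#'
#' Pools binomial counts within groups and reports the percentage
#' 100 * sum(events) / sum(sample) per group, i.e. each unit contributes
#' with weight proportional to its survey sample. Groups with a zero total
#' sample are dropped.
#'
#' @param table a [region_table].
#' @param grouping one of `"all"` (single pooled figure), `"country"`,
#'   `"region_label"`, `"survey_era"` (from `survey_year` via
#'   [assign_survey_era]).
#' @return data frame with columns `group`, `events`, `sample`,
#'   `proportion` (full precision) and `proportion_2dp` (rounded half-up to
#'   2 decimals, the conventional display precision).
#' @examples
#' weighted_group_proportion(load_table2_fixture(), "all")$proportion_2dp
#' @export
weighted_group_proportion <- function(table,
                                      grouping = c("all", "country",
                                                   "region_label",
                                                   "survey_era")) {
  stopifnot(inherits(table, "region_table"))
  grouping <- match.arg(grouping)
  if (nrow(table) == 0L) stop("no data to aggregate")
  g <- switch(grouping,
    all = rep("all", nrow(table)),
    country = {
      if (!"country" %in% names(table)) stop("column 'country' is absent")
      table$country
    },
    region_label = {
      if (!"region_label" %in% names(table))
        stop("column 'region_label' is absent")
      table$region_label
    },
    survey_era = {
      if (!"survey_year" %in% names(table))
        stop("column 'survey_year' is absent")
      assign_survey_era(table$survey_year)
    })
  ev <- tapply(table$events, g, sum)
  n <- tapply(table$sample, g, sum)
  keep <- n > 0
  ev <- ev[keep]; n <- n[keep]
  p <- 100 * ev / n
  out <- data.frame(group = names(p), events = as.numeric(ev),
                    sample = as.numeric(n), proportion = as.numeric(p),
                    proportion_2dp = round_half_up(as.numeric(p), 2L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

## round() ties to even; printed tables round ties upward.
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Read an areal count table from CSV
#'
#' Expects a UTF-8 CSV with a header row and at least the columns
#' `unit_id`, `sample`, `events`; the optional columns and any covariate
#' percentage columns of [region_table] are carried through. A pre-computed
#' `proportion` column is accepted, but counts take precedence when both
#' are present.
#'
#' @param path path to the CSV file.
#' @return a [region_table].
#' @export
read_region_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       fileEncoding = "UTF-8")
  if (!"events" %in% names(x) && all(c("proportion", "sample") %in% names(x)))
    x$events <- round(x$proportion / 100 * x$sample)
  region_table(x)
}

#' Write an areal count table to CSV
#'
#' @param table a [region_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_csv <- function(table, path) {
  stopifnot(inherits(table, "region_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
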