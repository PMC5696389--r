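## Reading, validating and summarising trawl-survey set records.
##
## One record ("set") is a single deployment of a research trawl: location,
## date, depth, bottom temperature, standardized effort, and the count and
## weight of the target species caught.

REGIONS <- c("NL", "NGSL", "NS", "SGSL", "USA")

survey_required_cols <- c("survey_id", "region", "year", "lat", "lon",
                          "depth", "bottom_temp", "count", "weight",
                          "effort", "stratum")

#' Management-regime period for a survey year
#'
#' The 1978-2013 series is split into three fisheries-management regimes:
#' period 1 (1978-1989, post-EEZ), period 2 (1990-2003, groundfish collapse
#' and moratoria), period 3 (2004-2013, high recruitment).
#'
#' @param year integer vector of survey years.
#' @return integer vector of periods in 1..3.
#' @export
assign_period <- function(year) {
  year <- as.integer(year)
  if (any(is.na(year)) || any(year < 1978L | year > 2013L))
    stop("year outside the 1978-2013 survey series")
  findInterval(year, c(1978L, 1990L, 2004L))
}

#' Read trawl-survey set records from a delimited text file
#'
#' Accepts comma- or tab-delimited text with a header naming the set fields
#' (`survey_id, region, year, lat, lon, depth, bottom_temp, count, weight,
#' effort, stratum`); unknown columns are ignored. Rows with missing
#' latitude, longitude or count are dropped with a per-row warning, as are
#' rows with non-numeric counts, latitudes outside the 40-52.25 degree survey
#' window, or non-positive effort. A `period` column is derived from `year`
#' when absent.
#'
#' @param path path to a delimited text file.
#' @return a `data.frame` of validated survey sets.
#' @export
read_survey_sets <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(survey_required_cols, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  raw <- validate_survey_sets(raw)
  raw
}

## Shared validation for read and generated records.
validate_survey_sets <- function(df) {
  df$count <- suppressWarnings(as.numeric(df$count))
  bad_num <- is.na(df$count)
  bad_pos <- is.na(df$lat) | is.na(df$lon)
  bad_int <- !bad_num & (df$count < 0 | df$count != floor(df$count))
  bad_lat <- !bad_pos & (df$lat < 40 | df$lat > 52.25)
  bad_eff <- is.na(df$effort) | df$effort <= 0
  bad <- bad_num | bad_pos | bad_int | bad_lat | bad_eff
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (rows ",
            paste(utils::head(which(bad), 20L), collapse = ", "),
            if (sum(bad) > 20L) ", ..." else "", "): missing/invalid ",
            "lat/lon/count, lat outside 40-52.25, or effort <= 0")
    df <- df[!bad, , drop = FALSE]
  }
  df$count <- as.integer(df$count)
  df$year <- as.integer(df$year)
  if (is.null(df$period)) df$period <- assign_period(df$year)
  rownames(df) <- NULL
  df
}

#' Write survey sets to delimited text
#'
#' @param records survey-set `data.frame`.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_survey_sets <- function(records, path, sep = ",") {
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Effort standardization for catch counts
#'
#' Surveys differ in tow duration and distance; `effort` is the tow's effort
#' relative to the survey standard. Two standardizations are provided:
#' `"offset"` returns `log(effort)` for use as a log-link offset (keeps the
#' counts integral for a Poisson likelihood, the mode used in model fits);
#' `"multiplier"` returns `count / effort`, a catch-per-standard-tow rate for
#' descriptive summaries only.
#'
#' @param records survey-set `data.frame` (needs `effort`, and `count` for
#'   the multiplier mode).
#' @param mode `"offset"` or `"multiplier"`.
#' @return numeric vector, one value per record.
#' @export
standardize_effort <- function(records, mode = c("offset", "multiplier")) {
  mode <- match.arg(mode)
  if (any(records$effort <= 0)) stop("effort must be positive")
  if (mode == "offset") log(records$effort) else records$count / records$effort
}

#' Remove records inside an exclusion polygon
#'
#' Drops records strictly inside the given closed lon/lat ring (e.g. a river
#' estuary carved out of the model domain); records on the ring boundary are
#' kept. Errors on a self-intersecting ring.
#'
#' @param records survey-set `data.frame` with `lon`, `lat`.
#' @param polygon two-column lon/lat matrix describing a simple closed ring,
#'   or a zero-row matrix for no exclusion.
#' @return list with `records` (kept rows) and `n_removed`.
#' @export
exclude_polygon <- function(records, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) == 0)
    return(list(records = records, n_removed = 0L))
  check_simple_ring(polygon)
  inside <- points_inside_ring(cbind(records$lon, records$lat), polygon,
                               strict = TRUE)
  list(records = records[!inside, , drop = FALSE],
       n_removed = sum(inside))
}

#' Occupancy summary by region
#'
#' For each region: total sets, sets with at least one individual caught,
#' and the percent occupied (half-up to two decimals), plus a `Summary` row
#' aggregating all regions and the first/last survey years. A bracketed
#' (post-exclusion) variant is obtained by calling this on the filtered
#' records.
#'
#' @param records survey-set `data.frame`.
#' @return `data.frame` with columns `region`, `total_sets`,
#'   `sets_with_halibut`, `percent`, `start_year`, `end_year`.
#' @export
occupancy_summary <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(region = character(), total_sets = integer(),
                      sets_with_halibut = integer(), percent = numeric(),
                      start_year = integer(), end_year = integer()))
  regions <- sort(unique(as.character(records$region)))
  rows <- lapply(c(regions, "Summary"), function(r) {
    sub <- if (r == "Summary") records else records[records$region == r, ]
    tot <- nrow(sub)
    pos <- sum(sub$count > 0)
    data.frame(region = r, total_sets = tot, sets_with_halibut = pos,
               percent = round_half_up(100 * pos / tot, 2),
               start_year = min(sub$year), end_year = max(sub$year),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified mean abundance by year
#'
#' Area-weighted mean catch per set following the stratified-random survey
#' design: the annual index is `sum_h (area_h / sum(area)) * mean(count in
#' stratum h)`, where the weight normalization uses only strata actually
#' sampled that year. `value = "positive_only"` restricts to sets with
#' non-zero catch before averaging (years with no positive sets are dropped).
#'
#' @param records survey-set `data.frame` with `stratum`, `year`, `count`.
#' @param strata `data.frame` with columns `stratum`, `area` (km^2) and
#'   optionally `region`; strata must be unique with positive areas.
#' @param value `"all"` or `"positive_only"`.
#' @param standardize divide counts by `effort` before averaging (descriptive
#'   catch-rate scale); default `FALSE` uses raw counts.
#' @return `data.frame` with columns `year`, `mean`.
#' @export
stratified_mean <- function(records, strata, value = c("all", "positive_only"),
                            standardize = FALSE) {
  value <- match.arg(value)
  if (anyDuplicated(strata$stratum)) stop("duplicate strata in strata table")
  if (any(strata$area <= 0)) stop("stratum areas must be strictly positive")
  unknown <- setdiff(unique(records$stratum), strata$stratum)
  if (length(unknown) > 0)
    stop("unknown stratum id(s): ", paste(unknown, collapse = ", "))
  if (value == "positive_only") records <- records[records$count > 0, ]
  v <- if (standardize) records$count / records$effort else records$count
  years <- sort(unique(records$year))
  out <- vapply(years, function(yr) {
    sub <- records[records$year == yr, , drop = FALSE]
    vv <- v[records$year == yr]
    sm <- tapply(vv, sub$stratum, mean)
    ar <- strata$area[match(names(sm), strata$stratum)]
    sum(ar * sm) / sum(ar)
  }, numeric(1))
  data.frame(year = years, mean = out)
}
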