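# Daily series input/output, the region registry and run configuration.
#
# A daily series is one region's mortality/temperature record: consecutive
# calendar dates, non-negative integer death counts (NA marks counts
# suppressed for data protection, i.e. observed < 3 -- zero is a legal
# observed value and is never conflated with missing), and finite daily mean
# temperatures in degrees Celsius.

#' Construct a validated daily series
#'
#' @param region_id single string naming the region.
#' @param dates `Date` vector, strictly increasing, no gaps.
#' @param deaths integer death counts; `NA` marks suppressed (censored) days.
#' @param tmean daily mean temperature in degrees C; must be finite.
#' @return a `daily_series` object (a data frame with columns `date`,
#'   `deaths`, `tmean` and attribute `region_id`).
#' @export
daily_series <- function(region_id, dates, deaths, tmean) {
  stopifnot(is.character(region_id), length(region_id) == 1)
  dates <- as.Date(dates)
  n <- length(dates)
  if (n == 0) stop("empty series")
  if (length(deaths) != n || length(tmean) != n) {
    stop("deaths and tmean must match dates in length")
  }
  d <- diff(as.integer(dates))
  if (any(d == 0)) {
    stop("duplicate date: ", format(dates[which(d == 0)[1] + 1]))
  }
  if (any(d != 1)) {
    stop("non-consecutive dates starting at: ",
         format(dates[which(d != 1)[1] + 1]))
  }
  deaths <- as.numeric(deaths)
  ok <- is.na(deaths) | (deaths >= 0 & deaths == floor(deaths))
  if (!all(ok)) stop("deaths must be non-negative integers or NA")
  tmean <- as.numeric(tmean)
  if (any(!is.finite(tmean))) {
    stop("non-finite tmean at: ", format(dates[which(!is.finite(tmean))[1]]))
  }
  out <- data.frame(date = dates, deaths = deaths, tmean = tmean)
  attr(out, "region_id") <- region_id
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Read a daily series from a delimited text file
#'
#' Expects a CSV with header `date,deaths,tmean`; dates ISO-8601. Empty or
#' `NA` cells in `deaths` become the missing marker (suppressed counts),
#' never zero.
#'
#' @param path file path.
#' @param region_id region identifier to attach.
#' @return a [daily_series()].
#' @export
read_daily_series <- function(path, region_id) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character"))
  need <- c("date", "deaths", "tmean")
  if (!all(need %in% names(tab))) {
    stop("file must have columns date, deaths, tmean")
  }
  dates <- as.Date(tab$date, format = "%Y-%m-%d")
  if (any(is.na(dates))) {
    stop("unparseable date: ", tab$date[which(is.na(dates))[1]])
  }
  deaths_raw <- trimws(tab$deaths)
  deaths <- suppressWarnings(as.numeric(deaths_raw))
  bad <- !is.na(deaths_raw) & nzchar(deaths_raw) &
    deaths_raw != "NA" & is.na(deaths)
  if (any(bad)) stop("non-numeric deaths at ", tab$date[which(bad)[1]])
  tmean <- suppressWarnings(as.numeric(tab$tmean))
  if (any(is.na(tmean))) {
    stop("non-numeric tmean at ", tab$date[which(is.na(tmean))[1]])
  }
  daily_series(region_id, dates, deaths, tmean)
}

#' Write a daily series as CSV
#'
#' Inverse of [read_daily_series()]: suppressed days are written as empty
#' cells so a round trip reproduces the series exactly.
#'
#' @param series a [daily_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(series, path) {
  stopifnot(inherits(series, "daily_series"))
  out <- data.frame(
    date = format(series$date, "%Y-%m-%d"),
    deaths = ifelse(is.na(series$deaths), "",
                    format(series$deaths, scientific = FALSE, trim = TRUE)),
    tmean = format(series$tmean, digits = 15, scientific = FALSE, trim = TRUE)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fraction of days with suppressed death counts
#'
#' @param series a [daily_series()].
#' @return proportion of days whose deaths are missing.
#' @export
missing_fraction <- function(series) mean(is.na(series$deaths))

#' Apply the data-availability inclusion rule
#'
#' Regions missing death data for more than `threshold` of the study days
#' are excluded (strictly greater than: a region at exactly the threshold is
#' kept).
#'
#' @param registry a region registry data frame with columns `region_id`,
#'   `mmt`, `missing_fraction`.
#' @param threshold proportion in (0, 1]; default 0.5.
#' @return the registry with column `included` set.
#' @export
apply_inclusion_rule <- function(registry, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  stopifnot(all(c("region_id", "missing_fraction") %in% names(registry)))
  registry$included <- registry$missing_fraction <= threshold
  excl <- registry$region_id[!registry$included]
  if (length(excl)) {
    message("excluded (missing fraction > ", threshold, "): ",
            paste(excl, collapse = ", "))
  }
  registry
}

#' Run configuration
#'
#' @param model_variant `"fixed_knots"` or `"qaic_knots"`.
#' @param max_lag maximum lag in days (default 21).
#' @param trend_df_per_year degrees of freedom per year for the long-term /
#'   seasonal trend spline (default 7).
#' @param mc_draws Monte-Carlo draws for confidence intervals (>= 100).
#' @param seed integer RNG seed.
#' @param decades list of `c(start_year, end_year)` closed 10-year intervals.
#' @return a `run_config` list.
#' @export
run_config <- function(model_variant = c("fixed_knots", "qaic_knots"),
                       max_lag = 21, trend_df_per_year = 7,
                       mc_draws = 1000, seed = 1,
                       decades = default_decades()) {
  model_variant <- match.arg(model_variant)
  stopifnot(max_lag >= 1, mc_draws >= 100)
  check_decades(decades)
  structure(
    list(model_variant = model_variant, max_lag = as.integer(max_lag),
         trend_df_per_year = as.integer(trend_df_per_year),
         mc_draws = as.integer(mc_draws), seed = as.integer(seed),
         decades = decades),
    class = "run_config"
  )
}

#' Default projection decades, 2010-2019 through 2090-2099
#' @return list of `c(start, end)` year pairs.
#' @export
default_decades <- function() {
  lapply(seq(2010, 2090, by = 10), function(s) c(s, s + 9))
}
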