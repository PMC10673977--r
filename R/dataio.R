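# Reading, validating and summarising long-format monitoring data.

#' Seasonal period of a calendar date
#'
#' Monitoring records are pooled into two hydrological half-years:
#' April--September (`"APR_SEP"`) and October--March (`"OCT_MAR"`). Every
#' month belongs to exactly one period.
#'
#' @param date A `Date` vector (or something `as.Date()` accepts).
#' @return Factor with levels `APR_SEP`, `OCT_MAR`.
#' @export
#' @examples
#' assign_period(as.Date(c("2015-04-01", "2015-10-15", "2016-03-31")))
assign_period <- function(date) {
  date <- as.Date(date)
  if (any(is.na(date))) stop("unparseable date(s)")
  m <- as.integer(format(date, "%m"))
  factor(ifelse(m >= 4 & m <= 9, "APR_SEP", "OCT_MAR"),
         levels = c("APR_SEP", "OCT_MAR"))
}

new_hm_dataset <- function(records) {
  records$site <- as.character(records$site)
  records$metal <- as.character(records$metal)
  records <- records[order(records$site, records$date, match(records$metal, hm_metals())), ]
  rownames(records) <- NULL
  structure(
    list(records = records,
         sites = sort(unique(records$site)),
         window = if (nrow(records)) range(records$date) else as.Date(character())),
    class = "hm_dataset")
}

#' Read long-format monitoring data
#'
#' Expects a delimited text file with header columns `site`, `date`
#' (ISO-8601), `metal` and `concentration_ugL`. Each row is one measured
#' concentration. Unknown analytes, unparseable dates, negative
#' concentrations and duplicated (site, date, metal) triples are rejected
#' with an error naming the offending row; duplicates are treated as
#' data-entry faults rather than silently averaged.
#'
#' @param path Path to the CSV file.
#' @return An object of class `"hm_dataset"`: a list with `records` (data
#'   frame), `sites` and the campaign `window`.
#' @export
read_monitoring_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "date", "metal", "concentration_ugL")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(raw)) {
    warning("empty monitoring file: ", path)
    return(new_hm_dataset(data.frame(site = character(), date = as.Date(character()),
                                     metal = character(), concentration_ugL = numeric())))
  }
  d <- as.Date(raw$date, format = "%Y-%m-%d")
  if (any(is.na(d)))
    stop("unparseable date in row(s): ", paste(utils::head(which(is.na(d)), 5), collapse = ", "))
  bad <- !raw$metal %in% hm_metals()
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown analyte '", raw$metal[i], "' in row ", i)
  }
  conc <- suppressWarnings(as.numeric(raw$concentration_ugL))
  if (any(is.na(conc) | conc < 0)) {
    i <- which(is.na(conc) | conc < 0)[1]
    stop("missing or negative concentration in row ", i)
  }
  key <- paste(raw$site, d, raw$metal)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicated (site, date, metal) record in row ", i, ": ", key[i])
  }
  new_hm_dataset(data.frame(site = raw$site, date = d, metal = raw$metal,
                            concentration_ugL = conc))
}

#' Write a monitoring dataset back to CSV
#'
#' @param dataset An `"hm_dataset"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_monitoring_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "hm_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.hm_dataset <- function(x, ...) {
  cat("Monitoring dataset:", nrow(x$records), "records,",
      length(x$sites), "sites")
  if (length(x$window)) cat(",", format(x$window[1]), "to", format(x$window[2]))
  cat("\n")
  invisible(x)
}

#' @export
summary.hm_dataset <- function(object, ...) summarize_sites(object)

#' Per-site, per-period concentration summaries
#'
#' Collapses a monitoring dataset to one row per (site, period, metal) with
#' the arithmetic mean, minimum, maximum and sample count. Site/period cells
#' with no records are simply absent. Row order of the input does not affect
#' the result.
#'
#' @param dataset An `"hm_dataset"`.
#' @return Data frame of class `"hm_summary"` with columns `site`, `period`,
#'   `metal`, `mean_ugL`, `min_ugL`, `max_ugL`, `n`.
#' @export
summarize_sites <- function(dataset) {
  stopifnot(inherits(dataset, "hm_dataset"))
  r <- dataset$records
  if (!nrow(r)) stop("cannot summarise an empty dataset")
  r$period <- assign_period(r$date)
  agg <- aggregate(concentration_ugL ~ site + period + metal, data = r,
                   FUN = function(v) c(mean = mean(v), min = min(v),
                                       max = max(v), n = length(v)))
  out <- data.frame(site = agg$site, period = agg$period, metal = agg$metal,
                    mean_ugL = agg$concentration_ugL[, "mean"],
                    min_ugL = agg$concentration_ugL[, "min"],
                    max_ugL = agg$concentration_ugL[, "max"],
                    n = as.integer(agg$concentration_ugL[, "n"]))
  out <- out[order(out$site, out$period, match(out$metal, hm_metals())), ]
  rownames(out) <- NULL
  class(out) <- c("hm_summary", "data.frame")
  out
}

#' Cross-site pooled mean concentrations
#'
#' The pooled mean for a period is the unweighted average, across sites, of
#' the per-site mean concentrations - the quantity all pooled indices and
#' pooled risk figures are computed from.
#'
#' @param summaries An `"hm_summary"` data frame (or anything with columns
#'   `site`, `period`, `metal`, `mean_ugL`).
#' @param period `"APR_SEP"` or `"OCT_MAR"`.
#' @return Named numeric vector of per-metal means (ug/L), in [hm_metals()]
#'   order (metals absent from the summaries are dropped).
#' @export
pooled_means <- function(summaries, period = c("APR_SEP", "OCT_MAR")) {
  period <- match.arg(period)
  s <- summaries[summaries$period == period, , drop = FALSE]
  if (!nrow(s)) stop("no summaries for period ", period)
  v <- tapply(s$mean_ugL, s$metal, mean)
  v <- v[intersect(hm_metals(), names(v))]
  stats::setNames(as.numeric(v), names(v))
}

#' Read a per-site seasonal means table
#'
#' Reads a CSV with columns `site`, `period` (`APR_SEP`/`OCT_MAR`), `metal`,
#' `mean_ugL` into an `"hm_summary"` - the same layout as
#' [danube_site_means()]. Useful when only summarised concentrations are
#' available rather than raw records.
#'
#' @param path Path to the CSV file.
#' @return An `"hm_summary"` data frame (`min_ugL`/`max_ugL`/`n` are `NA`).
#' @export
read_summary_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "period", "metal", "mean_ugL")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(d$period %in% c("APR_SEP", "OCT_MAR")))
    stop("period must be APR_SEP or OCT_MAR")
  if (!all(d$metal %in% hm_metals()))
    stop("unknown analyte(s): ", paste(setdiff(d$metal, hm_metals()), collapse = ", "))
  if (any(!is.finite(d$mean_ugL)) || any(d$mean_ugL < 0))
    stop("mean_ugL must be non-negative")
  out <- data.frame(site = as.character(d$site),
                    period = factor(d$period, levels = c("APR_SEP", "OCT_MAR")),
                    metal = d$metal, mean_ugL = d$mean_ugL,
                    min_ugL = NA_real_, max_ugL = NA_real_, n = NA_integer_)
  class(out) <- c("hm_summary", "data.frame")
  out
}

#' Packaged per-site seasonal mean concentrations (Danube campaign)
#'
#' The seasonal per-site mean concentrations (ug/L) of the eight analytes at
#' the seven Danube monitoring stations (S1--S7, 2013--2019) that the
#' synthetic generator is calibrated to and that all worked examples use.
#'
#' @return An `"hm_summary"` data frame with `mean_ugL` populated and
#'   `min_ugL`/`max_ugL`/`n` set to `NA` (the per-sample records behind these
#'   means are not distributed; use [generate_dataset()] for full synthetic
#'   records).
#' @export
#' @examples
#' pooled_means(danube_site_means(), "APR_SEP")["Fe"]   # ~520.63
danube_site_means <- function() {
  path <- system.file("extdata", "danube_site_means.csv", package = "aquametal",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(site = d$site,
                    period = factor(d$period, levels = c("APR_SEP", "OCT_MAR")),
                    metal = d$metal, mean_ugL = d$mean_ugL,
                    min_ugL = NA_real_, max_ugL = NA_real_, n = NA_integer_)
  class(out) <- c("hm_summary", "data.frame")
  out
}
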