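#' Number of expected calendar months in an inclusive window
#'
#' @param start,end YYYY-MM strings, both endpoints counted
#' @return integer month count
#' @export
#' @examples
#' expected_months("2014-01", "2017-09")  # 45
expected_months <- function(start, end) {
  length(month_seq(start, end))
}

#' Tool availability rate (percent)
#'
#' Percentage of expected tool-months (register-, tally-sheet- or
#' report-months) actually located. Vectorised.
#'
#' @param observed nonnegative integer(s), observed tool-months
#' @param expected positive integer(s), expected tool-months
#' @return rate(s) in percent; `NA` with a warning where `expected == 0`
#'   (such units are excluded from summaries)
#' @export
availability_rate <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0))
    abort("observed and expected month counts must be nonnegative")
  if (any(observed > expected, na.rm = TRUE))
    abort("observed months cannot exceed expected months")
  if (any(zero <- expected == 0)) {
    warn(sprintf("%d unit(s) with zero expected months; rate undefined, set NA",
                 sum(zero)))
  }
  ifelse(expected == 0, NA_real_, 100 * observed / expected)
}

#' District-level reporting completeness (percent)
#'
#' Percentage of expected facility monthly reports actually found at the
#' district office. Same arithmetic as [availability_rate()]; kept as its
#' own verb because it is a distinct indicator (the district copy of the
#' report, not the facility's own tools).
#'
#' @inheritParams availability_rate
#' @param received reports located at the district office
#' @export
district_report_completeness <- function(received, expected) {
  availability_rate(received, expected)
}

#' Median / quartile summary of a set of percentages
#'
#' Summarises unit-level rates with the median, 25th and 75th percentiles
#' (linear interpolation between closest order statistics, the type-7
#' convention) and their spread `range = p75 - p25`.
#'
#' @param values numeric vector of percentages; `NA`s are dropped
#' @param quantile_type quantile algorithm passed to [stats::quantile()]
#' @return a one-row tibble: `median`, `p25`, `p75`, `range`, `n`
#' @export
#' @examples
#' summarize_distribution(c(10, 20, 30, 40))
summarize_distribution <- function(values, quantile_type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("cannot summarise an empty set of rates")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = quantile_type))
  tibble::tibble(median = q[2], p25 = q[1], p75 = q[3],
                 range = q[3] - q[1], n = length(values))
}

#' Four-level availability category
#'
#' Classifies an availability rate into `very_high` (75, 100], `high`
#' \[50, 75\], `average` \[25, 50) or `low` \[0, 25). The four intervals
#' partition \[0, 100\]; the boundary value 75 falls in `high` because
#' `very_high` is strictly "above 75".
#'
#' @param rate percentage(s) in \[0, 100\]
#' @return ordered factor with levels `low < average < high < very_high`
#' @export
#' @examples
#' categorize_availability(c(80, 75, 50, 10))
categorize_availability <- function(rate) {
  if (any(is.na(rate)) || any(rate < 0 | rate > 100))
    abort("availability rates must lie in [0, 100]")
  lab <- ifelse(rate > 75, "very_high",
         ifelse(rate >= 50, "high",
         ifelse(rate >= 25, "average", "low")))
  factor(lab, levels = c("low", "average", "high", "very_high"),
         ordered = TRUE)
}

# map user-facing tool names to the columns whose presence defines them
TOOL_COLUMNS <- c(register = "register", tally_sheet = "tally",
                  report_form = "facility_report",
                  district_copy = "district_report")

#' Tool presence per facility, service area and month
#'
#' A tool-month counts as observed when at least one indicator record for
#' that tool, facility, service area and month is present in the dataset.
#'
#' @param counts wide counts tibble
#' @param tools subset of `register`, `tally_sheet`, `report_form`,
#'   `district_copy`
#' @return a tibble with facility attributes, `year`, `service_area`,
#'   `month`, `tool`, `observed` (0/1)
#' @export
tool_presence <- function(counts, tools = c("register", "tally_sheet",
                                            "report_form")) {
  tools <- match.arg(tools, names(TOOL_COLUMNS), several.ok = TRUE)
  attrs <- intersect(c("facility_id", "district", "level", "ownership",
                       "setting"), names(counts))
  per_tool <- lapply(tools, function(tl) {
    col <- TOOL_COLUMNS[[tl]]
    counts |>
      dplyr::group_by(dplyr::across(dplyr::all_of(
        c(attrs, "service_area", "month")))) |>
      dplyr::summarise(observed = as.integer(any(!is.na(.data[[col]]))),
                       .groups = "drop") |>
      dplyr::mutate(tool = tl, year = month_year(.data$month))
  })
  dplyr::bind_rows(per_tool)
}

#' Stratified tool-availability table
#'
#' Computes facility-level availability rates per tool within each
#' stratum, categorises them, and summarises their distribution across
#' facilities (median, p25, p75, range). Facility rates are always
#' computed before summarising across facilities. An `overall` pseudo-tool
#' pooling all requested tools is appended, mirroring the usual "all
#' tools" table rows.
#'
#' @param counts wide counts tibble (from [propagate_journey()] or
#'   [read_dataset()])
#' @param by character vector of stratifiers among `year`,
#'   `service_area`, `level`, `ownership`, `district`, `setting` (empty
#'   for an all-data table)
#' @param tools tools to include (see [tool_presence()])
#' @param overall append the pooled `overall` tool rows?
#' @return a list of class `availability_table`: `$units` — one row per
#'   (facility, tool, stratum) with `observed`, `expected`, `rate`,
#'   `category`; `$summary` — one row per (tool, stratum) with the
#'   distribution summary
#' @export
availability_table <- function(counts, by = character(),
                               tools = c("register", "tally_sheet",
                                         "report_form"),
                               overall = TRUE) {
  ok_attrs <- c("year", "service_area", "level", "ownership", "district",
                "setting")
  if (length(bad <- setdiff(by, ok_attrs)))
    abort(sprintf("unknown grouping attribute(s): %s",
                  paste(bad, collapse = ", ")))
  pres <- tool_presence(counts, tools)
  if (overall) pres <- dplyr::bind_rows(
    pres, dplyr::mutate(pres, tool = "overall"))
  units <- pres |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("tool", by, "facility_id")))) |>
    dplyr::summarise(observed = sum(.data$observed),
                     expected = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rate = availability_rate(.data$observed, .data$expected),
                  category = categorize_availability(.data$rate))
  summary <- units |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("tool", by)))) |>
    dplyr::reframe(summarize_distribution(.data$rate)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c("tool", by))))
  structure(list(units = units, summary = summary, by = by),
            class = "availability_table")
}

#' @export
print.availability_table <- function(x, ...) {
  cat(sprintf("<availability_table> %d unit rows, stratified by: %s\n",
              nrow(x$units),
              if (length(x$by)) paste(x$by, collapse = ", ") else "(none)"))
  print(x$summary, ...)
  invisible(x)
}

#' Stratified district-office reporting completeness
#'
#' Facility-level rates of reports located at the district office
#' (presence of the district copy), summarised per stratum. A facility's
#' rate is the share of its expected report-months whose district copy was
#' found.
#'
#' @inheritParams availability_table
#' @return an `availability_table` (tool = `district_copy`)
#' @export
district_completeness_table <- function(counts, by = "district") {
  availability_table(counts, by = by, tools = "district_copy",
                     overall = FALSE)
}

#' Write an availability table to CSV
#'
#' Unit rows and summary rows go to one file, distinguished by a
#' `row_type` column. Rates are printed to one decimal; the `range` column
#' to the nearest integer (the usual display convention); computation is
#' done unrounded.
#'
#' @param x an `availability_table`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_availability <- function(x, path) {
  stopifnot(inherits(x, "availability_table"))
  units <- x$units |>
    dplyr::mutate(row_type = "facility", rate = round(.data$rate, 1),
                  category = as.character(.data$category))
  summ <- x$summary |>
    dplyr::mutate(row_type = "summary",
                  dplyr::across(dplyr::all_of(c("median", "p25", "p75")),
                                ~ round(.x, 1)),
                  range = round(.data$range))
  readr::write_csv(dplyr::bind_rows(units, summ), path, na = "")
  invisible(path)
}
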