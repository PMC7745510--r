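#' Write a simulated or observed dataset to a directory of CSV files
#'
#' Serialises the package's containers to the plain-text exchange formats:
#'
#' * `counts.csv` — long format, one row per (facility, indicator, month,
#'   source) with columns `facility_id, district, level, ownership,
#'   setting, service_area, indicator_id, month, source, present, value`;
#'   `source` is one of `register, tally, facility_report, district_report,
#'   dhis2`; `value` is empty when `present = 0`.
#' * `register_rows.csv` — long format `facility_id, service_area, month,
#'   field, value` (blank allowed).
#' * `roster.csv`, `indicators.csv` — as-is.
#'
#' @param counts wide counts tibble from [propagate_journey()] or
#'   [read_dataset()]
#' @param dir output directory (created if missing)
#' @param register_rows optional register-row tibble from
#'   [simulate_register_rows()]
#' @param roster,indicators optional roster / indicator catalogue tibbles
#' @return `dir`, invisibly
#' @export
write_dataset <- function(counts, dir, register_rows = NULL, roster = NULL,
                          indicators = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- counts |>
    dplyr::select(dplyr::all_of(c("facility_id", "district", "level",
                                  "ownership", "setting", "service_area",
                                  "indicator_id", "month", JOURNEY_SOURCES))) |>
    tidyr::pivot_longer(dplyr::all_of(JOURNEY_SOURCES),
                        names_to = "source", values_to = "value") |>
    dplyr::mutate(present = as.integer(!is.na(.data$value))) |>
    dplyr::relocate("present", .before = "value")
  readr::write_csv(long, file.path(dir, "counts.csv"), na = "")
  if (!is.null(register_rows)) {
    meta <- intersect(c("facility_id", "service_area", "month", "row"),
                      names(register_rows))
    rr_long <- register_rows |>
      dplyr::select(-dplyr::any_of(c("district"))) |>
      tidyr::pivot_longer(-dplyr::all_of(meta),
                          names_to = "field", values_to = "value")
    readr::write_csv(rr_long, file.path(dir, "register_rows.csv"), na = "")
  }
  if (!is.null(roster))
    readr::write_csv(roster, file.path(dir, "roster.csv"))
  if (!is.null(indicators))
    readr::write_csv(indicators, file.path(dir, "indicators.csv"))
  invisible(dir)
}

# stop with up-to-5 offending CSV row numbers in the message
row_diag_abort <- function(bad, what) {
  rows <- which(bad) + 1L   # +1 for the header line
  shown <- paste(head(rows, 5), collapse = ", ")
  more <- if (length(rows) > 5) sprintf(" (and %d more)", length(rows) - 5) else ""
  abort(sprintf("counts.csv: %s at row(s) %s%s", what, shown, more))
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Validates the long-format `counts.csv` (known source labels, 0/1
#' presence flags, nonnegative integer values, value present iff flag set)
#' with row-level diagnostics, and reshapes it back to the wide
#' one-row-per-facility-indicator-month form. Reads `register_rows.csv`,
#' `roster.csv` and `indicators.csv` when present.
#'
#' @param dir directory containing the CSV files
#' @return a list with elements `counts`, and (when on disk)
#'   `register_rows`, `roster`, `indicators`
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "counts.csv")
  if (!file.exists(path)) abort(sprintf("no counts.csv under '%s'", dir))
  long <- readr::read_csv(path, col_types = readr::cols(
    facility_id = "c", district = "c", level = "c", ownership = "c",
    setting = "c", service_area = "c", indicator_id = "c", month = "c",
    source = "c", value = "d", present = "i"))
  if (any(bad <- !long$source %in% JOURNEY_SOURCES))
    row_diag_abort(bad, sprintf("unknown source label '%s'",
                                long$source[which(bad)[1]]))
  if (any(bad <- !long$present %in% c(0L, 1L)))
    row_diag_abort(bad, "presence flag not 0/1")
  v <- long$value
  if (any(bad <- !is.na(v) & (v < 0 | v != trunc(v))))
    row_diag_abort(bad, "negative or non-integer value")
  if (any(bad <- (long$present == 1L) != !is.na(v)))
    row_diag_abort(bad, "value present does not match presence flag")
  check_month(long$month, "counts.csv month")
  counts <- long |>
    dplyr::select(-"present") |>
    tidyr::pivot_wider(names_from = "source", values_from = "value") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(JOURNEY_SOURCES), as.integer)) |>
    dplyr::arrange(.data$facility_id, .data$indicator_id, .data$month)
  out <- list(counts = counts)
  rr <- file.path(dir, "register_rows.csv")
  if (file.exists(rr)) {
    rr_long <- readr::read_csv(rr, col_types = readr::cols(.default = "c"))
    if ("row" %in% names(rr_long)) rr_long$row <- as.integer(rr_long$row)
    rr_long$value[is.na(rr_long$value)] <- ""
    out$register_rows <- tidyr::pivot_wider(rr_long, names_from = "field",
                                            values_from = "value")
  }
  ro <- file.path(dir, "roster.csv")
  if (file.exists(ro))
    out$roster <- readr::read_csv(ro, col_types = readr::cols(.default = "c"))
  ic <- file.path(dir, "indicators.csv")
  if (file.exists(ic))
    out$indicators <- readr::read_csv(
      ic, col_types = readr::cols(age_split = "l", .default = "c"))
  if (!is.null(out$roster) && !is.null(out$register_rows) &&
      !"district" %in% names(out$register_rows)) {
    out$register_rows <- dplyr::left_join(
      out$register_rows, out$roster[, c("facility_id", "district")],
      by = "facility_id") |>
      dplyr::relocate("district", .after = "facility_id")
  }
  out
}
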