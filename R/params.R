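#' Journey error-process parameters
#'
#' Bundles every stage-wise error process of the facility-to-DHIS2 data
#' journey into a validated parameter object. The neutral defaults describe
#' a lossless journey: no recording misses, no over-marking, reports always
#' compiled from tally totals, no absences, no transmission loss, no
#' corrections, no entry errors — under which all five sources carry
#' identical values. Use [default_journey_params()] for an illustrative
#' error-laden preset.
#'
#' @param mean_monthly_volume mean true client events per indicator-month;
#'   either a single positive number or a data frame with columns
#'   `service_area`, `level`, `mean` giving a mean per (service area,
#'   facility level) pair (see [default_volume_table()]).
#' @param p_register_miss probability an event is never written in the
#'   register.
#' @param p_tally_miss probability an event is not marked on the tally sheet.
#' @param tally_overmark_rate expected extra tally marks per true event
#'   (Poisson rate, >= 0); models duplicate ticking.
#' @param compile_mode_probs length-3 numeric, probabilities that a monthly
#'   report is compiled from, in order, tally totals, a register recount, or
#'   an inflated guess; must sum to 1.
#' @param report_inflation_factor multiplier (> 0) applied to the register
#'   recount in "inflated guess" mode, rounded half away from zero.
#' @param p_register_absent,p_tally_absent,p_facility_report_absent per
#'   service-area-month probability that the tool cannot be located at
#'   review time.
#' @param p_transmission_loss probability the submitted report is
#'   unlocatable at the district office.
#' @param p_district_correction probability the district copy's value is
#'   revised (undocumented) before DHIS2 entry.
#' @param correction_factor multiplicative revision (> 0) applied when a
#'   correction occurs.
#' @param p_entry_error probability of a keystroke perturbation at DHIS2
#'   entry (+/- one unit in a random decimal place, floored at zero).
#' @param seed integer seed expanded into deterministic per-facility,
#'   per-stage sub-streams.
#' @return an object of class `journey_params` (a validated named list)
#' @export
#' @examples
#' journey_params(p_register_miss = 0.2, seed = 1)
journey_params <- function(mean_monthly_volume = 50,
                           p_register_miss = 0,
                           p_tally_miss = 0,
                           tally_overmark_rate = 0,
                           compile_mode_probs = c(tally = 1, register = 0, inflated = 0),
                           report_inflation_factor = 1,
                           p_register_absent = 0,
                           p_tally_absent = 0,
                           p_facility_report_absent = 0,
                           p_transmission_loss = 0,
                           p_district_correction = 0,
                           correction_factor = 1,
                           p_entry_error = 0,
                           seed = 1L) {
  probs <- list(p_register_miss = p_register_miss, p_tally_miss = p_tally_miss,
                p_register_absent = p_register_absent,
                p_tally_absent = p_tally_absent,
                p_facility_report_absent = p_facility_report_absent,
                p_transmission_loss = p_transmission_loss,
                p_district_correction = p_district_correction,
                p_entry_error = p_entry_error)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
      abort(sprintf("`%s` must be a single probability in [0, 1]", nm))
  }
  if (!is.numeric(compile_mode_probs) || length(compile_mode_probs) != 3 ||
      any(compile_mode_probs < 0) || abs(sum(compile_mode_probs) - 1) > 1e-8)
    abort("`compile_mode_probs` must be 3 nonnegative probabilities summing to 1")
  compile_mode_probs <- setNames(as.numeric(compile_mode_probs),
                                 c("tally", "register", "inflated"))
  if (!is.numeric(tally_overmark_rate) || tally_overmark_rate < 0)
    abort("`tally_overmark_rate` must be >= 0")
  for (nm in c("report_inflation_factor", "correction_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      abort(sprintf("`%s` must be a single value > 0", nm))
  }
  vol <- mean_monthly_volume
  if (is.data.frame(vol)) {
    need <- c("service_area", "level", "mean")
    if (!all(need %in% names(vol)))
      abort("volume table needs columns service_area, level, mean")
    if (any(vol$mean < 0)) abort("mean volumes must be nonnegative")
  } else if (!is.numeric(vol) || length(vol) != 1 || vol < 0) {
    abort("`mean_monthly_volume` must be a nonnegative number or a volume table")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer")
  structure(list(mean_monthly_volume = vol,
                 p_register_miss = p_register_miss,
                 p_tally_miss = p_tally_miss,
                 tally_overmark_rate = tally_overmark_rate,
                 compile_mode_probs = compile_mode_probs,
                 report_inflation_factor = report_inflation_factor,
                 p_register_absent = p_register_absent,
                 p_tally_absent = p_tally_absent,
                 p_facility_report_absent = p_facility_report_absent,
                 p_transmission_loss = p_transmission_loss,
                 p_district_correction = p_district_correction,
                 correction_factor = correction_factor,
                 p_entry_error = p_entry_error,
                 seed = seed),
            class = "journey_params")
}

#' @export
print.journey_params <- function(x, ...) {
  cat("<journey_params>\n")
  for (nm in setdiff(names(x), "mean_monthly_volume")) {
    v <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm,
                paste(format(v, digits = 4), collapse = " ")))
  }
  vol <- x$mean_monthly_volume
  cat(sprintf("  %-26s %s\n", "mean_monthly_volume",
              if (is.data.frame(vol)) sprintf("<table, %d rows>", nrow(vol))
              else format(vol)))
  invisible(x)
}

#' Default mean monthly client volumes by service area and facility level
#'
#' Illustrative mean true event counts per indicator-month. Outpatient
#' departments see by far the largest client loads and hospitals more than
#' health centres and dispensaries; inpatient and HIV
#' testing-and-counselling volumes are comparatively small.
#'
#' @return a tibble with columns `service_area`, `level`, `mean`
#' @export
default_volume_table <- function() {
  base <- c(OPD = 120, IPD = 15, ANC = 40, PNC = 25, LnD = 15, FP = 30,
            PITC = 20)
  mult <- c(dispensary = 1, health_centre = 2.5, hospital = 6)
  tidyr::expand_grid(service_area = names(base), level = names(mult)) |>
    dplyr::mutate(mean = base[.data$service_area] * mult[.data$level]) |>
    dplyr::arrange(.data$service_area, .data$level)
}

#' Illustrative error-laden journey parameter preset
#'
#' A single default scenario reproducing, qualitatively, the error
#' phenomena documented for paper-based reporting cascades: tally sheets
#' under-used and over-marked, a fraction of reports compiled by inflated
#' guesswork rather than from tally totals (driving report
#' over-representation relative to registers), roughly a third of submitted
#' reports unlocatable at the district office, and occasional undocumented
#' corrections before DHIS2 entry. The rates are illustrative defaults, not
#' calibrated estimates from any field dataset.
#'
#' @param seed integer seed
#' @return a `journey_params` object
#' @export
default_journey_params <- function(seed = 1L) {
  journey_params(
    mean_monthly_volume      = default_volume_table(),
    p_register_miss          = 0.25,
    p_tally_miss             = 0.30,
    tally_overmark_rate      = 0.10,
    compile_mode_probs       = c(tally = 0.55, register = 0.25, inflated = 0.20),
    report_inflation_factor  = 3,
    p_register_absent        = 0.09,
    p_tally_absent           = 0.25,
    p_facility_report_absent = 0.13,
    p_transmission_loss      = 0.35,
    p_district_correction    = 0.15,
    correction_factor        = 1.15,
    p_entry_error            = 0.02,
    seed                     = seed)
}

#' Read/write journey parameters as YAML or JSON
#'
#' The on-disk representation carries the `journey_params` fields verbatim;
#' a data-frame volume table is stored as a list of records.
#'
#' @param params a `journey_params` object
#' @param path file path ending in `.yaml`, `.yml` or `.json`
#' @return `read_journey_params()` returns a `journey_params` object;
#'   `write_journey_params()` returns `path` invisibly.
#' @export
write_journey_params <- function(params, path) {
  stopifnot(inherits(params, "journey_params"))
  x <- unclass(params)
  if (is.data.frame(x$mean_monthly_volume))
    x$mean_monthly_volume <- lapply(seq_len(nrow(x$mean_monthly_volume)),
                                    function(i) as.list(x$mean_monthly_volume[i, ]))
  x$compile_mode_probs <- as.list(x$compile_mode_probs)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_journey_params
#' @export
read_journey_params <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
       else yaml::read_yaml(path)
  vol <- x$mean_monthly_volume
  if (is.list(vol) && !is.data.frame(vol))
    vol <- dplyr::bind_rows(lapply(vol, tibble::as_tibble))
  cmp <- unlist(x$compile_mode_probs)
  do.call(journey_params, c(list(mean_monthly_volume = vol,
                                 compile_mode_probs = cmp),
                            x[setdiff(names(x),
                                      c("mean_monthly_volume",
                                        "compile_mode_probs"))]))
}
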