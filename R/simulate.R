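#' Simulate true client-event counts
#'
#' Generates the ground truth that the data journey subsequently distorts:
#' for every facility, every indicator whose service area the facility
#' offers, and every month in the window, a true event count drawn from a
#' Poisson distribution with the configured mean. Means come from
#' `params$mean_monthly_volume`, either a scalar or a per
#' (service area, facility level) table. Draws use per-facility
#' sub-streams of `params$seed`, so extending the roster leaves existing
#' facilities' counts unchanged.
#'
#' @param roster facility roster from [simulate_roster()]
#' @param indicators indicator catalogue, e.g. [indicator_catalogue()]
#' @param start,end first and last month (YYYY-MM), both included
#' @param params a [journey_params()] object
#' @return a tibble with facility attributes plus `service_area`,
#'   `indicator_id`, `month`, `true_count`
#' @export
simulate_true_events <- function(roster, indicators, start, end,
                                 params = journey_params()) {
  stopifnot(inherits(params, "journey_params"))
  months <- month_seq(start, end)
  vol <- params$mean_monthly_volume
  ind <- dplyr::arrange(tibble::as_tibble(indicators), .data$indicator_id)
  per_fac <- lapply(seq_len(nrow(roster)), function(i) {
    f <- roster[i, ]
    areas <- offered_areas(f$offered)[[1]]
    ind_f <- ind[ind$service_area %in% areas, ]
    if (nrow(ind_f) == 0) return(NULL)
    grid <- tidyr::expand_grid(indicator_id = ind_f$indicator_id,
                               month = months) |>
      dplyr::left_join(ind_f[, c("indicator_id", "service_area")],
                       by = "indicator_id")
    if (is.data.frame(vol)) {
      grid <- dplyr::left_join(
        grid, dplyr::filter(vol, .data$level == f$level),
        by = "service_area")
      if (anyNA(grid$mean))
        abort(sprintf("no mean volume configured for level '%s', area(s): %s",
                      f$level,
                      paste(unique(grid$service_area[is.na(grid$mean)]),
                            collapse = ", ")))
      mu <- grid$mean
    } else {
      mu <- rep(vol, nrow(grid))
    }
    set.seed(substream_seed(params$seed, f$facility_id, "truth"))
    tibble::tibble(
      facility_id = f$facility_id, district = f$district, level = f$level,
      ownership = f$ownership, setting = f$setting,
      service_area = grid$service_area, indicator_id = grid$indicator_id,
      month = grid$month,
      true_count = rpois(nrow(grid), mu))
  })
  dplyr::bind_rows(per_fac)
}

#' Propagate true events through the five-source data journey
#'
#' Applies the journey's stage-wise error processes to true event counts,
#' producing for every facility-indicator-month the values seen in each of
#' the five sources (absence encoded as `NA`):
#'
#' * `register`: binomial thinning of the truth with retention
#'   `1 - p_register_miss` (events never written down).
#' * `tally`: binomial thinning with retention `1 - p_tally_miss` plus
#'   Poisson over-marking noise with mean `tally_overmark_rate` times the
#'   truth.
#' * `facility_report`: compiled per service-area-month in one of three
#'   modes drawn from `compile_mode_probs` — a copy of the tally total, a
#'   register recount, or an inflated guess (register recount times
#'   `report_inflation_factor`, rounded half away from zero).
#' * `district_report`: the facility report unless lost in transmission
#'   (probability `p_transmission_loss`, drawn per service-area-month).
#' * `dhis2`: the district copy, optionally revised by `correction_factor`
#'   (probability `p_district_correction`, rounded half away from zero) and
#'   optionally hit by a keystroke perturbation (probability
#'   `p_entry_error`: plus/minus one unit in a random decimal place,
#'   floored at 0).
#'
#' Tool absences (`p_register_absent` etc., drawn per service-area-month)
#' model the audit team failing to locate the tool at review time; the
#' report is still compiled from the latent counts, so a report can exist
#' without locatable register support. If the facility report is absent,
#' the district copy and DHIS2 entry are absent too; an absent register or
#' tally sheet does not block downstream sources.
#'
#' @param true_events output of [simulate_true_events()]
#' @param params a [journey_params()] object
#' @return the input tibble with columns `register`, `tally`,
#'   `facility_report`, `district_report`, `dhis2` appended (`NA` = absent)
#' @export
propagate_journey <- function(true_events, params) {
  stopifnot(inherits(params, "journey_params"))
  per_fac <- lapply(split(true_events, true_events$facility_id), function(d) {
    d <- dplyr::arrange(d, .data$indicator_id, .data$month)
    n <- nrow(d)
    set.seed(substream_seed(params$seed, d$facility_id[1], "journey"))

    # service-area-month level draws, in a fixed order
    am <- dplyr::distinct(d, .data$service_area, .data$month) |>
      dplyr::arrange(.data$service_area, .data$month)
    m <- nrow(am)
    am$register_absent <- runif(m) < params$p_register_absent
    am$tally_absent    <- runif(m) < params$p_tally_absent
    am$report_absent   <- runif(m) < params$p_facility_report_absent
    am$lost            <- runif(m) < params$p_transmission_loss
    am$mode <- sample(names(params$compile_mode_probs), m, replace = TRUE,
                      prob = params$compile_mode_probs)

    # row-level draws
    reg   <- rbinom(n, d$true_count, 1 - params$p_register_miss)
    tal   <- rbinom(n, d$true_count, 1 - params$p_tally_miss) +
             rpois(n, params$tally_overmark_rate * d$true_count)
    corr  <- runif(n) < params$p_district_correction
    entry <- runif(n) < params$p_entry_error
    entry_sign  <- sample(c(-1L, 1L), n, replace = TRUE)
    entry_place <- sample(0:2, n, replace = TRUE)

    d <- dplyr::left_join(d, am, by = c("service_area", "month"))
    report <- dplyr::case_match(d$mode,
      "tally"    ~ tal,
      "register" ~ reg,
      "inflated" ~ round_half_away(reg * params$report_inflation_factor))
    district <- report
    dhis2 <- ifelse(corr, round_half_away(district * params$correction_factor),
                    district)
    dhis2 <- ifelse(entry, pmax(0, dhis2 + entry_sign * 10^entry_place), dhis2)

    d$register        <- as.integer(ifelse(d$register_absent, NA, reg))
    d$tally           <- as.integer(ifelse(d$tally_absent, NA, tal))
    d$facility_report <- as.integer(ifelse(d$report_absent, NA, report))
    gone <- d$report_absent | d$lost
    d$district_report <- as.integer(ifelse(gone, NA, district))
    d$dhis2           <- as.integer(ifelse(gone, NA, dhis2))
    d[setdiff(names(d), c("register_absent", "tally_absent", "report_absent",
                          "lost", "mode"))]
  })
  dplyr::bind_rows(per_fac) |>
    dplyr::arrange(.data$facility_id, .data$indicator_id, .data$month)
}

#' Per-field blank and invalid-code rates for the register-row simulator
#'
#' The default rates echo the completeness problems commonly reported for
#' paper registers: height and weight frequently left blank, sex and age
#' occasionally, and widespread use of the English Y/Yes code where the
#' instructed Swahili codes are N (Ndiyo) / H (Hapana).
#'
#' @return a tibble: `field`, `blank_rate`, `invalid_rate`
#' @export
default_register_error_rates <- function() {
  tibble::tribble(
    ~field,        ~blank_rate, ~invalid_rate,
    "sex",         0.08,        0.02,
    "age",         0.10,        0.00,
    "weight",      0.35,        0.02,
    "height",      0.40,        0.02,
    "diagnosis",   0.05,        0.00,
    "severity",    0.30,        0.05,
    "yes_no_code", 0.05,        0.25)
}

# valid + deliberately invalid generators per register field
register_field_values <- function(field, n) {
  switch(field,
    sex         = sample(c("M", "F"), n, replace = TRUE),
    age         = as.character(sample(0:95, n, replace = TRUE)),
    weight      = as.character(round(runif(n, 2.5, 95), 1)),
    height      = as.character(round(runif(n, 45, 195))),
    diagnosis   = sample(c("malaria", "ARI", "diarrhoea", "anaemia", "UTI"),
                         n, replace = TRUE),
    severity    = sample(c("mild", "severe"), n, replace = TRUE),
    yes_no_code = sample(c("N", "H"), n, replace = TRUE),
    abort(sprintf("unknown register field '%s'", field)))
}

register_field_invalid <- function(field, n) {
  switch(field,
    sex         = rep("X", n),
    age         = rep("999", n),
    weight      = rep("-1", n),
    height      = rep("999", n),
    diagnosis   = rep("???", n),
    severity    = rep("S", n),
    yes_no_code = sample(c("Y", "Yes"), n, replace = TRUE),
    abort(sprintf("unknown register field '%s'", field)))
}

#' Simulate row-level register records with completeness defects
#'
#' Generates patient-row register records for every facility, offered
#' service area and month, then injects blanks and invalid codes at the
#' configured per-field rates. Uses per-facility sub-streams of `seed`.
#'
#' @param roster facility roster from [simulate_roster()]
#' @param start,end month window (YYYY-MM, inclusive)
#' @param error_rates tibble with columns `field`, `blank_rate`,
#'   `invalid_rate` (see [default_register_error_rates()]); fields not
#'   listed get zero rates. Unknown field names are an error.
#' @param rows_per_month patient rows per facility-service-area-month
#' @param seed integer seed
#' @return a tibble with `facility_id`, `district`, `service_area`,
#'   `month`, `row` (patient-row number within the facility-area-month)
#'   and one character column per register field; `""` denotes a blank
#'   cell.
#' @export
simulate_register_rows <- function(roster, start, end,
                                   error_rates = default_register_error_rates(),
                                   rows_per_month = 5, seed = 1L) {
  fields <- c("sex", "age", "weight", "height", "diagnosis", "severity",
              "yes_no_code")
  error_rates <- tibble::as_tibble(error_rates)
  bad <- setdiff(error_rates$field, fields)
  if (length(bad))
    abort(sprintf("unknown field(s) in error_rates: %s",
                  paste(bad, collapse = ", ")))
  if (any(error_rates$blank_rate < 0 | error_rates$blank_rate > 1) ||
      any(error_rates$invalid_rate < 0 | error_rates$invalid_rate > 1))
    abort("error rates must lie in [0, 1]")
  rates <- merge(data.frame(field = fields), error_rates, all.x = TRUE)
  rates$blank_rate[is.na(rates$blank_rate)] <- 0
  rates$invalid_rate[is.na(rates$invalid_rate)] <- 0
  rates <- rates[match(fields, rates$field), ]
  months <- month_seq(start, end)

  per_fac <- lapply(seq_len(nrow(roster)), function(i) {
    f <- roster[i, ]
    areas <- sort(offered_areas(f$offered)[[1]])
    grid <- tidyr::expand_grid(service_area = areas, month = months,
                               row = seq_len(rows_per_month))
    n <- nrow(grid)
    if (n == 0) return(NULL)
    set.seed(substream_seed(seed, f$facility_id, "register_rows"))
    cols <- lapply(seq_along(fields), function(k) {
      fld <- fields[k]
      v <- register_field_values(fld, n)
      inv <- runif(n) < rates$invalid_rate[k]
      v[inv] <- register_field_invalid(fld, sum(inv))
      v[runif(n) < rates$blank_rate[k]] <- ""   # blanks trump invalid codes
      v
    })
    names(cols) <- fields
    tibble::tibble(facility_id = f$facility_id, district = f$district,
                   service_area = grid$service_area, month = grid$month,
                   row = grid$row, !!!cols)
  })
  dplyr::bind_rows(per_fac)
}
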