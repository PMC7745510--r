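# Independent oracles and small fixture builders used across the suite.

# Linear interpolation between closest order statistics, written from the
# definition (independent of stats::quantile).
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Brute-force pooled difference ratio: explicit loop over pairwise-complete
# rows, summing numerator and denominator.
pooled_dr_oracle <- function(counts, num, den) {
  s_num <- 0
  s_den <- 0
  for (i in seq_len(nrow(counts))) {
    a <- counts[[num]][i]
    b <- counts[[den]][i]
    if (!is.na(a) && !is.na(b)) {
      s_num <- s_num + a
      s_den <- s_den + b
    }
  }
  s_num / s_den
}

# Hand-built wide counts rows with constant facility attributes.
make_counts <- function(register, tally = register,
                        facility_report = register,
                        district_report = facility_report,
                        dhis2 = district_report,
                        month = "2016-01", service_area = "OPD",
                        indicator_id = "OPD01", facility_id = "F001",
                        district = "D1", level = "dispensary",
                        ownership = "government", setting = "rural") {
  tibble::tibble(
    facility_id = facility_id, district = district, level = level,
    ownership = ownership, setting = setting,
    service_area = service_area, indicator_id = indicator_id,
    month = month,
    register = as.integer(register), tally = as.integer(tally),
    facility_report = as.integer(facility_report),
    district_report = as.integer(district_report),
    dhis2 = as.integer(dhis2))
}

# Small roster + journey under given params; returns the wide counts.
small_journey <- function(params, n_fac = 6, start = "2016-01",
                          end = "2016-12", roster_seed = 42) {
  cfg <- roster_config(
    districts = tibble::tibble(district = c("D1", "D2"),
                               setting = c("urban", "rural"),
                               n_facilities = c(ceiling(n_fac / 2),
                                                floor(n_fac / 2))),
    level_counts = c(dispensary = n_fac - 1L, health_centre = 1L,
                     hospital = 0L),
    offer_probs = c(OPD = 1, ANC = 1))
  roster <- simulate_roster(cfg, seed = roster_seed)
  truth <- simulate_true_events(roster, indicator_catalogue(), start, end,
                                params)
  list(roster = roster, truth = truth,
       counts = propagate_journey(truth, params))
}

# Register rows that are fully valid under default_rule_set().
valid_register_rows <- function(n = 10) {
  tibble::tibble(
    facility_id = "F001", district = "D1", service_area = "OPD",
    month = "2016-01",
    sex = rep(c("M", "F"), length.out = n),
    age = as.character(seq_len(n) + 10),
    weight = rep("45.5", n), height = rep("150", n),
    diagnosis = rep("malaria", n), severity = rep("mild", n),
    yes_no_code = rep(c("N", "H"), length.out = n))
}
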