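test_that("simulated roster honours configured counts and is reproducible", {
  roster <- simulate_roster(roster_config(), seed = 7)
  expect_equal(nrow(roster), 115)
  expect_equal(unname(table(roster$level)[c("dispensary", "health_centre",
                                            "hospital")]),
               c(67L, 36L, 12L), ignore_attr = TRUE)
  expect_equal(sum(roster$district == "Kinondoni"), 18)
  expect_setequal(unique(roster$setting), c("urban", "rural"))
  expect_true(all(nchar(roster$offered) > 0))
  expect_identical(roster, simulate_roster(roster_config(), seed = 7))
  expect_false(identical(roster, simulate_roster(roster_config(), seed = 8)))

  empty <- roster_config(
    districts = tibble::tibble(district = character(),
                               setting = character(),
                               n_facilities = integer()),
    level_counts = c(dispensary = 0L, health_centre = 0L, hospital = 0L))
  expect_equal(nrow(simulate_roster(empty, seed = 1)), 0)
})

test_that("roster config rejects invalid specifications", {
  expect_error(roster_config(level_counts = c(dispensary = 1L,
                                              health_centre = 0L,
                                              hospital = 0L)),
               "sum")
  bad_d <- default_districts()
  bad_d$setting[1] <- "periurban"
  expect_error(roster_config(districts = bad_d), "urban")
  expect_error(roster_config(ownership_probs = c(government = 1,
                                                 faith_based = 1,
                                                 private = 0)), "sum to 1")
})

test_that("true event counts have the configured cardinality and mean", {
  p0 <- journey_params(mean_monthly_volume = 0, seed = 1)
  roster1 <- simulate_roster(roster_config(
    districts = tibble::tibble(district = "D1", setting = "rural",
                               n_facilities = 1L),
    level_counts = c(dispensary = 1L, health_centre = 0L, hospital = 0L),
    offer_probs = c(OPD = 1)), seed = 1)
  ind1 <- indicator_catalogue()[indicator_catalogue()$indicator_id == "OPD01", ]
  ev0 <- simulate_true_events(roster1, ind1, "2014-01", "2014-12", p0)
  expect_equal(nrow(ev0), 12)       # one facility x one indicator x 12 months
  expect_true(all(ev0$true_count == 0))

  # Monte-Carlo: pooled mean within 3 standard errors of the configured mean
  p50 <- journey_params(mean_monthly_volume = 50, seed = 11)
  sj <- small_journey(p50, n_fac = 14, start = "2014-01", end = "2017-12")
  truth <- sj$truth
  expect_gte(nrow(truth), 10000)
  se <- sqrt(50 / nrow(truth))      # Poisson: var = mean
  expect_lt(abs(mean(truth$true_count) - 50), 3 * se)
  # indicators outside offered areas emit no rows
  expect_setequal(unique(truth$service_area), c("OPD", "ANC"))
})

test_that("lossless parameters give five identical present sources", {
  p <- journey_params(seed = 3)     # neutral defaults: lossless journey
  sj <- small_journey(p)
  ct <- sj$counts
  for (src in JOURNEY_SOURCES) {
    expect_false(anyNA(ct[[src]]))
    expect_equal(ct[[src]], ct$true_count)
  }
})

test_that("forced transmission loss empties district and DHIS2 sources", {
  p <- journey_params(p_transmission_loss = 1, seed = 3)
  ct <- small_journey(p)$counts
  expect_true(all(is.na(ct$district_report)))
  expect_true(all(is.na(ct$dhis2)))
  expect_false(anyNA(ct$facility_report))
})

test_that("absence dependencies follow the journey structure", {
  p <- journey_params(p_facility_report_absent = 0.5,
                      p_register_absent = 0.5, seed = 9)
  ct <- small_journey(p)$counts
  # report absent => district and dhis2 absent
  expect_true(all(is.na(ct$district_report[is.na(ct$facility_report)])))
  expect_true(all(is.na(ct$dhis2[is.na(ct$facility_report)])))
  # register absent does not block the report
  reg_absent <- is.na(ct$register)
  expect_gt(sum(reg_absent), 0)
  expect_gt(sum(!is.na(ct$facility_report[reg_absent])), 0)
})

test_that("binomial thinning is recovered in the pooled register ratio", {
  p <- journey_params(p_register_miss = 0.2, seed = 21)
  sj <- small_journey(p, n_fac = 8, start = "2014-01", end = "2016-12")
  ct <- sj$counts
  n_truth <- sum(ct$true_count)
  ratio <- sum(ct$tally) / sum(ct$register)    # tally carries the truth here
  se <- sqrt(0.8 * 0.2 / n_truth) / 0.8^2      # delta method for N/S
  expect_lt(abs(ratio - 1.25), 3 * se)
})

test_that("propagation yields only nonnegative integer counts and is deterministic", {
  p <- default_journey_params(seed = 4)
  sj <- small_journey(p)
  ct <- sj$counts
  for (src in JOURNEY_SOURCES) {
    v <- ct[[src]][!is.na(ct[[src]])]
    expect_true(all(v >= 0))
    expect_true(is.integer(ct[[src]]))
  }
  expect_identical(ct, propagate_journey(sj$truth, p))
})

test_that("per-facility substreams shield facilities from roster growth", {
  p <- journey_params(p_register_miss = 0.3, seed = 6)
  big <- small_journey(p, n_fac = 6)
  small <- small_journey(p, n_fac = 6)
  # same roster seed: first facilities identical; now grow the roster
  cfg2 <- roster_config(
    districts = tibble::tibble(district = c("D1", "D2"),
                               setting = c("urban", "rural"),
                               n_facilities = c(3L, 3L)),
    level_counts = c(dispensary = 5L, health_centre = 1L, hospital = 0L),
    offer_probs = c(OPD = 1, ANC = 1))
  roster <- simulate_roster(cfg2, seed = 42)
  truth_sub <- simulate_true_events(roster[1:3, ], indicator_catalogue(),
                                    "2016-01", "2016-12", p)
  truth_all <- simulate_true_events(roster, indicator_catalogue(),
                                    "2016-01", "2016-12", p)
  keep <- truth_all$facility_id %in% roster$facility_id[1:3]
  expect_identical(truth_sub, truth_all[keep, ])
})

test_that("register-row simulator hits configured blank and invalid rates", {
  roster1 <- simulate_roster(roster_config(
    districts = tibble::tibble(district = "D1", setting = "rural",
                               n_facilities = 1L),
    level_counts = c(dispensary = 1L, health_centre = 0L, hospital = 0L),
    offer_probs = c(OPD = 1)), seed = 2)

  none <- simulate_register_rows(
    roster1, "2016-01", "2016-06",
    error_rates = tibble::tibble(field = "weight", blank_rate = 0,
                                 invalid_rate = 0),
    rows_per_month = 20, seed = 5)
  flds <- c("sex", "age", "weight", "height", "diagnosis", "severity",
            "yes_no_code")
  expect_true(all(vapply(flds, function(f) all(none[[f]] != ""), TRUE)))

  all_bad <- simulate_register_rows(
    roster1, "2016-01", "2016-03",
    error_rates = tibble::tibble(field = "yes_no_code", blank_rate = 0,
                                 invalid_rate = 1),
    rows_per_month = 10, seed = 5)
  expect_true(all(!all_bad$yes_no_code %in% c("N", "H")))

  # blank rate 0.3 on weight over >= 10,000 rows: within 3 binomial SEs
  many <- simulate_register_rows(
    roster1, "2014-01", "2017-12",
    error_rates = tibble::tibble(field = "weight", blank_rate = 0.3,
                                 invalid_rate = 0),
    rows_per_month = 250, seed = 8)
  n <- nrow(many)
  expect_gte(n, 10000)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(many$weight == "") - 0.3), 3 * se)

  expect_error(simulate_register_rows(
    roster1, "2016-01", "2016-02",
    error_rates = tibble::tibble(field = "eye_colour", blank_rate = 0.1,
                                 invalid_rate = 0)),
    "eye_colour")
})

test_that("journey parameter validation and serialisation round-trip", {
  expect_error(journey_params(p_register_miss = 1.2), "probability")
  expect_error(journey_params(compile_mode_probs = c(0.5, 0.4, 0.3)),
               "sum")
  expect_error(journey_params(report_inflation_factor = 0), "> 0")
  p <- default_journey_params(seed = 13)
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_journey_params(p, f)
    q <- read_journey_params(f)
    expect_equal(q[setdiff(names(q), "mean_monthly_volume")],
                 p[setdiff(names(p), "mean_monthly_volume")])
    expect_equal(as.data.frame(q$mean_monthly_volume),
                 as.data.frame(p$mean_monthly_volume))
  }
})
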