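test_that("difference ratios and their degenerate flags", {
  expect_equal(difference_ratio(100, 100), 1)
  expect_equal(difference_ratio(309, 100), 3.09)
  expect_equal(dr_flag(difference_ratio(0, 0)), "undefined_0_over_0")
  expect_equal(dr_flag(difference_ratio(7, 0)), "infinite_over")
  expect_equal(dr_flag(difference_ratio(3, 4)), "ok")
  expect_error(difference_ratio(-1, 10), "nonnegative")
})

test_that("match categories partition [0, Inf) across all printed thresholds", {
  expect_equal(as.character(categorize_dr(1.00)), "matched")
  expect_equal(as.character(categorize_dr(2.01)), "extremely_over")
  expect_equal(as.character(categorize_dr(0.5)), "moderately_under")
  expect_equal(as.character(categorize_dr(Inf)), "extremely_over")
  expect_true(is.na(categorize_dr(NaN)))
  expect_error(categorize_dr(-0.1), "negative")

  eps <- 1e-9
  bounds <- c(0.5, 0.75, 0.95, 1.05, 1.25, 1.5, 2)
  grid <- sort(c(0, bounds, bounds - eps, bounds + eps,
                 seq(0.01, 3, by = 0.01), 10, 1e6))
  cats <- categorize_dr(grid)
  expect_false(anyNA(cats))                      # exactly one category each
  # closures at the printed boundaries
  expect_equal(as.character(categorize_dr(c(0.5, 0.75, 0.95, 1.05))),
               c("moderately_under", "moderately_under", "matched",
                 "matched"))
  expect_equal(as.character(categorize_dr(c(1.25, 1.5, 2))),
               c("moderately_matched", "moderately_over", "highly_over"))
  expect_equal(as.character(categorize_dr(c(0.49, 0.76, 1.06, 1.26, 1.51))),
               c("highly_under", "moderately_matched", "moderately_matched",
                 "moderately_over", "highly_over"))
  # the configurable 0.5 closure
  expect_equal(as.character(categorize_dr(0.5, half_rule = "highly_under")),
               "highly_under")
})

test_that("index definitions map onto the three journey phases", {
  expect_equal(phase_of("Diff1"), "health_facility")
  expect_equal(phase_of("Diff4"), "transmission")
  expect_equal(phase_of("Diff6"), "robust")
  expect_equal(phase_of(c("Diff2", "Diff3", "Diff5")),
               c("health_facility", "transmission", "transmission"))
  expect_error(phase_of("Diff7"), "unknown")
  tab <- diff_index_table()
  expect_equal(tab$index_id, paste0("Diff", 1:6))
})

test_that("the six indices on hand-built rows", {
  one <- make_counts(register = 10, tally = 12, facility_report = 13,
                     district_report = 13, dhis2 = 13)
  res <- compute_diff_indices(one)
  expect_equal(res$dr, c(1.2, 1.3, 1.0, 1.0, 1.0, 1.3))
  expect_equal(res$n_pairs, rep(1L, 6))

  same <- make_counts(register = c(5, 9, 30))
  res2 <- compute_diff_indices(same)
  expect_true(all(res2$dr == 1))
  expect_true(all(res2$category == "matched"))

  # absent district copies: Diff3/Diff4 carry no pairs, the rest compute
  noda <- make_counts(register = c(10, 20), tally = c(11, 21),
                      facility_report = c(12, 22),
                      district_report = c(NA, NA), dhis2 = c(12, 22))
  res3 <- compute_diff_indices(noda)
  expect_equal(res3$flag[res3$index_id %in% c("Diff3", "Diff4")],
               c("no_pairs", "no_pairs"))
  expect_equal(res3$n_pairs[res3$index_id == "Diff6"], 2L)
  expect_false(anyNA(res3$dr[res3$index_id %in%
                               c("Diff1", "Diff2", "Diff5", "Diff6")]))
})

test_that("pooled ratios agree with a brute-force re-summation oracle", {
  set.seed(321)
  for (i in 1:15) {
    n <- sample(20:80, 1)
    vals <- function() {
      v <- rpois(n, 30)
      v[runif(n) < 0.2] <- NA
      as.integer(v)
    }
    counts <- make_counts(register = vals(), tally = vals(),
                          facility_report = vals(),
                          district_report = vals(), dhis2 = vals(),
                          month = rep("2016-01", n),
                          indicator_id = sprintf("OPD%02d", rep(1:4, length.out = n)))
    res <- compute_diff_indices(counts)
    tab <- diff_index_table()
    for (j in 1:6) {
      expect_equal(res$dr[j],
                   pooled_dr_oracle(counts, tab$numerator[j],
                                    tab$denominator[j]))
    }
    # pooled identity: Diff6 is the ratio of total dhis2 to total register
    expect_equal(res$dr[res$index_id == "Diff6"],
                 pooled_dr_oracle(counts, "dhis2", "register"))
  }
})

test_that("stratified accuracy is consistent, additive and scale invariant", {
  p <- default_journey_params(seed = 19)
  sj <- small_journey(p, n_fac = 4, start = "2015-01", end = "2016-12")
  ct <- sj$counts

  # constant grouping attribute reproduces the ungrouped table
  by_const <- stratified_accuracy(ct, by = "setting")
  flat <- compute_diff_indices(ct)
  for (st in unique(by_const$setting)) {
    expect_equal(by_const$dr[by_const$setting == st],
                 compute_diff_indices(ct[ct$setting == st, ])$dr)
  }

  # splitting by year and recombining the pooled sums gives the all-year dr
  by_year <- stratified_accuracy(ct, by = "year")
  for (id in flat$index_id) {
    rows <- by_year[by_year$index_id == id, ]
    expect_equal(sum(rows$numerator_sum) / sum(rows$denominator_sum),
                 flat$dr[flat$index_id == id])
  }

  # multiplying every count by k leaves all ratios unchanged
  k <- 7L
  scaled <- dplyr::mutate(ct, dplyr::across(
    dplyr::all_of(JOURNEY_SOURCES), ~ .x * k))
  expect_equal(compute_diff_indices(scaled)$dr, flat$dr)

  expect_error(stratified_accuracy(ct, by = "region"), "unknown")
  expect_error(compute_diff_indices(ct[0, ]), "no rows")
})

test_that("journey thinning rates are recovered as 1/(1-p) in the indices", {
  p <- journey_params(p_register_miss = 0.5, seed = 57)
  sj <- small_journey(p, n_fac = 8, start = "2014-01", end = "2016-12")
  ct <- sj$counts
  res <- compute_diff_indices(ct)
  expect_true(all(res$n_pairs >= 1000))
  n_truth <- sum(ct$true_count)
  se <- sqrt(0.5 * 0.5 / n_truth) / 0.5^2      # delta method for N/S
  for (id in c("Diff1", "Diff2")) {
    expect_lt(abs(res$dr[res$index_id == id] - 2), 3 * se)
  }
  for (id in c("Diff3", "Diff4", "Diff5")) {
    expect_equal(res$dr[res$index_id == id], 1)
  }
})
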