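#' The six difference-ratio indices and their journey phases
#'
#' Each index compares pooled counts in a later (numerator) source against
#' an earlier (denominator) source of the data journey:
#'
#' | index | numerator / denominator | phase |
#' |-------|--------------------------|-------|
#' | Diff1 | tally / register | health_facility |
#' | Diff2 | facility_report / register | health_facility |
#' | Diff3 | district_report / facility_report | transmission |
#' | Diff4 | dhis2 / district_report | transmission |
#' | Diff5 | dhis2 / facility_report | transmission |
#' | Diff6 | dhis2 / register | robust |
#'
#' The health-facility phase covers recording through report compilation;
#' the transmission phase covers report submission, filing and DHIS2 entry
#' (Diff3 captures documented revisions of the submitted copy, Diff4
#' undocumented revisions at entry); the robust phase compares the two
#' extreme ends of the journey, register recounts against DHIS2.
#'
#' @return a tibble: `index_id`, `numerator`, `denominator`, `phase`
#' @export
diff_index_table <- function() {
  tibble::tribble(
    ~index_id, ~numerator,        ~denominator,      ~phase,
    "Diff1",   "tally",           "register",        "health_facility",
    "Diff2",   "facility_report", "register",        "health_facility",
    "Diff3",   "district_report", "facility_report", "transmission",
    "Diff4",   "dhis2",           "district_report", "transmission",
    "Diff5",   "dhis2",           "facility_report", "transmission",
    "Diff6",   "dhis2",           "register",        "robust")
}

#' Journey phase of a difference-ratio index
#'
#' @param index_id one or more of `"Diff1"`..`"Diff6"`
#' @return character vector of phases
#' @export
#' @examples
#' phase_of(c("Diff1", "Diff4", "Diff6"))
phase_of <- function(index_id) {
  tab <- diff_index_table()
  i <- match(index_id, tab$index_id)
  if (anyNA(i))
    abort(sprintf("unknown index id(s): %s",
                  paste(index_id[is.na(i)], collapse = ", ")))
  tab$phase[i]
}

#' Difference ratio of pooled counts
#'
#' The ratio of an indicator's pooled count in a subsequent source to its
#' pooled count in an earlier source. DR > 1 means over-representation in
#' the later source, DR < 1 under-representation. Degenerate denominators
#' are flagged rather than silently dropped: `0/0` yields `NaN` (flag
#' `undefined_0_over_0`) and `positive/0` yields `Inf` (flag
#' `infinite_over`); see [dr_flag()].
#'
#' @param numerator_sum,denominator_sum nonnegative pooled counts
#' @return numeric ratio(s); `NaN` / `Inf` in the degenerate cases
#' @export
#' @examples
#' difference_ratio(309, 100)  # 3.09
difference_ratio <- function(numerator_sum, denominator_sum) {
  if (any(numerator_sum < 0, na.rm = TRUE) ||
      any(denominator_sum < 0, na.rm = TRUE))
    abort("pooled counts must be nonnegative")
  numerator_sum / denominator_sum
}

#' Audit flag for a difference ratio
#'
#' @param dr values from [difference_ratio()]
#' @return `"ok"`, `"undefined_0_over_0"` (0/0) or `"infinite_over"`
#'   (positive over zero)
#' @export
dr_flag <- function(dr) {
  ifelse(is.nan(dr), "undefined_0_over_0",
         ifelse(is.infinite(dr), "infinite_over", "ok"))
}

#' Seven-level match category of a difference ratio
#'
#' Categorises a DR against the standard thresholds, from `matched`
#' (within +/- 5% of 1) to `extremely_over` (DR > 2):
#' `highly_under` \[0, 0.5), `moderately_under` \[0.5, 0.75\],
#' `moderately_matched` (0.75, 0.95) or (1.05, 1.25\],
#' `matched` \[0.95, 1.05\], `moderately_over` (1.25, 1.5\],
#' `highly_over` (1.5, 2\], `extremely_over` (2, Inf). The categories
#' partition \[0, Inf); an `Inf` ratio (positive over zero) maps to
#' `extremely_over`, a `NaN` ratio (0/0) to `NA`. The printed threshold
#' conventions leave 0.5 and 0.75 ambiguous; both default to
#' `moderately_under`, and `half_rule = "highly_under"` moves the 0.5
#' boundary down instead.
#'
#' @param dr nonnegative ratio(s), possibly `Inf`/`NaN`
#' @param half_rule which side DR = 0.5 exactly falls on
#' @return factor over the seven category labels (plus `NA` for 0/0)
#' @export
#' @examples
#' categorize_dr(c(1.00, 2.01, 0.5))
categorize_dr <- function(dr, half_rule = c("moderately_under",
                                            "highly_under")) {
  half_rule <- match.arg(half_rule)
  if (any(dr < 0, na.rm = TRUE)) abort("difference ratios cannot be negative")
  levs <- c("highly_under", "moderately_under", "moderately_matched",
            "matched", "moderately_over", "highly_over", "extremely_over")
  under_cut <- if (half_rule == "moderately_under") 0.5 else 0.5 + 1e-12
  lab <- rep(NA_character_, length(dr))
  ok <- !is.na(dr) & !is.nan(dr)
  x <- dr[ok]
  lab[ok] <-
    ifelse(is.infinite(x) | x > 2, "extremely_over",
    ifelse(x > 1.5, "highly_over",
    ifelse(x > 1.25, "moderately_over",
    ifelse(x > 1.05, "moderately_matched",
    ifelse(x >= 0.95, "matched",
    ifelse(x > 0.75, "moderately_matched",
    ifelse(x >= under_cut, "moderately_under", "highly_under")))))))
  factor(lab, levels = levs)
}

#' Compute the six difference-ratio indices on a set of counts
#'
#' For each index, sums numerator and denominator over the
#' facility-months where **both** sources are present (pairwise-complete
#' pooling; absence is never imputed as zero), takes the ratio of pooled
#' sums (not the mean of per-row ratios), and attaches the phase, audit
#' flag and match category. A stratum with no pairwise-complete rows for
#' an index gets `n_pairs = 0` and flag `no_pairs`.
#'
#' @param counts wide counts tibble; pre-filter with [dplyr::filter()] to
#'   restrict the window or stratum
#' @param half_rule passed to [categorize_dr()]
#' @return a tibble with one row per index: `index_id`, `phase`,
#'   `numerator_source`, `denominator_source`, `numerator_sum`,
#'   `denominator_sum`, `n_pairs`, `dr`, `flag`, `category`
#' @export
compute_diff_indices <- function(counts, half_rule = "moderately_under") {
  if (nrow(counts) == 0) abort("no rows to compute difference ratios from")
  tab <- diff_index_table()
  res <- lapply(seq_len(nrow(tab)), function(i) {
    num <- counts[[tab$numerator[i]]]
    den <- counts[[tab$denominator[i]]]
    both <- !is.na(num) & !is.na(den)
    tibble::tibble(index_id = tab$index_id[i], phase = tab$phase[i],
                   numerator_source = tab$numerator[i],
                   denominator_source = tab$denominator[i],
                   numerator_sum = sum(num[both]),
                   denominator_sum = sum(den[both]),
                   n_pairs = sum(both))
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(
      dr = ifelse(.data$n_pairs == 0, NA_real_,
                  difference_ratio(.data$numerator_sum,
                                   .data$denominator_sum)),
      flag = ifelse(.data$n_pairs == 0, "no_pairs", dr_flag(.data$dr)),
      category = categorize_dr(.data$dr, half_rule = half_rule))
}

#' Stratified difference-ratio accuracy table
#'
#' [compute_diff_indices()] applied within every stratum defined by `by`,
#' with deterministic ordering (stratum lexicographic, then index
#' ascending). The `year` stratifier is derived from the month string.
#'
#' @param counts wide counts tibble
#' @param by stratifiers among `year`, `service_area`, `indicator_id`,
#'   `level`, `ownership`, `district`, `setting`, `facility_id`
#' @param half_rule passed to [categorize_dr()]
#' @return a tibble: stratum columns, then one row per index per stratum
#' @export
stratified_accuracy <- function(counts, by = character(),
                                half_rule = "moderately_under") {
  ok <- c("year", "service_area", "indicator_id", "level", "ownership",
          "district", "setting", "facility_id")
  if (length(bad <- setdiff(by, ok)))
    abort(sprintf("unknown grouping attribute(s): %s",
                  paste(bad, collapse = ", ")))
  if ("year" %in% by) counts$year <- month_year(counts$month)
  counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ compute_diff_indices(.x, half_rule = half_rule)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(by, "index_id"))))
}

#' Write an accuracy table to CSV
#'
#' Difference ratios are printed to two decimals (computation is
#' unrounded); flags and categories are carried as text.
#'
#' @param x output of [stratified_accuracy()] or [compute_diff_indices()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_accuracy <- function(x, path) {
  out <- dplyr::mutate(x, dr = round(.data$dr, 2),
                       category = as.character(.data$category))
  readr::write_csv(out, path, na = "")
  invisible(path)
}
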