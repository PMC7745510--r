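#' A validation rule for one register field
#'
#' @param field field name as it appears in the register rows
#' @param kind `"coded"` (value must be one of `allowed_codes`),
#'   `"numeric"` (value must parse and fall in `numeric_range`), or
#'   `"free_text"` (any non-blank value is valid)
#' @param allowed_codes character set of valid codes (coded fields);
#'   comparison is case-sensitive and after whitespace trimming
#' @param numeric_range optional length-2 bounds for numeric fields
#' @param required must the field be filled? A blank required field counts
#'   as a blank violation; blanks in optional fields are ignored.
#' @param required_if name of a sibling field: the requirement (and hence
#'   blank counting) applies only to rows where that sibling is non-blank.
#'   Used for severity, which is only expected when a diagnosis was
#'   recorded.
#' @return an object of class `field_rule`
#' @export
field_rule <- function(field, kind = c("coded", "numeric", "free_text"),
                       allowed_codes = NULL, numeric_range = NULL,
                       required = TRUE, required_if = NULL) {
  kind <- match.arg(kind)
  if (kind == "coded" && (is.null(allowed_codes) || !length(allowed_codes)))
    abort(sprintf("coded rule for '%s' needs non-empty allowed_codes", field))
  if (kind == "numeric" && !is.null(numeric_range) &&
      (length(numeric_range) != 2 || numeric_range[1] > numeric_range[2]))
    abort("numeric_range must be c(lower, upper)")
  structure(list(field = field, kind = kind,
                 allowed_codes = allowed_codes,
                 numeric_range = numeric_range,
                 required = isTRUE(required), required_if = required_if),
            class = "field_rule")
}

#' Default register field rules
#'
#' The audit rules for the standard patient-row register fields: sex, age,
#' weight and height are required (height and weight are the fields most
#' often left blank in practice); diagnosis is required free text;
#' severity is a coded field required only when a diagnosis is recorded;
#' the yes/no column must use the instructed codes `N` (Ndiyo/yes) and `H`
#' (Hapana/no) — the English `Y`/`Yes` tokens are coding violations. Code
#' comparison is case-sensitive. Pure: returns the same rules on every
#' call.
#'
#' @return a named list of [field_rule()] objects
#' @export
default_rule_set <- function() {
  rules <- list(
    field_rule("sex", "coded", allowed_codes = c("M", "F")),
    field_rule("age", "numeric", numeric_range = c(0, 120)),
    field_rule("weight", "numeric", numeric_range = c(0.5, 250)),
    field_rule("height", "numeric", numeric_range = c(30, 250)),
    field_rule("diagnosis", "free_text"),
    field_rule("severity", "coded", allowed_codes = c("mild", "severe"),
               required_if = "diagnosis"),
    field_rule("yes_no_code", "coded", allowed_codes = c("N", "H")))
  setNames(rules, vapply(rules, `[[`, "", "field"))
}

# per-row violation matrix for one rule; returns list(blank=, invalid=)
apply_field_rule <- function(rule, rows) {
  v <- trimws(rows[[rule$field]])
  v[is.na(v)] <- ""
  blank <- v == ""
  required_here <- rep(rule$required, length(v))
  if (!is.null(rule$required_if)) {
    sib <- trimws(rows[[rule$required_if]])
    sib[is.na(sib)] <- ""
    required_here <- required_here & sib != ""
  }
  blank_viol <- blank & required_here
  invalid <- !blank & switch(rule$kind,
    coded = !v %in% rule$allowed_codes,
    numeric = {
      num <- suppressWarnings(as.numeric(v))
      bad <- !is.finite(num)
      if (!is.null(rule$numeric_range))
        bad <- bad | (is.finite(num) &
                        (num < rule$numeric_range[1] |
                         num > rule$numeric_range[2]))
      bad
    },
    free_text = rep(FALSE, length(v)))
  list(blank = blank_viol, invalid = invalid)
}

#' Rule-based completeness audit of register rows
#'
#' Checks every audited field of every register row against its
#' [field_rule()]: a blank required field counts as blank, a present value
#' outside the allowed codes or numeric range counts as invalid, and a row
#' is adherent iff it carries no violation at all. Results are reported
#' per field and stratum as counts and percentage rates, with an overall
#' adherence rate per stratum.
#'
#' @param rows register rows (wide, as from [simulate_register_rows()] or
#'   [read_dataset()])
#' @param rules named list of [field_rule()]s, e.g. [default_rule_set()];
#'   every non-metadata column of `rows` must have a rule
#' @param by stratifier columns among the metadata (`district`,
#'   `service_area`, `month`, `facility_id`, plus `year`)
#' @return a list of class `completeness_report`: `$by_field` — per
#'   (stratum, field): `n_rows`, `n_blank`, `n_invalid`, `blank_rate`,
#'   `invalid_rate`; `$adherence` — per stratum: `n_rows`, `n_adherent`,
#'   `adherence_rate`
#' @export
audit_register_rows <- function(rows, rules = default_rule_set(),
                                by = character()) {
  meta <- c("facility_id", "district", "service_area", "month", "year",
            "row")
  if ("year" %in% by && !"year" %in% names(rows))
    rows$year <- month_year(rows$month)
  field_cols <- setdiff(names(rows), meta)
  if (length(bad <- setdiff(field_cols, names(rules))))
    abort(sprintf("no rule for field(s): %s", paste(bad, collapse = ", ")))
  if (length(bad <- setdiff(by, names(rows))))
    abort(sprintf("unknown stratifier(s): %s", paste(bad, collapse = ", ")))
  audited <- rules[field_cols]
  viol <- lapply(audited, apply_field_rule, rows = rows)
  any_viol <- Reduce(`|`, lapply(viol, function(x) x$blank | x$invalid),
                     init = rep(FALSE, nrow(rows)))
  per_field <- dplyr::bind_rows(lapply(names(audited), function(f) {
    dplyr::bind_cols(rows[by],
                     tibble::tibble(field = f, blank = viol[[f]]$blank,
                                    invalid = viol[[f]]$invalid))
  })) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "field")))) |>
    dplyr::summarise(n_rows = dplyr::n(),
                     n_blank = sum(.data$blank),
                     n_invalid = sum(.data$invalid), .groups = "drop") |>
    dplyr::mutate(blank_rate = 100 * .data$n_blank / .data$n_rows,
                  invalid_rate = 100 * .data$n_invalid / .data$n_rows)
  adherence <- dplyr::bind_cols(rows[by],
                                tibble::tibble(adherent = !any_viol)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_rows = dplyr::n(),
                     n_adherent = sum(.data$adherent), .groups = "drop") |>
    dplyr::mutate(adherence_rate = 100 * .data$n_adherent / .data$n_rows)
  structure(list(by_field = per_field, adherence = adherence, by = by),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("<completeness_report> stratified by: %s\n",
              if (length(x$by)) paste(x$by, collapse = ", ") else "(none)"))
  print(x$by_field, ...)
  cat("adherence:\n")
  print(x$adherence, ...)
  invisible(x)
}

#' Write a completeness report to CSV
#'
#' Per-field rows carry the stratum's overall adherence rate in an extra
#' column; rates are printed to one decimal.
#'
#' @param x a `completeness_report`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_completeness <- function(x, path) {
  stopifnot(inherits(x, "completeness_report"))
  ad <- x$adherence[, c(x$by, "adherence_rate"), drop = FALSE]
  out <- if (length(x$by)) dplyr::left_join(x$by_field, ad, by = x$by)
         else dplyr::cross_join(x$by_field, ad)
  out <- dplyr::mutate(out,
                       dplyr::across(dplyr::ends_with("_rate"), ~ round(.x, 1)))
  readr::write_csv(out, path)
  invisible(path)
}
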