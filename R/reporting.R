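#' Fixed colour legend for the match categories
#'
#' Colour-blind-safe hex colours (Okabe–Ito derived), one per match
#' category, used by [export_colour_coded_table()].
#'
#' @return named character vector of hex colours
#' @export
match_palette <- function() {
  c(highly_under       = "#0072B2",
    moderately_under   = "#56B4E9",
    moderately_matched = "#F0E442",
    matched            = "#009E73",
    moderately_over    = "#E69F00",
    highly_over        = "#D55E00",
    extremely_over     = "#CC79A7")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a colour-coded accuracy table
#'
#' Writes an HTML rendering of a difference-ratio table in which each DR
#' cell (two decimals) is shaded by its match category, with the fixed
#' seven-colour legend emitted alongside, plus a CSV twin carrying the
#' category as text.
#'
#' @param results output of [stratified_accuracy()] or
#'   [compute_diff_indices()]; must be non-empty
#' @param path output path for the HTML file; the CSV twin replaces the
#'   extension with `.csv`
#' @param title heading placed above the table
#' @return named character vector of the two paths, invisibly
#' @export
export_colour_coded_table <- function(results, path,
                                      title = "Difference-ratio accuracy") {
  if (is.null(results) || nrow(results) == 0)
    abort("refusing to export an empty results table")
  pal <- match_palette()
  csv_path <- sub("\\.[A-Za-z]+$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  write_accuracy(results, csv_path)

  show_cols <- setdiff(names(results),
                       c("dr", "category", "flag", "phase",
                         "numerator_source", "denominator_source"))
  header <- paste0("<tr>", paste0("<th>", html_escape(show_cols),
                                  "</th>", collapse = ""),
                   "<th>phase</th><th>DR</th></tr>")
  body <- vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    cat_i <- as.character(r$category)
    colour <- if (!is.na(cat_i)) pal[[cat_i]] else "#DDDDDD"
    dr_txt <- if (is.na(r$dr) || is.nan(r$dr)) r$flag
              else sprintf("%.2f", r$dr)
    cells <- vapply(show_cols,
                    function(cn) html_escape(as.character(r[[cn]])),
                    character(1))
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""),
           sprintf("<td>%s</td>", html_escape(r$phase)),
           sprintf("<td style='background:%s'>%s</td></tr>",
                   colour, html_escape(dr_txt)))
  }, character(1))
  legend <- paste0(
    "<p class='legend'>",
    paste(sprintf("<span style='background:%s'>&nbsp;&nbsp;</span> %s",
                  pal, names(pal)), collapse = " &middot; "),
    "</p>")
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<style>table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:3px 7px;",
    "font:13px sans-serif}</style>",
    sprintf("<title>%s</title></head><body><h2>%s</h2>",
            html_escape(title), html_escape(title)),
    legend, "<table>", header, paste(body, collapse = ""),
    "</table></body></html>")
  writeLines(html, path)
  invisible(c(html = path, csv = csv_path))
}

#' End-to-end pipeline configuration
#'
#' @param out_dir directory for all artifacts
#' @param start,end simulated month window (YYYY-MM, inclusive)
#' @param detailed_start,detailed_end sub-window used for the accuracy
#'   tables and the register-row completeness audit (the detailed-review
#'   subset); defaults to the last 12 months of the window
#' @param by stratifiers used for the availability and accuracy tables
#' @param seed global seed; all stage seeds derive from it
#' @param params a [journey_params()]; its seed is overridden by `seed`
#' @param roster_cfg a [roster_config()]
#' @param register_rows generate register rows and run the completeness
#'   audit? (skipped with a logged notice when `FALSE`)
#' @param rows_per_month register rows per facility-area-month
#' @return a list of class `run_config`
#' @export
run_config <- function(out_dir, start = "2014-01", end = "2017-09",
                       detailed_start = NULL, detailed_end = NULL,
                       by = c("service_area"), seed = 1L,
                       params = default_journey_params(seed),
                       roster_cfg = roster_config(),
                       register_rows = TRUE, rows_per_month = 3) {
  months <- month_seq(start, end)   # validates the window
  if (is.null(detailed_end)) detailed_end <- end
  if (is.null(detailed_start))
    detailed_start <- months[max(1L, length(months) - 11L)]
  month_seq(detailed_start, detailed_end)
  params$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, start = start, end = end,
                 detailed_start = detailed_start,
                 detailed_end = detailed_end, by = by,
                 seed = as.integer(seed), params = params,
                 roster_cfg = roster_cfg,
                 register_rows = isTRUE(register_rows),
                 rows_per_month = rows_per_month),
            class = "run_config")
}

#' Run the full simulate-and-assess pipeline
#'
#' Simulates a roster and its data journey, writes the dataset, then
#' computes the availability table, district reporting completeness, the
#' register completeness audit (on the detailed-review window) and the
#' stratified accuracy table, exporting each as CSV plus a colour-coded
#' HTML accuracy table and a JSON manifest (package version, seed, config
#' hash). Deterministic given the config: running the same config twice
#' yields byte-identical CSVs.
#'
#' @param config a [run_config()]
#' @param quiet suppress progress messages?
#' @return invisibly, a list with the computed objects and file paths
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("simulate: roster + %s..%s journey", config$start, config$end)
  roster <- simulate_roster(config$roster_cfg, seed = config$seed)
  indicators <- indicator_catalogue()
  truth <- simulate_true_events(roster, indicators, config$start,
                                config$end, config$params)
  counts <- propagate_journey(truth, config$params)
  rr <- NULL
  if (config$register_rows) {
    rr <- simulate_register_rows(roster, config$detailed_start,
                                 config$detailed_end,
                                 rows_per_month = config$rows_per_month,
                                 seed = config$seed)
  } else {
    say("completeness stage skipped: register rows disabled in config")
  }
  write_dataset(counts, config$out_dir, register_rows = rr,
                roster = roster, indicators = indicators)

  say("availability: stratified by %s", paste(config$by, collapse = ", "))
  avail <- availability_table(counts, by = config$by)
  write_availability(avail, file.path(config$out_dir, "availability.csv"))
  dist <- district_completeness_table(counts, by = "district")
  write_availability(dist, file.path(config$out_dir,
                                     "district_completeness.csv"))

  audit <- NULL
  if (!is.null(rr)) {
    say("completeness: auditing %d register rows", nrow(rr))
    audit <- audit_register_rows(rr, by = intersect(config$by,
                                                    c("district",
                                                      "service_area")))
    write_completeness(audit, file.path(config$out_dir, "completeness.csv"))
  }

  say("accuracy: difference ratios on %s..%s",
      config$detailed_start, config$detailed_end)
  detail <- dplyr::filter(counts,
                          .data$month >= config$detailed_start,
                          .data$month <= config$detailed_end)
  acc <- stratified_accuracy(detail, by = config$by)
  export_colour_coded_table(acc, file.path(config$out_dir, "accuracy.html"))

  cfg_path <- file.path(config$out_dir, "params.yaml")
  write_journey_params(config$params, cfg_path)
  manifest <- list(
    package = "hmisdq",
    version = as.character(utils::packageVersion("hmisdq")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    window = c(config$start, config$end),
    detailed_window = c(config$detailed_start, config$detailed_end),
    by = config$by,
    params_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(roster = roster, counts = counts, register_rows = rr,
                 availability = avail, district_completeness = dist,
                 completeness = audit, accuracy = acc,
                 out_dir = config$out_dir, manifest = manifest))
}
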