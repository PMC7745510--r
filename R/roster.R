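#' Roster specification for the facility simulator
#'
#' Describes the population of health facilities to generate: how many
#' facilities per district (with urban/rural setting), the marginal counts
#' of facility levels, ownership mix, and per-service-area offer
#' probabilities. Defaults mirror a published census of 115 primary-care
#' facilities in 11 districts: 67 dispensaries, 36 health centres and 12
#' hospitals, with OPD offered almost everywhere and IPD mostly in larger
#' facilities.
#'
#' @param districts data frame with columns `district`, `setting`
#'   (`"urban"`/`"rural"`) and `n_facilities`.
#' @param level_counts named integer vector over
#'   `c("dispensary", "health_centre", "hospital")`; must sum to the total
#'   facility count.
#' @param ownership_probs named probabilities over
#'   `c("government", "faith_based", "private")`, summing to 1.
#' @param offer_probs named probabilities, one per service area, that a
#'   facility offers that area.
#' @return an object of class `roster_config`
#' @export
roster_config <- function(districts = default_districts(),
                          level_counts = c(dispensary = 67L,
                                           health_centre = 36L,
                                           hospital = 12L),
                          ownership_probs = c(government = 0.70,
                                              faith_based = 0.20,
                                              private = 0.10),
                          offer_probs = default_offer_probs()) {
  districts <- tibble::as_tibble(districts)
  need <- c("district", "setting", "n_facilities")
  if (!all(need %in% names(districts)))
    abort("`districts` needs columns district, setting, n_facilities")
  if (!all(districts$setting %in% c("urban", "rural")))
    abort("`setting` must be 'urban' or 'rural'")
  if (any(districts$n_facilities < 0))
    abort("district facility counts must be >= 0")
  if (!setequal(names(level_counts), FACILITY_LEVELS))
    abort(sprintf("`level_counts` must be named over {%s}",
                  paste(FACILITY_LEVELS, collapse = ", ")))
  level_counts <- vapply(level_counts[FACILITY_LEVELS], as.integer, 1L)
  if (any(level_counts < 0)) abort("level counts must be >= 0")
  if (sum(level_counts) != sum(districts$n_facilities))
    abort(sprintf("level counts sum to %d but districts hold %d facilities",
                  sum(level_counts), sum(districts$n_facilities)))
  if (!setequal(names(ownership_probs), OWNERSHIP_TYPES) ||
      abs(sum(ownership_probs) - 1) > 1e-8)
    abort("`ownership_probs` must be named over the ownership types and sum to 1")
  if (!all(names(offer_probs) %in% SERVICE_AREAS) ||
      any(offer_probs < 0 | offer_probs > 1))
    abort("`offer_probs` must be probabilities named by service area")
  structure(list(districts = districts, level_counts = level_counts,
                 ownership_probs = ownership_probs[OWNERSHIP_TYPES],
                 offer_probs = offer_probs),
            class = "roster_config")
}

#' @rdname roster_config
#' @export
default_districts <- function() {
  tibble::tribble(
    ~district,    ~setting, ~n_facilities,
    "Dodoma",     "urban",  11L,
    "Igunga",     "urban",  10L,
    "Kahama",     "urban",  10L,
    "Kinondoni",  "urban",  18L,
    "Njombe",     "urban",  10L,
    "Hai",        "rural",  10L,
    "Kibaha",     "rural",   8L,
    "Mbinga",     "rural",  10L,
    "Mbulu",      "rural",   8L,
    "Nkasi",      "rural",  10L,
    "Tandahimba", "rural",  10L)
}

#' @rdname roster_config
#' @export
default_offer_probs <- function() {
  # observed offer frequencies out of 115 facilities
  c(OPD = 114, IPD = 43, ANC = 108, PNC = 105, LnD = 93, FP = 88,
    PITC = 94) / 115
}

#' Simulate a facility roster
#'
#' Draws a roster of facility profiles from a [roster_config()]: facility
#' identifiers, level, ownership, district, urban/rural setting and the set
#' of service areas offered. Level counts per roster match the
#' configuration exactly; ownership and offered areas are sampled from
#' their configured probabilities. Deterministic given `seed`.
#'
#' @param config a `roster_config`
#' @param seed integer seed
#' @return a tibble with one row per facility: `facility_id`, `level`,
#'   `ownership`, `district`, `setting`, and `offered` (a semicolon-joined
#'   string of offered service areas).
#' @export
#' @examples
#' roster <- simulate_roster(roster_config(), seed = 1)
#' table(roster$level)
simulate_roster <- function(config = roster_config(), seed = 1L) {
  stopifnot(inherits(config, "roster_config"))
  n <- sum(config$districts$n_facilities)
  if (n == 0) {
    return(tibble::tibble(facility_id = character(), level = character(),
                          ownership = character(), district = character(),
                          setting = character(), offered = character()))
  }
  set.seed(substream_seed(seed, "roster"))
  district <- rep(config$districts$district, config$districts$n_facilities)
  setting <- rep(config$districts$setting, config$districts$n_facilities)
  level <- sample(rep(FACILITY_LEVELS, config$level_counts))
  ownership <- sample(OWNERSHIP_TYPES, n, replace = TRUE,
                      prob = config$ownership_probs)
  areas <- names(config$offer_probs)
  offered <- vapply(seq_len(n), function(i) {
    on <- runif(length(areas)) < config$offer_probs
    if (!any(on)) on[which.max(config$offer_probs)] <- TRUE  # never empty
    paste(areas[on], collapse = ";")
  }, character(1))
  tibble::tibble(
    facility_id = sprintf("F%03d", seq_len(n)),
    level = level, ownership = ownership,
    district = district, setting = setting, offered = offered)
}

#' Split an `offered` string into a character vector of service areas
#' @param offered semicolon-joined service-area string(s)
#' @return a list of character vectors
#' @export
offered_areas <- function(offered) strsplit(offered, ";", fixed = TRUE)

#' Default indicator catalogue
#'
#' Thirty-four monthly indicators spread over the seven routine service
#' areas, with flags for the structural features known to make an
#' indicator error-prone: multiple contributing variables, disease-severity
#' categorisation, linkage to medicine dispensing, restriction to a client
#' subset, or a bounded time window. Flags are stored semicolon-joined for
#' CSV friendliness.
#'
#' @return a tibble: `indicator_id`, `service_area`, `label`, `age_split`,
#'   `complexity_flags`
#' @export
indicator_catalogue <- function() {
  spec <- list(
    OPD = c("New attendances" = "",
            "Repeat attendances" = "",
            "Malaria, blood smear positive" = "multi_variable",
            "Mild/severe anaemia" = "severity_categorised;multi_variable",
            "Pneumonia cases treated" = "medicine_linked",
            "Diarrhoea cases" = "severity_categorised",
            "Referrals out" = "",
            "Skin infections" = ""),
    IPD = c("Admissions" = "",
            "Severe anaemia admissions" = "severity_categorised",
            "Deaths within 48h" = "time_window",
            "Discharges" = ""),
    ANC = c("First ANC visits" = "",
            "Fourth or later ANC visits" = "subset_population",
            "TT2 vaccine doses given" = "medicine_linked",
            "IPT2 doses given" = "medicine_linked",
            "First visit before 12 weeks gestation" = "time_window",
            "Haemoglobin checked" = "multi_variable",
            "HIV tested at ANC" = "multi_variable",
            "HIV tested, under 25 years" = "subset_population;multi_variable"),
    PNC = c("Attendance within 48h of delivery" = "time_window",
            "Attendance days 3-7" = "time_window",
            "Breastfeeding counselling given" = "",
            "Postnatal complications" = "severity_categorised"),
    LnD = c("Deliveries at facility" = "",
            "Deliveries assisted by skilled attendant" = "multi_variable",
            "Live births" = ""),
    FP = c("New acceptors" = "",
           "Continuing users" = "",
           "Cervical cancer screening" = "subset_population",
           "Breast cancer screening" = "subset_population"),
    PITC = c("New clients tested" = "",
             "Clients tested positive" = "multi_variable",
             "Couples counselled" = "subset_population"))
  rows <- lapply(names(spec), function(area) {
    labs <- names(spec[[area]])
    tibble::tibble(
      indicator_id = sprintf("%s%02d", area, seq_along(labs)),
      service_area = area,
      label = labs,
      age_split = grepl("attendance|admission", labs, ignore.case = TRUE),
      complexity_flags = unname(spec[[area]]))
  })
  dplyr::bind_rows(rows)
}
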