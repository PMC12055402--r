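# Healthcare resource counting and costing: unit costs for non-inpatient
# activity, HRG lookup for inpatient episodes, NYHA-stratified summaries.

#' Count healthcare activity within follow-up
#'
#' Gathers dated activity rows by category: consultations (`gp`, `nurse`,
#' `telephone`, `out_of_hours`), hospital activity (`outpatient`, `ae`,
#' `critical_care`, and the inpatient types `elective`, `non_elective`,
#' `day_case`), and procedure events (codes in `procedure_codes`). Rows
#' outside the patient's follow-up are dropped; unknown categories are
#' dropped with a warning.
#'
#' @param ehr An `hcm_ehr` list (or equivalent tables).
#' @param cohort Cohort tibble (`patient_id`, `index_date`, `followup_end`).
#' @param categories Categories to keep (default: all known).
#' @param procedure_codes Codes in `clinical_events` counted as procedures.
#' @return Tibble `patient_id`, `date`, `category`, `n` (activity counts by
#'   patient, category and date) with an `hrg_code` column for inpatient
#'   rows.
#' @export
count_activity <- function(ehr, cohort,
                           categories = c("gp", "nurse", "telephone",
                                          "out_of_hours", "outpatient", "ae",
                                          "critical_care", "elective",
                                          "non_elective", "day_case",
                                          "procedure"),
                           procedure_codes = "PROC") {
  coh <- cohort
  if ("included" %in% names(coh)) coh <- filter(coh, .data$included)
  coh <- select(coh, "patient_id", "index_date", "followup_end")
  rows <- bind_rows(
    ehr$consultations |>
      select("patient_id", "date", category = "type") |>
      mutate(hrg_code = NA_character_),
    ehr$hospital_activity |>
      select("patient_id", date = "admit_date", category = "type", "hrg_code"),
    ehr$clinical_events |>
      filter(.data$code %in% procedure_codes) |>
      select("patient_id", "date") |>
      mutate(category = "procedure", hrg_code = NA_character_)
  )
  unknown <- setdiff(unique(rows$category), categories)
  if (length(unknown)) {
    warn(sprintf("unknown activity categor%s dropped: %s",
                 if (length(unknown) > 1) "ies" else "y",
                 paste(unknown, collapse = ", ")))
  }
  rows |>
    filter(.data$category %in% categories) |>
    inner_join(coh, by = "patient_id") |>
    filter(.data$date >= .data$index_date, .data$date < .data$followup_end) |>
    count(.data$patient_id, .data$date, .data$category, .data$hrg_code,
          name = "n") |>
    arrange(.data$patient_id, .data$date)
}

INPATIENT_TYPES <- c("elective", "non_elective", "day_case")

#' Cost non-inpatient activity with a unit-cost table
#'
#' Cost = count x unit cost x inflation factor. Every non-inpatient
#' category present must be priced; unpriced categories raise an error
#' naming them. Out-of-hours consultations are excluded from costing by
#' default (reported activity only).
#'
#' @param counts Output of [count_activity()].
#' @param unit_costs Unit-cost table, see [default_unit_costs()].
#' @param inflation Multiplicative uplift from the reference year.
#' @param exclude_categories Categories counted but never costed.
#' @return Tibble of dated cost items: `patient_id`, `date`, `category`,
#'   `component`, `cost`.
#' @export
cost_non_inpatient <- function(counts, unit_costs = default_unit_costs(),
                               inflation = 1,
                               exclude_categories = "out_of_hours") {
  check_that(inflation > 0, "inflation factor must be positive")
  check_that(all(unit_costs$unit_cost >= 0), "unit costs must be non-negative")
  x <- counts |>
    filter(!.data$category %in% c(INPATIENT_TYPES, exclude_categories))
  unpriced <- setdiff(unique(x$category), unit_costs$category)
  if (length(unpriced)) {
    abort(sprintf("unpriced activity categories: %s",
                  paste(unpriced, collapse = ", ")))
  }
  x |>
    inner_join(select(unit_costs, "category", "unit_cost", "component"),
               by = "category") |>
    mutate(cost = .data$n * .data$unit_cost * inflation) |>
    select("patient_id", "date", "category", "component", "cost")
}

#' Cost inpatient episodes with an HRG table
#'
#' Per-episode cost looked up by HRG currency code for elective,
#' non-elective and day-case stays. Episodes with missing or unknown HRG
#' codes are dropped with a warning (`missing_hrg = "drop"`) or raise an
#' error (`"error"`).
#'
#' @param counts Output of [count_activity()] (inpatient rows carry
#'   `hrg_code`).
#' @param hrg_costs HRG cost table, see [default_hrg_costs()].
#' @param missing_hrg Policy for unpriced episodes.
#' @param inflation Multiplicative uplift.
#' @return Tibble of dated cost items (component `"secondary_care"`).
#' @export
cost_inpatient <- function(counts, hrg_costs = default_hrg_costs(),
                           missing_hrg = c("drop", "error"), inflation = 1) {
  missing_hrg <- match.arg(missing_hrg)
  x <- counts |> filter(.data$category %in% INPATIENT_TYPES)
  priced <- x |>
    left_join(hrg_costs, by = "hrg_code")
  bad <- sum(is.na(priced$cost))
  if (bad > 0) {
    msg <- sprintf("%d inpatient episode(s) with missing/unknown HRG code", bad)
    if (missing_hrg == "error") abort(msg)
    warn(paste(msg, "dropped"))
    priced <- filter(priced, !is.na(.data$cost))
  }
  priced |>
    mutate(cost = .data$n * .data$cost * inflation,
           component = "secondary_care") |>
    select("patient_id", "date", "category", "component", "cost")
}

#' Summarize costs from pre-computed totals
#'
#' The reporting arithmetic shared by [stratified_costs()]: cost per
#' patient-year = total / person-years, reported to the nearest pound
#' (half-up); internal values stay unrounded in `cost_per_py_raw`.
#'
#' @param totals Tibble with `stratum`, `component`, `total`,
#'   `person_years`.
#' @return `totals` with `cost_per_py_raw` and `cost_per_py`.
#' @export
summarize_costs <- function(totals) {
  totals |>
    mutate(cost_per_py_raw = .data$total / .data$person_years,
           cost_per_py = round_half_up(.data$cost_per_py_raw, 0))
}

#' NYHA-stratified cost summary
#'
#' Attributes each dated cost item to the NYHA interval containing its date
#' (inpatient stays spanning a class change attribute their full cost to
#' the class at admission), sums by stratum and component, and divides by
#' the stratum person-years from the same trajectory. Adds `II+` (classes
#' II-IV pooled) and `overall` strata and a `total` component row per
#' stratum; items outside follow-up are dropped with a warning.
#'
#' @param cost_items Cost items from [cost_non_inpatient()] /
#'   [cost_inpatient()] (rows may be concatenated).
#' @param nyha_intervals NYHA interval tibble from [classify_nyha()].
#' @return Tibble `stratum`, `component`, `total`, `person_years`,
#'   `cost_per_py_raw`, `cost_per_py`.
#' @export
stratified_costs <- function(cost_items, nyha_intervals) {
  located <- cost_items |>
    left_join(select(nyha_intervals, "patient_id", "start", "end", "nyha_class"),
              by = "patient_id", relationship = "many-to-many") |>
    filter(.data$date >= .data$start, .data$date < .data$end)
  n_drop <- nrow(cost_items) - nrow(located)
  if (n_drop > 0) warn(sprintf("%d cost item(s) outside follow-up dropped", n_drop))
  pt <- person_time_by_class(nyha_intervals)
  components <- sort(unique(cost_items$component))

  class_rows <- located |>
    group_by(stratum = as.character(nyha_label(.data$nyha_class)),
             .data$component) |>
    summarise(total = sum(.data$cost), .groups = "drop")
  pool <- function(strata, label, py) {
    tidyr::expand_grid(stratum = label, component = components) |>
      left_join(
        class_rows |> filter(.data$stratum %in% strata) |>
          group_by(.data$component) |>
          summarise(total = sum(.data$total), .groups = "drop"),
        by = "component") |>
      mutate(total = ifelse(is.na(.data$total), 0, .data$total),
             person_years = py)
  }
  py_of <- function(classes) {
    sum(pt$years[pt$nyha_class %in% classes])
  }
  per_class <- bind_rows(lapply(1:4, function(k) {
    if (py_of(k) == 0) return(NULL)
    pool(NYHA_LEVELS[k], NYHA_LEVELS[k], py_of(k))
  }))
  pooled <- bind_rows(
    pool(NYHA_LEVELS[2:4], "II+", py_of(2:4)),
    pool(NYHA_LEVELS, "overall", py_of(1:4))
  )
  all_rows <- bind_rows(per_class, pooled)
  totals <- all_rows |>
    group_by(.data$stratum) |>
    summarise(component = "total", total = sum(.data$total),
              person_years = .data$person_years[1], .groups = "drop")
  summarize_costs(bind_rows(all_rows, totals)) |>
    arrange(factor(.data$stratum, levels = c(NYHA_LEVELS, "II+", "overall")),
            .data$component)
}
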