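# Cohort construction: index date and cohort assignment, eligibility and
# exclusion flags, follow-up window, baseline characterization, attrition.

# join coded events to the codelist; returns events with concept flags
join_codelists <- function(clinical_events, codelists) {
  clinical_events |>
    inner_join(codelists, by = c("vocabulary", "code"))
}

#' Find the index date and cohort for each patient
#'
#' The index date is the earliest HCM diagnosis code within the study
#' window. Patients with any obstructive code are assigned to the
#' obstructive cohort with index at the earliest *obstructive* code, even
#' when a non-obstructive code came first; unspecified codes pool with the
#' non-obstructive cohort. Patients with no HCM code are omitted.
#'
#' @param clinical_events Coded-event table (`patient_id`, `date`,
#'   `vocabulary`, `code`, `setting`).
#' @param codelists Codelist table, see [default_codelists()].
#' @param study_start,study_end Study window; codes outside it are ignored.
#' @return A tibble `patient_id`, `index_date`, `cohort`
#'   (obstructive / nonobstructive_unspecified).
#' @export
find_index_and_cohort <- function(clinical_events, codelists = default_codelists(),
                                  study_start, study_end) {
  coded <- join_codelists(clinical_events, codelists) |>
    filter(.data$is_hcm, .data$date >= study_start, .data$date <= study_end)
  if (nrow(coded) == 0) {
    return(tibble(patient_id = character(), index_date = as.Date(character()),
                  cohort = character()))
  }
  coded |>
    group_by(.data$patient_id) |>
    summarise(
      has_obs = any(.data$hcm_subtype == "obstructive"),
      index_date = if (any(.data$hcm_subtype == "obstructive")) {
        min(.data$date[.data$hcm_subtype == "obstructive"])
      } else {
        min(.data$date)
      },
      .groups = "drop"
    ) |>
    mutate(cohort = ifelse(.data$has_obs, "obstructive",
                           "nonobstructive_unspecified")) |>
    select("patient_id", "index_date", "cohort")
}

#' Apply eligibility and exclusion criteria
#'
#' One boolean flag per criterion; a patient is included iff all flags are
#' `FALSE`. Exclusion conditions are checked over the whole study period,
#' not just pre-index. Research-quality and linkage-eligibility are
#' provider-determined inputs (`acceptable_quality`, `linkage_eligible`
#' columns on the patients table; assumed `TRUE` when absent).
#'
#' @param index_tbl Output of [find_index_and_cohort()].
#' @param patients Patients table.
#' @param clinical_events Coded-event table.
#' @param codelists Codelist table.
#' @param study_start,study_end Study window for exclusion-code search.
#' @param index_period_start Earliest permissible index date (the look-back
#'   must fit inside the study window); defaults to `study_start + 730`.
#' @param min_registration_days Continuous pre-index registration required.
#' @return `index_tbl` with logical columns `flag_age_under_18`,
#'   `flag_registration_lt_1y`, `flag_not_linkage_eligible`,
#'   `flag_quality_fail`, `flag_exclusion_condition`,
#'   `flag_index_before_index_period`, and `included`.
#' @export
apply_eligibility <- function(index_tbl, patients, clinical_events,
                              codelists = default_codelists(),
                              study_start, study_end,
                              index_period_start = study_start + 730L,
                              min_registration_days = 365L) {
  excl_pat <- join_codelists(clinical_events, codelists) |>
    filter(.data$is_exclusion, .data$date >= study_start, .data$date <= study_end) |>
    distinct(.data$patient_id) |>
    mutate(has_exclusion = TRUE)
  pat <- patients
  if (!"acceptable_quality" %in% names(pat)) pat$acceptable_quality <- TRUE
  if (!"linkage_eligible" %in% names(pat)) pat$linkage_eligible <- TRUE
  index_tbl |>
    left_join(pat, by = "patient_id") |>
    left_join(excl_pat, by = "patient_id") |>
    mutate(
      age_at_index = as.integer(format(.data$index_date, "%Y")) - .data$birth_year,
      flag_age_under_18 = .data$age_at_index < 18L,
      flag_registration_lt_1y =
        as.integer(.data$index_date - .data$reg_start) < min_registration_days,
      flag_not_linkage_eligible = !.data$linkage_eligible,
      flag_quality_fail = !.data$acceptable_quality,
      flag_exclusion_condition = !is.na(.data$has_exclusion),
      flag_index_before_index_period = .data$index_date < index_period_start,
      included = !(.data$flag_age_under_18 | .data$flag_registration_lt_1y |
                     .data$flag_not_linkage_eligible | .data$flag_quality_fail |
                     .data$flag_exclusion_condition |
                     .data$flag_index_before_index_period)
    ) |>
    select("patient_id", "index_date", "cohort", "age_at_index",
           starts_with("flag_"), "included")
}

#' Compute follow-up end dates
#'
#' Follow-up runs from the index date to the earliest of study end, death,
#' the practice's last collection date and registration end.
#'
#' @param index_date,death_date,practice_last_collection,reg_end,study_end
#'   Date vectors (recycled); `death_date` may be `NA`.
#' @return Date vector of follow-up end; errors if any candidate set ends
#'   before its index date (degenerate follow-up).
#' @export
compute_followup_end <- function(index_date, death_date, practice_last_collection,
                                 reg_end, study_end) {
  end <- pmin(as.Date(study_end), practice_last_collection, reg_end, na.rm = TRUE)
  end <- pmin(end, death_date, na.rm = TRUE)
  if (any(end < index_date)) {
    abort("degenerate follow-up: all candidate end dates precede the index date")
  }
  end
}

#' Baseline characterization
#'
#' Condition flags are set when a matching code lies in the 2-year window
#' `[index - lookback_condition_days, index]` (inclusive of the index day).
#' A prescription is "active at baseline" when dated within the 6-week
#' window `[index - lookback_rx_days, index]`. The age-adjusted Charlson
#' score sums the configured weights over flagged conditions plus one point
#' per full decade of age over 40.
#'
#' @param index_tbl Tibble with `patient_id`, `index_date` (and
#'   `age_at_index` for the Charlson score; computed from `patients` if
#'   missing).
#' @param clinical_events,prescriptions,patients EHR tables.
#' @param codelists Codelist table.
#' @param drug_map Product-to-class map, see [default_drug_map()].
#' @param lookback_condition_days,lookback_rx_days Look-back windows in days
#'   (2 years = 730; 6 weeks = 42).
#' @param cci_weights Charlson weights, see [default_cci_weights()].
#' @return Tibble keyed by `patient_id` with one logical `cond_*` column per
#'   condition concept, `baseline_active_rx` (";"-separated therapy classes),
#'   `n_baseline_rx_classes` and `cci_age_adjusted`.
#' @export
baseline_characteristics <- function(index_tbl, clinical_events, prescriptions,
                                     patients, codelists = default_codelists(),
                                     drug_map = default_drug_map(),
                                     lookback_condition_days = 730L,
                                     lookback_rx_days = 42L,
                                     cci_weights = default_cci_weights()) {
  if (!"age_at_index" %in% names(index_tbl)) {
    index_tbl <- index_tbl |>
      left_join(select(patients, "patient_id", "birth_year"), by = "patient_id") |>
      mutate(age_at_index =
               as.integer(format(.data$index_date, "%Y")) - .data$birth_year)
  }
  idx <- select(index_tbl, "patient_id", "index_date", "age_at_index")
  cond_concepts <- sort(unique(codelists$concept[codelists$is_condition]))

  cond_hits <- join_codelists(clinical_events, codelists) |>
    filter(.data$is_condition) |>
    inner_join(idx, by = "patient_id") |>
    filter(.data$date >= .data$index_date - lookback_condition_days,
           .data$date <= .data$index_date) |>
    distinct(.data$patient_id, .data$concept) |>
    mutate(hit = TRUE) |>
    pivot_wider(names_from = "concept", values_from = "hit",
                names_prefix = "cond_", values_fill = FALSE)

  rx_hits <- prescriptions |>
    inner_join(idx, by = "patient_id") |>
    filter(.data$date >= .data$index_date - lookback_rx_days,
           .data$date <= .data$index_date) |>
    inner_join(select(drug_map, "product", map_class = "therapy_class"),
               by = "product") |>
    group_by(.data$patient_id) |>
    summarise(
      baseline_active_rx = paste(sort(unique(.data$map_class)), collapse = ";"),
      n_baseline_rx_classes = n_distinct(.data$map_class), .groups = "drop")

  out <- idx |>
    left_join(cond_hits, by = "patient_id") |>
    left_join(rx_hits, by = "patient_id")
  for (cc in paste0("cond_", cond_concepts)) {
    if (!cc %in% names(out)) out[[cc]] <- FALSE
    out[[cc]] <- !is.na(out[[cc]]) & out[[cc]]
  }
  out$baseline_active_rx <- out$baseline_active_rx %||% NA_character_
  out$baseline_active_rx[is.na(out$baseline_active_rx)] <- ""
  out$n_baseline_rx_classes[is.na(out$n_baseline_rx_classes)] <- 0L

  w <- setNames(cci_weights$weight, cci_weights$concept)
  cond_mat <- as.matrix(out[paste0("cond_", cond_concepts)])
  weight_vec <- w[cond_concepts]
  weight_vec[is.na(weight_vec)] <- 0
  age_pts <- pmax(0L, floor((out$age_at_index - 40) / 10))
  out$cci_age_adjusted <- as.numeric(cond_mat %*% weight_vec) + age_pts
  select(out, -"index_date")
}

#' Build the study cohort
#'
#' Runs index/cohort assignment, eligibility, follow-up and baseline
#' characterization over an EHR extract in one call.
#'
#' @param ehr An `hcm_ehr` list (or any list with the same table names).
#' @param codelists,drug_map Reference tables.
#' @param study_start,study_end Study window; default from `ehr$config`.
#' @param ... Passed on to [apply_eligibility()] and
#'   [baseline_characteristics()] (`index_period_start`,
#'   `min_registration_days`, `lookback_condition_days`, `lookback_rx_days`,
#'   `cci_weights`).
#' @return Cohort tibble: one row per identified patient with index date,
#'   cohort, attrition flags, `included`, `followup_start`, `followup_end`,
#'   baseline condition flags, active prescriptions and Charlson score.
#' @export
build_cohort <- function(ehr, codelists = default_codelists(),
                         drug_map = default_drug_map(),
                         study_start = NULL, study_end = NULL, ...) {
  study_start <- study_start %||% ehr$config$study_start
  study_end <- study_end %||% ehr$config$study_end
  dots <- list(...)
  idx <- find_index_and_cohort(ehr$clinical_events, codelists, study_start, study_end)
  elig <- apply_eligibility(
    idx, ehr$patients, ehr$clinical_events, codelists,
    study_start = study_start, study_end = study_end,
    index_period_start = dots$index_period_start %||% (study_start + 730L),
    min_registration_days = dots$min_registration_days %||% 365L
  )
  fu <- elig |>
    left_join(select(ehr$patients, "patient_id", "reg_end",
                     "practice_last_collection"), by = "patient_id") |>
    left_join(ehr$deaths |> distinct(.data$patient_id, .keep_all = TRUE) |>
                select("patient_id", death_date = "date"), by = "patient_id")
  fu$followup_start <- fu$index_date
  fu$followup_end <- compute_followup_end(
    fu$index_date, fu$death_date, fu$practice_last_collection, fu$reg_end,
    study_end)
  base <- baseline_characteristics(
    elig, ehr$clinical_events, ehr$prescriptions, ehr$patients,
    codelists, drug_map,
    lookback_condition_days = dots$lookback_condition_days %||% 730L,
    lookback_rx_days = dots$lookback_rx_days %||% 42L,
    cci_weights = dots$cci_weights %||% default_cci_weights()
  )
  fu |>
    select(-"reg_end", -"practice_last_collection") |>
    left_join(base, by = c("patient_id", "age_at_index"))
}

#' Attrition report
#'
#' Counts patients lost at each eligibility criterion in order (each patient
#' counted at the first criterion that fails), the eligible remainder, and
#' the cohort split among eligible patients. Percentages use half-up
#' rounding to two decimal places.
#'
#' @param cohort Cohort tibble from [build_cohort()] (or any tibble with the
#'   `flag_*`, `included` and `cohort` columns).
#' @return Tibble `stage`, `n`, `pct` (percentage of identified patients,
#'   except the cohort-split rows, which are percentages of eligible
#'   patients).
#' @export
attrition_report <- function(cohort) {
  if (nrow(cohort) == 0) {
    return(tibble(stage = character(), n = integer(), pct = numeric()))
  }
  criteria <- c("flag_age_under_18", "flag_registration_lt_1y",
                "flag_not_linkage_eligible", "flag_quality_fail",
                "flag_exclusion_condition", "flag_index_before_index_period")
  identified <- nrow(cohort)
  remaining <- rep(TRUE, identified)
  rows <- list(tibble(stage = "identified", n = identified, pct = 100))
  for (cr in criteria) {
    dropped <- remaining & cohort[[cr]]
    rows[[length(rows) + 1L]] <- tibble(
      stage = sub("^flag_", "excluded_", cr), n = sum(dropped),
      pct = pct_of(sum(dropped), identified, 2))
    remaining <- remaining & !dropped
  }
  eligible <- sum(remaining)
  rows[[length(rows) + 1L]] <- tibble(stage = "eligible", n = eligible,
                                      pct = pct_of(eligible, identified, 2))
  for (coh in c("obstructive", "nonobstructive_unspecified")) {
    n_c <- sum(remaining & cohort$cohort == coh)
    rows[[length(rows) + 1L]] <- tibble(stage = paste0("eligible_", coh), n = n_c,
                                        pct = pct_of(n_c, eligible, 2))
  }
  bind_rows(rows)
}
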