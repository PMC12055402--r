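# Reporting: statistical disclosure suppression, NYHA distribution
# summaries, and the end-to-end pipeline driver.

#' Small-cell disclosure suppression
#'
#' Primary suppression hides every count of 1-4. Secondary suppression then
#' protects against subtraction: while any row (or column) whose total is
#' shown contains exactly one suppressed cell, the smallest remaining shown
#' cell in that row (column) is also suppressed; this iterates to a
#' fixpoint.
#'
#' @param counts Matrix (or data frame) of non-negative integer counts.
#' @param row_totals,col_totals Whether row/column totals are published
#'   alongside the table (and hence subtraction is possible).
#' @return List of class `hcm_suppressed`: `counts` (input), `state`
#'   (matrix of "shown" / "primary_suppressed" / "secondary_suppressed"),
#'   `display` (character matrix with suppressed cells shown as "NR").
#' @export
suppress_small_cells <- function(counts, row_totals = TRUE, col_totals = TRUE) {
  x <- as.matrix(counts)
  check_that(all(x >= 0) && all(x == floor(x)), "counts must be non-negative integers")
  state <- matrix("shown", nrow(x), ncol(x), dimnames = dimnames(x))
  state[x >= 1 & x <= 4] <- "primary_suppressed"

  protect_line <- function(vals, st) {
    # exactly one suppressed cell in a published line -> hide the smallest
    # remaining shown cell
    if (sum(st != "shown") == 1L && sum(st == "shown") > 0L) {
      shown_idx <- which(st == "shown")
      st[shown_idx[which.min(vals[shown_idx])]] <- "secondary_suppressed"
    }
    st
  }
  repeat {
    before <- state
    if (row_totals) {
      for (i in seq_len(nrow(x))) state[i, ] <- protect_line(x[i, ], state[i, ])
    }
    if (col_totals) {
      for (j in seq_len(ncol(x))) state[, j] <- protect_line(x[, j], state[, j])
    }
    if (identical(state, before)) break
  }
  display <- matrix(as.character(x), nrow(x), ncol(x), dimnames = dimnames(x))
  display[state != "shown"] <- "NR"
  structure(list(counts = x, state = state, display = display),
            class = "hcm_suppressed")
}

#' @export
print.hcm_suppressed <- function(x, ...) {
  cat("<hcm_suppressed> table with small-cell suppression\n")
  print(x$display, quote = FALSE)
  invisible(x)
}

#' NYHA class distribution report
#'
#' Counts and percentages (one decimal place, half-up) of NYHA classes at
#' baseline and at end of follow-up, including the symptomatic (II+)
#' aggregate, plus per-class person-time shares when supplied.
#'
#' @param baseline_classes Integer (1-4) or label vector of baseline
#'   classes, one per patient.
#' @param end_classes Same for the class at end of follow-up.
#' @param person_time Optional per-class person-time from
#'   [person_time_by_class()].
#' @return Tibble `measure` ("baseline", "end_of_followup",
#'   "person_time_years"), `nyha_class` ("I".."IV", "II+"), `n`
#'   (patients or years), `pct`.
#' @export
nyha_distribution_report <- function(baseline_classes, end_classes,
                                     person_time = NULL) {
  one <- function(classes, measure) {
    k <- if (is.numeric(classes)) as.integer(classes) else nyha_class_int(classes)
    total <- length(k)
    n4 <- vapply(1:4, function(j) sum(k == j), 0L)
    n_all <- c(n4, sum(n4[2:4]))
    tibble(measure = measure,
           nyha_class = c(NYHA_LEVELS, "II+"),
           n = n_all,
           pct = pct_of(n_all, total, 1))
  }
  out <- bind_rows(one(baseline_classes, "baseline"),
                   one(end_classes, "end_of_followup"))
  if (!is.null(person_time)) {
    yrs <- vapply(1:4, function(j) {
      sum(person_time$years[person_time$nyha_class == j])
    }, 0)
    yrs_all <- c(yrs, sum(yrs[2:4]))
    out <- bind_rows(out, tibble(
      measure = "person_time_years",
      nyha_class = c(NYHA_LEVELS, "II+"),
      n = yrs_all,
      pct = pct_of(yrs_all, sum(yrs), 1)))
  }
  out
}

#' Class at end of follow-up
#'
#' Convenience accessor: the NYHA class of each patient's last interval.
#'
#' @param nyha_intervals NYHA interval tibble from [classify_nyha()].
#' @return Tibble `patient_id`, `nyha_class`.
#' @export
end_of_followup_class <- function(nyha_intervals) {
  nyha_intervals |>
    group_by(.data$patient_id) |>
    slice_max(.data$start, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("patient_id", "nyha_class")
}

#' Run the full burden-analysis pipeline
#'
#' Simulate (or accept) an EHR extract, build the cohort, classify the
#' time-varying proxy NYHA trajectory for included obstructive-cohort
#' patients, reconstruct treatment pathways, identify clinical events and
#' estimate NYHA-stratified incidence, cost healthcare activity, and
#' assemble the report tables.
#'
#' @param config An [gen_config()] (used when `ehr` is not supplied).
#' @param seed Seed for the simulation.
#' @param ehr Optional pre-built `hcm_ehr` list; overrides `config`.
#' @param codelists,drug_map,nyha_rules,event_rules,unit_costs,hrg_costs
#'   Reference tables / rulesets.
#' @param inflation Cost inflation factor.
#' @param gap_days No-treatment gap threshold (days).
#' @return List of class `hcm_pipeline`: `ehr`, `cohort`, `attrition`,
#'   `nyha`, `person_time`, `baseline_nyha`, `nyha_distribution`,
#'   `regimens`, `initial_treatment`, `changes`, `change_summary`,
#'   `events`, `incidence`, `activity`, `costs`, and a `log` of seeds and
#'   row counts.
#' @export
run_pipeline <- function(config = gen_config(), seed = config$seed, ehr = NULL,
                         codelists = default_codelists(),
                         drug_map = default_drug_map(),
                         nyha_rules = nyha_ruleset(),
                         event_rules = default_event_ruleset(),
                         unit_costs = default_unit_costs(),
                         hrg_costs = default_hrg_costs(),
                         inflation = 1, gap_days = 90L) {
  if (is.null(ehr)) ehr <- generate_population(config, seed = seed)
  cohort <- build_cohort(ehr, codelists, drug_map)
  attrition <- attrition_report(cohort)

  obs <- cohort |>
    filter(.data$included, .data$cohort == "obstructive",
           .data$followup_end > .data$index_date)
  nyha <- classify_nyha(ehr, obs, codelists, drug_map, nyha_rules)
  pt <- person_time_by_class(nyha)
  baseline_nyha <- nyha |>
    group_by(.data$patient_id) |>
    slice_min(.data$start, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("patient_id", "nyha_class")
  end_nyha <- end_of_followup_class(nyha)
  distribution <- nyha_distribution_report(baseline_nyha$nyha_class,
                                           end_nyha$nyha_class, pt)

  post_rx <- ehr$prescriptions |>
    inner_join(select(obs, "patient_id", "index_date"), by = "patient_id") |>
    filter(.data$date >= .data$index_date) |>
    select(-"index_date")
  exposure <- build_exposure_intervals(post_rx, drug_map)
  regimens <- derive_regimens(exposure)
  initial <- initial_treatment(regimens, obs)
  changes <- detect_first_change(regimens, obs, gap_days = gap_days)
  n_treated <- sum(initial$initial_label != "none")
  chg_summary <- if (n_treated > 0) change_summary(changes, n_treated) else
    tibble(category = character(), n = integer(), pct = numeric())

  events <- identify_events(ehr$clinical_events, obs, codelists, event_rules,
                            deaths = ehr$deaths)
  class_events <- split_person_time(events, nyha)
  incidence <- estimate_incidence(class_events, pt)

  activity <- count_activity(ehr, obs)
  items <- bind_rows(
    cost_non_inpatient(activity, unit_costs, inflation = inflation),
    cost_inpatient(activity, hrg_costs, inflation = inflation)
  )
  costs <- stratified_costs(items, nyha)

  structure(list(
    ehr = ehr, cohort = cohort, attrition = attrition, nyha = nyha,
    person_time = pt, baseline_nyha = baseline_nyha,
    nyha_distribution = distribution, regimens = regimens,
    initial_treatment = initial, changes = changes,
    change_summary = chg_summary, events = events, incidence = incidence,
    activity = activity, costs = costs,
    log = list(
      seed = seed,
      n_identified = nrow(cohort),
      n_included = sum(cohort$included),
      n_obstructive = nrow(obs),
      rows = vapply(ehr[c("patients", "clinical_events", "prescriptions",
                          "consultations", "hospital_activity", "deaths")],
                    nrow, 0L)
    )
  ), class = "hcm_pipeline")
}

#' @export
print.hcm_pipeline <- function(x, ...) {
  cat("<hcm_pipeline> obstructive-HCM burden analysis\n")
  cat("  identified:", x$log$n_identified,
      "| included:", x$log$n_included,
      "| obstructive:", x$log$n_obstructive, "\n")
  cat("  person-years by NYHA class:\n")
  print(as.data.frame(x$person_time), row.names = FALSE)
  invisible(x)
}

#' Glance at a pipeline run
#'
#' @param x An `hcm_pipeline` object.
#' @param ... Unused.
#' @return One-row tibble with cohort sizes, total person-years and total
#'   cost per patient-year.
#' @method glance hcm_pipeline
#' @export
glance.hcm_pipeline <- function(x, ...) {
  overall <- x$costs |>
    filter(.data$stratum == "overall", .data$component == "total")
  tibble(
    n_identified = x$log$n_identified,
    n_included = x$log$n_included,
    n_obstructive = x$log$n_obstructive,
    person_years = sum(x$person_time$years),
    cost_per_py = if (nrow(overall)) overall$cost_per_py else NA_real_
  )
}
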