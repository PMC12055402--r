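# Cohort builder: index/cohort assignment, eligibility, follow-up,
# baseline characterization, attrition arithmetic.

STUDY_START <- as.Date("2007-04-01")
STUDY_END <- as.Date("2020-10-30")

test_that("obstructive codes set the cohort and index even when later", {
  ehr <- empty_ehr(STUDY_START, STUDY_END) |>
    add_code("A", "2011-03-01", "hcm_nonobstructive") |>
    add_code("A", "2013-06-01", "hcm_obstructive")
  idx <- find_index_and_cohort(ehr$clinical_events, CL, STUDY_START, STUDY_END)
  expect_equal(idx$cohort, "obstructive")
  expect_equal(idx$index_date, as.Date("2013-06-01"))
})

test_that("unspecified codes pool with the non-obstructive cohort", {
  ehr <- empty_ehr() |> add_code("A", "2012-05-01", "hcm_unspecified")
  idx <- find_index_and_cohort(ehr$clinical_events, CL, STUDY_START, STUDY_END)
  expect_equal(idx$cohort, "nonobstructive_unspecified")
  expect_equal(idx$index_date, as.Date("2012-05-01"))
})

test_that("patients without an HCM code are omitted", {
  ehr <- empty_ehr() |> add_code("A", "2012-05-01", "hypertension")
  idx <- find_index_and_cohort(ehr$clinical_events, CL, STUDY_START, STUDY_END)
  expect_equal(nrow(idx), 0L)
})

test_that("obstructive precedence holds under random extra codes", {
  set.seed(42)
  for (i in 1:25) {
    ehr <- empty_ehr()
    n <- sample(1:4, 1)
    for (j in seq_len(n)) {
      ehr <- add_code(ehr, "A", STUDY_START + sample.int(4000, 1),
                      sample(c("hcm_nonobstructive", "hcm_unspecified"), 1))
    }
    base <- find_index_and_cohort(ehr$clinical_events, CL, STUDY_START, STUDY_END)
    obs_date <- STUDY_START + sample.int(4000, 1)
    ehr2 <- add_code(ehr, "A", obs_date, "hcm_obstructive")
    with_obs <- find_index_and_cohort(ehr2$clinical_events, CL,
                                      STUDY_START, STUDY_END)
    expect_equal(with_obs$cohort, "obstructive")
    expect_equal(with_obs$index_date, obs_date)
    # index monotonicity: removing later codes never moves the index later
    expect_lte(base$index_date, max(ehr$clinical_events$date))
  }
})

eligibility_fixture <- function(reg_start, index_code_date, birth_year = 1950L,
                                extra = identity) {
  ehr <- empty_ehr(STUDY_START, STUDY_END) |>
    add_patient("A", reg_start, STUDY_END, birth_year = birth_year) |>
    add_code("A", index_code_date, "hcm_obstructive")
  ehr <- extra(ehr)
  idx <- find_index_and_cohort(ehr$clinical_events, CL, STUDY_START, STUDY_END)
  apply_eligibility(idx, ehr$patients, ehr$clinical_events, CL,
                    STUDY_START, STUDY_END)
}

test_that("short registration, youth and exclusion codes set their flags", {
  e1 <- eligibility_fixture("2010-01-01", "2010-06-01")
  expect_true(e1$flag_registration_lt_1y)
  expect_false(e1$included)

  e2 <- eligibility_fixture("2008-01-01", "2012-06-01", birth_year = 1995L)
  expect_equal(e2$age_at_index, 17L)
  expect_true(e2$flag_age_under_18)

  e3 <- eligibility_fixture("2008-01-01", "2012-06-01",
                            extra = function(e) add_code(e, "A", "2018-03-01",
                                                         "amyloidosis"))
  expect_true(e3$flag_exclusion_condition)

  e4 <- eligibility_fixture("2008-01-01", "2012-06-01")
  expect_true(e4$included)
  expect_false(any(unlist(e4[startsWith(names(e4), "flag_")])))
})

test_that("index before the index period is flagged", {
  e <- eligibility_fixture("2007-06-01", "2008-09-01")
  expect_true(e$flag_index_before_index_period)
})

test_that("follow-up ends at the earliest candidate date", {
  idx <- as.Date("2012-01-01")
  expect_equal(
    compute_followup_end(idx, as.Date("2015-01-01"), as.Date("2020-06-01"),
                         as.Date("2019-01-01"), STUDY_END),
    as.Date("2015-01-01"))
  expect_equal(
    compute_followup_end(idx, as.Date(NA), STUDY_END + 100, STUDY_END + 100,
                         STUDY_END),
    STUDY_END)
  set.seed(7)
  for (i in 1:20) {
    cand <- idx + sample.int(3000, 4)
    got <- compute_followup_end(idx, cand[1], cand[2], cand[3], cand[4])
    # brute-force oracle: exhaustive pairwise comparison
    best <- cand[1]
    for (k in 2:4) if (cand[k] < best) best <- cand[k]
    expect_equal(got, best)
  }
  expect_error(
    compute_followup_end(idx, idx - 10, idx - 20, idx - 30, idx - 5),
    "degenerate")
})

test_that("baseline windows are inclusive and correctly bounded", {
  idx_date <- as.Date("2014-06-01")
  ehr <- empty_ehr() |>
    add_patient("A", "2008-01-01", STUDY_END) |>
    add_code("A", idx_date, "hcm_obstructive") |>
    add_code("A", idx_date - 760, "af_flutter") |>       # ~25 months: out
    add_code("A", idx_date, "hypertension") |>           # on index day: in
    add_code("A", idx_date - 100, "mi") |>               # within 2y: in
    add_rx("A", idx_date - 30, "atorvastatin") |>        # 30d: active
    add_rx("A", idx_date - 50, "bisoprolol")             # 50d: not active
  idx <- tibble::tibble(patient_id = "A", index_date = idx_date,
                        age_at_index = 64L)
  b <- baseline_characteristics(idx, ehr$clinical_events, ehr$prescriptions,
                                ehr$patients, CL, DM)
  expect_false(b$cond_af_flutter)
  expect_true(b$cond_hypertension)
  expect_true(b$cond_mi)
  expect_equal(b$baseline_active_rx, "statin")
  # Charlson: MI (1) + two age decades over 40 at 64 years
  expect_equal(b$cci_age_adjusted, 1 + 2)
})

test_that("attrition arithmetic reproduces flag-first counts and percentages", {
  n_id <- 35886L
  n_elig <- 6440L
  n_obs <- 3730L
  coh <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n_id)),
    cohort = c(rep("obstructive", n_obs),
               rep("nonobstructive_unspecified", n_elig - n_obs),
               sample(c("obstructive", "nonobstructive_unspecified"),
                      n_id - n_elig, replace = TRUE)),
    flag_age_under_18 = FALSE, flag_registration_lt_1y = FALSE,
    flag_not_linkage_eligible = c(rep(FALSE, n_elig), rep(TRUE, n_id - n_elig)),
    flag_quality_fail = FALSE, flag_exclusion_condition = FALSE,
    flag_index_before_index_period = FALSE,
    included = c(rep(TRUE, n_elig), rep(FALSE, n_id - n_elig)))
  rep_tbl <- attrition_report(coh)
  expect_equal(rep_tbl$pct[rep_tbl$stage == "eligible"], 17.95)
  expect_equal(rep_tbl$pct[rep_tbl$stage == "eligible_obstructive"], 57.92)
  expect_equal(rep_tbl$n[rep_tbl$stage == "eligible"], n_elig)
})

test_that("attrition counts partition the identified cohort", {
  set.seed(13)
  n <- 500L
  flags <- c("flag_age_under_18", "flag_registration_lt_1y",
             "flag_not_linkage_eligible", "flag_quality_fail",
             "flag_exclusion_condition", "flag_index_before_index_period")
  coh <- tibble::tibble(patient_id = as.character(seq_len(n)),
                        cohort = sample(c("obstructive",
                                          "nonobstructive_unspecified"),
                                        n, replace = TRUE))
  for (f in flags) coh[[f]] <- runif(n) < 0.1
  coh$included <- !Reduce(`|`, coh[flags])
  rep_tbl <- attrition_report(coh)
  dropped <- sum(rep_tbl$n[startsWith(rep_tbl$stage, "excluded_")])
  expect_equal(dropped + rep_tbl$n[rep_tbl$stage == "eligible"], n)
})

test_that("an empty cohort gives an empty report without division", {
  expect_equal(nrow(attrition_report(tibble::tibble())), 0L)
})

test_that("build_cohort runs end to end on generated data", {
  ehr <- generate_population(gen_config(n_patients = 60), seed = 3)
  coh <- build_cohort(ehr)
  expect_equal(nrow(coh), dplyr::n_distinct(
    join_ids <- unique(dplyr::inner_join(
      ehr$clinical_events, CL, by = c("vocabulary", "code")) |>
        dplyr::filter(is_hcm) |> dplyr::pull(patient_id))))
  expect_true(all(coh$followup_end >= coh$index_date))
  expect_true(all(c("cci_age_adjusted", "baseline_active_rx") %in% names(coh)))
})
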