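# Synthetic reference tables: codelists, drug map, event rules, cost tables.
#
# The shipped codelists are deliberately synthetic placeholders: they give
# every clinical concept the pipeline needs a unique (vocabulary, code) pair
# so that generator output and classifier input join cleanly. They are not
# real UK coding dictionaries and make no claim of clinical completeness;
# users with licensed data supply their own tables in the same shape.

#' Synthetic codelist table
#'
#' One row per (vocabulary, code), flagged by role: HCM diagnosis codes
#' (split obstructive / non-obstructive / unspecified), study exclusion
#' conditions, baseline comorbidity concepts, symptom concepts feeding the
#' proxy NYHA classifier, intervention concepts that can release the
#' asymptomatic-correction ratchet, and recorded NYHA class codes.
#'
#' @return A tibble with columns `concept`, `vocabulary`, `code`,
#'   `is_hcm`, `hcm_subtype`, `is_exclusion`, `is_condition`, `is_symptom`,
#'   `is_intervention`, `is_nyha`, `nyha_class`.
#' @export
default_codelists <- function() {
  row <- function(concept, vocab, code, hcm = FALSE, subtype = NA_character_,
                  excl = FALSE, cond = FALSE, symp = FALSE, interv = FALSE,
                  nyha = FALSE, nyha_class = NA_integer_) {
    tibble(
      concept = concept, vocabulary = vocab, code = code,
      is_hcm = hcm, hcm_subtype = subtype, is_exclusion = excl,
      is_condition = cond, is_symptom = symp, is_intervention = interv,
      is_nyha = nyha, nyha_class = nyha_class
    )
  }
  bind_rows(
    # HCM diagnosis codes (ICD-10 I42.1 / I42.2 pattern plus primary-care codes)
    row("hcm_obstructive", "ICD10", "I42.1", hcm = TRUE, subtype = "obstructive"),
    row("hcm_obstructive", "SNOMED", "45227007", hcm = TRUE, subtype = "obstructive"),
    row("hcm_nonobstructive", "ICD10", "I42.2", hcm = TRUE, subtype = "nonobstructive"),
    row("hcm_nonobstructive", "SNOMED", "78954000", hcm = TRUE, subtype = "nonobstructive"),
    row("hcm_unspecified", "READ", "G554.", hcm = TRUE, subtype = "unspecified"),
    # exclusion conditions
    row("hypertensive_heart_disease", "ICD10", "I11", excl = TRUE),
    row("aortic_stenosis", "ICD10", "I35.0", excl = TRUE),
    row("athletes_heart", "READ", "G55y1", excl = TRUE),
    row("storage_disease", "ICD10", "E74.0", excl = TRUE),
    row("takotsubo", "ICD10", "I51.81", excl = TRUE),
    row("anderson_fabry", "ICD10", "E75.21", excl = TRUE),
    row("pompe_disease", "ICD10", "E74.02", excl = TRUE),
    row("amyloidosis", "ICD10", "E85", excl = TRUE),
    # baseline comorbidity / clinical-event concepts
    row("asthma", "ICD10", "J45", cond = TRUE),
    row("af_flutter", "ICD10", "I48", cond = TRUE),
    row("cardiac_arrest", "ICD10", "I46", cond = TRUE),
    row("cardiac_dysrhythmias", "ICD10", "I49", cond = TRUE),
    row("ckd", "ICD10", "N18", cond = TRUE),
    row("conduction_disorders", "ICD10", "I45", cond = TRUE),
    row("copd", "ICD10", "J44", cond = TRUE),
    row("dvt_pe", "ICD10", "I26", cond = TRUE),
    row("depression", "ICD10", "F32", cond = TRUE),
    row("dilated_cardiomyopathy", "ICD10", "I42.0", cond = TRUE),
    row("heart_failure", "ICD10", "I50", cond = TRUE),
    row("heart_transplant", "OPCS", "K01", cond = TRUE),
    row("ventricular_assist_device", "OPCS", "K54", cond = TRUE),
    row("stroke", "ICD10", "I63", cond = TRUE),
    row("tia", "ICD10", "G45", cond = TRUE),
    row("mi", "ICD10", "I21", cond = TRUE),
    row("ihd", "ICD10", "I25", cond = TRUE),
    row("pvd", "ICD10", "I73.9", cond = TRUE),
    row("t1dm", "ICD10", "E10", cond = TRUE),
    row("t2dm", "ICD10", "E11", cond = TRUE),
    row("diabetes_unspecified", "ICD10", "E14", cond = TRUE),
    row("hypertension", "ICD10", "I10", cond = TRUE),
    row("hcm_family_history", "READ", "12CL.", cond = TRUE),
    row("vt", "ICD10", "I47.2", cond = TRUE),
    # interventions (also comorbidity concepts at baseline)
    row("srt", "OPCS", "K24.5", cond = TRUE, interv = TRUE),
    row("icd_insertion", "OPCS", "K59.1", cond = TRUE, interv = TRUE),
    row("pacemaker", "OPCS", "K60.1", cond = TRUE, interv = TRUE),
    # symptom concepts used by the proxy classifier
    row("breathlessness", "READ", "173..", symp = TRUE),
    row("fatigue", "READ", "168..", symp = TRUE),
    row("oedema", "READ", "1B14.", symp = TRUE),
    row("palpitations", "READ", "1733.", symp = TRUE),
    row("dizziness", "READ", "1B52.", symp = TRUE),
    row("syncope", "READ", "1B1V.", symp = TRUE),
    row("chest_pain", "READ", "182..", symp = TRUE),
    row("angina", "READ", "G33..", symp = TRUE),
    row("pre_syncope", "READ", "1B1W.", symp = TRUE),
    row("tachycardia", "READ", "243..", symp = TRUE),
    # recorded NYHA class codes
    row("nyha_i", "READ", "662f.", nyha = TRUE, nyha_class = 1L),
    row("nyha_ii", "READ", "662g.", nyha = TRUE, nyha_class = 2L),
    row("nyha_iii", "READ", "662h.", nyha = TRUE, nyha_class = 3L),
    row("nyha_iv", "READ", "662i.", nyha = TRUE, nyha_class = 4L)
  )
}

#' Product-to-therapy-class map
#'
#' Maps prescription product names to therapy classes. BBs,
#' non-dihydropyridine CCBs and disopyramide are the HCM-specific classes;
#' dihydropyridine CCBs (e.g. amlodipine) are mapped but flagged
#' non-HCM-specific. Loop diuretics are flagged because the default proxy
#' NYHA ruleset treats an active loop diuretic as a class III marker.
#'
#' @return A tibble with columns `product`, `therapy_class`,
#'   `is_hcm_specific`, `is_non_dihydropyridine`, `is_loop_diuretic`.
#' @export
default_drug_map <- function() {
  tribble(
    ~product, ~therapy_class, ~is_hcm_specific, ~is_non_dihydropyridine, ~is_loop_diuretic,
    "bisoprolol", "BB", TRUE, FALSE, FALSE,
    "atenolol", "BB", TRUE, FALSE, FALSE,
    "metoprolol", "BB", TRUE, FALSE, FALSE,
    "propranolol", "BB", TRUE, FALSE, FALSE,
    "verapamil", "CCB", TRUE, TRUE, FALSE,
    "diltiazem", "CCB", TRUE, TRUE, FALSE,
    "amlodipine", "CCB", FALSE, FALSE, FALSE,
    "disopyramide", "disopyramide", TRUE, FALSE, FALSE,
    "furosemide", "loop_diuretic", FALSE, FALSE, TRUE,
    "atorvastatin", "statin", FALSE, FALSE, FALSE,
    "simvastatin", "statin", FALSE, FALSE, FALSE,
    "aspirin", "aspirin", FALSE, FALSE, FALSE,
    "clopidogrel", "antiplatelet", FALSE, FALSE, FALSE,
    "apixaban", "anticoagulant", FALSE, FALSE, FALSE,
    "amiodarone", "amiodarone", FALSE, FALSE, FALSE
  )
}

#' Default clinical-event ruleset
#'
#' Chronic conditions are counted at first occurrence only (`first_only`,
#' excluding patients with a pre-index record when `incident_only`); acute
#' events are repeatable, with successive codes counted as distinct events
#' only when at least `dedup_days` apart.
#'
#' @return A tibble with columns `event`, `concepts` (list column of concept
#'   names), `mode`, `dedup_days`, `incident_only`.
#' @export
default_event_ruleset <- function() {
  tibble(
    event = c(
      "af_flutter", "cardiac_dysrhythmias", "conduction_disorders",
      "heart_failure", "dilated_cardiomyopathy", "icd_insertion",
      "pacemaker", "all_cause_mortality",
      "mi", "stroke", "vt", "srt", "dvt_pe", "cardiac_arrest_vf"
    ),
    concepts = list(
      "af_flutter", "cardiac_dysrhythmias", "conduction_disorders",
      "heart_failure", "dilated_cardiomyopathy", "icd_insertion",
      "pacemaker", "death",
      "mi", "stroke", "vt", "srt", "dvt_pe", c("cardiac_arrest", "vt")
    ),
    mode = c(rep("first_only", 8L), rep("repeatable", 6L)),
    dedup_days = c(rep(NA_integer_, 8L), rep(30L, 6L)),
    incident_only = c(rep(TRUE, 8L), rep(FALSE, 6L))
  )
}

#' Default unit-cost table for non-inpatient activity
#'
#' Synthetic unit costs in the shape of an NHS National Schedule extract
#' (reference-year pounds per activity), used with a single multiplicative
#' inflation factor. Inpatient activity (elective, non-elective, day case)
#' is costed separately through the HRG table.
#'
#' @return A tibble with columns `category`, `unit_cost`, `year`,
#'   `component` (primary_care / secondary_care / tests_procedures).
#' @export
default_unit_costs <- function() {
  tribble(
    ~category, ~unit_cost, ~year, ~component,
    "gp", 39, 2019L, "primary_care",
    "nurse", 14, 2019L, "primary_care",
    "telephone", 15, 2019L, "primary_care",
    "outpatient", 150, 2019L, "secondary_care",
    "ae", 180, 2019L, "secondary_care",
    "critical_care", 1500, 2019L, "secondary_care",
    "procedure", 120, 2019L, "tests_procedures"
  )
}

#' Default HRG cost table for inpatient episodes
#'
#' Synthetic Healthcare Resource Group currency codes with per-episode costs.
#'
#' @return A tibble with columns `hrg_code`, `cost`.
#' @export
default_hrg_costs <- function() {
  tibble(
    hrg_code = c("EB07A", "EB07B", "EB10C", "EB12Z", "DZ65A"),
    cost = c(3200, 2400, 1800, 950, 1450)
  )
}

#' Default Charlson comorbidity weights
#'
#' Classic weights for the conditions observable from the baseline flags;
#' the age adjustment adds one point per full decade of age over 40.
#'
#' @return A tibble with columns `concept`, `weight`.
#' @export
default_cci_weights <- function() {
  tribble(
    ~concept, ~weight,
    "mi", 1,
    "heart_failure", 1,
    "pvd", 1,
    "stroke", 1,
    "tia", 1,
    "copd", 1,
    "t1dm", 1,
    "t2dm", 1,
    "diabetes_unspecified", 1,
    "ckd", 2
  )
}
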