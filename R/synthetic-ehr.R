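# Seeded synthetic CPRD/HES-like EHR generator with a latent severity process.
#
# Each patient carries a latent NYHA class that evolves as a Markov chain on
# a 30-day month grid over their registration window. Observable rows
# (symptom codes, prescriptions, consultations, hospital activity, clinical
# events, death) are emitted with class-dependent rates, so downstream
# classifier and estimator recovery can be checked against retained truth.

# cheap data.frame constructor for hot loops
qdf <- function(...) {
  x <- list(...)
  n <- if (length(x)) length(x[[1L]]) else 0L
  structure(x, class = "data.frame", row.names = if (n) seq_len(n) else integer(0))
}

default_transition_matrix <- function() {
  # slow, progression-only dynamics: upper-triangular so severity never
  # improves spontaneously, matching the clinical premise behind the
  # asymptomatic-correction ratchet
  matrix(c(
    0.980, 0.014, 0.005, 0.001,
    0.000, 0.984, 0.013, 0.003,
    0.000, 0.000, 0.995, 0.005,
    0.000, 0.000, 0.000, 1.000
  ), nrow = 4, byrow = TRUE, dimnames = list(NYHA_LEVELS, NYHA_LEVELS))
}

default_rx_policy <- function() {
  # therapy-class sets by latent class, consistent with the default proxy
  # NYHA ruleset: none -> I, single agent -> II, two agents -> III/IV
  list(
    list(list(products = character(0), prob = 1)),
    list(list(products = "bisoprolol", prob = 1)),
    list(list(products = c("bisoprolol", "verapamil"), prob = 1)),
    list(list(products = c("bisoprolol", "verapamil"), prob = 1))
  )
}

#' Synthetic-EHR generator configuration
#'
#' Bundles and validates every knob of the generator. Defaults emulate the
#' study conditions of an English obstructive-HCM cohort: baseline NYHA
#' distribution 25.9/33.9/37.7/2.5%, 61.9% male, mean age 61 (SD 15.6),
#' 57.9% of HCM diagnoses obstructive, recorded NYHA coding in 1.26% of
#' patients, and prescribing that tracks latent severity (rule-consistent
#' emission), so the proxy classifier is recoverable by construction.
#'
#' @param n_patients Number of patients to simulate.
#' @param study_start,study_end Study window (dates); all generated dates
#'   fall inside it.
#' @param age_mean,age_sd Age at diagnosis, years (normal, truncated 16-95).
#' @param sex_fraction_male Probability of male sex.
#' @param initial_class_probs Length-4 probability vector over NYHA I-IV at
#'   registration start.
#' @param monthly_transition_matrix 4x4 row-stochastic matrix; latent class
#'   transitions once per 30-day month.
#' @param symptom_rate_by_class Per-class monthly probability of a symptom
#'   code.
#' @param rx_policy_by_class Length-4 list; each element a list of
#'   `list(products =, prob =)` options. One option is drawn per patient per
#'   class and prescribed monthly (30 days' supply) while in that class.
#' @param rule_consistent_symptoms If `TRUE`, all symptom codes use a single
#'   concept so the classifier's two-distinct-symptom adjustment never
#'   fires; set `FALSE` to sample from the full symptom list.
#' @param event_rates_by_class Named list: clinical event -> length-4 vector
#'   of rates per 100 patient-years.
#' @param activity_rates_by_class Named list: activity category -> length-4
#'   vector of rates per patient-year. Categories `gp`, `nurse`,
#'   `telephone`, `out_of_hours` become consultations; `outpatient`, `ae`,
#'   `elective`, `day_case`, `critical_care` become hospital activity;
#'   `procedure` becomes OPCS-coded procedure events.
#' @param other_rx_monthly_prob Named numeric: non-HCM-specific product ->
#'   monthly prescription probability (baseline cardiovascular medication).
#' @param monthly_death_rate_by_class Length-4 monthly death probability;
#'   all zero by default to keep person-time simple.
#' @param fraction_obstructive Probability an HCM diagnosis is coded
#'   obstructive.
#' @param both_codes_prob Probability a patient first receives a
#'   non-obstructive code and later an obstructive one.
#' @param exclusion_code_prob Probability of carrying a study-exclusion
#'   condition code.
#' @param comorbidity_prob_by_class Per-class probability of baseline
#'   comorbidity codes in the 2 years before diagnosis.
#' @param recorded_nyha_prob Probability the latent class is written to the
#'   record as a recorded NYHA code at diagnosis.
#' @param quality_fail_prob,linkage_fail_prob Probabilities of failing the
#'   provider-determined research-quality and linkage-eligibility flags.
#' @param unit_cost_seed_table Unit-cost table (see [default_unit_costs()]).
#' @param seed Default seed used by [generate_population()].
#' @return A validated list of class `hcm_gen_config`.
#' @export
gen_config <- function(n_patients = 300,
                       study_start = as.Date("2007-04-01"),
                       study_end = as.Date("2020-10-30"),
                       age_mean = 61, age_sd = 15.6,
                       sex_fraction_male = 0.619,
                       initial_class_probs = c(0.259, 0.339, 0.377, 0.025),
                       monthly_transition_matrix = default_transition_matrix(),
                       symptom_rate_by_class = c(0.02, 0.10, 0.20, 0.40),
                       rx_policy_by_class = default_rx_policy(),
                       rule_consistent_symptoms = TRUE,
                       event_rates_by_class = list(
                         stroke = c(2, 6, 12, 20),
                         af_flutter = c(6, 10, 14, 19),
                         mi = c(3, 6, 12, 21)
                       ),
                       activity_rates_by_class = list(
                         gp = c(4, 6, 8, 12),
                         nurse = c(1, 2, 3, 4),
                         telephone = c(1, 1.5, 2, 3),
                         out_of_hours = c(0.1, 0.2, 0.3, 0.5),
                         outpatient = c(1, 2, 3, 5),
                         ae = c(0.2, 0.5, 1, 2),
                         elective = c(0.1, 0.2, 0.3, 0.4),
                         day_case = c(0.2, 0.3, 0.5, 0.8),
                         critical_care = c(0.01, 0.02, 0.05, 0.2),
                         procedure = c(1, 2, 3, 4)
                       ),
                       other_rx_monthly_prob = c(atorvastatin = 0.05, aspirin = 0.04),
                       monthly_death_rate_by_class = c(0, 0, 0, 0),
                       fraction_obstructive = 0.579,
                       both_codes_prob = 0.006,
                       exclusion_code_prob = 0.02,
                       comorbidity_prob_by_class = c(0.45, 0.55, 0.70, 0.85),
                       recorded_nyha_prob = 0.0126,
                       quality_fail_prob = 0.02,
                       linkage_fail_prob = 0.05,
                       unit_cost_seed_table = default_unit_costs(),
                       seed = 1L) {
  cfg <- list(
    n_patients = n_patients, study_start = as.Date(study_start),
    study_end = as.Date(study_end), age_mean = age_mean, age_sd = age_sd,
    sex_fraction_male = sex_fraction_male,
    initial_class_probs = initial_class_probs,
    monthly_transition_matrix = monthly_transition_matrix,
    symptom_rate_by_class = symptom_rate_by_class,
    rx_policy_by_class = rx_policy_by_class,
    rule_consistent_symptoms = rule_consistent_symptoms,
    event_rates_by_class = event_rates_by_class,
    activity_rates_by_class = activity_rates_by_class,
    other_rx_monthly_prob = other_rx_monthly_prob,
    monthly_death_rate_by_class = monthly_death_rate_by_class,
    fraction_obstructive = fraction_obstructive,
    both_codes_prob = both_codes_prob,
    exclusion_code_prob = exclusion_code_prob,
    comorbidity_prob_by_class = comorbidity_prob_by_class,
    recorded_nyha_prob = recorded_nyha_prob,
    quality_fail_prob = quality_fail_prob,
    linkage_fail_prob = linkage_fail_prob,
    unit_cost_seed_table = unit_cost_seed_table,
    seed = seed
  )
  validate_gen_config(cfg)
  structure(cfg, class = "hcm_gen_config")
}

validate_gen_config <- function(cfg) {
  check_that(cfg$n_patients >= 0, "n_patients must be non-negative")
  check_that(cfg$study_start < cfg$study_end, "study_start must precede study_end")
  check_that(length(cfg$initial_class_probs) == 4 &&
               all(cfg$initial_class_probs >= 0) &&
               abs(sum(cfg$initial_class_probs) - 1) <= 1e-12,
             "initial_class_probs must be a 4-vector summing to 1")
  P <- cfg$monthly_transition_matrix
  check_that(is.matrix(P) && all(dim(P) == c(4, 4)) && all(P >= 0) &&
               all(abs(rowSums(P) - 1) <= 1e-12),
             "monthly_transition_matrix must be 4x4 row-stochastic")
  rates_ok <- all(vapply(cfg$event_rates_by_class, function(r) all(r >= 0), TRUE)) &&
    all(vapply(cfg$activity_rates_by_class, function(r) all(r >= 0), TRUE)) &&
    all(cfg$symptom_rate_by_class >= 0) && all(cfg$monthly_death_rate_by_class >= 0)
  check_that(rates_ok, "all rates must be non-negative")
  invisible(cfg)
}

#' Simulate one latent severity path
#'
#' Evolves a single patient's latent NYHA class monthly (30-day grid) over
#' the half-open registration window `[reg_start, reg_end)`. Uses the
#' current RNG state; seed before calling for reproducibility.
#'
#' @param reg_start,reg_end Registration window (dates); a zero-length
#'   window yields an empty path.
#' @param initial_class Integer NYHA class 1-4 at `reg_start`.
#' @param config An [gen_config()] object (transition matrix is read from it).
#' @return A tibble with one row per month: `month`, `start`, `end`
#'   (half-open dates) and `nyha_class`.
#' @export
simulate_severity_path <- function(reg_start, reg_end, initial_class, config) {
  P <- config$monthly_transition_matrix
  check_that(is.matrix(P) && all(abs(rowSums(P) - 1) <= 1e-12) && all(P >= 0),
             "transition matrix must be row-stochastic")
  reg_start <- as.Date(reg_start)
  reg_end <- as.Date(reg_end)
  n_days <- as.integer(reg_end - reg_start)
  if (n_days <= 0L) {
    return(tibble(month = integer(), start = as.Date(character()),
                  end = as.Date(character()), nyha_class = integer()))
  }
  n_months <- as.integer(ceiling(n_days / 30))
  states <- integer(n_months)
  states[1L] <- as.integer(initial_class)
  if (n_months > 1L) {
    u <- runif(n_months - 1L)
    cp <- t(apply(P, 1L, cumsum))
    for (m in seq_len(n_months - 1L)) {
      states[m + 1L] <- findInterval(u[m], cp[states[m], ], left.open = TRUE) + 1L
    }
  }
  start <- reg_start + 30L * (seq_len(n_months) - 1L)
  end <- pmin(start + 30L, reg_end)
  tibble(month = seq_len(n_months), start = start, end = end,
         nyha_class = states)
}

# concept -> (vocabulary, code) lookup used by the emitter
concept_lookup <- function(codelists = default_codelists()) {
  codelists |>
    group_by(.data$concept) |>
    slice(1L) |>
    ungroup() |>
    select("concept", "vocabulary", "code")
}

# internal per-patient emitter on plain vectors; `path` is the monthly tibble
# from simulate_severity_path(). Returns a list of plain data.frames.
emit_patient <- function(path, config, patient_id, diagnosis_date, lk,
                         death_date = as.Date(NA)) {
  n_m <- nrow(path)
  ms <- path$start
  me <- path$end
  len <- as.integer(me - ms)
  st <- path$nyha_class
  reg_start <- ms[1L]
  reg_end <- me[n_m]
  horizon <- if (is.na(death_date)) reg_end else min(reg_end, death_date + 1L)

  code_of <- function(concepts) {
    i <- match(concepts, lk$concept)
    list(vocabulary = lk$vocabulary[i], code = lk$code[i])
  }
  ev_concept <- character(0); ev_date <- numeric(0); ev_setting <- character(0)
  add_event <- function(concepts, dates, setting) {
    keep <- dates < horizon
    ev_concept <<- c(ev_concept, concepts[keep])
    ev_date <<- c(ev_date, as.numeric(dates[keep]))
    ev_setting <<- c(ev_setting, rep(setting, sum(keep)))
  }

  # HCM diagnosis code(s); index derives from these downstream
  if (runif(1) < config$both_codes_prob) {
    add_event("hcm_nonobstructive", diagnosis_date, "primary")
    later <- diagnosis_date + sample(30:400, 1L)
    add_event("hcm_obstructive", min(later, reg_end - 1L), "primary")
  } else if (runif(1) < config$fraction_obstructive) {
    add_event("hcm_obstructive", diagnosis_date, "primary")
  } else {
    add_event(sample(c("hcm_nonobstructive", "hcm_unspecified"), 1L),
              diagnosis_date, "primary")
  }

  # exclusion condition
  if (runif(1) < config$exclusion_code_prob) {
    excl <- sample(c("hypertensive_heart_disease", "aortic_stenosis",
                     "athletes_heart", "amyloidosis", "takotsubo"), 1L)
    add_event(excl, reg_start + sample.int(max(1L, as.integer(reg_end - reg_start)), 1L) - 1L,
              "primary")
  }

  # baseline comorbidities in the 2 years before diagnosis
  diag_month <- min(n_m, findInterval(as.numeric(diagnosis_date), as.numeric(ms)))
  if (runif(1) < config$comorbidity_prob_by_class[st[diag_month]]) {
    pool <- c("hypertension", "af_flutter", "t2dm", "ihd", "asthma",
              "depression", "ckd", "copd", "mi")
    k <- sample.int(3L, 1L)
    picks <- sample(pool, k)
    lo <- as.numeric(max(reg_start, diagnosis_date - 730L))
    d <- as.Date(lo + floor(runif(k) * max(1, as.numeric(diagnosis_date) - lo + 1)),
                 origin = "1970-01-01")
    add_event(picks, pmin(d, diagnosis_date), "primary")
  }

  # recorded NYHA class code at diagnosis (rare)
  if (runif(1) < config$recorded_nyha_prob) {
    add_event(c("nyha_i", "nyha_ii", "nyha_iii", "nyha_iv")[st[diag_month]],
              diagnosis_date, "primary")
  }

  # symptoms: monthly Bernoulli with class-dependent probability
  symp_m <- which(runif(n_m) < config$symptom_rate_by_class[st])
  if (length(symp_m)) {
    concepts <- if (config$rule_consistent_symptoms) {
      rep("breathlessness", length(symp_m))
    } else {
      sample(default_codelists()$concept[default_codelists()$is_symptom],
             length(symp_m), replace = TRUE)
    }
    add_event(concepts, ms[symp_m] + floor(runif(length(symp_m)) * len[symp_m]),
              "primary")
  }

  # clinical events: monthly Poisson at class-dependent rates (per 100 PY)
  true_event <- character(0); true_event_date <- numeric(0)
  for (evn in names(config$event_rates_by_class)) {
    lam <- config$event_rates_by_class[[evn]][st] / 100 * len / DAYS_PER_YEAR
    cnt <- rpois(n_m, lam)
    hit <- which(cnt > 0L)
    if (length(hit)) {
      m_rep <- rep(hit, cnt[hit])
      d <- ms[m_rep] + floor(runif(length(m_rep)) * len[m_rep])
      keep <- d < horizon
      true_event <- c(true_event, rep(evn, sum(keep)))
      true_event_date <- c(true_event_date, as.numeric(d[keep]))
      add_event(rep(evn, length(m_rep)), d, "secondary")
    }
  }

  # prescriptions: regimen per latent class (one policy draw per class),
  # issued at each month start with 30 days' supply
  rx_product <- character(0); rx_date <- numeric(0)
  policy_pick <- lapply(config$rx_policy_by_class, function(opts) {
    probs <- vapply(opts, function(o) o$prob, 0)
    opts[[sample.int(length(opts), 1L, prob = probs)]]$products
  })
  for (m in seq_len(n_m)) {
    if (ms[m] >= horizon) break
    prods <- policy_pick[[st[m]]]
    if (length(prods)) {
      rx_product <- c(rx_product, prods)
      rx_date <- c(rx_date, rep(as.numeric(ms[m]), length(prods)))
    }
  }
  for (prod in names(config$other_rx_monthly_prob)) {
    hit <- which(runif(n_m) < config$other_rx_monthly_prob[[prod]] & as.numeric(ms) < as.numeric(horizon))
    if (length(hit)) {
      rx_product <- c(rx_product, rep(prod, length(hit)))
      rx_date <- c(rx_date, as.numeric(ms[hit]) + floor(runif(length(hit)) * len[hit]))
    }
  }

  # hospital activity
  ha_admit <- numeric(0); ha_disch <- numeric(0); ha_type <- character(0); ha_hrg <- character(0)
  hrg_codes <- default_hrg_costs()$hrg_code
  add_hosp <- function(adm, type, los, hrg) {
    keep <- adm < horizon
    adm <- adm[keep]
    ha_admit <<- c(ha_admit, as.numeric(adm))
    ha_disch <<- c(ha_disch, as.numeric(pmin(adm + los[keep], reg_end)))
    ha_type <<- c(ha_type, rep(type, length(adm)))
    ha_hrg <<- c(ha_hrg, if (is.null(hrg)) rep(NA_character_, length(adm)) else
      sample(hrg_codes, length(adm), replace = TRUE))
  }
  # heart-failure hospitalization at entry to latent class IV and every
  # 90 days while it persists: the signal the class-IV proxy branch keys
  # on (90-day look-back keeps the proxy in IV between admissions)
  iv_all <- which(st == 4L & as.numeric(ms) < as.numeric(horizon))
  if (length(iv_all)) {
    sel <- logical(length(iv_all))
    cnt <- 0L
    for (k in seq_along(iv_all)) {
      if (k == 1L || iv_all[k] != iv_all[k - 1L] + 1L) cnt <- 0L
      sel[k] <- cnt %% 3L == 0L
      cnt <- cnt + 1L
    }
    iv_m <- iv_all[sel]
    add_hosp(ms[iv_m], "non_elective", rpois(length(iv_m), 4) + 1L, hrg = TRUE)
    add_event(rep("heart_failure", length(iv_m)), ms[iv_m], "secondary")
  }
  act <- config$activity_rates_by_class
  consult_types <- intersect(names(act), c("gp", "nurse", "telephone", "out_of_hours"))
  hosp_types <- intersect(names(act), c("outpatient", "ae", "elective", "day_case",
                                        "critical_care"))
  draw_monthly <- function(rates) {
    cnt <- rpois(n_m, rates[st] * len / DAYS_PER_YEAR)
    hit <- which(cnt > 0L)
    m_rep <- rep(hit, cnt[hit])
    d <- if (length(m_rep)) ms[m_rep] + floor(runif(length(m_rep)) * len[m_rep]) else ms[0]
    d[d < horizon]
  }
  co_date <- numeric(0); co_type <- character(0)
  for (tp in consult_types) {
    d <- draw_monthly(act[[tp]])
    co_date <- c(co_date, as.numeric(d))
    co_type <- c(co_type, rep(tp, length(d)))
  }
  for (tp in hosp_types) {
    d <- draw_monthly(act[[tp]])
    if (length(d)) {
      los <- switch(tp,
        elective = rpois(length(d), 2),
        day_case = rep(0L, length(d)),
        rep(0L, length(d))
      )
      add_hosp(d, tp, los, hrg = if (tp %in% c("elective", "day_case")) TRUE else NULL)
    }
  }
  if ("procedure" %in% names(act)) {
    d <- draw_monthly(act$procedure)
    if (length(d)) {
      ev_concept <- c(ev_concept, rep("procedure", length(d)))
      ev_date <- c(ev_date, as.numeric(d))
      ev_setting <- c(ev_setting, rep("secondary", length(d)))
    }
  }

  ccodes <- code_of(ev_concept)
  list(
    clinical_events = qdf(
      patient_id = rep(patient_id, length(ev_date)), date = ev_date,
      vocabulary = ifelse(ev_concept == "procedure", "OPCS", ccodes$vocabulary),
      code = ifelse(ev_concept == "procedure", "PROC", ccodes$code),
      setting = ev_setting
    ),
    prescriptions = qdf(
      patient_id = rep(patient_id, length(rx_date)), date = rx_date,
      product = rx_product,
      therapy_class = default_drug_map()$therapy_class[
        match(rx_product, default_drug_map()$product)],
      days_supply = rep(30L, length(rx_date))
    ),
    consultations = qdf(
      patient_id = rep(patient_id, length(co_date)), date = co_date,
      type = co_type
    ),
    hospital_activity = qdf(
      patient_id = rep(patient_id, length(ha_admit)), admit_date = ha_admit,
      discharge_date = ha_disch, type = ha_type, hrg_code = ha_hrg
    ),
    truth_events = qdf(
      patient_id = rep(patient_id, length(true_event_date)),
      event = true_event, date = true_event_date
    )
  )
}

#' Emit observable EHR rows for one latent path
#'
#' Draws one patient's coded events, prescriptions, consultations and
#' hospital activity conditional on a latent severity path, using the
#' current RNG state. The HCM diagnosis code is placed at `diagnosis_date`.
#'
#' @param path Monthly path tibble from [simulate_severity_path()]
#'   (non-empty).
#' @param config An [gen_config()] object.
#' @param patient_id Identifier written to every row.
#' @param diagnosis_date Date of the HCM diagnosis code; defaults to one
#'   year into the path (clipped to the path range).
#' @return Named list of tibbles: `clinical_events`, `prescriptions`,
#'   `consultations`, `hospital_activity`, `truth_events`.
#' @export
emit_observations <- function(path, config, patient_id = "P000001",
                              diagnosis_date = NULL) {
  check_that(nrow(path) > 0, "path must be non-empty")
  if (is.null(diagnosis_date)) {
    diagnosis_date <- min(path$start[1L] + 365L, max(path$end) - 1L)
  }
  lk <- concept_lookup()
  out <- emit_patient(path, config, patient_id, as.Date(diagnosis_date), lk)
  lapply(out, finalize_table)
}

finalize_table <- function(df) {
  tb <- as_tibble(df)
  for (cl in intersect(names(tb), c("date", "admit_date", "discharge_date"))) {
    tb[[cl]] <- as.Date(tb[[cl]], origin = "1970-01-01")
  }
  tb
}

#' Generate a synthetic EHR extract
#'
#' Simulates `config$n_patients` independent patients: demographics and a
#' registration window, a latent monthly NYHA severity path, and observable
#' rows emitted from it. A single global seed streams per-patient sub-seeds,
#' so any one patient regenerates identically regardless of cohort size.
#'
#' @param config An [gen_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `hcm_ehr` with tibbles `patients`,
#'   `clinical_events`, `prescriptions`, `consultations`,
#'   `hospital_activity`, `deaths`, and `truth` (list: `paths` latent
#'   class intervals, `events` true event times), plus the `config`.
#' @examples
#' ehr <- generate_population(gen_config(n_patients = 20), seed = 42)
#' nrow(ehr$patients)
#' @export
generate_population <- function(config, seed = config$seed) {
  validate_gen_config(config)
  n <- config$n_patients
  check_that(n >= 0, "n_patients must be non-negative")
  lk <- concept_lookup()
  set.seed(seed)
  sub_seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n) else integer(0)

  pats <- vector("list", n)
  parts <- vector("list", n)
  truth_paths <- vector("list", n)
  span <- as.integer(config$study_end - config$study_start)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    pid <- sprintf("P%06d", i)
    reg_start <- config$study_start +
      sample.int(max(1L, min(6L * 365L, span - 400L)), 1L)
    reg_len <- 730L + as.integer(rexp(1, 1 / (6 * 365)))
    reg_end <- min(config$study_end, reg_start + reg_len)
    n_days <- as.integer(reg_end - reg_start)
    # diagnosis tends to fall early in registration (squared-uniform draw),
    # giving a realistic mean follow-up of roughly five years
    diagnosis_date <- if (n_days <= 400L) {
      reg_start + sample.int(max(1L, n_days), 1L) - 1L
    } else {
      reg_start + 365L + as.integer(floor(runif(1)^2 * (n_days - 395L)))
    }
    age <- min(95, max(16, rnorm(1, config$age_mean, config$age_sd)))
    birth_year <- as.integer(format(diagnosis_date, "%Y")) - as.integer(floor(age))
    init <- sample.int(4L, 1L, prob = config$initial_class_probs)
    path <- simulate_severity_path(reg_start, reg_end, init, config)

    death_date <- as.Date(NA)
    if (any(config$monthly_death_rate_by_class > 0)) {
      u <- runif(nrow(path))
      hit <- which(u < config$monthly_death_rate_by_class[path$nyha_class])
      if (length(hit)) {
        m <- hit[1L]
        death_date <- path$start[m] +
          sample.int(as.integer(path$end[m] - path$start[m]), 1L) - 1L
      }
    }

    parts[[i]] <- emit_patient(path, config, pid, diagnosis_date, lk, death_date)
    parts[[i]]$deaths <- qdf(
      patient_id = rep(pid, !is.na(death_date)),
      date = as.numeric(death_date)[!is.na(death_date)],
      cause_code = rep("R99", !is.na(death_date))
    )
    r <- rle(path$nyha_class)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    truth_paths[[i]] <- qdf(
      patient_id = rep(pid, length(r$values)),
      start = as.numeric(path$start[idx_start]),
      end = as.numeric(path$end[idx_end]),
      nyha_class = r$values
    )
    pats[[i]] <- qdf(
      patient_id = pid, birth_year = birth_year,
      sex = if (runif(1) < config$sex_fraction_male) "M" else "F",
      ethnicity = sample(c("white", "asian", "black", "mixed", "other", "unknown"),
                         1L, prob = c(0.791, 0.089, 0.063, 0.012, 0.016, 0.029)),
      reg_start = as.numeric(reg_start), reg_end = as.numeric(reg_end),
      practice_last_collection = as.numeric(
        min(config$study_end, reg_end + sample.int(365L, 1L))),
      acceptable_quality = runif(1) >= config$quality_fail_prob,
      linkage_eligible = runif(1) >= config$linkage_fail_prob
    )
  }

  bind_part <- function(name) {
    tb <- finalize_table(bind_rows(lapply(parts, `[[`, name)))
    if (nrow(tb) == 0 && name == "deaths") {
      tb <- tibble(patient_id = character(), date = as.Date(character()),
                   cause_code = character())
    }
    tb
  }
  patients <- finalize_table(bind_rows(pats))
  for (cl in c("reg_start", "reg_end", "practice_last_collection")) {
    if (nrow(patients)) patients[[cl]] <- as.Date(patients[[cl]], origin = "1970-01-01")
  }
  if (n == 0) {
    patients <- tibble(patient_id = character(), birth_year = integer(),
                       sex = character(), ethnicity = character(),
                       reg_start = as.Date(character()), reg_end = as.Date(character()),
                       practice_last_collection = as.Date(character()),
                       acceptable_quality = logical(), linkage_eligible = logical())
  }
  truth_paths_tb <- finalize_table(bind_rows(truth_paths))
  if (nrow(truth_paths_tb)) {
    truth_paths_tb$start <- as.Date(truth_paths_tb$start, origin = "1970-01-01")
    truth_paths_tb$end <- as.Date(truth_paths_tb$end, origin = "1970-01-01")
  } else {
    truth_paths_tb <- tibble(patient_id = character(), start = as.Date(character()),
                             end = as.Date(character()), nyha_class = integer())
  }
  empty_or <- function(tb, proto) if (nrow(tb)) tb else proto
  structure(list(
    patients = patients,
    clinical_events = empty_or(bind_part("clinical_events"),
      tibble(patient_id = character(), date = as.Date(character()),
             vocabulary = character(), code = character(), setting = character())),
    prescriptions = empty_or(bind_part("prescriptions"),
      tibble(patient_id = character(), date = as.Date(character()),
             product = character(), therapy_class = character(),
             days_supply = integer())),
    consultations = empty_or(bind_part("consultations"),
      tibble(patient_id = character(), date = as.Date(character()),
             type = character())),
    hospital_activity = empty_or(bind_part("hospital_activity"),
      tibble(patient_id = character(), admit_date = as.Date(character()),
             discharge_date = as.Date(character()), type = character(),
             hrg_code = character())),
    deaths = bind_part("deaths"),
    truth = list(
      paths = truth_paths_tb,
      events = empty_or(bind_part("truth_events"),
        tibble(patient_id = character(), event = character(),
               date = as.Date(character())))
    ),
    config = config
  ), class = "hcm_ehr")
}

#' @export
print.hcm_ehr <- function(x, ...) {
  cat("<hcm_ehr> synthetic EHR extract\n")
  cat("  patients:          ", nrow(x$patients), "\n")
  cat("  clinical events:   ", nrow(x$clinical_events), "\n")
  cat("  prescriptions:     ", nrow(x$prescriptions), "\n")
  cat("  consultations:     ", nrow(x$consultations), "\n")
  cat("  hospital activity: ", nrow(x$hospital_activity), "\n")
  cat("  deaths:            ", nrow(x$deaths), "\n")
  invisible(x)
}
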