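# Fixture builders and independent oracles, constructed in code.

CL <- default_codelists()
DM <- default_drug_map()

# minimal empty EHR extract with a config stub
empty_ehr <- function(study_start = as.Date("2008-01-01"),
                      study_end = as.Date("2020-12-31")) {
  list(
    patients = tibble::tibble(
      patient_id = character(), birth_year = integer(), sex = character(),
      ethnicity = character(), reg_start = as.Date(character()),
      reg_end = as.Date(character()),
      practice_last_collection = as.Date(character()),
      acceptable_quality = logical(), linkage_eligible = logical()),
    clinical_events = tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      vocabulary = character(), code = character(), setting = character()),
    prescriptions = tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      product = character(), therapy_class = character(),
      days_supply = integer()),
    consultations = tibble::tibble(
      patient_id = character(), date = as.Date(character()), type = character()),
    hospital_activity = tibble::tibble(
      patient_id = character(), admit_date = as.Date(character()),
      discharge_date = as.Date(character()), type = character(),
      hrg_code = character()),
    deaths = tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      cause_code = character()),
    config = list(study_start = study_start, study_end = study_end)
  )
}

add_patient <- function(ehr, id, reg_start, reg_end, birth_year = 1950L,
                        sex = "M", plc = NULL, quality = TRUE, linkage = TRUE) {
  ehr$patients <- dplyr::bind_rows(ehr$patients, tibble::tibble(
    patient_id = id, birth_year = as.integer(birth_year), sex = sex,
    ethnicity = "white", reg_start = as.Date(reg_start),
    reg_end = as.Date(reg_end),
    practice_last_collection = as.Date(if (is.null(plc)) ehr$config$study_end else plc),
    acceptable_quality = quality, linkage_eligible = linkage))
  ehr
}

# add a coded clinical event by concept name (codes resolved from CL)
add_code <- function(ehr, id, date, concept, setting = "primary") {
  row <- CL[match(concept, CL$concept), ]
  stopifnot(!is.na(row$code))
  ehr$clinical_events <- dplyr::bind_rows(ehr$clinical_events, tibble::tibble(
    patient_id = id, date = as.Date(date), vocabulary = row$vocabulary,
    code = row$code, setting = setting))
  ehr
}

add_rx <- function(ehr, id, date, product, days_supply = 28L) {
  cls <- DM$therapy_class[match(product, DM$product)]
  ehr$prescriptions <- dplyr::bind_rows(ehr$prescriptions, tibble::tibble(
    patient_id = id, date = as.Date(date), product = product,
    therapy_class = cls, days_supply = as.integer(days_supply)))
  ehr
}

# one-row cohort tibble for classifier-level tests
mini_cohort <- function(id, index, followup_end, cohort = "obstructive") {
  tibble::tibble(
    patient_id = id, index_date = as.Date(index), cohort = cohort,
    included = TRUE, followup_start = as.Date(index),
    followup_end = as.Date(followup_end))
}

# expand a NYHA interval tibble to one class per day (relative to index)
expand_days <- function(intervals, id, index) {
  iv <- intervals[intervals$patient_id == id, ]
  iv <- iv[order(iv$start), ]
  unlist(lapply(seq_len(nrow(iv)), function(i) {
    rep(iv$nyha_class[i], as.integer(iv$end[i] - iv$start[i]))
  }))
}

# --- independent day-by-day reference classifier -------------------------
# Literal replay of the proxy rules, one calendar day at a time. Kept free
# of the package's interval algebra on purpose.
ref_daily_nyha <- function(index, L, rx, sym, hf_dates, rec, interventions,
                           rs = nyha_ruleset(), ratchet = TRUE) {
  index <- as.Date(index)
  raw <- integer(L)
  for (d in 0:(L - 1)) {
    today <- index + d
    active <- rep(FALSE, nrow(rx))
    if (nrow(rx)) {
      active <- rx$date <= today &
        today < rx$date + rx$days_supply + rs$supply_grace_days
    }
    prods <- unique(rx$product[active])
    any_diso <- any(rx$therapy_class[active] == "disopyramide")
    any_loop <- any(rx$is_loop[active])
    hf_recent <- any(hf_dates <= today & today < hf_dates + rs$hf_lookback_days)
    cls <- if (hf_recent) 4L
    else if (any_diso || any_loop || length(prods) >= 2L) 3L
    else if (length(prods) == 1L) 2L else 1L
    n_sym <- length(unique(sym$concept[sym$date <= today &
                                         today < sym$date + rs$symptom_lookback_days]))
    if (n_sym >= rs$symptom_min_distinct) cls <- min(4L, cls + rs$symptom_step)
    raw[d + 1L] <- cls
  }
  # baseline class (recorded wins; else med window + baseline symptoms)
  rec_pre <- rec[rec$date <= index, , drop = FALSE]
  if (nrow(rec_pre)) {
    b <- rec_pre$nyha_class[which.max(as.numeric(rec_pre$date))]
  } else {
    off <- as.integer(rx$date - index)
    w <- off >= rs$med_window[1] & off <= rs$med_window[2]
    prods <- unique(rx$product[w])
    b <- if (any(hf_dates >= index - rs$hf_lookback_days & hf_dates <= index)) 4L
    else if (any(rx$therapy_class[w] == "disopyramide") || any(rx$is_loop[w]) ||
             length(prods) >= 2L) 3L
    else if (length(prods) == 1L) 2L else 1L
    n_sym <- length(unique(
      sym$concept[sym$date >= index - rs$baseline_symptom_lookback_days &
                    sym$date <= index]))
    if (n_sym >= rs$symptom_min_distinct) b <- min(4L, b + rs$symptom_step)
  }
  # overrides: baseline at day 0, recorded codes at their day, each holding
  # until the raw series next changes value
  cls <- raw
  prov <- rep("proxy", L)
  apply_ov <- function(cls, prov, day0, k, pv) {
    v <- raw[day0 + 1L]
    d <- day0
    while (d < L && raw[d + 1L] == v) {
      cls[d + 1L] <- k
      prov[d + 1L] <- pv
      d <- d + 1L
    }
    list(cls = cls, prov = prov)
  }
  o <- apply_ov(cls, prov, 0L, b,
                if (nrow(rec_pre)) "recorded" else "proxy")
  cls <- o$cls; prov <- o$prov
  rec_in <- rec[rec$date > index & rec$date < index + L, , drop = FALSE]
  rec_in <- rec_in[order(rec_in$date), , drop = FALSE]
  for (i in seq_len(nrow(rec_in))) {
    o <- apply_ov(cls, prov, as.integer(rec_in$date[i] - index),
                  rec_in$nyha_class[i], "recorded")
    cls <- o$cls; prov <- o$prov
  }
  if (!ratchet) return(cls)
  out <- cls
  prev <- NA_integer_
  spell <- NA_integer_
  ivd <- as.integer(as.Date(interventions) - index)
  for (d in 0:(L - 1)) {
    cj <- cls[d + 1L]
    if (prov[d + 1L] != "recorded" && cj == 1L && !is.na(prev) && prev >= 2L) {
      if (!any(ivd >= spell & ivd <= d)) cj <- prev
    }
    out[d + 1L] <- cj
    if ((is.na(prev) || prev == 1L) && cj >= 2L) spell <- d
    prev <- cj
  }
  out
}

# --- brute-force product-limit oracle ------------------------------------
bf_km <- function(times, status) {
  ts <- sort(unique(times[status == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & status == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  tibble::tibble(time = ts, surv = surv)
}
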