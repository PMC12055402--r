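# Proxy NYHA classification: baseline decision tree, daily time-varying
# classification, asymptomatic-correction ratchet, interval compression.
#
# The daily algorithm is computed event-wise on a piecewise-constant
# representation (every input that can change the class opens or closes a
# dated half-open interval), which is exactly equivalent to evaluating the
# rules on every calendar day; tests verify this against a literal
# day-by-day replay.

#' Proxy NYHA ruleset
#'
#' Tunable parameters of the classifier. The published decision tree's
#' internal branches are not public; the default ruleset here is: no
#' HCM-relevant therapy and no symptoms -> I; a single active agent (BB or
#' non-dihydropyridine CCB) -> II; two or more agents, or disopyramide, or a
#' loop diuretic -> III; heart-failure hospitalization within the look-back
#' -> IV; then one class added (capped at IV) when at least
#' `symptom_min_distinct` distinct symptom concepts occur within the
#' symptom look-back. Every branch is overridable.
#'
#' @param med_window Baseline medication window as day offsets from index
#'   (inclusive); default -2 to +28.
#' @param supply_grace_days Days a prescription stays "active" beyond its
#'   days' supply in the daily algorithm.
#' @param symptom_lookback_days Daily symptom look-back.
#' @param baseline_symptom_lookback_days Symptom look-back for the baseline
#'   classification.
#' @param hf_lookback_days Window after a heart-failure hospitalization
#'   during which the class IV branch holds.
#' @param symptom_min_distinct Distinct symptom concepts required to step
#'   the class up.
#' @param symptom_step Classes added by the symptom adjustment.
#' @param intervention_concepts Codelist concepts whose occurrence releases
#'   the ratchet (septal reduction therapy, device insertion by default).
#' @param therapy_initiation_releases Whether starting any new
#'   HCM-relevant product also counts as an intervention.
#' @param ratchet Apply the asymptomatic correction (symptomatic patients
#'   cannot return to class I without an intervention).
#' @return List of class `hcm_nyha_ruleset`.
#' @export
nyha_ruleset <- function(med_window = c(-2L, 28L),
                         supply_grace_days = 30L,
                         symptom_lookback_days = 90L,
                         baseline_symptom_lookback_days = 90L,
                         hf_lookback_days = 90L,
                         symptom_min_distinct = 2L,
                         symptom_step = 1L,
                         intervention_concepts = c("srt", "icd_insertion", "pacemaker"),
                         therapy_initiation_releases = TRUE,
                         ratchet = TRUE) {
  rs <- list(
    med_window = as.integer(med_window),
    supply_grace_days = as.integer(supply_grace_days),
    symptom_lookback_days = as.integer(symptom_lookback_days),
    baseline_symptom_lookback_days = as.integer(baseline_symptom_lookback_days),
    hf_lookback_days = as.integer(hf_lookback_days),
    symptom_min_distinct = as.integer(symptom_min_distinct),
    symptom_step = as.integer(symptom_step),
    intervention_concepts = intervention_concepts,
    therapy_initiation_releases = isTRUE(therapy_initiation_releases),
    ratchet = isTRUE(ratchet)
  )
  check_that(length(rs$med_window) == 2 && rs$med_window[1] <= rs$med_window[2],
             "med_window must be an ordered pair of day offsets")
  check_that(rs$symptom_step >= 0 && rs$symptom_min_distinct >= 1,
             "symptom adjustment parameters out of range")
  structure(rs, class = "hcm_nyha_ruleset")
}

# split a keyed table into a per-patient list aligned with `ids`
split_by_patient <- function(df, ids) {
  f <- factor(df$patient_id, levels = ids)
  keep <- !is.na(f)
  split(as.data.frame(df[keep, , drop = FALSE]), f[keep], drop = FALSE)
}

# classifier inputs, pre-joined and split per patient
nyha_inputs <- function(ehr, cohort, codelists, drug_map, ruleset) {
  coh <- cohort |>
    filter(.data$included, .data$followup_end > .data$index_date)
  ids <- coh$patient_id
  coded <- join_codelists(ehr$clinical_events, codelists)
  rx <- ehr$prescriptions |>
    select("patient_id", "date", "product", "days_supply") |>
    filter(.data$days_supply > 0) |>
    inner_join(drug_map, by = "product") |>
    filter(.data$is_hcm_specific | .data$is_loop_diuretic)
  list(
    cohort = coh,
    rx = split_by_patient(rx, ids),
    sym = split_by_patient(
      coded |> filter(.data$is_symptom) |> select("patient_id", "date", "concept"), ids),
    hf = split_by_patient(
      coded |> filter(.data$concept == "heart_failure", .data$setting == "secondary") |>
        select("patient_id", "date"), ids),
    rec = split_by_patient(
      coded |> filter(.data$is_nyha) |>
        select("patient_id", "date", rec_class = "nyha_class"), ids),
    ivc = split_by_patient(
      coded |> filter(.data$concept %in% ruleset$intervention_concepts) |>
        select("patient_id", "date"), ids)
  )
}

# baseline class for one patient from pre-split inputs (dates, not offsets)
baseline_one <- function(index, rx_i, sym_i, hf_i, rec_i, rs) {
  rec_pre <- rec_i[rec_i$date <= index, , drop = FALSE]
  if (nrow(rec_pre)) {
    k <- rec_pre$rec_class[which.max(as.numeric(rec_pre$date))]
    return(list(class = as.integer(k), provenance = "recorded"))
  }
  rel_rx <- as.integer(rx_i$date - index)
  in_win <- rel_rx >= rs$med_window[1] & rel_rx <= rs$med_window[2]
  prods <- unique(rx_i$product[in_win])
  any_diso <- any(rx_i$therapy_class[in_win] == "disopyramide")
  any_loop <- any(rx_i$is_loop_diuretic[in_win])
  hf_recent <- any(hf_i$date >= index - rs$hf_lookback_days & hf_i$date <= index)
  cls <- if (hf_recent) 4L
  else if (any_diso || any_loop || length(prods) >= 2L) 3L
  else if (length(prods) == 1L) 2L
  else 1L
  n_sym <- length(unique(
    sym_i$concept[sym_i$date >= index - rs$baseline_symptom_lookback_days &
                    sym_i$date <= index]))
  if (n_sym >= rs$symptom_min_distinct) {
    cls <- min(4L, cls + rs$symptom_step)
  }
  list(class = cls, provenance = "proxy")
}

#' Baseline proxy NYHA classification
#'
#' A recorded NYHA class code on or before the index date always wins
#' (closest code; provenance "recorded"). Otherwise the class is derived
#' from prescriptions dated in the baseline medication window and adjusted
#' for recorded symptoms (provenance "proxy").
#'
#' @param ehr An `hcm_ehr` list (or equivalent tables).
#' @param cohort Cohort tibble from [build_cohort()]; only included patients
#'   with positive follow-up are classified.
#' @param codelists,drug_map Reference tables.
#' @param ruleset An [nyha_ruleset()].
#' @return Tibble `patient_id`, `nyha_class` (integer 1-4), `provenance`.
#' @export
classify_baseline <- function(ehr, cohort, codelists = default_codelists(),
                              drug_map = default_drug_map(),
                              ruleset = nyha_ruleset()) {
  inp <- nyha_inputs(ehr, cohort, codelists, drug_map, ruleset)
  coh <- inp$cohort
  out <- vector("list", nrow(coh))
  for (i in seq_len(nrow(coh))) {
    b <- baseline_one(coh$index_date[i], inp$rx[[i]], inp$sym[[i]], inp$hf[[i]],
                      inp$rec[[i]], ruleset)
    out[[i]] <- c(b$class, b$provenance)
  }
  tibble(
    patient_id = coh$patient_id,
    nyha_class = vapply(out, function(x) as.integer(x[1]), 1L),
    provenance = vapply(out, function(x) x[2], "")
  )
}

# raw daily series for one patient as uncompressed segments (day offsets)
daily_one <- function(index, L, rx_i, sym_i, hf_i, rec_i, rs) {
  grace <- rs$supply_grace_days
  # merged activity intervals per product (supply + grace)
  p_s <- integer(0); p_e <- integer(0); p_diso <- logical(0); p_loop <- logical(0)
  if (nrow(rx_i)) {
    s <- as.integer(rx_i$date - index)
    e <- s + as.integer(rx_i$days_supply) + grace
    for (pr in unique(rx_i$product)) {
      j <- rx_i$product == pr
      m <- merge_intervals(s[j], e[j])
      p_s <- c(p_s, m$start); p_e <- c(p_e, m$end)
      p_diso <- c(p_diso, rep(rx_i$therapy_class[j][1] == "disopyramide",
                              length(m$start)))
      p_loop <- c(p_loop, rep(isTRUE(rx_i$is_loop_diuretic[j][1]), length(m$start)))
    }
  }
  hf_s <- as.integer(hf_i$date - index)
  hf_e <- hf_s + rs$hf_lookback_days
  sy_s <- integer(0); sy_e <- integer(0)
  if (nrow(sym_i)) {
    ss <- as.integer(sym_i$date - index)
    for (cc in unique(sym_i$concept)) {
      m <- merge_intervals(ss[sym_i$concept == cc],
                           ss[sym_i$concept == cc] + rs$symptom_lookback_days)
      sy_s <- c(sy_s, m$start); sy_e <- c(sy_e, m$end)
    }
  }
  clip <- function(s, e) {
    keep <- e > 0L & s < L
    list(s = pmax(s[keep], 0L), e = pmin(e[keep], L))
  }
  cp <- clip(p_s, p_e)
  cd <- clip(p_s[p_diso], p_e[p_diso])
  cl <- clip(p_s[p_loop], p_e[p_loop])
  ch <- clip(hf_s, hf_e)
  cs <- clip(sy_s, sy_e)
  rec_day <- as.integer(rec_i$date - index)
  rec_keep <- rec_day >= 0L & rec_day < L
  rec_day <- rec_day[rec_keep]
  rec_class <- as.integer(rec_i$rec_class[rec_keep])

  bp <- sort(unique(c(0L, L, cp$s, cp$e, cd$s, cd$e, cl$s, cl$e,
                      ch$s, ch$e, cs$s, cs$e, rec_day)))
  bp <- bp[bp >= 0L & bp <= L]
  seg_s <- bp[-length(bp)]
  seg_e <- bp[-1L]
  nprod <- count_covering(seg_s, cp$s, cp$e)
  ndiso <- count_covering(seg_s, cd$s, cd$e)
  nloop <- count_covering(seg_s, cl$s, cl$e)
  nhf <- count_covering(seg_s, ch$s, ch$e)
  nsym <- count_covering(seg_s, cs$s, cs$e)
  raw <- ifelse(nhf > 0L, 4L,
                ifelse(ndiso > 0L | nloop > 0L | nprod >= 2L, 3L,
                       ifelse(nprod == 1L, 2L, 1L)))
  raw <- pmin(4L, raw + (nsym >= rs$symptom_min_distinct) * rs$symptom_step)
  list(seg_s = seg_s, seg_e = seg_e, raw = as.integer(raw),
       rec_day = rec_day, rec_class = rec_class)
}

# override the class from `day` forward until the raw series next changes
apply_override <- function(cls, prov, raw, seg_s, day, k, pv) {
  j0 <- findInterval(day, seg_s)
  v <- raw[j0]
  j1 <- j0
  n <- length(raw)
  while (j1 < n && raw[j1 + 1L] == v) j1 <- j1 + 1L
  cls[j0:j1] <- k
  prov[j0:j1] <- pv
  list(cls = cls, prov = prov)
}

#' Raw daily proxy NYHA series
#'
#' Applies the daily classification rules over each included patient's
#' follow-up: medications active by date + days' supply + grace, symptoms
#' within the daily look-back, the heart-failure-hospitalization branch,
#' the baseline class at day 0, and recorded NYHA codes overriding the
#' proxy from their date until the next rule-driven change. No ratchet is
#' applied (see [apply_ratchet()]).
#'
#' @inheritParams classify_baseline
#' @return Tibble `patient_id`, `start`, `end` (half-open dates),
#'   `nyha_class`, `provenance`; segments tile each follow-up exactly but
#'   adjacent equal classes are not yet merged.
#' @export
classify_daily <- function(ehr, cohort, codelists = default_codelists(),
                           drug_map = default_drug_map(),
                           ruleset = nyha_ruleset()) {
  inp <- nyha_inputs(ehr, cohort, codelists, drug_map, ruleset)
  coh <- inp$cohort
  res <- vector("list", nrow(coh))
  for (i in seq_len(nrow(coh))) {
    index <- coh$index_date[i]
    L <- as.integer(coh$followup_end[i] - index)
    d <- daily_one(index, L, inp$rx[[i]], inp$sym[[i]], inp$hf[[i]],
                   inp$rec[[i]], ruleset)
    cls <- d$raw
    prov <- rep("proxy", length(cls))
    b <- baseline_one(index, inp$rx[[i]], inp$sym[[i]], inp$hf[[i]],
                      inp$rec[[i]], ruleset)
    o <- apply_override(cls, prov, d$raw, d$seg_s, 0L, b$class,
                        if (b$provenance == "recorded") "recorded" else "proxy")
    cls <- o$cls; prov <- o$prov
    if (length(d$rec_day)) {
      for (r in order(d$rec_day)) {
        o <- apply_override(cls, prov, d$raw, d$seg_s, d$rec_day[r],
                            d$rec_class[r], "recorded")
        cls <- o$cls; prov <- o$prov
      }
    }
    res[[i]] <- qdf(
      patient_id = rep(coh$patient_id[i], length(cls)),
      start = as.numeric(index) + d$seg_s,
      end = as.numeric(index) + d$seg_e,
      nyha_class = cls, provenance = prov
    )
  }
  out <- as_tibble(bind_rows(res))
  if (nrow(out) == 0) {
    return(tibble(patient_id = character(), start = as.Date(character()),
                  end = as.Date(character()), nyha_class = integer(),
                  provenance = character()))
  }
  out$start <- as.Date(out$start, origin = "1970-01-01")
  out$end <- as.Date(out$end, origin = "1970-01-01")
  out
}

#' Intervention dates eligible to release the ratchet
#'
#' Dates of intervention concept codes plus, when the ruleset allows,
#' the start of every HCM-relevant product exposure (therapy initiation or
#' augmentation).
#'
#' @inheritParams classify_baseline
#' @return Tibble `patient_id`, `date`.
#' @export
nyha_interventions <- function(ehr, cohort, codelists = default_codelists(),
                               drug_map = default_drug_map(),
                               ruleset = nyha_ruleset()) {
  coded <- join_codelists(ehr$clinical_events, codelists)
  iv <- coded |>
    filter(.data$concept %in% ruleset$intervention_concepts) |>
    select("patient_id", "date")
  if (ruleset$therapy_initiation_releases) {
    rx <- ehr$prescriptions |>
      select("patient_id", "date", "product", "days_supply") |>
      filter(.data$days_supply > 0) |>
      inner_join(drug_map, by = "product") |>
      filter(.data$is_hcm_specific | .data$is_loop_diuretic)
    if (nrow(rx)) {
      starts <- rx |>
        group_by(.data$patient_id, .data$product) |>
        arrange(.data$date, .by_group = TRUE) |>
        summarise(date = list({
          s <- as.numeric(.data$date)
          e <- s + .data$days_supply + ruleset$supply_grace_days
          as.Date(merge_intervals(s, e)$start, origin = "1970-01-01")
        }), .groups = "drop") |>
        unnest("date") |>
        select("patient_id", "date")
      iv <- bind_rows(iv, starts)
    }
  }
  arrange(distinct(iv), .data$patient_id, .data$date)
}

#' Apply the asymptomatic-correction ratchet
#'
#' Walks each patient's segment series forward in time: a proxy transition
#' from class II+ down to class I is blocked (the previous class is held)
#' unless an intervention occurred since the patient last entered the
#' symptomatic spell. Recorded-provenance segments are taken as
#' authoritative and are never altered.
#'
#' @param series Segment tibble from [classify_daily()].
#' @param interventions Tibble `patient_id`, `date` from
#'   [nyha_interventions()] (or any intervention dates).
#' @return `series` with the corrected `nyha_class`.
#' @export
apply_ratchet <- function(series, interventions = NULL) {
  if (nrow(series) == 0) return(series)
  ids <- unique(series$patient_id)
  iv_split <- if (is.null(interventions)) {
    setNames(rep(list(numeric(0)), length(ids)), ids)
  } else {
    f <- factor(interventions$patient_id, levels = ids)
    keep <- !is.na(f)
    split(as.numeric(interventions$date)[keep], f[keep])
  }
  out <- series |> arrange(.data$patient_id, .data$start)
  cls <- out$nyha_class
  prov <- out$provenance
  starts <- as.numeric(out$start)
  grp <- match(out$patient_id, ids)
  new_cls <- cls
  pos <- 1L
  n <- length(cls)
  while (pos <= n) {
    g <- grp[pos]
    end_pos <- pos
    while (end_pos < n && grp[end_pos + 1L] == g) end_pos <- end_pos + 1L
    iv <- iv_split[[ids[g]]] %||% numeric(0)
    prev <- NA_integer_
    spell_start <- NA_real_
    for (j in pos:end_pos) {
      cj <- cls[j]
      if (prov[j] != "recorded" && cj == 1L && !is.na(prev) && prev >= 2L) {
        released <- any(iv >= spell_start & iv <= starts[j])
        if (!released) cj <- prev
      }
      new_cls[j] <- cj
      if ((is.na(prev) || prev == 1L) && cj >= 2L) spell_start <- starts[j]
      prev <- cj
    }
    pos <- end_pos + 1L
  }
  out$nyha_class <- new_cls
  out
}

#' Compress a segment series to maximal NYHA intervals
#'
#' Merges adjacent segments with equal class and provenance and validates
#' that each patient's intervals tile follow-up without gaps or overlaps.
#'
#' @param series Segment tibble (`patient_id`, `start`, `end`,
#'   `nyha_class`, `provenance`).
#' @return Tibble of maximal half-open intervals.
#' @export
compress_to_intervals <- function(series) {
  if (nrow(series) == 0) return(series)
  s <- series |> arrange(.data$patient_id, .data$start)
  by_pat <- s |> group_by(.data$patient_id)
  gaps <- by_pat |>
    summarise(bad = any(.data$start[-1] != .data$end[-n()]), .groups = "drop")
  if (any(gaps$bad)) abort("gap or overlap in NYHA segment series")
  s |>
    group_by(.data$patient_id) |>
    mutate(run = cumsum(c(TRUE, .data$nyha_class[-1] != .data$nyha_class[-n()] |
                            .data$provenance[-1] != .data$provenance[-n()]))) |>
    group_by(.data$patient_id, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              nyha_class = .data$nyha_class[1],
              provenance = .data$provenance[1], .groups = "drop") |>
    select(-"run") |>
    arrange(.data$patient_id, .data$start)
}

#' Person-time by NYHA class
#'
#' @param intervals NYHA interval tibble (from [classify_nyha()] or
#'   [compress_to_intervals()]).
#' @param by `"class"` for per-class totals, `"patient_class"` for
#'   per-patient per-class person-time.
#' @return Tibble with `nyha_class`, `days`, `years` (and `patient_id` when
#'   `by = "patient_class"`); class totals sum to total follow-up exactly
#'   (day resolution).
#' @export
person_time_by_class <- function(intervals, by = c("class", "patient_class")) {
  by <- match.arg(by)
  keys <- if (by == "class") "nyha_class" else c("patient_id", "nyha_class")
  intervals |>
    mutate(d = as.integer(.data$end - .data$start)) |>
    group_by(across(all_of(keys))) |>
    summarise(days = sum(.data$d), .groups = "drop") |>
    mutate(years = days_to_years(.data$days))
}

#' Time-varying proxy NYHA trajectory
#'
#' End-to-end classifier: raw daily series (baseline class at day 0,
#' medication/symptom/heart-failure rules, recorded-code overrides), the
#' asymptomatic-correction ratchet, then compression to maximal intervals
#' that tile each included patient's follow-up.
#'
#' @inheritParams classify_baseline
#' @return NYHA interval tibble: `patient_id`, `start`, `end` (half-open),
#'   `nyha_class`, `provenance` ("proxy" or "recorded").
#' @export
classify_nyha <- function(ehr, cohort, codelists = default_codelists(),
                          drug_map = default_drug_map(),
                          ruleset = nyha_ruleset()) {
  series <- classify_daily(ehr, cohort, codelists, drug_map, ruleset)
  if (ruleset$ratchet) {
    iv <- nyha_interventions(ehr, cohort, codelists, drug_map, ruleset)
    series <- apply_ratchet(series, iv)
  }
  compress_to_intervals(series)
}

#' Agreement between a trajectory and the latent truth
#'
#' Fraction of follow-up person-days on which the classified NYHA class
#' equals the generator's latent class.
#'
#' @param trajectory NYHA interval tibble from [classify_nyha()].
#' @param truth_paths Latent-path tibble (`ehr$truth$paths`).
#' @return A single proportion in `[0, 1]`.
#' @export
trajectory_agreement <- function(trajectory, truth_paths) {
  ids <- unique(trajectory$patient_id)
  tr <- split_by_patient(trajectory, ids)
  th <- split_by_patient(truth_paths, ids)
  total <- 0
  matched <- 0
  for (i in seq_along(ids)) {
    a <- tr[[i]]
    b <- th[[i]]
    if (nrow(a) == 0 || nrow(b) == 0) next
    lo <- as.numeric(min(a$start))
    hi <- as.numeric(max(a$end))
    bp <- sort(unique(pmin(pmax(c(as.numeric(a$start), as.numeric(a$end),
                                  as.numeric(b$start), as.numeric(b$end)), lo), hi)))
    s <- bp[-length(bp)]
    e <- bp[-1L]
    ca <- a$nyha_class[findInterval(s, as.numeric(a$start))]
    ib <- findInterval(s, as.numeric(b$start))
    cb <- ifelse(ib >= 1L & s < as.numeric(b$end)[pmax(ib, 1L)],
                 b$nyha_class[pmax(ib, 1L)], NA_integer_)
    w <- e - s
    total <- total + sum(w[!is.na(cb)])
    matched <- matched + sum(w[!is.na(cb) & ca == cb])
  }
  if (total == 0) return(NA_real_)
  matched / total
}
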