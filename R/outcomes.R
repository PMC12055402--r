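# Clinical events: first-occurrence / repeatable identification, person-time
# splitting by time-varying NYHA class, incidence estimation, Kaplan-Meier.

#' Identify clinical events under the event ruleset
#'
#' `first_only` events keep at most the earliest in-study code per patient
#' (the patient is excluded entirely when `incident_only` and a pre-index
#' record exists). `repeatable` events are a greedy forward scan: a code is
#' kept iff it falls at least `dedup_days` after the last *kept* code.
#' The special concept `"death"` reads the deaths table.
#'
#' @param clinical_events Coded-event table.
#' @param cohort Cohort tibble (`patient_id`, `index_date`, `followup_end`);
#'   only included patients' events are returned.
#' @param codelists Codelist table.
#' @param ruleset Event ruleset, see [default_event_ruleset()].
#' @param deaths Optional deaths table for mortality events.
#' @return Tibble `patient_id`, `event`, `date`.
#' @export
identify_events <- function(clinical_events, cohort,
                            codelists = default_codelists(),
                            ruleset = default_event_ruleset(),
                            deaths = NULL) {
  check_that(all(ruleset$mode %in% c("first_only", "repeatable")),
             "unknown event mode in ruleset")
  check_that(all(is.na(ruleset$dedup_days) | ruleset$dedup_days >= 0),
             "dedup_days must be non-negative")
  coh <- cohort
  if ("included" %in% names(coh)) coh <- filter(coh, .data$included)
  coh <- select(coh, "patient_id", "index_date", "followup_end")
  coded <- join_codelists(clinical_events, codelists) |>
    select("patient_id", "date", "concept") |>
    inner_join(coh, by = "patient_id")
  out <- vector("list", nrow(ruleset))
  for (i in seq_len(nrow(ruleset))) {
    evn <- ruleset$event[i]
    concepts <- ruleset$concepts[[i]]
    if (identical(concepts, "death")) {
      hits <- if (is.null(deaths) || nrow(deaths) == 0) {
        tibble(patient_id = character(), date = as.Date(character()),
               index_date = as.Date(character()), followup_end = as.Date(character()))
      } else {
        deaths |> select("patient_id", "date") |> inner_join(coh, by = "patient_id")
      }
    } else {
      hits <- coded |> filter(.data$concept %in% concepts)
    }
    in_study <- hits |>
      filter(.data$date >= .data$index_date, .data$date < .data$followup_end)
    if (ruleset$mode[i] == "first_only") {
      kept <- in_study |>
        group_by(.data$patient_id) |>
        slice_min(.data$date, n = 1, with_ties = FALSE) |>
        ungroup()
      if (isTRUE(ruleset$incident_only[i])) {
        prevalent <- hits |>
          filter(.data$date < .data$index_date) |>
          distinct(.data$patient_id)
        kept <- anti_join(kept, prevalent, by = "patient_id")
      }
    } else {
      dd <- ruleset$dedup_days[i]
      kept <- in_study |>
        group_by(.data$patient_id) |>
        arrange(.data$date, .by_group = TRUE) |>
        filter(greedy_keep(as.numeric(.data$date), dd)) |>
        ungroup()
    }
    out[[i]] <- kept |> mutate(event = evn) |> select("patient_id", "event", "date")
  }
  bind_rows(out) |> arrange(.data$event, .data$patient_id, .data$date)
}

# greedy dedup: keep a code iff >= dd days after the last kept code
greedy_keep <- function(days, dd) {
  n <- length(days)
  keep <- logical(n)
  last <- -Inf
  for (j in seq_len(n)) {
    if (days[j] - last >= dd || is.infinite(last)) {
      keep[j] <- TRUE
      last <- days[j]
    }
  }
  keep
}

#' Attribute events to time-varying NYHA strata
#'
#' Each event is attributed to the NYHA interval whose half-open range
#' contains its date; events outside any interval (outside follow-up) are
#' dropped with a warning.
#'
#' @param events Event tibble from [identify_events()].
#' @param nyha_intervals NYHA interval tibble from [classify_nyha()].
#' @return `events` with an added `nyha_class` column.
#' @export
split_person_time <- function(events, nyha_intervals) {
  if (nrow(events) == 0) {
    return(mutate(events, nyha_class = integer(0)))
  }
  joined <- events |>
    left_join(nyha_intervals, by = "patient_id", relationship = "many-to-many") |>
    filter(.data$date >= .data$start, .data$date < .data$end) |>
    select(all_of(names(events)), "nyha_class")
  n_drop <- nrow(events) - nrow(joined)
  if (n_drop > 0) {
    warn(sprintf("%d event(s) outside follow-up dropped", n_drop))
  }
  joined
}

#' Estimate incidence per 100 patient-years by stratum
#'
#' Point rate = 100 x events / person-years per (event, NYHA class)
#' stratum. Confidence intervals by `"poisson_exact"` (Garwood chi-square
#' closed form, the default) or `"nb_robust"` (negative-binomial rate with
#' patient-clustered robust variance; requires per-patient data via
#' `patient_time`).
#'
#' @param class_events Output of [split_person_time()].
#' @param person_time Per-class person-time from [person_time_by_class()]
#'   (or, for `nb_robust`, with `by = "patient_class"`).
#' @param method CI method.
#' @param level Confidence level.
#' @return Tibble of class `hcm_incidence`: `event`, `nyha_class`, `events`,
#'   `person_years`, `rate`, `ci_low`, `ci_high`, `method`. Strata with
#'   zero person-time are omitted with a warning.
#' @export
estimate_incidence <- function(class_events, person_time,
                               method = c("poisson_exact", "nb_robust"),
                               level = 0.95) {
  method <- match.arg(method)
  per_patient <- "patient_id" %in% names(person_time)
  pt <- person_time |>
    group_by(.data$nyha_class) |>
    summarise(person_years = sum(.data$years), .groups = "drop")
  zero <- filter(pt, .data$person_years <= 0)
  if (nrow(zero)) {
    warn(sprintf("stratum with zero person-time omitted: class %s",
                 paste(zero$nyha_class, collapse = ", ")))
    pt <- filter(pt, .data$person_years > 0)
  }
  counts <- class_events |>
    count(.data$event, .data$nyha_class, name = "events")
  grid <- tidyr::expand_grid(event = unique(class_events$event),
                             nyha_class = pt$nyha_class) |>
    left_join(counts, by = c("event", "nyha_class")) |>
    mutate(events = ifelse(is.na(.data$events), 0L, .data$events)) |>
    inner_join(pt, by = "nyha_class")
  alpha <- 1 - level
  if (method == "poisson_exact") {
    res <- grid |>
      mutate(
        rate = 100 * .data$events / .data$person_years,
        ci_low = ifelse(.data$events == 0, 0,
                        100 * qchisq(alpha / 2, 2 * .data$events) /
                          (2 * .data$person_years)),
        ci_high = 100 * qchisq(1 - alpha / 2, 2 * .data$events + 2) /
          (2 * .data$person_years),
        method = "poisson_exact"
      )
  } else {
    check_that(per_patient,
               "nb_robust needs person_time with by = \"patient_class\"")
    rlang::check_installed(c("MASS", "sandwich"))
    res <- nb_robust_rates(class_events, person_time, alpha)
  }
  structure(arrange(res, .data$event, .data$nyha_class),
            class = c("hcm_incidence", class(tibble())))
}

# negative-binomial rates with patient-clustered robust (sandwich) variance
nb_robust_rates <- function(class_events, patient_time, alpha) {
  counts <- class_events |> count(.data$patient_id, .data$event, .data$nyha_class,
                                  name = "n_ev")
  out <- list()
  for (evn in unique(class_events$event)) {
    dat <- patient_time |>
      filter(.data$years > 0) |>
      left_join(filter(counts, .data$event == evn),
                by = c("patient_id", "nyha_class")) |>
      mutate(n_ev = ifelse(is.na(.data$n_ev), 0L, .data$n_ev),
             cls = factor(.data$nyha_class))
    fit <- suppressWarnings(MASS::glm.nb(
      n_ev ~ cls - 1 + offset(log(years)), data = dat))
    V <- sandwich::vcovCL(fit, cluster = dat$patient_id)
    co <- unname(stats::coef(fit))
    se <- unname(sqrt(diag(V)))
    z <- stats::qnorm(1 - alpha / 2)
    lev <- as.integer(levels(dat$cls))
    py <- dat |> group_by(.data$nyha_class) |>
      summarise(person_years = sum(.data$years), .groups = "drop")
    nev <- dat |> group_by(.data$nyha_class) |>
      summarise(events = sum(.data$n_ev), .groups = "drop")
    out[[evn]] <- tibble(
      event = evn, nyha_class = lev,
      rate = 100 * exp(co), ci_low = 100 * exp(co - z * se),
      ci_high = 100 * exp(co + z * se), method = "nb_robust") |>
      left_join(nev, by = "nyha_class") |>
      left_join(py, by = "nyha_class") |>
      select("event", "nyha_class", "events", "person_years", "rate",
             "ci_low", "ci_high", "method")
  }
  bind_rows(out)
}

#' Kaplan-Meier time to first event
#'
#' Product-limit survival estimator with right censoring.
#'
#' @param event_times Times from index to first event.
#' @param censor_times Censoring times for subjects without the event.
#' @return Object of class `hcm_km` wrapping the [survival::survfit] fit;
#'   see [tidy.hcm_km()] and [autoplot.hcm_km()].
#' @export
km_time_to_first <- function(event_times, censor_times = numeric(0)) {
  check_that(all(c(event_times, censor_times) >= 0), "times must be non-negative")
  times <- c(event_times, censor_times)
  status <- c(rep(1L, length(event_times)), rep(0L, length(censor_times)))
  fit <- survival::survfit(survival::Surv(times, status) ~ 1)
  structure(list(fit = fit, n = length(times), events = sum(status)),
            class = "hcm_km")
}

#' @export
print.hcm_km <- function(x, ...) {
  cat("<hcm_km> Kaplan-Meier fit:", x$n, "subjects,", x$events, "events\n")
  invisible(x)
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x An `hcm_km` object.
#' @param ... Unused.
#' @return Tibble `time`, `n_risk`, `n_event`, `n_censor`, `estimate`
#'   (survival), `risk` (1 - survival).
#' @method tidy hcm_km
#' @export
tidy.hcm_km <- function(x, ...) {
  f <- x$fit
  tibble(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
         n_censor = f$n.censor, estimate = f$surv, risk = 1 - f$surv)
}

#' Glance at a Kaplan-Meier fit
#'
#' @param x An `hcm_km` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `events`, `median_time` (NA when survival
#'   never crosses 0.5).
#' @method glance hcm_km
#' @export
glance.hcm_km <- function(x, ...) {
  st <- tidy(x)
  med <- st$time[st$estimate <= 0.5][1]
  tibble(n = x$n, events = x$events, median_time = med)
}
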