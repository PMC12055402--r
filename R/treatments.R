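# Treatment exposure reconstruction and change taxonomy.
#
# Prescriptions with non-zero days' supply become per-product exposure
# intervals (merged across within-grace gaps); concurrent product sets
# become regimen intervals; the first departure from the initial regimen is
# classified with a mutually exclusive, exhaustive taxonomy.

#' Build per-product exposure intervals
#'
#' Each prescription spans `[date, date + days_supply)`. Overlapping or
#' within-grace successive spans of the same product merge into one
#' interval. Rows with zero or missing days' supply are dropped; rows with
#' negative supply are rejected with a warning.
#'
#' @param prescriptions Prescription table (`patient_id`, `date`, `product`,
#'   `days_supply`).
#' @param drug_map Product-to-class map; only `is_hcm_specific` products are
#'   kept when `hcm_specific_only` is `TRUE`.
#' @param grace_days Maximum gap (days) bridged when merging successive
#'   supplies of the same product.
#' @param hcm_specific_only Restrict to HCM-specific therapy classes.
#' @return Tibble `patient_id`, `product`, `therapy_class`, `start`, `end`
#'   (half-open dates), ordered within patient.
#' @export
build_exposure_intervals <- function(prescriptions, drug_map = default_drug_map(),
                                     grace_days = 30L, hcm_specific_only = TRUE) {
  rx <- prescriptions |>
    select("patient_id", "date", "product", "days_supply") |>
    inner_join(select(drug_map, "product", "therapy_class", "is_hcm_specific"),
               by = "product")
  if (hcm_specific_only) rx <- filter(rx, .data$is_hcm_specific)
  if (any(rx$days_supply < 0, na.rm = TRUE)) {
    warn(sprintf("%d prescription row(s) with negative days' supply rejected",
                 sum(rx$days_supply < 0, na.rm = TRUE)))
  }
  rx <- filter(rx, !is.na(.data$days_supply), .data$days_supply > 0)
  if (nrow(rx) == 0) {
    return(tibble(patient_id = character(), product = character(),
                  therapy_class = character(), start = as.Date(character()),
                  end = as.Date(character())))
  }
  rx |>
    group_by(.data$patient_id, .data$product, .data$therapy_class) |>
    reframe({
      m <- merge_intervals(as.numeric(.data$date),
                           as.numeric(.data$date) + .data$days_supply,
                           join_gap = grace_days)
      tibble(start = as.Date(m$start, origin = "1970-01-01"),
             end = as.Date(m$end, origin = "1970-01-01"))
    }) |>
    arrange(.data$patient_id, .data$start, .data$product) |>
    select("patient_id", "product", "therapy_class", "start", "end")
}

# canonical label for a class multiset, e.g. c("BB","BB") -> "BB + BB dual therapy"
regimen_label <- function(classes) {
  k <- length(classes)
  if (k == 0L) return("none")
  parts <- paste(sort(classes), collapse = " + ")
  kind <- if (k == 1L) "monotherapy" else if (k == 2L) "dual therapy"
  else if (k == 3L) "triple therapy" else sprintf("combination therapy (%d agents)", k)
  if (k == 1L) paste(parts, kind) else paste(parts, kind)
}

#' Derive regimen intervals from exposure intervals
#'
#' Partitions each patient's timeline at every product start/end and labels
#' each segment with the set of concurrently active products and the
#' corresponding therapy-class multiset. Segments with no active product
#' are omitted (gaps are detected by [detect_first_change()]).
#'
#' @param exposure Output of [build_exposure_intervals()].
#' @return Tibble `patient_id`, `start`, `end`, `products` (sorted,
#'   "+"-separated), `classes` (sorted class multiset, "+"-separated),
#'   `label`.
#' @export
derive_regimens <- function(exposure) {
  empty <- tibble(patient_id = character(), start = as.Date(character()),
                  end = as.Date(character()), products = character(),
                  classes = character(), label = character())
  if (nrow(exposure) == 0) return(empty)
  out <- exposure |>
    group_by(.data$patient_id) |>
    reframe({
      s <- as.numeric(.data$start)
      e <- as.numeric(.data$end)
      bp <- sort(unique(c(s, e)))
      seg_s <- bp[-length(bp)]
      seg_e <- bp[-1L]
      prods <- character(length(seg_s))
      cls <- character(length(seg_s))
      keep <- logical(length(seg_s))
      for (j in seq_along(seg_s)) {
        on <- s <= seg_s[j] & e > seg_s[j]
        keep[j] <- any(on)
        if (keep[j]) {
          prods[j] <- paste(sort(.data$product[on]), collapse = "+")
          cls[j] <- paste(sort(.data$therapy_class[on]), collapse = "+")
        }
      }
      tibble(start = as.Date(seg_s[keep], origin = "1970-01-01"),
             end = as.Date(seg_e[keep], origin = "1970-01-01"),
             products = prods[keep], classes = cls[keep])
    })
  # merge adjacent segments with identical product sets
  out |>
    group_by(.data$patient_id) |>
    mutate(run = cumsum(c(TRUE, .data$products[-1] != .data$products[-n()] |
                            .data$start[-1] != .data$end[-n()]))) |>
    group_by(.data$patient_id, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              products = .data$products[1], classes = .data$classes[1],
              .groups = "drop") |>
    select(-"run") |>
    mutate(label = vapply(strsplit(.data$classes, "+", fixed = TRUE),
                          regimen_label, "")) |>
    arrange(.data$patient_id, .data$start)
}

#' Initial treatment label
#'
#' The label of each patient's first regimen on or after the index date
#' ("initial treatment" = first prescription record after the first HCM
#' diagnosis); patients with no HCM-specific regimen get `"none"`.
#'
#' @param regimens Output of [derive_regimens()].
#' @param cohort Cohort tibble (supplies `index_date` per patient); rows
#'   are returned for every patient in it.
#' @return Tibble `patient_id`, `initial_label`, `initial_classes`,
#'   `initial_start`.
#' @export
initial_treatment <- function(regimens, cohort) {
  first_reg <- regimens |>
    inner_join(select(cohort, "patient_id", "index_date"), by = "patient_id") |>
    filter(.data$start >= .data$index_date) |>
    group_by(.data$patient_id) |>
    slice_min(.data$start, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("patient_id", initial_label = "label", initial_classes = "classes",
           initial_start = "start")
  cohort |>
    select("patient_id") |>
    left_join(first_reg, by = "patient_id") |>
    mutate(initial_label = ifelse(is.na(.data$initial_label), "none",
                                  .data$initial_label))
}

# classify a from -> to regimen transition; product/class vectors
classify_transition <- function(from_products, to_products,
                                from_classes, to_classes) {
  if (setequal(from_products, to_products) &&
      length(from_products) == length(to_products)) {
    abort("classify_transition called with identical regimens")
  }
  subset_of <- function(a, b) {
    # multiset containment
    ta <- table(a)
    tb <- table(b)
    all(names(ta) %in% names(tb)) && all(ta <= tb[names(ta)])
  }
  if (subset_of(from_products, to_products)) return("augment")
  if (subset_of(to_products, from_products)) return("discontinuation")
  if (identical(sort(from_classes), sort(to_classes))) return("switch_within_class")
  if (length(to_products) > length(from_products)) return("switch_with_addition")
  "switch_between_class"
}

#' Detect each patient's first treatment change
#'
#' Scans forward from the initial regimen. The earliest of (a) an exposure
#' gap of at least `gap_days` with no HCM-specific supply (category
#' `no_treatment_gap`, dated at the end of the last exposure) and (b) a
#' regimen-composition change (classified as `augment`, `discontinuation`,
#' `switch_within_class`, `switch_between_class` or `switch_with_addition`)
#' is returned. A trailing gap before follow-up end also counts.
#'
#' @param regimens Output of [derive_regimens()].
#' @param cohort Cohort tibble with `index_date` and `followup_end`.
#' @param gap_days Gap defining "no treatment" (default 90).
#' @return Tibble `patient_id`, `date`, `category`, `from_regimen`,
#'   `to_regimen`; one row per patient with a detected change.
#' @export
detect_first_change <- function(regimens, cohort, gap_days = 90L) {
  reg <- regimens |>
    inner_join(select(cohort, "patient_id", "index_date", "followup_end"),
               by = "patient_id") |>
    filter(.data$start >= .data$index_date, .data$start < .data$followup_end) |>
    arrange(.data$patient_id, .data$start)
  if (nrow(reg) == 0) {
    return(tibble(patient_id = character(), date = as.Date(character()),
                  category = character(), from_regimen = character(),
                  to_regimen = character()))
  }
  reg |>
    group_by(.data$patient_id) |>
    reframe({
      st <- .data$start
      en <- .data$end
      pr <- .data$products
      cl <- .data$classes
      n <- length(st)
      fu_end <- .data$followup_end[1]
      res <- NULL
      if (n > 1) {
        for (j in 2:n) {
          gap <- as.integer(st[j] - en[j - 1])
          if (gap >= gap_days) {
            res <- tibble(date = en[j - 1], category = "no_treatment_gap",
                          from_regimen = pr[j - 1], to_regimen = "")
            break
          }
          if (pr[j] != pr[j - 1]) {
            cat_j <- classify_transition(
              strsplit(pr[j - 1], "+", fixed = TRUE)[[1]],
              strsplit(pr[j], "+", fixed = TRUE)[[1]],
              strsplit(cl[j - 1], "+", fixed = TRUE)[[1]],
              strsplit(cl[j], "+", fixed = TRUE)[[1]])
            res <- tibble(date = st[j], category = cat_j,
                          from_regimen = pr[j - 1], to_regimen = pr[j])
            break
          }
        }
      }
      if (is.null(res)) {
        if (as.integer(fu_end - en[n]) >= gap_days) {
          res <- tibble(date = en[n], category = "no_treatment_gap",
                        from_regimen = pr[n], to_regimen = "")
        } else {
          res <- tibble(date = as.Date(character()), category = character(),
                        from_regimen = character(), to_regimen = character())
        }
      }
      res
    })
}

#' Summarize first treatment changes
#'
#' Counts and percentages (one decimal place, half-up) per change category
#' over a stated denominator, plus an `any_change` row.
#'
#' @param changes Output of [detect_first_change()] (or any tibble with a
#'   `category` column).
#' @param denominator Number of patients at risk of a change (e.g. patients
#'   with any HCM-specific treatment).
#' @return Tibble `category`, `n`, `pct`.
#' @export
change_summary <- function(changes, denominator) {
  check_that(denominator > 0, "denominator must be positive")
  cats <- c("no_treatment_gap", "augment", "discontinuation",
            "switch_between_class", "switch_within_class", "switch_with_addition")
  counts <- unname(vapply(cats, function(cc) sum(changes$category == cc), 0L))
  bind_rows(
    tibble(category = cats, n = as.integer(counts),
           pct = pct_of(counts, denominator, 1)),
    tibble(category = "any_change", n = sum(counts),
           pct = pct_of(sum(counts), denominator, 1))
  )
}

#' Cumulative-risk curve of an event
#'
#' One minus the Kaplan-Meier product-limit survival estimate under right
#' censoring, as used for time-to-first-treatment-change plots.
#'
#' @param event_times Times (from index) at which the event occurred.
#' @param censor_times Censoring times for subjects without the event.
#' @return Tibble `time`, `n_risk`, `n_event`, `risk` (right-continuous
#'   step function; `risk` is non-decreasing in `[0, 1]`).
#' @export
cumulative_risk_curve <- function(event_times, censor_times = numeric(0)) {
  check_that(all(c(event_times, censor_times) >= 0), "times must be non-negative")
  times <- c(event_times, censor_times)
  status <- c(rep(1L, length(event_times)), rep(0L, length(censor_times)))
  if (length(times) == 0 || sum(status) == 0) {
    return(tibble(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                  risk = numeric(0)))
  }
  fit <- survival::survfit(survival::Surv(times, status) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         risk = 1 - fit$surv)
}
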