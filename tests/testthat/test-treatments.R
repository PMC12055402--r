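# Treatment pathways: exposure construction, regimen derivation, change
# taxonomy, cumulative risk.

D0 <- as.Date("2015-01-01")

rx_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, "", 1),
    date = D0 + as.integer(vapply(rows, `[[`, "", 2)),
    product = vapply(rows, `[[`, "", 3),
    days_supply = as.integer(vapply(rows, `[[`, "", 4)))
}

test_that("exposure intervals span supply and merge within grace", {
  x <- build_exposure_intervals(
    rx_tbl(c("A", "10", "bisoprolol", "28")), DM, grace_days = 30)
  expect_equal(as.integer(x$start - D0), 10L)
  expect_equal(as.integer(x$end - D0), 38L)

  # spans ending day 38 and starting day 50 (gap 12 <= 30) merge
  x2 <- build_exposure_intervals(
    rx_tbl(c("A", "10", "bisoprolol", "28"), c("A", "50", "bisoprolol", "28")),
    DM, grace_days = 30)
  expect_equal(nrow(x2), 1L)
  expect_equal(as.integer(c(x2$start, x2$end) - D0), c(10L, 78L))

  # gap beyond grace stays split
  x3 <- build_exposure_intervals(
    rx_tbl(c("A", "10", "bisoprolol", "28"), c("A", "80", "bisoprolol", "28")),
    DM, grace_days = 30)
  expect_equal(nrow(x3), 2L)
})

test_that("zero days' supply is dropped and negative supply warns", {
  expect_equal(nrow(build_exposure_intervals(
    rx_tbl(c("A", "10", "bisoprolol", "0")), DM)), 0L)
  expect_warning(
    x <- build_exposure_intervals(
      rx_tbl(c("A", "10", "bisoprolol", "-5"), c("A", "10", "atenolol", "28")),
      DM),
    "negative")
  expect_equal(x$product, "atenolol")
})

test_that("merging is idempotent and order-independent", {
  set.seed(4)
  rows <- do.call(rx_tbl, lapply(1:12, function(i) {
    c("A", as.character(sample(0:200, 1)),
      sample(c("bisoprolol", "verapamil"), 1), as.character(sample(7:56, 1)))
  }))
  a <- build_exposure_intervals(rows, DM)
  b <- build_exposure_intervals(rows[sample(nrow(rows)), ], DM)
  expect_equal(a, b)
  # re-feeding the merged intervals as single prescriptions is a fixpoint
  refed <- tibble::tibble(patient_id = a$patient_id, date = a$start,
                          product = a$product,
                          days_supply = as.integer(a$end - a$start))
  expect_equal(build_exposure_intervals(refed, DM), a)
})

test_that("regimen labels follow the therapy-class multiset", {
  x <- build_exposure_intervals(rx_tbl(c("A", "0", "bisoprolol", "28")), DM)
  expect_equal(derive_regimens(x)$label, "BB monotherapy")

  x2 <- build_exposure_intervals(
    rx_tbl(c("A", "0", "atenolol", "28"), c("A", "0", "bisoprolol", "28")), DM)
  expect_equal(derive_regimens(x2)$label, "BB + BB dual therapy")

  x3 <- build_exposure_intervals(
    rx_tbl(c("A", "0", "bisoprolol", "28"), c("A", "0", "verapamil", "28"),
           c("A", "0", "disopyramide", "28")), DM)
  expect_equal(derive_regimens(x3)$label,
               "BB + CCB + disopyramide triple therapy")

  # non-HCM-specific products produce no regimen
  x4 <- build_exposure_intervals(rx_tbl(c("A", "0", "atorvastatin", "28")), DM)
  expect_equal(nrow(derive_regimens(x4)), 0L)
})

test_that("regimens partition the timeline at product boundaries", {
  x <- build_exposure_intervals(
    rx_tbl(c("A", "0", "bisoprolol", "100"), c("A", "30", "verapamil", "40")),
    DM)
  r <- derive_regimens(x)
  expect_equal(r$label, c("BB monotherapy", "BB + CCB dual therapy",
                          "BB monotherapy"))
  expect_equal(as.integer(r$start - D0), c(0L, 30L, 70L))
  expect_equal(as.integer(r$end - D0), c(30L, 70L, 100L))
})

test_that("initial treatment is the first on/after-index regimen", {
  coh <- mini_cohort("A", D0, D0 + 400)
  x <- build_exposure_intervals(
    rx_tbl(c("A", "20", "verapamil", "28")), DM)
  it <- initial_treatment(derive_regimens(x), coh)
  expect_equal(it$initial_label, "CCB monotherapy")

  x2 <- build_exposure_intervals(
    rx_tbl(c("A", "20", "bisoprolol", "28"), c("A", "20", "disopyramide", "28")),
    DM)
  expect_equal(initial_treatment(derive_regimens(x2), coh)$initial_label,
               "BB + disopyramide dual therapy")

  empty <- build_exposure_intervals(rx_tbl(c("A", "20", "aspirin", "28")), DM)
  expect_equal(initial_treatment(derive_regimens(empty), coh)$initial_label,
               "none")
})

test_that("first-change taxonomy classifies the worked transitions", {
  coh <- mini_cohort("A", D0, D0 + 500)
  # BB -> BB + CCB: augment
  x <- build_exposure_intervals(
    rx_tbl(c("A", "0", "bisoprolol", "100"), c("A", "40", "verapamil", "60")),
    DM)
  ch <- detect_first_change(derive_regimens(x), coh)
  expect_equal(ch$category, "augment")
  expect_equal(as.integer(ch$date - D0), 40L)

  # atenolol -> bisoprolol: switch within class
  x2 <- build_exposure_intervals(
    rx_tbl(c("A", "0", "atenolol", "40"), c("A", "40", "bisoprolol", "40")), DM)
  expect_equal(detect_first_change(derive_regimens(x2), coh)$category,
               "switch_within_class")

  # bisoprolol -> verapamil: switch between classes
  x3 <- build_exposure_intervals(
    rx_tbl(c("A", "0", "bisoprolol", "40"), c("A", "40", "verapamil", "40")), DM)
  expect_equal(detect_first_change(derive_regimens(x3), coh)$category,
               "switch_between_class")

  # BB + CCB -> BB: discontinuation
  x4 <- build_exposure_intervals(
    rx_tbl(c("A", "0", "bisoprolol", "100"), c("A", "0", "verapamil", "40")), DM)
  expect_equal(detect_first_change(derive_regimens(x4), coh)$category,
               "discontinuation")

  # bisoprolol -> atenolol + verapamil: switch with addition
  x5 <- build_exposure_intervals(
    rx_tbl(c("A", "0", "bisoprolol", "40"), c("A", "40", "atenolol", "40"),
           c("A", "40", "verapamil", "40")), DM)
  expect_equal(detect_first_change(derive_regimens(x5), coh)$category,
               "switch_with_addition")

  # >= 90-day gap: no-treatment, dated at end of last exposure
  x6 <- build_exposure_intervals(rx_tbl(c("A", "0", "bisoprolol", "40")), DM)
  ch6 <- detect_first_change(derive_regimens(x6), coh)
  expect_equal(ch6$category, "no_treatment_gap")
  expect_equal(as.integer(ch6$date - D0), 40L)

  # a short trailing gap is no change at all
  coh_short <- mini_cohort("A", D0, D0 + 100)
  expect_equal(nrow(detect_first_change(derive_regimens(x6), coh_short)), 0L)

  # composition change before the gap reaches 90 days wins
  x7 <- build_exposure_intervals(
    rx_tbl(c("A", "0", "bisoprolol", "40"), c("A", "100", "verapamil", "40")),
    DM)
  expect_equal(detect_first_change(derive_regimens(x7), coh)$category,
               "switch_between_class")
})

test_that("the taxonomy is exhaustive and mutually exclusive by enumeration", {
  prods <- c("bisoprolol", "atenolol", "verapamil", "diltiazem", "disopyramide")
  cls <- DM$therapy_class[match(prods, DM$product)]
  sets <- list()
  for (k in 1:3) {
    cmb <- utils::combn(length(prods), k)
    for (j in seq_len(ncol(cmb))) sets[[length(sets) + 1L]] <- cmb[, j]
  }
  cats <- c("augment", "discontinuation", "switch_within_class",
            "switch_between_class", "switch_with_addition")
  n_pairs <- 0L
  for (a in sets) for (b in sets) {
    if (identical(a, b)) next
    got <- classify_transition(prods[a], prods[b], cls[a], cls[b])
    expect_true(got %in% cats)
    expect_length(got, 1L)
    n_pairs <- n_pairs + 1L
  }
  expect_equal(n_pairs, length(sets)^2 - length(sets))
})

test_that("change summaries reproduce printed-table arithmetic", {
  changes <- tibble::tibble(category = rep(
    c("no_treatment_gap", "augment", "discontinuation", "switch_between_class",
      "switch_within_class", "switch_with_addition"),
    times = c(557, 296, 146, 140, 142, 5)))
  cs <- change_summary(changes, 3084)
  expect_equal(cs$pct[cs$category == "no_treatment_gap"], 18.1)
  expect_equal(cs$pct[cs$category == "augment"], 9.6)
  expect_equal(cs$n[cs$category == "any_change"], 1286L)
  expect_equal(cs$pct[cs$category == "any_change"], 41.7)

  empty <- change_summary(tibble::tibble(category = character()), 100)
  expect_true(all(empty$pct == 0))
  expect_error(change_summary(changes, 0), "positive")
})

test_that("cumulative risk matches hand and brute-force product-limit", {
  # no events -> empty flat-zero curve
  expect_equal(nrow(cumulative_risk_curve(numeric(0), c(1, 2))), 0L)

  # 4 subjects: events at 1, 1; censored at 2, 3 -> risk 0.5 at t = 1
  cr <- cumulative_risk_curve(c(1, 1), c(2, 3))
  expect_equal(cr$risk[cr$time == 1], 0.5)

  set.seed(66)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    times <- sample(1:15, n, replace = TRUE)
    status <- rbinom(n, 1, 0.6)
    if (sum(status) == 0) status[1] <- 1L
    cr <- cumulative_risk_curve(times[status == 1], times[status == 0])
    bf <- bf_km(times, status)
    got <- cr$risk[match(bf$time, cr$time)]
    expect_equal(got, 1 - bf$surv, tolerance = 1e-12)
    # monotone, bounded
    expect_true(all(diff(cr$risk) >= -1e-12))
    expect_true(all(cr$risk >= 0 & cr$risk <= 1))
  }

  # with no censoring the curve equals the empirical CDF
  tt <- c(1, 2, 2, 5)
  cr2 <- cumulative_risk_curve(tt)
  expect_equal(cr2$risk, stats::ecdf(tt)(cr2$time))

  expect_error(cumulative_risk_curve(c(-1, 2)), "non-negative")
})
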