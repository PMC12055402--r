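# Proxy NYHA classifier: baseline rules, daily series vs a literal
# day-by-day oracle, ratchet behaviour, compression and person-time.

IDX <- as.Date("2012-03-01")

nyha_fixture <- function(build, fu_days = 200L, reg_start = "2009-01-01") {
  ehr <- empty_ehr() |>
    add_patient("A", reg_start, IDX + fu_days) |>
    add_code("A", IDX, "hcm_obstructive")
  ehr <- build(ehr)
  cohort <- mini_cohort("A", IDX, IDX + fu_days)
  list(ehr = ehr, cohort = cohort)
}

test_that("a recorded NYHA code dominates the proxy at baseline", {
  fx <- nyha_fixture(function(e) {
    e |>
      add_code("A", IDX - 30, "nyha_iii") |>
      add_rx("A", IDX - 1, "bisoprolol")   # proxy would say II
  })
  b <- classify_baseline(fx$ehr, fx$cohort)
  expect_equal(b$nyha_class, 3L)
  expect_equal(b$provenance, "recorded")
})

test_that("no therapy and no symptoms is class I by proxy", {
  fx <- nyha_fixture(identity)
  b <- classify_baseline(fx$ehr, fx$cohort)
  expect_equal(b$nyha_class, 1L)
  expect_equal(b$provenance, "proxy")
})

test_that("default rule table traces: therapy and symptom branches", {
  # BB monotherapy in the window plus a single symptom concept -> II
  fx <- nyha_fixture(function(e) {
    e |> add_rx("A", IDX + 10, "bisoprolol") |>
      add_code("A", IDX - 20, "breathlessness")
  })
  expect_equal(classify_baseline(fx$ehr, fx$cohort)$nyha_class, 2L)

  # two distinct symptom concepts step the class up by one
  fx2 <- nyha_fixture(function(e) {
    e |> add_rx("A", IDX + 10, "bisoprolol") |>
      add_code("A", IDX - 20, "breathlessness") |>
      add_code("A", IDX - 40, "syncope")
  })
  expect_equal(classify_baseline(fx2$ehr, fx2$cohort)$nyha_class, 3L)

  # disopyramide, or two agents, or a loop diuretic -> III
  fx3 <- nyha_fixture(function(e) add_rx(e, "A", IDX, "disopyramide"))
  expect_equal(classify_baseline(fx3$ehr, fx3$cohort)$nyha_class, 3L)
  fx4 <- nyha_fixture(function(e) {
    e |> add_rx("A", IDX, "bisoprolol") |> add_rx("A", IDX + 5, "verapamil")
  })
  expect_equal(classify_baseline(fx4$ehr, fx4$cohort)$nyha_class, 3L)

  # heart-failure hospitalization within the look-back -> IV
  fx5 <- nyha_fixture(function(e) {
    add_code(e, "A", IDX - 30, "heart_failure", setting = "secondary")
  })
  expect_equal(classify_baseline(fx5$ehr, fx5$cohort)$nyha_class, 4L)

  # medications outside the -2..+28 window do not count at baseline
  fx6 <- nyha_fixture(function(e) add_rx(e, "A", IDX + 40, "bisoprolol"))
  expect_equal(classify_baseline(fx6$ehr, fx6$cohort)$nyha_class, 1L)
})

test_that("constant therapy with no symptoms gives a constant daily series", {
  fx <- nyha_fixture(function(e) {
    # monthly scripts keep one BB continuously active
    for (d in seq(0, 180, by = 28)) e <- add_rx(e, "A", IDX + d, "bisoprolol")
    e
  })
  tr <- classify_nyha(fx$ehr, fx$cohort)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$nyha_class, 2L)
  expect_equal(as.integer(tr$end - tr$start), 200L)
})

test_that("medication is active through supply plus grace and not after", {
  fx <- nyha_fixture(function(e) add_rx(e, "A", IDX + 40, "bisoprolol", 28L),
                     fu_days = 150L)
  raw <- classify_daily(fx$ehr, fx$cohort)
  days <- expand_days(raw, "A", IDX)
  # active days 40 .. 40+28+30-1 = 97
  expect_true(all(days[1:40] == 1L))        # days 0..39
  expect_true(all(days[41:98] == 2L))       # days 40..97
  expect_true(all(days[99:150] == 1L))      # day 98 onward (no ratchet here)
})

test_that("therapy augmentation changes the class on the day it happens", {
  fx <- nyha_fixture(function(e) {
    for (d in seq(0, 180, by = 28)) e <- add_rx(e, "A", IDX + d, "bisoprolol")
    add_rx(e, "A", IDX + 60, "verapamil", 120L)
  })
  tr <- classify_nyha(fx$ehr, fx$cohort)
  expect_equal(tr$nyha_class[1], 2L)
  expect_equal(tr$nyha_class[2], 3L)
  expect_equal(as.integer(tr$start[2] - IDX), 60L)
})

test_that("daily classifier equals a literal day-by-day replay", {
  rs <- nyha_ruleset()
  set.seed(314)
  for (rep in 1:8) {
    fu <- sample(120:400, 1)
    ehr <- empty_ehr() |>
      add_patient("A", "2009-01-01", IDX + fu) |>
      add_code("A", IDX, "hcm_obstructive")
    n_rx <- sample(0:6, 1)
    for (k in seq_len(n_rx)) {
      ehr <- add_rx(ehr, "A", IDX + sample(-40:fu, 1),
                    sample(c("bisoprolol", "atenolol", "verapamil",
                             "disopyramide", "furosemide"), 1),
                    sample(c(14L, 28L, 56L), 1))
    }
    n_sym <- sample(0:5, 1)
    for (k in seq_len(n_sym)) {
      ehr <- add_code(ehr, "A", IDX + sample(-100:fu, 1),
                      sample(c("breathlessness", "syncope", "fatigue",
                               "chest_pain"), 1))
    }
    if (runif(1) < 0.4) {
      ehr <- add_code(ehr, "A", IDX + sample(-50:fu, 1), "heart_failure",
                      setting = "secondary")
    }
    if (runif(1) < 0.4) {
      ehr <- add_code(ehr, "A", IDX + sample(0:fu, 1),
                      sample(c("nyha_i", "nyha_ii", "nyha_iii"), 1))
    }
    if (runif(1) < 0.3) {
      ehr <- add_code(ehr, "A", IDX + sample(0:fu, 1), "srt")
    }
    cohort <- mini_cohort("A", IDX, IDX + fu)

    tr <- classify_nyha(ehr, cohort)
    got <- expand_days(tr, "A", IDX)

    coded <- dplyr::inner_join(ehr$clinical_events, CL,
                               by = c("vocabulary", "code"))
    rx <- dplyr::inner_join(ehr$prescriptions[, c("patient_id", "date",
                                                  "product", "days_supply")],
                            DM, by = "product")
    rx <- rx[rx$is_hcm_specific | rx$is_loop_diuretic, ]
    rx$is_loop <- rx$is_loop_diuretic
    iv <- nyha_interventions(ehr, cohort)
    want <- ref_daily_nyha(
      IDX, fu, rx,
      coded[coded$is_symptom, c("date", "concept")],
      coded$date[coded$concept == "heart_failure" & coded$setting == "secondary"],
      coded[coded$is_nyha, c("date", "nyha_class")],
      iv$date, rs)
    expect_equal(got, want, label = sprintf("replay rep %d", rep))
  }
})

test_that("the ratchet blocks II+ to I without an intervention", {
  mk_series <- function(classes, starts, ends) {
    tibble::tibble(patient_id = "A", start = IDX + starts, end = IDX + ends,
                   nyha_class = classes, provenance = "proxy")
  }
  s <- mk_series(c(2L, 1L), c(0L, 50L), c(50L, 100L))
  out <- apply_ratchet(s, NULL)
  expect_equal(out$nyha_class, c(2L, 2L))

  # constant I is untouched
  s1 <- mk_series(1L, 0L, 100L)
  expect_equal(apply_ratchet(s1, NULL)$nyha_class, 1L)

  # an intervention during the symptomatic spell releases the ratchet
  iv <- tibble::tibble(patient_id = "A", date = IDX + 30)
  expect_equal(apply_ratchet(s, iv)$nyha_class, c(2L, 1L))

  # an intervention before the spell started does not
  s2 <- mk_series(c(1L, 2L, 1L), c(0L, 20L, 60L), c(20L, 60L, 100L))
  iv_pre <- tibble::tibble(patient_id = "A", date = IDX + 5)
  expect_equal(apply_ratchet(s2, iv_pre)$nyha_class, c(1L, 2L, 2L))
})

test_that("recorded segments are authoritative under the ratchet", {
  s <- tibble::tibble(patient_id = "A", start = IDX + c(0L, 50L),
                      end = IDX + c(50L, 100L), nyha_class = c(3L, 1L),
                      provenance = c("proxy", "recorded"))
  expect_equal(apply_ratchet(s, NULL)$nyha_class, c(3L, 1L))
})

test_that("corrected series never crosses II+ to I without intervention", {
  set.seed(77)
  for (rep in 1:20) {
    n_seg <- sample(3:10, 1)
    bounds <- sort(sample(0:300, n_seg + 1))
    s <- tibble::tibble(
      patient_id = "A", start = IDX + bounds[-(n_seg + 1)],
      end = IDX + bounds[-1], nyha_class = sample(1:4, n_seg, replace = TRUE),
      provenance = "proxy")
    iv <- tibble::tibble(patient_id = "A",
                         date = IDX + sample(0:300, sample(0:2, 1)))
    out <- apply_ratchet(s, iv)
    expect_true(all(out$nyha_class >= s$nyha_class))
    drops <- which(out$nyha_class[-1] == 1L & out$nyha_class[-n_seg] >= 2L) + 1L
    for (j in drops) {
      expect_true(any(iv$date <= out$start[j]),
                  label = "drop to I requires a prior intervention")
    }
  }
})

test_that("interval compression round-trips the daily series", {
  set.seed(55)
  for (rep in 1:10) {
    n_seg <- sample(2:12, 1)
    bounds <- sort(sample(0:400, n_seg + 1))
    s <- tibble::tibble(
      patient_id = "A", start = IDX + bounds[-(n_seg + 1)],
      end = IDX + bounds[-1],
      nyha_class = sample(1:3, n_seg, replace = TRUE), provenance = "proxy")
    cmp <- compress_to_intervals(s)
    expect_true(all(cmp$nyha_class[-1] != cmp$nyha_class[-nrow(cmp)] |
                      cmp$provenance[-1] != cmp$provenance[-nrow(cmp)]))
    expect_equal(expand_days(cmp, "A", IDX + bounds[1]),
                 expand_days(s, "A", IDX + bounds[1]))
  }
  # gaps are an internal error
  gap <- tibble::tibble(patient_id = "A", start = IDX + c(0L, 20L),
                        end = IDX + c(10L, 30L), nyha_class = c(1L, 2L),
                        provenance = "proxy")
  expect_error(compress_to_intervals(gap), "gap")
})

test_that("person-time sums are exact and conserved", {
  iv <- tibble::tibble(
    patient_id = "A", start = IDX + c(0L, 731L), end = IDX + c(731L, 914L),
    nyha_class = c(2L, 3L), provenance = "proxy")
  pt <- person_time_by_class(iv)
  expect_equal(pt$days, c(731L, 183L))
  expect_equal(pt$years, c(731, 183) / 365.25)

  ehr <- generate_population(gen_config(n_patients = 50), seed = 15)
  coh <- build_cohort(ehr)
  obs <- dplyr::filter(coh, included, followup_end > index_date)
  tr <- classify_nyha(ehr, obs)
  pt_all <- person_time_by_class(tr)
  expect_equal(sum(pt_all$days),
               sum(as.integer(obs$followup_end - obs$index_date)))
  # per-patient tiling with zero slack
  per <- person_time_by_class(tr, by = "patient_class") |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(days = sum(days)) |>
    dplyr::inner_join(obs, by = "patient_id")
  expect_true(all(per$days == as.integer(per$followup_end - per$index_date)))
})

test_that("recorded codes dominate the baseline on random inputs", {
  set.seed(88)
  for (rep in 1:10) {
    k <- sample(1:4, 1)
    fx <- nyha_fixture(function(e) {
      for (j in seq_len(sample(0:3, 1))) {
        e <- add_rx(e, "A", IDX + sample(-2:28, 1),
                    sample(c("bisoprolol", "verapamil", "disopyramide"), 1))
      }
      add_code(e, "A", IDX - sample.int(300, 1),
               c("nyha_i", "nyha_ii", "nyha_iii", "nyha_iv")[k])
    })
    b <- classify_baseline(fx$ehr, fx$cohort)
    expect_equal(b$nyha_class, k)
    expect_equal(b$provenance, "recorded")
  }
})
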