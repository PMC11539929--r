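# a minimal two-cohort assignments table
mk_assignments <- function(ids, status = "agitation", index = t0) {
  data.frame(beneficiary_id = ids, status = status, index_date = index,
             smi_reasons = "", stringsAsFactors = FALSE)
}

test_that("annualized per-100 rates follow the direct formula", {
  # 10 beneficiaries, 365-day follow-up, 9 events in total -> 90 per 100 PY
  counts <- c(2, 1, 1, 1, 1, 1, 1, 1, 0, 0)
  r <- annualized_rate_per_100(counts, 365)
  expect_equal(unname(r["mean"]), 90)
  expect_equal(unname(r["sd"]), sd(counts * 100))
  z <- annualized_rate_per_100(rep(0L, 5), 365)
  expect_equal(unname(z), c(0, 0))
  # half-year follow-up doubles the annualized count
  expect_equal(unname(annualized_rate_per_100(1, 182.5)["mean"]), 200)
  expect_error(annualized_rate_per_100(1, 0), "positive")
})

test_that("post-acute summary counts zero-stay members in per-patient LOS", {
  st <- data.frame(beneficiary_id = "B1", setting = "snf", admit = t0,
                   discharge = t0 + 9, los_days = 10L)
  s <- pac_summary(st, members = c("B1", "B2"))
  snf <- s[s$setting == "snf", ]
  expect_equal(snf$los_per_patient_mean, 5)
  expect_equal(snf$los_per_stay_mean, 10)
  expect_equal(snf$proportion_with_use_pct, 50)
  overall <- s[s$setting == "overall", ]
  expect_equal(overall$los_per_patient_mean, 5)
  expect_equal(overall$n_with_use, 1L)
  # no stays anywhere: zeros and absent per-stay statistics
  s0 <- pac_summary(st[0, ], members = c("B1", "B2"))
  expect_equal(s0$los_per_patient_mean, rep(0, 6))
  expect_true(all(is.na(s0$los_per_stay_mean)))
  expect_equal(s0$proportion_with_use_pct, rep(0, 6))
})

test_that("cohort utilization reproduces hand-computed Table-2-style metrics", {
  sets <- test_code_sets()
  ids <- c("B1", "B2")
  med <- rbind(
    # identification claims (pre-index, zero cost)
    mk_claims("B1", c(-90, -55), "ICD10:F0390", prefix = "D"),
    mk_claims("B1", c(0, 40), "ICD10:G300", prefix = "A"),
    mk_claims("B2", c(-90, -55), "ICD10:F0390", prefix = "D"),
    mk_claims("B2", c(0, 40), "ICD10:G300", prefix = "A"),
    # B1: two acute stays (readmission 20 days after first discharge),
    # the first AD-specific; an ED visit inside the first stay (converted)
    # and one outside; 3 outpatient visits; a 10-day SNF stay
    mk_claims("B1", 10, end_days = 14, dx = "ICD10:G300|ICD10:I10",
              setting = "inpatient_acute", prefix = "H1"),
    mk_claims("B1", 34, end_days = 36, dx = "ICD10:J189",
              setting = "inpatient_acute", prefix = "H2"),
    mk_claims("B1", 12, dx = "ICD10:I10", setting = "emergency", prefix = "E1"),
    mk_claims("B1", 100, dx = "ICD10:I10", setting = "emergency", prefix = "E2"),
    mk_claims("B1", c(50, 60, 70), dx = "ICD10:I10", setting = "outpatient",
              prefix = "O"),
    mk_claims("B1", 200, end_days = 209, dx = "ICD10:I10", setting = "snf",
              prefix = "S"))
  b <- mk_bundle(med, ids = ids)
  asg <- mk_assignments(ids)
  u <- utilization_summary(b, asg, sets)
  g <- function(m) u[u$metric == m & u$cohort == "agitation", ]

  expect_equal(g("hospitalizations_all_cause_per100py")$mean, 100)  # 2 stays / 2 members
  expect_equal(g("acute_los_per_patient")$mean, 4)   # (5+3+0)/2
  expect_equal(g("acute_los_per_stay")$mean, 4)      # (5+3)/2
  expect_equal(g("hospitalizations_ad_specific_per100py")$mean, 50)
  expect_equal(g("ad_specific_los_per_stay")$mean, 5)
  expect_equal(g("ed_visits_per100py")$mean, 50)     # converted visit dropped
  expect_equal(g("outpatient_visits_per100py")$mean, 150)
  # one observable discharge pair: readmission at gap 20 -> 1/2 discharges
  expect_equal(g("readmission_rate_30d_pct")$mean, 50)
  expect_equal(g("pac_snf_los_per_patient")$mean, 5)
  expect_equal(g("pac_snf_los_per_stay")$mean, 10)
  expect_equal(g("pac_snf_proportion_with_use_pct")$mean, 50)
  expect_equal(g("pac_overall_los_per_patient")$mean, 5)
})

test_that("ED conversion is configurable", {
  ids <- "B1"
  med <- rbind(
    mk_claims("B1", c(-90, -55), "ICD10:F0390", prefix = "D"),
    mk_claims("B1", c(0, 40), "ICD10:G300", prefix = "A"),
    mk_claims("B1", 10, end_days = 14, dx = "ICD10:I10",
              setting = "inpatient_acute", prefix = "H"),
    mk_claims("B1", 12, dx = "ICD10:I10", setting = "emergency", prefix = "E"))
  b <- mk_bundle(med, ids = ids)
  asg <- mk_assignments(ids)
  on_ <- utilization_summary(b, asg, test_code_sets())
  off <- utilization_summary(b, asg, test_code_sets(),
                             identification_params(ed_conversion = FALSE))
  expect_equal(on_[metric == "ed_visits_per100py" & cohort == "agitation", mean], 0)
  expect_equal(off[metric == "ed_visits_per100py" & cohort == "agitation", mean], 100)
})

test_that("LOS accounting identity holds on a synthetic cohort", {
  gen <- generate_population(generator_config(600, seed = 23))
  res <- assign_cohorts(gen$bundle, default_sets_cache())
  u <- utilization_summary(gen$bundle, res$assignments, default_sets_cache())
  for (coh in unique(u$cohort)) {
    for (lbl in c("acute", "ad_specific", "pac_overall", "pac_snf",
                  "pac_hospice")) {
      pp <- u[u$cohort == coh & u$metric == paste0(lbl, "_los_per_patient"), ]
      ps <- u[u$cohort == coh & u$metric == paste0(lbl, "_los_per_stay"), ]
      if (ps$n > 0) {
        expect_equal(pp$mean * pp$n, ps$mean * ps$n, tolerance = 1e-12,
                     info = paste(coh, lbl))
      } else {
        expect_equal(pp$mean, 0)
      }
    }
    readm <- u[u$cohort == coh & u$metric == "readmission_rate_30d_pct", ]
    expect_true(is.na(readm$mean) || (readm$mean >= 0 && readm$mean <= 100))
  }
})

test_that("annualized mean equals 100 * total events / person-years", {
  set.seed(31)
  counts <- rpois(500, 1.3)
  r <- annualized_rate_per_100(counts, 365)
  expect_equal(unname(r["mean"]), 100 * sum(counts) / (500 * 365 / 365))
})
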