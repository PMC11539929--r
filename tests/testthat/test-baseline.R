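test_that("completed age is birthday-adjusted", {
  expect_equal(age_at_index(as.Date("1930-01-01"), as.Date("2013-01-01")), 83L)
  expect_equal(age_at_index(as.Date("1930-06-15"), as.Date("2013-06-14")), 82L)
  expect_equal(age_at_index(as.Date("1930-06-15"), as.Date("2013-06-15")), 83L)
  expect_error(age_at_index(as.Date("2013-01-01"), as.Date("2013-01-01")),
               "precede")
})

test_that("age agrees with a day-count calendar oracle", {
  set.seed(61)
  for (rep in 1:300) {
    birth <- as.Date("1920-01-01") + sample(0:20000, 1)
    index <- birth + sample(400:30000, 1)
    got <- age_at_index(birth, index)
    # oracle: walk anniversaries with calendar arithmetic
    approx <- floor(as.integer(index - birth) / 365.2425)
    want <- NA_integer_
    for (a in c(approx - 1L, approx, approx + 1L)) {
      anniv <- seq(birth, by = paste(a, "years"), length.out = 2)[2]
      nxt <- seq(birth, by = paste(a + 1L, "years"), length.out = 2)[2]
      if (anniv <= index && index < nxt) want <- a
    }
    expect_equal(got, want, info = paste(birth, index))
  }
})

test_that("age bands are half-open as printed", {
  expect_equal(age_band(c(64, 65, 79, 80, 100, 0)),
               c("<65", "65-<80", "65-<80", ">=80", ">=80", "<65"))
})

test_that("the Charlson score sums configured weights with hierarchy overrides", {
  cci <- read_cci_config(system.file("extdata", "cci-illustrative.yaml",
                                     package = "agitAD"))
  expect_equal(charlson_score(mk_claims("B1", 0, "ICD10:I10"), cci), 0L)
  # diabetes (1) + CHF (1) = 2
  cl <- rbind(mk_claims("B1", 0, "ICD10:E119"),
              mk_claims("B1", 5, "ICD10:I509", prefix = "X"))
  expect_equal(charlson_score(cl, cci), 2L)
  # diabetes suppressed by diabetes with complications: 2, not 3
  cl2 <- rbind(mk_claims("B1", 0, "ICD10:E119"),
               mk_claims("B1", 5, "ICD10:E1121", prefix = "X"))
  expect_equal(charlson_score(cl2, cci), 2L)
  # repeat claims do not double-count
  cl3 <- rbind(cl, mk_claims("B1", 9, "ICD10:E119", prefix = "Y"))
  expect_equal(charlson_score(cl3, cci), 2L)
  # adding a qualifying claim never decreases the score
  expect_gte(charlson_score(rbind(cl, mk_claims("B1", 11, "ICD9:1744",
                                                prefix = "Z")), cci),
             charlson_score(cl, cci))
})

test_that("the baseline profile matches a hand-computed four-patient fixture", {
  cci <- read_cci_config(system.file("extdata", "cci-illustrative.yaml",
                                     package = "agitAD"))
  ben <- data.frame(
    id = c("A1", "A2", "N1", "N2"),
    birth_date = as.Date(c("1930-01-01", "1940-01-01", "1925-06-15",
                           "1950-01-02")),
    sex = c("F", "M", "F", "F"),
    race_ethnicity = c("White", "Black", "White", "Unknown"),
    region = c("South", "South", "West", "Northeast"),
    dual_eligible = c(TRUE, FALSE, FALSE, TRUE),
    entitlement_reason = c("aged", "disability", "aged", "disability_and_ESRD"),
    cms_hcc_score = c(1.5, NA, 0.5, 2.5))
  med <- rbind(mk_claims("A1", -30, "ICD10:E119", prefix = "C"),   # baseline
               mk_claims("A1", 10, "ICD10:I509", prefix = "F"),    # follow-up: ignored
               mk_claims("N1", -183, "ICD10:E1121", prefix = "C"), # window edge: in
               mk_claims("N2", -200, "ICD10:I509", prefix = "C"))  # out of window
  asg <- data.frame(beneficiary_id = c("A1", "A2", "N1", "N2"),
                    status = c("agitation", "agitation", "no_agitation",
                               "no_agitation"),
                    index_date = t0, smi_reasons = "")
  b <- mk_bundle(med, ids = ben$id, beneficiaries = ben)
  prof <- baseline_table(b, asg, cci)
  g <- function(coh, var, lev = NULL) {
    r <- prof[prof$cohort == coh & prof$variable == var, ]
    if (!is.null(lev)) r <- r[r$level == lev & !is.na(r$level), ]
    r
  }
  expect_equal(g("agitation", "n")$n, 2L)
  expect_equal(g("agitation", "age_years")$mean, (82 + 72) / 2)  # 2012-01-01 index
  expect_equal(g("agitation", "sex", "F")$n, 1L)
  expect_equal(g("agitation", "sex", "F")$pct, 50)
  expect_equal(g("agitation", "dual_eligible", "yes")$pct, 50)
  expect_equal(g("agitation", "disability_proxy", "yes")$n, 1L)
  expect_equal(g("no_agitation", "disability_proxy", "yes")$n, 1L)  # ESRD combo
  expect_equal(g("agitation", "cms_hcc_score")$mean, 1.5)  # NA dropped
  expect_equal(g("agitation", "cms_hcc_score")$n, 1L)
  expect_equal(g("agitation", "cci_score")$mean, 0.5)      # diabetes on A1 only
  expect_equal(g("no_agitation", "cci_score")$mean, 1.0)   # E1121 (w2) in window
  expect_equal(g("no_agitation", "age_band", ">=80")$n, 1L)
  expect_equal(g("no_agitation", "age_band", "<65")$n, 1L)
})

test_that("categorical percentages sum to 100 within rounding", {
  gen <- generate_population(generator_config(400, seed = 37))
  res <- run_pipeline(gen$bundle)
  prof <- res$baseline
  for (coh in unique(prof$cohort)) {
    for (var in c("age_band", "sex", "race_ethnicity", "region",
                  "entitlement", "dual_eligible")) {
      tot <- sum(prof$pct[prof$cohort == coh & prof$variable == var])
      expect_lt(abs(tot - 100), 0.1 + 1e-9)
    }
  }
})

test_that("an all-female cohort reports Female 100.0%", {
  ben <- mk_beneficiaries(c("B1", "B2"))
  med <- rbind(mk_claims("B1", c(-90, -55), "ICD10:F0390", prefix = "D"),
               mk_claims("B1", c(0, 40), "ICD10:G300", prefix = "A"))
  asg <- data.frame(beneficiary_id = c("B1", "B2"), status = "agitation",
                    index_date = t0, smi_reasons = "")
  cci <- read_cci_config(system.file("extdata", "cci-illustrative.yaml",
                                     package = "agitAD"))
  prof <- baseline_table(mk_bundle(med, ids = ben$id), asg, cci)
  r <- prof[prof$variable == "sex" & prof$level == "F" &
              prof$cohort == "agitation", ]
  expect_equal(r$pct, 100)
  # empty cohort: n = 0 row, no statistics
  expect_equal(prof[prof$cohort == "no_agitation" & prof$variable == "n", n], 0L)
})
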