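agit_dx <- "ICD10:R455"
ad_dx <- "ICD10:G300"
dem_dx <- "ICD10:F0390"

test_that("diagnosis confirmation honors the inclusive 30-day boundary", {
  sets <- test_code_sets()
  r <- confirm_code_set(mk_claims("B1", c(0, 30), ad_dx), sets$AD, 30, 2)
  expect_true(r$confirmed)
  expect_equal(r$first_date, t0)
  expect_equal(r$qualifying_second_date, t0 + 30)

  expect_false(confirm_code_set(mk_claims("B1", c(0, 29), ad_dx),
                                sets$AD, 30, 2)$confirmed)
  expect_false(confirm_code_set(mk_claims("B1", 0, ad_dx),
                                sets$AD, 30, 2)$confirmed)
  # same-day duplicates count once
  expect_false(confirm_code_set(mk_claims("B1", c(0, 0, 0), ad_dx),
                                sets$AD, 30, 2)$confirmed)
  # spread-out triples: span decides
  expect_false(confirm_code_set(mk_claims("B1", c(0, 10, 25), ad_dx),
                                sets$AD, 30, 2)$confirmed)
  r <- confirm_code_set(mk_claims("B1", c(0, 10, 41), ad_dx), sets$AD, 30, 2)
  expect_true(r$confirmed)
  expect_equal(r$qualifying_second_date, t0 + 41)
})

test_that("confirmation respects the diagnosis-position limit", {
  sets <- test_code_sets()
  # AD code in third position: invisible to the primary/secondary search
  claims <- mk_claims("B1", c(0, 40), "ICD10:I10|ICD10:J189|ICD10:G300")
  expect_false(confirm_code_set(claims, sets$AD, 30, 2)$confirmed)
  expect_true(confirm_code_set(claims, sets$AD, 30, Inf)$confirmed)
})

test_that("the index date is the first claim of the later diagnosis", {
  sets <- test_code_sets()
  ad <- confirm_code_set(mk_claims("B1", c(0, 40), ad_dx), sets$AD, 30, 2)
  dem <- confirm_code_set(mk_claims("B1", c(60, 95), dem_dx),
                          sets$dementia, 30, 2)
  expect_equal(determine_index(ad, dem), t0 + 60)
  expect_equal(determine_index(dem, ad), t0 + 60)  # symmetric
  # tie: both first claims on the same date
  dem2 <- confirm_code_set(mk_claims("B1", c(0, 33), dem_dx),
                           sets$dementia, 30, 2)
  expect_equal(determine_index(ad, dem2), t0)
  not_conf <- confirm_code_set(mk_claims("B1", 0, dem_dx), sets$dementia, 30, 2)
  expect_error(determine_index(ad, not_conf), "confirmed")
})

test_that("random confirmed pairs match the later-of-first-dates oracle", {
  sets <- test_code_sets()
  set.seed(55)
  for (rep in 1:200) {
    d_ad <- sort(sample(0:400, sample(2:4, 1)))
    d_dem <- sort(sample(0:400, sample(2:4, 1)))
    ad <- confirm_code_set(mk_claims("B1", d_ad, ad_dx), sets$AD, 30, 2)
    dem <- confirm_code_set(mk_claims("B1", d_dem, dem_dx), sets$dementia, 30, 2)
    if (ad$confirmed && dem$confirmed) {
      expect_equal(determine_index(ad, dem), max(t0 + d_ad[1], t0 + d_dem[1]))
    }
  }
})

test_that("continuous enrollment requires full two-sided coverage", {
  idx <- as.Date("2013-01-01")
  full <- data.frame(beneficiary_id = "B1", start = idx - 183, end = idx + 365,
                     medical = TRUE, pharmacy = TRUE)
  expect_true(check_continuous_enrollment(full, idx))
  # pharmacy ends one day early
  short_rx <- rbind(full,
                    data.frame(beneficiary_id = "B1", start = idx - 183,
                               end = idx + 364, medical = FALSE, pharmacy = TRUE))
  short_rx$pharmacy[1] <- FALSE
  expect_false(check_continuous_enrollment(short_rx, idx))
  expect_true(check_continuous_enrollment(
    short_rx, idx, identification_params(enrollment_gap_tolerance_days = 1)))
})

test_that("enrollment check equals a day-by-day coverage scan", {
  set.seed(99)
  idx <- as.Date("2013-06-01")
  for (rep in 1:40) {
    n <- sample(1:5, 1)
    start <- idx - 183 + sample(-30:400, n, replace = TRUE)
    periods <- data.frame(
      beneficiary_id = "B1", start = start,
      end = start + sample(0:300, n, replace = TRUE),
      medical = sample(c(TRUE, FALSE), n, replace = TRUE),
      pharmacy = sample(c(TRUE, FALSE), n, replace = TRUE))
    tol <- sample(c(0L, 1L, 7L), 1)
    p <- identification_params(enrollment_gap_tolerance_days = tol)
    expect_equal(check_continuous_enrollment(periods, idx, p),
                 oracle_enrollment(periods, idx, tol = tol),
                 info = paste("rep", rep))
  }
})

test_that("agitation detection honors the inclusive 14-day boundary", {
  sets <- test_code_sets()
  expect_true(detect_agitation(mk_claims("B1", c(0, 14), agit_dx),
                               sets$agitation)$confirmed)
  expect_false(detect_agitation(mk_claims("B1", c(0, 13), agit_dx),
                                sets$agitation)$confirmed)
})

test_that("SMI exclusion applies per illness, not pooled", {
  sets <- test_code_sets()
  smi <- sets[c("bipolar", "MDD", "schizophrenia")]
  # one bipolar claim + one MDD claim 60 days apart: no illness qualifies
  mixed <- rbind(mk_claims("B1", 0, "ICD10:F310"),
                 mk_claims("B1", 60, "ICD10:F329", prefix = "D"))
  expect_length(detect_smi_exclusion(mixed, smi), 0L)
  # schizophrenia at exactly 30 days qualifies
  scz <- mk_claims("B1", c(0, 30), "ICD10:F200")
  expect_equal(detect_smi_exclusion(scz, smi), "schizophrenia")
  # two illnesses can qualify simultaneously
  two <- rbind(mk_claims("B1", c(0, 31), "ICD10:F310"),
               mk_claims("B1", c(5, 40), "ICD10:F200", prefix = "D"))
  expect_setequal(detect_smi_exclusion(two, smi), c("bipolar", "schizophrenia"))
})

test_that("randomized SMI mixtures match the illness-by-illness oracle", {
  sets <- test_code_sets()
  smi <- sets[c("bipolar", "MDD", "schizophrenia")]
  codes <- c(bipolar = "ICD10:F310", MDD = "ICD10:F329",
             schizophrenia = "ICD10:F200")
  set.seed(313)
  for (rep in 1:60) {
    ill <- sample(names(codes), sample(1:6, 1), replace = TRUE)
    days <- sample(0:90, length(ill), replace = TRUE)
    claims <- mk_claims("B1", days, codes[ill])
    got <- detect_smi_exclusion(claims, smi)
    want <- names(codes)[vapply(names(codes), function(lbl) {
      oracle_confirm(t0 + days[ill == lbl], 30)$confirmed
    }, logical(1))]
    expect_setequal(got, want)
  }
})

test_that("assign_cohorts walks every beneficiary through its branch", {
  sets <- test_code_sets()
  conf <- function(ben) rbind(mk_claims(ben, c(-90, -55), dem_dx, prefix = "D"),
                              mk_claims(ben, c(0, 40), ad_dx, prefix = "A"))
  med <- rbind(
    conf("AGIT"), mk_claims("AGIT", c(10, 24), agit_dx, prefix = "G"),
    conf("CTRL"),
    conf("NEAR"), mk_claims("NEAR", c(10, 23), agit_dx, prefix = "G"),
    mk_claims("NOCONF", c(0, 20), ad_dx, prefix = "A"),
    mk_claims("NOCONF", c(-90, -55), dem_dx, prefix = "D"),
    conf("SMI"), mk_claims("SMI", c(-10, 25), "ICD10:F310", prefix = "S"),
    conf("GAP"))
  ids <- c("AGIT", "CTRL", "NEAR", "NOCONF", "SMI", "GAP")
  enr <- mk_enrollment(ids)
  # GAP loses pharmacy coverage for one week inside the follow-up
  enr <- rbind(enr[enr$beneficiary_id != "GAP", ],
               data.frame(beneficiary_id = "GAP", start = test_window[1],
                          end = t0 + 99, medical = TRUE, pharmacy = TRUE),
               data.frame(beneficiary_id = "GAP", start = t0 + 100,
                          end = t0 + 106, medical = TRUE, pharmacy = FALSE),
               data.frame(beneficiary_id = "GAP", start = t0 + 107,
                          end = test_window[2], medical = TRUE, pharmacy = TRUE))
  b <- mk_bundle(med, ids = ids, enrollment = enr)
  res <- assign_cohorts(b, sets)
  asg <- as.data.frame(res$assignments)
  rownames(asg) <- asg$beneficiary_id
  expect_equal(asg["AGIT", "status"], "agitation")
  expect_equal(asg["CTRL", "status"], "no_agitation")
  expect_equal(asg["NEAR", "status"], "no_agitation")
  expect_equal(asg["NOCONF", "status"], "excluded_not_confirmed")
  expect_equal(asg["SMI", "status"], "excluded_smi")
  expect_equal(asg["SMI", "smi_reasons"], "bipolar")
  expect_equal(asg["GAP", "status"], "excluded_enrollment")
  # index date = first claim of the later (AD) diagnosis
  expect_equal(asg["AGIT", "index_date"], t0)
  att <- as.data.frame(res$attrition)
  expect_equal(att$n_remaining, c(6L, 5L, 4L, 3L))
  expect_equal(attr(res$attrition, "n_agitation"), 1L)
  expect_equal(attr(res$attrition, "n_no_agitation"), 2L)
})

test_that("SMI exclusion takes precedence over the agitation split", {
  sets <- test_code_sets()
  med <- rbind(mk_claims("B1", c(-90, -55), dem_dx, prefix = "D"),
               mk_claims("B1", c(0, 40), ad_dx, prefix = "A"),
               mk_claims("B1", c(5, 30), agit_dx, prefix = "G"),
               mk_claims("B1", c(-20, 15), "ICD10:F200", prefix = "S"))
  res <- assign_cohorts(mk_bundle(med), sets)
  expect_equal(res$assignments$status, "excluded_smi")
})

test_that("an empty bundle yields empty assignments and zero attrition", {
  b <- claims_bundle(mk_beneficiaries(character(0)),
                     mk_enrollment(character(0)),
                     mk_claims("B", integer(0))[0, ], empty_rx(), test_window)
  res <- assign_cohorts(b, test_code_sets())
  expect_equal(nrow(res$assignments), 0L)
  expect_equal(as.data.frame(res$attrition)$n_remaining, rep(0L, 4))
})

test_that("statuses partition the population and attrition telescopes", {
  gen <- generate_population(generator_config(400, seed = 17))
  res <- assign_cohorts(gen$bundle, default_sets_cache())
  expect_false(anyNA(res$assignments$status))
  expect_equal(nrow(res$assignments), nrow(gen$bundle$beneficiaries))
  att <- as.data.frame(res$attrition)
  expect_equal(att$n_remaining[1] , nrow(gen$bundle$beneficiaries))
  expect_true(all(diff(att$n_remaining) <= 0))
  expect_equal(att$n_remaining[-1] + att$n_excluded[-1],
               att$n_remaining[-4])
  expect_equal(attr(res$attrition, "n_agitation") +
                 attr(res$attrition, "n_no_agitation"),
               att$n_remaining[4])
})

test_that("confirmation is monotone in code set size and gap parameter", {
  sets <- test_code_sets()
  set.seed(21)
  for (rep in 1:30) {
    days <- sample(0:80, sample(2:5, 1))
    claims <- mk_claims("B1", days, sample(c(ad_dx, "ICD9:3310"),
                                           length(days), replace = TRUE))
    small <- code_set("AD", "ICD10", "G30", TRUE)
    if (confirm_code_set(claims, small, 30, 2)$confirmed) {
      expect_true(confirm_code_set(claims, sets$AD, 30, 2)$confirmed)
    }
    if (confirm_code_set(claims, sets$AD, 30, 2)$confirmed) {
      expect_true(confirm_code_set(claims, sets$AD, 14, 2)$confirmed)
    }
  }
})
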