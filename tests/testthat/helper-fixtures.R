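# Shared in-code fixtures and independent brute-force oracles.

test_code_sets <- function() {
  list(
    AD = code_set("AD", c("ICD9", "ICD10"), c("3310", "G30"), c(FALSE, TRUE)),
    dementia = code_set("dementia", c("ICD9", "ICD10", "ICD10", "ICD10"),
                        c("290", "F01", "F02", "F03"), TRUE),
    agitation = code_set("agitation", c("ICD9", "ICD10", "ICD10"),
                         c("7992", "R455", "R456"), TRUE),
    bipolar = code_set("bipolar", c("ICD9", "ICD10"), c("2964", "F31"), TRUE),
    MDD = code_set("MDD", c("ICD9", "ICD10"), c("2962", "F32"), TRUE),
    schizophrenia = code_set("schizophrenia", c("ICD9", "ICD10"),
                             c("295", "F20"), TRUE))
}

t0 <- as.Date("2012-01-01")
test_window <- as.Date(c("2009-07-01", "2016-12-31"))

# compact medical-claim builder: one claim per element of `days`
mk_claims <- function(ben = "B1", days = 0L, dx = "ICD10:F0390",
                      setting = "physician_service", end_days = days,
                      paid = 0, prefix = "C") {
  n <- max(length(days), length(dx), length(setting), length(paid))
  data.frame(
    claim_id = paste0(prefix, ben, "-", seq_len(n)),
    beneficiary_id = rep_len(ben, n),
    service_start = t0 + rep_len(days, n),
    service_end = t0 + rep_len(end_days, n),
    setting = rep_len(setting, n),
    diagnoses = rep_len(dx, n),
    paid_amount = rep_len(paid, n),
    stringsAsFactors = FALSE)
}

mk_beneficiaries <- function(ids, birth = as.Date("1930-06-15")) {
  n <- length(ids)
  data.frame(id = ids, birth_date = rep_len(birth, n), sex = rep_len("F", n),
             race_ethnicity = rep_len("White", n), region = rep_len("South", n),
             dual_eligible = rep_len(FALSE, n),
             entitlement_reason = rep_len("aged", n),
             cms_hcc_score = rep_len(1.0, n), stringsAsFactors = FALSE)
}

mk_enrollment <- function(ids, start = test_window[1], end = test_window[2],
                          medical = TRUE, pharmacy = TRUE) {
  n <- length(ids)
  data.frame(beneficiary_id = ids, start = rep_len(start, n),
             end = rep_len(end, n), medical = rep_len(medical, n),
             pharmacy = rep_len(pharmacy, n), stringsAsFactors = FALSE)
}

empty_rx <- function() {
  data.frame(claim_id = character(0), beneficiary_id = character(0),
             fill_date = as.Date(character(0)), paid_amount = numeric(0))
}

mk_bundle <- function(med, ids = unique(med$beneficiary_id),
                      enrollment = mk_enrollment(ids), rx = empty_rx(),
                      beneficiaries = mk_beneficiaries(ids)) {
  claims_bundle(beneficiaries, enrollment, med, rx, test_window)
}

# --- independent oracles -------------------------------------------------

# all-pairs scan of the two-claim temporal rule
oracle_confirm <- function(dates, gap) {
  d <- sort(unique(dates))
  if (!length(d)) {
    return(list(confirmed = FALSE, first = as.Date(NA), second = as.Date(NA)))
  }
  confirmed <- FALSE
  for (i in seq_along(d)) {
    for (j in seq_along(d)) {
      if (abs(as.integer(d[j] - d[i])) >= gap) confirmed <- TRUE
    }
  }
  first <- d[1]
  cand <- d[as.integer(d - first) >= gap]
  list(confirmed = confirmed, first = first,
       second = if (length(cand)) cand[1] else as.Date(NA))
}

# day-by-day coverage scan of the enrollment window
oracle_enrollment <- function(periods, index, pre = 183, post = 365, tol = 0) {
  days <- seq(index - pre, index + post, by = "day")
  covered <- function(flag_col) {
    p <- periods[periods[[flag_col]], , drop = FALSE]
    sapply(days, function(day) {
      any(p$start <= day & day <= p$end)
    })
  }
  sum(!covered("medical")) <= tol && sum(!covered("pharmacy")) <= tol
}

# day-grid interval merging: occupied runs, then close gaps <= merge_gap
oracle_stays <- function(starts, ends, merge_gap = 1L) {
  s <- as.integer(starts); e <- as.integer(ends)
  iv <- Map(c, s, e)
  repeat {
    merged <- FALSE
    for (i in seq_along(iv)) {
      for (j in seq_along(iv)) {
        if (i < j && iv[[i]][1] <= iv[[j]][2] + merge_gap &&
            iv[[j]][1] <= iv[[i]][2] + merge_gap) {
          iv[[i]] <- c(min(iv[[i]][1], iv[[j]][1]), max(iv[[i]][2], iv[[j]][2]))
          iv <- iv[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  out <- do.call(rbind, iv)
  out[order(out[, 1]), , drop = FALSE]
}

default_sets_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- read_code_sets(system.file("extdata",
                                           "codesets-illustrative.yaml",
                                           package = "agitAD"))
    }
    cache
  }
})
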