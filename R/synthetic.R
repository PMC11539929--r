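planted_patterns <- c("agitation_case", "non_agitation_control",
                      "fail_ad_confirmation", "fail_dementia_confirmation",
                      "fail_enrollment", "smi_excluded", "smi_near_miss",
                      "agitation_near_miss")

pattern_status <- c(agitation_case = "agitation",
                    non_agitation_control = "no_agitation",
                    agitation_near_miss = "no_agitation",
                    smi_near_miss = "no_agitation",
                    fail_ad_confirmation = "excluded_not_confirmed",
                    fail_dementia_confirmation = "excluded_not_confirmed",
                    fail_enrollment = "excluded_enrollment",
                    smi_excluded = "excluded_smi")

#' Default planted-pattern mix
#'
#' The default mix mirrors the attrition structure of the study population:
#' 55.3% of diagnosis-confirmed beneficiaries fail the continuous-enrollment
#' requirement, 35.8% of the enrolled are excluded for severe mental
#' illness, and 36.5% of the final analytic population are agitation cases.
#' Confirmation failures (6%) and the one-day near-miss patterns (2% of the
#' included population each) are added so every identification branch is
#' represented.
#'
#' @return named probability vector over the planted patterns (sums to 1).
#' @export
default_pattern_mix <- function() {
  p_conf <- 0.94
  p_enroll_fail <- 0.553
  p_smi <- 0.358
  p_incl <- p_conf * (1 - p_enroll_fail) * (1 - p_smi)
  mix <- c(
    fail_ad_confirmation = 0.03,
    fail_dementia_confirmation = 0.03,
    fail_enrollment = p_conf * p_enroll_fail,
    smi_excluded = p_conf * (1 - p_enroll_fail) * p_smi,
    agitation_case = p_incl * 0.365,
    agitation_near_miss = p_incl * 0.02,
    smi_near_miss = p_incl * 0.02,
    non_agitation_control = p_incl * (1 - 0.365 - 0.04))
  mix[planted_patterns]
}

#' Default per-cohort utilization and cost intensities
#'
#' Event-rate, length-of-stay, post-acute-use and cost parameters for the
#' two follow-up cohorts, taken from the published utilization table and
#' cost figure: hospitalizations 0.89 vs 0.81 per patient-year, ED visits
#' 1.15 vs 0.96, outpatient 15.99 vs 14.76, 30-day readmission 21.8% vs
#' 19.3%, acute LOS 8.96 vs 8.69 days per stay, post-acute use and per-stay
#' LOS by setting, and per-patient-per-year cost means summing to $32,322
#' vs $30,121. Rates without a published value (physician, DME, pharmacy
#' fill counts) are set to realistic Medicare magnitudes.
#'
#' @return named list with elements `agitation` and `no_agitation`.
#' @export
default_cohort_params <- function() {
  list(
    agitation = list(
      hosp_rate = 0.89, ed_rate = 1.15, outpatient_rate = 15.99,
      physician_rate = 24, dme_rate = 2, rx_rate = 30,
      acute_los_mean = 8.96, ad_principal_frac = 4 / 89,
      readmit_prob = 0.218,
      pac_use_prob = c(snf = 0.354, home_health = 0.366, ltach = 0.010,
                       irf = 0.019, hospice = 0.096),
      pac_los_mean = c(snf = 93.52, home_health = 107.63, ltach = 32.29,
                       irf = 13.37, hospice = 152.45),
      cost_pppy = c(emergency_department = 652, inpatient = 8062,
                    outpatient = 2152, physician_services_tests = 5149,
                    durable_medical_equipment = 324, prescription_drug = 4496,
                    post_acute_care = 11487),
      cost_sigma = 1.0),
    no_agitation = list(
      hosp_rate = 0.81, ed_rate = 0.96, outpatient_rate = 14.76,
      physician_rate = 24, dme_rate = 2, rx_rate = 30,
      acute_los_mean = 8.69, ad_principal_frac = 1 / 81,
      readmit_prob = 0.193,
      pac_use_prob = c(snf = 0.286, home_health = 0.382, ltach = 0.009,
                       irf = 0.026, hospice = 0.095),
      pac_los_mean = c(snf = 84.19, home_health = 105.09, ltach = 31.03,
                       irf = 13.26, hospice = 163.42),
      cost_pppy = c(emergency_department = 581, inpatient = 6970,
                    outpatient = 2133, physician_services_tests = 5080,
                    durable_medical_equipment = 420, prescription_drug = 4237,
                    post_acute_care = 10700),
      cost_sigma = 1.0))
}

#' Default demographic distributions
#'
#' Categorical distributions for the synthetic beneficiary file, matching
#' the published baseline table: 70% female, dual eligibility 45.2%, age at
#' index ~ Normal(83, 8) truncated at 45, race/region/entitlement mixes as
#' printed, and a lognormal CMS-HCC risk score with mean ~1.1.
#'
#' @return named list of distribution parameters.
#' @export
default_demography <- function() {
  list(
    sex = c(F = 0.70, M = 0.30),
    race_ethnicity = c(White = 0.82, Black = 0.114, `Hispanic/Latino` = 0.027,
                       Asian = 0.016, `North American Native` = 0.003,
                       Unknown = 0.02),
    region = c(South = 0.418, Midwest = 0.233, Northeast = 0.213,
               West = 0.134, Unknown = 0.002),
    entitlement = c(aged = 0.894, disability = 0.104, ESRD = 0.001,
                    disability_and_ESRD = 0.001),
    dual_prob = 0.452,
    age_mean = 83, age_sd = 8, age_min = 45,
    hcc_meanlog = -0.40, hcc_sdlog = 1.01, hcc_missing_prob = 0.02)
}

#' Synthetic-population generator configuration
#'
#' Validates and assembles the configuration of the seeded claims
#' generator: population size, study window, planted-pattern mix,
#' per-cohort utilization/cost intensities, and demographic distributions.
#' Fails before any output when the study window is too short to hold the
#' 183-day baseline plus 365-day follow-up around any index date.
#'
#' @param n_beneficiaries number of beneficiaries to generate.
#' @param study_window length-2 date vector (inclusive).
#' @param seed integer seed; per-beneficiary substreams are derived from it
#'   so one beneficiary's claims do not depend on the others.
#' @param pattern_mix named probability vector over the planted patterns.
#' @param cohort_params per-cohort intensities, see [default_cohort_params()].
#' @param demography see [default_demography()].
#' @param code_sets named list of [code_set()]s (default: the illustrative
#'   configuration shipped with the package).
#' @param cci_plant_rate mean number of planted baseline comorbidities per
#'   included beneficiary (Poisson).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_beneficiaries,
                             study_window = c("2009-07-01", "2016-12-31"),
                             seed = 1L,
                             pattern_mix = default_pattern_mix(),
                             cohort_params = default_cohort_params(),
                             demography = default_demography(),
                             code_sets = NULL,
                             cci_plant_rate = 1.2) {
  study_window <- as_claims_date(study_window, "study_window")
  stopifnot(length(study_window) == 2L)
  n_beneficiaries <- as.integer(n_beneficiaries)
  stopifnot(n_beneficiaries >= 0L)
  if (is.null(code_sets)) {
    code_sets <- read_code_sets(system.file("extdata",
                                            "codesets-illustrative.yaml",
                                            package = "agitAD"))
  }
  miss <- setdiff(planted_patterns, names(pattern_mix))
  if (length(miss)) {
    stop("pattern_mix missing pattern(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pattern_mix <- pattern_mix[planted_patterns]
  if (any(pattern_mix < 0) || abs(sum(pattern_mix) - 1) > 1e-9) {
    stop("pattern_mix must be nonnegative and sum to 1", call. = FALSE)
  }
  for (coh in c("agitation", "no_agitation")) {
    cp <- cohort_params[[coh]]
    rates <- c(cp$hosp_rate, cp$ed_rate, cp$outpatient_rate, cp$physician_rate,
               cp$dme_rate, cp$rx_rate)
    stopifnot(all(rates >= 0), cp$acute_los_mean >= 1,
              all(cp$pac_use_prob >= 0 & cp$pac_use_prob <= 1),
              all(cp$pac_los_mean >= 1),
              cp$readmit_prob >= 0 && cp$readmit_prob <= 1,
              all(cp$cost_pppy >= 0), cp$cost_sigma > 0)
    exp_n <- c(emergency_department = cp$ed_rate, inpatient = cp$hosp_rate,
               outpatient = cp$outpatient_rate,
               physician_services_tests = cp$physician_rate,
               durable_medical_equipment = cp$dme_rate,
               prescription_drug = cp$rx_rate,
               post_acute_care = sum(cp$pac_use_prob))
    impossible <- cp$cost_pppy > 0 & exp_n[names(cp$cost_pppy)] == 0
    if (any(impossible)) {
      stop("cohort '", coh, "': positive cost target with zero event rate: ",
           paste(names(cp$cost_pppy)[impossible], collapse = ", "),
           call. = FALSE)
    }
  }
  idx_lo <- study_window[1] + 183L
  idx_hi <- study_window[2] - 365L
  if (idx_lo > idx_hi) {
    stop("study window too short: needs room for a 183-day baseline and ",
         "365-day follow-up around an index date", call. = FALSE)
  }
  cfg <- list(n_beneficiaries = n_beneficiaries, study_window = study_window,
              seed = as.integer(seed), pattern_mix = pattern_mix,
              cohort_params = cohort_params, demography = demography,
              code_sets = code_sets, cci_plant_rate = cci_plant_rate,
              index_range = c(idx_lo, idx_hi))
  class(cfg) <- "generator_config"
  cfg
}

# deterministic per-beneficiary substream seed (kept below 2^31)
substream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647
}

icd10_cutover <- as.Date("2015-10-01")

era_system <- function(date) {
  ifelse(unclass(date) < unclass(icd10_cutover), "ICD9", "ICD10")
}

# one claim code matching `set`, in the code system of the claim-date era
pick_code <- function(set, date) {
  sys <- era_system(date)
  rows <- which(set$system == sys)
  if (!length(rows)) rows <- seq_len(nrow(set))
  i <- rows[sample.int(length(rows), 1L)]
  val <- set$value[i]
  if (set$prefix[i] && stats::runif(1) < 0.5) {
    val <- paste0(val, sample(0:9, 1L))
  }
  paste0(set$system[i], ":", val)
}

filler_icd9 <- c("4019", "486", "5990", "V700", "7242")
filler_icd10 <- c("I10", "J189", "N390", "Z0000", "M545")

filler_code <- function(date) {
  if (era_system(date) == "ICD9") {
    paste0("ICD9:", sample(filler_icd9, 1L))
  } else {
    paste0("ICD10:", sample(filler_icd10, 1L))
  }
}

# packed diagnoses with the target code at `position` and fillers before it
packed_with_target <- function(set, date, position = 1L) {
  codes <- character(position)
  if (position > 1L) {
    for (j in seq_len(position - 1L)) codes[j] <- filler_code(date)
  }
  codes[position] <- pick_code(set, date)
  paste(codes, collapse = "|")
}

#' Plant the diagnostic claims of one identification pattern
#'
#' Emits the dated diagnosis claims that force a beneficiary through a
#' chosen branch of the identification algorithm: confirmed AD and dementia
#' pairs spaced 30+ days, agitation pairs spaced 14+ days, per-illness
#' severe-mental-illness pairs spaced 30+ days — with the near-miss
#' variants violating their rule by exactly one day (29- or 13-day gaps).
#' Claims are physician-service lines with zero paid amount; codes are
#' ICD-9 before 2015-10-01 and ICD-10 after.
#'
#' @param pattern one of the planted patterns (see [default_pattern_mix()]).
#' @param anchor the intended index date (for confirmation-failure patterns,
#'   the anchor around which the failing claims are placed).
#' @param code_sets named list of [code_set()]s.
#' @param study_window length-2 Date vector; all claims are kept inside it.
#' @return list: `claims` (data.table with `service_start`, `service_end`,
#'   `setting`, `diagnoses`, `paid_amount`), `enrollment_gap` (`NULL` or a
#'   list describing the planted coverage gap).
#' @export
plant_diagnosis_pattern <- function(pattern, anchor, code_sets,
                                    study_window) {
  pattern <- match.arg(pattern, planted_patterns)
  we <- study_window[2]
  dates <- as.Date(character(0)); dx <- character(0)

  add <- function(date, set, pos_choices = 1:2, pos_prob = c(0.7, 0.3)) {
    pos <- sample(pos_choices, 1L, prob = pos_prob)
    dates <<- c(dates, date)
    dx <<- c(dx, packed_with_target(set, date, pos))
  }
  confirmed_pair <- function(set, first) {
    second <- min(first + 30L + sample(0:60, 1L), we)
    add(first, set); add(second, set)
  }
  # AD/dementia confirmation claims: one diagnosis appears first, the other
  # (the "later" one) first appears exactly at the anchor, fixing the index
  plant_confirmation <- function(fail = c("none", "ad", "dementia")) {
    fail <- match.arg(fail)
    later_is_ad <- stats::runif(1) < 0.5
    earlier_set <- if (later_is_ad) code_sets$dementia else code_sets$AD
    later_set <- if (later_is_ad) code_sets$AD else code_sets$dementia
    e1 <- anchor - 60L - sample(0:60, 1L)
    confirmed_pair(earlier_set, e1)
    fail_later <- (fail == "ad" && later_is_ad) ||
      (fail == "dementia" && !later_is_ad)
    fail_earlier <- (fail != "none") && !fail_later
    if (fail_earlier) {
      # overwrite: rebuild with the earlier diagnosis failing instead
      dates <<- as.Date(character(0)); dx <<- character(0)
      if (stats::runif(1) < 0.5) {
        add(e1, earlier_set)                      # single claim
      } else {
        add(e1, earlier_set); add(e1 + 29L, earlier_set)  # 29-day gap
      }
      confirmed_pair(later_set, anchor)
    } else if (fail_later) {
      if (stats::runif(1) < 0.5) {
        add(anchor, later_set)
      } else {
        add(anchor, later_set); add(anchor + 29L, later_set)
      }
    } else {
      confirmed_pair(later_set, anchor)
    }
  }

  enrollment_gap <- NULL
  if (pattern %in% c("fail_ad_confirmation", "fail_dementia_confirmation")) {
    plant_confirmation(if (pattern == "fail_ad_confirmation") "ad" else "dementia")
  } else {
    plant_confirmation("none")
  }

  if (pattern == "agitation_case") {
    a1 <- anchor - 120L + sample(0:320, 1L)
    a2 <- min(a1 + 14L + sample(0:60, 1L), we)
    add(a1, code_sets$agitation, 1:3, c(0.5, 0.3, 0.2))
    add(a2, code_sets$agitation, 1:3, c(0.5, 0.3, 0.2))
  } else if (pattern == "agitation_near_miss") {
    a1 <- anchor - 120L + sample(0:320, 1L)
    add(a1, code_sets$agitation, 1:3, c(0.5, 0.3, 0.2))
    add(a1 + 13L, code_sets$agitation, 1:3, c(0.5, 0.3, 0.2))
  } else if (pattern == "non_agitation_control") {
    if (stats::runif(1) < 0.3) {            # a lone agitation claim: below threshold
      add(anchor - sample(20:120, 1L), code_sets$agitation, 1:3, c(0.5, 0.3, 0.2))
    }
  } else if (pattern == "smi_excluded") {
    illness <- sample(c("bipolar", "MDD", "schizophrenia"), 1L)
    s1 <- anchor - sample(30:150, 1L)
    s2 <- min(s1 + 30L + sample(0:60, 1L), we)
    add(s1, code_sets[[illness]], 1:3, c(0.5, 0.3, 0.2))
    add(s2, code_sets[[illness]], 1:3, c(0.5, 0.3, 0.2))
    if (stats::runif(1) < 0.5) {            # agitation too: exclusion must win
      a1 <- anchor - sample(20:120, 1L)
      add(a1, code_sets$agitation, 1:3, c(0.5, 0.3, 0.2))
      add(min(a1 + 14L + sample(0:30, 1L), we), code_sets$agitation,
          1:3, c(0.5, 0.3, 0.2))
    }
  } else if (pattern == "smi_near_miss") {
    if (stats::runif(1) < 0.5) {            # same illness, 29-day gap
      illness <- sample(c("bipolar", "MDD", "schizophrenia"), 1L)
      s1 <- anchor - sample(60:150, 1L)
      add(s1, code_sets[[illness]], 1:3, c(0.5, 0.3, 0.2))
      add(s1 + 29L, code_sets[[illness]], 1:3, c(0.5, 0.3, 0.2))
    } else {                                # one claim each of two illnesses
      ill <- sample(c("bipolar", "MDD", "schizophrenia"), 2L)
      s1 <- anchor - sample(60:150, 1L)
      add(s1, code_sets[[ill[1]]], 1:3, c(0.5, 0.3, 0.2))
      add(s1 + 60L, code_sets[[ill[2]]], 1:3, c(0.5, 0.3, 0.2))
    }
  } else if (pattern == "fail_enrollment") {
    gap_len <- sample(1:30, 1L)
    gap_start <- anchor - 183L + sample.int(549L - gap_len + 1L, 1L) - 1L
    enrollment_gap <- list(start = gap_start, end = gap_start + gap_len - 1L,
                           coverage = sample(c("medical", "pharmacy", "both"), 1L))
  }

  claims <- data.table::data.table(
    service_start = dates, service_end = dates,
    setting = "physician_service", diagnoses = dx, paid_amount = 0)
  list(claims = claims, enrollment_gap = enrollment_gap)
}

#' Generate one beneficiary's follow-up utilization and costs
#'
#' Draws the 12-month post-index events of one cohort member: acute
#' hospitalizations (Poisson count, shifted-geometric length of stay,
#' readmissions planted 2-30 days after a prior discharge at a placement
#' probability calibrated so the pooled 30-day readmission rate matches
#' `readmit_prob`), ED / outpatient / physician / DME visits, post-acute
#' stays per setting, pharmacy fills, and per-claim lognormal costs whose
#' per-category means are the configured per-patient-per-year targets.
#'
#' @param cp one cohort's parameter list (see [default_cohort_params()]).
#' @param index index date; events are dated in `(index, index + 365]`.
#' @param study_window length-2 Date vector; discharge dates are clamped to
#'   its end.
#' @param code_sets named list of code sets (AD + dementia feed the
#'   AD-specific principal diagnoses).
#' @return list: `medical` (data.table of claims), `pharmacy`, and `truth`
#'   (realized event counts and total in-window cost).
#' @export
generate_followup_utilization <- function(cp, index, study_window, code_sets) {
  fu_lo <- index + 1L
  fu_hi <- index + 365L
  we <- study_window[2]
  combined_ad <- combine_code_sets(code_sets[c("AD", "dementia")], "AD_dementia")

  starts <- as.Date(character(0)); ends <- as.Date(character(0))
  settings <- character(0); dxs <- character(0); cats <- character(0)

  add_claim <- function(s, e, setting, dx, cat) {
    starts <<- c(starts, s); ends <<- c(ends, e)
    settings <<- c(settings, setting); dxs <<- c(dxs, dx); cats <<- c(cats, cat)
  }
  rand_day <- function() fu_lo + sample.int(365L, 1L) - 1L
  shifted_geom <- function(mean) 1L + stats::rgeom(1L, 1 / mean)

  # --- acute stays -------------------------------------------------------
  n_hosp <- stats::rpois(1L, cp$hosp_rate)
  admits <- integer(0); discharges <- integer(0)
  r <- cp$hosp_rate
  placement_prob <- if (r > 0) {
    min(1, cp$readmit_prob * r / (r - (1 - exp(-r))))
  } else 0
  conflicts <- function(a, d) {
    if (!length(admits)) return(FALSE)
    any(a <= discharges + 31L & d >= admits - 31L)  # keep stays well apart
  }
  for (k in seq_len(n_hosp)) {
    los <- shifted_geom(cp$acute_los_mean)
    placed <- FALSE
    if (k > 1L && stats::runif(1) < placement_prob) {
      prev <- max(discharges)
      a <- prev + sample(2:30, 1L)
      if (a <= unclass(fu_hi) && prev + 30L <= unclass(fu_hi)) {
        d <- min(a + los - 1L, unclass(we))
        admits <- c(admits, a); discharges <- c(discharges, d)
        placed <- TRUE
      }
    }
    if (!placed) {
      for (try in 1:60) {
        a <- unclass(rand_day())
        d <- min(a + los - 1L, unclass(we))
        if (!conflicts(a, d)) {
          admits <- c(admits, a); discharges <- c(discharges, d)
          placed <- TRUE
          break
        }
      }
    }
  }
  for (k in seq_along(admits)) {
    a <- as.Date(admits[k], origin = "1970-01-01")
    d <- as.Date(discharges[k], origin = "1970-01-01")
    dx1 <- if (stats::runif(1) < cp$ad_principal_frac) {
      pick_code(combined_ad, a)
    } else filler_code(a)
    add_claim(a, d, "inpatient_acute", dx1, "inpatient")
  }
  in_acute <- function(day) {
    length(admits) && any(unclass(day) >= admits & unclass(day) <= discharges)
  }

  # --- point events ------------------------------------------------------
  n_ed <- stats::rpois(1L, cp$ed_rate)
  for (k in seq_len(n_ed)) {
    day <- rand_day()
    for (try in 1:60) {
      if (!in_acute(day)) break
      day <- rand_day()
    }
    if (in_acute(day)) next
    add_claim(day, day, "emergency", filler_code(day), "emergency_department")
  }
  n_out <- stats::rpois(1L, cp$outpatient_rate)
  for (k in seq_len(n_out)) {
    day <- rand_day()
    add_claim(day, day, "outpatient", filler_code(day), "outpatient")
  }
  n_phy <- stats::rpois(1L, cp$physician_rate)
  for (k in seq_len(n_phy)) {
    day <- rand_day()
    add_claim(day, day, "physician_service", filler_code(day),
              "physician_services_tests")
  }
  n_dme <- stats::rpois(1L, cp$dme_rate)
  for (k in seq_len(n_dme)) {
    day <- rand_day()
    add_claim(day, day, "dme", "", "durable_medical_equipment")  # DME: no dx
  }

  # --- post-acute stays --------------------------------------------------
  n_pac <- 0L
  for (s in names(cp$pac_use_prob)) {
    if (stats::runif(1) < cp$pac_use_prob[[s]]) {
      a <- rand_day()
      d <- min(a + shifted_geom(cp$pac_los_mean[[s]]) - 1L, unclass(we))
      add_claim(a, as.Date(d, origin = "1970-01-01"), s, filler_code(a),
                "post_acute_care")
      n_pac <- n_pac + 1L
    }
  }

  # --- pharmacy ----------------------------------------------------------
  n_rx <- stats::rpois(1L, cp$rx_rate)
  rx_dates <- if (n_rx) fu_lo + sample.int(365L, n_rx, replace = TRUE) - 1L
              else as.Date(character(0))

  # --- costs: per-claim lognormal, category mean = PPPY target -----------
  expected_n <- c(emergency_department = cp$ed_rate, inpatient = cp$hosp_rate,
                  outpatient = cp$outpatient_rate,
                  physician_services_tests = cp$physician_rate,
                  durable_medical_equipment = cp$dme_rate,
                  prescription_drug = cp$rx_rate,
                  post_acute_care = sum(cp$pac_use_prob))
  claim_cost <- function(cat, n) {
    if (n == 0L) return(numeric(0))
    target <- cp$cost_pppy[[cat]]
    if (is.null(target) || target == 0 || expected_n[[cat]] == 0) {
      return(rep(0, n))
    }
    m <- target / expected_n[[cat]]
    stats::rlnorm(n, meanlog = log(m) - cp$cost_sigma^2 / 2,
                  sdlog = cp$cost_sigma)
  }
  paid <- numeric(length(starts))
  for (cat in unique(cats)) {
    idx <- which(cats == cat)
    paid[idx] <- claim_cost(cat, length(idx))
  }
  rx_paid <- claim_cost("prescription_drug", n_rx)

  medical <- data.table::data.table(
    service_start = starts, service_end = ends, setting = settings,
    diagnoses = dxs, paid_amount = paid)
  pharmacy <- data.table::data.table(fill_date = rx_dates,
                                     paid_amount = rx_paid)
  list(medical = medical, pharmacy = pharmacy,
       truth = list(n_hosp = length(admits), n_ed = sum(settings == "emergency"),
                    n_outpatient = n_out, n_pac_stays = n_pac,
                    total_cost = sum(paid) + sum(rx_paid)))
}

#' Generate a seeded synthetic claims population with ground truth
#'
#' Draws each beneficiary's planted pattern from `pattern_mix`, constructs
#' diagnosis claims that realize the pattern exactly under the
#' identification rules, gives included beneficiaries 12 months of
#' cohort-specific utilization and costs plus baseline comorbidity claims,
#' and returns the validated bundle together with the per-beneficiary
#' ground truth. Deterministic: the same configuration and seed reproduce
#' the output exactly, and each beneficiary has its own RNG substream
#' derived from `(seed, position)`.
#'
#' @param config a [generator_config()].
#' @return list: `bundle` (a [claims_bundle()]) and `ground_truth`
#'   (data.table: `beneficiary_id`, `pattern`, `intended_status`,
#'   `intended_index_date`, realized event counts, `total_cost`).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_beneficiaries
  ws <- config$study_window[1]; we <- config$study_window[2]
  idx_lo <- config$index_range[1]; idx_hi <- config$index_range[2]
  demo <- config$demography
  sets <- config$code_sets
  mix <- config$pattern_mix
  cci_cfg <- read_cci_config(system.file("extdata", "cci-illustrative.yaml",
                                         package = "agitAD"))
  # conditions safe to plant at baseline: no overlap with the phenotype sets
  plantable <- setdiff(names(cci_cfg$conditions), "dementia")

  ben <- vector("list", n)
  med <- vector("list", n)
  rx <- vector("list", n)
  enr <- vector("list", n)
  gt <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    id <- sprintf("B%06d", i)
    pattern <- sample(planted_patterns, 1L, prob = mix)
    status <- pattern_status[[pattern]]

    sex <- sample(names(demo$sex), 1L, prob = demo$sex)
    race <- sample(names(demo$race_ethnicity), 1L, prob = demo$race_ethnicity)
    region <- sample(names(demo$region), 1L, prob = demo$region)
    entitle <- sample(names(demo$entitlement), 1L, prob = demo$entitlement)
    dual <- stats::runif(1) < demo$dual_prob
    hcc <- if (stats::runif(1) < demo$hcc_missing_prob) NA_real_ else
      stats::rlnorm(1, demo$hcc_meanlog, demo$hcc_sdlog)
    age <- max(demo$age_min, stats::rnorm(1, demo$age_mean, demo$age_sd))
    index <- idx_lo + (if (idx_hi > idx_lo)
      sample.int(as.integer(idx_hi - idx_lo) + 1L, 1L) - 1L else 0L)
    birth <- index - as.integer(round(age * 365.25 + stats::runif(1, 0, 364)))

    planted <- plant_diagnosis_pattern(pattern, index, sets, c(ws, we))
    claims <- planted$claims

    truth_counts <- list(n_hosp = NA_integer_, n_ed = NA_integer_,
                         n_outpatient = NA_integer_, n_pac_stays = NA_integer_,
                         total_cost = NA_real_)
    rx_i <- NULL
    if (status %in% c("agitation", "no_agitation")) {
      fu <- generate_followup_utilization(config$cohort_params[[status]],
                                          index, c(ws, we), sets)
      claims <- data.table::rbindlist(list(claims, fu$medical))
      rx_i <- fu$pharmacy
      truth_counts <- fu$truth
      # baseline comorbidity claims for the Charlson profile
      k <- min(stats::rpois(1L, config$cci_plant_rate), length(plantable))
      if (k > 0L) {
        conds <- sample(plantable, k)
        for (cn in conds) {
          d <- index - sample(7:180, 1L)
          claims <- data.table::rbindlist(list(claims, data.table::data.table(
            service_start = d, service_end = d, setting = "physician_service",
            diagnoses = pick_code(cci_cfg$conditions[[cn]]$codes, d),
            paid_amount = 0)))
        }
      }
    }

    claims[, claim_id := sprintf("%s-M%03d", id, seq_len(.N))]
    claims[, beneficiary_id := id]
    med[[i]] <- claims
    if (!is.null(rx_i) && nrow(rx_i)) {
      rx_i[, claim_id := sprintf("%s-P%03d", id, seq_len(.N))]
      rx_i[, beneficiary_id := id]
      rx[[i]] <- rx_i
    }

    gap <- planted$enrollment_gap
    if (is.null(gap)) {
      enr[[i]] <- data.table::data.table(beneficiary_id = id, start = ws,
                                         end = we, medical = TRUE,
                                         pharmacy = TRUE)
    } else {
      gs <- gap$start; ge <- gap$end
      pre <- if (gs > ws) data.table::data.table(
        beneficiary_id = id, start = ws, end = gs - 1L,
        medical = TRUE, pharmacy = TRUE) else NULL
      post <- if (ge < we) data.table::data.table(
        beneficiary_id = id, start = ge + 1L, end = we,
        medical = TRUE, pharmacy = TRUE) else NULL
      mid <- if (gap$coverage == "both") NULL else data.table::data.table(
        beneficiary_id = id, start = gs, end = ge,
        medical = gap$coverage == "pharmacy",
        pharmacy = gap$coverage == "medical")
      enr[[i]] <- data.table::rbindlist(list(pre, mid, post))
    }

    ben[[i]] <- data.table::data.table(
      id = id, birth_date = birth, sex = sex, race_ethnicity = race,
      region = region, dual_eligible = dual, entitlement_reason = entitle,
      cms_hcc_score = hcc)
    gt[[i]] <- data.table::data.table(
      beneficiary_id = id, pattern = pattern, intended_status = status,
      intended_index_date = if (status == "excluded_not_confirmed")
        as.Date(NA) else index,
      n_hosp = truth_counts$n_hosp, n_ed = truth_counts$n_ed,
      n_outpatient = truth_counts$n_outpatient,
      n_pac_stays = truth_counts$n_pac_stays,
      total_cost = truth_counts$total_cost)
  }

  empty_med <- data.table::data.table(
    claim_id = character(0), beneficiary_id = character(0),
    service_start = as.Date(character(0)), service_end = as.Date(character(0)),
    setting = character(0), diagnoses = character(0), paid_amount = numeric(0))
  empty_rx <- data.table::data.table(
    claim_id = character(0), beneficiary_id = character(0),
    fill_date = as.Date(character(0)), paid_amount = numeric(0))
  med_all <- data.table::rbindlist(c(list(empty_med), med), use.names = TRUE)
  rx_all <- data.table::rbindlist(c(list(empty_rx), rx), use.names = TRUE)
  ben_all <- data.table::rbindlist(ben)
  enr_all <- data.table::rbindlist(enr)
  if (is.null(ben_all)) {
    ben_all <- data.table::data.table(
      id = character(0), birth_date = as.Date(character(0)),
      sex = character(0), race_ethnicity = character(0), region = character(0),
      dual_eligible = logical(0), entitlement_reason = character(0),
      cms_hcc_score = numeric(0))
    enr_all <- data.table::data.table(
      beneficiary_id = character(0), start = as.Date(character(0)),
      end = as.Date(character(0)), medical = logical(0), pharmacy = logical(0))
  }
  data.table::setcolorder(med_all, c("claim_id", "beneficiary_id",
                                     "service_start", "service_end",
                                     "setting", "diagnoses", "paid_amount"))
  data.table::setcolorder(rx_all, c("claim_id", "beneficiary_id", "fill_date",
                                    "paid_amount"))
  bundle <- claims_bundle(ben_all, enr_all, med_all, rx_all, c(ws, we))
  gt_all <- data.table::rbindlist(gt)
  if (is.null(gt_all)) {
    gt_all <- data.table::data.table(
      beneficiary_id = character(0), pattern = character(0),
      intended_status = character(0),
      intended_index_date = as.Date(character(0)), n_hosp = integer(0),
      n_ed = integer(0), n_outpatient = integer(0), n_pac_stays = integer(0),
      total_cost = numeric(0))
  }
  list(bundle = bundle, ground_truth = gt_all)
}
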