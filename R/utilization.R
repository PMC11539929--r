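#' Build institutional stays from claims
#'
#' Claims of one setting are merged into episodes of care: after sorting by
#' service start, a claim joins the current stay when its start date is at
#' most `merge_gap_days` after the running discharge date (so transfers and
#' interim bills collapse into one stay). Length of stay is the inclusive
#' day count `discharge - admit + 1`; a same-day stay has LOS 1. The
#' principal diagnosis is taken from position 1 of the earliest constituent
#' claim.
#'
#' @param claims medical claims (any beneficiaries; one or more settings).
#' @param setting optional setting filter (e.g. `"inpatient_acute"`).
#' @param merge_gap_days merge threshold in days (default 1: abutting and
#'   1-day-gap claims merge).
#' @return data.table of stays: `beneficiary_id`, `setting`, `admit`,
#'   `discharge`, `los_days`, `principal_system`, `principal_dx`.
#' @export
build_stays <- function(claims, setting = NULL, merge_gap_days = 1L) {
  cl <- data.table::as.data.table(claims)
  if (!is.null(setting)) cl <- cl[cl$setting %in% setting, ]
  empty <- data.table::data.table(
    beneficiary_id = character(0), setting = character(0),
    admit = as.Date(character(0)), discharge = as.Date(character(0)),
    los_days = integer(0), principal_system = NA_character_[0],
    principal_dx = NA_character_[0])
  if (!nrow(cl)) return(empty)
  data.table::setorder(cl, beneficiary_id, setting, service_start,
                       service_end, claim_id)
  cl[, .grp := island_id(as.integer(service_start), as.integer(service_end),
                         as.integer(merge_gap_days)),
     by = .(beneficiary_id, setting)]
  first_dx <- function(packed) {
    p <- packed[1L]
    if (!nzchar(p)) return(c(NA_character_, NA_character_))
    d1 <- strsplit(p, "|", fixed = TRUE)[[1L]][1L]
    c(sub(":.*$", "", d1), sub("^[^:]*:", "", d1))
  }
  stays <- cl[, {
    pd <- first_dx(diagnoses)
    .(admit = min(service_start), discharge = max(service_end),
      principal_system = pd[1L], principal_dx = pd[2L])
  }, by = .(beneficiary_id, setting, .grp)]
  stays[, los_days := as.integer(discharge - admit) + 1L]
  stays[, .grp := NULL]
  data.table::setcolorder(stays, c("beneficiary_id", "setting", "admit",
                                   "discharge", "los_days",
                                   "principal_system", "principal_dx"))
  stays[]
}

#' Filter stays to AD-specific hospitalizations
#'
#' Retains the stays whose principal diagnosis falls in the combined
#' AD + dementia code set; stays without a principal diagnosis are dropped.
#'
#' @param stays a [build_stays()] table.
#' @param ad_dementia_set the combined [code_set()].
#' @return the matching subset of `stays`.
#' @export
ad_specific_stays <- function(stays, ad_dementia_set) {
  if (!nrow(stays)) return(stays)
  keep <- !is.na(stays$principal_dx) &
    code_matches(stays$principal_system, stays$principal_dx, ad_dementia_set)
  stays[keep, ]
}

#' Annualized event rate per 100 members per year
#'
#' Each beneficiary's event count is annualized (`count * 365 /
#' followup_days`); the mean and SD over beneficiaries are reported on the
#' per-100-members-per-year scale. With the fixed 365-day follow-up this is
#' simply 100 times the mean per-patient count.
#'
#' @param event_counts integer vector, one count per beneficiary.
#' @param followup_days per-beneficiary follow-up days (recycled).
#' @return named numeric: `mean`, `sd` (per 100 members per year).
#' @export
annualized_rate_per_100 <- function(event_counts, followup_days = 365) {
  followup_days <- rep_len(followup_days, length(event_counts))
  if (any(followup_days <= 0)) {
    stop("followup_days must be positive", call. = FALSE)
  }
  ann <- event_counts * 365 / followup_days
  c(mean = mean(ann) * 100,
    sd = if (length(ann) > 1L) stats::sd(ann) * 100 else 0)
}

#' Pooled 30-day all-cause readmission rate
#'
#' Denominator: acute discharges with at least 30 observable days before
#' the beneficiary's follow-up end. Numerator: discharges followed by
#' another acute admission 1 to 30 days (inclusive) later. Transfers
#' (admission on the discharge day) are merged upstream by [build_stays()]
#' and therefore never counted as readmissions.
#'
#' @param stays acute stays (`beneficiary_id`, `admit`, `discharge`),
#'   non-overlapping per beneficiary.
#' @param followup_end named Date vector or data.frame
#'   (`beneficiary_id`, `followup_end`) giving each beneficiary's follow-up
#'   end; a single date is recycled.
#' @return list: `rate_pct` (`NA` when the denominator is 0),
#'   `numerator`, `denominator`.
#' @export
readmission_rate_30d <- function(stays, followup_end) {
  st <- data.table::as.data.table(stays)
  if (!nrow(st)) return(list(rate_pct = NA_real_, numerator = 0L, denominator = 0L))
  if (is.data.frame(followup_end)) {
    fe <- data.table::as.data.table(followup_end)
    st <- merge(st, fe, by = "beneficiary_id")
  } else {
    st[, followup_end := rep_len(followup_end, .N)]
  }
  data.table::setorder(st, beneficiary_id, admit)
  st[, next_admit := data.table::shift(admit, type = "lead"),
     by = beneficiary_id]
  st[, observable := as.integer(followup_end - discharge) >= 30L]
  st[, readmit := !is.na(next_admit) &
       as.integer(next_admit - discharge) >= 1L &
       as.integer(next_admit - discharge) <= 30L]
  den <- sum(st$observable)
  num <- sum(st$readmit & st$observable)
  list(rate_pct = if (den > 0) 100 * num / den else NA_real_,
       numerator = num, denominator = den)
}

#' Post-acute care summary by setting
#'
#' For each post-acute setting (and the pooled `overall` row across
#' settings): length of stay per patient (mean/SD over all cohort members,
#' members with no stay contributing 0), length of stay per stay (mean/SD
#' over stays; absent when there are none), and the percentage of members
#' with at least one stay.
#'
#' @param stays post-acute stays of the cohort (from [build_stays()]).
#' @param members character vector of the cohort's beneficiary ids.
#' @param settings settings to report (default the five post-acute settings).
#' @return data.table: `setting`, `los_per_patient_mean`, `los_per_patient_sd`,
#'   `los_per_stay_mean`, `los_per_stay_sd`, `n_stays`, `n_with_use`,
#'   `proportion_with_use_pct`.
#' @export
pac_summary <- function(stays, members, settings = pac_settings) {
  st <- data.table::as.data.table(stays)
  st <- st[st$setting %in% settings & st$beneficiary_id %in% members, ]
  n <- length(members)
  one <- function(sub, label) {
    per_pat <- rep(0, n)
    names(per_pat) <- members
    if (nrow(sub)) {
      tot <- sub[, .(days = sum(los_days)), by = beneficiary_id]
      per_pat[tot$beneficiary_id] <- tot$days
    }
    data.table::data.table(
      setting = label,
      los_per_patient_mean = if (n) mean(per_pat) else NA_real_,
      los_per_patient_sd = if (n > 1L) stats::sd(per_pat) else 0,
      los_per_stay_mean = if (nrow(sub)) mean(sub$los_days) else NA_real_,
      los_per_stay_sd = if (nrow(sub) > 1L) stats::sd(sub$los_days) else
        if (nrow(sub) == 1L) 0 else NA_real_,
      n_stays = nrow(sub),
      n_with_use = if (nrow(sub)) length(unique(sub$beneficiary_id)) else 0L,
      proportion_with_use_pct = if (n) 100 * (if (nrow(sub))
        length(unique(sub$beneficiary_id)) else 0L) / n else NA_real_)
  }
  rows <- data.table::rbindlist(c(list(one(st, "overall")),
                                  lapply(settings, function(s)
                                    one(st[setting == s], s))))
  rows[]
}

# Follow-up window (index, index + post_window_days]; membership test for
# event dates.
in_followup <- function(dates, index, params) {
  dates > index & dates <= index + params$post_window_days
}

#' Cohort utilization summary
#'
#' Computes the utilization panel over the 12-month follow-up
#' `(index, index + 365]` for each cohort: all-cause and AD-specific
#' hospitalizations (annualized per 100 members per year) with LOS per
#' patient and per stay, emergency-department and outpatient visit rates,
#' the pooled 30-day readmission rate, and post-acute care by setting.
#' Stays are attributed to the window by admission date; emergency claims
#' dated inside an acute stay are treated as part of the hospitalization
#' when `params$ed_conversion` is `TRUE`.
#'
#' @param bundle a [claims_bundle()].
#' @param assignments the `assignments` table from [assign_cohorts()].
#' @param code_sets named list of code sets (uses `AD` and `dementia` for
#'   the AD-specific panel).
#' @param params an [identification_params()].
#' @return object of class `utilization_summary`: a data.table keyed
#'   (`cohort`, `metric`, `mean`, `sd`, `n`).
#' @export
utilization_summary <- function(bundle, assignments, code_sets,
                                params = identification_params()) {
  asg <- data.table::as.data.table(assignments)
  asg <- asg[status %in% c("agitation", "no_agitation")]
  med <- bundle$medical_claims
  combined_ad <- combine_code_sets(code_sets[c("AD", "dementia")], "AD_dementia")

  res <- list()
  for (coh in c("agitation", "no_agitation")) {
    mem <- asg[status == coh]
    members <- mem$beneficiary_id
    n <- length(members)
    if (n == 0L) next
    idx <- mem$index_date
    names(idx) <- members
    fu_end <- idx + params$post_window_days
    cl <- merge(med, mem[, .(beneficiary_id, index_date)], by = "beneficiary_id")

    all_stays <- build_stays(cl, merge_gap_days = params$stay_merge_gap_days)
    all_stays <- merge(all_stays, mem[, .(beneficiary_id, index_date)],
                       by = "beneficiary_id")
    win_stays <- all_stays[in_followup(admit, index_date, params)]
    acute <- win_stays[setting == "inpatient_acute"]

    per_count <- function(dt) {
      cnt <- rep(0L, n); names(cnt) <- members
      if (nrow(dt)) {
        tt <- dt[, .N, by = beneficiary_id]
        cnt[tt$beneficiary_id] <- tt$N
      }
      cnt
    }
    per_los <- function(dt) {
      v <- rep(0, n); names(v) <- members
      if (nrow(dt)) {
        tt <- dt[, .(days = sum(los_days)), by = beneficiary_id]
        v[tt$beneficiary_id] <- tt$days
      }
      v
    }
    row <- function(metric, mean, sd = NA_real_, nn = n) {
      data.table::data.table(cohort = coh, metric = metric,
                             mean = as.numeric(mean), sd = as.numeric(sd),
                             n = nn)
    }
    stay_stats <- function(dt, label) {
      pl <- per_los(dt)
      data.table::rbindlist(list(
        row(paste0(label, "_los_per_patient"), mean(pl), stats::sd(pl)),
        row(paste0(label, "_los_per_stay"),
            if (nrow(dt)) mean(dt$los_days) else NA_real_,
            if (nrow(dt) > 1L) stats::sd(dt$los_days) else NA_real_,
            nrow(dt))))
    }

    hosp_rate <- annualized_rate_per_100(per_count(acute), params$post_window_days)
    ad_acute <- ad_specific_stays(acute, combined_ad)
    ad_rate <- annualized_rate_per_100(per_count(ad_acute), params$post_window_days)

    # ED visits: emergency claims in the window, minus those converted
    # into an acute stay
    ed <- cl[setting == "emergency" &
               in_followup(service_start, index_date, params)]
    if (params$ed_conversion && nrow(ed) && nrow(acute)) {
      conv <- merge(ed[, .(claim_id, beneficiary_id, service_start)],
                    acute[, .(beneficiary_id, admit, discharge)],
                    by = "beneficiary_id", allow.cartesian = TRUE)
      conv <- conv[service_start >= admit & service_start <= discharge]
      ed <- ed[!claim_id %in% conv$claim_id]
    }
    ed_rate <- annualized_rate_per_100(per_count(ed), params$post_window_days)
    outp <- cl[setting == "outpatient" &
                 in_followup(service_start, index_date, params)]
    outp_rate <- annualized_rate_per_100(per_count(outp), params$post_window_days)

    readm <- readmission_rate_30d(
      acute, mem[, .(beneficiary_id, followup_end = index_date +
                       params$post_window_days)])

    pac <- pac_summary(win_stays[setting %in% pac_settings], members)
    pac_rows <- data.table::rbindlist(lapply(seq_len(nrow(pac)), function(i) {
      s <- pac$setting[i]
      data.table::rbindlist(list(
        row(paste0("pac_", s, "_los_per_patient"),
            pac$los_per_patient_mean[i], pac$los_per_patient_sd[i]),
        row(paste0("pac_", s, "_los_per_stay"),
            pac$los_per_stay_mean[i], pac$los_per_stay_sd[i], pac$n_stays[i]),
        row(paste0("pac_", s, "_proportion_with_use_pct"),
            pac$proportion_with_use_pct[i], NA_real_, pac$n_with_use[i])))
    }))

    res[[coh]] <- data.table::rbindlist(list(
      row("hospitalizations_all_cause_per100py", hosp_rate["mean"], hosp_rate["sd"]),
      stay_stats(acute, "acute"),
      row("hospitalizations_ad_specific_per100py", ad_rate["mean"], ad_rate["sd"]),
      stay_stats(ad_acute, "ad_specific"),
      row("ed_visits_per100py", ed_rate["mean"], ed_rate["sd"]),
      row("outpatient_visits_per100py", outp_rate["mean"], outp_rate["sd"]),
      row("readmission_rate_30d_pct", readm$rate_pct, NA_real_,
          readm$denominator),
      pac_rows))
  }
  out <- data.table::rbindlist(res)
  if (!nrow(out)) {
    out <- data.table::data.table(cohort = character(0), metric = character(0),
                                  mean = numeric(0), sd = numeric(0),
                                  n = integer(0))
  }
  data.table::setattr(out, "class", c("utilization_summary", class(out)))
  out
}
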