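#' Identification algorithm parameters
#'
#' Temporal and windowing parameters of the claims-based phenotype. The
#' defaults encode the published rules: diagnosis confirmation requires 2+
#' claims 30 or more days apart (in the primary or secondary diagnosis
#' position), agitation requires 2+ claims 14 or more days apart, each
#' severe mental illness is excluded on 2+ claims 30 or more days apart,
#' and continuous enrollment covers 6 months (183 days) before through 12
#' months (365 days) after the index date with zero-day gap tolerance.
#'
#' @param ad_dementia_gap_days minimum days between qualifying AD/dementia
#'   claims (inclusive: a gap of exactly this many days qualifies).
#' @param agitation_gap_days minimum days between qualifying agitation claims.
#' @param smi_gap_days minimum days between qualifying claims of one severe
#'   mental illness.
#' @param pre_window_days baseline enrollment window before index.
#' @param post_window_days follow-up enrollment window after index.
#' @param dx_position_limit_confirmation highest diagnosis position searched
#'   for AD/dementia confirmation (2 = primary or secondary).
#' @param dx_position_limit_agitation_smi highest position searched for
#'   agitation and severe-mental-illness codes (`Inf` = any position).
#' @param agitation_search_window `"full_study_period"` (default) or
#'   `"followup_only"`.
#' @param enrollment_gap_tolerance_days uncovered days tolerated per
#'   coverage type inside the enrollment window.
#' @param stay_merge_gap_days claims this many days apart or closer are
#'   merged into one institutional stay.
#' @param ed_conversion if `TRUE`, an emergency claim dated inside an acute
#'   stay counts as part of the hospitalization, not as an ED visit.
#' @param hospice_as_pac if `TRUE`, hospice claims fall in the post-acute
#'   care cost category; otherwise they form their own category.
#' @return list of class `identification_params`.
#' @export
identification_params <- function(ad_dementia_gap_days = 30L,
                                  agitation_gap_days = 14L,
                                  smi_gap_days = 30L,
                                  pre_window_days = 183L,
                                  post_window_days = 365L,
                                  dx_position_limit_confirmation = 2L,
                                  dx_position_limit_agitation_smi = Inf,
                                  agitation_search_window = c("full_study_period",
                                                              "followup_only"),
                                  enrollment_gap_tolerance_days = 0L,
                                  stay_merge_gap_days = 1L,
                                  ed_conversion = TRUE,
                                  hospice_as_pac = TRUE) {
  agitation_search_window <- match.arg(agitation_search_window)
  p <- list(ad_dementia_gap_days = as.integer(ad_dementia_gap_days),
            agitation_gap_days = as.integer(agitation_gap_days),
            smi_gap_days = as.integer(smi_gap_days),
            pre_window_days = as.integer(pre_window_days),
            post_window_days = as.integer(post_window_days),
            dx_position_limit_confirmation = dx_position_limit_confirmation,
            dx_position_limit_agitation_smi = dx_position_limit_agitation_smi,
            agitation_search_window = agitation_search_window,
            enrollment_gap_tolerance_days = as.integer(enrollment_gap_tolerance_days),
            stay_merge_gap_days = as.integer(stay_merge_gap_days),
            ed_conversion = isTRUE(ed_conversion),
            hospice_as_pac = isTRUE(hospice_as_pac))
  stopifnot(p$ad_dementia_gap_days > 0, p$agitation_gap_days > 0,
            p$smi_gap_days > 0, p$pre_window_days > 0, p$post_window_days > 0,
            p$enrollment_gap_tolerance_days >= 0)
  class(p) <- "identification_params"
  p
}

# Matching claim dates for one beneficiary's claims against a code set,
# restricted to diagnosis positions <= position_limit. Claims may be a
# medical-claims data.frame (packed diagnoses) or a pre-built dx table.
matching_dates <- function(claims, set, position_limit = Inf) {
  if (!nrow(claims)) return(as.Date(character(0)))
  if (!"position" %in% names(claims)) {
    claims <- dx_table(list(medical_claims = data.table::as.data.table(claims)))
  }
  keep <- claims$position <= position_limit &
    code_matches(claims$system, claims$value, set)
  sort(unique(claims$service_start[keep]))
}

#' Confirm a diagnosis by the two-claim temporal rule
#'
#' A diagnosis is confirmed when the beneficiary has 2 or more claims
#' carrying a matching code, with at least `gap_days` between the earliest
#' and some later matching claim (the gap is inclusive: exactly `gap_days`
#' qualifies). Multiple claims on the same date count once.
#'
#' @param claims medical claims of one beneficiary (data.frame with packed
#'   `diagnoses`, or a [dx_table()] subset).
#' @param set the diagnosis [code_set()].
#' @param gap_days required spacing in days.
#' @param position_limit highest diagnosis position searched.
#' @return list of class `confirmation_result`: `confirmed`, `first_date`,
#'   `qualifying_second_date` (earliest matching date at least `gap_days`
#'   after `first_date`; `NA` unless confirmed).
#' @export
confirm_code_set <- function(claims, set, gap_days, position_limit = Inf) {
  d <- matching_dates(claims, set, position_limit)
  res <- list(confirmed = FALSE, first_date = as.Date(NA),
              qualifying_second_date = as.Date(NA))
  if (length(d)) {
    res$first_date <- d[1]
    qual <- d[as.integer(d - d[1]) >= gap_days]
    if (length(qual)) {
      res$confirmed <- TRUE
      res$qualifying_second_date <- qual[1]
    }
  }
  class(res) <- "confirmation_result"
  res
}

#' @export
print.confirmation_result <- function(x, ...) {
  cat(sprintf("<confirmation_result> confirmed=%s first=%s second=%s\n",
              x$confirmed, x$first_date, x$qualifying_second_date))
  invisible(x)
}

# Vectorized confirmation over all beneficiaries: dx is a dx_table(),
# returns one row per beneficiary with any matching claim.
confirm_all <- function(dx, set, gap_days, position_limit = Inf) {
  if (!nrow(dx)) {
    return(data.table::data.table(beneficiary_id = character(0),
                                  confirmed = logical(0),
                                  first_date = as.Date(character(0)),
                                  second_date = as.Date(character(0))))
  }
  keep <- dx$position <= position_limit & code_matches(dx$system, dx$value, set)
  m <- dx[keep, .(beneficiary_id, service_start)]
  if (!nrow(m)) {
    return(data.table::data.table(beneficiary_id = character(0),
                                  confirmed = logical(0),
                                  first_date = as.Date(character(0)),
                                  second_date = as.Date(character(0))))
  }
  m[, .(confirmed = max(service_start) - min(service_start) >= gap_days,
        first_date = min(service_start),
        second_date = {
          f <- min(service_start)
          q <- service_start[as.integer(service_start - f) >= gap_days]
          if (length(q)) min(q) else as.Date(NA)
        }),
    by = beneficiary_id]
}

#' Index date from the AD and dementia confirmations
#'
#' The index date is the service date of the first claim of whichever of
#' the two qualifying diagnoses (Alzheimer's disease, dementia) appeared
#' later — the date on which both diagnoses are first jointly evidenced.
#'
#' @param ad,dementia [confirm_code_set()] results, both confirmed.
#' @return the index date.
#' @export
determine_index <- function(ad, dementia) {
  if (!isTRUE(ad$confirmed) || !isTRUE(dementia$confirmed)) {
    stop("index date requires both AD and dementia to be confirmed",
         call. = FALSE)
  }
  max(ad$first_date, dementia$first_date)
}

# Covered days of [win_start, win_end] by the union of spans (inclusive
# dates). Spans: data.table with start/end. Used per coverage type.
covered_days <- function(start, end, win_start, win_end) {
  if (!length(start)) return(0L)
  s <- pmax(as.integer(start), as.integer(win_start))
  e <- pmin(as.integer(end), as.integer(win_end))
  keep <- s <= e
  if (!any(keep)) return(0L)
  s <- s[keep]; e <- e[keep]
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  grp <- island_id(s, e, join_gap = 0L)
  sum(tapply(e, grp, max) - tapply(s, grp, min) + 1L)
}

#' Continuous-enrollment check around an index date
#'
#' `TRUE` iff every day of `[index - pre_window_days, index +
#' post_window_days]` is covered by medical coverage and by pharmacy
#' coverage, tolerating at most `enrollment_gap_tolerance_days` uncovered
#' days per coverage type.
#'
#' @param periods canonical enrollment spans of one beneficiary
#'   (`start`, `end`, `medical`, `pharmacy`).
#' @param index index date.
#' @param params an [identification_params()].
#' @return logical flag.
#' @export
check_continuous_enrollment <- function(periods, index, params = identification_params()) {
  periods <- data.table::as.data.table(periods)
  win_start <- index - params$pre_window_days
  win_end <- index + params$post_window_days
  need <- as.integer(win_end - win_start) + 1L
  med <- periods[periods$medical, ]
  rxp <- periods[periods$pharmacy, ]
  miss_med <- need - covered_days(med$start, med$end, win_start, win_end)
  miss_rx <- need - covered_days(rxp$start, rxp$end, win_start, win_end)
  miss_med <= params$enrollment_gap_tolerance_days &&
    miss_rx <= params$enrollment_gap_tolerance_days
}

#' Detect agitation by the 14-day two-claim rule
#'
#' Same semantics as [confirm_code_set()] with the agitation gap (default
#' 14 days) and the agitation/SMI diagnosis-position limit. The claims
#' passed in should already reflect the configured search window.
#'
#' @inheritParams confirm_code_set
#' @param params an [identification_params()].
#' @return a `confirmation_result`.
#' @export
detect_agitation <- function(claims, set, params = identification_params()) {
  confirm_code_set(claims, set, params$agitation_gap_days,
                   params$dx_position_limit_agitation_smi)
}

#' Severe-mental-illness exclusion screen
#'
#' Each illness (bipolar disorder, major depressive disorder,
#' schizophrenia) is evaluated on its own code set: an illness qualifies
#' when the beneficiary has 2 or more claims for that illness 30 or more
#' days apart. The rule applies per illness — one bipolar claim plus one
#' MDD claim never qualifies.
#'
#' @param claims medical claims of one beneficiary.
#' @param smi_sets named list of per-illness [code_set()]s.
#' @param params an [identification_params()].
#' @return character vector of illness labels meeting the criterion.
#' @export
detect_smi_exclusion <- function(claims, smi_sets, params = identification_params()) {
  hits <- vapply(smi_sets, function(s) {
    confirm_code_set(claims, s, params$smi_gap_days,
                     params$dx_position_limit_agitation_smi)$confirmed
  }, logical(1))
  names(smi_sets)[hits]
}

#' Run the full cohort-identification algorithm
#'
#' Applies the selection steps in order: (1) AD confirmed and dementia
#' confirmed (2+ claims 30+ days apart each, primary/secondary position),
#' else `excluded_not_confirmed`; (2) index date = first claim date of the
#' later-appearing diagnosis; (3) continuous enrollment with medical and
#' pharmacy coverage for 183 days before through 365 days after index, else
#' `excluded_enrollment`; (4) any severe mental illness with 2+ claims 30+
#' days apart, `excluded_smi`; (5) remaining beneficiaries split into
#' `agitation` (2+ agitation claims 14+ days apart) vs `no_agitation`.
#'
#' @param bundle a [claims_bundle()].
#' @param code_sets named list of [code_set()]s containing at least
#'   `AD`, `dementia`, `agitation`, `bipolar`, `MDD`, `schizophrenia`.
#' @param params an [identification_params()].
#' @return list with `assignments` (data.table: `beneficiary_id`, `status`,
#'   `index_date`, `smi_reasons`) and `attrition` (class `attrition_report`).
#' @export
assign_cohorts <- function(bundle, code_sets, params = identification_params()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  need <- c("AD", "dementia", "agitation", "bipolar", "MDD", "schizophrenia")
  miss <- setdiff(need, names(code_sets))
  if (length(miss)) {
    stop("code_sets missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  ben_ids <- bundle$beneficiaries$id
  dx <- dx_table(bundle)

  out <- data.table::data.table(beneficiary_id = ben_ids,
                                status = NA_character_,
                                index_date = as.Date(NA),
                                smi_reasons = "")

  ad <- confirm_all(dx, code_sets$AD, params$ad_dementia_gap_days,
                    params$dx_position_limit_confirmation)
  dem <- confirm_all(dx, code_sets$dementia, params$ad_dementia_gap_days,
                     params$dx_position_limit_confirmation)
  both <- merge(ad[confirmed == TRUE], dem[confirmed == TRUE],
                by = "beneficiary_id", suffixes = c("_ad", "_dem"))
  both[, index_date := pmax(first_date_ad, first_date_dem)]
  out[!beneficiary_id %in% both$beneficiary_id, status := "excluded_not_confirmed"]
  out[both, index_date := i.index_date, on = "beneficiary_id"]

  confirmed_ids <- both$beneficiary_id

  # enrollment: per coverage type, union spans per beneficiary and sum
  # their overlap with [index - pre, index + post]
  enr <- bundle$enrollment
  win <- both[, .(beneficiary_id,
                  ws = index_date - params$pre_window_days,
                  we = index_date + params$post_window_days)]
  need_days <- params$pre_window_days + params$post_window_days + 1L
  cover_ok <- function(spans) {
    if (!nrow(spans)) return(character(0))
    sp <- spans[, .(beneficiary_id, start, end)]
    data.table::setorder(sp, beneficiary_id, start, end)
    sp[, .grp := island_id(as.integer(start), as.integer(end), 0L),
       by = beneficiary_id]
    sp <- sp[, .(start = min(start), end = max(end)),
             by = .(beneficiary_id, .grp)]
    j <- merge(sp, win, by = "beneficiary_id", allow.cartesian = TRUE)
    j[, ov := pmax(0L, as.integer(pmin(end, we)) - as.integer(pmax(start, ws)) + 1L)]
    cov <- j[, .(covered = sum(ov)), by = beneficiary_id]
    cov[need_days - covered <= params$enrollment_gap_tolerance_days,
        beneficiary_id]
  }
  ok_med <- cover_ok(enr[medical == TRUE & beneficiary_id %in% confirmed_ids])
  ok_rx <- cover_ok(enr[pharmacy == TRUE & beneficiary_id %in% confirmed_ids])
  enrolled_ids <- intersect(intersect(confirmed_ids, ok_med), ok_rx)
  out[beneficiary_id %in% setdiff(confirmed_ids, enrolled_ids),
      status := "excluded_enrollment"]

  # SMI exclusion (full study period, per illness)
  smi_labels <- c("bipolar", "MDD", "schizophrenia")
  smi_conf <- lapply(smi_labels, function(lbl) {
    confirm_all(dx, code_sets[[lbl]], params$smi_gap_days,
                params$dx_position_limit_agitation_smi)[confirmed == TRUE,
                                                        beneficiary_id]
  })
  names(smi_conf) <- smi_labels
  smi_map <- data.table::rbindlist(lapply(smi_labels, function(lbl) {
    data.table::data.table(beneficiary_id = smi_conf[[lbl]], illness = lbl)
  }))
  smi_by_ben <- if (nrow(smi_map)) {
    smi_map[, .(smi_reasons = paste(illness, collapse = ",")), by = beneficiary_id]
  } else smi_map
  smi_excluded_ids <- intersect(enrolled_ids,
                                unique(smi_map$beneficiary_id))
  out[beneficiary_id %in% smi_excluded_ids, status := "excluded_smi"]
  if (length(smi_excluded_ids)) {
    out[smi_by_ben[beneficiary_id %in% smi_excluded_ids],
        smi_reasons := i.smi_reasons, on = "beneficiary_id"]
  }
  included_ids <- setdiff(enrolled_ids, smi_excluded_ids)

  # agitation split
  agit_dx <- dx
  if (params$agitation_search_window == "followup_only" && nrow(dx)) {
    agit_dx <- merge(dx, both[, .(beneficiary_id, index_date)],
                     by = "beneficiary_id")
    agit_dx <- agit_dx[service_start > index_date &
                         service_start <= index_date + params$post_window_days]
  }
  agit <- confirm_all(agit_dx, code_sets$agitation, params$agitation_gap_days,
                      params$dx_position_limit_agitation_smi)
  agit_ids <- intersect(included_ids, agit[confirmed == TRUE, beneficiary_id])
  out[beneficiary_id %in% agit_ids, status := "agitation"]
  out[beneficiary_id %in% setdiff(included_ids, agit_ids), status := "no_agitation"]

  n_total <- length(ben_ids)
  n_conf <- length(confirmed_ids)
  n_enr <- length(enrolled_ids)
  n_incl <- length(included_ids)
  n_agit <- length(agit_ids)
  attrition <- data.table::data.table(
    step = c("total_beneficiaries", "ad_dementia_confirmed",
             "continuous_enrollment", "smi_exclusion"),
    n_remaining = c(n_total, n_conf, n_enr, n_incl),
    n_excluded = c(0L, n_total - n_conf, n_conf - n_enr, n_enr - n_incl))
  attr(attrition, "n_agitation") <- n_agit
  attr(attrition, "n_no_agitation") <- n_incl - n_agit
  attr(attrition, "agitation_share") <- if (n_incl > 0) n_agit / n_incl else NA_real_
  class(attrition) <- c("attrition_report", class(attrition))

  list(assignments = out[], attrition = attrition)
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("<attrition_report>\n")
  print(data.table::as.data.table(x))
  cat(sprintf("  agitation: %d  no_agitation: %d  share: %.3f\n",
              attr(x, "n_agitation"), attr(x, "n_no_agitation"),
              attr(x, "agitation_share")))
  invisible(x)
}
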