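cost_categories <- c("emergency_department", "inpatient", "outpatient",
                     "physician_services_tests", "durable_medical_equipment",
                     "prescription_drug", "post_acute_care")

setting_category_map <- c(inpatient_acute = "inpatient",
                          emergency = "emergency_department",
                          outpatient = "outpatient",
                          physician_service = "physician_services_tests",
                          dme = "durable_medical_equipment",
                          snf = "post_acute_care",
                          home_health = "post_acute_care",
                          ltach = "post_acute_care",
                          irf = "post_acute_care",
                          hospice = "post_acute_care")

#' Map claims to cost categories
#'
#' Every claim maps to exactly one of the seven cost categories: ED,
#' inpatient, outpatient, physician services/tests, durable medical
#' equipment, prescription drug, and post-acute care (skilled nursing
#' facility, home health, long-term acute care hospital, inpatient
#' rehabilitation facility, and — by default — hospice). Pharmacy claims
#' are always `prescription_drug`. An emergency claim dated inside an
#' acute stay is assigned to `inpatient` when `ed_conversion` applies.
#'
#' @param setting character vector of claim settings (use
#'   `"pharmacy"` for pharmacy claims).
#' @param hospice_as_pac map hospice into post-acute care (default) or to a
#'   separate `"hospice"` category.
#' @return character vector of categories.
#' @export
categorize_claim <- function(setting, hospice_as_pac = TRUE) {
  map <- setting_category_map
  if (!hospice_as_pac) map["hospice"] <- "hospice"
  map <- c(map, pharmacy = "prescription_drug")
  unknown <- setdiff(unique(setting), names(map))
  if (length(unknown)) {
    stop("unknown claim setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(map[setting])
}

#' Per-patient-per-year costs by category
#'
#' Sums each cohort member's paid amounts over the follow-up window
#' `(index, index + 365]` by cost category (annualized by
#' `365 / followup_days`, the identity under the fixed window), then
#' reports the cohort mean and SD per category plus the total. Members with
#' no claims in a category contribute zero, so the per-beneficiary total is
#' exactly the sum of the category amounts and the cohort total mean equals
#' the sum of category means.
#'
#' @param bundle a [claims_bundle()].
#' @param assignments the `assignments` table from [assign_cohorts()].
#' @param params an [identification_params()].
#' @return object of class `cost_summary`: data.table keyed
#'   (`cohort`, `category`, `mean_pppy`, `sd_pppy`, `n`), categories in the
#'   fixed reporting order with a `total` row per cohort.
#' @export
pppy_costs <- function(bundle, assignments, params = identification_params()) {
  asg <- data.table::as.data.table(assignments)
  asg <- asg[status %in% c("agitation", "no_agitation")]
  if (nrow(asg) && anyNA(asg$index_date)) {
    stop("cohort member without index date", call. = FALSE)
  }
  cats <- cost_categories
  if (!params$hospice_as_pac) cats <- c(cats, "hospice")

  res <- list()
  for (coh in c("agitation", "no_agitation")) {
    mem <- asg[status == coh]
    n <- nrow(mem)
    if (n == 0L) next
    cl <- merge(bundle$medical_claims,
                mem[, .(beneficiary_id, index_date)], by = "beneficiary_id")
    cl <- cl[in_followup(service_start, index_date, params)]
    cl[, category := categorize_claim(setting, params$hospice_as_pac)]
    if (params$ed_conversion && nrow(cl)) {
      acute <- build_stays(cl, "inpatient_acute",
                           params$stay_merge_gap_days)
      ed <- cl[setting == "emergency"]
      if (nrow(ed) && nrow(acute)) {
        conv <- merge(ed[, .(claim_id, beneficiary_id, service_start)],
                      acute[, .(beneficiary_id, admit, discharge)],
                      by = "beneficiary_id", allow.cartesian = TRUE)
        conv <- conv[service_start >= admit & service_start <= discharge]
        cl[claim_id %in% conv$claim_id, category := "inpatient"]
      }
    }
    rx <- merge(bundle$pharmacy_claims,
                mem[, .(beneficiary_id, index_date)], by = "beneficiary_id")
    rx <- rx[in_followup(fill_date, index_date, params)]
    spend <- data.table::rbindlist(list(
      cl[, .(beneficiary_id, category, paid_amount)],
      if (nrow(rx)) rx[, .(beneficiary_id, category = "prescription_drug",
                           paid_amount)]))
    # dense beneficiary x category grid so zero spenders stay in denominators
    grid <- data.table::CJ(beneficiary_id = mem$beneficiary_id, category = cats)
    agg <- if (nrow(spend)) {
      spend[, .(amount = sum(paid_amount)), by = .(beneficiary_id, category)]
    } else {
      data.table::data.table(beneficiary_id = character(0),
                             category = character(0), amount = numeric(0))
    }
    grid <- merge(grid, agg, by = c("beneficiary_id", "category"), all.x = TRUE)
    grid[is.na(amount), amount := 0]
    grid[, pppy := amount * 365 / params$post_window_days]
    per_cat <- grid[, .(mean_pppy = mean(pppy),
                        sd_pppy = if (.N > 1L) stats::sd(pppy) else 0,
                        n = .N), by = category]
    totals <- grid[, .(pppy = sum(pppy)), by = beneficiary_id]
    per_cat <- data.table::rbindlist(list(
      per_cat,
      data.table::data.table(category = "total",
                             mean_pppy = mean(totals$pppy),
                             sd_pppy = if (n > 1L) stats::sd(totals$pppy) else 0,
                             n = n)))
    per_cat[, cohort := coh]
    per_cat[, category := factor(category, levels = c(cats, "total"))]
    data.table::setorder(per_cat, category)
    per_cat[, category := as.character(category)]
    data.table::setcolorder(per_cat, c("cohort", "category", "mean_pppy",
                                       "sd_pppy", "n"))
    res[[coh]] <- per_cat
  }
  out <- data.table::rbindlist(res)
  if (!nrow(out)) {
    out <- data.table::data.table(cohort = character(0), category = character(0),
                                  mean_pppy = numeric(0), sd_pppy = numeric(0),
                                  n = integer(0))
  }
  data.table::setattr(out, "class", c("cost_summary", class(out)))
  out
}
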