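#' Completed age in years at the index date
#'
#' Birthday-adjusted integer age: the number of whole years elapsed between
#' birth and index.
#'
#' @param birth_date,index_date Date vectors (recycled to a common length);
#'   every birth date must precede its index date.
#' @return integer vector of completed years.
#' @export
age_at_index <- function(birth_date, index_date) {
  n <- max(length(birth_date), length(index_date))
  birth_date <- rep_len(birth_date, n)
  index_date <- rep_len(index_date, n)
  if (any(birth_date >= index_date)) {
    stop("birth_date must precede index_date", call. = FALSE)
  }
  b <- as.POSIXlt(birth_date)
  i <- as.POSIXlt(index_date)
  before_birthday <- (i$mon < b$mon) | (i$mon == b$mon & i$mday < b$mday)
  as.integer(i$year - b$year - before_birthday)
}

#' Age band as reported
#'
#' The published bands: `<65`, `65-<80` and `>=80` years.
#'
#' @param age integer vector of non-negative ages.
#' @return character vector of band labels.
#' @export
age_band <- function(age) {
  stopifnot(all(age >= 0))
  ifelse(age < 65, "<65", ifelse(age < 80, "65-<80", ">=80"))
}

#' Read a Charlson Comorbidity Index configuration
#'
#' The mapping (condition code sets, integer weights, hierarchy pairs in
#' which the severer condition suppresses the milder) ships as editable
#' YAML; the illustrative Quan-style mapping at
#' `system.file("extdata", "cci-illustrative.yaml", package = "agitAD")`
#' is non-authoritative and intended as a template.
#'
#' @param path path to the YAML file.
#' @return list of class `cci_config`: `conditions` (per label: `weight`,
#'   `codes` as a [code_set()]) and `hierarchy` (list of
#'   `(milder, severer)` pairs).
#' @export
read_cci_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$conditions) || !length(raw$conditions)) {
    stop("CCI configuration needs a 'conditions' map: ", path, call. = FALSE)
  }
  conditions <- lapply(names(raw$conditions), function(lbl) {
    c0 <- raw$conditions[[lbl]]
    w <- as.integer(c0$weight)
    if (is.na(w) || w < 1L) {
      stop("CCI condition '", lbl, "' needs an integer weight >= 1",
           call. = FALSE)
    }
    list(weight = w,
         codes = code_set(
           lbl,
           system = vapply(c0$codes, function(e) as.character(e$system), character(1)),
           code = vapply(c0$codes, function(e) as.character(e$code), character(1)),
           prefix = vapply(c0$codes, function(e) isTRUE(e$prefix), logical(1))))
  })
  names(conditions) <- names(raw$conditions)
  hierarchy <- lapply(raw$hierarchy, function(h) {
    h <- list(milder = as.character(h$milder), severer = as.character(h$severer))
    if (!all(c(h$milder, h$severer) %in% names(conditions))) {
      stop("CCI hierarchy references undefined condition(s): ",
           h$milder, " / ", h$severer, call. = FALSE)
    }
    h
  })
  structure(list(conditions = conditions, hierarchy = hierarchy),
            class = "cci_config")
}

#' Charlson Comorbidity Index of one beneficiary
#'
#' A condition is present when at least one claim in the supplied baseline
#' claims carries a matching code (any diagnosis position). Hierarchy pairs
#' are applied — a present severer condition suppresses its milder form —
#' and the score is the sum of the retained conditions' weights.
#'
#' @param claims the beneficiary's baseline-window medical claims.
#' @param cci_config a [read_cci_config()] result.
#' @return integer score.
#' @export
charlson_score <- function(claims, cci_config) {
  stopifnot(inherits(cci_config, "cci_config"))
  present <- vapply(cci_config$conditions, function(cond) {
    length(matching_dates(claims, cond$codes)) > 0L
  }, logical(1))
  for (h in cci_config$hierarchy) {
    if (present[[h$severer]]) present[[h$milder]] <- FALSE
  }
  sum(vapply(cci_config$conditions[present], `[[`, integer(1), "weight"))
}

# vectorized CCI over a cohort: dx = dx_table rows already restricted to
# each beneficiary's baseline window
charlson_scores_all <- function(dx, members, cci_config) {
  score <- rep(0L, length(members))
  names(score) <- members
  if (!nrow(dx)) return(score)
  pres <- sapply(cci_config$conditions, function(cond) {
    hit <- code_matches(dx$system, dx$value, cond$codes)
    members %in% unique(dx$beneficiary_id[hit])
  })
  pres <- matrix(pres, nrow = length(members),
                 dimnames = list(members, names(cci_config$conditions)))
  for (h in cci_config$hierarchy) {
    pres[pres[, h$severer], h$milder] <- FALSE
  }
  w <- vapply(cci_config$conditions, `[[`, integer(1), "weight")
  as.integer(pres %*% w)
}

#' Baseline characteristics table
#'
#' Table-1-style per-cohort profile: n; age mean (SD) and band counts;
#' sex, race/ethnicity, region, original-entitlement and dual-eligibility
#' frequencies with percentages (1 decimal, cohort n as denominator,
#' Unknown categories reported); the disability proxy (original Medicare
#' entitlement due to disability, with or without ESRD); CMS-HCC risk score
#' mean (SD) over beneficiaries with a score; and the Charlson Comorbidity
#' Index mean (SD) computed from claims in the 183-day baseline window
#' `[index - 183, index)`.
#'
#' @param bundle a [claims_bundle()].
#' @param assignments the `assignments` table from [assign_cohorts()].
#' @param cci_config a [read_cci_config()] result.
#' @param params an [identification_params()].
#' @return object of class `baseline_profile`: data.table
#'   (`cohort`, `variable`, `level`, `n`, `pct`, `mean`, `sd`).
#' @export
baseline_table <- function(bundle, assignments, cci_config,
                           params = identification_params()) {
  asg <- data.table::as.data.table(assignments)
  asg <- asg[status %in% c("agitation", "no_agitation")]
  dx <- dx_table(bundle)

  res <- list()
  for (coh in c("agitation", "no_agitation")) {
    mem <- asg[status == coh]
    n <- nrow(mem)
    rows <- list(data.table::data.table(
      cohort = coh, variable = "n", level = NA_character_, n = n,
      pct = NA_real_, mean = NA_real_, sd = NA_real_))
    if (n > 0L) {
      ben <- merge(bundle$beneficiaries,
                   mem[, .(id = beneficiary_id, index_date)], by = "id")
      num_row <- function(variable, x, nn = length(x)) {
        data.table::data.table(cohort = coh, variable = variable,
                               level = NA_character_, n = nn, pct = NA_real_,
                               mean = mean(x),
                               sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
      }
      cat_rows <- function(variable, values, levels) {
        cnt <- table(factor(values, levels = levels))
        data.table::data.table(cohort = coh, variable = variable,
                               level = levels, n = as.integer(cnt),
                               pct = round(100 * as.integer(cnt) / n, 1),
                               mean = NA_real_, sd = NA_real_)
      }
      age <- age_at_index(ben$birth_date, ben$index_date)
      rows <- c(rows, list(
        num_row("age_years", age),
        cat_rows("age_band", age_band(age), c(">=80", "65-<80", "<65")),
        cat_rows("sex", ben$sex, sex_levels),
        cat_rows("race_ethnicity", ben$race_ethnicity, race_levels),
        cat_rows("region", ben$region, region_levels),
        cat_rows("entitlement", ben$entitlement_reason, entitlement_levels),
        cat_rows("disability_proxy",
                 ifelse(ben$entitlement_reason %in%
                          c("disability", "disability_and_ESRD"),
                        "yes", "no"), c("yes", "no")),
        cat_rows("dual_eligible", ifelse(ben$dual_eligible, "yes", "no"),
                 c("yes", "no"))))
      hcc <- ben$cms_hcc_score[!is.na(ben$cms_hcc_score)]
      if (length(hcc)) rows <- c(rows, list(num_row("cms_hcc_score", hcc)))
      base_dx <- merge(dx, mem[, .(beneficiary_id, index_date)],
                       by = "beneficiary_id")
      base_dx <- base_dx[service_start >= index_date - params$pre_window_days &
                           service_start < index_date]
      cci <- charlson_scores_all(base_dx, mem$beneficiary_id, cci_config)
      rows <- c(rows, list(num_row("cci_score", cci)))
    }
    res[[coh]] <- data.table::rbindlist(rows)
  }
  out <- data.table::rbindlist(res)
  data.table::setattr(out, "class", c("baseline_profile", class(out)))
  out
}
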