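claim_settings <- c("inpatient_acute", "emergency", "outpatient",
                    "physician_service", "dme", "snf", "home_health",
                    "ltach", "irf", "hospice")
pac_settings <- c("snf", "home_health", "ltach", "irf", "hospice")
sex_levels <- c("F", "M", "unknown")
race_levels <- c("White", "Black", "Hispanic/Latino", "Asian",
                 "North American Native", "Unknown")
region_levels <- c("South", "Midwest", "Northeast", "West", "Unknown")
entitlement_levels <- c("aged", "disability", "ESRD", "disability_and_ESRD")

as_claims_date <- function(x, what, ids = NULL) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- is.na(out) & !is.na(x) & nzchar(as.character(x))
  bad <- bad | (is.na(x) | !nzchar(as.character(x)))
  if (any(bad)) {
    where <- if (is.null(ids)) which(bad) else ids[bad]
    stop("unparseable or missing ", what, " date(s) for: ",
         paste(utils::head(where, 10L), collapse = ", "), call. = FALSE)
  }
  out
}

# Island/merge index for inclusive integer intervals, already ordered by
# start within a group: a new island begins where start > running max end +
# join_gap (join_gap = 1 merges abutting intervals).
island_id <- function(start, end, join_gap = 1L) {
  n <- length(start)
  if (n <= 1L) return(rep(1L, n))
  run_end <- cummax(end)
  cumsum(c(TRUE, start[-1L] > run_end[-n] + join_gap))
}

#' Canonicalize enrollment periods
#'
#' Merges overlapping and abutting enrollment spans that share the same
#' beneficiary and (medical, pharmacy) coverage flags. Order-independent:
#' any permutation of the input rows yields the same canonical spans.
#'
#' @param enrollment data.frame with columns `beneficiary_id`, `start`,
#'   `end` (inclusive dates), `medical`, `pharmacy` (logical).
#' @return a data.table of canonical spans, sorted.
#' @export
canonicalize_enrollment <- function(enrollment) {
  enr <- data.table::as.data.table(enrollment)
  if (nrow(enr) == 0L) return(enr)
  bad <- enr$start > enr$end
  if (any(bad)) {
    stop("enrollment period start after end for beneficiary: ",
         paste(utils::head(enr$beneficiary_id[bad], 10L), collapse = ", "),
         call. = FALSE)
  }
  data.table::setorder(enr, beneficiary_id, medical, pharmacy, start, end)
  enr[, .grp := island_id(as.integer(start), as.integer(end)),
      by = .(beneficiary_id, medical, pharmacy)]
  out <- enr[, .(start = min(start), end = max(end)),
             by = .(beneficiary_id, medical, pharmacy, .grp)]
  out[, .grp := NULL]
  data.table::setcolorder(out, c("beneficiary_id", "start", "end",
                                 "medical", "pharmacy"))
  data.table::setorder(out, beneficiary_id, start, medical, pharmacy)
  out[]
}

#' Assemble and validate a claims bundle
#'
#' A claims bundle joins the four longitudinal tables of the data model —
#' beneficiaries, enrollment periods, medical claims, pharmacy claims —
#' under a study window, with referential integrity enforced. Diagnosis
#' codes are carried on medical claims as a packed string
#' `"SYS:CODE|SYS:CODE"` (position 1 = principal diagnosis) and are
#' normalized on construction. Enrollment periods are canonicalized.
#'
#' @param beneficiaries data.frame: `id`, `birth_date`, `sex`,
#'   `race_ethnicity`, `region`, `dual_eligible`, `entitlement_reason`,
#'   `cms_hcc_score` (precomputed risk score; may be `NA`).
#' @param enrollment data.frame: `beneficiary_id`, `start`, `end`,
#'   `medical`, `pharmacy`.
#' @param medical_claims data.frame: `claim_id`, `beneficiary_id`,
#'   `service_start`, `service_end`, `setting`, `diagnoses`, `paid_amount`.
#' @param pharmacy_claims data.frame: `claim_id`, `beneficiary_id`,
#'   `fill_date`, `paid_amount`.
#' @param study_window length-2 Date vector (inclusive).
#' @return object of class `claims_bundle`.
#' @export
claims_bundle <- function(beneficiaries, enrollment, medical_claims,
                          pharmacy_claims, study_window) {
  ben <- data.table::as.data.table(beneficiaries)
  med <- data.table::as.data.table(medical_claims)
  rx <- data.table::as.data.table(pharmacy_claims)
  study_window <- as_claims_date(study_window, "study_window")
  stopifnot(length(study_window) == 2L, study_window[1] <= study_window[2])

  ben[, birth_date := as_claims_date(birth_date, "birth", id)]
  if (!"cms_hcc_score" %in% names(ben)) ben[, cms_hcc_score := NA_real_]
  ben[, cms_hcc_score := as.numeric(cms_hcc_score)]
  ben[, dual_eligible := as.logical(dual_eligible)]
  med[, `:=`(service_start = as_claims_date(service_start, "service_start", claim_id),
             service_end = as_claims_date(service_end, "service_end", claim_id),
             paid_amount = as.numeric(paid_amount))]
  if (!"diagnoses" %in% names(med)) med[, diagnoses := ""]
  med[, diagnoses := normalize_packed_dx(diagnoses, claim_id)]
  rx[, `:=`(fill_date = as_claims_date(fill_date, "fill_date", claim_id),
            paid_amount = as.numeric(paid_amount))]
  enr <- data.table::as.data.table(enrollment)
  if (nrow(enr)) {
    enr[, `:=`(start = as_claims_date(start, "enrollment start", beneficiary_id),
               end = as_claims_date(end, "enrollment end", beneficiary_id),
               medical = as.logical(medical), pharmacy = as.logical(pharmacy))]
  }
  enr <- canonicalize_enrollment(enr)

  bundle <- structure(
    list(beneficiaries = ben[], enrollment = enr, medical_claims = med[],
         pharmacy_claims = rx[], study_window = study_window),
    class = "claims_bundle")
  validate_bundle(bundle)
  bundle
}

# Normalize a packed diagnoses column ("SYS:CODE|SYS:CODE"); empty allowed
# (validated against setting later).
normalize_packed_dx <- function(packed, claim_id) {
  packed <- as.character(packed)
  packed[is.na(packed)] <- ""
  nz <- which(nzchar(packed))
  if (!length(nz)) return(packed)
  parts <- strsplit(packed[nz], "|", fixed = TRUE)
  lens <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  sys <- sub(":.*$", "", flat)
  code <- sub("^[^:]*:", "", flat)
  bad <- !(sys %in% code_systems) | !nzchar(code)
  if (any(bad)) {
    stop("malformed diagnosis entries on claim(s): ",
         paste(utils::head(unique(rep(claim_id[nz], lens)[bad]), 10L),
               collapse = ", "), call. = FALSE)
  }
  norm <- toupper(gsub(".", "", trimws(code), fixed = TRUE))
  badn <- !nzchar(norm) | !grepl("^[A-Z0-9]+$", norm)
  if (any(badn)) {
    stop("invalid diagnosis code(s) on claim(s): ",
         paste(utils::head(unique(rep(claim_id[nz], lens)[badn]), 10L),
               collapse = ", "), call. = FALSE)
  }
  rebuilt <- vapply(split(paste(sys, norm, sep = ":"),
                          rep(seq_along(parts), lens)),
                    paste, character(1), collapse = "|")
  packed[nz] <- rebuilt
  packed
}

#' Validate a claims bundle
#'
#' Checks referential integrity (every claim and enrollment row references
#' an existing beneficiary), date sanity (service_start <= service_end,
#' birth date precedes all of a beneficiary's claims, all claim dates inside
#' the study window), enum membership and non-negative paid amounts.
#' Violations raise an error listing the offending row identifiers.
#'
#' @param bundle a [claims_bundle()].
#' @return `TRUE`, invisibly, if valid.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  ben <- bundle$beneficiaries
  med <- bundle$medical_claims
  rx <- bundle$pharmacy_claims
  enr <- bundle$enrollment
  win <- bundle$study_window

  fail <- function(msg, ids) {
    stop(msg, ": ", paste(utils::head(ids, 10L), collapse = ", "),
         if (length(ids) > 10L) sprintf(" (+%d more)", length(ids) - 10L),
         call. = FALSE)
  }
  if (anyDuplicated(ben$id)) fail("duplicate beneficiary id", unique(ben$id[duplicated(ben$id)]))
  if (any(!ben$sex %in% sex_levels)) fail("invalid sex for beneficiary", ben$id[!ben$sex %in% sex_levels])
  if (any(!ben$race_ethnicity %in% race_levels)) fail("invalid race_ethnicity for beneficiary", ben$id[!ben$race_ethnicity %in% race_levels])
  if (any(!ben$region %in% region_levels)) fail("invalid region for beneficiary", ben$id[!ben$region %in% region_levels])
  if (any(!ben$entitlement_reason %in% entitlement_levels)) fail("invalid entitlement_reason for beneficiary", ben$id[!ben$entitlement_reason %in% entitlement_levels])
  hcc_bad <- !is.na(ben$cms_hcc_score) & ben$cms_hcc_score < 0
  if (any(hcc_bad)) fail("negative cms_hcc_score for beneficiary", ben$id[hcc_bad])

  if (nrow(enr)) {
    orphan <- !enr$beneficiary_id %in% ben$id
    if (any(orphan)) fail("enrollment row for unknown beneficiary", unique(enr$beneficiary_id[orphan]))
  }
  if (nrow(med)) {
    if (anyDuplicated(med$claim_id)) fail("duplicate medical claim_id", unique(med$claim_id[duplicated(med$claim_id)]))
    orphan <- !med$beneficiary_id %in% ben$id
    if (any(orphan)) fail("medical claim for unknown beneficiary", med$claim_id[orphan])
    bad <- med$service_start > med$service_end
    if (any(bad)) fail("service_start after service_end on claim", med$claim_id[bad])
    bad <- !med$setting %in% claim_settings
    if (any(bad)) fail("unknown setting on claim", med$claim_id[bad])
    bad <- med$paid_amount < 0
    if (any(bad)) fail("negative paid_amount on claim", med$claim_id[bad])
    bad <- !nzchar(med$diagnoses) & med$setting != "dme"
    if (any(bad)) fail("missing diagnoses on non-DME claim", med$claim_id[bad])
    bad <- med$service_start < win[1] | med$service_end > win[2]
    if (any(bad)) fail("claim outside study window", med$claim_id[bad])
  }
  if (nrow(rx)) {
    if (anyDuplicated(rx$claim_id)) fail("duplicate pharmacy claim_id", unique(rx$claim_id[duplicated(rx$claim_id)]))
    orphan <- !rx$beneficiary_id %in% ben$id
    if (any(orphan)) fail("pharmacy claim for unknown beneficiary", rx$claim_id[orphan])
    bad <- rx$paid_amount < 0
    if (any(bad)) fail("negative paid_amount on pharmacy claim", rx$claim_id[bad])
    bad <- rx$fill_date < win[1] | rx$fill_date > win[2]
    if (any(bad)) fail("pharmacy claim outside study window", rx$claim_id[bad])
  }
  # birth date precedes all claims of the beneficiary
  first_claim <- data.table::rbindlist(list(
    if (nrow(med)) med[, .(beneficiary_id, d = service_start)],
    if (nrow(rx)) rx[, .(beneficiary_id, d = fill_date)]))
  if (!is.null(first_claim) && nrow(first_claim)) {
    fc <- first_claim[, .(d = min(d)), by = beneficiary_id]
    fc <- merge(fc, ben[, .(beneficiary_id = id, birth_date)], by = "beneficiary_id")
    bad <- fc$birth_date >= fc$d
    if (any(bad)) fail("birth_date not before first claim for beneficiary", fc$beneficiary_id[bad])
  }
  invisible(TRUE)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat(sprintf("  study window : %s .. %s\n", x$study_window[1], x$study_window[2]))
  cat(sprintf("  beneficiaries: %d\n", nrow(x$beneficiaries)))
  cat(sprintf("  enrollment   : %d canonical spans\n", nrow(x$enrollment)))
  cat(sprintf("  medical      : %d claims\n", nrow(x$medical_claims)))
  cat(sprintf("  pharmacy     : %d claims\n", nrow(x$pharmacy_claims)))
  invisible(x)
}

bundle_files <- c(beneficiaries = "beneficiaries.csv",
                  enrollment = "enrollment.csv",
                  medical_claims = "medical_claims.csv",
                  pharmacy_claims = "pharmacy_claims.csv",
                  study_window = "study_window.csv")

#' Read a claims bundle from delimited text tables
#'
#' Reads the four comma-separated tables (UTF-8, header row, ISO-8601 dates)
#' plus a `study_window.csv` written by [write_bundle()], validates, and
#' canonicalizes enrollment. Medical claims may carry diagnoses either as a
#' packed `diagnoses` column (`"SYS:CODE|SYS:CODE"`) or as `dx1..dxK`
#' columns (cells `"SYS:CODE"`, or bare codes with `default_dx_system`).
#'
#' @param dir directory containing `beneficiaries.csv`, `enrollment.csv`,
#'   `medical_claims.csv`, `pharmacy_claims.csv` and (optionally)
#'   `study_window.csv`.
#' @param study_window optional length-2 Date vector; overrides / replaces
#'   `study_window.csv`.
#' @param default_dx_system code system assumed for bare `dx*` columns.
#' @return a validated [claims_bundle()].
#' @export
read_bundle <- function(dir, study_window = NULL, default_dx_system = "ICD10") {
  paths <- file.path(dir, bundle_files)
  names(paths) <- names(bundle_files)
  missing <- !file.exists(paths[1:4])
  if (any(missing)) {
    stop("missing bundle table(s): ", paste(paths[1:4][missing], collapse = ", "),
         call. = FALSE)
  }
  rd <- function(p) data.table::fread(p, colClasses = "character",
                                      na.strings = "", keepLeadingZeros = TRUE)
  ben <- rd(paths["beneficiaries"])
  need <- c("id", "birth_date", "sex", "race_ethnicity", "region",
            "dual_eligible", "entitlement_reason", "cms_hcc_score")
  check_columns(ben, need, paths["beneficiaries"])
  enr <- rd(paths["enrollment"])
  check_columns(enr, c("beneficiary_id", "start", "end", "medical", "pharmacy"),
                paths["enrollment"])
  med <- rd(paths["medical_claims"])
  check_columns(med, c("claim_id", "beneficiary_id", "service_start",
                       "service_end", "setting", "paid_amount"),
                paths["medical_claims"])
  med <- unpack_dx_columns(med, default_dx_system)
  rx <- rd(paths["pharmacy_claims"])
  check_columns(rx, c("claim_id", "beneficiary_id", "fill_date", "paid_amount"),
                paths["pharmacy_claims"])
  if (is.null(study_window)) {
    if (!file.exists(paths["study_window"])) {
      stop("no study_window given and ", paths["study_window"], " not found",
           call. = FALSE)
    }
    sw <- data.table::fread(paths["study_window"], colClasses = "character")
    study_window <- c(sw$start[1], sw$end[1])
  }
  ben[, sex := ifelse(is.na(sex), "unknown", sex)]
  claims_bundle(ben, enr, med, rx, study_window)
}

check_columns <- function(dt, need, path) {
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  invisible(TRUE)
}

unpack_dx_columns <- function(med, default_dx_system) {
  if ("diagnoses" %in% names(med)) return(med)
  dxcols <- grep("^dx[0-9]+$", names(med), value = TRUE)
  if (!length(dxcols)) {
    stop("medical claims need a 'diagnoses' column or dx1..dxK columns",
         call. = FALSE)
  }
  dxcols <- dxcols[order(as.integer(sub("^dx", "", dxcols)))]
  cells <- as.matrix(med[, dxcols, with = FALSE])
  cells[is.na(cells)] <- ""
  bare <- nzchar(cells) & !grepl(":", cells, fixed = TRUE)
  cells[bare] <- paste0(default_dx_system, ":", cells[bare])
  med[, diagnoses := apply(cells, 1L, function(r) paste(r[nzchar(r)], collapse = "|"))]
  med[, (dxcols) := NULL]
  med
}

#' Write a claims bundle to delimited text tables
#'
#' Writes the bundle's tables as CSV into `out_dir`, plus `study_window.csv`.
#' The round trip `read_bundle(write_bundle(b))` reproduces every field,
#' and identical bundles produce byte-identical files.
#'
#' @param bundle a [claims_bundle()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, bundle_files)
  names(paths) <- names(bundle_files)
  wr <- function(dt, p) data.table::fwrite(dt, p, na = "", dateTimeAs = "ISO")
  wr(bundle$beneficiaries, paths["beneficiaries"])
  wr(bundle$enrollment, paths["enrollment"])
  wr(bundle$medical_claims, paths["medical_claims"])
  wr(bundle$pharmacy_claims, paths["pharmacy_claims"])
  wr(data.table::data.table(start = bundle$study_window[1],
                            end = bundle$study_window[2]),
     paths["study_window"])
  invisible(paths)
}

#' Long diagnosis table of a bundle
#'
#' Unpacks the per-claim packed diagnoses into one row per (claim, position)
#' with normalized `system` and `value` columns — the working format of the
#' identification module.
#'
#' @param bundle a [claims_bundle()].
#' @return data.table: `claim_id`, `beneficiary_id`, `service_start`,
#'   `setting`, `position`, `system`, `value`.
#' @export
dx_table <- function(bundle) {
  med <- bundle$medical_claims
  empty <- data.table::data.table(
    claim_id = character(0), beneficiary_id = character(0),
    service_start = as.Date(character(0)), setting = character(0),
    position = integer(0), system = character(0), value = character(0))
  if (!nrow(med)) return(empty)
  nz <- which(nzchar(med$diagnoses))
  if (!length(nz)) return(empty)
  parts <- strsplit(med$diagnoses[nz], "|", fixed = TRUE)
  lens <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  out <- data.table::data.table(
    claim_id = rep(med$claim_id[nz], lens),
    beneficiary_id = rep(med$beneficiary_id[nz], lens),
    service_start = rep(med$service_start[nz], lens),
    setting = rep(med$setting[nz], lens),
    position = unlist(lapply(lens, seq_len), use.names = FALSE),
    system = sub(":.*$", "", flat),
    value = sub("^[^:]*:", "", flat))
  out
}
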