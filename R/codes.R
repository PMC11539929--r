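#' Normalize a raw diagnosis code
#'
#' Administrative claims carry ICD-9-CM / ICD-10-CM codes in inconsistent
#' shapes ("G30.0", "g300", " 331.0 "). All code handling in this package
#' operates on a canonical form: upper case, no dot, alphanumeric only.
#' Normalization is idempotent.
#'
#' @param raw character vector of raw code strings.
#' @param system code system, `"ICD9"` or `"ICD10"` (recycled; kept for
#'   validation symmetry, normalization itself is system-agnostic).
#' @return character vector of normalized code values.
#' @examples
#' normalize_code("G30.0", "ICD10")  # "G300"
#' normalize_code("331.0", "ICD9")   # "3310"
#' @export
normalize_code <- function(raw, system = c("ICD9", "ICD10")) {
  system <- match.arg(system[1L], c("ICD9", "ICD10"))
  if (length(raw) == 0L) return(character(0))
  val <- toupper(gsub(".", "", trimws(raw), fixed = TRUE))
  bad <- !nzchar(val) | !grepl("^[A-Z0-9]+$", val)
  if (any(bad)) {
    stop("invalid diagnosis code(s) after normalization: ",
         paste(sprintf("'%s'", raw[bad]), collapse = ", "),
         call. = FALSE)
  }
  val
}

code_systems <- c("ICD9", "ICD10")

#' Construct a diagnosis code set
#'
#' A code set is the unit of phenotype configuration: a labelled collection
#' of (system, code, prefix) entries. An exact entry matches a claim code
#' equal to it; a prefix entry matches any claim code starting with it.
#' Matching is always system-aware: an ICD-9 code never matches an ICD-10
#' entry.
#'
#' @param label single string naming the set (e.g. `"AD"`, `"agitation"`).
#' @param system character vector, `"ICD9"`/`"ICD10"` per entry.
#' @param code character vector of code values (normalized on construction).
#' @param prefix logical vector; `TRUE` entries match by prefix.
#' @return an object of class `code_set`: a data.frame with columns
#'   `system`, `value`, `prefix` and attribute `label`.
#' @export
code_set <- function(label, system, code, prefix = FALSE) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  n <- length(code)
  if (n == 0L) stop("code set '", label, "' has no entries", call. = FALSE)
  system <- rep_len(as.character(system), n)
  prefix <- rep_len(as.logical(prefix), n)
  if (!all(system %in% code_systems)) {
    stop("unknown code system(s): ",
         paste(unique(setdiff(system, code_systems)), collapse = ", "),
         call. = FALSE)
  }
  value <- vapply(seq_len(n), function(i) normalize_code(code[i], system[i]),
                  character(1))
  key <- paste(system, value, prefix)
  if (anyDuplicated(key)) {
    stop("duplicate entries in code set '", label, "': ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  out <- data.frame(system = system, value = value, prefix = prefix,
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("code_set", class(out))
  out
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf("<code_set '%s'> %d entries\n", attr(x, "label"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Match normalized codes against a code set
#'
#' @param system character vector of code systems for the codes to test.
#' @param value character vector of normalized code values (same length).
#' @param set a [code_set()].
#' @return logical vector: `TRUE` where some entry of `set` matches.
#' @examples
#' ad <- code_set("AD", c("ICD10", "ICD9"), c("G30", "3310"), c(TRUE, FALSE))
#' code_matches("ICD10", "G300", ad)  # TRUE (prefix)
#' code_matches("ICD9",  "G300", ad)  # FALSE (system mismatch)
#' @export
code_matches <- function(system, value, set) {
  stopifnot(inherits(set, "code_set"))
  n <- max(length(system), length(value))
  system <- rep_len(system, n)
  value <- rep_len(value, n)
  hit <- logical(n)
  for (i in seq_len(nrow(set))) {
    same_sys <- system == set$system[i]
    if (set$prefix[i]) {
      hit <- hit | (same_sys & startsWith(value, set$value[i]))
    } else {
      hit <- hit | (same_sys & value == set$value[i])
    }
  }
  hit
}

#' Read phenotype code sets from a YAML configuration file
#'
#' The file maps each label to a list of entries with fields `system`,
#' `code` and optional `prefix` (default `FALSE`):
#' ```yaml
#' AD:
#'   - {system: ICD10, code: G30, prefix: true}
#'   - {system: ICD9,  code: "3310"}
#' ```
#'
#' @param path path to the YAML file.
#' @return named list of [code_set()] objects.
#' @seealso [write_code_sets()]; an illustrative configuration ships at
#'   `system.file("extdata", "codesets-illustrative.yaml", package = "agitAD")`.
#' @export
read_code_sets <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw) || is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop("code-set configuration must map labels to entry lists: ", path,
         call. = FALSE)
  }
  if (anyDuplicated(names(raw))) {
    stop("duplicate code-set labels in ", path, call. = FALSE)
  }
  out <- lapply(names(raw), function(lbl) {
    entries <- raw[[lbl]]
    code_set(
      label = lbl,
      system = vapply(entries, function(e) as.character(e$system), character(1)),
      code = vapply(entries, function(e) as.character(e$code), character(1)),
      prefix = vapply(entries, function(e) isTRUE(e$prefix), logical(1))
    )
  })
  names(out) <- names(raw)
  out
}

#' Write code sets to a YAML configuration file
#'
#' Inverse of [read_code_sets()]: `read_code_sets(write_code_sets(x, f))`
#' reproduces `x`.
#'
#' @param sets named list of [code_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_code_sets <- function(sets, path) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  obj <- lapply(sets, function(s) {
    lapply(seq_len(nrow(s)), function(i) {
      list(system = s$system[i], code = s$value[i], prefix = s$prefix[i])
    })
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

# Union of several code sets (used for the combined AD+dementia set).
combine_code_sets <- function(sets, label = "combined") {
  stopifnot(length(sets) >= 1L)
  df <- unique(do.call(rbind, lapply(sets, function(s) as.data.frame(s))))
  code_set(label, df$system, df$value, df$prefix)
}
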