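#' Diagnosis code sets
#'
#' A labelled set of ICD-9 / ICD-10 codes, used to flag prior colorectal
#' cancer or surveillance-relevant conditions (polyps, inflammatory bowel
#' disease) in participant code lists.
#'
#' @param label Human-readable label.
#' @param codes Character vector of ICD-9 (e.g. `"153.4"`) or ICD-10
#'   (e.g. `"C18.4"`) codes; must be non-empty and syntactically valid.
#' @return An object of class `crc_code_set`.
#' @export
code_set <- function(label, codes) {
  codes <- as.character(codes)
  if (length(codes) == 0) stop("code set '", label, "' must be non-empty")
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$", codes) |  # ICD-10
        grepl("^[0-9]{3}(\\.[0-9]{1,2})?$", codes)            # ICD-9
  if (!all(ok))
    stop("syntactically invalid code(s): ", paste(codes[!ok], collapse = ", "))
  structure(list(label = label, codes = codes), class = "crc_code_set")
}

#' @export
print.crc_code_set <- function(x, ...) {
  cat("<crc_code_set> ", x$label, ": ", length(x$codes), " codes\n", sep = "")
  invisible(x)
}

#' Colorectal cancer diagnosis codes
#'
#' The ICD-9 (153.0-153.9, 154.0, 154.1, 154.8) and ICD-10 (C18.0-C18.9,
#' C19, C20, C21.8) codes defining colorectal cancer for the prior-diagnosis
#' exclusion and the incident outcome.
#'
#' @return A `crc_code_set`.
#' @export
crc_code_set <- function() {
  code_set("colorectal cancer",
           c(sprintf("153.%d", 0:9), "154.0", "154.1", "154.8",
             sprintf("C18.%d", 0:9), "C19", "C20", "C21.8"))
}

#' Colorectal polyp and IBD codes
#'
#' Codes flagging participants likely to be in colonoscopic surveillance
#' programmes: history of colorectal polyp or inflammatory bowel disease.
#'
#' @return A `crc_code_set`.
#' @export
surveillance_code_set <- function() {
  code_set("colorectal polyp / IBD",
           c("K63.5", "D12.6",                       # polyps
             "K50", "K50.0", "K50.1", "K50.8", "K50.9",   # Crohn's
             "K51", "K51.0", "K51.2", "K51.3", "K51.5", "K51.8", "K51.9"))
}

# Split a semicolon-delimited code cell into a character vector.
split_codes <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

# TRUE for each record whose code list intersects the code set.
# Vectorised for large cohorts: only non-empty cells are inspected.
codes_match <- function(code_cells, set) {
  out <- logical(length(code_cells))
  nonempty <- nzchar(code_cells) & !is.na(code_cells)
  if (any(nonempty)) {
    parts <- strsplit(code_cells[nonempty], ";", fixed = TRUE)
    out[nonempty] <- vapply(parts, function(cc)
      any(trimws(cc) %in% set$codes), logical(1))
  }
  out
}

#' Read / write a cohort table
#'
#' Plain CSV, one row per participant; the empty field is the missing
#' marker; ICD codes live in a semicolon-delimited
#' `prior_diagnosis_codes` cell. Logical columns (`family_history`,
#' `aspirin` and the like) are stored as `TRUE`/`FALSE`.
#'
#' @param path CSV path.
#' @return `read_cohort` returns a data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("prior_diagnosis_codes" %in% names(df)) {
    df$prior_diagnosis_codes[is.na(df$prior_diagnosis_codes)] <- ""
    df$prior_diagnosis_codes <- as.character(df$prior_diagnosis_codes)
  }
  df
}

#' @rdname read_cohort
#' @param cohort Data frame of participant records.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
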