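# Shared validators and text normalisation helpers.

DUI_RE <- "^D\\d+$"
TREE_RE <- "^[A-Z]\\d{2}(\\.\\d+)*$"
ICD_STEM_RE <- "^[A-Z]\\d{2,}[0-9A-Z]*$"
ATC_RE <- "^[A-Z](\\d{2}([A-Z]([A-Z](\\d{2})?)?)?)?$"

is_dui <- function(x) grepl(DUI_RE, x)
is_tree_number <- function(x) grepl(TREE_RE, x)

#' Normalise an ICD-10 code for comparison
#'
#' Billing extracts write the same code with or without a dot ("E10.1" vs
#' "E101"); comparison is always on the dot-stripped, upper-cased form.
#'
#' @param code Character vector of raw ICD-10 codes.
#' @return Character vector of normalised codes.
#' @export
#' @examples
#' normalize_icd(c("E10.1", "e063"))
normalize_icd <- function(code) {
  toupper(gsub(".", "", code, fixed = TRUE))
}

#' Fold accents and case for text matching
#'
#' Transliterates to ASCII (so French clinical text like "diabète"
#' matches the pattern stem "diab") and lower-cases. Applied to both pattern
#' literals and documents so matching is accent- and case-insensitive.
#'
#' @param x Character vector.
#' @return Character vector, accent-folded and lower-cased.
#' @export
#' @examples
#' fold_text("Diabète de type 1")
fold_text <- function(x) {
  tolower(stringi::stri_trans_general(x, "Latin-ASCII"))
}

# stop with a classed error carrying the offending field
stop_field <- function(msg, ..., class = "litcomorbid_error") {
  abort(sprintf(msg, ...), class = class)
}

# require columns in a data frame, with a caller-facing message
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_field("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}
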