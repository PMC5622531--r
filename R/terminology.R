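# Terminology detectors: ICD-10 patterns (descendant / OR semantics),
# ATC prefixes, and text regex patterns forming the review catalog.

#' ICD-10 code pattern
#'
#' A pattern is one or more alternative code stems (the `|` of a billing
#' catalog entry such as `"E271|E272"`), optionally covering all descending
#' codes (a trailing `*` in the compact spec, the "all descending nodes"
#' convention of diagnosis-code catalogs). Stems are stored dot-stripped and
#' upper-cased.
#'
#' @param spec Compact pattern string: alternatives joined by `|`, trailing
#'   `*` for descendant semantics (e.g. `"E10*"`, `"E271|E272"`).
#' @return An `icd_pattern` object.
#' @export
#' @examples
#' icd_matches(icd_pattern("E10*"), "E10.1")
#' icd_matches(icd_pattern("E271|E272"), "E273")
icd_pattern <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  descendant <- grepl("\\*$", spec)
  body <- sub("\\*$", "", spec)
  alternatives <- normalize_icd(strsplit(body, "|", fixed = TRUE)[[1]])
  alternatives <- alternatives[nzchar(alternatives)]
  if (length(alternatives) == 0 || any(!grepl(ICD_STEM_RE, alternatives))) {
    stop_field("invalid ICD-10 pattern '%s'", spec, class = "litcomorbid_parse_error")
  }
  structure(list(alternatives = alternatives, descendant = descendant),
            class = "icd_pattern")
}

#' @export
format.icd_pattern <- function(x, ...) {
  paste0(paste(x$alternatives, collapse = "|"), if (x$descendant) "*" else "")
}

#' @export
print.icd_pattern <- function(x, ...) {
  cat("<icd_pattern>", format(x), "\n")
  invisible(x)
}

#' Match ICD-10 codes against a pattern
#'
#' Codes are dot-stripped and upper-cased before comparison. An exact pattern
#' matches only its own stems; a descendant pattern also matches any code
#' beginning with a stem.
#'
#' @param pattern An [icd_pattern()].
#' @param code Character vector of raw ICD-10 codes.
#' @return Logical vector.
#' @export
icd_matches <- function(pattern, code) {
  stopifnot(inherits(pattern, "icd_pattern"))
  code <- normalize_icd(code)
  hit <- rep(FALSE, length(code))
  for (stem in pattern$alternatives) {
    hit <- hit | if (pattern$descendant) startsWith(code, stem) else code == stem
  }
  hit
}

#' Match ATC codes against a prefix
#'
#' ATC codes are hierarchical: a prefix at any of the five levels (1, 3, 4,
#' 5 or 7 characters) covers every code beneath it, so a short stem covers
#' all formulations of a drug family.
#'
#' @param prefix ATC code or prefix (1, 3, 4, 5 or 7 characters).
#' @param code Character vector of 7-character ATC codes.
#' @return Logical vector.
#' @export
#' @examples
#' atc_matches("A10A", "A10AB01")
atc_matches <- function(prefix, code) {
  prefix <- toupper(prefix)
  if (!grepl(ATC_RE, prefix)) {
    stop_field("invalid ATC prefix '%s'", prefix, class = "litcomorbid_parse_error")
  }
  code <- toupper(code)
  bad <- !grepl("^[A-Z]\\d{2}[A-Z]{2}\\d{2}$", code)
  if (any(bad)) {
    stop_field("malformed ATC code '%s'", code[bad][1],
               class = "litcomorbid_parse_error")
  }
  startsWith(code, prefix)
}

#' Text term pattern
#'
#' A regular expression applied case-insensitively to accent-folded text.
#' Patterns are word-boundary anchored unless they already carry their own
#' anchors or `anchor = FALSE`. `fuzzy = TRUE` additionally enables
#' approximate token matching (edit distance 1) for plain-word patterns.
#'
#' @param pattern Regular expression (applied to folded, lower-case text).
#' @param label Human-readable term name; defaults to the pattern.
#' @param fuzzy Enable approximate matching for this term.
#' @param anchor Add `\\b` word-boundary anchors around the pattern.
#' @return A one-row tibble (`pattern`, `label`, `fuzzy`).
#' @export
term_pattern <- function(pattern, label = pattern, fuzzy = FALSE, anchor = TRUE) {
  force(label)
  pattern <- fold_text(pattern)
  if (anchor && !grepl("\\\\b", pattern)) {
    pattern <- paste0("\\b", pattern, "\\b")
  }
  ok <- tryCatch({ stringr::str_detect("", stringr::regex(pattern)); TRUE },
                 error = function(e) FALSE)
  if (!ok) {
    stop_field("term pattern '%s' does not compile", pattern,
               class = "litcomorbid_parse_error")
  }
  tibble(pattern = pattern, label = label, fuzzy = isTRUE(fuzzy))
}

#' Assemble a disease mapping
#'
#' Bundles the three detector families for one disease: ICD-10 patterns,
#' ATC prefixes and text term patterns. At least one detector is required.
#'
#' @param dui Descriptor identifier of the disease.
#' @param name Disease name.
#' @param icd Character vector of compact ICD pattern specs (may be empty).
#' @param atc Character vector of ATC prefixes (may be empty).
#' @param terms List of term specs: strings or `list(pattern=, fuzzy=)`.
#' @return A one-row tibble with list-columns `icd`, `atc`, `terms`.
#' @export
disease_mapping <- function(dui, name = dui, icd = character(),
                            atc = character(), terms = list()) {
  if (!is_dui(dui)) stop_field("invalid descriptor identifier '%s'", dui)
  icd_pats <- purrr::map(as.character(icd), function(s) {
    tryCatch(icd_pattern(s), error = function(e) {
      stop_field("disease %s: %s", dui, conditionMessage(e),
                 class = "litcomorbid_parse_error")
    })
  })
  atc <- toupper(as.character(atc))
  bad_atc <- atc[!grepl(ATC_RE, sub("\\*$", "", atc))]
  if (length(bad_atc) > 0) {
    stop_field("disease %s: invalid ATC prefix '%s'", dui, bad_atc[1],
               class = "litcomorbid_parse_error")
  }
  atc <- sub("\\*$", "", atc)  # trailing * is implicit in prefix semantics
  term_tbl <- purrr::map_dfr(terms, function(t) {
    if (is.character(t)) return(term_pattern(t))
    tryCatch(
      term_pattern(t$pattern, label = t$label %||% t$pattern,
                   fuzzy = isTRUE(t$fuzzy),
                   anchor = !isFALSE(t$anchor)),
      error = function(e) stop_field("disease %s: %s", dui, conditionMessage(e),
                                     class = "litcomorbid_parse_error"))
  })
  if (nrow(term_tbl) == 0) {
    term_tbl <- tibble(pattern = character(), label = character(), fuzzy = logical())
  }
  if (length(icd_pats) + length(atc) + nrow(term_tbl) == 0) {
    stop_field("disease %s has no detectors (icd, atc or terms required)", dui,
               class = "litcomorbid_parse_error")
  }
  tibble(dui = dui, name = name, icd = list(icd_pats), atc = list(atc),
         terms = list(term_tbl))
}

#' Read a terminology-mapping configuration
#'
#' Parses a YAML (or JSON) config of per-disease detectors:
#' ```yaml
#' diseases:
#'   - dui: D003922
#'     name: Diabetes Mellitus, Type 1
#'     icd: ["E10*"]
#'     atc: ["A10A"]
#'     terms:
#'       - pattern: "diab\\w+"
#' ```
#' A trailing `*` on an ICD entry encodes descendant semantics; `|` separates
#' alternatives. Every pattern is validated and compiled; a disease with no
#' detectors at all is rejected.
#'
#' @param file Path to the YAML/JSON mapping config.
#' @return A mapping tibble, one row per disease, list-columns `icd`, `atc`,
#'   `terms`.
#' @export
read_mapping_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  parse_mapping_config(cfg)
}

#' @rdname read_mapping_config
#' @param cfg A list as produced by reading the YAML config.
#' @export
parse_mapping_config <- function(cfg) {
  if (is.null(cfg$diseases)) {
    stop_field("mapping config has no 'diseases' entry",
               class = "litcomorbid_parse_error")
  }
  out <- purrr::map_dfr(cfg$diseases, function(d) {
    disease_mapping(dui = d$dui, name = d$name %||% d$dui,
                    icd = unlist(d$icd) %||% character(),
                    atc = unlist(d$atc) %||% character(),
                    terms = d$terms %||% list())
  })
  dup <- out$dui[duplicated(out$dui)]
  if (length(dup) > 0) {
    stop_field("duplicate disease mapping for %s", paste(dup, collapse = ", "),
               class = "litcomorbid_parse_error")
  }
  out
}

#' Serialise a mapping tibble back to config form
#'
#' Inverse of [parse_mapping_config()]: `parse_mapping_config(serialize_mappings(m))`
#' reproduces `m`.
#'
#' @param mappings Mapping tibble from [read_mapping_config()].
#' @param file Optional path; when given the YAML is written there.
#' @return The config list, invisibly when `file` is given.
#' @export
serialize_mappings <- function(mappings, file = NULL) {
  cfg <- list(diseases = purrr::pmap(mappings, function(dui, name, icd, atc, terms) {
    list(dui = dui, name = name,
         icd = purrr::map_chr(icd, format),
         atc = as.list(atc),
         terms = purrr::pmap(terms, function(pattern, label, fuzzy) {
           list(pattern = pattern, label = label, fuzzy = fuzzy, anchor = FALSE)
         }))
  }))
  if (!is.null(file)) {
    yaml::write_yaml(cfg, file)
    return(invisible(cfg))
  }
  cfg
}
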